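#' Configuration for the synthetic population generator
#'
#' Bundles and validates the parameters of [simulate_dataset()]. Defaults
#' emulate a closed, intensively monitored population of resident killer
#' whales: roughly ninety individuals in six social communities followed
#' over 1976-2010 (two-year sampling periods before 1990, annual networks
#' after), each individual sighted about 31 times per year in groups
#' averaging 2.5 animals, with strong within-community dyadic preference
#' heterogeneity and mortality concentrated in low-salmon years.
#'
#' @param n_individuals Population size (default 88).
#' @param n_communities Number of true social communities (default 6).
#' @param years Study years (default 1976:2010).
#' @param pooling Pooling rule passed to [assign_sampling_periods()]
#'   (default: two-year periods 1976-1989, annual thereafter).
#' @param mean_obs_per_whale_year Target mean sightings per individual per
#'   year (default 31.3).
#' @param mean_group_size Target mean group size (default 2.5).
#' @param max_group_size Hard cap on group size (default 24).
#' @param groups_per_encounter Mean number of association groups per
#'   encounter (default 2).
#' @param p_within,p_between Relative propensity to join a group seeded by a
#'   member of one's own vs. another community (defaults 1 and 0.01; must
#'   satisfy `p_within > p_between`).
#' @param dyad_cv Coefficient of variation of the latent within-community
#'   dyadic affinities (gamma distributed, mean 1; default 3). Large values
#'   reproduce the strong social differentiation (some strong bonds, many
#'   weak ones) seen in real association data.
#' @param sociability_sd Log-scale standard deviation of an individual
#'   gregariousness multiplier (log-normal, mean 1; default 0). Positive
#'   values make some individuals consistently central and others
#'   consistently peripheral within their community, emulating the wide
#'   spread of node centralities seen in real association networks.
#' @param equal_community_sizes If `TRUE`, communities are as equal-sized as
#'   possible instead of multinomially dispersed. Useful in recovery
#'   experiments where the mechanical link between community size and
#'   normalized degree would otherwise confound within-community effects.
#' @param homogeneous_density If `TRUE`, within-community affinities are
#'   rescaled so every community has the same mean affinity. Dyad-level
#'   heterogeneity is preserved but community-level density differences are
#'   removed, which concentrates a planted centrality effect in the
#'   within-community variance component — the component a within-community
#'   node-permutation test is built to detect.
#' @param sex_ratio Proportion male (default 0.5).
#' @param p_sex_unknown Proportion of individuals whose recorded sex is `U`
#'   (true sex is retained in the ground truth; default 0.05).
#' @param salmon_log_mean,salmon_log_sd Log-normal parameters of the annual
#'   abundance index (defaults log(1000) and 0.6).
#' @param hazard List of log-hazard coefficients: `beta0` (baseline annual
#'   log-hazard), `beta_centrality_male`, `beta_centrality_female` (effect
#'   of realized within-community normalized degree, by sex),
#'   `beta_salmon` (effect of a low-salmon period), `beta_interaction`
#'   (additional male centrality effect in low-salmon periods). Defaults:
#'   baseline ~1.7% annual mortality, tripled hazard in low-salmon periods
#'   (so roughly half of deaths fall in the lowest-quartile years), male
#'   degree hazard ratio 0.21, no female or interaction effect.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 88,
                             n_communities = 6,
                             years = 1976:2010,
                             pooling = data.frame(
                               from = c(1976, 1990), to = c(1989, 2010),
                               width = c(2, 1)),
                             mean_obs_per_whale_year = 31.3,
                             mean_group_size = 2.5,
                             max_group_size = 24,
                             groups_per_encounter = 2,
                             p_within = 1,
                             p_between = 0.01,
                             dyad_cv = 3,
                             sociability_sd = 0,
                             equal_community_sizes = FALSE,
                             homogeneous_density = FALSE,
                             sex_ratio = 0.5,
                             p_sex_unknown = 0.05,
                             salmon_log_mean = log(1000),
                             salmon_log_sd = 0.6,
                             hazard = list(),
                             seed = 1) {
  hz <- list(beta0 = log(0.0167),
             beta_centrality_male = log(0.21),
             beta_centrality_female = 0,
             beta_salmon = log(3),
             beta_interaction = 0)
  unknown <- setdiff(names(hazard), names(hz))
  if (length(unknown)) stop_socsurv("unknown hazard parameter(s): ",
                                    paste(unknown, collapse = ", "))
  hz[names(hazard)] <- hazard
  cfg <- list(n_individuals = n_individuals, n_communities = n_communities,
              years = sort(unique(as.integer(years))), pooling = pooling,
              mean_obs_per_whale_year = mean_obs_per_whale_year,
              mean_group_size = mean_group_size,
              max_group_size = max_group_size,
              groups_per_encounter = groups_per_encounter,
              p_within = p_within, p_between = p_between,
              dyad_cv = dyad_cv, sociability_sd = sociability_sd,
              equal_community_sizes = isTRUE(equal_community_sizes),
              homogeneous_density = isTRUE(homogeneous_density),
              sex_ratio = sex_ratio,
              p_sex_unknown = p_sex_unknown,
              salmon_log_mean = salmon_log_mean,
              salmon_log_sd = salmon_log_sd,
              hazard = hz, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_individuals < 2) stop_socsurv("need at least 2 individuals")
    if (n_communities < 1) stop_socsurv("n_communities must be >= 1")
    if (mean_group_size > n_individuals) {
      stop_socsurv("infeasible config: mean_group_size exceeds population size")
    }
    if (mean_group_size < 1) stop_socsurv("mean_group_size must be >= 1")
    if (!(p_within > p_between)) stop_socsurv("require p_within > p_between")
    probs <- c(p_between, sex_ratio, p_sex_unknown)
    if (any(probs < 0 | probs > 1) || p_within <= 0 || p_within > 1) {
      stop_socsurv("propensities and probabilities must lie in [0, 1]")
    }
    if (mean_obs_per_whale_year <= 0) {
      stop_socsurv("mean_obs_per_whale_year must be positive")
    }
    invisible(NULL)
  })
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic population config: %d individuals, %d communities, %d years (%d-%d), seed %d\n",
    x$n_individuals, x$n_communities, length(x$years), min(x$years),
    max(x$years), x$seed))
  invisible(x)
}

#' Simulate a grouped-sighting dataset with known ground truth
#'
#' Generates a full synthetic study — encounter table, individual registry,
#' annual abundance series — together with the ground truth needed for
#' parameter-recovery experiments. The generative model is:
#'
#' 1. An annual abundance index is drawn log-normally; sampling periods in
#'    the lowest quartile of the period-level index are "low" resource
#'    periods (the same rule the analysis applies).
#' 2. Individuals are split into communities and every within-community
#'    dyad receives a latent gamma-distributed affinity (mean 1, CV
#'    `dyad_cv`), creating the strong-bonds/weak-bonds structure typical of
#'    association data.
#' 3. Each year, encounters containing one or more association groups are
#'    generated: a group grows around a randomly chosen seed individual,
#'    other individuals joining with weight proportional to
#'    community propensity x dyadic affinity; an individual appears at most
#'    once per encounter. Group counts are set so the expected sightings
#'    per individual and the mean group size match the configuration.
#' 4. At the end of each sampling period every living individual may die
#'    with piecewise-exponential probability
#'    `1 - exp(-w * exp(log-hazard))` (`w` the period width in years) where
#'    the log-hazard is `beta0 + beta_sex * c + beta_salmon * low +
#'    beta_interaction * c * low * male`, and `c` is the individual's
#'    realized within-community normalized degree in that period (computed
#'    from the simulated sightings and the true partition; 0 if unsighted).
#'    Dead individuals produce no later sightings.
#'
#' @param config A [synthetic_config()].
#' @return List with `encounters`, `registry`, `salmon` (annual series),
#'   `truth` (class `ground_truth`: `true_partition`, `true_centrality`
#'   data frame, `hazard`, `death_period`, `true_sex`, `period_map`), and
#'   `period_map`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  k <- config$n_communities
  ids <- sprintf("W%03d", seq_len(n))

  # communities: every community at least 2 members, mean n/k
  sizes <- if (k == 1L) n else if (config$equal_community_sizes) {
    s <- rep(n %/% k, k)
    if (n %% k) s[seq_len(n %% k)] <- s[seq_len(n %% k)] + 1L
    s
  } else {
    spare <- n - 2L * k
    if (spare < 0) stop_socsurv("too many communities for the population")
    as.vector(rmultinom(1L, spare, rep(1 / k, k))) + 2L
  }
  comm <- rep(seq_len(k), sizes)

  # latent dyadic affinities (within-community heterogeneity)
  shape <- if (config$dyad_cv > 0) 1 / config$dyad_cv^2 else Inf
  A <- matrix(1, n, n)
  if (is.finite(shape)) {
    up <- upper.tri(A)
    g <- matrix(0, n, n)
    g[up] <- rgamma(sum(up), shape = shape, rate = shape)
    A <- g + t(g)
  }
  if (config$sociability_sd > 0) {
    soc <- rlnorm(n, -config$sociability_sd^2 / 2, config$sociability_sd)
    A <- A * outer(soc, soc)
  }
  same <- outer(comm, comm, "==")
  if (config$homogeneous_density && (is.finite(shape) ||
                                     config$sociability_sd > 0)) {
    for (cc in seq_len(k)) {
      ix <- which(comm == cc)
      if (length(ix) < 2L) next
      blk <- A[ix, ix]
      A[ix, ix] <- blk / mean(blk[upper.tri(blk)])
    }
  }
  P <- ifelse(same, config$p_within, config$p_between) * A
  diag(P) <- 0

  # sexes
  true_sex <- ifelse(runif(n) < config$sex_ratio, "M", "F")
  obs_sex <- ifelse(runif(n) < config$p_sex_unknown, "U", true_sex)

  # salmon series and period classes
  period_map <- assign_sampling_periods(config$years, config$pooling)
  info <- period_info(period_map)
  salmon <- data.frame(year = config$years,
                       index = rlnorm(length(config$years),
                                      config$salmon_log_mean,
                                      config$salmon_log_sd))
  low <- if (nrow(info) >= 4L) {
    psal <- period_salmon(salmon, period_map)
    setNames(psal$class == "low", psal$period)
  } else {
    # too few periods for a quartile split: no low-resource periods
    setNames(rep(FALSE, nrow(info)), info$period)
  }

  alive <- rep(TRUE, n)
  death_period <- setNames(rep(NA_character_, n), ids)
  enc_counter <- 0L
  out_period <- list(); out_enc <- list(); out_grp <- list(); out_ind <- list()
  cent_rows <- list()
  first_seen <- rep(NA_integer_, n)
  last_seen <- rep(NA_integer_, n)
  hz <- config$hazard

  for (pi in seq_len(nrow(info))) {
    per <- info$period[pi]
    if (!any(alive)) break
    aidx <- which(alive)
    yrs <- config$years[period_map[as.character(config$years)] == per]
    pp_enc <- list(); pp_grp <- list(); pp_ind <- list()
    for (yr in yrs) {
      sim <- simulate_year_groups(aidx, P, config, enc_counter, yr)
      enc_counter <- sim$enc_counter
      pp_enc[[length(pp_enc) + 1L]] <- sim$encounter
      pp_grp[[length(pp_grp) + 1L]] <- sim$group
      pp_ind[[length(pp_ind) + 1L]] <- sim$individual
    }
    p_enc <- unlist(pp_enc); p_grp <- unlist(pp_grp); p_ind <- unlist(pp_ind)
    out_period[[pi]] <- rep(per, length(p_ind))
    out_enc[[pi]] <- p_enc; out_grp[[pi]] <- p_grp
    out_ind[[pi]] <- ids[p_ind]

    seen <- sort(unique(p_ind))
    first_seen[seen] <- ifelse(is.na(first_seen[seen]), pi, first_seen[seen])
    last_seen[seen] <- pi

    # realized within-true-community normalized degree this period
    rows <- data.frame(period = per, encounter = p_enc, group = p_grp,
                       individual = ids[p_ind], stringsAsFactors = FALSE)
    m <- compute_sri(rows, per, validate = FALSE)
    cvec <- setNames(rep(0, length(aidx)), ids[aidx])
    node_comm <- comm[match(m$nodes, ids)]
    for (cc in unique(node_comm)) {
      mem <- m$nodes[node_comm == cc]
      if (length(mem) < 2L) { cvec[mem] <- 0; next }
      Wc <- m$weights[mem, mem, drop = FALSE]
      cvec[mem] <- colSums(Wc > 0) / (length(mem) - 1)
    }
    cent_rows[[pi]] <- data.frame(period = per, individual = ids[aidx],
                                  degree_norm = as.numeric(cvec[ids[aidx]]),
                                  stringsAsFactors = FALSE)

    # piecewise-exponential mortality at period end
    is_low <- isTRUE(low[[per]])
    cv <- as.numeric(cvec[ids[aidx]])
    male <- true_sex[aidx] == "M"
    lh <- hz$beta0 +
      ifelse(male, hz$beta_centrality_male, hz$beta_centrality_female) * cv +
      hz$beta_salmon * is_low +
      hz$beta_interaction * cv * is_low * male
    p_die <- 1 - exp(-info$width[pi] * exp(lh))
    dies <- runif(length(aidx)) < p_die
    if (pi < nrow(info)) {            # deaths in the final period unobservable
      death_period[aidx[dies]] <- per
      alive[aidx[dies]] <- FALSE
    }
  }

  encounters <- data.frame(period = unlist(out_period),
                           encounter = unlist(out_enc),
                           group = unlist(out_grp),
                           individual = unlist(out_ind),
                           stringsAsFactors = FALSE)

  sighted <- !is.na(first_seen)
  registry <- data.frame(
    id = ids, sex = obs_sex,
    first_period = info$period[ifelse(sighted, first_seen, 1L)],
    last_period = info$period[ifelse(sighted, last_seen, 1L)],
    fate = ifelse(unname(!is.na(death_period)), "died", "censored"),
    stringsAsFactors = FALSE)
  rownames(registry) <- NULL

  truth <- structure(list(
    true_partition = setNames(comm, ids),
    true_centrality = do.call(rbind, cent_rows),
    hazard = hz,
    death_period = death_period,
    true_sex = setNames(true_sex, ids),
    period_map = period_map), class = "ground_truth")

  list(encounters = encounters, registry = registry, salmon = salmon,
       truth = truth, period_map = period_map)
}

# one year of encounters among the currently alive individuals
simulate_year_groups <- function(aidx, P, config, enc_counter, year) {
  na <- length(aidx)
  n_slots <- round(na * config$mean_obs_per_whale_year)
  n_groups <- max(1L, round(n_slots / config$mean_group_size))
  sizes <- pmin(1L + rpois(n_groups, config$mean_group_size - 1),
                min(config$max_group_size, na))
  # chunk groups into encounters
  enc_sizes <- integer(0)
  while (sum(enc_sizes) < n_groups) {
    enc_sizes <- c(enc_sizes,
                   1L + rpois(max(16L, n_groups %/% 2L),
                              config$groups_per_encounter - 1))
  }
  enc_sizes <- enc_sizes[cumsum(enc_sizes) - enc_sizes < n_groups]
  enc_sizes[length(enc_sizes)] <- n_groups - sum(enc_sizes[-length(enc_sizes)])

  Pa <- P[aidx, aidx, drop = FALSE]
  e_col <- g_col <- i_col <- vector("list", length(enc_sizes))
  gix <- 0L
  for (e in seq_along(enc_sizes)) {
    enc_counter <- enc_counter + 1L
    eid <- sprintf("Y%dE%06d", year, enc_counter)
    avail <- rep(TRUE, na)
    ge <- enc_sizes[e]
    enc_i <- vector("list", ge); enc_g <- character(ge)
    for (g in seq_len(ge)) {
      gix <- gix + 1L
      av <- which(avail)
      if (!length(av)) { enc_g[g] <- NA; next }
      s <- av[sample.int(length(av), 1L)]
      ksz <- min(sizes[gix], length(av))
      mem <- if (ksz > 1L) {
        cand <- av[av != s]
        w <- Pa[s, cand]
        npos <- sum(w > 0)
        if (npos == 0L) mem_k <- 0L
        else mem_k <- min(ksz - 1L, npos)
        if (mem_k > 0L) c(s, sample_safe(cand, mem_k, prob = w)) else s
      } else s
      avail[mem] <- FALSE
      enc_i[[g]] <- mem
      enc_g[g] <- sprintf("%sG%d", eid, g)
    }
    keep <- !is.na(enc_g)
    nmem <- lengths(enc_i[keep])
    e_col[[e]] <- rep(eid, sum(nmem))
    g_col[[e]] <- rep(enc_g[keep], nmem)
    i_col[[e]] <- aidx[unlist(enc_i[keep], use.names = FALSE)]
  }
  list(encounter = unlist(e_col), group = unlist(g_col),
       individual = unlist(i_col), enc_counter = enc_counter)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d individuals, %d communities, %d deaths\n",
    length(x$true_partition), length(unique(x$true_partition)),
    sum(!is.na(x$death_period))))
  invisible(x)
}

#' Planted-partition association matrix
#'
#' Generates a block-structured SRI-like weight matrix with known community
#' labels for community-detection benchmarks: each dyad's weight is a
#' binomial proportion over `n_occasions` sampling occasions with success
#' probability `w_in` within blocks and `w_out` between blocks.
#'
#' @param n_communities Number of planted blocks.
#' @param size Individuals per block (>= 2).
#' @param w_in,w_out Within- and between-block association probabilities
#'   (`w_in > w_out >= 0`).
#' @param seed Optional seed.
#' @param n_occasions Sampling occasions behind each dyadic proportion
#'   (default 20).
#' @return An `sri_matrix` whose `truth` attribute carries the planted
#'   labels.
#' @export
planted_partition_network <- function(n_communities, size, w_in, w_out,
                                      seed = NULL, n_occasions = 20) {
  if (size < 2) stop_socsurv("block size must be >= 2")
  if (!(w_in > w_out) || w_out < 0 || w_in > 1) {
    stop_socsurv("require 1 >= w_in > w_out >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_communities * size
  labels <- rep(seq_len(n_communities), each = size)
  ids <- sprintf("N%03d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  up <- which(upper.tri(W), arr.ind = TRUE)
  p <- ifelse(labels[up[, 1L]] == labels[up[, 2L]], w_in, w_out)
  w <- rbinom(nrow(up), n_occasions, p) / n_occasions
  W[up] <- w
  W <- W + t(W)
  m <- structure(list(period = "planted", nodes = ids, weights = W,
                      sampled = matrix(TRUE, n, n, dimnames = list(ids, ids)),
                      counts = list(x = W * n_occasions,
                                    y_ab = matrix(0, n, n),
                                    y_a = matrix(0, n, n),
                                    y_b = matrix(0, n, n),
                                    denom = matrix(n_occasions, n, n)),
                      n_sightings = setNames(rep(n_occasions, n), ids),
                      n_groups = NA_integer_, n_encounters = NA_integer_),
                 class = "sri_matrix")
  diag(m$sampled) <- FALSE
  attr(m, "truth") <- setNames(labels, ids)
  m
}
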