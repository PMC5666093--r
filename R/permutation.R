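#' Within-community node permutation of network covariates
#'
#' Randomly reassigns the centrality covariate values among the members of
#' each community within each period, leaving survival outcomes, sex, and
#' community membership untouched. This is the null model for
#' within-community analyses: it preserves everything about the data except
#' which community member holds which social position. Singleton groups are
#' returned unchanged.
#'
#' @param pp A `person_period` table (or any data frame with `period` and
#'   `community` columns).
#' @param covariates Columns permuted jointly (default the two centrality
#'   measures).
#' @return The table with permuted covariate columns.
#' @export
node_permutation <- function(pp,
                             covariates = c("degree_norm",
                                            "closeness_rank_norm")) {
  covariates <- intersect(covariates, names(pp))
  if (!length(covariates)) stop_socsurv("no covariate columns to permute")
  g <- paste(pp$period, pp$community, sep = "\r")
  idx <- perm_index(split(seq_len(nrow(pp)), g), nrow(pp))
  pp[covariates] <- pp[idx, covariates, drop = FALSE]
  pp
}

# random within-group permutation of 1:n given a list of index groups
perm_index <- function(groups, n) {
  idx <- seq_len(n)
  for (ix in groups) {
    if (length(ix) > 1L) idx[ix] <- ix[sample.int(length(ix))]
  }
  idx
}

#' Data-stream permutation of grouped sightings
#'
#' Applies a sequence of checkerboard swaps to one period's group-by-
#' individual incidence structure: two individuals `i`, `j` in different
#' groups `g`, `h` (with `i` absent from `h`'s encounter and `j` absent from
#' `g`'s encounter) exchange group memberships. Every swap — and therefore
#' any number of swaps — preserves each individual's number of observations
#' and every group's size exactly, so the null model holds gregariousness
#' and sampling effort fixed while randomizing who associates with whom.
#' Swaps never cross sampling periods.
#'
#' @param encounters Encounter table.
#' @param period Period whose records are permuted (other periods pass
#'   through unchanged).
#' @param n_swaps Number of accepted swaps to perform.
#' @param max_tries Failed proposals tolerated in a row before concluding no
#'   legal swap exists (the input is then returned with a warning).
#' @return The encounter table with the period's rows permuted.
#' @export
datastream_permutation <- function(encounters, period, n_swaps,
                                   max_tries = 200) {
  rows <- encounters[encounters$period == period, , drop = FALSE]
  if (length(unique(paste(rows$encounter, rows$group))) < 2L) {
    stop_socsurv("period needs >= 2 groups for data-stream permutation")
  }
  st <- ds_state_init(rows)
  st <- ds_swap(st, n_swaps, max_tries)
  out <- rbind(encounters[encounters$period != period, , drop = FALSE],
               ds_rows(st))
  rownames(out) <- NULL
  out
}

# internal swap-chain state ------------------------------------------------

ds_state_init <- function(rows) {
  ids <- sort(unique(rows$individual))
  grp_key <- paste(rows$encounter, rows$group, sep = "\r")
  grp <- factor(grp_key, levels = unique(grp_key))
  enc_of_grp <- rows$encounter[!duplicated(grp_key)]
  grp_of_grp <- rows$group[!duplicated(grp_key)]
  encs <- unique(rows$encounter)
  members <- split(match(rows$individual, ids), grp)
  ind_enc <- matrix(FALSE, length(ids), length(encs),
                    dimnames = list(ids, encs))
  ind_enc[cbind(match(rows$individual, ids), match(rows$encounter, encs))] <- TRUE
  list(period = rows$period[1L], ids = ids, members = members,
       enc_of_grp = match(enc_of_grp, encs), encs = encs,
       grp_names = grp_of_grp, enc_names = enc_of_grp,
       ind_enc = ind_enc)
}

ds_swap <- function(st, n_swaps, max_tries = 200) {
  ng <- length(st$members)
  done <- 0L
  fails <- 0L
  while (done < n_swaps) {
    if (fails >= max_tries) {
      warning("no legal checkerboard swap found after ", max_tries,
              " proposals; returning current state")
      break
    }
    gh <- sample.int(ng, 2L)
    g <- gh[1L]; h <- gh[2L]
    eg <- st$enc_of_grp[g]; eh <- st$enc_of_grp[h]
    mg <- st$members[[g]]; mh <- st$members[[h]]
    if (eg == eh) {
      cand_i <- mg; cand_j <- mh       # same encounter: disjoint by invariant
    } else {
      cand_i <- mg[!st$ind_enc[mg, eh]]
      cand_j <- mh[!st$ind_enc[mh, eg]]
    }
    if (!length(cand_i) || !length(cand_j)) { fails <- fails + 1L; next }
    i <- sample_safe(cand_i, 1L)
    j <- sample_safe(cand_j, 1L)
    st$members[[g]][match(i, st$members[[g]])] <- j
    st$members[[h]][match(j, st$members[[h]])] <- i
    if (eg != eh) {
      st$ind_enc[i, eg] <- FALSE; st$ind_enc[i, eh] <- TRUE
      st$ind_enc[j, eh] <- FALSE; st$ind_enc[j, eg] <- TRUE
    }
    done <- done + 1L
    fails <- 0L
  }
  st
}

ds_rows <- function(st) {
  sizes <- lengths(st$members)
  data.frame(period = st$period,
             encounter = rep(st$enc_names, sizes),
             group = rep(st$grp_names, sizes),
             individual = st$ids[unlist(st$members, use.names = FALSE)],
             stringsAsFactors = FALSE)
}

#' Stateful data-stream permuter for use with [permutation_test()]
#'
#' Returns a function that, each time it is called, advances the
#' checkerboard-swap Markov chain for every period and returns the permuted
#' encounter table. The first call applies `burn_in + thin` swaps per
#' period, later calls `thin` swaps, so successive null datasets are
#' decorrelated from the observed data and from each other.
#'
#' @param encounters Encounter table.
#' @param burn_in Swaps per period before the first retained permutation.
#' @param thin Swaps per period between retained permutations.
#' @return A function `function(data)` (the argument is ignored; the chain
#'   carries its own state) returning a permuted encounter table.
#' @export
datastream_permuter <- function(encounters, burn_in = 1000, thin = 100) {
  periods <- unique(encounters$period)
  states <- lapply(periods, function(p) {
    ds_state_init(encounters[encounters$period == p, , drop = FALSE])
  })
  first <- TRUE
  function(data = NULL) {
    n <- if (first) burn_in + thin else thin
    first <<- FALSE
    states <<- lapply(states, ds_swap, n_swaps = n)
    out <- do.call(rbind, lapply(states, ds_rows))
    rownames(out) <- NULL
    out
  }
}

#' Average a statistic over random sex imputations
#'
#' Individuals of unknown sex (`"U"`) are assigned male or female
#' independently with probability 1/2; `stat_fn` is evaluated on each fully
#' sexed registry and the mean over draws is returned. With no unknown-sex
#' individuals `stat_fn` is evaluated once.
#'
#' @param stat_fn Function taking a fully sexed registry and returning a
#'   scalar.
#' @param registry Individual registry (column `sex` in `{M, F, U}`).
#' @param n_imp Number of imputations (default 1000).
#' @return Mean statistic over imputations.
#' @export
impute_sex_statistic <- function(stat_fn, registry, n_imp = 1000) {
  u <- which(registry$sex == "U")
  if (!length(u)) return(stat_fn(registry))
  if (n_imp < 1) stop_socsurv("n_imp must be >= 1")
  vals <- vapply(seq_len(n_imp), function(k) {
    r2 <- registry
    r2$sex[u] <- sample(c("M", "F"), length(u), replace = TRUE)
    as.numeric(stat_fn(r2))
  }, numeric(1))
  mean(vals)
}

#' Permutation test of a model statistic against a null model
#'
#' Evaluates `stat_fn` on the observed data and on `n_perm` permuted
#' datasets produced by `permuter`, and computes the permutation p-value by
#' the counting rule
#' \deqn{p = (b + 1) / (m + 1)}
#' where `b` is the number of null statistics at least as extreme as the
#' observed one in the test's direction and `m` the number of usable null
#' statistics — i.e. the observed sample is included in both numerator and
#' denominator, so `p` is never below `1/(m + 1)`. Null fits that fail
#' (non-finite statistic) are dropped from the denominator and counted in
#' `n_dropped`.
#'
#' @param stat_fn Function mapping a dataset to a scalar statistic.
#' @param permuter Function mapping a dataset to a permuted dataset (may be
#'   stateful, e.g. [datastream_permuter()]).
#' @param data The observed dataset.
#' @param n_perm Number of permutations (>= 1).
#' @param direction `"ge"` (null >= observed counts as extreme), `"le"`,
#'   `"two_sided"` (compare absolute values), or `"observed"` (one-sided in
#'   the direction of the observed statistic's sign).
#' @param seed Optional seed.
#' @return Object of class `perm_result`: `observed`, `null` (vector),
#'   `n_perm` (usable permutations), `p_value`, `direction`, `n_dropped`.
#' @export
permutation_test <- function(stat_fn, permuter, data, n_perm = 10000,
                             direction = c("ge", "le", "two_sided",
                                           "observed"),
                             seed = NULL) {
  if (n_perm < 1) stop_socsurv("n_perm must be >= 1")
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  obs <- as.numeric(stat_fn(data))
  if (!is.finite(obs)) stop_socsurv("observed statistic is not finite")
  null <- vapply(seq_len(n_perm), function(i) {
    as.numeric(stat_fn(permuter(data)))
  }, numeric(1))
  finite <- is.finite(null)
  nv <- null[finite]
  m <- length(nv)
  if (m == 0L) stop_socsurv("all null fits failed")
  dir <- if (direction == "observed") {
    if (obs >= 0) "ge" else "le"
  } else direction
  b <- switch(dir,
              ge = sum(nv >= obs),
              le = sum(nv <= obs),
              two_sided = sum(abs(nv) >= abs(obs)))
  new_perm_result(observed = obs, null = nv, n_perm = m,
                  p_value = (b + 1) / (m + 1), direction = dir,
                  n_dropped = n_perm - m)
}

new_perm_result <- function(observed, null, n_perm, p_value, direction,
                            n_dropped = 0L) {
  structure(list(observed = observed, null = null, n_perm = n_perm,
                 p_value = p_value, direction = direction,
                 n_dropped = n_dropped),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed = %.4g, p = %.4g (%s, %d permutations%s)\n",
    x$observed, x$p_value, x$direction, x$n_perm,
    if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped") else ""))
  invisible(x)
}

# fast Cox z statistic for permutation loops -------------------------------
# thin wrapper over survival::agreg.fit, skipping formula/model.frame
# overhead; returns NA on failure so callers can drop the permutation.
cox_z_fast <- function(t_start, t_stop, event, x) {
  if (sum(event) < 1L || length(unique(x)) < 2L) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(
      survival::agreg.fit(x = matrix(x, ncol = 1L),
                          y = survival::Surv(t_start, t_stop, event),
                          strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(),
                          weights = NULL, method = "efron",
                          rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$coefficients)) return(NA_real_)
  co <- fit$coefficients[1L]
  v <- fit$var[1L, 1L]
  if (!is.finite(co) || !is.finite(v) || v <= 0) return(NA_real_)
  co / sqrt(v)
}

#' Cox z statistic on a person-period subset
#'
#' Lightweight statistic for permutation loops: the z value (coefficient
#' over standard error) of a single-covariate counting-process Cox fit on
#' the requested subset. Returns `NA` when the fit is degenerate, so
#' permutation machinery can drop that draw.
#'
#' @inheritParams fit_cox
#' @return Scalar z (or `NA`).
#' @export
cox_z_statistic <- function(pp, covariate = "degree_norm", sex = NULL,
                            salmon = NULL) {
  sub <- subset_pp(pp, covariate, sex, salmon)
  if (!nrow(sub)) return(NA_real_)
  cox_z_fast(sub$t_start, sub$t_stop, sub$event, sub[[covariate]])
}
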