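#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one of (`encounters_path`/`individuals_path`/`salmon_path`) or
#' `synthetic` must be given.
#'
#' @param encounters_path,individuals_path,salmon_path Input CSVs (see
#'   [read_dataset()]).
#' @param synthetic A [synthetic_config()] to simulate the inputs instead.
#' @param pooling Pooling rule for [assign_sampling_periods()]; ignored for
#'   synthetic data (the generator's own pooling is reused).
#' @param min_community_size Community size filter (default 5).
#' @param covariates Centrality covariates to test (default both).
#' @param n_perm Permutations per survival test (default 10000).
#' @param n_imp Sex imputations per statistic when unknown-sex individuals
#'   are present (default 1000).
#' @param n_boot Bootstrap replicates for community consistency; 0 skips
#'   the bootstrap (default 1000).
#' @param n_perm_network Data-stream permutations for the per-period
#'   modularity null test; 0 skips it (default 0, as it is the most
#'   expensive stage).
#' @param seed Seed for all randomness (default 1).
#' @param outdir Optional output directory; when given, per-period GraphML,
#'   CSV tables, JSON results and a reproducibility manifest are written.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(encounters_path = NULL, individuals_path = NULL,
                            salmon_path = NULL, synthetic = NULL,
                            pooling = NULL, min_community_size = 5,
                            covariates = c("degree_norm",
                                           "closeness_rank_norm"),
                            n_perm = 10000, n_imp = 1000, n_boot = 1000,
                            n_perm_network = 0, seed = 1, outdir = NULL) {
  have_paths <- !is.null(encounters_path) || !is.null(individuals_path) ||
    !is.null(salmon_path)
  if (have_paths == !is.null(synthetic)) {
    stop_socsurv("give either the three input paths or a synthetic config")
  }
  if (have_paths &&
      (is.null(encounters_path) || is.null(individuals_path))) {
    stop_socsurv("encounters_path and individuals_path are both required")
  }
  if (any(c(n_perm, n_imp) < 1) || any(c(n_boot, n_perm_network) < 0)) {
    stop_socsurv("counts must be positive (n_boot/n_perm_network may be 0)")
  }
  structure(list(encounters_path = encounters_path,
                 individuals_path = individuals_path,
                 salmon_path = salmon_path, synthetic = synthetic,
                 pooling = pooling,
                 min_community_size = min_community_size,
                 covariates = covariates, n_perm = n_perm, n_imp = n_imp,
                 n_boot = n_boot, n_perm_network = n_perm_network,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes ingest (or simulation), per-period association networks,
#' community detection, within-community centrality, the person-period
#' survival table, sex- and resource-stratified Cox fits with
#' within-community node-permutation tests (averaging over sex imputations
#' when unknown-sex individuals are present), and the degree-vs-resource
#' binomial GLMM. Identical configuration and seed give identical output.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `socsurv_pipeline`: list with `networks`,
#'   `partitions`, `centrality`, `salmon_periods`, `person_periods`,
#'   `differentiation`, `cox_tests` (one entry per covariate x sex x salmon
#'   stratum with the fit and its permutation result), `glmm`,
#'   `consistency` (per-period r_com, when `n_boot > 0`),
#'   `modularity_null` (per-period, when `n_perm_network > 0`), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_socsurv("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  dat <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      simulate_dataset(config$synthetic)
    } else {
      d <- read_dataset(config$encounters_path, config$individuals_path,
                        config$salmon_path)
      yrs <- suppressWarnings(as.integer(unique(d$encounters$period)))
      d$period_map <- if (!anyNA(yrs)) {
        assign_sampling_periods(yrs, config$pooling)
      } else {
        # period ids are not plain years: take them as given, in sorted order
        pm <- sort(unique(d$encounters$period))
        structure(setNames(pm, pm),
                  info = data.frame(period = pm,
                                    start_year = seq_along(pm),
                                    width = 1L))
      }
      d
    }
  })
  info <- period_info(dat$period_map)
  periods <- intersect(info$period, unique(dat$encounters$period))

  networks <- stage("networks", {
    validate_dataset(dat$encounters, dat$registry)
    build_networks(dat$encounters, periods)
  })
  diffn <- stage("networks", {
    pooled_x <- unlist(lapply(networks, function(m)
      m$counts$x[upper.tri(m$counts$x)]))
    pooled_d <- unlist(lapply(networks, function(m)
      m$counts$denom[upper.tri(m$counts$denom)]))
    if (sum(pooled_d >= 1) >= 2) {
      estimate_social_differentiation(pooled_x, pooled_d)
    } else NULL
  })
  partitions <- stage("communities", {
    lapply(networks, detect_communities,
           min_community_size = config$min_community_size)
  })
  centrality <- stage("centrality", {
    tabs <- Map(centrality_table, networks, partitions,
                MoreArgs = list(min_community_size = config$min_community_size))
    tab <- do.call(rbind, tabs)
    rownames(tab) <- NULL
    class(tab) <- c("centrality_table", "data.frame")
    tab
  })
  salmon_periods <- stage("survival/classify_salmon", {
    if (is.null(dat$salmon) || !nrow(dat$salmon)) {
      stop_socsurv("no salmon series available for stratified analysis")
    }
    period_salmon(dat$salmon, dat$period_map)
  })
  pp <- stage("survival", {
    build_person_periods(dat$registry, centrality, salmon_periods, info)
  })

  has_u <- any(dat$registry$sex == "U")
  cox_tests <- list()
  for (cov in config$covariates) {
    for (sx in c("M", "F")) {
      for (sal in list(NULL, "low", "high")) {
        key <- paste0(cov, "_", sx, "_", sal %||% "all")
        res <- stage("permutation_inference", {
          run_cox_perm_test(pp, dat$registry, cov, sx, sal,
                            n_perm = config$n_perm,
                            n_imp = if (has_u) config$n_imp else 1L)
        })
        cox_tests[[key]] <- res
      }
    }
  }

  glmm <- stage("survival/glmm", {
    tryCatch(fit_binomial_glmm(centrality, salmon_periods),
             error = function(e) NULL)
  })

  consistency <- NULL
  if (config$n_boot > 0) {
    consistency <- stage("communities/bootstrap", {
      vapply(periods, function(p) {
        tryCatch(bootstrap_community_consistency(
          dat$encounters, p, n_boot = config$n_boot,
          min_community_size = config$min_community_size)$r_com,
          error = function(e) NA_real_)
      }, numeric(1))
    })
  }
  modularity_null <- NULL
  if (config$n_perm_network > 0) {
    modularity_null <- stage("communities/null", {
      lapply(setNames(periods, periods), function(p) {
        modularity_null_test(dat$encounters, p,
                             n_perm = config$n_perm_network,
                             min_community_size = config$min_community_size)
      })
    })
  }

  # the two centrality measures are related but weakly so; report, per
  # period, how strongly they agree
  cent_cor <- vapply(split(as.data.frame(centrality), centrality$period),
                     function(g) {
                       ok <- !is.na(g$closeness_rank_norm)
                       if (sum(ok) < 3) return(NA_real_)
                       cor(g$degree_norm[ok], g$closeness_rank_norm[ok])
                     }, numeric(1))

  manifest <- list(package_version = as.character(utils::packageVersion("socsurv")),
                   seed = config$seed,
                   n_perm = config$n_perm, n_imp = config$n_imp,
                   n_boot = config$n_boot,
                   min_community_size = config$min_community_size,
                   periods = periods,
                   n_individuals = nrow(dat$registry),
                   n_events = sum(pp$event),
                   degree_closeness_correlation = cent_cor)
  bundle <- structure(list(networks = networks, partitions = partitions,
                           centrality = centrality,
                           salmon_periods = salmon_periods,
                           person_periods = pp,
                           differentiation = diffn,
                           cox_tests = cox_tests, glmm = glmm,
                           consistency = consistency,
                           modularity_null = modularity_null,
                           registry = dat$registry,
                           truth = dat$truth,
                           manifest = manifest),
                      class = "socsurv_pipeline")
  if (!is.null(config$outdir)) write_bundle(bundle, dat, config)
  bundle
}

# observed + node-permutation test for one Cox model, with sex-imputation
# averaging of the z statistic when unknown-sex individuals are present
run_cox_perm_test <- function(pp, registry, covariate, sex, salmon,
                              n_perm, n_imp) {
  stat_fn <- function(tab) {
    if (n_imp > 1L) {
      impute_sex_statistic(function(reg) {
        t2 <- tab
        t2$sex <- reg$sex[match(t2$individual, reg$id)]
        cox_z_statistic(t2, covariate, sex, salmon)
      }, registry, n_imp = n_imp)
    } else {
      cox_z_statistic(tab, covariate, sex, salmon)
    }
  }
  fit <- tryCatch(fit_cox(pp, covariate, sex, salmon),
                  error = function(e) NULL)
  perm <- tryCatch(
    permutation_test(stat_fn, node_permutation, pp, n_perm = n_perm,
                     direction = "le"),
    error = function(e) NULL)
  list(covariate = covariate, sex = sex, salmon = salmon %||% "all",
       fit = fit, perm = perm)
}

write_bundle <- function(bundle, dat, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(bundle$networks)) {
    m <- bundle$networks[[p]]
    if (!length(m$nodes)) next
    write_network(m, file.path(config$outdir, paste0("network_", p, ".graphml")),
                  partition = bundle$partitions[[p]],
                  centrality = bundle$centrality[bundle$centrality$period == p, ],
                  registry = bundle$registry,
                  edge_csv = file.path(config$outdir,
                                       paste0("edges_", p, ".csv")))
  }
  write.csv(as.data.frame(bundle$centrality),
            file.path(config$outdir, "centrality.csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$person_periods),
            file.path(config$outdir, "person_periods.csv"),
            row.names = FALSE)
  results <- list(
    modularity = vapply(bundle$partitions, `[[`, numeric(1), "modularity"),
    consistency = bundle$consistency,
    differentiation = if (!is.null(bundle$differentiation))
      bundle$differentiation[c("S", "r", "mean_H", "n_dyads")] else NULL,
    cox_tests = lapply(bundle$cox_tests, function(x) {
      list(covariate = x$covariate, sex = x$sex, salmon = x$salmon,
           hazard_ratio = if (!is.null(x$fit)) x$fit$hazard_ratio else NULL,
           z = if (!is.null(x$fit)) x$fit$z else NULL,
           n_events = if (!is.null(x$fit)) x$fit$n_events else NULL,
           p_perm = if (!is.null(x$perm)) x$perm$p_value else NULL)
    }),
    glmm = if (!is.null(bundle$glmm))
      bundle$glmm[c("beta", "se", "z", "singular", "n")] else NULL)
  jsonlite::write_json(results, file.path(config$outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- config
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  manifest <- c(bundle$manifest,
                list(config = unclass(cfg),
                     r_version = R.version.string))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(NULL)
}

#' @export
print.socsurv_pipeline <- function(x, ...) {
  cat("socsurv pipeline results\n")
  cat(sprintf("  %d periods, %d individuals, %d events\n",
              length(x$networks), x$manifest$n_individuals,
              x$manifest$n_events))
  mods <- vapply(x$partitions, `[[`, numeric(1), "modularity")
  cat(sprintf("  modularity range: %.2f-%.2f\n",
              min(mods, na.rm = TRUE), max(mods, na.rm = TRUE)))
  if (!is.null(x$differentiation)) {
    cat(sprintf("  social differentiation S = %.2f (r = %.2f)\n",
                x$differentiation$S, x$differentiation$r))
  }
  for (k in names(x$cox_tests)) {
    t <- x$cox_tests[[k]]
    if (is.null(t$fit)) next
    cat(sprintf("  %-32s Haz. = %8.4g  z = %6.2f  e = %3d  p_perm = %s\n",
                k, t$fit$hazard_ratio, t$fit$z, t$fit$n_events,
                if (!is.null(t$perm)) sprintf("%.4g", t$perm$p_value) else "NA"))
  }
  invisible(x)
}
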