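#' Classify years (or periods) by resource abundance
#'
#' Marks each entry as a `low` resource year if its index falls in the
#' lowest quartile of the series (type-7 sample quantile, ties at the
#' threshold going to `low`), and `high` otherwise. Entries with a missing
#' index keep `NA` and are excluded from resource-stratified analyses.
#'
#' @param salmon Data frame with a numeric `index` column (and typically
#'   `year` or `period`).
#' @return The input with a `class` column (`"low"`/`"high"`).
#' @export
classify_salmon <- function(salmon) {
  stopifnot(is.data.frame(salmon), "index" %in% names(salmon))
  idx <- salmon$index
  ok <- !is.na(idx)
  if (sum(ok) < 4L) stop_socsurv("need at least 4 years of abundance data")
  if (any(idx[ok] < 0)) stop_socsurv("abundance index must be non-negative")
  cls <- rep(NA_character_, length(idx))
  if (length(unique(idx[ok])) == 1L) {
    warning("all abundance indices are equal; no low years identifiable")
    cls[ok] <- "high"
  } else {
    thr <- quantile(idx[ok], 0.25, type = 7, names = FALSE)
    cls[ok] <- ifelse(idx[ok] <= thr, "low", "high")
  }
  salmon$class <- cls
  salmon
}

#' Aggregate an annual abundance series to sampling periods
#'
#' Period-level index = mean of the member years with data; periods with no
#' data get `NA`. Classification (lowest quartile = low) is then applied at
#' the period level.
#'
#' @param salmon Data frame with `year` and `index`.
#' @param period_map Year-to-period map from [assign_sampling_periods()].
#' @return Data frame `period`, `index`, `class`, in chronological order.
#' @export
period_salmon <- function(salmon, period_map) {
  info <- period_info(period_map)
  per <- period_map[as.character(salmon$year)]
  keep <- !is.na(per)
  agg <- tapply(salmon$index[keep], per[keep], mean, na.rm = TRUE)
  out <- data.frame(period = info$period,
                    index = as.numeric(agg[info$period]),
                    stringsAsFactors = FALSE)
  out$index[is.nan(out$index)] <- NA_real_
  classify_salmon(out)
}

#' Assemble a counting-process person-period table
#'
#' Expands the individual registry into one survival row per individual per
#' sampling period, carrying the time-varying network covariates. The time
#' axis is years since the individual's first observation (left truncation
#' at study entry). An individual recorded as dead contributes `event = 1`
#' on the row of its last observed period — a death is assigned to the
#' period after whose final summer the individual is no longer seen; all
#' other rows are censored.
#'
#' Rows exist only for periods in which the individual was observed and its
#' community passed the size filter (i.e. it has a centrality row); rows
#' lost to the size filter are reported in the `exclusions` attribute, and
#' events whose final row was excluded in the `events_lost` attribute.
#'
#' @param registry Data frame `id`, `sex`, `first_period`, `last_period`,
#'   `fate` (`"died"`/`"censored"`).
#' @param centrality A `centrality_table` covering all periods.
#' @param salmon Optional period-level abundance table from
#'   [period_salmon()] (columns `period`, `class`).
#' @param info Period info data frame (see [period_info()]).
#'
#' @return Data frame of class `person_period` with columns `individual`,
#'   `period`, `t_start`, `t_stop`, `event`, `sex`, `degree_norm`,
#'   `closeness_rank_norm`, `community`, `community_size`, `salmon_class`.
#' @export
build_person_periods <- function(registry, centrality, salmon = NULL,
                                 info) {
  stopifnot(all(c("id", "sex", "first_period", "last_period", "fate")
                %in% names(registry)))
  pord <- setNames(seq_len(nrow(info)), info$period)
  offs <- setNames(cumsum(c(0, info$width[-nrow(info)])), info$period)
  widths <- setNames(info$width, info$period)
  if (anyNA(pord[registry$first_period]) || anyNA(pord[registry$last_period]))
    stop_socsurv("registry refers to periods missing from the period info")

  cent_key <- paste(centrality$period, centrality$individual, sep = "\r")
  sal_class <- if (!is.null(salmon)) {
    setNames(salmon$class, salmon$period)
  } else NULL

  rows <- vector("list", nrow(registry))
  excl <- list()
  events_lost <- character(0)
  for (i in seq_len(nrow(registry))) {
    id <- registry$id[i]
    f <- pord[[registry$first_period[i]]]
    l <- pord[[registry$last_period[i]]]
    if (f > l) stop_socsurv("individual ", id, ": first_period after last_period")
    pers <- info$period[f:l]
    hit <- match(paste(pers, id, sep = "\r"), cent_key)
    miss <- is.na(hit)
    if (any(miss)) {
      excl[[length(excl) + 1L]] <- data.frame(individual = id,
                                              period = pers[miss],
                                              stringsAsFactors = FALSE)
    }
    if (all(miss)) {
      if (registry$fate[i] == "died") events_lost <- c(events_lost, id)
      next
    }
    pers_k <- pers[!miss]
    hk <- hit[!miss]
    ev <- rep(0L, length(pers_k))
    if (registry$fate[i] == "died") {
      if (pers_k[length(pers_k)] == registry$last_period[i]) {
        ev[length(ev)] <- 1L
      } else {
        events_lost <- c(events_lost, id)
      }
    }
    rows[[i]] <- data.frame(
      individual = id, period = pers_k,
      t_start = offs[pers_k] - offs[[registry$first_period[i]]],
      t_stop = offs[pers_k] - offs[[registry$first_period[i]]] +
        widths[pers_k],
      event = ev, sex = registry$sex[i],
      degree_norm = centrality$degree_norm[hk],
      closeness_rank_norm = centrality$closeness_rank_norm[hk],
      community = centrality$community[hk],
      community_size = centrality$community_size[hk],
      salmon_class = if (is.null(sal_class)) NA_character_
                     else as.character(sal_class[pers_k]),
      stringsAsFactors = FALSE)
  }
  pp <- do.call(rbind, rows)
  if (is.null(pp)) stop_socsurv("no person-period rows could be built")
  rownames(pp) <- NULL
  attr(pp, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(individual = character(0), period = character(0))
  attr(pp, "events_lost") <- events_lost
  class(pp) <- c("person_period", "data.frame")
  pp
}

#' Fit an extended Cox proportional-hazards model
#'
#' Fits a counting-process Cox model on `(t_start, t_stop, event)` rows with
#' a single time-varying covariate, optionally restricted to one sex and/or
#' one resource stratum (stratified results come from separate fits within
#' the low and high strata). Partial-likelihood optimization is delegated to
#' [survival::coxph()].
#'
#' @param pp A `person_period` table.
#' @param covariate Column name of the covariate (e.g. `"degree_norm"`).
#' @param sex Optional `"M"` or `"F"` subset.
#' @param salmon Optional `"low"` or `"high"` subset on `salmon_class`.
#'
#' @return Object of class `cox_fit`: list with `coef`, `hazard_ratio`
#'   (= exp(coef)), `se`, `z`, `n`, `n_events`, `converged`, `covariate`,
#'   `subset`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(pp, covariate = "degree_norm", sex = NULL,
                    salmon = NULL) {
  sub <- subset_pp(pp, covariate, sex, salmon)
  if (sum(sub$event) < 1L) {
    stop_socsurv("no events in the requested subset (sex=",
                 sex %||% "all", ", salmon=", salmon %||% "all", ")")
  }
  fml <- as.formula(paste0("survival::Surv(t_start, t_stop, event) ~ ",
                           covariate))
  fit <- survival::coxph(fml, data = sub)
  co <- unname(coef(fit)[1L])
  se <- unname(sqrt(vcov(fit)[1L, 1L]))
  structure(list(coef = co, hazard_ratio = exp(co), se = se, z = co / se,
                 n = nrow(sub), n_events = sum(sub$event),
                 converged = is.finite(co) && is.finite(se),
                 covariate = covariate,
                 subset = list(sex = sex, salmon = salmon),
                 fit = fit),
            class = "cox_fit")
}

subset_pp <- function(pp, covariate, sex, salmon) {
  if (!covariate %in% names(pp)) {
    stop_socsurv("unknown covariate '", covariate, "'")
  }
  keep <- !is.na(pp[[covariate]])
  if (!is.null(sex)) keep <- keep & pp$sex %in% sex
  if (!is.null(salmon)) {
    keep <- keep & !is.na(pp$salmon_class) & pp$salmon_class %in% salmon
  }
  pp[keep, , drop = FALSE]
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox PH fit: %s%s\n  Haz. = %.4g (coef %.3f, se %.3f), z = %.2f, n = %d, events = %d\n",
    x$covariate,
    paste0(if (!is.null(x$subset$sex)) paste0(", sex=", x$subset$sex),
           if (!is.null(x$subset$salmon)) paste0(", salmon=", x$subset$salmon)),
    x$hazard_ratio, x$coef, x$se, x$z, x$n, x$n_events))
  hri <- hazard_ratio_interpretation(x$hazard_ratio)
  cat("  ", format(hri), "\n", sep = "")
  invisible(x)
}

#' Interpret a hazard ratio as a percent change in risk
#'
#' A hazard ratio of exactly 1 means no change in mortality risk per unit of
#' the covariate; 0.25 means a 75% decrease; 2 means a 100% increase.
#'
#' @param hr Positive hazard ratio.
#' @return Object of class `hr_interpretation` with `$hazard_ratio`,
#'   `$percent` (signed, = 100 * (hr - 1)), `$direction`
#'   (`"decrease"`, `"increase"` or `"no change"`).
#' @examples
#' hazard_ratio_interpretation(0.25)  # 75% decrease
#' @export
hazard_ratio_interpretation <- function(hr) {
  if (!is_one(hr) || !is.numeric(hr) || hr <= 0) {
    stop_socsurv("hazard ratio must be a single positive number")
  }
  pct <- 100 * (hr - 1)
  structure(list(hazard_ratio = hr, percent = pct,
                 direction = if (pct < 0) "decrease"
                             else if (pct > 0) "increase" else "no change"),
            class = "hr_interpretation")
}

#' @export
format.hr_interpretation <- function(x, ...) {
  if (x$direction == "no change") "0% change in risk per unit of variable"
  else sprintf("%.4g%% %s in risk per unit of variable",
               abs(x$percent), x$direction)
}

#' @export
print.hr_interpretation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Binomial GLMM for within-community degree
#'
#' Models each individual's unweighted within-community degree as binomial
#' successes out of (community size - 1) trials against the resource class,
#' with a random intercept per individual, via [lme4::glmer()]. Used to ask
#' whether individuals change their number of associates in low-resource
#' years.
#'
#' @param centrality A `centrality_table` spanning several periods.
#' @param salmon Period-level abundance table (columns `period`, `class`).
#' @return Object of class `glmm_fit`: list with `beta` (fixed effect of the
#'   low-resource class on the logit scale), `se`, `z`, `singular`, `n`, and
#'   the `merMod` fit.
#' @export
fit_binomial_glmm <- function(centrality, salmon) {
  df <- merge(as.data.frame(centrality), salmon[c("period", "class")],
              by = "period")
  df <- df[!is.na(df$class), , drop = FALSE]
  if (length(unique(df$period)) < 2L) {
    stop_socsurv("need data from at least 2 periods to identify the ",
                 "individual random effect")
  }
  df$salmon_class <- factor(df$class, levels = c("high", "low"))
  df$trials <- df$community_size - 1L
  fit <- lme4::glmer(
    cbind(degree_raw, trials - degree_raw) ~ salmon_class + (1 | individual),
    data = df, family = binomial())
  sm <- summary(fit)$coefficients
  structure(list(beta = sm["salmon_classlow", "Estimate"],
                 se = sm["salmon_classlow", "Std. Error"],
                 z = sm["salmon_classlow", "z value"],
                 singular = lme4::isSingular(fit),
                 n = nrow(df), fit = fit),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial GLMM (degree ~ salmon class + (1 | individual))\n  beta[low] = %.3f (se %.3f), z = %.2f, n = %d%s\n",
    x$beta, x$se, x$z, x$n, if (x$singular) " [singular fit]" else ""))
  invisible(x)
}
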