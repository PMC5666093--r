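make_info <- function(periods) {
  data.frame(period = periods, start_year = seq_along(periods),
             width = 1L, stringsAsFactors = FALSE)
}

full_centrality <- function(ids, periods, size = 6L) {
  out <- expand.grid(individual = ids, period = periods,
                     stringsAsFactors = FALSE)
  out$community <- 1L
  out$community_size <- size
  out$degree_raw <- 3L
  out$degree_norm <- 0.5
  out$closeness_rank_norm <- 0.5
  class(out) <- c("centrality_table", "data.frame")
  out
}

test_that("lowest-quartile classification follows the type-7 rule", {
  s <- classify_salmon(data.frame(year = 1:20, index = 1:20))
  expect_equal(sum(s$class == "low"), 5L)
  expect_equal(which(s$class == "low"), 1:5)
  # 8 distinct values: exactly the 2 smallest are low
  s8 <- classify_salmon(data.frame(year = 1:8, index = c(10, 3, 8, 1, 9, 7, 5, 6)))
  expect_equal(s8$class[s8$index %in% c(1, 3)], c("low", "low"))
  expect_equal(sum(s8$class == "low"), 2L)
  # ties at the threshold go to low
  st <- classify_salmon(data.frame(year = 1:8, index = c(2, 2, 2, 5, 6, 7, 8, 9)))
  expect_equal(sum(st$class == "low"), 3L)
})

test_that("degenerate and undersized salmon series are handled", {
  expect_warning(
    s <- classify_salmon(data.frame(year = 1:6, index = rep(4, 6))),
    "equal")
  expect_true(all(s$class == "high"))
  expect_error(classify_salmon(data.frame(year = 1:3, index = 1:3)),
               "at least 4")
})

test_that("death events land on the last observed period", {
  periods <- as.character(1990:1996)
  reg <- data.frame(id = c("A", "B"), sex = c("M", "F"),
                    first_period = "1990",
                    last_period = c("1995", "1996"),
                    fate = c("died", "censored"))
  ct <- full_centrality(c("A", "B"), periods)
  pp <- build_person_periods(reg, ct, info = make_info(periods))
  a <- pp[pp$individual == "A", ]
  expect_equal(nrow(a), 6L)
  expect_equal(a$event, c(0, 0, 0, 0, 0, 1))
  expect_equal(a$t_start, 0:5)
  expect_equal(a$t_stop, 1:6)
  b <- pp[pp$individual == "B", ]
  expect_true(all(b$event == 0))   # censored at study end
  expect_equal(sum(pp$event), 1L)
})

test_that("small-community exclusions drop rows and are logged", {
  periods <- as.character(1990:1994)
  reg <- data.frame(id = "A", sex = "M", first_period = "1990",
                    last_period = "1994", fate = "censored")
  ct <- full_centrality("A", setdiff(periods, "1992"))
  pp <- build_person_periods(reg, ct, info = make_info(periods))
  expect_equal(nrow(pp), 4L)
  expect_false("1992" %in% pp$period)
  excl <- attr(pp, "exclusions")
  expect_equal(excl$period, "1992")
  # other rows keep their calendar positions
  expect_equal(pp$t_start, c(0, 1, 3, 4))
})

test_that("an event whose final row is excluded is logged as lost", {
  periods <- as.character(1990:1993)
  reg <- data.frame(id = "A", sex = "M", first_period = "1990",
                    last_period = "1993", fate = "died")
  ct <- full_centrality("A", as.character(1990:1992))
  pp <- build_person_periods(reg, ct, info = make_info(periods))
  expect_equal(sum(pp$event), 0L)
  expect_equal(attr(pp, "events_lost"), "A")
})

test_that("event count equals died whales with an eligible final row", {
  cfg <- synthetic_config(n_individuals = 40, n_communities = 4,
                          years = 1990:2001, pooling = NULL, seed = 19)
  x <- pp_from_config(cfg)
  died <- x$data$registry$id[x$data$registry$fate == "died"]
  lost <- attr(x$pp, "events_lost")
  expect_equal(sum(x$pp$event), length(died) - length(lost))
  # no sightings after death, entry starts at first observation
  expect_true(all(x$pp$t_start < x$pp$t_stop))
  ev_rows <- x$pp[x$pp$event == 1, ]
  expect_true(all(tapply(x$pp$event, x$pp$individual, sum) <= 1))
})

test_that("Cox fit recovers a two-group exponential log rate ratio", {
  # closed form: coefficient = log(lambda1/lambda0)
  set.seed(32)
  n <- 6000
  x <- rep(0:1, each = n / 2)
  rate <- ifelse(x == 1, 0.5, 0.25)
  time <- rexp(n, rate)
  cens <- pmin(time, 6)
  pp <- data.frame(individual = as.character(1:n), period = "p",
                   t_start = 0, t_stop = cens,
                   event = as.integer(time <= 6), sex = "M",
                   degree_norm = x, closeness_rank_norm = 0.5,
                   community = 1L, community_size = 10L,
                   salmon_class = NA_character_)
  class(pp) <- c("person_period", "data.frame")
  fit <- fit_cox(pp, "degree_norm")
  expect_equal(fit$coef, log(2), tolerance = 0.08)
  expect_equal(fit$hazard_ratio, exp(fit$coef))
  expect_equal(fit$z, fit$coef / fit$se)
})

test_that("a simulated hazard-ratio-0.5 covariate is recovered", {
  set.seed(57)
  n <- 1000
  x <- runif(n)
  rate <- 0.35 * exp(log(0.5) * x)
  time <- rexp(n, rate)
  pp <- data.frame(individual = as.character(1:n), period = "p",
                   t_start = 0, t_stop = pmin(time, 4),
                   event = as.integer(time <= 4), sex = "F",
                   degree_norm = x, closeness_rank_norm = 0.5,
                   community = 1L, community_size = 10L,
                   salmon_class = NA_character_)
  class(pp) <- c("person_period", "data.frame")
  fit <- fit_cox(pp, "degree_norm")
  expect_gt(fit$n_events, 300)
  expect_gt(fit$hazard_ratio, 0.4)
  expect_lt(fit$hazard_ratio, 0.6)
})

test_that("subset with no events raises an informative error", {
  periods <- as.character(1990:1994)
  reg <- data.frame(id = "A", sex = "M", first_period = "1990",
                    last_period = "1994", fate = "censored")
  ct <- full_centrality("A", periods)
  pp <- build_person_periods(reg, ct, info = make_info(periods))
  expect_error(fit_cox(pp, "degree_norm", sex = "F"), "no events")
})

test_that("hazard ratio interpretation matches its definition", {
  h <- hazard_ratio_interpretation(0.25)
  expect_equal(h$percent, -75)
  expect_equal(h$direction, "decrease")
  expect_equal(hazard_ratio_interpretation(1)$direction, "no change")
  h2 <- hazard_ratio_interpretation(2)
  expect_equal(h2$percent, 100)
  expect_equal(h2$direction, "increase")
  expect_error(hazard_ratio_interpretation(-1), "positive")
  # monotone in the coefficient
  pcts <- vapply(c(-1, -0.3, 0, 0.4, 1.2),
                 function(b) hazard_ratio_interpretation(exp(b))$percent,
                 numeric(1))
  expect_true(all(diff(pcts) > 0))
})

test_that("coverage: Cox estimates bracket the simulated coefficient", {
  set.seed(77)
  hits <- 0L
  reps <- 15L
  for (r in seq_len(reps)) {
    n <- 400
    x <- runif(n)
    b <- -1
    time <- rexp(n, 0.4 * exp(b * x))
    pp <- data.frame(individual = as.character(1:n), period = "p",
                     t_start = 0, t_stop = pmin(time, 5),
                     event = as.integer(time <= 5), sex = "M",
                     degree_norm = x, closeness_rank_norm = 0.5,
                     community = 1L, community_size = 10L,
                     salmon_class = NA_character_)
    class(pp) <- c("person_period", "data.frame")
    fit <- fit_cox(pp, "degree_norm")
    if (abs(fit$coef - b) <= 2 * fit$se) hits <- hits + 1L
  }
  expect_gte(hits, 13L)
})

test_that("binomial GLMM recovers a planted salmon effect on degree", {
  sim_glmm <- function(beta_low, seed, n_id = 60, n_per = 8) {
    set.seed(seed)
    u <- rnorm(n_id, 0, 0.4)
    per <- sprintf("p%02d", seq_len(n_per))
    low <- rep(c("low", "high"), length.out = n_per)
    df <- expand.grid(individual = sprintf("w%02d", seq_len(n_id)),
                      period = per, stringsAsFactors = FALSE)
    df$community <- 1L
    df$community_size <- 11L
    eta <- qlogis(0.6) + u[match(df$individual, unique(df$individual))] +
      beta_low * (low[match(df$period, per)] == "low")
    df$degree_raw <- rbinom(nrow(df), 10L, plogis(eta))
    df$degree_norm <- df$degree_raw / 10
    df$closeness_rank_norm <- 0.5
    class(df) <- c("centrality_table", "data.frame")
    sal <- data.frame(period = per, class = low)
    fit_binomial_glmm(df, sal)
  }
  # null: beta near 0
  f0 <- sim_glmm(0, seed = 1)
  expect_lt(abs(f0$beta), 0.15)
  # planted +0.5 logit effect: positive sign recovered across replicates
  signs <- vapply(1:20, function(s) sim_glmm(0.5, seed = s)$beta > 0,
                  logical(1))
  expect_gte(sum(signs), 19L)
})

test_that("single-period data cannot identify the GLMM random effect", {
  df <- full_centrality(c("A", "B", "C"), "1996")
  sal <- data.frame(period = "1996", class = "high")
  expect_error(fit_binomial_glmm(df, sal), "2 periods")
})
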