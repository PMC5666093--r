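test_that("node permutation conserves within-community multisets and never
           crosses community boundaries", {
  pp <- data.frame(
    period = "p1", individual = LETTERS[1:6],
    community = rep(1:2, each = 3),
    degree_norm = c(1, 0.5, 0, 0.9, 0.6, 0.3),
    closeness_rank_norm = c(1, 0.5, 0, 0.75, 0.5, 0.25),
    event = c(0, 1, 0, 0, 0, 1), sex = rep(c("M", "F"), 3))
  set.seed(5)
  vals1 <- pp$degree_norm[1:3]
  vals2 <- pp$degree_norm[4:6]
  for (i in 1:50) {
    pm <- node_permutation(pp)
    expect_setequal(pm$degree_norm[1:3], vals1)
    expect_setequal(pm$degree_norm[4:6], vals2)
    # outcomes, sex and membership untouched
    expect_equal(pm$event, pp$event)
    expect_equal(pm$sex, pp$sex)
    expect_equal(pm$community, pp$community)
    # both covariates move together
    ix <- match(pm$degree_norm[1:3], pp$degree_norm[1:3])
    expect_equal(pm$closeness_rank_norm[1:3], pp$closeness_rank_norm[ix])
  }
  # a singleton community is an identity permutation
  solo <- pp[c(1, 4), ]
  solo$community <- c(1, 2)
  set.seed(1)
  expect_equal(node_permutation(solo)$degree_norm, solo$degree_norm)
})

test_that("node permutation is reproducible under a fixed seed", {
  pp <- data.frame(period = rep(c("p1", "p2"), each = 6),
                   individual = rep(LETTERS[1:6], 2),
                   community = rep(rep(1:2, each = 3), 2),
                   degree_norm = runif(12),
                   closeness_rank_norm = runif(12))
  set.seed(42); a <- node_permutation(pp)
  set.seed(42); b <- node_permutation(pp)
  expect_equal(a, b)
})

test_that("a 2x2 checkerboard swap exchanges exactly one pair", {
  enc <- data.frame(period = "p1",
                    encounter = c("e1", "e1", "e2", "e2"),
                    group = c("g1", "g1", "g1", "g1"),
                    individual = c("A", "B", "C", "D"))
  set.seed(3)
  out <- datastream_permutation(enc, "p1", n_swaps = 1)
  g1 <- sort(out$individual[out$encounter == "e1"])
  g2 <- sort(out$individual[out$encounter == "e2"])
  # one member moved each way; all four whales still observed once
  expect_setequal(c(g1, g2), c("A", "B", "C", "D"))
  expect_equal(lengths(list(g1, g2)), c(2L, 2L))
  expect_equal(sum(c("A", "B") %in% g1), 1L)
})

test_that("swaps preserve sighting counts and group sizes exactly", {
  set.seed(11)
  cfg <- synthetic_config(n_individuals = 20, n_communities = 2,
                          years = 1999, pooling = NULL,
                          mean_obs_per_whale_year = 12, seed = 3)
  enc <- simulate_dataset(cfg)$encounters
  per <- enc$period[1]
  out <- datastream_permutation(enc, per, n_swaps = 1000)
  expect_equal(table(out$individual), table(enc$individual))
  expect_equal(sort(as.integer(table(paste(out$encounter, out$group)))),
               sort(as.integer(table(paste(enc$encounter, enc$group)))))
  expect_equal(length(unique(out$encounter)), length(unique(enc$encounter)))
  # no individual twice in one encounter
  expect_false(any(duplicated(paste(out$encounter, out$individual))))
  # the permutation did change the association structure
  expect_false(identical(
    compute_sri(out, per)$weights, compute_sri(enc, per)$weights))
})

test_that("swaps never cross sampling periods", {
  enc <- rbind(
    data.frame(period = "p1", encounter = c("e1", "e1", "e2", "e2"),
               group = "g1", individual = c("A", "B", "C", "D")),
    data.frame(period = "p2", encounter = c("f1", "f1", "f2", "f2"),
               group = "g1", individual = c("E", "F", "G", "H")))
  set.seed(2)
  out <- datastream_permutation(enc, "p1", n_swaps = 25)
  expect_setequal(out$individual[out$period == "p1"], c("A", "B", "C", "D"))
  expect_equal(out[out$period == "p2", ], enc[enc$period == "p2", ],
               ignore_attr = TRUE)
})

test_that("a period with no legal swap returns its input with a warning", {
  # two groups in one encounter: same-encounter swaps are always legal,
  # so use two groups sharing all members via distinct encounters instead
  enc <- data.frame(period = "p1", encounter = c("e1", "e2"),
                    group = c("g1", "g1"), individual = c("A", "A"))
  expect_warning(out <- datastream_permutation(enc, "p1", n_swaps = 5,
                                               max_tries = 20),
                 "no legal")
  expect_setequal(out$individual, enc$individual)
})

test_that("the permutation p-value follows the (b+1)/(m+1) counting rule", {
  # constructed null sets via a deterministic "permuter"
  mk <- function(nulls) {
    i <- 0
    function(data) { i <<- i + 1; nulls[i] }
  }
  # 49 of 9999 nulls >= observed -> p = 50/10000
  nulls <- c(rep(5, 49), rep(-5, 9950))
  res <- permutation_test(function(d) d, mk(nulls), data = 1,
                          n_perm = 9999, direction = "ge")
  expect_equal(res$p_value, 0.005)
  # observed above every null: the floor 1/(n+1)
  res2 <- permutation_test(function(d) d, mk(rep(-1, 100)), data = 1,
                           n_perm = 100, direction = "ge")
  expect_equal(res2$p_value, 1 / 101)
  # constant statistic: all ties count, p = 1
  res3 <- permutation_test(function(d) d, mk(rep(1, 50)), data = 1,
                           n_perm = 50, direction = "ge")
  expect_equal(res3$p_value, 1)
  expect_error(permutation_test(function(d) d, identity, 1, n_perm = 0),
               "n_perm")
})

test_that("p-values respect the attainable bounds over random nulls", {
  set.seed(8)
  for (i in 1:20) {
    m <- sample(5:50, 1)
    nulls <- rnorm(m)
    i0 <- 0
    res <- permutation_test(function(d) d,
                            function(d) { i0 <<- i0 + 1; nulls[i0] },
                            data = rnorm(1), n_perm = m,
                            direction = sample(c("ge", "le", "two_sided"), 1))
    expect_gte(res$p_value, 1 / (m + 1))
    expect_lte(res$p_value, 1)
  }
})

test_that("failed null fits are dropped from the denominator", {
  i <- 0
  nulls <- c(1, NA, 2, NA, 3)
  res <- permutation_test(function(d) if (is.na(d)) NA_real_ else d,
                          function(d) { i <<- i + 1; nulls[i] },
                          data = 10, n_perm = 5, direction = "ge")
  expect_equal(res$n_perm, 3L)
  expect_equal(res$n_dropped, 2L)
  expect_equal(res$p_value, 1 / 4)
})

test_that("sex imputation averages the two assignments of a U whale", {
  reg <- data.frame(id = c("A", "B"), sex = c("U", "M"))
  stat <- function(r) if (r$sex[1] == "M") 2 else 0   # linear in indicator
  set.seed(13)
  est <- impute_sex_statistic(stat, reg, n_imp = 1000)
  expect_equal(est, 1, tolerance = 0.1)   # closed form (2 + 0)/2
  # no unknown-sex whales: single evaluation, exact
  reg2 <- data.frame(id = c("A", "B"), sex = c("F", "M"))
  expect_equal(impute_sex_statistic(stat, reg2, n_imp = 1000), 0)
  # reproducible under seed
  set.seed(99); a <- impute_sex_statistic(stat, reg, n_imp = 50)
  set.seed(99); b <- impute_sex_statistic(stat, reg, n_imp = 50)
  expect_equal(a, b)
})
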