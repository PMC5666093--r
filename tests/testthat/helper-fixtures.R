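# shared fixtures and independent oracles, built in code

# small hand-written encounter table: 4 encounters, 4 whales, one period
# dyad (A,B) by hand: x = 1 (e1), y_ab = 1 (e2), y_a = 0, y_b = 2 (e3, e4)
# so SRI(A,B) = 1 / (1 + 1 + 0 + 2) = 0.25
toy_encounters <- function() {
  data.frame(
    period = "1996",
    encounter = c("e1", "e1", "e1", "e2", "e2", "e2", "e3", "e3",
                  "e4", "e4", "e4"),
    group     = c("g1", "g1", "g2", "g1", "g2", "g2", "g1", "g1",
                  "g1", "g2", "g2"),
    individual = c("A", "B", "C", "A", "B", "C", "B", "C",
                   "B", "C", "D"),
    stringsAsFactors = FALSE)
}

toy_registry <- function(ids = c("A", "B", "C", "D")) {
  data.frame(id = ids, sex = rep(c("M", "F"), length.out = length(ids)),
             first_period = "1996", last_period = "1996",
             fate = "censored", stringsAsFactors = FALSE)
}

# brute-force SRI recount: loop over encounters, classify each dyad-encounter
# into x / y_ab / y_a / y_b with plain integer arithmetic
brute_sri <- function(encounters, period) {
  rows <- encounters[encounters$period == period, , drop = FALSE]
  ids <- sort(unique(rows$individual))
  n <- length(ids)
  x <- yab <- ya <- yb <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (e in unique(rows$encounter)) {
    er <- rows[rows$encounter == e, , drop = FALSE]
    for (ai in seq_len(n - 1L)) for (bi in (ai + 1L):n) {
      a <- ids[ai]; b <- ids[bi]
      ga <- er$group[er$individual == a]
      gb <- er$group[er$individual == b]
      if (length(ga) && length(gb)) {
        if (any(ga %in% gb)) x[ai, bi] <- x[ai, bi] + 1L
        else yab[ai, bi] <- yab[ai, bi] + 1L
      } else if (length(ga)) ya[ai, bi] <- ya[ai, bi] + 1L
      else if (length(gb)) yb[ai, bi] <- yb[ai, bi] + 1L
    }
  }
  den <- x + yab + ya + yb
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  W[den > 0] <- x[den > 0] / den[den > 0]
  W <- W + t(W)
  list(weights = W, x = x, y_ab = yab, y_a = ya, y_b = yb, denom = den)
}

# random small encounter table for property tests
random_encounters <- function(n_whales = 6, n_encounters = 8, period = "p1") {
  ids <- LETTERS[seq_len(n_whales)]
  out <- list()
  for (e in seq_len(n_encounters)) {
    present <- ids[runif(n_whales) < 0.6]
    if (!length(present)) next
    grp <- sample(1:3, length(present), replace = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      period = period, encounter = paste0("e", e),
      group = paste0("g", grp), individual = present,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# sri_matrix from an explicit weight matrix (for centrality/community tests)
sri_from_weights <- function(W, period = "p1") {
  ids <- rownames(W) %||% sprintf("N%02d", seq_len(nrow(W)))
  dimnames(W) <- list(ids, ids)
  s <- matrix(TRUE, nrow(W), nrow(W), dimnames = dimnames(W))
  diag(s) <- FALSE
  structure(list(period = period, nodes = ids, weights = W, sampled = s,
                 counts = list(x = W, y_ab = 0 * W, y_a = 0 * W,
                               y_b = 0 * W, denom = (W > 0) + 0),
                 n_sightings = setNames(rep(1, nrow(W)), ids),
                 n_groups = NA_integer_, n_encounters = NA_integer_),
            class = "sri_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block-diagonal uniform-weight matrix (cliques)
clique_blocks <- function(sizes, w = 1) {
  n <- sum(sizes)
  W <- matrix(0, n, n)
  at <- 0L
  for (s in sizes) {
    ix <- at + seq_len(s)
    W[ix, ix] <- w
    at <- at + s
  }
  diag(W) <- 0
  W
}

# adjusted Rand index between two label vectors (independent of package code)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# full-pipeline helper: synthetic data -> person-period table
pp_from_config <- function(cfg) {
  d <- simulate_dataset(cfg)
  info <- period_info(d$period_map)
  nets <- build_networks(d$encounters, info$period)
  parts <- lapply(nets, detect_communities)
  ct <- do.call(rbind, Map(centrality_table, nets, parts))
  class(ct) <- c("centrality_table", "data.frame")
  sal <- period_salmon(d$salmon, d$period_map)
  pp <- build_person_periods(d$registry, ct, sal, info)
  list(pp = pp, data = d, centrality = ct, salmon = sal, info = info)
}
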