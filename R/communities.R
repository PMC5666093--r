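#' Detect social communities by weighted random walks
#'
#' Partitions a period's association network into communities with the
#' walktrap algorithm: short random walks on the SRI-weighted graph define a
#' vertex distance that is agglomerated into a merge dendrogram, which is cut
#' at maximum modularity. The result is deterministic for a given matrix.
#'
#' A matrix with no positive weights yields the all-singletons partition,
#' flagged degenerate.
#'
#' @param m An `sri_matrix`.
#' @param steps Random-walk length (default 4, the walktrap standard).
#' @param min_community_size Communities at or above this size are flagged
#'   "large"; downstream centrality is restricted to them (default 5).
#'
#' @return An object of class `community_partition`: list with `period`,
#'   `assignment` (named integer vector, individual to community id),
#'   `modularity` (of the assignment; `NA` for a degenerate matrix),
#'   `sizes`, `large` (logical per community), `degenerate`.
#' @export
detect_communities <- function(m, steps = 4, min_community_size = 5) {
  stopifnot(inherits(m, "sri_matrix"))
  n <- length(m$nodes)
  if (n == 0L) stop_socsurv("empty association matrix")
  W <- m$weights

  if (all(W == 0)) {
    memb <- setNames(seq_len(n), m$nodes)
    return(new_partition(m$period, memb, modularity = NA_real_,
                         min_community_size, degenerate = TRUE))
  }

  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cw <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = steps)
  memb <- setNames(as.integer(igraph::membership(cw)), m$nodes)
  Q <- q_modularity(W, memb)
  new_partition(m$period, memb, Q, min_community_size, degenerate = FALSE)
}

new_partition <- function(period, assignment, modularity,
                          min_community_size, degenerate) {
  # renumber communities by order of first appearance for label stability
  ids <- unique(assignment)
  assignment <- setNames(match(assignment, ids), names(assignment))
  sizes <- table(assignment)
  sizes <- setNames(as.integer(sizes), names(sizes))
  structure(list(period = period, assignment = assignment,
                 modularity = modularity, sizes = sizes,
                 large = sizes >= min_community_size,
                 min_community_size = min_community_size,
                 degenerate = degenerate),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition, period ", x$period, "\n", sep = "")
  cat(sprintf("  %d individuals in %d communities (%d of size >= %d)\n",
              length(x$assignment), length(x$sizes), sum(x$large),
              x$min_community_size))
  cat(sprintf("  modularity Q = %s%s\n",
              ifelse(is.na(x$modularity), "NA",
                     sprintf("%.3f", x$modularity)),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Weighted Newman modularity of a partition
#'
#' \deqn{Q = \sum_c \left[ W_c/W - (k_c/2W)^2 \right]}
#' with `W` the total edge weight, `W_c` the weight inside community `c` and
#' `k_c` the summed strength of its members. Lies in \[-0.5, 1\].
#'
#' @param weights Symmetric non-negative weight matrix (zero diagonal), or an
#'   `sri_matrix`.
#' @param assignment Community membership vector, one entry per node (named
#'   vectors are matched by node name when `weights` is an `sri_matrix`).
#' @return Modularity `Q`.
#' @export
q_modularity <- function(weights, assignment) {
  if (inherits(weights, "sri_matrix")) {
    m <- weights
    assignment <- assignment[m$nodes]
    weights <- m$weights
  }
  n <- nrow(weights)
  if (length(assignment) != n) stop_socsurv("assignment must cover all nodes")
  if (anyNA(assignment)) stop_socsurv("assignment has missing entries")
  tw <- sum(weights)                 # = 2W
  if (tw <= 0) stop_socsurv("modularity undefined for a zero-weight network")
  k <- rowSums(weights)
  Q <- 0
  for (cc in unique(assignment)) {
    idx <- which(assignment == cc)
    Q <- Q + sum(weights[idx, idx]) / tw - (sum(k[idx]) / tw)^2
  }
  Q
}

#' Bootstrap consistency of community assignment
#'
#' Resamples the period's encounters with replacement, rebuilds the
#' association matrix and re-detects communities. For each replicate the
#' proportion of originally co-assigned dyads (both members present in the
#' replicate network) that are again co-assigned is recorded; `r_com` is the
#' mean of that proportion over replicates. Values near 1 mean community
#' membership is robust to sampling noise.
#'
#' @inheritParams compute_sri
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @param steps,min_community_size Passed to [detect_communities()].
#' @return List with `r_com`, `per_replicate` proportions, and the original
#'   partition, classed `community_consistency`.
#' @export
bootstrap_community_consistency <- function(encounters, period,
                                            n_boot = 1000, seed = NULL,
                                            steps = 4,
                                            min_community_size = 5) {
  if (n_boot < 1) stop_socsurv("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- encounters[encounters$period == period, , drop = FALSE]
  encs <- unique(rows$encounter)
  if (length(encs) < 2L) stop_socsurv("need >= 2 encounters in the period")

  m0 <- compute_sri(rows, period)
  p0 <- detect_communities(m0, steps, min_community_size)
  a0 <- p0$assignment
  pair_idx <- which(upper.tri(diag(length(a0))), arr.ind = TRUE)
  co0 <- a0[pair_idx[, 1L]] == a0[pair_idx[, 2L]]
  pa <- names(a0)[pair_idx[co0, 1L]]
  pb <- names(a0)[pair_idx[co0, 2L]]
  if (!length(pa)) stop_socsurv("original partition has no co-assigned dyads")

  by_enc <- split(seq_len(nrow(rows)), rows$encounter)
  prop <- vapply(seq_len(n_boot), function(b) {
    take <- sample(encs, length(encs), replace = TRUE)
    ix <- unlist(by_enc[take], use.names = FALSE)
    reps <- rep.int(seq_along(take), vapply(by_enc[take], length, 1L))
    brows <- rows[ix, , drop = FALSE]
    brows$encounter <- paste0(brows$encounter, "#", reps)
    brows$group <- paste0(brows$group, "#", reps)
    mb <- compute_sri(brows, period, validate = FALSE)
    ab <- detect_communities(mb, steps, min_community_size)$assignment
    present <- pa %in% names(ab) & pb %in% names(ab)
    if (!any(present)) return(NA_real_)
    mean(ab[pa[present]] == ab[pb[present]])
  }, numeric(1))

  structure(list(r_com = mean(prop, na.rm = TRUE), per_replicate = prop,
                 n_boot = n_boot, partition = p0),
            class = "community_consistency")
}

#' @export
print.community_consistency <- function(x, ...) {
  cat(sprintf("Bootstrap community consistency: r_com = %.3f (%d replicates)\n",
              x$r_com, x$n_boot))
  invisible(x)
}

#' Is the network more modular than random?
#'
#' Compares the modularity of the detected partition with the modularities
#' obtained after data-stream permutation of the sighting records
#' (checkerboard swaps preserving each individual's number of observations
#' and every group's size). The permutations form a Markov chain: `burn_in`
#' swaps first, then `thin` swaps between retained null networks. The
#' p-value uses the counting rule (b + 1)/(m + 1) with the observed sample
#' included in numerator and denominator.
#'
#' @inheritParams bootstrap_community_consistency
#' @param n_perm Number of null networks (must be >= 1).
#' @param burn_in Swaps before the first retained permutation.
#' @param thin Swaps between retained permutations.
#' @return A [permutation_test()]-style `perm_result`.
#' @export
modularity_null_test <- function(encounters, period, n_perm, seed = NULL,
                                 burn_in = 1000, thin = 100,
                                 steps = 4, min_community_size = 5) {
  if (n_perm < 1) stop_socsurv("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- encounters[encounters$period == period, , drop = FALSE]
  if (!nrow(rows)) stop_socsurv("no encounters in period '", period, "'")

  qual <- function(r) {
    m <- compute_sri(r, period, validate = FALSE)
    p <- detect_communities(m, steps, min_community_size)
    if (is.na(p$modularity)) return(NA_real_)
    p$modularity
  }
  obs <- qual(rows)

  st <- ds_state_init(rows)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    st <- ds_swap(st, if (i == 1L) burn_in + thin else thin)
    null[i] <- qual(ds_rows(st))
  }
  finite <- is.finite(null)
  b <- sum(null[finite] >= obs)
  m <- sum(finite)
  new_perm_result(observed = obs, null = null[finite], n_perm = m,
                  p_value = (b + 1) / (m + 1), direction = "ge",
                  n_dropped = n_perm - m)
}
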