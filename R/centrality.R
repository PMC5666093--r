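#' Within-community centrality (degree and rank-normalized closeness)
#'
#' Computes, for every member of every sufficiently large community, the two
#' centrality measures used to characterise social position:
#'
#' * **degree** — the unweighted count of same-community associates (dyads
#'   with SRI > 0), normalized by community size minus one;
#' * **closeness** — the inverse of the mean weighted shortest-path length
#'   to all other community members, where an edge with association weight
#'   `w` has length `1/w` so that strong associates are close. Because raw
#'   closeness is highly skewed it is rank-transformed (average ranks on
#'   ties) and min-max normalized to \[0, 1\], with the most central
#'   individual at 1.
#'
#' Communities smaller than `min_community_size` are excluded entirely:
#' patterns of social connection are too constrained in very small groups.
#' Within a disconnected community closeness is computed inside each
#' connected component; members of components smaller than
#' `min_community_size` get `NA` closeness and are flagged.
#'
#' @param m An `sri_matrix`.
#' @param partition A `community_partition` for the same period and nodes.
#' @param min_community_size Minimum community size (default 5).
#' @param rank_scope Rank closeness `"community"`-wise (default) or across
#'   the whole period `"network"`.
#'
#' @return A data frame of class `centrality_table` with columns `period`,
#'   `individual`, `community`, `community_size`, `degree_raw`,
#'   `degree_norm`, `closeness_raw`, `closeness_rank_norm`,
#'   `small_component` (TRUE where closeness is undefined because the
#'   member's component was below the size threshold).
#' @export
centrality_table <- function(m, partition, min_community_size = 5,
                             rank_scope = c("community", "network")) {
  stopifnot(inherits(m, "sri_matrix"),
            inherits(partition, "community_partition"))
  rank_scope <- match.arg(rank_scope)
  if (!identical(m$period, partition$period)) {
    stop_socsurv("matrix and partition refer to different periods")
  }
  a <- partition$assignment
  if (!setequal(names(a), m$nodes)) {
    stop_socsurv("matrix and partition cover different node sets")
  }
  a <- a[m$nodes]

  keep <- names(partition$sizes)[partition$sizes >= min_community_size]
  out <- lapply(keep, function(cc) {
    members <- m$nodes[a == as.integer(cc)]
    nc <- length(members)
    Wc <- m$weights[members, members, drop = FALSE]
    deg <- as.integer(colSums(Wc > 0))

    # weighted shortest paths on edge length 1/SRI
    gc <- igraph::graph_from_adjacency_matrix(Wc, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    len <- 1 / igraph::E(gc)$weight
    D <- igraph::distances(gc, weights = if (length(len)) len else NULL)
    comp <- igraph::components(gc)$membership
    clo <- rep(NA_real_, nc)
    small <- rep(FALSE, nc)
    for (k in unique(comp)) {
      ix <- which(comp == k)
      if (length(ix) < min_community_size) {
        small[ix] <- TRUE
        next
      }
      dsum <- rowSums(D[ix, ix, drop = FALSE])
      clo[ix] <- (length(ix) - 1) / dsum
    }

    data.frame(period = m$period, individual = members,
               community = as.integer(cc), community_size = nc,
               degree_raw = deg, degree_norm = deg / (nc - 1),
               closeness_raw = clo,
               closeness_rank_norm = NA_real_,
               small_component = small,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  if (is.null(tab) || nrow(tab) == 0L) {
    tab <- data.frame(period = character(0), individual = character(0),
                      community = integer(0), community_size = integer(0),
                      degree_raw = integer(0), degree_norm = numeric(0),
                      closeness_raw = numeric(0),
                      closeness_rank_norm = numeric(0),
                      small_component = logical(0),
                      stringsAsFactors = FALSE)
    class(tab) <- c("centrality_table", "data.frame")
    return(tab)
  }

  ok <- !is.na(tab$closeness_raw)
  if (any(ok)) {
    if (rank_scope == "community") {
      for (cc in unique(tab$community[ok])) {
        ix <- which(ok & tab$community == cc)
        tab$closeness_rank_norm[ix] <- rank_minmax(tab$closeness_raw[ix])
      }
    } else {
      tab$closeness_rank_norm[ok] <- rank_minmax(tab$closeness_raw[ok])
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Within-community degree centrality
#'
#' Convenience wrapper around [centrality_table()] returning the degree
#' columns only.
#'
#' @inheritParams centrality_table
#' @return Data frame with `period`, `individual`, `community`,
#'   `community_size`, `degree_raw`, `degree_norm`.
#' @export
community_degree <- function(m, partition, min_community_size = 5) {
  tab <- centrality_table(m, partition, min_community_size)
  tab[c("period", "individual", "community", "community_size",
        "degree_raw", "degree_norm")]
}

#' Within-community closeness centrality
#'
#' Convenience wrapper around [centrality_table()] returning the closeness
#' columns only.
#'
#' @inheritParams centrality_table
#' @return Data frame with `period`, `individual`, `community`,
#'   `community_size`, `closeness_raw`, `closeness_rank_norm`,
#'   `small_component`.
#' @export
community_closeness <- function(m, partition, min_community_size = 5,
                                rank_scope = c("community", "network")) {
  tab <- centrality_table(m, partition, min_community_size, rank_scope)
  tab[c("period", "individual", "community", "community_size",
        "closeness_raw", "closeness_rank_norm", "small_component")]
}
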