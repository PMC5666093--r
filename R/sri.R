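#' Simple-ratio-index association matrix for one sampling period
#'
#' Builds the weighted association network for a sampling period from
#' grouped sighting records under the gambit of the group: all members of an
#' observed group are taken to be associating. For a dyad (a, b) the simple
#' ratio index is
#' \deqn{SRI = x / (x + y_{ab} + y_a + y_b)}
#' where, counting over the period's encounters, `x` is the number of groups
#' containing both, `y_ab` the number of encounters where both were seen but
#' in different groups, and `y_a`, `y_b` the numbers of encounters where only
#' one of the two was seen. Because each individual belongs to at most one
#' group per encounter, `x` is equivalently counted per encounter.
#'
#' Dyads never observed in a common encounter have an undefined index; they
#' are reported as weight 0 but distinguished from an observed zero by the
#' `sampled` matrix.
#'
#' @param encounters Encounter table: data frame with columns `period`,
#'   `encounter`, `group`, `individual`.
#' @param period Period id to build the network for.
#' @param validate If `TRUE`, reject individuals appearing in more than one
#'   group of the same encounter.
#'
#' @return An object of class `sri_matrix`: a list with `period`, `nodes`
#'   (individuals sighted at least once in the period, sorted), `weights`
#'   (symmetric SRI matrix, zero diagonal), `sampled` (logical matrix, TRUE
#'   where the dyad shared at least one encounter), `counts` (matrices `x`,
#'   `y_ab`, `y_a`, `y_b`, `denom`), and `n_sightings` (encounters per
#'   individual).
#'
#' @examples
#' enc <- data.frame(period = "1996",
#'   encounter = c("e1", "e1", "e2", "e2"),
#'   group     = c("g1", "g1", "g1", "g2"),
#'   individual = c("A", "B", "A", "B"))
#' compute_sri(enc, "1996")$weights
#' @export
compute_sri <- function(encounters, period, validate = TRUE) {
  rows <- encounters[encounters$period == period, , drop = FALSE]
  if (nrow(rows) == 0L) {
    warning("no encounters in period '", period, "'; returning empty matrix")
    return(empty_sri(period))
  }
  if (validate) {
    dup <- duplicated(paste(rows$encounter, rows$individual, sep = "\r"))
    dupg <- duplicated(paste(rows$encounter, rows$group, rows$individual,
                             sep = "\r"))
    if (any(dupg)) {
      stop_socsurv("individual repeated within a group (encounter ",
                   rows$encounter[dupg][1L], ")")
    }
    if (any(dup)) {
      stop_socsurv("individual in multiple groups of one encounter ",
                   "(encounter ", rows$encounter[dup][1L], ")")
    }
  }

  ids <- sort(unique(rows$individual))
  n <- length(ids)
  i <- match(rows$individual, ids)
  enc <- factor(rows$encounter)
  grp <- factor(paste(rows$encounter, rows$group, sep = "\r"))

  G <- matrix(0, n, nlevels(grp))
  G[cbind(i, as.integer(grp))] <- 1
  X <- tcrossprod(G)                      # co-group counts
  E <- matrix(0, n, nlevels(enc))
  E[cbind(i, as.integer(enc))] <- 1
  B <- tcrossprod(E)                      # co-encounter counts
  nenc <- diag(B)

  denom <- outer(nenc, nenc, "+") - B     # = x + y_ab + y_a + y_b
  W <- matrix(0, n, n)
  pos <- denom > 0
  W[pos] <- X[pos] / denom[pos]
  diag(W) <- 0
  sampled <- B > 0
  diag(sampled) <- FALSE

  dimnames(W) <- dimnames(sampled) <- list(ids, ids)
  counts <- list(x = X, y_ab = B - X,
                 y_a = outer(nenc, rep(1, n)) - B,
                 y_b = outer(rep(1, n), nenc) - B,
                 denom = denom)
  counts <- lapply(counts, function(m) {
    dimnames(m) <- list(ids, ids)
    diag(m) <- 0
    m
  })

  structure(list(period = period, nodes = ids, weights = W,
                 sampled = sampled, counts = counts,
                 n_sightings = setNames(nenc, ids),
                 n_groups = nlevels(grp), n_encounters = nlevels(enc)),
            class = "sri_matrix")
}

empty_sri <- function(period) {
  m <- matrix(numeric(0), 0, 0)
  structure(list(period = period, nodes = character(0), weights = m,
                 sampled = matrix(logical(0), 0, 0),
                 counts = list(x = m, y_ab = m, y_a = m, y_b = m, denom = m),
                 n_sightings = setNames(numeric(0), character(0)),
                 n_groups = 0L, n_encounters = 0L),
            class = "sri_matrix")
}

#' @export
print.sri_matrix <- function(x, ...) {
  cat("Simple-ratio association matrix, period ", x$period, "\n", sep = "")
  cat("  ", length(x$nodes), " individuals, ", x$n_encounters,
      " encounters, ", x$n_groups, " groups\n", sep = "")
  w <- x$weights[upper.tri(x$weights)]
  if (length(w)) {
    cat(sprintf("  nonzero dyads: %d / %d, mean SRI (nonzero): %.3f\n",
                sum(w > 0), length(w), mean(w[w > 0])))
  }
  invisible(x)
}

#' Association networks for every sampling period
#'
#' @param encounters Encounter table (see [compute_sri()]).
#' @param periods Optional character vector restricting/ordering the periods;
#'   defaults to the periods present, sorted.
#' @return Named list of `sri_matrix` objects.
#' @export
build_networks <- function(encounters, periods = NULL) {
  periods <- periods %||% sort(unique(encounters$period))
  out <- lapply(periods, function(p) compute_sri(encounters, p))
  names(out) <- periods
  out
}
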