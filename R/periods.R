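#' Assign calendar years to sampling periods
#'
#' Maps each study year to a sampling-period identifier. Densely sampled
#' years form one network per year; sparsely sampled stretches can be pooled
#' into multi-year periods (typically two years) so that each network is
#' built from enough sightings to be reliable.
#'
#' @param years Integer vector of study years (need not be contiguous).
#' @param pooling Optional data frame with columns `from`, `to`, `width`
#'   giving the pooling width (in years) to apply within each inclusive year
#'   range. Years not covered by any range get width 1. Ranges must not
#'   overlap. `NULL` means one period per year.
#'
#' @return A named character vector mapping year (as name) to period id.
#'   Single-year periods are labelled `"1996"`; pooled periods
#'   `"1976-1977"`. The attribute `"info"` holds a data frame
#'   (`period`, `start_year`, `width`) in chronological order.
#'
#' @examples
#' assign_sampling_periods(1990:2010)
#' assign_sampling_periods(1976:1989,
#'   pooling = data.frame(from = 1976, to = 1989, width = 2))
#' @export
assign_sampling_periods <- function(years, pooling = NULL) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 0L) stop_socsurv("no years supplied")
  if (is.null(pooling)) {
    pooling <- data.frame(from = min(years), to = max(years), width = 1L)
  }
  stopifnot(all(c("from", "to", "width") %in% names(pooling)))
  if (any(pooling$width < 1)) stop_socsurv("pooling width must be >= 1")
  if (any(pooling$from > pooling$to)) stop_socsurv("pooling range with from > to")
  pooling <- pooling[order(pooling$from), , drop = FALSE]
  if (nrow(pooling) > 1L &&
      any(pooling$from[-1L] <= pooling$to[-nrow(pooling)])) {
    stop_socsurv("overlapping pooling ranges")
  }

  map <- character(length(years))
  names(map) <- as.character(years)
  covered <- rep(FALSE, length(years))
  for (k in seq_len(nrow(pooling))) {
    rng_years <- years[years >= pooling$from[k] & years <= pooling$to[k]]
    if (!length(rng_years)) next
    w <- as.integer(pooling$width[k])
    # chunk contiguously from the start of the range
    block <- (rng_years - rng_years[1L]) %/% w
    for (b in unique(block)) {
      yy <- rng_years[block == b]
      map[as.character(yy)] <- period_label(yy)
      covered[years %in% yy] <- TRUE
    }
  }
  if (any(!covered)) {
    solo <- years[!covered]
    map[as.character(solo)] <- as.character(solo)
  }

  starts <- tapply(years, map[as.character(years)], min)
  widths <- tapply(years, map[as.character(years)], length)
  info <- data.frame(period = names(starts),
                     start_year = as.integer(starts),
                     width = as.integer(widths),
                     row.names = NULL, stringsAsFactors = FALSE)
  info <- info[order(info$start_year), , drop = FALSE]
  rownames(info) <- NULL
  attr(map, "info") <- info
  map
}

period_label <- function(yy) {
  if (length(yy) == 1L) as.character(yy) else paste0(min(yy), "-", max(yy))
}

#' Period bookkeeping for a year-to-period map
#'
#' @param period_map A map produced by [assign_sampling_periods()].
#' @return Data frame with `period`, `start_year`, `width`, ordered in time.
#' @export
period_info <- function(period_map) {
  info <- attr(period_map, "info")
  if (is.null(info)) stop_socsurv("period map lacks an 'info' attribute")
  info
}
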