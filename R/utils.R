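# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() with deterministic behaviour for length-1 x
sample_safe <- function(x, size = length(x), prob = NULL) {
  if (length(x) == 1L && size == 1L) return(x)
  x[sample.int(length(x), size, prob = prob)]
}

stop_socsurv <- function(..., class = "socsurv_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# min-max normalization of average ranks: top rank -> 1
rank_minmax <- function(x) {
  r <- rank(x, ties.method = "average")
  n <- length(x)
  if (n == 1L) return(0.5)
  (r - 1) / (n - 1)
}

is_one <- function(x) length(x) == 1L && !is.na(x)
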