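# Shared helpers: rounding, seeds, interval arithmetic.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; repertoire percentages are reported
#' with halves rounded away from zero, the convention used in the tables
#' this package reproduces.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Merge overlapping intervals
#'
#' Collapses a set of 1-based inclusive intervals on a single reference into
#' the minimal set of disjoint intervals covering their union, sorted by
#' start. Intervals sharing an endpoint coordinate overlap (inclusive
#' coordinates) and are merged; strictly adjacent intervals are kept apart.
#'
#' @param intervals A data frame with columns `start` and `end` (1-based,
#'   inclusive, `start <= end`). Extra columns are dropped.
#' @return A tibble with columns `start` and `end`.
#' @examples
#' merge_intervals(data.frame(start = c(1, 50), end = c(100, 150)))
#' @export
merge_intervals <- function(intervals) {
  intervals <- as_tibble(intervals)[, c("start", "end")]
  if (nrow(intervals) == 0) return(intervals)
  stopifnot(all(intervals$start <= intervals$end))
  intervals <- arrange(intervals, .data$start, .data$end)
  out_start <- intervals$start[1]
  out_end <- intervals$end[1]
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(intervals))[-1]) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s <= out_end + 0) {  # overlap or touch at shared coordinate
      out_end <- max(out_end, e)
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- s; out_end <- e
    }
  }
  tibble(start = c(starts, out_start), end = c(ends, out_end))
}

# Uniform integer draws from [lo, hi], safe when lo == hi (unlike sample()).
sample_int_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Overlap length of two 1-based inclusive intervals (0 if disjoint).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}
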