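# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported obstruction ratios use the
#' conventional half-up rule at 0.1\% granularity.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate a positive scalar integer-ish value.
check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "airway_invalid_parameter")
  }
  as.integer(x)
}

# Clip a window of side `s` centred at 0-based (x, y) to an H x W raster.
# Returns 1-based row/col index ranges, or NULL when the window misses the
# raster entirely.
clip_window <- function(x, y, s, width, height) {
  x0 <- x - floor(s / 2)
  y0 <- y - floor(s / 2)
  cols <- max(x0, 0L):min(x0 + s - 1, width - 1L)
  rows <- max(y0, 0L):min(y0 + s - 1, height - 1L)
  if (x0 + s - 1 < 0 || x0 > width - 1L || y0 + s - 1 < 0 || y0 > height - 1L) {
    return(NULL)
  }
  list(rows = rows + 1L, cols = cols + 1L)
}

# Parse "a-b" interval strings into a 2-column matrix of frame ranges.
parse_intervals <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(matrix(integer(), ncol = 2L))
  }
  if (is.list(x)) x <- vapply(x, function(v) paste0(v[1], "-", v[2]), character(1))
  parts <- strsplit(as.character(x), "-", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed interval '%s'; expected 'start-end'.",
                  x[which(bad)[1]]), class = "airway_invalid_parameter")
  }
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  if (any(is.na(m)) || any(m[, 1] > m[, 2])) {
    abort("Intervals must be integer ranges with start <= end.",
          class = "airway_invalid_parameter")
  }
  m
}

in_intervals <- function(n, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(n)))
  out <- rep(FALSE, length(n))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (n >= intervals[i, 1] & n <= intervals[i, 2])
  }
  out
}
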