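#' Detect oscillation peaks and troughs
#'
#' Finds local maxima that clear three gates — a minimum height, a minimum
#' topographic prominence, and a minimum mutual separation — and, on the
#' negated trace, the matching local minima.  The defaults (10 mV height,
#' 5 mV prominence, 100 s separation) are the thresholds used for the
#' recorded cultures.
#'
#' Prominence of a local maximum is its height above the higher of the two
#' valleys that separate it from higher terrain (or the record edge) on each
#' side.  When two candidate peaks fall within `min_separation` of each
#' other, the higher one is kept; at equal height, the earlier one.
#'
#' Troughs by default have no height gate (recordings can sit on a negative
#' baseline, where a positive height requirement on minima is meaningless):
#' they must only meet the prominence and separation requirements.  Set
#' `trough_height_gate = TRUE` to require trough values <= `-min_height`.
#'
#' @param ts An [osc_timeseries].
#' @param min_height Minimum peak value, mV (default 10).
#' @param prominence Minimum topographic prominence, mV (default 5).
#' @param min_separation Minimum spacing between kept peaks, s (default 100).
#'   Must be at least one sample interval.
#' @param trough_height_gate If `TRUE`, troughs must reach `-min_height`.
#' @return An object of class `peak_table`: a list with numeric vectors
#'   `peak_times`, `peak_values`, `trough_times`, `trough_values` (times in
#'   seconds, values in mV, both strictly increasing in time).  An empty
#'   trace yields an empty table, not an error.
#' @examples
#' ts <- generate_channel(channel_params("X", 80, 500, 0), 5000, 1)
#' pt <- detect_extrema(ts)
#' pt$peak_times  # ~ 125 + 500 k
#' @export
detect_extrema <- function(ts, min_height = 10, prominence = 5,
                           min_separation = 100,
                           trough_height_gate = FALSE) {
  stopifnot(inherits(ts, "osc_timeseries"))
  if (min_separation < 1 / ts$rate)
    stop("`min_separation` must be >= one sample interval", call. = FALSE)
  v <- ts$values
  tt <- ts_times(ts)
  sep_samples <- min_separation * ts$rate

  pk <- .find_peaks(v, min_height, prominence, sep_samples,
                    height_gate = TRUE)
  tr <- .find_peaks(-v, min_height, prominence, sep_samples,
                    height_gate = trough_height_gate)

  structure(
    list(peak_times = tt[pk], peak_values = v[pk],
         trough_times = tt[tr], trough_values = v[tr]),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d peaks, %d troughs\n",
              length(x$peak_times), length(x$trough_times)))
  invisible(x)
}

# Local-maximum detection with height, prominence and separation gates.
# Returns sorted sample indices.  Plateaus count once, at their midpoint.
.find_peaks <- function(v, min_height, min_prominence, sep_samples,
                        height_gate = TRUE) {
  n <- length(v)
  if (n < 3L) return(integer(0))

  # candidate local maxima (plateau-aware): rising edge followed by a fall
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) {
        cand <- c(cand, (i + j) %/% 2L)  # midpoint of the plateau
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(integer(0))

  if (height_gate) cand <- cand[v[cand] >= min_height]
  if (!length(cand)) return(integer(0))

  prom <- vapply(cand, .prominence_at, 0, v = v)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))

  # enforce separation: higher peak wins, earlier wins ties
  ord <- order(-v[cand], cand)
  keep <- logical(length(cand))
  kept_idx <- integer(0)
  for (k in ord) {
    if (!length(kept_idx) ||
        all(abs(cand[k] - kept_idx) >= sep_samples - 1e-9)) {
      keep[k] <- TRUE
      kept_idx <- c(kept_idx, cand[k])
    }
  }
  sort(cand[keep])
}

# Topographic prominence of the local maximum at index p: height above the
# higher of the two minima separating it from higher terrain (or the edge).
.prominence_at <- function(v, p) {
  vp <- v[p]
  left_min <- vp
  i <- p - 1L
  while (i >= 1L && v[i] <= vp) {
    if (v[i] < left_min) left_min <- v[i]
    i <- i - 1L
  }
  right_min <- vp
  i <- p + 1L
  while (i <= length(v) && v[i] <= vp) {
    if (v[i] < right_min) right_min <- v[i]
    i <- i + 1L
  }
  vp - max(left_min, right_min)
}
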