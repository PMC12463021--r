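#' Read a multichannel recording from delimited text
#'
#' Expects the data-logger export layout this package also writes: a header
#' row naming a time column (first column, seconds) and one potential
#' column per channel (mV), one row per sample.  The sampling rate is
#' inferred from the median time step; time must be strictly increasing and
#' uniform to within 1% of the median step.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).  The decimal separator is
#'   always `"."`.
#' @return Named list of [osc_timeseries], one per channel column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' ens <- generate_ensemble(ensemble_preset("pure_algae"), 100)
#' write_timeseries(ens, f)
#' rt <- read_timeseries(f)
#' names(rt)
#' @export
read_timeseries <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = sep, header = TRUE, dec = ".",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) < 2L)
    stop("recording too short: need at least 2 samples", call. = FALSE)
  if (ncol(tab) < 2L)
    stop("need a time column plus at least one channel column", call. = FALSE)
  tt <- as.numeric(tab[[1]])
  if (anyNA(tt)) stop("non-numeric time column", call. = FALSE)
  dt <- diff(tt)
  if (any(dt <= 0))
    stop("time column must be strictly increasing", call. = FALSE)
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step))
    stop("irregular sampling: time steps deviate more than 1% from the median",
         call. = FALSE)
  rate <- 1 / step
  labels <- names(tab)[-1]
  out <- lapply(labels, function(lab) {
    v <- as.numeric(tab[[lab]])
    if (anyNA(v)) stop("non-numeric values in channel ", lab, call. = FALSE)
    osc_timeseries(v, rate = rate, t0 = tt[1], label = lab)
  })
  names(out) <- labels
  out
}

#' Write a multichannel recording as delimited text
#'
#' Writes the layout [read_timeseries()] reads: `time_s` plus one column per
#' channel.  All series must share a sampling grid.
#'
#' @param series Named list of [osc_timeseries] on a common grid.
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @param digits Significant digits written (default 10; values survive a
#'   round-trip to well below 1e-6 mV at recording scale).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path, sep = ",", digits = 10) {
  if (inherits(series, "osc_timeseries")) series <- list(series)
  stopifnot(length(series) > 0)
  ref <- series[[1]]
  for (ts in series) {
    stopifnot(inherits(ts, "osc_timeseries"))
    if (!same_grid(ts, ref))
      stop("all series must share the same sampling grid", call. = FALSE)
  }
  labels <- vapply(series, `[[`, "", "label")
  cols <- c(list(time_s = ts_times(ref)),
            stats::setNames(lapply(series, `[[`, "values"), labels))
  tab <- as.data.frame(lapply(cols, function(x) sprintf("%.*g", digits, x)))
  names(tab) <- names(cols)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
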