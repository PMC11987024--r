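#' Running median with shrinking end windows
#'
#' Centered running median of window `window`; at the series ends the
#' window shrinks to the available samples. For an even effective window
#' the lower median is used (no averaging), so the statistic is always an
#' observed value.
#'
#' @param x Numeric vector.
#' @param window Window size in samples (default 15).
#' @return Numeric vector of the same length.
#' @export
running_median <- function(x, window = 15) {
  n <- length(x)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  if (window < 1) stop("window must be >= 1")
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - left):min(n, i + right)]
    sort(w)[(length(w) + 1L) %/% 2L]  # lower median when even
  }, 0)
}

#' Normalized elugram
#'
#' Divides a raw elugram by the plateau fluorescence of the relevant
#' compound-only control, so the control's own plateau maps to 1 and sample
#' plateaus read directly as free-compound fractions.
#'
#' @param times Times (s), increasing.
#' @param fluorescence Raw fluorescence trace.
#' @param control_plateau Plateau fluorescence of the control (> 0).
#' @param meta Optional named list (compound, concentration, ...).
#' @return List of class `"elugram"` with `times`, `fluorescence`
#'   (normalized) and `meta`.
#' @export
normalize_elugram <- function(times, fluorescence, control_plateau,
                              meta = list()) {
  if (any(diff(times) <= 0)) stop("`times` must be increasing")
  if (!is.finite(control_plateau) || control_plateau <= 0)
    stop("`control_plateau` must be > 0 (got ", control_plateau, ")")
  structure(list(times = as.numeric(times),
                 fluorescence = fluorescence / control_plateau,
                 meta = meta),
            class = "elugram")
}

#' Spike detection by running-median thresholding
#'
#' Flags samples exceeding the running median by more than `threshold`
#' normalized fluorescence units; contiguous flagged samples are merged
#' into single spikes (a gap of at least one unflagged sample separates
#' spikes). Spikes reflect individual fibrils or fibril clusters passing
#' the detector.
#'
#' @param e An [normalize_elugram()] result, or a list with `times` and
#'   `fluorescence`.
#' @param threshold Height above the running median (normalized units,
#'   default 0.01).
#' @param window Running-median window in samples (default 15).
#' @return List of class `"spike_call"`: `count`, `times` (peak time of
#'   each spike), `heights` (peak height above the running median),
#'   `index` (logical flag per sample), `baseline` (running median).
#' @export
detect_spikes <- function(e, threshold = 0.01, window = 15) {
  x <- e$fluorescence
  med <- running_median(x, window)
  excess <- x - med
  flag <- excess > threshold
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  spike_runs <- which(runs$values)
  peak_idx <- vapply(spike_runs, function(k) {
    i <- starts[k]:ends[k]
    i[which.max(excess[i])]
  }, 0L)
  structure(list(count = length(spike_runs),
                 times = e$times[peak_idx],
                 heights = excess[peak_idx],
                 index = flag, baseline = med,
                 threshold = threshold, window = window),
            class = "spike_call")
}

#' @export
print.spike_call <- function(x, ...) {
  cat("Spike call:", x$count, "spike(s) above running median + ",
      x$threshold, "\n")
  if (x$count)
    cat("  at t =", paste(signif(x$times, 4), collapse = ", "), "s\n")
  invisible(x)
}

#' Plateau level of an elugram
#'
#' Median of the normalized fluorescence inside the plateau window, with
#' spike-flagged samples masked out; on a control-normalized elugram this
#' is the free-compound fraction.
#'
#' @param e A normalized elugram.
#' @param plateau_window Time window (s) of the plateau, default
#'   `c(30, 80)`.
#' @param threshold,window Spike-detection settings used for masking.
#' @return Plateau level (fraction of the control).
#' @export
plateau_concentration <- function(e, plateau_window = c(30, 80),
                                  threshold = 0.01, window = 15) {
  sel <- e$times >= plateau_window[1L] & e$times <= plateau_window[2L]
  if (!any(sel)) stop("no samples inside the plateau window [",
                      plateau_window[1L], ", ", plateau_window[2L], "] s")
  spikes <- detect_spikes(e, threshold = threshold, window = window)
  keep <- sel & !spikes$index
  if (!any(keep))
    stop("plateau window is empty after spike masking")
  stats::median(e$fluorescence[keep])
}
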