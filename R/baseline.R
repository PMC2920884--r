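# Baseline detection and subtraction. Baselines are TIC-level: one background
# abundance per scan, index-aligned with the scan list, never exceeding the
# TIC (clamped). Detectors are pluggable via register_baseline_detector().

#' Detect a baseline by centered moving minimum
#'
#' The per-scan baseline inside the selection is the centered moving minimum
#' of the TIC over `window_scans` scans (truncated at the window edges),
#' optionally followed by a centered moving average of the same width.  The
#' result is clamped so that `baseline[i] <= TIC[i]` everywhere; scans outside
#' the selection get baseline 0.  On a peak-free linear drift `a + b * t` the
#' recovered baseline lags the truth by at most
#' `|b| * window_scans * scan_interval / 2`.
#'
#' @param selection a [chromatogram_selection()].
#' @param window_scans odd window width in scans (>= 3), at most the selection
#'   length.
#' @param smooth apply the moving-average pass (default `TRUE`).
#' @return numeric baseline vector, one value per scan of the chromatogram.
#' @export
detect_baseline_moving_min <- function(selection, window_scans = 31L,
                                       smooth = TRUE) {
  stopifnot(inherits(selection, "chromatogram_selection"))
  window_scans <- as.integer(window_scans)
  if (window_scans < 3L || window_scans %% 2L == 0L)
    stop("window_scans must be an odd integer >= 3")
  idx <- selection_indices(selection)
  if (window_scans > length(idx)) stop("window too large for selection")

  tic_all <- chromatogram_tic(selection$chromatogram)
  tic <- tic_all[idx]
  hw <- (window_scans - 1L) %/% 2L
  n <- length(tic)
  base <- vapply(seq_len(n), function(i)
    min(tic[max(1L, i - hw):min(n, i + hw)]), double(1))
  if (smooth && n > 2L * hw) {
    # average only where the full window fits; truncated edge windows would
    # add lag beyond the documented |slope| * window * dt / 2 bound
    sm <- base
    for (i in (hw + 1L):(n - hw)) sm[i] <- mean(base[(i - hw):(i + hw)])
    base <- sm
  }
  base <- pmin(pmax(base, 0), tic)

  out <- numeric(length(tic_all))
  out[idx] <- base
  out
}

#' Detect and attach a baseline by detector id
#'
#' @param selection a [chromatogram_selection()].
#' @param method id of a registered baseline detector (default "moving-min").
#' @param ... parameters passed to the detector.
#' @return the chromatogram with the detected baseline attached.
#' @export
detect_baseline <- function(selection, method = "moving-min", ...) {
  entry <- registry_lookup("baseline_detectors", method)
  values <- entry$fun(selection, ...)
  set_baseline(selection$chromatogram, values)
}

#' Subtract the attached baseline from a chromatogram
#'
#' Each scan's spectrum is scaled by `max(TIC - baseline, 0) / TIC`
#' (proportional removal, consistent with the TIC convention of the filters);
#' zero-TIC scans are untouched.  The attached baseline is reset to 0 over the
#' subtracted scans.  [subtract_baseline()] operates on the whole
#' chromatogram; [filter_subtract_baseline()] is the selection-local variant
#' registered as the `"subtract-baseline"` filter.
#'
#' @param x a `chromatogram` with a baseline attached.
#' @return the modified `chromatogram`.
#' @export
subtract_baseline <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  filter_subtract_baseline(chromatogram_selection(x))
}

#' @rdname subtract_baseline
#' @param selection a [chromatogram_selection()]; scans outside its window are
#'   left untouched.
#' @export
filter_subtract_baseline <- function(selection) {
  stopifnot(inherits(selection, "chromatogram_selection"))
  x <- selection$chromatogram
  if (is.null(x$baseline)) stop("no baseline attached; run a baseline detector first")
  tic <- chromatogram_tic(x)
  for (i in selection_indices(selection)) {
    if (tic[i] > 0 && x$baseline[i] > 0)
      x$scans[[i]]$spectrum <- scale_spectrum(
        x$scans[[i]]$spectrum, max(tic[i] - x$baseline[i], 0) / tic[i])
    x$baseline[i] <- 0
  }
  x
}
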