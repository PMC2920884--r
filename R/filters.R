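# Quality-enhancing filters. Every filter takes a chromatogram_selection and
# returns the full modified chromatogram; scans outside the selection window
# are returned bit-identical. No filter may produce negative abundances or
# reorder/remove scans (checked by apply_filter()).

# scale one scan's spectrum by a non-negative factor
scale_spectrum <- function(spectrum, factor) {
  factor <- max(factor, 0)
  spectrum$abundance <- spectrum$abundance * factor
  spectrum
}

#' Savitzky-Golay smoothing of the TIC
#'
#' Smooths the total ion chromatogram inside the selection window with a
#' Savitzky-Golay least-squares polynomial convolution filter and rescales
#' each scan's spectrum proportionally (by `smoothed TIC / original TIC`), so
#' that relative ion patterns are preserved.  Scans with zero TIC are left
#' untouched.  The first and last `(window - 1) / 2` scans of the selection
#' are left unsmoothed (no asymmetric edge filters); negative smoothed values
#' are clamped to 0.
#'
#' @param selection a [chromatogram_selection()].
#' @param window odd filter length in scans, `5 <= window <=` selection size.
#' @param poly_order polynomial fit order, `2 <= poly_order <= window - 2`.
#' @return the modified `chromatogram`.
#' @export
filter_savitzky_golay <- function(selection, window = 9L, poly_order = 2L) {
  stopifnot(inherits(selection, "chromatogram_selection"))
  window <- as.integer(window); poly_order <- as.integer(poly_order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 5L) stop("window must be >= 5")
  if (poly_order < 2L || poly_order > window - 2L)
    stop("poly_order must satisfy 2 <= poly_order <= window - 2")
  idx <- selection_indices(selection)
  if (length(idx) < window) stop("selection smaller than window")

  chrom <- selection$chromatogram
  tic <- chromatogram_tic(chrom)[idx]
  smoothed <- sg_smooth_interior(tic, window, poly_order)
  smoothed <- pmax(smoothed, 0)

  for (k in seq_along(idx)) {
    i <- idx[k]
    if (tic[k] > 0 && smoothed[k] != tic[k])
      chrom$scans[[i]]$spectrum <-
        scale_spectrum(chrom$scans[[i]]$spectrum, smoothed[k] / tic[k])
  }
  chrom
}

# SG convolution with the central coefficient row; edges (first/last half
# window) are returned unchanged. Coefficients come from signal::sgolay.
sg_smooth_interior <- function(y, window, poly_order) {
  hw <- (window - 1L) %/% 2L
  coef <- signal::sgolay(p = poly_order, n = window)[hw + 1L, ]
  n <- length(y)
  out <- y
  if (n >= window) {
    sm <- stats::filter(y, rev(coef), method = "convolution", sides = 2)
    mid <- (hw + 1L):(n - hw)
    out[mid] <- as.numeric(sm)[mid]
  }
  out
}

#' Remove per-ion background from a selection
#'
#' For every nominal mass observed inside the selection window, the minimum
#' abundance of that ion trace over the window (0 if the ion is absent from
#' any scan in the window) is subtracted from that ion at every scan; results
#' are floored at 0.  This removes a constant background per mass fragment,
#' e.g. column bleed ions.
#'
#' @param selection a [chromatogram_selection()] covering at least 2 scans.
#' @return the modified `chromatogram`.
#' @export
filter_remove_background <- function(selection) {
  stopifnot(inherits(selection, "chromatogram_selection"))
  idx <- selection_indices(selection)
  if (length(idx) < 2L) stop("selection must cover at least 2 scans")
  chrom <- selection$chromatogram

  mzs <- sort(unique(unlist(lapply(chrom$scans[idx],
                                   function(s) s$spectrum$mz))))
  if (!length(mzs)) return(chrom)
  mins <- rep(Inf, length(mzs))
  for (i in idx) {
    sp <- chrom$scans[[i]]$spectrum
    ab <- sp$abundance[match(mzs, sp$mz)]
    ab[is.na(ab)] <- 0          # absent ion counts as abundance 0
    mins <- pmin(mins, ab)
  }

  for (i in idx) {
    sp <- chrom$scans[[i]]$spectrum
    j <- match(sp$mz, mzs)
    sp$abundance <- pmax(sp$abundance - mins[j], 0)
    chrom$scans[[i]]$spectrum <- sp
  }
  chrom
}

#' Mean-normalize a selection's TIC
#'
#' Multiplies every abundance inside the selection window by
#' `target / mean(TIC)` so that the post-filter mean TIC over the window
#' equals `target`.
#'
#' @param selection a [chromatogram_selection()].
#' @param target desired mean TIC, positive real (default 1000).
#' @return the modified `chromatogram`.
#' @export
filter_mean_normalize <- function(selection, target = 1000) {
  stopifnot(inherits(selection, "chromatogram_selection"))
  target <- as.double(target)
  if (!is.finite(target) || target <= 0) stop("target must be positive")
  idx <- selection_indices(selection)
  if (!length(idx)) stop("selection contains no scans")
  chrom <- selection$chromatogram
  m <- mean(chromatogram_tic(chrom)[idx])
  if (m <= 0) stop("cannot normalize zero signal")
  f <- target / m
  if (f != 1)
    for (i in idx)
      chrom$scans[[i]]$spectrum <- scale_spectrum(chrom$scans[[i]]$spectrum, f)
  chrom
}
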