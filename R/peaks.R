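# Peak detection, integration and geometry. Detection and integration are
# deliberately decoupled: any detector produces Peak objects with the area
# unset; a single integrator is then applied to the whole peak list, so that
# areas from mixed detectors remain comparable.

#' Construct a peak
#'
#' A peak is a detected feature spanning `[start_scan, stop_scan]` with its
#' apex strictly inside the span.  `profile` holds the raw TIC over the span;
#' `background_line` is the straight (valley-to-valley) segment under the
#' peak, given by its values at the start and stop scans.  Integrators
#' subtract the background line from the profile.
#'
#' @param start_scan,apex_scan,stop_scan scan indices with
#'   `start < apex < stop`.
#' @param profile numeric vector of TIC values over `[start_scan, stop_scan]`,
#'   non-negative, maximal at the apex.
#' @param background_line length-2 numeric: background value at the start and
#'   stop scan (default `c(0, 0)`).
#' @return an object of class `chrom_peak` with `area`, `integrator_id` and
#'   `geometry` unset.
#' @export
new_peak <- function(start_scan, apex_scan, stop_scan, profile,
                     background_line = c(0, 0)) {
  start_scan <- as.integer(start_scan); apex_scan <- as.integer(apex_scan)
  stop_scan <- as.integer(stop_scan)
  if (!(start_scan < apex_scan && apex_scan < stop_scan))
    stop("peak indices must satisfy start < apex < stop")
  profile <- as.double(profile)
  n <- stop_scan - start_scan + 1L
  if (length(profile) != n)
    stop("profile length must equal the scan span")
  if (any(profile < 0)) stop("profile values must be >= 0")
  background_line <- as.double(background_line)
  stopifnot(length(background_line) == 2L, all(background_line >= 0))
  # apex maximality is judged above the background line
  q <- profile - (background_line[1] +
    (background_line[2] - background_line[1]) * (seq_len(n) - 1) / (n - 1))
  if (q[apex_scan - start_scan + 1L] < max(q) - 1e-9 * max(abs(q), 1))
    stop("profile (above background) must be maximal at the apex scan")
  structure(list(start_scan = start_scan, apex_scan = apex_scan,
                 stop_scan = stop_scan, profile = profile,
                 background_line = background_line, area = NULL,
                 integrator_id = NULL, geometry = NULL),
            class = "chrom_peak")
}

#' @export
print.chrom_peak <- function(x, ...) {
  cat(sprintf("<peak: scans %d-%d, apex %d, height %.6g%s>\n",
              x$start_scan, x$stop_scan, x$apex_scan, peak_height(x),
              if (!is.null(x$area))
                sprintf(", area %.6g [%s]", x$area, x$integrator_id) else ""))
  invisible(x)
}

# interpolated background line under the peak, one value per profile point
peak_background <- function(peak) {
  n <- length(peak$profile)
  peak$background_line[1] +
    (peak$background_line[2] - peak$background_line[1]) *
    (seq_len(n) - 1) / (n - 1)
}

#' Peak height above the background line
#' @param peak a `chrom_peak`.
#' @return apex intensity minus the interpolated background at the apex.
#' @export
peak_height <- function(peak) {
  stopifnot(inherits(peak, "chrom_peak"))
  q <- pmax(peak$profile - peak_background(peak), 0)
  q[peak$apex_scan - peak$start_scan + 1L]
}

#' First-derivative peak detection on the smoothed TIC
#'
#' The TIC inside the selection is Savitzky-Golay smoothed (order 2, width
#' `smooth_window`); candidate peaks are the spans between the local TIC
#' minima flanking each +/- zero crossing of the first derivative.  The noise
#' level is estimated as `1.4826 * median(|d - median(d)|)` over the
#' derivative `d` of the raw TIC.  A candidate is kept iff its apex
#' height above the local (valley-to-valley) background divided by the noise
#' level is at least `snr_threshold` and its span is at least
#' `min_width_scans`.  Detected peaks are non-overlapping, sorted by start
#' scan, and attached to the returned chromatogram with their area unset.
#'
#' @param selection a [chromatogram_selection()] covering at least
#'   `smooth_window` scans.
#' @param snr_threshold minimum signal-to-noise ratio, positive (default 5).
#' @param min_width_scans minimum peak span in scans (default 3).
#' @param smooth_window odd Savitzky-Golay window (default 9).
#' @return the chromatogram with `$peaks` replaced by the detected list.
#' @export
detect_peaks_first_derivative <- function(selection, snr_threshold = 5,
                                          min_width_scans = 3L,
                                          smooth_window = 9L) {
  stopifnot(inherits(selection, "chromatogram_selection"))
  if (!is.finite(snr_threshold) || snr_threshold <= 0)
    stop("snr_threshold must be positive")
  min_width_scans <- as.integer(min_width_scans)
  if (min_width_scans < 3L) stop("min_width_scans must be >= 3")
  idx <- selection_indices(selection)
  if (length(idx) < smooth_window) stop("selection smaller than smooth_window")

  chrom <- selection$chromatogram
  tic_all <- chromatogram_tic(chrom)
  tic <- tic_all[idx]
  s <- sg_smooth_interior(tic, as.integer(smooth_window), 2L)
  n <- length(s)
  d <- diff(s)
  # noise level from the raw-TIC derivative: robust to peaks (median) and not
  # deflated by the smoothing that the candidate search runs on
  draw <- diff(tic)
  noise <- 1.4826 * stats::median(abs(draw - stats::median(draw)))
  if (noise <= 0) noise <- .Machine$double.eps * max(max(abs(s)), 1)

  # apex candidates: derivative crosses from positive to non-positive
  cross <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  # local minima of the smoothed TIC (boundaries count as minima)
  is_min <- c(TRUE, s[2:(n - 1)] <= s[1:(n - 2)] & s[2:(n - 1)] <= s[3:n],
              TRUE)
  mins <- which(is_min)

  cand <- list()
  for (a in cross) {
    lo <- max(mins[mins < a])
    hi <- min(mins[mins > a])
    key <- sprintf("%d:%d", lo, hi)
    if (!is.null(cand[[key]]) && s[cand[[key]]$apex] >= s[a]) next
    cand[[key]] <- list(start = lo, apex = a, stop = hi)
  }
  cand <- cand[order(vapply(cand, `[[`, integer(1), "start"))]

  keep <- list()
  for (p in cand) {
    if (p$stop - p$start + 1L < min_width_scans) next
    bg <- s[p$start] + (s[p$stop] - s[p$start]) *
      (p$apex - p$start) / (p$stop - p$start)
    if ((s[p$apex] - bg) / noise < snr_threshold) next
    keep[[length(keep) + 1L]] <- p
  }

  # resolve shared valleys so spans do not overlap
  if (length(keep) > 1L)
    for (k in seq_len(length(keep) - 1L))
      if (!is.null(keep[[k + 1L]]) && keep[[k + 1L]]$start <= keep[[k]]$stop)
        keep[[k + 1L]]$start <- keep[[k]]$stop + 1L
  keep <- Filter(function(p) p$start < p$apex && p$apex < p$stop &&
                   p$stop - p$start + 1L >= min_width_scans, keep)

  peaks <- lapply(keep, function(p) {
    gi <- idx[p$start]:idx[p$stop]          # absolute scan indices
    profile <- tic_all[gi]
    m <- length(gi)
    bg <- profile[1] + (profile[m] - profile[1]) * (seq_len(m) - 1) / (m - 1)
    interior <- 2:(m - 1L)
    apex_abs <- gi[interior][which.max((profile - bg)[interior])]
    new_peak(gi[1], apex_abs, gi[m], profile,
             background_line = c(profile[1], profile[m]))
  })
  chrom$peaks <- peaks
  chrom
}

#' Detect peaks by detector id
#'
#' @param selection a [chromatogram_selection()].
#' @param method id of a registered peak detector (default "first-derivative").
#' @param ... parameters passed to the detector.
#' @return the chromatogram with detected peaks attached.
#' @export
detect_peaks <- function(selection, method = "first-derivative", ...) {
  entry <- registry_lookup("peak_detectors", method)
  out <- entry$fun(selection, ...)
  stopifnot(inherits(out, "chromatogram"))
  out
}

#' Trapezoidal peak integration
#'
#' Integrates the peak profile minus its linear background line (clamped at 0)
#' by the trapezoidal rule over the actual scan times.  The area unit is
#' abundance x seconds.
#'
#' @param peak a `chrom_peak` with a profile of length >= 2.
#' @param scan_times integer vector of the chromatogram's scan times (ms).
#' @return the peak with `area` (>= 0) and `integrator_id` set.
#' @export
integrate_trapezoid <- function(peak, scan_times) {
  stopifnot(inherits(peak, "chrom_peak"))
  if (length(peak$profile) < 2L) stop("peak profile must have >= 2 points")
  t_s <- scan_times[peak$start_scan:peak$stop_scan] / 1000  # ms -> s
  if (length(t_s) != length(peak$profile))
    stop("scan_times do not cover the peak span")
  q <- pmax(peak$profile - peak_background(peak), 0)
  dt <- diff(t_s)
  peak$area <- sum((q[-length(q)] + q[-1]) / 2 * dt)
  peak$integrator_id <- "trapezoid"
  peak
}

#' Integrate all detected peaks with one integrator
#'
#' Applies the same registered integrator to every peak of the chromatogram,
#' so that all areas are directly comparable; the integrator id is recorded
#' identically on every peak.  Calling again with another integrator
#' overwrites areas and ids (last integrator wins).
#'
#' @param x a `chromatogram` with at least one detected peak.
#' @param integrator_id id of a registered integrator (default "trapezoid").
#' @return the chromatogram with every peak's `area` and `integrator_id` set.
#' @export
integrate_all <- function(x, integrator_id = "trapezoid") {
  stopifnot(inherits(x, "chromatogram"))
  if (!length(x$peaks)) stop("run a peak detector first")
  entry <- registry_lookup("integrators", integrator_id)
  st <- scan_times(x)
  x$peaks <- lapply(x$peaks, function(p) {
    p <- entry$fun(p, st)
    p$integrator_id <- integrator_id
    p
  })
  x
}

#' Peak geometry: flank tangents and widths
#'
#' Fits least-squares tangent lines through the background-corrected profile
#' points lying between 15% and 85% of the apex height on the rising and
#' falling flank, computes the width at 50% of apex height (linear
#' interpolation between bracketing scans) and the tangent width at the
#' background (span between each tangent's intersection with the background
#' line, i.e. height 0 after correction).
#'
#' @param peak a `chrom_peak` spanning at least 5 scans.
#' @param scan_times integer vector of the chromatogram's scan times (ms).
#' @return a list of class `peak_geometry` with elements `inc_slope`,
#'   `inc_intercept`, `dec_slope`, `dec_intercept` (abundance vs ms),
#'   `width_50` and `width_0` (ms).
#' @export
compute_geometry <- function(peak, scan_times) {
  stopifnot(inherits(peak, "chrom_peak"))
  if (peak$stop_scan - peak$start_scan + 1L < 5L)
    stop("peak span must be >= 5 scans")
  t_ms <- as.double(scan_times[peak$start_scan:peak$stop_scan])
  q <- pmax(peak$profile - peak_background(peak), 0)
  a <- peak$apex_scan - peak$start_scan + 1L
  h <- q[a]
  if (h <= 0) stop("peak has zero height above background")

  band <- function(i) i[q[i] >= 0.15 * h & q[i] <= 0.85 * h]
  inc <- band(seq_len(a))
  dec <- band(a:length(q))
  if (length(inc) < 2L || length(dec) < 2L)
    stop("flank has < 2 points in the 15-85% height band")
  fit <- function(i) stats::lsfit(t_ms[i], q[i])$coefficients  # (intercept, slope)
  fi <- fit(inc); fd <- fit(dec)
  if (fi[2] <= 0) stop("increasing tangent slope is not positive")
  if (fd[2] >= 0) stop("decreasing tangent slope is not negative")

  interp_t <- function(i, j, target) {      # q[i], q[j] bracket the target
    if (q[j] == q[i]) return(t_ms[i])
    t_ms[i] + (t_ms[j] - t_ms[i]) * (target - q[i]) / (q[j] - q[i])
  }
  target <- h / 2
  left50 <- t_ms[1]
  for (i in a:2)
    if (q[i - 1] <= target && q[i] >= target) {
      left50 <- interp_t(i - 1L, i, target); break
    }
  right50 <- t_ms[length(q)]
  for (i in a:(length(q) - 1))
    if (q[i] >= target && q[i + 1] <= target) {
      right50 <- interp_t(i, i + 1L, target); break
    }

  x0_inc <- -fi[1] / fi[2]   # tangent meets background (height 0)
  x0_dec <- -fd[1] / fd[2]
  structure(list(inc_slope = unname(fi[2]), inc_intercept = unname(fi[1]),
                 dec_slope = unname(fd[2]), dec_intercept = unname(fd[1]),
                 width_50 = right50 - left50,
                 width_0 = unname(x0_dec - x0_inc)),
            class = "peak_geometry")
}

#' @export
print.peak_geometry <- function(x, ...) {
  cat(sprintf(paste0("<peak geometry: width50 %.1f ms, width0 %.1f ms, ",
                     "slopes %+.4g / %+.4g>\n"),
              x$width_50, x$width_0, x$inc_slope, x$dec_slope))
  invisible(x)
}

#' Attach geometry to every integrated peak
#'
#' @param x a `chromatogram` with detected peaks.
#' @return the chromatogram with `geometry` set on each peak for which the
#'   tangent fit is possible (others keep `geometry = NULL`).
#' @export
compute_all_geometry <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  st <- scan_times(x)
  x$peaks <- lapply(x$peaks, function(p) {
    g <- tryCatch(compute_geometry(p, st), error = function(e) NULL)
    p$geometry <- g
    p
  })
  x
}

#' Tabulate detected peaks
#'
#' @param x a `chromatogram`.
#' @return data.frame with one row per peak: apex_rt_ms, start_scan,
#'   stop_scan, height, area, width_50_ms, integrator_id.
#' @export
peak_table <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  st <- scan_times(x)
  rows <- lapply(x$peaks, function(p) {
    data.frame(apex_rt_ms = st[p$apex_scan], start_scan = p$start_scan,
               stop_scan = p$stop_scan, height = peak_height(p),
               area = if (is.null(p$area)) NA_real_ else p$area,
               width_50_ms = if (is.null(p$geometry)) NA_real_
                             else p$geometry$width_50,
               integrator_id = if (is.null(p$integrator_id)) NA_character_
                               else p$integrator_id)
  })
  if (!length(rows))
    return(data.frame(apex_rt_ms = numeric(), start_scan = integer(),
                      stop_scan = integer(), height = numeric(),
                      area = numeric(), width_50_ms = numeric(),
                      integrator_id = character()))
  do.call(rbind, rows)
}
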