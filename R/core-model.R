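#' chromkit: vendor-neutral processing of nominal-mass GC/MS chromatograms
#'
#' The package models a chromatogram as an ordered list of scans, each scan
#' holding a centroided nominal-mass spectrum of (m/z, abundance) pairs, with
#' optional attached baseline and peak list.  Retention times are integer
#' milliseconds; m/z values are positive integers (nominal mass); abundances
#' are non-negative doubles in arbitrary intensity units.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a nominal-mass spectrum
#'
#' A mass spectrum is a set of ions keyed by integer m/z; each m/z appears at
#' most once.  Abundances are stored as doubles.
#'
#' @param mz integer vector of nominal m/z values (>= 1), no duplicates.
#' @param abundance numeric vector of non-negative abundances, same length.
#' @return an object of class `mass_spectrum` with ions sorted by m/z.
#' @examples
#' ms <- mass_spectrum(c(57, 43, 71), c(100, 999, 40))
#' total_signal(ms)
#' @export
mass_spectrum <- function(mz = integer(), abundance = numeric()) {
  if (length(mz) != length(abundance))
    stop("mz and abundance must have the same length")
  mz <- validate_mz(mz)
  abundance <- as.double(abundance)
  if (anyNA(abundance) || any(abundance < 0))
    stop("abundances must be non-negative and finite")
  if (anyDuplicated(mz))
    stop("duplicate m/z values; merge ions before constructing a spectrum")
  o <- order(mz)
  structure(list(mz = mz[o], abundance = abundance[o]),
            class = "mass_spectrum")
}

validate_mz <- function(mz) {
  if (length(mz) == 0L) return(integer())
  if (anyNA(mz)) stop("m/z values must not be NA")
  imz <- as.integer(round(mz))
  if (any(abs(mz - imz) > 1e-9))
    stop("m/z values must be integers (nominal mass); round on import")
  if (any(imz < 1L)) stop("m/z values must be >= 1")
  imz
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum: %d ions, total signal %.6g>\n",
              length(x$mz), total_signal(x)))
  invisible(x)
}

#' Total signal of a mass spectrum
#'
#' Sum of all ion abundances; 0 for an empty spectrum.  This is the quantity
#' summed per scan to form the total ion chromatogram (TIC).
#'
#' @param spectrum a `mass_spectrum`.
#' @return non-negative double.
#' @export
total_signal <- function(spectrum) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  sum(spectrum$abundance)
}

#' Set (replace) one ion of a spectrum
#'
#' If the m/z is already present its abundance is replaced (last write wins);
#' otherwise the ion is added.  Importers that need to merge colliding nominal
#' masses use [add_ion()] instead.
#'
#' @param spectrum a `mass_spectrum`.
#' @param mz nominal m/z, positive integer.
#' @param abundance non-negative abundance.
#' @return the updated `mass_spectrum`.
#' @export
set_ion <- function(spectrum, mz, abundance) {
  stopifnot(inherits(spectrum, "mass_spectrum"), length(mz) == 1L,
            length(abundance) == 1L)
  mz <- validate_mz(mz)
  abundance <- as.double(abundance)
  if (is.na(abundance) || abundance < 0) stop("abundance must be >= 0")
  i <- match(mz, spectrum$mz)
  if (is.na(i)) {
    at <- findInterval(mz, spectrum$mz)
    spectrum$mz <- append(spectrum$mz, mz, after = at)
    spectrum$abundance <- append(spectrum$abundance, abundance, after = at)
  } else {
    spectrum$abundance[i] <- abundance
  }
  spectrum
}

#' Add abundance to one ion of a spectrum (merge semantics)
#'
#' Accumulates into an existing ion or creates it.  This is the import path
#' for fractional m/z collisions under the nominal-mass policy.
#'
#' @inheritParams set_ion
#' @return the updated `mass_spectrum`.
#' @export
add_ion <- function(spectrum, mz, abundance) {
  mz <- validate_mz(mz)
  i <- match(mz, spectrum$mz)
  cur <- if (is.na(i)) 0 else spectrum$abundance[i]
  set_ion(spectrum, mz, cur + abundance)
}

#' Construct a scan
#'
#' @param retention_time integer milliseconds >= 0.
#' @param spectrum a `mass_spectrum`.
#' @return a list with elements `rt` and `spectrum`.
#' @export
ms_scan <- function(retention_time, spectrum) {
  stopifnot(length(retention_time) == 1L, inherits(spectrum, "mass_spectrum"))
  rt <- as.integer(round(retention_time))
  if (is.na(rt) || rt < 0) stop("retention_time must be a non-negative integer (ms)")
  list(rt = rt, spectrum = spectrum)
}

#' Construct a chromatogram
#'
#' @param scans list of scans (see [ms_scan()]); retention times must be strictly
#'   increasing and at least one scan is required.
#' @param metadata named character vector (operator, sample name, instrument,
#'   source file, source format, ...).
#' @param baseline optional numeric vector, one non-negative value per scan.
#' @param peaks optional list of peaks (see [new_peak()]).
#' @return an object of class `chromatogram`.
#' @export
chromatogram <- function(scans, metadata = character(), baseline = NULL,
                         peaks = list()) {
  if (length(scans) < 1L) stop("a chromatogram needs at least one scan")
  rts <- vapply(scans, function(s) as.integer(s$rt), integer(1))
  if (any(diff(rts) <= 0L))
    stop("scan retention times must be strictly increasing")
  md <- as.character(metadata)
  names(md) <- names(metadata)
  x <- structure(list(scans = scans, metadata = md, baseline = NULL,
                      peaks = peaks), class = "chromatogram")
  if (!is.null(baseline)) x <- set_baseline(x, baseline)
  x
}

#' Number of scans in a chromatogram
#' @param x a `chromatogram`.
#' @return integer scan count.
#' @export
n_scans <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  length(x$scans)
}

#' Scan retention times
#' @param x a `chromatogram`.
#' @return integer vector of retention times in milliseconds.
#' @export
scan_times <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  vapply(x$scans, function(s) s$rt, integer(1))
}

#' Total ion chromatogram over all scans
#' @param x a `chromatogram`.
#' @return double vector, one TIC value per scan.
#' @export
chromatogram_tic <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  vapply(x$scans, function(s) total_signal(s$spectrum), double(1))
}

#' Attach a baseline to a chromatogram
#'
#' @param x a `chromatogram`.
#' @param values numeric vector, one non-negative value per scan.
#' @return the chromatogram with `$baseline` set.
#' @export
set_baseline <- function(x, values) {
  stopifnot(inherits(x, "chromatogram"))
  values <- as.double(values)
  if (length(values) != n_scans(x))
    stop("baseline length must equal the number of scans")
  if (anyNA(values) || any(values < 0))
    stop("baseline values must be non-negative")
  x$baseline <- values
  x
}

#' Peaks attached to a chromatogram
#' @param x a `chromatogram`.
#' @return list of peaks (possibly empty).
#' @export
chromatogram_peaks <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  x$peaks
}

#' @export
print.chromatogram <- function(x, ...) {
  rts <- scan_times(x)
  cat(sprintf("<chromatogram: %d scans, %.3f-%.3f min>\n",
              n_scans(x), rts[1] / 60000, rts[length(rts)] / 60000))
  if (length(x$metadata))
    cat(sprintf("  %s: %s\n", names(x$metadata), x$metadata), sep = "")
  if (!is.null(x$baseline)) cat("  baseline: attached\n")
  if (length(x$peaks)) cat(sprintf("  peaks: %d\n", length(x$peaks)))
  invisible(x)
}

#' @export
summary.chromatogram <- function(object, ...) {
  tic <- chromatogram_tic(object)
  res <- list(n_scans = n_scans(object), rt_range_ms = range(scan_times(object)),
              tic_range = range(tic), n_peaks = length(object$peaks),
              has_baseline = !is.null(object$baseline))
  class(res) <- "summary.chromatogram"
  res
}

#' @export
print.summary.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram: %d scans, rt %d-%d ms, TIC %.6g-%.6g, %d peaks%s\n",
              x$n_scans, x$rt_range_ms[1], x$rt_range_ms[2],
              x$tic_range[1], x$tic_range[2], x$n_peaks,
              if (x$has_baseline) ", baseline attached" else ""))
  invisible(x)
}

#' Plot a chromatogram TIC with baseline and peaks
#'
#' @param x a `chromatogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.chromatogram <- function(x, ...) {
  rt <- scan_times(x) / 60000
  tic <- chromatogram_tic(x)
  graphics::plot(rt, tic, type = "l", xlab = "retention time [min]",
                 ylab = "TIC [a.u.]", ...)
  if (!is.null(x$baseline))
    graphics::lines(rt, x$baseline, col = "grey50", lty = 2)
  for (p in x$peaks)
    graphics::points(rt[p$apex_scan], tic[p$apex_scan], pch = 2, col = "red")
  invisible(x)
}

#' Nearest scan by retention time
#'
#' Returns the scan minimizing the absolute retention-time distance; on ties
#' the earlier scan wins.
#'
#' @param x a `chromatogram`.
#' @param rt query retention time in milliseconds.
#' @return a scan (list with `rt`, `spectrum`).
#' @export
scan_nearest <- function(x, rt) {
  stopifnot(inherits(x, "chromatogram"), length(rt) == 1L)
  d <- abs(scan_times(x) - as.numeric(rt))
  x$scans[[which.min(d)]]  # which.min takes the first minimum: earlier scan
}

#' Define a selection (retention-time window plus ion filters)
#'
#' Every filter and detector operates on a selection: a retention-time window
#' of a chromatogram with optional include/exclude nominal-mass sets.  The
#' default selection spans the whole chromatogram with all ions.
#'
#' @param chromatogram a `chromatogram`.
#' @param start_rt,stop_rt window bounds in milliseconds (defaults: full range).
#' @param included_ions optional integer m/z set; if given, only these ions
#'   contribute to traces.
#' @param excluded_ions optional integer m/z set removed from traces; must be
#'   disjoint from `included_ions`.
#' @return an object of class `chromatogram_selection`.
#' @export
chromatogram_selection <- function(chromatogram, start_rt = NULL, stop_rt = NULL,
                                   included_ions = NULL, excluded_ions = NULL) {
  stopifnot(inherits(chromatogram, "chromatogram"))
  rts <- scan_times(chromatogram)
  if (is.null(start_rt)) start_rt <- rts[1]
  if (is.null(stop_rt)) stop_rt <- rts[length(rts)]
  start_rt <- as.numeric(start_rt); stop_rt <- as.numeric(stop_rt)
  if (start_rt > stop_rt) stop("start_rt must be <= stop_rt")
  if (stop_rt < rts[1] || start_rt > rts[length(rts)])
    stop("selection window does not intersect the chromatogram's time range")
  if (!is.null(included_ions)) included_ions <- validate_mz(included_ions)
  if (!is.null(excluded_ions)) excluded_ions <- validate_mz(excluded_ions)
  if (length(intersect(included_ions, excluded_ions)))
    stop("included and excluded ion sets must be disjoint")
  structure(list(chromatogram = chromatogram, start_rt = start_rt,
                 stop_rt = stop_rt, included_ions = included_ions,
                 excluded_ions = excluded_ions),
            class = "chromatogram_selection")
}

#' @export
print.chromatogram_selection <- function(x, ...) {
  cat(sprintf("<selection: %d of %d scans, rt %.0f-%.0f ms>\n",
              length(selection_indices(x)), n_scans(x$chromatogram),
              x$start_rt, x$stop_rt))
  invisible(x)
}

#' Scan indices covered by a selection
#' @param selection a `chromatogram_selection`.
#' @return integer vector of scan indices inside the window.
#' @export
selection_indices <- function(selection) {
  stopifnot(inherits(selection, "chromatogram_selection"))
  rts <- scan_times(selection$chromatogram)
  which(rts >= selection$start_rt & rts <= selection$stop_rt)
}

# abundance of one spectrum under the selection's ion filters
filtered_signal <- function(spectrum, included_ions, excluded_ions) {
  keep <- rep(TRUE, length(spectrum$mz))
  if (!is.null(included_ions)) keep <- keep & spectrum$mz %in% included_ions
  if (length(excluded_ions)) keep <- keep & !(spectrum$mz %in% excluded_ions)
  sum(spectrum$abundance[keep])
}

#' Total ion trace of a selection
#'
#' One (retention time, abundance) point per scan inside the window; the
#' abundance respects the selection's included/excluded ion sets.
#'
#' @param selection a `chromatogram_selection`.
#' @return data.frame with columns `rt` (ms) and `abundance`.
#' @export
tic_trace <- function(selection) {
  idx <- selection_indices(selection)
  if (!length(idx)) stop("selection contains no scans")
  ab <- vapply(selection$chromatogram$scans[idx], function(s)
    filtered_signal(s$spectrum, selection$included_ions, selection$excluded_ions),
    double(1))
  data.frame(rt = scan_times(selection$chromatogram)[idx], abundance = ab)
}

#' Extracted-ion trace of a selection
#'
#' Per-scan abundance summed over only the requested m/z values; an m/z absent
#' from a scan contributes 0.  The selection's own ion filters are applied on
#' top of `mz_values`.
#'
#' @param selection a `chromatogram_selection`.
#' @param mz_values non-empty integer set of nominal m/z values to extract.
#' @return data.frame with columns `rt` (ms) and `abundance`.
#' @export
extracted_ion_trace <- function(selection, mz_values) {
  if (length(mz_values) == 0L) stop("mz_values must be non-empty")
  mz_values <- validate_mz(mz_values)
  idx <- selection_indices(selection)
  if (!length(idx)) stop("selection contains no scans")
  ab <- vapply(selection$chromatogram$scans[idx], function(s) {
    sp <- s$spectrum
    keep <- sp$mz %in% mz_values
    if (!is.null(selection$included_ions))
      keep <- keep & sp$mz %in% selection$included_ions
    if (length(selection$excluded_ions))
      keep <- keep & !(sp$mz %in% selection$excluded_ions)
    sum(sp$abundance[keep])
  }, double(1))
  data.frame(rt = scan_times(selection$chromatogram)[idx], abundance = ab)
}

#' All nominal masses observed in a chromatogram
#' @param x a `chromatogram`.
#' @return sorted integer vector of observed m/z values.
#' @export
observed_mz <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  sort(unique(unlist(lapply(x$scans, function(s) s$spectrum$mz))))
}

# internal consistency check used after mutating operations
assert_chromatogram_valid <- function(x) {
  stopifnot(inherits(x, "chromatogram"), n_scans(x) >= 1L)
  rts <- scan_times(x)
  if (any(diff(rts) <= 0L)) stop("internal error: scan times not increasing")
  for (s in x$scans)
    if (any(s$spectrum$abundance < 0)) stop("internal error: negative abundance")
  invisible(TRUE)
}
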