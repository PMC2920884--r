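# Deterministic synthetic chromatograms, on-disk format fixtures and MSP
# libraries, with machine-readable ground truth. These are first-class
# generators (exported, tested), used both by the test suite and by the CLI
# `simulate` subcommand.

# run code with a private RNG state so generators never disturb the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify one synthetic Gaussian peak
#'
#' @param apex_rt apex retention time in ms.
#' @param sigma_ms Gaussian width (standard deviation) in ms, > 0.
#' @param height apex TIC contribution in intensity units, > 0.
#' @param pattern a non-empty `mass_spectrum` giving the relative ion pattern
#'   (it is normalized to unit maximum internally).
#' @return a list of class `peak_spec`.
#' @export
peak_spec <- function(apex_rt, sigma_ms, height, pattern) {
  stopifnot(sigma_ms > 0, height > 0, inherits(pattern, "mass_spectrum"),
            length(pattern$mz) > 0)
  pattern$abundance <- pattern$abundance / max(pattern$abundance)
  structure(list(apex_rt = as.double(apex_rt), sigma_ms = as.double(sigma_ms),
                 height = as.double(height), pattern = pattern),
            class = "peak_spec")
}

#' Specify a synthetic chromatogram
#'
#' The generated TIC is
#' `offset + slope * t + sum_k height_k * exp(-(t - apex_k)^2 / (2 sigma_k^2))`
#' plus Gaussian noise of standard deviation `noise_sigma` on the background
#' component.  The baseline-plus-noise share of each scan is carried by a
#' fixed background ion (m/z `background_mz`); each peak's share is spread
#' over its ion pattern.  The same seed always yields a bit-identical
#' chromatogram.
#'
#' @param n_scans number of scans (>= 2).
#' @param scan_interval scan spacing in ms (default 1000, i.e. 1 scan/s).
#' @param peaks list of [peak_spec()]s (may be empty).
#' @param baseline_offset,baseline_slope background TIC as `offset + slope*t`
#'   (slope per ms).
#' @param noise_sigma standard deviation of the Gaussian background noise.
#' @param seed RNG seed for the noise.
#' @param background_mz nominal mass carrying the background signal
#'   (default 44).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_scans, scan_interval = 1000, peaks = list(),
                         baseline_offset = 0, baseline_slope = 0,
                         noise_sigma = 0, seed = 1L, background_mz = 44L) {
  stopifnot(n_scans >= 2, scan_interval >= 1, noise_sigma >= 0,
            baseline_offset >= 0)
  for (p in peaks) stopifnot(inherits(p, "peak_spec"))
  structure(list(n_scans = as.integer(n_scans),
                 scan_interval = as.integer(round(scan_interval)),
                 peaks = peaks, baseline_offset = as.double(baseline_offset),
                 baseline_slope = as.double(baseline_slope),
                 noise_sigma = as.double(noise_sigma), seed = as.integer(seed),
                 background_mz = as.integer(background_mz)),
            class = "fixture_spec")
}

#' Generate a synthetic chromatogram with ground truth
#'
#' @param spec a [fixture_spec()].
#' @return a list with elements `chromatogram` and `truth`; `truth` records
#'   per-peak apex retention time, apex scan index, true area
#'   (`height * sigma_s * sqrt(2*pi)` in abundance x seconds), sigma and
#'   height, plus the baseline parameters and noise level.
#' @export
generate_chromatogram <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  t_ms <- as.double(seq_len(spec$n_scans) - 1L) * spec$scan_interval
  noise <- if (spec$noise_sigma > 0)
    with_seed(spec$seed, stats::rnorm(spec$n_scans, 0, spec$noise_sigma))
  else numeric(spec$n_scans)
  background <- pmax(spec$baseline_offset + spec$baseline_slope * t_ms +
                       noise, 0)

  gauss <- lapply(spec$peaks, function(p)
    p$height * exp(-(t_ms - p$apex_rt)^2 / (2 * p$sigma_ms^2)))

  scans <- vector("list", spec$n_scans)
  for (i in seq_len(spec$n_scans)) {
    mz <- spec$background_mz
    ab <- background[i]
    for (k in seq_along(spec$peaks)) {
      g <- gauss[[k]][i]
      if (g > 0) {
        pat <- spec$peaks[[k]]$pattern
        share <- pat$abundance / sum(pat$abundance)
        mz <- c(mz, pat$mz)
        ab <- c(ab, g * share)
      }
    }
    nom <- nominalize(mz, ab)
    scans[[i]] <- ms_scan(t_ms[i], mass_spectrum(nom$mz, nom$abundance))
  }
  chrom <- chromatogram(scans, metadata = c(
    sample_name = sprintf("synthetic chromatogram (seed %d)", spec$seed),
    operator_name = "chromkit simulator",
    source_format = "synthetic"))

  truth <- list(
    peaks = data.frame(
      apex_rt_ms = vapply(spec$peaks, `[[`, double(1), "apex_rt"),
      apex_scan = vapply(spec$peaks, function(p)
        which.min(abs(t_ms - p$apex_rt)), integer(1)),
      sigma_ms = vapply(spec$peaks, `[[`, double(1), "sigma_ms"),
      height = vapply(spec$peaks, `[[`, double(1), "height"),
      area = vapply(spec$peaks, function(p)
        p$height * (p$sigma_ms / 1000) * sqrt(2 * pi), double(1))),
    baseline_offset = spec$baseline_offset,
    baseline_slope = spec$baseline_slope,
    noise_sigma = spec$noise_sigma,
    scan_interval = spec$scan_interval)
  list(chromatogram = chrom, truth = truth)
}

#' Deterministic random ion pattern
#'
#' @param n_ions number of ions.
#' @param seed RNG seed.
#' @param mz_range candidate nominal-mass range.
#' @param base_mz optional forced base-peak m/z.
#' @return a `mass_spectrum` with unit maximum abundance.
#' @export
random_pattern <- function(n_ions, seed, mz_range = c(40L, 250L),
                           base_mz = NULL) {
  stopifnot(n_ions >= 1)
  with_seed(seed, {
    pool <- setdiff(seq.int(mz_range[1], mz_range[2]), base_mz)
    mz <- sample(pool, n_ions - !is.null(base_mz))
    ab <- stats::runif(length(mz), 0.05, 0.8)
    if (!is.null(base_mz)) {
      mz <- c(base_mz, mz)
      ab <- c(1, ab)
    } else {
      ab[which.max(ab)] <- 1
    }
    mass_spectrum(mz, ab)
  })
}

#' Standard three-peak study fixture
#'
#' Three Gaussian peaks of width sigma = 10 scans and height around 1e5 TIC
#' units on a gently drifting background with Gaussian noise of sigma = 1e2
#' (apex signal-to-noise about 1000), sampled at 1 scan per second over 300
#' scans.  This is the default condition for detector and integrator recovery
#' checks.
#'
#' @param seed RNG seed (controls noise and ion patterns).
#' @param noise_sigma background noise level (default 100).
#' @param baseline_slope background drift per ms (default 0).
#' @return a [fixture_spec()].
#' @export
three_peak_spec <- function(seed, noise_sigma = 100, baseline_slope = 0) {
  dt <- 1000
  mk <- function(k, apex_scan, height)
    peak_spec(apex_rt = apex_scan * dt, sigma_ms = 10 * dt, height = height,
              pattern = random_pattern(6L, seed = seed * 10L + k,
                                       base_mz = c(57L, 73L, 91L)[k]))
  fixture_spec(n_scans = 300L, scan_interval = dt,
               peaks = list(mk(1L, 75L, 1e5), mk(2L, 150L, 8e4),
                            mk(3L, 225L, 1.2e5)),
               baseline_offset = 500, baseline_slope = baseline_slope,
               noise_sigma = noise_sigma, seed = seed)
}

#' Write a chromatogram to all supported formats in a directory
#'
#' @param x a `chromatogram`.
#' @param directory output directory (created if missing).
#' @param stem file-name stem (default "fixture").
#' @return named character vector of the three written paths.
#' @export
write_fixture_files <- function(x, directory, stem = "fixture") {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- c(mzxml = file.path(directory, paste0(stem, ".mzXML")),
             `andi-netcdf` = file.path(directory, paste0(stem, ".cdf")),
             `native-xml` = file.path(directory, paste0(stem, ".chrom.xml")))
  for (f in names(paths)) write_chromatogram(x, paths[[f]], f)
  paths
}

#' Generate a deterministic MSP library with ground truth
#'
#' Entries have pairwise-distinct base peaks so that identification tests have
#' an unambiguous truth.
#'
#' @param n_entries number of entries (>= 1).
#' @param ions_per_entry ions per spectrum.
#' @param seed RNG seed.
#' @param path optional output path; if given, the MSP file is written there.
#' @return list with `entries` (the in-memory truth) and `path` (or `NULL`).
#' @export
generate_msp_library <- function(n_entries, ions_per_entry = 8L, seed = 1L,
                                 path = NULL) {
  stopifnot(n_entries >= 1)
  base_peaks <- with_seed(seed, sample(seq(45L, 45L + 4L * 60L, by = 4L),
                                       n_entries))
  entries <- lapply(seq_len(n_entries), function(k) {
    sp <- random_pattern(ions_per_entry, seed = seed * 1000L + k,
                         base_mz = base_peaks[k])
    sp$abundance <- round(sp$abundance * 999)
    sp$abundance[sp$abundance < 1] <- 1
    library_entry(sprintf("Synthetic compound %03d", k), sp,
                  metadata = c(Formula = sprintf("C%dH%d", k + 2L, 2L * k + 6L)))
  })
  if (!is.null(path)) write_msp_library(entries, path)
  list(entries = entries, path = path)
}
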