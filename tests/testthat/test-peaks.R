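test_that("flat noisy TIC yields zero peaks", {
  fx <- generate_chromatogram(fixture_spec(
    n_scans = 200L, baseline_offset = 1000, noise_sigma = 10, seed = 5))
  x <- detect_peaks(chromatogram_selection(fx$chromatogram),
                    snr_threshold = 5)
  expect_length(x$peaks, 0L)
})

test_that("three Gaussian peaks are recovered with apex error <= 1 scan", {
  fx <- generate_chromatogram(three_peak_spec(seed = 6))
  x <- detect_peaks(chromatogram_selection(fx$chromatogram),
                    snr_threshold = 5)
  expect_length(x$peaks, 3L)
  apexes <- vapply(x$peaks, `[[`, integer(1), "apex_scan")
  expect_true(all(abs(apexes - fx$truth$peaks$apex_scan) <= 1L))
  for (p in x$peaks) {
    expect_true(p$start_scan < p$apex_scan && p$apex_scan < p$stop_scan)
    q <- p$profile - chromkit:::peak_background(p)
    expect_equal(max(q), q[p$apex_scan - p$start_scan + 1L])
  }
})

test_that("baseline-separated peaks do not overlap in scan span", {
  fx <- generate_chromatogram(fixture_spec(
    n_scans = 200L, peaks = list(
      peak_spec(50000, 8000, 1e5, random_pattern(4L, 61)),
      peak_spec(150000, 8000, 9e4, random_pattern(4L, 62))),
    baseline_offset = 200, noise_sigma = 100, seed = 6))
  x <- detect_peaks(chromatogram_selection(fx$chromatogram),
                    snr_threshold = 5)
  expect_length(x$peaks, 2L)
  expect_lt(x$peaks[[1]]$stop_scan, x$peaks[[2]]$start_scan)
  expect_error(detect_peaks(chromatogram_selection(fx$chromatogram),
                            snr_threshold = 0), "positive")
})

test_that("trapezoid integration has the rectangle/degenerate closed forms", {
  # rectangular profile height h over n scans at dt seconds: h * (n-1) * dt
  h <- 1234; n <- 9L; dt_ms <- 500
  pk <- new_peak(2L, 5L, 10L, rep(h, n))
  pk <- integrate_trapezoid(pk, seq(0, by = dt_ms, length.out = 20L))
  expect_equal(pk$area, h * (n - 1) * dt_ms / 1000)
  expect_equal(pk$integrator_id, "trapezoid")

  # profile equal to its background line integrates to zero
  prof <- seq(100, 300, length.out = 7)
  pk0 <- new_peak(1L, 4L, 7L, prof, background_line = c(100, 300))
  pk0 <- integrate_trapezoid(pk0, seq(0, by = 1000, length.out = 7L))
  expect_equal(pk0$area, 0, tolerance = 1e-12)
})

test_that("trapezoid area matches the analytic Gaussian area at dt = sigma/5", {
  sigma_ms <- 10000; A <- 1e5
  fx <- gaussian_fixture(sigma_ms = sigma_ms, height = A,
                         dt_ms = sigma_ms / 5, span_sigmas = 4)
  x <- fx$chromatogram
  n <- n_scans(x)
  pk <- new_peak(1L, (n + 1L) %/% 2L, n, chromatogram_tic(x))
  pk <- integrate_trapezoid(pk, scan_times(x))
  analytic <- A * (sigma_ms / 1000) * sqrt(2 * pi)
  expect_lt(abs(pk$area - analytic) / analytic, 0.005)
  # and agrees with a dense-grid quadrature oracle over the same span
  oracle <- dense_gauss_area(A, scan_times(x)[pk$apex_scan] / 1000,
                             sigma_ms / 1000, 0, max(scan_times(x)) / 1000)
  expect_equal(pk$area, oracle, tolerance = 1e-3)
})

test_that("trapezoid error shows order-2 convergence as dt halves", {
  # span +-2 sigma, where endpoint slopes dominate the quadrature error;
  # the exact partial area comes from the Gaussian CDF
  sigma_s <- 10; A <- 1e5
  err <- sapply(c(2, 1, 0.5), function(dt_s) {
    half <- 2 * sigma_s / dt_s
    t_s <- seq(0, 4 * sigma_s, by = dt_s)
    mu <- 2 * sigma_s
    prof <- A * exp(-(t_s - mu)^2 / (2 * sigma_s^2))
    pk <- new_peak(1L, as.integer(half + 1), length(t_s), prof)
    pk <- integrate_trapezoid(pk, t_s * 1000)
    exact <- A * sigma_s * sqrt(2 * pi) *
      (stats::pnorm(4 * sigma_s, mu, sigma_s) - stats::pnorm(0, mu, sigma_s))
    abs(pk$area - exact)
  })
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 3.3 & ratios < 4.7))  # ~4 = order 2
})

test_that("one integrator stamps every peak identically and last wins", {
  fx <- generate_chromatogram(three_peak_spec(seed = 10))
  x <- detect_peaks(chromatogram_selection(fx$chromatogram))
  expect_true(all(vapply(x$peaks, function(p) is.null(p$area), logical(1))))
  x <- integrate_all(x, "trapezoid")
  ids <- vapply(x$peaks, `[[`, character(1), "integrator_id")
  expect_equal(unique(ids), "trapezoid")
  areas1 <- vapply(x$peaks, `[[`, double(1), "area")

  # a second integrator overwrites areas and ids on the same peak list
  register_integrator("raw-rect", "Raw-profile rectangle integrator",
                      function(peak, scan_times) {
    t_s <- scan_times[peak$start_scan:peak$stop_scan] / 1000
    q <- peak$profile             # no background subtraction, by design
    peak$area <- sum(q[-length(q)] * diff(t_s))
    peak
  })
  x2 <- integrate_all(x, "raw-rect")
  expect_equal(unique(vapply(x2$peaks, `[[`, character(1), "integrator_id")),
               "raw-rect")
  expect_false(any(vapply(x2$peaks, `[[`, double(1), "area") == areas1))
  chromkit:::register_builtins()

  y <- fx$chromatogram
  expect_error(integrate_all(y), "run a peak detector first")
})

test_that("peaks from different detectors integrate comparably", {
  # a deliberately different detector: fixed-threshold segmentation
  register_peak_detector("threshold", "Fixed-threshold detector",
                         function(selection, level) {
    x <- selection$chromatogram
    tic <- chromatogram_tic(x)
    above <- tic > level
    r <- rle(above)
    stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1L
    x$peaks <- list()
    for (k in which(r$values & r$lengths >= 3L)) {
      i <- starts[k]:stops[k]
      apex <- i[which.max(tic[i])]
      if (apex > i[1] && apex < i[length(i)])
        x$peaks[[length(x$peaks) + 1L]] <-
          new_peak(i[1], apex, i[length(i)], pmin(tic[i], tic[apex]),
                   background_line = c(tic[i[1]], tic[i[length(i)]]))
    }
    x
  })
  fx <- generate_chromatogram(three_peak_spec(seed = 11))
  sel <- chromatogram_selection(fx$chromatogram)
  xa <- integrate_all(detect_peaks(sel, method = "first-derivative"))
  xb <- integrate_all(detect_peaks(sel, method = "threshold", level = 5e3))
  expect_length(xb$peaks, 3L)
  for (x in list(xa, xb))
    expect_equal(unique(vapply(x$peaks, `[[`, character(1),
                               "integrator_id")), "trapezoid")
  # both detectors' peak areas approximate the generating truth
  for (x in list(xa, xb)) {
    areas <- vapply(x$peaks, `[[`, double(1), "area")
    # threshold spans clip the tails harder; agreement is coarse by design
    expect_equal(areas / fx$truth$peaks$area, rep(1, 3), tolerance = 0.25)
  }
  chromkit:::register_builtins()
})

test_that("peak geometry matches the analytic Gaussian FWHM", {
  sigma_ms <- 10000; dt_ms <- 1000
  fx <- gaussian_fixture(sigma_ms = sigma_ms, height = 1e5, dt_ms = dt_ms)
  x <- fx$chromatogram
  n <- n_scans(x)
  pk <- new_peak(1L, (n + 1L) %/% 2L, n, chromatogram_tic(x))
  g <- compute_geometry(pk, scan_times(x))
  expect_lt(abs(g$width_50 - 2.35482 * sigma_ms), dt_ms)
  # symmetry: equal-magnitude slopes, tangent crossing at the apex
  expect_lt(abs(abs(g$inc_slope) - abs(g$dec_slope)) / abs(g$inc_slope),
            0.01)
  t_cross <- (g$dec_intercept - g$inc_intercept) / (g$inc_slope - g$dec_slope)
  expect_lt(abs(t_cross - scan_times(x)[pk$apex_scan]), dt_ms)
  expect_lt(g$width_50, g$width_0)
})

test_that("triangular profiles give exact tangents and base width", {
  h <- 1e4; dt <- 1000
  prof <- h * c(0, .2, .4, .6, .8, 1, .8, .6, .4, .2, 0)
  pk <- new_peak(1L, 6L, 11L, prof)
  t_ms <- seq(0, by = dt, length.out = 11L)
  g <- compute_geometry(pk, t_ms)
  expect_equal(g$inc_slope, h * 0.2 / dt, tolerance = 1e-6)
  expect_equal(g$dec_slope, -h * 0.2 / dt, tolerance = 1e-6)
  expect_equal(g$width_0, 10 * dt, tolerance = 1e-6)   # the triangle's base
  expect_equal(g$width_50, 5 * dt, tolerance = 1e-6)
  expect_error(compute_geometry(new_peak(1L, 2L, 3L, c(0, 1, 0)), t_ms),
               ">= 5 scans")
})

test_that("width at half height is below tangent width on detected peaks", {
  for (seed in 1:5) {
    fx <- generate_chromatogram(three_peak_spec(seed = seed))
    x <- compute_all_geometry(integrate_all(detect_peaks(
      chromatogram_selection(fx$chromatogram))))
    for (p in x$peaks) {
      expect_false(is.null(p$geometry))
      expect_lt(p$geometry$width_50, p$geometry$width_0)
      expect_gt(p$geometry$inc_slope, 0)
      expect_lt(p$geometry$dec_slope, 0)
    }
  }
})

test_that("peak_table reports one labelled row per peak", {
  fx <- generate_chromatogram(three_peak_spec(seed = 12))
  x <- compute_all_geometry(integrate_all(detect_peaks(
    chromatogram_selection(fx$chromatogram))))
  tab <- peak_table(x)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$area > 0))
  expect_true(all(tab$integrator_id == "trapezoid"))
  expect_equal(tab$apex_rt_ms, fx$truth$peaks$apex_rt_ms, tolerance = 1e-2)
  expect_equal(nrow(peak_table(fx$chromatogram)), 0L)
})
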