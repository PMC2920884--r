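# helper: chromatogram with a fully controlled TIC carried by one ion
tic_chromatogram <- function(tic, dt = 1000) {
  chromatogram(lapply(seq_along(tic), function(i)
    ms_scan((i - 1) * dt, mass_spectrum(100L, tic[i]))))
}

test_that("Savitzky-Golay reproduces constants and fitted-order polynomials", {
  x <- tic_chromatogram(rep(500, 30))
  y <- filter_savitzky_golay(chromatogram_selection(x), window = 9)
  expect_equal(chromatogram_tic(y), chromatogram_tic(x), tolerance = 1e-12)

  t <- seq_len(40)
  quad <- 5000 + 30 * t + 2 * t^2
  x <- tic_chromatogram(quad)
  y <- filter_savitzky_golay(chromatogram_selection(x), window = 7,
                             poly_order = 2)
  interior <- 4:37
  expect_equal(chromatogram_tic(y)[interior], quad[interior],
               tolerance = 1e-9)
})

test_that("Savitzky-Golay equals an explicit local least-squares fit", {
  fx <- generate_chromatogram(fixture_spec(
    n_scans = 60L, peaks = list(peak_spec(30000, 8000, 5e4,
                                          random_pattern(4L, 30))),
    baseline_offset = 200, noise_sigma = 300, seed = 3))
  x <- fx$chromatogram
  tic <- chromatogram_tic(x)
  for (params in list(c(7L, 2L), c(11L, 3L))) {
    y <- filter_savitzky_golay(chromatogram_selection(x),
                               window = params[1], poly_order = params[2])
    oracle <- pmax(local_ls_smooth(tic, params[1], params[2]), 0)
    expect_equal(chromatogram_tic(y), oracle, tolerance = 1e-8)
  }
})

test_that("Savitzky-Golay leaves edges and out-of-window scans untouched", {
  fx <- generate_chromatogram(fixture_spec(
    n_scans = 50L, peaks = list(peak_spec(25000, 6000, 1e4,
                                          random_pattern(4L, 31))),
    baseline_offset = 100, noise_sigma = 50, seed = 4))
  x <- fx$chromatogram
  rts <- scan_times(x)
  sel <- chromatogram_selection(x, rts[11], rts[40])
  y <- filter_savitzky_golay(sel, window = 9)
  expect_scans_identical(y, x, c(1:10, 41:50))      # outside window
  expect_scans_identical(y, x, c(11:14, 37:40))     # unsmoothed edges
  expect_false(identical(y$scans[[25]], x$scans[[25]]))
})

test_that("Savitzky-Golay validates its parameters", {
  x <- tic_chromatogram(rep(10, 20))
  sel <- chromatogram_selection(x)
  expect_error(filter_savitzky_golay(sel, window = 8), "odd")
  expect_error(filter_savitzky_golay(sel, window = 3), ">= 5")
  expect_error(filter_savitzky_golay(sel, window = 7, poly_order = 6),
               "poly_order")
  expect_error(filter_savitzky_golay(sel, window = 21), "smaller than window")
})

test_that("background removal subtracts per-ion minima exactly", {
  # constant ion disappears entirely
  x <- tic_chromatogram(rep(777, 10))
  y <- filter_remove_background(chromatogram_selection(x))
  expect_true(all(chromatogram_tic(y) == 0))

  # an ion absent from one in-window scan is untouched (its minimum is 0)
  scans <- list(
    ms_scan(0, mass_spectrum(c(50L, 60L), c(10, 5))),
    ms_scan(1000, mass_spectrum(50L, 12)),
    ms_scan(2000, mass_spectrum(c(50L, 60L), c(11, 7))))
  x <- chromatogram(scans)
  y <- filter_remove_background(chromatogram_selection(x))
  for (i in 1:3) {
    sp <- y$scans[[i]]$spectrum
    orig <- x$scans[[i]]$spectrum
    expect_equal(sp$abundance[sp$mz == 60L], orig$abundance[orig$mz == 60L])
    # ion 50 loses its window minimum (10)
    expect_equal(sp$abundance[sp$mz == 50L],
                 orig$abundance[orig$mz == 50L] - 10)
  }

  # seeded fixture with known per-ion offsets, checked against a naive oracle
  offsets <- c(`60` = 40, `75` = 15, `90` = 220)
  scans <- chromkit:::with_seed(77, lapply(0:19, function(i)
    ms_scan(i * 500, mass_spectrum(c(60L, 75L, 90L),
                                   offsets + runif(3, 0, 50)))))
  x <- chromatogram(scans)
  mins <- sapply(c(60L, 75L, 90L), function(m)
    min(vapply(x$scans, function(s) s$spectrum$abundance[s$spectrum$mz == m],
               double(1))))
  y <- filter_remove_background(chromatogram_selection(x))
  for (i in 1:20)
    expect_equal(y$scans[[i]]$spectrum$abundance,
                 x$scans[[i]]$spectrum$abundance - mins)
  expect_error(filter_remove_background(
    chromatogram_selection(x, 0, 400)), "at least 2 scans")
})

test_that("mean normalization hits the target mean exactly", {
  x <- tic_chromatogram(rep(500, 12))
  y <- filter_mean_normalize(chromatogram_selection(x), target = 1000)
  expect_equal(chromatogram_tic(y), rep(1000, 12))  # uniform 500 -> doubled

  # already at target -> unchanged
  z <- filter_mean_normalize(chromatogram_selection(y), target = 1000)
  expect_identical(z$scans, y$scans)

  fx <- generate_chromatogram(fixture_spec(
    n_scans = 40L, peaks = list(peak_spec(20000, 5000, 2e4,
                                          random_pattern(4L, 44))),
    baseline_offset = 50, noise_sigma = 20, seed = 4))
  w <- filter_mean_normalize(chromatogram_selection(fx$chromatogram))
  expect_equal(mean(chromatogram_tic(w)), 1000, tolerance = 1e-9)

  zero <- tic_chromatogram(rep(0, 8))
  expect_error(filter_mean_normalize(chromatogram_selection(zero)),
               "cannot normalize zero signal")
})

test_that("the filter registry lists built-ins and accepts plugins", {
  lf <- list_filters()
  expect_gte(nrow(lf), 4L)
  expect_true(all(c("savitzky-golay", "remove-background", "mean-normalize",
                    "subtract-baseline") %in% lf$filter_id))
  expect_identical(lf$filter_id, sort(lf$filter_id))  # deterministic order
  expect_error(register_filter("mean-normalize", "dup", identity),
               "already registered")
  register_filter("halve", "Halve all abundances", function(selection) {
    x <- selection$chromatogram
    for (i in selection_indices(selection))
      x$scans[[i]]$spectrum$abundance <- x$scans[[i]]$spectrum$abundance / 2
    x
  })
  expect_true("halve" %in% list_filters()$filter_id)
  x <- tic_chromatogram(rep(100, 10))
  y <- apply_filter(chromatogram_selection(x), "halve")
  expect_equal(chromatogram_tic(y), rep(50, 10))
  chromkit:::register_builtins()  # restore pristine registries
})

test_that("every filter is selection-local and keeps the model valid", {
  fx <- generate_chromatogram(fixture_spec(
    n_scans = 60L, peaks = list(peak_spec(30000, 7000, 3e4,
                                          random_pattern(5L, 50))),
    baseline_offset = 150, baseline_slope = 0.002, noise_sigma = 60,
    seed = 5))
  x <- fx$chromatogram
  rts <- scan_times(x)
  sel <- chromatogram_selection(x, rts[16], rts[45])
  outside <- c(1:15, 46:60)
  cases <- list(list("savitzky-golay", list(window = 9L)),
                list("remove-background", list()),
                list("mean-normalize", list(target = 500)))
  for (cs in cases) {
    y <- apply_filter(sel, cs[[1]], cs[[2]])
    expect_scans_identical(y, x, outside)
    expect_identical(scan_times(y), rts)
    for (s in y$scans) expect_true(all(s$spectrum$abundance >= 0))
  }
})
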