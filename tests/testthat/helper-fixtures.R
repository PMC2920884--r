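# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (loops, local least squares, dense grids) and never call the code
# paths they check.

# random chromatogram with irregular scan spacing and random ion content
random_chromatogram <- function(seed, n_scans = 25L, max_ions = 8L) {
  chromkit:::with_seed(seed, {
    rts <- cumsum(sample(200:1500, n_scans, replace = TRUE))
    scans <- lapply(rts, function(rt) {
      k <- sample.int(max_ions, 1L)
      ms_scan(rt, mass_spectrum(sample(20:300, k),
                                stats::runif(k, 0, 5000)))
    })
    chromatogram(scans)
  })
}

# per-scan trace by explicit loops (oracle for tic_trace / extracted_ion_trace)
naive_trace <- function(x, start_rt, stop_rt, include = NULL, exclude = NULL,
                        mz_values = NULL) {
  rt <- c(); ab <- c()
  for (s in x$scans) {
    if (s$rt < start_rt || s$rt > stop_rt) next
    tot <- 0
    for (j in seq_along(s$spectrum$mz)) {
      m <- s$spectrum$mz[j]
      if (!is.null(mz_values) && !(m %in% mz_values)) next
      if (!is.null(include) && !(m %in% include)) next
      if (!is.null(exclude) && m %in% exclude) next
      tot <- tot + s$spectrum$abundance[j]
    }
    rt <- c(rt, s$rt); ab <- c(ab, tot)
  }
  data.frame(rt = rt, abundance = ab)
}

# local least-squares polynomial fit evaluated at the window center (oracle
# for the Savitzky-Golay convolution coefficients)
local_ls_smooth <- function(y, window, poly_order) {
  hw <- (window - 1L) %/% 2L
  n <- length(y)
  out <- y
  for (i in (hw + 1L):(n - hw)) {
    t <- (-hw):hw
    fit <- stats::lm(y[(i - hw):(i + hw)] ~ stats::poly(t, poly_order,
                                                        raw = TRUE))
    out[i] <- unname(stats::predict(fit,
      newdata = data.frame(t = 0))[1])
  }
  out
}

# dense-grid trapezoid quadrature of a Gaussian over [lo, hi] (seconds)
dense_gauss_area <- function(A, mu_s, sigma_s, lo_s, hi_s, n = 200001L) {
  t <- seq(lo_s, hi_s, length.out = n)
  y <- A * exp(-(t - mu_s)^2 / (2 * sigma_s^2))
  sum((y[-1] + y[-n]) / 2) * (t[2] - t[1])
}

# brute-force cosine / euclidean scores over the explicit m/z union
naive_cosine <- function(a, b) {
  u <- sort(union(a$mz, b$mz))
  num <- 0; na <- 0; nb <- 0
  for (m in u) {
    va <- if (m %in% a$mz) a$abundance[a$mz == m] else 0
    vb <- if (m %in% b$mz) b$abundance[b$mz == m] else 0
    num <- num + va * vb; na <- na + va^2; nb <- nb + vb^2
  }
  num / (sqrt(na) * sqrt(nb))
}

naive_euclidean <- function(a, b) {
  u <- sort(union(a$mz, b$mz))
  ma <- max(a$abundance); mb <- max(b$abundance)
  d2 <- 0
  for (m in u) {
    va <- if (m %in% a$mz) a$abundance[a$mz == m] / ma else 0
    vb <- if (m %in% b$mz) b$abundance[b$mz == m] / mb else 0
    d2 <- d2 + (va - vb)^2
  }
  1 - sqrt(d2) / sqrt(2 * length(u))
}

random_spectrum <- function(seed, n_ions = 12L) {
  chromkit:::with_seed(seed,
    mass_spectrum(sample(20:300, n_ions), stats::runif(n_ions, 1, 1000)))
}

# single clean Gaussian fixture used by geometry and integrator checks
gaussian_fixture <- function(sigma_ms = 10000, height = 1e5, dt_ms = 1000,
                             span_sigmas = 5, seed = 1L) {
  half <- ceiling(span_sigmas * sigma_ms / dt_ms)
  n <- 2L * half + 1L
  apex_rt <- half * dt_ms
  spec <- fixture_spec(n_scans = n, scan_interval = dt_ms,
                       peaks = list(peak_spec(apex_rt, sigma_ms, height,
                                              random_pattern(5L, seed))),
                       seed = seed)
  generate_chromatogram(spec)
}

expect_scans_identical <- function(a, b, idx) {
  for (i in idx) expect_identical(a$scans[[i]], b$scans[[i]])
}
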