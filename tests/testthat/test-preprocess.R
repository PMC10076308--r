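flat_spectrum <- function(value, n = 200, lo = 2000) {
  mass_spectrum(seq(lo, by = 1, length.out = n), rep(value, n))
}

test_that("square-root transform matches elementwise evaluation", {
  s <- mass_spectrum(2000:2003, c(0, 1, 4, 9))
  expect_equal(transform_sqrt(s)$intensity, c(0, 1, 2, 3))
  expect_equal(transform_sqrt(flat_spectrum(0))$intensity, rep(0, 200))
  set.seed(1)
  v <- stats::runif(500, 0, 1e4)
  s <- mass_spectrum(seq_along(v) + 2000, v)
  expect_equal(transform_sqrt(s)$intensity, vapply(v, sqrt, numeric(1)),
               tolerance = 1e-12)
  s$intensity[3] <- -1
  expect_error(transform_sqrt(s), "negative")
})

test_that("Savitzky-Golay reproduces polynomials and matches the per-window oracle", {
  params <- preprocess_params()
  expect_equal(smooth_sg(flat_spectrum(7), params)$intensity, rep(7, 200))

  # an order-3 filter is exact on cubics at interior points
  x <- seq(2000, 2199)
  cubic <- 1e-6 * (x - 2100)^3 + 5e-4 * (x - 2100)^2 + 50
  s <- mass_spectrum(x, cubic - min(cubic) + 1)
  sm <- smooth_sg(s, params)$intensity
  interior <- 11:190
  expect_equal(sm[interior], s$intensity[interior], tolerance = 1e-9)

  # white noise: agree with the explicit normal-equations fit per window,
  # including the shrunk-window edges
  set.seed(4)
  v <- stats::runif(300, 10, 20)
  s <- mass_spectrum(seq_along(v) + 2000, v)
  sm <- smooth_sg(s, params)$intensity
  expect_equal(sm, oracle_sg(v, params$sg_half_window, params$sg_poly_order),
               tolerance = 1e-10)

  expect_error(smooth_sg(flat_spectrum(1, n = 15), params), "shorter")
})

test_that("SNIP baseline equals the literal recursion and stays under the signal", {
  params <- preprocess_params()
  # constant spectrum: baseline is the constant
  expect_equal(snip_baseline(flat_spectrum(12.5), params), rep(12.5, 200),
               tolerance = 1e-9)

  # single Gaussian (height 100, sd 3 points) on a flat level 10: clipped
  x <- seq_len(201)
  v <- 10 + 100 * exp(-(x - 101)^2 / (2 * 3^2))
  s <- mass_spectrum(x + 2000, v)
  bl <- snip_baseline(s, params)
  expect_lt(bl[101], 15)
  expect_equal(bl, oracle_snip(v, params$snip_iterations), tolerance = 1e-9)

  # property over random spectra: oracle equality and baseline <= input
  set.seed(11)
  for (i in 1:100) {
    n <- sample(60:200, 1)
    v <- stats::runif(n, 0, 50) +
      stats::rpois(n, 2) * stats::runif(n, 0, 30)
    s <- mass_spectrum(seq_len(n) + 2000, v)
    bl <- snip_baseline(s, params)
    expect_equal(bl, oracle_snip(v, params$snip_iterations),
                 tolerance = 1e-9)
    expect_true(all(bl <= v + 1e-9))
    expect_true(all(subtract_baseline(s, bl)$intensity >= 0))
  }
})

test_that("MAD noise estimation is calibrated and scale-equivariant", {
  expect_equal(estimate_noise_mad(flat_spectrum(3)), 0)
  set.seed(21)
  v <- 50 + stats::rnorm(10000)
  s <- mass_spectrum(seq_along(v) + 2000, v)
  est <- estimate_noise_mad(s)
  expect_gt(est, 0.95)
  expect_lt(est, 1.05)
  s10 <- mass_spectrum(s$mz, 10 * v)
  expect_equal(estimate_noise_mad(s10), 10 * est, tolerance = 1e-12)
})

test_that("peak detection matches the exhaustive window scan", {
  params <- preprocess_params()
  expect_equal(nrow(detect_peaks(flat_spectrum(5), params)), 0L)

  # two planted Gaussians, apex 10x noise, 500 points apart: both found at
  # their exact apex, and nothing else
  set.seed(31)
  n <- 1200
  noise <- stats::rnorm(n)
  v <- pmax(10 * exp(-(seq_len(n) - 300)^2 / 18) +
            10 * exp(-(seq_len(n) - 800)^2 / 18) + noise, 0)
  s <- mass_spectrum(seq_len(n) + 2000, v)
  nl <- estimate_noise_mad(s)
  pt <- detect_peaks(s, params, noise = nl)
  oracle <- oracle_peak_indices(v, params$peak_half_window,
                                params$snr_threshold * nl)
  expect_equal(match(pt$mz, s$mz), oracle)
  planted <- intersect(oracle, c(299:301, 799:801))
  expect_length(planted, 2L)
  expect_equal(pt$snr, v[oracle] / nl)

  # a clean bump with apex at 2x the noise level fails the 3x threshold
  v2 <- 2 * exp(-(seq_len(n) - 600)^2 / 18)
  s2 <- mass_spectrum(seq_len(n) + 2000, v2)
  pt2 <- detect_peaks(s2, params, noise = 1)
  expect_equal(nrow(pt2), 0L)
})

test_that("raising the SNR threshold never adds peaks", {
  set.seed(41)
  n <- 800
  v <- pmax(stats::rnorm(n) + 8 * exp(-(seq_len(n) - 400)^2 / 8), 0)
  s <- mass_spectrum(seq_len(n) + 2000, v)
  counts <- vapply(c(0.5, 1, 2, 3, 5, 10), function(thr) {
    nrow(detect_peaks(s, preprocess_params(snr_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

peak_table_of <- function(mz, intensity, id) {
  s <- mass_spectrum(c(2000, mz, 20000), c(0, intensity, 0),
                     spectrum_id = id)
  pt <- data.frame(spectrum_id = id, label = "A", bio_rep = 1L,
                   exp_rep = 1L, tech_rep = 1L, mz = mz,
                   intensity = intensity, snr = 10)
  class(pt) <- c("peak_table", "data.frame")
  attr(pt, "spectrum_meta") <- data.frame(
    spectrum_id = id, label = "A", bio_rep = 1L, exp_rep = 1L,
    tech_rep = 1L, stringsAsFactors = FALSE)
  pt
}

test_that("binning groups peaks by relative tolerance", {
  params <- preprocess_params()  # tolerance 0.002
  # 5000 and 5005 (delta/mean = 0.001): one feature at the mean
  im <- bin_peaks(list(peak_table_of(5000, 2, "s1"),
                       peak_table_of(5005, 4, "s2")), params)
  expect_equal(im$mz, 5002.5)
  expect_equal(as.vector(im$values), c(2, 4))

  # 5000 and 5100 (delta/mean ~ 0.0198): two features
  im <- bin_peaks(list(peak_table_of(5000, 2, "s1"),
                       peak_table_of(5100, 4, "s2")), params)
  expect_equal(im$mz, c(5000, 5100))
  expect_equal(im$values, rbind(c(2, 0), c(0, 4)), ignore_attr = TRUE)

  # single spectrum with far-apart peaks: identity
  im <- bin_peaks(list(peak_table_of(c(4000, 8000, 12000), c(1, 2, 3),
                                     "s1")), params)
  expect_equal(im$mz, c(4000, 8000, 12000))
  expect_equal(as.vector(im$values), c(1, 2, 3))

  # bin reference m/z strictly increasing and members within tolerance
  set.seed(51)
  tables <- lapply(1:6, function(i) {
    base <- c(5000, 7000, 9000, 11000)
    peak_table_of(base + stats::rnorm(4, 0, 3), stats::runif(4, 1, 5),
                  paste0("s", i))
  })
  im <- bin_peaks(tables, params)
  expect_true(all(diff(im$mz) > 0))
  expect_equal(length(im$mz), 4L)
})

test_that("frequency filtering keeps the boundary and drops below it", {
  meta <- data.frame(spectrum_id = sprintf("s%d", 1:10), label = "A",
                     bio_rep = 1L, exp_rep = 1:10, tech_rep = 1L)
  values <- cbind(c(rep(1, 4), rep(0, 6)),   # 4/10: removed
                  rep(1, 10),                # 10/10: kept
                  c(rep(1, 5), rep(0, 5)))   # exactly 5/10: kept
  im <- intensity_matrix(values, c(3000, 4000, 5000), meta)
  out <- filter_peaks_by_frequency(im, preprocess_params())
  expect_equal(out$mz, c(4000, 5000))
  expect_warning(
    filter_peaks_by_frequency(
      intensity_matrix(values[, 1L, drop = FALSE], 3000, meta),
      preprocess_params()),
    "below")
})

test_that("technical-replicate averaging reproduces the replicate arithmetic", {
  # the CML obtained design collapses 77 rows to 40 experimental groups
  im <- matrix_from_design(design_cml())
  avg <- average_technical_replicates(im)
  expect_equal(nrow(avg$values), 40L)
  expect_equal(as.vector(table(avg$meta$label)[c("K562", "Ko562", "Ki562",
                                                 "Kv562")]),
               c(9L, 11L, 8L, 12L))

  # a single-member group is returned unchanged; {2, 4} averages to 3
  meta <- data.frame(spectrum_id = c("a", "b", "c"),
                     label = c("L", "L", "L"),
                     bio_rep = c(1L, 1L, 1L), exp_rep = c(1L, 1L, 2L),
                     tech_rep = c(1L, 2L, 1L))
  im <- intensity_matrix(cbind(c(2, 4, 7)), 5000, meta)
  avg <- average_technical_replicates(im)
  expect_equal(as.vector(avg$values), c(3, 7))
  expect_equal(avg$meta$n_tech, c(2L, 1L))
})

test_that("the preprocessing chain recovers planted peaks and is deterministic", {
  # zero noise, no jitter, all peaks present: every planted peak appears as
  # a feature within the bin tolerance of its true m/z
  model <- tiny_model(classes = "A", noise_sd = 0, bio_jitter_sd = 0,
                      exp_jitter_sd = 0, tech_jitter_sd = 0,
                      calibration_shift_ppm_sd = 0)
  design <- data.frame(label = "A", bio_rep = 1L, exp_rep = rep(1:2, 2),
                       tech_rep = rep(1:2, each = 2))
  ds <- simulate_dataset(model, design, seed = 3)
  params <- preprocess_params(mass_range = c(2000, 3000))
  res <- run_preprocessing(ds$spectra, params)
  for (true_mz in model$peaks$mz) {
    expect_true(any(abs(res$matrix$mz - true_mz) / true_mz <=
                    params$bin_tolerance),
                label = paste("planted peak", true_mz, "recovered"))
  }
  expect_equal(res$log$n[res$log$stage == "averaged_spectra"], 2L)

  # identical spectra as technical replicates average to the single-spectrum
  # peak vector
  one <- ds$spectra[[1L]]
  copies <- lapply(1:4, function(t) {
    s <- one
    s$tech_rep <- t
    s$exp_rep <- 1L
    s$spectrum_id <- paste0("c", t)
    s
  })
  res2 <- run_preprocessing(copies, params)
  expect_equal(nrow(res2$matrix$values), 1L)
  expect_equal(as.vector(res2$matrix$values),
               as.vector(res2$spectrum_matrix$values[1L, ]))

  # determinism: same input, bit-identical output
  res3 <- run_preprocessing(ds$spectra, params)
  expect_identical(res3$matrix$values, res$matrix$values)
  expect_identical(res3$matrix$mz, res$matrix$mz)
})
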