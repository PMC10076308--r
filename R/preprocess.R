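#' Preprocessing parameters
#'
#' Bundles the tunable parameters of the spectral preprocessing chain. The
#' defaults follow linear-mode whole-cell biotyping practice: profile spectra
#' restricted to 2,000-20,000 Da, Savitzky-Golay smoothing, 50 SNIP
#' iterations, peak picking at signal-to-noise 3 with a +-40-point window, a
#' 0.2% relative binning tolerance, and removal of peaks seen in fewer than
#' half of the spectra.
#'
#' @param mass_range Numeric `(low, high)` mass window in Da.
#' @param sg_half_window Savitzky-Golay half window (points); the filter
#'   window is `2 * sg_half_window + 1` points wide.
#' @param sg_poly_order Savitzky-Golay polynomial order.
#' @param snip_iterations Number of SNIP clipping iterations.
#' @param snr_threshold Minimum signal-to-noise ratio of a retained peak.
#' @param peak_half_window Half window (points) of the strict local-maximum
#'   rule in peak detection.
#' @param bin_tolerance Relative m/z tolerance of peak binning (fraction, e.g.
#'   0.002 is 0.2%, about 20 Da at 10 kDa).
#' @param min_frequency Minimum fraction of spectra in which a binned peak
#'   must occur; features below the threshold are discarded (equality kept).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(mass_range = c(2000, 20000),
                              sg_half_window = 10L,
                              sg_poly_order = 3L,
                              snip_iterations = 50L,
                              snr_threshold = 3,
                              peak_half_window = 40L,
                              bin_tolerance = 0.002,
                              min_frequency = 0.5) {
  stopifnot(length(mass_range) == 2L, mass_range[1L] < mass_range[2L],
            sg_half_window >= 1L,
            sg_poly_order >= 0L, sg_poly_order < 2L * sg_half_window + 1L,
            snip_iterations >= 1L,
            snr_threshold > 0,
            peak_half_window >= 1L,
            bin_tolerance > 0, bin_tolerance < 1,
            min_frequency > 0, min_frequency <= 1)
  structure(list(mass_range = as.numeric(mass_range),
                 sg_half_window = as.integer(sg_half_window),
                 sg_poly_order = as.integer(sg_poly_order),
                 snip_iterations = as.integer(snip_iterations),
                 snr_threshold = as.numeric(snr_threshold),
                 peak_half_window = as.integer(peak_half_window),
                 bin_tolerance = as.numeric(bin_tolerance),
                 min_frequency = as.numeric(min_frequency)),
            class = "preprocess_params")
}

#' Square-root variance stabilization
#'
#' Replaces every intensity by its square root; detector counts have roughly
#' Poisson-like variance, which the square root stabilizes. The m/z axis is
#' unchanged.
#'
#' @param spectrum A [mass_spectrum] with non-negative intensities.
#' @return The transformed [mass_spectrum].
#' @export
transform_sqrt <- function(spectrum) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (any(spectrum$intensity < 0)) {
    stop("transform_sqrt: negative intensity in '", spectrum$spectrum_id, "'")
  }
  replace_intensity(spectrum, sqrt(spectrum$intensity))
}

# central Savitzky-Golay coefficient row for half window h, order p:
# the least-squares polynomial value at offset 0 is a fixed linear
# combination of the window values (first row of (A'A)^{-1} A').
sg_center_coefficients <- function(h, p) {
  offs <- seq.int(-h, h)
  A <- outer(offs, 0:p, `^`)
  drop(solve(crossprod(A), t(A))[1L, ])
}

#' Savitzky-Golay smoothing
#'
#' Each interior point is replaced by the value at the window center of the
#' least-squares polynomial of order `sg_poly_order` fitted over the
#' `2 * sg_half_window + 1` surrounding points. Near the edges the window
#' shrinks symmetrically (and the polynomial order with it, down to an exact
#' interpolation at the first/last point), so no point is dropped.
#'
#' @param spectrum A [mass_spectrum] longer than `2 * sg_half_window` points.
#' @param params A [preprocess_params].
#' @return The smoothed [mass_spectrum] (small negative excursions near sharp
#'   features are possible and tolerated; the baseline stage clamps at zero).
#' @export
smooth_sg <- function(spectrum, params = preprocess_params()) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(params, "preprocess_params"))
  h <- params$sg_half_window
  p <- params$sg_poly_order
  x <- spectrum$intensity
  n <- length(x)
  if (n <= 2L * h) {
    stop("smooth_sg: spectrum '", spectrum$spectrum_id,
         "' is shorter than the filter window")
  }
  w <- sg_center_coefficients(h, p)
  sm <- as.numeric(stats::filter(x, w, method = "convolution", sides = 2L))
  # edges: symmetric window shrinkage
  for (i in seq_len(h)) {
    hi <- i - 1L
    pi_ <- min(p, 2L * hi)
    if (hi == 0L) {
      sm[i] <- x[i]
      sm[n - i + 1L] <- x[n - i + 1L]
    } else {
      we <- sg_center_coefficients(hi, pi_)
      sm[i] <- sum(we * x[(i - hi):(i + hi)])
      j <- n - i + 1L
      sm[j] <- sum(we * x[(j - hi):(j + hi)])
    }
  }
  out <- replace_intensity(spectrum, sm)
  out
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak clipping: intensities are
#' compressed with the log-log-square-root (LLS) operator
#' `y = ln(ln(sqrt(v + 1) + 1) + 1)`, then for clipping widths
#' `p = 1 .. snip_iterations` every interior value is replaced by
#' `min(y_i, (y_{i-p} + y_{i+p}) / 2)`, and the result is decompressed with
#' the inverse LLS. The estimate never exceeds the input signal (up to
#' floating-point round-off).
#'
#' @param spectrum A smoothed [mass_spectrum].
#' @param params A [preprocess_params] (`snip_iterations` is used).
#' @return Numeric baseline vector, same length as the spectrum.
#' @export
snip_baseline <- function(spectrum, params = preprocess_params()) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(params, "preprocess_params"))
  v <- pmax(spectrum$intensity, 0)
  n <- length(v)
  y <- log(log(sqrt(v + 1) + 1) + 1)
  kmax <- min(params$snip_iterations, (n - 1L) %/% 2L)
  for (p in seq_len(kmax)) {
    idx <- (p + 1L):(n - p)
    avg <- (y[idx - p] + y[idx + p]) / 2
    y[idx] <- pmin(y[idx], avg)
  }
  (exp(exp(y) - 1) - 1)^2 - 1
}

#' Subtract a baseline, clamping at zero
#'
#' @param spectrum A [mass_spectrum].
#' @param baseline Numeric vector as returned by [snip_baseline].
#' @return The baseline-corrected [mass_spectrum] (non-negative).
#' @export
subtract_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            length(baseline) == length(spectrum$mz))
  replace_intensity(spectrum, pmax(spectrum$intensity - baseline, 0))
}

#' Noise level by median absolute deviation
#'
#' A single global noise scale per spectrum:
#' `1.4826 * median(|v - median(v)|)`, the MAD calibrated to estimate the
#' standard deviation of Gaussian noise.
#'
#' @param spectrum A baseline-corrected [mass_spectrum].
#' @return A scalar noise level.
#' @export
estimate_noise_mad <- function(spectrum) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (length(spectrum$mz) == 0L) stop("estimate_noise_mad: empty spectrum")
  stats::mad(spectrum$intensity)
}

#' Detect peaks by strict local maximum and signal-to-noise ratio
#'
#' A point is a peak iff its intensity is the strict maximum over the window
#' of `peak_half_window` points on each side (truncated at the spectrum
#' edges) and is at least `snr_threshold` times the noise level.
#'
#' @param spectrum A baseline-corrected [mass_spectrum].
#' @param params A [preprocess_params].
#' @param noise Noise level; computed with [estimate_noise_mad] when `NULL`.
#' @return A `peak_table` data frame with columns `spectrum_id`, `label`,
#'   `bio_rep`, `exp_rep`, `tech_rep`, `mz`, `intensity`, `snr`, sorted by
#'   m/z.
#' @export
detect_peaks <- function(spectrum, params = preprocess_params(), noise = NULL) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(params, "preprocess_params"))
  if (is.null(noise)) noise <- estimate_noise_mad(spectrum)
  x <- spectrum$intensity
  n <- length(x)
  w <- params$peak_half_window
  is_max <- rep(TRUE, n)
  for (s in seq_len(min(w, n - 1L))) {
    left <- c(rep(-Inf, s), x[seq_len(n - s)])
    right <- c(x[(s + 1L):n], rep(-Inf, s))
    is_max <- is_max & x > left & x > right
    if (!any(is_max)) break
  }
  thr <- params$snr_threshold * noise
  keep <- which(is_max & x >= thr & x > 0)
  out <- data.frame(
    spectrum_id = rep(spectrum$spectrum_id, length(keep)),
    label = rep(spectrum$label, length(keep)),
    bio_rep = rep(spectrum$bio_rep, length(keep)),
    exp_rep = rep(spectrum$exp_rep, length(keep)),
    tech_rep = rep(spectrum$tech_rep, length(keep)),
    mz = spectrum$mz[keep],
    intensity = x[keep],
    snr = if (noise > 0) x[keep] / noise else rep(Inf, length(keep)),
    stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}
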