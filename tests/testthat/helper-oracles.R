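# Independent reference implementations and small fixtures used across the
# suite. The oracles deliberately take the slow, literal route (per-window
# regressions, double loops, exhaustive enumeration) so they share no code
# path with the package.

# literal SNIP recursion: explicit simultaneous-update loop
oracle_snip <- function(v, iterations) {
  v <- pmax(v, 0)
  y <- log(log(sqrt(v + 1) + 1) + 1)
  n <- length(y)
  for (p in seq_len(min(iterations, (n - 1) %/% 2))) {
    y2 <- y
    for (i in (p + 1):(n - p)) {
      y2[i] <- min(y[i], (y[i - p] + y[i + p]) / 2)
    }
    y <- y2
  }
  (exp(exp(y) - 1) - 1)^2 - 1
}

# Savitzky-Golay by explicit normal-equations polynomial fit per window
# (interior points only; edges use the same fit on the shrunk window)
oracle_sg <- function(x, h, p) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    pi_ <- min(p, 2L * hi)
    if (hi == 0L) next
    offs <- seq.int(-hi, hi)
    A <- outer(offs, 0:pi_, `^`)
    beta <- solve(crossprod(A), crossprod(A, x[i + offs]))
    out[i] <- beta[1L]
  }
  out
}

# exhaustive strict-local-maximum scan
oracle_peak_indices <- function(x, w, thr) {
  n <- length(x)
  res <- integer(0)
  for (i in seq_len(n)) {
    win <- max(1L, i - w):min(n, i + w)
    others <- setdiff(win, i)
    if (x[i] > 0 && x[i] >= thr && all(x[i] > x[others])) {
      res <- c(res, i)
    }
  }
  res
}

# feature-by-feature evaluation of the regularized group-vs-pooled t-score
oracle_t_scores <- function(x01, labels) {
  groups <- sort(unique(labels))
  n <- nrow(x01)
  out <- matrix(0, ncol(x01), length(groups),
                dimnames = list(NULL, groups))
  for (j in seq_len(ncol(x01))) {
    xj <- sum(x01[, j])
    pj <- (xj + 0.5) / (n + 1)
    for (g in seq_along(groups)) {
      rows <- labels == groups[g]
      nk <- sum(rows)
      pjk <- (sum(x01[rows, j]) + 0.5) / (nk + 1)
      se <- sqrt(pj * (1 - pj) * (1 / nk - 1 / n))
      out[j, g] <- (pjk - pj) / se
    }
  }
  out
}

# all 2-partitions of 1..n (non-empty both sides), as logical membership
all_two_partitions <- function(n) {
  codes <- 1:(2^(n - 1) - 1)
  lapply(codes, function(code) {
    as.logical(bitwAnd(code, 2^(0:(n - 1))) > 0)
  })
}

two_partition_wss <- function(x, members) {
  wss_part <- function(rows) {
    xs <- x[rows, , drop = FALSE]
    sum(sweep(xs, 2L, colMeans(xs))^2)
  }
  wss_part(members) + wss_part(!members)
}

# small fast spectrum model for unit tests: 1 kDa window, wide peaks
tiny_model <- function(classes = c("A", "B"), noise_sd = 2,
                       heights = c(300, 250, 280, 220), p_in = 1,
                       p_out = 0, ...) {
  peaks <- data.frame(mz = c(2200, 2400, 2600, 2800),
                      meanlog = log(heights))
  presence <- matrix(1, 4, length(classes))
  if (length(classes) >= 2L) {
    presence[3L, ] <- p_out
    presence[3L, 1L] <- p_in
    presence[4L, ] <- p_out
    presence[4L, 2L] <- p_in
  }
  spectrum_model(classes = classes, peaks = peaks, presence = presence,
                 mass_range = c(2000, 3000), resolution = 150,
                 noise_sd = noise_sd, ...)
}

# write a spectrum to a two-column csv, return the path
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(mz = spectrum$mz,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  path
}

# write a one-spectrum mzML file through mzR
write_spectrum_mzml <- function(spectrum, path) {
  hd <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = length(spectrum$mz),
    totIonCurrent = sum(spectrum$intensity), retentionTime = 1,
    basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
    basePeakIntensity = max(spectrum$intensity),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(list(cbind(spectrum$mz, spectrum$intensity)),
                   file = path, header = hd)
  path
}

# intensity matrix with a given replicate design and constant values,
# for averaging-arithmetic tests
matrix_from_design <- function(design, n_features = 3L, seed = 1L) {
  set.seed(seed)
  values <- matrix(stats::runif(nrow(design) * n_features),
                   nrow = nrow(design))
  meta <- data.frame(
    spectrum_id = sprintf("s%03d", seq_len(nrow(design))),
    label = design$label, bio_rep = design$bio_rep,
    exp_rep = design$exp_rep, tech_rep = design$tech_rep,
    stringsAsFactors = FALSE)
  intensity_matrix(values, seq(3000, by = 500, length.out = n_features),
                   meta)
}
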