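#' Construct an aligned intensity matrix
#'
#' Rows are spectra (or averaged spectra) with their labels and replicate
#' keys; columns are binned peak features identified by their reference m/z;
#' a value of 0 means the peak is absent from that spectrum.
#'
#' @param values Numeric matrix, spectra x features, non-negative.
#' @param mz Numeric vector of strictly increasing reference m/z values, one
#'   per column.
#' @param meta Data frame with one row per matrix row; must contain
#'   `spectrum_id` and `label` (replicate keys as available).
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, mz, meta) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || ncol(values) == 0L,
            ncol(values) == length(mz),
            nrow(values) == nrow(meta),
            all(c("spectrum_id", "label") %in% names(meta)))
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("feature reference m/z must be strictly increasing")
  }
  rownames(values) <- meta$spectrum_id
  if (length(mz) > 0L) colnames(values) <- sprintf("mz_%.4f", mz)
  structure(list(values = values, mz = as.numeric(mz), meta = meta),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d spectra x %d features (%s)\n",
              nrow(x$values), length(x$mz),
              paste(unique(x$meta$label), collapse = ", ")))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

# greedy single-pass binning of peaks sorted by ascending m/z; peaks of the
# same spectrum that collide inside a bin are resolved by closeness to the
# bin mean, losers are re-binned among themselves.
greedy_bin <- function(df, tol) {
  if (nrow(df) == 0L) return(list())
  df <- df[order(df$mz), , drop = FALSE]
  bins <- list()
  deferred <- df[0L, , drop = FALSE]
  cur <- df[1L, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1L]) {
    peak <- df[i, , drop = FALSE]
    cand <- rbind(cur, peak)
    m <- mean(cand$mz)
    if (all(abs(cand$mz - m) / m <= tol)) {
      j <- which(cur$spectrum == peak$spectrum)
      if (length(j) > 0L) {
        # one peak per spectrum per bin: the one closer to the bin mean wins
        m0 <- mean(cur$mz)
        if (abs(peak$mz - m0) < abs(cur$mz[j[1L]] - m0)) {
          deferred <- rbind(deferred, cur[j[1L], , drop = FALSE])
          cur <- rbind(cur[-j[1L], , drop = FALSE], peak)
        } else {
          deferred <- rbind(deferred, peak)
        }
      } else {
        cur <- cand
      }
    } else {
      bins[[length(bins) + 1L]] <- cur
      cur <- peak
    }
  }
  bins[[length(bins) + 1L]] <- cur
  if (nrow(deferred) > 0L) {
    bins <- c(bins, greedy_bin(deferred, tol))
  }
  bins
}

#' Bin peaks across spectra into aligned features
#'
#' Peaks from all spectra are pooled, sorted by m/z and grouped greedily such
#' that every member of a bin lies within `bin_tolerance` (relative) of the
#' bin mean; the bin's reference m/z is the mean of its members' m/z. At most
#' one peak per spectrum enters a bin (the peak closest to the bin mean wins;
#' displaced peaks are grouped among themselves). Spectra with no retained
#' peaks contribute an all-zero row.
#'
#' @param peak_tables A list of `peak_table` objects as returned by
#'   [detect_peaks], one per spectrum.
#' @param params A [preprocess_params] (`bin_tolerance` is used).
#' @return An [intensity_matrix], rows in the order of `peak_tables`.
#' @export
bin_peaks <- function(peak_tables, params = preprocess_params()) {
  stopifnot(length(peak_tables) >= 1L)
  meta <- do.call(rbind, lapply(peak_tables, function(pt) {
    m <- attr(pt, "spectrum_meta")
    if (is.null(m)) {
      if (nrow(pt) == 0L) {
        stop("an empty peak_table needs a 'spectrum_meta' attribute")
      }
      m <- pt[1L, c("spectrum_id", "label", "bio_rep", "exp_rep", "tech_rep")]
    }
    m
  }))
  rownames(meta) <- NULL
  all_peaks <- do.call(rbind, lapply(seq_along(peak_tables), function(i) {
    pt <- peak_tables[[i]]
    if (nrow(pt) == 0L) return(NULL)
    data.frame(spectrum = i, mz = pt$mz, intensity = pt$intensity)
  }))
  if (is.null(all_peaks) || nrow(all_peaks) == 0L) {
    return(intensity_matrix(matrix(0, nrow(meta), 0L), numeric(0), meta))
  }
  bins <- greedy_bin(all_peaks, params$bin_tolerance)
  ref <- vapply(bins, function(b) mean(b$mz), numeric(1))
  o <- order(ref)
  bins <- bins[o]
  ref <- ref[o]
  values <- matrix(0, nrow = nrow(meta), ncol = length(bins))
  for (j in seq_along(bins)) {
    values[bins[[j]]$spectrum, j] <- bins[[j]]$intensity
  }
  intensity_matrix(values, ref, meta)
}

#' Discard infrequent features
#'
#' A feature is kept iff it is non-zero in at least `min_frequency` of the
#' rows (a feature occurring in exactly the threshold fraction is kept;
#' strictly fewer is discarded).
#'
#' @param matrix An [intensity_matrix].
#' @param params A [preprocess_params] (`min_frequency` is used).
#' @return The filtered [intensity_matrix]; a warning is issued if no feature
#'   survives.
#' @export
filter_peaks_by_frequency <- function(matrix, params = preprocess_params()) {
  stopifnot(inherits(matrix, "intensity_matrix"), nrow(matrix$values) > 0L)
  if (length(matrix$mz) == 0L) return(matrix)
  freq <- colMeans(matrix$values > 0)
  keep <- freq >= params$min_frequency
  if (!any(keep)) {
    warning("all features fall below the occurrence threshold; ",
            "returning an empty feature set")
  }
  intensity_matrix(matrix$values[, keep, drop = FALSE], matrix$mz[keep],
                   matrix$meta)
}

#' Average technical replicates
#'
#' Rows sharing a `(label, bio_rep, exp_rep)` key — repeated acquisitions of
#' the same spot — are replaced by their arithmetic mean intensity vector
#' (absent peaks count as 0). The number of output rows equals the number of
#' distinct experimental-replicate groups.
#'
#' @param matrix An [intensity_matrix] whose rows carry replicate keys.
#' @return An [intensity_matrix] of averaged spectra; the metadata keeps
#'   `label`, `bio_rep`, `exp_rep` and records the group size as `n_tech`.
#' @export
average_technical_replicates <- function(matrix) {
  stopifnot(inherits(matrix, "intensity_matrix"),
            all(c("bio_rep", "exp_rep") %in% names(matrix$meta)))
  key <- paste(matrix$meta$label, matrix$meta$bio_rep, matrix$meta$exp_rep,
               sep = "\r")
  first <- !duplicated(key)
  ukey <- key[first]
  grp <- match(key, ukey)
  counts <- tabulate(grp, nbins = length(ukey))
  if (ncol(matrix$values) > 0L) {
    sums <- rowsum(matrix$values, grp, reorder = TRUE)
    avg <- sums / counts
  } else {
    avg <- matrix(0, length(ukey), 0L)
  }
  meta <- matrix$meta[first, , drop = FALSE][order(unique(grp)), , drop = FALSE]
  out_meta <- data.frame(
    spectrum_id = sprintf("%s_b%d_e%d", meta$label, meta$bio_rep,
                          meta$exp_rep),
    label = meta$label,
    bio_rep = meta$bio_rep,
    exp_rep = meta$exp_rep,
    n_tech = counts,
    stringsAsFactors = FALSE)
  intensity_matrix(avg, matrix$mz, out_meta)
}

#' Run the full spectral preprocessing chain
#'
#' Composes the preprocessing stages in their canonical order: crop to the
#' mass range, square-root transform, Savitzky-Golay smoothing, SNIP baseline
#' subtraction, MAD noise estimation, signal-to-noise peak detection, m/z
#' binning, occurrence filtering, and technical-replicate averaging.
#'
#' @param spectra A list of at least two [mass_spectrum] objects.
#' @param params A [preprocess_params].
#' @return An object of class `preprocess_result`: a list with `matrix` (the
#'   averaged [intensity_matrix]), `spectrum_matrix` (the per-spectrum matrix
#'   before averaging), and `log` (a data frame of per-stage counts).
#' @export
run_preprocessing <- function(spectra, params = preprocess_params()) {
  stopifnot(is.list(spectra), length(spectra) >= 2L)
  peak_tables <- vector("list", length(spectra))
  n_peaks <- 0L
  for (i in seq_along(spectra)) {
    s <- crop_spectrum(spectra[[i]], params$mass_range[1L],
                       params$mass_range[2L])
    s <- transform_sqrt(s)
    s <- smooth_sg(s, params)
    s <- replace_intensity(s, pmax(s$intensity, 0))
    bl <- snip_baseline(s, params)
    s <- subtract_baseline(s, bl)
    noise <- estimate_noise_mad(s)
    pt <- detect_peaks(s, params, noise = noise)
    attr(pt, "spectrum_meta") <- spectra_metadata(spectra[i])
    peak_tables[[i]] <- pt
    n_peaks <- n_peaks + nrow(pt)
  }
  binned <- bin_peaks(peak_tables, params)
  filtered <- filter_peaks_by_frequency(binned, params)
  averaged <- average_technical_replicates(filtered)
  log <- data.frame(
    stage = c("input_spectra", "detected_peaks", "binned_features",
              "frequent_features", "averaged_spectra"),
    n = c(length(spectra), n_peaks, length(binned$mz), length(filtered$mz),
          nrow(averaged$values)))
  structure(list(matrix = averaged, spectrum_matrix = filtered,
                 peak_tables = peak_tables, log = log, params = params),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result>\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-18s %d\n", x$log$stage[i], x$log$n[i]))
  }
  invisible(x)
}
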