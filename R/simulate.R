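# run expr with a local RNG state so generators are reproducible without
# disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# distribute `total` units over `n` slots as evenly as possible
distribute_counts <- function(total, n) {
  base <- total %/% n
  counts <- rep(base, n)
  rem <- total %% n
  if (rem > 0L) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  counts
}

#' Generative model of a linear-mode profile spectrum
#'
#' Describes synthetic whole-cell spectra: an exponentially decaying
#' baseline, Gaussian peaks whose width follows a constant mass resolution
#' (`sigma(m) = m / (2.355 R)`), class-dependent peak presence
#' probabilities, a three-tier multiplicative intensity jitter (biological /
#' experimental / technical), additive detector noise clipped at zero, and a
#' per-spectrum mass-calibration shift.
#'
#' @param classes Character vector of class (cell-line) names.
#' @param peaks Data frame of peak definitions: `mz` (Da), `meanlog` (mean
#'   log height).
#' @param presence Numeric matrix of presence probabilities, one row per
#'   peak, one column per class.
#' @param mass_range Acquisition window in Da.
#' @param points_per_da Sampling density of the m/z grid.
#' @param baseline_amplitude,baseline_decay Baseline
#'   `A * exp(-decay * (m - low))`.
#' @param resolution Mass resolution `R` (FWHM = m / R).
#' @param noise_sd Additive Gaussian noise scale.
#' @param bio_jitter_sd,exp_jitter_sd,tech_jitter_sd Log-normal intensity
#'   jitter standard deviations per replicate tier.
#' @param calibration_shift_ppm_sd Per-spectrum relative m/z shift (ppm).
#' @param truth Marker annotation table carried along as ground truth.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(classes, peaks, presence,
                           mass_range = c(2000, 20000),
                           points_per_da = 1,
                           baseline_amplitude = 300,
                           baseline_decay = 3e-4,
                           resolution = 700,
                           noise_sd = 4,
                           bio_jitter_sd = 0.15,
                           exp_jitter_sd = 0.10,
                           tech_jitter_sd = 0.05,
                           calibration_shift_ppm_sd = 100,
                           truth = NULL) {
  presence <- as.matrix(presence)
  stopifnot(length(classes) >= 1L,
            nrow(presence) == nrow(peaks),
            ncol(presence) == length(classes),
            all(presence >= 0), all(presence <= 1),
            baseline_amplitude > 0, resolution > 0, noise_sd >= 0,
            mass_range[1L] < mass_range[2L], points_per_da > 0)
  colnames(presence) <- classes
  structure(list(classes = as.character(classes), peaks = peaks,
                 presence = presence,
                 mass_range = as.numeric(mass_range),
                 points_per_da = points_per_da,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay,
                 resolution = resolution, noise_sd = noise_sd,
                 bio_jitter_sd = bio_jitter_sd,
                 exp_jitter_sd = exp_jitter_sd,
                 tech_jitter_sd = tech_jitter_sd,
                 calibration_shift_ppm_sd = calibration_shift_ppm_sd,
                 truth = truth),
            class = "spectrum_model")
}

#' Default spectrum model with planted discriminant peaks
#'
#' Builds a model with `n_shared` backbone peaks present in every class and
#' `n_markers` class-discriminant peaks per class. Two marker schemes exist:
#'
#' * `"complement"` (default): each class is marked by peaks that are ABSENT
#'   in it (presence `p_out`) and present in all other classes (`p_in`).
#'   With two or more classes such peaks occur in well over half of the
#'   spectra and therefore survive the 50% occurrence filter, while still
#'   carrying the full in/out presence contrast; a class is recognized by
#'   the negative t-scores of its absent markers, mirroring how absence
#'   signals group membership in whole-cell profiling.
#' * `"exclusive"`: each class's markers are present only in that class
#'   (`p_in` in-class, `p_out` elsewhere). Maximal contrast, but in a
#'   multi-class dataset such peaks occur in a minority of spectra and the
#'   occurrence filter removes them; intended for direct tests of the
#'   ranking stage.
#'
#' @param classes Class names.
#' @param scheme Marker scheme, see above.
#' @param n_shared Number of shared backbone peaks.
#' @param n_markers Number of discriminant peaks per class.
#' @param p_in,p_out Presence probabilities on the carrying / non-carrying
#'   side of a marker.
#' @param ... Further arguments passed to [spectrum_model].
#' @return A `spectrum_model` with a `truth` table listing each class's
#'   marker m/z values and their direction (`"absent"` or `"present"`).
#' @export
default_spectrum_model <- function(classes,
                                   scheme = c("complement", "exclusive"),
                                   n_shared = 8L, n_markers = 6L,
                                   p_in = 0.95, p_out = 0.02, ...) {
  scheme <- match.arg(scheme)
  k <- length(classes)
  shared_mz <- round(seq(4300, 15700, length.out = n_shared))
  shared_h <- log(seq(420, 140, length.out = n_shared))
  n_mark_total <- n_markers * k
  marker_mz <- round(seq(4450, 17300, length.out = n_mark_total)) + 73
  # keep markers clear of the shared backbone
  for (i in seq_along(marker_mz)) {
    while (any(abs(marker_mz[i] - shared_mz) < 100) ||
           any(abs(marker_mz[i] - marker_mz[-i]) < 100)) {
      marker_mz[i] <- marker_mz[i] + 61
    }
  }
  # interleave so each class's markers span the mass range
  marker_class <- rep_len(seq_len(k), n_mark_total)
  marker_h <- log(rep_len(c(260, 210, 310, 180, 240, 200), n_mark_total))
  peaks <- data.frame(mz = c(shared_mz, marker_mz),
                      meanlog = c(shared_h, marker_h))
  presence <- matrix(1, nrow(peaks), k)
  for (j in seq_len(k)) {
    rows <- n_shared + which(marker_class == j)
    if (scheme == "complement") {
      presence[rows, ] <- p_in
      presence[rows, j] <- p_out
    } else {
      presence[rows, ] <- p_out
      presence[rows, j] <- p_in
    }
  }
  truth <- data.frame(
    class = classes[marker_class],
    mz = marker_mz,
    direction = if (scheme == "complement") "absent" else "present",
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$class, truth$mz), ]
  rownames(truth) <- NULL
  spectrum_model(classes = classes, peaks = peaks, presence = presence,
                 truth = truth, ...)
}

#' Replicate design table
#'
#' Expands per-cell-line totals into one row per acquired spectrum.
#' Experimental replicates are distributed as evenly as possible over
#' `n_bio` biological replicates, and technical replicates as evenly as
#' possible over the experimental replicates, so the totals are reproduced
#' exactly even when they are not multiples of each other.
#'
#' @param lines Data frame with columns `label`, `n_exp` (total experimental
#'   replicates), `n_tech` (total technical spectra) and optionally `n_bio`
#'   (default 3, biological triplicate).
#' @return A data frame with one row per spectrum: `label`, `bio_rep`,
#'   `exp_rep` (numbered within the biological replicate), `tech_rep`.
#' @export
replicate_design <- function(lines) {
  stopifnot(all(c("label", "n_exp", "n_tech") %in% names(lines)))
  if (is.null(lines$n_bio)) lines$n_bio <- 3L
  rows <- list()
  for (i in seq_len(nrow(lines))) {
    n_exp <- lines$n_exp[i]
    n_bio <- min(lines$n_bio[i], n_exp)
    exp_per_bio <- distribute_counts(n_exp, n_bio)
    tech_per_exp <- distribute_counts(lines$n_tech[i], n_exp)
    g <- 0L
    for (b in seq_len(n_bio)) {
      for (e in seq_len(exp_per_bio[b])) {
        g <- g + 1L
        for (t in seq_len(tech_per_exp[g])) {
          rows[[length(rows) + 1L]] <- data.frame(
            label = lines$label[i], bio_rep = b, exp_rep = e, tech_rep = t,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate designs of the profiling experiments
#'
#' Obtained replicate counts of the chronic myeloid leukemia model (K562,
#' Ko562, Ki562, Kv562: 16+22+16+23 technical spectra over 9+11+8+12
#' experimental replicates), the U251 glioblastoma model (36+32+36 over
#' 12+11+12) and the LN229 glioblastoma model (40+41+44 over 14+14+15), each
#' in biological triplicate.
#'
#' @param labels Optional subset of cell lines to keep (in the given order).
#' @return A design data frame for [replicate_design]-expanded use with
#'   [simulate_dataset].
#' @export
design_cml <- function(labels = c("K562", "Ko562", "Ki562", "Kv562")) {
  all <- data.frame(label = c("K562", "Ko562", "Ki562", "Kv562"),
                    n_exp = c(9L, 11L, 8L, 12L),
                    n_tech = c(16L, 22L, 16L, 23L),
                    stringsAsFactors = FALSE)
  replicate_design(all[match(labels, all$label), , drop = FALSE])
}

#' @rdname design_cml
#' @export
design_u251 <- function(labels = c("U251", "U251-V", "U251-R")) {
  all <- data.frame(label = c("U251", "U251-V", "U251-R"),
                    n_exp = c(12L, 11L, 12L),
                    n_tech = c(36L, 32L, 36L),
                    stringsAsFactors = FALSE)
  replicate_design(all[match(labels, all$label), , drop = FALSE])
}

#' @rdname design_cml
#' @export
design_ln229 <- function(labels = c("LN229", "LN229-V", "LN229-R")) {
  all <- data.frame(label = c("LN229", "LN229-V", "LN229-R"),
                    n_exp = c(14L, 14L, 15L),
                    n_tech = c(40L, 41L, 44L),
                    stringsAsFactors = FALSE)
  replicate_design(all[match(labels, all$label), , drop = FALSE])
}

# core spectrum synthesis using the current RNG stream
synthesize_spectrum <- function(model, class_label, spectrum_id,
                                bio_rep, exp_rep, tech_rep,
                                presence, bio_jitter, exp_jitter) {
  lo <- model$mass_range[1L]
  hi <- model$mass_range[2L]
  grid <- seq(lo, hi, by = 1 / model$points_per_da)
  shift <- stats::rnorm(1L, 0, model$calibration_shift_ppm_sd * 1e-6)
  tech_jitter <- stats::rnorm(1L, 0, model$tech_jitter_sd)
  y <- model$baseline_amplitude * exp(-model$baseline_decay * (grid - lo))
  truth_peaks <- list()
  for (p in which(presence)) {
    center <- model$peaks$mz[p] * (1 + shift)
    sigma <- center / (2.355 * model$resolution)
    h <- exp(model$peaks$meanlog[p] + bio_jitter + exp_jitter + tech_jitter)
    i1 <- max(1L, findInterval(center - 6 * sigma, grid))
    i2 <- min(length(grid), findInterval(center + 6 * sigma, grid) + 1L)
    idx <- i1:i2
    y[idx] <- y[idx] + h * exp(-(grid[idx] - center)^2 / (2 * sigma^2))
    truth_peaks[[length(truth_peaks) + 1L]] <-
      data.frame(mz = model$peaks$mz[p], height = h)
  }
  if (model$noise_sd > 0) {
    y <- y + stats::rnorm(length(grid), 0, model$noise_sd)
  }
  y <- pmax(y, 0)
  mass_spectrum(grid, y, spectrum_id = spectrum_id, label = class_label,
                bio_rep = bio_rep, exp_rep = exp_rep, tech_rep = tech_rep,
                truth = list(peaks = do.call(rbind, truth_peaks),
                             shift = shift))
}

#' Simulate one profile spectrum
#'
#' Draws the peak presence, replicate-tier jitters, calibration shift and
#' detector noise for a single spectrum of the given class. The planted peak
#' list is attached as ground truth. Identical arguments (including `seed`)
#' give a bit-identical spectrum.
#'
#' @param model A [spectrum_model].
#' @param class_label Which class to draw from.
#' @param bio_rep,exp_rep,tech_rep Replicate key recorded in the record.
#' @param seed Integer seed.
#' @param spectrum_id Identifier (default built from class and key).
#' @return A [mass_spectrum] with a `truth` annotation.
#' @export
simulate_spectrum <- function(model, class_label, bio_rep = 1L,
                              exp_rep = 1L, tech_rep = 1L, seed = 1L,
                              spectrum_id = NULL) {
  stopifnot(inherits(model, "spectrum_model"),
            class_label %in% model$classes)
  if (is.null(spectrum_id)) {
    spectrum_id <- sprintf("%s_b%d_e%d_t%d", class_label, bio_rep, exp_rep,
                           tech_rep)
  }
  with_local_seed(seed, {
    presence <- stats::runif(nrow(model$peaks)) <
      model$presence[, class_label]
    bio_jitter <- stats::rnorm(1L, 0, model$bio_jitter_sd)
    exp_jitter <- stats::rnorm(1L, 0, model$exp_jitter_sd)
    synthesize_spectrum(model, class_label, spectrum_id, bio_rep, exp_rep,
                        tech_rep, presence, bio_jitter, exp_jitter)
  })
}

#' Simulate a replicated spectrum dataset
#'
#' Generates one spectrum per design row. Peak presence and the biological /
#' experimental intensity jitters are drawn once per replicate unit and
#' shared by that unit's technical replicates (repeated acquisitions of the
#' same spot see the same analyte); the technical jitter, calibration shift
#' and noise are per spectrum.
#'
#' @param model A [spectrum_model].
#' @param design A design data frame (see [replicate_design], [design_cml]).
#' @param seed Integer seed; identical `(model, design, seed)` give
#'   bit-identical output.
#' @return A list: `spectra` (list of [mass_spectrum]), `truth` (the model's
#'   marker table), `design`.
#' @export
simulate_dataset <- function(model, design, seed = 1L) {
  stopifnot(inherits(model, "spectrum_model"),
            all(c("label", "bio_rep", "exp_rep", "tech_rep") %in%
                names(design)),
            all(design$label %in% model$classes))
  with_local_seed(seed, {
    spectra <- vector("list", nrow(design))
    unit_key <- paste(design$label, design$bio_rep, design$exp_rep,
                      sep = "\r")
    bio_key <- paste(design$label, design$bio_rep, sep = "\r")
    unit_presence <- list()
    unit_expj <- list()
    bio_j <- list()
    for (i in seq_len(nrow(design))) {
      lab <- design$label[i]
      bk <- bio_key[i]
      uk <- unit_key[i]
      if (is.null(bio_j[[bk]])) {
        bio_j[[bk]] <- stats::rnorm(1L, 0, model$bio_jitter_sd)
      }
      if (is.null(unit_presence[[uk]])) {
        unit_presence[[uk]] <- stats::runif(nrow(model$peaks)) <
          model$presence[, lab]
        unit_expj[[uk]] <- stats::rnorm(1L, 0, model$exp_jitter_sd)
      }
      spectra[[i]] <- synthesize_spectrum(
        model, lab,
        sprintf("%s_b%d_e%d_t%d", lab, design$bio_rep[i], design$exp_rep[i],
                design$tech_rep[i]),
        design$bio_rep[i], design$exp_rep[i], design$tech_rep[i],
        unit_presence[[uk]], bio_j[[bk]], unit_expj[[uk]])
    }
    list(spectra = spectra, truth = model$truth, design = design)
  })
}

#' Generative model of an XTT dose-response experiment
#'
#' @param lines Data frame with columns `cell_line`, `b`, `c`, `d`, `e`: the
#'   true four-parameter log-logistic parameters per cell line.
#' @param concentrations Positive concentration grid in uM (0 basal wells
#'   are added automatically).
#' @param replicates Wells per concentration (default 9: biological times
#'   experimental triplicate).
#' @param noise_sd Gaussian noise on the metabolic-index scale (percent
#'   points) of treated wells.
#' @param basal_ab Corrected absorbance of the untreated wells (the 100%
#'   anchor).
#' @param ab620 Constant 620 nm background channel.
#' @return An object of class `dose_response_model`.
#' @export
dose_response_model <- function(lines,
                                concentrations = 10^seq(-2, 3, length.out = 8),
                                replicates = 9L, noise_sd = 3,
                                basal_ab = 0.68, ab620 = 0.12) {
  stopifnot(all(c("cell_line", "b", "c", "d", "e") %in% names(lines)),
            all(lines$e > 0), all(lines$d > lines$c),
            all(concentrations > 0), replicates >= 1L, noise_sd >= 0,
            basal_ab > 0)
  structure(list(lines = lines, concentrations = sort(concentrations),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 basal_ab = basal_ab, ab620 = ab620),
            class = "dose_response_model")
}

#' Simulate an XTT plate
#'
#' Treated wells draw their metabolic index from the true curve plus
#' Gaussian noise and are back-converted to 450/620 nm absorbance pairs
#' against a fixed basal corrected absorbance; basal (0 uM) wells carry the
#' anchor absorbance exactly, so with `noise_sd = 0` the index computed from
#' the plate reproduces the true curve value at every concentration.
#'
#' @param model A [dose_response_model].
#' @param seed Integer seed.
#' @return A plate data frame (`cell_line`, `concentration_uM`, `ab450`,
#'   `ab620`, `replicate`) with the true parameters attached as the
#'   `"truth"` attribute.
#' @export
simulate_xtt <- function(model, seed = 1L) {
  stopifnot(inherits(model, "dose_response_model"))
  with_local_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(model$lines))) {
      ln <- model$lines[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = ln$cell_line, concentration_uM = 0,
        ab450 = model$basal_ab + model$ab620, ab620 = model$ab620,
        replicate = seq_len(model$replicates), stringsAsFactors = FALSE)
      for (x in model$concentrations) {
        idx <- f4pl(x, ln$b, ln$c, ln$d, ln$e) +
          stats::rnorm(model$replicates, 0, model$noise_sd)
        corr <- idx / 100 * model$basal_ab
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = ln$cell_line, concentration_uM = x,
          ab450 = corr + model$ab620, ab620 = model$ab620,
          replicate = seq_len(model$replicates), stringsAsFactors = FALSE)
      }
    }
    plate <- do.call(rbind, rows)
    rownames(plate) <- NULL
    attr(plate, "truth") <- model$lines
    plate
  })
}
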