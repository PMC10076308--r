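#' Construct a mass spectrum record
#'
#' A `mass_spectrum` holds one profile spectrum (m/z in Da versus intensity in
#' arbitrary units) together with its replicate-hierarchy metadata: the
#' cell-line label and the biological, experimental and technical replicate
#' indices. The m/z axis is stored strictly increasing; input points are sorted
#' and duplicate m/z values are collapsed by mean intensity so the invariant is
#' enforceable on real instrument exports.
#'
#' @param mz Numeric vector of mass-to-charge values (Da).
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param spectrum_id Identifier of the spectrum.
#' @param label Cell-line name (group label), `NA` if unknown.
#' @param bio_rep,exp_rep,tech_rep Replicate indices (>= 1): independently
#'   grown culture, spot on the target plate, repeated acquisition of a spot.
#' @param truth Optional list of ground-truth annotations (used by the
#'   synthetic-data generator to record planted peaks).
#' @param nonneg Require all intensities to be non-negative (default `TRUE`;
#'   internal smoothing stages may relax this).
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, spectrum_id = "spectrum",
                          label = NA_character_, bio_rep = 1L, exp_rep = 1L,
                          tech_rep = 1L, truth = NULL, nonneg = TRUE) {
  if (!is.numeric(mz) || !is.numeric(intensity)) {
    stop("mz and intensity must be numeric")
  }
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (length(mz) == 0L) {
    stop("empty spectrum: '", spectrum_id, "'")
  }
  if (anyNA(mz) || anyNA(intensity) || any(!is.finite(mz))) {
    stop("non-finite values in spectrum '", spectrum_id, "'")
  }
  if (nonneg && any(intensity < 0)) {
    stop("negative intensity in spectrum '", spectrum_id, "'")
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    grp <- match(mz, unique(mz))
    intensity <- as.numeric(rowsum(intensity, grp) / tabulate(grp))
    mz <- unique(mz)
  }
  structure(
    list(mz = mz, intensity = as.numeric(intensity),
         spectrum_id = as.character(spectrum_id),
         label = as.character(label),
         bio_rep = as.integer(bio_rep), exp_rep = as.integer(exp_rep),
         tech_rep = as.integer(tech_rep), truth = truth),
    class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %s [%s b%d e%d t%d]: %d points, m/z %.1f-%.1f Da\n",
              x$spectrum_id,
              ifelse(is.na(x$label), "-", x$label),
              x$bio_rep, x$exp_rep, x$tech_rep,
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' @export
length.mass_spectrum <- function(x) length(x$mz)

#' Restrict a spectrum to a mass range
#'
#' Keeps points with `low <= mz <= high` (closed interval, so peaks exactly at
#' the bounds are retained).
#'
#' @param spectrum A [mass_spectrum].
#' @param low,high Mass range bounds in Da.
#' @return A cropped [mass_spectrum].
#' @export
crop_spectrum <- function(spectrum, low, high) {
  stopifnot(inherits(spectrum, "mass_spectrum"), low < high)
  keep <- spectrum$mz >= low & spectrum$mz <= high
  if (!any(keep)) {
    stop("cropping removed all points of spectrum '", spectrum$spectrum_id, "'")
  }
  out <- spectrum
  out$mz <- spectrum$mz[keep]
  out$intensity <- spectrum$intensity[keep]
  out
}

# replace the intensity vector, keeping metadata
replace_intensity <- function(spectrum, intensity) {
  out <- spectrum
  out$intensity <- as.numeric(intensity)
  out
}

#' Metadata of a spectrum collection as a data frame
#'
#' @param spectra A list of [mass_spectrum] objects.
#' @return A data frame with one row per spectrum: `spectrum_id`, `label`,
#'   `bio_rep`, `exp_rep`, `tech_rep`.
#' @export
spectra_metadata <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  data.frame(
    spectrum_id = vapply(spectra, function(s) s$spectrum_id, character(1)),
    label = vapply(spectra, function(s) s$label, character(1)),
    bio_rep = vapply(spectra, function(s) s$bio_rep, integer(1)),
    exp_rep = vapply(spectra, function(s) s$exp_rep, integer(1)),
    tech_rep = vapply(spectra, function(s) s$tech_rep, integer(1)),
    stringsAsFactors = FALSE)
}
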