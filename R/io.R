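#' Read a sample sheet
#'
#' The sample sheet is a comma-separated file with columns
#' `spectrum_id,path,label,bio_rep,exp_rep,tech_rep`, one row per spectrum.
#' Relative `path` entries are resolved against the directory of the sheet.
#'
#' @param path Path to the sample sheet csv.
#' @return A data frame with the six columns above, `path` resolved.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("spectrum_id", "path", "label", "bio_rep", "exp_rep", "tech_rep")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sheet$spectrum_id)) {
    stop("duplicate spectrum_id in sample sheet: ",
         paste(unique(sheet$spectrum_id[duplicated(sheet$spectrum_id)]),
               collapse = ", "))
  }
  base <- dirname(path)
  abs <- file.path(base, sheet$path)
  sheet$path <- ifelse(file.exists(sheet$path), sheet$path, abs)
  for (i in seq_len(nrow(sheet))) {
    if (!file.exists(sheet$path[i])) {
      stop(sprintf("sample sheet row %d ('%s'): file not found: %s",
                   i, sheet$spectrum_id[i], sheet$path[i]))
    }
  }
  sheet
}

# read one two-column delimited spectrum file; error messages carry the
# offending line number (header is line 1)
read_spectrum_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2L) stop("spectrum file ", path, " needs >= 2 columns")
  mz <- suppressWarnings(as.numeric(raw[[1L]]))
  intensity <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(mz) & nzchar(raw[[1L]]) |
               is.na(intensity) & nzchar(raw[[2L]]))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value in %s at line %d", path, bad[1L] + 1L))
  }
  keep <- !is.na(mz) & !is.na(intensity)
  list(mz = mz[keep], intensity = intensity[keep])
}

# read the first profile spectrum of an mzML file through mzR
read_spectrum_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  pk <- mzR::peaks(handle, 1L)
  list(mz = as.numeric(pk[, 1L]), intensity = as.numeric(pk[, 2L]))
}

#' Load profile spectra listed in a sample sheet
#'
#' Reads one spectrum per sample-sheet row and attaches the row's label and
#' replicate keys. m/z axes are sorted ascending (intensities co-permuted) and
#' duplicate m/z values are collapsed by mean intensity; empty spectra are
#' rejected.
#'
#' @param sheet_path Path to the sample sheet (see [read_sample_sheet]).
#' @param format `"csv"` for two-column `mz,intensity` files (header
#'   required), `"mzml"` for HUPO-PSI mzML profile spectra (one spectrum per
#'   file, read through \pkg{mzR}).
#' @return A list of [mass_spectrum] objects, one per sheet row, in row order.
#' @export
load_spectra <- function(sheet_path, format = c("csv", "mzml")) {
  format <- match.arg(format)
  sheet <- read_sample_sheet(sheet_path)
  reader <- switch(format, csv = read_spectrum_csv, mzml = read_spectrum_mzml)
  out <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    xy <- tryCatch(reader(sheet$path[i]), error = function(e) {
      stop(sprintf("sample sheet row %d ('%s'): %s",
                   i, sheet$spectrum_id[i], conditionMessage(e)), call. = FALSE)
    })
    if (length(xy$mz) == 0L) {
      stop(sprintf("sample sheet row %d ('%s'): empty spectrum",
                   i, sheet$spectrum_id[i]))
    }
    out[[i]] <- mass_spectrum(xy$mz, xy$intensity,
                              spectrum_id = sheet$spectrum_id[i],
                              label = sheet$label[i],
                              bio_rep = sheet$bio_rep[i],
                              exp_rep = sheet$exp_rep[i],
                              tech_rep = sheet$tech_rep[i])
  }
  out
}

#' Write a rectangular table as comma-separated text
#'
#' UTF-8, comma delimiter, decimal point, no row names. Numeric values are
#' written at full precision so a save/load round trip reproduces them to
#' better than 1e-9 relative.
#'
#' @param rows A data frame or matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_table <- function(rows, path) {
  if (is.matrix(rows)) rows <- as.data.frame(rows)
  if (!is.data.frame(rows)) stop("'rows' must be a data frame or matrix")
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con), add = TRUE)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [save_table]
#'
#' @param path Path to a csv file.
#' @return A data frame (0 rows for a header-only file).
#' @export
load_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
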