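#' Profiling pipeline configuration
#'
#' Validated bundle of the parameters of the spectral profiling workflow.
#' Unknown fields are rejected (arguments are matched strictly).
#'
#' @param k Number of clusters.
#' @param preprocess A [preprocess_params].
#' @param bda_threshold Absolute t-score selection cutoff.
#' @param top_n Fallback number of top-ranked peaks.
#' @param cluster A [cluster_params]; its `k` is overridden by `k`.
#' @param pca_on Run PCA and clustering on the `"binary"` (default) or
#'   `"intensity"` values of the selected peaks.
#' @return An object of class `profiling_config`.
#' @export
profiling_config <- function(k = 3L,
                             preprocess = preprocess_params(),
                             bda_threshold = 2.5,
                             top_n = 10L,
                             cluster = cluster_params(k = k),
                             pca_on = c("binary", "intensity")) {
  pca_on <- match.arg(pca_on)
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(cluster, "cluster_params"),
            k >= 2L, bda_threshold > 0)
  cluster$k <- as.integer(k)
  structure(list(k = as.integer(k), preprocess = preprocess,
                 bda_threshold = bda_threshold, top_n = top_n,
                 cluster = cluster, pca_on = pca_on),
            class = "profiling_config")
}

#' Run the spectral profiling workflow
#'
#' End-to-end: preprocessing (crop, sqrt, smooth, SNIP, detect, bin, filter,
#' average), dichotomization, binary-discriminant t-score ranking and peak
#' selection, hierarchical k-means clustering on the binary distance of the
#' selected peaks, PCA, per-cluster homogeneity and confidence ellipses.
#' Every stage is deterministic.
#'
#' @param spectra A list of [mass_spectrum] objects (labels attached).
#' @param config A [profiling_config].
#' @return An object of class `profiling_report`: `counts` (per-stage log),
#'   `ranking` (the peak ranking with selection flags), `selected_mz`,
#'   `assignment` (data frame spectrum_id, label, cluster, PC1, PC2),
#'   `variance_fraction`, `homogeneity`, `ellipses`, `clustering`,
#'   `config`.
#' @export
run_profiling <- function(spectra, config = profiling_config()) {
  stopifnot(inherits(config, "profiling_config"))
  pre <- run_preprocessing(spectra, config$preprocess)
  avg <- pre$matrix
  if (config$k > nrow(avg$values)) {
    stop(sprintf("config k = %d exceeds the %d averaged spectra",
                 config$k, nrow(avg$values)))
  }
  if (length(avg$mz) < 2L) {
    stop("fewer than 2 features survived preprocessing")
  }
  binary <- dichotomize(avg)
  ranking <- group_t_scores(binary)
  ranking <- select_discriminant_peaks(ranking, config$bda_threshold,
                                       config$top_n)
  sel_mz <- sort(ranking$mz[ranking$selected])
  keep <- match(sel_mz, binary$mz)
  sel_binary <- intensity_matrix(binary$values[, keep, drop = FALSE],
                                 binary$mz[keep], binary$meta)
  class(sel_binary) <- class(binary)
  cluster_input <- if (config$pca_on == "binary") sel_binary else
    intensity_matrix(avg$values[, keep, drop = FALSE], avg$mz[keep],
                     avg$meta)
  d <- binary_distance_matrix(sel_binary)
  hk <- hkmeans(cluster_input, dist = d, params = config$cluster)
  pca <- pca_scores(cluster_input)
  hom <- cluster_homogeneity(hk$assignment, avg$meta$label)
  assignment <- data.frame(spectrum_id = avg$meta$spectrum_id,
                           label = avg$meta$label,
                           cluster = hk$assignment,
                           PC1 = pca$scores[, 1L],
                           PC2 = pca$scores[, 2L],
                           stringsAsFactors = FALSE)
  rownames(assignment) <- NULL
  ellipses <- lapply(split(seq_len(nrow(assignment)), assignment$cluster),
                     function(rows) {
    if (length(rows) < 3L) return(NULL)
    confidence_ellipse(as.matrix(assignment[rows, c("PC1", "PC2")]),
                       config$cluster$ellipse_confidence)
  })
  structure(list(counts = pre$log, ranking = ranking, selected_mz = sel_mz,
                 assignment = assignment,
                 variance_fraction = pca$variance_fraction,
                 homogeneity = hom, ellipses = ellipses, clustering = hk,
                 matrix = avg, config = config),
            class = "profiling_report")
}

#' @export
print.profiling_report <- function(x, ...) {
  cat("<profiling_report>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-18s %d\n", x$counts$stage[i], x$counts$n[i]))
  }
  cat(sprintf("  selected peaks     %d\n", length(x$selected_mz)))
  cat(sprintf("  PC1+PC2 variance   %.1f%%\n",
              sum(x$variance_fraction[1:2])))
  for (i in seq_len(nrow(x$homogeneity))) {
    h <- x$homogeneity[i, ]
    cat(sprintf("  cluster %d (%s, n=%d): %d%% homogeneous\n",
                h$cluster, h$modal_label, h$size, h$homogeneity_pct))
  }
  invisible(x)
}

#' Write the profiling report tables
#'
#' Exports the ranking and cluster assignment as csv and a machine-readable
#' JSON summary (per-stage counts, variance fractions, homogeneities,
#' ellipse parameters).
#'
#' @param report A `profiling_report`.
#' @param outdir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_profiling_report <- function(report, outdir, prefix = "profiling") {
  stopifnot(inherits(report, "profiling_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ranking = file.path(outdir, paste0(prefix, "_ranking.csv")),
    clusters = file.path(outdir, paste0(prefix, "_clusters.csv")),
    summary = file.path(outdir, paste0(prefix, "_summary.json")))
  save_table(as.data.frame(report$ranking), paths["ranking"])
  save_table(report$assignment, paths["clusters"])
  summary <- list(
    counts = stats::setNames(as.list(report$counts$n), report$counts$stage),
    selected_mz = report$selected_mz,
    variance_fraction = report$variance_fraction,
    pc12_percent = sum(report$variance_fraction[1:2]),
    homogeneity = report$homogeneity,
    ellipses = lapply(report$ellipses, function(e) {
      if (is.null(e)) return(NULL)
      list(center = e$center, semi_axes = e$semi_axes, angle = e$angle,
           degenerate = e$degenerate)
    }))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}

#' Run the dose-response workflow
#'
#' Computes the metabolic index from a plate table, fits a four-parameter
#' log-logistic curve per cell line, and assembles the potency summary
#' (EC50, IC50 with its not-reached `NaN` semantics, and fold-changes
#' against the reference lines). A line that cannot be fitted is flagged
#' (`converged = FALSE`) and the run continues.
#'
#' @param plate Plate data frame (see [metabolic_index]).
#' @param reference Cell lines against which fold-changes are reported.
#' @return A list of class `doseresponse_report`: `index` (the metabolic
#'   index table), `fits` (per-line `fourpl_fit`), `summary` (the potency
#'   table).
#' @export
run_doseresponse <- function(plate, reference = NULL) {
  index <- metabolic_index(plate)
  lines <- unique(index$cell_line)
  fits <- lapply(lines, function(ln) {
    tryCatch(fit_4pl(index, ln), error = function(e) {
      warning("cell line ", ln, " could not be fitted: ",
              conditionMessage(e))
      structure(list(b = NA_real_, c = NA_real_, d = NA_real_,
                     e = NA_real_, rss = NA_real_, converged = FALSE,
                     cell_line = ln, data = NULL), class = "fourpl_fit")
    })
  })
  names(fits) <- lines
  structure(list(index = index, fits = fits,
                 summary = potency_summary(fits, reference = reference)),
            class = "doseresponse_report")
}

#' @export
print.doseresponse_report <- function(x, ...) {
  cat("<doseresponse_report>\n")
  print(x$summary)
  invisible(x)
}

#' Scatter plot of the cluster scores with confidence ellipses
#'
#' Base-graphics rendering of the first two principal components, colored by
#' cluster, with the per-cluster multivariate-normal confidence ellipses.
#'
#' @param report A `profiling_report`.
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, `NULL`.
#' @export
plot_cluster_scores <- function(report, ...) {
  stopifnot(inherits(report, "profiling_report"))
  a <- report$assignment
  cols <- grDevices::hcl.colors(max(a$cluster), "Dark 3")
  graphics::plot(a$PC1, a$PC2, col = cols[a$cluster],
                 pch = 14 + a$cluster,
                 xlab = sprintf("PC1 (%.1f%%)", report$variance_fraction[1]),
                 ylab = sprintf("PC2 (%.1f%%)", report$variance_fraction[2]),
                 ...)
  th <- seq(0, 2 * pi, length.out = 181)
  for (cl in names(report$ellipses)) {
    e <- report$ellipses[[cl]]
    if (is.null(e)) next
    u <- cbind(e$semi_axes[1L] * cos(th), e$semi_axes[2L] * sin(th))
    rot <- cbind(c(cos(e$angle), sin(e$angle)),
                 c(-sin(e$angle), cos(e$angle)))
    pts <- sweep(u %*% t(rot), 2L, e$center, `+`)
    graphics::lines(pts, col = cols[as.integer(cl)], lty = 2)
  }
  graphics::text(a$PC1, a$PC2, a$label, pos = 3, cex = 0.6)
  invisible(NULL)
}
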