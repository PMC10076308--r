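#' Clustering parameters
#'
#' @param k Number of clusters (typically 2 or 3, matching the number of
#'   phenotype levels compared).
#' @param distance Dissimilarity for the tree; only `"binary"` (asymmetric
#'   Jaccard-type distance) is implemented.
#' @param linkage Agglomeration criterion; only `"ward2"` (Ward applied to
#'   squared dissimilarities with square-root back-transform, R's
#'   `"ward.D2"`) is implemented.
#' @param kmeans_max_iter Maximum k-means refinement iterations.
#' @param ellipse_confidence Coverage level of the cluster ellipses.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(k = 3L, distance = "binary", linkage = "ward2",
                           kmeans_max_iter = 10L, ellipse_confidence = 0.95) {
  distance <- match.arg(distance, "binary")
  linkage <- match.arg(linkage, "ward2")
  stopifnot(k >= 2L, kmeans_max_iter >= 1L,
            ellipse_confidence > 0, ellipse_confidence < 1)
  structure(list(k = as.integer(k), distance = distance, linkage = linkage,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 ellipse_confidence = as.numeric(ellipse_confidence)),
            class = "cluster_params")
}

#' Binary (asymmetric Jaccard-type) distance matrix
#'
#' For two 0/1 vectors, the number of positions where exactly one is 1
#' divided by the number of positions where at least one is 1. Two all-zero
#' vectors have distance 0 by convention (identical observations are
#' maximally similar).
#'
#' @param binary A `binary_matrix` or a 0/1 matrix.
#' @return A symmetric numeric matrix with zero diagonal and values in
#'   `[0, 1]`.
#' @export
binary_distance_matrix <- function(binary) {
  x <- if (inherits(binary, "intensity_matrix")) binary$values else
    as.matrix(binary)
  stopifnot(all(x %in% c(0, 1)))
  d <- as.matrix(stats::dist(x, method = "binary"))
  d[is.nan(d)] <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# total within-cluster sum of squares of an assignment on matrix x
within_ss <- function(x, assignment) {
  sum(vapply(split(seq_len(nrow(x)), assignment), function(rows) {
    xs <- x[rows, , drop = FALSE]
    ctr <- colMeans(xs)
    sum(sweep(xs, 2L, ctr)^2)
  }, numeric(1)))
}

#' Hierarchical k-means clustering
#'
#' The tree-initialized k-means hybrid: (1) agglomerative clustering of the
#' supplied dissimilarity with the ward.D2 criterion; (2) the tree is cut
#' into `k` groups; (3) the group centroids of the (binary) data matrix seed
#' a Euclidean k-means refinement (at most `kmeans_max_iter` iterations),
#' whose assignment is returned. There is no random initialization, so the
#' result is deterministic.
#'
#' @param binary A `binary_matrix` (or plain matrix) of observations.
#' @param dist Symmetric dissimilarity matrix (see
#'   [binary_distance_matrix]); computed from `binary` when `NULL`.
#' @param params A [cluster_params].
#' @return A list of class `hkmeans_result`: `assignment` (integer cluster
#'   per row), `centers`, `tot_withinss`, `init_withinss` (objective of the
#'   tree cut), and the `hclust` tree.
#' @export
hkmeans <- function(binary, dist = NULL, params = cluster_params()) {
  x <- if (inherits(binary, "intensity_matrix")) binary$values else
    as.matrix(binary)
  k <- params$k
  if (k > nrow(x)) stop("k exceeds the number of observations")
  if (is.null(dist)) dist <- binary_distance_matrix(binary)
  hc <- stats::hclust(stats::as.dist(dist), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  centers <- rowsum(x, grp) / as.vector(table(grp))
  init_ss <- within_ss(x, grp)
  assignment <- grp
  km <- NULL
  if (anyDuplicated(centers) == 0L) {
    km <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = params$kmeans_max_iter),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(km)) assignment <- km$cluster
  }
  tot <- if (!is.null(km)) km$tot.withinss else init_ss
  structure(list(assignment = as.integer(assignment),
                 centers = if (!is.null(km)) km$centers else centers,
                 tot_withinss = tot, init_withinss = init_ss,
                 hclust = hc, k = k),
            class = "hkmeans_result")
}

#' Principal component scores of a peak matrix
#'
#' Columns are centered (not scaled: binary features share a common scale)
#' and the rows are projected onto the eigenvectors of the covariance
#' matrix.
#'
#' @param binary A `binary_matrix` (or numeric matrix) with at least 2 rows
#'   and 2 features.
#' @return A list: `scores` (rows x components), `variance_fraction`
#'   (percent of total variance per component, summing to 100), `rotation`.
#' @export
pca_scores <- function(binary) {
  x <- if (inherits(binary, "intensity_matrix")) binary$values else
    as.matrix(binary)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  if (all(apply(x, 2L, stats::var) < .Machine$double.eps)) {
    stop("pca_scores: zero-variance matrix")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  list(scores = p$x,
       variance_fraction = 100 * ev / sum(ev),
       rotation = p$rotation)
}

#' Cluster homogeneity against true labels
#'
#' The homogeneity of a cluster is the percentage of its members carrying
#' the cluster's most frequent (modal) label. Reported percentages are
#' rounded half away from zero to integers; the unrounded value is kept.
#'
#' @param assignment Cluster id per observation.
#' @param labels True label per observation.
#' @return A data frame: `cluster`, `size`, `modal_label`, `homogeneity`
#'   (unrounded percent), `homogeneity_pct` (integer percent).
#' @export
cluster_homogeneity <- function(assignment, labels) {
  stopifnot(length(assignment) == length(labels))
  clusters <- sort(unique(assignment))
  rows <- lapply(clusters, function(cl) {
    members <- labels[assignment == cl]
    if (length(members) == 0L) {
      warning("cluster ", cl, " is empty; excluded")
      return(NULL)
    }
    tab <- sort(table(members), decreasing = TRUE)
    h <- 100 * as.numeric(tab[1L]) / length(members)
    data.frame(cluster = cl, size = length(members),
               modal_label = names(tab)[1L],
               homogeneity = h,
               homogeneity_pct = as.integer(floor(h + 0.5)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariate-normal confidence ellipse of a score cloud
#'
#' Center at the mean; axes along the eigenvectors of the 2x2 sample
#' covariance; semi-axis lengths `sqrt(q * lambda_i)` with `q` the
#' chi-squared quantile at the requested confidence with 2 degrees of
#' freedom.
#'
#' @param scores Numeric matrix with 2 columns and at least 3 rows.
#' @param confidence Coverage level (default 0.95).
#' @return A list: `center`, `semi_axes` (major, minor), `angle` (radians,
#'   orientation of the major axis), `axes` (eigenvector matrix),
#'   `degenerate` (`TRUE` when the covariance is singular and the ellipse
#'   collapses to a segment).
#' @export
confidence_ellipse <- function(scores, confidence = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, nrow(scores) >= 3L,
            confidence > 0, confidence < 1)
  center <- colMeans(scores)
  S <- stats::cov(scores)
  ee <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(confidence, df = 2L)
  vals <- pmax(ee$values, 0)
  list(center = center,
       semi_axes = sqrt(q * vals),
       angle = atan2(ee$vectors[2L, 1L], ee$vectors[1L, 1L]),
       axes = ee$vectors,
       degenerate = vals[2L] < .Machine$double.eps * max(vals[1L], 1))
}
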