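#' Dichotomize an intensity matrix
#'
#' Converts intensities into presence/absence calls: a cell becomes 1 iff its
#' intensity exceeds `threshold` (default 0, i.e. any detected peak counts as
#' present — binned absences are true zeros).
#'
#' @param matrix An [intensity_matrix].
#' @param threshold Dichotomization threshold.
#' @return A `binary_matrix`: same structure as the input, values in `{0, 1}`.
#' @export
dichotomize <- function(matrix, threshold = 0) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  out <- intensity_matrix((matrix$values > threshold) + 0, matrix$mz,
                          matrix$meta)
  class(out) <- c("binary_matrix", class(out))
  out
}

#' Binary discriminant t-scores of peaks
#'
#' For every feature and group, the standardized contrast of the regularized
#' in-group presence frequency against the pooled frequency. With `x_jk` the
#' number of group-`k` rows in which feature `j` is present, `n_k` the group
#' size and `n` the total:
#' \deqn{\tilde p_{jk} = (x_{jk} + 0.5) / (n_k + 1), \quad
#'       \tilde p_j = (x_j + 0.5) / (n + 1)}
#' \deqn{t_{jk} = (\tilde p_{jk} - \tilde p_j) /
#'       \sqrt{\tilde p_j (1 - \tilde p_j) (1/n_k - 1/n)}}
#' A positive score marks presence of the peak in that group relative to the
#' pool, a negative score absence. The per-feature ranking score is
#' \eqn{S_j = \sum_k t_{jk}^2}. The 0.5 pseudo-count keeps scores finite for
#' all-present / all-absent features.
#'
#' @param binary A `binary_matrix` (see [dichotomize]).
#' @param labels Group assignment per row; defaults to the matrix labels.
#' @return A `peak_ranking` data frame: `mz`, one `t.<group>` column per
#'   group, `score`, and a `selected` flag (all `NA` until
#'   [select_discriminant_peaks] is applied), plus a `threshold` attribute.
#' @export
group_t_scores <- function(binary, labels = NULL) {
  stopifnot(inherits(binary, "binary_matrix"))
  if (is.null(labels)) labels <- binary$meta$label
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(binary$values))
  groups <- sort(unique(labels))
  if (length(groups) < 2L) {
    stop("group_t_scores needs at least 2 groups")
  }
  nk <- table(factor(labels, levels = groups))
  if (any(nk < 2L)) stop("every group needs at least 2 rows")
  n <- nrow(binary$values)
  x <- binary$values
  xj <- colSums(x)
  pj <- (xj + 0.5) / (n + 1)
  tmat <- sapply(groups, function(g) {
    rows <- labels == g
    xjk <- colSums(x[rows, , drop = FALSE])
    pjk <- (xjk + 0.5) / (sum(rows) + 1)
    v <- pj * (1 - pj) * (1 / sum(rows) - 1 / n)
    tt <- (pjk - pj) / sqrt(v)
    tt[!is.finite(tt) | v < .Machine$double.eps] <- 0
    tt
  })
  tmat <- matrix(tmat, ncol = length(groups),
                 dimnames = list(NULL, paste0("t.", groups)))
  out <- data.frame(mz = binary$mz, tmat,
                    score = rowSums(tmat^2),
                    selected = NA,
                    check.names = FALSE)
  attr(out, "groups") <- groups
  class(out) <- c("peak_ranking", "data.frame")
  out
}

#' Select the best discriminating peaks
#'
#' Default rule: a feature is selected when its largest absolute group
#' t-score reaches `threshold` (2.5, the 95%-significance criterion; equality
#' selects). If fewer than 3 features qualify, the `top_n` features by
#' ranking score are taken instead. The result is sorted by descending score.
#'
#' @param ranking A `peak_ranking` from [group_t_scores].
#' @param threshold Absolute t-score cutoff.
#' @param top_n Fallback number of top-ranked features (`NULL` disables the
#'   fallback).
#' @return The ranking, sorted by descending `score`, with `selected` filled.
#' @export
select_discriminant_peaks <- function(ranking, threshold = 2.5, top_n = 10L) {
  stopifnot(inherits(ranking, "peak_ranking"))
  if (nrow(ranking) == 0L) stop("empty ranking")
  tcols <- grep("^t\\.", names(ranking), value = TRUE)
  maxabs <- do.call(pmax, c(lapply(ranking[tcols], abs), list(na.rm = TRUE)))
  sel <- maxabs >= threshold
  if (sum(sel) < 3L && !is.null(top_n)) {
    sel <- rank(-ranking$score, ties.method = "first") <= top_n
  }
  out <- ranking
  out$selected <- sel
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- attr(ranking, "groups")
  attr(out, "threshold") <- threshold
  class(out) <- class(ranking)
  out
}
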