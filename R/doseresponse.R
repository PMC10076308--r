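#' Corrected absorbance
#'
#' Background-corrected XTT readout: absorbance at 450 nm minus the 620 nm
#' reference channel. Vectorized.
#'
#' @param ab450,ab620 Absorbance readings.
#' @return `ab450 - ab620`.
#' @export
corrected_absorbance <- function(ab450, ab620) {
  ab450 - ab620
}

#' Metabolic index of an XTT plate
#'
#' For every `(cell_line, concentration)`, the mean corrected absorbance of
#' the treated wells as a percentage of the mean corrected absorbance of the
#' basal (0 concentration) wells of that cell line.
#'
#' @param plate Data frame with columns `cell_line`, `concentration_uM`,
#'   `ab450`, `ab620`, `replicate`; each cell line must have basal
#'   (concentration 0) rows.
#' @return Data frame `cell_line`, `concentration_uM`, `index` (percent),
#'   `n_replicates`, ordered by cell line and concentration.
#' @export
metabolic_index <- function(plate) {
  required <- c("cell_line", "concentration_uM", "ab450", "ab620")
  stopifnot(is.data.frame(plate), all(required %in% names(plate)),
            all(plate$concentration_uM >= 0))
  plate$corrected <- corrected_absorbance(plate$ab450, plate$ab620)
  out <- lapply(split(plate, plate$cell_line), function(p) {
    basal <- p$corrected[p$concentration_uM == 0]
    if (length(basal) == 0L) {
      stop("no basal (0 concentration) wells for cell line ",
           p$cell_line[1L])
    }
    b <- mean(basal)
    if (b <= 0) {
      stop("non-positive basal absorbance for cell line ", p$cell_line[1L])
    }
    agg <- stats::aggregate(corrected ~ concentration_uM, data = p, mean)
    cnt <- stats::aggregate(corrected ~ concentration_uM, data = p, length)
    data.frame(cell_line = p$cell_line[1L],
               concentration_uM = agg$concentration_uM,
               index = 100 * agg$corrected / b,
               n_replicates = cnt$corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$cell_line, out$concentration_uM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Four-parameter log-logistic dose-response function
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))`: lower asymptote `c`,
#' upper asymptote `d`, midpoint (EC50) `e`, Hill coefficient `b` (the curve
#' decreases in `x` for `b > 0`).
#'
#' @param x Concentration (> 0).
#' @param b,c,d,e Model parameters.
#' @return Response values.
#' @export
f4pl <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Fit a four-parameter log-logistic curve
#'
#' Ordinary least squares on the metabolic index over the positive
#' concentrations (the basal 0 anchor is excluded from the log-domain fit:
#' the index is already normalized to it). Initialization is multi-start:
#' the midpoint starts at the geometric median concentration and at every
#' tested concentration, the Hill coefficient at 0.5, 1 and 2; the start
#' with the lowest residual sum of squares wins (ties by first).
#'
#' @param index_table Output of [metabolic_index] (or any data frame with
#'   `cell_line`, `concentration_uM`, `index`).
#' @param cell_line Which cell line to fit.
#' @return An object of class `fourpl_fit`: `b`, `c`, `d`, `e` (EC50),
#'   `rss`, `converged`, `cell_line`, `data`.
#' @export
fit_4pl <- function(index_table, cell_line) {
  stopifnot(all(c("cell_line", "concentration_uM", "index") %in%
                names(index_table)))
  dat <- index_table[index_table$cell_line == cell_line &
                     index_table$concentration_uM > 0, , drop = FALSE]
  x <- dat$concentration_uM
  y <- dat$index
  if (length(unique(x)) < 5L) {
    stop("fit_4pl needs >= 5 distinct positive concentrations for ",
         cell_line)
  }
  e_starts <- unique(c(exp(stats::median(log(x))), sort(unique(x))))
  b_starts <- c(0.5, 1, 2)
  c0 <- max(min(y), 0)
  d0 <- max(y)
  if (d0 <= c0) d0 <- c0 + 1
  best <- NULL
  for (e0 in e_starts) {
    for (b0 in b_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ f4pl(x, b, c, d, e),
          start = list(b = b0, c = c0, d = d0, e = e0),
          lower = c(b = -Inf, c = -Inf, d = -Inf, e = .Machine$double.xmin),
          control = minpack.lm::nls.lm.control(
            maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
        error = function(err) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    out <- list(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_,
                rss = NA_real_, converged = FALSE, cell_line = cell_line,
                data = dat)
    class(out) <- "fourpl_fit"
    return(out)
  }
  cf <- stats::coef(best$fit)
  conv <- isTRUE(best$fit$convInfo$isConv) ||
    best$rss < 1e-8 * max(sum(y^2), 1)
  out <- list(b = unname(cf["b"]), c = unname(cf["c"]), d = unname(cf["d"]),
              e = unname(cf["e"]), rss = best$rss, converged = conv,
              cell_line = cell_line, data = dat)
  class(out) <- "fourpl_fit"
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> %s: b=%.4g c=%.4g d=%.4g EC50=%.4g (rss=%.4g, %s)\n",
    x$cell_line, x$b, x$c, x$d, x$e, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration_uM else
    if (is.data.frame(newdata)) newdata$concentration_uM else newdata
  f4pl(x, object$b, object$c, object$d, object$e)
}

#' EC50 of a fit
#'
#' The midpoint parameter `e` of the four-parameter log-logistic model: the
#' concentration at which the response is halfway between the fitted maximum
#' and minimum.
#'
#' @param fit A `fourpl_fit`.
#' @return EC50 in the concentration units of the fit.
#' @export
ec50 <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  fit$e
}

#' IC50 from a fitted curve
#'
#' The concentration at which the fitted metabolic index equals 50% of
#' control, obtained by inverting the model analytically:
#' `x = e * ((d - 50) / (50 - c))^(1/b)`. When the 50% level lies outside
#' the open interval between the fitted asymptotes the curve never reaches
#' half-inhibition and `NaN` is returned (a value, not an error).
#'
#' @param fit A converged `fourpl_fit`.
#' @return IC50 in concentration units, or `NaN`.
#' @export
ic50_from_fit <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!isTRUE(fit$converged)) return(NaN)
  lo <- min(fit$c, fit$d)
  hi <- max(fit$c, fit$d)
  if (!(50 > lo && 50 < hi)) return(NaN)
  fit$e * ((fit$d - 50) / (50 - fit$c))^(1 / fit$b)
}

#' Potency summary over fitted cell lines
#'
#' @param fits A list of `fourpl_fit` objects.
#' @param reference Optional character vector of reference cell lines; a
#'   fold-change column `fold_vs_<ref>` (EC50 ratio) is added per reference.
#' @return Data frame with one row per cell line: `EC50`, `IC50`,
#'   `converged`, and fold-change columns.
#' @export
potency_summary <- function(fits, reference = NULL) {
  stopifnot(length(fits) > 0L)
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_line = f$cell_line,
               b = f$b, c = f$c, d = f$d,
               EC50 = f$e, IC50 = ic50_from_fit(f),
               converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  for (ref in reference) {
    eref <- out$EC50[out$cell_line == ref]
    if (length(eref) != 1L) stop("reference cell line not found: ", ref)
    out[[paste0("fold_vs_", ref)]] <- out$EC50 / eref
  }
  class(out) <- c("potency_summary", "data.frame")
  out
}

#' EC50 fold-change between two cell lines
#'
#' @param summary A `potency_summary` (or data frame with `cell_line` and
#'   `EC50`).
#' @param line_a,line_b Cell-line names; the result is
#'   `EC50(line_a) / EC50(line_b)`.
#' @return The EC50 ratio; `NaN` (with a warning) when either EC50 is not
#'   finite.
#' @export
fold_change <- function(summary, line_a, line_b) {
  stopifnot(all(c("cell_line", "EC50") %in% names(summary)))
  ea <- summary$EC50[summary$cell_line == line_a]
  eb <- summary$EC50[summary$cell_line == line_b]
  if (length(ea) != 1L || length(eb) != 1L) {
    stop("cell line not found in summary")
  }
  if (!is.finite(ea) || !is.finite(eb)) {
    warning("fold_change: non-finite EC50 for ", line_a, " or ", line_b)
    return(NaN)
  }
  ea / eb
}
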