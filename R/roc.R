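#' ROC curve from continuous decision scores
#'
#' Standard threshold sweep over the unique score values; tied scores step
#' diagonally (simultaneous TP/FP step), and the AUC is the trapezoidal
#' area, which equals the Mann-Whitney pairwise count with ties counted
#' one half.
#'
#' @param scores Numeric decision scores, higher = more positive.
#' @param labels Binary labels.
#' @param positive Label value treated as positive; default the second
#'   factor level.
#' @return An object of class \code{roc_curve} with \code{fpr}, \code{tpr}
#'   (from (0,0) to (1,1)) and \code{auc}.
#' @export
roc_from_scores <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("both classes must be present", call. = FALSE)
  if (nlevels(labels) > 2L) stop("'labels' must be binary", call. = FALSE)
  if (is.null(positive)) positive <- levels(labels)[2]
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- is_pos[ord]
  ## collapse tied scores into single simultaneous steps
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  fpr <- c(0, fp / n_neg); tpr <- c(0, tp / n_pos)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, length(x$fpr)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

## step-function TPR of a curve at arbitrary FPR values:
## tpr(f) = max{ tpr_i : fpr_i <= f }
roc_tpr_at <- function(curve, f) {
  idx <- findInterval(f, curve$fpr)
  curve$tpr[pmax(idx, 1L)]
}

#' Vertical averaging of ROC curves
#'
#' Interpolates every curve's TPR (step-function convention) on a fixed
#' FPR grid and averages across curves, the standard way of summarizing
#' the ROC over repeated cross-validation; the per-grid-point SD is the
#' population SD across curves.
#'
#' @param curves Non-empty list of \code{roc_curve} objects.
#' @param grid_size Number of evenly spaced FPR grid points (default 101).
#' @return An object of class \code{averaged_roc} with \code{fpr_grid},
#'   \code{mean_tpr}, \code{sd_tpr}, \code{n_curves} and \code{mean_auc}
#'   (trapezoidal area of the averaged curve).
#' @export
vertical_average <- function(curves, grid_size = 101L) {
  if (length(curves) == 0L) stop("'curves' must be non-empty", call. = FALSE)
  fgrid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(curves, roc_tpr_at, numeric(grid_size), f = fgrid)
  tprs <- matrix(tprs, nrow = grid_size)
  mean_tpr <- rowMeans(tprs)
  sd_tpr <- sqrt(rowMeans(tprs^2) - mean_tpr^2)
  sd_tpr[sd_tpr < 0 | is.na(sd_tpr)] <- 0
  mean_auc <- sum(diff(fgrid) * (mean_tpr[-1] + mean_tpr[-grid_size]) / 2)
  structure(list(fpr_grid = fgrid, mean_tpr = mean_tpr, sd_tpr = sd_tpr,
                 n_curves = length(curves), mean_auc = mean_auc),
            class = "averaged_roc")
}

#' @export
print.averaged_roc <- function(x, ...) {
  cat(sprintf("averaged_roc: %d curves on %d-point FPR grid, AUC of mean curve = %.4f\n",
              x$n_curves, length(x$fpr_grid), x$mean_auc))
  invisible(x)
}

#' @export
plot.averaged_roc <- function(x, band = TRUE, ...) {
  plot(x$fpr_grid, x$mean_tpr, type = "l", lwd = 2,
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Vertically averaged ROC (%d curves)", x$n_curves), ...)
  if (band) {
    lo <- pmax(0, x$mean_tpr - x$sd_tpr)
    hi <- pmin(1, x$mean_tpr + x$sd_tpr)
    graphics::polygon(c(x$fpr_grid, rev(x$fpr_grid)), c(lo, rev(hi)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(x$fpr_grid, x$mean_tpr, lwd = 2)
  }
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Mean and SD of the summary metrics for one grid combination
#'
#' Arithmetic means and sample SDs of AUC/ACC/SPEC/SENS over the valid
#' repetitions.
#'
#' @param result An \code{rhst_experiment}.
#' @param combo Grid column index.
#' @return Numeric matrix with rows AUC/ACC/SPEC/SENS and columns
#'   mean/sd.
#' @export
summarize_metrics <- function(result, combo) {
  if (combo < 1L || combo > ncol(result$auc)) stop("no such combo", call. = FALSE)
  ok <- result$valid & !is.na(result$auc[, combo])
  if (!any(ok)) stop("no valid repetitions for this combo", call. = FALSE)
  vals <- cbind(AUC = result$auc[ok, combo], ACC = result$acc[ok, combo],
                SPEC = result$spec[ok, combo], SENS = result$sens[ok, combo])
  out <- cbind(mean = colMeans(vals, na.rm = TRUE),
               sd = apply(vals, 2, stats::sd, na.rm = TRUE))
  out
}

#' Test whether an AUC sample beats chance
#'
#' One-sided nonparametric location test of repetition AUCs against the
#' chance value 0.5. The default is the Wilcoxon signed-rank test of
#' (AUC - 0.5), the coherent one-sample form of the comparison; a literal
#' two-sample rank-sum against a degenerate sample of 0.5s is available as
#' \code{method = "rank-sum"}. Repetition AUCs from repeated holdout share
#' subjects and are therefore not independent; the p-value does not adjust
#' for that dependence.
#'
#' @param auc_samples Numeric vector of repetition AUCs (>= 10).
#' @param method \code{"signed-rank"} (default) or \code{"rank-sum"}.
#' @param chance Chance level (default 0.5).
#' @return The one-sided p-value; attribute \code{degenerate} is TRUE when
#'   all samples equal the chance value (p = 1, no evidence).
#' @export
auc_vs_chance <- function(auc_samples, method = c("signed-rank", "rank-sum"),
                          chance = 0.5) {
  method <- match.arg(method)
  auc_samples <- auc_samples[!is.na(auc_samples)]
  if (length(auc_samples) < 10L) stop("need >= 10 AUC samples", call. = FALSE)
  if (all(auc_samples == chance))
    return(structure(1, degenerate = TRUE))
  p <- if (method == "signed-rank") {
    suppressWarnings(stats::wilcox.test(auc_samples, mu = chance,
                                        alternative = "greater",
                                        exact = FALSE, correct = TRUE)$p.value)
  } else {
    suppressWarnings(stats::wilcox.test(auc_samples,
                                        rep(chance, length(auc_samples)),
                                        alternative = "greater",
                                        exact = FALSE, correct = TRUE)$p.value)
  }
  structure(p, degenerate = FALSE)
}
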