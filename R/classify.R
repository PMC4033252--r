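#' Feature budget under the N/10 rule
#'
#' The number of features fed to the classifier is capped at one tenth of
#' the pooled sample size of the binary problem, \code{K = floor(N / 10)},
#' to keep the dimensionality in check: 80 subjects allow 8 features,
#' 74 allow 7.
#'
#' @param n_total Pooled sample size of the binary comparison (>= 10).
#' @return Integer K.
#' @export
kmax <- function(n_total) {
  if (!is.numeric(n_total) || length(n_total) != 1L || is.na(n_total) ||
      n_total < 10)
    stop("'n_total' must be >= 10 (no features selectable under the N/10 rule)",
         call. = FALSE)
  as.integer(floor(n_total / 10))
}

#' Rank features by two-sample T and keep the top K
#'
#' Features are ranked by the absolute pooled-variance two-sample T
#' statistic computed on the training data only, descending; ties (and
#' undefined T from zero pooled variance) are broken by lower column index.
#' Shares its T computation with \code{\link{vertexwise_tmap}}.
#'
#' @param train_features Training subjects x features matrix.
#' @param train_labels Binary labels for the training rows.
#' @param K Number of features to keep (1 <= K <= feature count).
#' @return Integer vector of column indices, in rank order; attribute
#'   \code{n_undefined} counts zero-variance features.
#' @export
select_features <- function(train_features, train_labels, K) {
  X <- as.matrix(train_features)
  lv <- unique(train_labels)
  if (length(lv) != 2L) stop("both classes must be present in training labels",
                             call. = FALSE)
  if (K < 1L) stop("'K' must be >= 1", call. = FALSE)
  if (K > ncol(X)) stop("'K' exceeds the feature count", call. = FALSE)
  pt <- pooled_t(X[train_labels == lv[1], , drop = FALSE],
                 X[train_labels == lv[2], , drop = FALSE])
  score <- abs(pt$t)
  score[is.na(score)] <- -Inf
  ord <- order(-score, seq_along(score))
  structure(ord[seq_len(K)], n_undefined = pt$n_undefined)
}

#' SVM hyper-parameter grid
#'
#' The standard grid for the RBF-kernel classifier: penalty constants
#' \code{C = 10^m, m = -1..5} (7 values) and kernel widths
#' \code{gamma = 2^n, n = -5..4} (10 values), 70 combinations.
#'
#' @param C_values,gamma_values Override the default ranges.
#' @return Data frame of the combinations, class \code{svm_grid}.
#' @export
svm_grid <- function(C_values = 10^(-1:5), gamma_values = 2^(-5:4)) {
  if (any(C_values <= 0) || any(gamma_values <= 0))
    stop("grid values must be positive", call. = FALSE)
  g <- expand.grid(C = C_values, gamma = gamma_values,
                   KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("svm_grid", "data.frame")
  g
}

#' Repeated stratified holdout split plan
#'
#' Each repetition draws \code{floor(train_fraction * min class size)}
#' subjects from every class for training (so training sets are exactly
#' class-balanced even under cohort imbalance) and uses all remaining
#' subjects as the test set.
#'
#' @param labels Per-subject class labels.
#' @param n_reps Number of repetitions (default 250).
#' @param train_fraction Fraction of the smallest class used per class for
#'   training (default 0.5).
#' @param seed Integer seed.
#' @return An object of class \code{split_plan}: list of repetitions, each
#'   with \code{train} and \code{test} index vectors.
#' @export
rhst_splits <- function(labels, n_reps = 250L, train_fraction = 0.5, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2L)) stop("every class needs >= 2 subjects", call. = FALSE)
  tpc <- as.integer(floor(train_fraction * min(tab)))
  if (tpc < 1L) stop("train_per_class < 1: classes too small", call. = FALSE)
  idx_by_class <- split(seq_along(labels), labels)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      train <- sort(unlist(lapply(idx_by_class, function(ix)
        sample(ix, tpc)), use.names = FALSE))
      list(train = train,
           test = setdiff(seq_along(labels), train))
    })
  })
  structure(list(repetitions = reps, n_reps = as.integer(n_reps),
                 train_per_class = tpc, seed = seed),
            class = "split_plan")
}

## binary classification metrics at decision threshold 0
threshold_metrics <- function(scores, is_pos) {
  pred_pos <- scores > 0
  tp <- sum(pred_pos & is_pos); fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos); fp <- sum(pred_pos & !is_pos)
  c(ACC = (tp + tn) / length(scores),
    SPEC = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    SENS = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Run the full grid-search classification experiment
#'
#' For every repetition of the split plan: features are z-scored with
#' training-set statistics, the top-K features are selected by training-set
#' T ranking, and an RBF-kernel SVM is trained for every (C, gamma) grid
#' point; continuous decision scores on the held-out test set give AUC and,
#' at decision threshold 0, ACC/SPEC/SENS. Test rows never enter scaling,
#' selection or fitting. The second factor level of \code{labels} is the
#' positive class.
#'
#' @param features Subjects x features matrix (e.g. from
#'   \code{\link{patch_means}}).
#' @param labels Binary per-subject labels.
#' @param grid An \code{\link{svm_grid}}.
#' @param splits A \code{\link{rhst_splits}} plan for the same subjects.
#' @param K Features kept per repetition; default \code{kmax(n)}.
#' @param scale Z-score features with training statistics (default TRUE;
#'   RBF kernels are scale-sensitive).
#' @param select_on_all If TRUE, reproduces the leaky variant that ranks
#'   features on the full dataset once (for comparison only; default
#'   FALSE).
#' @return An object of class \code{rhst_experiment} holding per-combo,
#'   per-repetition AUC/ACC/SPEC/SENS, the per-repetition test scores and
#'   labels, selected feature indices, and the flagged-repetition count.
#' @export
run_experiment <- function(features, labels, grid = svm_grid(), splits,
                           K = NULL, scale = TRUE, select_on_all = FALSE) {
  X <- unclass(as.matrix(features))
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("'labels' must be binary", call. = FALSE)
  n <- nrow(X)
  if (max(vapply(splits$repetitions, function(r) max(r$train, r$test), 0)) > n)
    stop("split plan is inconsistent with the feature rows", call. = FALSE)
  if (is.null(K)) K <- kmax(n)
  pos <- levels(y)[2]
  n_comb <- nrow(grid)
  n_reps <- splits$n_reps
  auc <- acc <- spec <- sens <- matrix(NA_real_, n_reps, n_comb)
  scores <- vector("list", n_reps)
  sel_idx <- vector("list", n_reps)
  valid <- rep(TRUE, n_reps)
  global_sel <- if (select_on_all) select_features(X, y, K) else NULL
  for (r in seq_len(n_reps)) {
    sp <- splits$repetitions[[r]]
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
    if (scale) {
      mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0 | is.na(sdv)] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    sel <- if (select_on_all) global_sel else
      tryCatch(select_features(Xtr, ytr, K), error = function(e) NULL)
    if (is.null(sel) || all(!is.finite(Xtr[, sel]))) {
      valid[r] <- FALSE
      next
    }
    sel_idx[[r]] <- as.integer(sel)
    Str <- Xtr[, sel, drop = FALSE]; Ste <- Xte[, sel, drop = FALSE]
    sc <- matrix(NA_real_, length(sp$test), n_comb)
    for (ci in seq_len(n_comb)) {
      fit <- tryCatch(
        e1071::svm(Str, ytr, kernel = "radial", cost = grid$C[ci],
                   gamma = grid$gamma[ci], scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) next
      dtr <- attr(stats::predict(fit, Str, decision.values = TRUE),
                  "decision.values")[, 1]
      ## orient scores so that higher = more positive-class, judged on the
      ## training set only
      flip <- mean(dtr[ytr == pos]) < mean(dtr[ytr != pos])
      dte <- attr(stats::predict(fit, Ste, decision.values = TRUE),
                  "decision.values")[, 1]
      if (flip) dte <- -dte
      sc[, ci] <- dte
      auc[r, ci] <- roc_from_scores(dte, yte, positive = pos)$auc
      m <- threshold_metrics(dte, yte == pos)
      acc[r, ci] <- m["ACC"]; spec[r, ci] <- m["SPEC"]; sens[r, ci] <- m["SENS"]
    }
    if (all(is.na(auc[r, ]))) valid[r] <- FALSE
    scores[[r]] <- sc
  }
  structure(list(grid = grid, auc = auc, acc = acc, spec = spec, sens = sens,
                 scores = scores,
                 test_labels = lapply(splits$repetitions, function(sp) y[sp$test]),
                 selected = sel_idx, valid = valid,
                 n_flagged = sum(!valid), K = K, positive = pos,
                 levels = levels(y), n_subjects = n),
            class = "rhst_experiment")
}

#' @export
print.rhst_experiment <- function(x, ...) {
  best <- select_best(x)
  cat(sprintf("rhst_experiment: %d reps x %d grid combos, K = %d, positive class '%s' (%d flagged reps)\n",
              nrow(x$auc), ncol(x$auc), x$K, x$positive, x$n_flagged))
  cat(sprintf("  best combo: C = %g, gamma = %g, mean AUC = %.3f (sd %.3f)\n",
              best$C, best$gamma, best$metrics["AUC", "mean"],
              best$metrics["AUC", "sd"]))
  invisible(x)
}

#' @export
summary.rhst_experiment <- function(object, ...) {
  best <- select_best(object)
  p <- auc_vs_chance(object$auc[object$valid, best$combo])
  out <- list(best = best, p_vs_chance = p,
              n_reps = nrow(object$auc), K = object$K,
              n_flagged = object$n_flagged)
  class(out) <- "summary.rhst_experiment"
  out
}

#' @export
print.summary.rhst_experiment <- function(x, ...) {
  b <- x$best
  cat(sprintf("Best model (by mean AUC over %d repetitions): K = %d, gamma = %g, C = %g\n",
              x$n_reps, x$K, b$gamma, b$C))
  m <- b$metrics
  cat(sprintf("  AUC  %.2f (sd %.2f)\n  ACC  %.0f%% (sd %.0f)\n  SPEC %.0f%% (sd %.0f)\n  SENS %.0f%% (sd %.0f)\n",
              m["AUC", "mean"], m["AUC", "sd"],
              100 * m["ACC", "mean"], 100 * m["ACC", "sd"],
              100 * m["SPEC", "mean"], 100 * m["SPEC", "sd"],
              100 * m["SENS", "mean"], 100 * m["SENS", "sd"]))
  cat(sprintf("  p (AUC > chance, one-sided signed-rank): %.3g\n", x$p_vs_chance))
  invisible(x)
}

#' @export
plot.rhst_experiment <- function(x, combo = NULL, grid_size = 101L, ...) {
  if (is.null(combo)) combo <- select_best(x)$combo
  av <- vertical_average(experiment_rocs(x, combo), grid_size)
  plot(av, ...)
  invisible(av)
}

#' Per-repetition ROC curves of one grid combination
#' @param result An \code{rhst_experiment}.
#' @param combo Grid column index (e.g. \code{select_best(result)$combo}).
#' @return List of \code{roc_curve} objects, one per valid repetition.
#' @export
experiment_rocs <- function(result, combo) {
  reps <- which(result$valid & !is.na(result$auc[, combo]))
  lapply(reps, function(r)
    roc_from_scores(result$scores[[r]][, combo], result$test_labels[[r]],
                    positive = result$positive))
}

#' Pick the best grid combination by mean AUC
#'
#' Averages AUC over valid repetitions for every (C, gamma) combination and
#' returns the winner; exact ties go to the smaller C, then the smaller
#' gamma.
#'
#' @param result An \code{rhst_experiment}.
#' @return List with \code{combo} (column index), \code{C}, \code{gamma}
#'   and \code{metrics} (mean and SD of AUC/ACC/SPEC/SENS).
#' @export
select_best <- function(result) {
  if (!inherits(result, "rhst_experiment")) stop("not an rhst_experiment", call. = FALSE)
  ok <- result$valid
  if (!any(ok)) stop("no valid repetitions", call. = FALSE)
  mean_auc <- colMeans(result$auc[ok, , drop = FALSE], na.rm = TRUE)
  if (all(is.na(mean_auc))) stop("no valid grid combination", call. = FALSE)
  ord <- order(-mean_auc, result$grid$C, result$grid$gamma)
  combo <- ord[1]
  list(combo = combo, C = result$grid$C[combo], gamma = result$grid$gamma[combo],
       metrics = summarize_metrics(result, combo))
}
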