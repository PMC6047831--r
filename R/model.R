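#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a random positive scores above a random negative, with
#' ties contributing 1/2.
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels logical or 0/1 vector, TRUE = positive
#' @return AUC in [0, 1]
#' @export
compute_auc <- function(scores, labels) {
  y <- as.logical(labels)
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Empirical ROC curve
#'
#' @inheritParams compute_auc
#' @return data.frame with columns fpr, tpr (step curve, including (0,0) and
#'   (1,1))
#' @export
roc_curve <- function(scores, labels) {
  y <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[o]); fp <- cumsum(!y[o])
  # collapse ties: keep the last point of each distinct score
  keep <- c(diff(scores[o]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(!y)), tpr = c(0, tp[keep] / sum(y)))
}

# staircase interpolation of a ROC onto an FPR grid (vertical averaging)
interp_tpr <- function(roc, grid) {
  vapply(grid, function(f) max(roc$tpr[roc$fpr <= f]), 0)
}

#' Training/test sizes of a proportional holdout split
#'
#' @param n number of positives
#' @param train_fraction fraction used for training (default 0.9); the
#'   training set has `floor(train_fraction * n)` members, the remainder is
#'   the test set
#' @return named integer vector (train, test)
#' @export
holdout_split_sizes <- function(n, train_fraction = 0.9) {
  tr <- as.integer(floor(train_fraction * n))
  c(train = tr, test = as.integer(n) - tr)
}

#' L1-penalized logistic regression fit
#'
#' Fits a binomial model with lasso penalty; the penalty is chosen by
#' internal cross-validation on the supplied data (deviance loss), using the
#' one-standard-error rule by default. Features are standardized internally;
#' coefficients are returned on the original feature scale.
#'
#' @param x numeric feature matrix (no missing values)
#' @param y logical or 0/1 labels
#' @param nfolds cross-validation folds (default 5)
#' @param rule `"1se"` (default) or `"min"` penalty selection
#' @return list with intercept, coefficients (named, original scale), lambda
#' @export
fit_l1_logistic <- function(x, y, nfolds = 5L, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2L) stopf("degenerate fit: constant label vector")
  if (anyNA(x)) stopf("missing values in feature matrix")
  cv <- glmnet::cv.glmnet(as.matrix(x), y, family = "binomial", alpha = 1,
                          nfolds = nfolds, type.measure = "deviance",
                          standardize = TRUE)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  b <- as.matrix(stats::coef(cv, s = lam))
  list(intercept = b[1, 1],
       coefficients = stats::setNames(b[-1, 1], rownames(b)[-1]),
       lambda = lam)
}

#' Repeated-holdout L1-logistic dependence model
#'
#' The central fitting routine: classifies factor-dependent (positive)
#' against control (negative) introns from a feature panel with an
#' L1-penalized logistic model under repeated 90/10 holdout. Per repeat, the
#' positives are split into `floor(train_fraction * n_pos)` training and the
#' remaining test introns; control training/test sets of matching sizes are
#' drawn without replacement (and without train/test overlap) from the
#' negatives; features are standardized on the training split (the same
#' transform is applied to its test data); the model is fitted with internal
#' cross-validated lasso penalty selection; held-out introns are scored and
#' the ROC/AUC recorded. Reported are the vertically averaged ROC on a fixed
#' FPR grid, the mean AUC with a 95% confidence interval over repeats, mean
#' coefficients on the standardized scale (comparable across repeats) and
#' per-feature selection frequencies. Alternate positive sets supplied via
#' `alt_sets` are evaluated per repeat with the already-fitted model against
#' the repeat's held-out controls (transfer evaluation).
#'
#' @param x numeric feature matrix with column names, one row per intron
#' @param y logical or 0/1 labels, TRUE = dependent
#' @param n_repeats number of holdout repeats (default 1000)
#' @param train_fraction training fraction (default 0.9)
#' @param seed optional RNG seed for reproducibility
#' @param alt_sets optional named list of feature matrices (same columns) of
#'   alternate positive sets for transfer evaluation
#' @param nfolds,rule passed to [fit_l1_logistic()]'s penalty selection
#' @param fpr_grid number of FPR grid points for ROC averaging (default 101)
#' @return object of class `ir_dependence`
#' @export
ir_dependence <- function(x, y, n_repeats = 1000L, train_fraction = 0.9,
                          seed = NULL, alt_sets = NULL, nfolds = 5L,
                          rule = c("1se", "min"), fpr_grid = 101L) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  if (is.null(colnames(x))) stopf("feature matrix needs column names")
  if (anyNA(x)) stopf("missing values in feature matrix")
  y <- as.logical(y)
  pos <- which(y); neg <- which(!y)
  npos <- length(pos); nneg <- length(neg)
  if (npos < 20L) stopf("need at least 20 positives, got %d", npos)
  if (nneg < npos) stopf("need at least as many negatives as positives")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  sz <- holdout_split_sizes(npos, train_fraction)
  if (sz["test"] < 1L) stopf("test partition is empty")
  p <- ncol(x)
  grid <- seq(0, 1, length.out = fpr_grid)

  coefs <- matrix(0, n_repeats, p + 1L,
                  dimnames = list(NULL, c("(Intercept)", colnames(x))))
  centers <- matrix(0, n_repeats, p); scales <- matrix(1, n_repeats, p)
  aucs <- numeric(n_repeats)
  tprs <- matrix(0, n_repeats, fpr_grid)
  ctrl_scores <- matrix(0, sz["test"], n_repeats)
  alt_aucs <- if (length(alt_sets))
    matrix(0, n_repeats, length(alt_sets),
           dimnames = list(NULL, names(alt_sets))) else NULL

  for (r in seq_len(n_repeats)) {
    tr_pos <- sample(pos, sz["train"])
    te_pos <- setdiff(pos, tr_pos)
    ctrl <- sample(neg, sz["train"] + sz["test"])
    tr_neg <- ctrl[seq_len(sz["train"])]
    te_neg <- ctrl[sz["train"] + seq_len(sz["test"])]

    tr_idx <- c(tr_pos, tr_neg)
    ctr <- colMeans(x[tr_idx, , drop = FALSE])
    scl <- apply(x[tr_idx, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
    xt <- std(x[tr_idx, , drop = FALSE])
    yt <- c(rep(1, length(tr_pos)), rep(0, length(tr_neg)))
    cv <- glmnet::cv.glmnet(xt, yt, family = "binomial", alpha = 1,
                            nfolds = nfolds, type.measure = "deviance",
                            standardize = FALSE)
    lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    b <- as.numeric(as.matrix(stats::coef(cv, s = lam)))

    score <- function(m) drop(b[1] + std(m) %*% b[-1])
    s_pos <- score(x[te_pos, , drop = FALSE])
    s_neg <- score(x[te_neg, , drop = FALSE])
    sc <- c(s_pos, s_neg)
    lab <- c(rep(TRUE, length(s_pos)), rep(FALSE, length(s_neg)))
    aucs[r] <- compute_auc(sc, lab)
    tprs[r, ] <- interp_tpr(roc_curve(sc, lab), grid)
    coefs[r, ] <- b
    centers[r, ] <- ctr; scales[r, ] <- scl
    ctrl_scores[, r] <- s_neg
    if (length(alt_sets)) {
      for (k in seq_along(alt_sets)) {
        a <- as.matrix(alt_sets[[k]])
        if (nrow(a) < sz["test"])
          stopf("alternate set '%s' smaller than the test subsample (%d)",
                names(alt_sets)[k], sz["test"])
        sub <- a[sample(nrow(a), sz["test"]), , drop = FALSE]
        alt_aucs[r, k] <- compute_auc(c(score(sub), s_neg),
                                      c(rep(TRUE, sz["test"]),
                                        rep(FALSE, sz["test"])))
      }
    }
  }

  ci <- 1.96 * stats::sd(aucs) / sqrt(n_repeats)
  structure(list(
    mean_auc = mean(aucs), auc_ci = ci, aucs = aucs,
    mean_roc = data.frame(fpr = grid, tpr = colMeans(tprs)),
    mean_coefficients = colMeans(coefs),
    selection_freq = colMeans(coefs[, -1, drop = FALSE] != 0),
    coefficients = coefs, centers = centers, scales = scales,
    ctrl_scores = ctrl_scores,
    transfer_aucs = if (length(alt_sets)) colMeans(alt_aucs) else NULL,
    transfer_auc_matrix = alt_aucs,
    n_pos = npos, n_neg = nneg, n_train = unname(sz["train"]),
    n_test = unname(sz["test"]), n_repeats = n_repeats,
    train_fraction = train_fraction, feature_names = colnames(x),
    call = match.call()), class = "ir_dependence")
}

#' @export
print.ir_dependence <- function(x, ...) {
  cat("Repeated-holdout L1-logistic dependence model\n")
  cat(sprintf("  %d positives vs %d controls; %d repeats, %d/%d train/test\n",
              x$n_pos, x$n_neg, x$n_repeats, x$n_train, x$n_test))
  cat(sprintf("  mean AUC %.3f (95%% CI +/- %.3f)\n", x$mean_auc, x$auc_ci))
  if (!is.null(x$transfer_aucs)) {
    cat("  transfer AUCs:\n")
    for (k in names(x$transfer_aucs))
      cat(sprintf("    %-24s %.3f\n", k, x$transfer_aucs[k]))
  }
  invisible(x)
}

#' @export
summary.ir_dependence <- function(object, ...) {
  tab <- data.frame(feature = object$feature_names,
                    mean_coefficient =
                      object$mean_coefficients[object$feature_names],
                    selection_freq =
                      object$selection_freq[object$feature_names],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$mean_coefficient)), ]
  rownames(tab) <- NULL
  out <- list(mean_auc = object$mean_auc, auc_ci = object$auc_ci,
              coefficients = tab, transfer_aucs = object$transfer_aucs,
              n_repeats = object$n_repeats)
  class(out) <- "summary.ir_dependence"
  out
}

#' @export
print.summary.ir_dependence <- function(x, ...) {
  cat(sprintf("Mean holdout AUC: %.3f (95%% CI +/- %.3f) over %d repeats\n\n",
              x$mean_auc, x$auc_ci, x$n_repeats))
  cat("Averaged coefficients (standardized scale):\n")
  print(utils::head(x$coefficients, 15), digits = 3)
  invisible(x)
}

#' @export
coef.ir_dependence <- function(object, ...) object$mean_coefficients

#' Predict dependence probabilities with the averaged model
#'
#' Applies the repeat-averaged coefficients (with the repeat-averaged
#' standardization) to new feature rows.
#'
#' @param object an `ir_dependence` fit
#' @param newdata numeric matrix/data.frame with the model's feature columns
#' @param type `"response"` (probability, default) or `"link"`
#' @param ... unused
#' @export
predict.ir_dependence <- function(object, newdata,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  m <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  ctr <- colMeans(object$centers); scl <- colMeans(object$scales)
  z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  b <- object$mean_coefficients
  eta <- drop(b[1] + z %*% b[-1])
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
plot.ir_dependence <- function(x, ...) {
  graphics::plot(x$mean_roc$fpr, x$mean_roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Mean ROC (AUC %.3f)", x$mean_auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Transfer evaluation of a fitted dependence model
#'
#' Re-scores alternate positive sets with the per-repeat models of an
#' existing fit (parameters held fixed): per repeat, `n_test` members of the
#' alternate set are subsampled, standardized with that repeat's training
#' transform, scored, and compared against the repeat's stored held-out
#' control scores.
#'
#' @param fit an `ir_dependence` object
#' @param alt_sets named list of feature matrices sharing the fit's panel
#' @param seed optional RNG seed
#' @return named numeric vector of mean AUCs
#' @export
transfer_evaluate <- function(fit, alt_sets, seed = NULL) {
  if (!inherits(fit, "ir_dependence")) stopf("fit must be an ir_dependence")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(length(alt_sets))
  names(out) <- names(alt_sets)
  nt <- fit$n_test
  for (k in seq_along(alt_sets)) {
    a <- as.matrix(as.data.frame(alt_sets[[k]])[, fit$feature_names,
                                                drop = FALSE])
    if (nrow(a) < nt)
      stopf("alternate set '%s' smaller than the test subsample (%d)",
            names(alt_sets)[k], nt)
    av <- numeric(fit$n_repeats)
    for (r in seq_len(fit$n_repeats)) {
      sub <- a[sample(nrow(a), nt), , drop = FALSE]
      z <- sweep(sweep(sub, 2, fit$centers[r, ]), 2, fit$scales[r, ], "/")
      b <- fit$coefficients[r, ]
      s <- drop(b[1] + z %*% b[-1])
      av[r] <- compute_auc(c(s, fit$ctrl_scores[, r]),
                           c(rep(TRUE, nt), rep(FALSE, nt)))
    }
    out[k] <- mean(av)
  }
  out
}

#' Single-feature discrimination analysis
#'
#' Under the same repeated-holdout scheme as [ir_dependence()], fits an
#' unpenalized one-feature logistic model per feature per repeat, records the
#' test AUC and the fraction of the training null deviance reduced by the
#' feature, and averages over repeats. Features constant within a training
#' split contribute AUC 0.5 and reduction 0 and are flagged.
#'
#' @inheritParams ir_dependence
#' @return data.frame: feature, mean_auc, auc_ci, mean_deviance_reduction,
#'   deviance_ci, flagged
#' @export
single_feature_analysis <- function(x, y, n_repeats = 1000L,
                                    train_fraction = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  y <- as.logical(y)
  pos <- which(y); neg <- which(!y)
  npos <- length(pos)
  sz <- holdout_split_sizes(npos, train_fraction)
  p <- ncol(x)
  auc <- matrix(NA_real_, n_repeats, p)
  dev <- matrix(NA_real_, n_repeats, p)
  flagged <- rep(FALSE, p)
  for (r in seq_len(n_repeats)) {
    tr_pos <- sample(pos, sz["train"]); te_pos <- setdiff(pos, tr_pos)
    ctrl <- sample(neg, sz["train"] + sz["test"])
    tr_neg <- ctrl[seq_len(sz["train"])]
    te_neg <- ctrl[sz["train"] + seq_len(sz["test"])]
    tr <- c(tr_pos, tr_neg); te <- c(te_pos, te_neg)
    ytr <- c(rep(1, length(tr_pos)), rep(0, length(tr_neg)))
    yte <- c(rep(TRUE, length(te_pos)), rep(FALSE, length(te_neg)))
    for (j in seq_len(p)) {
      xj <- x[tr, j]
      if (stats::sd(xj) == 0) {
        auc[r, j] <- 0.5; dev[r, j] <- 0; flagged[j] <- TRUE
        next
      }
      fit <- stats::glm.fit(cbind(1, xj), ytr, family = stats::binomial())
      bb <- fit$coefficients
      auc[r, j] <- compute_auc(bb[1] + bb[2] * x[te, j], yte)
      dev[r, j] <- (fit$null.deviance - fit$deviance) / fit$null.deviance
    }
  }
  data.frame(
    feature = colnames(x),
    mean_auc = colMeans(auc),
    auc_ci = 1.96 * apply(auc, 2, stats::sd) / sqrt(n_repeats),
    mean_deviance_reduction = colMeans(dev),
    deviance_ci = 1.96 * apply(dev, 2, stats::sd) / sqrt(n_repeats),
    flagged = flagged, stringsAsFactors = FALSE)
}
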