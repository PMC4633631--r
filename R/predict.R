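#' Prediction configuration
#'
#' @param thresholds Decreasing p-value thresholds for selecting SNP
#'   predictors from the training-fold GWAS (defaults: 1e-5 ... 1e-9).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param cost Linear-SVM cost parameter (default 1).
#' @param class_weights Use inverse-frequency class weights (default TRUE;
#'   essential with control:case ratios far from 1).
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `prediction_config`.
#' @export
prediction_config <- function(thresholds = c(1e-5, 1e-6, 1e-7, 1e-8, 1e-9),
                              n_folds = 10L, cost = 1.0,
                              class_weights = TRUE, seed = 1L) {
  if (is.unsorted(rev(thresholds)))
    stop("thresholds must be decreasing", call. = FALSE)
  if (n_folds < 2) stop("need at least 2 folds", call. = FALSE)
  structure(list(thresholds = thresholds, n_folds = as.integer(n_folds),
                 cost = cost, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "prediction_config")
}

#' Area under the ROC curve by the rank statistic
#'
#' The probability that a randomly chosen case receives a higher score than
#' a randomly chosen control, with ties counted one half (the
#' Wilcoxon-Mann-Whitney form of the AUC).
#'
#' @param decision_values Numeric scores.
#' @param labels Binary labels (1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(decision_values, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(decision_values)            # average ranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated linear-SVM disease prediction from top GWAS SNPs
#'
#' Stratified k-fold cross-validation with strict leakage control: in each
#' fold the GWAS, the SNP selection at every p-value threshold, the
#' mean-imputation and the feature standardization are all fitted on the
#' training folds only. A linear SVM (inverse-frequency class weights by
#' default) is trained per threshold and its decision values are scored on
#' the held-out fold by the rank AUC. Cells where a threshold selects no
#' SNPs are recorded as missing rather than failing.
#'
#' @param geno Post-QC [genotype_data()] object.
#' @param case_status Binary vector (1 = case).
#' @param config A [prediction_config()] object.
#' @param covariates Optional covariates passed to the per-fold GWAS.
#' @return Object of class `prediction_result`: `folds` (data frame:
#'   threshold, fold, n_snps, auc), `auc_mean`, `auc_max`, and the
#'   per-threshold mean AUCs.
#' @export
cv_svm_predict <- function(geno, case_status,
                           config = prediction_config(),
                           covariates = NULL) {
  stopifnot(inherits(geno, "genotype_data"))
  y <- as.integer(case_status)
  n <- length(y)
  set.seed(config$seed)
  fold <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(config$n_folds), length(idx))
  }

  rows <- list()
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f; te <- !tr
    if (sum(y[te] == 1L) == 0 || sum(y[te] == 0L) == 0) next
    gw <- gwas_logistic(subset_geno(geno, i = which(tr)), y[tr],
                        covariates = if (is.null(covariates)) NULL
                                     else covariates[tr, , drop = FALSE])
    pv <- gw$table$p
    for (th in config$thresholds) {
      sel <- which(!is.na(pv) & pv < th)
      if (length(sel) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          threshold = th, fold = f, n_snps = 0L, auc = NA_real_)
        next
      }
      Xtr <- geno$dosage[tr, sel, drop = FALSE]
      Xte <- geno$dosage[te, sel, drop = FALSE]
      mu <- colMeans(Xtr, na.rm = TRUE)
      for (jj in seq_along(sel)) {
        Xtr[is.na(Xtr[, jj]), jj] <- mu[jj]
        Xte[is.na(Xte[, jj]), jj] <- mu[jj]
      }
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
      wts <- if (config$class_weights) {
        tab <- table(factor(y[tr], levels = c(0, 1)))
        w <- as.numeric(sum(tab) / (2 * tab)); names(w) <- c("0", "1"); w
      } else NULL
      fit <- e1071::svm(Xtr, factor(y[tr], levels = c(0, 1)),
                        kernel = "linear", cost = config$cost,
                        class.weights = wts, scale = FALSE)
      dvm <- attr(stats::predict(fit, Xte, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # orient decision values so that larger = more case-like
      if (colnames(dvm)[1] == "0/1") dv <- -dv
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, fold = f, n_snps = length(sel),
        auc = auc(dv, y[te]))
    }
  }
  folds <- do.call(rbind, rows)
  ok <- !is.na(folds$auc)
  if (!any(ok)) warning("no threshold selected any SNPs in any fold")
  by_th <- tapply(folds$auc[ok], folds$threshold[ok], mean)
  structure(list(folds = folds,
                 auc_mean = if (any(ok)) mean(folds$auc[ok]) else NA_real_,
                 auc_max = if (any(ok)) max(folds$auc[ok]) else NA_real_,
                 auc_by_threshold = by_th),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("SVM prediction: AUC mean %.3f, max %.3f over %d cells\n",
              x$auc_mean, x$auc_max, sum(!is.na(x$folds$auc))))
  invisible(x)
}
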