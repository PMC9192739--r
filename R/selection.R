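## Bootstrap-LASSO stability selection of protein predictors, and ROC/AUC
## comparison of nested logistic prediction models.

#' Bootstrap-LASSO stability selection
#'
#' Approximates the sampling distribution of L1-penalized logistic
#' regression coefficients by the nonparametric bootstrap: in each of B
#' iterations, subjects are resampled with replacement and a LASSO logistic
#' model of the outcome on all analytes is fitted with age and sex left
#' unpenalized (per-feature penalty factor 0).
#' The penalty is chosen per replicate by 10-fold cross-validated deviance;
#' the default penalty rule is the one-standard-error rule, which keeps the
#' per-replicate models parsimonious so that stability fractions separate
#' signal from noise (the minimum-loss rule is available but admits many
#' noise analytes per replicate).
#' Results are summarized per analyte as the fraction of iterations with a
#' non-zero coefficient, the mean coefficient, and the 2.5%/97.5%
#' coefficient quantiles; analytes at or above the selection-fraction
#' threshold are flagged selected. Replicates in which the resample contains
#' a single outcome class are redrawn (logged); subjects with any missing
#' analyte value are excluded up front (complete-case). One master seed
#' derives per-replicate seeds deterministically, so runs are reproducible
#' and selection fractions are invariant to analyte column order.
#'
#' @param proteins transformed-state \linkS4class{ProteinMatrix}.
#' @param phen phenotype table.
#' @param outcome outcome label (both classes must be present).
#' @param covariates character subset of c("age", "sex"); always included,
#'   never penalized, never reported as selectable analytes.
#' @param B bootstrap iterations (>= 2; 500 in a full analysis).
#' @param threshold selection fraction flagging an analyte as selected
#'   (default 0.8).
#' @param lambdaRule per-replicate penalty choice: \code{"1se"} (default)
#'   or \code{"min"}.
#' @param seed master seed.
#' @return data.frame of selection records: \code{analyte}, \code{fraction},
#'   \code{meanCoef}, \code{q025}, \code{q975}, \code{selected}; number of
#'   redrawn replicates attached as attribute \code{"redraws"}.
#' @export
bootstrapLasso <- function(proteins, phen, outcome,
                           covariates = c("age", "sex"), B = 500,
                           threshold = 0.8, seed = 1,
                           lambdaRule = c("1se", "min")) {
  lambdaRule <- match.arg(lambdaRule)
  stopifnot(is(proteins, "ProteinMatrix"), B >= 2)
  y <- outcomeIndicator(phen, outcome)
  X <- assayValues(proteins)
  C <- covariateDesign(phen, covariates)
  M <- cbind(as.matrix(C), X)
  ok <- !is.na(y) & complete.cases(M)
  M <- M[ok, , drop = FALSE]
  y <- y[ok]
  if (length(unique(y)) < 2) stop("outcome must have both classes present")
  nCov <- if (is.null(C)) 0L else ncol(C)
  pf <- c(rep(0, nCov), rep(1, ncol(X)))
  analytes <- colnames(X)
  coefMat <- matrix(0, B, length(analytes), dimnames = list(NULL, analytes))
  n <- nrow(M)
  redraws <- 0L
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0L
    while (length(unique(y[idx])) < 2) {
      redraws <- redraws + 1L
      tries <- tries + 1L
      if (tries > 100L) stop("bootstrap resampling repeatedly produced a single outcome class")
      idx <- sample.int(n, n, replace = TRUE)
    }
    cv <- glmnet::cv.glmnet(M[idx, , drop = FALSE], y[idx],
                            family = "binomial", penalty.factor = pf,
                            nfolds = 10)
    cf <- as.numeric(coef(cv, s = paste0("lambda.", lambdaRule)))[-1]  # drop intercept
    coefMat[b, ] <- cf[(nCov + 1):length(cf)]
  }
  if (redraws > 0L)
    message(redraws, " bootstrap replicate(s) redrawn for single-class resamples")
  out <- data.frame(
    analyte = analytes,
    fraction = colMeans(coefMat != 0),
    meanCoef = colMeans(coefMat),
    q025 = apply(coefMat, 2, quantile, probs = 0.025, type = 7),
    q975 = apply(coefMat, 2, quantile, probs = 0.975, type = 7),
    stringsAsFactors = FALSE)
  out$selected <- out$fraction >= threshold
  rownames(out) <- NULL
  attr(out, "redraws") <- redraws
  out
}

#' ROC area under the curve with confidence interval
#'
#' AUC as the tie-corrected rank (Mann-Whitney) statistic, with a DeLong
#' 95% confidence interval.
#'
#' @param scores numeric predictor scores.
#' @param labels binary labels (0/1).
#' @return list: \code{auc}, \code{ci} (length-2), \code{n1}, \code{n0}.
#' @export
rocAuc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<", levels = c(0, 1))
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), ci = ci[c(1, 3)],
       n1 = sum(labels == 1), n0 = sum(labels == 0))
}

#' Compare nested logistic prediction models by AUC
#'
#' Fits a base and an augmented logistic model (the augmented predictor set
#' must contain the base set), computes both AUCs on the common complete-
#' case data, and tests the paired AUC difference with a stratified
#' bootstrap of the two correlated ROC curves.
#'
#' @param base,augmented character vectors of predictor column names.
#' @param data data.frame holding the outcome and all predictors.
#' @param outcomeCol name of the binary outcome column.
#' @param bootN bootstrap resamples for the AUC-difference test (default
#'   2000).
#' @param seed RNG seed for the bootstrap test.
#' @return list of class \code{roc_comparison}: \code{aucBase},
#'   \code{aucAugmented} (each with DeLong CI), \code{diff}, \code{p},
#'   \code{base}, \code{augmented}.
#' @export
compareModels <- function(base, augmented, data, outcomeCol = "y",
                          bootN = 2000, seed = 1) {
  if (!all(base %in% augmented))
    stop("augmented model must nest the base model")
  cols <- unique(c(outcomeCol, augmented))
  d <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  y <- d[[outcomeCol]]
  fml <- function(preds) as.formula(paste(
    outcomeCol, "~", if (length(preds)) paste(preds, collapse = "+") else "1"))
  fitB <- glm(fml(base), data = d, family = binomial())
  fitA <- glm(fml(augmented), data = d, family = binomial())
  sB <- predict(fitB, type = "link")
  sA <- predict(fitA, type = "link")
  rB <- pROC::roc(y, sB, quiet = TRUE, direction = "<", levels = c(0, 1))
  rA <- pROC::roc(y, sA, quiet = TRUE, direction = "<", levels = c(0, 1))
  aucB <- as.numeric(pROC::auc(rB)); aucA <- as.numeric(pROC::auc(rA))
  if (identical(sort(base), sort(augmented))) {
    p <- 1
  } else {
    set.seed(seed)
    p <- pROC::roc.test(rA, rB, method = "bootstrap", boot.n = bootN,
                        boot.stratified = TRUE, paired = TRUE)$p.value
  }
  out <- list(aucBase = aucB, ciBase = as.numeric(pROC::ci.auc(rB, method = "delong"))[c(1, 3)],
              aucAugmented = aucA,
              ciAugmented = as.numeric(pROC::ci.auc(rA, method = "delong"))[c(1, 3)],
              diff = aucA - aucB, p = p, base = base, augmented = augmented)
  class(out) <- "roc_comparison"
  out
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC base = %.3f [%.3f, %.3f]; augmented = %.3f [%.3f, %.3f]\n",
              x$aucBase, x$ciBase[1], x$ciBase[2],
              x$aucAugmented, x$ciAugmented[1], x$ciAugmented[2]))
  cat(sprintf("difference = %.3f, bootstrap P = %.3g\n", x$diff, x$p))
  invisible(x)
}
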