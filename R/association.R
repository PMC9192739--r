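## Protein-outcome association stage: study-wide logistic screening,
## quantile profiling, module enrichment, eigenprotein analysis.

covariateDesign <- function(phen, covariates) {
  out <- list()
  if ("age" %in% covariates) out$age <- phen$age
  if ("sex" %in% covariates) out$sex <- as.numeric(phen$sex == "F")
  if (length(out)) as.data.frame(out) else NULL
}

#' Study-wide logistic protein screen
#'
#' Sex- and age-adjusted logistic regression of a staged disease outcome on
#' each analyte (one model per analyte, case-wise deletion of missing
#' values). The multiple-testing unit is the number of unique gene symbols,
#' not analytes: the study-wide significance threshold is 0.05 / (gene
#' count) and the adjusted P is the Bonferroni value min(1, P x gene count).
#' With 4137 unique genes the threshold is 1.21e-5.
#'
#' @param proteins transformed-state \linkS4class{ProteinMatrix}.
#' @param phen phenotype table (see \code{\link{simulateOutcome}}).
#' @param outcome outcome label understood by \code{\link{outcomeIndicator}}.
#' @param covariates character subset of c("age", "sex").
#' @return data.frame with one row per analyte: \code{analyte}, \code{gene},
#'   \code{outcome}, \code{beta} (log OR per SD), \code{se}, \code{p},
#'   \code{padj}, \code{significant}, \code{nCase}, \code{nCtrl},
#'   \code{converged}; the threshold used is attached as attribute
#'   \code{"threshold"}.
#' @export
logisticScreen <- function(proteins, phen, outcome,
                           covariates = c("age", "sex")) {
  stopifnot(is(proteins, "ProteinMatrix"))
  if (transformState(proteins) != "transformed")
    stop("logisticScreen expects transformed proteins")
  y <- outcomeIndicator(phen, outcome)
  if (sum(y == 1, na.rm = TRUE) < 2)
    stop("outcome '", outcome, "' has fewer than 2 cases")
  X <- assayValues(proteins)
  ann <- analyteInfo(proteins)
  C <- covariateDesign(phen, covariates)
  nGenes <- length(unique(ann$gene))
  thr <- 0.05 / nGenes
  res <- data.frame(analyte = ann$analyte, gene = ann$gene, outcome = outcome,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    padj = NA_real_, significant = NA, nCase = NA_integer_,
                    nCtrl = NA_integer_, converged = NA,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    d <- data.frame(y = y, x = X[, j])
    if (!is.null(C)) d <- cbind(d, C)
    d <- d[complete.cases(d), , drop = FALSE]
    if (sd(d$x) == 0) { res$converged[j] <- FALSE; next }
    fit <- suppressWarnings(glm(y ~ ., data = d, family = binomial()))
    sm <- coef(summary(fit))
    res$beta[j] <- sm["x", 1]
    res$se[j] <- sm["x", 2]
    res$p[j] <- sm["x", 4]
    res$nCase[j] <- sum(d$y == 1)
    res$nCtrl[j] <- sum(d$y == 0)
    ## flag (quasi-)separation: non-convergence or exploding SE
    res$converged[j] <- fit$converged && sm["x", 2] < 50
  }
  res$padj <- pmin(1, res$p * nGenes)
  res$significant <- !is.na(res$p) & res$p < thr
  attr(res, "threshold") <- thr
  attr(res, "nGenes") <- nGenes
  res
}

#' Deterministic near-equal-size quantile bins
#'
#' Ranks with ties broken by stable sample order, then assigns bin
#' \code{ceiling(rank * q / n)}; bin sizes differ by at most one.
#'
#' @param x numeric vector (NA allowed; NA stays NA).
#' @param q number of bins.
#' @return integer bin vector in 1..q.
#' @export
quantileBins <- function(x, q) {
  bins <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "first")
  bins[ok] <- as.integer(ceiling(r * q / sum(ok)))
  bins
}

#' Quantile profile of a protein against a staged outcome
#'
#' Two age/sex-adjusted logistic models on protein quantile bins (quintiles
#' by default, quartiles supported): one treating the bins as a factor (no
#' linearity assumption) and one coding them 1..q as a numeric score. The
#' factor model yields per-bin predicted log-odds (at mean covariate values)
#' with 95% CIs; the continuous model yields a per-bin slope; the top-vs-
#' bottom contrast is the expected marginal difference between the q-th and
#' 1st bins (the q-th bin coefficient against the reference bin, which is
#' exactly 0).
#'
#' @param protein numeric vector of analyte values.
#' @param phen phenotype table.
#' @param outcome outcome label.
#' @param q bin count, 4 or 5.
#' @param covariates character subset of c("age", "sex").
#' @return list of class \code{quantile_profile}: \code{bins} (data.frame of
#'   per-bin predicted log-odds with CIs), \code{slope} (continuous-coded
#'   log OR per bin with CI and P), \code{contrast} (top vs bottom bin with
#'   CI and P), \code{q}.
#' @export
quantileProfile <- function(protein, phen, outcome, q = 5,
                            covariates = c("age", "sex")) {
  if (!q %in% c(4, 5)) stop("q must be 4 or 5")
  if (length(unique(protein[!is.na(protein)])) < q)
    stop("protein has fewer than q distinct values; bins undefined")
  y <- outcomeIndicator(phen, outcome)
  bins <- quantileBins(protein, q)
  C <- covariateDesign(phen, covariates)
  d <- data.frame(y = y, bin = bins)
  if (!is.null(C)) d <- cbind(d, C)
  d <- d[complete.cases(d), , drop = FALSE]
  dFac <- d; dFac$bin <- factor(dFac$bin, levels = seq_len(q))
  fitF <- glm(y ~ ., data = dFac, family = binomial())
  fitC <- glm(y ~ ., data = d, family = binomial())
  V <- vcov(fitF)
  cf <- coef(fitF)
  covMeans <- if (is.null(C)) NULL else colMeans(d[, names(C), drop = FALSE])
  binRows <- lapply(seq_len(q), function(b) {
    ## contrast vector for predicted log-odds of bin b at mean covariates
    cv <- setNames(numeric(length(cf)), names(cf))
    cv["(Intercept)"] <- 1
    if (b > 1) cv[paste0("bin", b)] <- 1
    if (!is.null(covMeans)) cv[names(covMeans)] <- covMeans
    est <- sum(cv * cf)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    data.frame(bin = b, logOdds = est, lo = est - 1.96 * se,
               hi = est + 1.96 * se, n = sum(d$bin == b))
  })
  smF <- coef(summary(fitF))
  top <- paste0("bin", q)
  contrast <- data.frame(estimate = smF[top, 1], se = smF[top, 2],
                         lo = smF[top, 1] - 1.96 * smF[top, 2],
                         hi = smF[top, 1] + 1.96 * smF[top, 2],
                         p = smF[top, 4])
  smC <- coef(summary(fitC))
  slope <- data.frame(estimate = smC["bin", 1], se = smC["bin", 2],
                      lo = smC["bin", 1] - 1.96 * smC["bin", 2],
                      hi = smC["bin", 1] + 1.96 * smC["bin", 2],
                      p = smC["bin", 4])
  out <- list(bins = do.call(rbind, binRows), slope = slope,
              contrast = contrast, q = q, outcome = outcome)
  class(out) <- "quantile_profile"
  out
}

#' @export
print.quantile_profile <- function(x, ...) {
  cat("quantile_profile (", x$q, "bins ) for outcome", x$outcome, "\n")
  print(x$bins, row.names = FALSE)
  cat(sprintf("top-vs-bottom contrast: %.3f [%.3f, %.3f], P = %.3g\n",
              x$contrast$estimate, x$contrast$lo, x$contrast$hi, x$contrast$p))
  invisible(x)
}

#' Module enrichment by Fisher's exact test
#'
#' Two-sided Fisher exact test of whether association hits concentrate in a
#' protein coregulation module, with the sample odds ratio from the 2x2
#' table (hits/non-hits x in/out of module over a stated analyte universe).
#'
#' @param hits character vector of hit analytes (subset of universe).
#' @param module character vector of module analytes (subset of universe).
#' @param universe character vector of all analytes tested.
#' @return list of class \code{enrichment_result}: \code{table} (2x2
#'   counts), \code{or} (sample odds ratio ad/bc), \code{p} (two-sided
#'   Fisher P), \code{degenerate} flag for empty margins.
#' @export
moduleEnrichment <- function(hits, module, universe) {
  if (!all(hits %in% universe) || !all(module %in% universe))
    stop("hits and module must be subsets of the universe")
  a <- length(intersect(hits, module))
  b <- length(setdiff(hits, module))
  cc <- length(setdiff(module, hits))
  dd <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, dd), 2, byrow = TRUE,
                dimnames = list(c("hit", "nonhit"), c("inModule", "outModule")))
  degenerate <- length(hits) == 0 || length(module) == 0
  p <- if (degenerate) 1 else fisher.test(tab, alternative = "two.sided")$p.value
  or <- (a * dd) / (b * cc)
  out <- list(table = tab, or = or, p = p, degenerate = degenerate)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: OR = %.3g, Fisher two-sided P = %.3g%s\n",
              x$or, x$p, if (x$degenerate) " (degenerate)" else ""))
  print(x$table)
  invisible(x)
}

#' Eigenprotein (module principal-component) scores
#'
#' First (and second) principal components of a module's standardized
#' abundance sub-matrix, as per-sample scores usable as module-level traits.
#' Loadings have unit norm, and each component's sign is fixed so its score
#' correlates positively with the module mean profile. Samples missing more
#' than half of the module's values get a missing score; remaining missing
#' values are mean-imputed for the decomposition.
#'
#' @param proteins transformed-state \linkS4class{ProteinMatrix}.
#' @param module character vector of analyte ids (>= 2).
#' @param nComp number of components to return (1 or 2).
#' @return list: \code{scores} (samples x components), \code{loadings},
#'   \code{varExplained} (proportion of total variance per component).
#' @export
eigenprotein <- function(proteins, module, nComp = 2) {
  stopifnot(is(proteins, "ProteinMatrix"))
  if (length(module) < 2) stop("module must contain at least 2 analytes")
  X <- assayValues(proteins)[, module, drop = FALSE]
  tooMissing <- rowMeans(is.na(X)) > 0.5
  Xi <- X
  for (j in seq_len(ncol(Xi))) {
    m <- mean(Xi[, j], na.rm = TRUE)
    Xi[is.na(Xi[, j]), j] <- m
  }
  Xc <- scale(Xi, center = TRUE, scale = FALSE)
  fit <- svd(Xc[!tooMissing, , drop = FALSE], nu = 0, nv = nComp)
  loadings <- fit$v
  scores <- Xc %*% loadings
  profile <- rowMeans(Xc)
  for (k in seq_len(nComp)) {
    s <- cor(scores[!tooMissing, k], profile[!tooMissing])
    if (is.na(s)) s <- mean(loadings[, k])
    if (s < 0) { loadings[, k] <- -loadings[, k]; scores[, k] <- -scores[, k] }
  }
  scores[tooMissing, ] <- NA
  totVar <- sum(fit$d^2)
  dimnames(loadings) <- list(module, paste0("PC", seq_len(nComp)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(nComp)))
  list(scores = scores, loadings = loadings,
       varExplained = fit$d[seq_len(nComp)]^2 / totVar)
}
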