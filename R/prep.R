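## Protein preprocessing: per-analyte Box-Cox transformation, scaling, and a
## two-level extreme-outlier exclusion rule.
##
## Quantile convention, used everywhere in this package: linear interpolation
## between order statistics (stats::quantile type 7).

boxcoxLogLik <- function(x, lambda) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum(log(x))
}

## Profile-ML lambda on a fixed grid [-2, 2] step 0.01.
fitBoxcoxLambda <- function(x, grid = seq(-2, 2, by = 0.01)) {
  ll <- vapply(grid, function(l) boxcoxLogLik(x, l), numeric(1))
  grid[which.max(ll)]
}

#' Box-Cox transform and scale a protein matrix
#'
#' For each analyte, a Box-Cox power-transform parameter lambda is chosen by
#' profile maximum likelihood on the fixed grid \[-2, 2\] in steps of 0.01
#' (lambda = 0 meaning the log). Nonpositive values are handled by shifting
#' the analyte so its minimum becomes positive (shift = -min + 1e-6 x SD,
#' recorded per analyte). The transformed values are then centred and scaled
#' to mean 0, SD 1 per analyte. The transform is strictly monotone, so
#' within-analyte rank order is preserved. Constant analytes have no defined
#' lambda; they are flagged and passed through centred at 0.
#'
#' @param matrix a raw-state \linkS4class{ProteinMatrix}.
#' @return list with \code{matrix} (transformed-state
#'   \linkS4class{ProteinMatrix}) and \code{report} (a \code{prep_report}:
#'   per-analyte lambda, shift, 99th-percentile cutoff placeholder and
#'   exclusion counts, plus the global outlier threshold once computed).
#' @export
boxcoxTransform <- function(matrix) {
  stopifnot(is(matrix, "ProteinMatrix"))
  if (transformState(matrix) != "raw")
    stop("boxcoxTransform expects a raw-state ProteinMatrix")
  X <- assayValues(matrix)
  rep <- data.frame(analyte = analyteInfo(matrix)$analyte,
                    lambda = NA_real_, shift = 0, q99 = NA_real_,
                    nExcluded = 0L, constant = FALSE,
                    stringsAsFactors = FALSE)
  out <- X
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ok <- !is.na(x)
    if (sd(x[ok]) == 0) {
      rep$constant[j] <- TRUE
      out[ok, j] <- 0
      next
    }
    s <- 0
    if (min(x[ok]) <= 0) {
      s <- -min(x[ok]) + 1e-6 * sd(x[ok])
      x <- x + s
    }
    l <- fitBoxcoxLambda(x[ok])
    y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
    out[, j] <- (y - mean(y, na.rm = TRUE)) / sd(y, na.rm = TRUE)
    rep$lambda[j] <- l
    rep$shift[j] <- s
  }
  pm <- ProteinMatrix(out, analyteInfo(matrix), state = "transformed")
  report <- list(analytes = rep, globalThreshold = NA_real_)
  class(report) <- "prep_report"
  list(matrix = pm, report = report)
}

#' @export
print.prep_report <- function(x, ...) {
  cat("prep_report:", nrow(x$analytes), "analytes;",
      sum(x$analytes$constant), "constant;",
      "global outlier threshold:",
      if (is.na(x$globalThreshold)) "not yet computed"
      else format(x$globalThreshold, digits = 4),
      "; excluded values:", sum(x$analytes$nExcluded), "\n")
  invisible(x)
}

#' Exclude extreme outliers with a two-level percentile rule
#'
#' On the scaled data, each analyte's 99th percentile is computed, and the
#' 99.5th percentile of the distribution of those per-analyte cutoffs is
#' taken as a single global threshold. Values above the global threshold are
#' set to missing, per value: a sample losing one analyte retains all its
#' other analytes. Downstream regressions drop missing values case-wise per
#' model. The threshold is fixed at its first computation and stored in the
#' report, so repeating the exclusion with the same report removes nothing
#' further (idempotence).
#'
#' @param matrix a transformed-state \linkS4class{ProteinMatrix}.
#' @param report the \code{prep_report} from \code{\link{boxcoxTransform}};
#'   if its global threshold has already been computed it is reused rather
#'   than recomputed.
#' @return list with \code{matrix} (values above the threshold set to NA)
#'   and the updated \code{report} (per-analyte cutoffs, global threshold,
#'   per-analyte exclusion counts).
#' @export
excludeOutliers <- function(matrix, report) {
  stopifnot(is(matrix, "ProteinMatrix"))
  if (transformState(matrix) != "transformed")
    stop("excludeOutliers expects a transformed (scaled) ProteinMatrix")
  X <- assayValues(matrix)
  if (ncol(X) < 2)
    stop("global outlier threshold undefined with fewer than 2 analytes")
  q99 <- apply(X, 2, quantile, probs = 0.99, na.rm = TRUE, type = 7)
  report$analytes$q99 <- q99
  if (is.na(report$globalThreshold))
    report$globalThreshold <- as.numeric(
      quantile(q99, probs = 0.995, na.rm = TRUE, type = 7))
  thr <- report$globalThreshold
  drop <- !is.na(X) & X > thr
  X[drop] <- NA
  report$analytes$nExcluded <- report$analytes$nExcluded + colSums(drop)
  list(matrix = ProteinMatrix(X, analyteInfo(matrix), state = "transformed"),
       report = report)
}
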