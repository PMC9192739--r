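#' @import methods
#' @importFrom stats aggregate anova as.formula binomial coef complete.cases
#'   cor cov glm lm glm.fit lm.wfit model.matrix p.adjust pchisq plogis pnorm
#'   pt qlogis qnorm qt quantile rbinom rnorm runif sd setNames uniroot var
#'   vcov fisher.test phyper dhyper predict
#' @importFrom utils head read.delim write.table
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix: samples x variants allele-dosage matrix with variant
## metadata. Dosages live in [0, 2]; effect allele is the counted allele.
## ---------------------------------------------------------------------------

#' GenotypeMatrix: allele dosages with variant metadata
#'
#' Samples-by-variants dosage matrix (values in \[0, 2\], possibly fractional
#' for imputed-style data) together with per-variant metadata: chromosome,
#' position, effect allele (the counted allele), other allele and allele
#' frequency of the effect allele.
#'
#' @slot dosage numeric matrix, samples x variants, dimnames set.
#' @slot variants data.frame with one row per variant and columns
#'   \code{variant}, \code{chrom}, \code{pos}, \code{ea}, \code{oa},
#'   \code{maf}; row order matches the dosage columns.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", variants = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  v <- object@variants
  msg <- character()
  if (ncol(d) != nrow(v))
    msg <- c(msg, "number of dosage columns must equal number of variant rows")
  need <- c("variant", "chrom", "pos", "ea", "oa", "maf")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variant metadata must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(v$variant))
      msg <- c(msg, "variant identifiers must be unique")
    # positions strictly increasing within each chromosome
    for (ch in unique(v$chrom)) {
      p <- v$pos[v$chrom == ch]
      if (length(p) > 1L && any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("positions not strictly increasing on chromosome %s", ch))
        break
      }
    }
  }
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosages must lie within [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage samples x variants numeric matrix with values in \[0, 2\].
#' @param variants data.frame of variant metadata (columns \code{variant},
#'   \code{chrom}, \code{pos}, \code{ea}, \code{oa}, \code{maf}).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$variant
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  rownames(variants) <- variants$variant
  new("GenotypeMatrix", dosage = dosage, variants = variants)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "variants\n")
  cat("  chromosomes:", paste(unique(object@variants$chrom), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ProteinMatrix: samples x analytes abundances with analyte -> gene mapping.
## Multiple analytes may target the same gene (aptamer-style multiplicity).
## ---------------------------------------------------------------------------

#' ProteinMatrix: analyte abundances with gene annotation
#'
#' Samples-by-analytes abundance matrix. Each analyte maps to exactly one
#' gene record (symbol plus locus); several analytes may share a gene. The
#' object carries its transform state: \code{"raw"} before preprocessing,
#' \code{"transformed"} after Box-Cox transformation and scaling.
#'
#' @slot values numeric matrix, samples x analytes.
#' @slot analytes data.frame with columns \code{analyte}, \code{gene},
#'   \code{chrom}, \code{start}, \code{end}; row order matches columns of
#'   \code{values}.
#' @slot state character, \code{"raw"} or \code{"transformed"}.
#'
#' @exportClass ProteinMatrix
setClass("ProteinMatrix",
  representation(values = "matrix", analytes = "data.frame", state = "character"))

setValidity("ProteinMatrix", function(object) {
  msg <- character()
  a <- object@analytes
  if (ncol(object@values) != nrow(a))
    msg <- c(msg, "number of value columns must equal number of analyte rows")
  need <- c("analyte", "gene", "chrom", "start", "end")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("analyte metadata must contain:", paste(need, collapse = ", ")))
  else if (anyDuplicated(a$analyte))
    msg <- c(msg, "analyte identifiers must be unique")
  if (!object@state %in% c("raw", "transformed"))
    msg <- c(msg, "state must be 'raw' or 'transformed'")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinMatrix
#'
#' @param values samples x analytes numeric matrix.
#' @param analytes data.frame of analyte metadata (columns \code{analyte},
#'   \code{gene}, \code{chrom}, \code{start}, \code{end}).
#' @param state transform state, \code{"raw"} (default) or \code{"transformed"}.
#' @return A \linkS4class{ProteinMatrix}.
#' @export
ProteinMatrix <- function(values, analytes, state = "raw") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- analytes$analyte
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  rownames(analytes) <- analytes$analyte
  new("ProteinMatrix", values = values, analytes = analytes, state = state)
}

setMethod("show", "ProteinMatrix", function(object) {
  cat("ProteinMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "analytes (", object@state, ")\n")
  cat("  genes:", length(unique(object@analytes$gene)), "unique symbols\n")
})

## ---------------------------------------------------------------------------
## InstrumentSet: harmonized instruments for one protein.
## ---------------------------------------------------------------------------

#' InstrumentSet: harmonized MR instruments for one protein
#'
#' Holds, for a single analyte, the retained cis instruments with paired
#' exposure/outcome effects expressed for the same effect allele, the signed
#' LD correlation matrix among them, the window-wide significance level
#' \code{pb} used for instrument selection, and the full window exposure
#' statistics (kept for proxy search).
#'
#' @slot analyte analyte identifier.
#' @slot gene one-row data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end}.
#' @slot data data.frame with one row per instrument: \code{variant},
#'   \code{chrom}, \code{pos}, \code{ea}, \code{oa}, \code{betaX},
#'   \code{seX}, \code{pX}, \code{betaY}, \code{seY}, \code{proxyFor}
#'   (NA unless the row substitutes a missing outcome variant).
#' @slot ld signed LD correlation matrix among the instruments.
#' @slot pb window-wide significance level 0.05 / N (N = variants in window).
#' @slot windowStats exposure summary statistics for every window variant.
#' @slot status \code{"ok"} or \code{"no_instruments"}.
#'
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(analyte = "character", gene = "data.frame",
                 data = "data.frame", ld = "matrix", pb = "numeric",
                 windowStats = "data.frame", status = "character"))

setValidity("InstrumentSet", function(object) {
  msg <- character()
  m <- nrow(object@data)
  ld <- object@ld
  if (m > 0L) {
    if (!all(dim(ld) == c(m, m)))
      msg <- c(msg, "LD matrix dimensions must match instrument count")
    else {
      if (max(abs(ld - t(ld))) > 1e-8) msg <- c(msg, "LD matrix must be symmetric")
      if (max(abs(diag(ld) - 1)) > 1e-8) msg <- c(msg, "LD matrix must have unit diagonal")
      if (max(abs(ld)) > 1 + 1e-8) msg <- c(msg, "LD entries must lie in [-1, 1]")
    }
    if (anyDuplicated(object@data$variant))
      msg <- c(msg, "instrument variants must be unique")
  }
  if (!object@status %in% c("ok", "no_instruments"))
    msg <- c(msg, "status must be 'ok' or 'no_instruments'")
  if (length(msg)) msg else TRUE
})

#' Construct an InstrumentSet
#'
#' Usually produced by \code{\link{selectInstruments}} and
#' \code{\link{harmonizeAndProxy}}; the constructor is exported so that
#' instrument sets can also be assembled directly from summary statistics
#' (for example in simulation studies where clumping is not wanted).
#'
#' @param analyte analyte identifier.
#' @param data instrument data.frame (see the class documentation). Columns
#'   \code{betaY}, \code{seY}, \code{proxyFor} are filled with NA when absent.
#' @param ld signed LD correlation matrix (defaults to identity).
#' @param gene one-row gene locus data.frame.
#' @param pb window-wide significance level.
#' @param windowStats exposure statistics for the full cis window.
#' @return An \linkS4class{InstrumentSet}.
#' @export
InstrumentSet <- function(analyte, data, ld = NULL,
                          gene = data.frame(gene = NA_character_,
                                            chrom = NA, start = NA, end = NA),
                          pb = NA_real_, windowStats = data.frame()) {
  for (col in c("betaY", "seY"))
    if (is.null(data[[col]])) data[[col]] <- rep(NA_real_, nrow(data))
  if (is.null(data$proxyFor)) data$proxyFor <- rep(NA_character_, nrow(data))
  m <- nrow(data)
  if (is.null(ld)) ld <- diag(m)
  dimnames(ld) <- list(data$variant, data$variant)
  new("InstrumentSet", analyte = analyte, gene = gene, data = data,
      ld = ld, pb = pb, windowStats = windowStats,
      status = if (m > 0L) "ok" else "no_instruments")
}

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet for", object@analyte, "-", nrow(object@data),
      "instrument(s), status:", object@status, "\n")
  if (nrow(object@data) > 0L) {
    harm <- sum(!is.na(object@data$betaY))
    cat("  harmonized outcome effects:", harm, "/", nrow(object@data), "\n")
  }
})

## ---------------------------------------------------------------------------
## MREstimate: one causal-effect record.
## ---------------------------------------------------------------------------

#' MREstimate: a causal-effect record
#'
#' One Mendelian randomization estimate for one analyte: point estimate,
#' standard error, two-sided P (from the configured null distribution),
#' BH-adjusted P (filled by \code{\link{bhAdjust}} across analytes), the
#' instrument count, residual mean squared error and the SE inflation
#' factor alpha = max(1, sqrt(MSE)), Egger intercept terms where relevant,
#' and the two-step sensitivity-gate status.
#'
#' @slot analyte analyte identifier.
#' @slot method one of \code{"gwls"}, \code{"wald"}, \code{"weighted_median"},
#'   \code{"egger"}.
#' @slot estimate,se,p,fdr numeric scalars (fdr NA until adjusted).
#' @slot m instrument count.
#' @slot mse,alpha residual MSE and SE inflation factor (alpha >= 1).
#' @slot eggerIntercept,eggerInterceptP Egger intercept and its P (NA for
#'   other methods).
#' @slot gate one of \code{"not_tested"}, \code{"failed_step1"},
#'   \code{"failed_step2"}, \code{"causal_candidate"}.
#' @slot nullDist null used for the causal P (\code{"t"} or \code{"normal"}).
#'
#' @exportClass MREstimate
setClass("MREstimate",
  representation(analyte = "character", method = "character",
                 estimate = "numeric", se = "numeric", p = "numeric",
                 fdr = "numeric", m = "numeric", mse = "numeric",
                 alpha = "numeric", eggerIntercept = "numeric",
                 eggerInterceptP = "numeric", gate = "character",
                 nullDist = "character"))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("gwls", "wald", "weighted_median", "egger"))
    msg <- c(msg, "unknown method")
  if (!is.na(object@se) && object@se <= 0) msg <- c(msg, "SE must be positive")
  if (!is.na(object@alpha) && object@alpha < 1) msg <- c(msg, "alpha must be >= 1")
  if (!object@gate %in% c("not_tested", "failed_step1", "failed_step2",
                          "causal_candidate"))
    msg <- c(msg, "unknown gate status")
  if (length(msg)) msg else TRUE
})

MREstimateRecord <- function(analyte, method, estimate, se, p, m,
                             mse = NA_real_, alpha = NA_real_,
                             eggerIntercept = NA_real_,
                             eggerInterceptP = NA_real_,
                             nullDist = "t") {
  new("MREstimate", analyte = analyte, method = method,
      estimate = estimate, se = se, p = p, fdr = NA_real_, m = as.numeric(m),
      mse = mse, alpha = alpha, eggerIntercept = eggerIntercept,
      eggerInterceptP = eggerInterceptP, gate = "not_tested",
      nullDist = nullDist)
}

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] %s: theta = %.4g, SE = %.4g, P = %.3g (M = %d, gate: %s)\n",
              object@method, object@analyte, object@estimate, object@se,
              object@p, as.integer(object@m), object@gate))
  if (object@method == "egger" && !is.na(object@eggerIntercept))
    cat(sprintf("  Egger intercept = %.4g (P = %.3g)\n",
                object@eggerIntercept, object@eggerInterceptP))
})

#' Convert MREstimate objects to a data.frame
#'
#' @param x an \linkS4class{MREstimate} or a list of them.
#' @return data.frame with one row per estimate.
#' @export
mrTable <- function(x) {
  if (is(x, "MREstimate")) x <- list(x)
  do.call(rbind, lapply(x, function(e)
    data.frame(analyte = e@analyte, method = e@method, estimate = e@estimate,
               se = e@se, p = e@p, fdr = e@fdr, m = e@m, mse = e@mse,
               alpha = e@alpha, egger_intercept = e@eggerIntercept,
               egger_intercept_p = e@eggerInterceptP, gate = e@gate,
               null = e@nullDist, stringsAsFactors = FALSE)))
}
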