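## Per-variant additive-model association of genotype dosages with protein
## levels, cis/trans labelling, and export of exposure summary statistics.

#' Classify a variant as cis or trans for a gene
#'
#' A variant is cis when it lies on the gene's chromosome within the closed
#' interval \[start - halfwidth, end + halfwidth\] (1-based inclusive
#' coordinates); otherwise trans. Missing gene coordinates give an
#' undetermined label.
#'
#' @param chrom,pos variant coordinates (vectorized).
#' @param gene list or one-row data.frame with \code{chrom}, \code{start},
#'   \code{end}.
#' @param halfwidth window half-width in bp (default 500 kb, matching the
#'   MR instrument window).
#' @return character vector: \code{"cis"}, \code{"trans"} or
#'   \code{"undetermined"}.
#' @export
classifyCisTrans <- function(chrom, pos, gene, halfwidth = 5e5) {
  if (is.na(gene$chrom) || is.na(gene$start) || is.na(gene$end))
    return(rep("undetermined", length(pos)))
  ifelse(chrom == gene$chrom &
           pos >= gene$start - halfwidth & pos <= gene$end + halfwidth,
         "cis", "trans")
}

#' Genome-wide variant x protein association scan
#'
#' Additive-model linear regression of every analyte on every variant's
#' dosage (used as-is, no hard-calling), adjusted for covariates, with
#' case-wise deletion per analyte. Each record carries a cis/trans label
#' from the analyte's gene locus and a \code{reportable} flag for records
#' below the P threshold. Monomorphic variants are skipped with a message.
#' Output is deterministic and invariant to analyte ordering.
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param proteins transformed-state \linkS4class{ProteinMatrix} sharing
#'   sample ids with the genotypes.
#' @param phen optional phenotype table supplying covariates.
#' @param covariates character subset of c("age", "sex") (ignored when
#'   \code{phen} is NULL).
#' @param pThreshold reporting threshold (default 1e-6).
#' @param windowHalfwidth cis window half-width in bp.
#' @return data.frame of records: \code{analyte}, \code{gene},
#'   \code{variant}, \code{chrom}, \code{pos}, \code{ea}, \code{oa},
#'   \code{beta}, \code{se}, \code{p}, \code{n}, \code{label},
#'   \code{reportable}.
#' @export
snpProteinScan <- function(genotypes, proteins, phen = NULL,
                           covariates = c("age", "sex"), pThreshold = 1e-6,
                           windowHalfwidth = 5e5) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(proteins, "ProteinMatrix"))
  ids <- intersect(rownames(dosage(genotypes)), rownames(assayValues(proteins)))
  if (length(ids) == 0) stop("no shared sample ids between genotypes and proteins")
  D <- dosage(genotypes)[ids, , drop = FALSE]
  X <- assayValues(proteins)[ids, , drop = FALSE]
  v <- variantInfo(genotypes)
  ann <- analyteInfo(proteins)
  C <- if (is.null(phen)) NULL else {
    cd <- covariateDesign(phen[match(ids, phen$sample), , drop = FALSE], covariates)
    if (is.null(cd)) NULL else as.matrix(cd)
  }
  X0 <- cbind(`(Intercept)` = rep(1, length(ids)), C)
  mono <- apply(D, 2, var) == 0
  if (any(mono))
    message("skipping ", sum(mono), " monomorphic variant(s): ",
            paste(v$variant[mono], collapse = ", "))
  keepV <- which(!mono)
  q0 <- qr(X0)
  RG <- qr.resid(q0, D[, keepV, drop = FALSE])
  gss <- colSums(RG^2)
  res <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    y <- X[, j]
    ok <- !is.na(y)
    if (all(ok)) {
      ry <- qr.resid(q0, y)
      bet <- colSums(RG * ry) / gss
      df <- length(y) - ncol(X0) - 1L
      rss <- sum(ry^2) - bet^2 * gss
      se <- sqrt(rss / df / gss)
      nUsed <- rep(length(y), length(keepV))
    } else {
      ## case-wise deletion per analyte: residualize within the subset
      q1 <- qr(X0[ok, , drop = FALSE])
      ry <- qr.resid(q1, y[ok])
      RG1 <- qr.resid(q1, D[ok, keepV, drop = FALSE])
      g1 <- colSums(RG1^2)
      bet <- colSums(RG1 * ry) / g1
      df <- sum(ok) - ncol(X0) - 1L
      rss <- sum(ry^2) - bet^2 * g1
      se <- sqrt(rss / df / g1)
      gss1 <- g1
      nUsed <- rep(sum(ok), length(keepV))
    }
    p <- 2 * pt(-abs(bet / se), df)
    lab <- classifyCisTrans(v$chrom[keepV], v$pos[keepV],
                            ann[j, c("chrom", "start", "end")],
                            halfwidth = windowHalfwidth)
    res[[j]] <- data.frame(
      analyte = ann$analyte[j], gene = ann$gene[j],
      variant = v$variant[keepV], chrom = v$chrom[keepV], pos = v$pos[keepV],
      ea = v$ea[keepV], oa = v$oa[keepV], beta = bet, se = se, p = p,
      n = nUsed, label = lab, reportable = p < pThreshold,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export exposure summary statistics for one analyte
#'
#' Extracts one analyte's records from a \code{\link{snpProteinScan}} result
#' in the standard summary-statistics layout consumed by the MR engine.
#'
#' @param scan result of \code{\link{snpProteinScan}}.
#' @param analyte analyte id.
#' @return data.frame with columns \code{variant}, \code{chrom}, \code{pos},
#'   \code{ea}, \code{oa}, \code{beta}, \code{se}, \code{p}, \code{n}.
#' @export
exposureStats <- function(scan, analyte) {
  s <- scan[scan$analyte == analyte,
            c("variant", "chrom", "pos", "ea", "oa", "beta", "se", "p", "n")]
  rownames(s) <- NULL
  s
}
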