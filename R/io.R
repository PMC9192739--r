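## Plain-text readers/writers for the pipeline's tabular interfaces.

#' Read / write summary statistics TSV
#'
#' The standard layout used throughout: tab-separated with header
#' \code{variant chrom pos ea oa beta se p n}.
#'
#' @param path file path.
#' @return \code{readSummaryStats}: a data.frame in the standard layout.
#' @export
readSummaryStats <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant", "chrom", "pos", "ea", "oa", "beta", "se", "p", "n")
  if (!all(need %in% names(s)))
    stop("summary-statistics file must have columns: ", paste(need, collapse = " "))
  s[, need]
}

#' @rdname readSummaryStats
#' @param stats summary-statistics data.frame.
#' @export
writeSummaryStats <- function(stats, path) {
  need <- c("variant", "chrom", "pos", "ea", "oa", "beta", "se", "p", "n")
  write.table(stats[, need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype dosage matrix as TSV
#'
#' Variant metadata columns first, then one dosage column per sample.
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param path file path.
#' @export
writeDosageTSV <- function(genotypes, path) {
  D <- dosage(genotypes)
  out <- cbind(variantInfo(genotypes), as.data.frame(t(D)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal unphased diploid VCF
#'
#' Dosages are hard-called to GT codes 0/0, 0/1, 1/1 (effect allele as ALT).
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param path file path.
#' @export
writeGenotypesVCF <- function(genotypes, path) {
  D <- dosage(genotypes)
  v <- variantInfo(genotypes)
  gt <- c("0/0", "0/1", "1/1")[pmin(pmax(round(t(D)), 0), 2) + 1]
  gt <- matrix(gt, nrow = ncol(D))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(D)), collapse = "\t")), con)
  body <- cbind(v$chrom, v$pos, v$variant, v$oa, v$ea, ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a protein matrix (and its annotation) as TSV
#'
#' @param proteins \linkS4class{ProteinMatrix}.
#' @param path abundance TSV path (samples x analytes, sample id in first
#'   column).
#' @param annotationPath optional path for the analyte -> gene annotation.
#' @export
writeProteinTSV <- function(proteins, path, annotationPath = NULL) {
  X <- assayValues(proteins)
  out <- data.frame(sample = rownames(X), X, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotationPath))
    write.table(analyteInfo(proteins), annotationPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein matrix from TSV
#'
#' @param path abundance TSV (as written by \code{\link{writeProteinTSV}}).
#' @param annotationPath analyte annotation TSV.
#' @param state transform state of the stored values.
#' @return A \linkS4class{ProteinMatrix}.
#' @export
readProteinTSV <- function(path, annotationPath, state = "raw") {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(d[, -1, drop = FALSE])
  rownames(X) <- d[[1]]
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  ProteinMatrix(X, ann[match(colnames(X), ann$analyte), , drop = FALSE],
                state = state)
}

#' Write / read a preprocessing report as TSV
#'
#' The per-analyte table (lambda, shift, 99th-percentile cutoff, exclusion
#' count, constant flag) with the global outlier threshold stored in a
#' leading comment line, so a written report reloads with its threshold
#' fixed (preserving the idempotence of \code{\link{excludeOutliers}}).
#'
#' @param report a \code{prep_report}.
#' @param path file path.
#' @export
writePrepReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# globalThreshold\t%.15g", report$globalThreshold), con)
  write.table(report$analytes, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePrepReport
#' @export
readPrepReport <- function(path) {
  first <- readLines(path, n = 1)
  thr <- as.numeric(sub("^# globalThreshold\t", "", first))
  report <- list(analytes = read.delim(path, skip = 1,
                                       stringsAsFactors = FALSE),
                 globalThreshold = thr)
  class(report) <- "prep_report"
  report
}

#' Write simulation ground truth as a flat key-value text file
#'
#' @param trueParams the \code{trueParams} element of
#'   \code{\link{simulateCohort}}.
#' @param path file path.
#' @export
writeTrueParams <- function(trueParams, path) {
  lines <- character()
  eff <- trueParams$effects
  if (!is.null(eff) && nrow(eff))
    lines <- c(lines, sprintf("effect\t%s\t%s\t%.10g",
                              eff$protein, eff$variant, eff$beta))
  for (nm in names(trueParams$causalThetas))
    lines <- c(lines, sprintf("theta\t%s\t%.10g", nm,
                              trueParams$causalThetas[[nm]]))
  for (nm in names(trueParams$directSnpEffects))
    lines <- c(lines, sprintf("direct\t%s\t%.10g", nm,
                              trueParams$directSnpEffects[[nm]]))
  lines <- c(lines, sprintf("confounderOutcome\t%.10g",
                            trueParams$confounderOutcome))
  writeLines(lines, path)
  invisible(path)
}
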