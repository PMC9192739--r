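## Two-sample Mendelian randomization for correlated cis instruments:
## instrument selection (cis window, window-wide P threshold, LD clumping),
## harmonization with proxy substitution, generalized weighted least squares
## (GWLS) causal estimation, Wald ratio, weighted-median and MR-Egger
## sensitivity estimators, BH-FDR, and the two-step sensitivity gate.

#' MR engine configuration
#'
#' @param windowHalfwidth cis window half-width in bp around the gene body
#'   (default 500 kb, i.e. a 1 Mb window).
#' @param clumpR2 LD r-squared at/above which variants are clumped together
#'   (default 0.2).
#' @param proxyR2 minimum r-squared for proxy substitution of variants
#'   missing from the outcome set (default 0.8, rule r2 > 0.8).
#' @param fdrLevel BH-FDR level for the causal screen (default 0.05).
#' @param nullDist null distribution for causal P-values: \code{"t"}
#'   (t with M-1 df for GWLS, M-2 for the Egger slope; normal when M = 1) or
#'   \code{"normal"}.
#' @param palindromicMafMax palindromic (A/T, C/G) variants with minor
#'   allele frequency above this are dropped as strand-unresolvable
#'   (default 0.42).
#' @param ridgeEps diagonal ridge added to the LD correlation matrix when
#'   its smallest eigenvalue falls below 1e-8.
#' @param wmBoot parametric-bootstrap resamples for the weighted-median SE
#'   (default 1000).
#' @return list of class \code{mr_config}.
#' @export
mrConfig <- function(windowHalfwidth = 5e5, clumpR2 = 0.2, proxyR2 = 0.8,
                     fdrLevel = 0.05, nullDist = c("t", "normal"),
                     palindromicMafMax = 0.42, ridgeEps = 1e-6,
                     wmBoot = 1000) {
  nullDist <- match.arg(nullDist)
  stopifnot(windowHalfwidth > 0, clumpR2 > 0, clumpR2 < 1,
            proxyR2 > 0, proxyR2 < 1, fdrLevel > 0, fdrLevel < 1)
  structure(list(windowHalfwidth = windowHalfwidth, clumpR2 = clumpR2,
                 proxyR2 = proxyR2, fdrLevel = fdrLevel, nullDist = nullDist,
                 palindromicMafMax = palindromicMafMax, ridgeEps = ridgeEps,
                 wmBoot = wmBoot), class = "mr_config")
}

## Signed LD correlation among variants, from reference-panel dosages.
ldCorrelation <- function(ldSource, variants) {
  D <- dosage(ldSource)
  miss <- setdiff(variants, colnames(D))
  if (length(miss))
    stop("LD source lacks variant(s): ", paste(miss, collapse = ", "))
  r <- cor(D[, variants, drop = FALSE], use = "pairwise.complete.obs")
  dimnames(r) <- list(variants, variants)
  r
}

#' Select cis instruments for one protein
#'
#' Restricts the exposure summary statistics to the gene's cis window
#' (gene body +/- halfwidth, closed interval), computes the window-wide
#' significance level P_b = 0.05 / N from the number of window variants,
#' greedily clumps by ascending P (the index variant of each clump is
#' retained; variants within 1 Mb of a retained index at LD r-squared >=
#' the clump threshold are removed), then prunes remaining variants with
#' P >= P_b, and attaches the signed empirical LD among the survivors. An
#' empty survivor set yields status \code{"no_instruments"} (the analyte is
#' untestable), not an error.
#'
#' @param exposure exposure summary statistics (columns \code{variant},
#'   \code{chrom}, \code{pos}, \code{ea}, \code{oa}, \code{beta}, \code{se},
#'   \code{p}, \code{n}).
#' @param gene one-row data.frame/list with \code{gene}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param config an \code{\link{mrConfig}}.
#' @param ldSource \linkS4class{GenotypeMatrix} from the exposure sample.
#' @return An \linkS4class{InstrumentSet} (betaY/seY not yet filled).
#' @export
selectInstruments <- function(exposure, gene, config, ldSource) {
  hw <- config$windowHalfwidth
  win <- exposure[exposure$chrom == gene$chrom &
                    exposure$pos >= gene$start - hw &
                    exposure$pos <= gene$end + hw, , drop = FALSE]
  win <- win[!is.na(win$beta), , drop = FALSE]
  geneDf <- as.data.frame(gene)[, c("gene", "chrom", "start", "end")]
  if (nrow(win) == 0)
    return(InstrumentSet(analyte = if (!is.null(gene$analyte)) gene$analyte else gene$gene,
                         data = win, gene = geneDf, pb = NA_real_,
                         windowStats = win))
  pb <- 0.05 / nrow(win)
  ld <- ldCorrelation(ldSource, win$variant)
  ## greedy PLINK-style clump: ascending P, index retained, r2 >= threshold
  ## within 1 Mb removed
  ord <- order(win$p)
  retained <- integer()
  for (i in ord) {
    clumped <- FALSE
    for (k in retained) {
      if (abs(win$pos[i] - win$pos[k]) <= 1e6 &&
          ld[win$variant[i], win$variant[k]]^2 >= config$clumpR2) {
        clumped <- TRUE; break
      }
    }
    if (!clumped) retained <- c(retained, i)
  }
  retained <- retained[win$p[retained] < pb]
  retained <- sort(retained)
  keep <- win[retained, , drop = FALSE]
  rownames(keep) <- NULL
  dat <- keep
  anl <- if (!is.null(gene$analyte)) gene$analyte else gene$gene
  dat$betaX <- dat$beta; dat$seX <- dat$se; dat$pX <- dat$p
  dat <- dat[, c("variant", "chrom", "pos", "ea", "oa", "betaX", "seX", "pX")]
  InstrumentSet(analyte = anl, data = dat,
                ld = if (nrow(dat)) ld[dat$variant, dat$variant, drop = FALSE] else NULL,
                gene = geneDf, pb = pb, windowStats = win)
}

complementAllele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

isPalindromic <- function(ea, oa) !is.na(ea) & complementAllele(ea) == oa

## Align one outcome record to an exposure effect allele.
## Returns list(beta, se) or NULL when alleles cannot be reconciled.
alignOutcomeRecord <- function(eaX, oaX, rec) {
  if (rec$ea == eaX && rec$oa == oaX) return(list(beta = rec$beta, se = rec$se))
  if (rec$ea == oaX && rec$oa == eaX) return(list(beta = -rec$beta, se = rec$se))
  if (!is.na(complementAllele(rec$ea)) &&
      complementAllele(rec$ea) == eaX && complementAllele(rec$oa) == oaX)
    return(list(beta = rec$beta, se = rec$se))
  if (!is.na(complementAllele(rec$ea)) &&
      complementAllele(rec$ea) == oaX && complementAllele(rec$oa) == eaX)
    return(list(beta = -rec$beta, se = rec$se))
  NULL
}

#' Harmonize outcome effects onto an instrument set, with proxy substitution
#'
#' Aligns outcome betas to each instrument's exposure effect allele (sign
#' flip on allele swap, strand-flip reconciliation where unambiguous).
#' Palindromic (A/T, C/G) variants with minor allele frequency above the
#' configured bound are dropped as strand-unresolvable. Instruments missing
#' from the outcome set are replaced by their best in-window proxy with
#' r-squared above the proxy threshold when one exists — the exposure effect
#' is re-estimated at the proxy (its own summary record), so both samples
#' refer to the same physical variant — and dropped otherwise. The LD matrix
#' is rebuilt for the final set.
#'
#' @param iset \linkS4class{InstrumentSet} from
#'   \code{\link{selectInstruments}}.
#' @param outcome outcome summary statistics (same layout as exposure,
#'   log-odds scale).
#' @param ldSource \linkS4class{GenotypeMatrix} for LD and allele
#'   frequencies.
#' @param config an \code{\link{mrConfig}}.
#' @return The harmonized \linkS4class{InstrumentSet}.
#' @export
harmonizeAndProxy <- function(iset, outcome, ldSource, config) {
  dat <- instruments(iset)
  if (nrow(dat) == 0) return(iset)
  vi <- variantInfo(ldSource)
  win <- iset@windowStats
  dropPalindromic <- function(variant, ea, oa) {
    if (!isTRUE(isPalindromic(ea, oa))) return(FALSE)
    maf <- vi$maf[match(variant, vi$variant)]
    if (is.na(maf)) return(TRUE)
    min(maf, 1 - maf) > config$palindromicMafMax
  }
  rows <- list()
  used <- character()
  for (i in seq_len(nrow(dat))) {
    row <- dat[i, , drop = FALSE]
    orec <- outcome[outcome$variant == row$variant, , drop = FALSE]
    if (nrow(orec) >= 1) {
      if (dropPalindromic(row$variant, row$ea, row$oa)) {
        message("dropping palindromic variant ", row$variant,
                " (ambiguous strand at MAF > ", config$palindromicMafMax, ")")
        next
      }
      al <- alignOutcomeRecord(row$ea, row$oa, orec[1, ])
      if (is.null(al)) {
        message("dropping ", row$variant, ": alleles cannot be reconciled")
        next
      }
      row$betaY <- al$beta; row$seY <- al$se; row$proxyFor <- NA_character_
      rows[[length(rows) + 1L]] <- row
      used <- c(used, row$variant)
    } else {
      ## proxy search among window variants present in the outcome set
      cand <- win[win$variant %in% outcome$variant &
                    !win$variant %in% c(dat$variant, used), , drop = FALSE]
      if (nrow(cand) == 0) next
      r2 <- ldCorrelation(ldSource, c(row$variant, cand$variant))[1, -1]^2
      cand <- cand[order(-r2), , drop = FALSE]
      r2 <- sort(r2, decreasing = TRUE)
      sub <- NULL
      for (k in seq_len(nrow(cand))) {
        if (r2[k] <= config$proxyR2) break
        pk <- cand[k, , drop = FALSE]
        if (dropPalindromic(pk$variant, pk$ea, pk$oa)) next
        orec <- outcome[outcome$variant == pk$variant, , drop = FALSE]
        al <- alignOutcomeRecord(pk$ea, pk$oa, orec[1, ])
        if (is.null(al)) next
        sub <- data.frame(variant = pk$variant, chrom = pk$chrom,
                          pos = pk$pos, ea = pk$ea, oa = pk$oa,
                          betaX = pk$beta, seX = pk$se, pX = pk$p,
                          betaY = al$beta, seY = al$se,
                          proxyFor = row$variant, stringsAsFactors = FALSE)
        break
      }
      if (is.null(sub)) {
        message("no qualifying proxy (r2 > ", config$proxyR2, ") for ",
                row$variant, "; instrument dropped")
        next
      }
      rows[[length(rows) + 1L]] <- sub
      used <- c(used, sub$variant)
    }
  }
  final <- if (length(rows)) do.call(rbind, rows) else dat[0, , drop = FALSE]
  rownames(final) <- NULL
  ld <- if (nrow(final)) ldCorrelation(ldSource, final$variant) else NULL
  InstrumentSet(analyte = iset@analyte, data = final, ld = ld,
                gene = iset@gene, pb = iset@pb, windowStats = win)
}

## Regularized weighting matrix Sigma with entries rho_ij sigma_Yi sigma_Yj.
buildSigma <- function(ld, seY, ridgeEps) {
  if (min(eigen(ld, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    ld <- ld + diag(ridgeEps, nrow(ld))
  S <- ld * tcrossprod(seY)
  if (rcond(S) < 1e-12)
    stop(sprintf("weighting matrix numerically singular (rcond = %.3g)",
                 rcond(S)))
  S
}

causalP <- function(est, se, m, nullDist) {
  z <- abs(est / se)
  if (nullDist == "t" && m >= 2) 2 * pt(-z, df = m - 1) else 2 * pnorm(-z)
}

#' Generalized weighted least squares causal estimate
#'
#' Combines M correlated instruments into one causal estimate:
#' theta-hat = (beta_X' Sigma^-1 beta_X)^-1 beta_X' Sigma^-1 beta_Y, where
#' Sigma has entries rho_ij sigma_Yi sigma_Yj (rho the signed LD
#' correlation). The standard error is alpha * sqrt((beta_X' Sigma^-1
#' beta_X)^-1) with alpha = max(1, sqrt(MSE)) and MSE the Sigma^-1-weighted
#' residual quadratic form divided by (M - 1): the SE is inflated under
#' residual heterogeneity but never deflated by good fit. Exposure SEs are
#' carried but unused (no-measurement-error first-order convention). With
#' rho = I this is the classical IVW estimate; with M = 1 it collapses
#' exactly to the Wald ratio (alpha fixed to 1). The two-sided P uses the
#' configured null (t with M - 1 df by default; normal at M = 1).
#'
#' @param iset harmonized \linkS4class{InstrumentSet}.
#' @param config an \code{\link{mrConfig}}.
#' @return An \linkS4class{MREstimate} with method \code{"gwls"}.
#' @export
gwlsEstimate <- function(iset, config = mrConfig()) {
  dat <- instruments(iset)
  dat <- dat[!is.na(dat$betaY), , drop = FALSE]
  m <- nrow(dat)
  if (m < 1) stop("no harmonized instruments")
  ld <- ldMatrix(iset)[dat$variant, dat$variant, drop = FALSE]
  S <- buildSigma(ld, dat$seY, config$ridgeEps)
  Sinv <- solve(S)
  bX <- dat$betaX; bY <- dat$betaY
  denom <- drop(t(bX) %*% Sinv %*% bX)
  theta <- drop(t(bX) %*% Sinv %*% bY) / denom
  res <- bY - bX * theta
  mse <- if (m > 1) drop(t(res) %*% Sinv %*% res) / (m - 1) else 0
  alpha <- if (m > 1) max(1, sqrt(mse)) else 1
  se <- alpha * sqrt(1 / denom)
  p <- causalP(theta, se, m, config$nullDist)
  MREstimateRecord(iset@analyte, "gwls", theta, se, p, m, mse = mse,
                   alpha = alpha, nullDist = config$nullDist)
}

#' Wald ratio causal estimate for a single instrument
#'
#' theta-hat = beta_Y / beta_X with first-order delta-method SE
#' sigma_Y / |beta_X| and a two-sided normal P.
#'
#' @param iset harmonized \linkS4class{InstrumentSet} with exactly one
#'   instrument.
#' @param config an \code{\link{mrConfig}}.
#' @return An \linkS4class{MREstimate} with method \code{"wald"}.
#' @export
waldRatio <- function(iset, config = mrConfig()) {
  dat <- instruments(iset)
  dat <- dat[!is.na(dat$betaY), , drop = FALSE]
  if (nrow(dat) != 1) stop("waldRatio requires exactly one instrument")
  if (dat$betaX == 0) stop("Wald ratio undefined for beta_X = 0")
  theta <- dat$betaY / dat$betaX
  se <- dat$seY / abs(dat$betaX)
  MREstimateRecord(iset@analyte, "wald", theta, se,
                   2 * pnorm(-abs(theta / se)), 1, mse = 0, alpha = 1,
                   nullDist = config$nullDist)
}

weightedMedianPoint <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  j <- max(which(p <= 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

#' Weighted-median causal estimate
#'
#' The interpolated weighted median of the per-instrument ratio estimates
#' beta_Y/beta_X, weighted by the first-order inverse variance of each
#' ratio (beta_X^2 / sigma_Y^2). Consistent when at least half the weight
#' comes from valid instruments. The SE comes from a parametric bootstrap
#' drawing beta_Y from MVN(beta_Y, Sigma) — so instrument correlation is
#' propagated — and beta_X from N(beta_X, sigma_X); the resample count is
#' configurable and the draw is seeded.
#'
#' @param iset harmonized \linkS4class{InstrumentSet} with M >= 3.
#' @param config an \code{\link{mrConfig}}.
#' @param seed bootstrap seed.
#' @return An \linkS4class{MREstimate} with method \code{"weighted_median"}.
#' @export
weightedMedian <- function(iset, config = mrConfig(), seed = 1) {
  dat <- instruments(iset)
  dat <- dat[!is.na(dat$betaY), , drop = FALSE]
  m <- nrow(dat)
  if (m < 3) stop("weightedMedian requires at least 3 instruments")
  w <- dat$betaX^2 / dat$seY^2
  est <- weightedMedianPoint(dat$betaY / dat$betaX, w)
  ld <- ldMatrix(iset)[dat$variant, dat$variant, drop = FALSE]
  S <- buildSigma(ld, dat$seY, config$ridgeEps)
  U <- chol(S)
  seX <- ifelse(is.na(dat$seX), 0, dat$seX)
  set.seed(seed)
  boot <- vapply(seq_len(config$wmBoot), function(b) {
    bY <- dat$betaY + drop(t(U) %*% rnorm(m))
    bX <- dat$betaX + seX * rnorm(m)
    weightedMedianPoint(bY / bX, bX^2 / dat$seY^2)
  }, numeric(1))
  se <- sd(boot)
  MREstimateRecord(iset@analyte, "weighted_median", est, se,
                   2 * pnorm(-abs(est / se)), m, nullDist = "normal")
}

#' MR-Egger regression
#'
#' Generalized weighted regression of beta_Y on beta_X with an intercept:
#' the slope is the pleiotropy-robust causal estimate under the InSIDE
#' assumption and the intercept measures directional pleiotropy. The
#' weighting uses the full Sigma = rho o (sigma_Y sigma_Y') so correlated
#' instruments are handled; with rho = I it reduces exactly to the
#' classical 1/sigma_Y^2-weighted Egger regression. Instruments are
#' oriented so all beta_X >= 0. Coefficient SEs use the residual variance
#' floored at 1 (never deflated by good fit); P-values are two-sided t with
#' M - 2 df.
#'
#' @param iset harmonized \linkS4class{InstrumentSet} with M >= 3 and
#'   spread in beta_X.
#' @param config an \code{\link{mrConfig}}.
#' @return An \linkS4class{MREstimate} with method \code{"egger"}, carrying
#'   the intercept and its P.
#' @export
mrEgger <- function(iset, config = mrConfig()) {
  dat <- instruments(iset)
  dat <- dat[!is.na(dat$betaY), , drop = FALSE]
  m <- nrow(dat)
  if (m < 3) stop("mrEgger requires at least 3 instruments")
  flip <- sign(dat$betaX)
  flip[flip == 0] <- 1
  bX <- dat$betaX * flip
  bY <- dat$betaY * flip
  if (var(bX) == 0) stop("all beta_X equal: Egger slope unidentifiable")
  ld <- ldMatrix(iset)[dat$variant, dat$variant, drop = FALSE]
  ## simultaneous allele flips change the sign of the LD rows/cols too
  ld <- ld * tcrossprod(flip)
  S <- buildSigma(ld, dat$seY, config$ridgeEps)
  U <- chol(S)
  X <- cbind(intercept = 1, slope = bX)
  Xs <- backsolve(U, X, transpose = TRUE)
  ys <- backsolve(U, bY, transpose = TRUE)
  A <- crossprod(Xs)
  Ainv <- solve(A)
  cf <- drop(Ainv %*% crossprod(Xs, ys))
  res <- ys - Xs %*% cf
  sigma2 <- sum(res^2) / (m - 2)
  covm <- Ainv * max(1, sigma2)
  se <- sqrt(diag(covm))
  pv <- if (config$nullDist == "t")
    function(z) 2 * pt(-abs(z), df = m - 2)
  else function(z) 2 * pnorm(-abs(z))
  MREstimateRecord(iset@analyte, "egger", cf[2], se[2], pv(cf[2] / se[2]), m,
                   mse = sigma2, alpha = max(1, sqrt(sigma2)),
                   eggerIntercept = cf[1], eggerInterceptP = pv(cf[1] / se[1]),
                   nullDist = config$nullDist)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of P-values
#' (monotone, capped at 1, never smaller than the raw P).
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @return adjusted P-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1)))
    stop("P-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Two-step sensitivity gate for a causal estimate
#'
#' Proteins whose GWLS estimate is BH-significant are reassessed: step 1
#' requires the weighted-median estimate to agree in direction with the
#' GWLS estimate and remain significant at P < 0.05; step 2 requires the
#' MR-Egger slope to agree in direction and the Egger intercept P to exceed
#' 0.05 (no detectable directional pleiotropy). Survivors are causal
#' candidates.
#'
#' @param gwls GWLS \linkS4class{MREstimate} with its \code{fdr} slot
#'   filled (see \code{\link{bhAdjust}}).
#' @param wm weighted-median \linkS4class{MREstimate} (NULL allowed when
#'   M < 3, in which case a BH-significant estimate stays
#'   \code{"not_tested"}: the gate is untestable).
#' @param egger MR-Egger \linkS4class{MREstimate} (NULL under the same
#'   condition).
#' @param config an \code{\link{mrConfig}}.
#' @return The \code{gwls} estimate with its gate status filled.
#' @export
sensitivityGate <- function(gwls, wm, egger, config = mrConfig()) {
  if (is.na(gwls@fdr))
    stop("gwls estimate has no FDR; run bhAdjust across analytes first")
  if (gwls@fdr >= config$fdrLevel) { gwls@gate <- "not_tested"; return(gwls) }
  if (gwls@m >= 3 && (is.null(wm) || is.null(egger)))
    stop("sensitivity estimates missing for an analyte with M >= 3 (pipeline ordering bug)")
  if (is.null(wm) || is.null(egger)) { gwls@gate <- "not_tested"; return(gwls) }
  if (sign(wm@estimate) != sign(gwls@estimate) || wm@p >= 0.05) {
    gwls@gate <- "failed_step1"; return(gwls)
  }
  if (sign(egger@estimate) != sign(gwls@estimate) ||
      egger@eggerInterceptP <= 0.05) {
    gwls@gate <- "failed_step2"; return(gwls)
  }
  gwls@gate <- "causal_candidate"
  gwls
}

#' Run the full MR pipeline over a set of proteins
#'
#' For each analyte: select cis instruments from its exposure statistics,
#' harmonize against the outcome statistics (with proxy substitution),
#' estimate the causal effect (GWLS for M >= 2, Wald ratio for M = 1),
#' BH-adjust across analytes, and apply the two-step sensitivity gate
#' (weighted median, then MR-Egger) to BH-significant estimates with
#' M >= 3.
#'
#' @param exposureList named list of exposure summary-statistics tables,
#'   one per analyte.
#' @param outcome outcome summary statistics (log-odds scale).
#' @param genes data.frame of gene loci with columns \code{analyte},
#'   \code{gene}, \code{chrom}, \code{start}, \code{end}.
#' @param ldSource \linkS4class{GenotypeMatrix} from the exposure sample.
#' @param config an \code{\link{mrConfig}}.
#' @param seed seed for the weighted-median bootstrap.
#' @return list with \code{estimates} (data.frame, one row per analyte x
#'   method plus gate status) and \code{instrumentSets}.
#' @export
mrAnalysis <- function(exposureList, outcome, genes, ldSource,
                       config = mrConfig(), seed = 1) {
  sets <- list(); fits <- list()
  for (anl in names(exposureList)) {
    g <- genes[genes$analyte == anl, , drop = FALSE]
    if (nrow(g) != 1) stop("need exactly one gene locus for analyte ", anl)
    g$analyte <- anl
    iset <- selectInstruments(exposureList[[anl]], g, config, ldSource)
    iset <- harmonizeAndProxy(iset, outcome, ldSource, config)
    sets[[anl]] <- iset
    nH <- sum(!is.na(instruments(iset)$betaY))
    if (nH == 0) next
    fits[[anl]] <- if (nH == 1) waldRatio(iset, config)
                   else gwlsEstimate(iset, config)
  }
  if (length(fits) == 0)
    return(list(estimates = data.frame(), instrumentSets = sets))
  fdr <- bhAdjust(vapply(fits, function(f) f@p, numeric(1)))
  rows <- list()
  for (i in seq_along(fits)) {
    anl <- names(fits)[i]
    f <- fits[[i]]
    f@fdr <- fdr[i]
    wm <- egger <- NULL
    if (f@fdr < config$fdrLevel && f@m >= 3) {
      wm <- weightedMedian(sets[[anl]], config, seed = seed)
      egger <- mrEgger(sets[[anl]], config)
    }
    f <- sensitivityGate(f, wm, egger, config)
    rows[[length(rows) + 1L]] <- mrTable(c(list(f), Filter(Negate(is.null), list(wm, egger))))
  }
  list(estimates = do.call(rbind, rows), instrumentSets = sets)
}
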