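## Synthetic two-sample proteogenomic cohort generator.
##
## Genotypes are built from a latent multivariate Gaussian thresholded at
## MAF-determined quantiles, one draw per haplotype, two haplotypes summed
## per subject.  The latent correlation of each variant pair is calibrated
## (bivariate-normal orthant probability, root-finding) so that the
## *genotype* correlation matches the configured signed target r; this
## preserves Hardy-Weinberg proportions within each variant.  Proteins are
## sums of genetic effects, a module latent factor, an optional shared
## confounder and independent noise, with total variance 1 so configured
## per-allele effects are on the SD scale.  Disease is a logistic model in
## proteins (causal path), optional direct variant effects (pleiotropy), the
## confounder and age/sex.

#' Simulation configuration for the synthetic cohort
#'
#' Defines the full ground truth of a simulated two-sample study: an
#' exposure cohort (individual-level genotypes, proteins, phenotypes) and an
#' independent outcome cohort sharing the same variant map, from which
#' outcome summary statistics are computed. Defaults emulate an elderly
#' population-based cohort: ~5000 subjects per sample, age 76.6 +/- 5.6
#' years (minimum 67), 57.3% female, disease prevalence 0.37 with staged
#' severity assigned among cases at early:late odds 1755:272 and a nested
#' stricter early definition covering 1054 of 1755 early cases.
#'
#' @param blocks list of LD-block specifications, each a list with elements
#'   \code{chrom}, \code{n} (variant count), \code{r} (target signed
#'   within-block genotype correlation, |r| < 1) and \code{maf} (length-2
#'   MAF range within (0, 1)).
#' @param nProteins number of protein analytes.
#' @param moduleAssign integer vector (length \code{nProteins}) giving each
#'   protein's coregulation module, 0 for none.
#' @param moduleR named/indexed numeric vector of within-module target
#'   correlations.
#' @param cisEffects data.frame with columns \code{protein}, \code{variant},
#'   \code{beta} (per-allele effect, SD units). The protein-encoding gene is
#'   placed at the first cis variant so these effects are cis by
#'   construction.
#' @param transEffects same shape; genes are placed away from these variants.
#' @param causalThetas named numeric vector, protein -> log-odds per SD
#'   effect on disease.
#' @param directSnpEffects named numeric vector, variant -> direct log-odds
#'   effect on disease (pleiotropy knob, a violation of the exclusion
#'   assumption).
#' @param confounderLoadings named numeric vector, protein -> loading of a
#'   shared standard-normal latent confounder.
#' @param confounderOutcome log-odds loading of the confounder on disease
#'   (with \code{confounderLoadings}, the knob violating instrument
#'   independence).
#' @param prevalence target disease prevalence in (0, 1).
#' @param ageEffect,sexEffect log-odds per year of age (centred) and for
#'   female sex.
#' @param nExposure,nOutcome subjects in the exposure and outcome samples.
#' @param ageMean,ageSD,ageMin,femaleProp demographics of both samples.
#' @param lateGivenCase probability a case is late-stage (default 272/2027).
#' @param earlyBGivenEarly probability an early case also meets the stricter
#'   early definition (default 1054/1755).
#' @param lateSubtypeProps multinomial proportions of late subtypes.
#' @param followupFraction fraction of baseline non-late subjects
#'   re-examined.
#' @param progressionProb per-subject probability a re-examined subject
#'   progresses one stage at follow-up.
#' @param seed integer master seed; together with the config it fully
#'   determines all outputs.
#' @return object of class \code{sim_config} (validated list).
#' @export
simConfig <- function(blocks = list(list(chrom = 1L, n = 10L, r = 0.5, maf = c(0.25, 0.40))),
                      nProteins = 1L,
                      moduleAssign = rep(0L, nProteins),
                      moduleR = numeric(),
                      cisEffects = data.frame(protein = character(),
                                              variant = character(),
                                              beta = numeric()),
                      transEffects = data.frame(protein = character(),
                                                variant = character(),
                                                beta = numeric()),
                      causalThetas = numeric(),
                      directSnpEffects = numeric(),
                      confounderLoadings = numeric(),
                      confounderOutcome = 0,
                      prevalence = 0.37,
                      ageEffect = 0.06, sexEffect = -0.1,
                      nExposure = 5000L, nOutcome = 5000L,
                      ageMean = 76.6, ageSD = 5.6, ageMin = 67,
                      femaleProp = 0.573,
                      lateGivenCase = 272 / 2027,
                      earlyBGivenEarly = 1054 / 1755,
                      lateSubtypeProps = c(GA_pure = 0.40, nAMD = 0.45,
                                           GA_plus_nAMD = 0.15),
                      followupFraction = 0.5, progressionProb = 0.15,
                      seed = 1L) {
  cfg <- list(blocks = blocks, nProteins = as.integer(nProteins),
              moduleAssign = as.integer(moduleAssign), moduleR = moduleR,
              cisEffects = cisEffects, transEffects = transEffects,
              causalThetas = causalThetas, directSnpEffects = directSnpEffects,
              confounderLoadings = confounderLoadings,
              confounderOutcome = confounderOutcome,
              prevalence = prevalence, ageEffect = ageEffect,
              sexEffect = sexEffect, nExposure = as.integer(nExposure),
              nOutcome = as.integer(nOutcome), ageMean = ageMean,
              ageSD = ageSD, ageMin = ageMin, femaleProp = femaleProp,
              lateGivenCase = lateGivenCase,
              earlyBGivenEarly = earlyBGivenEarly,
              lateSubtypeProps = lateSubtypeProps,
              followupFraction = followupFraction,
              progressionProb = progressionProb, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  for (b in cfg$blocks) {
    if (any(b$maf <= 0) || any(b$maf >= 1)) stop("MAF range must lie in (0, 1)")
    if (abs(b$r) >= 1) stop("target |r| must be < 1")
    if (b$n < 1) stop("each block needs at least one variant")
  }
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  if (length(cfg$moduleAssign) != cfg$nProteins)
    stop("moduleAssign must have one entry per protein")
  if (any(cfg$moduleAssign > 0) &&
      any(!cfg$moduleAssign[cfg$moduleAssign > 0] %in% seq_along(cfg$moduleR)))
    stop("moduleAssign references a module without a moduleR entry")
  vids <- variantIds(cfg)
  pids <- proteinIds(cfg)
  for (df in list(cfg$cisEffects, cfg$transEffects)) {
    if (nrow(df) == 0) next
    if (!all(df$variant %in% vids)) stop("effect references an unknown variant")
    if (!all(df$protein %in% pids)) stop("effect references an unknown protein")
  }
  if (length(cfg$causalThetas) && !all(names(cfg$causalThetas) %in% pids))
    stop("causalThetas references an unknown protein")
  if (length(cfg$directSnpEffects) && !all(names(cfg$directSnpEffects) %in% vids))
    stop("directSnpEffects references an unknown variant")
  if (length(cfg$confounderLoadings) &&
      !all(names(cfg$confounderLoadings) %in% pids))
    stop("confounderLoadings references an unknown protein")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$blocks), "LD block(s),",
      sum(vapply(x$blocks, function(b) b$n, 1L)), "variants,",
      x$nProteins, "proteins; n =", x$nExposure, "/", x$nOutcome,
      "(exposure/outcome); seed", x$seed, "\n")
  invisible(x)
}

variantIds <- function(cfg)
  unlist(lapply(seq_along(cfg$blocks), function(bi)
    paste0("b", bi, "v", seq_len(cfg$blocks[[bi]]$n))))

proteinIds <- function(cfg) sprintf("P%03d", seq_len(cfg$nProteins))

## Genotype correlation between two thresholded-latent allele indicators
## with latent correlation rho and allele frequencies p1, p2.
thresholdCorr <- function(rho, t1, t2, p1, p2) {
  p11 <- mvtnorm::pmvnorm(lower = c(t1, t2), upper = c(Inf, Inf),
                          corr = matrix(c(1, rho, rho, 1), 2))
  (as.numeric(p11) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

## Latent correlation achieving a target genotype correlation; errors when
## the target is infeasible for the given allele frequencies.
latentRho <- function(target, p1, p2) {
  if (target == 0) return(0)
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  lim <- 0.9999
  lo <- thresholdCorr(-lim, t1, t2, p1, p2)
  hi <- thresholdCorr(lim, t1, t2, p1, p2)
  if (target > hi || target < lo)
    stop(sprintf(paste0("target correlation %.3f infeasible for MAFs %.3f/%.3f ",
                        "(attainable range [%.3f, %.3f])"),
                 target, p1, p2, lo, hi))
  uniroot(function(r) thresholdCorr(r, t1, t2, p1, p2) - target,
          c(-lim, lim), tol = 1e-5)$root
}

## Nearest-correlation repair: clip eigenvalues, restore unit diagonal.
fixCorrMatrix <- function(L, floor = 1e-6) {
  e <- eigen(L, symmetric = TRUE)
  if (min(e$values) >= floor) return(L)
  v <- pmax(e$values, floor)
  L2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(L2))
  L2 / tcrossprod(d)
}

#' Build the shared variant map for a simulation
#'
#' Draws MAFs, assigns positions and calibrates the latent LD structure.
#' The map depends only on the configuration (its seed), so the exposure
#' and outcome samples share one variant map while sharing no individuals.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with variant metadata, per-block latent Cholesky factors and
#'   thresholds.
#' @export
makeVariantMap <- function(config) {
  set.seed(config$seed)
  blocks <- list()
  meta <- list()
  chromCount <- integer()
  for (bi in seq_along(config$blocks)) {
    b <- config$blocks[[bi]]
    ch <- as.character(b$chrom)
    chromCount[ch] <- if (ch %in% names(chromCount)) chromCount[[ch]] + 1L else 1L
    base <- 1e6 + (chromCount[ch] - 1L) * 5e6
    maf <- runif(b$n, b$maf[1], b$maf[2])
    thr <- qnorm(1 - maf)
    L <- diag(b$n)
    if (b$n > 1 && b$r != 0) {
      for (i in seq_len(b$n - 1)) for (j in (i + 1):b$n) {
        L[i, j] <- L[j, i] <- latentRho(b$r, maf[i], maf[j])
      }
      L <- fixCorrMatrix(L)
    }
    blocks[[bi]] <- list(chol = chol(L), thr = thr, n = b$n)
    meta[[bi]] <- data.frame(
      variant = paste0("b", bi, "v", seq_len(b$n)),
      chrom = b$chrom, pos = base + (seq_len(b$n) - 1L) * 5000L,
      ea = "A", oa = "G", maf = maf, block = bi,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, meta)
  ## positions must be strictly increasing within a chromosome
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- variants$variant
  list(variants = variants, blocks = blocks)
}

#' Simulate LD-structured genotypes
#'
#' Two latent-Gaussian haplotypes per subject are thresholded at
#' MAF-determined quantiles and summed, giving dosages in {0, 1, 2} that
#' satisfy Hardy-Weinberg proportions at the drawn MAF while matching the
#' configured signed within-block genotype correlation. Blocks are mutually
#' independent.
#'
#' @param config a \code{\link{simConfig}}.
#' @param n number of subjects.
#' @param seed seed for the dosage draw (defaults to the config seed); the
#'   variant map itself always derives from the config seed.
#' @param map optional precomputed \code{\link{makeVariantMap}} result.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
simulateGenotypes <- function(config, n, seed = config$seed, map = NULL) {
  if (is.null(map)) map <- makeVariantMap(config)
  set.seed(seed)
  cols <- list()
  for (bi in seq_along(map$blocks)) {
    blk <- map$blocks[[bi]]
    h1 <- matrix(rnorm(n * blk$n), n) %*% blk$chol
    h2 <- matrix(rnorm(n * blk$n), n) %*% blk$chol
    d <- (sweep(h1, 2, blk$thr, ">") + sweep(h2, 2, blk$thr, ">")) * 1
    colnames(d) <- paste0("b", bi, "v", seq_len(blk$n))
    cols[[bi]] <- d
  }
  d <- do.call(cbind, cols)[, map$variants$variant, drop = FALSE]
  rownames(d) <- sprintf("s%05d", seq_len(n))
  GenotypeMatrix(d, map$variants[, c("variant", "chrom", "pos", "ea", "oa", "maf")])
}

proteinAnnotation <- function(config, map) {
  pids <- proteinIds(config)
  ann <- data.frame(analyte = pids, gene = sub("^P", "GENE", pids),
                    chrom = 22L, start = 0, end = 0, stringsAsFactors = FALSE)
  ann$start <- 1e6 + (seq_along(pids) - 1) * 2e5
  ann$end <- ann$start + 2e4
  if (nrow(config$cisEffects)) {
    for (p in unique(config$cisEffects$protein)) {
      vv <- config$cisEffects$variant[config$cisEffects$protein == p]
      vi <- map$variants[vv, , drop = FALSE]
      i <- match(p, ann$analyte)
      ann$chrom[i] <- vi$chrom[1]
      ann$start[i] <- min(vi$pos) - 1e4
      ann$end[i] <- max(vi$pos) + 1e4
    }
  }
  rownames(ann) <- ann$analyte
  ann
}

#' Simulate genetically regulated, module-correlated proteins
#'
#' Each protein is the sum of its configured per-allele genetic effects, a
#' module latent factor (loading sqrt(module r)), an optional shared
#' confounder and independent Gaussian noise, with the noise variance chosen
#' so the total variance is 1: configured effects are therefore on the SD
#' scale and are recovered by a per-allele regression when effect variants
#' are unlinked. Genes of cis-regulated proteins are placed at their cis
#' variants; all other genes sit on chromosome 22, so configured trans
#' effects are distal by construction.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} for the sample.
#' @param config a \code{\link{simConfig}}.
#' @param confounder optional length-n standard-normal confounder shared
#'   with \code{\link{simulateOutcome}}; drawn internally when NULL.
#' @param seed RNG seed (defaults to config seed + 1).
#' @param rawScale when TRUE, return exp(3 + 0.5 x) as a raw positive
#'   abundance scale (state "raw") for exercising the preprocessing stage;
#'   default returns the standardized values (state "transformed").
#' @return list with elements \code{proteins} (\linkS4class{ProteinMatrix}),
#'   \code{confounder} and \code{trueParams} (realized variance shares and
#'   the configured effects).
#' @export
simulateProteins <- function(genotypes, config, confounder = NULL,
                             seed = config$seed + 1L, rawScale = FALSE) {
  set.seed(seed)
  D <- dosage(genotypes)
  n <- nrow(D)
  Gc <- sweep(D, 2, colMeans(D))
  if (is.null(confounder)) confounder <- rnorm(n)
  nMod <- length(config$moduleR)
  modF <- if (nMod) matrix(rnorm(n * nMod), n) else NULL
  pids <- proteinIds(config)
  eff <- rbind(config$cisEffects, config$transEffects)
  X <- matrix(0, n, length(pids), dimnames = list(rownames(D), pids))
  shares <- data.frame(protein = pids, varGenetic = 0, varModule = 0,
                       varConfounder = 0, varNoise = 1)
  for (i in seq_along(pids)) {
    p <- pids[i]
    g <- numeric(n)
    rows <- eff[eff$protein == p, , drop = FALSE]
    if (nrow(rows))
      g <- as.numeric(Gc[, rows$variant, drop = FALSE] %*% rows$beta)
    varGen <- if (nrow(rows)) var(g) else 0
    m <- config$moduleAssign[i]
    lm_ <- if (m > 0) sqrt(config$moduleR[[m]]) else 0
    lc <- if (p %in% names(config$confounderLoadings))
      config$confounderLoadings[[p]] else 0
    varNoise <- 1 - varGen - lm_^2 - lc^2
    if (varNoise < 0)
      stop(sprintf("configured variance share exceeds 1 for protein %s", p))
    X[, i] <- g + (if (m > 0) lm_ * modF[, m] else 0) + lc * confounder +
      rnorm(n, sd = sqrt(varNoise))
    shares[i, 2:5] <- c(varGen, lm_^2, lc^2, varNoise)
  }
  ann <- proteinAnnotation(config, makeVariantMap(config))
  pm <- if (rawScale)
    ProteinMatrix(exp(3 + 0.5 * X), ann, state = "raw")
  else ProteinMatrix(X, ann, state = "transformed")
  list(proteins = pm, confounder = confounder,
       trueParams = list(effects = eff, varianceShares = shares))
}

#' Simulate a staged binary disease outcome
#'
#' Disease is drawn from a logistic model: protein effects (causal path),
#' direct variant effects (pleiotropy), the shared confounder, and age/sex.
#' The intercept is solved numerically so the expected prevalence equals the
#' configured target; with no effects it reduces to logit(prevalence).
#' Severity stages and late subtypes are assigned among cases by the
#' configured multinomial proportions; the two early definitions are nested
#' (every strict early case is also a broad early case). A configured
#' fraction of baseline non-late subjects is flagged re-examined and given a
#' follow-up stage for progression analyses.
#'
#' @param proteins \linkS4class{ProteinMatrix} (standardized scale).
#' @param genotypes \linkS4class{GenotypeMatrix} for the same subjects.
#' @param config a \code{\link{simConfig}}.
#' @param phenBase optional data.frame with \code{age} and \code{sex}
#'   ("F"/"M") per subject; drawn from the configured demographics when NULL.
#' @param confounder the shared confounder returned by
#'   \code{\link{simulateProteins}} (zeros when NULL).
#' @param seed RNG seed (defaults to config seed + 2).
#' @return A phenotype table (data.frame) with columns \code{sample},
#'   \code{age}, \code{sex}, \code{case}, \code{stage} (none/early/late),
#'   \code{early_A}, \code{early_B} (nested logicals), \code{late_subtype},
#'   \code{reexamined}, \code{followup_stage}.
#' @export
simulateOutcome <- function(proteins, genotypes, config, phenBase = NULL,
                            confounder = NULL, seed = config$seed + 2L) {
  set.seed(seed)
  X <- assayValues(proteins)
  n <- nrow(X)
  if (is.null(phenBase)) {
    age <- config$ageMean + config$ageSD * rnorm(n)
    while (any(bad <- age < config$ageMin))
      age[bad] <- config$ageMean + config$ageSD * rnorm(sum(bad))
    sex <- ifelse(runif(n) < config$femaleProp, "F", "M")
  } else {
    age <- phenBase$age; sex <- phenBase$sex
  }
  if (is.null(confounder)) confounder <- numeric(n)
  lp <- numeric(n)
  if (length(config$causalThetas))
    lp <- lp + as.numeric(X[, names(config$causalThetas), drop = FALSE] %*%
                            config$causalThetas)
  if (length(config$directSnpEffects)) {
    D <- dosage(genotypes)[, names(config$directSnpEffects), drop = FALSE]
    lp <- lp + as.numeric(sweep(D, 2, colMeans(D)) %*% config$directSnpEffects)
  }
  lp <- lp + config$confounderOutcome * confounder +
    config$ageEffect * (age - config$ageMean) +
    config$sexEffect * (sex == "F")
  icpt <- uniroot(function(a) mean(plogis(a + lp)) - config$prevalence,
                  c(-30, 30), tol = 1e-8)$root
  y <- rbinom(n, 1, plogis(icpt + lp))
  stage <- rep("none", n)
  lateDraw <- runif(n) < config$lateGivenCase
  stage[y == 1] <- ifelse(lateDraw[y == 1], "late", "early")
  early_A <- stage == "early"
  early_B <- early_A & runif(n) < config$earlyBGivenEarly
  subtype <- rep("none", n)
  isLate <- stage == "late"
  if (any(isLate))
    subtype[isLate] <- sample(names(config$lateSubtypeProps), sum(isLate),
                              replace = TRUE, prob = config$lateSubtypeProps)
  reexamined <- stage != "late" & runif(n) < config$followupFraction
  followup <- rep(NA_character_, n)
  prog <- runif(n) < config$progressionProb
  followup[reexamined] <- stage[reexamined]
  adv <- reexamined & prog
  followup[adv & stage == "none"] <- "early"
  followup[adv & stage == "early"] <- "late"
  data.frame(sample = rownames(X), age = age, sex = sex, case = y,
             stage = stage, early_A = early_A, early_B = early_B,
             late_subtype = subtype, reexamined = reexamined,
             followup_stage = followup, stringsAsFactors = FALSE)
}

#' Binary indicator for a staged outcome label
#'
#' Maps a phenotype table to a case/control indicator for one outcome
#' definition, with subjects outside the comparison set to NA. Controls are
#' always stage "none" subjects. \code{"progression_late"} restricts to
#' re-examined baseline-early subjects and contrasts progression to late
#' disease at follow-up against no progression.
#'
#' @param phen phenotype table from \code{\link{simulateOutcome}}.
#' @param outcome one of \code{"amd_any"}, \code{"amd_early_A"},
#'   \code{"amd_early_B"}, \code{"amd_late"}, \code{"ga_pure"},
#'   \code{"namd"}, \code{"progression_late"}.
#' @return integer vector (1 case, 0 control, NA excluded).
#' @export
outcomeIndicator <- function(phen, outcome) {
  ctrl <- phen$stage == "none"
  ind <- rep(NA_integer_, nrow(phen))
  switch(outcome,
    amd_any = { ind[ctrl] <- 0L; ind[phen$stage != "none"] <- 1L },
    amd_early_A = { ind[ctrl] <- 0L; ind[phen$early_A] <- 1L },
    amd_early_B = { ind[ctrl] <- 0L; ind[phen$early_B] <- 1L },
    amd_late = { ind[ctrl] <- 0L; ind[phen$stage == "late"] <- 1L },
    ga_pure = { ind[ctrl] <- 0L; ind[phen$late_subtype == "GA_pure"] <- 1L },
    namd = { ind[ctrl] <- 0L; ind[phen$late_subtype == "nAMD"] <- 1L },
    progression_late = {
      sub <- phen$reexamined & phen$stage == "early"
      ind[sub] <- ifelse(phen$followup_stage[sub] == "late", 1L, 0L)
    },
    stop("unknown outcome label: ", outcome))
  ind
}

#' Per-variant association summary statistics
#'
#' Additive-model single-variant association of every variant with a trait:
#' linear regression for continuous traits, logistic regression (log-odds
#' scale) for binary traits, optionally adjusted for covariates. Results are
#' deterministic given the inputs. Monomorphic variants are flagged in the
#' \code{note} column, never dropped.
#'
#' @param genotypes \linkS4class{GenotypeMatrix}.
#' @param trait numeric vector (binary 0/1 traits are detected and fitted by
#'   logistic regression); NAs allowed.
#' @param covariates optional data.frame of numeric covariates (e.g. age and
#'   sex coded 0/1).
#' @return data.frame with columns \code{variant}, \code{chrom}, \code{pos},
#'   \code{ea}, \code{oa}, \code{beta}, \code{se}, \code{p}, \code{n},
#'   \code{note} — effect sizes per effect-allele copy (log-odds for binary
#'   traits).
#' @export
computeSummaryStats <- function(genotypes, trait, covariates = NULL) {
  D <- dosage(genotypes)
  v <- variantInfo(genotypes)
  if (length(trait) != nrow(D))
    stop("trait length must match sample count")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(trait)
  if (!is.null(C)) keep <- keep & complete.cases(C)
  y <- trait[keep]
  D <- D[keep, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, sum(keep)),
              if (is.null(C)) NULL else C[keep, , drop = FALSE])
  binary <- all(y %in% c(0, 1))
  n <- length(y)
  out <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                    ea = v$ea, oa = v$oa, beta = NA_real_, se = NA_real_,
                    p = NA_real_, n = n, note = NA_character_,
                    stringsAsFactors = FALSE)
  mono <- apply(D, 2, function(g) var(g) == 0)
  out$note[mono] <- "monomorphic"
  idx <- which(!mono)
  if (binary) {
    for (j in idx) {
      x <- cbind(X0, g = D[, j])
      fit <- suppressWarnings(glm.fit(x, y, family = binomial()))
      p1 <- seq_len(fit$rank)
      cov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
      k <- ncol(x)
      out$beta[j] <- fit$coefficients[k]
      out$se[j] <- sqrt(cov[k, k])
      z <- out$beta[j] / out$se[j]
      out$p[j] <- 2 * pnorm(-abs(z))
      if (!fit$converged) out$note[j] <- "non_converged"
    }
  } else {
    ## Frisch-Waugh: residualize trait and dosages on the covariate design,
    ## then per-variant slopes with the full-model residual df.
    q0 <- qr(X0)
    ry <- qr.resid(q0, y)
    RG <- qr.resid(q0, D[, idx, drop = FALSE])
    gss <- colSums(RG^2)
    bet <- colSums(RG * ry) / gss
    df <- n - ncol(X0) - 1L
    rss <- sum(ry^2) - bet^2 * gss
    se <- sqrt(rss / df / gss)
    tval <- bet / se
    out$beta[idx] <- bet
    out$se[idx] <- se
    out$p[idx] <- 2 * pt(-abs(tval), df)
  }
  out
}

#' Simulate one cohort of the two-sample design
#'
#' Convenience wrapper producing genotypes, proteins and phenotypes for the
#' exposure sample or the outcome sample. Both samples share the variant map
#' (derived from the config seed alone) but are otherwise independent draws.
#'
#' @param config a \code{\link{simConfig}}.
#' @param which \code{"exposure"} or \code{"outcome"}.
#' @param rawScale passed to \code{\link{simulateProteins}}.
#' @return list with \code{genotypes}, \code{proteins}, \code{phenotypes},
#'   \code{confounder} and \code{trueParams}.
#' @export
simulateCohort <- function(config, which = c("exposure", "outcome"),
                           rawScale = FALSE) {
  which <- match.arg(which)
  off <- if (which == "exposure") 0L else 1000000L
  n <- if (which == "exposure") config$nExposure else config$nOutcome
  map <- makeVariantMap(config)
  geno <- simulateGenotypes(config, n, seed = config$seed + off + 11L, map = map)
  pr <- simulateProteins(geno, config, seed = config$seed + off + 12L,
                         rawScale = rawScale)
  phen <- simulateOutcome(pr$proteins, geno, config, confounder = pr$confounder,
                          seed = config$seed + off + 13L)
  list(genotypes = geno, proteins = pr$proteins, phenotypes = phen,
       confounder = pr$confounder,
       trueParams = c(pr$trueParams,
                      list(causalThetas = config$causalThetas,
                           directSnpEffects = config$directSnpEffects,
                           confounderOutcome = config$confounderOutcome)))
}
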