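# MR engine: instrument selection, harmonization, GWLS, Wald, weighted
# median, MR-Egger, BH adjustment, sensitivity gate.

# -- instrument selection ----------------------------------------------------

makeLdPanel <- function(r = 0.5, nVar = 10, n = 2000, seed = 601,
                        maf = c(0.25, 0.4)) {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = nVar, r = r, maf = maf)),
                   seed = seed)
  simulateGenotypes(cfg, n, seed = seed)
}

test_that("window-wide significance level is 0.05 over the variant count", {
  panel <- makeLdPanel(r = 0, nVar = 10, n = 500, seed = 611)
  v <- variantInfo(panel)
  expo <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                     ea = v$ea, oa = v$oa, beta = 0.3, se = 0.05,
                     p = 10^-(2:11), n = 500)
  gene <- list(gene = "G", analyte = "P", chrom = 1L,
               start = min(v$pos), end = max(v$pos))
  iset <- selectInstruments(expo, gene, mrConfig(), panel)
  expect_equal(iset@pb, 0.05 / 10)
  # P >= P_b pruned after clumping: p = 1e-2 (>= 5e-3) must be gone
  expect_false("b1v1" %in% instruments(iset)$variant)
})

test_that("greedy clumping matches an exhaustive pairwise-r2 oracle", {
  panel <- makeLdPanel(r = 0.45, nVar = 10, n = 3000, seed = 621)
  v <- variantInfo(panel)
  set.seed(622)
  pvals <- 10^-runif(10, 4, 12)
  expo <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                     ea = v$ea, oa = v$oa, beta = 0.3, se = 0.05,
                     p = pvals, n = 3000)
  gene <- list(gene = "G", analyte = "P", chrom = 1L,
               start = min(v$pos), end = max(v$pos))
  cfg <- mrConfig()
  iset <- selectInstruments(expo, gene, cfg, panel)
  got <- sort(instruments(iset)$variant)
  # oracle: repeatedly take the lowest-P remaining variant, discard all
  # variants at r2 >= 0.2 with it (all are within 1 Mb here)
  r2 <- cor(dosage(panel))^2
  remaining <- order(pvals)
  keep <- integer()
  while (length(remaining)) {
    i <- remaining[1]
    keep <- c(keep, i)
    remaining <- remaining[r2[remaining, i] < cfg$clumpR2]
  }
  keep <- keep[pvals[keep] < 0.05 / 10]
  expect_identical(got, sort(v$variant[keep]))
  # retained set is mutually below the clump threshold
  if (length(got) > 1) {
    sub <- r2[got, got]
    expect_lt(max(sub[upper.tri(sub)]), cfg$clumpR2)
  }
})

test_that("a fully correlated window keeps only the top variant", {
  panel <- makeLdPanel(r = 0.8, nVar = 5, n = 3000, seed = 631,
                       maf = c(0.35, 0.4))
  v <- variantInfo(panel)
  expo <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                     ea = v$ea, oa = v$oa, beta = 0.3, se = 0.05,
                     p = c(1e-8, 1e-6, 1e-7, 1e-5, 1e-9), n = 3000)
  gene <- list(gene = "G", analyte = "P", chrom = 1L,
               start = min(v$pos), end = max(v$pos))
  iset <- selectInstruments(expo, gene, mrConfig(), panel)
  expect_identical(instruments(iset)$variant, "b1v5")  # the lowest P
  # and an empty window marks the analyte untestable, not an error
  geneFar <- list(gene = "G2", analyte = "P2", chrom = 9L,
                  start = 1e6, end = 2e6)
  empty <- selectInstruments(expo, geneFar, mrConfig(), panel)
  expect_identical(empty@status, "no_instruments")
})

# -- harmonization and proxies ----------------------------------------------

test_that("harmonization aligns alleles, flips swapped records, keeps SEs", {
  panel <- makeLdPanel(r = 0.5, nVar = 4, n = 2000, seed = 641)
  v <- variantInfo(panel)
  dat <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                    ea = v$ea, oa = v$oa, betaX = c(0.3, 0.25, 0.2, 0.15),
                    seX = 0.02, pX = 1e-10, stringsAsFactors = FALSE)
  iset <- InstrumentSet("P", dat, ld = cor(dosage(panel)),
                        windowStats = data.frame())
  outc <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                     ea = c("A", "G", "A", "A"), oa = c("G", "A", "G", "G"),
                     beta = c(0.10, 0.08, -0.05, 0.02), se = 0.03,
                     p = 0.01, n = 9000)
  h <- harmonizeAndProxy(iset, outc, panel, mrConfig())
  hd <- instruments(h)
  expect_equal(hd$betaY, c(0.10, -0.08, -0.05, 0.02))   # swap negates
  expect_equal(hd$seY, rep(0.03, 4))
  expect_true(all(is.na(hd$proxyFor)))
  # perfectly aligned records are a no-op on betaX
  expect_equal(hd$betaX, dat$betaX)
})

test_that("missing outcome variants are proxied only above the r2 bound", {
  panel <- makeLdPanel(r = 0.9, nVar = 3, n = 4000, seed = 651,
                       maf = c(0.4, 0.45))
  v <- variantInfo(panel)
  r2 <- cor(dosage(panel))^2
  expect_gt(r2[1, 2], 0.8)                    # strong proxy available
  win <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                    ea = v$ea, oa = v$oa, beta = c(0.30, 0.28, 0.27),
                    se = 0.02, p = c(1e-12, 1e-11, 1e-10), n = 4000)
  dat <- data.frame(variant = "b1v1", chrom = 1L, pos = v$pos[1],
                    ea = "A", oa = "G", betaX = 0.30, seX = 0.02,
                    pX = 1e-12, stringsAsFactors = FALSE)
  iset <- InstrumentSet("P", dat, ld = matrix(1, 1, 1), windowStats = win)
  # outcome set lacks b1v1 but has b1v2/b1v3
  outc <- data.frame(variant = c("b1v2", "b1v3"), chrom = 1L,
                     pos = v$pos[2:3], ea = "A", oa = "G",
                     beta = c(0.09, 0.07), se = 0.03, p = 0.01, n = 9000)
  h <- harmonizeAndProxy(iset, outc, panel, mrConfig())
  hd <- instruments(h)
  expect_equal(nrow(hd), 1L)
  expect_identical(hd$proxyFor, "b1v1")
  # exposure effect re-estimated at the proxy, not transferred
  expect_equal(hd$betaX, win$beta[match(hd$variant, win$variant)])

  # weak panel: no proxy survives an r2 > 0.8 rule
  weak <- makeLdPanel(r = 0.5, nVar = 3, n = 4000, seed = 652)
  r2w <- cor(dosage(weak))^2
  expect_lt(max(r2w[upper.tri(r2w)]), 0.8)
  isetW <- InstrumentSet("P", dat, ld = matrix(1, 1, 1), windowStats = win)
  expect_message(hW <- harmonizeAndProxy(isetW, outc, weak, mrConfig()),
                 "no qualifying proxy")
  expect_identical(hW@status, "no_instruments")
})

test_that("ambiguous palindromic variants are dropped", {
  panel <- makeLdPanel(r = 0, nVar = 2, n = 2000, seed = 661,
                       maf = c(0.44, 0.46))
  v <- variantInfo(panel)
  dat <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                    ea = c("A", "A"), oa = c("T", "G"),
                    betaX = c(0.3, 0.3), seX = 0.02, pX = 1e-10,
                    stringsAsFactors = FALSE)
  iset <- InstrumentSet("P", dat, ld = diag(2), windowStats = data.frame())
  outc <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                     ea = c("A", "A"), oa = c("T", "G"),
                     beta = 0.1, se = 0.03, p = 0.01, n = 9000)
  expect_message(h <- harmonizeAndProxy(iset, outc, panel, mrConfig()),
                 "palindromic")
  # the A/T variant at MAF ~0.45 goes; the A/G variant stays
  expect_identical(instruments(h)$variant, v$variant[2])
})

# -- estimators --------------------------------------------------------------

test_that("GWLS reproduces the worked two-instrument example", {
  iset <- toyInstrumentSet(betaX = c(0.4, 0.2), betaY = c(0.2, 0.12),
                           seY = c(0.1, 0.1))
  est <- gwlsEstimate(iset, mrConfig())
  expect_equal(est@estimate, 0.52, tolerance = 1e-12)
  expect_equal(est@alpha, 1, tolerance = 1e-12)
  expect_equal(est@se, sqrt(1 / 20), tolerance = 1e-12)
  # zero-residual case: exact fit, MSE = 0
  iset2 <- toyInstrumentSet(betaX = c(0.4, 0.2, 0.1),
                            betaY = c(0.4, 0.2, 0.1), seY = c(0.1, 0.2, 0.1))
  est2 <- gwlsEstimate(iset2, mrConfig())
  expect_equal(est2@estimate, 1, tolerance = 1e-12)
  expect_equal(est2@mse, 0, tolerance = 1e-12)
  expect_equal(est2@alpha, 1)
})

test_that("GWLS at rho = I equals closed-form IVW on random fixtures", {
  set.seed(671)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    bX <- runif(m, 0.05, 0.6) * sample(c(-1, 1), m, replace = TRUE)
    bY <- 0.3 * bX + rnorm(m, sd = 0.05)
    sY <- runif(m, 0.02, 0.2)
    est <- gwlsEstimate(toyInstrumentSet(bX, bY, sY), mrConfig())
    expect_equal(est@estimate, ivwOracle(bX, bY, sY), tolerance = 1e-10)
  }
})

test_that("GWLS with one instrument is exactly the Wald ratio", {
  iset <- toyInstrumentSet(betaX = 0.5, betaY = 0.25, seY = 0.1)
  g <- gwlsEstimate(iset, mrConfig())
  w <- waldRatio(iset, mrConfig())
  expect_identical(g@estimate, w@estimate)
  expect_identical(g@se, w@se)
  expect_identical(g@p, w@p)
  expect_equal(w@estimate, 0.5)
  expect_equal(w@se, 0.2)
  expect_equal(waldRatio(toyInstrumentSet(0.5, 0, 0.1))@estimate, 0)
  expect_error(waldRatio(toyInstrumentSet(0, 0.1, 0.1)), "beta_X = 0")
})

test_that("GWLS is invariant to simultaneous allele flips", {
  set.seed(681)
  m <- 5
  A <- matrix(rnorm(m * m), m); ld <- cov2cor(crossprod(A) + diag(m))
  bX <- runif(m, 0.1, 0.5); bY <- 0.4 * bX + rnorm(m, sd = 0.02)
  sY <- runif(m, 0.02, 0.1)
  base <- gwlsEstimate(toyInstrumentSet(bX, bY, sY, ld = ld), mrConfig())
  flip <- c(1, -1, -1, 1, -1)
  ldF <- ld * tcrossprod(flip)
  flipped <- gwlsEstimate(toyInstrumentSet(bX * flip, bY * flip, sY, ld = ldF),
                          mrConfig())
  expect_equal(flipped@estimate, base@estimate, tolerance = 1e-12)
  expect_equal(flipped@se, base@se, tolerance = 1e-12)
  # rescaling all outcome SEs rescales the SE when alpha = 1
  exact <- toyInstrumentSet(bX, 0.4 * bX, sY, ld = ld)
  e1 <- gwlsEstimate(exact, mrConfig())
  e2 <- gwlsEstimate(toyInstrumentSet(bX, 0.4 * bX, 3 * sY, ld = ld),
                     mrConfig())
  expect_equal(e2@se / e1@se, 3, tolerance = 1e-10)
})

test_that("weighted median interpolates correctly and is robust", {
  # equal ratios collapse to the common value
  allSame <- toyInstrumentSet(c(0.2, 0.4, 0.5), c(0.2, 0.4, 0.5) * 0.7,
                              seY = c(0.1, 0.1, 0.1))
  expect_equal(weightedMedian(allSame, mrConfig(wmBoot = 50))@estimate, 0.7,
               tolerance = 1e-12)
  # ratios (0.2, 0.5, 0.9) with equal weights -> 0.5
  bX <- c(1, 1, 1); sY <- c(1, 1, 1)
  wm <- weightedMedian(toyInstrumentSet(bX, c(0.2, 0.5, 0.9), sY),
                       mrConfig(wmBoot = 50))
  expect_equal(wm@estimate, 0.5, tolerance = 1e-12)
  expect_error(weightedMedian(toyInstrumentSet(c(1, 1), c(1, 1), c(1, 1))),
               "at least 3")

  # 40% contaminated instruments: weighted median beats IVW on bias
  set.seed(691)
  biasWM <- biasIVW <- numeric(100)
  for (i in 1:100) {
    m <- 10
    bXs <- runif(m, 0.2, 0.6)
    sYs <- rep(0.05, m)
    off <- c(rep(0.25, 4), rep(0, 6))          # pleiotropic offset on 40%
    bYs <- 0.3 * bXs + off + rnorm(m, sd = sYs)
    iset <- toyInstrumentSet(bXs, bYs, sYs)
    biasWM[i] <- proteoMR:::weightedMedianPoint(bYs / bXs, bXs^2 / sYs^2) - 0.3
    biasIVW[i] <- ivwOracle(bXs, bYs, sYs) - 0.3
  }
  expect_lt(abs(mean(biasWM)), abs(mean(biasIVW)))
})

test_that("MR-Egger is exact on linear data and matches normal equations", {
  # exact linear relation: slope and intercept recovered with zero residual
  bX <- c(0.2, 0.4, 0.6)
  iset <- toyInstrumentSet(bX, 0.1 + 0.5 * bX, seY = c(0.1, 0.1, 0.1))
  e <- mrEgger(iset, mrConfig())
  expect_equal(e@estimate, 0.5, tolerance = 1e-10)
  expect_equal(e@eggerIntercept, 0.1, tolerance = 1e-10)
  expect_equal(e@mse, 0, tolerance = 1e-10)

  # weighted normal-equations oracle on a 5-instrument toy set (rho = I)
  set.seed(701)
  bX5 <- runif(5, 0.1, 0.7)
  sY5 <- runif(5, 0.05, 0.2)
  bY5 <- 0.05 + 0.4 * bX5 + rnorm(5, sd = 0.05)
  e5 <- mrEgger(toyInstrumentSet(bX5, bY5, sY5), mrConfig())
  W <- diag(1 / sY5^2)
  Xd <- cbind(1, bX5)
  cf <- solve(t(Xd) %*% W %*% Xd, t(Xd) %*% W %*% bY5)
  expect_equal(e5@eggerIntercept, cf[1], tolerance = 1e-10)
  expect_equal(e5@estimate, cf[2], tolerance = 1e-10)
  # SEs from the same normal equations with the residual variance floor
  res <- bY5 - Xd %*% cf
  s2 <- drop(t(res) %*% W %*% res) / 3
  covO <- solve(t(Xd) %*% W %*% Xd) * max(1, s2)
  expect_equal(e5@se, sqrt(covO[2, 2]), tolerance = 1e-10)

  expect_error(mrEgger(toyInstrumentSet(c(0.3, 0.3, 0.3), c(1, 1, 1),
                                        c(0.1, 0.1, 0.1))),
               "unidentifiable")
})

test_that("Egger intercept is calibrated under no pleiotropy", {
  set.seed(711)
  rej <- 0L
  for (i in 1:200) {
    m <- 8
    bXs <- runif(m, 0.2, 0.6)
    sYs <- runif(m, 0.04, 0.08)
    bYs <- 0.3 * bXs + rnorm(m, sd = sYs)
    e <- mrEgger(toyInstrumentSet(bXs, bYs, sYs), mrConfig())
    if (e@eggerInterceptP < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 200 - 0.05), 0.05)
})

# -- BH and the gate ---------------------------------------------------------

test_that("BH adjustment matches the hand-computed step-up", {
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(0.2, 7)), rep(0.2, 7))
  # random vector vs an independent step-up implementation
  set.seed(721)
  p <- runif(30)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  oracle <- numeric(m)
  running <- 1
  for (k in seq_along(o)) {
    i <- o[k]
    rank <- m - k + 1
    running <- min(running, p[i] * m / rank)
    oracle[i] <- running
  }
  expect_equal(bhAdjust(p), oracle, tolerance = 1e-12)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
})

test_that("the two-step sensitivity gate follows its ordering", {
  mk <- function(est, p, fdr = NA_real_, intP = NA_real_, method = "gwls") {
    e <- proteoMR:::MREstimateRecord("P", method, est, 0.1, p, 5,
                          eggerIntercept = if (method == "egger") 0.01 else NA_real_,
                          eggerInterceptP = intP)
    e@fdr <- fdr
    e
  }
  cfg <- mrConfig()
  g <- mk(0.5, 1e-4, fdr = 0.2)
  expect_identical(gateStatus(sensitivityGate(g, NULL, NULL, cfg)),
                   "not_tested")
  gSig <- mk(0.5, 1e-4, fdr = 0.01)
  wmBad <- mk(-0.4, 0.01, method = "weighted_median")
  wmWeak <- mk(0.5, 0.2, method = "weighted_median")
  wmGood <- mk(0.45, 0.01, method = "weighted_median")
  egBad <- mk(0.5, 0.01, intP = 0.01, method = "egger")
  egGood <- mk(0.4, 0.04, intP = 0.4, method = "egger")
  expect_identical(gateStatus(sensitivityGate(gSig, wmBad, egGood, cfg)),
                   "failed_step1")
  expect_identical(gateStatus(sensitivityGate(gSig, wmWeak, egGood, cfg)),
                   "failed_step1")
  expect_identical(gateStatus(sensitivityGate(gSig, wmGood, egBad, cfg)),
                   "failed_step2")
  expect_identical(gateStatus(sensitivityGate(gSig, wmGood, egGood, cfg)),
                   "causal_candidate")
  expect_error(sensitivityGate(gSig, NULL, NULL, cfg), "missing")
  expect_error(sensitivityGate(mk(0.5, 1e-4), wmGood, egGood, cfg), "FDR")
})

# -- end-to-end over several analytes ---------------------------------------

test_that("mrAnalysis recovers a causal protein and skips an untestable one", {
  cfg <- simConfig(
    blocks = list(list(chrom = 1L, n = 6L, r = 0.4, maf = c(0.25, 0.4))),
    nProteins = 2L,
    cisEffects = data.frame(protein = "P001",
                            variant = c("b1v1", "b1v2"),
                            beta = c(0.35, 0.25)),
    causalThetas = c(P001 = 0.6),
    prevalence = 0.1, nExposure = 4000L, nOutcome = 4000L, seed = 731)
  expo <- simulateCohort(cfg, "exposure")
  outc <- simulateCohort(cfg, "outcome")
  scan <- snpProteinScan(expo$genotypes, expo$proteins, expo$phenotypes,
                         pThreshold = 1)
  covs <- data.frame(age = outc$phenotypes$age,
                     sex = as.numeric(outc$phenotypes$sex == "F"))
  ssY <- computeSummaryStats(outc$genotypes, outc$phenotypes$case,
                             covariates = covs)
  genes <- analyteInfo(expo$proteins)
  res <- mrAnalysis(list(P001 = exposureStats(scan, "P001"),
                         P002 = exposureStats(scan, "P002")),
                    ssY, genes, expo$genotypes, mrConfig(wmBoot = 200),
                    seed = 732)
  est <- res$estimates
  gw <- est[est$analyte == "P001" & est$method == "gwls", ]
  expect_equal(nrow(gw), 1L)
  # true effect within 3 SE of the estimate
  expect_lt(abs(gw$estimate - 0.6), 3 * gw$se)
  # P002 has no cis pQTL: every window variant fails P_b
  expect_false("P002" %in% est$analyte)
  expect_identical(res$instrumentSets$P002@status, "no_instruments")
})
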