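# Synthetic cohort generator: LD-structured genotypes, genetically
# regulated proteins, staged outcome, and summary statistics.

test_that("genotypes without LD follow Hardy-Weinberg proportions", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 1L, r = 0,
                                      maf = c(0.3, 0.3))), seed = 21)
  g <- simulateGenotypes(cfg, 10000, seed = 21)
  d <- dosage(g)[, 1]
  freq <- tabulate(d + 1, 3) / length(d)
  # expected 0.49 / 0.42 / 0.09 for the non-effect homozygote downwards
  expect_equal(freq, c(0.49, 0.42, 0.09), tolerance = 0.05)
  expect_true(all(d %in% 0:2))
})

test_that("within-block genotype correlation matches the signed target", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 5L, r = 0.5,
                                      maf = c(0.25, 0.35))), seed = 31)
  g <- simulateGenotypes(cfg, 5000, seed = 31)
  r <- cor(dosage(g))
  expect_lt(abs(mean(r[upper.tri(r)]) - 0.5), 0.05)

  cfgNeg <- simConfig(blocks = list(list(chrom = 1L, n = 3L, r = -0.3,
                                         maf = c(0.3, 0.4))), seed = 32)
  gn <- simulateGenotypes(cfgNeg, 5000, seed = 32)
  rn <- cor(dosage(gn))
  expect_lt(abs(mean(rn[upper.tri(rn)]) - (-0.3)), 0.05)
})

test_that("blocks on different chromosomes are uncorrelated", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 4L, r = 0.6, maf = c(0.25, 0.35)),
                                 list(chrom = 2L, n = 4L, r = 0.6, maf = c(0.25, 0.35))),
                   seed = 41)
  g <- simulateGenotypes(cfg, 5000, seed = 41)
  v <- variantInfo(g)
  r <- cor(dosage(g))
  cross <- r[v$chrom == 1, v$chrom == 2]
  expect_lt(max(abs(cross)), 0.05)
})

test_that("infeasible target correlations are rejected with a diagnostic", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 2L, r = 0.9,
                                      maf = c(0.05, 0.45))), seed = 51)
  set.seed(51)
  expect_error(makeVariantMap(cfg), "infeasible")
})

test_that("identical configuration gives bit-identical outputs", {
  cfg <- smallConfig(seed = 61, n = 200)
  a <- simulateCohort(cfg, "exposure")
  b <- simulateCohort(cfg, "exposure")
  expect_identical(dosage(a$genotypes), dosage(b$genotypes))
  expect_identical(assayValues(a$proteins), assayValues(b$proteins))
  expect_identical(a$phenotypes, b$phenotypes)
  # exposure and outcome samples share the variant map but not draws
  o <- simulateCohort(cfg, "outcome")
  expect_identical(variantInfo(a$genotypes), variantInfo(o$genotypes))
  expect_false(identical(dosage(a$genotypes)[1:10, 1],
                         dosage(o$genotypes)[1:10, 1]))
})

test_that("configured cis effect is recovered by per-allele regression", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 1L, r = 0,
                                      maf = c(0.3, 0.3))),
                   nProteins = 1L,
                   cisEffects = data.frame(protein = "P001", variant = "b1v1",
                                           beta = 0.6),
                   nExposure = 2000L, seed = 71)
  g <- simulateGenotypes(cfg, 2000, seed = 71)
  pr <- simulateProteins(g, cfg, seed = 72)
  fit <- summary(lm(assayValues(pr$proteins)[, 1] ~ dosage(g)[, 1]))
  est <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(est - 0.6), 1.96 * se + 1e-12)
  # total variance is ~1 so the effect is on the SD scale
  expect_equal(var(assayValues(pr$proteins)[, 1]), 1, tolerance = 0.1)
})

test_that("module proteins reach the target within-module correlation", {
  cfg <- smallConfig(seed = 81, n = 5000)
  g <- simulateGenotypes(cfg, 5000, seed = 81)
  pr <- simulateProteins(g, cfg, seed = 82)
  X <- assayValues(pr$proteins)[, cfg$moduleAssign == 1L]
  r <- cor(X)
  expect_lt(abs(mean(r[upper.tri(r)]) - 0.4), 0.05)
})

test_that("null proteins give uniform association P-values", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 5L, r = 0,
                                      maf = c(0.2, 0.4))),
                   nProteins = 40L, nExposure = 300L, seed = 91)
  g <- simulateGenotypes(cfg, 300, seed = 91)
  pr <- simulateProteins(g, cfg, seed = 92)
  ps <- unlist(lapply(seq_len(40), function(j)
    computeSummaryStats(g, assayValues(pr$proteins)[, j])$p))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("overcommitted variance budget is rejected", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 1L, r = 0,
                                      maf = c(0.4, 0.4))),
                   nProteins = 1L,
                   cisEffects = data.frame(protein = "P001", variant = "b1v1",
                                           beta = 2.0),
                   nExposure = 500L, seed = 93)
  g <- simulateGenotypes(cfg, 500, seed = 93)
  expect_error(simulateProteins(g, cfg, seed = 94), "variance share")
})

test_that("intercept-only outcome hits the target prevalence and labels nest", {
  cfg <- simConfig(nProteins = 1L, prevalence = 0.2, ageEffect = 0,
                   sexEffect = 0, nExposure = 5000L, seed = 101)
  co <- simulateCohort(cfg, "exposure")
  phen <- co$phenotypes
  pHat <- mean(phen$case)
  expect_lt(abs(pHat - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  # late subtype only for late stage; early_B nested in early_A
  expect_true(all(phen$late_subtype == "none" | phen$stage == "late"))
  expect_true(all(!phen$early_B | phen$early_A))
  expect_true(any(phen$early_A & !phen$early_B))
  # follow-up labels only for re-examined subjects
  expect_true(all(is.na(phen$followup_stage) == !phen$reexamined))
})

test_that("summary statistics match a full-fit regression oracle", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 50L, r = 0.3,
                                      maf = c(0.1, 0.45))),
                   nProteins = 1L, nExposure = 500L, seed = 111)
  co <- simulateCohort(cfg, "exposure")
  g <- co$genotypes
  y <- assayValues(co$proteins)[, 1]
  covs <- data.frame(age = co$phenotypes$age,
                     sex = as.numeric(co$phenotypes$sex == "F"))
  ss <- computeSummaryStats(g, y, covariates = covs)
  for (j in seq(1, 50, by = 7)) {
    fit <- summary(lm(y ~ dosage(g)[, j] + covs$age + covs$sex))
    expect_equal(ss$beta[j], fit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(ss$se[j], fit$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(ss$p[j], fit$coefficients[2, 4], tolerance = 1e-8)
  }
  # binary trait: logistic oracle on a few variants
  yb <- co$phenotypes$case
  ssb <- computeSummaryStats(g, yb, covariates = covs)
  for (j in c(1, 25, 50)) {
    fit <- summary(glm(yb ~ covs$age + covs$sex + dosage(g)[, j],
                       family = binomial()))
    expect_equal(ssb$beta[j], fit$coefficients[4, 1], tolerance = 1e-6)
    expect_equal(ssb$se[j], fit$coefficients[4, 2], tolerance = 1e-6)
  }
})

test_that("allele recoding negates beta and a permuted trait is null", {
  cfg <- simConfig(blocks = list(list(chrom = 1L, n = 20L, r = 0,
                                      maf = c(0.2, 0.4))),
                   nProteins = 1L, nExposure = 400L, seed = 121)
  co <- simulateCohort(cfg, "exposure")
  g <- co$genotypes
  y <- assayValues(co$proteins)[, 1]
  ss <- computeSummaryStats(g, y)
  v <- variantInfo(g)
  flipped <- GenotypeMatrix(2 - dosage(g),
                            transform(v, ea = oa, oa = ea, maf = 1 - maf))
  ssf <- computeSummaryStats(flipped, y)
  expect_equal(ssf$beta, -ss$beta, tolerance = 1e-12)
  expect_equal(ssf$se, ss$se, tolerance = 1e-12)
  expect_equal(ssf$p, ss$p, tolerance = 1e-12)
  # permuted trait: P below 0.05 about 5% of the time
  set.seed(122)
  ps <- replicate(25, computeSummaryStats(g, sample(y))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("monomorphic variants are flagged, not dropped", {
  d <- cbind(v1 = c(1, 2, 0, 1, 2, 1), v2 = rep(2, 6))
  v <- data.frame(variant = c("v1", "v2"), chrom = 1L, pos = c(100L, 200L),
                  ea = "A", oa = "G", maf = c(0.5, 1))
  g <- GenotypeMatrix(d, v)
  ss <- computeSummaryStats(g, rnorm(6))
  expect_equal(nrow(ss), 2L)
  expect_identical(ss$note[2], "monomorphic")
  expect_true(is.na(ss$beta[2]))
  expect_false(is.na(ss$beta[1]))
})

test_that("container validity catches malformed objects", {
  v <- data.frame(variant = c("a", "b"), chrom = 1L, pos = c(2L, 1L),
                  ea = "A", oa = "G", maf = 0.3)
  expect_error(GenotypeMatrix(matrix(0, 2, 2), v), "increasing")
  v$pos <- c(1L, 2L)
  expect_error(GenotypeMatrix(matrix(3, 2, 2), v), "within")
  expect_error(simConfig(prevalence = 1.2), "prevalence")
  expect_error(simConfig(causalThetas = c(P009 = 1)), "unknown protein")
})
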