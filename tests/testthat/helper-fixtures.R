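# Shared fixture builders for the test suite. Everything is generated in
# code; seeds are fixed so the suite is deterministic.

# A small multi-protein configuration: two LD blocks on different
# chromosomes, one cis-regulated protein, one 20-protein module.
smallConfig <- function(seed = 11, n = 800) {
  simConfig(
    blocks = list(list(chrom = 1L, n = 5L, r = 0.5, maf = c(0.25, 0.35)),
                  list(chrom = 2L, n = 4L, r = 0.3, maf = c(0.2, 0.4))),
    nProteins = 22L,
    moduleAssign = c(0L, 0L, rep(1L, 20L)),
    moduleR = c(0.4),
    cisEffects = data.frame(protein = "P001", variant = "b1v1", beta = 0.6,
                            stringsAsFactors = FALSE),
    nExposure = n, nOutcome = n, seed = seed)
}

# Hand-built instrument set from explicit summary statistics.
toyInstrumentSet <- function(betaX, betaY, seY, ld = NULL,
                             seX = rep(NA_real_, length(betaX))) {
  m <- length(betaX)
  InstrumentSet("toy", data.frame(
    variant = paste0("v", seq_len(m)), chrom = 1L,
    pos = 1e6 + seq_len(m) * 1000, ea = "A", oa = "G",
    betaX = betaX, seX = seX, pX = NA_real_,
    betaY = betaY, seY = seY, stringsAsFactors = FALSE), ld = ld)
}

# Closed-form inverse-variance-weighted estimate (independent instruments):
# the textbook formula, used as the oracle for gwlsEstimate at rho = I.
ivwOracle <- function(betaX, betaY, seY) {
  w <- 1 / seY^2
  sum(w * betaX * betaY) / sum(w * betaX^2)
}

# ProteinMatrix wrapper around a bare matrix, one gene per analyte.
quickProteinMatrix <- function(X, state = "transformed") {
  p <- ncol(X)
  ids <- sprintf("A%03d", seq_len(p))
  colnames(X) <- ids
  ProteinMatrix(X, data.frame(analyte = ids, gene = sub("A", "G", ids),
                              chrom = 22L, start = 1e6 + seq_len(p) * 1e5,
                              end = 1e6 + seq_len(p) * 1e5 + 2e4,
                              stringsAsFactors = FALSE), state = state)
}

# Minimal phenotype table with a given case vector.
quickPhen <- function(y, age = NULL, sex = NULL, seed = 5) {
  set.seed(seed)
  n <- length(y)
  if (is.null(age)) age <- 76 + 5 * rnorm(n)
  if (is.null(sex)) sex <- ifelse(runif(n) < 0.57, "F", "M")
  data.frame(sample = sprintf("s%05d", seq_len(n)), age = age, sex = sex,
             case = y, stage = ifelse(y == 1, "late", "none"),
             early_A = FALSE, early_B = FALSE,
             late_subtype = ifelse(y == 1, "GA_pure", "none"),
             reexamined = FALSE, followup_stage = NA_character_,
             stringsAsFactors = FALSE)
}
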