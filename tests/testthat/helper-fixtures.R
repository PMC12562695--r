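# Shared fixtures: reduced device profiles (desk-scale geometry, same FOV
# and quality rules as the stock profiles) and brute-force statistical
# oracles used to cross-check the vectorized implementations.

tiny_profile <- function() {
  deviceProfile("spectralis", nativeDims = c(32L, 16L, 8L),
                netInputDims = c(8L, 8L, 4L))
}

small_profile <- function() {
  deviceProfile("spectralis", nativeDims = c(96L, 64L, 32L),
                netInputDims = c(32L, 32L, 16L))
}

tiny_cohort <- function(dir, nSubjects = 3L, visits = 2L, seed = 7L,
                        profile = tiny_profile(), namdFraction = 0,
                        speckleSigma = 0.1) {
  params <- syntheticParams(device = profile, nSubjects = nSubjects,
                            visitsPerEye = visits, speckleSigma = speckleSigma,
                            namdFraction = namdFraction,
                            focusRadiusRangeMM = c(0.8, 1.5), seed = seed)
  generateCohort(params, dir)
}

# synthetic metadata-only cohort (no files) for fold-assignment audits
random_records <- function(nSubjects, maxScans, seed) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nSubjects), function(s) {
    n <- sample.int(maxScans, 1)
    data.frame(subject_id = sprintf("S%03d", s),
               eye = "OD", visit_index = seq_len(n) - 1L,
               device = "spectralis",
               quality_score = runif(n, 26, 40),
               has_nAMD = FALSE, has_GA = TRUE,
               volume_path = "", mask_path = "",
               stringsAsFactors = FALSE)
  }))
  rows$record_id <- paste(rows$subject_id, rows$eye, rows$visit_index,
                          sep = "_")
  rows
}

# ---- brute-force oracles (plain loops, independent of the package code) ----

oracle_dsc <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    sa <- sa + a[i]; sb <- sb + b[i]
  }
  if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  (sxy / sqrt(sxx * syy))^2
}

oracle_bland_altman <- function(auto, manual) {
  n <- length(auto)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- manual[i] - auto[i]
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  c(bias = bias, lo = bias - 1.96 * s, hi = bias + 1.96 * s)
}

oracle_ttest <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  v1 <- sum((a - m1)^2) / (n1 - 1)
  v2 <- sum((b - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = t, p = 2 * stats::pt(-abs(t), df = n1 + n2 - 2))
}

oracle_fisher_z <- function(r1, n1, r2, n2) {
  z <- (0.5 * log((1 + r1) / (1 - r1)) - 0.5 * log((1 + r2) / (1 - r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}
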