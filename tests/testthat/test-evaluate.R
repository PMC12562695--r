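test_that("Dice similarity matches closed-form counts and its conventions", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, 1 - a), 0)
  # |A|=4, |B|=4, |A n B|=2 -> 0.5
  A <- matrix(0, 4, 2); A[1:4, 1] <- 1
  B <- matrix(0, 4, 2); B[3:4, ] <- 1
  expect_equal(dsc(A, B), 0.5)
  expect_equal(dsc(matrix(0, 3, 3), matrix(0, 3, 3)), 1)  # empty agreement
  # symmetry and range over random masks
  set.seed(8)
  for (i in 1:25) {
    x <- matrix(rbinom(24, 1, runif(1)), 6, 4)
    y <- matrix(rbinom(24, 1, runif(1)), 6, 4)
    expect_equal(dsc(x, y), dsc(y, x))
    expect_true(dsc(x, y) >= 0 && dsc(x, y) <= 1)
  }
})

test_that("lesion areas conserve the field of view and are additive", {
  # full 128x64 mask over a 6x6 mm FOV -> 36 mm^2
  px <- (6 / 128) * (6 / 64)
  expect_equal(areaMM2(EnFaceMask(matrix(1, 128, 64), px)), 36)
  one <- matrix(0, 128, 64); one[5, 9] <- 1
  expect_equal(areaMM2(EnFaceMask(one, px)), 0.00439453125)
  expect_equal(areaMM2(EnFaceMask(matrix(0, 128, 64), px)), 0)
  # additivity over disjoint masks
  g1 <- matrix(0, 8, 8); g1[1:3, ] <- 1
  g2 <- matrix(0, 8, 8); g2[6:8, ] <- 1
  expect_equal(areaMM2(EnFaceMask(g1 + g2, 0.3)),
               areaMM2(EnFaceMask(g1, 0.3)) + areaMM2(EnFaceMask(g2, 0.3)))
})

test_that("r^2, Bland-Altman and the t-test match their textbook forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonR2(x, 2 * x + 1), 1)
  expect_equal(pearsonR2(x, -x), 1)
  expect_equal(pearsonR2(c(1, 2, 3), c(1, 2, 4)),
               oracle_r2(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_error(pearsonR2(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearsonR2(c(1, 2), c(1, 2)), "at least 3")

  ba <- blandAltman(x, x)
  expect_equal(unlist(ba), c(bias = 0, loaLow = 0, loaHigh = 0))
  ba2 <- blandAltman(x, x + 2)
  expect_equal(unlist(ba2), c(bias = 2, loaLow = 2, loaHigh = 2))
  ba3 <- blandAltman(c(1, 0), c(0, 1))  # d = (-1, 1)
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$loaHigh, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(blandAltman(1, 1), "at least 2")

  tt <- studentTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  tt0 <- studentTTest(c(0, 0), c(1, 1))
  expect_equal(tt0$p, 0)
  o <- oracle_ttest(c(1, 2, 3), c(2, 3, 4))
  tt2 <- studentTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt2$t, unname(o["t"]), tolerance = 1e-12)
  expect_equal(tt2$p, unname(o["p"]), tolerance = 1e-12)
})

test_that("the Fisher-z comparison of correlations behaves at and away from equality", {
  expect_equal(compareCorrelations(0.9, 50, 0.9, 200)$p, 1)
  got <- compareCorrelations(0.97, 100, 0.85, 267)
  expect_equal(got$p, oracle_fisher_z(0.97, 100, 0.85, 267), tolerance = 1e-12)
  expect_lt(got$p, 0.05)  # clearly different correlations are detected
  expect_error(compareCorrelations(1, 10, 0.5, 10), "boundary")
  expect_error(compareCorrelations(0.5, 3, 0.5, 10), "n >= 4")
})

test_that("strata correlation comparison works from a per-scan table", {
  set.seed(12)
  n1 <- 30L; n2 <- 20L
  m1 <- runif(n1, 1, 10); m2 <- runif(n2, 1, 10)
  ps <- data.frame(
    area_manual_mm2 = c(m1, m2),
    area_auto_mm2 = c(m1 + rnorm(n1, 0, 0.1), m2 + rnorm(n2, 0, 3)),
    has_nAMD = rep(c(FALSE, TRUE), c(n1, n2)))
  out <- compareR2Strata(ps)
  expect_equal(out$n_GA_only, n1)
  expect_equal(out$p, compareCorrelations(out$r_GA_only, n1,
                                          out$r_GA_nAMD, n2)$p)
  expect_gt(out$r_GA_only, out$r_GA_nAMD)
  expect_error(compareR2Strata(ps[c(1:3, 31:40), ]), "at least 4")
})

test_that("connected-component counts use 8-connectivity", {
  e <- matrix(0, 6, 6)
  expect_equal(unname(coalescenceDiagnostic(e, e)), c(0L, 0L))
  blob <- e; blob[2:4, 2:4] <- 1
  expect_equal(unname(coalescenceDiagnostic(blob, blob)), c(1L, 1L))
  # two 1-px foci separated by one background px vs their filled union
  manual <- e; manual[2, 2] <- 1; manual[2, 4] <- 1
  auto <- e; auto[2, 2:4] <- 1
  expect_equal(unname(coalescenceDiagnostic(auto, manual)), c(1L, 2L))
  # diagonal touch counts as connected
  diagm <- e; diagm[1, 1] <- 1; diagm[2, 2] <- 1
  expect_equal(unname(coalescenceDiagnostic(diagm, diagm)), c(1L, 1L))
})

test_that("a miniature cross-validation partitions the cohort without leakage", {
  dir <- withr::local_tempdir()
  rec <- tiny_cohort(dir, nSubjects = 5L, visits = 2L, seed = 17L)
  prof <- tiny_profile()
  netCfg <- netConfig(prof@netInputDims, levels = 2L, baseChannels = 2L,
                      seed = 1L)
  tc <- trainConfig(epochs = 1L, batchSize = 4L, patience = 1L,
                    learningRate = 1e-3, seed = 1L)
  rep <- crossValidate(rec, prof, netCfg, tc, nFolds = 3L, seed = 9L)
  expect_s4_class(rep, "EvalReport")
  expect_identical(sort(rep@perScan$record_id), sort(rec$record_id))
  expect_false(anyDuplicated(rep@perScan$record_id) > 0)
  # no subject's scans span a fold boundary
  sub <- sub("_OD.*", "", rep@perScan$record_id)
  expect_true(all(tapply(rep@perScan$fold, sub,
                         function(f) length(unique(f))) == 1L))
  expect_true(all(rep@perScan$dsc >= 0 & rep@perScan$dsc <= 1))
  expect_true(rep@loa[1] <= rep@bias && rep@bias <= rep@loa[2])
})

test_that("longitudinal reports are sorted, complete, and reject mixed eyes", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile()
  params <- syntheticParams(device = prof, nSubjects = 1L, visitsPerEye = 4L,
                            speckleSigma = 0.1, namdFraction = 0, seed = 23L)
  rec <- generateCohort(params, dir)
  net <- buildNet(netConfig(prof@netInputDims, levels = 2L, baseChannels = 2L,
                            seed = 1L))
  tab <- longitudinalReport(rec, net, prof)
  expect_equal(tab$visit_index, 0:3)
  perm <- rec[c(3, 1, 4, 2), ]
  expect_equal(longitudinalReport(perm, net, prof), tab)
  mixed <- rec; mixed$eye[2] <- "OS"
  expect_error(longitudinalReport(mixed, net, prof), "single subject-eye")
})

test_that("agreement plots build from a report", {
  skip_if_not_installed("ggplot2")
  ps <- data.frame(record_id = letters[1:6], dsc = runif(6, 0.7, 1),
                   area_manual_mm2 = 1:6,
                   area_auto_mm2 = (1:6) + rnorm(6, 0, 0.1),
                   has_nAMD = rep(c(TRUE, FALSE), 3))
  rep <- oct3d2d:::summarize_per_scan(ps)
  expect_no_error(plotAgreement(rep))
})
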