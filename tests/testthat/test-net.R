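test_that("output shape is a pure function of the configuration", {
  cases <- list(list(dims = c(16L, 16L, 8L), levels = 2L),
                list(dims = c(8L, 16L, 16L), levels = 2L),
                list(dims = c(4L, 32L, 8L), levels = 3L))
  for (cs in cases) {
    net <- buildNet(netConfig(cs$dims, levels = cs$levels, baseChannels = 2L,
                              seed = 1L))
    p <- netForward(net, array(rnorm(prod(cs$dims)), cs$dims))
    expect_identical(dim(p), cs$dims[2:3])
    expect_true(all(maskGrid(p) >= 0 & maskGrid(p) <= 1))
  }
  expect_error(netConfig(c(16L, 12L, 8L), levels = 3L), "divisible")
})

test_that("builds are deterministic under the configuration seed", {
  cfg <- netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 3L, seed = 11L)
  expect_identical(netChecksum(buildNet(cfg)), netChecksum(buildNet(cfg)))
  cfg2 <- netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 3L, seed = 12L)
  expect_false(netChecksum(buildNet(cfg2)) == netChecksum(buildNet(cfg)))
})

test_that("inference is deterministic and a zeroed final layer gives exactly 0.5", {
  net <- buildNet(netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 3L,
                            seed = 2L))
  vol <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_identical(maskGrid(netForward(net, vol)),
                   maskGrid(netForward(net, vol)))
  p <- netParameters(net)
  p$fW[] <- 0; p$fb[] <- 0
  netParameters(net) <- p
  expect_true(all(maskGrid(netForward(net, vol)) == 0.5))
})

test_that("axial collapse degenerates to the mean (zero logits) and to the slice (z = 1)", {
  f <- array(rnorm(6 * 4 * 3 * 2), c(6, 4, 3, 2))
  expect_equal(collapseTo2d(f), apply(f, c(2, 3, 4), mean), tolerance = 1e-12)
  f1 <- array(rnorm(1 * 4 * 3 * 2), c(1, 4, 3, 2))
  expect_equal(collapseTo2d(f1), array(f1, c(4, 3, 2)), tolerance = 1e-12)
  # output (x,y) always equals input (x,y) over random shapes
  set.seed(3)
  for (i in 1:10) {
    d <- c(sample(1:7, 1), sample(1:9, 1), sample(1:9, 1), sample(1:3, 1))
    out <- collapseTo2d(array(rnorm(prod(d)), d))
    expect_identical(dim(out), d[2:4])
  }
  # non-zero logit scale weights bright voxels more
  g <- array(0, c(4, 2, 2, 1)); g[, 1, 1, 1] <- c(0, 0, 0, 10)
  up <- collapseTo2d(g, a = 1)
  expect_gt(up[1, 1, 1], mean(g[, 1, 1, 1]))
})

test_that("attention gates bound their output by the skip and honour forced alpha", {
  skip <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  gating <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  ci <- 1L
  mk <- function(bp) list(Wx = matrix(0, 3, ci), Wg = matrix(0, 5, ci),
                          bg = numeric(ci), psi = matrix(0, ci, 1), bp = bp)
  expect_identical(attentionGate(skip, gating, mk(100)), skip)  # alpha -> 1
  expect_lt(max(abs(attentionGate(skip, gating, mk(-100)))), 1e-30)
  set.seed(4)
  for (i in 1:10) {
    prm <- list(Wx = matrix(rnorm(3), 3, 1), Wg = matrix(rnorm(5), 5, 1),
                bg = rnorm(1), psi = matrix(rnorm(1), 1, 1), bp = rnorm(1))
    out <- attentionGate(skip, gating, prm)
    expect_true(all(abs(out) <= abs(skip) + 1e-12))
  }
  # coarser gating is upsampled; incompatible shapes error
  expect_identical(dim(attentionGate(skip, array(0, c(3, 2, 2)))), dim(skip))
  expect_error(attentionGate(skip, array(0, c(5, 4, 2))), "match")
})

test_that("ablation switches preserve the shape and range contracts", {
  for (att in c(TRUE, FALSE)) for (res in c(TRUE, FALSE)) {
    net <- buildNet(netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 2L,
                              useAttention = att, useResidual = res,
                              seed = 6L))
    p <- netForward(net, array(rnorm(8 * 8 * 4), c(8, 8, 4)))
    expect_identical(dim(p), c(8L, 4L))
    expect_true(all(maskGrid(p) >= 0 & maskGrid(p) <= 1))
  }
})

test_that("binarization uses a >= threshold with ties mapped to 1 and is idempotent", {
  half <- EnFaceMask(matrix(0.5, 3, 3), 1, binary = FALSE)
  expect_true(all(maskGrid(binarizeMask(half, 0.5)) == 1))
  expect_true(all(maskGrid(binarizeMask(half, 0.9)) == 0))
  b <- binarizeMask(EnFaceMask(matrix(c(0, 1, 1, 0), 2, 2), 1))
  expect_identical(maskGrid(binarizeMask(b)), maskGrid(b))
  expect_error(binarizeMask(half, 1.2), "threshold")
})

test_that("every parameter receives a nonzero gradient on some random batch (no dead branches)", {
  for (cfgargs in list(list(useAttention = TRUE, useResidual = TRUE,
                            inChannels = 2L),
                       list(useAttention = FALSE, useResidual = FALSE,
                            inChannels = 1L))) {
    cfg <- do.call(netConfig, c(list(c(8L, 8L, 4L), levels = 2L,
                                     baseChannels = 2L, seed = 9L), cfgargs))
    net <- buildNet(cfg)
    seen <- lapply(netParameters(net), function(x) FALSE)
    set.seed(31)
    for (trial in 1:5) {
      vol <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
      nir <- if (cfg@inChannels == 2L) matrix(rnorm(8 * 4), 8, 4) else NULL
      tgt <- matrix(rbinom(8 * 4, 1, 0.5), 8, 4)
      fw <- oct3d2d:::net_fw(net, vol, nir, keepCache = TRUE)
      lg <- oct3d2d:::loss_grad_logit(fw$prob, tgt, c(1, 1))
      g <- oct3d2d:::net_bw(net, fw$cache, lg$dLogit)
      for (nm in names(g)) if (any(g[[nm]] != 0)) seen[[nm]] <- TRUE
    }
    expect_true(all(unlist(seen)),
                info = paste("dead:", paste(names(seen)[!unlist(seen)],
                                            collapse = ", ")))
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 2L,
                   inChannels = 2L, seed = 7L)
  net <- buildNet(cfg)
  set.seed(17)
  vol <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  nir <- matrix(rnorm(8 * 4), 8, 4)
  tgt <- matrix(rbinom(8 * 4, 1, 0.3), 8, 4)
  fw <- oct3d2d:::net_fw(net, vol, nir, keepCache = TRUE)
  lg <- oct3d2d:::loss_grad_logit(fw$prob, tgt, c(1, 1))
  g <- oct3d2d:::net_bw(net, fw$cache, lg$dLogit)
  lossAt <- function(n) {
    p <- oct3d2d:::net_fw(n, vol, nir, keepCache = FALSE)$prob
    oct3d2d:::loss_grad_logit(p, tgt, c(1, 1))$loss
  }
  eps <- 1e-6
  for (nm in names(netParameters(net))) {
    P <- netParameters(net)
    for (i in sample(length(P[[nm]]), min(2L, length(P[[nm]])))) {
      P2 <- P; P2[[nm]][i] <- P2[[nm]][i] + eps
      P3 <- P; P3[[nm]][i] <- P3[[nm]][i] - eps
      n2 <- net; netParameters(n2) <- P2
      n3 <- net; netParameters(n3) <- P3
      num <- (lossAt(n2) - lossAt(n3)) / (2 * eps)
      denom <- max(1e-6, abs(num) + abs(g[[nm]][i]))
      expect_lt(abs(num - g[[nm]][i]) / denom, 1e-3,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("the nIR channel is consumed (output responds to it)", {
  cfg <- netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 2L,
                   inChannels = 2L, seed = 8L)
  net <- buildNet(cfg)
  vol <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  p1 <- netForward(net, NetInput(vol, nir = matrix(0, 8, 4)))
  p2 <- netForward(net, NetInput(vol, nir = matrix(1, 8, 4)))
  expect_gt(max(abs(maskGrid(p1) - maskGrid(p2))), 0)
  expect_error(netForward(net, NetInput(vol)), "nIR")
})
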