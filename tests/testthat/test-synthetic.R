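test_that("background volumes are deterministic and have the configured band count", {
  prof <- tiny_profile()
  v1 <- makeBackground(prof, seed = 4)
  v2 <- makeBackground(prof, seed = 4)
  expect_identical(volumeData(v1), volumeData(v2))
  expect_identical(dim(v1), prof@nativeDims)

  # with speckle disabled, each A-scan has exactly nBands strict local maxima
  count_maxima <- function(p) {
    n <- length(p)
    sum(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n])
  }
  for (nb in c(2L, 3L)) {
    v <- volumeData(makeBackground(small_profile(), seed = 9, nBands = nb))
    cols <- expand.grid(x = c(1, 20, 40, 64), y = c(1, 8, 16, 32))
    counts <- mapply(function(x, y) count_maxima(v[, x, y]),
                     cols$x, cols$y)
    expect_true(all(counts == nb),
                info = sprintf("nBands=%d counts: %s", nb,
                               paste(counts, collapse = ",")))
  }
})

test_that("lesion masks respect focus count, radius calibration and determinism", {
  prof <- small_profile()
  m0 <- sampleLesionMask(prof, 0L, c(0.5, 1), seed = 1)
  expect_equal(sum(maskGrid(m0)), 0)
  expect_equal(attr(m0, "trueAreaMM2"), 0)

  # single focus of fixed radius: pixel-count area within 25% of pi r^2
  for (seed in 1:5) {
    m <- sampleLesionMask(prof, 1L, c(1, 1), seed = seed)
    a <- sum(maskGrid(m)) * pixelAreaMM2(m)
    expect_lt(abs(a - pi) / pi, 0.25)
    expect_equal(attr(m, "trueAreaMM2"), a)
  }
  expect_identical(maskGrid(sampleLesionMask(prof, 2L, c(0.5, 1), seed = 3)),
                   maskGrid(sampleLesionMask(prof, 2L, c(0.5, 1), seed = 3)))
  expect_error(sampleLesionMask(prof, 1L, c(1, 4), seed = 1), "radius")
})

test_that("atrophy imprinting attenuates the RPE band and brightens the sub-RPE slab", {
  prof <- small_profile()
  bg <- oct3d2d:::background_internal(prof, seed = 2, speckleSigma = 0)
  empty <- EnFaceMask(matrix(0, 64, 32), enFacePixel(prof)$pixelAreaMM2)
  expect_identical(volumeData(applyAtrophy(bg$vol, empty, prof)),
                   volumeData(bg$vol))

  full <- EnFaceMask(matrix(1, 64, 32), enFacePixel(prof)$pixelAreaMM2)
  va <- applyAtrophy(bg$vol, full, prof, rpeDepth = bg$rpe)
  sub_rpe_mean <- function(vol, rpe) {
    tot <- 0; n <- 0
    for (x in seq_len(dim(vol)[2])) for (y in seq_len(dim(vol)[3])) {
      zz <- min(dim(vol)[1], round(rpe[x, y]) + 5):dim(vol)[1]
      tot <- tot + sum(volumeData(vol)[zz, x, y]); n <- n + length(zz)
    }
    tot / n
  }
  expect_gt(sub_rpe_mean(va, bg$rpe), 2 * sub_rpe_mean(bg$vol, bg$rpe))

  # partial mask: atrophic columns separable from intact ones
  part <- sampleLesionMask(prof, 1L, c(1.2, 1.2), seed = 6)
  vp <- applyAtrophy(bg$vol, part, prof, rpeDepth = bg$rpe)
  ins <- which(maskGrid(part) == 1, arr.ind = TRUE)
  outs <- which(maskGrid(part) == 0, arr.ind = TRUE)
  colmean <- function(vol, ij) {
    mean(vapply(seq_len(nrow(ij)), function(r) {
      x <- ij[r, 1]; y <- ij[r, 2]
      zz <- min(dim(vol)[1], round(bg$rpe[x, y]) + 5):dim(vol)[1]
      mean(volumeData(vol)[zz, x, y])
    }, numeric(1)))
  }
  expect_gt(colmean(vp, ins), colmean(vp, outs))

  expect_error(applyAtrophy(bg$vol, EnFaceMask(matrix(0, 3, 3), 1), prof),
               "dimensions")
})

test_that("nAMD confounders perturb the volume but never the ground truth", {
  prof <- small_profile()
  bg <- oct3d2d:::background_internal(prof, seed = 3, speckleSigma = 0)
  mask <- sampleLesionMask(prof, 1L, c(1, 1), seed = 3)
  v1 <- addNamdFeatures(bg$vol, seed = 8, rpeDepth = bg$rpe, avoidMask = mask)
  v2 <- addNamdFeatures(bg$vol, seed = 8, rpeDepth = bg$rpe, avoidMask = mask)
  expect_identical(volumeData(v1), volumeData(v2))
  expect_gt(sum(volumeData(v1) != volumeData(bg$vol)), 0)
})

test_that("synthetic nIR images reflect hypertransmission and device capability", {
  prof <- small_profile()
  bg <- oct3d2d:::background_internal(prof, seed = 5, speckleSigma = 0)
  nir0 <- renderNIR(bg$vol, prof, rpeDepth = bg$rpe)
  expect_equal(nrow(nirGrid(nir0)), ncol(nirGrid(nir0)))  # square grid
  expect_lt(stats::var(as.numeric(nirGrid(nir0))), 1e-3)  # homogeneous

  mask <- sampleLesionMask(prof, 1L, c(1.2, 1.2), seed = 2)
  va <- applyAtrophy(bg$vol, mask, prof, rpeDepth = bg$rpe)
  nir1 <- renderNIR(va, prof, rpeDepth = bg$rpe)
  side <- nrow(nirGrid(nir1))
  msq <- (oct3d2d:::cpp_resample2d_area(maskGrid(mask), side, side) >= 0.5)
  expect_gt(mean(nirGrid(nir1)[msq]), mean(nirGrid(nir1)[!msq]))

  cir <- deviceProfile("cirrus", nativeDims = c(16L, 8L, 8L),
                       netInputDims = c(8L, 8L, 8L))
  expect_error(renderNIR(bg$vol, cir), "nIR")
})

test_that("generated cohorts have the programmed structure, growth and determinism", {
  dir1 <- withr::local_tempdir()
  rec <- tiny_cohort(dir1, nSubjects = 5L, visits = 3L, seed = 13L)
  expect_equal(nrow(rec), 15L)
  expect_equal(length(unique(rec$subject_id)), 5L)
  expect_true(all(file.exists(rec$volume_path)))
  expect_true(all(file.exists(rec$mask_path)))

  # per-eye ground-truth area series are non-decreasing
  for (sid in unique(rec$subject_id)) {
    a <- rec$truth_area_mm2[rec$subject_id == sid][order(rec$visit_index[rec$subject_id == sid])]
    expect_true(all(diff(a) >= 0))
  }

  # recorded area equals pixel count x pixel area of the stored mask
  px <- enFacePixel(tiny_profile())$pixelAreaMM2
  for (i in c(1L, 8L, 15L)) {
    m <- readMask(rec$mask_path[i], px)
    expect_equal(areaMM2(m), rec$truth_area_mm2[i], tolerance = 1e-9)
  }

  dir2 <- withr::local_tempdir()
  tiny_cohort(dir2, nSubjects = 5L, visits = 3L, seed = 13L)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(f1, list.files(dir2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
})

test_that("thresholding the sub-RPE projection recovers the lesion (task well-posedness)", {
  # the learning task must be solvable by a trivial oracle on clean volumes
  prof <- small_profile()
  for (seed in 1:3) {
    bg <- oct3d2d:::background_internal(prof, seed = seed, speckleSigma = 0)
    mask <- sampleLesionMask(prof, 2L, c(0.8, 1.4), seed = seed + 10L)
    va <- applyAtrophy(bg$vol, mask, prof, rpeDepth = bg$rpe)
    v <- volumeData(va)
    slab <- matrix(0, dim(v)[2], dim(v)[3])
    for (x in seq_len(dim(v)[2])) for (y in seq_len(dim(v)[3])) {
      zz <- min(dim(v)[1], round(bg$rpe[x, y]) + 5):dim(v)[1]
      slab[x, y] <- mean(v[zz, x, y])
    }
    thr <- quantile(slab, 1 - mean(maskGrid(mask)))
    expect_gte(dsc((slab >= thr) * 1, maskGrid(mask)), 0.7)
  }
})
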