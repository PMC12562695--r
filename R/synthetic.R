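#' @section Synthetic OCT phenotype:
#' The generator emulates the imaging phenotype that defines GA on OCT
#' (complete RPE and outer retinal atrophy): inside the lesion footprint the
#' RPE/outer bands lose most of their reflectivity and the choroid below
#' brightens (hypertransmission), while columns outside the lesion are left
#' untouched. It does not attempt physical speckle/PSF simulation.
#' @name synthetic-oct
#' @keywords internal
NULL

# shift a matrix by (di, dj) with zero padding
shift2 <- function(m, di, dj) {
  n <- matrix(0, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  ok_i <- si >= 1 & si <= nrow(m)
  ok_j <- sj >= 1 & sj <= ncol(m)
  n[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  n
}

# 3x3 box blur with zero padding (used for edge feathering)
blur3 <- function(m) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1) acc <- acc + shift2(m, di, dj)
  acc / 9
}

# smooth random surface on an (nx, ny) grid in [-1, 1], varying slowly
rand_surface <- function(nx, ny, knots = 4L) {
  coarse <- matrix(runif(knots * knots, -1, 1), knots, knots)
  arr <- array(coarse, c(1L, knots, knots))
  out <- cpp_resample3d(arr, c(1L, as.integer(nx), as.integer(ny)))
  matrix(out, nx, ny)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# background volume plus the band surfaces used to build it
background_internal <- function(profile, seed, speckleSigma = 0, nBands = 3L) {
  d <- profile@nativeDims
  nz <- d[1]; nx <- d[2]; ny <- d[3]
  with_seed(seed, {
    rpe <- nz * (0.55 + 0.06 * rand_surface(nx, ny))
    ilm <- rpe - nz * (0.30 + 0.04 * rand_surface(nx, ny))
    ez <- rpe - pmax(2.5, 0.05 * nz)
    amp <- c(ilm = 0.40, ez = 0.55, rpe = 0.85) * (1 + 0.08 * runif(3, -1, 1))
    sig <- max(1.2, 0.008 * nz)
    data <- array(0, c(nz, nx, ny))
    for (z in seq_len(nz)) {
      plateau <- clamp01(z - ilm) * clamp01(rpe - z + 2)  # inner retinal tissue
      prof <- 0.05 + 0.12 * plateau +
        amp["ilm"] * exp(-0.5 * ((z - ilm) / (1.6 * sig))^2) +
        amp["rpe"] * exp(-0.5 * ((z - rpe) / sig)^2) +
        0.15 * ifelse(z > rpe, exp(-(z - rpe) / (0.08 * nz)), 0)
      if (nBands >= 3L)
        prof <- prof + amp["ez"] * exp(-0.5 * ((z - ez) / sig)^2)
      data[z, , ] <- prof
    }
    if (speckleSigma > 0) {
      data <- data * exp(speckleSigma * array(rnorm(length(data)), dim(data)) -
                           speckleSigma^2 / 2)
    }
    sp <- c(1 / nz, profile@fovMM[1] / nx, profile@fovMM[2] / ny)
    list(vol = OCTVolume(data, sp), rpe = rpe)
  })
}

#' Generate a lesion-free synthetic OCT background volume
#'
#' Produces a volume at the profile's native dimensions containing a dark
#' vitreous, two or three bright retinal bands (inner retina, optionally the
#' ellipsoid zone, and the RPE) whose depths vary smoothly across the en
#' face plane, and a dim exponentially decaying choroid under the RPE.
#' Optional multiplicative log-normal speckle is applied last.
#'
#' @param profile a \linkS4class{DeviceProfile}.
#' @param seed generator seed; identical seeds give identical volumes.
#' @param speckleSigma log-normal speckle sigma (0 disables noise).
#' @param nBands 2 or 3 bright bands.
#' @return An \linkS4class{OCTVolume} at native dimensions.
#' @examples
#' prof <- deviceProfile("spectralis", nativeDims = c(64, 32, 8),
#'                       netInputDims = c(32, 16, 8))
#' vol <- makeBackground(prof, seed = 1)
#' dim(vol)
#' @export
makeBackground <- function(profile, seed, speckleSigma = 0, nBands = 3L) {
  background_internal(profile, seed, speckleSigma, nBands)$vol
}

# multiplicative log-normal speckle, mean-preserving
apply_speckle <- function(vol, sigma, seed) {
  if (sigma <= 0) return(vol)
  with_seed(seed, {
    vol@data <- vol@data *
      exp(sigma * array(rnorm(length(vol@data)), dim(vol@data)) - sigma^2 / 2)
  })
  vol
}

#' Sample a multifocal GA lesion mask
#'
#' Draws \code{nFoci} randomly placed smooth blobs (radially perturbed
#' ellipses) on the device's native en face grid and returns their union.
#' The per-focus equivalent radius is drawn from \code{radiusRangeMM}; the
#' realized pixel-count area in mm^2 is attached as attribute
#' \code{"trueAreaMM2"}.
#'
#' @param profile a \linkS4class{DeviceProfile}.
#' @param nFoci number of lesion foci (>= 0).
#' @param radiusRangeMM equivalent-radius range in mm; the upper end must
#'   fit inside the field of view.
#' @param seed generator seed.
#' @return A binary \linkS4class{EnFaceMask} at native en face resolution.
#' @export
sampleLesionMask <- function(profile, nFoci, radiusRangeMM, seed) {
  if (nFoci < 0) stop("nFoci must be >= 0")
  if (max(radiusRangeMM) > min(profile@fovMM) / 2)
    stop("focus radius exceeds the field of view")
  nx <- profile@nativeDims[2]; ny <- profile@nativeDims[3]
  px <- enFacePixel(profile)
  xmm <- (seq_len(nx) - 0.5) * px$dx
  ymm <- (seq_len(ny) - 0.5) * px$dy
  grid <- matrix(0, nx, ny)
  with_seed(seed, {
    for (f in seq_len(nFoci)) {
      r0 <- runif(1, radiusRangeMM[1], radiusRangeMM[2])
      mx <- min(1.2 * r0, profile@fovMM[1] / 2 * 0.95)
      my <- min(1.2 * r0, profile@fovMM[2] / 2 * 0.95)
      cx <- runif(1, mx, profile@fovMM[1] - mx)
      cy <- runif(1, my, profile@fovMM[2] - my)
      a <- runif(3, 0, 0.12)
      ph <- runif(3, 0, 2 * pi)
      dx <- outer(xmm - cx, rep(1, ny))
      dy <- outer(rep(1, nx), ymm - cy)
      rho <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      rb <- r0 * (1 + a[1] * cos(2 * th + ph[1]) + a[2] * cos(3 * th + ph[2]) +
                    a[3] * cos(4 * th + ph[3]))
      grid[rho <= rb] <- 1
    }
  })
  m <- EnFaceMask(grid, px$pixelAreaMM2, binary = TRUE)
  attr(m, "trueAreaMM2") <- sum(grid) * px$pixelAreaMM2
  m
}

# per-column RPE depth estimate: argmax of an axially smoothed A-scan
estimate_rpe <- function(vol) {
  d <- dim(vol@data)
  nz <- d[1]
  m <- matrix(vol@data, nz, d[2] * d[3])
  k <- max(3L, as.integer(round(nz / 40)))
  cs <- apply(m, 2, cumsum)
  sm <- (rbind(cs[-seq_len(k), , drop = FALSE],
               matrix(rep(cs[nz, ], k), k, ncol(cs), byrow = TRUE)) -
           rbind(matrix(0, k, ncol(cs)),
                 cs[seq_len(nz - k), , drop = FALSE])) / k
  matrix(apply(sm, 2, which.max) + k / 2, d[2], d[3])
}

#' Imprint atrophy into a volume under an en face lesion mask
#'
#' Within lesion columns the outer-retina/RPE band is attenuated by 80
#' percent and everything deeper than the RPE is brightened 2.5-fold
#' (hypertransmission). The transition is feathered over one pixel just
#' inside the lesion boundary; columns outside the mask are returned
#' bit-identical.
#'
#' @param vol an \linkS4class{OCTVolume} at native dimensions.
#' @param mask a binary \linkS4class{EnFaceMask} at the volume's en face
#'   dimensions.
#' @param profile the owning \linkS4class{DeviceProfile}.
#' @param rpeDepth optional (nx, ny) matrix of RPE depths in px; estimated
#'   from the volume when missing.
#' @return The modified \linkS4class{OCTVolume}.
#' @export
applyAtrophy <- function(vol, mask, profile, rpeDepth = NULL) {
  d <- dim(vol@data)
  if (!all(dim(mask@grid) == d[2:3]))
    stop("mask dimensions do not match the volume's en face grid")
  if (sum(mask@grid) == 0) return(vol)
  if (is.null(rpeDepth)) rpeDepth <- estimate_rpe(vol)
  w <- mask@grid * (1 - blur3(1 - mask@grid))  # inward feather, <= 1 px
  nz <- d[1]
  top <- rpeDepth - 0.09 * nz
  bot <- rpeDepth + 2
  for (z in seq_len(nz)) {
    att <- clamp01(z - top) * clamp01(bot - z + 1)
    hyper <- clamp01((z - bot) / 2)
    vol@data[z, , ] <- vol@data[z, , ] * (1 - 0.8 * w * att) *
      (1 + 1.5 * w * hyper)
  }
  vol
}

#' Add nAMD-like confounders to a volume
#'
#' Inserts one to three dark intraretinal/subretinal fluid pockets and up to
#' two bright fibrosis-like hyperreflective patches near the RPE (extending
#' slightly below it, which locally mimics hypertransmission). The GA
#' ground-truth mask is untouched: only voxel intensities change, at loci
#' sampled away from the lesion when a mask is supplied.
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param seed generator seed.
#' @param rpeDepth optional RPE depth matrix (estimated when missing).
#' @param avoidMask optional binary \linkS4class{EnFaceMask}; feature
#'   centers are drawn outside it.
#' @return The perturbed \linkS4class{OCTVolume}.
#' @export
addNamdFeatures <- function(vol, seed, rpeDepth = NULL, avoidMask = NULL) {
  d <- dim(vol@data)
  nz <- d[1]; nx <- d[2]; ny <- d[3]
  if (is.null(rpeDepth)) rpeDepth <- estimate_rpe(vol)
  pick_center <- function() {
    for (i in 1:50) {
      cx <- sample.int(nx, 1)
      cy <- sample.int(ny, 1)
      if (is.null(avoidMask) || avoidMask@grid[cx, cy] == 0)
        return(c(cx, cy))
    }
    c(cx, cy)
  }
  bump <- function(data, cx, cy, cz, rz, rx, ry, f) {
    zi <- max(1, floor(cz - rz)):min(nz, ceiling(cz + rz))
    xi <- max(1, floor(cx - rx)):min(nx, ceiling(cx + rx))
    yi <- max(1, floor(cy - ry)):min(ny, ceiling(cy + ry))
    q <- outer(((zi - cz) / rz)^2, outer(((xi - cx) / rx)^2,
                                         ((yi - cy) / ry)^2, `+`), `+`)
    data[zi, xi, yi] <- f(data[zi, xi, yi], pmax(0, 1 - q))
    data
  }
  with_seed(seed, {
    for (i in seq_len(sample(1:3, 1))) {   # dark fluid pockets
      ce <- pick_center()
      cz <- rpeDepth[ce[1], ce[2]] - runif(1, 0.10, 0.22) * nz
      vol@data <- bump(vol@data, ce[1], ce[2], cz,
                       rz = runif(1, 0.04, 0.08) * nz,
                       rx = runif(1, 0.06, 0.12) * nx,
                       ry = runif(1, 0.06, 0.12) * ny,
                       f = function(v, s) v * (1 - 0.7 * s))
    }
    for (i in seq_len(sample(0:2, 1))) {   # bright fibrosis-like patches
      ce <- pick_center()
      cz <- rpeDepth[ce[1], ce[2]] + 1
      vol@data <- bump(vol@data, ce[1], ce[2], cz,
                       rz = runif(1, 0.03, 0.06) * nz,
                       rx = runif(1, 0.05, 0.10) * nx,
                       ry = runif(1, 0.05, 0.10) * ny,
                       f = function(v, s) v + 0.35 * s)
    }
  })
  vol
}

#' Render a synthetic near-infrared en face image
#'
#' The nIR facsimile is the mean axial projection of the slab just below the
#' estimated RPE, resized to a square grid. Atrophic regions appear bright
#' because of the hypertransmission imprinted by \code{\link{applyAtrophy}}.
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param profile the owning \linkS4class{DeviceProfile}; must have
#'   \code{hasNIR} capability.
#' @param rpeDepth optional RPE depth matrix.
#' @return An \linkS4class{NIRImage} on a square grid.
#' @export
renderNIR <- function(vol, profile, rpeDepth = NULL) {
  if (!profile@hasNIR)
    stop("device profile '", profile@name, "' has no nIR capability")
  d <- dim(vol@data)
  nz <- d[1]
  if (is.null(rpeDepth)) rpeDepth <- estimate_rpe(vol)
  lo <- pmin(nz, round(rpeDepth + 3))
  hi <- pmin(nz, round(rpeDepth + max(4, 0.2 * nz)))
  slab <- matrix(0, d[2], d[3])
  cnt <- pmax(1, hi - lo + 1)
  for (z in seq_len(nz)) {
    inslab <- (z >= lo) & (z <= hi)
    slab <- slab + vol@data[z, , ] * inslab
  }
  slab <- slab / cnt
  side <- max(d[2], d[3])
  sq <- matrix(cpp_resample3d(array(slab, c(1L, d[2], d[3])),
                              c(1L, side, side)), side, side)
  NIRImage(sq, fovDeg = 30)
}

# grow a mask by anisotropic distance dilation until its area increases by
# `growth` mm^2 (or the FOV is exhausted); returns list(mask, truncated)
grow_mask <- function(mask, growth) {
  pxA <- mask@pixelAreaMM2
  target <- sum(mask@grid) * pxA + growth
  if (sum(mask@grid) == 0 || growth <= 0)
    return(list(mask = mask, truncated = FALSE))
  if (target >= length(mask@grid) * pxA) {
    mask@grid[] <- 1
    return(list(mask = mask, truncated = TRUE))
  }
  # pixel extents in mm ride along as attributes; square pixels otherwise
  edt <- cpp_edt2d(mask@grid > 0, attr(mask, "dxMM") %||% sqrt(pxA),
                   attr(mask, "dyMM") %||% sqrt(pxA))
  dist <- sort(edt[edt > 0])
  need <- ceiling((target - sum(mask@grid) * pxA) / pxA)
  thr <- dist[min(length(dist), need)]
  mask@grid[edt <= thr & edt > 0] <- 1
  list(mask = mask, truncated = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic longitudinal cohort on disk
#'
#' For every subject/eye a baseline multifocal lesion is drawn; at each
#' subsequent visit the lesion is dilated (anisotropic distance dilation)
#' until its area has grown by \code{growthRateMM2PerVisit}, so per-eye area
#' series are non-decreasing by construction. A fixed fraction of eyes
#' additionally receive nAMD-like confounders. Volumes (multi-page TIFF),
#' masks (PNG), nIR images (PNG, Spectralis-like profiles only) and a
#' metadata CSV are written under \code{outDir}.
#'
#' @param params a \linkS4class{SyntheticParams}.
#' @param outDir output directory (created if needed).
#' @return The cohort metadata data.frame (invisibly also on disk as
#'   \code{metadata.csv}); extra columns \code{truth_area_mm2} and
#'   \code{truncated} record the generator ground truth.
#' @export
generateCohort <- function(params, outDir) {
  profile <- params@device
  px <- enFacePixel(profile)
  dir.create(file.path(outDir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (profile@hasNIR)
    dir.create(file.path(outDir, "nir"), recursive = TRUE, showWarnings = FALSE)
  eyes <- expand.grid(subject = seq_len(params@nSubjects),
                      eye = c("OD", "OS")[seq_len(params@eyesPerSubject)],
                      stringsAsFactors = FALSE)
  nEyes <- nrow(eyes)
  namd_eyes <- with_seed(derive_seed(params@seed, "namd"), {
    k <- round(params@namdFraction * nEyes)
    sample(seq_len(nEyes), k)
  })
  rows <- list()
  for (e in seq_len(nEyes)) {
    sid <- sprintf("S%03d", eyes$subject[e])
    eye <- eyes$eye[e]
    eyeSeed <- derive_seed(params@seed, paste0("eye", sid, eye))
    bg <- background_internal(profile, eyeSeed, speckleSigma = 0)
    nFoci <- with_seed(eyeSeed + 1L,
                       sample(params@nFociRange[1]:params@nFociRange[2], 1))
    mask <- sampleLesionMask(profile, nFoci, params@focusRadiusRangeMM,
                             seed = eyeSeed + 2L)
    attr(mask, "dxMM") <- px$dx
    attr(mask, "dyMM") <- px$dy
    for (v in seq_len(params@visitsPerEye) - 1L) {
      truncated <- FALSE
      if (v > 0L) {
        g <- grow_mask(mask, params@growthRateMM2PerVisit)
        mask <- g$mask
        attr(mask, "dxMM") <- px$dx
        attr(mask, "dyMM") <- px$dy
        truncated <- g$truncated
      }
      visitSeed <- derive_seed(eyeSeed, paste0("visit", v))
      vol <- applyAtrophy(bg$vol, mask, profile, rpeDepth = bg$rpe)
      if (e %in% namd_eyes)
        vol <- addNamdFeatures(vol, seed = visitSeed + 1L, rpeDepth = bg$rpe,
                               avoidMask = mask)
      nir <- if (profile@hasNIR) renderNIR(vol, profile, rpeDepth = bg$rpe)
             else NULL
      vol <- apply_speckle(vol, params@speckleSigma, visitSeed + 2L)
      rid <- sprintf("%s_%s_%d", sid, eye, v)
      vpath <- file.path("volumes", paste0(rid, ".tif"))
      mpath <- file.path("masks", paste0(rid, ".png"))
      writeVolume(vol, file.path(outDir, vpath))
      writeMask(mask, file.path(outDir, mpath))
      npath <- NA_character_
      if (!is.null(nir)) {
        npath <- file.path("nir", paste0(rid, ".png"))
        writeNIR(nir, file.path(outDir, npath))
      }
      quality <- with_seed(visitSeed + 3L,
                           runif(1, params@qualityScoreRange[1],
                                 params@qualityScoreRange[2]))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, eye = eye, visit_index = v,
        device = profile@name, quality_score = quality,
        has_nAMD = e %in% namd_eyes, has_GA = sum(mask@grid) > 0,
        volume_path = vpath, mask_path = mpath, nir_path = npath,
        truth_area_mm2 = sum(mask@grid) * px$pixelAreaMM2,
        truncated = truncated, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  writeCohort(df, file.path(outDir, "metadata.csv"))
  as_cohort(df, outDir)
}
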