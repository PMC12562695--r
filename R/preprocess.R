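#' Partition scan records by device quality thresholds
#'
#' A scan is included when its quality score is at least the device
#' profile's minimum (thresholds are inclusive: a Spectralis quality index
#' of exactly 25 or a Cirrus signal score of exactly 5 passes). The
#' partition is exhaustive and disjoint.
#'
#' @param records cohort data.frame (see \code{\link{readCohort}}).
#' @param profiles named list of \linkS4class{DeviceProfile}s covering every
#'   device name appearing in \code{records}.
#' @return list with elements \code{included} and \code{excluded}.
#' @export
qualityFilter <- function(records, profiles) {
  if (nrow(records) == 0L)
    return(list(included = records, excluded = records))
  unknown <- setdiff(unique(records$device), names(profiles))
  if (length(unknown))
    stop("no device profile configured for: ", paste(unknown, collapse = ", "))
  thr <- vapply(records$device,
                function(d) profiles[[d]]@qualityMin, numeric(1))
  keep <- records$quality_score >= thr
  list(included = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE])
}

#' Subsample a volume to the network input resolution
#'
#' Trilinear resampling of the intensity grid to the profile's
#' \code{netInputDims}; voxel spacing is rescaled so the physical extent is
#' preserved. Upsampling of toy inputs uses the same interpolation.
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param profile the target \linkS4class{DeviceProfile}.
#' @return An \linkS4class{OCTVolume} at \code{netInputDims}.
#' @export
subsampleVolume <- function(vol, profile) {
  target <- profile@netInputDims
  d <- dim(vol@data)
  out <- cpp_resample3d(vol@data, target)
  OCTVolume(array(out, target), vol@spacingMM * d / target, vol@recordID)
}

#' Resample a binary en face mask
#'
#' Area-weighted resampling followed by a 0.5 threshold (ties map to 1).
#' The pixel area is updated so the full field-of-view area is conserved
#' exactly; an individual mask's area is conserved up to the rounding of
#' partially covered boundary cells.
#'
#' @param mask a binary \linkS4class{EnFaceMask}.
#' @param targetDims integer pair (nx, ny).
#' @return A binary \linkS4class{EnFaceMask} at \code{targetDims}.
#' @export
resampleMask <- function(mask, targetDims) {
  if (!mask@binary) stop("resampleMask expects a binary mask")
  d <- dim(mask@grid)
  if (all(d == targetDims)) return(mask)
  frac <- cpp_resample2d_area(mask@grid, targetDims[1], targetDims[2])
  newArea <- mask@pixelAreaMM2 * prod(d) / prod(targetDims)
  EnFaceMask((frac >= 0.5) * 1, newArea, binary = TRUE)
}

#' Z-score normalize an intensity grid
#'
#' Per-volume standardization to mean 0 and unit variance (population
#' variance). Constant volumes map to all zeros.
#'
#' @param x a numeric array (any shape) or \linkS4class{OCTVolume}.
#' @return The normalized object, same type as the input.
#' @export
normalizeVolume <- function(x) {
  if (is(x, "OCTVolume")) {
    x@data <- normalizeVolume(x@data)
    return(x)
  }
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) return(array(0, dim(x)))
  (x - mu) / sqrt(s2)
}

#' Assemble a network-ready input from a scan record
#'
#' Reads the volume (and mask / nIR when present), subsamples to the
#' profile's network input dimensions, z-score normalizes, resamples the
#' ground-truth mask to the output resolution, and resizes the nIR image to
#' mask dimensions.
#'
#' @param record one row of a cohort data.frame.
#' @param profile the scan's \linkS4class{DeviceProfile}.
#' @param withNIR load and attach the nIR channel when available.
#' @return A \linkS4class{NetInput}.
#' @export
prepareInput <- function(record, profile, withNIR = FALSE) {
  sp <- c(1 / profile@nativeDims[1],
          enFacePixel(profile)$dx, enFacePixel(profile)$dy)
  vol <- readVolume(record$volume_path, sp, record$record_id)
  vol <- subsampleVolume(vol, profile)
  volN <- normalizeVolume(vol@data)
  target <- NULL
  if (!is.null(record$mask_path) && !is.na(record$mask_path)) {
    m <- readMask(record$mask_path, enFacePixel(profile)$pixelAreaMM2)
    target <- resampleMask(m, profile@maskDims)
  }
  nir <- NULL
  if (withNIR && "nir_path" %in% names(record) && !is.na(record$nir_path)) {
    ni <- readNIR(record$nir_path)
    d <- dim(ni@grid)
    nir <- matrix(cpp_resample3d(array(ni@grid, c(1L, d[1], d[2])),
                                 c(1L, profile@maskDims)),
                  profile@maskDims[1], profile@maskDims[2])
    nir <- normalizeVolume(nir)
    dim(nir) <- profile@maskDims
  }
  NetInput(volN, nir = nir, target = target, recordID = record$record_id)
}

#' Prepare all records of a cohort
#'
#' @param records cohort data.frame.
#' @param profile shared \linkS4class{DeviceProfile}.
#' @param withNIR attach nIR channels when available.
#' @return Named list of \linkS4class{NetInput}s keyed by record_id.
#' @export
prepareCohortInputs <- function(records, profile, withNIR = FALSE) {
  out <- lapply(seq_len(nrow(records)),
                function(i) prepareInput(records[i, , drop = FALSE], profile,
                                         withNIR))
  names(out) <- records$record_id
  out
}

#' Load device profiles from a YAML or JSON configuration file
#'
#' The file maps profile names to overrides of the stock profiles, e.g.
#' \preformatted{
#'   spectralis:
#'     nativeDims: [96, 64, 32]
#'     netInputDims: [32, 32, 16]
#'     qualityMin: 25
#' }
#' Fields not given fall back to the stock profile of the same name.
#'
#' @param path .yaml/.yml or .json configuration file.
#' @return Named list of \linkS4class{DeviceProfile}s.
#' @export
readDeviceProfiles <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- lapply(names(cfg), function(nm) {
    o <- cfg[[nm]]
    deviceProfile(nm,
                  fovMM = o$fovMM, nativeDims = o$nativeDims,
                  netInputDims = o$netInputDims, maskDims = o$maskDims,
                  qualityMin = o$qualityMin, hasNIR = o$hasNIR)
  })
  names(out) <- names(cfg)
  out
}
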