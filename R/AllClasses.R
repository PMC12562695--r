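#' Core S4 classes
#'
#' S4 containers used throughout the package: volumetric scans, en face
#' masks, near-infrared images, device profiles, network/training
#' configurations and evaluation reports.
#'
#' @name oct3d2d-classes
NULL

# ---------------------------------------------------------------------------

#' OCTVolume: a 3D OCT intensity grid
#'
#' Axis convention is fixed package-wide: the array is indexed
#' \code{(z, x, y)} = (axial depth in pixels, lateral position within a
#' B-scan, B-scan index). \code{spacingMM} gives the physical size of one
#' voxel along each axis, in mm.
#'
#' @slot data 3D numeric array, dims \code{(nz, nx, ny)}.
#' @slot spacingMM numeric(3), mm per voxel along (z, x, y); all positive.
#' @slot recordID character(1) key into a cohort metadata table.
#'
#' @export
setClass("OCTVolume",
  representation(data = "array", spacingMM = "numeric", recordID = "character"),
  prototype(data = array(0, c(1, 1, 1)), spacingMM = c(1, 1, 1), recordID = "")
)

setValidity("OCTVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array (z, x, y)")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (!all(is.finite(object@data))) return("intensities must be finite")
  if (length(object@spacingMM) != 3L || any(!is.finite(object@spacingMM)) ||
      any(object@spacingMM <= 0)) {
    return("spacingMM must be three strictly positive values")
  }
  TRUE
})

#' Construct an OCTVolume
#'
#' @param data 3D numeric array indexed (z, x, y).
#' @param spacingMM numeric(3), mm per voxel along (z, x, y).
#' @param recordID optional record identifier.
#' @return An \linkS4class{OCTVolume}.
#' @examples
#' v <- OCTVolume(array(runif(8 * 8 * 2), c(8, 8, 2)), c(0.01, 0.05, 0.25))
#' dim(v)
#' @export
OCTVolume <- function(data, spacingMM, recordID = "") {
  new("OCTVolume", data = data, spacingMM = as.numeric(spacingMM),
      recordID = as.character(recordID))
}

#' @describeIn OCTVolume dimensions (nz, nx, ny) of the intensity grid
#' @param x an \code{OCTVolume}
#' @export
setMethod("dim", "OCTVolume", function(x) dim(x@data))

#' Accessors for OCTVolume
#' @param x an \linkS4class{OCTVolume}
#' @return \code{volumeData}: the 3D array; \code{spacingMM}: mm per voxel.
#' @export
volumeData <- function(x) x@data

#' @rdname volumeData
#' @export
spacingMM <- function(x) x@spacingMM

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "OCTVolume %s: %d x %d x %d (z,x,y), voxel %.4g x %.4g x %.4g mm\n",
    if (nzchar(object@recordID)) object@recordID else "<unnamed>",
    d[1], d[2], d[3],
    object@spacingMM[1], object@spacingMM[2], object@spacingMM[3]))
})

# ---------------------------------------------------------------------------

#' EnFaceMask: a 2D en face GA map
#'
#' The grid lives on the (x = lateral, y = B-scan) plane. Values are GA
#' probabilities in [0, 1], or strictly {0, 1} when \code{binary} is TRUE.
#'
#' @slot grid numeric matrix (nx, ny) with values in [0, 1].
#' @slot pixelAreaMM2 area of one en face pixel in mm^2 (dx * dy).
#' @slot binary logical flag; when TRUE values must be exactly 0 or 1.
#'
#' @export
setClass("EnFaceMask",
  representation(grid = "matrix", pixelAreaMM2 = "numeric", binary = "logical"),
  prototype(grid = matrix(0, 1, 1), pixelAreaMM2 = 1, binary = TRUE)
)

setValidity("EnFaceMask", function(object) {
  g <- object@grid
  if (!is.numeric(g)) return("grid must be numeric")
  if (any(!is.finite(g))) return("grid values must be finite")
  if (any(g < 0 | g > 1)) return("grid values must lie in [0, 1]")
  if (isTRUE(object@binary) && !all(g %in% c(0, 1))) {
    return("binary mask must contain only 0/1 values")
  }
  if (length(object@pixelAreaMM2) != 1L || !is.finite(object@pixelAreaMM2) ||
      object@pixelAreaMM2 <= 0) {
    return("pixelAreaMM2 must be a single positive value")
  }
  TRUE
})

#' Construct an EnFaceMask
#'
#' @param grid numeric matrix (nx, ny), values in [0, 1].
#' @param pixelAreaMM2 area of one pixel in mm^2.
#' @param binary logical; is the grid strictly 0/1?
#' @return An \linkS4class{EnFaceMask}.
#' @examples
#' m <- EnFaceMask(matrix(c(0, 1, 1, 0), 2, 2), pixelAreaMM2 = 0.25)
#' areaMM2(m)
#' @export
EnFaceMask <- function(grid, pixelAreaMM2, binary = TRUE) {
  storage.mode(grid) <- "double"
  new("EnFaceMask", grid = grid, pixelAreaMM2 = as.numeric(pixelAreaMM2),
      binary = isTRUE(binary))
}

#' @describeIn EnFaceMask mask grid dimensions (nx, ny)
#' @param x an \code{EnFaceMask}
#' @export
setMethod("dim", "EnFaceMask", function(x) dim(x@grid))

#' Accessors for EnFaceMask
#' @param x an \linkS4class{EnFaceMask}
#' @return \code{maskGrid}: the (nx, ny) matrix; \code{pixelAreaMM2}: pixel
#'   area in mm^2; \code{isBinary}: the binary flag.
#' @export
maskGrid <- function(x) x@grid

#' @rdname maskGrid
#' @export
pixelAreaMM2 <- function(x) x@pixelAreaMM2

#' @rdname maskGrid
#' @export
isBinary <- function(x) x@binary

setMethod("show", "EnFaceMask", function(object) {
  d <- dim(object@grid)
  cat(sprintf("EnFaceMask: %d x %d (x,y), %s, %.3f mm^2/px, area %.3f mm^2\n",
              d[1], d[2], if (object@binary) "binary" else "probability",
              object@pixelAreaMM2,
              sum(object@grid >= 0.5) * object@pixelAreaMM2))
})

# ---------------------------------------------------------------------------

#' NIRImage: a near-infrared reflectance en face image
#'
#' @slot grid numeric matrix (width, height) of finite reflectance values.
#' @slot fovDeg nominal field of view in degrees.
#' @export
setClass("NIRImage",
  representation(grid = "matrix", fovDeg = "numeric"),
  prototype(grid = matrix(0, 1, 1), fovDeg = 30)
)

setValidity("NIRImage", function(object) {
  if (any(dim(object@grid) < 1L)) return("dimensions must be >= 1")
  if (any(!is.finite(object@grid))) return("intensities must be finite")
  TRUE
})

#' Construct an NIRImage
#' @param grid numeric matrix of reflectance values.
#' @param fovDeg nominal field of view in degrees (Spectralis nIR: 30).
#' @return An \linkS4class{NIRImage}.
#' @export
NIRImage <- function(grid, fovDeg = 30) {
  storage.mode(grid) <- "double"
  new("NIRImage", grid = grid, fovDeg = as.numeric(fovDeg))
}

#' @rdname NIRImage
#' @param x an \code{NIRImage}
#' @export
nirGrid <- function(x) x@grid

# ---------------------------------------------------------------------------

#' DeviceProfile: acquisition geometry and inclusion rules for one OCT device
#'
#' Bundles the native scan geometry, the resolution the network consumes,
#' the en face output-mask resolution, and the device's minimum quality
#' score for inclusion. Two stock profiles are provided:
#' \describe{
#'   \item{spectralis}{49 B-scans of 512 x 496 px, network input
#'     128 x 128 x 64 (z,x,y), mask 128 x 64, quality index >= 25, nIR
#'     available.}
#'   \item{cirrus}{200 B-scans of 200 x 1024 px, network input
#'     128 x 128 x 128, mask 128 x 128, signal score >= 5, no nIR.}
#' }
#'
#' @slot name profile name.
#' @slot fovMM lateral and slow-axis field of view in mm (default 6 x 6).
#' @slot nativeDims native (z, x, y) dimensions in px.
#' @slot netInputDims (z, x, y) dimensions fed to the network.
#' @slot maskDims en face output (x, y) dimensions; must equal
#'   \code{netInputDims[2:3]}.
#' @slot qualityMin minimum quality score for inclusion (> 0).
#' @slot hasNIR does the device provide nIR en face images?
#' @export
setClass("DeviceProfile",
  representation(name = "character", fovMM = "numeric", nativeDims = "integer",
                 netInputDims = "integer", maskDims = "integer",
                 qualityMin = "numeric", hasNIR = "logical")
)

setValidity("DeviceProfile", function(object) {
  if (length(object@nativeDims) != 3L || any(object@nativeDims < 1L))
    return("nativeDims must be three positive integers")
  if (length(object@netInputDims) != 3L || any(object@netInputDims < 1L))
    return("netInputDims must be three positive integers")
  if (length(object@maskDims) != 2L ||
      !all(object@maskDims == object@netInputDims[2:3]))
    return("maskDims must equal netInputDims (x, y)")
  if (object@qualityMin <= 0) return("qualityMin must be > 0")
  if (length(object@fovMM) != 2L || any(object@fovMM <= 0))
    return("fovMM must be two positive extents")
  TRUE
})

#' Build a device profile
#'
#' @param name \code{"spectralis"} or \code{"cirrus"}; selects stock
#'   defaults which any argument below can override (useful for reduced,
#'   desk-scale experiments).
#' @param fovMM field of view (lateral, slow axis) in mm.
#' @param nativeDims native (z, x, y) px.
#' @param netInputDims network input (z, x, y) px.
#' @param maskDims en face mask (x, y) px; defaults to
#'   \code{netInputDims[2:3]}.
#' @param qualityMin minimum quality score for inclusion.
#' @param hasNIR whether nIR en face imaging is available.
#' @return A \linkS4class{DeviceProfile}.
#' @examples
#' deviceProfile("spectralis")
#' ## a reduced profile for quick experiments
#' deviceProfile("spectralis", nativeDims = c(96, 64, 32),
#'               netInputDims = c(32, 32, 16))
#' @export
deviceProfile <- function(name = c("spectralis", "cirrus"), fovMM = NULL,
                          nativeDims = NULL, netInputDims = NULL,
                          maskDims = NULL, qualityMin = NULL, hasNIR = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    spectralis = list(fovMM = c(6, 6), nativeDims = c(496L, 512L, 49L),
                      netInputDims = c(128L, 128L, 64L), qualityMin = 25,
                      hasNIR = TRUE),
    cirrus = list(fovMM = c(6, 6), nativeDims = c(1024L, 200L, 200L),
                  netInputDims = c(128L, 128L, 128L), qualityMin = 5,
                  hasNIR = FALSE))
  if (is.null(fovMM)) fovMM <- def$fovMM
  if (is.null(nativeDims)) nativeDims <- def$nativeDims
  if (is.null(netInputDims)) netInputDims <- def$netInputDims
  if (is.null(maskDims)) maskDims <- netInputDims[2:3]
  if (is.null(qualityMin)) qualityMin <- def$qualityMin
  if (is.null(hasNIR)) hasNIR <- def$hasNIR
  new("DeviceProfile", name = name, fovMM = as.numeric(fovMM),
      nativeDims = as.integer(nativeDims),
      netInputDims = as.integer(netInputDims),
      maskDims = as.integer(maskDims), qualityMin = as.numeric(qualityMin),
      hasNIR = isTRUE(hasNIR))
}

setMethod("show", "DeviceProfile", function(object) {
  cat(sprintf(paste0(
    "DeviceProfile '%s': native %s, net input %s, mask %s,\n",
    "  FOV %.1f x %.1f mm, quality >= %g, nIR: %s\n"),
    object@name, paste(object@nativeDims, collapse = "x"),
    paste(object@netInputDims, collapse = "x"),
    paste(object@maskDims, collapse = "x"),
    object@fovMM[1], object@fovMM[2], object@qualityMin,
    if (object@hasNIR) "yes" else "no"))
})

#' En face pixel geometry of a device profile
#'
#' @param profile a \linkS4class{DeviceProfile}.
#' @param dims en face (nx, ny) pixel dimensions; defaults to the native
#'   en face grid.
#' @return list with \code{dx}, \code{dy} (mm/px) and \code{pixelAreaMM2}.
#' @export
enFacePixel <- function(profile, dims = profile@nativeDims[2:3]) {
  dx <- profile@fovMM[1] / dims[1]
  dy <- profile@fovMM[2] / dims[2]
  list(dx = dx, dy = dy, pixelAreaMM2 = dx * dy)
}

# ---------------------------------------------------------------------------

#' SyntheticParams: study-design parameters for a synthetic cohort
#'
#' @slot device a \linkS4class{DeviceProfile}.
#' @slot nSubjects number of subjects.
#' @slot eyesPerSubject eyes imaged per subject (1 = OD, 2 = OD+OS).
#' @slot visitsPerEye longitudinal visits per eye.
#' @slot nFociRange integer pair, lesion focus count per eye at baseline.
#' @slot focusRadiusRangeMM equivalent-radius range of one focus, mm.
#' @slot growthRateMM2PerVisit programmed GA area increase per visit, mm^2.
#' @slot speckleSigma log-normal multiplicative speckle sigma (0 = none).
#' @slot namdFraction fraction of eyes given nAMD confounders, in [0, 1].
#' @slot qualityScoreRange range quality scores are drawn from.
#' @slot seed root seed for the cohort.
#' @export
setClass("SyntheticParams",
  representation(device = "DeviceProfile", nSubjects = "integer",
                 eyesPerSubject = "integer", visitsPerEye = "integer",
                 nFociRange = "integer", focusRadiusRangeMM = "numeric",
                 growthRateMM2PerVisit = "numeric", speckleSigma = "numeric",
                 namdFraction = "numeric", qualityScoreRange = "numeric",
                 seed = "integer")
)

setValidity("SyntheticParams", function(object) {
  ordered <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!ordered(object@nFociRange) || any(object@nFociRange < 0L))
    return("nFociRange must be an ordered non-negative pair")
  if (!ordered(object@focusRadiusRangeMM) || any(object@focusRadiusRangeMM <= 0))
    return("focusRadiusRangeMM must be an ordered positive pair")
  if (!ordered(object@qualityScoreRange))
    return("qualityScoreRange must be ordered (low <= high)")
  if (object@namdFraction < 0 || object@namdFraction > 1)
    return("namdFraction must lie in [0, 1]")
  if (object@growthRateMM2PerVisit < 0)
    return("growthRateMM2PerVisit must be >= 0")
  if (object@speckleSigma < 0) return("speckleSigma must be >= 0")
  TRUE
})

#' Construct synthetic-cohort parameters
#'
#' Defaults describe the emulated clinical setting: every eye has GA (one to
#' three foci of 0.75-1.5 mm equivalent radius), lesions grow by about
#' 0.4 mm^2 per visit, speckle is moderate, and roughly 30 percent of eyes
#' carry nAMD-like confounders. Quality scores are drawn above the device
#' threshold by default so the inclusion filter only acts when configured to.
#'
#' @param device a \linkS4class{DeviceProfile}.
#' @param nSubjects,eyesPerSubject,visitsPerEye cohort structure.
#' @param nFociRange integer pair of lesion focus counts.
#' @param focusRadiusRangeMM per-focus equivalent radius range, mm.
#' @param growthRateMM2PerVisit programmed area growth per visit, mm^2.
#' @param speckleSigma multiplicative log-normal speckle sigma.
#' @param namdFraction fraction of eyes with nAMD confounders.
#' @param qualityScoreRange range to draw quality scores from; default
#'   \code{qualityMin + c(1, 15)} of the device.
#' @param seed root seed.
#' @return A \linkS4class{SyntheticParams}.
#' @export
syntheticParams <- function(device = deviceProfile("spectralis"),
                            nSubjects = 20L, eyesPerSubject = 1L,
                            visitsPerEye = 3L, nFociRange = c(1L, 3L),
                            focusRadiusRangeMM = c(0.75, 1.5),
                            growthRateMM2PerVisit = 0.4, speckleSigma = 0.2,
                            namdFraction = 0.3, qualityScoreRange = NULL,
                            seed = 1L) {
  if (is.null(qualityScoreRange))
    qualityScoreRange <- device@qualityMin + c(1, 15)
  new("SyntheticParams", device = device, nSubjects = as.integer(nSubjects),
      eyesPerSubject = as.integer(eyesPerSubject),
      visitsPerEye = as.integer(visitsPerEye),
      nFociRange = as.integer(nFociRange),
      focusRadiusRangeMM = as.numeric(focusRadiusRangeMM),
      growthRateMM2PerVisit = as.numeric(growthRateMM2PerVisit),
      speckleSigma = as.numeric(speckleSigma),
      namdFraction = as.numeric(namdFraction),
      qualityScoreRange = as.numeric(qualityScoreRange), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------

#' NetConfig: architecture hyperparameters of the 3D-to-2D network
#'
#' @slot levels encoder/decoder depth (default 4).
#' @slot baseChannels channels at the finest level (default 16); doubled at
#'   each deeper level.
#' @slot useAttention use attention gates on the skip connections.
#' @slot useResidual use residual double-convolution blocks.
#' @slot inChannels 1, or 2 when an nIR channel is fused.
#' @slot inputDims network input (z, x, y).
#' @slot maskDims output (x, y); must equal \code{inputDims[2:3]}.
#' @slot seed parameter-initialization seed.
#' @export
setClass("NetConfig",
  representation(levels = "integer", baseChannels = "integer",
                 useAttention = "logical", useResidual = "logical",
                 inChannels = "integer", inputDims = "integer",
                 maskDims = "integer", seed = "integer")
)

setValidity("NetConfig", function(object) {
  if (object@levels < 1L) return("levels must be >= 1")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  if (!object@inChannels %in% c(1L, 2L)) return("inChannels must be 1 or 2")
  if (length(object@inputDims) != 3L || any(object@inputDims < 1L))
    return("inputDims must be three positive integers")
  if (!all(object@maskDims == object@inputDims[2:3]))
    return("maskDims must equal inputDims (x, y)")
  f <- 2^object@levels
  if (any(object@inputDims[2:3] %% f != 0L))
    return(sprintf("input x,y dims must be divisible by 2^levels = %d", f))
  TRUE
})

#' Construct a network configuration
#'
#' @param inputDims network input dimensions (z, x, y).
#' @param levels encoder/decoder depth.
#' @param baseChannels channels at the finest level.
#' @param useAttention enable attention gates (ablation switch).
#' @param useResidual enable residual blocks (ablation switch).
#' @param inChannels 1, or 2 to fuse an nIR channel.
#' @param seed initialization seed.
#' @return A \linkS4class{NetConfig}.
#' @examples
#' netConfig(c(128, 128, 64))            # Spectralis geometry
#' netConfig(c(128, 128, 128))           # Cirrus geometry
#' @export
netConfig <- function(inputDims, levels = 4L, baseChannels = 16L,
                      useAttention = TRUE, useResidual = TRUE,
                      inChannels = 1L, seed = 1L) {
  new("NetConfig", levels = as.integer(levels),
      baseChannels = as.integer(baseChannels),
      useAttention = isTRUE(useAttention), useResidual = isTRUE(useResidual),
      inChannels = as.integer(inChannels), inputDims = as.integer(inputDims),
      maskDims = as.integer(inputDims[2:3]), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------

#' TrainConfig: optimization hyperparameters
#'
#' Defaults describe the full-scale reference recipe: up to 450 epochs,
#' batch size 32, early-stopping patience 70 epochs, AdamW at learning
#' rate 5e-5, and a loss weighing cross-entropy and Dice equally.
#'
#' @slot epochs maximum epochs (default 450).
#' @slot batchSize minibatch size (default 32).
#' @slot patience epochs without validation improvement before stopping
#'   (default 70); must be <= epochs and >= 1.
#' @slot learningRate AdamW learning rate (default 5e-5).
#' @slot lossWeights (w_ce, w_dice), non-negative, not both zero.
#' @slot valFraction fraction of training subjects held out for validation.
#' @slot weightDecay decoupled weight-decay coefficient (default 1e-2).
#' @slot seed shuffling/initialization seed for the optimization.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 patience = "integer", learningRate = "numeric",
                 lossWeights = "numeric", valFraction = "numeric",
                 weightDecay = "numeric", seed = "integer")
)

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@patience < 1L || object@patience > object@epochs)
    return("patience must satisfy 1 <= patience <= epochs")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (length(object@lossWeights) != 2L || any(object@lossWeights < 0) ||
      sum(object@lossWeights) <= 0)
    return("lossWeights must be non-negative with positive sum")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    return("valFraction must lie in (0, 1)")
  TRUE
})

#' Construct a training configuration
#'
#' @param epochs,batchSize,patience,learningRate,lossWeights,valFraction,
#'   weightDecay,seed see \linkS4class{TrainConfig}.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(epochs = 450L, batchSize = 32L, patience = 70L,
                        learningRate = 5e-5, lossWeights = c(1, 1),
                        valFraction = 0.2, weightDecay = 1e-2, seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), patience = as.integer(patience),
      learningRate = as.numeric(learningRate),
      lossWeights = as.numeric(lossWeights),
      valFraction = as.numeric(valFraction),
      weightDecay = as.numeric(weightDecay), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------

#' GANet: the 3D-encoder/2D-decoder segmentation network
#'
#' Holds the immutable \linkS4class{NetConfig} plus the parameter list.
#' Parameters are plain named numeric arrays so they can be checksummed,
#' serialized and manipulated in tests; use \code{\link{netParameters}}.
#'
#' @slot config a \linkS4class{NetConfig}.
#' @slot params nested named list of numeric arrays.
#' @export
setClass("GANet", representation(config = "NetConfig", params = "list"))

#' Access or replace network parameters
#' @param net a \linkS4class{GANet}.
#' @param value replacement parameter list (same structure).
#' @return \code{netParameters} returns the nested parameter list.
#' @export
netParameters <- function(net) net@params

#' @rdname netParameters
#' @export
`netParameters<-` <- function(net, value) {
  net@params <- value
  net
}

#' @rdname netParameters
#' @export
netConfigOf <- function(net) net@config

setMethod("show", "GANet", function(object) {
  np <- sum(vapply(rapply(object@params, length, how = "unlist"),
                   identity, numeric(1)))
  cat(sprintf(
    "GANet: %d levels, base %d ch, input %s -> mask %s, %s%s%d parameters\n",
    object@config@levels, object@config@baseChannels,
    paste(object@config@inputDims, collapse = "x"),
    paste(object@config@maskDims, collapse = "x"),
    if (object@config@useAttention) "attention, " else "no attention, ",
    if (object@config@useResidual) "residual, " else "plain, ",
    as.integer(np)))
})

# ---------------------------------------------------------------------------

#' NetInput: one network-ready sample
#'
#' @slot volume normalized 3D array at the profile's network input dims.
#' @slot nir optional 2D matrix at mask dims (or NULL).
#' @slot target optional binary \linkS4class{EnFaceMask} at mask dims.
#' @slot recordID originating scan record.
#' @export
setClass("NetInput",
  representation(volume = "array", nir = "ANY", target = "ANY",
                 recordID = "character"),
  prototype(nir = NULL, target = NULL, recordID = "")
)

setValidity("NetInput", function(object) {
  if (length(dim(object@volume)) != 3L) return("volume must be a 3D array")
  if (!is.null(object@target)) {
    if (!is(object@target, "EnFaceMask")) return("target must be an EnFaceMask")
    if (!object@target@binary) return("target must be binary")
  }
  TRUE
})

#' Construct a NetInput
#' @param volume normalized 3D array (z, x, y).
#' @param nir optional 2D matrix at mask dims.
#' @param target optional binary \linkS4class{EnFaceMask}.
#' @param recordID originating record id.
#' @return A \linkS4class{NetInput}.
#' @export
NetInput <- function(volume, nir = NULL, target = NULL, recordID = "") {
  new("NetInput", volume = volume, nir = nir, target = target,
      recordID = as.character(recordID))
}

# ---------------------------------------------------------------------------

#' EvalReport: cohort-level agreement analysis
#'
#' @slot perScan data.frame with one row per evaluated scan: record_id, dsc,
#'   area_manual_mm2, area_auto_mm2, has_nAMD (+ fold when cross-validated).
#' @slot r2 squared Pearson correlation between manual and automated areas.
#' @slot bias mean of (manual - automated) areas, mm^2.
#' @slot loa Bland-Altman limits of agreement (low, high), mm^2.
#' @slot strata per-stratum summaries (GA_only, GA_nAMD): n, mean_dsc, r2.
#' @slot pDSC p-value of the pooled Student t-test comparing DSC between
#'   strata.
#' @slot pR2 p-value of the Fisher-z test comparing the two strata's
#'   area correlations.
#' @slot pR2Method label of the correlation-comparison method.
#' @slot nFolds number of cross-validation folds (0 when not applicable).
#' @export
setClass("EvalReport",
  representation(perScan = "data.frame", r2 = "numeric", bias = "numeric",
                 loa = "numeric", strata = "list", pDSC = "numeric",
                 pR2 = "numeric", pR2Method = "character", nFolds = "integer"),
  prototype(r2 = NA_real_, bias = NA_real_, loa = c(NA_real_, NA_real_),
            strata = list(), pDSC = NA_real_, pR2 = NA_real_,
            pR2Method = "fisher-z", nFolds = 0L)
)

setValidity("EvalReport", function(object) {
  ps <- object@perScan
  need <- c("record_id", "dsc", "area_manual_mm2", "area_auto_mm2", "has_nAMD")
  if (!all(need %in% names(ps)))
    return(paste("perScan must contain columns:", paste(need, collapse = ", ")))
  if (nrow(ps) && (any(ps$dsc < 0) || any(ps$dsc > 1)))
    return("dsc values must lie in [0, 1]")
  if (!is.na(object@bias) && length(object@loa) == 2L &&
      all(is.finite(object@loa)) &&
      (object@loa[1] > object@bias || object@bias > object@loa[2]))
    return("limits of agreement must bracket the bias")
  if (length(object@strata)) {
    n <- sum(vapply(object@strata, function(s) s$n, numeric(1)))
    if (n != nrow(ps)) return("strata sizes must sum to the per-scan count")
  }
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d scans, %d folds\n", nrow(object@perScan),
              object@nFolds))
  if (nrow(object@perScan)) {
    cat(sprintf("  mean DSC %.3f, area r^2 %.3f\n",
                mean(object@perScan$dsc), object@r2))
    cat(sprintf("  Bland-Altman bias %.3f mm^2, LOA [%.3f, %.3f]\n",
                object@bias, object@loa[1], object@loa[2]))
    for (nm in names(object@strata)) {
      s <- object@strata[[nm]]
      cat(sprintf("  %s: n = %d, mean DSC %.3f, r^2 %.3f\n", nm, s$n,
                  s$mean_dsc, s$r2))
    }
    cat(sprintf("  p(DSC, pooled t) = %.3g; p(r^2, %s) = %.3g\n",
                object@pDSC, object@pR2Method, object@pR2))
  }
})
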