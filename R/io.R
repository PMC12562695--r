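#' Read an OCT volume from disk
#'
#' Volumes are stored as multi-page TIFF (one page per B-scan; each page is a
#' z-by-x image) or NIfTI with axes already ordered (z, x, y). The returned
#' grid always follows the package's (z, x, y) axis convention.
#'
#' @param path path to a .tif/.tiff or .nii/.nii.gz file.
#' @param spacingMM numeric(3), mm per voxel along (z, x, y).
#' @param recordID optional record identifier to attach.
#' @return An \linkS4class{OCTVolume}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, spacingMM, recordID = "") {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- tryCatch(as.array(RNifti::readNifti(path)),
                    error = function(e) stop("unreadable NIfTI file: ", path))
    if (length(dim(arr)) != 3L) stop("NIfTI volume must be 3D: ", path)
    return(OCTVolume(array(as.numeric(arr), dim(arr)), spacingMM, recordID))
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("unreadable TIFF file: ", path))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("corrupt stack: page size differs across pages in ", path)
  data <- array(0, c(d1[1], d1[2], length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]
  OCTVolume(data, spacingMM, recordID)
}

#' Write an OCT volume as a multi-page TIFF
#'
#' Intensities are clamped to [0, 1] and quantized to 16-bit; a volume whose
#' values already sit on the 16-bit grid round-trips bit-identically.
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param path output .tif path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  d <- dim(vol)
  pages <- lapply(seq_len(d[3]), function(i) {
    p <- vol@data[, , i]
    p[p < 0] <- 0
    p[p > 1] <- 1
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an en face GA mask from an 8-bit grayscale PNG
#'
#' Any nonzero pixel is taken as GA. The on-disk image has x along the
#' width and y (B-scan index) along the height; the returned grid is
#' indexed (x, y).
#'
#' @param path path to the PNG.
#' @param pixelAreaMM2 area of one en face pixel in mm^2.
#' @return A binary \linkS4class{EnFaceMask}.
#' @export
readMask <- function(path, pixelAreaMM2) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("unreadable PNG file: ", path))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 2L) stop("mask PNG must be grayscale: ", path)
    img <- img[, , 1]
  }
  grid <- t(img)  # (height=y, width=x) -> (x, y)
  grid[grid > 0] <- 1
  EnFaceMask(grid, pixelAreaMM2, binary = TRUE)
}

#' Write a binary en face mask as an 8-bit grayscale PNG
#'
#' @param mask a binary \linkS4class{EnFaceMask}.
#' @param path output .png path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  if (!mask@binary) stop("only binary masks are written to PNG")
  png::writePNG(t(mask@grid), path)
  invisible(path)
}

#' Read / write an nIR en face image (PNG, grayscale)
#'
#' @param path image path.
#' @param fovDeg nominal field of view in degrees.
#' @return \code{readNIR}: an \linkS4class{NIRImage}.
#' @export
readNIR <- function(path, fovDeg = 30) {
  if (!file.exists(path)) stop("nIR file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  NIRImage(t(img), fovDeg = fovDeg)
}

#' @rdname readNIR
#' @param nir an \linkS4class{NIRImage}.
#' @export
writeNIR <- function(nir, path) {
  g <- nir@grid
  g <- (g - min(g)) / max(max(g) - min(g), 1e-12)
  png::writePNG(t(g), path)
  invisible(path)
}

cohort_required_cols <- c("subject_id", "eye", "visit_index", "device",
                          "quality_score", "has_nAMD", "has_GA",
                          "volume_path", "mask_path")

#' Read a cohort metadata table
#'
#' The CSV must carry columns \code{subject_id, eye, visit_index, device,
#' quality_score, has_nAMD, has_GA, volume_path, mask_path} and optionally
#' \code{nir_path} (plus any extra columns, which are preserved). The key
#' (subject_id, eye, visit_index) must be unique.
#'
#' @param metadataPath path to the cohort CSV.
#' @param root directory file paths are interpreted relative to; defaults to
#'   the CSV's directory.
#' @return A data.frame of scan records with absolute file paths and a
#'   \code{record_id} column.
#' @export
readCohort <- function(metadataPath, root = dirname(metadataPath)) {
  if (!file.exists(metadataPath)) stop("metadata file not found: ", metadataPath)
  df <- read.csv(metadataPath, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_cols, names(df))
  if (length(missing))
    stop("cohort schema error; missing columns: ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(as_cohort(df, root))
  if (!all(df$eye %in% c("OD", "OS"))) stop("eye must be 'OD' or 'OS'")
  key <- paste(df$subject_id, df$eye, df$visit_index, sep = "|")
  if (anyDuplicated(key))
    stop("cohort integrity error: duplicated (subject_id, eye, visit_index)")
  as_cohort(df, root)
}

as_cohort <- function(df, root = NULL) {
  df$has_nAMD <- as.logical(df$has_nAMD)
  df$has_GA <- as.logical(df$has_GA)
  df$visit_index <- as.integer(df$visit_index)
  df$record_id <- paste(df$subject_id, df$eye, df$visit_index, sep = "_")
  if (!is.null(root)) {
    for (col in intersect(c("volume_path", "mask_path", "nir_path"), names(df)))
      df[[col]] <- ifelse(is.na(df[[col]]) | df[[col]] == "", NA_character_,
                          file.path(root, df[[col]]))
  }
  df
}

#' Write a cohort metadata table
#'
#' @param records cohort data.frame (see \code{\link{readCohort}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(records, path) {
  drop <- intersect("record_id", names(records))
  write.csv(records[setdiff(names(records), drop)], path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize an evaluation report as JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output .json path.
#' @return \code{writeEvalReport}: \code{path} invisibly;
#'   \code{readEvalReport}: the reconstructed \linkS4class{EvalReport}.
#' @export
writeEvalReport <- function(report, path) {
  obj <- list(per_scan = report@perScan, r2 = report@r2, bias = report@bias,
              loa = report@loa, strata = report@strata, p_dsc = report@pDSC,
              p_r2 = report@pR2, p_r2_method = report@pR2Method,
              n_folds = report@nFolds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x, n = 1L) {
    v <- suppressWarnings(as.numeric(unlist(x)))
    if (!length(v)) rep(NA_real_, n) else v
  }
  new("EvalReport", perScan = as.data.frame(obj$per_scan),
      r2 = num(obj$r2), bias = num(obj$bias), loa = num(obj$loa, 2L),
      strata = lapply(obj$strata, function(s)
        list(n = num(s$n), mean_dsc = num(s$mean_dsc), r2 = num(s$r2))),
      pDSC = num(obj$p_dsc), pR2 = num(obj$p_r2),
      pR2Method = as.character(obj$p_r2_method),
      nFolds = as.integer(obj$n_folds))
}
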