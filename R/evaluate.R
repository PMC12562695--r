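#' Dice similarity coefficient between two binary masks
#'
#' \code{2|A n B| / (|A| + |B|)}; symmetric, in [0, 1]. Two empty masks are
#' in perfect agreement about the absence of GA, so the score is defined as
#' 1 in that case.
#'
#' @param a,b binary \linkS4class{EnFaceMask}s or 0/1 matrices of equal
#'   dimensions.
#' @return Scalar in [0, 1].
#' @export
dsc <- function(a, b) {
  ga <- if (is(a, "EnFaceMask")) a@grid else a
  gb <- if (is(b, "EnFaceMask")) b@grid else b
  if (!all(dim(ga) == dim(gb))) stop("mask shape mismatch")
  sa <- sum(ga); sb <- sum(gb)
  if (sa + sb == 0) return(1)
  2 * sum(ga * gb) / (sa + sb)
}

#' Lesion area of a binary mask in mm^2
#'
#' Count of positive pixels times the per-pixel area.
#'
#' @param mask a binary \linkS4class{EnFaceMask}.
#' @return Area in mm^2.
#' @export
areaMM2 <- function(mask) {
  if (!is(mask, "EnFaceMask")) stop("areaMM2 expects an EnFaceMask")
  if (!isTRUE(mask@binary)) stop("areaMM2 expects a binary mask")
  sum(mask@grid) * mask@pixelAreaMM2
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return r^2 in [0, 1].
#' @export
pearsonR2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("r^2 needs at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance")
  cor(x, y)^2
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as manual minus automated. The limits of
#' agreement are \code{bias +/- 1.96 * sd} with the sample (n-1) standard
#' deviation.
#'
#' @param auto,manual numeric vectors of equal length >= 2.
#' @return list with \code{bias}, \code{loaLow}, \code{loaHigh} (mm^2 when
#'   areas are supplied).
#' @export
blandAltman <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("length mismatch")
  if (length(auto) < 2L) stop("Bland-Altman needs at least 2 pairs")
  d <- manual - auto
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s)
}

#' Two-sample pooled-variance Student t-test
#'
#' Classical equal-variance t-test with a two-sided p-value. Degenerate
#' zero-variance inputs follow the conventions: equal means give p = 1,
#' separated means give p = 0 (below the machine floor).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{p} and \code{significant} (p < 0.05).
#' @export
studentTTest <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, significant = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, significant = TRUE))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), df = n1 + n2 - 2)
  list(t = t, p = p, significant = p < 0.05)
}

#' @importFrom stats var setNames
NULL

#' Compare two independent correlations (Fisher z-transform)
#'
#' Two-sided test of the equality of two independent Pearson correlations:
#' \code{z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))}.
#' Used to compare the manual-vs-automated area correlation between the
#' GA-only and GA-with-nAMD strata.
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 stratum sizes (each >= 4).
#' @return list with \code{z} and two-sided \code{p}.
#' @export
compareCorrelations <- function(r1, n1, r2, n2) {
  if (n1 < 4L || n2 < 4L) stop("each stratum needs n >= 4")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1 is on the boundary of the Fisher z-transform")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Connected-component counts of automated vs manual masks
#'
#' Labels both binary masks with 8-connectivity and returns the component
#' counts, a diagnostic for the tendency of automated segmentations to
#' coalesce neighbouring small lesions into fewer blobs than manual
#' grading.
#'
#' @param auto,manual binary \linkS4class{EnFaceMask}s or 0/1 matrices of
#'   equal dimensions.
#' @return named integer vector \code{c(auto = ..., manual = ...)}.
#' @export
coalescenceDiagnostic <- function(auto, manual) {
  ga <- if (is(auto, "EnFaceMask")) auto@grid else auto
  gm <- if (is(manual, "EnFaceMask")) manual@grid else manual
  if (!all(dim(ga) == dim(gm))) stop("mask shape mismatch")
  c(auto = max(cpp_label8(ga > 0)), manual = max(cpp_label8(gm > 0)))
}

#' Compare the area correlations of the nAMD strata of a per-scan table
#'
#' Splits the per-scan rows on \code{has_nAMD}, computes each stratum's
#' Pearson correlation between manual and automated areas, and tests their
#' equality with \code{\link{compareCorrelations}}.
#'
#' @param perScan data.frame with columns \code{area_manual_mm2},
#'   \code{area_auto_mm2} and \code{has_nAMD}; both strata need n >= 4.
#' @return list with per-stratum \code{r}, \code{n}, and the two-sided
#'   \code{p} of the Fisher-z test.
#' @export
compareR2Strata <- function(perScan) {
  g1 <- perScan[!perScan$has_nAMD, , drop = FALSE]
  g2 <- perScan[perScan$has_nAMD, , drop = FALSE]
  if (nrow(g1) < 4L || nrow(g2) < 4L)
    stop("each stratum needs at least 4 scans")
  r1 <- cor(g1$area_manual_mm2, g1$area_auto_mm2)
  r2 <- cor(g2$area_manual_mm2, g2$area_auto_mm2)
  list(r_GA_only = r1, n_GA_only = nrow(g1), r_GA_nAMD = r2,
       n_GA_nAMD = nrow(g2),
       p = compareCorrelations(r1, nrow(g1), r2, nrow(g2))$p)
}

# strata/correlation/bland-altman summary from a per-scan table
summarize_per_scan <- function(perScan, nFolds = 0L) {
  r2 <- if (nrow(perScan) >= 3L &&
            sd(perScan$area_manual_mm2) > 0 && sd(perScan$area_auto_mm2) > 0)
    pearsonR2(perScan$area_manual_mm2, perScan$area_auto_mm2) else NA_real_
  ba <- if (nrow(perScan) >= 2L)
    blandAltman(perScan$area_auto_mm2, perScan$area_manual_mm2)
  else list(bias = NA_real_, loaLow = NA_real_, loaHigh = NA_real_)
  strata <- list()
  pDSC <- NA_real_
  pR2 <- NA_real_
  stratum_stats <- function(rows) {
    r <- if (nrow(rows) >= 3L && sd(rows$area_manual_mm2) > 0 &&
             sd(rows$area_auto_mm2) > 0)
      cor(rows$area_manual_mm2, rows$area_auto_mm2) else NA_real_
    list(n = nrow(rows), mean_dsc = mean(rows$dsc), r2 = r^2, r = r)
  }
  gaOnly <- perScan[!perScan$has_nAMD, , drop = FALSE]
  gaNamd <- perScan[perScan$has_nAMD, , drop = FALSE]
  if (nrow(gaOnly) && nrow(gaNamd)) {
    s1 <- stratum_stats(gaOnly)
    s2 <- stratum_stats(gaNamd)
    strata <- list(GA_only = s1[c("n", "mean_dsc", "r2")],
                   GA_nAMD = s2[c("n", "mean_dsc", "r2")])
    if (s1$n >= 2L && s2$n >= 2L)
      pDSC <- studentTTest(gaOnly$dsc, gaNamd$dsc)$p
    if (s1$n >= 4L && s2$n >= 4L && is.finite(s1$r) && is.finite(s2$r) &&
        abs(s1$r) < 1 && abs(s2$r) < 1)
      pR2 <- compareCorrelations(s1$r, s1$n, s2$r, s2$n)$p
  } else if (nrow(perScan)) {
    strata <- list(
      GA_only = stratum_stats(gaOnly)[c("n", "mean_dsc", "r2")],
      GA_nAMD = stratum_stats(gaNamd)[c("n", "mean_dsc", "r2")])
    strata <- strata[vapply(strata, function(s) s$n > 0, logical(1))]
  }
  new("EvalReport", perScan = perScan, r2 = r2, bias = ba$bias,
      loa = c(ba$loaLow, ba$loaHigh), strata = strata, pDSC = pDSC,
      pR2 = pR2, pR2Method = "fisher-z", nFolds = as.integer(nFolds))
}

#' Subject-grouped k-fold cross-validation of the full pipeline
#'
#' Applies the quality filter, assigns subject-grouped folds, and for each
#' fold trains a fresh network on the remaining folds (with an internal
#' subject-level train/validation split driving early stopping) and
#' predicts the held-out scans. Every included scan is predicted exactly
#' once. Per-scan Dice scores and manual/automated lesion areas (computed
#' at the output-mask resolution) are aggregated into an
#' \linkS4class{EvalReport} with r^2, Bland-Altman limits of agreement and
#' nAMD-stratified statistics. Deterministic under \code{seed}.
#'
#' @param records cohort data.frame (one device).
#' @param profile the cohort's \linkS4class{DeviceProfile}.
#' @param netCfg a \linkS4class{NetConfig} matching the profile's
#'   network-input dims.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param nFolds number of folds (default 5).
#' @param seed root seed.
#' @param inputs optional pre-built list of \linkS4class{NetInput}s keyed
#'   by record_id (avoids re-reading files across repeated runs).
#' @param keepModels attach the per-fold trained networks to the report
#'   (attribute \code{"models"}, a list indexed fold+1).
#' @param verbose print fold progress.
#' @return An \linkS4class{EvalReport}; the per-scan table carries a
#'   \code{fold} column.
#' @export
crossValidate <- function(records, profile, netCfg, trainCfg, nFolds = 5L,
                          seed = 1L, inputs = NULL, keepModels = FALSE,
                          verbose = FALSE) {
  qf <- qualityFilter(records, setNames(list(profile), profile@name))
  records <- qf$included
  if (nrow(records) == 0L) stop("no records pass the quality filter")
  folds <- makeGroupedFolds(records, nFolds, derive_seed(seed, "folds"))
  if (is.null(inputs))
    inputs <- prepareCohortInputs(records, profile,
                                  withNIR = netCfg@inChannels == 2L)
  pxArea <- enFacePixel(profile, profile@maskDims)$pixelAreaMM2
  rows <- list()
  models <- vector("list", nFolds)
  for (k in seq_len(nFolds) - 1L) {
    testIds <- names(folds$foldOf)[folds$foldOf == k]
    trainRec <- records[!records$record_id %in% testIds, , drop = FALSE]
    sp <- splitTrainVal(trainRec, trainCfg@valFraction,
                        derive_seed(seed, paste0("val", k)))
    net <- buildNet(`slot<-`(netCfg, "seed", value = derive_seed(seed, paste0("net", k))))
    tc <- `slot<-`(trainCfg, "seed", value = derive_seed(seed, paste0("fit", k)))
    fit <- fitNet(net, inputs[sp$train$record_id], inputs[sp$val$record_id],
                  tc, verbose = FALSE)
    if (keepModels) models[[k + 1L]] <- fit$net
    if (verbose)
      message(sprintf("fold %d: trained %d epochs (best %d, val DSC %.3f)",
                      k, nrow(fit$history), fit$bestEpoch,
                      max(fit$history$val_dsc)))
    for (rid in testIds) {
      s <- inputs[[rid]]
      pred <- binarizeMask(netForward(fit$net, s, pixelAreaMM2 = pxArea))
      manual <- EnFaceMask(s@target@grid, pxArea, binary = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rid, dsc = dsc(pred, manual),
        area_manual_mm2 = areaMM2(manual), area_auto_mm2 = areaMM2(pred),
        has_nAMD = records$has_nAMD[records$record_id == rid],
        fold = k, stringsAsFactors = FALSE)
    }
  }
  perScan <- do.call(rbind, rows)
  perScan <- perScan[match(records$record_id, perScan$record_id), ]
  rownames(perScan) <- NULL
  rep <- summarize_per_scan(perScan, nFolds)
  if (keepModels) attr(rep, "models") <- models
  rep
}

#' Longitudinal lesion-area report for one eye under a fixed model
#'
#' Applies a fixed (already trained) network to every visit of a single
#' subject-eye and reports the automated GA area per visit, sorted by
#' visit index; the clinical use case of tracking GA growth over time.
#'
#' @param records cohort rows, all of one (subject, eye).
#' @param net a trained \linkS4class{GANet}.
#' @param profile the scans' \linkS4class{DeviceProfile}.
#' @param inputs optional prepared \linkS4class{NetInput}s keyed by
#'   record_id.
#' @return data.frame with \code{visit_index} and \code{area_auto_mm2},
#'   one row per visit in ascending visit order.
#' @export
longitudinalReport <- function(records, net, profile, inputs = NULL) {
  if (length(unique(records$subject_id)) != 1L ||
      length(unique(records$eye)) != 1L)
    stop("longitudinal report requires a single subject-eye series")
  if (is.null(inputs))
    inputs <- prepareCohortInputs(records, profile,
                                  withNIR = net@config@inChannels == 2L)
  pxArea <- enFacePixel(profile, profile@maskDims)$pixelAreaMM2
  ord <- order(records$visit_index)
  data.frame(
    visit_index = records$visit_index[ord],
    area_auto_mm2 = vapply(records$record_id[ord], function(rid) {
      areaMM2(binarizeMask(netForward(net, inputs[[rid]],
                                      pixelAreaMM2 = pxArea)))
    }, numeric(1)),
    row.names = NULL)
}
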