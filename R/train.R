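#' Dice loss between a probability mask and a binary target
#'
#' \code{1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)} with
#' \code{eps = 1e-6}; lies in [0, 1].
#'
#' @param pred probability \linkS4class{EnFaceMask} or numeric matrix.
#' @param target binary \linkS4class{EnFaceMask} or 0/1 matrix of the same
#'   dimensions.
#' @return Scalar loss.
#' @export
diceLoss <- function(pred, target) {
  p <- if (is(pred, "EnFaceMask")) pred@grid else pred
  t <- if (is(target, "EnFaceMask")) target@grid else target
  if (!all(dim(p) == dim(t))) stop("prediction/target shape mismatch")
  eps <- 1e-6
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' Combined cross-entropy + Dice loss
#'
#' \code{w_ce * BCE + w_dice * diceLoss}, the training objective.
#' Probabilities are clipped to [1e-7, 1 - 1e-7] inside the cross-entropy.
#'
#' @param pred,target as in \code{\link{diceLoss}}.
#' @param weights numeric pair (w_ce, w_dice), non-negative, not both zero.
#' @return Scalar loss.
#' @export
combinedLoss <- function(pred, target, weights = c(1, 1)) {
  if (sum(weights) <= 0) stop("at least one loss weight must be positive")
  p <- if (is(pred, "EnFaceMask")) pred@grid else pred
  t <- if (is(target, "EnFaceMask")) target@grid else target
  if (!all(dim(p) == dim(t))) stop("prediction/target shape mismatch")
  pc <- pmin(1 - 1e-7, pmax(1e-7, p))
  ce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  weights[1] * ce + weights[2] * diceLoss(p, t)
}

# loss value and gradient w.r.t. the pre-sigmoid logit
loss_grad_logit <- function(p, t, weights) {
  n <- length(p)
  pc <- pmin(1 - 1e-7, pmax(1e-7, p))
  ce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  eps <- 1e-6
  num <- 2 * sum(p * t) + eps
  den <- sum(p) + sum(t) + eps
  dice <- 1 - num / den
  dCE_dlogit <- (p - t) / n                       # exact through the sigmoid
  dDice_dp <- -(2 * t * den - num) / den^2
  dDice_dlogit <- dDice_dp * p * (1 - p)
  list(loss = weights[1] * ce + weights[2] * dice,
       dLogit = weights[1] * dCE_dlogit + weights[2] * dDice_dlogit)
}

#' Subject-grouped fold assignment
#'
#' Subjects are shuffled under \code{seed}, ordered by decreasing scan
#' count (shuffle breaking ties) and dealt round-robin onto the folds, so
#' scan counts are balanced and all scans of a subject share one fold --
#' no subject ever appears in both the train and test side of a split.
#'
#' @param records cohort data.frame with \code{subject_id} and
#'   \code{record_id} columns.
#' @param nFolds number of folds; must not exceed the number of subjects.
#' @param seed shuffling seed.
#' @return list with \code{nFolds} and \code{foldOf}, a named integer
#'   vector mapping record_id to a fold index in \code{0:(nFolds-1)}.
#' @export
makeGroupedFolds <- function(records, nFolds, seed) {
  subjects <- unique(records$subject_id)
  if (length(subjects) < nFolds)
    stop("grouped folds infeasible: fewer subjects (", length(subjects),
         ") than folds (", nFolds, ")")
  counts <- table(records$subject_id)
  shuffled <- with_seed(seed, sample(subjects))
  ordered <- shuffled[order(-as.integer(counts[shuffled]))]
  foldOfSubject <- setNames((seq_along(ordered) - 1L) %% nFolds, ordered)
  foldOf <- foldOfSubject[records$subject_id]
  names(foldOf) <- records$record_id
  list(nFolds = as.integer(nFolds), foldOf = foldOf)
}

#' Split training records into train and validation at subject granularity
#'
#' The validation side receives \code{ceiling(valFraction * nSubjects)}
#' subjects; no subject spans both sides.
#'
#' @param records cohort data.frame.
#' @param valFraction fraction in (0, 1).
#' @param seed shuffling seed.
#' @return list with data.frames \code{train} and \code{val}.
#' @export
splitTrainVal <- function(records, valFraction, seed) {
  subjects <- unique(records$subject_id)
  if (length(subjects) < 2L)
    stop("train/validation split needs at least two subjects")
  nVal <- ceiling(valFraction * length(subjects))
  if (nVal >= length(subjects))
    stop("validation fraction leaves no training subjects")
  valSubjects <- with_seed(seed, sample(subjects, nVal))
  list(train = records[!records$subject_id %in% valSubjects, , drop = FALSE],
       val = records[records$subject_id %in% valSubjects, , drop = FALSE])
}

# AdamW step over a flat named parameter list; state carries m, v, t
adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    step <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  list(params = params, state = state)
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

mean_val_dsc <- function(net, val) {
  mean(vapply(val, function(s) {
    p <- net_fw(net, s@volume, s@nir, keepCache = FALSE)$prob
    dsc((p >= 0.5) * 1, s@target@grid)
  }, numeric(1)))
}

#' Train the network with the combined cross-entropy/Dice recipe
#'
#' Minimizes \code{\link{combinedLoss}} with AdamW (decoupled weight
#' decay). After every epoch the mean validation Dice score of the
#' binarized predictions is evaluated; training stops when the epoch budget
#' is exhausted or the validation score has not improved for
#' \code{patience} consecutive epochs. The parameters from the best
#' validation epoch are returned together with the per-epoch history.
#' Fully deterministic under the configuration seed.
#'
#' The learning rate is warmed up linearly over the first three epochs
#' (1/3, 2/3, then full rate). Without it, an aggressive rate can slam the
#' output towards the all-background solution on class-imbalanced masks
#' before the Dice term has any foothold, and the sigmoid saturation then
#' starves it of gradient.
#'
#' @param net a \linkS4class{GANet} (possibly already partially trained;
#'   calling again warm-starts from the given parameters).
#' @param train,val non-empty lists of \linkS4class{NetInput}s with binary
#'   targets.
#' @param config a \linkS4class{TrainConfig}.
#' @param verbose print per-epoch progress.
#' @return list with \code{net} (best-epoch parameters), \code{history}
#'   (data.frame epoch/train_loss/val_dsc) and \code{bestEpoch}.
#' @export
fitNet <- function(net, train, val, config, verbose = FALSE) {
  validObject(config)
  if (length(train) == 0L || length(val) == 0L)
    stop("training and validation sets must be non-empty")
  for (s in c(train, val))
    if (is.null(s@target)) stop("all samples must carry a binary target")
  params <- net@params
  zeros <- lapply(params, function(x) x * 0)
  state <- list(t = 0L, m = zeros, v = zeros)
  bestDsc <- -Inf
  bestParams <- params
  bestEpoch <- 0L
  bad <- 0L
  hist <- list()
  for (epoch in seq_len(config@epochs)) {
    lrEpoch <- config@learningRate * min(1, epoch / 3)
    idx <- with_seed(derive_seed(config@seed, paste0("shuffle", epoch)),
                     sample(length(train)))
    batches <- split(idx, ceiling(seq_along(idx) / config@batchSize))
    epochLoss <- 0
    for (bt in batches) {
      acc <- NULL
      bloss <- 0
      for (i in bt) {
        s <- train[[i]]
        fw <- net_fw(net, s@volume, s@nir, keepCache = TRUE)
        lg <- loss_grad_logit(fw$prob, s@target@grid, config@lossWeights)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (record ", s@recordID, "); aborting")
        bloss <- bloss + lg$loss
        g <- net_bw(net, fw$cache, lg$dLogit / length(bt))
        acc <- add_grads(acc, g)
      }
      st <- adamw_step(net@params, acc, state, lrEpoch, config@weightDecay)
      net@params <- st$params
      state <- st$state
      epochLoss <- epochLoss + bloss / length(bt)
    }
    valDsc <- mean_val_dsc(net, val)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = epochLoss / length(batches),
                                val_dsc = valDsc)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val DSC %.4f", epoch,
                      epochLoss / length(batches), valDsc))
    if (valDsc > bestDsc) {
      bestDsc <- valDsc
      bestParams <- net@params
      bestEpoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config@patience) break
    }
  }
  net@params <- bestParams
  list(net = net, history = do.call(rbind, hist), bestEpoch = bestEpoch)
}
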