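test_that("Dice loss follows its closed form", {
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(diceLoss(t, t), 1e-6)                    # perfect overlap
  expect_gt(diceLoss(1 - t, t), 1 - 1e-5)            # total miss
  # pred all 0.5, target half ones on 2x2: 1 - (2*1+eps)/(2+2+eps) ~ 0.5
  half <- matrix(0.5, 2, 2)
  tgt <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(diceLoss(half, tgt), 1 - (2 * 1 + 1e-6) / (4 + 1e-6),
               tolerance = 1e-12)
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("combined loss reduces to its parts and is small for perfect predictions", {
  tgt <- matrix(rbinom(20, 1, 0.5), 4, 5)
  half <- matrix(0.5, 4, 5)
  expect_equal(combinedLoss(half, tgt, c(1, 0)), log(2), tolerance = 1e-12)
  p <- matrix(runif(20), 4, 5)
  expect_equal(combinedLoss(p, tgt, c(0, 1)), diceLoss(p, tgt),
               tolerance = 1e-12)
  clipped <- pmin(1 - 1e-7, pmax(1e-7, tgt))
  expect_lt(combinedLoss(clipped, tgt, c(1, 1)), 1e-4)
  expect_error(combinedLoss(half, tgt, c(0, 0)), "weight")
})

test_that("grouped folds balance scans and never split a subject", {
  rec <- random_records(10L, 1L, seed = 2)  # 10 subjects x 1 scan
  fa <- makeGroupedFolds(rec, 5L, seed = 3)
  expect_equal(unname(table(fa$foldOf)), rep(2L, 5L), ignore_attr = TRUE)

  # one subject with 14 visits stays together
  rec14 <- rbind(random_records(6L, 2L, seed = 4),
                 within(random_records(1L, 1L, seed = 5), {
                   subject_id <- "S999"
                   record_id <- "S999_OD_0"
                 }))
  extra <- do.call(rbind, lapply(1:13, function(v) {
    r <- rec14[nrow(rec14), ]
    r$visit_index <- v
    r$record_id <- paste0("S999_OD_", v)
    r
  }))
  rec14 <- rbind(rec14, extra)
  fa <- makeGroupedFolds(rec14, 3L, seed = 1)
  f999 <- fa$foldOf[grepl("S999", names(fa$foldOf))]
  expect_equal(length(f999), 14L)
  expect_equal(length(unique(f999)), 1L)

  expect_error(makeGroupedFolds(random_records(3L, 2L, seed = 1), 5L, 1),
               "infeasible")
})

test_that("train/validation splits are subject-grouped with a ceiling-sized validation side", {
  rec <- random_records(10L, 3L, seed = 6)
  sp <- splitTrainVal(rec, 0.2, seed = 7)
  expect_equal(length(unique(sp$val$subject_id)), 2L)   # ceiling(0.2*10)
  expect_length(intersect(sp$train$subject_id, sp$val$subject_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$val), nrow(rec))
  sp2 <- splitTrainVal(rec, 0.2, seed = 7)
  expect_identical(sp$val$record_id, sp2$val$record_id)
  expect_error(splitTrainVal(rec[rec$subject_id == "S001", ], 0.2, 1),
               "two subjects")
  expect_error(splitTrainVal(random_records(2L, 1L, seed = 1), 0.9, 1),
               "no training subjects")
})

make_toy_samples <- function(n, seed, dims = c(8L, 8L, 4L)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tgt <- matrix(0, dims[2], dims[3])
    cx <- sample(2:(dims[2] - 1), 1)
    tgt[(cx - 1):(cx + 1), 2:3] <- 1
    vol <- array(rnorm(prod(dims), sd = 0.1), dims)
    vol[dims[1] %/% 2, , ] <- vol[dims[1] %/% 2, , ] + 2 * tgt
    NetInput(normalizeVolume(vol),
             target = EnFaceMask(tgt, 1), recordID = paste0("r", i))
  })
}

test_that("early stopping obeys the patience rule and history bounds", {
  samples <- make_toy_samples(2L, seed = 1)
  net <- buildNet(netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 2L,
                            seed = 1L))
  # patience 1 with a non-improving metric stops after exactly 2 epochs:
  # zero learning rate freezes the network, so val DSC never improves
  tc <- trainConfig(epochs = 10L, batchSize = 2L, patience = 1L,
                    learningRate = 1e-30, seed = 1L)
  fit <- fitNet(net, samples, samples, tc)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$bestEpoch, 1L)

  tc2 <- trainConfig(epochs = 5L, batchSize = 2L, patience = 5L,
                     learningRate = 1e-3, seed = 1L)
  fit2 <- fitNet(net, samples, samples, tc2)
  expect_lte(nrow(fit2$history), 5L)
  expect_error(trainConfig(epochs = 5L, patience = 10L), "patience")
})

test_that("the returned network reproduces the best recorded validation score", {
  samples <- make_toy_samples(4L, seed = 2)
  net <- buildNet(netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 4L,
                            seed = 2L))
  tc <- trainConfig(epochs = 15L, batchSize = 4L, patience = 15L,
                    learningRate = 3e-3, seed = 2L)
  fit <- fitNet(net, samples, samples, tc)
  expect_equal(oct3d2d:::mean_val_dsc(fit$net, samples),
               max(fit$history$val_dsc), tolerance = 1e-12)
})

test_that("training is bit-reproducible under a fixed seed", {
  samples <- make_toy_samples(3L, seed = 3)
  run <- function() {
    net <- buildNet(netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 2L,
                              seed = 5L))
    tc <- trainConfig(epochs = 4L, batchSize = 2L, patience = 4L,
                      learningRate = 1e-3, seed = 5L)
    fitNet(net, samples, samples, tc)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(netChecksum(f1$net), netChecksum(f2$net))
})

test_that("training reduces the loss on a learnable toy task", {
  # median first-to-last loss drop over several seeds
  drops <- vapply(1:3, function(s) {
    samples <- make_toy_samples(4L, seed = s + 10)
    net <- buildNet(netConfig(c(8L, 8L, 4L), levels = 2L, baseChannels = 4L,
                              seed = s))
    tc <- trainConfig(epochs = 8L, batchSize = 4L, patience = 8L,
                      learningRate = 3e-3, seed = s)
    h <- fitNet(net, samples, samples, tc)$history
    h$train_loss[1] - h$train_loss[nrow(h)]
  }, numeric(1))
  expect_gt(median(drops), 0)
})
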