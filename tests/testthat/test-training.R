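test_that("triplet sampling honors the positive/negative policy", {
  labels <- rep(c("A", "B"), each = 2)
  batches <- sample_triplets(labels, 8, 4, seed = 1)
  idx <- do.call(rbind, batches)
  expect_true(all(labels[idx[, "a"]] == labels[idx[, "p"]]))
  expect_true(all(idx[, "a"] != idx[, "p"]))
  expect_true(all(labels[idx[, "a"]] != labels[idx[, "n"]]))
})

test_that("triplet sampling is reproducible and validates classes", {
  labels <- rep(c("A", "B", "C"), each = 4)
  expect_identical(sample_triplets(labels, 20, 8, seed = 3),
                   sample_triplets(labels, 20, 8, seed = 3))
  expect_false(identical(sample_triplets(labels, 20, 8, seed = 3),
                         sample_triplets(labels, 20, 8, seed = 4)))
  err <- expect_error(sample_triplets(c("A", "A", "B"), 4, 2, seed = 1),
                      class = "taxembed_sampling_error")
  expect_match(conditionMessage(err), "B")
  expect_error(sample_triplets(rep("A", 4), 4, 2, seed = 1),
               class = "taxembed_sampling_error")
})

test_that("negative classes are drawn uniformly", {
  labels <- rep(c("A", "B", "C", "D", "E"), each = 4)
  idx <- do.call(rbind, sample_triplets(labels, 10000, 500, seed = 11))
  counts <- table(labels[idx[, "n"]])
  # each class appears as negative with probability 1/5; 3 sigma binomial
  expected <- 10000 / 5
  sigma <- sqrt(10000 * 0.2 * 0.8)
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("plateau reducer cuts the learning rate after patience stagnant epochs", {
  st <- plateau_reducer(lr = 0.001, patience = 20, threshold = 0.01,
                        factor = 0.1)
  lrs <- numeric(30)
  for (e in 1:30) {
    st <- plateau_update(st, 1.0)  # constant loss stream
    lrs[e] <- st$lr
  }
  expect_equal(lrs[20], 0.001)      # first reduction not before patience
  expect_equal(lrs[21], 1e-4)
  # improvement resets the counter
  st <- plateau_reducer(lr = 0.001, patience = 3, threshold = 0.01)
  for (v in c(1, 1, 1, 0.5, 0.5, 0.5)) st <- plateau_update(st, v)
  expect_equal(st$lr, 0.001)
  st <- plateau_update(st, 0.5)
  expect_equal(st$lr, 1e-4)
})

test_that("training returns the minimum-loss checkpoint deterministically", {
  fx <- tiny_training_dataset()
  split <- split_k_shot(fx$ds, 4, seed = 2)
  enc <- encoder_create(input_size = 16, embedding_dim = 16, seed = 1)
  cfg <- training_config(loss = "taxonomic", epochs = 5, batch_size = 8,
                         embedding_dim = 16, seed = 2)
  fit <- train_encoder(enc, fx$ds, split, cfg, taxdist = fx$taxdist)
  expect_equal(fit$best_loss, min(fit$log$loss))
  expect_equal(fit$log$loss[fit$best_epoch], fit$best_loss)
  # the returned encoder reproduces the checkpoint loss contract:
  # its recorded loss is <= every epoch loss in the log
  expect_true(all(fit$best_loss <= fit$log$loss))
  fit2 <- train_encoder(enc, fx$ds, split, cfg, taxdist = fx$taxdist)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$encoder$layers, fit2$encoder$layers)
})

test_that("taxonomic training validates its tree up front", {
  fx <- tiny_training_dataset()
  split <- split_k_shot(fx$ds, 4, seed = 2)
  enc <- encoder_create(input_size = 16, embedding_dim = 16, seed = 1)
  cfg <- training_config(loss = "taxonomic", epochs = 2, batch_size = 8,
                         embedding_dim = 16, seed = 2)
  expect_error(train_encoder(enc, fx$ds, split, cfg),
               class = "taxembed_config_error")
  wrong <- build_distance_matrix(parse_newick("(X:1,Y:1);"))
  expect_error(train_encoder(enc, fx$ds, split, cfg, taxdist = wrong),
               class = "taxembed_validation_error")
})

test_that("HTL training rebuilds the hierarchy on the 5-epoch schedule", {
  fx <- tiny_training_dataset()
  split <- split_k_shot(fx$ds, 4, seed = 3)
  enc <- encoder_create(input_size = 16, embedding_dim = 16, seed = 1)
  cfg <- training_config(loss = "htl", epochs = 12, batch_size = 8,
                         embedding_dim = 16, seed = 3)
  fit <- train_encoder(enc, fx$ds, split, cfg)
  expect_equal(fit$log$epoch[fit$log$rebuild], c(5L, 10L))
})

test_that("the cross-entropy baseline learns a separable toy exactly", {
  # two clearly separable spatial patterns: bright left half vs bright
  # right half, with light pixel noise
  set.seed(10)
  mk <- function(pattern, n) {
    vapply(seq_len(n),
           function(i) pattern + matrix(rnorm(256, 0, 0.05), 16),
           matrix(0, 16, 16))
  }
  pa <- matrix(0.2, 16, 16); pa[, 1:8] <- 0.8
  pb <- matrix(0.2, 16, 16); pb[, 9:16] <- 0.8
  imgs <- pmin(pmax(array(c(mk(pa, 6), mk(pb, 6)), c(16, 16, 12)), 0), 1)
  ds <- image_dataset(imgs, rep(c("left", "right"), each = 6))
  split <- split_k_shot(ds, 4, seed = 1)
  enc <- encoder_create(input_size = 16, embedding_dim = 8, seed = 2)
  cfg <- training_config(loss = "generic", epochs = 20, batch_size = 4,
                         embedding_dim = 8, seed = 1)
  fit <- train_generic(enc, ds, split, cfg)
  pred <- predict_generic(fit, slice_train(ds, split))
  expect_equal(pred, ds$labels[split$train])
  # reproducible loss curve
  fit2 <- train_generic(enc, ds, split, cfg)
  expect_identical(fit$log, fit2$log)
})

test_that("the baseline refuses single-class data", {
  imgs <- array(runif(16 * 16 * 4), c(16, 16, 4))
  ds <- image_dataset(imgs, rep("only", 4))
  split <- list(train = 1:4, val = integer(0), test = integer(0))
  class(split) <- "split_spec"
  enc <- encoder_create(input_size = 16, embedding_dim = 8, seed = 2)
  cfg <- training_config(loss = "generic", epochs = 2, batch_size = 4,
                         embedding_dim = 8)
  expect_error(train_generic(enc, ds, split, cfg),
               class = "taxembed_config_error")
})

test_that("training config validates its ranges", {
  expect_error(training_config(epochs = 0),
               class = "taxembed_validation_error")
  expect_error(training_config(batch_size = 1),
               class = "taxembed_validation_error")
  expect_error(training_config(margin = -1),
               class = "taxembed_validation_error")
})
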