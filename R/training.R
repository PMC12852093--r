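# Siamese training harness: triplet sampling, Adam optimization with a
# reduce-on-plateau schedule, checkpoint selection by smallest training
# loss, and the periodic HTL hierarchy rebuild. No image augmentation is
# applied anywhere in the training path.

#' Training configuration
#'
#' Collects every knob of the training protocol with the defaults used
#' throughout: learning rate 0.001 with a plateau reducer (patience 20,
#' threshold 0.01, factor 0.1), embedding size 64, batch size 128 (64 is
#' the convention for 512-px inputs), and an HTL hierarchy rebuild every 5
#' epochs capped at 16 levels.
#'
#' @param loss one of `"triplet"`, `"taxonomic"`, `"htl"`, `"generic"`.
#' @param epochs maximum number of epochs (>= 1).
#' @param batch_size triplets (or images, for `"generic"`) per batch (>= 2).
#' @param margin fixed margin for the standard triplet loss.
#' @param margin_mode orientation of the taxonomic margin
#'   (see [taxonomic_margin()]).
#' @param norm_scope normalization scope of the taxonomic margin.
#' @param eps division guard of the min-max normalization.
#' @param embedding_dim embedding dimension d.
#' @param lr initial learning rate.
#' @param patience,threshold,factor,threshold_mode,min_lr plateau reducer
#'   settings; `threshold_mode` `"rel"` treats an epoch as improved when the
#'   monitored loss drops below `best * (1 - threshold)`, `"abs"` when it
#'   drops below `best - threshold`.
#' @param htl_rebuild_every rebuild period (epochs) of the HTL hierarchy.
#' @param htl_beta constant offset of the HTL margin.
#' @param htl_max_levels HTL hierarchy depth cap.
#' @param triplets_per_epoch triplets sampled per epoch; defaults to the
#'   training-set size.
#' @param seed master replicate seed; sampler and weight-init seeds are
#'   derived from it.
#' @return an object of class `training_config`.
#' @export
training_config <- function(loss = c("triplet", "taxonomic", "htl", "generic"),
                            epochs = 50L, batch_size = 128L,
                            margin = 1.0,
                            margin_mode = c("monotone", "literal"),
                            norm_scope = c("batch", "matrix"),
                            eps = 1e-6,
                            embedding_dim = 64L,
                            lr = 0.001, patience = 20L, threshold = 0.01,
                            factor = 0.1,
                            threshold_mode = c("rel", "abs"),
                            min_lr = 0,
                            htl_rebuild_every = 5L, htl_beta = 0.1,
                            htl_max_levels = 16L,
                            triplets_per_epoch = NULL,
                            seed = 1L) {
  loss <- match.arg(loss)
  margin_mode <- match.arg(margin_mode)
  norm_scope <- match.arg(norm_scope)
  threshold_mode <- match.arg(threshold_mode)
  if (epochs < 1L) stop_taxembed("epochs must be >= 1",
                                 class = "taxembed_validation_error")
  if (batch_size < 2L) stop_taxembed("batch_size must be >= 2",
                                     class = "taxembed_validation_error")
  if (margin < 0) stop_taxembed("margin must be >= 0",
                                class = "taxembed_validation_error")
  structure(
    list(loss = loss, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), margin = margin,
         margin_mode = margin_mode, norm_scope = norm_scope, eps = eps,
         embedding_dim = as.integer(embedding_dim),
         lr = lr, patience = as.integer(patience), threshold = threshold,
         factor = factor, threshold_mode = threshold_mode, min_lr = min_lr,
         htl_rebuild_every = as.integer(htl_rebuild_every),
         htl_beta = htl_beta, htl_max_levels = as.integer(htl_max_levels),
         triplets_per_epoch = triplets_per_epoch,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

# --- plateau reducer --------------------------------------------------------

#' Reduce-on-plateau learning-rate schedule
#'
#' Stateful schedule: when the monitored loss fails to improve for
#' `patience` consecutive epochs, the learning rate is multiplied by
#' `factor`. Feed each epoch's loss with [plateau_update()].
#'
#' @inheritParams training_config
#' @return a plateau state list with elements `lr`, `best`, `wait`,
#'   `reduced`.
#' @export
plateau_reducer <- function(lr, patience = 20L, threshold = 0.01,
                            factor = 0.1, threshold_mode = c("rel", "abs"),
                            min_lr = 0) {
  threshold_mode <- match.arg(threshold_mode)
  list(lr = lr, patience = as.integer(patience), threshold = threshold,
       factor = factor, threshold_mode = threshold_mode, min_lr = min_lr,
       best = Inf, wait = 0L, reduced = FALSE)
}

#' @rdname plateau_reducer
#' @param state a plateau state.
#' @param value the monitored loss of the current epoch.
#' @export
plateau_update <- function(state, value) {
  improved <- if (state$threshold_mode == "rel") {
    value < state$best * (1 - state$threshold)
  } else {
    value < state$best - state$threshold
  }
  state$reduced <- FALSE
  if (improved || !is.finite(state$best)) {
    state$best <- value
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$min_lr, state$lr * state$factor)
      state$wait <- 0L
      state$reduced <- TRUE
    }
  }
  state
}

# --- triplet sampling -------------------------------------------------------

#' Sample triplet index batches
#'
#' Default policy: anchors are drawn uniformly with replacement; the
#' positive is a different image of the anchor's class; the negative class
#' is drawn uniformly among the other classes, then the negative image
#' uniformly within it. Reproducible under a fixed seed.
#'
#' @param labels class label per training image.
#' @param n_triplets number of triplets to sample.
#' @param batch_size triplets per batch; the last batch may be smaller.
#' @param seed integer seed.
#' @return a list of integer matrices with columns `a`, `p`, `n`.
#' @export
sample_triplets <- function(labels, n_triplets, batch_size, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 2L) {
    stop_taxembed("triplet sampling needs >= 2 classes",
                  class = "taxembed_sampling_error")
  }
  by_class <- split(seq_len(n), labels)
  sizes <- lengths(by_class)
  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons) > 0L) {
    stop_taxembed("class(es) with a single image cannot supply same-class ",
                  "positives: ", paste(singletons, collapse = ", "),
                  class = "taxembed_sampling_error")
  }
  with_seed(seed, {
    a <- sample.int(n, n_triplets, replace = TRUE)
    a_class <- labels[a]
    # positive: uniform over the anchor class excluding the anchor itself
    p <- vapply(seq_len(n_triplets), function(i) {
      pool <- by_class[[a_class[i]]]
      pool <- pool[pool != a[i]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    # negative: class uniform among the others, image uniform within
    n_class_idx <- vapply(seq_len(n_triplets), function(i) {
      others <- which(classes != a_class[i])
      others[sample.int(length(others), 1L)]
    }, integer(1))
    neg <- vapply(seq_len(n_triplets), function(i) {
      pool <- by_class[[classes[n_class_idx[i]]]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    idx <- cbind(a = a, p = p, n = neg)
    starts <- seq(1L, n_triplets, by = batch_size)
    lapply(starts, function(s) {
      idx[s:min(s + batch_size - 1L, n_triplets), , drop = FALSE]
    })
  })
}

# --- training loops ---------------------------------------------------------

# slice a (H, W, N) or (H, W, C, N) image stack by sample index
slice_images <- function(images, idx) {
  d <- dim(images)
  if (length(d) == 3L) images[, , idx, drop = FALSE]
  else images[, , , idx, drop = FALSE]
}

n_images <- function(images) {
  d <- dim(images)
  if (length(d) == 3L) d[3] else d[4]
}

#' Train a Siamese encoder with a triplet-style loss
#'
#' Runs at most `config$epochs` epochs of Adam on triplet batches, applies
#' the reduce-on-plateau schedule to the training loss, and returns the
#' checkpoint with the smallest training loss. For the `"htl"` loss the
#' class hierarchy is rebuilt from current embeddings every
#' `config$htl_rebuild_every` epochs; for the `"taxonomic"` loss a
#' taxonomic distance matrix is required up front.
#'
#' @param encoder an [encoder_create()] object.
#' @param dataset an `image_dataset` (or any list with `images` and
#'   `labels`).
#' @param split a [split_k_shot()] partition; only the training indices are
#'   used.
#' @param config a [training_config()].
#' @param taxdist taxonomic distance matrix; required iff
#'   `config$loss == "taxonomic"`.
#' @param verbose print a per-epoch progress line to stderr.
#' @return an object of class `taxembed_fit`: the best-checkpoint `encoder`,
#'   the per-epoch `log` (loss, learning rate, HTL rebuild flags),
#'   `best_epoch` and `best_loss`.
#' @export
train_encoder <- function(encoder, dataset, split, config, taxdist = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(encoder, "encoder"), inherits(config, "training_config"))
  if (config$loss == "generic") {
    stop_taxembed("use train_generic() for the cross-entropy baseline",
                  class = "taxembed_config_error")
  }
  if (config$loss == "taxonomic" && is.null(taxdist)) {
    stop_taxembed("the taxonomic loss requires a taxonomic distance matrix",
                  class = "taxembed_config_error")
  }
  train_idx <- split$train
  labels <- as.character(dataset$labels)[train_idx]
  if (config$loss == "taxonomic") {
    absent <- setdiff(unique(labels), rownames(taxdist))
    if (length(absent) > 0L) {
      stop_taxembed("class(es) absent from the taxonomy: ",
                    paste(absent, collapse = ", "),
                    class = "taxembed_validation_error")
    }
  }
  images <- slice_images(dataset$images, train_idx)
  n_train <- length(labels)
  n_trip <- config$triplets_per_epoch %||% n_train

  layers <- encoder$layers
  opt <- adam_init(layers)
  sched <- plateau_reducer(config$lr, config$patience, config$threshold,
                           config$factor, config$threshold_mode,
                           config$min_lr)
  best_loss <- Inf
  best_layers <- layers
  best_epoch <- NA_integer_
  state <- NULL
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    rebuild <- FALSE
    if (config$loss == "htl") {
      needs_init <- is.null(state)
      scheduled <- epoch %% config$htl_rebuild_every == 0L
      if (needs_init || scheduled) {
        enc_now <- encoder; enc_now$layers <- layers
        emb_all <- encoder_embed(enc_now, images)
        state <- htl_rebuild_hierarchy(emb_all, labels,
                                       max_levels = config$htl_max_levels,
                                       beta = config$htl_beta, epoch = epoch)
        rebuild <- scheduled   # the epoch-1 build is initialization
      }
    }
    batches <- sample_triplets(labels, n_trip, config$batch_size,
                               derive_seed(config$seed, "sampler", epoch))
    tot_loss <- 0
    for (b in batches) {
      nb <- nrow(b)
      x <- stack_triplet_images(images, b)
      fwd <- nn_forward(layers, x)
      emb <- fwd$out
      xa <- emb[seq_len(nb), , drop = FALSE]
      xp <- emb[nb + seq_len(nb), , drop = FALSE]
      xn <- emb[2L * nb + seq_len(nb), , drop = FALSE]
      m <- switch(config$loss,
        triplet = rep(config$margin, nb),
        taxonomic = taxonomic_margin(labels[b[, "a"]], labels[b[, "p"]],
                                     labels[b[, "n"]], taxdist,
                                     orientation = config$margin_mode,
                                     scope = config$norm_scope,
                                     eps = config$eps),
        htl = htl_margin(state, labels[b[, "a"]], labels[b[, "n"]])
      )
      d_ap <- pairwise_distance(xa, xp)
      d_an <- pairwise_distance(xa, xn)
      lvec <- hinge(d_ap, d_an, m)
      tot_loss <- tot_loss + sum(lvec)
      active <- as.numeric(lvec > 0) / nb
      u_ap <- (xa - xp) / pmax(d_ap, 1e-12)
      u_an <- (xa - xn) / pmax(d_an, 1e-12)
      demb <- rbind((u_ap - u_an) * active,
                    -u_ap * active,
                    u_an * active)
      grads <- nn_backward(layers, fwd$caches, demb)
      upd <- adam_step(layers, grads, opt, sched$lr)
      layers <- upd$layers; opt <- upd$state
    }
    epoch_loss <- tot_loss / n_trip
    lr_now <- sched$lr
    sched <- plateau_update(sched, epoch_loss)
    improved <- epoch_loss < best_loss
    if (improved) {
      best_loss <- epoch_loss
      best_layers <- layers
      best_epoch <- epoch
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = epoch_loss, lr = lr_now,
                               rebuild = rebuild, improved = improved)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  lr %.2e%s", epoch, epoch_loss,
                      lr_now, if (rebuild) "  [hierarchy rebuilt]" else ""))
    }
  }
  best <- encoder; best$layers <- best_layers
  structure(
    list(encoder = best, log = do.call(rbind, log),
         best_epoch = best_epoch, best_loss = best_loss,
         config = config, classes = sort(unique(labels), method = "radix"),
         head = NULL),
    class = "taxembed_fit"
  )
}

stack_triplet_images <- function(images, b) {
  idx <- c(b[, "a"], b[, "p"], b[, "n"])
  x <- slice_images(images, idx)
  d <- dim(x)
  if (length(d) == 3L) array(x, c(d, 1L)) else aperm(x, c(1, 2, 4, 3))
}

#' Train the cross-entropy baseline classifier
#'
#' The non-Siamese control condition: the same encoder topped with a dense
#' softmax head, trained with standard cross-entropy on the k-shot training
#' set under the identical optimization schedule.
#'
#' @inheritParams train_encoder
#' @return a `taxembed_fit` whose `head` holds the softmax layer; predict
#'   with [predict_generic()].
#' @export
train_generic <- function(encoder, dataset, split, config, verbose = FALSE) {
  stopifnot(inherits(encoder, "encoder"), inherits(config, "training_config"))
  train_idx <- split$train
  labels <- as.character(dataset$labels)[train_idx]
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 2L) {
    stop_taxembed("the baseline classifier needs >= 2 classes",
                  class = "taxembed_config_error")
  }
  images <- slice_images(dataset$images, train_idx)
  y <- match(labels, classes)
  n_train <- length(y)
  n_cls <- length(classes)

  layers <- c(encoder$layers,
              list(with_seed(derive_seed(config$seed, "head"),
                             nn_dense_init(encoder$embedding_dim, n_cls))))
  opt <- adam_init(layers)
  sched <- plateau_reducer(config$lr, config$patience, config$threshold,
                           config$factor, config$threshold_mode,
                           config$min_lr)
  best_loss <- Inf; best_layers <- layers; best_epoch <- NA_integer_
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "shuffle", epoch),
                     sample.int(n_train))
    starts <- seq(1L, n_train, by = config$batch_size)
    tot_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n_train)]
      nb <- length(idx)
      x <- slice_images(images, idx)
      d <- dim(x)
      x <- if (length(d) == 3L) array(x, c(d, 1L)) else aperm(x, c(1, 2, 4, 3))
      fwd <- nn_forward(layers, x)
      logits <- fwd$out
      logits <- logits - apply(logits, 1, max)
      p <- exp(logits) / rowSums(exp(logits))
      truth <- y[idx]
      tot_loss <- tot_loss - sum(log(pmax(p[cbind(seq_len(nb), truth)],
                                          1e-12)))
      dlogits <- p
      dlogits[cbind(seq_len(nb), truth)] <-
        dlogits[cbind(seq_len(nb), truth)] - 1
      dlogits <- dlogits / nb
      grads <- nn_backward(layers, fwd$caches, dlogits)
      upd <- adam_step(layers, grads, opt, sched$lr)
      layers <- upd$layers; opt <- upd$state
    }
    epoch_loss <- tot_loss / n_train
    lr_now <- sched$lr
    sched <- plateau_update(sched, epoch_loss)
    improved <- epoch_loss < best_loss
    if (improved) {
      best_loss <- epoch_loss; best_layers <- layers; best_epoch <- epoch
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = epoch_loss, lr = lr_now,
                               rebuild = FALSE, improved = improved)
    if (verbose) {
      message(sprintf("epoch %3d  CE loss %.5f  lr %.2e", epoch, epoch_loss,
                      lr_now))
    }
  }
  n_enc <- length(encoder$layers)
  best <- encoder; best$layers <- best_layers[seq_len(n_enc)]
  structure(
    list(encoder = best, log = do.call(rbind, log),
         best_epoch = best_epoch, best_loss = best_loss,
         config = config, classes = classes,
         head = best_layers[[n_enc + 1L]]),
    class = "taxembed_fit"
  )
}

#' Predict classes with a trained baseline classifier
#'
#' @param fit a `taxembed_fit` from [train_generic()].
#' @param images image array as in [encoder_embed()].
#' @return a character vector of predicted class labels.
#' @export
predict_generic <- function(fit, images) {
  stopifnot(inherits(fit, "taxembed_fit"))
  if (is.null(fit$head)) {
    stop_taxembed("fit has no softmax head; it was not trained with ",
                  "train_generic()", class = "taxembed_config_error")
  }
  emb <- encoder_embed(fit$encoder, images)
  logits <- nn_dense_forward(fit$head, emb)$out
  fit$classes[max.col(logits, ties.method = "first")]
}

#' @export
print.taxembed_fit <- function(x, ...) {
  cat(sprintf("<taxembed_fit: %s loss, best epoch %d (loss %.5f), %d classes>\n",
              x$config$loss, x$best_epoch, x$best_loss, length(x$classes)))
  invisible(x)
}
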