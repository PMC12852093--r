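# Replicate-level experiment driver: split -> train -> evaluate, repeated
# over seeds and loss conditions on the same data, as in a standard
# simulation study (N replicates, identical splits across conditions within
# a replicate).

#' Run one training/evaluation replicate
#'
#' Splits the dataset k-shot under the replicate seed, trains the requested
#' condition, and evaluates it. Within a replicate, every condition sees the
#' identical split (the split seed depends only on the replicate seed).
#'
#' @param dataset an [image_dataset()] with pixel data.
#' @param config a [training_config()]; `config$seed` is the replicate
#'   seed.
#' @param k training images per class.
#' @param taxdist taxonomic distance matrix (required for the taxonomic
#'   loss; enables the tree-correlation metric otherwise).
#' @param encoder optional pre-built [encoder_create()]; by default a
#'   `tiny_cnn` matching the dataset is created with a seed derived from
#'   the replicate seed.
#' @param verbose print per-epoch progress.
#' @return a list with `fit`, `split` and `report`.
#' @export
run_replicate <- function(dataset, config, k, taxdist = NULL,
                          encoder = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "image_dataset"),
            inherits(config, "training_config"))
  split <- split_k_shot(dataset, k, derive_seed(config$seed, "split"))
  if (is.null(encoder)) {
    encoder <- encoder_create("tiny_cnn", input_size = dataset$size,
                              channels = dataset$channels,
                              embedding_dim = config$embedding_dim,
                              seed = derive_seed(config$seed, "init"))
  }
  fit <- if (config$loss == "generic") {
    train_generic(encoder, dataset, split, config, verbose = verbose)
  } else {
    train_encoder(encoder, dataset, split, config, taxdist = taxdist,
                  verbose = verbose)
  }
  report <- evaluate_fit(fit, dataset, split, taxdist = taxdist,
                         tsne_seed = derive_seed(config$seed, "tsne"))
  list(fit = fit, split = split, report = report)
}

#' Run a replicated multi-condition experiment
#'
#' Runs every loss condition over every replicate seed on the same dataset
#' and collects the per-replicate metrics into a long data frame, ready for
#' [compare_conditions()].
#'
#' @param dataset an [image_dataset()].
#' @param losses character vector of conditions, subset of
#'   `c("triplet", "taxonomic", "htl", "generic")`.
#' @param seeds integer vector of replicate seeds (the convention is 10
#'   replicates).
#' @param k training images per class.
#' @param taxdist taxonomic distance matrix.
#' @param config_fn function `(loss, seed) -> training_config`; defaults to
#'   [training_config()] with the given loss and seed.
#' @param verbose print progress lines.
#' @return a data frame with one row per (loss, seed): macro
#'   precision/recall/F1, accuracy, Silhouette, tree correlation.
#' @export
run_experiment <- function(dataset, losses, seeds, k, taxdist = NULL,
                           config_fn = NULL, verbose = FALSE) {
  config_fn <- config_fn %||%
    function(loss, seed) training_config(loss = loss, seed = seed)
  rows <- list()
  for (loss in losses) {
    for (seed in seeds) {
      if (verbose) message("condition ", loss, ", seed ", seed)
      res <- run_replicate(dataset, config_fn(loss, seed), k,
                           taxdist = taxdist, verbose = FALSE)
      rep <- res$report
      rows[[length(rows) + 1L]] <- data.frame(
        loss = loss, seed = seed,
        precision = rep$macro_precision, recall = rep$macro_recall,
        f1 = rep$macro_f1, accuracy = rep$accuracy,
        silhouette = rep$silhouette,
        tree_correlation = rep$tree_correlation %||% NA_real_
      )
    }
  }
  do.call(rbind, rows)
}
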