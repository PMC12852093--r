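# Nearest-embedding classification and the per-replicate metric battery:
# per-class and macro precision/recall/F1, Silhouette of the t-SNE-projected
# training embeddings, and exact rank-sum comparisons across conditions.

#' Classify by nearest training embedding
#'
#' Each test vector receives the label of its Euclidean-nearest training
#' vector. Exact ties are broken toward the lowest training index.
#'
#' @param test_emb numeric matrix (n_test x d).
#' @param train_emb numeric matrix (n_train x d).
#' @param train_labels class label per training row.
#' @return character vector of predicted labels.
#' @export
nearest_embedding_classify <- function(test_emb, train_emb, train_labels) {
  test_emb <- as.matrix(test_emb); train_emb <- as.matrix(train_emb)
  if (ncol(test_emb) != ncol(train_emb)) {
    stop_taxembed("embedding dimensions differ: ", ncol(test_emb), " vs ",
                  ncol(train_emb), class = "taxembed_shape_error")
  }
  if (nrow(train_emb) == 0L) {
    stop_taxembed("training set is empty", class = "taxembed_validation_error")
  }
  stopifnot(length(train_labels) == nrow(train_emb))
  # squared distances via the expansion ||t - r||^2 = ||t||^2 + ||r||^2 - 2 t.r
  d2 <- outer(rowSums(test_emb^2), rowSums(train_emb^2), "+") -
    2 * tcrossprod(test_emb, train_emb)
  as.character(train_labels)[max.col(-d2, ties.method = "first")]
}

#' Per-class and macro precision, recall and F1
#'
#' Computes the confusion matrix (rows = truth, columns = prediction),
#' per-class precision/recall/F1 and their macro averages. Undefined
#' per-class values (zero denominators) are set to 0 and flagged.
#'
#' @param predictions,truths equal-length label vectors.
#' @param classes label universe; defaults to the union of both vectors.
#' @return an object of class `evaluation_report`: `per_class` data frame
#'   (with `zero_division` flags), `macro_precision`, `macro_recall`,
#'   `macro_f1`, `accuracy` and the `confusion` matrix.
#' @export
compute_metrics <- function(predictions, truths, classes = NULL) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths) || length(truths) == 0L) {
    stop_taxembed("predictions and truths must be non-empty and equal ",
                  "length", class = "taxembed_validation_error")
  }
  classes <- classes %||% sort(unique(c(predictions, truths)),
                               method = "radix")
  cm <- table(factor(truths, classes), factor(predictions, classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(truth = classes, prediction = classes))
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  prec_flag <- pred_tot == 0
  rec_flag <- true_tot == 0
  precision <- ifelse(prec_flag, 0, tp / pmax(pred_tot, 1))
  recall <- ifelse(rec_flag, 0, tp / pmax(true_tot, 1))
  f1_flag <- precision + recall == 0
  f1 <- ifelse(f1_flag, 0, 2 * precision * recall / (precision + recall))
  per_class <- data.frame(
    class = classes, precision = precision, recall = recall, f1 = f1,
    support = as.integer(true_tot),
    zero_division = prec_flag | rec_flag | f1_flag,
    row.names = NULL
  )
  structure(
    list(per_class = per_class,
         macro_precision = mean(precision), macro_recall = mean(recall),
         macro_f1 = mean(f1), accuracy = sum(tp) / sum(cm),
         confusion = cm),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report: macro P %.3f / R %.3f / ",
                     "F1 %.3f, accuracy %.3f, %d classes>\n"),
              x$macro_precision, x$macro_recall, x$macro_f1, x$accuracy,
              nrow(x$per_class)))
  invisible(x)
}

#' Mean Silhouette score of labelled points
#'
#' Textbook Silhouette with Euclidean distance: per point,
#' `(b - a) / max(a, b)` where `a` is the mean intra-cluster distance and
#' `b` the mean distance to the nearest other cluster; averaged over all
#' points.
#'
#' @param x numeric matrix of coordinates.
#' @param labels cluster/class label per row (>= 2 distinct values).
#' @return the mean Silhouette width, in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop_taxembed("Silhouette is undefined for a single class",
                  class = "taxembed_validation_error")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist(as.matrix(x)))
  mean(sil[, "sil_width"])
}

#' Silhouette score of t-SNE-projected embeddings
#'
#' Projects the embeddings to 2-D with t-SNE (2 components, perplexity 2, a
#' fixed random seed) and scores the class labels on the projected
#' coordinates — the convention used for reporting cluster quality of the
#' training set. The projection is attached as attribute `"projection"`.
#'
#' @param embeddings numeric matrix (n x d), at least 3 points and 2
#'   classes. t-SNE additionally requires `n >= 3 * perplexity + 2`.
#' @param labels class label per row.
#' @param perplexity t-SNE perplexity (default 2).
#' @param components projection dimension (default 2).
#' @param seed integer seed for the t-SNE initialization.
#' @param max_iter t-SNE iterations.
#' @return the mean Silhouette width of the projected points.
#' @export
tsne_silhouette <- function(embeddings, labels, perplexity = 2,
                            components = 2L, seed = 1L, max_iter = 1000L) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  if (nrow(embeddings) < 3L) {
    stop_taxembed("need at least 3 points", class = "taxembed_validation_error")
  }
  if (length(unique(labels)) < 2L) {
    stop_taxembed("Silhouette is undefined for a single class",
                  class = "taxembed_validation_error")
  }
  proj <- with_seed(seed, Rtsne::Rtsne(
    embeddings, dims = components, perplexity = perplexity,
    theta = 0, pca = FALSE, check_duplicates = FALSE,
    max_iter = max_iter
  )$Y)
  score <- silhouette_score(proj, labels)
  attr(score, "projection") <- proj
  score
}

#' Spearman agreement between embedding geometry and the taxonomy
#'
#' Correlates the pairwise Euclidean distances between class centroid
#' embeddings with the corresponding taxonomic tree distances. Values near
#' 1 mean the embedding space mirrors the taxonomy.
#'
#' @param embeddings numeric matrix (n x d).
#' @param labels class label per row; every label must be a leaf of the
#'   taxonomy.
#' @param taxdist distance matrix from [build_distance_matrix()].
#' @return Spearman rank correlation over all class pairs.
#' @export
centroid_tree_correlation <- function(embeddings, labels, taxdist) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 3L) {
    stop_taxembed("need >= 3 classes for a rank correlation",
                  class = "taxembed_validation_error")
  }
  missing <- setdiff(classes, rownames(taxdist))
  if (length(missing) > 0L) {
    stop_taxembed("class(es) absent from the taxonomy: ",
                  paste(missing, collapse = ", "),
                  class = "taxembed_lookup_error")
  }
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(embeddings[labels == cl, , drop = FALSE])
  }))
  emb_d <- as.matrix(dist(centroids))
  tax_d <- taxdist[classes, classes]
  ut <- upper.tri(emb_d)
  stats::cor(emb_d[ut], tax_d[ut], method = "spearman")
}

#' Compare replicate metric vectors across conditions
#'
#' Reports mean and SD per condition and exact two-sided Wilcoxon rank-sum
#' p-values for every condition pair, Bonferroni-corrected (multiplied by
#' the number of pairs, capped at 1).
#'
#' @param values named list of numeric vectors, one per condition, each with
#'   at least 2 replicate values.
#' @return an object of class `replicate_summary`: a `conditions` data frame
#'   (n, mean, sd) and a `comparisons` data frame (pairwise p-values, raw
#'   and corrected). Unequal replicate counts are flagged in the output.
#' @export
compare_conditions <- function(values) {
  if (!is.list(values) || length(values) < 2L || is.null(names(values))) {
    stop_taxembed("values must be a named list with >= 2 conditions",
                  class = "taxembed_validation_error")
  }
  if (any(vapply(values, length, integer(1)) < 2L)) {
    stop_taxembed("every condition needs >= 2 replicate values",
                  class = "taxembed_validation_error")
  }
  conds <- names(values)
  summary_df <- data.frame(
    condition = conds,
    n = vapply(values, length, integer(1)),
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, stats::sd, numeric(1)),
    row.names = NULL
  )
  pairs <- utils::combn(conds, 2L)
  p_raw <- apply(pairs, 2L, function(pr) {
    suppressWarnings(stats::wilcox.test(values[[pr[1]]], values[[pr[2]]],
                                        exact = TRUE)$p.value)
  })
  comparisons <- data.frame(
    condition_a = pairs[1, ], condition_b = pairs[2, ],
    p_value = p_raw,
    p_adjusted = stats::p.adjust(p_raw, method = "bonferroni"),
    unequal_n = vapply(seq_len(ncol(pairs)), function(i) {
      length(values[[pairs[1, i]]]) != length(values[[pairs[2, i]]])
    }, logical(1)),
    row.names = NULL
  )
  structure(list(conditions = summary_df, comparisons = comparisons),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("Replicate summary (mean ± SD):\n")
  for (i in seq_len(nrow(x$conditions))) {
    r <- x$conditions[i, ]
    cat(sprintf("  %-12s %.4f ± %.4f (n = %d)\n", r$condition, r$mean,
                r$sd, r$n))
  }
  cat("Pairwise exact rank-sum tests (Bonferroni-corrected):\n")
  for (i in seq_len(nrow(x$comparisons))) {
    r <- x$comparisons[i, ]
    cat(sprintf("  %s vs %s: p = %.4g%s\n", r$condition_a, r$condition_b,
                r$p_adjusted, if (r$unequal_n) " [unequal n]" else ""))
  }
  invisible(x)
}

#' Evaluate a trained model on a split
#'
#' Embeds training and test images with the fitted encoder, classifies the
#' test set by nearest training embedding (or softmax head for the generic
#' baseline), and assembles the metric bundle: macro precision/recall/F1,
#' confusion matrix, and the Silhouette of the t-SNE-projected training
#' embeddings.
#'
#' @param fit a `taxembed_fit`.
#' @param dataset the dataset the split indexes into.
#' @param split a `split_spec`.
#' @param taxdist optional taxonomic distance matrix; when supplied, the
#'   centroid/taxonomy Spearman correlation is included.
#' @param tsne_seed seed of the t-SNE projection.
#' @return an `evaluation_report` with `silhouette` (and optionally
#'   `tree_correlation`) fields added.
#' @export
evaluate_fit <- function(fit, dataset, split, taxdist = NULL, tsne_seed = 1L) {
  stopifnot(inherits(fit, "taxembed_fit"), inherits(split, "split_spec"))
  train_images <- slice_images(dataset$images, split$train)
  test_images <- slice_images(dataset$images, split$test)
  train_labels <- dataset$labels[split$train]
  test_labels <- dataset$labels[split$test]
  train_emb <- encoder_embed(fit$encoder, train_images)
  if (is.null(fit$head)) {
    test_emb <- encoder_embed(fit$encoder, test_images)
    pred <- nearest_embedding_classify(test_emb, train_emb, train_labels)
  } else {
    pred <- predict_generic(fit, test_images)
  }
  report <- compute_metrics(pred, test_labels,
                            classes = sort(unique(dataset$labels),
                                           method = "radix"))
  report$silhouette <- if (is.null(fit$head)) {
    as.numeric(tsne_silhouette(train_emb, train_labels, seed = tsne_seed))
  } else NA_real_
  if (!is.null(taxdist) && is.null(fit$head)) {
    report$tree_correlation <-
      centroid_tree_correlation(train_emb, train_labels, taxdist)
  }
  report$seed <- fit$config$seed
  report
}
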