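# Triplet-style losses: standard triplet, taxonomic triplet with a dynamic
# min-max normalized margin derived from tree distances, and hierarchical
# triplet loss (HTL) with a periodically rebuilt class hierarchy.
#
# All losses return the per-triplet hinge vector; reduction to the batch
# mean is a separate, explicit step (see reduce_loss) so tests and training
# can inspect individual triplets.

#' Construct a triplet batch
#'
#' Bundles anchor/positive/negative embedding blocks with their class
#' labels. All three blocks must share the same batch size and embedding
#' dimension.
#'
#' @param x_a,x_p,x_n numeric matrices (n x d): anchor, positive, negative
#'   embeddings.
#' @param labels_a,labels_p,labels_n character vectors of class codes, one
#'   per triplet.
#' @return an object of class `triplet_batch`.
#' @export
triplet_batch <- function(x_a, x_p, x_n, labels_a, labels_p, labels_n) {
  x_a <- as.matrix(x_a); x_p <- as.matrix(x_p); x_n <- as.matrix(x_n)
  if (!all(dim(x_a) == dim(x_p)) || !all(dim(x_a) == dim(x_n))) {
    stop_taxembed("anchor/positive/negative embeddings must share one shape",
                  class = "taxembed_shape_error")
  }
  n <- nrow(x_a)
  if (length(labels_a) != n || length(labels_p) != n || length(labels_n) != n) {
    stop_taxembed("label vectors must have one entry per triplet",
                  class = "taxembed_shape_error")
  }
  structure(
    list(x_a = x_a, x_p = x_p, x_n = x_n,
         labels_a = as.character(labels_a),
         labels_p = as.character(labels_p),
         labels_n = as.character(labels_n)),
    class = "triplet_batch"
  )
}

#' @export
print.triplet_batch <- function(x, ...) {
  cat(sprintf("<triplet_batch: %d triplets, d = %d>\n",
              nrow(x$x_a), ncol(x$x_a)))
  invisible(x)
}

#' Row-wise Euclidean distance between two embedding blocks
#'
#' @param u,v numeric matrices of identical shape (n x d); vectors are
#'   treated as single rows.
#' @return a length-n vector of Euclidean distances.
#' @examples
#' pairwise_distance(c(0, 0), c(3, 4))  # 5
#' @export
pairwise_distance <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (!all(dim(u) == dim(v))) {
    stop_taxembed("embedding blocks must share one shape: ",
                  paste(dim(u), collapse = "x"), " vs ",
                  paste(dim(v), collapse = "x"),
                  class = "taxembed_shape_error")
  }
  sqrt(rowSums((u - v)^2))
}

#' Standard triplet loss (fixed margin)
#'
#' Per-triplet hinge `max(0, dist(x_a, x_p) - dist(x_a, x_n) + m)`: the
#' anchor-negative distance must exceed the anchor-positive distance by at
#' least the margin `m` before a triplet stops contributing loss.
#'
#' @param batch a [triplet_batch()].
#' @param margin non-negative fixed margin `m`.
#' @return per-triplet loss vector (>= 0). Reduce with [reduce_loss()].
#' @export
triplet_loss <- function(batch, margin) {
  stopifnot(inherits(batch, "triplet_batch"))
  if (!is.numeric(margin) || length(margin) != 1L || margin < 0) {
    stop_taxembed("margin must be a single non-negative number",
                  class = "taxembed_validation_error")
  }
  hinge(pairwise_distance(batch$x_a, batch$x_p),
        pairwise_distance(batch$x_a, batch$x_n),
        rep(margin, nrow(batch$x_a)))
}

hinge <- function(d_ap, d_an, m) pmax(0, d_ap - d_an + m)

#' Batch reduction of a per-triplet loss vector
#'
#' @param losses per-triplet loss vector.
#' @return the unweighted batch mean.
#' @export
reduce_loss <- function(losses) mean(losses)

#' Min-max normalization with a division guard
#'
#' `(z - min(z)) / (max(z) - min(z) + eps)`. The additive `eps` keeps the
#' denominator positive when all entries are equal, in which case the result
#' is exactly zero everywhere.
#'
#' @param z non-empty numeric vector.
#' @param eps small positive constant (default `1e-6`).
#' @return a vector in `[0, 1)`.
#' @examples
#' minmax_normalize(c(0, 1, 2))  # 0, ~0.5, ~1
#' @export
minmax_normalize <- function(z, eps = 1e-6) {
  if (length(z) == 0L) {
    stop_taxembed("cannot normalize an empty vector",
                  class = "taxembed_validation_error")
  }
  (z - min(z)) / (max(z) - min(z) + eps)
}

#' Dynamic taxonomic margin
#'
#' For each triplet, looks up the taxonomic distances `T_p` (anchor to
#' positive class) and `T_n` (anchor to negative class) in the tree distance
#' matrix and min-max normalizes their difference across the batch, yielding
#' a per-triplet margin in `[0, 1]`.
#'
#' Two orientations are available. `"monotone"` (the default) normalizes
#' `T_n - T_p`, so taxonomically distant negatives receive larger margins
#' and are pushed further away — the geometry the dynamic margin is meant to
#' produce. `"literal"` normalizes `T_p - T_n`, the printed form of the
#' margin definition, kept for fidelity experiments.
#'
#' @param labels_a,labels_p,labels_n class labels per triplet.
#' @param taxdist distance matrix from [build_distance_matrix()].
#' @param orientation `"monotone"` or `"literal"` (see Details).
#' @param scope `"batch"` normalizes over the current batch's difference
#'   vector; `"matrix"` normalizes against the extreme attainable difference
#'   range `[-max(D), max(D)]` so margins are comparable across batches.
#' @param eps division guard for the normalization.
#' @return a numeric margin vector, every entry in `[0, 1]`.
#' @export
taxonomic_margin <- function(labels_a, labels_p, labels_n, taxdist,
                             orientation = c("monotone", "literal"),
                             scope = c("batch", "matrix"),
                             eps = 1e-6) {
  orientation <- match.arg(orientation)
  scope <- match.arg(scope)
  labs <- rownames(taxdist)
  missing <- setdiff(unique(c(labels_a, labels_p, labels_n)), labs)
  if (length(missing) > 0L) {
    stop_taxembed("labels absent from the taxonomy: ",
                  paste(missing, collapse = ", "),
                  "; known labels: ", paste(labs, collapse = ", "),
                  class = "taxembed_lookup_error")
  }
  t_p <- taxdist[cbind(labels_a, labels_p)]
  t_n <- taxdist[cbind(labels_a, labels_n)]
  z <- if (orientation == "monotone") t_n - t_p else t_p - t_n
  if (scope == "batch") {
    minmax_normalize(z, eps)
  } else {
    hi <- max(taxdist)
    (z + hi) / (2 * hi + eps)
  }
}

#' Taxonomic triplet loss with dynamic margin
#'
#' The triplet hinge in which the fixed margin is replaced per triplet by
#' the normalized taxonomic-distance difference from [taxonomic_margin()].
#' With a taxonomy in hand, triplets whose negative belongs to a distant
#' clade must be separated by a larger margin than triplets whose negative
#' is a congener, so the embedding space inherits the tree topology.
#'
#' @inheritParams triplet_loss
#' @inheritParams taxonomic_margin
#' @return per-triplet loss vector with the margin vector attached as
#'   attribute `"margins"`.
#' @export
taxonomic_loss <- function(batch, taxdist,
                           orientation = c("monotone", "literal"),
                           scope = c("batch", "matrix"),
                           eps = 1e-6) {
  stopifnot(inherits(batch, "triplet_batch"))
  m_t <- taxonomic_margin(batch$labels_a, batch$labels_p, batch$labels_n,
                          taxdist, orientation = orientation,
                          scope = scope, eps = eps)
  out <- hinge(pairwise_distance(batch$x_a, batch$x_p),
               pairwise_distance(batch$x_a, batch$x_n),
               m_t)
  attr(out, "margins") <- m_t
  out
}

# ---------------------------------------------------------------------------
# Hierarchical triplet loss (HTL): the margin is beta + d_H(T_a, T_n) - S_a,
# where d_H is the (discretized) hierarchy level at which the anchor and
# negative classes merge and S_a the mean intra-class embedding distance of
# the anchor class. The hierarchy is learned from the embeddings themselves
# and rebuilt periodically during training.
# ---------------------------------------------------------------------------

#' Construct an HTL state directly
#'
#' Low-level constructor, mainly for tests and resuming; during training the
#' state is produced by [htl_rebuild_hierarchy()].
#'
#' @param classes class labels.
#' @param d_H symmetric class-by-class matrix of hierarchy merge distances.
#' @param S named vector of mean intra-class embedding distances.
#' @param beta constant margin offset (default 0.1).
#' @param max_levels hierarchy depth cap.
#' @param n_levels number of distinct merge levels actually present.
#' @param epoch epoch at which the state was (re)built.
#' @return an object of class `htl_state`.
#' @export
htl_state <- function(classes, d_H, S, beta = 0.1, max_levels = 16L,
                      n_levels = NA_integer_, epoch = NA_integer_) {
  stopifnot(length(classes) >= 1L, all(S >= 0))
  structure(
    list(classes = classes, d_H = d_H, S = S, beta = beta,
         max_levels = as.integer(max_levels),
         n_levels = as.integer(n_levels), epoch = epoch),
    class = "htl_state"
  )
}

#' Rebuild the HTL class hierarchy from current embeddings
#'
#' Class centroids are computed from the supplied embeddings, agglomerated
#' with average linkage, and the merge heights are discretized upward onto at
#' most `max_levels` equally spaced levels. `d_H` between two classes is the
#' discretized height at which their clusters merge; `S_a` is the mean
#' pairwise Euclidean distance among the anchor class's embeddings.
#'
#' @param embeddings numeric matrix (n x d) of current training embeddings.
#' @param labels class label per row.
#' @param max_levels maximum hierarchy depth (default 16).
#' @param beta constant margin offset (default 0.1).
#' @param epoch optional epoch stamp recorded in the state.
#' @return an `htl_state`.
#' @export
htl_rebuild_hierarchy <- function(embeddings, labels, max_levels = 16L,
                                  beta = 0.1, epoch = NA_integer_) {
  embeddings <- as.matrix(embeddings)
  stopifnot(nrow(embeddings) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels), method = "radix")
  S <- vapply(classes, function(cl) {
    e <- embeddings[labels == cl, , drop = FALSE]
    if (nrow(e) < 2L) 0 else mean(stats::dist(e))
  }, numeric(1))
  names(S) <- classes
  if (length(classes) == 1L) {
    d_H <- matrix(0, 1, 1, dimnames = list(classes, classes))
    return(htl_state(classes, d_H, S, beta, max_levels, 0L, epoch))
  }
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(embeddings[labels == cl, , drop = FALSE])
  }))
  hc <- stats::hclust(stats::dist(centroids), method = "average")
  merge_h <- as.matrix(stats::cophenetic(hc))
  dimnames(merge_h) <- list(classes, classes)
  h_max <- max(merge_h)
  if (h_max <= 0) {
    d_H <- merge_h * 0
    n_levels <- 0L
  } else {
    # quantize merge heights upward onto a grid of max_levels values so the
    # hierarchy never has more than max_levels distinct levels
    step <- h_max / max_levels
    d_H <- ceiling(merge_h / step) * step
    diag(d_H) <- 0
    n_levels <- length(unique(d_H[upper.tri(d_H)]))
  }
  htl_state(classes, d_H, S, beta, max_levels, n_levels, epoch)
}

#' HTL adaptive margin for one class pair
#'
#' `max(0, beta + d_H(T_a, T_n) - S_a)`: the margin grows with the hierarchy
#' level at which the anchor and negative classes merge and shrinks as the
#' anchor class becomes internally spread out.
#'
#' @param state an `htl_state` from [htl_rebuild_hierarchy()] or
#'   [htl_state()].
#' @param anchor_class,negative_class class labels.
#' @return a single non-negative margin.
#' @export
htl_margin <- function(state, anchor_class, negative_class) {
  if (!inherits(state, "htl_state")) {
    stop_taxembed("HTL hierarchy has not been built yet",
                  class = "taxembed_state_error")
  }
  missing <- setdiff(c(anchor_class, negative_class), state$classes)
  if (length(missing) > 0L) {
    stop_taxembed("class(es) absent from the HTL hierarchy: ",
                  paste(missing, collapse = ", "),
                  class = "taxembed_state_error")
  }
  pmax(0, state$beta + state$d_H[cbind(anchor_class, negative_class)] -
         state$S[anchor_class])
}

#' Hierarchical triplet loss for a batch
#'
#' @inheritParams triplet_loss
#' @param state an `htl_state`.
#' @return per-triplet loss vector with margins attached as attribute
#'   `"margins"`.
#' @export
htl_loss <- function(batch, state) {
  stopifnot(inherits(batch, "triplet_batch"))
  m <- htl_margin(state, batch$labels_a, batch$labels_n)
  out <- hinge(pairwise_distance(batch$x_a, batch$x_p),
               pairwise_distance(batch$x_a, batch$x_n),
               m)
  attr(out, "margins") <- m
  out
}
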