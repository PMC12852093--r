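# Synthetic tree-structured image datasets. A smooth random "blob field"
# prototype is evolved down the taxonomy: each child prototype adds an
# independent smooth perturbation scaled by sigma_b times the branch length,
# so expected prototype distance grows with tree path length. Leaf images
# add per-pixel noise and a small geometric jitter. The same tree object can
# then drive the taxonomic loss, closing the loop between the generative
# hierarchy and the training signal.

#' Specification of a synthetic hierarchical image dataset
#'
#' @param tree a `phylo` taxonomy whose leaves are the classes.
#' @param n_per_class images per class (>= 2).
#' @param size square image size in pixels (default 32).
#' @param sigma_b prototype drift per unit branch length (> 0); larger
#'   values separate clades more strongly.
#' @param sigma_w within-class per-pixel noise standard deviation (>= 0).
#' @param jitter geometric jitter amplitude: images are translated by up to
#'   `jitter` pixels and rotated by up to `5 * jitter` degrees. 0 disables.
#' @param grid resolution of the low-frequency field the prototypes are
#'   built from; smaller values give smoother, larger blobs but fewer
#'   degrees of freedom, so realized inter-class distances track the tree
#'   less reliably. The default of 12 keeps the fields smooth while the
#'   class distance structure mirrors the taxonomy in every seed.
#' @param seed integer seed; generation is bitwise reproducible.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(tree, n_per_class = 40L, size = 32L,
                           sigma_b = 1.0, sigma_w = 0.1, jitter = 1,
                           grid = 12L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!(sigma_b > 0) || sigma_w < 0 || n_per_class < 2L) {
    stop_taxembed("need sigma_b > 0, sigma_w >= 0, n_per_class >= 2",
                  class = "taxembed_validation_error")
  }
  tree <- validate_taxonomy(tree)
  structure(
    list(tree = tree, n_per_class = as.integer(n_per_class),
         size = as.integer(size), sigma_b = sigma_b, sigma_w = sigma_w,
         jitter = jitter, grid = as.integer(grid), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# low-frequency smooth field: coarse Gaussian grid bilinearly upsampled
smooth_field <- function(size, grid) {
  z <- matrix(stats::rnorm(grid * grid), grid, grid)
  bilinear_upsample(z, size)
}

bilinear_upsample <- function(z, size) {
  g <- nrow(z)
  # sample the coarse grid at evenly spaced fractional coordinates
  pos <- seq(1, g, length.out = size)
  i0 <- pmin(floor(pos), g - 1L); f <- pos - i0
  a <- z[i0, i0, drop = FALSE];      b <- z[i0 + 1, i0, drop = FALSE]
  cc <- z[i0, i0 + 1, drop = FALSE]; d <- z[i0 + 1, i0 + 1, drop = FALSE]
  fy <- matrix(f, size, size); fx <- t(fy)
  a * (1 - fy) * (1 - fx) + b * fy * (1 - fx) + cc * (1 - fy) * fx +
    d * fy * fx
}

# nearest-neighbour rotation + integer translation; out-of-frame pixels = 0
jitter_image <- function(img, dx, dy, theta) {
  s <- nrow(img)
  if (dx == 0 && dy == 0 && theta == 0) return(img)
  ctr <- (s + 1) / 2
  co <- cos(theta); si <- sin(theta)
  xs <- matrix(seq_len(s), s, s) - ctr
  ys <- t(xs)
  sx <- round(co * xs + si * ys + ctr - dx)
  sy <- round(-si * xs + co * ys + ctr - dy)
  ok <- sx >= 1 & sx <= s & sy >= 1 & sy <= s
  out <- matrix(0, s, s)
  out[ok] <- img[cbind(sx[ok], sy[ok])]
  out
}

#' Generate a synthetic hierarchical image dataset
#'
#' Evolves a root prototype down the taxonomy (perturbation scale
#' `sigma_b * branch length` per edge) and renders `n_per_class` images per
#' leaf: prototype + pixel noise + jitter, squashed into `[0, 1]` and
#' quantized to 8-bit so in-memory pixels equal what [write_dataset()]
#' stores on disk. Each image carries a synthetic BBCH stage cycling over
#' 10, 11, 12, 14.
#'
#' @param spec a [synthetic_spec()].
#' @return an [image_dataset()]; the generating tree is attached as
#'   attribute `"tree"`.
#' @examples
#' ds <- synth_generate(synthetic_spec(balanced_taxonomy(2), n_per_class = 3))
#' ds
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tree <- spec$tree
  with_seed(spec$seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    n_node <- n_tip + tree$Nnode
    protos <- vector("list", n_node)
    protos[[root]] <- smooth_field(spec$size, spec$grid)
    # parents precede children in a preorder edge walk
    ord <- order(tree$edge[, 1])
    pending <- tree$edge[ord, , drop = FALSE]
    lens <- tree$edge.length[ord]
    # iterate until every node has a prototype (handles arbitrary edge order)
    repeat {
      done <- TRUE
      for (e in seq_len(nrow(pending))) {
        par <- pending[e, 1]; child <- pending[e, 2]
        if (is.null(protos[[child]])) {
          if (is.null(protos[[par]])) { done <- FALSE; next }
          protos[[child]] <- protos[[par]] +
            spec$sigma_b * lens[e] * smooth_field(spec$size, spec$grid)
        }
      }
      if (done) break
    }
    labels <- character(0)
    bbch <- integer(0)
    imgs <- vector("list", n_tip * spec$n_per_class)
    stages <- c(10L, 11L, 12L, 14L)
    k <- 0L
    for (tip in seq_len(n_tip)) {
      proto <- protos[[tip]]
      for (j in seq_len(spec$n_per_class)) {
        raw <- proto
        if (spec$jitter > 0) {
          dx <- sample.int(2L * spec$jitter + 1L, 1L) - spec$jitter - 1L
          dy <- sample.int(2L * spec$jitter + 1L, 1L) - spec$jitter - 1L
          theta <- stats::runif(1, -5 * spec$jitter, 5 * spec$jitter) *
            pi / 180
          raw <- jitter_image(raw, dx, dy, theta)
        }
        if (spec$sigma_w > 0) {
          raw <- raw + spec$sigma_w *
            matrix(stats::rnorm(spec$size^2), spec$size, spec$size)
        }
        img <- pmin(pmax(0.5 + 0.15 * raw, 0), 1)
        k <- k + 1L
        imgs[[k]] <- round(img * 255) / 255   # 8-bit grid, disk == memory
        labels <- c(labels, tree$tip.label[tip])
        bbch <- c(bbch, stages[(j - 1L) %% 4L + 1L])
      }
    }
    images <- array(unlist(imgs), c(spec$size, spec$size, k))
    ds <- image_dataset(images, labels, bbch)
    attr(ds, "tree") <- tree
    ds
  })
}

#' Write a synthetic dataset, its manifest and its taxonomy to disk
#'
#' Produces the exact directory layout [load_dataset()] reads, plus the
#' ground-truth Newick tree as `tree.nwk`.
#'
#' @param spec a [synthetic_spec()].
#' @param root output directory.
#' @return the generated [image_dataset()], invisibly.
#' @export
synth_write <- function(spec, root) {
  ds <- synth_generate(spec)
  write_dataset(ds, root)
  write_taxonomy(spec$tree, file.path(root, "tree.nwk"))
  invisible(ds)
}
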