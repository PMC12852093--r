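#' Create a trainable image encoder
#'
#' An encoder is any trainable map from an image array to a d-dimensional
#' real embedding (d = 64 by default). The bundled backbone is `tiny_cnn`:
#' three 3x3 convolution + ReLU + 2x2 average-pooling blocks (widths
#' 8/16/32) followed by a dense head to the embedding dimension — small
#' enough to train in minutes on one CPU. The GPU-scale backbones named
#' `resnet50` and `mobilenet_v3_small` are recognized but not bundled;
#' selecting them raises an informative error.
#'
#' @param architecture one of `"tiny_cnn"`, `"resnet50"`,
#'   `"mobilenet_v3_small"`.
#' @param input_size square input size in pixels (must be a multiple of 8
#'   for `tiny_cnn`).
#' @param channels image channels (1 = grayscale, 3 = RGB).
#' @param embedding_dim embedding dimension d (default 64).
#' @param seed integer seed for weight initialization.
#' @param pretrained logical; pretrained initialization is not available for
#'   `tiny_cnn` and must be `FALSE`.
#' @return an object of class `encoder`.
#' @examples
#' enc <- encoder_create(input_size = 32, seed = 1)
#' emb <- encoder_embed(enc, array(runif(32 * 32 * 2), c(32, 32, 2)))
#' dim(emb)  # 2 x 64
#' @export
encoder_create <- function(architecture = c("tiny_cnn", "resnet50",
                                            "mobilenet_v3_small"),
                           input_size = 32L, channels = 1L,
                           embedding_dim = 64L, seed = 1L,
                           pretrained = FALSE) {
  architecture <- match.arg(architecture)
  if (architecture != "tiny_cnn") {
    stop_taxembed(architecture, " requires a GPU-scale deep learning ",
                  "framework and is not bundled; use architecture = ",
                  "'tiny_cnn'", class = "taxembed_config_error")
  }
  if (isTRUE(pretrained)) {
    stop_taxembed("pretrained initialization is not available for tiny_cnn",
                  class = "taxembed_config_error")
  }
  layers <- with_seed(seed, nn_tiny_cnn(input_size, channels, embedding_dim))
  structure(
    list(architecture = architecture, layers = layers,
         input_size = as.integer(input_size),
         channels = as.integer(channels),
         embedding_dim = as.integer(embedding_dim), seed = as.integer(seed)),
    class = "encoder"
  )
}

#' @export
print.encoder <- function(x, ...) {
  cat(sprintf("<encoder: %s, %dx%dx%d -> %d-d embedding>\n",
              x$architecture, x$input_size, x$input_size, x$channels,
              x$embedding_dim))
  invisible(x)
}

# Coerce images to the internal (H, W, N, C) activation layout.
# Accepted inputs: (H, W, N) for grayscale stacks, (H, W, C, N), or a single
# (H, W) matrix.
as_activation <- function(images, channels) {
  d <- dim(images)
  if (is.null(d) || length(d) == 2L) {
    images <- array(images, c(dim(images) %||% c(length(images), 1L), 1L, 1L))
    d <- dim(images)
  }
  if (length(d) == 3L) {
    images <- array(images, c(d[1], d[2], d[3], 1L))      # (H, W, N, 1)
  } else if (length(d) == 4L) {
    images <- aperm(images, c(1, 2, 4, 3))                # (H,W,C,N) -> (H,W,N,C)
  } else {
    stop_taxembed("images must be a 2-, 3- or 4-dimensional array",
                  class = "taxembed_shape_error")
  }
  if (dim(images)[4] != channels) {
    stop_taxembed("image channels (", dim(images)[4],
                  ") do not match the encoder (", channels, ")",
                  class = "taxembed_shape_error")
  }
  images
}

#' Embed images with an encoder
#'
#' Deterministic inference pass: identical parameters and inputs always
#' yield identical embeddings.
#'
#' @param encoder an [encoder_create()] object.
#' @param images array of images: `(H, W, N)` for grayscale stacks or
#'   `(H, W, C, N)`.
#' @return an N x d embedding matrix.
#' @export
encoder_embed <- function(encoder, images) {
  stopifnot(inherits(encoder, "encoder"))
  x <- as_activation(images, encoder$channels)
  if (dim(x)[1] != encoder$input_size || dim(x)[2] != encoder$input_size) {
    stop_taxembed("image size ", dim(x)[1], "x", dim(x)[2],
                  " does not match the encoder input size ",
                  encoder$input_size, class = "taxembed_shape_error")
  }
  nn_forward(encoder$layers, x, keep_cache = FALSE)$out
}
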