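# Dataset loading (directory of PNG/JPEG images with a CSV manifest or a
# folder-per-class layout) and the k-shot train/validation/test partition.

#' Construct an image dataset
#'
#' @param images `(H, W, N)` array for grayscale stacks, `(H, W, C, N)` for
#'   multi-channel, or `NULL` for a records-only (lazy) dataset.
#' @param labels class code per image (non-empty).
#' @param bbch optional integer BBCH growth stage per image (`NA` when
#'   unknown).
#' @param paths optional source path per image.
#' @return an object of class `image_dataset`.
#' @export
image_dataset <- function(images, labels, bbch = NULL, paths = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (any(!nzchar(labels)) || any(is.na(labels))) {
    stop_taxembed("every image needs a non-empty class code",
                  class = "taxembed_validation_error")
  }
  if (!is.null(images)) {
    d <- dim(images)
    stopifnot(length(d) %in% c(3L, 4L))
    n_img <- if (length(d) == 3L) d[3] else d[4]
    if (n_img != n) {
      stop_taxembed("images (", n_img, ") and labels (", n, ") disagree",
                    class = "taxembed_shape_error")
    }
  }
  bbch <- if (is.null(bbch)) rep(NA_integer_, n) else as.integer(bbch)
  paths <- if (is.null(paths)) rep(NA_character_, n) else as.character(paths)
  stopifnot(length(bbch) == n, length(paths) == n)
  d <- dim(images)
  structure(
    list(images = images, labels = labels, bbch = bbch, paths = paths,
         size = if (is.null(images)) NA_integer_ else d[1],
         channels = if (is.null(images) || length(d) == 3L) 1L else d[3],
         n = n),
    class = "image_dataset"
  )
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset: %d images, %d classes%s%s>\n", x$n,
              length(unique(x$labels)),
              if (is.na(x$size)) ", records only"
              else sprintf(", %dx%dx%d", x$size, x$size, x$channels),
              if (all(is.na(x$bbch))) "" else ", BBCH annotated"))
  invisible(x)
}

# subset a dataset by image index, preserving order
subset_dataset <- function(ds, idx) {
  images <- if (is.null(ds$images)) NULL else slice_images(ds$images, idx)
  image_dataset(images, ds$labels[idx], ds$bbch[idx], ds$paths[idx])
}

#' Load an image dataset from a directory
#'
#' Two layouts are accepted: a CSV manifest (`path,class[,bbch]`, paths
#' relative to `root`) or, as a fallback, one subdirectory per class
#' containing PNG/JPEG files. Images are center-cropped to a square and
#' bilinearly resized to `resize` pixels on load (conventional sizes: 512,
#' 224 and 64 for the common seedling datasets; 32 for the synthetic ones).
#' Undecodable files are excluded with a warning.
#'
#' @param root dataset directory.
#' @param manifest manifest path; defaults to `root/manifest.csv` when that
#'   file exists.
#' @param resize target square size in pixels, or `NULL` to keep images at
#'   their native size (all images must then agree).
#' @param load_images if `FALSE`, return a records-only dataset (labels,
#'   BBCH, paths) without decoding any pixels.
#' @param channels 1 to convert everything to grayscale, 3 to keep RGB;
#'   default 1.
#' @return an [image_dataset()].
#' @export
load_dataset <- function(root, manifest = NULL, resize = NULL,
                         load_images = TRUE, channels = 1L) {
  if (!dir.exists(root)) {
    stop_taxembed("dataset directory not found: ", root,
                  class = "taxembed_file_error")
  }
  default_manifest <- file.path(root, "manifest.csv")
  if (is.null(manifest) && file.exists(default_manifest)) {
    manifest <- default_manifest
  }
  if (!is.null(manifest)) {
    mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "class") %in% names(mf))) {
      stop_taxembed("manifest must have 'path' and 'class' columns",
                    class = "taxembed_validation_error")
    }
    paths <- file.path(root, mf$path)
    labels <- as.character(mf$class)
    bbch <- if ("bbch" %in% names(mf)) as.integer(mf$bbch) else NULL
  } else {
    dirs <- list.dirs(root, recursive = FALSE)
    if (length(dirs) == 0L) {
      stop_taxembed("no manifest and no class subdirectories in ", root,
                    class = "taxembed_validation_error")
    }
    files <- lapply(dirs, list.files,
                    pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                    full.names = TRUE)
    empty <- basename(dirs)[lengths(files) == 0L]
    if (length(empty) > 0L) {
      stop_taxembed("class folder(s) contain no images: ",
                    paste(empty, collapse = ", "),
                    class = "taxembed_validation_error")
    }
    paths <- unlist(files)
    labels <- rep(basename(dirs), lengths(files))
    bbch <- NULL
  }
  if (!load_images) {
    return(image_dataset(NULL, labels, bbch, paths))
  }
  imgs <- vector("list", length(paths))
  ok <- rep(TRUE, length(paths))
  for (i in seq_along(paths)) {
    img <- tryCatch(read_image_file(paths[i], resize, channels),
                    error = function(e) NULL)
    if (is.null(img)) ok[i] <- FALSE else imgs[[i]] <- img
  }
  if (any(!ok)) {
    warning(sum(!ok), " undecodable image(s) excluded, e.g. ",
            paths[which(!ok)[1]])
  }
  imgs <- imgs[ok]
  if (length(imgs) == 0L) {
    stop_taxembed("no decodable images in ", root,
                  class = "taxembed_validation_error")
  }
  sizes <- vapply(imgs, function(m) dim(m)[1], numeric(1))
  if (length(unique(sizes)) != 1L) {
    stop_taxembed("images have mixed sizes; pass resize=",
                  class = "taxembed_validation_error")
  }
  h <- dim(imgs[[1]])[1]
  if (channels == 1L) {
    images <- array(unlist(imgs), c(h, h, length(imgs)))
  } else {
    images <- array(unlist(imgs), c(h, h, channels, length(imgs)))
  }
  image_dataset(images, labels[ok],
                if (is.null(bbch)) NULL else bbch[ok], paths[ok])
}

# read one PNG/JPEG as a [0,1] matrix (grayscale) or (H, W, C) array,
# center-cropped square then bilinearly resized. PNGs go through the png
# package (byte-exact round trip with write_dataset); other formats through
# EBImage.
read_image_file <- function(path, resize = NULL, channels = 1L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L && channels == 1L) {
      img <- matrix(rowMeans(matrix(img[, , 1:3], prod(dim(img)[1:2]), 3)),
                    dim(img)[1], dim(img)[2])
    }
  } else {
    img <- EBImage::readImage(path)
    if (channels == 1L && EBImage::colorMode(img) != 0L) {
      img <- EBImage::channel(img, "gray")
    }
    img <- as.array(img)
    if (length(dim(img)) == 2L) img <- as.matrix(img)
  }
  d <- dim(img)
  if (d[1] != d[2]) {
    side <- min(d[1], d[2])
    off <- floor((d[1:2] - side) / 2)
    img <- if (length(d) == 2L) {
      img[(off[1] + 1):(off[1] + side), (off[2] + 1):(off[2] + side)]
    } else {
      img[(off[1] + 1):(off[1] + side), (off[2] + 1):(off[2] + side), ]
    }
  }
  if (!is.null(resize) && dim(img)[1] != resize) {
    img <- EBImage::resize(img, w = resize, h = resize)
  }
  a <- as.array(img)
  if (channels == 1L) {
    matrix(a, dim(a)[1], dim(a)[2])
  } else {
    array(a, c(dim(a)[1], dim(a)[2], channels))
  }
}

#' Filter a dataset by BBCH growth stage
#'
#' Keeps only the images whose annotated BBCH stage is in `stages`,
#' preserving order.
#'
#' @param dataset an [image_dataset()] carrying BBCH annotations.
#' @param stages integer vector of stages to keep (e.g. `10:12` for the
#'   earliest seedling stages).
#' @return the filtered dataset.
#' @export
filter_bbch <- function(dataset, stages) {
  stopifnot(inherits(dataset, "image_dataset"))
  if (all(is.na(dataset$bbch))) {
    stop_taxembed("dataset carries no BBCH annotations",
                  class = "taxembed_validation_error")
  }
  keep <- which(dataset$bbch %in% as.integer(stages))
  subset_dataset(dataset, keep)
}

#' k-shot train/validation/test split
#'
#' For every class, `k` images are sampled uniformly for training; the
#' remaining images are shuffled and distributed evenly (50/50) into
#' validation and test sets, each side truncated at the cap (250 by
#' default). When the remainder is odd, validation receives the extra
#' image. Deterministic under a fixed seed.
#'
#' @param x an [image_dataset()] or a character vector of labels.
#' @param k training images per class; every class must have more than `k`
#'   images.
#' @param seed integer replicate seed.
#' @param caps `c(validation, test)` per-class ceilings.
#' @return an object of class `split_spec` with integer index vectors
#'   `train`, `val`, `test`, a `per_class` breakdown, and the `k`, `seed`,
#'   `caps` used.
#' @export
split_k_shot <- function(x, k, seed, caps = c(250L, 250L)) {
  labels <- if (inherits(x, "image_dataset")) x$labels else as.character(x)
  stopifnot(k >= 1L, length(caps) == 2L)
  by_class <- split(seq_along(labels), labels)
  too_small <- names(by_class)[lengths(by_class) <= k]
  if (length(too_small) > 0L) {
    counts <- lengths(by_class)[too_small]
    stop_taxembed("class(es) with <= k = ", k, " images: ",
                  paste0(too_small, " (", counts, ")", collapse = ", "),
                  class = "taxembed_validation_error")
  }
  classes <- sort(names(by_class), method = "radix")
  per_class <- with_seed(seed, {
    lapply(classes, function(cl) {
      idx <- by_class[[cl]]
      idx <- idx[sample.int(length(idx))]
      train <- idx[seq_len(k)]
      rest <- idx[-seq_len(k)]
      r <- length(rest)
      n_val <- min(ceiling(r / 2), caps[1])
      n_test <- min(floor(r / 2), caps[2])
      list(train = train,
           val = if (n_val > 0L) rest[seq_len(n_val)] else integer(0),
           test = if (n_test > 0L) rest[n_val + seq_len(n_test)]
                  else integer(0))
    })
  })
  names(per_class) <- classes
  structure(
    list(train = unlist(lapply(per_class, `[[`, "train"), use.names = FALSE),
         val = unlist(lapply(per_class, `[[`, "val"), use.names = FALSE),
         test = unlist(lapply(per_class, `[[`, "test"), use.names = FALSE),
         per_class = per_class, k = as.integer(k), seed = as.integer(seed),
         caps = as.integer(caps)),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec: k = %d, %d train / %d val / %d test, seed %d>\n",
              x$k, length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Serialize a split to JSON
#'
#' @param split a [split_k_shot()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(k = split$k, seed = split$seed, caps = split$caps,
         per_class = lapply(split$per_class, function(p) {
           list(train = p$train, val = p$val, test = p$test)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split written by [write_split()]
#'
#' @param path JSON path.
#' @return a `split_spec`.
#' @export
read_split <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_class <- lapply(j$per_class, function(p) {
    lapply(p, as.integer)
  })
  structure(
    list(train = unlist(lapply(per_class, `[[`, "train"), use.names = FALSE),
         val = unlist(lapply(per_class, `[[`, "val"), use.names = FALSE),
         test = unlist(lapply(per_class, `[[`, "test"), use.names = FALSE),
         per_class = per_class, k = as.integer(j$k),
         seed = as.integer(j$seed), caps = as.integer(j$caps)),
    class = "split_spec"
  )
}

#' Write a dataset to a directory with a manifest
#'
#' Writes one PNG per image under `root/<class>/` plus a `manifest.csv`
#' (`path,class,bbch`) in the exact layout [load_dataset()] reads.
#'
#' @param dataset an [image_dataset()] with pixel data.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "image_dataset"), !is.null(dataset$images))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counters <- list()
  rows <- vector("list", dataset$n)
  for (i in seq_len(dataset$n)) {
    cl <- dataset$labels[i]
    counters[[cl]] <- (counters[[cl]] %||% 0L) + 1L
    dir.create(file.path(root, cl), showWarnings = FALSE)
    rel <- file.path(cl, sprintf("%s_%04d.png", cl, counters[[cl]]))
    img <- slice_images(dataset$images, i)
    png::writePNG(array(img, dim(img)[1:2]), file.path(root, rel))
    rows[[i]] <- data.frame(path = rel, class = cl, bbch = dataset$bbch[i])
  }
  utils::write.csv(do.call(rbind, rows), file.path(root, "manifest.csv"),
                   row.names = FALSE)
  invisible(root)
}
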