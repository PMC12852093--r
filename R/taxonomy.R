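#' Parse a Newick taxonomy string
#'
#' Reads a rooted taxonomic tree whose leaf labels are class codes (for
#' example the EPPO-style species codes `AMARE`, `AMATU`, `CHEAL`, `ECHCG`,
#' `SETFA`). Branch lengths that are absent from the string default to 1.0,
#' matching the convention of one unit of distance per taxonomic level.
#'
#' @param text a Newick string, e.g. `"((A:1,B:1):1,C:1);"`.
#' @param unit_levels logical; if `TRUE`, every branch length is forced to
#'   1.0 regardless of what the string contains (one unit per level).
#' @return an object of class `phylo` (see [ape::read.tree()]) validated to
#'   be a rooted tree with unique, non-empty leaf labels and non-negative
#'   branch lengths.
#' @examples
#' tr <- parse_newick("((ECHCG:1,SETFA:1):1,(CHEAL:1,(AMARE:1,AMATU:1):1):1);")
#' tr$tip.label
#' @seealso [build_distance_matrix()]
#' @export
parse_newick <- function(text, unit_levels = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop_taxembed("Newick parse error: string could not be read as a tree",
                  class = "taxembed_parse_error")
  }
  validate_taxonomy(tree, unit_levels = unit_levels)
}

# Cheap structural scan so that malformed strings fail with the offending
# character position instead of whatever ape happens to return.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_taxembed("Newick parse error at position ", i,
                      ": unmatched ')'", class = "taxembed_parse_error")
      }
    }
  }
  if (depth != 0L) {
    stop_taxembed("Newick parse error at position ", nchar(text),
                  ": ", depth, " unclosed '('", class = "taxembed_parse_error")
  }
  if (!grepl(";\\s*$", text)) {
    stop_taxembed("Newick parse error at position ", nchar(text),
                  ": missing terminal ';'", class = "taxembed_parse_error")
  }
  invisible(TRUE)
}

validate_taxonomy <- function(tree, unit_levels = FALSE) {
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(!nzchar(labs))) {
    stop_taxembed("taxonomy has empty leaf labels",
                  class = "taxembed_validation_error")
  }
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0L) {
    stop_taxembed("duplicate leaf labels in taxonomy: ",
                  paste(dup, collapse = ", "),
                  class = "taxembed_validation_error")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1.0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 1.0
  if (unit_levels) tree$edge.length <- rep(1.0, nrow(tree$edge))
  if (any(tree$edge.length < 0)) {
    stop_taxembed("negative branch lengths in taxonomy",
                  class = "taxembed_validation_error")
  }
  tree
}

#' Read a Newick taxonomy from a file
#'
#' @param path path to a Newick file.
#' @inheritParams parse_newick
#' @return a validated `phylo` tree.
#' @export
read_taxonomy <- function(path, unit_levels = FALSE) {
  if (!file.exists(path)) {
    stop_taxembed("taxonomy file not found: ", path,
                  class = "taxembed_file_error")
  }
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               unit_levels = unit_levels)
}

#' Write a taxonomy to a Newick file
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' All-pairs taxonomic distance matrix
#'
#' Computes the symmetric matrix of leaf-to-leaf path lengths (sums of branch
#' lengths along the unique path between two leaves). These are the taxonomic
#' distances `T_p` and `T_n` consumed by the taxonomic margin. Labels are
#' ordered lexicographically so the matrix serializes deterministically.
#'
#' @param tree a `phylo` taxonomy, e.g. from [parse_newick()].
#' @return a numeric matrix with `dimnames` equal to the sorted leaf labels;
#'   symmetric, zero on the diagonal, strictly positive off-diagonal.
#' @examples
#' tr <- parse_newick("((ECHCG:1,SETFA:1):1,(CHEAL:1,(AMARE:1,AMATU:1):1):1);")
#' D <- build_distance_matrix(tr)
#' D["AMARE", "AMATU"]   # 2
#' D["AMARE", "CHEAL"]   # 3
#' @export
build_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- validate_taxonomy(tree)
  if (length(tree$tip.label) < 2L) {
    stop_taxembed("taxonomy must have at least 2 leaves",
                  class = "taxembed_validation_error")
  }
  D <- stats::cophenetic(tree)
  ord <- order(rownames(D), method = "radix")
  D <- D[ord, ord, drop = FALSE]
  # path lengths are exact sums; symmetrize to kill fp asymmetry from ape
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Look up the taxonomic distance between two classes
#'
#' @param taxdist a distance matrix from [build_distance_matrix()].
#' @param a,b class labels (leaf labels of the taxonomy).
#' @return the path length between the two leaves; 0 when `a == b`.
#' @export
class_distance <- function(taxdist, a, b) {
  labs <- rownames(taxdist)
  missing <- setdiff(c(a, b), labs)
  if (length(missing) > 0L) {
    stop_taxembed("unknown class label(s): ", paste(missing, collapse = ", "),
                  "; known labels: ", paste(labs, collapse = ", "),
                  class = "taxembed_lookup_error")
  }
  taxdist[a, b]
}

#' Export a taxonomic distance matrix as CSV
#'
#' Writes a square CSV whose header row and first column are the class
#' labels.
#'
#' @param taxdist distance matrix from [build_distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(taxdist, path) {
  df <- data.frame(label = rownames(taxdist), taxdist, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomic distance matrix from CSV
#'
#' @param path a CSV written by [write_distance_csv()].
#' @return a numeric matrix with label dimnames.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Build a balanced taxonomy with unit branch lengths
#'
#' Convenience constructor for synthetic experiments: a full `arity`-ary tree
#' with `n_levels` internal levels (so `arity ^ n_levels` leaves), every
#' branch of length 1.
#'
#' @param n_levels number of levels below the root (>= 1).
#' @param arity children per internal node (default 2).
#' @param prefix leaf label prefix; labels are `prefix` followed by a
#'   zero-padded index.
#' @return a `phylo` tree.
#' @examples
#' balanced_taxonomy(3)$tip.label  # 8 leaves
#' @export
balanced_taxonomy <- function(n_levels, arity = 2L, prefix = "C") {
  stopifnot(n_levels >= 1L, arity >= 2L)
  n_leaves <- arity^n_levels
  labels <- sprintf("%s%0*d", prefix, nchar(as.character(n_leaves)),
                    seq_len(n_leaves))
  build <- function(leaves, level) {
    if (level == 0L) return(leaves)
    size <- length(leaves) / arity
    kids <- vapply(seq_len(arity), function(i) {
      sub <- leaves[((i - 1) * size + 1):(i * size)]
      build(sub, level - 1L)
    }, character(1))
    paste0("(", paste0(kids, ":1", collapse = ","), ")")
  }
  txt <- paste0(build(labels, n_levels), ";")
  parse_newick(txt, unit_levels = TRUE)
}
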