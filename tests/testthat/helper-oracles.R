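# Independent oracles and fixture builders. Everything here deliberately
# avoids the code paths it checks: tree distances are recomputed from
# root-to-leaf edge walks, losses from scalar loops.

# random rooted tree with the given number of leaves and uniform(0.1, 2)
# branch lengths
random_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr
}

# brute-force leaf-to-leaf distances: each leaf's root path is an edge set;
# d(i, j) = sum of branch lengths over the symmetric difference of the two
# edge sets
oracle_tree_dist <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(max(tree$edge))
  parent_node[tree$edge[, 2]] <- tree$edge[, 1]
  path_edges <- lapply(seq_len(n_tip), function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      edges <- c(edges, parent_edge[node])
      node <- parent_node[node]
    }
    edges
  })
  D <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      if (i == j) next
      sym <- c(setdiff(path_edges[[i]], path_edges[[j]]),
               setdiff(path_edges[[j]], path_edges[[i]]))
      D[i, j] <- sum(tree$edge.length[sym])
    }
  }
  ord <- order(rownames(D), method = "radix")
  D[ord, ord]
}

# four-point condition: for any 4 leaves, the two largest of the three
# pairwise distance sums must be equal (within tol)
four_point_ok <- function(D, n_checks = 20, tol = 1e-9) {
  n <- nrow(D)
  if (n < 4) return(TRUE)
  for (rep in seq_len(n_checks)) {
    q <- sample.int(n, 4)
    sums <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                   D[q[1], q[3]] + D[q[2], q[4]],
                   D[q[1], q[4]] + D[q[2], q[3]]))
    if (abs(sums[3] - sums[2]) > tol) return(FALSE)
  }
  TRUE
}

# scalar-loop triplet hinge: the reference for every vectorized loss
oracle_triplet_loop <- function(x_a, x_p, x_n, margins) {
  n <- nrow(x_a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d_ap <- sqrt(sum((x_a[i, ] - x_p[i, ])^2))
    d_an <- sqrt(sum((x_a[i, ] - x_n[i, ])^2))
    out[i] <- max(0, d_ap - d_an + margins[i])
  }
  out
}

# random batch over the labels of a taxonomic distance matrix, same-class
# positives
random_batch <- function(D, n = 16, d = 8) {
  labs <- rownames(D)
  a <- sample(labs, n, replace = TRUE)
  ng <- vapply(a, function(l) sample(setdiff(labs, l), 1), character(1))
  triplet_batch(matrix(rnorm(n * d), n), matrix(rnorm(n * d), n),
                matrix(rnorm(n * d), n), a, a, ng)
}

# the worked 5-leaf unit taxonomy used throughout
example_taxonomy <- function() {
  parse_newick("((ECHCG:1,SETFA:1):1,(CHEAL:1,(AMARE:1,AMATU:1):1):1);")
}

# WPD-shaped records-only fixture: per-class totals with BBCH annotations
# arranged to match the published per-stage counts
wpd_records_fixture <- function() {
  total    <- c(AMARE = 934, AMATU = 409, CHEAL = 832, ECHCG = 768,
                SETFA = 977)
  upto14   <- c(AMARE = 658, AMATU = 292, CHEAL = 655, ECHCG = 725,
                SETFA = 900)
  upto12   <- c(AMARE = 570, AMATU = 238, CHEAL = 498, ECHCG = 581,
                SETFA = 580)
  labels <- character(0); bbch <- integer(0)
  for (cl in names(total)) {
    n12 <- upto12[[cl]]
    n34 <- upto14[[cl]] - n12          # BBCH 13-14
    rest <- total[[cl]] - upto14[[cl]] # outside 10-14
    stages <- c(rep_len(c(10L, 11L, 12L), n12),
                rep_len(c(13L, 14L), n34),
                rep_len(c(9L, 21L), rest))
    labels <- c(labels, rep(cl, total[[cl]]))
    bbch <- c(bbch, stages)
  }
  image_dataset(NULL, labels, bbch)
}

# training images of a split (image slicing is internal to the package)
slice_train <- function(ds, split) {
  d <- dim(ds$images)
  if (length(d) == 3L) ds$images[, , split$train, drop = FALSE]
  else ds$images[, , , split$train, drop = FALSE]
}

# small, fast synthetic dataset for training tests: 4 classes, 16 px
tiny_training_dataset <- function(n_per_class = 8, seed = 5) {
  tree <- balanced_taxonomy(2, prefix = "T")
  ds <- synth_generate(synthetic_spec(tree, n_per_class = n_per_class,
                                      size = 16, seed = seed))
  list(ds = ds, tree = tree, taxdist = build_distance_matrix(tree))
}
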