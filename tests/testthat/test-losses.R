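# a distance matrix with hand-set entries for margin tests (labels only;
# taxonomic_margin just indexes it)
hand_matrix <- function() {
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- D["B", "A"] <- 1
  D["A", "C"] <- D["C", "A"] <- 2
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 2
  D["B", "D"] <- D["D", "B"] <- 3
  D["C", "D"] <- D["D", "C"] <- 3
  D
}

# batch with prescribed anchor-positive / anchor-negative distances using
# 2-d embeddings
dist_batch <- function(d_ap, d_an, labels_a = NULL, labels_n = NULL) {
  n <- length(d_ap)
  labels_a <- labels_a %||% rep("A", n)
  triplet_batch(matrix(0, n, 2),
                cbind(d_ap, 0), cbind(0, d_an),
                labels_a, labels_a, labels_n %||% rep("B", n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pairwise_distance is Euclidean and validates shape", {
  u <- matrix(rnorm(12), 4)
  expect_equal(pairwise_distance(u, u), rep(0, 4))
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_error(pairwise_distance(matrix(0, 2, 3), matrix(0, 2, 4)),
               class = "taxembed_shape_error")
  set.seed(1)
  for (rep in 1:20) {
    a <- matrix(rnorm(40), 8); b <- matrix(rnorm(40), 8)
    loop <- vapply(1:8, function(i) sqrt(sum((a[i, ] - b[i, ])^2)),
                   numeric(1))
    expect_equal(pairwise_distance(a, b), loop, tolerance = 1e-6)
  }
})

test_that("triplet hinge matches its definition on prescribed distances", {
  expect_equal(triplet_loss(dist_batch(0.2, 0.9), 0.5), 0)
  expect_equal(triplet_loss(dist_batch(0.7, 0.7), 0.5), 0.5)
  expect_equal(triplet_loss(dist_batch(1.0, 0.0), 0), 1.0)
  expect_error(triplet_loss(dist_batch(1, 1), -0.1),
               class = "taxembed_validation_error")
  expect_equal(reduce_loss(triplet_loss(dist_batch(c(0.2, 0.7), c(0.9, 0.7)),
                                        0.5)),
               mean(c(0, 0.5)))
})

test_that("min-max normalization handles regular, constant and single input", {
  expect_equal(minmax_normalize(c(0, 1, 2)),
               c(0, 1, 2) / (2 + 1e-6), tolerance = 1e-12)
  expect_equal(round(minmax_normalize(c(0, 1, 2)), 7),
               c(0, 0.4999998, 0.9999995))
  expect_equal(minmax_normalize(c(3, 3, 3)), c(0, 0, 0))
  expect_equal(minmax_normalize(5), 0)
  expect_error(minmax_normalize(numeric(0)),
               class = "taxembed_validation_error")
})

test_that("taxonomic margins grow with the negative's taxonomic distance", {
  D <- hand_matrix()
  m <- taxonomic_margin(rep("A", 3), rep("A", 3), c("B", "C", "D"), D)
  expect_equal(m[1], 0)
  expect_equal(m[2], 1 / (2 + 1e-6))
  expect_equal(m[3], 2 / (2 + 1e-6))
  expect_true(all(diff(m) > 0))
  # literal orientation reverses the ordering
  lit <- taxonomic_margin(rep("A", 3), rep("A", 3), c("B", "C", "D"), D,
                          orientation = "literal")
  expect_true(all(diff(lit) < 0))
  # degenerate: a single negative class collapses every margin to 0
  expect_equal(taxonomic_margin(rep("A", 4), rep("A", 4), rep("B", 4), D),
               rep(0, 4))
  expect_error(taxonomic_margin("A", "A", "Z", D),
               class = "taxembed_lookup_error")
})

test_that("taxonomic margins are always within [0, 1]", {
  set.seed(99)
  D <- build_distance_matrix(example_taxonomy())
  for (rep in 1:1000) {
    b <- random_batch(D, n = sample(2:12, 1))
    m <- taxonomic_margin(b$labels_a, b$labels_p, b$labels_n, D)
    expect_true(all(m >= 0 & m <= 1))
    mg <- taxonomic_margin(b$labels_a, b$labels_p, b$labels_n, D,
                           scope = "matrix")
    expect_true(all(mg >= 0 & mg <= 1))
  }
})

test_that("taxonomic loss composes margin and hinge exactly", {
  D <- build_distance_matrix(example_taxonomy())
  set.seed(3)
  for (rep in 1:25) {
    b <- random_batch(D, n = 16, d = 8)
    lv <- taxonomic_loss(b, D)
    m <- taxonomic_margin(b$labels_a, b$labels_p, b$labels_n, D)
    expect_equal(as.numeric(lv), oracle_triplet_loop(b$x_a, b$x_p, b$x_n, m),
                 tolerance = 1e-6)
    expect_true(all(lv >= 0))
  }
  # all negatives in one class: margins 0, so the loss equals the
  # margin-free triplet loss
  b <- random_batch(D, n = 8)
  b$labels_n <- rep("SETFA", 8)
  b$labels_a <- b$labels_p <- rep("AMARE", 8)
  expect_equal(as.numeric(taxonomic_loss(b, D)),
               as.numeric(triplet_loss(b, 0)))
  # equal anchor distances: the loss vector is exactly the margin vector
  db <- dist_batch(c(1, 1, 1), c(1, 1, 1), rep("A", 3))
  db$labels_n <- c("B", "C", "D")
  lv <- taxonomic_loss(db, hand_matrix())
  expect_equal(as.numeric(lv), as.numeric(attr(lv, "margins")))
})

test_that("a uniform off-diagonal taxonomy collapses the loss to margin 0", {
  labs <- c("A", "B", "C")
  D <- matrix(2, 3, 3, dimnames = list(labs, labs)); diag(D) <- 0
  set.seed(8)
  b <- triplet_batch(matrix(rnorm(12), 6), matrix(rnorm(12), 6),
                     matrix(rnorm(12), 6),
                     rep("A", 6), rep("A", 6),
                     sample(c("B", "C"), 6, replace = TRUE))
  expect_equal(as.numeric(taxonomic_loss(b, D)),
               as.numeric(triplet_loss(b, 0)))
})

test_that("HTL margin reproduces beta + d_H - S_a and validates classes", {
  st <- htl_state(classes = c("A", "B"),
                  d_H = matrix(c(0, 1, 1, 0), 2,
                               dimnames = list(c("A", "B"), c("A", "B"))),
                  S = c(A = 0.4, B = 0.2), beta = 0.1)
  expect_equal(htl_margin(st, "A", "B"), 0.7)
  st0 <- htl_state(classes = c("A", "B"),
                   d_H = matrix(c(0, 0.4, 0.4, 0), 2,
                                dimnames = list(c("A", "B"), c("A", "B"))),
                   S = c(A = 0.4, B = 0.4), beta = 0)
  expect_equal(htl_margin(st0, "A", "B"), 0)
  expect_error(htl_margin(st, "A", "Z"), class = "taxembed_state_error")
  expect_error(htl_margin(list(), "A", "B"), class = "taxembed_state_error")
  # margins never go negative
  stn <- htl_state(classes = c("A", "B"),
                   d_H = matrix(c(0, 0.1, 0.1, 0), 2,
                                dimnames = list(c("A", "B"), c("A", "B"))),
                   S = c(A = 5, B = 5), beta = 0.1)
  expect_equal(htl_margin(stn, "A", "B"), 0)
})

test_that("hierarchy rebuild follows average-linkage merges and the level cap", {
  # 4 classes on a line at 0, 1, 10, 12: merges at heights 1 (A,B),
  # 2 (C,D), then 10.5 between the two pairs (mean of 10, 12, 9, 11);
  # discretized upward on a 16-level grid of step 10.5/16
  emb <- matrix(rep(c(0, 1, 10, 12), each = 2), ncol = 1)
  labels <- rep(c("A", "B", "C", "D"), each = 2)
  st <- htl_rebuild_hierarchy(emb, labels)
  step <- 10.5 / 16
  expect_equal(st$d_H["A", "B"], ceiling(1 / step) * step)
  expect_equal(st$d_H["C", "D"], ceiling(2 / step) * step)
  expect_equal(st$d_H["A", "C"], 10.5)
  expect_equal(st$d_H["A", "D"], st$d_H["B", "C"])
  expect_lt(st$d_H["A", "B"], st$d_H["C", "D"])
  expect_lt(st$d_H["C", "D"], st$d_H["A", "C"])
  expect_equal(unname(st$S["A"]), 0)

  # two classes: a single merge at their discretized centroid distance
  emb2 <- matrix(c(0, 0, 3, 3), ncol = 1)
  st2 <- htl_rebuild_hierarchy(emb2, c("X", "X", "Y", "Y"))
  expect_equal(st2$d_H["X", "Y"], 3)
  expect_equal(st2$n_levels, 1L)

  # the hierarchy depth never exceeds the cap
  set.seed(21)
  emb3 <- matrix(rnorm(60 * 4), 60)
  labels3 <- paste0("K", rep(1:30, each = 2))
  st3 <- htl_rebuild_hierarchy(emb3, labels3)
  expect_lte(st3$n_levels, 16L)
  expect_lte(length(unique(st3$d_H[upper.tri(st3$d_H)])), 16L)
})

test_that("htl_loss applies the state margins through the hinge", {
  st <- htl_state(classes = c("A", "B"),
                  d_H = matrix(c(0, 1, 1, 0), 2,
                               dimnames = list(c("A", "B"), c("A", "B"))),
                  S = c(A = 0.4, B = 0.2), beta = 0.1)
  b <- dist_batch(c(0.5, 0.5), c(0.6, 2.0))
  lv <- htl_loss(b, st)
  expect_equal(as.numeric(lv), c(max(0, 0.5 - 0.6 + 0.7),
                                 max(0, 0.5 - 2.0 + 0.7)))
})
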