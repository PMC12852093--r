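test_that("nearest-embedding classification matches the brute-force oracle", {
  # identity: a test vector equal to a training vector takes its label
  train <- matrix(c(0, 0, 1, 1, 5, 5), 3, byrow = TRUE)
  labs <- c("a", "b", "c")
  expect_equal(nearest_embedding_classify(train, train, labs), labs)
  # exact tie: lowest training index wins
  test <- matrix(c(0.5, 0.5), 1)
  expect_equal(nearest_embedding_classify(test, train, labs), "a")
  expect_error(nearest_embedding_classify(matrix(0, 1, 3), train, labs),
               class = "taxembed_shape_error")

  set.seed(31)
  for (rep in 1:100) {
    ntr <- sample(3:20, 1); nte <- sample(1:10, 1); d <- sample(2:6, 1)
    tr <- matrix(rnorm(ntr * d), ntr)
    te <- matrix(rnorm(nte * d), nte)
    lb <- sample(letters[1:4], ntr, replace = TRUE)
    oracle <- vapply(seq_len(nte), function(i) {
      dists <- vapply(seq_len(ntr), function(j) sqrt(sum((te[i, ] - tr[j, ])^2)),
                      numeric(1))
      lb[which.min(dists)]
    }, character(1))
    expect_equal(nearest_embedding_classify(te, tr, lb), oracle)
  }
})

test_that("metrics reproduce the hand-computed confusion example", {
  rep <- compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  pc <- rep$per_class
  expect_equal(pc$precision[pc$class == "A"], 0.5)
  expect_equal(pc$recall[pc$class == "A"], 1.0)
  expect_equal(pc$f1[pc$class == "A"], 2 / 3)
  expect_equal(pc$precision[pc$class == "B"], 1.0)
  expect_equal(pc$recall[pc$class == "B"], 2 / 3)
  expect_equal(pc$f1[pc$class == "B"], 0.8)
  expect_equal(rep$macro_f1, (2 / 3 + 0.8) / 2)
  # confusion rows are truths: row sums equal per-class test counts
  expect_equal(unname(rowSums(rep$confusion)), c(1L, 3L))
  expect_equal(rep$accuracy, 3 / 4)
})

test_that("metric conventions and identities hold", {
  all_ok <- compute_metrics(c("x", "y", "x"), c("x", "y", "x"))
  expect_equal(all_ok$per_class$precision, c(1, 1))
  expect_equal(all_ok$per_class$f1, c(1, 1))
  expect_equal(all_ok$macro_f1, 1)
  # never-predicted class: precision 0 with a zero-division flag
  none <- compute_metrics(c("x", "x"), c("x", "y"))
  pc <- none$per_class
  expect_equal(pc$precision[pc$class == "y"], 0)
  expect_true(pc$zero_division[pc$class == "y"])
  expect_error(compute_metrics("x", c("x", "y")),
               class = "taxembed_validation_error")
  # macro F1 cannot exceed the best per-class F1; trace/total = accuracy
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    pr <- sample(c("u", "v", "w"), n, replace = TRUE)
    tr <- sample(c("u", "v", "w"), n, replace = TRUE)
    r <- compute_metrics(pr, tr)
    expect_lte(r$macro_f1, max(r$per_class$f1) + 1e-12)
    expect_equal(sum(diag(r$confusion)) / sum(r$confusion), r$accuracy)
  }
})

test_that("silhouette matches a hand computation on a fixed 6-point instance", {
  # cluster 1: (0,0), (0,1), (1,0); cluster 2: (10,0), (10,1), (11,0)
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 0), c(10, 1), c(11, 0))
  labels <- rep(c("g1", "g2"), each = 3)
  # manual a/b means, point by point (textbook formula)
  dm <- as.matrix(dist(x))
  s_manual <- vapply(1:6, function(i) {
    own <- which(labels == labels[i] & seq_len(6) != i)
    oth <- which(labels != labels[i])
    a <- mean(dm[i, own]); b <- mean(dm[i, oth])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(silhouette_score(x, labels), mean(s_manual),
               tolerance = 1e-12)
  expect_gt(silhouette_score(x, labels), 0.8)  # far-separated tight clusters
  expect_error(silhouette_score(x, rep("one", 6)),
               class = "taxembed_validation_error")
})

test_that("shuffled labels on mixed data give near-zero or negative silhouette", {
  set.seed(17)
  x <- matrix(rnorm(60), 30)
  labels <- sample(rep(c("p", "q"), each = 15))
  expect_lt(silhouette_score(x, labels), 0.1)
})

test_that("t-SNE projection plus silhouette separates clear clusters", {
  set.seed(23)
  emb <- rbind(matrix(rnorm(8 * 8, 0, 0.05), 8),
               matrix(rnorm(8 * 8, 4, 0.05), 8))
  labels <- rep(c("near", "far"), each = 8)
  s <- tsne_silhouette(emb, labels, seed = 1)
  expect_gt(as.numeric(s), 0.8)
  expect_equal(dim(attr(s, "projection")), c(16L, 2L))
  # fixed seed => identical projection
  expect_equal(as.numeric(tsne_silhouette(emb, labels, seed = 1)),
               as.numeric(s))
  expect_error(tsne_silhouette(emb, rep("x", 40)),
               class = "taxembed_validation_error")
})

test_that("replicate comparison uses exact rank-sum tests with Bonferroni", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  cs <- compare_conditions(same)
  expect_equal(cs$comparisons$p_adjusted, 1)
  # fully separated samples of 10 vs 10: exact two-sided p = 2 / C(20, 10)
  sep <- list(lo = 1:10 / 100, hi = 1:10 / 100 + 1)
  p <- compare_conditions(sep)$comparisons$p_value
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
  # three conditions: three pairwise tests, Bonferroni factor 3
  three <- list(a = 1:5 / 10, b = 1:5 / 10 + 1, c = 1:5 / 10 + 2)
  ct <- compare_conditions(three)
  expect_equal(nrow(ct$comparisons), 3)
  expect_equal(ct$comparisons$p_adjusted,
               pmin(1, ct$comparisons$p_value * 3))
  expect_equal(ct$conditions$mean, c(0.3, 1.3, 2.3))
  expect_error(compare_conditions(list(a = 1:3)),
               class = "taxembed_validation_error")
  expect_error(compare_conditions(list(a = 1:3, b = 2)),
               class = "taxembed_validation_error")
})
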