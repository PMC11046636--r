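# Conceptual change/distance models: signed numeric change, judgment
# dissimilarities, classical MDS, embedding distances, animal distance
# models and transition counts.

test_that("signed number change subtracts the current number from the next", {
  expect_equal(signed_number_change(c("4", "10"))$value, 6)
  expect_equal(signed_number_change(c("7", "7", "7"))$value, c(0, 0))
  expect_equal(signed_number_change(c("12", "1"))$value, -11)
  expect_error(signed_number_change(c("4", "red")), "red")
  # block boundaries break the series
  s <- signed_number_change(c("1", "5", "2", "9"), block = c(1, 1, 2, 2))
  expect_equal(s$value, c(4, 7))
  expect_equal(s$from_trial, c(1, 3))
})

test_that("judgment dissimilarities average orderings and apply 10 - s", {
  tb <- data.frame(word_a = c("a", "a", "b"), word_b = c("b", "c", "c"),
                   rating = c(2, 9, 9))
  dm <- dissimilarity_from_judgments(tb)
  expect_equal(dm["a", "b"], 8)
  expect_equal(dm["a", "c"], 1)
  expect_equal(diag(dm), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(dm, t(dm))

  # repeated and reversed ratings are averaged first
  tb2 <- data.frame(word_a = c("a", "b", "a"), word_b = c("b", "a", "c"),
                    rating = c(3, 5, 9))
  tb2 <- rbind(tb2, data.frame(word_a = "b", word_b = "c", rating = 9))
  expect_equal(dissimilarity_from_judgments(tb2)["a", "b"], 6)

  expect_error(dissimilarity_from_judgments(
    data.frame(word_a = "a", word_b = "b", rating = 5),
    labels = c("a", "b", "c")), "a-c")
})

test_that("classical MDS embeds exact configurations up to isometry", {
  # degenerate: all-zero dissimilarities collapse to the origin
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(emb0 <- classical_mds(z), "padding")
  expect_equal(unname(emb0), matrix(0, 4, 2))

  # three collinear points with additive distances
  m <- as_dissimilarity(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3))
  expect_warning(emb1 <- classical_mds(m), "padding")
  expect_equal(sort(emb1[, 1]), c(-1, 0, 1))
  expect_equal(emb1[, 2], rep(0, 3))

  # exact ring chords reproduce the ring
  ring <- make_geometry("color")$coords
  emb2 <- classical_mds(as.matrix(dist(ring)))
  expect_lt(procrustes_disparity(ring, emb2), 1e-6)
})

test_that("classical MDS agrees with cmdscale on random planar configurations", {
  set.seed(42)
  for (i in 1:10) {
    pts <- matrix(rnorm(2 * 9, sd = 3), 9, 2)
    rownames(pts) <- paste0("p", 1:9)
    dm <- as.matrix(dist(pts))
    mine <- classical_mds(dm)
    ref <- cmdscale(dm, k = 2)
    expect_lt(procrustes_disparity(ref, mine), 1e-10)
    expect_lt(procrustes_disparity(pts, mine), 1e-8)
    expect_equal(colMeans(mine), c(dim1 = 0, dim2 = 0))
  }
})

test_that("embedding distance series equals a brute-force pairwise lookup", {
  emb <- rbind(red = c(1, 0), cyan = c(-1, 0), lime = c(0, 1))
  expect_equal(mds_distance_series(c("red", "red"), emb)$value, 0)
  expect_equal(mds_distance_series(c("red", "cyan"), emb)$value, 2)
  expect_error(mds_distance_series(c("red", "pink"), emb), "pink")

  set.seed(3)
  emb2 <- matrix(rnorm(24), 12, 2,
                 dimnames = list(make_geometry("color")$labels, NULL))
  words <- sample(rownames(emb2), 10, replace = TRUE)
  got <- mds_distance_series(words, emb2)$value
  oracle <- vapply(seq_len(9), function(i)
    sqrt(sum((emb2[words[i + 1], ] - emb2[words[i], ])^2)), numeric(1))
  expect_equal(got, oracle)
})

test_that("animal distance models honor their resource tables", {
  cl <- data.frame(word = c("dog", "cat", "eagle"),
                   label = c("pets", "pets", "birds"))
  s <- animal_distance_series(c("dog", "cat", "eagle"), "cluster",
                              list(clusters = cl))
  expect_equal(s$value, c(0, 1))
  graded <- animal_distance_series(c("dog", "cat", "eagle"), "cluster",
                                   list(clusters = cl), graded = TRUE)
  expect_equal(graded$value, c(1, 0))

  fr <- c(a = 100, b = 80, c = 1)
  expect_equal(animal_distance_series(c("a", "b", "c"), "frequency",
                                      list(frequency = fr))$value,
               c(20, 79))

  v <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 2), d = c(0, 0))
  cs <- animal_distance_series(c("a", "b", "c"), "cosine",
                               list(vectors = v))
  expect_equal(cs$value, c(0, 1))
  expect_error(animal_distance_series(c("a", "d"), "cosine",
                                      list(vectors = v)), "zero-norm")
  expect_error(animal_distance_series(c("a", "zz"), "frequency",
                                      list(frequency = fr)), "zz")

  sim <- matrix(c(9, 3, 3, 9), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_equal(animal_distance_series(c("a", "b"), "external_similarity",
                                      list(similarity = sim))$value, 7)
})

test_that("PC1 projection matches an eigendecomposition oracle", {
  # points already on one axis
  v <- cbind(c(0, 1, 4), 0)
  rownames(v) <- c("a", "b", "c")
  p <- pc1_projection(v)
  expect_equal(abs(diff(p[c("a", "c")])), c(c = 4), ignore_attr = TRUE)

  # two points: PC1 distance is the full Euclidean distance
  v2 <- rbind(a = c(0, 0, 0), b = c(3, 4, 0))
  p2 <- pc1_projection(v2)
  expect_equal(abs(p2["b"] - p2["a"]), c(b = 5))

  set.seed(8)
  v3 <- matrix(rnorm(100), 20, 5)
  rownames(v3) <- paste0("w", 1:20)
  p3 <- pc1_projection(v3)
  cv <- cov(scale(v3, scale = FALSE))
  axis <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  oracle <- drop(scale(v3, scale = FALSE) %*% axis)
  d_mine <- abs(outer(p3, p3, "-"))
  d_orac <- abs(outer(oracle, oracle, "-"))
  expect_lt(max(abs(d_mine - d_orac)), 1e-10)

  expect_error(pc1_projection(matrix(1, 5, 2,
                                     dimnames = list(letters[1:5], NULL))),
               "constant")
})

test_that("transition counts tally ordered pairs across blocks", {
  s <- transition_count_series(c("1", "2", "1", "2"))
  expect_equal(s$value, c(2, 1, 2))
  u <- transition_count_series(c("a", "b", "c", "d"))
  expect_equal(u$value, rep(1, 3))
  set.seed(2)
  words <- sample(letters[1:4], 30, replace = TRUE)
  expect_equal(sum(table(paste(words[-30], words[-1]))),
               length(transition_count_series(words)$value))
  # counts pool across blocks, transitions do not
  b <- transition_count_series(c("a", "b", "a", "b"), block = c(1, 1, 2, 2))
  expect_equal(b$value, c(2, 2))
  expect_equal(b$from_trial, c(1, 3))
})

test_that("distance models are invariant to resource-table permutation", {
  set.seed(5)
  v <- matrix(rnorm(60), 12, 5,
              dimnames = list(make_geometry("animal")$labels, NULL))
  words <- sample(rownames(v), 15, replace = TRUE)
  perm <- sample(12)
  for (model in c("cosine", "pc1")) {
    a <- animal_distance_series(words, model, list(vectors = v))$value
    b <- animal_distance_series(words, model,
                                list(vectors = v[perm, ]))$value
    expect_equal(a, b)
  }
})
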