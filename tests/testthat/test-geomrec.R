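# Geometry recovery from absolute gaze positions: concept means, the
# number-line position regression, fixation distance matrices, RSA and
# Procrustes alignment.

trials_at <- function(words, x, y, valid = TRUE) {
  data.frame(subject = "s01", block = 1L, trial = seq_along(words),
             word = words, median_x_px = x, median_y_px = y,
             n_valid_samples = 50, valid = valid)
}

test_that("concept means average per-trial medians over valid trials", {
  tr <- trials_at(c("a", "a", "b"), c(0, 10, 4), c(0, 0, 2))
  pos <- concept_mean_positions(tr)
  expect_equal(pos$mean_x_px[pos$concept == "a"], 5)
  expect_equal(pos$n_trials, c(2, 1))
  # invalid trials and empty tables drop out
  tr$valid <- c(TRUE, FALSE, FALSE)
  pos2 <- concept_mean_positions(tr)
  expect_equal(pos2$concept, "a")
  expect_equal(pos2$mean_x_px, 0)
  expect_equal(nrow(concept_mean_positions(trials_at("a", 1, 1,
                                                     valid = FALSE))), 0)

  set.seed(6)
  words <- sample(letters[1:5], 60, replace = TRUE)
  tr3 <- trials_at(words, rnorm(60), rnorm(60))
  pos3 <- concept_mean_positions(tr3)
  oracle <- tapply(tr3$median_x_px, tr3$word, mean)
  expect_equal(pos3$mean_x_px, as.vector(oracle[pos3$concept]))
})

test_that("position regression recovers exact linear number-line layouts", {
  vals <- setNames(1:12, as.character(1:12))
  tab <- data.frame(concept = as.character(1:12),
                    mean_x_px = 873.94 + 6.46 * (1:12),
                    mean_y_px = 453.26, n_trials = 10)
  fit <- position_regression(tab, vals, axis = "x")
  expect_equal(fit$slope, 6.46)
  expect_equal(fit$intercept, 873.94)
  # flat layout has zero slope; two points fix the line exactly
  expect_equal(position_regression(tab, vals, axis = "y")$slope, 0)
  two <- data.frame(concept = c("1", "2"), mean_x_px = c(0, 10),
                    mean_y_px = 0, n_trials = 1)
  fit2 <- position_regression(two, vals)
  expect_equal(fit2$slope, 10)
  expect_equal(fit2$intercept, -10)
  expect_error(position_regression(two[1, ], vals), "distinct")

  # list input adds per-subject slopes and group inference
  fits <- position_regression(list(tab, tab, two), vals, axis = "x")
  expect_equal(fits$subject_slopes, c(6.46, 6.46, 10))
  expect_s3_class(fits$group, "group_stats")
})

test_that("fixation distance matrices are exact pairwise Euclidean distances", {
  tab <- data.frame(concept = c("a", "b", "c"),
                    mean_x_px = c(0, 3, 0), mean_y_px = c(0, 0, 4),
                    n_trials = 1)
  dm <- distance_matrix_from_points(tab)
  expect_equal(dm["a", "b"], 3)
  expect_equal(dm["a", "c"], 4)
  expect_equal(dm["b", "c"], 5)
  same <- data.frame(concept = c("a", "b"), mean_x_px = 1, mean_y_px = 1,
                     n_trials = 1)
  expect_true(all(distance_matrix_from_points(same) == 0))
  set.seed(12)
  tab2 <- data.frame(concept = paste0("c", 1:8), mean_x_px = rnorm(8),
                     mean_y_px = rnorm(8), n_trials = 1)
  expect_equal(unname(distance_matrix_from_points(tab2)),
               unname(as.matrix(dist(cbind(tab2$mean_x_px,
                                           tab2$mean_y_px)))))
})

test_that("RSA correlates lower triangles, rank-invariantly and symmetrically", {
  set.seed(13)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  dm <- as.matrix(dist(pts))
  expect_equal(rsa_lower_triangle(dm, dm)$rho, 1)
  expect_equal(rsa_lower_triangle(dm, dm^2)$rho, 1)  # monotone transform
  dm2 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  dimnames(dm2) <- dimnames(dm)
  got <- rsa_lower_triangle(dm, dm2)
  expect_equal(got$rho, spearman_oracle(dm[lower.tri(dm)],
                                        dm2[lower.tri(dm2)]))
  expect_equal(got$rho, rsa_lower_triangle(dm2, dm)$rho)
  bad <- dm2
  rownames(bad) <- colnames(bad) <- LETTERS[1:6]
  expect_error(rsa_lower_triangle(dm, bad), "labels")
  expect_error(rsa_lower_triangle(dm[1:3, 1:3], dm2[1:3, 1:3]), "at least 4")
})

test_that("group gaze MDS normalizes, averages and embeds subject matrices", {
  ring <- make_geometry("color")$coords
  chord <- as.matrix(dist(ring))
  # single subject or identical subjects behave like plain MDS
  solo <- group_gaze_mds(list(chord * 37))
  expect_lt(procrustes_disparity(ring, solo), 1e-8)
  trio <- group_gaze_mds(list(chord, chord * 5, chord * 0.1))
  expect_lt(procrustes_disparity(solo, trio), 1e-8)
  # noisy copies still recover the ring
  set.seed(14)
  noisy <- lapply(1:20, function(i) {
    m <- chord * exp(rnorm(1, sd = 0.3))
    e <- matrix(rnorm(144, sd = 0.05 * mean(chord)), 12, 12)
    e <- (e + t(e)) / 2
    diag(e) <- 0
    pmax(m + e, 0)
  })
  emb <- group_gaze_mds(noisy)
  expect_lt(procrustes_disparity(ring, emb), 0.02)
  # all-zero subjects are skipped with a warning
  zero <- chord * 0
  expect_warning(with_zero <- group_gaze_mds(list(chord, zero)), "skipped")
  expect_lt(procrustes_disparity(solo, with_zero), 1e-8)
})

test_that("procrustes disparity is zero under similarity transforms", {
  set.seed(15)
  a <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("p", 1:10), NULL))
  expect_equal(procrustes_disparity(a, a), 0)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- 2.5 * a %*% (R %*% diag(c(-1, 1))) + 40   # rotate, reflect, scale
  rownames(b) <- rownames(a)
  expect_lt(procrustes_disparity(a, b), 1e-12)
  expect_gt(procrustes_disparity(a,
                                 matrix(rnorm(20), 10, 2,
                                        dimnames = dimnames(a))), 0.1)
  expect_error(procrustes_disparity(a, matrix(0, 10, 2,
                                              dimnames = dimnames(a))),
               "degenerate")
})

test_that("procrustes disparity matches an exhaustive rotation-grid oracle", {
  a <- rbind(p1 = c(0, 0), p2 = c(1, 0), p3 = c(0.2, 0.9))
  b <- rbind(p1 = c(0.1, 0.1), p2 = c(0.9, -0.2), p3 = c(0.4, 1.1))
  grid_oracle <- function(a, b) {
    ca <- scale(a, scale = FALSE); cb <- scale(b, scale = FALSE)
    ca <- ca / sqrt(sum(ca^2)); cb <- cb / sqrt(sum(cb^2))
    best <- Inf
    for (th in seq(0, 2 * pi, length.out = 20001)) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      for (M in list(R, R %*% diag(c(-1, 1)))) {
        rb <- cb %*% M
        s <- sum(ca * rb)             # optimal uniform scale
        best <- min(best, sum((ca - s * rb)^2))
      }
    }
    best
  }
  expect_equal(procrustes_disparity(a, b), grid_oracle(a, b),
               tolerance = 1e-6)
})

test_that("synthetic number cohorts recover the embedded line direction", {
  geo <- make_geometry("number")
  vals <- setNames(1:12, geo$labels)
  signs <- vapply(1:20, function(cohort) {
    cfg <- quick_config("number", n_trials = 40, coupling = 20,
                        noise_sd = 30, seed = 300 + cohort)
    set.seed(cfg$seed)
    seeds <- sample.int(.Machine$integer.max, 6)
    tabs <- lapply(seeds, function(s) {
      c2 <- cfg; c2$seed <- s
      concept_mean_positions(simulate_subject_trials(c2, geo)$trials)
    })
    sign(position_regression(tabs, vals, axis = "x")$slope)
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
})
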