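# Recovering conceptual geometry from absolute gaze positions: per-concept
# mean fixation points, number-line regression of position on value,
# representational similarity analysis between fixation-distance and
# concept-distance matrices, and group-level MDS reconstruction from gaze.

#' Mean gaze position per concept
#'
#' Arithmetic mean of the per-trial gaze medians, per concept word, over
#' valid trials.  Concepts without any valid trial are absent from the
#' output.
#'
#' @param trials a trial table from [window_median_gaze()].
#' @return data frame `concept`, `mean_x_px`, `mean_y_px`, `n_trials`.
#' @export
concept_mean_positions <- function(trials) {
  t_ok <- trials[trials$valid, , drop = FALSE]
  if (nrow(t_ok) == 0)
    return(data.frame(concept = character(), mean_x_px = numeric(),
                      mean_y_px = numeric(), n_trials = integer()))
  agg <- aggregate(cbind(median_x_px, median_y_px) ~ word, data = t_ok,
                   FUN = mean)
  n <- as.integer(table(t_ok$word)[agg$word])
  data.frame(concept = agg$word, mean_x_px = agg$median_x_px,
             mean_y_px = agg$median_y_px, n_trials = n,
             stringsAsFactors = FALSE)
}

#' Regress mean gaze position on concept value
#'
#' Ordinary least squares of the per-concept mean position (one axis) on a
#' scalar concept value (e.g. the integer magnitude of a number word).  With
#' a list of per-subject position tables, fits each subject separately and
#' adds group inference: a one-sample t test (with JZS Bayes factor) of the
#' per-subject slopes against zero.
#'
#' @param table a [concept_mean_positions()] table, or a list of them (one
#'   per subject).
#' @param concept_values named numeric vector mapping concept labels to
#'   scalar values.
#' @param axis `"x"` or `"y"`.
#' @return list with `slope`, `intercept` (group means when a list is
#'   given), `subject_slopes`, `subject_intercepts`, and `group` (a
#'   [group_t()] result, `NULL` for a single table).
#' @export
position_regression <- function(table, concept_values, axis = c("x", "y")) {
  axis <- match.arg(axis)
  tables <- if (is.data.frame(table)) list(table) else table
  fit_one <- function(tb) {
    v <- concept_values[tb$concept]
    if (anyNA(v))
      stop_config("concepts missing from concept_values: %s",
                  paste(tb$concept[is.na(v)], collapse = ", "))
    if (length(unique(v)) < 2)
      stop_config("need at least 2 distinct concept values")
    pos <- if (axis == "x") tb$mean_x_px else tb$mean_y_px
    unname(coef(lm(pos ~ v)))
  }
  co <- vapply(tables, fit_one, numeric(2))
  slopes <- co[2, ]
  intercepts <- co[1, ]
  group <- if (length(tables) > 1) group_t(slopes) else NULL
  list(slope = mean(slopes), intercept = mean(intercepts),
       subject_slopes = slopes, subject_intercepts = intercepts,
       group = group)
}

#' Pairwise Euclidean distance matrix of concept positions
#'
#' @param table a [concept_mean_positions()] table (at least 2 concepts).
#' @return labeled symmetric distance matrix.
#' @export
distance_matrix_from_points <- function(table) {
  if (nrow(table) < 2) stop_config("need at least 2 concepts")
  m <- as.matrix(dist(cbind(table$mean_x_px, table$mean_y_px)))
  dimnames(m) <- list(table$concept, table$concept)
  m
}

#' Representational similarity of two distance matrices
#'
#' Spearman correlation of the strictly-lower-triangle entries (diagonal
#' excluded) of two dissimilarity matrices over the same labels.  The
#' returned p-value treats the triangle entries as independent and is only
#' a descriptive, subject-less quantity: group inference should be run on
#' per-subject correlations via [group_t()].
#'
#' @param dm_a,dm_b dissimilarity matrices with identical labels and order
#'   (at least 4 labels).
#' @return list with `rho` and `p_subjectless`.
#' @export
rsa_lower_triangle <- function(dm_a, dm_b) {
  dm_a <- as_dissimilarity(dm_a)
  dm_b <- as_dissimilarity(dm_b)
  if (nrow(dm_a) < 4) stop_config("need at least 4 labels")
  if (!identical(dim(dm_a), dim(dm_b)) ||
      !identical(rownames(dm_a), rownames(dm_b)))
    stop_config("matrices must share labels and order")
  a <- dm_a[lower.tri(dm_a)]
  b <- dm_b[lower.tri(dm_b)]
  if (length(unique(a)) == 1L || length(unique(b)) == 1L)
    stop_config("undefined correlation: constant lower triangle")
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  list(rho = unname(ct$estimate), p_subjectless = ct$p.value)
}

#' Group-level MDS reconstruction from per-subject gaze distances
#'
#' Scales each subject's fixation-distance matrix to unit mean off-diagonal
#' entry (removing subject-specific gaze dispersion), averages the scaled
#' matrices entrywise, and embeds the average with [classical_mds()].
#' Subjects contributing an all-zero matrix are skipped with a warning.
#'
#' @param matrices list of per-subject dissimilarity matrices sharing
#'   labels.
#' @param dims embedding dimensionality (default 2).
#' @return coordinates matrix from [classical_mds()].
#' @export
group_gaze_mds <- function(matrices, dims = 2L) {
  if (!length(matrices)) stop_config("no matrices supplied")
  labels <- rownames(matrices[[1]])
  scaled <- list()
  for (i in seq_along(matrices)) {
    m <- as_dissimilarity(matrices[[i]])
    if (!identical(rownames(m), labels))
      stop_config("matrix %d does not share the common labels", i)
    mu <- mean(m[lower.tri(m)])
    if (mu == 0) {
      warning(sprintf("subject %d has an all-zero distance matrix; skipped", i))
      next
    }
    scaled[[length(scaled) + 1L]] <- m / mu
  }
  if (!length(scaled)) stop_config("all subject matrices were zero")
  classical_mds(Reduce(`+`, scaled) / length(scaled), dims = dims)
}

#' Procrustes disparity between two embeddings
#'
#' Minimized normalized sum of squared differences after optimal
#' translation, uniform scaling and rotation/reflection of `b` onto `a`
#' (symmetric Procrustes), in `[0, 1]`.  Zero means the configurations are
#' identical up to a similarity transform.  Rows are matched by label when
#' both embeddings carry row names.
#'
#' @param a,b numeric coordinate matrices with the same dimensions.
#' @return the disparity.
#' @export
procrustes_disparity <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop_config("embeddings must share dimensions")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b)))
      stop_config("embeddings must share labels")
    b <- b[rownames(a), , drop = FALSE]
  }
  ssa <- sum(scale(a, scale = FALSE)^2)
  ssb <- sum(scale(b, scale = FALSE)^2)
  if (ssa < 1e-24 || ssb < 1e-24)
    stop_config("degenerate configuration: all points coincide")
  vegan::procrustes(a, b, symmetric = TRUE)$ss
}

#' Scatter plot of a 2D embedding
#'
#' Simple labeled scatter of an embedding (e.g. a reconstructed color
#' wheel or the average gaze position per concept).
#'
#' @param emb matrix of 2D coordinates with row names.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot_embedding <- function(emb, main = "", ...) {
  graphics::plot(emb[, 1], emb[, 2], pch = 19, xlab = "dim 1",
                 ylab = "dim 2", main = main, asp = 1, ...)
  graphics::text(emb[, 1], emb[, 2], labels = rownames(emb), pos = 3,
                 cex = 0.8)
}
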