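# Single-trial decoding of concepts from gaze coordinates: balanced
# leave-one-trial-out LDA with label-permutation significance.  Number
# sessions are decoded as small (1-6) vs large (7-12) from the horizontal
# coordinate alone; color sessions as all pairwise binary problems on the
# bidimensional coordinates.

#' Train-and-predict step of a two-class LDA
#'
#' Linear discriminant with pooled within-class covariance (ridge
#' `1e-6 * trace / d` added to the diagonal) and equal priors.  A test point
#' exactly on the boundary is assigned to the lexicographically smaller
#' label.
#'
#' @param train_features numeric matrix (n x d, d in 1..2) or vector.
#' @param train_labels vector with exactly two classes, both present.
#' @param test_feature length-d numeric vector.
#' @return the predicted label.
#' @export
lda_train_predict <- function(train_features, train_labels, test_feature) {
  X <- as.matrix(train_features)
  labs <- as.character(train_labels)
  classes <- sort(unique(labs))
  if (length(classes) != 2)
    stop_config("training data must contain exactly 2 classes (got %d)",
                length(classes))
  d <- ncol(X)
  i1 <- labs == classes[1]
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[!i1, , drop = FALSE])
  n1 <- sum(i1)
  n2 <- sum(!i1)
  if (d == 1L) {
    s2 <- (sum((X[i1, 1] - mu1)^2) + sum((X[!i1, 1] - mu2)^2)) /
      (n1 + n2 - 2)
    s2 <- s2 * (1 + 1e-6)
    if (s2 <= 0) {                       # coincident degenerate classes
      score <- abs(test_feature - mu2) - abs(test_feature - mu1)
      return(if (score > 0) classes[1] else if (score < 0) classes[2]
             else classes[1])
    }
    w <- (mu2 - mu1) / s2
    score <- w * (test_feature - (mu1 + mu2) / 2)
  } else {
    cv <- function(M, mu) crossprod(sweep(M, 2, mu))
    S <- (cv(X[i1, , drop = FALSE], mu1) + cv(X[!i1, , drop = FALSE], mu2)) /
      (n1 + n2 - 2)
    S <- S + diag(1e-6 * sum(diag(S)) / d, d)
    if (sum(diag(S)) <= 0) S <- diag(d)  # all points coincide
    w <- solve(S, mu2 - mu1)
    score <- sum(w * (as.numeric(test_feature) - (mu1 + mu2) / 2))
  }
  if (score > 0) classes[2] else classes[1]
}

# LOOCV with per-fold balancing, using the current RNG state (callers seed)
loocv_core <- function(X, labs) {
  n <- nrow(X)
  classes <- sort(unique(labs))
  correct <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    l <- labs[tr]
    n1 <- sum(l == classes[1])
    n2 <- length(l) - n1
    if (n1 != n2) {
      maj <- if (n1 > n2) classes[1] else classes[2]
      keep_min <- tr[l != maj]
      pool <- tr[l == maj]
      keep_maj <- pool[sample.int(length(pool), min(n1, n2))]
      tr <- c(keep_min, keep_maj)
    }
    pred <- lda_train_predict(X[tr, , drop = FALSE], labs[tr], X[i, ])
    correct[i] <- pred == labs[i]
  }
  mean(correct)
}

#' Balanced leave-one-trial-out LDA accuracy
#'
#' One fold per trial: the held-out trial is predicted from all remaining
#' trials, after the majority class in the training set is randomly
#' downsampled (without replacement) to the minority size so the two classes
#' are balanced in every fold.
#'
#' @param features numeric matrix (n x d) or vector of gaze coordinates.
#' @param labels two-class label vector; each class needs at least 2 trials.
#' @param seed integer seed for the balancing resamples.
#' @return observed accuracy: fraction of correctly predicted held-out
#'   trials.
#' @export
loocv_balanced_accuracy <- function(features, labels, seed = 1L) {
  X <- as.matrix(features)
  labs <- as.character(labels)
  if (nrow(X) != length(labs)) stop_config("features/labels length mismatch")
  tab <- table(labs)
  if (length(tab) != 2) stop_config("need exactly 2 classes")
  if (any(tab < 2))
    stop_config("each class needs at least 2 trials (got %s)",
                paste(tab, collapse = "/"))
  set.seed(seed)
  loocv_core(X, labs)
}

#' Label-permutation significance of the decoding accuracy
#'
#' Recomputes the balanced LOOCV accuracy `n_perm` times with independently
#' shuffled labels (balancing resampled afresh in every permutation) and
#' reports the fraction of permuted accuracies at least as large as the
#' observed one.
#'
#' @inheritParams loocv_balanced_accuracy
#' @param n_perm number of permutations (default 1000).
#' @param add_one use the `(count + 1) / (n_perm + 1)` estimator instead of
#'   the plain `count / n_perm`, avoiding exact-zero p-values.
#' @return object of class `decoding_result`: list with
#'   `observed_accuracy`, `permuted_accuracies`, `p_perm`, `n_trials`,
#'   `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(features, labels, n_perm = 1000L, seed = 1L,
                               add_one = FALSE) {
  if (!is_count(n_perm)) stop_config("n_perm must be a positive integer")
  X <- as.matrix(features)
  labs <- as.character(labels)
  tab <- table(labs)
  if (length(tab) != 2 || any(tab < 2))
    stop_config("need 2 classes with at least 2 trials each")
  set.seed(seed)
  observed <- loocv_core(X, labs)
  perm <- vapply(seq_len(n_perm),
                 function(k) loocv_core(X, sample(labs)), numeric(1))
  count <- sum(perm >= observed)
  p <- if (add_one) (count + 1) / (n_perm + 1) else count / n_perm
  structure(list(observed_accuracy = observed, permuted_accuracies = perm,
                 p_perm = p, n_trials = nrow(X), n_perm = n_perm,
                 seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("LOOCV decoding: accuracy = %.3f (n = %d), permutation p = %.4g (%d permutations)\n",
              x$observed_accuracy, x$n_trials, x$p_perm, x$n_perm))
  invisible(x)
}

#' Small (1-6) vs large (7-12) labels for number trials
#'
#' @param words number words (coercible to integers 1..12).
#' @return character vector `"small"` / `"large"`; numbers up to and
#'   including 6 are small.
#' @export
small_large_labels <- function(words) {
  v <- suppressWarnings(as.numeric(words))
  if (anyNA(v)) stop_config("non-numeric number words")
  ifelse(v <= 6, "small", "large")
}

#' All-pairs color decoding matrix
#'
#' Runs the balanced LOOCV LDA on the bidimensional gaze coordinates for
#' every unordered pair of concepts and mirrors the accuracy into a
#' symmetric matrix; the overall accuracy is the mean of the strictly lower
#' triangle.  Pairs with fewer than 2 valid trials for either concept are
#' left undefined (`NA`) with a warning.
#'
#' @param trials a trial table from [window_median_gaze()].
#' @param seed integer seed.
#' @return object of class `accuracy_matrix`: the labeled symmetric matrix
#'   with attribute `overall`.
#' @export
pairwise_color_decoding <- function(trials, seed = 1L) {
  t_ok <- trials[trials$valid, , drop = FALSE]
  labels <- sort(unique(t_ok$word))
  k <- length(labels)
  if (k < 2) stop_config("need at least 2 decodable concepts")
  acc <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  set.seed(seed)
  skipped <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sel <- t_ok$word %in% labels[c(i, j)]
      tab <- table(t_ok$word[sel])
      if (length(tab) < 2 || any(tab < 2)) {
        skipped <- skipped + 1L
        next
      }
      a <- loocv_core(cbind(t_ok$median_x_px[sel], t_ok$median_y_px[sel]),
                      t_ok$word[sel])
      acc[i, j] <- acc[j, i] <- a
    }
  }
  if (skipped > 0)
    warning(sprintf("%d pair(s) had too few trials and were left undefined",
                    skipped))
  lt <- acc[lower.tri(acc)]
  if (all(is.na(lt))) stop_config("no decodable pairs")
  acc <- (acc + t(acc)) / 2
  structure(acc, overall = mean(lt, na.rm = TRUE),
            class = c("accuracy_matrix", "matrix"))
}

#' Relate pairwise decoding accuracy to conceptual distance
#'
#' Spearman correlation and OLS slope of the lower-triangle pairwise
#' accuracies on the corresponding conceptual distances.
#'
#' @param acc an [pairwise_color_decoding()] accuracy matrix.
#' @param dm dissimilarity matrix with the same labels.
#' @return list with `rho` and `slope`.
#' @export
accuracy_vs_distance <- function(acc, dm) {
  dm <- as_dissimilarity(dm)
  if (!setequal(rownames(acc), rownames(dm)))
    stop_config("accuracy and distance matrices must share labels")
  dm <- dm[rownames(acc), rownames(acc)]
  a <- acc[lower.tri(acc)]
  d <- dm[lower.tri(dm)]
  ok <- !is.na(a)
  if (sum(ok) < 4) stop_config("need at least 4 defined pairs")
  a <- a[ok]
  d <- d[ok]
  if (length(unique(a)) == 1L)
    stop_config("undefined correlation: constant accuracies")
  list(rho = spearman_rho(a, d), slope = unname(coef(lm(a ~ d))[2]))
}
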