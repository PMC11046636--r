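# Conceptual change/distance series under the distance models used in the
# analyses: signed numeric change on the mental number line, Euclidean
# distance in a subject-specific MDS color space, and several distance
# models over animal words (embedding cosine, semantic cluster jumps,
# external similarity matrices, first-principal-component projection, and
# word-frequency differences).

# within-block consecutive transitions of a word sequence; returns indices
# of the "from" and "to" trials in utterance order
transition_pairs <- function(words, block = NULL,
                             trial = seq_along(words)) {
  n <- length(words)
  if (is.null(block)) block <- rep(1L, n)
  if (n < 2) return(list(from = integer(), to = integer()))
  a <- seq_len(n - 1)
  keep <- block[a] == block[a + 1L]
  list(from = trial[a][keep], to = trial[a + 1L][keep])
}

change_series <- function(model, from, to, value) {
  data.frame(model = model, from_trial = from, to_trial = to, value = value,
             stringsAsFactors = FALSE)
}

#' Signed trial-to-trial change in generated numbers
#'
#' `value_t = n_{t+1} - n_t`: negative when the next number is smaller,
#' positive when larger; the absolute value is the distance along the mental
#' number line.
#'
#' @param words character (or numeric) sequence of generated number words,
#'   each parsing as an integer 1..12.
#' @param block optional block id per word; transitions never span blocks.
#' @param trial optional trial ids used for alignment with a displacement
#'   series (defaults to utterance order).
#' @return a concept-change data frame (`model`, `from_trial`, `to_trial`,
#'   `value`).
#' @export
signed_number_change <- function(words, block = NULL,
                                 trial = seq_along(words)) {
  v <- suppressWarnings(as.numeric(words))
  bad <- !is.finite(v) | v != round(v) | v < 1 | v > 12
  if (any(bad))
    stop_config("words not parseable as integers 1..12: %s",
                paste(unique(words[bad]), collapse = ", "))
  tp <- transition_pairs(words, block, trial)
  idx <- match(tp$from, trial)
  jdx <- match(tp$to, trial)
  change_series("number_signed", tp$from, tp$to, v[jdx] - v[idx])
}

#' Dissimilarity matrix from 1-to-9 similarity judgments
#'
#' Averages the ratings of each unordered pair across repetitions and
#' presentation orders and maps them to dissimilarities as
#' `10 - mean rating`, so a pair always rated 9 (maximally similar) gets
#' dissimilarity 1 and a pair rated 1 gets 9.  The diagonal is zero.
#'
#' @param table data frame with columns `word_a`, `word_b`, `rating`
#'   (1..9); extra columns (subject, day) are ignored.
#' @param labels optional label order of the output matrix; defaults to the
#'   sorted union of the rated words.
#' @return a symmetric, zero-diagonal dissimilarity matrix with dimnames.
#' @export
dissimilarity_from_judgments <- function(table, labels = NULL) {
  need <- c("word_a", "word_b", "rating")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_config("judgments need columns %s", paste(need, collapse = ", "))
  if (any(table$rating < 1 | table$rating > 9))
    stop_config("ratings must lie in 1..9")
  if (is.null(labels))
    labels <- sort(unique(c(table$word_a, table$word_b)))
  k <- length(labels)
  a <- pmin(match(table$word_a, labels), match(table$word_b, labels))
  b <- pmax(match(table$word_a, labels), match(table$word_b, labels))
  if (anyNA(a) || anyNA(b))
    stop_config("judgment table contains words outside the label set")
  mean_r <- tapply(table$rating, paste(a, b), mean)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  want <- combn(k, 2)
  key <- paste(want[1, ], want[2, ])
  missing <- key[!key %in% names(mean_r)]
  if (length(missing))
    stop_config("unrated pairs: %s",
                paste(vapply(strsplit(missing, " "), function(ij)
                  paste(labels[as.integer(ij)], collapse = "-"),
                  character(1)), collapse = ", "))
  m[cbind(want[1, ], want[2, ])] <- 10 - mean_r[key]
  m[cbind(want[2, ], want[1, ])] <- 10 - mean_r[key]
  as_dissimilarity(m)
}

#' Validate a dissimilarity matrix
#'
#' @param m square numeric matrix; must be symmetric, finite, non-negative
#'   and zero on the diagonal.
#' @return the matrix, invisibly validated.
#' @export
as_dissimilarity <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || any(!is.finite(m)) ||
      !isTRUE(all.equal(m, t(m), check.attributes = FALSE)) ||
      any(diag(m) != 0) || any(m < 0))
    stop_config("not a valid dissimilarity matrix (symmetric, finite, non-negative, zero diagonal)")
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and builds
#' coordinates from the top `dims` non-negative eigenvalues.  Negative
#' eigenvalues (non-Euclidean noise) are clipped to zero; if fewer than
#' `dims` positive eigenvalues exist the missing columns are zero-padded
#' with a warning.  The output is column-centered and defined only up to
#' rotation/reflection.
#'
#' @param dm dissimilarity matrix (see [as_dissimilarity()]).
#' @param dims number of output dimensions (default 2).
#' @return numeric matrix of coordinates (labels x dims).
#' @export
classical_mds <- function(dm, dims = 2L) {
  dm <- as_dissimilarity(dm)
  if (!is_count(dims)) stop_config("dims must be a positive integer")
  n <- nrow(dm)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% dm^2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-12 & ev > 0)
  if (length(pos) < dims)
    warning(sprintf("only %d positive eigenvalue(s); padding %d dimension(s) with zeros",
                    length(pos), dims - length(pos)))
  take <- pos[seq_len(min(dims, length(pos)))]
  coords <- matrix(0, n, dims)
  if (length(take))
    coords[, seq_along(take)] <- e$vectors[, take, drop = FALSE] %*%
      diag(sqrt(ev[take]), length(take))
  coords <- sweep(coords, 2, colMeans(coords))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("dim", seq_len(dims))
  coords
}

#' Euclidean distances between consecutive words in an embedding
#'
#' @param words word sequence; every word must appear among the embedding's
#'   row labels.
#' @param emb numeric matrix of coordinates with row names (e.g. a
#'   subject-specific MDS color space).
#' @inheritParams signed_number_change
#' @return a concept-change data frame of non-negative distances.
#' @export
mds_distance_series <- function(words, emb, block = NULL,
                                trial = seq_along(words)) {
  if (is.null(rownames(emb)))
    stop_config("embedding must have row names")
  miss <- setdiff(unique(words), rownames(emb))
  if (length(miss))
    stop_config("words missing from embedding: %s",
                paste(miss, collapse = ", "))
  tp <- transition_pairs(words, block, trial)
  idx <- match(tp$from, trial)
  jdx <- match(tp$to, trial)
  a <- emb[words[idx], , drop = FALSE]
  b <- emb[words[jdx], , drop = FALSE]
  change_series("mds_distance", tp$from, tp$to, sqrt(rowSums((a - b)^2)))
}

#' Distance series over animal words under a named model
#'
#' Models:
#' * `cosine`: cosine distance between the words' embedding vectors;
#' * `cluster`: 1 when the two words share no semantic cluster label
#'   (a jump to a new cluster), else 0; with `graded = TRUE` the number of
#'   shared labels is emitted instead of the binary code;
#' * `external_similarity`: `10 - similarity` read from an external 1..9
#'   similarity matrix;
#' * `pc1`: absolute difference of the words' projections on the first
#'   principal component of the embedding (see [pc1_projection()]);
#' * `frequency`: unsigned difference of the words' frequency values,
#'   used exactly as supplied (no log transform).
#'
#' @param words animal word sequence.
#' @param model one of `"cosine"`, `"cluster"`, `"external_similarity"`,
#'   `"pc1"`, `"frequency"`.
#' @param resources model-specific tables: `vectors` (matrix, row names =
#'   words) for `cosine`/`pc1`; `clusters` (data frame `word`, `label`,
#'   multi-label via repeated rows) for `cluster`; `similarity` (labeled
#'   matrix of 1..9 scores) for `external_similarity`; `frequency` (named
#'   numeric vector or data frame `word`, `frequency`) for `frequency`.
#' @param graded emit shared-label counts instead of the binary cluster
#'   jump code.
#' @inheritParams signed_number_change
#' @return a concept-change data frame.
#' @export
animal_distance_series <- function(words,
                                   model = c("cosine", "cluster",
                                             "external_similarity", "pc1",
                                             "frequency"),
                                   resources, block = NULL,
                                   trial = seq_along(words),
                                   graded = FALSE) {
  model <- match.arg(model)
  tp <- transition_pairs(words, block, trial)
  idx <- match(tp$from, trial)
  jdx <- match(tp$to, trial)
  wa <- words[idx]
  wb <- words[jdx]
  uw <- unique(words)

  value <- switch(model,
    cosine = {
      v <- resources$vectors
      check_words(uw, rownames(v), "embedding")
      nrm <- sqrt(rowSums(v^2))
      if (any(nrm[uw] == 0))
        stop_config("zero-norm vector(s): %s",
                    paste(uw[nrm[uw] == 0], collapse = ", "))
      num <- rowSums(v[wa, , drop = FALSE] * v[wb, , drop = FALSE])
      1 - num / (nrm[wa] * nrm[wb])
    },
    cluster = {
      cl <- resources$clusters
      check_words(uw, unique(cl$word), "cluster table")
      labs <- split(as.character(cl$label), cl$word)
      shared <- mapply(function(a, b) length(intersect(labs[[a]], labs[[b]])),
                       wa, wb)
      if (graded) as.numeric(shared) else as.numeric(shared == 0)
    },
    external_similarity = {
      s <- resources$similarity
      check_words(uw, rownames(s), "similarity matrix")
      10 - s[cbind(wa, wb)]
    },
    pc1 = {
      proj <- pc1_projection(resources$vectors)
      check_words(uw, names(proj), "embedding")
      abs(proj[wb] - proj[wa])
    },
    frequency = {
      f <- resources$frequency
      if (is.data.frame(f)) f <- setNames(f$frequency, f$word)
      check_words(uw, names(f), "frequency table")
      abs(f[wb] - f[wa])
    })
  change_series(model, tp$from, tp$to, as.numeric(value))
}

check_words <- function(words, known, what) {
  miss <- setdiff(words, known)
  if (length(miss))
    stop_config("words missing from %s: %s", what,
                paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Projection onto the first principal component
#'
#' Centers the columns (no scaling) and projects every word onto the leading
#' principal axis of the embedding.  The sign of the projection is
#' arbitrary; distances along it are not.
#'
#' @param vectors numeric matrix, one row per word (row names required).
#' @return named numeric vector of PC1 scores.
#' @export
pc1_projection <- function(vectors) {
  v <- as.matrix(vectors)
  if (nrow(v) < 2) stop_config("need at least 2 labels")
  if (is.null(rownames(v))) stop_config("vectors must have row names")
  if (all(apply(v, 2, function(col) length(unique(col)) == 1L)))
    stop_config("constant data: no principal axis")
  p <- prcomp(v, center = TRUE, scale. = FALSE)
  setNames(p$x[, 1], rownames(v))
}

#' Transition-frequency control series
#'
#' Annotates each within-block transition with the number of times that
#' ordered word pair occurs across all of the subject's blocks, for use as
#' a control covariate.
#'
#' @inheritParams signed_number_change
#' @return a concept-change data frame of positive counts.
#' @export
transition_count_series <- function(words, block = NULL,
                                    trial = seq_along(words)) {
  tp <- transition_pairs(words, block, trial)
  idx <- match(tp$from, trial)
  jdx <- match(tp$to, trial)
  key <- paste(words[idx], words[jdx], sep = "\r")
  counts <- table(key)
  change_series("transition_count", tp$from, tp$to,
                as.numeric(counts[key]))
}
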