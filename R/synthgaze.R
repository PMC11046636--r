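# Synthetic verbal-fluency sessions with a known embedded conceptual geometry.
#
# The generator emulates the structure of a metronome-paced word-generation
# block recorded with a screen-based eye tracker: words are produced at a
# fixed pace, and in the short window before each utterance the gaze settles
# around a screen position that is an affine image of the concept's latent
# coordinate.  Between windows the gaze follows a bounded random walk.
# Everything is seeded so downstream stages can be tested against ground
# truth.

#' Latent conceptual geometry for a 12-item vocabulary
#'
#' Builds the latent coordinates that a synthetic session embeds in gaze:
#' the integers 1..12 for the number line, 12 equally spaced points on the
#' unit circle for the color wheel, and a log-uniform (Zipf-like) lexical
#' frequency value per word for the animal domain.
#'
#' @param domain one of `"number"`, `"color"`, `"animal"`.
#' @param labels optional character vector of 12 unique concept names;
#'   defaults to `"1".."12"`, the 12 color terms of the color-wheel task,
#'   or 12 common animal names.
#' @param freq_range for the animal domain, range (per-million counts) of the
#'   log-uniform distribution the frequency values are drawn from.
#' @param seed integer seed used only for the animal frequency draw.
#' @return an object of class `latent_geometry`: a list with `domain`,
#'   `labels`, `coords` (12 x 2 matrix of latent coordinates, second column
#'   zero for 1D domains) and, for 1D domains, `values` (named scalar per
#'   label: the integer value or the frequency).
#' @export
make_geometry <- function(domain = c("number", "color", "animal"),
                          labels = NULL, freq_range = c(0.5, 500),
                          seed = 1L) {
  domain <- match.arg(domain)
  default_labels <- switch(domain,
    number = as.character(1:12),
    color  = c("red", "orange", "yellow", "lime", "green", "turquoise",
               "cyan", "blue", "violet", "lilac", "pink", "magenta"),
    animal = c("dog", "cat", "horse", "cow", "lion", "tiger", "elephant",
               "giraffe", "eagle", "shark", "whale", "ant"))
  if (is.null(labels)) labels <- default_labels
  if (length(labels) != 12L || anyDuplicated(labels))
    stop_config("a latent geometry needs 12 unique labels")
  if (domain == "number") {
    values <- setNames(1:12, labels)
    coords <- cbind(as.numeric(values), 0)
  } else if (domain == "color") {
    theta <- 2 * pi * (0:11) / 12
    values <- NULL
    coords <- cbind(cos(theta), sin(theta))
  } else {
    if (freq_range[1] <= 0 || freq_range[2] <= freq_range[1])
      stop_config("freq_range must be positive and increasing")
    set.seed(seed)
    values <- setNames(exp(runif(12, log(freq_range[1]), log(freq_range[2]))),
                       labels)
    coords <- cbind(as.numeric(values), 0)
  }
  rownames(coords) <- labels
  colnames(coords) <- c("lat_1", "lat_2")
  structure(list(domain = domain, labels = labels, coords = coords,
                 values = values),
            class = "latent_geometry")
}

#' Affine latent-to-screen map
#'
#' Convenience constructor for the 2 x 2 matrix plus offset that places the
#' (coupling-scaled) latent coordinate on the screen.  For the color wheel a
#' random subject-specific rotation/reflection can be drawn, since the wheel
#' is defined only up to isometry.
#'
#' @param scale multiplicative factor applied on top of the session coupling.
#' @param angle rotation angle in radians.
#' @param reflect reflect the first axis before rotating.
#' @param center screen offset in pixels (where a zero latent coordinate
#'   lands); defaults to the center of a 1920 x 1080 display.
#' @return list with elements `A` (2 x 2 matrix) and `b` (length-2 offset).
#' @export
make_affine <- function(scale = 1, angle = 0, reflect = FALSE,
                        center = c(960, 540)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  if (reflect) R <- R %*% diag(c(-1, 1))
  list(A = scale * R, b = as.numeric(center))
}

#' Session configuration for the synthetic generator
#'
#' @param domain conceptual domain, matching the geometry the session embeds.
#' @param n_trials words generated per block.
#' @param n_blocks number of blocks; transitions never span block boundaries.
#' @param pace_hz word-generation pace (words per second); the metronome pace
#'   of the task is 0.75 Hz, i.e. one word every 1333 ms.
#' @param sample_rate_hz eye-tracker sampling rate (Hz); the recording setup
#'   samples at 1000 Hz.
#' @param coupling pixels of gaze displacement per unit latent coordinate;
#'   `0` embeds no geometry (null sessions).
#' @param noise_sd trial-level fixation scatter (px): each pre-onset window is
#'   displaced from its latent target by a Gaussian offset with this SD (plus
#'   small within-window sample jitter, SD `noise_sd / 4`).
#' @param drift_sd random-walk step SD (px per sample) outside windows.
#' @param dropout_rate expected fraction of samples lost to blinks/track loss
#'   (applied by [inject_dropouts()] when > 0).
#' @param affine latent-to-screen map, see [make_affine()].
#' @param screen `c(width, height)` in pixels.
#' @param window_ms length of the pre-onset window the gaze settles in.
#' @param no_repeat disallow immediate word repetitions (default off: the
#'   task permits them).
#' @param subject subject identifier written into the event table.
#' @param seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @return an object of class `session_config`.
#' @export
session_config <- function(domain = c("number", "color", "animal"),
                           n_trials = 90L, n_blocks = 1L, pace_hz = 0.75,
                           sample_rate_hz = 1000, coupling = 10,
                           noise_sd = 40, drift_sd = 1, dropout_rate = 0,
                           affine = make_affine(), screen = c(1920, 1080),
                           window_ms = 500, no_repeat = FALSE,
                           subject = "s01", seed = 1L) {
  domain <- match.arg(domain)
  if (!is_count(n_trials) || !is_count(n_blocks))
    stop_config("n_trials and n_blocks must be positive integers")
  if (pace_hz <= 0 || sample_rate_hz <= 0)
    stop_config("pace_hz and sample_rate_hz must be positive")
  if (coupling < 0 || noise_sd < 0 || drift_sd < 0)
    stop_config("coupling, noise_sd and drift_sd must be non-negative")
  if (!is_prob(dropout_rate))
    stop_config("dropout_rate must lie in [0, 1]")
  if (!is.list(affine) || !all(c("A", "b") %in% names(affine)) ||
      !all(dim(affine$A) == c(2, 2)) || length(affine$b) != 2)
    stop_config("affine must be a list with a 2x2 matrix A and length-2 b")
  if (coupling > 0 && abs(det(affine$A)) < 1e-12)
    stop_config("affine matrix is singular but coupling is positive")
  if (window_ms <= 0) stop_config("window_ms must be positive")
  structure(list(domain = domain, n_trials = as.integer(n_trials),
                 n_blocks = as.integer(n_blocks), pace_hz = pace_hz,
                 sample_rate_hz = sample_rate_hz, coupling = coupling,
                 noise_sd = noise_sd, drift_sd = drift_sd,
                 dropout_rate = dropout_rate, affine = affine,
                 screen = as.numeric(screen), window_ms = window_ms,
                 no_repeat = isTRUE(no_repeat), subject = subject,
                 seed = as.integer(seed)),
            class = "session_config")
}

# word sequence for one block (uniform over the vocabulary)
sample_words <- function(k, n, no_repeat) {
  idx <- sample.int(k, n, replace = TRUE)
  if (no_repeat && n > 1) {
    for (i in 2:n) {
      while (idx[i] == idx[i - 1]) idx[i] <- sample.int(k, 1)
    }
  }
  idx
}

# per-trial 2D latent coordinate; for animals the embedded effect couples
# gaze to the unsigned between-trial frequency difference (normalized to
# [0, 1] by the largest pairwise difference), first trial at zero.
trial_latents <- function(geometry, idx) {
  if (geometry$domain == "animal") {
    f <- as.numeric(geometry$values[idx])
    dmax <- diff(range(geometry$values))
    cbind(c(0, abs(diff(f))) / dmax, 0)
  } else {
    geometry$coords[idx, , drop = FALSE]
  }
}

#' Generate one synthetic eye-tracking session
#'
#' Produces a gaze recording, a word-event table and the per-trial latent
#' ground truth for a seeded verbal-fluency session.  Word onsets are spaced
#' `1 / pace_hz` seconds apart.  In the `window_ms` window preceding each
#' onset, gaze samples scatter around the affine image of
#' `coupling * latent coordinate` (trial-level Gaussian offset `noise_sd`
#' plus within-window jitter); everywhere else the gaze follows a bounded
#' random walk with per-sample step SD `drift_sd`, clipped to the screen.
#'
#' @param config a [session_config()]; its `domain` must match `geometry`.
#' @param geometry a [make_geometry()] object.
#' @return list with elements `gaze` (data frame `time_ms`, `x_px`, `y_px`,
#'   `valid`), `events` (data frame `subject`, `block`, `word`, `onset_ms`,
#'   `offset_ms`) and `truth` (data frame `trial`, `block`, `word`, `lat_1`,
#'   `lat_2`).
#' @export
generate_session <- function(config, geometry) {
  if (!inherits(config, "session_config"))
    stop_config("config must be a session_config")
  if (!inherits(geometry, "latent_geometry"))
    stop_config("geometry must be a latent_geometry")
  if (config$domain != geometry$domain)
    stop_config("config domain '%s' does not match geometry domain '%s'",
                config$domain, geometry$domain)

  set.seed(config$seed)
  k <- length(geometry$labels)
  dt <- 1000 / config$sample_rate_hz
  iti <- 1000 / config$pace_hz
  lead_in <- config$window_ms + iti
  n <- config$n_trials

  gaze_blocks <- vector("list", config$n_blocks)
  event_blocks <- vector("list", config$n_blocks)
  truth_blocks <- vector("list", config$n_blocks)
  t0 <- 0

  for (b in seq_len(config$n_blocks)) {
    idx <- sample_words(k, n, config$no_repeat)
    words <- geometry$labels[idx]
    lat <- trial_latents(geometry, idx)
    targets <- t(config$affine$A %*% (config$coupling * t(lat)) +
                   config$affine$b)

    onsets <- t0 + lead_in + (seq_len(n) - 1) * iti
    offsets <- onsets + min(400, iti / 2)
    t_end <- max(offsets) + iti
    time_ms <- seq(t0, t_end, by = dt)
    m <- length(time_ms)

    # window membership: trial index per sample, 0 = free-viewing walk
    win_of <- integer(m)
    for (tr in seq_len(n)) {
      ids <- which(time_ms >= onsets[tr] - config$window_ms &
                     time_ms < onsets[tr])
      win_of[ids] <- tr
    }

    eta <- matrix(rnorm(2 * n, 0, config$noise_sd), n, 2)
    x <- numeric(m)
    y <- numeric(m)
    in_win <- win_of > 0
    nwin <- sum(in_win)
    jit <- matrix(rnorm(2 * nwin, 0, config$noise_sd / 4), nwin, 2)
    x[in_win] <- targets[win_of[in_win], 1] + eta[win_of[in_win], 1] +
      jit[, 1]
    y[in_win] <- targets[win_of[in_win], 2] + eta[win_of[in_win], 2] +
      jit[, 2]

    # bounded random walk over the free-viewing segments, re-anchored at the
    # last sample of the preceding window
    csx <- cumsum(rnorm(m, 0, config$drift_sd))
    csy <- cumsum(rnorm(m, 0, config$drift_sd))
    runs <- rle(in_win)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in seq_along(runs$lengths)) {
      if (runs$values[r]) next
      s <- starts[r]
      e <- ends[r]
      anchor <- if (s == 1L) config$screen / 2 else c(x[s - 1L], y[s - 1L])
      base <- if (s == 1L) c(0, 0) else c(csx[s - 1L], csy[s - 1L])
      x[s:e] <- anchor[1] + csx[s:e] - base[1]
      y[s:e] <- anchor[2] + csy[s:e] - base[2]
    }

    x <- pmin(pmax(x, 0), config$screen[1])
    y <- pmin(pmax(y, 0), config$screen[2])

    gaze_blocks[[b]] <- data.frame(time_ms = time_ms, x_px = x, y_px = y,
                                   valid = TRUE)
    event_blocks[[b]] <- data.frame(subject = config$subject, block = b,
                                    word = words, onset_ms = onsets,
                                    offset_ms = offsets,
                                    stringsAsFactors = FALSE)
    truth_blocks[[b]] <- data.frame(trial = (b - 1L) * n + seq_len(n),
                                    block = b, word = words,
                                    lat_1 = lat[, 1], lat_2 = lat[, 2],
                                    stringsAsFactors = FALSE)
    t0 <- t_end + 2 * iti
  }

  rec <- gaze_recording(do.call(rbind, gaze_blocks))
  out <- list(gaze = rec,
              events = do.call(rbind, event_blocks),
              truth = do.call(rbind, truth_blocks))
  if (config$dropout_rate > 0)
    out$gaze <- inject_dropouts(out$gaze, config$dropout_rate,
                                mean_len_ms = 100,
                                seed = config$seed + 1L,
                                sample_rate_hz = config$sample_rate_hz)
  out
}

#' Synthetic pairwise similarity judgments over a latent ring
#'
#' Emulates a 1-to-9 similarity-rating task over a 2D geometry: each
#' unordered pair is rated in both presentation orders per repetition, with
#' `rating = clip(round(9 - 8 * d / d_max + e), 1, 9)` where `d` is the
#' latent Euclidean distance, `d_max` the largest pairwise distance, and
#' `e ~ N(0, noise_sd)` drawn independently per emission.
#'
#' @param geometry a 2D [make_geometry()] object (color domain).
#' @param noise_sd rating noise SD on the 1..9 scale.
#' @param n_reps repetitions (sessions/days) of the full pair list.
#' @param seed integer seed.
#' @param subject subject identifier.
#' @return data frame with columns `subject`, `day`, `word_a`, `word_b`,
#'   `rating`.
#' @export
generate_similarity_judgments <- function(geometry, noise_sd = 0.5,
                                          n_reps = 2L, seed = 1L,
                                          subject = "s01") {
  if (!inherits(geometry, "latent_geometry") || geometry$domain != "color")
    stop_config("similarity judgments need a 2D (color) geometry")
  if (!is_count(n_reps)) stop_config("n_reps must be a positive integer")
  set.seed(seed)
  d <- as.matrix(dist(geometry$coords))
  dmax <- max(d)
  pairs <- t(combn(geometry$labels, 2))
  out <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    both <- rbind(pairs, pairs[, 2:1])
    dd <- d[both]
    rating <- round(9 - 8 * dd / dmax + rnorm(nrow(both), 0, noise_sd))
    out[[rep]] <- data.frame(subject = subject, day = rep,
                             word_a = both[, 1], word_b = both[, 2],
                             rating = pmin(pmax(rating, 1), 9),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mark contiguous runs of samples as lost
#'
#' Emulates blinks and out-of-range track loss: contiguous runs of samples
#' are flagged invalid so that the expected invalid fraction approximates
#' `rate`, using a two-state Markov process with mean invalid run length
#' `mean_len_ms`.  Timestamps and coordinates are unchanged.
#'
#' @param rec a gaze recording data frame.
#' @param rate target invalid fraction in `[0, 1]`.
#' @param mean_len_ms mean length of an invalid run, in ms.
#' @param seed integer seed.
#' @param sample_rate_hz sampling rate used to convert `mean_len_ms` to
#'   samples; inferred from the median timestamp step when `NULL`.
#' @return the recording with its `valid` column updated.
#' @export
inject_dropouts <- function(rec, rate, mean_len_ms = 100, seed = 1L,
                            sample_rate_hz = NULL) {
  rec <- gaze_recording(rec)
  if (!is_prob(rate)) stop_config("rate must lie in [0, 1]")
  if (mean_len_ms <= 0) stop_config("mean_len_ms must be positive")
  m <- nrow(rec)
  if (rate == 0 || m == 0L) return(rec)
  if (rate == 1) {
    rec$valid <- FALSE
    return(rec)
  }
  if (is.null(sample_rate_hz))
    sample_rate_hz <- 1000 / median(diff(rec$time_ms))
  len_bad <- max(1, mean_len_ms * sample_rate_hz / 1000)
  len_good <- max(1, len_bad * (1 - rate) / rate)
  set.seed(seed)
  bad <- logical(m)
  state <- runif(1) < rate
  i <- 1L
  while (i <= m) {
    run <- 1L + rgeom(1L, 1 / (if (state) len_bad else len_good))
    j <- min(m, i + run - 1L)
    if (state) bad[i:j] <- TRUE
    i <- j + 1L
    state <- !state
  }
  rec$valid <- rec$valid & !bad
  rec
}
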