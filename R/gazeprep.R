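# Raw gaze samples + word events -> per-trial medians and displacement
# series.  The only preprocessing is exclusion of invalid samples: no
# filtering, smoothing, interpolation or detrending is applied, so the
# analyses run on raw spontaneous gaze behavior.

#' Validate a gaze recording table
#'
#' A gaze recording is a data frame with strictly increasing `time_ms`,
#' screen coordinates `x_px`/`y_px` (origin top-left, y increasing downward)
#' and a logical/0-1 `valid` flag.
#'
#' @param df data frame to validate.
#' @return the validated data frame (with `valid` coerced to logical).
#' @export
gaze_recording <- function(df) {
  need <- c("time_ms", "x_px", "y_px", "valid")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop_config("gaze recording needs columns %s", paste(need, collapse = ", "))
  df$valid <- as.logical(df$valid)
  if (nrow(df) > 1 && any(diff(df$time_ms) <= 0))
    stop_config("gaze timestamps must be strictly increasing")
  if (any(!is.finite(df$x_px[df$valid])) || any(!is.finite(df$y_px[df$valid])))
    stop_config("valid gaze samples must have finite coordinates")
  df
}

#' Drop invalid samples from a recording
#'
#' Removes samples where the tracker signal was unavailable (blinks,
#' out-of-range gaze).  No other transformation is applied.
#'
#' @param rec a gaze recording.
#' @return the recording restricted to valid samples.
#' @export
clean_recording <- function(rec) {
  rec <- gaze_recording(rec)
  rec[rec$valid, , drop = FALSE]
}

#' Median gaze position in the pre-onset window of each word
#'
#' For each word event, takes the median of the valid gaze samples whose
#' timestamps fall in the half-open window `[onset - window_ms, onset)` —
#' strictly before the word is pronounced.  A trial with fewer than
#' `min_samples` valid samples in its window is marked invalid and excluded
#' from downstream displacement series.
#'
#' @param rec a gaze recording.
#' @param events data frame of word events (`subject`, `block`, `word`,
#'   `onset_ms`, `offset_ms`), time-ordered within block.
#' @param window_ms window length in ms before each onset (default 500).
#' @param min_samples minimum valid samples for a usable trial (default 10,
#'   i.e. 10 ms of data at 1 kHz).
#' @return a trial table: one row per event with `subject`, `block`, `trial`,
#'   `word`, `median_x_px`, `median_y_px`, `n_valid_samples`, `valid`.
#' @export
window_median_gaze <- function(rec, events, window_ms = 500,
                               min_samples = 10L) {
  rec <- gaze_recording(rec)
  if (window_ms <= 0) stop_config("window_ms must be positive")
  need <- c("subject", "block", "word", "onset_ms", "offset_ms")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop_config("events needs columns %s", paste(need, collapse = ", "))
  if (any(events$onset_ms >= events$offset_ms))
    stop_config("event onsets must precede offsets")

  n <- nrow(events)
  mx <- my <- rep(NA_real_, n)
  nv <- integer(n)
  span <- range(rec$time_ms)
  out_of_span <- events$onset_ms <= span[1] |
    events$onset_ms - window_ms > span[2]
  if (any(out_of_span))
    warning(sprintf("%d event(s) fall outside the recording span",
                    sum(out_of_span)))
  for (i in seq_len(n)) {
    sel <- rec$valid & rec$time_ms >= events$onset_ms[i] - window_ms &
      rec$time_ms < events$onset_ms[i]
    nv[i] <- sum(sel)
    if (nv[i] > 0) {
      mx[i] <- median(rec$x_px[sel])
      my[i] <- median(rec$y_px[sel])
    }
  }
  data.frame(subject = events$subject, block = events$block,
             trial = seq_len(n), word = as.character(events$word),
             median_x_px = mx, median_y_px = my, n_valid_samples = nv,
             valid = nv >= min_samples, stringsAsFactors = FALSE)
}

#' Trial-to-trial gaze displacement series
#'
#' Differences the per-trial gaze medians between trials that are adjacent
#' in utterance order within a block: `dx`/`dy` are signed pixel changes and
#' `d2` their Euclidean combination.  A pair is dropped when either member
#' is invalid (no bridging across lost trials) and pairs never span block
#' boundaries.
#'
#' @param trials a trial table from [window_median_gaze()].
#' @return data frame with one row per kept transition: `block`,
#'   `from_trial`, `to_trial`, `dx`, `dy`, `d2`.
#' @export
displacement_series <- function(trials) {
  need <- c("block", "trial", "median_x_px", "median_y_px", "valid")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop_config("trials needs columns %s", paste(need, collapse = ", "))
  trials <- trials[order(trials$trial), , drop = FALSE]
  n <- nrow(trials)
  if (n < 2)
    return(data.frame(block = integer(), from_trial = integer(),
                      to_trial = integer(), dx = numeric(), dy = numeric(),
                      d2 = numeric()))
  a <- seq_len(n - 1)
  b <- a + 1L
  keep <- trials$valid[a] & trials$valid[b] &
    trials$block[a] == trials$block[b] &
    trials$trial[b] == trials$trial[a] + 1L
  dx <- trials$median_x_px[b] - trials$median_x_px[a]
  dy <- trials$median_y_px[b] - trials$median_y_px[a]
  data.frame(block = trials$block[a][keep],
             from_trial = trials$trial[a][keep],
             to_trial = trials$trial[b][keep],
             dx = dx[keep], dy = dy[keep],
             d2 = sqrt(dx[keep]^2 + dy[keep]^2))
}
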