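# Plain-text file contracts: gaze recordings as TSV, event/similarity/trial
# tables as CSV, embeddings in word2vec text format, labeled matrices as
# CSV with a label column, and seed sidecars as JSON.

#' Write / read a gaze recording as TSV
#'
#' Columns `time_ms`, `x_px`, `y_px`, `valid` (0/1).
#'
#' @param rec gaze recording data frame.
#' @param path file path.
#' @export
write_gaze_tsv <- function(rec, path) {
  rec <- gaze_recording(rec)
  rec$valid <- as.integer(rec$valid)
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  gaze_recording(read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a word-event table as CSV
#'
#' Columns `subject`, `block`, `word`, `onset_ms`, `offset_ms`.
#'
#' @param events event data frame.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  ev$word <- as.character(ev$word)
  ev
}

#' Read word vectors in word2vec text format
#'
#' Expects a header line `"n dim"` followed by one `"word v1 ... vdim"`
#' line per word.
#'
#' @param path file path.
#' @return numeric matrix with one row per word (row names = words).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop_config("malformed word2vec header: '%s'", lines[1])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(body) != hdr[1])
    stop_config("header announces %d words, file has %d", hdr[1],
                length(body))
  words <- vapply(body, `[`, character(1), 1)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(hdr[2])))
  rownames(vals) <- words
  vals
}

#' Write / read a labeled square matrix as CSV
#'
#' The first column holds the row labels; column names hold the same
#' labels.
#'
#' @param m labeled matrix.
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(label = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read an external similarity table into a matrix
#'
#' Reads per-pair 1..9 similarity scores (CSV columns `word_a`, `word_b`,
#' `rating`), averages repeated ratings of the same unordered pair, and
#' returns the symmetric similarity matrix (diagonal 9, the maximal score).
#'
#' @param path file path.
#' @return labeled symmetric similarity matrix.
#' @export
read_similarity_csv <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  labels <- sort(unique(c(tb$word_a, tb$word_b)))
  d <- dissimilarity_from_judgments(tb, labels = labels)
  s <- 10 - d
  diag(s) <- 9
  s
}

#' Read a word-frequency table (CSV columns `word`, `frequency`)
#'
#' @param path file path.
#' @return named numeric vector of frequencies.
#' @export
read_frequency_csv <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  setNames(as.numeric(tb$frequency), tb$word)
}

#' Read a cluster-label table (CSV columns `word`, `label`)
#'
#' Multi-label words appear as repeated rows.
#'
#' @param path file path.
#' @return data frame `word`, `label`.
#' @export
read_clusters_csv <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  tb[, c("word", "label")]
}

#' Record the seeds of a run in a JSON sidecar
#'
#' @param seeds named list/vector of integer seeds.
#' @param path file path.
#' @export
write_seed_sidecar <- function(seeds, path) {
  jsonlite::write_json(as.list(seeds), path, auto_unbox = TRUE, digits = NA)
}
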