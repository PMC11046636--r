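# Configuration-driven orchestration: simulate (or ingest) sessions, run
# the per-subject correlational analyses and group statistics end-to-end,
# and write tidy result tables with a hashed manifest.

#' Simulate one subject and reduce to a trial table
#'
#' Convenience wrapper chaining [generate_session()] and
#' [window_median_gaze()].
#'
#' @param config a [session_config()].
#' @param geometry a [make_geometry()].
#' @param min_samples minimum valid window samples per usable trial.
#' @return list with `trials`, `events`, `truth`, `gaze`.
#' @export
simulate_subject_trials <- function(config, geometry, min_samples = 10L) {
  ses <- generate_session(config, geometry)
  trials <- window_median_gaze(ses$gaze, ses$events,
                               window_ms = config$window_ms,
                               min_samples = min_samples)
  list(trials = trials, events = ses$events, truth = ses$truth,
       gaze = ses$gaze)
}

#' Per-subject condition correlations for a simulated cohort
#'
#' Simulates `n_subjects` independent sessions from a common configuration
#' template (each with its own derived seed), runs the full preprocessing
#' and correlation pipeline, and returns the tidy per-subject results.
#' Number cohorts use the signed number change, color cohorts the distance
#' in the true latent ring (the generating conceptual space).
#'
#' @param n_subjects cohort size.
#' @param config a [session_config()] template; its `seed` seeds the cohort.
#' @param geometry a [make_geometry()] matching the config domain.
#' @param axis,mode passed to [condition_correlation()].
#' @param min_samples passed to [window_median_gaze()].
#' @return data frame of [condition_correlation()] rows, one per subject.
#' @export
cohort_correlations <- function(n_subjects, config, geometry,
                                axis = "x_signed", mode = "combined",
                                min_samples = 10L) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- seeds[s]
    cfg$subject <- sprintf("s%02d", s)
    sim <- simulate_subject_trials(cfg, geometry, min_samples)
    disp <- displacement_series(sim$trials)
    change <- if (config$domain == "number") {
      signed_number_change(sim$trials$word, block = sim$trials$block,
                           trial = sim$trials$trial)
    } else if (config$domain == "color") {
      mds_distance_series(sim$trials$word, geometry$coords,
                          block = sim$trials$block,
                          trial = sim$trials$trial)
    } else {
      animal_distance_series(sim$trials$word, "frequency",
                             list(frequency = geometry$values),
                             block = sim$trials$block,
                             trial = sim$trials$trial)
    }
    out[[s]] <- condition_correlation(disp, change, axis = axis,
                                      mode = mode, subject = cfg$subject,
                                      condition = config$domain)
  }
  do.call(rbind, out)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; fields mirror the arguments of [run_pipeline()]'s
#'   config list.
#' @return the configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  fill_run_defaults(yaml::read_yaml(path))
}

fill_run_defaults <- function(config) {
  defaults <- list(mode = "simulate", conditions = c("number", "color"),
                   n_subjects = 8L, n_trials = 90L, n_blocks = 3L,
                   pace_hz = 0.75, sample_rate_hz = 1000, coupling = 10,
                   noise_sd = 40, drift_sd = 1, window_ms = 500,
                   min_samples = 10L, n_perm = 1000L, seed = 1L,
                   out_dir = "gazegeom-run", sessions = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Pre-flight validation of a run configuration
#'
#' Checks the configuration (and, in ingest mode, the referenced files and
#' their schemas) without running any analysis.  Issues are reported, not
#' raised.
#'
#' @param config configuration list (see [run_pipeline()]).
#' @return data frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when the configuration is clean.
#' @export
validate_inputs <- function(config) {
  config <- fill_run_defaults(config)
  issues <- list()
  add <- function(level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(level = level,
                                                 message = msg,
                                                 stringsAsFactors = FALSE)
  known <- c("number", "color", "animal")
  bad <- setdiff(config$conditions, known)
  if (length(bad))
    add("error", sprintf("unknown condition(s): %s", paste(bad, collapse = ", ")))
  if (!config$mode %in% c("simulate", "ingest"))
    add("error", sprintf("unknown mode '%s'", config$mode))
  if (config$mode == "ingest") {
    if (is.null(config$sessions) || !length(config$sessions)) {
      add("error", "ingest mode needs a 'sessions' list")
    } else {
      for (i in seq_along(config$sessions)) {
        ses <- config$sessions[[i]]
        for (f in c("gaze", "events")) {
          if (is.null(ses[[f]])) {
            add("error", sprintf("session %d: missing '%s' path", i, f))
          } else if (!file.exists(ses[[f]])) {
            add("error", sprintf("session %d: file not found: %s", i,
                                 ses[[f]]))
          }
        }
        if (!is.null(ses$gaze) && file.exists(ses$gaze) &&
            !is.null(ses$events) && file.exists(ses$events)) {
          rec <- tryCatch(read_gaze_tsv(ses$gaze), error = function(e) e)
          if (inherits(rec, "error")) {
            add("error", sprintf("session %d: %s", i,
                                 conditionMessage(rec)))
          } else {
            ev <- read_events_csv(ses$events)
            if (any(ev$onset_ms > max(rec$time_ms) |
                      ev$onset_ms < min(rec$time_ms)))
              add("warning",
                  sprintf("session %d: event onset(s) beyond gaze span", i))
          }
        }
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(level = character(), message = character())
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) sessions for the configured conditions, computes
#' per-subject correlations, group statistics, geometry reconstructions and
#' (for number sessions) small-vs-large decoding, and writes everything to
#' `out_dir` as tidy CSV/JSON files together with a content-hash manifest
#' and a seed sidecar.  Identical configurations yield identical manifest
#' hashes.
#'
#' @param config configuration list (see [read_run_config()] for the YAML
#'   form); recognized fields: `mode` (`"simulate"`/`"ingest"`),
#'   `conditions`, `n_subjects`, `n_trials`, `n_blocks`, `pace_hz`,
#'   `sample_rate_hz`, `coupling`, `noise_sd`, `drift_sd`, `window_ms`,
#'   `min_samples`, `n_perm` (0 disables decoding), `seed`, `out_dir`,
#'   `sessions` (ingest mode).
#' @return invisibly, a list with the per-subject correlation table, group
#'   statistics and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- fill_run_defaults(config)
  issues <- validate_inputs(config)
  if (any(issues$level == "error"))
    stop_config("invalid configuration:\n%s",
                paste(issues$message[issues$level == "error"],
                      collapse = "\n"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "simulate") {
    bundles <- simulate_bundles(config)
  } else {
    bundles <- ingest_bundles(config)
  }

  subject_rows <- list()
  group_stats <- list()
  extras <- list()

  for (condition in names(bundles)) {
    bundle <- bundles[[condition]]
    res <- analyze_condition(condition, bundle, config)
    subject_rows[[condition]] <- res$subject_rows
    group_stats[[condition]] <- res$group
    extras[[condition]] <- res$extra
  }

  subj <- do.call(rbind, unname(subject_rows))
  f_subj <- file.path(config$out_dir, "subject_correlations.csv")
  write.csv(subj, f_subj, row.names = FALSE, quote = FALSE)
  f_group <- file.path(config$out_dir, "group_stats.json")
  jsonlite::write_json(group_stats, f_group, auto_unbox = TRUE, digits = NA)
  files <- c(f_subj, f_group)

  for (condition in names(extras)) {
    for (nm in names(extras[[condition]])) {
      obj <- extras[[condition]][[nm]]
      f <- file.path(config$out_dir,
                     sprintf("%s_%s.%s", condition, nm,
                             if (is.matrix(obj)) "csv" else "json"))
      if (is.matrix(obj)) write_matrix_csv(obj, f)
      else jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
  }

  f_seed <- file.path(config$out_dir, "seeds.json")
  write_seed_sidecar(list(master = config$seed), f_seed)
  files <- c(files, f_seed)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(list(subject_correlations = subj, group_stats = group_stats,
                 manifest = manifest))
}

# simulate trial tables (+ conceptual resources) for each condition
simulate_bundles <- function(config) {
  set.seed(config$seed)
  cond_seeds <- setNames(sample.int(.Machine$integer.max,
                                    length(config$conditions)),
                         config$conditions)
  bundles <- list()
  for (condition in config$conditions) {
    geometry <- make_geometry(condition, seed = cond_seeds[[condition]])
    set.seed(cond_seeds[[condition]])
    seeds <- sample.int(.Machine$integer.max, config$n_subjects)
    subjects <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      cfg <- session_config(domain = condition, n_trials = config$n_trials,
                            n_blocks = config$n_blocks,
                            pace_hz = config$pace_hz,
                            sample_rate_hz = config$sample_rate_hz,
                            coupling = config$coupling,
                            noise_sd = config$noise_sd,
                            drift_sd = config$drift_sd,
                            window_ms = config$window_ms,
                            subject = sprintf("%s%02d", substr(condition, 1, 1), s),
                            seed = seeds[s])
      sim <- simulate_subject_trials(cfg, geometry, config$min_samples)
      judg <- if (condition == "color")
        generate_similarity_judgments(geometry, noise_sd = 0.5, n_reps = 2,
                                      seed = seeds[s] %% 1000000L + s)
      subjects[[s]] <- list(trials = sim$trials, judgments = judg)
    }
    bundles[[condition]] <- list(geometry = geometry, subjects = subjects)
  }
  bundles
}

ingest_bundles <- function(config) {
  bundles <- list()
  for (i in seq_along(config$sessions)) {
    ses <- config$sessions[[i]]
    condition <- if (is.null(ses$condition)) "number" else ses$condition
    rec <- read_gaze_tsv(ses$gaze)
    ev <- read_events_csv(ses$events)
    trials <- window_median_gaze(rec, ev, window_ms = config$window_ms,
                                 min_samples = config$min_samples)
    judg <- if (!is.null(ses$judgments)) read.csv(ses$judgments,
                                                  stringsAsFactors = FALSE)
    entry <- list(trials = trials, judgments = judg)
    if (is.null(bundles[[condition]]))
      bundles[[condition]] <- list(geometry = NULL, subjects = list())
    bundles[[condition]]$subjects <-
      c(bundles[[condition]]$subjects, list(entry))
  }
  bundles
}

analyze_condition <- function(condition, bundle, config) {
  subjects <- bundle$subjects
  rows <- list()
  extra <- list()
  rsa_rho <- c()
  gaze_dms <- list()
  pos_tables <- list()
  decode_p <- c()

  for (s in seq_along(subjects)) {
    trials <- subjects[[s]]$trials
    disp <- displacement_series(trials)
    sid <- trials$subject[1]

    emb <- NULL
    if (condition == "color") {
      emb <- if (!is.null(subjects[[s]]$judgments))
        classical_mds(dissimilarity_from_judgments(subjects[[s]]$judgments))
      else bundle$geometry$coords
    }
    change <- switch(condition,
      number = signed_number_change(trials$word, block = trials$block,
                                    trial = trials$trial),
      color = mds_distance_series(trials$word, emb, block = trials$block,
                                  trial = trials$trial),
      animal = animal_distance_series(trials$word, "frequency",
                                      list(frequency = bundle$geometry$values),
                                      block = trials$block,
                                      trial = trials$trial))
    ctrl <- transition_count_series(trials$word, block = trials$block,
                                    trial = trials$trial)

    specs <- list(c("x_signed", "combined"), c("y_signed", "combined"),
                  c("euclid_2d", "combined"), c("x_signed", "sign_only"),
                  c("x_signed", "magnitude_only"))
    if (condition != "number")
      specs <- specs[1:3]  # signed decomposition is number-line specific
    for (sp in specs) {
      r <- tryCatch(condition_correlation(disp, change, axis = sp[1],
                                          mode = sp[2], subject = sid,
                                          condition = condition),
                    error = function(e) NULL)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
    r <- tryCatch(condition_correlation(disp, ctrl, axis = "x_signed",
                                        mode = "control_transition",
                                        subject = sid,
                                        condition = condition),
                  error = function(e) NULL)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r

    pos <- concept_mean_positions(trials)
    pos_tables[[s]] <- pos
    if (condition == "color" && nrow(pos) >= 4 && !is.null(emb)) {
      dm_gaze <- distance_matrix_from_points(pos)
      keep <- intersect(rownames(emb), pos$concept)
      if (length(keep) >= 4) {
        dm_conc <- as.matrix(dist(emb[keep, , drop = FALSE]))
        rsa <- rsa_lower_triangle(dm_gaze[keep, keep], dm_conc)
        rsa_rho <- c(rsa_rho, rsa$rho)
        gaze_dms[[length(gaze_dms) + 1L]] <- dm_gaze[keep, keep]
      }
    }
    if (condition == "number" && config$n_perm > 0) {
      ok <- trials[trials$valid, ]
      labs <- small_large_labels(ok$word)
      if (all(table(labs) >= 2)) {
        dr <- permutation_pvalue(ok$median_x_px, labs,
                                 n_perm = config$n_perm,
                                 seed = config$seed + s)
        decode_p <- c(decode_p, dr$p_perm)
      }
    }
  }

  rows <- do.call(rbind, rows)
  group <- list()
  for (key in unique(paste(rows$axis, rows$mode))) {
    sub <- rows[paste(rows$axis, rows$mode) == key, ]
    if (nrow(sub) >= 2 && sd(sub$z) > 0) {
      g <- group_t(sub$z)
      group[[key]] <- g[c("mean_z", "sd_z", "t", "df", "p", "bf10", "n")]
    }
  }

  if (condition == "number") {
    vals <- setNames(1:12, as.character(1:12))
    reg <- tryCatch(position_regression(pos_tables, vals, axis = "x"),
                    error = function(e) NULL)
    if (!is.null(reg))
      extra$regression_x <- list(slope = reg$slope,
                                 intercept = reg$intercept,
                                 t = if (!is.null(reg$group)) reg$group$t,
                                 p = if (!is.null(reg$group)) reg$group$p)
    if (length(decode_p))
      extra$decoding <- list(p_perm = decode_p,
                             n_significant = sum(decode_p < 0.05))
  }
  if (condition == "color" && length(gaze_dms) >= 2) {
    shared <- Reduce(intersect, lapply(gaze_dms, rownames))
    if (length(shared) >= 4) {
      mats <- lapply(gaze_dms, function(m) m[shared, shared])
      extra$group_embedding <- group_gaze_mds(mats)
      group[["rsa"]] <- {
        g <- group_t(fisher_z(rsa_rho, clip = TRUE))
        g[c("mean_z", "sd_z", "t", "df", "p", "bf10", "n")]
      }
    }
  }
  list(subject_rows = rows, group = group, extra = extra)
}
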