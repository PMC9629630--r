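#' Instrument track objects
#'
#' An instrument track is one instrument's raw motion-capture time series:
#' tip position (`x`, `y`, `z`, millimetres), shaft attitude (`roll`, `pitch`,
#' `yaw`, degrees) and gripper opening angle (`grip`, degrees), sampled on a
#' regular time grid `t` (seconds). Tracks are tibbles with attributes
#' `instrument_id`, `hand` and `sample_rate`.
#'
#' @param data data frame with numeric columns `t, x, y, z, roll, pitch, yaw,
#'   grip`, all the same length; `t` strictly increasing with spacing
#'   `1/sample_rate` (tolerance 1e-6 s).
#' @param instrument_id instrument label, e.g. `"grasper"`, `"scissors"`,
#'   `"clip_applier"`, `"needle_holder"`.
#' @param hand `"right"` or `"left"`.
#' @param sample_rate sampling frequency in Hz (default 30).
#' @return A tibble of class `mocap_track`.
#' @export
instrument_track <- function(data, instrument_id, hand, sample_rate = 30) {
  stopifnot(is.data.frame(data))
  hand <- match.arg(hand, c("right", "left"))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  missing_cols <- setdiff(track_channels(), names(data))
  if (length(missing_cols)) {
    stop("track is missing channels: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)[track_channels()]
  if (nrow(data) == 0) stop("empty track", call. = FALSE)
  for (ch in track_channels()) {
    if (!is.numeric(data[[ch]])) stop("channel '", ch, "' is not numeric", call. = FALSE)
    if (anyNA(data[[ch]])) stop("channel '", ch, "' contains missing values", call. = FALSE)
  }
  validate_timebase(data$t, sample_rate)
  structure(data,
            class = c("mocap_track", class(tibble::tibble()))) |>
    set_track_attrs(instrument_id, hand, sample_rate)
}

track_channels <- function() c("t", "x", "y", "z", "roll", "pitch", "yaw", "grip")

set_track_attrs <- function(x, instrument_id, hand, sample_rate) {
  attr(x, "instrument_id") <- instrument_id
  attr(x, "hand") <- hand
  attr(x, "sample_rate") <- sample_rate
  x
}

validate_timebase <- function(t, sample_rate, tol = 1e-6) {
  if (length(t) > 1) {
    dt <- diff(t)
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop("non-monotone time at line ", bad[1] + 2L, call. = FALSE)
    }
    off <- which(abs(dt - 1 / sample_rate) > tol)
    if (length(off)) {
      stop("irregular time spacing at line ", off[1] + 2L,
           " (expected ", signif(1 / sample_rate, 6), " s)", call. = FALSE)
    }
  }
  invisible(t)
}

#' @export
print.mocap_track <- function(x, ...) {
  cat(sprintf("<mocap_track> %s (%s hand), %d samples @ %g Hz, %.2f s\n",
              attr(x, "instrument_id"), attr(x, "hand"), nrow(x),
              attr(x, "sample_rate"), nrow(x) / attr(x, "sample_rate")))
  NextMethod()
}

#' Read an instrument track from a CSV file
#'
#' The on-disk dialect is a plain comma-separated UTF-8 file with header
#' `t,x,y,z,roll,pitch,yaw,grip`; positions in mm, angles in degrees, time in
#' seconds. Instrument identity and hand assignment live in the trial
#' manifest, not the track file.
#'
#' @param path path to the track CSV.
#' @inheritParams instrument_track
#' @return A `mocap_track`.
#' @export
read_track_file <- function(path, instrument_id = "instrument", hand = "right",
                            sample_rate = 30) {
  if (!file.exists(path)) stop("no such track file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(header), track_channels())) {
    stop("malformed header in ", path, ": expected '",
         paste(track_channels(), collapse = ","), "'", call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  for (ch in track_channels()) {
    if (anyNA(df[[ch]])) {
      stop("ragged or non-numeric values in column '", ch, "' at line ",
           which(is.na(df[[ch]]))[1] + 1L, " of ", path, call. = FALSE)
    }
  }
  instrument_track(df, instrument_id, hand, sample_rate)
}

#' Write an instrument track to CSV
#'
#' Values are written with 10 significant digits, enough for a bit-stable
#' round-trip at 1e-9 relative tolerance.
#'
#' @param track a `mocap_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_file <- function(track, path) {
  stopifnot(inherits(track, "mocap_track"))
  if (nrow(track) == 0) stop("empty track", call. = FALSE)
  formatted <- vapply(track_channels(), function(ch) {
    sprintf("%.10g", track[[ch]])
  }, character(nrow(track)))
  if (is.null(dim(formatted))) formatted <- matrix(formatted, nrow = 1)
  lines <- c(paste(track_channels(), collapse = ","),
             apply(formatted, 1, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- trials -----------------------------------------------------------------

task_instruments <- function(task) {
  switch(task,
    task1_dissection = tibble::tribble(
      ~instrument_id, ~hand,
      "grasper", "left",
      "scissors", "right",
      "clip_applier", "right"
    ),
    task3_suturing = tibble::tribble(
      ~instrument_id, ~hand,
      "needle_holder", "right",
      "needle_holder", "left"
    ),
    stop("unknown task: ", task, call. = FALSE)
  )
}

#' Trial recordings
#'
#' A trial recording bundles all instrument tracks of one training session
#' with its labels. Task 1 (tissue dissection) requires a left-hand grasper
#' plus right-hand scissors and clip applier; task 3 (suturing) requires right
#' and left needle holders.
#'
#' @param trial_id,participant_id identifiers.
#' @param task `"task1_dissection"` or `"task3_suturing"`.
#' @param n_prior_surgeries non-negative integer count of prior laparoscopic
#'   surgeries; drives experience-group assignment.
#' @param tracks list of `mocap_track` objects.
#' @return An object of class `mocap_trial`.
#' @export
trial_recording <- function(trial_id, participant_id, task, n_prior_surgeries,
                            tracks) {
  task <- match.arg(task, c("task1_dissection", "task3_suturing"))
  if (n_prior_surgeries < 0 || n_prior_surgeries != round(n_prior_surgeries)) {
    stop("n_prior_surgeries must be a non-negative integer", call. = FALSE)
  }
  stopifnot(length(tracks) >= 1, all(vapply(tracks, inherits, TRUE, "mocap_track")))
  have <- tibble::tibble(
    instrument_id = vapply(tracks, attr, "", "instrument_id"),
    hand = vapply(tracks, attr, "", "hand")
  )
  need <- task_instruments(task)
  for (i in seq_len(nrow(need))) {
    ok <- any(have$instrument_id == need$instrument_id[i] & have$hand == need$hand[i])
    if (!ok) {
      stop(task, " trial '", trial_id, "' is missing required instrument: ",
           need$hand[i], " ", need$instrument_id[i], call. = FALSE)
    }
  }
  structure(
    list(trial_id = trial_id, participant_id = participant_id, task = task,
         n_prior_surgeries = as.integer(n_prior_surgeries), tracks = tracks),
    class = "mocap_trial"
  )
}

#' @export
print.mocap_trial <- function(x, ...) {
  cat(sprintf("<mocap_trial> %s (%s), participant %s, %d prior surgeries, %d tracks\n",
              x$trial_id, x$task, x$participant_id, x$n_prior_surgeries,
              length(x$tracks)))
  invisible(x)
}

#' Write / read a trial directory
#'
#' A trial is stored as a directory containing one CSV per instrument track
#' plus a `manifest.yaml` sidecar listing the track files, hand assignments,
#' task, participant and prior-surgery count.
#'
#' @param trial a `mocap_trial`.
#' @param dir directory to create.
#' @return the manifest path (write) or a `mocap_trial` (read).
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "mocap_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(trial$tracks))
  for (i in seq_along(trial$tracks)) {
    tr <- trial$tracks[[i]]
    fname <- sprintf("%s_%s.csv", attr(tr, "hand"), attr(tr, "instrument_id"))
    write_track_file(tr, file.path(dir, fname))
    entries[[i]] <- list(file = fname,
                         instrument_id = attr(tr, "instrument_id"),
                         hand = attr(tr, "hand"),
                         sample_rate = attr(tr, "sample_rate"))
  }
  manifest <- list(trial_id = trial$trial_id,
                   participant_id = trial$participant_id,
                   task = trial$task,
                   n_prior_surgeries = trial$n_prior_surgeries,
                   tracks = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @param manifest_path path to a trial `manifest.yaml`.
#' @rdname write_trial
#' @export
read_trial <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("no such manifest: ", manifest_path, call. = FALSE)
  }
  m <- yaml::read_yaml(manifest_path)
  for (f in c("trial_id", "participant_id", "task", "n_prior_surgeries", "tracks")) {
    if (is.null(m[[f]])) stop("manifest missing field '", f, "'", call. = FALSE)
  }
  dir <- dirname(manifest_path)
  tracks <- lapply(m$tracks, function(e) {
    read_track_file(file.path(dir, e$file), e$instrument_id, e$hand,
                    e$sample_rate %||% 30)
  })
  trial_recording(m$trial_id, m$participant_id, m$task, m$n_prior_surgeries, tracks)
}

# ---- cohorts ----------------------------------------------------------------

#' Cohort objects
#'
#' A cohort is a sequence of trial recordings with unique trial ids, tagged
#' with its provenance (`"synthetic"` or `"imported"`) and, when synthetic,
#' the seed it was generated from.
#'
#' @param trials list of `mocap_trial` objects.
#' @param provenance `"synthetic"` or `"imported"`.
#' @param seed generating seed or `NULL`.
#' @return An object of class `mocap_cohort`.
#' @export
cohort <- function(trials, provenance = c("imported", "synthetic"), seed = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(length(trials) >= 1, all(vapply(trials, inherits, TRUE, "mocap_trial")))
  ids <- vapply(trials, `[[`, "", "trial_id")
  if (anyDuplicated(ids)) {
    stop("duplicate trial_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  structure(list(trials = trials, provenance = provenance, seed = seed),
            class = "mocap_cohort")
}

#' @export
print.mocap_cohort <- function(x, ...) {
  cat(sprintf("<mocap_cohort> %d trials (%s%s)\n", length(x$trials), x$provenance,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}

#' @export
length.mocap_cohort <- function(x) length(x$trials)

#' Write / read a cohort directory
#'
#' A cohort on disk is a directory of per-trial subdirectories (each with its
#' manifest) plus a `labels.csv` ground-truth table with one row per trial.
#'
#' @param x a `mocap_cohort`.
#' @param dir cohort directory.
#' @return the directory (write) or a `mocap_cohort` (read).
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "mocap_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in x$trials) write_trial(tr, file.path(dir, tr$trial_id))
  labels <- tibble::tibble(
    trial_id = vapply(x$trials, `[[`, "", "trial_id"),
    participant_id = vapply(x$trials, `[[`, "", "participant_id"),
    task = vapply(x$trials, `[[`, "", "task"),
    n_prior_surgeries = vapply(x$trials, `[[`, 0L, "n_prior_surgeries"),
    group = as.character(assign_group(vapply(x$trials, `[[`, 0L, "n_prior_surgeries")))
  )
  readr::write_csv(labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifests <- sort(list.files(dir, "^manifest\\.yaml$", recursive = TRUE,
                               full.names = TRUE))
  if (!length(manifests)) stop("no trial manifests under ", dir, call. = FALSE)
  cohort(lapply(manifests, read_trial), provenance = "imported")
}

# ---- experience groups ------------------------------------------------------

#' Assign experience groups from prior caseload
#'
#' The three-level scheme labels participants with at least 50 prior
#' laparoscopic surgeries as experts, 10-49 as intermediates and 0-9 as
#' novices. The two-level scheme collapses intermediates and novices into
#' `non_expert`.
#'
#' @param n_prior_surgeries vector of non-negative integer caseloads.
#' @return A factor: levels `novice < intermediate < expert` for
#'   [assign_group()], `non_expert < expert` for [assign_group2()].
#' @examples
#' assign_group(c(0, 9, 10, 49, 50))
#' assign_group2(c(49, 50))
#' @export
assign_group <- function(n_prior_surgeries) {
  if (any(n_prior_surgeries < 0)) {
    stop("n_prior_surgeries must be non-negative", call. = FALSE)
  }
  factor(ifelse(n_prior_surgeries >= 50, "expert",
                ifelse(n_prior_surgeries >= 10, "intermediate", "novice")),
         levels = c("novice", "intermediate", "expert"))
}

#' @rdname assign_group
#' @export
assign_group2 <- function(n_prior_surgeries) {
  if (any(n_prior_surgeries < 0)) {
    stop("n_prior_surgeries must be non-negative", call. = FALSE)
  }
  factor(ifelse(n_prior_surgeries >= 50, "expert", "non_expert"),
         levels = c("non_expert", "expert"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
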