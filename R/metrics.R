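#' Efficiency metrics: operative time, path length, depth path length,
#' working area
#'
#' `OT` is the elapsed time of the series; `PL` the summed Euclidean step
#' length of the smoothed tip positions; `DPL` the summed absolute step along
#' the depth axis (the endoscope viewing direction); `WA` the area of the 2-D
#' convex hull of the tip positions projected onto the plane perpendicular to
#' the depth axis. Shorter PL/DPL and smaller WA indicate more economical
#' movement; the depth metrics isolate the component that depends on depth
#' perception.
#'
#' @param kin a `mocap_kin` from [smooth_and_differentiate()].
#' @param depth_axis `"x"`, `"y"` or `"z"` (default); which axis is depth.
#' @return A one-row tibble with columns `OT`, `PL`, `DPL`, `WA`.
#' @export
compute_efficiency_metrics <- function(kin, depth_axis = "z") {
  depth_axis <- match.arg(depth_axis, c("x", "y", "z"))
  if (nrow(kin) < 2) stop("need at least 2 samples", call. = FALSE)
  pos <- cbind(kin$x, kin$y, kin$z)
  steps <- diff(pos)
  d_col <- match(depth_axis, c("x", "y", "z"))
  plane <- pos[, -d_col, drop = FALSE]
  tibble::tibble(
    OT = kin$t[nrow(kin)] - kin$t[1],
    PL = sum(sqrt(rowSums(steps^2))),
    DPL = sum(abs(steps[, d_col])),
    WA = convex_hull_area(plane[, 1], plane[, 2])
  )
}

# Shoelace area of the convex hull of a 2-D point cloud.
convex_hull_area <- function(u, v) {
  keep <- !duplicated(cbind(u, v))
  u <- u[keep]; v <- v[keep]
  if (length(u) < 3) return(0)
  h <- grDevices::chull(u, v)
  uu <- u[h]; vv <- v[h]
  nxt <- c(seq_along(h)[-1], 1)
  abs(sum(uu * vv[nxt] - uu[nxt] * vv)) / 2
}

#' Speed metrics: mean velocity, acceleration, jerk and depth velocity
#'
#' Time-means of the per-sample Euclidean norms of the first three
#' derivatives of tip position, plus `DV`, the mean absolute velocity along
#' the depth axis. Experts show faster, brisker profiles on all four.
#'
#' @inheritParams compute_efficiency_metrics
#' @return A one-row tibble with columns `v_mean`, `a_mean`, `j_mean`, `DV`.
#' @export
compute_speed_metrics <- function(kin, depth_axis = "z") {
  depth_axis <- match.arg(depth_axis, c("x", "y", "z"))
  if (nrow(kin) < 1) stop("empty kinematics", call. = FALSE)
  vd <- kin[[paste0("v", depth_axis)]]
  tibble::tibble(
    v_mean = mean(kin$speed),
    a_mean = mean(kin$accel),
    j_mean = mean(kin$jerk),
    DV = mean(abs(vd))
  )
}

#' Detect gripper open/close events with hysteresis
#'
#' An open event fires when the gripper angle rises through
#' `threshold + hysteresis` after having been below `threshold - hysteresis`;
#' a close event is symmetric. The hysteresis band suppresses chatter from
#' measurement noise, and alternation (open, close, open, ...) is enforced by
#' construction of the two-state machine.
#'
#' @param x a `mocap_track` or `mocap_kin` with `t` and `grip` columns.
#' @param threshold gripper angle threshold, degrees.
#' @param hysteresis half-width of the dead band, degrees.
#' @return A tibble with columns `time` (s) and `kind` (`"open"`/`"close"`).
#' @export
detect_gripper_events <- function(x, threshold = 20, hysteresis = 5) {
  g <- x$grip
  if (is.null(g)) stop("no grip channel", call. = FALSE)
  hi <- threshold + hysteresis
  lo <- threshold - hysteresis
  state <- if (g[1] >= hi) "open" else "closed"
  times <- numeric(0); kinds <- character(0)
  for (i in seq_along(g)) {
    if (state == "closed" && g[i] >= hi) {
      state <- "open"; times <- c(times, x$t[i]); kinds <- c(kinds, "open")
    } else if (state == "open" && g[i] <= lo) {
      state <- "closed"; times <- c(times, x$t[i]); kinds <- c(kinds, "close")
    }
  }
  tibble::tibble(time = times, kind = kinds)
}

#' Bimanual coordination metrics
#'
#' Computed on the two hands' series resampled to their common timebase:
#' `BD` (bimanual dexterity) is the zero-lag Pearson correlation of the two
#' speed profiles; `ROB` the ratio of right- to left-hand gripper open+close
#' event counts; `RPLB` the right/left path-length ratio; `ADB` the time-mean
#' inter-tip distance; `ADBO` the mean inter-tip distance sampled at the
#' open/close event times of either hand. Undefined values (zero left-hand
#' events or path length, constant speed series, no events) are returned as
#' `NA` rather than infinities.
#'
#' @param right,left `mocap_kin` tables for the right and left hand.
#' @param right_events,left_events event tables from
#'   [detect_gripper_events()]; detected from the kinematic tables when
#'   omitted.
#' @param lag_window if positive, BD is the maximum cross-correlation over
#'   lags within `+/- lag_window` seconds instead of the zero-lag
#'   correlation.
#' @return A one-row tibble with columns `BD`, `ROB`, `RPLB`, `ADBO`, `ADB`.
#' @export
compute_bimanual_metrics <- function(right, left, right_events = NULL,
                                     left_events = NULL, lag_window = 0) {
  if (is.null(right_events)) right_events <- detect_gripper_events(right)
  if (is.null(left_events)) left_events <- detect_gripper_events(left)
  common <- resample_to_common_timebase(right, left)
  sr <- common$a$speed; sl <- common$b$speed
  bd <- if (stats::sd(sr) == 0 || stats::sd(sl) == 0) {
    NA_real_
  } else if (lag_window > 0) {
    fs <- 1 / stats::median(diff(common$a$t))
    max_lag <- max(1L, round(lag_window * fs))
    cc <- stats::ccf(sr, sl, lag.max = max_lag, plot = FALSE)
    max(cc$acf)
  } else {
    stats::cor(sr, sl)
  }
  n_r <- nrow(right_events); n_l <- nrow(left_events)
  pl <- function(k) sum(sqrt(rowSums(diff(cbind(k$x, k$y, k$z))^2)))
  pl_l <- pl(left)
  dist_t <- sqrt((common$a$x - common$b$x)^2 + (common$a$y - common$b$y)^2 +
                   (common$a$z - common$b$z)^2)
  ev_times <- sort(c(right_events$time, left_events$time))
  ev_times <- ev_times[ev_times >= min(common$a$t) & ev_times <= max(common$a$t)]
  adbo <- if (length(ev_times)) {
    mean(stats::approx(common$a$t, dist_t, xout = ev_times, rule = 2)$y)
  } else NA_real_
  tibble::tibble(
    BD = bd,
    ROB = if (n_l == 0) NA_real_ else n_r / n_l,
    RPLB = if (pl_l == 0) NA_real_ else pl(right) / pl_l,
    ADBO = adbo,
    ADB = mean(dist_t)
  )
}

#' Attitude metrics
#'
#' `AGRA` is the mean gripper opening angle; `Roll`, `Pitch`, `Yaw` the
#' arithmetic means of the unwrapped attitude angles; `AL_Roll` the total
#' variation of roll (accumulated rotation about the shaft axis); and
#' `AL_PitchYaw` the accumulated great-circle angle between consecutive shaft
#' direction vectors reconstructed from pitch and yaw - the total angular
#' excursion of the shaft direction. Larger angular lengths reflect more
#' frequent attitude adjustments.
#'
#' @inheritParams compute_efficiency_metrics
#' @return A one-row tibble with columns `AGRA`, `Roll`, `Pitch`, `Yaw`,
#'   `AL_Roll`, `AL_PitchYaw`.
#' @export
compute_attitude_metrics <- function(kin) {
  for (ch in c("roll", "pitch", "yaw", "grip")) {
    if (is.null(kin[[ch]])) stop("missing attitude channel '", ch, "'", call. = FALSE)
  }
  u <- shaft_vector(kin$pitch, kin$yaw)
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  arc <- acos(pmin(pmax(dots, -1), 1)) * 180 / pi
  tibble::tibble(
    AGRA = mean(kin$grip),
    Roll = mean(kin$roll),
    Pitch = mean(kin$pitch),
    Yaw = mean(kin$yaw),
    AL_Roll = sum(abs(diff(kin$roll))),
    AL_PitchYaw = sum(arc)
  )
}

# Unit shaft-direction vector from pitch (elevation) and yaw (azimuth about
# the depth axis), both in degrees.
shaft_vector <- function(pitch, yaw) {
  p <- pitch * pi / 180
  y <- yaw * pi / 180
  cbind(cos(p) * sin(y), sin(p), cos(p) * cos(y))
}

# Instrument prefix scheme used in metric names.
instrument_prefix <- function(instrument_id, hand) {
  switch(instrument_id,
         grasper = "G", scissors = "S", clip_applier = "C",
         needle_holder = if (hand == "right") "R" else "L",
         toupper(substr(instrument_id, 1, 1)))
}

#' Compute the full metric vector of one trial
#'
#' Runs smoothing/differentiation on every track, then assembles the
#' per-instrument efficiency, speed and attitude metrics (prefixed `G_`,
#' `S_`, `C_` for grasper/scissors/clip applier and `R_`/`L_` for the needle
#' holders), the trial-level operative time `OT` (full span over all
#' instruments), and one set of bimanual metrics computed between the
#' left-hand track and the right-hand track with the longest overlap.
#'
#' @param trial a `mocap_trial`.
#' @param config a [run_config()]; supplies filter settings, depth axis and
#'   gripper event thresholds.
#' @return A one-row tibble: `trial_id`, `participant_id`, `task`,
#'   `n_prior_surgeries`, then named metrics.
#' @export
compute_metric_vector <- function(trial, config = run_config()) {
  stopifnot(inherits(trial, "mocap_trial"))
  kins <- lapply(trial$tracks, smooth_and_differentiate,
                 window = config$window, polyorder = config$polyorder)
  hands <- vapply(trial$tracks, attr, "", "hand")
  spans <- vapply(kins, function(k) max(k$t) - min(k$t), 0)
  per_instrument <- purrr::map2(kins, trial$tracks, function(k, tr) {
    pre <- instrument_prefix(attr(tr, "instrument_id"), attr(tr, "hand"))
    eff <- compute_efficiency_metrics(k, config$depth_axis)
    eff$OT <- NULL
    row <- dplyr::bind_cols(eff,
                            compute_speed_metrics(k, config$depth_axis),
                            compute_attitude_metrics(k))
    names(row) <- paste(pre, names(row), sep = "_")
    row
  })
  left_i <- which(hands == "left")
  right_i <- which(hands == "right")
  bim <- if (length(left_i) && length(right_i)) {
    li <- left_i[which.max(spans[left_i])]
    overlap <- vapply(right_i, function(i) {
      min(max(kins[[i]]$t), max(kins[[li]]$t)) -
        max(min(kins[[i]]$t), min(kins[[li]]$t))
    }, 0)
    ri <- right_i[which.max(overlap)]
    ev <- lapply(c(ri, li), function(i) {
      detect_gripper_events(kins[[i]], config$grip_threshold,
                            config$grip_hysteresis)
    })
    compute_bimanual_metrics(kins[[ri]], kins[[li]], ev[[1]], ev[[2]],
                             lag_window = config$bd_lag_window)
  } else {
    tibble::tibble(BD = NA_real_, ROB = NA_real_, RPLB = NA_real_,
                   ADBO = NA_real_, ADB = NA_real_)
  }
  t_all <- unlist(lapply(kins, function(k) range(k$t)))
  dplyr::bind_cols(
    tibble::tibble(trial_id = trial$trial_id,
                   participant_id = trial$participant_id,
                   task = trial$task,
                   n_prior_surgeries = trial$n_prior_surgeries,
                   OT = max(t_all) - min(t_all)),
    dplyr::bind_cols(per_instrument),
    bim
  )
}

#' Assemble the feature matrix of a cohort
#'
#' One row per trial: identifiers, caseload, the derived three- and two-level
#' experience labels, and all named metrics. Rows keep `NA` flags from
#' undefined metrics; screening and classification handle them listwise.
#'
#' @param x a `mocap_cohort`.
#' @param config a [run_config()].
#' @return A tibble (the feature matrix).
#' @export
compute_features <- function(x, config = run_config()) {
  stopifnot(inherits(x, "mocap_cohort"))
  out <- purrr::map_dfr(x$trials, compute_metric_vector, config = config)
  dplyr::mutate(out,
                label3 = assign_group(.data$n_prior_surgeries),
                label2 = assign_group2(.data$n_prior_surgeries),
                .after = "n_prior_surgeries")
}

#' Names of the metric columns of a feature matrix
#'
#' @param features a feature matrix from [compute_features()].
#' @return Character vector of metric column names.
#' @export
metric_columns <- function(features) {
  setdiff(names(features),
          c("trial_id", "participant_id", "task", "n_prior_surgeries",
            "label3", "label2"))
}
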