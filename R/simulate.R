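#' Synthetic cohort configuration
#'
#' Parameters of the trajectory simulator. Instrument motion is composed of
#' minimum-jerk reaching segments between goal points, with skill-dependent
#' corrective submovements, physiological tremor, depth excursions, roll
#' fidgeting, pauses and bimanual timing jitter. Each `skill_map` entry is a
#' pair `c(novice_value, expert_value)` interpolated linearly in the scalar
#' skill in `[0, 1]`; all noise and inefficiency parameters decrease with
#' skill while movement briskness increases (segment durations shrink), so
#' that efficiency metrics (time, path length, depth path length) fall and
#' speed metrics (velocity, acceleration, jerk) rise with expertise.
#'
#' @param n_per_group named integer vector: trials per experience group,
#'   names `expert`, `intermediate`, `novice`.
#' @param task task identifier; decides the instrument set.
#' @param workspace named numeric: box extent in mm along `x`, `y`, `z`.
#' @param goals_per_trial number of reaching goals per trial.
#' @param base_segment_duration nominal duration (s) of a 60 mm reach at
#'   skill-map scale 1.
#' @param sample_rate sampling frequency, Hz.
#' @param skill_map list of `c(novice, expert)` parameter pairs, see Details.
#' @param seed base seed; all simulator randomness flows from it.
#'
#' @details `skill_map` entries:
#' \describe{
#'   \item{corrective_rate}{mean corrective submovements per goal (Poisson).}
#'   \item{tremor_rms}{tremor amplitude, mm RMS per axis, Gaussian noise
#'     low-pass filtered at 8 Hz.}
#'   \item{depth_excursion}{amplitude (mm) of a slow sinusoidal drift along
#'     the depth axis.}
#'   \item{roll_fidget}{roll random-walk accumulation rate, deg/s.}
#'   \item{pause_duration}{mean pause (s) between goals.}
#'   \item{timing_jitter}{SD (s) of the left hand's schedule offset per goal.}
#'   \item{spurious_grip_rate}{rate (1/s) of task-irrelevant gripper cycles.}
#'   \item{duration_scale}{multiplier on segment durations; below 1 means
#'     faster than nominal.}
#' }
#' @return A list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_per_group = c(expert = 32, intermediate = 18, novice = 20),
                                    task = "task1_dissection",
                                    workspace = c(x = 100, y = 80, z = 60),
                                    goals_per_trial = 15,
                                    base_segment_duration = 1.0,
                                    sample_rate = 30,
                                    skill_map = list(
                                      corrective_rate = c(2.5, 0.25),
                                      tremor_rms = c(0.05, 0.01),
                                      depth_excursion = c(6, 0.5),
                                      roll_fidget = c(12, 3),
                                      pause_duration = c(1.4, 0.3),
                                      timing_jitter = c(0.35, 0.05),
                                      spurious_grip_rate = c(0.05, 0.005),
                                      duration_scale = c(1.7, 0.8)
                                    ),
                                    seed = 1L) {
  stopifnot(all(c("expert", "intermediate", "novice") %in% names(n_per_group)),
            all(n_per_group >= 0),
            all(workspace > 0), goals_per_trial >= 1,
            base_segment_duration > 0, sample_rate > 0)
  defaults <- formals(synthetic_cohort_config)$skill_map
  defaults <- eval(defaults)
  for (nm in names(defaults)) {
    if (is.null(skill_map[[nm]])) skill_map[[nm]] <- defaults[[nm]]
    v <- skill_map[[nm]]
    if (length(v) != 2 || any(v < 0)) {
      stop("skill_map$", nm, " must be a non-negative pair c(novice, expert)",
           call. = FALSE)
    }
    if (v[2] > v[1]) {
      stop("skill_map$", nm, " must not increase with skill", call. = FALSE)
    }
  }
  structure(list(n_per_group = n_per_group, task = task,
                 workspace = workspace, goals_per_trial = goals_per_trial,
                 base_segment_duration = base_segment_duration,
                 sample_rate = sample_rate, skill_map = skill_map,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Zero-effect configuration
#'
#' A copy of a cohort configuration with every skill map held constant at
#' its midpoint, so skill has no influence on the simulated kinematics.
#' Serves as the null model for classifier and screening calibration: any
#' apparent group difference under this configuration is a false positive.
#'
#' @param config a [synthetic_cohort_config()] to flatten.
#' @return A `synthetic_cohort_config` with constant skill maps.
#' @export
zero_effect_config <- function(config = synthetic_cohort_config()) {
  config$skill_map <- lapply(config$skill_map, function(v) rep(mean(v), 2))
  config
}

skill_value <- function(config, name, skill) {
  v <- config$skill_map[[name]]
  v[1] + (v[2] - v[1]) * skill
}

#' Minimum-jerk position profile
#'
#' The classic smooth point-to-point reaching primitive: position follows
#' `start + (end - start) * (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t / duration`, so velocity and acceleration vanish at both ends and
#' peak speed is `1.875 * distance / duration`.
#'
#' @param start,end numeric length-3 points (mm).
#' @param duration segment duration, s (> 0).
#' @param t times within `[0, duration]` (vectorized).
#' @return A `length(t) x 3` matrix of positions.
#' @export
minimum_jerk_position <- function(start, end, duration, t) {
  stopifnot(length(start) == 3, length(end) == 3, duration > 0)
  if (any(t < -1e-9) || any(t > duration + 1e-9)) {
    stop("t outside [0, duration]", call. = FALSE)
  }
  tau <- pmin(pmax(t / duration, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  outer(s, end - start) + matrix(start, length(t), 3, byrow = TRUE)
}

# last-observation-carried-forward with a leading fill value
locf_fill <- function(x, lead) {
  filled <- !is.na(x)
  idx <- cumsum(filled)
  out <- c(lead, x[filled])[idx + 1L]
  out
}

# Build one hand's movement schedule: a data frame of minimum-jerk segments
# (start time, duration, endpoints) plus goal arrival times. Corrective
# submovements model overshoot-and-fix: the primary reach lands a short
# distance off the goal and a geometric cascade of hops converges on it.
build_schedule <- function(goals, start_pt, config, skill, pause_base, offsets = NULL) {
  n_goal <- nrow(goals)
  dur_scale <- skill_value(config, "duration_scale", skill)
  corr_rate <- skill_value(config, "corrective_rate", skill)
  segs <- list()
  arrivals <- numeric(n_goal)
  t_cur <- 0.5
  p <- start_pt
  for (k in seq_len(n_goal)) {
    t_cur <- t_cur + pause_base[k] + if (is.null(offsets)) 0 else offsets[k]
    t_cur <- max(t_cur, if (length(segs)) segs[[length(segs)]]$t0 +
                   segs[[length(segs)]]$duration + 0.1 else 0.1)
    g <- goals[k, ]
    D <- sqrt(sum((g - p)^2))
    T_primary <- max(0.3, dur_scale * config$base_segment_duration *
                       sqrt(max(D, 10) / 60))
    n_corr <- stats::rpois(1, corr_rate)
    if (n_corr == 0) {
      segs[[length(segs) + 1]] <- list(t0 = t_cur, duration = T_primary,
                                       start = p, end = g)
      t_cur <- t_cur + T_primary
      p <- g
    } else {
      err_mag <- stats::runif(1, 0.05, 0.15) * max(D, 10)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      target <- g + err_mag * u
      segs[[length(segs) + 1]] <- list(t0 = t_cur, duration = T_primary,
                                       start = p, end = target)
      t_cur <- t_cur + T_primary
      p <- target
      for (j in seq_len(n_corr)) {
        e <- if (j == n_corr) 0 else err_mag * 0.5^j
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        hop_target <- g + e * u
        hop_len <- sqrt(sum((hop_target - p)^2))
        T_hop <- min(max(0.45 * dur_scale * sqrt(max(hop_len, 3) / 15), 0.35), 1.0)
        segs[[length(segs) + 1]] <- list(t0 = t_cur, duration = T_hop,
                                         start = p, end = hop_target)
        t_cur <- t_cur + T_hop + stats::runif(1, 0.05, 0.15)
        p <- hop_target
      }
    }
    arrivals[k] <- t_cur
  }
  list(segments = segs, arrivals = arrivals, end_time = t_cur, end_point = p)
}

# Render a schedule onto a regular time grid; the tip holds position between
# segments.
render_schedule <- function(schedule, t_grid, start_pt) {
  n <- length(t_grid)
  pos <- matrix(NA_real_, n, 3)
  for (seg in schedule$segments) {
    i <- which(t_grid >= seg$t0 & t_grid < seg$t0 + seg$duration)
    if (length(i)) {
      pos[i, ] <- minimum_jerk_position(seg$start, seg$end, seg$duration,
                                        t_grid[i] - seg$t0)
    }
    i_end <- which(t_grid >= seg$t0 + seg$duration)
    if (length(i_end)) pos[i_end[1], ] <- seg$end
  }
  for (ax in 1:3) pos[, ax] <- locf_fill(pos[, ax], start_pt[ax])
  pos
}

# Band-limited Gaussian tremor: white noise low-passed at 8 Hz and rescaled
# to an exact per-axis RMS.
tremor_noise <- function(n, rms, sample_rate) {
  if (rms <= 0 || n < 12) return(matrix(0, n, 3))
  bf <- signal::butter(2, min(8 / (sample_rate / 2), 0.95))
  sapply(1:3, function(ax) {
    w <- stats::rnorm(n)
    f <- signal::filtfilt(bf, w)
    f <- f - mean(f)
    s <- sqrt(mean(f^2))
    if (s > 0) f * (rms / s) else f
  })
}

# Gripper channel: raised-cosine open/close bumps at the given event times.
render_gripper <- function(t_grid, cycle_times, base = 8, open_angle = 45,
                           width = 0.8) {
  g <- rep(base, length(t_grid))
  for (tc in cycle_times) {
    i <- which(t_grid >= tc & t_grid <= tc + width)
    if (length(i)) {
      bump <- base + (open_angle - base) *
        0.5 * (1 - cos(2 * pi * (t_grid[i] - tc) / width))
      g[i] <- pmax(g[i], bump)
    }
  }
  g
}

# Attitude from geometry: the shaft points from a fixed trocar towards the
# tip; yaw is the azimuth about the depth axis, pitch the elevation.
attitude_from_tip <- function(pos, trocar, sample_rate) {
  d <- sweep(pos, 2, trocar)
  d <- d / sqrt(rowSums(d^2))
  yaw <- atan2(d[, 1], d[, 3]) * 180 / pi
  pitch <- atan2(d[, 2], sqrt(d[, 1]^2 + d[, 3]^2)) * 180 / pi
  n <- nrow(pos)
  if (n >= 12) {
    bf <- signal::butter(2, min(2 / (sample_rate / 2), 0.95))
    yaw <- yaw + signal::filtfilt(bf, stats::rnorm(n, 0, 1.5))
    pitch <- pitch + signal::filtfilt(bf, stats::rnorm(n, 0, 1.5))
  }
  list(pitch = pitch, yaw = yaw)
}

# Bounded roll random walk with a prescribed mean absolute increment rate.
roll_walk <- function(n, fidget_rate, sample_rate) {
  sigma <- fidget_rate / sample_rate * sqrt(pi / 2)
  r <- cumsum(stats::rnorm(n, 0, sigma))
  abs(((r + 80) %% 320) - 160) - 80
}

simulate_hand <- function(goals, start_pt, config, skill, pause_base, offsets,
                          trocar, t_grid = NULL) {
  schedule <- build_schedule(goals, start_pt, config, skill, pause_base, offsets)
  fs <- config$sample_rate
  if (is.null(t_grid)) {
    t_end <- schedule$end_time + 1.0
    t_grid <- seq(0, t_end, by = 1 / fs)
  }
  pos <- render_schedule(schedule, t_grid, start_pt)
  # slow depth drift, then tremor
  amp <- skill_value(config, "depth_excursion", skill)
  if (amp > 0) {
    f_d <- stats::runif(1, 0.15, 0.4)
    pos[, 3] <- pos[, 3] + amp * sin(2 * pi * f_d * t_grid + stats::runif(1, 0, 2 * pi))
  }
  pos <- pos + tremor_noise(length(t_grid),
                            skill_value(config, "tremor_rms", skill), fs)
  att <- attitude_from_tip(pos, trocar, fs)
  roll <- roll_walk(length(t_grid), skill_value(config, "roll_fidget", skill), fs)
  # gripper cycles at goal arrivals plus spurious ones
  sp_rate <- skill_value(config, "spurious_grip_rate", skill)
  n_sp <- stats::rpois(1, sp_rate * max(t_grid))
  cyc <- sort(c(schedule$arrivals, stats::runif(n_sp, 0, max(t_grid) - 1)))
  grip <- render_gripper(t_grid, cyc)
  list(t = t_grid, pos = pos, roll = roll, pitch = att$pitch, yaw = att$yaw,
       grip = grip, schedule = schedule)
}

hand_track <- function(hand_sim, idx, instrument_id, hand, sample_rate) {
  instrument_track(
    tibble::tibble(t = hand_sim$t[idx],
                   x = hand_sim$pos[idx, 1], y = hand_sim$pos[idx, 2],
                   z = hand_sim$pos[idx, 3],
                   roll = hand_sim$roll[idx], pitch = hand_sim$pitch[idx],
                   yaw = hand_sim$yaw[idx], grip = hand_sim$grip[idx]),
    instrument_id = instrument_id, hand = hand, sample_rate = sample_rate)
}

#' Simulate one training trial
#'
#' Builds a two-handed trial at the configured sample rate. Both hands share
#' one goal schedule: the right hand reaches a sequence of uniform workspace
#' goals with minimum-jerk segments plus skill-dependent corrective
#' submovements; the left hand follows a laterally offset copy of the goals
#' with per-goal timing jitter. Tremor, depth excursions, roll fidget and
#' spurious gripper cycles are all governed by the skill maps in `config`.
#' For the dissection task the right-hand trajectory is split in time between
#' scissors (first part) and clip applier (second part); the suturing task
#' uses right and left needle holders over the full trial.
#'
#' @param config a [synthetic_cohort_config()].
#' @param skill scalar in `[0, 1]`; 0 = least, 1 = most skilled.
#' @param participant_id,trial_id identifiers.
#' @param n_prior_surgeries caseload label stored in the trial.
#' @param seed integer; the same seed reproduces the trial exactly.
#' @return A `mocap_trial`.
#' @export
simulate_trial <- function(config, skill, participant_id = "P000",
                           trial_id = "T000", n_prior_surgeries = 0L,
                           seed = 1L) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (skill < 0 || skill > 1) stop("skill must lie in [0, 1]", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    fs <- config$sample_rate
    K <- config$goals_per_trial
    w <- config$workspace
    margin <- pmin(5, w / 4)
    goals_r <- cbind(stats::runif(K, margin[1], w[1] - margin[1]),
                     stats::runif(K, margin[2], w[2] - margin[2]),
                     stats::runif(K, margin[3], w[3] - margin[3]))
    shift <- c(-0.25 * w[1], 0, 0)
    goals_l <- sweep(goals_r, 2, -shift - stats::rnorm(3, 0, 2))
    goals_l <- pmin(pmax(goals_l, 1), matrix(w - 1, K, 3, byrow = TRUE))
    start_r <- w * c(0.6, 0.5, 0.5)
    start_l <- w * c(0.35, 0.5, 0.5)
    pause_mean <- skill_value(config, "pause_duration", skill)
    pause_base <- pause_mean * stats::runif(K, 0.6, 1.4)
    jitter_sd <- skill_value(config, "timing_jitter", skill)
    offsets_l <- stats::rnorm(K, 0, jitter_sd)

    right <- simulate_hand(goals_r, start_r, config, skill, pause_base, NULL,
                           trocar = c(0.85 * w[1], 0.5 * w[2], -160))
    left <- simulate_hand(goals_l, start_l, config, skill, pause_base, offsets_l,
                          trocar = c(0.15 * w[1], 0.5 * w[2], -160),
                          t_grid = right$t)

    n <- length(right$t)
    tracks <- if (config$task == "task1_dissection") {
      m <- if (K >= 2) ceiling(0.6 * K) else NA
      t_split <- if (is.na(m)) 0.7 * max(right$t) else right$schedule$arrivals[m]
      i_sc <- which(right$t < t_split)
      i_ca <- which(right$t >= t_split)
      min_len <- 12L
      if (length(i_sc) < min_len) i_sc <- seq_len(min(min_len, n))
      if (length(i_ca) < min_len) i_ca <- seq.int(max(1L, n - min_len + 1L), n)
      list(hand_track(left, seq_len(n), "grasper", "left", fs),
           hand_track(right, i_sc, "scissors", "right", fs),
           hand_track(right, i_ca, "clip_applier", "right", fs))
    } else {
      list(hand_track(right, seq_len(n), "needle_holder", "right", fs),
           hand_track(left, seq_len(n), "needle_holder", "left", fs))
    }
    trial_recording(trial_id, participant_id, config$task,
                    n_prior_surgeries, tracks)
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_group` trials per experience group. Prior caseloads are
#' uniform within each group's range (expert 50-500, intermediate 10-49,
#' novice 0-9) and the simulator skill is log-linear in caseload,
#' `skill = log10(1 + n) / log10(501)` clipped to `[0, 1]`, reflecting a
#' saturating learning curve. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_cohort_config()].
#' @return A `mocap_cohort` with provenance `"synthetic"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n <- config$n_per_group
  if (sum(n) == 0) stop("all n_per_group are zero", call. = FALSE)
  withr::with_seed(config$seed, {
    ranges <- list(expert = 50:500, intermediate = 10:49, novice = 0:9)
    rows <- purrr::map_dfr(c("expert", "intermediate", "novice"), function(g) {
      k <- n[[g]]
      if (k == 0) return(tibble::tibble())
      tibble::tibble(group = g,
                     n_prior = sample(ranges[[g]], k, replace = TRUE))
    })
    rows$skill <- pmin(pmax(log10(1 + rows$n_prior) / log10(501), 0), 1)
    rows$seed <- sample.int(.Machine$integer.max - 1L, nrow(rows))
    trials <- purrr::pmap(
      list(seq_len(nrow(rows)), rows$n_prior, rows$skill, rows$seed),
      function(i, n_prior, skill, seed) {
        simulate_trial(config, skill,
                       participant_id = sprintf("P%03d", i),
                       trial_id = sprintf("T%03d", i),
                       n_prior_surgeries = n_prior, seed = seed)
      })
    cohort(trials, provenance = "synthetic", seed = config$seed)
  })
}
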