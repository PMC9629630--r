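# Shared fixtures, all built in code.

# A track sampled from channel functions of time (defaults are smooth and
# non-degenerate).
make_track <- function(n = 60, fs = 30,
                       fx = function(t) 10 * t,
                       fy = function(t) 5 * sin(t),
                       fz = function(t) 2 * t^2,
                       froll = function(t) 3 * t,
                       fpitch = function(t) 5 * cos(t),
                       fyaw = function(t) 10 * sin(0.5 * t),
                       fgrip = function(t) rep(8, length(t)),
                       instrument_id = "scissors", hand = "right") {
  t <- seq(0, by = 1 / fs, length.out = n)
  instrument_track(
    tibble::tibble(t = t, x = fx(t), y = fy(t), z = fz(t),
                   roll = froll(t), pitch = fpitch(t), yaw = fyaw(t),
                   grip = fgrip(t)),
    instrument_id = instrument_id, hand = hand, sample_rate = fs)
}

# A bare kinematics table for direct metric-function tests (positions and
# derivatives supplied analytically, no filtering involved).
make_kin <- function(t, x, y, z, vx = NULL, vy = NULL, vz = NULL,
                     roll = 0, pitch = 0, yaw = 0, grip = 8, fs = 30) {
  n <- length(t)
  rep_n <- function(v) if (length(v) == 1) rep(v, n) else v
  zeros <- rep(0, n)
  k <- tibble::tibble(
    t = t, x = x, y = y, z = z,
    vx = rep_n(vx %||% zeros), vy = rep_n(vy %||% zeros),
    vz = rep_n(vz %||% zeros),
    ax = zeros, ay = zeros, az = zeros,
    jx = zeros, jy = zeros, jz = zeros,
    roll = rep_n(roll), pitch = rep_n(pitch), yaw = rep_n(yaw),
    grip = rep_n(grip))
  k$speed <- sqrt(k$vx^2 + k$vy^2 + k$vz^2)
  k$accel <- sqrt(k$ax^2 + k$ay^2 + k$az^2)
  k$jerk <- sqrt(k$jx^2 + k$jy^2 + k$jz^2)
  structure(k, class = c("mocap_kin", class(tibble::tibble())),
            sample_rate = fs, instrument_id = "test", hand = "right")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent convex-hull oracle: Andrew's monotone chain + shoelace
hull_area_oracle <- function(u, v) {
  pts <- unique(cbind(u, v))
  if (nrow(pts) < 3) return(0)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(build(seq_len(nrow(pts))), build(rev(seq_len(nrow(pts)))))
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  nxt <- c(seq_along(hull)[-1], 1)
  abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
}

# Small, fast simulator configuration for module tests.
small_config <- function(n = c(expert = 4, intermediate = 4, novice = 4),
                         goals = 6, task = "task1_dissection", seed = 42) {
  synthetic_cohort_config(n_per_group = n, goals_per_trial = goals,
                          task = task, seed = seed)
}

# Noise-free configuration: a single goal, every stochastic amplitude zero.
noise_free_config <- function(task = "task3_suturing") {
  synthetic_cohort_config(
    n_per_group = c(expert = 1, intermediate = 0, novice = 0),
    goals_per_trial = 1, task = task,
    skill_map = list(corrective_rate = c(0, 0), tremor_rms = c(0, 0),
                     depth_excursion = c(0, 0), roll_fidget = c(0, 0),
                     pause_duration = c(0.5, 0.5), timing_jitter = c(0, 0),
                     spurious_grip_rate = c(0, 0),
                     duration_scale = c(2.5, 2.5)),
    seed = 1)
}

# Tiny grids so classifier tests stay fast.
tiny_grids <- function() {
  list(svm = data.frame(cost = c(1, 10), gamma = c(0.01, 0.1)),
       pca_svm = data.frame(cost = c(1, 10), gamma = c(0.01, 0.1),
                            retained_variance = c(0.9, 0.9)),
       gbdt = data.frame(learning_rate = 0.1, n_trees = c(50, 50),
                         max_depth = c(2, 3)))
}

fast_config <- function(outer_k = 5, inner_k = 3, repetitions = 2, seed = 99) {
  run_config(outer_k = outer_k, inner_k = inner_k, repetitions = repetitions,
             grids = tiny_grids(), seed = seed)
}

# Labels are a deterministic threshold of feature m1, with a margin so the
# problem is perfectly separable.
threshold_feature_table <- function(n = 40, p = 4, seed = 2) {
  withr::with_seed(seed, {
    x1 <- runif(n)
    x1 <- x1 + 0.25 * sign(x1 - 0.5)
    # companion features echo m1 so no direction of the scaled space is
    # dominated by irrelevant noise
    x <- cbind(x1, sapply(seq_len(p - 1), function(i) x1 + rnorm(n, 0, 0.02)))
    df <- tibble::as_tibble(as.data.frame(x))
    names(df) <- paste0("m", seq_len(p))
    df$label <- factor(ifelse(x1 > 0.5, "high", "low"))
    df
  })
}

# A plain feature table with a planted two-class structure.
make_feature_table <- function(n = 40, p = 5, effect = 2, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c("a", "b"), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    x[label == "b", 1] <- x[label == "b", 1] + effect
    df <- tibble::as_tibble(as.data.frame(x))
    names(df) <- paste0("m", seq_len(p))
    df$label <- factor(label)
    df
  })
}
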