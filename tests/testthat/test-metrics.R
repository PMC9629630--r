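test_that("efficiency metrics match geometry and brute-force oracles", {
  # straight 3-4-5 segment in the viewing plane
  t <- seq(0, 1, by = 1 / 30)
  k <- make_kin(t, x = 3 * t, y = 4 * t, z = 0 * t)
  eff <- compute_efficiency_metrics(k, "z")
  expect_equal(eff$PL, 5, tolerance = 1e-12)
  expect_equal(eff$DPL, 0)
  expect_equal(eff$WA, 0)
  expect_equal(eff$OT, 1, tolerance = 1e-9)

  # 10 x 10 mm square perimeter -> hull area 100
  sq <- rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 5), c(10, 10), c(5, 10),
              c(0, 10), c(0, 5), c(0, 0))
  ks <- make_kin(seq_len(nrow(sq)) / 30, x = sq[, 1], y = sq[, 2],
                 z = rep(0, nrow(sq)))
  expect_equal(compute_efficiency_metrics(ks, "z")$WA, 100)

  # random walk vs brute-force summation and independent hull construction
  withr::with_seed(13, {
    n <- 200
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n)); z <- cumsum(rnorm(n))
    kr <- make_kin(seq_len(n) / 30, x, y, z)
    eff2 <- compute_efficiency_metrics(kr, "z")
    pl_oracle <- 0; dpl_oracle <- 0
    for (i in 1:(n - 1)) {
      pl_oracle <- pl_oracle + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2 +
                                      (z[i + 1] - z[i])^2)
      dpl_oracle <- dpl_oracle + abs(z[i + 1] - z[i])
    }
    expect_equal(eff2$PL, pl_oracle, tolerance = 1e-9)
    expect_equal(eff2$DPL, dpl_oracle, tolerance = 1e-9)
    expect_equal(eff2$WA, hull_area_oracle(x, y), tolerance = 1e-9)
  })

  expect_error(compute_efficiency_metrics(make_kin(0, 1, 1, 1)), "2 samples")
})

test_that("speed metrics are exact for analytic motions", {
  t <- seq(0, 1, by = 1 / 30)
  k <- make_kin(t, x = 3 * t, y = 4 * t, z = 0 * t, vx = 3, vy = 4, vz = 0)
  sp <- compute_speed_metrics(k, "z")
  expect_equal(sp$v_mean, 5)
  expect_equal(sp$a_mean, 0)
  expect_equal(sp$DV, 0)

  kz <- make_kin(t, x = 0 * t, y = 0 * t, z = 2 * t, vz = 2)
  spz <- compute_speed_metrics(kz, "z")
  expect_equal(spz$DV, 2)
  expect_equal(spz$v_mean, 2)

  # minimum-jerk reach, 200 mm in 2 s: sample-mean speed close to D/T
  T <- 2; D <- 200; fs <- 30
  tt <- seq(0, T, by = 1 / fs)
  p <- minimum_jerk_position(c(0, 0, 0), c(D, 0, 0), T, tt)
  tr <- make_track(n = length(tt), fx = function(t) p[, 1],
                   fy = function(t) p[, 2], fz = function(t) p[, 3])
  kin <- smooth_and_differentiate(tr)
  v_mean <- compute_speed_metrics(kin, "z")$v_mean
  # independent analytic oracle at the sample times
  tau <- tt / T
  v_analytic <- D / T * 30 * (tau^2 - 2 * tau^3 + tau^4)
  expect_equal(v_mean, mean(abs(v_analytic)), tolerance = 5e-3)
  expect_equal(v_mean, D / T, tolerance = 0.02)
})

test_that("gripper event detection is hysteresis-robust", {
  fs <- 30
  n_block <- 15
  square <- rep(c(rep(c(0, 40), 4), 0), each = n_block)
  t <- seq_along(square) / fs
  mk <- function(g) make_kin(t, x = t, y = t, z = t, grip = g)
  expect_equal(nrow(detect_gripper_events(mk(rep(0, length(t))))), 0)

  ev <- detect_gripper_events(mk(square), threshold = 20, hysteresis = 5)
  expect_equal(sum(ev$kind == "open"), 4)
  expect_equal(sum(ev$kind == "close"), 4)
  expect_equal(ev$kind, rep(c("open", "close"), 4))

  withr::with_seed(3, {
    noisy <- square + runif(length(square), -4, 4)
    ev2 <- detect_gripper_events(mk(noisy), threshold = 20, hysteresis = 5)
    expect_equal(ev2$kind, ev$kind)
    expect_equal(ev2$time, ev$time)
  })
})

test_that("bimanual metrics behave on constructed pairs", {
  fs <- 30
  t <- seq(0, 4, by = 1 / fs)
  speed_profile <- 5 + 3 * sin(2 * pi * 0.7 * t)
  mk_hand <- function(x0, grip) {
    k <- make_kin(t, x = x0 + 0 * t, y = 0 * t, z = 0 * t,
                  vx = speed_profile, grip = grip)
    k
  }
  grip_wave <- function(cycles) {
    g <- rep(0, length(t))
    starts <- seq(0.2, 3.5, length.out = cycles)
    for (s in starts) g[t >= s & t < s + 0.3] <- 40
    g
  }
  right <- mk_hand(0, grip_wave(4))
  left <- mk_hand(5, grip_wave(2))
  bm <- compute_bimanual_metrics(right, left)
  expect_equal(bm$BD, 1, tolerance = 1e-9)       # identical speed profiles
  expect_equal(bm$ROB, 2)                        # 4 vs 2 open/close cycles
  expect_equal(bm$ADB, 5, tolerance = 1e-9)      # static 5 mm separation
  expect_equal(bm$ADBO, 5, tolerance = 1e-9)

  # degenerate inputs flag missing rather than explode
  static <- make_kin(t, x = 0 * t, y = 0 * t, z = 0 * t)
  bm2 <- compute_bimanual_metrics(static, static)
  expect_true(is.na(bm2$BD))   # zero-variance speed
  expect_true(is.na(bm2$ROB))  # no left-hand events
  expect_true(is.na(bm2$RPLB)) # zero left path length

  # swapping hands inverts the ratios, leaves the symmetric metrics alone
  mov_r <- make_kin(t, x = 10 * t, y = 0 * t, z = 0 * t, vx = 10 + sin(t),
                    grip = grip_wave(4))
  mov_l <- make_kin(t, x = 5 * t + 5, y = 0 * t, z = 0 * t, vx = 5 + cos(t),
                    grip = grip_wave(2))
  ab <- compute_bimanual_metrics(mov_r, mov_l)
  ba <- compute_bimanual_metrics(mov_l, mov_r)
  expect_equal(ba$ROB, 1 / ab$ROB, tolerance = 1e-12)
  expect_equal(ba$RPLB, 1 / ab$RPLB, tolerance = 1e-12)
  expect_equal(ba$BD, ab$BD, tolerance = 1e-12)
  expect_equal(ba$ADB, ab$ADB, tolerance = 1e-12)
  expect_equal(ba$ADBO, ab$ADBO, tolerance = 1e-12)
})

test_that("attitude metrics sum angular excursions correctly", {
  # triangle wave 0 -> 90 -> 0 has total roll variation 180
  roll <- c(seq(0, 90, by = 9), seq(81, 0, by = -9))
  k <- make_kin(seq_along(roll) / 30, x = seq_along(roll), y = 0 * roll,
                z = 0 * roll, roll = roll)
  att <- compute_attitude_metrics(k)
  expect_equal(att$AL_Roll, 180)
  expect_equal(att$AGRA, 8)

  # wrap crossing: 350 -> 10 degrees counts as 20 after unwrapping
  n <- 21
  tr <- make_track(n = n, froll = function(t) (350 + 20 * t / t[length(t)]) %% 360)
  kw <- smooth_and_differentiate(tr)
  expect_equal(compute_attitude_metrics(kw)$AL_Roll, 20, tolerance = 1e-6)

  # spherical-arc oracle on a random smooth pitch/yaw walk
  withr::with_seed(21, {
    m <- 100
    pitch <- cumsum(rnorm(m, 0, 0.8))
    yaw <- cumsum(rnorm(m, 0, 0.8))
    kk <- make_kin(seq_len(m) / 30, x = seq_len(m), y = 0 * pitch, z = 0 * pitch,
                   pitch = pitch, yaw = yaw)
    arc_oracle <- 0
    for (i in 1:(m - 1)) {
      u <- c(cos(pitch[i] * pi / 180) * sin(yaw[i] * pi / 180),
             sin(pitch[i] * pi / 180),
             cos(pitch[i] * pi / 180) * cos(yaw[i] * pi / 180))
      v <- c(cos(pitch[i + 1] * pi / 180) * sin(yaw[i + 1] * pi / 180),
             sin(pitch[i + 1] * pi / 180),
             cos(pitch[i + 1] * pi / 180) * cos(yaw[i + 1] * pi / 180))
      cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      arc_oracle <- arc_oracle + atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
    }
    expect_equal(compute_attitude_metrics(kk)$AL_PitchYaw, arc_oracle,
                 tolerance = 1e-9)
  })
})

test_that("metrics transform correctly under frame changes and time rescaling", {
  curve <- function(tt) cbind(30 * sin(0.8 * tt), 20 * sin(1.6 * tt),
                              10 * cos(0.8 * tt))
  fs <- 30
  t1 <- seq(0, 5, by = 1 / fs)
  t2 <- seq(0, 2.5, by = 1 / fs)
  mk_pos <- function(p, t) make_track(n = length(t), fx = function(.) p[, 1],
                                      fy = function(.) p[, 2],
                                      fz = function(.) p[, 3])
  k1 <- smooth_and_differentiate(mk_pos(curve(t1), t1))
  k2 <- smooth_and_differentiate(mk_pos(curve(2 * t2), t2))
  e1 <- compute_efficiency_metrics(k1); e2 <- compute_efficiency_metrics(k2)
  s1 <- compute_speed_metrics(k1); s2 <- compute_speed_metrics(k2)
  expect_equal(e2$OT, e1$OT / 2, tolerance = 1e-9)
  expect_equal(e2$PL, e1$PL, tolerance = 0.01)
  expect_equal(e2$WA, e1$WA, tolerance = 0.01)
  expect_equal(s2$v_mean, 2 * s1$v_mean, tolerance = 0.01)
  expect_equal(s2$a_mean, 4 * s1$a_mean, tolerance = 0.01)
  expect_equal(s2$j_mean, 8 * s1$j_mean, tolerance = 0.01)

  # translation leaves everything positional unchanged; rotation about the
  # depth axis leaves the depth metrics and working area unchanged
  base <- make_track(n = 120)
  shift <- c(7, -4, 11)
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  pos <- cbind(base$x, base$y, base$z)
  remake <- function(p) instrument_track(
    tibble::tibble(t = base$t, x = p[, 1], y = p[, 2], z = p[, 3],
                   roll = base$roll, pitch = base$pitch, yaw = base$yaw,
                   grip = base$grip), "scissors", "right", 30)
  kb <- smooth_and_differentiate(base)
  kt <- smooth_and_differentiate(remake(sweep(pos, 2, -shift)))
  kz <- smooth_and_differentiate(remake(pos %*% t(Rz)))
  eb <- compute_efficiency_metrics(kb); et <- compute_efficiency_metrics(kt)
  ez <- compute_efficiency_metrics(kz)
  expect_equal(et[c("PL", "DPL", "WA")], eb[c("PL", "DPL", "WA")],
               tolerance = 1e-9)
  expect_equal(ez$DPL, eb$DPL, tolerance = 1e-9)
  expect_equal(ez$WA, eb$WA, tolerance = 1e-6)
  expect_equal(ez$PL, eb$PL, tolerance = 1e-9)
  sb <- compute_speed_metrics(kb); sz <- compute_speed_metrics(kz)
  expect_equal(sz$DV, sb$DV, tolerance = 1e-9)
})

test_that("trial metric vectors assemble with the prefix scheme and invariants", {
  # noise-free single segment: path length equals displacement
  tr <- simulate_trial(noise_free_config(), skill = 1, seed = 9)
  mv <- compute_metric_vector(tr)
  right <- tr$tracks[[1]]
  disp <- sqrt(sum((c(right$x[nrow(right)], right$y[nrow(right)], right$z[nrow(right)]) -
                      c(right$x[1], right$y[1], right$z[1]))^2))
  expect_equal(mv$R_PL, disp, tolerance = 1e-3)
  expect_true(all(c("R_PL", "L_PL", "R_AL_Roll", "L_DV", "BD", "ROB", "OT")
                  %in% names(mv)))

  # invariant sweep over a default synthetic cohort
  feats <- compute_features(generate_cohort(small_config()))
  expect_true(all(c("G_PL", "S_PL", "C_PL", "S_WA", "S_AGRA") %in% names(feats)))
  for (pre in c("G", "S", "C")) {
    expect_true(all(feats[[paste0(pre, "_PL")]] >=
                      feats[[paste0(pre, "_DPL")]] - 1e-9))
    expect_true(all(feats[[paste0(pre, "_WA")]] >= 0))
  }
  expect_true(all(feats$OT > 0))
  bd <- feats$BD[!is.na(feats$BD)]
  expect_true(all(bd >= -1 & bd <= 1))
  expect_true(all(feats$ROB[!is.na(feats$ROB)] >= 0))
  expect_true(all(feats$RPLB[!is.na(feats$RPLB)] >= 0))
})
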