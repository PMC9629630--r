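#' Smooth a track and estimate derivatives with a Savitzky-Golay filter
#'
#' Each tip coordinate is convolved with Savitzky-Golay least-squares
#' coefficients for derivative orders 0-3, scaled by the sample rate, giving
#' the smoothed position together with velocity, acceleration and jerk
#' estimates straight from the filter (not finite differences of the smoothed
#' signal). Boundary samples come from the polynomial fitted to the first and
#' last window rather than from reflection padding, so polynomials up to the
#' fit order are reproduced exactly everywhere. Attitude channels are
#' unwrapped (the +/-180 degree seam removed) and smoothed at order 0; the
#' gripper channel is carried through untouched for event detection.
#'
#' @param track a `mocap_track`.
#' @param window filter window length in samples; odd, `> polyorder`.
#' @param polyorder polynomial order; at least 3 so jerk is estimable.
#' @return A tibble of class `mocap_kin` with columns `t`, smoothed
#'   `x, y, z`, per-axis derivatives `vx..vz`, `ax..az`, `jx..jz`, norm
#'   channels `speed`, `accel`, `jerk`, unwrapped smoothed `roll`, `pitch`,
#'   `yaw`, and raw `grip`; track attributes are carried over.
#' @export
smooth_and_differentiate <- function(track, window = 9, polyorder = 3) {
  stopifnot(inherits(track, "mocap_track"))
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (polyorder < 3) stop("polyorder must be >= 3 to estimate jerk", call. = FALSE)
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  if (nrow(track) < window) {
    stop("track shorter than filter window (", nrow(track), " < ", window, ")",
         call. = FALSE)
  }
  fs <- attr(track, "sample_rate")
  sg <- function(x, m) signal::sgolayfilt(x, p = polyorder, n = window,
                                          m = m, ts = 1 / fs)
  der <- lapply(c(x = "x", y = "y", z = "z"), function(ch) {
    lapply(0:3, function(m) sg(track[[ch]], m))
  })
  unwrap_deg <- function(a) signal::unwrap(a * pi / 180) * 180 / pi
  out <- tibble::tibble(
    t = track$t,
    x = der$x[[1]], y = der$y[[1]], z = der$z[[1]],
    vx = der$x[[2]], vy = der$y[[2]], vz = der$z[[2]],
    ax = der$x[[3]], ay = der$y[[3]], az = der$z[[3]],
    jx = der$x[[4]], jy = der$y[[4]], jz = der$z[[4]],
    roll = sg(unwrap_deg(track$roll), 0),
    pitch = sg(unwrap_deg(track$pitch), 0),
    yaw = sg(unwrap_deg(track$yaw), 0),
    grip = track$grip
  )
  out$speed <- sqrt(out$vx^2 + out$vy^2 + out$vz^2)
  out$accel <- sqrt(out$ax^2 + out$ay^2 + out$az^2)
  out$jerk <- sqrt(out$jx^2 + out$jy^2 + out$jz^2)
  structure(out, class = c("mocap_kin", class(tibble::tibble()))) |>
    set_track_attrs(attr(track, "instrument_id"), attr(track, "hand"), fs)
}

#' Resample two series onto a common timebase
#'
#' Both inputs are linearly interpolated onto a regular grid covering the
#' intersection of their time ranges at their (shared) sample rate; needed
#' for bimanual metrics when the two hands' tracks span different windows.
#'
#' @param a,b data frames with a `t` column and numeric channels (tracks or
#'   kinematic tables).
#' @return A list with elements `a` and `b`, tibbles on the identical grid.
#' @export
resample_to_common_timebase <- function(a, b) {
  fs_a <- attr(a, "sample_rate") %||% (1 / stats::median(diff(a$t)))
  fs_b <- attr(b, "sample_rate") %||% (1 / stats::median(diff(b$t)))
  fs <- max(fs_a, fs_b)
  t0 <- max(min(a$t), min(b$t))
  t1 <- min(max(a$t), max(b$t))
  if (t1 <= t0) stop("time ranges do not overlap", call. = FALSE)
  grid <- seq(t0, t1, by = 1 / fs)
  interp <- function(df) {
    cols <- setdiff(names(df), "t")
    out <- tibble::tibble(t = grid)
    for (ch in cols) {
      if (is.numeric(df[[ch]])) {
        out[[ch]] <- stats::approx(df$t, df[[ch]], xout = grid, rule = 2)$y
      }
    }
    out
  }
  list(a = interp(tibble::as_tibble(a)), b = interp(tibble::as_tibble(b)))
}
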