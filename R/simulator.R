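#' Camera, sensor and motion models for the scene simulator
#'
#' `camera_model` describes a nadir (straight-down) pinhole camera hovering
#' over the field centre: a gimbal-stabilised drone retains only small
#' residual XY translation and yaw rotation, modelled as per-frame random
#' walks; pitch/roll are taken as zero. The default focal length of 2700 px
#' with a 3840 x 2160 image reproduces the ground sampling distance of a
#' 1/2-inch 4K sensor: `GSD = height / focal` metres per pixel (1 cm/px at
#' 27 m).
#'
#' @param height Hover height in metres (27, 50 and 85 are the preset
#'   scenario heights).
#' @param focal Focal length in pixels.
#' @param image_size Width, height of the image in pixels.
#' @param jitter_xy_sd Per-frame random-walk step of the camera ground
#'   position, metres.
#' @param jitter_yaw_sd Per-frame random-walk step of the yaw angle, radians.
#' @param frame_rate Video rate in Hz (default 24).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(height = 27, focal = 2700,
                         image_size = c(3840, 2160),
                         jitter_xy_sd = 0.02, jitter_yaw_sd = 0.002,
                         frame_rate = 24) {
  stopifnot(height > 0, focal > 0, frame_rate > 0, jitter_xy_sd >= 0,
            jitter_yaw_sd >= 0, length(image_size) == 2)
  structure(list(height = height, focal = focal, image_size = image_size,
                 jitter_xy_sd = jitter_xy_sd, jitter_yaw_sd = jitter_yaw_sd,
                 frame_rate = frame_rate),
            class = "camera_model")
}

#' Ground sampling distance of a camera
#'
#' Metres on the ground per image pixel at nadir: `height / focal`.
#'
#' @param cam A [camera_model()].
#' @return Metres per pixel.
#' @export
ground_sampling_distance <- function(cam) cam$height / cam$focal

#' @rdname camera_model
#'
#' @description `sensor_model` describes a wearable positioning stream:
#' sampling rate, positional noise (optionally AR(1)-autocorrelated, since
#' GNSS error is strongly correlated over seconds and white noise would
#' unrealistically inflate distance), an independent Doppler speed-noise
#' channel for GPS, and a dropout probability.
#'
#' @param rate Sampling rate in Hz.
#' @param position_noise_sd Positional noise sd per axis, metres.
#' @param noise_correlation AR(1) coefficient of the positional noise in
#'   `[0, 1)`.
#' @param speed_noise_sd Doppler speed noise sd, km/h (GPS only; 0 disables
#'   the channel).
#' @param dropout_prob Probability that a sample is dropped.
#' @export
sensor_model <- function(rate, position_noise_sd = 0, noise_correlation = 0,
                         speed_noise_sd = 0, dropout_prob = 0) {
  stopifnot(rate > 0, position_noise_sd >= 0, speed_noise_sd >= 0,
            noise_correlation >= 0, noise_correlation < 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(rate = rate, position_noise_sd = position_noise_sd,
                 noise_correlation = noise_correlation,
                 speed_noise_sd = speed_noise_sd, dropout_prob = dropout_prob),
            class = "sensor_model")
}

#' @rdname camera_model
#' @description `gps_model` and `lps_model` are the default sensor presets:
#' GPS at 15 Hz with 0.50 m AR(1)-correlated positional noise (coefficient
#' 0.95) and 0.3 km/h Doppler speed noise; LPS at 20 Hz with 0.10 m noise.
#' @export
gps_model <- function(position_noise_sd = 0.50, noise_correlation = 0.95,
                      speed_noise_sd = 0.3) {
  sensor_model(rate = 15, position_noise_sd = position_noise_sd,
               noise_correlation = noise_correlation,
               speed_noise_sd = speed_noise_sd)
}

#' @rdname camera_model
#' @export
lps_model <- function(position_noise_sd = 0.10, noise_correlation = 0) {
  sensor_model(rate = 20, position_noise_sd = position_noise_sd,
               noise_correlation = noise_correlation)
}

#' @rdname camera_model
#'
#' @description `motion_profile` parameterises simulated player motion:
#' a hard speed cap (team-sport validation samples rarely exceed 14 km/h,
#' which is the default), the bandwidth of the velocity process (Hz) and an
#' acceleration scale.
#'
#' @param max_speed Speed cap in km/h.
#' @param bandwidth Velocity-process bandwidth in Hz; paths are band-limited
#'   below this frequency.
#' @param accel_limit Acceleration scale in m/s^2 (upper bound on the
#'   smooth velocity process's derivative target).
#' @export
motion_profile <- function(max_speed = 14, bandwidth = 0.3, accel_limit = 6) {
  stopifnot(max_speed > 0, bandwidth > 0, accel_limit > 0)
  structure(list(max_speed = max_speed, bandwidth = bandwidth,
                 accel_limit = accel_limit),
            class = "motion_profile")
}

# band-limited standard-normal-ish series: zero-phase 4th-order low-pass of
# white noise, rescaled to unit sd
bandlimited_noise <- function(n, bandwidth, rate) {
  w <- stats::rnorm(n + 2 * rate)          # pad one second each side
  bf <- signal::butter(4, min(0.99, 2 * bandwidth / rate), type = "low")
  f <- zero_phase_filter(bf$b, bf$a, w)[(rate + 1):(rate + n)]
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

#' Simulate ground-truth player trajectories
#'
#' Generates smooth band-limited random motion for `n_players` players
#' confined to the field, sampled at a master rate (default 120 Hz, which is
#' integer-divisible into the 24 / 20 / 15 Hz sensor rates so that sampling
#' the truth never needs interpolation). Players are assigned anchor points
#' on a grid across the field; per player and axis, a displacement process
#' is drawn as low-pass-filtered Gaussian noise at the profile bandwidth and
#' normalized to the anchor's clearance from the walls, then the whole path
#' is scaled down (never up) so the peak instantaneous speed equals 90 % of
#' the cap. The construction guarantees every position is inside the field
#' and every speed is at most `max_speed`, while keeping paths band-limited
#' and smooth (no boundary reflections).
#'
#' @param field A [field_spec()].
#' @param n_players Number of players (>= 1).
#' @param duration Duration in seconds.
#' @param profile A [motion_profile()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param rate Master sampling rate in Hz.
#' @return A [trajectory_table()] at the master rate.
#' @export
simulate_ground_truth <- function(field, n_players, duration,
                                  profile = motion_profile(), seed = 1,
                                  rate = 120) {
  stopifnot(inherits(field, "field_spec"), n_players >= 1, duration > 0)
  m <- 0.5                                   # wall margin, metres
  if ((field$length - 2 * m) * (field$width - 2 * m) < 4 * n_players) {
    stop("field too small to place ", n_players, " players with spacing")
  }
  set.seed(seed)
  n <- round(duration * rate) + 1L
  dt <- 1 / rate
  vmax <- profile$max_speed / 3.6            # m/s
  # anchors on a grid across the field interior
  gx <- ceiling(sqrt(n_players * field$length / field$width))
  gy <- ceiling(n_players / gx)
  ax <- field$length * ((rep(seq_len(gx), times = gy) - 0.5) / gx)
  ay <- field$width * ((rep(seq_len(gy), each = gx) - 0.5) / gy)
  out <- vector("list", n_players)
  t <- (seq_len(n) - 1L) * dt
  for (p in seq_len(n_players)) {
    qx <- bandlimited_noise(n, profile$bandwidth, rate)
    qy <- bandlimited_noise(n, profile$bandwidth, rate)
    qx <- qx / max(abs(qx), 1e-12)           # unit peak displacement
    qy <- qy / max(abs(qy), 1e-12)
    half_x <- max(min(ax[p], field$length - ax[p]) - m, 0.1)
    half_y <- max(min(ay[p], field$width - ay[p]) - m, 0.1)
    dxdt <- diff_central(half_x * qx, dt)
    dydt <- diff_central(half_y * qy, dt)
    peak <- max(sqrt(dxdt^2 + dydt^2))
    s <- if (peak > 0) min(1, 0.9 * vmax / peak) else 0
    out[[p]] <- data.frame(player_id = sprintf("P%02d", p), time = t,
                           x = ax[p] + s * half_x * qx,
                           y = ay[p] + s * half_y * qy,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  trajectory_table(res, rate = rate, field = field)
}

# true instantaneous speed (m/s) per player from master-rate positions:
# central differences interior, one-sided ends
true_speed_ms <- function(traj) {
  rate <- attr(traj, "rate")
  unlist(lapply(split(seq_len(nrow(traj)), traj$player_id), function(i) {
    x <- traj$x[i]; y <- traj$y[i]; n <- length(i)
    diff_central(x, 1 / rate, y)
  }), use.names = FALSE)
}

diff_central <- function(x, h, y = NULL) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  dx <- numeric(n)
  dx[1] <- (x[2] - x[1]) / h
  dx[n] <- (x[n] - x[n - 1]) / h
  if (n > 2) dx[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  if (is.null(y)) return(dx)
  dy <- diff_central(y, h)
  sqrt(dx^2 + dy^2)
}

project_points <- function(xy, cam_xy, yaw, cam) {
  c0 <- cam$image_size / 2
  f_h <- cam$focal / cam$height
  co <- cos(yaw); si <- sin(yaw)
  dx <- xy[, 1] - cam_xy[1]; dy <- xy[, 2] - cam_xy[2]
  cbind(c0[1] + f_h * (co * dx - si * dy),
        c0[2] + f_h * (si * dx + co * dy))
}

# exact pixel->world homography of the nadir pose (affine for a nadir camera)
true_homography <- function(cam_xy, yaw, cam, frame_index = NA_integer_) {
  c0 <- cam$image_size / 2
  g <- cam$height / cam$focal
  co <- cos(yaw); si <- sin(yaw)
  Rt <- rbind(c(co, si), c(-si, co))       # inverse of the yaw rotation
  A <- g * Rt
  b <- cam_xy - A %*% c0
  homography(rbind(cbind(A, b), c(0, 0, 1)), frame_index)
}

#' Render drone detections and control-point observations from ground truth
#'
#' Emulates the aerial video measurement chain at the camera frame rate: the
#' camera pose follows XY/yaw random walks around the field centre, players
#' and control points are projected through the nadir pinhole model, Gaussian
#' pixel noise is added, and player detections are dropped with probability
#' `dropout_prob`. Bounding boxes are squares of `bbox_size_m` metres around
#' the projected player centre. The true per-frame pixel-to-field homography
#' is returned alongside, so downstream stages can be checked against an
#' exact oracle.
#'
#' @param truth A [trajectory_table()] at a master rate divisible by the
#'   camera frame rate (e.g. from [simulate_ground_truth()]); may contain
#'   zero players for a static (control-points only) scene.
#' @param cam A [camera_model()].
#' @param field A [field_spec()].
#' @param pixel_noise_sd Gaussian pixel noise sd added to control-point
#'   observations and box centres.
#' @param dropout_prob Per-detection dropout probability.
#' @param seed Integer seed.
#' @param duration Scene duration in seconds; defaults to the truth's span,
#'   and must be given for a playerless static scene.
#' @param bbox_size_m Side of the square bounding box, metres on the ground.
#' @return List with elements `detections` (data.frame
#'   `frame,time,player_id,u1,v1,u2,v2`), `control_points` (data.frame
#'   `frame,point_id,u,v`) and `homographies` (list of true per-frame
#'   [homography()], pixel to field, named by frame).
#' @export
render_detections <- function(truth, cam, field, pixel_noise_sd = 1,
                              dropout_prob = 0, seed = 1, duration = NULL,
                              bbox_size_m = 0.8) {
  stopifnot(inherits(cam, "camera_model"), inherits(field, "field_spec"))
  has_players <- !is.null(truth) && nrow(truth) > 0
  if (has_players) {
    master <- attr(truth, "rate")
    step <- master / cam$frame_rate
    if (abs(step - round(step)) > 1e-9) {
      stop("master rate must be an integer multiple of the camera frame rate")
    }
    step <- as.integer(round(step))
    if (is.null(duration)) duration <- max(truth$time)
  } else if (is.null(duration)) {
    stop("duration must be given for a static (playerless) scene")
  }
  n_frames <- floor(duration * cam$frame_rate) + 1L
  # coverage check at nominal pose
  ctr <- c(field$length, field$width) / 2
  corners <- cbind(c(0, field$length, field$length, 0),
                   c(0, 0, field$width, field$width))
  px <- project_points(corners, ctr, 0, cam)
  if (any(px[, 1] < 0 | px[, 1] > cam$image_size[1] |
          px[, 2] < 0 | px[, 2] > cam$image_size[2])) {
    stop("camera does not cover the field at the nominal pose")
  }
  set.seed(seed)
  cam_x <- ctr[1] + cumsum(c(0, stats::rnorm(n_frames - 1, 0, cam$jitter_xy_sd)))
  cam_y <- ctr[2] + cumsum(c(0, stats::rnorm(n_frames - 1, 0, cam$jitter_xy_sd)))
  yaw <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, cam$jitter_yaw_sd)))
  cp <- field$control_points
  half_px <- bbox_size_m / 2 * cam$focal / cam$height
  det_list <- vector("list", n_frames)
  cp_list <- vector("list", n_frames)
  hs <- vector("list", n_frames)
  dropped_offimg <- 0L
  players <- if (has_players) unique(truth$player_id) else character()
  if (has_players) {
    truth_by_player <- split(as.data.frame(truth), truth$player_id)
  }
  frames <- seq_len(n_frames) - 1L
  for (k in seq_len(n_frames)) {
    f <- frames[k]
    t_k <- f / cam$frame_rate
    pose_xy <- c(cam_x[k], cam_y[k])
    hs[[k]] <- true_homography(pose_xy, yaw[k], cam, frame_index = f)
    uv <- project_points(cbind(cp$x, cp$y), pose_xy, yaw[k], cam)
    uv <- uv + stats::rnorm(length(uv), 0, pixel_noise_sd)
    cp_list[[k]] <- data.frame(frame = f, point_id = cp$id,
                               u = uv[, 1], v = uv[, 2],
                               stringsAsFactors = FALSE)
    if (has_players) {
      idx <- f * step + 1L
      pxy <- t(vapply(truth_by_player,
                      function(d) c(d$x[idx], d$y[idx]), numeric(2)))
      uvp <- project_points(pxy, pose_xy, yaw[k], cam)
      uvp <- uvp + stats::rnorm(length(uvp), 0, pixel_noise_sd)
      keep <- stats::runif(nrow(uvp)) >= dropout_prob
      inimg <- uvp[, 1] >= 0 & uvp[, 1] <= cam$image_size[1] &
               uvp[, 2] >= 0 & uvp[, 2] <= cam$image_size[2]
      dropped_offimg <- dropped_offimg + sum(!inimg)
      keep <- keep & inimg
      if (any(keep)) {
        det_list[[k]] <- data.frame(
          frame = f, time = t_k, player_id = names(truth_by_player)[keep],
          u1 = uvp[keep, 1] - half_px, v1 = uvp[keep, 2] - half_px,
          u2 = uvp[keep, 1] + half_px, v2 = uvp[keep, 2] + half_px,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped_offimg > 0) {
    warning(dropped_offimg, " player projection(s) outside the image; dropped")
  }
  names(hs) <- frames
  det <- do.call(rbind, det_list[!vapply(det_list, is.null, logical(1))])
  if (is.null(det)) {
    det <- data.frame(frame = integer(), time = numeric(),
                      player_id = character(), u1 = numeric(), v1 = numeric(),
                      u2 = numeric(), v2 = numeric())
  }
  rownames(det) <- NULL
  list(detections = det,
       control_points = do.call(rbind, cp_list),
       homographies = hs)
}

ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

sample_sensor <- function(truth, rate) {
  master <- attr(truth, "rate")
  step <- master / rate
  if (abs(step - round(step)) > 1e-9) {
    stop("sensor rate must divide the master rate")
  }
  step <- as.integer(round(step))
  idx_by_player <- lapply(split(seq_len(nrow(truth)), truth$player_id),
                          function(i) i[seq(1, length(i), by = step)])
  idx_by_player
}

#' Emulate a GPS stream with Doppler speed
#'
#' Samples the ground truth at the sensor rate (timestamps spaced exactly
#' `1/rate` s), adds AR(1)-correlated positional noise per axis, and emits a
#' Doppler speed channel: the true instantaneous speed plus independent white
#' noise — deliberately *not* differentiated noisy positions, mirroring how
#' GPS units derive speed from the satellite signal's frequency shift.
#'
#' @param truth A [trajectory_table()] at the master rate.
#' @param model A [sensor_model()], by default [gps_model()] (15 Hz).
#' @param seed Integer seed.
#' @return `data.frame` with columns `player_id`, `time`, `x`, `y`,
#'   `speed_kmh`, with attribute `rate`.
#' @export
emulate_gps <- function(truth, model = gps_model(), seed = 1) {
  set.seed(seed)
  idx <- sample_sensor(truth, model$rate)
  v_ms <- true_speed_ms(truth)
  out <- lapply(names(idx), function(p) {
    i <- idx[[p]]
    n <- length(i)
    data.frame(
      player_id = p, time = truth$time[i],
      x = truth$x[i] + ar1_noise(n, model$position_noise_sd, model$noise_correlation),
      y = truth$y[i] + ar1_noise(n, model$position_noise_sd, model$noise_correlation),
      speed_kmh = pmax(0, v_ms[i] * 3.6 + stats::rnorm(n, 0, model$speed_noise_sd)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rate") <- model$rate
  res
}

#' Emulate an LPS stream
#'
#' As [emulate_gps()] but at 20 Hz by default, without a Doppler channel, and
#' with an optional clock offset: with `lag` nonzero the emitted timestamps
#' are shifted by exactly that many seconds, which the cross-correlation
#' synchronization must recover.
#'
#' @inheritParams emulate_gps
#' @param model A [sensor_model()], by default [lps_model()] (20 Hz).
#' @param lag Clock offset in seconds added to the emitted timestamps.
#' @return `data.frame` with columns `player_id`, `time`, `x`, `y`.
#' @export
emulate_lps <- function(truth, model = lps_model(), seed = 1, lag = 0) {
  set.seed(seed)
  idx <- sample_sensor(truth, model$rate)
  out <- lapply(names(idx), function(p) {
    i <- idx[[p]]
    n <- length(i)
    data.frame(
      player_id = p, time = truth$time[i] + lag,
      x = truth$x[i] + ar1_noise(n, model$position_noise_sd, model$noise_correlation),
      y = truth$y[i] + ar1_noise(n, model$position_noise_sd, model$noise_correlation),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rate") <- model$rate
  res
}
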