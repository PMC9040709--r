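# Shared fixtures built in code.

# random invertible projective matrix with a nonzero perspective row,
# scaled so typical pixel inputs stay well away from the plane at infinity
random_projective_h <- function(seed) {
  set.seed(seed)
  repeat {
    H <- rbind(c(stats::runif(1, 0.5, 2), stats::runif(1, -0.3, 0.3), stats::runif(1, -50, 50)),
               c(stats::runif(1, -0.3, 0.3), stats::runif(1, 0.5, 2), stats::runif(1, -50, 50)),
               c(stats::runif(2, -2e-4, 2e-4), 1))
    if (abs(det(H)) > 1e-3) return(H)
  }
}

# pixel points spread over an image-like domain
random_pixel_points <- function(n, seed) {
  set.seed(seed)
  cbind(stats::runif(n, 100, 3700), stats::runif(n, 100, 2000))
}

tennis_corners_px <- function(scale = 100) {
  f <- field_preset("tennis")
  cp <- f$control_points[f$control_points$calibration, ]
  list(px = cbind(cp$x, cp$y) * scale, world = cbind(cp$x, cp$y), field = f)
}

# a small rendered scene shared across tests
make_scene <- function(preset = "tennis", n_players = 2, duration = 5,
                       pixel_noise_sd = 0, seed = 7, ...) {
  f <- field_preset(preset)
  tr <- simulate_ground_truth(f, n_players, duration, seed = seed)
  cam <- camera_model(height = attr(f, "camera_height"))
  sc <- render_detections(tr, cam, f, pixel_noise_sd = pixel_noise_sd,
                          seed = seed + 1, ...)
  list(field = f, truth = tr, cam = cam, scene = sc)
}
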