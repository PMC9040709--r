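test_that("field_spec validates its invariants", {
  cp <- data.frame(id = c("a", "b", "c", "d"),
                   x = c(0, 10, 10, 0), y = c(0, 0, 5, 5))
  f <- field_spec("toy", 10, 5, cp)
  expect_s3_class(f, "field_spec")
  expect_error(field_spec("toy", -1, 5, cp), "length")
  expect_error(field_spec("toy", 10, 5, cp[1:3, ]), "4 control points")
  bad <- cp; bad$x[1] <- 50
  expect_error(field_spec("toy", 10, 5, bad), "outside")
})

test_that("field presets carry the published dimensions and setups", {
  t <- field_preset("tennis")
  u <- field_preset("ultimate")
  s <- field_preset("soccer")
  expect_equal(c(t$length, t$width), c(23.77, 8.23))
  expect_equal(c(u$length, u$width), c(97.11, 36.25))
  expect_equal(c(s$length, s$width), c(39, 29))
  expect_equal(sapply(list(t, u, s), attr, "camera_height"), c(27, 85, 50))
  expect_equal(sapply(list(t, u, s), attr, "n_players"), c(2L, 14L, 8L))
  expect_equal(nrow(t$control_points), 8L)
})

test_that("estimating from identical image and world points gives the identity", {
  tc <- tennis_corners_px(scale = 1)
  h <- estimate_homography(tc$world, tc$world)
  expect_equal(h$matrix, diag(3), tolerance = 1e-9)
})

test_that("pure pixel scaling is recovered exactly", {
  tc <- tennis_corners_px(scale = 100)
  h <- estimate_homography(tc$px, tc$world)
  expect_equal(as.vector(apply_homography(h, c(2377, 823))),
               c(23.77, 8.23), tolerance = 1e-9)
})

test_that("DLT recovers a known random projective map from 8 noiseless points", {
  for (seed in 1:20) {
    H <- random_projective_h(seed)
    px <- random_pixel_points(8, seed + 1000)
    world <- apply_homography(homography(H), px)
    rec <- estimate_homography(px, world)
    expect_lt(max(abs(rec$matrix - H / H[3, 3])), 1e-9)
  }
})

test_that("apply_homography handles identity, translation and perspective division", {
  expect_equal(as.vector(apply_homography(homography(diag(3)), c(5, 7))), c(5, 7))
  Ht <- diag(3); Ht[1, 3] <- 5; Ht[2, 3] <- -3
  expect_equal(as.vector(apply_homography(homography(Ht), c(0, 0))), c(5, -3))
  Hp <- diag(3); Hp[3, ] <- c(0.001, 0, 1)
  expect_equal(as.vector(apply_homography(homography(Hp), c(100, 50))),
               c(100 / 1.1, 50 / 1.1), tolerance = 1e-12)
})

test_that("points mapping to the plane at infinity are flagged, not silently dropped", {
  Hp <- diag(3); Hp[3, ] <- c(-0.01, 0, 1)   # w = 0 at u = 100
  expect_warning(out <- apply_homography(homography(Hp), rbind(c(100, 50), c(10, 10))),
                 "infinity")
  expect_true(all(is.na(out[1, ])))
  expect_false(anyNA(out[2, ]))
})

test_that("homography normalization is idempotent and inversion round-trips", {
  H <- random_projective_h(3) * 7.3
  h <- homography(H)
  expect_equal(h$matrix, homography(h$matrix)$matrix)
  expect_equal(h$matrix[3, 3], 1)
  pts <- random_pixel_points(25, 4)
  there <- apply_homography(h, pts)
  back <- apply_homography(inverse_homography(h), there)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("degenerate and undersized configurations raise calibration errors", {
  world <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))   # all collinear
  px <- world * 100
  expect_error(estimate_homography(px[1:3, ], world[1:3, ]), "at least 4")
  expect_error(estimate_homography(px, world), "collinear|degenerate")
  # 3 of 4 collinear
  w2 <- cbind(c(0, 1, 2, 5), c(0, 1, 2, 9))
  expect_error(estimate_homography(w2 * 100, w2), "collinear")
})

test_that("scaling all pixel coordinates leaves reconstructed world points unchanged", {
  H <- random_projective_h(11)
  px <- random_pixel_points(6, 12)
  world <- apply_homography(homography(H), px)
  for (s in c(0.5, 2, 10)) {
    hs <- estimate_homography(px * s, world)
    expect_lt(max(abs(apply_homography(hs, px * s) - world)), 1e-8)
  }
})

test_that("frame-by-frame calibration is reproducible and reports bad frames", {
  f <- field_preset("tennis")
  cp <- f$control_points[f$control_points$calibration, ]
  obs <- do.call(rbind, lapply(0:9, function(fr)
    data.frame(frame = fr, point_id = cp$id, u = cp$x * 100, v = cp$y * 100)))
  hs <- calibrate_frames(obs, f)
  expect_length(hs, 10L)
  for (i in 2:10) expect_equal(hs[[i]]$matrix, hs[[1]]$matrix)
  # one frame missing a point
  obs2 <- obs[!(obs$frame == 7 & obs$point_id == "c1"), ]
  expect_error(calibrate_frames(obs2, f), "frame 7")
  # documented fallback: reuse previous calibration
  hs2 <- calibrate_frames(obs2, f, reuse_last = TRUE)
  expect_length(hs2, 10L)
  expect_true(isTRUE(attr(hs2[["7"]], "reused")))
  expect_equal(hs2[["7"]]$matrix, hs2[["6"]]$matrix)
})

test_that("calibration against simulator drift matches the true per-frame maps", {
  sc <- make_scene("soccer", n_players = 1, duration = 2, pixel_noise_sd = 0)
  hs <- calibrate_frames(sc$scene$control_points, sc$field)
  for (f in names(sc$scene$homographies)) {
    expect_lt(max(abs(hs[[f]]$matrix - sc$scene$homographies[[f]]$matrix)), 1e-6)
  }
})

test_that("reconstruction maps bounding-box centres through the frame's map", {
  hs <- list("0" = homography(diag(3), 0))
  det <- data.frame(frame = 0, time = 0, player_id = "p1",
                    u1 = 10, v1 = 10, u2 = 20, v2 = 20)
  tr <- reconstruct_positions(det, hs)
  expect_equal(c(tr$x, tr$y), c(15, 15))
  # pure scaling: pixels are 100 x metres
  tc <- tennis_corners_px(100)
  h100 <- estimate_homography(tc$px, tc$world)
  det2 <- data.frame(frame = 0, time = 0, player_id = "p1",
                     u1 = 2377 - 5, v1 = 823 - 5, u2 = 2377 + 5, v2 = 823 + 5)
  tr2 <- reconstruct_positions(det2, list("0" = h100))
  expect_equal(c(tr2$x, tr2$y), c(23.77, 8.23), tolerance = 1e-9)
  expect_error(reconstruct_positions(det, list("3" = homography(diag(3)))),
               "no homography")
})

test_that("noiseless simulated scenes round-trip to ground truth", {
  sc <- make_scene("tennis", n_players = 2, duration = 3, pixel_noise_sd = 0)
  hs <- calibrate_frames(sc$scene$control_points, sc$field)
  rec <- reconstruct_positions(sc$scene$detections, hs, field = sc$field)
  m <- merge(as.data.frame(rec), as.data.frame(sc$truth),
             by = c("player_id", "time"))
  expect_gt(nrow(m), 100)
  expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y)), 1e-9)
})

test_that("reprojection error matches hand-computed cases and ignores point order", {
  tc <- tennis_corners_px(1)
  h <- homography(diag(3))
  expect_equal(reprojection_error(h, tc$world, tc$world), 0)
  off <- tc$world
  off[2, ] <- off[2, ] + c(0.03, 0.04)
  expect_equal(reprojection_error(h, tc$world, off), 0.025)
  perm <- sample(4)
  expect_equal(reprojection_error(h, tc$world[perm, ], off[perm, ]), 0.025)
  expect_error(reprojection_error(h, tc$world[0, ], tc$world[0, ]), "at least one")
})

test_that("reprojection error grows with pixel noise in expectation", {
  f <- field_preset("tennis")
  world <- as.matrix(f$control_points[, c("x", "y")])  # 8 points: overdetermined
  px <- world * 100
  sds <- c(0.5, 2, 8)
  mean_err <- sapply(sds, function(s) {
    mean(sapply(1:100, function(seed) {
      set.seed(seed)
      noisy <- px + stats::rnorm(length(px), 0, s)
      h <- estimate_homography(noisy, world)
      reprojection_error(h, noisy, world)
    }))
  })
  expect_true(all(diff(mean_err) > 0))
})
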