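#' Planar homography objects
#'
#' A planar homography is the 8-degree-of-freedom projective map between two
#' planes; here it maps continuous image pixel coordinates `(u, v)` (origin
#' top-left, u rightward, v downward) to field coordinates `(x, y)` in metres.
#' Matrices are stored normalized: scaled so the bottom-right entry is 1, or
#' to unit Frobenius norm (with positive leading sign) when that entry is 0.
#'
#' @param matrix A 3x3 numeric matrix, invertible.
#' @param frame_index Optional integer video frame the calibration belongs to.
#' @return An object of class `homography`.
#' @export
homography <- function(matrix, frame_index = NA_integer_) {
  m <- base::matrix(as.numeric(matrix), 3, 3)
  if (any(!is.finite(m))) stop("homography matrix must be finite")
  m <- normalize_hmat(m)
  d <- abs(det(m))
  if (d < 1e-12) stop("homography matrix is singular")
  structure(list(matrix = m, frame_index = as.integer(frame_index)),
            class = "homography")
}

# scale so H[3,3] == 1, or unit Frobenius norm with sign fixed when H[3,3] == 0
normalize_hmat <- function(m) {
  if (abs(m[3, 3]) > 1e-12 * max(abs(m))) {
    m / m[3, 3]
  } else {
    m <- m / sqrt(sum(m^2))
    lead <- m[which(abs(m) > 1e-12)[1]]
    if (!is.na(lead) && lead < 0) m <- -m
    m
  }
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography>",
      if (!is.na(x$frame_index)) sprintf(" frame %d", x$frame_index), "\n",
      sep = "")
  print(x$matrix)
  invisible(x)
}

#' Invert a homography
#'
#' @param h A [homography()].
#' @return The inverse map as a `homography` (same frame index).
#' @export
inverse_homography <- function(h) {
  homography(solve(h$matrix), h$frame_index)
}

#' Apply a homography to points
#'
#' Homogeneous multiplication followed by perspective division. Points mapping
#' (numerically) to the plane at infinity are returned as `NA` with a warning
#' identifying them.
#'
#' @param h A [homography()].
#' @param pts Two-column matrix or data.frame of input coordinates; a single
#'   point may be given as a length-2 vector.
#' @return A two-column matrix of mapped coordinates, rows in input order.
#' @export
apply_homography <- function(h, pts) {
  stopifnot(inherits(h, "homography"))
  p <- as_xy_matrix(pts)
  ph <- cbind(p, 1) %*% t(h$matrix)
  w <- ph[, 3]
  bad <- abs(w) < 1e-12 * pmax(1, abs(ph[, 1]), abs(ph[, 2]))
  if (any(bad)) {
    warning("point(s) ", paste(which(bad), collapse = ", "),
            " map to the plane at infinity; returning NA")
    w[bad] <- NA_real_
  }
  cbind(ph[, 1] / w, ph[, 2] / w)
}

as_xy_matrix <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, 1:2])
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2, byrow = TRUE)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L) stop("points must have two columns")
  pts
}

collinear3 <- function(p) {
  # area of the triangle relative to its scale
  a <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
           (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
  s <- max(1e-12, max(abs(sweep(p, 2, colMeans(p)))))
  a / s^2 < 1e-9
}

check_degenerate_quad <- function(pts, what) {
  idx <- utils::combn(4L, 3L)
  for (j in seq_len(ncol(idx))) {
    if (collinear3(pts[idx[, j], , drop = FALSE])) {
      stop("degenerate configuration: ", what, " points ",
           paste(idx[, j], collapse = ", "), " are collinear")
    }
  }
}

# Hartley conditioning: translate to the centroid, scale to RMS radius sqrt(2)
hartley_transform <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- rbind(c(s, 0, -s * ctr[1]),
             c(0, s, -s * ctr[2]),
             c(0, 0, 1))
  list(T = T, p = sweep(p, 2, ctr) * s)
}

#' Estimate a homography by the direct linear transform (DLT)
#'
#' Solves for the 3x3 projective matrix H mapping image points to world
#' points from n >= 4 correspondences. Both point sets are conditioned
#' (zero-mean, sqrt(2) RMS radius) before building the 2n x 9 DLT system;
#' the solution is the right singular vector of the smallest singular value,
#' i.e. the algebraic least-squares fit for overdetermined inputs. No
#' iterative geometric refinement is applied: with 4-8 well-spread control
#' points and sub-pixel noise the algebraic solution is already at the noise
#' floor, and it is deterministic.
#'
#' @param image_pts n x 2 pixel coordinates.
#' @param world_pts n x 2 field coordinates (metres), aligned row-by-row with
#'   `image_pts`.
#' @param frame_index Optional frame label attached to the result.
#' @return A [homography()] mapping image to world coordinates.
#' @export
estimate_homography <- function(image_pts, world_pts, frame_index = NA_integer_) {
  p <- as_xy_matrix(image_pts)
  q <- as_xy_matrix(world_pts)
  n <- nrow(p)
  if (nrow(q) != n) stop("image and world point lists differ in length")
  if (n < 4L) {
    stop("calibration error: at least 4 point correspondences are required, got ", n)
  }
  if (any(!is.finite(p)) || any(!is.finite(q))) {
    stop("calibration error: non-finite coordinates")
  }
  if (n == 4L) {
    check_degenerate_quad(q, "world")
    check_degenerate_quad(p, "image")
  }
  hp <- hartley_transform(p)
  hq <- hartley_transform(q)
  pn <- hp$p; qn <- hq$p
  A <- matrix(0, 2 * n, 9)
  u <- pn[, 1]; v <- pn[, 2]; x <- qn[, 1]; y <- qn[, 2]
  odd <- seq(1, 2 * n, by = 2)
  A[odd, 4] <- -u; A[odd, 5] <- -v; A[odd, 6] <- -1
  A[odd, 7] <- y * u; A[odd, 8] <- y * v; A[odd, 9] <- y
  A[odd + 1, 1] <- u; A[odd + 1, 2] <- v; A[odd + 1, 3] <- 1
  A[odd + 1, 7] <- -x * u; A[odd + 1, 8] <- -x * v; A[odd + 1, 9] <- -x
  sv <- svd(A, nu = 0, nv = 9)
  # a unique solution needs nullspace dimension exactly 1
  if (sv$d[8] < 1e-8 * sv$d[1]) {
    stop("degenerate configuration: point set does not determine a unique homography")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(hq$T) %*% Hn %*% hp$T
  homography(H, frame_index)
}

#' Per-frame calibration from control-point observations
#'
#' Estimates one image-to-field homography per video frame from observed
#' control-point pixel positions, matching each observation to the surveyed
#' world coordinates in the field spec by `point_id`. Calibration is
#' performed independently frame by frame so that small camera movements
#' (drift, gimbal jitter) are absorbed rather than propagated.
#'
#' @param obs `data.frame` of control-point observations with columns
#'   `frame`, `point_id`, `u`, `v`.
#' @param field A [field_spec()]; only points flagged `calibration` are used
#'   unless `use_all_points = TRUE`.
#' @param reuse_last If `TRUE`, a frame with fewer than 4 usable control
#'   points inherits the previous frame's calibration (and is flagged);
#'   default `FALSE`, in which case such a frame is an error.
#' @param use_all_points Use every control point in the field spec, not just
#'   the calibration subset.
#' @return A list of [homography()] objects named by frame index, ordered by
#'   frame. Frames that reused a neighbouring calibration carry attribute
#'   `reused = TRUE`.
#' @export
calibrate_frames <- function(obs, field, reuse_last = FALSE, use_all_points = FALSE) {
  stopifnot(inherits(field, "field_spec"))
  obs <- as.data.frame(obs)
  req <- c("frame", "point_id", "u", "v")
  if (!all(req %in% names(obs))) {
    stop("observations must have columns frame, point_id, u, v")
  }
  cp <- field$control_points
  if (!use_all_points) cp <- cp[cp$calibration, , drop = FALSE]
  unknown <- setdiff(unique(obs$point_id), field$control_points$id)
  if (length(unknown) > 0) {
    stop("observed point ids not in field spec: ", paste(unknown, collapse = ", "))
  }
  frames <- sort(unique(obs$frame))
  out <- vector("list", length(frames))
  names(out) <- frames
  last <- NULL
  for (i in seq_along(frames)) {
    f <- frames[i]
    o <- obs[obs$frame == f & obs$point_id %in% cp$id, , drop = FALSE]
    if (nrow(o) < 4L) {
      if (reuse_last && !is.null(last)) {
        h <- last
        attr(h, "reused") <- TRUE
        out[[i]] <- h
        next
      }
      stop("calibration error: frame ", f, " has only ", nrow(o),
           " usable control points (>= 4 required)")
    }
    m <- match(o$point_id, cp$id)
    h <- estimate_homography(cbind(o$u, o$v), cbind(cp$x[m], cp$y[m]),
                             frame_index = f)
    out[[i]] <- h
    last <- h
  }
  out
}

#' Reconstruct player field positions from bounding-box detections
#'
#' Maps the centre of each detection's bounding box through the homography of
#' its frame, yielding a trajectory table in field coordinates at the video
#' rate. Points landing far outside the field are kept but counted in a
#' warning (they usually indicate an identity switch or a bad box, which is a
#' tracking-stage problem, not a geometry one).
#'
#' @param detections `data.frame` of detections with columns `frame`, `time`,
#'   `player_id`, `u1`, `v1`, `u2`, `v2` (see [read_detections()]).
#' @param hs List of [homography()] named by frame, e.g. from
#'   [calibrate_frames()].
#' @param field Optional [field_spec()] used for the out-of-field check and
#'   attached to the result.
#' @param rate Nominal video rate in Hz (default 24).
#' @param margin Metres beyond the field bounds tolerated before a point is
#'   flagged as suspicious.
#' @return A [trajectory_table()] with columns `player_id`, `time`, `x`, `y`.
#' @export
reconstruct_positions <- function(detections, hs, field = NULL, rate = 24,
                                  margin = 2) {
  det <- as.data.frame(detections)
  if (nrow(det) == 0L) {
    return(trajectory_table(
      data.frame(player_id = character(), time = numeric(),
                 x = numeric(), y = numeric()),
      rate = rate, field = field, validate = FALSE))
  }
  missing_h <- setdiff(unique(det$frame), as.numeric(names(hs)))
  if (length(missing_h) > 0) {
    stop("no homography for frame(s): ",
         paste(utils::head(missing_h, 5), collapse = ", "))
  }
  ctr <- bbox_center(det[, c("u1", "v1", "u2", "v2")])
  xy <- matrix(NA_real_, nrow(det), 2)
  for (f in unique(det$frame)) {
    sel <- det$frame == f
    xy[sel, ] <- apply_homography(hs[[as.character(f)]], ctr[sel, , drop = FALSE])
  }
  if (!is.null(field)) {
    out <- xy[, 1] < -margin | xy[, 1] > field$length + margin |
           xy[, 2] < -margin | xy[, 2] > field$width + margin
    if (any(out, na.rm = TRUE)) {
      warning(sum(out, na.rm = TRUE), " reconstructed point(s) lie more than ",
              margin, " m outside the field; retained")
    }
  }
  tr <- data.frame(player_id = det$player_id, time = det$time,
                   x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  tr <- tr[order(tr$player_id, tr$time), ]
  rownames(tr) <- NULL
  trajectory_table(tr, rate = rate, field = field)
}

#' Reprojection root-mean-square error of a calibration
#'
#' RMSE over correspondences of the Euclidean distance between each image
#' point mapped through the homography and its surveyed world position;
#' a quality-control number for a frame's calibration, in metres.
#'
#' @inheritParams estimate_homography
#' @param h A [homography()].
#' @return RMSE in metres (scalar).
#' @export
reprojection_error <- function(h, image_pts, world_pts) {
  p <- as_xy_matrix(image_pts)
  q <- as_xy_matrix(world_pts)
  if (nrow(p) == 0L) stop("at least one correspondence is required")
  if (nrow(p) != nrow(q)) stop("point lists differ in length")
  mapped <- apply_homography(h, p)
  sqrt(mean(rowSums((mapped - q)^2)))
}

#' Reconstruct control-point tracks in field coordinates
#'
#' Maps observed control-point pixels through per-frame homographies; used by
#' the static validation to compare reconstructed marker positions against
#' the surveyed (tachymeter) coordinates.
#'
#' @inheritParams calibrate_frames
#' @param hs List of [homography()] named by frame.
#' @param ids Optional subset of point ids to reconstruct.
#' @return `data.frame` with columns `point_id`, `frame`, `x`, `y`.
#' @export
reconstruct_control_points <- function(obs, hs, ids = NULL) {
  obs <- as.data.frame(obs)
  if (!is.null(ids)) obs <- obs[obs$point_id %in% ids, , drop = FALSE]
  missing_h <- setdiff(unique(obs$frame), as.numeric(names(hs)))
  if (length(missing_h) > 0) {
    stop("no homography for frame(s): ",
         paste(utils::head(missing_h, 5), collapse = ", "))
  }
  xy <- matrix(NA_real_, nrow(obs), 2)
  for (f in unique(obs$frame)) {
    sel <- obs$frame == f
    xy[sel, ] <- apply_homography(hs[[as.character(f)]],
                                  cbind(obs$u[sel], obs$v[sel]))
  }
  data.frame(point_id = obs$point_id, frame = obs$frame,
             x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}
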