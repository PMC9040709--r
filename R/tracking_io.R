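#' Trajectory tables
#'
#' The pipeline's central container: per-player, time-stamped XY positions in
#' field coordinates (metres) at a stated nominal rate. Samples must lie on
#' the rate grid (times are integer multiples of `1/rate` to within 1e-9) and
#' be strictly increasing per player; individual samples may be missing
#' (detection dropouts), which [fill_gaps()] repairs or marks as segment
#' breaks.
#'
#' @param df `data.frame` with columns `player_id`, `time` (s), `x`, `y` (m).
#'   Optional columns `interpolated` (logical) and `segment` (integer) are
#'   preserved.
#' @param rate Nominal sampling rate in Hz.
#' @param field Optional [field_spec()] attached as an attribute.
#' @param validate Check invariants (default `TRUE`).
#' @return The data frame with class `trajectory_table` and attributes
#'   `rate` and `field`.
#' @export
trajectory_table <- function(df, rate, field = NULL, validate = TRUE) {
  df <- as.data.frame(df)
  req <- c("player_id", "time", "x", "y")
  if (!all(req %in% names(df))) {
    stop("trajectory table needs columns player_id, time, x, y")
  }
  if (validate && nrow(df) > 0) {
    if (anyDuplicated(df[, c("player_id", "time")])) {
      stop("duplicate (player_id, time) rows")
    }
    for (p in unique(df$player_id)) {
      tt <- df$time[df$player_id == p]
      if (is.unsorted(tt, strictly = TRUE)) {
        stop("timestamps not strictly increasing for player ", p)
      }
      k <- tt * rate
      if (max(abs(k - round(k))) > 1e-6) {
        stop("timestamps of player ", p, " are not on the 1/", rate, " s grid")
      }
    }
  }
  structure(df, class = c("trajectory_table", "data.frame"),
            rate = rate, field = field)
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf("<trajectory_table> %d samples, %d player(s), %g Hz\n",
              nrow(x), length(unique(x$player_id)), attr(x, "rate")))
  NextMethod()
}

#' Bounding-box centre
#'
#' The tracked position of a player is defined as the centre of the bounding
#' box enclosing the player's outline: `((u1+u2)/2, (v1+v2)/2)`.
#'
#' @param b Length-4 vector `(u1, v1, u2, v2)` or a data.frame/matrix with
#'   those four columns.
#' @return Two-column matrix of pixel centres.
#' @export
bbox_center <- function(b) {
  if (is.data.frame(b)) b <- as.matrix(b)
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2)
}

validate_detections <- function(det, source = "detections") {
  req <- c("frame", "time", "player_id", "u1", "v1", "u2", "v2")
  miss <- setdiff(req, names(det))
  if (length(miss) > 0) {
    stop("format error in ", source, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!(det$u1 < det$u2 & det$v1 < det$v2))
  if (length(bad) > 0) {
    stop("validation error in ", source, ": invalid bounding box at line(s) ",
         paste(bad + 1L, collapse = ", "), " (need u1 < u2 and v1 < v2)")
  }
  ord <- order(det$frame)
  if (is.unsorted(det$time[ord])) {
    stop("validation error in ", source, ": time not non-decreasing with frame")
  }
  det
}

#' Read / write detection CSV files
#'
#' Detections are stored as comma-separated UTF-8 text with header
#' `frame,time,player_id,u1,v1,u2,v2`; pixel coordinates are continuous
#' (sub-pixel). Structurally invalid rows are rejected with their line
#' numbers, never silently repaired.
#'
#' @param path File path.
#' @return `read_detections` returns a validated `data.frame`.
#' @export
read_detections <- function(path) {
  det <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_detections(det, source = path)
}

#' @rdname read_detections
#' @param det Detection `data.frame`.
#' @export
write_detections <- function(det, path) {
  validate_detections(det)
  utils::write.csv(det, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write control-point observation CSV files
#'
#' Header `frame,point_id,u,v`.
#'
#' @param path File path.
#' @export
read_control_points <- function(path) {
  cp <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "point_id", "u", "v")
  miss <- setdiff(req, names(cp))
  if (length(miss) > 0) {
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  cp
}

#' @rdname read_control_points
#' @param cp Control-point observation `data.frame`.
#' @export
write_control_points <- function(cp, path) {
  utils::write.csv(cp[, c("frame", "point_id", "u", "v")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write trajectory CSV files
#'
#' Header `player_id,time,x,y`; optional `interpolated` and `segment`
#' columns round-trip as well.
#'
#' @param path File path.
#' @param rate Nominal rate (Hz) to attach on read.
#' @param field Optional [field_spec()] to attach.
#' @export
read_trajectory <- function(path, rate, field = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trajectory_table(df, rate = rate, field = field)
}

#' @rdname read_trajectory
#' @param traj A [trajectory_table()].
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-frame homography CSV files
#'
#' Row-major export with header `frame,h11,h12,h13,h21,h22,h23,h31,h32,h33`.
#'
#' @param hs List of [homography()] named by frame.
#' @param path File path.
#' @export
write_homographies <- function(hs, path) {
  m <- t(vapply(hs, function(h) as.vector(t(h$matrix)), numeric(9)))
  df <- data.frame(frame = as.numeric(names(hs)), m)
  names(df) <- c("frame", paste0("h", rep(1:3, each = 3), rep(1:3, 3)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_homographies
#' @export
read_homographies <- function(path) {
  df <- utils::read.csv(path)
  hs <- lapply(seq_len(nrow(df)), function(i) {
    homography(matrix(as.numeric(df[i, -1]), 3, 3, byrow = TRUE),
               frame_index = df$frame[i])
  })
  names(hs) <- df$frame
  hs
}

#' Fill short detection gaps by linear interpolation
#'
#' Missing samples on a player's nominal rate grid are repaired when the run
#' of consecutive missing samples is at most `max_gap`: interpolated rows are
#' inserted on the line between the bracketing samples and flagged
#' `interpolated = TRUE`. Longer gaps are left open and start a new `segment`,
#' and downstream distance computation never bridges a segment break, so a
#' dropout cannot teleport a player and inflate distance.
#'
#' @param traj A [trajectory_table()].
#' @param max_gap Maximum number of consecutive missing samples to
#'   interpolate.
#' @return A [trajectory_table()] with `interpolated` and `segment` columns.
#' @export
fill_gaps <- function(traj, max_gap = 5) {
  rate <- attr(traj, "rate")
  out <- lapply(split(as.data.frame(traj), traj$player_id), function(d) {
    d <- d[order(d$time), ]
    k <- round(d$time * rate)
    full <- seq(k[1], k[length(k)])
    have <- full %in% k
    x <- stats::approx(k, d$x, xout = full)$y
    y <- stats::approx(k, d$y, xout = full)$y
    # run-lengths of missing samples decide interpolate vs break
    seg <- integer(length(full)); seg[1] <- 1L
    r <- rle(have)
    keep <- rep(TRUE, length(full))
    pos <- cumsum(c(1L, r$lengths))
    cur_seg <- 1L
    seg_vec <- integer(length(full))
    drop <- logical(length(full))
    for (j in seq_along(r$lengths)) {
      i0 <- pos[j]; i1 <- pos[j] + r$lengths[j] - 1L
      if (!r$values[j] && r$lengths[j] > max_gap) drop[i0:i1] <- TRUE
    }
    seg_id <- cumsum(c(TRUE, drop[-length(drop)] & !drop[-1]))
    res <- data.frame(player_id = d$player_id[1],
                      time = full / rate, x = x, y = y,
                      interpolated = !have,
                      segment = seg_id,
                      stringsAsFactors = FALSE)
    res[!drop, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  trajectory_table(res, rate = rate, field = attr(traj, "field"))
}

#' Occupancy heatmap of a trajectory
#'
#' 2D histogram of trajectory samples over the field extent, the standard
#' visual summary of spatial occupation during a game. Samples outside the
#' field are clipped to the edge bins and counted (the clip tally is
#' reported), so the total count always equals the number of samples.
#'
#' @param traj A [trajectory_table()] (its `field` attribute supplies the
#'   extent) or a data.frame with `x`, `y`.
#' @param nx,ny Number of bins along the length and width.
#' @param field [field_spec()]; required when `traj` carries none.
#' @param normalize Divide counts by the total to give a relative frequency
#'   grid.
#' @return Object of class `heatmap_grid`: list with `x_edges`, `y_edges`,
#'   `counts` (nx x ny matrix), `n_clipped`, `normalized`.
#' @export
heatmap_grid <- function(traj, nx = 20, ny = 10, field = attr(traj, "field"),
                         normalize = FALSE) {
  if (is.null(field)) stop("a field_spec is required for the heatmap extent")
  stopifnot(nx >= 1, ny >= 1)
  x <- pmin(pmax(traj$x, 0), field$length)
  y <- pmin(pmax(traj$y, 0), field$width)
  n_clip <- sum(traj$x < 0 | traj$x > field$length |
                traj$y < 0 | traj$y > field$width)
  if (n_clip > 0) message(n_clip, " sample(s) outside the field clipped to edge bins")
  xe <- seq(0, field$length, length.out = nx + 1)
  ye <- seq(0, field$width, length.out = ny + 1)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), ny)
  counts <- matrix(0, nx, ny)
  tab <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
  counts[] <- as.numeric(tab)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 n_clipped = n_clip, normalized = normalize),
            class = "heatmap_grid")
}

#' @rdname heatmap_grid
#' @param hm A `heatmap_grid`.
#' @param path File path for the long-format CSV (`x_bin,y_bin,count`).
#' @export
write_heatmap <- function(hm, path) {
  df <- expand.grid(x_bin = seq_len(nrow(hm$counts)),
                    y_bin = seq_len(ncol(hm$counts)))
  df$count <- as.vector(hm$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
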