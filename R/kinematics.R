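#' Speed-zone schemes
#'
#' Ordered positive boundaries (km/h) partitioning speed into half-open
#' zones; the default `c(4, 8)` gives stationary/walking `[0, 4)`, jogging
#' `[4, 8)` and quick running `[8, Inf)` km/h. Half-open intervals make the
#' printed zone labels (0-3.9 / 4.0-7.9 / above 8) exhaustive and disjoint:
#' a speed of exactly 4.0 km/h belongs to the jogging zone.
#'
#' @param boundaries Strictly increasing positive boundaries in km/h.
#' @return Object of class `speed_zone_scheme`.
#' @export
speed_zone_scheme <- function(boundaries = c(4, 8)) {
  b <- as.numeric(boundaries)
  if (length(b) < 1 || any(b <= 0) || is.unsorted(b, strictly = TRUE)) {
    stop("zone boundaries must be strictly increasing and positive")
  }
  structure(list(boundaries = b), class = "speed_zone_scheme")
}

#' Linear resampling onto a uniform grid
#'
#' Down-samples (or re-phases) a series onto a uniform grid at `target_rate`
#' by linear interpolation of the original values, the standard way to bring
#' 20 Hz and 24 Hz streams onto a common 15 Hz clock before comparison. The
#' grid spans only the overlap of the source: no extrapolation beyond the
#' endpoints. If the source is already on the target grid the values pass
#' through unchanged.
#'
#' @param time Strictly increasing source timestamps (s).
#' @param values Numeric vector, or matrix/data.frame of columns to resample
#'   together.
#' @param target_rate Target rate in Hz (default 15).
#' @return List with `time` (uniform grid) and `values` (same shape family
#'   as the input).
#' @export
resample_linear <- function(time, values, target_rate = 15) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("source timestamps must be strictly increasing")
  }
  h <- 1 / target_rate
  k0 <- ceiling(time[1] / h - 1e-9)
  k1 <- floor(time[length(time)] / h + 1e-9)
  if (k1 < k0) stop("target grid is empty over the source span")
  grid <- (k0:k1) * h
  vm <- if (is.null(dim(values))) matrix(values, ncol = 1) else as.matrix(values)
  out <- apply(vm, 2, function(col) stats::approx(time, col, xout = grid)$y)
  out <- matrix(out, ncol = ncol(vm))
  colnames(out) <- colnames(vm)
  list(time = grid,
       values = if (is.null(dim(values))) out[, 1] else out)
}

#' Zero-phase Butterworth low-pass filtering of positional data
#'
#' Applies a fourth-order Butterworth low-pass filter forward and backward
#' (`signal::filtfilt`), so the net filter has zero phase lag — phase lag
#' would bias cross-correlation synchronization and shift every kinematic
#' event in time. The forward-backward pass squares the magnitude response,
#' so the amplitude ratio at the cutoff is 1/2 rather than 1/sqrt(2); DC gain
#' is exactly 1 and the output length equals the input length.
#'
#' @param values Numeric vector, or matrix/data.frame of columns filtered
#'   independently (e.g. x and y).
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist rate.
#' @param rate Sampling rate of the series in Hz.
#' @param order Filter order (default 4).
#' @return Filtered object of the same shape.
#' @export
butterworth_lowpass <- function(values, cutoff_hz, rate, order = 4) {
  if (cutoff_hz >= rate / 2) {
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         rate / 2, " Hz)")
  }
  n <- if (is.null(dim(values))) length(values) else nrow(values)
  if (n < 3 * (order + 1) * 3) {
    stop("series too short for stable zero-phase filtering (need > ",
         9 * (order + 1), " samples)")
  }
  bf <- signal::butter(order, 2 * cutoff_hz / rate, type = "low")
  filt1 <- function(col) zero_phase_filter(bf$b, bf$a, col)
  if (is.null(dim(values))) return(filt1(values))
  out <- apply(as.matrix(values), 2, filt1)
  colnames(out) <- colnames(values)
  out
}

# Forward-backward IIR filtering with odd-reflection padding and
# offset-referenced initial conditions, so constants pass exactly and edge
# transients decay inside the padding instead of leaking into the data.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 18L * (max(length(a), length(b)) - 1L))
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  one_pass <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(b, a, z - z0)) + z0
  }
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Speed from uniformly sampled positions
#'
#' Instantaneous speed (km/h) by central differences at interior samples and
#' one-sided differences at the ends; central differences are exact for
#' quadratic position profiles (constant acceleration). Positions should be
#' filtered first and free of gaps (see [fill_gaps()]).
#'
#' @param x,y Position coordinates in metres, uniformly sampled.
#' @param rate Sampling rate in Hz.
#' @return Speed in km/h, same length as the input.
#' @export
speed_from_positions <- function(x, y, rate) {
  if (length(x) < 2) stop("need at least 2 samples to differentiate")
  diff_central(x, 1 / rate, y) * 3.6
}

#' Acceleration from a speed series
#'
#' Differentiates speed (converted to m/s) by the same central-difference
#' scheme as [speed_from_positions()].
#'
#' @param speed_kmh Speed series in km/h, uniformly sampled.
#' @param rate Sampling rate in Hz.
#' @return Acceleration in m/s^2.
#' @export
acceleration_from_speed <- function(speed_kmh, rate) {
  if (length(speed_kmh) < 2) stop("need at least 2 samples to differentiate")
  diff_central(speed_kmh / 3.6, 1 / rate)
}

#' Cumulative distance of a trajectory segment
#'
#' Sum of Euclidean segment lengths between consecutive samples. With a
#' `segment` vector, steps crossing a segment break contribute zero, so
#' dropout gaps never add phantom distance.
#'
#' @param x,y Position coordinates in metres.
#' @param segment Optional integer segment labels (from [fill_gaps()]).
#' @param series If `TRUE` return the running cumulative distance per sample
#'   instead of the total.
#' @return Total metres (scalar) or the cumulative series.
#' @export
cumulative_distance <- function(x, y, segment = NULL, series = FALSE) {
  if (length(x) < 2) {
    return(if (series) numeric(length(x)) else 0)
  }
  d <- sqrt(diff(x)^2 + diff(y)^2)
  if (!is.null(segment)) d[diff(segment) != 0] <- 0
  if (series) c(0, cumsum(d)) else sum(d)
}

#' Per-step distance increments
#'
#' Euclidean step lengths aligned with the intervals between samples
#' (length `n - 1`); steps crossing segment breaks are zero.
#'
#' @inheritParams cumulative_distance
#' @return Numeric vector of length `length(x) - 1`.
#' @export
distance_increments <- function(x, y, segment = NULL) {
  d <- sqrt(diff(x)^2 + diff(y)^2)
  if (!is.null(segment)) d[diff(segment) != 0] <- 0
  d
}

#' Distance by integrating a speed series
#'
#' Trapezoidal integration of speed over time, the natural total-distance
#' estimate for a system whose speed channel is measured independently of
#' its positions (Doppler-based GPS speed). Provided as an alternative to
#' differencing positions ([cumulative_distance()]).
#'
#' @param speed_kmh Uniformly sampled speed series in km/h.
#' @param rate Sampling rate, Hz.
#' @return Total distance in metres.
#' @export
distance_from_speed <- function(speed_kmh, rate) {
  if (length(speed_kmh) < 2) return(0)
  v <- speed_kmh / 3.6
  sum((v[-length(v)] + v[-1]) / 2) / rate
}

#' Distance covered per speed zone
#'
#' Assigns each inter-sample distance increment to the zone of its interval
#' speed, taken as the mean of the two endpoint speeds (symmetric, so the
#' zone totals are conserved under reversal of the trajectory). Increments
#' whose interval speed is `NA` are reported as `unassigned`; zone sums plus
#' the unassigned remainder always equal the total distance.
#'
#' @param speed_kmh Speed series, km/h, length `n`.
#' @param increments Distance increments (m), length `n - 1`, e.g. from
#'   [distance_increments()].
#' @param zones A [speed_zone_scheme()].
#' @return Named numeric vector: one entry per zone (`z1`, `z2`, ...) plus
#'   `unassigned`; attribute `total` holds the summed distance.
#' @export
distance_by_speed_zone <- function(speed_kmh, increments,
                                   zones = speed_zone_scheme()) {
  if (length(increments) != length(speed_kmh) - 1) {
    stop("increments must have length one less than the speed series")
  }
  b <- zones$boundaries
  nz <- length(b) + 1
  interval_speed <- (speed_kmh[-length(speed_kmh)] + speed_kmh[-1]) / 2
  zone <- findInterval(interval_speed, c(0, b))  # 1..nz, NA propagates
  out <- numeric(nz + 1)
  names(out) <- c(paste0("z", seq_len(nz)), "unassigned")
  ok <- !is.na(zone) & zone >= 1
  for (z in seq_len(nz)) out[z] <- sum(increments[ok & zone == z])
  out["unassigned"] <- sum(increments[!ok])
  attr(out, "total") <- sum(increments)
  out
}

#' Synchronize two speed series by cross-correlation
#'
#' Finds the integer-sample lag within `±max_lag` maximizing the normalized
#' cross-correlation (Pearson correlation of the overlapping parts) between
#' two series on a common rate, and shifts `b` onto `a`'s clock. Wearable
#' and video systems have independent clocks; speed traces are the shared
#' signal used to line them up. Ties are broken toward the smallest `|lag|`.
#'
#' @param a,b Numeric series at the same rate.
#' @param rate Common sampling rate, Hz.
#' @param max_lag Maximum lag magnitude searched, seconds.
#' @return List with `lag` (seconds; positive means `b` lags `a`),
#'   `correlation`, and the aligned overlapping series `a`, `b`.
#' @export
align_by_xcorr <- function(a, b, rate, max_lag = 2) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("cross-correlation undefined for a flat (zero-variance) series")
  }
  L <- floor(max_lag * rate)
  n <- min(length(a), length(b))
  if (n <= 2 * L) stop("series overlap must exceed twice the maximum lag")
  lags <- -L:L
  overlap <- function(k) {
    # positive k: b's sample i+k lines up with a's sample i (b lags a)
    if (k >= 0) list(ia = 1:(n - k), ib = (1 + k):n)
    else list(ia = (1 - k):n, ib = 1:(n + k))
  }
  cors <- vapply(lags, function(k) {
    o <- overlap(k)
    suppressWarnings(stats::cor(a[o$ia], b[o$ib]))
  }, numeric(1))
  cors[is.na(cors)] <- -Inf
  best <- max(cors)
  cand <- lags[cors >= best - 1e-12]
  k <- cand[which.min(abs(cand))]
  o <- overlap(k)
  ia <- o$ia; ib <- o$ib
  list(lag = k / rate, correlation = best, a = a[ia], b = b[ib])
}

#' Full kinematic series for one trajectory segment
#'
#' Convenience wrapper chaining the standard per-player processing: zero-phase
#' Butterworth filtering of positions, speed and acceleration by central
#' differences, and running cumulative distance.
#'
#' @param x,y Positions (m) of a single gap-free segment, uniformly sampled.
#' @param rate Sampling rate, Hz.
#' @param cutoff_hz Filter cutoff (default 1 Hz); `NULL` skips filtering.
#' @return `data.frame` with columns `speed_kmh`, `accel_ms2`,
#'   `cum_dist_m`, `x`, `y` (filtered positions).
#' @export
kinematic_series <- function(x, y, rate, cutoff_hz = 1) {
  if (!is.null(cutoff_hz)) {
    xy <- butterworth_lowpass(cbind(x, y), cutoff_hz, rate)
    x <- xy[, 1]; y <- xy[, 2]
  }
  sp <- speed_from_positions(x, y, rate)
  data.frame(speed_kmh = sp,
             accel_ms2 = acceleration_from_speed(sp, rate),
             cum_dist_m = cumulative_distance(x, y, series = TRUE),
             x = x, y = y)
}
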