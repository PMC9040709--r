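#' Root-mean-square error
#'
#' `sqrt(mean((predicted - observed)^2))`, the workhorse accuracy measure for
#' positional validation. For 2D static points, stack the X and Y residuals
#' of each frame into one vector (see [static_validation()]).
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(observed)) stop("lengths differ")
  sqrt(mean((predicted - observed)^2))
}

#' Static validation against surveyed control points
#'
#' Compares reconstructed control-point tracks (marker positions mapped
#' through the per-frame calibration) with their surveyed world coordinates,
#' the gold standard. Per point, the X and Y residuals of every frame are
#' stacked into a single RMSE; the report aggregates across points (mean,
#' sample sd, max) and expresses the mean as a percentage of the field's
#' length and width.
#'
#' @param recon `data.frame` of reconstructed tracks with columns `point_id`,
#'   `frame`, `x`, `y` (see [reconstruct_control_points()]).
#' @param field A [field_spec()] providing the surveyed coordinates and the
#'   field dimensions.
#' @param ids Optional subset of control-point ids to validate (defaults to
#'   every id present in `recon`).
#' @return Object of class `static_validation_report`: list with
#'   `per_point` (data.frame `point_id`, `rmse`, `n_frames`), `mean`, `sd`,
#'   `max` (metres), `pct_of_length`, `pct_of_width`.
#' @export
static_validation <- function(recon, field, ids = NULL) {
  stopifnot(inherits(field, "field_spec"))
  recon <- as.data.frame(recon)
  if (is.null(ids)) ids <- unique(recon$point_id)
  cp <- field$control_points
  missing <- setdiff(ids, cp$id)
  if (length(missing) > 0) {
    stop("point id(s) not in field spec: ", paste(missing, collapse = ", "))
  }
  per <- lapply(ids, function(id) {
    r <- recon[recon$point_id == id, , drop = FALSE]
    if (nrow(r) == 0) stop("no reconstructed frames for point ", id)
    truth <- cp[cp$id == id, ]
    data.frame(point_id = id,
               rmse = rmse(c(r$x, r$y), rep(c(truth$x, truth$y), each = nrow(r))),
               n_frames = nrow(r), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  static_summary(stats::setNames(per$rmse, per$point_id), field, per_point = per)
}

#' Aggregate per-point static RMSEs into a report
#'
#' The aggregation step of [static_validation()] exposed on its own, so a
#' report can also be built from per-point RMSE values computed elsewhere
#' (e.g. a published table).
#'
#' @param rmse_values Named or unnamed numeric vector of per-point RMSEs (m).
#' @param field A [field_spec()] (for the percentage denominators).
#' @param per_point Optional pre-built per-point data.frame.
#' @return A `static_validation_report`.
#' @export
static_summary <- function(rmse_values, field, per_point = NULL) {
  if (is.null(per_point)) {
    per_point <- data.frame(
      point_id = if (is.null(names(rmse_values)))
        paste0("p", seq_along(rmse_values)) else names(rmse_values),
      rmse = as.numeric(rmse_values), n_frames = NA_integer_)
  }
  m <- mean(per_point$rmse)
  structure(list(per_point = per_point,
                 mean = m,
                 sd = if (nrow(per_point) > 1) stats::sd(per_point$rmse) else NA_real_,
                 max = max(per_point$rmse),
                 pct_of_length = 100 * m / field$length,
                 pct_of_width = 100 * m / field$width),
            class = "static_validation_report")
}

#' @export
print.static_validation_report <- function(x, ...) {
  cat(sprintf("<static validation> mean RMSE %.3f m (sd %.3f, max %.3f); %.2f%% of length, %.2f%% of width\n",
              x$mean, x$sd, x$max, x$pct_of_length, x$pct_of_width))
  invisible(x)
}

#' Bland-Altman analysis of two measurement systems
#'
#' Bias (mean of paired differences `a - b`) and 1.96-sd limits of agreement,
#' the standard picture of systematic and random disagreement between two
#' methods measuring the same quantity. The sample (n-1) standard deviation
#' is used. Swapping the systems negates the bias and mirrors the limits.
#'
#' @param a,b Paired measurements (e.g. per-session total distances) from the
#'   two systems; differences are taken as `a - b`.
#' @return List with `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `differences`, `means` (pairwise means, the Bland-Altman x-axis).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  if (length(a) < 2) stop("at least 2 pairs are required (sd undefined)")
  d <- a - b
  s <- stats::sd(d)
  list(n = length(d), bias = mean(d), sd_diff = s,
       loa_low = mean(d) - 1.96 * s, loa_high = mean(d) + 1.96 * s,
       differences = d, means = (a + b) / 2)
}

# two-way ANOVA mean squares for an n x k ratings matrix
icc_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Intraclass correlation coefficient (two-way, single measures)
#'
#' Computes the ICC for paired measurement columns from two-way ANOVA mean
#' squares (Shrout-Fleiss): the consistency form
#' `(MSR - MSE) / (MSR + (k-1) MSE)` ignores a constant offset between
#' systems, while absolute agreement adds the rater variance term
#' `(k/n)(MSC - MSE)` to the denominator and penalizes it. The returned
#' class follows the conventional cut-offs: poor (<= 0.5), moderate
#' (<= 0.75), good (<= 0.9), excellent (> 0.9).
#'
#' @param a,b Paired measurement columns (sessions x systems), n >= 3.
#' @param model `"consistency"` or `"absolute"`.
#' @return List with `icc`, `model`, `class`, and the ANOVA mean squares
#'   (`msr`, `msc`, `mse`).
#' @export
icc <- function(a, b, model = c("consistency", "absolute")) {
  model <- match.arg(model)
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  if (length(a) < 3) stop("at least 3 pairs are required")
  m <- cbind(a, b)
  ms <- icc_mean_squares(m)
  if (ms$msr <= .Machine$double.eps * mean(m)^2) {
    stop("zero between-subject variance: ICC undefined")
  }
  k <- ms$k
  denom <- ms$msr + (k - 1) * ms$mse +
    if (model == "absolute") (k / ms$n) * (ms$msc - ms$mse) else 0
  val <- (ms$msr - ms$mse) / denom
  list(icc = val, model = model, class = icc_class(val),
       msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

icc_class <- function(v) {
  if (v <= 0.5) "poor" else if (v <= 0.75) "moderate"
  else if (v <= 0.9) "good" else "excellent"
}

#' Pearson correlation with effect-size class
#'
#' Product-moment correlation classified by the conventional effect
#' thresholds: small (< 0.3), medium (< 0.5), large (>= 0.5), on the
#' magnitude of r.
#'
#' @param x,y Paired numeric vectors, n >= 3, non-constant.
#' @return List with `r` and `class`.
#' @export
pearson_with_class <- function(x, y) {
  if (length(x) != length(y)) stop("paired inputs must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input")
  }
  r <- stats::cor(x, y)
  cls <- if (abs(r) < 0.3) "small" else if (abs(r) < 0.5) "medium" else "large"
  list(r = r, class = cls)
}

#' Ordinary least-squares agreement regression
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, R-squared, the RMSE
#' of the residuals (computed as `sqrt(mean(residuals^2))`, consistent with
#' [rmse()]), and RMSE as a percentage of the mean of `y`.
#'
#' @param x,y Paired totals from the two systems, n >= 3.
#' @return List with `slope`, `intercept`, `r2`, `rmse`, `rmse_pct`.
#' @export
regression_fit <- function(x, y) {
  if (length(x) != length(y)) stop("paired inputs must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0) stop("regression undefined for constant x")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  rm <- sqrt(mean(res^2))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       rmse = rm,
       rmse_pct = 100 * rm / mean(y))
}

#' Coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, n >= 2, nonzero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("at least 2 values are required")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Mean percentage absolute difference between paired totals
#'
#' Mean over paired sessions of `100 * |a - b| / b`, with the reference
#' system `b` as denominator.
#'
#' @param a Totals from the system under test.
#' @param b Totals from the reference system (nonzero).
#' @return Percentage.
#' @export
percent_abs_difference <- function(a, b) {
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  if (any(b == 0)) stop("reference totals must be nonzero")
  mean(100 * abs(a - b) / b)
}

#' Full agreement report for a system pair
#'
#' Bundles the dynamic-validation statistics for paired per-session totals:
#' Bland-Altman bias and limits of agreement, Pearson r with class, both ICC
#' variants with classes, OLS regression R-squared / RMSE / RMSE%, per-system
#' coefficients of variation and the mean percentage absolute difference.
#' Differences are oriented `a - b` and percentage differences use `b` as
#' reference.
#'
#' @param a,b Paired per-session totals for the two systems.
#' @param names Labels for the two systems.
#' @return Object of class `agreement_report` (a list of the statistics).
#' @export
agreement_report <- function(a, b, names = c("a", "b")) {
  ba <- bland_altman(a, b)
  ic <- icc(a, b, "consistency")
  ia <- icc(a, b, "absolute")
  pc <- pearson_with_class(a, b)
  rg <- regression_fit(b, a)
  structure(list(
    systems = names, n = length(a),
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    sd_diff = ba$sd_diff,
    pearson_r = pc$r, pearson_class = pc$class,
    icc_consistency = ic$icc, icc_consistency_class = ic$class,
    icc_absolute = ia$icc, icc_absolute_class = ia$class,
    r2 = rg$r2, regression_rmse = rg$rmse, rmse_pct = rg$rmse_pct,
    cv_a = cv_percent(a), cv_b = cv_percent(b),
    pct_abs_difference = percent_abs_difference(a, b)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement> %s vs %s (n = %d)\n", x$systems[1], x$systems[2], x$n))
  cat(sprintf("  bias %.2f [LoA %.2f, %.2f]\n", x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  ICC consistency %.3f (%s), absolute %.3f (%s)\n",
              x$icc_consistency, x$icc_consistency_class,
              x$icc_absolute, x$icc_absolute_class))
  cat(sprintf("  r %.3f (%s), R2 %.3f, RMSE %.2f (%.2f%%), |diff| %.2f%%\n",
              x$pearson_r, x$pearson_class, x$r2, x$regression_rmse,
              x$rmse_pct, x$pct_abs_difference))
  invisible(x)
}
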