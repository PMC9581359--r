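#' Fit the stochastic Index of Difficulty to a trial ensemble
#'
#' The central model of the package. From n repeated trajectories it builds
#' the mean path, the stochastic width profile \eqn{W_{obs}(s, \phi)} and the
#' cumulative stochastic Index of Difficulty
#' \deqn{ID_{obs}(s^*, \phi) = \int_0^{s^*} \frac{ds}{W_{obs}(s, \phi)},}
#' the integral of the reciprocal width along the average trajectory from the
#' start to the curvilinear coordinate \eqn{s^* \in [0, |\bar t|]}. Small
#' dispersion (a narrow tube of trials, i.e. low motor flexibility) makes the
#' integrand large: difficulty accumulates fastest where the movement is most
#' constrained. The quantity is dimensionless — path length and width share
#' units — so uniform spatial scaling of all trials leaves it unchanged.
#'
#' @param ensemble A [trial_ensemble()], or anything [read_trials()] accepts
#'   (a path, passed through).
#' @param phi Probability level of the confidence ellipse, default 0.95.
#' @param M Number of section planes along the mean path, default 200.
#' @param regime Confidence scaling regime, see [c_squared()].
#' @param center Section PCA centering, see [plane_pca()].
#' @param w_min Guard width in mm (default 1e-6): any plane whose
#'   interpolated width falls at or below it aborts the fit, since the
#'   difficulty integral diverges as the tube closes.
#' @param ... Further arguments passed to [width_profile()].
#' @return An object of class `idobs`: list with `ensemble` (labels and n),
#'   `path` ([mean_path()]), `width` ([width_profile()]), `s`, `ID`
#'   (cumulative profile, `ID[1] = 0`), `total` (ID at `s* = |t-bar|`),
#'   `phi`, and `call`.
#' @examples
#' spec <- generator_spec(n = 7, seed = 1)
#' ens <- simulate_trials(spec)
#' fit <- idobs(ens, M = 60)
#' coef(fit)
#' @export
idobs <- function(ensemble, phi = 0.95, M = 200L,
                  regime = c("hotelling", "chi2"),
                  center = c("centroid", "path"),
                  w_min = 1e-6, ...) {
  cl <- match.call()
  if (is.character(ensemble)) ensemble <- read_trials(ensemble)
  stopifnot(inherits(ensemble, "trial_ensemble"))
  regime <- match.arg(regime)
  center <- match.arg(center)
  path <- mean_path(ensemble, M = M)
  width <- width_profile(ensemble, path = path, phi = phi, regime = regime,
                         center = center, ...)
  prof <- id_profile(width, w_min = w_min)
  structure(list(ensemble = list(subject = ensemble$subject,
                                 condition = ensemble$condition,
                                 n = length(ensemble$trials)),
                 path = path, width = width,
                 s = prof$s, ID = prof$ID, total = prof$total,
                 phi = phi, call = cl),
            class = "idobs")
}

#' Cumulative difficulty profile from a width profile
#'
#' Cumulative trapezoid of \eqn{1/W(s)} over the arc-length grid. The
#' trapezoid rule is applied on the grid the widths are known on (no
#' resampling inside the integral) and is exact for a constant integrand.
#'
#' @param width A [width_profile()], or a list/data frame with numeric
#'   elements `s` and `W` for a user-supplied deterministic width (the
#'   trajectory-ID generalization with target width \eqn{W_t(s)}).
#' @param w_min Divergence guard in mm; any `W <= w_min` is an error naming
#'   the offending arc length.
#' @return List of class `id_profile` with `s`, `ID` (same length,
#'   `ID[1] = 0`, non-decreasing) and `total`.
#' @export
id_profile <- function(width, w_min = 1e-6) {
  s <- width$s
  W <- width$W
  if (length(s) != length(W) || length(s) < 2L)
    stop("'s' and 'W' must be equal-length vectors of length >= 2")
  if (is.unsorted(s, strictly = TRUE))
    stop("'s' must be strictly increasing")
  bad <- which(W <= w_min)
  if (length(bad))
    stop("width <= w_min (", format(w_min), " mm) at s = ",
         format(s[bad[1L]], digits = 6),
         " mm: the difficulty integral diverges")
  ID <- pracma::cumtrapz(s, 1 / W)[, 1L]
  ID[1L] <- 0
  structure(list(s = s, ID = ID, total = ID[length(ID)]),
            class = "id_profile")
}

#' Trajectory index of difficulty with a deterministic width
#'
#' The deterministic generalization of Fitts' index to a constrained path: a
#' trajectory traversed as an infinite sequence of reaching tasks with local
#' target width \eqn{W_t(s)}, giving \eqn{\int ds / W_t(s)}. Identical
#' integration contract to the stochastic profile, with the width supplied by
#' the task geometry instead of observed variability.
#'
#' @param s Arc-length grid (mm), strictly increasing.
#' @param W_t Target widths on the grid (mm), all positive.
#' @param w_min Divergence guard, see [id_profile()].
#' @return The total (dimensionless) difficulty of the path.
#' @export
id_t <- function(s, W_t, w_min = 1e-6) {
  id_profile(list(s = s, W = W_t), w_min = w_min)$total
}

#' Classical point-to-point indices of difficulty
#'
#' Fitts' original formulation \eqn{ID = \log_2(2D/W)} and MacKenzie's
#' variant \eqn{ID = \log_2(D/W + 1)} (bits), for a target of width `W` at
#' distance `D`. Provided as deterministic baselines for the stochastic
#' index.
#'
#' @param D Movement distance, >= 0.
#' @param W Target width, > 0.
#' @param variant `"fitts"` or `"mackenzie"`.
#' @return Index of difficulty in bits.
#' @examples
#' fitts_id(100, 100)                        # 1 bit
#' fitts_id(300, 100, "mackenzie")           # 2 bits
#' @export
fitts_id <- function(D, W, variant = c("fitts", "mackenzie")) {
  variant <- match.arg(variant)
  if (any(W <= 0)) stop("'W' must be positive")
  if (any(D < 0)) stop("'D' must be non-negative")
  switch(variant,
    fitts = log2(2 * D / W),
    mackenzie = log2(D / W + 1))
}

# ---- methods for the fitted object ----------------------------------------

#' @export
print.idobs <- function(x, digits = 4, ...) {
  cat("Stochastic Index of Difficulty fit\n")
  cat(sprintf("  subject '%s', condition '%s', n = %d trials\n",
              x$ensemble$subject, x$ensemble$condition, x$ensemble$n))
  cat(sprintf("  mean path length %.1f mm over %d planes; phi = %g (%s regime)\n",
              x$path$total_length, length(x$s), x$phi, x$width$scale$regime))
  cat(sprintf("  total ID_obs = %s\n", format(x$total, digits = digits)))
  invisible(x)
}

#' @export
summary.idobs <- function(object, ...) {
  W <- object$width$W
  out <- list(ensemble = object$ensemble,
              phi = object$phi,
              regime = object$width$scale$regime,
              c2 = object$width$scale$c2,
              length_mm = object$path$total_length,
              planes = length(object$s),
              invalid_planes = sum(!object$width$valid),
              W_summary = summary(W),
              total = object$total)
  class(out) <- "summary.idobs"
  out
}

#' @export
print.summary.idobs <- function(x, ...) {
  cat("Stochastic Index of Difficulty — summary\n")
  cat(sprintf("  subject '%s', condition '%s', n = %d trials\n",
              x$ensemble$subject, x$ensemble$condition, x$ensemble$n))
  cat(sprintf("  phi = %g, %s regime, c2 = %.4f\n", x$phi, x$regime, x$c2))
  cat(sprintf("  mean path %.1f mm, %d planes (%d interpolated)\n",
              x$length_mm, x$planes, x$invalid_planes))
  cat("  W_obs (mm):\n")
  print(x$W_summary)
  cat(sprintf("  total ID_obs = %.4f\n", x$total))
  invisible(x)
}

#' @export
coef.idobs <- function(object, ...) {
  c(total_ID = object$total,
    path_length_mm = object$path$total_length,
    mean_W_mm = mean(object$width$W),
    phi = object$phi,
    c2 = object$width$scale$c2)
}

#' Evaluate the cumulative difficulty at arbitrary arc lengths
#'
#' Linear interpolation of the fitted \eqn{ID_{obs}(s^*, \phi)} profile;
#' values outside \eqn{[0, |\bar t|]} are clamped to the ends.
#'
#' @param object An [idobs()] fit.
#' @param s Arc lengths (mm) at which to evaluate; defaults to the fitted
#'   grid.
#' @param ... Unused.
#' @return Numeric vector of ID values.
#' @export
predict.idobs <- function(object, s = NULL, ...) {
  if (is.null(s)) return(object$ID)
  stats::approx(object$s, object$ID, xout = s, rule = 2)$y
}

#' Plot width and difficulty profiles of a fit
#'
#' Two stacked panels: the stochastic width \eqn{W_{obs}(s, \phi)} and the
#' cumulative \eqn{ID_{obs}(s^*, \phi)} against arc length.
#'
#' @param x An [idobs()] fit.
#' @param ... Passed to the underlying `plot` calls.
#' @export
plot.idobs <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$s, x$width$W, type = "l", xlab = "s (mm)",
                 ylab = expression(W[obs] ~ (mm)),
                 main = sprintf("Stochastic width, phi = %g", x$phi), ...)
  if (any(!x$width$valid))
    graphics::points(x$s[!x$width$valid], x$width$W[!x$width$valid],
                     pch = 4, col = "red")
  graphics::plot(x$s, x$ID, type = "l", xlab = "s* (mm)",
                 ylab = expression(ID[obs]),
                 main = "Cumulative stochastic index of difficulty", ...)
  invisible(x)
}

#' Write the fitted profiles as CSV
#'
#' Columns `s_mm`, `W_mm`, `ID`.
#'
#' @param fit An [idobs()] fit.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_idobs <- function(fit, file) {
  stopifnot(inherits(fit, "idobs"))
  utils::write.csv(data.frame(s_mm = fit$s, W_mm = fit$width$W, ID = fit$ID),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
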