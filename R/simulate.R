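#' Specification of a synthetic trial generator
#'
#' Describes a repetitive reach-transport-return manipulation cycle with a
#' known mean path and prescribed in-plane dispersion, so that every stage of
#' the analysis can be exercised against ground truth. The default geometry
#' emulates a seated tabletop task: the hand starts at the table edge,
#' reaches the grasp point 300 mm into the table, transports the object
#' 500 mm to a release point placed symmetrically on the other side, and
#' returns to the start. Dispersion follows a per-phase bell: broad at
#' mid-phase (travelling, where the end-effector is free to vary) with
#' minima at the grasp/release/return events (positioning, where accuracy is
#' required).
#'
#' @param waypoints Numeric matrix of ordered 3D event positions (mm), one
#'   row per event; default the 4-point cycle above.
#' @param lift Height (mm) of mid-segment control points inserted between
#'   consecutive waypoints, emulating the hand lifting over the table;
#'   0 keeps the path planar.
#' @param n Number of trials per ensemble, default 7 (one experimental
#'   condition's worth of repetitions).
#' @param M Samples per simulated trial, default 150.
#' @param sigma_max,sigma_min Largest / smallest first-PC dispersion (mm)
#'   of the per-phase bell profile; defaults 20 and 2.
#' @param anisotropy Ratio of second- to first-PC dispersion, default 0.6.
#' @param sigma_profile Optional override: function of normalized arc
#'   length `u` in \[0, 1\] returning a 2-column matrix
#'   `(sigma_eps, sigma_eta)` in mm.
#' @param speed_model `"minjerk"` (per-phase minimum-jerk timing, default)
#'   or `"constant"`.
#' @param cycle_time Total cycle duration in seconds, default 3; phases get
#'   equal durations, so longer phases have higher peak speeds.
#' @param corr_length Correlation length of the along-path noise process as
#'   a fraction of total path length, default 0.1; uncorrelated noise would
#'   produce non-physical jagged trials.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param subject,condition Labels for generated ensembles.
#' @return An object of class `idobs_spec`.
#' @export
generator_spec <- function(waypoints = NULL, lift = 60, n = 7L, M = 150L,
                           sigma_max = 20, sigma_min = 2, anisotropy = 0.6,
                           sigma_profile = NULL,
                           speed_model = c("minjerk", "constant"),
                           cycle_time = 3, corr_length = 0.1, seed = NULL,
                           subject = "sim", condition = "default") {
  if (is.null(waypoints)) {
    waypoints <- rbind(start   = c(0, 0, 0),
                       grasp   = c(250, 300, 0),
                       release = c(-250, 300, 0),
                       final   = c(0, 0, 0))
  }
  waypoints <- as.matrix(waypoints)
  if (ncol(waypoints) != 3L || nrow(waypoints) < 2L)
    stop("'waypoints' must be a matrix of >= 2 rows and 3 columns")
  gaps <- sqrt(rowSums(diff(waypoints)^2))
  if (any(gaps == 0))
    stop("coincident consecutive waypoints at row ", which(gaps == 0)[1L])
  if (sigma_max < 0 || sigma_min < 0 || sigma_min > sigma_max)
    stop("need 0 <= sigma_min <= sigma_max")
  if (anisotropy < 0 || anisotropy > 1)
    stop("'anisotropy' must be in [0, 1]")
  if (n < 2L) stop("'n' must be >= 2")
  speed_model <- match.arg(speed_model)
  structure(list(waypoints = waypoints, lift = lift, n = as.integer(n),
                 M = as.integer(M), sigma_max = sigma_max,
                 sigma_min = sigma_min, anisotropy = anisotropy,
                 sigma_profile = sigma_profile, speed_model = speed_model,
                 cycle_time = cycle_time, corr_length = corr_length,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 subject = subject, condition = condition),
            class = "idobs_spec")
}

#' @export
print.idobs_spec <- function(x, ...) {
  cat(sprintf("Trial generator: %d waypoints, n = %d trials x %d samples, sigma %g-%g mm (ratio %g), %s timing over %g s\n",
              nrow(x$waypoints), x$n, x$M, x$sigma_min, x$sigma_max,
              x$anisotropy, x$speed_model, x$cycle_time))
  invisible(x)
}

#' Build the generator's mean path
#'
#' Natural cubic splines through the waypoints (plus optional lifted
#' mid-segment control points), parametrized by cumulative chord length.
#' The evaluation grid always contains the control-point parameters, so the
#' returned path passes through every waypoint exactly.
#'
#' @param spec An [generator_spec()].
#' @param M Approximate number of path points, default 200.
#' @return A [mean_path()] object, with attributes `event_u` (normalized
#'   arc-length positions of the waypoints) and `event_idx` (their row
#'   indices in the path).
#' @export
make_mean_path <- function(spec, M = 200L) {
  stopifnot(inherits(spec, "idobs_spec"))
  wp <- spec$waypoints
  ctrl <- wp
  is_wp <- rep(TRUE, nrow(wp))
  if (spec$lift != 0 && nrow(wp) >= 2L) {
    mids <- (wp[-nrow(wp), , drop = FALSE] + wp[-1L, , drop = FALSE]) / 2
    mids[, 3L] <- mids[, 3L] + spec$lift
    ctrl <- matrix(NA_real_, nrow(wp) + nrow(mids), 3L)
    ctrl[seq(1L, nrow(ctrl), by = 2L), ] <- wp
    ctrl[seq(2L, nrow(ctrl), by = 2L), ] <- mids
    is_wp <- seq_len(nrow(ctrl)) %% 2L == 1L
  }
  u_ctrl <- cum_arclen(ctrl)
  u_ctrl <- u_ctrl / max(u_ctrl)
  grid <- sort(unique(c(seq(0, 1, length.out = as.integer(M)), u_ctrl)))
  xyz <- sapply(1:3, function(j)
    stats::spline(u_ctrl, ctrl[, j], xout = grid, method = "natural")$y)
  path <- new_mean_path(xyz)
  wp_idx <- match(u_ctrl[is_wp], grid)
  attr(path, "event_idx") <- wp_idx
  attr(path, "event_u") <- path$s[wp_idx] / path$total_length
  path
}

# per-phase bell dispersion profile: sigma_eps rises from sigma_min at each
# event to sigma_max at mid-phase; sigma_eta = anisotropy * sigma_eps
sigma_profile_fun <- function(spec, event_u) {
  if (!is.null(spec$sigma_profile)) return(spec$sigma_profile)
  force(event_u)
  function(u) {
    u <- pmin(pmax(u, 0), 1)
    phase <- findInterval(u, event_u, rightmost.closed = TRUE,
                          all.inside = TRUE)
    lo <- event_u[phase]; hi <- event_u[phase + 1L]
    v <- ifelse(hi > lo, (u - lo) / (hi - lo), 0)
    se <- spec$sigma_min + (spec$sigma_max - spec$sigma_min) * sin(pi * v)^2
    cbind(sigma_eps = se, sigma_eta = spec$anisotropy * se)
  }
}

#' Ground-truth dispersion of the generator at given arc positions
#'
#' @param spec An [generator_spec()].
#' @param u Normalized arc-length positions in \[0, 1\].
#' @return 2-column matrix `(sigma_eps, sigma_eta)` in mm.
#' @export
generator_sigma <- function(spec, u) {
  path <- make_mean_path(spec)
  sigma_profile_fun(spec, attr(path, "event_u"))(u)
}

#' Generator-predicted stochastic width
#'
#' The width the analysis should recover on simulated data: twice the mean
#' confidence-ellipse radius computed from the generator's own dispersion
#' profile, \eqn{2\, r_{mean}(\sigma_\epsilon(u), \sigma_\eta(u))} at the
#' scale `c2`.
#'
#' @param spec An [generator_spec()].
#' @param u Normalized arc-length positions in \[0, 1\].
#' @param c2 A [c_squared()] object or positive number; default the
#'   Hotelling scale for `spec$n` trials at `phi = 0.95`.
#' @return Predicted widths (mm).
#' @export
predicted_width <- function(spec, u, c2 = NULL) {
  if (is.null(c2)) c2 <- c_squared(n = spec$n, phi = 0.95)
  if (inherits(c2, "confidence_scale")) c2 <- c2$c2
  sg <- generator_sigma(spec, u)
  vapply(seq_along(u), function(i)
    2 * mean_radius(sg[i, 1L], sg[i, 2L], c2), numeric(1))
}

#' Simulate a trial ensemble
#'
#' Each trial is the mean path plus smooth correlated dispersion drawn in
#' the local orthogonal plane: two independent Gaussian processes along
#' normalized arc length (squared-exponential correlation, length
#' `corr_length`), scaled pointwise by the dispersion profile and applied
#' along a continuously transported in-plane frame. Time stamps follow the
#' spec's speed model. Reproducible for a fixed `spec$seed`.
#'
#' @param spec An [generator_spec()].
#' @param path Optional precomputed [make_mean_path()] result.
#' @return A [trial_ensemble()] of `spec$n` trials.
#' @export
simulate_trials <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "idobs_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(path)) path <- make_mean_path(spec)
  # trial base: M points equispaced in arc length along the path
  base <- resample_trajectory(
    trajectory(t = seq(0, 1, length.out = nrow(path$xyz)), xyz = path$xyz),
    M = spec$M, mode = "arclength")$xyz
  M <- spec$M
  u <- cum_arclen(base)
  u <- u / max(u)
  tang <- path_tangents(base)
  frames <- transport_frames(tang)
  sg <- sigma_profile_fun(spec, attr(path, "event_u"))(u)
  tt <- time_stamps(spec, u)
  Lc <- gp_chol(u, spec$corr_length)
  trials <- vector("list", spec$n)
  for (k in seq_len(spec$n)) {
    a_eps <- drop(Lc %*% stats::rnorm(M)) * sg[, 1L]
    a_eta <- drop(Lc %*% stats::rnorm(M)) * sg[, 2L]
    xyz <- base + a_eps * frames$e1 + a_eta * frames$e2
    trials[[k]] <- trajectory(t = tt, xyz = xyz,
                              trial_id = sprintf("trial%02d", k))
  }
  trial_ensemble(trials, subject = spec$subject, condition = spec$condition)
}

#' @rdname simulate_trials
#' @param object An [generator_spec()] (for the [stats::simulate()]
#'   generic).
#' @param nsim Number of ensembles to draw.
#' @param seed Overrides `object$seed` (then incremented per ensemble).
#' @param ... Unused.
#' @return For `simulate`: a list of `nsim` ensembles.
#' @export
simulate.idobs_spec <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$seed <- as.integer(seed)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    if (!is.null(object$seed)) object$seed <- object$seed + (i > 1L)
    out[[i]] <- simulate_trials(object)
  }
  out
}

# continuously transported orthonormal in-plane frames along the path:
# previous normal projected onto the new plane and re-normalized
transport_frames <- function(tang) {
  M <- nrow(tang)
  e1 <- matrix(NA_real_, M, 3L)
  e2 <- matrix(NA_real_, M, 3L)
  e1[1L, ] <- plane_basis(tang[1L, ])[, 1L]
  for (i in seq_len(M)[-1L]) {
    v <- e1[i - 1L, ] - sum(e1[i - 1L, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) v <- plane_basis(tang[i, ])[, 1L] else v <- v / nv
    e1[i, ] <- v
  }
  for (i in seq_len(M))
    e2[i, ] <- c(tang[i, 2L] * e1[i, 3L] - tang[i, 3L] * e1[i, 2L],
                 tang[i, 3L] * e1[i, 1L] - tang[i, 1L] * e1[i, 3L],
                 tang[i, 1L] * e1[i, 2L] - tang[i, 2L] * e1[i, 1L])
  list(e1 = e1, e2 = e2)
}

# Cholesky factor of the squared-exponential correlation over grid u
gp_chol <- function(u, corr_length) {
  if (corr_length <= 0) return(diag(length(u)))
  D <- outer(u, u, `-`)
  K <- exp(-D^2 / (2 * corr_length^2))
  diag(K) <- diag(K) + 1e-8
  t(chol(K))
}

# time stamps for arc positions u in [0,1] under the spec's speed model;
# phases get equal shares of cycle_time
time_stamps <- function(spec, u) {
  if (spec$speed_model == "constant") return(u * spec$cycle_time)
  path <- make_mean_path(spec)
  ev <- attr(path, "event_u")
  n_ph <- length(ev) - 1L
  Tph <- spec$cycle_time / n_ph
  tt <- numeric(length(u))
  tau_fine <- seq(0, 1, length.out = 2001L)
  v_fine <- 10 * tau_fine^3 - 15 * tau_fine^4 + 6 * tau_fine^5  # min-jerk s-curve
  for (j in seq_len(n_ph)) {
    lo <- ev[j]; hi <- ev[j + 1L]
    in_ph <- if (j < n_ph) u >= lo & u < hi else u >= lo & u <= hi
    v <- (u[in_ph] - lo) / (hi - lo)
    tau <- stats::approx(v_fine, tau_fine, xout = pmin(pmax(v, 0), 1),
                         ties = "ordered")$y
    tt[in_ph] <- (j - 1L) * Tph + tau * Tph
  }
  # enforce strict monotonicity against interpolation round-off
  tt <- cummax(tt)
  dup <- which(diff(tt) <= 0)
  while (length(dup)) {
    tt[dup + 1L] <- tt[dup] + 1e-9
    dup <- which(diff(tt) <= 0)
  }
  tt
}

#' Named condition presets emulating manipulated objects
#'
#' Conditions differ only in the amplitude of the dispersion profile,
#' standing in for grasp types: objects held with a constrained grip allow
#' less end-effector variability (smaller widths, higher difficulty). No
#' physical fidelity is claimed.
#'
#' @param base A [generator_spec()] to scale; defaults to
#'   `generator_spec()`.
#' @return Named list of specs:
#'   `tennis_ball`, `bottle_full`, `bottle_half`, `ellipsoid_soft`,
#'   `ellipsoid_stiff`.
#' @export
condition_presets <- function(base = generator_spec()) {
  amp <- c(tennis_ball = 1.0, bottle_full = 0.7, bottle_half = 0.72,
           ellipsoid_soft = 1.2, ellipsoid_stiff = 1.18)
  out <- lapply(names(amp), function(nm) {
    sp <- base
    sp$sigma_max <- base$sigma_max * amp[[nm]]
    sp$sigma_min <- base$sigma_min * amp[[nm]]
    sp$condition <- nm
    sp
  })
  names(out) <- names(amp)
  out
}
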