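#' Speed profile of an ensemble along the normalized path
#'
#' Per-trial speed by central differences of position over time, mapped to
#' normalized arc length \eqn{u \in [0, 1]} (consistent with the width and
#' difficulty grids, which are spatial), resampled to a shared grid and
#' averaged across trials. Repetitive reach-type movements yield the
#' familiar bell-shaped profiles with peaks near mid-phase.
#'
#' @param ensemble A [trial_ensemble()].
#' @param M Grid size on \[0, 1\], default 100.
#' @return An object of class `speed_profile`: list with `u` (length M),
#'   `mean_speed` (mm/s), and `trial_speeds` (M x n matrix).
#' @export
speed_profile <- function(ensemble, M = 100L) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  M <- as.integer(M)
  if (M < 2L) stop("'M' must be >= 2")
  grid <- seq(0, 1, length.out = M)
  sp <- sapply(ensemble$trials, function(tr) {
    m <- nrow(tr$xyz)
    if (m < 3L)
      stop("trial '", tr$trial_id, "' has ", m,
           " samples; speed estimation needs at least 3")
    # centered differences, one-sided at the ends
    iw <- cbind(c(1L, seq_len(m - 2L), m - 1L),
                c(2L, seq_len(m - 2L) + 2L, m))
    dt <- tr$t[iw[, 2L]] - tr$t[iw[, 1L]]
    v <- sqrt(rowSums((tr$xyz[iw[, 2L], , drop = FALSE] -
                       tr$xyz[iw[, 1L], , drop = FALSE])^2)) / dt
    u <- cum_arclen(tr$xyz)
    u <- u / max(u)
    keep <- c(TRUE, diff(u) > 0)
    stats::approx(u[keep], v[keep], xout = grid, rule = 2)$y
  })
  sp <- matrix(sp, nrow = M)
  structure(list(u = grid, mean_speed = rowMeans(sp), trial_speeds = sp),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("Speed profile: %d grid points, %d trials, peak %.1f mm/s at u = %.2f\n",
              length(x$u), ncol(x$trial_speeds), max(x$mean_speed),
              x$u[which.max(x$mean_speed)]))
  invisible(x)
}

#' Peak speed within each movement phase
#'
#' Maximum of the mean speed profile within each supplied interval of
#' normalized position, with its location. Ties are broken by the earliest
#' `u`.
#'
#' @param profile A [speed_profile()].
#' @param phase_bounds List of length-2 numeric vectors `(lo, hi)` within
#'   \[0, 1\], non-overlapping.
#' @return Data frame with columns `phase`, `u_lo`, `u_hi`, `u_peak`,
#'   `peak` (mm/s).
#' @export
phase_peaks <- function(profile, phase_bounds) {
  stopifnot(inherits(profile, "speed_profile"))
  if (!is.list(phase_bounds)) phase_bounds <- list(phase_bounds)
  b <- t(vapply(phase_bounds, function(x) as.numeric(x[1:2]), numeric(2)))
  if (any(b < 0) || any(b > 1) || any(b[, 1L] >= b[, 2L]))
    stop("phase bounds must be non-empty intervals within [0, 1]")
  o <- order(b[, 1L])
  if (any(b[o, 1L][-1L] < b[o, 2L][-nrow(b)]))
    stop("phase bounds must not overlap")
  out <- lapply(seq_len(nrow(b)), function(j) {
    idx <- which(profile$u >= b[j, 1L] & profile$u <= b[j, 2L])
    if (!length(idx))
      stop("no grid points inside phase interval [", b[j, 1L], ", ",
           b[j, 2L], "]")
    v <- profile$mean_speed[idx]
    i_max <- idx[which.max(v)]   # which.max: earliest index on ties
    data.frame(phase = j, u_lo = b[j, 1L], u_hi = b[j, 2L],
               u_peak = profile$u[i_max], peak = profile$mean_speed[i_max])
  })
  do.call(rbind, out)
}

#' Phase boundaries from speed minima (helper)
#'
#' Splits \[0, 1\] at the `n_phases - 1` deepest interior local minima of
#' the mean speed profile. A convenience for unlabelled data; the contract
#' interface is user-supplied bounds (e.g. the generator's event positions).
#'
#' @param profile A [speed_profile()].
#' @param n_phases Number of phases expected.
#' @param min_sep Minimal spacing (in normalized position) between detected
#'   cut points and from the path ends, default 0.1.
#' @return List of `(lo, hi)` intervals covering \[0, 1\].
#' @export
phase_bounds_from_minima <- function(profile, n_phases, min_sep = 0.1) {
  v <- profile$mean_speed
  m <- length(v)
  i_min <- which(v[2:(m - 1L)] <= v[1:(m - 2L)] &
                 v[2:(m - 1L)] <= v[3:m]) + 1L
  i_min <- i_min[order(v[i_min])]      # deepest first
  cuts <- numeric(0)
  for (i in i_min) {                   # greedy, enforcing separation
    u0 <- profile$u[i]
    if (length(cuts) == n_phases - 1L) break
    if (all(abs(u0 - c(cuts, 0, 1)) >= min_sep)) cuts <- c(cuts, u0)
  }
  if (length(cuts) < n_phases - 1L)
    stop("found only ", length(cuts) + 1L, " phases")
  edges <- c(0, sort(cuts), 1)
  lapply(seq_len(n_phases), function(j) c(edges[j], edges[j + 1L]))
}

#' Write a speed profile as CSV
#'
#' Columns `u`, `speed_mm_s`.
#'
#' @param profile A [speed_profile()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_speed_profile <- function(profile, file) {
  stopifnot(inherits(profile, "speed_profile"))
  utils::write.csv(data.frame(u = profile$u, speed_mm_s = profile$mean_speed),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
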