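#' Average trajectory of an ensemble
#'
#' Each trial is resampled to `M` points by normalized arc length and the
#' trials are averaged pointwise, giving the mean path t-bar. Correspondence
#' by arc length (rather than time) makes the average independent of speed
#' fluctuations, matching the purely spatial difficulty integral. Tangents
#' are unit central differences on the resampled mean, one-sided at the
#' endpoints.
#'
#' @param ensemble A [trial_ensemble()].
#' @param M Grid size (number of planes), default 200.
#' @return An object of class `mean_path`: list with `xyz` (M x 3), `s`
#'   (arc-length grid, mm, `s[1] = 0`), `tangents` (M x 3 unit rows) and
#'   `total_length` (mm).
#' @export
mean_path <- function(ensemble, M = 200L) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  if (M < 2) stop("'M' must be >= 2")
  M <- as.integer(M)
  for (tr in ensemble$trials)
    if (arc_length(tr) <= 0)
      stop("degenerate trial '", tr$trial_id, "': zero arc length")
  res <- lapply(ensemble$trials, resample_trajectory, M = M, mode = "arclength")
  avg <- Reduce(`+`, lapply(res, `[[`, "xyz")) / length(res)
  new_mean_path(avg)
}

# build a mean_path object from an M x 3 matrix of ordered points
new_mean_path <- function(xyz) {
  xyz <- as.matrix(xyz)
  s <- cum_arclen(xyz)
  structure(list(xyz = xyz, s = s, tangents = path_tangents(xyz),
                 total_length = s[length(s)]),
            class = "mean_path")
}

# unit tangents: central differences, one-sided at the ends
path_tangents <- function(xyz) {
  M <- nrow(xyz)
  d <- rbind(xyz[2L, ] - xyz[1L, ],
             xyz[3:M, , drop = FALSE] - xyz[1:(M - 2L), , drop = FALSE],
             xyz[M, ] - xyz[M - 1L, ])
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm == 0))
    stop("zero-length tangent on the mean path (coincident grid points)")
  d / nrm
}

#' @export
print.mean_path <- function(x, ...) {
  cat("Mean path: ", nrow(x$xyz), " points, total arc length ",
      format(x$total_length, digits = 6), " mm\n", sep = "")
  invisible(x)
}

#' Trial crossings of the orthogonal plane at one grid point
#'
#' The plane P(s) passes through the mean-path point p(s) with normal equal
#' to the path tangent there. For every trial, each polyline segment whose
#' endpoints fall on opposite sides of P(s) is a candidate crossing, located
#' by linear interpolation; if a trial crosses several times, the crossing
#' nearest p(s) within the plane is kept (ties broken by earliest position
#' along the trial). Trials that never cross are reported in `missing`, not
#' raised as errors.
#'
#' @param ensemble A [trial_ensemble()].
#' @param path The [mean_path()] built from it (or a geometrically
#'   compatible one).
#' @param s_index Grid index, 1-based, into `path$s`.
#' @return An object of class `plane_crossing`: list with `s_index`, `s`,
#'   `q` (matrix of crossing points, one row per crossing trial), `trial_ids`
#'   and `missing` (trial ids with no crossing).
#' @export
plane_crossings <- function(ensemble, path, s_index) {
  stopifnot(inherits(ensemble, "trial_ensemble"), inherits(path, "mean_path"))
  s_index <- as.integer(s_index)
  if (s_index < 1L || s_index > nrow(path$xyz))
    stop("'s_index' out of range")
  p0 <- path$xyz[s_index, ]
  nv <- path$tangents[s_index, ]
  q <- vector("list", length(ensemble$trials))
  ids <- vapply(ensemble$trials, `[[`, character(1), "trial_id")
  hit <- logical(length(ids))
  for (k in seq_along(ensemble$trials)) {
    ck <- segment_plane_crossing(ensemble$trials[[k]]$xyz, p0, nv)
    if (!is.null(ck)) {
      q[[k]] <- ck
      hit[k] <- TRUE
    }
  }
  if (!any(hit))
    stop("no trial crosses the plane at s_index = ", s_index,
         " (s = ", format(path$s[s_index], digits = 6), " mm)")
  structure(list(s_index = s_index, s = path$s[s_index],
                 q = do.call(rbind, q[hit]),
                 trial_ids = ids[hit], missing = ids[!hit]),
            class = "plane_crossing")
}

# crossing of one polyline with the plane through p0 with unit normal nv;
# returns the crossing nearest p0 in-plane (earliest on tie), or NULL
segment_plane_crossing <- function(pts, p0, nv) {
  d <- drop((pts - matrix(p0, nrow(pts), 3, byrow = TRUE)) %*% nv)
  n <- length(d)
  on_plane <- which(d == 0)
  i <- which(d[-n] * d[-1L] < 0)
  cand <- NULL
  if (length(i)) {
    w <- d[i] / (d[i] - d[i + 1L])
    cand <- pts[i, , drop = FALSE] * (1 - w) + pts[i + 1L, , drop = FALSE] * w
  }
  if (length(on_plane))
    cand <- rbind(pts[on_plane, , drop = FALSE], cand)
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  # project candidates exactly onto the plane (kills round-off drift)
  off <- drop((cand - matrix(p0, nrow(cand), 3, byrow = TRUE)) %*% nv)
  cand <- cand - outer(off, nv)
  r2 <- rowSums((cand - matrix(p0, nrow(cand), 3, byrow = TRUE))^2)
  cand[which.min(r2), ]  # which.min takes the earliest on ties
}

#' Dump crossings for every plane as a tidy CSV (diagnostic)
#'
#' One row per (plane, trial): columns `s`, `trial`, `qx`, `qy`, `qz`.
#' Useful for plotting section clouds around the mean path.
#'
#' @param ensemble A [trial_ensemble()].
#' @param path Its [mean_path()].
#' @param file Output CSV path, or `NULL` to return the data frame.
#' @return The data frame, invisibly if written.
#' @export
write_crossings <- function(ensemble, path, file = NULL) {
  rows <- lapply(seq_along(path$s), function(i) {
    cr <- tryCatch(plane_crossings(ensemble, path, i), error = function(e) NULL)
    if (is.null(cr)) return(NULL)
    data.frame(s = cr$s, trial = cr$trial_ids,
               qx = cr$q[, 1], qy = cr$q[, 2], qz = cr$q[, 3])
  })
  out <- do.call(rbind, rows)
  if (is.null(file)) return(out)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(out)
}
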