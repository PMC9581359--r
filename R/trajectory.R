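#' Construct a trial trajectory
#'
#' A trajectory is one trial's ordered, time-stamped sequence of 3D
#' end-effector positions. Internally all positions are in millimetres and
#' all times in seconds.
#'
#' @param t Numeric vector of time stamps in seconds, strictly increasing.
#' @param xyz Numeric matrix with 3 columns (x, y, z) in millimetres, one row
#'   per time stamp.
#' @param trial_id Label for the trial (coerced to character).
#' @return An object of class `trajectory`: a list with elements `trial_id`,
#'   `t` and `xyz`.
#' @examples
#' tr <- trajectory(t = 0:3 / 10, xyz = cbind(0:3 * 10, 0, 0))
#' arc_length(tr)
#' @export
trajectory <- function(t, xyz, trial_id = "trial") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  t <- as.numeric(t)
  if (ncol(xyz) != 3L)
    stop("'xyz' must have exactly 3 columns (x, y, z)")
  if (nrow(xyz) != length(t))
    stop("point count (", nrow(xyz), ") does not match time-stamp count (",
         length(t), ")")
  if (length(t) < 2L)
    stop("a trajectory needs at least 2 points")
  if (anyNA(t) || anyNA(xyz) || any(!is.finite(t)) || any(!is.finite(xyz)))
    stop("non-finite values in trajectory '", trial_id, "'")
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop("time stamps not strictly increasing in trial '", trial_id,
         "' at row ", bad)
  }
  colnames(xyz) <- c("x", "y", "z")
  structure(list(trial_id = as.character(trial_id), t = t, xyz = xyz),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory '", x$trial_id, "': ", nrow(x$xyz), " points, ",
      format(diff(range(x$t)), digits = 4), " s, arc length ",
      format(arc_length(x), digits = 6), " mm\n", sep = "")
  invisible(x)
}

#' Polyline arc length of a trajectory (mm)
#'
#' @param x A `trajectory`, or a numeric matrix of ordered 3D points.
#' @return Total length of the polyline through the points, in mm.
#' @export
arc_length <- function(x) {
  pts <- if (inherits(x, "trajectory")) x$xyz else as.matrix(x)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# cumulative chord length from the first point, length nrow(pts)
cum_arclen <- function(pts) {
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

#' Bundle trials into an ensemble
#'
#' A trial ensemble is the unit of analysis: the n repeated trajectories of
#' one subject under one condition, sharing a coordinate frame and units.
#' At least `nu1 + 1 = 3` trials are needed for the small-sample (Hotelling)
#' confidence scaling to have a positive F denominator; the constructor
#' enforces the weaker structural minimum n >= 2 and the width stage enforces
#' the statistical one.
#'
#' @param trials List of [trajectory()] objects, length >= 2.
#' @param subject,condition Labels.
#' @return An object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(trials, subject = "subject", condition = "condition") {
  if (!is.list(trials) || length(trials) < 2L)
    stop("an ensemble needs at least 2 trials (got ", length(trials), ")")
  ok <- vapply(trials, inherits, logical(1), what = "trajectory")
  if (!all(ok))
    stop("all elements of 'trials' must be trajectory objects")
  structure(list(subject = as.character(subject),
                 condition = as.character(condition),
                 trials = trials),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat("Trial ensemble: subject '", x$subject, "', condition '", x$condition,
      "', n = ", length(x$trials), " trials\n", sep = "")
  invisible(x)
}

#' @export
length.trial_ensemble <- function(x) length(x$trials)

#' Read trial trajectories from CSV
#'
#' Accepts either a single long-format CSV with columns
#' `trial, t, x, y, z` (one block per trial) or a directory of per-trial CSVs
#' each with columns `t, x, y, z`. Units are taken as seconds and millimetres
#' unless `scale` converts them.
#'
#' @param source Path to a CSV file or a directory of CSV files.
#' @param schema Named character vector mapping the canonical column names
#'   `t`, `x`, `y`, `z` (and optionally `trial`) to the names used in the
#'   files.
#' @param subject,condition Labels attached to the returned ensemble.
#' @param scale Length multiplier applied to coordinates on input (e.g. 1000
#'   for files in metres); times are multiplied by `time_scale`.
#' @param time_scale Time multiplier, see `scale`.
#' @return A [trial_ensemble()].
#' @export
read_trials <- function(source, schema = NULL, subject = "subject",
                        condition = "condition", scale = 1, time_scale = 1) {
  map <- c(trial = "trial", t = "t", x = "x", y = "y", z = "z")
  if (!is.null(schema)) map[names(schema)] <- schema
  read_one <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- map[c("t", "x", "y", "z")]
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("file '", path, "' is missing column(s): ",
           paste(miss, collapse = ", "))
    df
  }
  make_traj <- function(df, id) {
    trajectory(t = df[[map["t"]]] * time_scale,
               xyz = cbind(df[[map["x"]]], df[[map["y"]]], df[[map["z"]]]) * scale,
               trial_id = id)
  }
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) < 2L)
      stop("directory '", source, "' holds ", length(files),
           " csv files; an ensemble needs at least 2 trials")
    trials <- lapply(files, function(f) {
      make_traj(read_one(f), sub("\\.csv$", "", basename(f)))
    })
  } else if (file.exists(source)) {
    df <- read_one(source)
    if (!map["trial"] %in% names(df))
      stop("long-format file '", source, "' is missing the '",
           map["trial"], "' column")
    ids <- unique(df[[map["trial"]]])
    if (length(ids) < 2L)
      stop("file '", source, "' holds ", length(ids),
           " trial(s); an ensemble needs at least 2")
    trials <- lapply(ids, function(id) {
      make_traj(df[df[[map["trial"]]] == id, , drop = FALSE], id)
    })
  } else {
    stop("source '", source, "' does not exist")
  }
  trial_ensemble(trials, subject = subject, condition = condition)
}

#' Write an ensemble to the long CSV dialect
#'
#' Emits the same `trial,t,x,y,z` dialect [read_trials()] accepts, so
#' write/read round trips are value-preserving to printed precision.
#'
#' @param ensemble A [trial_ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  rows <- lapply(ensemble$trials, function(tr) {
    data.frame(trial = tr$trial_id, t = tr$t,
               x = tr$xyz[, 1], y = tr$xyz[, 2], z = tr$xyz[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a trajectory to M equispaced samples
#'
#' Linear interpolation at M equispaced parameters; endpoints are preserved
#' exactly. In `"arclength"` mode the parameter is normalized cumulative
#' chord length (so output points are equispaced along the polyline); in
#' `"time"` mode it is the time stamp. Time stamps are carried through by the
#' same interpolation.
#'
#' @param traj A [trajectory()].
#' @param M Number of output samples, >= 2.
#' @param mode `"arclength"` (default) or `"time"`.
#' @return A [trajectory()] of length `M`.
#' @export
resample_trajectory <- function(traj, M, mode = c("arclength", "time")) {
  stopifnot(inherits(traj, "trajectory"))
  mode <- match.arg(mode)
  if (!is.numeric(M) || length(M) != 1L || M < 2)
    stop("'M' must be a single number >= 2")
  M <- as.integer(M)
  par <- switch(mode,
    arclength = cum_arclen(traj$xyz),
    time = traj$t)
  if (max(par) <= 0)
    stop("degenerate trial '", traj$trial_id, "': zero total ",
         if (mode == "arclength") "arc length" else "duration")
  # collapse duplicated parameter values (repeated points in arclength mode)
  keep <- c(TRUE, diff(par) > 0)
  par <- par[keep]
  grid <- seq(par[1L], par[length(par)], length.out = M)
  xyz <- apply(traj$xyz[keep, , drop = FALSE], 2,
               function(v) stats::approx(par, v, xout = grid)$y)
  tt <- stats::approx(par, traj$t[keep], xout = grid)$y
  # guard against round-off at the endpoints
  xyz[1L, ] <- traj$xyz[1L, ]
  xyz[M, ] <- traj$xyz[nrow(traj$xyz), ]
  trajectory(t = tt, xyz = xyz, trial_id = traj$trial_id)
}

#' Moving-average smoothing of a trajectory (optional, off by default)
#'
#' Centered moving average of the coordinates with an odd window; time stamps
#' are untouched. Raw marker noise suppression is deliberately minimal: the
#' dispersion across trials is the signal here, so smoothing defaults to off
#' in every pipeline entry point.
#'
#' @param traj A [trajectory()].
#' @param window Odd integer window length; `1` is the identity.
#' @return A smoothed [trajectory()].
#' @export
smooth_trajectory <- function(traj, window = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("'window' must be a positive odd integer")
  if (window == 1L) return(traj)
  n <- nrow(traj$xyz)
  h <- (window - 1L) %/% 2L
  sm <- traj$xyz
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    sm[i, ] <- colMeans(traj$xyz[lo:hi, , drop = FALSE])
  }
  trajectory(t = traj$t, xyz = sm, trial_id = traj$trial_id)
}
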