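#' Squared confidence scale for the dispersion ellipse
#'
#' The standard-deviation ellipse of the section crossings is inflated to a
#' confidence region at probability level `phi` by the squared scale c2.
#' With a small sample of n trials the scale is the Hotelling T-squared
#' quantile
#' \deqn{c^2 = \frac{(n-1)\,\nu_1}{n\,(n-\nu_1)}\; F_{\nu_1,\; n-\nu_1,\; \phi},}
#' with \eqn{\nu_1 = 2} the in-plane dimensionality. When the whole
#' population is known (or n is large) the squared Mahalanobis distance
#' applies instead: the chi-squared quantile with \eqn{\nu_1} degrees of
#' freedom. The two regimes are defined exactly as stated and do not meet in
#' the large-n limit (T2 decreases below the chi-squared quantile as n
#' grows); the choice of regime is the caller's.
#'
#' @param n Number of trials (ignored in the population regime).
#' @param phi Probability level in (0, 1), default 0.95.
#' @param population_known If `TRUE` use the chi-squared (Mahalanobis)
#'   regime; otherwise the Hotelling small-sample regime (default).
#' @param nu1 In-plane dimensionality, 2 for 3D movement data.
#' @return An object of class `confidence_scale`: list with `phi`, `nu1`,
#'   `nu2`, `c2` and `regime`.
#' @examples
#' c_squared(n = 7, phi = 0.95)$c2                       # 1.984
#' c_squared(phi = 0.95, population_known = TRUE)$c2     # 5.992
#' @export
c_squared <- function(n = NULL, phi = 0.95, population_known = FALSE, nu1 = 2L) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 1)
    stop("'phi' must be a single probability strictly inside (0, 1)")
  nu1 <- as.integer(nu1)
  if (population_known) {
    return(structure(list(phi = phi, nu1 = nu1, nu2 = Inf,
                          c2 = stats::qchisq(phi, df = nu1),
                          regime = "chi2"),
                     class = "confidence_scale"))
  }
  if (is.null(n)) stop("'n' is required in the Hotelling regime")
  n <- as.integer(n)
  if (n <= nu1)
    stop("Hotelling regime needs n > nu1 = ", nu1,
         " trials (F denominator df = n - nu1 would be <= 0); got n = ", n)
  nu2 <- n - nu1
  c2 <- ((n - 1) * nu1) / (n * nu2) * stats::qf(phi, df1 = nu1, df2 = nu2)
  structure(list(phi = phi, nu1 = nu1, nu2 = nu2, c2 = c2,
                 regime = "hotelling"),
            class = "confidence_scale")
}

#' @export
print.confidence_scale <- function(x, ...) {
  cat(sprintf("Confidence scale (%s regime): phi = %g, nu1 = %d, nu2 = %s, c2 = %.4f\n",
              x$regime, x$phi, x$nu1, format(x$nu2), x$c2))
  invisible(x)
}

#' PCA of the section crossings in the orthogonal plane
#'
#' Expresses the crossing points of one plane in an in-plane orthonormal
#' basis, centers them, and eigen-decomposes their 2x2 sample covariance
#' (n - 1 denominator). `sigma_eps` and `sigma_eta` are the standard
#' deviations along the first and second principal component; the third
#' direction (the path tangent) has zero spread by construction since every
#' crossing lies in the plane.
#'
#' @param crossing A [plane_crossings()] result.
#' @param tangent Unit normal of the plane (the path tangent at s).
#' @param center `"centroid"` (default): center on the mean of the
#'   crossings, standard PCA practice; `"path"`: center on the mean-path
#'   point p(s), the nominal ellipse center.
#' @param path_point The mean-path point p(s); required when
#'   `center = "path"`.
#' @return An object of class `section_stats`: list with `s`, `sigma_eps`,
#'   `sigma_eta` (mm), `axes` (3 x 2, in-plane unit principal directions),
#'   `center` (3-vector) and `n_used`.
#' @export
plane_pca <- function(crossing, tangent, center = c("centroid", "path"),
                      path_point = NULL) {
  stopifnot(inherits(crossing, "plane_crossing"))
  center <- match.arg(center)
  q <- crossing$q
  n <- nrow(q)
  if (n < 2L)
    stop("plane PCA needs at least 2 crossings; got ", n,
         " at s = ", format(crossing$s, digits = 6))
  tangent <- tangent / sqrt(sum(tangent^2))
  B <- plane_basis(tangent)             # 3 x 2 in-plane orthonormal basis
  ctr <- switch(center,
    centroid = colMeans(q),
    path = {
      if (is.null(path_point)) stop("'path_point' required for center = \"path\"")
      as.numeric(path_point)
    })
  uv <- (q - matrix(ctr, n, 3, byrow = TRUE)) %*% B   # n x 2 in-plane coords
  S <- crossprod(uv) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)      # eigenvalues in decreasing order
  ev <- pmax(eg$values, 0)
  axes <- B %*% eg$vectors              # back to 3D, columns = PCs
  structure(list(s = crossing$s,
                 sigma_eps = sqrt(ev[1L]), sigma_eta = sqrt(ev[2L]),
                 axes = axes, center = ctr, n_used = n),
            class = "section_stats")
}

# two unit vectors spanning the plane orthogonal to unit vector nv
plane_basis <- function(nv) {
  ref <- if (abs(nv[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * nv) * nv
  u <- u / sqrt(sum(u^2))
  v <- c(nv[2L] * u[3L] - nv[3L] * u[2L],
         nv[3L] * u[1L] - nv[1L] * u[3L],
         nv[1L] * u[2L] - nv[2L] * u[1L])
  cbind(u, v)
}

#' Mean radius of the confidence ellipse
#'
#' The ellipse with semi-axes \eqn{\sqrt{c^2}\,\sigma_\epsilon} and
#' \eqn{\sqrt{c^2}\,\sigma_\eta} is converted to an equivalent circle whose
#' radius is the angular mean of the ellipse radius,
#' \deqn{r_{mean} = \frac{1}{2\pi}\int_0^{2\pi}
#'   \sqrt{c^2\sigma_\epsilon^2\cos^2\theta + c^2\sigma_\eta^2\sin^2\theta}
#'   \, d\theta,}
#' evaluated by fixed-order trapezoid quadrature on the periodic integrand
#' (spectrally accurate). Closed forms: a circle gives
#' \eqn{\sqrt{c^2}\sigma}, a fully degenerate ellipse
#' \eqn{(2/\pi)\sqrt{c^2}\sigma_\epsilon}.
#'
#' @param sigma_eps,sigma_eta In-plane standard deviations (mm),
#'   `sigma_eps >= sigma_eta >= 0`.
#' @param c2 Squared confidence scale (a positive number or a
#'   [c_squared()] object).
#' @param quadrature_points Number of trapezoid nodes over \eqn{[0, 2\pi]},
#'   default 256.
#' @return Mean radius in mm.
#' @export
mean_radius <- function(sigma_eps, sigma_eta, c2, quadrature_points = 256L) {
  if (inherits(c2, "confidence_scale")) c2 <- c2$c2
  if (!is.numeric(c2) || c2 <= 0) stop("'c2' must be a positive number")
  if (sigma_eps < 0 || sigma_eta < 0)
    stop("standard deviations must be non-negative")
  if (sigma_eta > sigma_eps + 1e-12 * max(1, sigma_eps))
    stop("'sigma_eps' must be >= 'sigma_eta'")
  # exact limits: a circle, and a fully collapsed ellipse (where the
  # integrand kink would defeat the trapezoid rule)
  if (sigma_eta == sigma_eps) return(sqrt(c2) * sigma_eps)
  if (sigma_eta == 0) return((2 / pi) * sqrt(c2) * sigma_eps)
  m <- as.integer(quadrature_points)
  # periodic analytic integrand: trapezoid == mean over equispaced nodes,
  # spectrally accurate
  theta <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  r <- sqrt(c2 * (sigma_eps^2 * cos(theta)^2 + sigma_eta^2 * sin(theta)^2))
  mean(r)
}

#' Stochastic width profile of an ensemble
#'
#' For every plane of the arc-length grid: intersect the trials with the
#' plane, run the in-plane PCA, scale the standard-deviation ellipse to the
#' `phi`-level confidence ellipse, and set
#' \eqn{W_{obs}(s, \phi) = 2\, r_{mean}(s, \phi)}. Planes with fewer than
#' `nu1 + 1` crossings, or with zero dispersion, are flagged invalid and
#' filled by linear interpolation from their valid neighbours so the
#' difficulty integrand stays defined without fabricating dispersion.
#'
#' @param ensemble A [trial_ensemble()].
#' @param path Its [mean_path()]; built with `mean_path(ensemble, M)` if
#'   omitted.
#' @param phi Probability level, default 0.95.
#' @param M Grid size used when `path` is omitted.
#' @param regime `"hotelling"` (small-sample, default) or `"chi2"`
#'   (population known).
#' @param center PCA centering, see [plane_pca()].
#' @param quadrature_points Nodes for the mean-radius quadrature.
#' @param max_invalid Maximal tolerated fraction of invalid planes
#'   (default 0.5) before the ensemble is declared too degenerate.
#' @return An object of class `width_profile`: list with `s`, `W` (mm),
#'   `valid` (logical), `phi`, `scale` (the [c_squared()] object), and
#'   `sections` (list of per-plane [plane_pca()] results, `NULL` where
#'   invalid).
#' @export
width_profile <- function(ensemble, path = NULL, phi = 0.95, M = 200L,
                          regime = c("hotelling", "chi2"),
                          center = c("centroid", "path"),
                          quadrature_points = 256L, max_invalid = 0.5) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  regime <- match.arg(regime)
  center <- match.arg(center)
  if (is.null(path)) path <- mean_path(ensemble, M = M)
  n <- length(ensemble$trials)
  scale <- c_squared(n = n, phi = phi,
                     population_known = (regime == "chi2"))
  Mg <- nrow(path$xyz)
  need <- scale$nu1 + 1L                    # minimum crossings per plane
  W <- rep(NA_real_, Mg)
  sections <- vector("list", Mg)
  pts_all <- do.call(rbind, lapply(ensemble$trials, `[[`, "xyz"))
  idx_all <- rep(seq_len(n), vapply(ensemble$trials, function(tr) nrow(tr$xyz),
                                    integer(1)))
  for (i in seq_len(Mg)) {
    cr <- plane_crossings_fast(pts_all, idx_all, ensemble, path, i)
    if (is.null(cr) || nrow(cr$q) < need) next
    st <- plane_pca(cr, path$tangents[i, ], center = center,
                    path_point = path$xyz[i, ])
    sections[[i]] <- st
    if (st$sigma_eps <= 0) next             # zero dispersion: flag invalid
    W[i] <- 2 * mean_radius(st$sigma_eps, st$sigma_eta, scale$c2,
                            quadrature_points = quadrature_points)
  }
  valid <- !is.na(W) & W > 0
  if (mean(!valid) > max_invalid)
    stop("ensemble too degenerate: ", sum(!valid), " of ", Mg,
         " planes have no usable dispersion")
  if (any(!valid)) {
    W <- stats::approx(path$s[valid], W[valid], xout = path$s, rule = 2)$y
    message(sum(!valid), " of ", Mg,
            " planes invalid; widths interpolated from neighbours")
  }
  structure(list(s = path$s, W = W, valid = valid, phi = phi, scale = scale,
                 sections = sections),
            class = "width_profile")
}

# vectorised re-implementation of plane_crossings used by the profile loop:
# identical tie-break rules, but reuses the stacked point matrix.
plane_crossings_fast <- function(pts_all, idx_all, ensemble, path, i) {
  p0 <- path$xyz[i, ]
  nv <- path$tangents[i, ]
  d_all <- drop(pts_all %*% nv) - sum(p0 * nv)
  qs <- vector("list", length(ensemble$trials))
  ids <- character(0)
  for (k in seq_along(ensemble$trials)) {
    sel <- idx_all == k
    ck <- segment_plane_crossing_d(ensemble$trials[[k]]$xyz, d_all[sel], p0, nv)
    if (!is.null(ck)) {
      qs[[k]] <- ck
      ids <- c(ids, ensemble$trials[[k]]$trial_id)
    }
  }
  keep <- !vapply(qs, is.null, logical(1))
  if (!any(keep)) return(NULL)
  structure(list(s_index = i, s = path$s[i],
                 q = do.call(rbind, qs[keep]), trial_ids = ids,
                 missing = setdiff(vapply(ensemble$trials, `[[`, character(1),
                                          "trial_id"), ids)),
            class = "plane_crossing")
}

# same contract as segment_plane_crossing, with precomputed signed distances
segment_plane_crossing_d <- function(pts, d, p0, nv) {
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
  off <- drop((cand - matrix(p0, nrow(cand), 3, byrow = TRUE)) %*% nv)
  cand <- cand - outer(off, nv)
  r2 <- rowSums((cand - matrix(p0, nrow(cand), 3, byrow = TRUE))^2)
  cand[which.min(r2), ]
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("Stochastic width profile: %d planes over %.1f mm, phi = %g (%s regime)\n",
              length(x$s), max(x$s), x$phi, x$scale$regime))
  cat(sprintf("  W_obs range %.2f - %.2f mm, %d invalid plane(s) interpolated\n",
              min(x$W), max(x$W), sum(!x$valid)))
  invisible(x)
}

#' Write a width profile as CSV
#'
#' Columns `s_mm`, `W_mm`, `valid`.
#'
#' @param profile A [width_profile()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_width_profile <- function(profile, file) {
  stopifnot(inherits(profile, "width_profile"))
  utils::write.csv(data.frame(s_mm = profile$s, W_mm = profile$W,
                              valid = profile$valid),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
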