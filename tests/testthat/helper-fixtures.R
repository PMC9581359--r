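# Fixtures are built in code: small deterministic ensembles and rigid-motion
# helpers shared across the test files.

# straight-line trials along x from 0 to L, one per row of `offsets` (y, z)
straight_ensemble <- function(offsets, L = 10, m = 11, speed = 1) {
  trials <- lapply(seq_len(nrow(offsets)), function(k) {
    x <- seq(0, L, length.out = m)
    trajectory(t = x / speed,
               xyz = cbind(x, offsets[k, 1], offsets[k, 2]),
               trial_id = paste0("tr", k))
  })
  trial_ensemble(trials)
}

# rotation matrix about a unit axis by angle (Rodrigues)
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# apply a rigid motion (rotation R then translation v) to every trial
apply_rigid <- function(ensemble, R = diag(3), v = c(0, 0, 0)) {
  trials <- lapply(ensemble$trials, function(tr) {
    trajectory(t = tr$t,
               xyz = tr$xyz %*% t(R) + matrix(v, nrow(tr$xyz), 3, byrow = TRUE),
               trial_id = tr$trial_id)
  })
  trial_ensemble(trials, ensemble$subject, ensemble$condition)
}

# uniform spatial scaling at fixed times
scale_ensemble <- function(ensemble, lambda) {
  trials <- lapply(ensemble$trials, function(tr)
    trajectory(t = tr$t, xyz = tr$xyz * lambda, trial_id = tr$trial_id))
  trial_ensemble(trials, ensemble$subject, ensemble$condition)
}

# straight-path generator spec with constant isotropic in-plane dispersion
straight_tube_spec <- function(sigma = 2, n = 50, L = 1000, M = 120,
                               seed = 1, corr_length = 0.1) {
  generator_spec(waypoints = rbind(c(0, 0, 0), c(L, 0, 0)), lift = 0,
                 n = n, M = M,
                 sigma_profile = function(u) cbind(rep(sigma, length(u)),
                                                   rep(sigma, length(u))),
                 speed_model = "constant", corr_length = corr_length,
                 seed = seed)
}

# brute-force oracle: every intersection of a polyline with the plane
# through p0 with unit normal nv, as an r x 3 matrix
all_plane_crossings <- function(pts, p0, nv) {
  d <- drop((pts - matrix(p0, nrow(pts), 3, byrow = TRUE)) %*% nv)
  out <- NULL
  for (i in seq_len(nrow(pts) - 1)) {
    if (d[i] == 0) out <- rbind(out, pts[i, ])
    if (d[i] * d[i + 1] < 0) {
      w <- d[i] / (d[i] - d[i + 1])
      out <- rbind(out, pts[i, ] * (1 - w) + pts[i + 1, ] * w)
    }
  }
  if (d[nrow(pts)] == 0) out <- rbind(out, pts[nrow(pts), ])
  out
}
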