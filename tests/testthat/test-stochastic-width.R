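make_crossing <- function(q, s = 5) {
  structure(list(s_index = 1L, s = s, q = q,
                 trial_ids = paste0("t", seq_len(nrow(q))),
                 missing = character(0)),
            class = "plane_crossing")
}

test_that("confidence scaling matches the tabulated quantile values", {
  cs <- c_squared(n = 7, phi = 0.95)
  expect_equal(cs$nu2, 5L)
  expect_equal(qf(0.95, 2, 5), 5.786, tolerance = 1e-3)
  expect_equal(cs$c2, 1.984, tolerance = 1e-3)
  pop <- c_squared(phi = 0.95, population_known = TRUE)
  expect_equal(pop$c2, 5.992, tolerance = 1e-3)
  expect_identical(pop$regime, "chi2")
})

test_that("confidence scale is monotone in phi and guards its domain", {
  phis <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  c2s <- sapply(phis, function(p) c_squared(n = 7, phi = p)$c2)
  expect_true(all(diff(c2s) > 0))
  expect_lt(c_squared(n = 7, phi = 1e-8)$c2, 1e-6)   # c2 -> 0 as phi -> 0
  expect_error(c_squared(n = 2, phi = 0.95), "n > nu1")
  expect_error(c_squared(n = 7, phi = 1.2), "strictly inside")
})

test_that("section PCA recovers a collinear spread exactly", {
  # three crossings on the z = 0 plane: (1,0), (-1,0), (0,0) in-plane
  q <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 0))
  st <- plane_pca(make_crossing(q), tangent = c(0, 0, 1))
  expect_equal(st$sigma_eps, 1)
  expect_equal(st$sigma_eta, 0)
  expect_equal(st$n_used, 3L)
  # leading axis is +-x, and both axes are orthogonal to the tangent
  expect_equal(abs(st$axes[, 1]), c(1, 0, 0), tolerance = 1e-12)
  expect_lt(max(abs(crossprod(st$axes, c(0, 0, 1)))), 1e-9)
})

test_that("section PCA is consistent with prcomp and with large-sample truth", {
  set.seed(31)
  n <- 1e4
  uv <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 3))
  q <- cbind(uv[, 1], uv[, 2], 0)           # plane z = 0
  st <- plane_pca(make_crossing(q), tangent = c(0, 0, 1))
  expect_equal(st$sigma_eps, 3, tolerance = 0.03)
  expect_equal(st$sigma_eta, 3, tolerance = 0.03)
  # cross-check against prcomp on the in-plane coordinates
  pr <- prcomp(uv)
  expect_equal(st$sigma_eps, unname(pr$sdev[1]), tolerance = 1e-9)
  expect_equal(st$sigma_eta, unname(pr$sdev[2]), tolerance = 1e-9)
})

test_that("section PCA is rotation-equivariant", {
  set.seed(5)
  uv <- cbind(rnorm(40, sd = 4), rnorm(40, sd = 1.5))
  q0 <- cbind(uv[, 1], uv[, 2], 0)
  st0 <- plane_pca(make_crossing(q0), tangent = c(0, 0, 1))
  R <- rotation_matrix(c(1, 2, -1), 0.83)
  st1 <- plane_pca(make_crossing(q0 %*% t(R)), tangent = drop(R %*% c(0, 0, 1)))
  expect_equal(st1$sigma_eps, st0$sigma_eps, tolerance = 1e-9)
  expect_equal(st1$sigma_eta, st0$sigma_eta, tolerance = 1e-9)
  expect_equal(abs(sum(st1$axes[, 1] * (R %*% st0$axes[, 1]))), 1,
               tolerance = 1e-9)
  expect_error(plane_pca(make_crossing(q0[1, , drop = FALSE]), c(0, 0, 1)),
               "at least 2")
})

test_that("mean ellipse radius matches its closed forms and a quadrature oracle", {
  c2 <- 1.984
  # circle: r = sqrt(c2) * sigma
  expect_equal(mean_radius(2, 2, c2), sqrt(c2) * 2, tolerance = 1e-9)
  # fully degenerate: (2 / pi) sqrt(c2) sigma_eps
  expect_equal(mean_radius(3, 0, c2), (2 / pi) * sqrt(c2) * 3,
               tolerance = 1e-9)
  # general case against adaptive quadrature
  oracle <- integrate(function(th)
    sqrt(c2 * (3^2 * cos(th)^2 + 1^2 * sin(th)^2)),
    0, 2 * pi, rel.tol = 1e-12)$value / (2 * pi)
  expect_equal(mean_radius(3, 1, c2), oracle, tolerance = 1e-9)
  expect_error(mean_radius(1, 2, c2), "sigma_eps")
  expect_error(mean_radius(3, 1, -1), "positive")
})

test_that("mean radius is monotone in each argument", {
  base <- mean_radius(3, 1, 2)
  for (d in c(0.1, 0.5, 2)) {
    expect_gte(mean_radius(3 + d, 1, 2), base)
    expect_gte(mean_radius(3, 1 + d * 0.4, 2), base)
    expect_gte(mean_radius(3, 1, 2 + d), base)
  }
})

test_that("width of an isotropic straight tube matches the circle closed form", {
  sigma <- 2
  spec <- straight_tube_spec(sigma = sigma, n = 200, L = 1000, M = 120,
                             seed = 21)
  ens <- simulate_trials(spec)
  wp <- width_profile(ens, M = 100, phi = 0.95, regime = "chi2")
  expected <- 2 * sqrt(qchisq(0.95, 2)) * sigma
  interior <- wp$s > 0.1 * max(wp$s) & wp$s < 0.9 * max(wp$s)
  expect_equal(mean(wp$W[interior]), expected, tolerance = 0.05)
})

test_that("an ensemble of identical trials has no usable width", {
  tr <- trajectory(t = 0:10, xyz = cbind(0:10 * 10, 0, 0))
  ens <- trial_ensemble(list(tr, tr, tr, tr))
  expect_error(width_profile(ens, M = 20), "degenerate")
})

test_that("doubling the dispersion doubles the width profile (paired seeds)", {
  w_of <- function(sigma) {
    spec <- straight_tube_spec(sigma = sigma, n = 40, L = 800, M = 80,
                               seed = 77)
    width_profile(simulate_trials(spec), M = 60)
  }
  w1 <- w_of(2); w2 <- w_of(4)
  interior <- seq(10, 50)
  expect_equal(w2$W[interior] / w1$W[interior], rep(2, length(interior)),
               tolerance = 0.05)
})

test_that("the width profile is invariant under rigid motions", {
  spec <- generator_spec(n = 7, seed = 13)
  ens <- simulate_trials(spec)
  wp0 <- width_profile(ens, M = 60)
  moved <- apply_rigid(ens, rotation_matrix(c(1, 1, 1), 1.1),
                       v = c(100, -50, 30))
  wp1 <- width_profile(moved, M = 60)
  expect_equal(wp1$W, wp0$W, tolerance = 1e-6)
})

test_that("the width profile scales linearly with the trajectories", {
  spec <- generator_spec(n = 7, seed = 14)
  ens <- simulate_trials(spec)
  wp0 <- width_profile(ens, M = 60)
  wp2 <- width_profile(scale_ensemble(ens, 2.5), M = 60)
  expect_equal(wp2$W, 2.5 * wp0$W, tolerance = 1e-6)
  expect_equal(wp2$s, 2.5 * wp0$s, tolerance = 1e-9)
})

test_that("Hotelling scaling at the study's n = 7 is reproduced in-profile", {
  spec <- generator_spec(n = 7, seed = 15)
  wp <- width_profile(simulate_trials(spec), M = 40)
  expect_equal(wp$scale$c2, 1.984, tolerance = 1e-3)
  expect_identical(wp$scale$regime, "hotelling")
})
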