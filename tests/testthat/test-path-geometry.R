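test_that("the mean path of identical trials is the resampled trial", {
  th <- seq(0, pi, length.out = 15)
  tr <- trajectory(t = th, xyz = cbind(100 * cos(th), 100 * sin(th), 10 * th))
  ens <- trial_ensemble(list(tr, tr, tr))
  mp <- mean_path(ens, M = 40)
  ref <- resample_trajectory(tr, M = 40)$xyz
  expect_equal(unname(mp$xyz), unname(ref), tolerance = 1e-12)
})

test_that("two parallel offset trials average to the midline", {
  ens <- straight_ensemble(rbind(c(3, 0), c(-3, 0)), L = 10, m = 11)
  mp <- mean_path(ens, M = 11)
  expect_equal(mp$xyz[, 2], rep(0, 11), tolerance = 1e-12)
  expect_equal(mp$total_length, 10, tolerance = 1e-9)
})

test_that("mean path bookkeeping: arc length, grid, unit tangents", {
  spec <- generator_spec(n = 5, seed = 3)
  mp <- mean_path(simulate_trials(spec), M = 80)
  # s grid matches consecutive point distances and total length
  expect_equal(diff(mp$s), sqrt(rowSums(diff(mp$xyz)^2)), tolerance = 1e-12)
  expect_equal(mp$s[80], mp$total_length)
  expect_equal(mp$s[1], 0)
  # tangents have unit norm
  expect_lt(max(abs(sqrt(rowSums(mp$tangents^2)) - 1)), 1e-9)
})

test_that("mean of a noisy tube converges to the generator path as 1/sqrt(n)", {
  rms_dev <- function(n, seed) {
    spec <- straight_tube_spec(sigma = 5, n = n, L = 500, M = 60, seed = seed)
    mp <- mean_path(simulate_trials(spec), M = 60)
    # true center path is the x-axis: deviation is the (y, z) distance
    sqrt(mean(mp$xyz[, 2]^2 + mp$xyz[, 3]^2))
  }
  r_small <- mean(sapply(1:4, function(s) rms_dev(16, 100 + s)))
  r_large <- mean(sapply(1:4, function(s) rms_dev(256, 200 + s)))
  # expected ratio sqrt(256/16) = 4; allow a factor-2 band around it
  expect_gt(r_small / r_large, 2)
  expect_lt(r_small / r_large, 8)
})

test_that("plane crossings of straight trials are the points on the plane", {
  ens <- straight_ensemble(rbind(c(1, 2), c(-1, 0), c(0, -2)), L = 10, m = 11)
  mp <- mean_path(ens, M = 11)
  cr <- plane_crossings(ens, mp, s_index = 6)   # plane at x = 5
  expect_equal(nrow(cr$q), 3L)
  expect_equal(cr$q[, 1], rep(5, 3), tolerance = 1e-9)
  expect_equal(sort(cr$q[, 2]), c(-1, 0, 1), tolerance = 1e-9)
  expect_length(cr$missing, 0L)
  # every crossing lies on the plane
  p0 <- mp$xyz[6, ]; nv <- mp$tangents[6, ]
  expect_lt(max(abs((cr$q - matrix(p0, 3, 3, byrow = TRUE)) %*% nv)), 1e-6)
})

test_that("multi-crossing trials return the crossing nearest the plane center", {
  # zig-zag trial crossing the x = 5 plane three times at different radii
  zig <- trajectory(
    t = 0:6,
    xyz = rbind(c(0, 0, 0), c(6, 8, 0), c(4, 5, 0), c(7, 2, 0),
                c(3, -6, 0), c(8, -1, 0), c(10, 0, 0)),
    trial_id = "zig")
  straight <- trajectory(t = c(0, 1), xyz = rbind(c(0, 0, 0), c(10, 0, 0)),
                         trial_id = "line")
  ens <- trial_ensemble(list(straight, zig, straight))
  mp <- mean_path(straight_ensemble(rbind(c(0, 0), c(0, 0)), L = 10, m = 11),
                  M = 11)
  cr <- plane_crossings(ens, mp, s_index = 6)
  p0 <- mp$xyz[6, ]; nv <- mp$tangents[6, ]
  # oracle: enumerate every segment-plane intersection, take the nearest
  allq <- all_plane_crossings(zig$xyz, p0, nv)
  expect_gte(nrow(allq), 3L)
  best <- allq[which.min(rowSums((allq - matrix(p0, nrow(allq), 3,
                                                byrow = TRUE))^2)), ]
  got <- cr$q[cr$trial_ids == "zig", ]
  expect_equal(unname(got), unname(best), tolerance = 1e-9)
})

test_that("trials that never reach the plane are reported missing", {
  short <- trajectory(t = c(0, 1), xyz = rbind(c(0, 1, 0), c(3, 1, 0)),
                      trial_id = "short")
  full1 <- trajectory(t = c(0, 1), xyz = rbind(c(0, 0, 0), c(10, 0, 0)),
                      trial_id = "full1")
  full2 <- trajectory(t = c(0, 1), xyz = rbind(c(0, -1, 0), c(10, -1, 0)),
                      trial_id = "full2")
  ens <- trial_ensemble(list(full1, full2, short))
  mp <- mean_path(trial_ensemble(list(full1, full2)), M = 11)
  cr <- plane_crossings(ens, mp, s_index = 9)
  expect_identical(cr$missing, "short")
  expect_equal(nrow(cr$q), 2L)
})

test_that("crossings vary continuously along a smooth tube", {
  spec <- generator_spec(n = 6, seed = 9)
  ens <- simulate_trials(spec)
  mp <- mean_path(ens, M = 120)
  h <- mean(diff(mp$s))
  prev <- plane_crossings(ens, mp, 20)
  worst <- 0
  for (i in 21:100) {
    cur <- plane_crossings(ens, mp, i)
    shared <- intersect(prev$trial_ids, cur$trial_ids)
    d <- sqrt(rowSums((cur$q[match(shared, cur$trial_ids), , drop = FALSE] -
                       prev$q[match(shared, prev$trial_ids), , drop = FALSE])^2))
    worst <- max(worst, d)
    prev <- cur
  }
  expect_lt(worst, 4 * h)   # an index jump would be tens of grid steps
})

test_that("degenerate geometry is rejected", {
  z <- trajectory(t = c(0, 1), xyz = rbind(c(0, 0, 0), c(0, 0, 0) + 1e-300))
  expect_error(mean_path(trial_ensemble(list(z, z)), M = 5), "degenerate")
  ens <- straight_ensemble(rbind(c(0, 0), c(1, 0)), L = 10, m = 5)
  mp <- mean_path(ens, M = 5)
  expect_error(plane_crossings(ens, mp, 99), "out of range")
})
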