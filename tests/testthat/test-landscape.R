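# Distribution, peak, state-call and substate analyses on planted truth.

test_that("KDE distribution recovers unimodal and bimodal peak locations", {
  set.seed(61)
  x1 <- rnorm(10000, 17, 0.5)
  d1 <- make_distribution(x1)
  expect_equal(nrow(d1$peaks), 1)
  expect_equal(d1$peaks$location, 17, tolerance = 0.1)
  # normalization invariant
  expect_equal(sum(d1$density) * diff(d1$grid[1:2]), 1, tolerance = 1e-6)

  x2 <- c(rnorm(5000, 17, 0.5), rnorm(5000, 20, 0.5))
  d2 <- make_distribution(x2)
  expect_equal(nrow(d2$peaks), 2)
  expect_equal(d2$peaks$location, c(17, 20), tolerance = 0.15)

  # peak locations are equivariant under a constant shift
  d3 <- make_distribution(x2 + 2.5)
  expect_equal(d3$peaks$location, d2$peaks$location + 2.5, tolerance = 0.02)
})

test_that("constant series is flagged degenerate with no peaks", {
  d <- suppressWarnings(make_distribution(rep(17, 10)))
  expect_true(d$degenerate)
  expect_equal(nrow(d$peaks), 0)
  expect_warning(make_distribution(rep(17, 10)), "fewer than 50")
})

test_that("find_peaks honours prominence and separation filters", {
  # hand-built trimodal density: the 18.2 A mode is a low shoulder
  grid <- seq(10, 26, by = 0.05)
  dens <- dnorm(grid, 14, 0.4) + dnorm(grid, 20, 0.4) +
    0.03 * dnorm(grid, 18.2, 0.3)
  dens <- dens / (sum(dens) * 0.05)
  d <- structure(list(grid = grid, density = dens, bandwidth = 0.3,
                      peaks = NULL, degenerate = FALSE),
                 class = "distance_distribution")
  pk <- find_peaks(d, min_prominence = 0.05, min_separation = 1.0)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$location, c(14, 20), tolerance = 0.05)
  # with no prominence filter the shoulder appears
  pk3 <- find_peaks(d, min_prominence = 0.001, min_separation = 1.0)
  expect_equal(nrow(pk3), 3)
  # separation filter keeps the higher of two close peaks
  dens2 <- dnorm(grid, 14, 0.4) + 0.8 * dnorm(grid, 14.8, 0.4)
  d2 <- d; d2$density <- dens2 / (sum(dens2) * 0.05)
  pk2 <- find_peaks(d2, min_prominence = 0.01, min_separation = 2)
  expect_equal(nrow(pk2), 1)
})

test_that("classify_state partitions the plane and validates thresholds", {
  expect_equal(classify_state(0, 14), "R_like")
  expect_equal(classify_state(12, 21), "T_like")
  expect_equal(classify_state(2, 18), "intermediate")
  expect_equal(classify_state(-12, 21), "T_like")  # |theta| convention
  grid <- expand.grid(theta = seq(-20, 20, by = 1.7),
                      d = seq(10, 26, by = 0.9))
  lab <- classify_state(grid$theta, grid$d)
  expect_true(all(lab %in% c("R_like", "T_like", "intermediate")))
  expect_error(classify_state(0, 14, list(d_R = 18, d_T = 16, theta_R = 4,
                                          theta_T = 8)), "inconsistent")
})

test_that("landscape recovers planted state structure", {
  # degenerate all-R spec, zero noise: pure R cloud at the planted mean
  pure <- make_ensemble(ensemble_spec(
    n_frames = 40, fractions = c(R_like = 1, T_like = 0, intermediate = 0),
    d_in_sd = 0, theta_R_sd = 0, coord_noise_sd = 0, seed = 71))
  lp <- landscape(pure$ensemble, "A", pure$reference)
  expect_true(all(lp$label == "R_like"))
  expect_equal(lp$d_A, rep(14.5, 40), tolerance = 1e-6)

  # 30% planted T fraction
  mix <- make_ensemble(ensemble_spec(n_frames = 400, seed = 72))
  lpA <- landscape(mix$ensemble, "A", mix$reference)
  expect_equal(mean(lpA$label == "T_like"), 0.30, tolerance = 0.03)
  expect_identical(attr(lpA, "thresholds"), default_state_thresholds())

  # label invariance under frame permutation
  perm <- sample(n_frames(mix$ensemble))
  shuf <- mix$ensemble
  shuf$coords <- shuf$coords[, , perm]
  shuf$frame_times <- shuf$frame_times[perm]
  lpP <- landscape(shuf, "A", mix$reference)
  expect_equal(lpP$label, lpA$label[perm])
})

test_that("side-chain substates recover planted chi modes", {
  out <- make_ensemble(ensemble_spec(n_frames = 400, seed = 73))
  ss <- sidechain_substates(out$ensemble, "A", 250, seed = 3)
  expect_equal(ss$k, 3)
  expect_equal(unname(ss$occupancy), c(0.5, 0.3, 0.2), tolerance = 0.05)
  expect_equal(sum(ss$occupancy), 1)
  expect_length(ss$cluster, 400)

  # planted truth: recovered clusters coincide with scheduled modes
  tr <- subset(out$truth$per_frame, chain == "A")
  tab <- table(tr$chi_mode, ss$cluster)
  expect_gte(sum(apply(tab, 1, max)) / 400, 0.95)
})

test_that("single-mode side chain yields k = 1", {
  out <- make_ensemble(ensemble_spec(
    n_frames = 150,
    chi_modes = cbind(chi1 = -60, chi2 = 170, occupancy = 1),
    seed = 74))
  ss <- sidechain_substates(out$ensemble, "A", 250, seed = 3)
  expect_equal(ss$k, 1)
  expect_equal(unname(ss$occupancy), 1)
})

test_that("modes straddling +/-180 degrees merge on the torus", {
  out <- make_ensemble(ensemble_spec(
    n_frames = 150,
    chi_modes = cbind(chi1 = c(175, -175), chi2 = c(60, 60),
                      occupancy = c(0.5, 0.5)),
    chi_sd = 4, seed = 75))
  ss <- sidechain_substates(out$ensemble, "A", 250, seed = 3)
  expect_equal(ss$k, 1)
})

test_that("proline at 250 is refused with a clear message", {
  out <- make_ensemble(ensemble_spec(n_frames = 5, res250 = "PRO",
                                     seed = 76))
  expect_error(sidechain_substates(out$ensemble, "A", 250, seed = 1),
               "unsupported|lacks")
})

test_that("loop state calls match the printed exemplars and planted schedule", {
  # closed-state exemplar (Holo-like) and open-state exemplar (Apo-like)
  expect_equal(classify_loop(13.1, 9.6), "closed")
  expect_equal(classify_loop(22, 21), "open")
  expect_equal(classify_loop(17, 13), "intermediate")

  out <- make_ensemble(ensemble_spec(
    n_frames = 200,
    loop_fractions = c(closed = 0.5, open = 0.3, intermediate = 0.2),
    seed = 77))
  ls <- loop_state(out$ensemble, "B")
  tr <- subset(out$truth$per_frame, chain == "B")
  expect_equal(mean(ls$state == "closed"), mean(tr$loop == "closed"),
               tolerance = 0.03)
  expect_equal(mean(ls$state == "open"), mean(tr$loop == "open"),
               tolerance = 0.03)
})
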