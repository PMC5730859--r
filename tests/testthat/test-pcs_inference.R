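power_law_slopes <- function(exponent = -1.5, n = 30) {
  s <- 10e3 * 1.3^(0:n)
  cv <- tibble::tibble(s_lo = s, s_hi = s * 1.3, s_mid = s,
                       n_contacts = 1L, n_pairs = 1, p = s^exponent)
  class(cv) <- c("pcs_curve", class(cv))
  pcs_slope(cv)
}

test_that("a pure power law yields no loop-size maximum", {
  est <- infer_extruded_loop_size(power_law_slopes())
  expect_true(est$no_maximum_detected)
  expect_true(est$no_minimum_detected)
  # flat slope series as well
  est0 <- infer_extruded_loop_size(power_law_slopes(0))
  expect_true(est0$no_maximum_detected)
})

test_that("a constructed shoulder is located and its dip measured", {
  s <- 10e3 * 1.3^(0:30)
  # smooth bump peaking near 80 kb and a dip near 1 Mb
  slope <- -1.5 + 0.8 * exp(-0.5 * (log(s / 80e3) / 0.5)^2) -
    0.6 * exp(-0.5 * (log(s / 1e6) / 0.5)^2)
  sl <- tibble::tibble(s_mid = s, slope = slope)
  est <- infer_extruded_loop_size(sl)
  expect_false(est$no_maximum_detected)
  expect_lt(abs(log(est$loop_size_bp / 80e3)), log(1.4))
  expect_false(est$no_minimum_detected)
  expect_lt(abs(log(est$min_slope_location_bp / 1e6)), log(1.5))
  expect_gt(est$density_signature, 1.0)
})

test_that("the slope maximum of a simulated control run matches its mean loop", {
  p <- lef_params(10000, 120e3, 120e3, n_steps = 1500)
  st <- run_lef_dynamics(p, build_boundary_map(10000), record_every = 30L,
                         seeds = 1:2)
  cv <- pcs_from_loops(st, pairs_per_bin = 250L, capture_radius = 3,
                       seed = 1)
  est <- infer_extruded_loop_size(pcs_slope(cv))
  expect_false(est$no_maximum_detected)
  expect_lt(abs(log(est$loop_size_bp / st$mean_loop_bp)), log(1.5))
})

test_that("loop-size inference is invariant to curve normalization", {
  p <- lef_params(8000, 120e3, 120e3, n_steps = 1000)
  st <- run_lef_dynamics(p, build_boundary_map(8000, period = 8000L,
                                               pattern = tad_boundary_pattern()[
                                                 tad_boundary_pattern() < 8000]),
                         record_every = 25L, seeds = 1)
  cv <- pcs_from_loops(st, pairs_per_bin = 200L, seed = 2)
  est1 <- infer_extruded_loop_size(pcs_slope(cv))
  cv$p <- cv$p * 1e3
  est2 <- infer_extruded_loop_size(pcs_slope(cv))
  expect_equal(est1$loop_size_bp, est2$loop_size_bp)
  expect_equal(est1$density_signature, est2$density_signature)
})

test_that("sweep matching identifies its own member and a noisy resample", {
  sw <- simulate_pcs_sweep(processivity_bp = c(120e3, 480e3),
                           separation_bp = c(120e3, 480e3),
                           n_monomers = 8000, n_steps = 800,
                           boundaries = build_boundary_map(8000,
                             pattern = tad_boundary_pattern()[
                               tad_boundary_pattern() < 8000],
                             period = 8000L),
                           seeds = 1, pairs_per_bin = 150L)
  own <- sw$curve[[2]]
  best <- match_simulation_parameters(own, sw)
  expect_equal(best$processivity_bp[1], sw$processivity_bp[2])
  expect_equal(best$separation_bp[1], sw$separation_bp[2])
  expect_equal(best$distance[1], 0)
  # noisy resamples of one member recover it
  set.seed(4)
  hits <- vapply(1:20, function(i) {
    noisy <- own
    noisy$p <- noisy$p * exp(rnorm(nrow(noisy), 0, 0.08))
    b <- match_simulation_parameters(noisy, sw)
    b$processivity_bp[1] == sw$processivity_bp[2] &&
      b$separation_bp[1] == sw$separation_bp[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(match_simulation_parameters(own, sw[0, ]), "empty")
})
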