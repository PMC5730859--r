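test_that("boundary map tiles the pattern with truncation", {
  b <- build_boundary_map(30000)
  expect_length(b, 45)
  expect_equal(b[1:3], c(0L, 1200L, 1500L))
  # enumerate tiles 0 / 10000 / 20000 and truncate by brute force
  brute <- sort(unique(as.vector(outer(tad_boundary_pattern(),
                                       c(0L, 10000L, 20000L), `+`))))
  brute <- brute[brute < 25000]
  b25 <- build_boundary_map(25000)
  expect_equal(as.integer(b25), brute)
  expect_length(b25, 38)
  expect_equal(max(b25), 24800)
  expect_equal(as.integer(build_boundary_map(10000, pattern = 0L)), 0L)
  expect_error(build_boundary_map(10000, pattern = 12000L), "period")
  expect_error(build_boundary_map(5000, period = -1), "positive")
})

test_that("LEF count follows floor(L / separation) and capacity is enforced", {
  expect_equal(lef_params(30000, 120e3, 120e3)$n_lefs, 150L)
  expect_equal(lef_params(30000, 120e3, 2400e3)$n_lefs, 7L)
  p <- lef_params(10, 120e3, 1000)   # 6 LEFs on 10 sites
  expect_error(init_lef_system(p), "cannot place")
})

test_that("stepping preserves exclusion and LEF number; blocked legs stay", {
  p <- lef_params(400, 60e3, 12e3, n_steps = 200, seed = 3)
  sys <- init_lef_system(p, seed = 3)
  set.seed(3)
  for (i in 1:20) {
    sys <- step_lef_system(sys, 10L)
    legs <- c(sys$legs$left, sys$legs$right)
    expect_equal(length(unique(legs)), length(legs))
    expect_true(all(sys$legs$left < sys$legs$right))
    expect_equal(nrow(sys$legs), p$n_lefs)
  }
})

test_that("a free LEF extrudes bidirectionally; an obstructed leg stalls", {
  # single LEF, no boundaries, deterministic expansion when pause/release off
  p <- lef_params(100, Inf, 100 * 600, pause_prob = 0, n_steps = 1)
  sys <- init_lef_system(p, seed = 1)
  sys$legs$left <- 50L
  sys$legs$right <- 51L
  l0 <- sys$legs$left
  set.seed(1)
  sys2 <- step_lef_system(sys)
  expect_equal(sys2$legs$left, l0 - 1L)
  expect_equal(sys2$legs$right, l0 + 2L)
  # lattice edge blocks outward movement
  sys$legs$left <- 0L
  sys$legs$right <- 1L
  set.seed(1)
  sys3 <- step_lef_system(sys)
  expect_equal(sys3$legs$left, 0L)
  expect_equal(sys3$legs$right, 2L)
})

test_that("snapshot-mean span of an isolated LEF approaches the processivity", {
  # memoryless release: stationary age ~ geometric with mean 1/p_off, so the
  # snapshot-mean extruded span equals ~ lambda (verified against a long
  # direct simulation)
  p <- lef_params(100000, 120e3, 100000 * 600, n_steps = 200000, seed = 7)
  st <- run_lef_dynamics(p, record_every = 50L, seeds = 7:9)
  expect_gt(st$mean_loop_bp, 120e3 * 0.9)
  expect_lt(st$mean_loop_bp, 120e3 * 1.1)
})

test_that("mean loop size is non-decreasing in processivity at fixed separation", {
  b <- build_boundary_map(10000)
  means <- vapply(c(60e3, 120e3, 240e3, 480e3, 960e3), function(lam) {
    p <- lef_params(10000, lam, 120e3, n_steps = 1500)
    run_lef_dynamics(p, b, record_every = 30L, seeds = 1:2)$mean_loop_bp
  }, numeric(1))
  expect_true(all(diff(means) > -0.03 * means[-length(means)]))
  expect_gt(means[5], means[1])
})

test_that("freshly initialized systems hold one-monomer loops", {
  p <- lef_params(1000, 120e3, 60e3, n_steps = 0)
  st <- run_lef_dynamics(p, record_every = 1L, equilibration_fraction = 0,
                         seeds = 1)
  expect_true(all(st$snapshots$span_bp == p$monomer_bp))
})

test_that("trajectories are reproducible given a seed", {
  p <- lef_params(2000, 120e3, 120e3, n_steps = 300)
  b <- build_boundary_map(2000, period = 2000L,
                          pattern = c(0L, 700L, 1500L))
  a1 <- run_lef_dynamics(p, b, seeds = 11)
  a2 <- run_lef_dynamics(p, b, seeds = 11)
  expect_identical(a1$snapshots, a2$snapshots)
})

test_that("tidy and glance summarise a run", {
  p <- lef_params(1000, 120e3, 120e3, n_steps = 100)
  st <- run_lef_dynamics(p, record_every = 10L, seeds = 1)
  expect_s3_class(tidy(st), "tbl_df")
  g <- glance(st)
  expect_equal(g$n_lefs, 5L)
  expect_equal(g$mean_loop_bp, st$mean_loop_bp)
})
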