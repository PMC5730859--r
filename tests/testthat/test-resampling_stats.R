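make_windows <- function(n_nuclei = 4, eps = 1, n_contacts = 20000,
                         seed0 = 1, genome = synthetic_genome(),
                         anchors = synthetic_loop_anchors(genome)) {
  cts <- dplyr::bind_rows(lapply(seq_len(n_nuclei), function(i) {
    spec <- synthetic_spec(genome = genome, n_contacts = n_contacts,
                           loop_anchors = if (eps > 0) anchors else NULL,
                           loop_enrichment = eps, trans_fraction = 0,
                           seed = seed0 + i)
    ct <- generate_cell(spec)$contacts
    ct$nucleus <- i
    ct
  }))
  suppressWarnings(collect_loop_windows(cts, anchors, genome))
}

test_that("bootstrap CI is ordered, seeded, and degenerate on identical windows", {
  w <- make_windows(seed0 = 10)
  b1 <- bootstrap_loop_strength_ci(w, n_resamples = 200, seed = 5)
  b2 <- bootstrap_loop_strength_ci(w, n_resamples = 200, seed = 5)
  expect_identical(b1$statistics, b2$statistics)   # bitwise reproducible
  expect_lte(b1$ci_low, b1$point_estimate)
  expect_gte(b1$ci_high, b1$point_estimate)
  # identical windows give a zero-width interval
  w0 <- w
  one_obs <- rep(1, 400)
  one_obs[(9:11 - 1) * 20 + 9:11] <- 3
  w0$obs <- matrix(rep(one_obs, each = nrow(w0$obs)), nrow(w0$obs))
  w0$ctrl <- matrix(1, nrow(w0$ctrl), 400)
  b0 <- bootstrap_loop_strength_ci(w0, n_resamples = 100, seed = 1)
  expect_equal(b0$ci_low, b0$ci_high)
  expect_equal(b0$ci_low, b0$point_estimate)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n loops)", {
  g <- synthetic_genome(3, 50e6)
  an1 <- synthetic_loop_anchors(g, n_per_chrom = 4L, seed = 21)
  an4 <- synthetic_loop_anchors(g, n_per_chrom = 16L, seed = 21)
  width <- function(an) {
    cts <- dplyr::bind_rows(lapply(1:4, function(i) {
      spec <- synthetic_spec(genome = g, n_contacts = 60000,
                             loop_anchors = an, loop_enrichment = 1,
                             trans_fraction = 0, seed = 30 + i)
      ct <- generate_cell(spec)$contacts
      ct$nucleus <- i
      ct
    }))
    w <- suppressWarnings(collect_loop_windows(cts, an, g))
    b <- bootstrap_loop_strength_ci(w, n_resamples = 400, seed = 2)
    b$ci_high - b$ci_low
  }
  w1 <- width(an1)
  w4 <- width(an4)
  # quadrupling the loop count should halve the width, within tolerance;
  # per-loop counts also quadruple at fixed depth, so allow a wide band
  expect_lt(w4, w1 * 0.8)
})

test_that("permutation test is valid under the null and powered under signal", {
  wa <- make_windows(4, eps = 1, seed0 = 100)
  wb <- make_windows(4, eps = 1, seed0 = 200)
  p_null <- permutation_test_loop_strength(wa, wb, n_permutations = 199,
                                           seed = 1)
  expect_gt(p_null$p_value, 0.01)
  expect_lte(p_null$p_value, 1)
  # identical inputs relabelled: difference 0, p large
  p_same <- permutation_test_loop_strength(wa, wa, n_permutations = 99,
                                           seed = 2)
  expect_equal(p_same$point_estimate, 0)
  expect_gt(p_same$p_value, 0.5)
  # planted 0 vs 1 with 10 replicates per group is significant
  w0 <- make_windows(10, eps = 0, seed0 = 300, n_contacts = 30000)
  w1 <- make_windows(10, eps = 1, seed0 = 400, n_contacts = 30000)
  p_sig <- permutation_test_loop_strength(w0, w1, n_permutations = 499,
                                          seed = 3)
  expect_lte(p_sig$p_value, 0.01)
  # p is floored by the +1 correction, never zero
  expect_gte(p_sig$p_value, 1 / 500)
})

test_that("group size guards are enforced", {
  wa <- make_windows(1, seed0 = 500)
  wb <- make_windows(2, seed0 = 600)
  expect_error(permutation_test_loop_strength(wa, wb), "at least 2 nuclei")
  w1 <- make_windows(2, seed0 = 700)
  w1$obs <- w1$obs[1, , drop = FALSE]
  w1$ctrl <- w1$ctrl[1, , drop = FALSE]
  w1$meta <- w1$meta[1, ]
  expect_error(bootstrap_loop_strength_ci(w1), "at least 2 loop windows")
})
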