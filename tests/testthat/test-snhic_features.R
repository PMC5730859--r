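test_that("binning increments one cell and its mirror, conserving mass", {
  g <- tibble::tibble(chrom = "chr1", size = 100e3)
  ct <- tibble::tibble(chrom1 = "chr1", pos1 = 15000,
                       chrom2 = "chr1", pos2 = 25000)
  bm <- bin_contacts(ct, g, 10000)
  m <- as.matrix(bm$intra$chr1)
  expect_equal(m[2, 3], 1)
  expect_equal(m[3, 2], 1)
  expect_equal(sum(m), 2)
  # empty list
  bm0 <- bin_contacts(ct[0, ], g, 10000)
  expect_equal(sum(bm0$intra$chr1), 0)
  # mass conservation on random input
  g2 <- tiny_genome()
  cell <- generate_cell(flat_spec(10000, seed = 2, genome = g2,
                                  trans_fraction = 0))
  bm2 <- bin_contacts(cell$contacts, g2, 10000)
  expect_equal(sum(vapply(bm2$intra, sum, numeric(1))), 2 * 10000)
  expect_error(bin_contacts(tibble::tibble(chrom1 = "chr1", pos1 = 2e5,
                                           chrom2 = "chr1", pos2 = 1),
                            g, 1e4), "outside")
})

test_that("P_c(s) recovers a generating power law and localizes spikes", {
  g <- synthetic_genome()
  cell <- generate_cell(flat_spec(4e5, exponent = -1.5, seed = 3,
                                  genome = g, trans_fraction = 0))
  curve <- compute_pcs(cell$contacts, g)
  win <- curve$s_mid >= 50e3 & curve$s_mid <= 5e6 & curve$p > 0
  fit <- coef(lm(log(p) ~ log(s_mid), data = curve[win, ]))[2]
  expect_lt(abs(fit + 1.5), 0.05)
  # all contacts at one separation occupy a single log bin
  ct <- tibble::tibble(chrom1 = "chr1", pos1 = seq(1e6, 2e6, by = 1e4),
                       chrom2 = "chr1", pos2 = seq(1e6, 2e6, by = 1e4) + 5e4)
  cv <- compute_pcs(ct, g)
  expect_equal(sum(cv$n_contacts > 0), 1L)
  nz <- cv[cv$n_contacts > 0, ]
  expect_true(nz$s_lo <= 5e4 & 5e4 < nz$s_hi)
  expect_error(compute_pcs(ct[0, ], g), "intra")
})

test_that("slope of an exact power law is constant; flat curve gives zero", {
  s <- 10e3 * 1.3^(0:30)
  cv <- tibble::tibble(s_lo = s, s_hi = s * 1.3, s_mid = s,
                       n_contacts = 1L, n_pairs = 1, p = s^-1.5)
  class(cv) <- c("pcs_curve", class(cv))
  sl <- pcs_slope(cv)
  expect_true(all(abs(sl$slope[3:28] + 1.5) < 0.02))
  cv$p <- 1
  sl0 <- pcs_slope(cv)
  expect_true(all(abs(sl0$slope) < 1e-10))
  expect_error(pcs_slope(cv[1:2, ]), "3 bins")
})

test_that("P_c(s) pools linearly over nuclei", {
  g <- tiny_genome()
  c1 <- generate_cell(flat_spec(20000, seed = 5, genome = g,
                                trans_fraction = 0))$contacts
  c2 <- generate_cell(flat_spec(20000, seed = 6, genome = g,
                                trans_fraction = 0))$contacts
  merged <- compute_pcs(dplyr::bind_rows(c1, c2), g)
  p1 <- compute_pcs(c1, g)
  p2 <- compute_pcs(c2, g)
  expect_equal(merged$n_contacts,
               p1$n_contacts[match(merged$s_mid, p1$s_mid)] +
                 p2$n_contacts[match(merged$s_mid, p2$s_mid)])
  # the pooled curve is the contact-weighted combination (same denominators)
  expect_equal(merged$p * merged$n_pairs, merged$n_contacts)
})

test_that("loop strength is exact on constructed aggregates", {
  expect_equal(loop_strength(matrix(1, 20, 20)), 0)
  m <- matrix(1, 20, 20)
  m[8:13, 8:13] <- 2
  expect_equal(loop_strength(m), 1)
  expect_error(loop_strength(matrix(0, 20, 20)), "zero")
})

test_that("uniform contacts give a flat loop aggregate", {
  g <- synthetic_genome()
  an <- synthetic_loop_anchors(g)
  cell <- generate_cell(flat_spec(8e5, seed = 8, genome = g,
                                  trans_fraction = 0))
  agg <- suppressWarnings(average_loops(cell$contacts, an, g))
  expect_lt(abs(agg$strength), 0.2)
  # anchors too close to the diagonal are skipped with a warning
  near <- tibble::tibble(chrom = "chr1", pos1 = 10e6, pos2 = 10.05e6)
  expect_warning(
    expect_error(collect_loop_windows(cell$contacts, near, g), "usable"),
    "skipped")
})

test_that("planted loops are recovered with the planted strength", {
  g <- synthetic_genome()
  an <- synthetic_loop_anchors(g)
  cell <- generate_cell(loop_spec(1.0, n_contacts = 2e6, seed = 5,
                                  genome = g, anchors = an))
  agg <- suppressWarnings(average_loops(cell$contacts, an, g))
  expect_lt(abs(agg$strength - 1.0), 0.25)
  # size-class filter restricts anchors by separation
  w <- suppressWarnings(collect_loop_windows(cell$contacts, an, g,
                                             size_class = "large"))
  sep <- w$loops$pos2 - w$loops$pos1
  expect_true(all(sep >= 250e3 & sep < 500e3))
})

test_that("TAD strength is the verbatim box ratio", {
  expect_equal(tad_strength(matrix(1, 90, 90)), 1)
  m <- matrix(1, 90, 90)
  m[31:60, 31:60] <- 2
  expect_equal(tad_strength(m), 0.5)
  expect_error(tad_strength(matrix(0, 90, 90)), "empty")
})

test_that("average_tads flags size bounds and recovers planted interiors", {
  g <- synthetic_genome()
  td <- synthetic_tad_intervals(g)
  bnd <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(chrom = td$chrom, pos = td$start),
    tibble::tibble(chrom = td$chrom, pos = td$end)))
  planted <- generate_cell(synthetic_spec(genome = g, n_contacts = 4e5,
                                          tad_intervals = td,
                                          tad_enrichment = 2,
                                          trans_fraction = 0, seed = 11))
  flat <- generate_cell(flat_spec(4e5, seed = 12, genome = g,
                                  trans_fraction = 0))
  agg_t <- average_tads(bin_contacts(planted$contacts, g), bnd)
  agg_0 <- average_tads(bin_contacts(flat$contacts, g), bnd)
  expect_lt(agg_t$strength, agg_0$strength)   # stronger TADs, smaller ratio
  expect_lt(abs(agg_0$strength - 1), 0.15)
  # interior exceeds flank blocks in the planted aggregate
  m <- agg_t$average
  expect_gt(mean(m[31:60, 31:60]), mean(m[1:30, 31:60]))
  # all TADs below the minimum size are skipped
  small <- tibble::tibble(chrom = "chr1", pos = c(10e6, 10.05e6))
  expect_error(average_tads(bin_contacts(flat$contacts, g), small,
                            min_size = 100e3), "size bounds")
})

test_that("compartment saddle detects planted checkerboards, flat otherwise", {
  g <- synthetic_genome()
  gc <- synthetic_gc_track(g)
  planted <- generate_cell(synthetic_spec(genome = g, n_contacts = 3e5,
                                          gc_track = gc,
                                          compartment_weight = 0.3,
                                          trans_fraction = 0, seed = 13))
  flat <- generate_cell(flat_spec(3e5, seed = 14, genome = g,
                                  trans_fraction = 0))
  sad_p <- compartment_saddle(bin_contacts(planted$contacts, g), gc)
  sad_0 <- compartment_saddle(bin_contacts(flat$contacts, g), gc)
  expect_gt(sad_p$strength, 0.3)
  expect_lt(abs(sad_0$strength), 0.15)
  # corners dominate the off-corner in the planted saddle
  expect_gt(sad_p$saddle[1, 1], sad_p$saddle[1, 5])
  expect_gt(sad_p$saddle[5, 5], sad_p$saddle[1, 5])
  # iterative correction equalizes row sums
  rs <- rowSums(sad_p$saddle)
  expect_lt(max(abs(rs - mean(rs))) / mean(rs), 1e-6)
  # shuffled GC gives a flat saddle
  gc_sh <- gc
  set.seed(1)
  gc_sh$gc <- sample(gc_sh$gc)
  sad_sh <- compartment_saddle(bin_contacts(planted$contacts, g), gc_sh)
  expect_lt(abs(sad_sh$strength), 0.15)
})

test_that("compartment strength formula and guards", {
  m <- matrix(1, 5, 5)
  expect_equal(compartment_strength(m), 0)
  m[1, 1] <- m[5, 5] <- 2
  expect_equal(compartment_strength(m), log(4))
  m[1, 5] <- 0
  expect_error(compartment_strength(m), "non-positive")
})

test_that("strength estimators are invariant to global count rescaling", {
  g <- synthetic_genome()
  gc <- synthetic_gc_track(g)
  td <- synthetic_tad_intervals(g)
  bnd <- tibble::tibble(chrom = td$chrom, pos = td$start)
  cell <- generate_cell(synthetic_spec(genome = g, n_contacts = 2e5,
                                       tad_intervals = td, tad_enrichment = 2,
                                       gc_track = gc, compartment_weight = 0.2,
                                       trans_fraction = 0, seed = 15))
  bm <- bin_contacts(cell$contacts, g)
  bm5 <- bm
  for (cn in names(bm5$intra)) bm5$intra[[cn]] <- bm5$intra[[cn]] * 5
  expect_equal(average_tads(bm, bnd)$strength,
               average_tads(bm5, bnd)$strength, tolerance = 1e-10)
  expect_equal(compartment_saddle(bm, gc)$strength,
               compartment_saddle(bm5, gc)$strength, tolerance = 1e-8)
})

test_that("insulation profile dips at planted boundaries", {
  g <- synthetic_genome()
  td <- synthetic_tad_intervals(g)
  bnd <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(chrom = td$chrom, pos = td$start),
    tibble::tibble(chrom = td$chrom, pos = td$end)))
  strong <- generate_cell(synthetic_spec(genome = g, n_contacts = 4e5,
                                         tad_intervals = td,
                                         tad_enrichment = 2.5,
                                         trans_fraction = 0, seed = 16))
  weak <- generate_cell(synthetic_spec(genome = g, n_contacts = 4e5,
                                       tad_intervals = td,
                                       tad_enrichment = 1.4,
                                       trans_fraction = 0, seed = 17))
  ins_s <- insulation_profile(bin_contacts(strong$contacts, g), bnd)
  ins_w <- insulation_profile(bin_contacts(weak$contacts, g), bnd)
  at0 <- function(x) x$aligned$mean[x$aligned$offset_bins == 0]
  far <- function(x) mean(x$aligned$mean[abs(x$aligned$offset_bins) > 15])
  # normalized dip at boundaries deeper (relative to flanks) when stronger
  expect_lt(at0(ins_s) / far(ins_s), at0(ins_w) / far(ins_w))
  # normalization: minimum of every profile is zero
  expect_true(all(vapply(split(ins_s$profile$norm, ins_s$profile$chrom),
                         min, numeric(1)) == 0))
})

test_that("pronucleus classification follows the thresholds", {
  # constructed curves at the decision points
  mk <- function(p15) {
    s <- 10e3 * 1.3^(0:32)
    p <- (s / 9e3)^-1.5
    i15 <- which.min(abs(log(s / 15e6)))
    p[i15] <- p15
    cv <- tibble::tibble(s_lo = s, s_hi = s * 1.3, s_mid = s,
                         n_contacts = 1L, n_pairs = 1, p = p)
    class(cv) <- c("pcs_curve", class(cv))
    cv
  }
  # normalize_pcs divides by the 9-kb bin (first bin here, ~1)
  expect_equal(classify_pronucleus(mk(1e-3), "G1"), "maternal")
  expect_equal(classify_pronucleus(mk(1.5e-5), "G1"), "paternal")
  # bad-data filter: P_c(30 kb) < 0.1 after normalization
  low <- mk(1e-3)
  i30 <- which.min(abs(log(low$s_mid / 30e3)))
  low$p[i30] <- 1e-3
  expect_equal(classify_pronucleus(low, "G1"), "excluded")
})
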