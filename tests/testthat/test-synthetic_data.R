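test_that("generator hits the requested trans fraction and background slope", {
  g <- synthetic_genome()
  spec <- synthetic_spec(genome = g, n_contacts = 1e5,
                         trans_fraction = 0.08, seed = 2)
  cell <- generate_cell(spec)
  tf <- trans_fraction(cell$contacts)
  expect_lt(abs(tf - 0.08), 0.003)
  curve <- compute_pcs(cell$contacts, g)
  win <- curve$s_mid >= 50e3 & curve$s_mid <= 5e6 & curve$p > 0
  fit <- coef(lm(log(p) ~ log(s_mid), data = curve[win, ]))[2]
  expect_lt(abs(fit + 1.5), 0.05)
})

test_that("generator is reproducible and respects edge cases", {
  spec <- flat_spec(5000, seed = 9)
  a <- generate_cell(spec)$contacts
  b <- generate_cell(spec)$contacts
  expect_identical(a, b)
  # distinct seeds give (almost) disjoint contact sets
  spec2 <- flat_spec(5000, seed = 10)
  cc <- generate_cell(spec2)$contacts
  overlap <- nrow(dplyr::inner_join(a, cc,
                                    by = c("chrom1", "pos1", "chrom2", "pos2")))
  expect_lt(overlap, 5)
  # empty cell
  empty <- generate_cell(flat_spec(0, seed = 1))
  expect_equal(nrow(empty$contacts), 0)
  expect_equal(empty$truth$parent, "paternal")
  # positions inside chromosomes
  v <- generate_cell(flat_spec(20000, seed = 11))
  expect_silent(zygoloop:::validate_contacts(v$contacts, synthetic_genome()))
})

test_that("panels classify 100% correctly with and without the plateau", {
  g <- synthetic_genome()
  for (gt in c("control", "scc1", "wapl")) {
    mat <- generate_panel(3, gt, "maternal", n_contacts = 30000, seed = 5)
    pat <- generate_panel(3, gt, "paternal", n_contacts = 30000, seed = 6)
    phase <- mat$truth[[1]]$phase
    lm_ <- sort_pronuclei(mat$contacts, g, phase)
    lp_ <- sort_pronuclei(pat$contacts, g, phase)
    expect_true(all(lm_$label == "maternal"), label = paste(gt, "maternal"))
    expect_true(all(lp_$label == "paternal"), label = paste(gt, "paternal"))
  }
})

test_that("genotype presets order features as expected", {
  g <- synthetic_genome()
  an <- synthetic_loop_anchors(g)
  gc <- synthetic_gc_track(g)
  panel <- function(gt, n = 5) {
    p <- generate_panel(n, gt, "paternal", n_contacts = 60000, seed = 3)
    p$contacts
  }
  ctrl <- panel("control")
  scc1 <- panel("scc1")
  wapl <- panel("wapl")
  s_ctrl <- suppressWarnings(average_loops(ctrl, an, g))$strength
  s_scc1 <- suppressWarnings(average_loops(scc1, an, g))$strength
  s_wapl <- suppressWarnings(average_loops(wapl, an, g))$strength
  expect_lt(abs(s_scc1), 0.25)          # no loops planted
  expect_gt(s_ctrl, s_scc1 + 0.3)
  expect_gt(s_wapl, s_ctrl)             # stronger loops when release blocked
  c_scc1 <- compartment_saddle(bin_contacts(scc1, g), gc)$strength
  c_wapl <- compartment_saddle(bin_contacts(wapl, g), gc)$strength
  expect_gt(c_scc1, c_wapl)             # compartments stronger without cohesin
})

test_that("downsampling preserves the contact-probability curve", {
  g <- tiny_genome()
  cell <- generate_cell(flat_spec(50000, seed = 4, genome = g))
  sub1 <- contacts_from_simulation(cell$contacts, 10000, seed = 1)
  sub2 <- contacts_from_simulation(cell$contacts, 10000, seed = 2)
  expect_equal(nrow(sub1), 10000)
  expect_false(identical(sub1, sub2))
  p1 <- compute_pcs(sub1, g)
  p2 <- compute_pcs(sub2, g)
  j <- dplyr::inner_join(p1, p2, by = "s_mid")
  big <- j$n_contacts.x + j$n_contacts.y > 100
  expect_lt(max(abs(log(j$p.x[big] / j$p.y[big]))), 0.5)
  expect_identical(contacts_from_simulation(cell$contacts, nrow(cell$contacts)),
                   cell$contacts)
  expect_equal(nrow(contacts_from_simulation(cell$contacts, 0)), 0)
  expect_error(contacts_from_simulation(cell$contacts, 1e7), "exceeds")
})
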