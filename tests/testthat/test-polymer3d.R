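test_that("box side follows the volume-fraction algebra", {
  p <- polymer_params(30000, density = 0.02, init_mode = "random_walk")
  expect_equal(p$box_side, (30000 * (4 / 3) * pi * 0.5^3 / 0.02)^(1 / 3))
})

test_that("fractal globule initialization is compact (R ~ N^(1/3))", {
  p <- polymer_params(4096, init_mode = "fractal_globule", seed = 2)
  cf <- init_conformation(p)
  xyz <- cf$coords
  # consecutive monomers at ~unit spacing
  bl <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
  expect_lt(abs(mean(bl) - 1), 0.1)
  # subchain extent scaling exponent close to 1/3
  ss <- c(64, 256, 1024, 4096)
  ext <- vapply(ss, function(s) {
    starts <- seq(1, 4096 - s + 1, by = s)
    mean(vapply(starts, function(a) {
      seg <- xyz[a:(a + s - 1), ]
      sqrt(sum((apply(seg, 2, max) - apply(seg, 2, min))^2))
    }, numeric(1)))
  }, numeric(1))
  expo <- coef(lm(log(ext) ~ log(ss)))[2]
  expect_lt(abs(expo - 1 / 3), 0.1)
})

test_that("mitotic-like initialization stacks loops along an axis", {
  p <- polymer_params(1000, init_mode = "mitotic_like")
  cf <- init_conformation(p)
  xyz <- cf$coords
  rho <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  r_cyl <- max(rho)
  expect_gt(mean(rho <= 2 * median(rho)), 0.95)
  # linear ordering along the axis: monomer index correlates with z
  expect_gt(cor(seq_len(1000), xyz[, 3]), 0.95)
  expect_lt(r_cyl, 20)
})

test_that("bond lengths stay near rest length under the integrator", {
  p <- polymer_params(500, density = 0.05, md_steps_per_extrusion = 300,
                      init_mode = "random_walk", seed = 4)
  cf <- init_conformation(p)
  ser <- evolve_with_extrusion(cf, NULL, p, n_epochs = 2)
  co <- ser[[length(ser)]]$coords
  bl <- sqrt(rowSums((co[-1, ] - co[-nrow(co), ])^2))
  expect_lt(abs(mean(bl) - 1), 0.1)
})

test_that("contact capture respects the radius threshold and symmetry", {
  # dilute box so no periodic image comes within reach of the rod
  p <- polymer_params(10, n_chains = 1, density = 1e-4,
                      init_mode = "random_walk", seed = 1)
  cf <- init_conformation(p)
  # straight rod at unit spacing: contacts exactly for |i - j| <= radius
  cf$coords <- cbind(seq_len(10), 0, 0)
  ct <- simulated_contacts(cf, contact_radius_monomers = 2)
  sep <- abs(ct$pos2 - ct$pos1) / p$monomer_bp
  expect_true(all(sep <= 2))
  expect_equal(nrow(ct), 9 + 8)        # |i-j| = 1 and 2
  # threshold inclusion at 4.9 vs radius 5
  cf2 <- cf
  cf2$coords <- rbind(c(0, 0, 0), c(4.9, 0, 0), c(100, 100, 100))
  cf2$chain_id <- rep(1L, 3)
  cf2$params$n_monomers <- 3L
  ct2 <- simulated_contacts(cf2, contact_radius_monomers = 5)
  expect_equal(nrow(ct2), 1L)
  # canonical storage is symmetric under pair swap
  expect_true(all(ct$pos1 <= ct$pos2))
})

test_that("LEF bonds compact the chain relative to a LEF-free run", {
  n <- 600
  lp <- lef_params(n, 240e3, 90e3, n_steps = 80, seed = 2)
  st <- run_lef_dynamics(lp, record_every = 1L, seeds = 2)
  tr <- tidy(st)
  tr <- tr[tr$step > 0, ]
  pp <- polymer_params(n, density = 0.05, md_steps_per_extrusion = 60,
                       init_mode = "random_walk", seed = 2)
  cf <- init_conformation(pp)
  with_lef <- evolve_with_extrusion(cf, tr, pp)
  free <- evolve_with_extrusion(cf, NULL, pp, n_epochs = 80)
  rg <- function(co) sqrt(mean(rowSums(sweep(co, 2, colMeans(co))^2)))
  expect_lt(rg(with_lef[[length(with_lef)]]$coords),
            rg(free[[length(free)]]$coords))
})

test_that("hull metrics match closed forms for spheres", {
  p <- polymer_params(2, init_mode = "random_walk", seed = 1)
  cf <- init_conformation(p)
  r <- 75
  # two disjoint spheres: exactly twice the single-sphere area and volume
  cf$coords <- matrix(c(0, 0, 0, 1000, 0, 0), 2, 3, byrow = TRUE)
  hm <- hull_metrics(cf, r, n_dirs = 1000L, n_vol_samples = 2000L)
  expect_equal(hm$surface_area_nm2, 2 * 4 * pi * r^2, tolerance = 0.01)
  expect_equal(hm$volume_nm3, 2 * (4 / 3) * pi * r^3, tolerance = 0.02)
  # overlapping spheres: lens-corrected union
  d <- 37.5
  cf$coords <- matrix(c(0, 0, 0, d / 15, 0, 0), 2, 3, byrow = TRUE)
  hm2 <- hull_metrics(cf, r, n_dirs = 2000L, n_vol_samples = 8000L, seed = 2)
  h <- r - d / 2
  area <- 2 * (4 * pi * r^2 - 2 * pi * r * h)
  vol <- 2 * (4 / 3) * pi * r^3 -
    pi * (2 * r - d)^2 * (d^2 + 4 * d * r) / (12 * d)
  expect_equal(hm2$surface_area_nm2, area, tolerance = 0.02)
  expect_equal(hm2$volume_nm3, vol, tolerance = 0.03)
})

test_that("hull estimates agree with a voxelization oracle", {
  # oracle: occupied-voxel volume and dV/dr area on a random blob
  set.seed(9)
  p <- polymer_params(40, init_mode = "random_walk", seed = 9)
  cf <- init_conformation(p)
  cf$coords <- matrix(rnorm(120, sd = 3), 40, 3)
  r <- 5   # monomer units (75 nm / 15 nm)
  voxel_volume <- function(coords, radius, h = 0.3) {
    lo <- apply(coords, 2, min) - radius - h
    hi <- apply(coords, 2, max) + radius + h
    gx <- seq(lo[1], hi[1], by = h)
    gy <- seq(lo[2], hi[2], by = h)
    gz <- seq(lo[3], hi[3], by = h)
    occ <- array(FALSE, c(length(gx), length(gy), length(gz)))
    for (k in seq_len(nrow(coords))) {
      ix <- which(abs(gx - coords[k, 1]) <= radius)
      iy <- which(abs(gy - coords[k, 2]) <= radius)
      iz <- which(abs(gz - coords[k, 3]) <= radius)
      d2 <- outer(outer((gx[ix] - coords[k, 1])^2,
                        (gy[iy] - coords[k, 2])^2, `+`),
                  (gz[iz] - coords[k, 3])^2, `+`)
      occ[ix, iy, iz] <- occ[ix, iy, iz] | (d2 <= radius^2)
    }
    sum(occ) * h^3
  }
  v0 <- voxel_volume(cf$coords, r)
  dv <- 0.4
  a0 <- (voxel_volume(cf$coords, r + dv / 2) -
           voxel_volume(cf$coords, r - dv / 2)) / dv
  hm <- hull_metrics(cf, monomer_radius_nm = r * 15, n_dirs = 600L,
                     n_vol_samples = 800L, seed = 3)
  expect_equal(hm$volume_nm3 / 15^3, v0, tolerance = 0.05)
  expect_equal(hm$surface_area_nm2 / 15^2, a0, tolerance = 0.05)
})

test_that("trans fraction counts inter-chain contacts", {
  ct <- tibble::tibble(chrom1 = c("a", "a", "b"), pos1 = c(1, 2, 3),
                       chrom2 = c("a", "b", "b"), pos2 = c(5, 6, 7))
  expect_equal(trans_fraction(ct), 1 / 3)
  expect_equal(trans_fraction(ct[c(1, 3), ]), 0)
  # 3 trans of 50
  ct50 <- tibble::tibble(chrom1 = rep("a", 50), pos1 = 1:50,
                         chrom2 = c(rep("b", 3), rep("a", 47)), pos2 = 1:50)
  expect_equal(trans_fraction(ct50), 0.06)
  expect_error(trans_fraction(ct[0, ]), "empty")
  # invariant under mirroring
  mir <- ct
  names(mir) <- c("chrom2", "pos2", "chrom1", "pos1")
  expect_equal(trans_fraction(dplyr::bind_rows(ct, mir)), trans_fraction(ct))
})
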