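#' Parameters of the coarse-grained 3-D polymer model
#'
#' One monomer represents `monomer_bp` of chromatin and one monomer diameter
#' equals `nm_per_monomer` nanometres (default 15 nm). Dynamics are overdamped
#' Langevin (kT = 1, friction = 1) with harmonic backbone and LEF bonds and a
#' soft purely repulsive excluded volume, in a cubic periodic box whose side is
#' set by the monomer volume fraction `density`.
#'
#' @param n_monomers Monomers per chain.
#' @param n_chains Number of chains in the box (default 1).
#' @param density Monomer volume fraction (default 0.02; the sparser paternal
#'   Wapl-knockout condition uses 0.01).
#' @param md_steps_per_extrusion Integration steps per loop-extrusion step
#'   (default 2,000).
#' @param init_mode One of `"fractal_globule"` (space-filling-curve collapsed
#'   state), `"mitotic_like"` (consecutive 100-monomer loops stacked along an
#'   axis) or `"random_walk"` (equilibrium ideal-chain draw).
#' @param contact_radius_monomers Capture radius for contact detection in
#'   monomer diameters (default 5 = 75 nm; 2 and 10 are used as alternates).
#' @param monomer_bp Base pairs per monomer (default 600).
#' @param nm_per_monomer Nanometres per monomer diameter (default 15).
#' @param dt Integration time step (default 0.01).
#' @param k_bond Harmonic bond stiffness (default 40; LEF bonds use the same).
#' @param ev_eps Excluded-volume energy scale (default 10; 0 disables it).
#' @param chain_placement `"side_by_side"` (default) places chains on a grid;
#'   `"overlapping"` superimposes their centres of mass, modelling an
#'   initially intermingled (pre-territorial) nuclear state. Only meaningful
#'   with soft excluded volume and expanded initial conformations.
#' @param seed RNG seed.
#' @return List of class `polymer_params` with a derived `box_side`.
#' @export
polymer_params <- function(n_monomers, n_chains = 1L, density = 0.02,
                           md_steps_per_extrusion = 2000L,
                           init_mode = c("fractal_globule", "mitotic_like",
                                         "random_walk"),
                           contact_radius_monomers = 5,
                           monomer_bp = 600, nm_per_monomer = 15,
                           dt = 0.01, k_bond = 40, ev_eps = 10,
                           chain_placement = c("side_by_side", "overlapping"),
                           seed = 1L) {
  init_mode <- match.arg(init_mode)
  chain_placement <- match.arg(chain_placement)
  stopifnot(n_monomers >= 2, n_chains >= 1, md_steps_per_extrusion >= 1,
            contact_radius_monomers > 0, dt > 0)
  if (density <= 0 || density > 0.3)
    stop("`density` must lie in (0, 0.3]")
  n_tot <- n_monomers * n_chains
  box_side <- (n_tot * pi / (6 * density))^(1 / 3)
  structure(
    list(n_monomers = as.integer(n_monomers), n_chains = as.integer(n_chains),
         density = density,
         md_steps_per_extrusion = as.integer(md_steps_per_extrusion),
         init_mode = init_mode,
         contact_radius_monomers = contact_radius_monomers,
         monomer_bp = monomer_bp, nm_per_monomer = nm_per_monomer,
         dt = dt, k_bond = k_bond, ev_eps = ev_eps,
         chain_placement = chain_placement,
         seed = as.integer(seed), box_side = box_side),
    class = "polymer_params")
}

#' 3-D Hilbert space-filling curve
#'
#' Returns the first `n_points` vertices of the 3-D Hilbert curve of the
#' smallest order whose cube holds them; consecutive vertices are at unit
#' distance and any subchain of length s occupies a region of linear size
#' ~ s^(1/3), the defining property of a fractal (crumpled) globule.
#'
#' @param n_points Number of curve vertices.
#' @return Integer matrix `n_points` x 3 of lattice coordinates.
#' @keywords internal
hilbert_curve_3d <- function(n_points) {
  b <- 1L
  while ((2L^b)^3 < n_points) b <- b + 1L
  n_side <- 2L^b
  out <- matrix(0L, n_points, 3L)
  for (d in seq_len(n_points) - 1L) {
    # transpose form: bits of d distributed cyclically over the 3 axes
    X <- integer(3L)
    for (bit in 0:(3L * b - 1L)) {
      v <- bitwAnd(bitwShiftR(d, 3L * b - 1L - bit), 1L)
      ax <- (bit %% 3L) + 1L
      X[ax] <- bitwOr(bitwShiftL(X[ax], 1L), v)
    }
    # Gray decode
    t <- bitwShiftR(X[3L], 1L)
    for (k in 3:2) X[k] <- bitwXor(X[k], X[k - 1L])
    X[1L] <- bitwXor(X[1L], t)
    # undo excess work
    Q <- 2L
    while (Q != n_side) {
      P <- Q - 1L
      for (k in 3:1) {
        if (bitwAnd(X[k], Q)) {
          X[1L] <- bitwXor(X[1L], P)
        } else {
          tt <- bitwAnd(bitwXor(X[1L], X[k]), P)
          X[1L] <- bitwXor(X[1L], tt)
          X[k] <- bitwXor(X[k], tt)
        }
      }
      Q <- bitwShiftL(Q, 1L)
    }
    out[d + 1L, ] <- X
  }
  out
}

#' Initialise a polymer conformation
#'
#' Builds the initial coordinates for each chain according to
#' `params$init_mode` and places the chains side by side in the periodic box.
#' Coordinates are kept unwrapped throughout; the box applies to excluded
#' volume and inter-chain contact detection only.
#'
#' @param params A [polymer_params()] object.
#' @return List of class `conformation`: `coords` (matrix n x 3), `box_side`,
#'   `chain_id` (integer vector), `params`.
#' @export
init_conformation <- function(params) {
  set.seed(params$seed)
  n <- params$n_monomers
  one_chain <- switch(params$init_mode,
    fractal_globule = {
      xyz <- hilbert_curve_3d(n)
      xyz + matrix(runif(3L * n, -0.05, 0.05), n, 3L)
    },
    mitotic_like = {
      loop_len <- min(100L, max(10L, n %/% 10L))
      rho <- loop_len / (2 * pi)
      k <- (seq_len(n) - 1L) %/% loop_len
      phi <- 2 * pi * ((seq_len(n) - 1L) %% loop_len) / loop_len
      theta <- 0.05 * k
      cbind(rho * cos(phi + theta), rho * sin(phi + theta), k * 1.0)
    },
    random_walk = {
      steps <- matrix(rnorm(3L * (n - 1L)), n - 1L, 3L)
      steps <- steps / sqrt(rowSums(steps^2))
      rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    })
  coords <- NULL
  chain_id <- integer(0)
  spacing <- if (identical(params$chain_placement, "overlapping")) 0 else
    max(apply(one_chain, 2L, function(v) diff(range(v)))) + 3
  for (c in seq_len(params$n_chains)) {
    block <- switch(params$init_mode,
      random_walk = {
        steps <- matrix(rnorm(3L * (n - 1L)), n - 1L, 3L)
        steps <- steps / sqrt(rowSums(steps^2))
        rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
      },
      one_chain)
    block <- sweep(block, 2L, c((c - 1L) * spacing, 0, 0), `+`)
    coords <- rbind(coords, block)
    chain_id <- c(chain_id, rep.int(c, n))
  }
  structure(list(coords = coords, box_side = params$box_side,
                 chain_id = as.integer(chain_id), params = params),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", nrow(x$coords), " monomers in ",
      length(unique(x$chain_id)), " chain(s), box side ",
      round(x$box_side, 1), " monomer diameters\n", sep = "")
  invisible(x)
}

#' @export
tidy.conformation <- function(x, ...) {
  tibble::tibble(chain = x$chain_id,
                 monomer = stats::ave(x$chain_id, x$chain_id,
                                      FUN = seq_along) - 1L,
                 x = x$coords[, 1L], y = x$coords[, 2L], z = x$coords[, 3L])
}

#' Evolve a conformation under loop-extrusion coupling
#'
#' Advances the bead-spring dynamics, updating the set of harmonic LEF bonds
#' (connecting each LEF's left and right legs) after every loop-extrusion
#' step, with `params$md_steps_per_extrusion` integration steps per extrusion
#' step. With `lef_trajectory = NULL` the chain evolves without LEFs for
#' `n_epochs` equivalent windows.
#'
#' @param conf A [init_conformation()] object.
#' @param lef_trajectory Tibble with columns `step`, `lef`, `left`, `right` and
#'   optionally `chain` (1-based; default 1), as produced by
#'   `tidy(run_lef_dynamics(...))`, or `NULL` for LEF-free dynamics.
#' @param params The [polymer_params()] object.
#' @param n_epochs Number of epochs when `lef_trajectory` is `NULL`.
#' @param record_every Record the conformation every this many epochs.
#' @return List of `conformation` objects (class `conformation_series`), the
#'   last element being the final state.
#' @export
evolve_with_extrusion <- function(conf, lef_trajectory = NULL, params = conf$params,
                                  n_epochs = NULL, record_every = 1L) {
  coords <- conf$coords
  n <- params$n_monomers
  if (is.null(lef_trajectory)) {
    if (is.null(n_epochs)) stop("`n_epochs` is required without a trajectory")
    epochs <- seq_len(n_epochs)
    bonds_for <- function(e) matrix(integer(0), 0L, 2L)
  } else {
    stopifnot(all(c("step", "left", "right") %in% names(lef_trajectory)))
    if (max(lef_trajectory$right) >= n)
      stop("LEF trajectory does not match the chain length")
    if (!"chain" %in% names(lef_trajectory)) lef_trajectory$chain <- 1L
    split_tr <- split(lef_trajectory, lef_trajectory$step)
    epochs <- as.integer(names(split_tr))
    bonds_for <- function(e) {
      tr <- split_tr[[as.character(e)]]
      off <- (tr$chain - 1L) * n
      cbind(tr$left + off, tr$right + off)
    }
  }
  set.seed(params$seed)
  out <- list()
  for (k in seq_along(epochs)) {
    eb <- bonds_for(epochs[k])
    storage.mode(eb) <- "integer"
    coords <- cpp_md_run(coords, conf$box_side, conf$chain_id, eb,
                         params$md_steps_per_extrusion, params$dt,
                         params$k_bond, params$ev_eps, 1.0)
    if (k %% record_every == 0L || k == length(epochs)) {
      snap <- conf
      snap$coords <- coords
      snap$epoch <- epochs[k]
      out[[length(out) + 1L]] <- snap
    }
  }
  structure(out, class = "conformation_series")
}

#' Contacts captured from simulated conformations
#'
#' Emits every monomer pair within the capture radius as a contact with
#' genomic coordinates `monomer * monomer_bp`. Intra-chain pairs use the
#' direct (unwrapped) chain geometry; pairs close only to a periodic image of
#' the same chain are flagged `"self_image"`, and pairs between distinct
#' chains `"trans"`.
#'
#' @param confs A `conformation`, a `conformation_series`, or a list of
#'   conformations.
#' @param contact_radius_monomers Capture radius (monomer diameters).
#' @param monomer_bp Base pairs per monomer.
#' @return Tibble with columns `chrom1`, `pos1`, `chrom2`, `pos2`, `type`
#'   (`"intra"`, `"trans"`, `"self_image"`) and `conformation`.
#' @export
simulated_contacts <- function(confs,
                               contact_radius_monomers = NULL,
                               monomer_bp = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  stopifnot(length(confs) >= 1)
  p <- confs[[1L]]$params
  if (is.null(contact_radius_monomers))
    contact_radius_monomers <- p$contact_radius_monomers
  if (is.null(monomer_bp)) monomer_bp <- p$monomer_bp
  if (contact_radius_monomers <= 0) stop("contact radius must be positive")
  n <- p$n_monomers
  res <- purrr::imap(confs, function(cf, idx) {
    ct <- cpp_contacts(cf$coords, cf$box_side, cf$chain_id,
                       contact_radius_monomers)
    i <- ct$i
    j <- ct$j
    ch_i <- cf$chain_id[i + 1L]
    ch_j <- cf$chain_id[j + 1L]
    mono_i <- i - (ch_i - 1L) * n
    mono_j <- j - (ch_j - 1L) * n
    tibble::tibble(
      chrom1 = paste0("chain", ch_i),
      pos1 = mono_i * monomer_bp,
      chrom2 = paste0("chain", ch_j),
      pos2 = mono_j * monomer_bp,
      type = c("intra", "trans", "self_image")[ct$type + 1L],
      conformation = idx)
  })
  out <- dplyr::bind_rows(res)
  canonicalize_contacts(out)
}

#' Genome table for a simulated system
#'
#' @param params A [polymer_params()] object.
#' @return Tibble with columns `chrom`, `size` (one row per chain).
#' @export
simulation_genome <- function(params) {
  tibble::tibble(chrom = paste0("chain", seq_len(params$n_chains)),
                 size = params$n_monomers * params$monomer_bp)
}

#' Concave-hull surface area and volume of a conformation
#'
#' Measures the surface area and enclosed volume of the chromatin fiber,
#' modelled as the union of spheres of radius `monomer_radius_nm` centred on
#' the monomers (the concave hull at the capture radius). Area uses
#' deterministic Shrake-Rupley point counting; volume uses an unbiased
#' per-sphere Monte Carlo estimator with inverse-multiplicity weights.
#'
#' @param conf A `conformation`.
#' @param monomer_radius_nm Effective sphere radius in nm (default 75 nm, the
#'   capture radius of 5 monomer diameters).
#' @param n_dirs Surface sample directions per sphere (default 300).
#' @param n_vol_samples Volume samples per sphere (default 60).
#' @param by_chain Compute the hull of each chain (chromosome territory)
#'   separately instead of the whole system (default FALSE).
#' @param seed RNG seed for the volume estimator.
#' @return Tibble with columns `surface_area_nm2`, `volume_nm3`,
#'   `monomer_radius_nm` (one row, or one per chain with a `chain` column).
#' @export
hull_metrics <- function(conf, monomer_radius_nm = 75,
                         n_dirs = 300L, n_vol_samples = 60L,
                         by_chain = FALSE, seed = 1L) {
  stopifnot(inherits(conf, "conformation"))
  if (nrow(conf$coords) < 1) stop("empty conformation")
  nm <- conf$params$nm_per_monomer
  radius <- monomer_radius_nm / nm
  set.seed(seed)
  one <- function(coords) {
    res <- cpp_hull_metrics(coords, radius, as.integer(n_dirs),
                            as.integer(n_vol_samples))
    tibble::tibble(surface_area_nm2 = res$area * nm^2,
                   volume_nm3 = res$volume * nm^3,
                   monomer_radius_nm = monomer_radius_nm)
  }
  if (!by_chain) return(one(conf$coords))
  chains <- sort(unique(conf$chain_id))
  out <- purrr::map(chains, function(ch) one(conf$coords[conf$chain_id == ch, , drop = FALSE]))
  dplyr::bind_rows(out) %>% dplyr::mutate(chain = chains, .before = 1)
}

#' Geometry/trans-contact sweep across loop-extrusion regimes
#'
#' Runs the coupled 1-D/3-D model for a series of (processivity, separation)
#' parameter pairs, from cohesin-depleted to release-deficient regimes, in a
#' box of several initially intermingled chains, and measures the mean
#' chromosome-territory hull surface area and the inter-chain (trans) contact
#' fraction of each regime. Loop extrusion compacts and demixes the chains, so
#' both quantities decrease together as extrusion strengthens.
#'
#' @param cells List of `c(processivity_bp, separation_bp)` pairs, ordered
#'   from weakest to strongest extrusion by default.
#' @param n_monomers Monomers per chain (default 500).
#' @param n_chains Chains in the box (default 6).
#' @param density Monomer volume fraction (default 0.1).
#' @param n_epochs Extrusion steps (default 200).
#' @param md_steps Integration steps per extrusion step (default 80).
#' @param replicates Independent replicate runs per cell (default 2).
#' @param contact_radius_monomers Capture radius (default 5).
#' @param seed Master seed.
#' @return Tibble with one row per cell: `processivity_bp`, `separation_bp`,
#'   `surface_area_nm2` (mean per-chain territory area), `trans_fraction`.
#' @export
extrusion_geometry_sweep <- function(cells = list(c(60e3, 600e3),
                                                  c(120e3, 120e3),
                                                  c(480e3, 60e3)),
                                     n_monomers = 1000L, n_chains = 6L,
                                     density = 0.1, n_epochs = 180L,
                                     md_steps = 60L, replicates = 3L,
                                     contact_radius_monomers = 5,
                                     seed = 1L) {
  boundaries <- tad_boundary_pattern()[tad_boundary_pattern() < n_monomers]
  out <- purrr::imap(cells, function(cell, ci) {
    reps <- purrr::map(seq_len(replicates), function(rep) {
      seed0 <- seed + ci * 1000L + rep * 7L
      trs <- purrr::map(seq_len(n_chains), function(ch) {
        lp <- lef_params(n_monomers, cell[1], cell[2], n_steps = n_epochs,
                         seed = seed0 + ch)
        st <- run_lef_dynamics(lp, boundaries, record_every = 1L,
                               seeds = seed0 + ch)
        tr <- tidy(st)
        tr <- tr[tr$step > 0, ]
        tr$chain <- ch
        tr
      })
      tr <- dplyr::bind_rows(trs)
      pp <- polymer_params(n_monomers, n_chains = n_chains, density = density,
                           md_steps_per_extrusion = md_steps,
                           init_mode = "random_walk",
                           chain_placement = "overlapping",
                           contact_radius_monomers = contact_radius_monomers,
                           seed = seed0)
      cf <- init_conformation(pp)
      ser <- evolve_with_extrusion(cf, tr, pp, record_every = 15L)
      nl <- length(ser)
      ct <- simulated_contacts(ser[max(1, nl - 7):nl])
      hm <- dplyr::bind_rows(purrr::map(ser[max(1, nl - 2):nl], hull_metrics,
                                        monomer_radius_nm = 75,
                                        n_dirs = 150L, n_vol_samples = 10L,
                                        by_chain = TRUE))
      tibble::tibble(surface_area_nm2 = mean(hm$surface_area_nm2),
                     trans_fraction = trans_fraction(ct,
                                                     include_self_images = FALSE))
    })
    reps <- dplyr::bind_rows(reps)
    tibble::tibble(processivity_bp = cell[1], separation_bp = cell[2],
                   surface_area_nm2 = mean(reps$surface_area_nm2),
                   trans_fraction = mean(reps$trans_fraction))
  })
  dplyr::bind_rows(out)
}

#' Trans-contact fraction
#'
#' Fraction of contacts joining distinct chromosomes (distinct chains in
#' simulations). Contacts between a chain and its own periodic image, when
#' flagged by [simulated_contacts()], can be counted as trans or excluded.
#'
#' @param contacts Contact tibble with `chrom1`, `chrom2` (and optionally
#'   `type`).
#' @param include_self_images Count `"self_image"` contacts as trans
#'   (default TRUE).
#' @return A single number in `[0, 1]`.
#' @export
trans_fraction <- function(contacts, include_self_images = TRUE) {
  if (nrow(contacts) == 0) stop("empty contact list")
  trans <- contacts$chrom1 != contacts$chrom2
  if ("type" %in% names(contacts)) {
    if (include_self_images) {
      trans <- trans | contacts$type == "self_image"
    }
  }
  mean(trans)
}
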