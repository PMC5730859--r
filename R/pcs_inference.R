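find_local_extrema <- function(x, persistence = 3L, prominence = 0.02) {
  # indices of local maxima/minima that dominate a +/- persistence
  # neighbourhood and rise/drop by at least `prominence` on both sides
  n <- length(x)
  maxima <- integer(0)
  minima <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - persistence)
    hi <- min(n, i + persistence)
    nb <- x[lo:hi]
    if (x[i] >= max(nb)) {
      left <- x[seq_len(i - 1L)]
      right <- x[seq.int(i + 1L, length.out = n - i)]
      if (length(left) && length(right) &&
          x[i] - min(left) >= prominence && x[i] - min(right) >= prominence)
        maxima <- c(maxima, i)
    }
    if (x[i] <= min(nb)) {
      left <- x[seq_len(i - 1L)]
      right <- x[seq.int(i + 1L, length.out = n - i)]
      if (length(left) && length(right) &&
          max(left) - x[i] >= prominence && max(right) - x[i] >= prominence)
        minima <- c(minima, i)
    }
  }
  list(maxima = maxima, minima = minima)
}

#' Infer the average extruded loop size from a P_c(s) slope series
#'
#' The location of the local maximum of the smoothed log-log slope (the
#' position of the least-negative slope) closely matches the average length of
#' cohesin-extruded loops; the depth of the subsequent local minimum grows
#' with the linear density of extruders. Extrema are detected with a
#' `persistence`-bin dominance criterion and a minimum prominence, so a
#' monotone slope (a pure power law) yields `no_maximum_detected`.
#'
#' @param slopes A slope series from [pcs_slope()] (columns `s_mid`, `slope`).
#' @param s_window Search window in bp (default 10 kb - 10 Mb).
#' @param persistence Dominance half-width in bins (default 3).
#' @param prominence Minimum slope prominence (default 0.02).
#' @param plateau_tol In strongly compacted (dense) regimes the slope maximum
#'   broadens into a plateau; the reported location is the left edge of the
#'   contiguous region within `plateau_tol` of the maximum (default 0.05),
#'   which reduces to the peak position for a rounded maximum.
#' @return List of class `extrusion_estimate`: `loop_size_bp`,
#'   `min_slope_location_bp`, `density_signature` (slope at the maximum minus
#'   slope at the subsequent minimum; non-negative), `max_slope`, `min_slope`,
#'   and flags `no_maximum_detected`, `no_minimum_detected`.
#' @export
infer_extruded_loop_size <- function(slopes, s_window = c(10e3, 10e6),
                                     persistence = 3L, prominence = 0.02,
                                     plateau_tol = 0.05) {
  stopifnot(all(c("s_mid", "slope") %in% names(slopes)))
  sel <- slopes$s_mid >= s_window[1] & slopes$s_mid <= s_window[2]
  s <- slopes$s_mid[sel]
  v <- slopes$slope[sel]
  if (length(v) < 5) stop("slope series shorter than 5 bins in the window")
  ex <- find_local_extrema(v, persistence, prominence)
  est <- structure(
    list(loop_size_bp = NA_real_, min_slope_location_bp = NA_real_,
         density_signature = NA_real_, max_slope = NA_real_,
         min_slope = NA_real_, no_maximum_detected = TRUE,
         no_minimum_detected = TRUE),
    class = "extrusion_estimate")
  if (!length(ex$maxima)) return(est)
  # the loop-size shoulder is the first local maximum; later maxima are the
  # recovery of the slope beyond the density dip
  imax <- ex$maxima[1]
  ipeak <- imax
  while (imax > 1 && v[imax - 1] >= v[ipeak] - plateau_tol)
    imax <- imax - 1L
  est$loop_size_bp <- s[imax]
  est$max_slope <- v[ipeak]
  est$no_maximum_detected <- FALSE
  # the density dip: deepest point beyond the shoulder (the slope need not
  # recover within the observable range for the dip to be real)
  if (ipeak < length(v)) {
    imin <- ipeak + which.min(v[(ipeak + 1):length(v)])
    if (v[ipeak] - v[imin] >= prominence) {
      est$min_slope_location_bp <- s[imin]
      est$min_slope <- v[imin]
      est$density_signature <- v[ipeak] - v[imin]
      est$no_minimum_detected <- FALSE
    }
  }
  est
}

#' Cohesin-density signature of a slope series
#'
#' Convenience wrapper around [infer_extruded_loop_size()] returning the same
#' estimate; the `density_signature` (depth of the slope minimum below the
#' preceding maximum) is monotone in the linear density of extruders at fixed
#' processivity. When no local minimum exists beyond the loop-size maximum
#' (very low cohesin density, e.g. Scc1-depleted chromatin), the
#' `no_minimum_detected` flag is set rather than an error thrown.
#'
#' @inheritParams infer_extruded_loop_size
#' @return An `extrusion_estimate`.
#' @export
infer_density_signature <- function(slopes, s_window = c(10e3, 10e6),
                                    persistence = 3L, prominence = 0.02) {
  infer_extruded_loop_size(slopes, s_window, persistence, prominence)
}

#' @export
print.extrusion_estimate <- function(x, ...) {
  if (x$no_maximum_detected) {
    cat("<extrusion_estimate> no slope maximum detected\n")
  } else {
    cat("<extrusion_estimate> loop size ", round(x$loop_size_bp / 1e3, 1),
        " kb; ", sep = "")
    if (x$no_minimum_detected) {
      cat("no slope minimum (low cohesin density)\n")
    } else {
      cat("density signature ", round(x$density_signature, 3),
          " (minimum at ", round(x$min_slope_location_bp / 1e6, 2),
          " Mb)\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
tidy.extrusion_estimate <- function(x, ...) {
  tibble::tibble(loop_size_bp = x$loop_size_bp,
                 min_slope_location_bp = x$min_slope_location_bp,
                 density_signature = x$density_signature,
                 no_maximum_detected = x$no_maximum_detected,
                 no_minimum_detected = x$no_minimum_detected)
}

#' Contact-probability surrogate from 1-D loop configurations
#'
#' Builds a P_c(s) curve directly from loop-extrusion snapshots: the anchors
#' of each extruded loop are bridged, so the effective contour distance
#' between two loci is the shortest path along the chain when loops may be
#' crossed through their anchor bond; the contact probability of a pair is
#' `(effective distance)^exponent` (the equilibrium-chain return probability,
#' exponent -1.5). This is orders of magnitude cheaper than full 3-D dynamics
#' and preserves the slope phenomenology used by the inference: a slope
#' maximum near the mean extruded loop size and a density-dependent dip
#' beyond it.
#'
#' @param stats A `loop_size_stats` from [run_lef_dynamics()] (post-
#'   equilibration snapshots are used).
#' @param resolution,log_factor P_c(s) binning (defaults 10 kb and 1.3).
#' @param pairs_per_bin Sampled pairs per log bin per snapshot subset
#'   (default 40).
#' @param max_snapshots Random subset of snapshots used (default 20).
#' @param exponent Contact exponent of the underlying chain (default -1.5).
#' @param bond_res Resistance of the loop-closing bond in monomer units
#'   (default 0.25: the LEF holds its two anchors within a fraction of a
#'   monomer, so the bridge is much stiffer than one backbone spring).
#' @param capture_radius Hi-C capture radius in monomer diameters (default 5).
#'   The pair contact probability is the exact Gaussian capture probability
#'   P(chi2_3 <= 3 r^2 / R_eff), which saturates for pairs whose effective
#'   distance is below the capture radius instead of following the raw power
#'   law; set to 0 for the pure power-law form.
#' @param seed RNG seed for pair sampling.
#' @return A `pcs_curve` tibble (columns `s_mid`, `p`, `n_contacts`).
#' @export
pcs_from_loops <- function(stats, resolution = 10000, log_factor = 1.3,
                           pairs_per_bin = 150L, max_snapshots = 20L,
                           exponent = -1.5, bond_res = 0.25,
                           capture_radius = 5, seed = 1L) {
  stopifnot(inherits(stats, "loop_size_stats"))
  monomer_bp <- stats$params$monomer_bp
  n_monomers <- stats$params$n_monomers
  snaps <- stats$snapshots[stats$snapshots$after_equilibration, ]
  keys <- unique(snaps[c("seed", "step")])
  set.seed(seed)
  if (nrow(keys) > max_snapshots)
    keys <- keys[sort(sample.int(nrow(keys), max_snapshots)), ]
  snap_list <- purrr::pmap(keys, function(seed, step) {
    sub <- snaps[snaps$seed == seed & snaps$step == step, ]
    cbind(sub$left, sub$right)
  })
  max_s <- (n_monomers - 1) * monomer_bp
  bins <- log_bin_table(max_s, resolution, log_factor)
  bins$s_mid <- sqrt(bins$s_lo * bins$s_hi)
  s_mono <- pmax(1L, as.integer(round(bins$s_mid / monomer_bp)))
  keep <- s_mono < n_monomers & !duplicated(s_mono)
  bins <- bins[keep, ]
  s_mono <- s_mono[keep]
  res <- cpp_loop_pcs(snap_list, n_monomers, s_mono,
                      as.integer(pairs_per_bin), exponent, bond_res,
                      capture_radius)
  out <- tibble::tibble(s_lo = bins$s_lo, s_hi = bins$s_hi,
                        s_mid = s_mono * monomer_bp,
                        n_contacts = res$n,
                        n_pairs = res$n,
                        p = ifelse(res$n > 0, res$p_sum / res$n, NA_real_),
                        mean_deff = ifelse(res$n > 0, res$deff_sum / res$n,
                                           NA_real_))
  out <- out[!is.na(out$p), ]
  class(out) <- c("pcs_curve", class(out))
  out
}

#' Simulate a processivity-separation sweep of P_c(s) curves
#'
#' Runs the 1-D LEF dynamics for every (processivity, separation) combination
#' and converts each run to a P_c(s) curve with [pcs_from_loops()]. The true
#' mean extruded loop size of each cell is recorded alongside.
#'
#' @param processivity_bp,separation_bp Sweep values in bp (defaults: the
#'   5 x 6 grid 60-960 kb x 30-2,400 kb).
#' @param n_monomers Lattice size per run (default 10,000).
#' @param n_steps Extrusion steps (default 1,000).
#' @param boundaries Boundary map (default: the standard pattern tiled).
#' @param seeds Replicate seeds per cell (default 1:2).
#' @param monomer_bp Monomer size (default 600).
#' @param ... Passed to [pcs_from_loops()].
#' @return Tibble with columns `processivity_bp`, `separation_bp`,
#'   `true_loop_bp`, `curve` (list of `pcs_curve`).
#' @export
simulate_pcs_sweep <- function(processivity_bp = c(60, 120, 240, 480, 960) * 1e3,
                               separation_bp = c(30, 60, 120, 240, 480, 2400) * 1e3,
                               n_monomers = 10000L, n_steps = 1000L,
                               boundaries = build_boundary_map(n_monomers),
                               seeds = 1:2, monomer_bp = 600, ...) {
  grid <- tidyr::expand_grid(processivity_bp = processivity_bp,
                             separation_bp = separation_bp)
  grid$true_loop_bp <- NA_real_
  grid$curve <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- lef_params(n_monomers, grid$processivity_bp[r],
                    grid$separation_bp[r], monomer_bp = monomer_bp,
                    n_steps = n_steps)
    stats <- run_lef_dynamics(p, boundaries, record_every = 20L, seeds = seeds)
    grid$true_loop_bp[r] <- stats$mean_loop_bp
    grid$curve[[r]] <- pcs_from_loops(stats, ...)
  }
  grid
}

#' Match an experimental P_c(s) curve against a simulation sweep
#'
#' Normalizes both curves at the 9-kb reference and finds the sweep member
#' minimizing the mean squared log-difference over the matching window
#' (default 30 kb - 3 Mb, excluding the cohesin-independent > 10 Mb features).
#'
#' @param curve A `pcs_curve`.
#' @param sweep A sweep tibble from [simulate_pcs_sweep()] (columns
#'   `processivity_bp`, `separation_bp`, `curve`).
#' @param s_window Matching window in bp (default `c(30e3, 3e6)`).
#' @return Tibble of the 3 best matches, ascending `distance`, with the sweep
#'   columns retained.
#' @export
match_simulation_parameters <- function(curve, sweep,
                                        s_window = c(30e3, 3e6)) {
  if (nrow(sweep) == 0) stop("empty sweep library")
  target <- normalize_pcs(curve)
  sel <- target$s_mid >= s_window[1] & target$s_mid <= s_window[2] &
    target$p > 0
  ts <- target$s_mid[sel]
  tp <- log(target$p[sel])
  if (length(ts) < 3) stop("too few usable bins in the matching window")
  dist <- vapply(sweep$curve, function(cv) {
    cv <- normalize_pcs(cv)
    m <- match(round(log(ts), 6), round(log(cv$s_mid), 6))
    if (anyNA(m)) {
      # interpolate in log space onto the target grid
      ok <- cv$p > 0
      lp <- stats::approx(log(cv$s_mid[ok]), log(cv$p[ok]), xout = log(ts),
                          rule = 2)$y
    } else {
      lp <- log(cv$p[m])
    }
    mean((lp - tp)^2)
  }, numeric(1))
  out <- sweep
  out$curve <- NULL
  out$distance <- dist
  out <- out[order(out$distance), ]
  head(out, 3L)
}
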