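#' Default bidirectional TAD-boundary pattern
#'
#' The canonical within-tile positions of bidirectional TAD boundaries used by
#' the loop-extrusion model: 15 monomer indices inside a 10,000-monomer tile.
#' With 600-bp monomers this corresponds to TADs of 180 kb to 1.02 Mb
#' (mean 400 kb), a realistic mammalian TAD size distribution.
#'
#' @return Integer vector of 15 monomer indices (0-based).
#' @export
tad_boundary_pattern <- function() {
  c(0L, 1200L, 1500L, 2000L, 2900L, 3900L, 4300L, 4800L,
    5600L, 6100L, 6500L, 7600L, 8300L, 8900L, 9500L)
}

#' Build a boundary map by tiling a pattern
#'
#' Tiles a within-period pattern of boundary monomers across the lattice,
#' truncating at `n_monomers`. Boundary monomers stall LEF legs
#' bidirectionally with the pause probability set in [lef_params()].
#'
#' @param n_monomers Lattice length (number of monomers).
#' @param pattern Integer vector of 0-based boundary indices within one tile;
#'   defaults to [tad_boundary_pattern()].
#' @param period Tile period in monomers (default 10,000).
#' @return Sorted integer vector of unique 0-based boundary monomers, of class
#'   `boundary_map`.
#' @export
build_boundary_map <- function(n_monomers, pattern = tad_boundary_pattern(),
                               period = 10000L) {
  stopifnot(n_monomers >= 1)
  if (period <= 0) stop("`period` must be positive")
  if (period > n_monomers) stop("`period` must not exceed `n_monomers`")
  pattern <- as.integer(pattern)
  if (any(pattern < 0) || any(pattern >= period))
    stop("pattern indices must lie in [0, period)")
  n_tiles <- ceiling(n_monomers / period)
  b <- as.integer(outer(pattern, (seq_len(n_tiles) - 1L) * as.integer(period), `+`))
  b <- sort(unique(b[b < n_monomers]))
  structure(b, class = c("boundary_map", "integer"))
}

#' Parameters of the 1-D loop-extrusion model
#'
#' @param n_monomers Number of lattice sites.
#' @param monomer_bp Base pairs per monomer (default 600 bp, consistent with a
#'   contact capture radius of 5 monomers = 75 nm in the 3-D layer).
#' @param processivity_bp Processivity \eqn{\lambda}: mean total genomic length
#'   extruded by an unobstructed LEF before release (bp). The per-step release
#'   probability is `2 * monomer_bp / processivity_bp`, because both legs
#'   advance one monomer per step. Use `Inf` for non-releasing LEFs.
#' @param separation_bp Separation \eqn{d}: genome length divided by the number
#'   of bound LEFs (bp); the inverse linear density of cohesin.
#' @param pause_prob Per-step probability that a leg sitting on a boundary
#'   monomer fails to translocate (default 0.995, i.e. a mean boundary delay of
#'   200 extrusion steps).
#' @param n_steps Number of extrusion steps to simulate.
#' @param seed Integer RNG seed.
#' @return A list of class `lef_params` with an added `n_lefs` element,
#'   `floor(n_monomers * monomer_bp / separation_bp)`.
#' @export
lef_params <- function(n_monomers, processivity_bp, separation_bp,
                       monomer_bp = 600, pause_prob = 0.995,
                       n_steps = 4000L, seed = 1L) {
  stopifnot(n_monomers >= 1, processivity_bp > 0, monomer_bp > 0,
            n_steps >= 0)
  if (separation_bp < monomer_bp)
    stop("`separation_bp` must be at least one monomer")
  if (pause_prob < 0 || pause_prob >= 1)
    stop("`pause_prob` must lie in [0, 1)")
  n_lefs <- floor(n_monomers * monomer_bp / separation_bp)
  if (n_lefs < 1)
    stop("parameters imply zero bound LEFs; decrease `separation_bp`")
  structure(
    list(n_monomers = as.integer(n_monomers), monomer_bp = monomer_bp,
         processivity_bp = processivity_bp, separation_bp = separation_bp,
         pause_prob = pause_prob, n_steps = as.integer(n_steps),
         seed = as.integer(seed), n_lefs = as.integer(n_lefs),
         p_off = 2 * monomer_bp / processivity_bp),
    class = "lef_params")
}

#' @export
print.lef_params <- function(x, ...) {
  cat("<lef_params> ", x$n_monomers, " monomers x ", x$monomer_bp, " bp, ",
      x$n_lefs, " LEFs (separation ", x$separation_bp / 1e3, " kb), ",
      "processivity ", x$processivity_bp / 1e3, " kb, pause ",
      x$pause_prob, "\n", sep = "")
  invisible(x)
}

#' Initialise a LEF system with randomly placed LEFs
#'
#' Places `n_lefs` LEFs uniformly at random, each occupying two adjacent free
#' lattice sites (a freshly loaded LEF holds a one-monomer loop).
#'
#' @param params A [lef_params()] object.
#' @param boundaries A [build_boundary_map()] vector (may be empty).
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A list of class `lef_system` with elements `legs` (tibble with
#'   columns `lef`, `left`, `right`), `params`, `boundaries`, `step`.
#' @export
init_lef_system <- function(params, boundaries = integer(0), seed = params$seed) {
  n <- params$n_monomers
  n_lefs <- params$n_lefs
  if (2L * n_lefs > n)
    stop("cannot place ", 2L * n_lefs, " legs on ", n, " sites")
  set.seed(seed)
  occ <- logical(n)
  left <- integer(n_lefs)
  for (k in seq_len(n_lefs)) {
    placed <- FALSE
    for (attempt in seq_len(100000L)) {
      x <- sample.int(n - 1L, 1L) - 1L           # 0-based site
      if (!occ[x + 1L] && !occ[x + 2L]) {
        occ[x + 1L] <- occ[x + 2L] <- TRUE
        left[k] <- x
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("lattice too crowded to place LEF ", k)
  }
  structure(
    list(legs = tibble::tibble(lef = seq_len(n_lefs), left = left,
                               right = left + 1L),
         params = params,
         boundaries = as.integer(boundaries),
         step = 0L),
    class = "lef_system")
}

boundary_indicator <- function(n_monomers, boundaries) {
  b <- logical(n_monomers)
  if (length(boundaries)) b[as.integer(boundaries) + 1L] <- TRUE
  b
}

#' Advance a LEF system by extrusion steps
#'
#' Runs the stochastic extrusion update (release/rebind, then blocked outward
#' leg moves with boundary stalling) for `n_steps` steps. Uses R's RNG stream,
#' so results are reproducible under [set.seed()].
#'
#' @param system A `lef_system` from [init_lef_system()].
#' @param n_steps Number of steps to advance (default 1).
#' @return The updated `lef_system`.
#' @export
step_lef_system <- function(system, n_steps = 1L) {
  p <- system$params
  res <- cpp_lef_run(p$n_monomers, system$legs$left, system$legs$right,
                     min(p$p_off, 1), p$pause_prob,
                     boundary_indicator(p$n_monomers, system$boundaries),
                     as.integer(n_steps), 0L, FALSE)
  system$legs$left <- res$final_left
  system$legs$right <- res$final_right
  system$step <- system$step + as.integer(n_steps)
  system
}

#' Run LEF dynamics and collect loop-size statistics
#'
#' Simulates `params$n_steps` extrusion steps for each seed, recording leg
#' positions every `record_every` steps, and summarises extruded loop spans
#' \eqn{(right - left) \cdot monomer\_bp} over the post-equilibration window.
#' Nested loops are counted with their full spans (one span per LEF per
#' snapshot).
#'
#' @param params A [lef_params()] object.
#' @param boundaries Boundary monomers (default: none).
#' @param record_every Record a snapshot every this many steps (default 10).
#' @param equilibration_fraction Fraction of the trajectory discarded before
#'   averaging (default 0.5).
#' @param seeds Integer vector of replicate seeds (default `params$seed`).
#' @return A list of class `loop_size_stats`: `snapshots` (tibble with columns
#'   `seed`, `step`, `lef`, `left`, `right`, `span_bp`; post-equilibration
#'   snapshots flagged by `after_equilibration`), `mean_loop_bp`,
#'   `n_replicates`, `seeds`, `params`.
#' @export
run_lef_dynamics <- function(params, boundaries = integer(0),
                             record_every = 10L,
                             equilibration_fraction = 0.5,
                             seeds = params$seed) {
  stopifnot(record_every >= 0, equilibration_fraction >= 0,
            equilibration_fraction < 1)
  is_b <- boundary_indicator(params$n_monomers, boundaries)
  record_initial <- params$n_steps == 0L
  snaps <- purrr::map(seeds, function(s) {
    sys <- init_lef_system(params, boundaries, seed = s)
    res <- cpp_lef_run(params$n_monomers, sys$legs$left, sys$legs$right,
                       min(params$p_off, 1), params$pause_prob, is_b,
                       params$n_steps, as.integer(record_every),
                       record_initial)
    n_rec <- length(res$step)
    n_lef <- params$n_lefs
    tibble::tibble(
      seed = s,
      step = rep(res$step, times = n_lef),
      lef = rep(seq_len(n_lef), each = n_rec),
      left = as.vector(res$left),
      right = as.vector(res$right))
  })
  snaps <- dplyr::bind_rows(snaps)
  snaps$span_bp <- (snaps$right - snaps$left) * params$monomer_bp
  cutoff <- equilibration_fraction * params$n_steps
  snaps$after_equilibration <- snaps$step >= cutoff
  kept <- snaps$span_bp[snaps$after_equilibration]
  if (!length(kept))
    stop("post-equilibration window is empty; record more snapshots")
  structure(
    list(snapshots = snaps,
         mean_loop_bp = mean(kept),
         n_replicates = length(seeds),
         seeds = as.integer(seeds),
         params = params,
         boundaries = as.integer(boundaries)),
    class = "loop_size_stats")
}

#' @export
print.loop_size_stats <- function(x, ...) {
  cat("<loop_size_stats> mean extruded loop ",
      round(x$mean_loop_bp / 1e3, 1), " kb over ",
      sum(x$snapshots$after_equilibration), " post-equilibration spans (",
      x$n_replicates, " replicate", if (x$n_replicates > 1) "s", ")\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.loop_size_stats <- function(x, ...) {
  x$snapshots
}

#' @export
glance.loop_size_stats <- function(x, ...) {
  tibble::tibble(
    mean_loop_bp = x$mean_loop_bp,
    n_spans = sum(x$snapshots$after_equilibration),
    n_replicates = x$n_replicates,
    n_lefs = x$params$n_lefs,
    processivity_bp = x$params$processivity_bp,
    separation_bp = x$params$separation_bp)
}

#' Parameter presets of the zygote loop-extrusion models
#'
#' Processivity/separation pairs for the modelled genotypes. The paternal
#' Wapl-knockout condition ships in two variants because the best-matching
#' simulation was reported with different parameter descriptions in different
#' places: `wapl_paternal` (processivity 480 kb, separation 60 kb) and
#' `wapl_paternal_alt` (processivity 240 kb, separation 240 kb).
#'
#' @param condition One of `"control"`, `"scc1"`, `"wapl_maternal"`,
#'   `"wapl_paternal"`, `"wapl_paternal_alt"`.
#' @return Named list with `processivity_bp` and `separation_bp`.
#' @export
lef_preset <- function(condition = c("control", "scc1", "wapl_maternal",
                                     "wapl_paternal", "wapl_paternal_alt")) {
  condition <- match.arg(condition)
  switch(condition,
    control           = list(processivity_bp = 120e3, separation_bp = 120e3),
    scc1              = list(processivity_bp = 120e3, separation_bp = 2400e3),
    wapl_maternal     = list(processivity_bp = 480e3, separation_bp = 120e3),
    wapl_paternal     = list(processivity_bp = 480e3, separation_bp = 60e3),
    wapl_paternal_alt = list(processivity_bp = 240e3, separation_bp = 240e3))
}

#' Measure boundary stall durations
#'
#' Runs a single non-releasing LEF on a long lattice with regularly spaced
#' boundaries, recording every step, and returns the durations (in steps) that
#' each leg spent parked on a boundary site before passing it. With pause
#' probability `p` the durations are geometric with mean `1 / (1 - p)`.
#'
#' @param pause_prob Boundary pause probability (default 0.995).
#' @param n_events Approximate number of passage events wanted.
#' @param boundary_spacing Spacing of boundary monomers (default 100).
#' @param seed RNG seed.
#' @return Integer vector of stall durations (steps spent on a boundary site,
#'   counting the arrival step's subsequent failed attempts plus the passing
#'   attempt).
#' @export
measure_boundary_delay <- function(pause_prob = 0.995, n_events = 10000,
                                   boundary_spacing = 100L, seed = 1L) {
  mean_cost <- 1 / (1 - pause_prob) + boundary_spacing
  n_steps <- ceiling(n_events / 2 * mean_cost * 1.25)
  n_monomers <- as.integer((n_events / 2 + 10) * boundary_spacing * 2 + 1000)
  boundaries <- seq(0L, n_monomers - 1L, by = as.integer(boundary_spacing))
  set.seed(seed)
  centre <- n_monomers %/% 2L
  centre <- centre - (centre %% boundary_spacing) + boundary_spacing %/% 2L
  res <- cpp_lef_run(n_monomers, centre, centre + 1L, 0, pause_prob,
                     boundary_indicator(n_monomers, boundaries),
                     as.integer(n_steps), 1L, FALSE)
  durations <- function(pos) {
    r <- rle(as.vector(pos))
    on_boundary <- (r$values %% boundary_spacing) == 0L
    # drop the final (possibly censored) run
    keep <- on_boundary & seq_along(r$values) < length(r$values)
    r$lengths[keep]
  }
  c(durations(res$left), durations(res$right))
}
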