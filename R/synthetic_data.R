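#' Default synthetic genome
#'
#' @param n_chroms Number of chromosomes (default 3).
#' @param size Chromosome size in bp (default 50 Mb).
#' @return Tibble `chrom`, `size`.
#' @export
synthetic_genome <- function(n_chroms = 3L, size = 50e6) {
  tibble::tibble(chrom = paste0("chr", seq_len(n_chroms)), size = size)
}

# --- piecewise power-law separation model -----------------------------------

# pieces: tibble(s_lo, s_hi, exponent); amplitudes are chained so the density
# is continuous across breakpoints.
piecewise_model <- function(pieces) {
  stopifnot(nrow(pieces) >= 1, all(pieces$s_hi > pieces$s_lo))
  k <- nrow(pieces)
  amp <- numeric(k)
  amp[1] <- 1
  if (k > 1) {
    for (i in 2:k) {
      s <- pieces$s_lo[i]
      amp[i] <- amp[i - 1] * s^(pieces$exponent[i - 1] - pieces$exponent[i])
    }
  }
  mass <- vapply(seq_len(k), function(i) {
    e <- pieces$exponent[i]
    if (abs(e + 1) < 1e-12) {
      amp[i] * log(pieces$s_hi[i] / pieces$s_lo[i])
    } else {
      amp[i] * (pieces$s_hi[i]^(e + 1) - pieces$s_lo[i]^(e + 1)) / (e + 1)
    }
  }, numeric(1))
  list(pieces = pieces, amp = amp, mass = mass, total = sum(mass))
}

piecewise_density <- function(model, s) {
  i <- findInterval(s, c(model$pieces$s_lo, tail(model$pieces$s_hi, 1)),
                    rightmost.closed = TRUE)
  i <- pmax(pmin(i, nrow(model$pieces)), 1L)
  model$amp[i] * s^model$pieces$exponent[i] / model$total
}

piecewise_sample <- function(model, n) {
  if (n == 0) return(numeric(0))
  piece <- sample.int(nrow(model$pieces), n, replace = TRUE,
                      prob = model$mass)
  u <- runif(n)
  lo <- model$pieces$s_lo[piece]
  hi <- model$pieces$s_hi[piece]
  e <- model$pieces$exponent[piece]
  out <- numeric(n)
  lg <- abs(e + 1) < 1e-12
  if (any(lg)) out[lg] <- lo[lg] * (hi[lg] / lo[lg])^u[lg]
  if (any(!lg)) {
    p1 <- e[!lg] + 1
    out[!lg] <- (lo[!lg]^p1 + u[!lg] * (hi[!lg]^p1 - lo[!lg]^p1))^(1 / p1)
  }
  out
}

# numeric integral of f(s) * g(s) over [lo, hi] on a log grid
piecewise_integral <- function(model, lo, hi, g = function(s) 1,
                               n_grid = 2000L) {
  if (hi <= lo) return(0)
  s <- exp(seq(log(lo), log(hi), length.out = n_grid))
  f <- piecewise_density(model, s) * g(s)
  sum((f[-1] + f[-n_grid]) / 2 * diff(s))
}

# --- synthetic annotations ---------------------------------------------------

#' Synthetic loop anchors
#'
#' Deterministic anchor pairs with separations in `sep_range`, spaced at least
#' `spacing` apart along each chromosome so that shifted-control windows of
#' one loop never overlap another loop.
#'
#' @param genome Genome tibble.
#' @param n_per_chrom Anchors per chromosome (default 16).
#' @param sep_range Anchor separation range in bp (default 150-500 kb).
#' @param spacing Distance between successive anchor starts (default 2.5 Mb).
#' @param seed RNG seed.
#' @return Tibble `chrom`, `pos1`, `pos2`.
#' @export
synthetic_loop_anchors <- function(genome, n_per_chrom = 16L,
                                   sep_range = c(150e3, 500e3),
                                   spacing = 2.5e6, seed = 42L) {
  set.seed(seed)
  purrr::pmap(genome, function(chrom, size) {
    starts <- seq(2e6, size - 2e6 - sep_range[2], by = spacing)
    starts <- head(starts, n_per_chrom)
    sep <- runif(length(starts), sep_range[1], sep_range[2])
    tibble::tibble(chrom = chrom, pos1 = starts, pos2 = starts + sep)
  }) %>% dplyr::bind_rows()
}

#' Synthetic TAD intervals
#'
#' Contiguous TADs tiling part of each chromosome.
#'
#' @param genome Genome tibble.
#' @param n_per_chrom TADs per chromosome (default 20).
#' @param size_range TAD length range in bp (default 300-800 kb).
#' @param seed RNG seed.
#' @return Tibble `chrom`, `start`, `end` (consecutive TADs share boundaries).
#' @export
synthetic_tad_intervals <- function(genome, n_per_chrom = 20L,
                                    size_range = c(300e3, 800e3), seed = 43L) {
  set.seed(seed)
  purrr::pmap(genome, function(chrom, size) {
    lens <- runif(n_per_chrom, size_range[1], size_range[2])
    edges <- 2e6 + c(0, cumsum(lens))
    stopifnot(max(edges) < size - 2e6)
    tibble::tibble(chrom = chrom, start = head(edges, -1), end = edges[-1])
  }) %>% dplyr::bind_rows()
}

#' Synthetic GC-content track
#'
#' Blocky alternating A/B compartment structure encoded as a GC proxy: B
#' blocks around 38% GC, A blocks around 48%, with small within-block noise,
#' one value per bin.
#'
#' @param genome Genome tibble.
#' @param resolution Bin size (default 10 kb).
#' @param block Compartment block size in bp (default 2 Mb).
#' @param seed RNG seed.
#' @return Tibble `chrom`, `start`, `end`, `gc`.
#' @export
synthetic_gc_track <- function(genome, resolution = 10000, block = 2e6,
                               seed = 44L) {
  set.seed(seed)
  purrr::pmap(genome, function(chrom, size) {
    nb <- ceiling(size / resolution)
    start <- (seq_len(nb) - 1L) * resolution
    blk <- start %/% block
    is_a <- blk %% 2L == 1L
    gc <- ifelse(is_a, 0.48, 0.38) + rnorm(nb, 0, 0.005)
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + resolution, size), gc = gc)
  }) %>% dplyr::bind_rows()
}

# --- spec --------------------------------------------------------------------

#' Specification of a synthetic single-nucleus contact list
#'
#' Contacts are drawn i.i.d.: with probability `trans_fraction` a uniform
#' inter-chromosomal pair; otherwise an intra-chromosomal pair whose
#' separation follows a continuous piecewise power law (`pieces`), with
#' optional redirection onto planted features: loop-anchor pixels (so that the
#' expected aggregate loop strength equals `loop_enrichment`), TAD interiors
#' (average interior enrichment `tad_enrichment`), same-compartment bins
#' (probability `compartment_weight` of enforcing compartment matching) and a
#' long-range plateau (`plateau_weight` of intra contacts drawn log-uniformly
#' from `plateau_range`, the maternal 10-30 Mb signature).
#'
#' @param genome Genome tibble (default [synthetic_genome()]).
#' @param n_contacts Contacts per nucleus (default 30,000).
#' @param pieces Background separation pieces: tibble `s_lo`, `s_hi`,
#'   `exponent` (default a single s^-1.5 piece from 10 kb to the chromosome
#'   size).
#' @param loop_anchors Anchor tibble or `NULL`.
#' @param loop_enrichment Target fractional loop strength (default 0 = none).
#' @param tad_intervals TAD tibble or `NULL`.
#' @param tad_enrichment Average interior enrichment factor (default 1 = none).
#' @param gc_track GC tibble (required when `compartment_weight > 0`).
#' @param compartment_weight Probability of enforcing same-compartment
#'   placement of a background contact (default 0).
#' @param plateau_weight Fraction of intra contacts in the plateau (default 0).
#' @param plateau_range Plateau separation range (default 10-30 Mb).
#' @param trans_fraction Target trans-contact fraction (default 0.08).
#' @param resolution Pixel size used for feature planting (default 10 kb).
#' @param phase Cell-cycle phase label, `"G1"` or `"G2"`.
#' @param parent `"maternal"` or `"paternal"` ground-truth label.
#' @param seed RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome = synthetic_genome(),
                           n_contacts = 30000L,
                           pieces = NULL,
                           loop_anchors = NULL, loop_enrichment = 0,
                           tad_intervals = NULL, tad_enrichment = 1,
                           gc_track = NULL, compartment_weight = 0,
                           plateau_weight = 0,
                           plateau_range = c(10e6, 30e6),
                           trans_fraction = 0.08,
                           resolution = 10000,
                           phase = "G1", parent = "paternal", seed = 1L) {
  if (is.null(pieces))
    pieces <- tibble::tibble(s_lo = 10e3, s_hi = min(genome$size),
                             exponent = -1.5)
  stopifnot(trans_fraction >= 0, trans_fraction <= 0.5,
            loop_enrichment >= 0, tad_enrichment >= 1,
            compartment_weight >= 0, compartment_weight <= 1,
            plateau_weight >= 0, plateau_weight < 1)
  if (compartment_weight > 0 && is.null(gc_track))
    stop("`gc_track` is required when planting compartments")
  if (loop_enrichment > 0 && is.null(loop_anchors))
    stop("`loop_anchors` is required when planting loops")
  if (tad_enrichment > 1 && is.null(tad_intervals))
    stop("`tad_intervals` is required when planting TADs")
  structure(
    list(genome = genome, n_contacts = as.integer(n_contacts),
         pieces = pieces, loop_anchors = loop_anchors,
         loop_enrichment = loop_enrichment, tad_intervals = tad_intervals,
         tad_enrichment = tad_enrichment, gc_track = gc_track,
         compartment_weight = compartment_weight,
         plateau_weight = plateau_weight, plateau_range = plateau_range,
         trans_fraction = trans_fraction, resolution = resolution,
         phase = phase, parent = parent, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# mixture weights for feature planting (see the methods vignette):
# alpha scales loop mass, beta TAD mass, relative to background intra mass
spec_mixture <- function(spec) {
  model <- piecewise_model(spec$pieces)
  res <- spec$resolution
  p_chrom <- spec$genome$size / sum(spec$genome$size)
  names(p_chrom) <- spec$genome$chrom
  alpha <- 0
  pix <- NULL
  if (spec$loop_enrichment > 0) {
    an <- anchor_midpoints(spec$loop_anchors)
    sep <- an$pos2 - an$pos1
    L <- setNames(spec$genome$size, spec$genome$chrom)[an$chrom]
    pi_a <- piecewise_density(model, sep) * res^2 / (L - sep) * p_chrom[an$chrom]
    alpha <- 36 * spec$loop_enrichment * sum(pi_a)
    pix <- pi_a
  }
  beta <- 0
  m_t <- NULL
  if (spec$tad_enrichment > 1) {
    td <- spec$tad_intervals
    L <- setNames(spec$genome$size, spec$genome$chrom)[td$chrom]
    len <- td$end - td$start
    m_t <- vapply(seq_len(nrow(td)), function(i) {
      p_chrom[td$chrom[i]] *
        piecewise_integral(model, res, len[i],
                           function(s) (len[i] - s) / (L[i] - s))
    }, numeric(1))
    beta <- (spec$tad_enrichment - 1) * sum(m_t)
  }
  w_pl <- spec$plateau_weight
  bg_frac <- (1 - w_pl) / (1 + alpha + beta)
  list(model = model, p_chrom = p_chrom,
       q_loop = alpha * bg_frac, q_tad = beta * bg_frac,
       w_plateau = w_pl, bg_frac = bg_frac,
       pi_a = pix, m_t = m_t)
}

compartment_label <- function(gc_track, chrom, pos, resolution) {
  key <- paste0(gc_track$chrom, ":", gc_track$start %/% resolution)
  med <- median(gc_track$gc)
  lab <- setNames(gc_track$gc >= med, key)
  lab[paste0(chrom, ":", pos %/% resolution)]
}

#' Generate one synthetic nucleus
#'
#' Draws `spec$n_contacts` contacts from the mixture defined by the spec and
#' returns the contact list together with the analytic ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `contacts` (canonical tibble `chrom1`, `pos1`, `chrom2`,
#'   `pos2`) and `truth` (list echoing the planted parameters, with
#'   `expected_loop_strength` and the `parent` label).
#' @export
generate_cell <- function(spec) {
  set.seed(spec$seed)
  g <- spec$genome
  sizes <- setNames(g$size, g$chrom)
  n <- spec$n_contacts
  mix <- spec_mixture(spec)
  if (mix$q_loop + mix$q_tad + mix$w_plateau >= 1)
    stop("infeasible enrichment: planted mass exceeds the contact budget")

  if (n == 0) {
    contacts <- tibble::tibble(chrom1 = character(), pos1 = numeric(),
                               chrom2 = character(), pos2 = numeric())
    return(list(contacts = contacts, truth = synthetic_truth(spec)))
  }

  is_trans <- runif(n) < spec$trans_fraction
  n_tr <- sum(is_trans)
  n_in <- n - n_tr

  # trans contacts: uniform pairs on distinct chromosomes
  trans <- NULL
  if (n_tr > 0) {
    if (nrow(g) < 2) stop("trans contacts need at least two chromosomes")
    c1 <- sample(g$chrom, n_tr, replace = TRUE)
    c2 <- sample(g$chrom, n_tr, replace = TRUE)
    while (any(bad <- c1 == c2))
      c2[bad] <- sample(g$chrom, sum(bad), replace = TRUE)
    trans <- tibble::tibble(chrom1 = c1, pos1 = floor(runif(n_tr) * sizes[c1]),
                            chrom2 = c2, pos2 = floor(runif(n_tr) * sizes[c2]))
  }

  comp <- sample(c("loop", "tad", "plateau", "bg"), n_in, replace = TRUE,
                 prob = c(mix$q_loop, mix$q_tad, mix$w_plateau,
                          1 - mix$q_loop - mix$q_tad - mix$w_plateau))
  res <- spec$resolution
  out <- vector("list", 4L)

  n_bg <- sum(comp == "bg")
  if (n_bg > 0) {
    ch <- sample(g$chrom, n_bg, replace = TRUE, prob = mix$p_chrom)
    s <- piecewise_sample(mix$model, n_bg)
    s <- pmin(s, sizes[ch] - res)
    pos1 <- runif(n_bg) * (sizes[ch] - s)
    # enforce same-compartment placement for a fraction of the background
    if (spec$compartment_weight > 0) {
      enforce <- runif(n_bg) < spec$compartment_weight
      if (any(enforce)) {
        idx <- which(enforce)
        for (try in 1:30) {
          l1 <- compartment_label(spec$gc_track, ch[idx], pos1[idx], res)
          l2 <- compartment_label(spec$gc_track, ch[idx], pos1[idx] + s[idx],
                                  res)
          bad <- which(is.na(l1) | is.na(l2) | l1 != l2)
          if (!length(bad)) break
          pos1[idx[bad]] <- runif(length(bad)) * (sizes[ch[idx[bad]]] - s[idx[bad]])
          idx <- idx[bad]
        }
      }
    }
    out[[1]] <- tibble::tibble(chrom1 = ch, pos1 = floor(pos1),
                               chrom2 = ch, pos2 = floor(pos1 + s))
  }

  n_lp <- sum(comp == "loop")
  if (n_lp > 0) {
    an <- anchor_midpoints(spec$loop_anchors)
    a <- sample.int(nrow(an), n_lp, replace = TRUE, prob = mix$pi_a)
    b1 <- an$pos1[a] %/% res + sample(-1:1, n_lp, replace = TRUE)
    b2 <- an$pos2[a] %/% res + sample(-1:1, n_lp, replace = TRUE)
    out[[2]] <- tibble::tibble(
      chrom1 = an$chrom[a],
      pos1 = floor(b1 * res + runif(n_lp) * res),
      chrom2 = an$chrom[a],
      pos2 = floor(b2 * res + runif(n_lp) * res))
  }

  n_td <- sum(comp == "tad")
  if (n_td > 0) {
    td <- spec$tad_intervals
    t_idx <- sample.int(nrow(td), n_td, replace = TRUE, prob = mix$m_t)
    len <- td$end[t_idx] - td$start[t_idx]
    # separation from the background law truncated to the TAD length,
    # weighted by the within-TAD placement freedom (len - s)
    s <- numeric(n_td)
    need <- seq_len(n_td)
    while (length(need)) {
      cand <- piecewise_sample(mix$model, length(need))
      acc <- cand <= len[need] &
        runif(length(need)) < (len[need] - cand) / len[need]
      s[need[acc]] <- cand[acc]
      need <- need[!acc]
    }
    pos1 <- td$start[t_idx] + runif(n_td) * (len - s)
    out[[3]] <- tibble::tibble(chrom1 = td$chrom[t_idx], pos1 = floor(pos1),
                               chrom2 = td$chrom[t_idx],
                               pos2 = floor(pos1 + s))
  }

  n_pl <- sum(comp == "plateau")
  if (n_pl > 0) {
    lo <- spec$plateau_range[1]
    hi <- spec$plateau_range[2]
    s <- lo * (hi / lo)^runif(n_pl)
    ok_chrom <- g$chrom[g$size > hi + res]
    if (!length(ok_chrom)) stop("no chromosome long enough for the plateau")
    ch <- sample(ok_chrom, n_pl, replace = TRUE)
    pos1 <- runif(n_pl) * (sizes[ch] - s)
    out[[4]] <- tibble::tibble(chrom1 = ch, pos1 = floor(pos1),
                               chrom2 = ch, pos2 = floor(pos1 + s))
  }

  contacts <- dplyr::bind_rows(c(out, list(trans)))
  contacts <- canonicalize_contacts(contacts)[sample.int(n), ]
  list(contacts = contacts, truth = synthetic_truth(spec))
}

synthetic_truth <- function(spec) {
  list(parent = spec$parent, phase = spec$phase,
       expected_loop_strength = spec$loop_enrichment,
       tad_enrichment = spec$tad_enrichment,
       compartment_weight = spec$compartment_weight,
       plateau_weight = spec$plateau_weight,
       trans_fraction = spec$trans_fraction,
       seed = spec$seed)
}

#' Genotype presets for synthetic panels
#'
#' Returns a [synthetic_spec()] emulating the snHi-C phenotype of a genotype:
#' `control` (loops, TADs, moderate compartments, shallow P_c(s) shoulder
#' around 40-120 kb), `scc1` (cohesin-less: no loops or TADs, a clean s^-1.5
#' background, stronger compartments, more trans contacts) and `wapl`
#' (cohesin release blocked: stronger and larger loops, weaker compartments,
#' fewer trans contacts, shoulder shifted to 80-250 kb). Maternal presets add
#' the 10-30 Mb plateau; G2 presets use a steeper long-range decay.
#'
#' @param genotype `"control"`, `"scc1"` or `"wapl"`.
#' @param parent `"maternal"` or `"paternal"`.
#' @param phase `"G1"` or `"G2"` (default G1 for control/scc1, G2 for wapl,
#'   matching the experimental design).
#' @param genome,n_contacts,seed Passed to [synthetic_spec()].
#' @param loop_anchors,tad_intervals,gc_track Annotations (defaults generated
#'   deterministically from the genome).
#' @return A `synthetic_spec`.
#' @export
genotype_preset <- function(genotype = c("control", "scc1", "wapl"),
                            parent = c("paternal", "maternal"),
                            phase = NULL,
                            genome = synthetic_genome(),
                            n_contacts = 30000L,
                            loop_anchors = synthetic_loop_anchors(genome),
                            tad_intervals = synthetic_tad_intervals(genome),
                            gc_track = synthetic_gc_track(genome),
                            seed = 1L) {
  genotype <- match.arg(genotype)
  parent <- match.arg(parent)
  if (is.null(phase)) phase <- if (genotype == "wapl") "G2" else "G1"
  maxs <- min(genome$size)
  # long-range decay: G2-phase chromatin falls off more steeply than G1;
  # paternal curves must sit clearly below the maternal plateau thresholds
  tail_exp <- if (phase == "G2") -3.3 else -2.6
  pieces <- switch(genotype,
    control = tibble::tibble(
      s_lo = c(10e3, 40e3, 120e3, 1e6, 3e6),
      s_hi = c(40e3, 120e3, 1e6, 3e6, maxs),
      exponent = c(-1.0, -0.5, -1.3, -2.0, tail_exp)),
    scc1 = tibble::tibble(
      s_lo = c(10e3, 10e6), s_hi = c(10e6, maxs),
      exponent = c(-1.5, -2.5)),
    wapl = tibble::tibble(
      s_lo = c(10e3, 80e3, 250e3, 2e6),
      s_hi = c(80e3, 250e3, 2e6, maxs),
      exponent = c(-1.0, -0.45, -1.55, tail_exp)))
  cfg <- switch(genotype,
    control = list(loop = 1.0, tad = 2.0, comp = 0.15, trans = 0.08),
    scc1    = list(loop = 0.0, tad = 1.0, comp = 0.30, trans = 0.12),
    wapl    = list(loop = 1.5, tad = 1.6, comp = 0.08, trans = 0.06))
  synthetic_spec(
    genome = genome, n_contacts = n_contacts, pieces = pieces,
    loop_anchors = if (cfg$loop > 0) loop_anchors else NULL,
    loop_enrichment = cfg$loop,
    tad_intervals = if (cfg$tad > 1) tad_intervals else NULL,
    tad_enrichment = cfg$tad,
    gc_track = gc_track, compartment_weight = cfg$comp,
    plateau_weight = if (parent == "maternal") 0.12 else 0,
    trans_fraction = cfg$trans,
    phase = phase, parent = parent, seed = seed)
}

#' Generate a panel of synthetic nuclei
#'
#' @param n_nuclei Number of nuclei.
#' @param genotype,parent,phase Preset selectors (see [genotype_preset()]).
#' @param n_contacts Contacts per nucleus.
#' @param genome Genome tibble.
#' @param seed Master seed; per-nucleus seeds are derived from it.
#' @param ... Further arguments to [genotype_preset()].
#' @return List with `contacts` (tibble with a `nucleus` column), `truth`
#'   (list per nucleus), `genome`.
#' @export
generate_panel <- function(n_nuclei, genotype = "control",
                           parent = "paternal", phase = NULL,
                           n_contacts = 30000L,
                           genome = synthetic_genome(), seed = 1L, ...) {
  stopifnot(n_nuclei >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_nuclei)
  cells <- purrr::map(seq_len(n_nuclei), function(i) {
    spec <- genotype_preset(genotype, parent, phase, genome = genome,
                            n_contacts = n_contacts, seed = seeds[i], ...)
    cell <- generate_cell(spec)
    cell$contacts$nucleus <- i
    cell
  })
  list(contacts = dplyr::bind_rows(purrr::map(cells, "contacts")),
       truth = purrr::map(cells, "truth"),
       genome = genome)
}

#' Downsample simulated contacts to single-nucleus sparsity
#'
#' Uniform subsample without replacement, bridging dense simulated contact
#' lists to the sparsity of a single nucleus.
#'
#' @param contacts Contact tibble (e.g. from [simulated_contacts()]).
#' @param downsample_to Target number of contacts.
#' @param seed RNG seed.
#' @return The subsampled tibble.
#' @export
contacts_from_simulation <- function(contacts, downsample_to, seed = 1L) {
  if (downsample_to > nrow(contacts))
    stop("downsample_to exceeds the available ", nrow(contacts), " contacts")
  if (downsample_to == nrow(contacts)) return(contacts)
  set.seed(seed)
  contacts[sort(sample.int(nrow(contacts), downsample_to)), ]
}
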