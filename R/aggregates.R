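#' @importFrom data.table data.table := .N setkey
NULL

# Normalise loop-anchor input: accepts BEDPE-like tibbles
# (chrom1,start1,end1,chrom2,start2,end2) or midpoint form (chrom,pos1,pos2).
anchor_midpoints <- function(anchors) {
  if (all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2") %in%
          names(anchors))) {
    if (!all(anchors$chrom1 == anchors$chrom2))
      stop("loop anchors must be intra-chromosomal")
    out <- tibble::tibble(chrom = anchors$chrom1,
                          pos1 = (anchors$start1 + anchors$end1) / 2,
                          pos2 = (anchors$start2 + anchors$end2) / 2)
  } else if (all(c("chrom", "pos1", "pos2") %in% names(anchors))) {
    out <- tibble::tibble(chrom = anchors$chrom, pos1 = anchors$pos1,
                          pos2 = anchors$pos2)
  } else {
    stop("anchors must be BEDPE-like or have columns chrom, pos1, pos2")
  }
  swap <- out$pos1 > out$pos2
  if (any(swap)) {
    tmp <- out$pos1[swap]
    out$pos1[swap] <- out$pos2[swap]
    out$pos2[swap] <- tmp
  }
  out
}

#' Collect per-loop observed and control windows
#'
#' For every loop anchor, extracts the `window` x `window` matrix of binned
#' contacts centred on the loop pixel (observed), and the average of the same
#' window displaced along the diagonal over a deterministic grid of
#' `n_shifts` shifts spanning `shift_range` (control). Windows are collected
#' per nucleus when the contact tibble has a `nucleus` column, so the result
#' supports pooling, bootstrap over loops, and permutation over nuclei.
#'
#' Anchors whose window crosses the diagonal or falls outside the chromosome
#' are skipped with a warning.
#'
#' @param contacts Contact tibble (optionally with `nucleus`).
#' @param anchors Loop anchors (BEDPE-like or `chrom`, `pos1`, `pos2`).
#' @param genome Genome tibble.
#' @param resolution Bin size (default 10 kb).
#' @param window Window size in bins (default 20).
#' @param shift_range Control shift range in bp (default 100 kb - 1.1 Mb).
#' @param n_shifts Number of control shifts (default 100, on an even grid).
#' @param size_class Optional anchor-separation filter: `"small"`
#'   (100-150 kb), `"intermediate"` (150-250 kb), `"large"` (250-500 kb), or a
#'   numeric `c(min_bp, max_bp)`.
#' @return List of class `loop_windows`: `obs` and `ctrl` (matrices with one
#'   row per nucleus x loop and `window^2` columns, ctrl averaged over its
#'   valid shifts), `meta` (tibble `nucleus`, `loop_id`), `loops` (anchor
#'   table with bin coordinates), `window`, `resolution`.
#' @export
collect_loop_windows <- function(contacts, anchors, genome,
                                 resolution = 10000, window = 20L,
                                 shift_range = c(100e3, 1100e3),
                                 n_shifts = 100L, size_class = NULL) {
  validate_contacts(contacts, genome)
  an <- anchor_midpoints(anchors)
  if (!is.null(size_class)) {
    rng <- if (is.numeric(size_class)) size_class else
      switch(match.arg(size_class, c("small", "intermediate", "large")),
             small = c(100e3, 150e3), intermediate = c(150e3, 250e3),
             large = c(250e3, 500e3))
    keep <- (an$pos2 - an$pos1) >= rng[1] & (an$pos2 - an$pos1) < rng[2]
    an <- an[keep, ]
    if (nrow(an) == 0) stop("no anchors in the requested size class")
  }
  w <- as.integer(window)
  half_lo <- w %/% 2L - 1L          # bins below the loop pixel (9 for w=20)
  half_hi <- w - half_lo - 1L       # bins above (10 for w=20)
  n_bins <- setNames(as.integer(ceiling(genome$size / resolution)),
                     genome$chrom)
  an$a1 <- as.integer(an$pos1 %/% resolution)
  an$a2 <- as.integer(an$pos2 %/% resolution)
  an$loop_id <- seq_len(nrow(an))
  # geometry guards
  too_close <- (an$a2 - an$a1) <= w
  out_of_chrom <- an$a1 - half_lo < 0L |
    an$a2 + half_hi > n_bins[an$chrom] - 1L
  drop <- too_close | out_of_chrom
  if (any(drop)) {
    warning(sum(drop), " anchor(s) skipped (window crosses the diagonal or ",
            "chromosome end)")
    an <- an[!drop, ]
  }
  if (nrow(an) == 0) stop("no usable loop anchors")

  shifts_bin <- as.integer(round(seq(shift_range[1], shift_range[2],
                                     length.out = n_shifts) / resolution))
  shift_min <- min(shifts_bin)
  shift_max <- max(shifts_bin)
  shift_mult <- table(shifts_bin)
  shift_levels <- as.integer(names(shift_mult))
  mult_of <- function(d) as.integer(shift_mult[match(d, shift_levels)])

  intra <- contacts[contacts$chrom1 == contacts$chrom2, ]
  if (!("nucleus" %in% names(intra))) intra$nucleus <- 1L
  ct <- data.table(nucleus = intra$nucleus, chrom = intra$chrom1,
                   b1 = as.integer(pmin(intra$pos1, intra$pos2) %/% resolution),
                   b2 = as.integer(pmax(intra$pos1, intra$pos2) %/% resolution))
  nuclei <- sort(unique(ct$nucleus))
  andt <- data.table(chrom = an$chrom, loop_id = an$loop_id,
                     a1 = an$a1, a2 = an$a2)

  # observed windows
  andt[, `:=`(lo1 = a1 - half_lo, hi1 = a1 + half_hi,
              lo2 = a2 - half_lo, hi2 = a2 + half_hi)]
  obs_hits <- ct[andt,
                 .(nucleus = x.nucleus, loop_id = i.loop_id,
                   u = x.b1 - i.a1 + half_lo + 1L,
                   v = x.b2 - i.a2 + half_lo + 1L),
                 on = .(chrom, b1 >= lo1, b1 <= hi1, b2 >= lo2, b2 <= hi2),
                 nomatch = NULL, allow.cartesian = TRUE]

  # control windows: all shifted positions at once
  andt[, `:=`(lo1 = a1 + shift_min - half_lo, hi1 = a1 + shift_max + half_hi,
              lo2 = a2 + shift_min - half_lo, hi2 = a2 + shift_max + half_hi)]
  ctrl_raw <- ct[andt,
                 .(nucleus = x.nucleus, loop_id = i.loop_id,
                   d1 = x.b1 - i.a1, d2 = x.b2 - i.a2),
                 on = .(chrom, b1 >= lo1, b1 <= hi1, b2 >= lo2, b2 <= hi2),
                 nomatch = NULL, allow.cartesian = TRUE]
  # valid shifts per loop (shifted window must stay inside the chromosome)
  an$max_shift <- n_bins[an$chrom] - 1L - half_hi - an$a2
  an$n_valid_shifts <- vapply(an$max_shift, function(m)
    sum(shift_mult[shift_levels <= m]), numeric(1))
  if (any(an$n_valid_shifts == 0))
    warning("some loops have no valid control shifts")

  # expand each control hit over the admissible shift values
  ctrl_hits <- NULL
  if (nrow(ctrl_raw) > 0) {
    d_lo <- pmax(ctrl_raw$d1, ctrl_raw$d2) - half_hi
    d_hi <- pmin(ctrl_raw$d1, ctrl_raw$d2) + half_lo
    max_shift_of <- an$max_shift[match(ctrl_raw$loop_id, an$loop_id)]
    d_lo <- pmax(d_lo, shift_min)
    d_hi <- pmin(d_hi, shift_max, max_shift_of)
    keep <- d_hi >= d_lo
    if (any(keep)) {
      reps <- (d_hi - d_lo + 1L)[keep]
      idx <- rep(which(keep), reps)
      delta <- unlist(lapply(which(keep), function(r) d_lo[r]:d_hi[r]),
                      use.names = FALSE)
      wgt <- mult_of(delta)
      ok <- !is.na(wgt) & wgt > 0
      ctrl_hits <- data.table(
        nucleus = ctrl_raw$nucleus[idx][ok],
        loop_id = ctrl_raw$loop_id[idx][ok],
        u = (ctrl_raw$d1[idx] - delta + half_lo + 1L)[ok],
        v = (ctrl_raw$d2[idx] - delta + half_lo + 1L)[ok],
        wgt = wgt[ok])
    }
  }

  n_loops <- nrow(an)
  row_key <- function(nuc, lid)
    (match(nuc, nuclei) - 1L) * n_loops + match(lid, an$loop_id)
  n_rows <- length(nuclei) * n_loops
  obs <- matrix(0, n_rows, w * w)
  ctrl <- matrix(0, n_rows, w * w)
  if (nrow(obs_hits) > 0) {
    rk <- row_key(obs_hits$nucleus, obs_hits$loop_id)
    cell <- (obs_hits$v - 1L) * w + obs_hits$u
    lin <- (cell - 1L) * n_rows + rk
    obs <- matrix(as.numeric(tabulate(lin, nbins = n_rows * w * w)),
                  n_rows, w * w)
  }
  if (!is.null(ctrl_hits) && nrow(ctrl_hits) > 0) {
    rk <- row_key(ctrl_hits$nucleus, ctrl_hits$loop_id)
    cell <- (ctrl_hits$v - 1L) * w + ctrl_hits$u
    lin <- (cell - 1L) * n_rows + rk
    agg <- rowsum(ctrl_hits$wgt, lin)
    vec <- numeric(n_rows * w * w)
    vec[as.integer(rownames(agg))] <- agg[, 1L]
    ctrl <- matrix(vec, n_rows, w * w)
    # per-shift average, so ctrl rows are on the same scale as obs rows
    ctrl <- ctrl / pmax(an$n_valid_shifts[((seq_len(n_rows) - 1L) %% n_loops) + 1L], 1)
  }
  meta <- tibble::tibble(
    nucleus = rep(nuclei, each = n_loops),
    loop_id = rep(an$loop_id, times = length(nuclei)))
  structure(list(obs = obs, ctrl = ctrl, meta = meta,
                 loops = tibble::as_tibble(an), window = w,
                 resolution = resolution),
            class = "loop_windows")
}

sum_windows_by <- function(windows, group) {
  # sums obs/ctrl rows within groups; returns list of matrices
  g <- as.factor(group)
  obs <- rowsum(windows$obs, g)
  ctrl <- rowsum(windows$ctrl, g)
  list(obs = obs, ctrl = ctrl, levels = levels(g))
}

corner_cells <- function(window = 20L, box = (window * 3L) %/% 10L) {
  b <- max(1L, as.integer(box))
  tl <- as.matrix(expand.grid(seq_len(b), seq_len(b)))
  br <- as.matrix(expand.grid(window - b + seq_len(b), window - b + seq_len(b)))
  rbind(tl, br)
}

centre_cells <- function(window = 20L, box = (window * 3L) %/% 10L) {
  b <- max(1L, as.integer(box))
  off <- (window - b) %/% 2L
  as.matrix(expand.grid(off + seq_len(b), off + seq_len(b)))
}

corner_box_mean <- function(m, window = nrow(m)) {
  mean(m[corner_cells(window)], na.rm = TRUE)
}

#' Aggregate (average) loops over nuclei
#'
#' Pools per-loop windows across nuclei by summation, averages over loops,
#' divides the observed average by the shifted-control average, and rescales
#' the background (the two corner boxes) to 1.
#'
#' @inheritParams collect_loop_windows
#' @param windows Optionally, a precomputed `loop_windows` object (then
#'   `contacts`/`anchors`/`genome` are ignored).
#' @return List of class `loop_aggregate`: `observed`, `control`, `ratio`
#'   (background-rescaled observed/control), `strength`, `n_loops`,
#'   `n_nuclei`, `window`.
#' @export
average_loops <- function(contacts = NULL, anchors = NULL, genome = NULL,
                          resolution = 10000, window = 20L,
                          shift_range = c(100e3, 1100e3), n_shifts = 100L,
                          size_class = NULL, windows = NULL) {
  if (is.null(windows))
    windows <- collect_loop_windows(contacts, anchors, genome, resolution,
                                    window, shift_range, n_shifts, size_class)
  w <- windows$window
  obs_mean <- colMeans(rowsum(windows$obs, windows$meta$loop_id))
  ctrl_mean <- colMeans(rowsum(windows$ctrl, windows$meta$loop_id))
  observed <- matrix(obs_mean, w, w)
  control <- matrix(ctrl_mean, w, w)
  if (any(control == 0))
    warning("control average has empty cells; ratio undefined there")
  ratio <- observed / control
  bg <- corner_box_mean(ratio, w)
  if (!is.finite(bg) || bg <= 0)
    stop("zero control mass in the background boxes")
  agg <- structure(list(kind = "loop", observed = observed, control = control,
                        ratio = ratio / bg,
                        n_loops = length(unique(windows$meta$loop_id)),
                        n_nuclei = length(unique(windows$meta$nucleus)),
                        window = w),
                   class = "loop_aggregate")
  agg$strength <- loop_strength(agg)
  agg
}

#' Loop strength of an aggregate
#'
#' Mean of the central box divided by the mean of the two corner boxes at the
#' same diagonal distance, minus 1 — the fractional contact enrichment at the
#' loop over the distance background. For the standard 20 x 20 window at
#' 10-kb bins the boxes are 6 x 6 (60 x 60 kb).
#'
#' @param agg A `loop_aggregate`, or a plain window matrix.
#' @return A single number (0 for a featureless map).
#' @export
loop_strength <- function(agg) {
  m <- if (inherits(agg, "loop_aggregate")) agg$ratio else agg
  w <- nrow(m)
  corner <- mean(m[corner_cells(w)], na.rm = TRUE)
  centre <- mean(m[centre_cells(w)], na.rm = TRUE)
  if (!is.finite(corner) || corner == 0) stop("corner box mean is zero")
  centre / corner - 1
}

#' @export
print.loop_aggregate <- function(x, ...) {
  cat("<loop_aggregate> ", x$n_loops, " loops x ", x$n_nuclei,
      " nuclei; strength ", round(x$strength, 3), "\n", sep = "")
  invisible(x)
}

#' @export
glance.loop_aggregate <- function(x, ...) {
  tibble::tibble(strength = x$strength, n_loops = x$n_loops,
                 n_nuclei = x$n_nuclei, window = x$window)
}

# --- TAD aggregates ---------------------------------------------------------

boundary_positions <- function(boundaries) {
  if (all(c("chrom", "start", "end") %in% names(boundaries))) {
    tibble::tibble(chrom = boundaries$chrom,
                   pos = (boundaries$start + boundaries$end) / 2)
  } else if (all(c("chrom", "pos") %in% names(boundaries))) {
    tibble::tibble(chrom = boundaries$chrom, pos = boundaries$pos)
  } else {
    stop("boundaries must have columns chrom,start,end or chrom,pos")
  }
}

expected_by_distance <- function(mat, max_k = nrow(mat) - 1L) {
  # mean count at each bin separation 0..max_k of a symmetric sparse matrix
  n <- nrow(mat)
  tm <- Matrix::summary(mat)
  k <- abs(tm$j - tm$i)
  keep <- tm$j >= tm$i & k <= max_k
  sums <- rep(0, max_k + 1L)
  if (any(keep)) {
    agg <- rowsum(tm$x[keep], k[keep])
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  }
  counts <- n - 0:max_k
  sums / pmax(counts, 1)
}

rescale_matrix <- function(m, out_dim = 90L) {
  # area-weighted mean pooling / interpolation of m (n x n) onto out_dim^2
  n <- nrow(m)
  edges <- seq(0, n, length.out = out_dim + 1L)
  wmat <- matrix(0, out_dim, n)
  for (t in seq_len(out_dim)) {
    lo <- edges[t]
    hi <- edges[t + 1L]
    cells <- floor(lo):min(ceiling(hi) - 1, n - 1)
    overlap <- pmin(hi, cells + 1) - pmax(lo, cells)
    keep <- overlap > 1e-12
    wmat[t, cells[keep] + 1L] <- overlap[keep]
  }
  wmat <- wmat / rowSums(wmat)
  wmat %*% m %*% t(wmat)
}

#' Aggregate (average) rescaled TADs
#'
#' For each TAD (consecutive boundary pair within the size bounds), extracts
#' the TAD plus equal-length flanks (a 3L x 3L window), normalizes it by the
#' per-chromosome expected contact frequency at each bin separation
#' (observed/expected) and rescales it to `out_dim` x `out_dim` by
#' area-weighted interpolation; the result is the average over TADs of the
#' pooled (summed over nuclei) maps.
#'
#' @param mats A `binned_matrix` or list of them (pooled by summation).
#' @param boundaries Boundary tibble (`chrom`, `pos`) or BED-like
#'   (`chrom`, `start`, `end`).
#' @param min_size,max_size TAD size bounds in bp (default 100 kb and 1 Mb).
#' @param out_dim Output matrix size (default 90).
#' @return List of class `tad_aggregate`: `average` (out_dim x out_dim
#'   observed/expected), `strength` (see [tad_strength()]), `n_tads`,
#'   `n_skipped`.
#' @export
average_tads <- function(mats, boundaries, min_size = 100e3, max_size = 1e6,
                         out_dim = 90L) {
  pooled <- pool_binned(mats)
  res <- pooled$resolution
  bpos <- boundary_positions(boundaries)
  acc <- matrix(0, out_dim, out_dim)
  n_tads <- 0L
  n_skipped <- 0L
  for (cn in unique(bpos$chrom)) {
    if (!cn %in% names(pooled$intra)) next
    mat <- pooled$intra[[cn]]
    nb <- nrow(mat)
    exp_k <- NULL
    bb <- sort(unique(as.integer(bpos$pos[bpos$chrom == cn] %/% res)))
    if (length(bb) < 2) next
    for (t in seq_len(length(bb) - 1L)) {
      b1 <- bb[t]
      b2 <- bb[t + 1L]
      len <- b2 - b1
      size_bp <- len * res
      if (size_bp < min_size || size_bp > max_size) {
        n_skipped <- n_skipped + 1L
        next
      }
      lo <- b1 - len
      hi <- b2 + len - 1L
      if (lo < 0L || hi > nb - 1L) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (is.null(exp_k)) exp_k <- expected_by_distance(mat)
      idx <- (lo:hi) + 1L
      wmat <- as.matrix(mat[idx, idx])
      kmat <- abs(outer(lo:hi, lo:hi, `-`))
      emat <- matrix(exp_k[kmat + 1L], nrow(wmat))
      oe <- ifelse(emat > 0, wmat / emat, 0)
      acc <- acc + rescale_matrix(oe, out_dim)
      n_tads <- n_tads + 1L
    }
  }
  if (n_tads == 0L) stop("no TADs within the size bounds")
  if (n_skipped > 0L)
    message(n_skipped, " TAD(s) skipped (size bounds or chromosome ends)")
  agg <- structure(list(kind = "tad", average = acc / n_tads,
                        n_tads = n_tads, n_skipped = n_skipped,
                        out_dim = out_dim),
                   class = "tad_aggregate")
  agg$strength <- tad_strength(agg)
  agg
}

#' TAD strength ratio
#'
#' `box1 / box2`, where `box1` is the half-weighted sum of the two
#' flank-to-TAD blocks (rows 1-30 x cols 31-60 plus rows 31-60 x cols 61-90 of
#' the 90 x 90 aggregate) and `box2` the sum of the TAD-interior block (rows
#' and cols 31-60). A featureless observed/expected map gives 1; stronger TAD
#' insulation gives a smaller ratio.
#'
#' @param agg A `tad_aggregate` or a square matrix with side divisible by 3.
#' @return A single number.
#' @export
tad_strength <- function(agg) {
  m <- if (inherits(agg, "tad_aggregate")) agg$average else agg
  L <- nrow(m)
  stopifnot(L %% 3L == 0L)
  a <- L %/% 3L
  box1 <- 0.5 * sum(m[1:a, (a + 1):(2 * a)]) +
    0.5 * sum(m[(a + 1):(2 * a), (2 * a + 1):L])
  box2 <- sum(m[(a + 1):(2 * a), (a + 1):(2 * a)])
  if (box2 == 0) stop("TAD interior block is empty")
  box1 / box2
}

#' @export
print.tad_aggregate <- function(x, ...) {
  cat("<tad_aggregate> ", x$n_tads, " TADs; strength ratio ",
      round(x$strength, 3), "\n", sep = "")
  invisible(x)
}
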