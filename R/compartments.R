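cross_count_by_distance <- function(a, b) {
  # c(k) = sum_i a[i] * b[i + k] for k = 1 .. n-1, via FFT cross-correlation
  n <- length(a)
  np <- stats::nextn(2L * n)
  fa <- stats::fft(c(a, rep(0, np - n)))
  fb <- stats::fft(c(b, rep(0, np - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / np
  cc[2:n]
}

#' Compartment saddle matrix
#'
#' Ranks genomic bins by a compartment signal (GC content as A/B proxy),
#' splits them into `n_groups` percentile groups, and computes the mean
#' observed/expected interaction (ratio of sums) for each group pair, pooled
#' over chromosomes and nuclei. The resulting matrix is iteratively corrected
#' so that all row/column sums equalize.
#'
#' @param mats A `binned_matrix` or a list of them (pooled by summation).
#' @param gc Tibble with one value per genomic bin: columns `chrom`, `start`,
#'   `gc` (bins at the matrix resolution; missing bins are excluded).
#' @param n_groups Number of percentile groups (default 5).
#' @param tol Convergence tolerance of the iterative correction (relative
#'   row-sum spread; default 1e-9).
#' @return List of class `saddle_matrix`: `saddle` (corrected n x n matrix,
#'   group 1 = lowest GC), `raw` (before correction), `strength`.
#' @export
compartment_saddle <- function(mats, gc, n_groups = 5L, tol = 1e-9) {
  pooled <- pool_binned(mats)
  res <- pooled$resolution
  stopifnot(all(c("chrom", "start", "gc") %in% names(gc)))
  gc <- gc[is.finite(gc$gc), ]
  if (nrow(gc) < n_groups) stop("too few bins with a compartment signal")
  # genome-wide percentile groups
  grp <- dplyr::ntile(gc$gc, n_groups)
  gc$group <- grp
  if (any(tabulate(grp, n_groups) == 0))
    stop("a percentile group has no covered bins")
  num <- matrix(0, n_groups, n_groups)
  den <- matrix(0, n_groups, n_groups)
  for (cn in names(pooled$intra)) {
    mat <- pooled$intra[[cn]]
    nb <- nrow(mat)
    gsub_ <- gc[gc$chrom == cn, ]
    if (nrow(gsub_) == 0) next
    gvec <- rep(NA_integer_, nb)
    bin_idx <- as.integer(gsub_$start %/% res) + 1L
    gvec[bin_idx] <- gsub_$group
    exp_k <- expected_by_distance(mat)
    tm <- Matrix::summary(mat)
    keep <- tm$j > tm$i
    i <- tm$i[keep]; j <- tm$j[keep]; x <- tm$x[keep]
    gi <- gvec[i]; gj <- gvec[j]
    ok <- !is.na(gi) & !is.na(gj)
    if (any(ok)) {
      # numerator: observed counts per group pair (both orientations)
      lin <- c((gj[ok] - 1L) * n_groups + gi[ok],
               (gi[ok] - 1L) * n_groups + gj[ok])
      agg <- rowsum(rep(x[ok], 2L), lin)
      num[as.integer(rownames(agg))] <- num[as.integer(rownames(agg))] +
        agg[, 1L]
    }
    # denominator: sum over pairs of expected counts per group pair
    ind <- matrix(0, nb, n_groups)
    ind[cbind(which(!is.na(gvec)), gvec[!is.na(gvec)])] <- 1
    ek <- exp_k[-1L]                      # k = 1 .. nb-1
    for (g1 in seq_len(n_groups)) {
      for (g2 in g1:n_groups) {
        cc <- cross_count_by_distance(ind[, g1], ind[, g2])
        v <- sum(cc * ek)
        if (g1 == g2) {
          cc2 <- cross_count_by_distance(ind[, g2], ind[, g1])
          v <- v + sum(cc2 * ek)
          den[g1, g1] <- den[g1, g1] + v
        } else {
          cc2 <- cross_count_by_distance(ind[, g2], ind[, g1])
          den[g1, g2] <- den[g1, g2] + v + sum(cc2 * ek)
          den[g2, g1] <- den[g1, g2]
        }
      }
    }
  }
  if (any(den == 0)) stop("a group pair has no expected contacts")
  raw <- num / den
  saddle <- iterative_correction(raw, tol = tol)
  out <- structure(list(saddle = saddle, raw = raw, n_groups = n_groups),
                   class = "saddle_matrix")
  out$strength <- compartment_strength(out)
  out
}

#' Iterative correction of a small symmetric matrix
#'
#' Rescales rows and columns symmetrically until all row sums agree to the
#' given relative tolerance.
#'
#' @param m Square matrix with positive entries.
#' @param tol Relative tolerance (default 1e-9).
#' @param max_iter Iteration cap.
#' @return The balanced matrix (mean row sum preserved).
#' @export
iterative_correction <- function(m, tol = 1e-9, max_iter = 10000L) {
  if (any(m < 0)) stop("matrix must be non-negative")
  target <- mean(rowSums(m))
  for (it in seq_len(max_iter)) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("a row of the saddle matrix is empty")
    if (max(abs(rs - mean(rs))) / mean(rs) < tol) break
    d <- sqrt(rs / mean(rs))
    m <- m / outer(d, d)
  }
  m * target / mean(rowSums(m))
}

#' Compartment strength of a saddle matrix
#'
#' `log(AA * BB / (AB * BA))` over the four corner cells of the corrected
#' saddle; 0 for no compartmentalization.
#'
#' @param saddle A `saddle_matrix` or plain matrix.
#' @return A single number (natural log).
#' @export
compartment_strength <- function(saddle) {
  m <- if (inherits(saddle, "saddle_matrix")) saddle$saddle else saddle
  n <- nrow(m)
  corners <- c(m[1, 1], m[n, n], m[1, n], m[n, 1])
  if (any(corners <= 0)) stop("non-positive saddle corner")
  log(corners[1] * corners[2] / (corners[3] * corners[4]))
}

#' @export
print.saddle_matrix <- function(x, ...) {
  cat("<saddle_matrix> ", x$n_groups, "x", x$n_groups,
      " groups; compartment strength ", round(x$strength, 3), "\n", sep = "")
  invisible(x)
}

#' Insulation profile around boundaries
#'
#' Computes, at each genomic bin, the sum of contacts within a sliding
#' `diamond` x `diamond` window whose tip touches the diagonal; normalizes
#' each chromosome's profile by its minimum and subtracts 1 (so the deepest
#' insulation valley is 0); and averages the normalized profiles across
#' boundaries aligned at offset 0.
#'
#' @param mats A `binned_matrix` or a list of them (pooled).
#' @param boundaries Boundary tibble (`chrom`, `pos` or BED-like).
#' @param diamond Window edge in bp (default 40 kb).
#' @param flank_bins Alignment half-width in bins (default 20).
#' @return List of class `insulation_profile`: `profile` (tibble `chrom`,
#'   `bin`, `score`, `norm`), `aligned` (tibble `offset_bins`, `mean`, `se`,
#'   `n`).
#' @export
insulation_profile <- function(mats, boundaries, diamond = 40e3,
                               flank_bins = 20L) {
  pooled <- pool_binned(mats)
  res <- pooled$resolution
  w <- as.integer(diamond %/% res)
  if (w < 1) stop("diamond smaller than one bin")
  bpos <- boundary_positions(boundaries)
  profiles <- list()
  for (cn in names(pooled$intra)) {
    mat <- pooled$intra[[cn]]
    nb <- nrow(mat)
    if (nb < 2L * w + 1L) next
    tm <- Matrix::summary(mat)
    keep <- tm$j > tm$i & (tm$j - tm$i) <= 2L * w - 1L
    score <- numeric(nb)
    if (any(keep)) {
      a <- tm$i[keep] - 1L      # 0-based
      b <- tm$j[keep] - 1L
      x <- tm$x[keep]
      # pixel (a, b) contributes to boundary positions t with
      # a in [t-w+1, t] and b in [t+1, t+w]
      lo <- pmax(a, b - w)
      hi <- pmin(b - 1L, a + w - 1L)
      ok <- hi >= lo
      if (any(ok)) {
        reps <- (hi - lo + 1L)[ok]
        t_idx <- unlist(lapply(which(ok), function(r) lo[r]:hi[r]),
                        use.names = FALSE)
        vals <- rep(x[ok], reps)
        agg <- rowsum(vals, t_idx)
        score[as.integer(rownames(agg)) + 1L] <-
          score[as.integer(rownames(agg)) + 1L] + agg[, 1L]
      }
    }
    valid <- (w):(nb - w - 1L) + 1L     # 1-based bins with a full diamond
    sc <- score[valid]
    if (all(sc == 0)) stop("all diamond sums are zero on ", cn)
    mn <- min(sc)
    if (mn == 0) {
      warning("zero minimum insulation on ", cn,
              "; using smallest positive value")
      mn <- min(sc[sc > 0])
    }
    profiles[[cn]] <- tibble::tibble(chrom = cn, bin = valid - 1L,
                                     score = sc, norm = sc / mn - 1)
  }
  prof <- dplyr::bind_rows(profiles)
  if (nrow(prof) == 0) stop("no chromosome long enough for the diamond")
  # align at boundaries
  bpos$bin <- as.integer(bpos$pos %/% res)
  rows <- list()
  for (r in seq_len(nrow(bpos))) {
    p <- prof[prof$chrom == bpos$chrom[r], ]
    if (nrow(p) == 0) next
    off <- (-flank_bins):flank_bins
    m <- match(bpos$bin[r] + off, p$bin)
    rows[[r]] <- tibble::tibble(offset_bins = off, norm = p$norm[m])
  }
  ali <- dplyr::bind_rows(rows) %>%
    dplyr::filter(!is.na(norm)) %>%
    dplyr::group_by(offset_bins) %>%
    dplyr::summarise(mean = mean(norm), se = sd(norm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(profile = prof, aligned = ali, diamond = diamond,
                 resolution = res),
            class = "insulation_profile")
}

#' @export
print.insulation_profile <- function(x, ...) {
  dip <- x$aligned$mean[x$aligned$offset_bins == 0]
  cat("<insulation_profile> ", length(unique(x$profile$chrom)),
      " chromosome(s); mean normalized score at boundaries ",
      round(dip, 3), "\n", sep = "")
  invisible(x)
}
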