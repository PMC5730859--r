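#' Canonicalize a contact list
#'
#' Stores unordered pairs canonically: `chrom1 <= chrom2` (lexicographic), and
#' `pos1 <= pos2` for intra-chromosomal contacts.
#'
#' @param contacts Tibble with columns `chrom1`, `pos1`, `chrom2`, `pos2` (and
#'   any others, which are preserved).
#' @return The canonicalized tibble.
#' @export
canonicalize_contacts <- function(contacts) {
  swap <- contacts$chrom1 > contacts$chrom2 |
    (contacts$chrom1 == contacts$chrom2 & contacts$pos1 > contacts$pos2)
  if (any(swap)) {
    tmp_c <- contacts$chrom1[swap]
    tmp_p <- contacts$pos1[swap]
    contacts$chrom1[swap] <- contacts$chrom2[swap]
    contacts$pos1[swap] <- contacts$pos2[swap]
    contacts$chrom2[swap] <- tmp_c
    contacts$pos2[swap] <- tmp_p
  }
  contacts
}

validate_contacts <- function(contacts, genome) {
  stopifnot(all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(contacts)))
  sizes <- setNames(genome$size, genome$chrom)
  bad <- !(contacts$chrom1 %in% genome$chrom) |
    !(contacts$chrom2 %in% genome$chrom)
  if (any(bad))
    stop("contacts reference unknown chromosomes: ",
         paste(head(unique(c(contacts$chrom1[bad], contacts$chrom2[bad]))),
               collapse = ", "))
  out_of_range <- contacts$pos1 < 0 | contacts$pos2 < 0 |
    contacts$pos1 >= sizes[contacts$chrom1] |
    contacts$pos2 >= sizes[contacts$chrom2]
  if (any(out_of_range))
    stop(sum(out_of_range), " contact(s) fall outside chromosome bounds ",
         "(first at record ", which(out_of_range)[1], ")")
  invisible(contacts)
}

#' Bin a contact list into sparse per-chromosome matrices
#'
#' Each intra-chromosomal contact increments one `(bin_i, bin_j)` cell and its
#' mirror, so the total intra matrix mass equals twice the number of intra
#' contacts. Trans contacts are tallied per chromosome pair. Bins are 0-based
#' and half-open.
#'
#' @param contacts Contact tibble (`chrom1`, `pos1`, `chrom2`, `pos2`).
#' @param genome Tibble with columns `chrom`, `size`.
#' @param resolution Bin size in bp (default 10,000).
#' @return List of class `binned_matrix`: `resolution`, `genome`, `n_bins`
#'   (named vector), `intra` (named list of symmetric `dgCMatrix`), `trans`
#'   (tibble `chrom1`, `chrom2`, `n`).
#' @export
bin_contacts <- function(contacts, genome, resolution = 10000) {
  validate_contacts(contacts, genome)
  contacts <- canonicalize_contacts(contacts)
  n_bins <- setNames(as.integer(ceiling(genome$size / resolution)),
                     genome$chrom)
  intra_idx <- contacts$chrom1 == contacts$chrom2
  intra <- contacts[intra_idx, ]
  mats <- lapply(genome$chrom, function(cn) {
    nb <- n_bins[[cn]]
    sel <- intra$chrom1 == cn
    i <- intra$pos1[sel] %/% resolution
    j <- intra$pos2[sel] %/% resolution
    s <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = 1,
                              dims = c(nb, nb))
    s + Matrix::t(s)
  })
  names(mats) <- genome$chrom
  trans <- contacts[!intra_idx, ] %>%
    dplyr::count(chrom1, chrom2, name = "n")
  structure(list(resolution = resolution, genome = genome, n_bins = n_bins,
                 intra = mats, trans = trans),
            class = "binned_matrix")
}

#' Pool several binned matrices
#'
#' Sums the per-chromosome matrices of multiple nuclei (pooled single-cell
#' maps). All inputs must share the genome and resolution.
#'
#' @param mats A `binned_matrix` or a list of them.
#' @return A single pooled `binned_matrix`.
#' @export
pool_binned <- function(mats) {
  if (inherits(mats, "binned_matrix")) return(mats)
  stopifnot(length(mats) >= 1)
  out <- mats[[1L]]
  for (m in mats[-1L]) {
    stopifnot(m$resolution == out$resolution,
              identical(m$genome$chrom, out$genome$chrom))
    for (cn in names(out$intra)) out$intra[[cn]] <- out$intra[[cn]] + m$intra[[cn]]
    out$trans <- dplyr::bind_rows(out$trans, m$trans) %>%
      dplyr::count(chrom1, chrom2, wt = n, name = "n")
  }
  out
}

log_bin_table <- function(max_s, resolution = 10000, log_factor = 1.3) {
  n_edges <- ceiling(log(max_s / resolution) / log(log_factor)) + 1L
  edges <- resolution * log_factor^(0:n_edges)
  tibble::tibble(bin = seq_len(length(edges) - 1L),
                 s_lo = edges[-length(edges)],
                 s_hi = edges[-1L])
}

#' Contact probability as a function of genomic separation
#'
#' Computes P_c(s) from a contact list: genomic separations are taken at the
#' `resolution` bin level, grouped into logarithmic bins with the given
#' factor, and each bin's contact count is divided by the genome-wide number
#' of locus pairs at those separations.
#'
#' @param contacts Contact tibble.
#' @param genome Tibble `chrom`, `size`.
#' @param resolution Base bin size (default 10 kb).
#' @param log_factor Geometric bin factor (default 1.3).
#' @return Tibble of class `pcs_curve` with columns `s_lo`, `s_hi`, `s_mid`
#'   (geometric mean of the covered lattice separations), `n_contacts`,
#'   `n_pairs`, `p`. Log bins containing no lattice separation are dropped.
#' @export
compute_pcs <- function(contacts, genome, resolution = 10000,
                        log_factor = 1.3) {
  validate_contacts(contacts, genome)
  intra <- contacts[contacts$chrom1 == contacts$chrom2, ]
  if (nrow(intra) == 0) stop("no intra-chromosomal contacts")
  k <- abs(intra$pos2 %/% resolution - intra$pos1 %/% resolution)
  k <- k[k >= 1L]
  n_bins <- ceiling(genome$size / resolution)
  max_k <- max(n_bins) - 1L
  bins <- log_bin_table(max_k * resolution + 1, resolution, log_factor)
  # lattice separations covered by each log bin
  k_all <- seq_len(max_k)
  k_bin <- findInterval(k_all * resolution, bins$s_lo)
  pairs_k <- vapply(k_all, function(kk) sum(pmax(n_bins - kk, 0)), numeric(1))
  per_bin <- tibble::tibble(bin = k_bin, k = k_all, pairs = pairs_k) %>%
    dplyr::group_by(bin) %>%
    dplyr::summarise(s_mid = exp(mean(log(k * resolution))),
                     n_pairs = sum(pairs), .groups = "drop")
  counts <- tabulate(findInterval(k * resolution, bins$s_lo),
                     nbins = nrow(bins))
  out <- bins %>%
    dplyr::inner_join(per_bin, by = "bin") %>%
    dplyr::mutate(n_contacts = counts[bin],
                  p = n_contacts / n_pairs) %>%
    dplyr::filter(n_pairs > 0) %>%
    dplyr::select(s_lo, s_hi, s_mid, n_contacts, n_pairs, p)
  class(out) <- c("pcs_curve", class(out))
  out
}

#' Normalize a P_c(s) curve at a reference separation
#'
#' Divides the curve by its value in the log bin whose centre is nearest the
#' reference separation (default 9 kb, i.e. the first bin on a 10-kb grid).
#'
#' @param curve A `pcs_curve`.
#' @param at_bp Reference separation (default 9,000).
#' @return The curve with `p` rescaled so the reference bin equals 1.
#' @export
normalize_pcs <- function(curve, at_bp = 9000) {
  ref <- which.min(abs(log(curve$s_mid / at_bp)))
  if (curve$p[ref] <= 0) stop("reference bin has zero contact probability")
  curve$p <- curve$p / curve$p[ref]
  curve
}

#' Gaussian smoothing of a numeric series
#'
#' One-dimensional Gaussian filter with reflected boundaries (the smoothing
#' applied to both log axes before differentiating P_c(s)).
#'
#' @param v Numeric vector.
#' @param sigma Kernel standard deviation in index units.
#' @return Smoothed vector of the same length.
#' @export
gaussian_smooth1d <- function(v, sigma = 0.8) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-0.5 * ((-r:r) / sigma)^2)
  kern <- kern / sum(kern)
  n <- length(v)
  pad <- c(v[pmin(r, n):1], v, v[n:max(1L, n - r + 1L)])
  out <- stats::filter(pad, kern, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Log-log slope of a P_c(s) curve
#'
#' Applies Gaussian smoothing (default radius 0.8 bins) to both log(s) and
#' log(P_c) and differentiates by central differences (one-sided at the
#' endpoints). Only bins with positive probability enter the computation.
#'
#' @param curve A `pcs_curve`.
#' @param smoothing_radius Gaussian sigma in bins (default 0.8).
#' @return The curve restricted to usable bins, with columns `log_s_smooth`,
#'   `log_p_smooth` and `slope` added.
#' @export
pcs_slope <- function(curve, smoothing_radius = 0.8) {
  use <- curve$p > 0 & is.finite(curve$p)
  cv <- curve[use, ]
  if (nrow(cv) < 3) stop("need at least 3 bins with positive P_c(s)")
  lx <- gaussian_smooth1d(log(cv$s_mid), smoothing_radius)
  ly <- gaussian_smooth1d(log(cv$p), smoothing_radius)
  n <- length(lx)
  slope <- numeric(n)
  slope[1] <- (ly[2] - ly[1]) / (lx[2] - lx[1])
  slope[n] <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    slope[i] <- (ly[i + 1] - ly[i - 1]) / (lx[i + 1] - lx[i - 1])
  }
  cv$log_s_smooth <- lx
  cv$log_p_smooth <- ly
  cv$slope <- slope
  cv
}

#' Classify a nucleus as maternal or paternal from its P_c(s) curve
#'
#' Maternal chromatin shows a long-range (10-30 Mb) plateau in P_c(s). After
#' normalizing the curve to 1 at 9 kb, a nucleus is excluded when
#' P_c(30 kb) < 0.1 (bad data filter); otherwise, in G1 it is maternal when
#' P_c(15 Mb) > 1e-4 and in G2 when P_c(20 Mb) > 2.5e-5.
#'
#' @param curve A `pcs_curve` for one nucleus (raw; normalized internally).
#' @param phase `"G1"` or `"G2"`.
#' @return One of `"maternal"`, `"paternal"`, `"excluded"`.
#' @export
classify_pronucleus <- function(curve, phase = c("G1", "G2")) {
  phase <- match.arg(phase)
  curve <- normalize_pcs(curve, at_bp = 9000)
  value_at <- function(s_bp) {
    i <- which.min(abs(log(curve$s_mid / s_bp)))
    if (abs(log(curve$s_mid[i] / s_bp)) > log(1.3))
      stop("curve has no bin within one log-bin factor of ", s_bp, " bp")
    curve$p[i]
  }
  if (value_at(30e3) < 1e-1) return("excluded")
  if (phase == "G1") {
    if (value_at(15e6) > 1e-4) "maternal" else "paternal"
  } else {
    if (value_at(20e6) > 2.5e-5) "maternal" else "paternal"
  }
}

#' Sort nuclei into maternal and paternal pronuclei
#'
#' Applies [classify_pronucleus()] per nucleus of a multi-nucleus contact
#' tibble.
#'
#' @param contacts Contact tibble with a `nucleus` column.
#' @param genome Genome tibble.
#' @param phase `"G1"` or `"G2"`.
#' @return Tibble with columns `nucleus`, `label`.
#' @export
sort_pronuclei <- function(contacts, genome, phase = c("G1", "G2")) {
  phase <- match.arg(phase)
  stopifnot("nucleus" %in% names(contacts))
  contacts %>%
    dplyr::group_by(nucleus) %>%
    dplyr::group_map(function(g, key) {
      tibble::tibble(nucleus = key$nucleus,
                     label = classify_pronucleus(compute_pcs(g, genome),
                                                 phase))
    }) %>%
    dplyr::bind_rows()
}
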