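strength_from_sums <- function(obs_vec, ctrl_vec, window) {
  ratio <- matrix(obs_vec, window, window) / matrix(ctrl_vec, window, window)
  loop_strength(ratio)
}

#' Bootstrap confidence interval for the aggregate loop strength
#'
#' Resamples loops (pooled across nuclei) with replacement, recomputes the
#' aggregate observed/control windows and the loop strength for each
#' resample, and reports percentile confidence intervals from the sorted
#' resample statistics.
#'
#' @param windows A `loop_windows` object from [collect_loop_windows()].
#' @param n_resamples Number of bootstrap resamples (default 10,000).
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return List of class `resampling_result`: `point_estimate`, `ci_low`,
#'   `ci_high`, `n_resamples`, `seed`, `statistics` (the resample values).
#' @export
bootstrap_loop_strength_ci <- function(windows, n_resamples = 10000L,
                                       conf = 0.95, seed = 1L) {
  stopifnot(inherits(windows, "loop_windows"))
  w <- windows$window
  # pool over nuclei: one observed/control window per loop
  obs <- rowsum(windows$obs, windows$meta$loop_id)
  ctrl <- rowsum(windows$ctrl, windows$meta$loop_id)
  n <- nrow(obs)
  if (n < 2) stop("need at least 2 loop windows to bootstrap")
  point <- strength_from_sums(colSums(obs), colSums(ctrl), w)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                n_resamples, n)
  # counts-per-loop representation: resampled sums are count-matrix products
  counts <- matrix(0, n_resamples, n)
  for (r in seq_len(n_resamples))
    counts[r, ] <- tabulate(idx[r, ], nbins = n)
  obs_s <- counts %*% obs
  ctrl_s <- counts %*% ctrl
  stat <- vapply(seq_len(n_resamples), function(r)
    strength_from_sums(obs_s[r, ], ctrl_s[r, ], w), numeric(1))
  alpha <- (1 - conf) / 2
  qs <- quantile(sort(stat), c(alpha, 1 - alpha), names = FALSE, type = 1)
  structure(list(point_estimate = point, ci_low = qs[1], ci_high = qs[2],
                 n_resamples = as.integer(n_resamples), conf = conf,
                 seed = as.integer(seed), statistics = stat,
                 n_loops = n),
            class = "resampling_result")
}

#' Permutation test for a difference in mean loop strength
#'
#' The observed statistic is the difference between the two groups' pooled
#' loop strengths. The null distribution is obtained by randomly permuting the
#' nucleus (replicate) labels — loops within a nucleus stay together — and the
#' two-sided p-value is the +1-corrected fraction of permuted absolute
#' differences at least as large as the observed one.
#'
#' @param windows_a,windows_b `loop_windows` objects for the two conditions
#'   (each with at least 2 nuclei).
#' @param n_permutations Number of label permutations (default 1,000).
#' @param seed RNG seed.
#' @return List of class `resampling_result`: `point_estimate` (observed
#'   difference), `p_value`, `n_permutations`, `seed`, `null_statistics`.
#' @export
permutation_test_loop_strength <- function(windows_a, windows_b,
                                           n_permutations = 1000L,
                                           seed = 1L) {
  stopifnot(inherits(windows_a, "loop_windows"),
            inherits(windows_b, "loop_windows"),
            windows_a$window == windows_b$window)
  w <- windows_a$window
  per_nucleus <- function(wd) {
    list(obs = rowsum(wd$obs, wd$meta$nucleus),
         ctrl = rowsum(wd$ctrl, wd$meta$nucleus))
  }
  a <- per_nucleus(windows_a)
  b <- per_nucleus(windows_b)
  na <- nrow(a$obs)
  nb <- nrow(b$obs)
  if (na < 2 || nb < 2)
    stop("need at least 2 nuclei per group for a permutation test")
  obs_all <- rbind(a$obs, b$obs)
  ctrl_all <- rbind(a$ctrl, b$ctrl)
  group_stat <- function(sel) {
    sa <- strength_from_sums(colSums(obs_all[sel, , drop = FALSE]),
                             colSums(ctrl_all[sel, , drop = FALSE]), w)
    sb <- strength_from_sums(colSums(obs_all[!sel, , drop = FALSE]),
                             colSums(ctrl_all[!sel, , drop = FALSE]), w)
    sa - sb
  }
  sel0 <- c(rep(TRUE, na), rep(FALSE, nb))
  observed <- group_stat(sel0)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_permutations), function(r) {
    sel <- logical(na + nb)
    sel[sample.int(na + nb, na)] <- TRUE
    group_stat(sel)
  }, numeric(1))
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (n_permutations + 1)
  structure(list(point_estimate = observed, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), null_statistics = null_stats,
                 n_nuclei = c(a = na, b = nb)),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  if (!is.null(x$p_value)) {
    cat("<resampling_result> difference ", signif(x$point_estimate, 4),
        ", p = ", signif(x$p_value, 3), " (", x$n_permutations,
        " permutations)\n", sep = "")
  } else {
    cat("<resampling_result> estimate ", signif(x$point_estimate, 4),
        ", ", 100 * x$conf, "% CI [", signif(x$ci_low, 4), ", ",
        signif(x$ci_high, 4), "] (", x$n_resamples, " resamples)\n",
        sep = "")
  }
  invisible(x)
}

#' @export
glance.resampling_result <- function(x, ...) {
  tibble::tibble(point_estimate = x$point_estimate,
                 ci_low = x$ci_low %||% NA_real_,
                 ci_high = x$ci_high %||% NA_real_,
                 p_value = x$p_value %||% NA_real_,
                 n_resamples = x$n_resamples %||% NA_integer_,
                 n_permutations = x$n_permutations %||% NA_integer_,
                 seed = x$seed)
}
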