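## ROC construction: empirical sliding-threshold curves with trapezoidal AUC,
## kernel-smoothed log-likelihood-ratio (proper) ROC curves, and the
## bootstrapped above-chance test on the LR-ROC AUC.

new_roc <- function(points, auc, variant, n_normal, n_abnormal) {
  structure(list(points = points, auc = auc, variant = variant,
                 n_normal = n_normal, n_abnormal = n_abnormal),
            class = "gist_roc")
}

trapezoid_auc <- function(fa, hit) {
  n <- length(fa)
  sum(diff(fa) * (hit[-1] + hit[-n]) / 2)
}

## survivor counts on the 0..100 rating lattice: surv[t + 1] = #{x >= t}
lattice_survivor <- function(x) {
  counts <- tabulate(as.integer(round(x)) + 1L, nbins = 101L)
  rev(cumsum(rev(counts)))
}

#' Empirical sliding-threshold ROC
#'
#' Sweeps the decision threshold t over 1..99, classifying a trial as
#' "abnormal" when its rating is at least t (so the fixed-threshold metric at
#' 50, rating > 50, coincides with the sweep point t = 51), and plots the
#' resulting (false-alarm, hit) pairs together with the (0,0) and (1,1)
#' endpoints. The AUC is the trapezoidal area over the points sorted by
#' false-alarm then hit rate; for integer ratings it equals the rank
#' statistic P(abnormal > normal) + P(abnormal = normal)/2.
#'
#' @param normal_ratings integer ratings (0--100) of normal-truth trials.
#' @param abnormal_ratings integer ratings of abnormal-truth trials.
#' @return object of class `gist_roc` with elements `points` (data frame of
#'   `fa_rate`, `hit_rate`), `auc`, `variant = "empirical"`, `n_normal`,
#'   `n_abnormal`.
#' @export
empirical_roc <- function(normal_ratings, abnormal_ratings) {
  assert_ratings(normal_ratings, "normal_ratings")
  assert_ratings(abnormal_ratings, "abnormal_ratings")
  sn <- lattice_survivor(normal_ratings) / length(normal_ratings)
  sa <- lattice_survivor(abnormal_ratings) / length(abnormal_ratings)
  t <- 2:100                                   # thresholds 1..99 -> index t+1
  fa <- c(1, sn[t], 0)
  hit <- c(1, sa[t], 0)
  ord <- order(fa, hit)
  pts <- unique(data.frame(fa_rate = fa[ord], hit_rate = hit[ord]))
  rownames(pts) <- NULL
  new_roc(pts, trapezoid_auc(pts$fa_rate, pts$hit_rate), "empirical",
          length(normal_ratings), length(abnormal_ratings))
}

## Column-normalised Gaussian smoothing kernel on the 0..100 lattice.
## Normalising each source column to unit mass reassigns the mass a kernel
## would lose past the boundaries back onto the lattice (boundary
## renormalisation, equivalent in effect to reflecting truncated mass).
smoothing_kernel <- function(sigma) {
  key <- sprintf("K_%.12g", sigma)
  if (!is.null(.gist_cache[[key]])) return(.gist_cache[[key]])
  K <- outer(0:100, 0:100, function(i, j) stats::dnorm(i - j, 0, sigma))
  K <- sweep(K, 2, colSums(K), "/")
  .gist_cache[[key]] <- K
  K
}

smoothed_density <- function(ratings, sigma, eps) {
  p <- tabulate(as.integer(round(ratings)) + 1L, nbins = 101L) / length(ratings)
  p <- as.vector(smoothing_kernel(sigma) %*% p)
  p <- pmax(p, eps)
  p / sum(p)
}

#' Kernel-smoothed log-likelihood-ratio ROC
#'
#' Builds a proper ROC robust to bimodal rating distributions: each class's
#' rating distribution on the 0--100 lattice is smoothed with a Gaussian
#' kernel (width 10 by default, interpreted as the standard deviation in
#' rating units; `width_type = "fwhm"` interprets it as full width at half
#' maximum), floored at `eps` and renormalised; the log-likelihood ratio
#' log(p_abnormal / p_normal) is computed at each lattice value; lattice
#' values are then visited in order of decreasing likelihood ratio,
#' accumulating the two class masses to trace the curve. Ordering by the
#' likelihood ratio of the same densities that supply the masses makes the
#' curve concave by construction.
#'
#' @inheritParams empirical_roc
#' @param kernel_width Gaussian kernel width in rating units (default 10).
#' @param width_type `"sd"` (default) or `"fwhm"`.
#' @param eps density floor applied before taking log-likelihood ratios.
#' @return object of class `gist_roc` with `variant = "loglikelihood"`; the
#'   `points` data frame carries the log-likelihood ratio of each segment in
#'   column `llr`.
#' @export
llroc <- function(normal_ratings, abnormal_ratings, kernel_width = 10,
                  width_type = c("sd", "fwhm"), eps = 1e-6) {
  assert_ratings(normal_ratings, "normal_ratings")
  assert_ratings(abnormal_ratings, "abnormal_ratings")
  if (!is.numeric(kernel_width) || kernel_width <= 0)
    stop_gist("kernel_width must be positive")
  width_type <- match.arg(width_type)
  sigma <- if (width_type == "fwhm") kernel_width / (2 * sqrt(2 * log(2)))
           else kernel_width

  pn <- smoothed_density(normal_ratings, sigma, eps)
  pa <- smoothed_density(abnormal_ratings, sigma, eps)
  llr <- log(pa) - log(pn)

  ord <- order(llr, decreasing = TRUE)
  grp <- cumsum(!duplicated(llr[ord]))         # group exactly tied LR values
  fa_step <- as.vector(rowsum(pn[ord], grp))
  hit_step <- as.vector(rowsum(pa[ord], grp))
  llr_grp <- llr[ord][!duplicated(llr[ord])]

  fa <- c(0, cumsum(fa_step))
  hit <- c(0, cumsum(hit_step))
  pts <- data.frame(fa_rate = fa, hit_rate = hit, llr = c(Inf, llr_grp))
  new_roc(pts, trapezoid_auc(fa, hit), "loglikelihood",
          length(normal_ratings), length(abnormal_ratings))
}

#' Bootstrapped above-chance test for the LR-ROC AUC
#'
#' Compares the observed log-likelihood-ratio ROC AUC against a chance null
#' built from `n_boot` bootstrap samples. Under the default
#' `null = "label_shuffle"` chance model, each null sample pools all ratings
#' and resamples both classes (original sizes preserved) with replacement
#' from the pool, destroying any label information;
#' `null = "within_class"` instead resamples each class from itself (a
#' variability bootstrap, not a chance null). The cutoff is the nearest-rank
#' `percentile`-th value of the null AUCs, and the observed AUC counts as
#' above chance when it strictly exceeds the cutoff.
#'
#' @inheritParams llroc
#' @param n_boot number of bootstrap samples (default 100).
#' @param percentile null percentile used as the cutoff (default 95).
#' @param seed integer seed; the result is fully reproducible from it.
#' @param null `"label_shuffle"` (default) or `"within_class"`.
#' @param ... further arguments passed to [llroc()].
#' @return object of class `gist_chance_test`: `observed_auc`, `null_aucs`,
#'   `percentile_cutoff`, `above_chance`, `n_boot`, `percentile`, `seed`.
#' @export
chance_test <- function(normal_ratings, abnormal_ratings, n_boot = 100,
                        percentile = 95, seed = NULL,
                        null = c("label_shuffle", "within_class"), ...) {
  if (!is.numeric(n_boot) || n_boot < 1) stop_gist("n_boot must be >= 1")
  null <- match.arg(null)
  observed <- llroc(normal_ratings, abnormal_ratings, ...)$auc
  n_norm <- length(normal_ratings)
  n_abn <- length(abnormal_ratings)
  pool <- c(normal_ratings, abnormal_ratings)

  null_aucs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    if (null == "label_shuffle") {
      nn <- sample(pool, n_norm, replace = TRUE)
      aa <- sample(pool, n_abn, replace = TRUE)
    } else {
      nn <- sample(normal_ratings, n_norm, replace = TRUE)
      aa <- sample(abnormal_ratings, n_abn, replace = TRUE)
    }
    llroc(nn, aa, ...)$auc
  }, 0))

  cutoff <- nearest_rank(null_aucs, percentile)
  structure(list(observed_auc = observed, null_aucs = null_aucs,
                 percentile_cutoff = cutoff,
                 above_chance = observed > cutoff,
                 n_boot = as.integer(n_boot), percentile = percentile,
                 seed = seed),
            class = "gist_chance_test")
}

#' @export
print.gist_roc <- function(x, ...) {
  cat(sprintf("%s ROC: %d points, AUC = %.4f (%d normal, %d abnormal trials)\n",
              x$variant, nrow(x$points), x$auc, x$n_normal, x$n_abnormal))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x a `gist_roc` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gist_roc <- function(x, ...) {
  graphics::plot(x$points$fa_rate, x$points$hit_rate, type = "l",
                 xlab = "False-alarm rate", ylab = "Hit rate",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("%s ROC (AUC = %.3f)", x$variant, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
print.gist_chance_test <- function(x, ...) {
  cat(sprintf(
    "LR-ROC chance test: observed AUC %.4f vs %g-th percentile of %d null AUCs (%.4f): %s\n",
    x$observed_auc, x$percentile, x$n_boot, x$percentile_cutoff,
    if (x$above_chance) "above chance" else "not above chance"))
  invisible(x)
}
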