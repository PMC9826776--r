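## Equal-variance signal detection metrics at a fixed rating threshold:
## hit/false-alarm rates with extreme-proportion correction, d', criterion,
## and per-participant x phase x category summaries.

#' Binarize a 0--100 rating at a threshold
#'
#' A rating strictly above the threshold is an "abnormal" decision; a rating
#' at or below it is "normal". The default threshold of 50 matches the
#' feedback rule of the training task (ratings above 50 counted as correct
#' for abnormal ground truth).
#'
#' @param rating integer vector of ratings in \[0, 100\].
#' @param threshold decision threshold (default 50).
#' @return character vector of `"normal"` / `"abnormal"` decisions.
#' @export
binarize_rating <- function(rating, threshold = 50) {
  assert_ratings(rating, "rating")
  ifelse(rating > threshold, "abnormal", "normal")
}

## Corrected proportion of a count out of n.
## loglinear: (k + 0.5) / (n + 1) applied to every cell (standard practice,
## keeps estimates finite and comparable across cells).
## clamp: k/n, with 0 and 1 replaced by 1/(2n) and 1 - 1/(2n).
corrected_rate <- function(k, n, correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  if (correction == "loglinear") {
    list(rate = (k + 0.5) / (n + 1), applied = rep(TRUE, length(k)))
  } else {
    p <- k / n
    lo <- 1 / (2 * n)
    applied <- p <= 0 | p >= 1
    list(rate = pmin(pmax(p, lo), 1 - lo), applied = applied)
  }
}

#' Hit and false-alarm rates for one grouping of trials
#'
#' Computes P(decision = abnormal | truth = abnormal) and
#' P(decision = abnormal | truth = normal) at the fixed rating threshold,
#' with an extreme-proportion correction so both rates are strictly inside
#' (0, 1) and the z-transforms of [dprime()] and [criterion()] stay finite.
#' The default log-linear correction \eqn{(k + 0.5)/(n + 1)} is applied to
#' every cell; `correction = "clamp"` instead replaces only exact 0 and 1
#' proportions by \eqn{1/(2n)} and \eqn{1 - 1/(2n)}.
#'
#' @param ratings integer ratings in \[0, 100\].
#' @param ground_truth character vector, `"normal"` / `"abnormal"`, aligned
#'   with `ratings`.
#' @param threshold decision threshold (default 50).
#' @param correction `"loglinear"` (default) or `"clamp"`.
#' @return object of class `gist_rates`: list with `hit_rate`, `fa_rate`,
#'   `n_abnormal`, `n_normal`, `correction_applied`.
#' @export
rate_estimate <- function(ratings, ground_truth, threshold = 50,
                          correction = c("loglinear", "clamp")) {
  assert_ratings(ratings)
  if (length(ratings) != length(ground_truth))
    stop_gist("ratings and ground_truth lengths differ")
  abn <- ground_truth == "abnormal"
  n_abn <- sum(abn); n_norm <- sum(!abn)
  if (n_abn == 0 || n_norm == 0)
    stop_gist("grouping must contain both classes (",
              n_abn, " abnormal, ", n_norm, " normal trials)")
  k_hit <- sum(ratings[abn] > threshold)
  k_fa <- sum(ratings[!abn] > threshold)
  h <- corrected_rate(k_hit, n_abn, correction)
  f <- corrected_rate(k_fa, n_norm, correction)
  structure(list(hit_rate = h$rate, fa_rate = f$rate,
                 n_abnormal = n_abn, n_normal = n_norm,
                 correction_applied = h$applied || f$applied),
            class = "gist_rates")
}

rates_args <- function(rates, fa_rate) {
  if (inherits(rates, "gist_rates")) c(rates$hit_rate, rates$fa_rate)
  else c(rates, fa_rate)
}

#' Signal-detection sensitivity d'
#'
#' \eqn{d' = z(\mathrm{hit}) - z(\mathrm{fa})} with \eqn{z} the standard
#' normal quantile. Zero is chance; higher is better discrimination.
#'
#' @param rates a `gist_rates` object from [rate_estimate()], or a hit rate.
#' @param fa_rate false-alarm rate when `rates` is given as a bare hit rate.
#' @return d' (numeric scalar).
#' @export
dprime <- function(rates, fa_rate = NULL) {
  hf <- rates_args(rates, fa_rate)
  if (any(hf <= 0 | hf >= 1))
    stop_gist("rates must be strictly inside (0, 1); apply a correction upstream")
  stats::qnorm(hf[1]) - stats::qnorm(hf[2])
}

#' Signal-detection response bias (criterion)
#'
#' \eqn{c = -(z(\mathrm{hit}) + z(\mathrm{fa})) / 2}. Zero is unbiased;
#' negative is liberal (prone to respond "abnormal"), positive conservative.
#'
#' @inheritParams dprime
#' @return criterion (numeric scalar).
#' @export
criterion <- function(rates, fa_rate = NULL) {
  hf <- rates_args(rates, fa_rate)
  if (any(hf <= 0 | hf >= 1))
    stop_gist("rates must be strictly inside (0, 1); apply a correction upstream")
  -(stats::qnorm(hf[1]) + stats::qnorm(hf[2])) / 2
}

## vectorised d' from counts (internal fast path used by the simulation null)
dprime_from_counts <- function(k_hit, n_abn, k_fa, n_norm) {
  stats::qnorm((k_hit + 0.5) / (n_abn + 1)) -
    stats::qnorm((k_fa + 0.5) / (n_norm + 1))
}

category_group_members <- list(
  obvious = "obvious",
  subtle = "subtle",
  global = c("contralateral", "prior"),
  all_abnormal = abnormal_categories
)

#' Per-participant, per-phase, per-category-group SDT summaries
#'
#' For every participant and phase, computes hit/false-alarm rates, d',
#' criterion, and the empirical sliding-threshold AUC for each requested
#' abnormal category group against that phase's normal trials. Only one
#' normal pool exists per phase, so the false-alarm rate is computed once
#' per phase and shared across category groups. The `global` group pools
#' contralateral and prior mammograms; `all_abnormal` pools every abnormal
#' category. Mammogram-kind trials only (attention and practice excluded).
#'
#' @param trials validated trial data frame.
#' @param threshold decision threshold (default 50).
#' @param groups category groups to summarise.
#' @param correction extreme-proportion correction, see [rate_estimate()].
#' @return data frame with columns `participant_id`, `phase_type`,
#'   `phase_index`, `category_group`, `n_abnormal`, `n_normal`, `hit_rate`,
#'   `fa_rate`, `dprime`, `criterion`, `auc_empirical`.
#' @export
phase_summaries <- function(trials, threshold = 50,
                            groups = c("obvious", "subtle", "global", "all_abnormal"),
                            correction = c("loglinear", "clamp")) {
  validate_trials(trials)
  correction <- match.arg(correction)
  groups <- match.arg(groups, names(category_group_members), several.ok = TRUE)
  mam <- trials[trials$trial_kind == "mammogram", , drop = FALSE]

  rows <- list()
  for (pt in split(mam, mam$participant_id)) {
    key <- interaction(pt$phase_type, pt$phase_index, drop = TRUE)
    for (ph in split(pt, key)) {
      normals <- ph$rating[ph$ground_truth == "normal"]
      for (g in groups) {
        abns <- ph$rating[ph$category %in% category_group_members[[g]]]
        if (!length(abns) || !length(normals))
          stop_gist("participant ", ph$participant_id[1], ", phase ",
                    ph$phase_type[1], " ", ph$phase_index[1], ", group ", g,
                    ": one class absent")
        rr <- rate_estimate(c(normals, abns),
                            rep(c("normal", "abnormal"), c(length(normals), length(abns))),
                            threshold = threshold, correction = correction)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ph$participant_id[1],
          phase_type = ph$phase_type[1],
          phase_index = ph$phase_index[1],
          category_group = g,
          n_abnormal = rr$n_abnormal, n_normal = rr$n_normal,
          hit_rate = rr$hit_rate, fa_rate = rr$fa_rate,
          dprime = dprime(rr), criterion = criterion(rr),
          auc_empirical = empirical_roc(normals, abns)$auc,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
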