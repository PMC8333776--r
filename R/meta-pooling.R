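# Inverse-variance pooling of trial-level risk ratios.
#
# Trials report an RR with a 95% CI; the log-scale standard error is
# reconstructed from the CI width, then pooled by fixed-effect or
# DerSimonian-Laird random-effects inverse-variance weighting.

#' Construct a set of trial effect estimates
#'
#' A `trial_effects` object holds one row per randomized trial: the risk
#' ratio (RR) for cancer mortality and its 95% confidence interval, plus
#' optional informational columns (participant count, dose label).
#'
#' @param study Character vector of study labels.
#' @param rr Risk ratios (dimensionless, strictly positive).
#' @param ci_lower,ci_upper 95% confidence bounds; must satisfy
#'   `0 < ci_lower <= rr <= ci_upper`.
#' @param n Optional participant counts (informational).
#' @param dose Optional dose labels (informational).
#' @return A data frame of class `trial_effects`.
#' @seealso [pool_random_dl()], [keum_trials()]
#' @export
#' @examples
#' trial_effects("VITAL", 0.83, 0.67, 1.02)
trial_effects <- function(study, rr, ci_lower, ci_upper, n = NA_real_, dose = NA_character_) {
  k <- length(study)
  if (k == 0L) stop_invalid("at least one trial is required")
  if (length(rr) != k || length(ci_lower) != k || length(ci_upper) != k) {
    stop_invalid("study, rr, ci_lower and ci_upper must have equal length")
  }
  out <- data.frame(
    study = as.character(study),
    rr = as.numeric(rr),
    ci_lower = as.numeric(ci_lower),
    ci_upper = as.numeric(ci_upper),
    n = rep_len(as.numeric(n), k),
    dose = rep_len(as.character(dose), k),
    stringsAsFactors = FALSE
  )
  validate_trial_effects(out)
  class(out) <- c("trial_effects", "data.frame")
  out
}

validate_trial_effects <- function(x) {
  bad <- !is.finite(x$rr) | !is.finite(x$ci_lower) | !is.finite(x$ci_upper) |
    x$ci_lower <= 0 | x$rr <= 0 | x$ci_upper <= 0 |
    x$ci_lower > x$rr | x$rr > x$ci_upper
  if (any(bad)) {
    stop_invalid(
      "invalid RR/CI (need 0 < ci_lower <= rr <= ci_upper) for trial(s): ",
      paste(x$study[bad], collapse = ", ")
    )
  }
  invisible(x)
}

#' Trial-level cancer mortality effects of daily/bolus vitamin D supplementation
#'
#' The five randomized trials whose cancer-mortality risk ratios feed the
#' pooled effect used by the burden model: Trivedi 2003, Wactawski-Wende
#' 2006, Avenell 2012, Scragg 2018 and Manson 2019 (VITAL).
#'
#' @return A [trial_effects()] object with five rows.
#' @export
#' @examples
#' pool_random_dl(keum_trials())
keum_trials <- function() {
  trial_effects(
    study = c("Trivedi 2003", "Wactawski-Wende 2006", "Avenell 2012",
              "Scragg 2018", "Manson 2019"),
    rr = c(0.86, 0.89, 0.85, 0.99, 0.83),
    ci_lower = c(0.61, 0.77, 0.68, 0.60, 0.67),
    ci_upper = c(1.20, 1.03, 1.06, 1.64, 1.02),
    n = c(2686, 36282, 5292, 5110, 25871),
    dose = c("100 000 IU per 4 months", "400 IU per day", "800 IU per day",
             "100 000 IU per month after bolus", "2000 IU per day")
  )
}

#' Reconstruct the log-scale standard error from a 95% confidence interval
#'
#' Assumes the CI is symmetric on the log scale, the standard situation
#' for a published risk ratio:
#' `se = (ln(ci_upper) - ln(ci_lower)) / (2 * 1.959964)`.
#'
#' @inheritParams trial_effects
#' @param study Optional labels used in error messages.
#' @return Positive numeric vector of log-scale standard errors.
#' @export
#' @examples
#' log_se_from_ci(1, 0.5, 2)   # ln(4) / (2 * 1.96)
log_se_from_ci <- function(rr, ci_lower, ci_upper, study = NULL) {
  if (is.null(study)) study <- paste0("trial ", seq_along(rr))
  bad <- !is.finite(rr) | !is.finite(ci_lower) | !is.finite(ci_upper) |
    ci_lower <= 0 | ci_upper <= 0 | rr <= 0 | ci_lower > rr | rr > ci_upper
  if (any(bad)) {
    stop_invalid("non-positive or inverted CI bounds for: ",
                 paste(study[bad], collapse = ", "))
  }
  (log(ci_upper) - log(ci_lower)) / (2 * z975())
}

new_pooled_effect <- function(log_rr, se_log, tau_squared, q_statistic,
                              method, weights, studies) {
  ci <- log_rr + c(-1, 1) * z975() * se_log
  structure(
    list(
      rr = exp(log_rr),
      ci_lower = exp(ci[1]),
      ci_upper = exp(ci[2]),
      log_rr = log_rr,
      se_log = se_log,
      tau_squared = tau_squared,
      q_statistic = q_statistic,
      method = method,
      weights = stats::setNames(weights / sum(weights), studies),
      k = length(weights)
    ),
    class = "pooled_effect"
  )
}

#' Fixed-effect inverse-variance pooling
#'
#' Pools trial log-RRs with weights `1/se^2`; the pooled standard error is
#' `1/sqrt(sum(w))` and Cochran's Q is computed against the pooled mean.
#'
#' @param trials A [trial_effects()] object (or a data frame with the same
#'   columns); at least one trial.
#' @return A `pooled_effect` list with elements `rr`, `ci_lower`,
#'   `ci_upper`, `log_rr`, `se_log`, `tau_squared` (0 for fixed),
#'   `q_statistic`, `method` and normalized `weights`.
#' @export
pool_fixed <- function(trials) {
  trials <- as_trial_effects(trials)
  y <- log(trials$rr)
  se <- log_se_from_ci(trials$rr, trials$ci_lower, trials$ci_upper, trials$study)
  w <- 1 / se^2
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  new_pooled_effect(mu, 1 / sqrt(sum(w)), 0, q, "fixed", w, trials$study)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Estimates the between-study variance `tau^2` by the method of moments,
#' `tau^2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w`, then re-pools with weights
#' `1/(se^2 + tau^2)`. With `Q` below its degrees of freedom `tau^2` is
#' truncated at zero and the estimate coincides with the fixed-effect one.
#'
#' @param trials A [trial_effects()] object with at least two trials.
#' @return A `pooled_effect` list; see [pool_fixed()].
#' @export
#' @examples
#' pool_random_dl(keum_trials())
pool_random_dl <- function(trials) {
  trials <- as_trial_effects(trials)
  if (nrow(trials) < 2L) stop_invalid("random-effects pooling needs at least 2 trials")
  y <- log(trials$rr)
  se <- log_se_from_ci(trials$rr, trials$ci_lower, trials$ci_upper, trials$study)
  w <- 1 / se^2
  mu_f <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_f)^2)
  k <- length(y)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  new_pooled_effect(mu, 1 / sqrt(sum(ws)), tau2, q, "random", ws, trials$study)
}

as_trial_effects <- function(trials) {
  if (inherits(trials, "trial_effects")) return(trials)
  if (is.data.frame(trials)) {
    need <- c("study", "rr", "ci_lower", "ci_upper")
    if (!all(need %in% names(trials))) {
      stop_invalid("trials must have columns ", paste(need, collapse = ", "))
    }
    if (nrow(trials) == 0L) stop_invalid("at least one trial is required")
    return(trial_effects(trials$study, trials$rr, trials$ci_lower, trials$ci_upper,
                         if ("n" %in% names(trials)) trials$n else NA_real_,
                         if ("dose" %in% names(trials)) trials$dose else NA_character_))
  }
  stop_invalid("trials must be a trial_effects object or data frame")
}

#' Percent mortality reduction implied by a pooled risk ratio
#'
#' Converts a pooled RR and its CI to the percent-reduction scale:
#' point `100 * (1 - rr)`, with the CI bounds swapping roles (the lower RR
#' bound gives the upper reduction bound). Unrounded values are returned;
#' `rounded` carries the nearest-integer presentation values.
#'
#' @param pooled A `pooled_effect` from [pool_fixed()] or [pool_random_dl()].
#' @return A list with `point`, `lower`, `upper` (percent, unrounded) and
#'   `rounded` (named integer vector).
#' @export
#' @examples
#' reduction_percent(pool_random_dl(keum_trials()))
reduction_percent <- function(pooled) {
  if (!inherits(pooled, "pooled_effect")) stop_invalid("pooled must be a pooled_effect")
  point <- 100 * (1 - pooled$rr)
  lower <- 100 * (1 - pooled$ci_upper)
  upper <- 100 * (1 - pooled$ci_lower)
  list(
    point = point, lower = lower, upper = upper,
    rounded = c(point = round_half_away(point),
                lower = round_half_away(lower),
                upper = round_half_away(upper))
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  red <- reduction_percent(x)
  cat(sprintf("Pooled RR (%s effects, k = %d): %.2f (95%% CI %.2f-%.2f)\n",
              x$method, x$k, x$rr, x$ci_lower, x$ci_upper))
  cat(sprintf("Mortality reduction: %d%% (95%% CI %d-%d%%)\n",
              red$rounded[["point"]], red$rounded[["lower"]], red$rounded[["upper"]]))
  cat(sprintf("tau^2 = %.4g, Q = %.4g (df = %d)\n", x$tau_squared, x$q_statistic, x$k - 1L))
  cat("Weights:", paste(sprintf("%s %.1f%%", names(x$weights), 100 * x$weights),
                        collapse = ", "), "\n")
  invisible(x)
}
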