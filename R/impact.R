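# Proportional mortality-reduction impact model: a single relative-risk
# reduction applied uniformly to baseline deaths and YLL.

#' Baseline cancer burden (deaths and YLL) in the population aged 50+
#'
#' @param total_deaths Total cancer deaths at ages 50+.
#' @param total_yll Total years of life lost for those deaths.
#' @return A list of class `baseline_burden`.
#' @seealso [as_baseline_burden()] to derive one from a [compute_yll()] result.
#' @export
baseline_burden <- function(total_deaths, total_yll) {
  check_scalar_number(total_deaths, "total_deaths", nonneg = TRUE)
  check_scalar_number(total_yll, "total_yll", nonneg = TRUE)
  structure(list(total_deaths = total_deaths, total_yll = total_yll),
            class = "baseline_burden")
}

#' @rdname baseline_burden
#' @param yll A `yll_result` from [compute_yll()].
#' @export
as_baseline_burden <- function(yll) {
  stopifnot(inherits(yll, "yll_result"))
  baseline_burden(yll$total_deaths_50plus, yll$total_yll)
}

#' Prevented deaths and YLL under a proportional mortality reduction
#'
#' Multiplies the baseline by the reduction fraction. Unrounded values
#' drive all downstream computation; the `*_rounded` fields apply
#' nearest-integer (half away from zero) presentation rounding.
#'
#' @param baseline A [baseline_burden()].
#' @param reduction Mortality-reduction fraction in `[0, 1]` (e.g. 0.13
#'   for the pooled 13% reduction).
#' @return A list of class `impact_result` with `reduction`,
#'   `prevented_deaths`, `prevented_yll` (unrounded) and
#'   `prevented_deaths_rounded`, `prevented_yll_rounded`.
#' @export
#' @examples
#' prevented_burden(baseline_burden(221862, 2474392), 0.13)
prevented_burden <- function(baseline, reduction) {
  stopifnot(inherits(baseline, "baseline_burden"))
  check_scalar_number(reduction, "reduction")
  if (reduction < 0 || reduction > 1) stop_invalid("reduction must lie in [0, 1]")
  structure(
    list(
      reduction = reduction,
      prevented_deaths = baseline$total_deaths * reduction,
      prevented_yll = baseline$total_yll * reduction,
      prevented_deaths_rounded = round_half_away(baseline$total_deaths * reduction),
      prevented_yll_rounded = round_half_away(baseline$total_yll * reduction)
    ),
    class = "impact_result"
  )
}

#' Rescale an impact result to a different reduction level
#'
#' Scales the unrounded prevented quantities by
#' `new_reduction / base$reduction`; equivalent to calling
#' [prevented_burden()] on the same baseline with the new reduction.
#'
#' @param base An `impact_result` with strictly positive reduction.
#' @param new_reduction New reduction fraction in `[0, 1]`.
#' @return An `impact_result` at `new_reduction`.
#' @export
rescale_impact <- function(base, new_reduction) {
  stopifnot(inherits(base, "impact_result"))
  if (base$reduction <= 0) stop_invalid("base reduction must be > 0 to rescale")
  check_scalar_number(new_reduction, "new_reduction")
  if (new_reduction < 0 || new_reduction > 1) stop_invalid("new_reduction must lie in [0, 1]")
  f <- new_reduction / base$reduction
  structure(
    list(
      reduction = new_reduction,
      prevented_deaths = base$prevented_deaths * f,
      prevented_yll = base$prevented_yll * f,
      prevented_deaths_rounded = round_half_away(base$prevented_deaths * f),
      prevented_yll_rounded = round_half_away(base$prevented_yll * f)
    ),
    class = "impact_result"
  )
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("Impact at %.1f%% mortality reduction: %s prevented deaths, %s prevented YLL\n",
              100 * x$reduction,
              format(x$prevented_deaths_rounded, big.mark = " "),
              format(x$prevented_yll_rounded, big.mark = " ")))
  invisible(x)
}
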