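# Cost/savings accounting: annual supplementation cost versus saved
# end-of-life cancer care costs, and cost per prevented life-year.
# All computation is in exact euros; million-euro conversion and
# rounding happen only in the presentation layer.

#' Annual cost of supplementing a population
#'
#' @param population_size Persons aged 50+ receiving supplementation.
#' @param annual_unit_cost Drug cost in euro per person per year.
#' @return Total cost in euro per year.
#' @export
#' @examples
#' supplementation_cost(36e6, 25)  # 900 million euro
supplementation_cost <- function(population_size, annual_unit_cost) {
  check_scalar_number(population_size, "population_size", positive = TRUE)
  check_scalar_number(annual_unit_cost, "annual_unit_cost", positive = TRUE)
  population_size * annual_unit_cost
}

#' Saved end-of-life cancer care costs
#'
#' @param prevented_deaths Prevented cancer deaths per year (unrounded
#'   values are accepted).
#' @param eol_cost_per_death Average end-of-life cancer care cost in euro
#'   per cancer death.
#' @return Total savings in euro per year.
#' @export
eol_savings <- function(prevented_deaths, eol_cost_per_death) {
  check_scalar_number(prevented_deaths, "prevented_deaths", nonneg = TRUE)
  check_scalar_number(eol_cost_per_death, "eol_cost_per_death", positive = TRUE)
  prevented_deaths * eol_cost_per_death
}

#' Net cost of supplementation
#'
#' @param total_cost,total_savings Euro per year; both non-negative.
#' @return `total_cost - total_savings`; negative values are net savings.
#' @export
net_cost <- function(total_cost, total_savings) {
  check_scalar_number(total_cost, "total_cost", nonneg = TRUE)
  check_scalar_number(total_savings, "total_savings", nonneg = TRUE)
  total_cost - total_savings
}

#' Net cost per prevented year of life lost
#'
#' When savings exceed costs the intervention is cost saving and no
#' ratio is reported: the function returns `NA_real_` as the
#' cost-saving sentinel (rendered as "Cost saving" in tables; see
#' [is_cost_saving()]).
#'
#' @param net_cost Euro per year, signed.
#' @param prevented_yll Prevented years of life lost; must be > 0.
#' @return Euro per prevented YLL, or `NA_real_` when `net_cost < 0`.
#' @export
cost_per_yll <- function(net_cost, prevented_yll) {
  check_scalar_number(net_cost, "net_cost")
  check_scalar_number(prevented_yll, "prevented_yll")
  if (prevented_yll <= 0) stop_invalid("prevented_yll must be strictly positive")
  if (net_cost < 0) return(NA_real_)
  net_cost / prevented_yll
}

#' Is a net cost a net saving?
#'
#' @param net_cost Euro per year, signed.
#' @return `TRUE` iff `net_cost < 0`.
#' @export
is_cost_saving <- function(net_cost) net_cost < 0

#' Supplementation cost per prevented YLL, ignoring savings
#'
#' The conservative cost-effectiveness ratio that credits no savings from
#' avoided end-of-life care: gross supplementation cost divided by
#' prevented YLL.
#'
#' @param total_cost Euro per year, non-negative.
#' @param prevented_yll Prevented years of life lost; must be > 0.
#' @return Euro per prevented YLL (always >= 0).
#' @export
#' @examples
#' cost_per_yll_no_savings(900e6, 321671)  # ~2798
cost_per_yll_no_savings <- function(total_cost, prevented_yll) {
  check_scalar_number(total_cost, "total_cost", nonneg = TRUE)
  check_scalar_number(prevented_yll, "prevented_yll")
  if (prevented_yll <= 0) stop_invalid("prevented_yll must be strictly positive")
  total_cost / prevented_yll
}

#' Full cost accounting for one supplementation scenario
#'
#' Composes [supplementation_cost()], [eol_savings()], [net_cost()] and
#' the two cost-effectiveness ratios.
#'
#' @param population_size Persons aged 50+.
#' @param annual_unit_cost Euro per person per year.
#' @param eol_cost_per_death Euro per cancer death, or `NA` to skip the
#'   savings side entirely (no-savings accounting).
#' @param prevented_deaths,prevented_yll Unrounded prevented quantities.
#' @return A list of class `cost_result` with `total_cost`,
#'   `total_savings`, `net_cost`, `cost_saving`, `cost_per_yll`
#'   (`NA` when cost saving) and `cost_per_yll_no_savings`, all in exact
#'   euros per year.
#' @export
cost_result <- function(population_size, annual_unit_cost, eol_cost_per_death,
                        prevented_deaths, prevented_yll) {
  total_cost <- supplementation_cost(population_size, annual_unit_cost)
  savings <- if (is.na(eol_cost_per_death)) 0 else {
    eol_savings(prevented_deaths, eol_cost_per_death)
  }
  net <- net_cost(total_cost, savings)
  structure(
    list(
      total_cost = total_cost,
      total_savings = savings,
      net_cost = net,
      cost_saving = is_cost_saving(net),
      cost_per_yll = cost_per_yll(net, prevented_yll),
      cost_per_yll_no_savings = cost_per_yll_no_savings(total_cost, prevented_yll)
    ),
    class = "cost_result"
  )
}

#' @export
print.cost_result <- function(x, ...) {
  mln <- function(v) sprintf("%.0f million euro", round_half_away(v / 1e6))
  cat("Total cost:   ", mln(x$total_cost), "per year\n")
  cat("Total savings:", mln(x$total_savings), "per year\n")
  if (x$cost_saving) {
    cat("Net:           cost saving,", mln(-x$net_cost), "saved per year\n")
  } else {
    cat("Net cost:     ", mln(x$net_cost), "per year\n")
    cat(sprintf("Euro per prevented YLL: %.0f\n", round_half_away(x$cost_per_yll)))
  }
  cat(sprintf("Euro per prevented YLL (no savings): %.0f\n",
              round_half_away(x$cost_per_yll_no_savings)))
  invisible(x)
}
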