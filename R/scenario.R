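# Deterministic sensitivity-scenario grid: base case plus variations of
# effect size, daily dose (and its cost), and end-of-life care costs.

#' German population aged 50+ used for the cost side
#'
#' 16.8 million men plus 19.2 million women (2016).
#'
#' @return Number of persons.
#' @export
default_population_50plus <- function() 16.8e6 + 19.2e6

#' Define a supplementation scenario
#'
#' @param label Scenario name.
#' @param reduction Cancer-mortality reduction fraction in `(0, 1]`.
#' @param annual_unit_cost Euro per person per year (> 0).
#' @param eol_cost_per_death Euro per cancer death, or `NA` for
#'   no-savings accounting.
#' @param dose_label Informational dose description; the mapping from
#'   dose to (reduction, cost) is an assumption, not a model.
#' @return A list of class `scenario`.
#' @export
scenario <- function(label, reduction, annual_unit_cost,
                     eol_cost_per_death = NA_real_, dose_label = NA_character_) {
  check_scalar_number(reduction, "reduction")
  if (reduction <= 0 || reduction > 1) stop_invalid("reduction must lie in (0, 1]")
  check_scalar_number(annual_unit_cost, "annual_unit_cost", positive = TRUE)
  if (!is.na(eol_cost_per_death)) {
    check_scalar_number(eol_cost_per_death, "eol_cost_per_death", positive = TRUE)
  }
  structure(
    list(label = as.character(label), reduction = reduction,
         annual_unit_cost = annual_unit_cost,
         eol_cost_per_death = as.numeric(eol_cost_per_death),
         dose_label = as.character(dose_label)),
    class = "scenario"
  )
}

#' Built-in sensitivity scenarios
#'
#' The seven with-savings scenarios: base case (13% reduction, 25
#' euro/year, 40 000 euro saved per prevented death); stronger/weaker
#' effect at the pooled CI bounds (21%, 4%); 400 IU per day (11%, 10
#' euro/year) and 2000 IU per day (17%, 50 euro/year); lower/higher
#' end-of-life care costs (20 000 / 60 000 euro). The five no-savings
#' scenarios are the first five with the savings side dropped.
#'
#' @param mode `"with_savings"` (7 scenarios) or `"no_savings"` (5).
#' @return A list of [scenario()] objects.
#' @export
builtin_scenarios <- function(mode = c("with_savings", "no_savings")) {
  mode <- match.arg(mode)
  core <- list(
    scenario("Base case", 0.13, 25, 40000, "1000 IU per day"),
    scenario("Stronger effect", 0.21, 25, 40000, "1000 IU per day"),
    scenario("Weaker effect", 0.04, 25, 40000, "1000 IU per day"),
    scenario("400 IU per day", 0.11, 10, 40000, "400 IU per day"),
    scenario("2000 IU per day", 0.17, 50, 40000, "2000 IU per day")
  )
  if (mode == "no_savings") {
    return(lapply(core, function(s) { s$eol_cost_per_death <- NA_real_; s }))
  }
  c(core, list(
    scenario("Lower end-of-life cancer care costs", 0.13, 25, 20000, "1000 IU per day"),
    scenario("Higher end-of-life cancer care costs", 0.13, 25, 60000, "1000 IU per day")
  ))
}

#' Run one scenario end-to-end
#'
#' Applies the scenario's mortality reduction to the baseline burden,
#' then the cost accounting with the scenario's unit and end-of-life
#' costs.
#'
#' @param scn A [scenario()].
#' @param baseline A [baseline_burden()].
#' @param population_size Persons aged 50+ paying supplementation costs
#'   (default [default_population_50plus()]).
#' @return A list of class `scenario_result` with elements `scenario`,
#'   `impact` ([prevented_burden()] result) and `costs` ([cost_result()]).
#' @export
#' @examples
#' run_scenario(builtin_scenarios()[[1]], baseline_burden(221862, 2474392))
run_scenario <- function(scn, baseline, population_size = default_population_50plus()) {
  stopifnot(inherits(scn, "scenario"), inherits(baseline, "baseline_burden"))
  impact <- prevented_burden(baseline, scn$reduction)
  costs <- cost_result(population_size, scn$annual_unit_cost,
                       scn$eol_cost_per_death,
                       impact$prevented_deaths, impact$prevented_yll)
  structure(list(scenario = scn, impact = impact, costs = costs),
            class = "scenario_result")
}

#' Run a list of scenarios against one baseline
#'
#' @param scenarios List of [scenario()] objects (default: built-ins).
#' @inheritParams run_scenario
#' @return List of `scenario_result` objects.
#' @export
run_scenarios <- function(scenarios = builtin_scenarios(), baseline,
                          population_size = default_population_50plus()) {
  lapply(scenarios, run_scenario, baseline = baseline,
         population_size = population_size)
}

fmt_million <- function(eur, signed = FALSE) {
  m <- round_half_away(eur / 1e6)
  if (signed) sprintf("%+d", as.integer(m)) else sprintf("%d", as.integer(m))
}

#' Render scenario results as a publication-style table
#'
#' Money columns are in million euro rounded to the nearest integer (net
#' costs carry an explicit sign); prevented counts are rounded to the
#' nearest integer; euro per prevented YLL is rounded to the nearest
#' euro, with a net saving rendered as `"Cost saving"`.
#'
#' @param results List of `scenario_result` objects.
#' @param mode `"with_savings"` renders the full accounting;
#'   `"no_savings"` omits the savings and net-cost columns and reports
#'   the gross cost-effectiveness ratio.
#' @return A character data frame, one row per scenario.
#' @export
render_table <- function(results, mode = c("with_savings", "no_savings")) {
  mode <- match.arg(mode)
  if (length(results) == 0L) stop_invalid("results must be non-empty")
  rows <- lapply(results, function(r) {
    scn <- r$scenario; imp <- r$impact; cst <- r$costs
    base <- data.frame(
      scenario = scn$label,
      supplementation_cost_per_person = sprintf("%.0f€ per year", scn$annual_unit_cost),
      stringsAsFactors = FALSE
    )
    if (mode == "with_savings") {
      ratio <- if (cst$cost_saving) "Cost saving" else {
        sprintf("%d", as.integer(round_half_away(cst$cost_per_yll)))
      }
      cbind(base, data.frame(
        eol_cost_per_death = sprintf("%.0f€", scn$eol_cost_per_death),
        mortality_reduction = sprintf("%d%%", as.integer(round_half_away(100 * scn$reduction))),
        total_costs_million = fmt_million(cst$total_cost),
        total_savings_million = fmt_million(cst$total_savings),
        total_net_costs_million = fmt_million(cst$net_cost, signed = TRUE),
        prevented_deaths = sprintf("%d", as.integer(imp$prevented_deaths_rounded)),
        prevented_yll = sprintf("%d", as.integer(imp$prevented_yll_rounded)),
        eur_per_prevented_yll = ratio,
        stringsAsFactors = FALSE
      ))
    } else {
      cbind(base, data.frame(
        mortality_reduction = sprintf("%d%%", as.integer(round_half_away(100 * scn$reduction))),
        total_costs_million = fmt_million(cst$total_cost),
        prevented_deaths = sprintf("%d", as.integer(imp$prevented_deaths_rounded)),
        prevented_yll = sprintf("%d", as.integer(imp$prevented_yll_rounded)),
        eur_per_prevented_yll = sprintf("%d", as.integer(round_half_away(cst$cost_per_yll_no_savings))),
        stringsAsFactors = FALSE
      ))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$scenario$label, "\n")
  print(x$impact)
  print(x$costs)
  invisible(x)
}
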