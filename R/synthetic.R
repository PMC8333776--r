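# Synthetic age/sex-stratified cancer mortality and life tables.
#
# Stand-in generator for the (undeposited) national input tables: death
# counts follow a Gompertz-shaped age-at-death profile over 5-year groups
# from age 50, life expectancy decays smoothly with age, and a
# two-stage calibration rescales the counts so the downstream pipeline
# reproduces stated aggregate totals. All outputs are synthetic and are
# documented as such.

#' Configuration for the synthetic table generator
#'
#' Defaults emulate the structure of German 2016 cancer mortality and
#' the 2016/2018 period life table: 5-year age groups 50-54 ... 80-84
#' plus 85+, a male share of cancer deaths of 0.53, a Gompertz-like
#' age-at-death profile with modal age 77 and dispersion 10 years, and
#' further life expectancy anchored at 28 (men) / 32 (women) years at
#' age 52 with exponential decay 0.049 per year. Calibration targets
#' default to the base-case totals implied by a 13% preventable
#' fraction: 221 862 deaths and 2 474 392 YLL.
#'
#' @param seed Integer seed fixing all randomness.
#' @param age_lower Lower bounds of the 5-year groups; the last group is
#'   open-ended.
#' @param sex_death_share Fraction of cancer deaths that are male.
#' @param gompertz_modal_age Modal age at death (years).
#' @param gompertz_dispersion Dispersion of the age-at-death profile (years).
#' @param noise_sdlog Log-sd of the multiplicative lognormal noise on
#'   stratum counts (small, keeps strata positive).
#' @param nominal_total_deaths Pre-calibration total death count.
#' @param calibration List with `target_total_deaths` and
#'   `target_total_yll` (either may be `NA` to skip that constraint), or
#'   `NULL` for no calibration.
#' @param expectancy_anchor List with `male_at_52`, `female_at_52`
#'   (further life expectancy in years at age 52) and `decay_rate`
#'   (exponential decay per year of age).
#' @param age_range Integer range of single-year ages in the life table.
#' @param reference_year Calendar year label for the mortality table.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             age_lower = seq(50L, 85L, by = 5L),
                             sex_death_share = 0.53,
                             gompertz_modal_age = 77,
                             gompertz_dispersion = 10,
                             noise_sdlog = 0.02,
                             nominal_total_deaths = 250000,
                             calibration = list(target_total_deaths = 221862,
                                                target_total_yll = 2474392),
                             expectancy_anchor = list(male_at_52 = 28,
                                                      female_at_52 = 32,
                                                      decay_rate = 0.049),
                             age_range = c(50L, 99L),
                             reference_year = 2016L) {
  check_scalar_number(sex_death_share, "sex_death_share")
  if (sex_death_share <= 0 || sex_death_share >= 1) {
    stop_invalid("sex_death_share must lie in (0, 1)")
  }
  check_scalar_number(gompertz_modal_age, "gompertz_modal_age", positive = TRUE)
  check_scalar_number(gompertz_dispersion, "gompertz_dispersion", positive = TRUE)
  check_scalar_number(nominal_total_deaths, "nominal_total_deaths", positive = TRUE)
  if (!is.null(calibration)) {
    for (f in c("target_total_deaths", "target_total_yll")) {
      v <- calibration[[f]]
      if (!is.null(v) && !is.na(v)) check_scalar_number(v, f, positive = TRUE)
    }
  }
  structure(
    list(seed = as.integer(seed), age_lower = as.integer(age_lower),
         sex_death_share = sex_death_share,
         gompertz_modal_age = gompertz_modal_age,
         gompertz_dispersion = gompertz_dispersion,
         noise_sdlog = noise_sdlog,
         nominal_total_deaths = nominal_total_deaths,
         calibration = calibration,
         expectancy_anchor = expectancy_anchor,
         age_range = as.integer(age_range),
         reference_year = as.integer(reference_year)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic further-life-expectancy table
#'
#' For each sex, expectancy at age `a` is
#' `anchor * exp(-decay_rate * (a - 52))`: strictly decreasing in age,
#' equal to the anchors at age 52 exactly, and female >= male at every
#' age whenever the female anchor is at least the male one.
#'
#' @param config A [synthetic_config()].
#' @return A [life_table()] covering both sexes over `config$age_range`.
#' @export
generate_life_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  an <- config$expectancy_anchor
  if (an$female_at_52 < an$male_at_52) {
    stop_invalid("invalid expectancy anchors: female_at_52 must be >= male_at_52")
  }
  ages <- seq(config$age_range[1], config$age_range[2])
  life_table(
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, 2L),
    expectancy = c(an$male_at_52 * exp(-an$decay_rate * (ages - 52)),
                   an$female_at_52 * exp(-an$decay_rate * (ages - 52)))
  )
}

# Gompertz-type age-at-death density (Gumbel shape): mode at modal_age.
gompertz_weight <- function(age, modal_age, dispersion) {
  z <- (age - modal_age) / dispersion
  exp(z - exp(z))
}

#' Generate a synthetic age/sex mortality table
#'
#' Stratum counts follow the discretized Gompertz-shaped age profile
#' evaluated at interval midpoints, split between the sexes by
#' `sex_death_share`, perturbed by seeded multiplicative lognormal
#' noise, and rounded to integers. Deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @return A [mortality_table()] (uncalibrated).
#' @export
generate_mortality_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  al <- config$age_lower
  k <- length(al)
  au <- c(al[-k] + 4L, NA_integer_)   # final group open-ended
  mid <- interval_midpoint(al, au)
  w <- gompertz_weight(mid, config$gompertz_modal_age, config$gompertz_dispersion)
  set.seed(config$seed)
  noise <- matrix(stats::rlnorm(2L * k, 0, config$noise_sdlog), nrow = k)
  share <- c(config$sex_death_share, 1 - config$sex_death_share)
  counts <- sweep(w * noise, 2L, share, `*`)
  counts <- counts / sum(counts) * config$nominal_total_deaths
  mortality_table(
    sex = rep(c("male", "female"), each = k),
    age_lower = rep(al, 2L),
    age_upper = rep(au, 2L),
    deaths = pmax(0L, as.integer(round(c(counts[, 1], counts[, 2])))),
    reference_year = config$reference_year
  )
}

# Largest-remainder rounding of non-negative reals to integers with an
# exact target sum.
round_to_sum <- function(x, target) {
  fl <- floor(x)
  r <- as.integer(round(target - sum(fl)))
  if (r > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(r)]
    fl[idx] <- fl[idx] + 1
  } else if (r < 0) {
    idx <- order(x - fl)[seq_len(min(-r, sum(fl > 0)))]
    fl[idx] <- pmax(0, fl[idx] - 1)
  }
  as.integer(fl)
}

#' Calibrate a mortality table to target totals
#'
#' Rescales death counts so that the table's total deaths hit
#' `target_total_deaths` and the pipeline's total YLL hits
#' `target_total_yll`. Two stages: (1) an exponential age-tilt
#' `d_i -> d_i * exp(theta * midpoint_i)` whose parameter is solved so
#' the YLL-per-death ratio matches the target ratio, followed by a
#' global scale and largest-remainder integer rounding that hits the
#' deaths target exactly; (2) greedy single-death transfers between
#' strata (deaths total fixed) that shrink the remaining YLL residual
#' below the granularity of the expectancy differences. With a deaths
#' target only, stage (1) reduces to a global scale factor.
#'
#' @param table A [mortality_table()] (age 50+ strata).
#' @param life_tables A [life_table()] resolving every stratum midpoint.
#' @param targets List with `target_total_deaths` and `target_total_yll`
#'   (`NA` to leave the YLL side unconstrained).
#' @param open_ended_offset Midpoint offset for the open-ended group.
#' @param tol_deaths Guaranteed absolute tolerance on total deaths.
#' @param tol_yll_rel Guaranteed relative tolerance on total YLL.
#' @param max_transfers Cap on stage-2 unit transfers.
#' @return The calibrated `mortality_table`.
#' @export
calibrate_to_totals <- function(table, life_tables, targets,
                                open_ended_offset = 2L,
                                tol_deaths = 2, tol_yll_rel = 0.002,
                                max_transfers = 5000L) {
  stopifnot(inherits(table, "mortality_table"))
  td <- targets$target_total_deaths
  ty <- targets$target_total_yll
  if (is.null(td) || is.na(td)) stop_invalid("target_total_deaths is required")
  d <- as.numeric(table$deaths)
  if (sum(d) <= 0) stop_invalid("table has no deaths to calibrate")
  mid <- interval_midpoint(table$age_lower, table$age_upper, open_ended_offset)
  e <- vapply(seq_len(nrow(table)),
              function(i) lookup_expectancy(life_tables, table$sex[i], mid[i]),
              numeric(1))

  if (!is.null(ty) && !is.na(ty)) {
    ratio_target <- ty / td
    if (ratio_target <= min(e) || ratio_target >= max(e)) {
      stop_invalid("target YLL/deaths ratio ", signif(ratio_target, 6),
                   " outside achievable range (", signif(min(e), 4), ", ",
                   signif(max(e), 4), ")")
    }
    ratio_at <- function(theta) {
      w <- d * exp(theta * (mid - mean(mid)))
      sum(w * e) / sum(w)
    }
    lo <- -1; hi <- 1
    while (ratio_at(lo) < ratio_target && lo > -64) lo <- lo * 2
    while (ratio_at(hi) > ratio_target && hi < 64) hi <- hi * 2
    theta <- stats::uniroot(function(t) ratio_at(t) - ratio_target,
                            lower = lo, upper = hi, tol = 1e-12)$root
    d <- d * exp(theta * (mid - mean(mid)))
  }
  d <- d / sum(d) * td
  n <- round_to_sum(d, td)

  if (!is.null(ty) && !is.na(ty)) {
    resid <- ty - sum(n * e)
    transfers <- 0L
    repeat {
      if (transfers >= max_transfers) break
      src <- which(n >= 1L)
      # delta of moving one death from stratum i to stratum j: e[j] - e[i]
      delta <- outer(e[src], e, function(ei, ej) ej - ei)
      best <- which.min(abs(resid - delta))
      step <- delta[best]
      if (abs(resid - step) >= abs(resid) - 1e-12) break
      i <- src[(best - 1L) %% length(src) + 1L]
      j <- (best - 1L) %/% length(src) + 1L
      n[i] <- n[i] - 1L
      n[j] <- n[j] + 1L
      resid <- resid - step
      transfers <- transfers + 1L
    }
    if (abs(ty - sum(n * e)) / ty > tol_yll_rel) {
      stop(errorCondition(
        paste0("calibration failed to converge: YLL residual ",
               signif(ty - sum(n * e), 6), " (relative ",
               signif(abs(ty - sum(n * e)) / ty, 3), ") exceeds tolerance"),
        class = c("preventyll_calibration_error", "error")
      ))
    }
  }
  if (abs(sum(n) - td) > tol_deaths) {
    stop(errorCondition(
      paste0("calibration failed: deaths residual ", sum(n) - td),
      class = c("preventyll_calibration_error", "error")
    ))
  }
  mortality_table(table$sex, table$age_lower, table$age_upper, n,
                  reference_year = attr(table, "reference_year"))
}

#' Generate the full synthetic input set
#'
#' Convenience wrapper: builds the life table, the raw mortality table,
#' and (when `config$calibration` is set) the calibrated mortality
#' table.
#'
#' @param config A [synthetic_config()].
#' @return List with `life_table` and `mortality` (calibrated when
#'   calibration targets are configured).
#' @export
#' @examples
#' tabs <- synthetic_s1_tables(synthetic_config(seed = 42))
#' compute_yll(tabs$mortality, tabs$life_table)$total_deaths_50plus
synthetic_s1_tables <- function(config = synthetic_config()) {
  lt <- generate_life_table(config)
  mt <- generate_mortality_table(config)
  if (!is.null(config$calibration)) {
    mt <- calibrate_to_totals(mt, lt, config$calibration)
  }
  list(life_table = lt, mortality = mt)
}
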