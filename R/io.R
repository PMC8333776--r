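# CSV and config-file IO.
#
# Dialects (headers required, UTF-8, "." decimal separator; values from
# German sources using "," decimals must be converted before reading):
#   mortality:  sex,age_lower,age_upper,deaths   (age_upper empty or "+"
#               marks the open-ended final group)
#   life table: sex,age,expectancy
#   trials:     study,rr,ci_lower,ci_upper[,n,dose]

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_invalid(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (nrow(df) == 0L) stop_invalid(what, " file is empty: ", path)
  if (!all(required %in% names(df))) {
    stop_invalid(what, " file ", path, " must have header columns: ",
                 paste(required, collapse = ","))
  }
  df
}

num_field <- function(x, col, path, integer = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x == ""))
  bad <- union(bad, which(is.na(v)))
  if (length(bad)) {
    stop_invalid("malformed value in column '", col, "' of ", path,
                 " at line ", bad[1] + 1L)   # +1 for header line
  }
  if (integer && any(abs(v - round(v)) > 1e-9)) {
    stop_invalid("non-integer value in column '", col, "' of ", path)
  }
  v
}

#' Read an age/sex mortality table from CSV
#'
#' Expects header `sex,age_lower,age_upper,deaths`; an empty or `+`
#' `age_upper` marks the open-ended final group. Rows are validated
#' (non-negative integer deaths, no duplicate or overlapping strata)
#' with line-numbered errors.
#'
#' @param path CSV file path.
#' @param reference_year Calendar year label.
#' @return A [mortality_table()].
#' @export
read_mortality_csv <- function(path, reference_year = 2016L) {
  df <- read_csv_checked(path, c("sex", "age_lower", "age_upper", "deaths"),
                         "mortality")
  upper_raw <- df$age_upper
  open <- is.na(upper_raw) | upper_raw == "" | upper_raw == "+"
  upper <- rep(NA_integer_, nrow(df))
  if (any(!open)) {
    upper[!open] <- as.integer(num_field(upper_raw[!open], "age_upper", path,
                                         integer = TRUE))
  }
  deaths <- num_field(df$deaths, "deaths", path, integer = TRUE)
  neg <- which(deaths < 0)
  if (length(neg)) {
    stop_invalid("negative deaths in ", path, " at line ", neg[1] + 1L)
  }
  mortality_table(df$sex, num_field(df$age_lower, "age_lower", path, integer = TRUE),
                  upper, deaths, reference_year = reference_year)
}

#' Write a mortality table to CSV
#'
#' Inverse of [read_mortality_csv()]; the open-ended group is written
#' with `+` in `age_upper`.
#'
#' @param table A [mortality_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mortality_csv <- function(table, path) {
  stopifnot(inherits(table, "mortality_table"))
  out <- data.frame(
    sex = table$sex,
    age_lower = table$age_lower,
    age_upper = ifelse(is.na(table$age_upper), "+", as.character(table$age_upper)),
    deaths = table$deaths,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a further-life-expectancy table from CSV
#'
#' Expects header `sex,age,expectancy`. Non-monotone entries within a
#' sex produce a warning (values are kept); a missing sex or empty file
#' is an error.
#'
#' @param path CSV file path.
#' @return A [life_table()].
#' @export
read_lifetable_csv <- function(path) {
  df <- read_csv_checked(path, c("sex", "age", "expectancy"), "life-table")
  lt <- life_table(df$sex, num_field(df$age, "age", path, integer = TRUE),
                   num_field(df$expectancy, "expectancy", path))
  missing <- setdiff(c("male", "female"), unique(lt$sex))
  if (length(missing)) {
    stop_invalid("life-table file ", path, " is missing sex: ",
                 paste(missing, collapse = ", "))
  }
  lt
}

#' Write a life table to CSV
#'
#' @param life_tables A [life_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetable_csv <- function(life_tables, path) {
  stopifnot(inherits(life_tables, "life_table"))
  utils::write.csv(as.data.frame(life_tables), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read trial RR/CI records from CSV
#'
#' Expects header `study,rr,ci_lower,ci_upper` with optional `n` and
#' `dose` columns. A packaged copy of the five cancer-mortality trials
#' ships at `system.file("extdata", "keum2019_trials.csv",
#' package = "preventyll")`.
#'
#' @param path CSV file path.
#' @return A [trial_effects()] object.
#' @export
read_trials_csv <- function(path) {
  df <- read_csv_checked(path, c("study", "rr", "ci_lower", "ci_upper"), "trials")
  trial_effects(
    df$study,
    num_field(df$rr, "rr", path),
    num_field(df$ci_lower, "ci_lower", path),
    num_field(df$ci_upper, "ci_upper", path),
    n = if ("n" %in% names(df)) suppressWarnings(as.numeric(df$n)) else NA_real_,
    dose = if ("dose" %in% names(df)) df$dose else NA_character_
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `baseline` (either `deaths_total` + `yll_total`, or
#' `deaths_csv` + `lifetable_csv`), `population_size`, and optionally
#' `scenarios` (`"builtin"`, the default, or a list of scenario maps
#' with `label`, `reduction`, `annual_unit_cost`, `eol_cost_per_death`).
#' Exactly one baseline source must be given.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with `baseline`
#'   (a [baseline_burden()]), `population_size` and `scenarios`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  b <- cfg$baseline
  if (is.null(b)) stop_invalid("config must contain a 'baseline' block")
  inline <- !is.null(b$deaths_total) && !is.null(b$yll_total)
  from_csv <- !is.null(b$deaths_csv) && !is.null(b$lifetable_csv)
  if (inline == from_csv) {
    stop_invalid("baseline must specify exactly one source: ",
                 "deaths_total/yll_total or deaths_csv/lifetable_csv")
  }
  baseline <- if (inline) {
    baseline_burden(b$deaths_total, b$yll_total)
  } else {
    mt <- read_mortality_csv(b$deaths_csv)
    lt <- read_lifetable_csv(b$lifetable_csv)
    as_baseline_burden(compute_yll(mt, lt))
  }
  pop <- if (is.null(cfg$population_size)) default_population_50plus() else cfg$population_size
  scenarios <- if (is.null(cfg$scenarios) || identical(cfg$scenarios, "builtin")) {
    builtin_scenarios()
  } else {
    lapply(cfg$scenarios, function(s) {
      scenario(s$label, s$reduction, s$annual_unit_cost,
               if (is.null(s$eol_cost_per_death)) NA_real_ else s$eol_cost_per_death,
               if (is.null(s$dose_label)) NA_character_ else s$dose_label)
    })
  }
  structure(list(baseline = baseline, population_size = pop, scenarios = scenarios),
            class = "run_config")
}
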