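# Years of life lost (YLL) from an age/sex-stratified deaths table and a
# period life table, using the age-interval midpoint rule: each stratum
# contributes deaths * further life expectancy at the interval midpoint
# (e.g. age 52 for the group 50-54).

#' Construct an age/sex-stratified mortality table
#'
#' One row per (sex, age interval) stratum with an integer death count.
#' Age intervals use inclusive integer bounds: "50-54" means ages 50
#' through 54. The final group may be open-ended (`age_upper = NA`,
#' written as `+` in CSV files).
#'
#' @param sex Character vector, `"male"` or `"female"`.
#' @param age_lower Integer lower bounds (inclusive), `>= 0`.
#' @param age_upper Integer upper bounds (inclusive) or `NA` for an
#'   open-ended final group.
#' @param deaths Non-negative integer death counts.
#' @param reference_year Calendar year the counts refer to.
#' @return A data frame of class `mortality_table` with attribute
#'   `reference_year`.
#' @export
#' @examples
#' mortality_table(c("male", "female"), c(50, 50), c(54, 54), c(1200, 900))
mortality_table <- function(sex, age_lower, age_upper, deaths, reference_year = 2016L) {
  n <- length(sex)
  if (!(length(age_lower) == n && length(age_upper) == n && length(deaths) == n)) {
    stop_invalid("sex, age_lower, age_upper and deaths must have equal length")
  }
  out <- data.frame(
    sex = as.character(sex),
    age_lower = as.integer(age_lower),
    age_upper = as.integer(age_upper),
    deaths = as.numeric(deaths),
    stringsAsFactors = FALSE
  )
  validate_mortality_table(out)
  out$deaths <- as.integer(round(out$deaths))
  attr(out, "reference_year") <- as.integer(reference_year)
  class(out) <- c("mortality_table", "data.frame")
  out
}

validate_mortality_table <- function(x) {
  if (any(!x$sex %in% c("male", "female"))) {
    stop_invalid("sex must be 'male' or 'female'")
  }
  if (any(is.na(x$age_lower) | x$age_lower < 0)) {
    stop_invalid("age_lower must be a non-negative integer")
  }
  closed <- !is.na(x$age_upper)
  if (any(closed & x$age_upper < x$age_lower)) {
    stop_invalid("age_upper must be >= age_lower for closed intervals")
  }
  if (any(!is.finite(x$deaths) | x$deaths < 0 | abs(x$deaths - round(x$deaths)) > 1e-8)) {
    stop_invalid("deaths must be non-negative integers")
  }
  key <- paste(x$sex, x$age_lower, ifelse(is.na(x$age_upper), "+", x$age_upper))
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (sex, age interval) strata: ",
                 paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  # non-overlap within sex: treat open-ended upper as +Inf
  for (s in unique(x$sex)) {
    xs <- x[x$sex == s, , drop = FALSE]
    xs <- xs[order(xs$age_lower), , drop = FALSE]
    up <- ifelse(is.na(xs$age_upper), Inf, xs$age_upper)
    if (nrow(xs) > 1L && any(xs$age_lower[-1L] <= up[-nrow(xs)])) {
      stop_invalid("overlapping age intervals within sex '", s, "'")
    }
  }
  invisible(x)
}

#' Construct a further-life-expectancy table
#'
#' Single-year-of-age period life table: for each sex and exact age, the
#' expected remaining years of life. Values must be positive; within a
#' sex they should be non-increasing in age (violations are reported as a
#' warning, since published tables occasionally contain small inversions).
#'
#' @param sex Character vector, `"male"` or `"female"`.
#' @param age Integer ages in years.
#' @param expectancy Further life expectancy in years (> 0).
#' @return A data frame of class `life_table`.
#' @export
life_table <- function(sex, age, expectancy) {
  n <- length(sex)
  if (length(age) != n || length(expectancy) != n) {
    stop_invalid("sex, age and expectancy must have equal length")
  }
  out <- data.frame(
    sex = as.character(sex),
    age = as.integer(age),
    expectancy = as.numeric(expectancy),
    stringsAsFactors = FALSE
  )
  if (any(!out$sex %in% c("male", "female"))) stop_invalid("sex must be 'male' or 'female'")
  if (any(!is.finite(out$expectancy) | out$expectancy <= 0)) {
    stop_invalid("expectancy values must be positive")
  }
  if (anyDuplicated(paste(out$sex, out$age))) {
    stop_invalid("duplicate (sex, age) life-table entries")
  }
  for (s in unique(out$sex)) {
    e <- out$expectancy[out$sex == s][order(out$age[out$sex == s])]
    if (any(diff(e) > 0)) {
      warning("life table for sex '", s, "' is not non-increasing in age",
              call. = FALSE)
    }
  }
  class(out) <- c("life_table", "data.frame")
  out
}

#' Midpoint age of a 5-year or open-ended age interval
#'
#' A closed 5-year interval `[a, a+4]` has midpoint `a + 2` (age 52 for
#' 50-54); a general closed interval uses the integer floor of its
#' midpoint. An open-ended interval `[a, Inf)` uses `a + open_ended_offset`.
#'
#' @param age_lower,age_upper Integer bounds; `age_upper = NA` marks an
#'   open-ended interval.
#' @param open_ended_offset Years added to the lower bound of an
#'   open-ended group (default 2, the same rule as a 5-year group).
#' @return Integer midpoint ages.
#' @export
#' @examples
#' interval_midpoint(50, 54)  # 52
#' interval_midpoint(85, NA)  # 87
interval_midpoint <- function(age_lower, age_upper, open_ended_offset = 2L) {
  if (any(is.na(age_lower) | age_lower < 0)) stop_invalid("malformed interval: bad age_lower")
  closed <- !is.na(age_upper)
  if (any(closed & age_upper < age_lower)) stop_invalid("malformed interval: age_upper < age_lower")
  out <- integer(length(age_lower))
  out[closed] <- (age_lower[closed] + age_upper[closed]) %/% 2L
  out[!closed] <- age_lower[!closed] + as.integer(open_ended_offset)
  out
}

#' Restrict a mortality table to ages 50 and above
#'
#' Keeps only strata whose interval lower bound is at least `min_age`.
#' Idempotent.
#'
#' @param table A [mortality_table()].
#' @param min_age Minimum interval lower bound (default 50).
#' @return The filtered `mortality_table`.
#' @export
restrict_age50plus <- function(table, min_age = 50L) {
  stopifnot(inherits(table, "mortality_table"))
  out <- table[table$age_lower >= min_age, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_year") <- attr(table, "reference_year")
  class(out) <- class(table)
  out
}

#' Look up further life expectancy for a sex and exact age
#'
#' Returns the tabulated value when present. With `interpolate = TRUE` a
#' non-tabulated age strictly inside the table range is linearly
#' interpolated between the flanking tabulated ages. Ages outside the
#' table range are an error.
#'
#' @param life_tables A [life_table()].
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (may be fractional when interpolating).
#' @param interpolate Allow linear interpolation between tabulated ages.
#' @return Further life expectancy in years.
#' @export
lookup_expectancy <- function(life_tables, sex, age, interpolate = FALSE) {
  stopifnot(inherits(life_tables, "life_table"))
  lt <- life_tables[life_tables$sex == sex, , drop = FALSE]
  if (nrow(lt) == 0L) stop_lookup("no life table for sex '", sex, "'")
  hit <- lt$age == age
  if (any(hit)) return(lt$expectancy[hit][1L])
  if (age < min(lt$age) || age > max(lt$age)) {
    stop_lookup("age ", age, " outside life-table range [", min(lt$age), ", ",
                max(lt$age), "] for sex '", sex, "'")
  }
  if (!interpolate) {
    stop_lookup("no life-table entry at age ", age, " for sex '", sex,
                "' (interpolation disabled)")
  }
  stats::approx(lt$age, lt$expectancy, xout = age)$y
}

#' Years of life lost from a mortality table and life table
#'
#' Each stratum of age `>= min_age` contributes
#' `deaths * expectancy(sex, midpoint age)`; totals are summed over all
#' strata and both sexes. Strata below `min_age` are dropped first.
#'
#' @param table A [mortality_table()].
#' @param life_tables A [life_table()] covering every needed
#'   (sex, midpoint) pair.
#' @param min_age Minimum stratum lower bound (default 50).
#' @param open_ended_offset Midpoint offset for the open-ended group.
#' @return A list of class `yll_result`: `per_stratum` (data frame with
#'   midpoint, expectancy and yll per stratum), `total_deaths_50plus`,
#'   `total_yll`.
#' @export
#' @examples
#' mt <- mortality_table("male", 50, 54, 100)
#' lt <- life_table("male", 52, 30)
#' compute_yll(mt, lt)$total_yll  # 3000
compute_yll <- function(table, life_tables, min_age = 50L, open_ended_offset = 2L) {
  stopifnot(inherits(table, "mortality_table"))
  tab <- restrict_age50plus(table, min_age)
  if (nrow(tab) == 0L) {
    return(structure(
      list(per_stratum = cbind(as.data.frame(tab),
                               midpoint = integer(0), expectancy = numeric(0),
                               yll = numeric(0)),
           total_deaths_50plus = 0L, total_yll = 0),
      class = "yll_result"
    ))
  }
  mid <- interval_midpoint(tab$age_lower, tab$age_upper, open_ended_offset)
  exp_at <- vapply(seq_len(nrow(tab)), function(i) {
    tryCatch(
      lookup_expectancy(life_tables, tab$sex[i], mid[i]),
      preventyll_lookup_error = function(e) {
        stop_lookup("stratum ", tab$sex[i], " ", tab$age_lower[i], "-",
                    ifelse(is.na(tab$age_upper[i]), "+", tab$age_upper[i]),
                    ": ", conditionMessage(e))
      }
    )
  }, numeric(1))
  per <- as.data.frame(tab)
  per$midpoint <- mid
  per$expectancy <- exp_at
  per$yll <- per$deaths * per$expectancy
  structure(
    list(per_stratum = per,
         total_deaths_50plus = sum(per$deaths),
         total_yll = sum(per$yll)),
    class = "yll_result"
  )
}

#' @export
print.yll_result <- function(x, ...) {
  cat(sprintf("YLL result: %s deaths (age 50+), %.1f years of life lost\n",
              format(x$total_deaths_50plus, big.mark = " "), x$total_yll))
  print(x$per_stratum, row.names = FALSE)
  invisible(x)
}
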