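# Independent brute-force oracles and random-case generators.
# Written as plain direct-formula loops, deliberately sharing no code
# with the package implementation.

Z95 <- qnorm(0.975)

# Direct-formula inverse-variance pooling (fixed and DL random effects).
oracle_pool <- function(rr, lo, hi, method = c("fixed", "random")) {
  method <- match.arg(method)
  k <- length(rr)
  y <- numeric(k); se <- numeric(k)
  for (i in seq_len(k)) {
    y[i] <- log(rr[i])
    se[i] <- (log(hi[i]) - log(lo[i])) / (2 * Z95)
  }
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / se[i]^2
  num <- 0; den <- 0
  for (i in seq_len(k)) { num <- num + w[i] * y[i]; den <- den + w[i] }
  mu_f <- num / den
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (y[i] - mu_f)^2
  if (method == "fixed") {
    return(list(log_rr = mu_f, se_log = 1 / sqrt(den), tau2 = 0, q = q))
  }
  sw <- 0; sw2 <- 0
  for (i in seq_len(k)) { sw <- sw + w[i]; sw2 <- sw2 + w[i]^2 }
  tau2 <- (q - (k - 1)) / (sw - sw2 / sw)
  if (tau2 < 0) tau2 <- 0
  ws <- numeric(k)
  for (i in seq_len(k)) ws[i] <- 1 / (se[i]^2 + tau2)
  num <- 0; den <- 0
  for (i in seq_len(k)) { num <- num + ws[i] * y[i]; den <- den + ws[i] }
  list(log_rr = num / den, se_log = 1 / sqrt(den), tau2 = tau2, q = q)
}

# Nested-loop YLL recomputation straight from the data frames.
oracle_yll <- function(mortality, lifetab, min_age = 50, open_offset = 2) {
  total <- 0
  for (r in seq_len(nrow(mortality))) {
    if (mortality$age_lower[r] < min_age) next
    lo <- mortality$age_lower[r]; up <- mortality$age_upper[r]
    mid <- if (is.na(up)) lo + open_offset else (lo + up) %/% 2
    e <- NA_real_
    for (s in seq_len(nrow(lifetab))) {
      if (lifetab$sex[s] == mortality$sex[r] && lifetab$age[s] == mid) {
        e <- lifetab$expectancy[s]
        break
      }
    }
    total <- total + mortality$deaths[r] * e
  }
  total
}

# Random trial sets: RR drawn around 1 on the log scale, CI rebuilt from
# a random SE so the invariants 0 < lo <= rr <= hi always hold.
random_trials <- function(k) {
  logrr <- rnorm(k, 0, 0.3)
  se <- runif(k, 0.05, 0.6)
  trial_effects(
    study = paste0("T", seq_len(k)),
    rr = exp(logrr),
    ci_lower = exp(logrr - Z95 * se),
    ci_upper = exp(logrr + Z95 * se)
  )
}

# Random mortality + life tables on the standard 50-54 ... 85+ layout.
random_tables <- function() {
  al <- seq(50L, 85L, 5L)
  au <- c(al[-length(al)] + 4L, NA_integer_)
  ages <- 50:99
  lt <- life_table(
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, 2),
    expectancy = c(30 * exp(-0.05 * (ages - 50)) + runif(1, 0, 2),
                   33 * exp(-0.05 * (ages - 50)) + runif(1, 0, 2))
  )
  mt <- mortality_table(
    sex = rep(c("male", "female"), each = length(al)),
    age_lower = rep(al, 2),
    age_upper = rep(au, 2),
    deaths = rpois(2 * length(al), lambda = runif(1, 50, 5000))
  )
  list(mortality = mt, life_table = lt)
}
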