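# Independent oracles used across the suite.
#
# Exact rational arithmetic on small integers (numerator/denominator kept in
# doubles; all values stay far below 2^53 for the cohort sizes used here),
# plus naive loop-based enumeration of product-limit risk sets. These
# deliberately share no code with the package: risk sets are recomputed per
# member per event time, and survival/incidence are accumulated as reduced
# fractions.

r_gcd <- function(a, b) { while (b != 0) { t <- a %% b; a <- b; b <- t }; a }

rat <- function(num, den = 1) {
  stopifnot(den != 0)
  s <- sign(num) * sign(den)
  num <- abs(num); den <- abs(den)
  g <- if (num == 0) den else r_gcd(num, den)
  list(num = s * num / g, den = den / g)
}
rat_mul <- function(x, y) rat(x$num * y$num, x$den * y$den)
rat_add <- function(x, y) rat(x$num * y$den + y$num * x$den, x$den * y$den)
rat_eq <- function(x, y) (x$num * y$den) == (y$num * x$den)
rat_val <- function(x) x$num / x$den

# Brute-force cumulative incidence of `target` deaths with delayed entry:
# single pass over sorted known-cause event times, risk sets counted member
# by member, S carried as its left limit in exact fractions.
oracle_cif <- function(entry, exit, dead, cause, target = "cancer") {
  known <- dead & cause %in% c("cancer", "other")
  times <- sort(unique(exit[known]))
  S <- rat(1); cif <- rat(0)
  for (t in times) {
    n <- 0L; d_target <- 0L; d_all <- 0L
    for (i in seq_along(entry)) {
      if (entry[i] < t && exit[i] >= t) n <- n + 1L
      if (known[i] && exit[i] == t) {
        d_all <- d_all + 1L
        if (cause[i] == target) d_target <- d_target + 1L
      }
    }
    if (n == 0L) break
    cif <- rat_add(cif, rat_mul(S, rat(d_target, n)))
    S <- rat_mul(S, rat(n - d_all, n))
  }
  list(cif = cif, S_final = S)
}

# Textbook classical Kaplan-Meier (all entries at zero), exact fractions;
# returns survival after each distinct death time.
oracle_km <- function(exit, dead) {
  times <- sort(unique(exit[dead]))
  out <- numeric(0)
  S <- rat(1)
  for (t in times) {
    n <- sum(exit >= t)
    d <- sum(dead & exit == t)
    S <- rat_mul(S, rat(n - d, n))
    out <- c(out, rat_val(S))
  }
  list(times = times, S = out)
}

# cohort-member constructor for hand-built fixtures
members <- function(entry, exit, event, cause = NA_character_) {
  data.frame(entry_age = entry, exit_age = exit, event = event,
             cause = rep_len(cause, length(entry)),
             necropsy = rep_len(!is.na(cause) & cause %in% c("cancer", "other"),
                                length(entry)),
             stringsAsFactors = FALSE)
}

# random small cohort generator over a grid of cause/censoring patterns
random_cohort <- function(n, allow_truncation = TRUE, allow_censoring = TRUE,
                          allow_unknown = FALSE) {
  entry <- if (allow_truncation) sample(c(0, 0, 0.5, 1.5), n, replace = TRUE)
           else rep(0, n)
  exit <- entry + sample(1:6, n, replace = TRUE) / 2
  event <- if (allow_censoring) sample(c("death", "censored"), n, replace = TRUE,
                                       prob = c(0.7, 0.3))
           else rep("death", n)
  pool <- c("cancer", "other", if (allow_unknown) "unknown")
  cause <- ifelse(event == "death", sample(pool, n, replace = TRUE),
                  NA_character_)
  members(entry, exit, event, cause)
}
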