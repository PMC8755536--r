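#' Delayed-entry Kaplan-Meier (product-limit) estimator
#'
#' Fits the product-limit survival estimator with delayed entry (left
#' truncation) and right censoring. An individual is in the risk set at an
#' event age `t` iff `entry_age < t <= exit_age` (the counting-process
#' convention: deaths at `t` precede censorings at `t`, and an individual is
#' never at risk before it enters). Deaths not selected by `event_selector`
#' are treated as censored at their exit age:
#' * `"all-deaths"` — every death is an event (adult life-expectancy curve);
#' * `"known-cause-only"` — deaths with cause `cancer` or `other` are events
#'   (the complete-case overall survival used by the cumulative incidence);
#' * `"cancer-only"` — only cancer deaths are events (cause-specific hazard).
#'
#' @param members cohort-member data.frame with columns `entry_age`,
#'   `exit_age`, `event` (`"death"`/`"censored"`) and `cause`.
#' @param event_selector which deaths count as events.
#' @param alpha reference adulthood age for the curve; defaults to the
#'   smallest entry age.
#' @return object of class `conc_km`: `event_ages`, `n_risk`, `n_event`,
#'   step values `S` (right-continuous) and left limits `S_left`, `alpha`,
#'   `max_age`, `reaches_zero`, and `terminated` (TRUE when an empty risk
#'   set forced early termination of the curve).
#' @export
km_fit <- function(members,
                   event_selector = c("all-deaths", "cancer-only", "known-cause-only"),
                   alpha = NULL) {
  event_selector <- match.arg(event_selector)
  if (is.null(members) || nrow(members) == 0L) stop("empty cohort")
  entry <- as.numeric(members$entry_age)
  exit <- as.numeric(members$exit_age)
  if (any(exit < entry)) stop("exit_age < entry_age")
  is_death <- members$event == "death"
  known <- !is.na(members$cause) & members$cause %in% c("cancer", "other")
  sel <- switch(event_selector,
    "all-deaths" = is_death,
    "known-cause-only" = is_death & known,
    "cancer-only" = is_death & !is.na(members$cause) & members$cause == "cancer")

  times <- sort(unique(exit[sel]))
  se <- sort(entry)
  sx <- sort(exit)
  # risk set size: #(entry < t) - #(exit < t)
  n_risk <- findInterval(times, se, left.open = TRUE) -
            findInterval(times, sx, left.open = TRUE)
  n_event <- tabulate(match(exit[sel], times), nbins = length(times))

  terminated <- FALSE
  zero <- which(n_risk == 0L)
  if (length(zero)) {
    keep <- seq_len(zero[1L] - 1L)
    times <- times[keep]; n_risk <- n_risk[keep]; n_event <- n_event[keep]
    terminated <- TRUE
  }
  S <- cumprod(1 - n_event / n_risk)
  S_left <- c(1, S[-length(S)])
  if (!length(times)) { S <- numeric(0); S_left <- numeric(0) }

  structure(list(
    event_ages = times, n_risk = n_risk, n_event = n_event,
    S = S, S_left = S_left,
    alpha = alpha %||% (if (length(entry)) min(entry) else NA_real_),
    max_age = max(exit),
    reaches_zero = length(S) > 0 && S[length(S)] <= 0,
    terminated = terminated,
    selector = event_selector,
    n = length(entry)
  ), class = "conc_km")
}

#' @export
print.conc_km <- function(x, ...) {
  cat("Delayed-entry product-limit curve (", x$selector, ")\n", sep = "")
  cat("  n =", x$n, "members,", length(x$event_ages), "event ages, alpha =",
      signif(x$alpha, 4), "\n")
  if (length(x$S)) cat("  final S =", signif(x$S[length(x$S)], 4),
                       if (x$terminated) " [terminated: empty risk set]\n" else "\n")
  invisible(x)
}

#' Evaluate a product-limit curve as a step function
#'
#' Right-continuous evaluation: `S(t)` is the value after any jump at `t`;
#' `left = TRUE` gives the left limit `S(t-)`.
#'
#' @param curve a `conc_km` object.
#' @param t ages.
#' @param left evaluate the left limit instead.
#' @return survival probabilities at `t`.
#' @export
km_eval <- function(curve, t, left = FALSE) {
  if (!length(curve$event_ages)) return(rep(1, length(t)))
  i <- findInterval(t, curve$event_ages, left.open = left)
  c(1, curve$S)[i + 1L]
}

#' Adult life expectancy from a survival curve
#'
#' Area under the survival step function from the adulthood reference age
#' `alpha` to the last observed exit age (restricted mean adult lifetime
#' beyond maturity). When the curve does not reach zero the area is
#' truncated at the last observation and flagged.
#'
#' @param curve a `conc_km` fitted with the all-deaths selector.
#' @return list with `value` (years beyond `alpha`) and `truncated`.
#' @export
adult_life_expectancy <- function(curve) {
  a <- curve$alpha
  knots <- c(a, curve$event_ages[curve$event_ages > a], curve$max_age)
  knots <- knots[!duplicated(knots)]
  heights <- km_eval(curve, knots[-length(knots)])
  value <- sum(diff(knots) * heights)
  list(value = value, truncated = !curve$reaches_zero)
}

#' Survival quantile age
#'
#' Smallest event age at which the survival step value drops to `q` or
#' below. Species whose curves never reach `q = 0.10` are flagged
#' undefined and excluded from cumulative-incidence analyses.
#'
#' @param curve a `conc_km` object.
#' @param q survival probability in (0, 1].
#' @return list with `age` (NA when undefined) and `defined`.
#' @export
survival_quantile <- function(curve, q) {
  stopifnot(q > 0, q <= 1)
  i <- which(curve$S <= q + 1e-9)   # tolerance for exact-tie step values
  if (!length(i)) return(list(age = NA_real_, defined = FALSE))
  list(age = curve$event_ages[i[1L]], defined = TRUE)
}

#' Export a survival curve as a table
#'
#' @param curve a `conc_km` object.
#' @return data.frame `(age, n_risk, n_event, S)`.
#' @export
km_table <- function(curve) {
  data.frame(age = curve$event_ages, n_risk = curve$n_risk,
             n_event = curve$n_event, S = curve$S)
}
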