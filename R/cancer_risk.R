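#' Crude cancer mortality risk (CMR)
#'
#' The ratio of cancer-attributed deaths to individuals with postmortem
#' pathological records, per species.
#'
#' @param n_cancer number of cancer deaths.
#' @param n_necropsied number of necropsied (known-cause) dead individuals.
#' @return proportion in \[0, 1\].
#' @export
compute_cmr <- function(n_cancer, n_necropsied) {
  if (any(n_necropsied < 1)) stop("n_necropsied must be >= 1")
  if (any(n_cancer < 0 | n_cancer > n_necropsied)) {
    stop("n_cancer must lie in [0, n_necropsied]")
  }
  n_cancer / n_necropsied
}

#' Complete-case subset of a cohort
#'
#' Retains deaths whose cause is specified (`cancer` or `other`) together
#' with right-censored survivors; dead individuals with unknown cause are
#' dropped. This is the set on which cause-specific quantities are
#' estimated, under the assumption that missingness in the cause of failure
#' is random.
#'
#' @param members cohort-member data.frame.
#' @return the subset, same columns.
#' @export
complete_case_subset <- function(members) {
  keep <- members$event == "censored" |
    (!is.na(members$cause) & members$cause %in% c("cancer", "other"))
  members[keep, , drop = FALSE]
}

#' Cumulative incidence of cancer mortality (ICM)
#'
#' Competing-risks cumulative incidence of death by cancer from adulthood
#' onward: `ICM = sum over cancer event ages x of S_x * h^c_x`, where `S_x`
#' is the all-known-cause survival (delayed-entry product limit on the
#' complete-case set) and `h^c_x = d^c_x / n_x` is the cancer-specific
#' hazard jump from a product-limit analysis in which only cancer deaths
#' are events. Hazards are carried as exact event-age jumps, zero between
#' events, rather than pooled over fixed intervals; `S` enters as its left
#' limit at each jump (`s_convention = "left"`), the convention under which
#' the cause-specific incidences and the terminal survival add exactly to
#' one on fully observed cohorts. The post-jump alternative is exposed for
#' comparison.
#'
#' @param members complete-case cohort members (see
#'   [complete_case_subset()]); must already satisfy any eligibility rule.
#' @param cause which cause's cumulative incidence to compute.
#' @param s_convention evaluate overall survival at the left limit
#'   (default) or post-jump value at each event age.
#' @return list with `value` (proportion; NA when undefined), `defined`,
#'   and the two underlying curves.
#' @export
compute_icm <- function(members, cause = "cancer",
                        s_convention = c("left", "right")) {
  s_convention <- match.arg(s_convention)
  if (is.null(members) || nrow(members) == 0L) {
    return(list(value = NA_real_, defined = FALSE))
  }
  # relabel so any non-target known cause acts as the single competing cause
  m <- members
  known <- !is.na(m$cause) & m$cause %in% c("cancer", "other")
  m$cause[known] <- ifelse(m$cause[known] == cause, "cancer", "other")

  surv <- km_fit(m, "known-cause-only")
  haz <- km_fit(m, "cancer-only")
  if (!length(haz$event_ages)) {
    return(list(value = 0, defined = TRUE, surv = surv, hazard = haz))
  }
  jumps <- haz$n_event / haz$n_risk
  S_at <- km_eval(surv, haz$event_ages, left = (s_convention == "left"))
  list(value = sum(S_at * jumps), defined = TRUE, surv = surv, hazard = haz)
}

#' Species-level cancer-risk estimation
#'
#' Runs the survival and risk chain for every species in a cohort table:
#' counts, CMR, the all-deaths survival curve with adult life expectancy
#' and the 10%-survival eligibility age, and the complete-case ICM for
#' eligible species.
#'
#' @param cohorts cohort table from [filter_eligible()].
#' @param q_eligibility survival level that must be reached for the ICM to
#'   be considered estimable (default 0.10).
#' @param s_convention passed to [compute_icm()].
#' @return data.frame with one row per species: `species, n_total, n_dead,
#'   n_necropsied, n_cancer, cmr, icm, icm_eligible, alpha,
#'   adult_life_expectancy, le_truncated, q_age`.
#' @export
estimate_cancer_risk <- function(cohorts, q_eligibility = 0.10,
                                 s_convention = "left") {
  cs <- cohort_summary(cohorts)
  out <- cs
  out$cmr <- ifelse(cs$n_necropsied >= 1, cs$n_cancer / cs$n_necropsied, NA_real_)
  out$icm <- NA_real_
  out$icm_eligible <- FALSE
  out$alpha <- NA_real_
  out$adult_life_expectancy <- NA_real_
  out$le_truncated <- NA
  out$q_age <- NA_real_

  by_sp <- split(seq_len(nrow(cohorts)), cohorts$species)
  for (k in seq_len(nrow(out))) {
    m <- cohorts[by_sp[[out$species[k]]], , drop = FALSE]
    alpha <- min(m$alpha %||% m$entry_age)
    curve <- km_fit(m, "all-deaths", alpha = alpha)
    le <- adult_life_expectancy(curve)
    qa <- survival_quantile(curve, q_eligibility)
    out$alpha[k] <- alpha
    out$adult_life_expectancy[k] <- le$value
    out$le_truncated[k] <- le$truncated
    out$q_age[k] <- qa$age
    out$icm_eligible[k] <- qa$defined
    if (qa$defined) {
      icm <- compute_icm(complete_case_subset(m), s_convention = s_convention)
      if (icm$defined) out$icm[k] <- icm$value else out$icm_eligible[k] <- FALSE
    }
  }
  out
}

#' Assemble the species-level trait table
#'
#' Joins the cancer-risk estimates with the life-history table (body mass,
#' taxonomic order, recoded diet flags) to give the analysis table used by
#' the comparative models.
#'
#' @param risk output of [estimate_cancer_risk()].
#' @param life_history species table ([read_species_table()]); 4-level
#'   `diet_*` columns are recoded to binary flags via [recode_diet()].
#' @return data.frame, one row per species present in `risk`.
#' @export
build_trait_table <- function(risk, life_history) {
  i <- match(risk$species, life_history$species)
  if (anyNA(i)) {
    stop("species missing from life-history table: ",
         paste(risk$species[is.na(i)], collapse = ", "))
  }
  out <- risk
  out$body_mass <- life_history$body_mass[i]
  out$order <- if ("order" %in% names(life_history)) life_history$order[i] else NA
  for (col in grep("^diet_", names(life_history), value = TRUE)) {
    out[[col]] <- recode_diet(life_history[[col]][i])
  }
  out
}

#' Recode a 4-level diet item to a binary flag
#'
#' `never`/`occasional` map to 0, `secondary`/`primary` to 1 (already
#' binary 0/1 input passes through).
#'
#' @param x character (4-level) or 0/1 vector.
#' @return integer 0/1 vector.
#' @export
recode_diet <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(x %in% c(0, 1) | is.na(x)))
    return(as.integer(x))
  }
  lv <- c(never = 0L, occasional = 0L, secondary = 1L, primary = 1L)
  bad <- !is.na(x) & !x %in% names(lv)
  if (any(bad)) stop("unknown diet level: ", paste(unique(x[bad]), collapse = ", "))
  unname(lv[x])
}
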