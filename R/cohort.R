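#' Read individual-level animal records
#'
#' Reads a CSV of individual demographic histories with columns
#' `id, species, sex, birth_date, birth_precision_days, death_date, alive,
#' necropsy, cause` (ISO-8601 dates; `death_date` and `cause` may be empty).
#' Basic record invariants are checked: a death date must be present exactly
#' when the animal is not alive at extraction, a known cause of death
#' (`cancer` or `other`) requires an available necropsy, and the birth-date
#' precision must be non-negative.
#'
#' @param path path to the records CSV.
#' @return a data.frame of validated individual records.
#' @export
read_records <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("id", "species", "sex", "birth_date", "birth_precision_days",
              "death_date", "alive", "necropsy", "cause")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) stop("records file lacks columns: ", paste(miss, collapse = ", "))
  raw$alive <- as.logical(raw$alive)
  raw$necropsy <- as.logical(raw$necropsy)
  validate_records(raw)
  raw
}

parse_date_checked <- function(x, id, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(d)
  if (any(bad)) {
    stop("unparseable ", what, " for record(s): ",
         paste(head(id[bad], 5L), collapse = ", "))
  }
  d
}

validate_records <- function(records) {
  records$birth_date <- parse_date_checked(records$birth_date, records$id, "birth_date")
  records$death_date <- parse_date_checked(records$death_date, records$id, "death_date")
  if (anyNA(records$birth_date)) stop("missing birth_date")
  if (any(records$birth_precision_days < 0, na.rm = TRUE)) {
    stop("birth_precision_days must be >= 0")
  }
  dd_ok <- is.na(records$death_date) == records$alive
  if (!all(dd_ok)) {
    stop("death_date must be present iff not alive; offending ids: ",
         paste(head(records$id[!dd_ok], 5L), collapse = ", "))
  }
  known <- !is.na(records$cause) & records$cause %in% c("cancer", "other")
  if (any(known & !records$necropsy)) {
    stop("cause cancer/other requires necropsy availability")
  }
  invisible(records)
}

#' Read the species life-history table
#'
#' Columns: `species, alpha_male, alpha_female, body_mass, order,
#' domesticated`, plus optional 4-level `diet_*` columns (values `never`,
#' `occasional`, `secondary`, `primary`).
#'
#' @param path path to the species CSV.
#' @return data.frame keyed by species.
#' @export
read_species_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("species", "alpha_male", "alpha_female", "body_mass")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stop("species file lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species)) stop("duplicated species in life-history table")
  if (any(tab$body_mass <= 0, na.rm = TRUE)) stop("body_mass must be > 0")
  if (any(c(tab$alpha_male, tab$alpha_female) <= 0, na.rm = TRUE)) {
    stop("ages at sexual maturity must be > 0")
  }
  tab
}

#' Resolve the age at sexual maturity for a species and sex
#'
#' Returns the sex-specific age at sexual maturity (alpha, in years). For
#' individuals of unknown sex the maximum of the male and female ages is
#' used as the adulthood threshold, so no juvenile can slip in through an
#' unsexed record.
#'
#' @param species character vector of species names.
#' @param sex character vector in `male`, `female`, `unknown` (recycled).
#' @param life_history species table as from [read_species_table()].
#' @return numeric vector of maturity ages in years.
#' @export
resolve_maturity_age <- function(species, sex, life_history) {
  n <- max(length(species), length(sex))
  species <- rep_len(species, n)
  sex <- rep_len(sex, n)
  i <- match(species, life_history$species)
  if (anyNA(i)) {
    stop("species not in life-history table: ",
         paste(unique(species[is.na(i)]), collapse = ", "))
  }
  am <- life_history$alpha_male[i]
  af <- life_history$alpha_female[i]
  out <- ifelse(sex == "male", am,
         ifelse(sex == "female", af, pmax(am, af)))
  bad <- is.na(out)
  if (any(bad)) {
    stop("missing maturity age for requested sex; species: ",
         paste(unique(species[bad]), collapse = ", "))
  }
  out
}

#' Build per-species adult cohorts from individual records
#'
#' Applies the eligibility, left-truncation and censoring rules of the study
#' design to raw records:
#' * individuals dead before `window_start` are excluded;
#' * individuals with birth-date precision worse than `max_precision_days`
#'   (default 30 days) are excluded;
#' * individuals must reach their age at sexual maturity (sex-specific;
#'   maximum of the two sexes when sex is unknown) before death and before
#'   `extraction_date` — everyone else is a juvenile and excluded;
#' * entry age is the age on `window_start` for individuals already adult
#'   then (left truncation / delayed entry), otherwise the maturity age;
#' * exit age is the age at death, or the age at `extraction_date` for
#'   individuals still alive (right censoring).
#'
#' Ages are exact day differences divided by 365.25.
#'
#' @param records validated record data.frame ([read_records()]).
#' @param life_history species table ([read_species_table()]).
#' @param window_start,extraction_date observation window (ISO dates).
#' @param max_precision_days birth-date precision ceiling in days.
#' @return data.frame of cohort members (class `conc_cohorts`) with columns
#'   `species, id, sex, entry_age, exit_age, event, necropsy, cause`;
#'   dead members without necropsy keep `cause = "unknown"`.
#' @export
filter_eligible <- function(records, life_history,
                            window_start = "2010-01-01",
                            extraction_date = "2020-05-30",
                            max_precision_days = 30) {
  window_start <- as.Date(window_start)
  extraction_date <- as.Date(extraction_date)
  stopifnot(window_start < extraction_date)
  records <- validate_records(records)

  keep <- records$birth_precision_days <= max_precision_days
  dead_before <- !records$alive & records$death_date < window_start
  keep <- keep & !dead_before

  alpha <- resolve_maturity_age(records$species, records$sex, life_history)
  end_date <- ifelse(records$alive, as.numeric(extraction_date),
                     as.numeric(records$death_date))
  end_age <- (end_date - as.numeric(records$birth_date)) / DAYS_PER_YEAR
  keep <- keep & end_age >= alpha   # must reach maturity in observable time

  r <- records[keep, , drop = FALSE]
  alpha <- alpha[keep]
  age_at_ws <- (as.numeric(window_start) - as.numeric(r$birth_date)) / DAYS_PER_YEAR
  entry <- pmax(alpha, age_at_ws)
  exit <- end_age[keep]
  cause <- ifelse(r$alive, NA_character_,
                  ifelse(r$necropsy & !is.na(r$cause), r$cause, "unknown"))

  out <- data.frame(
    species = r$species,
    id = r$id,
    sex = r$sex,
    alpha = alpha,
    entry_age = entry,
    exit_age = exit,
    event = ifelse(r$alive, "censored", "death"),
    necropsy = !r$alive & r$necropsy & !is.na(r$cause) & r$cause %in% c("cancer", "other"),
    cause = cause,
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$exit_age >= out$entry_age - 1e-12))
  attr(out, "window_start") <- window_start
  attr(out, "extraction_date") <- extraction_date
  attr(out, "included_ids") <- out$id
  class(out) <- c("conc_cohorts", "data.frame")
  out
}

#' Per-species cohort counts
#'
#' @param cohorts cohort table from [filter_eligible()].
#' @return data.frame with `species, n_total, n_dead, n_necropsied, n_cancer`.
#' @export
cohort_summary <- function(cohorts) {
  sp <- factor(cohorts$species)
  dead <- cohorts$event == "death"
  cancer <- dead & !is.na(cohorts$cause) & cohorts$cause == "cancer"
  out <- data.frame(
    species = levels(sp),
    n_total = as.integer(table(sp)),
    n_dead = as.integer(tapply(dead, sp, sum)),
    n_necropsied = as.integer(tapply(cohorts$necropsy, sp, sum)),
    n_cancer = as.integer(tapply(cancer, sp, sum)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$n_necropsied <= out$n_dead), all(out$n_dead <= out$n_total))
  out
}

#' Apply the minimum-necropsy species threshold
#'
#' Keeps species with at least `min_necropsied` adult individuals having
#' postmortem pathological records (default 20; 40/60/80/100 form the
#' sensitivity ladder).
#'
#' @param cohorts cohort table.
#' @param min_necropsied integer threshold (>= 1).
#' @return character vector of retained species.
#' @export
apply_species_thresholds <- function(cohorts, min_necropsied = 20) {
  stopifnot(min_necropsied >= 1)
  cs <- cohort_summary(cohorts)
  cs$species[cs$n_necropsied >= min_necropsied]
}

#' Default domesticated-species exclusion list
#'
#' A plain-text default list of widely domesticated mammal binomials (and
#' their wild ancestors) shipped with the package; users studying a real
#' extract should supply their own curated list.
#'
#' @return character vector of binomials.
#' @export
default_domesticated_species <- function() {
  path <- system.file("extdata", "domesticated_default.txt", package = "comparonc")
  x <- readLines(path)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Exclude domesticated species
#'
#' @param species_list character vector of candidate species.
#' @param exclusion_list binomials to drop; defaults to
#'   [default_domesticated_species()].
#' @param quiet suppress the log message listing removals.
#' @return `species_list` without the excluded names.
#' @export
exclude_domesticated <- function(species_list, exclusion_list = NULL, quiet = FALSE) {
  exclusion_list <- exclusion_list %||% default_domesticated_species()
  hit <- species_list %in% exclusion_list
  if (!quiet) {
    if (any(hit)) {
      message("excluding domesticated species: ",
              paste(species_list[hit], collapse = ", "))
    } else message("no domesticated species present in data")
  }
  species_list[!hit]
}
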