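lht <- data.frame(
  species = c("Panthera leo", "Gazella marica", "Suncus murinus"),
  alpha_male = c(2, 1.5, NA),
  alpha_female = c(3, 1, 0.2),
  body_mass = c(160, 25, 0.05),
  order = c("Carnivora", "Artiodactyla", "Eulipotyphla"),
  stringsAsFactors = FALSE
)

rec <- function(id, species, sex, birth, prec = 0, death = NA, necropsy = FALSE,
                cause = NA) {
  data.frame(id = id, species = species, sex = sex, birth_date = birth,
             birth_precision_days = prec, death_date = death,
             alive = is.na(death), necropsy = necropsy, cause = cause,
             stringsAsFactors = FALSE)
}

test_that("maturity age resolves by sex with the max rule for unknowns", {
  expect_equal(resolve_maturity_age("Panthera leo", "male", lht), 2)
  expect_equal(resolve_maturity_age("Panthera leo", "female", lht), 3)
  expect_equal(resolve_maturity_age("Panthera leo", "unknown", lht), 3)
  expect_equal(
    resolve_maturity_age(c("Gazella marica", "Gazella marica"),
                         c("unknown", "female"), lht),
    c(1.5, 1))
  expect_error(resolve_maturity_age("Vulpes vulpes", "male", lht), "not in")
  expect_error(resolve_maturity_age("Suncus murinus", "male", lht), "missing maturity")
})

test_that("eligibility rules: truncation, precision, window, juveniles", {
  records <- rbind(
    # adult before window start: left-truncated at age on 2010-01-01
    rec("a", "Panthera leo", "female", "2005-01-01"),
    # imprecise birth date: dropped
    rec("b", "Panthera leo", "female", "2005-01-01", prec = 45),
    # dead before the window: dropped
    rec("c", "Panthera leo", "male", "2000-01-01", death = "2009-06-01",
        necropsy = TRUE, cause = "cancer"),
    # matures inside the window: enters at maturity age
    rec("d", "Panthera leo", "male", "2012-03-10", death = "2019-03-10",
        necropsy = TRUE, cause = "other"),
    # never reaches maturity before extraction: dropped
    rec("e", "Panthera leo", "female", "2019-01-01"),
    # dies as a juvenile: dropped
    rec("f", "Panthera leo", "male", "2011-01-01", death = "2012-01-01",
        necropsy = TRUE, cause = "other"),
    # dead without necropsy: kept, cause unknown
    rec("g", "Panthera leo", "unknown", "2004-01-01", death = "2015-06-01")
  )
  coh <- filter_eligible(records, lht, "2010-01-01", "2020-05-30")
  expect_setequal(coh$id, c("a", "d", "g"))

  a <- coh[coh$id == "a", ]
  expect_equal(a$entry_age, years_between("2005-01-01", "2010-01-01"),
               tolerance = 1e-12)
  expect_equal(a$entry_age, 5.0, tolerance = 1e-3)
  expect_equal(a$event, "censored")
  expect_equal(a$exit_age, years_between("2005-01-01", "2020-05-30"),
               tolerance = 1e-12)

  d <- coh[coh$id == "d", ]
  expect_equal(d$entry_age, 2)          # alpha_male
  expect_equal(d$event, "death")

  g <- coh[coh$id == "g", ]
  expect_equal(g$cause, "unknown")
  expect_false(g$necropsy)

  # entry >= alpha and exit >= entry for every member
  expect_true(all(coh$entry_age >= coh$alpha - 1e-12))
  expect_true(all(coh$exit_age >= coh$entry_age))
})

test_that("filtering is idempotent and conserves counts", {
  set.seed(42)
  w <- simulate_world(world_spec(n_species = 8, n_individuals = 60, seed = 9))
  coh <- filter_eligible(w$records, w$life_history)
  # re-filtering the already-eligible records reproduces the cohort
  again <- filter_eligible(w$records[w$records$id %in% coh$id, ],
                           w$life_history)
  expect_equal(again$id, coh$id)
  expect_equal(again$entry_age, coh$entry_age)
  expect_equal(again$exit_age, coh$exit_age)
  # excluded + included = input, per species
  cs <- cohort_summary(coh)
  input_n <- table(w$records$species)
  excl <- !w$records$id %in% coh$id
  excl_n <- table(factor(w$records$species[excl], levels = names(input_n)))
  expect_equal(as.integer(input_n),
               as.integer(excl_n) +
                 as.integer(cs$n_total[match(names(input_n), cs$species)]))
})

test_that("species thresholds retain nested subsets along the ladder", {
  set.seed(1)
  w <- simulate_world(world_spec(n_species = 12, n_individuals = 120, seed = 2))
  coh <- filter_eligible(w$records, w$life_history)
  cs <- cohort_summary(coh)
  expect_true(all(cs$n_necropsied <= cs$n_dead))
  prev <- apply_species_thresholds(coh, 20)
  for (th in c(40, 60, 80, 100)) {
    cur <- apply_species_thresholds(coh, th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # boundary: exactly at the threshold is included
  cs20 <- cs$species[cs$n_necropsied >= 20]
  expect_setequal(apply_species_thresholds(coh, 20), cs20)
})

test_that("domesticated-species exclusion is a logged set difference", {
  expect_equal(suppressMessages(exclude_domesticated(c("A", "B", "C"), "B")),
               c("A", "C"))
  expect_equal(suppressMessages(exclude_domesticated(c("A", "B"), character(0))),
               c("A", "B"))
  expect_message(exclude_domesticated(c("A"), "Z"), "no domesticated")
  # packaged default list catches classic domesticates
  expect_false("Bos taurus" %in%
                 suppressMessages(exclude_domesticated(c("Bos taurus", "Panthera leo"))))
})
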