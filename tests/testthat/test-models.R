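# species-level-only world: traits plus binomial necropsy sampling, no
# individual records; fast enough for repeated fits
trait_world <- function(n = 100, beta = c(-2.5, -0.2, 0.8), lambda = 0.5,
                        resid_sd = 0.8, seed = 1) {
  tr <- simulate_tree(n, seed)
  set.seed(seed + 7000)
  C1 <- ape::vcv(tr)
  lnm <- as.numeric(2 + 2 * crossprod(chol(C1), rnorm(n)))
  lnl <- as.numeric(2.3 + 0.6 * crossprod(chol(C1), rnorm(n)))
  u <- as.numeric(resid_sd * crossprod(chol(comparonc:::scale_lambda(C1, lambda)),
                                       rnorm(n)))
  p <- pmin(plogis(beta[1] + beta[2] * (lnm - 2) + beta[3] * (lnl - 2.3) + u), 0.9)
  n_necropsied <- round(runif(n, 100, 400))
  k <- rbinom(n, n_necropsied, p)
  traits <- data.frame(species = tr$tip.label,
                       body_mass = exp(lnm),
                       adult_life_expectancy = exp(lnl),
                       n_necropsied = n_necropsied,
                       cmr = k / n_necropsied,
                       icm = k / n_necropsied,
                       stringsAsFactors = FALSE)
  list(tree = tr, traits = traits, p = p)
}

test_that("phylogenetic signal agrees with an independent implementation", {
  set.seed(61)
  tr <- simulate_tree(80, 17)
  # Brownian component plus independent noise: interior optimum for lambda
  y <- setNames(as.numeric(crossprod(chol(ape::vcv(tr)), rnorm(80))) +
                  rnorm(80, 0, 0.5), tr$tip.label)
  ours <- phylo_signal(y, tr)
  ref <- suppressWarnings(phytools::phylosig(tr, y, method = "lambda", test = TRUE))
  expect_equal(ours$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(ours$p, ref$P, tolerance = 1e-4)
  expect_error(phylo_signal(y[1:3], tr), "at least 4")
  expect_true(phylo_signal(setNames(rep(1, 80), tr$tip.label), tr)$degenerate)
})

test_that("permuting tip labels destroys the signal", {
  set.seed(62)
  tr <- simulate_tree(128, 23)
  y <- setNames(as.numeric(crossprod(chol(ape::vcv(tr)), rnorm(128))), tr$tip.label)
  lam <- replicate(8, phylo_signal(setNames(sample(y), names(y)), tr)$lambda)
  expect_lt(median(lam), 0.1)
})

test_that("PQL with s2 fixed at zero reproduces plain logistic regression", {
  set.seed(63)
  tr <- simulate_tree(50, 31)
  x <- rnorm(50)
  y <- rbinom(50, 1, plogis(-0.3 + x))
  f <- binary_pglmm(y, cbind(intercept = 1, x = x), tr, s2_fixed = 0)
  g <- glm(y ~ x, family = binomial)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-4)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-3)
})

test_that("PQL estimates agree with the reference PQL implementation", {
  set.seed(64)
  tr <- simulate_tree(60, 37)
  C1 <- ape::vcv(tr)
  x <- as.numeric(crossprod(chol(C1), rnorm(60)))
  b <- as.numeric(0.8 * crossprod(chol(C1), rnorm(60)))
  y <- rbinom(60, 1, plogis(-0.5 + x + b))
  f <- binary_pglmm(y, cbind(intercept = 1, x = x), tr)
  ref <- ape::binaryPGLMM(y ~ x, phy = tr,
                          data = data.frame(y = y, x = x, row.names = tr$tip.label))
  expect_equal(unname(f$coefficients), as.numeric(ref$B), tolerance = 0.02)
  expect_equal(f$s2, ref$s2, tolerance = 0.05)
})

test_that("PQL recovers a known slope on the log2-mass scale", {
  set.seed(65)
  est <- numeric(10)
  for (i in 1:10) {
    tr <- simulate_tree(200, 100 + i)
    set.seed(9000 + i)
    x <- rnorm(200, 0, 1.5)           # log2 body mass, centred
    b <- as.numeric(0.5 * crossprod(chol(ape::vcv(tr)), rnorm(200)))
    y <- rbinom(200, 1, plogis(0.2 + 1 * x + b))
    est[i] <- binary_pglmm(y, cbind(intercept = 1, log2_mass = x),
                           tr)$coefficients[["log2_mass"]]
  }
  expect_lt(abs(mean(est) - 1), 0.25)
})

test_that("complete separation is flagged rather than fitted", {
  tr <- simulate_tree(30, 41)
  f <- suppressWarnings(binary_pglmm(rep(1, 30), cbind(intercept = rep(1, 30)),
                                     tr, s2_fixed = 0))
  expect_true(f$separation || !f$converged)
})

test_that("the two-part model splits species exhaustively and disjointly", {
  tw <- trait_world(seed = 5)
  tw$traits$cmr[1:25] <- 0
  fit <- fit_zero_inflated(tw$traits, tw$tree, "cmr")
  expect_length(intersect(fit$species_zero, fit$species_nonzero), 0)
  expect_setequal(c(fit$species_zero, fit$species_nonzero), tw$traits$species)
  expect_s3_class(fit$detection, "conc_pglmm")
  expect_named(fit$magnitude$coefficients,
               c("intercept", "log_body_mass", "log_life_expectancy"))
  # interaction and exclusions are honoured
  fit2 <- fit_zero_inflated(tw$traits, tw$tree, "cmr", interaction = TRUE,
                            exclude = tw$traits$species[30:31])
  expect_true("mass_x_life" %in% names(fit2$magnitude$coefficients))
  expect_false(any(tw$traits$species[30:31] %in%
                     c(fit2$species_zero, fit2$species_nonzero)))
})

test_that("degenerate two-part branches behave as documented", {
  tw <- trait_world(n = 40, seed = 6)
  tw$traits$cmr <- pmin(pmax(tw$traits$cmr, 0.005), 0.9)   # all non-zero
  expect_message(fit <- fit_zero_inflated(tw$traits, tw$tree, "cmr"),
                 "detection part skipped")
  expect_null(fit$detection)
  tw$traits$cmr[seq(1, 35)] <- 0                  # too few non-zero species
  expect_error(fit_zero_inflated(tw$traits, tw$tree, "cmr"), "non-zero")
})

test_that("risk predictions invert the logit and scale per doubling", {
  f <- as_risk_model(-3, 0, 0)
  expect_equal(predict_risk(f, 1, 27), 100 * plogis(-3), tolerance = 1e-12)
  expect_equal(round(predict_risk(f, 123, 4), 2), 4.74)
  fb <- as_risk_model(-3, b_log_mass = -0.05)
  lp1 <- qlogis(predict_risk(fb, 2, 10) / 100)
  lp0 <- qlogis(predict_risk(fb, 1, 10) / 100)
  expect_equal(lp1 - lp0, -0.05 * log(2), tolerance = 1e-12)
  # monotone in each coefficient direction
  fl <- as_risk_model(-3, -0.1, 0.4)
  expect_lt(predict_risk(fl, 100, 10), predict_risk(fl, 1, 10))
  expect_gt(predict_risk(fl, 10, 30), predict_risk(fl, 10, 5))
  expect_error(predict_risk(fl, -1, 10), "positive")
})

test_that("partial R2 is zero for identical models and tracks effect size", {
  set.seed(71)
  n <- 60
  x <- rnorm(n); z <- rnorm(n)
  X_red <- cbind(intercept = rep(1, n), z = z)
  r2_at <- function(b) {
    y <- 0.5 * z + b * x + rnorm(n)
    full <- gls_fit(y, cbind(X_red, x = x), diag(n))
    red <- gls_fit(y, X_red, diag(n))
    partial_r2(full, red)
  }
  full_same <- gls_fit(rnorm(n), X_red, diag(n))
  expect_equal(partial_r2(full_same, full_same), 0)
  r_small <- median(replicate(7, r2_at(0.4)))
  r_big <- median(replicate(7, r2_at(1.5)))
  expect_gt(r_big, r_small)
  expect_gt(r_big, 0)
  # a useless orthogonal predictor explains (almost) nothing
  r_null <- replicate(11, r2_at(0))
  expect_lt(median(r_null), 0.02)
  expect_error(partial_r2(full_same, gls_fit(rnorm(n), cbind(q = rnorm(n)), diag(n))),
               "nested")
})

test_that("phylogenetic paired t-test matches the classical test on a star tree", {
  set.seed(72)
  n <- 20
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, n)
  star$tip.label <- paste0("s", 1:n)
  a <- setNames(rnorm(n, 0.5), star$tip.label)
  b <- setNames(rnorm(n), star$tip.label)
  ours <- phylo_paired_ttest(a, b, star)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$df, n - 2)
  expect_equal(phylo_paired_ttest(a, b, star, df = n - 1)$p, ref$p.value,
               tolerance = 1e-8)
  # a constant shift has the t sign of the shift
  shift <- phylo_paired_ttest(a, setNames(a + 2, names(a)), star)
  expect_true(is.na(shift$t) || shift$t < 0)  # zero-variance flag or negative
  expect_true(phylo_paired_ttest(a, a + rnorm(n, 2, 1e-3), star)$t < 0)
  expect_true(phylo_paired_ttest(a, a - rnorm(n, 2, 1e-3), star)$t > 0)
})

test_that("diet effects are recovered and constant flags rejected", {
  set.seed(73)
  est <- numeric(10)
  for (i in 1:10) {
    tw <- trait_world(n = 90, seed = 300 + i)
    set.seed(300 + i)
    flag <- rbinom(90, 1, 0.35)
    lp <- qlogis(pmin(pmax(tw$traits$cmr, 0.01), 0.6)) + 1 * flag
    tw$traits$cmr <- plogis(lp)
    tw$traits$diet_mammal <- flag
    f <- diet_model(tw$traits, tw$tree, "diet_mammal", "cmr")
    est[i] <- f$coefficients[["diet_mammal"]]
  }
  expect_lt(abs(mean(est) - 1), 0.4)
  tw$traits$diet_mammal <- 1L
  expect_error(diet_model(tw$traits, tw$tree, "diet_mammal", "cmr"),
               "rank deficient")
})

test_that("order contrasts give k(k-1)/2 Tukey comparisons on marginal means", {
  traits <- data.frame(
    species = paste0("s", 1:12),
    cmr = c(rep(0.1, 4), rep(0.1, 4), rep(0.3, 4)) +
      rep(c(0, 0.01, -0.01, 0), 3),
    order = rep(c("A", "B", "C"), each = 4),
    stringsAsFactors = FALSE
  )
  oc <- order_contrasts(traits, "cmr")
  expect_equal(nrow(oc$contrasts), 3)
  # balanced design: marginal means equal arithmetic group means (percent)
  gm <- tapply(100 * traits$cmr, traits$order, mean)
  expect_equal(oc$means$emmean, as.numeric(gm[as.character(oc$means$order)]),
               tolerance = 1e-10)
  # equal-mean orders: contrast estimate zero
  expect_equal(oc$contrasts$estimate[oc$contrasts$contrast == "A - B"], 0,
               tolerance = 1e-10)
  # single qualifying order is an error
  expect_error(order_contrasts(traits[1:5, ], "cmr"), "at least 2 orders")
})

test_that("magnitude-part confidence intervals cover the truth", {
  hits <- 0
  for (i in 1:20) {
    tw <- trait_world(n = 80, beta = c(-2.5, -0.2, 0.8), seed = 600 + i)
    fit <- suppressMessages(fit_zero_inflated(tw$traits, tw$tree, "cmr"))
    m <- fit$magnitude
    ci <- m$coefficients[["log_life_expectancy"]] +
      c(-1, 1) * qt(0.975, m$df) * m$se[["log_life_expectancy"]]
    if (ci[1] <= 0.8 && 0.8 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 15)   # ~85% empirical coverage with PQL/profile bias
})
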