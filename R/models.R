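#' Phylogenetic signal of a continuous trait (Pagel's lambda)
#'
#' ML lambda for an intercept-only GLS model, with a likelihood-ratio test
#' against lambda = 0 (chi-squared, 1 df). Because lambda = 0 lies on the
#' boundary of the parameter space, an optional boundary correction halves
#' the P value.
#'
#' @param trait named numeric vector (names = tip labels).
#' @param tree a `phylo` object.
#' @param halve_boundary_p apply the 50:50 boundary mixture correction.
#' @return list with `lambda`, `p`, `lr`, `loglik`, `loglik0`, `n`,
#'   `degenerate` (constant trait).
#' @export
phylo_signal <- function(trait, tree, halve_boundary_p = FALSE) {
  trait <- trait[!is.na(trait)]
  if (length(trait) < 4) stop("need at least 4 species with non-missing trait")
  tree <- ape::keep.tip(tree, names(trait))
  trait <- trait[tree$tip.label]
  if (sd(trait) == 0) {
    return(list(lambda = NA_real_, p = NA_real_, lr = NA_real_,
                n = length(trait), degenerate = TRUE))
  }
  prof <- lambda_ml(trait, cbind(intercept = rep(1, length(trait))), tree)
  lr <- 2 * (prof$loglik - prof$loglik0)
  p <- pchisq(lr, df = 1, lower.tail = FALSE)
  if (halve_boundary_p) p <- p / 2
  list(lambda = prof$lambda, p = p, lr = lr, loglik = prof$loglik,
       loglik0 = prof$loglik0, n = length(trait), degenerate = FALSE)
}

#' Phylogenetic logistic regression by penalized quasi-likelihood
#'
#' Logistic regression for a binary species trait with a phylogenetically
#' structured random effect `b ~ N(0, s2 * C(1))`. Fitting alternates a
#' working-response (PQL) linearization with joint updates of the fixed
#' effects and the scale `s2`, the latter maximized on the working model's
#' restricted likelihood at each sweep. With `s2_fixed = 0` the iteration
#' collapses to ordinary logistic IRLS.
#'
#' @param y01 binary 0/1 response.
#' @param X design matrix (with intercept column).
#' @param tree a `phylo` aligned with rows, or a `C(1)` covariance matrix.
#' @param s2_fixed optionally fix `s2` instead of estimating it.
#' @param maxit,tol iteration control.
#' @return object of class `conc_pglmm`: coefficients, `se`, `zstat`,
#'   `pval`, `s2`, `converged`, `separation` (divergence flag), `n`.
#' @export
binary_pglmm <- function(y01, X, tree, s2_fixed = NULL, maxit = 60, tol = 1e-5) {
  y <- as.numeric(y01)
  stopifnot(all(y %in% c(0, 1)))
  X <- as.matrix(X)
  n <- length(y)
  C1 <- if (inherits(tree, "phylo")) ape::vcv(tree) else as.matrix(tree)
  stopifnot(nrow(X) == n, nrow(C1) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "), ")")
  }
  p <- ncol(X)

  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, p))
  beta[is.na(beta)] <- 0
  b <- rep(0, n)
  s2 <- if (is.null(s2_fixed)) 0.1 else s2_fixed
  separation <- FALSE
  converged <- FALSE

  rll <- function(s2v, Wd, z) {
    V <- s2v * C1 + diag(1 / Wd, n)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    zt <- backsolve(R, z, transpose = TRUE)
    Xt <- backsolve(R, X, transpose = TRUE)
    f <- lm.fit(Xt, zt)
    XtX <- crossprod(Xt)
    -0.5 * (2 * sum(log(diag(R))) + determinant(XtX)$modulus[1] +
              sum(f$residuals^2))
  }

  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta + b)
    mu <- plogis(eta)
    Wd <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / Wd
    if (is.null(s2_fixed)) {
      opt <- optimize(function(s) rll(s, Wd, z), c(0, 25), maximum = TRUE,
                      tol = 1e-5)
      s2_new <- if (rll(0, Wd, z) >= opt$objective) 0 else opt$maximum
    } else s2_new <- s2_fixed
    V <- s2_new * C1 + diag(1 / Wd, n)
    Vinv <- chol2inv(chol(V))
    XtVinv <- crossprod(X, Vinv)
    A <- XtVinv %*% X
    beta_new <- solve(A, XtVinv %*% z)
    b_new <- as.numeric(s2_new * C1 %*% (Vinv %*% (z - X %*% beta_new)))
    delta <- max(abs(beta_new - beta), abs(s2_new - s2))
    beta <- as.numeric(beta_new); b <- b_new; s2 <- s2_new
    if (max(abs(beta)) > 15) { separation <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }

  eta <- as.numeric(X %*% beta + b)
  mu <- plogis(eta)
  Wd <- pmax(mu * (1 - mu), 1e-8)
  V <- s2 * C1 + diag(1 / Wd, n)
  covb <- chol2inv(chol(crossprod(X, chol2inv(chol(V))) %*% X))
  se <- sqrt(diag(covb))
  zstat <- beta / se
  structure(list(
    coefficients = setNames(beta, colnames(X)),
    se = setNames(se, colnames(X)),
    zstat = setNames(zstat, colnames(X)),
    pval = setNames(2 * pnorm(-abs(zstat)), colnames(X)),
    s2 = s2, ranef = b, n = n,
    converged = converged, separation = separation,
    iterations = it
  ), class = "conc_pglmm")
}

#' @export
print.conc_pglmm <- function(x, ...) {
  cat("Phylogenetic logistic regression (PQL), n =", x$n, "\n")
  print(signif(data.frame(estimate = x$coefficients, se = x$se,
                          z = x$zstat, p = x$pval), 4))
  cat("s2 =", signif(x$s2, 4),
      if (x$separation) " [separation detected]" else "",
      if (!x$converged) " [not converged]" else "", "\n")
  invisible(x)
}

#' Zero-inflated two-part phylogenetic model of cancer risk
#'
#' Part 1 (detection): phylogenetic logistic regression of whether any
#' cancer death was observed in the species, on the log number of
#' necropsied individuals plus log body mass and log adult life
#' expectancy. Part 2 (magnitude): lambda-profiled GLS of the
#' logit-transformed risk on log body mass and log adult life expectancy,
#' restricted to species with strictly positive risk and weighted by the
#' log number of necropsied individuals. The logit is only ever applied to
#' the positive part, so no zero-correction constant is needed.
#'
#' @param traits species table with `species, body_mass,
#'   adult_life_expectancy, n_necropsied` and the response column.
#' @param tree a `phylo` covering the species.
#' @param response `"cmr"` or `"icm"`.
#' @param interaction also include log mass x log life expectancy in the
#'   magnitude part.
#' @param exclude species names dropped before fitting (e.g. high-leverage
#'   outliers).
#' @param min_nonzero refuse to fit the magnitude part below this many
#'   non-zero species.
#' @return object of class `conc_zifit`: `detection` (`conc_pglmm` or NULL
#'   with a note when all species are non-zero/zero), `magnitude`
#'   (`conc_gls`), `lambda`, species sets, `response`.
#' @export
fit_zero_inflated <- function(traits, tree, response = c("cmr", "icm"),
                              interaction = FALSE, exclude = NULL,
                              min_nonzero = 10) {
  response <- match.arg(response)
  tr <- traits[!traits$species %in% exclude, , drop = FALSE]
  tr <- tr[!is.na(tr[[response]]) & !is.na(tr$body_mass) &
             !is.na(tr$adult_life_expectancy) & tr$adult_life_expectancy > 0 &
             !is.na(tr$n_necropsied) & tr$n_necropsied > 0, , drop = FALSE]
  tr <- tr[tr$species %in% tree$tip.label, , drop = FALSE]
  risk <- tr[[response]]

  detected <- as.integer(risk > 0)
  zero_set <- tr$species[detected == 0]
  nonzero_set <- tr$species[detected == 1]

  detection <- NULL
  detection_note <- NULL
  if (length(zero_set) == 0L || length(nonzero_set) == 0L) {
    detection_note <- "detection part skipped: response all zero or all non-zero"
    message(detection_note)
  } else {
    td <- ape::keep.tip(tree, tr$species)
    ord <- match(td$tip.label, tr$species)
    Xd <- cbind(intercept = 1,
                log_n_necropsied = log(tr$n_necropsied[ord]),
                log_body_mass = log(tr$body_mass[ord]),
                log_life_expectancy = log(tr$adult_life_expectancy[ord]))
    detection <- binary_pglmm(detected[ord], Xd, td)
  }

  nz <- tr[detected == 1, , drop = FALSE]
  if (nrow(nz) < min_nonzero) {
    stop("only ", nrow(nz), " species with non-zero risk; need >= ", min_nonzero)
  }
  tm <- ape::keep.tip(tree, nz$species)
  ord <- match(tm$tip.label, nz$species)
  nz <- nz[ord, , drop = FALSE]
  Xm <- cbind(intercept = 1,
              log_body_mass = log(nz$body_mass),
              log_life_expectancy = log(nz$adult_life_expectancy))
  if (interaction) {
    Xm <- cbind(Xm, mass_x_life = Xm[, "log_body_mass"] *
                  Xm[, "log_life_expectancy"])
  }
  w <- log(nz$n_necropsied)
  prof <- lambda_ml(qlogis(nz[[response]]), Xm, tm, weights = w)

  structure(list(
    detection = detection, detection_note = detection_note,
    magnitude = prof$fit, lambda = prof$lambda,
    loglik0 = prof$loglik0,
    species_zero = zero_set, species_nonzero = nz$species,
    response = response
  ), class = "conc_zifit")
}

#' @export
print.conc_zifit <- function(x, ...) {
  cat("Zero-inflated two-part phylogenetic model of", toupper(x$response), "\n")
  cat("-- detection part (", length(x$species_zero), "zero /",
      length(x$species_nonzero), "non-zero species)\n")
  if (is.null(x$detection)) cat("   ", x$detection_note, "\n") else print(x$detection)
  cat("-- magnitude part (lambda =", signif(x$lambda, 4), ")\n")
  print(x$magnitude)
  invisible(x)
}

#' Build a magnitude-part risk model from known coefficients
#'
#' Convenience constructor for a logit-linear risk model with given
#' intercept and natural-log slopes, usable with [predict_risk()] — e.g. to
#' anchor a model through externally reported predictions.
#'
#' @param intercept logit-scale intercept.
#' @param b_log_mass slope on natural-log body mass (kg).
#' @param b_log_life slope on natural-log adult life expectancy (years).
#' @return a minimal `conc_gls`-like object.
#' @export
as_risk_model <- function(intercept, b_log_mass = 0, b_log_life = 0) {
  structure(list(
    coefficients = c(intercept = intercept, log_body_mass = b_log_mass,
                     log_life_expectancy = b_log_life),
    converged = TRUE
  ), class = "conc_gls")
}

#' Predicted cancer mortality risk (per cent)
#'
#' Inverse-logit of the magnitude-part linear predictor at the supplied
#' body mass and adult life expectancy, returned as a percentage. A slope
#' `b` on log2 scale means doubling the covariate shifts the linear
#' predictor by exactly `b` (natural-log slopes are `b / log(2)` per
#' doubling).
#'
#' @param fit a `conc_zifit`, or a magnitude `conc_gls` with coefficients
#'   named `intercept`, `log_body_mass`, `log_life_expectancy` (optionally
#'   `mass_x_life`).
#' @param body_mass body mass in kg (> 0).
#' @param life_expectancy adult life expectancy in years (> 0).
#' @return predicted risk in per cent.
#' @export
predict_risk <- function(fit, body_mass, life_expectancy) {
  if (inherits(fit, "conc_zifit")) fit <- fit$magnitude
  if (!isTRUE(fit$converged)) stop("model fit did not converge")
  if (any(body_mass <= 0) || any(life_expectancy <= 0)) {
    stop("covariates must be positive")
  }
  cf <- fit$coefficients
  lp <- cf[["intercept"]] + cf[["log_body_mass"]] * log(body_mass) +
    cf[["log_life_expectancy"]] * log(life_expectancy)
  if ("mass_x_life" %in% names(cf)) {
    lp <- lp + cf[["mass_x_life"]] * log(body_mass) * log(life_expectancy)
  }
  100 * plogis(as.numeric(lp))
}

#' Prediction-based partial coefficient of determination
#'
#' Compares a full and a nested reduced GLS model by the error of their
#' phylogeny-informed predictions: each species' predicted value is its
#' conditional expectation given all other species under the fitted error
#' covariance, and `partial R2 = 1 - SSE(full) / SSE(reduced)`, clipped at
#' zero.
#'
#' @param full,reduced `conc_gls` fits on the same species, with the
#'   reduced design's columns a subset of the full design's.
#' @return proportion in \[0, 1\].
#' @export
partial_r2 <- function(full, reduced) {
  if (full$n != reduced$n) stop("models fitted on different species sets")
  if (!all(colnames(reduced$X) %in% colnames(full$X))) {
    stop("reduced model is not nested in the full model")
  }
  sse <- function(fit) {
    Vinv <- chol2inv(chol(fit$V))
    r <- fit$y - fit$fitted
    # conditional (leave-one-out) residual: (Vinv r)_i / Vinv_ii
    e <- as.numeric(Vinv %*% r) / diag(Vinv)
    sum(e^2)
  }
  max(0, 1 - sse(full) / sse(reduced))
}

#' Phylogenetic paired t-test
#'
#' Tests whether the mean within-species difference `a - b` is zero under
#' phylogenetic error covariance `C(lambda)` with lambda profiled by ML
#' (intercept-only GLS on the differences). On a star phylogeny the t
#' statistic equals the classical paired t-test. The degrees of freedom
#' default to `n - 2`, charging one df for the estimated lambda; pass `df`
#' to use another convention.
#'
#' @param values_a,values_b named numeric vectors paired by species.
#' @param tree a `phylo` covering the paired species.
#' @param df degrees of freedom for the reference t distribution
#'   (default `n - 2`).
#' @return list with `t`, `df`, `p`, `lambda`, `n`, `mean_difference`,
#'   `degenerate` (zero-variance differences).
#' @export
phylo_paired_ttest <- function(values_a, values_b, tree, df = NULL) {
  common <- intersect(intersect(names(values_a), names(values_b)), tree$tip.label)
  if (length(common) < 3) stop("need at least 3 paired species")
  tree <- ape::keep.tip(tree, common)
  d <- (values_a[common] - values_b[common])[tree$tip.label]
  n <- length(d)
  if (sd(d) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, lambda = NA_real_,
                n = n, mean_difference = mean(d), degenerate = TRUE))
  }
  prof <- lambda_ml(d, cbind(intercept = rep(1, n)), tree)
  df <- df %||% (n - 2)
  tval <- prof$fit$tstat[[1]]
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df),
       lambda = prof$lambda, n = n,
       mean_difference = prof$fit$coefficients[[1]], degenerate = FALSE)
}

#' Per-food-item diet model of cancer risk
#'
#' Lambda-profiled PGLS of logit risk on a binary diet flag plus log body
#' mass and log adult life expectancy, on species with non-zero risk,
#' weighted by log necropsy count. A diet level represented by fewer than
#' three species is flagged (`level_warning`) but still fitted.
#'
#' @param traits trait table with the binary `diet_item` column (see
#'   [recode_diet()]), `body_mass`, `adult_life_expectancy`,
#'   `n_necropsied`, and the response.
#' @param tree a `phylo`.
#' @param diet_item column name, e.g. `"diet_mammal"`.
#' @param response `"cmr"` or `"icm"`.
#' @return a `conc_gls` fit with extra fields `lambda`, `diet_item`,
#'   `level_counts`, `level_warning`.
#' @export
diet_model <- function(traits, tree, diet_item, response = c("cmr", "icm")) {
  response <- match.arg(response)
  tr <- traits[!is.na(traits[[response]]) & traits[[response]] > 0 &
                 !is.na(traits[[diet_item]]), , drop = FALSE]
  tr <- tr[tr$species %in% tree$tip.label, , drop = FALSE]
  tm <- ape::keep.tip(tree, tr$species)
  tr <- tr[match(tm$tip.label, tr$species), , drop = FALSE]
  counts <- table(factor(tr[[diet_item]], levels = c(0, 1)))
  X <- cbind(intercept = 1,
             diet = tr[[diet_item]],
             log_body_mass = log(tr$body_mass),
             log_life_expectancy = log(tr$adult_life_expectancy))
  colnames(X)[2] <- diet_item
  prof <- lambda_ml(qlogis(tr[[response]]), X, tm, weights = log(tr$n_necropsied))
  fit <- prof$fit
  fit$lambda <- prof$lambda
  fit$diet_item <- diet_item
  fit$level_counts <- counts
  fit$level_warning <- any(counts < 3)
  if (fit$level_warning) {
    warning("diet level with < 3 species for ", diet_item)
  }
  fit
}

#' Taxonomic-order differences in cancer risk
#'
#' One-way linear model of the untransformed percentage risk on taxonomic
#' order, restricted to orders with at least `min_species` species, with
#' marginal (estimated) order means and all pairwise contrasts,
#' Tukey-adjusted by default.
#'
#' @param traits trait table with `order` and the response.
#' @param response `"cmr"` or `"icm"`.
#' @param min_species minimum species per retained order (default 2).
#' @param adjust multiplicity adjustment for pairwise contrasts.
#' @return list with `means` (per-order marginal means), `contrasts`
#'   (pairwise differences), and the underlying `lm` fit.
#' @export
order_contrasts <- function(traits, response = c("cmr", "icm"),
                            min_species = 2, adjust = "tukey") {
  response <- match.arg(response)
  tr <- traits[!is.na(traits[[response]]) & !is.na(traits$order), , drop = FALSE]
  keep_orders <- names(which(table(tr$order) >= min_species))
  if (length(keep_orders) < 2) stop("need at least 2 orders with >= ",
                                    min_species, " species")
  tr <- tr[tr$order %in% keep_orders, , drop = FALSE]
  dat <- data.frame(risk_pct = 100 * tr[[response]],
                    order = factor(tr$order))
  fit <- lm(risk_pct ~ order, data = dat)
  emm <- emmeans::emmeans(fit, "order")
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  list(means = as.data.frame(emm), contrasts = as.data.frame(ctr), model = fit)
}
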