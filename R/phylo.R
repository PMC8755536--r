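#' Read and validate a rooted phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces unique tip labels
#' and non-negative branch lengths, and records (attribute `ultrametric`)
#' whether the tree is ultrametric to a 1e-6 relative tolerance.
#'
#' @param path file path, or `text =` a Newick string.
#' @param text optional Newick string instead of a file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  attr(tr, "ultrametric") <- ape::is.ultrametric(tr, tol = 1e-6)
  tr
}

#' Graft a new tip as sister to an existing tip
#'
#' Splits the existing tip's terminal edge at its midpoint and attaches the
#' new tip there with the same half-length, so tip depths (and hence
#' ultrametricity) are preserved. Used for species recently elevated from a
#' close relative that are absent from the source tree.
#'
#' @param tree a `phylo` object.
#' @param existing_tip label of the sister-to-be.
#' @param new_tip label to add (must be absent).
#' @return the enlarged tree.
#' @export
graft_sister <- function(tree, existing_tip, new_tip) {
  i <- match(existing_tip, tree$tip.label)
  if (is.na(i)) stop("tip not in tree: ", existing_tip)
  if (new_tip %in% tree$tip.label) stop("tip already present: ", new_tip)
  L <- tree$edge.length[tree$edge[, 2] == i]
  tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                        tip.label = new_tip,
                        edge.length = L / 2,
                        Nnode = 1L),
                   class = "phylo")
  ape::bind.tree(tree, tip, where = i, position = L / 2)
}

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Shared-path-length covariance `C(1)` from the tree, with off-diagonal
#' elements multiplied by `lambda` (diagonals untouched): `lambda = 0` is a
#' star phylogeny, `lambda = 1` the Brownian expectation.
#'
#' @param tree a `phylo` object.
#' @param lambda scaling in \[0, 1\].
#' @return covariance matrix with species dimnames and attribute `lambda`.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  C <- ape::vcv(tree)
  scale_lambda(C, lambda)
}

scale_lambda <- function(C, lambda) {
  d <- diag(C)
  Cl <- C * lambda
  diag(Cl) <- d
  attr(Cl, "lambda") <- lambda
  Cl
}

#' Generalized least squares under a species covariance
#'
#' Fits `y = X beta + e` with `Var(e) = sigma^2 * D C D`, where `C` is the
#' (lambda-scaled) phylogenetic covariance and `D = diag(1/sqrt(w))` so
#' case weights act as precision multipliers: heavier-weighted species are
#' assumed measured with proportionally smaller residual variance. With an
#' identity covariance and unit weights this is ordinary least squares.
#' Solving is Cholesky-based; a singular design is an error naming the
#' collinear columns (no pseudo-inverse fallback).
#'
#' @param y numeric response.
#' @param X design matrix (include the intercept column yourself, e.g. via
#'   `cbind(1, ...)` or `model.matrix`).
#' @param covariance species covariance matrix aligned with `y` rows.
#' @param weights positive case weights (precision multipliers).
#' @return object of class `conc_gls` with coefficients, standard errors,
#'   t statistics, two-sided P values, `sigma2` (method-of-moments,
#'   df-corrected), ML `loglik`, residual df, and the ingredients needed
#'   for prediction-based diagnostics.
#' @export
gls_fit <- function(y, X, covariance, weights = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(covariance) == n, ncol(covariance) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-seq_len(qrX$rank)]
    stop("design matrix is rank deficient (collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "), ")")
  }
  w <- weights %||% rep(1, n)
  if (any(w <= 0)) stop("weights must be > 0")
  ds <- 1 / sqrt(w)
  V <- covariance * tcrossprod(ds)          # D C D
  R <- tryCatch(chol(V), error = function(e)
    stop("species covariance (with weights) is not positive definite"))
  # whiten: solve(t(R)) %*% .
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  fit <- lm.fit(Xt, yt)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  p <- ncol(X)
  df <- n - p
  sigma2_ml <- rss / n
  sigma2 <- rss / df
  XtX <- crossprod(Xt)
  covb <- sigma2 * chol2inv(chol(XtX))
  se <- sqrt(diag(covb))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  logdetV <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    se = setNames(se, colnames(X)),
    tstat = setNames(as.numeric(tstat), colnames(X)),
    pval = setNames(as.numeric(pval), colnames(X)),
    df = df, n = n, sigma2 = sigma2, sigma2_ml = sigma2_ml,
    loglik = loglik,
    lambda = attr(covariance, "lambda"),
    weights = w, y = y, X = X, V = V,
    fitted = as.numeric(X %*% beta),
    converged = TRUE
  ), class = "conc_gls")
}

#' @export
print.conc_gls <- function(x, ...) {
  cat("Generalized least squares fit (n =", x$n, ")\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    t = x$tstat, p = x$pval)
  print(signif(tab, 4))
  cat("sigma2 =", signif(x$sigma2, 4),
      " logLik(ML) =", signif(x$loglik, 6))
  if (!is.null(x$lambda)) cat("  lambda =", signif(x$lambda, 4))
  cat("\n")
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param fit a `conc_gls` or `conc_pglmm` fit.
#' @return data.frame of estimates, standard errors, statistics, P values.
#' @export
coef_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = as.numeric(fit$coefficients),
             se = as.numeric(fit$se),
             statistic = as.numeric(fit$tstat %||% fit$zstat),
             p = as.numeric(fit$pval),
             row.names = NULL)
}

#' Profile-ML estimation of Pagel's lambda in a GLS model
#'
#' Maximizes the ML log-likelihood of [gls_fit()] over `lambda` in \[0, 1\]
#' (bounded scalar optimization, tolerance 1e-6), with explicit endpoint
#' checks so the profile optimum is never below the boundary likelihoods.
#' An interior optimizer drifting to the lower bound (a "negative" optimum
#' on an unbounded scale) yields `lambda = 0`, mirroring the convention of
#' refitting with lambda fixed at zero.
#'
#' @param y,X,weights as in [gls_fit()].
#' @param tree a `phylo` whose tips match `names(y)`/rows of `X`, or a
#'   precomputed `C(1)` covariance matrix.
#' @return list with `lambda`, the fit at `lambda` (`fit`), `loglik`,
#'   `loglik0` (lambda = 0), `loglik1`, and `converged`.
#' @export
lambda_ml <- function(y, X, tree, weights = NULL) {
  if (length(y) < 4) stop("need at least 4 species to profile lambda")
  C1 <- if (inherits(tree, "phylo")) ape::vcv(tree) else as.matrix(tree)
  ll <- function(lam) gls_fit(y, X, scale_lambda(C1, lam), weights)$loglik
  opt <- tryCatch(optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6),
                  error = function(e) NULL)
  ll0 <- ll(0); ll1 <- ll(1)
  cand <- c(0, 1, if (!is.null(opt)) opt$maximum)
  vals <- c(ll0, ll1, if (!is.null(opt)) opt$objective)
  lam <- cand[which.max(vals)]
  fit <- gls_fit(y, X, scale_lambda(C1, lam), weights)
  list(lambda = lam, fit = fit, loglik = fit$loglik,
       loglik0 = ll0, loglik1 = ll1, converged = !is.null(opt))
}
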