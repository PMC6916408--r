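#' Maximum-likelihood phylogenetic generalized least squares
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V_lambda)` where `V` is the
#' Brownian-motion covariance of the tree and `V_lambda` its Pagel's-lambda
#' transform. `beta` is the GLS estimate, `sigma2` its ML estimate
#' (divisor `n`), and `lambda` is either fixed or profiled over `[0, 1]`.
#' Standard errors carry the `n/(n - k)` small-sample correction so
#' t-statistics follow the GLS convention on `n - k` degrees of freedom,
#' while the log-likelihood and AIC use the ML rate.
#'
#' @param y Named numeric response vector (names = tip labels).
#' @param X Design matrix with rownames matching tip labels (include the
#'   intercept column explicitly, or use [pgls()] with a formula).
#' @param tree A `phylo` tree containing all rows of `X`.
#' @param lambda A number in `[0, 1]` to fix Pagel's lambda, or `"free"` to
#'   maximize it on the profile likelihood (golden-section with a grid
#'   multistart to avoid local optima).
#' @param tol Convergence tolerance on the profile log-likelihood.
#' @return A `pgls_fit` object: coefficients table (`estimate`, `se`, `t`,
#'   `p`), `sigma2`, `lambda`, `logLik`, `n`, `k`, `df`, `AIC`, residuals and
#'   fitted values on the response scale.
#' @export
fit_pgls <- function(y, X, tree, lambda = 1, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  X <- as.matrix(X)
  if (is.null(rownames(X)) && !is.null(names(y))) rownames(X) <- names(y)
  if (is.null(names(y)) && !is.null(rownames(X))) names(y) <- rownames(X)
  if (is.null(names(y)))
    stop("y (or rownames of X) must carry species names matching tree tips")
  if (!all(names(y) %in% tree$tip.label))
    stop("species absent from tree: ",
         paste(setdiff(names(y), tree$tip.label), collapse = ", "))
  if (length(setdiff(tree$tip.label, names(y))) > 0)
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, names(y)))
  ord <- tree$tip.label
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  n <- length(y); k <- ncol(X)
  if (n <= k) stop("need n > k; n = ", n, ", k = ", k)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))

  V <- ape::vcv.phylo(tree)[ord, ord]
  dV <- diag(V)
  prof <- function(lam) {
    Vl <- V * lam; diag(Vl) <- dV
    .gls_core(y, X, Vl)
  }
  free <- identical(lambda, "free")
  if (free) {
    grid <- seq(0, 1, by = 0.1)
    ll_grid <- vapply(grid, function(l) prof(l)$logLik, numeric(1))
    i <- which.max(ll_grid)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- optimize(function(l) prof(l)$logLik, c(lo, hi),
                    maximum = TRUE, tol = tol)
    cand <- c(opt$maximum, 0, 1)
    ll_cand <- c(opt$objective, ll_grid[1L], ll_grid[length(grid)])
    lam_hat <- cand[which.max(ll_cand)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be in [0, 1] or \"free\"")
    lam_hat <- lambda
  }
  core <- prof(lam_hat)
  se <- sqrt(diag(core$XtViX_inv) * core$sigma2 * n / (n - k))
  tval <- core$beta / se
  df <- n - k
  pval <- 2 * pt(-abs(tval), df)
  k_total <- k + 1L + as.integer(free)
  fit <- list(
    coefficients = data.frame(term = colnames(X), estimate = core$beta,
                              se = se, t = tval, p = pval,
                              stringsAsFactors = FALSE, row.names = NULL),
    beta = setNames(core$beta, colnames(X)),
    sigma2 = core$sigma2, lambda = lam_hat,
    lambda_mode = if (free) "free" else "fixed",
    logLik = core$logLik, n = n, k = k, df = df, k_total = k_total,
    AIC = 2 * k_total - 2 * core$logLik,
    residuals = setNames(as.numeric(y - X %*% core$beta), ord),
    fitted = setNames(as.numeric(X %*% core$beta), ord),
    response = deparse(substitute(y))[1L], terms = colnames(X))
  class(fit) <- "pgls_fit"
  fit
}

# GLS at a fixed covariance: beta = (X'V^-1 X)^-1 X'V^-1 y, ML sigma2,
# exact multivariate-normal log-likelihood
.gls_core <- function(y, X, V) {
  n <- length(y)
  L <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance is not positive definite: ",
         conditionMessage(e)))
  wX <- backsolve(L, X, transpose = TRUE)
  wy <- backsolve(L, y, transpose = TRUE)
  XtViX <- crossprod(wX)
  qrx <- qr(XtViX)
  if (qrx$rank < ncol(X))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]], collapse = ", "))
  XtViX_inv <- chol2inv(chol(XtViX))
  beta <- as.numeric(XtViX_inv %*% crossprod(wX, wy))
  resid_w <- wy - wX %*% beta
  rss <- sum(resid_w^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  logLik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = beta, sigma2 = sigma2, logLik = logLik,
       XtViX_inv = XtViX_inv)
}

#' Formula interface to PGLS
#'
#' @param formula Model formula over columns of `data`.
#' @param data Data frame with a `species` column matching tree tips.
#' @param tree A `phylo` tree.
#' @param lambda Passed to [fit_pgls()].
#' @param ... Passed to [fit_pgls()].
#' @return A `pgls_fit`, with listwise-dropped species recorded in the
#'   `dropped` element.
#' @export
pgls <- function(formula, data, tree, lambda = 1, ...) {
  stopifnot("species" %in% names(data))
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[, vars, drop = FALSE]) &
    data$species %in% tree$tip.label
  dropped <- data$species[!keep]
  d <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  X <- stats::model.matrix(formula, mf)
  rownames(X) <- d$species
  y <- setNames(stats::model.response(mf), d$species)
  fit <- fit_pgls(y, X, tree, lambda = lambda, ...)
  fit$response <- deparse(formula[[2L]])
  fit$dropped <- as.character(dropped)
  fit
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (", x$lambda_mode, " lambda = ",
      formatC(x$lambda, digits = 4), ")\n", sep = "")
  cat("n =", x$n, " df =", x$df, " logLik =",
      formatC(x$logLik, digits = 6), " AIC =",
      formatC(x$AIC, digits = 6), "\n")
  printCoefmat(as.matrix(x$coefficients[, -1, drop = FALSE]),
               has.Pvalue = TRUE, P.values = TRUE)
  invisible(x)
}

#' Phylogenetic t-test for a clade grade shift
#'
#' Tests whether a flagged group departs from the allometric line shared with
#' the remaining tips, by entering a binary group indicator alongside the
#' covariates in a PGLS; the indicator's t and two-tailed p are the reported
#' phylogenetic t-test, its estimate the grade shift (intercept offset).
#'
#' @param y Named response vector.
#' @param covariates Matrix/data frame of covariates (may be `NULL`), rownames
#'   = species.
#' @param group_flag Named logical/0-1 vector marking the focal clade.
#' @param tree A `phylo` tree.
#' @param lambda Passed to [fit_pgls()].
#' @return A `pgls_fit` with element `group_term` naming the indicator row of
#'   the coefficient table.
#' @export
phylo_ttest <- function(y, covariates = NULL, group_flag, tree, lambda = 1) {
  sp <- names(y)
  if (is.null(sp)) stop("y must be named by species")
  g <- as.numeric(group_flag[sp])
  if (anyNA(g)) stop("group_flag missing for some species")
  if (length(unique(g)) < 2 || min(table(g)) < 2)
    stop("each group level needs at least 2 species")
  X <- matrix(1, length(sp), 1, dimnames = list(sp, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[sp, , drop = FALSE]
    X <- cbind(X, covariates)
  }
  X <- cbind(X, group = g)
  rownames(X) <- sp
  fit <- fit_pgls(y, X, tree, lambda = lambda)
  fit$group_term <- "group"
  fit
}

#' Likelihood-ratio test of fixed vs free lambda
#'
#' @param fit_fixed,fit_free `pgls_fit`s of the same response and design with
#'   lambda fixed and free.
#' @return List `statistic` (`2 * (logLik_free - logLik_fixed)`, clipped at
#'   0), `df = 1`, `p` from the chi-square reference.
#' @export
lr_test <- function(fit_fixed, fit_free) {
  stopifnot(inherits(fit_fixed, "pgls_fit"), inherits(fit_free, "pgls_fit"))
  if (!identical(fit_fixed$terms, fit_free$terms) ||
      fit_fixed$n != fit_free$n)
    stop("models are not nested: designs or species sets differ")
  stat <- 2 * (fit_free$logLik - fit_fixed$logLik)
  if (stat < -1e-8)
    stop("free-lambda logLik below fixed-lambda logLik beyond tolerance; ",
         "optimizer failure")
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Akaike information criterion of a fit
#'
#' AIC = 2 x (number of parameters) - 2 x log-likelihood, counting `beta`,
#' `sigma2`, and lambda when freely estimated.
#'
#' @param fit A `pgls_fit`.
#' @return AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  2 * fit$k_total - 2 * fit$logLik
}

#' AIC difference between two fits
#'
#' Reported as `aic(fit_a) - aic(fit_b)`: positive values favour `fit_b`
#' (lower AIC is better); differences above 2 indicate substantial support.
#'
#' @param fit_a,fit_b `pgls_fit`s on the same data.
#' @return Numeric AIC difference.
#' @export
delta_aic <- function(fit_a, fit_b) aic(fit_a) - aic(fit_b)

#' Response-scale residuals of a PGLS fit
#'
#' `y - X beta_hat`, tip-aligned: phylogenetically corrected deviations from
#' the fitted allometry, as used for residual-on-residual comparisons
#' between components.
#'
#' @param fit A `pgls_fit`.
#' @return Named residual vector.
#' @export
phylo_residuals <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$residuals
}

#' Ordinary (nonphylogenetic) least-squares regression
#'
#' Simple `y ~ x` regression via [stats::lm()], reported in the same shape as
#' the phylogenetic fits; used for residual-on-residual tests and for
#' regressions between sets of branch scalars.
#'
#' @param y,x Numeric vectors.
#' @return List: `intercept`, `slope`, `se`, `t`, `p` (slope, two-tailed on
#'   `n - 2` df), `n`, `r_squared`.
#' @export
ols_fit <- function(y, x) {
  ok <- stats::complete.cases(cbind(y, x))
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("x has zero variance")
  m <- lm(y ~ x)
  sm <- summary(m)
  list(intercept = unname(coef(m)[1L]), slope = unname(coef(m)[2L]),
       se = sm$coefficients[2L, 2L], t = sm$coefficients[2L, 3L],
       p = sm$coefficients[2L, 4L], n = length(y),
       r_squared = sm$r.squared)
}

#' Parametric-bootstrap power check for lambda model comparison
#'
#' Monte-Carlo model adequacy in the phylogenetic Monte Carlo style: both
#' models are fitted to the data, `nsim` datasets are simulated under each
#' fitted model, both models are refitted to every simulated dataset, and the
#' two likelihood-ratio distributions are compared. Power is the probability
#' that data generated under the free-lambda fit yield an LR above the 95th
#' percentile of the LR distribution under the fixed-lambda fit.
#'
#' @param tree A `phylo` tree.
#' @param y,X Response and design as in [fit_pgls()].
#' @param lambda_null Fixed lambda of the null model (default 1).
#' @param nsim Simulated datasets per model (default 200; below 50 a warning
#'   is issued).
#' @param seed Integer seed.
#' @return List: `lr_obs`, `lr_null` and `lr_alt` distributions, `crit`
#'   (95th percentile under the null), `power`, and the two fitted models.
#' @export
pmc_power <- function(tree, y, X, lambda_null = 1, nsim = 200, seed = 1) {
  if (nsim < 50) warning("nsim < 50 gives unstable power estimates")
  fit0 <- fit_pgls(y, X, tree, lambda = lambda_null)
  fit1 <- fit_pgls(y, X, tree, lambda = "free")
  lr_obs <- lr_test(fit0, fit1)$statistic
  set.seed(seed)
  sim_lr <- function(fit) {
    replicate(nsim, {
      ysim <- simulate_pgls(tree, X, fit$beta, fit$sigma2, fit$lambda)
      f0 <- fit_pgls(ysim, X, tree, lambda = lambda_null)
      f1 <- fit_pgls(ysim, X, tree, lambda = "free")
      lr_test(f0, f1)$statistic
    })
  }
  lr_null <- sim_lr(fit0)
  lr_alt <- sim_lr(fit1)
  crit <- as.numeric(quantile(lr_null, 0.95))
  list(lr_obs = lr_obs, lr_null = lr_null, lr_alt = lr_alt, crit = crit,
       power = mean(lr_alt > crit), fit_fixed = fit0, fit_free = fit1)
}

#' Simulate a response under a fitted PGLS model
#'
#' One multivariate-normal draw with mean `X beta` and covariance
#' `sigma2 * V_lambda`.
#'
#' @param tree A `phylo` tree.
#' @param X Design matrix (rownames = species).
#' @param beta Coefficient vector.
#' @param sigma2 Brownian rate.
#' @param lambda Pagel's lambda.
#' @return Named response vector in tree tip order.
#' @export
simulate_pgls <- function(tree, X, beta, sigma2, lambda = 1) {
  ord <- tree$tip.label
  X <- as.matrix(X)[ord, , drop = FALSE]
  V <- ape::vcv.phylo(tree)[ord, ord]
  dV <- diag(V)
  V <- V * lambda; diag(V) <- dV
  L <- chol(sigma2 * V)
  setNames(as.numeric(X %*% beta + t(L) %*% rnorm(length(ord))), ord)
}
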