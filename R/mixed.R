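#' Default parameter-expanded priors for the animal model
#'
#' G-side (phylogenetic variance): scaled inverse-chi-squared working prior
#' with `V = 1`, `nu = 1`, expanded by a normal multiplier `alpha ~
#' N(alpha_mu, alpha_V)` with `alpha_mu = 0`, `alpha_V = 1000`; R-side
#' (residual): `V = 1`, `nu = 0.002`; fixed effects: diffuse normal with
#' variance `1e8`.
#'
#' @param G_V,G_nu,alpha_mu,alpha_V G-side working prior and expansion.
#' @param R_V,R_nu R-side prior.
#' @param beta_var Fixed-effect prior variance.
#' @return A `prior_spec` list.
#' @export
animal_prior <- function(G_V = 1, G_nu = 1, alpha_mu = 0, alpha_V = 1000,
                         R_V = 1, R_nu = 0.002, beta_var = 1e8) {
  stopifnot(G_V > 0, alpha_V > 0, R_V > 0, beta_var > 0)
  structure(list(G_V = G_V, G_nu = G_nu, alpha_mu = alpha_mu,
                 alpha_V = alpha_V, R_V = R_V, R_nu = R_nu,
                 beta_var = beta_var), class = "prior_spec")
}

#' Gaussian phylogenetic mixed model over individual records
#'
#' The "animal model" at species level: individual measurements share their
#' species' random effect, whose covariance across species is
#' `sigma2_phylo * A` with `A` the tree's Brownian correlation (covariance
#' scaled to unit root-to-tip height). Sampled by blocked Gibbs: fixed and
#' random effects jointly multivariate normal given the variances, the
#' G-side variance under the parameter-expanded prior (working variance
#' scaled inverse-chi-squared times a normal expansion multiplier), the
#' residual variance scaled inverse-chi-squared.
#'
#' @param formula Fixed-effect formula over columns of `data`.
#' @param data Individual-level data frame with a `species` column; every
#'   species must be a tree tip.
#' @param tree A `phylo` tree.
#' @param prior A `prior_spec` from [animal_prior()].
#' @param iterations,burnin,thin Chain spec (defaults 50000/10000/20).
#' @param seed Integer seed.
#' @return A `mixed_posterior`: matrix `samples` (columns = fixed effects,
#'   `sigma2_phylo`, `sigma2_resid`), `ess`, chain spec, and a `summary`
#'   data frame with P-mean, 95% credible interval and pMCMC per fixed
#'   effect.
#' @export
fit_animal_model <- function(formula, data, tree,
                             prior = animal_prior(),
                             iterations = 50000, burnin = 10000, thin = 20,
                             seed = 1) {
  stopifnot(inherits(tree, "phylo"), "species" %in% names(data))
  vars <- all.vars(formula)
  if (!all(stats::complete.cases(data[, vars, drop = FALSE])))
    stop("response and covariates must be complete")
  bad <- setdiff(unique(data$species), tree$tip.label)
  if (length(bad) > 0)
    stop("species not in tree: ", paste(bad, collapse = ", "))
  n_keep <- floor((iterations - burnin) / thin)
  if (n_keep < 100)
    stop("chain too short: fewer than 100 retained samples")

  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  N <- length(y); p <- ncol(X)
  sp <- factor(data$species, levels = intersect(tree$tip.label,
                                                unique(data$species)))
  spid <- as.integer(sp); q <- nlevels(sp)

  keep_tips <- levels(sp)
  tr <- if (length(setdiff(tree$tip.label, keep_tips)) > 0)
    ape::drop.tip(tree, setdiff(tree$tip.label, keep_tips)) else tree
  A <- ape::vcv.phylo(tr)[keep_tips, keep_tips]
  A <- A / max(diag(A))
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
    stop("phylogenetic covariance is not positive definite"))

  # fixed cross-products; only alpha and the variances change per iteration
  XtX <- crossprod(X)
  Zt_counts <- tabulate(spid, nbins = q)
  XtZ <- t(rowsum(X, spid)) # p x q  (actually t of q x p)
  Xty <- crossprod(X, y)
  Zty <- as.numeric(rowsum(y, spid))

  set.seed(seed)
  b <- as.numeric(qr.coef(qr(X), y)); b[is.na(b)] <- 0
  v <- rep(0, q); alpha <- 1
  r0 <- y - X %*% b
  s2e <- max(var(as.numeric(r0)) / 2, 1e-6); s2v <- s2e
  keep <- matrix(NA_real_, n_keep, p + 2L)
  colnames(keep) <- c(colnames(X), "sigma2_phylo", "sigma2_resid")
  ki <- 0L
  for (it in seq_len(iterations)) {
    # (b, v) | alpha, variances: joint normal
    M <- matrix(0, p + q, p + q)
    M[1:p, 1:p] <- XtX / s2e + diag(1 / prior$beta_var, p)
    M[1:p, p + 1:q] <- alpha * XtZ / s2e
    M[p + 1:q, 1:p] <- t(M[1:p, p + 1:q, drop = FALSE])
    M[p + 1:q, p + 1:q] <- Ainv / s2v + diag(alpha^2 * Zt_counts / s2e, q)
    rhs <- c(Xty / s2e, alpha * Zty / s2e)
    Lc <- chol(M)
    mu <- backsolve(Lc, backsolve(Lc, rhs, transpose = TRUE))
    theta <- mu + backsolve(Lc, rnorm(p + q))
    b <- theta[1:p]; v <- theta[p + 1:q]

    # alpha | rest: scalar normal regression of residuals on Z v
    r <- y - as.numeric(X %*% b)
    w <- v[spid]
    prec <- sum(Zt_counts * v^2) / s2e + 1 / prior$alpha_V
    mean_a <- (sum(w * r) / s2e + prior$alpha_mu / prior$alpha_V) / prec
    alpha <- rnorm(1, mean_a, sqrt(1 / prec))

    # variances: scaled inverse-chi-squared updates
    s2v <- 1 / rgamma(1, (prior$G_nu + q) / 2,
                      rate = (prior$G_nu * prior$G_V +
                                as.numeric(t(v) %*% Ainv %*% v)) / 2)
    e <- r - alpha * w
    s2e <- 1 / rgamma(1, (prior$R_nu + N) / 2,
                      rate = (prior$R_nu * prior$R_V + sum(e^2)) / 2)

    if (it > burnin && (it - burnin) %% thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- c(b, alpha^2 * s2v, s2e)
    }
  }
  keep <- keep[seq_len(ki), , drop = FALSE]
  ess <- apply(keep, 2, .ess)
  if (any(ess[seq_len(p)] < 200))
    warning("effective sample size below 200 for: ",
            paste(colnames(keep)[seq_len(p)][ess[seq_len(p)] < 200],
                  collapse = ", "))
  summ <- do.call(rbind, lapply(seq_len(p), function(j)
    summarize_posterior(keep[, j])))
  summ <- data.frame(term = colnames(X), summ, row.names = NULL)
  structure(list(samples = keep, ess = ess, summary = summ,
                 chain = list(iterations = iterations, burnin = burnin,
                              thin = thin, seed = seed),
                 n_individuals = N, n_species = q),
            class = "mixed_posterior")
}

# effective sample size by initial-positive-sequence autocorrelation sum
.ess <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  acf_x <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(acf_x < 0)
  if (length(pos) > 0) acf_x <- acf_x[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(acf_x))
}

#' @export
print.mixed_posterior <- function(x, ...) {
  cat("Phylogenetic mixed model:", x$n_individuals, "individuals,",
      x$n_species, "species,", nrow(x$samples), "retained samples\n")
  print(x$summary, digits = 4)
  vm <- colMeans(x$samples[, c("sigma2_phylo", "sigma2_resid"), drop = FALSE])
  cat("posterior mean sigma2_phylo =", formatC(vm[1], digits = 4),
      " sigma2_resid =", formatC(vm[2], digits = 4), "\n")
  invisible(x)
}

#' Monte-Carlo two-tailed probability that a coefficient differs from zero
#'
#' `2 * min(P(draws <= 0), P(draws >= 0))`, floored at `1/n_draws` and capped
#' at 1.
#'
#' @param samples Numeric vector of at least 100 posterior draws.
#' @return pMCMC in `(0, 1]`.
#' @export
pmcmc <- function(samples) {
  n <- length(samples)
  if (n < 100) stop("need at least 100 draws")
  p <- 2 * min(mean(samples <= 0), mean(samples >= 0))
  min(max(p, 1 / n), 1)
}

#' Posterior mean, 95 percent credible interval and pMCMC
#'
#' @param samples Numeric vector of at least 100 posterior draws.
#' @return Data frame: `p_mean`, `ci_lower`, `ci_upper` (0.025/0.975
#'   quantiles), `p_mcmc`.
#' @export
summarize_posterior <- function(samples) {
  n <- length(samples)
  if (n < 100) stop("need at least 100 draws")
  ci <- unname(quantile(samples, c(0.025, 0.975)))
  data.frame(p_mean = mean(samples), ci_lower = ci[1L], ci_upper = ci[2L],
             p_mcmc = pmcmc(samples))
}
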