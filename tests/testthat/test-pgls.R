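test_that("PGLS with lambda 0 on a unit-depth tree equals ordinary least squares", {
  cs <- pgls_case(n = 24, seed = 3)
  f <- fit_pgls(cs$y, cs$X, cs$tree, lambda = 0)
  ols <- summary(lm(cs$y ~ cs$x))
  expect_equal(unname(f$beta), unname(coef(ols)[, 1]), tolerance = 1e-8)
  expect_equal(f$coefficients$se, unname(coef(ols)[, 2]), tolerance = 1e-8)
  expect_equal(f$coefficients$t, unname(coef(ols)[, 3]), tolerance = 1e-8)

  # star phylogeny, equal depths: identical to OLS at lambda 1 too
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, 12)
  x <- setNames(rnorm(12), star$tip.label)
  y <- setNames(1 + 2 * x + rnorm(12, 0, 0.3), star$tip.label)
  X <- cbind(`(Intercept)` = 1, x = x)
  fs <- fit_pgls(y, X, star, lambda = 1)
  olss <- summary(lm(y ~ x))
  expect_equal(unname(fs$beta), unname(coef(olss)[, 1]), tolerance = 1e-8)
  expect_equal(fs$coefficients$t, unname(coef(olss)[, 3]), tolerance = 1e-8)
})

test_that("PGLS equals the Cholesky-whitening oracle and nlme::gls", {
  cs <- pgls_case(n = 8, seed = 11)
  V <- ape::vcv.phylo(cs$tree)[names(cs$y), names(cs$y)]
  orc <- gls_whitening_oracle(cs$y, cs$X, V)
  f <- fit_pgls(cs$y, cs$X, cs$tree, lambda = 1)
  expect_equal(unname(f$beta), orc$beta, tolerance = 1e-8)
  expect_equal(f$logLik, orc$logLik, tolerance = 1e-8)
  expect_equal(unname(f$residuals), orc$resid_response, tolerance = 1e-8)

  skip_if_not_installed("nlme")
  d <- data.frame(y = cs$y, x = cs$x, sp = names(cs$y))
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(1, cs$tree, form = ~sp,
                                             fixed = TRUE), method = "ML")
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(f$coefficients$t, unname(summary(g)$tTable[, 3]),
               tolerance = 1e-6)
})

test_that("free-lambda profiling attains a local optimum and handles boundaries", {
  cs <- pgls_case(n = 60, seed = 21, lambda = 0.5, sigma2 = 0.5)
  f <- fit_pgls(cs$y, cs$X, cs$tree, lambda = "free")
  # profile value at the optimum beats a lambda grid
  for (lam in seq(0, 1, by = 0.2)) {
    fl <- fit_pgls(cs$y, cs$X, cs$tree, lambda = lam)
    expect_lte(fl$logLik, f$logLik + 1e-6)
  }
  expect_equal(f$k_total, f$k + 2L)
  # perturbing beta or sigma2 away from the ML solution lowers the density
  ll_at <- function(beta, s2) {
    V <- apply_lambda(phylo_vcv(cs$tree, names(cs$y)), f$lambda)$V
    r <- cs$y - cs$X %*% beta
    -0.5 * (length(cs$y) * log(2 * pi * s2) +
              determinant(V)$modulus[1] + t(r) %*% solve(V, r) / s2)
  }
  base <- ll_at(f$beta, f$sigma2)
  for (eps in c(-0.05, 0.05)) {
    expect_lte(ll_at(f$beta + eps, f$sigma2), base)
    expect_lte(ll_at(f$beta, f$sigma2 * (1 + eps)), base)
  }
})

test_that("scale equivariance: rescaling y rescales beta, leaves t and lambda alone", {
  cs <- pgls_case(n = 40, seed = 31, lambda = 0.7)
  f1 <- fit_pgls(cs$y, cs$X, cs$tree, lambda = "free")
  f2 <- fit_pgls(cs$y * 7, cs$X, cs$tree, lambda = "free")
  expect_equal(unname(f2$beta), unname(f1$beta) * 7, tolerance = 1e-6)
  expect_equal(f2$coefficients$t, f1$coefficients$t, tolerance = 1e-6)
  expect_equal(f2$coefficients$p, f1$coefficients$p, tolerance = 1e-6)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-5)
})

test_that("lr_test follows the chi-square reference and rejects non-nested fits", {
  mk <- function(ll, terms = c("a", "b"), n = 20) {
    structure(list(logLik = ll, terms = terms, n = n), class = "pgls_fit")
  }
  expect_equal(lr_test(mk(-50), mk(-50))$statistic, 0)
  expect_equal(lr_test(mk(-50), mk(-50))$p, 1)
  r <- lr_test(mk(-52), mk(-50))
  expect_equal(r$statistic, 4)
  expect_equal(r$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p, 0.0455, tolerance = 1e-3)
  expect_error(lr_test(mk(-52, terms = "a"), mk(-50)), "nested")
})

test_that("AIC counts beta, sigma2 and free lambda", {
  cs <- pgls_case(n = 20, seed = 41)
  f <- fit_pgls(cs$y, cs$X, cs$tree, lambda = 1) # k_total = 2 + 1
  expect_equal(aic(f), 2 * 3 - 2 * f$logLik)
  expect_equal(delta_aic(f, f), 0)
  ff <- fit_pgls(cs$y, cs$X, cs$tree, lambda = "free")
  expect_equal(aic(ff), 2 * 4 - 2 * ff$logLik)
})

test_that("phylogenetic residuals are response-scale deviations", {
  tree <- random_tree(10, seed = 51, scale_to_height = 1)
  X <- cbind(`(Intercept)` = rep(1, 10))
  rownames(X) <- tree$tip.label
  y <- setNames(3 + numeric(10), tree$tip.label)
  f <- fit_pgls(y + 0, X, tree, lambda = 0)
  expect_equal(unname(phylo_residuals(f)), rep(0, 10))

  y2 <- setNames(rnorm(10), tree$tip.label)
  f2 <- fit_pgls(y2, X, tree, lambda = 0)
  expect_equal(phylo_residuals(f2), y2 - mean(y2), tolerance = 1e-10)

  cs <- pgls_case(n = 10, seed = 61)
  V <- ape::vcv.phylo(cs$tree)[names(cs$y), names(cs$y)]
  orc <- gls_whitening_oracle(cs$y, cs$X, V)
  f3 <- fit_pgls(cs$y, cs$X, cs$tree, lambda = 1)
  expect_equal(unname(phylo_residuals(f3)), orc$resid_response,
               tolerance = 1e-8)
})

test_that("ols_fit matches the normal-equations oracle and catches degenerate x", {
  x <- 1:10
  r <- suppressWarnings(ols_fit(2 * x, x)) # zero-residual fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_lt(r$p, 1e-12)
  expect_error(ols_fit(rnorm(5), rep(1, 5)), "variance")

  set.seed(7)
  x2 <- rnorm(20); y2 <- 1 + 0.5 * x2 + rnorm(20)
  r2 <- ols_fit(y2, x2)
  Xm <- cbind(1, x2)
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y2)
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)
  expect_equal(r2$intercept, beta[1], tolerance = 1e-10)
})

test_that("phylo_ttest flags the group coefficient and validates inputs", {
  scen <- synthetic_mammal_scenario(seed = 5, n_tips = 60, clade_size = 10)
  d <- scen$data
  y <- setNames(d$log_cx, d$species)
  covs <- cbind(log_rob = d$log_rob); rownames(covs) <- d$species
  g <- setNames(d$in_clade, d$species)
  f <- phylo_ttest(y, covs, g, scen$tree, lambda = 1)
  expect_equal(f$group_term, "group")
  j <- match("group", f$coefficients$term)
  # built-in shift of 0.5 log units is detected
  expect_gt(f$coefficients$t[j], 2)
  expect_equal(f$df, f$n - 3L)

  expect_error(phylo_ttest(y, covs, setNames(rep(TRUE, length(y)), names(y)),
                           scen$tree), "2 species")
})

test_that("pmc_power is calibrated for self-comparison and grows with tree size", {
  cs <- pgls_case(n = 16, seed = 71, lambda = 1)
  p_small <- pmc_power(cs$tree, cs$y, cs$X, nsim = 60, seed = 1)
  # data generated under lambda = 1: the two fitted models nearly coincide
  expect_lt(p_small$power, 0.35)
  expect_warning(pmc_power(cs$tree, cs$y, cs$X, nsim = 20, seed = 1),
                 "unstable")

  cs2 <- pgls_case(n = 100, seed = 72, lambda = 0.5, sigma2 = 0.5)
  p_big <- pmc_power(cs2$tree, cs2$y, cs2$X, nsim = 60, seed = 2)
  cs3 <- pgls_case(n = 16, seed = 73, lambda = 0.5, sigma2 = 0.5)
  p_tiny <- pmc_power(cs3$tree, cs3$y, cs3$X, nsim = 60, seed = 3)
  expect_gt(p_big$power, p_tiny$power - 0.05)
  expect_gt(p_big$power, 0.5)
})
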