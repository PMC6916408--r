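test_that("pmcmc matches tail-probability oracles", {
  expect_equal(pmcmc(rep(1, 500) + runif(500)), 1 / 500)
  set.seed(1)
  sym <- rnorm(2000)
  expect_gt(pmcmc(sym), 0.9)
  z <- rnorm(1e5, 1.96, 1)
  expect_equal(pmcmc(z), 2 * pnorm(-1.96), tolerance = 0.1)
  expect_error(pmcmc(rnorm(50)), "100")
})

test_that("summarize_posterior reports mean, quantile CI and pMCMC", {
  s <- summarize_posterior(rep(3, 200))
  expect_equal(s$p_mean, 3)
  expect_equal(c(s$ci_lower, s$ci_upper), c(3, 3))
  set.seed(2)
  u <- runif(1e5)
  su <- summarize_posterior(u)
  expect_equal(su$p_mean, 0.5, tolerance = 0.01)
  expect_equal(su$ci_lower, 0.025, tolerance = 0.01)
  expect_equal(su$ci_upper, 0.975, tolerance = 0.01)
})

test_that("animal model on a star phylogeny recovers OLS fixed effects", {
  star <- ape::stree(30, "star")
  star$edge.length <- rep(1, 30)
  set.seed(3)
  x <- setNames(rnorm(30), star$tip.label)
  y <- 1 + 0.65 * x + rnorm(30, 0, 0.1)
  d <- data.frame(species = star$tip.label, y = y, x = x)
  fit <- fit_animal_model(y ~ x, d, star, iterations = 6000, burnin = 1000,
                          thin = 5, seed = 4)
  ols <- coef(lm(y ~ x, d))
  slope <- fit$summary[fit$summary$term == "x", ]
  expect_equal(slope$p_mean, unname(ols[2]), tolerance = 0.05)
  expect_lt(slope$p_mcmc, 0.01)
  expect_true(slope$ci_lower < 0.65 && slope$ci_upper > 0.65)
})

test_that("animal model recovers a known slope with phylogenetic signal", {
  tree <- random_tree(40, seed = 5, scale_to_height = 1)
  x_sp <- simulate_bm(tree, 1, 0, seed = 6)
  u <- simulate_bm(tree, 0.3, 0, seed = 7) # phylogenetic species effect
  set.seed(8)
  d <- data.frame(species = rep(tree$tip.label, each = 3))
  d$x <- x_sp[d$species] + rnorm(nrow(d), 0, 0.05)
  d$y <- 0.5 + 0.65 * d$x + u[d$species] + rnorm(nrow(d), 0, 0.1)
  fit <- fit_animal_model(y ~ x, d, tree, iterations = 8000, burnin = 2000,
                          thin = 5, seed = 9)
  slope <- fit$summary[fit$summary$term == "x", ]
  expect_true(slope$ci_lower < 0.65 && slope$ci_upper > 0.65)
  # phylogenetic variance is found
  expect_gt(mean(fit$samples[, "sigma2_phylo"]), 0.02)
})

test_that("two chains at different seeds agree within Monte-Carlo error", {
  tree <- random_tree(25, seed = 10, scale_to_height = 1)
  x_sp <- simulate_bm(tree, 1, 0, seed = 11)
  set.seed(12)
  d <- data.frame(species = rep(tree$tip.label, each = 2))
  d$x <- x_sp[d$species]
  d$y <- 0.3 + 0.5 * d$x + rnorm(nrow(d), 0, 0.2)
  f1 <- fit_animal_model(y ~ x, d, tree, iterations = 8000, burnin = 2000,
                         thin = 5, seed = 1)
  f2 <- fit_animal_model(y ~ x, d, tree, iterations = 8000, burnin = 2000,
                         thin = 5, seed = 2)
  for (term in c("(Intercept)", "x")) {
    m1 <- f1$summary[f1$summary$term == term, "p_mean"]
    m2 <- f2$summary[f2$summary$term == term, "p_mean"]
    mcse <- sd(f1$samples[, term]) / sqrt(f1$ess[term]) +
      sd(f2$samples[, term]) / sqrt(f2$ess[term])
    expect_lt(abs(m1 - m2), 3 * mcse + 1e-8)
  }
})

test_that("flattening the expanded G prior does not shrink the phylogenetic-variance posterior", {
  tree <- random_tree(20, seed = 13, scale_to_height = 1)
  u <- simulate_bm(tree, 0.3, 0, seed = 14)
  set.seed(15)
  d <- data.frame(species = rep(tree$tip.label, each = 2))
  d$y <- 1 + u[d$species] + rnorm(nrow(d), 0, 0.1)
  f_tight <- fit_animal_model(y ~ 1, d, tree,
                              prior = animal_prior(alpha_V = 1),
                              iterations = 8000, burnin = 2000, thin = 5,
                              seed = 16)
  f_flat <- fit_animal_model(y ~ 1, d, tree,
                             prior = animal_prior(alpha_V = 1000),
                             iterations = 8000, burnin = 2000, thin = 5,
                             seed = 16)
  iqr <- function(f) diff(quantile(f$samples[, "sigma2_phylo"],
                                   c(0.25, 0.75)))
  expect_gte(iqr(f_flat), 0.8 * iqr(f_tight))
})

test_that("chain validation rejects too-short runs and off-tree species", {
  tree <- random_tree(5, seed = 17)
  d <- data.frame(species = tree$tip.label, y = rnorm(5))
  expect_error(fit_animal_model(y ~ 1, d, tree, iterations = 500,
                                burnin = 400, thin = 10), "100 retained")
  d2 <- d; d2$species[1] <- "nope"
  expect_error(fit_animal_model(y ~ 1, d2, tree), "not in tree")
})
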