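test_that("unit scalars reproduce the single-rate Brownian likelihood exactly", {
  cs <- pgls_case(n = 20, seed = 2)
  f <- fit_pgls(cs$y, cs$X, cs$tree, lambda = 1)
  ll <- vr_loglik(cs$y, cs$X, cs$tree, scalar_map(), f$beta, f$sigma2)
  expect_equal(ll, f$logLik, tolerance = 1e-10)
})

test_that("a scaled terminal branch changes the covariance as computed by hand", {
  tr <- tree3()
  y <- c(A = 0.1, B = 0.2, C = -0.3)
  X <- cbind(`(Intercept)` = c(A = 1, B = 1, C = 1))
  eC <- which(tr$edge[, 2] == match("C", tr$tip.label))
  m <- scalar_map(edge = eC, type = "branch", value = 4)
  # C's depth rises from 2 to 8; A,B rows unchanged
  V <- ape::vcv.phylo(tr)
  V["C", "C"] <- 8
  r <- y - 0.05
  ll_dense <- -0.5 * (3 * log(2 * pi * 0.2) + determinant(V)$modulus[1] +
                        t(r) %*% solve(V, r) / 0.2)
  expect_equal(vr_loglik(y, X, tr, m, beta = 0.05, sigma2 = 0.2),
               as.numeric(ll_dense), tolerance = 1e-10)
})

test_that("scaling all branches by c and sigma2 by 1/c leaves the likelihood unchanged", {
  tr <- random_tree(15, seed = 3, scale_to_height = 1)
  y <- simulate_bm(tr, 1, 0, seed = 4)
  X <- cbind(`(Intercept)` = setNames(rep(1, 15), tr$tip.label))
  ne <- nrow(tr$edge)
  m <- scalar_map(edge = seq_len(ne), type = rep("branch", ne),
                  value = rep(3, ne))
  expect_equal(vr_loglik(y, X, tr, m, 0.1, 0.2 / 3),
               vr_loglik(y, X, tr, scalar_map(), 0.1, 0.2),
               tolerance = 1e-10)
})

test_that("clade scalars compound multiplicatively with branch scalars", {
  tr <- random_tree(10, seed = 5)
  desc <- mosaicbrain:::.edge_descendants(tr)
  internal <- which(tr$edge[, 2] > 10)
  e <- internal[which.max(lengths(desc[internal]))]
  m <- scalar_map(edge = c(e, desc[[e]][2]),
                  type = c("clade", "branch"), value = c(2, 5))
  mult <- effective_multipliers(tr, m)
  expect_equal(mult[desc[[e]][2]], 10)
  expect_equal(mult[setdiff(desc[[e]], desc[[e]][2])],
               rep(2, length(desc[[e]]) - 1))
  expect_equal(mult[-desc[[e]]], rep(1, nrow(tr$edge) - length(desc[[e]])))
})

test_that("prior predictive draws never break positive-definiteness", {
  tr <- random_tree(20, seed = 6, scale_to_height = 1)
  y <- simulate_bm(tr, 1, 0, seed = 7)
  X <- cbind(`(Intercept)` = setNames(rep(1, 20), tr$tip.label))
  pr <- vr_prior()
  ne <- nrow(tr$edge)
  set.seed(8)
  for (i in 1:1000) {
    k <- min(rpois(1, pr$k_mean), pr$kmax)
    m <- if (k == 0) scalar_map() else
      scalar_map(edge = sample.int(ne, k),
                 type = sample(c("branch", "clade"), k, replace = TRUE),
                 value = exp(rnorm(k, 0, pr$rate_sd_log)))
    ll <- vr_loglik(y, X, tr, m, beta = 0, sigma2 = 1)
    expect_true(is.finite(ll))
  }
})

test_that("bayes_factor applies the doubled log-marginal difference and labels", {
  b <- bayes_factor(-100, -110)
  expect_equal(b$bf, 20)
  expect_equal(b$support, "very strong")
  expect_equal(bayes_factor(-50, -50)$bf, 0)
  expect_equal(bayes_factor(-50, -50)$support, "none")
  b7 <- bayes_factor(-100, -103.5)
  expect_equal(b7$bf, 7)
  expect_equal(b7$support, "strong")
})

test_that("scaled branch lengths follow posterior mean and median multipliers", {
  tr <- random_tree(6, seed = 9)
  ne <- nrow(tr$edge)
  fake <- function(mult) {
    structure(list(mult = mult, mean_scalar = colMeans(mult),
                   median_scalar = apply(mult, 2, median), tree = tr),
              class = "vr_posterior")
  }
  # constant scalar 2 on edge 1
  m1 <- matrix(1, 5, ne); m1[, 1] <- 2
  sc <- scaled_branch_lengths(fake(m1), "mean")
  expect_equal(sc$edge.length[1], 2 * tr$edge.length[1])
  expect_equal(sc$edge.length[-1], tr$edge.length[-1])
  # empty posterior: identity
  sc0 <- scaled_branch_lengths(fake(matrix(1, 5, ne)), "median")
  expect_equal(sc0$edge.length, tr$edge.length)
  # samples {1, 2, 9}: mean x4, median x2
  m2 <- matrix(1, 3, ne); m2[, 2] <- c(1, 2, 9)
  expect_equal(scaled_branch_lengths(fake(m2), "mean")$edge.length[2],
               4 * tr$edge.length[2])
  expect_equal(scaled_branch_lengths(fake(m2), "median")$edge.length[2],
               2 * tr$edge.length[2])
})

test_that("rank_deviant_branches orders by scaled/raw ratio", {
  tr <- random_tree(8, seed = 10)
  sc <- tr
  sc$edge.length[3] <- tr$edge.length[3] * 5
  top <- rank_deviant_branches(sc, tr, k = 2)
  expect_equal(top$edge[1], 3L)
  expect_equal(top$ratio[1], 5)
  # all ratios 1: nothing exceeds ratio 1
  same <- rank_deviant_branches(tr, tr, k = 4)
  expect_true(all(same$ratio == 1))
})

test_that("compare_scalars regresses one scalar set on the other", {
  a <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(compare_scalars(a, a)) # zero-residual fit
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_error(compare_scalars(1:5, 1:4), "same branch")
  # independent scalars are usually unassociated
  set.seed(11)
  hits <- replicate(20, {
    abs(compare_scalars(exp(rnorm(30, 0, 0.5)),
                        exp(rnorm(30, 0, 0.5)))$t) < 2
  })
  expect_gte(mean(hits), 0.9 - 0.15) # binomial slack at 20 reps
})

test_that("stepping stone matches the quadrature marginal likelihood of the null model", {
  tr <- random_tree(12, seed = 4, scale_to_height = 1)
  x <- simulate_bm(tr, 1, 0, seed = 5)
  set.seed(6)
  y <- setNames(0.5 + 0.8 * x + simulate_bm(tr, 0.3, 0), tr$tip.label)
  X <- cbind(`(Intercept)` = 1, x = x); rownames(X) <- tr$tip.label
  pr <- vr_prior()
  oracle <- null_mlh_quadrature(y, X, tr, pr)
  ss <- stepping_stone(y, X, tr, "null", K = 16, iter_per_stone = 500,
                       burnin_per_stone = 150, prior = pr, seed = 7)
  expect_lt(abs(ss$log_mlh - oracle), 0.5)
  expect_true(all(diff(ss$powers) > 0))
  expect_equal(ss$powers[ss$K], 1)

  # estimator consistency across stone counts
  ss10 <- stepping_stone(y, X, tr, "null", K = 10, iter_per_stone = 500,
                         burnin_per_stone = 150, prior = pr, seed = 8)
  ss50 <- stepping_stone(y, X, tr, "null", K = 50, iter_per_stone = 500,
                         burnin_per_stone = 150, prior = pr, seed = 9)
  expect_lt(abs(ss10$log_mlh - ss50$log_mlh),
            2 * (ss10$se + ss50$se) + 0.3)
})

test_that("the sampler finds a planted clade rate shift", {
  hits <- vapply(1:3, function(seed) {
    sc <- synthetic_rate_shift_scenario(seed, rate = 10)
    post <- run_vr_mcmc(sc$y, sc$X, sc$tree, iterations = 8000,
                        burnin = 2000, thin = 10, seed = seed + 50)
    mean(post$mean_scalar[sc$clade_edges]) >
      mean(post$mean_scalar[-sc$clade_edges])
  }, logical(1))
  expect_true(all(hits))
})

test_that("homogeneous data yield scalar maps close to identity", {
  sc <- synthetic_rate_shift_scenario(3, rate = 1)
  post <- run_vr_mcmc(sc$y, sc$X, sc$tree, iterations = 8000, burnin = 2000,
                      thin = 10, seed = 60)
  expect_lt(mean(post$n_scalars), 4)
  expect_gte(mean(post$median_scalar >= 0.5 & post$median_scalar <= 2),
             0.95)
})
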