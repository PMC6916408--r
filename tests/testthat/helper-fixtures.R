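# shared in-code fixtures; everything is generated, nothing is stored

tree3 <- function() read_tree("((A:1,B:1):1,C:2):0;")

# 6-tip dated backbone (height 100) with a monophyletic {A,B,C} clade of
# crown age 50, and a donor containing {A,B,C} (crown age 25) plus F
splice_fixture <- function() {
  list(backbone = read_tree(
         "(((A:50,(B:25,C:25):25):25,G:75):25,(D:80,E:80):20):0;"),
       donor = read_tree("(A:25,((B:10,C:10):5,F:15):10):0;"),
       anchor = c("A", "B", "C"))
}

# brute-force phylogenetic covariance: explicit root-path enumeration
vcv_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  path_edges <- function(tip) {
    out <- integer(); node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      out <- c(out, e); node <- tree$edge[e, 1]
    }
    out
  }
  paths <- lapply(seq_len(ntip), path_edges)
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip))
    for (j in seq_len(ntip))
      V[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  V
}

# GLS by explicit Cholesky whitening then OLS on the whitened system
gls_whitening_oracle <- function(y, X, V) {
  L <- t(chol(V))
  wy <- solve(L, y); wX <- solve(L, X)
  beta <- solve(crossprod(wX), crossprod(wX, wy))
  resid <- wy - wX %*% beta
  n <- length(y)
  sigma2 <- sum(resid^2) / n
  logLik <- -0.5 * (n * log(2 * pi * sigma2) +
                      2 * sum(log(diag(L))) + n)
  list(beta = as.numeric(beta), sigma2 = sigma2, logLik = logLik,
       resid_response = as.numeric(y - X %*% beta))
}

# analytic marginal likelihood of the single-rate model: beta integrated in
# closed form (Gaussian), sigma2 by adaptive quadrature over its prior
null_mlh_quadrature <- function(y, X, tree, prior) {
  ord <- tree$tip.label
  y <- y[ord]; X <- as.matrix(X)[ord, , drop = FALSE]
  V <- ape::vcv.phylo(tree)[ord, ord]
  n <- length(y)
  log_m_given_s2 <- function(s2) {
    S <- s2 * V + prior$beta_sd^2 * X %*% t(X)
    -0.5 * (n * log(2 * pi) + determinant(S)$modulus[1] +
              as.numeric(t(y) %*% solve(S, y)))
  }
  ig_log_dens <- function(s2) {
    dgamma(1 / s2, prior$sigma2_shape, rate = prior$sigma2_rate,
           log = TRUE) - 2 * log(s2)
  }
  f <- Vectorize(function(s2) exp(log_m_given_s2(s2) + ig_log_dens(s2)))
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}

# small regression dataset simulated under BM on a random tree
pgls_case <- function(n = 20, seed = 1, beta = c(1, 0.5), sigma2 = 0.2,
                      lambda = 1) {
  tree <- random_tree(n, seed = seed, scale_to_height = 1)
  x <- simulate_bm(tree, 1, 0, seed = seed + 100)
  X <- cbind(`(Intercept)` = 1, x = x)
  rownames(X) <- tree$tip.label
  set.seed(seed + 200)
  y <- simulate_pgls(tree, X, beta, sigma2, lambda)
  list(tree = tree, X = X, x = x, y = y)
}
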