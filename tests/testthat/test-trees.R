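test_that("read_tree parses Newick, rejects malformed input and trees without lengths", {
  tr <- read_tree("(A:1,B:1):0;")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(node_depths(tr)[1:2]), c(1, 1))

  tr3 <- tree3()
  expect_equal(ape::Ntip(tr3), 3L)
  expect_true(is_ultrametric(tr3))
  expect_equal(max(node_depths(tr3)), 2)

  expect_error(read_tree("((A:1,B:1):1,C:2)):0;"), "character")
  expect_error(read_tree("((A:1,B:1):1,C:2"), "unclosed")
  expect_error(read_tree("((A,B),C);"), "branch lengths")
})

test_that("Nexus write-read round-trips topology and branch lengths", {
  tr <- read_tree("((A:1,(B:0.5,C:0.5):0.5):1,(D:1.5,E:1.5):0.5):0;")
  tf <- tempfile(fileext = ".nex")
  write_tree(tr, tf, format = "nexus")
  back <- read_tree(tf)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_true(ape::all.equal.phylo(back, tr, use.edge.length = TRUE))
  d0 <- node_depths(tr)[seq_len(5)][order(tr$tip.label)]
  d1 <- node_depths(back)[seq_len(5)][order(back$tip.label)]
  expect_equal(unname(d1), unname(d0), tolerance = 1e-9)

  nwk <- write_tree(tr)
  expect_true(ape::all.equal.phylo(read_tree(nwk), tr,
                                   use.edge.length = TRUE))
})

test_that("splice_clade rescales by the LCA age ratio and keeps the tree dated", {
  fx <- splice_fixture()
  sp <- splice_clade(fx$backbone, fx$donor, fx$anchor)
  info <- attr(sp, "splice")
  expect_equal(info$ratio, 2) # backbone crown 50, donor crown 25
  expect_equal(info$stem_adjustment, 0)
  # 6 backbone tips - 3 replaced + 4 donor tips
  expect_equal(ape::Ntip(sp), 7L)
  expect_true(all(c("A", "B", "C", "F") %in% sp$tip.label))
  expect_true(is_ultrametric(sp, tol = 1e-6))
  # every donor branch doubled
  eB <- sp$edge.length[sp$edge[, 2] == match("B", sp$tip.label)]
  expect_equal(eB, 20)

  # ratio exactly 1 leaves donor branch lengths unchanged
  dn2 <- fx$donor
  dn2$edge.length <- dn2$edge.length * 2 # crown age now 50 = backbone's
  sp2 <- splice_clade(fx$backbone, dn2, fx$anchor)
  expect_equal(attr(sp2, "splice")$ratio, 1)
  eB2 <- sp2$edge.length[sp2$edge[, 2] == match("B", sp2$tip.label)]
  expect_equal(eB2, 20)

  expect_error(splice_clade(fx$backbone, fx$donor, c("A", "B", "G")),
               "monophyletic")
})

test_that("phylo_vcv matches the path-enumeration oracle and hand values", {
  v <- phylo_vcv(tree3())
  expect_equal(v$V["A", "B"], 1)
  expect_equal(v$V["A", "A"], 2)
  expect_equal(v$V["A", "C"], 0)
  expect_equal(v$lambda, 1)

  v2 <- phylo_vcv(read_tree("(A:1,B:1):0;"))
  expect_equal(unname(v2$V), diag(2), ignore_attr = TRUE)

  for (seed in 1:3) {
    tree <- random_tree(10, seed = seed)
    V <- phylo_vcv(tree)$V
    expect_equal(V, vcv_oracle(tree), tolerance = 1e-10)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= -1e-9)
    expect_equal(V, t(V))
  }
  expect_error(phylo_vcv(tree3(), c("A", "Z")), "unknown")
})

test_that("apply_lambda scales off-diagonals only and composes multiplicatively", {
  v <- phylo_vcv(tree3())
  expect_equal(apply_lambda(v, 1)$V, v$V)
  v0 <- apply_lambda(v, 0)
  expect_equal(unname(v0$V), diag(c(2, 2, 2)), ignore_attr = TRUE)
  vh <- apply_lambda(v, 0.5)
  expect_equal(vh$V["A", "B"], 0.5)
  expect_equal(diag(vh$V), diag(v$V))

  vab <- apply_lambda(apply_lambda(v, 0.6), 0.5)
  expect_equal(vab$V["A", "B"], 0.3)
  expect_equal(vab$lambda, 0.3)
  expect_error(apply_lambda(v, 1.2), "lambda")
  expect_error(apply_lambda(v, -0.1), "lambda")
})

test_that("is_ultrametric discriminates by tolerance", {
  expect_true(is_ultrametric(read_tree("(A:1,B:1):0;")))
  expect_false(is_ultrametric(read_tree("(A:1,B:2):0;")))
  expect_true(is_ultrametric(read_tree("(A:1,B:2):0;"), tol = 1.5))
})

test_that("lambda as a branch-length transform reproduces apply_lambda", {
  tree <- random_tree(12, seed = 9, scale_to_height = 1)
  for (lam in c(0, 0.35, 1)) {
    tr2 <- tree
    tr2$edge.length <- mosaicbrain:::.lambda_edge_lengths(tree, lam)
    expect_equal(ape::vcv.phylo(tr2),
                 apply_lambda(phylo_vcv(tree), lam)$V[tree$tip.label,
                                                      tree$tip.label],
                 tolerance = 1e-12)
  }
})
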