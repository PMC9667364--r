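test_that("phylogenetic covariance reproduces hand-built path lengths", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  C <- phylo_covariance(star)$C
  expect_equal(unname(C), diag(4), tolerance = 1e-12)

  cherry <- ape::read.tree(text = "((a:0.5,b:0.5):1.0,c:1.5);")
  C2 <- phylo_covariance(cherry)$C
  expect_equal(C2["a", "a"], 1.5)
  expect_equal(C2["a", "b"], 1.0)
  expect_equal(C2["a", "c"], 0)
})

test_that("covariance equals brute-force MRCA path enumeration and ape::vcv", {
  tr <- make_tree(5, seed = 3)
  C <- phylo_covariance(tr)$C
  bf <- brute_force_vcv(tr)
  expect_equal(C, bf[rownames(C), colnames(C)], tolerance = 1e-12)
  tr2 <- make_tree(40, seed = 8)
  C2 <- phylo_covariance(tr2)$C
  V <- ape::vcv(tr2)
  expect_equal(C2, V[rownames(C2), colnames(C2)], tolerance = 1e-12)
})

test_that("pruning to a tip subset matches pruning the tree first", {
  tr <- make_tree(12, seed = 2)
  keep <- tr$tip.label[c(2, 5, 7, 11)]
  C_sub <- phylo_covariance(tr, keep)$C
  C_pruned <- phylo_covariance(ape::keep.tip(tr, keep))$C
  expect_equal(C_sub[keep, keep], C_pruned[keep, keep], tolerance = 1e-12)
  expect_error(phylo_covariance(tr, c(keep, "nope", "missing2")),
               "nope.*missing2|missing2.*nope")
})

test_that("tip names are matched after whitespace/underscore normalization", {
  tr <- make_tree(4, seed = 1)
  tr$tip.label <- c("Xenopus laevis", "Bufo_bufo", "Rana  temporaria", "Hyla_x")
  C <- phylo_covariance(tr, c("Xenopus_laevis", "Bufo bufo"))$C
  expect_setequal(rownames(C), c("Xenopus_laevis", "Bufo_bufo"))
})

test_that("lambda transform scales only the off-diagonal", {
  cherry <- ape::read.tree(text = "((a:0.5,b:0.5):1.0,c:1.5);")
  C <- phylo_covariance(cherry)$C
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- lambda_transform(C, 0.5)
  expect_equal(half["a", "b"], 0.5)
  expect_equal(diag(half), diag(C))
  expect_error(lambda_transform(C, 1.2), "0, 1")
  expect_error(lambda_transform(C, -0.1), "0, 1")
})

test_that("zero-length terminal branches are regularized with a warning", {
  tr <- ape::read.tree(text = "((a:0,b:0.5):1.0,c:1.5);")
  expect_warning(cv <- phylo_covariance(tr), "zero-length")
  expect_gt(det(cv$C), 0)
})

test_that("make_tree yields seeded ultrametric unit-height pure-birth trees", {
  t2 <- make_tree(2, seed = 1)
  expect_equal(sort(t2$tip.label), c("sp0001", "sp0002"))
  expect_equal(unname(ape::node.depth.edgelength(t2)[1:2]), c(1, 1),
               tolerance = 1e-12)

  t126 <- make_tree(126, seed = 5)
  expect_equal(t126$Nnode, 125L)
  depths <- ape::node.depth.edgelength(t126)[1:126]
  expect_lt(diff(range(depths)), 1e-9)

  expect_identical(ape::write.tree(make_tree(30, seed = 9)),
                   ape::write.tree(make_tree(30, seed = 9)))
  expect_false(identical(ape::write.tree(make_tree(30, seed = 9)),
                         ape::write.tree(make_tree(30, seed = 10))))
})

test_that("simulate_bm is deterministic and matches the tree covariance", {
  tr <- make_tree(16, seed = 4)
  X1 <- simulate_bm(tr, n_traits = 3, rate = 2, lambda = 0.7, seed = 11)
  X2 <- simulate_bm(tr, n_traits = 3, rate = 2, lambda = 0.7, seed = 11)
  expect_identical(X1, X2)

  # Monte-Carlo covariance across replicates matches C on a 3-tip tree
  cherry <- ape::read.tree(text = "((a:0.5,b:0.5):1.0,c:1.5);")
  C <- phylo_covariance(cherry)$C
  reps <- vapply(1:4000, function(i) {
    simulate_bm(cherry, 1, rate = 1, lambda = 1, seed = i)[, 1]
  }, numeric(3))
  expect_equal(unname(cov(t(reps))), unname(C[rownames(reps), rownames(reps)]),
               tolerance = 0.12)

  # lambda = 0: traits i.i.d. across species (off-diagonal covariance ~ 0)
  reps0 <- vapply(1:4000, function(i) {
    simulate_bm(cherry, 1, rate = 1, lambda = 0, seed = 10000 + i)[, 1]
  }, numeric(3))
  S0 <- cov(t(reps0))
  expect_lt(max(abs(S0[upper.tri(S0)])), 0.08)
  expect_equal(unname(diag(S0)), unname(diag(C)[rownames(reps0)]),
               tolerance = 0.12)
  expect_error(simulate_bm(cherry, 1, rate = 0), "> 0")
})
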