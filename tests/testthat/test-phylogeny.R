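test_that("distance corrections follow their closed forms", {
  # 10% observed difference over 100 ungapped columns
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 90), rep("C", 10)), collapse = "")
  c_ <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  aln <- c(x = a, y = b, z = c_)
  expect_equal(protein_distance(aln, "none")["x", "y"], 0.1)
  expect_equal(protein_distance(aln, "poisson")["x", "y"], -log(0.9),
               tolerance = 1e-12)
  expect_equal(protein_distance(aln, "kimura")["x", "y"],
               -log(1 - 0.1 - 0.01 / 5), tolerance = 1e-12)
  ident <- c(x = a, y = a, z = a)
  for (corr in c("none", "poisson", "kimura"))
    expect_true(all(protein_distance(ident, corr) == 0))
})

test_that("kimura >= poisson >= p over the correction domain", {
  p <- seq(0.01, 0.74, by = 0.01)
  pois <- -log(1 - p)
  kim <- -log(1 - p - p^2 / 5)
  expect_true(all(kim >= pois & pois >= p))
})

test_that("gapped columns are excluded pairwise", {
  aln <- c(x = "AAAAA--CCC", y = "AAAAACCCCC", z = "AAAAACC--C")
  d <- protein_distance(aln, "none")
  expect_equal(d["x", "y"], 0)            # 8 shared columns, all equal
  expect_equal(d["x", "z"], 0)
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(123)
  for (k in 1:40) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n, br = function(nn) runif(nn, 0.05, 1))
    tr <- ape::unroot(tr)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D[tr$tip.label, tr$tip.label])
    expect_equal(as.numeric(ape::dist.topo(est, tr)), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[tr$tip.label, tr$tip.label] -
                        D[tr$tip.label, tr$tip.label])), 1e-8)
  }
})

test_that("three taxa resolve by the three-point formulas", {
  D <- base::matrix(c(0, 0.3, 0.5,
                      0.3, 0, 0.4,
                      0.5, 0.4, 0), 3, 3,
                    dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2L])], tr$tip.label)
  expect_equal(len[["a"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(len[["b"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(len[["c"]], (0.5 + 0.4 - 0.3) / 2)
})

test_that("equidistant taxa resolve deterministically", {
  D <- base::matrix(1, 5, 5,
                    dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("bootstrap supports live in [0,1]; one replicate gives 0/1", {
  fam <- demo_family()
  aln <- fam$alignment
  bt1 <- bootstrap_support(aln, n_replicates = 1, seed = 3)
  sup <- attr(bt1, "bipartition_support")
  expect_true(all(sup %in% c(0, 1)))
  bt <- bootstrap_support(aln, n_replicates = 25, seed = 3)
  sup <- attr(bt, "bipartition_support")
  expect_true(all(sup >= 0 & sup <= 1))
})

test_that("a deep split earns near-unit support", {
  fam <- demo_family()
  bt <- bootstrap_support(fam$alignment, n_replicates = 100, seed = 1)
  expect_gte(split_support(bt, paste0("t", 1:6, "_A")), 0.99)
})

test_that("column order does not affect the full-data tree", {
  fam <- demo_family()
  aln <- fam$alignment
  m <- do.call(rbind, strsplit(unname(aln), ""))
  set.seed(4)
  perm <- sample(ncol(m))
  aln_perm <- setNames(apply(m[, perm], 1, paste, collapse = ""), names(aln))
  t1 <- neighbor_joining(protein_distance(aln))
  t2 <- neighbor_joining(protein_distance(aln_perm))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("outgroup rooting bisects the outgroup edge and is idempotent", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,og:4):1):1);")
  tr <- ape::unroot(tr)
  rooted <- root_with_outgroup(tr, "og")
  expect_true(ape::is.rooted(rooted))
  root_kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2L]
  og_idx <- match("og", rooted$tip.label)
  expect_true(og_idx %in% root_kids)
  # outgroup pendant edge split at its midpoint
  og_len <- rooted$edge.length[rooted$edge[, 2L] == og_idx]
  expect_equal(og_len, 2)
  # ingroup side unchanged
  ingroup <- ape::drop.tip(rooted, "og")
  expect_true(ape::is.monophyletic(ingroup, c("a", "b")))
  again <- root_with_outgroup(rooted, "og")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(again),
                                         ape::unroot(rooted))), 0)
  expect_error(root_with_outgroup(tr, "nope"), "unknown leaf")
})

test_that("trees round-trip through Newick", {
  fam <- demo_family()
  bt <- bootstrap_support(fam$alignment, n_replicates = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(bt, path)
  back <- ape::read.tree(path)
  expect_identical(sort(back$tip.label), sort(bt$tip.label))
  expect_equal(as.numeric(ape::dist.topo(back, bt)), 0)
  expect_lt(max(abs(sort(back$edge.length) - sort(bt$edge.length))), 1e-9)
  expect_identical(back$node.label, bt$node.label)
})
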