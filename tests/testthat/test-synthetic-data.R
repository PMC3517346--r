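zero_tree <- function() {
  species_tree("(((t1:0,t2:0):0,(t3:0,t4:0):0):0,og:0);", "og")
}

test_that("no time means no change: zero branch lengths copy the root", {
  fam <- simulate_family(zero_tree(), duplication_scenario(),
                         evolver_params(seed = 1, indel_rate = 0),
                         root_length = 120)
  expect_identical(length(unique(fam$sequences)), 1L)
  expect_identical(sum(fam$site_counts), 0L)
})

test_that("p_invariant = 1 freezes every site regardless of branch lengths", {
  sp <- species_tree("(((t1:0.5,t2:0.5):0.5,(t3:0.5,t4:0.5):0.5):0.5,og:2);",
                     "og")
  fam <- simulate_family(sp, duplication_scenario(),
                         evolver_params(seed = 2, p_invariant = 1,
                                        indel_rate = 0),
                         root_length = 150)
  expect_identical(length(unique(fam$sequences)), 1L)
})

test_that("copy counts follow the retention scenario", {
  # 12 taxa; duplication on the stem of a 6-taxon clade; 6*2 + 6*1 = 18
  nwk <- paste0("(((a1:.1,a2:.1):.1,((a3:.1,a4:.1):.1,(a5:.1,a6:.1):.1):.1):.2,",
                "((b1:.1,b2:.1):.1,((b3:.1,b4:.1):.1,(b5:.1,b6:.1):.1):.1):.2);")
  sp <- species_tree(nwk)
  scen <- duplication_scenario(duplication_clade = paste0("a", 1:6))
  fam <- simulate_family(sp, scen, evolver_params(seed = 3), root_length = 100)
  expect_identical(length(fam$sequences), 18L)
  expect_identical(sum(fam$truth$locus == "A"), 6L)
  expect_identical(sum(fam$truth$locus == "B"), 6L)
  expect_identical(sum(fam$truth$locus == "pre"), 6L)
  # the duplication node is the MRCA of the two copies in the true tree
  gt <- fam$gene_tree
  dup_node <- ape::Ntip(gt) + which(gt$node.label == "D")
  copies <- fam$truth$sequence_id[fam$truth$locus %in% c("A", "B")]
  expect_identical(ape::getMRCA(gt, copies), dup_node)
  # losses reduce the census accordingly
  scen2 <- duplication_scenario(duplication_clade = paste0("a", 1:6),
                                retained = list(a3 = c(B = 0),
                                                b1 = c(pre = 0)))
  fam2 <- simulate_family(sp, scen2, evolver_params(seed = 3),
                          root_length = 100)
  expect_identical(length(fam2$sequences), 16L)
})

test_that("identical seeds reproduce byte-identical artifacts", {
  sp <- demo_species_tree()
  run <- function() {
    fam <- simulate_family(sp, demo_scenario(isoform_clade = c("t1", "t2")),
                           evolver_params(seed = 11, indel_rate = 0.02),
                           root_length = 200)
    fa <- withr::local_tempfile(fileext = ".fasta")
    tt <- withr::local_tempfile(fileext = ".tsv")
    write_fasta(fam$sequences, fa)
    write_truth_table(fam$truth, tt)
    list(fa = readLines(fa), tt = readLines(tt))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$fa, r2$fa)
  expect_identical(r1$tt, r2$tt)
  fam3 <- simulate_family(sp, demo_scenario(),
                          evolver_params(seed = 12), root_length = 200)
  fam4 <- simulate_family(sp, demo_scenario(),
                          evolver_params(seed = 13), root_length = 200)
  expect_false(identical(fam3$sequences, fam4$sequences))
})

test_that("constrained columns never substitute and survive indels", {
  fam <- demo_family()
  expect_identical(sum(fam$site_counts[fam$constrained_alignment_columns]), 0L)
  m <- alignment_rows_to_matrix(fam$alignment)
  for (col in fam$constrained_alignment_columns)
    expect_identical(length(unique(m[, col])), 1L)
})

test_that("the extra exon appears only in the isoform clade, on copy A", {
  fam <- simulate_family(demo_species_tree(),
                         demo_scenario(isoform_clade = c("t1", "t2")),
                         evolver_params(seed = 21), root_length = 150)
  expect_setequal(fam$truth$sequence_id[fam$truth$has_extra_exon],
                  c("t1_A", "t2_A"))
  expect_identical(length(fam$exon_columns), 40L)
  carriers <- nchar(fam$sequences[c("t1_A", "t2_A")])
  others <- nchar(fam$sequences[setdiff(names(fam$sequences),
                                        c("t1_A", "t2_A"))])
  expect_true(min(carriers) > max(others))
})

test_that("an empty scenario is rejected", {
  sp <- demo_species_tree()
  expect_error(simulate_family(sp,
                               duplication_scenario(
                                 duplication_clade = paste0("t", 1:6),
                                 retained = sapply(c(paste0("t", 1:6), "og"),
                                                   function(t)
                                                     c(A = 0, B = 0, pre = 0),
                                                   simplify = FALSE)),
                               evolver_params(seed = 1), root_length = 100),
               "empty scenario")
})

test_that("zero-substitution fraction matches the invariant-sites model", {
  par <- evolver_params(seed = 5, p_invariant = 0.5, gamma_shape = 4)
  t_len <- 10
  counts <- realized_rate_distribution(par, 2000, time = t_len)
  # closed form for P(no event): the waiting time out of state s at site rate
  # r is Exponential(leave_s * r); integrating over Gamma(a, a) rates gives
  # (a / (a + leave_s * t))^a, mixed over the stationary state distribution
  ex <- jtt_exchange()
  rowrate <- as.numeric((ex$S %*% ex$freqs))
  leave <- rowrate / sum(ex$freqs * rowrate)
  p0 <- 0.5 + 0.5 * sum(ex$freqs * (4 / (4 + leave * t_len))^4)
  pv <- stats::binom.test(sum(counts == 0), 2000, p0)$p.value
  expect_gt(pv, 0.01)
})

test_that("rate heterogeneity controls the dispersion of site counts", {
  # a state-symmetric model isolates the gamma component: every state leaves
  # at the same rate, so the alpha -> Inf limit is exactly a one-rate Poisson
  uni <- list(S = matrix(1, 20, 20,
                         dimnames = list(paofam:::AA_ALPHABET,
                                         paofam:::AA_ALPHABET)),
              freqs = setNames(rep(0.05, 20), paofam:::AA_ALPHABET))
  near_poisson <- realized_rate_distribution(
    evolver_params(exchange = uni, seed = 6, p_invariant = 0,
                   gamma_shape = 1000), 10000, time = 3)
  disp <- stats::var(near_poisson) / mean(near_poisson)
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)
  overdispersed <- realized_rate_distribution(
    evolver_params(exchange = uni, seed = 6, p_invariant = 0,
                   gamma_shape = 0.3), 10000, time = 3)
  expect_gt(stats::var(overdispersed) / mean(overdispersed), 1.5)
  # constrained columns never substitute
  par <- evolver_params(seed = 7, constrained_columns = 1:50)
  expect_identical(sum(realized_rate_distribution(par, 500, time = 10)[1:50]),
                   0L)
})
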