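test_that("identical sequences align without gaps, fully conserved", {
  s <- setNames(rep("MKTAYIAKQRQISFVKSHFSRQ", 5), paste0("s", 1:5))
  aln <- progressive_align(s)
  expect_identical(unname(aln), unname(s))
  cons <- column_conservation(aln)
  expect_true(all(cons$score == 1))
  expect_true(all(cons$flagged))
})

test_that("two sequences reduce to plain pairwise global alignment", {
  a <- "MKTAYIAKQRQISFVK"
  b <- "MKTAYIKQRQISFVK"
  aln <- progressive_align(c(a = a, b = b))
  expect_identical(nchar(aln[["a"]]), nchar(aln[["b"]]))
  expect_identical(gsub("-", "", aln[["a"]]), a)
  expect_identical(gsub("-", "", aln[["b"]]), b)
  expect_identical(aln[["b"]], "MKTAYI-KQRQISFVK")
})

test_that("row order of the output equals the input order", {
  set.seed(12)
  base <- random_protein(80)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- sample(c("A","C","D","E","F","G"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(z = mut(base, 10), a = mut(base, 12), m = mut(base, 8))
  aln <- progressive_align(seqs)
  expect_identical(names(aln), c("z", "a", "m"))
})

test_that("column conservation counts majorities with gaps as mismatches", {
  aln <- c(r1 = "W", r2 = "W", r3 = "W", r4 = "W", r5 = "W",
           r6 = "W", r7 = "W", r8 = "W", r9 = "W", r10 = "W")
  expect_equal(column_conservation(aln)$score, 1.0)
  nine_w_gap <- setNames(c(rep("W", 9), "-"), paste0("r", 1:10))
  cons <- column_conservation(nine_w_gap)
  expect_equal(cons$score, 0.90)
  expect_true(cons$flagged)       # inclusive threshold
  expect_false(column_conservation(nine_w_gap, strict_gt = TRUE)$flagged)
  mixed <- setNames(c(rep("W", 8), "F", "F"), paste0("r", 1:10))
  cons2 <- column_conservation(mixed)
  expect_equal(cons2$score, 0.80)
  expect_false(cons2$flagged)
  # excluding gaps from the denominator rescues the gapped column
  expect_equal(column_conservation(nine_w_gap,
                                   gaps_in_denominator = FALSE)$score, 1.0)
})

test_that("conservation is invariant to row order and unaffected by removals", {
  fam <- demo_family()
  aln <- fam$alignment
  c1 <- column_conservation(aln)
  c2 <- column_conservation(aln[rev(seq_along(aln))])
  expect_equal(c1$score, c2$score)
  # scoring a subset via `rows` equals scoring the subsetted alignment
  sub <- names(aln)[1:6]
  expect_equal(column_conservation(aln, rows = sub)$score,
               column_conservation(aln[sub])$score)
})

test_that("consensus applies majority, alphabetic ties, and gap-drop rules", {
  one <- c(a = "MK-TA")
  expect_identical(consensus_of(one), "MKTA")
  ties <- c(r1 = "E", r2 = "E", r3 = "E", r4 = "E", r5 = "E",
            r6 = "D", r7 = "D", r8 = "D", r9 = "D", r10 = "D")
  expect_identical(consensus_of(ties), "D")
  gappy <- c(r1 = "A-", r2 = "A-", r3 = "A-", r4 = "AW", r5 = "AW")
  expect_identical(consensus_of(gappy), "A")   # gap majority drops column 2
  half <- c(r1 = "A-", r2 = "A-", r3 = "AW", r4 = "AW")
  expect_identical(consensus_of(half), "AW")   # tie: gap is not a majority
})

test_that("planted constrained columns give a root-residue consensus", {
  fam <- demo_family()
  cons_str <- consensus_of(fam$alignment)
  m <- do.call(rbind, strsplit(unname(fam$alignment), ""))
  for (col in fam$constrained_alignment_columns) {
    expect_identical(length(unique(m[, col])), 1L)
  }
})

test_that("active-site mapping resolves reference numbering and subsets", {
  deep <- species_tree(paste0("((((t1:0.8,t2:0.8):0.6,(t3:0.8,t4:0.8):0.6):0.6,",
                              "(t5:1.4,t6:1.4):0.6):1.0,og:3.0);"), "og")
  fam <- simulate_family(
    deep, demo_scenario(locus_constraints = list(A = c(30, 60))),
    evolver_params(seed = 77, p_invariant = 0, gamma_shape = 20,
                   indel_rate = 0.01),
    root_length = 250)
  aln <- fam$alignment
  A_rows <- paste0("t", 1:6, "_A")
  B_rows <- paste0("t", 1:6, "_B")
  ref <- "t1_A"
  rm_ <- reference_map(aln, ref)
  cols <- fam$locus_constrained_alignment_columns$A
  ref_pos <- rm_$ref_pos[match(cols, rm_$column)]
  panel <- active_site_panel(ref, ref_pos,
                             rm_$ref_residue[match(cols, rm_$column)])
  repA <- map_active_sites(aln, panel, ids = A_rows)
  repB <- map_active_sites(aln, panel, ids = B_rows)
  # the subfamily-specific pocket: conserved in A, free in B
  expect_true(all(repA$conserved))
  expect_false(any(repB$conserved))
  # panel built from the reference itself, scored on the reference alone
  solo <- map_active_sites(aln, panel, ids = ref)
  expect_true(all(solo$conserved))
  # numbering drift guard
  bad <- panel
  bad$expected_aa[1] <- setdiff(c("A", "C"), bad$expected_aa[1])[1]
  expect_error(map_active_sites(aln, bad, ids = A_rows),
               "panel/reference disagreement")
})

test_that("aligned FASTA and Clustal imports round-trip", {
  fam <- demo_family()
  aln <- fam$alignment[1:4]
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, fa)
  expect_identical(read_alignment(fa), aln)
  # minimal Clustal dialect
  aln2 <- c(seq1 = "MKTA-YIAK", seq2 = "MKTAWYI-K")
  clu <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.0) multiple sequence alignment", "",
               "seq1  MKTA-YIAK", "seq2  MKTAWYI-K"), clu)
  expect_identical(read_alignment(clu), aln2)
})

test_that("progressive alignment keeps planted homologous columns together", {
  fam <- demo_family()
  aln <- progressive_align(fam$sequences)
  # compare against the simulator's truth alignment through pairwise
  # distances: identical column homology implies identical mismatch counts
  dT <- protein_distance(fam$alignment)
  dP <- protein_distance(aln)
  expect_lt(max(abs(dT - dP[rownames(dT), colnames(dT)])), 0.05)
})
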