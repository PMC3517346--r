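chained_row <- function(q, s, identity, bitscore, aq, as_) {
  data.frame(query_id = q, subject_id = s, n_hits = 1L,
             total_aligned_q = aq, total_aligned_s = as_,
             combined_identity = identity, combined_bitscore = bitscore,
             stringsAsFactors = FALSE)
}

test_that("filter thresholds are inclusive and self-hits are excluded", {
  lens <- c(A = 100L, B = 100L)
  # exactly at every threshold: passes ("at least" semantics)
  at <- chained_row("A", "B", 0.30, 50, 50L, 50L)
  expect_true(apply_filters(at, lens)$pass)
  # a perfect self-pair: rejected
  self <- chained_row("A", "A", 1.0, 1000, 100L, 100L)
  expect_false(apply_filters(self, lens)$pass)
  expect_true(apply_filters(self, lens,
                            filter_thresholds(exclude_self = FALSE))$pass)
  # one failed conjunct (subject coverage) rejects despite high identity
  low_cov <- chained_row("A", "B", 0.95, 500, 80L, 40L)
  expect_false(apply_filters(low_cov, lens)$pass)
  # just below one threshold: rejected
  below <- chained_row("A", "B", 0.2999, 50, 50L, 50L)
  expect_false(apply_filters(below, lens)$pass)
})

test_that("missing sequence lengths are an error", {
  expect_error(apply_filters(chained_row("A", "Z", 0.5, 60, 50L, 50L),
                             c(A = 100L)),
               "unknown sequence length")
})

test_that("two-way hits require both directions to pass", {
  lens <- c(A = 100L, B = 100L, C = 100L)
  tab <- rbind(chained_row("A", "B", 0.5, 60, 60L, 60L),
               chained_row("B", "A", 0.5, 60, 60L, 60L),
               chained_row("A", "C", 0.5, 60, 60L, 60L))   # C->A absent
  edges <- reciprocal_edges(apply_filters(tab, lens))
  ab <- edges[edges$id_a == "A" & edges$id_b == "B", ]
  ac <- edges[edges$id_a == "A" & edges$id_b == "C", ]
  expect_true(ab$two_way)
  expect_false(ac$two_way)
  expect_identical(nrow(reciprocal_edges(apply_filters(tab[0, ], lens))), 0L)
})

test_that("single linkage merges transitively and leaves the rest singletons", {
  ids <- c("A", "B", "C", "D")
  edges <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
                      passed_ab = TRUE, passed_ba = TRUE, two_way = TRUE)
  fams <- single_linkage_families(ids, edges)
  expect_identical(sort(fams$id[fams$family_id == "F1"]), c("A", "B", "C"))
  expect_true(fams$is_singleton[fams$id == "D"])
  # no two-way edges at all: everything a singleton
  none <- single_linkage_families(ids, edges[0, ])
  expect_true(all(none$is_singleton))
  expect_identical(length(unique(none$family_id)), 4L)
  expect_error(single_linkage_families(ids,
                                       data.frame(id_a = "A", id_b = "Z",
                                                  passed_ab = TRUE,
                                                  passed_ba = TRUE,
                                                  two_way = TRUE)),
               "unknown id")
})

test_that("families equal BFS connected components on random graphs", {
  set.seed(31)
  for (k in 1:60) {
    ids <- paste0("g", sprintf("%02d", 1:30))
    edges <- random_edge_table(ids, sample(0:40, 1))
    fams <- single_linkage_families(ids, edges)
    got <- canonical_partition(setNames(fams$family_id, fams$id))
    want <- bfs_components_oracle(ids, edges$id_a, edges$id_b)
    expect_identical(got, want)
    # partition invariant: every id exactly once
    expect_identical(sort(fams$id), sort(ids))
  }
})

test_that("the partition is invariant to edge order", {
  set.seed(8)
  ids <- paste0("s", 1:12)
  edges <- random_edge_table(ids, 15)
  f1 <- single_linkage_families(ids, edges)
  f2 <- single_linkage_families(ids, edges[rev(seq_len(nrow(edges))), ])
  expect_identical(f1, f2)
})

test_that("default thresholds recover the simulated family partition exactly", {
  two <- demo_two_families()
  passes <- apply_filters(two$chained, two$seqs)
  fams <- single_linkage_families(names(two$seqs), reciprocal_edges(passes))
  pred <- setNames(fams$family_id, fams$id)[two$truth$sequence_id]
  ari <- mclust::adjustedRandIndex(pred, two$truth$family_id)
  expect_equal(ari, 1.0)
  # the study condition itself: within-subfamily identity is >= 40%
  ch <- two$chained
  same_subfam <- substr(ch$query_id, 1, 1) == substr(ch$subject_id, 1, 1) &
    sub("^.*_", "", ch$query_id) == sub("^.*_", "", ch$subject_id) &
    ch$query_id != ch$subject_id
  expect_gte(min(ch$combined_identity[same_subfam]), 0.40)
})
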