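# Shared simulated data sets, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# study-condition species tree: six ingroup taxa, a deep duplication stem,
# and a distant outgroup carrying the single ancestral copy
demo_species_tree <- function() {
  species_tree(paste0("((((t1:0.08,t2:0.08):0.06,(t3:0.08,t4:0.08):0.06):0.06,",
                      "(t5:0.14,t6:0.14):0.06):0.4,og:0.6);"),
               outgroup_taxon = "og")
}

demo_scenario <- function(...) {
  duplication_scenario(duplication_clade = paste0("t", 1:6), ...)
}

# one duplicated family under default evolver settings
demo_family <- function() {
  if (is.null(.fixture_cache$family)) {
    .fixture_cache$family <- simulate_family(
      demo_species_tree(), demo_scenario(),
      evolver_params(seed = 42L, constrained_columns = 1:10),
      root_length = 400L)
  }
  .fixture_cache$family
}

# two unrelated families over the same taxa, with the full homology-search
# stages precomputed (used by clustering and threshold tests)
demo_two_families <- function() {
  if (is.null(.fixture_cache$two)) {
    f1 <- demo_family()
    f2 <- simulate_family(
      demo_species_tree(), demo_scenario(),
      evolver_params(seed = 99L, constrained_columns = 1:10),
      root_length = 350L, family_id = "F2")
    seqs <- c(setNames(f1$sequences, paste0("x.", names(f1$sequences))),
              setNames(f2$sequences, paste0("y.", names(f2$sequences))))
    truth <- rbind(
      transform(f1$truth, sequence_id = paste0("x.", sequence_id)),
      transform(f2$truth, sequence_id = paste0("y.", sequence_id)))
    hits <- all_vs_all(seqs)
    chained <- chain_all(hits)
    .fixture_cache$two <- list(seqs = seqs, truth = truth, hits = hits,
                               chained = chained)
  }
  .fixture_cache$two
}

family_count_at <- function(chained, seqs, thresholds) {
  passes <- apply_filters(chained, seqs, thresholds)
  fams <- single_linkage_families(names(seqs), reciprocal_edges(passes))
  length(unique(fams$family_id))
}
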