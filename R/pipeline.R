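#' Path to a packaged fixture
#' @param name file name under the package's `extdata` directory.
#' @return absolute file path.
#' @export
paofam_fixture <- function(name) {
  p <- system.file("extdata", name, package = "paofam")
  if (p == "") stop("no such fixture: ", name)
  p
}

#' Summaries of the packaged sequence tables
#'
#' `"table1"`: the 76 polyamine oxidase proteins surveyed across yeast and
#' Metazoa, counted by enzyme class (SMO / APAO / PAO) and by evidence
#' level.  `"table2"`: the SMO splice-isoform survey, counted by
#' long-isoform presence.
#'
#' @param which `"table1"` or `"table2"`.
#' @return named list of counts.
#' @export
fixture_summary <- function(which = c("table1", "table2")) {
  which <- match.arg(which)
  if (which == "table1") {
    df <- read.delim(paofam_fixture("table1_sequences.tsv"),
                     stringsAsFactors = FALSE)
    list(total = nrow(df),
         smo = sum(df$class == "SMO"),
         apao = sum(df$class == "APAO"),
         pao = sum(df$class == "PAO"),
         pao_metazoan = sum(df$class == "PAO" &
                              df$organism != "Saccharomyces cerevisiae"),
         evidence_protein = sum(df$evidence == "protein"),
         n_taxa = length(unique(df$organism)))
  } else {
    rec <- read_isoform_records()
    cen <- isoform_census(rec)
    list(total = nrow(rec),
         with_long_isoform = unname(cen[["with_isoform"]]),
         without_long_isoform = unname(cen[["without"]]))
  }
}

#' Pipeline configuration
#'
#' Collects every stage threshold, with defaults equal to the published
#' workflow's stated values: E-value cutoff 1e-10, identity 0.30, bitscore
#' 50, coverage 0.50 of both sequences, conservation threshold 0.90, and
#' 500 bootstrap replicates.
#'
#' @param evalue_cutoff all-vs-all E-value cutoff.
#' @param thresholds a [filter_thresholds()].
#' @param conservation_threshold column conservation flag threshold.
#' @param bootstrap_replicates bootstrap replicate count.
#' @param correction distance correction for tree building.
#' @param seed master seed.
#' @param stages character vector of stages to run, a prefix-closed subset
#'   of `c("search", "chain", "families", "align", "conserve", "tree",
#'   "reconcile")`.
#' @return list of class `run_config`.
#' @export
run_config <- function(evalue_cutoff = 1e-10,
                       thresholds = filter_thresholds(),
                       conservation_threshold = 0.90,
                       bootstrap_replicates = 500L,
                       correction = "poisson",
                       seed = 1L,
                       stages = c("search", "chain", "families", "align",
                                  "conserve", "tree", "reconcile")) {
  structure(list(evalue_cutoff = evalue_cutoff, thresholds = thresholds,
                 conservation_threshold = conservation_threshold,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 correction = correction, seed = as.integer(seed),
                 stages = stages),
            class = "run_config")
}

#' Run the homology-to-phylogeny pipeline
#'
#' Dependency-ordered driver: all-vs-all local alignment, hit chaining,
#' filtering + reciprocal hits + single-linkage families, progressive
#' alignment, conservation report, neighbor-joining tree with bootstrap and
#' outgroup rooting, and (optionally, when a species tree is given)
#' reconciliation.  Every stage writes a TSV/Newick artifact into `outdir`
#' and a `manifest.json` records thresholds, seeds and per-stage row
#' counts.  Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param sequences named character vector (or `AAStringSet`) of proteins.
#' @param outdir output directory (created if missing).
#' @param config a [run_config()].
#' @param scoring a [scoring_scheme()].
#' @param species_tree optional rooted `phylo` for the reconcile stage.
#' @param outgroup_id optional sequence id used to root the gene tree
#'   (defaults to the first sequence when reconciling).
#' @param leaf_taxon_map optional gene-leaf -> taxon map for reconciliation.
#' @return invisible list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(sequences, outdir, config = run_config(),
                         scoring = scoring_scheme(), species_tree = NULL,
                         outgroup_id = NULL, leaf_taxon_map = NULL) {
  seqs <- as_protein_set(sequences)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "paofam",
                   version = as.character(utils::packageVersion("paofam")),
                   config = list(
                     evalue_cutoff = config$evalue_cutoff,
                     min_identity = config$thresholds$min_identity,
                     min_bitscore = config$thresholds$min_bitscore,
                     min_coverage_both = config$thresholds$min_coverage_both,
                     conservation_threshold = config$conservation_threshold,
                     bootstrap_replicates = config$bootstrap_replicates,
                     correction = config$correction,
                     seed = config$seed),
                   stages = list())
  res <- list()
  log_stage <- function(name, n_in, n_out) {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out)
    message(sprintf("[paofam] %-9s in=%d out=%d", name, n_in, n_out))
  }
  run <- function(name) name %in% config$stages

  if (run("search")) {
    res$hits <- all_vs_all(seqs, scoring, config$evalue_cutoff)
    write_hit_table(res$hits, file.path(outdir, "hits.tsv"))
    log_stage("search", length(seqs), nrow(res$hits))
  }
  if (run("chain") && !is.null(res$hits)) {
    res$chained <- chain_all(res$hits)
    write_chain_table(res$chained, file.path(outdir, "chained.tsv"))
    log_stage("chain", nrow(res$hits), nrow(res$chained))
  }
  if (run("families") && !is.null(res$chained)) {
    passes <- apply_filters(res$chained, seqs, config$thresholds)
    res$edges <- reciprocal_edges(passes)
    res$families <- single_linkage_families(names(seqs), res$edges)
    write.table(res$edges, file.path(outdir, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_family_table(res$families, file.path(outdir, "families.tsv"))
    log_stage("families", nrow(res$chained),
              length(unique(res$families$family_id)))
  }
  if (run("align")) {
    res$alignment <- progressive_align(seqs, scoring)
    write_alignment(res$alignment, file.path(outdir, "alignment.fasta"))
    log_stage("align", length(seqs), nchar(res$alignment[[1L]]))
  }
  if (run("conserve") && !is.null(res$alignment)) {
    res$conservation <- column_conservation(
      res$alignment, threshold = config$conservation_threshold)
    write_conservation_table(res$alignment,
                             file.path(outdir, "conservation.tsv"),
                             threshold = config$conservation_threshold)
    log_stage("conserve", nchar(res$alignment[[1L]]),
              sum(res$conservation$flagged))
  }
  if (run("tree") && !is.null(res$alignment)) {
    res$tree <- bootstrap_support(res$alignment,
                                  n_replicates = config$bootstrap_replicates,
                                  seed = config$seed,
                                  correction = config$correction)
    if (!is.null(outgroup_id) && outgroup_id %in% names(seqs))
      res$rooted_tree <- root_with_outgroup(res$tree, outgroup_id)
    ape::write.tree(res$tree, file.path(outdir, "tree.nwk"))
    log_stage("tree", length(seqs), config$bootstrap_replicates)
  }
  if (run("reconcile") && !is.null(species_tree) && !is.null(res$tree)) {
    og <- if (is.null(outgroup_id)) names(seqs)[1L] else outgroup_id
    rooted <- if (!is.null(res$rooted_tree)) res$rooted_tree else
      root_with_outgroup(res$tree, og)
    ingroup <- ape::drop.tip(rooted, og)
    res$reconciliation <- reconcile(ingroup, species_tree, leaf_taxon_map)
    write_reconciliation(res$reconciliation,
                         file.path(outdir, "reconciliation.tsv"))
    log_stage("reconcile", ape::Ntip(ingroup),
              sum(res$reconciliation$events$label == "duplication"))
  }
  manifest$stages_run <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
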