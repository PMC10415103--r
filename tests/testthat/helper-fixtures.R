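# Bundles are moderately expensive to generate; build each configuration
# once per test run and share it across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# the default study conditions (strong effects, dispersion 0.05)
study_bundle <- function()
  cached("study", function() generate_bundle(plant_config(seed = 42L)))

# near-noiseless variant used to check exact planted-truth recovery
crisp_bundle <- function()
  cached("crisp", function()
    generate_bundle(plant_config(seed = 42L, nb_dispersion = 1e-3)))

the_study_fixture <- function()
  cached("study_fixture", function() study_fixture(seed = 42L))

# normalized layers + per-layer DE tables for a bundle
run_de_stage <- function(bundle) {
  norm <- list(lncRNA = compute_fpkm(bundle$counts$lncRNA, bundle$lengths),
               mRNA = compute_fpkm(bundle$counts$mRNA, bundle$lengths),
               miRNA = compute_tpm(bundle$counts$miRNA, bundle$lengths))
  tables <- list()
  for (layer in names(norm)) {
    thr <- threshold_config(layer)
    per <- lapply(bundle$comparisons, function(cmp) {
      res <- de_test(norm[[layer]], cmp)
      if (thr$significance_field == "fdr")
        res$fdr <- benjamini_hochberg(res$p)
      filter_de(res, thr)
    })
    tables[[layer]] <- do.call(rbind, per)
  }
  list(norm = norm,
       tables = tables,
       de_sets = lapply(tables, function(tab)
         unique(tab$feature_id[tab$direction != "ns"])))
}

# all-vs-all MRE hits for a bundle
bundle_mre_hits <- function(bundle) {
  hosts <- c(bundle$lnc_seqs,
             structure(bundle$gene_seqs,
                       names = paste0("T_", names(bundle$gene_seqs))))
  layers <- c(rep("lncRNA", length(bundle$lnc_seqs)),
              rep("mRNA", length(bundle$gene_seqs)))
  hits <- list()
  for (mi in names(bundle$mirna_seqs))
    for (h in seq_along(hosts))
      hits[[length(hits) + 1L]] <-
        predict_mre(bundle$mirna_seqs[[mi]], hosts[[h]], mi,
                    names(hosts)[h], layers[h])
  do.call(rbind, hits)
}

triad_key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
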