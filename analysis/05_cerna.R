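#!/usr/bin/env Rscript
# Stage 5 — ceRNA network: seed-match MRE prediction for every miRNA against
# every lncRNA and mRNA, triad assembly under the sign-constrained Spearman
# rules plus shared-MRE hypergeometric enrichment (candidates scoped to DE
# features), metabolite correlation edges for the triad members, and the
# four-column Sankey flow export. Compares the result with the planted truth.

suppressPackageStartupMessages(library(cernaflow))

cfg <- read_run_config("results/bundle/samples.yaml")
groups <- unlist(cfg$sample_groups); libs <- unlist(cfg$library_sizes)
lens_tab <- read.delim("results/bundle/lengths.tsv")
lens <- structure(lens_tab$length, names = lens_tab$feature_id)
norm <- list(
  lncRNA = compute_fpkm(read_abundance("results/bundle/counts_lncRNA.tsv",
                                       "lncRNA", "raw_count", groups, libs), lens),
  mRNA = compute_fpkm(read_abundance("results/bundle/counts_mRNA.tsv",
                                     "mRNA", "raw_count", groups, libs), lens),
  miRNA = compute_tpm(read_abundance("results/bundle/counts_miRNA.tsv",
                                     "miRNA", "raw_count", groups, libs), lens))
de_sets <- lapply(c(lncRNA = "lncRNA", mRNA = "mRNA", miRNA = "miRNA"),
                  function(layer) {
                    tab <- read.delim(sprintf("results/de_%s.tsv", layer))
                    unique(tab$feature_id[tab$direction != "ns"])
                  })

lnc_seqs <- read_fasta("results/bundle/lncrna.fa")
mrna_seqs <- read_fasta("results/bundle/mrna.fa")
mirna_seqs <- read_fasta("results/bundle/mirna.fa")
hits <- list()
for (mi in names(mirna_seqs)) {
  for (h in names(lnc_seqs))
    hits[[length(hits) + 1L]] <- predict_mre(mirna_seqs[[mi]],
                                             lnc_seqs[[h]], mi, h, "lncRNA")
  for (h in names(mrna_seqs))
    hits[[length(hits) + 1L]] <- predict_mre(mirna_seqs[[mi]],
                                             mrna_seqs[[h]], mi, h, "mRNA")
}
hits <- do.call(rbind, hits)
cat(sprintf("MRE scan: %d seed-match sites across %d miRNAs\n",
            nrow(hits), length(mirna_seqs)))

triads <- build_cerna_triads(hits, norm, de_sets = de_sets)
write.table(triads, "results/cerna_triads.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
truth <- jsonlite::read_json("results/bundle/truth.json", simplifyVector = TRUE)
key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
tp <- sum(key(triads) %in% key(truth$triads))
cat(sprintf("triads: %d emitted, %d planted; precision %.2f, recall %.2f\n",
            nrow(triads), nrow(truth$triads),
            tp / max(nrow(triads), 1), tp / nrow(truth$triads)))

metab <- read_abundance("results/bundle/metabolites.tsv", "metabolite",
                        "intensity", groups)
vip_tab <- read.delim("results/bundle/vip.tsv")
thr <- threshold_config("metabolite")
met_de <- do.call(rbind, lapply(
  list(comparison_group("McII", "McI"), comparison_group("McIII", "McI"),
       comparison_group("McIII", "McII")),
  function(cmp) {
    res <- de_test(metab, cmp)
    res$vip <- vip_tab$vip[match(res$feature_id, vip_tab$metabolite_id)]
    suppressMessages(filter_de(res, thr))
  }))
ds <- unique(met_de$feature_id[met_de$direction != "ns"])
cat(sprintf("%d differentially synthesized metabolites\n", length(ds)))

edges <- attach_metabolites(triads, norm, metab, ds_ids = ds)
write.table(edges, "results/metabolite_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
export_sankey(triads, edges, "results/sankey.tsv")
cat(sprintf("metabolite edges: %d significant of %d tested; sankey flows in results/sankey.tsv\n",
            sum(edges$significance_tier != "ns"), nrow(edges)))
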