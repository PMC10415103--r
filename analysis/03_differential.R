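#!/usr/bin/env Rscript
# Stage 3 — differential filtering: FPKM (lncRNA/mRNA) and TPM (miRNA)
# normalization, the Welch-on-log2 stand-in test, BH correction where the
# layer rule uses FDR, the per-layer thresholds, and the Venn arithmetic
# over the three stage comparisons. Also runs the study-scale fixture whose
# planted memberships realize a fixed table of headline cardinalities.

suppressPackageStartupMessages(library(cernaflow))

cfg <- read_run_config("results/bundle/samples.yaml")
groups <- unlist(cfg$sample_groups)
libs <- unlist(cfg$library_sizes)
lens_tab <- read.delim("results/bundle/lengths.tsv")
lens <- structure(lens_tab$length, names = lens_tab$feature_id)
comparisons <- list(comparison_group("McII", "McI"),
                    comparison_group("McIII", "McI"),
                    comparison_group("McIII", "McII"))

norm <- list(
  lncRNA = compute_fpkm(read_abundance("results/bundle/counts_lncRNA.tsv",
                                       "lncRNA", "raw_count", groups, libs), lens),
  mRNA = compute_fpkm(read_abundance("results/bundle/counts_mRNA.tsv",
                                     "mRNA", "raw_count", groups, libs), lens),
  miRNA = compute_tpm(read_abundance("results/bundle/counts_miRNA.tsv",
                                     "miRNA", "raw_count", groups, libs), lens))

de_sets <- list()
for (layer in names(norm)) {
  thr <- threshold_config(layer)
  per <- lapply(comparisons, function(cmp) {
    res <- de_test(norm[[layer]], cmp)
    if (thr$significance_field == "fdr") res$fdr <- benjamini_hochberg(res$p)
    filter_de(res, thr)
  })
  tab <- do.call(rbind, per)
  write.table(tab, sprintf("results/de_%s.tsv", layer), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s layer (|log2FC| >= %.3f, %s <= %.2f):\n", layer,
              thr$log2fc_min, thr$significance_field, thr$significance_max))
  print(with(tab, table(comparison, direction)))
  de_sets[[layer]] <- split(tab$feature_id[tab$direction != "ns"],
                            tab$comparison[tab$direction != "ns"])
}

vn <- venn(de_sets$lncRNA)
cat(sprintf("lncRNA DE Venn: %d common across the three comparisons, union %d\n",
            length(vn$intersection), length(vn$union)))

cat("\nStudy-scale fixture (planted-cardinality check):\n")
fx <- study_fixture(seed = 42L)
res <- run_study_fixture_analysis(fx)
tab <- data.frame(
  quantity = c("McII_vs_McI up", "McII_vs_McI down", "McIII_vs_McI up",
               "McIII_vs_McI down", "McIII_vs_McII up", "McIII_vs_McII down",
               "three-way common", "union", "CNCI set", "CPC2 set",
               "intersection"),
  value = c(res$counts$McII_vs_McI, res$counts$McIII_vs_McI,
            res$counts$McIII_vs_McII, res$venn$common, res$venn$union,
            res$calling$cnci, res$calling$cpc2, res$calling$both))
write.table(tab, "results/study_fixture_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)
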