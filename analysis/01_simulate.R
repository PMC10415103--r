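#!/usr/bin/env Rscript
# Stage 1 — simulate the study: a two-chromosome genome with 40 coding genes,
# planted lncRNAs in all five positional classes, 10 ceRNA sponge triads among
# 200 decoy chains, planted DE features at log2FC 3, NB dispersion 0.05, and
# metabolites coupled to the triad mRNAs. Writes the plain-text bundle that
# the later stages consume.

suppressPackageStartupMessages(library(cernaflow))

dir.create("results", showWarnings = FALSE)
cfg <- plant_config(seed = 42L)
bundle <- generate_bundle(cfg)
write_bundle(bundle, "results/bundle")

cat("Simulated bundle written to results/bundle\n")
cat(sprintf("  %d reference genes, %d assembled transcripts\n",
            length(bundle$reference), length(bundle$assembled)))
cat(sprintf("  %d planted lncRNAs expected to be called\n",
            length(bundle$truth$lnc_called)))
cat(sprintf("  %d planted triads, %d decoy chains, %d metabolites (%d coupled)\n",
            nrow(bundle$truth$triads), nrow(bundle$truth$decoy_chains),
            nrow(bundle$metabolites$values),
            length(bundle$truth$ds_metabolites)))
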