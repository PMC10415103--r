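#!/usr/bin/env Rscript
# Stage 2 — identify lncRNAs: cuffcompare-style class codes against the
# reference annotation, the novel-transcript filters (> 200 bp exonic,
# > 1 exon, code in u/i/j/x/c/e/o), coding-potential calling (CNCI-like
# score < 0 AND CPC2-like probability < 0.5), and the five-way positional
# classification of the called set.

suppressPackageStartupMessages(library(cernaflow))

reference <- read_gtf("results/bundle/reference.gtf")
reference <- lapply(reference, function(tx) { tx$biotype <- "coding"; tx })
assembled <- read_gtf("results/bundle/assembled.gtf")
scores <- read.delim("results/bundle/scores.tsv")

codes <- lapply(assembled, assign_class_code, reference = reference)
cat("Class codes of assembled transcripts:\n")
print(table(vapply(codes, `[[`, "", "code")))

novel <- filter_novel(assembled, codes)
cat(sprintf("%d of %d transcripts pass the novel-transcript filters\n",
            length(novel), length(assembled)))

calling <- call_lncrnas(names(novel), scores)
cat(sprintf("Coding-potential calling: %d pass CNCI, %d pass CPC2, %d called (intersection)\n",
            length(calling$cnci_set), length(calling$cpc2_set),
            length(calling$called)))
jsonlite::write_json(
  list(cnci_only = length(setdiff(calling$cnci_set, calling$cpc2_set)),
       cpc2_only = length(setdiff(calling$cpc2_set, calling$cnci_set)),
       both = length(intersect(calling$cnci_set, calling$cpc2_set))),
  "results/calling_venn.json", auto_unbox = TRUE, digits = NA)

lnc <- assembled[calling$called]
cls <- lapply(lnc, classify_lncrna_position, pcgs = reference)
records <- data.frame(
  transcript_id = names(lnc),
  class_code = vapply(codes[names(lnc)], `[[`, "", "code"),
  category = vapply(cls, `[[`, "", "category"),
  anchor_gene_id = vapply(cls, `[[`, "", "anchor_gene_id"),
  row.names = NULL)
write.table(records, "results/lncrna_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Positional classes of called lncRNAs:\n")
print(table(records$category))
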