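#' Run the full analysis pipeline on a bundle directory
#'
#' Orchestrates the stages in order — identify (class codes + novel filter +
#' coding-potential calling), classify (positional categories), differential
#' (per-layer normalization, testing, thresholds, Venn), interact (antisense
#' / cis / trans edges), cerna (MRE scan, triads, metabolite edges, Sankey)
#' — reading a directory written by [write_bundle()] and writing one TSV per
#' stage plus a JSON run summary. Deterministic given identical inputs.
#'
#' @param bundle_dir Directory with the input files (see [write_bundle()]).
#' @param out_dir Output directory (created if needed).
#' @param params Optional overrides: `cis_window`, `mfe_max`, `r_min`,
#'   `scc_min`, `p_max`, `q_max`, `vip_direction`.
#' @return The run summary (invisibly also written as `summary.json`).
#' @export
run_pipeline <- function(bundle_dir, out_dir, params = list()) {
  p <- utils::modifyList(list(cis_window = 10000L, mfe_max = -10,
                              r_min = 0.999, scc_min = 0.7, p_max = 0.05,
                              q_max = 0.05, vip_direction = "ge"), params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(bundle_dir, ...)
  op <- function(...) file.path(out_dir, ...)
  need <- c("reference.gtf", "assembled.gtf", "scores.tsv", "samples.yaml",
            "counts_lncRNA.tsv", "counts_miRNA.tsv", "counts_mRNA.tsv",
            "metabolites.tsv", "lengths.tsv", "lncrna.fa", "mrna.fa",
            "mirna.fa", "vip.tsv")
  missing <- need[!file.exists(fp(need))]
  if (length(missing))
    stop("missing input file(s): ", paste(fp(missing), collapse = ", "))

  cfg <- read_run_config(fp("samples.yaml"))
  groups <- unlist(cfg$sample_groups)
  libsizes <- unlist(cfg$library_sizes)
  lengths_tab <- utils::read.delim(fp("lengths.tsv"), stringsAsFactors = FALSE)
  lengths <- structure(lengths_tab$length, names = lengths_tab$feature_id)
  comparisons <- list(comparison_group("McII", "McI"),
                      comparison_group("McIII", "McI"),
                      comparison_group("McIII", "McII"))

  # --- identify + classify --------------------------------------------------
  reference <- read_gtf(fp("reference.gtf"))
  reference <- lapply(reference, function(tx) { tx$biotype <- "coding"; tx })
  assembled <- read_gtf(fp("assembled.gtf"))
  codes <- lapply(assembled, assign_class_code, reference = reference)
  novel <- filter_novel(assembled, codes)
  scores <- utils::read.delim(fp("scores.tsv"), stringsAsFactors = FALSE)
  calling <- call_lncrnas(names(novel), scores)
  lnc_models <- assembled[calling$called]
  classes <- lapply(lnc_models, classify_lncrna_position, pcgs = reference)
  lnc_table <- data.frame(
    transcript_id = names(lnc_models),
    class_code = vapply(codes[names(lnc_models)], `[[`, "", "code"),
    category = vapply(classes, `[[`, "", "category"),
    anchor_gene_id = vapply(classes, `[[`, "", "anchor_gene_id"),
    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(lnc_table, op("lncrna_records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- differential ---------------------------------------------------------
  read_counts <- function(layer)
    read_abundance(fp(paste0("counts_", layer, ".tsv")), layer, "raw_count",
                   groups, libsizes)
  norm <- list(
    lncRNA = compute_fpkm(read_counts("lncRNA"), lengths),
    mRNA = compute_fpkm(read_counts("mRNA"), lengths),
    miRNA = compute_tpm(read_counts("miRNA"), lengths))
  metab <- read_abundance(fp("metabolites.tsv"), "metabolite", "intensity",
                          groups)
  vip_tab <- utils::read.delim(fp("vip.tsv"), stringsAsFactors = FALSE)
  vip <- structure(vip_tab$vip, names = vip_tab$metabolite_id)

  de_tables <- list()
  de_sets <- list()
  for (layer in c("lncRNA", "mRNA", "miRNA", "metabolite")) {
    thr <- threshold_config(layer, vip_direction =
                              if (layer == "metabolite") p$vip_direction)
    ab <- if (layer == "metabolite") metab else norm[[layer]]
    per <- list()
    for (cmp in comparisons) {
      res <- de_test(ab, cmp, method = "welch_log")
      if (thr$significance_field == "fdr") res$fdr <- benjamini_hochberg(res$p)
      if (layer == "metabolite") res$vip <- unname(vip[res$feature_id])
      per[[cmp$name]] <- suppressMessages(filter_de(res, thr))
    }
    tab <- do.call(rbind, per)
    rownames(tab) <- NULL
    de_tables[[layer]] <- tab
    de_sets[[layer]] <- sort(unique(tab$feature_id[tab$direction != "ns"]))
    utils::write.table(tab, op(paste0("de_", layer, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  lnc_de_by_cmp <- split(de_tables$lncRNA, de_tables$lncRNA$comparison)
  venn_sets <- lapply(lnc_de_by_cmp, function(d)
    d$feature_id[d$direction != "ns"])
  lnc_venn <- venn(venn_sets)

  # --- interactions ---------------------------------------------------------
  lnc_seqs <- read_fasta(fp("lncrna.fa"))
  mrna_seqs_tx <- read_fasta(fp("mrna.fa"))
  mrna_gene_of <- structure(vapply(reference, `[[`, "", "gene_id"),
                            names = names(reference))
  mrna_seqs <- structure(mrna_seqs_tx,
                         names = unname(mrna_gene_of[names(mrna_seqs_tx)]))
  anti <- antisense_edges(lnc_table, lnc_seqs, mrna_seqs,
                          mfe_max = p$mfe_max)
  cis <- cis_edges(lnc_models, reference, window = p$cis_window)
  trans <- trans_edges(norm$lncRNA$values[intersect(names(lnc_models),
                                                    rownames(norm$lncRNA$values)), ,
                                          drop = FALSE],
                       norm$mRNA$values, r_min = p$r_min)
  # trans rows are transcript-level: map to gene ids, then drop cis-linked
  # pairs so the two models stay mutually exclusive
  trans$edges$gene_id <- unname(mrna_gene_of[trans$edges$gene_id])
  if (nrow(cis) && nrow(trans$edges))
    trans$edges <- trans$edges[!paste(trans$edges$lncrna_id, trans$edges$gene_id) %in%
                                 paste(cis$lncrna_id, cis$gene_id), , drop = FALSE]
  acting <- rbind(anti[, c("lncrna_id", "gene_id", "model", "statistic")],
                  cis, trans$edges)
  utils::write.table(acting, op("acting_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- ceRNA network --------------------------------------------------------
  mirna_seqs <- read_fasta(fp("mirna.fa"))
  mre <- list()
  for (mi in names(mirna_seqs)) {
    for (l in names(lnc_seqs))
      mre[[length(mre) + 1L]] <- predict_mre(mirna_seqs[[mi]], lnc_seqs[[l]],
                                             mi, l, "lncRNA")
    for (m in names(mrna_seqs_tx))
      mre[[length(mre) + 1L]] <- predict_mre(mirna_seqs[[mi]],
                                             mrna_seqs_tx[[m]], mi, m, "mRNA")
  }
  mre <- do.call(rbind, mre)
  triads <- build_cerna_triads(mre, norm, de_sets = de_sets,
                               scc_min = p$scc_min, p_max = p$p_max,
                               q_max = p$q_max)
  utils::write.table(triads, op("cerna_triads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  met_edges <- attach_metabolites(triads, norm, metab,
                                  ds_ids = de_sets$metabolite)
  utils::write.table(met_edges, op("metabolite_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_sankey(triads, met_edges, op("sankey.tsv"))
  if (nrow(triads)) {
    net <- rbind(
      data.frame(source = triads$mirna_id, source_layer = "miRNA",
                 target = triads$lncrna_id, target_layer = "lncRNA",
                 stat_name = "scc", stat_value = triads$scc_mi_lnc,
                 p = triads$p_mi_lnc, q = NA_real_),
      data.frame(source = triads$mirna_id, source_layer = "miRNA",
                 target = triads$mrna_id, target_layer = "mRNA",
                 stat_name = "scc", stat_value = triads$scc_mi_mrna,
                 p = triads$p_mi_mrna, q = NA_real_),
      data.frame(source = triads$lncrna_id, source_layer = "lncRNA",
                 target = triads$mrna_id, target_layer = "mRNA",
                 stat_name = "scc", stat_value = triads$scc_lnc_mrna,
                 p = triads$p_lnc_mrna, q = triads$enrichment_q))
    write_network_table(net, op("network.tsv"))
  } else write_network_table(data.frame(), op("network.tsv"))

  summary <- list(
    n_assembled = length(assembled),
    n_novel = length(novel),
    calling = list(cnci = length(calling$cnci_set),
                   cpc2 = length(calling$cpc2_set),
                   called = length(calling$called)),
    classes = as.list(table(lnc_table$category)),
    de = lapply(de_tables, function(tab)
      lapply(split(tab, tab$comparison), function(d)
        list(up = sum(d$direction == "up"),
             down = sum(d$direction == "down")))),
    lnc_venn = list(common = length(lnc_venn$intersection),
                    union = length(lnc_venn$union)),
    edges = as.list(table(acting$model)),
    n_triads = nrow(triads),
    n_metabolite_edges = sum(met_edges$significance_tier != "ns"),
    params = p)
  jsonlite::write_json(summary, op("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
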