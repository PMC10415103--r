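# ---------------------------------------------------------------------------
# Seeded synthetic-data generator: a miniature genome + annotation + sequences
# + 9-sample multi-layer abundances + coding-potential scores + metabolites,
# with planted ground truth for every pipeline stage (positional classes,
# DE directions, sponge triads, metabolite couplings).
# ---------------------------------------------------------------------------

.dna_revcomp <- function(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1L]]), collapse = "")

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# Spliced transcript sequence (RNA) from a DNA genome.
.splice <- function(tx, genome) {
  chrom <- genome[[tx$chrom]]
  parts <- substring(chrom, tx$exon_starts + 1L, tx$exon_ends)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- .dna_revcomp(s)
  chartr("T", "U", s)
}

# Genomic positions (0-based) of each spliced base, 5'->3' in transcript order.
.spliced_positions <- function(tx) {
  pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                       tx$exon_starts, tx$exon_ends, SIMPLIFY = FALSE))
  if (tx$strand == "-") rev(pos) else pos
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a 3-stage x 3-replicate design with strong planted
#' effects: negative-binomial counts with `nb_dispersion` overdispersion,
#' planted per-comparison fold changes of `effect_log2fc`, ten sponge triads
#' among decoy chains, and metabolites linearly coupled to the triad mRNAs.
#'
#' @param seed Integer RNG seed; the whole bundle is deterministic given it.
#' @param n_pcgs Number of protein-coding genes (split over two chromosomes;
#'   must be at least 40 so every planted placement has flanking genes).
#' @param n_lnc_per_class Planted lncRNAs per positional class.
#' @param n_mirnas miRNA universe size.
#' @param n_decoys Decoy ceRNA chains (half sequence-level, half
#'   expression-level decoys).
#' @param n_planted_de Planted differentially expressed lncRNAs.
#' @param effect_log2fc Planted per-comparison log2 fold change.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param n_planted_triads Planted ceRNA triads.
#' @param n_metabolites Metabolite features (first `n_planted_triads` are
#'   coupled to the triad mRNAs).
#' @param metabolite_slope,metabolite_sigma Linear coupling
#'   `met = slope * mRNA_FPKM + N(0, sigma * slope * mean)`.
#' @param stage_jitter_sd Per-sample log2 jitter around the stage means for
#'   trend features.
#' @param triad_stage_step Per-stage log2 increment of the triad sponge
#'   trend.
#' @export
plant_config <- function(seed = 0L, n_pcgs = 40L, n_lnc_per_class = 2L,
                         n_mirnas = 30L, n_decoys = 200L, n_planted_de = 32L,
                         effect_log2fc = 3, nb_dispersion = 0.05,
                         n_planted_triads = 10L, n_metabolites = 15L,
                         metabolite_slope = 2, metabolite_sigma = 0.05,
                         stage_jitter_sd = 0.2, triad_stage_step = 2) {
  if (n_pcgs < 40L || n_pcgs %% 2L != 0L)
    stop("n_pcgs must be an even number >= 40 (planted placements need ",
         "flanking genes on both chromosome arms)")
  if (n_lnc_per_class < 1L || n_lnc_per_class > 2L)
    stop("n_lnc_per_class must be 1 or 2 with the fixed gene layout")
  if (n_planted_triads > 10L) stop("at most 10 planted triads are supported")
  if (n_decoys > 208L) stop("at most 208 decoy chains fit the gene layout")
  if (n_mirnas < 3L * n_planted_triads)
    stop("need at least 3 miRNAs per planted triad (one target, two support)")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  list(seed = as.integer(seed), n_pcgs = as.integer(n_pcgs),
       n_lnc_per_class = as.integer(n_lnc_per_class),
       n_mirnas = as.integer(n_mirnas), n_decoys = as.integer(n_decoys),
       n_planted_de = as.integer(n_planted_de),
       effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
       n_planted_triads = as.integer(n_planted_triads),
       n_metabolites = as.integer(n_metabolites),
       metabolite_slope = metabolite_slope,
       metabolite_sigma = metabolite_sigma,
       stage_jitter_sd = stage_jitter_sd,
       triad_stage_step = triad_stage_step)
}

# Fixed gene layout: slots every 5500 bp starting at 3000; gene structure
# exon 300 / intron 1500 / exon 200 / intron 1500 / exon 300 (span 3800,
# spliced mRNA 800 nt); all genes on '+'.
.GENE_PITCH <- 5500L
.GENE_FIRST <- 3000L
.GENE_EXONS <- cbind(start = c(0L, 1800L, 3500L), end = c(300L, 2000L, 3800L))

.gene_slot <- function(chrom_idx, slot)
  list(chrom = paste0("chr", chrom_idx),
       pos = .GENE_FIRST + (slot - 1L) * .GENE_PITCH)

.make_gene <- function(chrom_idx, slot, gene_id) {
  sl <- .gene_slot(chrom_idx, slot)
  transcript_model(paste0("T_", gene_id), gene_id, sl$chrom, "+",
                   sl$pos + .GENE_EXONS[, "start"],
                   sl$pos + .GENE_EXONS[, "end"], biotype = "coding")
}

.make_lnc <- function(id, chrom_idx, slot, local_starts, local_ends,
                      strand = "+") {
  sl <- .gene_slot(chrom_idx, slot)
  transcript_model(id, id, sl$chrom, strand,
                   sl$pos + as.integer(local_starts),
                   sl$pos + as.integer(local_ends), biotype = "noncoding")
}

# Per-sample log2 mean matrix for the 9-sample design: one row per feature,
# stage means recycled over 3 replicates, optional per-sample jitter.
.stage_log2 <- function(stage_means, jitter_sd = 0) {
  v <- rep(stage_means, each = 3L)
  if (jitter_sd > 0) v <- v + stats::rnorm(9L, 0, jitter_sd)
  v
}

.draw_counts <- function(log2_means, dispersion) {
  mu <- 2^log2_means
  if (dispersion <= 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

.SAMPLES <- paste0(rep(c("McI", "McII", "McIII"), each = 3L), "_", 1:3)
.GROUPS <- structure(rep(c("McI", "McII", "McIII"), each = 3L),
                     names = .SAMPLES)
.LIBSIZE <- structure(rep(5e6, 9L), names = .SAMPLES)

#' Generate a synthetic multi-omics bundle with planted truth
#'
#' Builds, deterministically for the configured seed: a two-chromosome
#' genome; a '+'-strand protein-coding annotation; planted lncRNAs in each
#' positional class plus intergenic triad/decoy/DE-planted lncRNAs; miRNAs
#' whose seed complements are embedded in the planted sponge pairs (and
#' scrubbed from everywhere else); negative-binomial counts for the three
#' RNA layers; metabolite intensities coupled to the triad mRNAs; and
#' coding-potential scores that recover the planted lncRNA set. The `truth`
#' element records every planted label.
#'
#' @param config A [plant_config()].
#' @return A `synthetic_bundle` list (models, genome, sequences, counts,
#'   scores, vip, metabolites, lengths, truth).
#' @export
generate_bundle <- function(config = plant_config()) {
  set.seed(config$seed)
  n_side <- config$n_pcgs %/% 2L
  chrom_len <- .GENE_FIRST + n_side * .GENE_PITCH + 2000L

  genes <- list()
  for (ci in 1:2) for (s in seq_len(n_side)) {
    gid <- sprintf("G%03d", (ci - 1L) * n_side + s)
    genes[[gid]] <- .make_gene(ci, s, gid)
  }
  gene_ids <- names(genes)
  chr2_gene <- function(slot) gene_ids[n_side + slot]

  # --- planted lncRNA models -----------------------------------------------
  lnc <- list()
  meta <- list()   # per-lnc bookkeeping: role, expected class/code, anchor
  add_lnc <- function(tx, role, class, code, anchor = NA_character_) {
    lnc[[tx$transcript_id]] <<- tx
    meta[[tx$transcript_id]] <<- list(role = role, class = class,
                                      code = code, anchor = anchor)
  }
  class_geom <- list(
    intronic = list(starts = c(400, 580), ends = c(520, 700), strand = "+",
                    code = "i"),
    sense = list(starts = c(1600, 2100), ends = c(1900, 2300), strand = "+",
                 code = "o"),
    bidirectional = list(starts = c(-1200, -1000), ends = c(-1050, -800),
                         strand = "-", code = "u"),
    antisense = list(starts = c(100, 350), ends = c(250, 500), strand = "-",
                     code = "x"),
    intergenic = list(starts = c(4100, 4350), ends = c(4250, 4500),
                      strand = "+", code = "u"))
  slot <- 2L
  for (cls in names(class_geom)) for (k in seq_len(config$n_lnc_per_class)) {
    g <- class_geom[[cls]]
    id <- sprintf("LNC_%s_%d", cls, k)
    add_lnc(.make_lnc(id, 1L, slot, g$starts, g$ends, g$strand),
            role = "classed", class = cls, code = g$code,
            anchor = if (cls %in% c("intergenic")) NA_character_
            else gene_ids[slot])
    slot <- slot + 1L
  }

  for (t in seq_len(config$n_planted_triads))
    add_lnc(.make_lnc(sprintf("LNC_triad_%02d", t), 2L, t + 1L,
                      c(4100, 4350), c(4250, 4500)),
            role = "triad", class = "intergenic", code = "u")

  n_site <- config$n_decoys %/% 2L
  n_expr <- config$n_decoys - n_site
  for (d in seq_len(n_site))
    add_lnc(.make_lnc(sprintf("LNC_sited_%03d", d), 1L,
                      2L + ((d - 1L) %% 16L),
                      3900 + 80 * ((d - 1L) %/% 16L) + c(0, 250),
                      3900 + 80 * ((d - 1L) %/% 16L) + c(150, 400)),
            role = "site_decoy", class = "intergenic", code = "u")
  for (d in seq_len(n_expr))
    add_lnc(.make_lnc(sprintf("LNC_exprd_%03d", d), 2L,
                      12L + ((d - 1L) %% 8L),
                      3900 + 80 * ((d - 1L) %/% 8L) + c(0, 250),
                      3900 + 80 * ((d - 1L) %/% 8L) + c(150, 400)),
            role = "expr_decoy", class = "intergenic", code = "u")

  for (k in seq_len(config$n_planted_de))
    add_lnc(.make_lnc(sprintf("LNC_de_%03d", k), 1L, 12L + ((k - 1L) %% 8L),
                      3900 + 80 * ((k - 1L) %/% 8L) + c(0, 250),
                      3900 + 80 * ((k - 1L) %/% 8L) + c(150, 400)),
            role = "de_planted", class = "intergenic", code = "u")

  for (k in 1:3)
    add_lnc(.make_lnc(sprintf("LNC_trans_%d", k), 2L, 11L + k,
                      c(5000, 5250), c(5150, 5400)),
            role = "trans", class = "intergenic", code = "u")

  # candidates that fail identification: wrong structure or coding-like scores
  add_lnc(.make_lnc("CAND_short", 2L, 15L, c(5000, 5150), c(5080, 5230)),
          role = "structure_fail", class = "intergenic", code = "u")
  add_lnc(transcript_model("CAND_monoexon", "CAND_monoexon", "chr2", "+",
                           .gene_slot(2L, 16L)$pos + 5000L,
                           .gene_slot(2L, 16L)$pos + 5400L,
                           biotype = "noncoding"),
          role = "structure_fail", class = "intergenic", code = "u")
  for (k in seq_len(10L))
    add_lnc(.make_lnc(sprintf("CAND_coding_%02d", k), 2L, 1L + k,
                      c(5000, 5250), c(5150, 5400)),
            role = "coding_like", class = "intergenic", code = "u")

  roles <- vapply(meta, `[[`, "", "role")

  # --- genome and sequences -------------------------------------------------
  genome <- list(chr1 = .rand_dna(chrom_len), chr2 = .rand_dna(chrom_len))

  # miRNAs: distinct seeds, 22-nt sequences (seed at positions 2-8)
  repeat {
    seeds <- replicate(config$n_mirnas,
                       paste(sample(c("A", "C", "G", "U"), 7L, replace = TRUE),
                             collapse = ""))
    if (!anyDuplicated(seeds)) break
  }
  mirna_ids <- sprintf("mir%03d", seq_len(config$n_mirnas))
  mirna_seqs <- vapply(seq_len(config$n_mirnas), function(i) {
    rest <- paste(sample(c("A", "C", "G", "U"), 14L, replace = TRUE),
                  collapse = "")
    paste0(substr(rest, 1L, 1L), seeds[i], substr(rest, 2L, 14L))
  }, character(1))
  names(mirna_seqs) <- mirna_ids
  sites <- vapply(seeds, rna_revcomp, character(1))  # 7-mer host motifs
  names(sites) <- mirna_ids

  nt <- config$n_planted_triads
  triad_mir <- mirna_ids[seq_len(nt)]
  support_pool <- mirna_ids[nt + seq_len(10L)]
  sited_mir <- mirna_ids[nt + 11L:15L]
  exprd_mir <- mirna_ids[nt + 16L:20L]

  # planted site plan: host transcript id -> data.frame(mirna, spliced offset)
  plan <- list()
  add_site <- function(host, mir, offset)
    plan[[host]] <<- rbind(plan[[host]],
                           data.frame(mirna_id = mir, offset = offset,
                                      stringsAsFactors = FALSE))
  supports_of <- function(t)
    support_pool[c((t - 1L) %% 10L, t %% 10L) + 1L]
  for (t in seq_len(nt)) {
    sup <- supports_of(t)
    for (i in 1:3) {
      add_site(sprintf("LNC_triad_%02d", t),
               c(triad_mir[t], sup)[i], 160L + 20L * (i - 1L))
      add_site(paste0("T_", chr2_gene(t + 1L)),
               c(triad_mir[t], sup)[i], 600L + 20L * (i - 1L))
    }
  }
  for (d in seq_len(n_site)) {
    m <- sited_mir[(d - 1L) %% 5L + 1L]
    add_site(sprintf("LNC_sited_%03d", d), m, 170L)
    host_gene <- paste0("T_", gene_ids[(d - 1L) %% 10L + 1L])
    if (is.null(plan[[host_gene]]) ||
        !m %in% plan[[host_gene]]$mirna_id)
      add_site(host_gene, m, 660L)
  }

  hosts <- c(structure(genes, names = paste0("T_", names(genes))), lnc)
  # write the planted motifs into the genome ('+' hosts only, by construction)
  for (hid in names(plan)) {
    tx <- hosts[[hid]]
    pos <- .spliced_positions(tx)
    for (r in seq_len(nrow(plan[[hid]]))) {
      motif <- chartr("U", "T", sites[[plan[[hid]]$mirna_id[r]]])
      gpos <- pos[plan[[hid]]$offset[r] + 1:7]
      chrom <- genome[[tx$chrom]]
      substr(chrom, min(gpos) + 1L, max(gpos) + 1L) <- motif
      genome[[tx$chrom]] <- chrom
    }
  }

  # scrub every stray seed complement so MRE hits are exactly the planted ones
  planted_key <- unlist(lapply(names(plan), function(hid)
    paste(hid, plan[[hid]]$mirna_id, plan[[hid]]$offset)), use.names = FALSE)
  protected <- unlist(lapply(names(plan), function(hid) {
    tx <- hosts[[hid]]; pos <- .spliced_positions(tx)
    paste(tx$chrom,
          unlist(lapply(plan[[hid]]$offset, function(o) pos[o + 1:7])))
  }), use.names = FALSE)
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  for (pass in 1:20) {
    seq_vec <- vapply(hosts, .splice, "", genome = genome)
    stray <- list()
    for (mi in mirna_ids) {
      gm <- gregexpr(chartr("U", "T", sites[[mi]]), chartr("U", "T", seq_vec),
                     fixed = TRUE)
      for (h in which(vapply(gm, function(g) g[1L] != -1L, logical(1)))) {
        hid <- names(hosts)[h]
        for (off in as.integer(gm[[h]]) - 1L)
          if (!paste(hid, mi, off) %in% planted_key)
            stray[[length(stray) + 1L]] <- list(host = hid, offset = off)
      }
    }
    if (!length(stray)) break
    fixed_any <- FALSE
    for (st in stray) {
      tx <- hosts[[st$host]]
      pos <- .spliced_positions(tx)
      gpos <- pos[st$offset + 1:7]
      # a stray fully covered by planted windows of an overlapping host is
      # left in place: it can only sit on flat-expression decoys, which the
      # correlation rules exclude from triads regardless
      free <- gpos[!paste(tx$chrom, gpos) %in% protected]
      if (!length(free)) next
      g <- free[1L]
      chrom <- genome[[tx$chrom]]
      substr(chrom, g + 1L, g + 1L) <- flip[[substr(chrom, g + 1L, g + 1L)]]
      genome[[tx$chrom]] <- chrom
      fixed_any <- TRUE
    }
    if (!fixed_any) break
  }
  seqs <- lapply(hosts, .splice, genome = genome)
  gene_seqs <- structure(unlist(seqs[paste0("T_", gene_ids)]),
                         names = gene_ids)
  lnc_seqs <- unlist(seqs[names(lnc)])

  # --- expression ----------------------------------------------------------
  e <- config$effect_log2fc
  step <- config$triad_stage_step
  jit <- config$stage_jitter_sd
  de_patterns <- list(early_up = c(0, e, e), early_down = c(e, 0, 0),
                      late_up = c(0, 0, e), late_down = c(e, e, 0))

  log2_rows <- list()   # feature -> per-sample log2 mean
  plant_lfc <- list()   # feature -> designed stage means (for DE truth)
  triad_lnc_log2 <- list()

  for (id in names(lnc)[roles %in% c("classed", "site_decoy",
                                     "structure_fail", "coding_like")])
    log2_rows[[id]] <- .stage_log2(rep(stats::runif(1, 9, 11), 3L))
  for (t in seq_len(nt)) {
    id <- sprintf("LNC_triad_%02d", t)
    base <- stats::runif(1, 9, 10)
    v <- .stage_log2(base + step * 0:2, jit)
    triad_lnc_log2[[t]] <- list(base = base, values = v)
    log2_rows[[id]] <- v
    plant_lfc[[id]] <- base + step * 0:2
  }
  for (d in seq_len(n_expr)) {
    id <- sprintf("LNC_exprd_%03d", d)
    base <- stats::runif(1, 9, 10)
    log2_rows[[id]] <- .stage_log2(base + step * 0:2, jit)
  }
  de_ids <- names(lnc)[roles == "de_planted"]
  for (k in seq_along(de_ids)) {
    pat <- de_patterns[[(k - 1L) %% 4L + 1L]]
    base <- stats::runif(1, 11, 13)
    log2_rows[[de_ids[k]]] <- .stage_log2(base + pat, jit)
    plant_lfc[[de_ids[k]]] <- base + pat
  }

  gene_log2 <- list()
  mrna_plant <- list()
  for (g in seq_along(gene_ids)) {
    gid <- gene_ids[g]
    if (g >= 11L && g <= 20L) {                      # DE-planted mRNAs
      pat <- de_patterns[[(g - 11L) %% 4L + 1L]]
      base <- stats::runif(1, 11, 13)
      gene_log2[[gid]] <- .stage_log2(base + pat, jit)
      mrna_plant[[paste0("T_", gid)]] <- base + pat
    } else if (g > n_side + 1L && g <= n_side + 1L + nt) { # triad mRNAs
      t <- g - n_side - 1L
      gene_log2[[gid]] <- triad_lnc_log2[[t]]$values + stats::rnorm(9L, 0, 0.15)
      mrna_plant[[paste0("T_", gid)]] <- triad_lnc_log2[[t]]$base + step * 0:2
    } else {
      gene_log2[[gid]] <- .stage_log2(rep(stats::runif(1, 9, 11), 3L))
    }
  }

  mir_log2 <- list()
  mir_plant <- list()
  for (i in seq_along(mirna_ids)) {
    mi <- mirna_ids[i]
    if (i <= nt) {                                   # triad miRNAs: sponge-coupled
      t <- i
      base <- stats::runif(1, 8, 9)
      mir_log2[[mi]] <- base -
        (triad_lnc_log2[[t]]$values - triad_lnc_log2[[t]]$base) +
        stats::rnorm(9L, 0, 0.15)
      mir_plant[[mi]] <- base - step * 0:2
    } else if (mi %in% exprd_mir) {                  # anticorrelated decoys
      base <- stats::runif(1, 8, 9)
      mir_log2[[mi]] <- .stage_log2(base - step * 0:2, jit)
      mir_plant[[mi]] <- base - step * 0:2
    } else {
      mir_log2[[mi]] <- .stage_log2(rep(stats::runif(1, 7, 9), 3L))
    }
  }

  draw_layer <- function(rows, layer) {
    m <- t(vapply(rows, function(lm) .draw_counts(lm, config$nb_dispersion),
                  numeric(9L)))
    colnames(m) <- .SAMPLES
    abundance_matrix(m, layer, "raw_count", .GROUPS, .LIBSIZE)
  }
  lnc_counts <- draw_layer(log2_rows[setdiff(names(lnc),
                                             names(lnc)[roles == "trans"])],
                           "lncRNA")
  mrna_counts <- draw_layer(structure(gene_log2[gene_ids],
                                      names = paste0("T_", gene_ids)), "mRNA")
  mir_counts <- draw_layer(mir_log2[mirna_ids], "miRNA")

  # planted trans pairs: exact 2x copies of a gene's counts (Pearson r = 1)
  trans_ids <- names(lnc)[roles == "trans"]
  trans_pairs <- data.frame(lncrna_id = trans_ids,
                            mrna_id = paste0("T_", gene_ids[10L + seq_along(trans_ids)]),
                            stringsAsFactors = FALSE)
  trans_rows <- 2 * mrna_counts$values[trans_pairs$mrna_id, , drop = FALSE]
  rownames(trans_rows) <- trans_ids
  lnc_counts <- abundance_matrix(rbind(lnc_counts$values, trans_rows)[names(lnc), ],
                                 "lncRNA", "raw_count", .GROUPS, .LIBSIZE)

  # --- metabolites ----------------------------------------------------------
  met_ids <- sprintf("met%03d", seq_len(config$n_metabolites))
  n_ds <- min(nt, config$n_metabolites)
  met_vals <- matrix(0, config$n_metabolites, 9L,
                     dimnames = list(met_ids, .SAMPLES))
  met_target <- rep(NA_character_, config$n_metabolites)
  for (j in seq_len(config$n_metabolites)) {
    if (j <= n_ds) {
      gid <- chr2_gene(j + 1L)
      fpkm <- mrna_counts$values[paste0("T_", gid), ] /
        (800 / 1e3) / (.LIBSIZE / 1e6)
      mu <- config$metabolite_slope * fpkm
      met_vals[j, ] <- pmax(0, mu + stats::rnorm(9L, 0,
        config$metabolite_sigma * config$metabolite_slope * mean(fpkm)))
      met_target[j] <- paste0("T_", gid)
    } else {
      met_vals[j, ] <- 2^.stage_log2(rep(stats::runif(1, 10, 14), 3L)) *
        stats::rlnorm(9L, 0, 0.2)
    }
  }
  metab <- abundance_matrix(met_vals, "metabolite", "intensity", .GROUPS)
  vip <- data.frame(metabolite_id = met_ids,
                    vip = c(stats::runif(n_ds, 1.2, 2.5),
                            stats::runif(config$n_metabolites - n_ds, 0.2, 0.8)),
                    stringsAsFactors = FALSE)

  # --- coding-potential scores ---------------------------------------------
  ids_all <- names(lnc)
  is_coding_like <- roles == "coding_like"
  scores <- data.frame(
    transcript_id = ids_all,
    cnci_score = ifelse(is_coding_like, stats::runif(length(ids_all), 0.5, 3),
                        stats::runif(length(ids_all), -5, -0.5)),
    cpc2_probability = ifelse(is_coding_like,
                              stats::runif(length(ids_all), 0.55, 0.95),
                              stats::runif(length(ids_all), 0.05, 0.45)),
    stringsAsFactors = FALSE)

  # --- lengths and truth ----------------------------------------------------
  lengths <- c(vapply(lnc, exonic_length, 0L),
               structure(rep(800L, length(gene_ids)), names = paste0("T_", gene_ids)),
               vapply(mirna_seqs, nchar, 0L))

  comparisons <- list(comparison_group("McII", "McI"),
                      comparison_group("McIII", "McI"),
                      comparison_group("McIII", "McII"))
  stage_idx <- c(McI = 1L, McII = 2L, McIII = 3L)
  de_truth <- function(plants, log2fc_min) {
    rows <- list()
    for (id in names(plants)) for (cmp in comparisons) {
      lfc <- plants[[id]][stage_idx[[cmp$case_group]]] -
        plants[[id]][stage_idx[[cmp$control_group]]]
      dir <- if (lfc >= log2fc_min) "up"
      else if (lfc <= -log2fc_min) "down" else "ns"
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = id, comparison = cmp$name, direction = dir,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  truth <- list(
    lnc_called = sort(names(lnc)[!roles %in% c("structure_fail", "coding_like")]),
    classes = data.frame(
      transcript_id = names(meta),
      category = vapply(meta, `[[`, "", "class"),
      anchor_gene_id = vapply(meta, `[[`, "", "anchor"),
      role = unname(roles), stringsAsFactors = FALSE, row.names = NULL),
    class_codes = structure(vapply(meta, `[[`, "", "code"), names = names(meta)),
    de = list(lncRNA = de_truth(plant_lfc, 1),
              mRNA = de_truth(mrna_plant, 1),
              miRNA = de_truth(mir_plant, 0.585)),
    triads = data.frame(
      lncrna_id = sprintf("LNC_triad_%02d", seq_len(nt)),
      mirna_id = triad_mir,
      mrna_id = paste0("T_", vapply(seq_len(nt) + 1L, chr2_gene, "")),
      stringsAsFactors = FALSE),
    decoy_chains = rbind(
      data.frame(lncrna_id = sprintf("LNC_sited_%03d", seq_len(n_site)),
                 mirna_id = sited_mir[(seq_len(n_site) - 1L) %% 5L + 1L],
                 mrna_id = paste0("T_", gene_ids[(seq_len(n_site) - 1L) %% 10L + 1L]),
                 type = "site", stringsAsFactors = FALSE),
      data.frame(lncrna_id = sprintf("LNC_exprd_%03d", seq_len(n_expr)),
                 mirna_id = exprd_mir[(seq_len(n_expr) - 1L) %% 5L + 1L],
                 mrna_id = paste0("T_", gene_ids[10L + (seq_len(n_expr) - 1L) %% 10L + 1L]),
                 type = "expression", stringsAsFactors = FALSE)),
    ds_metabolites = met_ids[seq_len(n_ds)],
    metabolite_targets = structure(met_target, names = met_ids),
    trans_pairs = trans_pairs)

  structure(list(
    config = config, genome = genome, reference = genes, assembled = lnc,
    gene_seqs = gene_seqs, lnc_seqs = lnc_seqs, mirna_seqs = mirna_seqs,
    counts = list(lncRNA = lnc_counts, miRNA = mir_counts, mRNA = mrna_counts),
    metabolites = metab, scores = scores, vip = vip, lengths = lengths,
    sample_groups = .GROUPS, library_sizes = .LIBSIZE,
    comparisons = comparisons, truth = truth), class = "synthetic_bundle")
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' FASTA (genome, lncRNA, mRNA, miRNA), GTF (reference + assembled), TSV
#' (counts per layer, metabolites, scores, VIP, lengths), YAML (sample to
#' group map and library sizes) and a JSON truth file. Output is
#' byte-deterministic for a given bundle.
#'
#' @param bundle A `synthetic_bundle` from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_fasta(unlist(bundle$genome), fp("genome.fa"))
  write_gtf(bundle$reference, fp("reference.gtf"))
  write_gtf(bundle$assembled, fp("assembled.gtf"))
  write_fasta(bundle$lnc_seqs, fp("lncrna.fa"))
  write_fasta(structure(bundle$gene_seqs,
                        names = paste0("T_", names(bundle$gene_seqs))),
              fp("mrna.fa"))
  write_fasta(bundle$mirna_seqs, fp("mirna.fa"))
  for (layer in names(bundle$counts))
    write_abundance(bundle$counts[[layer]],
                    fp(paste0("counts_", layer, ".tsv")))
  write_abundance(bundle$metabolites, fp("metabolites.tsv"))
  utils::write.table(bundle$scores, fp("scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$vip, fp("vip.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(bundle$lengths),
               length = unname(bundle$lengths)),
    fp("lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(sample_groups = as.list(bundle$sample_groups),
                        library_sizes = as.list(bundle$library_sizes)),
                   fp("samples.yaml"))
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Study-scale fixture: a lncRNA count matrix + coding-potential score table
# whose planted memberships realize a fixed table of headline set cardinalities.
# ---------------------------------------------------------------------------

# Region design for the three stage comparisons A = McII_vs_McI,
# B = McIII_vs_McI, C = McIII_vs_McII. Exclusive-region sizes are derived
# from the per-comparison totals (418/1154/880), the three-way intersection
# (67) and pairwise overlaps (100/120/800) summing so that the union is
# 1499. Each region row fixes the planted (a, b) = (lfc II/I, lfc III/I);
# the third comparison follows by additivity c = b - a. Every planted |lfc|
# sits at least 0.2 log2 units away from the 1.0 decision boundary.
.study_regions <- function() {
  reg <- data.frame(
    region = c("A_up", "A_down", "B_up", "B_down", "C_up", "C_down",
               "AB_uu", "AB_dd", "AC_ud", "AC_du", "BC_uu", "BC_dd",
               "ABC_uuu", "ABC_ddd", "null"),
    n = c(112L, 153L, 141L, 180L, 6L, 21L,
          17L, 16L, 27L, 26L, 360L, 373L, 34L, 33L, 2456L),
    a = c(1.6, -1.6, 0.8, -0.8, -0.8, 0.8,
          1.5, -1.5, 1.5, -1.5, 0, 0, 1.5, -1.5, 0),
    b = c(0.8, -0.8, 1.6, -1.6, 0.8, -0.8,
          1.5, -1.5, 0, 0, 1.5, -1.5, 3, -3, 0),
    stringsAsFactors = FALSE)
  reg$c <- reg$b - reg$a
  dir_of <- function(x) ifelse(x >= 1, "up", ifelse(x <= -1, "down", "ns"))
  tot <- function(lfc, d) sum(reg$n[dir_of(lfc) == d])
  chk <- c(A_up = tot(reg$a, "up"), A_down = tot(reg$a, "down"),
           B_up = tot(reg$b, "up"), B_down = tot(reg$b, "down"),
           C_up = tot(reg$c, "up"), C_down = tot(reg$c, "down"))
  want <- c(A_up = 190, A_down = 228, B_up = 552, B_down = 602,
            C_up = 426, C_down = 454)
  if (!isTRUE(all.equal(chk, want)))
    stop("study fixture region design violates its inclusion-exclusion ",
         "identities: got ", paste(names(chk), chk, collapse = ", "))
  reg
}

#' Packaged study-scale fixture
#'
#' A lncRNA study fixture whose planted memberships realize a fixed
#' table of headline set cardinalities: per-comparison up/down counts
#' 190/228 (McII vs McI), 552/602 (McIII vs McI), 426/454 (McIII vs McII),
#' a three-way common set of 67, a union of 1499, and coding-potential
#' single-criterion sets of 4508 (CNCI-like) and 6567 (CPC2-like) with
#' intersection 3955. Effects are planted with >= 0.2 log2 margin to every
#' decision boundary and counts drawn at dispersion 1e-4, so thresholded
#' recovery of the planted cardinalities is exact regardless of seed.
#'
#' @param seed Integer RNG seed (default 42).
#' @return A `study_fixture` list: `scores` (7520 transcripts), `counts`
#'   (3955 x 9 lncRNA raw counts), `lengths`, `comparisons`, `truth`.
#' @export
study_fixture <- function(seed = 42L) {
  set.seed(as.integer(seed))
  n_both <- 3955L; n_cnci_only <- 553L; n_cpc2_only <- 2612L; n_neither <- 400L
  n_all <- n_both + n_cnci_only + n_cpc2_only + n_neither
  ids <- sprintf("TX%05d", seq_len(n_all))
  stratum <- rep(c("both", "cnci_only", "cpc2_only", "neither"),
                 c(n_both, n_cnci_only, n_cpc2_only, n_neither))
  cnci_pass <- stratum %in% c("both", "cnci_only")
  cpc2_pass <- stratum %in% c("both", "cpc2_only")
  scores <- data.frame(
    transcript_id = ids,
    cnci_score = ifelse(cnci_pass, stats::runif(n_all, -5, -0.5),
                        stats::runif(n_all, 0.5, 5)),
    cpc2_probability = ifelse(cpc2_pass, stats::runif(n_all, 0.05, 0.45),
                              stats::runif(n_all, 0.55, 0.95)),
    stringsAsFactors = FALSE)

  reg <- .study_regions()
  lnc_ids <- ids[stratum == "both"]
  stopifnot(sum(reg$n) == length(lnc_ids))
  region_of <- rep(reg$region, reg$n)
  a <- rep(reg$a, reg$n); b <- rep(reg$b, reg$n)

  # planted FPKM group means on the pseudocount-shifted scale so the
  # realized log2 ratios equal the design exactly
  f1 <- stats::runif(length(lnc_ids), 400, 800)
  f2 <- (f1 + 1) * 2^a - 1
  f3 <- (f1 + 1) * 2^b - 1
  # length 1000 bp, library 5e6 -> count mean = 5 * FPKM
  mu <- cbind(f1, f1, f1, f2, f2, f2, f3, f3, f3) * 5
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1e4),
                   nrow = nrow(mu), dimnames = list(lnc_ids, .SAMPLES))
  ab <- abundance_matrix(counts, "lncRNA", "raw_count", .GROUPS, .LIBSIZE)

  dir_of <- function(x) ifelse(x >= 1, "up", ifelse(x <= -1, "down", "ns"))
  truth <- list(
    regions = data.frame(feature_id = lnc_ids, region = region_of,
                         a = a, b = b, c = b - a, stringsAsFactors = FALSE),
    expected = list(
      McII_vs_McI = c(up = 190L, down = 228L),
      McIII_vs_McI = c(up = 552L, down = 602L),
      McIII_vs_McII = c(up = 426L, down = 454L),
      common = 67L, union = 1499L,
      cnci = 4508L, cpc2 = 6567L, both = 3955L),
    directions = data.frame(
      feature_id = rep(lnc_ids, 3L),
      comparison = rep(c("McII_vs_McI", "McIII_vs_McI", "McIII_vs_McII"),
                       each = length(lnc_ids)),
      direction = c(dir_of(a), dir_of(b), dir_of(b - a)),
      stringsAsFactors = FALSE))

  structure(list(
    scores = scores, counts = ab,
    lengths = structure(rep(1000L, length(lnc_ids)), names = lnc_ids),
    comparisons = list(comparison_group("McII", "McI"),
                       comparison_group("McIII", "McI"),
                       comparison_group("McIII", "McII")),
    truth = truth), class = "study_fixture")
}

#' Run the differential stage on the study fixture
#'
#' FPKM normalization, the built-in Welch test, BH correction and the
#' lncRNA-layer thresholds for each of the three stage comparisons,
#' followed by the Venn arithmetic over the per-comparison DE sets and the
#' coding-potential calling on the fixture's score table. This is the
#' computation behind the fixture's headline set cardinalities.
#'
#' @param fixture A [study_fixture()].
#' @return List with `per_comparison` (data.frames with directions),
#'   `counts` (up/down per comparison), `venn` (common/union), and
#'   `calling` (cnci/cpc2/both set sizes).
#' @export
run_study_fixture_analysis <- function(fixture) {
  fpkm <- compute_fpkm(fixture$counts, fixture$lengths)
  thr <- threshold_config("lncRNA")
  per <- list()
  de_sets <- list()
  counts <- list()
  for (cmp in fixture$comparisons) {
    res <- de_test(fpkm, cmp, method = "welch_log")
    res$fdr <- benjamini_hochberg(res$p)
    res <- filter_de(res, thr)
    per[[cmp$name]] <- res
    de_sets[[cmp$name]] <- res$feature_id[res$direction != "ns"]
    counts[[cmp$name]] <- c(up = sum(res$direction == "up"),
                            down = sum(res$direction == "down"))
  }
  vn <- venn(de_sets)
  calling <- call_lncrnas(fixture$scores$transcript_id, fixture$scores)
  list(per_comparison = per, counts = counts,
       venn = list(common = length(vn$intersection),
                   union = length(vn$union)),
       calling = list(cnci = length(calling$cnci_set),
                      cpc2 = length(calling$cpc2_set),
                      both = length(calling$called)))
}
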