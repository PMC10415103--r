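#' Antisense-acting lncRNA-mRNA edges by duplex hybridization
#'
#' For every lncRNA classified as antisense, hybridizes its sequence against
#' the anchor gene's mRNA with [duplex_mfe()]; an edge is emitted iff the
#' duplex MFE is at or below `mfe_max` and the paired fraction (paired bases
#' over the shorter of the lncRNA length and a 50-nt window) reaches
#' `min_paired_fraction`.
#'
#' @param lnc_records data.frame with columns `transcript_id`, `category`,
#'   `anchor_gene_id` (as produced by the classification stage).
#' @param lnc_seqs,mrna_seqs Named RNA string vectors (mRNAs keyed by gene id).
#' @param model An [energy_model()].
#' @param mfe_max Emit edges with MFE <= this (model units; default -10).
#' @param min_paired_fraction Minimum paired fraction (default 0.5).
#' @return data.frame(lncrna_id, gene_id, model, statistic, paired_fraction).
#' @export
antisense_edges <- function(lnc_records, lnc_seqs, mrna_seqs,
                            model = energy_model(), mfe_max = -10,
                            min_paired_fraction = 0.5) {
  anti <- lnc_records[lnc_records$category == "antisense", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(anti))) {
    id <- anti$transcript_id[k]
    gene <- anti$anchor_gene_id[k]
    if (is.na(gene) || !gene %in% names(mrna_seqs) ||
        !id %in% names(lnc_seqs)) {
      warning("antisense lncRNA ", id, ": missing anchor mRNA sequence, skipped")
      next
    }
    d <- duplex_mfe(lnc_seqs[[id]], mrna_seqs[[gene]], model)
    pf <- d$n_paired / min(nchar(lnc_seqs[[id]]), 50L)
    if (d$mfe <= mfe_max && min(pf, 1) >= min_paired_fraction)
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = id, gene_id = gene, model = "antisense",
        statistic = d$mfe, paired_fraction = min(pf, 1),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      model = character(0), statistic = numeric(0),
                      paired_fraction = numeric(0)))
  do.call(rbind, out)
}

#' Cis-acting lncRNA-gene edges by genomic proximity
#'
#' Every protein-coding gene whose span lies within `window` bp of a
#' lncRNA's span (or overlaps it) on the same chromosome, any strand,
#' yields an edge. The statistic is the signed gap in bp: positive when the
#' gene lies 5' of the lncRNA on the forward axis, negative when 3', zero
#' when the spans overlap.
#'
#' @param lncrnas,pcgs Lists of [transcript_model()].
#' @param window Neighborhood size in bp (default 10 kb).
#' @return data.frame(lncrna_id, gene_id, model, statistic).
#' @export
cis_edges <- function(lncrnas, pcgs, window = 10000L) {
  out <- list()
  for (lnc in lncrnas) {
    for (p in pcgs) {
      if (p$chrom != lnc$chrom) next
      d <- if (ranges_overlap(lnc$start, lnc$end, p$start, p$end)) 0L
      else if (p$end <= lnc$start) lnc$start - p$end
      else -(p$start - lnc$end)
      if (abs(d) <= window)
        out[[length(out) + 1L]] <- data.frame(
          lncrna_id = lnc$transcript_id, gene_id = p$gene_id,
          model = "cis", statistic = as.numeric(d), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      model = character(0), statistic = numeric(0)))
  do.call(rbind, out)
}

#' Trans-acting lncRNA-gene edges by co-expression
#'
#' Pearson correlation per (lncRNA, gene) pair across the shared sample
#' columns; an edge requires `r > r_min` (strict, default 0.999).
#' Anticorrelated pairs (`r < -r_min`) are reported separately, not as
#' edges. Zero-variance features are skipped with a logged count, and pairs
#' already linked by a cis edge can be excluded so the two models stay
#' mutually exclusive.
#'
#' @param lnc_expr,mrna_expr [abundance_matrix()] objects (or plain
#'   matrices) with identical sample columns, >= 3 samples.
#' @param r_min Strict lower bound on r.
#' @param exclude Optional data.frame with `lncrna_id`, `gene_id` columns
#'   (e.g. the cis edge table).
#' @return List with `edges` and `anticorrelated` data.frames
#'   (lncrna_id, gene_id, model, statistic = r).
#' @export
trans_edges <- function(lnc_expr, mrna_expr, r_min = 0.999, exclude = NULL) {
  xl <- if (inherits(lnc_expr, "abundance_matrix")) lnc_expr$values else lnc_expr
  xm <- if (inherits(mrna_expr, "abundance_matrix")) mrna_expr$values else mrna_expr
  if (!identical(colnames(xl), colnames(xm)))
    stop("trans_edges: sample columns differ between matrices")
  if (ncol(xl) < 3L) stop("trans_edges needs >= 3 samples")
  sd_l <- apply(xl, 1L, stats::sd)
  sd_m <- apply(xm, 1L, stats::sd)
  n_skip <- sum(sd_l == 0) + sum(sd_m == 0)
  if (n_skip > 0L)
    message("trans_edges: skipped ", n_skip, " zero-variance feature(s)")
  xl <- xl[sd_l > 0, , drop = FALSE]
  xm <- xm[sd_m > 0, , drop = FALSE]
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      model = character(0), statistic = numeric(0))
  if (!nrow(xl) || !nrow(xm))
    return(list(edges = empty, anticorrelated = empty))
  r <- stats::cor(t(xl), t(xm))
  as_edges <- function(idx) {
    if (!nrow(idx)) return(empty)
    df <- data.frame(lncrna_id = rownames(xl)[idx[, 1L]],
                     gene_id = rownames(xm)[idx[, 2L]],
                     model = "trans", statistic = r[idx],
                     stringsAsFactors = FALSE)
    if (!is.null(exclude) && nrow(exclude))
      df <- df[!paste(df$lncrna_id, df$gene_id) %in%
                 paste(exclude$lncrna_id, exclude$gene_id), , drop = FALSE]
    df[order(df$lncrna_id, df$gene_id, method = "radix"), , drop = FALSE]
  }
  list(edges = as_edges(which(r > r_min, arr.ind = TRUE)),
       anticorrelated = as_edges(which(r < -r_min, arr.ind = TRUE)))
}
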