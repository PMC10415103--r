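#' Call lncRNAs by coding-potential score intersection
#'
#' A candidate is called iff its CNCI-like sequence score is strictly below
#' `cnci_max` (default 0) AND its CPC2-like coding probability is strictly
#' below `cpc2_max` (default 0.5): the intersection of the two
#' single-criterion sets, which are also returned for Venn reporting.
#'
#' @param candidates Character vector of candidate transcript ids.
#' @param scores data.frame with columns `transcript_id`, `cnci_score`,
#'   `cpc2_probability`.
#' @param cnci_max,cpc2_max Strict upper thresholds.
#' @return List with `called`, `cnci_set`, `cpc2_set` (character vectors).
#' @export
call_lncrnas <- function(candidates, scores, cnci_max = 0, cpc2_max = 0.5) {
  stopifnot(all(c("transcript_id", "cnci_score", "cpc2_probability") %in%
                  names(scores)))
  if (any(scores$cpc2_probability < 0 | scores$cpc2_probability > 1))
    stop("cpc2_probability outside [0, 1]")
  idx <- match(candidates, scores$transcript_id)
  if (anyNA(idx))
    stop("candidate(s) without a coding-potential score: ",
         paste(candidates[is.na(idx)], collapse = ", "))
  cnci <- scores$cnci_score[idx]
  cpc2 <- scores$cpc2_probability[idx]
  list(called = candidates[cnci < cnci_max & cpc2 < cpc2_max],
       cnci_set = candidates[cnci < cnci_max],
       cpc2_set = candidates[cpc2 < cpc2_max])
}

#' Classify a lncRNA into the five positional categories
#'
#' Deterministic precedence (first match wins), relative to protein-coding
#' genes (PCGs):
#'
#' 1. `intronic` — same strand, fully inside one PCG intron
#' 2. `sense`    — same strand, span overlapping a PCG (its exons/introns)
#' 3. `bidirectional` — opposite strand, transcription start within
#'    `promoter_window` bp upstream of a PCG's transcription start, no
#'    exonic overlap with that PCG
#' 4. `antisense` — opposite strand, exonic overlap with a PCG
#' 5. `intergenic` — no PCG overlap, and PCG spans exist on both sides on
#'    the same chromosome
#' 6. `unclassified` — anything else (e.g. a chromosome end with no
#'    flanking PCG)
#'
#' @param lnc A [transcript_model()].
#' @param pcgs List of coding [transcript_model()]s.
#' @param promoter_window Promoter size in bp upstream of the annotated TSS
#'   (default 1000, i.e. 1 kb).
#' @return List with `category` and `anchor_gene_id` (NA where not applicable).
#' @export
classify_lncrna_position <- function(lnc, pcgs, promoter_window = 1000L) {
  pcgs <- Filter(function(p) p$biotype == "coding", pcgs)
  same_chrom <- Filter(function(p) p$chrom == lnc$chrom, pcgs)
  if (length(same_chrom)) {
    ord <- order(vapply(same_chrom, `[[`, 0L, "start"),
                 vapply(same_chrom, `[[`, "", "gene_id"), method = "radix")
    same_chrom <- same_chrom[ord]
  }
  res <- function(category, anchor = NA_character_)
    list(category = category, anchor_gene_id = anchor)

  same_strand <- Filter(function(p) p$strand == lnc$strand, same_chrom)
  opp_strand <- Filter(function(p) p$strand != lnc$strand, same_chrom)

  # 1. intronic
  for (p in same_strand) {
    pi <- introns(p)
    if (nrow(pi) && any(pi[, 1L] <= lnc$start & lnc$end <= pi[, 2L]))
      return(res("intronic", p$gene_id))
  }
  # 2. sense: same-strand span overlap with the gene body
  for (p in same_strand)
    if (ranges_overlap(lnc$start, lnc$end, p$start, p$end))
      return(res("sense", p$gene_id))
  # 3. bidirectional: divergent promoter-proximal arrangement
  lnc_tss <- tss(lnc)
  for (p in opp_strand) {
    d <- if (p$strand == "+") p$start - lnc_tss else lnc_tss - (p$end - 1L)
    if (d > 0L && d <= promoter_window && !exonic_overlap(lnc, p))
      return(res("bidirectional", p$gene_id))
  }
  # 4. antisense: opposite-strand exonic overlap
  for (p in opp_strand)
    if (exonic_overlap(lnc, p))
      return(res("antisense", p$gene_id))
  # 5. intergenic: flanked by PCG spans on both sides, no overlap
  overlaps_any <- any(vapply(same_chrom, function(p)
    ranges_overlap(lnc$start, lnc$end, p$start, p$end), logical(1)))
  if (!overlaps_any && length(same_chrom)) {
    left <- any(vapply(same_chrom, function(p) p$end <= lnc$start, logical(1)))
    right <- any(vapply(same_chrom, function(p) p$start >= lnc$end, logical(1)))
    if (left && right) return(res("intergenic"))
  }
  res("unclassified")
}
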