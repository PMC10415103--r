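#' Assign a cuffcompare-style class code to an assembled transcript
#'
#' Compares a query transcript against a reference annotation and returns the
#' first matching code in a fixed specificity order (most specific spatial
#' relation first):
#'
#' * `=` exact intron-chain match (same ordered intron set, same strand,
#'   overlapping span)
#' * `c` query contained within a same-strand reference with a compatible
#'   intron chain (every query intron is a reference intron)
#' * `j` multi-exon query sharing at least one splice junction with a
#'   same-strand reference, chain otherwise different
#' * `e` single-exon query overlapping a reference exon and extending into
#'   an adjacent intron
#' * `o` other same-strand exonic overlap
#' * `x` exonic overlap with a reference on the opposite strand
#' * `i` query entirely within a single same-strand reference intron
#' * `u` no overlap with any reference transcript span
#' * `other` anything else (e.g. span overlap without exonic overlap)
#'
#' @param query A [transcript_model()].
#' @param reference List of reference [transcript_model()]s.
#' @return A list with `code` and `reference_transcript_id` (NA for `u`/`other`).
#' @export
assign_class_code <- function(query, reference) {
  # deterministic reference order: chrom, start, id
  if (length(reference)) {
    ord <- order(vapply(reference, `[[`, "", "chrom"),
                 vapply(reference, `[[`, 0L, "start"),
                 vapply(reference, `[[`, "", "transcript_id"),
                 method = "radix")
    reference <- reference[ord]
  }
  hit <- function(code, ref) list(code = code,
                                  reference_transcript_id = ref$transcript_id)
  q_introns <- introns(query)
  same_chrom <- Filter(function(r) r$chrom == query$chrom, reference)
  span_ovl <- Filter(function(r) ranges_overlap(query$start, query$end,
                                                r$start, r$end), same_chrom)
  if (!length(span_ovl))
    return(list(code = "u", reference_transcript_id = NA_character_))
  same_strand <- Filter(function(r) r$strand == query$strand, span_ovl)

  intron_key <- function(m) paste(m[, 1L], m[, 2L], sep = "-", collapse = ";")

  # "=": identical ordered intron chain
  for (r in same_strand)
    if (identical(intron_key(q_introns), intron_key(introns(r))))
      return(hit("=", r))
  # "c": contained, compatible chain — every query intron is a reference
  # intron AND no query exon spills into a reference intron (a spilling
  # mono-exon query is "e" territory)
  for (r in same_strand) {
    if (query$start < r$start || query$end > r$end) next
    ri <- introns(r)
    chain_ok <- nrow(q_introns) == 0L ||
      all(paste(q_introns[, 1L], q_introns[, 2L]) %in%
            paste(ri[, 1L], ri[, 2L]))
    exon_clean <- !nrow(ri) || !any(vapply(seq_along(query$exon_starts),
      function(i) any(ranges_overlap(query$exon_starts[i], query$exon_ends[i],
                                     ri[, 1L], ri[, 2L])), logical(1)))
    if (chain_ok && exon_clean && exonic_overlap(query, r))
      return(hit("c", r))
  }
  # "j": shares >= 1 junction, chain differs
  if (nrow(q_introns) > 0L) {
    for (r in same_strand) {
      ri <- introns(r)
      if (nrow(ri) && any(paste(q_introns[, 1L], q_introns[, 2L]) %in%
                          paste(ri[, 1L], ri[, 2L])))
        return(hit("j", r))
    }
  }
  # "e": single-exon query over a reference exon, extending into an intron
  if (n_exons(query) == 1L) {
    for (r in same_strand) {
      if (!exonic_overlap(query, r)) next
      ri <- introns(r)
      if (nrow(ri) && any(ranges_overlap(query$start, query$end,
                                         ri[, 1L], ri[, 2L])))
        return(hit("e", r))
    }
  }
  # "o": generic same-strand exonic overlap
  for (r in same_strand)
    if (exonic_overlap(query, r)) return(hit("o", r))
  # "x": opposite-strand exonic overlap
  for (r in span_ovl)
    if (r$strand != query$strand && exonic_overlap(query, r))
      return(hit("x", r))
  # "i": fully inside a single same-strand reference intron
  for (r in same_strand) {
    ri <- introns(r)
    if (nrow(ri) && any(ri[, 1L] <= query$start & query$end <= ri[, 2L]))
      return(hit("i", r))
  }
  list(code = "other", reference_transcript_id = NA_character_)
}

#' Filter assembled transcripts down to novel-transcript candidates
#'
#' A transcript is kept iff its class code is one of `u, i, j, x, c, e, o`,
#' its exonic length exceeds `min_length` and its exon count exceeds
#' `min_exons` (strict inequalities, defaults as conventionally printed:
#' > 200 bp, > 1 exon).
#'
#' @param transcripts Named list of [transcript_model()].
#' @param class_codes List of class-code results (parallel to `transcripts`)
#'   as returned by [assign_class_code()].
#' @param novel_codes Codes considered novel.
#' @param min_length Exonic length must be strictly greater than this.
#' @param min_exons Exon count must be strictly greater than this.
#' @return The surviving subset of `transcripts`.
#' @export
filter_novel <- function(transcripts, class_codes,
                         novel_codes = c("u", "i", "j", "x", "c", "e", "o"),
                         min_length = 200L, min_exons = 1L) {
  stopifnot(length(transcripts) == length(class_codes))
  keep <- vapply(seq_along(transcripts), function(i) {
    tx <- transcripts[[i]]
    class_codes[[i]]$code %in% novel_codes &&
      exonic_length(tx) > min_length && n_exons(tx) > min_exons
  }, logical(1))
  transcripts[keep]
}
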