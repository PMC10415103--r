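#' Genomic interval
#'
#' Strand-aware interval in the package-internal coordinate convention:
#' 0-based, half-open `[start, end)`. GTF/GFF3 coordinates (1-based,
#' inclusive) are converted at the I/O boundary only.
#'
#' @param chrom Sequence (chromosome/scaffold) identifier.
#' @param start Non-negative integer, 0-based.
#' @param end Integer strictly greater than `start` (half-open).
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_interval` object (a named list).
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || start < 0L) stop("interval start must be a non-negative integer")
  if (is.na(end) || end <= start) stop("interval end must be > start (0-based half-open)")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-', got: ", strand)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' Transcript model
#'
#' An exon-chain transcript: the substrate for class-code assignment and
#' positional lncRNA classification. Exons must be non-overlapping, sorted,
#' and all on the transcript's chromosome and strand; the span is derived
#' as `[min exon start, max exon end)`.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom,strand Location of the transcript and all of its exons.
#' @param exon_starts,exon_ends Parallel integer vectors, 0-based half-open.
#' @param biotype `"coding"`, `"noncoding"` or `"unknown"`.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             biotype = c("unknown", "coding", "noncoding")) {
  biotype <- match.arg(biotype)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L)
    stop("transcript ", transcript_id, ": need >= 1 exon with paired starts/ends")
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (any(exon_ends <= exon_starts))
    stop("transcript ", transcript_id, ": exon end must be > start")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("transcript ", transcript_id, ": exons overlap")
  if (!strand %in% c("+", "-"))
    stop("transcript ", transcript_id, ": strand must be '+' or '-'")
  structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    start = exon_starts[1L],
    end = exon_ends[length(exon_ends)],
    exon_starts = exon_starts,
    exon_ends = exon_ends,
    biotype = biotype
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d(%s) %d exon(s), %d nt exonic>\n",
              x$transcript_id, x$gene_id, x$chrom, x$start, x$end, x$strand,
              n_exons(x), exonic_length(x)))
  invisible(x)
}

#' Number of exons of a transcript model
#' @param tx A `transcript_model`.
#' @export
n_exons <- function(tx) length(tx$exon_starts)

#' Total exonic (spliced) length of a transcript model, in bp
#' @param tx A `transcript_model`.
#' @export
exonic_length <- function(tx) sum(tx$exon_ends - tx$exon_starts)

# Intron intervals as a 2-column matrix (start, end), 0-based half-open;
# zero rows for single-exon transcripts.
introns <- function(tx) {
  k <- n_exons(tx)
  if (k < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = tx$exon_ends[-k], end = tx$exon_starts[-1L])
}

# 0-based position of the first transcribed base (transcription start site).
tss <- function(tx) if (tx$strand == "+") tx$start else tx$end - 1L

# Half-open interval overlap.
ranges_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Any exon of tx1 overlapping any exon of tx2 (same chrom assumed checked).
exonic_overlap <- function(tx1, tx2) {
  for (i in seq_along(tx1$exon_starts))
    if (any(ranges_overlap(tx1$exon_starts[i], tx1$exon_ends[i],
                           tx2$exon_starts, tx2$exon_ends)))
      return(TRUE)
  FALSE
}

# Translate all coordinates of a transcript by a constant (used by the
# translation-invariance property tests and the generator).
shift_transcript <- function(tx, delta) {
  transcript_model(tx$transcript_id, tx$gene_id, tx$chrom, tx$strand,
                   tx$exon_starts + as.integer(delta),
                   tx$exon_ends + as.integer(delta), tx$biotype)
}
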