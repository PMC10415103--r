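#' Read transcript models from GTF or GFF3
#'
#' Coordinates are converted from the on-disk 1-based inclusive convention to
#' the internal 0-based half-open convention. Exon rows are grouped per
#' transcript and sorted; feature types other than transcript/mRNA/exon are
#' skipped with a logged count. A declared transcript with zero exon rows is
#' an error, as is a strandless (`.`) exon row: strand is semantically
#' required by the positional lncRNA classes.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` (attribute pairs) or `"gff3"` (`ID=`/`Parent=` chains).
#' @return A named list of [transcript_model()] objects (names = transcript ids).
#' @export
read_gtf <- function(path, dialect = c("gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  .scan_gxf_structure(path)

  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  type <- as.character(df$type)

  is_exon <- type == "exon"
  is_txrow <- type %in% c("transcript", "mRNA")
  n_skipped <- sum(!(is_exon | is_txrow))
  if (n_skipped > 0L)
    message("read_gtf: skipped ", n_skipped, " non-transcript/exon feature row(s)")

  if (dialect == "gtf") {
    if (is.null(df$transcript_id))
      stop("GTF lacks transcript_id attributes: ", path)
    ex_tx <- df$transcript_id[is_exon]
    ex_gene <- if (!is.null(df$gene_id)) df$gene_id[is_exon] else ex_tx
    declared <- unique(df$transcript_id[is_txrow])
  } else {
    parent1 <- vapply(df$Parent, function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    ex_tx <- parent1[is_exon]
    if (anyNA(ex_tx)) stop("GFF3 exon row without Parent attribute: ", path)
    tx_gene <- parent1[is_txrow]
    names(tx_gene) <- as.character(df$ID[is_txrow])
    ex_gene <- tx_gene[ex_tx]
    ex_gene[is.na(ex_gene)] <- ex_tx[is.na(ex_gene)]
    declared <- names(tx_gene)
  }

  missing_exons <- setdiff(declared, unique(ex_tx))
  if (length(missing_exons))
    stop("transcript(s) declared with zero exon rows: ",
         paste(missing_exons, collapse = ", "))

  ex <- data.frame(tx = ex_tx, gene = ex_gene,
                   chrom = df$seqnames[is_exon],
                   # GRanges keeps 1-based inclusive; internal is 0-based half-open
                   start = df$start[is_exon] - 1L, end = df$end[is_exon],
                   strand = df$strand[is_exon], stringsAsFactors = FALSE)
  if (any(ex$strand == "*"))
    stop("strandless ('.') exon rows are not allowed for transcripts: ",
         paste(unique(ex$tx[ex$strand == "*"]), collapse = ", "))

  out <- lapply(split(ex, ex$tx), function(g) {
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L)
      stop("transcript ", g$tx[1L], ": exons on mixed chromosome/strand")
    transcript_model(g$tx[1L], g$gene[1L], g$chrom[1L], g$strand[1L],
                     g$start, g$end)
  })
  out[order(names(out))]
}

# Structural pre-scan honoring the line-number error contract: 9 tab fields,
# numeric coordinates, end >= start (1-based inclusive on disk).
.scan_gxf_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed annotation line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop("malformed annotation line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("malformed annotation line ", i, ": end < start")
  }
  invisible(TRUE)
}

#' Write transcript models as GTF
#'
#' Internal round-trip writer (1-based inclusive on disk). Used by the
#' synthetic-data generator and the round-trip tests.
#'
#' @param transcripts List of [transcript_model()].
#' @param path Output path.
#' @export
write_gtf <- function(transcripts, path) {
  rows <- character(0)
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id, tx$transcript_id)
    rows <- c(rows,
              paste(tx$chrom, "cernaflow", "transcript", tx$start + 1L, tx$end,
                    ".", tx$strand, ".", attrs, sep = "\t"),
              paste(tx$chrom, "cernaflow", "exon", tx$exon_starts + 1L, tx$exon_ends,
                    ".", tx$strand, ".", attrs, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a FASTA file as uppercase RNA strings
#'
#' DNA input is transliterated (`T` -> `U`); mixed case is uppercased.
#' `N` (and the other IUPAC ambiguity codes) are legal but defined as never
#' pairable and never seed-matching downstream. Duplicate record ids and
#' non-IUPAC characters are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("Tt", "Uu", toupper(as.character(set)))
  names(seqs) <- ids
  bad <- grepl("[^ACGURYSWKMBDHVN]", seqs)
  if (any(bad))
    stop("non-IUPAC character in FASTA record(s): ",
         paste(ids[bad], collapse = ", "))
  seqs
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Feature-by-sample abundance matrix with layer metadata
#'
#' @param values Non-negative numeric matrix, rownames = feature ids,
#'   colnames = sample ids.
#' @param layer One of `"lncRNA"`, `"miRNA"`, `"mRNA"`, `"metabolite"`.
#' @param unit One of `"raw_count"`, `"FPKM"`, `"TPM"`, `"intensity"`.
#' @param sample_groups Named character vector mapping every sample id to its
#'   group (e.g. McI/McII/McIII).
#' @param library_sizes Named positive numeric vector per sample; required
#'   when `unit = "raw_count"`.
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, layer, unit, sample_groups,
                             library_sizes = NULL) {
  layer <- match.arg(layer, c("lncRNA", "miRNA", "mRNA", "metabolite"))
  unit <- match.arg(unit, c("raw_count", "FPKM", "TPM", "intensity"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance values need feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in abundance matrix")
  if (any(values < 0)) stop("negative abundance value(s)")
  missing_grp <- setdiff(colnames(values), names(sample_groups))
  if (length(missing_grp))
    stop("sample(s) missing from group map: ", paste(missing_grp, collapse = ", "))
  sample_groups <- sample_groups[colnames(values)]
  if (unit == "raw_count") {
    if (is.null(library_sizes))
      stop("library_sizes are required for raw_count matrices")
    if (!all(colnames(values) %in% names(library_sizes)))
      stop("library_sizes missing for some samples")
    library_sizes <- library_sizes[colnames(values)]
    if (any(library_sizes <= 0)) stop("library sizes must be positive")
  }
  structure(list(values = values, layer = layer, unit = unit,
                 sample_groups = sample_groups, library_sizes = library_sizes),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix %s [%s]: %d features x %d samples, groups: %s>\n",
              x$layer, x$unit, nrow(x$values), ncol(x$values),
              paste(unique(x$sample_groups), collapse = "/")))
  invisible(x)
}

#' Read a TSV abundance table
#'
#' First column = feature id, header row = sample ids. TSV is the only
#' accepted dialect.
#'
#' @inheritParams abundance_matrix
#' @param path Path to the TSV file.
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path, layer, unit, sample_groups,
                           library_sizes = NULL) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  abundance_matrix(m, layer, unit, sample_groups, library_sizes)
}

#' Write an abundance matrix as TSV (feature id first column)
#' @param ab An [abundance_matrix()].
#' @param path Output path.
#' @export
write_abundance <- function(ab, path) {
  df <- data.frame(feature_id = rownames(ab$values), ab$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge table with a deterministic layout
#'
#' Fixed column order (source, source_layer, target, target_layer, stat_name,
#' stat_value, p, q) and byte-stable lexicographic row order, so the output
#' is a pure function of the edge multiset.
#'
#' @param edges data.frame carrying the eight columns above (missing
#'   statistic columns are filled with NA).
#' @param path Output path.
#' @export
write_network_table <- function(edges, path) {
  cols <- c("source", "source_layer", "target", "target_layer",
            "stat_name", "stat_value", "p", "q")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (cl in setdiff(cols, names(edges))) edges[[cl]] <- NA
  edges <- edges[, cols, drop = FALSE]
  if (nrow(edges))
    edges <- edges[order(edges$source, edges$target, edges$stat_name,
                         method = "radix"), , drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#' @param path Path to a YAML file (sample->group map, thresholds, paths).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
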