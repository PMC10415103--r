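# Reverse complement of an RNA string (Watson-Crick; ambiguity codes map to N).
rna_revcomp <- function(seq) {
  comp <- chartr("ACGURYSWKMBDHVN", "UGCANNNNNNNNNNN", seq)
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

#' Predict miRNA response elements (MREs) on a host transcript
#'
#' Scans the host for perfect Watson-Crick reverse complements of the miRNA
#' seed (positions 2-8, 1-based from the 5' end; a 7-mer). G:U wobble is
#' disallowed in the seed, and N never seed-matches. Every occurrence is one
#' hit.
#'
#' @param mirna_seq miRNA RNA string, >= 8 nt.
#' @param host_seq Host (lncRNA or mRNA) RNA string.
#' @param mirna_id,host_id,host_layer Identifiers attached to the hits.
#' @return data.frame(mirna_id, host_id, host_layer, site_start (0-based),
#'   match_type).
#' @export
predict_mre <- function(mirna_seq, host_seq, mirna_id = "miRNA",
                        host_id = "host", host_layer = "mRNA") {
  if (nchar(mirna_seq) < 8L)
    stop("miRNA ", mirna_id, " shorter than 8 nt")
  empty <- data.frame(mirna_id = character(0), host_id = character(0),
                      host_layer = character(0), site_start = integer(0),
                      match_type = character(0))
  seed <- substr(mirna_seq, 2L, 8L)
  if (grepl("[^ACGU]", seed)) return(empty)   # ambiguous seed never matches
  site <- rna_revcomp(seed)
  if (nchar(host_seq) < 7L) return(empty)
  starts <- integer(0)
  from <- 1L
  repeat {   # overlapping occurrences included
    hit <- regexpr(site, substr(host_seq, from, nchar(host_seq)), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + hit - 1L)
    from <- from + hit
  }
  if (!length(starts)) return(empty)
  data.frame(mirna_id = mirna_id, host_id = host_id, host_layer = host_layer,
             site_start = starts - 1L, match_type = "seed7",
             stringsAsFactors = FALSE)
}

#' Spearman correlation with a t-approximation p-value
#'
#' Average-rank Spearman rho; p from the t approximation on n-2 degrees of
#' freedom. Zero rank variance yields `(NA, 1)` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_cc <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) stop("spearman_cc needs equal lengths >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("spearman_cc: zero rank variance, correlation undefined")
    return(list(rho = NA_real_, p = 1))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p)
}

#' Shared-miRNA enrichment for a (lncRNA, mRNA) pair
#'
#' Hypergeometric upper tail `P(X >= k)` with `k` shared miRNAs, drawing
#' `|lnc_mirnas|` from a universe of `M` expressed miRNAs of which
#' `|mrna_mirnas|` are successes. This operationalizes the "enrichment
#' degree" of a candidate sponge pair binding the same miRNAs.
#'
#' @param lnc_mirnas,mrna_mirnas Character vectors of miRNA ids with MREs on
#'   the lncRNA / mRNA.
#' @param universe Character vector of all expressed miRNA ids.
#' @return The upper-tail p-value.
#' @export
shared_mre_enrichment <- function(lnc_mirnas, mrna_mirnas, universe) {
  lnc_mirnas <- unique(lnc_mirnas); mrna_mirnas <- unique(mrna_mirnas)
  if (!all(lnc_mirnas %in% universe) || !all(mrna_mirnas %in% universe))
    stop("miRNA set not contained in the expressed universe")
  M <- length(unique(universe))
  k <- length(intersect(lnc_mirnas, mrna_mirnas))
  stats::phyper(k - 1L, length(mrna_mirnas), M - length(mrna_mirnas),
                length(lnc_mirnas), lower.tail = FALSE)
}

#' Assemble lncRNA-miRNA-mRNA ceRNA triads
#'
#' A triad (lncRNA, miRNA, mRNA) is emitted iff
#' (a) the miRNA has at least one MRE on both the lncRNA and the mRNA;
#' (b) Spearman rho(miRNA, lncRNA) <= -scc_min and rho(miRNA, mRNA) <=
#'     -scc_min, each with p <= p_max (negative regulation by the shared
#'     miRNA);
#' (c) rho(lncRNA, mRNA) >= +scc_min with p <= p_max (the sponge pair
#'     co-varies); and
#' (d) the shared-MRE hypergeometric enrichment of the (lncRNA, mRNA) pair
#'     survives BH at q_max over all tested pairs.
#' Candidate members can be restricted to differentially expressed features
#' via `de_sets`, mirroring an analysis built from DElncRNAs/DEmiRNAs/
#' DEmRNAs. Correlations are computed jointly across all shared samples.
#'
#' @param mre_hits data.frame of [predict_mre()] hits over all
#'   miRNA x host combinations (host_layer `"lncRNA"` or `"mRNA"`).
#' @param expr Named list of [abundance_matrix()] objects for layers
#'   `lncRNA`, `miRNA`, `mRNA`, sharing sample columns.
#' @param de_sets Optional named list of DE feature ids per layer; when
#'   given, candidates are restricted to them.
#' @param scc_min Minimum |Spearman rho| (default 0.7).
#' @param p_max Correlation p-value cap (default 0.05).
#' @param q_max Enrichment BH q cap (default 0.05).
#' @return data.frame of triads with the three correlations, their p-values,
#'   and the pair enrichment p and q.
#' @export
build_cerna_triads <- function(mre_hits, expr, de_sets = NULL,
                               scc_min = 0.7, p_max = 0.05, q_max = 0.05) {
  stopifnot(all(c("lncRNA", "miRNA", "mRNA") %in% names(expr)))
  vals <- lapply(expr, function(e)
    if (inherits(e, "abundance_matrix")) e$values else e)
  samples <- colnames(vals$lncRNA)
  if (!identical(samples, colnames(vals$miRNA)) ||
      !identical(samples, colnames(vals$mRNA)))
    stop("expression layers must share sample columns")

  scope <- function(layer) {
    ids <- rownames(vals[[layer]])
    if (!is.null(de_sets) && !is.null(de_sets[[layer]]))
      ids <- intersect(ids, de_sets[[layer]])
    ids
  }
  lnc_ids <- scope("lncRNA"); mir_ids <- scope("miRNA"); mrna_ids <- scope("mRNA")
  universe <- mir_ids

  hits <- mre_hits[mre_hits$mirna_id %in% mir_ids, , drop = FALSE]
  lnc_hits <- hits[hits$host_layer == "lncRNA" & hits$host_id %in% lnc_ids, ]
  mrna_hits <- hits[hits$host_layer == "mRNA" & hits$host_id %in% mrna_ids, ]
  dropped <- setdiff(unique(mre_hits$host_id),
                     c(lnc_ids, mrna_ids, unique(hits$mirna_id)))
  empty <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), scc_mi_lnc = numeric(0),
                      p_mi_lnc = numeric(0), scc_mi_mrna = numeric(0),
                      p_mi_mrna = numeric(0), scc_lnc_mrna = numeric(0),
                      p_lnc_mrna = numeric(0), enrichment_p = numeric(0),
                      enrichment_q = numeric(0))
  if (!nrow(lnc_hits) || !nrow(mrna_hits)) return(empty)

  mirnas_on <- function(h) lapply(split(h$mirna_id, h$host_id), unique)
  lnc_sets <- mirnas_on(lnc_hits)
  mrna_sets <- mirnas_on(mrna_hits)

  # candidate triads: miRNA with >= 1 MRE on both sides
  cand <- do.call(rbind, lapply(intersect(unique(lnc_hits$mirna_id),
                                          unique(mrna_hits$mirna_id)),
                                function(mi) {
    expand.grid(lncrna_id = unique(lnc_hits$host_id[lnc_hits$mirna_id == mi]),
                mrna_id = unique(mrna_hits$host_id[mrna_hits$mirna_id == mi]),
                mirna_id = mi, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || !nrow(cand)) return(empty)

  # pair-level enrichment with BH over all tested pairs
  pairs <- unique(cand[, c("lncrna_id", "mrna_id")])
  pairs$enrichment_p <- mapply(function(l, m)
    shared_mre_enrichment(lnc_sets[[l]], mrna_sets[[m]], universe),
    pairs$lncrna_id, pairs$mrna_id)
  pairs$enrichment_q <- benjamini_hochberg(pairs$enrichment_p)

  scc_cache <- new.env(parent = emptyenv())
  scc <- function(key, x, y) {
    if (!is.null(scc_cache[[key]])) return(scc_cache[[key]])
    r <- suppressWarnings(spearman_cc(x, y))
    scc_cache[[key]] <- r
    r
  }
  out <- list()
  for (k in seq_len(nrow(cand))) {
    l <- cand$lncrna_id[k]; mi <- cand$mirna_id[k]; mr <- cand$mrna_id[k]
    c1 <- scc(paste0("ml|", mi, "|", l), vals$miRNA[mi, ], vals$lncRNA[l, ])
    c2 <- scc(paste0("mm|", mi, "|", mr), vals$miRNA[mi, ], vals$mRNA[mr, ])
    c3 <- scc(paste0("lm|", l, "|", mr), vals$lncRNA[l, ], vals$mRNA[mr, ])
    if (anyNA(c(c1$rho, c2$rho, c3$rho))) next
    pr <- pairs[pairs$lncrna_id == l & pairs$mrna_id == mr, ]
    ok <- c1$rho <= -scc_min && c1$p <= p_max &&
      c2$rho <= -scc_min && c2$p <= p_max &&
      c3$rho >= scc_min && c3$p <= p_max &&
      pr$enrichment_q <= q_max
    if (ok)
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = l, mirna_id = mi, mrna_id = mr,
        scc_mi_lnc = c1$rho, p_mi_lnc = c1$p,
        scc_mi_mrna = c2$rho, p_mi_mrna = c2$p,
        scc_lnc_mrna = c3$rho, p_lnc_mrna = c3$p,
        enrichment_p = pr$enrichment_p, enrichment_q = pr$enrichment_q,
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$lncrna_id, res$mirna_id, res$mrna_id, method = "radix"), ,
      drop = FALSE]
}

#' Correlate ceRNA members with metabolites
#'
#' Spearman correlation of every RNA appearing in a triad against every
#' (differentially synthesized) metabolite, with significance tiers
#' `***` (p <= 0.001), `**` (p <= 0.01), `*` (p <= 0.05), `ns` otherwise.
#' No sign constraint is imposed on metabolite edges.
#'
#' @param triads Triad table from [build_cerna_triads()].
#' @param expr Named list of RNA [abundance_matrix()] objects.
#' @param metab Metabolite [abundance_matrix()] with matching samples.
#' @param ds_ids Optional metabolite ids to restrict to.
#' @return data.frame(rna_id, rna_layer, metabolite_id, scc, p,
#'   significance_tier).
#' @export
attach_metabolites <- function(triads, expr, metab, ds_ids = NULL) {
  vals <- lapply(expr, function(e)
    if (inherits(e, "abundance_matrix")) e$values else e)
  mv <- if (inherits(metab, "abundance_matrix")) metab$values else metab
  if (!is.null(ds_ids)) mv <- mv[intersect(rownames(mv), ds_ids), , drop = FALSE]
  members <- unique(rbind(
    data.frame(rna_id = triads$lncrna_id, rna_layer = "lncRNA"),
    data.frame(rna_id = triads$mirna_id, rna_layer = "miRNA"),
    data.frame(rna_id = triads$mrna_id, rna_layer = "mRNA")))
  out <- list()
  for (k in seq_len(nrow(members))) {
    rid <- members$rna_id[k]; layer <- members$rna_layer[k]
    x <- vals[[layer]][rid, ]
    for (met in rownames(mv)) {
      r <- suppressWarnings(spearman_cc(x, mv[met, ]))
      tier <- if (is.na(r$rho)) "ns"
      else if (r$p <= 0.001) "***"
      else if (r$p <= 0.01) "**"
      else if (r$p <= 0.05) "*"
      else "ns"
      out[[length(out) + 1L]] <- data.frame(
        rna_id = rid, rna_layer = layer, metabolite_id = met,
        scc = r$rho, p = r$p, significance_tier = tier,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(rna_id = character(0), rna_layer = character(0),
                      metabolite_id = character(0), scc = numeric(0),
                      p = numeric(0), significance_tier = character(0)))
  do.call(rbind, out)
}

#' Generic hypergeometric set enrichment
#'
#' Per term, the upper-tail probability of observing at least `k` of the
#' feature set among the term's annotation, with BH correction across
#' terms; terms with zero overlap are omitted. Term annotations are
#' user-supplied (database content is out of scope).
#'
#' @param feature_set Character vector, a subset of `universe`.
#' @param annotation Named list mapping term -> annotated feature ids.
#' @param universe Character vector of all features.
#' @return data.frame(term, k, n_set, K, M, p, q) ordered by p.
#' @export
enrich_terms <- function(feature_set, annotation, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  feature_set <- unique(intersect(feature_set, universe))
  rows <- lapply(names(annotation), function(term) {
    ann <- unique(intersect(annotation[[term]], universe))
    k <- length(intersect(feature_set, ann))
    if (k == 0L) return(NULL)
    data.frame(term = term, k = k, n_set = length(feature_set),
               K = length(ann), M = length(universe),
               p = stats::phyper(k - 1L, length(ann),
                                 length(universe) - length(ann),
                                 length(feature_set), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(0), k = integer(0), n_set = integer(0),
                      K = integer(0), M = integer(0), p = numeric(0),
                      q = numeric(0)))
  tab <- do.call(rbind, rows)
  tab$q <- benjamini_hochberg(tab$p)
  tab[order(tab$p, tab$term, method = "radix"), , drop = FALSE]
}

#' Export lncRNA -> miRNA -> mRNA -> metabolite Sankey flows
#'
#' One row per complete chain; triads whose mRNA has no significant
#' metabolite edge keep an empty metabolite field. Output order is
#' deterministic, so the file is a pure function of the input sets.
#'
#' @param triads Triad table from [build_cerna_triads()].
#' @param metabolite_edges Edge table from [attach_metabolites()].
#' @param path Output TSV path.
#' @export
export_sankey <- function(triads, metabolite_edges, path) {
  rows <- list()
  for (k in seq_len(nrow(triads))) {
    tr <- triads[k, ]
    mets <- metabolite_edges[
      metabolite_edges$rna_id == tr$mrna_id &
        metabolite_edges$rna_layer == "mRNA" &
        metabolite_edges$significance_tier != "ns", , drop = FALSE]
    met_ids <- if (nrow(mets)) sort(mets$metabolite_id) else ""
    rows[[length(rows) + 1L]] <- data.frame(
      lncrna_id = tr$lncrna_id, mirna_id = tr$mirna_id,
      mrna_id = tr$mrna_id, metabolite_id = met_ids,
      stringsAsFactors = FALSE)
  }
  flows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), mirna_id = character(0),
               mrna_id = character(0), metabolite_id = character(0))
  flows <- flows[order(flows$lncrna_id, flows$mirna_id, flows$mrna_id,
                       flows$metabolite_id, method = "radix"), , drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(flows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
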