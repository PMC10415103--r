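# Independent reference implementations used as oracles. They deliberately
# use different mechanics (per-base sets, exhaustive enumeration, direct pmf
# summation) from the package code they check.

# --- duplex: exhaustive enumeration over all chains with <= 1-nt bulges ----
oracle_duplex_enum <- function(seq_a, seq_b, model = energy_model()) {
  a <- strsplit(seq_a, "")[[1L]]
  brev <- rev(strsplit(seq_b, "")[[1L]])
  n <- length(a); m <- length(brev)
  pe <- model$pair_energies
  e <- function(x, y) {
    k <- paste0(x, y)
    if (k %in% c("GC", "CG")) pe[["GC"]]
    else if (k %in% c("AU", "UA")) pe[["AU"]]
    else if (k %in% c("GU", "UG")) pe[["GU"]]
    else Inf
  }
  best <- 0
  rec <- function(i, j, val) {
    if (val < best) best <<- val
    for (step in list(c(1L, 1L, 0), c(2L, 1L, model$bulge_penalty),
                      c(1L, 2L, model$bulge_penalty))) {
      ni <- i + step[1L]; nj <- j + step[2L]
      if (ni <= n && nj <= m) {
        en <- e(a[ni], brev[nj])
        if (is.finite(en)) rec(ni, nj, val + step[3L] + en)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    en <- e(a[i], brev[j])
    if (is.finite(en)) rec(i, j, en)
  }
  best
}

# --- quadratic-time Benjamini-Hochberg ------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- integer(m); r[o] <- seq_len(m)   # stable ranks
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m))
      if (r[j] >= r[i]) cand <- min(cand, p[j] * m / r[j])
    q[i] <- min(1, cand)
  }
  q
}

# --- Spearman rho from first principles -----------------------------------
oracle_avg_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}
oracle_spearman <- function(x, y) {
  rx <- oracle_avg_ranks(x); ry <- oracle_avg_ranks(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# --- hypergeometric upper tail by direct pmf summation --------------------
oracle_hyper_tail <- function(k, n_draw, n_success, M) {
  tot <- 0
  for (i in k:min(n_draw, n_success))
    tot <- tot + choose(n_success, i) * choose(M - n_success, n_draw - i) /
      choose(M, n_draw)
  min(1, tot)
}

# --- per-base-set oracles for class codes and positional classes ----------
.bases <- function(s, e) if (e > s) seq.int(s, e - 1L) else integer(0)
.exon_bases <- function(tx)
  unlist(mapply(.bases, tx$exon_starts, tx$exon_ends, SIMPLIFY = FALSE))
.intron_list <- function(tx) {
  k <- length(tx$exon_starts)
  if (k < 2L) return(list())
  lapply(seq_len(k - 1L), function(i)
    c(tx$exon_ends[i], tx$exon_starts[i + 1L]))
}
.intron_keys <- function(tx)
  vapply(.intron_list(tx), function(iv) paste(iv, collapse = ":"), "")

oracle_class_code <- function(q, refs) {
  qb <- .exon_bases(q)
  span_q <- .bases(q$start, q$end)
  same <- Filter(function(r) r$chrom == q$chrom, refs)
  ovl <- Filter(function(r) length(intersect(span_q, .bases(r$start, r$end))) > 0, same)
  if (!length(ovl)) return("u")
  ss <- Filter(function(r) r$strand == q$strand, ovl)
  qi <- .intron_keys(q)
  for (r in ss) if (identical(qi, .intron_keys(r))) return("=")
  for (r in ss) {
    ref_intron_bases <- unlist(lapply(.intron_list(r), function(iv)
      .bases(iv[1L], iv[2L])))
    if (all(span_q %in% .bases(r$start, r$end)) &&
        (length(qi) == 0 || all(qi %in% .intron_keys(r))) &&
        length(intersect(qb, ref_intron_bases)) == 0 &&
        length(intersect(qb, .exon_bases(r))) > 0) return("c")
  }
  if (length(qi))
    for (r in ss) if (any(qi %in% .intron_keys(r))) return("j")
  if (length(q$exon_starts) == 1L)
    for (r in ss) {
      if (length(intersect(qb, .exon_bases(r))) == 0) next
      for (iv in .intron_list(r))
        if (length(intersect(span_q, .bases(iv[1L], iv[2L]))) > 0) return("e")
    }
  for (r in ss) if (length(intersect(qb, .exon_bases(r))) > 0) return("o")
  for (r in ovl)
    if (r$strand != q$strand && length(intersect(qb, .exon_bases(r))) > 0)
      return("x")
  for (r in ss)
    for (iv in .intron_list(r))
      if (all(span_q %in% .bases(iv[1L], iv[2L]))) return("i")
  "other"
}

oracle_classify <- function(lnc, pcgs, window = 1000L) {
  pcgs <- Filter(function(p) p$biotype == "coding" & p$chrom == lnc$chrom, pcgs)
  span_l <- .bases(lnc$start, lnc$end)
  lb <- .exon_bases(lnc)
  ss <- Filter(function(p) p$strand == lnc$strand, pcgs)
  os <- Filter(function(p) p$strand != lnc$strand, pcgs)
  for (p in ss)
    for (iv in .intron_list(p))
      if (all(span_l %in% .bases(iv[1L], iv[2L]))) return("intronic")
  for (p in ss)
    if (length(intersect(span_l, .bases(p$start, p$end))) > 0) return("sense")
  ltss <- if (lnc$strand == "+") lnc$start else lnc$end - 1L
  for (p in os) {
    ptss <- if (p$strand == "+") p$start else p$end - 1L
    upstream <- if (p$strand == "+") .bases(ptss - window, ptss)
    else .bases(ptss + 1L, ptss + window + 1L)
    if (ltss %in% upstream &&
        length(intersect(lb, .exon_bases(p))) == 0) return("bidirectional")
  }
  for (p in os)
    if (length(intersect(lb, .exon_bases(p))) > 0) return("antisense")
  ovl <- any(vapply(pcgs, function(p)
    length(intersect(span_l, .bases(p$start, p$end))) > 0, logical(1)))
  if (!ovl && length(pcgs)) {
    left <- any(vapply(pcgs, function(p) p$end <= lnc$start, logical(1)))
    right <- any(vapply(pcgs, function(p) p$start >= lnc$end, logical(1)))
    if (left && right) return("intergenic")
  }
  "unclassified"
}

oracle_cis <- function(lncrnas, pcgs, window) {
  out <- character(0)
  for (l in lncrnas) for (p in pcgs) {
    if (l$chrom != p$chrom) next
    lb <- .bases(l$start, l$end); pb <- .bases(p$start, p$end)
    d <- if (length(intersect(lb, pb)) > 0) 0
    else min(abs(outer(range(lb), range(pb), "-")))
    if (d <= window) out <- c(out, paste(l$transcript_id, p$gene_id))
  }
  sort(out)
}

# --- random mini-genomes for the interval-logic property tests ------------
random_transcript <- function(id, gene, chrom = "c1", strand = NULL,
                              max_start = 1500L) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(1:3, 1L)
  s <- sample.int(max_start, 1L)
  starts <- integer(n_ex); ends <- integer(n_ex)
  for (i in seq_len(n_ex)) {
    starts[i] <- s
    ends[i] <- s + sample(50:200, 1L)
    s <- ends[i] + sample(30:150, 1L)
  }
  transcript_model(id, gene, chrom, strand, starts, ends, biotype = "coding")
}

random_mini_genome <- function(n_ref = NULL, n_query = NULL) {
  if (is.null(n_ref)) n_ref <- sample(3:8, 1L)
  if (is.null(n_query)) n_query <- sample(5:12, 1L)
  refs <- lapply(seq_len(n_ref), function(i)
    random_transcript(paste0("R", i), paste0("GR", i)))
  queries <- lapply(seq_len(n_query), function(i)
    random_transcript(paste0("Q", i), paste0("GQ", i)))
  list(refs = refs, queries = queries)
}
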