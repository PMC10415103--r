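test_that("MRE prediction scans for the seed reverse complement", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"              # seed GAGGUAG -> site CUACCUC
  host <- paste0("AAAA", "CUACCUC", "GGGG")
  hits <- predict_mre(let7, host, "let7", "h1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$site_start, 4L)
  expect_equal(hits$match_type, "seed7")

  expect_equal(nrow(predict_mre(let7, "AAAAAAAAAAAA", "let7", "h2")), 0L)
  expect_error(predict_mre("UGAGGUA", host), "shorter than 8")

  tandem <- paste(rep(paste0("CUACCUC", "AAA"), 3), collapse = "")
  h3 <- predict_mre(let7, tandem, "let7", "h3")
  expect_equal(h3$site_start, c(0L, 10L, 20L))   # spacing = repeat length

  # N in the host never seed-matches
  expect_equal(nrow(predict_mre(let7, "CUACCNC", "let7", "h4")), 0L)
})

test_that("spearman_cc matches the rank-based reference, ties included", {
  expect_equal(spearman_cc(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cc(1:3, c(30, 20, 10))$rho, -1)
  expect_equal(spearman_cc(1:3, c(30, 20, 10))$p, 0)

  set.seed(41)
  for (i in 1:30) {
    n <- sample(c(6L, 9L), 1L)
    x <- sample(1:4, n, replace = TRUE)      # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    r <- spearman_cc(x, y)
    expect_equal(r$rho, oracle_spearman(x, y), tolerance = 1e-12)
    tstat <- r$rho * sqrt((n - 2) / (1 - r$rho^2))
    expect_equal(r$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  }
  expect_warning(res <- spearman_cc(rep(1, 5), 1:5), "zero rank variance")
  expect_equal(res$p, 1)
})

test_that("shared-MRE enrichment equals direct pmf summation", {
  U <- sprintf("m%02d", 1:20)
  expect_equal(shared_mre_enrichment(U[1:5], U[6:10], U), 1.0)  # disjoint
  expect_equal(shared_mre_enrichment(U, U, U), 1.0)             # certain
  expect_error(shared_mre_enrichment(c("zz"), U[1:3], U), "universe")

  p <- shared_mre_enrichment(U[1:5], U[3:7], U)                 # k = 3
  expect_equal(p, oracle_hyper_tail(3, 5, 5, 20), tolerance = 1e-12)

  set.seed(43)
  for (i in 1:30) {
    M <- sample(10:50, 1L)
    U <- sprintf("m%02d", seq_len(M))
    a <- sample(U, sample(1:M, 1L))
    b <- sample(U, sample(1:M, 1L))
    expect_equal(shared_mre_enrichment(a, b, U),
                 oracle_hyper_tail(length(intersect(a, b)),
                                   length(a), length(b), M),
                 tolerance = 1e-12)
  }
})

# A miniature hand-built sponge: one planted triad among decoys, built so
# every rule is individually decidable.
sponge_setup <- function(flip_mrna = FALSE) {
  samples <- paste0("s", 1:9)
  groups <- structure(rep(c("McI", "McII", "McIII"), each = 3),
                      names = samples)
  trend <- rep(c(1, 2, 3), each = 3) + seq(0, 0.08, length.out = 9)
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- samples
    m
  }
  lnc <- mk(list(L1 = 2^trend, L2 = 2^rev(trend)))
  mrna <- mk(list(M1 = if (flip_mrna) 2^rev(trend) else 2^(trend + 0.1),
                  M2 = rep(5, 9)))
  # x3..x8 pad the expressed-miRNA universe so shared-site enrichment of the
  # planted pair is actually surprising (k = 2 of 8)
  mir <- mk(c(list(x1 = 2^(4 - trend), x2 = rep(3, 9) + (1:9) %% 2),
              structure(lapply(3:8, function(i) 3 + ((1:9 + i) %% 3)),
                        names = paste0("x", 3:8))))
  mre <- rbind(
    data.frame(mirna_id = "x1", host_id = "L1", host_layer = "lncRNA",
               site_start = 0L, match_type = "seed7"),
    data.frame(mirna_id = "x2", host_id = "L1", host_layer = "lncRNA",
               site_start = 10L, match_type = "seed7"),
    data.frame(mirna_id = "x1", host_id = "M1", host_layer = "mRNA",
               site_start = 5L, match_type = "seed7"),
    data.frame(mirna_id = "x2", host_id = "M1", host_layer = "mRNA",
               site_start = 15L, match_type = "seed7"))
  list(mre = mre, expr = list(lncRNA = lnc, miRNA = mir, mRNA = mrna))
}

test_that("triad assembly enforces the three sign rules and enrichment", {
  s <- sponge_setup()
  tri <- build_cerna_triads(s$mre, s$expr, q_max = 0.5)
  expect_equal(triad_key(tri), "L1 x1 M1")
  expect_lt(tri$scc_mi_lnc, -0.7)
  expect_lt(tri$scc_mi_mrna, -0.7)
  expect_gt(tri$scc_lnc_mrna, 0.7)
  expect_true(tri$enrichment_q <= 0.5)

  # same geometry, sponge-pair correlation forced negative -> no triad
  s2 <- sponge_setup(flip_mrna = TRUE)
  expect_equal(nrow(build_cerna_triads(s2$mre, s2$expr, q_max = 0.5)), 0L)

  # monotonicity in scc_min
  loose <- build_cerna_triads(s$mre, s$expr, scc_min = 0.7, q_max = 0.5)
  strict <- build_cerna_triads(s$mre, s$expr, scc_min = 0.9, q_max = 0.5)
  expect_true(all(triad_key(strict) %in% triad_key(loose)))

  # DE scoping drops candidates outside the DE sets
  none <- build_cerna_triads(s$mre, s$expr, q_max = 0.5,
                             de_sets = list(lncRNA = "L2"))
  expect_equal(nrow(none), 0L)
})

test_that("metabolite edges tier by p-value and tolerate degenerate vectors", {
  s <- sponge_setup()
  tri <- build_cerna_triads(s$mre, s$expr, q_max = 0.5)
  met <- rbind(coupled = 2 * s$expr$mRNA["M1", ],
               flat = rep(4, 9))
  colnames(met) <- colnames(s$expr$mRNA)
  edges <- attach_metabolites(tri, s$expr, met)
  coup <- edges[edges$metabolite_id == "coupled" & edges$rna_id == "M1", ]
  expect_equal(coup$scc, 1)
  expect_equal(coup$significance_tier, "***")
  expect_true(all(edges$significance_tier[edges$metabolite_id == "flat"] ==
                    "ns"))

  # independent metabolite stays ns in the vast majority of replicates
  set.seed(3)
  ns_frac <- mean(replicate(400, {
    rnd <- matrix(rlnorm(9), 1, 9, dimnames = list("r", colnames(met)))
    all(attach_metabolites(tri, s$expr, rnd)$significance_tier == "ns")
  }))
  expect_gte(ns_frac, 0.80)
})

test_that("term enrichment follows the hypergeometric tail with BH", {
  U <- sprintf("g%02d", 1:20)
  tab <- enrich_terms(U[1:5], list(T1 = U[1:5], T2 = U), U)
  expect_equal(tab$p[tab$term == "T2"], 1.0)
  expect_equal(tab$p[tab$term == "T1"],
               1 / choose(20, 5), tolerance = 1e-12)
  expect_true(all(tab$q >= tab$p))
  expect_error(enrich_terms(U[1:2], list(T1 = U[1:2]), character(0)),
               "empty universe")
  # zero-overlap terms are omitted
  expect_false("T3" %in%
                 enrich_terms(U[1:5], list(T1 = U[1:5], T3 = U[6:8]), U)$term)
})

test_that("sankey export is deterministic with empty metabolite fallback", {
  s <- sponge_setup()
  tri <- build_cerna_triads(s$mre, s$expr, q_max = 0.5)
  met <- matrix(2 * s$expr$mRNA["M1", ], 1, 9,
                dimnames = list("metA", colnames(s$expr$mRNA)))
  edges <- attach_metabolites(tri, s$expr, met)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  export_sankey(tri, edges, f1)
  export_sankey(tri[sample(nrow(tri)), , drop = FALSE], edges, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[2], "metA$")

  # no metabolite edge -> empty trailing field
  export_sankey(tri, edges[0, ], f3)
  expect_match(readLines(f3)[2], "\t$")
})
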