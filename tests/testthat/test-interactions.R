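tm <- function(id, strand, starts, ends, gene = id, chrom = "c1",
               biotype = "coding")
  transcript_model(id, gene, chrom, strand, starts, ends, biotype = biotype)

test_that("antisense edges require a deep, well-paired duplex", {
  mrna <- paste(rep("G", 60), collapse = "")
  lnc_hit <- paste(rep("C", 60), collapse = "")     # perfect 60-bp GC duplex
  lnc_miss <- paste(rep("A", 60), collapse = "")
  recs <- data.frame(transcript_id = c("l1", "l2"),
                     category = "antisense",
                     anchor_gene_id = "g1")
  seqs <- c(l1 = lnc_hit, l2 = lnc_miss)
  edges <- antisense_edges(recs, seqs, c(g1 = mrna))
  expect_equal(edges$lncrna_id, "l1")
  expect_equal(edges$statistic, -180)               # 60 stacked GC pairs
  expect_gte(edges$paired_fraction, 1)

  # missing anchor sequence -> warning, skipped
  expect_warning(
    none <- antisense_edges(data.frame(transcript_id = "l3",
                                       category = "antisense",
                                       anchor_gene_id = "gz"),
                            c(l3 = lnc_hit), c(g1 = mrna)),
    "missing anchor")
  expect_equal(nrow(none), 0L)

  # threshold sweep: a looser cutoff can only add edges
  loose <- antisense_edges(recs, seqs, c(g1 = mrna), mfe_max = -5)
  tight <- antisense_edges(recs, seqs, c(g1 = mrna), mfe_max = -20)
  expect_true(all(tight$lncrna_id %in% loose$lncrna_id))
})

test_that("cis edges capture genes within the window with signed distances", {
  lnc <- tm("l1", "+", c(20000, 20300), c(20200, 20500),
            biotype = "noncoding")
  near <- tm("T_g1", "+", 14000, 15000, gene = "g1")    # ends 5 kb upstream
  far <- tm("T_g2", "+", 70000, 71000, gene = "g2")
  over <- tm("T_g3", "-", 20400, 21400, gene = "g3")
  e <- cis_edges(list(lnc), list(near, far, over))
  expect_setequal(e$gene_id, c("g1", "g3"))
  expect_equal(e$statistic[e$gene_id == "g1"], 5000)
  expect_equal(e$statistic[e$gene_id == "g3"], 0)

  set.seed(31)
  for (i in 1:25) {
    mg <- random_mini_genome()
    got <- cis_edges(mg$queries, mg$refs, window = 300L)
    expect_equal(sort(paste(got$lncrna_id, got$gene_id)),
                 oracle_cis(mg$queries, mg$refs, window = 300L))
  }
})

test_that("trans edges demand near-perfect positive correlation", {
  x <- matrix(seq_len(9), 1, 9,
              dimnames = list("l1", paste0("s", 1:9)))
  up <- 2 * x + 1; rownames(up) <- "g_up"
  down <- -x; rownames(down) <- "g_down"
  res <- trans_edges(x, rbind(up, down))
  expect_equal(res$edges$gene_id, "g_up")
  expect_equal(res$edges$statistic, 1.0)
  expect_equal(res$anticorrelated$gene_id, "g_down")

  # per-feature affine rescaling leaves the edge set unchanged
  res2 <- trans_edges(5 * x - 3, rbind(0.1 * up + 7, down))
  expect_equal(res2$edges$gene_id, "g_up")

  # cis-linked pairs are excluded
  res3 <- trans_edges(x, up,
                      exclude = data.frame(lncrna_id = "l1",
                                           gene_id = "g_up"))
  expect_equal(nrow(res3$edges), 0L)

  expect_message(trans_edges(x, matrix(1, 1, 9,
                                       dimnames = list("flat", colnames(x)))),
                 "zero-variance")
})

test_that("independent Gaussian pairs essentially never clear r > 0.999", {
  set.seed(7)
  lncs <- matrix(rnorm(100 * 9), 100, 9,
                 dimnames = list(sprintf("l%03d", 1:100), paste0("s", 1:9)))
  genes <- matrix(rnorm(100 * 9), 100, 9,
                  dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:9)))
  res <- trans_edges(lncs, genes)       # 10^4 random pairs
  expect_equal(nrow(res$edges), 0L)
})
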