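tm <- function(id, strand, starts, ends, gene = id, chrom = "c1",
               biotype = "coding")
  transcript_model(id, gene, chrom, strand, starts, ends, biotype = biotype)

test_that("lncRNA calling is the strict intersection of the two score criteria", {
  scores <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    cnci_score = c(-1.2, -1.2, 0.0, 1.0),
    cpc2_probability = c(0.1, 0.9, 0.1, 0.6))
  res <- call_lncrnas(scores$transcript_id, scores)
  expect_equal(res$called, "a")            # b fails CPC2, c fails strict < 0
  expect_equal(res$cnci_set, c("a", "b"))
  expect_equal(res$cpc2_set, c("a", "c"))
  expect_error(call_lncrnas(c("a", "zz"), scores), "zz")
})

test_that("calling satisfies the inclusion-exclusion identity on random scores", {
  set.seed(7)
  for (i in 1:20) {
    n <- 50L
    scores <- data.frame(transcript_id = sprintf("t%02d", 1:n),
                         cnci_score = runif(n, -2, 2),
                         cpc2_probability = runif(n))
    r <- call_lncrnas(scores$transcript_id, scores)
    expect_setequal(r$called, intersect(r$cnci_set, r$cpc2_set))
    expect_equal(length(intersect(r$cnci_set, r$cpc2_set)),
                 length(r$cnci_set) + length(r$cpc2_set) -
                   length(union(r$cnci_set, r$cpc2_set)))
  }
})

test_that("positional classification matches its category definitions", {
  pcg <- tm("T_g1", "+", c(1000, 2800, 4500), c(1300, 3000, 4800), gene = "g1")
  pcg2 <- tm("T_g2", "+", 8000, 8800, gene = "g2")
  pcgs <- list(pcg, pcg2)

  intronic <- tm("l1", "+", c(1400, 1600), c(1500, 1700), biotype = "noncoding")
  expect_equal(classify_lncrna_position(intronic, pcgs)$category, "intronic")
  expect_equal(classify_lncrna_position(intronic, pcgs)$anchor_gene_id, "g1")

  sense <- tm("l2", "+", c(2600, 3100), c(2900, 3200), biotype = "noncoding")
  expect_equal(classify_lncrna_position(sense, pcgs)$category, "sense")

  anti <- tm("l3", "-", c(2700, 3100), c(2900, 3200), biotype = "noncoding")
  expect_equal(classify_lncrna_position(anti, pcgs)$category, "antisense")

  # TSS 800 bp upstream of a divergent PCG TSS, no overlap
  bidi <- tm("l4", "-", c(0, 150), c(100, 201), biotype = "noncoding")
  expect_equal(cernaflow:::tss(bidi), 200L)
  expect_equal(classify_lncrna_position(bidi, pcgs)$category, "bidirectional")
  expect_equal(oracle_classify(bidi, pcgs), "bidirectional")

  inter <- tm("l5", "+", c(6000, 6300), c(6200, 6500), biotype = "noncoding")
  expect_equal(classify_lncrna_position(inter, pcgs)$category, "intergenic")

  # beyond the last PCG: no flanking gene on the right -> unclassified
  tail_lnc <- tm("l6", "+", c(9000, 9300), c(9200, 9500), biotype = "noncoding")
  expect_equal(classify_lncrna_position(tail_lnc, pcgs)$category, "unclassified")
})

test_that("classification agrees with the per-base oracle on random genomes", {
  set.seed(202)
  for (g in 1:120) {
    mg <- random_mini_genome()
    for (q in mg$queries)
      expect_equal(classify_lncrna_position(q, mg$refs)$category,
                   oracle_classify(q, mg$refs),
                   info = sprintf("genome %d query %s", g, q$transcript_id))
  }
})

test_that("classification is invariant under coordinate translation", {
  set.seed(303)
  for (g in 1:25) {
    mg <- random_mini_genome()
    delta <- sample(1000:5000, 1L)
    refs2 <- lapply(mg$refs, cernaflow:::shift_transcript, delta = delta)
    for (q in mg$queries)
      expect_equal(
        classify_lncrna_position(q, mg$refs)$category,
        classify_lncrna_position(cernaflow:::shift_transcript(q, delta),
                                 refs2)$category)
  }
})
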