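tm <- function(id, strand, starts, ends, gene = id, chrom = "c1",
               biotype = "coding")
  transcript_model(id, gene, chrom, strand, starts, ends, biotype = biotype)

test_that("class codes follow the specificity precedence", {
  ref <- tm("r1", "+", c(100, 300, 600), c(200, 400, 700))
  # identical intron chain, different ends -> "="
  eq <- tm("q", "+", c(120, 300, 600), c(200, 400, 680))
  expect_equal(assign_class_code(eq, list(ref))$code, "=")
  expect_equal(assign_class_code(eq, list(ref))$reference_transcript_id, "r1")

  # disjoint -> "u" with no reference id
  u <- tm("q", "+", c(5000, 5300), c(5100, 5400))
  res <- assign_class_code(u, list(ref))
  expect_equal(res$code, "u")
  expect_true(is.na(res$reference_transcript_id))

  # shares the first junction only, novel terminal exon -> "j"
  j <- tm("q", "+", c(150, 300, 450), c(200, 350, 500))
  expect_equal(assign_class_code(j, list(ref))$code, "j")
  expect_equal(oracle_class_code(j, list(ref)), "j")

  # contained mono-exonic query inside an exon -> "c"
  cc <- tm("q", "+", 110, 190)
  expect_equal(assign_class_code(cc, list(ref))$code, "c")
  # single exon over an exon/intron boundary -> "e"
  e <- tm("q", "+", 150, 250)
  expect_equal(assign_class_code(e, list(ref))$code, "e")
  # opposite strand exonic overlap -> "x"
  x <- tm("q", "-", c(150, 320), c(250, 380))
  expect_equal(assign_class_code(x, list(ref))$code, "x")
  # fully inside a single intron, same strand -> "i"
  i <- tm("q", "+", c(210, 250), c(240, 290))
  expect_equal(assign_class_code(i, list(ref))$code, "i")
})

test_that("class codes agree with the per-base-set oracle on random genomes", {
  set.seed(101)
  for (g in 1:120) {
    mg <- random_mini_genome()
    for (q in mg$queries)
      expect_equal(assign_class_code(q, mg$refs)$code,
                   oracle_class_code(q, mg$refs),
                   info = sprintf("genome %d query %s", g, q$transcript_id))
  }
})

test_that("novel-transcript filtering applies code, length and exon rules strictly", {
  txs <- list(
    known = tm("known", "+", c(0, 300, 600), c(200, 400, 1500)),
    short = tm("short", "+", c(0, 100), c(80, 220)),        # 200 nt exactly
    mono = tm("mono", "+", 0, 900),
    ok = tm("ok", "+", c(0, 200), c(150, 351)))             # 301 nt, 2 exons
  codes <- list(list(code = "="), list(code = "u"), list(code = "u"),
                list(code = "j"))
  kept <- filter_novel(txs, codes)
  expect_equal(names(kept), "ok")
  # boundary: exactly 200 nt is dropped (strict >)
  expect_equal(exonic_length(txs$short), 200L)
})
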