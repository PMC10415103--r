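test_that("bundle generation is deterministic under a fixed seed", {
  b1 <- generate_bundle(plant_config(seed = 5, n_decoys = 20,
                                     n_planted_de = 8, n_planted_triads = 3))
  b2 <- generate_bundle(plant_config(seed = 5, n_decoys = 20,
                                     n_planted_de = 8, n_planted_triads = 3))
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$counts$lncRNA$values, b2$counts$lncRNA$values)
  expect_identical(b1$scores, b2$scores)

  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("bundle files cross-reference consistently", {
  b <- crisp_bundle()
  d <- tempfile()
  write_bundle(b, d)
  tx <- read_gtf(file.path(d, "assembled.gtf"))
  expect_setequal(names(tx), names(b$assembled))
  # exon coordinates round-trip exactly through the GTF writer
  for (id in names(tx)[1:20]) {
    expect_identical(tx[[id]]$exon_starts, b$assembled[[id]]$exon_starts)
    expect_identical(tx[[id]]$exon_ends, b$assembled[[id]]$exon_ends)
  }
  # spliced transcript lengths match the declared length table
  fa <- read_fasta(file.path(d, "lncrna.fa"))
  expect_equal(unname(nchar(fa[names(b$assembled)])),
               unname(b$lengths[names(b$assembled)]))
  # count matrices carry the 9-sample design
  ab <- read_abundance(file.path(d, "counts_lncRNA.tsv"), "lncRNA",
                       "raw_count", b$sample_groups, b$library_sizes)
  expect_identical(ab$values, b$counts$lncRNA$values)
})

test_that("planted positional classes and class codes recover exactly", {
  one <- generate_bundle(plant_config(seed = 0, n_lnc_per_class = 1,
                                      n_decoys = 10, n_planted_de = 4,
                                      n_planted_triads = 2))
  cls <- vapply(one$assembled, function(l)
    classify_lncrna_position(l, one$reference)$category, "")
  exp <- structure(one$truth$classes$category,
                   names = one$truth$classes$transcript_id)
  expect_equal(cls[names(exp)], exp)
  expect_setequal(unique(cls[one$truth$classes$role == "classed"]),
                  c("intergenic", "bidirectional", "intronic",
                    "antisense", "sense"))
  codes <- vapply(one$assembled, function(q)
    assign_class_code(q, one$reference)$code, "")
  expect_equal(codes[names(one$truth$class_codes)], one$truth$class_codes)
})

test_that("identification recovers the planted lncRNA set end to end", {
  b <- crisp_bundle()
  codes <- lapply(b$assembled, assign_class_code, reference = b$reference)
  novel <- filter_novel(b$assembled, codes)
  # the two structure-fail candidates drop here
  expect_false(any(c("CAND_short", "CAND_monoexon") %in% names(novel)))
  called <- call_lncrnas(names(novel), b$scores)$called
  expect_setequal(called, b$truth$lnc_called)
})

test_that("near-noiseless counts recover every planted DE direction", {
  b <- crisp_bundle()
  de <- run_de_stage(b)
  for (layer in c("lncRNA", "mRNA", "miRNA")) {
    tr <- b$truth$de[[layer]]
    tab <- de$tables[[layer]]
    got <- tab$direction[match(paste(tr$feature_id, tr$comparison),
                               paste(tab$feature_id, tab$comparison))]
    expect_equal(mean(got == tr$direction), 1,
                 info = paste("layer", layer))
  }
  # planted log2 fold changes are recovered within 0.1
  lnc_tab <- de$tables$lncRNA
  tr <- b$truth$de$lncRNA
  planted_up <- tr[tr$direction == "up", ]
  idx <- match(paste(planted_up$feature_id, planted_up$comparison),
               paste(lnc_tab$feature_id, lnc_tab$comparison))
  expect_true(all(lnc_tab$log2fc[idx] >= 1))
})

test_that("null generator stays within type-I expectations", {
  # effect 0: no feature should clear |log2fc| >= 1 + FDR <= 0.05 more than
  # rarely; a quick 5-seed screen (the 50-seed version runs in acceptance)
  frac <- vapply(1:5, function(s) {
    set.seed(s)
    m <- matrix(rnbinom(200 * 9, mu = 500, size = 20), 200, 9,
                dimnames = list(sprintf("f%03d", 1:200),
                                cernaflow:::.SAMPLES))
    ab <- abundance_matrix(m, "lncRNA", "raw_count",
                           cernaflow:::.GROUPS, cernaflow:::.LIBSIZE)
    res <- de_test(compute_fpkm(ab, structure(rep(1000, 200),
                                              names = rownames(m))),
                   comparison_group("McII", "McI"))
    mean(benjamini_hochberg(res$p) <= 0.05)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("the study fixture's planted sets satisfy their set identities", {
  fx <- the_study_fixture()
  tr <- fx$truth
  sets <- lapply(split(tr$directions, tr$directions$comparison), function(d)
    d$feature_id[d$direction != "ns"])
  expect_equal(length(sets$McII_vs_McI), 418L)
  expect_equal(length(sets$McIII_vs_McI), 1154L)
  expect_equal(length(sets$McIII_vs_McII), 880L)
  expect_equal(length(Reduce(intersect, sets)), 67L)
  expect_equal(length(Reduce(union, sets)), 1499L)
  # additivity: lfc(III/I) = lfc(II/I) + lfc(III/II) by construction
  expect_equal(tr$regions$b, tr$regions$a + tr$regions$c)
  # every planted value keeps >= 0.2 log2 of margin to the decision boundary
  margins <- abs(abs(c(tr$regions$a, tr$regions$b, tr$regions$c)) - 1)
  expect_true(all(margins >= 0.2 - 1e-9))
})
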