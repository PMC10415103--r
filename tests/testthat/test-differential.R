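mk_counts <- function(values, layer = "lncRNA", lib = NULL) {
  m <- as.matrix(values)
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  groups <- structure(rep(c("A", "B", "C"), length.out = ncol(m)),
                      names = colnames(m))
  if (is.null(lib)) lib <- structure(rep(1e6, ncol(m)), names = colnames(m))
  abundance_matrix(m, layer, "raw_count", groups, lib)
}

test_that("FPKM follows its defining formula and is linear in counts", {
  ab <- mk_counts(matrix(c(10, 0, 5), 3, 1), lib = c(s1 = 1e6))
  lens <- c(f1 = 1000, f2 = 700, f3 = 500)
  f <- compute_fpkm(ab, lens)
  expect_equal(unname(f$values[, 1]), c(10, 0, 5 / 0.5))

  ab2 <- mk_counts(matrix(c(5, 0, 2.5), 3, 1), lib = c(s1 = 2e6))
  f2 <- compute_fpkm(ab2, lens)
  expect_equal(f2$values[, 1], f$values[, 1] / 4)  # half counts, double depth

  expect_error(compute_fpkm(ab, c(f1 = 0, f2 = 700, f3 = 500)), "length")
})

test_that("TPM columns sum to 1e6 and equal rates share it equally", {
  ab <- mk_counts(matrix(c(10, 20), 2, 1))
  t1 <- compute_tpm(ab, c(f1 = 1000, f2 = 2000))
  expect_equal(unname(t1$values[, 1]), c(5e5, 5e5))

  solo <- mk_counts(matrix(7, 1, 1))
  expect_equal(unname(compute_tpm(solo, c(f1 = 123))$values[1, 1]), 1e6)

  set.seed(11)
  big <- mk_counts(matrix(rpois(60, 50), 10, 6))
  lens <- structure(sample(200:2000, 10), names = rownames(big$values))
  expect_equal(unname(colSums(compute_tpm(big, lens)$values)),
               rep(1e6, 6), tolerance = 1e-9)

  zero <- mk_counts(matrix(c(1, 2, 0, 0), 2, 2))
  expect_error(compute_tpm(zero, c(f1 = 100, f2 = 100)), "all-zero")
})

test_that("de_test fold change and degenerate p-value conventions hold", {
  m <- matrix(c(8, 8, 8, 1, 1, 1), 1, 6,
              dimnames = list("f1", paste0("s", 1:6)))
  ab <- abundance_matrix(m, "mRNA", "FPKM",
                         structure(rep(c("case", "ctrl"), each = 3),
                                   names = colnames(m)))
  cmp <- comparison_group("case", "ctrl")
  res <- de_test(ab, cmp)
  expect_equal(res$log2fc, log2(9 / 2), tolerance = 1e-12)
  expect_equal(res$p, 0)                    # zero variance, unequal means

  m2 <- m; m2[1, ] <- 5
  ab2 <- abundance_matrix(m2, "mRNA", "FPKM", ab$sample_groups)
  expect_equal(de_test(ab2, cmp)$p, 1)      # identical groups
  expect_equal(de_test(ab2, cmp)$log2fc, 0)

  expect_error(de_test(ab, comparison_group("case", "ctrl"),
                       method = "passthrough"), "p_values")
  pt <- de_test(ab, cmp, method = "passthrough", p_values = c(f1 = 0.2))
  expect_equal(pt$p, 0.2)
})

test_that("welch stand-in detects strong planted effects (Monte-Carlo)", {
  set.seed(1)
  n <- 1000L
  base <- 100
  case <- matrix(base * 8 * exp(rnorm(n * 3, 0, 0.1)), n, 3)
  ctrl <- matrix(base * exp(rnorm(n * 3, 0, 0.1)), n, 3)
  m <- cbind(case, ctrl)
  dimnames(m) <- list(sprintf("f%04d", 1:n), paste0("s", 1:6))
  ab <- abundance_matrix(m, "mRNA", "FPKM",
                         structure(rep(c("case", "ctrl"), each = 3),
                                   names = colnames(m)))
  res <- de_test(ab, comparison_group("case", "ctrl"))
  expect_gte(mean(res$p < 0.01), 0.99)
  expect_equal(median(res$log2fc), 3, tolerance = 0.05)
})

test_that("BH adjustment matches the quadratic-time reference exactly", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:25) {
    p <- round(runif(sample(3:40, 1L)), 3)   # rounding forces ties
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    perm <- sample(seq_along(p))
    expect_equal(benjamini_hochberg(p[perm]), q[perm])
  }
})

test_that("per-layer thresholds apply inclusively with the printed boundaries", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    comparison = "x_vs_y",
                    log2fc = c(1.0, 0.58, -1.2),
                    p = c(0.01, 0.01, 0.2),
                    fdr = c(0.05, 0.01, 0.2))
  lnc <- filter_de(res, threshold_config("lncRNA"))
  expect_equal(lnc$direction, c("up", "ns", "ns"))   # boundary 1.0/0.05 is up

  mir <- filter_de(res, threshold_config("miRNA"))
  expect_equal(mir$direction[2], "ns")               # 0.58 < 0.585

  met <- data.frame(feature_id = "m", comparison = "x_vs_y",
                    log2fc = 0.6, p = 0.2, vip = 1.5)
  expect_message(
    out <- filter_de(met, threshold_config("metabolite")), "VIP")
  expect_equal(out$direction, "up")
  out_le <- suppressMessages(
    filter_de(met, threshold_config("metabolite", vip_direction = "le")))
  expect_equal(out_le$direction, "ns")               # literal "vip <= 1" reading
})

test_that("relaxing any threshold never removes a feature from up/down", {
  set.seed(9)
  res <- data.frame(feature_id = sprintf("f%03d", 1:200),
                    comparison = "x_vs_y",
                    log2fc = rnorm(200, 0, 2),
                    p = runif(200))
  res$fdr <- benjamini_hochberg(res$p)
  called <- function(lfc, sig) {
    d <- filter_de(res, threshold_config("lncRNA", log2fc_min = lfc,
                                         significance_max = sig))
    d$feature_id[d$direction != "ns"]
  }
  strict <- called(1.5, 0.01)
  expect_true(all(strict %in% called(1.0, 0.01)))
  expect_true(all(strict %in% called(1.5, 0.10)))
  expect_true(all(called(1.0, 0.01) %in% called(0.5, 0.05)))
})

test_that("venn regions satisfy inclusion-exclusion on random sets", {
  v <- venn(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(v$intersection, "2")
  expect_equal(v$union, c("1", "2", "3"))

  d <- venn(list(A = "a", B = "b", C = "c"))
  expect_length(d$intersection, 0L)
  expect_length(d$union, 3L)

  set.seed(13)
  for (i in 1:20) {
    gs <- lapply(1:3, function(j)
      as.character(sample.int(40, sample(5:30, 1L))))
    names(gs) <- LETTERS[1:3]
    v <- venn(gs)
    expect_equal(length(v$union), sum(unlist(v$regions)))
    # |A u B u C| by inclusion-exclusion
    ie <- length(gs$A) + length(gs$B) + length(gs$C) -
      length(intersect(gs$A, gs$B)) - length(intersect(gs$A, gs$C)) -
      length(intersect(gs$B, gs$C)) +
      length(Reduce(intersect, gs))
    expect_equal(length(v$union), ie)
    expect_equal(sort(v$intersection), sort(Reduce(intersect, gs)))
  }
})
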