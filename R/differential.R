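#' Comparison group ("case vs control")
#' @param case_group,control_group Group labels (must differ).
#' @param name Optional name; default `"<case>_vs_<control>"`.
#' @export
comparison_group <- function(case_group, control_group,
                             name = paste0(case_group, "_vs_", control_group)) {
  if (identical(case_group, control_group))
    stop("case and control groups must differ")
  list(name = name, case_group = case_group, control_group = control_group)
}

#' FPKM normalization
#'
#' `fpkm[i,s] = counts[i,s] / (length[i]/1e3) / (library_size[s]/1e6)`
#' (fragments per kilobase of transcript per million mapped reads).
#'
#' @param counts An [abundance_matrix()] with `unit = "raw_count"`.
#' @param lengths Named numeric vector of transcript lengths in bp.
#' @return An [abundance_matrix()] with `unit = "FPKM"`.
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(inherits(counts, "abundance_matrix"))
  if (counts$unit != "raw_count") stop("compute_fpkm needs raw counts")
  ids <- rownames(counts$values)
  if (!all(ids %in% names(lengths)))
    stop("missing transcript length(s): ",
         paste(utils::head(setdiff(ids, names(lengths))), collapse = ", "))
  len <- lengths[ids]
  if (any(len <= 0)) stop("zero or negative transcript length")
  fpkm <- sweep(counts$values / (len / 1e3), 2L,
                counts$library_sizes / 1e6, "/")
  abundance_matrix(fpkm, counts$layer, "FPKM", counts$sample_groups)
}

#' TPM normalization
#'
#' Per-sample length-normalized rates rescaled to sum to 1e6.
#'
#' @inheritParams compute_fpkm
#' @return An [abundance_matrix()] with `unit = "TPM"`.
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(inherits(counts, "abundance_matrix"))
  if (counts$unit != "raw_count") stop("compute_tpm needs raw counts")
  ids <- rownames(counts$values)
  if (!all(ids %in% names(lengths)))
    stop("missing transcript length(s)")
  len <- lengths[ids]
  if (any(len <= 0)) stop("zero or negative transcript length")
  rate <- counts$values / len
  tot <- colSums(rate)
  if (any(tot == 0)) stop("all-zero sample column: TPM undefined")
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  abundance_matrix(tpm, counts$layer, "TPM", counts$sample_groups)
}

#' Per-feature fold change and significance between two groups
#'
#' The built-in test is Welch's two-sample t on `log2(value + pseudocount)`
#' per feature (a documented stand-in for negative-binomial engines such as
#' DESeq2/edgeR, whose machinery is out of scope here); `passthrough` keeps
#' externally computed p-values and computes only the fold change. The fold
#' change is always
#' `log2((mean case + pseudocount) / (mean control + pseudocount))` on the
#' normalized values. Degenerate features (zero variance in both groups) get
#' p = 1 when the means are equal and p = 0 otherwise.
#'
#' @param ab An [abundance_matrix()] of normalized values.
#' @param comparison A [comparison_group()].
#' @param method `"welch_log"` or `"passthrough"`.
#' @param pseudocount Added before the log2 ratio (default 1).
#' @param p_values Named vector of externally computed p-values
#'   (required for `passthrough`).
#' @return data.frame(feature_id, comparison, log2fc, p).
#' @export
de_test <- function(ab, comparison, method = c("welch_log", "passthrough"),
                    pseudocount = 1, p_values = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ab, "abundance_matrix"))
  grp <- ab$sample_groups
  case_idx <- which(grp == comparison$case_group)
  ctrl_idx <- which(grp == comparison$control_group)
  if (!length(case_idx) || !length(ctrl_idx))
    stop("comparison groups not present in sample map: ", comparison$name)
  x <- ab$values
  m_case <- rowMeans(x[, case_idx, drop = FALSE])
  m_ctrl <- rowMeans(x[, ctrl_idx, drop = FALSE])
  log2fc <- log2((m_case + pseudocount) / (m_ctrl + pseudocount))

  if (method == "passthrough") {
    if (is.null(p_values)) stop("passthrough requires p_values")
    p <- unname(p_values[rownames(x)])
    if (anyNA(p)) stop("p_values missing for some features")
  } else {
    n1 <- length(case_idx); n2 <- length(ctrl_idx)
    if (n1 < 2L || n2 < 2L)
      stop("welch_log needs >= 2 replicates per group (",
           comparison$name, " has ", n1, "/", n2, ")")
    l1 <- log2(x[, case_idx, drop = FALSE] + pseudocount)
    l2 <- log2(x[, ctrl_idx, drop = FALSE] + pseudocount)
    mu1 <- rowMeans(l1); mu2 <- rowMeans(l2)
    v1 <- rowSums((l1 - mu1)^2) / (n1 - 1L)
    v2 <- rowSums((l2 - mu2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (mu1 - mu2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- 2 * stats::pt(-abs(tstat), df)
    degen <- se2 == 0
    p[degen] <- ifelse(mu1[degen] == mu2[degen], 1, 0)
  }
  data.frame(feature_id = rownames(x), comparison = comparison$name,
             log2fc = unname(log2fc), p = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH with monotonicity enforcement, aligned to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values (same order).
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-layer differential filtering thresholds
#'
#' Defaults as conventionally printed per layer:
#' lncRNA: fold change >= 2 (log2fc >= 1), FDR <= 0.05;
#' miRNA: |log2fc| >= 0.585, p <= 0.05;
#' mRNA: |log2fc| >= 1, p <= 0.05;
#' metabolite: |log2fc| >= 0.585 plus the VIP rule. The printed metabolite
#' direction is "vip <= 1", which contradicts standard (O)PLS VIP ranking
#' (VIP >= 1); the default ships as `vip_direction = "ge"` with the literal
#' `"le"` switch available, and the choice is surfaced when filtering.
#'
#' @param layer One of lncRNA/miRNA/mRNA/metabolite.
#' @param log2fc_min,significance_field,significance_max,vip_min,vip_direction
#'   Override the per-layer defaults.
#' @export
threshold_config <- function(layer = c("lncRNA", "miRNA", "mRNA", "metabolite"),
                             log2fc_min = NULL,
                             significance_field = NULL,
                             significance_max = NULL,
                             vip_min = NULL,
                             vip_direction = c("ge", "le")) {
  layer <- match.arg(layer)
  defaults <- list(
    lncRNA = list(log2fc_min = 1, significance_field = "fdr",
                  significance_max = 0.05),
    miRNA = list(log2fc_min = 0.585, significance_field = "p",
                 significance_max = 0.05),
    mRNA = list(log2fc_min = 1, significance_field = "p",
                significance_max = 0.05),
    metabolite = list(log2fc_min = 0.585, significance_field = "p",
                      significance_max = 1, vip_min = 1)
  )[[layer]]
  cfg <- list(
    layer = layer,
    log2fc_min = if (is.null(log2fc_min)) defaults$log2fc_min else log2fc_min,
    significance_field = if (is.null(significance_field))
      defaults$significance_field else
        match.arg(significance_field, c("p", "fdr")),
    significance_max = if (is.null(significance_max))
      defaults$significance_max else significance_max,
    vip_min = if (layer == "metabolite") {
      if (is.null(vip_min)) defaults$vip_min else vip_min
    } else NULL,
    vip_direction = if (layer == "metabolite") match.arg(vip_direction) else NULL
  )
  if (cfg$log2fc_min < 0) stop("log2fc_min must be non-negative")
  if (cfg$significance_max <= 0 || cfg$significance_max > 1)
    stop("significance_max must lie in (0, 1]")
  cfg
}

#' Apply per-layer thresholds to differential results
#'
#' `direction = "up"` iff `log2fc >= log2fc_min` with the significance
#' (and, for metabolites, VIP) rule satisfied; `"down"` for
#' `log2fc <= -log2fc_min` likewise; `"ns"` otherwise. All comparisons are
#' inclusive, as printed.
#'
#' @param results data.frame from [de_test()], with an `fdr` column when the
#'   layer's significance field is `fdr`, and a `vip` column for metabolites.
#' @param thresholds A [threshold_config()].
#' @return `results` with a `direction` factor column added.
#' @export
filter_de <- function(results, thresholds) {
  sig_col <- thresholds$significance_field
  if (is.null(results[[sig_col]]))
    stop("results lack the required significance column: ", sig_col)
  sig_ok <- results[[sig_col]] <= thresholds$significance_max
  extra_ok <- TRUE
  if (thresholds$layer == "metabolite") {
    if (is.null(results$vip)) stop("metabolite filtering requires a vip column")
    message("filter_de: metabolite VIP rule applied as vip ",
            if (thresholds$vip_direction == "ge") ">=" else "<=", " ",
            thresholds$vip_min,
            " (the literature convention is VIP >= 1)")
    extra_ok <- if (thresholds$vip_direction == "ge")
      results$vip >= thresholds$vip_min else results$vip <= thresholds$vip_min
  }
  up <- results$log2fc >= thresholds$log2fc_min & sig_ok & extra_ok
  down <- results$log2fc <= -thresholds$log2fc_min & sig_ok & extra_ok
  results$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  results
}

#' Venn arithmetic over named feature sets
#'
#' @param groups Named list (>= 2) of character vectors.
#' @return List with `regions` (exclusive region cardinalities, names like
#'   `"A&B"`), `intersection` (the k-way common set), and `union`.
#' @export
venn <- function(groups) {
  if (length(groups) < 2L) stop("venn needs >= 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  groups <- lapply(groups, unique)
  all_ids <- unique(unlist(groups, use.names = FALSE))
  member <- vapply(groups, function(g) all_ids %in% g,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, names(groups)))
  key <- apply(member, 1L, function(r) paste(names(groups)[r], collapse = "&"))
  regions <- table(key)
  common <- all_ids[rowSums(member) == length(groups)]
  list(regions = as.list(regions),
       intersection = sort(common),
       union = sort(all_ids))
}
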