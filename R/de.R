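# Differential-expression summary rules: Benjamini-Hochberg adjustment,
# threshold classification (|log2FC| >= 1 inclusive, FDR < 0.05 strict),
# summary counts/percentages, volcano coordinates and row-Z-scored
# heatmap matrices clamped to [-2, +2].

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`p_(i) * m / i`, monotonicity enforced from the
#' largest rank down, capped at 1, original order restored), delegated to
#' `stats::p.adjust(method = "BH")` after validation.
#'
#' @param pvalues numeric vector of p-values in [0, 1]; may be empty.
#' @return adjusted p-values in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Classify genes as up-, down-regulated or not significant
#'
#' A gene is `up` iff `log2fc >= lfc_min` and `padj < fdr_max`; `down` iff
#' `log2fc <= -lfc_min` and `padj < fdr_max`; otherwise `ns`. The log2FC
#' bound is inclusive and the FDR bound strict. When `padj` is absent it
#' is computed from `pvalue` with [bh_adjust()]. Genes with missing
#' log2fc are labeled `ns` with a warning.
#'
#' @param table data.frame with columns `gene_id, log2fc, pvalue` and
#'   optionally `padj`; gene ids must be unique.
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return the table with columns `padj` and `label` (factor `up`, `down`,
#'   `ns`) appended.
#' @export
classify_genes <- function(table, lfc_min = 1.0, fdr_max = 0.05) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(table)))
  if (anyDuplicated(table$gene_id)) stopf("gene_id values must be unique")
  if (!"padj" %in% names(table)) {
    if (!"pvalue" %in% names(table))
      stopf("need either a 'padj' or a 'pvalue' column")
    table$padj <- bh_adjust(table$pvalue)
  }
  lfc <- table$log2fc
  if (anyNA(lfc)) {
    warnf("%d gene(s) lack log2fc; labeled ns", sum(is.na(lfc)))
  }
  sig <- !is.na(lfc) & !is.na(table$padj) & table$padj < fdr_max
  label <- rep("ns", nrow(table))
  label[sig & lfc >= lfc_min] <- "up"
  label[sig & lfc <= -lfc_min] <- "down"
  table$label <- factor(label, levels = c("up", "down", "ns"))
  table
}

#' Summarize a classified differential-expression table
#'
#' Counts of detected/up/down genes and one-decimal percentages of
#' detected genes ("detected" = rows present in the table).
#'
#' @param table a table classified by [classify_genes()] (or any
#'   data.frame with a `label` column).
#' @return a list `n_detected, n_up, n_down, pct_up, pct_down`.
#' @export
#' @examples
#' de <- classify_genes(simulate_de_table(1000, 80, 60, seed = 2))
#' summarize_de(de)
summarize_de <- function(table) {
  stopifnot("label" %in% names(table))
  n <- nrow(table)
  if (n == 0L) stopf("cannot summarize an empty table")
  n_up <- sum(table$label == "up")
  n_down <- sum(table$label == "down")
  list(n_detected = n, n_up = n_up, n_down = n_down,
       pct_up = round(100 * n_up / n, 1),
       pct_down = round(100 * n_down / n, 1))
}

#' Row-Z-score a genes-by-samples matrix with clamping
#'
#' Per row: subtract the mean, divide by the sample SD (denominator
#' n - 1), clamp to `[-clamp, +clamp]`. Constant rows become all zeros
#' with a warning.
#'
#' @param m numeric matrix, genes in rows, >= 2 samples (columns).
#' @param clamp symmetric clamp bound (default 2).
#' @return the scaled, clamped matrix (same dimnames).
#' @export
zscore_rows <- function(m, clamp = 2) {
  if (!is.matrix(m) || ncol(m) < 2L)
    stopf("need a matrix with >= 2 samples per row")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flat <- s == 0
  if (any(flat)) {
    warnf("%d constant row(s) set to zero", sum(flat))
    s[flat] <- 1
  }
  z <- (m - mu) / s
  z[flat, ] <- 0
  pmin(pmax(z, -clamp), clamp)
}

#' Volcano-plot coordinates for a classified table
#'
#' Per gene: `x = log2fc`, `y = -log10(padj)`, plus the classification
#' label. Zero adjusted p-values are mapped to one tenth of the smallest
#' nonzero `padj` (flagged in `padj_floored`) so every coordinate is
#' finite.
#'
#' @param table a table classified by [classify_genes()].
#' @return a data.frame `gene_id, log2fc, neg_log10_padj, label,
#'   padj_floored`.
#' @export
volcano_coordinates <- function(table) {
  stopifnot(all(c("gene_id", "log2fc", "padj", "label") %in% names(table)))
  padj <- table$padj
  zero <- !is.na(padj) & padj == 0
  if (any(zero)) {
    nz <- padj[!is.na(padj) & padj > 0]
    floor_val <- if (length(nz)) min(nz) / 10 else 1e-300
    padj[zero] <- floor_val
  }
  data.frame(gene_id = table$gene_id, log2fc = table$log2fc,
             neg_log10_padj = -log10(padj), label = table$label,
             padj_floored = zero)
}
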