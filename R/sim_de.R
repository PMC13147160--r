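#' Simulate a differential-expression result table with spiked genes
#'
#' Produces a per-gene statistics table (`gene_id, log2fc, pvalue`) with
#' `n_up` genes spiked up, `n_down` spiked down and the remainder null.
#' Spiked genes receive `|log2FC| >= lfc_effect` and essentially zero
#' p-values; null genes draw log2FC from N(0, 0.2) (so `|log2FC|` is
#' concentrated well below 1) and uniform p-values. With a strong effect the
#' standard classification rules (|log2FC| >= 1, BH-FDR < 0.05) recover the
#' spiked counts exactly with very high probability. The row order is
#' shuffled; the attribute `truth` records each gene's programmed class.
#'
#' @param n_genes total number of genes.
#' @param n_up,n_down numbers of up-/down-spiked genes
#'   (`n_up + n_down <= n_genes`).
#' @param lfc_effect minimum absolute log2 fold change of spiked genes
#'   (> 1).
#' @param seed integer seed.
#' @return a data.frame with columns `gene_id, log2fc, pvalue` and attribute
#'   `truth` (character vector `up`/`down`/`null` aligned with rows).
#' @export
#' @examples
#' de <- simulate_de_table(1000, 50, 30, seed = 1)
#' table(attr(de, "truth"))
simulate_de_table <- function(n_genes, n_up, n_down, lfc_effect = 4,
                              seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", min = 1)
  assert_scalar_number(n_up, "n_up", min = 0)
  assert_scalar_number(n_down, "n_down", min = 0)
  if (n_up + n_down > n_genes)
    stopf("n_up + n_down (%d) exceeds n_genes (%d)", n_up + n_down, n_genes)
  assert_scalar_number(lfc_effect, "lfc_effect", min = 1, strict_min = TRUE)

  n_null <- n_genes - n_up - n_down
  withr::with_seed(as.integer(seed), {
    lfc <- c(lfc_effect + abs(rnorm(n_up, 0, 0.5)),
             -(lfc_effect + abs(rnorm(n_down, 0, 0.5))),
             rnorm(n_null, 0, 0.2))
    pval <- c(10^-runif(n_up + n_down, 10, 40), runif(n_null))
    truth <- c(rep("up", n_up), rep("down", n_down), rep("null", n_null))
    ord <- sample.int(n_genes)
  })
  out <- data.frame(
    gene_id = sprintf("gene%06d", seq_len(n_genes)),
    log2fc = lfc[ord], pvalue = pval[ord])
  attr(out, "truth") <- truth[ord]
  out
}
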