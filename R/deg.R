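# DEG filtering and Venn-overlap summaries for comparing the
# transcriptional footprints of two treatments.

#' Filter a differential-expression table to DEGs
#'
#' A gene is a DEG when `|log2FC| >= lfc_threshold` and its p-value is
#' strictly below `p_threshold`. The gate uses the raw p-value column by
#' default, with the FDR column available as an option.
#'
#' @param table data.frame with columns `gene`, `log2FC` and `pvalue`
#'   (and `FDR` if selected).
#' @param lfc_threshold minimal absolute log2 fold change (default 1).
#' @param p_threshold significance cutoff (default 0.05).
#' @param p_column `"pvalue"` (default) or `"FDR"`.
#' @return data.frame `gene`, `log2FC`, `direction` (`"up"`/`"down"`).
#' @export
filter_degs <- function(table, lfc_threshold = 1, p_threshold = 0.05,
                        p_column = c("pvalue", "FDR")) {
  p_column <- match.arg(p_column)
  p <- table[[p_column]]
  keep <- abs(table$log2FC) >= lfc_threshold & p < p_threshold
  data.frame(gene = table$gene[keep], log2FC = table$log2FC[keep],
             direction = ifelse(table$log2FC[keep] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

# round-half-up to `digits` decimals (what printed percentage tables use;
# base round() would go half-to-even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Pairwise overlap (Venn) summary of two gene sets
#'
#' Exact set arithmetic plus percentages of the shared and unique parts
#' relative to each set, rounded half-up to one decimal. Percentages are
#' always recomputed from the counts; for an empty set they are `NA`
#' ("undefined"), never 0.
#'
#' @param setA,setB character vectors of gene ids (duplicates ignored).
#' @param labels length-2 names for the sets.
#' @return list of class `venn_summary`: `n_a`, `n_b`, `n_shared`,
#'   `n_only_a`, `n_only_b`, and percentages `pct_shared_of_a`,
#'   `pct_shared_of_b`, `pct_only_a`, `pct_only_b`.
#' @export
venn_overlap <- function(setA, setB, labels = c("A", "B")) {
  a <- unique(setA); b <- unique(setB)
  shared <- intersect(a, b)
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  structure(list(labels = labels,
                 n_a = length(a), n_b = length(b),
                 n_shared = length(shared),
                 n_only_a = length(a) - length(shared),
                 n_only_b = length(b) - length(shared),
                 pct_shared_of_a = pct(length(shared), length(a)),
                 pct_shared_of_b = pct(length(shared), length(b)),
                 pct_only_a = pct(length(a) - length(shared), length(a)),
                 pct_only_b = pct(length(b) - length(shared), length(b))),
            class = "venn_summary")
}

#' Overlap summary directly from printed counts
#'
#' When only the set sizes and intersection count are known (e.g. from a
#' published Venn diagram), this recomputes every derived quantity without
#' materializing gene ids.
#'
#' @param n_a,n_b,n_shared set sizes and intersection size.
#' @param labels length-2 names for the sets.
#' @return a `venn_summary` (see [venn_overlap()]).
#' @export
venn_from_counts <- function(n_a, n_b, n_shared, labels = c("A", "B")) {
  stopifnot(n_shared <= n_a, n_shared <= n_b, n_shared >= 0)
  ids <- paste0("s", seq_len(n_shared))
  only_a <- paste0("a", seq_len(n_a - n_shared))
  only_b <- paste0("b", seq_len(n_b - n_shared))
  venn_overlap(c(ids, only_a), c(ids, only_b), labels)
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("<venn_summary> ", x$labels[1], " (n=", x$n_a, ") vs ",
      x$labels[2], " (n=", x$n_b, ")\n", sep = "")
  cat("  shared: ", x$n_shared, " (", x$pct_shared_of_a, "% of ",
      x$labels[1], ", ", x$pct_shared_of_b, "% of ", x$labels[2], ")\n",
      sep = "")
  cat("  unique: ", x$n_only_a, " (", x$pct_only_a, "%) / ", x$n_only_b,
      " (", x$pct_only_b, "%)\n", sep = "")
  invisible(x)
}

#' Top-ranked differentially expressed genes
#'
#' Deterministic ranking by descending `|log2FC|` with ties broken by
#' gene id, truncated to `n` rows.
#'
#' @param table a DEG table with columns `gene` and `log2FC`.
#' @param n number of genes to keep (default 50).
#' @return the top rows of `table`, re-ordered.
#' @export
top_degs <- function(table, n = 50) {
  ord <- order(-abs(table$log2FC), table$gene)
  utils::head(table[ord, , drop = FALSE], n)
}

#' Export a gene list for external enrichment tools
#'
#' One gene id per line, plain text.
#'
#' @param genes character vector.
#' @param path output file.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(unique(genes), path)
  invisible(path)
}
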