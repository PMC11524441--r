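# Cross-model concordance of two DE tables: shared-significant-gene
# selection, Spearman rank correlation and discordant-sign fraction.

#' Genes significant in both of two DE tables
#'
#' Selects genes with `fdr < fdr_threshold` (strict, matching the
#' "FDR < 0.05" convention used for cross-model scatter plots) in *both*
#' tables and returns their paired log2 fold changes, ordered
#' deterministically by gene symbol. Tables must be keyed by comparable
#' symbols; map orthologs upstream with [map_orthologs()] if the species
#' differ.
#'
#' @param table_a,table_b [de_table()]s.
#' @param fdr_threshold strict FDR cutoff (default 0.05).
#' @return Data frame with columns `gene`, `log2fc_a`, `log2fc_b`; zero rows
#'   when no gene is significant in both.
#' @export
shared_significant <- function(table_a, table_b, fdr_threshold = 0.05) {
  stopifnot(inherits(table_a, "de_table"), inherits(table_b, "de_table"))
  sig_a <- table_a$gene[table_a$fdr < fdr_threshold]
  sig_b <- table_b$gene[table_b$fdr < fdr_threshold]
  genes <- sort(intersect(sig_a, sig_b))
  fa <- fold_changes(table_a); fb <- fold_changes(table_b)
  data.frame(gene = genes,
             log2fc_a = unname(fa[genes]),
             log2fc_b = unname(fb[genes]),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks), so the statistic is invariant under strictly monotone transforms
#' of either input.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return The correlation coefficient rho in `[-1, 1]`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop_oasig("x and y must have equal length", "oasig_validation_error")
  if (length(x) < 3)
    stop_oasig("need at least 3 pairs", "oasig_validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_oasig("undefined correlation: constant input", "oasig_degenerate_error")
  stats::cor(x, y, method = "spearman")
}

#' Fraction of sign-discordant pairs
#'
#' Fraction of gene pairs whose two log2 fold changes have opposite signs,
#' among pairs where both values are non-zero (the sign of an exact zero is
#' undefined, so such pairs are excluded).
#'
#' @param x,y numeric vectors of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
discordant_fraction <- function(x, y) {
  if (length(x) != length(y))
    stop_oasig("x and y must have equal length", "oasig_validation_error")
  keep <- x != 0 & y != 0
  if (!any(keep))
    stop_oasig("undefined fraction: no pairs with both signs defined",
               "oasig_degenerate_error")
  mean(sign(x[keep]) * sign(y[keep]) < 0)
}

#' Concordance of two differential-expression experiments
#'
#' Runs the full cross-model comparison: selects genes significant in both
#' tables ([shared_significant()]), computes their Spearman rank correlation
#' and the fraction regulated in opposing directions, and returns a
#' gene-level table with a per-gene concordant flag.
#'
#' @param table_a,table_b [de_table()]s on a shared gene namespace.
#' @param fdr_threshold strict FDR cutoff applied to both tables.
#' @return An object of class `"concordance"`: list with `n_genes`,
#'   `spearman_rho`, `discordant_fraction` and `genes` (data frame with
#'   `gene`, `log2fc_a`, `log2fc_b`, `concordant`).
#' @export
concordance <- function(table_a, table_b, fdr_threshold = 0.05) {
  pairs <- shared_significant(table_a, table_b, fdr_threshold)
  if (nrow(pairs) < 3)
    stop_oasig(sprintf("only %d gene(s) significant in both tables; need >= 3",
                       nrow(pairs)), "oasig_degenerate_error")
  rho <- spearman_correlation(pairs$log2fc_a, pairs$log2fc_b)
  disc <- discordant_fraction(pairs$log2fc_a, pairs$log2fc_b)
  pairs$concordant <- sign(pairs$log2fc_a) * sign(pairs$log2fc_b) >= 0
  structure(list(n_genes = nrow(pairs), spearman_rho = rho,
                 discordant_fraction = disc, genes = pairs,
                 fdr_threshold = fdr_threshold,
                 dataset_a = attr(table_a, "dataset_id"),
                 dataset_b = attr(table_b, "dataset_id")),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Concordance of '%s' vs '%s' (FDR < %g in both):\n",
              x$dataset_a, x$dataset_b, x$fdr_threshold))
  cat(sprintf("  shared significant genes: %d\n", x$n_genes))
  cat(sprintf("  Spearman rho:             %.3f\n", x$spearman_rho))
  cat(sprintf("  discordant fraction:      %.3f (%.1f%%)\n",
              x$discordant_fraction, 100 * x$discordant_fraction))
  invisible(x)
}

#' Scatter plot of paired log2 fold changes
#'
#' @param x a [concordance()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.concordance <- function(x, ...) {
  g <- x$genes
  graphics::plot(g$log2fc_a, g$log2fc_b, pch = 16,
                 col = ifelse(g$concordant, "grey40", "red"),
                 xlab = sprintf("log2FC (%s)", x$dataset_a),
                 ylab = sprintf("log2FC (%s)", x$dataset_b), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::mtext(sprintf("Spearman rho = %.2f, discordant = %.1f%%",
                          x$spearman_rho, 100 * x$discordant_fraction),
                  side = 3, line = 0.5, cex = 0.9)
  invisible(x)
}
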