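# Exact 2x2 enrichment tests: directional curated-annotation enrichment
# (Protective vs Detrimental among DE genes) and predicted miRNA-target
# enrichment among up- vs downregulated genes.

#' 2x2 contingency table
#'
#' Four non-negative integer counts with the layout
#' `a = DE & group1`, `b = non-DE & group1`, `c = DE & group2`,
#' `d = non-DE & group2`. At least one margin must be positive.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return An object of class `"contingency_2x2"`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop_oasig("counts must be non-negative integers", "oasig_validation_error")
  if (sum(counts) == 0)
    stop_oasig("all-zero contingency table", "oasig_validation_error")
  counts <- as.integer(round(counts))
  structure(list(a = counts[1], b = counts[2], c = counts[3], d = counts[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"), c("DE", "non-DE")))
  print(m)
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional exact test with both margins fixed. Hypergeometric point
#' probabilities are evaluated in log space; the two-sided p-value follows
#' the minimum-likelihood rule (sum of the probabilities of all tables with
#' the same margins whose point probability does not exceed that of the
#' observed table, within relative tolerance 1e-7), the convention used by
#' standard statistical software. One-sided tails are direct sums. The odds
#' ratio is the sample odds ratio `(a d)/(b c)`, `Inf` when `b c = 0`.
#'
#' @param table a [contingency_2x2()].
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   `"greater"` means group1 is enriched for DE relative to group2.
#' @param direction free-text description of what group1 vs group2 are,
#'   carried into the result.
#' @return An object of class `"enrichment_result"`: a list with `table`,
#'   `odds_ratio`, `pvalue` (clipped to `(0, 1]`), `alternative`,
#'   `direction`.
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "greater", "less"),
                             direction = "group1 vs group2") {
  stopifnot(inherits(table, "contingency_2x2"))
  alternative <- match.arg(alternative)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- a + b            # size of group1
  n <- c + d            # size of group2
  k <- a + c            # number of DE genes among both groups
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- stats::dhyper(xs, m, n, k, log = TRUE)
  obs <- logp[match(a, xs)]
  p <- switch(alternative,
    two.sided = sum(exp(logp[logp <= obs + log1p(1e-7)])),
    greater   = sum(exp(logp[xs >= a])),
    less      = sum(exp(logp[xs <= a])))
  p <- min(1, max(p, .Machine$double.xmin))
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c)
  structure(list(table = table, odds_ratio = or, pvalue = p,
                 alternative = alternative, direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Exact 2x2 enrichment (%s), %s:\n", x$direction, x$alternative))
  print(x$table)
  or <- if (is.nan(x$odds_ratio)) "undefined"
        else formatC(x$odds_ratio, digits = 4, format = "g")
  cat(sprintf("odds ratio = %s, p = %s\n", or,
              formatC(x$pvalue, digits = 4, format = "g")))
  invisible(x)
}

#' Directional enrichment of curated effect labels among DE genes
#'
#' Tests whether differentially expressed genes are biased towards
#' `Protective` rather than `Detrimental` curated labels. The 2x2 table is
#' built from the annotated genes present in the experiment's background:
#' `a` = DE & Protective, `b` = non-DE & Protective, `c` = DE & Detrimental,
#' `d` = non-DE & Detrimental. `Ambiguous`-labelled genes are excluded
#' entirely. The test is two-sided Fisher's exact.
#'
#' @param de_genes character vector of differentially expressed genes
#'   (restricted to `background`).
#' @param background character vector of genes detected in the experiment.
#' @param annotation a [curated_annotation()].
#' @return An [fisher_exact_2x2()] result with
#'   `direction = "Protective vs Detrimental"`.
#' @export
directional_enrichment <- function(de_genes, background, annotation) {
  stopifnot(inherits(annotation, "curated_annotation"))
  background <- unique(norm_symbols(background))
  de_genes <- intersect(unique(norm_symbols(de_genes)), background)
  prot <- intersect(names(annotation)[annotation == "Protective"], background)
  det <- intersect(names(annotation)[annotation == "Detrimental"], background)
  if (!length(prot) && !length(det))
    stop_oasig("no Protective/Detrimental annotated genes in the background",
               "oasig_empty_background")
  a <- length(intersect(de_genes, prot))
  c_ <- length(intersect(de_genes, det))
  tab <- contingency_2x2(a, length(prot) - a, c_, length(det) - c_)
  fisher_exact_2x2(tab, "two.sided", direction = "Protective vs Detrimental")
}

#' Predicted-target enrichment among up- vs downregulated genes
#'
#' Tests whether a predicted miRNA target set is over-represented among
#' upregulated compared with downregulated genes (as after miRNA inhibition,
#' where direct targets are expected to rise). Table:
#' `a` = targets & up, `b` = up non-targets, `c` = targets & down,
#' `d` = down non-targets; two-sided Fisher's exact.
#'
#' @param up,down disjoint character vectors of up-/downregulated genes.
#' @param targets a [target_gene_set()].
#' @return An [fisher_exact_2x2()] result.
#' @export
target_enrichment <- function(up, down, targets) {
  stopifnot(inherits(targets, "target_gene_set"))
  up <- unique(norm_symbols(up)); down <- unique(norm_symbols(down))
  if (!length(up) && !length(down))
    stop_oasig("both up and down gene sets are empty", "oasig_empty_input")
  if (length(intersect(up, down)))
    stop_oasig("up and down gene sets must be disjoint", "oasig_validation_error")
  a <- length(intersect(targets$genes, up))
  c_ <- length(intersect(targets$genes, down))
  tab <- contingency_2x2(a, length(up) - a, c_, length(down) - c_)
  fisher_exact_2x2(tab, "two.sided",
                   direction = sprintf("%s targets: up vs down", targets$set_id))
}
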