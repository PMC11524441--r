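# Cosine-similarity search of a query fold-change profile against a
# compendium, with z-score standardisation across the compendium and
# deterministic ranking.

#' Cosine similarity between two fold-change vectors
#'
#' Computed over the intersection of gene names: similar fold changes score
#' positively, opposite fold changes negatively. Symmetric in its arguments
#' and invariant to positive rescaling of either.
#'
#' @param u,v named numeric vectors keyed by gene symbol.
#' @return List with `cosine` (in `[-1, 1]`) and `n_shared` (genes used).
#'   An empty intersection or a zero-norm restricted vector is an error, not
#'   a silent 0.
#' @export
cosine_similarity <- function(u, v) {
  if (is.null(names(u)) || is.null(names(v)))
    stop_oasig("u and v must be named numeric vectors", "oasig_validation_error")
  shared <- intersect(names(u), names(v))
  if (!length(shared))
    stop_oasig("undefined similarity: no shared genes", "oasig_undefined_similarity")
  a <- as.numeric(u[shared]); b <- as.numeric(v[shared])
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop_oasig("undefined similarity: zero-norm vector on shared genes",
               "oasig_undefined_similarity")
  list(cosine = sum(a * b) / (na * nb), n_shared = length(shared))
}

#' Standardise similarity scores to z-scores
#'
#' Converts raw similarity scores to standard deviations from their mean
#' (sample standard deviation, n - 1 denominator), so scores are comparable
#' across queries.
#'
#' @param scores numeric vector, length >= 2, not constant.
#' @return Numeric vector of z-scores with mean 0 and sample sd 1.
#' @export
zscore_standardize <- function(scores) {
  if (length(scores) < 2)
    stop_oasig("need at least 2 scores to standardise", "oasig_degenerate_error")
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0)
    stop_oasig("degenerate score distribution (zero variance)",
               "oasig_degenerate_error")
  (scores - mean(scores)) / s
}

#' Search a fold-change compendium by cosine similarity
#'
#' Compares a query profile against every compendium dataset over their
#' shared genes, converts the cosine scores to z-scores across the datasets
#' that pass the `min_shared` filter, and ranks by z-score (ties broken by
#' `dataset_id` so ranks are reproducible). Datasets sharing fewer than
#' `min_shared` genes with the query are reported separately and never
#' scored; the query itself is not part of the background.
#'
#' @param query a [fold_change_profile()] or [de_table()].
#' @param compendium a [compendium()].
#' @param min_shared minimum number of shared genes for a dataset to be
#'   scored (default 100, guarding against spuriously high cosines on tiny
#'   intersections).
#' @return A data frame of class `"simsearch"` with columns `dataset_id`,
#'   `n_shared`, `cosine`, `zscore`, `rank`, sorted by decreasing z-score.
#'   Attribute `skipped` lists datasets failing the filter with their shared
#'   gene counts; attribute `query_id` records the query.
#' @export
compendium_search <- function(query, compendium, min_shared = 100) {
  stopifnot(inherits(compendium, "compendium"))
  q <- fold_changes(query)
  qid <- if (inherits(query, "fold_change_profile")) query$dataset_id
         else attr(query, "dataset_id")
  ids <- names(compendium$profiles)
  cos <- numeric(length(ids)); nsh <- integer(length(ids))
  for (i in seq_along(ids)) {
    p <- compendium$profiles[[i]]
    shared <- intersect(names(q), names(p$values))
    nsh[i] <- length(shared)
    if (nsh[i] >= min_shared) {
      r <- cosine_similarity(q[shared], p$values[shared])
      cos[i] <- r$cosine
    } else cos[i] <- NA_real_
  }
  pass <- nsh >= min_shared
  if (sum(pass) < 2)
    stop_oasig(sprintf(
      "degenerate background: only %d dataset(s) share >= %d genes with the query",
      sum(pass), min_shared), "oasig_degenerate_error")
  z <- zscore_standardize(cos[pass])
  res <- data.frame(dataset_id = ids[pass], n_shared = nsh[pass],
                    cosine = cos[pass], zscore = z, stringsAsFactors = FALSE)
  ord <- order(-res$zscore, res$dataset_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res,
            skipped = data.frame(dataset_id = ids[!pass],
                                 n_shared = nsh[!pass],
                                 stringsAsFactors = FALSE),
            query_id = qid, min_shared = min_shared,
            class = c("simsearch", "data.frame"))
}

#' @export
print.simsearch <- function(x, ...) {
  cat(sprintf("Compendium search for query '%s': %d datasets scored, %d skipped (< %d shared genes)\n",
              attr(x, "query_id"), nrow(x), nrow(attr(x, "skipped")),
              attr(x, "min_shared")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... %d more datasets\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.simsearch <- function(object, top = 10, ...) {
  cat(sprintf("Top %d of %d datasets by cosine-similarity z-score (query '%s'):\n",
              min(top, nrow(object)), nrow(object), attr(object, "query_id")))
  print.data.frame(utils::head(as.data.frame(object), top), digits = 4)
  invisible(object)
}

#' Rank/z-score table for plotting a compendium search
#'
#' Flattens a search result into a `(rank, zscore, dataset_id, highlight)`
#' table suitable for a rank-versus-z plot with a user-supplied set of
#' datasets highlighted. Unknown highlight ids produce a warning, not a
#' failure.
#'
#' @param results a [compendium_search()] result.
#' @param highlight character vector of dataset ids to flag.
#' @return Data frame with columns `rank`, `zscore`, `dataset_id`,
#'   `highlight` (logical).
#' @export
rank_plot_table <- function(results, highlight = character()) {
  stopifnot(inherits(results, "simsearch"))
  unknown <- setdiff(highlight, results$dataset_id)
  if (length(unknown))
    warning(sprintf("highlight id(s) not in results: %s",
                    paste(unknown, collapse = ", ")))
  data.frame(rank = results$rank, zscore = results$zscore,
             dataset_id = results$dataset_id,
             highlight = results$dataset_id %in% highlight,
             stringsAsFactors = FALSE)
}

#' Plot a compendium search as rank versus z-score
#'
#' @param x a [compendium_search()] result.
#' @param highlight dataset ids drawn in red.
#' @param ... further arguments passed to [graphics::plot()].
#' @return The plotting table, invisibly.
#' @export
plot.simsearch <- function(x, highlight = character(), ...) {
  tab <- rank_plot_table(x, highlight)
  graphics::plot(tab$rank, tab$zscore, pch = 16,
                 col = ifelse(tab$highlight, "red", "grey40"),
                 xlab = "Rank", ylab = "Cosine similarity z-score", ...)
  if (any(tab$highlight))
    graphics::points(tab$rank[tab$highlight], tab$zscore[tab$highlight],
                     pch = 16, col = "red", cex = 1.3)
  invisible(tab)
}
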