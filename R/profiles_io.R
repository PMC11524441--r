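# Data model and I/O for fold-change profiles, DE tables, curated annotations,
# target gene sets (GMT) and ortholog maps. All gene symbols are normalised to
# upper case on construction so that mouse ("Matn2") and human ("MATN2")
# symbols match across species.

norm_symbols <- function(x) toupper(trimws(as.character(x)))

stop_oasig <- function(msg, class) {
  stop(structure(class = c(class, "oasig_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Differential-expression result table
#'
#' Constructs a validated per-gene differential-expression table holding, for
#' each gene, the log2 fold change, the raw p-value and the
#' Benjamini-Hochberg-style false discovery rate. Gene symbols are upper-cased;
#' duplicates (after upper-casing) are rejected.
#'
#' @param gene character vector of gene symbols.
#' @param log2fc numeric vector of finite log2 fold changes.
#' @param pvalue numeric vector of p-values in `(0, 1]`.
#' @param fdr numeric vector of FDR-adjusted p-values in `[0, 1]`.
#' @param dataset_id single string identifying the experiment.
#' @param species single string, e.g. `"Mus musculus"`.
#'
#' @return A data frame of class `"de_table"` with columns `gene`, `log2fc`,
#'   `pvalue`, `fdr` and attributes `dataset_id` and `species`. Row order is
#'   preserved.
#' @seealso [read_de_table()], [significant_sets()]
#' @export
de_table <- function(gene, log2fc, pvalue, fdr, dataset_id = "dataset",
                     species = "unknown") {
  gene <- norm_symbols(gene)
  n <- length(gene)
  if (length(log2fc) != n || length(pvalue) != n || length(fdr) != n)
    stop_oasig("gene, log2fc, pvalue and fdr must have equal length",
               "oasig_validation_error")
  dup <- gene[duplicated(gene)]
  if (length(dup))
    stop_oasig(sprintf("duplicate gene symbol(s): %s",
                       paste(unique(dup), collapse = ", ")),
               "oasig_validation_error")
  if (n && any(!is.finite(log2fc)))
    stop_oasig("log2fc must be finite", "oasig_validation_error")
  if (n && (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1)))
    stop_oasig("pvalue must lie in (0, 1]", "oasig_validation_error")
  if (n && (any(!is.finite(fdr)) || any(fdr < 0) || any(fdr > 1)))
    stop_oasig("fdr must lie in [0, 1]", "oasig_validation_error")
  out <- data.frame(gene = gene, log2fc = as.numeric(log2fc),
                    pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                    stringsAsFactors = FALSE)
  structure(out, dataset_id = as.character(dataset_id),
            species = as.character(species),
            class = c("de_table", "data.frame"))
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("DE table '%s' (%s): %d genes\n",
              attr(x, "dataset_id"), attr(x, "species"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

# Parse a character column to numeric, reporting the 1-based *file* line of the
# first offending value (header is line 1).
parse_numeric_column <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad))
    stop_oasig(sprintf(
      "non-numeric value '%s' in column '%s' of %s at line %d",
      x[bad[1]], column, path, bad[1] + 1L), "oasig_parse_error")
  out
}

read_tsv_chr <- function(path) {
  if (!file.exists(path))
    stop_oasig(sprintf("file not found: %s", path), "oasig_format_error")
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a differential-expression table from tab-separated text
#'
#' Reads a TSV with a mandatory header row. Column names in the file are
#' resolved through `dialect`, a named character vector mapping the canonical
#' names (`gene`, `log2fc`, `pvalue`, `fdr`) to the names used in the file,
#' so tables from different pipelines (e.g. limma's `logFC`/`adj.P.Val`) can
#' be read without editing.
#'
#' @param path path to a tab-separated file with a header.
#' @param dataset_id,species metadata attached to the returned table.
#' @param dialect named character vector with entries `gene`, `log2fc`,
#'   `pvalue`, `fdr` giving the corresponding column names in the file.
#' @return A [de_table()] with rows in file order.
#' @export
read_de_table <- function(path, dataset_id = basename(path),
                          species = "unknown",
                          dialect = c(gene = "gene", log2fc = "log2FC",
                                      pvalue = "pvalue", fdr = "FDR")) {
  need <- c("gene", "log2fc", "pvalue", "fdr")
  if (!all(need %in% names(dialect)))
    stop_oasig("dialect must name columns gene, log2fc, pvalue, fdr",
               "oasig_format_error")
  raw <- read_tsv_chr(path)
  for (col in dialect[need])
    if (!col %in% names(raw))
      stop_oasig(sprintf("missing required column '%s' in %s", col, path),
                 "oasig_format_error")
  de_table(gene = raw[[dialect[["gene"]]]],
           log2fc = parse_numeric_column(raw[[dialect[["log2fc"]]]],
                                         dialect[["log2fc"]], path),
           pvalue = parse_numeric_column(raw[[dialect[["pvalue"]]]],
                                         dialect[["pvalue"]], path),
           fdr = parse_numeric_column(raw[[dialect[["fdr"]]]],
                                      dialect[["fdr"]], path),
           dataset_id = dataset_id, species = species)
}

#' Write a DE table as tab-separated text
#'
#' @param x a [de_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "de_table"))
  df <- as.data.frame(x)
  names(df) <- c("gene", "log2FC", "pvalue", "FDR")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Significantly up- and downregulated gene sets
#'
#' Applies the study's significance rule: a gene is upregulated when its fold
#' change is at least `fold_threshold` (supplied on the linear scale, so the
#' default 1.5 means `log2fc >= log2(1.5)`) and its FDR is at most
#' `fdr_threshold`; downregulated analogously with `log2fc <= -log2(fold)`.
#' Both thresholds are inclusive.
#'
#' @param table a [de_table()].
#' @param fold_threshold linear-scale fold-change threshold, `>= 1`.
#' @param fdr_threshold FDR threshold (inclusive).
#' @return A list with character vectors `up` and `down`; the two sets are
#'   disjoint. An empty table yields two empty sets.
#' @export
significant_sets <- function(table, fold_threshold = 1.5,
                             fdr_threshold = 0.05) {
  stopifnot(inherits(table, "de_table"))
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1 ||
      fold_threshold < 1)
    stop_oasig("fold_threshold must be a single number >= 1",
               "oasig_validation_error")
  lfc <- log2(fold_threshold)
  ok <- table$fdr <= fdr_threshold
  list(up = table$gene[ok & table$log2fc >= lfc],
       down = table$gene[ok & table$log2fc <= -lfc])
}

#' Fold-change profile
#'
#' One dataset's gene-to-log2-fold-change mapping, as stored in a fold-change
#' compendium such as SkeletalVis.
#'
#' @param dataset_id,species,description metadata strings.
#' @param values named numeric vector (names are gene symbols, upper-cased on
#'   construction; duplicates rejected; values must be finite).
#' @return An object of class `"fold_change_profile"`.
#' @export
fold_change_profile <- function(dataset_id, values, species = "unknown",
                                description = "") {
  if (is.null(names(values)) || any(names(values) == ""))
    stop_oasig("values must be a named numeric vector", "oasig_validation_error")
  names(values) <- norm_symbols(names(values))
  if (anyDuplicated(names(values)))
    stop_oasig(sprintf("duplicate gene symbol(s): %s",
                       paste(unique(names(values)[duplicated(names(values))]),
                             collapse = ", ")),
               "oasig_validation_error")
  if (any(!is.finite(values)))
    stop_oasig("fold-change values must be finite", "oasig_validation_error")
  structure(list(dataset_id = as.character(dataset_id),
                 species = as.character(species),
                 description = as.character(description),
                 values = values),
            class = "fold_change_profile")
}

#' @export
print.fold_change_profile <- function(x, ...) {
  cat(sprintf("Fold-change profile '%s' (%s): %d genes\n",
              x$dataset_id, x$species, length(x$values)))
  invisible(x)
}

#' Extract the log2 fold-change vector of a DE table or profile
#'
#' @param x a [de_table()] or [fold_change_profile()].
#' @return Named numeric vector of log2 fold changes keyed by gene symbol.
#' @export
fold_changes <- function(x) {
  if (inherits(x, "fold_change_profile")) return(x$values)
  if (inherits(x, "de_table")) return(stats::setNames(x$log2fc, x$gene))
  stop_oasig("x must be a de_table or fold_change_profile",
             "oasig_validation_error")
}

#' Fold-change profile compendium
#'
#' A collection of [fold_change_profile()]s plus a metadata table. Every
#' profile must have a metadata row and dataset ids must be unique.
#'
#' @param profiles list of [fold_change_profile()]s.
#' @param metadata data frame with columns `dataset_id`, `species`, `label`.
#' @return An object of class `"compendium"`.
#' @export
compendium <- function(profiles, metadata) {
  if (!is.list(profiles) || !all(vapply(profiles, inherits, logical(1),
                                        "fold_change_profile")))
    stop_oasig("profiles must be a list of fold_change_profile objects",
               "oasig_validation_error")
  ids <- vapply(profiles, function(p) p$dataset_id, character(1))
  if (anyDuplicated(ids))
    stop_oasig("duplicate dataset_id in profiles", "oasig_validation_error")
  if (!is.data.frame(metadata) ||
      !all(c("dataset_id", "species", "label") %in% names(metadata)))
    stop_oasig("metadata needs columns dataset_id, species, label",
               "oasig_validation_error")
  if (anyDuplicated(metadata$dataset_id))
    stop_oasig("duplicate dataset_id in metadata", "oasig_validation_error")
  missing <- setdiff(ids, metadata$dataset_id)
  if (length(missing))
    stop_oasig(sprintf("profiles without metadata: %s",
                       paste(utils::head(missing, 5), collapse = ", ")),
               "oasig_validation_error")
  names(profiles) <- ids
  structure(list(profiles = profiles, metadata = metadata),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("Fold-change compendium: %d profiles\n", length(x$profiles)))
  invisible(x)
}

#' @export
length.compendium <- function(x) length(x$profiles)

#' Read a fold-change compendium from a gene-by-dataset matrix
#'
#' The matrix file is tab-separated with genes in the first column (header
#' `gene`) and one column per dataset; blank cells (or `NA`) mean the gene was
#' not measured in that dataset and are dropped from its profile. Metadata is
#' a TSV with columns `dataset_id`, `species`, `label`.
#'
#' @param path path to the genes-by-datasets matrix TSV.
#' @param metadata_path path to the metadata TSV.
#' @return A [compendium()].
#' @export
read_profile_matrix <- function(path, metadata_path) {
  raw <- read_tsv_chr(path)
  if (ncol(raw) < 2)
    stop_oasig("profile matrix needs a gene column plus >= 1 dataset column",
               "oasig_format_error")
  genes <- norm_symbols(raw[[1]])
  meta_raw <- read_tsv_chr(metadata_path)
  if (!all(c("dataset_id", "species", "label") %in% names(meta_raw)))
    stop_oasig("metadata needs columns dataset_id, species, label",
               "oasig_format_error")
  meta <- data.frame(dataset_id = meta_raw$dataset_id,
                     species = meta_raw$species, label = meta_raw$label,
                     stringsAsFactors = FALSE)
  profiles <- lapply(names(raw)[-1], function(id) {
    col <- raw[[id]]
    keep <- !is.na(col) & col != ""
    vals <- parse_numeric_column(col[keep], id, path)
    i <- match(id, meta$dataset_id)
    fold_change_profile(id, stats::setNames(vals, genes[keep]),
                        species = if (is.na(i)) "unknown" else meta$species[i],
                        description = if (is.na(i)) "" else meta$label[i])
  })
  compendium(profiles, meta)
}

#' Write a compendium as a gene-by-dataset matrix plus metadata
#'
#' Inverse of [read_profile_matrix()]; genes are written in sorted order and
#' absent genes as blank cells.
#'
#' @param x a [compendium()].
#' @param path,metadata_path output paths.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "compendium"))
  genes <- sort(unique(unlist(lapply(x$profiles, function(p) names(p$values)))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (p in x$profiles)
    out[[p$dataset_id]] <- unname(p$values[match(genes, names(p$values))])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Curated gene effect annotation
#'
#' Gene-to-effect-label map in the style of the OATargets resource: each gene
#' is labelled `Protective` (less joint damage when activated), `Detrimental`
#' (more damage when activated) or `Ambiguous`.
#'
#' @param gene character vector of gene symbols (unique after upper-casing).
#' @param label character vector of labels.
#' @return Named character vector of class `"curated_annotation"` (names are
#'   genes, values labels).
#' @export
curated_annotation <- function(gene, label) {
  gene <- norm_symbols(gene)
  label <- as.character(label)
  if (length(gene) != length(label))
    stop_oasig("gene and label must have equal length", "oasig_validation_error")
  bad <- setdiff(unique(label), c("Protective", "Detrimental", "Ambiguous"))
  if (length(bad))
    stop_oasig(sprintf("unknown annotation label(s): %s",
                       paste(bad, collapse = ", ")), "oasig_validation_error")
  if (anyDuplicated(gene))
    stop_oasig(sprintf("gene annotated more than once: %s",
                       paste(unique(gene[duplicated(gene)]), collapse = ", ")),
               "oasig_validation_error")
  structure(stats::setNames(label, gene), class = "curated_annotation")
}

#' Read a curated annotation from tab-separated text
#'
#' Expects columns `gene` and `label`; labels must be `Protective`,
#' `Detrimental` or `Ambiguous`.
#'
#' @param path path to the annotation TSV.
#' @return A [curated_annotation()].
#' @export
read_annotation <- function(path) {
  raw <- read_tsv_chr(path)
  for (col in c("gene", "label"))
    if (!col %in% names(raw))
      stop_oasig(sprintf("missing required column '%s' in %s", col, path),
                 "oasig_format_error")
  curated_annotation(raw$gene, raw$label)
}

#' Predicted target gene set
#'
#' A named set of genes, e.g. the TargetScan- or mirDIP-predicted targets of
#' one miRNA. Members are upper-cased and de-duplicated; the set must be
#' non-empty.
#'
#' @param set_id set name (e.g. `"miR-199a-5p"`).
#' @param genes character vector of member gene symbols.
#' @param description free-text description.
#' @return An object of class `"target_gene_set"`.
#' @export
target_gene_set <- function(set_id, genes, description = "") {
  genes <- unique(norm_symbols(genes))
  if (!length(genes))
    stop_oasig("target gene set must be non-empty", "oasig_validation_error")
  structure(list(set_id = as.character(set_id),
                 description = as.character(description), genes = genes),
            class = "target_gene_set")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`; every line needs at
#' least one member.
#'
#' @param path path to a `.gmt` file.
#' @return Named list of [target_gene_set()]s.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop_oasig(sprintf("file not found: %s", path), "oasig_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_oasig(sprintf("ragged GMT line %d in %s (need name, description, >=1 member)",
                         i, path), "oasig_parse_error")
    target_gene_set(f[1], f[-(1:2)], description = f[2])
  })
  stats::setNames(sets, vapply(sets, function(s) s$set_id, character(1)))
}

#' Write gene sets in GMT format
#'
#' @param sets list of [target_gene_set()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$set_id, s$description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-to-one ortholog symbol map
#'
#' A mapping from source-species to target-species gene symbols used to
#' compare mouse models against human datasets. The map must be one-to-one:
#' duplicated source or target symbols are rejected here; use
#' [read_ortholog_map()] to drop many-to-many pairs instead.
#'
#' @param source,target character vectors of equal length.
#' @return Named character vector of class `"ortholog_map"` (names = source
#'   symbols, values = target symbols), upper-cased.
#' @export
ortholog_map <- function(source, target) {
  source <- norm_symbols(source); target <- norm_symbols(target)
  if (length(source) != length(target))
    stop_oasig("source and target must have equal length",
               "oasig_validation_error")
  if (anyDuplicated(source))
    stop_oasig(sprintf("source symbol maps to multiple targets: %s",
                       paste(unique(source[duplicated(source)]), collapse = ", ")),
               "oasig_validation_error")
  if (anyDuplicated(target))
    stop_oasig(sprintf("target symbol mapped from multiple sources: %s",
                       paste(unique(target[duplicated(target)]), collapse = ", ")),
               "oasig_validation_error")
  structure(stats::setNames(target, source), class = "ortholog_map")
}

#' Read an ortholog map, dropping many-to-many pairs
#'
#' Expects columns `source` and `target`. Pairs whose source or target symbol
#' occurs more than once are removed (both copies), so the result is strictly
#' one-to-one; the number of dropped pairs is reported via a message. This
#' avoids double-counting genes in enrichment backgrounds.
#'
#' @param path path to the two-column TSV.
#' @return An [ortholog_map()] with attribute `n_dropped`.
#' @export
read_ortholog_map <- function(path) {
  raw <- read_tsv_chr(path)
  for (col in c("source", "target"))
    if (!col %in% names(raw))
      stop_oasig(sprintf("missing required column '%s' in %s", col, path),
                 "oasig_format_error")
  src <- norm_symbols(raw$source); tgt <- norm_symbols(raw$target)
  keep <- !(src %in% src[duplicated(src)]) & !(tgt %in% tgt[duplicated(tgt)])
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(sprintf("read_ortholog_map: dropped %d many-to-many pair(s)",
                    n_dropped))
  m <- ortholog_map(src[keep], tgt[keep])
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Re-key a profile or DE table through an ortholog map
#'
#' Genes present in the map are renamed to their orthologs; genes absent from
#' the map are dropped and the dropped count is reported (message and
#' attribute `n_dropped`). Log2 fold changes and statistics are carried over
#' unchanged.
#'
#' @param x a [de_table()] or [fold_change_profile()].
#' @param map an [ortholog_map()].
#' @return Object of the same class as `x`, re-keyed; attribute `n_dropped`
#'   holds the number of genes without an ortholog.
#' @export
map_orthologs <- function(x, map) {
  stopifnot(inherits(map, "ortholog_map"))
  if (inherits(x, "fold_change_profile")) {
    keep <- names(x$values) %in% names(map)
    if (!any(keep))
      stop_oasig("no genes shared with the ortholog map (disjoint namespaces)",
                 "oasig_validation_error")
    vals <- x$values[keep]
    names(vals) <- unname(map[names(vals)])
    out <- fold_change_profile(x$dataset_id, vals, species = x$species,
                               description = x$description)
    attr(out, "n_dropped") <- sum(!keep)
  } else if (inherits(x, "de_table")) {
    keep <- x$gene %in% names(map)
    if (!any(keep))
      stop_oasig("no genes shared with the ortholog map (disjoint namespaces)",
                 "oasig_validation_error")
    sub <- as.data.frame(x)[keep, , drop = FALSE]
    out <- de_table(unname(map[sub$gene]), sub$log2fc, sub$pvalue, sub$fdr,
                    dataset_id = attr(x, "dataset_id"),
                    species = attr(x, "species"))
    attr(out, "n_dropped") <- sum(!keep)
  } else {
    stop_oasig("x must be a de_table or fold_change_profile",
               "oasig_validation_error")
  }
  message(sprintf("map_orthologs: %d gene(s) without ortholog dropped",
                  attr(out, "n_dropped")))
  out
}
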