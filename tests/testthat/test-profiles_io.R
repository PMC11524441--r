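test_that("read_de_table reads a well-formed TSV and preserves row order", {
  path <- write_lines_tmp(de_tsv_lines())
  tab <- read_de_table(path, dataset_id = "acl", species = "Mus musculus")
  expect_s3_class(tab, "de_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$gene, c("MATN2", "SOX9", "FYN"))  # upper-cased, file order
  expect_equal(tab$log2fc, c(2.98, 1.36, 0.39))
  expect_equal(attr(tab, "dataset_id"), "acl")
})

test_that("read_de_table resolves non-default column dialects", {
  path <- write_lines_tmp(c("symbol\tlfc\tP\tpadj", "Gdf5\t3.89\t4.11e-7\t1e-5"))
  tab <- read_de_table(path, dialect = c(gene = "symbol", log2fc = "lfc",
                                         pvalue = "P", fdr = "padj"))
  expect_equal(tab$gene, "GDF5")
  expect_equal(tab$fdr, 1e-5)
})

test_that("read_de_table reports missing columns, duplicates and bad values", {
  no_fdr <- write_lines_tmp(c("gene\tlog2FC\tpvalue", "A\t1\t0.1"))
  expect_error(read_de_table(no_fdr), "FDR", class = "oasig_format_error")

  dup <- write_lines_tmp(c("gene\tlog2FC\tpvalue\tFDR",
                           "Sox9\t1\t0.1\t0.2", "SOX9\t2\t0.1\t0.2"))
  expect_error(read_de_table(dup), "SOX9", class = "oasig_validation_error")

  # "NA" FDR sits on file line 4 (header is line 1)
  bad <- write_lines_tmp(c("gene\tlog2FC\tpvalue\tFDR",
                           "A\t1\t0.1\t0.2", "B\t1\t0.1\t0.2",
                           "C\t1\t0.1\tNA"))
  expect_error(read_de_table(bad), "line 4", class = "oasig_parse_error")
})

test_that("de_table enforces value ranges", {
  expect_error(de_table("A", Inf, 0.5, 0.5), class = "oasig_validation_error")
  expect_error(de_table("A", 1, 0, 0.5), class = "oasig_validation_error")
  expect_error(de_table("A", 1, 0.5, 1.2), class = "oasig_validation_error")
  expect_silent(de_table("A", 1, 1, 0))
})

test_that("significant_sets applies inclusive fold and FDR thresholds", {
  sets <- significant_sets(tiny_de_table(), 1.5, 0.05)
  expect_setequal(sets$up, "A")
  expect_setequal(sets$down, c("C", "E"))
  expect_length(intersect(sets$up, sets$down), 0)

  empty <- de_table(character(), numeric(), numeric(), numeric())
  expect_equal(significant_sets(empty), list(up = character(), down = character()))

  # fold_threshold = 1: every FDR-passing gene with nonzero log2fc classified
  tab <- de_table(c("A", "B", "C"), c(0.1, -0.1, 0), rep(0.5, 3), rep(0.01, 3))
  s1 <- significant_sets(tab, fold_threshold = 1)
  expect_setequal(s1$up, c("A", "C"))  # log2fc = 0 passes >= 0 inclusively
  expect_setequal(s1$down, c("B", "C"))
  expect_error(significant_sets(tab, fold_threshold = 0.5),
               class = "oasig_validation_error")
})

test_that("significant_sets is monotone in its thresholds", {
  set.seed(42)
  for (i in 1:10) {
    tab <- de_table(sprintf("G%03d", 1:50), rnorm(50, sd = 2),
                    runif(50, 1e-6, 1), runif(50))
    loose <- significant_sets(tab, 1.2, 0.2)
    tight <- significant_sets(tab, 2.0, 0.05)
    expect_true(all(tight$up %in% loose$up))
    expect_true(all(tight$down %in% loose$down))
  }
})

test_that("DE table and profile matrix round-trip through disk", {
  tab <- tiny_de_table()
  path <- tempfile(fileext = ".tsv")
  write_de_table(tab, path)
  back <- read_de_table(path, dataset_id = "tiny", species = "Mus musculus")
  expect_equal(as.data.frame(back), as.data.frame(tab))

  set.seed(7)
  profs <- list(
    fold_change_profile("DS1", random_profile(20), "Homo sapiens", "a"),
    fold_change_profile("DS2", random_profile(15), "Homo sapiens", "b"))
  meta <- data.frame(dataset_id = c("DS1", "DS2"),
                     species = "Homo sapiens", label = c("a", "b"))
  comp <- compendium(profs, meta)
  mpath <- tempfile(fileext = ".tsv"); dpath <- tempfile(fileext = ".tsv")
  write_profile_matrix(comp, mpath, dpath)
  back <- read_profile_matrix(mpath, dpath)
  expect_equal(length(back), 2L)
  for (id in c("DS1", "DS2")) {
    a <- comp$profiles[[id]]$values; b <- back$profiles[[id]]$values
    expect_equal(b[sort(names(b))], a[sort(names(a))])
  }
  expect_equal(back$metadata, comp$metadata)
})

test_that("compendium validates ids and metadata coverage", {
  p <- fold_change_profile("DS1", c(A = 1))
  expect_error(compendium(list(p, p), data.frame(dataset_id = "DS1",
                                                 species = "x", label = "y")),
               class = "oasig_validation_error")
  expect_error(compendium(list(p), data.frame(dataset_id = "DS9",
                                              species = "x", label = "y")),
               "without metadata", class = "oasig_validation_error")
})

test_that("GMT files parse, reject ragged lines, and round-trip", {
  path <- write_lines_tmp(c("miR-199a-5p\tpredicted targets\tFZD6\tECE1",
                            "miR-140\tdesc\tADAMTS5"), ext = ".gmt")
  sets <- read_gmt(path)
  expect_named(sets, c("miR-199a-5p", "miR-140"))
  expect_setequal(sets[["miR-199a-5p"]]$genes, c("FZD6", "ECE1"))

  out <- tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out), sets)

  ragged <- write_lines_tmp(c("ok\tdesc\tA", "bad\tdesc-only"), ext = ".gmt")
  expect_error(read_gmt(ragged), "line 2", class = "oasig_parse_error")
})

test_that("curated annotations validate labels and uniqueness", {
  path <- write_lines_tmp(c("gene\tlabel", "Matn2\tProtective",
                            "Htra1\tDetrimental", "Dkk1\tAmbiguous"))
  ann <- read_annotation(path)
  expect_equal(unname(ann["MATN2"]), "Protective")
  expect_equal(unname(ann["HTRA1"]), "Detrimental")

  bad <- write_lines_tmp(c("gene\tlabel", "Matn2\tprotectivee"))
  expect_error(read_annotation(bad), "protectivee",
               class = "oasig_validation_error")
  expect_error(curated_annotation(c("A", "a"), c("Protective", "Detrimental")),
               class = "oasig_validation_error")
})

test_that("ortholog maps are one-to-one; reader drops many-to-many pairs", {
  m <- ortholog_map(c("Matn2", "Sox9"), c("MATN2", "SOX9"))
  expect_equal(unname(m["MATN2"]), "MATN2")  # source upper-cased too
  expect_error(ortholog_map(c("A", "B"), c("X", "X")),
               class = "oasig_validation_error")
  expect_error(ortholog_map(c("A", "A"), c("X", "Y")),
               class = "oasig_validation_error")

  path <- write_lines_tmp(c("source\ttarget", "A\tX", "B\tY", "B\tZ", "C\tW"))
  expect_message(m2 <- read_ortholog_map(path), "2 many-to-many")
  expect_equal(attr(m2, "n_dropped"), 2L)
  expect_setequal(names(m2), c("A", "C"))
})

test_that("map_orthologs renames, drops, preserves values exactly", {
  p <- fold_change_profile("q", c(MATN2 = 1.234567890123, SOX9 = -2, FYN = 0.5))
  id_map <- ortholog_map(c("MATN2", "SOX9", "FYN"), c("MATN2", "SOX9", "FYN"))
  expect_message(same <- map_orthologs(p, id_map), "0 gene")
  expect_equal(same$values, p$values)

  partial <- ortholog_map(c("MATN2", "SOX9"), c("MATN2H", "SOX9H"))
  expect_message(out <- map_orthologs(p, partial), "1 gene")
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_identical(unname(out$values["MATN2H"]), 1.234567890123)

  disjoint <- ortholog_map("OTHER", "OTHERH")
  expect_error(suppressMessages(map_orthologs(p, disjoint)),
               "disjoint", class = "oasig_validation_error")

  tab <- tiny_de_table()
  tmap <- ortholog_map(c("A", "C"), c("AH", "CH"))
  expect_message(mt <- map_orthologs(tab, tmap))
  expect_equal(mt$gene, c("AH", "CH"))
  expect_equal(mt$log2fc, c(1.0, -0.7))
  expect_equal(attr(mt, "n_dropped"), 3L)
})

test_that("gene symbols match case-insensitively across species conventions", {
  tab <- de_table("Matn2", 2.98, 1e-6, 1e-4)
  ann <- curated_annotation("MATN2", "Protective")
  res <- directional_enrichment(tab$gene, c(tab$gene, "OTHER"),
                                curated_annotation(c("MATN2", "OTHER"),
                                                   c("Protective", "Detrimental")))
  expect_equal(res$table$a, 1L)
  expect_equal(names(ann), "MATN2")
})
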