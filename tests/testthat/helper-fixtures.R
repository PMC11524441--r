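# In-code fixtures: small DE tables, profiles and on-disk TSV/GMT files
# written to tempdir at test time.

tiny_de_table <- function() {
  # thresholds 1.5 / 0.05 classify: up = {A}, down = {C, E}
  de_table(gene = c("A", "B", "C", "D", "E"),
           log2fc = c(1.0, 0.5, -0.7, 2.0, -3.0),
           pvalue = c(1e-4, 1e-4, 1e-3, 2e-3, 1e-3),
           fdr = c(0.01, 0.01, 0.04, 0.06, 0.05),
           dataset_id = "tiny", species = "Mus musculus")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

de_tsv_lines <- function() c(
  "gene\tlog2FC\tpvalue\tFDR",
  "Matn2\t2.98\t4.74e-11\t1e-9",
  "Sox9\t1.36\t4.69e-05\t1e-3",
  "Fyn\t0.39\t0.012\t0.03")

random_profile <- function(n, prefix = "G", sd = 1) {
  setNames(rnorm(n, sd = sd), paste0(prefix, sprintf("%04d", seq_len(n))))
}
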