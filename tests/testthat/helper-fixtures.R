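# Small in-code fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(5, 0, 2, 1, 0, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m
}

toy_annotations <- function(samples = c("s1", "s2"),
                            groups = c("A", "B")) {
  data.frame(Sample = samples, Group = groups, stringsAsFactors = FALSE)
}

# balanced multi-group dataset with no signal, for contract tests
null_dataset <- function(n_groups = 3, n_per_group = 4, n_genes = 100,
                         seed = 42) {
  sim <- generate_counts(n_groups = n_groups, n_per_group = n_per_group,
                         n_genes = n_genes, n_markers_per_group = 0,
                         lfc = 0, dispersion = 0.1, seed = seed)
  sim$dataset
}

write_toy_tsv <- function(m, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "counts.tsv")
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(toy_annotations(colnames(m)),
                     sp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, samples = sp)
}
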