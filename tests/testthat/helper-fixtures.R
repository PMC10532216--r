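# Small shared fixtures, built in code.

extdata <- function(file) {
  system.file("extdata", file, package = "effectorscan", mustWork = TRUE)
}

two_group_design <- function(n_reps = 3, tissue = "whole", prefix = "s") {
  tibble::tibble(
    sample_id = c(paste0(prefix, "A", seq_len(n_reps)),
                  paste0(prefix, "B", seq_len(n_reps))),
    biotype = rep(c("A", "B"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2),
    tissue = tissue
  )
}

tiny_counts <- function(values, design) {
  m <- matrix(as.integer(values), ncol = nrow(design), byrow = TRUE)
  out <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(nrow(m))))
  for (j in seq_len(ncol(m))) out[[design$sample_id[j]]] <- m[, j]
  out
}

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
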