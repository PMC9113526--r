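# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

random_otu_table <- function(n_samples = 6, n_otus = 12, seed = 1,
                             max_count = 50, with_taxonomy = FALSE,
                             with_metadata = FALSE, min_total = 1) {
  set.seed(seed)
  repeat {
    counts <- matrix(rpois(n_samples * n_otus, lambda = max_count / 4),
                     nrow = n_samples,
                     dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                     sprintf("otu%03d", seq_len(n_otus))))
    if (all(rowSums(counts) >= min_total)) break
  }
  taxonomy <- NULL
  if (with_taxonomy) {
    phyla <- sample(c("Proteobacteria", "Firmicutes", "Bacteroidetes",
                      "Cyanobacteria"), n_otus, replace = TRUE)
    genus <- sample(c("Enterococcus", "Lactobacillus", "Chloroplast",
                      "Sphingomonas"), n_otus, replace = TRUE)
    taxonomy <- stats::setNames(
      paste0("k__Bacteria;p__", phyla, ";g__", genus), colnames(counts))
  }
  metadata <- NULL
  if (with_metadata) {
    metadata <- data.frame(
      sample_id = rownames(counts),
      population = rep_len(c("A", "B"), n_samples),
      variety = "v1", location = "l1", stringsAsFactors = FALSE)
  }
  otu_table(counts, metadata = metadata, taxonomy = taxonomy)
}

# minimal neutral_fit skeleton for classification tests
manual_fit <- function(per_otu, n_hosts, N = 1000, m = 0.1, d = 1) {
  structure(list(m = m, N = N, Nm = N * m, d = d, r_squared = NA_real_,
                 n_hosts = n_hosts, n_otus_fit = nrow(per_otu),
                 alpha = 0.05, per_otu = per_otu),
            class = "neutral_fit")
}
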