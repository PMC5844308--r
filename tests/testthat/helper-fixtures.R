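# Shared fixture builders. Everything is generated in code; file-based
# fixtures are written to tempfiles at test time.

toy_genome <- function(lengths = c(c1 = 100000, c2 = 50000), gaps = NULL) {
  suppressMessages(genome_model(
    tibble::tibble(chrom = names(lengths), length = unname(lengths)), gaps))
}

# Two genes on c1: gene a with two exons (intron 1500-2500), gene b with
# three exons; c2 is gene-free.
toy_annotation <- function(genome = toy_genome()) {
  suppressMessages(annotation_set(
    tibble::tibble(gene_id = c("a", "b"), chrom = "c1",
                   start = c(1000, 20000), end = c(3000, 30000),
                   strand = c("+", "-")),
    tibble::tibble(gene_id = c("a", "a", "b", "b", "b"), chrom = "c1",
                   start = c(1000, 2500, 20000, 24000, 29000),
                   end = c(1500, 3000, 21000, 25000, 30000)),
    genome))
}

# Random interval set on a toy genome for oracle comparisons.
random_intervals <- function(n, lengths, max_len = 500) {
  chrom <- sample(names(lengths), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (unname(lengths[chrom]) - len))
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

# Per-bp category labeling oracle: labels every base of a chromosome.
perbp_labels <- function(partition, chrom, len) {
  lab <- rep("intergenic", len)
  iv <- partition$intervals
  for (cat in c("intronic", "exonic")) {
    d <- iv[iv$chrom == chrom & iv$category == cat, ]
    for (i in seq_len(nrow(d))) lab[(d$start[i] + 1):d$end[i]] <- cat
  }
  lab
}

# Brute-force element category from per-bp labels (exon > intron > intergenic).
perbp_category <- function(lab, start, end) {
  seen <- unique(lab[(start + 1):end])
  if ("exonic" %in% seen) "exonic"
  else if ("intronic" %in% seen) "intronic"
  else "intergenic"
}

expect_tsv_roundtrip <- function(write_fn, read_fn, obj, ...) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fn(obj, path)
  suppressMessages(read_fn(path, ...))
}
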