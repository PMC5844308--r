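# Sequence divergence (uncorrected p-distance), group comparisons, and
# copy-number arithmetic.

#' Read an aligned FASTA into an alignment block
#'
#' All sequences must have equal (aligned) length; gaps are `-`.
#'
#' @param path Aligned FASTA file.
#' @return Character matrix (rows = sequences, named by FASTA ids,
#'   columns = alignment positions), uppercase.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1) {
    abort("alignment rows differ in length")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- names(seqs)
  mat
}

#' Uncorrected p-distance between two aligned rows
#'
#' Proportion of differing sites among comparable sites; any site with a
#' gap (`-`) or `N` in either row is excluded (pairwise deletion). With
#' `pairwise_deletion = FALSE`, columns to exclude must be removed from
#' the block beforehand (complete deletion) - the rows are then compared
#' over all sites.
#'
#' @param a,b Character vectors (or single strings) of equal aligned
#'   length, over A, C, G, T, -, N.
#' @return Fraction in \[0,1\], or `NA` when no site is comparable.
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1 && nchar(a[1]) > 1) a <- strsplit(a, "")[[1]]
  if (length(b) == 1 && nchar(b[1]) > 1) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) abort("rows differ in length")
  a <- toupper(a); b <- toupper(b)
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Mean pairwise divergence of an alignment block
#'
#' Mean uncorrected p-distance over all unordered row pairs, in percent.
#' Pairs with no comparable sites are skipped (with a message); if every
#' pair is undefined, an error is raised.
#'
#' @param block Character matrix from [read_alignment()] (or
#'   [mutate_block()]), >= 2 rows.
#' @return Percent divergence (numeric scalar).
#' @export
mean_pairwise_divergence <- function(block) {
  if (is.data.frame(block)) block <- as.matrix(block)
  if (nrow(block) < 2) abort("need at least two rows")
  m <- nrow(block)
  ds <- numeric(0)
  skipped <- 0L
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      d <- p_distance(block[i, ], block[j, ])
      if (is.na(d)) skipped <- skipped + 1L else ds <- c(ds, d)
    }
  }
  if (length(ds) == 0) abort("all pairs have no comparable sites")
  if (skipped > 0) inform(sprintf("skipped %d pair(s) with no comparable sites", skipped))
  100 * mean(ds)
}

#' Unpaired two-sample t test on per-family element counts
#'
#' Equal-variance (Student's) two-sample t test comparing, e.g., dispersed
#' element counts between transposon-origin and non-transposon families.
#' Welch's unequal-variance form is available with `var_equal = FALSE`.
#'
#' @param counts_a,counts_b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A `group_comparison` object: tibble with one row per group
#'   (`n`, `mean`, `sd`) plus attributes `statistic`, `df`, `p_value`;
#'   also accessible via [glance()].
#' @export
group_t_test <- function(counts_a, counts_b, var_equal = TRUE) {
  if (length(counts_a) < 2 || length(counts_b) < 2) {
    abort("each group needs at least two observations")
  }
  ht <- stats::t.test(counts_a, counts_b, var.equal = var_equal)
  out <- tibble(
    group = c("a", "b"),
    n = c(length(counts_a), length(counts_b)),
    mean = c(mean(counts_a), mean(counts_b)),
    sd = c(sd(counts_a), sd(counts_b))
  )
  attr(out, "statistic") <- unname(ht$statistic)
  attr(out, "df") <- unname(ht$parameter)
  attr(out, "p_value") <- ht$p.value
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.4f, df = %g, p = %.4f\n",
              attr(x, "statistic"), attr(x, "df"), attr(x, "p_value")))
  print(as_tibble(x))
  invisible(x)
}

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(statistic = attr(x, "statistic"), df = attr(x, "df"),
         p_value = attr(x, "p_value"),
         mean_a = x$mean[1], sd_a = x$sd[1],
         mean_b = x$mean[2], sd_b = x$sd[2])
}

#' Copy number from genomic fraction
#'
#' `copies = fraction * genome_size / monomer_length`: the number of
#' full-size repeat units accounting for the given fraction of the
#' genome. Full precision is returned; `signif_digits` (default 2,
#' matching how such estimates are usually printed) controls the rounded
#' `copies` column of the report.
#'
#' @param genome_fraction Fraction of the genome occupied (0..1).
#' @param genome_size_bp Genome size in bp.
#' @param monomer_length_bp Repeat unit length in bp (> 0).
#' @param signif_digits Significant figures for the rounded value.
#' @return Tibble with `copies_exact` and `copies` (rounded).
#' @export
copy_number <- function(genome_fraction, genome_size_bp, monomer_length_bp,
                        signif_digits = 2) {
  if (any(monomer_length_bp <= 0)) abort("monomer length must be positive")
  if (any(genome_fraction < 0 | genome_fraction > 1)) {
    abort("genome_fraction must be in [0, 1]")
  }
  if (any(genome_size_bp <= 0)) abort("genome size must be positive")
  exact <- genome_fraction * genome_size_bp / monomer_length_bp
  tibble(copies_exact = exact, copies = signif(exact, signif_digits))
}
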