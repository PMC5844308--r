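# Exon / intron / intergenic partition of the genome and element
# categorization. Precedence is exon > intron > intergenic: exonic space is
# the union of all exons; intronic space is the union of all introns minus
# exonic space (an exon of one gene overlapping an intron of another wins);
# intergenic space is the remainder. Assembly gaps inherit the category of
# their surroundings here — gaps constrain only null-model placement.

#' Derive introns for one gene
#'
#' Introns are the gaps between consecutive merged exons, within the gene
#' span. Single-exon (or exonless) genes have none.
#'
#' @param exons Data frame of the gene's exon intervals (`start`, `end`),
#'   already merged and sorted (as stored in an [annotation_set()]).
#' @return Tibble of intron intervals (`start`, `end`), possibly empty.
#' @export
derive_introns <- function(exons) {
  exons <- as_tibble(exons)
  if (nrow(exons) < 2) return(tibble(start = numeric(), end = numeric()))
  s <- exons$end[-nrow(exons)]
  e <- exons$start[-1]
  keep <- s < e
  tibble(start = s[keep], end = e[keep])
}

#' Partition a genome into exonic, intronic and intergenic space
#'
#' @param genome A [genome_model()].
#' @param annotation An [annotation_set()] on the same genome.
#' @return An object of class `genome_partition`: list with `intervals`
#'   (tibble `chrom`, `start`, `end`, `category`; sorted, disjoint,
#'   covering every chromosome exactly), `totals` (bp per category) and
#'   the input `genome`.
#' @export
build_partition <- function(genome, annotation) {
  lens <- chrom_lengths(genome)
  genes <- annotation$genes
  if (nrow(genes) > 0) {
    if (any(!genes$chrom %in% names(lens))) {
      abort("annotation contains chromosomes absent from the genome model")
    }
    if (any(genes$end > lens[genes$chrom])) {
      bad <- which(genes$end > lens[genes$chrom])[1]
      abort(sprintf("gene %s extends past chromosome end", genes$gene_id[bad]))
    }
  }
  exonic <- iv_merge(annotation$exons[, c("chrom", "start", "end")])
  # gene-body space is the union of gene spans: intronic = gene body minus
  # exonic (an exon of one gene overlapping an intron of another wins),
  # intergenic = the complement of the gene body. Nested or overlapping
  # genes therefore never create intergenic islands.
  genic <- iv_merge(genes[, c("chrom", "start", "end")])
  intronic <- iv_setdiff(genic, exonic, lens)
  intergenic <- iv_complement(genic, lens)

  intervals <- bind_rows(
    mutate(exonic, category = "exonic"),
    mutate(intronic, category = "intronic"),
    mutate(intergenic, category = "intergenic")
  )
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  totals <- intervals %>%
    group_by(.data$category) %>%
    summarise(bp = sum(.data$end - .data$start), .groups = "drop")
  for (cat in c("exonic", "intronic", "intergenic")) {
    if (!cat %in% totals$category) {
      totals <- bind_rows(totals, tibble(category = cat, bp = 0))
    }
  }
  structure(list(intervals = as_tibble(intervals), totals = totals,
                 genome = genome),
            class = "genome_partition")
}

#' @export
print.genome_partition <- function(x, ...) {
  t <- setNames(x$totals$bp, x$totals$category)
  cat(sprintf("<genome_partition> exonic %s bp, intronic %s bp, intergenic %s bp over %d chromosome(s)\n",
              format(t[["exonic"]], big.mark = ","),
              format(t[["intronic"]], big.mark = ","),
              format(t[["intergenic"]], big.mark = ","),
              nrow(x$genome$chromosomes)))
  invisible(x)
}

#' @method tidy genome_partition
#' @export
tidy.genome_partition <- function(x, ...) {
  x$intervals %>%
    group_by(.data$chrom, .data$category) %>%
    summarise(bp = sum(.data$end - .data$start), .groups = "drop")
}

# Category intervals of a partition on the global axis, sorted & disjoint.
partition_global <- function(partition, category) {
  lens <- chrom_lengths(partition$genome)
  off <- global_offsets(lens)$offsets
  d <- partition$intervals[partition$intervals$category == category, , drop = FALSE]
  gs <- unname(off[d$chrom]) + d$start
  ge <- unname(off[d$chrom]) + d$end
  o <- order(gs)
  list(start = gs[o], end = ge[o])
}

#' Categorize elements against a genome partition
#'
#' Applies exon > intron > intergenic precedence to whole elements: an
#' element overlapping at least one exonic bp is `exonic`; otherwise one
#' overlapping at least one intronic bp is `intronic`; otherwise it is
#' `intergenic`.
#'
#' @param elements Element tibble.
#' @param partition A [build_partition()] result.
#' @return `elements` with a `category` column appended.
#' @export
categorize_elements <- function(elements, partition) {
  elements <- check_elements(elements)
  lens <- chrom_lengths(partition$genome)
  if (nrow(elements) > 0 && any(!elements$chrom %in% names(lens))) {
    bad <- setdiff(unique(elements$chrom), names(lens))
    abort(sprintf("element(s) on unknown chromosome: %s",
                  paste(bad, collapse = ", ")))
  }
  off <- global_offsets(lens)$offsets
  gs <- unname(off[elements$chrom]) + elements$start
  ge <- unname(off[elements$chrom]) + elements$end
  ex <- partition_global(partition, "exonic")
  intr <- partition_global(partition, "intronic")
  in_ex <- global_overlaps_any(gs, ge, ex$start, ex$end)
  in_intr <- global_overlaps_any(gs, ge, intr$start, intr$end)
  elements$category <- ifelse(in_ex, "exonic",
                              ifelse(in_intr, "intronic", "intergenic"))
  elements
}

#' Summarize element positions per family and category
#'
#' Per-family and grand-total element and base-pair counts in exonic,
#' intronic and intergenic space, with percent-in-introns computed both by
#' base pairs and by element count. Element base pairs are assigned wholly
#' to the element's (single, precedence-resolved) category.
#'
#' @param elements Element tibble; categorized with [categorize_elements()]
#'   first if `partition` is supplied.
#' @param partition Optional [build_partition()] result; required when
#'   `elements` has no `category` column.
#' @return An object of class `partition_summary`: a tibble with one row
#'   per family plus an `All` grand-total row, columns
#'   `intergenic_bp/_n`, `intronic_bp/_n`, `exonic_bp/_n`, `total_bp/_n`,
#'   `pct_introns_bp`, `pct_introns_n`.
#' @export
summarize_partition <- function(elements, partition = NULL) {
  elements <- check_elements(elements)
  if (!"category" %in% names(elements)) {
    if (is.null(partition)) {
      abort("supply `partition` or pre-categorized elements")
    }
    elements <- categorize_elements(elements, partition)
  }
  counts <- elements %>%
    mutate(bp = .data$end - .data$start) %>%
    group_by(.data$family, .data$category) %>%
    summarise(n = n(), bp = sum(.data$bp), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "category",
                       values_from = c("bp", "n"),
                       values_fill = 0)
  for (col in c("bp_intergenic", "bp_intronic", "bp_exonic",
                "n_intergenic", "n_intronic", "n_exonic")) {
    if (!col %in% names(counts)) counts[[col]] <- 0
  }
  counts <- counts %>%
    rename(intergenic_bp = "bp_intergenic", intronic_bp = "bp_intronic",
           exonic_bp = "bp_exonic", intergenic_n = "n_intergenic",
           intronic_n = "n_intronic", exonic_n = "n_exonic")
  summarize_position_counts(counts)
}

#' Summary statistics from per-family category counts
#'
#' Computes totals and percent-in-introns (by bp and by element count) from
#' a table of per-family base-pair and element counts per category, and
#' appends an `All` grand-total row. This is the arithmetic layer of
#' [summarize_partition()], exposed so published per-family count tables
#' can be summarized directly.
#'
#' @param counts Tibble with columns `family`, `intergenic_bp`,
#'   `intergenic_n`, `intronic_bp`, `intronic_n`, `exonic_bp`, `exonic_n`.
#' @return A `partition_summary` tibble (see [summarize_partition()]).
#' @export
summarize_position_counts <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("family", "intergenic_bp", "intergenic_n", "intronic_bp",
            "intronic_n", "exonic_bp", "exonic_n")
  if (!all(need %in% names(counts))) {
    abort(paste("`counts` needs columns:", paste(need, collapse = ", ")))
  }
  counts <- counts[, need]
  all_row <- counts %>%
    summarise(family = "All",
              across(c("intergenic_bp", "intergenic_n", "intronic_bp",
                       "intronic_n", "exonic_bp", "exonic_n"), sum))
  out <- bind_rows(counts, all_row) %>%
    mutate(
      total_bp = .data$intergenic_bp + .data$intronic_bp + .data$exonic_bp,
      total_n = .data$intergenic_n + .data$intronic_n + .data$exonic_n,
      pct_introns_bp = ifelse(.data$total_bp > 0,
                              100 * .data$intronic_bp / .data$total_bp, NA_real_),
      pct_introns_n = ifelse(.data$total_n > 0,
                             100 * .data$intronic_n / .data$total_n, NA_real_)
    )
  class(out) <- c("partition_summary", class(out))
  out
}
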