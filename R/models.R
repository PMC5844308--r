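#' Construct a genome model
#'
#' A genome model holds the chromosome size table, assembly-gap intervals
#' and the names of excluded (unplaced/unlocalized) scaffolds. It defines
#' the universe over which elements are categorized and over which the
#' permutation nulls place intervals. Gaps are merged and sorted on
#' construction; gap records on excluded or unknown sequences are dropped
#' with a warning.
#'
#' @param chromosomes Data frame with columns `chrom` and `length` (bp),
#'   in the order chromosomes should be reported.
#' @param gaps Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), or `NULL` for a gapless genome.
#' @param excluded Character vector of scaffold names excluded from all
#'   analyses (e.g. unplaced scaffolds).
#' @return An object of class `genome_model`: a list with tibbles
#'   `chromosomes` and `gaps` plus the `excluded` name set.
#' @examples
#' gm <- genome_model(data.frame(chrom = "chr1", length = 1000))
#' gm
#' @export
genome_model <- function(chromosomes, gaps = NULL, excluded = character()) {
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns chrom, length")
  }
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (any(!is.finite(chromosomes$length)) ||
      any(chromosomes$length <= 0) ||
      any(chromosomes$length != floor(chromosomes$length))) {
    bad <- which(!is.finite(chromosomes$length) | chromosomes$length <= 0 |
                   chromosomes$length != floor(chromosomes$length))[1]
    abort(sprintf("chromosome length must be a positive integer (row %d: %s)",
                  bad, chromosomes$chrom[bad]))
  }
  if (anyDuplicated(chromosomes$chrom)) abort("duplicate chromosome names")
  chromosomes <- chromosomes[!chromosomes$chrom %in% excluded, , drop = FALSE]

  if (is.null(gaps)) {
    gaps <- tibble(chrom = character(), start = numeric(), end = numeric())
  }
  gaps <- as_tibble(gaps)[, c("chrom", "start", "end")]
  gaps$chrom <- as.character(gaps$chrom)
  unknown <- !gaps$chrom %in% chromosomes$chrom
  if (any(unknown)) {
    warn(sprintf("dropping %d gap record(s) on excluded or unknown sequences",
                 sum(unknown)))
    gaps <- gaps[!unknown, , drop = FALSE]
  }
  iv_check(gaps, "gaps")
  lens <- setNames(chromosomes$length, chromosomes$chrom)
  if (nrow(gaps) > 0) {
    out_of_bounds <- gaps$start < 0 | gaps$end > lens[gaps$chrom]
    if (any(out_of_bounds)) {
      bad <- which(out_of_bounds)[1]
      abort(sprintf("gap outside chromosome bounds: %s:%d-%d",
                    gaps$chrom[bad], gaps$start[bad], gaps$end[bad]))
    }
  }
  gaps <- iv_merge(gaps)
  structure(
    list(chromosomes = chromosomes, gaps = gaps,
         excluded = unique(as.character(excluded))),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %s bp; %d gap(s) (%s bp); %d excluded scaffold(s)\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","),
              nrow(x$gaps),
              format(iv_total_bp(x$gaps), big.mark = ","),
              length(x$excluded)))
  invisible(x)
}

#' @method tidy genome_model
#' @export
tidy.genome_model <- function(x, ...) {
  gap_bp <- rep(0, nrow(x$chromosomes))
  if (nrow(x$gaps) > 0) {
    g <- x$gaps %>% group_by(.data$chrom) %>%
      summarise(gap_bp = sum(.data$end - .data$start), .groups = "drop")
    gap_bp <- g$gap_bp[match(x$chromosomes$chrom, g$chrom)]
    gap_bp[is.na(gap_bp)] <- 0
  }
  mutate(x$chromosomes, gap_bp = gap_bp)
}

chrom_lengths <- function(genome) {
  setNames(genome$chromosomes$length, genome$chromosomes$chrom)
}

#' Construct an annotation set
#'
#' Pairs gene spans with their (merged) exon structure. Exons from multiple
#' transcripts of one gene are unioned; genes with no exon records are
#' treated as single-exon genes (their whole span is exonic), which avoids
#' manufacturing spurious whole-gene introns. Genes on sequences absent
#' from the genome model (e.g. excluded scaffolds) are dropped.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (0-based half-open coordinates).
#' @param exons Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   or `NULL` if no exon structure is available.
#' @param genome A [genome_model()] used to validate and filter sequences,
#'   or `NULL` to accept all.
#' @return An object of class `annotation_set` with tibbles `genes`
#'   (sorted by chromosome and start) and `exons` (merged per gene).
#' @export
annotation_set <- function(genes, exons = NULL, genome = NULL) {
  genes <- as_tibble(genes)
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(genes))) {
    abort("`genes` needs columns gene_id, chrom, start, end")
  }
  if (!"strand" %in% names(genes)) genes$strand <- "*"
  genes$chrom <- as.character(genes$chrom)
  genes$gene_id <- as.character(genes$gene_id)
  iv_check(genes, "genes")
  if (!is.null(genome)) {
    keep <- genes$chrom %in% genome$chromosomes$chrom
    if (any(!keep)) {
      inform(sprintf("dropping %d gene(s) on excluded or unknown sequences",
                     sum(!keep)))
      genes <- genes[keep, , drop = FALSE]
    }
    lens <- chrom_lengths(genome)
    if (nrow(genes) > 0 && any(genes$end > lens[genes$chrom] | genes$start < 0)) {
      bad <- which(genes$end > lens[genes$chrom] | genes$start < 0)[1]
      abort(sprintf("gene %s extends past chromosome bounds", genes$gene_id[bad]))
    }
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in `genes`")

  if (is.null(exons) || nrow(exons) == 0) {
    exons <- genes[0, c("gene_id", "chrom", "start", "end")]
  } else {
    exons <- as_tibble(exons)[, c("gene_id", "chrom", "start", "end")]
    exons$chrom <- as.character(exons$chrom)
    exons$gene_id <- as.character(exons$gene_id)
    iv_check(exons, "exons")
    orphan <- !exons$gene_id %in% genes$gene_id
    if (any(orphan)) {
      abort(sprintf("exon(s) with no resolvable gene parent: %s",
                    paste(unique(exons$gene_id[orphan])[1:min(3, sum(orphan))],
                          collapse = ", ")))
    }
  }
  # merge exons per gene; exonless genes become single-exon (full span)
  if (nrow(exons) > 0) {
    m <- merge_grouped(exons$gene_id, exons$start, exons$end)
    chrom_of <- setNames(genes$chrom, genes$gene_id)
    exons <- tibble(gene_id = m$group, chrom = unname(chrom_of[m$group]),
                    start = m$start, end = m$end)
  }
  exonless <- setdiff(genes$gene_id, unique(exons$gene_id))
  if (length(exonless) > 0) {
    add <- genes[match(exonless, genes$gene_id), c("gene_id", "chrom", "start", "end")]
    exons <- bind_rows(exons, add)
  }
  # exons must lie within their gene span
  gs <- genes$start[match(exons$gene_id, genes$gene_id)]
  ge <- genes$end[match(exons$gene_id, genes$gene_id)]
  if (any(exons$start < gs | exons$end > ge)) {
    bad <- which(exons$start < gs | exons$end > ge)[1]
    abort(sprintf("exon outside gene span for gene %s", exons$gene_id[bad]))
  }
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  exons <- exons[order(exons$chrom, exons$start, exons$end), , drop = FALSE]
  structure(list(genes = genes, exons = exons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d gene(s) on %d chromosome(s); %d merged exon interval(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom)), nrow(x$exons)))
  invisible(x)
}

#' @method tidy annotation_set
#' @export
tidy.annotation_set <- function(x, ...) {
  ex <- x$exons %>% count(.data$gene_id, name = "n_exons")
  x$genes %>% left_join(ex, by = "gene_id")
}

#' Per-chromosome gene counts
#'
#' @param annotation An [annotation_set()].
#' @param genome Optional [genome_model()]; when given, chromosomes with no
#'   genes are reported with a zero count and ordering follows the genome.
#' @return Tibble with columns `chrom`, `n_genes`.
#' @export
gene_counts <- function(annotation, genome = NULL) {
  tab <- annotation$genes %>% count(.data$chrom, name = "n_genes")
  if (!is.null(genome)) {
    tab <- tibble(chrom = genome$chromosomes$chrom) %>%
      left_join(tab, by = "chrom") %>%
      mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes))
  }
  tab
}

# Validate an element tibble (family, chrom, start, end, strand, structure...)
check_elements <- function(elements) {
  elements <- as_tibble(elements)
  need <- c("family", "chrom", "start", "end")
  if (!all(need %in% names(elements))) {
    abort("element table needs columns family, chrom, start, end")
  }
  if (!"strand" %in% names(elements)) elements$strand <- "+"
  if (!"structure" %in% names(elements)) elements$structure <- "single"
  if (!"n_units" %in% names(elements)) elements$n_units <- 1L
  if (!"spacer" %in% names(elements)) elements$spacer <- NA_real_
  iv_check(elements, "elements")
  elements
}
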