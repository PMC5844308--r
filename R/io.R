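# File readers/writers. All coordinates are normalized at this boundary to
# the internal 0-based half-open convention: BED is native; GFF3 (1-based,
# closed) is shifted on read and write.

#' Read a genome model from a chromosome-sizes table and a gaps BED
#'
#' @param chrom_sizes_path Two-column TSV (`name<TAB>length`), no header.
#' @param gaps_path Optional BED3+ file of assembly gaps; `NULL` for none.
#' @param excluded Character vector of sequence names (e.g. unplaced or
#'   unlocalized scaffolds) to drop from every analysis.
#' @return A [genome_model()].
#' @export
read_genome <- function(chrom_sizes_path, gaps_path = NULL,
                        excluded = character()) {
  sizes <- readr::read_tsv(chrom_sizes_path,
                           col_names = c("chrom", "length"),
                           col_types = "cc", progress = FALSE)
  len <- suppressWarnings(as.numeric(sizes$length))
  bad <- is.na(len) | len <= 0 | len != floor(len)
  if (any(bad)) {
    abort(sprintf("malformed chromosome length at line %d of %s: '%s'",
                  which(bad)[1], chrom_sizes_path, sizes$length[which(bad)[1]]))
  }
  sizes$length <- len
  gaps <- NULL
  if (!is.null(gaps_path)) {
    gaps <- read_bed(gaps_path)
    inform(sprintf("read_genome: %d gap record(s) from %s", nrow(gaps), gaps_path))
  }
  inform(sprintf("read_genome: %d chromosome record(s) from %s",
                 nrow(sizes), chrom_sizes_path))
  genome_model(sizes, gaps, excluded = excluded)
}

# Minimal BED reader used for gaps and elements (BED3/BED6); rtracklayer
# handles the dialect, we flatten to a tibble in internal coordinates.
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr))
  )
  out$strand[out$strand == "*"] <- "+"
  out
}

#' Read a gene annotation (GFF3) into an annotation set
#'
#' Gene features provide spans; exon features are attached to their parent
#' gene (through the Parent chain: exon -> mRNA -> gene, or exon -> gene).
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Genes on sequences excluded by the genome model
#' are dropped.
#'
#' @param gff3_path Path to a GFF3 file with `gene` and `exon` features.
#' @param genome A [genome_model()] to validate against, or `NULL`.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(gff3_path, genome = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "GFF3")
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  genes <- tibble(
    gene_id = id[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene]
  )
  if (any(is.na(genes$gene_id))) {
    genes$gene_id[is.na(genes$gene_id)] <-
      paste0("gene", which(is.na(genes$gene_id)))
  }
  # resolve exon parents through one level of transcript if needed
  tx_parent <- setNames(parent[!is.na(id)], id[!is.na(id)])
  is_exon <- type == "exon"
  if (any(is_exon)) {
    ep <- parent[is_exon]
    if (any(is.na(ep))) {
      abort(sprintf("exon feature(s) with no Parent attribute in %s", gff3_path))
    }
    resolved <- ifelse(ep %in% genes$gene_id, ep, unname(tx_parent[ep]))
    if (any(is.na(resolved) | !resolved %in% genes$gene_id)) {
      bad <- unique(ep[is.na(resolved) | !resolved %in% genes$gene_id])
      abort(sprintf("exon(s) with no resolvable gene parent: %s",
                    paste(head(bad, 3), collapse = ", ")))
    }
    exons <- tibble(
      gene_id = resolved,
      chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
      start = GenomicRanges::start(gr)[is_exon] - 1,
      end = GenomicRanges::end(gr)[is_exon]
    )
  } else {
    exons <- NULL
  }
  inform(sprintf("read_annotation: %d gene(s), %d exon record(s) from %s",
                 nrow(genes), if (is.null(exons)) 0L else nrow(exons), gff3_path))
  annotation_set(genes, exons, genome = genome)
}

#' Write an annotation set to GFF3
#'
#' @param annotation An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  lines <- c("##gff-version 3")
  gene_lines <- sprintf("%s\tdisperscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$chrom, g$start + 1, g$end,
                        ifelse(g$strand %in% c("+", "-"), g$strand, "."),
                        g$gene_id)
  ex <- e %>% group_by(.data$gene_id) %>% mutate(k = row_number()) %>% ungroup()
  strand_of <- setNames(g$strand, g$gene_id)
  exon_lines <- sprintf("%s\tdisperscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                        ex$chrom, ex$start + 1, ex$end,
                        ifelse(strand_of[ex$gene_id] %in% c("+", "-"),
                               strand_of[ex$gene_id], "."),
                        ex$gene_id, ex$k, ex$gene_id)
  writeLines(c(lines, gene_lines, exon_lines), path)
  invisible(path)
}

#' Read a 12-column similarity-search hit table
#'
#' Expects the standard tabular hit format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore). The query name is taken as the repeat family.
#' Subject coordinates are normalized to forward-strand 0-based half-open
#' intervals; strand is inferred from the sstart/send order. Query coverage
#' is alignment length divided by the family's consensus (monomer) length,
#' capped at 1.
#'
#' @param table_path Path to the tab-separated hit table (no header).
#' @param consensus_lengths Named numeric vector (or two-column data frame
#'   `family`,`length`) of per-family consensus lengths in bp.
#' @return Tibble of hits: `family`, `chrom`, `start`, `end`, `strand`,
#'   `identity` and `coverage` as fractions in \[0,1\], plus `align_length`.
#' @export
read_hits <- function(table_path, consensus_lengths) {
  if (is.data.frame(consensus_lengths)) {
    consensus_lengths <- setNames(consensus_lengths$length,
                                  consensus_lengths$family)
  }
  cols <- c("family", "chrom", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  h <- readr::read_tsv(table_path, col_names = cols,
                       col_types = "ccdddddddddd", progress = FALSE)
  unknown <- !h$family %in% names(consensus_lengths)
  if (any(unknown)) {
    abort(sprintf("unknown family in consensus length map: %s",
                  paste(unique(h$family[unknown]), collapse = ", ")))
  }
  if (any(h$sstart == h$send)) {
    abort(sprintf("hit with sstart == send at line %d", which(h$sstart == h$send)[1]))
  }
  strand <- ifelse(h$sstart < h$send, "+", "-")
  lo <- pmin(h$sstart, h$send)
  hi <- pmax(h$sstart, h$send)
  out <- tibble(
    family = h$family, chrom = h$chrom,
    start = lo - 1, end = hi,
    strand = strand,
    identity = h$pident / 100,
    coverage = pmin(h$length / unname(consensus_lengths[h$family]), 1),
    align_length = h$length
  )
  inform(sprintf("read_hits: %d hit record(s) from %s", nrow(out), table_path))
  out
}

#' Write a hit table in the 12-column tabular format
#'
#' Inverse of [read_hits()] for round-tripping generated hits. Fields not
#' represented internally (mismatches, gap opens, query coordinates,
#' e-value, bitscore) are emitted as consistent placeholders.
#'
#' @param hits Hit tibble as returned by [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  fwd <- hits$strand == "+"
  sstart <- ifelse(fwd, hits$start + 1, hits$end)
  send <- ifelse(fwd, hits$end, hits$start + 1)
  al <- if ("align_length" %in% names(hits)) hits$align_length else hits$end - hits$start
  lines <- sprintf("%s\t%s\t%.3f\t%d\t0\t0\t1\t%d\t%d\t%d\t0.0\t100",
                   hits$family, hits$chrom, hits$identity * 100,
                   as.integer(al), as.integer(al),
                   as.integer(sstart), as.integer(send))
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat elements from BED6 (+ optional structure sidecar)
#'
#' The BED name field carries the family. If `<path>.structure.tsv` exists
#' (as written by [write_elements_bed()]), multimer structure annotations
#' are joined back on; otherwise all elements are `single`.
#'
#' @param path BED6 file of elements.
#' @param genome Optional [genome_model()]; elements on excluded or unknown
#'   sequences are dropped with a warning.
#' @return Element tibble (`family`, `chrom`, `start`, `end`, `strand`,
#'   `structure`, `n_units`, `spacer`).
#' @export
read_elements_bed <- function(path, genome = NULL) {
  b <- read_bed(path)
  if (any(is.na(b$name))) abort("element BED needs the name (family) field")
  out <- tibble(
    family = b$name, chrom = b$chrom, start = b$start, end = b$end,
    strand = b$strand, structure = "single", n_units = 1L, spacer = NA_real_
  )
  sidecar <- paste0(path, ".structure.tsv")
  if (file.exists(sidecar)) {
    sc <- readr::read_tsv(sidecar, col_types = "ccddccdd", progress = FALSE)
    key <- paste(out$family, out$chrom, out$start, out$end)
    skey <- paste(sc$family, sc$chrom, sc$start, sc$end)
    m <- match(key, skey)
    hit <- !is.na(m)
    out$structure[hit] <- sc$structure[m[hit]]
    out$n_units[hit] <- as.integer(sc$n_units[m[hit]])
    out$spacer[hit] <- sc$spacer[m[hit]]
  }
  if (!is.null(genome)) {
    keep <- out$chrom %in% genome$chromosomes$chrom
    if (any(!keep)) {
      warn(sprintf("dropping %d element(s) on excluded or unknown sequences",
                   sum(!keep)))
      out <- out[keep, , drop = FALSE]
    }
  }
  iv_check(out, "elements")
  inform(sprintf("read_elements_bed: %d element record(s) from %s",
                 nrow(out), path))
  out
}

#' Write repeat elements to BED6 with a structure sidecar
#'
#' @param elements Element tibble (see [read_elements_bed()]).
#' @param path Output BED path; structure annotations go to
#'   `<path>.structure.tsv`.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  elements <- check_elements(elements)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   elements$chrom, as.integer(elements$start),
                   as.integer(elements$end), elements$family,
                   elements$strand)
  writeLines(lines, path)
  sc <- elements[, c("family", "chrom", "start", "end", "strand",
                     "structure", "n_units", "spacer")]
  readr::write_tsv(sc, paste0(path, ".structure.tsv"), progress = FALSE)
  invisible(path)
}
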