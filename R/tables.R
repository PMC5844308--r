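# Published reference tables for the ten TCAST repeat families of the
# red flour beetle (Tribolium castaneum, Tcas_3.0 assembly). These are the
# printed per-family summaries the pipeline reproduces from scratch on its
# own inputs; shipping them as tibbles makes them usable as fixtures and
# as regression anchors.

#' Reference table: per-family element characteristics
#'
#' Monomer length, A+T content, dispersed element and multimer counts,
#' number of alignable monomers, and average pairwise divergence for the
#' ten TCAST repeat families. `transposon_origin` marks the families with
#' sequence similarity to known transposons (TCAST1, 4, 7, 8, 10).
#'
#' @return A tibble with one row per family.
#' @export
tcast_family_table <- function() {
  tibble(
    family = paste0("TCAST", 1:10),
    monomer_length = c(360, 359, 581, 744, 417, 814, 1771, 294, 386, 498),
    at_percent = c(73.3, 71.5, 68.7, 74.6, 68.3, 67.2, 69.7, 70.7, 73.8, 72.7),
    n_elements = c(68L, 324L, 384L, 154L, 360L, 137L, 108L, 339L, 136L, 372L),
    n_multimers = c(18L, 2L, 12L, 24L, 13L, 2L, 1L, 2L, 4L, 7L),
    n_aligned_monomers = c(77L, 307L, 360L, 146L, 343L, 122L, 88L, 303L, 136L, 353L),
    # TCAST1's published divergence is given separately for monomer halves
    # (6.7/12.7); the larger value is carried here.
    avg_divergence_pct = c(12.7, 11, 15.8, 20.1, 12.7, 10.2, 13.6, 13.9, 11.7, 14.4),
    transposon_origin = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
}

#' Reference table: element and gene counts per chromosome
#'
#' Per-chromosome counts of dispersed elements for each repeat family,
#' total element counts, gene counts, and gap-excluded chromosome sizes
#' for the ten assembled chromosomes.
#'
#' @return A tibble with one row per chromosome (`chrom`, ten family
#'   columns, `all_tcast`, `n_genes`, `chrom_size`).
#' @export
tcast_chromosome_table <- function() {
  tibble(
    chrom = paste0("ChLG", c("X", 2:10)),
    TCAST1 = c(2L, 4L, 18L, 4L, 3L, 4L, 5L, 6L, 16L, 6L),
    TCAST2 = c(5L, 41L, 83L, 32L, 26L, 19L, 28L, 31L, 40L, 19L),
    TCAST3 = c(3L, 28L, 97L, 19L, 21L, 25L, 25L, 44L, 53L, 69L),
    TCAST4 = c(5L, 13L, 52L, 8L, 10L, 13L, 9L, 15L, 14L, 15L),
    TCAST5 = c(3L, 37L, 99L, 30L, 25L, 23L, 32L, 41L, 44L, 26L),
    TCAST6 = c(5L, 14L, 46L, 11L, 12L, 3L, 10L, 12L, 19L, 5L),
    TCAST7 = c(0L, 6L, 30L, 1L, 0L, 6L, 2L, 8L, 13L, 42L),
    TCAST8 = c(7L, 33L, 100L, 26L, 32L, 13L, 31L, 40L, 42L, 15L),
    TCAST9 = c(5L, 11L, 44L, 5L, 6L, 11L, 8L, 11L, 14L, 21L),
    TCAST10 = c(2L, 33L, 112L, 31L, 32L, 24L, 39L, 39L, 44L, 16L),
    all_tcast = c(37L, 219L, 680L, 167L, 167L, 141L, 189L, 247L, 299L, 234L),
    n_genes = c(698L, 1337L, 1614L, 1245L, 1550L, 898L, 1671L, 1361L, 1243L, 502L),
    chrom_size = c(7277635, 14518415, 28591480, 12094384, 14335781,
                   8976827, 15432854, 13521898, 15459655, 7486040)
  )
}

#' Reference table: genomic position of dispersed elements
#'
#' Per-family base-pair and element counts in intergenic, intronic and
#' exonic space, plus the published permutation probabilities (probability
#' of meeting or surpassing the observed intronic / intergenic statistic
#' by chance over 1000 random placements).
#'
#' @return A tibble with one row per family; `*_bp` columns are base
#'   pairs, `*_n` columns element counts, `p_*` columns the published
#'   empirical probabilities (`NA` where none was printed).
#' @export
tcast_position_table <- function() {
  tibble(
    family = paste0("TCAST", 1:10),
    intergenic_bp = c(12416, 35283, 72876, 51800, 53851, 36452, 65928, 45216, 30531, 47373),
    intergenic_n = c(32L, 130L, 144L, 60L, 141L, 52L, 40L, 151L, 57L, 150L),
    intronic_bp = c(15558, 50411, 133882, 89061, 78164, 64027, 103028, 56919, 38107, 67330),
    intronic_n = c(36L, 193L, 237L, 93L, 218L, 83L, 67L, 188L, 79L, 222L),
    exonic_bp = c(0, 234, 1481, 923, 336, 1286, 1633, 0, 0, 0),
    exonic_n = c(0L, 1L, 3L, 1L, 1L, 2L, 1L, 0L, 0L, 0L),
    p_intron_bp = c(0.624, 0.434, 0.007, 0.074, 0.357, 0.067, 0.101, 0.754, 0.623, 0.405),
    p_intron_n = c(0.843, 0.325, 0.041, 0.197, 0.196, 0.180, 0.081, 0.866, 0.532, 0.324),
    p_intergenic_bp = c(0.376, 0.566, 0.993, 0.926, 0.643, 0.933, 0.899, 0.246, 0.377, 0.595),
    p_intergenic_n = c(0.222, 0.705, 0.973, 0.841, 0.836, 0.855, 0.947, 0.157, 0.534, 0.715)
  )
}
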