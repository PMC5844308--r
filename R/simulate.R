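# Synthetic genome / annotation / repeat generator. Emulates the
# statistical structure the analysis assumes: multi-chromosome genome with
# assembly gaps, non-overlapping multi-exon genes, and repeat families
# placed with controllable intron bias, a near/far gene-proximity mixture
# for intergenic placements (bimodal distance profiles), shared hotspot
# windows across families, and a tandem/inverted multimer mix. Every
# emitted table re-reads through the io module; the truth table records
# planted properties per element.

#' Simulation configuration
#'
#' Defaults describe the study regime the package targets: ten
#' chromosomes with the assembled sizes of the beetle genome, ~12,100
#' genes, and the ten repeat families at their observed dispersed-element
#' counts and monomer lengths. All values can be overridden; fractions are
#' in \[0,1\], lengths in bp.
#'
#' @param seed Integer seed driving every random draw.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param gap_rate_per_mb Expected assembly gaps per Mb.
#' @param gap_mean_len Mean gap length (exponential).
#' @param n_genes Total gene count (allocated to chromosomes by length).
#' @param exon_rate Mean number of *additional* exons per gene
#'   (`n_exons = 1 + Poisson(exon_rate)`).
#' @param exon_len_mean,exon_len_min Exon length: `min + Exp(mean)`.
#' @param intron_len_mean,intron_len_min Intron length: `min + Exp(mean)`.
#' @param families Tibble with `family`, `n_elements`, `monomer_length`.
#' @param element_len_range Element length as a fraction of the family
#'   monomer length, drawn uniformly from this range (mirrors the >= 40%
#'   coverage calling rule).
#' @param intron_bias Per-bp placement weight multiplier inside introns
#'   (1 = unbiased).
#' @param exon_weight Per-bp weight in exons (0 = nonexonic elements).
#' @param hotspots `NULL`, or `list(n, width, boost)`: `n` shared windows
#'   of `width` bp whose placement weight is multiplied by `boost`.
#' @param proximity `NULL`, or `list(fraction, near_scale, far_scale)`:
#'   intergenic placements draw their distance to a random gene edge from
#'   `Exp(near_scale)` with probability `fraction`, else
#'   `Exp(far_scale)`.
#' @param multimer_fraction Fraction of elements emitted as multimers.
#' @param inverted_fraction Among multimers, fraction emitted as inverted
#'   dimers (the rest are direct multimers).
#' @param mu Per-site substitution rate for [mutate_block()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = NULL,
                       gap_rate_per_mb = 1,
                       gap_mean_len = 2000,
                       n_genes = 12119,
                       exon_rate = 3,
                       exon_len_mean = 300, exon_len_min = 50,
                       intron_len_mean = 1200, intron_len_min = 60,
                       families = NULL,
                       element_len_range = c(0.4, 1),
                       intron_bias = 1,
                       exon_weight = 0,
                       hotspots = NULL,
                       proximity = NULL,
                       multimer_fraction = 0.03,
                       inverted_fraction = 0.3,
                       mu = 0.07) {
  if (is.null(chrom_lengths)) {
    ct <- tcast_chromosome_table()
    chrom_lengths <- setNames(ct$chrom_size, ct$chrom)
  }
  # YAML/JSON configs deliver named lists
  if (is.list(chrom_lengths)) chrom_lengths <- unlist(chrom_lengths)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (is.null(families)) {
    ft <- tcast_family_table()
    families <- tibble(family = ft$family, n_elements = ft$n_elements,
                       monomer_length = ft$monomer_length)
  }
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              gap_rate_per_mb = gap_rate_per_mb, gap_mean_len = gap_mean_len,
              n_genes = n_genes, exon_rate = exon_rate,
              exon_len_mean = exon_len_mean, exon_len_min = exon_len_min,
              intron_len_mean = intron_len_mean,
              intron_len_min = intron_len_min,
              families = as_tibble(families),
              element_len_range = element_len_range,
              intron_bias = intron_bias, exon_weight = exon_weight,
              hotspots = hotspots, proximity = proximity,
              multimer_fraction = multimer_fraction,
              inverted_fraction = inverted_fraction, mu = mu)
  stopifnot(all(chrom_lengths > 0), intron_bias >= 0, exon_weight >= 0,
            multimer_fraction >= 0, multimer_fraction <= 1,
            mu >= 0, mu <= 0.75)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a genome model with assembly gaps
#'
#' Gap count per chromosome is Poisson at `gap_rate_per_mb`; gap lengths
#' are exponential around `gap_mean_len`; overlapping draws are merged so
#' stored gaps are disjoint.
#'
#' @param config A [sim_config()].
#' @return A [genome_model()].
#' @export
sim_genome <- function(config) {
  set.seed(config$seed)
  lens <- config$chrom_lengths
  gaps <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    n_gap <- stats::rpois(1, config$gap_rate_per_mb * L / 1e6)
    if (n_gap == 0) next
    glen <- pmax(1, round(rexp(n_gap, 1 / config$gap_mean_len)))
    if (sum(glen) >= L) abort("gap mass exceeds chromosome length")
    gs <- floor(runif(n_gap) * (L - glen))
    gaps[[ch]] <- tibble(chrom = ch, start = gs, end = gs + glen)
  }
  gaps <- if (length(gaps)) bind_rows(gaps) else NULL
  genome_model(tibble(chrom = names(lens), length = unname(lens)), gaps)
}

#' Generate a non-overlapping gene annotation
#'
#' Genes are allocated to chromosomes proportionally to length, laid out
#' left to right with random intergenic spacing (uniform composition of
#' the free space), and given `1 + Poisson(exon_rate)` exons separated by
#' introns. Genes never overlap, which keeps per-element truth
#' unambiguous; overlapping-gene handling in the partition module is
#' exercised by hand-built fixtures instead.
#'
#' @param config A [sim_config()].
#' @param genome A [sim_genome()] result (or any [genome_model()]).
#' @return An [annotation_set()].
#' @export
sim_annotation <- function(config, genome) {
  set.seed(config$seed + 1L)
  lens <- chrom_lengths(genome)
  if (config$n_genes == 0) {
    return(annotation_set(
      tibble(gene_id = character(), chrom = character(),
             start = numeric(), end = numeric()), NULL, genome))
  }
  alloc <- round(config$n_genes * lens / sum(lens))
  # fix rounding drift on the largest chromosome
  alloc[which.max(lens)] <- alloc[which.max(lens)] +
    (config$n_genes - sum(alloc))
  n_tot <- sum(alloc)
  n_ex <- 1L + stats::rpois(n_tot, config$exon_rate)
  exon_len <- config$exon_len_min +
    round(rexp(sum(n_ex), 1 / config$exon_len_mean))
  intron_len <- config$intron_len_min +
    round(rexp(sum(pmax(n_ex - 1L, 0L)), 1 / config$intron_len_mean))
  gene_of_exon <- rep(seq_len(n_tot), times = n_ex)
  gene_of_intron <- rep(seq_len(n_tot), times = pmax(n_ex - 1L, 0L))
  glen <- tapply(exon_len, gene_of_exon, sum)
  ilen_by_gene <- rep(0, n_tot)
  if (length(intron_len) > 0) {
    t2 <- tapply(intron_len, gene_of_intron, sum)
    ilen_by_gene[as.integer(names(t2))] <- t2
  }
  glen <- as.numeric(glen) + ilen_by_gene

  gene_chrom <- rep(names(lens), times = alloc)
  gene_ids <- sprintf("g%05d", seq_len(n_tot))
  gene_start <- numeric(n_tot)
  for (ch in names(lens)) {
    idx <- which(gene_chrom == ch)
    k <- length(idx)
    if (k == 0) next
    gl <- glen[idx]
    free <- lens[[ch]] - sum(gl)
    if (free < 0) {
      abort(sprintf("cannot place %d genes on %s without overlap; lower the gene density", k, ch))
    }
    cuts <- sort(runif(k)) * free
    spacers <- diff(c(0, cuts))
    gene_start[idx] <- floor(cumsum(spacers) + cumsum(c(0, gl[-k])))
  }
  genes <- tibble(gene_id = gene_ids, chrom = gene_chrom,
                  start = gene_start, end = gene_start + glen,
                  strand = sample(c("+", "-"), n_tot, replace = TRUE))

  # exon offsets within genes, fully vectorized: for the k-th exon of a
  # gene, offset = sum of its first k-1 exons + first k-1 introns
  k_vec <- sequence(n_ex)
  first_ex <- (cumsum(n_ex) - n_ex)[gene_of_exon]
  ecum <- cumsum(c(0, exon_len))
  exon_prev <- ecum[first_ex + k_vec] - ecum[first_ex + 1]
  n_in <- pmax(n_ex - 1L, 0L)
  first_in <- (cumsum(n_in) - n_in)[gene_of_exon]
  icum <- cumsum(c(0, intron_len))
  intron_prev <- icum[first_in + k_vec] - icum[first_in + 1]
  exon_start <- gene_start[gene_of_exon] + exon_prev + intron_prev
  exons <- tibble(gene_id = gene_ids[gene_of_exon],
                  chrom = gene_chrom[gene_of_exon],
                  start = exon_start, end = exon_start + exon_len)
  annotation_set(genes, exons, genome)
}

# Weighted placement field: partition runs minus gaps, with category
# multipliers and optional hotspot boosts. Returns run tibble with
# columns chrom, start, end, category, weight_mult.
placement_field <- function(config, genome, partition) {
  lens <- chrom_lengths(genome)
  runs <- partition$intervals
  if (nrow(genome$gaps) > 0) {
    runs <- bind_rows(lapply(split(runs, runs$category), function(d) {
      out <- iv_setdiff(d[, c("chrom", "start", "end")], genome$gaps, lens)
      out$category <- d$category[1]
      out
    }))
  }
  mult <- c(exonic = config$exon_weight, intronic = config$intron_bias,
            intergenic = 1)
  runs$weight_mult <- unname(mult[runs$category])
  hs <- NULL
  if (!is.null(config$hotspots)) {
    off <- global_offsets(lens)
    hstart <- floor(runif(config$hotspots$n) *
                      (off$total - config$hotspots$width))
    hs <- tibble(gstart = hstart, gend = hstart + config$hotspots$width)
    # split runs at hotspot boundaries and boost the inside pieces
    gs <- unname(off$offsets[runs$chrom]) + runs$start
    ge <- unname(off$offsets[runs$chrom]) + runs$end
    pieces <- list()
    for (i in seq_len(nrow(runs))) {
      cutpts <- sort(unique(c(gs[i], ge[i],
                              pmax(pmin(c(hs$gstart, hs$gend), ge[i]), gs[i]))))
      ps <- cutpts[-length(cutpts)]; pe <- cutpts[-1]
      keep <- ps < pe
      ps <- ps[keep]; pe <- pe[keep]
      inside <- vapply(ps, function(p) any(p >= hs$gstart & p < hs$gend),
                       logical(1))
      pieces[[i]] <- tibble(
        chrom = runs$chrom[i],
        start = ps - unname(off$offsets[runs$chrom[i]]),
        end = pe - unname(off$offsets[runs$chrom[i]]),
        category = runs$category[i],
        weight_mult = runs$weight_mult[i] *
          ifelse(inside, config$hotspots$boost, 1),
        hotspot = inside)
    }
    runs <- bind_rows(pieces)
  } else {
    runs$hotspot <- FALSE
  }
  runs <- runs[runs$weight_mult > 0 & runs$end > runs$start, , drop = FALSE]
  attr(runs, "hotspot_windows") <- hs
  runs
}

#' Place repeat elements with planted biases
#'
#' Draws each element's location from a per-bp weight field: baseline 1,
#' multiplied by `intron_bias` inside introns, by `hotspots$boost` inside
#' hotspot windows, and by `exon_weight` (default 0) inside exons;
#' assembly gaps always have weight 0. Elements fit entirely inside one
#' run, so the planted category is exact. When a proximity mixture is
#' configured, intergenic-routed elements are instead positioned at an
#' exponential distance (near or far scale) from a random gene edge.
#' A configured fraction of elements is emitted as direct multimers or
#' inverted dimers.
#'
#' @param config A [sim_config()].
#' @param genome A [genome_model()].
#' @param annotation An [annotation_set()] on `genome`.
#' @return List with `elements` (element tibble) and `truth` (tibble:
#'   `element_id`, `family`, `chrom`, `start`, `end`, `category`,
#'   `hotspot`, `planted_distance`, `structure`), plus `realized`
#'   (named vector: realized intron fraction of placements and of the
#'   allowed space).
#' @export
sim_repeats <- function(config, genome, annotation) {
  set.seed(config$seed + 2L)
  partition <- build_partition(genome, annotation)
  field <- placement_field(config, genome, partition)
  lens <- chrom_lengths(genome)
  off <- global_offsets(lens)
  gs_run <- unname(off$offsets[field$chrom]) + field$start
  ge_run <- unname(off$offsets[field$chrom]) + field$end
  o <- order(gs_run)
  field <- field[o, , drop = FALSE]
  gs_run <- gs_run[o]; ge_run <- ge_run[o]
  run_len <- ge_run - gs_run

  fams <- config$families
  fam_vec <- rep(fams$family, times = fams$n_elements)
  mon <- rep(fams$monomer_length, times = fams$n_elements)
  n <- length(fam_vec)
  frac <- runif(n, config$element_len_range[1], config$element_len_range[2])
  L <- pmax(1, round(frac * mon))

  # structure labels
  is_multi <- runif(n) < config$multimer_fraction
  inverted <- is_multi & runif(n) < config$inverted_fraction
  structure_ <- ifelse(!is_multi, "single",
                       ifelse(inverted, "inverted_dimer", "direct_multimer"))
  n_units <- ifelse(structure_ == "single", 1L, 2L)
  # multimers span roughly two units
  L <- ifelse(is_multi, pmin(2 * L, 2 * mon), L)
  spacer <- ifelse(structure_ == "inverted_dimer",
                   round(runif(n, 10, 60)), NA_real_)

  gstart <- numeric(n); category <- character(n); hotspot <- logical(n)
  planted_distance <- rep(NA_real_, n)

  # per-element eligible-start weights over runs (by unique length)
  for (Lu in unique(L)) {
    sel <- which(L == Lu)
    w <- pmax(0, run_len - Lu + 1) * field$weight_mult
    if (sum(w) <= 0) abort("infeasible placement weights (all zero)")
    cumw <- cumsum(w)
    u <- runif(length(sel)) * sum(w)
    j <- findInterval(u, cumw) + 1L
    within <- floor((u - c(0, cumw)[j]) / field$weight_mult[j])
    gstart[sel] <- gs_run[j] + within
    category[sel] <- field$category[j]
    hotspot[sel] <- field$hotspot[j]
  }

  # proximity mixture overrides intergenic placements
  if (!is.null(config$proximity)) {
    ig <- which(category == "intergenic")
    if (length(ig) > 0) {
      mix <- config$proximity
      genes <- annotation$genes
      ig_runs <- which(field$category == "intergenic")
      for (i in ig) {
        placed <- FALSE
        for (try in 1:50) {
          near <- runif(1) < mix$fraction
          d <- round(rexp(1, 1 / if (near) mix$near_scale else mix$far_scale))
          g <- genes[sample.int(nrow(genes), 1), ]
          goff <- unname(off$offsets[g$chrom])
          side <- sample(c("left", "right"), 1)
          cand <- if (side == "right") goff + g$end + d else
            goff + g$start - d - L[i]
          jr <- findInterval(cand, gs_run)
          if (jr >= 1 && jr <= length(gs_run) &&
              field$category[jr] == "intergenic" &&
              cand + L[i] <= ge_run[jr]) {
            gstart[i] <- cand
            hotspot[i] <- field$hotspot[jr]
            planted_distance[i] <- d
            placed <- TRUE
            break
          }
        }
        # fall back to the uniform draw already stored when all retries miss
        if (!placed) planted_distance[i] <- NA_real_
      }
    }
  }

  ci <- findInterval(gstart, c(unname(off$offsets), off$total))
  chrom <- names(lens)[ci]
  start <- gstart - unname(off$offsets)[ci]
  elements <- tibble(
    family = fam_vec, chrom = chrom, start = start, end = start + L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    structure = structure_, n_units = n_units, spacer = spacer
  )
  truth <- tibble(
    element_id = seq_len(n), family = fam_vec, chrom = chrom,
    start = start, end = start + L, category = category,
    hotspot = hotspot, planted_distance = planted_distance,
    structure = structure_
  )
  w_all <- (field$end - field$start) * field$weight_mult
  realized <- c(
    intron_fraction_planted = mean(category == "intronic"),
    intron_fraction_space =
      sum((field$end - field$start)[field$category == "intronic"]) /
      sum(field$end - field$start),
    intron_fraction_weighted =
      sum(w_all[field$category == "intronic"]) / sum(w_all)
  )
  list(elements = elements, truth = truth, realized = realized,
       partition = partition)
}

#' Mutate a consensus into an alignment block
#'
#' Each row is an independent copy of the consensus with per-site
#' substitutions at rate `mu`, uniform over the three alternative bases.
#' The expected pairwise p-distance between rows is
#' `2 * mu * (1 - 2 * mu / 3)`.
#'
#' @param consensus Character string or vector over A/C/G/T.
#' @param n_rows Number of rows to emit.
#' @param mu Per-site substitution rate in \[0, 0.75\].
#' @param seed Optional integer seed.
#' @return Character matrix (`n_rows` x consensus length).
#' @export
mutate_block <- function(consensus, n_rows, mu, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mu >= 0, mu <= 0.75)
  if (length(consensus) == 1) consensus <- strsplit(toupper(consensus), "")[[1]]
  Lc <- length(consensus)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  block <- matrix(rep(consensus, each = n_rows), nrow = n_rows)
  hit <- matrix(runif(n_rows * Lc) < mu, nrow = n_rows)
  if (any(hit)) {
    which_alt <- sample.int(3, sum(hit), replace = TRUE)
    orig <- block[hit]
    block[hit] <- mapply(function(b, k) alt[[b]][k], orig, which_alt)
  }
  block
}

#' Random consensus sequence
#'
#' @param length Sequence length in bp.
#' @param at_fraction A+T fraction (repeat families here are A+T rich).
#' @param seed Optional integer seed.
#' @return Character vector of bases.
#' @export
sim_consensus <- function(length, at_fraction = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = at_fraction / 2, T = at_fraction / 2,
         C = (1 - at_fraction) / 2, G = (1 - at_fraction) / 2)
  sample(names(p), length, replace = TRUE, prob = p)
}

#' Write an alignment block to FASTA
#'
#' @param block Character matrix (rows = sequences).
#' @param path Output path.
#' @param prefix Sequence id prefix.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(block, path, prefix = "seq") {
  ids <- rownames(block)
  if (is.null(ids)) ids <- sprintf("%s%03d", prefix, seq_len(nrow(block)))
  lines <- as.vector(rbind(paste0(">", ids),
                           apply(block, 1, paste0, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}
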