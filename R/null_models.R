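# Exclusion-aware interval permutation nulls. Elements are re-placed
# uniformly over every start position at which the whole element fits
# inside one allowed run, genome-wide (placement probability proportional
# to eligible space, not conserved per chromosome). Placements may overlap
# each other, matching the observed data in which elements overlap.

#' Placeable space after exclusions
#'
#' Complement, per chromosome, of the union of the requested exclusion
#' sources. Excluded scaffolds are absent from the genome model already.
#'
#' @param genome A [genome_model()].
#' @param annotation An [annotation_set()]; required when `exclude`
#'   mentions exons or genes.
#' @param exclude Character subset of `c("gaps", "exons", "genes")`.
#' @return Tibble of allowed runs (`chrom`, `start`, `end`), sorted and
#'   disjoint. Errors if nothing is placeable.
#' @export
allowed_space <- function(genome, annotation = NULL,
                          exclude = c("gaps", "exons")) {
  exclude <- match.arg(exclude, c("gaps", "exons", "genes"),
                       several.ok = TRUE)
  if (any(c("exons", "genes") %in% exclude) && is.null(annotation)) {
    abort("`annotation` is required to exclude exons or genes")
  }
  excl <- list()
  if ("gaps" %in% exclude) excl <- c(excl, list(genome$gaps))
  if ("exons" %in% exclude) {
    excl <- c(excl, list(annotation$exons[, c("chrom", "start", "end")]))
  }
  if ("genes" %in% exclude) {
    excl <- c(excl, list(annotation$genes[, c("chrom", "start", "end")]))
  }
  excl <- if (length(excl)) bind_rows(excl) else
    tibble(chrom = character(), start = numeric(), end = numeric())
  out <- iv_complement(excl, chrom_lengths(genome))
  if (nrow(out) == 0 || sum(out$end - out$start) == 0) {
    abort("no placeable space: exclusions cover the entire genome")
  }
  out
}

# Placement context: allowed runs on the global axis plus, per unique
# element length, cumulative eligible-start weights over runs.
placement_context <- function(genome, allowed) {
  lens <- chrom_lengths(genome)
  off <- global_offsets(lens)
  gs <- unname(off$offsets[allowed$chrom]) + allowed$start
  ge <- unname(off$offsets[allowed$chrom]) + allowed$end
  o <- order(gs)
  list(run_start = gs[o], run_end = ge[o], run_len = (ge - gs)[o],
       offsets = off$offsets, chrom_names = names(off$offsets),
       chrom_bounds = c(unname(off$offsets), off$total))
}

# Draw n placements of elements with the given lengths (vector recycled
# across reps): returns global start positions, a matrix-free vector of
# length(lengths) * n_reps, ordered rep-major (rep 1 elements first).
place_many <- function(lengths, ctx, n_reps) {
  n <- length(lengths)
  starts <- numeric(n * n_reps)
  for (L in unique(lengths)) {
    w <- pmax(0, ctx$run_len - L + 1)
    total <- sum(w)
    if (total <= 0) {
      abort(sprintf("element of length %d fits in no allowed run", L))
    }
    cumw <- cumsum(w)
    sel <- which(lengths == L)
    idx <- as.vector(outer(sel, (seq_len(n_reps) - 1L) * n, `+`))
    u <- runif(length(idx)) * total
    j <- findInterval(u, cumw) + 1L
    within <- floor(u - c(0, cumw)[j])
    starts[idx] <- ctx$run_start[j] + within
  }
  starts
}

#' Randomly re-place elements over allowed space
#'
#' One permutation draw: every element is independently placed uniformly
#' over all genome-wide start positions at which it fits entirely inside
#' one allowed run. Families, lengths and strands are preserved;
#' placements may overlap one another.
#'
#' @param elements Element tibble.
#' @param genome A [genome_model()].
#' @param allowed Allowed-space tibble from [allowed_space()].
#' @param seed Optional integer seed for reproducible placement.
#' @param per_chromosome Keep each element on its own chromosome instead
#'   of placing genome-wide (default `FALSE`: placement probability is
#'   proportional to eligible space across the whole genome).
#' @return Element tibble with new `chrom`, `start`, `end`.
#' @export
shuffle_elements <- function(elements, genome, allowed, seed = NULL,
                             per_chromosome = FALSE) {
  elements <- check_elements(elements)
  if (!is.null(seed)) set.seed(seed)
  if (per_chromosome) {
    out <- elements
    for (ch in unique(elements$chrom)) {
      sel <- elements$chrom == ch
      runs <- allowed[allowed$chrom == ch, , drop = FALSE]
      if (nrow(runs) == 0) {
        abort(sprintf("no allowed space on chromosome %s", ch))
      }
      sub_genome <- genome
      sub_genome$chromosomes <-
        genome$chromosomes[genome$chromosomes$chrom == ch, , drop = FALSE]
      placed <- shuffle_elements(elements[sel, , drop = FALSE],
                                 sub_genome, runs)
      out[sel, c("chrom", "start", "end")] <-
        placed[, c("chrom", "start", "end")]
    }
    return(out)
  }
  ctx <- placement_context(genome, allowed)
  L <- elements$end - elements$start
  gs <- place_many(L, ctx, 1L)
  ci <- findInterval(gs, ctx$chrom_bounds)
  elements$chrom <- ctx$chrom_names[ci]
  elements$start <- gs - ctx$chrom_bounds[ci]
  elements$end <- elements$start + L
  elements
}

#' Permutation enrichment test for introns and intergenic regions
#'
#' Re-places the (nonexonic) elements `n_reps` times over space excluding
#' assembly gaps and exons, and for each family (and pooled over families)
#' reports the empirical probability that a random placement meets or
#' surpasses the observed intronic / intergenic element count and base
#' pair count: `p = #(sim >= obs) / n_reps`. With
#' `conservative = TRUE` the `(k+1)/(n+1)` variant is reported instead.
#'
#' @param elements Element tibble (elements overlapping exons are dropped
#'   with a warning; the test is defined for the nonexonic set).
#' @param partition A [build_partition()] result.
#' @param genome The [genome_model()] the partition was built on.
#' @param annotation The [annotation_set()] (supplies exon exclusions).
#' @param n_reps Number of random placements (published analysis: 1000).
#' @param seed Integer seed recorded in the result.
#' @param conservative Use `(k+1)/(n_reps+1)` instead of `k/n_reps`.
#' @param bh Append Benjamini-Hochberg adjusted columns across families.
#' @return An `enrichment_result`: tibble with one row per family plus a
#'   pooled `All` row; observed statistics and empirical probabilities
#'   `p_intron_n`, `p_intron_bp`, `p_intergenic_n`, `p_intergenic_bp`.
#'   Attributes `n_reps` and `seed`.
#' @export
enrichment_test <- function(elements, partition, genome, annotation,
                            n_reps = 1000, seed = 1L,
                            conservative = FALSE, bh = FALSE) {
  stopifnot(n_reps >= 1)
  elements <- check_elements(elements)
  if (!"category" %in% names(elements)) {
    elements <- categorize_elements(elements, partition)
  }
  if (any(elements$category == "exonic")) {
    warn(sprintf("dropping %d exon-overlapping element(s); the test uses the nonexonic set",
                 sum(elements$category == "exonic")))
    elements <- elements[elements$category != "exonic", , drop = FALSE]
  }
  if (nrow(elements) == 0) abort("no nonexonic elements to test")
  set.seed(seed)
  allowed <- allowed_space(genome, annotation, exclude = c("gaps", "exons"))
  ctx <- placement_context(genome, allowed)
  intr <- partition_global(partition, "intronic")

  fam_levels <- sort(unique(elements$family))
  fam <- match(elements$family, fam_levels)
  nf <- length(fam_levels)
  L <- elements$end - elements$start
  n <- nrow(elements)

  obs <- elements %>%
    mutate(bp = .data$end - .data$start) %>%
    group_by(.data$family) %>%
    summarise(
      intron_n = sum(.data$category == "intronic"),
      intron_bp = sum(.data$bp[.data$category == "intronic"]),
      intergenic_n = sum(.data$category == "intergenic"),
      intergenic_bp = sum(.data$bp[.data$category == "intergenic"]),
      total_n = n(), total_bp = sum(.data$bp),
      .groups = "drop")

  # simulate in chunks to bound memory at large n_reps
  k_in_n <- matrix(0, nf, 1); k_in_bp <- matrix(0, nf, 1)
  k_out_n <- matrix(0, nf, 1); k_out_bp <- matrix(0, nf, 1)
  k_pool <- c(in_n = 0, in_bp = 0, out_n = 0, out_bp = 0)
  obs_in_n <- obs$intron_n[match(fam_levels, obs$family)]
  obs_in_bp <- obs$intron_bp[match(fam_levels, obs$family)]
  obs_out_n <- obs$intergenic_n[match(fam_levels, obs$family)]
  obs_out_bp <- obs$intergenic_bp[match(fam_levels, obs$family)]
  chunk <- max(1L, min(n_reps, as.integer(ceiling(2e6 / n))))
  done <- 0L
  while (done < n_reps) {
    m <- min(chunk, n_reps - done)
    gs <- place_many(L, ctx, m)
    ge <- gs + rep(L, times = m)
    hit <- global_overlaps_any(gs, ge, intr$start, intr$end)
    rep_id <- rep(seq_len(m), each = n)
    grp <- (rep_id - 1L) * nf + rep(fam, times = m)
    sim_in_n <- matrix(tabulate(grp[hit], nbins = nf * m), nrow = nf)
    sim_in_bp <- matrix(0, nf, m)
    if (any(hit)) {
      rs <- rowsum(rep(L, times = m)[hit], grp[hit])
      sim_in_bp[as.integer(rownames(rs))] <- rs[, 1]
    }
    tot_n <- tabulate(rep(fam, times = m) + (rep_id - 1L) * nf, nbins = nf * m)
    sim_tot_n <- matrix(tot_n, nrow = nf)
    sim_tot_bp <- matrix(rowsum(rep(L, times = m),
                                grp)[, 1][as.character(seq_len(nf * m))],
                         nrow = nf)
    sim_tot_bp[is.na(sim_tot_bp)] <- 0
    sim_out_n <- sim_tot_n - sim_in_n
    sim_out_bp <- sim_tot_bp - sim_in_bp
    k_in_n <- k_in_n + rowSums(sim_in_n >= obs_in_n)
    k_in_bp <- k_in_bp + rowSums(sim_in_bp >= obs_in_bp)
    k_out_n <- k_out_n + rowSums(sim_out_n >= obs_out_n)
    k_out_bp <- k_out_bp + rowSums(sim_out_bp >= obs_out_bp)
    k_pool["in_n"] <- k_pool["in_n"] + sum(colSums(sim_in_n) >= sum(obs_in_n))
    k_pool["in_bp"] <- k_pool["in_bp"] + sum(colSums(sim_in_bp) >= sum(obs_in_bp))
    k_pool["out_n"] <- k_pool["out_n"] + sum(colSums(sim_out_n) >= sum(obs_out_n))
    k_pool["out_bp"] <- k_pool["out_bp"] + sum(colSums(sim_out_bp) >= sum(obs_out_bp))
    done <- done + m
  }
  to_p <- if (conservative) function(k) (k + 1) / (n_reps + 1) else
    function(k) k / n_reps
  per_fam <- tibble(
    family = fam_levels,
    intron_n = obs_in_n, intron_bp = obs_in_bp,
    intergenic_n = obs_out_n, intergenic_bp = obs_out_bp,
    p_intron_n = to_p(as.vector(k_in_n)),
    p_intron_bp = to_p(as.vector(k_in_bp)),
    p_intergenic_n = to_p(as.vector(k_out_n)),
    p_intergenic_bp = to_p(as.vector(k_out_bp))
  )
  pooled <- tibble(
    family = "All",
    intron_n = sum(obs_in_n), intron_bp = sum(obs_in_bp),
    intergenic_n = sum(obs_out_n), intergenic_bp = sum(obs_out_bp),
    p_intron_n = to_p(k_pool[["in_n"]]), p_intron_bp = to_p(k_pool[["in_bp"]]),
    p_intergenic_n = to_p(k_pool[["out_n"]]),
    p_intergenic_bp = to_p(k_pool[["out_bp"]])
  )
  out <- bind_rows(per_fam, pooled)
  if (bh) {
    for (col in c("p_intron_n", "p_intron_bp", "p_intergenic_n",
                  "p_intergenic_bp")) {
      adj <- rep(NA_real_, nrow(out))
      idx <- out$family != "All"
      adj[idx] <- stats::p.adjust(out[[col]][idx], method = "BH")
      out[[paste0(col, "_bh")]] <- adj
    }
  }
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "enrichment_result")
  out
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  all_row <- x[x$family == "All", ]
  tibble(n_families = sum(x$family != "All"),
         n_reps = attr(x, "n_reps"), seed = attr(x, "seed"),
         p_intron_n = all_row$p_intron_n, p_intron_bp = all_row$p_intron_bp)
}

#' Distance from each element to the nearest gene
#'
#' Minimum edge-to-edge gap in bp between the element interval and any
#' gene span on the same chromosome; elements touching or overlapping a
#' gene get 0. Elements on chromosomes without genes get `NA` (reported
#' with a message) and are excluded from distance profiles.
#'
#' @param elements Element tibble.
#' @param annotation An [annotation_set()].
#' @return `elements` with a `gene_distance` column appended.
#' @export
nearest_gene_distance <- function(elements, annotation) {
  elements <- check_elements(elements)
  elements$gene_distance <- nearest_distance_vec(
    elements$chrom, elements$start, elements$end, annotation)
  n_na <- sum(is.na(elements$gene_distance))
  if (n_na > 0) {
    inform(sprintf("%d element(s) on chromosome(s) without genes: distance undefined",
                   n_na))
  }
  elements
}

# Vectorized nearest-gene distance; gene spans merged per chromosome.
nearest_distance_vec <- function(chrom, start, end, annotation) {
  spans <- iv_merge(annotation$genes[, c("chrom", "start", "end")])
  out <- rep(NA_real_, length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- spans[spans$chrom == ch, ]
    if (nrow(g) == 0) next
    S <- g$start; E <- g$end
    a <- start[sel]; b <- end[sel]
    i <- findInterval(b - 0.5, S)   # last gene with start < b
    d <- rep(Inf, sum(sel))
    hasL <- i >= 1L
    overlap <- hasL & E[pmax(i, 1L)] > a
    d[hasL] <- pmax(0, a[hasL] - E[i[hasL]])
    hasR <- i < length(S)
    d[hasR] <- pmin(d[hasR], S[i[hasR] + 1L] - b[hasR])
    d[overlap] <- 0
    out[sel] <- d
  }
  out
}

#' Nearest-gene distance profile versus random placement
#'
#' Compares the observed distances of intergenic elements to the nearest
#' gene against distances from `n_reps` random placements over space
#' excluding assembly gaps and gene bodies. All null replicates are pooled
#' into one null sample (set `pool = FALSE` to compare against a single
#' matched-size draw) and the two samples are compared with the two-sample
#' Kolmogorov-Smirnov test on raw distances.
#'
#' @param elements Intergenic element tibble (categorize first; rows with
#'   a `category` column are filtered to `intergenic`).
#' @param genome A [genome_model()].
#' @param annotation An [annotation_set()].
#' @param n_reps Number of random placements (published analysis: 100).
#' @param seed Integer seed.
#' @param pool Pool all null replicates (default) or use only the first.
#' @return A `distance_profile` object: list with `observed` and `null`
#'   distance vectors, `statistic` (K-S D), `p_value`, `direction`
#'   (`"closer"`/`"farther"` than null by median), `n_reps`, `seed`.
#' @export
distance_null <- function(elements, genome, annotation, n_reps = 100,
                          seed = 1L, pool = TRUE) {
  elements <- check_elements(elements)
  if ("category" %in% names(elements)) {
    elements <- elements[elements$category == "intergenic", , drop = FALSE]
  }
  if (nrow(elements) == 0) abort("empty intergenic element set")
  set.seed(seed)
  allowed <- allowed_space(genome, annotation, exclude = c("gaps", "genes"))
  ctx <- placement_context(genome, allowed)
  obs <- nearest_distance_vec(elements$chrom, elements$start, elements$end,
                              annotation)
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0) abort("no defined observed distances")
  L <- elements$end - elements$start
  use_reps <- if (pool) n_reps else 1L
  gs <- place_many(L, ctx, use_reps)
  ci <- findInterval(gs, ctx$chrom_bounds)
  nulld <- nearest_distance_vec(ctx$chrom_names[ci],
                                gs - ctx$chrom_bounds[ci],
                                gs - ctx$chrom_bounds[ci] + rep(L, use_reps),
                                annotation)
  nulld <- nulld[!is.na(nulld)]
  ks <- ks_two_sample(obs, nulld)
  structure(
    list(observed = obs, null = nulld,
         statistic = ks$statistic, p_value = ks$p_value,
         direction = if (stats::median(obs) < stats::median(nulld))
           "closer" else "farther",
         n_reps = n_reps, seed = seed),
    class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> n_obs = %d, pooled null = %d (%d reps); K-S D = %.4f, p = %.3g; observed %s to genes than null\n",
              length(x$observed), length(x$null), x$n_reps,
              x$statistic, x$p_value, x$direction))
  invisible(x)
}

#' @method tidy distance_profile
#' @export
tidy.distance_profile <- function(x, ...) {
  bind_rows(
    tibble(source = "observed", distance = x$observed),
    tibble(source = "null", distance = x$null)
  )
}

#' @method glance distance_profile
#' @export
glance.distance_profile <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         direction = x$direction, n_observed = length(x$observed),
         n_null = length(x$null), n_reps = x$n_reps, seed = x$seed)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs (ties handled by evaluating
#' both ECDFs at the sorted unique pooled values). The p-value uses the
#' asymptotic Kolmogorov distribution with effective sample size
#' `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("empty sample")
  pts <- sort(unique(c(a, b)))
  Fa <- ecdf(a)(pts)
  Fb <- ecdf(b)(pts)
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- sqrt(n_eff) * D
  if (lambda == 0) {
    p <- 1
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(1, max(0, p))
  }
  list(statistic = D, p_value = p)
}
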