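# Element calling: similarity hits -> dispersed repeat elements.

#' Filter similarity hits on coverage and identity
#'
#' Retains hits covering at least `min_coverage` of the family consensus
#' length *and* exceeding `min_identity` sequence identity. The identity
#' bound is strict (> 80\%) while the coverage bound is inclusive
#' (>= 40\%), mirroring the asymmetric screening rule the thresholds come
#' from. Input order is preserved; the filter is idempotent.
#'
#' @param hits Hit tibble from [read_hits()] (needs `coverage` and
#'   `identity` columns, fractions in \[0,1\]).
#' @param min_coverage Inclusive lower bound on consensus coverage.
#' @param min_identity Exclusive lower bound on identity.
#' @return The retained hits, same columns and order.
#' @export
filter_hits <- function(hits, min_coverage = 0.40, min_identity = 0.80) {
  hits <- as_tibble(hits)
  keep <- hits$coverage >= min_coverage & hits$identity > min_identity
  hits[keep, , drop = FALSE]
}

#' Merge filtered hits into dispersed elements
#'
#' Same-family hits on one chromosome are grouped by a single left-to-right
#' sweep: a hit joins the open group when the gap to the group's right edge
#' is at most `max_gap_factor` monomer lengths. Each group becomes one
#' element whose interval covers all grouped hits. Structure is classified
#' from group size and strand composition:
#'
#' * one hit: `single`;
#' * two hits on opposite strands: `inverted_dimer`, with `spacer` the
#'   inter-hit gap in bp (0 if the hits touch or overlap);
#' * otherwise: `direct_multimer` with `n_units` = number of grouped hits
#'   (partial monomers count); mixed-strand groups larger than two are
#'   classified `direct_multimer` with a warning.
#'
#' @param hits Filtered hit tibble.
#' @param monomer_lengths Named numeric vector (or `family`,`length` data
#'   frame) of per-family monomer lengths in bp.
#' @param max_gap_factor Grouping distance in units of the family monomer
#'   length (default 2).
#' @return Element tibble: `family`, `chrom`, `start`, `end`, `strand`
#'   (strand of the first hit), `structure`, `n_units`, `spacer`,
#'   `source_hits` (list column of source row indices in `hits`).
#' @export
merge_hits_to_elements <- function(hits, monomer_lengths, max_gap_factor = 2) {
  hits <- as_tibble(hits)
  if (is.data.frame(monomer_lengths)) {
    monomer_lengths <- setNames(monomer_lengths$length, monomer_lengths$family)
  }
  if (nrow(hits) == 0) {
    return(tibble(family = character(), chrom = character(), start = numeric(),
                  end = numeric(), strand = character(), structure = character(),
                  n_units = integer(), spacer = numeric(),
                  source_hits = list()))
  }
  unknown <- setdiff(unique(hits$family), names(monomer_lengths))
  if (length(unknown) > 0) {
    abort(sprintf("no monomer length for family: %s",
                  paste(unknown, collapse = ", ")))
  }
  hits$.row <- seq_len(nrow(hits))
  ord <- order(hits$family, hits$chrom, hits$start, hits$end)
  h <- hits[ord, , drop = FALSE]
  max_gap <- max_gap_factor * unname(monomer_lengths[h$family])
  # group ids by sweep: new group when family/chrom changes or gap too wide
  n <- nrow(h)
  run_end <- h$end[1]
  grp <- integer(n); grp[1] <- 1L; g <- 1L
  if (n > 1) {
    for (i in 2:n) {
      same <- h$family[i] == h$family[i - 1L] && h$chrom[i] == h$chrom[i - 1L]
      if (same && (h$start[i] - run_end) <= max_gap[i]) {
        run_end <- max(run_end, h$end[i])
      } else {
        g <- g + 1L
        run_end <- h$end[i]
      }
      grp[i] <- g
    }
  }
  h$.grp <- grp
  mixed_warned <- FALSE
  groups <- split(h, h$.grp)
  out <- lapply(groups, function(d) {
    nh <- nrow(d)
    strands <- d$strand
    if (nh == 1L) {
      structure_ <- "single"; n_units <- 1L; spacer <- NA_real_
    } else if (nh == 2L && length(unique(strands)) == 2L) {
      structure_ <- "inverted_dimer"; n_units <- 2L
      d2 <- d[order(d$start), ]
      spacer <- max(0, d2$start[2] - d2$end[1])
    } else {
      structure_ <- "direct_multimer"; n_units <- nh; spacer <- NA_real_
      if (length(unique(strands)) > 1L) {
        mixed_warned <<- TRUE
      }
    }
    tibble(family = d$family[1], chrom = d$chrom[1],
           start = min(d$start), end = max(d$end),
           strand = d$strand[which.min(d$start)],
           structure = structure_, n_units = n_units, spacer = spacer,
           source_hits = list(d$.row))
  })
  if (mixed_warned) {
    warn("mixed-strand group(s) larger than two classified as direct_multimer")
  }
  out <- bind_rows(out)
  out[order(out$chrom, out$start, out$family), , drop = FALSE]
}

#' Per-family multimer census
#'
#' Counts elements and multimers (any element whose structure is not
#' `single`) per family, with the largest multimer order observed.
#'
#' @param elements Element tibble.
#' @param families Optional character vector fixing the set and order of
#'   families reported (families absent from `elements` get zero rows).
#' @return Tibble: `family`, `n_elements`, `n_multimers`,
#'   `max_multimer_order`.
#' @export
multimer_census <- function(elements, families = NULL) {
  elements <- check_elements(elements)
  tab <- elements %>%
    group_by(.data$family) %>%
    summarise(
      n_elements = n(),
      n_multimers = sum(.data$structure != "single"),
      max_multimer_order = if (any(.data$structure != "single"))
        max(.data$n_units[.data$structure != "single"]) else 0L,
      .groups = "drop"
    )
  if (!is.null(families)) {
    tab <- tibble(family = families) %>%
      left_join(tab, by = "family") %>%
      mutate(across(c("n_elements", "n_multimers", "max_multimer_order"),
                    ~ ifelse(is.na(.x), 0L, .x)))
  }
  tab
}
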