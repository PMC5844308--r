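# Among- and along-chromosome distribution statistics.

#' Per-chromosome element and gene count table
#'
#' Elements are assigned to the chromosome containing their start. The
#' result mirrors the layout of a per-chromosome dispersion table: one
#' family column per family, a total column, gene counts and chromosome
#' sizes.
#'
#' @param elements Element tibble.
#' @param annotation An [annotation_set()].
#' @param genome A [genome_model()] (fixes chromosome set and order).
#' @return Tibble with columns `chrom`, one per family, `all_elements`,
#'   `n_genes`, `chrom_size`.
#' @export
count_table <- function(elements, annotation, genome) {
  elements <- check_elements(elements)
  fams <- sort(unique(elements$family))
  wide <- elements %>%
    count(.data$chrom, .data$family) %>%
    tidyr::pivot_wider(names_from = "family", values_from = "n",
                       values_fill = 0L)
  out <- tibble(chrom = genome$chromosomes$chrom) %>%
    left_join(wide, by = "chrom")
  for (f in fams) {
    out[[f]][is.na(out[[f]])] <- 0L
  }
  if (length(fams) == 0) out$all_elements <- 0L else
    out$all_elements <- rowSums(as.matrix(out[, fams, drop = FALSE]))
  out <- out %>%
    left_join(gene_counts(annotation, genome), by = "chrom") %>%
    left_join(genome$chromosomes %>% rename(chrom_size = "length"),
              by = "chrom")
  out
}

#' Ordinary least-squares fit of y on x
#'
#' A thin wrapper around [stats::lm()] returning slope, intercept, R-squared
#' and the two-tailed p-value of the slope (t distribution, n - 2 df).
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @param data Optional data frame; when given, `x` and `y` are column
#'   names in it (keeps the data-frame-first calling style).
#' @return A `lin_fit` object; use [tidy()] / [glance()] or access
#'   `$slope`, `$intercept`, `$r_squared`, `$p_value`, `$n`.
#' @export
linear_fit <- function(x, y, data = NULL) {
  if (!is.null(data)) {
    x_name <- x; y_name <- y
    x <- data[[x_name]]; y <- data[[y_name]]
  } else {
    x_name <- "x"; y_name <- "y"
  }
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 points")
  if (length(unique(x)) < 2) abort("x is constant; slope undefined")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  s <- summary(fit)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = s$r.squared,
         p_value = unname(s$coefficients[2, 4]),
         n = length(x), x = x_name, y = y_name, fit = fit),
    class = "lin_fit")
}

#' @export
print.lin_fit <- function(x, ...) {
  cat(sprintf("<lin_fit> %s ~ %s: slope %.4g, intercept %.4g, R^2 = %.3f, p = %.3g (n = %d)\n",
              x$y, x$x, x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @method tidy lin_fit
#' @export
tidy.lin_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", x$x),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @method glance lin_fit
#' @export
glance.lin_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value,
         slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Regression suite over a chromosome count table
#'
#' Fits, for each family and for the total: count ~ chromosome size and
#' count ~ gene count; plus gene count ~ chromosome size. This reproduces
#' the among-chromosome regression layout used to ask whether element
#' counts track chromosome size or gene density.
#'
#' @param table Count table from [count_table()] (or any tibble with
#'   family columns plus `all_elements`, `n_genes`, `chrom_size`).
#' @param families Character vector of family columns; defaults to every
#'   column that is not `chrom`, `all_elements`, `n_genes`, `chrom_size`.
#' @return Tibble with one row per fit: `response`, `predictor`,
#'   `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
regression_suite <- function(table, families = NULL) {
  table <- as_tibble(table)
  reserved <- c("chrom", "all_elements", "n_genes", "chrom_size")
  if (is.null(families)) families <- setdiff(names(table), reserved)
  responses <- c(families, "all_elements")
  rows <- list()
  for (resp in responses) {
    for (pred in c("chrom_size", "n_genes")) {
      f <- linear_fit(pred, resp, data = table)
      rows[[length(rows) + 1]] <- tibble(
        response = resp, predictor = pred, r_squared = f$r_squared,
        p_value = f$p_value, slope = f$slope, intercept = f$intercept,
        n = f$n)
    }
  }
  f <- linear_fit("chrom_size", "n_genes", data = table)
  rows[[length(rows) + 1]] <- tibble(
    response = "n_genes", predictor = "chrom_size", r_squared = f$r_squared,
    p_value = f$p_value, slope = f$slope, intercept = f$intercept, n = f$n)
  bind_rows(rows)
}

#' Binned along-chromosome profiles
#'
#' Counts features (elements per family, or genes) in bins along each
#' chromosome. Two schemes are supported: `"tenths"` — ten equal-width
#' bins per chromosome with boundaries at `floor(i * L / 10)` (half-open,
#' the last bin absorbing the rounding remainder) — and `"fixed_1mb"` —
#' 1 Mb bins, the last bin partial. A feature belongs to the bin
#' containing its start (set `midpoint = TRUE` to bin by midpoint).
#'
#' @param features Tibble with `chrom`, `start`, `end` and a grouping
#'   column named by `group` (e.g. `family`); pass genes with
#'   `group = NULL` to profile them as one track.
#' @param genome A [genome_model()].
#' @param scheme `"tenths"` or `"fixed_1mb"`.
#' @param group Name of the grouping column, or `NULL` for a single track
#'   labelled `"all"`.
#' @param midpoint Bin by feature midpoint instead of start.
#' @return Tibble: `chrom`, `track`, `bin` (1-based), `n`, `percent`
#'   (of the track's features on that chromosome; 0 when the chromosome
#'   has none). Every (chrom, track, bin) combination is present.
#' @export
bin_profile <- function(features, genome, scheme = c("tenths", "fixed_1mb"),
                        group = "family", midpoint = FALSE) {
  scheme <- match.arg(scheme)
  features <- as_tibble(features)
  iv_check(features, "features")
  lens <- chrom_lengths(genome)
  if (any(!features$chrom %in% names(lens))) {
    abort("feature(s) on chromosomes absent from the genome model")
  }
  track <- if (is.null(group)) rep("all", nrow(features)) else
    as.character(features[[group]])
  pos <- if (midpoint) floor((features$start + features$end) / 2) else
    features$start
  L <- unname(lens[features$chrom])
  if (scheme == "tenths") {
    bin <- pmin(floor(pos * 10 / L) + 1, 10)
    n_bins <- setNames(rep(10L, length(lens)), names(lens))
  } else {
    bin <- floor(pos / 1e6) + 1
    n_bins <- setNames(as.integer(ceiling(lens / 1e6)), names(lens))
  }
  tracks <- sort(unique(track))
  grid <- bind_rows(lapply(names(lens), function(ch) {
    tidyr::expand_grid(chrom = ch, track = tracks,
                       bin = seq_len(n_bins[[ch]]))
  }))
  counts <- tibble(chrom = features$chrom, track = track, bin = bin) %>%
    count(.data$chrom, .data$track, .data$bin)
  out <- grid %>%
    left_join(counts, by = c("chrom", "track", "bin")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    group_by(.data$chrom, .data$track) %>%
    mutate(percent = {
      s <- sum(.data$n)
      if (s > 0) 100 * .data$n / s else 0 * .data$n
    }) %>%
    ungroup()
  attr(out, "scheme") <- scheme
  out
}

#' Colocalization correlations between binned profiles
#'
#' Pearson correlation (Spearman optionally alongside) of bin-count
#' vectors between every pair of tracks, per chromosome and on the pooled
#' concatenation of all chromosomes. Significance is flagged at the
#' conventional threshold |r| > 0.700 and p < 0.05. Zero-variance tracks
#' yield `NA` correlations (reported with a message).
#'
#' @param profile Binned profile from [bin_profile()]; tracks to correlate
#'   are its `track` values (families, and genes if you bound them in).
#' @param use_percent Correlate per-chromosome percentages instead of
#'   counts (identical per chromosome up to scaling; differs pooled).
#' @param spearman Also report Spearman's rank correlation.
#' @return Tibble: `chrom` (`"pooled"` for the concatenation), `track_a`,
#'   `track_b`, `r`, `p_value`, `significant`, and optionally `rho`.
#' @export
colocalization <- function(profile, use_percent = FALSE, spearman = FALSE) {
  profile <- as_tibble(profile)
  val <- if (use_percent) "percent" else "n"
  tracks <- sort(unique(profile$track))
  if (length(tracks) < 2) abort("need at least two tracks to correlate")
  chroms <- unique(profile$chrom)
  wide_of <- function(d) {
    d <- d[order(d$chrom, d$bin), ]
    sapply(tracks, function(tr) d[[val]][d$track == tr])
  }
  any_na <- FALSE
  one_block <- function(mat, label) {
    pairs <- expand.grid(ai = seq_along(tracks), bi = seq_along(tracks))
    pairs <- pairs[pairs$ai <= pairs$bi, ]
    res <- lapply(seq_len(nrow(pairs)), function(k) {
      a <- mat[, pairs$ai[k]]; b <- mat[, pairs$bi[k]]
      if (sd(a) == 0 || sd(b) == 0) {
        any_na <<- TRUE
        r <- NA_real_; p <- NA_real_
      } else {
        r <- if (pairs$ai[k] == pairs$bi[k]) 1 else cor(a, b)
        n <- length(a)
        if (pairs$ai[k] == pairs$bi[k]) {
          p <- 0
        } else if (abs(r) >= 1) {
          p <- 0
        } else {
          tstat <- r * sqrt((n - 2) / (1 - r^2))
          p <- 2 * pt(-abs(tstat), df = n - 2)
        }
      }
      row <- tibble(chrom = label, track_a = tracks[pairs$ai[k]],
                    track_b = tracks[pairs$bi[k]], r = r, p_value = p,
                    significant = !is.na(r) & r > 0.700 & p < 0.05)
      if (spearman) {
        row$rho <- if (is.na(r)) NA_real_ else
          suppressWarnings(cor(a, b, method = "spearman"))
      }
      row
    })
    bind_rows(res)
  }
  out <- bind_rows(
    bind_rows(lapply(chroms, function(ch) {
      one_block(wide_of(profile[profile$chrom == ch, ]), ch)
    })),
    one_block(wide_of(profile), "pooled")
  )
  if (any_na) inform("zero-variance track(s): correlation undefined, reported as NA")
  # mirror to a full symmetric listing
  mirror <- out[out$track_a != out$track_b, ]
  tmp <- mirror$track_a; mirror$track_a <- mirror$track_b; mirror$track_b <- tmp
  bind_rows(out, mirror) %>%
    arrange(.data$chrom, .data$track_a, .data$track_b)
}
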