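# Permutation placement engine, enrichment probabilities, nearest-gene
# distances and the two-sample K-S test.

test_that("allowed space is the complement of the exclusions", {
  gm <- toy_genome(c(c1 = 1000))
  ann <- suppressMessages(annotation_set(
    tibble::tibble(gene_id = "g", chrom = "c1", start = 100, end = 200),
    tibble::tibble(gene_id = "g", chrom = "c1", start = 100, end = 200), gm))
  a <- allowed_space(gm, ann, exclude = c("gaps", "exons"))
  expect_equal(a$start, c(0, 200))
  expect_equal(a$end, c(100, 1000))
  # no exclusions: whole chromosomes
  a2 <- allowed_space(gm, exclude = "gaps")
  expect_equal(a2$start, 0)
  expect_equal(a2$end, 1000)
})

test_that("allowed space matches a per-bp oracle on random exclusion sets", {
  set.seed(31)
  lens <- c(c1 = 20000, c2 = 10000)
  gm <- toy_genome(lens)
  for (rep in 1:10) {
    gaps <- random_intervals(10, lens, max_len = 400)
    gm2 <- suppressWarnings(genome_model(gm$chromosomes, gaps))
    a <- allowed_space(gm2, exclude = "gaps")
    for (ch in names(lens)) {
      cov <- rep(TRUE, lens[[ch]])
      d <- gaps[gaps$chrom == ch, ]
      for (i in seq_len(nrow(d))) cov[(d$start[i] + 1):d$end[i]] <- FALSE
      da <- a[a$chrom == ch, ]
      got <- rep(FALSE, lens[[ch]])
      for (i in seq_len(nrow(da))) got[(da$start[i] + 1):da$end[i]] <- TRUE
      expect_equal(got, cov)
    }
  }
})

test_that("exclusions covering everything raise an error", {
  gm <- toy_genome(c(c1 = 100))
  gm$gaps <- tibble::tibble(chrom = "c1", start = 0, end = 100)
  expect_error(allowed_space(gm, exclude = "gaps"), "no placeable space")
})

test_that("a forced placement is deterministic and seeds reproduce", {
  gm <- toy_genome(c(c1 = 1000))
  allowed <- tibble::tibble(chrom = "c1", start = 300, end = 400)
  el <- tibble::tibble(family = "F", chrom = "c1", start = 0, end = 100)
  # run of exactly the element length: only one legal start
  placed <- shuffle_elements(el, gm, allowed, seed = 5)
  expect_equal(placed$start, 300)
  expect_equal(placed$end, 400)
  # identical seed, identical placements
  allowed2 <- allowed_space(gm, exclude = "gaps")
  p1 <- shuffle_elements(el, gm, allowed2, seed = 42)
  p2 <- shuffle_elements(el, gm, allowed2, seed = 42)
  expect_equal(p1, p2)
})

test_that("placement probability is proportional to eligible space", {
  gm <- toy_genome(c(c1 = 900, c2 = 100))
  allowed <- allowed_space(gm, exclude = "gaps")
  el <- tibble::tibble(family = rep("F", 10000), chrom = "c1",
                       start = 0, end = 1)
  placed <- shuffle_elements(el, gm, allowed, seed = 6)
  frac_c1 <- mean(placed$chrom == "c1")
  # 900 of 1000 eligible 1-bp starts are on c1; 3 binomial SDs
  expect_lt(abs(frac_c1 - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
})

test_that("per-chromosome shuffling conserves chromosome identity", {
  gm <- toy_genome()
  allowed <- allowed_space(gm, exclude = "gaps")
  el <- tibble::tibble(family = "F",
                       chrom = rep(c("c1", "c2"), c(30, 20)),
                       start = 0, end = 50)
  placed <- shuffle_elements(el, gm, allowed, seed = 8,
                             per_chromosome = TRUE)
  expect_equal(placed$chrom, el$chrom)
  expect_true(all(placed$end - placed$start == 50))
  lens <- c(c1 = 100000, c2 = 50000)
  expect_true(all(placed$end <= lens[placed$chrom]))
})

test_that("shuffling conserves the element multiset and respects exclusions", {
  set.seed(32)
  gm <- toy_genome()
  ann <- toy_annotation(gm)
  allowed <- allowed_space(gm, ann, exclude = c("gaps", "exons"))
  el <- random_intervals(200, c(c1 = 100000), max_len = 300)
  el$family <- sample(c("F1", "F2"), 200, replace = TRUE)
  placed <- shuffle_elements(el, gm, allowed)
  expect_equal(sort(placed$end - placed$start), sort(el$end - el$start))
  expect_equal(table(placed$family), table(el$family))
  # no placement may touch exonic space
  p <- build_partition(gm, ann)
  expect_false(any(categorize_elements(placed, p)$category == "exonic"))
})

test_that("an observed statistic of zero has empirical probability one", {
  gm <- toy_genome()
  ann <- toy_annotation(gm)
  p <- build_partition(gm, ann)
  # all elements intergenic on c2 (no genes there): observed intron count 0
  el <- tibble::tibble(family = "F", chrom = "c2",
                       start = c(1000, 2000), end = c(1100, 2100))
  enr <- enrichment_test(el, p, gm, ann, n_reps = 50, seed = 1)
  expect_equal(enr$p_intron_n[enr$family == "F"], 1)
  expect_equal(enr$p_intron_bp[enr$family == "F"], 1)
})

test_that("empirical probabilities are k/n_reps and monotone in the threshold", {
  gm <- toy_genome()
  ann <- toy_annotation(gm)
  p <- build_partition(gm, ann)
  set.seed(33)
  el <- random_intervals(60, c(c1 = 100000), max_len = 200)
  el$family <- "F"
  el <- categorize_elements(el, p)
  el <- el[el$category != "exonic", ]
  enr <- enrichment_test(el, p, gm, ann, n_reps = 80, seed = 2)
  ks <- enr$p_intron_n * 80
  expect_equal(ks, round(ks))
  expect_true(all(enr$p_intron_n >= 0 & enr$p_intron_n <= 1))
  # conservative variant shifts by the (k+1)/(n+1) rule
  enr_c <- enrichment_test(el, p, gm, ann, n_reps = 80, seed = 2,
                           conservative = TRUE)
  expect_equal(enr_c$p_intron_n, (ks + 1) / 81)
})

test_that("enrichment results are reproducible for identical seeds", {
  gm <- toy_genome()
  ann <- toy_annotation(gm)
  p <- build_partition(gm, ann)
  set.seed(34)
  el <- random_intervals(40, c(c1 = 100000), max_len = 200)
  el$family <- "F"
  el <- categorize_elements(el, p)
  el <- el[el$category != "exonic", , drop = FALSE]
  e1 <- enrichment_test(el, p, gm, ann, n_reps = 60, seed = 9)
  e2 <- enrichment_test(el, p, gm, ann, n_reps = 60, seed = 9)
  expect_equal(as.data.frame(e1), as.data.frame(e2))
})

test_that("nearest-gene distances match the exhaustive scan oracle", {
  gm <- toy_genome(c(c1 = 100000))
  set.seed(35)
  gstart <- seq(5000, 90000, by = 10000) + sample.int(2000, 9)
  genes <- tibble::tibble(gene_id = paste0("g", 1:9), chrom = "c1",
                          start = gstart, end = gstart + 3000)
  ann <- suppressMessages(annotation_set(genes, NULL, gm))
  el <- random_intervals(500, c(c1 = 100000), max_len = 400)
  el$family <- "F"
  got <- nearest_gene_distance(el, ann)$gene_distance
  want <- vapply(seq_len(nrow(el)), function(i) {
    d <- pmax(genes$start - el$end[i], el$start[i] - genes$end)
    max(min(pmax(d, 0)), 0)
  }, numeric(1))
  expect_equal(got, want)
})

test_that("nearest-gene distance handles bookended and two-sided cases", {
  gm <- toy_genome(c(c1 = 1000))
  ann <- suppressMessages(annotation_set(
    tibble::tibble(gene_id = c("g1", "g2"), chrom = "c1",
                   start = c(0, 400), end = c(50, 500)), NULL, gm))
  el <- tibble::tibble(family = "F", chrom = "c1",
                       start = c(100, 350), end = c(200, 400))
  d <- nearest_gene_distance(el, ann)$gene_distance
  expect_equal(d[1], 50)   # min(100-50, 400-200) = 50
  expect_equal(d[2], 0)    # bookended to g2
})

test_that("elements on gene-free chromosomes get an undefined distance", {
  gm <- toy_genome()
  ann <- toy_annotation(gm)  # genes only on c1
  el <- tibble::tibble(family = "F", chrom = "c2", start = 10, end = 60)
  expect_message(d <- nearest_gene_distance(el, ann), "without genes")
  expect_true(is.na(d$gene_distance))
})

test_that("two-sample K-S statistic and p match references", {
  # identical samples
  ks <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p_value, 1)
  # disjoint supports
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  # against stats::ks.test (asymptotic) and a brute-force pooled ECDF
  set.seed(36)
  for (rep in 1:100) {
    na <- sample(5:30, 1); nb <- sample(5:30, 1)
    a <- round(rnorm(na), 2); b <- round(rnorm(nb, 0.5), 2)
    got <- ks_two_sample(a, b)
    pts <- sort(unique(c(a, b)))
    D_brute <- max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x),
                              numeric(1))))
    expect_equal(got$statistic, D_brute, tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    # independent long-series evaluation of the asymptotic Kolmogorov tail
    lam <- sqrt(na * nb / (na + nb)) * D_brute
    p_series <- min(1, max(0, 2 * sum((-1)^(0:999) *
                                        exp(-2 * ((1:1000)^2) * lam^2))))
    expect_equal(got$p_value, p_series, tolerance = 1e-9)
    # R's reference truncates its series at a 1e-6 term tolerance, which
    # leaves up to ~3e-5 absolute error in its small-statistic branch
    expect_lt(abs(got$p_value - ref$p.value), 1e-4)
  }
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("distance profiles separate maximally when observed hugs genes", {
  gm <- toy_genome(c(c1 = 50000))
  ann <- suppressMessages(annotation_set(
    tibble::tibble(gene_id = "g", chrom = "c1", start = 20000, end = 25000),
    NULL, gm))
  # all observed elements bookended to the gene: all distances 0
  el <- tibble::tibble(family = "F", chrom = "c1",
                       start = rep(25000, 5) + c(0, 0, 0, 0, 0), end = 25100)
  dp <- distance_null(el, gm, ann, n_reps = 30, seed = 4)
  expect_equal(unique(dp$observed), 0)
  # null distances strictly positive almost surely -> D near 1
  expect_gt(dp$statistic, 0.9)
  expect_equal(dp$direction, "closer")
})

test_that("a null-true observed set yields small D and large p", {
  gm <- toy_genome()
  ann <- toy_annotation(gm)
  allowed <- allowed_space(gm, ann, exclude = c("gaps", "genes"))
  base <- tibble::tibble(family = rep("F", 150), chrom = "c1",
                         start = 0, end = 80)
  obs <- shuffle_elements(base, gm, allowed, seed = 77)
  dp <- distance_null(obs, gm, ann, n_reps = 50, seed = 78)
  expect_gt(dp$p_value, 0.01)
  expect_lt(dp$statistic, 0.2)
})

test_that("empty intergenic sets are rejected", {
  gm <- toy_genome()
  ann <- toy_annotation(gm)
  el <- tibble::tibble(family = character(), chrom = character(),
                       start = numeric(), end = numeric())
  expect_error(distance_null(el, gm, ann), "empty intergenic")
})
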