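# Genome partition, element categorization, and position summaries.

test_that("introns are the gaps between consecutive exons", {
  expect_equal(
    derive_introns(tibble::tibble(start = c(0, 200), end = c(100, 300))),
    tibble::tibble(start = 100, end = 200))
  # single-exon gene: no introns
  expect_equal(nrow(derive_introns(tibble::tibble(start = 0, end = 300))), 0)
})

test_that("introns equal the complement of exons within the span (oracle)", {
  set.seed(21)
  for (rep in 1:30) {
    k <- sample(1:6, 1)
    bounds <- sort(sample.int(5000, 2 * k))
    exons <- tibble::tibble(start = bounds[seq(1, 2 * k, 2)],
                            end = bounds[seq(2, 2 * k, 2)])
    introns <- derive_introns(exons)
    # oracle: set complement within [min(start), max(end))
    span <- c(min(exons$start), max(exons$end))
    lab <- rep(FALSE, span[2])
    for (i in seq_len(k)) lab[(exons$start[i] + 1):exons$end[i]] <- TRUE
    inside <- which(!lab[(span[1] + 1):span[2]]) + span[1]
    got <- if (nrow(introns) == 0) integer(0) else
      unlist(lapply(seq_len(nrow(introns)),
                    function(i) (introns$start[i] + 1):introns$end[i]))
    expect_equal(sort(got), inside)
  }
})

test_that("empty annotation yields an all-intergenic partition", {
  gm <- toy_genome()
  ann <- suppressMessages(annotation_set(
    tibble::tibble(gene_id = character(), chrom = character(),
                   start = numeric(), end = numeric()), NULL, gm))
  p <- build_partition(gm, ann)
  expect_equal(sum(p$totals$bp[p$totals$category == "intergenic"]), 150000)
  expect_equal(sum(p$totals$bp), 150000)
})

test_that("partition covers every chromosome exactly and disjointly", {
  gm <- toy_genome()
  p <- build_partition(gm, toy_annotation(gm))
  expect_equal(sum(p$totals$bp), sum(gm$chromosomes$length))
  iv <- p$intervals[order(p$intervals$chrom, p$intervals$start), ]
  for (ch in gm$chromosomes$chrom) {
    d <- iv[iv$chrom == ch, ]
    expect_equal(d$start, c(0, d$end[-nrow(d)]))
    expect_equal(d$end[nrow(d)],
                 gm$chromosomes$length[gm$chromosomes$chrom == ch])
  }
})

test_that("exon of one gene overlapping the intron of another wins", {
  gm <- toy_genome(c(c1 = 10000))
  ann <- suppressMessages(annotation_set(
    tibble::tibble(gene_id = c("a", "b"), chrom = "c1",
                   start = c(1000, 1400), end = c(3000, 2600)),
    tibble::tibble(gene_id = c("a", "a", "b"), chrom = "c1",
                   start = c(1000, 2800, 1400), end = c(1200, 3000, 2600)),
    gm))
  p <- build_partition(gm, ann)
  # gene b's exon (1400,2600) lies inside gene a's intron (1200,2800)
  el <- tibble::tibble(family = "F", chrom = "c1", start = 1500, end = 1600)
  expect_equal(categorize_elements(el, p)$category, "exonic")
})

test_that("categorization matches a per-bp labeling oracle", {
  set.seed(22)
  gm <- toy_genome(c(c1 = 100000))
  # random gene structures
  gstart <- sort(sample.int(90000, 8)) ; gstart <- gstart[c(TRUE, diff(gstart) > 6000)]
  genes <- tibble::tibble(
    gene_id = paste0("g", seq_along(gstart)), chrom = "c1",
    start = gstart, end = gstart + 4000)
  exons <- dplyr::bind_rows(lapply(seq_along(gstart), function(i) {
    tibble::tibble(gene_id = genes$gene_id[i], chrom = "c1",
                   start = gstart[i] + c(0, 1500, 3300),
                   end = gstart[i] + c(800, 2500, 4000))
  }))
  ann <- suppressMessages(annotation_set(genes, exons, gm))
  p <- build_partition(gm, ann)
  lab <- perbp_labels(p, "c1", 100000)
  el <- random_intervals(1000, c(c1 = 100000), max_len = 800)
  el$family <- "F"
  got <- categorize_elements(el, p)$category
  want <- vapply(seq_len(nrow(el)), function(i) {
    perbp_category(lab, el$start[i], el$end[i])
  }, character(1))
  expect_equal(got, want)
})

test_that("1 bp of exon overlap makes an element exonic; gene body beats intergenic", {
  gm <- toy_genome()
  p <- build_partition(gm, toy_annotation(gm))
  # exon a2 spans (2500,3000); element overlapping its last bp
  el <- tibble::tibble(family = "F", chrom = "c1",
                       start = c(2999, 1600, 900),
                       end = c(3200, 2400, 1100))
  got <- categorize_elements(el, p)$category
  expect_equal(got, c("exonic", "intronic", "exonic"))
  # element straddling the gene-body/intergenic boundary without touching
  # an exon: gene-body (intron) precedence over intergenic
  ann2 <- suppressMessages(annotation_set(
    tibble::tibble(gene_id = "g", chrom = "c1", start = 1000, end = 5000),
    tibble::tibble(gene_id = c("g", "g"), chrom = "c1",
                   start = c(1000, 3000), end = c(2000, 3500)), gm))
  p2 <- build_partition(gm, ann2)
  el2 <- tibble::tibble(family = "F", chrom = "c1", start = 4000, end = 6000)
  expect_equal(categorize_elements(el2, p2)$category, "intronic")
})

test_that("summaries reproduce the published per-family position table", {
  pos <- tcast_position_table()
  s <- summarize_position_counts(pos)
  # bp-based percent in introns, published to one decimal
  expect_equal(round(s$pct_introns_bp[s$family == "TCAST3"], 1), 64.3)
  expect_equal(round(s$pct_introns_bp[s$family == "TCAST1"], 1), 55.6)
  expect_equal(round(s$pct_introns_n[s$family == "TCAST3"], 1), 61.7)
  all_row <- s[s$family == "All", ]
  expect_equal(all_row$intronic_n, 1416L)
  expect_equal(all_row$intergenic_n, 957L)
  expect_equal(round(all_row$pct_introns_n, 1), 59.4)
})

test_that("summarize_partition is order-invariant and consistent", {
  gm <- toy_genome()
  p <- build_partition(gm, toy_annotation(gm))
  set.seed(23)
  el <- random_intervals(200, c(c1 = 100000), max_len = 400)
  el$family <- sample(c("F1", "F2"), 200, replace = TRUE)
  s1 <- summarize_partition(el, p)
  s2 <- summarize_partition(el[sample.int(200), ], p)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  # per-family counts sum to the family total
  expect_equal(s1$intergenic_n + s1$intronic_n + s1$exonic_n, s1$total_n)
  # grand totals equal column sums of the family rows
  fam_rows <- s1[s1$family != "All", ]
  expect_equal(s1$total_n[s1$family == "All"], sum(fam_rows$total_n))
})

test_that("all elements in one intron give 100 percent for both measures", {
  gm <- toy_genome()
  p <- build_partition(gm, toy_annotation(gm))
  el <- tibble::tibble(family = "F", chrom = "c1",
                       start = c(1600, 1700, 1800), end = c(1650, 1750, 1850))
  s <- summarize_partition(el, p)
  expect_equal(s$pct_introns_bp, c(100, 100))
  expect_equal(s$pct_introns_n, c(100, 100))
})

test_that("element category is stable under splitting at any internal point", {
  gm <- toy_genome()
  p <- build_partition(gm, toy_annotation(gm))
  set.seed(24)
  el <- random_intervals(50, c(c1 = 100000), max_len = 600)
  el <- el[el$end - el$start >= 2, ]
  el$family <- "F"
  whole <- categorize_elements(el, p)$category
  prec <- c(exonic = 3, intronic = 2, intergenic = 1)
  for (i in seq_len(nrow(el))) {
    cut <- el$start[i] + sample.int(el$end[i] - el$start[i] - 1, 1)
    parts <- tibble::tibble(family = "F", chrom = el$chrom[i],
                            start = c(el$start[i], cut),
                            end = c(cut, el$end[i]))
    pcats <- categorize_elements(parts, p)$category
    expect_equal(whole[i], pcats[which.max(prec[pcats])])
  }
})
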