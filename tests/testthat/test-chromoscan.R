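# Count tables, regressions, binned profiles and colocalization.

test_that("count table matches generator bookkeeping and handles empties", {
  gm <- toy_genome()
  ann <- toy_annotation(gm)
  set.seed(41)
  el <- dplyr::bind_rows(
    random_intervals(30, c(c1 = 100000), max_len = 100),
    random_intervals(20, c(c2 = 50000), max_len = 100))
  el$family <- sample(c("F1", "F2"), 50, replace = TRUE)
  ct <- count_table(el, ann, gm)
  expect_equal(ct$all_elements, c(30, 20))
  expect_equal(sum(ct$F1) + sum(ct$F2), 50)
  expect_equal(ct$n_genes, c(2, 0))
  # column sums equal per-family totals
  expect_equal(sum(ct$F1), sum(el$family == "F1"))
  # empty set
  ct0 <- count_table(el[0, ], ann, gm)
  expect_equal(ct0$all_elements, c(0, 0))
})

test_that("the published count table reproduces the printed regressions", {
  ct <- tcast_chromosome_table()
  f_all <- linear_fit("chrom_size", "all_tcast", data = ct)
  expect_equal(round(f_all$r_squared, 3), 0.813)
  f_genes <- linear_fit("chrom_size", "n_genes", data = ct)
  expect_equal(round(f_genes$r_squared, 3), 0.569)
  expect_equal(round(f_genes$p_value, 3), 0.012)
  f7 <- linear_fit("chrom_size", "TCAST7", data = ct)
  expect_equal(round(f7$r_squared, 3), 0.053)
  expect_equal(round(f7$p_value, 3), 0.524)
  f_ag <- linear_fit("n_genes", "all_tcast", data = ct)
  expect_equal(round(f_ag$r_squared, 3), 0.194)
  expect_equal(round(f_ag$p_value, 3), 0.202)
  # gene-number association of the two families the study flags
  expect_equal(round(linear_fit("n_genes", "TCAST8", data = ct)$r_squared, 3),
               0.415)
  expect_equal(round(linear_fit("n_genes", "TCAST10", data = ct)$r_squared, 3),
               0.414)
})

test_that("linear_fit matches closed-form normal equations", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n, sd = 10)
    y <- 2 + 0.5 * x + rnorm(n)
    f <- linear_fit(x, y)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    yhat <- intercept + slope * x
    r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    se <- sqrt(sum((y - yhat)^2) / (n - 2) / sum((x - mean(x))^2))
    p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
    expect_equal(f$slope, slope, tolerance = 1e-10)
    expect_equal(f$intercept, intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, r2, tolerance = 1e-10)
    expect_equal(f$p_value, p, tolerance = 1e-10)
  }
})

test_that("linear_fit degenerate inputs error; perfect fits behave", {
  expect_error(linear_fit(1:2, 1:2), "at least 3")
  expect_error(linear_fit(c(1, 1, 1), 1:3), "constant")
  f <- suppressWarnings(linear_fit(1:10, 2 * (1:10)))
  expect_equal(f$r_squared, 1)
  expect_lt(f$p_value, 1e-10)
})

test_that("linear_fit is scale-equivariant", {
  set.seed(43)
  x <- rnorm(10); y <- 1 + x + rnorm(10)
  f1 <- linear_fit(x, y)
  f2 <- linear_fit(1000 * x, y)
  expect_equal(f2$slope, f1$slope / 1000, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-12)
})

test_that("regression_suite emits the full fit matrix", {
  ct <- tcast_chromosome_table() %>% dplyr::rename(all_elements = all_tcast)
  rs <- regression_suite(ct)
  # 10 families x 2 predictors + totals x 2 + genes ~ size
  expect_equal(nrow(rs), 23)
  expect_equal(
    round(rs$r_squared[rs$response == "n_genes" &
                         rs$predictor == "chrom_size"], 3), 0.569)
  expect_true(all(rs$n == 10))
})

test_that("tenths binning follows the floor-boundary, half-open convention", {
  gm <- toy_genome(c(c1 = 1005))
  # start exactly on a boundary goes to the right bin
  el <- tibble::tibble(family = "F", chrom = "c1",
                       start = c(0, 100, 201, 904), end = c(1, 101, 202, 905))
  prof <- bin_profile(el, gm, scheme = "tenths")
  got <- prof$n[prof$track == "F"]
  # boundaries floor(i*1005/10): 100, 201, ... start 100 -> bin 1? oracle:
  oracle <- vapply(el$start, function(p) {
    min(floor(p * 10 / 1005) + 1, 10)
  }, numeric(1))
  expect_equal(which(got > 0), sort(unique(oracle)))
  expect_equal(sum(got), 4)
})

test_that("bin counts match the floor-division oracle and conserve totals", {
  set.seed(44)
  lens <- c(c1 = 98765, c2 = 54321)
  gm <- toy_genome(lens)
  el <- random_intervals(400, lens, max_len = 50)
  el$family <- sample(c("A", "B"), 400, replace = TRUE)
  for (scheme in c("tenths", "fixed_1mb")) {
    prof <- bin_profile(el, gm, scheme = scheme)
    per_chrom <- prof %>% dplyr::group_by(chrom, track) %>%
      dplyr::summarise(n = sum(n), pct = sum(percent), .groups = "drop")
    for (tr in c("A", "B")) {
      for (ch in names(lens)) {
        want <- sum(el$family == tr & el$chrom == ch)
        expect_equal(per_chrom$n[per_chrom$chrom == ch & per_chrom$track == tr],
                     want)
        if (want > 0) {
          expect_equal(
            per_chrom$pct[per_chrom$chrom == ch & per_chrom$track == tr], 100)
        }
      }
    }
  }
  # per-feature oracle for tenths
  prof <- bin_profile(el, gm, scheme = "tenths")
  for (i in sample.int(400, 30)) {
    b <- min(floor(el$start[i] * 10 / lens[[el$chrom[i]]]) + 1, 10)
    row <- prof[prof$chrom == el$chrom[i] & prof$track == el$family[i] &
                  prof$bin == b, ]
    expect_gte(row$n, 1)
  }
})

test_that("a fully end-clustered track shows 100 percent in the last tenth", {
  gm <- toy_genome(c(c1 = 10000))
  el <- tibble::tibble(family = "F", chrom = "c1",
                       start = 9000 + (0:9) * 90, end = 9000 + (0:9) * 90 + 10)
  prof <- bin_profile(el, gm, scheme = "tenths")
  expect_equal(prof$percent[prof$bin == 10], 100)
  expect_equal(sum(prof$percent[prof$bin < 10]), 0)
})

test_that("colocalization is symmetric, unit-diagonal, and matches the formula", {
  gm <- toy_genome(c(c1 = 10000))
  set.seed(45)
  el <- random_intervals(300, c(c1 = 10000), max_len = 10)
  el$family <- sample(c("A", "B", "C"), 300, replace = TRUE)
  prof <- bin_profile(el, gm, scheme = "tenths")
  cc <- colocalization(prof)
  # diagonal r = 1
  diag_rows <- cc[cc$track_a == cc$track_b, ]
  expect_true(all(diag_rows$r == 1))
  # symmetry
  ab <- cc$r[cc$chrom == "c1" & cc$track_a == "A" & cc$track_b == "B"]
  ba <- cc$r[cc$chrom == "c1" & cc$track_a == "B" & cc$track_b == "A"]
  expect_equal(ab, ba)
  # direct covariance-formula oracle
  va <- prof$n[prof$track == "A"][order(prof$bin[prof$track == "A"])]
  vb <- prof$n[prof$track == "B"][order(prof$bin[prof$track == "B"])]
  r_oracle <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(ab, r_oracle, tolerance = 1e-12)
})

test_that("identical profiles give r = 1; reversal of a skewed profile r < 0", {
  prof <- tibble::tibble(
    chrom = "c1",
    track = rep(c("A", "B", "C"), each = 10),
    bin = rep(1:10, 3),
    n = c(10:1, 10:1, 1:10),
    percent = 0)
  cc <- colocalization(prof)
  expect_equal(cc$r[cc$track_a == "A" & cc$track_b == "B" & cc$chrom == "c1"], 1)
  expect_lt(cc$r[cc$track_a == "A" & cc$track_b == "C" & cc$chrom == "c1"], 0)
  expect_true(cc$significant[cc$track_a == "A" & cc$track_b == "B" &
                               cc$chrom == "c1"])
})

test_that("zero-variance tracks are reported as NA", {
  prof <- tibble::tibble(
    chrom = "c1", track = rep(c("A", "B"), each = 10),
    bin = rep(1:10, 2), n = c(rep(2, 10), 1:10), percent = 0)
  expect_message(cc <- colocalization(prof), "zero-variance")
  expect_true(is.na(cc$r[cc$track_a == "A" & cc$track_b == "B" &
                           cc$chrom == "c1"]))
})
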