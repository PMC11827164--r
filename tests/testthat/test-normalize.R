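test_that("median-of-ratios size factors match hand arithmetic and symmetries", {
  # sample2 = 2 x sample1 gene-wise: factors must keep the 1:2 ratio and
  # have geometric mean 1, i.e. (1/sqrt(2), sqrt(2))
  x <- toy_matrix(matrix(c(2, 10, 50, 4, 20, 100), ncol = 2), stage = "raw")
  sf <- median_of_ratios_size_factors(x)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical samples -> all factors equal (and hence 1)
  y <- toy_matrix(matrix(rep(c(3, 7, 11), 3), ncol = 3), stage = "raw")
  expect_equal(unname(median_of_ratios_size_factors(y)), rep(1, 3),
               tolerance = 1e-12)

  # single sample -> factor 1 under the geometric-mean-1 rule
  z <- toy_matrix(matrix(c(5, 9), ncol = 1), stage = "raw")
  expect_equal(unname(median_of_ratios_size_factors(z)), 1, tolerance = 1e-12)

  # invariant under gene reordering
  set.seed(7)
  m <- matrix(rpois(60, 100) + 1, nrow = 20)
  a <- toy_matrix(m, stage = "raw")
  b <- toy_matrix(m[20:1, , drop = FALSE],
                  genes = sprintf("g%02d", 20:1), stage = "raw")
  expect_equal(unname(median_of_ratios_size_factors(a)),
               unname(median_of_ratios_size_factors(b)), tolerance = 1e-12)

  # all-zero gene contributes nothing to the geometric-mean reference
  m0 <- rbind(m, 0)
  expect_equal(unname(median_of_ratios_size_factors(
                 toy_matrix(m0, stage = "raw"))),
               unname(median_of_ratios_size_factors(a)), tolerance = 1e-12)

  # no gene positive everywhere -> hard error
  bad <- toy_matrix(matrix(c(0, 5, 5, 0), 2, 2), stage = "raw")
  expect_error(median_of_ratios_size_factors(bad), "positive")
})

test_that("scaling one sample by c scales its factor by c and leaves normalized values unchanged", {
  set.seed(21)
  m <- matrix(rpois(200, 80) + 1, nrow = 50)
  x <- toy_matrix(m, stage = "raw")
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  x2 <- toy_matrix(m2, stage = "raw")
  sf1 <- median_of_ratios_size_factors(x)
  sf2 <- median_of_ratios_size_factors(x2)
  # relative to any other sample the scaled sample's factor gains exactly c
  expect_equal(unname(sf2[3] / sf2[1]), unname(4 * sf1[3] / sf1[1]),
               tolerance = 1e-10)
  # normalized values are unchanged up to the single global constant the
  # geometric-mean-1 convention absorbs
  n1 <- unclass(normalize_counts(x, sf1))
  n2 <- unclass(normalize_counts(x2, sf2))
  ratio <- n2 / n1
  expect_lt(max(ratio) - min(ratio), 1e-10)
})

test_that("size factors agree with the DESeq2 estimator on all-positive data", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  # odd number of all-positive genes: the sample median is a single order
  # statistic, so the two formulations coincide exactly
  m <- matrix(rnbinom(101 * 6, mu = 150, size = 8) + 1, nrow = 101)
  x <- toy_matrix(m, stage = "raw")
  mine <- median_of_ratios_size_factors(x)
  ref <- DESeq2::estimateSizeFactorsForMatrix(unclass(x))
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("normalize_and_average averages replicates, rounds half away, passes singletons", {
  m <- matrix(c(2, 3, 4, 4, 7, 5), nrow = 2,
              dimnames = list(c("gA", "gB"),
                              c("c1_r1", "c1_r2", "c2_r1")))
  x <- count_matrix(m, stage = "raw")
  sheet <- data.frame(sample_id = colnames(m),
                      condition = c("c1", "c1", "c2"),
                      replicate = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  sf <- setNames(rep(1, 3), colnames(m))
  avg <- normalize_and_average(x, sheet, size_factors = sf)
  expect_identical(matrix_stage(avg), "averaged")
  expect_identical(colnames(avg), c("c1", "c2"))
  expect_equal(unclass(avg)["gA", ], c(c1 = 3, c2 = 7))    # mean(2,4)=3
  expect_equal(unclass(avg)["gB", ], c(c1 = 4, c2 = 5))    # mean(3,4)=3.5 -> 4
  # a sample missing from the sheet is an error
  expect_error(normalize_and_average(x, sheet[-3, ], size_factors = sf),
               "absent")
})

test_that("expression tiers follow strict housekeeping-relative thresholds", {
  # housekeeping mean is 1000 in both conditions; peak ratios by design:
  # 0.6, 0.2, 0.02, 0.005, 0 -> high, moderate, detectable, below, below
  m <- rbind(hk1 = c(900, 1100), hk2 = c(1100, 900),
             gA = c(600, 100), gB = c(10, 200), gC = c(20, 1),
             gD = c(5, 0), gE = c(0, 0))
  colnames(m) <- c("c1", "c2")
  avg <- count_matrix(m, stage = "averaged")
  cls <- classify_expression(avg, housekeeping = c("hk1", "hk2"))
  tiers <- setNames(as.character(cls$tier), cls$gene_id)
  expect_identical(unname(tiers[c("gA", "gB", "gC", "gD", "gE")]),
                   c("high", "moderate", "detectable", "below", "below"))
  # a gene matching the housekeeping mean exactly (ratio 1) is high
  expect_identical(unname(tiers["hk1"]), "high")
  s <- classification_summary(cls)
  expect_equal(unname(s$nested["detectable"]), 5)  # hk1, hk2, gA, gB, gC
  expect_equal(sum(s$disjoint), s$n_genes)

  # silent housekeeping reference is a data problem
  m2 <- m; m2[c("hk1", "hk2"), 2] <- 0
  expect_error(classify_expression(count_matrix(m2, stage = "averaged"),
                                   housekeeping = c("hk1", "hk2")),
               "housekeeping")
})

test_that("raising a gene's counts never lowers its tier", {
  set.seed(5)
  for (i in 1:25) {
    base <- matrix(rpois(40, 50), nrow = 4,
                   dimnames = list(c("hk", "g1", "g2", "g3"),
                                   sprintf("c%d", 1:10)))
    base["hk", ] <- base["hk", ] + 500
    avg <- count_matrix(base, stage = "averaged")
    cls <- classify_expression(avg, housekeeping = "hk")
    bumped <- base
    bumped["g2", ] <- bumped["g2", ] + rpois(10, 30)
    cls2 <- classify_expression(count_matrix(bumped, stage = "averaged"),
                                housekeeping = "hk")
    tier_rank <- function(cl, g)
      match(as.character(cl$tier[cl$gene_id == g]),
            c("below", "detectable", "moderate", "high"))
    expect_gte(tier_rank(cls2, "g2"), tier_rank(cls, "g2"))
  }
})

test_that("log10 heat-map transform applies the zero rule and validates the scale", {
  m <- toy_matrix(matrix(c(1e10, 0, 1000, 0.5), 2, 2))
  hm <- log10_heatmap(m)
  expect_equal(as.vector(hm), c(10, 0, 3, 0))
  expect_equal(attr(hm, "ceiling"), 10)
  expect_error(log10_heatmap(m, floor = 10, ceiling = 4.5), "floor")
  raw <- toy_matrix(matrix(1:4, 2, 2), stage = "raw")
  expect_error(log10_heatmap(raw), "stage")
})

test_that("printed-style proportion and category arithmetic behaves", {
  expect_equal(proportion_percent(0, 7), 0)
  expect_equal(proportion_percent(1, 3, decimals = 2), 33.33)
  expect_error(proportion_percent(5, 0), "denominator")
  expect_error(proportion_percent(8, 7), "numerator")
  # complement property: the two rounded halves differ from 100 only by
  # rounding slack
  set.seed(9)
  for (i in 1:50) {
    b <- sample(1:5000, 1); a <- sample(0:b, 1)
    tot <- proportion_percent(a, b) + proportion_percent(b - a, b)
    expect_lte(abs(tot - 100), 1)       # 10^(1 - decimals) with decimals = 1
  }
  expect_identical(category_sum(numeric(0)), 0L)
  expect_identical(category_sum(c(a = 2, b = 3)), 5L)
  expect_error(category_sum(c(1, -2)), "negative")
})
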