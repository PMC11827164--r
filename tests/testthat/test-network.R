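test_that("spearman_rho equals the brute-force rank-then-Pearson oracle", {
  # the worked tie example: ranks (1, 2.5, 2.5, 4) vs (1, 2, 3, 4)
  x <- c(1, 2, 2, 4); y <- c(10, 20, 30, 40)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-14)

  expect_equal(spearman_rho(c(3, 1, 7, 5), c(3, 1, 7, 5)), 1)
  expect_equal(spearman_rho(c(3, 1, 7, 5), c(-3, -1, -7, -5)), -1)
  expect_true(is.na(spearman_rho(rep(2, 5), 1:5)))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")

  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    a <- if (i %% 2) rnorm(n) else sample(1:4, n, replace = TRUE)  # ties
    b <- if (i %% 3) rnorm(n) else sample(1:3, n, replace = TRUE)
    if (max(a) == min(a) || max(b) == min(b)) next
    r <- spearman_rho(a, b)
    expect_equal(r, oracle_spearman(a, b), tolerance = 1e-12)
    # built-in cross-check and symmetry
    expect_equal(r, cor(a, b, method = "spearman"), tolerance = 1e-12)
    expect_equal(r, spearman_rho(b, a), tolerance = 1e-14)
    expect_lte(abs(r), 1 + 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(spearman_rho(exp(a), b), r, tolerance = 1e-12)
  }
})

test_that("correlation p-values: t approximation and permutation nulls", {
  expect_equal(correlation_pvalue(0, 10, "t_approx"), 1)
  expect_equal(correlation_pvalue(0, 5, "permutation"), 1)
  expect_message(p1 <- correlation_pvalue(1, 8, "t_approx"), "rho")
  expect_equal(p1, 0)

  # exhaustive permutation at n = 5 equals independent enumeration exactly
  set.seed(55)
  for (i in 1:6) {
    x <- if (i %% 2) rnorm(5) else c(1, 1, 2, 3, 3)   # with ties
    y <- rnorm(5)
    rho <- spearman_rho(x, y)
    expect_identical(correlation_pvalue(rho, 5, "permutation", x = x, y = y),
                     oracle_perm_pvalue(x, y))
  }

  # monotone-ish pair at n = 27: t approximation within Monte-Carlo error
  # of the resampled permutation p-value
  set.seed(77)
  x <- rnorm(27); y <- 0.6 * x + rnorm(27)
  rho <- spearman_rho(x, y)
  pt_ <- correlation_pvalue(rho, 27, "t_approx")
  pp <- correlation_pvalue(rho, 27, "permutation", x = x, y = y,
                           n_resamples = 10000)
  se <- sqrt(pp * (1 - pp) / 10000)
  expect_lt(abs(pt_ - pp), 3 * se + 1e-4)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))              # BH never lowers a p-value
    expect_true(all(diff(q[order(p)]) >= -1e-15)) # monotone in sorted order
  }
})

test_that("count_pairs gives the closed-form pair count", {
  expect_equal(count_pairs(13), 78)
  expect_equal(count_pairs(2), 1)
  expect_equal(count_pairs(40), 780)
  expect_equal(count_pairs(0), 0)
  expect_error(count_pairs(-1), "non-negative")
})

test_that("pairwise_edges evaluates all cohort pairs and filters by rho and q", {
  set.seed(42)
  m <- matrix(rpois(13 * 27, 50), nrow = 13,
              dimnames = list(sprintf("g%02d", 1:13), sprintf("c%02d", 1:27)))
  avg <- count_matrix(m, stage = "averaged")
  edges <- pairwise_edges(avg, rownames(m))
  expect_equal(attr(edges, "n_candidates"), 78)
  expect_true(all(edges$rho > 0.4 & edges$q < 0.05))
  expect_true(all(edges$gene_a < edges$gene_b))

  # identical profiles give a single rho = 1 pair
  two <- count_matrix(rbind(a = m[1, ], b = m[1, ]), stage = "averaged")
  suppressMessages(e2 <- pairwise_edges(two, c("a", "b")))
  expect_equal(nrow(e2), 1)
  expect_equal(e2$rho, 1)

  # constant genes are excluded and reported, missing genes are an error
  with_const <- count_matrix(rbind(m, flat = rep(3, 27)), stage = "averaged")
  expect_message(e3 <- pairwise_edges(with_const, rownames(with_const)),
                 "constant")
  expect_identical(attr(e3, "excluded_constant"), "flat")
  expect_equal(attr(e3, "n_candidates"), 78)
  expect_error(pairwise_edges(avg, c("g01", "nope")), "nope")
})

test_that("planted module pairs are retained and cross pairs rejected", {
  cfg <- simulation_config(n_genes = 30, seed = 3)
  sim <- simulate_dataset(cfg, list(planted_module(1:5, loading_for_rho(0.9))))
  avg <- normalize_and_average(sim$counts, sim$sheet)
  cohort <- sprintf("g%05d", c(1:5, 11:15))
  edges <- pairwise_edges(avg, cohort)
  planted <- sprintf("g%05d", 1:5)
  within <- edges$gene_a %in% planted & edges$gene_b %in% planted
  expect_equal(sum(within), 10)           # all C(5,2) module pairs retained
  expect_lte(sum(!within), 2)             # cross/null pairs overwhelmingly out
})

test_that("all_vs_one ranks an exact copy first and controls its family", {
  set.seed(8)
  m <- matrix(rpois(100 * 20, 60), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:20)))
  m[2, ] <- m[1, ]                         # exact copy of the focal profile
  avg <- count_matrix(m, stage = "averaged")
  suppressMessages(edges <- all_vs_one(avg, "g001"))
  expect_equal(nrow(edges), 99)
  top <- edges[1, ]
  expect_equal(sort(c(top$gene_a, top$gene_b)), c("g001", "g002"))
  expect_equal(top$rho, 1)
  expect_identical(attr(edges, "focal"), "g001")

  flat <- count_matrix(rbind(flat = rep(5, 20), m), stage = "averaged")
  expect_error(all_vs_one(flat, "flat"), "constant")
})

test_that("top_k_module keeps the k best partners with lexicographic ties", {
  rho <- c(0.99, 0.98, 0.97, 0.96, 0.95, 0.94, 0.93, 0.92, 0.91,
           0.90, 0.90, 0.89)
  partners <- sprintf("p%02d", 12:1)      # ids anti-sorted vs rho
  edges <- data.frame(gene_a = pmin("focal", partners),
                      gene_b = pmax("focal", partners),
                      rho = rho, p = 1e-9, q = 1e-8,
                      sign = "+", stringsAsFactors = FALSE)
  attr(edges, "focal") <- "focal"
  mod <- top_k_module(edges, k = 10,
                      params = network_params(rho_threshold = 0.5,
                                              alpha = 0.05))
  expect_equal(nrow(mod$partners), 10)
  expect_equal(mod$partners$rho[1], 0.99)
  # two partners tied at 0.90 at the cut: the lexicographically smaller of
  # p02/p03 survives
  tied <- partners[rho == 0.90]
  expect_true(min(tied) %in% mod$partners$partner)
  expect_false(max(tied) %in% mod$partners$partner)
  # fewer survivors than k gives a shorter module with a note
  edges$q <- c(rep(1e-8, 3), rep(0.5, 9))
  expect_message(short <- top_k_module(edges, k = 10,
                                       params = network_params(0.5, 0.05)),
                 "3 significant")
  expect_equal(nrow(short$partners), 3)
})

test_that("regulator embedding counts signed significant connections", {
  set.seed(12)
  base <- rpois(20, 200)
  noise <- function() rnorm(20, 0, 4)
  cohort <- t(sapply(1:4, function(i) base + noise()))
  cand_act <- base + noise()               # tracks the cohort
  cand_null <- rpois(20, 200)              # independent
  m <- rbind(cohort, act = cand_act, null = cand_null)
  rownames(m) <- c(sprintf("coh%d", 1:4), "act", "null")
  colnames(m) <- sprintf("c%02d", 1:20)
  avg <- count_matrix(round(m), stage = "averaged")
  sc <- regulator_embedding(avg, sprintf("coh%d", 1:4), c("act", "null"))
  expect_identical(sc$regulator[1], "act")
  expect_equal(sc$n_positive[sc$regulator == "act"], 4)
  expect_lte(sc$n_positive[sc$regulator == "null"] +
             sc$n_negative[sc$regulator == "null"], 1)
  expect_true(all(sc$cohort_size == 4))

  expect_warning(regulator_embedding(avg, sprintf("coh%d", 1:4),
                                     c("coh1", "act")), "overlap")
  expect_error(suppressWarnings(
    regulator_embedding(avg, sprintf("coh%d", 1:4), "coh1")), "no candidate")
})
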