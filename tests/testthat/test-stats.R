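test_that("chi-square handles the closed-form cases", {
  # proportional rows are independent by construction
  prop <- matrix(c(10, 20, 20, 40), 2, byrow = TRUE)
  res <- chi_square_independence(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # [[10,20],[20,10]]: all expected 15 -> X2 = 4 * 25/15
  res2 <- chi_square_independence(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res2$df, 1)
  # df formula for arbitrary shapes
  set.seed(4)
  for (rep in 1:5) {
    r <- sample(2:5, 1); cc <- sample(2:5, 1)
    tab <- matrix(stats::rpois(r * cc, 8) + 1, r, cc)
    expect_equal(chi_square_independence(tab)$df, (r - 1) * (cc - 1))
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero row margin")
  expect_error(chi_square_independence(matrix(1:3, 3, 1)), "at least 2")
})

test_that("chi-square is permutation-invariant and matches brute force", {
  set.seed(10)
  for (rep in 1:20) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(stats::rpois(r * cc, 10) + 1, r, cc)
    res <- chi_square_independence(tab)
    orc <- oracle_chisq(tab)
    expect_equal(res$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
    perm <- tab[sample(r), sample(cc), drop = FALSE]
    expect_equal(chi_square_independence(perm)$statistic, res$statistic,
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis handles symmetric, hand-computed and degenerate cases", {
  expect_equal(kruskal_wallis(list(1:3, 1:3))$statistic, 0, tolerance = 1e-12)
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-10)  # 4.571
  expect_equal(res$df, 2)
  deg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1, 2)), "at least 3")
})

test_that("H is invariant to group order and monotone transforms; matches oracle", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) {
      round(stats::rnorm(sample(3:8, 1), mean = i), 1)
    })
    h <- kruskal_wallis(groups)$statistic
    expect_equal(h, oracle_kw(groups), tolerance = 1e-10)
    expect_equal(kruskal_wallis(rev(groups))$statistic, h, tolerance = 1e-10)
    expect_equal(kruskal_wallis(lapply(groups, function(g) exp(g)))$statistic,
                 h, tolerance = 1e-10)
  }
})

test_that("Dunn pairwise z and Bonferroni adjustment behave as specified", {
  # identical groups: all adjusted p = 1
  same <- posthoc_dunn_bonferroni(list(a = 1:4, b = 1:4, c = 1:4))
  expect_true(all(same$pairs$p_adj > 0.9))
  expect_equal(nrow(same$pairs), 3)  # k = 3 -> 3 pairs
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) round(stats::rnorm(sample(3:7, 1), i), 1))
    names(groups) <- paste0("g", seq_len(k))
    res <- posthoc_dunn_bonferroni(groups)
    expect_equal(res$pairs$z, unname(oracle_dunn_z(groups)), tolerance = 1e-10)
    expect_true(all(res$pairs$p_adj >= res$pairs$p - 1e-12))
    expect_true(all(res$pairs$p_adj <= 1))
    m <- k * (k - 1) / 2
    expect_equal(res$pairs$p_adj, pmin(1, res$pairs$p * m), tolerance = 1e-12)
  }
  # a single pair: adjusted equals raw
  two <- posthoc_dunn_bonferroni(list(x = c(1, 5, 3), y = c(9, 7, 8)))
  expect_equal(two$pairs$p_adj, two$pairs$p)
})

test_that("compare_methods is calibrated under the null and powered under shift", {
  # identical pi across methods: adjusted p should rarely be extreme
  pi <- c(0.08, 0.3, 0.12, 0.5)
  cfg <- mini_config(pi, methods = c("Den", "Ref", "Per"),
                     n_postings = c(25, 25, 25), comment_mean = 40,
                     comment_dispersion = 5, seed = 61, include_text = FALSE)
  sim <- generate_corpus(cfg)
  sim$corpus$comments$stance <- sim$corpus$comments$truth_stance
  cmp_null <- compare_methods(sim$corpus)
  dei_p <- cmp_null$omnibus$p[cmp_null$omnibus$scope == "overall" &
                                cmp_null$omnibus$index == "dei"]
  expect_gt(dei_p, 0.001)

  # one method with a clearly higher-DEI pi dominates the pairwise table
  cfg2 <- generator_config(
    rumors = tibble::tibble(name = "solo", category = "society"),
    plan = tibble::tibble(rumor = "solo", method = c("Den", "Ref", "Per"),
                          n_postings = 30L),
    stance_probs = tibble::tibble(
      method = c("Den", "Ref", "Per"),
      p_support = c(0.10, 0.02, 0.10),
      p_deny = c(0.25, 0.58, 0.25),
      p_query = c(0.10, 0.10, 0.10),
      p_comment = c(0.55, 0.30, 0.55)),
    comment_mean = 40, comment_dispersion = 5, seed = 62, include_text = FALSE)
  sim2 <- generate_corpus(cfg2)
  sim2$corpus$comments$stance <- sim2$corpus$comments$truth_stance
  cmp <- compare_methods(sim2$corpus)
  pw <- cmp$pairwise[cmp$pairwise$scope == "overall" & cmp$pairwise$index == "dei", ]
  involves_ref <- pw$group_i == "Ref" | pw$group_j == "Ref"
  expect_lt(max(pw$p_adj[involves_ref]), min(1, min(pw$p_adj[!involves_ref]) + 1e-12))
})

test_that("single-method corpora skip the omnibus with a message", {
  cfg <- mini_config(c(0.1, 0.3, 0.1, 0.5), methods = "Ref", n_postings = 10,
                     seed = 3, include_text = FALSE)
  sim <- generate_corpus(cfg)
  sim$corpus$comments$stance <- sim$corpus$comments$truth_stance
  cmp <- compare_methods(sim$corpus)
  expect_true(all(grepl("skipped", cmp$omnibus$note)))
  expect_equal(nrow(cmp$pairwise), 0)
})
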