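test_that("stance tallies count directly and conserve totals", {
  corp <- tiny_corpus()
  per_post <- tally_stances(corp, "posting")
  p1 <- per_post[per_post$posting_id == "p1", ]
  expect_equal(unlist(p1[, c("n_support", "n_deny", "n_query", "n_comment")],
                      use.names = FALSE), c(1L, 2L, 0L, 0L))
  # conservation across grouping levels
  for (g in c("rumor_method", "method", "rumor", "posting")) {
    expect_equal(sum(tally_stances(corp, g)$n_all), nrow(corp$comments))
  }
  # single posting {S,D,D,Q,C}
  solo <- debunk_corpus(
    tibble::tibble(id = "r1", name = "x", category = "society"),
    tibble::tibble(id = "p1", rumor_id = "r1", text = "t", method = "Ref",
                   is_debunking = TRUE),
    tibble::tibble(id = paste0("c", 1:5), posting_id = "p1", text = "t",
                   stance = c("supporting", "denying", "denying", "querying",
                              "commenting"),
                   truth_stance = NA_character_))
  tal <- tally_stances(solo, "posting")
  expect_equal(unlist(tal[, c("n_support", "n_deny", "n_query", "n_comment")],
                      use.names = FALSE), c(1L, 2L, 1L, 1L))
  # unlabeled comments are an error naming ids
  bad <- corp
  bad$comments$stance[2] <- NA
  expect_error(tally_stances(bad, "method"), "c2")
})

test_that("tallies on generated corpora equal the generator's bookkeeping", {
  cfg <- mini_config(c(0.1, 0.3, 0.2, 0.4), methods = c("Ref", "Den"),
                     n_postings = c(15, 15), seed = 33)
  sim <- generate_corpus(cfg)
  tal <- tally_stances(sim$corpus, "rumor_method", "truth_stance")
  gt <- sim$ground_truth
  expect_equal(dplyr::arrange(tal, method)[, names(tal)],
               dplyr::arrange(gt, method)[, names(tal)])
})

test_that("denial index follows its formula and boundary conventions", {
  expect_equal(denial_index(30, 10), 0.5)
  expect_equal(denial_index(5, 0), 1)
  expect_equal(denial_index(0, 5), -1)
  expect_true(is.na(denial_index(0, 0)))
  expect_error(denial_index(-1, 2), "non-negative")
})

test_that("redundancy index follows its formula and bounds", {
  expect_equal(redundancy_index(55, 100), 0.55)
  expect_equal(redundancy_index(0, 10), 0)
  expect_equal(redundancy_index(10, 10), 1)
  expect_true(is.na(redundancy_index(0, 0)))
  expect_error(redundancy_index(5, 4), "exceed")
})

test_that("DEI is the DI/RI ratio with sign and undefinedness conventions", {
  expect_equal(round(dei(0.5, 0.55), 3), 0.909)
  expect_equal(dei(0, 0.4), 0)
  expect_true(is.na(dei(NA_real_, 0.5)))
  expect_true(is.na(dei(0.5, 0)))
  expect_true(is.na(dei(0.5, NA_real_)))
  expect_equal(sign(dei(c(-0.4, 0.4), c(0.5, 0.5))), c(-1, 1))
})

test_that("index ranges hold on random counts; scale invariance; monotonicity", {
  set.seed(99)
  for (rep in 1:50) {
    cnt <- stats::rpois(4, lambda = sample(0:20, 1))
    di <- denial_index(cnt[2], cnt[1])
    ri <- redundancy_index(cnt[4], sum(cnt))
    if (!is.na(di)) expect_true(di >= -1 && di <= 1)
    if (!is.na(ri)) expect_true(ri >= 0 && ri <= 1)
    d <- dei(di, ri)
    if (!is.na(d)) expect_equal(sign(d), sign(di))
    # multiplying all counts by a positive integer changes nothing
    k <- sample(2:7, 1)
    expect_equal(denial_index(k * cnt[2], k * cnt[1]), di)
    expect_equal(redundancy_index(k * cnt[4], k * sum(cnt)), ri)
  }
  # one extra denying comment raises DI, lowers RI, raises DEI
  base <- c(s = 4, d = 10, q = 3, c = 13)
  di0 <- denial_index(base["d"], base["s"])
  ri0 <- redundancy_index(base["c"], sum(base))
  di1 <- denial_index(base["d"] + 1, base["s"])
  ri1 <- redundancy_index(base["c"], sum(base) + 1)
  expect_gt(di1, di0)
  expect_lt(ri1, ri0)
  expect_gt(dei(di1, ri1), dei(di0, ri0))
})

test_that("effectiveness_table matches direct formula application", {
  corp <- tiny_corpus()
  eff <- effectiveness_table(corp, "method")
  for (i in seq_len(nrow(eff))) {
    expect_equal(eff$di[i], denial_index(eff$n_deny[i], eff$n_support[i]))
    expect_equal(eff$ri[i], redundancy_index(eff$n_comment[i], eff$n_all[i]))
    expect_equal(eff$dei[i], dei(eff$di[i], eff$ri[i]))
  }
  expect_equal(eff$dei_defined, !is.na(eff$dei))
  # Com signatures collapse into one method row by default
  expect_true("Com" %in% eff$method)
  effs <- effectiveness_table(corp, "method", collapse_com = FALSE)
  expect_true("Com<Ref,Org>" %in% effs$method)
})

test_that("pooled estimates converge to the analytic indices of pi", {
  pi <- c(0.05, 0.35, 0.10, 0.50)
  ana <- analytic_indices(pi)
  cfg <- mini_config(pi, n_postings = 150, comment_mean = 60,
                     comment_dispersion = 2, seed = 5, include_text = FALSE)
  sim <- generate_corpus(cfg)
  eff <- effectiveness_table(sim$corpus, "method", "truth_stance")
  expect_equal(eff$di, ana$di, tolerance = 0.05)
  expect_equal(eff$ri, ana$ri, tolerance = 0.05)
  expect_equal(eff$dei, ana$dei, tolerance = 0.08)
  # per-posting mean DI is close to analytic DI at large comment volume
  per_post <- effectiveness_table(sim$corpus, "posting", "truth_stance")
  expect_equal(mean(per_post$di, na.rm = TRUE), ana$di, tolerance = 0.05)
})

test_that("summarize_effectiveness reports mean, CI and median per method", {
  cfg <- mini_config(c(0.1, 0.3, 0.1, 0.5), methods = c("Ref", "Den"),
                     n_postings = c(25, 25), comment_mean = 30, seed = 13,
                     include_text = FALSE)
  sim <- generate_corpus(cfg)
  per_post <- effectiveness_table(sim$corpus, "posting", "truth_stance")
  s <- summarize_effectiveness(per_post)
  expect_setequal(unique(as.character(s$index)), c("di", "ri", "dei"))
  row <- s[s$method == "Ref" & s$index == "di", ]
  vals <- per_post$di[per_post$method == "Ref"]
  expect_equal(row$mean, mean(vals, na.rm = TRUE))
  expect_equal(row$median, stats::median(vals, na.rm = TRUE))
  expect_true(row$ci_lo < row$mean & row$mean < row$ci_hi)
})
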