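make_labeled <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(id = paste0("c", seq_len(n)),
                 text = paste("tok", seq_len(n)),
                 stance = sample(stance_levels(), n, replace = TRUE,
                                 prob = c(0.1, 0.3, 0.15, 0.45)))
}

test_that("split sizes follow the 7:3 rule and the seed contract", {
  df <- make_labeled(1200)
  sp <- split_train_test(df, 0.7, seed = 5)
  expect_equal(nrow(sp$train), 840)
  expect_equal(nrow(sp$test), 360)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), df$id)
  sp2 <- split_train_test(df, 0.7, seed = 5)
  expect_identical(sp$train$id, sp2$train$id)
  sp3 <- split_train_test(df, 0.7, seed = 6)
  expect_false(identical(sp$train$id, sp3$train$id))
  expect_error(split_train_test(dplyr::mutate(df, stance = replace(stance, 3, NA))),
               "unlabeled")
})

test_that("stratified split keeps each class within one item of the fraction", {
  df <- make_labeled(997, seed = 3)
  sp <- split_train_test(df, 0.7, seed = 9, stratified = TRUE)
  for (cl in unique(df$stance)) {
    n_cl <- sum(df$stance == cl)
    n_tr <- sum(sp$train$stance == cl)
    expect_lte(abs(n_tr - 0.7 * n_cl), 1)
  }
})

test_that("baseline learns separable marker vocabularies", {
  train <- tibble::tibble(
    text = c("aaa shared", "aaa shared", "bbb shared", "bbb shared",
             "ccc shared", "ddd shared"),
    stance = c("supporting", "supporting", "denying", "denying",
               "querying", "commenting"))
  model <- train_baseline(train)
  expect_false(model$degenerate)
  expect_equal(predict(model, c("aaa", "bbb", "ccc", "ddd")),
               c("supporting", "denying", "querying", "commenting"))
  # empty text falls back to the most frequent training class
  expect_true(predict(model, "") %in% c("supporting", "denying"))
  # deterministic: identical text, identical label
  expect_equal(predict(model, c("bbb zzz", "bbb zzz")),
               rep("denying", 2))
})

test_that("single-class training yields a flagged degenerate model", {
  model <- train_baseline(tibble::tibble(text = c("x", "y"),
                                         stance = c("denying", "denying")))
  expect_true(model$degenerate)
  expect_equal(predict(model, c("anything", "at all")), rep("denying", 2))
})

test_that("prediction agrees with a hand-computed per-class log score", {
  train <- tibble::tibble(text = c("u v", "u u", "w", "w v"),
                          stance = c("denying", "denying", "commenting", "commenting"))
  model <- train_baseline(train)
  texts <- c("u", "w", "u w", "v", "u u w")
  hand_scores <- function(tokens) {
    vocab <- c("u", "v", "w"); v1 <- length(vocab) + 1
    cnt <- list(commenting = c(u = 0, v = 1, w = 2),
                denying = c(u = 3, v = 1, w = 0))
    vapply(c("commenting", "denying"), function(cl) {
      tot <- sum(cnt[[cl]])
      log(2 / 4) + sum(log((cnt[[cl]][tokens] + 1) / (tot + v1)))
    }, numeric(1))
  }
  for (tx in texts) {
    toks <- strsplit(tx, " ")[[1]]
    sc <- hand_scores(toks)
    expect_equal(predict(model, tx), names(sc)[which.max(sc)], info = tx)
  }
})

test_that("model JSON persistence round-trips predictions", {
  train <- make_labeled(50, seed = 8)
  train$text <- paste(train$text, substr(train$stance, 1, 3))
  model <- train_baseline(train)
  f <- withr::local_tempfile(fileext = ".json")
  write_stance_model(model, f)
  back <- read_stance_model(f)
  probe <- c("tok 3 den", "sup tok", "", "qry qry")
  expect_equal(predict(back, probe), predict(model, probe))
})

test_that("classifier beats the majority class on synthetic marker corpora", {
  cfg <- mini_config(c(0.1, 0.25, 0.15, 0.5), n_postings = 60,
                     comment_mean = 15, seed = 21, marker_prob = 0.5)
  sim <- generate_corpus(cfg)
  cm <- sim$corpus$comments
  cm$stance <- cm$truth_stance
  sp <- split_train_test(cm, 0.7, seed = 2)
  model <- train_baseline(sp$train)
  pred <- predict(model, sp$test$text)
  acc <- mean(pred == sp$test$stance)
  majority <- max(table(sp$test$stance)) / nrow(sp$test)
  expect_gt(acc, majority)
})

test_that("evaluation metrics match hand computation and conventions", {
  gold <- rep(c("pos", "pos", "neg", "neg"), c(8, 2, 3, 7))
  pred <- rep(c("pos", "neg", "pos", "neg"), c(8, 2, 3, 7))
  ev <- evaluate_predictions(gold, pred)
  # class pos: P = 8/11, R = 0.8; class neg: P = 7/9, R = 0.7
  expect_equal(ev$per_class$precision[ev$per_class$class == "pos"], 8 / 11)
  expect_equal(ev$per_class$recall[ev$per_class$class == "neg"], 0.7)
  f_pos <- 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8)
  f_neg <- 2 * (7 / 9) * 0.7 / (7 / 9 + 0.7)
  expect_equal(ev$macro_f1, mean(c(f_pos, f_neg)))
  expect_equal(round(ev$macro_f1, 3), 0.749)
  # perfect predictions
  ev1 <- evaluate_predictions(gold, gold)
  expect_equal(ev1$accuracy, 1)
  expect_equal(ev1$macro_f1, 1)
  # a gold class never predicted contributes F1 = 0 to the macro mean
  ev0 <- evaluate_predictions(c("a", "a", "b"), c("a", "a", "a"))
  expect_equal(ev0$per_class$f1[ev0$per_class$class == "b"], 0)
  expect_equal(ev0$macro_f1, mean(c(ev0$per_class$f1)))
  expect_error(evaluate_predictions(c("a"), c("a", "b")), "equal-length")
})

test_that("macro-F1 is relabel-invariant, bounded by class F1s, and matches brute force", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(8:40, 1)
    lev <- letters[1:sample(2:4, 1)]
    gold <- sample(lev, n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.6, gold, sample(lev, n, replace = TRUE))
    if (length(unique(gold)) < 2) next
    ev <- evaluate_predictions(gold, pred)
    expect_equal(ev$macro_f1, oracle_macro_f1(gold, pred), tolerance = 1e-12)
    expect_lte(ev$macro_f1, max(ev$per_class$f1) + 1e-12)
    expect_gte(ev$macro_f1, min(ev$per_class$f1) - 1e-12)
    relabel <- stats::setNames(sample(LETTERS[seq_along(lev)]), lev)
    ev2 <- evaluate_predictions(relabel[gold], relabel[pred])
    expect_equal(ev2$macro_f1, ev$macro_f1, tolerance = 1e-12)
  }
})

test_that("CJK codepoints are tokenized per character", {
  toks <- tokenize_text("谣言 rumor")[[1]]
  expect_equal(toks, c("谣", "言", "rumor"))
})
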