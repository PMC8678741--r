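#' Split labeled comments into training and testing sets
#'
#' Random 7:3-style partition of a labeled comment table. The split is
#' disjoint and exhaustive, with `round(n * train_fraction)` training items,
#' and is reproducible under a fixed seed. With `stratified = TRUE` the
#' fraction is applied within each stance class (each class's training share
#' is then within one item of the target fraction).
#'
#' @param comments Data frame with at least a label column (default
#'   `stance`); every row must be labeled.
#' @param train_fraction Training share in (0, 1); default 0.7.
#' @param seed Integer seed for the permutation.
#' @param stratified Stratify by label (default `FALSE`; plain random split).
#' @param label_col Name of the label column.
#' @return List with elements `train` and `test` (disjoint row subsets).
#' @export
split_train_test <- function(comments, train_fraction = 0.7, seed = 1L,
                             stratified = FALSE, label_col = "stance") {
  stopifnot(is.numeric(train_fraction), train_fraction > 0, train_fraction < 1)
  comments <- tibble::as_tibble(comments)
  labels <- comments[[label_col]]
  if (anyNA(labels)) {
    bad <- if ("id" %in% names(comments)) comments$id[is.na(labels)] else which(is.na(labels))
    stop("unlabeled comment(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(comments)
  local_rng(seed)
  if (!stratified) {
    n_train <- round(n * train_fraction)
    idx <- sample.int(n)
    train_idx <- sort(idx[seq_len(n_train)])
  } else {
    train_idx <- sort(unlist(lapply(split(seq_len(n), labels), function(rows) {
      k <- round(length(rows) * train_fraction)
      if (length(rows) == 1L) return(rows)  # singleton class goes to train
      sample(rows, k)
    }), use.names = FALSE))
  }
  list(train = comments[train_idx, ],
       test = comments[setdiff(seq_len(n), train_idx), ])
}

local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Tokenize comment text
#'
#' Splits on whitespace and additionally breaks CJK codepoints into
#' single-character tokens, so both the synthetic marker-token corpora and
#' unsegmented Chinese text yield usable features.
#'
#' @param texts Character vector.
#' @return List of character token vectors, one per input text.
#' @export
tokenize_text <- function(texts) {
  texts <- ifelse(is.na(texts), "", as.character(texts))
  spaced <- gsub("(\\p{Han}|\\p{Hiragana}|\\p{Katakana}|\\p{Hangul})", " \\1 ",
                 texts, perl = TRUE)
  toks <- strsplit(trimws(spaced), "\\s+", perl = TRUE)
  lapply(toks, function(t) t[nzchar(t)])
}

#' Train the baseline stance classifier
#'
#' A multinomial token-frequency model with additive (Laplace) smoothing,
#' i.e. multinomial naive Bayes over the tokenization of [tokenize_text()].
#' It is a deterministic, dependency-light stand-in for heavier text
#' classifiers: any external model can be plugged into the evaluation
#' harness via prediction files instead.
#'
#' Ties in the class score are broken by training-class frequency, then
#' lexicographically by class name. A single-class training set yields a
#' flagged degenerate model that always predicts that class.
#'
#' @param train Data frame of training comments with `text` and a label
#'   column.
#' @param alpha Additive smoothing constant (default 1).
#' @param label_col Name of the label column (default `"stance"`).
#' @return A `stance_model` object.
#' @export
train_baseline <- function(train, alpha = 1, label_col = "stance") {
  train <- tibble::as_tibble(train)
  labels <- as.character(train[[label_col]])
  if (anyNA(labels) || nrow(train) < 1) {
    stop("every training comment must be labeled", call. = FALSE)
  }
  classes <- sort(unique(labels))
  degenerate <- length(classes) < 2
  toks <- tokenize_text(train$text)
  vocab <- sort(unique(unlist(toks)))
  counts <- matrix(0, nrow = length(classes), ncol = length(vocab),
                   dimnames = list(classes, vocab))
  for (i in seq_along(toks)) {
    t <- toks[[i]]
    if (length(t) == 0) next
    tt <- table(t)
    counts[labels[i], names(tt)] <- counts[labels[i], names(tt)] + as.numeric(tt)
  }
  class_n <- table(factor(labels, levels = classes))
  model <- list(classes = classes,
                class_n = as.numeric(class_n),
                vocab = vocab,
                counts = counts,
                alpha = alpha,
                degenerate = degenerate)
  class(model) <- "stance_model"
  model
}

#' @export
print.stance_model <- function(x, ...) {
  cat("<stance_model> multinomial token-frequency baseline\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  vocabulary:", length(x$vocab), "tokens; alpha =", x$alpha, "\n")
  if (x$degenerate) cat("  DEGENERATE: single training class\n")
  invisible(x)
}

#' Predict stances with the baseline classifier
#'
#' Scores each text by log prior plus smoothed log token likelihoods and
#' returns the arg-max class. Unknown tokens receive the smoothed
#' out-of-vocabulary probability; an empty text falls back to the prior
#' (most frequent training class).
#'
#' @param object A `stance_model` from [train_baseline()].
#' @param texts Character vector of comment texts.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per text.
#' @export
predict.stance_model <- function(object, texts, ...) {
  classes <- object$classes
  if (object$degenerate) return(rep(classes[1], length(texts)))
  v <- length(object$vocab)
  tot <- rowSums(object$counts)
  log_prior <- log(object$class_n / sum(object$class_n))
  # log-probability per (class, vocab token); OOV handled separately
  log_lik <- log(object$counts + object$alpha) -
    log(tot + object$alpha * (v + 1))
  log_oov <- log(object$alpha) - log(tot + object$alpha * (v + 1))
  toks <- tokenize_text(texts)
  # tie-break order: training frequency (desc), then class name (asc)
  pref <- order(-object$class_n, classes)
  vapply(toks, function(t) {
    if (length(t) == 0) {
      return(classes[pref[1]])
    }
    known <- t[t %in% object$vocab]
    n_oov <- length(t) - length(known)
    score <- log_prior + n_oov * log_oov
    if (length(known) > 0) {
      tt <- table(known)
      score <- score + as.vector(log_lik[, names(tt), drop = FALSE] %*% as.numeric(tt))
    }
    best <- which(score >= max(score) - 1e-12)
    if (length(best) > 1) best <- best[order(match(best, pref))][1]
    classes[best]
  }, character(1))
}

#' Persist / restore a stance model as JSON
#'
#' @param model A `stance_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_stance_model()` returns the model.
#' @export
write_stance_model <- function(model, path) {
  payload <- list(classes = model$classes, class_n = model$class_n,
                  vocab = model$vocab, counts = unname(as.data.frame(model$counts)),
                  alpha = model$alpha, degenerate = model$degenerate)
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname write_stance_model
#' @export
read_stance_model <- function(path) {
  payload <- jsonlite::fromJSON(path)
  counts <- as.matrix(as.data.frame(payload$counts))
  dimnames(counts) <- list(payload$classes, payload$vocab)
  model <- list(classes = payload$classes, class_n = payload$class_n,
                vocab = payload$vocab, counts = counts,
                alpha = payload$alpha, degenerate = payload$degenerate)
  class(model) <- "stance_model"
  model
}

#' Evaluate predicted stance labels against gold labels
#'
#' Computes accuracy and per-class precision, recall and F1, plus their
#' unweighted (macro) means over the classes present in the gold labels.
#' A class with `precision + recall = 0`, or one never predicted, gets
#' `F1 = 0` by convention so the macro mean stays defined.
#'
#' @param gold,predicted Equal-length label vectors.
#' @return An `eval_result`: list with `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `per_class` (tibble) and `confusion`.
#' @export
evaluate_predictions <- function(gold, predicted) {
  gold <- as.character(gold)
  predicted <- as.character(predicted)
  if (length(gold) != length(predicted) || length(gold) == 0) {
    stop("gold and predicted must be equal-length, non-empty", call. = FALSE)
  }
  classes <- sort(unique(gold))
  lev <- sort(unique(c(gold, predicted)))
  conf <- table(factor(gold, levels = lev), factor(predicted, levels = lev))
  per <- lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    n_pred <- sum(conf[, cl])
    n_gold <- sum(conf[cl, ])
    precision <- if (n_pred > 0) tp / n_pred else 0
    recall <- if (n_gold > 0) tp / n_gold else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble::tibble(class = cl, precision = precision, recall = recall, f1 = f1)
  })
  per <- dplyr::bind_rows(per)
  res <- list(accuracy = mean(gold == predicted),
              macro_precision = mean(per$precision),
              macro_recall = mean(per$recall),
              macro_f1 = mean(per$f1),
              per_class = per,
              confusion = conf)
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro-P %.4f | macro-R %.4f | macro-F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class)
  invisible(x)
}
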