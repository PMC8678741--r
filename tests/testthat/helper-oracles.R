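# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own code paths.

# Pearson chi-square from first principles.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Kruskal-Wallis H via the rank-sum formula with tie correction.
oracle_kw <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n_tot <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n_g <- tapply(r, idx, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(n_g * rbar^2) - 3 * (n_tot + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  h / correction
}

# Dunn z statistics by direct mean-rank arithmetic.
oracle_dunn_z <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n_tot <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n_g <- tapply(r, idx, length)
  ties <- table(x)
  var_base <- n_tot * (n_tot + 1) / 12 -
    sum(ties^3 - ties) / (12 * (n_tot - 1))
  combos <- utils::combn(seq_along(groups), 2)
  apply(combos, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    (rbar[[i]] - rbar[[j]]) /
      sqrt(var_base * (1 / n_g[[i]] + 1 / n_g[[j]]))
  })
}

# Cohen's kappa from observed/expected agreement proportions.
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  po <- sum(diag(tab)) / sum(tab)
  pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
  (po - pe) / (1 - pe)
}

# Macro-F1 by per-class tallying with plain sums.
oracle_macro_f1 <- function(gold, pred) {
  classes <- sort(unique(gold))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  mean(f1)
}

# Small hand-built corpus: 2 rumors, 5 postings (one Com pair, one
# non-debunking), 10 labeled comments.
tiny_corpus <- function() {
  rumors <- tibble::tibble(id = c("r1", "r2"),
                           name = c("alpha", "beta"),
                           category = c("authority", "society"))
  postings <- tibble::tibble(
    id = paste0("p", 1:5),
    rumor_id = c("r1", "r1", "r2", "r2", "r2"),
    text = paste("posting", 1:5),
    method = c("Ref", "Com<Org,Ref>", "Den", "Other", "Per"),
    is_debunking = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  comments <- tibble::tibble(
    id = paste0("c", 1:10),
    posting_id = c("p1", "p1", "p1", "p2", "p2", "p3", "p3", "p4", "p5", "p5"),
    text = paste("comment", 1:10),
    stance = c("supporting", "denying", "denying", "querying", "commenting",
               "denying", "commenting", "commenting", "supporting", "denying"),
    truth_stance = NA_character_)
  debunk_corpus(rumors, postings, comments)
}

# Minimal generator config: one rumor, chosen methods, one shared pi.
mini_config <- function(pi, methods = "Ref", n_postings = 10,
                        comment_mean = 20, comment_dispersion = 5,
                        seed = 1L, include_text = TRUE, marker_prob = 0.6) {
  generator_config(
    rumors = tibble::tibble(name = "solo", category = "society"),
    plan = tibble::tibble(rumor = "solo", method = methods,
                          n_postings = as.integer(n_postings)),
    stance_probs = tibble::tibble(method = unique(methods),
                                  p_support = pi[1], p_deny = pi[2],
                                  p_query = pi[3], p_comment = pi[4]),
    comment_mean = comment_mean, comment_dispersion = comment_dispersion,
    comment_length = 6, marker_prob = marker_prob,
    seed = seed, include_text = include_text)
}
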