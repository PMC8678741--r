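#' Pearson chi-square test of independence
#'
#' Classical Pearson chi-square on a two-dimensional contingency table of
#' counts, without continuity correction: `X2 = sum((O - E)^2 / E)` with
#' expected counts from the row/column margins and
#' `df = (nrow - 1) * (ncol - 1)`.
#'
#' @param table A matrix (or table) of non-negative integer counts with at
#'   least 2 rows and 2 columns; every row and column margin must be
#'   positive (a zero margin is an error naming the offender).
#' @return A `stat_result`: list with `test`, `statistic`, `df`, `p`,
#'   `expected`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(10, 20, 20, 10), 2))
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold non-negative integer counts", call. = FALSE)
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) {
    nm <- if (!is.null(rownames(tab))) rownames(tab)[rs == 0] else which(rs == 0)
    stop("zero row margin: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  if (any(cs == 0)) {
    nm <- if (!is.null(colnames(tab))) colnames(tab)[cs == 0] else which(cs == 0)
    stop("zero column margin: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- list(test = "pearson_chi_square",
              statistic = unname(ht$statistic),
              df = unname(ht$parameter),
              p = unname(ht$p.value),
              expected = ht$expected)
  class(res) <- "stat_result"
  res
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based comparison of two or more groups of per-posting index values,
#' using mid-ranks and the standard tie correction; the statistic H is
#' referred to a chi-square distribution with `k - 1` degrees of freedom.
#' When all pooled values are identical the tie correction degenerates; the
#' result is flagged with `H = 0` and `p = 1`.
#'
#' @param groups A list of 2 or more non-empty numeric vectors (total
#'   length >= 3). Names, if present, label the groups.
#' @return A `stat_result` with `test`, `statistic` (H), `df`, `p`,
#'   `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    res <- list(test = "kruskal_wallis", statistic = 0, df = length(groups) - 1L,
                p = 1, degenerate = TRUE)
    class(res) <- "stat_result"
    return(res)
  }
  ht <- stats::kruskal.test(x, g)
  res <- list(test = "kruskal_wallis",
              statistic = unname(ht$statistic),
              df = unname(ht$parameter),
              p = unname(ht$p.value),
              degenerate = FALSE)
  class(res) <- "stat_result"
  res
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  if (sum(lengths(groups)) < 3) stop("need at least 3 observations in total",
                                     call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' Pairwise follow-up to [kruskal_wallis()]: for each pair of groups, Dunn's
#' z statistic from the difference of mean mid-ranks with tie-corrected
#' pooled variance,
#' `z = (Rbar_I - Rbar_J) / sqrt((N(N+1)/12 - T) (1/n_I + 1/n_J))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups of size `t`.
#' Two-sided raw p-values are multiplied by the number of pairs
#' `k (k - 1) / 2` and capped at 1 (Bonferroni), matching the "Adj. Sig."
#' reported by SPSS-style pairwise Kruskal-Wallis comparisons.
#'
#' @inheritParams kruskal_wallis
#' @return A `stat_result` whose `pairs` element is a tibble with columns
#'   `group_i`, `group_j`, `z`, `p`, `p_adj`.
#' @export
posthoc_dunn_bonferroni <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n_tot <- length(x)
  r <- rank(x)  # mid-ranks
  mean_ranks <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term
  degenerate <- var_base <= 0
  combos <- utils::combn(names(groups), 2)
  m <- ncol(combos)
  pairs <- lapply(seq_len(m), function(idx) {
    i <- combos[1, idx]; j <- combos[2, idx]
    if (degenerate) {
      z <- 0; p <- 1
    } else {
      se <- sqrt(var_base * (1 / n_g[[i]] + 1 / n_g[[j]]))
      z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
      p <- 2 * stats::pnorm(-abs(z))
    }
    tibble::tibble(group_i = i, group_j = j, z = z, p = p,
                   p_adj = min(1, p * m))
  })
  res <- list(test = "dunn_bonferroni",
              statistic = NA_real_, df = NA_integer_, p = NA_real_,
              pairs = dplyr::bind_rows(pairs),
              n_pairs = m, degenerate = degenerate)
  class(res) <- "stat_result"
  res
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$test, "\n", sep = "")
  if (!is.na(x$statistic)) {
    cat(sprintf("  statistic = %.4f", x$statistic))
    if (!is.null(x$df) && !is.na(x$df)) cat(sprintf(", df = %s", format(x$df)))
    cat(sprintf(", p = %.4g\n", x$p))
  }
  if (!is.null(x$pairs)) {
    cat("  ", nrow(x$pairs), " pairwise comparisons (Bonferroni x ",
        x$n_pairs, ")\n", sep = "")
  }
  if (isTRUE(x$degenerate)) cat("  degenerate: all values tied\n")
  invisible(x)
}

#' Compare debunking methods statistically
#'
#' The full statistical battery over a labeled corpus, overall and per
#' rumor: a Pearson chi-square test on the method-by-stance contingency
#' table, and Kruskal-Wallis omnibus tests with Dunn-Bonferroni pairwise
#' follow-ups on per-posting DI, RI and DEI across debunking methods.
#' `"Other"` (non-debunking) postings are excluded from the method
#' comparisons; methods contributing fewer than 2 defined per-posting
#' values are dropped with a warning. P-values are reported as continuous
#' measures of compatibility; no significance stars are attached.
#'
#' @param corpus A labeled [debunk_corpus()].
#' @param stance_from Stance column to use (see [tally_stances()]).
#' @return A `method_comparison`: list with `contingency` (tibble of
#'   chi-square results per scope), `omnibus` (tibble: scope, index, H, df,
#'   p, k), `pairwise` (tibble: scope, index, group_i, group_j, z, p,
#'   p_adj), and `dropped` (tibble of dropped method/scope records).
#' @export
compare_methods <- function(corpus, stance_from = c("stance", "truth_stance")) {
  stance_from <- match.arg(stance_from)
  per_post <- effectiveness_table(corpus, "posting", stance_from) |>
    dplyr::filter(.data$method != "Other")
  tal <- tally_stances(corpus, "rumor_method", stance_from) |>
    dplyr::filter(.data$method != "Other")

  scopes <- c("overall", sort(unique(per_post$rumor)))
  contingency <- list(); omnibus <- list(); pairwise <- list(); dropped <- list()
  for (sc in scopes) {
    sub_tal <- if (sc == "overall") tal else dplyr::filter(tal, .data$rumor == sc)
    sub_tal <- sub_tal |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(dplyr::across(dplyr::starts_with("n_"), sum), .groups = "drop")
    mat <- as.matrix(sub_tal[, c("n_support", "n_deny", "n_query", "n_comment")])
    rownames(mat) <- sub_tal$method
    mat <- mat[, colSums(mat) > 0, drop = FALSE]
    if (nrow(mat) >= 2 && ncol(mat) >= 2) {
      ct <- chi_square_independence(mat)
      contingency[[sc]] <- tibble::tibble(scope = sc, statistic = ct$statistic,
                                          df = ct$df, p = ct$p)
    }
    sub <- if (sc == "overall") per_post else dplyr::filter(per_post, .data$rumor == sc)
    for (index in c("di", "ri", "dei")) {
      vals <- split(sub[[index]], sub$method)
      vals <- lapply(vals, function(v) v[!is.na(v)])
      small <- names(vals)[lengths(vals) < 2]
      if (length(small) > 0) {
        dropped[[paste(sc, index)]] <- tibble::tibble(scope = sc, index = index,
                                                      method = small,
                                                      n_defined = lengths(vals)[small])
        vals <- vals[lengths(vals) >= 2]
      }
      if (length(vals) < 2) {
        omnibus[[paste(sc, index)]] <- tibble::tibble(
          scope = sc, index = index, k = length(vals),
          H = NA_real_, df = NA_integer_, p = NA_real_,
          note = "omnibus skipped: fewer than 2 comparable methods")
        next
      }
      kw <- kruskal_wallis(vals)
      omnibus[[paste(sc, index)]] <- tibble::tibble(
        scope = sc, index = index, k = length(vals),
        H = kw$statistic, df = kw$df, p = kw$p, note = NA_character_)
      dn <- posthoc_dunn_bonferroni(vals)
      pairwise[[paste(sc, index)]] <- dplyr::mutate(dn$pairs, scope = sc,
                                                    index = index,
                                                    .before = 1)
    }
  }
  dropped <- dplyr::bind_rows(dropped)
  if (nrow(dropped) > 0) {
    warning("method(s) with <2 defined per-posting indices dropped: ",
            paste(unique(dropped$method), collapse = ", "), call. = FALSE)
  }
  structure(list(contingency = dplyr::bind_rows(contingency),
                 omnibus = dplyr::bind_rows(omnibus),
                 pairwise = dplyr::bind_rows(pairwise),
                 dropped = dropped),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  cat("  chi-square scopes:", nrow(x$contingency), "\n")
  cat("  omnibus tests:", nrow(x$omnibus), " | pairwise rows:",
      nrow(x$pairwise), "\n")
  if (nrow(x$dropped) > 0) cat("  dropped:", nrow(x$dropped), "method/scope cells\n")
  invisible(x)
}
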