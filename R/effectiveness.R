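#' Tally SDQC stances per group
#'
#' Counts supporting / denying / querying / commenting comments per group,
#' where a group is a (rumor, method) cell, a method, a rumor, or a single
#' posting. Every comment in scope must carry a stance label and every
#' posting a method label (`"Other"` marks non-debunking postings); the
#' tallies partition the comments, so group sums equal the corpus total.
#'
#' @param corpus A labeled [debunk_corpus()].
#' @param grouping One of `"rumor_method"`, `"method"`, `"rumor"`,
#'   `"posting"`.
#' @param stance_from Stance column to tally: the assigned `"stance"` label
#'   or the synthetic ground truth `"truth_stance"`.
#' @param collapse_com Fold all combination signatures (`Com<...>`) into a
#'   single `"Com"` group (default `TRUE`); set `FALSE` to keep each
#'   signature as its own group, as [decompose_combinations()] does.
#' @return A tibble with the grouping columns plus `n_support`, `n_deny`,
#'   `n_query`, `n_comment`, `n_all`.
#' @export
tally_stances <- function(corpus,
                          grouping = c("rumor_method", "method", "rumor", "posting"),
                          stance_from = c("stance", "truth_stance"),
                          collapse_com = TRUE) {
  grouping <- match.arg(grouping)
  stance_from <- match.arg(stance_from)
  validate_corpus(corpus)
  cm <- corpus$comments
  po <- corpus$postings
  stance <- cm[[stance_from]]
  if (anyNA(stance)) {
    stop("comment(s) lack a ", stance_from, " label: ",
         paste(utils::head(cm$id[is.na(stance)], 10), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(po$method)) {
    stop("posting(s) lack a method label: ",
         paste(utils::head(po$id[is.na(po$method)], 10), collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    posting_id = cm$posting_id,
    stance = stance) |>
    dplyr::left_join(dplyr::select(po, posting_id = "id", "rumor_id", "method"),
                     by = "posting_id") |>
    dplyr::left_join(dplyr::select(corpus$rumors, rumor_id = "id", rumor = "name"),
                     by = "rumor_id")
  if (collapse_com) df$method <- sub("^Com<.*>$", "Com", df$method)
  keys <- switch(grouping,
                 rumor_method = c("rumor", "method"),
                 method = "method",
                 rumor = "rumor",
                 posting = c("rumor", "method", "posting_id"))
  df |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "stance")))) |>
    tidyr::pivot_wider(names_from = "stance", values_from = "n",
                       values_fill = 0L) |>
    add_missing_stance_cols() |>
    dplyr::transmute(dplyr::across(dplyr::all_of(keys)),
                     n_support = .data$supporting,
                     n_deny = .data$denying,
                     n_query = .data$querying,
                     n_comment = .data$commenting,
                     n_all = .data$supporting + .data$denying +
                       .data$querying + .data$commenting) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

add_missing_stance_cols <- function(df) {
  for (s in stance_levels()) {
    if (!s %in% names(df)) df[[s]] <- 0L
  }
  df
}

#' Denial index (DI)
#'
#' Net denial among the veracity-relevant comments of a group:
#' `DI = (n_deny - n_support) / (n_deny + n_support)`. Querying and
#' commenting stances are omitted because they do not contribute to
#' resolving the rumor's veracity; the normalization makes DI comparable
#' across rumors and events. DI lies in `[-1, 1]`; it is undefined
#' (`NA`) when a group has neither denying nor supporting comments.
#'
#' @param n_deny,n_support Non-negative counts (vectorized).
#' @return Numeric vector of DI values, `NA` where undefined.
#' @export
#' @examples
#' denial_index(30, 10)  # 0.5
denial_index <- function(n_deny, n_support) {
  check_counts(n_deny, n_support)
  denom <- n_deny + n_support
  ifelse(denom > 0, (n_deny - n_support) / denom, NA_real_)
}

#' Redundancy index (RI)
#'
#' Share of comments that take the commenting stance, i.e. that do not
#' contribute toward resolving the rumor's veracity:
#' `RI = n_comment / n_all`. RI lies in `[0, 1]` and is undefined (`NA`)
#' for an empty group.
#'
#' @param n_comment Count of commenting-stance comments (vectorized).
#' @param n_all Total comment count of the group.
#' @return Numeric vector of RI values, `NA` where undefined.
#' @export
#' @examples
#' redundancy_index(55, 100)  # 0.55
redundancy_index <- function(n_comment, n_all) {
  check_counts(n_comment, n_all)
  if (any(n_comment > n_all, na.rm = TRUE)) {
    stop("n_comment cannot exceed n_all", call. = FALSE)
  }
  ifelse(n_all > 0, n_comment / n_all, NA_real_)
}

check_counts <- function(...) {
  for (v in list(...)) {
    if (any(!is.na(v) & (v < 0 | v != round(v)))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Debunking effectiveness index (DEI)
#'
#' The ratio `DEI = DI / RI`: debunking is effective when users clearly deny
#' the rumor (high DI) without burying the thread in redundant commentary
#' (low RI). DEI is directly proportional to DI and inversely proportional
#' to RI, shares DI's sign, and is undefined (`NA`) when DI is undefined or
#' RI is zero or undefined.
#'
#' @param di,ri Numeric vectors of denial and redundancy indices.
#' @return Numeric vector of DEI values, `NA` where undefined.
#' @export
#' @examples
#' dei(0.986, 0.492)  # 2.004 at 3 decimals
dei <- function(di, ri) {
  ifelse(!is.na(di) & !is.na(ri) & ri > 0, di / ri, NA_real_)
}

#' Per-group effectiveness table
#'
#' Tallies stances per group (pooled counts) and computes DI, RI and DEI for
#' each group, with explicit defined-ness flags. Headline per-method tables
#' use pooled counts; distributional comparisons across methods use
#' per-posting records (`grouping = "posting"`), which can be summarized
#' with [summarize_effectiveness()].
#'
#' @inheritParams tally_stances
#' @return A tibble: grouping columns, the four stance counts, `n_all`,
#'   `di`, `ri`, `dei`, and logical `di_defined`, `ri_defined`,
#'   `dei_defined`.
#' @export
effectiveness_table <- function(corpus,
                                grouping = c("rumor_method", "method", "rumor", "posting"),
                                stance_from = c("stance", "truth_stance"),
                                collapse_com = TRUE) {
  grouping <- match.arg(grouping)
  stance_from <- match.arg(stance_from)
  tal <- tally_stances(corpus, grouping, stance_from, collapse_com)
  tal |>
    dplyr::mutate(di = denial_index(.data$n_deny, .data$n_support),
                  ri = redundancy_index(.data$n_comment, .data$n_all),
                  dei = dei(.data$di, .data$ri),
                  di_defined = !is.na(.data$di),
                  ri_defined = !is.na(.data$ri),
                  dei_defined = !is.na(.data$dei))
}

#' Summarize per-posting effectiveness records
#'
#' Mean with normal-theory 95% confidence interval, and median, of each
#' index over per-posting records, grouped by method (or any grouping
#' columns). Undefined (`NA`) per-posting indices are excluded and counted.
#'
#' @param per_posting Output of `effectiveness_table(..., grouping = "posting")`.
#' @param by Grouping columns (default `"method"`).
#' @return A tibble with, per group and index, `n_defined`, `n_undefined`,
#'   `mean`, `ci_lo`, `ci_hi`, `median`.
#' @export
summarize_effectiveness <- function(per_posting, by = "method") {
  long <- per_posting |>
    dplyr::select(dplyr::all_of(by), "di", "ri", "dei") |>
    tidyr::pivot_longer(cols = c("di", "ri", "dei"),
                        names_to = "index", values_to = "value")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "index")))) |>
    dplyr::summarise(
      n_defined = sum(!is.na(.data$value)),
      n_undefined = sum(is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      ci_lo = .data$mean - 1.96 * stats::sd(.data$value, na.rm = TRUE) /
        sqrt(pmax(.data$n_defined, 1)),
      ci_hi = .data$mean + 1.96 * stats::sd(.data$value, na.rm = TRUE) /
        sqrt(pmax(.data$n_defined, 1)),
      median = stats::median(.data$value, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(index = factor(.data$index, levels = c("di", "ri", "dei"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)), .data$index)
}
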