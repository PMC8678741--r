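#' Cohen's kappa with asymptotic confidence interval and test
#'
#' Chance-corrected agreement between two annotators labelling the same
#' items with nominal categories: `kappa = (p_o - p_e) / (1 - p_e)`, where
#' `p_o` is observed agreement and `p_e` the agreement expected from the
#' annotators' marginal label frequencies.
#'
#' The 95% confidence interval uses the Fleiss-Cohen-Everitt large-sample
#' standard error under the alternative; the p-value for the null `kappa = 0`
#' uses the standard error computed under the null (a z-test). When both
#' annotators are constant and identical, `p_e = 1` and kappa is undefined;
#' the result is flagged rather than raising an error.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 2) over a
#'   shared finite alphabet. `NA`s are not allowed here; see
#'   [agreement_report()] for abstention handling.
#' @return A `kappa_result`: list with `kappa`, `se` (alternative), `se0`
#'   (null), `ci95` (`lo`, `hi`), `p`, `n`, `table` (confusion matrix) and
#'   `defined`.
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y", "y"), c("x", "y", "y", "y"))
cohens_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b)) {
    stop("annotator label sequences differ in length (",
         length(labels_a), " vs ", length(labels_b), ")", call. = FALSE)
  }
  if (anyNA(labels_a) || anyNA(labels_b)) {
    stop("missing labels; drop abstentions before calling cohens_kappa()",
         call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  lev <- sort(unique(c(labels_a, labels_b)))
  tab <- table(factor(labels_a, levels = lev), factor(labels_b, levels = lev))
  p <- tab / n
  po <- sum(diag(p))
  prow <- rowSums(p)
  pcol <- colSums(p)
  pe <- sum(prow * pcol)

  if (isTRUE(all.equal(pe, 1))) {
    res <- list(kappa = NA_real_, se = NA_real_, se0 = NA_real_,
                ci95 = c(lo = NA_real_, hi = NA_real_), p = NA_real_,
                n = n, table = tab, defined = FALSE)
    class(res) <- "kappa_result"
    return(res)
  }

  kappa <- (po - pe) / (1 - pe)

  # Fleiss, Cohen & Everitt (1969) large-sample variance under the alternative
  k <- length(lev)
  a_term <- 0
  for (i in seq_len(k)) {
    a_term <- a_term + p[i, i] * (1 - (prow[i] + pcol[i]) * (1 - kappa))^2
  }
  b_term <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) b_term <- b_term + p[i, j] * (pcol[i] + prow[j])^2
    }
  }
  b_term <- (1 - kappa)^2 * b_term
  c_term <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(a_term + b_term - c_term, 0)) / ((1 - pe) * sqrt(n))

  # variance under H0: kappa = 0
  s0 <- pe + pe^2 - sum(prow * pcol * (prow + pcol))
  se0 <- sqrt(max(s0, 0)) / ((1 - pe) * sqrt(n))
  z <- if (se0 > 0) kappa / se0 else Inf * sign(kappa)
  pval <- 2 * stats::pnorm(-abs(z))

  res <- list(kappa = unname(kappa), se = unname(se), se0 = unname(se0),
              ci95 = c(lo = unname(kappa - 1.96 * se),
                       hi = unname(kappa + 1.96 * se)),
              p = unname(pval), n = n, table = tab, defined = TRUE)
  class(res) <- "kappa_result"
  res
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Cohen's kappa on", x$n, "items\n")
  if (!x$defined) {
    cat("  kappa undefined: both annotators constant and identical (p_e = 1)\n")
    return(invisible(x))
  }
  cat(sprintf("  kappa = %.3f  (95%% CI [%.3f, %.3f]),  p = %.3g\n",
              x$kappa, x$ci95[["lo"]], x$ci95[["hi"]], x$p))
  invisible(x)
}

#' Inter-annotator agreement report for a corpus annotation field
#'
#' Computes [cohens_kappa()] between two annotator columns attached to a
#' corpus table (comments for `stance`, postings for `method` or
#' `is_debunking`) or to a plain data frame. Items where either annotator
#' abstained (`NA`) are dropped and counted in the report.
#'
#' @param x A [debunk_corpus()] or a data frame carrying the annotator
#'   columns.
#' @param label_field Which annotation the columns encode: `"stance"`,
#'   `"method"` or `"is_debunking"`; selects the corpus table when `x` is a
#'   corpus.
#' @param annotator_cols Length-2 character vector naming the two annotator
#'   columns.
#' @return A list with `kappa` (a `kappa_result`), `confusion` (the full
#'   cross-tabulation), `n_used` and `n_dropped`.
#' @export
agreement_report <- function(x, label_field = c("stance", "method", "is_debunking"),
                             annotator_cols) {
  label_field <- match.arg(label_field)
  if (inherits(x, "debunk_corpus")) {
    df <- if (label_field == "stance") x$comments else x$postings
  } else {
    df <- as.data.frame(x)
  }
  missing_cols <- setdiff(annotator_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("annotator column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  a <- as.character(df[[annotator_cols[1]]])
  b <- as.character(df[[annotator_cols[2]]])
  keep <- !is.na(a) & !is.na(b)
  dropped_ids <- if ("id" %in% names(df)) df$id[!keep] else which(!keep)
  kr <- cohens_kappa(a[keep], b[keep])
  list(kappa = kr, confusion = kr$table,
       n_used = sum(keep), n_dropped = sum(!keep), dropped = dropped_ids)
}

#' Write an agreement report to CSV
#'
#' Emits a one-row summary (kappa, se, ci_lo, ci_hi, p, n, n_dropped)
#' followed by the confusion matrix in long form.
#'
#' @param report Output of [agreement_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(report, path) {
  kr <- report$kappa
  summary_df <- tibble::tibble(
    kappa = kr$kappa, se = kr$se, ci_lo = kr$ci95[["lo"]],
    ci_hi = kr$ci95[["hi"]], p = kr$p, n = kr$n, n_dropped = report$n_dropped)
  conf <- as.data.frame(report$confusion, stringsAsFactors = FALSE)
  names(conf) <- c("annotator_a", "annotator_b", "count")
  readr::write_csv(summary_df, path, na = "")
  readr::write_csv(conf, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}
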