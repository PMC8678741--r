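#' Pipeline run configuration
#'
#' Bundles the inputs of [run_pipeline()]: exactly one corpus source (a
#' directory of corpus files or a [generator_config()]), the stance-label
#' source, the output directory and the seed for any stochastic stage.
#'
#' @param input_path Directory holding a serialized corpus (see
#'   [load_corpus()]); mutually exclusive with `generator`.
#' @param input_format Corpus file format, `"jsonl"` or `"csv"`.
#' @param generator A [generator_config()]; mutually exclusive with
#'   `input_path`.
#' @param label_source Where comment stances come from: `"gold"` (existing
#'   `stance`, falling back to `truth_stance`), `"classifier"` (train the
#'   baseline on a seeded 70% split of the labeled comments and predict all
#'   stances), or `"external"` (a predictions CSV with columns `id`,
#'   `stance`).
#' @param predictions_path Predictions CSV for `label_source = "external"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the split/training stage.
#' @return A `run_config` object.
#' @export
run_config <- function(input_path = NULL, input_format = c("jsonl", "csv"),
                       generator = NULL,
                       label_source = c("gold", "classifier", "external"),
                       predictions_path = NULL,
                       out_dir, seed = 1L) {
  label_source <- match.arg(label_source)
  input_format <- match.arg(input_format)
  if (is.null(input_path) == is.null(generator)) {
    stop("supply exactly one of input_path or generator", call. = FALSE)
  }
  if (!is.null(generator)) validate_generator_config(generator)
  if (label_source == "external" && is.null(predictions_path)) {
    stop("label_source = \"external\" requires predictions_path", call. = FALSE)
  }
  structure(list(input_path = input_path, input_format = input_format,
                 generator = generator, label_source = label_source,
                 predictions_path = predictions_path,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full debunking-effectiveness analysis
#'
#' Orchestrates the end-to-end analysis: load or generate the corpus,
#' restrict to debunking postings (non-debunking `Other` postings are kept
#' for context tallies but excluded from method comparisons), resolve
#' stance labels, compute pooled and per-posting effectiveness tables,
#' run the statistical comparisons, decompose combination methods, and
#' write all tables, a human-readable report and a run manifest (seed,
#' package version, record counts at every stage) into `out_dir`. A stage
#' failure aborts with the stage name. Identical configurations produce
#' identical output bytes.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects (`corpus`,
#'   `effectiveness`, `comparison`, `combo_edges`, `report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   label_source = config$label_source,
                   package_version = as.character(utils::packageVersion("debunkr")),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage \"", name, "\" failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  corpus <- stage("input", {
    if (!is.null(config$generator)) {
      generate_corpus(config$generator)$corpus
    } else {
      load_corpus(config$input_path, config$input_format)
    }
  })
  manifest$stages$loaded <- list(rumors = nrow(corpus$rumors),
                                 postings = nrow(corpus$postings),
                                 comments = nrow(corpus$comments))

  # Attach "Other" label to non-debunking postings so the full corpus is
  # tallyable; method comparisons exclude them downstream.
  corpus$postings$method[!corpus$postings$is_debunking &
                           is.na(corpus$postings$method)] <- "Other"
  debunking <- stage("filter_debunking", filter_debunking_postings(corpus))
  manifest$stages$debunking_filtered <- list(postings = nrow(debunking$postings),
                                             comments = nrow(debunking$comments))

  corpus <- stage("labels", resolve_labels(corpus, config))
  manifest$stages$labeled <- list(
    comments_labeled = sum(!is.na(corpus$comments$stance)))

  eff_rm <- stage("effectiveness", effectiveness_table(corpus, "rumor_method"))
  eff_m <- stage("effectiveness", effectiveness_table(corpus, "method"))
  eff_post <- stage("effectiveness", effectiveness_table(corpus, "posting"))
  eff_sum <- stage("effectiveness", summarize_effectiveness(
    dplyr::filter(eff_post, .data$method != "Other")))
  comparison <- stage("compare", compare_methods(corpus))
  edges <- stage("combination_graph", decompose_combinations(corpus))

  report <- stage("report", make_report(
    dplyr::filter(eff_m, .data$method != "Other"),
    per_rumor = dplyr::filter(eff_rm, .data$method != "Other"),
    comparison = comparison))

  stage("write", {
    readr::write_csv(eff_rm, file.path(out_dir, "effectiveness_rumor_method.csv"), na = "")
    readr::write_csv(eff_m, file.path(out_dir, "effectiveness_method.csv"), na = "")
    readr::write_csv(eff_post, file.path(out_dir, "effectiveness_posting.csv"), na = "")
    readr::write_csv(eff_sum, file.path(out_dir, "effectiveness_summary.csv"), na = "")
    readr::write_csv(comparison$contingency, file.path(out_dir, "stats_chisq.csv"), na = "")
    readr::write_csv(comparison$omnibus, file.path(out_dir, "stats_omnibus.csv"), na = "")
    readr::write_csv(comparison$pairwise, file.path(out_dir, "stats_pairwise.csv"), na = "")
    if (nrow(edges) > 0) {
      export_graph(edges, file.path(out_dir, "combo_edges.csv"), "csv")
      export_graph(edges, file.path(out_dir, "combo_graph.graphml"), "graphml")
    }
    writeLines(report, file.path(out_dir, "report.md"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(list(corpus = corpus,
                 effectiveness = list(rumor_method = eff_rm, method = eff_m,
                                      posting = eff_post, summary = eff_sum),
                 comparison = comparison, combo_edges = edges,
                 report = report, manifest = manifest))
}

resolve_labels <- function(corpus, config) {
  cm <- corpus$comments
  if (config$label_source == "gold") {
    fill <- is.na(cm$stance) & !is.na(cm$truth_stance)
    cm$stance[fill] <- cm$truth_stance[fill]
  } else if (config$label_source == "external") {
    preds <- readr::read_csv(config$predictions_path,
                             col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
    idx <- match(cm$id, preds$id)
    cm$stance <- preds$stance[idx]
  } else {
    gold <- ifelse(is.na(cm$stance), cm$truth_stance, cm$stance)
    labeled <- cm[!is.na(gold), ]
    labeled$gold <- gold[!is.na(gold)]
    sp <- split_train_test(labeled, train_fraction = 0.7, seed = config$seed,
                           label_col = "gold")
    model <- train_baseline(sp$train, label_col = "gold")
    cm$stance <- predict(model, cm$text)
  }
  corpus$comments <- cm
  validate_corpus(corpus)
  corpus
}

#' Render a human-readable effectiveness report
#'
#' Ranks the debunking methods by pooled DEI (3-decimal precision; exact
#' ties at that precision are listed together and noted), names the best
#' method overall and per rumor, and accounts for undefined indices and
#' any groups dropped from the statistical comparisons. With a single
#' method the comparison is skipped with an explanatory line.
#'
#' @param method_table Tibble with columns `method`, `di`, `ri`, `dei`
#'   (e.g. pooled [effectiveness_table()] rows, or any externally supplied
#'   per-method DI/RI pairs run through [dei()]).
#' @param per_rumor Optional tibble with `rumor`, `method`, `dei` for
#'   per-rumor rankings.
#' @param comparison Optional [compare_methods()] result, for dropped-group
#'   accounting.
#' @return Character vector of markdown lines.
#' @export
make_report <- function(method_table, per_rumor = NULL, comparison = NULL) {
  lines <- c("# Debunking effectiveness report", "")
  mt <- tibble::as_tibble(method_table)
  n_undef <- sum(is.na(mt$dei))
  defined <- mt[!is.na(mt$dei), ]
  if (nrow(mt) < 2) {
    lines <- c(lines, "Method comparison skipped: only one method present.", "")
  }
  if (nrow(defined) > 0) {
    defined$dei_r <- round(defined$dei, 3)
    ranks <- defined[order(-defined$dei_r, defined$method), ]
    grouped <- split(ranks$method, -ranks$dei_r)
    pos <- 1L
    lines <- c(lines, "## Ranking by DEI (pooled counts, 3 d.p.)", "")
    for (g in grouped) {
      val <- ranks$dei_r[match(g[1], ranks$method)]
      tie_note <- if (length(g) > 1) "  (tie)" else ""
      lines <- c(lines, sprintf("%d. %s — DEI %.3f%s", pos,
                                paste(g, collapse = ", "), val, tie_note))
      pos <- pos + length(g)
    }
    best <- grouped[[1]]
    lines <- c(lines, "",
               if (length(best) == 1) {
                 sprintf("Best method overall: **%s** (DEI %.3f).", best,
                         max(ranks$dei_r))
               } else {
                 sprintf("Best methods overall (tied): **%s** (DEI %.3f).",
                         paste(best, collapse = ", "), max(ranks$dei_r))
               })
  }
  if (n_undef > 0) {
    lines <- c(lines, "",
               sprintf("%d method(s) with undefined DEI excluded from the ranking.",
                       n_undef))
  }
  if (!is.null(per_rumor) && nrow(per_rumor) > 0) {
    lines <- c(lines, "", "## Best method per rumor", "")
    pr <- tibble::as_tibble(per_rumor)
    pr <- pr[!is.na(pr$dei), ]
    for (r in sort(unique(pr$rumor))) {
      sub <- pr[pr$rumor == r, ]
      sub$dei_r <- round(sub$dei, 3)
      top <- sub[sub$dei_r == max(sub$dei_r), ]
      lines <- c(lines, sprintf("- %s: %s (DEI %.3f)%s", r,
                                paste(sort(top$method), collapse = ", "),
                                max(sub$dei_r),
                                if (nrow(top) > 1) " (tie)" else ""))
    }
  }
  if (!is.null(comparison) && nrow(comparison$dropped) > 0) {
    lines <- c(lines, "",
               sprintf("Statistical comparisons dropped %d method/scope cell(s) with fewer than 2 defined per-posting indices.",
                       nrow(comparison$dropped)))
  }
  lines
}
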