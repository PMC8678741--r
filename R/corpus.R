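#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' SDQC stance labels
#'
#' The four-way stance scheme used to code reply comments relative to the
#' rumor's veracity: a comment can support the rumor, deny it, query for more
#' evidence, or merely comment without taking a clear stance.
#'
#' @return Character vector of the four stance labels, in canonical order.
#' @export
#' @examples
#' stance_levels()
stance_levels <- function() {
  c("supporting", "denying", "querying", "commenting")
}

#' Debunking-method labels
#'
#' The six debunking methods plus `"Other"` for non-debunking postings:
#' denial (`Den`), further fact-checking (`Fur`), refutation (`Ref`), person
#' response (`Per`), organization response (`Org`) and combination (`Com`).
#' Combination postings carry a signature of the base methods used, written
#' `Com<Ref,Org>` or `Com<Ref,Per,Org>`.
#'
#' @return Character vector of the base method labels.
#' @export
method_levels <- function() {
  c("Den", "Fur", "Ref", "Per", "Org", "Com", "Other")
}

# Base methods eligible to appear inside a combination signature.
combo_base_methods <- function() c("Ref", "Per", "Org")

#' Build a canonical combination-method token
#'
#' Combination postings use two or three of the cited-evidence base methods
#' `{Ref, Per, Org}` jointly; uncited-evidence methods (`Den`, `Fur`) never
#' appear in a combination. Member order in the input is irrelevant: the
#' token is always emitted in the canonical order `Ref, Per, Org`.
#'
#' @param members Character vector of 2 or 3 distinct base methods drawn from
#'   `Ref`, `Per`, `Org`.
#' @return A single token such as `"Com<Ref,Org>"`.
#' @export
#' @examples
#' combo_token(c("Org", "Ref"))
combo_token <- function(members) {
  members <- unique(as.character(members))
  bad <- setdiff(members, combo_base_methods())
  if (length(bad) > 0) {
    stop("combination signature may only contain ",
         paste(combo_base_methods(), collapse = ", "),
         "; found: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(members) < 2) {
    stop("combination signature needs at least 2 members", call. = FALSE)
  }
  ordered <- combo_base_methods()[combo_base_methods() %in% members]
  paste0("Com<", paste(ordered, collapse = ","), ">")
}

#' Parse a debunking-method token
#'
#' @param token A single method token, e.g. `"Ref"` or `"Com<Ref,Per>"`.
#' @return A list with elements `value` (one of [method_levels()]) and
#'   `combo` (character vector of signature members in canonical order, or
#'   `NULL` for non-combination methods).
#' @export
parse_method_token <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, !is.na(token))
  if (token %in% setdiff(method_levels(), "Com")) {
    return(list(value = token, combo = NULL))
  }
  m <- regmatches(token, regexec("^Com<([A-Za-z,]+)>$", token))[[1]]
  if (length(m) == 2L) {
    members <- strsplit(m[2], ",", fixed = TRUE)[[1]]
    canonical <- combo_token(members)  # validates membership and size
    members <- combo_base_methods()[combo_base_methods() %in% members]
    return(list(value = "Com", combo = members))
  }
  if (identical(token, "Com")) {
    stop("combination method token must carry a signature, e.g. \"Com<Ref,Org>\"",
         call. = FALSE)
  }
  stop("unknown debunking-method token: \"", token, "\"", call. = FALSE)
}

# Canonicalize a vector of method tokens, validating each. NA passes through.
canonicalize_methods <- function(tokens) {
  vapply(tokens, function(tok) {
    if (is.na(tok)) return(NA_character_)
    p <- parse_method_token(tok)
    if (is.null(p$combo)) p$value else combo_token(p$combo)
  }, character(1), USE.NAMES = FALSE)
}

#' Rumor categories
#'
#' @return The three rumor categories: slander of authoritative
#'   persons/organizations, social events, and political events.
#' @export
category_levels <- function() {
  c("authority", "society", "politics")
}

#' Construct a rumor-debunking corpus
#'
#' A corpus holds three linked tables: rumors, the original postings that
#' reference them (each optionally tagged with a debunking-method label), and
#' the reply comments to those postings (each optionally tagged with an SDQC
#' stance). Nested replies are flattened onto their root posting.
#'
#' @param rumors Data frame with columns `id`, `name`, `category`.
#' @param postings Data frame with columns `id`, `rumor_id`, `text`,
#'   `method` (token per [parse_method_token()], or `NA`), `is_debunking`.
#' @param comments Data frame with columns `id`, `posting_id`, `text`,
#'   `stance`, `truth_stance` (both `NA` or one of [stance_levels()];
#'   `truth_stance` is synthetic ground truth).
#' @param validate Run [validate_corpus()] (default `TRUE`).
#' @return A `debunk_corpus` object.
#' @export
debunk_corpus <- function(rumors = NULL, postings = NULL, comments = NULL,
                          validate = TRUE) {
  rumors <- complete_table(rumors, c(id = "character", name = "character",
                                     category = "character"))
  postings <- complete_table(postings, c(id = "character", rumor_id = "character",
                                         text = "character", method = "character",
                                         is_debunking = "logical"))
  comments <- complete_table(comments, c(id = "character", posting_id = "character",
                                         text = "character", stance = "character",
                                         truth_stance = "character"))
  postings$method <- canonicalize_methods(postings$method)
  x <- structure(list(rumors = rumors, postings = postings, comments = comments),
                 class = "debunk_corpus")
  if (validate) validate_corpus(x)
  x
}

# Coerce a possibly-NULL data frame to a tibble with exactly the given
# columns (name = mode), filling absent optional columns with NA.
complete_table <- function(df, cols) {
  if (is.null(df)) {
    df <- as_tibble(lapply(cols, function(m) vector(m, 0L)))
    return(df)
  }
  df <- as_tibble(df)
  missing_required <- setdiff(c("id"), names(df))
  if (length(missing_required) > 0 && nrow(df) > 0) {
    stop("table is missing required column(s): ",
         paste(missing_required, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cols)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- vector(cols[[nm]], nrow(df))
      df[[nm]][] <- NA
    } else {
      df[[nm]] <- switch(cols[[nm]],
                         character = as.character(df[[nm]]),
                         logical = as.logical(df[[nm]]))
    }
  }
  df[names(cols)]
}

#' Validate a corpus's referential and label invariants
#'
#' Checks id uniqueness within each table, that every comment resolves to a
#' posting and every posting to a rumor, that stance and method tokens come
#' from the recognized vocabularies, and that non-debunking postings carry no
#' debunking-method label other than `"Other"`.
#'
#' @param corpus A [debunk_corpus()].
#' @return The corpus, invisibly; errors name the offending record ids.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "debunk_corpus"))
  for (tab in c("rumors", "postings", "comments")) {
    ids <- corpus[[tab]]$id
    if (anyNA(ids)) stop("missing id in ", tab, call. = FALSE)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0) {
      stop("duplicate id(s) in ", tab, ": ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
  }
  bad_cat <- setdiff(stats::na.omit(corpus$rumors$category), category_levels())
  if (length(bad_cat) > 0) {
    stop("unknown rumor category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  dangling <- corpus$postings$id[!corpus$postings$rumor_id %in% corpus$rumors$id]
  if (length(dangling) > 0) {
    stop("posting(s) reference unknown rumor_id: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  dangling <- corpus$comments$id[!corpus$comments$posting_id %in% corpus$postings$id]
  if (length(dangling) > 0) {
    stop("comment(s) reference unknown posting_id: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  canonicalize_methods(corpus$postings$method)  # errors on unknown tokens
  non_deb <- !is.na(corpus$postings$is_debunking) & !corpus$postings$is_debunking
  offending <- corpus$postings$id[non_deb & !is.na(corpus$postings$method) &
                                    corpus$postings$method != "Other"]
  if (length(offending) > 0) {
    stop("non-debunking posting(s) carry a debunking-method label: ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  for (col in c("stance", "truth_stance")) {
    vals <- corpus$comments[[col]]
    bad <- !is.na(vals) & !vals %in% stance_levels()
    if (any(bad)) {
      stop("unknown ", col, " label(s) on comment(s): ",
           paste(corpus$comments$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(corpus)
}

#' @export
print.debunk_corpus <- function(x, ...) {
  cat("<debunk_corpus>\n")
  cat("  rumors:   ", nrow(x$rumors), "\n")
  cat("  postings: ", nrow(x$postings),
      sprintf(" (%d flagged debunking)", sum(x$postings$is_debunking, na.rm = TRUE)),
      "\n", sep = "")
  cat("  comments: ", nrow(x$comments),
      sprintf(" (%d stance-labeled)", sum(!is.na(x$comments$stance))),
      "\n", sep = "")
  invisible(x)
}

corpus_filenames <- function(format) {
  ext <- match.arg(format, c("jsonl", "csv"))
  stats::setNames(paste0(c("rumors", "postings", "comments"), ".", ext),
                  c("rumors", "postings", "comments"))
}

#' Save a corpus to disk
#'
#' Writes the three corpus tables to `rumors`, `postings` and `comments`
#' files inside `path`. JSONL holds one object per line; CSV is RFC 4180
#' with a header row. Both formats are UTF-8 and round-trip losslessly
#' through [load_corpus()], including combination signatures, which are
#' serialized as canonical `Com<...>` tokens.
#'
#' @param corpus A validated [debunk_corpus()].
#' @param path Directory to write into (created if absent).
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
save_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- corpus_filenames(format)
  for (tab in names(files)) {
    fp <- file.path(path, files[[tab]])
    df <- corpus[[tab]]
    if (format == "csv") {
      readr::write_csv(df, fp, na = "")
    } else {
      lines <- if (nrow(df) > 0) {
        vapply(seq_len(nrow(df)), function(i) {
          jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "null")
        }, character(1))
      } else {
        character(0)
      }
      con <- file(fp, open = "wb")
      writeLines(lines, con, useBytes = TRUE)
      close(con)
    }
  }
  invisible(path)
}

#' Load a corpus from disk
#'
#' Reads the file set written by [save_corpus()] and validates all corpus
#' invariants. Malformed JSONL records are reported with their file and line
#' number.
#'
#' @param path Directory containing the corpus files.
#' @param format `"jsonl"` or `"csv"`.
#' @return A validated [debunk_corpus()].
#' @export
load_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  files <- corpus_filenames(format)
  tabs <- lapply(names(files), function(tab) {
    fp <- file.path(path, files[[tab]])
    if (!file.exists(fp)) stop("missing corpus file: ", fp, call. = FALSE)
    if (format == "csv") {
      readr::read_csv(fp, col_types = readr::cols(.default = readr::col_character()),
                      na = "", progress = FALSE)
    } else {
      read_jsonl_table(fp)
    }
  })
  names(tabs) <- names(files)
  if ("is_debunking" %in% names(tabs$postings)) {
    tabs$postings$is_debunking <- as.logical(tabs$postings$is_debunking)
  }
  debunk_corpus(tabs$rumors, tabs$postings, tabs$comments)
}

read_jsonl_table <- function(fp) {
  lines <- readLines(fp, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(NULL)
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) {
                      stop("malformed JSONL record at ", basename(fp), ":", i,
                           " (", conditionMessage(e), ")", call. = FALSE)
                    })
    lapply(rec, function(v) if (is.null(v)) NA else v)
  })
  cols <- unique(unlist(lapply(rows, names)))
  as_tibble(lapply(stats::setNames(cols, cols), function(cn) {
    unlist(lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]]))
  }))
}

#' Restrict a corpus to debunking postings
#'
#' Keeps only postings flagged `is_debunking = TRUE` and the comments that
#' reply to them; retained records are unchanged. Mirrors the manual
#' filtering step that separates debunking postings from the rest of a
#' rumor-related collection.
#'
#' @param corpus A [debunk_corpus()] whose postings all carry an
#'   `is_debunking` flag; unflagged postings are an error (listed by id).
#' @return The filtered [debunk_corpus()].
#' @export
filter_debunking_postings <- function(corpus) {
  validate_corpus(corpus)
  unlabeled <- corpus$postings$id[is.na(corpus$postings$is_debunking)]
  if (length(unlabeled) > 0) {
    stop("posting(s) lack an is_debunking flag: ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  keep <- corpus$postings$is_debunking
  postings <- corpus$postings[keep, ]
  comments <- corpus$comments[corpus$comments$posting_id %in% postings$id, ]
  debunk_corpus(corpus$rumors, postings, comments)
}
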