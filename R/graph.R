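#' Decompose combination-method postings into signature groups
#'
#' Groups the comments under combination (`Com`) postings by the exact
#' combination signature over the base methods `{Ref, Per, Org}`. Each
#' distinct signature forms its own group: pooled stance counts, DI, RI and
#' DEI are computed per signature, and a triple is never counted into its
#' constituent pairs — the indices carried by pair and triple groups are
#' independent.
#'
#' @param corpus A labeled [debunk_corpus()].
#' @param stance_from Stance column to tally (see [tally_stances()]).
#' @return A `combo_edges` tibble: `signature` (canonical token),
#'   `members` (comma-joined), `edge_class` (`"pair"` solid / `"triple"`
#'   dotted), the pooled stance counts, `n_comments`, `di`, `ri`, `dei`.
#' @export
decompose_combinations <- function(corpus, stance_from = c("stance", "truth_stance")) {
  stance_from <- match.arg(stance_from)
  validate_corpus(corpus)
  is_com <- !is.na(corpus$postings$method) &
    startsWith(corpus$postings$method, "Com")
  postings <- corpus$postings[is_com, ]
  comments <- corpus$comments[corpus$comments$posting_id %in% postings$id, ]
  sub <- debunk_corpus(corpus$rumors, postings, comments)
  if (nrow(postings) == 0) {
    return(structure(tibble::tibble(signature = character(), members = character(),
                                    edge_class = character(), n_support = integer(),
                                    n_deny = integer(), n_query = integer(),
                                    n_comment = integer(), n_comments = integer(),
                                    di = double(), ri = double(), dei = double()),
                     class = c("combo_edges", "tbl_df", "tbl", "data.frame")))
  }
  eff <- effectiveness_table(sub, "method", stance_from, collapse_com = FALSE)
  member_list <- lapply(eff$method, function(tok) parse_method_token(tok)$combo)
  member_str <- vapply(member_list, paste, character(1), collapse = ",")
  edge_cls <- ifelse(lengths(member_list) == 2L, "pair", "triple")
  out <- eff |>
    dplyr::transmute(signature = .data$method,
                     members = member_str,
                     edge_class = edge_cls,
                     n_support = .data$n_support, n_deny = .data$n_deny,
                     n_query = .data$n_query, n_comment = .data$n_comment,
                     n_comments = .data$n_all,
                     di = .data$di, ri = .data$ri, dei = .data$dei)
  class(out) <- c("combo_edges", class(tibble::tibble()))
  out
}

combo_edges_to_igraph <- function(edges) {
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    members <- strsplit(edges$members[i], ",", fixed = TRUE)[[1]]
    if (edges$edge_class[i] == "pair") {
      ends <- matrix(members, ncol = 2)
    } else {
      # a triple renders as a clique of dotted edges sharing a triple id
      ends <- t(utils::combn(members, 2))
    }
    rows[[i]] <- tibble::tibble(
      from = ends[, 1], to = ends[, 2],
      signature = edges$signature[i],
      dei = edges$dei[i],
      n_comments = edges$n_comments[i],
      style = ifelse(edges$edge_class[i] == "pair", "solid", "dotted"),
      triple_id = ifelse(edges$edge_class[i] == "triple", edges$signature[i],
                         NA_character_))
  }
  edge_df <- dplyr::bind_rows(rows)
  igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                vertices = unique(c(edge_df$from, edge_df$to)))
}

#' Export the combination-method graph
#'
#' Writes the signature groups of [decompose_combinations()] as a graph
#' whose nodes are the base methods. Pair signatures become single solid
#' edges; a triple becomes a clique of dotted edges tagged with a shared
#' `triple_id`. Edge attributes carry `dei` (weight), `n_comments`
#' (thickness proxy), `style` and the originating `signature`. The CSV
#' format keeps one row per signature with the signature token verbatim
#' (lossless; see [read_combo_edges()]).
#'
#' @param edges A `combo_edges` table from [decompose_combinations()].
#' @param path Output file path.
#' @param format `"csv"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(edges, path, format = c("csv", "graphml", "dot")) {
  format <- match.arg(format)
  if (nrow(edges) == 0) stop("empty edge table", call. = FALSE)
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(edges), path, na = "")
  } else {
    g <- combo_edges_to_igraph(edges)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Re-import a CSV combination-edge table
#'
#' @param path CSV written by [export_graph()] with `format = "csv"`.
#' @return A `combo_edges` tibble equal (field-wise) to the exported one.
#' @export
read_combo_edges <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    signature = readr::col_character(), members = readr::col_character(),
    edge_class = readr::col_character(), n_support = readr::col_integer(),
    n_deny = readr::col_integer(), n_query = readr::col_integer(),
    n_comment = readr::col_integer(), n_comments = readr::col_integer(),
    di = readr::col_double(), ri = readr::col_double(),
    dei = readr::col_double()), na = "", progress = FALSE)
  class(out) <- c("combo_edges", class(tibble::tibble()))
  out
}
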