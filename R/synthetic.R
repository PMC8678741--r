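#' Build a synthetic-corpus generator configuration
#'
#' Describes a corpus-generating process with the statistical structure the
#' analysis assumes: rumors in three categories; postings per (rumor,
#' method) including combination signatures and `"Other"` (non-debunking)
#' postings; a per-(rumor, method) SDQC stance probability vector
#' `pi = (pS, pD, pQ, pC)`; overdispersed comments-per-posting via a
#' negative binomial; and a token-level text model in which each comment
#' token is, with probability `marker_prob`, a marker token specific to the
#' comment's true stance, and otherwise a shared filler token. Marker
#' tokens make the baseline classifier learnable; the text model is
#' deliberately language-agnostic.
#'
#' All randomness in [generate_corpus()] flows from the single `seed`
#' through one sequentially-consumed RNG stream, so identical configurations
#' produce identical corpora.
#'
#' @param rumors Tibble with columns `name`, `category`.
#' @param plan Tibble with columns `rumor`, `method` (token; `"Other"` rows
#'   are generated as non-debunking postings), `n_postings`.
#' @param stance_probs Tibble with columns `method`, `p_support`, `p_deny`,
#'   `p_query`, `p_comment` and optionally `rumor`; rows without a `rumor`
#'   apply to every rumor. Each row must sum to 1.
#' @param comment_mean,comment_dispersion Negative-binomial mean and size
#'   (smaller size = more overdispersion) for comments per posting.
#' @param comment_length Tokens per comment.
#' @param marker_prob Probability that a token is a stance marker.
#' @param n_marker_tokens Marker vocabulary size per stance.
#' @param n_filler_tokens Shared filler vocabulary size.
#' @param seed Integer seed.
#' @param include_text Generate comment texts (set `FALSE` for count-only
#'   simulations where text is irrelevant).
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(rumors, plan, stance_probs,
                             comment_mean = 25, comment_dispersion = 0.8,
                             comment_length = 8, marker_prob = 0.6,
                             n_marker_tokens = 3, n_filler_tokens = 40,
                             seed = 1L, include_text = TRUE) {
  cfg <- list(rumors = tibble::as_tibble(rumors),
              plan = tibble::as_tibble(plan),
              stance_probs = tibble::as_tibble(stance_probs),
              comment_mean = comment_mean,
              comment_dispersion = comment_dispersion,
              comment_length = comment_length,
              marker_prob = marker_prob,
              n_marker_tokens = n_marker_tokens,
              n_filler_tokens = n_filler_tokens,
              seed = as.integer(seed),
              include_text = isTRUE(include_text))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) stop(what, " is missing column(s): ",
                               paste(miss, collapse = ", "), call. = FALSE)
  }
  req(cfg$rumors, c("name", "category"), "rumors")
  req(cfg$plan, c("rumor", "method", "n_postings"), "plan")
  req(cfg$stance_probs, c("method", "p_support", "p_deny", "p_query", "p_comment"),
      "stance_probs")
  bad_cat <- setdiff(cfg$rumors$category, category_levels())
  if (length(bad_cat) > 0) stop("unknown category: ",
                                paste(bad_cat, collapse = ", "), call. = FALSE)
  if (anyDuplicated(cfg$rumors$name)) stop("duplicate rumor names", call. = FALSE)
  bad_rumor <- setdiff(cfg$plan$rumor, cfg$rumors$name)
  if (length(bad_rumor) > 0) stop("plan references unknown rumor(s): ",
                                  paste(bad_rumor, collapse = ", "), call. = FALSE)
  canonicalize_methods(cfg$plan$method)
  if (any(cfg$plan$n_postings < 0 | cfg$plan$n_postings != round(cfg$plan$n_postings))) {
    stop("n_postings must be non-negative integers", call. = FALSE)
  }
  pmat <- as.matrix(cfg$stance_probs[, c("p_support", "p_deny", "p_query", "p_comment")])
  if (any(pmat < 0)) stop("stance probabilities must be non-negative", call. = FALSE)
  sums <- rowSums(pmat)
  if (any(abs(sums - 1) > 1e-8)) {
    stop("stance probability row(s) do not sum to 1: rows ",
         paste(which(abs(sums - 1) > 1e-8), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(cfg$comment_mean) || cfg$comment_mean <= 0) {
    stop("comment_mean must be positive", call. = FALSE)
  }
  if (cfg$comment_dispersion <= 0) stop("comment_dispersion must be positive",
                                        call. = FALSE)
  if (cfg$marker_prob < 0 || cfg$marker_prob > 1) {
    stop("marker_prob must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  rumors:", nrow(x$rumors), "| plan rows:", nrow(x$plan),
      "| postings:", sum(x$plan$n_postings), "\n")
  cat(sprintf("  comments/posting ~ NegBin(mean = %g, size = %g); %d tokens/comment, marker prob %g\n",
              x$comment_mean, x$comment_dispersion, x$comment_length, x$marker_prob))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Analytic DI, RI and DEI for a stance probability vector
#'
#' Closed-form indices of the generating distribution
#' `pi = (pS, pD, pQ, pC)`: `DI = (pD - pS) / (pD + pS)`, `RI = pC`,
#' `DEI = DI / RI`, with the same undefined-value conventions as the
#' empirical indices (`NA` when `pD + pS = 0`, or for DEI when `pC = 0`).
#'
#' @param pi Numeric vector of 4 probabilities in the order supporting,
#'   denying, querying, commenting (need not be named).
#' @return List with `di`, `ri`, `dei`.
#' @export
#' @examples
#' analytic_indices(c(0.05, 0.35, 0.10, 0.50))  # DI 0.75, RI 0.5, DEI 1.5
analytic_indices <- function(pi) {
  stopifnot(length(pi) == 4, all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  ps <- pi[[1]]; pd <- pi[[2]]; pc <- pi[[4]]
  di <- if (pd + ps > 0) (pd - ps) / (pd + ps) else NA_real_
  ri <- pc
  list(di = di, ri = ri,
       dei = if (!is.na(di) && ri > 0) di / ri else NA_real_)
}

# Resolve the stance probability row for a (rumor, method); rumor-specific
# rows take precedence over method-wide rows.
lookup_pi <- function(stance_probs, rumor, method) {
  has_rumor <- "rumor" %in% names(stance_probs)
  if (has_rumor) {
    hit <- stance_probs[!is.na(stance_probs$rumor) &
                          stance_probs$rumor == rumor &
                          stance_probs$method == method, ]
    if (nrow(hit) == 0) {
      hit <- stance_probs[is.na(stance_probs$rumor) &
                            stance_probs$method == method, ]
    }
  } else {
    hit <- stance_probs[stance_probs$method == method, ]
  }
  if (nrow(hit) == 0) {
    stop("no stance probability vector for (", rumor, ", ", method, ")",
         call. = FALSE)
  }
  as.numeric(hit[1, c("p_support", "p_deny", "p_query", "p_comment")])
}

marker_vocab <- function(n_marker_tokens, n_filler_tokens) {
  short <- c(supporting = "sup", denying = "den", querying = "qry",
             commenting = "cmt")
  markers <- lapply(short, function(s) paste0(s, seq_len(n_marker_tokens)))
  filler <- paste0("flr", seq_len(n_filler_tokens))
  list(markers = markers, filler = filler)
}

#' Generate a synthetic labeled corpus with ground truth
#'
#' Draws a corpus from a [generator_config()]: per plan row, `n_postings`
#' postings; per posting, a negative-binomial number of comments; per
#' comment, a true SDQC stance from the group's `pi` and (optionally) a
#' marker-token text. `"Other"` plan rows yield non-debunking postings;
#' all other rows are flagged `is_debunking = TRUE`. The returned ground
#' truth records the exact drawn tallies and the analytic indices of each
#' group's `pi`, so downstream estimates can be checked against both.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a [debunk_corpus()]; `truth_stance` holds the
#'   generated labels, `stance` is left unset), `ground_truth` (tibble per
#'   (rumor, method): drawn stance tallies plus `analytic_di`, `analytic_ri`,
#'   `analytic_dei`), and `per_posting` (tibble of drawn per-posting
#'   tallies).
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  vocab <- marker_vocab(config$n_marker_tokens, config$n_filler_tokens)

  rumors <- tibble::tibble(id = paste0("r", seq_len(nrow(config$rumors))),
                           name = config$rumors$name,
                           category = config$rumors$category)
  plan <- config$plan[config$plan$n_postings > 0, ]
  postings_list <- list(); comments_list <- list()
  p_counter <- 0L; c_counter <- 0L
  for (row in seq_len(nrow(plan))) {
    rumor_name <- plan$rumor[row]
    method <- canonicalize_methods(plan$method[row])
    n_post <- plan$n_postings[row]
    pi <- lookup_pi(config$stance_probs, rumor_name, method)
    rumor_id <- rumors$id[rumors$name == rumor_name]
    p_ids <- sprintf("p%05d", p_counter + seq_len(n_post))
    p_counter <- p_counter + n_post
    postings_list[[row]] <- tibble::tibble(
      id = p_ids, rumor_id = rumor_id,
      text = paste("posting", p_ids),
      method = method,
      is_debunking = method != "Other")
    n_comments <- stats::rnbinom(n_post, size = config$comment_dispersion,
                                 mu = config$comment_mean)
    total <- sum(n_comments)
    if (total == 0) next
    drawn_stance <- sample(stance_levels(), total, replace = TRUE, prob = pi)
    comment_text <- if (config$include_text) {
      synth_texts(drawn_stance, config, vocab)
    } else {
      rep("", total)
    }
    comments_list[[row]] <- tibble::tibble(
      id = sprintf("c%07d", c_counter + seq_len(total)),
      posting_id = rep(p_ids, n_comments),
      text = comment_text,
      stance = NA_character_,
      truth_stance = drawn_stance)
    c_counter <- c_counter + total
  }
  postings <- dplyr::bind_rows(postings_list)
  comments <- dplyr::bind_rows(comments_list)
  corpus <- debunk_corpus(rumors, postings, comments)

  per_posting <- if (nrow(comments) > 0) {
    tally_stances(corpus, "posting", "truth_stance", collapse_com = FALSE)
  } else {
    tibble::tibble()
  }
  ground_truth <- if (nrow(comments) > 0) {
    tal <- tally_stances(corpus, "rumor_method", "truth_stance",
                         collapse_com = FALSE)
    ai <- purrr::map2(tal$rumor, tal$method, function(r, m) {
      analytic_indices(lookup_pi(config$stance_probs, r, m))
    })
    tal$analytic_di <- purrr::map_dbl(ai, "di")
    tal$analytic_ri <- purrr::map_dbl(ai, "ri")
    tal$analytic_dei <- purrr::map_dbl(ai, "dei")
    tal
  } else {
    tibble::tibble()
  }
  list(corpus = corpus, ground_truth = ground_truth, per_posting = per_posting)
}

synth_texts <- function(stance, config, vocab) {
  len <- config$comment_length
  vapply(stance, function(s) {
    is_marker <- stats::runif(len) < config$marker_prob
    toks <- character(len)
    n_m <- sum(is_marker)
    if (n_m > 0) toks[is_marker] <- sample(vocab$markers[[s]], n_m, replace = TRUE)
    if (n_m < len) toks[!is_marker] <- sample(vocab$filler, len - n_m, replace = TRUE)
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Default study-like generator configuration
#'
#' A desk-scale configuration mirroring the qualitative structure of a
#' large Weibo COVID-19 rumor-debunking collection: five rumors across the
#' authority, society and politics categories; a method mix dominated by
#' combination postings (over 60% of debunking postings, split across the
#' `Com<Ref,Per>`, `Com<Ref,Org>` and `Com<Ref,Per,Org>` signatures),
#' followed by refutation and denial; a small share of non-debunking
#' (`Other`) postings; and stance vectors with heavy commenting mass,
#' ordered `pC > pD > pQ > pS` for every debunking method, with a larger
#' supporting share under `Other`. Comment counts are overdispersed
#' (negative binomial, mean 25, size 0.8).
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
default_study_config <- function(seed = 1L) {
  rumors <- tibble::tibble(
    name = c("News", "PatientZero", "Jiangsu", "Car", "Russia"),
    category = c("authority", "authority", "society", "society", "politics"))
  per_rumor <- tibble::tibble(
    method = c("Den", "Fur", "Ref", "Per", "Org",
               "Com<Ref,Per>", "Com<Ref,Org>", "Com<Ref,Per,Org>", "Other"),
    n_postings = c(9L, 2L, 12L, 3L, 4L, 8L, 24L, 14L, 6L))
  plan <- tidyr::crossing(rumor = rumors$name, per_rumor)
  stance_probs <- tibble::tibble(
    method = c("Den", "Fur", "Ref", "Per", "Org",
               "Com<Ref,Per>", "Com<Ref,Org>", "Com<Ref,Per,Org>", "Other"),
    p_support = c(0.020, 0.030, 0.030, 0.040, 0.050, 0.035, 0.030, 0.030, 0.100),
    p_deny    = c(0.280, 0.150, 0.420, 0.220, 0.200, 0.345, 0.330, 0.300, 0.250),
    p_query   = c(0.080, 0.090, 0.100, 0.120, 0.160, 0.100, 0.100, 0.120, 0.120),
    p_comment = c(0.620, 0.730, 0.450, 0.620, 0.590, 0.520, 0.540, 0.550, 0.530))
  generator_config(rumors = rumors, plan = plan, stance_probs = stance_probs,
                   comment_mean = 25, comment_dispersion = 0.8,
                   comment_length = 8, marker_prob = 0.6, seed = seed)
}

#' Read / write a generator configuration as JSON
#'
#' @param config A [generator_config()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_generator_config()` returns the config.
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  payload <- unclass(config)
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  payload <- jsonlite::fromJSON(path)
  generator_config(rumors = payload$rumors, plan = payload$plan,
                   stance_probs = payload$stance_probs,
                   comment_mean = payload$comment_mean,
                   comment_dispersion = payload$comment_dispersion,
                   comment_length = payload$comment_length,
                   marker_prob = payload$marker_prob,
                   n_marker_tokens = payload$n_marker_tokens,
                   n_filler_tokens = payload$n_filler_tokens,
                   seed = payload$seed,
                   include_text = payload$include_text)
}
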