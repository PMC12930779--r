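#' Scoring configuration
#'
#' @param penalty Positive multiplier applied to the negative-keyword sum
#'   (default 1.2, the reference value of the scoring formula); exposed for
#'   sensitivity analysis.
#' @param overlap_policy Match-counting policy; only `"non_overlapping"`
#'   (greedy left-to-right) is implemented.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(penalty = 1.2, overlap_policy = "non_overlapping") {
  stopifnot(is.numeric(penalty), length(penalty) == 1, penalty > 0)
  overlap_policy <- match.arg(overlap_policy, "non_overlapping")
  structure(
    list(penalty = penalty, overlap_policy = overlap_policy),
    class = "scoring_config"
  )
}

score_components <- function(tokens, registry) {
  word_count <- length(tokens)
  phrase_tokens <- strsplit(registry$phrase, " ", fixed = TRUE)
  match_count <- vapply(
    phrase_tokens, function(p) count_matches(tokens, p), integer(1)
  )
  phrase_len <- lengths(phrase_tokens)
  m <- if (word_count > 0) match_count * phrase_len / word_count else
    rep(0, length(match_count))
  tibble::tibble(
    phrase = registry$phrase,
    polarity = registry$polarity,
    weight = registry$weight,
    match_count = match_count,
    m = m,
    contribution = registry$normalized_weight * m
  )
}

#' Compute the term score of one record
#'
#' The term score of a record with title+abstract token count `W` is
#' `TS = sum(w_p * m_p) - penalty * sum(w_n * m_n)`, where for each keyword
#' `w = weight / 10` and `m = match_count * phrase_word_count / W`. Positive
#' keywords raise the score, negative keywords lower it, and the penalty
#' (default 1.2) tilts the balance against records matching exclusion
#' vocabulary. Higher scores mean more relevant to the review.
#'
#' @param title Record title (must tokenize to at least one token together
#'   with the abstract; a record with no tokens should have been excluded
#'   upstream and raises an error here).
#' @param abstract Record abstract, may be `NA`.
#' @param registry A [keyword_registry()].
#' @param config A [scoring_config()].
#' @return An object of class `term_score`: a list with `ts`, `pos_sum`,
#'   `neg_sum`, `penalty`, `word_count` and a `components` tibble (one row
#'   per registry keyword with its match count, density `m` and weighted
#'   contribution) for audit.
#' @examples
#' reg <- keyword_registry() |>
#'   add_keyword("sleep quality", "positive", 8) |>
#'   add_keyword("rat", "negative", 5)
#' term_score("Sleep quality in shift workers",
#'            "A longitudinal sleep quality study.", reg)
#' @export
term_score <- function(title, abstract = NA_character_, registry,
                       config = scoring_config()) {
  doc <- tokenize_record(title, abstract)
  if (doc$word_count == 0) {
    stop(paste0(
      "record has no tokens (empty title and abstract); ",
      "it should have been excluded upstream"
    ), call. = FALSE)
  }
  components <- score_components(doc$tokens, registry)
  pos_sum <- sum(components$contribution[components$polarity == "positive"])
  neg_sum <- sum(components$contribution[components$polarity == "negative"])
  structure(
    list(
      ts = pos_sum - config$penalty * neg_sum,
      pos_sum = pos_sum,
      neg_sum = neg_sum,
      penalty = config$penalty,
      word_count = doc$word_count,
      components = components
    ),
    class = "term_score"
  )
}

#' @export
print.term_score <- function(x, ...) {
  cat(sprintf(
    "<term_score> TS = %.4f (pos %.4f - %.1f x neg %.4f), %d tokens\n",
    x$ts, x$pos_sum, x$penalty, x$neg_sum, x$word_count
  ))
  invisible(x)
}

#' @method tidy term_score
#' @export
tidy.term_score <- function(x, ...) {
  x$components
}

#' @method glance term_score
#' @export
glance.term_score <- function(x, ...) {
  tibble::tibble(
    ts = x$ts, pos_sum = x$pos_sum, neg_sum = x$neg_sum,
    penalty = x$penalty, word_count = x$word_count
  )
}

#' Score every record in a table
#'
#' Computes the term score for each non-excluded record from its title and
#' abstract tokens. Records flagged by [flag_exclusions()] are carried
#' through with `NA` scores (they are ranked last by [rank_records()], never
#' scored). A non-excluded record with no tokens raises an error.
#'
#' @param records A records tibble (run [flag_exclusions()] first if
#'   exclusion rules should apply; records with `excluded = NA` are treated
#'   as not excluded).
#' @param registry A [keyword_registry()].
#' @param config A [scoring_config()].
#' @return A tibble with columns `record_id`, `word_count`, `pos_sum`,
#'   `neg_sum`, `ts`, `excluded`.
#' @export
score_records <- function(records, registry, config = scoring_config()) {
  excluded <- if ("excluded" %in% names(records)) {
    !is.na(records$excluded) & records$excluded
  } else {
    rep(FALSE, nrow(records))
  }
  phrase_tokens <- strsplit(registry$phrase, " ", fixed = TRUE)
  phrase_len <- lengths(phrase_tokens)
  w <- registry$normalized_weight
  sign_pos <- registry$polarity == "positive"

  token_list <- purrr::map2(records$title, records$abstract,
                            ~ c(tokenize(.x), tokenize(.y)))
  word_count <- lengths(token_list)
  if (any(word_count == 0 & !excluded)) {
    bad <- records$record_id[which(word_count == 0 & !excluded)[1]]
    stop(sprintf(
      'record "%s" has no tokens and is not excluded; cannot score', bad
    ), call. = FALSE)
  }

  pos_sum <- rep(NA_real_, nrow(records))
  neg_sum <- rep(NA_real_, nrow(records))
  idx <- which(!excluded)
  if (nrow(registry) == 0) {
    pos_sum[idx] <- 0
    neg_sum[idx] <- 0
  } else {
    for (i in idx) {
      tokens <- token_list[[i]]
      counts <- vapply(phrase_tokens, function(p) count_matches(tokens, p),
                       integer(1))
      contrib <- w * counts * phrase_len / word_count[i]
      pos_sum[i] <- sum(contrib[sign_pos])
      neg_sum[i] <- sum(contrib[!sign_pos])
    }
  }
  tibble::tibble(
    record_id = records$record_id,
    word_count = word_count,
    pos_sum = pos_sum,
    neg_sum = neg_sum,
    ts = pos_sum - config$penalty * neg_sum,
    excluded = excluded
  )
}

#' Title-stage elimination decisions
#'
#' First-pass triage on titles alone: under the default rule a record is
#' eliminated when its title contains at least one negative keyword match and
#' no positive match. Decisions are returned per record (not applied
#' destructively) so they can be exported for manual review.
#'
#' @param records A records tibble (titles must be present).
#' @param registry A [keyword_registry()].
#' @param rule Only `"default"` is implemented.
#' @return A tibble with columns `record_id`, `n_positive`, `n_negative`,
#'   `decision` (`"eliminate"` or `"retain"`).
#' @export
title_screen <- function(records, registry, rule = "default") {
  rule <- match.arg(rule, "default")
  phrase_tokens <- strsplit(registry$phrase, " ", fixed = TRUE)
  is_pos <- registry$polarity == "positive"
  res <- purrr::map(records$title, function(title) {
    tokens <- tokenize(title)
    counts <- vapply(phrase_tokens, function(p) count_matches(tokens, p),
                     integer(1))
    c(n_positive = sum(counts[is_pos]), n_negative = sum(counts[!is_pos]))
  })
  n_positive <- vapply(res, `[[`, integer(1), "n_positive")
  n_negative <- vapply(res, `[[`, integer(1), "n_negative")
  tibble::tibble(
    record_id = records$record_id,
    n_positive = n_positive,
    n_negative = n_negative,
    decision = ifelse(n_negative >= 1 & n_positive == 0,
                      "eliminate", "retain")
  )
}
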