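#' Tokenize free text into normalized word tokens
#'
#' Normalization is deterministic and shared by every stage of the pipeline:
#' Unicode NFKC, lower case, punctuation replaced by whitespace, then split on
#' runs of whitespace. Digits are kept as tokens. `NA` or empty input yields a
#' zero-length token vector.
#'
#' @param text A character vector (each element tokenized independently when
#'   `length(text) > 1` and results are concatenated in order).
#' @return A character vector of tokens.
#' @examples
#' tokenize("Sleep, quality!")
#' @export
tokenize <- function(text) {
  text <- text[!is.na(text)]
  if (length(text) == 0) return(character())
  x <- stringi::stri_trans_nfkc(text)
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}\\s]+", " ")
  x <- stringr::str_squish(x)
  x <- x[x != ""]
  if (length(x) == 0) return(character())
  unlist(strsplit(x, " ", fixed = TRUE), use.names = FALSE)
}

#' Normalize a keyword phrase
#'
#' Applies the same normalization as [tokenize()] and rejoins with single
#' spaces, so stored registry phrases match document tokens by construction.
#'
#' @param phrase A character scalar.
#' @return A normalized character scalar (possibly `""` if nothing survives).
#' @export
normalize_phrase <- function(phrase) {
  paste(tokenize(phrase), collapse = " ")
}

#' Tokenize a record's title and abstract as one document
#'
#' Title tokens come first, abstract tokens after; the total token count is the
#' word-count denominator of the term score.
#'
#' @param title,abstract Character scalars; `abstract` may be `NA`.
#' @return A list with elements `tokens` (character) and `word_count` (integer).
#' @export
tokenize_record <- function(title, abstract = NA_character_) {
  tokens <- c(tokenize(title), tokenize(abstract))
  list(tokens = tokens, word_count = length(tokens))
}

#' Count non-overlapping phrase occurrences in a token sequence
#'
#' Occurrences are counted greedily left to right; once a match is taken its
#' tokens cannot take part in another match. This is the match-count used by
#' [term_score()].
#'
#' @param tokens Character vector of document tokens.
#' @param phrase Character vector of phrase tokens (length >= 1).
#' @return Integer count of matches.
#' @examples
#' count_matches(c("a", "a", "a"), c("a", "a")) # 1, greedy non-overlap
#' @export
count_matches <- function(tokens, phrase) {
  k <- length(phrase)
  if (k == 0) stop("`phrase` must contain at least one token", call. = FALSE)
  n <- length(tokens)
  if (n < k) return(0L)
  if (k == 1L) return(sum(tokens == phrase))
  starts <- which(tokens == phrase[1L])
  starts <- starts[starts + k - 1L <= n]
  if (length(starts) == 0) return(0L)
  hits <- starts[vapply(
    starts,
    function(s) all(tokens[s:(s + k - 1L)] == phrase),
    logical(1)
  )]
  count <- 0L
  last_end <- 0L
  for (s in hits) {
    if (s > last_end) {
      count <- count + 1L
      last_end <- s + k - 1L
    }
  }
  count
}
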