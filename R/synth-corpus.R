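#' Parameters for a synthetic labelled corpus
#'
#' The generator emulates the statistical structure the term-scoring method
#' relies on: a minority eligible class, class-dependent planting of keyword
#' phrases into titles and abstracts over a background of synthetic
#' vocabulary words, variable abstract lengths, and realistic missingness
#' (absent DOI, absent abstract, short abstract).
#'
#' @param n_records Number of records (>= 1).
#' @param prevalence Eligible fraction, strictly inside (0, 1).
#' @param vocab_size Background vocabulary size (synthetic words).
#' @param planted_positive,planted_negative Tibbles with columns `phrase`,
#'   `rate_eligible`, `rate_ineligible`: per-class probabilities that the
#'   phrase occurs (as one contiguous block) in a record of that class.
#' @param abstract_mean_tokens,abstract_dispersion Mean and negative-binomial
#'   size parameter of the abstract length distribution (tokens).
#' @param missing_doi_rate,missing_abstract_rate,short_abstract_rate
#'   Independent per-record probabilities of the corresponding defect; a
#'   "short" abstract is truncated under 200 characters.
#' @param title_plant_prob Probability that a planted phrase lands in the
#'   title rather than the abstract (titles drive the title-screening step).
#' @param rng_seed Integer seed; together with the other parameters it fully
#'   determines the corpus.
#' @return A list of class `corpus_params`.
#' @export
corpus_params <- function(n_records,
                          prevalence,
                          vocab_size = 1000L,
                          planted_positive = NULL,
                          planted_negative = NULL,
                          abstract_mean_tokens = 150,
                          abstract_dispersion = 12,
                          missing_doi_rate = 0,
                          missing_abstract_rate = 0,
                          short_abstract_rate = 0,
                          title_plant_prob = 0.25,
                          rng_seed = 1L) {
  stopifnot(n_records >= 1, vocab_size >= 10,
            abstract_mean_tokens > 0, abstract_dispersion > 0,
            title_plant_prob >= 0, title_plant_prob <= 1)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must be strictly between 0 and 1", call. = FALSE)
  }
  rates <- c(missing_doi_rate, missing_abstract_rate, short_abstract_rate)
  if (any(rates < 0 | rates >= 1)) {
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  }
  check_planted <- function(x, arg) {
    if (is.null(x)) {
      return(tibble::tibble(phrase = character(), rate_eligible = numeric(),
                            rate_ineligible = numeric()))
    }
    stopifnot(all(c("phrase", "rate_eligible", "rate_ineligible") %in%
                    names(x)))
    if (any(x$rate_eligible < 0 | x$rate_eligible >= 1 |
              x$rate_ineligible < 0 | x$rate_ineligible >= 1)) {
      stop(sprintf("`%s` rates must lie in [0, 1)", arg), call. = FALSE)
    }
    x$phrase <- vapply(x$phrase, normalize_phrase, character(1),
                       USE.NAMES = FALSE)
    tibble::as_tibble(x[, c("phrase", "rate_eligible", "rate_ineligible")])
  }
  structure(
    list(
      n_records = as.integer(n_records),
      prevalence = prevalence,
      vocab_size = as.integer(vocab_size),
      planted_positive = check_planted(planted_positive, "planted_positive"),
      planted_negative = check_planted(planted_negative, "planted_negative"),
      abstract_mean_tokens = abstract_mean_tokens,
      abstract_dispersion = abstract_dispersion,
      missing_doi_rate = missing_doi_rate,
      missing_abstract_rate = missing_abstract_rate,
      short_abstract_rate = short_abstract_rate,
      title_plant_prob = title_plant_prob,
      rng_seed = as.integer(rng_seed)
    ),
    class = "corpus_params"
  )
}

# Splice phrase blocks into a background token vector at the given gap
# positions (0 = before the first token). Blocks stay contiguous so a planted
# phrase is always recoverable by exact matching.
insert_blocks <- function(bg, blocks, slots) {
  if (length(blocks) == 0) return(bg)
  ord <- order(slots)
  pieces <- vector("list", 2 * length(blocks) + 1)
  k <- 0L
  prev <- 0L
  for (j in ord) {
    s <- slots[j]
    if (s > prev) {
      k <- k + 1L
      pieces[[k]] <- bg[(prev + 1L):s]
      prev <- s
    }
    k <- k + 1L
    pieces[[k]] <- blocks[[j]]
  }
  if (prev < length(bg)) {
    k <- k + 1L
    pieces[[k]] <- bg[(prev + 1L):length(bg)]
  }
  unlist(pieces[seq_len(k)], use.names = FALSE)
}

#' Generate a synthetic labelled corpus
#'
#' Each record is drawn independently: class by `prevalence`; background
#' title (5-15 tokens) and abstract tokens uniform over the synthetic
#' vocabulary; each planted phrase inserted as a contiguous block with its
#' class-conditional rate (into the title with probability
#' `title_plant_prob`, else the abstract); missingness applied independently
#' afterwards. The generation manifest (the `corpus_params`) is attached as
#' the `"manifest"` attribute and suffices to regenerate the corpus
#' bit-identically.
#'
#' @param params A [corpus_params()].
#' @return A labelled records tibble (columns as in [read_records()] plus
#'   `gold_label`), with attribute `manifest`.
#' @export
generate_corpus <- function(params) {
  stopifnot(inherits(params, "corpus_params"))
  n <- params$n_records
  planted <- dplyr::bind_rows(
    dplyr::mutate(params$planted_positive, polarity = "positive"),
    dplyr::mutate(params$planted_negative, polarity = "negative")
  )
  blocks_all <- strsplit(planted$phrase, " ", fixed = TRUE)
  withr::with_seed(params$rng_seed, {
    eligible <- stats::runif(n) < params$prevalence
    vocab <- sprintf("w%05d", seq_len(params$vocab_size))
    title_len <- sample(5:15, n, replace = TRUE)
    abs_len <- pmax(
      stats::rnbinom(n, size = params$abstract_dispersion,
                     mu = params$abstract_mean_tokens),
      3L
    )
    n_phrases <- nrow(planted)
    present <- matrix(FALSE, n, max(n_phrases, 1L))
    if (n_phrases > 0) {
      for (j in seq_len(n_phrases)) {
        rate <- ifelse(eligible, planted$rate_eligible[j],
                       planted$rate_ineligible[j])
        present[, j] <- stats::runif(n) < rate
      }
    }
    in_title <- matrix(stats::runif(n * max(n_phrases, 1L)) <
                         params$title_plant_prob, n)
    titles <- character(n)
    abstracts <- character(n)
    for (i in seq_len(n)) {
      title_bg <- sample(vocab, title_len[i], replace = TRUE)
      abs_bg <- sample(vocab, abs_len[i], replace = TRUE)
      here <- if (n_phrases > 0) which(present[i, ]) else integer()
      t_idx <- here[in_title[i, here]]
      a_idx <- setdiff(here, t_idx)
      title_tokens <- insert_blocks(
        title_bg, blocks_all[t_idx],
        if (length(t_idx)) sample(0:title_len[i], length(t_idx),
                                  replace = TRUE) else integer()
      )
      abs_tokens <- insert_blocks(
        abs_bg, blocks_all[a_idx],
        if (length(a_idx)) sample(0:abs_len[i], length(a_idx),
                                  replace = TRUE) else integer()
      )
      titles[i] <- paste(title_tokens, collapse = " ")
      abstracts[i] <- paste(abs_tokens, collapse = " ")
    }
    missing_doi <- stats::runif(n) < params$missing_doi_rate
    missing_abs <- stats::runif(n) < params$missing_abstract_rate
    short_abs <- stats::runif(n) < params$short_abstract_rate
    for (i in which(short_abs & !missing_abs)) {
      tokens <- strsplit(abstracts[i], " ", fixed = TRUE)[[1]]
      tokens <- tokens[seq_len(min(length(tokens), sample(8:20, 1)))]
      txt <- paste(tokens, collapse = " ")
      while (nchar(txt) >= 200 && length(tokens) > 1) {
        tokens <- tokens[-length(tokens)]
        txt <- paste(tokens, collapse = " ")
      }
      abstracts[i] <- txt
    }
  })
  doi <- sprintf("10.1000/synth.%05d", seq_len(n))
  doi[missing_doi] <- NA_character_
  abstracts[missing_abs] <- NA_character_
  corpus <- tibble::tibble(
    record_id = sprintf("R%05d", seq_len(n)),
    doi = doi,
    title = titles,
    abstract = abstracts,
    article_type = "article",
    gold_label = ifelse(eligible, "eligible", "ineligible"),
    excluded = NA,
    exclusion_rules = NA_character_
  )
  attr(corpus, "manifest") <- list(params = params)
  corpus
}

benchmark_cache <- new.env(parent = emptyenv())

benchmark_phrases <- function() {
  positive <- c(
    "mental health", "mood tracking", "smartphone survey",
    "general population", "anxiety screening",
    "longitudinal", "digital", "questionnaire", "cohort",
    "wellbeing", "depression", "followup"
  )
  negative <- c(
    "rat model", "in vitro", "gene expression", "cell line",
    "crystal structure", "wastewater treatment",
    "mice", "protein", "soil", "polymer", "astrophysics", "catalyst"
  )
  strong <- seq(0.30, 0.63, by = 0.03)
  list(
    positive = tibble::tibble(
      phrase = positive,
      rate_eligible = strong,
      rate_ineligible = strong / 8
    ),
    negative = tibble::tibble(
      phrase = negative,
      rate_eligible = strong / 8,
      rate_ineligible = strong
    )
  )
}

#' The fixed strong-planting benchmark corpus
#'
#' A 5,000-record corpus with eligible prevalence 0.08, twelve positive and
#' twelve negative planted phrases (one- and two-word) whose eligible-class
#' rates are 8x their ineligible-class rates (and vice versa for negatives),
#' missing-DOI and missing-abstract rates of 0.02 each and a short-abstract
#' rate of 0.01 (so roughly 5% of records trip the default exclusion rules),
#' generated under seed 13. [benchmark_registry()] is the matching keyword
#' registry with weights spanning 1-10.
#'
#' @param use_cache Reuse the in-session cached copy (the corpus is fully
#'   determined by its parameters).
#' @return A labelled records tibble of 5,000 rows.
#' @export
benchmark_corpus <- function(use_cache = TRUE) {
  if (use_cache && !is.null(benchmark_cache$corpus)) {
    return(benchmark_cache$corpus)
  }
  phrases <- benchmark_phrases()
  params <- corpus_params(
    n_records = 5000L,
    prevalence = 0.08,
    vocab_size = 1000L,
    planted_positive = phrases$positive,
    planted_negative = phrases$negative,
    abstract_mean_tokens = 150,
    abstract_dispersion = 12,
    missing_doi_rate = 0.02,
    missing_abstract_rate = 0.02,
    short_abstract_rate = 0.01,
    rng_seed = 13L
  )
  corpus <- generate_corpus(params)
  if (use_cache) benchmark_cache$corpus <- corpus
  corpus
}

#' @rdname benchmark_corpus
#' @export
benchmark_registry <- function() {
  phrases <- benchmark_phrases()
  reg <- keyword_registry()
  weights <- pmin(seq_len(12), 10L)  # ascending with planting rate, spans 1-10
  for (i in seq_len(12)) {
    reg <- add_keyword(reg, phrases$positive$phrase[i], "positive", weights[i])
  }
  for (i in seq_len(12)) {
    reg <- add_keyword(reg, phrases$negative$phrase[i], "negative", weights[i])
  }
  reg
}
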