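# Shared fixtures built in code at test time.

make_records <- function(n = 5, abstract_tokens = 60) {
  tibble::tibble(
    record_id = sprintf("A%03d", seq_len(n)),
    doi = sprintf("10.1000/test.%03d", seq_len(n)),
    title = sprintf("study number %d of sleep quality", seq_len(n)),
    abstract = vapply(
      seq_len(n),
      function(i) paste(rep(sprintf("token%d", i), abstract_tokens),
                        collapse = " "),
      character(1)
    ),
    article_type = "article",
    gold_label = NA_character_,
    excluded = NA,
    exclusion_rules = NA_character_
  )
}

small_registry <- function() {
  keyword_registry() |>
    add_keyword("sleep quality", "positive", 8) |>
    add_keyword("longitudinal", "positive", 10) |>
    add_keyword("rat", "negative", 5)
}

# Independent oracle: dumbest possible greedy non-overlapping match counter.
oracle_count <- function(tokens, phrase) {
  k <- length(phrase)
  count <- 0L
  i <- 1L
  while (i + k - 1L <= length(tokens)) {
    if (all(tokens[i:(i + k - 1L)] == phrase)) {
      count <- count + 1L
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  count
}

# Independent oracle for the scoring formula: explicit double loop over
# keywords, no shared code with score_components().
oracle_ts <- function(tokens, registry, penalty = 1.2) {
  pos <- numeric()
  neg <- numeric()
  for (r in seq_len(nrow(registry))) {
    phrase <- strsplit(registry$phrase[r], " ", fixed = TRUE)[[1]]
    m <- oracle_count(tokens, phrase) * length(phrase) / length(tokens)
    contrib <- (registry$weight[r] / 10) * m
    if (registry$polarity[r] == "positive") pos <- c(pos, contrib) else
      neg <- c(neg, contrib)
  }
  sum(pos) - penalty * sum(neg)
}

random_registry <- function(vocab, n_keywords = 8, max_len = 3) {
  reg <- keyword_registry()
  used <- character()
  for (i in seq_len(n_keywords)) {
    repeat {
      phrase <- paste(sample(vocab, sample.int(max_len, 1), replace = TRUE),
                      collapse = " ")
      if (!phrase %in% used) break
    }
    used <- c(used, phrase)
    reg <- add_keyword(reg, phrase,
                       sample(c("positive", "negative"), 1),
                       sample.int(10, 1))
  }
  reg
}
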