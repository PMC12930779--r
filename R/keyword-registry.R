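#' Create an empty keyword registry
#'
#' A keyword registry holds the expert-curated positive and negative keyword
#' phrases with integer weights in 1..10. It is a tibble with columns
#' `phrase`, `polarity`, `weight`, `normalized_weight`, plus a version counter
#' and a revision log kept as attributes. Every committed mutation
#' ([add_keyword()], [revise_weight()]) increments the version by one and
#' appends a log entry.
#'
#' @return A `keyword_registry` (tibble subclass) with zero rows, version 0.
#' @seealso [add_keyword()], [revise_weight()], [save_registry()],
#'   [load_registry()]
#' @export
keyword_registry <- function() {
  kw <- tibble::tibble(
    phrase = character(),
    polarity = character(),
    weight = integer(),
    normalized_weight = numeric()
  )
  new_registry(kw, version = 0L, revision_log = empty_revision_log())
}

empty_revision_log <- function() {
  tibble::tibble(
    version = integer(),
    description = character(),
    timestamp = character()
  )
}

new_registry <- function(keywords, version, revision_log) {
  out <- tibble::new_tibble(
    keywords,
    nrow = nrow(keywords),
    class = "keyword_registry"
  )
  attr(out, "version") <- as.integer(version)
  attr(out, "revision_log") <- revision_log
  out
}

#' @export
print.keyword_registry <- function(x, ...) {
  cat(sprintf(
    "<keyword_registry> %d keywords (%d positive, %d negative), version %d\n",
    nrow(x), sum(x$polarity == "positive"), sum(x$polarity == "negative"),
    registry_version(x)
  ))
  NextMethod()
}

#' Registry version and revision log accessors
#'
#' @param registry A `keyword_registry`.
#' @return `registry_version()` the integer number of committed mutations;
#'   `revision_log()` a tibble with columns `version`, `description`,
#'   `timestamp`.
#' @export
registry_version <- function(registry) {
  as.integer(attr(registry, "version") %||% 0L)
}

#' @rdname registry_version
#' @export
revision_log <- function(registry) {
  attr(registry, "revision_log") %||% empty_revision_log()
}

commit_registry <- function(registry, keywords, description) {
  version <- registry_version(registry) + 1L
  log <- dplyr::bind_rows(
    revision_log(registry),
    tibble::tibble(
      version = version,
      description = description,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  new_registry(keywords, version = version, revision_log = log)
}

check_weight <- function(weight) {
  if (length(weight) != 1 || is.na(weight) ||
      !is.numeric(weight) || weight != as.integer(weight)) {
    stop("`weight` must be a single integer between 1 and 10", call. = FALSE)
  }
  weight <- as.integer(weight)
  if (weight < 1L || weight > 10L) {
    stop(sprintf("`weight` must be between 1 and 10, got %d", weight),
         call. = FALSE)
  }
  weight
}

check_polarity <- function(polarity) {
  if (!is.character(polarity) || length(polarity) != 1 ||
      !polarity %in% c("positive", "negative")) {
    stop('`polarity` must be "positive" or "negative"', call. = FALSE)
  }
  polarity
}

#' Add a weighted keyword to a registry
#'
#' The phrase is normalized on insertion (lower case, NFKC, punctuation
#' stripped, whitespace collapsed) so that registry phrases match document
#' tokens by construction. A phrase may not carry both polarities, and exact
#' duplicates are rejected.
#'
#' @param registry A `keyword_registry`.
#' @param phrase Keyword phrase (one or more words).
#' @param polarity `"positive"` or `"negative"`.
#' @param weight Integer expert weight in 1..10 (used as `weight/10` when
#'   scoring).
#' @return A new registry with version incremented by one.
#' @examples
#' reg <- keyword_registry() |> add_keyword("sleep quality", "positive", 8)
#' @export
add_keyword <- function(registry, phrase, polarity, weight) {
  polarity <- check_polarity(polarity)
  weight <- check_weight(weight)
  norm <- normalize_phrase(phrase)
  if (norm == "") {
    stop("`phrase` is empty after normalization", call. = FALSE)
  }
  other <- setdiff(c("positive", "negative"), polarity)
  if (any(registry$phrase == norm & registry$polarity == other)) {
    stop(sprintf(
      'phrase "%s" is already registered with %s polarity', norm, other
    ), call. = FALSE)
  }
  if (any(registry$phrase == norm & registry$polarity == polarity)) {
    stop(sprintf('phrase "%s" (%s) is already in the registry', norm, polarity),
         call. = FALSE)
  }
  keywords <- dplyr::bind_rows(
    tibble::as_tibble(unclass_registry(registry)),
    tibble::tibble(
      phrase = norm, polarity = polarity,
      weight = weight, normalized_weight = weight / 10
    )
  )
  commit_registry(
    registry, keywords,
    sprintf('add "%s" (%s, weight %d)', norm, polarity, weight)
  )
}

unclass_registry <- function(registry) {
  out <- registry
  class(out) <- class(tibble::tibble())
  attr(out, "version") <- NULL
  attr(out, "revision_log") <- NULL
  out
}

#' Revise the weight of an existing keyword
#'
#' Weights are revised iteratively as screening proceeds; the old value is
#' retained in the revision log and the version is incremented.
#'
#' @inheritParams add_keyword
#' @param new_weight Integer in 1..10.
#' @return A new registry with the updated weight.
#' @export
revise_weight <- function(registry, phrase, polarity, new_weight) {
  polarity <- check_polarity(polarity)
  new_weight <- check_weight(new_weight)
  norm <- normalize_phrase(phrase)
  idx <- which(registry$phrase == norm & registry$polarity == polarity)
  if (length(idx) == 0) {
    stop(sprintf('keyword "%s" (%s) not found in registry', norm, polarity),
         call. = FALSE)
  }
  old <- registry$weight[idx]
  keywords <- tibble::as_tibble(unclass_registry(registry))
  keywords$weight[idx] <- new_weight
  keywords$normalized_weight[idx] <- new_weight / 10
  commit_registry(
    registry, keywords,
    sprintf('revise "%s" (%s) weight %d -> %d', norm, polarity, old, new_weight)
  )
}

registry_log_path <- function(path) {
  sub("\\.[^./\\\\]+$", "", path) |> paste0("_log.json")
}

#' Save / load a keyword registry
#'
#' The keyword table is written as a human-editable CSV (`phrase`, `polarity`,
#' `weight`); the version counter and revision log go to a sibling JSON file
#' (`<stem>_log.json`). `load_registry()` validates weights, duplicates and
#' polarity conflicts, reporting the offending row. A registry saved and
#' re-loaded is identical, revision log included.
#'
#' @param registry A `keyword_registry`.
#' @param path CSV file path.
#' @return `load_registry()` returns a `keyword_registry`; `save_registry()`
#'   returns `path` invisibly.
#' @export
save_registry <- function(registry, path) {
  readr::write_csv(
    tibble::as_tibble(unclass_registry(registry))[
      , c("phrase", "polarity", "weight")
    ],
    path
  )
  jsonlite::write_json(
    list(
      version = registry_version(registry),
      revision_log = revision_log(registry)
    ),
    registry_log_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_registry
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("registry file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(c("phrase", "polarity", "weight"), names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("registry file lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  weight_num <- suppressWarnings(as.numeric(raw$weight))
  bad <- which(is.na(weight_num) | weight_num != round(weight_num) |
                 weight_num < 1 | weight_num > 10)
  if (length(bad) > 0) {
    stop(sprintf(
      'row %d: weight "%s" is not an integer in 1..10',
      bad[1], raw$weight[bad[1]]
    ), call. = FALSE)
  }
  bad_pol <- which(!raw$polarity %in% c("positive", "negative"))
  if (length(bad_pol) > 0) {
    stop(sprintf('row %d: polarity "%s" is invalid',
                 bad_pol[1], raw$polarity[bad_pol[1]]), call. = FALSE)
  }
  norm <- vapply(raw$phrase, normalize_phrase, character(1), USE.NAMES = FALSE)
  dup <- which(duplicated(paste(norm, raw$polarity)))
  if (length(dup) > 0) {
    stop(sprintf('row %d: duplicate keyword "%s" (%s)',
                 dup[1], norm[dup[1]], raw$polarity[dup[1]]), call. = FALSE)
  }
  conflict <- norm[norm %in% norm[raw$polarity == "positive"] &
                     norm %in% norm[raw$polarity == "negative"]]
  if (length(conflict) > 0) {
    stop(sprintf('phrase "%s" appears with both polarities', conflict[1]),
         call. = FALSE)
  }
  keywords <- tibble::tibble(
    phrase = norm,
    polarity = raw$polarity,
    weight = as.integer(weight_num),
    normalized_weight = as.integer(weight_num) / 10
  )
  log_path <- registry_log_path(path)
  if (file.exists(log_path)) {
    meta <- jsonlite::read_json(log_path, simplifyVector = TRUE)
    log <- tibble::as_tibble(meta$revision_log)
    if (nrow(log) == 0) log <- empty_revision_log()
    log$version <- as.integer(log$version)
    new_registry(keywords, version = meta$version, revision_log = log)
  } else {
    log <- tibble::tibble(
      version = nrow(keywords),
      description = sprintf("imported %d keywords from %s",
                            nrow(keywords), basename(path)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    new_registry(keywords, version = nrow(keywords), revision_log = log)
  }
}

#' @method glance keyword_registry
#' @export
glance.keyword_registry <- function(x, ...) {
  tibble::tibble(
    n_keywords = nrow(x),
    n_positive = sum(x$polarity == "positive"),
    n_negative = sum(x$polarity == "negative"),
    version = registry_version(x)
  )
}
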