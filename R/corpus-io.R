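record_columns <- c(
  "record_id", "doi", "title", "abstract", "article_type",
  "gold_label", "excluded", "exclusion_rules"
)

default_ris_mapping <- c(
  record_id = "ID", title = "TI", abstract = "AB",
  doi = "DO", article_type = "TY"
)

finalize_records <- function(records, source) {
  for (col in setdiff(record_columns, names(records))) {
    records[[col]] <- if (col == "excluded") NA else NA_character_
  }
  records <- records[, record_columns]
  for (col in setdiff(record_columns, "excluded")) {
    records[[col]] <- as.character(records[[col]])
    blank <- !is.na(records[[col]]) & stringr::str_squish(records[[col]]) == ""
    records[[col]][blank] <- NA_character_
  }
  records$excluded <- as.logical(records$excluded)
  if (anyNA(records$record_id)) {
    stop(sprintf("row %d: missing record_id", which(is.na(records$record_id))[1]),
         call. = FALSE)
  }
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    stop(sprintf('duplicate record_id "%s"', dup[1]), call. = FALSE)
  }
  if (anyNA(records$title)) {
    stop(sprintf('record "%s": missing title',
                 records$record_id[which(is.na(records$title))[1]]),
         call. = FALSE)
  }
  bad_label <- !is.na(records$gold_label) &
    !records$gold_label %in% c("eligible", "ineligible")
  if (any(bad_label)) {
    stop(sprintf('record "%s": gold_label must be "eligible" or "ineligible"',
                 records$record_id[which(bad_label)[1]]), call. = FALSE)
  }
  out <- tibble::as_tibble(records)
  attr(out, "provenance") <- list(source = source, read_at = Sys.time())
  out
}

#' Read bibliographic records
#'
#' Reads RIS, CSV or TSV bibliographic exports into a normalized records
#' tibble with columns `record_id`, `doi`, `title`, `abstract`,
#' `article_type`, `gold_label`, `excluded`, `exclusion_rules`. Missing DOIs
#' and abstracts (including all-whitespace values) are stored as `NA`, never
#' as empty strings. `record_id` must be unique and `title` present; a
#' violation is reported with the offending row or id.
#'
#' @param path Input file path.
#' @param format One of `"csv"`, `"tsv"`, `"ris"`.
#' @param mapping Named character vector mapping record fields to source
#'   column names (CSV/TSV) or RIS tags, e.g. `c(record_id = "id", title =
#'   "Title")`. For RIS the default is `ID`→record_id, `TI`→title,
#'   `AB`→abstract, `DO`→doi, `TY`→article_type; RIS entries without an `ID`
#'   tag are numbered in file order.
#' @return A tibble of records; input order is preserved. The source path and
#'   read timestamp are kept in the `"provenance"` attribute.
#' @export
read_records <- function(path, format = c("csv", "tsv", "ris"), mapping = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "ris") {
    map <- default_ris_mapping
    if (!is.null(mapping)) map[names(mapping)] <- mapping
    return(finalize_records(read_ris_entries(path, map), path))
  }
  delim <- if (format == "csv") "," else "\t"
  raw <- readr::read_delim(
    path, delim = delim, na = c("", "NA"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  map <- stats::setNames(record_columns, record_columns)
  if (!is.null(mapping)) map[names(mapping)] <- mapping
  for (field in names(map)) {
    src <- map[[field]]
    if (src %in% names(raw) && src != field) {
      raw[[field]] <- raw[[src]]
    }
  }
  for (field in c("record_id", "title")) {
    if (!field %in% names(raw)) {
      stop(sprintf('missing mandatory column "%s" (mapped from "%s") in %s',
                   field, map[[field]], path), call. = FALSE)
    }
  }
  finalize_records(raw[, intersect(record_columns, names(raw))], path)
}

# Minimal RIS reader: "XX  - value" tag lines, bare lines continue the
# previous tag, "ER" closes an entry. Repeated tags are joined with "; ".
read_ris_entries <- function(path, map) {
  lines <- readr::read_lines(path, progress = FALSE)
  entries <- list()
  current <- list()
  last_tag <- NULL
  flush <- function(current) {
    if (length(current) == 0) return(NULL)
    lapply(current, function(v) paste(v, collapse = "; "))
  }
  for (line in lines) {
    m <- stringr::str_match(line, "^([A-Z][A-Z0-9])  ?- ?(.*)$")
    if (!is.na(m[1, 1])) {
      tag <- m[1, 2]
      value <- stringr::str_trim(m[1, 3])
      if (tag == "ER") {
        e <- flush(current)
        if (!is.null(e)) entries[[length(entries) + 1]] <- e
        current <- list()
        last_tag <- NULL
      } else {
        current[[tag]] <- c(current[[tag]], value)
        last_tag <- tag
      }
    } else if (!is.null(last_tag) && stringr::str_trim(line) != "") {
      n <- length(current[[last_tag]])
      current[[last_tag]][n] <- paste(current[[last_tag]][n],
                                      stringr::str_trim(line))
    }
  }
  e <- flush(current)
  if (!is.null(e)) entries[[length(entries) + 1]] <- e
  if (length(entries) == 0) {
    stop(sprintf("no RIS entries found in %s", path), call. = FALSE)
  }
  rows <- purrr::imap(entries, function(e, i) {
    get <- function(tag) {
      v <- e[[tag]]
      if (is.null(v)) NA_character_ else v
    }
    id <- get(map[["record_id"]])
    if (is.na(id)) id <- sprintf("ris_%05d", i)
    tibble::tibble(
      record_id = id,
      doi = get(map[["doi"]]),
      title = get(map[["title"]]),
      abstract = get(map[["abstract"]]),
      article_type = get(map[["article_type"]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Write records to CSV/TSV
#'
#' Inverse of [read_records()]: absent fields are written as empty cells and
#' read back as absent, delimiters and quotes inside fields are quoted per
#' RFC 4180, so a write/read round trip reproduces every field.
#'
#' @param records A records tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  out <- records[, intersect(record_columns, names(records))]
  if (format == "csv") {
    readr::write_csv(out, path, na = "")
  } else {
    # write_tsv() leaves embedded tabs unquoted; force quoting so the
    # round trip survives delimiter characters inside fields
    readr::write_delim(out, path, delim = "\t", na = "", quote = "all",
                       escape = "double")
  }
  invisible(path)
}

#' Exclusion rule configuration
#'
#' Hard-exclusion rules applied before scoring: records with no DOI, no
#' abstract, an ineligible article type, or an abstract shorter than
#' `min_abstract_chars` characters are flagged and later ranked last.
#' Abstract length is counted in characters of the whitespace-trimmed raw
#' abstract; an all-whitespace abstract counts as absent.
#'
#' @param min_abstract_chars Minimum abstract length in characters
#'   (default 200).
#' @param ineligible_article_types Character vector of article-type labels to
#'   exclude (case-insensitive; default review, editorial, erratum, letter).
#' @param require_doi,require_abstract Logical; flag records lacking the
#'   field (default `TRUE`).
#' @return A list of class `exclusion_config`.
#' @export
exclusion_config <- function(min_abstract_chars = 200L,
                             ineligible_article_types =
                               c("review", "editorial", "erratum", "letter"),
                             require_doi = TRUE,
                             require_abstract = TRUE) {
  min_abstract_chars <- as.integer(min_abstract_chars)
  stopifnot(length(min_abstract_chars) == 1, min_abstract_chars >= 0)
  structure(
    list(
      min_abstract_chars = min_abstract_chars,
      ineligible_article_types = tolower(ineligible_article_types),
      require_doi = isTRUE(require_doi),
      require_abstract = isTRUE(require_abstract)
    ),
    class = "exclusion_config"
  )
}

#' Flag records that meet hard-exclusion rules
#'
#' Sets the `excluded` flag and records which rules fired (`no_doi`,
#' `no_abstract`, `short_abstract`, `ineligible_type`, semicolon-separated)
#' for every record; non-excluded records get `excluded = FALSE` and no
#' rules. Total and idempotent: re-applying with the same configuration is a
#' no-op.
#'
#' @param records A records tibble.
#' @param config An [exclusion_config()].
#' @return The records tibble with `excluded` and `exclusion_rules` set.
#' @export
flag_exclusions <- function(records, config = exclusion_config()) {
  abstract <- stringr::str_trim(records$abstract)
  abstract[!is.na(abstract) & abstract == ""] <- NA_character_
  no_abstract <- config$require_abstract & is.na(abstract)
  short_abstract <- !is.na(abstract) &
    nchar(abstract) < config$min_abstract_chars
  no_doi <- config$require_doi & is.na(records$doi)
  ineligible_type <- !is.na(records$article_type) &
    tolower(records$article_type) %in% config$ineligible_article_types
  rules <- purrr::pmap_chr(
    list(no_doi, no_abstract, short_abstract, ineligible_type),
    function(d, a, s, t) {
      fired <- c("no_doi", "no_abstract", "short_abstract",
                 "ineligible_type")[c(d, a, s, t)]
      if (length(fired) == 0) NA_character_ else paste(fired, collapse = ";")
    }
  )
  records$excluded <- !is.na(rules)
  records$exclusion_rules <- rules
  records
}
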