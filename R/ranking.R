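#' Rank records by term score with excluded records last
#'
#' Non-excluded records are sorted by score, highest first (higher score =
#' more relevant = smaller rank number); score ties are broken by
#' `record_id` in lexicographic order so rankings are reproducible. Excluded
#' records are appended after every included record, in their input order,
#' regardless of any score they may carry.
#'
#' @param scores A tibble with columns `record_id`, `ts` and `excluded`
#'   (e.g. from [score_records()]). Every record must either carry a
#'   non-missing score or be excluded.
#' @return A `ranking` tibble with columns `record_id`, `rank` (1-based),
#'   `ts`, `excluded`.
#' @export
rank_records <- function(scores) {
  stopifnot(all(c("record_id", "ts", "excluded") %in% names(scores)))
  excluded <- !is.na(scores$excluded) & scores$excluded
  orphan <- which(!excluded & is.na(scores$ts))
  if (length(orphan) > 0) {
    stop(sprintf(
      'record "%s" has neither a score nor an exclusion flag',
      scores$record_id[orphan[1]]
    ), call. = FALSE)
  }
  inc <- scores[!excluded, ]
  exc <- scores[excluded, ]
  inc <- inc[order(-inc$ts, inc$record_id), ]
  out <- tibble::tibble(
    record_id = c(inc$record_id, exc$record_id),
    rank = seq_len(nrow(scores)),
    ts = c(inc$ts, exc$ts),
    excluded = c(rep(FALSE, nrow(inc)), rep(TRUE, nrow(exc)))
  )
  class(out) <- c("ranking", class(out))
  out
}

#' Validate ranking invariants
#'
#' Checks that ranks are a permutation of `1..n`, that every excluded record
#' ranks after every included one, and that scores are non-increasing in rank
#' within the included prefix.
#'
#' @param ranking A `ranking` tibble.
#' @return `TRUE` invisibly; raises an error naming the violated invariant.
#' @export
validate_ranking <- function(ranking) {
  n <- nrow(ranking)
  if (!setequal(ranking$rank, seq_len(n))) {
    stop("ranks are not a permutation of 1..n", call. = FALSE)
  }
  if (anyDuplicated(ranking$record_id) > 0) {
    stop("duplicate record_id in ranking", call. = FALSE)
  }
  if (any(ranking$excluded)) {
    if (min(ranking$rank[ranking$excluded]) <=
        suppressWarnings(max(ranking$rank[!ranking$excluded], -Inf))) {
      stop("an excluded record ranks before an included record", call. = FALSE)
    }
  }
  inc <- ranking[!ranking$excluded, ]
  inc <- inc[order(inc$rank), ]
  if (nrow(inc) > 1 && any(diff(inc$ts) > 0)) {
    stop("scores increase with rank within included records", call. = FALSE)
  }
  invisible(TRUE)
}

join_labels <- function(ranking, labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("record_id", "gold_label") %in% names(labels)))
    lab <- labels$gold_label[match(ranking$record_id, labels$record_id)]
  } else {
    lab <- unname(labels[ranking$record_id])
  }
  if (anyNA(lab)) {
    stop("every ranked record needs a gold label", call. = FALSE)
  }
  if (!all(lab %in% c("eligible", "ineligible"))) {
    stop('gold labels must be "eligible" or "ineligible"', call. = FALSE)
  }
  lab == "eligible"
}

#' Fraction of eligible records ranked in the top quartile
#'
#' The top quartile is ranks `1..ceiling(n/4)` of the full ranking. The
#' statistic is the share of truly eligible records falling in it; under a
#' random ordering it averages 0.25, and 1.0 for a perfect ranking whenever
#' the eligible class fits in the quartile.
#'
#' @param ranking A `ranking` tibble.
#' @param labels Either a tibble with `record_id` and `gold_label` columns or
#'   a named character vector of `"eligible"`/`"ineligible"`.
#' @return A single number in `[0, 1]`.
#' @export
quartile_eligible_fraction <- function(ranking, labels) {
  eligible <- join_labels(ranking, labels)
  if (!any(eligible)) {
    stop("no eligible records; fraction undefined", call. = FALSE)
  }
  cutoff <- ceiling(nrow(ranking) / 4)
  sum(eligible & ranking$rank <= cutoff) / sum(eligible)
}

#' Spearman rank-order correlation with average-rank ties
#'
#' Computed as the Pearson correlation of tie-adjusted (average) ranks, the
#' standard tie handling. Inputs are values per record (scores or ranks; any
#' strictly monotone transform of either argument leaves the result
#' unchanged).
#'
#' @param a,b Numeric vectors of equal length `>= 3`, or named vectors
#'   matched by name.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("`a` and `b` cover different record sets", call. = FALSE)
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  if (length(a) < 3) stop("need at least 3 paired values", call. = FALSE)
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("rho undefined for constant input", call. = FALSE)
  }
  stats::cor(ra, rb)
}

#' Recall as a function of screening effort
#'
#' For each prefix of the ranking of size `k`, the point
#' `(k/n, eligible found in prefix / total eligible)`. The curve is
#' non-decreasing and reaches recall 1 at effort 1.
#'
#' @inheritParams quartile_eligible_fraction
#' @return A `recall_curve` tibble with columns `effort` and `recall`.
#' @export
recall_curve <- function(ranking, labels) {
  eligible <- join_labels(ranking, labels)
  if (!any(eligible)) {
    stop("no eligible records; recall undefined", call. = FALSE)
  }
  n <- nrow(ranking)
  ord <- order(ranking$rank)
  found <- cumsum(eligible[ord])
  out <- tibble::tibble(
    effort = seq_len(n) / n,
    recall = found / sum(eligible)
  )
  class(out) <- c("recall_curve", class(out))
  out
}

#' Recall after screening a fixed fraction of the ranking
#'
#' @inheritParams quartile_eligible_fraction
#' @param effort Fraction of the list screened, in `(0, 1]`; the prefix size
#'   is `ceiling(effort * n)`.
#' @return Recall in `[0, 1]`.
#' @export
recall_at_effort <- function(ranking, labels, effort = 0.25) {
  stopifnot(effort > 0, effort <= 1)
  eligible <- join_labels(ranking, labels)
  if (!any(eligible)) {
    stop("no eligible records; recall undefined", call. = FALSE)
  }
  k <- ceiling(effort * nrow(ranking))
  sum(eligible & ranking$rank <= k) / sum(eligible)
}

#' Split labelled records into seed and test sets
#'
#' Simple random split without replacement: `round(fraction * n)` records
#' (half-up rounding) become the seed set, the remainder the test set. The
#' two sets are disjoint and exhaustive and the split is reproducible under
#' `rng_seed`.
#'
#' @param records A records tibble.
#' @param fraction Seed fraction in `(0, 1)` (0.7 mirrors a 70/30
#'   cross-validation split).
#' @param rng_seed Integer seed.
#' @return A list with tibbles `seed` and `test`.
#' @export
split_seed_test <- function(records, fraction = 0.7, rng_seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(records)
  n_seed <- as.integer(floor(fraction * n + 0.5))
  idx <- withr::with_seed(rng_seed, sample.int(n, n_seed))
  list(seed = records[sort(idx), ], test = records[-sort(idx), ])
}

#' Export a seed file for a semi-automated screening tool
#'
#' Writes a CSV with columns `title`, `abstract` and `label`
#' (1 = relevant, 0 = irrelevant), the prior-knowledge import layout common
#' to semi-automated screening tools. Every record must carry a binary
#' decision and an abstract (the tools need text to learn from).
#'
#' @param records A records tibble with a `decision` column (0/1 or logical).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_seed_file <- function(records, path) {
  if (!"decision" %in% names(records)) {
    stop('records need a binary "decision" column', call. = FALSE)
  }
  decision <- records$decision
  if (is.logical(decision)) decision <- as.integer(decision)
  if (anyNA(decision) || !all(decision %in% c(0L, 1L))) {
    bad <- records$record_id[which(is.na(decision) |
                                     !decision %in% c(0L, 1L))[1]]
    stop(sprintf('record "%s" lacks a binary decision', bad), call. = FALSE)
  }
  abstract <- stringr::str_trim(records$abstract)
  missing_abs <- is.na(abstract) | abstract == ""
  if (any(missing_abs)) {
    stop(sprintf(
      'record "%s" has no abstract; screening tools require text',
      records$record_id[which(missing_abs)[1]]
    ), call. = FALSE)
  }
  readr::write_csv(
    tibble::tibble(
      title = records$title,
      abstract = records$abstract,
      label = as.integer(decision)
    ),
    path
  )
  invisible(path)
}

#' Whole days needed to screen a set of articles by hand
#'
#' Ceiling of `n_articles / daily_rate`: 60,000 seed articles at roughly 470
#' titles/abstracts per day is 128 screening days, the kind of workload the
#' term-scoring triage is meant to avoid.
#'
#' @param n_articles Number of articles to screen (>= 0).
#' @param daily_rate Articles screenable per day (>= 1).
#' @return Integer number of days.
#' @examples
#' workload_days(60000, 470)
#' @export
workload_days <- function(n_articles, daily_rate = 470L) {
  stopifnot(is.numeric(n_articles), n_articles >= 0)
  if (!is.numeric(daily_rate) || daily_rate < 1) {
    stop("`daily_rate` must be at least 1 article per day", call. = FALSE)
  }
  as.integer(ceiling(n_articles / daily_rate))
}
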