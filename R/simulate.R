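#' Simulation configuration profile
#'
#' Describes one screening configuration: how many relevant/irrelevant seed
#' records prime the ranker, whether the remaining records are ranked once or
#' screened under active learning, and the optional stopping rule.
#' Profiles like 1/1 seeds with ~20 manual screens (minimal-seed active
#' learning) up to a 70%-of-corpus seed set (large-seed rank-once) can all be
#' expressed.
#'
#' @param mode `"rank_once"` (fit on the seeds, rank the unscreened records a
#'   single time) or `"active_learning"` (re-rank after every simulated
#'   reviewer decision).
#' @param n_seed_relevant,n_seed_irrelevant Seed counts per class; rank-once
#'   mode requires at least one of each.
#' @param n_manual_screens Number of simulated reviewer decisions in active
#'   mode (default 20).
#' @param ranker `"centroid"` (nearest-centroid bag-of-words reference
#'   ranker) or `"random"` (uniform scores; a null baseline).
#' @param rng_seed Integer seed covering seed sampling and any ranker
#'   randomness.
#' @param stopping_k Optional integer: stop active screening after this many
#'   consecutive irrelevant decisions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = c("rank_once", "active_learning"),
                       n_seed_relevant = 1L, n_seed_irrelevant = 1L,
                       n_manual_screens = 20L,
                       ranker = c("centroid", "random"),
                       rng_seed = 1L, stopping_k = NULL) {
  mode <- match.arg(mode)
  ranker <- match.arg(ranker)
  n_seed_relevant <- as.integer(n_seed_relevant)
  n_seed_irrelevant <- as.integer(n_seed_irrelevant)
  stopifnot(n_seed_relevant >= 0, n_seed_irrelevant >= 0,
            n_manual_screens >= 0)
  if (mode == "rank_once" &&
      (n_seed_relevant < 1 || n_seed_irrelevant < 1)) {
    stop("rank_once mode needs at least 1 relevant and 1 irrelevant seed",
         call. = FALSE)
  }
  if (mode == "active_learning" &&
      (n_seed_relevant < 1 || n_seed_irrelevant < 1)) {
    stop("active learning needs at least 1 seed of each class", call. = FALSE)
  }
  if (!is.null(stopping_k)) stopifnot(stopping_k >= 1)
  structure(
    list(
      mode = mode,
      n_seed_relevant = n_seed_relevant,
      n_seed_irrelevant = n_seed_irrelevant,
      n_manual_screens = as.integer(n_manual_screens),
      ranker = ranker,
      rng_seed = as.integer(rng_seed),
      stopping_k = if (is.null(stopping_k)) NULL else as.integer(stopping_k)
    ),
    class = "sim_config"
  )
}

#' Precompute ranker data for a corpus
#'
#' Tokenizes every record once and builds the sparse document-term matrix
#' (L2 row-normalized) backing the nearest-centroid reference ranker.
#' Passing the result to the `simulate_*` functions avoids re-tokenizing
#' the corpus on every replicate.
#'
#' @param records A records tibble.
#' @return An object of class `ranker_data`.
#' @export
prepare_ranker <- function(records) {
  token_list <- purrr::map2(records$title, records$abstract,
                            ~ c(tokenize(.x), tokenize(.y)))
  vocab <- unique(unlist(token_list, use.names = FALSE))
  lens <- lengths(token_list)
  i <- rep.int(seq_along(token_list), lens)
  j <- match(unlist(token_list, use.names = FALSE), vocab)
  dtm <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(token_list), length(vocab)),
    dimnames = list(records$record_id, vocab)
  )
  norms <- sqrt(Matrix::rowSums(dtm^2))
  norms[norms == 0] <- 1
  structure(
    list(record_ids = records$record_id, dtm_norm = dtm / norms),
    class = "ranker_data"
  )
}

# Cosine-to-centroid relevance scores for candidate records given the
# screened (labelled) set: cos(doc, relevant centroid) minus cos(doc,
# irrelevant centroid). Deterministic given the screened set.
centroid_scores <- function(ranker_data, relevant_ids, irrelevant_ids,
                            candidate_ids) {
  centroid <- function(ids) {
    rows <- match(ids, ranker_data$record_ids)
    v <- Matrix::colMeans(ranker_data$dtm_norm[rows, , drop = FALSE])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }
  c_rel <- centroid(relevant_ids)
  c_irr <- centroid(irrelevant_ids)
  rows <- match(candidate_ids, ranker_data$record_ids)
  sub <- ranker_data$dtm_norm[rows, , drop = FALSE]
  as.numeric(sub %*% c_rel) - as.numeric(sub %*% c_irr)
}

ranker_scores <- function(config, ranker_data, relevant_ids, irrelevant_ids,
                          candidate_ids) {
  switch(
    config$ranker,
    centroid = centroid_scores(ranker_data, relevant_ids, irrelevant_ids,
                               candidate_ids),
    random = stats::runif(length(candidate_ids))
  )
}

check_labelled <- function(corpus) {
  if (!"gold_label" %in% names(corpus) || anyNA(corpus$gold_label)) {
    stop("corpus must carry a gold_label for every record", call. = FALSE)
  }
}

sample_seeds <- function(corpus, config) {
  relevant_pool <- corpus$record_id[corpus$gold_label == "eligible"]
  irrelevant_pool <- corpus$record_id[corpus$gold_label == "ineligible"]
  if (length(relevant_pool) < config$n_seed_relevant) {
    stop(sprintf("corpus has %d eligible records, %d seeds requested",
                 length(relevant_pool), config$n_seed_relevant), call. = FALSE)
  }
  if (length(irrelevant_pool) < config$n_seed_irrelevant) {
    stop(sprintf("corpus has %d ineligible records, %d seeds requested",
                 length(irrelevant_pool), config$n_seed_irrelevant),
         call. = FALSE)
  }
  list(
    relevant = sample(relevant_pool, config$n_seed_relevant),
    irrelevant = sample(irrelevant_pool, config$n_seed_irrelevant)
  )
}

scores_to_ranking <- function(candidate_ids, scores) {
  out <- tibble::tibble(record_id = candidate_ids, ts = scores,
                        excluded = FALSE)
  rank_records(out)
}

#' Rank-once screening simulation
#'
#' Samples the configured number of relevant and irrelevant seed records
#' (stratified by gold label, reproducible under the configuration seed),
#' fits the reference ranker on the seeds once, and ranks every remaining
#' record a single time — the large-seed cross-validation style of use of a
#' semi-automated screening tool.
#'
#' @param corpus A labelled records tibble (`gold_label` present for all).
#' @param config A [sim_config()] with `mode = "rank_once"`.
#' @param ranker_data Optional precomputed [prepare_ranker()] object for the
#'   corpus.
#' @return A `ranking` tibble over the unscreened (non-seed) records, with
#'   the sampled seed ids in the `"seed_ids"` attribute.
#' @export
simulate_rank_once <- function(corpus, config, ranker_data = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "rank_once") {
    stop('config$mode must be "rank_once"', call. = FALSE)
  }
  check_labelled(corpus)
  if (is.null(ranker_data)) ranker_data <- prepare_ranker(corpus)
  withr::with_seed(config$rng_seed, {
    seeds <- sample_seeds(corpus, config)
    seed_ids <- c(seeds$relevant, seeds$irrelevant)
    candidate_ids <- setdiff(corpus$record_id, seed_ids)
    if (length(candidate_ids) == 0) {
      ranking <- scores_to_ranking(character(), numeric())
    } else {
      scores <- ranker_scores(config, ranker_data,
                              seeds$relevant, seeds$irrelevant, candidate_ids)
      ranking <- scores_to_ranking(candidate_ids, scores)
    }
  })
  attr(ranking, "seed_ids") <- seed_ids
  attr(ranking, "config") <- config
  ranking
}

#' Active-learning screening simulation
#'
#' Emulates a reviewer working with a semi-automated tool: starting from a
#' minimal seed set, the ranker orders the unscreened records, the simulated
#' reviewer (the gold label) screens the top suggestion, the ranker refits,
#' and the loop repeats for `n_manual_screens` decisions or until
#' `stopping_k` consecutive irrelevant decisions fire the stopping rule.
#'
#' @inheritParams simulate_rank_once
#' @param config A [sim_config()] with `mode = "active_learning"`.
#' @return An object of class `screening_trajectory`: a list with
#'   `trajectory` (tibble: `step`, `record_id`, `rank_at_screen`,
#'   `gold_label`), `stop_index` (step at which the stopping rule fired, or
#'   `NA`), `final_ranking` (a `ranking` over records still unscreened at
#'   the end, under the final fitted ranker) and `seed_ids`.
#' @export
simulate_active <- function(corpus, config, ranker_data = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "active_learning") {
    stop('config$mode must be "active_learning"', call. = FALSE)
  }
  check_labelled(corpus)
  if (is.null(ranker_data)) ranker_data <- prepare_ranker(corpus)
  labels <- stats::setNames(corpus$gold_label, corpus$record_id)
  withr::with_seed(config$rng_seed, {
    seeds <- sample_seeds(corpus, config)
    relevant <- seeds$relevant
    irrelevant <- seeds$irrelevant
    seed_ids <- c(relevant, irrelevant)
    unscreened <- setdiff(corpus$record_id, seed_ids)
    steps <- list()
    stop_index <- NA_integer_
    consecutive_irrelevant <- 0L
    step <- 0L
    while (step < config$n_manual_screens && length(unscreened) > 0) {
      step <- step + 1L
      scores <- ranker_scores(config, ranker_data, relevant, irrelevant,
                              unscreened)
      ord <- order(-scores, unscreened)
      top <- unscreened[ord[1]]
      lab <- unname(labels[top])
      steps[[step]] <- tibble::tibble(
        step = step, record_id = top, rank_at_screen = 1L, gold_label = lab
      )
      if (lab == "eligible") {
        relevant <- c(relevant, top)
        consecutive_irrelevant <- 0L
      } else {
        irrelevant <- c(irrelevant, top)
        consecutive_irrelevant <- consecutive_irrelevant + 1L
      }
      unscreened <- setdiff(unscreened, top)
      if (!is.null(config$stopping_k) &&
          consecutive_irrelevant >= config$stopping_k) {
        stop_index <- step
        break
      }
    }
    if (length(unscreened) > 0) {
      scores <- ranker_scores(config, ranker_data, relevant, irrelevant,
                              unscreened)
      final_ranking <- scores_to_ranking(unscreened, scores)
    } else {
      final_ranking <- scores_to_ranking(character(), numeric())
    }
  })
  trajectory <- if (length(steps) > 0) dplyr::bind_rows(steps) else
    tibble::tibble(step = integer(), record_id = character(),
                   rank_at_screen = integer(), gold_label = character())
  structure(
    list(
      trajectory = trajectory,
      stop_index = stop_index,
      final_ranking = final_ranking,
      seed_ids = seed_ids,
      config = config
    ),
    class = "screening_trajectory"
  )
}

#' @export
print.screening_trajectory <- function(x, ...) {
  cat(sprintf(
    "<screening_trajectory> %d screens (%d relevant found)%s, %d unscreened\n",
    nrow(x$trajectory), sum(x$trajectory$gold_label == "eligible"),
    if (!is.na(x$stop_index))
      sprintf(", stopped at step %d", x$stop_index) else "",
    nrow(x$final_ranking)
  ))
  invisible(x)
}

#' @method tidy screening_trajectory
#' @export
tidy.screening_trajectory <- function(x, ...) {
  x$trajectory
}

#' @method glance screening_trajectory
#' @export
glance.screening_trajectory <- function(x, ...) {
  tibble::tibble(
    n_screens = nrow(x$trajectory),
    n_relevant_found = sum(x$trajectory$gold_label == "eligible"),
    stop_index = x$stop_index,
    n_unscreened = nrow(x$final_ranking)
  )
}

#' Compare two rankings of the same record set
#'
#' Spearman rank-order correlation between the two rank vectors, plus (when
#' gold labels are supplied) per-class rank summaries — median and quartiles
#' of the ranks of eligible vs ineligible records under each ranking.
#'
#' @param ranking_a,ranking_b `ranking` tibbles over the same records.
#' @param labels Optional gold labels (tibble with `record_id`, `gold_label`
#'   or named vector).
#' @return An object of class `ranking_comparison` with elements
#'   `spearman_rho`, `n` and (if labelled) `class_summary`.
#' @export
compare_rankings <- function(ranking_a, ranking_b, labels = NULL) {
  if (!setequal(ranking_a$record_id, ranking_b$record_id)) {
    stop("rankings cover different record sets", call. = FALSE)
  }
  ra <- stats::setNames(ranking_a$rank, ranking_a$record_id)
  rb <- stats::setNames(ranking_b$rank, ranking_b$record_id)
  rho <- spearman_rho(ra, rb)
  class_summary <- NULL
  if (!is.null(labels)) {
    summarise_one <- function(rk, which_ranking) {
      eligible <- join_labels(rk, labels)
      tibble::tibble(
        ranking = which_ranking,
        gold_label = c("eligible", "ineligible"),
        n = c(sum(eligible), sum(!eligible)),
        rank_q1 = c(stats::quantile(rk$rank[eligible], 0.25),
                    stats::quantile(rk$rank[!eligible], 0.25)),
        rank_median = c(stats::median(rk$rank[eligible]),
                        stats::median(rk$rank[!eligible])),
        rank_q3 = c(stats::quantile(rk$rank[eligible], 0.75),
                    stats::quantile(rk$rank[!eligible], 0.75))
      )
    }
    class_summary <- dplyr::bind_rows(
      summarise_one(ranking_a, "a"),
      summarise_one(ranking_b, "b")
    )
  }
  structure(
    list(spearman_rho = rho, n = nrow(ranking_a),
         class_summary = class_summary),
    class = "ranking_comparison"
  )
}

#' @export
print.ranking_comparison <- function(x, ...) {
  cat(sprintf("<ranking_comparison> n = %d, Spearman rho = %.3f\n",
              x$n, x$spearman_rho))
  if (!is.null(x$class_summary)) print(x$class_summary)
  invisible(x)
}

#' @method tidy ranking_comparison
#' @export
tidy.ranking_comparison <- function(x, ...) {
  x$class_summary %||%
    tibble::tibble(ranking = character(), gold_label = character())
}

#' @method glance ranking_comparison
#' @export
glance.ranking_comparison <- function(x, ...) {
  tibble::tibble(spearman_rho = x$spearman_rho, n = x$n)
}
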