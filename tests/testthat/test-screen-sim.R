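# A small, clearly separable labelled corpus for simulator unit tests:
# eligible records share planted relevance vocabulary, ineligible records a
# disjoint vocabulary, over a common background.
sim_corpus <- function(n = 120, prevalence = 0.25, seed = 1) {
  phrases <- list(
    positive = tibble::tibble(
      phrase = c("mood tracking", "longitudinal"),
      rate_eligible = c(0.8, 0.7), rate_ineligible = c(0.05, 0.05)
    ),
    negative = tibble::tibble(
      phrase = c("rat model", "polymer"),
      rate_eligible = c(0.05, 0.05), rate_ineligible = c(0.8, 0.7)
    )
  )
  generate_corpus(corpus_params(
    n_records = n, prevalence = prevalence, vocab_size = 200,
    planted_positive = phrases$positive, planted_negative = phrases$negative,
    abstract_mean_tokens = 40, abstract_dispersion = 10, rng_seed = seed
  ))
}

test_that("sim_config enforces mode/seed invariants", {
  expect_error(sim_config("rank_once", 0, 5), "at least 1")
  expect_error(sim_config("active_learning", 1, 0), "each class")
  cfg <- sim_config("rank_once", 20, 20, rng_seed = 7)
  expect_s3_class(cfg, "sim_config")
  expect_error(
    simulate_active(sim_corpus(), sim_config("rank_once", 1, 1)),
    "active_learning"
  )
})

test_that("rank_once is reproducible, partitions the corpus, ranks validly", {
  corpus <- sim_corpus()
  rd <- prepare_ranker(corpus)
  cfg <- sim_config("rank_once", 10, 10, rng_seed = 42)
  r1 <- simulate_rank_once(corpus, cfg, rd)
  r2 <- simulate_rank_once(corpus, cfg, rd)
  expect_identical(r1$record_id, r2$record_id)
  expect_identical(r1$ts, r2$ts)
  validate_ranking(r1)
  seed_ids <- attr(r1, "seed_ids")
  expect_length(seed_ids, 20)
  expect_setequal(c(seed_ids, r1$record_id), corpus$record_id)

  # requesting more seeds of a class than exist is an error
  expect_error(
    simulate_rank_once(corpus, sim_config("rank_once", 10000, 1), rd),
    "seeds requested"
  )
})

test_that("rank_once with the whole corpus as seeds leaves nothing to rank", {
  corpus <- sim_corpus(n = 40, prevalence = 0.5, seed = 3)
  n_rel <- sum(corpus$gold_label == "eligible")
  cfg <- sim_config("rank_once", n_rel, 40 - n_rel, rng_seed = 1)
  r <- simulate_rank_once(corpus, cfg)
  expect_equal(nrow(r), 0)
})

test_that("rank_once recovers eligible records early on a separable corpus", {
  corpus <- sim_corpus(n = 300, seed = 13)
  rd <- prepare_ranker(corpus)
  labels <- stats::setNames(corpus$gold_label, corpus$record_id)
  recalls <- vapply(1:10, function(s) {
    r <- simulate_rank_once(corpus, sim_config("rank_once", 20, 20,
                                               rng_seed = s), rd)
    recall_at_effort(r, labels[r$record_id], 0.25)
  }, numeric(1))
  # chance level at 25% effort is 0.25; the planted structure should put the
  # ranker far above it on every corpus this small and separable
  expect_gte(mean(recalls), 0.6)
  expect_true(all(recalls > 0.25))
})

test_that("active learning runs the configured number of screens", {
  corpus <- sim_corpus()
  cfg <- sim_config("active_learning", 1, 1, n_manual_screens = 20,
                    rng_seed = 9)
  traj <- simulate_active(corpus, cfg)
  expect_equal(nrow(traj$trajectory), 20)
  expect_equal(traj$trajectory$step, 1:20)
  expect_true(is.na(traj$stop_index))
  expect_length(unique(traj$trajectory$record_id), 20)
  # screened + seeds + unscreened partition the corpus
  expect_setequal(
    c(traj$seed_ids, traj$trajectory$record_id,
      traj$final_ranking$record_id),
    corpus$record_id
  )
  validate_ranking(traj$final_ranking)
  expect_equal(glance(traj)$n_screens, 20)
})

test_that("the stopping rule fires after k consecutive irrelevant screens", {
  # an all-ineligible pool beyond the seeds forces an irrelevant streak
  corpus <- sim_corpus(n = 60, prevalence = 0.05, seed = 21)
  cfg <- sim_config("active_learning", 1, 1, n_manual_screens = 50,
                    rng_seed = 2, stopping_k = 3)
  traj <- simulate_active(corpus, cfg)
  expect_false(is.na(traj$stop_index))
  expect_equal(traj$stop_index, nrow(traj$trajectory))
  last3 <- utils::tail(traj$trajectory$gold_label, 3)
  expect_true(all(last3 == "ineligible"))
  # no earlier streak of 3: the rule fired at the first opportunity
  labs <- traj$trajectory$gold_label == "ineligible"
  runs <- rle(labs)
  first_hit <- which(runs$values & runs$lengths >= 3)[1]
  expect_equal(sum(runs$lengths[seq_len(first_hit - 1)]) + 3, traj$stop_index)
})

test_that("active learning finds relevant records earlier than a random ranker", {
  corpus <- sim_corpus(n = 200, prevalence = 0.2, seed = 5)
  rd <- prepare_ranker(corpus)
  found <- function(ranker, seed) {
    cfg <- sim_config("active_learning", 1, 1, n_manual_screens = 25,
                      ranker = ranker, rng_seed = seed)
    traj <- simulate_active(corpus, cfg, rd)
    sum(traj$trajectory$gold_label == "eligible")
  }
  centroid <- vapply(1:20, function(s) found("centroid", s), numeric(1))
  random <- vapply(1:20, function(s) found("random", s), numeric(1))
  expect_gt(mean(centroid), mean(random))
})

test_that("compare_rankings reports rho and per-class rank summaries", {
  corpus <- sim_corpus(n = 80, prevalence = 0.25, seed = 8)
  rd <- prepare_ranker(corpus)
  r <- simulate_rank_once(corpus, sim_config("rank_once", 5, 5, rng_seed = 1),
                          rd)
  self <- compare_rankings(r, r)
  expect_equal(self$spearman_rho, 1.0)

  reversed <- r
  reversed$rank <- rev(reversed$rank)
  expect_equal(compare_rankings(r, reversed)$spearman_rho, -1.0)

  labels <- stats::setNames(corpus$gold_label, corpus$record_id)
  cmp <- compare_rankings(r, r, labels = labels[r$record_id])
  expect_s3_class(tidy(cmp), "tbl_df")
  med <- tidy(cmp)
  expect_lt(med$rank_median[med$ranking == "a" & med$gold_label == "eligible"],
            med$rank_median[med$ranking == "a" & med$gold_label == "ineligible"])
  expect_equal(glance(cmp)$spearman_rho, 1.0)

  other <- r[-1, ]
  expect_error(compare_rankings(r, other), "different record sets")
})
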