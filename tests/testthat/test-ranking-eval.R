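scores_tbl <- function(ids, ts, excluded = FALSE) {
  tibble::tibble(record_id = ids, ts = ts, excluded = excluded)
}

test_that("rank_records sorts by score, breaks ties by id, excluded go last", {
  r <- rank_records(scores_tbl(c("A", "B"), c(0.5, 0.9)))
  expect_equal(r$record_id, c("B", "A"))
  validate_ranking(r)

  # an excluded record ranks after included ones regardless of its score
  r2 <- rank_records(scores_tbl(c("C", "D"), c(99.0, 0.01),
                                excluded = c(TRUE, FALSE)))
  expect_equal(r2$record_id, c("D", "C"))
  validate_ranking(r2)

  r3 <- rank_records(scores_tbl(c("F", "E"), c(0.3, 0.3)))
  expect_equal(r3$record_id, c("E", "F"))

  expect_error(rank_records(scores_tbl("G", NA_real_)),
               "neither a score nor an exclusion")
})

test_that("excluded records keep their input order at the tail", {
  r <- rank_records(scores_tbl(c("z", "m", "a", "q"), c(1, NA, 2, NA),
                               excluded = c(FALSE, TRUE, FALSE, TRUE)))
  expect_equal(r$record_id, c("a", "z", "m", "q"))
  validate_ranking(r)
})

test_that("validate_ranking catches broken invariants", {
  r <- rank_records(scores_tbl(c("A", "B", "C"), c(3, 2, NA),
                               excluded = c(FALSE, FALSE, TRUE)))
  bad <- r
  bad$rank <- c(1L, 1L, 3L)
  expect_error(validate_ranking(bad), "permutation")
  bad2 <- r
  bad2$excluded <- c(TRUE, FALSE, FALSE)
  expect_error(validate_ranking(bad2), "excluded")
  bad3 <- r
  bad3$ts[1:2] <- c(1, 5)
  expect_error(validate_ranking(bad3), "increase")
})

test_that("quartile_eligible_fraction matches direct enumeration", {
  ids <- sprintf("r%02d", 1:8)
  r <- rank_records(scores_tbl(ids, 8:1))
  labels <- stats::setNames(rep("ineligible", 8), ids)
  labels[c("r01", "r02", "r05")] <- "eligible"  # ranks 1, 2, 5; quartile = 2
  expect_equal(quartile_eligible_fraction(r, labels), 2 / 3)

  all_top <- stats::setNames(rep("ineligible", 8), ids)
  all_top[c("r01", "r02")] <- "eligible"
  expect_equal(quartile_eligible_fraction(r, all_top), 1.0)

  expect_error(
    quartile_eligible_fraction(r, stats::setNames(rep("ineligible", 8), ids)),
    "no eligible"
  )
})

test_that("random rankings put about a quarter of eligibles in the quartile", {
  withr::local_seed(202)
  n <- 80
  ids <- sprintf("r%03d", 1:n)
  labels <- stats::setNames(
    c(rep("eligible", 16), rep("ineligible", n - 16)), ids
  )
  fracs <- vapply(1:1000, function(i) {
    r <- rank_records(scores_tbl(ids, sample(n)))
    quartile_eligible_fraction(r, labels)
  }, numeric(1))
  expect_equal(mean(fracs), 0.25, tolerance = 0.03)
})

test_that("spearman_rho reproduces closed-form cases", {
  expect_equal(spearman_rho(1:10, 1:10), 1.0)
  expect_equal(spearman_rho(1:10, 10:1), -1.0)
  # classical no-ties formula: rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(spearman_rho(1:5, rep(1, 5)), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
  expect_error(
    spearman_rho(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, z = 3)),
    "different record sets"
  )
})

test_that("spearman tie handling agrees with brute-force average ranks", {
  withr::local_seed(77)
  avg_rank <- function(x) {
    # independent construction: mean position among a stable sort
    vapply(seq_along(x), function(i) mean(which(sort(x) == x[i])), numeric(1))
  }
  for (i in 1:200) {
    n <- sample(5:40, 1)
    a <- sample(1:8, n, replace = TRUE)  # heavy ties
    b <- sample(1:8, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    ra <- avg_rank(a)
    rb <- avg_rank(b)
    brute <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(spearman_rho(a, b), brute)
    expect_equal(spearman_rho(a, b), stats::cor(a, b, method = "spearman"))
    expect_equal(spearman_rho(a, b), spearman_rho(b, a))
  }
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  withr::local_seed(5)
  a <- stats::runif(30)
  b <- stats::runif(30)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
  expect_equal(spearman_rho(a, 3 * b - 10), spearman_rho(a, b))
})

test_that("recall_curve has the documented shape", {
  ids <- sprintf("r%02d", 1:10)
  labels <- stats::setNames(
    c(rep("eligible", 3), rep("ineligible", 7)), ids
  )
  perfect <- rank_records(scores_tbl(ids, 10:1))
  rc <- recall_curve(perfect, labels)
  expect_equal(rc$recall[rc$effort == 0.3], 1.0)
  expect_true(all(diff(rc$recall) >= 0))
  expect_equal(rc$recall[nrow(rc)], 1.0)

  worst <- rank_records(scores_tbl(ids, 1:10))
  rcw <- recall_curve(worst, labels)
  expect_true(all(rcw$recall[rcw$effort <= 0.7] == 0))
  expect_equal(recall_at_effort(perfect, labels, 0.3), 1.0)
})

test_that("random rankings recall about half the eligibles at half effort", {
  withr::local_seed(303)
  n <- 60
  ids <- sprintf("r%03d", 1:n)
  labels <- stats::setNames(
    c(rep("eligible", 12), rep("ineligible", n - 12)), ids
  )
  recalls <- vapply(1:1000, function(i) {
    recall_at_effort(rank_records(scores_tbl(ids, sample(n))), labels, 0.5)
  }, numeric(1))
  expect_equal(mean(recalls), 0.5, tolerance = 0.03)
})

test_that("split_seed_test rounds half-up, partitions, and is reproducible", {
  rec <- make_records(10)
  parts <- split_seed_test(rec, 0.7, rng_seed = 4)
  expect_equal(nrow(parts$seed), 7)
  expect_equal(nrow(parts$test), 3)
  again <- split_seed_test(rec, 0.7, rng_seed = 4)
  expect_identical(parts, again)
  other <- split_seed_test(rec, 0.7, rng_seed = 5)
  expect_false(identical(parts$seed$record_id, other$seed$record_id))
  expect_error(split_seed_test(rec, 1.2), "between 0 and 1")

  withr::local_seed(17)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    frac <- stats::runif(1, 0.1, 0.9)
    rr <- make_records(n)
    p <- split_seed_test(rr, frac, rng_seed = i)
    expect_equal(nrow(p$seed), floor(frac * n + 0.5))
    expect_setequal(c(p$seed$record_id, p$test$record_id), rr$record_id)
    expect_length(intersect(p$seed$record_id, p$test$record_id), 0)
  }
})

test_that("export_seed_file writes tool-compatible CSV and enforces decisions", {
  rec <- make_records(5)
  rec$decision <- c(1L, 1L, 0L, 0L, 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  export_seed_file(rec, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("title", "abstract", "label"))
  expect_equal(nrow(back), 5)
  expect_equal(sum(back$label), 2)
  expect_equal(back$label, rec$decision)

  no_dec <- make_records(2)
  expect_error(export_seed_file(no_dec, path), "decision")
  na_abs <- rec
  na_abs$abstract[2] <- NA_character_
  expect_error(export_seed_file(na_abs, path), "abstract")
})

test_that("workload_days is a ceiling of articles over daily rate", {
  expect_equal(workload_days(60000, 470), 128L)
  expect_equal(workload_days(470, 470), 1L)
  expect_equal(workload_days(0, 470), 0L)
  expect_equal(workload_days(471, 470), 2L)
  expect_error(workload_days(100, 0), "at least 1")
})
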