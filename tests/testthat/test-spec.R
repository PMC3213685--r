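test_that("pearson matches hand-derived values and enforces preconditions", {
  expect_equal(pearson(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  expect_equal(pearson(c(1, 2, 3), c(-1, -2, -3)), -1)
  # cov = 1.5, sd_x = 1, sd_y = sqrt(7/3)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-3)
  expect_error(pearson(1:3, 1:4), "length")
  expect_error(pearson(1:2, 1:2), ">= 3")
  expect_error(pearson(c(1, 1, 1), 1:3), "zero-variance")
})

test_that("correlate_query handles identity, negation, and degenerate subsets", {
  enr <- structure(list(
    scores = rbind(s1 = c(0.1, 0.5, 0.9, 0.3),
                   s2 = -c(0.1, 0.5, 0.9, 0.3),
                   flat = rep(0.2, 4)),
    query_scores = c(0.1, 0.5, 0.9, 0.3)
  ), class = "enrichment_result")
  expect_warning(cq <- correlate_query(enr), "flat")
  expect_equal(cq$correlations, c(s1 = 1, s2 = -1))
  expect_named(cq$excluded, "flat")

  enr$query_scores <- rep(0.4, 4)
  expect_error(correlate_query(enr), "constant")
})

test_that("predict_subset takes the argmax with first-wins tie flagging", {
  expect_identical(predict_subset(c(B = 0.9, T = 0.1)),
                   list(predicted = "B", observed_max = 0.9, tie = FALSE))
  tie <- predict_subset(c(B = 0.5, T = 0.5))
  expect_identical(tie$predicted, "B")
  expect_true(tie$tie)
  neg <- predict_subset(c(a = -0.2, b = -0.6))
  expect_identical(neg$predicted, "a")
  expect_error(predict_subset(numeric()), "excluded")
})

test_that("permutation null is seeded, size-aware, and rejects degenerate fits", {
  sim <- small_sim(seed = 2)
  n1 <- build_permutation_null(sim$expression, sim$markers, query_size = 15,
                               n_perm = 50, seed = 10)
  n2 <- build_permutation_null(sim$expression, sim$markers, query_size = 15,
                               n_perm = 50, seed = 10)
  expect_identical(n1$max_correlations, n2$max_correlations)
  expect_true(all(n1$max_correlations > -1 & n1$max_correlations < 1))
  expect_gt(n1$fitted_sd, 0)
  expect_equal(n1$fitted_mean, mean(n1$max_correlations))
  expect_equal(n1$fitted_sd, sd(n1$max_correlations))
  expect_error(build_permutation_null(sim$expression, sim$markers,
                                      query_size = 15, n_perm = 1, seed = 1),
               "degenerate")
})

test_that("p_value is the upper tail of the fitted normal", {
  null <- structure(list(fitted_mean = 0.3, fitted_sd = 0.1, n_perm = 100,
                         query_size = 10, max_correlations = numeric(100)),
                    class = "permutation_null")
  expect_equal(p_value(0.3, null), 0.5)
  expect_equal(p_value(0.3 + 1.645 * 0.1, null), 0.05, tolerance = 1e-3)
  expect_equal(p_value(0.3 + 2 * 0.1, null), pnorm(2, lower.tail = FALSE),
               tolerance = 1e-12)
  # monotone decreasing in the observed maximum (flat only where the
  # normal tail underflows double precision)
  obs <- seq(-1, 1, by = 0.05)
  ps <- p_value(obs, null)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(diff(ps[abs(obs - 0.3) < 0.5]) < 0))
})

test_that("run_spec recovers an identical-to-subset query and guards overlap", {
  sim <- small_sim(seed = 4, split_markers = FALSE)
  q <- sim$markers$subset1
  res <- run_spec(sim$expression, sim$markers, q, remove_overlap = FALSE,
                  n_perm = 50, seed = 1)
  expect_identical(res$predicted_subset, "subset1")
  expect_equal(unname(res$correlations["subset1"]), 1)
  expect_equal(res$observed_max, 1)
  expect_error(run_spec(sim$expression, sim$markers, q, remove_overlap = TRUE,
                        n_perm = 50, seed = 1),
               "empty after overlap removal")
})

test_that("run_spec recovers the true source of a held-out simulator query", {
  sim <- simulate_mixture(seed = 7)
  q <- make_query(sim, "subset2", size = 20, seed = 8)
  res <- run_spec(sim$expression, sim$markers, q, remove_overlap = FALSE,
                  n_perm = 200, seed = 9)
  expect_identical(res$predicted_subset, "subset2")
  expect_true(res$significant)
  expect_identical(res$query_size, 20L)
  expect_identical(res$null$query_size, 20L)
})

test_that("run_spec is deterministic given a seed and supports sample subsets", {
  sim <- small_sim(seed = 5)
  q <- make_query(sim, "subset1", size = 8, seed = 6)
  r1 <- run_spec(sim$expression, sim$markers, q, remove_overlap = FALSE,
                 n_perm = 60, seed = 42)
  r2 <- run_spec(sim$expression, sim$markers, q, remove_overlap = FALSE,
                 n_perm = 60, seed = 42)
  expect_identical(r1$correlations, r2$correlations)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null$max_correlations, r2$null$max_correlations)

  keep <- colnames(sim$expression)[1:20]
  rs <- run_spec(sim$expression, sim$markers, q, remove_overlap = FALSE,
                 n_perm = 60, seed = 42, sample_subset = keep)
  expect_length(rs$enrichment$query_scores, 20L)
  expect_error(run_spec(sim$expression, sim$markers, q, seed = 1,
                        sample_subset = c("nope")), "unknown sample")
  expect_error(run_spec(sim$expression, sim$markers, q, seed = 1,
                        sample_subset = keep[1:2]), ">= 3 samples")
})

test_that("overlap removal trims the query once, globally, and logs the count", {
  sim <- small_sim(seed = 8, split_markers = FALSE)
  q <- c(make_query_from_pool(sim), sim$markers$subset1[1:3])
  expect_message(
    res <- run_spec(sim$expression, sim$markers, q, remove_overlap = TRUE,
                    n_perm = 50, seed = 2),
    "removed 3 query gene"
  )
  expect_identical(res$n_overlap_removed, 3L)
  expect_identical(res$query_size, length(q) - 3L)
})

test_that("tidy and glance expose the result tables", {
  sim <- small_sim(seed = 12)
  q <- make_query(sim, "subset3", size = 10, seed = 1)
  res <- run_spec(sim$expression, sim$markers, q, remove_overlap = FALSE,
                  n_perm = 50, seed = 3)
  td <- tidy(res)
  expect_identical(nrow(td), 3L)
  expect_identical(sum(td$predicted), 1L)
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$predicted_subset, res$predicted_subset)
  expect_s3_class(autoplot(res), "ggplot")
})
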