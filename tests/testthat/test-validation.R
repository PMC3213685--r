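test_that("split_signature produces disjoint exhaustive halves of the right sizes", {
  genes <- paste0("g", 1:10)
  halves <- split_signature(genes, seed = 1)
  expect_length(halves$query, 5L)
  expect_length(halves$retained, 5L)
  expect_length(intersect(halves$query, halves$retained), 0L)
  expect_setequal(c(halves$query, halves$retained), genes)

  odd <- split_signature(paste0("g", 1:7), seed = 2)
  expect_length(odd$query, 4L)
  expect_length(odd$retained, 3L)

  expect_identical(split_signature(genes, seed = 9),
                   split_signature(genes, seed = 9))
  expect_error(split_signature("g1"), "fewer than 2")
})

test_that("split validation counts partition n_reps and recover well-separated subsets", {
  sim <- small_sim(seed = 31, split_markers = FALSE)
  rep0 <- run_split_validation(sim$expression, sim$markers, n_reps = 0,
                               n_perm = 40, seed = 1)
  expect_true(all(rep0$n_reps == 0L))

  report <- run_split_validation(sim$expression, sim$markers, n_reps = 6,
                                 n_perm = 40, seed = 13)
  expect_identical(nrow(report), 3L)
  totals <- report$correct_significant + report$correct_ns +
    report$incorrect_significant + report$incorrect_ns
  expect_true(all(totals == report$n_reps))
  frac_correct <- (report$correct_significant + report$correct_ns) / report$n_reps
  expect_true(all(frac_correct >= 0.9))
  expect_s3_class(attr(report, "mispredictions"), "tbl_df")
  expect_s3_class(plot_validation_report(report), "ggplot")
})

test_that("split validation is reproducible under a seed", {
  sim <- small_sim(seed = 31, split_markers = FALSE)
  r1 <- run_split_validation(sim$expression, sim$markers, n_reps = 3,
                             n_perm = 40, seed = 5)
  r2 <- run_split_validation(sim$expression, sim$markers, n_reps = 3,
                             n_perm = 40, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("independent validation handles disjoint and nested queries", {
  sim <- small_sim(seed = 17)
  queries <- list(q1 = make_query(sim, "subset1", 10, seed = 1),
                  q2 = make_query(sim, "subset2", 10, seed = 2))
  tab <- run_independent_validation(sim$expression, sim$markers, queries,
                                    n_perm = 60, seed = 3)
  expect_identical(tab$query, c("q1", "q2"))
  expect_identical(tab$predicted_subset, c("subset1", "subset2"))
  expect_true(all(c("subset1", "subset2", "subset3") %in% names(tab)))

  nested <- list(bad = sim$markers$subset1[1:5])
  expect_error(
    suppressMessages(run_independent_validation(sim$expression, sim$markers,
                                                nested, n_perm = 60, seed = 1)),
    "empty after overlap removal")
})

test_that("size sweep trims from the top and records decreasing sizes", {
  sim <- small_sim(seed = 23)
  ranked <- c(make_query(sim, "subset2", 10, seed = 4),
              make_query_from_pool(sim, 20))
  sweep <- run_size_sweep(sim$expression, sim$markers, ranked,
                          sizes = c(5, 30, 15), true_subset = "subset2",
                          n_perm = 60, seed = 6, remove_overlap = FALSE)
  expect_identical(sweep$query_size, c(30L, 15L, 5L))
  expect_true(all(diff(sweep$query_size) < 0))
  expect_identical(sweep$predicted_subset[1], "subset2")
  expect_type(sweep$correct, "logical")
  expect_s3_class(plot_size_sweep(sweep), "ggplot")
  # size 1 is allowed (degenerate but runnable)
  one <- run_size_sweep(sim$expression, sim$markers, ranked, sizes = 1,
                        n_perm = 60, seed = 7, remove_overlap = FALSE)
  expect_identical(one$query_size, 1L)
})

test_that("deconvolution recovers exact mixtures and rejects rank-deficient bases", {
  set.seed(91)
  B <- matrix(abs(rnorm(80 * 3, 6, 2)), 80, 3,
              dimnames = list(paste0("g", 1:80), c("B", "T", "NK")))
  basis <- deconvolution_basis(B)

  f1 <- deconvolve_fractions(setNames(B[, "T"], rownames(B)), basis)
  expect_equal(f1, c(B = 0, T = 1, NK = 0), tolerance = 1e-10)

  mix <- setNames(0.3 * B[, 1] + 0.7 * B[, 2], rownames(B))
  f2 <- deconvolve_fractions(mix, basis)
  expect_equal(f2, c(B = 0.3, T = 0.7, NK = 0), tolerance = 1e-8)

  # independent oracle: normal equations solved directly
  truth <- c(0.2, 0.5, 0.3)
  y <- drop(B %*% truth)
  oracle <- solve(crossprod(B), crossprod(B, y))
  f3 <- deconvolve_fractions(setNames(y, rownames(B)), basis)
  expect_equal(unname(f3), unname(drop(oracle) / sum(oracle)),
               tolerance = 1e-8)

  bad <- cbind(B, dup = B[, 1])
  expect_error(deconvolution_basis(bad), "linearly dependent")
})

test_that("deconvolution stays within 0.1 of truth under noise and aggregates subsets", {
  set.seed(92)
  B <- matrix(abs(rnorm(80 * 3, 6, 2)), 80, 3,
              dimnames = list(paste0("g", 1:80), c("CD4", "CD8", "Bcell")))
  agg <- c(CD4 = "T", CD8 = "T", Bcell = "B")
  basis <- deconvolution_basis(B, aggregation = agg)
  truth <- c(CD4 = 0.3, CD8 = 0.3, Bcell = 0.4)
  for (r in 1:10) {
    y <- drop(B %*% truth) + rnorm(80, 0, 0.1)
    f <- deconvolve_fractions(setNames(y, rownames(B)), basis)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_lt(abs(f[["T"]] - 0.6), 0.1)
    expect_lt(abs(f[["B"]] - 0.4), 0.1)
  }
  # matrix input tidies to a long tibble
  mats <- cbind(s1 = drop(B %*% truth), s2 = drop(B %*% c(0.1, 0.1, 0.8)))
  rownames(mats) <- rownames(B)
  tidy_f <- deconvolve_fractions(mats, basis)
  expect_identical(names(tidy_f), c("sample", "subset", "fraction"))
  expect_identical(nrow(tidy_f), 4L)
})

test_that("enrichment tracks simulated subset fractions", {
  sim <- small_sim(seed = 71, split_markers = FALSE)
  enr <- enrichment_matrix(sim$expression, sim$markers)
  for (s in names(sim$markers)) {
    expect_gte(es_fraction_correlation(enr$scores[s, ], sim$proportions[, s]),
               0.6)
  }
  # affine relation gives exactly 1; independent vectors decorrelate
  expect_equal(es_fraction_correlation(1:10 * 0.05, 2 + 3 * (1:10 * 0.05)), 1)
  set.seed(6)
  expect_lt(abs(es_fraction_correlation(rnorm(1000), rnorm(1000))), 0.1)
})

test_that("top-n signature derivation ranks shifted genes first and applies BH", {
  # step-up BH on p = (.01,.02,.03,.04): all adjusted to .04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  expect_equal(p.adjust(0.03, method = "BH"), 0.03)

  set.seed(55)
  genes <- paste0("g", 1:200)
  a <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(genes, paste0("a", 1:8)))
  b <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(genes, paste0("b", 1:8)))
  shifted <- genes[1:30]
  a[shifted, ] <- a[shifted, ] + 3
  sig <- derive_top_n_signature(a, b, n = 30, direction = "up")
  expect_gte(length(intersect(sig, shifted)), 27L)
  st <- attr(sig, "stats")
  expect_true(all(diff(st$p_adjusted) >= 0))
  expect_true(all(st$p_adjusted <= 1))
  expect_error(derive_top_n_signature(a, b, n = 200, direction = "down"),
               "requested")
})
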