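#' Pearson correlation with explicit degeneracy checks
#'
#' Thin wrapper around [stats::cor()] that enforces the preconditions the
#' engine relies on: equal length of at least 3 and non-zero variance in
#' both vectors (a constant enrichment vector is uninformative and must be
#' handled by exclusion, not silently returned as `NA`).
#'
#' @param x,y Numeric vectors.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input to pearson()", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Correlate query enrichment against each subset's enrichment
#'
#' For each subset signature `s`, computes the Pearson correlation across
#' samples between the query enrichment vector `Q[i]` and the subset
#' enrichment vector `E[s, i]`. Subsets whose enrichment vector is
#' constant across samples are excluded with a warning and reported, not
#' errored, so one degenerate signature does not sink a multi-subset run.
#'
#' @param enr An `enrichment_result` with `query_scores` present.
#' @return List with `correlations` (named numeric over retained subsets)
#'   and `excluded` (named character: subset -> reason).
#' @export
correlate_query <- function(enr) {
  q <- enr$query_scores
  if (is.null(q)) stop("enrichment result carries no query scores", call. = FALSE)
  if (length(q) < 3L) stop("need >= 3 samples to correlate", call. = FALSE)
  if (stats::sd(q) == 0) {
    stop("query enrichment is constant across samples", call. = FALSE)
  }
  sds <- apply(enr$scores, 1L, stats::sd)
  excluded <- stats::setNames(rep("zero-variance enrichment", sum(sds == 0)),
                              rownames(enr$scores)[sds == 0])
  if (length(excluded) > 0L) {
    warning("excluding subset(s) with constant enrichment: ",
            paste(names(excluded), collapse = ", "), call. = FALSE)
  }
  keep <- sds > 0
  cors <- drop(stats::cor(q, t(enr$scores[keep, , drop = FALSE])))
  list(correlations = stats::setNames(as.numeric(cors),
                                      rownames(enr$scores)[keep]),
       excluded = excluded)
}

#' Predict the source subset from the correlation vector
#'
#' The prediction is the subset attaining the maximum correlation. Exact
#' ties are broken in favour of the earlier subset in collection order and
#' flagged.
#'
#' @param correlations Named numeric vector of per-subset correlations.
#' @return List with `predicted`, `observed_max`, `tie`.
#' @export
predict_subset <- function(correlations) {
  if (length(correlations) == 0L) stop("all subsets excluded", call. = FALSE)
  i <- which.max(correlations)
  list(predicted = names(correlations)[i],
       observed_max = unname(correlations[i]),
       tie = sum(correlations == correlations[i]) > 1L)
}

#' Monte Carlo null distribution of the maximum subset correlation
#'
#' Random queries of the observed query's size are drawn uniformly without
#' replacement from the full measured gene universe (subset-signature
#' genes included: the permutation reassigns array genes to the query
#' without exclusions). For each replicate the maximum correlation between
#' the random query's enrichment and any retained subset's enrichment is
#' recorded, and a normal distribution is fitted to the resulting maxima
#' by sample mean and (unbiased) sample standard deviation.
#'
#' The null depends on the query size, so it is rebuilt for each distinct
#' query size rather than shared.
#'
#' @param mat Expression matrix (genes x samples) or data frame.
#' @param collection Subset [signature_collection()], restricted to
#'   measured genes.
#' @param query_size Number of genes in each permuted query (>= 1,
#'   < number of measured genes).
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed Optional integer seed; the null is bit-reproducible given
#'   the seed.
#' @param cfg An [enrichment_config()].
#' @return A `permutation_null`: list with `max_correlations`,
#'   `fitted_mean`, `fitted_sd`, `n_perm`, `query_size`, `seed`.
#' @export
build_permutation_null <- function(mat, collection, query_size,
                                   n_perm = 1000L, seed = NULL,
                                   cfg = enrichment_config()) {
  mat <- as_expression_matrix(mat)
  enr <- enrichment_matrix(mat, collection, query = NULL, cfg = cfg)
  rankpos <- rank_position_matrix(mat)
  perm_null_impl(mat, rankpos, enr$scores, query_size, n_perm, seed, cfg)
}

perm_null_impl <- function(mat, rankpos, subset_scores, query_size,
                           n_perm, seed, cfg) {
  N <- nrow(mat)
  stopifnot(query_size >= 1L, query_size < N, n_perm >= 1L)
  sds <- apply(subset_scores, 1L, stats::sd)
  E <- t(subset_scores[sds > 0, , drop = FALSE])
  if (ncol(E) == 0L) stop("all subset enrichment vectors are constant", call. = FALSE)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      idx <- sample.int(N, query_size)
      q <- es_columns(mat, rankpos, idx, cfg)
      if (stats::sd(q) == 0) return(NA_real_)
      max(stats::cor(q, E))
    }, numeric(1))
  })
  maxima <- maxima[!is.na(maxima)]
  if (length(maxima) < 2L || stats::sd(maxima) == 0) {
    stop("degenerate permutation null (sd = 0); increase n_perm", call. = FALSE)
  }
  structure(list(max_correlations = maxima,
                 fitted_mean = mean(maxima),
                 fitted_sd = stats::sd(maxima),
                 n_perm = n_perm,
                 query_size = as.integer(query_size),
                 seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> n_perm=%d query_size=%d fit N(%.4f, %.4f)\n",
              x$n_perm, x$query_size, x$fitted_mean, x$fitted_sd))
  invisible(x)
}

#' P-value of an observed maximum correlation under the fitted null
#'
#' One-sided upper tail of the normal distribution fitted to the permuted
#' maxima: only a high correlation between query and subset enrichment is
#' evidence that the subset sources the query.
#'
#' @param observed_max Observed maximum subset correlation.
#' @param null A `permutation_null` from [build_permutation_null()].
#' @return P-value in `[0, 1]`.
#' @export
p_value <- function(observed_max, null) {
  stopifnot(inherits(null, "permutation_null"))
  stats::pnorm(observed_max, mean = null$fitted_mean, sd = null$fitted_sd,
               lower.tail = FALSE)
}

#' Predict the cell-subset source of a query gene signature
#'
#' The full pipeline: score every subset signature and the query in each
#' sample with the running-sum enrichment statistic, correlate the query's
#' enrichment vector with each subset's across samples, call the subset
#' with the maximum correlation, and assess that maximum against a Monte
#' Carlo null of size-matched random queries.
#'
#' By default genes shared between the query and any subset signature are
#' removed from the query once, globally, before scoring
#' (`remove_overlap = TRUE`): shared genes mechanically inflate the
#' correlation with their own subset. Validation designs that construct
#' disjoint queries by hand turn this off. The permutation null is built
#' at the post-removal query size.
#'
#' @param mat Expression matrix (genes x samples) or data frame.
#' @param collection Subset [signature_collection()], restricted to
#'   measured genes ([restrict_to_measured()]).
#' @param query Character vector of query gene identifiers, restricted to
#'   measured genes.
#' @param remove_overlap Drop query genes shared with any subset signature
#'   before scoring (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Permutation replicates for the null (default 1000).
#' @param seed Optional integer seed controlling the permutation null.
#' @param sample_subset Optional character vector of sample identifiers to
#'   restrict the analysis to (case-study designs that run on a patient
#'   subgroup); at least 3 samples must remain.
#' @param cfg An [enrichment_config()].
#' @return A `spec_result`: list with `correlations`, `predicted_subset`,
#'   `observed_max`, `p_value`, `significant`, `alpha`, `tie`,
#'   `excluded_subsets`, `null`, `level`, `query_size`,
#'   `n_overlap_removed`.
#' @examples
#' sim <- simulate_mixture(n_subsets = 3, markers_per_subset = 20,
#'                         n_background_genes = 100, n_samples = 30,
#'                         seed = 1)
#' q <- make_query(sim, "subset2", size = 10, seed = 2)
#' res <- run_spec(sim$expression, sim$markers, q, n_perm = 50, seed = 3)
#' res$predicted_subset
#' @export
run_spec <- function(mat, collection, query,
                     remove_overlap = TRUE, alpha = 0.05,
                     n_perm = 1000L, seed = NULL,
                     sample_subset = NULL,
                     cfg = enrichment_config()) {
  mat <- as_expression_matrix(mat)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, colnames(mat))
    if (length(missing) > 0L) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    mat <- mat[, sample_subset, drop = FALSE]
  }
  if (ncol(mat) < 3L) stop("need >= 3 samples", call. = FALSE)

  query <- unique(as.character(query))
  n_removed <- 0L
  if (remove_overlap) {
    shared <- intersect(query, unique(unlist(collection)))
    n_removed <- length(shared)
    if (n_removed > 0L) {
      message("run_spec: removed ", n_removed,
              " query gene(s) shared with subset signatures")
      query <- setdiff(query, shared)
    }
    if (length(query) == 0L) {
      stop("query is empty after overlap removal", call. = FALSE)
    }
  }

  enr <- enrichment_matrix(mat, collection, query = query, cfg = cfg)
  cq <- correlate_query(enr)
  pred <- predict_subset(cq$correlations)
  rankpos <- rank_position_matrix(mat)
  null <- perm_null_impl(mat, rankpos, enr$scores, length(query),
                         n_perm, seed, cfg)
  p <- p_value(pred$observed_max, null)

  structure(list(correlations = cq$correlations,
                 predicted_subset = pred$predicted,
                 observed_max = pred$observed_max,
                 p_value = p,
                 significant = p < alpha,
                 alpha = alpha,
                 tie = pred$tie,
                 excluded_subsets = cq$excluded,
                 null = null,
                 level = attr(collection, "level"),
                 query_size = length(query),
                 n_overlap_removed = n_removed,
                 enrichment = enr),
            class = "spec_result")
}

#' @export
print.spec_result <- function(x, ...) {
  cat("<spec_result>\n")
  cat(sprintf("  predicted subset : %s%s\n", x$predicted_subset,
              if (x$tie) " (tie, first in collection order)" else ""))
  cat(sprintf("  max correlation  : %.4f\n", x$observed_max))
  cat(sprintf("  p-value          : %.4g (%ssignificant at alpha = %g)\n",
              x$p_value, if (x$significant) "" else "not ", x$alpha))
  cat(sprintf("  query size       : %d (%d overlap gene(s) removed)\n",
              x$query_size, x$n_overlap_removed))
  if (length(x$excluded_subsets) > 0L) {
    cat("  excluded subsets :", paste(names(x$excluded_subsets), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy per-subset correlations of a SPEC run
#'
#' @param x A `spec_result` from [run_spec()].
#' @param ... Unused.
#' @return Tibble with one row per subset: `subset`, `correlation`,
#'   `predicted` (logical).
#' @export
tidy.spec_result <- function(x, ...) {
  tibble::tibble(subset = names(x$correlations),
                 correlation = unname(x$correlations),
                 predicted = names(x$correlations) == x$predicted_subset)
}

#' One-row summary of a SPEC run
#'
#' @param x A `spec_result`.
#' @param ... Unused.
#' @return One-row tibble: prediction, max correlation, p-value,
#'   significance, query size, null fit.
#' @export
glance.spec_result <- function(x, ...) {
  tibble::tibble(predicted_subset = x$predicted_subset,
                 observed_max = x$observed_max,
                 p_value = x$p_value,
                 significant = x$significant,
                 alpha = x$alpha,
                 tie = x$tie,
                 query_size = x$query_size,
                 n_perm = x$null$n_perm,
                 null_mean = x$null$fitted_mean,
                 null_sd = x$null$fitted_sd)
}

# Run a closure under a temporary RNG state; the global stream is left
# untouched when a seed is supplied.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
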