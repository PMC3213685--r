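#' Randomly split a signature into two disjoint halves
#'
#' Used by the split-signature validation design: one half becomes the
#' query, the other is retained as the subset's tracking signature. Sizes
#' are `ceiling(n/2)` and `floor(n/2)`; the assignment is uniform given
#' the seed.
#'
#' @param genes Character vector of at least 2 gene identifiers.
#' @param seed Optional integer seed.
#' @return List with elements `query` and `retained`.
#' @export
split_signature <- function(genes, seed = NULL) {
  genes <- as.character(genes)
  n <- length(genes)
  if (n < 2L) stop("cannot split a signature with fewer than 2 genes", call. = FALSE)
  with_seed(seed, {
    take <- sample.int(n, ceiling(n / 2))
    list(query = genes[sort(take)], retained = genes[-sort(take)])
  })
}

#' Split-signature validation harness
#'
#' For each subset in turn, and for each of `n_reps` replicates: split
#' that subset's signature in half, use one half as the query and the
#' other half as the subset's tracking signature (all other subsets keep
#' their full signatures), run the prediction, and tabulate the outcome as
#' correct/incorrect crossed with significant/non-significant. Overlap
#' removal is off inside this harness — the halves are disjoint by
#' construction.
#'
#' @param mat Expression matrix (genes x samples) or data frame.
#' @param collection Subset [signature_collection()], restricted to
#'   measured genes; every signature must have >= 2 genes.
#' @param n_reps Replicates per subset (default 200).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Permutation replicates per run (default 1000).
#' @param seed Optional integer seed governing splits and permutation
#'   nulls.
#' @param cfg An [enrichment_config()].
#' @return A `validation_report` tibble, one row per subset, with columns
#'   `subset`, `correct_significant`, `correct_ns`,
#'   `incorrect_significant`, `incorrect_ns`, `n_reps` (the four counts
#'   partition `n_reps`). The attribute `"mispredictions"` holds a tibble
#'   breaking down incorrect-significant calls by predicted subset.
#' @export
run_split_validation <- function(mat, collection, n_reps = 200L,
                                 alpha = 0.05, n_perm = 1000L,
                                 seed = NULL, cfg = enrichment_config()) {
  mat <- as_expression_matrix(mat)
  subsets <- names(collection)
  with_seed(seed, {
    rows <- purrr::map(subsets, function(s) {
      outcomes <- purrr::map(seq_len(n_reps), function(r) {
        halves <- split_signature(collection[[s]])
        coll_r <- collection
        coll_r[[s]] <- halves$retained
        res <- run_spec(mat, coll_r, halves$query,
                        remove_overlap = FALSE, alpha = alpha,
                        n_perm = n_perm, seed = NULL, cfg = cfg)
        list(correct = res$predicted_subset == s,
             significant = res$significant,
             predicted = res$predicted_subset)
      })
      correct <- purrr::map_lgl(outcomes, "correct")
      signif <- purrr::map_lgl(outcomes, "significant")
      predicted <- purrr::map_chr(outcomes, "predicted")
      list(
        summary = tibble::tibble(
          subset = s,
          correct_significant = sum(correct & signif),
          correct_ns = sum(correct & !signif),
          incorrect_significant = sum(!correct & signif),
          incorrect_ns = sum(!correct & !signif),
          n_reps = n_reps
        ),
        miss = tibble::tibble(subset = s,
                              predicted = predicted[!correct & signif])
      )
    })
    report <- dplyr::bind_rows(purrr::map(rows, "summary"))
    miss <- dplyr::bind_rows(purrr::map(rows, "miss")) |>
      dplyr::count(.data$subset, .data$predicted, name = "n")
    attr(report, "mispredictions") <- miss
    attr(report, "alpha") <- alpha
    class(report) <- c("validation_report", class(report))
    report
  })
}

#' Independent-signature validation
#'
#' Runs the prediction for each externally derived query signature (for
#' example, a second laboratory's marker set for the same cell subset)
#' against the collection, with overlap removal on: the few genes a query
#' shares with a subset signature would otherwise bias the correlation.
#'
#' @param mat Expression matrix (genes x samples) or data frame.
#' @param collection Subset [signature_collection()], restricted to
#'   measured genes.
#' @param queries A [signature_collection()] (or named list) of query
#'   signatures, restricted to measured genes.
#' @param alpha Significance level (default 0.05).
#' @param n_perm Permutation replicates per query (default 1000).
#' @param seed Optional integer seed.
#' @param cfg An [enrichment_config()].
#' @return Tibble, one row per query: the per-subset correlations (one
#'   column per subset), `predicted_subset`, `p_value`, `significant`.
#' @export
run_independent_validation <- function(mat, collection, queries,
                                       alpha = 0.05, n_perm = 1000L,
                                       seed = NULL,
                                       cfg = enrichment_config()) {
  mat <- as_expression_matrix(mat)
  with_seed(seed, {
    purrr::imap(unclass(queries), function(q, qname) {
      res <- run_spec(mat, collection, q, remove_overlap = TRUE,
                      alpha = alpha, n_perm = n_perm, seed = NULL, cfg = cfg)
      dplyr::bind_cols(
        tibble::tibble(query = qname),
        tibble::as_tibble(as.list(res$correlations)),
        tibble::tibble(predicted_subset = res$predicted_subset,
                       p_value = res$p_value,
                       significant = res$significant)
      )
    }) |>
      dplyr::bind_rows()
  })
}

#' Query-size sweep
#'
#' Trims a ranked query (strongest differential-expression evidence
#' first) to each requested size and records how the prediction and its
#' p-value respond. Mirrors the observation that p-values generally rise
#' as the query shrinks, with predictions often remaining correct below
#' the significance threshold.
#'
#' @param mat Expression matrix (genes x samples) or data frame.
#' @param collection Subset [signature_collection()], restricted to
#'   measured genes.
#' @param ranked_query Character vector of query genes ordered by
#'   decreasing differential-expression strength (see
#'   [derive_top_n_signature()]).
#' @param sizes Integer vector of query sizes to test (each >= 1, at most
#'   `length(ranked_query)`); evaluated in decreasing order.
#' @param true_subset Optional subset name; fills the `correct` column.
#' @param alpha Significance level (default 0.05).
#' @param n_perm Permutation replicates per size (default 1000).
#' @param seed Optional integer seed.
#' @param remove_overlap Passed to [run_spec()] (default `TRUE`).
#' @param cfg An [enrichment_config()].
#' @return Tibble with one row per size, in decreasing size order:
#'   `query_size`, `predicted_subset`, `p_value`, `significant`,
#'   `correct` (`NA` when `true_subset` is absent).
#' @export
run_size_sweep <- function(mat, collection, ranked_query, sizes,
                           true_subset = NULL, alpha = 0.05,
                           n_perm = 1000L, seed = NULL,
                           remove_overlap = TRUE,
                           cfg = enrichment_config()) {
  mat <- as_expression_matrix(mat)
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  stopifnot(all(sizes >= 1L), max(sizes) <= length(ranked_query))
  with_seed(seed, {
    purrr::map(sizes, function(k) {
      res <- run_spec(mat, collection, ranked_query[seq_len(k)],
                      remove_overlap = remove_overlap, alpha = alpha,
                      n_perm = n_perm, seed = NULL, cfg = cfg)
      tibble::tibble(query_size = k,
                     predicted_subset = res$predicted_subset,
                     p_value = res$p_value,
                     significant = res$significant,
                     correct = if (is.null(true_subset)) NA else
                       res$predicted_subset == true_subset)
    }) |>
      dplyr::bind_rows()
  })
}

#' Build a deconvolution basis
#'
#' A basis of mean expression profiles for purified cell subsets, used by
#' the linear deconvolution comparator. The optional aggregation map adds
#' related basis subsets into one reported subset (e.g. CD4+, CD8+ and
#' pan-T columns all reported as "T").
#'
#' @param mean_expression Numeric matrix, genes x basis subsets, with
#'   rownames and colnames.
#' @param aggregation Named character vector mapping every basis subset to
#'   a reported subset name; defaults to identity.
#' @return A `deconvolution_basis` list.
#' @export
deconvolution_basis <- function(mean_expression, aggregation = NULL) {
  stopifnot(is.matrix(mean_expression), is.numeric(mean_expression))
  if (is.null(rownames(mean_expression)) || is.null(colnames(mean_expression))) {
    stop("basis needs gene rownames and subset colnames", call. = FALSE)
  }
  if (is.null(aggregation)) {
    aggregation <- stats::setNames(colnames(mean_expression),
                                   colnames(mean_expression))
  }
  missing <- setdiff(colnames(mean_expression), names(aggregation))
  if (length(missing) > 0L) {
    stop("aggregation map misses basis subset(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (qr(mean_expression)$rank < ncol(mean_expression)) {
    stop("basis columns are linearly dependent on the used gene rows", call. = FALSE)
  }
  structure(list(mean_expression = mean_expression, aggregation = aggregation),
            class = "deconvolution_basis")
}

#' Estimate cell-subset fractions of a mixed profile by linear deconvolution
#'
#' Fits the sample's expression over the basis genes as a linear
#' combination of the basis profiles by ordinary least squares, clips
#' negative coefficients to zero, sums related subsets per the
#' aggregation map, and renormalizes to fractions summing to 1. Clipping
#' plus renormalization is the simplest faithful stand-in for a
#' constrained fit; this estimator is a comparator for tracking subset
#' levels, not a core claim.
#'
#' @param sample_expr Named numeric vector (one mixed sample) or a genes x
#'   samples matrix; must cover all basis genes.
#' @param basis A [deconvolution_basis()].
#' @return For a vector input, a named numeric vector of fractions over
#'   reported subsets; for a matrix, a tibble with columns `sample`,
#'   `subset`, `fraction`.
#' @export
deconvolve_fractions <- function(sample_expr, basis) {
  stopifnot(inherits(basis, "deconvolution_basis"))
  B <- basis$mean_expression
  if (is.matrix(sample_expr)) {
    out <- purrr::map(colnames(sample_expr), function(s) {
      f <- deconvolve_fractions(sample_expr[, s], basis)
      tibble::tibble(sample = s, subset = names(f), fraction = unname(f))
    })
    return(dplyr::bind_rows(out))
  }
  if (is.null(names(sample_expr))) {
    stop("`sample_expr` must be named by gene", call. = FALSE)
  }
  missing <- setdiff(rownames(B), names(sample_expr))
  if (length(missing) > 0L) {
    stop(length(missing), " basis gene(s) absent from the sample profile",
         call. = FALSE)
  }
  y <- sample_expr[rownames(B)]
  coefs <- stats::lsfit(B, y, intercept = FALSE)$coefficients
  coefs <- pmax(coefs, 0)
  names(coefs) <- colnames(B)
  reported <- tapply(coefs, basis$aggregation[names(coefs)], sum)
  total <- sum(reported)
  if (total == 0) {
    stop("all deconvolution coefficients clipped to zero; cannot normalize",
         call. = FALSE)
  }
  out <- stats::setNames(as.numeric(reported) / total, names(reported))
  out[unique(unname(basis$aggregation))]
}

#' Correlation between enrichment scores and estimated subset fractions
#'
#' Enrichment of a subset's marker signature should track that subset's
#' abundance across samples; this helper quantifies the agreement between
#' the two estimates.
#'
#' @param enrichment Numeric vector of per-sample enrichment scores for
#'   one subset signature.
#' @param fractions Numeric vector of per-sample fractions for the same
#'   subset (deconvolution estimates or simulator ground truth).
#' @return Pearson correlation.
#' @export
es_fraction_correlation <- function(enrichment, fractions) {
  pearson(enrichment, fractions)
}

#' Derive a top-n differential-expression signature
#'
#' Ranks genes by a per-gene two-sample Welch t statistic between two
#' sample groups, adjusts two-sided p-values with the Benjamini-Hochberg
#' step-up procedure, keeps genes changed in the requested direction
#' (ranked by adjusted p, ties by absolute statistic), and returns the top
#' `n`. A deliberately plain substitute for a moderated-statistics linear
#' model fit: it exists so that signature-size sweeps and top-100-style
#' disease signatures can be exercised end-to-end on synthetic data.
#'
#' @param mat_a,mat_b Genes x samples matrices for the two groups (same
#'   gene rows, >= 2 samples each).
#' @param n Number of genes to return.
#' @param direction `"up"` (higher in group A) or `"down"`.
#' @return Character vector of `n` gene identifiers, strongest evidence
#'   first, with a tibble of per-gene statistics in attribute `"stats"`.
#' @export
derive_top_n_signature <- function(mat_a, mat_b, n,
                                   direction = c("up", "down")) {
  direction <- match.arg(direction)
  mat_a <- as_expression_matrix(mat_a)
  mat_b <- as_expression_matrix(mat_b)
  if (!identical(rownames(mat_a), rownames(mat_b))) {
    stop("group matrices must share the same gene rows", call. = FALSE)
  }
  na <- ncol(mat_a); nb <- ncol(mat_b)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group", call. = FALSE)
  ma <- rowMeans(mat_a); mb <- rowMeans(mat_b)
  va <- apply(mat_a, 1L, stats::var); vb <- apply(mat_b, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  keep <- if (direction == "up") tstat > 0 else tstat < 0
  if (sum(keep) < n) {
    stop("only ", sum(keep), " genes change in direction '", direction,
         "' but ", n, " requested", call. = FALSE)
  }
  stats <- tibble::tibble(gene = rownames(mat_a), statistic = tstat,
                          p_value = p, p_adjusted = padj)[keep, ] |>
    dplyr::arrange(.data$p_adjusted, dplyr::desc(abs(.data$statistic)))
  out <- stats$gene[seq_len(n)]
  attr(out, "stats") <- stats[seq_len(n), ]
  out
}
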