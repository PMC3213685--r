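#' Simulate a mixed-cell expression matrix with known subset proportions
#'
#' Emulates the premise that a mixed sample's expression is a
#' proportion-weighted combination of cell-subset profiles. Each sample
#' draws subset proportions from a symmetric Dirichlet; each marker gene's
#' log-expression rises linearly with its own subset's proportion; all
#' genes get an i.i.d. Gaussian gene baseline plus Gaussian measurement
#' noise. Mixing is applied on the log scale: downstream enrichment
#' scoring is rank-based, so only monotonicity of marker expression in the
#' subset proportion matters (linear-scale RNA mixing would be a natural
#' extension but adds nothing testable here). The model deliberately omits
#' probe effects, batch structure and count noise.
#'
#' With `split_markers = TRUE` (default) each subset's markers are
#' partitioned at random into a tracking half (returned in `markers`, for
#' use as the subset signature) and a held-out half (returned in
#' `query_pools`, for constructing queries that are disjoint from every
#' tracking signature by design).
#'
#' @param n_subsets Number of cell subsets (default 4).
#' @param markers_per_subset Marker genes per subset (default 40).
#' @param n_background_genes Genes unlinked to any subset (default 500).
#' @param n_samples Number of mixed samples (default 60).
#' @param dirichlet_alpha Symmetric Dirichlet concentration for per-sample
#'   proportions (default 2; smaller = more variable mixtures).
#' @param marker_fold Log-scale expression increment of a marker at
#'   proportion 1 in its own subset (default 2).
#' @param noise_sd SD of additive Gaussian noise on the log scale
#'   (default 0.5).
#' @param baseline_mean,baseline_sd Gene baseline log-expression
#'   distribution (defaults 6 and 1, a typical log2 microarray scale).
#' @param split_markers Reserve a random half of each subset's markers as
#'   a held-out query pool (default `TRUE`).
#' @param seed Optional integer seed; the simulation is bit-reproducible
#'   given the seed.
#' @return A `mixture_sim` list: `expression` (genes x samples matrix),
#'   `proportions` (samples x subsets matrix, rows sum to 1), `markers`
#'   (tracking [signature_collection()]), `query_pools` (held-out
#'   [signature_collection()] or `NULL`), and the call's configuration.
#' @export
simulate_mixture <- function(n_subsets = 4L, markers_per_subset = 40L,
                             n_background_genes = 500L, n_samples = 60L,
                             dirichlet_alpha = 2, marker_fold = 2,
                             noise_sd = 0.5, baseline_mean = 6,
                             baseline_sd = 1, split_markers = TRUE,
                             seed = NULL) {
  stopifnot(n_subsets >= 1L, markers_per_subset >= 1L,
            n_background_genes >= 0L, n_samples >= 1L,
            dirichlet_alpha > 0, marker_fold > 0, noise_sd >= 0,
            baseline_sd >= 0)
  with_seed(seed, {
    subsets <- paste0("subset", seq_len(n_subsets))
    marker_ids <- purrr::map(seq_len(n_subsets), function(s) {
      sprintf("s%d_m%03d", s, seq_len(markers_per_subset))
    })
    bg_ids <- if (n_background_genes > 0L) {
      sprintf("bg%04d", seq_len(n_background_genes))
    } else {
      character()
    }
    gene_ids <- c(unlist(marker_ids), bg_ids)
    N <- length(gene_ids)
    samples <- sprintf("sample%03d", seq_len(n_samples))

    # symmetric Dirichlet via normalized gammas
    g <- matrix(stats::rgamma(n_samples * n_subsets, shape = dirichlet_alpha),
                n_samples, n_subsets)
    props <- g / rowSums(g)
    dimnames(props) <- list(samples, subsets)

    baseline <- stats::rnorm(N, baseline_mean, baseline_sd)
    # subset index of each gene (0 = background)
    subset_of <- c(rep(seq_len(n_subsets), each = markers_per_subset),
                   rep(0L, n_background_genes))
    signal <- matrix(0, N, n_samples)
    is_marker <- subset_of > 0L
    signal[is_marker, ] <- marker_fold * t(props)[subset_of[is_marker], ,
                                                  drop = FALSE]
    expr <- baseline + signal +
      matrix(stats::rnorm(N * n_samples, 0, noise_sd), N, n_samples)
    dimnames(expr) <- list(gene_ids, samples)

    if (split_markers) {
      halves <- purrr::map(marker_ids, function(ids) {
        if (length(ids) < 2L) {
          stop("split_markers requires >= 2 markers per subset", call. = FALSE)
        }
        keep <- sort(sample.int(length(ids), ceiling(length(ids) / 2)))
        list(track = ids[keep], held = ids[-keep])
      })
      markers <- signature_collection(
        stats::setNames(purrr::map(halves, "track"), subsets))
      pools <- signature_collection(
        stats::setNames(purrr::map(halves, "held"), subsets))
    } else {
      markers <- signature_collection(stats::setNames(marker_ids, subsets))
      pools <- NULL
    }

    structure(list(expression = expr,
                   proportions = props,
                   markers = markers,
                   query_pools = pools,
                   config = list(n_subsets = n_subsets,
                                 markers_per_subset = markers_per_subset,
                                 n_background_genes = n_background_genes,
                                 n_samples = n_samples,
                                 dirichlet_alpha = dirichlet_alpha,
                                 marker_fold = marker_fold,
                                 noise_sd = noise_sd,
                                 baseline_mean = baseline_mean,
                                 baseline_sd = baseline_sd,
                                 split_markers = split_markers,
                                 seed = seed)),
              class = "mixture_sim")
  })
}

#' @export
print.mixture_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mixture_sim> %d genes x %d samples | %d subsets, %d markers each%s\n",
              nrow(x$expression), ncol(x$expression), cfg$n_subsets,
              cfg$markers_per_subset,
              if (cfg$split_markers) " (half held out)" else ""))
  invisible(x)
}

#' Draw a query signature from a simulated subset's held-out marker pool
#'
#' The resulting query is disjoint from every tracking signature by
#' construction, so it exercises the prediction path without the
#' mechanical overlap bias.
#'
#' @param sim A `mixture_sim` built with `split_markers = TRUE`.
#' @param subset Subset name (e.g. `"subset2"`).
#' @param size Number of genes to draw (at most the pool size).
#' @param seed Optional integer seed.
#' @return Character vector of query gene identifiers.
#' @export
make_query <- function(sim, subset, size, seed = NULL) {
  stopifnot(inherits(sim, "mixture_sim"))
  if (is.null(sim$query_pools)) {
    stop("simulation was built with split_markers = FALSE; no held-out pool",
         call. = FALSE)
  }
  pool <- sim$query_pools[[subset]]
  if (is.null(pool)) stop("unknown subset: ", subset, call. = FALSE)
  if (size > length(pool)) {
    stop("requested ", size, " genes from a pool of ", length(pool), call. = FALSE)
  }
  with_seed(seed, pool[sort(sample.int(length(pool), size))])
}
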