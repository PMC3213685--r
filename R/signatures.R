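#' Build a signature collection
#'
#' A signature collection is a named list of gene signatures (character
#' vectors of gene identifiers) plus a `level` tag. Marker signatures for
#' blood cell subsets are typically maintained at two resolutions: a
#' "detailed" level (B cells, T cells, NK cells, monocytes, neutrophils)
#' and a "general" lineage level (lymphoid, myeloid). Analyses never mix
#' levels: each level is run as its own collection.
#'
#' @param signatures Named list of character vectors of gene identifiers.
#' @param level Resolution tag, `"detailed"` or `"general"`.
#' @return A `signature_collection`: the validated named list with a
#'   `level` attribute.
#' @examples
#' sigs <- signature_collection(
#'   list(B = c("CD19", "MS4A1"), T = c("CD3D", "CD3E")),
#'   level = "detailed"
#' )
#' @export
signature_collection <- function(signatures, level = c("detailed", "general")) {
  level <- match.arg(level)
  if (!is.list(signatures)) {
    stop("`signatures` must be a named list of character vectors", call. = FALSE)
  }
  nm <- names(signatures)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("every signature must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate signature names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  signatures <- purrr::imap(signatures, function(g, name) {
    g <- as.character(g)
    if (length(g) == 0L) {
      stop("signature '", name, "' is empty", call. = FALSE)
    }
    if (anyDuplicated(g)) {
      warning("signature '", name, "' contains duplicate genes; keeping one copy",
              call. = FALSE)
      g <- unique(g)
    }
    g
  })
  structure(signatures, level = level, class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  cat("<signature_collection> level:", attr(x, "level"),
      "|", length(x), "signatures\n")
  sizes <- lengths(x)
  for (i in seq_along(x)) {
    cat(sprintf("  %-20s %d genes\n", names(x)[i], sizes[i]))
  }
  invisible(x)
}

#' @export
`[.signature_collection` <- function(x, i, ...) {
  structure(NextMethod(), level = attr(x, "level"),
            class = "signature_collection")
}

#' Read gene sets from a GMT file
#'
#' GMT is the standard tab-delimited gene-set format: one set per line,
#' fields `name TAB description TAB gene TAB gene ...`. Duplicate genes
#' within a line are dropped with a warning; duplicate set names across
#' lines are an error.
#'
#' @param path Path to a GMT file.
#' @inheritParams signature_collection
#' @return A [signature_collection()].
#' @export
read_gmt <- function(path, level = c("detailed", "general")) {
  level <- match.arg(level)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(signature_collection(stats::setNames(list(), character()), level))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  nm <- purrr::map_chr(fields, 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- purrr::map(fields, function(f) f[-(1:2)])
  signature_collection(stats::setNames(sets, nm), level = level)
}

#' Write gene sets to a GMT file
#'
#' Round-trips with [read_gmt()]: names and gene memberships are preserved
#' exactly. The description field is written as `"na"`.
#'
#' @param collection A [signature_collection()] or named list of character
#'   vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  nm <- names(collection)
  if (length(collection) > 0L) {
    has_tab <- grepl("\t", nm, fixed = TRUE) |
      purrr::map_lgl(collection, function(g) any(grepl("\t", g, fixed = TRUE)))
    if (any(has_tab)) {
      stop("signature names/genes must not contain TAB characters: ",
           paste(nm[has_tab], collapse = ", "), call. = FALSE)
    }
  }
  lines <- purrr::imap_chr(unclass(collection), function(g, name) {
    paste(c(name, "na", g), collapse = "\t")
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' Restrict a signature to the measured gene universe
#'
#' Enrichment scoring requires every signature gene to be present in the
#' expression matrix, so unmeasured genes must be removed up front (this
#' keeps the signature size, and hence the miss-step of the running sum,
#' unambiguous). Matching is exact, case-sensitive string equality; symbol
#' aliasing is an upstream concern. A warning is raised when the restricted
#' signature falls below `min_size`, the scale below which enrichment-based
#' predictions tend to lose statistical power.
#'
#' @param sig A character vector of gene identifiers, or a
#'   [signature_collection()] (restricted element-wise).
#' @param mat Expression matrix (genes in rows, rownames are identifiers).
#' @param min_size Emit a warning if the restricted signature has fewer
#'   genes than this (default 15).
#' @return Object of the same shape as `sig`, containing only measured
#'   genes. Errors if a signature becomes empty.
#' @export
restrict_to_measured <- function(sig, mat, min_size = 15L) {
  universe <- rownames(mat)
  if (is.null(universe)) {
    stop("`mat` must have gene identifiers as rownames", call. = FALSE)
  }
  if (inherits(sig, "signature_collection")) {
    restricted <- purrr::map(unclass(sig), restrict_one,
                             universe = universe, min_size = min_size,
                             label = NULL)
    for (i in seq_along(restricted)) {
      check_restricted(restricted[[i]], sig[[i]], names(sig)[i], min_size)
    }
    return(structure(restricted, level = attr(sig, "level"),
                     class = "signature_collection"))
  }
  out <- restrict_one(sig, universe, min_size, label = "signature")
  check_restricted(out, sig, "query", min_size)
  out
}

restrict_one <- function(genes, universe, min_size, label) {
  genes[genes %in% universe]
}

check_restricted <- function(kept, original, name, min_size) {
  dropped <- length(original) - length(kept)
  if (length(kept) == 0L) {
    stop("signature '", name, "' shares no genes with the expression matrix",
         call. = FALSE)
  }
  if (dropped > 0L) {
    message("restrict_to_measured: dropped ", dropped, " unmeasured gene",
            if (dropped > 1L) "s", " from '", name, "'")
  }
  if (length(kept) < min_size) {
    warning("signature '", name, "' has ", length(kept),
            " measured genes (< ", min_size,
            "); enrichment-based predictions may be underpowered",
            call. = FALSE)
  }
  invisible(kept)
}
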