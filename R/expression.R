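#' Expression matrix container
#'
#' A light container for a features x samples matrix of normalized
#' abundances (RPPA protein levels, microarray log-intensities, ...).
#' Feature and sample identifiers must be unique and every value finite.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   `rownames`/`colnames` carry the identifiers.
#' @param platform_tag free-text platform label, e.g. `"rppa"` or
#'   `"microarray"`.
#' @param normalize_case upper-case feature symbols (default `TRUE`).
#' @return an object of class `ExpressionMatrix` with fields `values`
#'   (the matrix) and `platform_tag`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("YAP1", "AKT1"), paste0("s", 1:3)))
#' em <- expression_matrix(m, "rppa")
#' dim(em)
#' @export
expression_matrix <- function(values, platform_tag = "", normalize_case = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    .stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    .stopf("`values` must carry feature rownames and sample colnames")
  }
  rownames(values) <- .norm_symbols(rownames(values), normalize_case)
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    .stopf("duplicate feature ids: %s", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    .stopf("duplicate sample ids: %s", paste(dup, collapse = ", "))
  }
  if (!all(is.finite(values))) {
    .stopf("expression values must all be finite")
  }
  structure(
    list(values = values, platform_tag = as.character(platform_tag)),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix [%s]: %d features x %d samples\n",
    if (nzchar(x$platform_tag)) x$platform_tag else "untagged",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Feature identifiers of an expression matrix
#' @param x an `ExpressionMatrix`
#' @return character vector of feature ids
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x an `ExpressionMatrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Two-group sample design
#'
#' Maps sample identifiers to group labels. Differential stages require
#' exactly two distinct labels with at least two samples each.
#'
#' @param samples character vector of sample ids, or a named character
#'   vector of group labels (names = sample ids) with `groups` missing.
#' @param groups group label per sample.
#' @return named character vector of class `SampleDesign`.
#' @examples
#' sample_design(c("s1", "s2", "s3", "s4"), c("ctrl", "ctrl", "plt", "plt"))
#' @export
sample_design <- function(samples, groups = NULL) {
  if (is.null(groups)) {
    groups <- as.character(samples)
    samples <- names(samples)
  }
  if (is.null(samples) || anyDuplicated(samples)) {
    .stopf("sample ids must be present and unique")
  }
  x <- stats::setNames(as.character(groups), as.character(samples))
  class(x) <- "SampleDesign"
  x
}

#' @export
print.SampleDesign <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf(
    "SampleDesign: %d samples in %d groups (%s)\n", length(x), length(tab),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

## Resolve a two-group design against a matrix; returns column indices per
## group, groups ordered lexicographically (group1 first).
.design_indices <- function(matrix, design, min_per_group = 2L) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  design <- design[names(design) %in% sample_ids(matrix)]
  if (length(design) == 0L) .stopf("no design sample overlaps the matrix")
  missing <- setdiff(names(design), sample_ids(matrix))
  if (length(missing)) {
    .stopf("design samples absent from matrix: %s",
           paste(missing, collapse = ", "))
  }
  groups <- sort(unique(unclass(design)))
  if (length(groups) != 2L) {
    .stopf("design must have exactly two groups, found %d", length(groups))
  }
  idx <- lapply(groups, function(g) {
    match(names(design)[unclass(design) == g], sample_ids(matrix))
  })
  sizes <- lengths(idx)
  if (any(sizes < min_per_group)) {
    .stopf("each group needs >= %d samples (found %s)",
           min_per_group, paste(sizes, collapse = "/"))
  }
  names(idx) <- groups
  idx
}

#' Gene list container
#'
#' An ordered, unique, non-empty list of gene/protein symbols with a name.
#'
#' @param name list name.
#' @param symbols character vector of symbols; duplicates are collapsed
#'   keeping first occurrence.
#' @param normalize_case upper-case symbols (default `TRUE`).
#' @return object of class `GeneList` with fields `name` and `symbols`.
#' @export
gene_list <- function(name, symbols, normalize_case = TRUE) {
  symbols <- .norm_symbols(symbols, normalize_case)
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(symbols)]
  if (length(symbols) == 0L) .stopf("gene list '%s' is empty", name)
  structure(list(name = as.character(name), symbols = symbols),
            class = "GeneList")
}

#' @export
print.GeneList <- function(x, ...) {
  cat(sprintf("GeneList '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.GeneList <- function(x) length(x$symbols)

## Accept a GeneList or a bare character vector of symbols.
.as_symbols <- function(x) {
  if (inherits(x, "GeneList")) x$symbols else .norm_symbols(x)
}
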