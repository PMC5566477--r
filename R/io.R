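## Readers and writers for the plain-text formats the pipeline touches.
## Fixed dialect throughout: tab separator, "." decimal, no quoting.

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds feature ids and
#' whose header row holds sample ids.
#'
#' @param path file path.
#' @param platform_tag platform label stored on the result.
#' @param duplicate_policy `"error"` (default) fails on duplicated feature
#'   ids naming the offenders; `"collapse_max"` keeps, per duplicated id,
#'   the row with the highest mean.
#' @param normalize_case upper-case feature symbols (default `TRUE`).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, platform_tag = "",
                                   duplicate_policy = c("error", "collapse_max"),
                                   normalize_case = TRUE) {
  duplicate_policy <- match.arg(duplicate_policy)
  df <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .stopf("malformed header in %s: need id column + samples", path)
  ids <- .norm_symbols(df[[1L]], normalize_case)
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1L))
  if (!all(num)) {
    .stopf("non-numeric cells in columns: %s",
           paste(names(vals)[!num], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    if (duplicate_policy == "error") {
      .stopf("duplicate feature ids in %s: %s", path, paste(dup, collapse = ", "))
    }
    ## collapse_max: keep the duplicate row with the largest mean
    keep <- order(-rowMeans(m))
    keep <- keep[!duplicated(ids[keep])]
    m <- m[sort(keep), , drop = FALSE]
  }
  expression_matrix(m, platform_tag, normalize_case = normalize_case)
}

#' Write an expression matrix as TSV
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(feature_id = feature_ids(x),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample design TSV
#'
#' Columns: sample id, group label; header optional (detected when the
#' first row repeats column names `sample_id`/`group`).
#'
#' @param path file path.
#' @return a [sample_design()].
#' @export
read_sample_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .stopf("design file needs two columns: sample, group")
  if (identical(tolower(df[1, 1]), "sample_id")) df <- df[-1L, , drop = FALSE]
  sample_design(df[[1L]], df[[2L]])
}

#' @rdname read_sample_design
#' @param design a `SampleDesign`
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = names(design), group = unclass(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read pathways as edge lists
#'
#' One pathway per file, named by the file stem. SIF rows are
#' `node relation node`; TSV rows are `node<TAB>node`. Self-edges are
#' dropped and duplicate edges within a pathway deduplicated.
#'
#' @param paths character vector of file paths.
#' @param format `"sif"` or `"tsv"`.
#' @param normalize_case upper-case symbols (default `TRUE`).
#' @return a named list of two-column character matrices, class
#'   `PathwayCollection`.
#' @export
read_pathway_collection <- function(paths, format = c("sif", "tsv"),
                                    normalize_case = TRUE) {
  format <- match.arg(format)
  pw <- lapply(paths, function(p) {
    lines <- readLines(p, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) .stopf("empty pathway file: %s", p)
    edges <- lapply(seq_along(lines), function(i) {
      tok <- if (format == "sif") {
        strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
      } else {
        strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      }
      tok <- trimws(tok)
      nodes <- if (format == "sif") {
        if (length(tok) < 3L) {
          .stopf("%s line %d: need `node relation node`", p, i)
        }
        tok[c(1L, 3L)]
      } else {
        if (length(tok) < 2L || !all(nzchar(tok[1:2]))) {
          .stopf("%s line %d: need two node tokens", p, i)
        }
        tok[1:2]
      }
      .norm_symbols(nodes, normalize_case)
    })
    e <- do.call(rbind, edges)
    .dedup_edges(e)
  })
  names(pw) <- vapply(paths, function(p) {
    tools::file_path_sans_ext(basename(p))
  }, character(1L))
  if (anyDuplicated(names(pw))) .stopf("duplicate pathway names (file stems)")
  structure(pw, class = "PathwayCollection")
}

## canonical undirected edge matrix: self-edges out, a < b, deduplicated
.dedup_edges <- function(e) {
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    e <- e[!duplicated(paste(e[, 1L], e[, 2L], sep = "\r")), , drop = FALSE]
  }
  colnames(e) <- c("from", "to")
  e
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection: %d pathways, %d edges total\n",
              length(x), sum(vapply(x, nrow, integer(1L)))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT is accepted for gene *sets* only (name, description, symbols...);
#' it is not an edge format.
#'
#' @param path file path.
#' @param normalize_case upper-case symbols (default `TRUE`).
#' @return a named list of [gene_list()] objects.
#' @export
read_gmt <- function(path, normalize_case = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .stopf("empty GMT file: %s", path)
  sets <- lapply(lines, function(l) {
    tok <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 3L) .stopf("GMT rows need name, description, >=1 symbol")
    gene_list(tok[[1L]], tok[-(1:2)], normalize_case = normalize_case)
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, character(1L)))
}

#' Write a network in SIF format
#'
#' @param net a `GeneNetwork`.
#' @param path output path.
#' @param relation SIF relation token (default `"pp"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, relation = "pp") {
  stopifnot(inherits(net, "GeneNetwork"))
  e <- net$edges
  lines <- if (nrow(e)) paste(e$from, relation, e$to) else character(0L)
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked gene list (.rnk)
#'
#' Two columns, symbol and signed statistic, ordered by decreasing
#' statistic - the export format consumed by external preranked gene-set
#' enrichment tools.
#'
#' @param result a `DifferentialResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(result, path) {
  stopifnot(inherits(result, "DifferentialResult"))
  ok <- !result$flagged
  df <- data.frame(symbol = result$feature_id[ok],
                   statistic = result$statistic[ok])
  df <- df[order(-df$statistic), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- write_outputs -------------------------------------------------------

#' Write stage results to a directory
#'
#' Tables go out as TSV with a header, subnetworks as SIF plus a
#' two-column edge TSV, and a run summary as JSON. Returns a manifest of
#' written files plus degenerate-case flags.
#'
#' @param results a stage result (`DifferentialResult`, `WalkResult`,
#'   `CohortStratification`, `CutoffScanResult`).
#' @param out_dir output directory, created if needed.
#' @param ... passed to methods.
#' @return named list: `files` (paths) and `flags`.
#' @export
write_outputs <- function(results, out_dir, ...) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) .stopf("cannot create '%s'", out_dir)
  }
  UseMethod("write_outputs")
}

#' @export
write_outputs.default <- function(results, out_dir, ...) {
  .stopf("no write_outputs method for class '%s'", class(results)[1L])
}

#' @export
write_outputs.DifferentialResult <- function(results, out_dir,
                                             prefix = "differential", ...) {
  tab <- file.path(out_dir, paste0(prefix, ".tsv"))
  utils::write.table(
    data.frame(feature_id = results$feature_id,
               effect = format(results$effect, digits = 17, trim = TRUE),
               statistic = format(results$statistic, digits = 17, trim = TRUE),
               p_value = format(results$p_value, digits = 17, trim = TRUE),
               fdr = format(results$fdr, digits = 17, trim = TRUE),
               flagged = results$flagged),
    tab, sep = "\t", quote = FALSE, row.names = FALSE
  )
  rnk <- file.path(out_dir, paste0(prefix, ".rnk"))
  write_rnk(results, rnk)
  list(files = c(table = tab, rnk = rnk), flags = list())
}

#' @export
write_outputs.WalkResult <- function(results, out_dir, summary = NULL, ...) {
  probs <- file.path(out_dir, "walk_probabilities.tsv")
  ord <- order(-results$g, names(results$g))
  utils::write.table(
    data.frame(node = names(results$g)[ord],
               probability = format(results$g[ord], digits = 17, trim = TRUE)),
    probs, sep = "\t", quote = FALSE, row.names = FALSE
  )
  sif <- file.path(out_dir, "crosstalk_component.sif")
  empty <- is.null(results$component) ||
    nrow(results$component$edges) == 0L
  if (is.null(results$component)) {
    writeLines(character(0L), sif)
  } else {
    write_sif(results$component, sif)
  }
  files <- c(probabilities = probs, component_sif = sif)
  if (!is.null(results$node_classes)) {
    cls <- file.path(out_dir, "node_classes.tsv")
    utils::write.table(
      data.frame(node = names(results$node_classes),
                 class = unname(results$node_classes)),
      cls, sep = "\t", quote = FALSE, row.names = FALSE
    )
    files <- c(files, node_classes = cls)
  }
  js <- file.path(out_dir, "summary.json")
  info <- list(
    iterations = results$iterations,
    converged = results$converged,
    config = unclass_deep(results$config),
    seeds = results$seeds,
    connector_drps = results$connector_drps,
    empty_component = empty
  )
  if (!is.null(summary)) info <- utils::modifyList(summary, info)
  jsonlite::write_json(info, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, summary = js)
  list(files = files, flags = list(empty_component = empty))
}

#' @export
write_outputs.CohortStratification <- function(results, out_dir, ...) {
  path <- file.path(out_dir, "stratification.tsv")
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], format, digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(files = c(stratification = path), flags = list())
}

#' @export
write_outputs.CutoffScanResult <- function(results, out_dir, ...) {
  grid <- file.path(out_dir, "cutoff_grid.tsv")
  g <- results$grid
  g[] <- lapply(g, function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE) else col
  })
  utils::write.table(g, grid, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(out_dir, "best_cutoff.json")
  jsonlite::write_json(
    list(best_percentile = results$best_percentile,
         best_cutoff = results$best_cutoff,
         best_p = results$best_p,
         significant = results$significant,
         adjusted_p = results$adjusted_p),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  list(files = c(grid = grid, best = js), flags = list())
}
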