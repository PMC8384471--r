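#' Construct an association dataset
#'
#' Bundles ordered disease and miRNA identifiers with the binary association
#' matrix `A` (`nd` disease rows, `nm` miRNA columns). `A[i, j] = 1` records a
#' known association between disease `i` and miRNA `j`.
#'
#' @param disease_ids character vector of unique disease identifiers.
#' @param mirna_ids character vector of unique miRNA identifiers.
#' @param A binary matrix, `length(disease_ids)` rows by `length(mirna_ids)`
#'   columns.
#' @return An object of class `association_dataset` with elements
#'   `disease_ids`, `mirna_ids` and `A` (with dimnames set).
#' @export
association_dataset <- function(disease_ids, mirna_ids, A) {
  disease_ids <- as.character(disease_ids)
  mirna_ids <- as.character(mirna_ids)
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids")
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA ids")
  A <- as.matrix(A)
  if (nrow(A) != length(disease_ids) || ncol(A) != length(mirna_ids)) {
    stop("association matrix dimensions do not match id lists")
  }
  if (!all(A %in% c(0, 1))) stop("association matrix entries must be 0 or 1")
  storage.mode(A) <- "double"
  dimnames(A) <- list(disease_ids, mirna_ids)
  structure(
    list(disease_ids = disease_ids, mirna_ids = mirna_ids, A = A),
    class = "association_dataset"
  )
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "association_dataset: %d diseases x %d miRNAs, %d known associations\n",
    length(x$disease_ids), length(x$mirna_ids), sum(x$A)
  ))
  invisible(x)
}

# Strip comment lines and blank lines from a TSV read as raw lines.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a disease-miRNA association edge list
#'
#' Reads a two-column TSV (`disease_id<TAB>mirna_id`; `#` comment lines
#' ignored; an optional `disease_id`/`mirna_id` header row is skipped) and
#' builds the binary association matrix. Identifiers are sorted
#' lexicographically so the result is independent of input row order.
#' Duplicate pairs collapse to a single entry with a warning.
#'
#' @param path path to the TSV file.
#' @return An [association_dataset()].
#' @export
read_associations <- function(path) {
  raw <- read_tsv_lines(path)
  if (length(raw$lines) == 0) stop("empty association file: ", path)
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    stop(sprintf(
      "malformed association row at line %d: expected 2 tab-separated fields, got %d",
      raw$lineno[bad], nf[bad]
    ))
  }
  d <- trimws(vapply(parts, `[[`, "", 1L))
  m <- trimws(vapply(parts, `[[`, "", 2L))
  if (length(d) >= 1 && tolower(d[1]) %in% c("disease_id", "disease") &&
      tolower(m[1]) %in% c("mirna_id", "mirna")) {
    d <- d[-1]
    m <- m[-1]
  }
  if (length(d) == 0) stop("association file contains no data rows: ", path)
  pair_key <- paste(d, m, sep = "\r")
  if (anyDuplicated(pair_key)) {
    warning(sprintf(
      "%d duplicate association row(s) collapsed", sum(duplicated(pair_key))
    ))
    keep <- !duplicated(pair_key)
    d <- d[keep]
    m <- m[keep]
  }
  disease_ids <- sort(unique(d))
  mirna_ids <- sort(unique(m))
  A <- matrix(0, length(disease_ids), length(mirna_ids),
              dimnames = list(disease_ids, mirna_ids))
  A[cbind(match(d, disease_ids), match(m, mirna_ids))] <- 1
  association_dataset(disease_ids, mirna_ids, A)
}

#' Construct an ontology forest
#'
#' Holds the child-to-parent edges of a disease ontology together with the
#' mapping from disease identifiers to their primary ontology terms. Each
#' disease's ancestor DAG is derived from this forest.
#'
#' @param parent_edges two-column character matrix or data frame of
#'   (child, parent) term pairs; may have zero rows.
#' @param terms character vector of term ids; defaults to all ids appearing
#'   in `parent_edges` plus mapped terms.
#' @param disease_to_term named character vector mapping disease id to term
#'   id; by default every term doubles as a disease id (identity convention).
#' @return An object of class `ontology_forest` with elements `terms`,
#'   `parent_edges` (two-column character matrix) and `disease_to_term`.
#' @export
ontology_forest <- function(parent_edges, terms = NULL, disease_to_term = NULL) {
  pe <- as.matrix(parent_edges)
  if (length(pe) == 0) pe <- matrix(character(), 0, 2)
  if (ncol(pe) != 2) stop("parent_edges must have two columns (child, parent)")
  storage.mode(pe) <- "character"
  colnames(pe) <- c("child", "parent")
  all_terms <- unique(c(terms, pe[, 1], pe[, 2]))
  if (nrow(pe) > 0) {
    g <- igraph::graph_from_edgelist(pe, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::girth(g)$circle
      stop(
        "ontology parent relation contains a cycle: ",
        paste(igraph::as_ids(cyc), collapse = " -> ")
      )
    }
  }
  if (is.null(disease_to_term)) {
    disease_to_term <- stats::setNames(all_terms, all_terms)
  }
  if (!all(disease_to_term %in% all_terms)) {
    orphan <- names(disease_to_term)[!(disease_to_term %in% all_terms)][1]
    stop("disease maps to a term absent from the ontology: ", orphan)
  }
  structure(
    list(terms = all_terms, parent_edges = pe,
         disease_to_term = disease_to_term),
    class = "ontology_forest"
  )
}

#' @export
print.ontology_forest <- function(x, ...) {
  cat(sprintf("ontology_forest: %d terms, %d parent edges, %d mapped diseases\n",
              length(x$terms), nrow(x$parent_edges), length(x$disease_to_term)))
  invisible(x)
}

#' Read an ontology parent edge list
#'
#' Reads a TSV of `child_term<TAB>parent_term` rows into an
#' [ontology_forest()]. Cycles are rejected. By default each disease id is
#' taken to be its own ontology term; pass `mapping_path` (TSV of
#' `disease_id<TAB>term_id`) to override.
#'
#' @param path path to the edge-list TSV.
#' @param mapping_path optional path to a disease-to-term mapping TSV.
#' @return An [ontology_forest()].
#' @export
read_ontology <- function(path, mapping_path = NULL) {
  raw <- read_tsv_lines(path)
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    stop(sprintf(
      "malformed ontology row at line %d: expected 2 fields, got %d",
      raw$lineno[bad], nf[bad]
    ))
  }
  child <- trimws(vapply(parts, `[[`, "", 1L))
  parent <- trimws(vapply(parts, `[[`, "", 2L))
  if (length(child) >= 1 && tolower(child[1]) %in% c("child", "child_term") &&
      tolower(parent[1]) %in% c("parent", "parent_term")) {
    child <- child[-1]
    parent <- parent[-1]
  }
  mapping <- NULL
  if (!is.null(mapping_path)) {
    mraw <- read_tsv_lines(mapping_path)
    mparts <- strsplit(mraw$lines, "\t", fixed = TRUE)
    if (any(lengths(mparts) != 2)) stop("malformed disease-to-term mapping row")
    mapping <- stats::setNames(
      trimws(vapply(mparts, `[[`, "", 2L)),
      trimws(vapply(mparts, `[[`, "", 1L))
    )
  }
  ontology_forest(cbind(child, parent), disease_to_term = mapping)
}

#' Read a labelled numeric matrix from TSV
#'
#' Expects a header row `id<TAB>col1<TAB>...` and row ids in the first
#' column. Used for similarity matrices such as the miRNA functional
#' similarity (MISIM-style) matrix.
#'
#' @param path path to the matrix TSV.
#' @param symmetric if `TRUE`, require a square matrix with matching row and
#'   column ids, symmetric within `1e-8`.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix <- function(path, symmetric = FALSE) {
  raw <- read_tsv_lines(path)
  if (length(raw$lines) < 2) stop("matrix file needs a header and >=1 row: ", path)
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  header <- trimws(parts[[1]])
  col_ids <- header[-1]
  body <- parts[-1]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("ragged matrix row at line %d: expected %d fields, got %d",
                 raw$lineno[-1][bad], length(header), nf[bad]))
  }
  row_ids <- trimws(vapply(body, `[[`, "", 1L))
  cells <- vapply(body, function(p) trimws(p[-1]), character(length(col_ids)))
  cells <- matrix(cells, nrow = length(col_ids))  # columns are input rows
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric matrix cell at row '%s', column '%s'",
                 row_ids[idx[2]], col_ids[idx[1]]))
  }
  m <- t(vals)
  dimnames(m) <- list(row_ids, col_ids)
  if (symmetric) {
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
      stop("matrix read with symmetric=TRUE must be square with matching ids")
    }
    if (max(abs(m - t(m))) > 1e-8) {
      stop("matrix read with symmetric=TRUE is not symmetric")
    }
  }
  m
}

#' Write a labelled numeric matrix to TSV
#'
#' Inverse of [read_matrix()]: values are written with 15 significant digits
#' so a write/read round trip preserves them to at least 12 significant
#' digits.
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must have row and column names")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) {
    paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = "\t")
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write an association dataset as an edge list TSV
#'
#' @param dataset an [association_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(dataset, path) {
  stopifnot(inherits(dataset, "association_dataset"))
  idx <- which(dataset$A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- paste(dataset$disease_ids[idx[, 1]], dataset$mirna_ids[idx[, 2]],
                 sep = "\t")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Write an ontology forest as an edge list TSV
#'
#' @param forest an [ontology_forest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(forest, path) {
  stopifnot(inherits(forest, "ontology_forest"))
  writeLines(paste(forest$parent_edges[, 1], forest$parent_edges[, 2],
                   sep = "\t"), path)
  invisible(path)
}
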