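#' Read an expression matrix and its cell annotation
#'
#' Two on-disk layouts are supported. `format = "tsv"`: `path_counts` is a
#' dense tab-separated table whose first column holds gene ids and whose
#' header holds cell ids. `format = "mtx"` (canonical interchange):
#' `path_counts` is a Matrix Market coordinate file with genes as rows;
#' sibling files `genes.tsv` and `cells.tsv` in the same directory hold the
#' identifiers, one per line.
#'
#' The TPM layer is computed from counts (per-cell scaling to 1e6) when not
#' already stored; see [expression_matrix()] for the gene-length caveat.
#'
#' @param path_counts counts file as described above.
#' @param path_annotation TSV of per-cell annotations keyed by cell_id.
#' @param format "tsv" or "mtx".
#' @return list with elements `matrix` (ExpressionMatrix) and `annotation`
#'   (data.frame, rows ordered as the matrix columns).
#' @export
read_expression <- function(path_counts, path_annotation, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  for (p in c(path_counts, path_annotation))
    if (!file.exists(p)) stop("file not found: ", p)
  if (format == "tsv") {
    tab <- utils::read.delim(path_counts, check.names = FALSE)
    gene_ids <- as.character(tab[[1L]])
    counts <- as.matrix(tab[, -1L, drop = FALSE])
    cell_ids <- colnames(counts)
  } else {
    dirn <- dirname(path_counts)
    gpath <- file.path(dirn, "genes.tsv"); cpath <- file.path(dirn, "cells.tsv")
    for (p in c(gpath, cpath)) if (!file.exists(p)) stop("file not found: ", p)
    counts <- as.matrix(Matrix::readMM(path_counts))
    gene_ids <- readLines(gpath); cell_ids <- readLines(cpath)
  }
  ann <- utils::read.delim(path_annotation, check.names = FALSE)
  mat <- expression_matrix(counts, gene_ids = gene_ids, cell_ids = cell_ids)
  ann <- validate_annotation(ann, cell_ids = mat$cell_ids)
  list(matrix = mat, annotation = ann)
}

write_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(file.path(dir, "counts.mtx"))
}

#' Write a result table as deterministic TSV
#'
#' TSV with header, floats at 6 significant digits, `NA` written literally,
#' rows sorted by the first (primary-key) column so reruns are byte-stable.
#'
#' @param obj data.frame.
#' @param path output file path.
#' @param digits significant digits for doubles (default 6).
#' @export
write_table <- function(obj, path, digits = 6L) {
  stopifnot(is.data.frame(obj))
  if (nrow(obj) > 1L) obj <- obj[order(obj[[1L]], method = "radix"), , drop = FALSE]
  out <- obj
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- signif(out[[j]], digits)
      s <- vapply(v, function(x)
        if (is.na(x)) "NA" else format(x, digits = digits, scientific = NA,
                                       trim = TRUE), character(1L))
      out[[j]] <- s
    }
  }
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    stop("cannot write table to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = "NA")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Resolve a gene set against a matrix
#'
#' Unresolved members are dropped with an INFO log line, never fatal, except
#' when nothing resolves.
#' @param genes character vector of set members.
#' @param universe gene ids present in the matrix.
#' @param set_name used in messages.
#' @return resolved members, in universe order.
#' @export
resolve_gene_set <- function(genes, universe, set_name = "gene set") {
  hit <- intersect(universe, genes)
  if (!length(hit)) stop("no member of ", set_name, " is present in the matrix")
  lost <- setdiff(genes, universe)
  if (length(lost))
    log_info("%s: %d/%d members unresolved and dropped", set_name,
             length(lost), length(genes))
  hit
}
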