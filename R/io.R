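## File formats: MatrixMarket expression triplets with genes/barcodes
## sidecars, GMT gene sets, and the CellMap CSV schema.

#' Read a sparse expression matrix from an MTX triplet directory
#'
#' Expects `matrix.mtx`, `genes.tsv` (one gene symbol per line) and
#' `barcodes.tsv` (one cell id per line), the layout emitted by
#' [write_expression()]. Genes are rows, cells are columns. Duplicate gene
#' symbols are disambiguated by suffixing (`SYM.1`, `SYM.2`, ...) with a
#' message.
#'
#' @param dir Directory containing the three files.
#' @param check_integer Require integer-valued entries (raw counts).
#' @return A `dgCMatrix` with gene symbols as rownames and cell ids as
#'   colnames.
#' @export
read_expression <- function(dir, check_integer = TRUE) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing expression files: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  m <- Matrix::readMM(paths[1])
  if (methods::is(m, "nMatrix")) { # pattern matrix (e.g. no stored entries)
    m <- methods::as(m, "dMatrix")
  }
  genes <- readLines(paths[2])
  cells <- readLines(paths[3])
  if (nrow(m) != length(genes)) {
    stop(sprintf("matrix has %d rows but genes.tsv names %d genes",
                 nrow(m), length(genes)), call. = FALSE)
  }
  if (ncol(m) != length(cells)) {
    stop(sprintf("matrix has %d columns but barcodes.tsv names %d cells",
                 ncol(m), length(cells)), call. = FALSE)
  }
  if (check_integer && length(m@x) && any(m@x != round(m@x))) {
    stop("expression matrix contains non-integer values where counts expected",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    genes <- make.unique(genes)
    message("duplicate gene symbols disambiguated by suffixing")
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a sparse expression matrix as an MTX triplet directory
#'
#' @param counts Matrix (genes x cells) with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and cell colnames", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 60), call. = FALSE)
    }
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-cell spatial table (CellMap)
#'
#' Columns: `cell_id`, `x_um`, `y_um`, `compartment`, `cell_type`, and
#' optionally `clonotype_id` and `state_label`.
#'
#' @param path CSV path.
#' @return A validated CellMap data.frame.
#' @export
read_cell_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cell_map(df)
}

#' Validate a CellMap data.frame
#'
#' @param df Candidate data.frame.
#' @return `df`, invisibly usable (returned for chaining).
#' @export
validate_cell_map <- function(df) {
  need <- c("cell_id", "x_um", "y_um", "compartment", "cell_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CellMap missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in CellMap", call. = FALSE)
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    stop("CellMap coordinates must be finite", call. = FALSE)
  }
  if (any(is.na(df$compartment)) || any(is.na(df$cell_type))) {
    stop("CellMap compartment and cell_type must be non-missing", call. = FALSE)
  }
  df
}
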