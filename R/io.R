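#' Read a gene x sample expression matrix
#'
#' Expression values are expected on a linear scale (TPM for bulk cohorts,
#' counts for single-cell references) and must be non-negative. Two on-disk
#' layouts are supported: a dense TSV (first column gene identifier, header
#' row of sample identifiers) and a MatrixMarket sparse triplet accompanied
#' by one-identifier-per-line gene and column index files.
#'
#' Duplicate gene identifiers are collapsed by summation (with a warning);
#' sample identifiers must be unique. Gene identifier matching throughout the
#' package is exact and case-sensitive.
#'
#' @param path Path to the matrix file (`.tsv` or `.mtx`).
#' @param format Either `"tsv"` or `"mtx_triplet"`.
#' @param genes_path,cells_path For `mtx_triplet`, paths to the row (gene)
#'   and column (cell) identifier files; default to `genes.tsv` and
#'   `barcodes.tsv` next to the matrix file.
#' @return A numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames), validated to be finite and non-negative.
#' @export
read_expression_matrix <- function(path, format = c("tsv", "mtx_triplet"),
                                   genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("malformed expression TSV (need gene column plus >= 1 sample): ", path)
    gene_ids <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
      stop("non-numeric expression values in column '", colnames(tab)[-1L][bad],
           "' of ", path)
    }
    rownames(mat) <- gene_ids
  } else {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(cells_path)) cells_path <- file.path(dirname(path), "barcodes.tsv")
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) stop("index file not found: ", p)
    }
    sp <- Matrix::readMM(path)
    gene_ids <- read_gene_set(genes_path, as_set = FALSE)
    cell_ids <- readLines(cells_path)
    cell_ids <- trimws(cell_ids[nzchar(trimws(cell_ids))])
    if (length(gene_ids) != nrow(sp)) {
      stop("gene index length (", length(gene_ids), ") does not match matrix rows (",
           nrow(sp), ")")
    }
    if (length(cell_ids) != ncol(sp)) {
      stop("cell index length (", length(cell_ids), ") does not match matrix columns (",
           ncol(sp), ")")
    }
    mat <- as.matrix(sp)
    dimnames(mat) <- list(gene_ids, cell_ids)
  }
  mat <- collapse_duplicate_genes(mat)
  validate_expression_matrix(mat)
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] for the TSV layout; round-trips
#' values at full double precision.
#'
#' @param mat Numeric gene x sample matrix with dimnames.
#' @param path Output path.
#' @param gene_column Name of the first (gene identifier) column.
#' @export
write_expression_matrix <- function(mat, path, gene_column = "gene_id") {
  validate_expression_matrix(mat)
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- gene_column
  # format() would truncate; write full precision via as.character on doubles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  body <- apply(mat, 1L, function(x) paste(formatC(x, digits = 17, format = "g"),
                                           collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

collapse_duplicate_genes <- function(mat) {
  dup <- duplicated(rownames(mat))
  if (!any(dup)) return(mat)
  n_dup <- length(unique(rownames(mat)[dup]))
  warning(n_dup, " duplicated gene identifier(s) collapsed by summation")
  out <- rowsum(mat, group = rownames(mat), reorder = FALSE)
  out
}

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric, finite, non-negative values and
#' unique gene/sample identifiers. Called by every reader; exported so that
#' programmatically built matrices can be checked too.
#'
#' @param mat Matrix to validate.
#' @return Invisibly `mat`; stops on violation.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyNA(mat) || any(!is.finite(mat))) stop("expression values must be finite (no NA/Inf)")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value at gene '", rownames(mat)[bad[1L]],
         "', sample '", colnames(mat)[bad[2L]], "'")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  invisible(mat)
}

#' Read a single-cell reference matrix with its cell-type annotation
#'
#' The annotation TSV must have columns `cell_id` and `cell_type`. The
#' returned matrix is restricted to, and ordered like, the annotated cells.
#' Every cell type must have at least two annotated cells, otherwise the
#' per-type marker statistics downstream are undefined.
#'
#' @param matrix_path Path to the reference expression matrix.
#' @param annotation_path Path to the annotation TSV.
#' @param format Matrix format, as in [read_expression_matrix()].
#' @param ... Passed to [read_expression_matrix()].
#' @return A list with elements `matrix` (genes x cells) and `annotation`
#'   (data.frame with `cell_id`, `cell_type`).
#' @export
read_cell_reference <- function(matrix_path, annotation_path,
                                format = c("tsv", "mtx_triplet"), ...) {
  mat <- read_expression_matrix(matrix_path, format = match.arg(format), ...)
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cell_type") %in% colnames(ann))) {
    stop("annotation must have columns 'cell_id' and 'cell_type': ", annotation_path)
  }
  ann$cell_id <- as.character(ann$cell_id)
  ann$cell_type <- as.character(ann$cell_type)
  validate_cell_annotation(ann, colnames(mat))
  list(matrix = mat[, ann$cell_id, drop = FALSE],
       annotation = ann[, c("cell_id", "cell_type")])
}

validate_cell_annotation <- function(ann, matrix_cells) {
  if (anyDuplicated(ann$cell_id)) stop("duplicate cell_id in annotation")
  missing <- setdiff(ann$cell_id, matrix_cells)
  if (length(missing)) {
    stop("annotated cell(s) missing from reference matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  counts <- table(ann$cell_type)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop("cell type(s) with fewer than 2 cells: ", paste(small, collapse = ", "))
  }
  invisible(ann)
}

#' Read a plain-text gene set
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored. Identifiers are case-sensitive; duplicates are dropped.
#'
#' @param path Path to the gene list.
#' @param as_set Deduplicate (default). `FALSE` keeps order and duplicates
#'   (used internally for matrix index files).
#' @return Character vector of gene identifiers.
#' @export
read_gene_set <- function(path, as_set = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("gene set file contains no identifiers: ", path)
  if (as_set) unique(lines) else lines
}

#' Read a clinical cohort table
#'
#' Expected TSV columns: `sample_id`, `grading` (G1/G2/G3 or empty),
#' `status` (NET/NEC or empty), `survival_time` (non-negative, or empty),
#' `event` (0/1, or empty), `study_id`. Empty strings encode missing values
#' and become `NA`. An event flag must accompany every survival time.
#'
#' @param path Path to the cohort TSV.
#' @param sample_ids Optional vector of bulk-matrix sample identifiers the
#'   table must match (order-insensitively).
#' @return data.frame, one row per sample.
#' @export
read_cohort_table <- function(path, sample_ids = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "")
  req <- c("sample_id", "grading", "status", "survival_time", "event", "study_id")
  miss <- setdiff(req, colnames(tab))
  if (length(miss)) stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  validate_cohort_table(tab, sample_ids)
  tab
}

validate_cohort_table <- function(tab, sample_ids = NULL) {
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in cohort table")
  badg <- !is.na(tab$grading) & !tab$grading %in% c("G1", "G2", "G3")
  if (any(badg)) stop("invalid grading value(s): ", paste(unique(tab$grading[badg]), collapse = ", "))
  bads <- !is.na(tab$status) & !tab$status %in% c("NET", "NEC")
  if (any(bads)) stop("invalid status value(s): ", paste(unique(tab$status[bads]), collapse = ", "))
  if (any(!is.na(tab$survival_time) & tab$survival_time < 0)) stop("negative survival_time")
  if (any(!is.na(tab$event) & !tab$event %in% c(0, 1))) stop("event flag must be 0 or 1")
  orphan <- !is.na(tab$survival_time) & is.na(tab$event)
  if (any(orphan)) {
    stop("survival_time without event flag for: ",
         paste(utils::head(tab$sample_id[orphan], 5L), collapse = ", "))
  }
  if (!is.null(sample_ids) && !setequal(tab$sample_id, sample_ids)) {
    stop("cohort sample_ids do not match the expression matrix")
  }
  invisible(tab)
}

#' Write a cohort table as TSV (missing values as empty strings)
#' @param tab Cohort data.frame as returned by [read_cohort_table()].
#' @param path Output path.
#' @export
write_cohort_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
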