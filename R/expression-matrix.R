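#' Expression matrix container
#'
#' A light S3 container for a genes-by-columns expression matrix together
#' with its normalization "flavor".  Columns are cells for single-cell data
#' and samples for bulk data.  The flavor records which transform the values
#' have already undergone, because downstream thresholds (detection calls,
#' mean-expression floors, TPM gates) are flavor-dependent:
#'
#' \describe{
#'   \item{\code{linear_tpm}}{non-negative TPM-scale values.}
#'   \item{\code{log2_tpm10}}{\code{log2(TPM/10 + 1)}, the full-length
#'     scRNA-seq convention used for the melanoma-style datasets.}
#'   \item{\code{centered}}{log-scale values with patient-level offsets
#'     removed (NSCLC-style); may be negative.}
#'   \item{\code{counts}}{raw non-negative integer counts.}
#' }
#'
#' @param values numeric matrix, genes in rows, cells/samples in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   \code{rownames(values)}).
#' @param col_ids character vector of unique cell/sample identifiers
#'   (defaults to \code{colnames(values)}).
#' @param flavor one of \code{"log2_tpm10"}, \code{"centered"},
#'   \code{"linear_tpm"}, \code{"counts"}.
#'
#' @return an object of class \code{"expr_matrix"}: a list with elements
#'   \code{values} (named numeric matrix) and \code{flavor}.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        col_ids = colnames(values),
                        flavor = c("log2_tpm10", "centered", "linear_tpm",
                                   "counts")) {
  flavor <- match.arg(flavor)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(col_ids)) {
    stop("expr_matrix requires gene and column identifiers")
  }
  gene_ids <- as.character(gene_ids)
  col_ids <- as.character(col_ids)
  if (length(gene_ids) != nrow(values) || length(col_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate cell/sample identifiers: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (flavor %in% c("log2_tpm10", "linear_tpm", "counts") &&
      any(values < 0)) {
    stop("flavor '", flavor, "' requires non-negative values")
  }
  dimnames(values) <- list(gene_ids, col_ids)
  structure(list(values = values, flavor = flavor), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d columns, flavor = %s\n",
              nrow(x$values), ncol(x$values), x$flavor))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and column identifiers of an expression matrix
#' @param m an \code{expr_matrix}.
#' @return character vector of identifiers.
#' @export
genes <- function(m) rownames(m$values)

#' @rdname genes
#' @export
cols <- function(m) colnames(m$values)

#' Subset an expression matrix by column identifiers or indices
#'
#' @param m an \code{expr_matrix}.
#' @param keep logical/integer/character selector of columns.
#' @return an \code{expr_matrix} restricted to the selected columns.
#' @export
subset_cols <- function(m, keep) {
  expr_matrix(m$values[, keep, drop = FALSE], flavor = m$flavor)
}

fetch_gene <- function(m, gene, context = "gene") {
  if (!gene %in% genes(m)) {
    stop("required ", context, " '", gene, "' not present in matrix")
  }
  m$values[gene, ]
}

#' Read an expression matrix from disk
#'
#' Two carriers are supported: a TSV with gene rows (first column
#' \code{gene}, remaining columns are cell/sample identifiers) and a
#' MatrixMarket coordinate triplet (\code{matrix.mtx} plus \code{genes.tsv}
#' and \code{barcodes.tsv} in the same directory, one identifier per line).
#'
#' @param path path to the TSV file, or for \code{format = "mtx_triplet"}
#'   either the \code{.mtx} file or its directory.
#' @param format \code{"tsv"} or \code{"mtx_triplet"}.
#' @param flavor normalization flavor to record on the result.
#' @return an \code{expr_matrix}.
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            flavor = "log2_tpm10") {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2 || names(tab)[1] != "gene") {
      stop("expression TSV must have a leading 'gene' column")
    }
    gene_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(tab[-1], is.numeric, logical(1)))
      stop("non-numeric expression values in column(s): ",
           paste(names(tab)[-1][bad], collapse = ", "))
    }
    rownames(vals) <- gene_ids
    return(expr_matrix(vals, flavor = flavor))
  }
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx <- if (dir.exists(path)) file.path(dir, "matrix.mtx") else path
  gf <- file.path(dir, "genes.tsv")
  bf <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, gf, bf)) {
    if (!file.exists(f)) stop("MTX triplet file not found: ", f)
  }
  m <- as.matrix(Matrix::readMM(mtx))
  gene_ids <- readLines(gf)
  col_ids <- readLines(bf)
  rownames(m) <- gene_ids
  colnames(m) <- col_ids
  expr_matrix(m, flavor = flavor)
}

#' Write an expression matrix
#'
#' @param m an \code{expr_matrix}.
#' @param path output path (TSV) or directory (MTX triplet).
#' @param format \code{"tsv"} or \code{"mtx_triplet"}.
#' @return the path, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(gene = genes(m), m$values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  writeLines(genes(m), file.path(path, "genes.tsv"))
  writeLines(cols(m), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a clinical table
#'
#' Expected TSV columns: \code{sample_id}, \code{time}, \code{event}, and
#' optionally \code{tmb}, \code{response}, \code{response_months},
#' \code{dialect}.  Unknown dialect strings are preserved verbatim so that
#' \code{\link{classify_response}} can reject them explicitly.
#'
#' @param path path to the TSV file.
#' @return a \code{data.frame} with validated \code{time} (> 0 where
#'   non-missing) and \code{event} coerced to 0/1.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_clinical(tab)
}

validate_clinical <- function(tab) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id values")
  t_ok <- is.na(tab$time) | tab$time > 0
  if (!all(t_ok)) {
    stop("non-positive survival time for sample(s): ",
         paste(tab$sample_id[!t_ok], collapse = ", "))
  }
  ev <- tab$event
  if (is.logical(ev)) ev <- as.integer(ev)
  e_ok <- is.na(ev) | ev %in% c(0, 1)
  if (!all(e_ok)) {
    stop("event indicator outside {0,1} for sample(s): ",
         paste(tab$sample_id[!e_ok], collapse = ", "))
  }
  tab$event <- as.integer(ev)
  tab
}

#' Write a clinical table
#' @param clinical a clinical \code{data.frame}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
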