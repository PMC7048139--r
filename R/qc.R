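#' Log-transform a linear TPM matrix
#'
#' Applies the full-length scRNA-seq normalization
#' \eqn{E = log2(TPM/10 + 1)} entry-wise.
#'
#' @param m an \code{expr_matrix} with flavor \code{"linear_tpm"}.
#' @return an \code{expr_matrix} with flavor \code{"log2_tpm10"}.
#' @export
normalize_log2_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$flavor != "linear_tpm") {
    stop("normalize_log2_tpm expects flavor 'linear_tpm', got '",
         m$flavor, "'")
  }
  if (any(m$values < 0)) stop("TPM values must be non-negative")
  expr_matrix(log2(m$values / 10 + 1), flavor = "log2_tpm10")
}

linearize_values <- function(m) {
  switch(m$flavor,
         linear_tpm = m$values,
         counts = m$values,
         log2_tpm10 = (2^m$values - 1) * 10,
         centered = 2^m$values)
}

qc_report <- function(rules, thresholds) {
  pass <- Reduce(`&`, rules[-1])
  rep <- data.frame(cell_id = rules$cell_id, rules[-1],
                    pass = pass, stringsAsFactors = FALSE)
  structure(list(cells = rep, thresholds = thresholds,
                 n_retained = sum(pass), n_removed = sum(!pass)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d retained, %d removed\n",
              x$n_retained, x$n_removed))
  for (nm in setdiff(names(x$cells), c("cell_id", "pass"))) {
    cat(sprintf("  rule %-12s removed %d\n", nm, sum(!x$cells[[nm]])))
  }
  invisible(x)
}

#' Full-length scRNA-seq cell filters
#'
#' Removes cells with fewer than \code{min_genes} detected genes (a gene is
#' detected when its normalized value is > 0, i.e. at least one mapped
#' read) or with a mean housekeeping expression below \code{min_hk}.
#' Thresholds are inclusive on the retained side: a cell with exactly
#' \code{min_genes} detected genes, or a housekeeping mean of exactly
#' \code{min_hk}, is kept.
#'
#' @param m an \code{expr_matrix} with flavor \code{"log2_tpm10"}.
#' @param min_genes detected-gene floor (default 1700).
#' @param housekeeping character vector of housekeeping gene identifiers.
#' @param min_hk housekeeping-mean floor (default 3).
#' @return a list with \code{matrix} (retained cells) and \code{report}
#'   (a \code{qc_report}).
#' @export
filter_cells_fulllength <- function(m, min_genes = 1700, housekeeping,
                                    min_hk = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$flavor != "log2_tpm10") {
    stop("full-length filters expect flavor 'log2_tpm10'")
  }
  if (missing(housekeeping) || length(housekeeping) == 0) {
    stop("housekeeping gene list must be non-empty")
  }
  miss <- setdiff(housekeeping, genes(m))
  if (length(miss)) {
    stop("housekeeping gene(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  }
  detected <- colSums(m$values > 0)
  hk_mean <- colMeans(m$values[housekeeping, , drop = FALSE])
  report <- qc_report(
    list(cell_id = cols(m),
         gene_count = detected >= min_genes,
         housekeeping = hk_mean >= min_hk),
    list(min_genes = min_genes, min_hk = min_hk))
  list(matrix = subset_cols(m, report$cells$pass), report = report)
}

#' Median/MAD and mitochondrial cell filters
#'
#' Removes cells whose detected-gene count falls below
#' \code{median - mad_mult * MAD} (MAD unscaled: the raw median absolute
#' deviation, no consistency factor) or whose mitochondrial count fraction
#' exceeds \code{max_mito} (strictly: a fraction exactly at the ceiling is
#' kept).  The gene-count cutoff may be frozen via \code{frozen_cutoff} so
#' that re-application to already-filtered data is idempotent; otherwise the
#' cutoff is computed from the cells given.  The mitochondrial fraction is
#' computed on raw counts when supplied, else on linearized expression.
#'
#' @param m an \code{expr_matrix}.
#' @param mad_mult MAD multiplier (default 3).
#' @param max_mito mitochondrial-fraction ceiling (default 0.10).
#' @param mito_genes mitochondrial gene identifiers.
#' @param counts optional raw count matrix (genes x cells) for the
#'   mitochondrial fraction.
#' @param frozen_cutoff optional pre-computed gene-count cutoff.
#' @return a list with \code{matrix} and \code{report}; the applied cutoff
#'   is in \code{report$thresholds$gene_count_cutoff}.
#' @export
filter_cells_mad <- function(m, mad_mult = 3, max_mito = 0.10, mito_genes,
                             counts = NULL, frozen_cutoff = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3) {
    stop("median/MAD filter needs at least 3 cells")
  }
  if (missing(mito_genes) || length(mito_genes) == 0) {
    stop("mitochondrial gene list must be non-empty")
  }
  miss <- setdiff(mito_genes, genes(m))
  if (length(miss)) {
    stop("mitochondrial gene(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  }
  detected <- colSums(m$values > 0)
  if (is.null(frozen_cutoff)) {
    med <- stats::median(detected)
    mad_raw <- stats::median(abs(detected - med))
    cutoff <- med - mad_mult * mad_raw
  } else {
    cutoff <- frozen_cutoff
  }
  basis <- if (!is.null(counts)) counts else linearize_values(m)
  tot <- colSums(basis)
  tot[tot == 0] <- 1
  mito_frac <- colSums(basis[mito_genes, , drop = FALSE]) / tot
  report <- qc_report(
    list(cell_id = cols(m),
         gene_count = detected >= cutoff,
         mito = mito_frac <= max_mito),
    list(mad_mult = mad_mult, max_mito = max_mito,
         gene_count_cutoff = cutoff,
         mito_basis = if (is.null(counts)) "linearized" else "counts"))
  list(matrix = subset_cols(m, report$cells$pass), report = report)
}

#' Marker-threshold T-cell gating
#'
#' In-silico analogue of FACS gating on sorted T cells, applied on the
#' linear TPM scale.  CD8 mode keeps cells with CD3D >= 3, CD8A >= 3 and
#' CD4 <= 30; CD4 mode keeps cells with CD4 >= 3 and CD8A <= 30 (boundaries
#' inclusive on the retained side, matching the strict discard conditions).
#' A matrix in \code{log2_tpm10} flavor is back-transformed internally.
#'
#' @param m an \code{expr_matrix} with flavor \code{"linear_tpm"} or
#'   \code{"log2_tpm10"}.
#' @param population \code{"CD8"} or \code{"CD4"}.
#' @param cd3d_min,cd8a_min,cd4_max,cd4_min,cd8a_max TPM gate thresholds.
#' @return a list with \code{matrix} (retained cells, original flavor) and
#'   \code{report}.
#' @export
gate_t_cells <- function(m, population = c("CD8", "CD4"),
                         cd3d_min = 3, cd8a_min = 3, cd4_max = 30,
                         cd4_min = 3, cd8a_max = 30) {
  population <- match.arg(population)
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$flavor %in% c("linear_tpm", "log2_tpm10")) {
    stop("gate_t_cells needs a TPM-scale matrix (linear_tpm or log2_tpm10)")
  }
  lin <- linearize_values(m)
  for (g in c("CD3D", "CD8A", "CD4")) {
    if (!g %in% genes(m)) stop("gate gene '", g, "' absent from matrix")
  }
  if (population == "CD8") {
    rules <- list(cell_id = cols(m),
                  cd3d = lin["CD3D", ] >= cd3d_min,
                  cd8a = lin["CD8A", ] >= cd8a_min,
                  cd4 = lin["CD4", ] <= cd4_max)
    thr <- list(population = "CD8", cd3d_min = cd3d_min,
                cd8a_min = cd8a_min, cd4_max = cd4_max)
  } else {
    rules <- list(cell_id = cols(m),
                  cd4 = lin["CD4", ] >= cd4_min,
                  cd8a = lin["CD8A", ] <= cd8a_max)
    thr <- list(population = "CD4", cd4_min = cd4_min, cd8a_max = cd8a_max)
  }
  report <- qc_report(rules, thr)
  list(matrix = subset_cols(m, report$cells$pass), report = report)
}
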