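#' Split cells at the median expression of a marker gene
#'
#' Cells strictly below the sample median of the marker are labeled
#' \code{low}, cells strictly above are \code{high}.  Cells exactly at the
#' median are assigned by \code{at_median}: \code{"low"} (default; keeps
#' both subsets populated when the median sits on a mass point such as
#' zero-inflated PDCD1) or \code{"drop"} (excluded from both subsets).
#'
#' @param m an \code{expr_matrix} with at least 4 cells.
#' @param marker marker gene identifier (default \code{"PDCD1"}).
#' @param at_median tie policy for cells exactly at the median.
#' @return a list of class \code{"subset_split"}: \code{marker},
#'   \code{median}, \code{labels} (named character vector over cells, with
#'   values \code{"low"}, \code{"high"}, or \code{"dropped"}), counts per
#'   label, and the applied policy.
#' @export
median_split <- function(m, marker = "PDCD1",
                         at_median = c("low", "drop")) {
  at_median <- match.arg(at_median)
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 4) stop("median split needs at least 4 cells")
  v <- fetch_gene(m, marker, context = "split marker")
  med <- stats::median(v)
  if (max(v) == min(v)) {
    stop("degenerate split: all '", marker, "' values identical")
  }
  labels <- ifelse(v < med, "low", ifelse(v > med, "high",
                   if (at_median == "low") "low" else "dropped"))
  names(labels) <- cols(m)
  if (sum(labels == "low") == 0 || sum(labels == "high") == 0) {
    stop("degenerate split: one subset is empty under policy '",
         at_median, "'")
  }
  structure(list(marker = marker, median = med, labels = labels,
                 n_low = sum(labels == "low"),
                 n_high = sum(labels == "high"),
                 n_at_median = sum(v == med),
                 at_median = at_median),
            class = "subset_split")
}

#' @export
print.subset_split <- function(x, ...) {
  cat(sprintf(
    "subset_split on %s: median %.4g; %d low, %d high (%d at median -> %s)\n",
    x$marker, x$median, x$n_low, x$n_high, x$n_at_median, x$at_median))
  invisible(x)
}

#' Screen differentially expressed genes between the two split subsets
#'
#' For every gene, a two-sided Wilcoxon rank-sum test compares the low and
#' high subsets.  A gene is called a DEG when its P value is below
#' \code{p_threshold} (raw, no multiple-testing correction; a
#' Benjamini-Hochberg column is reported for information only) and its mean
#' expression reaches \code{mean_floor} in at least one subset (the floor
#' removes a gene only when it is below threshold in both subsets).
#'
#' @param m an \code{expr_matrix}.
#' @param split a \code{\link{median_split}} result on the same cells.
#' @param p_threshold raw P threshold (default 0.001).
#' @param mean_floor mean-expression floor; \code{NULL} selects the
#'   flavor default (1 for \code{log2_tpm10}, 2 for \code{centered}).
#' @param exact_max pooled-size cutoff for the exact rank-sum branch.
#' @return a \code{data.frame} of class \code{"deg_table"} with columns
#'   \code{gene}, \code{stat} (rank sum of the high subset), \code{p},
#'   \code{p_bh}, \code{mean_low}, \code{mean_high}, \code{direction},
#'   \code{pass_p}, \code{pass_mean}, \code{is_deg}.
#' @export
screen_degs <- function(m, split, p_threshold = 0.001, mean_floor = NULL,
                        exact_max = 12) {
  stopifnot(inherits(m, "expr_matrix"), inherits(split, "subset_split"))
  if (!setequal(names(split$labels), cols(m))) {
    stop("split labels do not match matrix columns")
  }
  lab <- split$labels[cols(m)]
  low <- which(lab == "low"); high <- which(lab == "high")
  if (length(low) < 2 || length(high) < 2) {
    stop("each subset needs at least 2 cells")
  }
  if (is.null(mean_floor)) {
    floors <- c(log2_tpm10 = 1, centered = 2)
    if (!m$flavor %in% names(floors)) {
      stop("no default mean floor for flavor '", m$flavor,
           "'; supply mean_floor")
    }
    mean_floor <- unname(floors[m$flavor])
  }
  mean_low <- rowMeans(m$values[, low, drop = FALSE])
  mean_high <- rowMeans(m$values[, high, drop = FALSE])
  res <- apply(m$values, 1, function(v) {
    t <- rank_sum_test(v[high], v[low], "two_sided", exact_max = exact_max)
    c(t$statistic, t$p_value)
  })
  tab <- data.frame(
    gene = genes(m),
    stat = res[1, ],
    p = res[2, ],
    p_bh = stats::p.adjust(res[2, ], method = "BH"),
    mean_low = mean_low,
    mean_high = mean_high,
    direction = ifelse(mean_high >= mean_low, "up_in_high", "up_in_low"),
    stringsAsFactors = FALSE)
  tab$pass_p <- tab$p < p_threshold
  tab$pass_mean <- pmax(tab$mean_low, tab$mean_high) >= mean_floor
  tab$is_deg <- tab$pass_p & tab$pass_mean
  rownames(tab) <- NULL
  attr(tab, "p_threshold") <- p_threshold
  attr(tab, "mean_floor") <- mean_floor
  attr(tab, "flavor") <- m$flavor
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Intersect DEGs with a transcription-factor catalog
#'
#' @param degs a \code{deg_table}.
#' @param tf_catalog character vector of transcription-factor gene symbols.
#' @return a \code{data.frame} of candidate TFs (\code{gene}, \code{p},
#'   \code{direction}), ordered by P ascending.
#' @export
intersect_tfs <- function(degs, tf_catalog) {
  stopifnot(inherits(degs, "deg_table"))
  if (length(tf_catalog) == 0) stop("TF catalog must be non-empty")
  hits <- degs[degs$is_deg & degs$gene %in% tf_catalog,
               c("gene", "p", "direction"), drop = FALSE]
  hits <- hits[order(hits$p, hits$gene), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Candidate TFs shared across datasets
#'
#' Intersects per-dataset candidate lists (as returned by
#' \code{\link{intersect_tfs}}) and orders the shared genes by their worst
#' (maximum) P value across datasets, ascending.
#'
#' @param candidate_lists a list (length >= 2) of candidate data.frames.
#' @return a \code{data.frame} with \code{gene} and \code{max_p}.
#' @export
cross_dataset_candidates <- function(candidate_lists) {
  if (length(candidate_lists) < 2) {
    stop("need candidate lists from at least 2 datasets")
  }
  shared <- Reduce(intersect, lapply(candidate_lists, function(x) x$gene))
  if (length(shared) == 0) {
    return(data.frame(gene = character(0), max_p = numeric(0)))
  }
  max_p <- vapply(shared, function(g) {
    max(vapply(candidate_lists,
               function(x) x$p[match(g, x$gene)], numeric(1)))
  }, numeric(1))
  out <- data.frame(gene = shared, max_p = unname(max_p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$max_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a TF catalog (one gene symbol per line)
#' @param path text file path.
#' @return character vector of unique, non-empty symbols.
#' @export
read_tf_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
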