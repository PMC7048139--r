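#' Classify T cells into effector / exhausted / memory states from markers
#'
#' Applies the three marker rules per cell, with a marker called positive
#' when its expression exceeds \code{positivity_threshold} (default 0: any
#' detection on log-normalized data):
#' \itemize{
#'   \item effector: CD62L-, CD127-, PDCD1-
#'   \item exhausted: PDCD1+
#'   \item memory: CD62L+ or CD127+
#' }
#' A cell matching two or more rules is \code{ambiguous}; a cell matching
#' none is \code{unknown}.  Under the pure three-rule logic every cell
#' matches at least one rule, so \code{unknown} is only reachable when an
#' indeterminate band is configured: marker values strictly inside
#' \code{(indeterminate_band[1], indeterminate_band[2])} yield no call for
#' that marker, and a cell whose matched-rule count cannot reach 1 is
#' \code{unknown}.
#'
#' @param m an \code{expr_matrix}.
#' @param positivity_threshold expression above which a marker is positive.
#' @param markers named character vector mapping \code{cd62l}, \code{cd127},
#'   \code{pdcd1} to gene identifiers (defaults SELL, IL7R, PDCD1).
#' @param indeterminate_band optional numeric length-2 vector; values in the
#'   open interval give no marker call.
#' @return a \code{data.frame}: \code{cell_id}, the three positivity calls,
#'   and \code{state} (factor with levels effector, exhausted, memory,
#'   ambiguous, unknown).
#' @export
call_state <- function(m, positivity_threshold = 0,
                       markers = c(cd62l = "SELL", cd127 = "IL7R",
                                   pdcd1 = "PDCD1"),
                       indeterminate_band = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  need <- c("cd62l", "cd127", "pdcd1")
  if (!all(need %in% names(markers))) {
    stop("markers must name cd62l, cd127 and pdcd1")
  }
  vals <- vapply(markers[need], function(g) fetch_gene(m, g, "state marker"),
                 numeric(ncol(m$values)))
  if (ncol(m$values) == 1) vals <- matrix(vals, nrow = 1)
  pos <- vals > positivity_threshold
  if (!is.null(indeterminate_band)) {
    stopifnot(length(indeterminate_band) == 2,
              indeterminate_band[1] < indeterminate_band[2])
    pos[vals > indeterminate_band[1] & vals < indeterminate_band[2]] <- NA
  }
  s <- pos[, 1]; i7 <- pos[, 2]; p1 <- pos[, 3]
  rules <- cbind(effector = !s & !i7 & !p1,
                 exhausted = p1,
                 memory = s | i7)
  n_true <- rowSums(rules, na.rm = TRUE)
  state <- character(nrow(rules))
  state[n_true >= 2] <- "ambiguous"
  state[n_true == 0] <- "unknown"
  one <- which(n_true == 1)
  if (length(one)) {
    state[one] <- colnames(rules)[max.col(
      replace(rules[one, , drop = FALSE],
              is.na(rules[one, , drop = FALSE]), FALSE), "first")]
  }
  data.frame(cell_id = cols(m),
             cd62l_pos = s, cd127_pos = i7, pdcd1_pos = p1,
             state = factor(state, levels = c("effector", "exhausted",
                                              "memory", "ambiguous",
                                              "unknown")),
             stringsAsFactors = FALSE)
}

#' Binomial enrichment of marker-called states within trajectory branches
#'
#' For every (branch, state) pair among the classified cells (ambiguous and
#' unknown cells excluded), tests whether the branch contains more cells of
#' the state than expected from the pooled background frequency, with an
#' exact upper-tail binomial test: given k state cells among n classified
#' cells in the branch and pooled background proportion p0,
#' \eqn{P = \sum_{j \ge k} \binom{n}{j} p0^j (1-p0)^{n-j}}.
#'
#' @param states a \code{\link{call_state}} data.frame, or a vector of
#'   per-cell state labels.
#' @param branches per-cell branch labels, same order/length as cells.
#' @return a \code{data.frame}: \code{branch}, \code{state}, \code{k},
#'   \code{n}, \code{p0}, \code{p}.  P is \code{NA} when the branch has no
#'   classified cells or the background proportion is degenerate.
#' @export
branch_enrichment <- function(states, branches) {
  st <- if (is.data.frame(states)) as.character(states$state)
        else as.character(states)
  branches <- as.character(branches)
  if (length(st) != length(branches)) {
    stop("states and branches must have equal length")
  }
  if (length(unique(branches)) < 2) stop("need at least 2 branches")
  keep <- st %in% c("effector", "exhausted", "memory")
  st <- st[keep]; br <- branches[keep]
  out <- expand.grid(branch = sort(unique(branches)),
                     state = c("effector", "exhausted", "memory"),
                     stringsAsFactors = FALSE)
  out$k <- NA_integer_; out$n <- NA_integer_
  out$p0 <- NA_real_; out$p <- NA_real_
  for (row in seq_len(nrow(out))) {
    b <- out$branch[row]; s <- out$state[row]
    p0 <- mean(st == s)
    n <- sum(br == b)
    k <- sum(br == b & st == s)
    out$k[row] <- k; out$n[row] <- n; out$p0[row] <- p0
    if (n > 0 && p0 > 0 && p0 < 1) {
      out$p[row] <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    }
  }
  out
}

#' One-tailed expression-dynamics test against the effector state
#'
#' Tests whether a gene is upregulated in the target group (exhausted or
#' memory cells) relative to effector cells, by a one-tailed Mann-Whitney
#' U test (\code{\link{rank_sum_test}} with alternative "greater").  Groups
#' may be trajectory-branch labels or per-cell state calls.
#'
#' @param m an \code{expr_matrix}.
#' @param groups per-cell group labels aligned with the matrix columns.
#' @param gene gene identifier to test.
#' @param target label of the upregulated group (e.g. \code{"exhausted"} or
#'   \code{"memory"}).
#' @param reference label of the reference group (default
#'   \code{"effector"}).
#' @return a list with \code{p_value}, \code{statistic}, \code{n_target},
#'   \code{n_reference}.
#' @export
dynamics_test <- function(m, groups, gene, target = "exhausted",
                          reference = "effector") {
  stopifnot(inherits(m, "expr_matrix"))
  groups <- as.character(groups)
  if (length(groups) != ncol(m$values)) {
    stop("groups must align with matrix columns")
  }
  v <- fetch_gene(m, gene)
  x <- v[!is.na(groups) & groups == target]
  y <- v[!is.na(groups) & groups == reference]
  if (length(x) == 0 || length(y) == 0) {
    stop("empty comparison group ('", target, "' vs '", reference, "')")
  }
  t <- rank_sum_test(x, y, alternative = "greater")
  list(p_value = t$p_value, statistic = t$statistic,
       n_target = length(x), n_reference = length(y))
}

#' Kernel-smoothed expression trend along pseudotime
#'
#' Nadaraya-Watson local mean with a Gaussian kernel, evaluated on an even
#' grid over the observed pseudotime range.  A descriptive stand-in for
#' trajectory regression curves; no branch-dependent model is fitted.
#'
#' @param pseudotime per-cell pseudotime values (at least 10 cells).
#' @param expr per-cell expression values of one gene.
#' @param bandwidth Gaussian kernel bandwidth (> 0), in pseudotime units.
#' @param n_grid number of grid points.
#' @return a \code{data.frame} with \code{pseudotime} (grid) and
#'   \code{fitted}; fitted values lie within the data range.
#' @export
fit_expression_trend <- function(pseudotime, expr, bandwidth = 0.1,
                                 n_grid = 50) {
  if (length(pseudotime) != length(expr)) {
    stop("pseudotime and expr must have equal length")
  }
  if (length(pseudotime) < 10) stop("need at least 10 cells")
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be > 0")
  }
  grid <- seq(min(pseudotime), max(pseudotime), length.out = n_grid)
  fitted <- vapply(grid, function(g) {
    w <- stats::dnorm((pseudotime - g) / bandwidth)
    sum(w * expr) / sum(w)
  }, numeric(1))
  data.frame(pseudotime = grid, fitted = fitted)
}
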