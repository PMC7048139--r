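#' T-cell-normalized target-gene score for bulk tumors
#'
#' Normalizes a target gene (TOX by default) to the T-cell content of each
#' bulk sample, using the geometric mean of CD3D, CD3E and CD3G as the
#' T-cell reference.  In the default \code{"log_diff"} mode the score is
#' \deqn{score = log2(target + pc) - \frac{1}{3}\sum_k log2(cd3_k + pc)}
#' i.e. the log of the pseudocounted target over the CD3 geometric mean;
#' \code{"linear_ratio"} returns the pseudocounted ratio itself (same
#' ranking).  Samples with all three CD3 values zero are scored but flagged
#' \code{low_tcell}.
#'
#' @param m a linear-scale \code{expr_matrix} (flavor \code{linear_tpm} or
#'   \code{counts}).
#' @param target target gene (default \code{"TOX"}).
#' @param cd3_trio the three CD3 genes.
#' @param pseudocount added to every value before logs (default 1).
#' @param mode \code{"log_diff"} or \code{"linear_ratio"}.
#' @return a \code{data.frame} of class \code{"score_table"}:
#'   \code{sample_id}, \code{target_value}, \code{cd3_geomean},
#'   \code{score}, \code{low_tcell}.
#' @export
tcell_normalized_score <- function(m, target = "TOX",
                                   cd3_trio = c("CD3D", "CD3E", "CD3G"),
                                   pseudocount = 1,
                                   mode = c("log_diff", "linear_ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$flavor %in% c("linear_tpm", "counts")) {
    stop("scores are computed on linear-scale values (flavor linear_tpm ",
         "or counts), got '", m$flavor, "'")
  }
  if (length(cd3_trio) != 3) stop("cd3_trio must name exactly 3 genes")
  t_val <- fetch_gene(m, target, "target gene")
  trio <- vapply(cd3_trio, function(g) fetch_gene(m, g, "CD3 gene"),
                 numeric(ncol(m$values)))
  if (ncol(m$values) == 1) trio <- matrix(trio, nrow = 1)
  mean_log2 <- rowMeans(log2(trio + pseudocount))
  log_diff <- log2(t_val + pseudocount) - mean_log2
  score <- if (mode == "log_diff") log_diff else 2^log_diff
  out <- data.frame(
    sample_id = cols(m),
    target_value = unname(t_val),
    cd3_geomean = 2^mean_log2 - pseudocount,
    score = unname(score),
    low_tcell = unname(rowSums(trio) == 0),
    stringsAsFactors = FALSE)
  attr(out, "target") <- target
  attr(out, "pseudocount") <- pseudocount
  attr(out, "mode") <- mode
  class(out) <- c("score_table", "data.frame")
  out
}

#' Per-sample T-cell abundance estimate
#'
#' The (pseudocounted) geometric mean of CD3D/CD3E/CD3G expression, a proxy
#' for T-cell content used to judge whether T-cell-normalized scores are
#' trustworthy in a cohort.
#'
#' @inheritParams tcell_normalized_score
#' @return numeric vector of abundances, named by sample.
#' @export
estimate_t_cell_abundance <- function(m,
                                      cd3_trio = c("CD3D", "CD3E", "CD3G"),
                                      pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  trio <- vapply(cd3_trio, function(g) fetch_gene(m, g, "CD3 gene"),
                 numeric(ncol(m$values)))
  if (ncol(m$values) == 1) trio <- matrix(trio, nrow = 1)
  ab <- 2^rowMeans(log2(trio + pseudocount)) - pseudocount
  stats::setNames(ab, cols(m))
}

#' Advisory low-abundance check for a cohort
#'
#' Flags a cohort whose median T-cell abundance falls below a floor
#' (default: the 25th percentile of a pooled reference distribution, or of
#' the cohort itself when no reference is given).  Purely advisory: cohorts
#' with few tumor-infiltrating T cells carry little signal for a
#' T-cell-normalized score.
#'
#' @param abundance per-sample abundances of the cohort.
#' @param floor explicit abundance floor, or \code{NULL}.
#' @param reference pooled abundances used to derive the floor when
#'   \code{floor} is \code{NULL}.
#' @param quantile quantile of the reference defining the floor.
#' @return list with \code{median}, \code{floor}, \code{warn}.
#' @export
check_cohort_abundance <- function(abundance, floor = NULL,
                                   reference = abundance,
                                   quantile = 0.25) {
  if (is.null(floor)) {
    floor <- stats::quantile(reference, quantile, names = FALSE)
  }
  med <- stats::median(abundance)
  list(median = med, floor = floor, warn = med < floor)
}

#' Label the top fraction of scores as the high stratum
#'
#' The \code{ceiling(fraction * n)} highest scores are labeled
#' \code{"high"}, the rest \code{"low"}.  Ties at the boundary are broken
#' by stable input order, with a warning.
#'
#' @param scores numeric scores, or a \code{score_table}.
#' @param fraction fraction in (0, 1) (default 0.30).
#' @return factor of \code{"high"}/\code{"low"} in input order.
#' @export
stratify_top_fraction <- function(scores, fraction = 0.30) {
  if (is.data.frame(scores)) scores <- scores$score
  n <- length(scores)
  if (n < 4) stop("stratification needs at least 4 samples")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  k <- ceiling(fraction * n)
  ord <- order(-scores)  # stable: ties keep input order
  high <- ord[seq_len(k)]
  boundary <- scores[ord[k]]
  if (k < n && scores[ord[k + 1]] == boundary) {
    warning("ties at the stratification boundary broken by input order")
  }
  factor(ifelse(seq_len(n) %in% high, "high", "low"),
         levels = c("high", "low"))
}

#' Retain the top fraction of samples by tumor mutation burden
#'
#' @param clinical clinical \code{data.frame} with a \code{tmb} column.
#' @param fraction fraction in (0, 1] (default 0.25).
#' @return the retained rows of \code{clinical} (stable order tie-break).
#' @export
filter_top_tmb <- function(clinical, fraction = 0.25) {
  if (!"tmb" %in% names(clinical)) stop("clinical table has no tmb column")
  if (anyNA(clinical$tmb)) {
    stop("missing TMB for sample(s): ",
         paste(clinical$sample_id[is.na(clinical$tmb)], collapse = ", "))
  }
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nrow(clinical)
  k <- ceiling(fraction * n)
  keep <- sort(order(-clinical$tmb)[seq_len(k)])
  clinical[keep, , drop = FALSE]
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates via \code{survival::survfit}; at tied times,
#' deaths are processed before censorings (the standard convention).
#'
#' @param time positive survival/censoring times.
#' @param event event indicators in \{0, 1\}.
#' @param group group labels (a single group is allowed).
#' @return a \code{data.frame}: \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival}.
#' @export
km_estimate <- function(time, event, group = rep("all", length(time))) {
  check_surv_args(time, event, group)
  group <- as.character(group)
  out <- lapply(sort(unique(group)), function(g) {
    sel <- group == g
    if (!any(sel)) stop("empty group '", g, "'")
    fit <- survival::survfit(
      survival::Surv(time[sel], event[sel]) ~ 1)
    data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               survival = fit$surv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank: at each distinct event time the observed minus
#' expected events per group with hypergeometric variance; for two groups
#' the statistic is \eqn{(\sum O - \sum E)^2 / \sum V} on 1 df.  Delegates
#' to \code{survival::survdiff}.
#'
#' @inheritParams km_estimate
#' @return list with \code{chisq}, \code{df}, \code{p_value},
#'   \code{observed}, \code{expected} (named by group).
#' @export
logrank_test <- function(time, event, group) {
  check_surv_args(time, event, group)
  group <- factor(group)
  if (nlevels(group) < 2) stop("log-rank test needs at least 2 groups")
  if (sum(event) == 0) stop("no events: log-rank test undefined")
  if (any(table(group) == 0)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = stats::setNames(sd$obs, levels(group)),
       expected = stats::setNames(sd$exp, levels(group)))
}

check_surv_args <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group)) {
    stop("time, event and group must have equal length")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be positive and finite")
  }
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
}

#' Map cohort response annotations to responder labels
#'
#' Implements the four cohort dialects:
#' \describe{
#'   \item{hugo}{Partial/Complete Response -> responder; Progressive
#'     Disease -> non-responder.}
#'   \item{jung}{DCB (durable clinical benefit) -> responder; NDB ->
#'     non-responder.}
#'   \item{riaz}{Stable Disease -> excluded; otherwise as hugo.}
#'   \item{internal}{PR, or SD lasting > 6 months -> responder; PD, or SD
#'     lasting <= 6 months -> non-responder.  Requires a
#'     \code{response_months} duration for SD samples.}
#' }
#' Unknown annotation strings fail loudly, listing the offending samples.
#'
#' @param clinical clinical \code{data.frame} with a \code{response} column
#'   (and \code{response_months} for the internal dialect).
#' @param dialect one of \code{"hugo"}, \code{"jung"}, \code{"riaz"},
#'   \code{"internal"}.
#' @return \code{clinical} with an added \code{label} column
#'   (\code{responder}/\code{non_responder}/\code{excluded}).
#' @export
classify_response <- function(clinical,
                              dialect = c("hugo", "jung", "riaz",
                                          "internal")) {
  dialect <- match.arg(dialect)
  if (!"response" %in% names(clinical)) {
    stop("clinical table has no response column")
  }
  ann <- tolower(trimws(clinical$response))
  resp_set <- c("partial response", "complete response", "pr", "cr")
  pd_set <- c("progressive disease", "pd")
  sd_set <- c("stable disease", "sd")
  label <- rep(NA_character_, length(ann))
  if (dialect %in% c("hugo", "riaz")) {
    label[ann %in% resp_set] <- "responder"
    label[ann %in% pd_set] <- "non_responder"
    if (dialect == "riaz") label[ann %in% sd_set] <- "excluded"
  } else if (dialect == "jung") {
    label[ann == "dcb"] <- "responder"
    label[ann == "ndb"] <- "non_responder"
  } else {
    label[ann %in% c("pr", "partial response",
                     "cr", "complete response")] <- "responder"
    label[ann %in% pd_set] <- "non_responder"
    is_sd <- ann %in% sd_set
    if (any(is_sd)) {
      if (!"response_months" %in% names(clinical) ||
          anyNA(clinical$response_months[is_sd])) {
        stop("internal dialect requires response_months for SD samples")
      }
      label[is_sd] <- ifelse(clinical$response_months[is_sd] > 6,
                             "responder", "non_responder")
    }
  }
  if (anyNA(label)) {
    bad <- is.na(label)
    stop("unrecognized response annotation(s) for dialect '", dialect,
         "': ", paste(sprintf("%s='%s'", clinical$sample_id[bad],
                              clinical$response[bad]), collapse = ", "))
  }
  clinical$label <- label
  clinical
}

#' Score-vs-response association: Mann-Whitney test, ranking and AUROC
#'
#' Compares T-cell-normalized scores between responders and non-responders
#' with a two-tailed Mann-Whitney U test, and evaluates responder retrieval
#' when patients are ranked by ascending score (lowest target expression
#' first).  The AUROC uses the predictor \code{-score} and equals the
#' Mann-Whitney U statistic divided by \eqn{n_1 n_2}, with half-credit for
#' ties; ROC points are computed with tied predictor values grouped.
#' Excluded samples enter neither the test nor the ROC.
#'
#' @param scores a \code{score_table} or numeric score vector.
#' @param labels per-sample labels
#'   (\code{responder}/\code{non_responder}/\code{excluded}).
#' @return list with \code{p_value}, \code{auroc}, \code{n_responder},
#'   \code{n_nonresponder}, \code{roc} (data.frame \code{fpr}, \code{tpr}),
#'   and \code{ranking} (samples by ascending score).
#' @export
response_association <- function(scores, labels) {
  ids <- NULL
  if (is.data.frame(scores)) {
    ids <- scores$sample_id
    scores <- scores$score
  }
  labels <- as.character(labels)
  if (length(labels) != length(scores)) {
    stop("scores and labels must have equal length")
  }
  keep <- labels != "excluded"
  s <- scores[keep]; lab <- labels[keep]
  is_resp <- lab == "responder"
  n1 <- sum(is_resp); n2 <- sum(!is_resp)
  if (n1 == 0 || n2 == 0) {
    stop("need at least one responder and one non-responder")
  }
  mw <- rank_sum_test(s[is_resp], s[!is_resp], "two_sided")
  pred <- -s  # lower score predicts response
  r <- rank(pred)
  u <- sum(r[is_resp]) - n1 * (n1 + 1) / 2
  auroc <- u / (n1 * n2)
  ord <- order(pred, decreasing = TRUE)
  roc <- data.frame(fpr = 0, tpr = 0)
  tp <- 0; fp <- 0
  for (val in unique(pred[ord])) {
    at <- pred == val
    tp <- tp + sum(at & is_resp)
    fp <- fp + sum(at & !is_resp)
    roc <- rbind(roc, data.frame(fpr = fp / n2, tpr = tp / n1))
  }
  ranking <- data.frame(
    sample_id = if (is.null(ids)) which(keep) else ids[keep],
    score = s, label = lab, stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$score), , drop = FALSE]
  rownames(ranking) <- NULL
  list(p_value = mw$p_value, auroc = auroc,
       n_responder = n1, n_nonresponder = n2,
       roc = roc, ranking = ranking)
}

#' Waterfall values: score minus the cohort median
#'
#' @param scores a \code{score_table} or numeric vector.
#' @param cohort optional per-sample cohort labels; the median is taken
#'   within cohort.
#' @return numeric vector of waterfall values (median 0 per cohort).
#' @export
waterfall_values <- function(scores, cohort = NULL) {
  if (is.data.frame(scores)) scores <- scores$score
  if (is.null(cohort)) cohort <- rep("all", length(scores))
  stats::ave(scores, cohort, FUN = function(v) v - stats::median(v))
}
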