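#' Specification of a synthetic bulk tumor cohort
#'
#' Each synthetic tumor mixes a T-cell fraction (Beta-distributed) with a
#' within-T-cell TOX level \code{u} (normal on the log2 scale).  Bulk CD3
#' expression scales with the T-cell fraction; bulk TOX scales with fraction
#' times \code{2^u}, so the CD3-normalized TOX score recovers \code{u} up to
#' a constant.  Survival times follow an exponential proportional-hazards
#' model with hazard \code{baseline_hazard * hazard_ratio^u}; censoring is
#' exponential at a rate giving roughly the requested censoring fraction.
#' Response labels are Bernoulli with non-response probability
#' \code{plogis(response_slope * u)}: higher TOX in T cells makes
#' non-response more likely.  When \code{response_slope} is \code{NULL} it
#' is solved so that the true AUROC for retrieving responders by ascending
#' \code{u} equals \code{auroc_target}.
#'
#' @param n_patients cohort size.
#' @param tcell_alpha,tcell_beta Beta parameters of the T-cell fraction.
#' @param tox_sd sd of the within-T-cell log2 TOX level.
#' @param hazard_ratio hazard ratio per unit of true normalized TOX score.
#' @param baseline_hazard exponential baseline hazard (1/time-unit).
#' @param censoring_rate target fraction of censored subjects, in [0, 1).
#' @param response_slope logistic slope on \code{u} for non-response, or
#'   \code{NULL} to solve from \code{auroc_target}.
#' @param auroc_target true AUROC used when solving the slope.
#' @param tmb_meanlog,tmb_sdlog log-normal tumor mutation burden.
#' @param noise_sd log-normal measurement noise sd on bulk expression.
#' @param n_filler_genes number of unrelated bulk genes to include.
#' @param dialect response-annotation dialect to emit
#'   (\code{"hugo"}, \code{"jung"}, \code{"riaz"}, \code{"internal"}).
#' @param seed integer seed.
#' @return a list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_patients = 300, tcell_alpha = 2, tcell_beta = 6,
                        tox_sd = 1, hazard_ratio = 2.5,
                        baseline_hazard = 0.1, censoring_rate = 0.3,
                        response_slope = NULL, auroc_target = 0.8,
                        tmb_meanlog = log(5), tmb_sdlog = 1,
                        noise_sd = 0.2, n_filler_genes = 40,
                        dialect = c("hugo", "jung", "riaz", "internal"),
                        seed = 1L) {
  dialect <- match.arg(dialect)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must lie in [0, 1)")
  }
  if (is.null(response_slope)) {
    response_slope <- logistic_slope_for_auroc(auroc_target, sd = tox_sd)
  }
  structure(list(n_patients = n_patients, tcell_alpha = tcell_alpha,
                 tcell_beta = tcell_beta, tox_sd = tox_sd,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 response_slope = response_slope,
                 tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
                 noise_sd = noise_sd, n_filler_genes = n_filler_genes,
                 dialect = dialect, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Logistic slope giving a target true AUROC
#'
#' For a score \code{u ~ N(0, sd^2)} and non-response probability
#' \code{plogis(b * u)}, computes by deterministic quadrature the AUROC of
#' retrieving responders by ascending score, and solves for the slope
#' \code{b} that attains \code{target}.
#'
#' @param target desired AUROC in (0.5, 1).
#' @param sd standard deviation of the score.
#' @return the slope \code{b}.
#' @export
logistic_slope_for_auroc <- function(target, sd = 1) {
  if (target <= 0.5 || target >= 1) stop("target AUROC must be in (0.5, 1)")
  auroc_of <- function(b) {
    u <- seq(-8 * sd, 8 * sd, length.out = 4001)
    w <- stats::dnorm(u, 0, sd)
    p_non <- stats::plogis(b * u)
    wr <- w * (1 - p_non); wr <- wr / sum(wr)
    wn <- w * p_non; wn <- wn / sum(wn)
    # P(u_responder < u_nonresponder), grid cells treated as atoms
    tail_wn <- rev(cumsum(rev(wn)))
    sum(wr * (tail_wn - wn + 0.5 * wn))
  }
  stats::uniroot(function(b) auroc_of(b) - target, c(1e-3, 60),
                 tol = 1e-8)$root
}

#' Simulate a bulk cohort with planted survival and response effects
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return a list with \code{expression} (linear-scale \code{expr_matrix}
#'   with TOX, CD3D/CD3E/CD3G and filler genes), \code{clinical} (a
#'   clinical \code{data.frame} with survival, TMB and dialect-formatted
#'   response annotations), and \code{truth} (per-sample T-cell fraction,
#'   true log2 TOX level, non-response probability and responder label).
#' @export
make_bulk_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    ids <- sprintf("S%04d", seq_len(n))
    f <- stats::rbeta(n, spec$tcell_alpha, spec$tcell_beta)
    u <- stats::rnorm(n, 0, spec$tox_sd)
    noise <- function() exp(stats::rnorm(n, 0, spec$noise_sd))
    cd3_base <- c(CD3D = 500, CD3E = 400, CD3G = 300)
    vals <- rbind(
      TOX = f * 80 * 2^u * noise() + 0.5,
      CD3D = f * cd3_base["CD3D"] * noise() + 0.05,
      CD3E = f * cd3_base["CD3E"] * noise() + 0.05,
      CD3G = f * cd3_base["CD3G"] * noise() + 0.05)
    if (spec$n_filler_genes > 0) {
      filler <- matrix(
        stats::rlnorm(spec$n_filler_genes * n, log(50), 1),
        nrow = spec$n_filler_genes,
        dimnames = list(sprintf("BULK%03d", seq_len(spec$n_filler_genes)),
                        NULL))
      vals <- rbind(vals, filler)
    }
    colnames(vals) <- ids
    rownames(vals)[1:4] <- c("TOX", "CD3D", "CD3E", "CD3G")

    h <- spec$baseline_hazard * spec$hazard_ratio^u
    t_event <- stats::rexp(n, h)
    if (spec$censoring_rate > 0) {
      rc <- spec$baseline_hazard *
        spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- stats::rexp(n, rc)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    p_non <- stats::plogis(spec$response_slope * u)
    responder <- stats::runif(n) >= p_non
    months <- ifelse(responder, stats::runif(n, 7, 24),
                     stats::runif(n, 1, 6))
    response <- dialect_annotation(responder, spec$dialect, n)

    clinical <- data.frame(
      sample_id = ids, time = time, event = event,
      tmb = stats::rlnorm(n, spec$tmb_meanlog, spec$tmb_sdlog),
      response = response, response_months = round(months, 1),
      dialect = spec$dialect, stringsAsFactors = FALSE)
    truth <- data.frame(
      sample_id = ids, tcell_fraction = f, tox_log2 = u,
      p_nonresponse = p_non, responder = responder,
      stringsAsFactors = FALSE)
    list(expression = expr_matrix(vals, flavor = "linear_tpm"),
         clinical = validate_clinical(clinical), truth = truth)
  })
}

dialect_annotation <- function(responder, dialect, n) {
  switch(dialect,
    hugo = ifelse(responder,
                  sample(c("Partial Response", "Complete Response"), n,
                         replace = TRUE, prob = c(0.8, 0.2)),
                  "Progressive Disease"),
    jung = ifelse(responder, "DCB", "NDB"),
    riaz = {
      ann <- ifelse(responder,
                    sample(c("Partial Response", "Complete Response"), n,
                           replace = TRUE, prob = c(0.8, 0.2)),
                    "Progressive Disease")
      ann[stats::runif(n) < 0.15] <- "Stable Disease"
      ann
    },
    internal = ifelse(responder,
                      sample(c("PR", "SD"), n, replace = TRUE),
                      sample(c("PD", "SD"), n, replace = TRUE)))
}
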