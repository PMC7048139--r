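#' Pipeline configuration
#'
#' Collects every stage threshold in one structured list.  The
#' \code{"paper"} profile carries the published constants of the analysis
#' this package reproduces: QC gene-count floor 1700, housekeeping floor 3,
#' MAD multiplier 3, mitochondrial ceiling 10\%, TPM gates (CD3D/CD8A >= 3,
#' CD4 <= 30 for CD8 sorting), DEG threshold P < 0.001, mean-expression
#' floors 1 (log2 TPM flavor) and 2 (centered flavor), top-30\% score
#' stratification and top-25\% TMB pre-filter.
#'
#' @param profile currently only \code{"paper"}.
#' @param ... named overrides of individual fields.
#' @return a list of class \code{"exhaust_config"}.
#' @export
default_config <- function(profile = "paper", ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = 1L,
    qc = list(
      min_genes = 1700, min_hk = 3, mad_mult = 3, max_mito = 0.10,
      gate = list(cd3d_min = 3, cd8a_min = 3, cd4_max = 30,
                  cd4_min = 3, cd8a_max = 30)
    ),
    screen = list(
      marker = "PDCD1",
      p_threshold = 0.001,
      mean_floor = c(log2_tpm10 = 1, centered = 2),
      at_median = "low"
    ),
    dynamics = list(
      positivity_threshold = 0,
      markers = c(cd62l = "SELL", cd127 = "IL7R", pdcd1 = "PDCD1")
    ),
    clinical = list(
      target = "TOX",
      cd3_trio = c("CD3D", "CD3E", "CD3G"),
      pseudocount = 1,
      score_mode = "log_diff",
      top_fraction = 0.30,
      tmb_fraction = 0.25,
      abundance_floor_quantile = 0.25
    )
  )
  utils::modifyList(cfg, validate_overrides(list(...)), keep.null = TRUE) |>
    validate_config()
}

validate_overrides <- function(dots) {
  if (length(dots) && is.null(names(dots))) stop("overrides must be named")
  dots
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  # YAML maps come back as lists; normalize the named-vector fields
  cfg$screen$mean_floor <- unlist(cfg$screen$mean_floor)
  cfg$dynamics$markers <- unlist(cfg$dynamics$markers)
  cfg$clinical$cd3_trio <- unname(unlist(cfg$clinical$cd3_trio))
  fr <- c(cfg$clinical$top_fraction, cfg$clinical$tmb_fraction)
  if (any(fr <= 0 | fr >= 1)) stop("fractions must lie in (0,1)")
  num <- c(cfg$qc$min_genes, cfg$qc$min_hk, cfg$qc$mad_mult, cfg$qc$max_mito,
           cfg$screen$p_threshold, cfg$screen$mean_floor)
  if (any(!is.finite(num))) stop("thresholds must be finite")
  markers <- c(cfg$screen$marker, cfg$dynamics$markers,
               cfg$clinical$target, cfg$clinical$cd3_trio)
  if (any(!nzchar(markers))) stop("marker gene names must be non-empty")
  class(cfg) <- "exhaust_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return \code{read_config}: an \code{exhaust_config};
#'   \code{write_config}: the path, invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), raw, keep.null = TRUE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg an \code{exhaust_config}.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  # named atomic vectors serialize as YAML maps (names survive round-trip)
  out$screen$mean_floor <- as.list(cfg$screen$mean_floor)
  out$dynamics$markers <- as.list(cfg$dynamics$markers)
  yaml::write_yaml(out, path)
  invisible(path)
}
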