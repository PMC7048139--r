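#' Default gene panel for the synthetic T-cell generator
#'
#' Builds the per-gene program table the generator samples from.  Each gene
#' carries a baseline mean on the linear TPM scale, additive log2 modifiers
#' per cell state, and an exhaustion-coupling slope: the expected log2 mean
#' of a gene in a cell with latent exhaustion level \code{e} (0 = naive
#' effector, 1 = terminally exhausted) is
#' \deqn{log2(baseline) + mod_{state} + slope \cdot g(e)}
#' where \code{g(e) = e} for ordinary coupled genes and, for late-onset
#' genes (onset > 0), \code{g(e) = max(0, (e - onset)/(1 - onset))} so the
#' gene rises only past its onset.
#'
#' The panel encodes the biology the pipeline is screened against:
#' immune-checkpoint receptors (PDCD1, HAVCR2, CTLA4, TIGIT, LAG3) and the
#' transcription factor TOX rise monotonically with exhaustion;
#' TCF7/SELL/IL7R are memory-elevated; NR4A1 rises only late (onset 0.7);
#' NFATC1 is exhaustion-elevated while NFATC2 stays flat; CD3D/CD3E/CD3G
#' and CD8A mark the lineage; housekeeping and mitochondrial panels support
#' QC; anonymous null genes are state-independent for calibration.  Genes of
#' class \code{"planted"} (the EXH series plus the recoverable checkpoint
#' genes and TOX) define the ground-truth positives for screen-recovery
#' tests; class \code{"null"} defines the negatives.
#'
#' @param n_null number of state-independent null genes.
#' @param n_planted number of anonymous planted PDCD1-coupled genes.
#' @param n_housekeeping number of housekeeping genes.
#' @param planted_slope exhaustion-coupling slope (log2 units per unit
#'   exhaustion) of the planted genes.
#' @return a \code{data.frame} with columns \code{gene}, \code{class},
#'   \code{baseline}, \code{mod_effector}, \code{mod_memory},
#'   \code{mod_progenitor}, \code{mod_terminal}, \code{slope}, \code{onset}.
#' @export
default_gene_panel <- function(n_null = 200, n_planted = 30,
                               n_housekeeping = 30, planted_slope = 1.2) {
  row <- function(gene, class, baseline, eff = 0, mem = 0, prog = 0,
                  term = 0, slope = 0, onset = 0) {
    if (length(gene) == 0) return(NULL)
    data.frame(gene = gene, class = class, baseline = baseline,
               mod_effector = eff, mod_memory = mem, mod_progenitor = prog,
               mod_terminal = term, slope = slope, onset = onset,
               stringsAsFactors = FALSE)
  }
  named <- rbind(
    # split marker: low and zero-inflated at e = 0, strongly coupled
    row("PDCD1", "marker", 0.8, slope = 4.5),
    # recoverable checkpoint program + TOX (ground-truth positives)
    row("HAVCR2", "planted", 25, slope = 1.5),
    row("CTLA4", "planted", 20, slope = 1.5),
    row("TIGIT", "planted", 30, slope = 1.5),
    row("LAG3", "planted", 20, slope = 1.5),
    row("TOX", "planted", 25, slope = 1.5),
    # program genes with distinctive kinetics (not counted in recovery)
    row("TOX2", "program", 1.5, slope = 1.0),
    row("NR4A1", "program", 15, slope = 3.0, onset = 0.7),
    row("NFATC1", "program", 30, slope = 1.2),
    row("NFATC2", "program", 40, slope = 0),
    row("BATF", "program", 25, slope = 1.0),
    row("PRDM1", "program", 20, slope = 1.0),
    row("TCF7", "program", 15, mem = 2, prog = 1, slope = -1),
    # memory-state surface markers, near-silent elsewhere
    row("SELL", "program", 0.3, mem = 6.5),
    row("IL7R", "program", 0.3, mem = 6.5),
    # lineage markers (flat; drive the TPM gates)
    row("CD3D", "lineage", 150),
    row("CD3E", "lineage", 120),
    row("CD3G", "lineage", 100),
    row("CD8A", "lineage", 80),
    row("CD4", "lineage", 0.4)
  )
  planted <- row(sprintf("EXH%03d", seq_len(n_planted)), "planted",
                 30, slope = planted_slope)
  nulls <- row(sprintf("NULL%03d", seq_len(n_null)), "null",
               exp(seq(log(10), log(100), length.out = n_null)))
  hk <- row(sprintf("HK%02d", seq_len(n_housekeeping)), "housekeeping",
            exp(seq(log(100), log(1000), length.out = n_housekeeping)))
  mito_names <- paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5",
                                "ND6", "CO1", "CO2", "CO3", "ATP6", "ATP8",
                                "CYB"))
  mito <- row(mito_names, "mito", 55)
  panel <- rbind(named, planted, nulls, hk, mito)
  if (any(panel$baseline < 0)) stop("baseline means must be non-negative")
  rownames(panel) <- NULL
  panel
}

#' Expected linear-scale mean of a panel gene
#'
#' Closed-form expectation the generator draws around, exposed so tests can
#' audit monotonicity without sampling.
#'
#' @param panel a gene panel (see \code{\link{default_gene_panel}}).
#' @param gene gene identifier.
#' @param state one of \code{"effector"}, \code{"memory"},
#'   \code{"progenitor_exhausted"}, \code{"terminal_exhausted"}.
#' @param e latent exhaustion level in [0, 1].
#' @return expected mean on the linear TPM scale.
#' @export
expected_mean <- function(panel, gene, state, e) {
  i <- match(gene, panel$gene)
  if (is.na(i)) stop("gene '", gene, "' not in panel")
  mod <- switch(state,
                effector = panel$mod_effector[i],
                memory = panel$mod_memory[i],
                progenitor_exhausted = panel$mod_progenitor[i],
                terminal_exhausted = panel$mod_terminal[i],
                stop("unknown state '", state, "'"))
  onset <- panel$onset[i]
  g <- if (onset > 0) pmax(0, (e - onset) / (1 - onset)) else e
  panel$baseline[i] * 2^(mod + panel$slope[i] * g)
}

synthetic_states <- c("effector", "memory", "progenitor_exhausted",
                      "terminal_exhausted")

#' Simulate a single-cell T-cell dataset with a planted exhaustion program
#'
#' Cells are assigned a state, a trajectory branch (effector to exhausted,
#' or effector to memory), and a pseudotime drawn uniformly within
#' state-specific intervals (effector [0, 0.33], progenitor [0.33, 0.66],
#' terminal [0.66, 1]; memory [0.33, 1] on its own branch).  The latent
#' exhaustion level \code{e} equals pseudotime on the exhausted trajectory
#' and 0 for memory cells.  Counts are drawn from a negative binomial at the
#' panel's state/exhaustion-dependent means with mean-dependent dropout,
#' TPM-normalized per cell, and transformed to the requested flavor.  The
#' \code{"centered"} flavor subtracts each patient's grand-mean log offset
#' (patient-effect removal), mimicking patient-centered cohort data.
#'
#' An optional fraction of cells is generated as low-quality (shrunken
#' library, inflated mitochondrial load) with the true quality recorded, so
#' QC filters can be benchmarked against ground truth.
#'
#' @param panel gene panel, default \code{\link{default_gene_panel}()}.
#' @param n_cells number of cells.
#' @param state_proportions named numeric simplex over the four states.
#' @param flavor output normalization flavor.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param n_patients cells are assigned round-robin-free (random) to this
#'   many synthetic patients.
#' @param frac_low_quality fraction of cells generated as low-quality.
#' @param depth expected library size (reads) of a good cell.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param dropout_midpoint,dropout_slope logistic dropout on the log2 mean:
#'   a value with linear mean \code{mu} is zeroed with probability
#'   \code{plogis(-dropout_slope * (log2(mu + 1) - dropout_midpoint))}.
#' @param lib_sd log-normal sd of per-cell library size factors.
#' @return a list with \code{expression} (an \code{expr_matrix}),
#'   \code{annotation} (per-cell data.frame: cell_id, patient, state,
#'   branch, pseudotime, exhaustion, quality), and \code{gene_truth}
#'   (per-gene data.frame: gene, class).
#' @export
make_tcell_dataset <- function(panel = default_gene_panel(),
                               n_cells = 1000,
                               state_proportions = c(
                                 effector = 0.30, memory = 0.20,
                                 progenitor_exhausted = 0.25,
                                 terminal_exhausted = 0.25),
                               flavor = c("log2_tpm10", "centered",
                                          "linear_tpm", "counts"),
                               seed = 1L,
                               n_patients = 4,
                               frac_low_quality = 0,
                               depth = 2e4,
                               dispersion = 2,
                               dropout_midpoint = 1.5,
                               dropout_slope = 1.5,
                               lib_sd = 0.15) {
  flavor <- match.arg(flavor)
  if (length(state_proportions) != 4 ||
      !setequal(names(state_proportions), synthetic_states)) {
    stop("state_proportions must be named over the four states")
  }
  if (abs(sum(state_proportions) - 1) > 1e-9) {
    stop("state_proportions must sum to 1")
  }
  if (any(state_proportions < 0)) stop("state_proportions must be >= 0")
  with_seed(seed, {
    props <- state_proportions[synthetic_states]
    state <- sample(synthetic_states, n_cells, replace = TRUE, prob = props)
    pt_lo <- c(effector = 0, memory = 0.33, progenitor_exhausted = 0.33,
               terminal_exhausted = 0.66)
    pt_hi <- c(effector = 0.33, memory = 1, progenitor_exhausted = 0.66,
               terminal_exhausted = 1)
    pseudotime <- stats::runif(n_cells, pt_lo[state], pt_hi[state])
    branch <- ifelse(state == "memory", "memory",
              ifelse(state == "effector",
                     sample(c("exhausted", "memory"), n_cells,
                            replace = TRUE), "exhausted"))
    e <- ifelse(state == "memory", 0, pseudotime)
    patient <- paste0("P", sample.int(n_patients, n_cells, replace = TRUE))
    quality <- rep("ok", n_cells)
    if (frac_low_quality > 0) {
      quality[stats::runif(n_cells) < frac_low_quality] <- "low"
    }

    mods <- as.matrix(panel[, c("mod_effector", "mod_memory",
                                "mod_progenitor", "mod_terminal")])
    state_col <- match(state, synthetic_states)
    g <- outer(seq_len(nrow(panel)), seq_len(n_cells),
               function(i, j) {
                 on <- panel$onset[i]
                 ifelse(on > 0, pmax(0, (e[j] - on) / (1 - on)), e[j])
               })
    mu_tpm <- panel$baseline *
      2^(mods[, state_col, drop = FALSE] + panel$slope * g)

    # low-quality cells: collapsed library, quadrupled mitochondrial load
    lib <- exp(stats::rnorm(n_cells, 0, lib_sd))
    lib[quality == "low"] <- lib[quality == "low"] * 0.15
    is_mito <- panel$class == "mito"
    mu_tpm[is_mito, quality == "low"] <- mu_tpm[is_mito, quality == "low"] * 4

    s_total <- sum(panel$baseline)
    mu_counts <- sweep(mu_tpm, 2, depth * lib / s_total, `*`)
    counts <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                    size = dispersion),
                     nrow = nrow(panel))
    p_drop <- stats::plogis(-dropout_slope *
                              (log2(mu_tpm + 1) - dropout_midpoint))
    counts[matrix(stats::runif(length(counts)), nrow = nrow(counts)) <
             p_drop] <- 0
    rownames(counts) <- panel$gene
    colnames(counts) <- sprintf("C%05d", seq_len(n_cells))

    values <- transform_flavor(counts, flavor, s_total, patient)
    annotation <- data.frame(
      cell_id = colnames(counts), patient = patient, state = state,
      branch = branch, pseudotime = pseudotime, exhaustion = e,
      quality = quality, stringsAsFactors = FALSE)
    gene_truth <- data.frame(gene = panel$gene, class = panel$class,
                             stringsAsFactors = FALSE)
    list(expression = expr_matrix(values, flavor = flavor),
         annotation = annotation, gene_truth = gene_truth)
  })
}

transform_flavor <- function(counts, flavor, s_total, patient) {
  if (flavor == "counts") return(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  tpm <- sweep(counts, 2, s_total / tot, `*`)
  if (flavor == "linear_tpm") return(tpm)
  lg <- log2(tpm / 10 + 1)
  if (flavor == "log2_tpm10") return(lg)
  # centered: remove the patient-level grand-mean offset on the log scale
  grand <- mean(lg)
  for (p in unique(patient)) {
    sel <- patient == p
    lg[, sel] <- lg[, sel] - (mean(lg[, sel]) - grand)
  }
  lg
}

#' Null-only panel for calibration datasets
#'
#' A panel containing only the split marker (with its usual exhaustion
#' coupling, so a median split is possible) and state-independent null
#' genes.  Running the DEG screen on such a dataset probes the calibration
#' of the rank-sum P values: every null gene satisfies the null hypothesis.
#'
#' @param n_null number of null genes.
#' @return a gene panel \code{data.frame}.
#' @export
null_gene_panel <- function(n_null = 2000) {
  full <- default_gene_panel(n_null = n_null)
  full[full$class %in% c("marker", "null"), , drop = FALSE]
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
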