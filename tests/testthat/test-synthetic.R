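test_that("generation is deterministic in the seed", {
  a <- make_tcell_dataset(n_cells = 150, seed = 77)
  b <- make_tcell_dataset(n_cells = 150, seed = 77)
  c <- make_tcell_dataset(n_cells = 150, seed = 78)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$annotation, b$annotation)
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("state proportions and pseudotime intervals are honored", {
  ds <- make_tcell_dataset(
    n_cells = 300, seed = 3,
    state_proportions = c(effector = 1, memory = 0,
                          progenitor_exhausted = 0,
                          terminal_exhausted = 0))
  expect_true(all(ds$annotation$state == "effector"))
  expect_true(all(ds$annotation$pseudotime <= 0.33))
  expect_error(make_tcell_dataset(
    n_cells = 10, state_proportions = c(effector = 0.5, memory = 0.2,
                                        progenitor_exhausted = 0.2,
                                        terminal_exhausted = 0.2)),
    "sum to 1")
  # pseudotime is monotone with state severity on the exhausted branch
  ds2 <- make_tcell_dataset(n_cells = 400, seed = 4)
  ann <- ds2$annotation
  expect_lt(max(ann$pseudotime[ann$state == "effector"]),
            min(ann$pseudotime[ann$state == "terminal_exhausted"]))
})

test_that("sample means track panel expectations in the noise-free limit", {
  # no coupling, no state effects, tiny dispersion handled by large n
  panel <- default_gene_panel(n_null = 25, n_planted = 0)
  panel$slope <- 0
  panel[, c("mod_effector", "mod_memory", "mod_progenitor",
            "mod_terminal")] <- 0
  ds <- make_tcell_dataset(panel = panel, n_cells = 4000,
                           flavor = "linear_tpm", seed = 6,
                           dispersion = 1e4, dropout_midpoint = -100,
                           lib_sd = 0)
  sample_mean <- rowMeans(ds$expression$values)
  expected <- panel$baseline
  # TPM renormalization preserves relative composition; compare ratios
  rel_err <- abs(sample_mean / expected - 1)
  expect_lt(stats::median(rel_err), 0.02)
  expect_lt(max(rel_err[expected > 5]), 0.05)
})

test_that("planted expression programs behave as designed", {
  panel <- default_gene_panel()
  ic <- c("PDCD1", "HAVCR2", "CTLA4", "TIGIT", "LAG3", "TOX")
  for (g in ic) {
    expect_gt(expected_mean(panel, g, "terminal_exhausted", 0.9),
              expected_mean(panel, g, "terminal_exhausted", 0.1))
  }
  # TCF7 higher in memory than effector
  expect_gt(expected_mean(panel, "TCF7", "memory", 0),
            expected_mean(panel, "TCF7", "effector", 0))
  # NR4A1 flat before its 0.7 onset, rising after
  expect_equal(expected_mean(panel, "NR4A1", "terminal_exhausted", 0.3),
               expected_mean(panel, "NR4A1", "terminal_exhausted", 0.69))
  expect_gt(expected_mean(panel, "NR4A1", "terminal_exhausted", 0.95),
            expected_mean(panel, "NR4A1", "terminal_exhausted", 0.7))
  # NFATC2 constant in exhaustion; null genes state-independent
  expect_equal(expected_mean(panel, "NFATC2", "terminal_exhausted", 0.9),
               expected_mean(panel, "NFATC2", "effector", 0.1))
  expect_equal(expected_mean(panel, "NULL001", "memory", 0),
               expected_mean(panel, "NULL001", "terminal_exhausted", 1))
  # planted and null sets are disjoint
  expect_length(intersect(panel$gene[panel$class == "planted"],
                          panel$gene[panel$class == "null"]), 0)
})

test_that("bulk cohorts are deterministic and encode the planted effects", {
  a <- make_bulk_cohort(cohort_spec(n_patients = 120, seed = 5))
  b <- make_bulk_cohort(cohort_spec(n_patients = 120, seed = 5))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)

  # censoring rate 0: every subject has an observed event
  no_cens <- make_bulk_cohort(cohort_spec(n_patients = 80,
                                          censoring_rate = 0, seed = 2))
  expect_true(all(no_cens$clinical$event == 1))

  # null cohort: truth score uncorrelated with outcomes
  null_co <- make_bulk_cohort(cohort_spec(
    n_patients = 1000, hazard_ratio = 1, response_slope = 0.001, seed = 8))
  expect_lt(abs(cor(null_co$truth$tox_log2, null_co$clinical$time)), 0.1)
  expect_lt(abs(cor(null_co$truth$tox_log2,
                    as.numeric(null_co$truth$responder))), 0.1)

  # score recovered from bulk expression tracks the planted level
  co <- make_bulk_cohort(cohort_spec(n_patients = 250, seed = 11))
  sc <- tcell_normalized_score(co$expression)
  expect_gt(cor(sc$score, co$truth$tox_log2), 0.85)
})

test_that("cohort spec validates its rates", {
  expect_error(cohort_spec(hazard_ratio = 0), "hazard_ratio")
  expect_error(cohort_spec(censoring_rate = 1), "censoring_rate")
})
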