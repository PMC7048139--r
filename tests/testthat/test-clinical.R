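test_that("T-cell-normalized score matches exact arithmetic", {
  lin <- rbind(TOX = c(8, 4, 16), CD3D = c(2, 4, 4), CD3E = c(4, 4, 8),
               CD3G = c(8, 4, 16))
  m <- toy_matrix(lin, rownames(lin), flavor = "linear_tpm")
  sc <- tcell_normalized_score(m, pseudocount = 0)
  # geometric means 4, 4, 8 -> scores log2(8/4), log2(4/4), log2(16/8)
  expect_equal(sc$score, c(1, 0, 1))
  expect_equal(sc$cd3_geomean, c(4, 4, 8))
  # scaling all four genes by a constant leaves the score unchanged
  m2 <- toy_matrix(lin * 7, rownames(lin), flavor = "linear_tpm")
  expect_equal(tcell_normalized_score(m2, pseudocount = 0)$score, sc$score)
  # linear-ratio mode returns 2^score
  expect_equal(tcell_normalized_score(m, pseudocount = 0,
                                      mode = "linear_ratio")$score,
               2^sc$score)
  # all-zero CD3 flags low_tcell but still scores (with pseudocount)
  lin0 <- rbind(TOX = 5, CD3D = 0, CD3E = 0, CD3G = 0)
  m0 <- toy_matrix(lin0, rownames(lin0), flavor = "linear_tpm")
  sc0 <- tcell_normalized_score(m0)
  expect_true(sc0$low_tcell)
  expect_equal(sc0$score, log2(6))
  expect_error(tcell_normalized_score(
    toy_matrix(lin, rownames(lin), flavor = "log2_tpm10")), "linear")
})

test_that("abundance estimate is the CD3 geometric mean", {
  lin <- rbind(CD3D = c(1, 2), CD3E = c(1, 4), CD3G = c(1, 8))
  m <- toy_matrix(lin, rownames(lin), flavor = "linear_tpm")
  ab <- estimate_t_cell_abundance(m, pseudocount = 0)
  expect_equal(unname(ab), c(1, 4))
  chk <- check_cohort_abundance(c(1, 2, 3), floor = 2.5)
  expect_true(chk$warn)
  expect_false(check_cohort_abundance(c(3, 4, 5), floor = 2.5)$warn)
})

test_that("top-fraction stratification counts and tie policy", {
  s <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  lab <- stratify_top_fraction(s, 0.3)
  expect_equal(sum(lab == "high"), 3)
  expect_equal(which(lab == "high"), 1:3)
  expect_equal(sum(stratify_top_fraction(s, 0.5) == "high"), 5)
  # all tied: first ceil(0.3 n) in stable order, with a warning
  expect_warning(lab_t <- stratify_top_fraction(rep(1, 10), 0.3), "ties")
  expect_equal(which(lab_t == "high"), 1:3)
  expect_error(stratify_top_fraction(1:3), "4 samples")
})

test_that("TMB filter keeps the top fraction with stable ties", {
  clin <- data.frame(sample_id = paste0("S", 1:8), time = 1, event = 1,
                     tmb = c(5, 9, 1, 9, 2, 3, 8, 4))
  kept <- filter_top_tmb(clin, 0.25)
  expect_equal(kept$sample_id, c("S2", "S4"))  # two highest, stable order
  expect_equal(filter_top_tmb(clin, 1)$sample_id, clin$sample_id)
  expect_error(filter_top_tmb(clin[, -4], 0.25), "tmb")
})

test_that("Kaplan-Meier steps match hand computation", {
  km <- km_estimate(c(1, 2), c(1, 0))
  expect_equal(km$survival[km$time == 1], 0.5)
  expect_equal(km$survival[km$time == 2], 0.5)  # censoring: no drop
  km2 <- km_estimate(1:4, rep(1, 4))
  expect_equal(km2$survival, c(0.75, 0.5, 0.25, 0))
  km3 <- km_estimate(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
})

test_that("log-rank matches the hand-computed O/E/V table", {
  # A = {1, 2} both events, B = {3, 4} both events:
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  # chisq = (7/6)^2 / (17/36) = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-6)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # label swap leaves the statistic unchanged
  lr2 <- logrank_test(c(1, 2, 3, 4), rep(1, 4), c("B", "B", "A", "A"))
  expect_equal(lr2$chisq, lr$chisq)
  expect_error(logrank_test(1:4, rep(0, 4), c("A", "A", "B", "B")),
               "no events")
  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)), "2 groups")
})

test_that("log-rank null rejection rate is near nominal", {
  set.seed(55)
  n <- 60
  rejections <- replicate(400, {
    tt <- rexp(n, 0.1)
    ev <- rbinom(n, 1, 0.8)
    g <- sample(rep(c("A", "B"), n / 2))
    logrank_test(tt, ev, g)$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.025)
})

test_that("responder dialects map annotations per cohort rules", {
  clin <- data.frame(
    sample_id = paste0("S", 1:6), time = 1, event = 1,
    response = c("Complete Response", "Partial Response",
                 "Progressive Disease", "Stable Disease", "SD", "PD"),
    response_months = c(NA, NA, NA, 3, 7, NA),
    stringsAsFactors = FALSE)
  hugo <- classify_response(clin[1:3, ], "hugo")
  expect_equal(hugo$label,
               c("responder", "responder", "non_responder"))
  riaz <- classify_response(clin[1:4, ], "riaz")
  expect_equal(riaz$label[4], "excluded")
  internal <- classify_response(clin[3:6, ], "internal")
  # PD, SD 3mo, SD 7mo, PD
  expect_equal(internal$label,
               c("non_responder", "non_responder", "responder",
                 "non_responder"))
  jung <- classify_response(
    data.frame(sample_id = c("J1", "J2"), time = 1, event = 1,
               response = c("DCB", "NDB")), "jung")
  expect_equal(jung$label, c("responder", "non_responder"))
  expect_error(classify_response(
    data.frame(sample_id = "X", time = 1, event = 1,
               response = "Mixed Response"), "hugo"), "Mixed Response")
  # internal SD without a duration is an error
  bad <- clin[4, ]; bad$response_months <- NA
  expect_error(classify_response(bad, "internal"), "response_months")
})

test_that("response association: Mann-Whitney, AUROC and pair oracle", {
  # perfect separation, lower score = responder
  scores <- c(-1, -2, 1, 2, 3)
  labels <- c("responder", "responder", rep("non_responder", 3))
  res <- response_association(scores, labels)
  expect_equal(res$auroc, 1)
  # all tied
  expect_equal(response_association(rep(1, 5), labels)$auroc, 0.5)
  # excluded samples appear nowhere
  res_ex <- response_association(c(scores, -99),
                                 c(labels, "excluded"))
  expect_equal(res_ex$auroc, 1)
  expect_equal(res_ex$n_responder + res_ex$n_nonresponder, 5)
  expect_error(response_association(1:3, rep("responder", 3)), "at least")

  # AUROC equals pair counting on random instances, and equals U/(n1 n2)
  set.seed(66)
  for (rep in 1:200) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    s <- sample(seq(0, 3, 0.5), n1 + n2, replace = TRUE)
    lab <- c(rep("responder", n1), rep("non_responder", n2))
    got <- response_association(s, lab)$auroc
    want <- auroc_pair_oracle(-s[seq_len(n1)], -s[n1 + seq_len(n2)])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  s <- rnorm(60)
  lab <- ifelse(runif(60) < plogis(-1.2 * s), "responder",
                "non_responder")
  if (length(unique(lab)) < 2) skip("degenerate draw")
  got <- response_association(s, lab)$auroc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = lab == "responder", predictor = -s, quiet = TRUE,
    direction = "<")))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("waterfall values are median-centered per cohort", {
  s <- c(5, 1, 3, 10, 20, 30)
  coh <- c("a", "a", "a", "b", "b", "b")
  w <- waterfall_values(s, coh)
  expect_equal(as.numeric(tapply(w, coh, median)), c(0, 0))
  expect_equal(w[1:3], s[1:3] - 3)
})
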