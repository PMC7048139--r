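test_that("marker rules classify single cells correctly", {
  # rows: SELL (CD62L), IL7R (CD127), PDCD1; one cell per scenario
  vals <- cbind(c(0, 0, 2),   # PDCD1+ only -> exhausted
                c(0, 3, 2),   # PDCD1+ and CD127+ -> ambiguous
                c(0, 0, 0),   # all negative -> effector
                c(4, 0, 0),   # CD62L+ -> memory
                c(0, 5, 0))   # CD127+ -> memory
  rownames(vals) <- c("SELL", "IL7R", "PDCD1")
  m <- toy_matrix(vals, rownames(vals))
  st <- call_state(m)
  expect_equal(as.character(st$state),
               c("exhausted", "ambiguous", "effector", "memory", "memory"))
  m_miss <- toy_matrix(vals[1:2, , drop = FALSE], c("SELL", "IL7R"))
  expect_error(call_state(m_miss), "PDCD1")
})

test_that("an indeterminate band makes unknown reachable", {
  vals <- cbind(c(0, 0, 0.5))  # PDCD1 inside the band, others negative
  rownames(vals) <- c("SELL", "IL7R", "PDCD1")
  m <- toy_matrix(vals, rownames(vals))
  st <- call_state(m, indeterminate_band = c(0.1, 1))
  expect_equal(as.character(st$state), "unknown")
  # without the band every cell matches at least one rule
  st0 <- call_state(m)
  expect_false(any(st0$state == "unknown"))
})

test_that("state calls are column-permutation invariant", {
  ds <- make_tcell_dataset(n_cells = 200, seed = 12)
  st <- call_state(ds$expression)
  perm <- rev(seq_len(200))
  st_perm <- call_state(subset_cols(ds$expression, perm))
  expect_equal(as.character(st_perm$state),
               as.character(st$state)[perm])
})

test_that("binomial branch enrichment equals direct tail summation", {
  # k=n=5 at p0=0.5: tail is 0.5^5
  states <- c(rep("exhausted", 5), rep("effector", 5))
  branches <- c(rep("A", 5), rep("B", 5))
  enr <- branch_enrichment(states, branches)
  row_a <- enr[enr$branch == "A" & enr$state == "exhausted", ]
  expect_equal(row_a$p, 0.03125)
  # k=0: upper tail is total mass
  row_b <- enr[enr$branch == "B" & enr$state == "exhausted", ]
  expect_equal(row_b$p, 1)

  # property: matches the summation oracle across random instances
  set.seed(21)
  for (rep in 1:50) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    st <- sample(c("effector", "exhausted", "memory"), n1 + n2,
                 replace = TRUE)
    br <- c(rep("A", n1), rep("B", n2))
    got <- branch_enrichment(st, br)
    for (i in seq_len(nrow(got))) {
      if (is.na(got$p[i])) next
      expect_equal(got$p[i],
                   binom_tail_oracle(got$k[i], got$n[i], got$p0[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment P agrees with a Monte-Carlo label-shuffle null", {
  # small branch inside a large pool, where the with-replacement binomial
  # model is a faithful approximation of the label shuffle
  set.seed(33)
  st <- sample(c(rep("exhausted", 80), rep("effector", 120)))
  br <- c(rep("A", 15), rep("B", 185))
  enr <- branch_enrichment(st, br)
  row <- enr[enr$branch == "A" & enr$state == "exhausted", ]
  nmc <- 4000
  ge <- replicate(nmc, {
    shuffled <- sample(st)
    sum(shuffled[br == "A"] == "exhausted") >= row$k
  })
  mc_p <- mean(ge)
  se <- sqrt(mc_p * (1 - mc_p) / nmc)
  expect_lt(abs(row$p - mc_p), max(3 * se, 0.02))
})

test_that("dynamics test detects planted upregulation one-tailed", {
  # complete separation 5 vs 5 gives the enumeration minimum 1/252
  vals <- matrix(c(6:10, 1:5), nrow = 1)
  m <- toy_matrix(vals, "TOX")
  groups <- c(rep("exhausted", 5), rep("effector", 5))
  res <- dynamics_test(m, groups, "TOX", target = "exhausted")
  expect_equal(res$p_value, 1 / 252)
  expect_error(dynamics_test(m, rep("memory", 10), "TOX"), "empty")

  ds <- make_tcell_dataset(n_cells = 900, seed = 14)
  groups <- ifelse(ds$annotation$state == "effector", "effector",
                   ifelse(ds$annotation$branch == "exhausted",
                          "exhausted", "memory"))
  p_tox <- dynamics_test(ds$expression, groups, "TOX")$p_value
  p_nfatc2 <- dynamics_test(ds$expression, groups, "NFATC2")$p_value
  p_tcf7_mem <- dynamics_test(ds$expression, groups, "TCF7",
                              target = "memory")$p_value
  expect_lt(p_tox, 0.001)
  expect_gt(p_nfatc2, 0.05)
  expect_lt(p_tcf7_mem, 0.001)
})

test_that("kernel trend is order-invariant and tracks the signal", {
  set.seed(9)
  pt <- runif(200)
  # constant expression -> constant curve
  tr_const <- fit_expression_trend(pt, rep(2.5, 200), bandwidth = 0.1)
  expect_true(all(abs(tr_const$fitted - 2.5) < 1e-12))
  # identity signal, small bandwidth: curve close to identity inside
  tr_id <- fit_expression_trend(pt, pt, bandwidth = 0.02)
  interior <- tr_id$pseudotime > 0.1 & tr_id$pseudotime < 0.9
  expect_lt(max(abs(tr_id$fitted[interior] - tr_id$pseudotime[interior])),
            0.05)
  # permuting cells leaves the curve unchanged
  perm <- sample(200)
  tr_perm <- fit_expression_trend(pt[perm], pt[perm], bandwidth = 0.02)
  expect_equal(tr_perm$fitted, tr_id$fitted)
  expect_error(fit_expression_trend(pt, pt, bandwidth = 0), "bandwidth")
  expect_error(fit_expression_trend(pt[1:5], pt[1:5]), "10 cells")
})
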