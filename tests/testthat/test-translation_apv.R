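test_that("fit_gene_apv on noiseless constructions", {
  cond <- rep(c("a", "b"), each = 4)
  C <- c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5)
  # pure propagation: P = 2 + 1 * C, no condition effect
  f <- fit_gene_apv(2 + C, C, cond)
  expect_equal(f$slope, 1, tolerance = 1e-10)
  expect_equal(f$ss_effect, 0, tolerance = 1e-10)
  expect_equal(f$deltaPT, 0, tolerance = 1e-10)
  expect_equal(f$m, 8L - 3L)
  # planted intercept shift with C balanced across conditions
  C2 <- rep(c(1, 2, 3, 4), 2)
  delta <- 0.7
  f2 <- fit_gene_apv(C2 + delta * (cond == "b"), C2, cond)
  expect_equal(unname(diff(f2$adjusted_means)), delta, tolerance = 1e-10)
  expect_equal(f2$deltaPT, delta, tolerance = 1e-10)
  expect_error(fit_gene_apv(1:4, 1:4, c("a", "a", "a", "b")),
               class = "polytran_bad_contrast")
})

test_that("fit_gene_apv equals the normal-equations oracle", {
  set.seed(10)
  cond <- rep(c("a", "b"), each = 4)
  for (i in 1:25) {
    C <- rnorm(8, 7); P <- 0.5 + 1.2 * C + rnorm(8, 0, 0.4) +
      0.8 * (cond == "b")
    f <- fit_gene_apv(P, C, cond)
    o <- oracle_ancova(P, C, cond)
    expect_equal(f$slope, o$slope, tolerance = 1e-8)
    expect_equal(f$slope_se, o$slope_se, tolerance = 1e-8)
    expect_equal(f$s_sq, o$s_sq, tolerance = 1e-8)
    expect_equal(f$ss_effect, o$ss_effect, tolerance = 1e-8)
  }
})

test_that("slope filter only rejects significant boundary violations", {
  s <- analysis_settings()
  mk <- function(slope, se, m = 5L)
    structure(list(ok = TRUE, slope = slope, slope_se = se, m = m),
              class = "gene_apv_fit")
  expect_false(slope_filter(mk(0.5, 0.1), s))
  expect_true(slope_filter(mk(3, 1e-6), s))
  expect_true(slope_filter(mk(3, 0), s))     # zero SE, outside: deterministic
  # beta = 2.1 with large SE: p = P(T_5 > (2.1-2)/0.5) ~ 0.42 >> 0.01
  f <- mk(2.1, 0.5)
  expect_false(slope_filter(f, s))
  p_oracle <- pt((2.1 - 2) / 0.5, 5, lower.tail = FALSE)
  expect_true(p_oracle >= s$slopeP)
  # below minSlope, significant
  expect_true(slope_filter(mk(-2, 0.05), s))
})

test_that("bh_adjust matches textbook arithmetic and the reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(12)
  p <- runif(1000)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  p2 <- c(0.2, NA, 0.001)
  expect_equal(bh_adjust(p2), p.adjust(p2, "BH"), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "polytran_bad_pvalues")
})

test_that("translation analysis is equivariant and direction-consistent", {
  sim <- generate_experiment(list(gene_class_spec("NULL", 80),
                                  gene_class_spec("TOP_REPRESSED", 20,
                                                  delta_translation = -1.5)),
                             conditions = c("IFN", "IFN+Torin1"), seed = 14L)
  tr <- run_translation_analysis(sim$experiment, c("IFN", "IFN+Torin1"))
  # shifting all cytosolic values of a gene leaves slope/F/p/deltaPT alone
  e2 <- sim$experiment
  cyto_cols <- e2$design$sample_id[e2$design$fraction == "cytosolic"]
  e2$exprs["g00001", cyto_cols] <- e2$exprs["g00001", cyto_cols] + 5
  tr2 <- run_translation_analysis(e2, c("IFN", "IFN+Torin1"))
  for (col in c("slope", "F_mod", "p", "deltaPT"))
    expect_equal(tr2[tr2$gene_id == "g00001", col][[1]],
                 tr[tr$gene_id == "g00001", col][[1]], tolerance = 1e-8)
  # swapping the contrast negates the deltas and preserves p
  tr_sw <- run_translation_analysis(sim$experiment, c("IFN+Torin1", "IFN"))
  m1 <- tr[order(tr$gene_id), ]; m2 <- tr_sw[order(tr_sw$gene_id), ]
  expect_equal(m2$deltaP, -m1$deltaP, tolerance = 1e-10)
  expect_equal(m2$deltaC, -m1$deltaC, tolerance = 1e-10)
  expect_equal(m2$deltaPT, -m1$deltaPT, tolerance = 1e-10)
  expect_equal(m2$p, m1$p, tolerance = 1e-10)
})

test_that("deltaPT shift invariance holds exactly for cytosolic-only shifts", {
  # adding a constant to C changes deltaC and deltaP-adjusted intercepts but
  # deltaPT changes by -constant; verify the documented algebra instead of
  # accidental invariance
  cond <- rep(c("a", "b"), each = 4)
  set.seed(15)
  C <- rnorm(8, 7); P <- C + rnorm(8, 0, 0.1)
  f1 <- fit_gene_apv(P, C, cond)
  f2 <- fit_gene_apv(P, C + 2, cond)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$ss_effect, f1$ss_effect, tolerance = 1e-10)
  expect_equal(f2$deltaPT, f1$deltaPT, tolerance = 1e-10)
})

test_that("identical conditions yield no significant genes", {
  set.seed(16)
  d <- toy_design(c("x", "y"), 3L)
  # same values duplicated across the two conditions, epsilon-broken
  m <- matrix(0, 60, nrow(d), dimnames = list(sprintf("g%02d", 1:60), d$sample_id))
  vals <- matrix(rnorm(60 * 6, 8, 0.5), 60, 6)
  m[, d$sample_id[d$condition == "x"]] <- vals
  m[, d$sample_id[d$condition == "y"]] <- vals + rnorm(60 * 6, 0, 1e-6)
  exp <- polysome_experiment(m, d)
  tr <- run_translation_analysis(exp, c("x", "y"))
  expect_equal(sum(tr$significant), 0L)
})

test_that("rank-deficient genes are flagged and excluded, not fatal", {
  sim <- generate_experiment(list(gene_class_spec("NULL", 60)),
                             conditions = c("a", "b"), seed = 17L)
  e <- sim$experiment
  cyto <- e$design$sample_id[e$design$fraction == "cytosolic"]
  e$exprs["g00001", cyto] <- 7  # constant covariate
  expect_message(tr <- run_translation_analysis(e, c("a", "b")),
                 regexp = "rank-deficient")
  row <- tr[tr$gene_id == "g00001", ]
  expect_false(row$apv_ok)
  expect_true(is.na(row$p))
  expect_false(row$significant)
  expect_equal(attr(tr, "n_excluded"), 1L)
})

test_that("with RVM disabled the pipeline equals classical ANCOVA", {
  sim <- generate_experiment(list(gene_class_spec("NULL", 60)),
                             conditions = c("a", "b"), seed = 18L)
  tr <- run_translation_analysis(sim$experiment, c("a", "b"), rvm = FALSE)
  pc <- polytran:::paired_fraction_values(sim$experiment, c("a", "b"))
  for (g in c("g00003", "g00042")) {
    o <- oracle_ancova(pc$P[g, ], pc$C[g, ], pc$condition)
    expect_equal(tr$F_mod[tr$gene_id == g], o$F, tolerance = 1e-8)
    expect_equal(tr$p[tr$gene_id == g], o$p, tolerance = 1e-8)
  }
})
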