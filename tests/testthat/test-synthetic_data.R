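test_that("generated experiment has the design-implied dimensions", {
  sim <- generate_experiment(list(gene_class_spec("NULL", 960),
                                  gene_class_spec("ISG", 40, delta_cytosolic = 1)),
                             conditions = c("IFN", "IFN+Torin1"),
                             n_replicates = 4L, seed = 7L)
  expect_identical(dim(sim$experiment$exprs), c(1000L, 16L))
  expect_identical(nrow(sim$truth), 1000L)
  expect_identical(nrow(sim$experiment$design), 16L)
  expect_error(generate_experiment(list(gene_class_spec("NULL", 0)), seed = 1),
               class = "polytran_bad_config")
  expect_error(generate_experiment(list(gene_class_spec("NULL", 10)),
                                   n_replicates = 1L, seed = 1),
               class = "polytran_bad_config")
  expect_error(noise_spec(var_shape = 0.5), class = "polytran_bad_config")
})

test_that("noiseless generator reduces to polysomal = slope * cytosolic", {
  sim <- generate_experiment(list(gene_class_spec("NULL", 20)),
                             noise = noise_spec(var_scale = 0),
                             conditions = c("A", "B"), n_replicates = 2L,
                             seed = 3L)
  d <- sim$experiment$design
  cyto <- sim$experiment$exprs[, d$sample_id[d$fraction == "cytosolic"]]
  poly <- sim$experiment$exprs[, d$sample_id[d$fraction == "polysomal"]]
  expect_equal(unname(poly), unname(cyto), tolerance = 0)
})

test_that("planted translational effect is recovered by raw contrasts", {
  n_top <- 400L
  sim <- generate_experiment(
    list(gene_class_spec("TOP_REPRESSED", n_top, delta_translation = -1.5)),
    conditions = c("IFN", "IFN+Torin1"), n_replicates = 4L, seed = 11L)
  d <- sim$experiment$design
  mean_of <- function(fraction, condition)
    rowMeans(sim$experiment$exprs[, d$sample_id[d$fraction == fraction &
                                                  d$condition == condition]])
  dPT <- (mean_of("polysomal", "IFN+Torin1") - mean_of("polysomal", "IFN")) -
    (mean_of("cytosolic", "IFN+Torin1") - mean_of("cytosolic", "IFN"))
  se <- sd(dPT) / sqrt(n_top)
  expect_lt(abs(mean(dPT) - (-1.5)), 3 * se)
})

test_that("generation is deterministic under a fixed seed", {
  cls <- list(gene_class_spec("NULL", 50),
              gene_class_spec("TOP_REPRESSED", 10, delta_translation = -1))
  a <- generate_experiment(cls, seed = 9L)
  b <- generate_experiment(cls, seed = 9L)
  expect_identical(a$experiment$exprs, b$experiment$exprs)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_tss_fasta(generate_tss_sequences(a$truth, seed = 4L), f1)
  write_tss_fasta(generate_tss_sequences(b$truth, seed = 4L), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("emitted TSS sequences classify as their planted class", {
  sim <- generate_experiment(list(
    gene_class_spec("TOP_REPRESSED", 30, delta_translation = -1),
    gene_class_spec("ISG_TOP_SWITCH", 4, delta_cytosolic = 1),
    gene_class_spec("NULL", 30)), seed = 6L)
  rec <- generate_tss_sequences(sim$truth, seed = 6L)
  cls <- classify_fasta(rec)
  plain <- is.na(cls$condition)
  expect_identical(cls$class[plain],
                   sim$truth$motif_class[match(cls$gene_id[plain],
                                               sim$truth$gene_id)])
  # switch genes: non-TOP under control, TOP-like under IFN
  sw <- sim$truth$gene_id[sim$truth$class == "ISG_TOP_SWITCH"]
  for (g in sw) {
    expect_identical(cls$class[cls$gene_id == g & cls$condition == "control"],
                     "NON_TOP")
    expect_identical(cls$class[cls$gene_id == g & cls$condition == "IFN"],
                     "TOP_LIKE")
  }
})

test_that("yield summary: identical yields give 0% change, p near 1", {
  y <- expand.grid(condition = c("control", "Torin1"), replicate = 1:3,
                   fraction = c("cytosolic", "polysomal"),
                   stringsAsFactors = FALSE)
  y$ng <- rep(c(1000, 1000.0005, 999.9995), each = 2, times = 2)
  s <- polysome_yield_summary(y)
  expect_equal(s$pct_change, rep(0, 4), tolerance = 1e-6)
  expect_true(all(s$p_vs_control[!is.na(s$p_vs_control)] > 0.5))
})

test_that("Torin1-scaled polysomal yields show a 40-45% reduction", {
  y <- simulate_polysome_yields(conditions = c("control", "IFN+Torin1"),
                                n_replicates = 50L, seed = 21L)
  s <- polysome_yield_summary(y)
  red <- -s$pct_change[s$condition == "IFN+Torin1" & s$fraction == "polysomal"]
  expect_gt(red, 40); expect_lt(red, 45)
  expect_lt(s$p_vs_control[s$condition == "IFN+Torin1" &
                             s$fraction == "polysomal"], 0.05)
})

test_that("yield Welch p matches the closed-form oracle; 1 replicate errors", {
  set.seed(8)
  y <- simulate_polysome_yields(conditions = c("control", "Torin1"),
                                n_replicates = 7L, seed = 8L)
  s <- polysome_yield_summary(y)
  for (fr in c("cytosolic", "polysomal")) {
    x <- y$ng[y$condition == "Torin1" & y$fraction == fr]
    ref <- y$ng[y$condition == "control" & y$fraction == fr]
    expect_equal(s$p_vs_control[s$condition == "Torin1" & s$fraction == fr],
                 oracle_welch_t(x, ref)$p, tolerance = 1e-10)
  }
  expect_error(polysome_yield_summary(y[y$replicate == 1, ]),
               class = "polytran_bad_config")
})

test_that("residual variances follow the scaled-F law the RVM assumes", {
  # null genes, InvGamma(shape 3, scale 0.5) variances => precision
  # Gamma(shape a = 3, rate 0.5), RVM scale b = 2, so a*b*s^2 ~ F(m, 2a)
  sim <- generate_experiment(list(gene_class_spec("NULL", 5000)),
                             conditions = c("IFN", "IFN+Torin1"), seed = 11L)
  tr <- run_translation_analysis(sim$experiment, c("IFN", "IFN+Torin1"),
                                 rvm = FALSE)
  u <- pf(3 * 2 * tr$s_sq, unique(tr$m), 2 * 3)
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})
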