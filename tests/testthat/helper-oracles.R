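# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: regex rules for motifs, explicit normal-equation
# solves for the ANCOVA, enumeration sums for the hypergeometric tail, and
# closed-form t formulas.

# Motif oracle: TOP = leading C whose maximal following pyrimidine run has
# length in [top_min, top_max] (regex backtracking enforces maximality);
# TOP-like = a maximal pyrimidine run of >= min_run starting at position
# <= max_start (run start is position 1 or preceded by a non-pyrimidine).
oracle_classify <- function(seq, min_run = 5, max_start = 4,
                            top_min = 5, top_max = 15) {
  s <- chartr("U", "T", toupper(seq))
  top_re <- sprintf("^C[CT]{%d,%d}([AGN]|$)", top_min, top_max)
  if (grepl(top_re, s)) return("TOP")
  like <- grepl(sprintf("^[CT]{%d}", min_run), s) ||
    grepl(sprintf("^.{0,%d}[AGN][CT]{%d}", max_start - 2, min_run), s)
  if (like) "TOP_LIKE" else "NON_TOP"
}

# ANCOVA oracle: explicit design matrix, normal equations via solve().
oracle_ancova <- function(P, C, cond) {
  cond <- factor(cond)
  k <- nlevels(cond)
  X <- cbind(sapply(levels(cond), function(l) as.numeric(cond == l)), C)
  bhat <- solve(t(X) %*% X, t(X) %*% P)
  rss_full <- sum((P - X %*% bhat)^2)
  Xr <- cbind(1, C)
  br <- solve(t(Xr) %*% Xr, t(Xr) %*% P)
  rss_red <- sum((P - Xr %*% br)^2)
  m <- length(P) - (k + 1)
  s_sq <- rss_full / m
  Fstat <- ((rss_red - rss_full) / (k - 1)) / s_sq
  xtxinv <- solve(t(X) %*% X)
  list(slope = bhat[k + 1], slope_se = sqrt(s_sq * xtxinv[k + 1, k + 1]),
       s_sq = s_sq, ss_effect = rss_red - rss_full, F = Fstat,
       p = pf(Fstat, k - 1, m, lower.tail = FALSE), m = m)
}

# Exact hypergeometric upper tail P(X >= k) by enumeration over the support.
oracle_hyper_tail <- function(n_universe, n_setB, n_setA, k) {
  jmax <- min(n_setA, n_setB)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(exp(lchoose(n_setB, j) + lchoose(n_universe - n_setB, n_setA - j) -
            lchoose(n_universe, n_setA)))
}

# Closed-form two-sample t statistics and p-values.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
oracle_welch_t <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Small paired design + experiment built by hand: `values_fun(gene, sample
# row)` fills the matrix.
toy_design <- function(conditions = c("A", "B"), n_replicates = 2L) {
  g <- expand.grid(fraction = c("cytosolic", "polysomal"),
                   replicate = seq_len(n_replicates), condition = conditions,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%d", g$condition, substr(g$fraction, 1, 4),
                         g$replicate)
  g[, c("sample_id", "fraction", "condition", "replicate")]
}

toy_experiment <- function(n_genes = 60L, conditions = c("A", "B"),
                           n_replicates = 3L, sd = 0.01, seed = 1L,
                           shift_cyto = NULL) {
  set.seed(seed)
  d <- toy_design(conditions, n_replicates)
  m <- matrix(rnorm(n_genes * nrow(d), 8, sd), n_genes, nrow(d),
              dimnames = list(sprintf("t%03d", seq_len(n_genes)), d$sample_id))
  if (!is.null(shift_cyto)) {
    # shift_cyto: named numeric, log2 shift added to cytosolic (and
    # propagated to polysomal) samples of the second condition
    sel <- d$condition == conditions[2]
    for (g in names(shift_cyto))
      m[g, d$sample_id[sel]] <- m[g, d$sample_id[sel]] + shift_cyto[[g]]
  }
  polysome_experiment(m, d)
}

tss_records_for_test <- polytran:::tss_records
report_numbers_for_test <- polytran:::report_numbers

# the nine printed TSS sequences and their published judgments
paper_tss <- data.frame(
  gene = c("RPS15A", "RPL26", "GAPDH_dbTSS", "GAPDH_oligocap", "TLR3",
           "RNF19B", "NT5C3A_1", "NT5C3A_2", "NT5C3A_3"),
  seq = c("CTCTTTCCG", "CTCTTCCCTTTTG", "GCTCTCTGCTCCTCCTG",
          "CTCTGCTCCTCCTG", "CTATTTGCCACAC", "TTCTATCGCCGGGA",
          "CTTTTGCTGGTG", "TCTTTTGCTGGTG", "TTCTTTTGCTGGTG"),
  judgment = c("TOP", "TOP", "TOP_LIKE", "NON_TOP", "NON_TOP", "NON_TOP",
               "TOP_OR_TOP_LIKE", "TOP_OR_TOP_LIKE", "TOP_OR_TOP_LIKE"),
  stringsAsFactors = FALSE)
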