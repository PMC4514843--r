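# Gene-set overlap enrichment (hypergeometric) and polysomal-to-cytoplasmic
# ratio statistics for targeted validation genes.

#' Hypergeometric gene-set overlap enrichment
#'
#' Is set A (e.g. the translationally repressed genes) enriched for members
#' of set B (e.g. ISGs) within a stated universe? Fold enrichment is the
#' observed over expected overlap fraction,
#' `(k/|A|) / (|B|/|U|)`; the p-value is the exact one-sided hypergeometric
#' tail `P(X >= k)` (no normal approximation). The universe is a required
#' explicit argument: reported enrichments are only meaningful relative to
#' the set of genes that could have been called.
#'
#' @param setA,setB Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all eligible gene ids (non-empty).
#' @param alternative `"enrichment"` (one-sided tail, default) or
#'   `"two.sided"` (Fisher-style doubling of the smaller tail, capped at 1).
#' @return List of class `enrichment_result`: `n_universe`, `n_setA`,
#'   `n_setB`, `n_overlap`, `fold_enrichment`, `p`.
#' @export
overlap_enrichment <- function(setA, setB, universe,
                               alternative = c("enrichment", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (!length(universe)) pt_error("universe must be non-empty", "bad_sets")
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  outA <- setdiff(setA, universe); outB <- setdiff(setB, universe)
  if (length(outA) || length(outB))
    pt_error(paste0("set members outside universe: ",
                    paste(c(outA, outB), collapse = ", ")), "bad_sets")
  nU <- length(universe); nA <- length(setA); nB <- length(setB)
  k <- length(intersect(setA, setB))
  fold <- if (nA == 0L || nB == 0L) 0
  else (k / nA) / (nB / nU)
  p_hi <- stats::phyper(k - 1L, nB, nU - nB, nA, lower.tail = FALSE)
  p <- if (alternative == "enrichment") p_hi
  else min(1, 2 * min(p_hi, stats::phyper(k, nB, nU - nB, nA)))
  structure(list(n_universe = nU, n_setA = nA, n_setB = nB, n_overlap = k,
                 fold_enrichment = fold, p = p, alternative = alternative),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("overlap %d of setA %d x setB %d in universe %d: %.2f fold enrichment; p = %.3g\n",
              x$n_overlap, x$n_setA, x$n_setB, x$n_universe,
              x$fold_enrichment, x$p))
  invisible(x)
}

#' Correlation between translational and cytosolic responses
#'
#' Pearson correlation of per-gene translational changes under mTOR
#' inhibition against per-gene cytosolic IFN induction, matched by gene id.
#' Near-zero correlation indicates that IFN-induced mRNAs are no more
#' reliant on mTOR for their translation than average.
#'
#' @param delta_translation,delta_cytosolic Named numeric vectors (names =
#'   gene ids); only genes present in both are used (>= 3 required).
#' @return List: `r` (Pearson correlation; `NA` with a warning when either
#'   vector has zero variance), `n`, and `table` (gene, x, y) for plotting.
#' @export
correlation_check <- function(delta_translation, delta_cytosolic) {
  common <- intersect(names(delta_translation), names(delta_cytosolic))
  if (length(common) < 3L)
    pt_error("need >= 3 matched genes", "bad_sets")
  x <- delta_translation[common]; y <- delta_cytosolic[common]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    NA_real_
  } else stats::cor(x, y)
  list(r = r, n = length(common),
       table = data.frame(gene_id = common, delta_translation = unname(x),
                          delta_cytosolic = unname(y),
                          stringsAsFactors = FALSE))
}

#' Polysomal-to-cytoplasmic abundance ratios with a two-group t-test
#'
#' For each replicate the ratio of polysomal to cytosolic linear-scale
#' abundance (e.g. qPCR ng) is formed; groups (conditions) are compared by a
#' two-sided two-sample t-test on the per-replicate ratios (pooled-variance
#' Student's t by default, Welch optional) and each group receives a
#' t-quantile 95% confidence interval for its mean ratio.
#'
#' @param poly_abundance,cyto_abundance Positive abundances per replicate,
#'   matched pairwise.
#' @param group_labels Two-level grouping of the replicates.
#' @param var_equal Pooled-variance (Student) t-test when `TRUE` (default);
#'   Welch otherwise.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `ratio_result`: per-group `n`, `mean_ratio`,
#'   `ci_lo`, `ci_hi`; plus `t`, `df`, `p` for the group comparison.
#' @export
polysomal_cytoplasmic_ratio <- function(poly_abundance, cyto_abundance,
                                        group_labels, var_equal = TRUE,
                                        conf_level = 0.95) {
  if (length(poly_abundance) != length(cyto_abundance) ||
      length(poly_abundance) != length(group_labels))
    pt_error("abundances and group labels must have equal length", "bad_config")
  if (any(cyto_abundance <= 0))
    pt_error(paste0("non-positive cytosolic abundance in replicate(s) ",
                    paste(which(cyto_abundance <= 0), collapse = ", ")),
             "bad_config")
  if (any(poly_abundance < 0))
    pt_error("polysomal abundances must be non-negative", "bad_config")
  g <- factor(group_labels)
  if (nlevels(g) != 2L || any(table(g) < 2L))
    pt_error("need exactly 2 groups with >= 2 replicates each", "bad_config")
  ratio <- poly_abundance / cyto_abundance
  groups <- lapply(split(ratio, g), function(x) {
    n <- length(x); mu <- mean(x); se <- stats::sd(x) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1L)
    list(n = n, mean_ratio = mu, ci_lo = mu - tq * se, ci_hi = mu + tq * se)
  })
  sp <- split(ratio, g)
  x <- sp[[1L]]; y <- sp[[2L]]
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) *
                 (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0)
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    else n1 + n2 - 2
  }
  diff_means <- mean(x) - mean(y)
  if (se > 0) {
    tstat <- diff_means / se
    pval <- 2 * stats::pt(-abs(tstat), df)
  } else {
    # both groups constant: identical means are maximally non-significant
    tstat <- if (diff_means == 0) 0 else sign(diff_means) * Inf
    pval <- if (diff_means == 0) 1 else 0
  }
  structure(list(groups = groups, t = tstat, df = df, p = pval,
                 conf_level = conf_level, var_equal = var_equal),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %s: mean ratio %.3f [%.3f, %.3f] (n = %d)\n",
                nm, g$mean_ratio, g$ci_lo, g$ci_hi, g$n))
  }
  cat(sprintf("  %s t = %.3f, df = %.2f, p = %.4g\n",
              if (x$var_equal) "Student" else "Welch", x$t, x$df, x$p))
  invisible(x)
}
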