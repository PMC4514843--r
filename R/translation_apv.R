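# Differential translation by per-gene analysis of partial variance (APV):
# ANCOVA of polysomal on cytosolic log2 expression with a single common
# slope, an RVM-moderated F test on the condition term, BH FDR control, and
# the slope / deltaPT reliability filters.
#
# Changes in polysome-associated mRNA can simply track changes in cytosolic
# mRNA; the APV adjusts the polysomal contrast for the cytosolic one so that
# only genuine shifts in translational activity are tested.

#' Fit the per-gene ANCOVA of polysomal on cytosolic expression
#'
#' Least-squares fit of `P = alpha_condition + beta * C + e` with a single
#' common slope `beta`. The condition effect is the difference of intercepts
#' (adjusted means at the common slope); its sum of squares is obtained by
#' comparison with the reduced model `P = alpha + beta * C`.
#'
#' @param P,C Paired polysomal and cytosolic log2 values, one entry per
#'   (condition, replicate); `C[i]` is the cytosolic measurement from the
#'   same biological replicate as `P[i]`.
#' @param conditions Condition label per entry; the contrast is
#'   `levels[2] - levels[1]` (factor level order, or order of first
#'   appearance for character input).
#' @return List of class `gene_apv_fit`: `slope`, `slope_se`, per-condition
#'   `adjusted_means` (intercepts evaluated at the grand mean of `C`), `rss`,
#'   `m` (residual df = n - (n_conditions + 1)), `s_sq`, `ss_effect`, `df1`,
#'   `deltaP`, `deltaC`, `deltaPT = deltaP - deltaC`, and `ok` (`FALSE` for a
#'   rank-deficient design, e.g. constant `C`).
#' @export
fit_gene_apv <- function(P, C, conditions) {
  if (length(P) != length(C) || length(P) != length(conditions))
    pt_error("P, C and conditions must have equal length", "bad_contrast")
  f <- if (is.factor(conditions)) conditions else
    factor(conditions, levels = unique(conditions))
  if (nlevels(f) < 2L || any(table(f) < 2L))
    pt_error("need >= 2 conditions with >= 2 replicates each", "bad_contrast")
  n <- length(P)
  k <- nlevels(f)
  Z <- stats::model.matrix(~ 0 + f)            # cell means
  Xfull <- cbind(Z, C)
  Xred <- cbind(1, C)
  qr_full <- qr(Xfull)
  if (qr_full$rank < ncol(Xfull))
    return(structure(list(ok = FALSE, m = NA_integer_), class = "gene_apv_fit"))
  fit_full <- stats::lm.fit(Xfull, P)
  fit_red <- stats::lm.fit(Xred, P)
  rss <- sum(fit_full$residuals^2)
  m <- n - (k + 1L)
  s_sq <- rss / m
  ss_effect <- sum(fit_red$residuals^2) - rss
  ss_effect <- max(ss_effect, 0)
  xtx_inv <- solve(crossprod(Xfull))
  slope <- unname(fit_full$coefficients[k + 1L])
  slope_se <- sqrt(max(s_sq * xtx_inv[k + 1L, k + 1L], 0))
  means_P <- tapply(P, f, mean)
  means_C <- tapply(C, f, mean)
  adj <- unname(fit_full$coefficients[seq_len(k)]) + slope * mean(C)
  names(adj) <- levels(f)
  structure(list(ok = TRUE, slope = slope, slope_se = slope_se,
                 adjusted_means = adj, rss = rss, m = m, s_sq = s_sq,
                 ss_effect = ss_effect, df1 = k - 1L,
                 deltaP = unname(means_P[2L] - means_P[1L]),
                 deltaC = unname(means_C[2L] - means_C[1L]),
                 deltaPT = unname((means_P[2L] - means_P[1L]) -
                                  (means_C[2L] - means_C[1L]))),
            class = "gene_apv_fit")
}

#' Slope reliability filter
#'
#' A gene whose fitted common slope lies outside `[minSlope, maxSlope]` is
#' excluded only when it is *significantly* outside: a one-sided t test of
#' the slope against the violated boundary at level `slopeP`, using the
#' fit's slope standard error on `m` df. A zero standard error with the
#' slope outside the window flags deterministically.
#'
#' @param fit A `gene_apv_fit` (see [fit_gene_apv()]).
#' @param settings [analysis_settings()].
#' @return `TRUE` when the gene should be excluded from the significant set.
#' @export
slope_filter <- function(fit, settings = analysis_settings()) {
  if (!isTRUE(fit$ok)) return(NA)
  b <- fit$slope
  if (b >= settings$minSlope && b <= settings$maxSlope) return(FALSE)
  if (fit$slope_se <= 0) return(TRUE)
  p <- if (b < settings$minSlope)
    stats::pt((b - settings$minSlope) / fit$slope_se, fit$m)
  else
    stats::pt((b - settings$maxSlope) / fit$slope_se, fit$m, lower.tail = FALSE)
  p < settings$slopeP
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values, monotone non-decreasing in the ranks of
#'   `p_values`, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  n_all <- length(p_values)
  if (!n_all) return(numeric(0))
  out <- rep(NA_real_, n_all)
  idx <- which(!is.na(p_values))
  p <- p_values[idx]
  if (any(p < 0 | p > 1)) pt_error("p-values must lie in [0,1]", "bad_pvalues")
  n <- length(p)
  if (n) {
    o <- order(p, decreasing = TRUE)
    adj <- cummin(p[o] * n / seq(n, 1))
    adj <- pmin(adj, 1)
    out[idx[o]] <- adj
  }
  out
}

#' Genome-wide differential translation analysis
#'
#' Per gene: [fit_gene_apv()] on the two contrast conditions; across genes:
#' [fit_rvm()] on the residual variances, moderated F/p on the condition
#' term, [bh_adjust()], then the significance gate
#' `padj <= maxRvmPAdj  &  |deltaPT| >= selDeltaPT  &  !slope_flag`,
#' with direction `"repressed"` (`deltaPT < 0`) or `"enhanced"`.
#'
#' @param experiment A [polysome_experiment()] containing both fractions for
#'   both contrast conditions with paired replicates.
#' @param contrast Length-2 character vector `c(condition1, condition2)`;
#'   effects are condition2 minus condition1.
#' @param settings [analysis_settings()].
#' @param rvm If `FALSE`, skip moderation (`nu0 = 0`): classical per-gene
#'   ANCOVA F on `m` df. Used for diagnostics and oracle comparisons.
#' @return Data frame of class `translation_result`, sorted by `padj` (ties
#'   by gene id), with per-gene fit summaries, `F_mod`, `p`, `padj`, filter
#'   flags, `significant` and `direction`. Attributes: `settings`,
#'   `rvm_params` (when fitted), `n_excluded` (rank-deficient genes).
#' @export
run_translation_analysis <- function(experiment, contrast,
                                     settings = analysis_settings(),
                                     rvm = TRUE) {
  pc <- paired_fraction_values(experiment, contrast)
  genes <- rownames(pc$P)
  if (!is.null(settings$min_expression)) {
    keep <- rowMeans(cbind(pc$P, pc$C)) >= settings$min_expression
    pc$P <- pc$P[keep, , drop = FALSE]
    pc$C <- pc$C[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  n_genes <- length(genes)
  cond <- factor(pc$condition, levels = contrast)
  batch <- apv_batch(pc$P, pc$C, cond)
  res <- batch$stats
  ok <- batch$ok
  m_vec <- ifelse(ok, batch$m, NA_integer_)
  if (sum(ok) < 50L)
    pt_error("fewer than 50 testable genes: RVM unfittable", "bad_rvm")
  if (any(!ok))
    message(sum(!ok), " gene(s) excluded from testing (rank-deficient APV design)")
  m_modal <- as.integer(stats::median(m_vec[ok]))
  fit_set <- ok & m_vec == m_modal
  df1 <- length(contrast) - 1L
  p <- rep(NA_real_, n_genes)
  f_stat <- rep(NA_real_, n_genes)
  params <- NULL
  if (rvm) {
    params <- fit_rvm(res[fit_set, "s_sq"], m_modal)
    # genes with non-modal df are still moderated with the fitted prior
    s_tilde <- moderate_variance(res[ok, "s_sq"], m_vec[ok], params)
    mod <- moderated_f(res[ok, "ss_effect"], df1, s_tilde, m_vec[ok], params)
    f_stat[ok] <- mod$F
    p[ok] <- mod$p
  } else {
    f_stat[ok] <- (res[ok, "ss_effect"] / df1) / res[ok, "s_sq"]
    p[ok] <- stats::pf(f_stat[ok], df1, m_vec[ok], lower.tail = FALSE)
  }
  padj <- bh_adjust(p)
  slope_flag <- slope_filter_vec(res[, "slope"], res[, "slope_se"], m_vec,
                                 settings)
  deltaPT_pass <- abs(res[, "deltaPT"]) >= settings$selDeltaPT
  significant <- !is.na(padj) & padj <= settings$maxRvmPAdj &
    deltaPT_pass & !slope_flag
  significant[is.na(significant)] <- FALSE
  out <- data.frame(gene_id = genes, res, m = m_vec, F_mod = f_stat,
                    p = p, padj = padj, slope_flag = slope_flag,
                    deltaPT_pass = deltaPT_pass, significant = significant,
                    direction = ifelse(res[, "deltaPT"] < 0, "repressed", "enhanced"),
                    apv_ok = ok, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$padj, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "settings") <- settings
  attr(out, "rvm_params") <- params
  attr(out, "n_excluded") <- sum(!ok)
  class(out) <- c("translation_result", "data.frame")
  out
}

# Vectorized APV over all genes at once, numerically identical to
# fit_gene_apv (closed-form within-group ANCOVA algebra): with C and P
# centered within conditions, beta = sum(CwPw)/sum(Cw^2),
# RSS_full = sum(Pw^2) - beta^2 sum(Cw^2); the reduced (no condition term)
# model uses global centering. Genes x pairs matrices P and C.
apv_batch <- function(P, C, cond) {
  n <- ncol(P)
  k <- nlevels(cond)
  G <- stats::model.matrix(~ 0 + cond)            # pairs x k indicator
  counts <- colSums(G)
  groupmean <- function(M) (M %*% G) %*% diag(1 / counts, k) %*% t(G)
  Cw <- C - groupmean(C); Pw <- P - groupmean(P)
  Cg <- C - rowMeans(C); Pg <- P - rowMeans(P)
  sxx_w <- rowSums(Cw^2);  sxy_w <- rowSums(Cw * Pw)
  sxx_g <- rowSums(Cg^2);  sxy_g <- rowSums(Cg * Pg)
  ok <- is.finite(sxx_w) & sxx_w > 0
  beta <- ifelse(ok, sxy_w / sxx_w, NA_real_)
  rss_full <- rowSums(Pw^2) - ifelse(ok, beta^2 * sxx_w, 0)
  rss_red <- rowSums(Pg^2) - ifelse(sxx_g > 0, sxy_g^2 / sxx_g, 0)
  m <- n - k - 1L
  s_sq <- rss_full / m
  ss_effect <- pmax(rss_red - rss_full, 0)
  slope_se <- sqrt(pmax(s_sq / sxx_w, 0))
  meanP <- P %*% G %*% diag(1 / counts, k)
  meanC <- C %*% G %*% diag(1 / counts, k)
  dP <- meanP[, 2L] - meanP[, 1L]
  dC <- meanC[, 2L] - meanC[, 1L]
  stats <- cbind(slope = beta, slope_se = slope_se, deltaP = dP, deltaC = dC,
                 deltaPT = dP - dC, s_sq = s_sq, ss_effect = ss_effect)
  stats[!ok, ] <- NA_real_
  rownames(stats) <- rownames(P)
  list(stats = stats, ok = ok, m = m)
}

# vectorized version of slope_filter on (slope, se, m) triples
slope_filter_vec <- function(slope, slope_se, m, settings) {
  inside <- slope >= settings$minSlope & slope <= settings$maxSlope
  flag <- rep(NA, length(slope))
  flag[inside] <- FALSE
  out <- which(!inside & !is.na(slope))
  if (length(out)) {
    p <- ifelse(slope[out] < settings$minSlope,
                stats::pt((slope[out] - settings$minSlope) / slope_se[out], m[out]),
                stats::pt((slope[out] - settings$maxSlope) / slope_se[out], m[out],
                          lower.tail = FALSE))
    p[slope_se[out] <= 0] <- 0   # deterministically outside
    flag[out] <- p < settings$slopeP
  }
  flag
}

# Align polysomal and cytosolic measurements by (condition, replicate) for a
# two-condition contrast. Returns genes x pairs matrices P and C plus the
# per-pair condition labels, ordered condition-major then replicate.
paired_fraction_values <- function(experiment, contrast) {
  stopifnot(inherits(experiment, "polysome_experiment"))
  if (length(contrast) != 2L)
    pt_error("contrast must name exactly two conditions", "bad_contrast")
  d <- experiment$design
  missing_cond <- setdiff(contrast, unique(d$condition))
  if (length(missing_cond))
    pt_error(paste0("condition(s) absent from design: ",
                    paste(missing_cond, collapse = ", ")), "bad_contrast")
  cond_out <- character(0)
  p_ids <- c_ids <- character(0)
  for (cn in contrast) {
    reps <- sort(unique(d$replicate[d$condition == cn]))
    if (length(reps) < 2L)
      pt_error(paste0("condition '", cn, "' has fewer than 2 replicates"),
               "bad_contrast")
    for (r in reps) {
      sel <- d$condition == cn & d$replicate == r
      p_ids <- c(p_ids, d$sample_id[sel & d$fraction == "polysomal"])
      c_ids <- c(c_ids, d$sample_id[sel & d$fraction == "cytosolic"])
      cond_out <- c(cond_out, cn)
    }
  }
  list(P = experiment$exprs[, p_ids, drop = FALSE],
       C = experiment$exprs[, c_ids, drop = FALSE],
       condition = cond_out)
}

#' Write a translation (or DE) result table to TSV
#'
#' The settings used are echoed as a `#`-prefixed header line.
#'
#' @param result A `translation_result` or `de_result` data frame.
#' @param path Output path.
#' @export
write_result <- function(result, path) {
  write_result_table(result, path, attr(result, "settings"))
}
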