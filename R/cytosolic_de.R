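# RVM-moderated differential expression of cytosolic mRNA and ISG calling at
# a linear fold-change threshold ("at least 1.5 fold" induced by IFN).

#' Cytosolic differential expression and ISG calling
#'
#' Per-gene two-sample comparison of cytosolic log2 expression between two
#' conditions: pooled within-condition residual variance on
#' `n1 + n2 - 2` df, RVM moderation across genes, moderated F on the mean
#' difference, BH adjustment. A gene is called an interferon-stimulated gene
#' (ISG) when its linear fold change `2^deltaC` is at least `isg_fold`
#' (closed bound) and — by default — `padj <= maxRvmPAdj`; the significance
#' gate can be switched off to reproduce a fold-only list.
#'
#' @param experiment A [polysome_experiment()] whose cytosolic fraction
#'   covers both conditions with >= 2 replicates each.
#' @param contrast `c(condition1, condition2)` (for ISG calling: control
#'   first, IFN second); `deltaC` is condition2 minus condition1.
#' @param settings [analysis_settings()].
#' @param require_significance Gate ISG calls on `padj <= maxRvmPAdj`
#'   (default `TRUE`).
#' @param rvm If `FALSE`, classical (unmoderated) per-gene F on the pooled
#'   variance.
#' @return Data frame of class `de_result` sorted by `padj` (ties by gene
#'   id): `gene_id`, `deltaC`, `fold_change` (`2^deltaC`), `s_sq`, `F_mod`,
#'   `p`, `padj`, `is_isg`. Attributes `settings`, `rvm_params`.
#' @export
run_cytosolic_de <- function(experiment, contrast,
                             settings = analysis_settings(),
                             require_significance = TRUE, rvm = TRUE) {
  stopifnot(inherits(experiment, "polysome_experiment"))
  if (length(contrast) != 2L)
    pt_error("contrast must name exactly two conditions", "bad_contrast")
  d <- experiment$design
  sel <- lapply(contrast, function(cn) {
    ids <- d$sample_id[d$condition == cn & d$fraction == "cytosolic"]
    if (length(ids) < 2L)
      pt_error(paste0("condition '", cn,
                      "' needs >= 2 cytosolic replicates"), "bad_contrast")
    experiment$exprs[, ids, drop = FALSE]
  })
  x1 <- sel[[1L]]; x2 <- sel[[2L]]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (!is.null(settings$min_expression)) {
    keep <- rowMeans(cbind(x1, x2)) >= settings$min_expression
    x1 <- x1[keep, , drop = FALSE]; x2 <- x2[keep, , drop = FALSE]
  }
  genes <- rownames(x1)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  deltaC <- m2 - m1
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  m <- n1 + n2 - 2L
  s_sq <- rss / m
  ss_effect <- deltaC^2 * (n1 * n2 / (n1 + n2))
  if (length(genes) < 50L)
    pt_error("fewer than 50 testable genes: RVM unfittable", "bad_rvm")
  params <- NULL
  if (rvm) {
    params <- fit_rvm(s_sq, m)
    s_tilde <- moderate_variance(s_sq, m, params)
    mod <- moderated_f(ss_effect, 1L, s_tilde, m, params)
    f_stat <- mod$F; p <- mod$p
  } else {
    f_stat <- ss_effect / s_sq
    p <- stats::pf(f_stat, 1L, m, lower.tail = FALSE)
  }
  padj <- bh_adjust(p)
  fold <- 2^deltaC
  is_isg <- fold >= settings$isg_fold
  if (require_significance) is_isg <- is_isg & padj <= settings$maxRvmPAdj
  out <- data.frame(gene_id = genes, deltaC = deltaC, fold_change = fold,
                    s_sq = s_sq, F_mod = f_stat, p = p, padj = padj,
                    is_isg = is_isg, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$padj, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "settings") <- settings
  attr(out, "rvm_params") <- params
  class(out) <- c("de_result", "data.frame")
  out
}

#' Top-k genes ranked by linear fold change
#'
#' Descending `fold_change`, ties broken by gene id for stable output. `k`
#' larger than the table returns the whole ranking.
#'
#' @param de A `de_result` data frame (see [run_cytosolic_de()]).
#' @param k Number of genes to return.
#' @return `de_result` rows in rank order.
#' @export
rank_by_fold <- function(de, k) {
  o <- order(-de$fold_change, de$gene_id)
  de[o[seq_len(min(k, nrow(de)))], , drop = FALSE]
}
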