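# Seeded synthetic-data generator emulating a paired two-fraction
# (cytosolic + polysomal) expression design with planted gene classes, the
# matching TSS sequences, and polysome RNA-yield tables.
#
# The generative model mirrors the assumptions of the downstream ANCOVA:
# condition effects are additive on the log2 scale, the cytosolic signal
# propagates into the polysomal fraction through a per-class slope
# (default 1), and per-gene variances are inverse-gamma so the RVM's
# scaled-F identity holds exactly for the residual variances.
#
# Note that an overall scaling of polysomal RNA (the global translational
# repression by mTOR inhibitors) is deliberately NOT applied to expression
# matrices: array-style data are generated as if equal RNA amounts were used
# as input from all conditions, so values are relative to the average mRNA.
# Global yield effects live in simulate_polysome_yields() instead.

GENE_CLASSES <- c("NULL", "TOP_REPRESSED", "ISG", "ISG_TOP_SWITCH", "BUFFERED")

#' Planted gene-class specification
#'
#' @param label One of `"NULL"`, `"TOP_REPRESSED"`, `"ISG"`,
#'   `"ISG_TOP_SWITCH"`, `"BUFFERED"`.
#' @param n_genes Number of genes in the class.
#' @param delta_translation Polysome-specific log2 shift applied in
#'   inhibitor-containing conditions (e.g. -1.5 for a repressed TOP gene).
#' @param delta_cytosolic Cytosolic log2 shift applied in IFN-containing
#'   conditions (e.g. `log2(4)` for a strong ISG).
#' @param slope Propagation of cytosolic signal into the polysomal fraction
#'   (default 1).
#' @return A `gene_class_spec` list.
#' @export
gene_class_spec <- function(label, n_genes, delta_translation = 0,
                            delta_cytosolic = 0, slope = 1) {
  label <- match.arg(label, GENE_CLASSES)
  if (n_genes < 0) pt_error("n_genes must be >= 0", "bad_config")
  structure(list(label = label, n_genes = as.integer(n_genes),
                 delta_translation = delta_translation,
                 delta_cytosolic = delta_cytosolic, slope = slope),
            class = "gene_class_spec")
}

#' Noise specification
#'
#' Per-gene variances are drawn from an inverse-gamma distribution with
#' shape `var_shape` and scale `var_scale` (standard shape/scale
#' parameterization; mean variance `var_scale / (var_shape - 1)`), i.e.
#' precisions are Gamma(shape `var_shape`, rate `var_scale`) — exactly the
#' structure the random variance model assumes. Baselines are normal on the
#' log2 scale.
#'
#' @param var_shape Inverse-gamma shape `a > 1` (finite mean variance);
#'   default 3.
#' @param var_scale Inverse-gamma scale (default 0.5, mean variance 0.25;
#'   `0` gives noiseless data).
#' @param baseline_mean,baseline_sd Log2 baseline distribution (defaults 7
#'   and 1.5, typical of RMA-summarized arrays).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(var_shape = 3, var_scale = 0.5,
                       baseline_mean = 7, baseline_sd = 1.5) {
  if (var_shape <= 1) pt_error("var_shape must be > 1", "bad_config")
  if (var_scale < 0) pt_error("var_scale must be >= 0", "bad_config")
  structure(list(var_shape = var_shape, var_scale = var_scale,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "noise_spec")
}

is_ifn_condition <- function(x) grepl("IFN", x, ignore.case = FALSE)
is_inhibitor_condition <- function(x) grepl("Torin1|rapamycin", x, ignore.case = TRUE)

#' Generate a synthetic paired-fraction experiment with known truth
#'
#' For gene g with variance `sigma_g^2 ~ InvGamma(var_shape, var_scale)`:
#' cytosolic `C = baseline + delta_cytosolic * [IFN condition] + e` and
#' polysomal `P = slope * C + delta_translation * [inhibitor condition] + e'`
#' with `e, e' ~ N(0, sigma_g^2)`. `BUFFERED` genes instead receive a
#' polysomal offset `-delta_cytosolic` in IFN conditions, cancelling the
#' propagated cytosolic induction. Deterministic given `seed`.
#'
#' @param classes List of [gene_class_spec()] (unique labels).
#' @param noise A [noise_spec()].
#' @param conditions Condition labels (>= 2); labels containing `"IFN"`
#'   receive the cytosolic effect, labels containing `"Torin1"`/`"rapamycin"`
#'   the translational effect.
#' @param n_replicates Biological replicates per condition (>= 2; default 4).
#' @param seed Integer seed.
#' @return List with `experiment` (a [polysome_experiment()], genes x
#'   (2 x conditions x replicates) samples) and `truth` (data frame: gene
#'   id, class, true effects, slope, `sigma_sq`, assigned motif class per
#'   condition group).
#' @export
generate_experiment <- function(classes, noise = noise_spec(),
                                conditions = c("control", "IFN", "IFN+Torin1"),
                                n_replicates = 4L, seed = 1L) {
  if (inherits(classes, "gene_class_spec")) classes <- list(classes)
  labels <- vapply(classes, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    pt_error("class labels must be unique within a config", "bad_config")
  n_genes <- sum(vapply(classes, `[[`, integer(1), "n_genes"))
  if (n_genes < 1L) pt_error("need at least one gene", "bad_config")
  if (length(conditions) < 2L || n_replicates < 2L)
    pt_error("need >= 2 conditions and >= 2 replicates", "bad_config")
  set.seed(as.integer(seed))

  cls <- rep(labels, vapply(classes, `[[`, integer(1), "n_genes"))
  dT <- rep(vapply(classes, `[[`, numeric(1), "delta_translation"),
            vapply(classes, `[[`, integer(1), "n_genes"))
  dC <- rep(vapply(classes, `[[`, numeric(1), "delta_cytosolic"),
            vapply(classes, `[[`, integer(1), "n_genes"))
  slope <- rep(vapply(classes, `[[`, numeric(1), "slope"),
               vapply(classes, `[[`, integer(1), "n_genes"))
  gene_id <- sprintf("g%05d", seq_len(n_genes))

  sigma_sq <- if (noise$var_scale > 0)
    1 / stats::rgamma(n_genes, shape = noise$var_shape, rate = noise$var_scale)
  else rep(0, n_genes)
  sigma <- sqrt(sigma_sq)
  baseline <- stats::rnorm(n_genes, noise$baseline_mean, noise$baseline_sd)

  design <- expand.grid(fraction = FRACTIONS, replicate = seq_len(n_replicates),
                        condition = conditions, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  design <- design[, c("condition", "replicate", "fraction")]
  design$sample_id <- sprintf("%s.%s.r%d", design$condition,
                              substr(design$fraction, 1L, 4L), design$replicate)
  exprs <- matrix(NA_real_, n_genes, nrow(design),
                  dimnames = list(gene_id, design$sample_id))
  for (i in seq_len(nrow(design))) {
    cn <- design$condition[i]
    if (design$fraction[i] == "cytosolic") {
      val <- baseline + dC * is_ifn_condition(cn) +
        stats::rnorm(n_genes, 0, sigma)
      exprs[, i] <- val
    } else {
      # polysomal sample pairs with the cytosolic sample of the same
      # (condition, replicate), generated immediately before it
      cyto <- exprs[, i - 1L]
      offset <- dT * is_inhibitor_condition(cn) -
        ifelse(cls == "BUFFERED", dC, 0) * is_ifn_condition(cn)
      exprs[, i] <- slope * cyto + offset + stats::rnorm(n_genes, 0, sigma)
    }
  }

  motif <- rep("NON_TOP", n_genes)
  top_idx <- which(cls == "TOP_REPRESSED")
  if (length(top_idx))
    motif[top_idx] <- sample(c("TOP", "TOP_LIKE"), length(top_idx), replace = TRUE)
  motif_ifn <- motif
  motif_ifn[cls == "ISG_TOP_SWITCH"] <- "TOP_LIKE"

  truth <- data.frame(gene_id = gene_id, class = cls,
                      true_delta_translation = dT, true_delta_cytosolic = dC,
                      slope = slope, sigma_sq = sigma_sq,
                      motif_class = motif, motif_class_ifn = motif_ifn,
                      stringsAsFactors = FALSE)
  experiment <- polysome_experiment(
    exprs, design[, c("sample_id", "fraction", "condition", "replicate")])
  list(experiment = experiment, truth = truth)
}

# construct a sequence guaranteed to classify as `target`
make_tss_sequence <- function(target, settings) {
  bases <- c("A", "C", "G", "T")
  pyr <- c("C", "T")
  pur <- c("A", "G")
  rand_tail <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  seq <- switch(
    target,
    TOP = {
      len <- sample(settings$top_min_run:min(settings$top_max_run, 12L), 1L)
      paste0("C", paste(sample(pyr, len, replace = TRUE), collapse = ""),
             sample(pur, 1L), rand_tail(8L))
    },
    TOP_LIKE = {
      len <- sample(settings$toplike_min_run:(settings$toplike_min_run + 5L), 1L)
      run <- paste(sample(pyr, len, replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5)
        paste0(sample(pur, 1L), run, sample(pur, 1L), rand_tail(8L))  # run from pos 2
      else
        paste0("T", run, sample(pur, 1L), rand_tail(8L))              # run from pos 1
    },
    NON_TOP = {
      repeat {
        cand <- rand_tail(12L)
        if (classify_tss(cand, settings)$class == "NON_TOP") break
      }
      cand
    },
    pt_error(paste("unknown motif class", target), "bad_config"))
  stopifnot(classify_tss(seq, settings)$class == target)
  seq
}

#' Generate TSS-anchored 5' sequences matching planted motif classes
#'
#' Emits one FASTA record per gene whose classification by [classify_tss()]
#' equals the class assigned in `truth`; `ISG_TOP_SWITCH` genes get two
#' records — a non-TOP variant under the `control` condition header and a
#' TOP-like variant under the `IFN` header (an IFN-induced start-site
#' switch). Deterministic given `seed`.
#'
#' @param truth Truth table from [generate_experiment()].
#' @param settings [analysis_settings()].
#' @param seed Integer seed.
#' @return A `tss_records` data frame (write with [write_tss_fasta()]).
#' @export
generate_tss_sequences <- function(truth, settings = analysis_settings(),
                                   seed = 1L) {
  set.seed(as.integer(seed))
  gene_id <- character(0); condition <- character(0); sequence <- character(0)
  for (i in seq_len(nrow(truth))) {
    if (truth$class[i] == "ISG_TOP_SWITCH") {
      gene_id <- c(gene_id, truth$gene_id[i], truth$gene_id[i])
      condition <- c(condition, "control", "IFN")
      sequence <- c(sequence,
                    make_tss_sequence(truth$motif_class[i], settings),
                    make_tss_sequence(truth$motif_class_ifn[i], settings))
    } else {
      gene_id <- c(gene_id, truth$gene_id[i])
      condition <- c(condition, NA_character_)
      sequence <- c(sequence, make_tss_sequence(truth$motif_class[i], settings))
    }
  }
  tss_records(gene_id, condition, sequence)
}

#' Simulate polysome RNA-yield tables
#'
#' Nanogram yields of RNA recovered from the cytoplasmic and polysomal
#' fractions per (condition, replicate). Inhibitor-containing conditions
#' scale the *polysomal* yield (default 0.58 for Torin1 — a 40-45% loss of
#' polysome-associated RNA — and 0.9 for rapamycin's modest effect);
#' cytosolic yields are unaffected. Lognormal replicate noise with
#' coefficient of variation `cv`.
#'
#' @param conditions Condition labels (default the six-treatment design:
#'   control, each inhibitor, and each +/- IFN).
#' @param n_replicates Replicates per condition (default 7).
#' @param cytosolic_mean,polysomal_mean Control mean yields in ng.
#' @param torin1_scale,rapamycin_scale Polysomal yield scaling.
#' @param cv Replicate coefficient of variation (default 0.1).
#' @param seed Integer seed.
#' @return Data frame `condition`, `replicate`, `fraction`, `ng`.
#' @export
simulate_polysome_yields <- function(conditions = c("control", "rapamycin",
                                                    "Torin1", "IFN",
                                                    "IFN+rapamycin", "IFN+Torin1"),
                                     n_replicates = 7L,
                                     cytosolic_mean = 4000, polysomal_mean = 1500,
                                     torin1_scale = 0.58, rapamycin_scale = 0.9,
                                     cv = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  grid <- expand.grid(fraction = FRACTIONS, replicate = seq_len(n_replicates),
                      condition = conditions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c("condition", "replicate", "fraction")]
  scale <- ifelse(grid$fraction == "polysomal" & grepl("Torin1", grid$condition),
                  torin1_scale,
                  ifelse(grid$fraction == "polysomal" &
                           grepl("rapamycin", grid$condition, ignore.case = TRUE),
                         rapamycin_scale, 1))
  mu <- ifelse(grid$fraction == "cytosolic", cytosolic_mean, polysomal_mean) * scale
  sdlog <- sqrt(log(1 + cv^2))
  grid$ng <- stats::rlnorm(nrow(grid), log(mu) - sdlog^2 / 2, sdlog)
  grid
}

#' Summarize polysome RNA yields per condition
#'
#' Per (condition, fraction): mean, standard deviation, percent change of
#' the mean versus the control condition (same fraction), and a two-sided
#' Welch t-test p-value versus control.
#'
#' @param yields Data frame with columns `condition`, `replicate`,
#'   `fraction`, `ng` (see [simulate_polysome_yields()]).
#' @param control Name of the reference condition (default `"control"`).
#' @return Data frame `condition`, `fraction`, `n`, `mean_ng`, `sd_ng`,
#'   `pct_change`, `p_vs_control` (`NA` for the control rows).
#' @export
polysome_yield_summary <- function(yields, control = "control") {
  req <- c("condition", "replicate", "fraction", "ng")
  if (!all(req %in% names(yields)))
    pt_error(paste("yields must have columns", paste(req, collapse = ", ")),
             "bad_config")
  if (!control %in% yields$condition)
    pt_error(paste0("control condition '", control, "' absent"), "bad_config")
  key <- interaction(yields$condition, yields$fraction, drop = TRUE)
  if (any(table(key) < 2L))
    pt_error("every (condition, fraction) group needs >= 2 replicates",
             "bad_config")
  out <- do.call(rbind, lapply(split(yields, key), function(gr) {
    data.frame(condition = gr$condition[1L], fraction = gr$fraction[1L],
               n = nrow(gr), mean_ng = mean(gr$ng), sd_ng = stats::sd(gr$ng),
               stringsAsFactors = FALSE)
  }))
  out$pct_change <- NA_real_
  out$p_vs_control <- NA_real_
  for (i in seq_len(nrow(out))) {
    ref <- yields$ng[yields$condition == control &
                       yields$fraction == out$fraction[i]]
    out$pct_change[i] <- 100 * (out$mean_ng[i] / mean(ref) - 1)
    if (out$condition[i] != control) {
      x <- yields$ng[yields$condition == out$condition[i] &
                       yields$fraction == out$fraction[i]]
      out$p_vs_control[i] <- stats::t.test(x, ref)$p.value
    }
  }
  rownames(out) <- NULL
  out[order(out$fraction, out$condition), ]
}
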