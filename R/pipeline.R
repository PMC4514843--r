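# End-to-end orchestration: simulate -> differential translation ->
# cytosolic DE / ISG calling -> motif classification -> overlap enrichment
# -> report. One config, one seed, plain-file stage outputs so any stage can
# be re-run on user-supplied data instead.

#' Default pipeline configuration
#'
#' A plain nested list (JSON-serializable) describing the simulated
#' experiment and analysis: gene classes (defaults: 4347 null genes, 150
#' TOP-repressed at `delta_translation = -1.5`, 500 ISGs at 2-fold cytosolic
#' induction, 3 ISGs with an IFN-induced TSS switch that are both induced
#' and translationally repressed), noise, conditions, replicates and the
#' two contrasts. Override any element via `...` (full replacement of that
#' element).
#'
#' @param ... Named elements replacing defaults, e.g.
#'   `classes = list(...)`, `n_replicates = 3`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    classes = list(
      list(label = "NULL", n_genes = 4347),
      list(label = "TOP_REPRESSED", n_genes = 150, delta_translation = -1.5),
      list(label = "ISG", n_genes = 500, delta_cytosolic = 1),
      list(label = "ISG_TOP_SWITCH", n_genes = 3, delta_translation = -1.5,
           delta_cytosolic = 1)),
    noise = list(var_shape = 3, var_scale = 0.5, baseline_mean = 7,
                 baseline_sd = 1.5),
    conditions = c("control", "IFN", "IFN+Torin1"),
    n_replicates = 4,
    translation_contrast = c("IFN", "IFN+Torin1"),
    isg_contrast = c("control", "IFN"),
    settings = list())
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a JSON file
#'
#' Elements present in the file replace the corresponding
#' [pipeline_config()] defaults.
#'
#' @param path JSON file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(user$classes) && is.data.frame(user$classes))
    user$classes <- lapply(seq_len(nrow(user$classes)), function(i)
      Filter(Negate(is.na), as.list(user$classes[i, ])))
  do.call(pipeline_config, user)
}

config_classes <- function(cfg) {
  lapply(cfg$classes, function(cl) do.call(gene_class_spec, cl))
}

#' Run the full pipeline on simulated data
#'
#' Stages, in order: [generate_experiment()] (+ TSS sequences and RNA
#' yields), [run_translation_analysis()] on the translation contrast,
#' [run_cytosolic_de()] on the ISG contrast, [classify_fasta()],
#' [overlap_enrichment()] of the significantly repressed set against the
#' ISG set in the universe of all tested genes, [correlation_check()], and
#' recovery metrics against the planted truth. All stage outputs are written
#' as TSV/FASTA under `out_dir`; reruns with the same config and seed are
#' byte-identical. Randomness is funnelled through `seed` (stage seeds are
#' derived as `seed`, `seed + 1`, `seed + 2`).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return A `pipeline_report` list of headline numbers, stage output paths
#'   and recovery metrics; also written to `report.txt`/`report.json`.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- do.call(analysis_settings, config$settings)
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[polytran] stage %-12s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  sim <- stage("simulate", generate_experiment(
    config_classes(config), do.call(noise_spec, config$noise),
    conditions = config$conditions, n_replicates = config$n_replicates,
    seed = seed))
  write_expression(sim$experiment, path("expression.tsv"), path("design.tsv"))
  utils::write.table(sim$truth, path("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tss <- stage("tss", generate_tss_sequences(sim$truth, settings,
                                             seed = seed + 1L))
  write_tss_fasta(tss, path("tss.fasta"))
  yields <- stage("yields", simulate_polysome_yields(
    conditions = config$conditions, seed = seed + 2L))
  utils::write.table(yields, path("yields.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ysum <- polysome_yield_summary(yields, control = config$conditions[1L])
  utils::write.table(ysum, path("yield_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  trans <- stage("translation", run_translation_analysis(
    sim$experiment, config$translation_contrast, settings))
  write_result(trans, path("translation.tsv"))
  de <- stage("cytosolic_de", run_cytosolic_de(
    sim$experiment, config$isg_contrast, settings))
  write_result(de, path("cytosolic_de.tsv"))
  motif <- stage("motif", classify_fasta(tss, settings))
  write_result_table(motif, path("motif_classes.tsv"))

  repressed <- trans$gene_id[trans$significant & trans$direction == "repressed"]
  enhanced <- trans$gene_id[trans$significant & trans$direction == "enhanced"]
  isgs <- de$gene_id[de$is_isg]
  universe <- trans$gene_id
  write_gene_set(repressed, path("repressed.txt"))
  write_gene_set(isgs, path("isgs.txt"))
  write_gene_set(universe, path("universe.txt"))
  enr <- stage("enrichment", overlap_enrichment(repressed, isgs, universe))
  corr <- correlation_check(
    stats::setNames(trans$deltaPT, trans$gene_id),
    stats::setNames(de$deltaC, de$gene_id))

  # the IFN-condition 5' variant is the one relevant under IFN treatment
  motif_eff <- motif[is.na(motif$condition) | motif$condition == "IFN", ]
  motif_by_gene <- stats::setNames(motif_eff$class, motif_eff$gene_id)
  rep_motifs <- table(factor(motif_by_gene[repressed],
                             levels = c("TOP", "TOP_LIKE", "NON_TOP")))

  truth <- sim$truth
  true_rep <- truth$gene_id[truth$true_delta_translation < 0 &
                              truth$class != "BUFFERED"]
  true_isg <- truth$gene_id[truth$true_delta_cytosolic >= log2(settings$isg_fold)]
  recovery <- list(
    translation_sensitivity = if (length(true_rep))
      mean(true_rep %in% repressed) else NA_real_,
    translation_fdr = if (length(repressed))
      mean(!(repressed %in% true_rep)) else 0,
    isg_sensitivity = if (length(true_isg))
      mean(true_isg %in% isgs) else NA_real_,
    isg_fdr = if (length(isgs)) mean(!(isgs %in% true_isg)) else 0)

  report <- structure(list(
    seed = seed, out_dir = out_dir, settings = settings,
    n_genes = nrow(truth),
    n_significant_repressed = length(repressed),
    n_significant_enhanced = length(enhanced),
    n_isg = length(isgs),
    n_overlap = enr$n_overlap,
    fold_enrichment = enr$fold_enrichment,
    p_enrichment = enr$p,
    correlation_r = corr$r,
    repressed_motif_counts = rep_motifs,
    polysomal_yield_pct_change = stats::setNames(
      ysum$pct_change[ysum$fraction == "polysomal"],
      ysum$condition[ysum$fraction == "polysomal"]),
    recovery = recovery,
    files = vapply(c("expression.tsv", "design.tsv", "truth.tsv", "tss.fasta",
                     "yields.tsv", "yield_summary.tsv", "translation.tsv",
                     "cytosolic_de.tsv", "motif_classes.tsv", "repressed.txt",
                     "isgs.txt", "universe.txt"), path, character(1))),
    class = "pipeline_report")
  writeLines(utils::capture.output(print(report)), path("report.txt"))
  jsonlite::write_json(report_numbers(report), path("report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

report_numbers <- function(x) {
  list(seed = x$seed, n_genes = x$n_genes,
       n_significant_repressed = x$n_significant_repressed,
       n_significant_enhanced = x$n_significant_enhanced,
       n_isg = x$n_isg, n_overlap = x$n_overlap,
       fold_enrichment = x$fold_enrichment, p_enrichment = x$p_enrichment,
       correlation_r = x$correlation_r,
       repressed_motif_counts = as.list(x$repressed_motif_counts),
       polysomal_yield_pct_change = as.list(x$polysomal_yield_pct_change),
       recovery = x$recovery)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("polytran pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(settings_header(x$settings), "\n")
  cat(sprintf("genes tested: %d\n", x$n_genes))
  cat(sprintf("significant translation: %d repressed, %d enhanced\n",
              x$n_significant_repressed, x$n_significant_enhanced))
  cat(sprintf("ISGs (>= %.2g-fold induced): %d\n",
              x$settings$isg_fold, x$n_isg))
  cat(sprintf("overlap repressed x ISG: %d (%.2f fold enrichment; p = %.3g)\n",
              x$n_overlap, x$fold_enrichment, x$p_enrichment))
  cat(sprintf("correlation (IFN induction vs translation change): r = %.4f\n",
              x$correlation_r))
  cat("motif classes among repressed: ",
      paste(sprintf("%s=%d", names(x$repressed_motif_counts),
                    x$repressed_motif_counts), collapse = " "), "\n", sep = "")
  cat("polysomal yield change vs control (%):",
      paste(sprintf("%s %+.1f", names(x$polysomal_yield_pct_change),
                    x$polysomal_yield_pct_change), collapse = ", "), "\n")
  cat(sprintf("recovery: translation sens %.3f fdr %.3f; ISG sens %.3f fdr %.3f\n",
              x$recovery$translation_sensitivity, x$recovery$translation_fdr,
              x$recovery$isg_sensitivity, x$recovery$isg_fdr))
  invisible(x)
}
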