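# Data containers and file IO shared by all analysis stages.
#
# All expression values are log2-scale (RMA-style normalized upstream;
# normalization itself is out of scope). File dialect is fixed: tab-separated,
# UTF-8, "." decimal point.

pt_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("polytran_", class), "polytran_error")))
}

FRACTIONS <- c("cytosolic", "polysomal")

#' Analysis settings
#'
#' Bundle of all tunable thresholds used by the translation, differential
#' expression and motif stages. Defaults correspond to a stringent
#' polysome-profiling workflow: the anota-style slope window and the 15%
#' false discovery rate used for both the translation and cytosolic arms.
#'
#' @param minSlope,maxSlope Bounds of the biologically plausible window for
#'   the common slope of polysomal on cytosolic log2 expression. A fitted
#'   slope outside the window is only disqualifying when significantly so
#'   (see [slope_filter()]). Defaults -1 and 2.
#' @param slopeP One-sided p-value threshold for the slope boundary tests
#'   (default 0.01).
#' @param maxRvmPAdj BH-adjusted p-value (FDR) threshold used for calling
#'   significance in both the translation and cytosolic arms (default 0.15).
#' @param selDeltaPT Minimum absolute translational-activity difference
#'   |deltaPT| = |deltaP - deltaC| in log2 units (default `log2(1.5)`),
#'   applied two-sidedly with the sign recorded as direction.
#' @param isg_fold Minimum linear fold-change of cytosolic mRNA for calling a
#'   gene interferon-stimulated (default 1.5; closed bound, "at least").
#' @param toplike_min_run Minimum pyrimidine-stretch length for a TOP-like
#'   call (default 5).
#' @param toplike_max_start Latest 1-based start position (inclusive) of the
#'   stretch for a TOP-like call, i.e. "within 4 bases of the cap" (default 4).
#' @param top_min_run,top_max_run Allowed length range of the pyrimidine run
#'   immediately following the initial cytidine for a TOP call (defaults 5
#'   and 15).
#' @param top_allow_long If `TRUE`, a post-C pyrimidine run longer than
#'   `top_max_run` still yields TOP; default `FALSE` (strict range reading),
#'   in which case such sequences fall through to the TOP-like rule.
#' @param min_expression Optional minimum mean log2 expression; genes below it
#'   are dropped before testing. Default `NULL` (filter off).
#' @param rng_seed Integer seed echoed into result headers.
#'
#' @return An object of class `apv_settings` (a validated list).
#' @export
analysis_settings <- function(minSlope = -1, maxSlope = 2, slopeP = 0.01,
                              maxRvmPAdj = 0.15, selDeltaPT = log2(1.5),
                              isg_fold = 1.5,
                              toplike_min_run = 5L, toplike_max_start = 4L,
                              top_min_run = 5L, top_max_run = 15L,
                              top_allow_long = FALSE,
                              min_expression = NULL, rng_seed = 1L) {
  s <- list(minSlope = minSlope, maxSlope = maxSlope, slopeP = slopeP,
            maxRvmPAdj = maxRvmPAdj, selDeltaPT = selDeltaPT,
            isg_fold = isg_fold,
            toplike_min_run = as.integer(toplike_min_run),
            toplike_max_start = as.integer(toplike_max_start),
            top_min_run = as.integer(top_min_run),
            top_max_run = as.integer(top_max_run),
            top_allow_long = isTRUE(top_allow_long),
            min_expression = min_expression,
            rng_seed = as.integer(rng_seed))
  if (!(s$minSlope < s$maxSlope))
    pt_error("minSlope must be < maxSlope", "bad_settings")
  for (p in c("slopeP", "maxRvmPAdj"))
    if (!(s[[p]] > 0 && s[[p]] < 1))
      pt_error(sprintf("%s must be in (0,1)", p), "bad_settings")
  if (s$toplike_min_run < 1L || s$toplike_max_start < 1L ||
      s$top_min_run < 1L || s$top_min_run > s$top_max_run)
    pt_error("motif run bounds must be positive with min <= max", "bad_settings")
  if (s$isg_fold <= 0) pt_error("isg_fold must be positive", "bad_settings")
  structure(s, class = "apv_settings")
}

#' @export
print.apv_settings <- function(x, ...) {
  cat("polytran analysis settings\n")
  cat(sprintf("  slope window [%g, %g], slopeP %g\n", x$minSlope, x$maxSlope, x$slopeP))
  cat(sprintf("  maxRvmPAdj %g, selDeltaPT %.4g, isg_fold %g\n",
              x$maxRvmPAdj, x$selDeltaPT, x$isg_fold))
  cat(sprintf("  TOP run %d-%d%s, TOP-like run >= %d starting <= %d\n",
              x$top_min_run, x$top_max_run,
              if (x$top_allow_long) " (long runs allowed)" else "",
              x$toplike_min_run, x$toplike_max_start))
  invisible(x)
}

settings_header <- function(settings) {
  sprintf("# settings: minSlope=%g maxSlope=%g slopeP=%g maxRvmPAdj=%g selDeltaPT=%g isg_fold=%g",
          settings$minSlope, settings$maxSlope, settings$slopeP,
          settings$maxRvmPAdj, settings$selDeltaPT, settings$isg_fold)
}

validate_design <- function(design) {
  req <- c("sample_id", "fraction", "condition", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    pt_error(paste("design must have columns", paste(req, collapse = ", ")),
             "bad_design")
  design$sample_id <- as.character(design$sample_id)
  design$fraction <- as.character(design$fraction)
  design$condition <- as.character(design$condition)
  design$replicate <- as.integer(design$replicate)
  bad <- setdiff(unique(design$fraction), FRACTIONS)
  if (length(bad))
    pt_error(paste0("unknown fraction label(s): ", paste(bad, collapse = ", ")),
             "unknown_fraction")
  if (anyDuplicated(design$sample_id))
    pt_error("duplicate sample ids in design", "bad_design")
  if (any(is.na(design$replicate)) || any(design$replicate < 1L))
    pt_error("replicate must be a positive integer", "bad_design")
  # each (condition, replicate) must pair exactly one cytosolic with one
  # polysomal sample (same lysate split into two fractions)
  key <- paste(design$condition, design$replicate, sep = "\r")
  for (k in unique(key)) {
    fr <- design$fraction[key == k]
    if (!(length(fr) == 2L && setequal(fr, FRACTIONS)))
      pt_error(sprintf(
        "condition '%s' replicate %s must have exactly one cytosolic and one polysomal sample",
        sub("\r.*", "", k), sub(".*\r", "", k)), "bad_pairing")
  }
  design[, req]
}

#' Construct a polysome-profiling experiment container
#'
#' @param values Numeric matrix of log2 expression, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param design Data frame with columns `sample_id`, `fraction`
#'   (`"cytosolic"` or `"polysomal"`), `condition`, `replicate`; one row per
#'   matrix column. Each (condition, replicate) pair must contribute exactly
#'   one sample per fraction.
#' @return Object of class `polysome_experiment`: list with elements `exprs`
#'   (matrix, columns reordered to design order) and `design`.
#' @export
polysome_experiment <- function(values, design) {
  design <- validate_design(design)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    pt_error("gene ids (rownames) must be present and unique", "duplicate_gene_ids")
  if (!is.numeric(values) || any(!is.finite(values)))
    pt_error("expression values must be finite numerics", "non_numeric")
  miss <- setdiff(design$sample_id, colnames(values))
  if (length(miss))
    pt_error(paste0("design sample(s) absent from matrix: ",
                    paste(miss, collapse = ", ")), "sample_mismatch")
  extra <- setdiff(colnames(values), design$sample_id)
  if (length(extra))
    pt_error(paste0("matrix sample(s) absent from design: ",
                    paste(extra, collapse = ", ")), "sample_mismatch")
  structure(list(exprs = values[, design$sample_id, drop = FALSE],
                 design = design),
            class = "polysome_experiment")
}

#' @export
print.polysome_experiment <- function(x, ...) {
  cat(sprintf("polysome_experiment: %d genes x %d samples\n",
              nrow(x$exprs), ncol(x$exprs)))
  tab <- table(x$design$condition, x$design$fraction)
  print(tab)
  invisible(x)
}

#' Read a paired expression matrix and sample design from TSV files
#'
#' The matrix file has a header row of sample ids and gene ids in the first
#' column; the design file has columns `sample_id`, `fraction`, `condition`,
#' `replicate`. Columns are reordered to design order. Malformed inputs
#' (unknown fraction, sample mismatch in either direction, duplicated gene
#' ids, non-numeric cells) raise classed errors naming the offender.
#'
#' @param matrix_path,design_path Paths to tab-separated files.
#' @return A [polysome_experiment()].
#' @export
read_expression <- function(matrix_path, design_path) {
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE,
                              comment.char = "#")
  raw <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  gene_ids <- as.character(raw[[1L]])
  if (anyDuplicated(gene_ids))
    pt_error(paste0("duplicate gene id(s): ",
                    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")),
             "duplicate_gene_ids")
  vals <- raw[, -1L, drop = FALSE]
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum))
    pt_error(paste0("non-numeric cell(s) in sample column(s): ",
                    paste(nonnum, collapse = ", ")), "non_numeric")
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  polysome_experiment(m, design)
}

#' Write a polysome experiment to matrix + design TSV files
#'
#' Inverse of [read_expression()]; round-trips at full double precision.
#'
#' @param x A `polysome_experiment`.
#' @param matrix_path,design_path Output paths.
#' @export
write_expression <- function(x, matrix_path, design_path) {
  stopifnot(inherits(x, "polysome_experiment"))
  df <- data.frame(gene_id = rownames(x$exprs), x$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read TSS-anchored 5' sequences from FASTA
#'
#' Headers are `gene_id` or `gene_id|condition` (the optional condition tags
#' per-treatment start-site variants). Sequences are upper-cased and RNA `U`
#' is mapped to `T`; position 1 is the first transcribed base (the cap).
#'
#' @param path FASTA path.
#' @return Data frame of class `tss_records` with columns `gene_id`,
#'   `condition` (`NA` when untagged) and `sequence`.
#' @export
read_tss_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- normalize_tss_sequence(as.character(set), headers)
  parts <- strsplit(headers, "|", fixed = TRUE)
  tss_records(
    gene_id = vapply(parts, `[[`, character(1), 1L),
    condition = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                       character(1)),
    sequence = seqs)
}

normalize_tss_sequence <- function(seqs, names_for_errors = seqs) {
  out <- chartr("U", "T", toupper(seqs))
  empty <- !nzchar(out)
  if (any(empty))
    pt_error(paste0("empty sequence for record(s): ",
                    paste(names_for_errors[empty], collapse = ", ")), "bad_sequence")
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    pt_error(paste0("invalid characters in record(s): ",
                    paste(names_for_errors[bad], collapse = ", ")), "bad_sequence")
  out
}

tss_records <- function(gene_id, condition = NA_character_, sequence) {
  structure(data.frame(gene_id = as.character(gene_id),
                       condition = as.character(condition),
                       sequence = as.character(sequence),
                       stringsAsFactors = FALSE),
            class = c("tss_records", "data.frame"))
}

#' Write TSS records to FASTA
#'
#' @param records A `tss_records` data frame (see [read_tss_fasta()]).
#' @param path Output FASTA path.
#' @export
write_tss_fasta <- function(records, path) {
  headers <- ifelse(is.na(records$condition), records$gene_id,
                    paste(records$gene_id, records$condition, sep = "|"))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(records)
}

#' Read / write plain-text gene sets (one id per line)
#'
#' @param path File path; `#`-prefixed lines and blank lines are ignored on
#'   read.
#' @return `read_gene_set`: character vector of unique ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' @param ids Character vector of gene ids.
#' @rdname read_gene_set
#' @export
write_gene_set <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(ids)
}

# Results TSV with a commented settings header; read back with read.delim
# (comment.char = "#").
write_result_table <- function(df, path, settings = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(settings)) writeLines(settings_header(settings), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# Subset an experiment to given conditions (both fractions), preserving
# design order.
subset_conditions <- function(x, conditions) {
  keep <- x$design$condition %in% conditions
  if (!any(keep)) pt_error("no samples match requested conditions", "bad_contrast")
  polysome_experiment(x$exprs[, x$design$sample_id[keep], drop = FALSE],
                      x$design[keep, ])
}
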