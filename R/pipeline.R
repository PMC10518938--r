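#' Pipeline run configuration
#'
#' Defaults reproduce the published parameterisation of the workflow: peak
#' score threshold 100 (MACS2 Q <= 1e-10 under the \code{int(-10 log10 Q)}
#' convention), 5 kb TSS flank for gene-list mode, enrichment score cap
#' 500, no cell-type-class filtering.
#'
#' @param genome genome build label inputs are expected to carry.
#' @param peak_score_threshold minimum BED column-5 score for peaks in
#'   scored peak sets (applied to ATAC replicates and the ChIP-seq
#'   library; unscored 3-column sets pass unfiltered).
#' @param flank TSS half-window (bp) for gene-list mode.
#' @param score_cap cap for enrichment scores (see [enrich()]).
#' @param cell_type_class_filter optional library cell-type-class filter.
#' @param chr_normalize add a "chr" prefix to bare chromosome names on read.
#' @param seed optional integer recorded in the provenance sidecar.
#' @param log_level "info" or "quiet".
#' @return object of class \code{run_config}.
#' @export
run_config <- function(genome = NA_character_, peak_score_threshold = 100L,
                       flank = 5000L, score_cap = 500,
                       cell_type_class_filter = NULL, chr_normalize = FALSE,
                       seed = NULL, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(peak_score_threshold >= 0L, flank > 0L, score_cap > 0)
  structure(list(genome = as.character(genome),
                 peak_score_threshold = as.integer(peak_score_threshold),
                 flank = as.integer(flank), score_cap = score_cap,
                 cell_type_class_filter = cell_type_class_filter,
                 chr_normalize = isTRUE(chr_normalize),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

maybe_filter <- function(ps, threshold) {
  df <- ps$intervals
  scored <- "score" %in% names(df) && nrow(df) > 0L && !any(is.na(df$score))
  if (scored && threshold > 0L) filter_by_score(ps, threshold) else ps
}

#' Run the full workflow on files
#'
#' Executes DAR detection (or gene-list TSS-window construction), TF
#' enrichment, per-antigen collapse, triad building and -- when a standard
#' is supplied -- evaluation, writing every intermediate as BED/TSV under
#' \code{out_dir} together with a run log (stage-by-stage counts) and a
#' provenance sidecar (configuration hash + input digests). Reruns with
#' unchanged inputs and configuration are byte-identical. Any stage error
#' aborts with a message naming the stage.
#'
#' DAR mode takes \code{exposed_beds}/\code{control_beds}; gene-list mode
#' takes \code{up_genes}/\code{down_genes} (one symbol per line) plus
#' \code{gene_annotation}, and the up-/down-window sets flow through the
#' same enrichment code path as opened/closed DARs.
#'
#' @param out_dir output directory (created).
#' @param library_manifest peak-library manifest TSV
#'   (see [read_peak_library()]).
#' @param tf_disease TF-disease association TSV (see [read_tf_disease()]).
#' @param exposed_beds,control_beds character vectors of replicate BED
#'   paths (DAR mode).
#' @param up_genes,down_genes gene-symbol list files (gene-list mode).
#' @param gene_annotation annotation TSV (see [read_gene_annotation()]).
#' @param chrom_sizes optional chrom-sizes TSV for window clamping.
#' @param standard optional chemical-disease standard TSV
#'   (see [read_standard()]).
#' @param condition_id label for this perturbation condition.
#' @param config [run_config()].
#' @return named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(out_dir, library_manifest, tf_disease,
                         exposed_beds = NULL, control_beds = NULL,
                         up_genes = NULL, down_genes = NULL,
                         gene_annotation = NULL, chrom_sizes = NULL,
                         standard = NULL, condition_id = "condition",
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (config$log_level == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  out <- c()

  deg_mode <- !is.null(up_genes)
  if (deg_mode) {
    dars <- stage("dars", {
      ann <- read_gene_annotation(gene_annotation)
      sizes <- if (is.null(chrom_sizes)) NULL else read_chrom_sizes(chrom_sizes)
      up <- genes_to_windows(readLines(up_genes), ann, config$flank, sizes)
      down <- genes_to_windows(readLines(down_genes), ann, config$flank, sizes)
      say("dars: %d up-regulated windows (%d symbols skipped), %d down (%d skipped)",
          nrow(up), length(attr(up, "skipped")),
          nrow(down), length(attr(down, "skipped")))
      detect_dars(up, down, condition_id, config$genome)
    })
  } else {
    dars <- stage("dars", {
      if (is.null(exposed_beds) || length(exposed_beds) == 0L)
        stop("no exposed replicate BEDs supplied")
      if (is.null(control_beds) || length(control_beds) == 0L)
        stop("no control replicate BEDs supplied")
      read_reps <- function(paths, label) lapply(seq_along(paths), function(i)
        maybe_filter(read_bed(paths[i], genome = config$genome,
                              experiment_id = sprintf("%s_%s_rep%d",
                                                      condition_id, label, i),
                              chr_normalize = config$chr_normalize),
                     config$peak_score_threshold))
      exposed <- read_reps(exposed_beds, "exposed")
      control <- read_reps(control_beds, "control")
      say("dars: %d exposed and %d control replicates read",
          length(exposed), length(control))
      exposed_common <- intersect_replicates(exposed)
      control_common <- intersect_replicates(control)
      say("dars: %d exposed-common and %d control-common regions",
          nrow(exposed_common), nrow(control_common))
      write_bed(peak_set(exposed_common, "exposed_common",
                         genome = config$genome),
                file.path(out_dir, "common_exposed.bed"))
      write_bed(peak_set(control_common, "control_common",
                         genome = config$genome),
                file.path(out_dir, "common_control.bed"))
      detect_dars(exposed_common, control_common, condition_id, config$genome)
    })
    out <- c(out, common_exposed = file.path(out_dir, "common_exposed.bed"),
             common_control = file.path(out_dir, "common_control.bed"))
  }
  say("dars: %d opened and %d closed regions for %s",
      nrow(dars$opened), nrow(dars$closed), condition_id)
  dar_paths <- write_dar_set(dars, out_dir)
  out <- c(out, opened = dar_paths[1L], closed = dar_paths[2L])

  results <- stage("enrich", {
    lib <- read_peak_library(library_manifest,
                             cell_type_class_filter =
                               config$cell_type_class_filter,
                             chr_normalize = config$chr_normalize)
    lib <- lapply(lib, maybe_filter, config$peak_score_threshold)
    say("enrich: %d experiments tested", length(lib))
    res <- enrich(dars, lib, score_cap = config$score_cap)
    say("enrich: %d experiments at Q < 0.05", sum(res$q_value < 0.05))
    res
  })
  write_enrichment(results, file.path(out_dir, "enrichment.tsv"))
  collapsed <- collapse_by_antigen(results)
  say("collapse: %d distinct antigens", nrow(collapsed))
  write_enrichment(collapsed, file.path(out_dir, "enrichment_collapsed.tsv"))
  out <- c(out, enrichment = file.path(out_dir, "enrichment.tsv"),
           collapsed = file.path(out_dir, "enrichment_collapsed.tsv"))

  std <- if (is.null(standard)) NULL else read_standard(standard)
  triads <- stage("triad", {
    assoc <- read_tf_disease(tf_disease)
    tm <- build_triads(stats::setNames(list(collapsed), condition_id),
                       assoc, standard = std)
    say("triad: matrix %d x %d, %d non-zero cells",
        length(tm$conditions), length(tm$diseases), sum(tm$score > 0))
    tm
  })
  write_triads(triads, file.path(out_dir, "triad_long.tsv"),
               file.path(out_dir, "triad_wide.tsv"))
  out <- c(out, triad_long = file.path(out_dir, "triad_long.tsv"),
           triad_wide = file.path(out_dir, "triad_wide.tsv"))

  if (!is.null(std)) {
    report <- stage("evaluate", suppressMessages(evaluate(triads, std)))
    say("evaluate: global AUROC %.4f, global AUPR %.4f",
        report$global_auroc, report$global_aupr)
    write_eval_report(report, file.path(out_dir, "evaluation.tsv"))
    out <- c(out, evaluation = file.path(out_dir, "evaluation.tsv"))
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  inputs <- c(library_manifest, tf_disease, exposed_beds, control_beds,
              up_genes, down_genes, gene_annotation, chrom_sizes, standard)
  prov <- list(
    config = config[setdiff(names(config), NULL)],
    config_hash = config_hash(config),
    inputs = as.list(unname(tools::md5sum(inputs))),
    input_paths = as.list(basename(inputs)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out <- c(out, run_log = file.path(out_dir, "run.log"),
           provenance = file.path(out_dir, "provenance.json"))
  invisible(out)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}
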