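#' Read a chemical-disease standard table
#'
#' TSV with header columns \code{condition_id, disease_id}; duplicate pairs
#' are collapsed. This is the Boolean standard (curated chemical-disease
#' associations) evaluation is scored against.
#'
#' @param path TSV path.
#' @return data.frame with the two columns.
#' @export
read_standard <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "disease_id")
  if (!all(need %in% names(tab)))
    stop("standard must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- tab[!duplicated(tab[need]), need, drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic U / (n1 * n0) with half credit
#' for score ties -- identical to the trapezoidal area under the tie-aware
#' ROC curve, and invariant to any strictly monotone transform of the
#' scores.
#'
#' @param scores numeric vector.
#' @param labels logical vector (TRUE = positive), same length.
#' @return number in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC needs at least one positive and one negative label",
         call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Descending-score sweep; tied scores are processed as one block, so the
#' result does not depend on within-tie ordering. The area is the step
#' integral sum over blocks of (recall increment) x (precision at the block
#' end). A constant scorer therefore returns the positive prevalence, the
#' random-classifier baseline.
#'
#' @inheritParams auroc
#' @return number in [0, 1].
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0L) stop("AUPR needs at least one positive label", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[block_end]
  n_seen <- block_end
  recall <- tp / n1
  precision <- tp / n_seen
  sum((recall - c(0, recall[-length(recall)])) * precision)
}

#' Evaluate a TriadMatrix against a chemical-disease standard
#'
#' Per condition, the label of each disease column is its presence in the
#' standard for that condition, and AUROC/AUPR are computed over the
#' matrix's shared disease columns (negatives are diseases scored but not
#' in the standard for that chemical). Conditions with zero positives or
#' zero negatives among the columns are excluded from the per-condition
#' table and the unweighted means, but their cells stay in the merged
#' global score/label vector on which the global AUROC/AUPR are computed.
#' Exclusions are reported via \code{message()} and in the returned object.
#'
#' @param matrix TriadMatrix from [build_triads()].
#' @param standard data.frame from [read_standard()].
#' @return object of class \code{EvalReport}: list with \code{per_condition}
#'   (data.frame condition_id, auroc, aupr, n_pos, n_neg),
#'   \code{mean_auroc}, \code{mean_aupr}, \code{global_auroc},
#'   \code{global_aupr}, \code{excluded} (condition ids).
#' @export
evaluate <- function(matrix, standard) {
  stopifnot(inherits(matrix, "TriadMatrix"))
  std_by_cond <- split(standard$disease_id, standard$condition_id)
  if (!any(matrix$conditions %in% names(std_by_cond)))
    stop("no condition of the matrix appears in the standard", call. = FALSE)
  rows <- list()
  excluded <- character()
  g_scores <- numeric()
  g_labels <- logical()
  for (cond in matrix$conditions) {
    sc <- matrix$score[cond, ]
    lab <- matrix$diseases %in% std_by_cond[[cond]]
    g_scores <- c(g_scores, sc)
    g_labels <- c(g_labels, lab)
    n_pos <- sum(lab)
    n_neg <- sum(!lab)
    if (n_pos == 0L || n_neg == 0L) {
      excluded <- c(excluded, cond)
      next
    }
    rows[[cond]] <- data.frame(condition_id = cond,
                               auroc = auroc(sc, lab),
                               aupr = aupr(sc, lab),
                               n_pos = n_pos, n_neg = n_neg,
                               stringsAsFactors = FALSE)
  }
  if (length(excluded))
    message("excluded from per-condition metrics (single-class labels): ",
            paste(excluded, collapse = ", "))
  if (length(rows) == 0L)
    stop("no condition is evaluable (all have single-class labels)",
         call. = FALSE)
  per_condition <- do.call(rbind, rows)
  rownames(per_condition) <- NULL
  structure(list(per_condition = per_condition,
                 mean_auroc = mean(per_condition$auroc),
                 mean_aupr = mean(per_condition$aupr),
                 global_auroc = auroc(g_scores, g_labels),
                 global_aupr = aupr(g_scores, g_labels),
                 excluded = excluded),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(paste0("EvalReport: %d evaluable condition(s)\n",
                     "  mean AUROC %.4f  mean AUPR %.4f\n",
                     "  global AUROC %.4f  global AUPR %.4f\n"),
              nrow(x$per_condition), x$mean_auroc, x$mean_aupr,
              x$global_auroc, x$global_aupr))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write an EvalReport as TSV
#'
#' Per-condition rows followed by summary rows (mean and global metrics).
#'
#' @param report EvalReport.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "EvalReport"))
  pc <- report$per_condition
  fmt <- function(x) formatC(x, digits = 6, format = "g")
  lines <- c("condition_id\tauroc\taupr\tn_pos\tn_neg",
             paste(pc$condition_id, fmt(pc$auroc), fmt(pc$aupr),
                   pc$n_pos, pc$n_neg, sep = "\t"),
             paste("__mean__", fmt(report$mean_auroc), fmt(report$mean_aupr),
                   "", "", sep = "\t"),
             paste("__global__", fmt(report$global_auroc),
                   fmt(report$global_aupr), "", "", sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Compare per-condition metrics between two methods
#'
#' Unpaired two-tailed Wilcoxon rank-sum test with Bonferroni correction:
#' the raw p value is multiplied by \code{n_comparisons} and clamped to 1.
#' Exact enumeration is used for tie-free groups of size <= 20, otherwise
#' the tie-corrected normal approximation.
#'
#' @param metric_a,metric_b numeric vectors of per-condition metric values
#'   (e.g. AUROC scores) for the two methods.
#' @param n_comparisons number of tests in the Bonferroni family.
#' @return list with \code{statistic} (rank-sum W), \code{p_value} (raw
#'   two-tailed) and \code{adjusted_p}.
#' @export
compare_methods <- function(metric_a, metric_b, n_comparisons = 1L) {
  if (length(metric_a) == 0L || length(metric_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  stopifnot(n_comparisons >= 1L)
  use_exact <- length(metric_a) <= 20L && length(metric_b) <= 20L &&
    !anyDuplicated(c(metric_a, metric_b))
  wt <- suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, exact = use_exact,
                       correct = !use_exact))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       adjusted_p = min(1, wt$p.value * n_comparisons))
}
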