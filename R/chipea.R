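#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p value for the table \code{rbind(c(a, b), c(c, d))}:
#' with both margins fixed, sums the hypergeometric point probabilities of
#' every table whose probability is at most that of the observed table. A
#' relative tolerance of 1e-7 on the comparison keeps tables of equal
#' probability from being dropped by floating-point error.
#'
#' @param a,b,c,d non-negative integer counts. In the enrichment setting,
#'   \code{a}/\code{b} are opened DARs overlapping/not overlapping the
#'   experiment's peaks and \code{c}/\code{d} the same for closed DARs.
#' @return p value in (0, 1]. A degenerate margin (e.g. \code{a + b == 0})
#'   carries no information and returns 1 with a warning.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  m1 <- a + b  # opened margin
  m2 <- c + d  # closed margin
  k <- a + c   # overlapping margin
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) {
    warning("degenerate margin in 2x2 table; p = 1", call. = FALSE)
    return(1)
  }
  xs <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(xs, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false discovery rate control: on sorted p values,
#' \code{q_(i) = min over j >= i of min(1, p_(j) * m / j)}, mapped back to
#' the input order.
#'
#' @param p_values numeric vector with every element in (0, 1].
#' @return adjusted values, aligned with the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' TF enrichment of a ChIP-seq peak library against a DARSet
#'
#' For each experiment in the library, counts the opened and closed DARs
#' overlapping its peaks (binary per region, [count_overlapping_queries()]),
#' tests the 2x2 table with [fisher_exact_two_tailed()], adjusts across all
#' experiments of this call with [bh_adjust()], and reports the enrichment
#' score \code{-log10(Q)} (capped) plus a signed log2 fold enrichment of the
#' opened over the closed overlap rate. The fold enrichment uses a
#' Haldane-style +0.5 continuity correction on the rates so it stays finite
#' when one side has zero overlaps; p values always use the raw counts.
#'
#' DEG mode reuses this function verbatim with up-/down-regulated gene TSS
#' windows (see [genes_to_windows()]) substituted for opened/closed DARs,
#' and a methylation peak library can stand in for the ChIP-seq library.
#'
#' @param dars DARSet with non-empty opened AND closed sets.
#' @param library list of PeakSet on the same genome build.
#' @param score_cap cap for the enrichment score and |log2 fold
#'   enrichment| (default 500), keeping Q-value underflow finite.
#' @return data.frame with one row per experiment: experiment_id, antigen,
#'   cell_type_class, a, b, c, d, p_value, q_value, enrichment_score,
#'   log2_fold_enrichment.
#' @export
enrich <- function(dars, library, score_cap = 500) {
  stopifnot(inherits(dars, "DARSet"), length(library) >= 1L, score_cap > 0)
  n_open <- nrow(dars$opened)
  n_closed <- nrow(dars$closed)
  if (n_open == 0L || n_closed == 0L)
    stop("condition ", dars$condition_id, " has an empty opened or closed ",
         "DAR set and cannot be tested for differential enrichment",
         call. = FALSE)
  builds <- vapply(library, `[[`, character(1), "genome")
  bad <- !is.na(builds) & !is.na(dars$genome) & builds != dars$genome
  if (any(bad))
    stop("genome build mismatch between DARs (", dars$genome,
         ") and experiments: ",
         paste(vapply(library[bad], `[[`, character(1), "experiment_id"),
               collapse = ", "), call. = FALSE)
  a <- vapply(library, function(ps)
    count_overlapping_queries(dars$opened, ps), integer(1))
  cc <- vapply(library, function(ps)
    count_overlapping_queries(dars$closed, ps), integer(1))
  b <- n_open - a
  d <- n_closed - cc
  p <- mapply(fisher_exact_two_tailed, a, b, cc, d)
  q <- bh_adjust(p)
  score <- pmin(-log10(q), score_cap)
  l2fe <- log2(((a + 0.5) / (n_open + 0.5)) / ((cc + 0.5) / (n_closed + 0.5)))
  l2fe <- pmin(pmax(l2fe, -score_cap), score_cap)
  res <- data.frame(
    experiment_id = vapply(library, `[[`, character(1), "experiment_id"),
    antigen = vapply(library, `[[`, character(1), "antigen"),
    cell_type_class = vapply(library, `[[`, character(1), "cell_type_class"),
    a = a, b = b, c = cc, d = d,
    p_value = p, q_value = q,
    enrichment_score = score,
    log2_fold_enrichment = l2fe,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Collapse enrichment results to one row per antigen
#'
#' When several ChIP-seq experiments assay the same antigen (TF), only the
#' one with the highest enrichment score is retained. Ties break by larger
#' |log2 fold enrichment|, then by lexicographically smallest experiment_id,
#' so the result is deterministic.
#'
#' @param results data.frame from [enrich()].
#' @return data.frame with one row per distinct antigen.
#' @export
collapse_by_antigen <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) return(results)
  ord <- order(results$antigen,
               -results$enrichment_score,
               -abs(results$log2_fold_enrichment),
               results$experiment_id)
  res <- results[ord, , drop = FALSE]
  res <- res[!duplicated(res$antigen), , drop = FALSE]
  res <- res[order(res$antigen), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an enrichment table as TSV
#'
#' Fixed column order; numeric columns rendered with 6 significant digits
#' for bit-stable diffs.
#'
#' @param results data.frame from [enrich()] or [collapse_by_antigen()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  for (col in c("p_value", "q_value", "enrichment_score",
                "log2_fold_enrichment"))
    out[[col]] <- formatC(results[[col]], digits = 6, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an enrichment TSV written by [write_enrichment()]
#' @param path TSV path.
#' @return enrichment data.frame.
#' @export
read_enrichment <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
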