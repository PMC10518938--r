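#' Read a TF-disease association table
#'
#' TSV with header columns \code{antigen, disease_id, source} (source is a
#' provenance tag such as a PubMed ID). Duplicate (antigen, disease_id)
#' pairs are collapsed to one.
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
read_tf_disease <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("antigen", "disease_id", "source")
  if (!all(need %in% names(tab)))
    stop("TF-disease table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  tab <- tab[!duplicated(tab[c("antigen", "disease_id")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Build the chemical x disease triad score matrix
#'
#' Joins per-condition TF enrichment with TF-disease associations: the score
#' of a (condition, disease) cell is the maximum enrichment score over the
#' TFs linked to that disease, and the mediator records that argmax TF.
#' Among tied TFs the lexicographically smallest symbol wins. Cells with no
#' linking TF (or a maximum of exactly 0) score 0 with an empty mediator,
#' so every condition carries a complete score vector into evaluation.
#'
#' Antigen and TF symbols are matched exactly after uppercasing (so mouse
#' "Pparg" meets human "PPARG"); no ortholog mapping is attempted.
#'
#' @param per_condition_results named list (condition_id ->
#'   [collapse_by_antigen()] output).
#' @param assoc data.frame from [read_tf_disease()].
#' @param standard optional data.frame (see [read_standard()]); its disease
#'   IDs are added as columns so evaluation labels stay complete.
#' @return object of class \code{TriadMatrix}: list with \code{conditions},
#'   \code{diseases}, numeric \code{score} matrix and character
#'   \code{mediator} matrix.
#' @export
build_triads <- function(per_condition_results, assoc, standard = NULL) {
  if (length(per_condition_results) == 0L)
    stop("no enrichment results supplied", call. = FALSE)
  if (is.null(names(per_condition_results)) ||
      any(!nzchar(names(per_condition_results))))
    stop("per_condition_results must be named by condition_id", call. = FALSE)
  if (nrow(assoc) == 0L)
    stop("empty TF-disease association table", call. = FALSE)
  assoc <- assoc[!duplicated(assoc[c("antigen", "disease_id")]), , drop = FALSE]
  assoc$antigen <- toupper(assoc$antigen)

  score_maps <- lapply(per_condition_results, function(res) {
    key <- toupper(res$antigen)
    sc <- res$enrichment_score
    # after collapse antigens are unique; uppercasing could merge two, keep max
    ord <- order(key, -sc)
    sc <- sc[ord]; key <- key[ord]
    keep <- !duplicated(key)
    stats::setNames(sc[keep], key[keep])
  })
  tested_tfs <- unique(unlist(lapply(score_maps, names), use.names = FALSE))
  reachable <- unique(assoc$disease_id[assoc$antigen %in% tested_tfs])
  diseases <- sort(unique(c(reachable,
                            if (!is.null(standard)) standard$disease_id)))
  if (length(diseases) == 0L)
    stop("no disease reachable from any tested TF", call. = FALSE)
  conditions <- names(per_condition_results)
  score <- matrix(0, nrow = length(conditions), ncol = length(diseases),
                  dimnames = list(conditions, diseases))
  mediator <- matrix("", nrow = length(conditions), ncol = length(diseases),
                     dimnames = list(conditions, diseases))
  tfs_by_disease <- split(assoc$antigen, assoc$disease_id)
  for (i in seq_along(conditions)) {
    sm <- score_maps[[i]]
    for (j in seq_along(diseases)) {
      cand <- tfs_by_disease[[diseases[j]]]
      cand <- cand[cand %in% names(sm)]
      if (length(cand) == 0L) next
      v <- sm[cand]
      mx <- max(v)
      if (mx > 0) {
        score[i, j] <- mx
        mediator[i, j] <- sort(names(v)[v == mx])[1L]
      }
    }
  }
  structure(list(conditions = conditions, diseases = diseases,
                 score = score, mediator = mediator),
            class = "TriadMatrix")
}

#' @export
print.TriadMatrix <- function(x, ...) {
  cat(sprintf("TriadMatrix: %d condition(s) x %d disease(s), %d non-zero cells\n",
              length(x$conditions), length(x$diseases), sum(x$score > 0)))
  invisible(x)
}

#' Write a TriadMatrix as long- and wide-format TSV
#'
#' @param triads TriadMatrix.
#' @param long_path long-format TSV (condition_id, disease_id, score,
#'   mediator), one row per cell.
#' @param wide_path optional condition x disease wide TSV of scores.
#' @return \code{long_path}, invisibly.
#' @export
write_triads <- function(triads, long_path, wide_path = NULL) {
  stopifnot(inherits(triads, "TriadMatrix"))
  long <- data.frame(
    condition_id = rep(triads$conditions, times = length(triads$diseases)),
    disease_id = rep(triads$diseases, each = length(triads$conditions)),
    score = formatC(as.vector(triads$score), digits = 6, format = "g"),
    mediator = as.vector(triads$mediator),
    stringsAsFactors = FALSE)
  long <- long[order(long$condition_id, long$disease_id), , drop = FALSE]
  utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(wide_path)) {
    wide <- data.frame(condition_id = triads$conditions,
                       formatC(triads$score, digits = 6, format = "g"),
                       check.names = FALSE, stringsAsFactors = FALSE)
    colnames(wide) <- c("condition_id", triads$diseases)
    utils::write.table(wide, wide_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(long_path)
}
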