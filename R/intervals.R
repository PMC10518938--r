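#' darchip: TF enrichment in differentially accessible chromatin
#'
#' Workflow: [intersect_replicates()] + [detect_dars()] derive opened/closed
#' differentially accessible regions (DARs) from replicate ATAC-seq peak sets;
#' [enrich()] + [collapse_by_antigen()] score a ChIP-seq peak library for
#' differential binding between the two DAR sets; [build_triads()] joins
#' enriched factors with TF-disease annotations into a condition x disease
#' score matrix; [evaluate()] measures AUROC/AUPR against a curated standard.
#' [simulate_dataset()] generates a fully synthetic input set with planted
#' enrichment for validation, and [run_pipeline()] ties the stages together.
#'
#' All genomic coordinates are BED-native: 0-based, half-open \code{[start,
#' end)}. Chromosome names are matched as exact strings ("chr1" != "1").
#'
#' @keywords internal
"_PACKAGE"

## Interval collections are plain data.frames with columns chrom (character),
## start, end (integer, 0-based half-open) and optionally score (integer,
## BED column 5). Overlap queries go through GenomicRanges.

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; 0-based half-open coordinates with
#'   \code{0 <= start < end}.
#' @param score optional non-negative integer vector (BED column-5
#'   convention, \code{int(-10 log10 Q)} from the peak caller), or NULL.
#' @return data.frame with columns chrom, start, end and, when score is
#'   given, score.
#' @export
genomic_intervals <- function(chrom, start, end, score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.integer(score)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "intervals") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chromosome names must be non-empty", call. = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(what, ": start/end must be integers", call. = FALSE)
  if (any(df$start < 0L))
    stop(what, ": start must be >= 0", call. = FALSE)
  if (any(df$end <= df$start))
    stop(what, ": end must be > start", call. = FALSE)
  if ("score" %in% names(df) && any(!is.na(df$score) & df$score < 0L))
    stop(what, ": scores must be non-negative", call. = FALSE)
  invisible(df)
}

## 0-based half-open -> GRanges (1-based closed). Empty input allowed.
## seqlevels may name a shared chromosome universe so that pairwise overlap
## operations on disjoint chromosome sets stay warning-free.
as_gr <- function(x, seqlevels = NULL) {
  df <- if (inherits(x, "PeakSet")) x$intervals else x
  sq <- if (is.null(seqlevels)) unique(df$chrom) else seqlevels
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = sq),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

## shared chromosome universe for a pair of interval tables
pair_levels <- function(a, b) {
  adf <- if (inherits(a, "PeakSet")) a$intervals else a
  bdf <- if (inherits(b, "PeakSet")) b$intervals else b
  sort(unique(c(adf$chrom, bdf$chrom)))
}

## GRanges -> 0-based half-open data.frame, sorted by (chrom, start, end).
from_gr <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  sort_intervals(df)
}

sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a PeakSet
#'
#' A PeakSet holds the peak calls of one sequencing experiment together with
#' its metadata, mirroring one ChIP-Atlas-style experiment record.
#'
#' @param intervals data.frame of intervals (see [genomic_intervals()]).
#' @param experiment_id experiment identifier, unique within a library.
#' @param antigen TF or assay label (e.g. the ChIP'd factor).
#' @param cell_type_class cell-type class label.
#' @param genome genome build label; all intervals share it.
#' @return object of class \code{PeakSet}.
#' @export
peak_set <- function(intervals, experiment_id, antigen = NA_character_,
                     cell_type_class = NA_character_, genome) {
  validate_intervals(intervals, "PeakSet intervals")
  stopifnot(is.character(experiment_id), length(experiment_id) == 1L,
            nzchar(experiment_id),
            is.character(genome) || is.na(genome), length(genome) == 1L)
  rownames(intervals) <- NULL
  structure(list(experiment_id = experiment_id,
                 antigen = as.character(antigen),
                 cell_type_class = as.character(cell_type_class),
                 genome = as.character(genome),
                 intervals = intervals),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet %s (antigen %s, %s, genome %s): %d intervals\n",
              x$experiment_id, x$antigen, x$cell_type_class, x$genome,
              nrow(x$intervals)))
  invisible(x)
}

#' Read a BED3/BED5 file into a PeakSet
#'
#' Tab-separated, no header; \code{track}, \code{browser} and \code{#} lines
#' are skipped. Column 5, when present, is stored as the peak score
#' (\code{int(-10 log10 Q)} under the MACS2 convention); extra columns are
#' ignored. File order is preserved.
#'
#' @param path BED file path.
#' @param genome genome build label to record on the PeakSet.
#' @param experiment_id,antigen,cell_type_class metadata (see [peak_set()]).
#' @param chr_normalize if TRUE, prefix chromosome names lacking "chr".
#' @return PeakSet; an empty file yields a PeakSet with zero intervals.
#' @export
read_bed <- function(path, genome = NA_character_,
                     experiment_id = basename(path),
                     antigen = NA_character_,
                     cell_type_class = NA_character_,
                     chr_normalize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    ivs <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    return(peak_set(ivs, experiment_id, antigen, cell_type_class, genome))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s: line %d has %d column(s); BED needs >= 3",
                 path, idx[which(nf < 3L)[1L]], min(nf)), call. = FALSE)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s: non-integer coordinate at line %d", path, idx[bad[1L]]),
         call. = FALSE)
  bad <- which(end <= start | start < 0L)
  if (length(bad))
    stop(sprintf("%s: invalid interval (need 0 <= start < end) at line %d",
                 path, idx[bad[1L]]), call. = FALSE)
  if (chr_normalize) chrom <- ifelse(grepl("^chr", chrom), chrom,
                                     paste0("chr", chrom))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (any(nf >= 5L)) {
    sc <- rep(NA_character_, length(fields))
    has5 <- nf >= 5L
    sc[has5] <- vapply(fields[has5], `[[`, character(1), 5L)
    sc[sc == "."] <- NA_character_
    score <- suppressWarnings(as.integer(sc))
    badsc <- which(!is.na(sc) & (is.na(score) | score < 0L))
    if (length(badsc))
      stop(sprintf("%s: score must be a non-negative integer at line %d",
                   path, idx[badsc[1L]]), call. = FALSE)
    df$score <- score
  }
  peak_set(df, experiment_id, antigen, cell_type_class, genome)
}

#' Write a PeakSet as BED
#'
#' Emits 3 columns when no scores are present, otherwise 5 columns with
#' names autogenerated as \code{<experiment_id>.<index>}. Scores are clamped
#' to \code{[0, 1000]} per the BED convention. Newline-terminated.
#'
#' @param peaks PeakSet.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  df <- peaks$intervals
  has_score <- "score" %in% names(df) && nrow(df) > 0L && !all(is.na(df$score))
  if (has_score && any(is.na(df$score)))
    stop("cannot write BED5: some intervals lack a score", call. = FALSE)
  if (nrow(df) == 0L) {
    lines <- character()
  } else if (has_score) {
    lines <- paste(df$chrom, df$start, df$end,
                   paste0(peaks$experiment_id, ".", seq_len(nrow(df))),
                   pmin(pmax(df$score, 0L), 1000L), sep = "\t")
  } else {
    lines <- paste(df$chrom, df$start, df$end, sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Filter a PeakSet by peak score
#'
#' \code{min_score = 100} corresponds to a MACS2 peak-call Q value
#' \code{<= 1e-10} under the \code{int(-10 log10 Q)} score convention, the
#' default stringency for both the ATAC-seq and ChIP-seq libraries.
#'
#' @param peaks PeakSet whose intervals all carry scores.
#' @param min_score retain intervals with \code{score >= min_score}.
#' @return filtered PeakSet.
#' @export
filter_by_score <- function(peaks, min_score) {
  stopifnot(inherits(peaks, "PeakSet"), length(min_score) == 1L,
            !is.na(min_score))
  df <- peaks$intervals
  if (nrow(df) > 0L && (!"score" %in% names(df) || any(is.na(df$score))))
    stop("PeakSet has intervals without scores; ",
         "use 3-column sets unfiltered or supply scores", call. = FALSE)
  keep <- if (nrow(df) == 0L) logical(0) else df$score >= min_score
  out <- peaks
  out$intervals <- df[keep, , drop = FALSE]
  rownames(out$intervals) <- NULL
  out
}

#' Count query intervals overlapping a peak set
#'
#' Returns the number of DISTINCT query intervals that overlap >= 1 bp with
#' >= 1 peak, under half-open semantics (\code{[10,20)} and \code{[20,30)}
#' do not overlap). Each query counts at most once however many peaks it
#' touches; this is the binary per-region intersect count that feeds the
#' 2x2 enrichment table.
#'
#' @param queries interval data.frame (or PeakSet).
#' @param peaks PeakSet (or interval data.frame).
#' @return non-negative integer; empty inputs give 0.
#' @export
count_overlapping_queries <- function(queries, peaks) {
  qdf <- if (inherits(queries, "PeakSet")) queries$intervals else queries
  pdf <- if (inherits(peaks, "PeakSet")) peaks$intervals else peaks
  if (nrow(qdf) == 0L || nrow(pdf) == 0L) return(0L)
  lv <- pair_levels(qdf, pdf)
  hits <- GenomicRanges::countOverlaps(as_gr(qdf, lv), as_gr(pdf, lv),
                                       ignore.strand = TRUE)
  sum(hits > 0L)
}

#' Read a peak-library manifest
#'
#' The manifest is a TSV with header columns \code{experiment_id, antigen,
#' cell_type_class, genome, path}; relative paths resolve against the
#' manifest's directory.
#'
#' @param manifest_path manifest TSV.
#' @param cell_type_class_filter optional: keep only experiments of this
#'   cell-type class.
#' @param chr_normalize passed to [read_bed()].
#' @return list of PeakSet, named by experiment_id.
#' @export
read_peak_library <- function(manifest_path, cell_type_class_filter = NULL,
                              chr_normalize = FALSE) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "antigen", "cell_type_class", "genome", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$experiment_id))
    stop("experiment_id must be unique within a library", call. = FALSE)
  if (!is.null(cell_type_class_filter))
    man <- man[man$cell_type_class == cell_type_class_filter, , drop = FALSE]
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^/", man$path), man$path, file.path(base, man$path))
  sets <- lapply(seq_len(nrow(man)), function(i)
    read_bed(paths[i], genome = man$genome[i],
             experiment_id = man$experiment_id[i],
             antigen = man$antigen[i],
             cell_type_class = man$cell_type_class[i],
             chr_normalize = chr_normalize))
  names(sets) <- man$experiment_id
  sets
}
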