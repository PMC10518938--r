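#' Construct a DARSet
#'
#' Opened DARs are exposure-specific accessible regions; closed DARs are
#' control-specific ones. By construction the two sets never overlap; the
#' constructor verifies this.
#'
#' @param opened,closed interval data.frames (may be empty).
#' @param condition_id perturbation label (e.g. chemical+tissue+dose).
#' @param genome genome build label.
#' @return object of class \code{DARSet}.
#' @export
dar_set <- function(opened, closed, condition_id, genome = NA_character_) {
  validate_intervals(opened, "opened DARs")
  validate_intervals(closed, "closed DARs")
  if (nrow(opened) > 0L && nrow(closed) > 0L &&
      count_overlapping_queries(opened, closed) > 0L)
    stop("opened and closed DARs overlap; DAR sets must be disjoint",
         call. = FALSE)
  structure(list(condition_id = as.character(condition_id),
                 genome = as.character(genome),
                 opened = sort_intervals(opened[, c("chrom", "start", "end")]),
                 closed = sort_intervals(closed[, c("chrom", "start", "end")])),
            class = "DARSet")
}

#' @export
print.DARSet <- function(x, ...) {
  cat(sprintf("DARSet %s (genome %s): %d opened, %d closed\n",
              x$condition_id, x$genome, nrow(x$opened), nrow(x$closed)))
  invisible(x)
}

#' Genomic intersection of replicate peak sets
#'
#' Returns the maximal sub-intervals covered by at least one peak in EVERY
#' replicate -- the bp-level intersection a \code{bedtools intersect} chain
#' produces, not a per-peak voting rule. Output is sorted by (chrom, start)
#' and non-overlapping.
#'
#' @param replicates list of PeakSet, all on one genome build.
#' @return interval data.frame of common accessible regions.
#' @export
intersect_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  lapply(replicates, function(r) stopifnot(inherits(r, "PeakSet")))
  builds <- unique(vapply(replicates, `[[`, character(1), "genome"))
  if (length(builds[!is.na(builds)]) > 1L)
    stop("replicates are on mixed genome builds: ",
         paste(builds, collapse = ", "), call. = FALSE)
  grs <- lapply(replicates, function(r) GenomicRanges::reduce(as_gr(r)))
  common <- Reduce(function(x, y)
    suppressWarnings(GenomicRanges::intersect(x, y, ignore.strand = TRUE)),
    grs)
  from_gr(common)
}

#' Call opened and closed DARs between condition groups
#'
#' A DAR is a group-specific region with ZERO bp overlap against the other
#' group's common accessible regions: opened DARs are exposed-common
#' intervals untouched by any control-common interval, closed DARs the
#' converse. Intervals are kept whole, never truncated.
#'
#' @param exposed_common,control_common interval data.frames from
#'   [intersect_replicates()] (either may be empty).
#' @param condition_id perturbation label recorded on the result.
#' @param genome genome build label.
#' @return [dar_set()] object.
#' @export
detect_dars <- function(exposed_common, control_common, condition_id,
                        genome = NA_character_) {
  validate_intervals(exposed_common, "exposed_common")
  validate_intervals(control_common, "control_common")
  keep_disjoint <- function(x, other) {
    if (nrow(x) == 0L) return(x)
    if (nrow(other) == 0L) return(x)
    lv <- pair_levels(x, other)
    hits <- GenomicRanges::countOverlaps(as_gr(x, lv), as_gr(other, lv),
                                         ignore.strand = TRUE)
    x[hits == 0L, , drop = FALSE]
  }
  opened <- keep_disjoint(exposed_common[, c("chrom", "start", "end")],
                          control_common)
  closed <- keep_disjoint(control_common[, c("chrom", "start", "end")],
                          exposed_common)
  dar_set(opened, closed, condition_id, genome)
}

#' Write a DARSet as two BED3 files
#'
#' @param dars DARSet.
#' @param dir output directory (created if absent).
#' @return character vector of the two paths
#'   (\code{<condition>.opened.bed}, \code{<condition>.closed.bed}).
#' @export
write_dar_set <- function(dars, dir) {
  stopifnot(inherits(dars, "DARSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(dars$condition_id,
                                 c(".opened.bed", ".closed.bed")))
  write_bed(peak_set(dars$opened, paste0(dars$condition_id, ".opened"),
                     genome = dars$genome), paths[1L])
  write_bed(peak_set(dars$closed, paste0(dars$condition_id, ".closed"),
                     genome = dars$genome), paths[2L])
  invisible(paths)
}

#' Read a gene-annotation table
#'
#' TSV with header columns \code{symbol, chrom, tss, strand}; \code{tss} is
#' the 0-based transcription start site coordinate (strand determines which
#' gene end the TSS is, upstream of this function).
#'
#' @param path annotation TSV.
#' @return data.frame with those columns.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "chrom", "tss", "strand")
  if (!all(need %in% names(ann)))
    stop("gene annotation must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (any(ann$tss < 0)) stop("tss must be >= 0", call. = FALSE)
  ann$tss <- as.integer(ann$tss)
  ann
}

#' Convert gene symbols to TSS windows
#'
#' Emits \code{[tss - flank, tss + flank)} for each resolvable symbol --
#' symmetric about the TSS regardless of strand -- clamped to \code{[0,
#' chrom length)} when sizes are provided. Duplicate windows are collapsed;
#' unresolvable symbols are returned in the \code{skipped} attribute.
#'
#' @param symbols character vector of gene symbols.
#' @param annotation data.frame from [read_gene_annotation()].
#' @param flank half-window size in bp (default 5000, i.e. 5 kb upstream
#'   and downstream of the TSS).
#' @param chrom_sizes optional named vector chrom -> length (bp).
#' @return interval data.frame with attribute \code{skipped}.
#' @export
genes_to_windows <- function(symbols, annotation, flank = 5000L,
                             chrom_sizes = NULL) {
  stopifnot(flank > 0L)
  symbols <- unique(as.character(symbols))
  ann <- annotation[!duplicated(annotation$symbol), , drop = FALSE]
  hit <- match(symbols, ann$symbol)
  skipped <- symbols[is.na(hit)]
  found <- ann[hit[!is.na(hit)], , drop = FALSE]
  if (nrow(found) == 0L)
    stop("no symbol resolved against the annotation; ",
         "an empty query cannot be tested", call. = FALSE)
  start <- pmax(0L, found$tss - as.integer(flank))
  end <- found$tss + as.integer(flank)
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[found$chrom]
    if (any(is.na(len)))
      stop("chrom_sizes lacks: ",
           paste(unique(found$chrom[is.na(len)]), collapse = ", "),
           call. = FALSE)
    end <- pmin(end, as.integer(len))
  }
  df <- data.frame(chrom = found$chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- unique(sort_intervals(df))
  rownames(df) <- NULL
  validate_intervals(df, "TSS windows")
  attr(df, "skipped") <- skipped
  df
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (chrom, length), no header required if columns are
#' unnamed; returns a named vector.
#'
#' @param path TSV path.
#' @return named integer vector chrom -> length.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(tab[1L, 1L])), "chrom"))
    tab <- tab[-1L, , drop = FALSE]
  stats::setNames(as.integer(tab[[2L]]), as.character(tab[[1L]]))
}
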