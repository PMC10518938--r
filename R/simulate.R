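#' Simulation configuration
#'
#' Defines the study conditions for the toy-genome simulator: a small
#' multi-chromosome genome, planted opened/closed accessible loci, replicate
#' ATAC-seq peak sets with edge jitter, a ChIP-seq peak library in which a
#' subset of TFs is planted with elevated overlap of the opened loci, and
#' consistent TF-disease / chemical-disease tables.
#'
#' @param seed master seed; each generator stage derives its own stream
#'   from it by a fixed offset, so e.g. changing \code{n_tfs} does not
#'   perturb DAR placement.
#' @param n_chroms,chrom_length genome shape (chromosomes x bp).
#' @param n_dars_opened,n_dars_closed planted locus counts per side.
#' @param dar_width planted locus width (bp).
#' @param n_replicates ATAC replicates per group.
#' @param jitter maximum per-replicate, per-edge peak jitter (bp); placed
#'   loci keep enough clearance that jitter can never create cross-group
#'   overlap, so the group non-overlap DAR criterion is preserved.
#' @param n_background accessible background peaks shared by both groups.
#' @param n_tfs,experiments_per_tf library shape.
#' @param peak_width ChIP-seq peak width (bp).
#' @param n_decoys uniform decoy peaks per experiment.
#' @param p_fg probability a planted TF's experiment covers an opened
#'   locus (foreground overlap rate).
#' @param p_bg background overlap rate (non-planted TFs on opened loci;
#'   every TF on closed loci). \code{p_fg = p_bg} yields a null library.
#' @param planted_tfs labels of the planted TFs (default the first two).
#' @param n_diseases disease vocabulary size; each planted TF gets one
#'   dedicated "true" disease.
#' @param n_noise_assoc random TF-disease noise links, drawn among
#'   non-planted TFs and non-true diseases so planted truth stays
#'   unambiguous.
#' @param condition_id,genome labels stamped on the outputs.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1000000L,
                       n_dars_opened = 200L, n_dars_closed = 200L,
                       dar_width = 500L, n_replicates = 2L, jitter = 25L,
                       n_background = 200L, n_tfs = 10L,
                       experiments_per_tf = 2L, peak_width = 300L,
                       n_decoys = 100L, p_fg = 0.9, p_bg = 0.1,
                       planted_tfs = NULL, n_diseases = 20L,
                       n_noise_assoc = 30L, condition_id = "cond01",
                       genome = "toy1") {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_dars_opened = as.integer(n_dars_opened),
              n_dars_closed = as.integer(n_dars_closed),
              dar_width = as.integer(dar_width),
              n_replicates = as.integer(n_replicates),
              jitter = as.integer(jitter),
              n_background = as.integer(n_background),
              n_tfs = as.integer(n_tfs),
              experiments_per_tf = as.integer(experiments_per_tf),
              peak_width = as.integer(peak_width),
              n_decoys = as.integer(n_decoys),
              p_fg = p_fg, p_bg = p_bg,
              planted_tfs = planted_tfs,
              n_diseases = as.integer(n_diseases),
              n_noise_assoc = as.integer(n_noise_assoc),
              condition_id = as.character(condition_id),
              genome = as.character(genome))
  if (is.null(cfg$planted_tfs))
    cfg$planted_tfs <- sprintf("TF%02d", seq_len(min(2L, cfg$n_tfs)))
  with(cfg, {
    stopifnot(n_chroms > 0L, chrom_length > 0L, n_dars_opened > 0L,
              n_dars_closed > 0L, dar_width > 0L, n_replicates > 0L,
              jitter >= 0L, n_background >= 0L, n_tfs > 0L,
              experiments_per_tf > 0L, peak_width > 0L, n_decoys >= 0L,
              p_bg >= 0, p_fg >= p_bg, p_fg <= 1)
  })
  if (!all(cfg$planted_tfs %in% sprintf("TF%02d", seq_len(cfg$n_tfs))))
    stop("planted_tfs must be among the TF labels TF01..TF",
         sprintf("%02d", cfg$n_tfs), call. = FALSE)
  if (cfg$n_diseases < length(cfg$planted_tfs) + 1L)
    stop("need n_diseases > number of planted TFs so every condition has ",
         "at least one negative disease", call. = FALSE)
  structure(cfg, class = "sim_config")
}

## one RNG stream per generator stage, derived from the master seed
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 4000000L) * 521L + stage * 7L + 11L
}

tf_labels <- function(config) sprintf("TF%02d", seq_len(config$n_tfs))

disease_labels <- function(config) sprintf("D%02d", seq_len(config$n_diseases))

## non-overlapping locus placement with a guaranteed inter-locus gap
place_loci <- function(config, gap) {
  n_total <- config$n_dars_opened + config$n_dars_closed
  per_chrom <- diff(round(seq(0, n_total,
                              length.out = config$n_chroms + 1L)))
  w <- config$dar_width
  out <- vector("list", config$n_chroms)
  for (i in seq_len(config$n_chroms)) {
    n_i <- per_chrom[i]
    if (n_i == 0L) next
    need <- n_i * (w + gap)
    if (need > config$chrom_length)
      stop("cannot place ", n_i, " loci of ", w, " bp with ", gap,
           " bp gaps on a ", config$chrom_length,
           " bp chromosome; enlarge the genome", call. = FALSE)
    u <- sort(stats::runif(n_i, 0, config$chrom_length - need))
    start <- as.integer(floor(u)) + (seq_len(n_i) - 1L) * (w + gap)
    out[[i]] <- data.frame(chrom = sprintf("chr%d", i), start = start,
                           end = start + w, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

jitter_edges <- function(df, jitter) {
  if (jitter == 0L || nrow(df) == 0L) return(df)
  delta <- seq(-jitter, jitter)
  df$start <- pmax(0L, df$start + sample(delta, nrow(df), replace = TRUE))
  df$end <- df$end + sample(delta, nrow(df), replace = TRUE)
  df
}

#' Simulate one perturbation condition's replicate peak sets
#'
#' Places non-overlapping opened-truth and closed-truth loci uniformly on
#' the toy genome (with clearance so jitter can never cross the group
#' non-overlap criterion), then emits exposed replicates covering opened
#' loci plus a shared accessible background, and control replicates
#' covering closed loci plus the same background, each with per-replicate
#' edge jitter. Peak scores are drawn at or above the default stringency
#' threshold of 100.
#'
#' @param config [sim_config()].
#' @return list with \code{exposed} and \code{control} (lists of PeakSet)
#'   and \code{truth} (condition_id, genome, opened/closed/background locus
#'   tables).
#' @export
simulate_condition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  gap <- 2L * config$jitter + 50L
  loci <- place_loci(config, gap)
  idx <- sample(nrow(loci))
  opened <- sort_intervals(loci[idx[seq_len(config$n_dars_opened)], ])
  closed <- sort_intervals(loci[idx[-seq_len(config$n_dars_opened)], ])

  # background shared by both groups, kept clear of all loci so replicate
  # jitter cannot bridge a background region into a planted locus
  clearance <- 2L * config$jitter + 5L
  bg <- data.frame(chrom = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
  if (config$n_background > 0L) {
    grown <- loci
    grown$start <- pmax(0L, grown$start - clearance)
    grown$end <- grown$end + clearance
    picked <- 0L
    rows <- vector("list", config$n_background)
    for (tries in seq_len(50L)) {
      n_draw <- (config$n_background - picked) * 2L + 10L
      cand <- data.frame(
        chrom = sprintf("chr%d", sample.int(config$n_chroms, n_draw,
                                            replace = TRUE)),
        start = as.integer(floor(stats::runif(
          n_draw, 0, config$chrom_length - config$dar_width))),
        stringsAsFactors = FALSE)
      cand$end <- cand$start + config$dar_width
      hits <- GenomicRanges::countOverlaps(as_gr(cand), as_gr(grown))
      cand <- cand[hits == 0L, , drop = FALSE]
      if (nrow(cand) > 0L) {
        take <- utils::head(cand, config$n_background - picked)
        rows[[tries]] <- take
        picked <- picked + nrow(take)
      }
      if (picked >= config$n_background) break
    }
    if (picked < config$n_background)
      stop("could not place background peaks clear of loci; ",
           "enlarge the genome", call. = FALSE)
    bg <- sort_intervals(do.call(rbind, rows[!vapply(rows, is.null,
                                                     logical(1))]))
    # background regions must also stay clear of each other across groups:
    # drop any that overlap another background region when grown by jitter
    grown_bg <- bg
    grown_bg$start <- pmax(0L, grown_bg$start - config$jitter)
    grown_bg$end <- grown_bg$end + config$jitter
    self_hits <- GenomicRanges::countOverlaps(as_gr(grown_bg), as_gr(grown_bg))
    bg <- bg[self_hits == 1L, , drop = FALSE]
  }

  truth <- list(condition_id = config$condition_id, genome = config$genome,
                opened = opened, closed = closed, background = bg)

  set.seed(stage_seed(config$seed, 2L))
  make_reps <- function(loci_side, label) {
    lapply(seq_len(config$n_replicates), function(r) {
      df <- sort_intervals(jitter_edges(rbind(loci_side, bg), config$jitter))
      df$score <- sample(100:1000, nrow(df), replace = TRUE)
      peak_set(df,
               experiment_id = sprintf("%s_%s_rep%d", config$condition_id,
                                       label, r),
               antigen = "ATAC", cell_type_class = "simulated",
               genome = config$genome)
    })
  }
  exposed <- make_reps(opened, "exposed")
  control <- make_reps(closed, "control")
  list(exposed = exposed, control = control, truth = truth)
}

#' Simulate a ChIP-seq peak library with planted enrichment
#'
#' For each TF x experiment, covers each opened-truth locus with a centered
#' peak with probability \code{p_fg} when the TF is planted (else
#' \code{p_bg}), and each closed-truth locus with probability \code{p_bg};
#' uniform decoy peaks are added on top. Peak scores are at or above the
#' default filter threshold of 100.
#'
#' @param config [sim_config()].
#' @param truth truth record from [simulate_condition()].
#' @return named list of PeakSet (one per experiment).
#' @export
simulate_library <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 3L))
  classes <- c("Blood", "Liver", "Kidney")
  cover_peaks <- function(loci, p) {
    hit <- stats::runif(nrow(loci)) < p
    sub <- loci[hit, , drop = FALSE]
    if (nrow(sub) == 0L) return(sub[, c("chrom", "start", "end")])
    centre <- (sub$start + sub$end) %/% 2L
    half <- config$peak_width %/% 2L
    data.frame(chrom = sub$chrom,
               start = pmax(sub$start, centre - half),
               end = pmin(sub$end, centre - half + config$peak_width),
               stringsAsFactors = FALSE)
  }
  lib <- list()
  for (i in seq_len(config$n_tfs)) {
    tf <- tf_labels(config)[i]
    p_open <- if (tf %in% config$planted_tfs) config$p_fg else config$p_bg
    for (e in seq_len(config$experiments_per_tf)) {
      peaks <- rbind(cover_peaks(truth$opened, p_open),
                     cover_peaks(truth$closed, config$p_bg))
      if (config$n_decoys > 0L) {
        dstart <- as.integer(floor(stats::runif(
          config$n_decoys, 0, config$chrom_length - config$peak_width)))
        peaks <- rbind(peaks, data.frame(
          chrom = sprintf("chr%d", sample.int(config$n_chroms,
                                              config$n_decoys,
                                              replace = TRUE)),
          start = dstart, end = dstart + config$peak_width,
          stringsAsFactors = FALSE))
      }
      peaks <- sort_intervals(peaks)
      peaks$score <- sample(100:1000, nrow(peaks), replace = TRUE)
      id <- sprintf("%s_e%02d", tf, e)
      lib[[id]] <- peak_set(peaks, experiment_id = id, antigen = tf,
                            cell_type_class = classes[(i - 1L) %%
                                                        length(classes) + 1L],
                            genome = config$genome)
    }
  }
  lib
}

#' Simulate consistent TF-disease and chemical-disease tables
#'
#' Links each planted TF to one dedicated "true" disease and adds random
#' noise links among non-planted TFs and non-true diseases; the standard
#' marks the (condition, true disease) pairs positive. Every condition is
#' guaranteed at least one positive and one negative disease column.
#'
#' @param config [sim_config()].
#' @param truth truth record from [simulate_condition()].
#' @return list with \code{assoc} (antigen, disease_id, source) and
#'   \code{standard} (condition_id, disease_id).
#' @export
simulate_associations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 4L))
  diseases <- disease_labels(config)
  n_planted <- length(config$planted_tfs)
  true_dis <- diseases[seq_len(n_planted)]
  assoc <- data.frame(antigen = config$planted_tfs, disease_id = true_dis,
                      source = "planted", stringsAsFactors = FALSE)
  other_tfs <- setdiff(tf_labels(config), config$planted_tfs)
  other_dis <- setdiff(diseases, true_dis)
  if (config$n_noise_assoc > 0L && length(other_tfs) > 0L &&
      length(other_dis) > 0L) {
    pool <- expand.grid(antigen = other_tfs, disease_id = other_dis,
                        stringsAsFactors = FALSE)
    take <- sample.int(nrow(pool), min(config$n_noise_assoc, nrow(pool)))
    noise <- pool[sort(take), , drop = FALSE]
    noise$source <- "noise"
    assoc <- rbind(assoc, noise)
  }
  rownames(assoc) <- NULL
  standard <- data.frame(condition_id = truth$condition_id,
                         disease_id = true_dis, stringsAsFactors = FALSE)
  list(assoc = assoc, standard = standard)
}

#' Simulate a complete input set for one condition
#'
#' Bundles [simulate_condition()], [simulate_library()] and
#' [simulate_associations()].
#'
#' @param config [sim_config()].
#' @return list with \code{exposed}, \code{control}, \code{library},
#'   \code{assoc}, \code{standard}, \code{truth}.
#' @export
simulate_dataset <- function(config) {
  cond <- simulate_condition(config)
  lib <- simulate_library(config, cond$truth)
  tabs <- simulate_associations(config, cond$truth)
  list(exposed = cond$exposed, control = cond$control, library = lib,
       assoc = tabs$assoc, standard = tabs$standard, truth = cond$truth)
}

#' Write a simulated dataset to a directory tree
#'
#' Emits replicate BEDs under \code{replicates/}, library BEDs plus a
#' manifest under \code{library/}, association TSVs under \code{assoc/},
#' and the truth record as \code{truth.json}. Output is a pure function of
#' the configuration: the same seed rewrites byte-identical files.
#'
#' @param dataset list from [simulate_dataset()].
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(dataset, dir) {
  for (d in file.path(dir, c("replicates", "library", "assoc")))
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  for (ps in c(dataset$exposed, dataset$control))
    write_bed(ps, file.path(dir, "replicates",
                            paste0(ps$experiment_id, ".bed")))
  man <- data.frame(
    experiment_id = vapply(dataset$library, `[[`, character(1),
                           "experiment_id"),
    antigen = vapply(dataset$library, `[[`, character(1), "antigen"),
    cell_type_class = vapply(dataset$library, `[[`, character(1),
                             "cell_type_class"),
    genome = vapply(dataset$library, `[[`, character(1), "genome"),
    stringsAsFactors = FALSE)
  man$path <- paste0(man$experiment_id, ".bed")
  for (ps in dataset$library)
    write_bed(ps, file.path(dir, "library", paste0(ps$experiment_id, ".bed")))
  utils::write.table(man, file.path(dir, "library", "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$assoc, file.path(dir, "assoc", "tf_disease.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$standard, file.path(dir, "assoc", "standard.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
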