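# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: plain loops and choose() arithmetic, no
# GenomicRanges, no dhyper, no p.adjust.

rand_intervals <- function(n, n_chroms = 3L, max_pos = 5000L, max_w = 150L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sprintf("chr%d", sample.int(n_chroms, n, replace = TRUE)),
             start = start,
             end = start + sample.int(max_w, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# all-pairs scan: number of query intervals overlapping >= 1 bp with any peak
brute_count_overlaps <- function(q, p) {
  n <- 0L
  for (i in seq_len(nrow(q))) {
    if (any(p$chrom == q$chrom[i] & p$start < q$end[i] & p$end > q$start[i]))
      n <- n + 1L
  }
  n
}

# union-merge of possibly overlapping/touching intervals
merge_union <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- df[1L, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1L]) {
    last <- nrow(out)
    if (df$chrom[i] == out$chrom[last] && df$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], df$end[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

# bp-level intersection of two interval sets by explicit pairwise clipping
brute_intersect_pair <- function(x, y) {
  pieces <- list()
  k <- 0L
  for (i in seq_len(nrow(x))) {
    sel <- which(y$chrom == x$chrom[i] & y$start < x$end[i] &
                   y$end > x$start[i])
    for (j in sel) {
      k <- k + 1L
      pieces[[k]] <- data.frame(chrom = x$chrom[i],
                                start = max(x$start[i], y$start[j]),
                                end = min(x$end[i], y$end[j]),
                                stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  merge_union(do.call(rbind, pieces))
}

# two-tailed Fisher p by explicit table enumeration with choose()
fisher_enum <- function(a, b, c, d, tol = 1e-7) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  xs <- max(0L, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(m1 + m2, k)
  min(1, sum(pr[pr <= pr[xs == a] * (1 + tol)]))
}

# hand step-up Benjamini-Hochberg
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# AUROC as explicit pairwise comparison with half credit for ties
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y)))
}

# AUPR by explicit threshold enumeration
aupr_thresholds <- function(scores, labels) {
  n1 <- sum(labels)
  area <- 0
  prev_recall <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= t
    tp <- sum(labels & sel)
    recall <- tp / n1
    area <- area + (recall - prev_recall) * (tp / sum(sel))
    prev_recall <- recall
  }
  area
}

# chemical x disease max score by an explicit three-loop join
triad_oracle <- function(results_list, assoc, diseases) {
  conditions <- names(results_list)
  score <- matrix(0, length(conditions), length(diseases),
                  dimnames = list(conditions, diseases))
  mediator <- matrix("", length(conditions), length(diseases),
                     dimnames = list(conditions, diseases))
  for (i in seq_along(conditions)) {
    res <- results_list[[i]]
    for (j in seq_along(diseases)) {
      best <- -Inf
      best_tfs <- character()
      for (r in seq_len(nrow(assoc))) {
        if (assoc$disease_id[r] != diseases[j]) next
        tf <- toupper(assoc$antigen[r])
        hit <- which(toupper(res$antigen) == tf)
        if (length(hit) == 0L) next
        s <- max(res$enrichment_score[hit])
        if (s > best) {
          best <- s
          best_tfs <- tf
        } else if (s == best) {
          best_tfs <- c(best_tfs, tf)
        }
      }
      if (is.finite(best) && best > 0) {
        score[i, j] <- best
        mediator[i, j] <- sort(best_tfs)[1L]
      }
    }
  }
  list(score = score, mediator = mediator)
}

# quick literal-interval constructor for tests
iv <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1L]], start = as.integer(r[[2L]]),
               end = as.integer(r[[3L]]), stringsAsFactors = FALSE)))
}

md5_of <- function(paths) unname(tools::md5sum(sort(paths)))
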