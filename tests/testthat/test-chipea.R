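test_that("two-tailed Fisher test matches worked enumerations", {
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1.0)
  # margins (4,4)/(4,4): qualifying tables sum to 34/70
  expect_equal(fisher_exact_two_tailed(3, 1, 1, 3), 34 / 70)
  # only the two extreme tables qualify
  expect_equal(fisher_exact_two_tailed(0, 10, 10, 0), 2 / choose(20, 10))
  expect_error(fisher_exact_two_tailed(-1, 1, 1, 1), "non-negative")
  expect_warning(p <- fisher_exact_two_tailed(0, 0, 3, 2), "degenerate")
  expect_equal(p, 1)
  expect_warning(fisher_exact_two_tailed(0, 5, 0, 5), "degenerate")
})

test_that("Fisher test agrees with stats::fisher.test on random tables", {
  set.seed(41)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + c(1, 0, 0, 1), 2)
    expect_equal(fisher_exact_two_tailed(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand step-up", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.5, 0.6)), c(0.6, 0.6))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_equal(bh_adjust(numeric()), numeric())
})

planted_fixture <- function(seed = 5) {
  cfg <- sim_config(seed = seed, n_dars_opened = 100L, n_dars_closed = 100L,
                    n_tfs = 10L, experiments_per_tf = 1L,
                    planted_tfs = "TF01", n_decoys = 20L)
  ds <- simulate_dataset(cfg)
  dars <- detect_dars(intersect_replicates(ds$exposed),
                      intersect_replicates(ds$control),
                      cfg$condition_id, cfg$genome)
  list(cfg = cfg, ds = ds, dars = dars)
}

test_that("enrich builds exact 2x2 tables and the planted TF wins", {
  fx <- planted_fixture()
  res <- enrich(fx$dars, fx$ds$library)
  # margin conservation across all experiments
  expect_true(all(res$a + res$b == nrow(fx$dars$opened)))
  expect_true(all(res$c + res$d == nrow(fx$dars$closed)))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_true(all(res$enrichment_score >= 0))
  # p and q recomputed by the independent oracles
  p_oracle <- mapply(fisher_enum, res$a, res$b, res$c, res$d)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$q_value, bh_stepup(p_oracle), tolerance = 1e-12)
  # the single planted experiment attains the maximum enrichment score
  expect_equal(res$antigen[which.max(res$enrichment_score)], "TF01")
})

test_that("enrich is symmetric under swapping opened and closed", {
  fx <- planted_fixture(seed = 6)
  res <- enrich(fx$dars, fx$ds$library)
  swapped <- dar_set(fx$dars$closed, fx$dars$opened, "swap", fx$cfg$genome)
  res2 <- enrich(swapped, fx$ds$library)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$log2_fold_enrichment, -res$log2_fold_enrichment)
  # equal margins here, so the fold-enrichment sign tracks the rates
  rate_up <- res$a / (res$a + res$b) > res$c / (res$c + res$d)
  expect_equal(res$log2_fold_enrichment > 0, rate_up)
})

test_that("BH family is the enrich call: permuting the library leaves q fixed", {
  fx <- planted_fixture(seed = 7)
  res <- enrich(fx$dars, fx$ds$library)
  set.seed(1)
  res2 <- enrich(fx$dars, sample(fx$ds$library))
  m1 <- setNames(res$q_value, res$experiment_id)
  m2 <- setNames(res2$q_value, res2$experiment_id)
  expect_equal(m2[names(m1)], m1)
})

test_that("enrich refuses empty DAR sides and mismatched builds", {
  fx <- planted_fixture()
  empty <- fx$dars
  empty$opened <- empty$opened[0, ]
  expect_error(enrich(empty, fx$ds$library), "cannot be tested")
  other <- fx$ds$library[[1]]
  other$genome <- "other"
  expect_error(enrich(fx$dars, list(other)), "mismatch")
  # an experiment with no peaks near any DAR: p = 1, score 0
  far <- peak_set(iv(list("chrZ", 0, 10)), "far", antigen = "FAR",
                  genome = fx$cfg$genome)
  res <- suppressWarnings(enrich(fx$dars, list(far)))
  expect_equal(res$p_value, 1)
  expect_equal(res$enrichment_score, 0)
  expect_equal(res$log2_fold_enrichment, 0)  # equal margins in this fixture
})

test_that("collapse_by_antigen keeps the best experiment per antigen", {
  res <- data.frame(
    experiment_id = c("e1", "e2", "e3", "e4", "e5"),
    antigen = c("X", "X", "Y", "Z", "Z"),
    cell_type_class = "c",
    a = 1L, b = 1L, c = 1L, d = 1L, p_value = 0.5, q_value = 0.5,
    enrichment_score = c(5, 8, 2, 3, 3),
    log2_fold_enrichment = c(1, 1, 1, 0.4, -1.2),
    stringsAsFactors = FALSE)
  col <- collapse_by_antigen(res)
  expect_equal(nrow(col), 3L)  # one row per distinct antigen
  expect_equal(col$experiment_id[col$antigen == "X"], "e2")
  # tie at score 3: larger |log2 fold enrichment| wins
  expect_equal(col$experiment_id[col$antigen == "Z"], "e5")
  # residual tie: lexicographically smallest experiment_id
  res$log2_fold_enrichment[4:5] <- 1
  expect_equal(collapse_by_antigen(res)$experiment_id[3], "e4")
  expect_equal(collapse_by_antigen(res[3, ]), res[3, ], ignore_attr = TRUE)
})

test_that("enrichment tables round-trip through TSV at 6 significant digits", {
  fx <- planted_fixture()
  res <- enrich(fx$dars, fx$ds$library)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- read_enrichment(path)
  expect_equal(back$experiment_id, res$experiment_id)
  expect_equal(back$a, res$a)
  expect_equal(back$q_value, res$q_value, tolerance = 1e-5)
  expect_equal(back$enrichment_score, res$enrichment_score, tolerance = 1e-5)
})
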