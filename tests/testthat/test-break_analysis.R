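test_that("fibril summaries count labels, runs and switches as defined", {
  s <- summarize_fibril(c("A", "A", "A", "B", "B"))
  expect_equal(s$n_A, 3)
  expect_equal(s$n_B, 2)
  expect_equal(s$fraction_B, 0.4)
  expect_equal(s$n_runs, 2)
  expect_equal(s$n_switches, 1)
  expect_equal(s$purity_class, "mixed")

  s2 <- summarize_fibril(c("A", "A", "A"))
  expect_equal(s2$fraction_B, 0)
  expect_equal(s2$n_switches, 0)
  expect_equal(s2$purity_class, "pure_A")

  # runs are computed over the labeled subsequence; UNASSIGNED is skipped
  s3 <- summarize_fibril(c("A", "UNASSIGNED", "A", "B", "UNASSIGNED",
                           "B", "A"))
  expect_equal(s3$n_runs, 3)
  expect_equal(s3$n_switches, 2)
  expect_equal(s3$n_unassigned, 2)

  s4 <- summarize_fibril(character(0))
  expect_equal(s4$purity_class, "unlabeled")
  expect_true(is.na(s4$fraction_B))
  expect_equal(s4$n_runs, 0)

  s5 <- summarize_fibril(rep("UNASSIGNED", 4))
  expect_equal(s5$purity_class, "unlabeled")
})

test_that("run counting matches the brute-force oracle (exhaustive + random)", {
  # exhaustive over all sequences of length <= 7 on {A, B, UNASSIGNED}
  alph <- c("A", "B", "UNASSIGNED")
  for (len in 1:7) {
    grid <- as.matrix(expand.grid(rep(list(alph), len),
                                  stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      labels <- grid[i, ]
      s <- summarize_fibril(labels)
      expect_identical(s$n_runs, brute_run_count(labels))
      expect_identical(s$n_switches, max(s$n_runs - 1L, 0L))
      expect_identical(s$n_A + s$n_B + s$n_unassigned, s$n_segments)
    }
  }
  # random longer sequences
  set.seed(31)
  for (rep in 1:200) {
    labels <- sample(alph, sample(8:40, 1), replace = TRUE)
    expect_identical(summarize_fibril(labels)$n_runs,
                     brute_run_count(labels))
  }
})

test_that("gap splitting terminates runs across large axial gaps", {
  labels <- c("A", "A", "UNASSIGNED", "A", "B")
  pos <- c(0, 33.6, 67.2, 436.8, 470.4)
  # default: the run spans the unassigned gap
  expect_equal(summarize_fibril(labels)$n_runs, 2)
  # with a 100 A gap threshold the A run is split at the 403 A jump
  s <- summarize_fibril(labels, axial_pos = pos, break_at_gap = 100)
  expect_equal(s$n_runs, 3)
  expect_error(summarize_fibril(labels, break_at_gap = 100), "axial_pos")
})

test_that("fraction histogram normalises within threshold categories", {
  summaries <- data.frame(
    n_A = c(3, 2, 0, 1), n_B = c(0, 0, 1, 1),
    fraction_B = c(0, 0, 1, 0.5),
    purity_class = c("pure_A", "pure_A", "pure_B", "mixed")
  )
  h <- fraction_histogram(summaries, thresholds = 1, n_bins = 2)
  expect_equal(as.numeric(h$percentages), c(50, 50))
  expect_equal(as.numeric(h$counts), c(2, 2))

  # a fibril with 3 labeled segments appears only in the min-1 category
  h2 <- fraction_histogram(summaries[1, , drop = FALSE],
                           thresholds = c(1, 5))
  expect_equal(unname(h2$n_fibrils), c(1L, 0L))
  expect_true(h2$empty[["min_5"]])
  expect_true(all(is.na(h2$percentages["min_5", ])))
  expect_error(fraction_histogram(summaries, thresholds = 0), "positive")
})

test_that("histogram percentages sum to 100 and counts shrink with threshold", {
  cfg <- synthetic_config(n_fibrils = 1000, seed = 77)
  s <- fibril_summaries(generate_fibrils(cfg)$table)
  h <- fraction_histogram(s, thresholds = c(1, 5, 10, 20))
  for (k in seq_along(h$thresholds)) {
    if (!h$empty[k]) {
      expect_equal(sum(h$percentages[k, ]), 100, tolerance = 1e-9)
    }
  }
  expect_true(all(diff(unname(h$n_fibrils)) <= 0))
  # bin counts conserve fibrils within each category
  labeled <- s$n_A + s$n_B
  expect_equal(unname(h$n_fibrils),
               vapply(h$thresholds, function(t) sum(labeled >= t),
                      integer(1)))
})

test_that("permutation test: degenerate two-segment fibril gives p = 1", {
  tab <- one_fibril_table(c("A", "B"))
  res <- permutation_test_clustering(tab, n_permutations = 500, seed = 1)
  expect_equal(res$statistic_observed, 1)
  expect_equal(res$p_value, 1)
})

test_that("permutation test approximates the exhaustive single-fibril null", {
  labels <- c(rep("A", 5), rep("B", 5))
  oracle <- exact_clustering_p(labels)
  expect_equal(oracle$p, 2 / 252)
  expect_equal(oracle$n_arrangements, 252)

  tab <- one_fibril_table(labels)
  res <- permutation_test_clustering(tab, n_permutations = 20000, seed = 5)
  mc_sd <- sqrt(oracle$p * (1 - oracle$p) / res$n_permutations)
  expect_lt(abs(res$p_value - oracle$p), 3 * mc_sd + 1 / res$n_permutations)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
})

test_that("permutation test is reproducible given a seed and validates input", {
  cfg <- synthetic_config(n_fibrils = 30, seed = 8)
  tab <- generate_fibrils(cfg)$table
  r1 <- permutation_test_clustering(tab, n_permutations = 300, seed = 42)
  r2 <- permutation_test_clustering(tab, n_permutations = 300, seed = 42)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$null_mean, r2$null_mean)

  solo <- one_fibril_table("A")
  expect_error(permutation_test_clustering(solo, 100), "insufficient")
})

test_that("per-fibril p-values are reported with BH adjustment on request", {
  cfg <- synthetic_config(n_fibrils = 20,
                          length_distribution = list(kind = "fixed", n = 20),
                          p_switch = 0.02, epsilon = 0, seed = 9)
  tab <- generate_fibrils(cfg)$table
  res <- permutation_test_clustering(tab, n_permutations = 500, seed = 10,
                                     per_fibril = TRUE)
  pf <- res$per_fibril
  expect_s3_class(pf, "data.frame")
  expect_equal(nrow(pf), res$n_fibrils_tested)
  expect_true(all(pf$p_value >= 1 / 501 & pf$p_value <= 1))
  expect_equal(pf$p_adjust_BH, p.adjust(pf$p_value, method = "BH"))
})

test_that("mixture report tallies pure and mixed fibrils", {
  summaries <- data.frame(
    n_A = c(1, 2), n_B = c(1, 0), fraction_B = c(0.5, 0),
    purity_class = c("mixed", "pure_A")
  )
  rep1 <- mixture_report(summaries, min_segments = 1)
  expect_equal(unname(rep1$proportions["mixed"]), 0.5)

  pure <- data.frame(n_A = c(2, 0), n_B = c(0, 3), fraction_B = c(0, 1),
                     purity_class = c("pure_A", "pure_B"))
  rep2 <- mixture_report(pure)
  expect_equal(unname(rep2$proportions["mixed"]), 0)

  cfg <- synthetic_config(n_fibrils = 400, seed = 14)
  s <- fibril_summaries(generate_fibrils(cfg)$table)
  for (m in c(1, 5, 10)) {
    r <- mixture_report(s, min_segments = m)
    if (r$n_fibrils > 0) {
      expect_equal(sum(r$proportions), 1, tolerance = 1e-12)
      expect_equal(sum(r$counts), r$n_fibrils)
    }
  }
})
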