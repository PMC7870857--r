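#' Summarise one fibril's label sequence
#'
#' Computes the per-fibril conformational composition and run structure.
#' `UNASSIGNED` segments are excluded from fractions and runs: the labeled
#' subsequence is taken in axial order and a run is a maximal stretch of
#' identical labels within it, so a run may span an unassigned gap (final
#' reconstruction subsets cover fibrils sparsely). A switch is a boundary
#' between adjacent runs.
#'
#' @param labels Character vector of labels in axial order (`"A"`, `"B"`,
#'   `"UNASSIGNED"`).
#' @param axial_pos Optional numeric vector of axial positions (angstroms),
#'   same length as `labels`; only needed with `break_at_gap`.
#' @param break_at_gap Optional gap threshold in angstroms. When set, a run
#'   is additionally terminated wherever consecutive labeled segments are
#'   separated axially by more than this distance, so `n_runs` counts
#'   gap-split runs (two same-label runs separated by a large gap count
#'   twice). `n_switches` remains `n_runs - 1`. Default `NULL` (off).
#' @return An object of class `"fibril_summary"`: a list with `n_segments`,
#'   `n_A`, `n_B`, `n_unassigned`, `fraction_B` (`NA` if no labeled
#'   segment), `n_runs`, `n_switches` and `purity_class` (one of `"pure_A"`,
#'   `"pure_B"`, `"mixed"`, `"unlabeled"`).
#' @examples
#' summarize_fibril(c("A", "A", "A", "B", "B"))
#' @export
summarize_fibril <- function(labels, axial_pos = NULL, break_at_gap = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  labeled <- labels %in% c("A", "B")
  n_A <- sum(labels == "A")
  n_B <- sum(labels == "B")
  n_lab <- n_A + n_B
  lab <- labels[labeled]
  if (n_lab == 0) {
    n_runs <- 0L
    n_switches <- 0L
    fraction_B <- NA_real_
    purity <- "unlabeled"
  } else {
    boundary <- lab[-1] != lab[-n_lab]
    if (!is.null(break_at_gap)) {
      if (is.null(axial_pos) || length(axial_pos) != n) {
        stop("break_at_gap requires axial_pos of the same length as labels",
             call. = FALSE)
      }
      pos <- axial_pos[labeled]
      boundary <- boundary | (diff(pos) > break_at_gap)
    }
    n_runs <- 1L + sum(boundary)
    n_switches <- n_runs - 1L
    fraction_B <- n_B / n_lab
    purity <- if (n_B == 0) "pure_A" else if (n_A == 0) "pure_B" else "mixed"
  }
  structure(
    list(
      n_segments = n,
      n_A = n_A,
      n_B = n_B,
      n_unassigned = n - n_lab,
      fraction_B = fraction_B,
      n_runs = n_runs,
      n_switches = n_switches,
      purity_class = purity
    ),
    class = "fibril_summary"
  )
}

#' Per-fibril summaries for a whole segment table
#'
#' Applies [summarize_fibril()] to every fibril of a segment table.
#'
#' @inheritParams group_fibrils
#' @inheritParams summarize_fibril
#' @return A `data.frame` with one row per fibril: `micrograph_id`,
#'   `tube_id` and the fields of [summarize_fibril()].
#' @export
fibril_summaries <- function(table, break_at_gap = NULL) {
  chunks <- split_fibrils(table)
  if (!length(chunks)) {
    return(data.frame(
      micrograph_id = character(0), tube_id = integer(0),
      n_segments = integer(0), n_A = integer(0), n_B = integer(0),
      n_unassigned = integer(0), fraction_B = numeric(0),
      n_runs = integer(0), n_switches = integer(0),
      purity_class = character(0), stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(chunks, function(d) {
    s <- summarize_fibril(d$class_label, axial_pos = d$axial_pos,
                          break_at_gap = break_at_gap)
    data.frame(
      micrograph_id = d$micrograph_id[1], tube_id = d$tube_id[1],
      n_segments = s$n_segments, n_A = s$n_A, n_B = s$n_B,
      n_unassigned = s$n_unassigned, fraction_B = s$fraction_B,
      n_runs = s$n_runs, n_switches = s$n_switches,
      purity_class = s$purity_class, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Thresholded histogram of per-fibril B fractions
#'
#' Builds the B-fraction histogram over several minimum-segment thresholds.
#' A fibril belongs to threshold category `t` when its labeled-segment count
#' (`n_A + n_B`) is at least `t` (inclusive). Percentages are normalised
#' within each category by that category's fibril count; absolute counts are
#' retained. Bins are equal-width on \[0, 1\], left-closed, with the last
#' bin closed on the right.
#'
#' @param summaries A `data.frame` from [fibril_summaries()].
#' @param thresholds Positive integer vector of minimum labeled-segment
#'   counts. Default `c(1, 5, 10, 20)`.
#' @param n_bins Number of equal-width bins on \[0, 1\]. Default 10.
#' @return An object of class `"fraction_histogram"`: list with `breaks`,
#'   `thresholds`, `n_fibrils` (per category), `counts` and `percentages`
#'   (threshold x bin matrices) and `empty` (logical per category; an empty
#'   category is flagged, its percentages are `NA`).
#' @export
fraction_histogram <- function(summaries, thresholds = c(1, 5, 10, 20),
                               n_bins = 10) {
  if (!is.data.frame(summaries) || nrow(summaries) < 1) {
    stop("summaries must be a data.frame with at least one fibril",
         call. = FALSE)
  }
  if (any(thresholds < 1) || any(thresholds != floor(thresholds))) {
    stop("thresholds must be positive integers", call. = FALSE)
  }
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  labeled <- summaries$n_A + summaries$n_B
  frac <- summaries$fraction_B
  counts <- matrix(0L, nrow = length(thresholds), ncol = n_bins,
                   dimnames = list(
                     paste0("min_", thresholds),
                     sprintf("[%.2f,%.2f%s", breaks[-(n_bins + 1)],
                             breaks[-1],
                             c(rep(")", n_bins - 1), "]"))
                   ))
  for (k in seq_along(thresholds)) {
    f <- frac[labeled >= thresholds[k] & !is.na(frac)]
    if (!length(f)) next
    bin <- pmin(floor(f * n_bins) + 1L, n_bins)
    tab <- tabulate(bin, nbins = n_bins)
    counts[k, ] <- tab
  }
  n_fib <- rowSums(counts)
  pct <- counts / n_fib * 100
  pct[n_fib == 0, ] <- NA_real_
  structure(
    list(
      breaks = breaks,
      thresholds = thresholds,
      n_fibrils = setNames(as.integer(n_fib), rownames(counts)),
      counts = counts,
      percentages = pct,
      empty = setNames(n_fib == 0, rownames(counts))
    ),
    class = "fraction_histogram"
  )
}

#' @export
print.fraction_histogram <- function(x, ...) {
  cat("B-fraction histogram by minimum labeled-segment threshold\n")
  for (k in seq_along(x$thresholds)) {
    cat(sprintf("  >= %2d segments: %d fibrils%s\n", x$thresholds[k],
                x$n_fibrils[k], if (x$empty[k]) " (empty category)" else ""))
  }
  cat("\nPercentages per bin:\n")
  print(round(x$percentages, 2))
  invisible(x)
}

#' Permutation test for axial clustering of conformations
#'
#' Tests whether conformation labels are clustered into contiguous axial
#' regions within fibrils, against the null that each fibril's labels are
#' exchangeable along its axis. The statistic is the total number of
#' switches (run boundaries in the labeled subsequence) summed over
#' fibrils; the null is generated by independently shuffling the labels
#' within each fibril, which preserves every fibril's label composition
#' (`n_A`, `n_B`). The p-value is one-sided toward fewer switches than
#' expected (clustering) and uses the add-one correction
#' `p = (1 + #\{null <= observed\}) / (n_permutations + 1)`, so it is never
#' smaller than `1 / (n_permutations + 1)`.
#'
#' This test is a formalisation of the qualitative observation that A and B
#' segments occupy distinct regions along fibril axes; the choice of
#' statistic and null is this package's own.
#'
#' @param table A [segment_table()].
#' @param n_permutations Number of label shufflings. Default 10000.
#' @param seed Optional integer seed for reproducibility.
#' @param per_fibril If `TRUE`, also return unadjusted per-fibril p-values
#'   (exploratory) together with Benjamini-Hochberg adjusted values.
#' @return An object of class `"break_test"`: list with
#'   `statistic_observed`, `null_mean`, `null_sd`, `p_value`,
#'   `n_permutations`, `seed`, `n_fibrils_tested` (fibrils with >= 2 labeled
#'   segments), `per_fibril` (a `data.frame` or `NULL`) and `config` (echo
#'   of the call configuration).
#' @export
permutation_test_clustering <- function(table, n_permutations = 10000,
                                        seed = NULL, per_fibril = FALSE) {
  stopifnot(inherits(table, "segment_table"))
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  chunks <- split_fibrils(table)
  seqs <- lapply(chunks, function(d) {
    lab <- d$class_label[d$class_label %in% c("A", "B")]
    as.integer(lab == "B")
  })
  seqs <- seqs[vapply(seqs, length, integer(1)) >= 2L]
  if (!length(seqs)) {
    stop("insufficient data: no fibril with >= 2 labeled segments",
         call. = FALSE)
  }
  obs_per_fib <- vapply(seqs, function(x) sum(x[-1] != x[-length(x)]),
                        integer(1))
  observed <- sum(obs_per_fib)
  lens <- vapply(seqs, length, integer(1))
  starts <- c(0L, cumsum(lens)[-length(lens)])
  labels_flat <- unlist(seqs, use.names = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null_mat <- null_switch_matrix(labels_flat, starts, lens,
                                 as.integer(n_permutations))
  null_tot <- rowSums(null_mat)
  p <- (1 + sum(null_tot <= observed)) / (n_permutations + 1)
  pf <- NULL
  if (per_fibril) {
    p_i <- (1 + colSums(null_mat <= matrix(obs_per_fib,
                                           nrow = nrow(null_mat),
                                           ncol = length(obs_per_fib),
                                           byrow = TRUE))) /
      (n_permutations + 1)
    pf <- data.frame(
      fibril_id = names(seqs),
      n_labeled = lens,
      n_switches = obs_per_fib,
      p_value = p_i,
      p_adjust_BH = p.adjust(p_i, method = "BH"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  structure(
    list(
      statistic_observed = observed,
      null_mean = mean(null_tot),
      null_sd = sd(null_tot),
      p_value = p,
      n_permutations = as.integer(n_permutations),
      seed = seed,
      n_fibrils_tested = length(seqs),
      per_fibril = pf,
      config = list(
        statistic = "total switches, pooled over fibrils",
        null = "within-fibril label shuffle (composition preserved)",
        alternative = "fewer switches than exchangeable (axial clustering)",
        n_permutations = as.integer(n_permutations),
        seed = seed
      )
    ),
    class = "break_test"
  )
}

#' @export
print.break_test <- function(x, ...) {
  cat("Permutation test for axial clustering of conformation labels\n")
  cat(sprintf("  fibrils tested (>= 2 labeled segments): %d\n",
              x$n_fibrils_tested))
  cat(sprintf("  observed total switches: %d\n", x$statistic_observed))
  cat(sprintf("  null (within-fibril shuffle): mean %.2f, sd %.2f, %d permutations\n",
              x$null_mean, x$null_sd, x$n_permutations))
  cat(sprintf("  one-sided p (fewer switches): %.4g\n", x$p_value))
  invisible(x)
}

#' Mixture report: pure vs mixed fibrils
#'
#' Among fibrils whose labeled-segment count reaches `min_segments`, counts
#' and proportions of fibrils that are purely conformation A, purely B, or a
#' mixture of both, plus the per-fibril run structure for plotting axial
#' overlays.
#'
#' @param summaries A `data.frame` from [fibril_summaries()].
#' @param min_segments Minimum labeled-segment count (inclusive). Default 1.
#' @return An object of class `"mixture_report"`: list with `n_fibrils`,
#'   `counts` and `proportions` (named by `pure_A`, `pure_B`, `mixed`) and
#'   `per_fibril` (the filtered summary rows).
#' @export
mixture_report <- function(summaries, min_segments = 1) {
  labeled <- summaries$n_A + summaries$n_B
  keep <- labeled >= min_segments & summaries$purity_class != "unlabeled"
  sub <- summaries[keep, , drop = FALSE]
  cls <- factor(sub$purity_class, levels = c("pure_A", "pure_B", "mixed"))
  counts <- table(cls)
  n <- nrow(sub)
  props <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, 3)
  structure(
    list(
      n_fibrils = n,
      min_segments = min_segments,
      counts = setNames(as.integer(counts), names(counts)),
      proportions = setNames(props, names(counts)),
      per_fibril = sub
    ),
    class = "mixture_report"
  )
}

#' @export
print.mixture_report <- function(x, ...) {
  cat(sprintf(
    "Fibril mixture report (>= %d labeled segments): %d fibrils\n",
    x$min_segments, x$n_fibrils
  ))
  for (k in names(x$counts)) {
    cat(sprintf("  %-7s %6d  (%.1f%%)\n", k, x$counts[[k]],
                100 * x$proportions[[k]]))
  }
  invisible(x)
}
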