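#' Configuration for the synthetic fibril generator
#'
#' The generator emulates the statistical structure of a segment-classified
#' helical reconstruction data set: each fibril's true conformation sequence
#' is a two-state Markov chain along the axis (persistent regions of A and
#' B), observed labels are the true ones corrupted by symmetric
#' misclassification, and a sparse subset of segments is flagged as
#' retained for the final reconstruction.
#'
#' Defaults mirror the scale of the FOR005 heart-derived fibril data set:
#' 11,194 fibrils with geometrically distributed lengths of mean 9.05
#' segments (101,319 segments in total), an overall B share of 0.362, and a
#' final-subset retention of 0.228. The switch probability per 33.6 A step
#' (0.02) and the misclassification rate (0.02) are modelling choices, not
#' measured quantities; see the package vignette.
#'
#' @param n_fibrils Number of fibrils (>= 1).
#' @param length_distribution One of `list(kind = "fixed", n = ...)`,
#'   `list(kind = "geometric", mean = ...)` (lengths `1 + rgeom`, mean as
#'   given, must be > 1) or `list(kind = "empirical", lengths = ...)`
#'   (sampled with replacement).
#' @param p_switch Per-step probability that the true conformation changes.
#' @param p_B_init Probability that a fibril's first segment is truly B.
#' @param epsilon Probability that an observed label is flipped relative to
#'   the true conformation (symmetric misclassification).
#' @param p_unassigned Probability that a segment is reported `UNASSIGNED`
#'   (applied independently, after misclassification).
#' @param p_final Probability that a segment carries the `in_final` flag.
#' @param interbox Axial spacing between consecutive segments, angstroms.
#' @param seed Integer seed; the generator is fully reproducible given the
#'   seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_fibrils = 11194,
                             length_distribution = list(kind = "geometric",
                                                        mean = 9.05),
                             p_switch = 0.02,
                             p_B_init = 0.362,
                             epsilon = 0.02,
                             p_unassigned = 0,
                             p_final = 0.228,
                             interbox = 33.6,
                             seed = NULL) {
  probs <- c(p_switch = p_switch, p_B_init = p_B_init, epsilon = epsilon,
             p_unassigned = p_unassigned, p_final = p_final)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1][1]
    stop(sprintf("'%s' must be a probability in [0, 1]", bad), call. = FALSE)
  }
  if (n_fibrils < 1 || n_fibrils != floor(n_fibrils)) {
    stop("n_fibrils must be a positive integer", call. = FALSE)
  }
  if (!is.list(length_distribution) || is.null(length_distribution$kind) ||
      !length_distribution$kind %in% c("fixed", "geometric", "empirical")) {
    stop("length_distribution must be fixed, geometric or empirical",
         call. = FALSE)
  }
  if (length_distribution$kind == "geometric" &&
      (is.null(length_distribution$mean) || length_distribution$mean <= 1)) {
    stop("geometric length distribution needs mean > 1", call. = FALSE)
  }
  if (interbox <= 0) stop("interbox must be > 0", call. = FALSE)
  structure(
    list(
      n_fibrils = as.integer(n_fibrils),
      length_distribution = length_distribution,
      p_switch = p_switch,
      p_B_init = p_B_init,
      epsilon = epsilon,
      p_unassigned = p_unassigned,
      p_final = p_final,
      interbox = interbox,
      seed = seed
    ),
    class = "synthetic_config"
  )
}

draw_lengths <- function(ld, n) {
  switch(ld$kind,
    fixed = rep.int(as.integer(ld$n), n),
    geometric = 1L + rgeom(n, prob = 1 / ld$mean),
    empirical = sample(as.integer(ld$lengths), n, replace = TRUE)
  )
}

#' Generate a synthetic segment table with ground truth
#'
#' Draws fibril label sequences from the two-state Markov switching model
#' described in [synthetic_config()]. Fibrils are distributed over
#' micrographs eight at a time (tube IDs restart on each micrograph, to
#' exercise the pairwise fibril identity), axial positions follow
#' [axial_positions()], and the emitted table row order matches the ground
#' truth row for row.
#'
#' Random draws occur in a fixed order (lengths, initial states, switches,
#' misclassification flips, unassignment, final-subset retention), so the
#' output is byte-identical for a given seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `table` (a [segment_table()]), `truth`
#'   (list with `segments`: per-segment data frame including `true_label`;
#'   `fibrils`: per-fibril data frame with `true_n_switches`; and `config`).
#' @export
generate_fibrils <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- config$n_fibrils
  L <- draw_lengths(config$length_distribution, nf)
  if (any(L < 1)) stop("fibril lengths must be >= 1", call. = FALSE)
  total <- sum(L)
  fib <- rep.int(seq_len(nf), L)
  first <- !duplicated(fib)

  init <- rbinom(nf, 1L, config$p_B_init)
  flips <- as.integer(runif(total) < config$p_switch)
  flips[first] <- 0L
  parity <- stats::ave(flips, fib, FUN = cumsum) %% 2L
  true_state <- (init[fib] + parity) %% 2L           # 0 = A, 1 = B

  mis <- runif(total) < config$epsilon
  obs_state <- ifelse(mis, 1L - true_state, true_state)
  unk <- runif(total) < config$p_unassigned
  obs_label <- ifelse(unk, "UNASSIGNED", ifelse(obs_state == 1L, "B", "A"))
  in_final <- runif(total) < config$p_final

  fibrils_per_mic <- 8L
  mic_idx <- (fib - 1L) %/% fibrils_per_mic + 1L
  micrograph_id <- sprintf("mic%05d.mrc", mic_idx)
  tube_id <- (fib - 1L) %% fibrils_per_mic + 1L
  within <- stats::ave(rep(1L, total), fib, FUN = cumsum)
  axial <- (within - 1L) * config$interbox

  tab <- segment_table(
    micrograph_id = micrograph_id,
    tube_id = tube_id,
    axial_pos = axial,
    class_label = obs_label,
    in_final = in_final,
    provenance = "synthetic two-state Markov switching model",
    interbox_spacing = config$interbox
  )
  truth_segments <- data.frame(
    micrograph_id = micrograph_id,
    tube_id = tube_id,
    axial_pos = axial,
    true_label = ifelse(true_state == 1L, "B", "A"),
    observed_label = obs_label,
    in_final = in_final,
    stringsAsFactors = FALSE
  )
  truth_fibrils <- data.frame(
    micrograph_id = micrograph_id[first],
    tube_id = tube_id[first],
    n_segments = L,
    true_n_switches = as.integer(rowsum(flips, fib)[, 1]),
    stringsAsFactors = FALSE
  )
  list(table = tab,
       truth = list(segments = truth_segments,
                    fibrils = truth_fibrils,
                    config = config))
}

#' Pooled maximum-likelihood estimate of the switch probability
#'
#' For a two-state Markov chain observed at every step, the MLE of the
#' per-step switch probability is the number of observed switches divided by
#' the number of adjacent labeled pairs, pooled over fibrils. The standard
#' error uses the binomial approximation
#' `sqrt(p * (1 - p) / n_pairs)`.
#'
#' Only adjacent labeled pairs within a fibril's labeled subsequence are
#' counted; misclassification noise biases the estimate upward (an isolated
#' flipped label creates two spurious switches), which is why clustering is
#' assessed by the permutation test rather than by raw switch counts.
#'
#' @param table A [segment_table()].
#' @return List of class `"switch_rate_estimate"`: `estimate`, `se`,
#'   `n_switches`, `n_pairs`.
#' @export
estimate_switch_rate <- function(table) {
  chunks <- split_fibrils(table)
  sw <- 0L
  pairs <- 0L
  for (d in chunks) {
    lab <- d$class_label[d$class_label %in% c("A", "B")]
    n <- length(lab)
    if (n >= 2) {
      pairs <- pairs + (n - 1L)
      sw <- sw + sum(lab[-1] != lab[-n])
    }
  }
  if (pairs == 0) {
    stop("insufficient data: no adjacent labeled pairs", call. = FALSE)
  }
  p <- sw / pairs
  structure(
    list(
      estimate = p,
      se = sqrt(p * (1 - p) / pairs),
      n_switches = as.integer(sw),
      n_pairs = as.integer(pairs)
    ),
    class = "switch_rate_estimate"
  )
}

#' @export
print.switch_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "Switch probability per step: %.4f (SE %.4f; %d switches / %d pairs)\n",
    x$estimate, x$se, x$n_switches, x$n_pairs
  ))
  invisible(x)
}
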