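# Brute-force oracles, kept independent of the package implementation.

# single-pass run counter over the labeled subsequence (scalar loop)
brute_run_count <- function(labels) {
  runs <- 0L
  last <- NA_character_
  for (x in labels) {
    if (x == "A" || x == "B") {
      if (is.na(last) || x != last) runs <- runs + 1L
      last <- x
    }
  }
  runs
}

# vectorised single-pass run counter over a matrix (rows = sequences)
brute_run_count_matrix <- function(M) {
  n <- nrow(M)
  runs <- integer(n)
  last <- rep(NA_character_, n)
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    lab <- x == "A" | x == "B"
    runs <- runs + (lab & (is.na(last) | x != last))
    last[lab] <- x[lab]
  }
  runs
}

# pitch by accumulating whole subunits over one full turn, interpolating
# the final partial subunit
brute_pitch <- function(twist, rise) {
  full <- floor(360 / twist + 1e-12)
  rem_deg <- 360 - full * twist
  full * rise + (rem_deg / twist) * rise
}

# exhaustive within-fibril shuffle null for a single fibril:
# P(switches <= observed) over all placements of the B labels
exact_clustering_p <- function(labels) {
  n <- length(labels)
  k <- sum(labels == "B")
  switches <- function(v) sum(v[-1] != v[-n])
  obs <- switches(labels)
  combos <- utils::combn(n, k)
  cnt <- 0L
  for (j in seq_len(ncol(combos))) {
    v <- rep("A", n)
    v[combos[, j]] <- "B"
    if (switches(v) <= obs) cnt <- cnt + 1L
  }
  list(p = cnt / ncol(combos), n_arrangements = ncol(combos), observed = obs)
}

# FoldAmyloid rule by explicit window enumeration
brute_foldamyloid <- function(track, thr = 21.4, k = 5) {
  n <- length(track)
  hit <- rep(FALSE, n)
  if (n >= k) {
    for (s in seq_len(n - k + 1)) {
      if (all(track[s:(s + k - 1)] > thr)) hit[s:(s + k - 1)] <- TRUE
    }
  }
  hit
}

# highest-scoring window by exhaustive interval enumeration
brute_max_window <- function(cons) {
  m <- max(cons)
  if (m <= 0) return(NULL)
  best <- NULL
  for (i in seq_along(cons)) {
    for (j in i:length(cons)) {
      if (all(cons[i:j] == m)) {
        len <- j - i + 1L
        if (is.null(best) || len > best$len) {
          best <- list(start = i, end = j, len = len)
        }
      }
    }
  }
  best
}

# per-residue region classification by scanning every span
brute_classify <- function(position, annotation) {
  fp <- annotation$fibril_protein_span
  if (position < fp$start || position > fp$end) return("cleaved-or-absent")
  os <- annotation$ordered_spans
  for (i in seq_len(nrow(os))) {
    if (position >= os$start[i] && position <= os$end[i]) {
      return("ordered-core")
    }
  }
  "disordered"
}

# random valid segment table for round-trip properties
random_segment_table <- function(n, seed) {
  set.seed(seed)
  n_mic <- max(1, rbinom(1, 4, 0.5) + 1)
  mic <- sprintf("img_%02d.mrc", sample.int(n_mic, n, replace = TRUE))
  tube <- sample.int(3, n, replace = TRUE)
  key <- paste(mic, tube)
  axial <- stats::ave(runif(n, 0, 5000), key,
                      FUN = function(x) x + seq_along(x) * 1e-3)
  segment_table(
    micrograph_id = mic,
    tube_id = tube,
    axial_pos = round(axial, 3),
    class_label = sample(c("A", "B", "UNASSIGNED"), n, replace = TRUE),
    coord_x = round(runif(n, 0, 4096), 2),
    coord_y = round(runif(n, 0, 4096), 2),
    in_final = runif(n) < 0.3,
    provenance = "random"
  )
}

# single-fibril table from a label vector
one_fibril_table <- function(labels, interbox = 33.6) {
  segment_table(
    micrograph_id = rep("m1.mrc", length(labels)),
    tube_id = rep(1L, length(labels)),
    axial_pos = axial_positions(length(labels), interbox),
    class_label = labels
  )
}
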