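#' Per-residue hit calls for the four aggregation predictors
#'
#' Each predictor produces one numeric value per residue; a residue is a
#' "hit" under that predictor's published decision rule. All threshold
#' comparisons are strict ("above"/"below" read literally), so a value
#' exactly at the threshold is not a hit.
#'
#' * `tango_hits()`: per-residue beta-aggregation percentage; hit if
#'   value > 5.
#' * `foldamyloid_hits()`: triple-hybrid scale value; a residue is a hit if
#'   it belongs to a run of at least `min_run` (default 5) consecutive
#'   residues each scoring > 21.4.
#' * `pasta_hits()`: per-residue projected pairing energy in PASTA Energy
#'   Units; hit if value < -2.8. (The projection of pairwise energies onto
#'   residues happens upstream, in the predictor's own output.)
#' * `aggrescan_hits()`: a3v-style value; hit if value > -0.02.
#'
#' @param track Numeric vector of per-residue predictor values (finite).
#' @param threshold Decision threshold; defaults are the published values.
#' @param min_run Minimum run length for FoldAmyloid. Default 5.
#' @return Logical vector, same length as `track`.
#' @name predictor_hits
NULL

check_track <- function(track) {
  if (length(track) && any(!is.finite(track))) {
    stop("predictor track contains non-finite values", call. = FALSE)
  }
  as.numeric(track)
}

#' @rdname predictor_hits
#' @export
tango_hits <- function(track, threshold = 5) {
  check_track(track) > threshold
}

#' @rdname predictor_hits
#' @export
foldamyloid_hits <- function(track, threshold = 21.4, min_run = 5) {
  track <- check_track(track)
  above <- track > threshold
  if (!length(above)) return(logical(0))
  r <- rle(above)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' @rdname predictor_hits
#' @export
pasta_hits <- function(track, threshold = -2.8) {
  check_track(track) < threshold
}

#' @rdname predictor_hits
#' @export
aggrescan_hits <- function(track, threshold = -0.02) {
  check_track(track) > threshold
}

#' Bundle the four predictor tracks and derive the consensus
#'
#' @param tango,foldamyloid,pasta,aggrescan Numeric per-residue tracks of
#'   equal length, aligned to the same sequence starting at residue 1.
#' @return An object of class `"aggregation_tracks"`: list with the four
#'   raw tracks, the four logical hit vectors (`tango_hit`, ...), and
#'   `consensus`, the per-residue integer count of predictors calling the
#'   residue aggregation-prone (0-4).
#' @export
aggregation_tracks <- function(tango, foldamyloid, pasta, aggrescan) {
  lens <- c(tango = length(tango), foldamyloid = length(foldamyloid),
            pasta = length(pasta), aggrescan = length(aggrescan))
  if (length(unique(lens)) != 1) {
    stop(sprintf(
      "track lengths differ: %s",
      paste(sprintf("%s=%d", names(lens), lens), collapse = ", ")
    ), call. = FALSE)
  }
  hits <- list(
    tango_hit = tango_hits(tango),
    foldamyloid_hit = foldamyloid_hits(foldamyloid),
    pasta_hit = pasta_hits(pasta),
    aggrescan_hit = aggrescan_hits(aggrescan)
  )
  structure(
    c(
      list(sequence_length = lens[[1]],
           tango = as.numeric(tango), foldamyloid = as.numeric(foldamyloid),
           pasta = as.numeric(pasta), aggrescan = as.numeric(aggrescan)),
      hits,
      list(consensus = as.integer(hits$tango_hit) +
             as.integer(hits$foldamyloid_hit) +
             as.integer(hits$pasta_hit) +
             as.integer(hits$aggrescan_hit))
    ),
    class = "aggregation_tracks"
  )
}

#' Consensus aggregation score
#'
#' Per residue, the number of predictors (0-4) that call the residue
#' aggregation-prone under their stated rules: 0 means no program
#' identified the residue, 4 means all four did.
#'
#' @param tracks An [aggregation_tracks()] object.
#' @return Integer vector in \[0, 4\].
#' @export
consensus_score <- function(tracks) {
  stopifnot(inherits(tracks, "aggregation_tracks"))
  tracks$consensus
}

#' @export
print.aggregation_tracks <- function(x, ...) {
  cat(sprintf("Aggregation tracks over %d residues\n", x$sequence_length))
  cat(sprintf("  hits: TANGO %d, FoldAmyloid %d, PASTA %d, Aggrescan %d\n",
              sum(x$tango_hit), sum(x$foldamyloid_hit),
              sum(x$pasta_hit), sum(x$aggrescan_hit)))
  cat("  consensus score distribution:\n")
  print(table(factor(x$consensus, levels = 0:4)))
  invisible(x)
}

#' Highest-scoring contiguous region of a consensus track
#'
#' Finds the region of residues that all attain the track's maximum
#' consensus score: among maximal runs at the maximum, the longest run
#' wins, and ties are broken toward the lowest start index. Optionally the
#' search is restricted to a span (e.g. the variable-domain residues).
#'
#' @param consensus Integer consensus track (e.g. from [consensus_score()]).
#' @param restrict Optional [residue_span()] restricting the search (1-based
#'   positions into `consensus`).
#' @return A [residue_span()] with the maximum score as `label`, or `NULL`
#'   if the (restricted) track is empty or identically zero.
#' @export
max_scoring_window <- function(consensus, restrict = NULL) {
  if (!length(consensus)) stop("consensus track is empty", call. = FALSE)
  pos <- seq_along(consensus)
  if (!is.null(restrict)) {
    stopifnot(inherits(restrict, "residue_span"))
    keep <- pos >= restrict$start & pos <= min(restrict$end, length(consensus))
    pos <- pos[keep]
    consensus <- consensus[keep]
    if (!length(pos)) return(NULL)
  }
  m <- max(consensus)
  if (m <= 0) return(NULL)
  r <- rle(consensus == m)
  ends_at <- cumsum(r$lengths)
  starts_at <- ends_at - r$lengths + 1
  cand <- which(r$values)
  best <- cand[order(-r$lengths[cand], starts_at[cand])][1]
  residue_span(pos[starts_at[best]], pos[ends_at[best]],
               label = sprintf("consensus score %d", m))
}

#' Read a per-residue predictor track from TSV
#'
#' Expects a header row with columns `position` and `value`; positions must
#' be contiguous from residue 1.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric vector of values, ordered by position.
#' @export
read_score_track <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("position", "value"), names(df))
  if (length(missing)) {
    stop(sprintf("missing mandatory column '%s'", missing[1]), call. = FALSE)
  }
  df <- df[order(df$position), , drop = FALSE]
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop("positions must be contiguous from residue 1", call. = FALSE)
  }
  as.numeric(df$value)
}

#' Write hit flags and consensus score as TSV
#'
#' @param tracks An [aggregation_tracks()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_consensus_table <- function(tracks, path) {
  stopifnot(inherits(tracks, "aggregation_tracks"))
  out <- data.frame(
    position = seq_len(tracks$sequence_length),
    tango_hit = as.integer(tracks$tango_hit),
    foldamyloid_hit = as.integer(tracks$foldamyloid_hit),
    pasta_hit = as.integer(tracks$pasta_hit),
    aggrescan_hit = as.integer(tracks$aggrescan_hit),
    consensus = tracks$consensus
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
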