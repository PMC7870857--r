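#' Residue span
#'
#' A contiguous residue interval in 1-based inclusive precursor light-chain
#' numbering (numbering starts at the first residue after the cleaved signal
#' sequence). Residue names such as "Ser2" are annotations; positions are
#' what the algebra operates on.
#'
#' @param start,end 1-based inclusive residue numbers, `1 <= start <= end`.
#' @param label Optional free-text label (e.g. `"beta1"`, `"disordered"`).
#' @return A list of class `"residue_span"`.
#' @export
residue_span <- function(start, end, label = NA_character_) {
  if (length(start) != 1 || length(end) != 1 ||
      start != floor(start) || end != floor(end)) {
    stop("start and end must be single integers", call. = FALSE)
  }
  if (start < 1) stop("residue numbering is 1-based: start >= 1", call. = FALSE)
  if (start > end) stop("start must not exceed end", call. = FALSE)
  structure(list(start = as.integer(start), end = as.integer(end),
                 label = as.character(label)),
            class = "residue_span")
}

#' @export
print.residue_span <- function(x, ...) {
  cat(sprintf("Residue span %d-%d (%d residues)%s\n", x$start, x$end,
              span_length(x),
              if (is.na(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Number of residues in a span
#'
#' @param span A [residue_span()].
#' @return `end - start + 1`.
#' @examples
#' span_length(residue_span(2, 116))  # the 115-residue fibril protein
#' @export
span_length <- function(span) {
  stopifnot(inherits(span, "residue_span"))
  span$end - span$start + 1L
}

span_df <- function(starts, ends, labels = NA_character_) {
  df <- data.frame(start = as.integer(starts), end = as.integer(ends),
                   label = rep_len(as.character(labels), length(starts)),
                   stringsAsFactors = FALSE)
  bad <- df$start < 1 | df$start > df$end
  if (any(bad)) stop("invalid span in span list", call. = FALSE)
  df
}

in_any_span <- function(position, spans) {
  if (!nrow(spans)) return(rep(FALSE, length(position)))
  vapply(position, function(p) any(p >= spans$start & p <= spans$end),
         logical(1))
}

#' Structure annotation of one fibril protein conformation
#'
#' Validated container for the ordered, disordered and beta-strand residue
#' spans of a fibril protein conformation. Span lists are data frames with
#' columns `start`, `end`, `label`.
#'
#' Enforced invariants: ordered and disordered spans are disjoint, both lie
#' inside the fibril-protein span, and every beta strand lies inside an
#' ordered span.
#'
#' @param conformation `"A"` or `"B"`.
#' @param fibril_protein_span A [residue_span()] covering the whole fibril
#'   protein.
#' @param ordered_spans,disordered_spans,strand_spans Span data frames (see
#'   [residue_span()] for the numbering convention).
#' @return A list of class `"structure_annotation"`.
#' @export
structure_annotation <- function(conformation, fibril_protein_span,
                                 ordered_spans, disordered_spans,
                                 strand_spans) {
  stopifnot(conformation %in% c("A", "B"),
            inherits(fibril_protein_span, "residue_span"))
  fp <- fibril_protein_span
  within_fp <- function(spans) {
    !nrow(spans) || all(spans$start >= fp$start & spans$end <= fp$end)
  }
  if (!within_fp(ordered_spans) || !within_fp(disordered_spans)) {
    stop("ordered/disordered spans must lie within the fibril protein span",
         call. = FALSE)
  }
  res <- seq.int(fp$start, fp$end)
  ord_cov <- in_any_span(res, ordered_spans)
  dis_cov <- in_any_span(res, disordered_spans)
  if (any(ord_cov & dis_cov)) {
    stop("ordered and disordered spans overlap", call. = FALSE)
  }
  for (i in seq_len(nrow(strand_spans))) {
    s <- strand_spans[i, ]
    inside <- any(s$start >= ordered_spans$start & s$end <= ordered_spans$end)
    if (!inside) {
      stop(sprintf("strand %s (%d-%d) is not inside an ordered span",
                   s$label, s$start, s$end), call. = FALSE)
    }
  }
  structure(
    list(
      conformation = conformation,
      fibril_protein_span = fibril_protein_span,
      ordered_spans = ordered_spans,
      disordered_spans = disordered_spans,
      strand_spans = strand_spans
    ),
    class = "structure_annotation"
  )
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(sprintf("Structure annotation, conformation %s\n", x$conformation))
  cat(sprintf("  fibril protein: residues %d-%d (%d residues)\n",
              x$fibril_protein_span$start, x$fibril_protein_span$end,
              span_length(x$fibril_protein_span)))
  cat(sprintf("  ordered spans: %s\n",
              paste(sprintf("%d-%d", x$ordered_spans$start,
                            x$ordered_spans$end), collapse = ", ")))
  cat(sprintf("  disordered spans: %s\n",
              paste(sprintf("%d-%d", x$disordered_spans$start,
                            x$disordered_spans$end), collapse = ", ")))
  cat(sprintf("  beta strands: %d\n", nrow(x$strand_spans)))
  invisible(x)
}

#' Classify a residue position by structural region
#'
#' A position outside the fibril-protein span is `"cleaved-or-absent"`
#' (either N-terminal to the fibril protein or lost with the constant
#' domain); inside it, a position is `"ordered-core"` if it falls in any
#' ordered span and `"disordered"` otherwise.
#'
#' @param position Residue position(s), 1-based precursor numbering.
#' @param annotation A [structure_annotation()].
#' @return Character vector of region labels.
#' @export
classify_position <- function(position, annotation) {
  stopifnot(inherits(annotation, "structure_annotation"))
  if (any(position < 1 | position != floor(position))) {
    stop("positions must be integers >= 1", call. = FALSE)
  }
  fp <- annotation$fibril_protein_span
  out <- rep("disordered", length(position))
  out[position < fp$start | position > fp$end] <- "cleaved-or-absent"
  inside <- out == "disordered"
  out[inside][in_any_span(position[inside], annotation$ordered_spans)] <-
    "ordered-core"
  out
}

residue_status <- function(annotation) {
  # per-residue region + strand membership over the fibril protein span
  fp <- annotation$fibril_protein_span
  res <- seq.int(fp$start, fp$end)
  region <- classify_position(res, annotation)
  strands <- vapply(res, function(p) {
    hit <- annotation$strand_spans$start <= p & annotation$strand_spans$end >= p
    paste(sort(annotation$strand_spans$label[hit]), collapse = ",")
  }, character(1))
  data.frame(position = res, region = region, strands = strands,
             stringsAsFactors = FALSE)
}

merge_positions <- function(pos) {
  # maximal intervals from a sorted vector of positions
  if (!length(pos)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  brk <- which(diff(pos) > 1)
  starts <- pos[c(1, brk + 1)]
  ends <- pos[c(brk, length(pos))]
  data.frame(start = starts, end = ends)
}

#' Residue intervals where two annotations differ
#'
#' Compares two structure annotations residue by residue over the shared
#' fibril-protein span (region classification and beta-strand membership)
#' and merges differing positions into maximal intervals. The comparison is
#' symmetric: `diff_annotations(a, b)` equals `diff_annotations(b, a)`.
#'
#' @param a,b [structure_annotation()] objects on the same numbering; their
#'   fibril-protein spans must agree.
#' @return A `data.frame` with columns `start`, `end` and `what` (a brief
#'   description of what differs in that interval). Zero rows if identical.
#' @export
diff_annotations <- function(a, b) {
  stopifnot(inherits(a, "structure_annotation"),
            inherits(b, "structure_annotation"))
  if (a$fibril_protein_span$start != b$fibril_protein_span$start ||
      a$fibril_protein_span$end != b$fibril_protein_span$end) {
    stop("annotations cover different fibril protein spans", call. = FALSE)
  }
  sa <- residue_status(a)
  sb <- residue_status(b)
  differs <- sa$region != sb$region | sa$strands != sb$strands
  iv <- merge_positions(sa$position[differs])
  if (!nrow(iv)) {
    iv$what <- character(0)
    return(iv)
  }
  iv$what <- vapply(seq_len(nrow(iv)), function(i) {
    idx <- sa$position >= iv$start[i] & sa$position <= iv$end[i]
    kinds <- c(
      if (any(sa$region[idx] != sb$region[idx])) "region",
      if (any(sa$strands[idx] != sb$strands[idx])) "strands"
    )
    paste(kinds, collapse = "+")
  }, character(1))
  iv
}

#' Built-in FOR005 fibril protein annotations and germline mutations
#'
#' Loads the packaged annotation of the two fibril protein conformations of
#' the FOR005 lambda-3 light chain: the 115-residue fibril protein
#' (residues 2-116 of the precursor), its ordered cores, the internal and
#' terminal disordered segments (which differ between conformations A and B
#' in the region around residues 60-67), the twelve shared beta strands
#' plus the two A-only strands, and the seven mutations relative to the
#' germline segments IGLV3-19, IGLJ2 and IGLC2.
#'
#' The mutation table's `region_A` and `region_B` columns are derived by
#' [classify_position()] at load time, never stored.
#'
#' @return A list with elements `A` and `B` ([structure_annotation()]s) and
#'   `mutations` (a `data.frame` with `position`, `from_aa`, `to_aa`,
#'   `germline_segment`, `name`, `region_A`, `region_B`).
#' @export
load_default_annotations <- function() {
  path <- system.file("extdata", "for005_annotations.json",
                      package = "fibrilbreaks", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  mk <- function(conf) {
    structure_annotation(
      conformation = conf$conformation,
      fibril_protein_span = residue_span(conf$fibril_protein_span$start,
                                         conf$fibril_protein_span$end,
                                         "fibril protein"),
      ordered_spans = span_df(conf$ordered_spans$start,
                              conf$ordered_spans$end,
                              conf$ordered_spans$label),
      disordered_spans = span_df(conf$disordered_spans$start,
                                 conf$disordered_spans$end,
                                 conf$disordered_spans$label),
      strand_spans = span_df(conf$strand_spans$start,
                             conf$strand_spans$end,
                             conf$strand_spans$label)
    )
  }
  A <- mk(raw$A)
  B <- mk(raw$B)
  mut <- as.data.frame(raw$mutations, stringsAsFactors = FALSE)
  mut$region_A <- classify_position(mut$position, A)
  mut$region_B <- classify_position(mut$position, B)
  list(A = A, B = B, mutations = mut)
}

#' Export span lists as BED-like TSV
#'
#' Writes the ordered, disordered and strand spans of an annotation as a
#' TSV with columns `start`, `end`, `label`, `kind`. Coordinates are
#' 1-based inclusive residue numbers (not 0-based half-open BED), as used
#' throughout the package; the header row says so.
#'
#' @param annotation A [structure_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(inherits(annotation, "structure_annotation"))
  pieces <- rbind(
    cbind(annotation$ordered_spans, kind = "ordered"),
    cbind(annotation$disordered_spans, kind = "disordered"),
    cbind(annotation$strand_spans, kind = "strand")
  )
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# 1-based inclusive residue coordinates", con)
  write.table(pieces[c("start", "end", "label", "kind")], con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reported bookkeeping of the FOR005 segment data set
#'
#' Reported counts and resolutions of the original FOR005 data set, kept as
#' reference metadata for consistency checks and documentation. None of
#' these values is recomputable without the deposited micrographs; the
#' per-threshold fibril counts are documentation only.
#'
#' @return A list: `n_selected_segments` (segments retained after 2D
#'   classification), `n_class_A`, `n_class_B` (first 3D classification),
#'   `n_final_A`, `n_final_B` (final reconstructions), `n_extracted`,
#'   `n_micrographs_collected`, `fibril_counts` (named by minimum-segment
#'   threshold), `resolution_A`, `resolution_B` (angstroms).
#' @export
study_reference_counts <- function() {
  list(
    n_selected_segments = 101319L,
    n_class_A = 64652L,
    n_class_B = 36667L,
    n_final_A = 11003L,
    n_final_B = 12122L,
    n_extracted = 194502L,
    n_micrographs_collected = 1378L,
    fibril_counts = c(min_1 = 11194L, min_5 = 7738L,
                      min_10 = 4278L, min_20 = 951L),
    resolution_A = 3.2,
    resolution_B = 3.4
  )
}
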