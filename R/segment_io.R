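#' Construct a segment table
#'
#' A segment table holds one row per picked fibril segment. Fibril identity
#' is always the pair (micrograph_id, tube_id): helical tube IDs restart on
#' every micrograph and are never compared across micrographs.
#'
#' @param micrograph_id Character vector, opaque micrograph identifiers.
#' @param tube_id Integer vector of helical tube IDs, positive, unique only
#'   within a micrograph.
#' @param axial_pos Numeric vector, position along the fibril axis in
#'   angstroms (non-negative; distinct within a fibril).
#' @param class_label Character vector of 3D-class labels; anything other
#'   than `"A"` or `"B"` is normalised to `"UNASSIGNED"`.
#' @param coord_x,coord_y Optional picking coordinates in pixels (0-based).
#' @param in_final Logical, whether the segment was retained in the final
#'   reconstruction subset. Defaults to `TRUE`.
#' @param provenance Free-text source tag.
#' @param interbox_spacing Declared spacing between consecutive segments in
#'   angstroms, or `NULL` if unknown.
#' @return A `data.frame` of class `"segment_table"`, ordered by
#'   (micrograph_id, tube_id, axial_pos), with attributes `provenance` and
#'   `interbox_spacing`.
#' @export
segment_table <- function(micrograph_id, tube_id, axial_pos, class_label,
                          coord_x = NA_real_, coord_y = NA_real_,
                          in_final = TRUE, provenance = "",
                          interbox_spacing = NULL) {
  n <- length(micrograph_id)
  df <- data.frame(
    micrograph_id = as.character(micrograph_id),
    tube_id = as.integer(tube_id),
    axial_pos = as.numeric(axial_pos),
    coord_x = rep_len(as.numeric(coord_x), n),
    coord_y = rep_len(as.numeric(coord_y), n),
    class_label = normalize_labels(class_label),
    in_final = rep_len(as.logical(in_final), n),
    stringsAsFactors = FALSE
  )
  as_segment_table(df, provenance = provenance,
                   interbox_spacing = interbox_spacing)
}

normalize_labels <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !(x %in% c("A", "B"))] <- "UNASSIGNED"
  x
}

as_segment_table <- function(df, provenance = "", interbox_spacing = NULL) {
  validate_segment_table(df)
  ord <- order(df$micrograph_id, df$tube_id, df$axial_pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  attr(df, "interbox_spacing") <- interbox_spacing
  class(df) <- c("segment_table", "data.frame")
  df
}

validate_segment_table <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$micrograph_id) || anyNA(df$tube_id) || anyNA(df$axial_pos)) {
    stop("micrograph_id, tube_id and axial_pos must not contain NA",
         call. = FALSE)
  }
  if (any(df$tube_id < 1)) {
    stop("tube_id must be a positive integer", call. = FALSE)
  }
  if (any(df$axial_pos < 0)) {
    stop("axial_pos must be non-negative", call. = FALSE)
  }
  dup <- duplicated(df[c("micrograph_id", "tube_id", "axial_pos")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf(
      "duplicate (fibril, axial_pos) pair: micrograph '%s', tube %d, position %g",
      df$micrograph_id[i], df$tube_id[i], df$axial_pos[i]
    ), call. = FALSE)
  }
  invisible(df)
}

segment_table_columns <- c(
  "micrograph_id", "tube_id", "axial_pos",
  "coord_x", "coord_y", "class_label", "in_final"
)

#' Read a segment table from disk
#'
#' Two dialects are supported: a plain TSV with a header row (columns
#' `micrograph_id`, `tube_id`, `axial_pos`, `class_label` mandatory;
#' `coord_x`, `coord_y`, `in_final` optional), and a STAR particle table in
#' the helical reconstruction convention (`_rlnMicrographName`,
#' `_rlnHelicalTubeID`, `_rlnClassNumber` mandatory;
#' `_rlnHelicalTrackLengthAngst` / `_rlnHelicalTrackLength`,
#' `_rlnCoordinateX/Y` optional).
#'
#' For STAR input, class numbers are mapped to conformation labels through
#' `class_map` (the numbering of 3D classes is specific to each refinement
#' run, so the map is user input); unmapped class numbers become
#' `UNASSIGNED`. If no track-length column is present, axial positions are
#' synthesised as extraction order times `interbox_spacing` within each
#' fibril.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"star"`.
#' @param class_map Named character vector mapping class numbers to labels,
#'   e.g. `c("3" = "A", "5" = "B")`. STAR only.
#' @param interbox_spacing Spacing in angstroms used to synthesise axial
#'   positions when the STAR file lacks a track-length column.
#' @return A [segment_table()].
#' @export
read_segment_table <- function(path, dialect = c("auto", "tsv", "star"),
                               class_map = NULL, interbox_spacing = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "tsv"
  }
  if (dialect == "tsv") {
    read_segment_tsv(path)
  } else {
    read_segment_star(path, class_map = class_map,
                      interbox_spacing = interbox_spacing)
  }
}

read_segment_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = NA, stringsAsFactors = FALSE)
  mandatory <- c("micrograph_id", "tube_id", "axial_pos", "class_label")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop(sprintf("missing mandatory column '%s'", missing[1]), call. = FALSE)
  }
  n <- nrow(df)
  segment_table(
    micrograph_id = as.character(df$micrograph_id),
    tube_id = df$tube_id,
    axial_pos = df$axial_pos,
    class_label = if (n) df$class_label else character(0),
    coord_x = if ("coord_x" %in% names(df)) df$coord_x else NA_real_,
    coord_y = if ("coord_y" %in% names(df)) df$coord_y else NA_real_,
    in_final = if ("in_final" %in% names(df)) df$in_final else TRUE,
    provenance = path
  )
}

#' Write a segment table to disk
#'
#' `write_segment_table()` followed by [read_segment_table()] in the same
#' dialect is the identity on all defined fields (for STAR, provided the
#' same `class_map` is used in both directions).
#'
#' @param table A [segment_table()].
#' @param path Output path.
#' @param dialect `"auto"`, `"tsv"` or `"star"`.
#' @param class_map Named character vector as in [read_segment_table()];
#'   inverted when writing STAR. Defaults to `c("1" = "A", "2" = "B")`;
#'   `UNASSIGNED` segments are written as class 0.
#' @return Invisibly, `path`.
#' @export
write_segment_table <- function(table, path,
                                dialect = c("auto", "tsv", "star"),
                                class_map = c("1" = "A", "2" = "B")) {
  stopifnot(inherits(table, "segment_table"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "tsv"
  }
  if (dialect == "tsv") {
    out <- as.data.frame(table)[segment_table_columns]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_segment_star(table, path, class_map = class_map)
  }
  invisible(path)
}

# --- STAR particle-table dialect -------------------------------------------
#
# Minimal reader/writer for the loop_ block convention used by helical
# reconstruction particle tables. Only whitespace-separated loop data are
# supported; no installed R package reads STAR, so the dialect is handled
# here directly.

parse_star_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines, perl = FALSE)  # strip trailing comments
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) {
    stop(sprintf("no loop_ block found in STAR file '%s'", path),
         call. = FALSE)
  }
  i <- loop_at[1] + 1
  tags <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("^(_\\S+).*$", "\\1", lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "data_") || ln == "loop_") break
    rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
    i <- i + 1
  }
  if (length(rows)) {
    bad <- vapply(rows, length, integer(1)) != length(tags)
    if (any(bad)) {
      stop(sprintf("STAR row %d has %d fields, expected %d",
                   which(bad)[1], length(rows[[which(bad)[1]]]), length(tags)),
           call. = FALSE)
    }
    m <- do.call(rbind, rows)
  } else {
    m <- matrix(character(0), nrow = 0, ncol = length(tags))
  }
  colnames(m) <- tags
  as.data.frame(m, stringsAsFactors = FALSE)
}

read_segment_star <- function(path, class_map = NULL,
                              interbox_spacing = NULL) {
  raw <- parse_star_loop(path)
  need <- c("_rlnMicrographName", "_rlnHelicalTubeID", "_rlnClassNumber")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop(sprintf("missing mandatory column '%s'", missing[1]), call. = FALSE)
  }
  n <- nrow(raw)
  class_num <- raw[["_rlnClassNumber"]]
  if (is.null(class_map)) {
    labels <- rep("UNASSIGNED", n)
  } else {
    labels <- unname(class_map[as.character(as.integer(class_num))])
  }
  track_col <- intersect(
    c("_rlnHelicalTrackLengthAngst", "_rlnHelicalTrackLength"), names(raw)
  )
  mic <- raw[["_rlnMicrographName"]]
  tube <- as.integer(raw[["_rlnHelicalTubeID"]])
  if (length(track_col)) {
    axial <- as.numeric(raw[[track_col[1]]])
  } else {
    if (is.null(interbox_spacing)) {
      stop(paste("STAR file has no helical track-length column;",
                 "supply interbox_spacing to synthesise axial positions"),
           call. = FALSE)
    }
    key <- paste(mic, tube, sep = "\r")
    axial <- (stats::ave(rep(1, n), key, FUN = cumsum) - 1) * interbox_spacing
  }
  segment_table(
    micrograph_id = mic,
    tube_id = tube,
    axial_pos = axial,
    class_label = if (n) labels else character(0),
    coord_x = if ("_rlnCoordinateX" %in% names(raw))
      as.numeric(raw[["_rlnCoordinateX"]]) else NA_real_,
    coord_y = if ("_rlnCoordinateY" %in% names(raw))
      as.numeric(raw[["_rlnCoordinateY"]]) else NA_real_,
    in_final = if ("_fibrilInFinal" %in% names(raw))
      as.integer(raw[["_fibrilInFinal"]]) == 1L else TRUE,
    provenance = path,
    interbox_spacing = interbox_spacing
  )
}

write_segment_star <- function(table, path, class_map = c("1" = "A", "2" = "B")) {
  inv <- setNames(names(class_map), unname(class_map))
  cls <- inv[table$class_label]
  cls[is.na(cls)] <- "0"
  has_coords <- any(!is.na(table$coord_x)) || any(!is.na(table$coord_y))
  tags <- c("_rlnMicrographName", "_rlnHelicalTubeID",
            "_rlnHelicalTrackLengthAngst", "_rlnClassNumber")
  cols <- list(table$micrograph_id,
               format(table$tube_id, scientific = FALSE, trim = TRUE),
               sprintf("%.6f", table$axial_pos),
               cls)
  if (has_coords) {
    tags <- c(tags, "_rlnCoordinateX", "_rlnCoordinateY")
    cols <- c(cols, list(sprintf("%.6f", table$coord_x),
                         sprintf("%.6f", table$coord_y)))
  }
  if (!all(table$in_final)) {
    tags <- c(tags, "_fibrilInFinal")
    cols <- c(cols, list(as.character(as.integer(table$in_final))))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_",
               sprintf("%s #%d", tags, seq_along(tags))), con)
  if (nrow(table)) {
    body <- do.call(paste, c(cols, sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

# --- fibril grouping -------------------------------------------------------

fibril_key <- function(micrograph_id, tube_id) {
  sprintf("%s#%d", micrograph_id, tube_id)
}

split_fibrils <- function(table) {
  stopifnot(inherits(table, "segment_table"))
  df <- as.data.frame(table)
  if (!nrow(df)) return(list())
  key <- fibril_key(df$micrograph_id, df$tube_id)
  # table is stored sorted by (micrograph, tube, axial_pos), so each chunk
  # is already in axial order
  split(df, factor(key, levels = unique(key)))
}

#' Group segments into fibrils
#'
#' Groups a segment table by fibril identity (micrograph_id, tube_id) and
#' returns, for each fibril, its class-label sequence ordered by axial
#' position. The result is invariant under permutation of input rows.
#'
#' @param table A [segment_table()].
#' @return A named list (names `"<micrograph>#<tube>"`) of character label
#'   vectors. Each element carries its axial positions as attribute
#'   `"axial_pos"`.
#' @export
group_fibrils <- function(table) {
  chunks <- split_fibrils(table)
  lapply(chunks, function(d) {
    structure(d$class_label, axial_pos = d$axial_pos)
  })
}
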