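#' Helical pitch from per-subunit twist and rise
#'
#' For a C1 helix in which consecutive subunits are related by a rotation of
#' `twist` degrees and an axial translation of `rise` angstroms, the pitch
#' (axial distance per full 360 degree turn) is `(360 / twist) * rise`.
#'
#' @param twist Rotation between consecutive subunits, degrees (magnitude,
#'   must be positive; handedness is carried separately, see
#'   [helical_params()]).
#' @param rise Axial translation between consecutive subunits, in angstroms.
#' @return Pitch in angstroms.
#' @examples
#' pitch_from_twist_rise(1.11, 4.79)   # ~1553.5 A, i.e. ~155 nm
#' @export
pitch_from_twist_rise <- function(twist, rise) {
  if (any(!is.finite(twist)) || any(!is.finite(rise)) ||
      any(twist <= 0) || any(rise <= 0)) {
    stop("twist and rise must be finite and > 0", call. = FALSE)
  }
  (360 / twist) * rise
}

#' Crossover distance from pitch
#'
#' In projection a C1 amyloid fibril repeats every half turn, so the
#' apparent crossover distance on a micrograph is half the pitch.
#'
#' @param pitch Helical pitch in angstroms (> 0).
#' @return Crossover distance in angstroms.
#' @export
crossover_from_pitch <- function(pitch) {
  if (any(!is.finite(pitch)) || any(pitch <= 0)) {
    stop("pitch must be finite and > 0", call. = FALSE)
  }
  pitch / 2
}

#' Inter-box distance as a percentage of the box size
#'
#' Segment extraction for helical reconstruction places boxes at a fixed
#' axial spacing; the spacing is conventionally reported as a percentage of
#' the box edge (e.g. 33.6 A in a 312 A box is ~11%).
#'
#' @param interbox Inter-box distance in angstroms; must satisfy
#'   `0 < interbox <= box`.
#' @param box Box size in angstroms.
#' @return Percentage, `100 * interbox / box`. The nearest-integer value
#'   is attached as attribute `"rounded"`.
#' @export
interbox_percentage <- function(interbox, box) {
  if (any(!is.finite(interbox)) || any(!is.finite(box)) ||
      any(interbox <= 0) || any(box <= 0)) {
    stop("interbox and box must be finite and > 0", call. = FALSE)
  }
  if (any(interbox > box)) {
    stop("interbox distance cannot exceed the box size", call. = FALSE)
  }
  pct <- 100 * interbox / box
  attr(pct, "rounded") <- round(pct)
  pct
}

#' Axial positions of equally spaced segments
#'
#' @param n_segments Number of segments (>= 0).
#' @param interbox Inter-box spacing in angstroms (> 0).
#' @return Numeric vector `0, interbox, ..., (n_segments - 1) * interbox`.
#' @export
axial_positions <- function(n_segments, interbox) {
  if (length(n_segments) != 1 || !is.finite(n_segments) || n_segments < 0 ||
      n_segments != floor(n_segments)) {
    stop("n_segments must be a single non-negative integer", call. = FALSE)
  }
  if (length(interbox) != 1 || !is.finite(interbox) || interbox <= 0) {
    stop("interbox must be a single positive number", call. = FALSE)
  }
  if (n_segments == 0) return(numeric(0))
  (seq_len(n_segments) - 1) * interbox
}

#' Helical lattice parameters
#'
#' Bundles twist and rise with the derived pitch and crossover distance.
#' Twist is stored as a magnitude plus a handedness flag, because the
#' handedness of an amyloid fibril is often an assumption rather than a
#' measurement and none of the derived axial distances depend on it.
#'
#' @param twist Per-subunit twist magnitude in degrees (> 0).
#' @param rise Per-subunit rise in angstroms (> 0).
#' @param handedness `"left"` or `"right"`.
#' @return An object of class `"helical_params"`: a list with elements
#'   `twist`, `rise`, `handedness`, `pitch` (A), `crossover` (A) and
#'   `pitch_nm` (pitch rounded to the nearest nanometre, the usual
#'   reporting unit).
#' @examples
#' helical_params(1.11, 4.79)
#' @export
helical_params <- function(twist, rise, handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  pitch <- pitch_from_twist_rise(twist, rise)
  structure(
    list(
      twist = twist,
      rise = rise,
      handedness = handedness,
      pitch = pitch,
      crossover = crossover_from_pitch(pitch),
      pitch_nm = round(pitch / 10)
    ),
    class = "helical_params"
  )
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "Helical parameters: twist %.4g deg (%s-handed), rise %.4g A\n",
    x$twist, x$handedness, x$rise
  ))
  cat(sprintf("  pitch     %.1f A (%d nm)\n", x$pitch, x$pitch_nm))
  cat(sprintf("  crossover %.1f A\n", x$crossover))
  invisible(x)
}

#' Segment extraction geometry
#'
#' @param box_px Box size in pixels (positive integer).
#' @param box_A Box size in angstroms.
#' @param interbox_A Inter-box distance in angstroms; must not exceed
#'   `box_A`.
#' @return An object of class `"extraction_geometry"` with the pixel size
#'   (`box_A / box_px`), the inter-box percentage and its nearest-integer
#'   rounding, and the overlap fraction between consecutive boxes.
#' @export
extraction_geometry <- function(box_px, box_A, interbox_A) {
  if (box_px <= 0 || box_px != floor(box_px)) {
    stop("box_px must be a positive integer", call. = FALSE)
  }
  pct <- interbox_percentage(interbox_A, box_A)
  structure(
    list(
      box_px = as.integer(box_px),
      box_A = box_A,
      interbox_A = interbox_A,
      pixel_size = box_A / box_px,
      interbox_percent = as.numeric(pct),
      interbox_percent_rounded = attr(pct, "rounded"),
      overlap_fraction = 1 - interbox_A / box_A
    ),
    class = "extraction_geometry"
  )
}

#' @export
print.extraction_geometry <- function(x, ...) {
  cat(sprintf(
    "Extraction geometry: box %d px (%.4g A, %.3f A/px)\n",
    x$box_px, x$box_A, x$pixel_size
  ))
  cat(sprintf(
    "  inter-box %.4g A = %.2f%% (~%d%%), overlap %.1f%%\n",
    x$interbox_A, x$interbox_percent, x$interbox_percent_rounded,
    100 * x$overlap_fraction
  ))
  invisible(x)
}
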