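#' Optical disector specification
#'
#' Counting-frame geometry for the optical disector: a 420 x 320 um frame,
#' a 10 um-thick counting depth, and a 2 um guard zone at the section's
#' upper surface inside which nothing is counted.
#'
#' @param frame_width_um,frame_height_um counting-frame size in um.
#' @param depth_um disector depth in um.
#' @param guard_um guard-zone thickness in um (must be < section thickness,
#'   checked against `section_um` when supplied).
#' @param section_um optional section thickness in um.
#' @return object of class `disector_spec`.
#' @export
disector_spec <- function(frame_width_um = 420, frame_height_um = 320,
                          depth_um = 10, guard_um = 2, section_um = NULL) {
  vals <- c(frame_width_um, frame_height_um, depth_um, guard_um)
  if (any(vals <= 0)) stop("all disector dimensions must be positive")
  if (!is.null(section_um) && guard_um >= section_um) {
    stop("guard zone must be thinner than the section")
  }
  structure(list(frame_width_um = frame_width_um,
                 frame_height_um = frame_height_um,
                 depth_um = depth_um, guard_um = guard_um),
            class = "disector_spec")
}

#' Apply the optical-disector counting rule
#'
#' A nucleus is counted iff its top comes into focus strictly below the
#' guard zone and within the disector depth: top depth in
#' `(guard, guard + depth]`. A nucleus already in focus at the top of the
#' disector (top depth <= guard) is excluded.
#'
#' @param nucleus_top_depths_um depths of nucleus tops from the section's
#'   upper surface, in um (>= 0).
#' @param spec a [disector_spec()].
#' @return numeric vector of the counted depths, with attribute `index`
#'   giving their positions in the input.
#' @export
apply_disector_rule <- function(nucleus_top_depths_um, spec = disector_spec()) {
  d <- as.numeric(nucleus_top_depths_um)
  if (anyNA(d) || any(d < 0)) stop("depths must be non-negative numbers")
  keep <- d > spec$guard_um & d <= spec$guard_um + spec$depth_um
  structure(d[keep], index = which(keep))
}

#' Numerical density from disector counts
#'
#' `Nv = count / (frame area x disector depth x number of frames)`. The
#' count inside the disector volume is complete, not an estimate, so the
#' division yields the absolute density within the sampled volume.
#'
#' @param n_counted total number of counted cells.
#' @param spec a [disector_spec()].
#' @param n_frames number of counting frames pooled.
#' @param out_unit `"mm3"` (cells/mm^3, default) or `"um3"`.
#' @return density in cells per `out_unit`.
#' @export
disector_density <- function(n_counted, spec = disector_spec(), n_frames = 1,
                             out_unit = c("mm3", "um3")) {
  out_unit <- match.arg(out_unit)
  if (n_counted < 0 || n_frames <= 0) stop("invalid counts")
  v_um3 <- spec$frame_width_um * spec$frame_height_um * spec$depth_um * n_frames
  dens_um3 <- n_counted / v_um3
  if (out_unit == "um3") dens_um3 else dens_um3 * 1e9
}

#' Cavalieri volume estimate
#'
#' `V(ref) = a(p) * t * sum(P)`: the point count per systematic section,
#' times the area represented by each grid point, times the section
#' spacing. Units are the caller's; supply area and spacing in the same
#' length unit (e.g. mm^2 and mm for a volume in mm^3).
#'
#' @param point_counts_per_section non-negative integer vector `P`.
#' @param area_per_point grid area represented by one point, `a(p)` > 0.
#' @param section_spacing distance between sections, `t` > 0.
#' @return the volume estimate.
#' @export
cavalieri_volume <- function(point_counts_per_section, area_per_point,
                             section_spacing) {
  P <- as.numeric(point_counts_per_section)
  if (anyNA(P) || any(P < 0)) stop("point counts must be non-negative")
  if (area_per_point <= 0 || section_spacing <= 0) {
    stop("area per point and section spacing must be positive")
  }
  area_per_point * section_spacing * sum(P)
}

#' Total cell number from density and reference volume
#'
#' `N = Nv * V(ref)`, with no rounding. Both inputs must be non-negative
#' and expressed in matching units (cells/mm^3 and mm^3).
#'
#' @param nv numerical density.
#' @param v_ref reference volume.
#' @return estimated total number of cells.
#' @export
total_number <- function(nv, v_ref) {
  if (any(c(nv, v_ref) < 0)) stop("density and volume must be non-negative")
  nv * v_ref
}

#' Gundersen-Jensen coefficient of error of a systematic point count
#'
#' CE of a Cavalieri-type count over systematically spaced sections, using
#' the smoothness-class m = 1 variance of the systematic sampling with a
#' point-counting noise term of `sum(P)`:
#' `var = (3(A - sum(P)) - 4B + C) / 240 + sum(P)` with
#' `A = sum(P_i^2)`, `B = sum(P_i P_(i+1))`, `C = sum(P_i P_(i+2))`, and
#' `CE = sqrt(var) / sum(P)`.
#'
#' @param point_counts_per_section integer vector, >= 3 sections in
#'   anatomical order.
#' @return CE (>= 0); `NA` with a warning when all counts are zero.
#' @export
gundersen_ce <- function(point_counts_per_section) {
  P <- as.numeric(point_counts_per_section)
  if (length(P) < 3L) stop("need at least 3 sections")
  if (anyNA(P) || any(P < 0)) stop("point counts must be non-negative")
  sP <- sum(P)
  if (sP == 0) {
    warning("all counts zero: CE undefined")
    return(NA_real_)
  }
  A <- sum(P^2)
  B <- sum(P[-length(P)] * P[-1L])
  C <- sum(P[seq_len(length(P) - 2L)] * P[-(1:2)])
  var_srs <- (3 * (A - sP) - 4 * B + C) / 240
  sqrt(max(var_srs + sP, 0)) / sP
}
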