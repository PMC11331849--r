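#' Ground-truth macular hole geometry
#'
#' Constructs the parametric model of a full-thickness macular hole (FTMH)
#' used throughout the simulator: the minimum linear diameter (MLD) and
#' basal diameter (BD) apertures are modelled as concentric circles in their
#' respective horizontal planes, with a hole height on the nasal and
#' temporal side measured perpendicular to the retinal pigment epithelium.
#' All lengths are in micrometres.
#'
#' @param d_mld True minimum linear diameter, um. Must satisfy
#'   `0 < d_mld <= d_bd` (the MLD aperture is nested within the basal
#'   aperture).
#' @param d_bd True basal diameter, um.
#' @param h_nasal,h_temporal Hole height on the nasal / temporal side, um;
#'   both strictly positive.
#' @param center_y Lateral offset of the hole centre from the raster centre
#'   along the slow-scan axis, um (positive superior).
#' @return An object of class `"macular_hole"`: a named list with the five
#'   fields above.
#' @examples
#' macular_hole(d_mld = 400, d_bd = 800, h_nasal = 420, h_temporal = 410)
#' @export
macular_hole <- function(d_mld, d_bd, h_nasal, h_temporal, center_y = 0) {
  stopifnot(is.numeric(d_mld), is.numeric(d_bd),
            is.numeric(h_nasal), is.numeric(h_temporal),
            is.numeric(center_y))
  if (!(d_mld > 0)) stop("d_mld must be > 0", call. = FALSE)
  if (d_mld > d_bd) stop("d_mld must not exceed d_bd", call. = FALSE)
  if (!(h_nasal > 0) || !(h_temporal > 0))
    stop("hole heights must be > 0", call. = FALSE)
  structure(
    list(d_mld = as.numeric(d_mld), d_bd = as.numeric(d_bd),
         h_nasal = as.numeric(h_nasal), h_temporal = as.numeric(h_temporal),
         center_y = as.numeric(center_y)),
    class = "macular_hole")
}

#' @export
print.macular_hole <- function(x, ...) {
  cat("<macular_hole>  MLD", x$d_mld, "um | BD", x$d_bd,
      "um | heights (n/t)", x$h_nasal, "/", x$h_temporal,
      "um | centre offset", x$center_y, "um\n")
  invisible(x)
}

#' Chord of a circular aperture cut by an offset b-scan
#'
#' A horizontal b-scan passing at perpendicular distance `offset` from the
#' centre of a circular aperture of the given diameter sees a chord of
#' length `2 * sqrt((diameter/2)^2 - offset^2)`; a slice at or beyond the
#' radius misses the aperture and sees width 0.
#'
#' @param diameter Aperture diameter, um (> 0). Vectorised.
#' @param offset Perpendicular slice offset from the aperture centre, um;
#'   the sign is irrelevant. Vectorised.
#' @return Chord length, um; always in `[0, diameter]`.
#' @examples
#' chord_width(400, 0)    # central slice recovers the full diameter
#' chord_width(400, 200)  # tangent slice sees nothing
#' @export
chord_width <- function(diameter, offset) {
  stopifnot(is.numeric(diameter), is.numeric(offset))
  if (any(diameter <= 0)) stop("diameter must be > 0", call. = FALSE)
  offset <- abs(offset)
  r <- diameter / 2
  ifelse(offset < r, 2 * sqrt(pmax(r^2 - offset^2, 0)), 0)
}

#' Minimum possible apparent size under discrete b-scan sampling
#'
#' A raster of parallel b-scans with spacing `s` samples a circular aperture
#' of true diameter `D` at an arbitrary phase. The observer reads the widest
#' chord over all slices; the worst raster phase places the nearest slices
#' symmetrically at offset s/2 on either side of the centre, so the smallest
#' apparent size the raster can produce is the chord at offset s/2:
#' `2 * sqrt((D/2)^2 - (s/2)^2) = sqrt(D^2 - s^2)`. When `s >= D` a raster
#' phase exists for which no slice intersects the aperture at all, and the
#' minimum apparent size is 0 (the hole is missed, not an error).
#'
#' @param true_diameter True aperture diameter `D`, um (> 0). Vectorised.
#' @param scan_spacing Distance `s` between consecutive b-scans, um (>= 0).
#'   Vectorised.
#' @return The minimum over raster phase of the maximum chord over slices,
#'   um; always in `[0, true_diameter]`.
#' @examples
#' min_apparent_size(457, 125)
#' min_apparent_size(300, 300)  # spacing equals diameter: hole can be missed
#' @export
min_apparent_size <- function(true_diameter, scan_spacing) {
  stopifnot(is.numeric(true_diameter), is.numeric(scan_spacing))
  if (any(true_diameter <= 0)) stop("true_diameter must be > 0", call. = FALSE)
  if (any(scan_spacing < 0)) stop("scan_spacing must be >= 0", call. = FALSE)
  ifelse(scan_spacing < true_diameter,
         sqrt(pmax(true_diameter^2 - scan_spacing^2, 0)), 0)
}

#' Relative undermeasurement of the apparent diameter
#'
#' The worst-case fractional shortfall `(D - min_apparent_size(D, s)) / D`.
#' For fixed spacing `s > 0` this is strictly decreasing in `D`: smaller
#' holes are proportionally the most undermeasured by a sparse raster.
#'
#' @inheritParams min_apparent_size
#' @return Fraction in `[0, 1]`.
#' @export
relative_undermeasurement <- function(true_diameter, scan_spacing) {
  (true_diameter - min_apparent_size(true_diameter, scan_spacing)) /
    true_diameter
}

#' Tabulate minimum apparent size over a grid (worst-case curves)
#'
#' Evaluates [min_apparent_size()] and [relative_undermeasurement()] over
#' the cross of the supplied true-diameter and scan-spacing grids, yielding
#' the family of worst-case curves relating apparent to true diameter for
#' each acquisition density.
#'
#' @param true_diameters Numeric vector of true diameters, um.
#' @param scan_spacings Numeric vector of b-scan spacings, um.
#' @return A data.frame with columns `true_diameter_um`, `scan_spacing_um`,
#'   `min_apparent_um`, `relative_undermeasurement`.
#' @examples
#' head(model_curve(seq(100, 800, by = 100), c(50, 125)))
#' @export
model_curve <- function(true_diameters = seq(50, 1000, by = 10),
                        scan_spacings = c(50, 125)) {
  g <- expand.grid(true_diameter_um = as.numeric(true_diameters),
                   scan_spacing_um = as.numeric(scan_spacings),
                   KEEP.OUT.ATTRS = FALSE)
  g$min_apparent_um <- min_apparent_size(g$true_diameter_um,
                                         g$scan_spacing_um)
  g$relative_undermeasurement <-
    relative_undermeasurement(g$true_diameter_um, g$scan_spacing_um)
  g
}
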