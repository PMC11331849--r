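#' Simulate the discrete b-scan acquisition of a macular hole
#'
#' Places `n_bscans` parallel horizontal slices along the slow-scan axis and
#' reports, per slice, the apparent MLD and BD chords of the hole's circular
#' apertures. The raster is centred on the field: the j-th slice (0-based)
#' sits at `phase - spacing/2 + (j - (n-1)/2) * spacing`, so that the raster
#' phase, uniform on `[0, spacing)`, shifts the whole grid by up to half a
#' spacing around the centred position. Slice offsets are reported relative
#' to the hole centre (`center_y`). Apparent hole height does not depend on
#' slice offset in this model (height error is attributed to display
#' scaling, not slice choice).
#'
#' @param hole A [macular_hole()] object.
#' @param protocol A [scan_protocol()] object.
#' @param phase Raster phase, um, in `[0, bscan_spacing)`.
#' @return A data.frame of class `"slice_profile"` with columns
#'   `slice_index` (0-based), `offset` (signed distance from the hole
#'   centre, um), `apparent_mld` and `apparent_bd` (chords, um).
#' @examples
#' h <- macular_hole(457, 900, 420, 410)
#' s <- acquire_raster(h, spectralis_like(), phase = 62.5)
#' widest_slice(s)
#' @export
acquire_raster <- function(hole, protocol, phase) {
  stopifnot(inherits(hole, "macular_hole"),
            inherits(protocol, "scan_protocol"),
            is.numeric(phase), length(phase) == 1)
  s <- protocol$bscan_spacing
  n <- protocol$n_bscans
  if (phase < 0 || phase >= s)
    stop("phase must lie in [0, bscan_spacing)", call. = FALSE)
  span <- (n - 1) * s
  if (span < hole$d_bd)
    warning("raster field (", span, " um) smaller than the basal diameter (",
            hole$d_bd, " um)", call. = FALSE)
  j <- seq_len(n) - 1
  position <- phase - s / 2 + (j - (n - 1) / 2) * s
  offset <- position - hole$center_y
  out <- data.frame(
    slice_index = j,
    offset = offset,
    apparent_mld = chord_width(hole$d_mld, offset),
    apparent_bd = chord_width(hole$d_bd, offset))
  class(out) <- c("slice_profile", "data.frame")
  out
}

#' Pick the slice with the widest apparent MLD
#'
#' Returns the slice maximising `apparent_mld` — the slice a careful grader
#' would select to measure on. Ties are broken deterministically: smaller
#' absolute offset first, then lower slice index.
#'
#' @param slices A `slice_profile` data.frame from [acquire_raster()]
#'   (non-empty).
#' @return A single-row `slice_profile`.
#' @export
widest_slice <- function(slices) {
  stopifnot(is.data.frame(slices))
  if (nrow(slices) == 0) stop("empty slice list", call. = FALSE)
  ord <- order(-slices$apparent_mld, abs(slices$offset), slices$slice_index)
  slices[ord[1], , drop = FALSE]
}
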