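#' OCT acquisition and display protocol
#'
#' Bundles the parameters of one OCT machine's macular-volume acquisition
#' and its default viewing platform: horizontal b-scan spacing and count,
#' lateral and axial resolution, and the default vertical display scaling
#' (horizontal:vertical aspect ratio of the viewer; values > 1 vertically
#' magnify the image).
#'
#' @param name Protocol label, e.g. `"spectralis-like"`.
#' @param bscan_spacing Distance between consecutive horizontal b-scans, um
#'   (> 0).
#' @param n_bscans Number of b-scans in the raster (>= 1).
#' @param lateral_resolution In-plane resolution, um/pixel (> 0).
#' @param axial_resolution Depth resolution, um/pixel (> 0).
#' @param default_vscale Default vertical scaling ratio of the viewing
#'   platform (>= 1; 1 means true 1:1 um display).
#' @return An object of class `"scan_protocol"`.
#' @seealso [spectralis_like()], [triton_like()] for the shipped presets.
#' @export
scan_protocol <- function(name, bscan_spacing, n_bscans,
                          lateral_resolution, axial_resolution,
                          default_vscale = 1) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(bscan_spacing > 0)) stop("bscan_spacing must be > 0", call. = FALSE)
  if (!(n_bscans >= 1)) stop("n_bscans must be >= 1", call. = FALSE)
  if (!(lateral_resolution > 0))
    stop("lateral_resolution must be > 0", call. = FALSE)
  if (!(axial_resolution > 0))
    stop("axial_resolution must be > 0", call. = FALSE)
  if (!(default_vscale >= 1)) stop("default_vscale must be >= 1", call. = FALSE)
  structure(
    list(name = name, bscan_spacing = as.numeric(bscan_spacing),
         n_bscans = as.integer(n_bscans),
         lateral_resolution = as.numeric(lateral_resolution),
         axial_resolution = as.numeric(axial_resolution),
         default_vscale = as.numeric(default_vscale)),
    class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "<scan_protocol> %s: %d b-scans @ %g um spacing | lateral %g um, axial %g um | default vscale 1:%g\n",
    x$name, x$n_bscans, x$bscan_spacing, x$lateral_resolution,
    x$axial_resolution, x$default_vscale))
  invisible(x)
}

#' Preset protocols for the two simulated machines
#'
#' `spectralis_like()` mirrors a sparse, high-resolution macular volume:
#' 49 b-scans at 125 um spacing, 5.7 um lateral and 3.9 um axial
#' resolution, default vertical scaling 1:3.775. `triton_like()` mirrors a
#' dense, lower-resolution volume: 149 b-scans at 50 um spacing, 20 um
#' lateral and 8 um axial resolution, default vertical scaling 1:2.
#'
#' @return A `scan_protocol` object.
#' @rdname protocol_presets
#' @export
spectralis_like <- function() {
  scan_protocol("spectralis-like", bscan_spacing = 125, n_bscans = 49,
                lateral_resolution = 5.7, axial_resolution = 3.9,
                default_vscale = 3.775)
}

#' @rdname protocol_presets
#' @export
triton_like <- function() {
  scan_protocol("triton-like", bscan_spacing = 50, n_bscans = 149,
                lateral_resolution = 20, axial_resolution = 8,
                default_vscale = 2)
}
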