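#' Behavioural model of a human grader
#'
#' Parameters of the three observer-level error mechanisms: (i) endpoint
#' localization jitter and a signed systematic bias, both scaling with the
#' machine's lateral resolution (ambiguous reference points on
#' low-resolution scans); (ii) a probability of measuring on a neighbouring
#' rather than the widest slice; (iii) an angular tolerance for how far from
#' vertical, in display coordinates, a "vertical" height calliper may drift
#' — the mechanism by which vertical display magnification inflates height
#' measurements.
#'
#' @param observer_id Label, e.g. `"observer1"`.
#' @param jitter_coeff Dimensionless multiplier mapping lateral resolution
#'   (um) to the per-endpoint localization SD (>= 0). Default 0.5.
#' @param bias_coeff Signed dimensionless multiplier mapping lateral
#'   resolution to a systematic per-measurement offset. Default 0.
#' @param slice_error_prob Probability of selecting a slice adjacent to the
#'   widest one, in `[0, 1]`. Default 0.
#' @param oblique_tol_deg Maximum apparent deviation from vertical tolerated
#'   when drawing a height calliper, degrees in display coordinates,
#'   `0 <= tol < 90`. Default 3.
#' @return An object of class `"observer_model"`.
#' @export
observer_model <- function(observer_id, jitter_coeff = 0.5, bias_coeff = 0,
                           slice_error_prob = 0, oblique_tol_deg = 3) {
  stopifnot(is.character(observer_id), length(observer_id) == 1)
  if (!(jitter_coeff >= 0)) stop("jitter_coeff must be >= 0", call. = FALSE)
  if (slice_error_prob < 0 || slice_error_prob > 1)
    stop("slice_error_prob must be in [0, 1]", call. = FALSE)
  if (oblique_tol_deg < 0 || oblique_tol_deg >= 90)
    stop("oblique_tol_deg must be in [0, 90)", call. = FALSE)
  structure(
    list(observer_id = observer_id,
         jitter_coeff = as.numeric(jitter_coeff),
         bias_coeff = as.numeric(bias_coeff),
         slice_error_prob = as.numeric(slice_error_prob),
         oblique_tol_deg = as.numeric(oblique_tol_deg)),
    class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(
    "<observer_model> %s: jitter %g x latres | bias %g x latres | slice error p=%g | oblique tol %g deg\n",
    x$observer_id, x$jitter_coeff, x$bias_coeff, x$slice_error_prob,
    x$oblique_tol_deg))
  invisible(x)
}

#' Default pair of observers for the simulated reading study
#'
#' Observer 1 carries a negative systematic bias proportional to lateral
#' resolution (consistently reads shorter on the low-resolution machine;
#' the bias vanishes as resolution improves); observer 2 is unbiased. Both
#' share the default jitter and oblique-tolerance settings. Slice-selection
#' error defaults to 0 here: in the default study world interobserver
#' differences are attributed to resolution-driven reference-point error,
#' and the slice-choice mechanism is exercised explicitly by setting
#' `slice_error_prob > 0`.
#'
#' @param slice_error_prob Shared slice-selection error probability.
#' @return A list of two [observer_model()] objects.
#' @export
default_observers <- function(slice_error_prob = 0) {
  list(observer_model("observer1", bias_coeff = -0.75,
                      slice_error_prob = slice_error_prob),
       observer_model("observer2", bias_coeff = 0,
                      slice_error_prob = slice_error_prob))
}

#' Simulate a manual horizontal calliper measurement
#'
#' Returns `max(0, true_width + bias + eps_L + eps_R)` where the bias is
#' `bias_coeff * lateral_resolution` and `eps_L`, `eps_R` are independent
#' zero-mean Gaussian endpoint errors with SD
#' `jitter_coeff * lateral_resolution`. Consumes two draws from the ambient
#' RNG stream; deterministic after `set.seed()`.
#'
#' @param true_width True width presented on the slice, um (>= 0).
#' @param protocol A [scan_protocol()]; supplies the lateral resolution.
#' @param obs An [observer_model()].
#' @return Measured width, um (>= 0).
#' @export
measure_horizontal <- function(true_width, protocol, obs) {
  stopifnot(inherits(protocol, "scan_protocol"),
            inherits(obs, "observer_model"))
  if (true_width < 0) stop("true_width must be >= 0", call. = FALSE)
  res <- protocol$lateral_resolution
  eps <- stats::rnorm(2, mean = 0, sd = obs$jitter_coeff * res)
  max(0, true_width + obs$bias_coeff * res + sum(eps))
}

#' Simulate a height measurement under vertical display scaling
#'
#' On a display with vertical magnification `vscale`, a calliper that looks
#' vertical to within `oblique_tol_deg` degrees may hide a horizontal
#' endpoint drift of up to `w = vscale * true_height * tan(tol)` um (the
#' displayed height is `vscale` times taller, so a given apparent angle
#' conceals proportionally more true horizontal drift). The drift is drawn
#' uniformly on `[-w, w]` and the calliper reports the oblique length
#' `sqrt(drift^2 + true_height^2)`, which is never below the true height.
#' Consumes one draw from the ambient RNG stream.
#'
#' @param true_height True height, um (> 0).
#' @param vscale Vertical display scaling ratio (>= 1; 1 = true 1:1 um).
#' @param obs An [observer_model()]; supplies `oblique_tol_deg`.
#' @return Measured height, um (>= `true_height`).
#' @export
measure_height_scaled <- function(true_height, vscale, obs) {
  stopifnot(inherits(obs, "observer_model"))
  if (!(true_height > 0)) stop("true_height must be > 0", call. = FALSE)
  if (!(vscale >= 1)) stop("vscale must be >= 1", call. = FALSE)
  w <- vscale * true_height * tan(obs$oblique_tol_deg * pi / 180)
  drift <- stats::runif(1, -w, w)
  if (drift == 0) return(true_height)  # exact in the perfectly vertical limit
  sqrt(drift^2 + true_height^2)
}

#' Simulate the grader's slice selection
#'
#' With probability `1 - slice_error_prob` returns [widest_slice()];
#' otherwise returns an adjacent slice (index +/- 1 in list order, chosen
#' equiprobably, clamped to the available range). Consumes up to two draws
#' from the ambient RNG stream.
#'
#' @param slices A `slice_profile` data.frame (non-empty).
#' @param obs An [observer_model()].
#' @return A single-row `slice_profile`.
#' @export
select_slice <- function(slices, obs) {
  stopifnot(inherits(obs, "observer_model"), is.data.frame(slices))
  if (nrow(slices) == 0) stop("empty slice list", call. = FALSE)
  best <- widest_slice(slices)
  if (nrow(slices) == 1) return(best)
  if (stats::runif(1) >= obs$slice_error_prob) return(best)
  pos <- which(slices$slice_index == best$slice_index)
  step <- if (stats::runif(1) < 0.5) -1L else 1L
  pick <- min(max(pos + step, 1L), nrow(slices))
  slices[pick, , drop = FALSE]
}
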