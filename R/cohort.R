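#' Configuration of a synthetic FTMH cohort
#'
#' Distributional parameters for a simulated case mix of full-thickness
#' macular holes. MLD is lognormal (most holes a few hundred um with a long
#' right tail), the basal-to-MLD diameter ratio is uniform on a range above
#' 1, heights are Gaussian truncated at zero, and each eye carries a
#' fixation error that decentres the raster relative to the fovea.
#'
#' @param n_eyes Number of eyes (>= 1). Default 8, the emulated study size.
#' @param mld_log_mean,mld_log_sd Lognormal parameters of the true MLD (um).
#'   Defaults `log(350)` and 0.45.
#' @param bd_ratio_min,bd_ratio_max Uniform range of `d_bd / d_mld`
#'   (`bd_ratio_min > 1`). Defaults 1.5 and 2.5.
#' @param height_mean,height_sd Gaussian parameters of nasal and temporal
#'   hole height (um), truncated at > 0. Defaults 420 and 60.
#' @param fixation_sd Per-eye raster decentration SD, um (>= 0). Default 50.
#' @param seed RNG seed for [generate_cohort()].
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_eyes = 8,
                          mld_log_mean = log(350), mld_log_sd = 0.45,
                          bd_ratio_min = 1.5, bd_ratio_max = 2.5,
                          height_mean = 420, height_sd = 60,
                          fixation_sd = 50, seed = 1L) {
  if (!(n_eyes >= 1)) stop("n_eyes must be >= 1", call. = FALSE)
  if (!(bd_ratio_min > 1)) stop("bd_ratio_min must be > 1", call. = FALSE)
  if (bd_ratio_max < bd_ratio_min)
    stop("bd_ratio_max must be >= bd_ratio_min", call. = FALSE)
  if (mld_log_sd < 0 || height_sd < 0 || fixation_sd < 0)
    stop("all SDs must be >= 0", call. = FALSE)
  structure(
    list(n_eyes = as.integer(n_eyes),
         mld_log_mean = as.numeric(mld_log_mean),
         mld_log_sd = as.numeric(mld_log_sd),
         bd_ratio_min = as.numeric(bd_ratio_min),
         bd_ratio_max = as.numeric(bd_ratio_max),
         height_mean = as.numeric(height_mean),
         height_sd = as.numeric(height_sd),
         fixation_sd = as.numeric(fixation_sd),
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Deterministic child seed from a master seed and stream indices; the
# modulus keeps every derived seed a valid 32-bit R integer and the
# multipliers keep intermediate products well inside double precision.
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483629
  for (k in c(...)) {
    x <- (x * 1103 + as.numeric(k) * 7919 + 104729) %% 2147483629
  }
  as.integer(x)
}

#' Generate a seeded cohort of macular holes
#'
#' Draws `n_eyes` hole geometries from the distributions in `cfg`. Heights
#' are redrawn until positive. Deterministic given `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return A data.frame of class `"ftmh_cohort"` with columns `eye_id`,
#'   `d_mld`, `d_bd`, `h_nasal`, `h_temporal` (um). The `fixation_sd` used
#'   downstream by [simulate_study()] is carried as an attribute.
#' @examples
#' generate_cohort(cohort_config(n_eyes = 3, seed = 7))
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(derive_seed(cfg$seed, 1))
  n <- cfg$n_eyes
  d_mld <- exp(stats::rnorm(n, cfg$mld_log_mean, cfg$mld_log_sd))
  ratio <- stats::runif(n, cfg$bd_ratio_min, cfg$bd_ratio_max)
  rtruncnorm <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  out <- data.frame(
    eye_id = sprintf("eye%03d", seq_len(n)),
    d_mld = d_mld,
    d_bd = d_mld * ratio,
    h_nasal = rtruncnorm(n, cfg$height_mean, cfg$height_sd),
    h_temporal = rtruncnorm(n, cfg$height_mean, cfg$height_sd))
  attr(out, "fixation_sd") <- cfg$fixation_sd
  class(out) <- c("ftmh_cohort", "data.frame")
  out
}

#' Simulate the full two-machine, multi-observer reading study
#'
#' Emulates the study design: each eye is imaged once per protocol (one
#' raster phase, uniform on `[0, spacing)`, and one fixation decentration
#' per eye-protocol pair, shared by all observers, who read the same
#' acquired volume); each observer then independently selects a slice
#' ([select_slice()]), measures MLD and BD on its chords
#' ([measure_horizontal()]) and both hole heights
#' ([measure_height_scaled()]) at the protocol's default vertical scaling
#' (or at 1:1 when `use_default_vscale = FALSE`). Child RNG streams are
#' derived per eye/protocol/observer from the master seed, so subsetting
#' the cohort does not shift downstream draws.
#'
#' @param cohort An `ftmh_cohort` from [generate_cohort()].
#' @param protocols Non-empty list of [scan_protocol()] objects.
#' @param observers Non-empty list of [observer_model()] objects.
#' @param use_default_vscale If `TRUE` (default) heights are measured at
#'   each protocol's default display scaling; if `FALSE` at 1:1.
#' @param seed Master seed for all acquisition and observer randomness.
#' @param fixation_sd Raster decentration SD, um; defaults to the value
#'   carried by the cohort (50 if absent).
#' @return A data.frame of measurement records, one row per
#'   eye x machine x observer x parameter, with columns `eye_id`,
#'   `machine`, `observer`, `parameter` (one of `MLD`, `BD`, `HH_nasal`,
#'   `HH_temporal`), `value_um`, `vscale_used`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_eyes = 2, seed = 3))
#' rec <- simulate_study(coh, list(spectralis_like(), triton_like()),
#'                       default_observers(), seed = 3)
#' nrow(rec)  # 2 eyes x 2 machines x 2 observers x 4 parameters = 32
#' @export
simulate_study <- function(cohort, protocols, observers,
                           use_default_vscale = TRUE, seed = 1L,
                           fixation_sd = NULL) {
  stopifnot(is.data.frame(cohort))
  if (!length(protocols)) stop("protocols must be non-empty", call. = FALSE)
  if (!length(observers)) stop("observers must be non-empty", call. = FALSE)
  stopifnot(all(vapply(protocols, inherits, TRUE, "scan_protocol")),
            all(vapply(observers, inherits, TRUE, "observer_model")))
  if (is.null(fixation_sd))
    fixation_sd <- attr(cohort, "fixation_sd") %||% 50

  rows <- vector("list", nrow(cohort) * length(protocols) * length(observers))
  r <- 0L
  for (i in seq_len(nrow(cohort))) {
    eye <- cohort[i, ]
    for (m in seq_along(protocols)) {
      p <- protocols[[m]]
      set.seed(derive_seed(seed, i, m, 0))
      phase <- stats::runif(1, 0, p$bscan_spacing)
      decentre <- stats::rnorm(1, 0, fixation_sd)
      hole <- macular_hole(eye$d_mld, eye$d_bd, eye$h_nasal, eye$h_temporal,
                           center_y = decentre)
      slices <- acquire_raster(hole, p, phase)
      vs <- if (use_default_vscale) p$default_vscale else 1
      for (o in seq_along(observers)) {
        ob <- observers[[o]]
        set.seed(derive_seed(seed, i, m, o))
        sl <- select_slice(slices, ob)
        vals <- c(
          MLD = measure_horizontal(sl$apparent_mld, p, ob),
          BD = measure_horizontal(sl$apparent_bd, p, ob),
          HH_nasal = measure_height_scaled(hole$h_nasal, vs, ob),
          HH_temporal = measure_height_scaled(hole$h_temporal, vs, ob))
        r <- r + 1L
        rows[[r]] <- data.frame(
          eye_id = eye$eye_id, machine = p$name, observer = ob$observer_id,
          parameter = names(vals), value_um = unname(vals), vscale_used = vs)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write measurement tables
#'
#' The on-disk format is a UTF-8 comma-separated table with header
#' `eye_id,machine,observer,parameter,value_um,vscale_used` and `.` as the
#' decimal mark. The reader tolerates extra columns; the writer is
#' bit-stable for a fixed seed.
#'
#' @param records A measurement data.frame from [simulate_study()].
#' @param path File path.
#' @return `read_measurements()` returns the measurement data.frame;
#'   `write_measurements()` returns `path` invisibly.
#' @rdname measurement_io
#' @export
write_measurements <- function(records, path) {
  cols <- c("eye_id", "machine", "observer", "parameter", "value_um",
            "vscale_used")
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname measurement_io
#' @export
read_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  need <- c("eye_id", "machine", "observer", "parameter", "value_um")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("measurement file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(x$value_um < 0)) stop("negative value_um in file", call. = FALSE)
  bad <- setdiff(unique(x$parameter),
                 c("MLD", "BD", "HH_nasal", "HH_temporal"))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x
}
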