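#' Bland-Altman agreement between two paired measurement series
#'
#' Computes the mean difference (bias) and the 95% limits of agreement
#' `bias +/- 1.96 * sd(a - b)` (sample SD, n - 1 denominator; the classical
#' large-sample multiplier, no t correction), together with the per-pair
#' (mean, difference) points used for plotting.
#'
#' @param a,b Numeric vectors of paired measurements (um), equal length
#'   >= 2, no missing values.
#' @param labels Optional unit identifiers, recycled onto the points table.
#' @return An object of class `"bland_altman"`: a list with `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `n`, and a `points` data.frame with
#'   columns `label`, `mean`, `diff`.
#' @examples
#' ba <- bland_altman(c(400, 350, 500), c(390, 360, 480))
#' ba$bias
#' @export
bland_altman <- function(a, b, labels = NULL) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("insufficient data: need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(bias = bias,
         loa_low = bias - 1.96 * sd_d,
         loa_high = bias + 1.96 * sd_d,
         sd_diff = sd_d, n = n,
         points = data.frame(
           label = if (is.null(labels)) as.character(seq_len(n))
                   else as.character(labels),
           mean = (a + b) / 2, diff = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d | bias %.2f um | 95%% LoA [%.2f, %.2f] um\n",
    x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Two-way absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Single-measurement absolute-agreement ICC from the two-way ANOVA
#' decomposition of a complete subjects x raters matrix. With `n` subjects,
#' `k` raters and mean squares `MSR` (subjects), `MSC` (raters), `MSE`
#' (residual):
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#'
#' The 95% confidence interval and the test of ICC = 0 (observed F =
#' MSR/MSE on `(n-1, (n-1)(k-1))` degrees of freedom) follow the F-based
#' procedure of McGraw & Wong (1996) for this form, with the
#' Satterthwaite-style denominator degrees of freedom for the interval.
#' This form penalises systematic rater offsets as well as random error.
#'
#' @param m Numeric matrix, subjects in rows (>= 2), raters in columns
#'   (>= 2), complete (no missing cells).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `"icc_absolute"`: a list with `icc`,
#'   `icc_ci_low`, `icc_ci_high`, `p_value`, `n_subjects`, `n_raters`, the
#'   mean squares `msr`, `msc`, `mse`, and a logical `degenerate` flag. A
#'   constant matrix (zero total variance) yields a flagged degenerate
#'   report with `NA` estimates rather than an error.
#' @references McGraw, K.O. & Wong, S.P. (1996). Forming inferences about
#'   some intraclass correlation coefficients. Psychological Methods 1(1),
#'   30-46.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
#' icc_absolute(m)
#' @export
icc_absolute <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("matrix must be numeric", call. = FALSE)
  if (anyNA(m)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- max(sse / ((n - 1) * (k - 1)), 0)  # guard tiny negative round-off

  if (sst < .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    return(structure(
      list(icc = NA_real_, icc_ci_low = NA_real_, icc_ci_high = NA_real_,
           p_value = NA_real_, n_subjects = n, n_raters = k,
           msr = msr, msc = msc, mse = mse, degenerate = TRUE),
      class = "icc_absolute"))
  }

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  # McGraw & Wong (1996), case 2A single measures: F-based interval with
  # Satterthwaite denominator df v built from the point estimate.
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  f_obs <- msr / mse
  p <- if (is.finite(f_obs)) {
    stats::pf(f_obs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else 0

  structure(
    list(icc = icc,
         icc_ci_low = min(ci_low, icc), icc_ci_high = max(ci_high, icc),
         p_value = p, n_subjects = n, n_raters = k,
         msr = msr, msc = msc, mse = mse, degenerate = FALSE),
    class = "icc_absolute")
}

#' @export
print.icc_absolute <- function(x, ...) {
  if (x$degenerate) {
    cat("<icc_absolute> degenerate (constant matrix): ICC undefined\n")
  } else {
    cat(sprintf(
      "<icc_absolute> ICC(A,1) = %.4f (95%% CI %.4f to %.4f, p = %.3g) | n = %d subjects, k = %d raters\n",
      x$icc, x$icc_ci_low, x$icc_ci_high, x$p_value, x$n_subjects,
      x$n_raters))
  }
  invisible(x)
}

#' Stratified agreement reports over a measurement table
#'
#' Runs the agreement analysis on a long measurement table (columns
#' `eye_id`, `machine`, `observer`, `parameter`, `value_um`).
#'
#' In `"observer"` mode the two observers' readings are paired within each
#' (eye, machine, parameter) unit. In `"machine"` mode the readings of the
#' two observers are first averaged within each (eye, machine, parameter) —
#' machine agreement is assessed on the observer-mean — and the two
#' machines are then paired within each (eye, parameter) unit.
#'
#' One report ([bland_altman()] bias and limits plus [icc_absolute()]) is
#' produced per parameter present, plus a pooled report over all pairs.
#' Units lacking both levels of the pairing factor are listed in the
#' exclusion log rather than silently dropped.
#'
#' @param records Measurement data.frame from [simulate_study()] or
#'   [read_measurements()].
#' @param mode `"observer"` or `"machine"`.
#' @param parameters Optional subset of parameters to retain before
#'   pairing (default: all present).
#' @param machines,observers Optional explicit ordering of the two levels
#'   to pair as (a, b); defaults to sorted unique values found in the data.
#' @return An object of class `"agreement_report"`: a list with `mode`,
#'   `pair` (the two paired level names), `by_parameter` (named list of
#'   per-parameter strata), `pooled`, and `excluded` (character vector of
#'   incomplete unit keys). Each stratum holds `bland_altman`, `icc`, and
#'   `n_pairs`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_eyes = 8, seed = 11))
#' rec <- simulate_study(coh, list(spectralis_like(), triton_like()),
#'                       default_observers(), seed = 11)
#' rep <- stratified_report(rec, mode = "observer")
#' rep$pooled$icc
#' @export
stratified_report <- function(records, mode = c("observer", "machine"),
                              parameters = NULL, machines = NULL,
                              observers = NULL) {
  mode <- match.arg(mode)
  need <- c("eye_id", "machine", "observer", "parameter", "value_um")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (!is.null(parameters))
    records <- records[records$parameter %in% parameters, , drop = FALSE]
  if (!nrow(records)) stop("no records after filtering", call. = FALSE)

  if (mode == "observer") {
    lv <- observers %||% sort(unique(records$observer))
    if (length(lv) != 2)
      stop("observer mode needs exactly 2 observer levels", call. = FALSE)
    records <- records[records$observer %in% lv, , drop = FALSE]
    key <- interaction(records$eye_id, records$machine, records$parameter,
                       drop = TRUE, sep = "|")
    fac <- records$observer
  } else {
    lv <- machines %||% sort(unique(records$machine))
    if (length(lv) != 2)
      stop("machine mode needs exactly 2 machine levels", call. = FALSE)
    records <- records[records$machine %in% lv, , drop = FALSE]
    # the paper's rule: machine agreement uses the mean of the observers
    agg <- stats::aggregate(
      value_um ~ eye_id + machine + parameter, data = records, FUN = mean)
    records <- agg
    key <- interaction(records$eye_id, records$parameter,
                       drop = TRUE, sep = "|")
    fac <- records$machine
  }

  wide_a <- tapply(records$value_um, list(key, factor(fac, levels = lv)),
                   function(v) if (length(v) == 1) v else NA_real_)
  complete <- stats::complete.cases(wide_a)
  excluded <- rownames(wide_a)[!complete]
  wide <- wide_a[complete, , drop = FALSE]
  if (nrow(wide) < 2)
    stop("insufficient data: fewer than 2 complete pairs", call. = FALSE)

  param_of <- vapply(strsplit(rownames(wide), "|", fixed = TRUE),
                     function(p) p[[length(p)]], character(1))

  one_stratum <- function(w) {
    list(bland_altman = bland_altman(w[, 1], w[, 2], labels = rownames(w)),
         icc = icc_absolute(w),
         n_pairs = nrow(w))
  }
  by_par <- lapply(split(seq_len(nrow(wide)), param_of), function(idx) {
    w <- wide[idx, , drop = FALSE]
    if (nrow(w) < 2) return(NULL)
    one_stratum(w)
  })
  by_par <- by_par[!vapply(by_par, is.null, TRUE)]

  structure(
    list(mode = mode, pair = lv, by_parameter = by_par,
         pooled = one_stratum(wide), excluded = excluded),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> mode = %s: %s vs %s\n",
              x$mode, x$pair[1], x$pair[2]))
  show1 <- function(nm, s) {
    ba <- s$bland_altman
    ic <- s$icc
    icc_txt <- if (ic$degenerate) "ICC degenerate" else
      sprintf("ICC %.3f (%.3f to %.3f)", ic$icc, ic$icc_ci_low,
              ic$icc_ci_high)
    cat(sprintf("  %-12s n=%3d  bias %8.2f um  LoA [%8.2f, %8.2f]  %s\n",
                nm, s$n_pairs, ba$bias, ba$loa_low, ba$loa_high, icc_txt))
  }
  for (nm in names(x$by_parameter)) show1(nm, x$by_parameter[[nm]])
  show1("pooled", x$pooled)
  if (length(x$excluded))
    cat("  excluded incomplete units:", length(x$excluded), "\n")
  invisible(x)
}
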