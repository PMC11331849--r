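# Independent brute-force oracles, kept free of the closed forms they check.

# Worst-case apparent size by exhaustive phase sweep: for each raster phase
# place slices at phi + j*s across the aperture, take the widest chord a
# reader could see, then take the minimum over phases. Chords are computed
# from the circle equation directly, not via the package.
phase_sweep_min_apparent <- function(D, s, phase_step = 0.01) {
  if (s == 0) return(D)
  phases <- seq(0, s - phase_step / 2, by = phase_step)
  j <- seq(floor(-D / s) - 1, ceiling(D / s) + 1)
  off <- outer(phases, j * s, `+`)          # phases x slices offsets
  r <- D / 2
  ch <- ifelse(abs(off) < r, 2 * sqrt(pmax(r^2 - off^2, 0)), 0)
  min(apply(ch, 1, max))
}

# Chord length by numeric intersection of the circle x^2 + y^2 = r^2 with
# the horizontal line y = offset, via root finding on each side.
numeric_chord <- function(diameter, offset) {
  r <- diameter / 2
  if (abs(offset) >= r) return(0)
  f <- function(x) x^2 + offset^2 - r^2
  hi <- stats::uniroot(f, c(0, r), tol = 1e-12)$root
  2 * hi
}

# Direct two-way ANOVA sums for a subjects x raters matrix, written out
# longhand (no lm/aov, no package code).
hand_anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - g)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + g)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

default_protocol_pair <- function() list(spectralis_like(), triton_like())
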