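test_that("bland_altman reproduces hand-computed bias and limits", {
  eq <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$bias, 0)
  expect_equal(eq$loa_low, 0)
  expect_equal(eq$loa_high, 0)
  # differences {+10, -10}: bias 0, sample SD sqrt(200)
  ba <- bland_altman(c(110, 90), c(100, 100))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(200))
  expect_equal(ba$loa_low, -1.96 * sqrt(200))
  expect_equal(ba$points$diff, c(10, -10))
  expect_equal(ba$points$mean, c(105, 95))
  expect_error(bland_altman(1, numeric(0)), "equal length")
  expect_error(bland_altman(5, 3), "insufficient")
  expect_error(bland_altman(c(1, NA), c(1, 2)), "missing")
})

test_that("bland_altman is translation equivariant with fixed LoA width", {
  set.seed(21)
  a <- rnorm(50, 400, 40); b <- a + rnorm(50, 5, 10)
  ba <- bland_altman(a, b)
  ba_sh <- bland_altman(a, b + 17)
  expect_equal(ba_sh$bias, ba$bias - 17)
  expect_equal(ba_sh$loa_high - ba_sh$loa_low, ba$loa_high - ba$loa_low)
})

test_that("ICC(A,1) on the 4x2 toy matrix matches the hand ANOVA", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
  ms <- hand_anova_ms(m)
  icc_hand <- (ms$msr - ms$mse) /
    (ms$msr + (2 - 1) * ms$mse + (2 / 4) * (ms$msc - ms$mse))
  r <- icc_absolute(m)
  expect_equal(r$icc, icc_hand, tolerance = 1e-12)
  expect_equal(r$icc, 40 / 43, tolerance = 1e-12)  # exact rational hand value
  expect_equal(r$msr, ms$msr)
  expect_equal(r$msc, ms$msc)
  expect_equal(r$mse, ms$mse)
  expect_true(r$icc_ci_low <= r$icc && r$icc <= r$icc_ci_high)
})

test_that("ICC(A,1) estimate, CI and p match an independent implementation", {
  # frozen from pingouin.intraclass_corr (ICC(A,1) row) on this exact matrix
  set.seed(42)
  m <- matrix(rnorm(40 * 3, sd = 10), ncol = 3) + rnorm(40)
  r <- icc_absolute(m)
  expect_equal(r$icc, 0.12225851165662455, tolerance = 1e-10)
  expect_equal(r$p_value, 0.0997749862538832, tolerance = 1e-10)
  expect_equal(r$icc_ci_low, -0.06, tolerance = 0.01)   # oracle printed 2 dp
  expect_equal(r$icc_ci_high, 0.34, tolerance = 0.01)
})

test_that("ICC degenerate and perfect-agreement cases behave", {
  const <- matrix(5, nrow = 4, ncol = 2)
  r <- icc_absolute(const)
  expect_true(r$degenerate)
  expect_true(is.na(r$icc))
  ident <- matrix(c(1, 1, 4, 4, 9, 9), ncol = 2, byrow = TRUE)
  expect_equal(icc_absolute(ident)$icc, 1)
  expect_error(icc_absolute(matrix(1:2, ncol = 2)), "at least 2")
  expect_error(icc_absolute(matrix(c(1, NA, 3, 4), ncol = 2)), "complete")
})

test_that("ICC(A,1) invariances: relabeling and common shifts, not column shifts", {
  set.seed(13)
  m <- matrix(rnorm(30 * 2, 300, 50), ncol = 2) + rnorm(30, 0, 40)
  base <- icc_absolute(m)$icc
  expect_equal(icc_absolute(m[sample(nrow(m)), ])$icc, base)
  expect_equal(icc_absolute(m + 100)$icc, base)
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 30
  expect_lt(icc_absolute(shifted)$icc, base)   # absolute agreement penalty
})

test_that("ICC(A,1) recovers the population value from variance components", {
  set.seed(99)
  n <- 500; k <- 2
  subj <- rnorm(n, 0, 10)                # sigma2_subj = 100
  rater <- rnorm(k, 0, 1)                # sigma2_rater = 1
  m <- outer(subj, rep(1, k)) + outer(rep(1, n), rater) +
    matrix(rnorm(n * k, 0, 2), n, k)     # sigma2_err = 4
  pop <- 100 / (100 + 1 + 4)
  expect_equal(icc_absolute(m)$icc, pop, tolerance = 0.02 / pop)
})

test_that("LoA cover about 95% of large Gaussian samples", {
  set.seed(55)
  a <- rnorm(1e5, 400, 30)
  b <- a + rnorm(1e5, 8, 20)
  ba <- bland_altman(a, b)
  d <- a - b
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_equal(cover, 0.95, tolerance = 0.01 / 0.95)
})

test_that("observer-mode stratified report pairs readings within units", {
  coh <- generate_cohort(cohort_config(n_eyes = 8, seed = 3))
  rec <- simulate_study(coh, default_protocol_pair(), default_observers(),
                        seed = 3)
  rep <- stratified_report(rec, mode = "observer")
  expect_equal(rep$pooled$n_pairs, 64)    # 8 eyes x 2 machines x 4 params
  expect_setequal(names(rep$by_parameter),
                  c("MLD", "BD", "HH_nasal", "HH_temporal"))
  expect_equal(rep$by_parameter$MLD$n_pairs, 16)
  per_machine <- stratified_report(
    rec[rec$machine == "triton-like", ], mode = "observer")
  expect_equal(per_machine$pooled$n_pairs, 32)
  expect_length(rep$excluded, 0)
  expect_output(print(rep), "pooled")
})

test_that("identical observers give perfect pooled interobserver agreement", {
  coh <- generate_cohort(cohort_config(n_eyes = 8, seed = 6))
  rec <- simulate_study(coh, default_protocol_pair(), default_observers(),
                        seed = 6)
  dup <- rec
  dup$value_um[dup$observer == "observer2"] <-
    dup$value_um[dup$observer == "observer1"]
  rep <- stratified_report(dup, mode = "observer")
  expect_equal(rep$pooled$bland_altman$bias, 0)
  expect_equal(rep$pooled$icc$icc, 1)
})

test_that("machine mode averages observers then penalises a constant offset", {
  coh <- generate_cohort(cohort_config(n_eyes = 8, seed = 14))
  rec <- simulate_study(coh, default_protocol_pair(),
                        list(observer_model("o1", jitter_coeff = 0),
                             observer_model("o2", jitter_coeff = 0)),
                        use_default_vscale = FALSE, seed = 14)
  # machine B = machine A + 50 um everywhere
  base <- rec[rec$machine == "spectralis-like", ]
  shift <- base
  shift$machine <- "triton-like"
  shift$value_um <- shift$value_um + 50
  rep <- stratified_report(rbind(base, shift), mode = "machine")
  expect_equal(rep$pooled$bland_altman$bias, -50)   # A - B
  expect_lt(rep$pooled$icc$icc, 1)
  wideA <- base$value_um
  expect_equal(cor(wideA, wideA + 50), 1)   # consistency correlation blind
})

test_that("machine mode applies the observer-mean rule", {
  rec <- data.frame(
    eye_id = rep(c("e1", "e2", "e3"), each = 4),
    machine = rep(c("A", "A", "B", "B"), 3),
    observer = rep(c("o1", "o2"), 6),
    parameter = "MLD",
    value_um = c(100, 110, 200, 220,  300, 290, 400, 380,  150, 170, 240, 260))
  rep <- stratified_report(rec, mode = "machine")
  # pairs are mean(o1,o2): A = {105, 295, 160}, B = {210, 390, 250}
  expect_equal(rep$pooled$bland_altman$bias,
               mean(c(105 - 210, 295 - 390, 160 - 250)))
  expect_equal(rep$pooled$n_pairs, 3)
})

test_that("incomplete units land in the exclusion log", {
  coh <- generate_cohort(cohort_config(n_eyes = 4, seed = 17))
  rec <- simulate_study(coh, default_protocol_pair(), default_observers(),
                        seed = 17)
  drop1 <- rec[-which(rec$observer == "observer2" &
                        rec$eye_id == "eye001" &
                        rec$machine == "triton-like" &
                        rec$parameter == "MLD"), ]
  rep <- stratified_report(drop1, mode = "observer")
  expect_length(rep$excluded, 1)
  expect_match(rep$excluded, "eye001")
  expect_equal(rep$pooled$n_pairs, 31)
  two_pairs <- rec[rec$eye_id == "eye001" & rec$parameter == "MLD", ]
  expect_s3_class(stratified_report(two_pairs, mode = "observer"),
                  "agreement_report")
  expect_error(stratified_report(two_pairs[1:2, ], mode = "observer"),
               "insufficient|2 observer")
})
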