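test_that("calibration slope converts to PCR efficiency", {
  # perfect doubling: slope -1/log10(2) = -3.3219 -> efficiency 1
  lg <- 1:5
  cal <- fit_calibration(lg, 40 - 3.321928 * lg)
  expect_equal(cal$efficiency, 1.0, tolerance = 1e-5)
  expect_equal(cal$r_squared, 1.0)

  cal96 <- fit_calibration(lg, 40 - 3.42 * lg)
  expect_equal(cal96$efficiency, 0.96, tolerance = 0.005)

  expect_error(fit_calibration(c(1, 2), c(35, 32)), ">= 3")
  expect_error(fit_calibration(lg, 30 + 2 * lg), "negative")
})

test_that("noiseless generated dilution series recovers its efficiency", {
  cfg <- sim_config(seed = 3,
                    qpcr = list(efficiency = 0.96, intercept = 38,
                                cq_noise_sd = 0))
  sim <- make_qpcr(10^5, cfg)
  cal <- fit_calibration(sim$calibration$log10_copies, sim$calibration$cq)
  expect_equal(cal$efficiency, 0.96, tolerance = 1e-6)
  # ten-fold dilutions are 3.42 cycles apart at 96%
  expect_equal(abs(diff(sim$calibration$cq))[1], 3.42, tolerance = 0.005)
})

test_that("copies_from_cq inverts the calibration line", {
  lg <- 1:6
  cal <- fit_calibration(lg, 38 - 3.42 * lg)
  expect_equal(copies_from_cq(38 - 3.42 * 0, cal), 1, tolerance = 1e-6)
  expect_warning(one <- copies_from_cq(cal$intercept, cal), "extrapolating")
  expect_equal(one, 1, tolerance = 1e-6)
  expect_equal(copies_from_cq(cal$intercept + cal$slope, cal), 10,
               tolerance = 1e-6)
  expect_equal(copies_from_cq(predict(cal, 1e5), cal), 1e5, tolerance = 1e-6)
  expect_equal(unname(coef(cal)), c(38, -3.42), tolerance = 1e-6)
})

test_that("efficiency decreases as the slope steepens past perfect doubling", {
  slopes <- c(-3.3219, -3.42, -3.6, -3.9)
  effs <- vapply(slopes, function(s) 10^(-1 / s) - 1, numeric(1))
  fit_effs <- vapply(slopes, function(s)
    fit_calibration(1:4, 40 + s * (1:4))$efficiency, numeric(1))
  expect_equal(fit_effs, effs, tolerance = 1e-6)
  expect_true(all(diff(fit_effs) < 0))
})

test_that("compare_groups gates on normality and detects known separation", {
  set.seed(99)
  a <- rnorm(20); b <- rnorm(20, mean = 5)
  cmp <- compare_groups(a, b)
  expect_true(cmp$significant)

  same <- c(1, 2, 3, 4)
  cmp_same <- compare_groups(same, same)
  expect_equal(cmp_same$p_value, 1, tolerance = 1e-9)
  expect_false(cmp_same$significant)

  # constant groups cannot pass the normality gate
  cmp_const <- compare_groups(c(2, 2, 2, 2), c(2, 2, 2, 2))
  expect_equal(cmp_const$test_used, "mann-whitney")
  expect_false(cmp_const$significant)

  # heavily skewed data routes to the rank test
  set.seed(100)
  skew <- exp(rnorm(30, sd = 3))
  cmp_skew <- compare_groups(skew, skew + 0)
  expect_equal(cmp_skew$test_used, "mann-whitney")

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("null-induction simulations are mostly non-significant", {
  # control and exposed copies drawn from the same distribution: the gate
  # should declare no induction in >= 90% of runs
  n_sig <- 0
  for (i in 1:100) {
    cfg <- sim_config(seed = i)
    sim <- make_qpcr(rep(10^5, 8), cfg)
    cal_cfg <- sim_config(seed = i + 10000,
                          qpcr = list(efficiency = 0.96, intercept = 38,
                                      cq_noise_sd = 0))
    cal_sim <- make_qpcr(10^5, cal_cfg)
    cal <- fit_calibration(cal_sim$calibration$log10_copies,
                           cal_sim$calibration$cq)
    copies <- copies_from_cq(sim$cq, cal)
    cmp <- compare_groups(copies[1:4], copies[5:8])
    n_sig <- n_sig + cmp$significant
  }
  expect_lte(n_sig / 100, 0.10)
})

test_that("concentration_factor is a ratio of group means", {
  expect_equal(concentration_factor(c(2, 2), c(2, 2)), 1)
  expect_error(concentration_factor(c(1, 2), c(0, 0)), "> 0")
  cfg <- sim_config(seed = 21)
  tis <- make_tissue(cfg)
  cf <- concentration_factor(tis$exposed, tis$control)
  expect_gt(cf, 100)   # generated at 500x with 30% cv, n = 4
  expect_lt(cf, 2500)
})

test_that("amplicon_length spans both primer footprints", {
  insert <- paste(rep("ACGT", 13), collapse = "")     # 52 nt
  sense <- "GCACTGACACAGAATGCAGTTG"                    # 22 nt
  anti <- "TTTGCACCCTTCATCTGACTTAGT"                   # 24 nt
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                          collapse = "")
  template <- paste0("GGG", sense, insert, rc(anti), "CCC")
  expect_equal(amplicon_length(template, sense, anti),
               nchar(sense) + 52 + nchar(anti))
  expect_error(amplicon_length(template, "AAAAAAAAAA", anti), "not found")
  # sense site downstream of the antisense site is rejected
  swapped <- paste0("GGG", rc(anti), insert, sense, "CCC")
  expect_error(amplicon_length(swapped, sense, anti), "upstream")
  # multiple sense matches are rejected
  doubled <- paste0(sense, template)
  expect_error(amplicon_length(doubled, sense, anti), "more than once")
})

test_that("copies round-trip through simulated Cq values within noise", {
  cfg <- sim_config(seed = 8)
  sim <- make_qpcr(rep(1e5, 50), cfg)
  cal0 <- sim_config(seed = 8, qpcr = list(efficiency = 0.96, intercept = 38,
                                           cq_noise_sd = 0))
  cal <- fit_calibration(make_qpcr(1, cal0)$calibration$log10_copies,
                         make_qpcr(1, cal0)$calibration$cq)
  copies <- copies_from_cq(sim$cq, cal)
  # cq noise 0.15 cycles ~ 11% copy cv; the mean of 50 stays within 5%
  expect_lt(abs(mean(copies) - 1e5) / 1e5, 0.05)
})
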