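test_that("probit ML fit matches a dense grid-search oracle", {
  withr::local_seed(1)
  conc <- 10^seq(0, 2, length.out = 7)  # 1..100, true LC50 = 10, slope 2
  dead <- sim_probit_counts(alpha = -2, beta = 2, conc, n = 50)
  tab <- bioassay_table("sim", "bif", conc, 50, dead)
  fit <- fit_probit(tab)

  lc <- estimate_lc(fit, 0.5)
  expect_gt(lc$dose, 8.0)
  expect_lt(lc$dose, 12.5)
  expect_true(lc$ci_low <= lc$dose && lc$dose <= lc$ci_high)

  oracle <- grid_probit_oracle(conc, rep(50, 7), dead)
  ll_fit <- probit_loglik_kernel(fit$alpha, fit$beta, conc, rep(50, 7), dead)
  expect_lt(abs(ll_fit - oracle$loglik), 1e-3)
})

test_that("degenerate mortality patterns are refused with diagnostics", {
  conc <- c(1, 3.2, 10, 32, 100)
  step <- bioassay_table("s", "c", conc, 50, c(0, 0, 0, 50, 50))
  expect_error(fit_probit(step), "separation")

  flat <- bioassay_table("s", "c", conc, 50, rep(25, 5))
  expect_error(fit_probit(flat), "unidentifiable slope")

  one_conc <- bioassay_table("s", "c", c(10, 10), 50, c(20, 30))
  expect_error(fit_probit(one_conc), "2 distinct positive concentrations")
})

test_that("duplicating the data leaves estimates fixed and shrinks SEs by sqrt(2)", {
  withr::local_seed(42)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  dead <- sim_probit_counts(-1.5, 1.5, conc, 40)
  tab1 <- bioassay_table("s", "c", conc, 40, dead)
  tab2 <- bioassay_table("s", "c", rep(conc, 2), 40, rep(dead, 2))
  f1 <- fit_probit(tab1)
  f2 <- fit_probit(tab2)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$se_beta, f1$se_beta / sqrt(2), tolerance = 1e-5)
})

test_that("lethal concentrations follow the closed-form probit inverse", {
  # alpha = -2, beta = 2: LC50 = 10 exactly
  f <- fake_fit(-2, 2)
  expect_equal(estimate_lc(f, 0.5)$dose, 10)

  # susceptible-like line: slope 1.88, LC50 0.64 -> LC99 ~ 11.06
  beta <- 1.88
  f <- fake_fit(-beta * log10(0.64), beta)
  expect_equal(round(estimate_lc(f, 0.99)$dose, 2), 11.06)
  expect_equal(estimate_lc(f, 0.99)$dose, 0.64 * 10^(qnorm(0.99) / 1.88),
               tolerance = 1e-12)

  # inverse identity at p = 0.5 on an arbitrary fit
  f <- fake_fit(0.73, 1.21)
  d <- estimate_lc(f, 0.5)$dose
  expect_equal(pnorm(f$alpha + f$beta * log10(d)), 0.5, tolerance = 1e-12)

  expect_error(estimate_lc(f, 0), "in \\(0, 1\\)")
  expect_error(estimate_lc(f, 1), "in \\(0, 1\\)")
})

test_that("delta-method LC standard errors agree with MASS::dose.p", {
  skip_if_not_installed("MASS")
  withr::local_seed(7)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  dead <- sim_probit_counts(-1.2, 1.6, conc, 40)
  tab <- bioassay_table("s", "c", conc, 40, dead)
  fit <- fit_probit(tab)
  glm_fit <- glm(cbind(dead, 40 - dead) ~ log10(conc),
                 family = binomial("probit"))
  # dose.p works from the raw covariance; estimate_lc applies the
  # documented heterogeneity inflation on top when lack of fit is
  # significant, so divide it back out for the comparison
  infl <- if (fit$gof$inflated) sqrt(fit$gof$heterogeneity) else 1
  for (p in c(0.1, 0.5, 0.9, 0.99)) {
    dp <- MASS::dose.p(glm_fit, p = p)
    lc <- estimate_lc(fit, p)
    expect_equal(log10(lc$dose), as.numeric(dp), tolerance = 1e-8)
    expect_equal(lc$se_log10 / infl, as.numeric(attr(dp, "SE")),
                 tolerance = 1e-8)
  }
})

test_that("Pearson lack-of-fit test is calibrated on well-specified data", {
  withr::local_seed(2)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  reject <- vapply(seq_len(2000), function(i) {
    dead <- sim_probit_counts(-1.2, 1.6, conc, 40)
    f <- tryCatch(fit_probit(bioassay_table("s", "c", conc, 40, dead)),
                  error = function(e) NULL)
    if (is.null(f)) return(NA)
    f$gof$p_value < 0.05
  }, logical(1))
  rate <- mean(reject, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("lack-of-fit df follows the groups-minus-two convention", {
  withr::local_seed(3)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  dead <- sim_probit_counts(-1.2, 1.6, conc, 40)
  fit <- fit_probit(bioassay_table("s", "c", conc, 40, dead))
  expect_equal(fit$gof$df, 4L)  # 6 concentration groups
  expect_equal(goodness_of_fit(fit)$heterogeneity,
               fit$gof$chi2 / 4)

  two <- fit_probit(bioassay_table("s", "c", conc[c(2, 5)], 200,
                                   dead[c(2, 5)] * 5))
  expect_error(goodness_of_fit(two), "undefined")
})

test_that("resistance ratios are antisymmetric with lethal-dose-ratio CIs", {
  withr::local_seed(11)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  f1 <- fit_probit(bioassay_table("R", "c", conc * 30, 40,
                                  sim_probit_counts(-1.2, 1.4, conc * 30,
                                                    40)))
  f2 <- fit_probit(bioassay_table("S", "c", conc, 40,
                                  sim_probit_counts(-1.2, 1.4, conc, 40)))
  lr <- estimate_lc(f1, 0.5)
  ls <- estimate_lc(f2, 0.5)
  rr <- resistance_ratio(lr, ls)
  rr_rev <- resistance_ratio(ls, lr)
  expect_identical(rr$ratio, 1 / rr_rev$ratio)
  expect_equal(rr$ci_low, 1 / rr_rev$ci_high, tolerance = 1e-12)
  expect_true(rr$ci_low <= rr$ratio && rr$ratio <= rr$ci_high)

  self <- resistance_ratio(lr, lr)
  expect_equal(self$ratio, 1)
  expect_true(self$ci_low <= 1 && 1 <= self$ci_high)

  ls99 <- estimate_lc(f2, 0.99)
  expect_error(resistance_ratio(lr, ls99), "different quantiles")
})

test_that("line comparison chi-squares are near zero for identical lines", {
  withr::local_seed(5)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  dead <- sim_probit_counts(-1.2, 1.6, conc, 40)
  fa <- fit_probit(bioassay_table("a", "c", conc, 40, dead))
  fb <- fit_probit(bioassay_table("b", "c", conc, 40, dead))
  eq <- compare_lines(list(fa, fb), "equality")
  par <- compare_lines(list(fa, fb), "parallelism")
  expect_lt(eq$chi2, 1e-8)
  expect_lt(par$chi2, 1e-8)
  expect_equal(eq$df, 2L)
  expect_equal(par$df, 1L)
})

test_that("line comparison is invariant to concentration-unit rescaling", {
  withr::local_seed(6)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  d1 <- sim_probit_counts(-1.2, 1.6, conc, 40)
  d2 <- sim_probit_counts(-0.6, 1.6, conc, 40)
  fits <- list(fit_probit(bioassay_table("a", "c", conc, 40, d1)),
               fit_probit(bioassay_table("b", "c", conc, 40, d2)))
  fits_mg <- list(fit_probit(bioassay_table("a", "c", conc / 1000, 40, d1)),
                  fit_probit(bioassay_table("b", "c", conc / 1000, 40, d2)))
  for (h in c("equality", "parallelism")) {
    expect_equal(compare_lines(fits, h)$chi2,
                 compare_lines(fits_mg, h)$chi2, tolerance = 1e-6)
    expect_gte(compare_lines(fits, h)$chi2, 0)
  }
})

test_that("equality and parallelism tests have power and level as expected", {
  withr::local_seed(3)
  conc <- 10^seq(-0.5, 1.5, length.out = 6)
  res <- vapply(seq_len(500), function(i) {
    # common slope 1.5, intercepts offset by 1: parallel but not equal
    d1 <- sim_probit_counts(-1.0, 1.5, conc, 40)
    d2 <- sim_probit_counts(0.0, 1.5, conc, 40)
    fits <- list(fit_probit(bioassay_table("a", "c", conc, 40, d1)),
                 fit_probit(bioassay_table("b", "c", conc, 40, d2)))
    c(par = compare_lines(fits, "parallelism")$p_value < 0.05,
      eq = compare_lines(fits, "equality")$p_value < 0.05)
  }, logical(2))
  expect_lte(mean(res["par", ]), 0.07)
  expect_gte(mean(res["eq", ]), 0.95)
})

test_that("diagnostic dose is the upper confidence limit of the LC99", {
  # zero-variance fit: diagnostic dose collapses to the LC99 point
  f <- fake_fit(-1.88 * log10(0.64), 1.88)
  expect_equal(diagnostic_dose(f), estimate_lc(f, 0.99)$dose)

  # with sampling variance the returned dose exceeds the point LC99,
  # and grows with the slope SE (delta-method CI monotone in SE)
  v1 <- matrix(c(0.04, -0.01, -0.01, 0.02), 2)
  v2 <- v1 * 4
  f1 <- fake_fit(-1.88 * log10(0.64), 1.88, v1)
  f2 <- fake_fit(-1.88 * log10(0.64), 1.88, v2)
  expect_gt(diagnostic_dose(f1), estimate_lc(f1, 0.99)$dose)
  expect_gt(diagnostic_dose(f2), diagnostic_dose(f1))
})
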