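test_that("Stone's dominance reproduces the published reciprocal-cross values", {
  # H2 cross: LC50s 77.38 (F1), 3080.95 (R), 0.64 (S) on bifenthrin
  h2 <- dominance_stone(77.38, 3080.95, 0.64)
  expect_equal(round(h2$D, 2), 0.13)
  expect_equal(h2$classification, "incomplete dominant")

  # H1 cross from the same published LC50s evaluates to 0.07
  h1 <- dominance_stone(58.98, 3080.95, 0.64)
  expect_equal(round(h1$D, 2), 0.07)

  # endpoints
  expect_equal(dominance_stone(3080.95, 3080.95, 0.64)$D, 1)
  expect_equal(dominance_stone(0.64, 3080.95, 0.64)$D, -1)
  expect_error(dominance_stone(1, 5, 5), "denominator")
})

test_that("Bourguet dominance is the mortality-scale linear interpolant", {
  expect_equal(dominance_bourguet(0.95, 0.05, 0.95)$D, 0)
  expect_equal(dominance_bourguet(0.05, 0.05, 0.95)$D, 1)
  expect_equal(dominance_bourguet(0.50, 0.05, 0.95)$D, 0.5)
  expect_equal(dominance_bourguet(0.25, 0.03, 0.99)$D, 0.7708,
               tolerance = 1e-4)
  expect_error(dominance_bourguet(0.5, 0.4, 0.4), "denominator")

  # out-of-range values are flagged, never clamped (here the heterozygote
  # is less susceptible than the resistant homozygote, so D > 1)
  oor <- dominance_bourguet(0.02, 0.05, 0.95)
  expect_true(oor$out_of_range)
  expect_gt(oor$D, 1)
})

test_that("Bourguet dominance is unchanged by the survival/mortality flip", {
  withr::local_seed(8)
  for (i in 1:50) {
    m <- sort(runif(3))
    d1 <- dominance_bourguet(m[2], m[1], m[3])$D
    d2 <- dominance_bourguet(1 - m[2], 1 - m[1], 1 - m[3])$D
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("dominance classification uses the documented boundaries", {
  expect_equal(classify_dominance(0.13), "incomplete dominant")
  expect_equal(classify_dominance(1.0), "complete dominant")
  expect_equal(classify_dominance(0.996), "complete dominant")
  expect_equal(classify_dominance(-0.4), "incomplete recessive")
  expect_equal(classify_dominance(-1), "complete recessive")
  expect_equal(classify_dominance(0), "codominant/additive midpoint")
})

test_that("the dominance-level curve declines as concentration rises", {
  beta <- 1.5
  f_ss <- fake_fit(-beta * log10(0.64), beta)
  f_rs <- fake_fit(-beta * log10(59), beta)
  f_rr <- fake_fit(-beta * log10(3081), beta)

  # closed-form normal-CDF oracle at each dose
  closed_D <- function(cc) {
    m <- pnorm(beta * (log10(cc) - log10(c(0.64, 59, 3081))))
    (m[2] - m[1]) / (m[3] - m[1])
  }
  d <- dml_curve(f_ss, f_rs, f_rr, c(1, 100))
  expect_equal(d$D[1], closed_D(1), tolerance = 1e-12)
  expect_equal(d$D[2], closed_D(100), tolerance = 1e-12)
  expect_equal(round(d$D[1], 3), 0.994)
  expect_equal(round(d$D[2], 3), 0.370)

  scan <- dml_curve(f_ss, f_rs, f_rr,
                    10^seq(log10(0.5), log10(500), length.out = 50))
  expect_true(all(diff(scan$D) <= 1e-12))

  # F1 indistinguishable from RR: completely dominant at every dose
  same <- dml_curve(f_ss, f_rr, f_rr, c(1, 10, 100))
  expect_equal(same$D, rep(1, 3), tolerance = 1e-12)

  # coincident parental lines: flagged undefined, not dropped
  undef <- dml_curve(f_ss, f_rs, f_ss, c(1, 10))
  expect_true(all(undef$undefined))
  expect_equal(nrow(undef), 2L)
})

test_that("expected backcross mortality is the Mendelian midpoint", {
  expect_equal(expected_backcross_mortality(0.9, 0)$p, 0.45)
  expect_equal(expected_backcross_mortality(0.3, 0.3)$p, 0.3)
  expect_equal(expected_backcross_mortality(0.878, 0.022)$p, 0.45)
  expect_equal(expected_backcross_mortality(0.9, 0)$q, 0.55)
})

test_that("monogenic chi-square equals the squared proportion z statistic", {
  # exact agreement with expectation gives chi2 = 0
  r0 <- monogenic_test(data.frame(concentration = 1, Ni = 18, ni = 40,
                                  p = 0.45))
  expect_equal(r0$rows$chi2, 0)
  expect_false(r0$rows$significant)
  expect_equal(r0$verdict, "monogenic not rejected")

  # worked example: 5/40 observed against expected 45%
  r1 <- monogenic_test(data.frame(concentration = 3.2, Ni = 5, ni = 40,
                                  p = 0.45))
  expect_equal(r1$rows$chi2, 17.07, tolerance = 1e-3)
  expect_true(r1$rows$significant)
  expect_equal(r1$verdict, "monogenic rejected")

  # oracle equivalence on random rows: chi2 == z^2
  withr::local_seed(19)
  for (i in 1:1000) {
    ni <- sample(10:200, 1)
    p <- runif(1, 0.05, 0.95)
    Ni <- sample(0:ni, 1)
    z <- (Ni / ni - p) / sqrt(p * (1 - p) / ni)
    chi2 <- monogenic_test(data.frame(concentration = 1, Ni = Ni, ni = ni,
                                      p = p))$rows$chi2
    expect_equal(chi2, z^2, tolerance = 1e-10)
  }

  expect_error(monogenic_test(data.frame(concentration = 1, Ni = 1,
                                         ni = 10, p = 1)), "strictly")
})

test_that("the any-row verdict rule is explicit and configurable", {
  rows <- data.frame(concentration = c(1, 10), Ni = c(5, 18), ni = 40,
                     p = 0.45)
  expect_equal(monogenic_test(rows)$verdict, "monogenic rejected")
  expect_equal(monogenic_test(rows, reject_rule = "all_rows")$verdict,
               "monogenic not rejected")
})

test_that("functional dominance compares strains and extracts Bourguet D", {
  counts <- data.frame(strain = c("Sus", "Bif-R", "H1"),
                       n_exposed = 50, n_dead = c(48, 2, 25))
  res <- functional_dominance(counts, dose = 94, ss = "Sus", rr = "Bif-R",
                              het = "H1")
  expect_equal(res$D_at_dose$D, 0.5, tolerance = 1e-12)
  expect_equal(res$D_at_dose$classification, "incomplete dominant")
  # extreme strains must receive different letters
  expect_false(res$letters[["Sus"]] == res$letters[["Bif-R"]])

  # identical counts: everything shares one letter group
  same <- functional_dominance(data.frame(strain = c("a", "b", "c"),
                                          n_exposed = 50, n_dead = 25))
  expect_equal(length(unique(same$letters)), 1L)

  # complete separation of mortality: sparse cells, exact path, p < 0.001
  ext <- functional_dominance(data.frame(strain = c("Sus", "Bif-R"),
                                         n_exposed = 50, n_dead = c(50, 0)))
  expect_lt(ext$pairwise$p_adj, 0.001)
  expect_false(ext$letters[["Sus"]] == ext$letters[["Bif-R"]])
  expect_match(ext$method, "mid-p")

  expect_error(
    functional_dominance(data.frame(strain = c("a", "b"),
                                    n_exposed = c(50, 0),
                                    n_dead = c(10, 0))),
    "positive")
})

test_that("letter groups are consistent with the adjusted pairwise tests", {
  withr::local_seed(23)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    counts <- data.frame(strain = paste0("s", seq_len(k)),
                         n_exposed = 60,
                         n_dead = rbinom(k, 60, runif(k, 0.1, 0.9)))
    res <- functional_dominance(counts, alpha = 0.05)
    lets <- res$letters
    for (j in seq_len(nrow(res$pairwise))) {
      shared <- any(strsplit(lets[[res$pairwise$strain_1[j]]], "")[[1]] %in%
                      strsplit(lets[[res$pairwise$strain_2[j]]], "")[[1]])
      if (res$pairwise$p_adj[j] < 0.05) {
        expect_false(shared)
      } else {
        expect_true(shared)
      }
    }
  }
})
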