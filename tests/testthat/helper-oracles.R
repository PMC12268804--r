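# Independent oracles used across the suite. These never call the code
# paths they check.

# Binomial probit log-likelihood kernel (no binomial coefficients).
probit_loglik_kernel <- function(alpha, beta, conc, n, dead) {
  p <- stats::pnorm(alpha + beta * log10(conc))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dead * log(p) + (n - dead) * log1p(-p))
}

# Dense two-parameter grid search for the probit ML optimum, refined by
# repeated zooming; independent of glm.
grid_probit_oracle <- function(conc, n, dead, stages = 6L) {
  lo <- c(-16, -8)
  hi <- c(16, 10)
  as <- bs <- NULL
  ij <- c(1L, 1L)
  best <- -Inf
  for (s in seq_len(stages)) {
    as <- seq(lo[1], hi[1], length.out = 61)
    bs <- seq(lo[2], hi[2], length.out = 61)
    ll <- matrix(NA_real_, 61, 61)
    for (i in 1:61) {
      for (j in 1:61) {
        ll[i, j] <- probit_loglik_kernel(as[i], bs[j], conc, n, dead)
      }
    }
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- max(ll)
    step_a <- as[2] - as[1]
    step_b <- bs[2] - bs[1]
    lo <- c(as[ij[1]] - 2 * step_a, bs[ij[2]] - 2 * step_b)
    hi <- c(as[ij[1]] + 2 * step_a, bs[ij[2]] + 2 * step_b)
  }
  list(loglik = best, alpha = as[ij[1]], beta = bs[ij[2]])
}

# Simulate grouped binomial mortality straight from the probit law,
# without going through the package simulator.
sim_probit_counts <- function(alpha, beta, conc, n) {
  p <- stats::pnorm(alpha + beta * log10(conc))
  stats::rbinom(length(conc), n, p)
}

# Build a probit_fit object directly from known parameters (zero or given
# covariance), for closed-form checks of downstream operations.
fake_fit <- function(alpha, beta, vcov = matrix(0, 2, 2),
                     strain = "X", compound = "C") {
  structure(list(
    alpha = alpha, beta = beta,
    se_alpha = sqrt(vcov[1, 1]), se_beta = sqrt(vcov[2, 2]),
    vcov = vcov, vcov_adj = vcov,
    loglik = NA_real_, n = NA_integer_, n_groups = NA_integer_,
    gof = list(chi2 = NA_real_, df = NA_integer_, p_value = 1,
               heterogeneity = NA_real_, inflated = FALSE),
    data = NULL, strain = strain, compound = compound
  ), class = "probit_fit")
}

# Standard one-locus viability-selection recursion (independent oracle
# for the stability simulator).
selection_recursion <- function(p, s, h) {
  p * (1 - s * (p + h * (1 - p))) /
    (1 - s * (p^2 + 2 * h * p * (1 - p)))
}

# Paper-scale reference architecture used by several simulation tests:
# susceptible LC50 0.64, resistant 3080.95 ug/mL, F1 placed at Stone
# D = 0.13, common slope 1.5.
ref_arch <- function(n_loci = 1L) {
  genetic_architecture(0.64, 3080.95, slope = 1.5, n_loci = n_loci,
                       d_stone = 0.13)
}
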