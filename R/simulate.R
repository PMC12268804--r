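#' Simulate a quantal bioassay from a genotype mixture
#'
#' Each exposed insect independently draws a genotype from the mixture and
#' dies with probability `pnorm(slope * (log10(c) - tolerance))`; counts
#' are aggregated to one row per concentration. Output is a standard
#' [bioassay_table()] with a provenance attribute; the same seed and
#' configuration always give an identical table.
#'
#' @param arch A [genetic_architecture()].
#' @param mix A [genotype_mix()] (e.g. from [make_cross()]).
#' @param concentrations Positive doses (ug a.i./mL).
#' @param n_per_conc Insects exposed per concentration.
#' @param seed RNG seed (required; all randomness is derived from it).
#' @param strain_id,compound Labels for the emitted table.
#' @return A [bioassay_table()] with attribute `"provenance"`.
#' @export
simulate_bioassay <- function(arch, mix, concentrations, n_per_conc, seed,
                              strain_id = "sim", compound = "compound") {
  stopifnot(inherits(arch, "genetic_architecture"),
            inherits(mix, "genotype_mix"),
            all(concentrations > 0), n_per_conc > 0)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  tol <- apply(mix$genotypes, 1L,
               function(g) tolerance_of_genotype(arch, g))
  n_per_conc <- rep_len(n_per_conc, length(concentrations))
  dead <- withr::with_seed(seed, {
    vapply(seq_along(concentrations), function(i) {
      # multinomial genotype draw, then binomial deaths per genotype
      ng <- as.vector(stats::rmultinom(1, n_per_conc[i], mix$freq))
      pr <- stats::pnorm(arch$slope * (log10(concentrations[i]) - tol))
      sum(stats::rbinom(length(ng), ng, pr))
    }, numeric(1))
  })
  tab <- bioassay_table(strain = strain_id, compound = compound,
                        concentration = concentrations,
                        n_exposed = n_per_conc, n_dead = as.integer(dead))
  attr(tab, "provenance") <- list(architecture = arch, mix = mix,
                                  seed = seed)
  tab
}

#' Simulate a full inheritance experiment
#'
#' Generates the eight bioassay tables of a classical resistance
#' inheritance study: the two parental strains, the reciprocal F1s
#' (H1: R female x S male, H2: S female x R male) and the four backcrosses
#' of each F1 to the susceptible parent. Inheritance is autosomal in the
#' simulator, so reciprocal labels are metadata only; the F1s and the
#' backcross pairs share the same genotype mixtures but are assayed with
#' independent draws.
#'
#' @param arch A [genetic_architecture()].
#' @param concentrations Named list with elements `sus`, `rr`, `f1`, `bc`
#'   giving the dose series for the susceptible parent, resistant parent,
#'   F1 lines and backcrosses. Defaults follow a typical design: 7
#'   log-spaced doses bracketing the susceptible LC50, 6 bracketing the
#'   resistant one, and the 6-dose backcross series 3.2-560.
#' @param n_per_conc Insects per concentration (default 40: five
#'   replicates of eight).
#' @param seed RNG seed; per-table seeds are derived from it.
#' @return Named list of [bioassay_table()]s: `sus`, `bif_r`, `h1`, `h2`,
#'   `bc_susF_h1M`, `bc_susM_h1F`, `bc_susF_h2M`, `bc_susM_h2F`, plus
#'   `mixes` (the genotype mixtures used).
#' @export
simulate_inheritance_experiment <- function(arch,
                                            concentrations = NULL,
                                            n_per_conc = 40L,
                                            seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(concentrations)) {
    concentrations <- list(
      sus = 10^seq(arch$xs - 0.75, arch$xs + 0.75, length.out = 7),
      rr = 10^seq(arch$xr - 0.9, arch$xr + 0.6, length.out = 6),
      f1 = NULL,  # filled below from the F1 tolerance
      bc = c(3.2, 10, 32, 100, 320, 560)
    )
  }
  ss <- genotype(arch, 0L)
  rr <- genotype(arch, 2L)
  f1_mix <- make_cross(arch, rr, ss)$distribution
  bc_mix <- make_cross_mix(arch, f1_mix, genotype_mix(ss))
  if (is.null(concentrations$f1)) {
    xf <- tolerance_of_genotype(arch, genotype(arch, 1L))
    concentrations$f1 <- 10^seq(xf - 1.1, xf + 0.9, length.out = 7)
  }
  seeds <- derive_seeds(seed, 8L)
  sim <- function(mix, conc, s, id) {
    simulate_bioassay(arch, mix, conc, n_per_conc, seed = s,
                      strain_id = id, compound = "compound")
  }
  list(
    sus = sim(genotype_mix(ss), concentrations$sus, seeds[1], "Sus"),
    bif_r = sim(genotype_mix(rr), concentrations$rr, seeds[2], "Bif-R"),
    h1 = sim(f1_mix, concentrations$f1, seeds[3], "H1"),
    h2 = sim(f1_mix, concentrations$f1, seeds[4], "H2"),
    bc_susF_h1M = sim(bc_mix, concentrations$bc, seeds[5], "SusF x H1M"),
    bc_susM_h1F = sim(bc_mix, concentrations$bc, seeds[6], "SusM x H1F"),
    bc_susF_h2M = sim(bc_mix, concentrations$bc, seeds[7], "SusF x H2M"),
    bc_susM_h2F = sim(bc_mix, concentrations$bc, seeds[8], "SusM x H2F"),
    mixes = list(f1 = f1_mix, backcross = bc_mix)
  )
}

# Cross a genotype mixture with another mixture: offspring distribution is
# the frequency-weighted mixture of all pairwise crosses.
make_cross_mix <- function(arch, mix1, mix2) {
  acc <- list()
  for (i in seq_along(mix1$freq)) for (j in seq_along(mix2$freq)) {
    d <- make_cross(arch, mix1$genotypes[i, ], mix2$genotypes[j, ])$distribution
    w <- mix1$freq[i] * mix2$freq[j]
    for (r in seq_along(d$freq)) {
      key <- paste(d$genotypes[r, ], collapse = ",")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        w * d$freq[r]
    }
  }
  gmat <- do.call(rbind, lapply(names(acc), function(k) {
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
  }))
  genotype_mix(gmat, unlist(acc, use.names = FALSE))
}

# Derive child seeds from a master seed without touching the global RNG
# stream layout; kept below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Monte-Carlo power of the monogenic test across architectures
#'
#' For each architecture, simulates `reps` backcross experiments (paired
#' seeds across architectures so comparisons are head-to-head), applies
#' [monogenic_test()] with the model-expected mortality p = (a + b) / 2
#' from the true parental-genotype mortalities, and reports the fraction of
#' experiments rejected. Under a true one-locus architecture this is the
#' test's per-experiment type-I error (about 1 - (1 - alpha)^r for r
#' dose rows); under polygenic architectures it is power.
#'
#' @param architectures Named list of [genetic_architecture()]s.
#' @param reps Simulated experiments per architecture (>= 100).
#' @param alpha Row-wise significance level.
#' @param seed Master seed.
#' @param concentrations Backcross dose series.
#' @param n_per_conc Insects per dose.
#' @return Data frame with `architecture`, `n_loci`, `rejection_rate`,
#'   `reps`.
#' @export
power_study <- function(architectures, reps = 300L, alpha = 0.05, seed,
                        concentrations = c(3.2, 10, 32, 100, 320, 560),
                        n_per_conc = 40L) {
  stopifnot(reps >= 100L, length(architectures) >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  seeds <- derive_seeds(seed, reps)
  out <- lapply(seq_along(architectures), function(ai) {
    arch <- architectures[[ai]]
    ss <- genotype(arch, 0L)
    f1 <- make_cross(arch, genotype(arch, 2L), ss)$distribution
    bc <- make_cross_mix(arch, f1, genotype_mix(ss))
    # Mendelian one-locus expectation: mean of F1-het and SS mortalities
    a <- genotype_mortality(arch, genotype(arch, 1L), concentrations)
    b <- genotype_mortality(arch, ss, concentrations)
    p_exp <- (a + b) / 2
    rej <- vapply(seeds, function(s) {
      tab <- simulate_bioassay(arch, bc, concentrations, n_per_conc, s,
                               strain_id = "backcross")
      res <- monogenic_test(data.frame(
        concentration = tab$concentration, Ni = tab$n_dead,
        ni = tab$n_exposed, p = p_exp), alpha = alpha)
      res$verdict == "monogenic rejected"
    }, logical(1))
    data.frame(architecture = names(architectures)[ai] %||%
                 as.character(ai),
               n_loci = arch$n_loci,
               rejection_rate = mean(rej), reps = reps)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
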