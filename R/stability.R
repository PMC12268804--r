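#' Configuration for a resistance-stability cage simulation
#'
#' Describes a cage population founded from a mixture of resistant (RR)
#' and susceptible (SS) homozygotes and propagated for `generations`
#' discrete, non-overlapping generations without insecticide exposure
#' (unless `selection_dose` is set). A fitness cost acts on viability
#' before mating: relative fitness 1 for SS, `1 - h_cost * s` for RS and
#' `1 - s` for RR.
#'
#' @param prop_rr,prop_ss Founding proportions of RR and SS individuals
#'   (must sum to 1), e.g. 0.8 / 0.2 for an 80R:20S cage.
#' @param generations Number of generations to propagate, >= 1.
#' @param census Population size N per generation (stochastic mode).
#' @param fitness_cost Selection coefficient s in [0, 1) against RR.
#' @param cost_dominance Dominance h_c of the cost in [0, 1].
#' @param diagnostic_dose Discriminating dose (ug a.i./mL) at which
#'   survival is tracked each generation.
#' @param n_assay Insects assayed at the diagnostic dose per generation
#'   (default 480: 60 replicates of 8).
#' @param mode `"stochastic"` (Wright-Fisher multinomial sampling of N
#'   genotypes each generation) or `"deterministic"` (infinite-population
#'   recursion; `census` and `seed` are ignored).
#' @param selection_dose Optional dose applied to each generation before
#'   mating (survivorship selection), for emulating laboratory selection
#'   episodes; `NULL` for none.
#' @param seed RNG seed, required in stochastic mode.
#' @return A list of class `"stability_config"`.
#' @export
stability_config <- function(prop_rr, prop_ss,
                             generations = 6L, census = 600L,
                             fitness_cost = 0, cost_dominance = 0.5,
                             diagnostic_dose = 100,
                             n_assay = 480L,
                             mode = c("stochastic", "deterministic"),
                             selection_dose = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (abs(prop_rr + prop_ss - 1) >= 1e-9) {
    stop("founding proportions prop_rr and prop_ss must sum to 1",
         call. = FALSE)
  }
  stopifnot(prop_rr >= 0, prop_ss >= 0,
            generations >= 1, census >= 2,
            cost_dominance >= 0, cost_dominance <= 1,
            diagnostic_dose > 0)
  if (fitness_cost >= 1 || fitness_cost < 0) {
    stop("fitness cost s must lie in [0, 1)", call. = FALSE)
  }
  if (mode == "stochastic" && is.null(seed)) {
    stop("stochastic mode requires a seed", call. = FALSE)
  }
  structure(list(
    prop_rr = prop_rr, prop_ss = prop_ss,
    generations = as.integer(generations), census = as.integer(census),
    fitness_cost = fitness_cost, cost_dominance = cost_dominance,
    diagnostic_dose = diagnostic_dose, n_assay = as.integer(n_assay),
    mode = mode, selection_dose = selection_dose, seed = seed
  ), class = "stability_config")
}

#' Simulate resistance stability across cage generations
#'
#' One-locus dynamics (the architecture must have `n_loci == 1`) on the
#' standard discrete life cycle. Each cage generation g >= 1 is produced
#' from the adults of generation g - 1 by: (i) random mating, giving
#' Hardy-Weinberg zygote frequencies at the parental R allele frequency;
#' (ii) viability selection on the zygotes by the fitness cost (w_SS = 1,
#' w_RS = 1 - h_c s, w_RR = 1 - s) and, when `selection_dose` is set, by
#' survivorship of that exposure; (iii) in stochastic mode, multinomial
#' sampling of `census` surviving adults. Generation 0 is the founding
#' adult cage exactly as mixed (RR and SS homozygotes only). Because
#' selection always acts on Hardy-Weinberg zygotes, the deterministic
#' allele-frequency trajectory obeys the classical one-locus recursion
#' p' = p(1 - s(p + h_c(1 - p))) / (1 - s(p^2 + 2 h_c p(1 - p))) at every
#' generation. Expected survival at the diagnostic dose is the
#' frequency-weighted survival of the three genotypes among the assayed
#' adults, and in stochastic mode assayed survivor counts are drawn
#' binomially.
#'
#' @param cfg A [stability_config()].
#' @param arch A one-locus [genetic_architecture()].
#' @return A data frame, one row per generation 0..G (0 = founding cage):
#'   `generation`, `freq_rr`, `freq_rs`, `freq_ss`, `p_r` (R allele
#'   frequency), `expected_survival` (at the diagnostic dose),
#'   `n_assay`, `n_survived` (stochastic mode; `NA` otherwise), and
#'   `pop_lc50` (mixture LC50 of the population). Attribute `"config"`
#'   carries the configuration.
#' @export
simulate_stability <- function(cfg, arch) {
  stopifnot(inherits(cfg, "stability_config"),
            inherits(arch, "genetic_architecture"))
  if (arch$n_loci != 1L) {
    stop("stability dynamics are defined for one-locus architectures",
         call. = FALSE)
  }
  s <- cfg$fitness_cost
  hc <- cfg$cost_dominance
  w <- c(ss = 1, rs = 1 - hc * s, rr = 1 - s)
  tol <- vapply(0:2, function(cnt) tolerance_of_genotype(arch, cnt),
                numeric(1))  # ss, rs, rr
  surv_at <- function(freq, dose) {
    sum(freq * stats::pnorm(arch$slope * (log10(dose) - tol),
                            lower.tail = FALSE))
  }

  viability <- w
  if (!is.null(cfg$selection_dose)) {
    viability <- viability *
      stats::pnorm(arch$slope * (log10(cfg$selection_dose) - tol),
                   lower.tail = FALSE)
    if (all(viability <= 0)) {
      stop("selection dose kills every genotype; the cage cannot persist",
           call. = FALSE)
    }
  }

  run <- function() {
    freq <- c(ss = cfg$prop_ss, rs = 0, rr = cfg$prop_rr)
    rows <- vector("list", cfg$generations + 1L)
    for (gen in 0:cfg$generations) {
      if (gen > 0L) {
        # random mating -> HWE zygotes, then viability selection on them
        p <- freq[["rr"]] + freq[["rs"]] / 2
        freq <- c(ss = (1 - p)^2, rs = 2 * p * (1 - p), rr = p^2)
        freq <- freq * viability
        if (sum(freq) <= 0) stop("selection killed the whole cage",
                                 call. = FALSE)
        freq <- freq / sum(freq)
        if (cfg$mode == "stochastic") {
          counts <- as.vector(stats::rmultinom(1, cfg$census, freq))
          freq <- stats::setNames(counts / cfg$census, names(freq))
        }
      }
      p_r <- freq[["rr"]] + freq[["rs"]] / 2
      esurv <- surv_at(freq, cfg$diagnostic_dose)
      n_srv <- if (cfg$mode == "stochastic") {
        stats::rbinom(1, cfg$n_assay, esurv)
      } else NA_integer_
      rows[[gen + 1L]] <- data.frame(
        generation = gen,
        freq_rr = freq[["rr"]], freq_rs = freq[["rs"]],
        freq_ss = freq[["ss"]], p_r = p_r,
        expected_survival = esurv,
        n_assay = cfg$n_assay, n_survived = n_srv,
        pop_lc50 = population_lc50(arch, freq)
      )
    }
    do.call(rbind, rows)
  }

  out <- if (cfg$mode == "stochastic") {
    withr::with_seed(cfg$seed, run())
  } else {
    run()
  }
  attr(out, "config") <- cfg
  out
}

#' Population-level LC50 of a genotype mixture
#'
#' The dose at which the frequency-weighted mortality of the genotypes
#' reaches 50%, found by root-finding on the log10 dose scale. This is the
#' quantity a probit assay of the mixed cage estimates, and the numerator
#' of a cage resistance ratio.
#'
#' @param arch A one-locus [genetic_architecture()].
#' @param freq Genotype frequencies, ordered (ss, rs, rr) or named.
#' @return Dose in ug a.i./mL.
#' @export
population_lc50 <- function(arch, freq) {
  stopifnot(arch$n_loci == 1L, length(freq) == 3L)
  if (!is.null(names(freq))) freq <- freq[c("ss", "rs", "rr")]
  freq <- as.numeric(freq) / sum(freq)
  tol <- vapply(0:2, function(cnt) tolerance_of_genotype(arch, cnt),
                numeric(1))
  f <- function(x) sum(freq * stats::pnorm(arch$slope * (x - tol))) - 0.5
  lo <- min(tol) - 8 / arch$slope
  hi <- max(tol) + 8 / arch$slope
  10^stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Per-generation survival comparison at a diagnostic dose
#'
#' Summarizes a multi-treatment stability experiment: survival proportion
#' with Clopper-Pearson 95% CI per generation x treatment, within-
#' generation pairwise comparisons with letter groups (same engine as
#' [functional_dominance()], applied to survivor counts), and a monotone
#' trend summary per treatment (logistic regression of survival on
#' generation). Missing generations are flagged, never interpolated.
#'
#' @param tab A [bioassay_table()] assayed at the diagnostic dose; the
#'   `strain` column carries the treatment label and `generation` must be
#'   filled.
#' @param diagnostic_dose The dose rows must match (checked).
#' @param alpha Significance level for letters.
#' @return A list with `survival` (data frame), `comparisons` (per
#'   generation: pairwise table and letters), `trend` (per treatment:
#'   slope on the logit scale, p-value, direction), `gaps` (treatment x
#'   generation combinations absent from the data).
#' @export
stability_analysis <- function(tab, diagnostic_dose, alpha = 0.05) {
  tab <- validate_bioassay(tab)
  tab <- tab[abs(tab$concentration - diagnostic_dose) <
               1e-9 * max(1, diagnostic_dose), , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("no rows at the diagnostic dose", call. = FALSE)
  }
  if (anyNA(tab$generation)) {
    stop("stability analysis needs the generation column filled",
         call. = FALSE)
  }
  agg <- stats::aggregate(cbind(n_dead, n_exposed) ~ strain + generation,
                          data = tab, FUN = sum)
  agg$n_survived <- agg$n_exposed - agg$n_dead
  ci <- t(vapply(seq_len(nrow(agg)), function(i) {
    as.numeric(stats::binom.test(agg$n_survived[i],
                                 agg$n_exposed[i])$conf.int)
  }, numeric(2)))
  survival <- data.frame(
    treatment = agg$strain, generation = agg$generation,
    n_exposed = agg$n_exposed, n_survived = agg$n_survived,
    survival = agg$n_survived / agg$n_exposed,
    ci_low = ci[, 1], ci_high = ci[, 2]
  )
  survival <- survival[order(survival$generation, survival$treatment), ]
  rownames(survival) <- NULL

  gens <- sort(unique(survival$generation))
  treatments <- sort(unique(survival$treatment))
  full <- expand.grid(treatment = treatments, generation = gens,
                      stringsAsFactors = FALSE)
  have <- paste(survival$treatment, survival$generation)
  gaps <- full[!paste(full$treatment, full$generation) %in% have, ]

  comparisons <- lapply(gens, function(g) {
    sub <- survival[survival$generation == g, , drop = FALSE]
    if (nrow(sub) < 2L) {
      return(list(generation = g, pairwise = NULL, letters = NULL))
    }
    fd <- functional_dominance(
      data.frame(strain = sub$treatment, n_exposed = sub$n_exposed,
                 n_dead = sub$n_survived),  # compare survivor proportions
      dose = diagnostic_dose, alpha = alpha)
    list(generation = g, pairwise = fd$pairwise, letters = fd$letters)
  })
  names(comparisons) <- paste0("generation_", gens)

  trend <- do.call(rbind, lapply(treatments, function(tr) {
    sub <- survival[survival$treatment == tr, , drop = FALSE]
    if (nrow(sub) < 2L || length(unique(sub$survival)) == 1L) {
      return(data.frame(treatment = tr, slope_logit = NA_real_,
                        p_value = NA_real_, direction = "flat"))
    }
    m <- suppressWarnings(stats::glm(
      cbind(n_survived, n_exposed - n_survived) ~ generation,
      family = stats::binomial(), data = sub))
    co <- summary(m)$coefficients
    slope <- co["generation", "Estimate"]
    pv <- co["generation", "Pr(>|z|)"]
    data.frame(treatment = tr, slope_logit = slope, p_value = pv,
               direction = if (pv < alpha && slope < 0) "decreasing"
                           else if (pv < alpha && slope > 0) "increasing"
                           else "no significant trend")
  }))

  list(survival = survival, comparisons = comparisons, trend = trend,
       gaps = gaps)
}
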