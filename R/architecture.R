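#' Define a genetic architecture for insecticide tolerance
#'
#' The simulator's tolerance model: each of `n_loci` unlinked loci carries
#' an S and an R allele; log10 tolerance (the individual's LC50) is the
#' susceptible baseline plus equal additive contributions of
#' `(XR - XS) / (2k)` per R allele, so the all-S genotype sits at the
#' susceptible target LC50 and the all-R genotype at the resistant one
#' regardless of the number of loci. A heterozygous locus contributes
#' `2 h` times the per-allele effect (`h = 0.5` is additive). Mortality of
#' a genotype at dose c is `pnorm(slope * (log10(c) - tolerance))` — a
#' common probit slope across genotypes, consistent with the similar
#' slopes fitted lines usually show.
#'
#' When emulating an observed cross, the heterozygote is more naturally
#' placed by Stone's degree of dominance than by `h`: passing `d_stone`
#' sets `h = (D + 1) / 2`, which puts the all-het F1 exactly at
#' [heterozygote_lc_from_dominance()]'s LC50 for any number of loci.
#'
#' @param lc50_ss,lc50_rr Target LC50s (micrograms a.i. per mL) of the
#'   fully susceptible and fully resistant genotypes.
#' @param slope Common probit slope (probits per log10 ug/mL), > 0.
#' @param n_loci Number of loci, >= 1.
#' @param h Within-locus dominance of the R allele in [0, 1]; ignored when
#'   `d_stone` is given.
#' @param d_stone Optional Stone dominance in [-1, 1] placing the F1.
#' @return An object of class `"genetic_architecture"`.
#' @examples
#' arch <- genetic_architecture(0.64, 3080.95, slope = 1.5, d_stone = 0.13)
#' tolerance_of_genotype(arch, genotype(arch, 1))  # F1 log10 LC50
#' @export
genetic_architecture <- function(lc50_ss, lc50_rr, slope,
                                 n_loci = 1L, h = 0.5, d_stone = NULL) {
  stopifnot(lc50_ss > 0, lc50_rr > 0, slope > 0, n_loci >= 1)
  if (!is.null(d_stone)) {
    stopifnot(d_stone >= -1, d_stone <= 1)
    h <- (d_stone + 1) / 2
  }
  stopifnot(h >= 0, h <= 1)
  xs <- log10(lc50_ss)
  xr <- log10(lc50_rr)
  structure(list(
    n_loci = as.integer(n_loci),
    xs = xs, xr = xr,
    effect = rep((xr - xs) / (2 * n_loci), n_loci),
    h = h, slope = slope,
    d_stone = d_stone
  ), class = "genetic_architecture")
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf(
    "Tolerance architecture: %d locus/loci, LC50 %.3g -> %.3g, slope %.2f, h = %.3f\n",
    x$n_loci, 10^x$xs, 10^x$xr, x$slope, x$h))
  invisible(x)
}

#' Build a genotype as per-locus R-allele counts
#'
#' @param arch A [genetic_architecture()].
#' @param counts Integer vector of R-allele counts in `{0, 1, 2}`, either
#'   one per locus or a single value recycled to all loci.
#' @return Integer vector of class `"genotype"`.
#' @export
genotype <- function(arch, counts) {
  if (length(counts) == 1L) counts <- rep(counts, arch$n_loci)
  stopifnot(length(counts) == arch$n_loci, all(counts %in% 0:2))
  structure(as.integer(counts), class = "genotype")
}

#' Log10 tolerance of a genotype
#'
#' Homozygous R at a locus adds twice the per-allele effect, a heterozygous
#' locus adds `2 h` times it, homozygous S adds nothing.
#'
#' @param arch A [genetic_architecture()].
#' @param g A [genotype()] (or bare integer vector of allele counts).
#' @return Log10 tolerance (log10 ug a.i./mL).
#' @export
tolerance_of_genotype <- function(arch, g) {
  g <- as.integer(g)
  stopifnot(length(g) == arch$n_loci, all(g %in% 0:2))
  contrib <- ifelse(g == 2, 2, ifelse(g == 1, 2 * arch$h, 0))
  arch$xs + sum(arch$effect * contrib)
}

#' Place a heterozygote LC50 from Stone's dominance
#'
#' Inverts the Stone statistic: XF = XS + (D + 1)(XR - XS) / 2, returning
#' 10^XF. Exact inverse of [dominance_stone()], used to parameterize
#' simulated F1 lines by a reported degree of dominance.
#'
#' @param d Stone dominance in [-1, 1].
#' @param lc_rr,lc_ss Parental LC50s, > 0 and distinct.
#' @return Heterozygote LC50 (ug a.i./mL).
#' @export
heterozygote_lc_from_dominance <- function(d, lc_rr, lc_ss) {
  stopifnot(d >= -1, d <= 1, lc_rr > 0, lc_ss > 0, lc_rr != lc_ss)
  xs <- log10(lc_ss); xr <- log10(lc_rr)
  10^(xs + (d + 1) * (xr - xs) / 2)
}

#' Mortality of a genotype at given doses
#'
#' @param arch A [genetic_architecture()].
#' @param g A [genotype()].
#' @param conc Positive doses.
#' @return Vector of death probabilities.
#' @export
genotype_mortality <- function(arch, g, conc) {
  stopifnot(all(conc > 0))
  stats::pnorm(arch$slope * (log10(conc) - tolerance_of_genotype(arch, g)))
}

#' Mendelian cross of two genotypes
#'
#' Segregates each locus independently (unlinked loci, autosomal): a parent
#' heterozygous at a locus transmits R with probability 1/2, homozygotes
#' transmit their allele. Returns the exact offspring genotype distribution
#' by enumeration (supported for up to 10 loci) and, when `n_offspring > 0`,
#' a seeded sample of offspring genotypes.
#'
#' @param arch A [genetic_architecture()].
#' @param p1,p2 Parent [genotype()]s.
#' @param n_offspring Number of offspring to sample (0 for none).
#' @param seed RNG seed, required when `n_offspring > 0`.
#' @return A list with `distribution` (a `genotype_mix`: matrix `genotypes`
#'   with one row per distinct offspring genotype, vector `freq`) and
#'   `offspring` (integer matrix, `n_offspring` rows, or `NULL`).
#' @export
make_cross <- function(arch, p1, p2, n_offspring = 0L, seed = NULL) {
  k <- arch$n_loci
  stopifnot(length(p1) == k, length(p2) == k)
  if (k > 10L) stop("exact enumeration supported for up to 10 loci",
                    call. = FALSE)
  gamete <- function(count) {
    # P(transmit R) per allele count
    switch(count + 1L, 0, 0.5, 1)
  }
  # per-locus offspring count distribution over {0,1,2} R alleles
  per_locus <- lapply(seq_len(k), function(l) {
    r1 <- gamete(as.integer(p1[l])); r2 <- gamete(as.integer(p2[l]))
    c(`0` = (1 - r1) * (1 - r2),
      `1` = r1 * (1 - r2) + (1 - r1) * r2,
      `2` = r1 * r2)
  })
  support <- lapply(per_locus, function(pr) which(pr > 0) - 1L)
  grid <- as.matrix(expand.grid(support, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- paste0("locus", seq_len(k))
  freq <- apply(grid, 1L, function(row) {
    prod(vapply(seq_len(k),
                function(l) per_locus[[l]][row[l] + 1L], numeric(1)))
  })
  mix <- genotype_mix(grid, freq)
  offspring <- NULL
  if (n_offspring > 0L) {
    if (is.null(seed)) stop("seed required to sample offspring",
                            call. = FALSE)
    offspring <- withr::with_seed(seed, {
      idx <- sample.int(nrow(grid), n_offspring, replace = TRUE,
                        prob = freq)
      grid[idx, , drop = FALSE]
    })
  }
  list(distribution = mix, offspring = offspring)
}

#' Bundle genotypes and frequencies into a mixture
#'
#' @param genotypes Integer matrix, one row per genotype, one column per
#'   locus (a single genotype may be given as a vector).
#' @param freq Frequencies summing to 1.
#' @return An object of class `"genotype_mix"`.
#' @export
genotype_mix <- function(genotypes, freq = 1) {
  if (is.null(dim(genotypes))) {
    genotypes <- matrix(as.integer(genotypes), nrow = 1)
  }
  storage.mode(genotypes) <- "integer"
  stopifnot(length(freq) == nrow(genotypes), all(freq >= 0),
            abs(sum(freq) - 1) < 1e-9)
  structure(list(genotypes = genotypes, freq = as.numeric(freq)),
            class = "genotype_mix")
}

# Mortality of a genotype mixture at each dose (marginal death probability).
mix_mortality <- function(arch, mix, conc) {
  tol <- apply(mix$genotypes, 1L, function(g) tolerance_of_genotype(arch, g))
  vapply(conc, function(cc) {
    sum(mix$freq * stats::pnorm(arch$slope * (log10(cc) - tol)))
  }, numeric(1))
}
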