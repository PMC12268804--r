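#' Fit a probit concentration-mortality line
#'
#' Maximum-likelihood fit of mortality = Phi(alpha + beta * log10(dose)) to
#' the pooled counts of one strain x compound group, the standard quantal
#' dose-response model for insecticide bioassays. Control rows
#' (concentration 0) never enter the likelihood. Replicates at the same
#' concentration are pooled; the binomial likelihood is identical either
#' way and the Pearson goodness-of-fit statistic is defined on the pooled
#' concentration groups.
#'
#' Goodness of fit is a Pearson chi-square over the concentration groups
#' with `df = groups - 2`; the heterogeneity factor chi2/df multiplies the
#' parameter covariance whenever the lack-of-fit p-value is below 0.05
#' (classic probit practice for overdispersed assays), and the inflation is
#' recorded on the returned object.
#'
#' @param tab A [bioassay_table()].
#' @param strain,compound Optional filters; required when `tab` holds more
#'   than one strain or compound.
#' @return An object of class `"probit_fit"`: list with `alpha`, `beta`,
#'   `se_beta`, `vcov` (2x2, unadjusted), `vcov_adj` (heterogeneity-scaled
#'   when lack of fit is significant), `loglik`, `n`, `n_groups`, `gof`
#'   (`chi2`, `df`, `p_value`, `heterogeneity`, `inflated`), `data` (the
#'   pooled groups), `strain`, `compound`.
#' @examples
#' tab <- bioassay_table("Sus", "bifenthrin",
#'                       c(0.18, 0.32, 0.56, 1, 1.8, 3.2, 5.6),
#'                       n_exposed = 40,
#'                       n_dead = c(3, 8, 15, 24, 32, 37, 39))
#' fit <- fit_probit(tab)
#' estimate_lc(fit, 0.5)
#' @export
fit_probit <- function(tab, strain = NULL, compound = NULL) {
  tab <- validate_bioassay(tab)
  if (!is.null(strain)) tab <- tab[tab$strain == strain, , drop = FALSE]
  if (!is.null(compound)) tab <- tab[tab$compound == compound, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for requested strain/compound",
                            call. = FALSE)
  if (length(unique(tab$strain)) > 1L || length(unique(tab$compound)) > 1L) {
    stop("table holds several strain/compound groups; filter first",
         call. = FALSE)
  }
  tab <- tab[tab$concentration > 0, , drop = FALSE]
  grp <- pool_concentrations(tab)
  if (length(unique(grp$concentration)) < 2L) {
    stop("need at least 2 distinct positive concentrations", call. = FALSE)
  }
  prop <- grp$n_dead / grp$n_exposed
  if (length(unique(prop)) == 1L) {
    stop("unidentifiable slope: observed mortality identical at every ",
         "concentration", call. = FALSE)
  }
  .check_separation(grp)

  logc <- log10(grp$concentration)
  fit <- stats::glm(cbind(n_dead, n_exposed - n_dead) ~ logc,
                    family = stats::binomial(link = "probit"), data = grp)
  if (!fit$converged) {
    stop("probit fit did not converge", call. = FALSE)
  }
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  V <- unname(stats::vcov(fit))
  if (beta <= 0) {
    warning("fitted slope is non-positive: mortality declines with dose",
            call. = FALSE)
  }

  mu <- stats::fitted(fit)
  chi2 <- sum((grp$n_dead - grp$n_exposed * mu)^2 /
                (grp$n_exposed * mu * (1 - mu)))
  df <- nrow(grp) - 2L
  gof <- if (df > 0L) {
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    list(chi2 = chi2, df = df, p_value = p, heterogeneity = chi2 / df,
         inflated = p < 0.05)
  } else {
    list(chi2 = chi2, df = df, p_value = NA_real_,
         heterogeneity = NA_real_, inflated = FALSE)
  }
  vcov_adj <- if (isTRUE(gof$inflated)) V * gof$heterogeneity else V

  structure(list(
    alpha = alpha, beta = beta,
    se_alpha = sqrt(V[1, 1]), se_beta = sqrt(V[2, 2]),
    vcov = V, vcov_adj = vcov_adj,
    loglik = as.numeric(stats::logLik(fit)),
    n = sum(grp$n_exposed), n_groups = nrow(grp),
    gof = gof, data = grp,
    strain = grp$strain[1], compound = grp$compound[1]
  ), class = "probit_fit")
}

# Perfect separation (a 0 -> 1 mortality step in dose order) makes the
# slope diverge; refuse to fit and say why.
.check_separation <- function(grp) {
  grp <- grp[order(grp$concentration), , drop = FALSE]
  prop <- grp$n_dead / grp$n_exposed
  step <- all(prop %in% c(0, 1)) && any(prop == 0) && any(prop == 1) &&
    !is.unsorted(prop)
  if (step) {
    stop("complete separation: mortality steps from 0 to 1 between ",
         "adjacent concentrations, the slope is unbounded and the fit ",
         "cannot converge; add intermediate concentrations", call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit fit: %s / %s\n", x$strain, x$compound))
  cat(sprintf("  slope %.3f +/- %.3f (probits per log10 ug/mL), n = %d\n",
              x$beta, x$se_beta, x$n))
  cat(sprintf("  Pearson chi2 = %.2f on %d df (p = %.3f)%s\n",
              x$gof$chi2, x$gof$df, x$gof$p_value,
              if (isTRUE(x$gof$inflated)) {
                sprintf("; heterogeneity %.2f applied", x$gof$heterogeneity)
              } else ""))
  lc <- estimate_lc(x, 0.5)
  cat(sprintf("  LC50 %.4g (95%% CI %.4g - %.4g) ug a.i./mL\n",
              lc$dose, lc$ci_low, lc$ci_high))
  invisible(x)
}

#' Goodness of fit of a probit line
#'
#' Returns the Pearson chi-square lack-of-fit summary of a fitted line:
#' `chi2`, `df = groups - 2`, `p_value`, and the heterogeneity factor
#' chi2/df together with whether downstream variances were inflated by it.
#'
#' @param fit A [fit_probit()] object.
#' @return A list with `chi2`, `df`, `p_value`, `heterogeneity`, `inflated`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "probit_fit"))
  if (fit$gof$df <= 0L) {
    stop("goodness of fit undefined: fewer than 3 concentration groups",
         call. = FALSE)
  }
  fit$gof
}

#' Lethal concentration for a mortality quantile
#'
#' Inverts the fitted probit line at mortality `p`:
#' dose = 10^((qnorm(p) - alpha) / beta). The standard error on the log10
#' scale follows from the delta method on the parameter covariance (the
#' same computation as MASS's `dose.p`), and the 95% interval is
#' 10^(log10(dose) +/- 1.96 se). When the fit showed significant lack of
#' fit the heterogeneity-inflated covariance is used.
#'
#' @param fit A [fit_probit()] object.
#' @param p Mortality quantile in (0, 1); 0.5 gives the LC50.
#' @return An object of class `"lc_estimate"`: list with `p`, `dose`,
#'   `se_log10`, `ci_low`, `ci_high`, `heterogeneity_applied`, `strain`,
#'   `compound`.
#' @export
estimate_lc <- function(fit, p = 0.5) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!(p > 0 && p < 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (fit$beta == 0) stop("slope is zero; LC undefined", call. = FALSE)
  if (fit$beta < 0 && p > 0.5) {
    warning("extrapolating a declining mortality line beyond p = 0.5",
            call. = FALSE)
  }
  theta <- (stats::qnorm(p) - fit$alpha) / fit$beta
  grad <- c(-1 / fit$beta, -theta / fit$beta)
  se <- sqrt(drop(t(grad) %*% fit$vcov_adj %*% grad))
  structure(list(
    p = p,
    dose = 10^theta,
    se_log10 = se,
    ci_low = 10^(theta - 1.96 * se),
    ci_high = 10^(theta + 1.96 * se),
    heterogeneity_applied = isTRUE(fit$gof$inflated),
    strain = fit$strain, compound = fit$compound
  ), class = "lc_estimate")
}

#' @export
print.lc_estimate <- function(x, ...) {
  cat(sprintf("LC%g = %.4g (95%% CI %.4g - %.4g) ug a.i./mL [%s / %s]\n",
              100 * x$p, x$dose, x$ci_low, x$ci_high, x$strain, x$compound))
  invisible(x)
}

#' Resistance ratio of two lethal-concentration estimates
#'
#' RR = LC_p(resistant) / LC_p(susceptible), with a 95% interval by the
#' lethal-dose-ratio method for independent fits:
#' se = sqrt(se_log10_R^2 + se_log10_S^2), CI = RR * 10^(+/- 1.96 se).
#' Both estimates must be at the same quantile and compound.
#'
#' @param lc_r,lc_s [estimate_lc()] objects for the resistant and
#'   susceptible (reference) lines. Bare positive numbers are also accepted
#'   (point estimates, e.g. published table values); the CI is then `NA`.
#' @return An object of class `"ratio_estimate"`: `ratio`, `ci_low`,
#'   `ci_high`, `method`, `rounded_inputs` (TRUE when computed from bare
#'   point values rather than full fits).
#' @export
resistance_ratio <- function(lc_r, lc_s) {
  bare_r <- is.numeric(lc_r)
  bare_s <- is.numeric(lc_s)
  if (!bare_r) stopifnot(inherits(lc_r, "lc_estimate"))
  if (!bare_s) stopifnot(inherits(lc_s, "lc_estimate"))
  if (!bare_r && !bare_s) {
    if (!isTRUE(all.equal(lc_r$p, lc_s$p))) {
      stop("lethal concentrations are at different quantiles", call. = FALSE)
    }
    if (!identical(lc_r$compound, lc_s$compound)) {
      stop("lethal concentrations are for different compounds", call. = FALSE)
    }
  }
  dose_r <- if (bare_r) lc_r else lc_r$dose
  dose_s <- if (bare_s) lc_s else lc_s$dose
  stopifnot(dose_r > 0, dose_s > 0)
  ratio <- dose_r / dose_s
  if (bare_r || bare_s) {
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(lc_r$se_log10^2 + lc_s$se_log10^2)
    ci <- ratio * 10^(c(-1, 1) * 1.96 * se)
  }
  structure(list(
    ratio = ratio, ci_low = ci[1], ci_high = ci[2],
    method = "lethal-dose ratio (independent fits)",
    rounded_inputs = bare_r || bare_s
  ), class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("RR = %.2f", x$ratio))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (95%% CI %.2f - %.2f)", x$ci_low, x$ci_high))
  }
  if (x$rounded_inputs) cat("  [computed from point values]")
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio tests of equality and parallelism between lines
#'
#' Compares two or more fitted concentration-mortality lines for the same
#' compound. The full model fits a separate intercept and slope per line;
#' the `parallelism` hypothesis constrains the slopes to a common value
#' (df = n_lines - 1), and the `equality` hypothesis collapses all lines to
#' one (df = 2 * (n_lines - 1)). The statistic is twice the log-likelihood
#' difference, referred to the chi-square distribution. Equality of
#' reciprocal-cross lines is the standard evidence for autosomal,
#' non-maternal inheritance.
#'
#' @param fits A list of [fit_probit()] objects (each carries its pooled
#'   data), all for the same compound.
#' @param hypothesis `"equality"` or `"parallelism"`.
#' @return A list with `hypothesis`, `chi2`, `df`, `p_value`, `n_lines`.
#' @export
compare_lines <- function(fits, hypothesis = c("equality", "parallelism")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "probit_fit")))
  compounds <- vapply(fits, function(f) f$compound, character(1))
  if (length(unique(compounds)) > 1L) {
    stop("lines are for different compounds: ",
         paste(unique(compounds), collapse = ", "), call. = FALSE)
  }
  dat <- do.call(rbind, lapply(seq_along(fits), function(i) {
    d <- fits[[i]]$data
    d$line <- paste0(fits[[i]]$strain, "#", i)
    d
  }))
  dat$logc <- log10(dat$concentration)
  dat$line <- factor(dat$line)
  fam <- stats::binomial(link = "probit")
  dev_of <- function(formula) {
    m <- stats::glm(formula, family = fam, data = dat)
    if (!m$converged) {
      stop("constrained model failed to converge", call. = FALSE)
    }
    stats::deviance(m)
  }
  resp <- cbind(dat$n_dead, dat$n_exposed - dat$n_dead)
  dev_full <- dev_of(resp ~ line / logc - 1)
  dev_con <- switch(hypothesis,
    equality = dev_of(resp ~ logc),
    parallelism = dev_of(resp ~ line + logc)
  )
  n_lines <- length(fits)
  df <- switch(hypothesis,
    equality = 2L * (n_lines - 1L),
    parallelism = n_lines - 1L
  )
  chi2 <- max(dev_con - dev_full, 0)
  list(hypothesis = hypothesis, chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_lines = n_lines)
}

#' Diagnostic (discriminating) concentration from a susceptible fit
#'
#' A diagnostic concentration for monitoring resistance frequency is taken
#' near the upper limit of the susceptible strain's LC99: this returns the
#' upper 95% confidence limit of the LC99 from the fitted line, so that
#' essentially all susceptible homozygotes die at the returned dose.
#'
#' @param fit A [fit_probit()] object for the susceptible reference strain.
#' @return Dose in micrograms a.i. per mL.
#' @export
diagnostic_dose <- function(fit) {
  estimate_lc(fit, 0.99)$ci_high
}
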