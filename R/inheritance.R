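#' Stone's degree of dominance from LC50s
#'
#' D = (2 XF - XR - XS) / (XR - XS) with X the log10 LC50 of the
#' heterozygote (F1), resistant and susceptible lines. D = 1 means
#' resistance is completely dominant, D = -1 completely recessive;
#' intermediate values grade incomplete dominance.
#'
#' @param lc_rs,lc_rr,lc_ss LC50s (micrograms a.i. per mL, > 0) of the
#'   heterozygous, resistant-homozygous and susceptible-homozygous lines.
#' @return An object of class `"dominance_estimate"`: `D`, `method`
#'   (`"stone"`), `inputs`, `classification`, `out_of_range`.
#' @examples
#' dominance_stone(77.38, 3080.95, 0.64)  # D ~ 0.13, incomplete dominant
#' @export
dominance_stone <- function(lc_rs, lc_rr, lc_ss) {
  stopifnot(lc_rs > 0, lc_rr > 0, lc_ss > 0)
  if (lc_rr == lc_ss) {
    stop("undefined denominator: resistant and susceptible LC50s are equal",
         call. = FALSE)
  }
  xf <- log10(lc_rs); xr <- log10(lc_rr); xs <- log10(lc_ss)
  d <- (2 * xf - xr - xs) / (xr - xs)
  .dominance_estimate(d, "stone",
                      inputs = c(XF = xf, XR = xr, XS = xs))
}

#' Bourguet degree of dominance from mortalities at one concentration
#'
#' D = (MRS - MSS) / (MRR - MSS) on the mortality proportions of the
#' heterozygous, resistant and susceptible lines at a single tested
#' concentration. Unlike the LC50-based statistic this dominance level is
#' dose-dependent. Values outside [-1, 1] (possible when mortalities are
#' non-monotone in genotype) are returned with an `out_of_range` flag,
#' never clamped.
#'
#' @param m_rs,m_rr,m_ss Mortality proportions in `[0, 1]`.
#' @return A `"dominance_estimate"` with `method = "bourguet"`.
#' @export
dominance_bourguet <- function(m_rs, m_rr, m_ss) {
  stopifnot(m_rs >= 0, m_rs <= 1, m_rr >= 0, m_rr <= 1,
            m_ss >= 0, m_ss <= 1)
  if (m_rr == m_ss) {
    stop("undefined denominator: resistant and susceptible mortalities ",
         "are equal at this concentration", call. = FALSE)
  }
  d <- (m_rs - m_ss) / (m_rr - m_ss)
  .dominance_estimate(d, "bourguet",
                      inputs = c(MRS = m_rs, MRR = m_rr, MSS = m_ss))
}

.dominance_estimate <- function(d, method, inputs) {
  structure(list(
    D = d, method = method, inputs = inputs,
    classification = classify_dominance(d),
    out_of_range = d < -1 || d > 1
  ), class = "dominance_estimate")
}

#' @export
print.dominance_estimate <- function(x, ...) {
  cat(sprintf("D = %.2f (%s): %s%s\n", x$D, x$method, x$classification,
              if (x$out_of_range) " [outside -1..1]" else ""))
  invisible(x)
}

#' Classify a degree of dominance
#'
#' Endpoint convention: values within 0.005 of +1 or -1 are called complete
#' dominance or complete recessivity; otherwise the sign decides the
#' incomplete category, with exactly 0 labelled the additive midpoint.
#'
#' @param d Finite dominance value.
#' @return Character classification.
#' @export
classify_dominance <- function(d) {
  stopifnot(is.finite(d))
  if (abs(d - 1) <= 0.005) return("complete dominant")
  if (abs(d + 1) <= 0.005) return("complete recessive")
  if (d == 0) return("codominant/additive midpoint")
  if (d > 0) "incomplete dominant" else "incomplete recessive"
}

#' Dominance-level curve across concentrations
#'
#' Predicts genotype mortalities from three fitted probit lines and applies
#' the Bourguet dominance statistic at each requested concentration,
#' tracing how dominance of resistance erodes as the dose rises. A
#' concentration where the predicted resistant and susceptible mortalities
#' coincide yields `NA` with `undefined = TRUE` rather than being dropped.
#'
#' @param fit_ss,fit_rs,fit_rr [fit_probit()] objects for the susceptible,
#'   heterozygous and resistant lines.
#' @param concentrations Positive doses (micrograms a.i. per mL).
#' @return A data frame with `concentration`, `m_ss`, `m_rs`, `m_rr`, `D`,
#'   `undefined`.
#' @export
dml_curve <- function(fit_ss, fit_rs, fit_rr, concentrations) {
  stopifnot(inherits(fit_ss, "probit_fit"), inherits(fit_rs, "probit_fit"),
            inherits(fit_rr, "probit_fit"), all(concentrations > 0))
  pred <- function(f, conc) stats::pnorm(f$alpha + f$beta * log10(conc))
  m_ss <- pred(fit_ss, concentrations)
  m_rs <- pred(fit_rs, concentrations)
  m_rr <- pred(fit_rr, concentrations)
  undef <- m_rr == m_ss
  d <- ifelse(undef, NA_real_, (m_rs - m_ss) / (m_rr - m_ss))
  data.frame(concentration = concentrations,
             m_ss = m_ss, m_rs = m_rs, m_rr = m_rr,
             D = d, undefined = undef)
}

#' Expected backcross mortality under 1:1 Mendelian segregation
#'
#' A backcross of F1 heterozygotes to the susceptible parent segregates 1:1
#' into heterozygous and susceptible genotypes under a one-locus model, so
#' the expected mortality at any concentration is the arithmetic mean
#' p = (a + b) / 2 of the two parental-genotype mortalities.
#'
#' @param a Mortality proportion of the heterozygous parent line.
#' @param b Mortality proportion of the susceptible parent line.
#' @param concentration Optional dose the mortalities refer to.
#' @param source `"observed"` (parental mortalities read off the assayed
#'   counts at the same dose) or `"fitted"` (predicted from probit fits).
#' @return A list with `concentration`, `a`, `b`, `p`, `q`, `source`.
#' @export
expected_backcross_mortality <- function(a, b, concentration = NA_real_,
                                         source = c("observed", "fitted")) {
  source <- match.arg(source)
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1)
  p <- (a + b) / 2
  list(concentration = concentration, a = a, b = b, p = p, q = 1 - p,
       source = source)
}

#' Chi-square test of monogenic inheritance for backcross mortality
#'
#' For each concentration the observed backcross dead count Ni out of ni is
#' compared with the Mendelian expectation p (from
#' [expected_backcross_mortality()]) by
#' chi2 = (Ni - p ni)^2 / (p q ni), df = 1 — the squared one-sample
#' proportion z statistic. The monogenic hypothesis is rejected when any
#' row is significant at `alpha` (row-wise flags, no multiplicity
#' adjustment, mirroring the usual presentation of such tables); the
#' any-row verdict rule is explicit and can be changed via `reject_rule`.
#'
#' @param rows Data frame with columns `concentration`, `Ni` (observed
#'   dead), `ni` (exposed), `p` (expected mortality in (0,1)).
#' @param alpha Row-wise significance level.
#' @param reject_rule `"any_row"` (default) or `"all_rows"`.
#' @return A list with `rows` (the input plus `expected`, `chi2`,
#'   `p_value`, `significant`) and `verdict` (`"monogenic not rejected"` or
#'   `"monogenic rejected"`).
#' @export
monogenic_test <- function(rows, alpha = 0.05,
                           reject_rule = c("any_row", "all_rows")) {
  reject_rule <- match.arg(reject_rule)
  stopifnot(all(c("concentration", "Ni", "ni", "p") %in% names(rows)))
  if (any(rows$p <= 0 | rows$p >= 1)) {
    stop("expected mortality p must lie strictly in (0, 1): the binomial ",
         "variance vanishes at 0 or 1", call. = FALSE)
  }
  stopifnot(all(rows$ni > 0), all(rows$Ni >= 0), all(rows$Ni <= rows$ni))
  q <- 1 - rows$p
  chi2 <- (rows$Ni - rows$p * rows$ni)^2 / (rows$p * q * rows$ni)
  p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  out <- rows
  out$expected <- rows$p * rows$ni
  out$chi2 <- chi2
  out$p_value <- p_value
  out$significant <- p_value < alpha
  rejected <- switch(reject_rule,
                     any_row = any(out$significant),
                     all_rows = all(out$significant))
  list(rows = out,
       verdict = if (rejected) "monogenic rejected"
                 else "monogenic not rejected")
}

#' Functional dominance at a field-rate concentration
#'
#' Compares strain mortalities assayed at a single discriminating dose
#' (e.g. a label field rate): pairwise two-proportion z tests on the
#' binomial scale with a single-step max-|z| familywise adjustment
#' (Tukey-style, via the joint normal distribution of the contrasts) and a
#' compact letter display. When all four genotype classes (susceptible,
#' resistant, heterozygotes) are present, the Bourguet dominance at the
#' dose is attached. For sparse tables (any dead/alive cell below 5) the
#' pairwise p-values fall back to Fisher mid-p exact tests before the
#' single-step adjustment is replaced by Bonferroni.
#'
#' @param counts Data frame with columns `strain`, `n_exposed`, `n_dead`.
#' @param dose The concentration assayed (metadata).
#' @param ss,rr,het Strain labels identifying the susceptible, resistant
#'   and heterozygous classes for the dominance computation; `het` may name
#'   several strains (their pooled mortality is used). Any may be `NULL`.
#' @param alpha Familywise significance level for the letter display.
#' @return A list with `dose`, `mortality` (per strain, with CIs),
#'   `pairwise` (contrast, z, p_adj), `letters` (named letter groups) and
#'   `D_at_dose` (a `"dominance_estimate"` or `NULL`).
#' @export
functional_dominance <- function(counts, dose = NA_real_,
                                 ss = NULL, rr = NULL, het = NULL,
                                 alpha = 0.05) {
  stopifnot(all(c("strain", "n_exposed", "n_dead") %in% names(counts)),
            nrow(counts) >= 2L)
  if (any(counts$n_exposed <= 0)) {
    stop("every strain needs a positive number of exposed insects",
         call. = FALSE)
  }
  agg <- stats::aggregate(cbind(n_dead, n_exposed) ~ strain, data = counts,
                          FUN = sum)
  prop <- agg$n_dead / agg$n_exposed
  names(prop) <- agg$strain
  k <- nrow(agg)

  ci <- t(vapply(seq_len(k), function(i) {
    as.numeric(stats::binom.test(agg$n_dead[i], agg$n_exposed[i])$conf.int)
  }, numeric(2)))
  mortality <- data.frame(strain = agg$strain, n_exposed = agg$n_exposed,
                          n_dead = agg$n_dead, mortality = prop,
                          ci_low = ci[, 1], ci_high = ci[, 2])

  pairs <- utils::combn(k, 2)
  sparse <- any(c(agg$n_dead, agg$n_exposed - agg$n_dead) < 5)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (sparse) {
      p_raw[j] <- .fisher_midp(agg$n_dead[i1], agg$n_exposed[i1],
                               agg$n_dead[i2], agg$n_exposed[i2])
      z[j] <- stats::qnorm(1 - p_raw[j] / 2)
    } else {
      pool <- (agg$n_dead[i1] + agg$n_dead[i2]) /
        (agg$n_exposed[i1] + agg$n_exposed[i2])
      se <- sqrt(pool * (1 - pool) *
                   (1 / agg$n_exposed[i1] + 1 / agg$n_exposed[i2]))
      z[j] <- if (se == 0) 0 else (prop[i1] - prop[i2]) / se
      p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
  }

  if (sparse) {
    p_adj <- pmin(p_raw * ncol(pairs), 1)  # Bonferroni on exact mid-p
  } else {
    p_adj <- .single_step_adjust(z, pairs, agg$n_exposed, prop)
  }

  cmp <- data.frame(
    strain_1 = agg$strain[pairs[1, ]],
    strain_2 = agg$strain[pairs[2, ]],
    z = z, p_raw = p_raw, p_adj = p_adj
  )
  letters <- .compact_letters(agg$strain, cmp, alpha, order_by = -prop)

  d_at_dose <- NULL
  if (!is.null(ss) && !is.null(rr) && !is.null(het) &&
      all(c(ss, rr, het) %in% agg$strain)) {
    m_het <- sum(agg$n_dead[agg$strain %in% het]) /
      sum(agg$n_exposed[agg$strain %in% het])
    d_at_dose <- dominance_bourguet(m_het, prop[[rr]], prop[[ss]])
  }

  list(dose = dose, mortality = mortality, pairwise = cmp,
       letters = letters, D_at_dose = d_at_dose,
       method = if (sparse) "fisher mid-p + bonferroni"
                else "two-proportion z + single-step max-|z|")
}

# Two-sided Fisher mid-p for a 2x2 table of dead/alive by strain:
# all hypergeometric outcomes strictly less likely than the observed one,
# plus half the mass of outcomes exactly as likely (incl. the observed).
.fisher_midp <- function(d1, n1, d2, n2) {
  m <- d1 + d2
  support <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(support, n1, n2, m)
  p_obs <- stats::dhyper(d1, n1, n2, m)
  min(1, sum(probs[probs < p_obs * (1 - 1e-9)]) +
        0.5 * sum(probs[abs(probs - p_obs) <= p_obs * 1e-9]))
}

# Single-step max-|z| adjustment: p_adj = P(max |Z| >= |z_obs|) under the
# joint normal law of all pairwise contrasts (correlations induced by the
# shared strains), computed with mvtnorm.
.single_step_adjust <- function(z, pairs, n, prop) {
  k <- length(n)
  m <- ncol(pairs)
  # contrast matrix on the proportion scale; variance via unpooled binomial
  v <- prop * (1 - prop) / n
  v[v == 0] <- 1e-12
  C <- matrix(0, m, k)
  for (j in seq_len(m)) {
    C[j, pairs[1, j]] <- 1
    C[j, pairs[2, j]] <- -1
  }
  S <- C %*% diag(v, k) %*% t(C)
  R <- stats::cov2cor(S)
  vapply(abs(z), function(zj) {
    if (!is.finite(zj)) return(0)
    pr <- if (m == 1L) {
      stats::pnorm(zj) - stats::pnorm(-zj)
    } else {
      mvtnorm::pmvnorm(lower = rep(-zj, m), upper = rep(zj, m), corr = R,
                       keepAttr = FALSE)
    }
    max(min(1 - pr, 1), 0)
  }, numeric(1))
}

# Insert-absorb compact letter display from a pairwise comparison table.
.compact_letters <- function(labels, cmp, alpha, order_by = NULL) {
  k <- length(labels)
  ord <- if (is.null(order_by)) seq_len(k) else order(order_by)
  labels_o <- labels[ord]
  distinct <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (j in seq_len(nrow(cmp))) {
    if (cmp$p_adj[j] < alpha) {
      distinct[cmp$strain_1[j], cmp$strain_2[j]] <- TRUE
      distinct[cmp$strain_2[j], cmp$strain_1[j]] <- TRUE
    }
  }
  groups <- list(labels_o)  # start with one group holding everything
  for (a in labels_o) for (b in labels_o) {
    if (a < b && distinct[a, b]) {
      offending <- which(vapply(groups, function(g) all(c(a, b) %in% g),
                                logical(1)))
      for (gi in rev(offending)) {
        g <- groups[[gi]]
        groups[[gi]] <- setdiff(g, a)
        groups[[length(groups) + 1L]] <- setdiff(g, b)
      }
      # absorb groups contained in another
      keep <- rep(TRUE, length(groups))
      for (i in seq_along(groups)) for (jj in seq_along(groups)) {
        if (i != jj && keep[jj] &&
            all(groups[[i]] %in% groups[[jj]]) &&
            length(groups[[i]]) < length(groups[[jj]])) keep[i] <- FALSE
      }
      groups <- unique(groups[keep])
    }
  }
  out <- stats::setNames(rep("", k), labels_o)
  for (i in seq_along(groups)) {
    g <- groups[[i]][order(match(groups[[i]], labels_o))]
    out[g] <- paste0(out[g], letters[i])
  }
  out[match(labels, names(out))]
}
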