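#' Dose-response report table for a set of strains
#'
#' Fits one probit line per strain x compound group of the table and lays
#' the results out in the conventional published format: n, slope with SE,
#' Pearson chi2 with df and p, LC50 with 95% CI, and the resistance ratio
#' against a reference strain with its lethal-dose-ratio CI.
#'
#' @param tab A [bioassay_table()] (controls allowed; dropped before
#'   fitting, or used first via [abbott_correct()] when `abbott = TRUE`).
#' @param reference_strain Strain whose LC50 is the RR denominator within
#'   each compound; its own RR row is `NA`. `NULL` for no ratios.
#' @param abbott Apply Abbott's control-mortality correction first.
#' @return A data frame with one row per strain x compound and columns
#'   `strain`, `compound`, `n`, `slope`, `slope_se`, `chi2`, `df`, `p`,
#'   `lc50`, `lc50_lo`, `lc50_hi`, `rr`, `rr_lo`, `rr_hi`. Full precision;
#'   round at display time.
#' @export
dose_response_report <- function(tab, reference_strain = NULL,
                                 abbott = FALSE) {
  tab <- validate_bioassay(tab)
  if (abbott) tab <- abbott_correct(tab)
  groups <- unique(tab[, c("strain", "compound")])
  fits <- lapply(seq_len(nrow(groups)), function(i) {
    fit_probit(tab, strain = groups$strain[i],
               compound = groups$compound[i])
  })
  lcs <- lapply(fits, estimate_lc, p = 0.5)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; lc <- lcs[[i]]
    rr <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(reference_strain) &&
        f$strain != reference_strain) {
      j <- which(groups$strain == reference_strain &
                   groups$compound == f$compound)
      if (length(j) == 1L) {
        r <- resistance_ratio(lc, lcs[[j]])
        rr <- c(r$ratio, r$ci_low, r$ci_high)
      }
    }
    data.frame(strain = f$strain, compound = f$compound, n = f$n,
               slope = f$beta, slope_se = f$se_beta,
               chi2 = f$gof$chi2, df = f$gof$df, p = f$gof$p_value,
               lc50 = lc$dose, lc50_lo = lc$ci_low, lc50_hi = lc$ci_high,
               rr = rr[1], rr_lo = rr[2], rr_hi = rr[3])
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Run the full resistance-analysis pipeline
#'
#' Orchestrates the analyses on a set of bioassay tables: probit
#' dose-response per strain with resistance ratios; optionally the
#' inheritance analyses (equality/parallelism of the reciprocal-cross
#' lines, Stone dominance per cross, the backcross monogenic test) and the
#' multi-generation stability analysis. The returned report is fully
#' deterministic given the inputs, and records the methodological
#' decisions in effect so printed-table comparisons are auditable.
#'
#' @param tab A [bioassay_table()] holding all strains (inheritance
#'   analyses also accept the list layout of
#'   [simulate_inheritance_experiment()] via `inheritance_tables`).
#' @param config List of options: `reference_strain` (RR denominator),
#'   `abbott` (default FALSE), `alpha` (default 0.05), `analyses`
#'   (character subset of `c("dose_response", "inheritance",
#'   "stability")`), `resistant_strain`, `f1_strains`,
#'   `backcross_strains` (labels for the inheritance section),
#'   `diagnostic_dose` (for stability), `seed` (recorded).
#' @param inheritance_tables Optional named list as returned by
#'   [simulate_inheritance_experiment()]; used instead of label lookup.
#' @return A list of class `"analysis_report"` with `metadata` and the
#'   requested sections.
#' @export
run_pipeline <- function(tab, config = list(), inheritance_tables = NULL) {
  analyses <- config$analyses %||% "dose_response"
  alpha <- config$alpha %||% 0.05
  abbott <- isTRUE(config$abbott)
  report <- list(metadata = list(
    tool = paste0("resistlab ",
                  as.character(utils::packageVersion("resistlab"))),
    seed = config$seed %||% NA,
    alpha = alpha,
    decisions = c(
      sprintf("abbott_correction=%s", if (abbott) "on" else "off"),
      "ci_method=delta method on log10 dose, z = 1.96",
      "heterogeneity_inflation=when lack-of-fit p < 0.05",
      "rr_ci=lethal-dose ratio, independent fits"
    )
  ))
  class(report) <- "analysis_report"

  if ("dose_response" %in% analyses) {
    if (is.null(tab) && !is.null(inheritance_tables)) {
      tabs <- Filter(function(x) inherits(x, "bioassay_table"),
                     inheritance_tables)
      tab <- do.call(rbind, lapply(tabs, as.data.frame))
      tab <- validate_bioassay(tab)
    }
    report$dose_response <- dose_response_report(
      tab, reference_strain = config$reference_strain, abbott = abbott)
  }

  if ("inheritance" %in% analyses) {
    report$inheritance <- .inheritance_section(tab, config,
                                               inheritance_tables, alpha)
  }

  if ("stability" %in% analyses) {
    if (is.null(config$diagnostic_dose)) {
      stop("stability analysis requires config$diagnostic_dose",
           call. = FALSE)
    }
    report$stability <- stability_analysis(tab, config$diagnostic_dose,
                                           alpha = alpha)
  }
  report
}

.inheritance_section <- function(tab, config, inheritance_tables, alpha) {
  get_tab <- function(label, key) {
    if (!is.null(inheritance_tables)) return(inheritance_tables[[key]])
    if (is.null(label)) return(NULL)
    sub <- tab[tab$strain == label, , drop = FALSE]
    if (nrow(sub) == 0L) NULL else sub
  }
  sus_tab <- get_tab(config$susceptible_strain %||% "Sus", "sus")
  rr_tab <- get_tab(config$resistant_strain %||% "Bif-R", "bif_r")
  f1_keys <- c("h1", "h2")
  f1_labels <- config$f1_strains %||% c("H1", "H2")
  f1_tabs <- Filter(Negate(is.null), lapply(seq_along(f1_keys), function(i) {
    get_tab(f1_labels[i], f1_keys[i])
  }))
  if (is.null(sus_tab) || is.null(rr_tab) || length(f1_tabs) == 0L) {
    stop("inheritance analysis needs susceptible, resistant and at least ",
         "one F1 strain", call. = FALSE)
  }
  fit_sus <- fit_probit(sus_tab)
  fit_rr <- fit_probit(rr_tab)
  fits_f1 <- lapply(f1_tabs, fit_probit)
  lc_sus <- estimate_lc(fit_sus, 0.5)
  lc_rr <- estimate_lc(fit_rr, 0.5)

  reciprocal <- if (length(fits_f1) >= 2L) {
    list(equality = compare_lines(fits_f1, "equality"),
         parallelism = compare_lines(fits_f1, "parallelism"))
  } else NULL

  stone <- lapply(fits_f1, function(f) {
    dominance_stone(estimate_lc(f, 0.5)$dose, lc_rr$dose, lc_sus$dose)
  })
  names(stone) <- vapply(fits_f1, function(f) f$strain, character(1))

  bc_keys <- c("bc_susF_h1M", "bc_susM_h1F", "bc_susF_h2M", "bc_susM_h2F")
  bc_labels <- config$backcross_strains %||% bc_keys
  monogenic <- list()
  for (i in seq_along(bc_keys)) {
    bc_tab <- get_tab(bc_labels[i], bc_keys[i])
    if (is.null(bc_tab)) next
    bc <- pool_concentrations(validate_bioassay(bc_tab))
    bc <- bc[bc$concentration > 0, , drop = FALSE]
    f1_for_bc <- fits_f1[[min(if (i <= 2) 1L else 2L, length(fits_f1))]]
    a <- stats::pnorm(f1_for_bc$alpha +
                        f1_for_bc$beta * log10(bc$concentration))
    b <- stats::pnorm(fit_sus$alpha + fit_sus$beta * log10(bc$concentration))
    p_exp <- pmin(pmax((a + b) / 2, 1e-8), 1 - 1e-8)
    monogenic[[bc_labels[i]]] <- monogenic_test(
      data.frame(concentration = bc$concentration, Ni = bc$n_dead,
                 ni = bc$n_exposed, p = p_exp),
      alpha = alpha)
    monogenic[[bc_labels[i]]]$expectation_source <- "fitted"
  }

  list(reciprocal_cross_tests = reciprocal,
       stone_dominance = stone,
       dml_curve = if (length(fits_f1) >= 1L) {
         dml_curve(fit_sus, fits_f1[[1]], fit_rr,
                   10^seq(log10(0.5), log10(1000), length.out = 25))
       } else NULL,
       monogenic = monogenic)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full precision) and, for tabular sections, CSV
#' files rounded to 2 decimals in the conventional display style.
#'
#' @param report An [run_pipeline()] report.
#' @param dir Output directory (created if needed).
#' @param format `"json"`, `"csv"`, or both.
#' @return Vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, format = c("json", "csv")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(.report_jsonable(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    paths <- c(paths, p)
  }
  if ("csv" %in% format && !is.null(report$dose_response)) {
    p <- file.path(dir, "dose_response.csv")
    out <- report$dose_response
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) round(x, 2))
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("csv" %in% format && !is.null(report$stability)) {
    p <- file.path(dir, "stability_survival.csv")
    utils::write.csv(report$stability$survival, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# strip function-bearing members (fits) so the report serializes cleanly
.report_jsonable <- function(x) {
  if (inherits(x, "probit_fit")) {
    return(list(strain = x$strain, compound = x$compound,
                alpha = x$alpha, beta = x$beta, se_beta = x$se_beta))
  }
  if (is.data.frame(x)) { attr(x, "fits") <- NULL; return(x) }
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, .report_jsonable))
  }
  x
}

#' Read a plain-text scenario configuration
#'
#' Key-value lines (`key = value` or `key: value`, `#` comments).
#' Recognized keys mirror the simulator's parameters: `n_loci`, `d_stone`,
#' `lc50_rr`, `lc50_ss`, `slope`, `concentrations` (comma-separated),
#' `n_per_conc`, `generations`, `proportions` (e.g. `80R:20S`),
#' `fitness_cost`, `cost_dominance`, `census`, `mode`, `seed`,
#' `diagnostic_dose`, `selection_dose`.
#'
#' @param path Path to the config file.
#' @return Named list with parsed values.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  numeric_keys <- c("n_loci", "d_stone", "lc50_rr", "lc50_ss", "slope",
                    "n_per_conc", "generations", "fitness_cost",
                    "cost_dominance", "census", "seed", "diagnostic_dose",
                    "selection_dose", "alpha")
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$",
                                ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln,
                              call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    out[[key]] <- if (key == "concentrations") {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key == "proportions") {
      pm <- regmatches(val, regexec("^([0-9.]+)R:([0-9.]+)S$", val))[[1]]
      if (length(pm) != 3L) {
        stop("proportions must look like 80R:20S", call. = FALSE)
      }
      tot <- as.numeric(pm[2]) + as.numeric(pm[3])
      c(rr = as.numeric(pm[2]) / tot, ss = as.numeric(pm[3]) / tot)
    } else if (key %in% numeric_keys) {
      as.numeric(val)
    } else {
      val
    }
  }
  out
}
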