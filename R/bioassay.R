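#' Construct and validate a bioassay table
#'
#' A bioassay table holds replicated quantal-response records: for each
#' strain x compound x concentration, the number of insects exposed and the
#' number dead after the scoring interval. Concentration 0 flags an
#' untreated-control row; control rows never enter a probit likelihood but
#' are used by [abbott_correct()].
#'
#' @param strain Character vector of strain identifiers.
#' @param compound Character vector of compound (active ingredient) names.
#' @param concentration Numeric, micrograms a.i. per mL; `0` marks controls.
#' @param n_exposed Integer counts of exposed insects, all `> 0`.
#' @param n_dead Integer counts of dead insects, `0 <= n_dead <= n_exposed`.
#' @param replicate Optional replicate labels (recycled if length 1).
#' @param generation Optional integer generation labels.
#' @return A `data.frame` of class `"bioassay_table"` with columns
#'   `strain`, `compound`, `concentration`, `n_exposed`, `n_dead`,
#'   `replicate`, `generation`.
#' @examples
#' bioassay_table("Sus", "bifenthrin", c(0, 1, 3.2, 10),
#'                n_exposed = 40, n_dead = c(1, 6, 19, 36))
#' @export
bioassay_table <- function(strain, compound, concentration, n_exposed, n_dead,
                           replicate = NA_character_,
                           generation = NA_integer_) {
  tab <- data.frame(
    strain = as.character(strain),
    compound = as.character(compound),
    concentration = as.numeric(concentration),
    n_exposed = as.integer(n_exposed),
    n_dead = as.integer(n_dead),
    replicate = as.character(replicate),
    generation = as.integer(generation),
    stringsAsFactors = FALSE
  )
  validate_bioassay(tab)
}

#' Validate a bioassay table
#'
#' Checks the structural invariants: finite non-negative concentrations,
#' positive exposure counts, and `n_dead <= n_exposed` in every row.
#'
#' @param tab A data frame with the bioassay columns.
#' @return The validated table, classed `"bioassay_table"`.
#' @export
validate_bioassay <- function(tab) {
  needed <- c("strain", "compound", "concentration", "n_exposed", "n_dead")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop("bioassay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- NA_character_
  if (!"generation" %in% names(tab)) tab$generation <- NA_integer_
  bad <- which(!is.finite(tab$concentration) | tab$concentration < 0)
  if (length(bad) > 0L) {
    stop("non-finite or negative concentration at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(tab$n_exposed) | tab$n_exposed <= 0)
  if (length(bad) > 0L) {
    stop("n_exposed must be a positive count; offending row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(tab$n_dead < 0 | tab$n_dead > tab$n_exposed)
  if (length(bad) > 0L) {
    stop("n_dead outside [0, n_exposed] at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(tab) <- unique(c("bioassay_table", class(tab)))
  tab
}

#' Abbott's correction for control mortality
#'
#' Rescales treated mortality by the pooled control (concentration 0)
#' mortality within each strain x compound group:
#' corrected = (observed - c) / (1 - c). Corrected dead counts are rounded
#' to the nearest integer and clamped to `[0, n_exposed]`; control rows are
#' removed from the returned table. Assays whose pooled control mortality
#' is 20% or more are rejected outright, the usual quality threshold for
#' discarding a bioassay.
#'
#' @param tab A [bioassay_table()].
#' @return The corrected table (controls dropped) with an attached
#'   `"abbott_correction"` attribute recording the control mortality
#'   applied per group.
#' @export
abbott_correct <- function(tab) {
  tab <- validate_bioassay(tab)
  is_control <- tab$concentration == 0
  if (!any(is_control)) {
    warning("no control rows (concentration == 0); table returned unchanged",
            call. = FALSE)
    attr(tab, "abbott_correction") <- data.frame(
      strain = character(0), compound = character(0),
      control_mortality = numeric(0)
    )
    return(tab)
  }
  grp <- interaction(tab$strain, tab$compound, drop = TRUE)
  record <- list()
  out <- tab
  for (g in levels(grp)) {
    rows <- grp == g
    ctrl <- rows & is_control
    strain_g <- tab$strain[rows][1]
    compound_g <- tab$compound[rows][1]
    if (!any(ctrl)) {
      warning(sprintf("group %s/%s has no control rows; left uncorrected",
                      strain_g, compound_g), call. = FALSE)
      next
    }
    cm <- sum(tab$n_dead[ctrl]) / sum(tab$n_exposed[ctrl])
    if (cm >= 0.20) {
      stop(sprintf(
        "control mortality %.1f%% in group %s/%s: assay rejected (>= 20%%)",
        100 * cm, strain_g, compound_g), call. = FALSE)
    }
    trt <- rows & !is_control
    prop <- out$n_dead[trt] / out$n_exposed[trt]
    corrected <- (prop - cm) / (1 - cm)
    n_corr <- round(corrected * out$n_exposed[trt])
    out$n_dead[trt] <- as.integer(pmin(pmax(n_corr, 0), out$n_exposed[trt]))
    record[[g]] <- data.frame(strain = strain_g, compound = compound_g,
                              control_mortality = cm)
  }
  out <- out[!is_control, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "abbott_correction") <-
    if (length(record) > 0) do.call(rbind, record) else
      data.frame(strain = character(0), compound = character(0),
                 control_mortality = numeric(0))
  out
}

# canonical CSV header for bioassay files
.bioassay_header <- c("strain", "compound", "concentration_ug_ml",
                      "n_total", "n_dead", "replicate", "generation")

#' Read a bioassay CSV file
#'
#' Expects a UTF-8 CSV whose header is exactly
#' `strain,compound,concentration_ug_ml,n_total,n_dead,replicate,generation`
#' (the last two columns optional). Decimal points only; a thousands
#' separator such as `"3,200"` is a parse error because it silently shifts
#' the dose scale.
#'
#' @param path Path to the CSV file.
#' @return A [bioassay_table()].
#' @export
read_bioassay_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  required <- .bioassay_header[1:5]
  if (!identical(names(raw)[seq_along(required)], required)) {
    stop("bad header: expected columns ",
         paste(.bioassay_header, collapse = ","),
         " (last two optional); got ",
         paste(names(raw), collapse = ","), call. = FALSE)
  }
  parse_num <- function(x, col) {
    bad <- grepl(",", x, fixed = TRUE)
    if (any(bad)) {
      stop(sprintf(
        "column %s row %d: value '%s' contains a comma %s",
        col, which(bad)[1], x[which(bad)[1]],
        "(thousands separators are not accepted; write 3200 not 3,200)"),
        call. = FALSE)
    }
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out) && any(!is.na(x) & x != "")) {
      i <- which(is.na(out) & x != "")[1]
      stop(sprintf("column %s row %d: cannot parse '%s' as a number",
                   col, i, x[i]), call. = FALSE)
    }
    out
  }
  conc <- parse_num(raw$concentration_ug_ml, "concentration_ug_ml")
  n_total <- parse_num(raw$n_total, "n_total")
  n_dead <- parse_num(raw$n_dead, "n_dead")
  bad <- which(n_dead > n_total)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: n_dead (%g) exceeds n_total (%g)",
                 bad[1], n_dead[bad[1]], n_total[bad[1]]), call. = FALSE)
  }
  bad <- which(conc < 0)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: negative concentration", bad[1]), call. = FALSE)
  }
  bioassay_table(
    strain = raw$strain,
    compound = raw$compound,
    concentration = conc,
    n_exposed = n_total,
    n_dead = n_dead,
    replicate = if ("replicate" %in% names(raw)) raw$replicate else NA,
    generation = if ("generation" %in% names(raw)) {
      suppressWarnings(as.integer(raw$generation))
    } else NA_integer_
  )
}

#' Write a bioassay table to CSV
#'
#' Emits the canonical header accepted by [read_bioassay_csv()].
#'
#' @param tab A [bioassay_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bioassay_csv <- function(tab, path) {
  tab <- validate_bioassay(tab)
  out <- data.frame(
    strain = tab$strain,
    compound = tab$compound,
    concentration_ug_ml = tab$concentration,
    n_total = tab$n_exposed,
    n_dead = tab$n_dead,
    replicate = tab$replicate,
    generation = tab$generation
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Pool replicate rows to one row per concentration within a strain/compound
# group; probit fitting and Pearson grouping both operate on pooled groups.
pool_concentrations <- function(tab) {
  key <- paste(tab$strain, tab$compound, tab$concentration, sep = "\r")
  dead <- tapply(tab$n_dead, key, sum)
  tot <- tapply(tab$n_exposed, key, sum)
  first <- !duplicated(key)
  ord <- key[first]
  data.frame(
    strain = tab$strain[first],
    compound = tab$compound[first],
    concentration = tab$concentration[first],
    n_exposed = as.integer(tot[ord]),
    n_dead = as.integer(dead[ord]),
    stringsAsFactors = FALSE
  )[order(tab$concentration[first]), , drop = FALSE]
}
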