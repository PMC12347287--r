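# delimited-text boundary and report assembly
#
# unit convention at the file boundary: cyclodextrin in mM (as usually
# quoted), amphiphile and CMC in uM; converted to the internal M / uM
# convention on read

TITRATION_COLS <- c("guest", "cd_conc_mM", "conc_uM", "rel_fluorescence_pct",
                    "replicate", "ph", "temp_C", "medium")
DIAGRAM_COLS <- c("guest", "cd_conc_mM", "cmc_uM", "ph", "temp_C", "medium")
GUEST_COLS <- c("name", "formula", "binding_energy_kcal_mol")

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort_micellr(sprintf("file not found: %s", path), "micellr_input_error")
  }
  sep <- detect_sep(path)
  # quote = "\"" so apostrophes in guest names (Resv-4'-LA) stay literal
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_micellr(sprintf("missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  "micellr_schema_error")
  }
  df
}

#' Read fluorescence titrations from a delimited text file
#'
#' Expects a header with columns `guest`, `cd_conc_mM`, `conc_uM`,
#' `rel_fluorescence_pct`, `replicate`, `ph`, `temp_C`, `medium`; comma or
#' tab delimiter is auto-detected; row order is irrelevant. Rows are
#' grouped into one [titration_curve()] per (guest, condition,
#' cyclodextrin level).
#'
#' @param path file path.
#' @return A list of [titration_curve()] objects, ordered by guest then
#'   cyclodextrin level.
#' @export
read_titrations <- function(path) {
  df <- read_table_checked(path, TITRATION_COLS)
  df$guest <- as.character(df$guest)
  df$guest[is.na(df$guest)] <- ""
  bad <- which(df$conc_uM < 0 | df$cd_conc_mM < 0)
  if (length(bad)) {
    abort_micellr(sprintf("negative concentration at data row %d", bad[1]),
                  "micellr_validation_error")
  }
  key <- interaction(df$guest, df$cd_conc_mM, df$ph, df$temp_C, df$medium,
                     drop = TRUE)
  groups <- split(df, key)
  ord <- order(vapply(groups, function(g) g$guest[1], character(1)),
               vapply(groups, function(g) g$cd_conc_mM[1], numeric(1)))
  curves <- lapply(groups[ord], function(g) {
    titration_curve(
      conc = g$conc_uM, fluorescence = g$rel_fluorescence_pct,
      replicate = g$replicate, cd_conc = g$cd_conc_mM[1] / 1000,
      condition = cmc_condition(ph = g$ph[1], temperature = g$temp_C[1],
                                medium = g$medium[1]),
      guest = g$guest[1])
  })
  unname(curves)
}

#' Write titration curves to a delimited text file
#'
#' Inverse of [read_titrations()]: the written file reads back to curves
#' identical to the originals.
#'
#' @param curves a list of [titration_curve()] objects.
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_titrations <- function(curves, path, sep = c(",", "\t")) {
  sep <- match.arg(sep)
  rows <- lapply(curves, function(cur) {
    data.frame(guest = cur$guest, cd_conc_mM = cur$cd_conc * 1000,
               conc_uM = cur$data$conc,
               rel_fluorescence_pct = cur$data$fluorescence,
               replicate = cur$data$replicate,
               ph = cur$condition$ph, temp_C = cur$condition$temperature,
               medium = cur$condition$medium)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a micellar diagram from a delimited text file
#'
#' Columns `guest`, `cd_conc_mM`, `cmc_uM`, `ph`, `temp_C`, `medium`, and
#' optionally `cmc_se_uM`; one diagram (one guest/condition) per file.
#'
#' @param path file path.
#' @return A [micellar_diagram()].
#' @export
read_diagram <- function(path) {
  df <- read_table_checked(path, DIAGRAM_COLS)
  micellar_diagram(
    cd_conc = df$cd_conc_mM / 1000, cmc = df$cmc_uM,
    cmc_se = if ("cmc_se_uM" %in% names(df)) df$cmc_se_uM else NULL,
    condition = cmc_condition(ph = df$ph[1], temperature = df$temp_C[1],
                              medium = df$medium[1]),
    guest = df$guest[1])
}

#' Write a micellar diagram to a delimited text file
#'
#' @param diagram a [micellar_diagram()].
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path, sep = c(",", "\t")) {
  sep <- match.arg(sep)
  df <- data.frame(guest = diagram$guest,
                   cd_conc_mM = diagram$cd_conc * 1000,
                   cmc_uM = diagram$cmc,
                   ph = diagram$condition$ph,
                   temp_C = diagram$condition$temperature,
                   medium = diagram$condition$medium)
  if (!is.null(diagram$cmc_se)) df$cmc_se_uM <- diagram$cmc_se
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a guest table (name, formula, binding energy)
#'
#' Columns `name`, `formula`, `binding_energy_kcal_mol`.
#'
#' @param path file path.
#' @return A tibble with columns `name`, `formula`, `binding_energy`.
#' @export
read_guests <- function(path) {
  df <- read_table_checked(path, GUEST_COLS)
  tibble::tibble(name = df$name, formula = df$formula,
                 binding_energy = df$binding_energy_kcal_mol)
}

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (2.5 -> 3, -2.5 -> -3),
#' the convention of printed fold changes; R's own `round()` rounds ties
#' to even.
#'
#' @param x numeric vector.
#' @param decimals non-negative number of decimals.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, decimals = 0L) {
  if (decimals < 0) {
    abort_micellr("`decimals` must be >= 0", "micellr_domain_error")
  }
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fold change between two quantities
#'
#' `numerator / denominator`, rounded half away from zero to the stated
#' number of decimals -- the arithmetic behind narrative statements such
#' as "the CMC increased from 43 to 136 uM (3.2-fold)".
#'
#' @param numerator,denominator quantities in the same units;
#'   `denominator` > 0.
#' @param decimals decimals to round to (default 1).
#' @return The rounded ratio.
#' @examples
#' fold_change(136, 43)        # 3.2
#' fold_change(6, 0.001, 0)    # 6000
#' @export
fold_change <- function(numerator, denominator, decimals = 1L) {
  check_number(numerator, "numerator")
  if (!is.numeric(denominator) || anyNA(denominator) || any(denominator <= 0)) {
    abort_micellr("`denominator` must be > 0", "micellr_domain_error")
  }
  round_half_away(numerator / denominator, decimals)
}

condition_as_list <- function(cond) {
  list(ph = cond$ph, temperature = cond$temperature, medium = cond$medium)
}

#' Assemble a structured fit report
#'
#' Bundles the per-level breakpoint fits, the selected binding fit and any
#' narrative fold-change comparisons for one guest/condition into a single
#' serializable report. Every fold-change ratio is recomputed here from
#' its numerator and denominator with [fold_change()].
#'
#' @param guest guest name.
#' @param condition a [cmc_condition()].
#' @param breakpoints a `breakpoint_batch` or list of `breakpoint_fit`s.
#' @param binding a `binding_fit`.
#' @param fold_changes optional data frame with columns `label`,
#'   `numerator`, `denominator`, `decimals`.
#' @param seed the seed that produced any stochastic inputs (recorded in
#'   provenance).
#' @param timestamp if `TRUE`, stamp the report with the current time
#'   (default `FALSE` so that rendering is byte-deterministic).
#' @return An object of class `fit_report`.
#' @export
fit_report <- function(guest, condition, breakpoints, binding,
                       fold_changes = NULL, seed = NULL, timestamp = FALSE) {
  missing_parts <- character()
  if (missing(breakpoints) || length(breakpoints) == 0L) {
    missing_parts <- c(missing_parts, "breakpoint fits")
  }
  if (missing(binding) || !inherits(binding, "binding_fit")) {
    missing_parts <- c(missing_parts, "binding fit")
  }
  if (length(missing_parts)) {
    abort_micellr(paste("incomplete report, missing:",
                        paste(missing_parts, collapse = ", ")),
                  "micellr_assembly_error")
  }
  bps <- lapply(unclass(breakpoints), function(f) {
    if (inherits(f, "condition")) {
      list(error = conditionMessage(f))
    } else {
      list(cd_conc_mM = f$cd_conc * 1000, cmc_uM = f$cmc,
           cmc_se_uM = f$cmc_se, sse = f$sse, scale = f$scale,
           n_pre = f$n_pre, n_post = f$n_post, warnings = f$warnings)
    }
  })
  fc <- NULL
  if (!is.null(fold_changes)) {
    fc <- lapply(seq_len(NROW(fold_changes)), function(i) {
      row <- fold_changes[i, ]
      list(label = row$label, numerator = row$numerator,
           denominator = row$denominator, decimals = row$decimals,
           ratio = fold_change(row$numerator, row$denominator, row$decimals))
    })
  }
  structure(
    list(
      guest = guest,
      condition = condition_as_list(condition),
      breakpoints = bps,
      binding = list(
        model = binding$model, cmc0_uM = binding$cmc0,
        cmc0_source = binding$cmc0_source,
        params = as.list(binding$params),
        r_squared = binding$r_squared, sse = binding$sse,
        ci_lower = if (is.null(binding$ci_lower)) NULL
                   else as.list(binding$ci_lower),
        ci_upper = if (is.null(binding$ci_upper)) NULL
                   else as.list(binding$ci_upper),
        n_boot = binding$n_boot,
        selection = if (is.null(binding$selection)) NULL else list(
          alpha = binding$selection$alpha,
          f_statistic = binding$selection$f_statistic,
          f_pvalue = binding$selection$f_pvalue,
          aicc_delta = binding$selection$aicc_delta,
          curvature_ok = binding$selection$curvature_ok),
        warnings = binding$warnings),
      fold_changes = fc,
      provenance = list(
        package = "micellr",
        version = as.character(utils::packageVersion("micellr")),
        seed = seed,
        created = if (timestamp) format(Sys.time(), tz = "UTC") else NULL)
    ),
    class = "fit_report")
}

#' Render a fit report as JSON or a text table
#'
#' Serialization is deterministic: the same report renders to identical
#' bytes.
#'
#' @param report a [fit_report()].
#' @param format `"json"` (default) or `"text"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("json", "text")) {
  stopifnot(inherits(report, "fit_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                         digits = 10, pretty = TRUE,
                                         null = "null")))
  }
  b <- report$binding
  pars <- paste(sprintf("%s = %.6g 1/M", names(b$params), unlist(b$params)),
                collapse = ", ")
  lines <- c(
    sprintf("Guest: %s", report$guest),
    sprintf("Condition: pH %.1f, %g degC, %s", report$condition$ph,
            report$condition$temperature, report$condition$medium),
    sprintf("Stoichiometry: %s   CMC0 = %.6g uM (%s)", b$model, b$cmc0_uM,
            b$cmc0_source),
    sprintf("Constants: %s", pars),
    sprintf("R-squared: %s",
            ifelse(is.na(b$r_squared), "NA", sprintf("%.4f", b$r_squared))),
    "Breakpoint fits:",
    vapply(report$breakpoints, function(f) {
      if (!is.null(f$error)) sprintf("  (failed: %s)", f$error)
      else sprintf("  CD %g mM -> CMC %.6g uM", f$cd_conc_mM, f$cmc_uM)
    }, character(1)))
  if (!is.null(report$fold_changes)) {
    lines <- c(lines, "Fold changes:",
               vapply(report$fold_changes, function(f) {
                 sprintf("  %s: %g / %g = %g", f$label, f$numerator,
                         f$denominator, f$ratio)
               }, character(1)))
  }
  paste(lines, collapse = "\n")
}
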