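#' Experimental condition of a titration
#'
#' pH, temperature and medium at which a fluorescence titration (and hence
#' a CMC) was measured. The media are those used for the complexation
#' study: 100 mM phosphate buffer at pH 7.0, MilliQ water, and 100 mM
#' sodium borate buffer at pH 2.0.
#'
#' @param ph pH, in (0, 14).
#' @param temperature temperature in degrees Celsius, in [0, 60].
#' @param medium one of `"PBS_100mM"`, `"MILLIQ_WATER"`, `"BORATE_100mM"`.
#' @param label optional free-text label.
#' @return An object of class `cmc_condition`.
#' @examples
#' cmc_condition(ph = 7, temperature = 35, medium = "PBS_100mM")
#' @export
cmc_condition <- function(ph = 7.0, temperature = 35,
                          medium = c("PBS_100mM", "MILLIQ_WATER", "BORATE_100mM"),
                          label = "") {
  medium <- match.arg(medium)
  if (!is.numeric(ph) || length(ph) != 1L || is.na(ph) || ph <= 0 || ph >= 14) {
    abort_micellr("`ph` must be a single value in (0, 14)",
                  "micellr_domain_error")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature < 0 || temperature > 60) {
    abort_micellr("`temperature` must be a single value in [0, 60] degC",
                  "micellr_domain_error")
  }
  structure(list(ph = ph, temperature = temperature, medium = medium,
                 label = label),
            class = "cmc_condition")
}

#' @export
print.cmc_condition <- function(x, ...) {
  cat(sprintf("<condition> pH %.1f, %g degC, %s%s\n", x$ph, x$temperature,
              x$medium, if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

same_condition <- function(a, b) {
  isTRUE(all.equal(a$ph, b$ph)) &&
    isTRUE(all.equal(a$temperature, b$temperature)) &&
    identical(a$medium, b$medium)
}

#' One fluorescence titration at a fixed cyclodextrin level
#'
#' Relative fluorescence of the probe versus amphiphile concentration,
#' measured at one cyclodextrin concentration and one condition. This is
#' the raw evidence for a single CMC estimate.
#'
#' @param conc amphiphile concentrations (uM), >= 0; replicate points may
#'   share a concentration.
#' @param fluorescence matched relative fluorescence values (percent).
#' @param replicate replicate identifier per point (recycled).
#' @param cd_conc cyclodextrin concentration (M), a single value >= 0.
#' @param condition a [cmc_condition()].
#' @param guest guest (amphiphile) name.
#' @return An object of class `titration_curve`: a list with a `data`
#'   tibble (`conc`, `fluorescence`, `replicate`) sorted by concentration
#'   and the curve metadata.
#' @export
titration_curve <- function(conc, fluorescence, replicate = 1L,
                            cd_conc = 0, condition = cmc_condition(),
                            guest = "") {
  check_number(conc, "conc", lower = 0)
  if (!is.numeric(fluorescence) || anyNA(fluorescence)) {
    abort_micellr("`fluorescence` must be numeric without NA",
                  "micellr_input_error")
  }
  if (length(conc) != length(fluorescence)) {
    abort_micellr("`conc` and `fluorescence` lengths differ",
                  "micellr_input_error")
  }
  if (length(conc) < 6L) {
    abort_micellr("a titration needs at least 6 points",
                  "micellr_input_error")
  }
  if (length(cd_conc) != 1L) {
    abort_micellr("one `cd_conc` per curve", "micellr_input_error")
  }
  check_number(cd_conc, "cd_conc", lower = 0)
  stopifnot(inherits(condition, "cmc_condition"))
  replicate <- rep_len(replicate, length(conc))
  ord <- order(conc, replicate)
  structure(
    list(
      data = tibble::tibble(conc = conc[ord],
                            fluorescence = fluorescence[ord],
                            replicate = replicate[ord]),
      cd_conc = cd_conc,
      condition = condition,
      guest = guest
    ),
    class = "titration_curve"
  )
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf(
    "<titration_curve> %s, CD %g mM, %d points (%d concentrations), pH %.1f, %g degC\n",
    if (nzchar(x$guest)) x$guest else "unnamed guest",
    x$cd_conc * 1000, nrow(x$data), length(unique(x$data$conc)),
    x$condition$ph, x$condition$temperature))
  invisible(x)
}
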