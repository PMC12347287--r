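#' Micellar diagram: apparent CMC versus cyclodextrin concentration
#'
#' The central data structure for complexation-constant inference: at one
#' condition, the apparent CMC of a guest measured at several added
#' cyclodextrin levels, anchored by the zero-cyclodextrin measurement
#' (CMC0). A linear rise indicates 1:1 complexation; upward curvature
#' (quadratic) indicates sequential 1:2 complexation.
#'
#' @param cd_conc cyclodextrin concentrations (M), distinct, containing 0.
#' @param cmc matched apparent CMC values (uM), > 0.
#' @param cmc_se optional matched standard errors (uM).
#' @param condition a [cmc_condition()].
#' @param guest guest name.
#' @return An object of class `micellar_diagram` with the levels sorted by
#'   `cd_conc`.
#' @export
micellar_diagram <- function(cd_conc, cmc, cmc_se = NULL,
                             condition = cmc_condition(), guest = "") {
  check_number(cd_conc, "cd_conc", lower = 0)
  check_number(cmc, "cmc", lower = 0, allow_zero = FALSE)
  if (length(cd_conc) != length(cmc)) {
    abort_micellr("`cd_conc` and `cmc` lengths differ", "micellr_input_error")
  }
  if (anyDuplicated(cd_conc)) {
    abort_micellr("cyclodextrin levels must be distinct", "micellr_input_error")
  }
  if (length(cd_conc) < 3L) {
    abort_micellr("a micellar diagram needs at least 3 cyclodextrin levels",
                  "micellr_input_error")
  }
  if (!any(cd_conc == 0)) {
    abort_micellr("a zero-cyclodextrin level (the CMC0 anchor) is required",
                  "micellr_input_error")
  }
  if (!is.null(cmc_se)) {
    check_number(cmc_se, "cmc_se", lower = 0)
    if (length(cmc_se) != length(cmc)) {
      abort_micellr("`cmc_se` length differs from `cmc`", "micellr_input_error")
    }
  }
  ord <- order(cd_conc)
  structure(
    list(cd_conc = cd_conc[ord], cmc = cmc[ord],
         cmc_se = if (is.null(cmc_se)) NULL else cmc_se[ord],
         condition = condition, guest = guest),
    class = "micellar_diagram")
}

#' @export
print.micellar_diagram <- function(x, ...) {
  cat(sprintf("<micellar_diagram> %s, %d CD levels (%g-%g mM), CMC0 = %g uM\n",
              if (nzchar(x$guest)) x$guest else "unnamed guest",
              length(x$cd_conc), min(x$cd_conc) * 1000,
              max(x$cd_conc) * 1000, x$cmc[x$cd_conc == 0]))
  invisible(x)
}

#' Assemble a micellar diagram from per-level breakpoint fits
#'
#' Collects the CMC estimates of a [estimate_cmc_batch()] run (or a plain
#' list of `breakpoint_fit` objects) into a [micellar_diagram()], carrying
#' over per-curve bootstrap standard errors when every fit has one.
#' Elements of a batch that captured errors are dropped with a warning.
#'
#' @param fits a `breakpoint_batch` or list of `breakpoint_fit` objects for
#'   one guest and condition at distinct cyclodextrin levels, one of them
#'   at zero cyclodextrin.
#' @return A [micellar_diagram()].
#' @export
build_diagram <- function(fits) {
  fits <- unclass(fits)
  failed <- vapply(fits, inherits, logical(1), "condition")
  if (any(failed)) {
    warning(sprintf("dropping %d failed breakpoint fit(s) from the diagram",
                    sum(failed)))
    fits <- fits[!failed]
  }
  if (length(fits) == 0L) {
    abort_micellr("no successful breakpoint fits to assemble",
                  "micellr_input_error")
  }
  ok <- vapply(fits, inherits, logical(1), "breakpoint_fit")
  if (!all(ok)) {
    abort_micellr("all elements must be breakpoint_fit objects",
                  "micellr_input_error")
  }
  cds <- vapply(fits, `[[`, numeric(1), "cd_conc")
  cmcs <- vapply(fits, `[[`, numeric(1), "cmc")
  ses <- lapply(fits, `[[`, "cmc_se")
  has_se <- all(!vapply(ses, is.null, logical(1)))
  micellar_diagram(
    cd_conc = cds, cmc = cmcs,
    cmc_se = if (has_se) unlist(ses) else NULL,
    condition = fits[[1]]$condition, guest = fits[[1]]$guest)
}
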