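#' Ground-truth binding parameters for one host-guest system
#'
#' Bundles the zero-cyclodextrin CMC with the association constants of the
#' chosen stoichiometry. A `"1:1"` model carries a single constant `kc`; a
#' sequential `"1:2"` model carries the stepwise constants `k1` and `k2`
#' (first and second cyclodextrin binding to one guest).
#'
#' @param model `"1:1"` or `"1:2"`.
#' @param cmc0 CMC in the absence of cyclodextrin (uM), > 0.
#' @param kc association constant (1/M) for the 1:1 model.
#' @param k1,k2 stepwise association constants (1/M) for the 1:2 model.
#' @return An object of class `binding_params`.
#' @examples
#' binding_params("1:1", cmc0 = 6, kc = 720)
#' binding_params("1:2", cmc0 = 0.001, k1 = 17, k2 = 0.18)
#' @export
binding_params <- function(model = c("1:1", "1:2"), cmc0, kc = NULL,
                           k1 = NULL, k2 = NULL) {
  model <- match.arg(model)
  check_number(cmc0, "cmc0", lower = 0, allow_zero = FALSE)
  if (model == "1:1") {
    if (is.null(kc) || !is.null(k1) || !is.null(k2)) {
      abort_micellr("a 1:1 model takes `kc` only", "micellr_domain_error")
    }
    check_number(kc, "kc", lower = 0)
    out <- list(model = model, cmc0 = cmc0, kc = kc)
  } else {
    if (is.null(k1) || is.null(k2) || !is.null(kc)) {
      abort_micellr("a 1:2 model takes `k1` and `k2` only",
                    "micellr_domain_error")
    }
    check_number(k1, "k1", lower = 0)
    check_number(k2, "k2", lower = 0)
    out <- list(model = model, cmc0 = cmc0, k1 = k1, k2 = k2)
  }
  structure(out, class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  if (x$model == "1:1") {
    cat(sprintf("<binding_params 1:1> CMC0 = %g uM, Kc = %g 1/M\n",
                x$cmc0, x$kc))
  } else {
    cat(sprintf("<binding_params 1:2> CMC0 = %g uM, K1 = %g 1/M, K2 = %g 1/M\n",
                x$cmc0, x$k1, x$k2))
  }
  invisible(x)
}

#' Apparent CMC under 1:1 complexation
#'
#' Forward model for the micellar diagram of a guest forming a single 1:1
#' inclusion complex with cyclodextrin:
#' `CMC = CMC0 * (1 + Kc * cd)`. Monomer sequestration by the host raises
#' the free-monomer concentration needed for micellization linearly in the
#' added CD.
#'
#' @param cmc0 CMC without cyclodextrin (uM), > 0.
#' @param kc association constant (1/M), >= 0.
#' @param cd added cyclodextrin concentration (M), >= 0; vectorised.
#' @return Apparent CMC (uM), same length as `cd`.
#' @examples
#' cmc_1to1(6, 720, c(0, 0.005, 0.01))
#' @export
cmc_1to1 <- function(cmc0, kc, cd) {
  check_number(cmc0, "cmc0", lower = 0, allow_zero = FALSE)
  check_number(kc, "kc", lower = 0)
  check_number(cd, "cd", lower = 0)
  cmc0 * (1 + kc * cd)
}

#' Apparent CMC under sequential 1:2 complexation
#'
#' Forward model when two cyclodextrins bind one guest stepwise with
#' constants `k1` then `k2`:
#' `CMC = CMC0 * (1 + K1 * cd + K1 * K2 * cd^2)`. Reduces exactly to
#' [cmc_1to1()] with `kc = k1` when `k2 = 0`.
#'
#' @param cmc0 CMC without cyclodextrin (uM), > 0.
#' @param k1,k2 stepwise association constants (1/M), >= 0.
#' @param cd added cyclodextrin concentration (M), >= 0; vectorised.
#' @return Apparent CMC (uM), same length as `cd`.
#' @examples
#' cmc_1to2(0.001, 17, 0.18, c(0, 0.05, 0.1))
#' @export
cmc_1to2 <- function(cmc0, k1, k2, cd) {
  check_number(cmc0, "cmc0", lower = 0, allow_zero = FALSE)
  check_number(k1, "k1", lower = 0)
  check_number(k2, "k2", lower = 0)
  check_number(cd, "cd", lower = 0)
  cmc0 * (1 + k1 * cd + k1 * k2 * cd^2)
}

#' Evaluate the forward CMC model of a parameter set
#'
#' @param params a [binding_params()] object.
#' @param cd added cyclodextrin concentration (M), vectorised.
#' @return Apparent CMC (uM).
#' @export
predict_cmc <- function(params, cd) {
  stopifnot(inherits(params, "binding_params"))
  if (params$model == "1:1") {
    cmc_1to1(params$cmc0, params$kc, cd)
  } else {
    cmc_1to2(params$cmc0, params$k1, params$k2, cd)
  }
}

#' Equilibrium species fractions for stepwise 1:2 binding
#'
#' Fractions of guest present as free monomer, 1:1 complex and 1:2 complex
#' at a given free cyclodextrin concentration, from the stepwise mass-action
#' equilibria `K1 = [GC]/([G][C])`, `K2 = [GC2]/([GC][C])`:
#' `f0 = 1 / (1 + K1 c + K1 K2 c^2)`, `f1 = K1 c f0`, `f2 = K1 K2 c^2 f0`.
#'
#' Free (not total) cyclodextrin is taken as given; the ternary mass
#' balance is not solved here.
#'
#' @param k1,k2 stepwise association constants (1/M), >= 0.
#' @param cd_free free cyclodextrin concentration (M), >= 0; vectorised.
#' @return A tibble with columns `cd_free`, `free`, `complex_1_1`,
#'   `complex_1_2`; rows sum to 1.
#' @examples
#' species_fractions(17, 0.18, c(0, 0.01, 0.1))
#' @export
species_fractions <- function(k1, k2, cd_free) {
  check_number(k1, "k1", lower = 0)
  check_number(k2, "k2", lower = 0)
  check_number(cd_free, "cd_free", lower = 0)
  denom <- 1 + k1 * cd_free + k1 * k2 * cd_free^2
  f0 <- 1 / denom
  tibble::tibble(
    cd_free = cd_free,
    free = f0,
    complex_1_1 = k1 * cd_free * f0,
    complex_1_2 = k1 * k2 * cd_free^2 * f0
  )
}
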