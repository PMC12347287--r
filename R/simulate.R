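# synthetic titrations and micellar diagrams with known ground truth
#
# The fluorescence response is piecewise linear with a continuous join at
# the CMC: a flat or shallow pre-micellar baseline, then a steeper
# post-micellar rise as the probe partitions into micelle cores. On linear
# concentration grids the segments are linear in concentration (slopes in
# % per uM); on log grids (used for sub-micromolar CMCs) they are linear
# in log10 concentration (slopes in % per decade), matching the axis on
# which such data is plotted and fitted.

#' Simulate one fluorescence titration
#'
#' Generates a titration curve whose breakpoint sits at the apparent CMC
#' implied by the ground-truth binding model at the given cyclodextrin
#' concentration, with additive Gaussian measurement noise.
#'
#' @param binding a [binding_params()] ground truth.
#' @param cd_conc cyclodextrin concentration (M) of this curve.
#' @param post_slope post-micellar slope (% per uM on linear grids,
#'   % per decade on log grids); must exceed `baseline_slope`.
#' @param baseline_level fluorescence at the lowest concentration (%).
#' @param baseline_slope pre-micellar slope, >= 0 (default 0: flat
#'   baseline).
#' @param conc_grid explicit amphiphile concentrations (uM), or `NULL` to
#'   build one from `n_points`, `grid` and `conc_range`.
#' @param n_points number of grid points (default 12).
#' @param grid `"auto"` (log when the breakpoint is below 1 uM), `"linear"`
#'   or `"log"`.
#' @param conc_range range (uM) of the grid; defaults to 0 to 3x the
#'   breakpoint (linear) or breakpoint/30 to 30x (log).
#' @param noise_sd additive Gaussian noise on fluorescence (%; default 2).
#' @param n_replicates replicate measurements per concentration
#'   (default 3).
#' @param seed integer seed (required; all randomness flows from it).
#' @param condition a [cmc_condition()].
#' @param guest guest name.
#' @return A [titration_curve()]; the true breakpoint is attached as
#'   attribute `"true_cmc"`.
#' @examples
#' simulate_titration(binding_params("1:1", cmc0 = 6, kc = 720),
#'                    cd_conc = 0.005, post_slope = 8, seed = 42)
#' @export
simulate_titration <- function(binding, cd_conc = 0, post_slope = 8,
                               baseline_level = 20, baseline_slope = 0,
                               conc_grid = NULL, n_points = 12L,
                               grid = c("auto", "linear", "log"),
                               conc_range = NULL, noise_sd = 2,
                               n_replicates = 3L, seed,
                               condition = cmc_condition(), guest = "") {
  stopifnot(inherits(binding, "binding_params"))
  grid <- match.arg(grid)
  if (missing(seed) || is.null(seed)) {
    abort_micellr("`seed` is required", "micellr_input_error")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  if (baseline_slope < 0 || post_slope <= baseline_slope) {
    abort_micellr("`post_slope` must exceed `baseline_slope` (>= 0)",
                  "micellr_spec_error")
  }
  breakpoint <- predict_cmc(binding, cd_conc)

  if (is.null(conc_grid)) {
    if (grid == "auto") grid <- if (breakpoint < 1) "log" else "linear"
    if (is.null(conc_range)) {
      conc_range <- if (grid == "log") c(breakpoint / 30, breakpoint * 30)
                    else c(0, 3 * breakpoint)
    }
    conc_grid <- if (grid == "log") {
      10^seq(log10(conc_range[1]), log10(conc_range[2]),
             length.out = n_points)
    } else {
      seq(conc_range[1], conc_range[2], length.out = n_points)
    }
  } else {
    if (grid == "auto") {
      pos <- conc_grid[conc_grid > 0]
      grid <- if (all(conc_grid > 0) && max(pos) / min(pos) > 100) "log"
              else "linear"
    }
    if (grid == "log" && any(conc_grid <= 0)) {
      abort_micellr("a log grid requires strictly positive concentrations",
                    "micellr_spec_error")
    }
  }
  if (breakpoint <= min(conc_grid) || breakpoint >= max(conc_grid)) {
    abort_micellr(
      sprintf("breakpoint %.4g uM falls outside the concentration grid",
              breakpoint), "micellr_spec_error")
  }

  conc <- rep(conc_grid, times = n_replicates)
  replicate <- rep(seq_len(n_replicates), each = length(conc_grid))
  x <- if (grid == "log") log10(conc) else conc
  xb <- if (grid == "log") log10(breakpoint) else breakpoint
  x0 <- if (grid == "log") log10(min(conc_grid)) else 0
  f_break <- baseline_level + baseline_slope * (xb - x0)
  f <- ifelse(x <= xb,
              baseline_level + baseline_slope * (x - x0),
              f_break + post_slope * (x - xb))
  if (noise_sd > 0) {
    f <- f + withr::with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  }
  out <- titration_curve(conc, f, replicate = replicate, cd_conc = cd_conc,
                         condition = condition, guest = guest)
  attr(out, "true_cmc") <- breakpoint
  out
}

#' Simulate a micellar diagram directly
#'
#' Bypasses the titration stage: evaluates the ground-truth CMC model on a
#' cyclodextrin grid and applies multiplicative Gaussian noise,
#' `cmc = model(cd) * (1 + e)`, `e ~ N(0, noise_cv)`. This is the fast
#' route for statistical experiments on the binding-fit stage. The known
#' measurement dispersion is recorded as `cmc_se = noise_cv * true cmc`,
#' so downstream fits use inverse-variance weighting.
#'
#' @param binding a [binding_params()] ground truth.
#' @param cd_grid cyclodextrin concentrations (M), distinct, including 0.
#' @param noise_cv fractional coefficient of variation on the CMC
#'   (default 0.05).
#' @param seed integer seed (required when `noise_cv > 0`).
#' @param condition a [cmc_condition()].
#' @param guest guest name.
#' @return A [micellar_diagram()]; the noise-free skeleton is attached as
#'   attribute `"true_cmc"`.
#' @export
simulate_diagram <- function(binding, cd_grid, noise_cv = 0.05, seed = NULL,
                             condition = cmc_condition(), guest = "") {
  stopifnot(inherits(binding, "binding_params"))
  check_number(noise_cv, "noise_cv", lower = 0)
  truth <- predict_cmc(binding, cd_grid)
  cmc <- truth
  se <- NULL
  if (noise_cv > 0) {
    if (is.null(seed)) {
      abort_micellr("`seed` is required when `noise_cv` > 0",
                    "micellr_input_error")
    }
    eps <- withr::with_seed(seed, stats::rnorm(length(truth), 0, noise_cv))
    cmc <- truth * (1 + eps)
    if (any(cmc <= 0)) {
      abort_micellr("noise drove a simulated CMC non-positive; lower `noise_cv`",
                    "micellr_spec_error")
    }
    se <- noise_cv * truth
  }
  out <- micellar_diagram(cd_grid, cmc, cmc_se = se, condition = condition,
                          guest = guest)
  attr(out, "true_cmc") <- truth[order(cd_grid)]
  out
}

#' Study-condition presets with reported ground-truth constants
#'
#' The pH / temperature / medium grid of the complexation study with the
#' reported CMC0 and association constants for each guest, usable directly
#' as simulation ground truths. Where two CMC0 readings are reported for a
#' fatty acid, the value from the CMC-shift experiment is used and the
#' alternative is noted.
#'
#' @return A tibble with columns `guest`, `ph`, `temperature`, `medium`,
#'   `model`, `cmc0` (uM), `kc`, `k1`, `k2` (1/M; NA where not
#'   applicable), `note`.
#' @export
condition_presets <- function() {
  tibble::tibble(
    guest = c("LA", "DHA",
              "Resv-4'-LA", "Resv-4'-LA", "Resv-4'-LA", "Resv-4'-LA",
              "Resv-4'-LA",
              "Resv-4'-DHA", "Resv-4'-DHA", "Resv-4'-DHA", "Resv-4'-DHA",
              "Resv-4'-DHA"),
    ph = c(7, 7, 7, 2, 7, 7, 7, 7, 2, 7, 7, 7),
    temperature = c(35, 35, 35, 35, 25, 15, 35, 35, 35, 25, 15, 35),
    medium = c("PBS_100mM", "PBS_100mM",
               "PBS_100mM", "BORATE_100mM", "PBS_100mM", "PBS_100mM",
               "MILLIQ_WATER",
               "PBS_100mM", "BORATE_100mM", "PBS_100mM", "PBS_100mM",
               "MILLIQ_WATER"),
    model = c("1:1", "1:1", "1:1", "1:1", "1:1", "1:1", "1:1",
              "1:2", "1:2", "1:2", "1:2", "1:2"),
    cmc0 = c(43, 70, 6, 0.54, 0.27, 0.14, 0.11,
             0.001, 5e-4, 6e-4, 3e-4, 5e-4),
    kc = c(7432, 7557, 720, 4264, 8157, 10432, 42535,
           NA, NA, NA, NA, NA),
    k1 = c(NA, NA, NA, NA, NA, NA, NA, 17, 97, 787, 898, 707),
    k2 = c(NA, NA, NA, NA, NA, NA, NA, 0.18, 0.45, 0.1, 0.33, 0.33),
    note = c("CMC0 also reported as 50.5 uM alongside the Kc comparison",
             "CMC0 also reported as 57.5 uM alongside the Kc comparison",
             "", "", "", "", "Kc also reported as 719 in the text",
             "", "", "", "", "")
  )
}

#' Build binding parameters from one preset row
#'
#' @param preset a single row of [condition_presets()].
#' @return A [binding_params()].
#' @export
preset_params <- function(preset) {
  if (NROW(preset) != 1L) {
    abort_micellr("`preset` must be a single row", "micellr_input_error")
  }
  if (preset$model == "1:1") {
    binding_params("1:1", cmc0 = preset$cmc0, kc = preset$kc)
  } else {
    binding_params("1:2", cmc0 = preset$cmc0, k1 = preset$k1, k2 = preset$k2)
  }
}
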