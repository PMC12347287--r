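# two-segment least squares: the CMC is read as the intersection of the
# pre-micellar baseline with the post-micellar fluorescence trend

# OLS line fit returning coefficients, SSE and the slope standard error;
# x/y already on the fitting scale
fit_line <- function(x, y, intercept_only = FALSE) {
  n <- length(x)
  if (intercept_only) {
    mu <- mean(y)
    sse <- sum((y - mu)^2)
    return(list(intercept = mu, slope = 0, sse = sse, slope_se = 0))
  }
  X <- cbind(1, x)
  fit <- .lm.fit(X, y)
  res <- fit$residuals
  sse <- sum(res^2)
  df <- n - 2L
  slope_se <- if (df > 0) {
    sxx <- sum((x - mean(x))^2)
    if (sxx > 0) sqrt(max(sse, 0) / df / sxx) else Inf
  } else 0
  list(intercept = fit$coefficients[1], slope = fit$coefficients[2],
       sse = sse, slope_se = slope_se)
}

#' Estimate the CMC of a titration by two-segment regression
#'
#' Fits every admissible partition of the curve into a pre-micellar segment
#' and a post-micellar segment (each holding at least `min_segment` distinct
#' concentrations), fitting an ordinary least-squares line to each segment,
#' and keeps the partition with the smallest total sum of squared residuals.
#' The reported CMC is the abscissa of the analytic intersection of the two
#' lines -- the graphical construction used with probe-fluorescence CMC
#' assays -- not the abscissa of the split point itself.
#'
#' Replicate points are fitted jointly, never pre-averaged. When the
#' sampled concentrations span more than two decades (as for nanomolar-CMC
#' amphiphiles) the fit is performed on log10 concentration and the
#' intersection back-transformed; a two-line fit on a linear axis is
#' meaningless across four decades. Slopes are then in percent per decade.
#'
#' A fit is only accepted as micellization if the post-micellar slope
#' exceeds the baseline slope by more than `slope_tol_mult` pooled standard
#' errors of the slope difference; otherwise a "no micellization detected"
#' error is raised. A perfectly flat signal raises a "flat signal" error.
#'
#' @param curve a [titration_curve()].
#' @param scale `"auto"` (default), `"linear"` or `"log"` concentration
#'   axis. `"auto"` switches to log when positive concentrations span more
#'   than two decades and no zero concentration is present.
#' @param min_segment minimum number of distinct concentrations per
#'   segment (default 3).
#' @param constrain_baseline if `TRUE`, the pre-micellar baseline is fitted
#'   with slope fixed to zero.
#' @param slope_tol_mult multiplier on the pooled slope-difference standard
#'   error below which the break is not called (default 3).
#' @param n_boot optional number of residual-bootstrap replicates used to
#'   attach a standard error `cmc_se` to the CMC (0 = none).
#' @param seed seed for the bootstrap (required when `n_boot > 0`).
#' @return An object of class `breakpoint_fit`: the `cmc` (uM), segment
#'   line parameters (`pre_intercept`, `pre_slope`, `post_intercept`,
#'   `post_slope`, on the fitting scale), `split_index` (last pre-micellar
#'   concentration, by rank), `sse`, `n_pre`/`n_post` point counts,
#'   `scale`, `warnings`, and the curve metadata (`cd_conc`, `condition`,
#'   `guest`).
#' @examples
#' cur <- simulate_titration(binding_params("1:1", cmc0 = 6, kc = 720),
#'                           post_slope = 8, noise_sd = 0, seed = 1)
#' estimate_cmc(cur)$cmc
#' @export
estimate_cmc <- function(curve, scale = c("auto", "linear", "log"),
                         min_segment = 3L, constrain_baseline = FALSE,
                         slope_tol_mult = 3, n_boot = 0L, seed = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  scale <- match.arg(scale)
  d <- curve$data
  frng <- range(d$fluorescence)
  if (diff(frng) <= 1e-12 * max(1, abs(mean(d$fluorescence)))) {
    abort_micellr("flat signal: fluorescence does not vary across the titration",
                  "micellr_flat_signal_error")
  }
  uc <- sort(unique(d$conc))
  if (length(uc) < 2L * min_segment) {
    abort_micellr(sprintf(
      "need at least %d distinct concentrations (%d per segment)",
      2L * min_segment, min_segment), "micellr_input_error")
  }
  if (scale == "auto") {
    scale <- if (all(uc > 0) && max(uc) / min(uc) > 100) "log" else "linear"
  }
  if (scale == "log" && any(uc <= 0)) {
    abort_micellr("log-scale fitting requires strictly positive concentrations",
                  "micellr_input_error")
  }
  x <- if (scale == "log") log10(d$conc) else d$conc
  ux <- if (scale == "log") log10(uc) else uc
  y <- d$fluorescence

  best <- NULL
  for (s in seq(min_segment, length(uc) - min_segment)) {
    pre_idx <- d$conc <= uc[s]
    pre <- fit_line(x[pre_idx], y[pre_idx], intercept_only = constrain_baseline)
    post <- fit_line(x[!pre_idx], y[!pre_idx])
    sse <- pre$sse + post$sse
    if (is.null(best) || sse < best$sse) {
      best <- list(split = s, pre = pre, post = post, sse = sse,
                   n_pre = sum(pre_idx), n_post = sum(!pre_idx))
    }
  }

  dslope <- best$post$slope - best$pre$slope
  se_diff <- sqrt(best$pre$slope_se^2 + best$post$slope_se^2)
  if (!(dslope > slope_tol_mult * se_diff) || dslope <= 0) {
    abort_micellr(
      "no micellization detected: post-micellar slope does not exceed the baseline slope",
      "micellr_no_micellization_error")
  }

  x_star <- (best$pre$intercept - best$post$intercept) / dslope
  warnings <- character()
  if (x_star < ux[best$split] || x_star > ux[best$split + 1L]) {
    warnings <- c(warnings,
                  "intersection falls outside the interval between the last pre-micellar and first post-micellar concentrations")
  }
  cmc <- if (scale == "log") 10^x_star else x_star
  if (!is.finite(cmc) || cmc <= 0) {
    abort_micellr("two-line intersection does not yield a positive CMC",
                  "micellr_fit_error")
  }

  fit <- structure(
    list(cmc = cmc, cmc_se = NULL,
         pre_intercept = best$pre$intercept, pre_slope = best$pre$slope,
         post_intercept = best$post$intercept, post_slope = best$post$slope,
         split_index = best$split, sse = best$sse,
         n_pre = best$n_pre, n_post = best$n_post,
         scale = scale, warnings = warnings,
         cd_conc = curve$cd_conc, condition = curve$condition,
         guest = curve$guest),
    class = "breakpoint_fit")

  if (n_boot > 0L) {
    if (is.null(seed)) {
      abort_micellr("`seed` is required when `n_boot` > 0",
                    "micellr_input_error")
    }
    fit$cmc_se <- withr::with_seed(seed, {
      pre_idx <- d$conc <= uc[best$split]
      fitted <- ifelse(pre_idx,
                       best$pre$intercept + best$pre$slope * x,
                       best$post$intercept + best$post$slope * x)
      res <- y - fitted
      boots <- vapply(seq_len(n_boot), function(b) {
        yb <- fitted + sample(res, length(res), replace = TRUE)
        cb <- curve
        cb$data$fluorescence <- yb
        out <- tryCatch(
          estimate_cmc(cb, scale = scale, min_segment = min_segment,
                       constrain_baseline = constrain_baseline,
                       slope_tol_mult = 0)$cmc,
          micellr_error = function(e) NA_real_)
        out
      }, numeric(1))
      stats::sd(boots, na.rm = TRUE)
    })
  }
  fit
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("<breakpoint_fit> CMC = %.6g uM (%s axis), SSE = %.4g, %d + %d points\n",
              x$cmc, x$scale, x$sse, x$n_pre, x$n_post))
  if (length(x$warnings)) cat("  warning:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Estimate CMCs for a set of titrations at different cyclodextrin levels
#'
#' Maps [estimate_cmc()] over curves measured for one guest under one
#' condition at distinct cyclodextrin concentrations, as needed to assemble
#' a micellar diagram. Failures are captured per curve and do not abort the
#' batch.
#'
#' @param curves a list of [titration_curve()] objects sharing guest and
#'   condition, with distinct `cd_conc` values.
#' @param ... passed to [estimate_cmc()].
#' @return A list of class `breakpoint_batch`, one element per curve in the
#'   input order: a `breakpoint_fit` on success or the captured error
#'   condition on failure.
#' @export
estimate_cmc_batch <- function(curves, ...) {
  if (length(curves) == 0L) return(structure(list(), class = "breakpoint_batch"))
  ok <- vapply(curves, inherits, logical(1), "titration_curve")
  if (!all(ok)) {
    abort_micellr("all elements must be titration_curve objects",
                  "micellr_input_error")
  }
  guests <- vapply(curves, `[[`, character(1), "guest")
  if (length(unique(guests)) > 1L) {
    abort_micellr("curves in a batch must share one guest",
                  "micellr_input_error")
  }
  for (cur in curves[-1]) {
    if (!same_condition(cur$condition, curves[[1]]$condition)) {
      abort_micellr("curves in a batch must share one condition",
                    "micellr_input_error")
    }
  }
  cds <- vapply(curves, `[[`, numeric(1), "cd_conc")
  if (anyDuplicated(cds)) {
    abort_micellr("cyclodextrin levels in a batch must be distinct",
                  "micellr_input_error")
  }
  out <- lapply(curves, function(cur) {
    tryCatch(estimate_cmc(cur, ...), micellr_error = function(e) e)
  })
  structure(out, class = "breakpoint_batch")
}
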