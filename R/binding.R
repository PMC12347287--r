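# complexation-constant inference from micellar diagrams
#
# Both forward models are linear in transformed parameters:
#   1:1  cmc - cmc0 = (Kc cmc0) cd
#   1:2  cmc - cmc0 = (K1 cmc0) cd + (K1 K2 cmc0) cd^2
# so with cmc0 anchored to the measured zero-CD level the fits reduce to
# (weighted) least squares on those bases; non-negativity is enforced by a
# bounded multistart refit only when the unconstrained optimum is
# inadmissible. The zero-CD level is the anchor, not a data point: its
# residual is structurally zero and it is excluded from the regression
# degrees of freedom.

diagram_weights <- function(diagram) {
  se <- diagram$cmc_se
  if (is.null(se) || any(se <= 0)) return(NULL)
  1 / se^2
}

cmc0_measured <- function(diagram) diagram$cmc[diagram$cd_conc == 0]

new_binding_fit <- function(model, cmc0, params, cmc0_source, diagram,
                            warnings = character()) {
  fitted <- if (model == "1:1") {
    cmc_1to1(cmc0, params[["kc"]], diagram$cd_conc)
  } else {
    cmc_1to2(cmc0, params[["k1"]], params[["k2"]], diagram$cd_conc)
  }
  res <- diagram$cmc - fitted
  w <- diagram_weights(diagram)
  use <- diagram$cd_conc > 0 | cmc0_source == "fitted"
  sse <- if (is.null(w)) sum(res[use]^2) else sum(w[use] * res[use]^2)
  sstot <- sum((diagram$cmc - mean(diagram$cmc))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
  if (is.na(r2)) warnings <- c(warnings, "flat diagram: R-squared undefined")
  structure(
    list(model = model, cmc0 = cmc0, params = params,
         cmc0_source = cmc0_source, r_squared = r2, sse = sse,
         fitted = fitted, residuals = res, n_levels = length(diagram$cd_conc),
         warnings = warnings, condition = diagram$condition,
         guest = diagram$guest),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  pars <- paste(sprintf("%s = %.6g", names(x$params), x$params),
                collapse = ", ")
  cat(sprintf("<binding_fit %s> CMC0 = %.6g uM (%s), %s 1/M, R^2 = %s\n",
              x$model, x$cmc0, x$cmc0_source, pars,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  if (!is.null(x$ci_lower)) {
    for (p in names(x$params)) {
      cat(sprintf("  %s 95%% CI: [%.6g, %.6g] (B = %d)\n", p,
                  x$ci_lower[[p]], x$ci_upper[[p]], x$n_boot))
    }
  }
  if (!is.null(x$selection)) {
    cat(sprintf("  selection: one-sided curvature p = %.4g (alpha = %g)\n",
                x$selection$f_pvalue, x$selection$alpha))
  }
  invisible(x)
}

#' Fit the 1:1 complexation model to a micellar diagram
#'
#' Estimates the association constant Kc of a single 1:1 inclusion
#' equilibrium from the linear rise of the apparent CMC with cyclodextrin
#' concentration, `cmc = cmc0 * (1 + Kc * cd)`. By default `cmc0` is fixed
#' to the measured zero-cyclodextrin level (it is a characteristic constant
#' of the compound at the condition); `cmc0_source = "fitted"` frees it as
#' a regression intercept. Inverse-variance weighting is applied when the
#' diagram carries standard errors.
#'
#' A significantly negative slope is reported with a "CMC decreases with
#' CD" warning and Kc clamped to zero.
#'
#' @param diagram a [micellar_diagram()].
#' @param cmc0_source `"measured"` (default) or `"fitted"`.
#' @return A `binding_fit` with `params["kc"]` (1/M), `r_squared`
#'   computed on the full diagram, `sse`, fitted values and residuals.
#' @export
fit_binding_1to1 <- function(diagram, cmc0_source = c("measured", "fitted")) {
  stopifnot(inherits(diagram, "micellar_diagram"))
  cmc0_source <- match.arg(cmc0_source)
  w <- diagram_weights(diagram)
  warnings <- character()

  if (cmc0_source == "measured") {
    cmc0 <- cmc0_measured(diagram)
    use <- diagram$cd_conc > 0
    x <- diagram$cd_conc[use]
    y <- diagram$cmc[use] - cmc0
    ww <- if (is.null(w)) rep(1, length(x)) else w[use]
    beta <- sum(ww * x * y) / sum(ww * x^2)
    # slope significance for the decreasing-CMC warning
    df <- length(x) - 1L
    if (beta < 0) {
      if (df > 0) {
        s2 <- sum(ww * (y - beta * x)^2) / df
        se <- sqrt(s2 / sum(ww * x^2))
        if (se > 0 && beta / se < -2) {
          warnings <- c(warnings, "CMC decreases with CD")
        }
      }
      beta <- 0
    }
    kc <- beta / cmc0
  } else {
    X <- cbind(1, diagram$cd_conc)
    fit <- if (is.null(w)) stats::lm.fit(X, diagram$cmc)
           else stats::lm.wfit(X, diagram$cmc, w)
    cmc0 <- unname(fit$coefficients[1])
    if (!is.finite(cmc0) || cmc0 <= 0) {
      abort_micellr("fitted CMC0 is not positive", "micellr_fit_error")
    }
    slope <- unname(fit$coefficients[2])
    if (slope < 0) {
      warnings <- c(warnings, "CMC decreases with CD")
      slope <- 0
    }
    kc <- slope / cmc0
  }
  new_binding_fit("1:1", cmc0, c(kc = kc), cmc0_source, diagram, warnings)
}

# bounded multistart minimisation of the 1:2 SSE, used when the
# unconstrained least-squares optimum has an inadmissible sign
fit_1to2_constrained <- function(diagram, cmc0, w, k1_start) {
  use <- diagram$cd_conc > 0
  cd <- diagram$cd_conc[use]
  y <- diagram$cmc[use]
  ww <- if (is.null(w)) rep(1, length(cd)) else w[use]
  obj <- function(p) {
    sum(ww * (y - cmc0 * (1 + p[1] * cd + p[1] * p[2] * cd^2))^2)
  }
  starts <- lapply(c(0, 0.1, 1, 10), function(k2) c(max(k1_start, 0), k2))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = c(0, 0),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    abort_micellr("1:2 fit failed to converge from all starts",
                  "micellr_fit_error")
  }
  pmax(best$par, 0)  # L-BFGS-B can land a few ulp below its bound
}

#' Fit the sequential 1:2 complexation model to a micellar diagram
#'
#' Estimates the stepwise constants (K1, K2) from the quadratic dependence
#' of the apparent CMC on cyclodextrin,
#' `cmc = cmc0 * (1 + K1 cd + K1 K2 cd^2)`, with `cmc0` anchored as in
#' [fit_binding_1to1()]. The model is linear in (K1, K1 K2), so the
#' non-negative least-squares solution is found directly when admissible
#' and by bounded multistart optimisation otherwise.
#'
#' @param diagram a [micellar_diagram()] with at least 4 distinct
#'   cyclodextrin levels.
#' @param cmc0_source `"measured"` (default) or `"fitted"`.
#' @return A `binding_fit` with `params[c("k1", "k2")]` (1/M).
#' @export
fit_binding_1to2 <- function(diagram, cmc0_source = c("measured", "fitted")) {
  stopifnot(inherits(diagram, "micellar_diagram"))
  cmc0_source <- match.arg(cmc0_source)
  if (length(diagram$cd_conc) < 4L) {
    abort_micellr("the 1:2 model needs at least 4 cyclodextrin levels",
                  "micellr_input_error")
  }
  w <- diagram_weights(diagram)

  if (cmc0_source == "measured") {
    cmc0 <- cmc0_measured(diagram)
    use <- diagram$cd_conc > 0
    cd <- diagram$cd_conc[use]
    y <- diagram$cmc[use] - cmc0
    X <- cmc0 * cbind(cd, cd^2)
    fit <- if (is.null(w)) stats::lm.fit(X, y)
           else stats::lm.wfit(X, y, w[use])
    a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
    if (is.finite(a) && is.finite(b) && a >= 0 && b >= 0) {
      k1 <- a
      k2 <- if (a > 0) b / a else 0
    } else {
      slope <- sum(cd * y) / sum(cd^2) / cmc0
      par <- fit_1to2_constrained(diagram, cmc0, w, slope)
      k1 <- par[1]; k2 <- par[2]
    }
  } else {
    X <- cbind(1, diagram$cd_conc, diagram$cd_conc^2)
    fit <- if (is.null(w)) stats::lm.fit(X, diagram$cmc)
           else stats::lm.wfit(X, diagram$cmc, w)
    co <- unname(fit$coefficients)
    cmc0 <- co[1]
    if (!is.finite(cmc0) || cmc0 <= 0) {
      abort_micellr("fitted CMC0 is not positive", "micellr_fit_error")
    }
    a <- co[2] / cmc0; b <- co[3] / cmc0
    if (a >= 0 && b >= 0) {
      k1 <- a; k2 <- if (a > 0) b / a else 0
    } else {
      par <- fit_1to2_constrained(diagram, cmc0, diagram_weights(diagram),
                                  max(a, 0))
      k1 <- par[1]; k2 <- par[2]
    }
  }
  new_binding_fit("1:2", cmc0, c(k1 = unname(k1), k2 = unname(k2)),
                  cmc0_source, diagram)
}

#' Select the complexation stoichiometry of a micellar diagram
#'
#' Fits both the 1:1 (linear) and sequential 1:2 (quadratic) models and
#' decides between them. The field's visual rule -- a linear diagram means
#' 1:1, a quadratic one means 1:2 -- is made operational as a one-sided
#' test for positive curvature: in the unconstrained quadratic regression
#' the t statistic of the cd^2 coefficient is compared against Student's t
#' at level `alpha` (one-sided, because negative curvature is chemically
#' inadmissible and clamped; the two-sided extra-sum-of-squares F would
#' reject at only about half its nominal level once clamping is taken into
#' account). The 1:2 model is declared only when the test rejects *and*
#' the fitted curvature is material: `k2 * max(cd) > 0.01`, i.e. the
#' quadratic term contributes at least 1% of the linear term at the
#' highest cyclodextrin level.
#'
#' @param diagram a [micellar_diagram()] with at least 4 levels.
#' @param alpha significance level in (0, 0.5].
#' @param cmc0_source `"measured"` (default) or `"fitted"`.
#' @return The selected `binding_fit`, with a `$selection` list carrying
#'   `f_statistic`, `f_pvalue` (one-sided), `aicc_delta`
#'   (AICc(1:2) - AICc(1:1)), both models' SSE, the curvature-floor flag
#'   and the non-selected fit (`$selection$alternative`).
#' @export
select_stoichiometry <- function(diagram, alpha = 0.05,
                                 cmc0_source = c("measured", "fitted")) {
  stopifnot(inherits(diagram, "micellar_diagram"))
  cmc0_source <- match.arg(cmc0_source)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5) {
    abort_micellr("`alpha` must be in (0, 0.5]", "micellr_domain_error")
  }
  fit1 <- fit_binding_1to1(diagram, cmc0_source)
  fit2 <- fit_binding_1to2(diagram, cmc0_source)

  w <- diagram_weights(diagram)
  use <- diagram$cd_conc > 0 | cmc0_source == "fitted"
  cd <- diagram$cd_conc[use]
  ww <- if (is.null(w)) rep(1, length(cd)) else w[use]
  if (cmc0_source == "measured") {
    cmc0 <- cmc0_measured(diagram)
    y <- diagram$cmc[use] - cmc0
    X <- cmc0 * cbind(cd, cd^2)
  } else {
    y <- diagram$cmc[use]
    X <- cbind(1, cd, cd^2)
  }
  # one-sided t test for the quadratic coefficient, unconstrained fit
  qf <- stats::lm.wfit(X, y, ww)
  n_used <- length(y)
  p_full <- ncol(X)
  df <- n_used - p_full
  sse_full <- sum(ww * qf$residuals^2)
  sstot <- sum((diagram$cmc - mean(diagram$cmc))^2)
  eps <- 1e-12 * max(sstot, .Machine$double.eps)
  XtXinv <- chol2inv(chol(crossprod(X * sqrt(ww))))
  b_hat <- qf$coefficients[p_full]
  if (fit1$sse <= eps) {
    # the linear model already fits perfectly; no curvature to detect
    t_stat <- 0; p_val <- 1
  } else if (df <= 0) {
    abort_micellr("too few levels to test curvature", "micellr_fit_error")
  } else if (sse_full <= eps) {
    t_stat <- Inf; p_val <- 0
  } else {
    se_b <- sqrt(sse_full / df * XtXinv[p_full, p_full])
    t_stat <- b_hat / se_b
    p_val <- stats::pt(t_stat, df, lower.tail = FALSE)
  }

  cd_max <- max(diagram$cd_conc)
  curvature_ok <- fit2$params[["k1"]] > 0 &&
    fit2$params[["k2"]] * cd_max > 0.01
  choose_12 <- is.finite(p_val) && p_val < alpha && curvature_ok

  aicc <- function(sse, k) {
    # k counts free mean parameters; +1 for the error variance
    kk <- k + 1
    if (n_used - kk - 1 <= 0 || sse <= 0) return(NA_real_)
    n_used * log(sse / n_used) + 2 * kk + 2 * kk * (kk + 1) / (n_used - kk - 1)
  }
  selection <- list(
    alpha = alpha,
    f_statistic = if (is.finite(t_stat)) t_stat^2 else Inf,
    f_pvalue = p_val,
    aicc_delta = aicc(fit2$sse, p_full) - aicc(fit1$sse, p_full - 1),
    curvature_ok = curvature_ok,
    sse_1to1 = fit1$sse, sse_1to2 = fit2$sse,
    alternative = if (choose_12) fit1 else fit2)
  out <- if (choose_12) fit2 else fit1
  out$selection <- selection
  out
}

#' Residual-bootstrap confidence intervals for a binding fit
#'
#' Resamples the fit's residuals at the non-anchor cyclodextrin levels
#' (levels are designed, not sampled, so residual -- not pairs --
#' resampling is appropriate), refits the same model, and reports
#' per-parameter percentile intervals. Deterministic for a fixed seed.
#'
#' @param fit a `binding_fit` from [fit_binding_1to1()],
#'   [fit_binding_1to2()] or [select_stoichiometry()].
#' @param diagram the [micellar_diagram()] the fit came from.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed (required).
#' @param level confidence level (default 0.95).
#' @return The fit augmented with `ci_lower`, `ci_upper` (named as the
#'   parameters), `n_boot` and `seed`. With degenerate (all-zero)
#'   residuals the intervals collapse to the point estimate and a warning
#'   is attached.
#' @export
bootstrap_binding <- function(fit, diagram, n_boot = 1000L, seed,
                              level = 0.95) {
  stopifnot(inherits(fit, "binding_fit"), inherits(diagram, "micellar_diagram"))
  if (n_boot < 100L) {
    abort_micellr("`n_boot` must be at least 100", "micellr_input_error")
  }
  if (missing(seed) || is.null(seed)) {
    abort_micellr("`seed` is required for the bootstrap", "micellr_input_error")
  }
  refit <- function(dg) {
    if (fit$model == "1:1") fit_binding_1to1(dg, fit$cmc0_source)
    else fit_binding_1to2(dg, fit$cmc0_source)
  }
  use <- diagram$cd_conc > 0 | fit$cmc0_source == "fitted"
  res <- fit$residuals[use]
  scale0 <- max(abs(diagram$cmc))
  pnames <- names(fit$params)
  if (all(abs(res) <= 1e-10 * scale0)) {
    fit$ci_lower <- stats::setNames(fit$params, pnames)
    fit$ci_upper <- stats::setNames(fit$params, pnames)
    fit$warnings <- c(fit$warnings,
                      "degenerate residuals: intervals collapse to the point estimate")
    fit$n_boot <- as.integer(n_boot); fit$seed <- seed
    return(fit)
  }
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      dg <- diagram
      yb <- fit$fitted
      yb[use] <- fit$fitted[use] + sample(res, length(res), replace = TRUE)
      dg$cmc <- pmax(yb, .Machine$double.eps)
      out <- tryCatch(refit(dg)$params, micellr_error = function(e) {
        stats::setNames(rep(NA_real_, length(pnames)), pnames)
      })
      out
    }, numeric(length(pnames)))
  })
  boots <- matrix(boots, nrow = length(pnames))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- apply(boots, 1, stats::quantile, probs = probs, na.rm = TRUE,
              names = FALSE)
  fit$ci_lower <- stats::setNames(pmin(ci[1, ], fit$params), pnames)
  fit$ci_upper <- stats::setNames(pmax(ci[2, ], fit$params), pnames)
  fit$n_boot <- as.integer(n_boot)
  fit$seed <- seed
  fit
}
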