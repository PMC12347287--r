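test_that("noise-free 1:1 diagrams return the generating Kc", {
  for (p in list(resv_la_params(), la_params(),
                 binding_params("1:1", cmc0 = 70, kc = 7557))) {
    d <- noise_free_diagram(p)
    fit <- fit_binding_1to1(d)
    expect_equal(fit$params[["kc"]], p$kc, tolerance = 1e-6)
    expect_equal(fit$cmc0, p$cmc0)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("a flat diagram gives Kc = 0 with undefined R-squared", {
  d <- micellar_diagram(cd_levels_1to1(), rep(6, 5))
  fit <- fit_binding_1to1(d)
  expect_equal(fit$params[["kc"]], 0)
  expect_true(is.na(fit$r_squared))
  expect_true(any(grepl("flat diagram", fit$warnings)))
})

test_that("a decreasing diagram warns and clamps Kc to zero", {
  d <- micellar_diagram(cd_levels_1to1(), c(6, 5.5, 5, 4.2, 3))
  fit <- fit_binding_1to1(d)
  expect_equal(fit$params[["kc"]], 0)
  expect_true(any(grepl("CMC decreases with CD", fit$warnings)))
})

test_that("noise-free 1:2 diagrams return the generating (K1, K2)", {
  d <- noise_free_diagram(resv_dha_params())
  fit <- fit_binding_1to2(d)
  expect_equal(fit$params[["k1"]], 17, tolerance = 1e-4)
  expect_equal(fit$params[["k2"]], 0.18, tolerance = 1e-4)
  # nested reduction: linear truth gives k2 ~ 0 and k1 equal to the 1:1 Kc
  dl <- noise_free_diagram(resv_la_params())
  fit2 <- fit_binding_1to2(dl)
  expect_lt(abs(fit2$params[["k2"]]), 1e-8)
  expect_equal(fit2$params[["k1"]],
               fit_binding_1to1(dl)$params[["kc"]], tolerance = 1e-6)
  # too few levels for two free constants
  d3 <- micellar_diagram(c(0, 0.005, 0.01), cmc_1to1(6, 720, c(0, 0.005, 0.01)))
  expect_error(fit_binding_1to2(d3), class = "micellr_input_error")
})

test_that("the freed-CMC0 variant also recovers generating parameters", {
  d <- noise_free_diagram(resv_la_params())
  fit <- fit_binding_1to1(d, cmc0_source = "fitted")
  expect_equal(fit$cmc0, 6, tolerance = 1e-6)
  expect_equal(fit$params[["kc"]], 720, tolerance = 1e-4)
  d2 <- noise_free_diagram(resv_dha_params())
  fit2 <- fit_binding_1to2(d2, cmc0_source = "fitted")
  expect_equal(fit2$cmc0, 0.001, tolerance = 1e-4)
  expect_equal(fit2$params[["k1"]], 17, tolerance = 1e-3)
})

test_that("the 1:2 SSE never exceeds the 1:1 SSE on the same diagram", {
  for (i in 1:10) {
    d <- simulate_diagram(resv_la_params(), cd_levels_1to2(),
                          noise_cv = 0.05, seed = 1000 + i)
    expect_lte(fit_binding_1to2(d)$sse, fit_binding_1to1(d)$sse * (1 + 1e-10))
  }
})

test_that("stoichiometry selection returns the generating model on clean data", {
  s1 <- select_stoichiometry(noise_free_diagram(resv_la_params()))
  expect_identical(s1$model, "1:1")
  curved <- binding_params("1:2", cmc0 = 0.001, k1 = 17, k2 = 5)
  s2 <- select_stoichiometry(noise_free_diagram(curved, cd_levels_1to2()))
  expect_identical(s2$model, "1:2")
  expect_lt(s2$selection$f_pvalue, 0.05)
  # diagnostics of both models travel with the decision
  expect_s3_class(s2$selection$alternative, "binding_fit")
  expect_identical(s2$selection$alternative$model, "1:1")
})

test_that("selection converges on the generating model as noise shrinks", {
  curved <- binding_params("1:2", cmc0 = 0.001, k1 = 17, k2 = 5)
  rate_at <- function(params, cv, n = 60, seed0 = 5000) {
    picks <- vapply(seq_len(n), function(i) {
      d <- simulate_diagram(params, cd_levels_1to2(), noise_cv = cv,
                            seed = seed0 + i)
      select_stoichiometry(d)$model
    }, character(1))
    mean(picks == params$model)
  }
  rates1 <- vapply(c(0.02, 0.01, 0.005), function(cv)
    rate_at(resv_la_params(), cv), numeric(1))
  rates2 <- vapply(c(0.02, 0.01, 0.005), function(cv)
    rate_at(curved, cv), numeric(1))
  expect_gte(rates1[3], 0.9)
  expect_gte(rates2[3], 0.9)
  expect_true(all(diff(rates2) >= -0.1))  # non-degrading as cv drops
})

test_that("bootstrap intervals are deterministic, bracket the estimate, and collapse when exact", {
  d <- simulate_diagram(resv_la_params(), cd_levels_1to2(), noise_cv = 0.05,
                        seed = 31)
  fit <- fit_binding_1to1(d)
  b1 <- bootstrap_binding(fit, d, n_boot = 200, seed = 7)
  b2 <- bootstrap_binding(fit, d, n_boot = 200, seed = 7)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$ci_upper, b2$ci_upper)
  expect_lte(b1$ci_lower[["kc"]], fit$params[["kc"]])
  expect_gte(b1$ci_upper[["kc"]], fit$params[["kc"]])
  expect_lt(b1$ci_lower[["kc"]], b1$ci_upper[["kc"]])
  # noise-free diagram: degenerate residuals collapse the interval
  d0 <- noise_free_diagram(resv_la_params())
  f0 <- fit_binding_1to1(d0)
  b0 <- bootstrap_binding(f0, d0, n_boot = 100, seed = 1)
  expect_equal(unname(b0$ci_lower[["kc"]]), unname(b0$ci_upper[["kc"]]))
  expect_true(any(grepl("degenerate residuals", b0$warnings)))
  expect_error(bootstrap_binding(fit, d, n_boot = 50, seed = 1),
               class = "micellr_input_error")
  expect_error(bootstrap_binding(fit, d, n_boot = 200),
               class = "micellr_input_error")
})

test_that("bootstrap intervals cover the generating Kc at roughly nominal rate", {
  hits <- vapply(1:60, function(i) {
    d <- simulate_diagram(resv_la_params(), cd_levels_1to2(),
                          noise_cv = 0.05, seed = 9000 + i)
    b <- bootstrap_binding(fit_binding_1to1(d), d, n_boot = 199,
                           seed = 100 + i)
    b$ci_lower[["kc"]] <= 720 && 720 <= b$ci_upper[["kc"]]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("diagram construction validates its anchor and ordering", {
  expect_error(micellar_diagram(c(0.001, 0.005, 0.01), c(7, 10, 14)),
               class = "micellr_input_error")  # no zero-CD anchor
  expect_error(micellar_diagram(c(0, 0.005, 0.005), c(6, 10, 10)),
               class = "micellr_input_error")  # duplicate level
  d <- micellar_diagram(c(0.01, 0, 0.005), c(49.2, 6, 27.6))
  expect_equal(d$cd_conc, c(0, 0.005, 0.01))  # sorted on construction
  expect_equal(d$cmc, c(6, 27.6, 49.2))
})

test_that("diagrams assemble from breakpoint batches with unit bookkeeping", {
  bp <- resv_la_params()
  cds <- cd_levels_1to1()
  curves <- lapply(seq_along(cds), function(i) {
    simulate_titration(bp, cd_conc = cds[i], post_slope = 8, noise_sd = 0,
                       seed = i, guest = "Resv-4'-LA")
  })
  fits <- estimate_cmc_batch(curves)
  d <- build_diagram(fits)
  expect_equal(d$cd_conc, cds)
  expect_equal(d$cmc, cmc_1to1(6, 720, cds), tolerance = 1e-6)
  # shuffled input produces the identical diagram
  d2 <- build_diagram(unclass(fits)[c(3, 1, 5, 2, 4)])
  expect_equal(d2$cd_conc, d$cd_conc)
  expect_equal(d2$cmc, d$cmc)
  # failed fits are dropped with a warning; losing the anchor is an error
  flat_err <- tryCatch(estimate_cmc(titration_curve(1:10, rep(5, 10))),
                       micellr_error = function(e) e)
  expect_warning(d3 <- build_diagram(c(unclass(fits), list(flat_err))),
                 "dropping")
  expect_equal(d3$cmc, d$cmc)
  expect_error(suppressWarnings(build_diagram(c(unclass(fits)[-1], list(flat_err)))),
               class = "micellr_input_error")
})
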