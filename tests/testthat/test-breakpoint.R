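test_that("noise-free two-segment curves are recovered exactly", {
  # linear grid: breakpoint at 6 uM, flat baseline, steep rise
  cur <- simulate_titration(resv_la_params(), cd_conc = 0, post_slope = 8,
                            noise_sd = 0, seed = 1)
  fit <- estimate_cmc(cur)
  expect_s3_class(fit, "breakpoint_fit")
  expect_equal(fit$cmc, 6, tolerance = 1e-9)
  expect_gt(fit$post_slope, fit$pre_slope)
  expect_gte(fit$n_pre, 3)
  expect_gte(fit$n_post, 3)
  # sloped baseline
  cur2 <- simulate_titration(resv_la_params(), cd_conc = 0.005,
                             post_slope = 8, baseline_slope = 0.2,
                             noise_sd = 0, seed = 2)
  expect_equal(estimate_cmc(cur2)$cmc, 27.6, tolerance = 1e-7)
  # nanomolar CMC: log-axis route
  cur3 <- simulate_titration(resv_dha_params(), cd_conc = 0.01,
                             post_slope = 30, noise_sd = 0, seed = 3)
  fit3 <- estimate_cmc(cur3)
  expect_identical(fit3$scale, "log")
  expect_equal(fit3$cmc, cmc_1to2(0.001, 17, 0.18, 0.01), tolerance = 1e-7)
})

test_that("randomized noise-free generator/estimator round trips recover the breakpoint", {
  specs <- withr::with_seed(20250801, {
    lapply(1:20, function(i) {
      list(cmc0 = 10^stats::runif(1, -3, 1.5),
           kc = stats::runif(1, 0, 2000),
           cd = stats::runif(1, 0, 0.01),
           post = stats::runif(1, 4, 20),
           base = stats::runif(1, 0, 0.5))
    })
  })
  for (s in specs) {
    cur <- simulate_titration(binding_params("1:1", s$cmc0, kc = s$kc),
                              cd_conc = s$cd, post_slope = s$post,
                              baseline_slope = s$base, noise_sd = 0, seed = 7)
    truth <- attr(cur, "true_cmc")
    expect_equal(estimate_cmc(cur)$cmc, truth, tolerance = 1e-6)
  }
})

test_that("degenerate curves raise classed errors", {
  cond <- cmc_condition()
  flat <- titration_curve(1:10, rep(5, 10), condition = cond)
  expect_error(estimate_cmc(flat), class = "micellr_flat_signal_error")
  expect_error(titration_curve(1:5, c(1, 2, 3, 4, 5)),
               class = "micellr_input_error")
  # a single declining line has no slope break: no micellization called
  down <- titration_curve(1:12, 50 - 1 * (1:12))
  expect_error(estimate_cmc(down), class = "micellr_no_micellization_error")
})

test_that("breakpoint estimate is scale-equivariant and offset-invariant", {
  cur <- simulate_titration(resv_la_params(), cd_conc = 0.0025,
                            post_slope = 8, noise_sd = 1.5, seed = 11)
  base <- estimate_cmc(cur)$cmc
  for (c_mult in c(0.1, 3, 40)) {
    scaled <- titration_curve(cur$data$conc * c_mult, cur$data$fluorescence,
                              replicate = cur$data$replicate,
                              cd_conc = cur$cd_conc, condition = cur$condition)
    expect_equal(estimate_cmc(scaled, scale = "linear")$cmc, base * c_mult,
                 tolerance = 1e-9)
  }
  shifted <- titration_curve(cur$data$conc, cur$data$fluorescence + 37.5,
                             replicate = cur$data$replicate,
                             cd_conc = cur$cd_conc, condition = cur$condition)
  expect_equal(estimate_cmc(shifted)$cmc, base, tolerance = 1e-9)
})

test_that("replicates are fitted jointly and duplication changes nothing", {
  cur <- simulate_titration(resv_la_params(), cd_conc = 0, post_slope = 8,
                            noise_sd = 2, n_replicates = 1, seed = 13)
  fit1 <- estimate_cmc(cur)
  dup <- titration_curve(rep(cur$data$conc, 2), rep(cur$data$fluorescence, 2),
                         replicate = rep(1:2, each = nrow(cur$data)),
                         cd_conc = cur$cd_conc, condition = cur$condition)
  fit2 <- estimate_cmc(dup)
  expect_equal(fit2$cmc, fit1$cmc, tolerance = 1e-12)
  expect_equal(fit2$pre_slope, fit1$pre_slope, tolerance = 1e-12)
  expect_equal(fit2$post_slope, fit1$post_slope, tolerance = 1e-12)
})

test_that("batch estimation preserves order, isolates failures, and validates inputs", {
  bp <- resv_la_params()
  cds <- cd_levels_1to1()
  curves <- lapply(seq_along(cds), function(i) {
    simulate_titration(bp, cd_conc = cds[i], post_slope = 8, noise_sd = 0,
                       seed = i, guest = "Resv-4'-LA")
  })
  fits <- estimate_cmc_batch(curves)
  expect_length(fits, 5)
  got <- vapply(unclass(fits), `[[`, numeric(1), "cmc")
  expect_equal(got, cmc_1to1(6, 720, cds), tolerance = 1e-6)
  # empty batch is vacuous
  expect_length(estimate_cmc_batch(list()), 0)
  # a flat curve is reported in place, not fatal
  flat <- titration_curve(1:10, rep(5, 10), cd_conc = 0.02,
                          guest = "Resv-4'-LA")
  mixed <- estimate_cmc_batch(c(curves, list(flat)))
  expect_length(mixed, 6)
  expect_s3_class(mixed[[6]], "condition")
  expect_s3_class(mixed[[1]], "breakpoint_fit")
  # mixed guests or duplicate CD levels are input errors
  other <- titration_curve(1:10, c(1, 1, 1, 1, 2, 4, 6, 8, 10, 12),
                           cd_conc = 0.05, guest = "DHA")
  expect_error(estimate_cmc_batch(c(curves, list(other))),
               class = "micellr_input_error")
  expect_error(estimate_cmc_batch(c(curves, curves[1])),
               class = "micellr_input_error")
})

test_that("per-curve bootstrap attaches a deterministic cmc_se", {
  cur <- simulate_titration(resv_la_params(), cd_conc = 0, post_slope = 8,
                            noise_sd = 2, seed = 17)
  f1 <- estimate_cmc(cur, n_boot = 100, seed = 99)
  f2 <- estimate_cmc(cur, n_boot = 100, seed = 99)
  expect_identical(f1$cmc_se, f2$cmc_se)
  expect_gt(f1$cmc_se, 0)
  expect_error(estimate_cmc(cur, n_boot = 100), class = "micellr_input_error")
})
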