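test_that("noise-free titrations lie exactly on the piecewise-linear model", {
  cur <- simulate_titration(resv_la_params(), cd_conc = 0.005, post_slope = 8,
                            baseline_level = 20, noise_sd = 0, seed = 1,
                            n_replicates = 1)
  expect_equal(attr(cur, "true_cmc"), 27.6)  # 6 * (1 + 720 * 0.005)
  d <- cur$data
  pre <- d$conc <= 27.6
  expect_true(all(abs(d$fluorescence[pre] - 20) < 1e-12))
  expect_equal(d$fluorescence[!pre], 20 + 8 * (d$conc[!pre] - 27.6),
               tolerance = 1e-12)
})

test_that("titration simulation is seed-deterministic and seed-sensitive", {
  args <- list(binding = resv_la_params(), cd_conc = 0, post_slope = 8,
               noise_sd = 2)
  a <- do.call(simulate_titration, c(args, seed = 42))
  b <- do.call(simulate_titration, c(args, seed = 42))
  c_ <- do.call(simulate_titration, c(args, seed = 43))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data$fluorescence, c_$data$fluorescence))
  expect_error(do.call(simulate_titration, args),
               class = "micellr_input_error")
})

test_that("a breakpoint outside the sampled range is rejected", {
  expect_error(
    simulate_titration(resv_la_params(), cd_conc = 0, post_slope = 8,
                       conc_grid = seq(10, 30, length.out = 12),
                       noise_sd = 0, seed = 1),
    class = "micellr_spec_error")
  expect_error(
    simulate_titration(resv_la_params(), cd_conc = 0, post_slope = 1,
                       baseline_slope = 2, noise_sd = 0, seed = 1),
    class = "micellr_spec_error")
})

test_that("diagram simulation matches hand-evaluated skeletons", {
  # 0.001 * (1 + 17 cd + 17*0.18 cd^2) at cd = 0, 0.01, 0.05, 0.1 M
  d <- simulate_diagram(resv_dha_params(), c(0, 0.01, 0.05, 0.1),
                        noise_cv = 0)
  expect_equal(d$cmc, c(0.001, 0.001170306, 0.00185765, 0.0027306),
               tolerance = 1e-9)
  # two seeds: same skeleton, different realizations
  d1 <- simulate_diagram(resv_la_params(), cd_levels_1to1(),
                         noise_cv = 0.05, seed = 1)
  d2 <- simulate_diagram(resv_la_params(), cd_levels_1to1(),
                         noise_cv = 0.05, seed = 2)
  expect_identical(attr(d1, "true_cmc"), attr(d2, "true_cmc"))
  expect_false(identical(d1$cmc, d2$cmc))
  expect_identical(simulate_diagram(resv_la_params(), cd_levels_1to1(),
                                    noise_cv = 0.05, seed = 1)$cmc, d1$cmc)
})

test_that("estimated-CMC dispersion grows with titration noise", {
  sd_at <- function(noise_sd) {
    ests <- vapply(1:60, function(i) {
      cur <- simulate_titration(resv_la_params(), cd_conc = 0, post_slope = 8,
                                noise_sd = noise_sd, seed = 3000 + i)
      # slope_tol_mult = 0: this test measures dispersion, not detection
      estimate_cmc(cur, slope_tol_mult = 0)$cmc
    }, numeric(1))
    stats::sd(ests)
  }
  sds <- vapply(c(1, 3, 5), sd_at, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("condition presets carry the reported constants and build valid params", {
  pre <- condition_presets()
  ref <- pre[pre$guest == "Resv-4'-LA" & pre$ph == 7 &
               pre$temperature == 35 & pre$medium == "PBS_100mM", ]
  expect_equal(ref$cmc0, 6)
  expect_equal(ref$kc, 720)
  dha <- pre[pre$guest == "Resv-4'-DHA" & pre$ph == 7 &
               pre$temperature == 35 & pre$medium == "PBS_100mM", ]
  expect_equal(c(dha$k1, dha$k2), c(17, 0.18))
  acid <- pre[pre$guest == "Resv-4'-LA" & pre$ph == 2, ]
  expect_equal(acid$kc, 4264)
  # every preset row builds simulable parameters
  for (i in seq_len(nrow(pre))) {
    p <- preset_params(pre[i, ])
    expect_s3_class(p, "binding_params")
    expect_gt(predict_cmc(p, 0.01), p$cmc0 - 1e-15)
  }
  # 1:1 rows carry kc only, 1:2 rows carry k1/k2 only
  expect_true(all(is.na(pre$k1[pre$model == "1:1"])))
  expect_true(all(is.na(pre$kc[pre$model == "1:2"])))
})
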