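# shared fixtures built in code

la_params <- function() binding_params("1:1", cmc0 = 43, kc = 7432)
resv_la_params <- function() binding_params("1:1", cmc0 = 6, kc = 720)
resv_dha_params <- function() binding_params("1:2", cmc0 = 0.001,
                                             k1 = 17, k2 = 0.18)

cd_levels_1to1 <- function() c(0, 1, 2.5, 5, 10) / 1000
cd_levels_1to2 <- function() c(0, 5, 10, 25, 50, 100) / 1000

noise_free_diagram <- function(params, cd = NULL) {
  if (is.null(cd)) {
    cd <- if (params$model == "1:1") cd_levels_1to1() else cd_levels_1to2()
  }
  simulate_diagram(params, cd, noise_cv = 0)
}

# independent mass-action oracle: solve for the free-guest fraction from
# total balance g * (1 + K1 c + K1 K2 c^2) = 1 by root finding
species_oracle <- function(k1, k2, cd_free) {
  g <- stats::uniroot(function(g) g * (1 + k1 * cd_free + k1 * k2 * cd_free^2) - 1,
                      c(0, 1), tol = 1e-14)$root
  c(free = g, complex_1_1 = k1 * cd_free * g,
    complex_1_2 = k1 * k2 * cd_free^2 * g)
}
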