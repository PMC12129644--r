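test_that("bound fraction inverts the fast-exchange average", {
  # p-cresol at 200 g/L: (79 - 7) / (79 - 2) in 1e-11 units
  expect_equal(bound_fraction(79e-11, 2.0e-11, 7.0e-11), 72 / 77,
               tolerance = 1e-12)
  expect_equal(bound_fraction(79e-11, 2.0e-11, 79e-11), 0)
  expect_equal(bound_fraction(79e-11, 2.0e-11, 2.0e-11), 1)
})

test_that("bound fraction clamps small overshoots and rejects large ones", {
  # d_obs slightly above d_free: raw p just below 0
  expect_warning(p <- bound_fraction(79e-11, 2e-11, 79.5e-11),
                 class = "soludiff_clamped")
  expect_equal(p, 0)
  expect_error(bound_fraction(79e-11, 2e-11, 90e-11),
               class = "soludiff_inconsistent_inputs")
  expect_error(bound_fraction(2e-11, 79e-11, 7e-11),
               class = "soludiff_degenerate_model")
})

test_that("fast-exchange round trip is exact", {
  set.seed(42)
  for (i in 1:100) {
    d_free <- runif(1, 5e-10, 1e-9)
    d_mic <- runif(1, 1e-11, 1e-10)
    p_true <- runif(1)
    d_obs <- p_true * d_mic + (1 - p_true) * d_free
    expect_equal(bound_fraction(d_free, d_mic, d_obs), p_true,
                 tolerance = 1e-12)
  }
})

test_that("bound fraction is strictly decreasing in the observed D", {
  d_obs <- seq(2.5e-11, 78e-11, length.out = 25)
  p <- bound_fraction(79e-11, 2e-11, d_obs)
  expect_true(all(diff(p) < 0))
})

test_that("partition coefficient is p/(1-p), increasing and convex", {
  expect_equal(partition_coefficient(0.5), 1)
  expect_equal(partition_coefficient(0), 0)
  p <- seq(0.05, 0.95, by = 0.05)
  K <- partition_coefficient(p)
  expect_true(all(diff(K) > 0))
  expect_true(all(diff(diff(K)) > 0))
  expect_error(partition_coefficient(1), class = "soludiff_infinite_partition")
  expect_error(partition_coefficient(1.2), class = "soludiff_domain_error")
})

test_that("molar solubilization ratio reproduces the reference arithmetic", {
  # p-cresol at 200 g/L: p = 72/77, 5 g/L solute, M = 108.14, M_surf = 650
  cfg <- series_config("p-cresol")
  msr <- molar_solubilization_ratio(72 / 77, 200, cfg)
  expect_equal(round(100 * msr), 14)
  expect_equal(msr, (72 / 77) * (5 / 108.14) / ((200 - 0.4) / 650),
               tolerance = 1e-12)
  expect_equal(molar_solubilization_ratio(0, 200, cfg), 0)
  cfg_ph <- series_config("phenol")
  expect_equal(round(100 * molar_solubilization_ratio(0.8324, 200, cfg_ph)), 14)
  expect_error(molar_solubilization_ratio(0.5, 0.3, cfg),
               class = "soludiff_no_micellar_phase")
})

test_that("MSR is linear in p and invariant under mass-unit rescaling", {
  cfg <- series_config("phenol")
  p <- seq(0, 1, by = 0.1)
  msr <- molar_solubilization_ratio(p, 50, cfg)
  expect_equal(msr, p * msr[11], tolerance = 1e-12)
  # rescale g/L -> mg/L on every mass concentration
  cfg_mg <- series_config("phenol", c_sol = 5e3, cmc = 0.4e3)
  expect_equal(molar_solubilization_ratio(0.6, 50e3, cfg_mg),
               molar_solubilization_ratio(0.6, 50, cfg), tolerance = 1e-12)
})

test_that("series analysis reproduces the packaged p-cresol ladder", {
  tab <- read_d_table(rl_phenol_d_table())
  res <- analyze_series(tab[tab$species == "p-cresol", ],
                        series_config("p-cresol"))
  expect_true(is.na(res$p[1]))  # no micelle D at the lowest concentration
  printed <- c(49, 68, 83, 93)  # reference p (%) for C >= 25 g/L
  got <- 100 * res$p[res$concentration_g_per_L >= 25]
  expect_true(all(abs(got - printed) <= 1))
  # resorcinol at 200 g/L rounds to exactly 69%
  res_r <- analyze_series(tab[tab$species == "resorcinol", ],
                          series_config("resorcinol"))
  expect_equal(round(100 * res_r$p[res_r$concentration_g_per_L == 200]), 69)
})

test_that("rows at or below the CMC yield null results", {
  cfg <- series_config("phenol")
  tab <- data.frame(concentration_g_per_L = c(0.2, 10),
                    D_obs_m2s = c(91e-11, 70e-11),
                    D_mic_m2s = c(8e-11, 8e-11))
  res <- analyze_series(tab, cfg)
  expect_true(is.na(res$p[1]) && is.na(res$K_m[1]) && is.na(res$MSR[1]))
  expect_false(is.na(res$p[2]))
})

test_that("explicit free-D override changes low-concentration fractions", {
  tab <- read_d_table(rl_phenol_d_table())
  pc <- tab[tab$species == "p-cresol", ]
  default_res <- analyze_series(pc, series_config("p-cresol"))
  override <- analyze_series(pc, series_config("p-cresol", d_free = 82e-11))
  i <- which(default_res$concentration_g_per_L == 3.12)
  expect_gt(override$p[i], default_res$p[i])
})

test_that("formatted output follows the integer reporting convention", {
  tab <- read_d_table(rl_phenol_d_table())
  res <- analyze_series(tab[tab$species == "hydroquinone", ],
                        series_config("hydroquinone"))
  fmt <- format_series(res)
  expect_named(fmt, c("solute", "C_RL_g_per_L", "D_S_1e11", "D_mic_1e11",
                      "p_percent", "Km_percent", "MSR_x100"))
  last <- fmt[fmt$C_RL_g_per_L == 200, ]
  expect_equal(last$D_S_1e11, 33)
  expect_true(last$p_percent == round(100 * res$p[res$concentration_g_per_L == 200]))
})
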