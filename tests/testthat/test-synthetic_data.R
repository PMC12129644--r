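test_that("the default scenario matches the packaged concentration series", {
  sc <- default_scenario(seed = 1)
  expect_length(sc$species, 6)
  expect_equal(sc$concentrations,
               c(1.56, 3.12, 6.25, 12.5, 25, 50, 100, 200))
  # p-cresol truth at 200 g/L is the two-state value of its D ladder
  pc <- sc$species[["p-cresol"]]
  expect_equal(pc$p[8], 72 / 77, tolerance = 1e-12)
  expect_equal(pc$d_free, 79e-11, tolerance = 1e-12)
  for (sp in sc$species) {
    expect_true(all(sp$d_mic < sp$d_free))
    expect_true(all(diff(sp$p) >= 0))
    expect_true(all(sp$p >= 0 & sp$p <= 1))
    expect_equal(sp$p[1], 0)  # self-consistent with the lowest-C free-D policy
  }
})

test_that("equal seeds give byte-identical scenarios and decays", {
  a <- default_scenario(seed = 123, noise_sigma = 0.02)
  b <- default_scenario(seed = 123, noise_sigma = 0.02)
  expect_identical(jsonlite::toJSON(soludiff:::scenario_to_list(a), digits = NA),
                   jsonlite::toJSON(soludiff:::scenario_to_list(b), digits = NA))
  expect_identical(simulate_solubilizate_decay(a, "phenol", 50)$A,
                   simulate_solubilizate_decay(b, "phenol", 50)$A)
  expect_identical(simulate_surfactant_decay(a, 50, "phenol")$A,
                   simulate_surfactant_decay(b, 50, "phenol")$A)
})

test_that("noiseless solubilizate decays obey the fast-exchange average", {
  sc <- default_scenario(seed = 1, noise_sigma = 0)
  # p-cresol at 200 g/L: p * D_mic + (1 - p) * D_free = 7.0e-11 exactly
  dc <- simulate_solubilizate_decay(sc, "p-cresol", 200)
  expect_equal(attr(dc, "truth")$d_obs, 7.0e-11, tolerance = 1e-12)
  for (sp in c("phenol", "hydroquinone")) {
    for (C in c(12.5, 200)) {
      d <- simulate_solubilizate_decay(sc, sp, C)
      truth <- attr(d, "truth")
      expect_equal(fit_monoexp(d)$components$D,
                   truth$p * truth$d_mic + (1 - truth$p) * truth$d_free,
                   tolerance = 1e-9)
    }
  }
})

test_that("noiseless surfactant decays round-trip the micelle component", {
  sc <- default_scenario(seed = 1, noise_sigma = 0)
  dc <- simulate_surfactant_decay(sc, 200, "hydroquinone")
  fit <- fit_biexp(dc)
  mic <- assign_micelle_component(fit)
  expect_equal(mic$D, 2.9e-11, tolerance = 0.01)
  expect_equal(mic$fraction, 0.88, tolerance = 0.01)
  # below the CMC a single monomer component is generated
  tr <- species_truth("x", 8e-10, c(0.2, 5), c(6e-11, 5e-11), c(0, 0.4))
  sc2 <- scenario(seed = 2, species = list(tr), noise_sigma = 0)
  low <- simulate_surfactant_decay(sc2, 0.2, "x")
  expect_equal(fit_monoexp(low)$components$D, sc2$rl_monomer_D,
               tolerance = 1e-9)
})

test_that("a zero impurity fraction gives an effectively mono-exponential decay", {
  tr <- species_truth("x", 8e-10, c(5, 50), c(6e-11, 4e-11), c(0.2, 0.5),
                      impurity_fraction = 0)
  sc <- scenario(seed = 3, species = list(tr), noise_sigma = 0)
  dc <- simulate_surfactant_decay(sc, 50, "x")
  fit <- suppressWarnings(fit_biexp(dc))
  expect_true(fit$ill_conditioned)
  expect_equal(fit$components$D[1], 4e-11, tolerance = 0.01)
})

test_that("noise realizations are independent across curves but reproducible", {
  sc <- default_scenario(seed = 9, noise_sigma = 0.01)
  noiseless <- default_scenario(seed = 9, noise_sigma = 0)
  eps <- function(sp, C) {
    simulate_solubilizate_decay(sc, sp, C)$A -
      simulate_solubilizate_decay(noiseless, sp, C)$A
  }
  e1 <- eps("phenol", 50)
  e2 <- eps("phenol", 100)
  e3 <- eps("guaiacol", 50)
  expect_false(isTRUE(all.equal(e1, e2)))
  expect_false(isTRUE(all.equal(e1, e3)))
  expect_lt(abs(stats::cor(e1, e2)), 0.75)
  expect_identical(e1, eps("phenol", 50))
})

test_that("gradient grids hit the requested total attenuation", {
  pp <- std_params()
  comp <- exp_components(c(0.12, 0.88), c(7.6e-11, 2.9e-11))
  g <- gradient_grid(pp, comp, n = 16, attenuation = 12)
  expect_length(g, 16)
  expect_equal(g[1], 0)
  atten <- echo_amplitude(1, comp, b_factor(pp, max(g)))
  expect_equal(atten, 1 / 12, tolerance = 1e-9)
})

test_that("fixtures round-trip through disk with stable checksums", {
  sc <- default_scenario(seed = 4, noise_sigma = 0.01)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture(sc, d1)
  m2 <- write_fixture(sc, d2)
  # 6 species x 8 concentrations x {solubilizate, surfactant} + 2 JSON files
  expect_equal(nrow(m1), 6 * 8 * 2 + 2)
  expect_equal(m1$md5, m2$md5)
  dc <- read_decay_csv(file.path(d1, "solubilizate_phenol_C50.csv"),
                       label = "phenol", concentration = 50)
  ref <- simulate_solubilizate_decay(sc, "phenol", 50)
  expect_equal(dc$A, ref$A, tolerance = 1e-10)
  expect_equal(dc$g, ref$g, tolerance = 1e-10)
  expect_equal(dc$params$Delta, ref$params$Delta, tolerance = 1e-12)
  # ground truth serializes losslessly
  sc2 <- read_truth_json(file.path(d1, "truth.json"))
  expect_equal(simulate_solubilizate_decay(sc2, "phenol", 50)$A, ref$A,
               tolerance = 1e-12)
})
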