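#' Ground-truth description of one solubilizate species
#'
#' Holds everything needed to simulate a species' decays across a surfactant
#' concentration series: the free-solution diffusion coefficient, the
#' micelle diffusion coefficient at each concentration, the true bound
#' fraction at each concentration, and the fast impurity component of the
#' surfactant methylene signal (free fatty-acid residues).
#'
#' @param name Species name.
#' @param d_free Free-solution diffusion coefficient, m\eqn{^2}/s.
#' @param concentrations Surfactant concentrations, g/L; strictly increasing.
#' @param d_mic Micelle diffusion coefficients at each concentration,
#'   m\eqn{^2}/s; each below `d_free`.
#' @param p True bound fractions at each concentration; non-decreasing,
#'   in \[0, 1\].
#' @param impurity_fraction Population fraction of the fast impurity
#'   component in the surfactant decay, in \[0, 1).
#' @param impurity_D Impurity diffusion coefficient, m\eqn{^2}/s.
#' @return An object of class `species_truth`.
#' @export
species_truth <- function(name, d_free, concentrations, d_mic, p,
                          impurity_fraction = 0.12, impurity_D = 7.6e-11) {
  if (!is_number(d_free) || d_free <= 0) {
    stop_soludiff("'d_free' must be a single positive number", "parameter_error")
  }
  k <- length(concentrations)
  if (k < 1L || length(d_mic) != k || length(p) != k) {
    stop_soludiff("'concentrations', 'd_mic' and 'p' must have equal length",
                  "parameter_error")
  }
  if (any(diff(concentrations) <= 0)) {
    stop_soludiff("'concentrations' must be strictly increasing", "parameter_error")
  }
  if (any(d_mic <= 0) || any(d_mic >= d_free)) {
    stop_soludiff("'d_mic' must be positive and below 'd_free'", "parameter_error")
  }
  if (any(p < 0) || any(p > 1) || any(diff(p) < -1e-12)) {
    stop_soludiff("'p' must be non-decreasing within [0, 1]", "parameter_error")
  }
  if (!is_number(impurity_fraction) || impurity_fraction < 0 ||
      impurity_fraction >= 1 || !is_number(impurity_D) || impurity_D <= 0) {
    stop_soludiff("invalid impurity component", "parameter_error")
  }
  structure(
    list(name = name, d_free = d_free,
         concentrations = as.numeric(concentrations),
         d_mic = as.numeric(d_mic), p = as.numeric(p),
         impurity_fraction = impurity_fraction, impurity_D = impurity_D),
    class = "species_truth"
  )
}

truth_at <- function(truth, C) {
  i <- which(abs(truth$concentrations - C) < 1e-9)
  if (length(i) != 1L) {
    stop_soludiff(sprintf("concentration %g g/L not in the scenario for '%s'",
                          C, truth$name), "lookup_error")
  }
  list(d_mic = truth$d_mic[i], p = truth$p[i],
       d_obs = truth$p[i] * truth$d_mic[i] + (1 - truth$p[i]) * truth$d_free)
}

#' Construct a synthetic solubilization scenario
#'
#' @param seed Integer RNG seed; every simulated curve derives its own
#'   sub-seed from this, the species name and the concentration, so adding a
#'   curve never perturbs the noise of the others.
#' @param species A list of [species_truth()] objects.
#' @param noise_sigma Relative Gaussian amplitude noise (fraction of the
#'   zero-gradient amplitude) added independently per point.
#' @param grid_n Number of gradient points per curve (>= 8).
#' @param attenuation Target total attenuation at the strongest gradient;
#'   the default 12 honours the working rule of at least 10-fold echo decay.
#' @param params A [pulse_params()] object; the default uses 1 ms
#'   rectangular gradient pulses with a 50 ms diffusion time.
#' @param cmc CMC used for the surfactant decay regime switch, g/L.
#' @param rl_monomer_D Monomeric surfactant diffusion coefficient used below
#'   the CMC, m\eqn{^2}/s.
#' @param A0 Nominal zero-gradient amplitude before relaxation losses.
#' @return An object of class `scenario`.
#' @seealso [default_scenario()]
#' @export
scenario <- function(seed, species, noise_sigma = 0.01, grid_n = 16L,
                     attenuation = 12,
                     params = pulse_params(delta = 1e-3, t_d = 0.05,
                                           tau = 5e-3, tau1 = NULL,
                                           T1 = 0.5, T2 = 0.2),
                     cmc = 0.4, rl_monomer_D = 8e-10, A0 = 100) {
  if (!is_number(seed)) stop_soludiff("'seed' must be a number", "parameter_error")
  if (!is.list(species) || !length(species) ||
      !all(vapply(species, inherits, logical(1), "species_truth"))) {
    stop_soludiff("'species' must be a list of species_truth objects",
                  "parameter_error")
  }
  if (!is_number(noise_sigma) || noise_sigma < 0) {
    stop_soludiff("'noise_sigma' must be non-negative", "parameter_error")
  }
  grid_n <- as.integer(grid_n)
  if (grid_n < 8L) stop_soludiff("'grid_n' must be at least 8", "parameter_error")
  if (!is_number(attenuation) || attenuation <= 1) {
    stop_soludiff("'attenuation' must exceed 1", "parameter_error")
  }
  names(species) <- vapply(species, `[[`, character(1), "name")
  structure(
    list(seed = as.integer(seed), species = species,
         concentrations = species[[1]]$concentrations,
         noise_sigma = noise_sigma,
         grid = list(n = grid_n, attenuation = attenuation),
         params = params, cmc = cmc, rl_monomer_D = rl_monomer_D, A0 = A0),
    class = "scenario"
  )
}

# Default pulse parameters for simulation: tau = 5 ms, tau1 = Delta - tau.
default_params <- function() {
  delta <- 1e-3
  Delta <- 0.05 + delta / 3
  pulse_params(delta = delta, tau = 5e-3, tau1 = Delta - 5e-3,
               T1 = 0.5, T2 = 0.2, shape = "rectangular")
}

#' Default rhamnolipid/phenol scenario
#'
#' Builds a six-species scenario whose diffusion-coefficient ladders copy the
#' packaged rhamnolipid/phenol concentration series
#' (`inst/extdata/table1_diffusion.csv`): eight surfactant concentrations
#' from 1.56 to 200 g/L, per-species free and micellar diffusion
#' coefficients, and a 12%-population fast impurity component
#' (D = 7.6e-11 m\eqn{^2}/s) in the surfactant methylene decay.
#'
#' The truth is made self-consistent with the default free-D policy of
#' [analyze_series()]: the bound fraction at the lowest tabulated
#' concentration is zero, so the observed D there *is* the free-solution D.
#' Dashed (missing) micelle-D entries at the lowest concentrations are
#' filled from the nearest higher-concentration value for simulation
#' purposes only.
#'
#' @param seed Integer RNG seed.
#' @param noise_sigma Relative amplitude noise, fraction of A0 (default 0.01,
#'   consistent with the 3-5% uncertainty typical of the measured D values).
#' @param ... Further arguments passed to [scenario()].
#' @return A [scenario()] with six species.
#' @examples
#' sc <- default_scenario(seed = 1, noise_sigma = 0)
#' names(sc$species)
#' @export
default_scenario <- function(seed = 1L, noise_sigma = 0.01, ...) {
  tab <- read_d_table(system.file("extdata", "table1_diffusion.csv",
                                  package = "soludiff"))
  species <- lapply(split(tab, tab$species), function(df) {
    df <- df[order(df$concentration_g_per_L), , drop = FALSE]
    d_free <- df$D_obs_m2s[1]
    d_mic <- df$D_mic_m2s
    # back-fill leading NA micelle entries from the nearest measured value
    for (i in rev(seq_len(nrow(df) - 1L))) {
      if (is.na(d_mic[i])) d_mic[i] <- d_mic[i + 1L]
    }
    p <- (d_free - df$D_obs_m2s) / (d_free - d_mic)
    p <- pmin(pmax(p, 0), 1)
    p <- cummax(p)  # guard against rounding-induced non-monotonicity
    species_truth(df$species[1], d_free, df$concentration_g_per_L, d_mic, p)
  })
  # keep the conventional ordering of the packaged series
  order_ref <- unique(tab$species)
  scenario(seed = seed, species = species[order_ref],
           noise_sigma = noise_sigma, ...)
}

# Deterministic 31-bit sub-seed from the scenario seed and a curve key,
# via a polynomial string hash (platform-independent).
sub_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer((h + (seed %% 2147483629) * 7919) %% 2147483629)
}

add_noise <- function(A, A0, sigma, seed_i) {
  if (sigma <= 0) return(A)
  A + withr::with_seed(seed_i, rnorm(length(A))) * sigma * A0
}

#' Gradient grid reaching a target total attenuation
#'
#' Returns `n` gradient amplitudes linear in g from 0 to the value at which
#' the summed component attenuation \eqn{\sum_i p_i e^{-b D_i}} reaches
#' `1/attenuation`, emulating the working rule of choosing the maximum
#' gradient for at least 10-fold echo decay.
#'
#' @param params A [pulse_params()] object.
#' @param components Component table (`fraction`, `D`) from
#'   [exp_components()].
#' @param n Number of points.
#' @param attenuation Target fold-attenuation at the strongest gradient.
#' @return Gradient amplitudes, T/m.
#' @export
gradient_grid <- function(params, components, n = 16L, attenuation = 12) {
  components <- exp_components(components$fraction, components$D)
  target <- 1 / attenuation
  f <- function(b) sum(components$fraction * exp(-b * components$D)) - target
  # strictly negative at the upper bracket even when all D coincide
  b_up <- 1.01 * log(attenuation) / min(components$D)
  b_max <- uniroot(f, c(0, b_up), tol = 1e-12 * b_up)$root
  g_max <- sqrt(b_max / b_factor(params, 1))
  seq(0, g_max, length.out = n)
}

#' Simulate a solubilizate diffusion decay
#'
#' Under fast exchange the solubilizate decay is mono-exponential at the
#' population-weighted diffusion coefficient
#' \eqn{D_{obs} = p D_{mic} + (1-p) D_{free}}. Amplitudes carry the
#' relaxation prefactor and, when `noise_sigma > 0`, independent Gaussian
#' noise of standard deviation `noise_sigma * A0` per point, seeded
#' deterministically from (scenario seed, species, concentration).
#'
#' @param sc A [scenario()].
#' @param species Species name present in the scenario.
#' @param C Surfactant concentration, g/L; must be one of the scenario's
#'   concentrations.
#' @return A [decay_curve()] with the simulated truth attached as attribute
#'   `"truth"` (`d_obs`, `p`, `d_mic`, `d_free`).
#' @export
simulate_solubilizate_decay <- function(sc, species, C) {
  stopifnot(inherits(sc, "scenario"))
  truth <- sc$species[[species]]
  if (is.null(truth)) {
    stop_soludiff(sprintf("unknown species '%s'", species), "lookup_error")
  }
  at <- truth_at(truth, C)
  comp <- exp_components(1, at$d_obs)
  g <- gradient_grid(sc$params, comp, sc$grid$n, sc$grid$attenuation)
  A0_eff <- sc$A0 * relaxation_prefactor(sc$params)
  A <- echo_amplitude(A0_eff, comp, b_factor(sc$params, g))
  A <- add_noise(A, A0_eff, sc$noise_sigma,
                 sub_seed(sc$seed, sprintf("solubilizate|%s|%.6g", species, C)))
  out <- decay_curve(g, A, sc$params, label = species, concentration = C)
  attr(out, "truth") <- list(d_obs = at$d_obs, p = at$p, d_mic = at$d_mic,
                             d_free = truth$d_free)
  out
}

#' Simulate a surfactant methylene diffusion decay
#'
#' Above the CMC the methylene-proton decay is bi-exponential: a majority
#' micelle component plus a minor fast component from free fatty-acid
#' residues. Below the CMC a single monomeric component is used. Noise and
#' seeding are as in [simulate_solubilizate_decay()].
#'
#' @param sc A [scenario()].
#' @param C Surfactant concentration, g/L.
#' @param species Solute system whose micelle-D ladder is used (micelle
#'   diffusion coefficients differ slightly between solute systems);
#'   defaults to the scenario's first species.
#' @return A [decay_curve()] with attribute `"truth"` (the component table).
#' @export
simulate_surfactant_decay <- function(sc, C, species = names(sc$species)[1]) {
  stopifnot(inherits(sc, "scenario"))
  truth <- sc$species[[species]]
  if (is.null(truth)) {
    stop_soludiff(sprintf("unknown species '%s'", species), "lookup_error")
  }
  if (C > sc$cmc) {
    at <- truth_at(truth, C)
    if (truth$impurity_fraction > 0) {
      comp <- exp_components(c(truth$impurity_fraction, 1 - truth$impurity_fraction),
                             c(truth$impurity_D, at$d_mic))
    } else {
      comp <- exp_components(1, at$d_mic)
    }
  } else {
    comp <- exp_components(1, sc$rl_monomer_D)
  }
  g <- gradient_grid(sc$params, comp, sc$grid$n, sc$grid$attenuation)
  A0_eff <- sc$A0 * relaxation_prefactor(sc$params)
  A <- echo_amplitude(A0_eff, comp, b_factor(sc$params, g))
  A <- add_noise(A, A0_eff, sc$noise_sigma,
                 sub_seed(sc$seed, sprintf("surfactant|%s|%.6g", species, C)))
  out <- decay_curve(g, A, sc$params, label = "surfactant", concentration = C)
  attr(out, "truth") <- comp
  out
}

scenario_to_list <- function(sc) {
  list(
    seed = sc$seed, noise_sigma = sc$noise_sigma,
    grid = sc$grid, cmc = sc$cmc, rl_monomer_D = sc$rl_monomer_D, A0 = sc$A0,
    params = unclass(sc$params),
    species = lapply(sc$species, unclass)
  )
}

scenario_from_list <- function(x) {
  pp <- x$params
  params <- pulse_params(delta = pp$delta, tau = pp$tau, tau1 = pp$tau1,
                         gamma = pp$gamma, T1 = pp$T1, T2 = pp$T2,
                         shape = pp$shape)
  species <- lapply(x$species, function(s) {
    species_truth(s$name, s$d_free, s$concentrations, s$d_mic, s$p,
                  s$impurity_fraction, s$impurity_D)
  })
  scenario(seed = x$seed, species = unname(species),
           noise_sigma = x$noise_sigma, grid_n = x$grid$n,
           attenuation = x$grid$attenuation, params = params,
           cmc = x$cmc, rl_monomer_D = x$rl_monomer_D, A0 = x$A0)
}

safe_name <- function(species, C) {
  sprintf("%s_C%s", gsub("[^A-Za-z0-9]+", "-", species),
          gsub("\\.", "p", format(C)))
}

#' Write a scenario to disk as a plain-text fixture
#'
#' Writes one decay CSV (`g_T_per_m`, `amplitude`) per (species,
#' concentration) pair for both the solubilizate and the surfactant signal,
#' a pulse-parameter sidecar JSON, the full ground truth as JSON, and a
#' manifest of all files with MD5 checksums. Re-running with the same
#' scenario reproduces identical files.
#'
#' @param sc A [scenario()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_fixture <- function(sc, dir) {
  stopifnot(inherits(sc, "scenario"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_soludiff(paste0("cannot create directory ", dir), "io_error")
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
             error = function(e) stop_soludiff(
               paste0("failed writing ", path, ": ", conditionMessage(e)),
               "io_error"))
    files <<- c(files, name)
  }
  for (sp in names(sc$species)) {
    for (C in sc$species[[sp]]$concentrations) {
      sol <- simulate_solubilizate_decay(sc, sp, C)
      wr(data.frame(g_T_per_m = sol$g, amplitude = sol$A),
         paste0("solubilizate_", safe_name(sp, C), ".csv"))
      surf <- simulate_surfactant_decay(sc, C, species = sp)
      wr(data.frame(g_T_per_m = surf$g, amplitude = surf$A),
         paste0("surfactant_", safe_name(sp, C), ".csv"))
    }
  }
  pp <- sc$params
  jsonlite::write_json(
    list(gamma = pp$gamma, delta_s = pp$delta, Delta_s = pp$Delta,
         tau_s = pp$tau, tau1_s = pp$tau1, T1_s = pp$T1, T2_s = pp$T2,
         shape = pp$shape),
    file.path(dir, "pulse_params.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, "pulse_params.json")
  jsonlite::write_json(scenario_to_list(sc), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "truth.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}

#' Read a scenario ground-truth JSON back into a scenario object
#'
#' @param path Path to a `truth.json` written by [write_fixture()].
#' @return A [scenario()].
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) {
    stop_soludiff(paste0("no such file: ", path), "io_error")
  }
  scenario_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
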