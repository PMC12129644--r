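#' Molar masses of common phenolic solubilizates
#'
#' Built-in molar masses (g/mol) computed from atomic masses for the six
#' phenols the package's default scenarios cover. Overridable via
#' [series_config()].
#'
#' @param solute Solute name; one of `"phenol"`, `"p-cresol"`, `"guaiacol"`,
#'   `"pyrocatechol"`, `"resorcinol"`, `"hydroquinone"`.
#' @return Molar mass, g/mol.
#' @export
phenol_molar_mass <- function(solute) {
  masses <- c(
    "phenol" = 94.11, "p-cresol" = 108.14, "guaiacol" = 124.14,
    "pyrocatechol" = 110.11, "resorcinol" = 110.11, "hydroquinone" = 110.11
  )
  if (!is.character(solute) || length(solute) != 1L || !solute %in% names(masses)) {
    stop_soludiff(
      paste0("unknown solute '", solute, "'; supply 'm_sol' explicitly or use one of: ",
             paste(names(masses), collapse = ", ")),
      "config_error")
  }
  unname(masses[[solute]])
}

#' Micelle-bound fraction from the two-state fast-exchange model
#'
#' Under fast exchange between the free aqueous state and the micelle-bound
#' state, the observed solubilizate diffusion coefficient is the
#' population-weighted average
#' \deqn{D_{obs} = p\,D_{mic} + (1 - p)\,D_{free},}
#' which inverts to
#' \deqn{p = \frac{D_{free} - D_{obs}}{D_{free} - D_{mic}}.}
#'
#' Measurement noise can push the raw ratio slightly outside \[0, 1\]; an
#' overshoot of at most `tol` is clamped with a warning, anything beyond is
#' an error (inconsistent inputs).
#'
#' @param d_free Solubilizate diffusion coefficient without micelles,
#'   m\eqn{^2}/s.
#' @param d_mic Micelle diffusion coefficient, m\eqn{^2}/s
#'   (`d_mic < d_free`).
#' @param d_obs Observed solubilizate diffusion coefficient(s),
#'   m\eqn{^2}/s; vectorised.
#' @param tol Permitted overshoot outside \[0, 1\] before erroring
#'   (default 0.05).
#' @return Bound fraction(s) in \[0, 1\].
#' @examples
#' bound_fraction(79e-11, 2.0e-11, 7.0e-11) # ~0.935
#' @export
bound_fraction <- function(d_free, d_mic, d_obs, tol = 0.05) {
  if (!is_number(d_free) || !is_number(d_mic) || d_free <= 0 || d_mic <= 0) {
    stop_soludiff("'d_free' and 'd_mic' must be single positive numbers",
                  "parameter_error")
  }
  if (d_free <= d_mic) {
    stop_soludiff("'d_free' must exceed 'd_mic' (two-state model degenerate)",
                  "degenerate_model")
  }
  if (!is.numeric(d_obs) || any(!is.finite(d_obs)) || any(d_obs <= 0)) {
    stop_soludiff("'d_obs' must be positive and finite", "parameter_error")
  }
  p <- (d_free - d_obs) / (d_free - d_mic)
  if (any(p < -tol) || any(p > 1 + tol)) {
    stop_soludiff(
      sprintf("bound fraction %.3f outside [%.2f, %.2f]: D values inconsistent with the two-state model",
              p[which.max(abs(p - 0.5))], -tol, 1 + tol),
      "inconsistent_inputs")
  }
  if (any(p < 0) || any(p > 1)) {
    warn_soludiff("bound fraction slightly outside [0, 1]; clamped", "clamped")
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' Micelle-water partition coefficient
#'
#' The mole ratio of micelle-bound to aqueous-phase solubilizate,
#' \eqn{K_m = p / (1 - p)}. Dimensionless; conventionally reported as a
#' percentage (multiply by 100) at the output boundary.
#'
#' @param p Bound fraction(s) in \[0, 1).
#' @return \eqn{K_m}, dimensionless.
#' @export
partition_coefficient <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_soludiff("'p' must lie in [0, 1]", "domain_error")
  }
  if (any(p == 1)) {
    stop_soludiff("p = 1 implies an infinite partition coefficient",
                  "infinite_partition")
  }
  p / (1 - p)
}

#' Molar solubilization ratio
#'
#' Moles of solubilizate in micelles per mole of micellized surfactant:
#' \deqn{MSR = \frac{p\,C_{sol}/M_{sol}}{(C_{surf} - CMC)/M_{surf}},}
#' with all concentrations converted to molarity. Invariant under a common
#' rescaling of the mass-concentration units.
#'
#' @param p Bound fraction(s) in \[0, 1\].
#' @param c_surf Surfactant mass concentration(s), g/L; must exceed `cmc`.
#' @param cfg A [series_config()] supplying `c_sol`, `m_sol`, `m_surf`
#'   and `cmc`.
#' @return MSR, dimensionless (reported as MSR x 100 at the output boundary).
#' @examples
#' cfg <- series_config("p-cresol")
#' molar_solubilization_ratio(0.935, 200, cfg) # ~0.141
#' @export
molar_solubilization_ratio <- function(p, c_surf, cfg) {
  stopifnot(inherits(cfg, "series_config"))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_soludiff("'p' must lie in [0, 1]", "domain_error")
  }
  if (!is.numeric(c_surf) || any(!is.finite(c_surf)) || any(c_surf <= cfg$cmc)) {
    stop_soludiff("'c_surf' must exceed the CMC (no micellar phase otherwise)",
                  "no_micellar_phase")
  }
  (p * cfg$c_sol / cfg$m_sol) / ((c_surf - cfg$cmc) / cfg$m_surf)
}

#' Configuration of a solubilization concentration series
#'
#' @param solute Solute name (used for molar-mass lookup and labelling).
#' @param c_sol Solute mass concentration, g/L (default 5).
#' @param m_sol Solute molar mass, g/mol; looked up with
#'   [phenol_molar_mass()] when `NULL`.
#' @param m_surf Surfactant molar mass, g/mol (default 650, rhamnolipid).
#' @param cmc Critical micelle concentration, g/L (default 0.4).
#' @param d_free Explicit free-solute diffusion coefficient, m\eqn{^2}/s;
#'   when `NULL` (the default policy) the observed D at the lowest
#'   concentration of the series is used. Bound fractions at low
#'   concentrations are sensitive to this choice.
#' @return An object of class `series_config`.
#' @export
series_config <- function(solute, c_sol = 5, m_sol = NULL, m_surf = 650,
                          cmc = 0.4, d_free = NULL) {
  if (is.null(m_sol)) m_sol <- phenol_molar_mass(solute)
  for (v in c(c_sol = c_sol, m_sol = m_sol, m_surf = m_surf, cmc = cmc)) {
    if (!is_number(v) || v <= 0) {
      stop_soludiff("concentrations and molar masses must be positive",
                    "config_error")
    }
  }
  if (!is.null(d_free) && (!is_number(d_free) || d_free <= 0)) {
    stop_soludiff("'d_free' must be a positive number (m2/s) or NULL",
                  "config_error")
  }
  structure(
    list(solute = solute, c_sol = c_sol, m_sol = m_sol, m_surf = m_surf,
         cmc = cmc, d_free = d_free),
    class = "series_config"
  )
}

#' Solubilization analysis of a concentration series
#'
#' For each surfactant concentration, inverts the two-state fast-exchange
#' relation to the bound fraction `p`, then derives the micelle-water
#' partition coefficient and the molar solubilization ratio. The free-solute
#' diffusion coefficient is taken from `cfg$d_free`, or by default from the
#' lowest-concentration row of the table. Rows at or below the CMC, or with
#' no micelle diffusion coefficient, yield `NA` results.
#'
#' @param d_table Data frame with columns `concentration_g_per_L`,
#'   `D_obs_m2s` and `D_mic_m2s` (SI units; see [read_d_table()] for the
#'   CSV convention in 1e-11 m2/s).
#' @param cfg A [series_config()].
#' @return A data frame of class `solubilization_series`, ordered by
#'   concentration, with columns `solute`, `concentration_g_per_L`,
#'   `D_obs_m2s`, `D_mic_m2s`, `D_free_m2s`, `p`, `K_m` and `MSR`
#'   (full precision; see [format_series()] for reporting-style rounding).
#' @examples
#' tab <- read_d_table(system.file("extdata", "table1_diffusion.csv",
#'                                 package = "soludiff"))
#' res <- analyze_series(tab[tab$species == "p-cresol", ], series_config("p-cresol"))
#' round(100 * res$p)
#' @export
analyze_series <- function(d_table, cfg) {
  stopifnot(inherits(cfg, "series_config"))
  need <- c("concentration_g_per_L", "D_obs_m2s", "D_mic_m2s")
  if (!is.data.frame(d_table) || !all(need %in% names(d_table))) {
    stop_soludiff(paste("'d_table' must contain columns:",
                        paste(need, collapse = ", ")), "data_error")
  }
  if (nrow(d_table) < 1L) {
    stop_soludiff("'d_table' has no rows", "data_error")
  }
  d_table <- d_table[order(d_table$concentration_g_per_L), , drop = FALSE]
  d_free <- cfg$d_free
  if (is.null(d_free)) {
    d_free <- d_table$D_obs_m2s[1]
    if (!is.finite(d_free) || d_free <= 0) {
      stop_soludiff("cannot resolve D_free from the lowest-concentration row",
                    "config_error")
    }
  }
  n <- nrow(d_table)
  p <- K <- msr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    C <- d_table$concentration_g_per_L[i]
    d_mic <- d_table$D_mic_m2s[i]
    d_obs <- d_table$D_obs_m2s[i]
    if (C <= cfg$cmc || is.na(d_mic) || is.na(d_obs)) next
    p[i] <- bound_fraction(d_free, d_mic, d_obs)
    K[i] <- if (p[i] < 1) p[i] / (1 - p[i]) else Inf
    msr[i] <- molar_solubilization_ratio(p[i], C, cfg)
  }
  out <- data.frame(
    solute = cfg$solute,
    concentration_g_per_L = d_table$concentration_g_per_L,
    D_obs_m2s = d_table$D_obs_m2s,
    D_mic_m2s = d_table$D_mic_m2s,
    D_free_m2s = d_free,
    p = p, K_m = K, MSR = msr
  )
  class(out) <- c("solubilization_series", "data.frame")
  out
}

#' Reporting-style rounding of a solubilization series
#'
#' Converts a full-precision [analyze_series()] result to the conventional
#' reporting units: diffusion coefficients in 1e-11 m2/s, bound fraction and
#' partition coefficient as integer percent, MSR as integer MSR x 100.
#'
#' @param series A `solubilization_series` from [analyze_series()].
#' @param digits `NULL` for the integer reporting convention; otherwise the
#'   number of decimal places kept on the percent/x100 scales.
#' @return A data frame with columns `solute`, `C_RL_g_per_L`, `D_S_1e11`,
#'   `D_mic_1e11`, `p_percent`, `Km_percent`, `MSR_x100`.
#' @export
format_series <- function(series, digits = NULL) {
  stopifnot(inherits(series, "solubilization_series"))
  rnd <- function(x) if (is.null(digits)) round(x) else round(x, digits)
  data.frame(
    solute = series$solute,
    C_RL_g_per_L = series$concentration_g_per_L,
    D_S_1e11 = series$D_obs_m2s * 1e11,
    D_mic_1e11 = series$D_mic_m2s * 1e11,
    p_percent = rnd(100 * series$p),
    Km_percent = rnd(100 * series$K_m),
    MSR_x100 = rnd(100 * series$MSR)
  )
}
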