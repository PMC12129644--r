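#' Point-selection window for decay fitting
#'
#' Surfactant methylene decays are fitted on restricted windows: below the
#' CMC only the initial section carries the population-averaged slope; above
#' the CMC the initial points are contaminated by fast impurity components
#' (free fatty-acid residues) and are dropped.
#'
#' @param mode `"all"`, `"initial"` (keep the leading points) or `"tail"`
#'   (drop the leading points).
#' @param n_points For `"initial"`, the minimum number of leading points to
#'   keep (the window extends further if attenuation is still under 2-fold);
#'   for `"tail"`, the number of leading points to drop. Must leave >= 3
#'   usable points.
#' @return An object of class `fit_window`.
#' @export
fit_window <- function(mode = c("all", "initial", "tail"), n_points = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_points)) {
    n_points <- switch(mode, all = NA_integer_, initial = 5L, tail = 3L)
  }
  if (mode != "all") {
    n_points <- as.integer(n_points)
    if (!is.finite(n_points) || (mode == "initial" && n_points < 3L) ||
        (mode == "tail" && n_points < 0L)) {
      stop_soludiff("invalid 'n_points' for this window mode", "window_error")
    }
  }
  structure(list(mode = mode, n_points = n_points), class = "fit_window")
}

# Indices of the points a window selects on a given curve.
window_indices <- function(decay, window) {
  n <- length(decay$g)
  idx <- switch(window$mode,
    all = seq_len(n),
    initial = {
      # extend past n_points while total attenuation is still < 2-fold
      within2 <- which(decay$A >= decay$A[1] / 2)
      k <- if (length(within2)) max(window$n_points, max(within2)) else window$n_points
      seq_len(min(k, n))
    },
    tail = if (window$n_points >= n) integer(0) else seq.int(window$n_points + 1L, n)
  )
  if (length(idx) < 3L) {
    stop_soludiff("window selects fewer than 3 points", "window_error")
  }
  idx
}

#' Window strategy for surfactant decays around the CMC
#'
#' Below (or at) the CMC the initial section of the methylene-proton decay is
#' fitted, so that all surfactant fractions contribute to the apparent slope;
#' above the CMC the initial section is excluded to suppress the fast
#' impurity component.
#'
#' @param concentration Surfactant concentration, g/L.
#' @param cmc Critical micelle concentration, g/L (> 0).
#' @param initial_n,tail_drop Window sizes passed to [fit_window()].
#' @return A [fit_window()]: `"initial"` when `concentration <= cmc`,
#'   otherwise `"tail"`.
#' @export
choose_window <- function(concentration, cmc, initial_n = 5L, tail_drop = 3L) {
  if (!is_number(cmc) || cmc <= 0) {
    stop_soludiff("'cmc' must be a single positive number (g/L)", "parameter_error")
  }
  if (!is_number(concentration) || concentration < 0) {
    stop_soludiff("'concentration' must be a single non-negative number (g/L)",
                  "parameter_error")
  }
  if (concentration <= cmc) {
    fit_window("initial", initial_n)
  } else {
    fit_window("tail", tail_drop)
  }
}

new_decay_fit <- function(components, A0, stderr, rss, window, n_used,
                          method, ill_conditioned = FALSE) {
  components <- components[order(-components$fraction), , drop = FALSE]
  rownames(components) <- NULL
  structure(
    list(components = components, A0 = A0, stderr = stderr, rss = rss,
         window = window, n_used = n_used, method = method,
         ill_conditioned = ill_conditioned),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%s fit (%d points, window '%s'), A0 = %.4g, rss = %.4g\n",
              x$method, x$n_used, x$window$mode, x$A0, x$rss))
  with(x$components, for (i in seq_along(D)) {
    cat(sprintf("  component %d: fraction %.3f, D = %.3g e-11 m2/s\n",
                i, fraction[i], D[i] * 1e11))
  })
  if (x$ill_conditioned) cat("  (ill-conditioned: components poorly separated)\n")
  invisible(x)
}

#' Mono-exponential decay fit (log-linear)
#'
#' Fits a straight line to \eqn{(b, \ln A)} over the selected window by
#' weighted least squares (weights \eqn{A^2}, the inverse variance of
#' \eqn{\ln A} under constant-amplitude noise). The negated slope is the
#' apparent self-diffusion coefficient.
#'
#' @param decay A [decay_curve()].
#' @param window A [fit_window()]; default fits all points.
#' @return A `decay_fit` with one component. `stderr` holds the linear-fit
#'   standard errors of `A0` and `D`; `rss` is the residual sum of squares in
#'   amplitude space (comparable with [fit_biexp()]).
#' @examples
#' pp <- pulse_params(delta = 1e-3, t_d = 0.05)
#' g <- seq(0, 1, length.out = 8)
#' dc <- decay_curve(g, 100 * exp(-b_factor(pp, g) * 7e-11), pp)
#' fit_monoexp(dc)$components$D
#' @export
fit_monoexp <- function(decay, window = fit_window("all")) {
  stopifnot(inherits(decay, "decay_curve"), inherits(window, "fit_window"))
  idx <- window_indices(decay, window)
  b <- decay_b(decay)[idx]
  A <- decay$A[idx]
  if (any(A <= 0)) {
    stop_soludiff("non-positive amplitudes in fit window (log undefined)",
                  "data_error")
  }
  fit <- lm(log(A) ~ b, weights = A^2)
  cf <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  A0 <- exp(cf[[1]])
  D <- -cf[[2]]
  if (D <= 0) {
    warn_soludiff("non-positive apparent diffusion coefficient", "fit_warning")
  }
  pred <- A0 * exp(-b * D)
  new_decay_fit(
    components = data.frame(fraction = 1, D = D),
    A0 = A0,
    stderr = c(A0 = A0 * se[[1]], D = se[[2]]),
    rss = sum((A - pred)^2),
    window = window, n_used = length(idx), method = "monoexp"
  )
}

# Log-linear slope/intercept on a subset of points; NULL if unusable.
loglin <- function(b, A) {
  ok <- A > 0
  if (sum(ok) < 2L) return(NULL)
  cf <- tryCatch(coef(lm(log(A[ok]) ~ b[ok], weights = A[ok]^2)),
                 error = function(e) NULL)
  if (is.null(cf) || !all(is.finite(cf))) return(NULL)
  list(A0 = exp(cf[[1]]), D = -cf[[2]])
}

# Candidate starting values for the bi-exponential fit: a mono-exponential
# start first (guarantees rss never exceeds the mono fit), then exponential
# peeling at a deterministic set of head/tail splits.
biexp_starts <- function(b, A) {
  n <- length(b)
  mono <- loglin(b, A)
  if (is.null(mono)) mono <- list(A0 = A[1], D = log(2) / max(b[b > 0]))
  Dm <- max(mono$D, 1e-16)
  # near-mono start first (keeps the fit well-behaved on effectively
  # single-exponential data), then generic two-component splits
  starts <- list(
    list(A0 = mono$A0, p1 = 0.999, D1 = Dm, D2 = Dm / 3),
    list(A0 = mono$A0, p1 = 0.3, D1 = 3 * Dm, D2 = Dm / 3),
    list(A0 = mono$A0, p1 = 0.7, D1 = 3 * Dm, D2 = Dm / 3)
  )
  splits <- unique(round(seq(3L, n - 3L, length.out = min(8L, max(1L, n - 5L)))))
  for (k in splits) {
    tail_fit <- loglin(b[(k + 1L):n], A[(k + 1L):n])
    if (is.null(tail_fit) || tail_fit$D <= 0) next
    resid_head <- A[1:k] - tail_fit$A0 * exp(-b[1:k] * tail_fit$D)
    head_fit <- loglin(b[1:k][resid_head > 0], resid_head[resid_head > 0])
    if (is.null(head_fit) || head_fit$D <= 0) {
      head_fit <- list(A0 = max(A[1] - tail_fit$A0, 0.05 * A[1]), D = 4 * Dm)
    }
    A0 <- head_fit$A0 + tail_fit$A0
    p1 <- min(max(head_fit$A0 / A0, 0.02), 0.98)
    starts[[length(starts) + 1L]] <-
      list(A0 = A0, p1 = p1, D1 = head_fit$D, D2 = tail_fit$D)
  }
  starts
}

#' Bi-exponential decay fit
#'
#' Nonlinear least squares of
#' \eqn{A(b) = A_0 [p_1 e^{-b D_1} + (1 - p_1) e^{-b D_2}]} in amplitude
#' space with unit weights, under the constraints \eqn{p_1 \in [0, 1]},
#' \eqn{D_i > 0}. Starting values come from exponential peeling at a
#' deterministic ladder of head/tail splits (plus a mono-exponential start);
#' the best residual sum of squares is kept, so the fit is reproducible
#' without a random seed and its `rss` never exceeds the mono-exponential
#' fit's.
#'
#' @param decay A [decay_curve()] with >= 6 positive amplitudes.
#' @return A `decay_fit` with two components sorted by descending fraction.
#'   When the two components are poorly separated (diffusion coefficients
#'   within a factor 1.5, or a vanishing minor fraction) the fit is flagged
#'   `ill_conditioned` and a warning is issued.
#' @export
fit_biexp <- function(decay) {
  stopifnot(inherits(decay, "decay_curve"))
  b <- decay_b(decay)
  A <- decay$A
  if (length(b) < 6L) {
    stop_soludiff("bi-exponential fit needs at least 6 points", "data_error")
  }
  if (any(A <= 0)) {
    stop_soludiff("bi-exponential fit needs positive amplitudes", "data_error")
  }
  bmax <- max(b)
  bs <- b / bmax                     # O(1) abscissa for the optimiser
  model <- function(par) par[1] * (par[2] * exp(-bs * par[3]) +
                                     (1 - par[2]) * exp(-bs * par[4]))
  residfun <- function(par) A - model(par)
  lower <- c(0, 0, 1e-8, 1e-8)
  upper <- c(Inf, 1, 1e6, 1e6)
  best <- NULL
  diagnostics <- character(0)
  for (st in biexp_starts(b, A)) {
    par0 <- c(st$A0, st$p1, max(st$D1 * bmax, 1e-8), max(st$D2 * bmax, 1e-8))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = residfun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$deviance < best$deviance * (1 - 1e-10)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop_soludiff(paste0("bi-exponential fit failed to converge from any start: ",
                         paste(unique(diagnostics), collapse = "; ")),
                  "fit_error")
  }
  cf <- best$par
  D1 <- cf[3] / bmax
  D2 <- cf[4] / bmax
  p1 <- cf[2]
  # covariance-based standard errors; NA when the Jacobian is singular
  # (e.g. a fraction pinned at its bound)
  se <- tryCatch({
    sig2 <- best$deviance / (length(A) - 4L)
    sqrt(diag(solve(best$hessian)) * sig2)
  }, error = function(e) rep(NA_real_, 4))
  comp <- data.frame(fraction = c(p1, 1 - p1), D = c(D1, D2))
  ill <- max(D1, D2) / min(D1, D2) < 1.5 || min(p1, 1 - p1) < 0.02
  if (ill) {
    warn_soludiff(
      "bi-exponential components poorly separated; data may be effectively mono-exponential",
      "ill_conditioned")
  }
  new_decay_fit(
    components = comp, A0 = cf[1],
    stderr = c(A0 = unname(se[1]), p1 = unname(se[2]),
               D1 = unname(se[3]) / bmax, D2 = unname(se[4]) / bmax),
    rss = best$deviance, window = fit_window("all"), n_used = length(b),
    method = "biexp", ill_conditioned = ill
  )
}

#' Assign the micelle component of a two-component fit
#'
#' In a surfactant methylene decay above the CMC, the micellar surfactant
#' carries the large majority of the signal while fatty-acid impurity
#' residues contribute a minor component; the micelle is therefore taken as
#' the larger-fraction component. When the fractions are within 0.05 of each
#' other the slower (smaller-D) component is chosen and a warning is issued.
#'
#' @param fit A two-component `decay_fit` from [fit_biexp()].
#' @return A one-row component data frame (`fraction`, `D`).
#' @export
assign_micelle_component <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  comp <- fit$components
  if (nrow(comp) != 2L) {
    stop_soludiff("micelle assignment requires a two-component fit",
                  "assignment_error")
  }
  if (abs(comp$fraction[1] - comp$fraction[2]) < 0.05) {
    warn_soludiff(
      "component fractions nearly equal; assigning the slower component as micelle",
      "assignment_tie")
    comp <- comp[order(comp$D), , drop = FALSE]
  }
  # components are stored sorted by descending fraction
  out <- comp[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}
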