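#' Inhibited-oxidation experiment container
#'
#' Raw observations of one inhibited radical-chain oxidation experiment:
#' initial oxidation rates at a series of inhibitor concentrations and,
#' optionally, induction periods at the same or other concentrations,
#' together with the experiment constants.
#'
#' @param v0 Uninhibited oxidation rate (mol L^-1 s^-1).
#' @param vi Initiation rate (mol L^-1 s^-1).
#' @param k6 Recombination rate constant of the chain-carrying peroxyl
#'   radicals (L mol^-1 s^-1).
#' @param points data.frame with columns `inh_conc` (mol L^-1) and `v`
#'   (inhibited rate, mol L^-1 s^-1); may be NULL.
#' @param tau_points data.frame with columns `inh_conc` and `tau`
#'   (induction period, s); may be NULL.
#' @return Object of class `ao_inhibition_experiment`.
#' @export
inhibition_experiment <- function(v0, vi, k6, points = NULL,
                                  tau_points = NULL) {
  stopifnot(v0 > 0, vi > 0, k6 > 0)
  if (!is.null(points)) {
    stopifnot(all(c("inh_conc", "v") %in% names(points)))
    if (any(points$inh_conc <= 0)) stop("inhibitor concentrations must be positive")
    if (anyDuplicated(points$inh_conc)) stop("inhibitor concentrations must be distinct")
    if (any(points$v <= 0 | points$v > v0)) {
      stop("invalid rate: every inhibited rate must satisfy 0 < v <= v0")
    }
  }
  if (!is.null(tau_points)) {
    stopifnot(all(c("inh_conc", "tau") %in% names(tau_points)))
    if (any(tau_points$inh_conc <= 0)) stop("inhibitor concentrations must be positive")
    if (any(tau_points$tau < 0)) stop("induction periods must be non-negative")
  }
  structure(list(v0 = v0, vi = vi, k6 = k6, points = points,
                 tau_points = tau_points),
            class = "ao_inhibition_experiment")
}

#' @export
print.ao_inhibition_experiment <- function(x, ...) {
  cat("<inhibition experiment> v0 =", format(x$v0), " vi =", format(x$vi),
      " k6 =", format(x$k6), "\n  ",
      if (is.null(x$points)) 0 else nrow(x$points), "rate points, ",
      if (is.null(x$tau_points)) 0 else nrow(x$tau_points), "tau points\n")
  invisible(x)
}

#' Inhibition parameter F
#'
#' `F = V0/V - V/V0`: zero without inhibition (V = V0) and strictly
#' decreasing in the inhibited rate V.
#'
#' @param v0 Uninhibited rate.
#' @param v Inhibited rate(s), `0 < v <= v0`.
#' @return Numeric vector of F values (>= 0).
#' @export
inhibition_parameter <- function(v0, v) {
  if (any(v <= 0 | v > v0)) stop("invalid rate: need 0 < v <= v0")
  v0 / v - v / v0
}

#' Effective chain-termination constant from initial rates
#'
#' The inhibition parameter F computed from the rate points is regressed
#' linearly on the inhibitor concentration (with an intercept, as a
#' linearity diagnostic); the steady-state relation
#' `F = fk7 [InH] / sqrt(2 k6 Vi)` turns the slope into
#' `fk7 = slope * sqrt(2 k6 Vi)`.
#'
#' @param exp An [inhibition_experiment()] with at least 3 rate points.
#' @return List: `slope_F` (L mol^-1), `intercept_F`, `fk7`
#'   (L mol^-1 s^-1), `r2_fit`. A non-positive slope yields `fk7 = 0`
#'   with a non-inhibitor warning; `r2_fit < 0.95` warns about
#'   nonlinearity.
#' @export
fit_fk7 <- function(exp) {
  if (is.null(exp$points) || nrow(exp$points) < 3) {
    stop("need at least 3 rate points")
  }
  Fv <- inhibition_parameter(exp$v0, exp$points$v)
  fit <- stats::lm(Fv ~ inh_conc, data = data.frame(inh_conc = exp$points$inh_conc))
  slope <- unname(coef(fit)[2])
  tss <- sum((Fv - mean(Fv))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  if (slope <= 0) {
    warning("non-positive slope of F vs [InH]: compound is not an inhibitor")
    fk7 <- 0
  } else {
    fk7 <- slope * sqrt(2 * exp$k6 * exp$vi)
    if (r2 < 0.95) warning("F vs [InH] deviates from linearity (R2 = ",
                           sprintf("%.3f", r2), ")")
  }
  list(slope_F = slope, intercept_F = unname(coef(fit)[1]), fk7 = fk7,
       r2_fit = r2)
}

#' Stoichiometric inhibition coefficient from induction periods
#'
#' Through-origin least squares of the induction period on the inhibitor
#' concentration (`tau = f [InH] / Vi` has no intercept);
#' `f = slope * Vi`.
#'
#' @param exp An [inhibition_experiment()] with at least 3 tau points.
#' @return The stoichiometric coefficient f (dimensionless).
#' @export
fit_f <- function(exp) {
  if (is.null(exp$tau_points) || nrow(exp$tau_points) < 3) {
    stop("need at least 3 induction-period points")
  }
  fit <- stats::lm(tau ~ inh_conc + 0, data = exp$tau_points)
  unname(coef(fit)[1]) * exp$vi
}

#' Termination rate constant from fk7 and f
#'
#' `k7 = fk7 / f`, with `lgk7 = log10(k7)`.
#'
#' @param fk7 Effective chain-termination constant (> 0).
#' @param f Stoichiometric inhibition coefficient (> 0).
#' @return List with `k7` and `lgk7`.
#' @export
compute_k7 <- function(fk7, f) {
  if (fk7 <= 0 || f <= 0) stop("fk7 and f must be positive")
  k7 <- fk7 / f
  list(k7 = k7, lgk7 = log10(k7))
}

#' Full kinetic analysis of an inhibition experiment
#'
#' Runs [fit_fk7()] on the rate points, [fit_f()] on the induction-period
#' points (if present) and combines them into k7 via [compute_k7()].
#'
#' @param exp An [inhibition_experiment()].
#' @return List of class `ao_inhibition_fit`: `slope_F`, `intercept_F`,
#'   `fk7`, `f`, `k7`, `lgk7`, `r2_fit`. `f`, `k7`, `lgk7` are NA when no
#'   induction-period data are available or the compound does not
#'   inhibit.
#' @export
fit_inhibition <- function(exp) {
  fkfit <- fit_fk7(exp)
  f <- if (!is.null(exp$tau_points) && nrow(exp$tau_points) >= 3) {
    fit_f(exp)
  } else NA_real_
  if (is.finite(f) && f > 0 && fkfit$fk7 > 0) {
    kk <- compute_k7(fkfit$fk7, f)
  } else {
    kk <- list(k7 = NA_real_, lgk7 = NA_real_)
  }
  structure(c(fkfit, list(f = f, k7 = kk$k7, lgk7 = kk$lgk7)),
            class = "ao_inhibition_fit")
}

#' @export
print.ao_inhibition_fit <- function(x, ...) {
  cat(sprintf("<inhibition fit> fk7 = %.4g  f = %.3g  k7 = %.4g  lgk7 = %.4g  (R2 = %.4f)\n",
              x$fk7, x$f, x$k7, x$lgk7, x$r2_fit))
  invisible(x)
}
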