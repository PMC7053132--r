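# Closed-form isocline approximations for the three interaction models,
# for overlay on numerical isoclines and fast exploration.  Scaling
# relations whose prefactors the theory leaves open carry explicit,
# calibratable constants (defaults 1) and are labelled "scaling".

#' Calibration constants for scaling-form isoclines
#'
#' @param epsilon Small positive exponent correction in the antibiotics
#'   composition isocline (its lower branch decays as
#'   `xbar_1^-(1 + epsilon)`).
#' @param C Additive constant in the pyoverdine composition isocline
#'   numerator `log|delta_alpha_1| + C`.
#' @param prefactors Named numeric vector of branch prefactors for the
#'   scaling relations (`ab_comp_top`, `ab_comp_low`, `pyo_comp`);
#'   defaults 1.
#' @return An object of class `scaling_constants`.
#' @export
scaling_constants <- function(epsilon = 0.1, C = NULL,
                              prefactors = c(ab_comp_top = 1,
                                             ab_comp_low = 1,
                                             pyo_comp = 1)) {
  if (epsilon < 0) stop("'epsilon' must be >= 0")
  structure(list(epsilon = epsilon, C = C, prefactors = prefactors),
            class = "scaling_constants")
}

#' Analytic isoclines for the metabolic trade-off (base interaction)
#'
#' Closed-form approximations for two strains with constant rates: the
#' population-size isocline is the tilted dilution line
#' `nbar*(x) = d*s0_phi*(1 + delta_phi_1*(2x - 1))`, and the composition
#' isocline is the near-vertical line
#' `nbar = |delta_phi_1/delta_alpha_1| / log(s0_phi)`.
#'
#' @param world A two-strain base-interaction [world_config()].
#' @return A list with `population` (function of `xbar_1`) and
#'   `composition_nbar` (a constant).
#' @export
tradeoff_isoclines <- function(world) {
  .check_two_strains(world)
  if (world$interaction$kind != "base")
    stop("tradeoff_isoclines() applies to the base interaction")
  ct <- .centered_traits(world)
  comp <- if (ct$da1 == 0) NA_real_ else
    abs(ct$dp1 / ct$da1) / log(ct$s_eff)
  if (ct$da1 == 0)
    warning("delta_alpha_1 = 0: composition isocline undefined (neutral growth)")
  list(population = function(x) ct$dsphi_eff * (1 + ct$dp1 * (2 * x - 1)),
       composition_nbar = comp)
}

#' Analytic isoclines for the antibiotics interaction
#'
#' The population isocline has two branches: the resource-limited dilution
#' line `d*s0_phi` and the antibiotics-limited branch
#' `(1/x) * kappa*gamma*(1 + delta_alpha_1) / ((1 + gamma)*rho_1) *
#' log(b0)^2`, set by the producer-density threshold for degrading the
#' antibiotic in time.  The composition isocline branches are scaling
#' relations: `~ 1/(1 - x)` (non-producer survival threshold, top) and
#' `~ (1/|delta_alpha_1|) * x^-(1 + epsilon)` (bottom), with calibratable
#' prefactors.
#'
#' @param world A two-strain antibiotics [world_config()] (strain 1 is the
#'   producer).
#' @param consts A [scaling_constants()].
#' @return A list of functions of `xbar_1`: `population_dilution`,
#'   `population_ab_limited`, `composition_top`, `composition_low`; the
#'   composition entries carry attribute `kind = "scaling"`.
#' @export
antibiotic_isoclines <- function(world, consts = scaling_constants()) {
  .check_two_strains(world)
  inter <- world$interaction
  if (inter$kind != "antibiotics")
    stop("antibiotic_isoclines() applies to the antibiotics interaction")
  if (inter$b0 <= 1)
    stop("b0 <= 1: no death phase, the antibiotics-limited branch is undefined")
  s1 <- world$strains[[1]]
  if (s1$rho <= 0) stop("strain 1 must produce the degrading enzyme (rho > 0)")
  ct <- .centered_traits(world)
  dsphi <- ct$dsphi_eff
  ab_pref <- inter$kappa * inter$gamma * (1 + s1$delta_alpha) /
    ((1 + inter$gamma) * s1$rho) * log(inter$b0)^2
  da <- abs(ct$da1)
  eps <- consts$epsilon
  pf <- consts$prefactors
  out <- list(
    population_dilution = function(x) rep(dsphi, length(x)),
    population_ab_limited = function(x) ab_pref / x,
    composition_top = structure(function(x) pf[["ab_comp_top"]] / (1 - x),
                                kind = "scaling"),
    composition_low = structure(function(x)
      pf[["ab_comp_low"]] / (da * x^(1 + eps)), kind = "scaling"))
  out
}

#' Analytic isoclines for the pyoverdine interaction
#'
#' The population isocline runs between two branches of the dilution line:
#' `d*s0_phi` at `xbar_1 = 0` (no producers, base yield) and
#' `d*s0_phi*sigma` once pyoverdine saturates the yield.  The composition
#' isocline is the scaling relation `nbar ~ (log|delta_alpha_1| + C)/x`,
#' whose hyperbolic `1/x` shape underlies producer coexistence.
#'
#' @param world A two-strain pyoverdine [world_config()] (strain 1 is the
#'   producer).
#' @param consts A [scaling_constants()].  When `consts$C` is `NULL` the
#'   composition numerator defaults to the uncalibrated placeholder
#'   `pyo_comp` prefactor (i.e. `C = -log|delta_alpha_1| + prefactor`);
#'   use [calibrate_constants()] against a numerical isocline to fix `C`.
#' @return A list with constants `population_saturated`
#'   (`= d*s0_phi*sigma`), `population_nonproducer` (`= d*s0_phi`), and a
#'   `composition` function of `xbar_1` (attribute `kind = "scaling"`).
#' @export
pyoverdine_isoclines <- function(world, consts = scaling_constants()) {
  .check_two_strains(world)
  inter <- world$interaction
  if (inter$kind != "pyoverdine")
    stop("pyoverdine_isoclines() applies to the pyoverdine interaction")
  ct <- .centered_traits(world)
  dsphi <- ct$dsphi_eff
  da <- abs(ct$da1)
  numer <- if (!is.null(consts$C)) log(da) + consts$C
  else consts$prefactors[["pyo_comp"]]
  list(population_saturated = dsphi * inter$sigma,
       population_nonproducer = dsphi,
       composition = structure(function(x) numer / x, kind = "scaling"))
}

#' Calibrate scaling constants against numerical isoclines
#'
#' Fits the open constants of the scaling-form isoclines (`epsilon`, `C`,
#' branch prefactors) to numerically computed isocline points by least
#' squares on log-log axes.
#'
#' @param world A two-strain [world_config()] (antibiotics or pyoverdine).
#' @param numeric_isocline An `isocline_curve` from
#'   [composition_isocline()] (or a data frame with columns `xbar_1`,
#'   `nbar`) restricted to the branch to calibrate.
#' @param branch For antibiotics: `"low"` (the `x^-(1+epsilon)` branch) or
#'   `"top"` (the `1/(1-x)` branch).
#' @return A [scaling_constants()] object with fitted values and attributes
#'   `exponent` (fitted log-log slope) and `residual` (fit RMS on log
#'   scale).
#' @export
calibrate_constants <- function(world, numeric_isocline, branch = "low") {
  df <- as.data.frame(numeric_isocline)
  if (nrow(df) < 5)
    stop("calibration refused: need at least 5 numeric isocline points")
  kind <- world$interaction$kind
  da <- abs(.centered_traits(world)$da1)

  if (kind == "pyoverdine") {
    fit <- stats::lm(log(nbar) ~ log(xbar_1), data = df)
    K <- exp(stats::coef(fit)[[1]])           # nbar ~ K / x for slope -1
    out <- scaling_constants(C = K - log(da),
                             prefactors = c(ab_comp_top = 1, ab_comp_low = 1,
                                            pyo_comp = K))
  } else if (kind == "antibiotics") {
    if (branch == "top") {
      fit <- stats::lm(log(nbar) ~ log(1 - xbar_1), data = df)
      out <- scaling_constants(prefactors = c(
        ab_comp_top = exp(stats::coef(fit)[[1]]),
        ab_comp_low = 1, pyo_comp = 1))
    } else {
      fit <- stats::lm(log(nbar) ~ log(xbar_1), data = df)
      slope <- stats::coef(fit)[[2]]
      eps <- max(-slope - 1, 0)
      out <- scaling_constants(epsilon = eps, prefactors = c(
        ab_comp_top = 1,
        ab_comp_low = exp(stats::coef(fit)[[1]]) * da,
        pyo_comp = 1))
    }
  } else {
    stop("calibration applies to the antibiotics or pyoverdine interactions")
  }
  attr(out, "exponent") <- stats::coef(fit)[[2]]
  attr(out, "residual") <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' Fit a power law y = a * x^b by least squares on log-log axes
#'
#' Utility behind [calibrate_constants()], exposed for checking scaling
#' branches of numerical isoclines directly.
#'
#' @param x,y Positive numeric vectors.
#' @return Named vector `c(prefactor, exponent)` with attribute `residual`.
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y), all(x > 0), all(y > 0))
  fit <- stats::lm(log(y) ~ log(x))
  structure(c(prefactor = exp(stats::coef(fit)[[1]]),
              exponent = stats::coef(fit)[[2]]),
            residual = sqrt(mean(stats::residuals(fit)^2)))
}
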