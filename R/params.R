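#' Per-strain trait parameters
#'
#' A strain is characterised by small relative deviations of its growth rate
#' and yield from the population averages, and by its public-good production
#' rate.  Rates are expressed in the nondimensional units used throughout the
#' package: time is rescaled by the mean growth rate (`alpha = 1`) and
#' substrate is counted in cell equivalents (`phi = 1`), so `delta_alpha` and
#' `delta_phi` are dimensionless and `rho` is a production rate per cell per
#' unit rescaled time (i.e. the ratio rho/alpha).
#'
#' @param delta_alpha Relative growth-rate deviation (dimensionless,
#'   `|delta_alpha| < 1`; the model assumes it is small).
#' @param delta_phi Relative yield deviation (dimensionless,
#'   `|delta_phi| < 1`).
#' @param rho Public-good production rate per cell per unit rescaled time
#'   (`>= 0`).  Under the antibiotics interaction this is the degradation
#'   rate constant; under the pyoverdine interaction the production rate.
#' @return An object of class `strain_params`.
#' @examples
#' strain_params(delta_alpha = -0.02, rho = 5e-3)
#' @export
strain_params <- function(delta_alpha = 0, delta_phi = 0, rho = 0) {
  stopifnot(is.numeric(delta_alpha), length(delta_alpha) == 1L,
            is.numeric(delta_phi), length(delta_phi) == 1L,
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (abs(delta_alpha) >= 1 || abs(delta_phi) >= 1)
    stop("relative trait deviations must satisfy |delta_alpha| < 1 and |delta_phi| < 1")
  if (abs(delta_alpha) > 0.5 || abs(delta_phi) > 0.5)
    warning("trait deviation magnitude > 0.5; the small-deviation model assumption is strained")
  if (rho < 0) stop("'rho' must be >= 0")
  structure(list(delta_alpha = delta_alpha, delta_phi = delta_phi, rho = rho),
            class = "strain_params")
}

#' Antibiotic dose-response parameters
#'
#' Parameters of the Hill-type dose response of the effective growth rate to
#' the antibiotic concentration, measured in units of the minimal inhibitory
#' concentration (MIC).  Growth is zero at `b = 1` and saturates at death
#' rate `-gamma` for large `b`.
#'
#' @param b0 Initial antibiotic concentration in MIC units (`>= 0`),
#'   replenished at the start of every growth phase.
#' @param kappa Hill steepness of the dose response (`> 0`).
#' @param gamma Maximal relative death rate in units of the growth rate
#'   (`> 0`).
#' @return An object of class `antibiotic_params`.
#' @export
antibiotic_params <- function(b0, kappa = 2, gamma = 2) {
  stopifnot(is.numeric(b0), length(b0) == 1L, is.finite(b0),
            is.numeric(kappa), length(kappa) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (b0 < 0) stop("'b0' must be >= 0")
  if (kappa <= 0) stop("'kappa' must be > 0")
  if (gamma <= 0) stop("'gamma' must be > 0")
  structure(list(kind = "antibiotics", b0 = b0, kappa = kappa, gamma = gamma),
            class = c("antibiotic_params", "deme_interaction"))
}

#' Pyoverdine yield-enhancement parameter
#'
#' Pyoverdine (an iron-chelating siderophore) raises the effective yield of
#' all cells in a deme, saturating at an enhancement factor `sigma`.
#' `sigma = 1` reduces exactly to the base model.
#'
#' @param sigma Maximal yield enhancement factor (`>= 1`).
#' @return An object of class `pyoverdine_params`.
#' @export
pyoverdine_params <- function(sigma = 2) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma < 1) stop("'sigma' must be >= 1")
  structure(list(kind = "pyoverdine", sigma = sigma),
            class = c("pyoverdine_params", "deme_interaction"))
}

#' Environment and cycle configuration
#'
#' Bundles the strains and the nondimensional environment parameters of the
#' growth/mixing cycle: the resource supply `s0_phi` (total cell equivalents
#' of substrate, S0*phi), the rescaled mixing time `t_mix` (alpha*T_mix), the
#' dilution factor `d` applied to the pooled population before reseeding, and
#' the interaction model.
#'
#' @param strains List of [strain_params()] objects (a single
#'   `strain_params` is accepted and wrapped).
#' @param s0_phi Resource supply in cell equivalents (`> 0`).
#' @param t_mix Rescaled mixing time (`> 0`).  A warning is issued when
#'   `t_mix < log(s0_phi)`, since then even healthy demes may fail to
#'   deplete the resource before mixing.
#' @param d Dilution factor per cycle (`0 < d < 1`).
#' @param interaction `"base"`, or an [antibiotic_params()] /
#'   [pyoverdine_params()] object.
#' @param consumption `"clamped"` (default) stops resource consumption by
#'   strains whose effective growth rate is negative (dying cells do not
#'   regenerate substrate); `"literal"` keeps the signed consumption term.
#'   Only relevant under the antibiotics interaction.
#' @param extinction_cutoff Optional positive threshold: strain sizes below
#'   it at the end of a growth phase are set to zero.  Default `NULL`
#'   (populations are continuous and may decay without truncation).
#' @param rtol,atol Integrator tolerances for the within-deme ODE solver.
#' @return An object of class `world_config`.  The object carries a private
#'   memoisation environment for within-deme results; treat configurations
#'   as immutable and build a new one to change parameters.
#' @examples
#' w <- world_config(strains = list(strain_params(), strain_params()),
#'                   s0_phi = 1e5, t_mix = 24, d = 6e-4)
#' @export
world_config <- function(strains, s0_phi, t_mix = 24, d,
                         interaction = "base",
                         consumption = c("clamped", "literal"),
                         extinction_cutoff = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  stopifnot(is.list(strains), length(strains) >= 1L)
  if (!all(vapply(strains, inherits, logical(1), "strain_params")))
    stop("'strains' must be a list of strain_params objects")
  if (length(strains) > 8L) stop("at most 8 strains are supported")
  stopifnot(is.numeric(s0_phi), length(s0_phi) == 1L,
            is.numeric(t_mix), length(t_mix) == 1L,
            is.numeric(d), length(d) == 1L)
  if (!is.finite(s0_phi) || s0_phi <= 0) stop("'s0_phi' must be > 0")
  if (!is.finite(t_mix) || t_mix <= 0) stop("'t_mix' must be > 0")
  if (!is.finite(d) || d <= 0 || d >= 1) stop("'d' must satisfy 0 < d < 1")
  if (t_mix < log(s0_phi))
    warning("t_mix < log(s0_phi): demes may not deplete the resource before mixing")
  if (identical(interaction, "base")) {
    interaction <- structure(list(kind = "base"), class = "deme_interaction")
  } else if (!inherits(interaction, "deme_interaction")) {
    stop("'interaction' must be \"base\", antibiotic_params() or pyoverdine_params()")
  }
  consumption <- match.arg(consumption)
  if (!is.null(extinction_cutoff)) {
    stopifnot(is.numeric(extinction_cutoff), length(extinction_cutoff) == 1L,
              extinction_cutoff > 0)
  }
  w <- structure(list(
    strains = strains,
    s0_phi = s0_phi,
    t_mix = t_mix,
    d = d,
    interaction = interaction,
    consumption = consumption,
    extinction_cutoff = extinction_cutoff,
    rtol = rtol, atol = atol,
    cache = new.env(parent = emptyenv())
  ), class = "world_config")
  w
}

#' @export
print.world_config <- function(x, ...) {
  k <- length(x$strains)
  cat(sprintf("<world_config> %d strain%s, interaction: %s\n", k,
              if (k > 1) "s" else "", x$interaction$kind))
  cat(sprintf("  s0_phi = %g, t_mix = %g, d = %g (d*s0_phi = %g)\n",
              x$s0_phi, x$t_mix, x$d, x$d * x$s0_phi))
  for (i in seq_len(k)) {
    s <- x$strains[[i]]
    cat(sprintf("  strain %d: delta_alpha = %g, delta_phi = %g, rho = %g\n",
                i, s$delta_alpha, s$delta_phi, s$rho))
  }
  invisible(x)
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf("<strain_params> delta_alpha = %g, delta_phi = %g, rho = %g\n",
              x$delta_alpha, x$delta_phi, x$rho))
  invisible(x)
}

#' Two-strain world in the strain-average frame
#'
#' Figure-style parametrisations state strain 1's trait deviations relative
#' to the average over both strains; strain 2 then carries the mirrored
#' deviations (`-delta_alpha_1`, `-delta_phi_1`).  This constructor builds
#' that symmetric two-strain world, with only strain 1 producing the public
#' good.
#'
#' @param delta_alpha_1,delta_phi_1 Strain 1 trait deviations from the
#'   strain average (strain 2 gets the opposite sign).
#' @param rho_1 Public-good production rate of strain 1 (strain 2 does not
#'   produce).
#' @inheritParams world_config
#' @param ... Passed on to [world_config()].
#' @return A [world_config()] with two strains.
#' @examples
#' two_strain_world(delta_alpha_1 = -0.01, delta_phi_1 = 0.1,
#'                  s0_phi = 1e5, d = 6e-4)
#' @export
two_strain_world <- function(delta_alpha_1 = 0, delta_phi_1 = 0, rho_1 = 0,
                             s0_phi, t_mix = 24, d, interaction = "base",
                             ...) {
  world_config(list(strain_params(delta_alpha_1, delta_phi_1, rho_1),
                    strain_params(-delta_alpha_1, -delta_phi_1, 0)),
               s0_phi = s0_phi, t_mix = t_mix, d = d,
               interaction = interaction, ...)
}

# number of strains
.n_strains <- function(world) length(world$strains)

# strain traits in the strain-average frame: centered deviations of strain
# 1 and the resource/dilution scales rescaled by the mean yield, as used by
# the closed-form isocline approximations
.centered_traits <- function(world) {
  da <- .strain_vec(world, "delta_alpha")
  dp <- .strain_vec(world, "delta_phi")
  phi_bar <- 1 + mean(dp)
  alp_bar <- 1 + mean(da)
  list(da1 = (1 + da[1]) / alp_bar - 1,
       dp1 = (1 + dp[1]) / phi_bar - 1,
       s_eff = world$s0_phi * phi_bar,
       dsphi_eff = world$d * world$s0_phi * phi_bar)
}

# per-strain parameter vectors
.strain_vec <- function(world, field)
  vapply(world$strains, function(s) s[[field]], numeric(1))

# interaction code used by the compiled right-hand side
.interaction_code <- function(world)
  switch(world$interaction$kind, base = 0L, antibiotics = 1L, pyoverdine = 2L)

# parameter vector handed to the compiled model (layout in src/deme_rhs.c;
# padded to the fixed length the DLL initialiser expects)
.deme_parms <- function(world) {
  k <- .n_strains(world)
  inter <- world$interaction
  p <- c(k,
         .interaction_code(world),
         if (world$consumption == "clamped") 1 else 0,
         if (inter$kind == "antibiotics") inter$kappa else 0,
         if (inter$kind == "antibiotics") inter$gamma else 0,
         if (inter$kind == "pyoverdine") inter$sigma else 1,
         1 + .strain_vec(world, "delta_alpha"),
         1 / (1 + .strain_vec(world, "delta_phi")),
         .strain_vec(world, "rho"))
  c(p, numeric(40 - length(p)))
}

# validate an inoculum vector against a world
.check_inoculum <- function(n, world) {
  if (!is.numeric(n) || length(n) != .n_strains(world))
    stop("inoculum length must match the number of strains")
  if (any(!is.finite(n)) || any(n < 0))
    stop("inoculum counts must be non-negative")
  if (any(abs(n - round(n)) > 1e-8))
    stop("inoculum counts must be integers")
  as.numeric(round(n))
}
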