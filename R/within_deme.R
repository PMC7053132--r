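#' Hill dose-response factor of growth under antibiotics
#'
#' Effective growth-rate factor `A(b) = (1 - b^kappa) / (1 + b^kappa/gamma)`
#' as a function of the antibiotic concentration `b` in MIC units.  The
#' factor equals 1 without antibiotic, crosses zero at the minimal
#' inhibitory concentration `b = 1`, and saturates at `-gamma` (maximal
#' death rate) for large concentrations.
#'
#' @param b Antibiotic concentration in MIC units (`>= 0`); vectorised.
#' @param kappa Hill steepness (`> 0`).
#' @param gamma Maximal relative death rate (`> 0`).
#' @return Dimensionless growth-rate factor, same length as `b`.
#' @examples
#' hill_growth_factor(c(0, 1, 1e6), kappa = 2, gamma = 2)
#' @export
hill_growth_factor <- function(b, kappa, gamma) {
  if (any(!is.finite(b)) || any(b < 0)) stop("'b' must be >= 0")
  if (!is.numeric(kappa) || kappa <= 0) stop("'kappa' must be > 0")
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  h <- b^kappa
  (1 - h) / (1 + h / gamma)
}

#' Yield-enhancement factor under pyoverdine
#'
#' Effective yield factor `Y(P) = sigma - (sigma - 1) * exp(-P)`: yield
#' converges exponentially from 1 (no pyoverdine) to the saturating
#' enhancement `sigma` as the pyoverdine concentration `P` grows.
#'
#' @param p Pyoverdine concentration (dimensionless, `>= 0`); vectorised.
#' @param sigma Maximal yield enhancement (`>= 1`).
#' @return Dimensionless yield factor, same length as `p`.
#' @examples
#' yield_factor(c(0, log(2), 1e3), sigma = 2)
#' @export
yield_factor <- function(p, sigma) {
  if (any(!is.finite(p)) || any(p < 0)) stop("'p' must be >= 0")
  if (!is.numeric(sigma) || sigma < 1) stop("'sigma' must be >= 1")
  sigma - (sigma - 1) * exp(-p)
}

#' Grow a single deme from an integer inoculum
#'
#' Integrates the within-deme consumer-resource dynamics from time 0 to the
#' mixing time: exponential growth of every strain at its effective rate,
#' substrate consumed in proportion to growth, and (depending on the
#' interaction) an antibiotic degraded by producer cells or pyoverdine
#' accumulating and raising yield.  Growth stops when the substrate is
#' depleted; population sizes are then frozen until `t_mix`.
#'
#' @param n Integer inoculum vector, one count per strain.
#' @param world A [world_config()].
#' @param trajectory If `TRUE`, return the time course of all state
#'   variables at `n_times` points.
#' @param n_times Number of output times when `trajectory = TRUE`.
#' @return An object of class `deme_growth`: list with `final_sizes`
#'   (continuous, per strain, at `t_mix`), `t_depl` (depletion time, `NA`
#'   when the resource is not exhausted by `t_mix`), `depleted` (logical),
#'   and `trajectory` (a data frame with columns `t`, `N_1..N_k`, `S`, and
#'   `B` or `P` where applicable, or `NULL`).
#' @examples
#' w <- world_config(strain_params(), s0_phi = 1e5, t_mix = 24, d = 6e-4)
#' grow_deme(10, w)
#' @export
grow_deme <- function(n, world, trajectory = FALSE, n_times = 200L) {
  stopifnot(inherits(world, "world_config"))
  n <- .check_inoculum(n, world)
  k <- .n_strains(world)
  inter <- world$interaction$kind

  if (sum(n) == 0 && !trajectory) {
    return(.deme_growth(rep(0, k), NA_real_, FALSE, NULL, n, world))
  }

  g0 <- switch(inter, antibiotics = world$interaction$b0, pyoverdine = 0, 0)
  y0 <- c(n, world$s0_phi, g0)
  times <- if (trajectory) seq(0, world$t_mix, length.out = n_times) else
    c(0, world$t_mix)

  sol <- deSolve::lsodar(
    y = y0, times = times, func = "deme_derivs", parms = .deme_parms(world),
    dllname = "demecycles", initfunc = "deme_init",
    rootfunc = "deme_root", nroot = 1L,
    rtol = world$rtol, atol = world$atol)

  if (attr(sol, "istate")[1] < 0)
    stop("within-deme integration failed (istate = ",
         attr(sol, "istate")[1], ") for inoculum (",
         paste(n, collapse = ", "), ")")

  troot <- attr(sol, "troot")
  depleted <- length(troot) > 0 && is.finite(troot[1]) &&
    troot[1] <= world$t_mix
  t_depl <- if (depleted) troot[1] else NA_real_

  last <- sol[nrow(sol), -1]
  finals <- pmax(as.numeric(last[seq_len(k)]), 0)
  if (any(as.numeric(last[seq_len(k)]) < -1e-6 * max(1, world$s0_phi)))
    stop("negative population state beyond tolerance; integration unreliable")
  if (!is.null(world$extinction_cutoff))
    finals[finals < world$extinction_cutoff] <- 0

  traj <- NULL
  if (trajectory) {
    traj <- as.data.frame(sol)
    names(traj) <- c("t", paste0("N_", seq_len(k)), "S",
                     switch(inter, antibiotics = "B", pyoverdine = "P", "G"))
    if (inter == "base") traj$G <- NULL
    # growth stops at depletion: pad the remaining output times with the
    # frozen depletion state
    if (depleted && t_depl < world$t_mix) {
      missing_t <- times[times > max(traj$t)]
      if (length(missing_t)) {
        pad <- traj[rep(nrow(traj), length(missing_t)), , drop = FALSE]
        pad$t <- missing_t
        traj <- rbind(traj, pad)
        rownames(traj) <- NULL
      }
    }
  }

  .deme_growth(finals, t_depl, depleted, traj, n, world)
}

.deme_growth <- function(final_sizes, t_depl, depleted, trajectory, n, world) {
  structure(list(final_sizes = final_sizes, t_depl = t_depl,
                 depleted = depleted, trajectory = trajectory,
                 inoculum = n, interaction = world$interaction$kind),
            class = "deme_growth")
}

#' @export
print.deme_growth <- function(x, ...) {
  cat(sprintf("<deme_growth> interaction: %s, inoculum (%s)\n",
              x$interaction, paste(x$inoculum, collapse = ", ")))
  cat(sprintf("  final sizes: %s\n",
              paste(signif(x$final_sizes, 6), collapse = ", ")))
  cat(if (x$depleted)
    sprintf("  resource depleted at t = %.4f\n", x$t_depl)
    else "  resource not depleted by t_mix\n")
  invisible(x)
}

#' Exact growth-phase solution for the base interaction
#'
#' With constant growth rates and yields the within-deme dynamics have a
#' closed form: each strain grows exponentially, `N_i(t) = n_i *
#' exp((1 + delta_alpha_i) t)`, until the substrate budget
#' `sum_i (N_i(t) - n_i) / (1 + delta_phi_i) = s0_phi` is exhausted at the
#' depletion time (a scalar root of a monotone function), after which sizes
#' are frozen.  Serves as an independent oracle for the ODE integrator.
#'
#' @inheritParams grow_deme
#' @return A `deme_growth` object (no trajectory).
#' @export
base_closed_form <- function(n, world) {
  stopifnot(inherits(world, "world_config"))
  if (world$interaction$kind != "base")
    stop("base_closed_form() applies to the base interaction only")
  n <- .check_inoculum(n, world)
  res <- .base_finals(matrix(n, nrow = 1), world)
  .deme_growth(as.numeric(res$finals[1, ]), res$t_depl[1],
               res$depleted[1], NULL, n, world)
}

# Vectorised closed-form growth for the base interaction.
# nmat: one inoculum per row.  Returns finals matrix, t_depl, depleted.
# Depletion times solved by a safeguarded Newton iteration on the monotone
# substrate budget, vectorised across demes.
.base_finals <- function(nmat, world) {
  k <- .n_strains(world)
  a <- 1 + .strain_vec(world, "delta_alpha")
  invphi <- 1 / (1 + .strain_vec(world, "delta_phi"))
  s0 <- world$s0_phi
  tm <- world$t_mix
  m <- nrow(nmat)

  # substrate consumed by the mixing time decides which demes deplete
  consumed_tm <- numeric(m)
  for (i in seq_len(k))
    consumed_tm <- consumed_tm + nmat[, i] * invphi[i] * (exp(a[i] * tm) - 1)

  tot <- rowSums(nmat)
  depleted <- consumed_tm >= s0
  depleted[tot == 0] <- FALSE
  t_depl <- rep(NA_real_, m)

  idx <- which(depleted)
  if (length(idx)) {
    nsub <- nmat[idx, , drop = FALSE]
    fsub <- function(tt) {
      acc <- -s0
      for (i in seq_len(k))
        acc <- acc + nsub[, i] * invphi[i] * (exp(a[i] * tt) - 1)
      acc
    }
    dfsub <- function(tt) {
      acc <- 0
      for (i in seq_len(k))
        acc <- acc + nsub[, i] * invphi[i] * a[i] * exp(a[i] * tt)
      acc
    }
    # Newton from a slight underestimate; bisection fallback bounds
    lo <- rep(0, length(idx)); hi <- rep(tm, length(idx))
    tt <- pmin(tm, log1p(s0 / pmax(tot[idx], 1e-300)) / max(a))
    for (iter in 1:100) {
      fval <- fsub(tt)
      hi[fval > 0] <- pmin(hi[fval > 0], tt[fval > 0])
      lo[fval < 0] <- pmax(lo[fval < 0], tt[fval < 0])
      tt_new <- tt - fval / pmax(dfsub(tt), 1e-300)
      bad <- tt_new <= lo | tt_new >= hi | !is.finite(tt_new)
      tt_new[bad] <- (lo[bad] + hi[bad]) / 2
      if (max(abs(tt_new - tt)) < 1e-14 * tm) { tt <- tt_new; break }
      tt <- tt_new
    }
    t_depl[idx] <- tt
  }

  tgrow <- ifelse(depleted, t_depl, tm)
  tgrow[tot == 0] <- 0
  finals <- matrix(0, m, k)
  for (i in seq_len(k)) finals[, i] <- nmat[, i] * exp(a[i] * tgrow)
  if (!is.null(world$extinction_cutoff))
    finals[finals < world$extinction_cutoff] <- 0
  list(finals = finals, t_depl = t_depl, depleted = depleted)
}

# Final sizes for a matrix of integer inocula via the ODE integrator.
# Used by the lattice cache for the antibiotics / pyoverdine interactions.
.ode_finals <- function(nmat, world) {
  k <- .n_strains(world)
  m <- nrow(nmat)
  finals <- matrix(0, m, k)
  g0 <- switch(world$interaction$kind,
               antibiotics = world$interaction$b0, pyoverdine = 0, 0)
  parms <- .deme_parms(world)
  for (j in seq_len(m)) {
    n <- nmat[j, ]
    if (sum(n) == 0) next
    sol <- deSolve::lsodar(
      y = c(n, world$s0_phi, g0), times = c(0, world$t_mix),
      func = "deme_derivs", parms = parms,
      dllname = "demecycles", initfunc = "deme_init",
      rootfunc = "deme_root", nroot = 1L,
      rtol = world$rtol, atol = world$atol)
    if (attr(sol, "istate")[1] < 0)
      stop("within-deme integration failed for inoculum (",
           paste(n, collapse = ", "), ")")
    finals[j, ] <- pmax(as.numeric(sol[nrow(sol), 1 + seq_len(k)]), 0)
  }
  if (!is.null(world$extinction_cutoff))
    finals[finals < world$extinction_cutoff] <- 0
  finals
}

# Dispatch: closed form (exact, fast) for the base interaction, ODE solver
# otherwise.  All lattice/ensemble machinery funnels through here.
.deme_finals <- function(nmat, world) {
  if (world$interaction$kind == "base") .base_finals(nmat, world)$finals
  else .ode_finals(nmat, world)
}
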