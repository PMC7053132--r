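# Long-term outcome classification and parameter-space scans.

# stable positive fixed point of the single-strain map restricted to one
# axis (NA when the strain cannot persist alone)
.boundary_resident <- function(world, axis, trunc, n_upper) {
  f <- function(n) {
    v <- c(0, 0); v[axis] <- n
    .map_eval(v, world, trunc)[axis] - n
  }
  ngrid <- exp(seq(log(1e-2), log(n_upper), length.out = 40L))
  vals <- vapply(ngrid, f, numeric(1))
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  best <- NA_real_
  for (j in idx) {
    root <- stats::uniroot(f, c(ngrid[j], ngrid[j + 1]),
                           tol = 1e-9 * ngrid[j + 1])$root
    # stability of the restricted scalar map
    h <- max(root * 1e-4, 1e-6)
    slope <- (f(root + h) - f(root - h)) / (2 * h) + 1
    if (abs(slope) < 1) best <- max(best, root, na.rm = TRUE)
  }
  best
}

# invasion multipliers: growth factor per cycle of each strain when rare
# against the other strain's resident equilibrium
.invasion_analysis <- function(world, trunc, h = 1e-3) {
  dsphi <- world$d * world$s0_phi
  sig <- if (world$interaction$kind == "pyoverdine") world$interaction$sigma else 1
  n_upper <- max(5 * dsphi * sig, 150)
  res <- lapply(1:2, function(axis)
    .boundary_resident(world, axis, trunc, n_upper))
  lam <- rep(NA_real_, 2)
  for (invader in 1:2) {
    resident <- 3 - invader
    if (is.na(res[[resident]])) next
    v <- c(0, 0); v[resident] <- res[[resident]]; v[invader] <- h
    lam[invader] <- .map_eval(v, world, trunc)[invader] / h
  }
  list(resident_nbar = c(res[[1]], res[[2]]), lambda_invasion = lam)
}

# label for the end state of one trajectory
.terminal_label <- function(traj, world, trunc, coex_tol, ext_tol,
                            cycle_max = 2000L) {
  st <- attr(traj, "final_state")$mean_counts
  tot <- sum(st)
  if (tot < ext_tol) return(list(label = "extinction", state = st))
  x1 <- st[1] / tot
  if (x1 >= 1 - coex_tol) return(list(label = "fixation_strain1", state = st))
  if (x1 <= coex_tol) return(list(label = "fixation_strain2", state = st))
  if (attr(traj, "converged")) {
    fp <- tryCatch(classify_fixed_point(st, world, trunc),
                   error = function(e) NULL)
    if (is.null(fp)) return(list(label = "undetermined", state = st))
    lab <- switch(fp$classification,
                  stable_node = , stable_spiral = "coexistence",
                  marginal = "undetermined",
                  "undetermined")
    return(list(label = lab, state = st, fixed_point = fp))
  }
  lc <- detect_limit_cycle(world, st, max_cycles = cycle_max, trunc = trunc)
  if (lc$type == "limit_cycle")
    return(list(label = "limit_cycle", state = lc$state, cycle = lc))
  if (lc$terminal == "extinction")
    return(list(label = "extinction", state = lc$state))
  if (lc$terminal == "fixation") {
    xe <- lc$state[1] / sum(lc$state)
    return(list(label = if (xe > 0.5) "fixation_strain1" else "fixation_strain2",
                state = lc$state))
  }
  if (lc$terminal == "fixed_point")
    return(.relabel_converged(lc$state, world, trunc, coex_tol))
  list(label = "undetermined", state = lc$state)
}

.relabel_converged <- function(st, world, trunc, coex_tol) {
  tot <- sum(st); x1 <- st[1] / tot
  if (x1 >= 1 - coex_tol) return(list(label = "fixation_strain1", state = st))
  if (x1 <= coex_tol) return(list(label = "fixation_strain2", state = st))
  fp <- tryCatch(classify_fixed_point(st, world, trunc), error = function(e) NULL)
  lab <- if (!is.null(fp) && fp$classification %in% c("stable_node", "stable_spiral"))
    "coexistence" else "undetermined"
  list(label = lab, state = st, fixed_point = fp)
}

#' Invasion multipliers of a two-strain world
#'
#' For each strain, the per-cycle growth factor of an infinitesimally rare
#' invader against the other strain's monomorphic resident equilibrium.
#' A multiplier above 1 means the strain can invade; both above 1 is the
#' protected-coexistence condition used by [coexistence_scan()].
#'
#' @param world A two-strain [world_config()].
#' @param trunc A [truncation_policy()].
#' @return A list with `resident_nbar` (single-strain equilibria, `NA`
#'   when a strain cannot persist alone) and `lambda_invasion` (invasion
#'   multipliers, `NA` when the corresponding resident does not exist).
#' @export
invasion_multipliers <- function(world, trunc = truncation_policy()) {
  .check_two_strains(world)
  .invasion_analysis(world, trunc)
}

#' Classify the long-term outcome of a two-strain world
#'
#' Determines which of coexistence, fixation of either strain, total
#' extinction, a limit cycle, or undetermined describes the long-term
#' behaviour of the cycle map.  `method = "invasion"` uses mutual
#' invasibility: each strain's per-cycle growth factor when rare against
#' the other strain's resident equilibrium (both above 1 implies protected
#' coexistence).  `method = "trajectory"` iterates the map from a set of
#' starting states and labels the attractors reached.  The default
#' `"hybrid"` uses the invasion criterion where it is decisive and falls
#' back to trajectories for bistable, neutral, or non-equilibrium cases.
#'
#' @param world A two-strain [world_config()].
#' @param starts Optional matrix/data frame of starting states (columns
#'   `nbar`, `xbar_1`); a default set of 6 interior and near-boundary
#'   starts is used when `NULL`.
#' @param horizon Maximum cycles per trajectory.
#' @param trunc A [truncation_policy()].
#' @param method `"hybrid"`, `"invasion"` or `"trajectory"`.
#' @param coex_tol Composition tolerance separating interior attractors
#'   from boundary fixation.
#' @param ext_tol Total mean inoculum under which the population counts as
#'   extinct.
#' @return An `outcome_label` object: list with `label`, `basins` (labels
#'   per start, trajectory methods), and `evidence` (invasion multipliers,
#'   resident equilibria, fixed points / limit-cycle diagnostics).
#' @export
classify_outcome <- function(world, starts = NULL, horizon = 500L,
                             trunc = truncation_policy(),
                             method = c("hybrid", "invasion", "trajectory"),
                             coex_tol = 1e-3, ext_tol = 1e-6) {
  .check_two_strains(world)
  method <- match.arg(method)
  s1 <- world$strains[[1]]; s2 <- world$strains[[2]]
  neutral <- identical(unclass(s1), unclass(s2))
  evidence <- list()

  if (neutral) {
    # no selection: composition is conserved, coexistence is not meaningful
    return(structure(list(label = "undetermined", basins = NULL,
                          evidence = list(note = "identical strains: neutral (marginal eigenvalue)")),
                     class = "outcome_label"))
  }

  if (method %in% c("hybrid", "invasion")) {
    inv <- .invasion_analysis(world, trunc)
    evidence$invasion <- inv
    v1 <- !is.na(inv$resident_nbar[1]); v2 <- !is.na(inv$resident_nbar[2])
    l1 <- inv$lambda_invasion[1]; l2 <- inv$lambda_invasion[2]
    if (v1 && v2) {
      if (l1 > 1 && l2 > 1)
        return(structure(list(label = "coexistence", basins = NULL,
                              evidence = evidence), class = "outcome_label"))
      if (l1 > 1 && l2 < 1)
        return(structure(list(label = "fixation_strain1", basins = NULL,
                              evidence = evidence), class = "outcome_label"))
      if (l1 < 1 && l2 > 1)
        return(structure(list(label = "fixation_strain2", basins = NULL,
                              evidence = evidence), class = "outcome_label"))
      # neither invades: bistable fixation -- decide by trajectories below
    }
    if (!v1 && !v2 && world$interaction$kind == "base")
      return(structure(list(label = "extinction", basins = NULL,
                            evidence = evidence), class = "outcome_label"))
    if (method == "invasion") {
      # remaining one-resident cases need trajectories; report what is known
      lab <- if (v1 && !v2 && (is.na(l2) || l2 < 1)) "fixation_strain1"
      else if (v2 && !v1 && (is.na(l1) || l1 < 1)) "fixation_strain2"
      else "undetermined"
      return(structure(list(label = lab, basins = NULL, evidence = evidence),
                       class = "outcome_label"))
    }
  }

  # trajectory phase
  dsphi <- world$d * world$s0_phi
  sig <- if (world$interaction$kind == "pyoverdine") world$interaction$sigma else 1
  n_ref <- max(dsphi * sig, 1)
  if (is.null(starts))
    starts <- expand.grid(nbar = n_ref * c(0.5, 1.5),
                          xbar_1 = c(0.1, 0.5, 0.9))
  starts <- as.matrix(starts)
  basins <- character(nrow(starts))
  details <- vector("list", nrow(starts))
  for (r in seq_len(nrow(starts))) {
    v <- c(starts[r, 1] * starts[r, 2], starts[r, 1] * (1 - starts[r, 2]))
    traj <- iterate_cycles(v, world, horizon, trunc)
    res <- .terminal_label(traj, world, trunc, coex_tol, ext_tol)
    basins[r] <- res$label
    details[[r]] <- res
  }
  evidence$terminal <- details
  # primary label: the start closest to the interior reference state
  dist <- sqrt((log(starts[, 1] / n_ref))^2 + (starts[, 2] - 0.5)^2)
  label <- basins[which.min(dist)]
  structure(list(label = label, basins = basins, evidence = evidence),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("<outcome_label> %s\n", x$label))
  if (!is.null(x$basins))
    cat("  basins:", paste(unique(x$basins), collapse = ", "), "\n")
  if (!is.null(x$evidence$invasion)) {
    inv <- x$evidence$invasion
    cat(sprintf("  residents nbar: %s; invasion multipliers: %s\n",
                paste(signif(inv$resident_nbar, 5), collapse = ", "),
                paste(signif(inv$lambda_invasion, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Scan long-term outcomes over the trade-off plane
#'
#' Classifies the long-term outcome on a grid over the trait deviations of
#' strain 1 (growth-rate cost `delta_alpha_1 < 0`, yield advantage
#' `delta_phi_1`), holding strain 2 neutral and all environment parameters
#' fixed.  Cells are independent and the result is deterministic.
#'
#' @param world_template A two-strain [world_config()] supplying the
#'   environment, interaction and strain-2 parameters; strain 1's
#'   `delta_alpha`/`delta_phi` are replaced cell by cell (its `rho` is
#'   kept).
#' @param delta_alpha Vector of strain-1 growth-rate deviations.
#' @param delta_phi Vector of strain-1 yield deviations.
#' @param centered If `TRUE` (default) deviations are interpreted in the
#'   strain-average frame and strain 2 carries the mirrored deviations, as
#'   in [two_strain_world()]; if `FALSE` strain 2 keeps the template's
#'   parameters.
#' @param method Classification method, see [classify_outcome()]
#'   (`"invasion"` by default: fast and deterministic for scans).
#' @param trunc A [truncation_policy()].
#' @param ... Passed to [classify_outcome()].
#' @return A `scan_result`: list with the grids, an outcome character
#'   matrix (`delta_alpha` by `delta_phi`), and matrices of invasion
#'   multipliers where available.  Per-cell failures are recorded as
#'   `"undetermined"` without aborting the scan.
#' @export
coexistence_scan <- function(world_template, delta_alpha, delta_phi,
                             centered = TRUE, method = "invasion",
                             trunc = truncation_policy(), ...) {
  .check_two_strains(world_template)
  na <- length(delta_alpha); np <- length(delta_phi)
  if (na * np > 1e4) stop("scan grid larger than 10^4 cells")
  outcome <- matrix(NA_character_, na, np,
                    dimnames = list(signif(delta_alpha, 6), signif(delta_phi, 6)))
  lam1 <- lam2 <- matrix(NA_real_, na, np)
  tmpl <- world_template
  for (i in seq_len(na)) {
    for (j in seq_len(np)) {
      s1 <- tmpl$strains[[1]]
      s2 <- if (centered)
        strain_params(-delta_alpha[i], -delta_phi[j], tmpl$strains[[2]]$rho)
      else tmpl$strains[[2]]
      strains <- list(strain_params(delta_alpha[i], delta_phi[j], s1$rho), s2)
      w <- world_config(strains, s0_phi = tmpl$s0_phi, t_mix = tmpl$t_mix,
                        d = tmpl$d, interaction = tmpl$interaction,
                        consumption = tmpl$consumption,
                        extinction_cutoff = tmpl$extinction_cutoff,
                        rtol = tmpl$rtol, atol = tmpl$atol)
      res <- tryCatch(classify_outcome(w, method = method, trunc = trunc, ...),
                      error = function(e) NULL)
      if (is.null(res)) { outcome[i, j] <- "undetermined"; next }
      outcome[i, j] <- res$label
      if (!is.null(res$evidence$invasion)) {
        lam1[i, j] <- res$evidence$invasion$lambda_invasion[1]
        lam2[i, j] <- res$evidence$invasion$lambda_invasion[2]
      }
    }
  }
  structure(list(delta_alpha = delta_alpha, delta_phi = delta_phi,
                 outcome = outcome, lambda_invasion_1 = lam1,
                 lambda_invasion_2 = lam2),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d x %d cells\n", nrow(x$outcome), ncol(x$outcome)))
  print(table(x$outcome))
  invisible(x)
}

#' Search for a Simpson's-paradox state
#'
#' Scans a grid of mean states for a configuration where the within-deme
#' term of the Price decomposition is negative for strain 1 (it loses the
#' local competition in every deme on average) while the between-deme
#' covariance term is positive and large enough that its pooled frequency
#' still increases over the cycle.
#'
#' @param world A two-strain [world_config()].
#' @param nbar_grid,x1_grid Grids of total mean inoculum and composition.
#' @param trunc A [truncation_policy()].
#' @return A data frame of grid points with the three Price quantities for
#'   strain 1 and a logical `simpson` column; attribute `found` indicates
#'   whether any state realises the paradox.
#' @export
find_simpsons_paradox <- function(world,
                                  nbar_grid = c(5, 10, 20, 40, 60),
                                  x1_grid = seq(0.2, 0.8, by = 0.2),
                                  trunc = truncation_policy()) {
  .check_two_strains(world)
  grid <- expand.grid(nbar = nbar_grid, xbar_1 = x1_grid)
  out <- lapply(seq_len(nrow(grid)), function(r) {
    st <- c(grid$nbar[r] * grid$xbar_1[r], grid$nbar[r] * (1 - grid$xbar_1[r]))
    pt <- tryCatch(price_decomposition(st, world, trunc),
                   error = function(e) NULL)
    if (is.null(pt)) return(NULL)
    data.frame(nbar = grid$nbar[r], xbar_1 = grid$xbar_1[r],
               delta_xbar = pt$delta_xbar[1], within = pt$within[1],
               covariance = pt$covariance[1])
  })
  df <- do.call(rbind, out)
  df$simpson <- df$within < 0 & df$covariance > 0 & df$delta_xbar > 0
  structure(df, found = any(df$simpson))
}
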