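# Phase-plane analysis of the two-strain cycle map in (nbar, xbar_1):
# numerical isoclines, fixed points with stability classification from the
# map Jacobian, and limit-cycle detection.

.check_two_strains <- function(world) {
  if (.n_strains(world) != 2L)
    stop("phase-plane analysis requires a two-strain world")
}

# map in (nbar, x1) view: returns c(nbar', x1')
.map_nx <- function(nbar, x1, world, trunc) {
  v <- .map_eval(c(nbar * x1, nbar * (1 - x1)), world, trunc)
  tot <- sum(v)
  c(tot, if (tot > 0) v[1] / tot else NA_real_)
}

#' Numerical isocline of total population size
#'
#' For each composition value on a grid, finds the mean inoculum sizes at
#' which the total size is stationary over one cycle (`Delta nbar = 0`),
#' by bracketing sign changes of the one-cycle change on a logarithmic scan
#' grid and refining each root (relative tolerance `tol`).  Multiple roots
#' at a given composition (as in the antibiotics interaction, which has a
#' resource-limited and an antibiotics-limited branch) are reported as
#' separate branches, labelled by root index along increasing `nbar`.
#'
#' @param world A two-strain [world_config()].
#' @param x_grid Composition grid (values in `(0, 1)`).
#' @param n_range Range of `nbar` scanned for sign changes.
#' @param n_scan Number of (log-spaced) scan points in `n_range`.
#' @param trunc A [truncation_policy()].
#' @param tol Relative root tolerance in `nbar`.
#' @return An `isocline_curve` object: data frame with columns `xbar_1`,
#'   `nbar`, `branch`, and attributes `variable` and `tol`.  Grid values
#'   where no sign change is bracketed are omitted (with a message).
#' @export
population_isocline <- function(world, x_grid = seq(0.05, 0.95, by = 0.05),
                                n_range = c(0.05, 4 * world$d * world$s0_phi),
                                n_scan = 41L,
                                trunc = truncation_policy(), tol = 1e-6) {
  .check_two_strains(world)
  g <- function(nbar, x1) .map_nx(nbar, x1, world, trunc)[1] - nbar
  .isocline_scan(g, x_grid, n_range, n_scan, tol, variable = "total_size")
}

#' Numerical isocline of population composition
#'
#' As [population_isocline()], but finds where the composition of strain 1
#' is stationary over one cycle (`Delta xbar_1 = 0`), root-finding in
#' `nbar` at fixed `xbar_1`.  When the two strains are identical the
#' composition change vanishes identically; the returned object then has
#' attribute `degenerate = TRUE` ("everywhere stationary") and no points.
#'
#' @inheritParams population_isocline
#' @return An `isocline_curve` object (see [population_isocline()]).
#' @export
composition_isocline <- function(world, x_grid = seq(0.05, 0.95, by = 0.05),
                                 n_range = c(0.05, 4 * world$d * world$s0_phi),
                                 n_scan = 41L,
                                 trunc = truncation_policy(), tol = 1e-6) {
  .check_two_strains(world)
  s1 <- world$strains[[1]]; s2 <- world$strains[[2]]
  if (identical(unclass(s1), unclass(s2))) {
    out <- structure(data.frame(xbar_1 = numeric(0), nbar = numeric(0),
                                branch = integer(0)),
                     variable = "composition", tol = tol, degenerate = TRUE,
                     class = c("isocline_curve", "data.frame"))
    message("identical strains: composition is everywhere stationary")
    return(out)
  }
  h <- function(nbar, x1) .map_nx(nbar, x1, world, trunc)[2] - x1
  .isocline_scan(h, x_grid, n_range, n_scan, tol, variable = "composition")
}

# shared scan-and-refine machinery for isoclines
.isocline_scan <- function(fun, x_grid, n_range, n_scan, tol, variable) {
  stopifnot(length(n_range) == 2L, all(n_range > 0), n_range[1] < n_range[2])
  ngrid <- exp(seq(log(n_range[1]), log(n_range[2]), length.out = n_scan))
  rows <- list()
  skipped <- 0L
  for (x1 in x_grid) {
    vals <- vapply(ngrid, fun, numeric(1), x1 = x1)
    sgn <- sign(vals)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(idx)) {
      exact <- which(sgn == 0)
      if (length(exact)) {
        rows[[length(rows) + 1L]] <-
          data.frame(xbar_1 = x1, nbar = ngrid[exact], branch = seq_along(exact))
      } else skipped <- skipped + 1L
      next
    }
    roots <- vapply(idx, function(j) {
      stats::uniroot(fun, interval = c(ngrid[j], ngrid[j + 1]), x1 = x1,
                     tol = tol * ngrid[j + 1])$root
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(xbar_1 = x1, nbar = sort(roots), branch = seq_along(roots))
  }
  if (skipped > 0)
    message(skipped, " grid value(s) omitted: no sign change in the scan range")
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(xbar_1 = numeric(0), nbar = numeric(0), branch = integer(0))
  rownames(df) <- NULL
  structure(df, variable = variable, tol = tol, degenerate = FALSE,
            class = c("isocline_curve", "data.frame"))
}

# Finite-difference Jacobian of the one-cycle map F(nbar_1, nbar_2) with
# central differences (one-sided at the non-negativity boundary) and a
# Richardson step-halving error estimate (skipped inside Newton loops,
# where a single-step Jacobian is accurate enough).
.map_jacobian <- function(v, world, trunc, rel_step = 1e-4,
                          richardson = TRUE) {
  k <- length(v)
  jac_at <- function(h_vec) {
    J <- matrix(NA_real_, k, k)
    for (j in seq_len(k)) {
      h <- h_vec[j]
      lo <- v[j] - h
      if (lo >= 0) {
        vp <- v; vp[j] <- v[j] + h
        vm <- v; vm[j] <- lo
        J[, j] <- (.map_eval(vp, world, trunc) -
                     .map_eval(vm, world, trunc)) / (2 * h)
      } else {
        vp <- v; vp[j] <- v[j] + h
        vpp <- v; vpp[j] <- v[j] + 2 * h
        f0 <- .map_eval(v, world, trunc)
        J[, j] <- (4 * .map_eval(vp, world, trunc) -
                     .map_eval(vpp, world, trunc) - 3 * f0) / (2 * h)
      }
    }
    J
  }
  h1 <- pmax(abs(v) * rel_step, 1e-8)
  J1 <- jac_at(h1)
  if (!richardson) return(list(jacobian = J1, fd_error = NA_real_))
  J2 <- jac_at(h1 / 2)
  J <- (4 * J2 - J1) / 3          # Richardson extrapolation
  list(jacobian = J, fd_error = max(abs(J2 - J1)))
}

.new_fixed_point <- function(v, world, type) {
  v <- unname(v)
  tot <- sum(v)
  structure(list(
    counts = v,
    position = c(nbar = tot, xbar_1 = if (tot > 0) v[1] / tot else NA_real_),
    type = type, eigenvalues = NULL, classification = "unclassified",
    jacobian = NULL, fd_error = NA_real_),
    class = "fixed_point")
}

#' Classify a fixed point of the cycle map
#'
#' Computes the Jacobian of the one-cycle map at the fixed point by central
#' finite differences (relative step `rel_step`, with a step-halving
#' Richardson check), its eigenvalues, and the discrete-map stability
#' classification: stable iff all eigenvalue moduli are below 1, with
#' node/spiral distinguished by a complex eigenvalue pair, `saddle` for
#' mixed moduli, and `marginal` when a modulus lies within `band` of 1.
#'
#' @param fp A `fixed_point` (from [find_fixed_points()]) or a numeric
#'   vector of per-strain mean counts at the fixed point.
#' @param world A [world_config()].
#' @param trunc A [truncation_policy()].
#' @param rel_step Relative finite-difference step.
#' @param band Half-width of the marginal band around modulus 1.
#' @return The `fixed_point` with `eigenvalues`, `classification`,
#'   `jacobian` and `fd_error` filled in.
#' @export
classify_fixed_point <- function(fp, world, trunc = truncation_policy(),
                                 rel_step = 1e-4, band = 1e-6) {
  if (is.numeric(fp)) {
    tot <- sum(fp)
    type <- if (tot <= 0) "extinction"
    else if (any(fp <= 0)) "boundary_fixation" else "interior"
    fp <- .new_fixed_point(fp, world, type)
  }
  stopifnot(inherits(fp, "fixed_point"))
  jr <- .map_jacobian(fp$counts, world, trunc, rel_step)
  ev <- eigen(jr$jacobian, only.values = TRUE)$values
  mod <- Mod(ev)
  complex_pair <- any(abs(Im(ev)) > 1e-12)
  cls <- if (any(abs(mod - 1) < band)) "marginal"
  else if (all(mod < 1)) if (complex_pair) "stable_spiral" else "stable_node"
  else if (all(mod > 1)) if (complex_pair) "unstable_spiral" else "unstable_node"
  else "saddle"
  fp$eigenvalues <- ev
  fp$classification <- cls
  fp$jacobian <- jr$jacobian
  fp$fd_error <- jr$fd_error
  fp
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> %s: nbar = %g, xbar_1 = %g\n", x$type,
              x$position["nbar"], x$position["xbar_1"]))
  if (!is.null(x$eigenvalues)) {
    cat(sprintf("  classification: %s; |lambda| = %s\n", x$classification,
                paste(signif(Mod(x$eigenvalues), 6), collapse = ", ")))
  }
  invisible(x)
}

#' Locate fixed points of the two-strain cycle map
#'
#' Finds fixed points of the map on mean counts `(nbar_1, nbar_2)`:
#' the extinction state, boundary (single-strain) fixed points on each
#' axis found by scanning the restricted scalar map for sign changes, and
#' interior fixed points by damped Newton iteration with finite-difference
#' Jacobians, multi-started from `seed_grid` (and any supplied isocline
#' intersections).  Solutions are deduplicated within `dedupe_tol`
#' (relative) and classified via [classify_fixed_point()]; boundary points
#' keep their transverse (invasion) eigenvalue because the Jacobian is
#' taken on the full two-variable map.
#'
#' @param world A two-strain [world_config()].
#' @param seed_grid Optional matrix/data frame of Newton starting states,
#'   columns `nbar` and `xbar_1`.  A default grid around the dilution
#'   scale is used when `NULL`.
#' @param isoclines Optional list of `isocline_curve` objects (one
#'   population, one composition); their near-intersections are added to
#'   the Newton starts.
#' @param n_upper Upper end of the axis scan for boundary fixed points.
#' @param trunc A [truncation_policy()].
#' @param tol_res Residual tolerance (relative to `nbar`) for Newton
#'   convergence.
#' @param dedupe_tol Relative distance under which two solutions are
#'   considered the same fixed point.
#' @return A list of `fixed_point` objects (class `fixed_point_list`).
#' @export
find_fixed_points <- function(world, seed_grid = NULL, isoclines = NULL,
                              n_upper = NULL,
                              trunc = truncation_policy(),
                              tol_res = 1e-10, dedupe_tol = 1e-4) {
  .check_two_strains(world)
  dsphi <- world$d * world$s0_phi
  sig <- if (world$interaction$kind == "pyoverdine") world$interaction$sigma else 1
  if (is.null(n_upper)) n_upper <- max(5 * dsphi * sig, 150)

  found <- list()
  add <- function(fp) found[[length(found) + 1L]] <<- fp

  # extinction state: always examined
  add(classify_fixed_point(c(0, 0), world, trunc))

  # boundary fixed points on each single-strain axis
  for (axis in 1:2) {
    f <- function(n) {
      v <- c(0, 0); v[axis] <- n
      .map_eval(v, world, trunc)[axis] - n
    }
    ngrid <- exp(seq(log(1e-2), log(n_upper), length.out = 40L))
    vals <- vapply(ngrid, f, numeric(1))
    sgn <- sign(vals)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (j in idx) {
      root <- stats::uniroot(f, c(ngrid[j], ngrid[j + 1]),
                             tol = 1e-10 * ngrid[j + 1])$root
      v <- c(0, 0); v[axis] <- root
      add(classify_fixed_point(v, world, trunc))
    }
  }

  # interior fixed points: damped Newton, multi-start
  if (is.null(seed_grid)) {
    seed_grid <- expand.grid(nbar = dsphi * sig * c(0.4, 1),
                             xbar_1 = c(0.25, 0.5, 0.75))
  }
  seed_grid <- as.matrix(seed_grid)
  if (!is.null(isoclines)) {
    seed_grid <- rbind(seed_grid, .isocline_intersections(isoclines))
  }
  n_cap <- 3 * dsphi * sig + 50
  for (r in seq_len(nrow(seed_grid))) {
    nb <- seed_grid[r, 1]; x1 <- seed_grid[r, 2]
    v <- c(nb * x1, nb * (1 - x1))
    sol <- .newton_fixed_point(v, world, trunc, tol_res, n_cap = n_cap)
    if (is.null(sol)) next
    if (any(sol < 1e-8 * max(sum(sol), 1))) next  # drifted to a boundary
    add(classify_fixed_point(sol, world, trunc))
  }

  # deduplicate (relative distance on counts)
  keep <- list()
  for (fp in found) {
    dup <- FALSE
    for (kp in keep) {
      scale <- max(sum(fp$counts), sum(kp$counts), 1e-12)
      if (max(abs(fp$counts - kp$counts)) / scale < dedupe_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep[[length(keep) + 1L]] <- fp
  }
  structure(keep, class = "fixed_point_list")
}

#' @export
print.fixed_point_list <- function(x, ...) {
  cat(sprintf("%d fixed point(s):\n", length(x)))
  for (fp in x) print(fp)
  invisible(x)
}

# Near-intersections of two isocline curves: grid compositions where both
# curves have points, seeded at the midpoint of the closest nbar pair.
.isocline_intersections <- function(isoclines) {
  stopifnot(length(isoclines) == 2L)
  a <- as.data.frame(isoclines[[1]]); b <- as.data.frame(isoclines[[2]])
  xs <- intersect(unique(a$xbar_1), unique(b$xbar_1))
  out <- lapply(xs, function(x) {
    na <- a$nbar[a$xbar_1 == x]; nb <- b$nbar[b$xbar_1 == x]
    dd <- abs(outer(na, nb, "-"))
    j <- arrayInd(which.min(dd), dim(dd))
    if (dd[j] / max(na[j[1]], nb[j[2]]) < 0.5)
      c(nbar = (na[j[1]] + nb[j[2]]) / 2, xbar_1 = x)
    else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

# Damped Newton iteration on G(v) = F(v) - v; returns counts or NULL.
# Steps are clamped and the search aborts if the iterate leaves [0, n_cap]
# to keep the memoised lattice bounded.
.newton_fixed_point <- function(v, world, trunc, tol_res, max_iter = 30L,
                                n_cap = Inf) {
  v <- unname(v)
  scale <- function(v) max(sum(v), 1e-8)
  G <- function(v) .map_eval(v, world, trunc) - v
  g <- G(v)
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < tol_res * scale(v)) return(v)
    J <- .map_jacobian(v, world, trunc, richardson = FALSE)$jacobian -
      diag(length(v))
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    clamp <- max(0.5 * sum(v), 5)
    if (max(abs(step)) > clamp) step <- step * clamp / max(abs(step))
    lam <- 1
    repeat {
      v_new <- pmax(v + lam * step, 0)
      g_new <- G(v_new)
      if (max(abs(g_new)) < max(abs(g)) || lam < 1 / 256) break
      lam <- lam / 2
    }
    if (sum(v_new) > n_cap) return(NULL)
    if (max(abs(v_new - v)) < 1e-14 * scale(v)) {
      v <- v_new; g <- g_new; break
    }
    v <- v_new; g <- g_new
  }
  if (max(abs(g)) < 1e3 * tol_res * scale(v)) v else NULL
}

#' Detect a limit cycle of the cycle map
#'
#' Iterates the two-strain map from a starting state and tests whether the
#' orbit settles on a closed invariant curve, as expected beyond a
#' Neimark-Sacker bifurcation: the orbit must stay bounded away from
#' extinction and fixation, fail to converge to a point (state change above
#' `conv_tol` over the last tenth of the iterations), and revisit a
#' Poincare-like angular section around the orbit centroid with consistent
#' radius (coefficient of variation below `radius_tol`).
#'
#' @param world A two-strain [world_config()].
#' @param start Starting state: `mean_state`, counts vector, or
#'   `c(nbar, xbar_1)` named vector.
#' @param max_cycles Number of map iterations.
#' @param trunc A [truncation_policy()].
#' @param conv_tol Relative per-cycle change under which the orbit is
#'   declared converged to a fixed point.
#' @param radius_tol Allowed coefficient of variation of section radii.
#' @return A list with `type` (`"limit_cycle"` or `"none"`), `terminal`
#'   (`"limit_cycle"`, `"fixed_point"`, `"extinction"` or `"fixation"`),
#'   the terminal state, the orbit tail as a data frame, and for limit
#'   cycles the section radii.
#' @export
detect_limit_cycle <- function(world, start, max_cycles = 5000L,
                               trunc = truncation_policy(),
                               conv_tol = 1e-8, radius_tol = 0.01) {
  .check_two_strains(world)
  v <- if (inherits(start, "mean_state")) start$mean_counts
  else if (!is.null(names(start)) && all(c("nbar", "xbar_1") %in% names(start)))
    c(start[["nbar"]] * start[["xbar_1"]],
      start[["nbar"]] * (1 - start[["xbar_1"]]))
  else as.numeric(start)
  stopifnot(length(v) == 2, all(v >= 0))

  orbit <- matrix(NA_real_, max_cycles + 1L, 2L)
  orbit[1, ] <- v
  for (tau in seq_len(max_cycles)) {
    v <- .map_eval(v, world, trunc)
    orbit[tau + 1L, ] <- v
    if (sum(v) < 1e-9) {
      return(list(type = "none", terminal = "extinction", state = v,
                  orbit = NULL))
    }
  }
  nbar <- rowSums(orbit)
  x1 <- orbit[, 1] / nbar

  tail_n <- max(50L, ceiling(max_cycles / 10))
  ti <- seq(max_cycles + 1L - tail_n + 1L, max_cycles + 1L)
  tail_df <- data.frame(cycle = ti - 1L, nbar = nbar[ti], xbar_1 = x1[ti])

  if (min(x1[ti]) < 1e-3 || max(x1[ti]) > 1 - 1e-3)
    return(list(type = "none", terminal = "fixation", state = v,
                orbit = tail_df))

  step_rel <- abs(diff(nbar[ti])) / nbar[ti][-1] + abs(diff(x1[ti]))
  if (max(step_rel) < conv_tol)
    return(list(type = "none", terminal = "fixed_point", state = v,
                orbit = tail_df))

  # Poincare-like section through the orbit centroid, standardised coords
  zc <- scale(cbind(nbar[ti], x1[ti]))
  if (any(attr(zc, "scaled:scale") == 0))
    return(list(type = "none", terminal = "degenerate", state = v,
                orbit = tail_df))
  theta <- atan2(zc[, 2], zc[, 1])
  r <- sqrt(rowSums(zc^2))
  radii <- c()
  for (j in seq_len(nrow(zc) - 1)) {
    dth <- theta[j + 1] - theta[j]
    # crossing of the ray theta = 0, in either rotation direction
    if (abs(dth) < pi && theta[j] * theta[j + 1] <= 0 && theta[j] != theta[j + 1]) {
      w <- -theta[j] / dth
      radii <- c(radii, (1 - w) * r[j] + w * r[j + 1])
    }
  }
  if (length(radii) >= 3 &&
      stats::sd(radii) / mean(radii) < radius_tol) {
    return(list(type = "limit_cycle", terminal = "limit_cycle", state = v,
                orbit = tail_df, radii = radii))
  }
  list(type = "none", terminal = "nonconvergent", state = v, orbit = tail_df)
}
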