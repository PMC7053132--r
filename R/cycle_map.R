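#' Mean state of the cycle map
#'
#' The deterministic map between cycles acts on the vector of per-strain
#' mean inoculum sizes.  Total size `nbar` and composition `xbar` are
#' derived views.
#'
#' @param mean_counts Numeric vector of per-strain mean inoculum sizes
#'   (`>= 0`, real-valued).
#' @return An object of class `mean_state`.
#' @export
mean_state <- function(mean_counts) {
  stopifnot(is.numeric(mean_counts), length(mean_counts) >= 1L)
  if (any(!is.finite(mean_counts)) || any(mean_counts < 0))
    stop("mean inoculum sizes must be finite and >= 0")
  structure(list(mean_counts = as.numeric(mean_counts)), class = "mean_state")
}

#' @rdname mean_state
#' @param state A `mean_state` (or bare numeric vector).
#' @export
nbar_total <- function(state) sum(.state_counts(state))

#' @rdname mean_state
#' @export
xbar <- function(state) {
  m <- .state_counts(state)
  tot <- sum(m)
  if (tot <= 0) return(rep(NA_real_, length(m)))
  m / tot
}

.state_counts <- function(state) {
  if (inherits(state, "mean_state")) state$mean_counts
  else if (is.numeric(state)) as.numeric(state)
  else stop("expected a mean_state or numeric vector")
}

#' @export
print.mean_state <- function(x, ...) {
  tot <- nbar_total(x)
  cat(sprintf("<mean_state> nbar = %g", tot))
  if (length(x$mean_counts) > 1 && tot > 0)
    cat(sprintf(", xbar = (%s)", paste(signif(xbar(x), 5), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Truncation policy for the Poisson expectation lattice
#'
#' The expectation over Poisson-seeded inocula is an infinite lattice sum;
#' it is truncated so that the neglected probability mass stays below
#' `mass_tolerance`.  Per-strain support is `[0, U_i]` with `U_i` the
#' smaller of the Poisson quantile at the requested mass and a hard cap
#' `ceiling(m + 10*sqrt(m + 1) + 10)` for mean `m`.
#'
#' @param mass_tolerance Maximum neglected Poisson probability mass
#'   (in `(0, 1e-3)`).
#' @param max_lattice Cap on the total number of lattice points.
#' @return An object of class `truncation_policy`.
#' @export
truncation_policy <- function(mass_tolerance = 1e-12, max_lattice = 4e6) {
  stopifnot(is.numeric(mass_tolerance), length(mass_tolerance) == 1L)
  if (!(mass_tolerance > 0 && mass_tolerance < 1e-3))
    stop("'mass_tolerance' must lie in (0, 1e-3)")
  stopifnot(is.numeric(max_lattice), max_lattice >= 10)
  structure(list(mass_tolerance = mass_tolerance, max_lattice = max_lattice),
            class = "truncation_policy")
}

# per-strain support upper bounds for Poisson means m; means of zero get
# the single support point {0}
.support_upper <- function(m, k, trunc) {
  cap <- ceiling(m + 10 * sqrt(m + 1) + 10)
  umass <- stats::qpois(trunc$mass_tolerance / (2 * k), m, lower.tail = FALSE)
  pmin(cap, umass)
}

# Core expectation: E[N_i] over the truncated Poisson lattice, plus the
# pieces shared with the Price decomposition.
.expected_finals <- function(mvec, world, trunc, want_block = FALSE) {
  k <- .n_strains(world)
  stopifnot(length(mvec) == k)
  if (all(mvec == 0) && !want_block) {
    return(list(EN = rep(0, k), neglected = 0, lattice_points = 1L))
  }
  upper <- .support_upper(mvec, k, trunc)
  blocks <- .ensure_lattice(world, upper, trunc$max_lattice)
  pl <- lapply(seq_len(k), function(i) stats::dpois(0:upper[i], mvec[i]))
  W <- array(Reduce(`%o%`, pl), dim = upper + 1L)
  EN <- vapply(seq_len(k), function(i) sum(W * blocks[[i]]), numeric(1))
  neglected <- 1 - prod(vapply(seq_len(k), function(i)
    stats::ppois(upper[i], mvec[i]), numeric(1)))
  out <- list(EN = EN, neglected = neglected,
              lattice_points = prod(upper + 1L))
  if (want_block) { out$W <- W; out$blocks <- blocks; out$upper <- upper }
  out
}

#' Expected final deme sizes under Poisson seeding
#'
#' Computes the per-strain expectation of final population sizes at mixing,
#' averaged over demes seeded with independent Poisson inoculum counts with
#' the given means: the lattice sum of seeding probabilities times
#' within-deme growth outcomes.  Growth results are memoised on the integer
#' lattice, so repeated calls for the same world share all work.
#'
#' @param state A [mean_state()] (or numeric vector of means).
#' @param world A [world_config()].
#' @param trunc A [truncation_policy()].
#' @return Numeric vector of expected final sizes, with attributes
#'   `neglected_mass` (upper bound on the discarded Poisson probability)
#'   and `lattice_points`.
#' @export
expected_final_sizes <- function(state, world, trunc = truncation_policy()) {
  stopifnot(inherits(world, "world_config"), inherits(trunc, "truncation_policy"))
  res <- .expected_finals(.state_counts(state), world, trunc)
  structure(res$EN, neglected_mass = res$neglected,
            lattice_points = res$lattice_points)
}

#' One cycle of the mean-inoculum map
#'
#' Applies one full cycle of growth, pooling and dilution to the mean
#' inoculum vector: the next means are `d` times the expected final sizes
#' under Poisson seeding.
#'
#' @inheritParams expected_final_sizes
#' @return The next [mean_state()].
#' @examples
#' w <- world_config(strain_params(), s0_phi = 1e5, t_mix = 24, d = 6e-4)
#' cycle_step(mean_state(10), w)
#' @export
cycle_step <- function(state, world, trunc = truncation_policy()) {
  EN <- expected_final_sizes(state, world, trunc)
  mean_state(world$d * as.numeric(EN))
}

# bare-vector map for the phase-plane machinery: v -> d * E[N | v]
.map_eval <- function(v, world, trunc) {
  world$d * .expected_finals(v, world, trunc)$EN
}

#' Iterate the cycle map
#'
#' Repeatedly applies [cycle_step()], optionally stopping early once
#' successive states differ by less than a relative tolerance.
#'
#' @inheritParams expected_final_sizes
#' @param n_cycles Maximum number of cycles (`>= 1`).
#' @param tol Early-stopping tolerance: iteration stops when the maximum
#'   relative change of the mean counts over one cycle drops below `tol`.
#'   Set to `0` to always run `n_cycles` cycles.
#' @return An object of class `cycle_trajectory`: a data frame with columns
#'   `cycle`, `nbar_i`, `nbar_total` and `xbar_i`, with the final
#'   `mean_state` in attribute `final_state` and a `converged` attribute.
#' @export
iterate_cycles <- function(state, world, n_cycles,
                           trunc = truncation_policy(), tol = 1e-10) {
  stopifnot(n_cycles >= 1)
  m <- .state_counts(state)
  k <- length(m)
  out <- matrix(NA_real_, n_cycles + 1, k)
  out[1, ] <- m
  converged <- FALSE
  done <- n_cycles
  for (tau in seq_len(n_cycles)) {
    m_new <- world$d * .expected_finals(m, world, trunc)$EN
    out[tau + 1, ] <- m_new
    rel <- abs(m_new - m) / pmax(abs(m), 1e-300)
    rel[m == 0 & m_new == 0] <- 0
    m <- m_new
    if (max(rel) < tol) { converged <- TRUE; done <- tau; break }
  }
  out <- out[seq_len(done + 1), , drop = FALSE]
  df <- as.data.frame(out)
  names(df) <- paste0("nbar_", seq_len(k))
  df <- cbind(cycle = 0:done, df)
  df$nbar_total <- rowSums(out)
  for (i in seq_len(k))
    df[[paste0("xbar_", i)]] <- ifelse(df$nbar_total > 0,
                                       out[, i] / df$nbar_total, NA_real_)
  structure(df, final_state = mean_state(m), converged = converged,
            class = c("cycle_trajectory", "data.frame"))
}

#' Price-equation decomposition of the composition change
#'
#' Splits the one-cycle change of the mean composition of each strain into
#' a within-deme selection term (the seeding-averaged change of the local
#' fraction during growth) and a between-deme covariance term (covariance of
#' the local fraction with relative final deme size):
#' `delta_xbar = <Delta X> + Cov[X, N/<N>]`.
#'
#' Empty demes (inoculum 0) carry no cells into the pool; they are assigned
#' the pool composition `X := xbar` and `Delta X := 0`, which makes the
#' decomposition an exact algebraic identity on the truncated ensemble.
#' Composition averages use the normalised truncated Poisson measure.
#'
#' @inheritParams expected_final_sizes
#' @return An object of class `price_terms`: a data frame with one row per
#'   strain and columns `strain`, `delta_xbar`, `within`, `covariance`.
#' @export
price_decomposition <- function(state, world, trunc = truncation_policy()) {
  m <- .state_counts(state)
  k <- .n_strains(world)
  stopifnot(length(m) == k)
  tot <- sum(m)
  if (tot <= 0) stop("composition is undefined for an empty mean state (nbar = 0)")
  xb <- m / tot

  res <- .expected_finals(m, world, trunc, want_block = TRUE)
  W <- res$W
  Wn <- W / sum(W)

  N_tot <- Reduce(`+`, res$blocks)
  n_tot <- Reduce(`+`, lapply(seq_len(k), function(i) slice.index(W, i) - 1))

  ENn <- sum(Wn * N_tot)
  if (ENn <= 0) stop("expected pooled population is zero; composition change undefined")

  delta_xbar <- within <- covariance <- numeric(k)
  for (i in seq_len(k)) {
    ni <- slice.index(W, i) - 1
    xi <- ifelse(n_tot > 0, ni / pmax(n_tot, 1), xb[i])
    Xi <- ifelse(N_tot > 0, res$blocks[[i]] / pmax(N_tot, 1e-300), xi)
    Xi[n_tot == 0] <- xb[i]
    EX <- sum(Wn * Xi)
    ENX <- sum(Wn * Xi * N_tot)
    xbar_next <- ENX / ENn
    delta_xbar[i] <- xbar_next - xb[i]
    within[i] <- sum(Wn * (Xi - xi))
    covariance[i] <- xbar_next - EX
  }

  structure(data.frame(strain = seq_len(k), delta_xbar = delta_xbar,
                       within = within, covariance = covariance),
            neglected_mass = res$neglected,
            class = c("price_terms", "data.frame"))
}
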