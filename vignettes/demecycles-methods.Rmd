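---
title: "Multilevel selection in structured habitats: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection in structured habitats: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demecycles)
```

## The model

`demecycles` simulates microbial strains living through repeated cycles of
compartmentalised growth and global mixing — the situation of tidal pools
refilled at high tide, or droplet cultures that are pooled, diluted, and
re-emulsified.  Each cycle has two phases.

**Growth phase.**  A deme seeded with integer founder counts $n_i$ grows on
a single shared resource,
$$\dot N_i = \alpha_i N_i, \qquad
  \dot S = -\sum_i \alpha_i N_i / \varphi_i ,$$
with growth rates $\alpha_i$ and yields $\varphi_i$.  Growth stops when the
resource is depleted.  Strain differences are small relative deviations
from the strain averages,
$\alpha_i = \alpha(1+\delta\alpha_i)A(t)$ and
$\varphi_i = \varphi(1+\delta\varphi_i)Y(t)$, where $A(t)$ and $Y(t)$
carry the influence of the shared environment.  Everything is
nondimensionalised: $\alpha = 1$ sets the time unit (so `t_mix` is
$\alpha T_\mathrm{mix}$), $\varphi = 1$ sets the substrate unit (so
`s0_phi` is $S_0\varphi$, the number of cells the fresh medium can
produce).  Note that the deviations are defined against the *strain
average*: a two-strain system described by "$\delta\alpha_1$,
$\delta\varphi_1$" implies strain 2 carries the mirrored deviations.
`two_strain_world()` builds exactly that configuration.

Three interaction models set $A$ and $Y$:

* **base** — $A = Y = 1$; strains interact only through the shared
  resource.
* **antibiotics** — an antibiotic at concentration $b$ (in units of the
  minimal inhibitory concentration, MIC) rescales every growth rate by the
  Hill factor $A(b) = (1-b^{\kappa})/(1+b^{\kappa}/\gamma)$: growth at
  $b<1$, death at $b>1$, saturating at death rate $-\gamma$.  Producer
  cells degrade it, $\dot b = -\rho_1 N_1 b$.  Survival of a deme is a race
  between degradation and antibiotic-induced death, and depends on the
  number of producers seeded.
* **pyoverdine** — a siderophore accumulates, $\dot P = \rho_1 N_1$, and
  raises everyone's effective yield by
  $Y(P) = \sigma - (\sigma-1)e^{-P}$, saturating at $\sigma$.

**Mixing phase.**  All demes are pooled, diluted by a factor $d$, and
reseeded.  With many demes, founder counts are independent Poisson draws
per strain, so the cycle-to-cycle dynamics close on the vector of *mean*
inoculum sizes:
$$\bar{\mathbf n}^{(\tau+1)} \;=\; d \sum_{\mathbf n}
  P[\mathbf n \mid \bar{\mathbf n}^{(\tau)}]\; \mathbf N(T_\mathrm{mix};
  \mathbf n).$$
`cycle_step()` evaluates this expectation exactly on a truncated integer
lattice; `iterate_cycles()` follows it over cycles.

**Price decomposition.**  The one-cycle change of the mean composition
splits exactly into within-deme selection and between-deme selection,
$$\Delta\bar x_i = \langle \Delta X_i\rangle +
  \mathrm{Cov}[X_i,\, N/\langle N\rangle],$$
computed by `price_decomposition()`.  Simpson's paradox is the regime
where the first term is negative (the strain loses inside every deme) but
the covariance term wins, so its pooled frequency still rises;
`find_simpsons_paradox()` searches mean states for it.

## Parameters that matter

| Parameter | Meaning | Typical value here |
|---|---|---|
| `s0_phi` | resource supply per deme, in cells | $10^5$ |
| `t_mix` | rescaled mixing time $\alpha T_\mathrm{mix}$ | 24 |
| `d` | dilution factor per cycle | chosen so $dS_0\varphi$ is 1.2–60 |
| `delta_alpha_1`, `delta_phi_1` | strain-1 trait deviations from the average | $10^{-3}$–$0.3$ |
| `rho` | public-good production rate per cell, per unit time | $10^{-3}$–$5\times10^{-3}$ |
| `b0`, `kappa`, `gamma` | initial antibiotic (MIC units), Hill steepness, maximal death rate | 1.25, 2, 2 |
| `sigma` | maximal yield enhancement | 2 |

The product $dS_0\varphi$ is the *dilution line*: the equilibrium mean
inoculum of a uniform population, where dilution balances regrowth to
capacity.  It controls the population-size isocline almost independently
of the trait differences, which control the composition isocline — this
decoupling is what makes coexistence easy to engineer in this habitat
structure, and it is reproduced exactly by the numerical isoclines
(doubling `d` doubles the population isocline and leaves the composition
isocline untouched).

## Numerical choices

* **Within-deme integration** uses `deSolve`'s `lsodar` with a compiled
  right-hand side, relative tolerance $10^{-8}$ and absolute tolerance
  $10^{-10}$, and a root function that terminates the growth phase when
  the substrate hits zero; sizes are frozen afterwards.  For the base
  interaction the dynamics have an exact closed form (exponential growth
  up to a depletion time found by a safeguarded Newton iteration), which
  serves both as the production path for lattice sums and as an
  independent oracle for the integrator: the two agree to $10^{-6}$
  relative on a grid of inocula and trait deviations (see the test
  suite).
* **Resource consumption by dying cells** is clamped to zero by default
  (a strain with negative effective growth rate does not return substrate
  to the medium); the literal signed term can be selected with
  `consumption = "literal"`.  The model text does not fix this sign
  convention; clamping is the physical reading.
* **Poisson truncation.**  Per-strain support is cut at the smaller of
  the Poisson quantile leaving mass below `mass_tolerance` (default
  $10^{-12}$) and a hard cap $m + 10\sqrt{m+1} + 10$.  The default is
  deliberately tight so that the Price identity, which is algebraically
  exact on the *normalised* truncated ensemble, also agrees with the raw
  one-cycle composition change to better than $10^{-10}$.  Composition
  averages always use the normalised measure; absolute expectations use
  the raw truncated measure and report the neglected mass.
* **Empty demes** in the Price decomposition are assigned the pool
  composition ($X := \bar x$, $\Delta X := 0$).  They carry no cells, so
  this convention is unobservable in the pooled state, and it makes the
  decomposition identity exact.
* **Public goods are reset each cycle**: $b(0) = b_0$ in every deme
  (the antibiotic is supplied with the fresh medium) and $P(0) = 0$
  (no pyoverdine carry-over; the source text leaves this open, and fresh
  medium is the natural reading).
* **Memoisation.**  Growth outcomes are deterministic in (inoculum,
  world), so they are cached per world on the integer lattice and shared
  by the expectation map, the Price terms, the Monte Carlo ensemble and
  all phase-plane machinery.  Worlds should be treated as immutable.
* **Fixed points** are found by damped Newton iteration on
  $F(\mathbf v) - \mathbf v$ with finite-difference Jacobians (steps
  $10^{-4}$ relative; a Richardson step-halving check is applied when
  classifying).  Stability uses the discrete-map criterion $|\lambda|<1$,
  with a marginal band of $10^{-6}$ around the unit circle.  Boundary
  states keep their transverse eigenvalue, which is the invasion
  criterion of the missing strain.
* **Limit cycles** are declared when an orbit stays bounded away from
  extinction and fixation, does not converge (per-cycle change above
  $10^{-8}$ in the final tenth of the iterations), and crosses a
  Poincaré-style angular section with radii consistent to 1%.
* **Outcome classification.**  `classify_outcome()` combines trajectories
  with mutual invasibility: each strain's per-cycle growth factor when
  rare against the other's resident equilibrium.  Both multipliers above
  1 is protected coexistence.  Scans default to the invasion criterion
  because it is fast, deterministic, and agrees with trajectory
  classification on clear-cut cells (tested); trajectory evidence is used
  for bistable and non-equilibrium cases.  Coexistence requires an
  interior attractor with composition at least $10^{-3}$ away from the
  boundaries.

## Study conditions used in the tests

The quantitative checks run at the parameter sets quoted above with
$S_0\varphi = 10^5$ and $\alpha T_\mathrm{mix} = 24$ throughout.  Two
dilution regimes appear:

* $dS_0\varphi = 60$ ($d = 6\times10^{-4}$) for the dilution-line,
  pyoverdine and antibiotics phase-plane analyses.  The collective
  antibiotic resistance system then shows the full bifurcation sequence
  as the producer cost $|\delta\alpha_1|$ decreases from $10^{-1}$ to
  $10^{-3}$: no interior fixed point (only extinction and producer
  fixation) at high cost, an unstable interior point on the
  antibiotics-limited isocline branch, a Neimark–Sacker transition with a
  complex eigenvalue pair crossing the unit circle near
  $\delta\alpha_1 \approx -4.5\times10^{-3}$ (located by bisection at run
  time, never assumed), a stable limit cycle just beyond it, and a stable
  coexistence spiral/node once the intersection sits on the resource-limited
  dilution line.
* $dS_0\varphi = 1.2$ ($d = 1.2\times10^{-5}$) for the metabolic
  trade-off coexistence scan.  The trade-off mechanism lives on
  single-founder demes — the efficient strain persists through demes it
  seeds alone — so the mean founder number must be of order one, i.e.
  $dS_0\varphi$ just above the persistence threshold
  $dS_0\varphi = 1$.  In this regime the coexistence region forms bands
  in $\delta\varphi_1$ whose boundaries barely move with
  $\delta\alpha_1$ in the large-trade-off regime (measured shifts of
  roughly 5% and 13% for the lower and upper boundary across
  $\delta\alpha_1 = -0.15 \to -0.3$), while the small-trade-off band is
  much narrower — it requires a fine balance of cost and benefit.

Monte Carlo validation (`simulate_ensemble()`) uses $10^4$ demes for 30
cycles per interaction model and compares each cycle's pooled means
against the expectation map's one-step prediction from the previous
pooled state — the sharp test of the map, since deviations are then pure
finite-$M$ sampling noise with standard errors estimated from the demes
themselves.  Scan grids are $20\times20$; these sizes keep the full suite
in minutes on one CPU while leaving all conclusions unchanged at finer
resolution (halving the truncation tolerance or refining grids moves
results by less than the stated tolerances).

## What the simulations do and do not emulate

All data are self-generated: the model *is* the study system, and the
tests probe internal consistency (closed forms vs. integrator,
expectation map vs. finite-deme sampling, classification vs. iterated
dynamics) plus the characteristic phenomena: the dilution line, the
σ-fold pyoverdine enhancement, MIC anchors of the dose response, the
exact Price identity, Simpson's paradox, the stability transition, and
the structure of the coexistence region.  Real microbial habitats
violate several idealisations: demes are perfectly isolated during
growth and perfectly mixed between cycles (no partial dispersal or
spatial gradients), mixing time is constant, there is a single resource,
cell death is absent outside antibiotic action, and within-deme growth is
deterministic (demographic noise enters only through Poisson seeding).
Passing tests therefore validate the cycle-map machinery and its
mathematical consequences, not the fidelity of any particular microbial
system.

## Known limitations

* Expectation lattice sums are exact but scale with the product of
  per-strain supports; systems with more than two strains or mean
  inocula of several hundred cells hit the configurable lattice cap, and
  `simulate_ensemble()` is then the practical tool.
* The closed-form isocline approximations for the public-goods
  interactions are scaling relations with calibratable prefactors
  (`calibrate_constants()`); their exponents are validated against the
  numerical isoclines, their prefactors are not theory.
* Near the Neimark–Sacker transition, transients decay like
  $|\lambda|^{\tau}$ with $|\lambda|$ close to 1, so limit-cycle
  detection needs a few thousand cycles to settle.
* The antibiotics all-or-nothing deme outcome is sharp only when
  `t_mix` comfortably exceeds the recovery time; at `t_mix = 24` a
  narrow window of founder numbers recovers too late to deplete fully.
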