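# Shared world constructors for the test suite.  Standard study conditions:
# s0_phi = 1e5, alpha*T_mix = 24; dilution chosen per scenario.

base_world1 <- function(d = 6e-4, s0_phi = 1e5, ...)
  world_config(strain_params(), s0_phi = s0_phi, t_mix = 24, d = d, ...)

# two neutral strains
neutral_world2 <- function(d = 6e-4)
  world_config(list(strain_params(), strain_params()),
               s0_phi = 1e5, t_mix = 24, d = d)

# antibiotics interaction with the dose-response shape used in the
# collective-resistance phase planes (b0 = 1.25, kappa = gamma = 2,
# rho_1/alpha = 5e-3)
ab_world <- function(delta_alpha_1 = -0.005, d = 6e-4, rho_1 = 5e-3,
                     b0 = 1.25, ...)
  two_strain_world(delta_alpha_1 = delta_alpha_1, rho_1 = rho_1,
                   s0_phi = 1e5, t_mix = 24, d = d,
                   interaction = antibiotic_params(b0, 2, 2), ...)

# pyoverdine interaction (sigma = 2, rho_1/alpha = 1e-3)
pyo_world <- function(delta_alpha_1 = -1e-3, d = 6e-4, rho_1 = 1e-3,
                      sigma = 2)
  two_strain_world(delta_alpha_1 = delta_alpha_1, rho_1 = rho_1,
                   s0_phi = 1e5, t_mix = 24, d = d,
                   interaction = pyoverdine_params(sigma))

# random small worlds for property-style tests (means kept modest so the
# Poisson lattices stay small)
random_world <- function(kind) {
  s1 <- strain_params(delta_alpha = runif(1, -0.05, 0),
                      delta_phi = runif(1, -0.1, 0.1),
                      rho = if (kind == "base") 0 else 10^runif(1, -3, -2.3))
  s2 <- strain_params(delta_alpha = -s1$delta_alpha,
                      delta_phi = -s1$delta_phi)
  inter <- switch(kind,
                  base = "base",
                  antibiotics = antibiotic_params(runif(1, 1.05, 1.5), 2, 2),
                  pyoverdine = pyoverdine_params(runif(1, 1.2, 3)))
  world_config(list(s1, s2), s0_phi = 10^runif(1, 3.5, 5), t_mix = 24,
               d = 10^runif(1, -4, -3), interaction = inter)
}
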