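# Default cantilever used throughout: 10 mm free length x 10 mm width,
# 200 um thick, 12 kPa gel, incompressible, in water.
default_beam <- function(E = 12e3, mu = 1e-3)
  beam_spec(L0 = 10e-3, b = 10e-3, h = 200e-6, E = E, nu = 0.5, mu = mu)

# Independent oracle: solve the instantaneous power balance
#   Ebar I c cdot L0 = int pm wdot dx + int pd wdot dx - Fcell Ldot
# for Fcell by numeric quadrature of the two integrals. Stays clear of the
# closed form used by cell_force().
oracle_cell_force <- function(W, Wdot, p_m, beam) {
  Ebar <- beam$E / (1 - beam$nu^2)
  I <- beam$b * beam$h^3 / 12
  L0 <- beam$L0
  cc <- 2 * W / L0^2
  cdot <- 2 * Wdot / L0^2
  wdot <- function(x) Wdot * x^2 / L0^2
  k_d <- 3 * beam$mu * pi * (3 * beam$b + 2 * L0) / (5 * L0)
  I_m <- stats::integrate(function(x) p_m * wdot(x), 0, L0,
                          rel.tol = 1e-13)$value
  I_d <- stats::integrate(function(x) -k_d * wdot(x) * wdot(x), 0, L0,
                          rel.tol = 1e-13)$value
  Ldot <- Wdot * beam$h / L0
  (I_m + I_d - Ebar * I * cc * cdot * L0) / Ldot
}

# Random beam specs for property tests (kept thin and soft).
random_beam <- function() {
  beam_spec(L0 = runif(1, 5e-3, 20e-3), b = runif(1, 5e-3, 15e-3),
            h = runif(1, 1e-4, 4e-4), E = runif(1, 5e3, 30e3),
            nu = runif(1, 0, 0.5), mu = runif(1, 5e-4, 5e-3))
}

# Small protocol for fast tests.
small_protocol <- function(beam, eps = c(0, 0.5e-3, 1e-3), n_twitches = 2L,
                           label = "untreated")
  twitch_protocol(preload_pm = preload_pm_for_strain(eps, beam),
                  n_twitches = n_twitches, label = label)

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
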