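#' Cantilever beam specification
#'
#' Describes the geometry, material and fluid environment of one
#' magnetoresponsive hydrogel cantilever. All quantities are SI (m, Pa,
#' Pa·s); use [as_metres()] to convert tagged mm/µm inputs at the boundary.
#'
#' The derived quantities -- equivalent modulus `Ebar = E / (1 - nu^2)`,
#' second moment of area `I = b h^3 / 12`, drag coefficient and relaxation
#' time -- are always recomputed from the stored fields (see
#' [beam_constants()]); they are never stored, so they cannot go stale.
#'
#' @param L0 free (unclamped) length of the cantilever in metres.
#' @param b beam width in metres.
#' @param h beam thickness in metres.
#' @param E elastic modulus of the gel in pascals.
#' @param nu Poisson ratio (default 0.5, an incompressible gel). Must lie
#'   in `[0, 1)`.
#' @param mu dynamic viscosity of the surrounding fluid in Pa·s (default
#'   `1e-3`, water/PBS at room temperature). An effective viscosity larger
#'   than water may be used to emulate measured relaxation times.
#' @return An object of class `beam_spec`.
#' @examples
#' beam <- beam_spec(L0 = 10e-3, b = 10e-3, h = 200e-6, E = 12e3)
#' beam_constants(beam)
#' @export
beam_spec <- function(L0, b, h, E, nu = 0.5, mu = 1e-3) {
  for (nm in c("L0", "b", "h", "E", "nu", "mu")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("beam_spec: '", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (L0 <= 0 || b <= 0 || h <= 0 || E <= 0 || mu < 0)
    stop("beam_spec: L0, b, h, E must be > 0 and mu >= 0", call. = FALSE)
  if (nu < 0 || nu >= 1)
    stop("beam_spec: Poisson ratio must satisfy 0 <= nu < 1 (1 - nu^2 > 0)",
         call. = FALSE)
  slender <- h / L0
  if (slender > 0.5)
    stop("beam_spec: h/L0 = ", signif(slender, 3),
         " violates the thin-beam assumption (limit 0.5)", call. = FALSE)
  if (slender > 0.1)
    warning("beam_spec: h/L0 = ", signif(slender, 3),
            " > 0.1; thin-beam model is approximate", call. = FALSE)
  structure(list(L0 = L0, b = b, h = h, E = E, nu = nu, mu = mu),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  k <- beam_constants(x)
  cat("<beam_spec>\n")
  cat(sprintf("  L0 = %g mm, b = %g mm, h = %g um\n",
              x$L0 * 1e3, x$b * 1e3, x$h * 1e6))
  cat(sprintf("  E = %g kPa, nu = %g, mu = %g mPa.s\n",
              x$E / 1e3, x$nu, x$mu * 1e3))
  cat(sprintf("  Ebar = %g kPa, I = %g m^4, k_d = %g N.s/m^2, tau = %.1f ms\n",
              k$Ebar / 1e3, k$I, k$k_d, k$tau * 1e3))
  invisible(x)
}

is_beam_spec <- function(x) inherits(x, "beam_spec")

stopifnot_beam <- function(beam) {
  if (!is_beam_spec(beam))
    stop("expected a 'beam_spec' object; see beam_spec()", call. = FALSE)
  invisible(beam)
}

#' Derived mechanical constants of a beam
#'
#' @param beam a [beam_spec()].
#' @return A list with `Ebar` (equivalent modulus, Pa), `I` (second moment
#'   of area, m^4), `k_d` (drag coefficient, N·s/m^2) and `tau` (first-order
#'   relaxation time, s).
#' @export
beam_constants <- function(beam) {
  stopifnot_beam(beam)
  Ebar <- beam$E / (1 - beam$nu^2)
  I <- beam$b * beam$h^3 / 12
  k_d <- drag_coefficient(beam)
  list(Ebar = Ebar, I = I, k_d = k_d,
       tau = k_d * beam$L0^4 / (20 * Ebar * I))
}

# Hard/soft limits of the small-deflection model, |W|/L0.
.w_hard_limit <- 0.3
.w_warn_limit <- 0.1

check_deflection <- function(W, beam, warn = TRUE) {
  r <- max(abs(W)) / beam$L0
  if (!is.finite(r))
    stop("deflection contains non-finite values", call. = FALSE)
  if (r > .w_hard_limit)
    stop("deflection |W|/L0 = ", signif(r, 3),
         " exceeds the model validity limit ", .w_hard_limit, call. = FALSE)
  if (warn && r > .w_warn_limit)
    warning("deflection |W|/L0 = ", signif(r, 3),
            " > ", .w_warn_limit, "; small-deformation model is approximate",
            call. = FALSE)
  invisible(r)
}

#' Curvature from tip deflection
#'
#' Under the constant-curvature assumption the bent beam has curvature
#' `c = 2 W / L0^2`, equal to the mean curvature of the parabolic profile
#' `w(x) = W x^2 / L0^2`. Downward bending is positive.
#'
#' @param W tip deflection in metres (downward positive); vectorized.
#' @param beam a [beam_spec()].
#' @return Curvature in 1/m, same sign as `W`.
#' @export
curvature_from_tip <- function(W, beam) {
  stopifnot_beam(beam)
  check_deflection(W, beam)
  2 * W / beam$L0^2
}

#' Parabolic deflection profile
#'
#' Evaluates `w(x) = W x^2 / L0^2`, the assumed beam shape: clamped at
#' `x = 0`, tip deflection `W` at `x = L0`.
#'
#' @param W tip deflection (m, scalar).
#' @param beam a [beam_spec()].
#' @param x positions along the beam (m), each in `[0, L0]`.
#' @return Deflections `w(x)` (m).
#' @export
deflection_profile <- function(W, beam, x) {
  stopifnot_beam(beam)
  if (any(x < 0 | x > beam$L0))
    stop("x must lie within [0, L0]", call. = FALSE)
  W * x^2 / beam$L0^2
}

#' Cell-layer length change and strain
#'
#' The cell layer sits on the top surface; bending the beam downward by `W`
#' stretches it by `dL = W h / L0` (equivalently `L0 * c * h / 2`), giving
#' strain `eps = W h / L0^2`.
#'
#' @param W tip deflection (m, downward positive); vectorized.
#' @param beam a [beam_spec()].
#' @return A list with `dL` (m) and `eps` (dimensionless), same length as `W`.
#' @export
cell_layer_strain <- function(W, beam) {
  stopifnot_beam(beam)
  dL <- W * beam$h / beam$L0
  list(dL = dL, eps = dL / beam$L0)
}

#' Viscous drag coefficient of the beam
#'
#' Coefficient `k_d` of the local drag force density `p_d = -k_d * wdot`,
#' uniform along the beam: `k_d = 3 mu pi (3 b + 2 L0) / (5 L0)`.
#'
#' @param beam a [beam_spec()].
#' @return Drag coefficient in N·s/m^2.
#' @export
drag_coefficient <- function(beam) {
  stopifnot_beam(beam)
  3 * beam$mu * pi * (3 * beam$b + 2 * beam$L0) / (5 * beam$L0)
}

#' First-order relaxation time of the beam in fluid
#'
#' The quasi-static power balance reduces to a first-order linear ODE in
#' the tip deflection whose time constant is
#' `tau = k_d L0^4 / (20 Ebar I)`: larger viscosity slows relaxation,
#' a stiffer gel speeds it up.
#'
#' @param beam a [beam_spec()].
#' @return Relaxation time in seconds.
#' @export
relaxation_time <- function(beam) {
  k <- beam_constants(beam)
  k$tau
}

#' Cell-generated force from an instantaneous beam state
#'
#' Inverts the quasi-static energy (power) balance for the tension force
#' generated by the cell layer:
#' \deqn{F_{cell} = -\frac{\bar E b h^2}{3 L_0^2} W
#'   + \frac{p_m L_0^2}{3 h} - \frac{k_d L_0^2}{5 h} \dot W}
#' with `Ebar = E/(1-nu^2)` and `k_d` from [drag_coefficient()]. Positive
#' `F_cell` is contractile tension (pulls the tip upward); downward
#' deflection and magnetic pull are positive.
#'
#' The drag and magnetic coefficients are the exact result of substituting
#' the parabolic profile into the power balance and dividing by `Wdot`
#' (verified against numeric quadrature of the three power integrals).
#'
#' @param W tip deflection (m, downward positive); vectorized.
#' @param Wdot tip velocity (m/s); vectorized.
#' @param p_m magnetic force density along the beam (N/m, downward
#'   positive); vectorized.
#' @param beam a [beam_spec()].
#' @param check if `TRUE` (default) validate the deflection against the
#'   small-deformation limits.
#' @return Cell force in newtons (positive = tension).
#' @export
cell_force <- function(W, Wdot, p_m, beam, check = TRUE) {
  stopifnot_beam(beam)
  if (!all(is.finite(W), is.finite(Wdot), is.finite(p_m)))
    stop("cell_force: non-finite input", call. = FALSE)
  if (check) check_deflection(W, beam)
  k <- beam_constants(beam)
  L0 <- beam$L0; h <- beam$h
  -k$Ebar * beam$b * h^2 * W / (3 * L0^2) +
    p_m * L0^2 / (3 * h) -
    k$k_d * Wdot * L0^2 / (5 * h)
}

#' Magnetic force density from a static cell-free deflection
#'
#' Calibration step: with no cells and the beam held statically deflected
#' by `W_m` under a magnetic load alone, the uniform force density is
#' recovered from the deflection. Two inversion formulas are provided:
#'
#' * `"energy_consistent"` (default): `p_m = Ebar b h^3 W_m / L0^4`, the
#'   value that makes [cell_force()] vanish identically on the same static
#'   cell-free state, so the whole pipeline is internally consistent.
#' * `"uniform_load"`: `p_m = 2 W_m E b h^3 / (3 (1 - nu^2) L0^4)`, the
#'   classical uniformly loaded cantilever inversion `W = q L0^4/(8 Ebar I)`.
#'
#' The two differ by a constant factor: `uniform_load / energy_consistent`
#' is exactly 2/3 (the constant-curvature shape is stiffer than the true
#' quartic deflection shape of a uniformly loaded cantilever). Feeding the
#' `uniform_load` value back into [cell_force()] on the same static
#' cell-free state leaves a bias of `-Ebar b h^2 W_m / (9 L0^2)` instead of
#' zero; both modes are exposed so either convention can be reproduced.
#'
#' @param W_m static cell-free tip deflection (m); vectorized.
#' @param beam a [beam_spec()].
#' @param mode `"energy_consistent"` or `"uniform_load"`.
#' @return Magnetic force density in N/m.
#' @export
magnetic_density_from_static_deflection <- function(
    W_m, beam, mode = c("energy_consistent", "uniform_load")) {
  stopifnot_beam(beam)
  mode <- match.arg(mode)
  k <- beam_constants(beam)
  p <- k$Ebar * beam$b * beam$h^3 * W_m / beam$L0^4
  if (mode == "uniform_load") p <- p * 2 / 3
  p
}

#' Convert a tagged length to metres
#'
#' Boundary helper: configuration files carry lengths in mm or µm; the
#' package is SI-internal.
#'
#' @param x numeric value(s).
#' @param unit one of `"m"`, `"mm"`, `"um"`.
#' @return Value(s) in metres.
#' @export
as_metres <- function(x, unit = c("m", "mm", "um")) {
  unit <- match.arg(unit)
  x * switch(unit, m = 1, mm = 1e-3, um = 1e-6)
}
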