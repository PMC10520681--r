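#' Stack of cuboid permanent magnets
#'
#' The actuation magnets are identical cuboid blocks stacked coaxially on
#' a motor arm below the chamber (default: seven 10 mm x 10 mm x 5 mm
#' magnets with remanence ~1.2 T). The stack is modelled as a single
#' uniformly magnetized block of length `n * dims[3]`.
#'
#' @param n number of stacked magnets (>= 1).
#' @param dims edge lengths (m): in-plane `a`, `b` and axial thickness.
#' @param remanence remanent flux density (T).
#' @return An object of class `magnet_stack`.
#' @export
magnet_stack <- function(n = 7L, dims = c(10e-3, 10e-3, 5e-3),
                         remanence = 1.2) {
  n <- as.integer(n)
  if (n < 1L) stop("need at least one magnet", call. = FALSE)
  if (length(dims) != 3L || any(dims <= 0))
    stop("dims must be three positive edge lengths (m)", call. = FALSE)
  if (remanence <= 0) stop("remanence must be > 0", call. = FALSE)
  structure(list(n = n, dims = dims, remanence = remanence),
            class = "magnet_stack")
}

#' @export
print.magnet_stack <- function(x, ...) {
  cat(sprintf("<magnet_stack> %d x (%g x %g x %g mm), Br = %g T\n",
              x$n, x$dims[1] * 1e3, x$dims[2] * 1e3, x$dims[3] * 1e3,
              x$remanence))
  invisible(x)
}

#' On-axis flux density of the magnet stack
#'
#' Closed-form axial field of a uniformly magnetized cuboid, evaluated at
#' distance `d` from the near face:
#' \deqn{B(d) = \frac{B_r}{\pi}\left[\arctan\frac{ab}{2d\sqrt{4d^2+a^2+b^2}}
#'  - \arctan\frac{ab}{2D\sqrt{4D^2+a^2+b^2}}\right],\quad D = d + nL_z}
#' Strictly decreasing in `d`, with the dipole `d^{-3}` far field that the
#' cantilever platform exhibits.
#'
#' @param stack a [magnet_stack()].
#' @param d distance(s) from the near magnet face (m), `> 0`.
#' @return Flux density (T).
#' @export
axial_field <- function(stack, d) {
  if (!inherits(stack, "magnet_stack"))
    stop("expected a magnet_stack", call. = FALSE)
  if (any(d <= 0)) stop("d must be > 0 (measured from the near face)",
                        call. = FALSE)
  a <- stack$dims[1]; b <- stack$dims[2]
  L <- stack$n * stack$dims[3]
  term <- function(z) atan(a * b / (2 * z * sqrt(4 * z^2 + a^2 + b^2)))
  stack$remanence / pi * (term(d) - term(d + L))
}

# Numeric axial gradient dB/dd (central difference, relative step).
axial_field_gradient <- function(stack, d) {
  hh <- pmax(1e-6 * d, 1e-9)
  (axial_field(stack, d + hh) - axial_field(stack, d - hh)) / (2 * hh)
}

#' Magnetic force density on the beam vs. magnet distance
#'
#' The nanoparticle-laden gel behaves superparamagnetically: the body
#' force per unit beam length is proportional to `B * dB/dd`, scaled by a
#' single calibratable gain that absorbs particle loading and geometry.
#' This functional form is a modelling choice (the physical platform is
#' calibrated empirically); it has the correct `d^{-7}` dipole-limit decay.
#'
#' @param stack a [magnet_stack()].
#' @param d distance(s) from the near face (m).
#' @param gain non-negative scale factor (N/m per T^2/m).
#' @return Force density (N/m), non-negative and strictly decreasing in `d`.
#' @export
force_density_model <- function(stack, d, gain = 1) {
  if (gain < 0) stop("gain must be >= 0", call. = FALSE)
  gain * axial_field(stack, d) * (-axial_field_gradient(stack, d))
}

#' Build a magnet-distance calibration curve from cell-free deflections
#'
#' Converts static cell-free tip deflections `W_m(d)` measured at several
#' magnet distances into force densities via
#' [magnetic_density_from_static_deflection()], and fits a monotone
#' shape-preserving interpolant of `p_m` vs. `d`. When all densities are
#' positive the interpolation is done on log-log axes (exact for power-law
#' decay); evaluation outside the sampled range clamps to the end values
#' with a warning.
#'
#' @param d magnet distances (m), strictly increasing after sorting;
#'   duplicates are an error.
#' @param W_m matching cell-free static tip deflections (m).
#' @param beam a [beam_spec()].
#' @param mode calibration inversion mode, see
#'   [magnetic_density_from_static_deflection()].
#' @param tol fractional non-monotonicity tolerated in `W_m` vs. `d`
#'   before a calibration error is raised (measurement noise allowance).
#' @return A `calibration_curve` with a `samples` data.frame
#'   (`d`, `W_m`, `p_m`) and a `predict()` method.
#' @export
build_calibration <- function(d, W_m, beam,
                              mode = c("energy_consistent", "uniform_load"),
                              tol = 0.05) {
  stopifnot_beam(beam)
  mode <- match.arg(mode)
  if (length(d) != length(W_m) || length(d) < 3L)
    stop("need >= 3 (d, W_m) pairs", call. = FALSE)
  o <- order(d)
  d <- d[o]; W_m <- W_m[o]
  if (any(diff(d) <= 0))
    stop("calibration distances must be distinct", call. = FALSE)
  # deflection should shrink with distance, up to a noise allowance
  up <- diff(W_m) > tol * max(abs(W_m), 1e-12)
  if (any(up))
    stop("W_m increases with distance beyond tolerance: not a valid ",
         "cell-free calibration sweep", call. = FALSE)
  p_m <- magnetic_density_from_static_deflection(W_m, beam, mode)
  p_m <- pmax(p_m, 0)
  samples <- data.frame(d = d, W_m = W_m, p_m = p_m)
  # enforce non-increasing density before fitting the monotone interpolant
  # (small noise-driven inversions inside `tol` are flattened)
  p_fit <- cummin(p_m)
  fun <- if (all(p_fit > 0)) {
    # log-log axes: exact for power-law decay, the expected far-field form
    sf <- stats::splinefun(log(d), log(p_fit), method = "monoH.FC")
    function(x) exp(sf(log(x)))
  } else if (all(p_fit == 0)) {
    function(x) rep(0, length(x))
  } else {
    sf <- stats::splinefun(d, p_fit, method = "monoH.FC")
    function(x) pmax(sf(x), 0)
  }
  structure(list(samples = samples, mode = mode, beam = beam,
                 fun = fun),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<calibration_curve> %d points, d in [%g, %g] mm, mode %s\n",
              nrow(s), min(s$d) * 1e3, max(s$d) * 1e3, x$mode))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param object a `calibration_curve` from [build_calibration()].
#' @param d magnet distances (m) at which to evaluate.
#' @param ... unused.
#' @return Interpolated force densities (N/m); values outside the sampled
#'   range are clamped to the end samples with a warning.
#' @export
predict.calibration_curve <- function(object, d, ...) {
  s <- object$samples
  lo <- d < min(s$d); hi <- d > max(s$d)
  if (any(lo | hi))
    warning("distance outside calibrated range: clamped to end values",
            call. = FALSE)
  d2 <- pmin(pmax(d, min(s$d)), max(s$d))
  object$fun(d2)
}

#' Write / read a calibration curve (CSV + JSON metadata)
#'
#' @param cal a `calibration_curve`.
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @return The path (write) or a rebuilt `calibration_curve` (read).
#' @export
write_calibration <- function(cal, path) {
  s <- cal$samples
  utils::write.csv(data.frame(d_m = s$d, W_m_m = s$W_m,
                              p_m_N_per_m = s$p_m),
                   path, row.names = FALSE)
  jsonlite::write_json(list(mode = cal$mode, beam = unclass(cal$beam)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  need <- c("d_m", "W_m_m", "p_m_N_per_m")
  if (!all(need %in% names(df)))
    stop("calibration CSV must carry the units header: ",
         paste(need, collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  beam <- do.call(beam_spec, as.list(meta$beam))
  build_calibration(df$d_m, df$W_m_m, beam, mode = meta$mode)
}
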