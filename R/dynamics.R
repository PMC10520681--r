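#' Savitzky-Golay smoothing and differentiation
#'
#' Local least-squares polynomial filter with proper one-sided handling at
#' the series ends (the polynomial is fitted on the edge window and
#' evaluated, with its derivative, at the off-centre point). Used for the
#' smoothed tip-velocity estimate `Wdot`.
#'
#' @param y numeric series, uniformly sampled.
#' @param window odd window length in samples (>= poly + 1).
#' @param poly polynomial order (default 2).
#' @param deriv derivative order to return (0 = smoothing).
#' @param dt sample spacing, used to scale derivatives to physical units.
#' @return Numeric vector, same length as `y`.
#' @export
savitzky_golay <- function(y, window = 7L, poly = 2L, deriv = 0L, dt = 1) {
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) {
    # short series: single global fit
    window <- if (n %% 2L == 1L) n else n - 1L
    if (window < 2L) return(if (deriv == 0L) y else rep(0, n))
  }
  poly <- min(poly, window - 1L)
  if (deriv > poly) return(rep(0, n))
  m <- (window - 1L) %/% 2L
  X <- outer(seq.int(-m, m), 0:poly, `^`)
  P <- solve(crossprod(X), t(X))            # (poly+1) x window projector

  eval_row <- function(p) {
    # row vector giving f^(deriv)(p) from the fitted coefficients
    r <- numeric(poly + 1L)
    for (k in deriv:poly)
      r[k + 1L] <- prod(seq_len(deriv) + (k - deriv)) * p^(k - deriv)
    r
  }
  w0 <- drop(eval_row(0) %*% P)
  out <- numeric(n)
  mid <- stats::filter(y, rev(w0), sides = 2)
  out[] <- as.numeric(mid)
  # edges: same window anchored at the boundary, evaluated off-centre
  yl <- y[seq_len(window)]
  yr <- y[seq.int(n - window + 1L, n)]
  for (i in seq_len(m)) {
    out[i] <- drop(eval_row(i - m - 1L) %*% P %*% yl)
    out[n - m + i] <- drop(eval_row(i) %*% P %*% yr)
  }
  out / dt^deriv
}

# Apply savitzky_golay independently on segments delimited by `breaks`
# (indices that START a new segment). Keeps known discontinuities (magnet
# steps) from bleeding into the derivative estimate.
sg_segmented <- function(y, window, poly = 2L, deriv = 0L, dt = 1,
                         breaks = integer(0)) {
  n <- length(y)
  starts <- sort(unique(c(1L, breaks[breaks > 1L & breaks <= n])))
  ends <- c(starts[-1L] - 1L, n)
  out <- numeric(n)
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    out[idx] <- savitzky_golay(y[idx], window, poly, deriv, dt)
  }
  out
}

#' Per-frame deflection trace
#'
#' Container for a tip-deflection time series: time, deflection `W`
#' (downward positive), velocity `Wdot` and constant-curvature estimate
#' `c = 2 W / L0^2`, with the owning [beam_spec()] and a provenance tag.
#'
#' @param t time base (s), strictly increasing and uniform.
#' @param W tip deflection (m).
#' @param beam a [beam_spec()].
#' @param Wdot tip velocity (m/s); if `NULL` it is obtained by
#'   Savitzky-Golay differentiation (`sg_window` frames, quadratic).
#' @param provenance `"tracked"` or `"simulated"`.
#' @param sg_window smoothing window (frames) for the derivative fallback.
#' @param breaks optional indices starting new smoothing segments (known
#'   actuation discontinuities).
#' @param check validate the deflection magnitude against model limits.
#' @return A `deflection_trace`: data.frame with columns `t`, `W`, `Wdot`,
#'   `curvature` and attributes `beam`, `provenance`.
#' @export
deflection_trace <- function(t, W, beam, Wdot = NULL,
                             provenance = c("tracked", "simulated"),
                             sg_window = 7L, breaks = integer(0),
                             check = TRUE) {
  stopifnot_beam(beam)
  provenance <- match.arg(provenance)
  n <- length(t)
  if (length(W) != n || n < 2L)
    stop("t and W must have equal length >= 2", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt))
    stop("time base must be strictly increasing and uniform", call. = FALSE)
  if (check) check_deflection(W, beam)
  if (is.null(Wdot))
    Wdot <- sg_segmented(W, sg_window, poly = 3L, deriv = 1L,
                         dt = mean(dt), breaks = breaks)
  out <- data.frame(t = t, W = W, Wdot = Wdot,
                    curvature = 2 * W / beam$L0^2)
  structure(out, beam = beam, provenance = provenance,
            class = c("deflection_trace", "data.frame"))
}

#' @export
print.deflection_trace <- function(x, ...) {
  cat(sprintf("<deflection_trace> %d frames, %.3f s, provenance: %s\n",
              nrow(x), diff(range(x$t)), attr(x, "provenance")))
  cat(sprintf("  W range [%.3g, %.3g] mm\n",
              min(x$W) * 1e3, max(x$W) * 1e3))
  invisible(x)
}

#' Simulate the beam's deflection under given forces
#'
#' Integrates the first-order linear ODE obtained from the quasi-static
#' power balance,
#' \deqn{\frac{4 \bar E I}{L_0^3} W + \frac{k_d L_0}{5}\dot W =
#'   \frac{p_m L_0}{3} - \frac{F_{cell} h}{L_0}}
#' using an exact exponential step with the forcing held over each sample
#' interval. With constant forcing the solution relaxes exponentially with
#' time constant [relaxation_time()]. The stored `Wdot` is the
#' instantaneous ODE rate at each sample, so inverting the output with
#' [cell_force()] reproduces the input force series to machine precision.
#'
#' @param F_cell cell-force series (N), one value per step.
#' @param p_m magnetic force-density series (N/m), scalar or same length.
#' @param beam a [beam_spec()].
#' @param W0 initial tip deflection (m).
#' @param dt sample interval (s); must satisfy `dt <= tau / 10`.
#' @param t0 time of the first sample (s).
#' @return A [deflection_trace()] (provenance `"simulated"`) with an
#'   attribute `p_m` holding the force-density series.
#' @export
simulate_deflection <- function(F_cell, p_m, beam, W0 = 0, dt, t0 = 0) {
  stopifnot_beam(beam)
  n <- length(F_cell)
  if (length(p_m) == 1L) p_m <- rep(p_m, n)
  if (length(p_m) != n)
    stop("F_cell and p_m must have equal length", call. = FALSE)
  if (!all(is.finite(F_cell)) || !all(is.finite(p_m)))
    stop("non-finite forcing", call. = FALSE)
  k <- beam_constants(beam)
  if (dt > k$tau / 10)
    stop("dt = ", signif(dt, 3), " s too coarse: must be <= tau/10 = ",
         signif(k$tau / 10, 3), " s", call. = FALSE)
  A <- 4 * k$Ebar * k$I / beam$L0^3      # elastic stiffness term
  B <- k$k_d * beam$L0 / 5               # drag term
  u <- p_m * beam$L0 / 3 - F_cell * beam$h / beam$L0
  decay <- exp(-dt / k$tau)
  W <- numeric(n)
  W[1L] <- W0
  for (i in seq_len(n - 1L)) {
    Wss <- u[i] / A
    W[i + 1L] <- Wss + (W[i] - Wss) * decay
  }
  Wdot <- (u - A * W) / B
  check_deflection(W, beam)
  tr <- deflection_trace(t0 + dt * (seq_len(n) - 1L), W, beam, Wdot = Wdot,
                         provenance = "simulated", check = FALSE)
  attr(tr, "p_m") <- p_m
  tr
}

#' Recover the cell-force series from a deflection trace
#'
#' Applies [cell_force()] frame by frame. For tracked traces the velocity
#' is re-estimated by segmented Savitzky-Golay differentiation so that
#' known actuation discontinuities (magnet on/off steps) do not bias the
#' derivative; for simulated traces the stored exact `Wdot` can be used.
#'
#' @param trace a [deflection_trace()].
#' @param p_m magnetic force-density series (N/m), scalar or per frame.
#'   Defaults to the trace's own `p_m` attribute when present.
#' @param beam a [beam_spec()]; defaults to the trace's beam.
#' @param wdot `"stored"` to use `trace$Wdot`, `"savgol"` to re-estimate.
#' @param sg_window Savitzky-Golay window (frames) for `"savgol"`.
#' @param breaks indices starting new smoothing segments.
#' @return A data.frame of cell-force samples: `t`, `F_cell` (N), `dL` (m),
#'   `eps` (strain).
#' @export
invert_cell_force <- function(trace, p_m = NULL, beam = NULL,
                              wdot = c("stored", "savgol"),
                              sg_window = 7L, breaks = integer(0)) {
  if (!inherits(trace, "deflection_trace"))
    stop("expected a deflection_trace", call. = FALSE)
  wdot <- match.arg(wdot)
  if (is.null(beam)) beam <- attr(trace, "beam")
  stopifnot_beam(beam)
  if (is.null(p_m)) p_m <- attr(trace, "p_m")
  if (is.null(p_m))
    stop("p_m series required (none stored on the trace)", call. = FALSE)
  n <- nrow(trace)
  if (length(p_m) == 1L) p_m <- rep(p_m, n)
  if (length(p_m) != n)
    stop("p_m must be scalar or one value per frame", call. = FALSE)
  Wd <- if (wdot == "stored") {
    trace$Wdot
  } else {
    dt <- mean(diff(trace$t))
    # cubic local fit: a quadratic's O(f''') derivative bias is visible on
    # the exponential release transient and scales with preload
    sg_segmented(trace$W, sg_window, poly = 3L, deriv = 1L, dt = dt,
                 breaks = breaks)
  }
  Fc <- cell_force(trace$W, Wd, p_m, beam, check = FALSE)
  s <- cell_layer_strain(trace$W, beam)
  data.frame(t = trace$t, F_cell = Fc, dL = s$dL, eps = s$eps)
}

#' Write / read a deflection trace as CSV + JSON sidecar
#'
#' The CSV carries a units-bearing header (`t_s, W_m, Wdot_mps,
#' curvature_per_m`); the sidecar (`<path>.json`) stores the beam
#' specification and provenance. The reader validates the header.
#'
#' @param trace a [deflection_trace()].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_deflection_trace` returns `path` invisibly;
#'   `read_deflection_trace` returns a [deflection_trace()].
#' @export
write_deflection_trace <- function(trace, path) {
  if (!inherits(trace, "deflection_trace"))
    stop("expected a deflection_trace", call. = FALSE)
  df <- data.frame(t_s = trace$t, W_m = trace$W, Wdot_mps = trace$Wdot,
                   curvature_per_m = trace$curvature)
  utils::write.csv(df, path, row.names = FALSE)
  beam <- attr(trace, "beam")
  meta <- list(beam = unclass(beam), provenance = attr(trace, "provenance"))
  if (!is.null(attr(trace, "p_m"))) meta$p_m <- attr(trace, "p_m")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_deflection_trace
#' @export
read_deflection_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "W_m", "Wdot_mps", "curvature_per_m")
  if (!all(need %in% names(df)))
    stop("trace CSV must carry the units header: ",
         paste(need, collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  beam <- do.call(beam_spec, as.list(meta$beam))
  tr <- deflection_trace(df$t_s, df$W_m, beam, Wdot = df$Wdot_mps,
                         provenance = meta$provenance, check = FALSE)
  if (!is.null(meta$p_m)) attr(tr, "p_m") <- meta$p_m
  tr
}
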