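# Run `code` under a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Preload/stimulation protocol
#'
#' One recording per preload level. Each level starts with a rest period,
#' then `n_twitches` pacing cycles; in every cycle the magnets hold the
#' beam preloaded for `hold` seconds and are released at the moment the
#' electrical stimulus fires (a short monophasic pulse), so the twitch
#' develops from the preloaded, released beam.
#'
#' @param preload_pm magnetic force densities (N/m), one per preload level,
#'   typically including 0 (baseline). See [preload_pm_for_strain()].
#' @param preload_d alternatively, magnet distances (m); converted to
#'   force densities by the calibration curve passed to [run_protocol()].
#' @param pacing pacing period (s); default 2 s (0.5 Hz).
#' @param pulse stimulus pulse width (s); metadata only, default 5 ms.
#' @param hold preload hold duration before each stimulus (s), < pacing.
#' @param n_twitches stimuli per preload level.
#' @param fps video/sampling rate (frames per second).
#' @param rest initial rest period per level (s); also the reference
#'   window for tracking.
#' @param label free-text condition label.
#' @return An object of class `twitch_protocol`.
#' @export
twitch_protocol <- function(preload_pm = NULL, preload_d = NULL,
                            pacing = 2, pulse = 0.005, hold = 0.5,
                            n_twitches = 8L, fps = 240, rest = 1,
                            label = "untreated") {
  if (is.null(preload_pm) && is.null(preload_d))
    stop("give preload levels as preload_pm (N/m) or preload_d (m)",
         call. = FALSE)
  if (hold >= pacing) stop("hold must be shorter than the pacing period",
                           call. = FALSE)
  if (fps <= 0 || pacing <= 0 || hold < 0 || rest < 0)
    stop("invalid protocol timing", call. = FALSE)
  structure(list(preload_pm = preload_pm, preload_d = preload_d,
                 pacing = pacing, pulse = pulse, hold = hold,
                 n_twitches = as.integer(n_twitches), fps = fps,
                 rest = rest, label = label),
            class = "twitch_protocol")
}

#' Force density needed to impose a given preload strain
#'
#' Static inversion: a cell-layer strain `eps` corresponds to tip
#' deflection `W = eps L0^2 / h`, held by `p_m = Ebar b h^2 eps / L0^2`
#' (energy-consistent calibration).
#'
#' @param eps target preload strain(s), dimensionless.
#' @param beam a [beam_spec()].
#' @return Force density(ies) in N/m.
#' @export
preload_pm_for_strain <- function(eps, beam) {
  stopifnot_beam(beam)
  k <- beam_constants(beam)
  k$Ebar * beam$b * beam$h^2 * eps / beam$L0^2
}

#' Twitch force model
#'
#' Parameterizes the synthetic twitch: a double-exponential waveform whose
#' peak grows linearly with the preload strain, the in-silico counterpart
#' of the Frank-Starling force-length dependence. The inotropy gain
#' `s_FL` is the fractional peak-force increase per `eps_ref` of preload
#' strain; a positive inotrope corresponds to a larger `s_FL`.
#'
#' @param F0 baseline (zero-preload) peak twitch force (N).
#' @param s_FL force-length gain (dimensionless, >= 0).
#' @param t_rise,t_decay waveform time constants (s), `t_rise < t_decay`.
#' @param noise_sd additive measurement noise on the tip deflection (m);
#'   default 3 µm, ~40 dB below the RMS deflection of a default protocol.
#' @param eps_ref normalization strain for the gain (default 1e-3), kept
#'   in output metadata so `s_FL` stays unitless and recoverable.
#' @return An object of class `twitch_model`.
#' @export
twitch_model <- function(F0 = 1e-5, s_FL = 1, t_rise = 0.04,
                         t_decay = 0.15, noise_sd = 3e-6,
                         eps_ref = 1e-3) {
  if (F0 <= 0) stop("F0 must be > 0", call. = FALSE)
  if (s_FL < 0) stop("s_FL must be >= 0", call. = FALSE)
  if (t_rise <= 0 || t_decay <= t_rise)
    stop("need 0 < t_rise < t_decay", call. = FALSE)
  if (eps_ref <= 0) stop("eps_ref must be > 0", call. = FALSE)
  structure(list(F0 = F0, s_FL = s_FL, t_rise = t_rise, t_decay = t_decay,
                 noise_sd = noise_sd, eps_ref = eps_ref),
            class = "twitch_model")
}

#' Twitch force waveform
#'
#' Double-exponential transient starting at zero force at the stimulus,
#' peaking at `F0 (1 + s_FL * eps_pre / eps_ref)` and decaying back to
#' (numerically) zero within a pacing period.
#'
#' @param model a [twitch_model()].
#' @param eps_pre preload strain at the stimulus (dimensionless).
#' @param t time since the stimulus (s), `>= 0`; vectorized.
#' @return Force (N), non-negative, single-peaked.
#' @export
twitch_waveform <- function(model, eps_pre, t) {
  if (any(t < 0)) stop("t must be >= 0 (time since stimulus)", call. = FALSE)
  tr <- model$t_rise; td <- model$t_decay
  tp <- log(td / tr) * tr * td / (td - tr)      # time of the peak
  gmax <- exp(-tp / td) - exp(-tp / tr)
  peak <- model$F0 * (1 + model$s_FL * eps_pre / model$eps_ref)
  peak * (exp(-t / td) - exp(-t / tr)) / gmax
}

# Sampling schedule for one preload level: frame times, magnet force
# density, stimulus times/frame indices.
protocol_schedule <- function(protocol, level_pm) {
  fps <- protocol$fps
  dur <- protocol$rest + protocol$hold +
    protocol$n_twitches * protocol$pacing
  n <- as.integer(round(dur * fps))
  t <- (seq_len(n) - 1L) / fps
  stim_t <- protocol$rest + protocol$hold +
    (seq_len(protocol$n_twitches) - 1L) * protocol$pacing
  p_m <- rep(0, n)
  for (s in stim_t) {
    on <- t >= (s - protocol$hold) & t < s
    p_m[on] <- level_pm
  }
  stim_idx <- as.integer(round(stim_t * fps)) + 1L
  list(t = t, p_m = p_m, stim_t = stim_t, stim_idx = stim_idx, n = n)
}

#' Simulate a full preload/stimulation experiment
#'
#' For every preload level: the magnet force density steps on for each
#' hold and off at the stimulus; the twitch force is the
#' [twitch_waveform()] evaluated with the preload strain actually reached
#' at the end of that hold; the deflection follows the forward beam ODE
#' (exact exponential stepping); optional seeded Gaussian measurement
#' noise is added to the observed deflection. Regeneration from the same
#' parameters and seed is bit-identical.
#'
#' @param protocol a [twitch_protocol()].
#' @param model a [twitch_model()].
#' @param beam a [beam_spec()].
#' @param calibration a `calibration_curve`, required when the protocol
#'   gives preload levels as magnet distances.
#' @param seed integer seed for the measurement noise.
#' @return An object of class `ground_truth`: a list with one element per
#'   preload level (`frames` data.frame with `t`, `W`, `W_obs`, `Wdot`,
#'   `F_cell`, `p_m`, `eps`; `stim_t`; `eps_pre`; `peaks` = true per-twitch
#'   peak active forces), plus `protocol`, `model`, `beam`, `seed`.
#' @export
run_protocol <- function(protocol, model, beam, calibration = NULL,
                         seed = 1L) {
  if (!inherits(protocol, "twitch_protocol")) stop("invalid protocol")
  if (!inherits(model, "twitch_model")) stop("invalid twitch model")
  stopifnot_beam(beam)
  if (protocol$fps < 2 / model$t_rise)
    stop("fps too low to resolve the twitch rise time", call. = FALSE)
  level_pm <- protocol$preload_pm
  if (is.null(level_pm)) {
    if (is.null(calibration))
      stop("protocol gives magnet distances: a calibration curve is needed",
           call. = FALSE)
    level_pm <- predict(calibration, protocol$preload_d)
  }
  k <- beam_constants(beam)
  dt <- 1 / protocol$fps
  if (dt > k$tau / 10)
    stop("frame interval exceeds tau/10: raise fps or viscosity",
         call. = FALSE)
  A <- 4 * k$Ebar * k$I / beam$L0^3
  B <- k$k_d * beam$L0 / 5
  decay <- exp(-dt / k$tau)
  npac <- as.integer(round(protocol$pacing * protocol$fps))

  levels <- with_local_seed(seed, lapply(seq_along(level_pm), function(j) {
    sch <- protocol_schedule(protocol, level_pm[j])
    n <- sch$n
    Fc <- numeric(n)
    W <- numeric(n)
    eps_pre <- numeric(length(sch$stim_idx))
    tw <- 0L
    for (i in seq_len(n)) {
      if (tw < length(sch$stim_idx) && i == sch$stim_idx[tw + 1L]) {
        tw <- tw + 1L
        eps_pre[tw] <- W[i] * beam$h / beam$L0^2
        idx <- i:min(i + npac - 1L, n)
        Fc[idx] <- twitch_waveform(model, eps_pre[tw], sch$t[idx] - sch$t[i])
      }
      if (i < n) {
        u <- sch$p_m[i] * beam$L0 / 3 - Fc[i] * beam$h / beam$L0
        Wss <- u / A
        W[i + 1L] <- Wss + (W[i] - Wss) * decay
      }
    }
    u <- sch$p_m * beam$L0 / 3 - Fc * beam$h / beam$L0
    Wdot <- (u - A * W) / B
    W_obs <- W + stats::rnorm(n, 0, model$noise_sd)
    peaks <- model$F0 * (1 + model$s_FL * eps_pre / model$eps_ref)
    list(frames = data.frame(t = sch$t, W = W, W_obs = W_obs, Wdot = Wdot,
                             F_cell = Fc, p_m = sch$p_m,
                             eps = W * beam$h / beam$L0^2),
         stim_t = sch$stim_t, stim_idx = sch$stim_idx,
         eps_pre = eps_pre, peaks = peaks, level_pm = level_pm[j])
  }))
  r <- max(vapply(levels, function(l) max(abs(l$frames$W)), 0)) / beam$L0
  if (r > .w_hard_limit)
    stop("simulated deflection exceeds the model validity limit", call. = FALSE)
  if (r > .w_warn_limit)
    warning("simulated |W|/L0 reaches ", signif(r, 2),
            "; small-deformation model is approximate", call. = FALSE)
  structure(list(levels = levels, protocol = protocol, model = model,
                 beam = beam, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> '%s': %d preload levels x %d twitches @ %g fps, seed %d\n",
    x$protocol$label, length(x$levels), x$protocol$n_twitches,
    x$protocol$fps, x$seed))
  invisible(x)
}

#' Write ground truth as CSV + JSON
#'
#' One long CSV (per-frame state for all levels) plus a JSON file with
#' protocol, twitch-model and beam parameters, per-twitch truth and seed.
#'
#' @param truth a `ground_truth` from [run_protocol()].
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  frames <- do.call(rbind, lapply(seq_along(truth$levels), function(j) {
    cbind(level = j, truth$levels[[j]]$frames)
  }))
  utils::write.csv(frames, path, row.names = FALSE)
  meta <- list(
    protocol = unclass(truth$protocol), model = unclass(truth$model),
    beam = unclass(truth$beam), seed = truth$seed,
    eps_pre = lapply(truth$levels, `[[`, "eps_pre"),
    peaks = lapply(truth$levels, `[[`, "peaks"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
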