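pm_breaks <- function(p_m) which(diff(p_m) != 0) + 1L

#' Recover cell forces and build measurements from a simulated experiment
#'
#' Runs the inverse model on each preload level of a [run_protocol()]
#' result and assembles [twitch_measurement()]s. Three sources are
#' supported:
#' * `"observed"`: invert the noisy observed deflection with segmented
#'   Savitzky-Golay velocity estimation (segments split at magnet steps);
#' * `"exact"`: invert the exact simulated `W`, `Wdot` (round-trip mode);
#' * `"video"`: render each level as a silhouette video, track it, then
#'   invert the tracked deflection.
#'
#' @param truth a `ground_truth` from [run_protocol()].
#' @param source `"observed"`, `"exact"` or `"video"`.
#' @param sg_window Savitzky-Golay window (frames) for the velocity.
#' @param rc a [render_config()] (video source; default from the beam).
#' @param tc a [tracking_config()] (video source; default matches `rc`).
#' @param seed pixel-noise seed for the rendered video.
#' @param blank,smooth peak-extraction settings, see [active_force()].
#' @return list of [twitch_measurement()]s, one per preload level, with
#'   attribute `recovered` (list of per-level inversion data.frames).
#' @export
recover_measurements <- function(truth,
                                 source = c("observed", "exact", "video"),
                                 sg_window = 7L, rc = NULL, tc = NULL,
                                 seed = 1L, blank = 0.05, smooth = 0.08) {
  source <- match.arg(source)
  beam <- truth$beam
  fps <- truth$protocol$fps
  if (source == "video") {
    if (is.null(rc)) rc <- render_config(beam)
    if (is.null(tc))
      tc <- tracking_config(px_per_mm = rc$px_per_mm,
                            clamp_px = as.integer(floor(rc$clamp_px)),
                            sg_window = sg_window, L0 = beam$L0)
  }
  rec <- vector("list", length(truth$levels))
  meas <- vector("list", length(truth$levels))
  for (j in seq_along(truth$levels)) {
    lv <- truth$levels[[j]]
    fr <- lv$frames
    brk <- pm_breaks(fr$p_m)
    if (source == "exact") {
      tr <- deflection_trace(fr$t, fr$W, beam, Wdot = fr$Wdot,
                             provenance = "simulated", check = FALSE)
      inv <- invert_cell_force(tr, fr$p_m, beam, wdot = "stored")
    } else if (source == "observed") {
      tr <- deflection_trace(fr$t, fr$W_obs, beam, provenance = "tracked",
                             sg_window = sg_window, breaks = brk,
                             check = FALSE)
      inv <- invert_cell_force(tr, fr$p_m, beam, wdot = "savgol",
                               sg_window = sg_window, breaks = brk)
    } else {
      prov <- frame_provider(fr$W_obs, rc, seed = seed + 7919L * j)
      ref <- seq_len(max(2L, as.integer(truth$protocol$rest * fps) - 2L))
      tr <- track(prov, tc, beam, fps, reference = ref)
      inv <- invert_cell_force(tr, fr$p_m, beam, wdot = "savgol",
                               sg_window = sg_window, breaks = brk)
    }
    rec[[j]] <- inv
    meas[[j]] <- twitch_measurement(
      t = inv$t, eps = inv$eps, F_cell = inv$F_cell,
      stim_t = lv$stim_t, eps_pre = mean(lv$eps_pre), level_id = j,
      blank = blank, smooth = smooth,
      window = truth$protocol$pacing - truth$protocol$hold)
  }
  attr(meas, "recovered") <- rec
  meas
}

#' Full in-silico contractility experiment
#'
#' Convenience wrapper chaining simulate (-> render -> track) -> invert ->
#' force-length analysis for one condition.
#'
#' @param protocol a [twitch_protocol()].
#' @param model a [twitch_model()].
#' @param beam a [beam_spec()].
#' @param seed experiment seed (noise in the simulation, rendering and
#'   bootstrap all derive from it).
#' @param source recovery route, see [recover_measurements()].
#' @param calibration optional `calibration_curve` when the protocol uses
#'   magnet distances.
#' @param n_boot bootstrap resamples for the FL slope.
#' @param ... further arguments to [recover_measurements()].
#' @return list with `truth`, `measurements` (normalized), `loops`,
#'   `fl` (an [fl_relation()]).
#' @export
run_dtl_experiment <- function(protocol, model, beam, seed = 1L,
                               source = "observed", calibration = NULL,
                               n_boot = 1000L, ...) {
  truth <- run_protocol(protocol, model, beam, calibration = calibration,
                        seed = seed)
  meas <- recover_measurements(truth, source = source, seed = seed, ...)
  meas_n <- normalize_measurements(meas)
  loops <- build_loops(meas_n, hold = protocol$hold)
  fl <- fl_relation(meas, n_boot = n_boot, seed = seed + 1L,
                    label = protocol$label)
  list(truth = truth, measurements = meas_n, loops = loops, fl = fl)
}

#' Export analysis outputs as tidy CSV/JSON
#'
#' Writes one row per twitch (condition, preload level, preload strain,
#' peak active force), the loops in long format and a JSON report with
#' the fitted slope and CI.
#'
#' @param result output of [run_dtl_experiment()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fl <- result$fl
  tw <- do.call(rbind, lapply(seq_along(fl$peaks), function(j) {
    data.frame(condition = fl$label, level = j,
               eps_pre = fl$eps_pre[j], twitch = seq_along(fl$peaks[[j]]),
               peak_active_N = fl$peaks[[j]])
  }))
  utils::write.csv(tw, file.path(dir, "twitches.csv"), row.names = FALSE)
  lp <- do.call(rbind, lapply(result$loops, function(l) {
    data.frame(level = l$level_id, eps_pre = l$eps_pre,
               eps = l$eps, sigma_hat = l$sigma_hat)
  }))
  utils::write.csv(lp, file.path(dir, "loops.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(condition = fl$label, slope = fl$slope,
         intercept = fl$intercept, r2 = fl$r2,
         slope_ci = fl$slope_ci, slope_se = fl$slope_se,
         points = fl$points),
    file.path(dir, "fl_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
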