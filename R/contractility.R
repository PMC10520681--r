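odd_window <- function(seconds, fps, minimum = 5L) {
  w <- max(minimum, as.integer(round(seconds * fps)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Per-twitch peak active forces
#'
#' For each stimulus, the active force is the force trace referenced to
#' its value at the stimulus onset; the peak is read from the smoothed
#' trace at a fixed lag after the stimulus. Three details keep the
#' estimator unbiased on inverted (noisy, step-actuated) traces:
#'
#' * the onset reference is the median of the *unsmoothed* trace over the
#'   pre-stimulus window, which lies inside the preload hold where the
#'   inverted force is flat -- a smoothed value there would straddle the
#'   magnet-release step;
#' * a short blanking interval after the stimulus is excluded from the
#'   search, because the release makes the numerically differentiated
#'   velocity (hence the inverted force) unreliable for a few frames
#'   around the step;
#' * the peak is sampled two-pass at the per-recording median argmax lag
#'   (fixed-lag sampling), so the "maximum of noise" upward bias of a
#'   plain windowed maximum cancels instead of growing with the local
#'   noise level.
#'
#' @param F_cell force trace (N).
#' @param t time base (s), uniform.
#' @param stim_t stimulus times (s); at least one, each followed by a full
#'   twitch window inside the trace.
#' @param window twitch search window after each stimulus (s); default the
#'   spacing between stimuli.
#' @param blank post-stimulus blanking (s) excluded from the peak search.
#' @param smooth smoothing span (s) for peak picking; 0 disables.
#' @param ref_window pre-onset span (s) for the onset reference (default
#'   0.12 s, inside a 0.5 s hold).
#' @return A list with `peaks` (N, one per stimulus), `mean`, `sd`,
#'   `t_peak` (the fixed lag used, s) and the smoothed trace `F_smooth`.
#' @export
active_force <- function(F_cell, t, stim_t, window = NULL, blank = 0.05,
                         smooth = 0.08, ref_window = 0.12) {
  if (!length(stim_t)) stop("need at least one stimulus", call. = FALSE)
  dt <- mean(diff(t))
  fps <- 1 / dt
  if (is.null(window))
    window <- if (length(stim_t) > 1L) min(diff(stim_t)) else
      max(t) - max(stim_t)
  if (any(stim_t < min(t)) || any(stim_t + window > max(t) + dt / 2))
    stop("no full twitch window inside the trace for some stimuli",
         call. = FALSE)
  Fs <- if (smooth > 0) {
    savitzky_golay(F_cell, odd_window(smooth, fps), poly = 2L)
  } else F_cell
  lag <- vapply(stim_t, function(s) {
    win <- t >= s + blank & t <= s + window
    t[win][which.max(Fs[win])] - s
  }, 0)
  t_peak <- stats::median(lag)
  peaks <- vapply(stim_t, function(s) {
    pre <- t >= s - ref_window & t < s
    ref <- if (any(pre)) stats::median(F_cell[pre]) else
      F_cell[which.min(abs(t - s))]
    Fs[which.min(abs(t - (s + t_peak)))] - ref
  }, 0)
  list(peaks = peaks, mean = mean(peaks), sd = stats::sd(peaks),
       t_peak = t_peak, F_smooth = Fs)
}

#' Normalize a force/stress trace to the baseline peak
#'
#' Dynamic stress normalized to the peak baseline (no-preload) stress.
#' Because the cell-layer cross-section cancels in the ratio, forces can
#' be normalized directly; the baseline run normalized by its own peak
#' attains exactly 1.
#'
#' @param F_cell force (or stress) series.
#' @param baseline_peak peak value of the no-preload baseline run (> 0).
#' @return The dimensionless normalized series `sigma_hat`.
#' @export
normalize_stress <- function(F_cell, baseline_peak) {
  if (!is.finite(baseline_peak) || baseline_peak <= 0)
    stop("baseline peak must be > 0", call. = FALSE)
  F_cell / baseline_peak
}

#' One preload level's twitch measurement
#'
#' Bundles the per-frame series and the per-twitch peak active forces of
#' one preload level.
#'
#' @param t,eps,F_cell per-frame time (s), cell-layer strain and force (N).
#' @param stim_t stimulus times (s).
#' @param eps_pre preload strain (mean strain at the end of the holds).
#' @param level_id identifier of the preload level.
#' @param ... passed to [active_force()] (`blank`, `smooth`, `window`...).
#' @return An object of class `twitch_measurement`.
#' @export
twitch_measurement <- function(t, eps, F_cell, stim_t, eps_pre,
                               level_id = NA, ...) {
  af <- active_force(F_cell, t, stim_t, ...)
  structure(list(level_id = level_id, eps_pre = eps_pre,
                 frames = data.frame(t = t, eps = eps, F_cell = F_cell,
                                     F_smooth = af$F_smooth),
                 stim_t = stim_t, peaks = af$peaks,
                 peak_active = af$mean, peak_active_sd = af$sd),
            class = "twitch_measurement")
}

# Baseline = level with the smallest preload strain.
baseline_index <- function(measurements) {
  which.min(vapply(measurements, `[[`, 0, "eps_pre"))
}

#' Attach normalized stress to a set of measurements
#'
#' @param measurements list of [twitch_measurement()]s across preloads.
#' @return The list, with a `sigma_hat` column added to each `frames`
#'   data.frame and the baseline peak recorded as attribute
#'   `baseline_peak`. The baseline's own maximum is exactly 1.
#' @export
normalize_measurements <- function(measurements) {
  b <- baseline_index(measurements)
  base_peak <- max(measurements[[b]]$frames$F_cell)
  out <- lapply(measurements, function(m) {
    m$frames$sigma_hat <- normalize_stress(m$frames$F_cell, base_peak)
    m
  })
  attr(out, "baseline_peak") <- base_peak
  attr(out, "baseline_index") <- b
  out
}

#' Normalized stress-strain loops per preload
#'
#' For each preload level, the mean cycle across twitches of the
#' `(eps(t), sigma_hat(t))` trajectory over one pacing period starting at
#' the onset of the preload hold (so the loop covers hold, release, twitch
#' and return to rest). The shoelace (signed) area is reported as a work
#' surrogate.
#'
#' @param measurements list of [twitch_measurement()]s (normalized via
#'   [normalize_measurements()] or not; normalization is applied if
#'   missing).
#' @param hold preload hold duration (s) preceding each stimulus.
#' @return A list of loops, each with `eps`, `sigma_hat` (mean cycle) and
#'   `area` (absolute) plus `area_signed`.
#' @export
build_loops <- function(measurements, hold = 0.5) {
  if (is.null(measurements[[1]]$frames$sigma_hat))
    measurements <- normalize_measurements(measurements)
  lapply(measurements, function(m) {
    fr <- m$frames
    dt <- mean(diff(fr$t))
    if (length(m$stim_t) > 1L) {
      period <- stats::median(diff(m$stim_t))
    } else {
      period <- max(fr$t) - m$stim_t[1] + hold
    }
    npc <- as.integer(round(period / dt))
    starts <- m$stim_t - hold
    cycles_e <- list(); cycles_s <- list()
    for (s in starts) {
      i0 <- which.min(abs(fr$t - s))
      idx <- i0:(i0 + npc - 1L)
      if (max(idx) > nrow(fr)) next
      cycles_e[[length(cycles_e) + 1L]] <- fr$eps[idx]
      cycles_s[[length(cycles_s) + 1L]] <- fr$sigma_hat[idx]
    }
    if (!length(cycles_e))
      stop("no complete pacing cycle in the trace", call. = FALSE)
    eps <- rowMeans(do.call(cbind, cycles_e))
    sig <- rowMeans(do.call(cbind, cycles_s))
    a <- shoelace_area(eps, sig)
    list(level_id = m$level_id, eps_pre = m$eps_pre,
         eps = eps, sigma_hat = sig,
         area = abs(a), area_signed = a)
  })
}

# Signed area of the closed polygon (x, y).
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

# Point estimate + weighted fit of the force-length relation from
# per-level peak lists. Weights are delta-method variances of the
# percentage increases; the baseline point (identically 0) takes the
# smallest non-degenerate weight companion so it cannot dominate.
fl_fit_points <- function(eps_pre, peaks_list) {
  b <- which.min(eps_pre)
  P <- vapply(peaks_list, mean, 0)
  nT <- vapply(peaks_list, length, 0L)
  V <- vapply(peaks_list, function(p)
    if (length(p) > 1L) stats::var(p) / length(p) else 0, 0)
  P0 <- P[b]
  if (!is.finite(P0) || P0 <= 0)
    stop("baseline peak active force must be > 0", call. = FALSE)
  pct <- 100 * (P - P0) / P0
  pct[b] <- 0
  se2 <- (100 / P0)^2 * V + (100 * P / P0^2)^2 * V[b]
  se2[b] <- NA
  pos <- se2[-b][se2[-b] > 0]
  se2[b] <- if (length(pos)) min(pos) else 1
  se2[se2 <= 0] <- if (length(pos)) min(pos) else 1
  rel <- eps_pre / max(eps_pre)
  w <- 1 / se2
  fit <- stats::lm.wfit(cbind(1, rel), pct, w)
  r2 <- if (stats::sd(pct) > 0)
    1 - sum(w * fit$residuals^2) / sum(w * (pct - stats::weighted.mean(pct, w))^2)
  else NA_real_
  list(rel = rel, pct = pct, se = sqrt(se2),
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = r2, P = P, P0 = P0, baseline = b)
}

#' Quasi-static force-length relation and contractility index
#'
#' Builds the percentage increase in average peak active force as a
#' function of the relative preload (preload strain normalized to the
#' largest tested level), fits a weighted least-squares line whose slope
#' is the contractility index, and bootstraps the slope by resampling
#' twitches within each preload level.
#'
#' @param measurements list of [twitch_measurement()]s, >= 3 preload
#'   levels including a (near-)zero baseline.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param label condition label.
#' @return An object of class `fl_relation`: `points` data.frame
#'   (`level_id`, `eps_pre`, `rel_preload`, `pct_increase`, `se`),
#'   `slope`, `intercept`, `r2`, `slope_ci` (95% percentile), `slope_se`,
#'   `boot` (resampled slopes), and the per-level `peaks` for condition
#'   comparisons.
#' @export
fl_relation <- function(measurements, n_boot = 1000L, seed = 1L,
                        label = "condition") {
  if (length(measurements) < 3L)
    stop("need at least 3 preload levels", call. = FALSE)
  eps_pre <- vapply(measurements, `[[`, 0, "eps_pre")
  peaks_list <- lapply(measurements, `[[`, "peaks")
  pt <- fl_fit_points(eps_pre, peaks_list)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(k) {
      res <- lapply(peaks_list, function(p)
        p[sample.int(length(p), replace = TRUE)])
      fl_fit_points(eps_pre, res)$slope
    }, 0)
  })
  structure(list(
    points = data.frame(
      level_id = vapply(measurements, function(m) as.integer(m$level_id),
                        0L),
      eps_pre = eps_pre, rel_preload = pt$rel,
      pct_increase = pt$pct, se = pt$se),
    slope = pt$slope, intercept = pt$intercept, r2 = pt$r2,
    slope_ci = unname(stats::quantile(boot, c(0.025, 0.975))),
    slope_se = stats::sd(boot), boot = boot,
    peaks = peaks_list, eps_pre = eps_pre,
    label = label, n_boot = n_boot, seed = seed),
    class = "fl_relation")
}

#' @export
print.fl_relation <- function(x, ...) {
  cat(sprintf("<fl_relation> '%s': %d preload levels\n", x$label,
              nrow(x$points)))
  cat(sprintf("  slope (contractility index) = %.1f %%/rel-preload",
              x$slope))
  cat(sprintf("  [95%% CI %.1f, %.1f]\n", x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Compare the contractility of two conditions
#'
#' Bootstrap comparison of two force-length slopes (e.g. untreated vs.
#' inotrope-treated): reports `delta_slope = slope_b - slope_a`, its
#' bootstrap confidence interval, a two-sided resampling p-value and a
#' verdict (`"steeper"` when condition b's preload response is credibly
#' steeper than condition a's).
#'
#' @param fl_a,fl_b [fl_relation()]s for the two conditions.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param tol relative tolerance when matching preload grids.
#' @return An object of class `fl_comparison`.
#' @export
compare_conditions <- function(fl_a, fl_b, n_boot = 1000L, seed = 1L,
                               tol = 0.05) {
  if (!inherits(fl_a, "fl_relation") || !inherits(fl_b, "fl_relation"))
    stop("expected two fl_relation objects", call. = FALSE)
  ra <- fl_a$points$rel_preload
  rb <- fl_b$points$rel_preload
  ia <- seq_along(ra); ib <- seq_along(rb)
  if (length(ra) != length(rb) || any(abs(ra - rb) > tol)) {
    warning("preload grids differ: using common levels", call. = FALSE)
    ia <- which(vapply(ra, function(r) any(abs(rb - r) <= tol), TRUE))
    ib <- vapply(ra[ia], function(r) which.min(abs(rb - r)), 0L)
    if (length(ia) < 3L)
      stop("fewer than 3 common preload levels", call. = FALSE)
  }
  sub <- function(fl, idx) list(eps = fl$eps_pre[idx],
                                peaks = fl$peaks[idx])
  a <- sub(fl_a, ia); b <- sub(fl_b, ib)
  slope_of <- function(z) fl_fit_points(z$eps, z$peaks)$slope
  delta <- slope_of(b) - slope_of(a)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(k) {
      res <- function(z) {
        z$peaks <- lapply(z$peaks, function(p)
          p[sample.int(length(p), replace = TRUE)])
        z
      }
      slope_of(res(b)) - slope_of(res(a))
    }, 0)
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  p <- 2 * min((sum(boot <= 0) + 1) / (n_boot + 1),
               (sum(boot >= 0) + 1) / (n_boot + 1))
  p <- min(p, 1)
  verdict <- if (ci[1] > 0) "steeper" else if (ci[2] < 0) "shallower" else
    "not distinguishable"
  structure(list(delta_slope = delta, ci = ci, p_value = p,
                 verdict = verdict, boot = boot,
                 labels = c(fl_a$label, fl_b$label)),
            class = "fl_comparison")
}

#' @export
print.fl_comparison <- function(x, ...) {
  cat(sprintf("<fl_comparison> '%s' vs '%s'\n", x$labels[2], x$labels[1]))
  cat(sprintf("  delta slope = %.1f [95%% CI %.1f, %.1f], p = %.4g -> %s\n",
              x$delta_slope, x$ci[1], x$ci[2], x$p_value, x$verdict))
  invisible(x)
}
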