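make_meas <- function(eps_pre, peaks, level_id = 1) {
  # hand-built measurement for unit tests that bypass the simulator
  structure(list(level_id = level_id, eps_pre = eps_pre,
                 frames = NULL, stim_t = NULL, peaks = peaks,
                 peak_active = mean(peaks), peak_active_sd = sd(peaks)),
            class = "twitch_measurement")
}

test_that("active_force: trivial, single-twitch and sampled-truth cases", {
  t <- seq(0, 8, by = 1 / 240)
  expect_equal(active_force(rep(2, length(t)), t, c(1, 3, 5))$peaks,
               c(0, 0, 0))
  m <- twitch_model()
  stim <- c(1, 3, 5)
  Fc <- rep(0, length(t))
  for (s in stim) {
    w <- t >= s & t < s + 2
    Fc[w] <- twitch_waveform(m, 1e-3, t[w] - s)
  }
  af <- active_force(Fc, t, stim, smooth = 0, blank = 0.02)
  # onset referencing subtracts the (tiny) tail of the previous twitch
  refs <- vapply(stim, function(s) median(Fc[t >= s - 0.12 & t < s]), 0)
  truth <- vapply(stim, function(s) max(Fc[t >= s & t < s + 2]), 0) - refs
  expect_equal(af$peaks, truth, tolerance = 1e-10)
  one <- active_force(Fc, t, 3, window = 2, smooth = 0)
  expect_equal(one$mean, one$peaks[1])
  expect_error(active_force(Fc, t, 7.5, window = 2), "full twitch window")
})

test_that("normalize_stress: identities, scale invariance, guard", {
  expect_equal(normalize_stress(3, 3), 1)
  expect_equal(normalize_stress(0, 2), 0)
  x <- c(0.5, 1, 2)
  expect_equal(normalize_stress(2 * x, 2 * 1.5), normalize_stress(x, 1.5))
  expect_error(normalize_stress(1, 0), "baseline")
  expect_error(normalize_stress(1, -2), "baseline")
})

test_that("baseline loop attains a normalized maximum of exactly 1", {
  beam <- default_beam()
  pr <- small_protocol(beam)
  truth <- run_protocol(pr, twitch_model(), beam, seed = 4)
  meas <- recover_measurements(truth, source = "observed")
  mn <- normalize_measurements(meas)
  b <- attr(mn, "baseline_index")
  expect_identical(max(mn[[b]]$frames$sigma_hat), 1)
  expect_gt(max(mn[[3]]$frames$sigma_hat), 1)   # preloaded twitch is larger
})

test_that("loops close, grow with preload, and flip orientation in reverse", {
  beam <- default_beam()
  pr <- small_protocol(beam, n_twitches = 3L)
  truth <- run_protocol(pr, twitch_model(), beam, seed = 5)
  meas <- normalize_measurements(recover_measurements(truth, "observed"))
  loops <- build_loops(meas, hold = pr$hold)
  areas <- vapply(loops, `[[`, 0, "area")
  expect_true(all(diff(areas) > 0))             # s_FL > 0: work grows
  # degenerate loop: quiescent zero-preload beam
  m0 <- meas[[1]]
  m0$frames$eps <- 0 * m0$frames$eps
  m0$frames$sigma_hat <- 0 * m0$frames$sigma_hat
  l0 <- build_loops(list(m0), hold = pr$hold)
  expect_equal(l0[[1]]$area, 0)
  # time reversal: same magnitude, opposite orientation
  mR <- meas[[3]]
  mR$frames <- mR$frames[rev(seq_len(nrow(mR$frames))), ]
  mR$frames$t <- rev(mR$frames$t)
  mR$stim_t <- max(mR$frames$t) - rev(mR$stim_t) + pr$hold
  lF <- build_loops(list(meas[[3]]), hold = pr$hold)[[1]]
  lR <- build_loops(list(mR), hold = pr$hold)[[1]]
  expect_rel(lR$area, lF$area, 0.05)
  expect_equal(sign(lR$area_signed), -sign(lF$area_signed))
})

test_that("fl_relation: null gain is flat, gain ratio is recovered", {
  beam <- default_beam()
  pr <- small_protocol(beam, eps = seq(0, 1e-3, length.out = 4),
                       n_twitches = 4L)
  run_fl <- function(s_FL, seed) {
    # s_FL = 3 twitches reach |W|/L0 ~ 0.16: the approximation warning is
    # expected there
    truth <- suppressWarnings(
      run_protocol(pr, twitch_model(s_FL = s_FL), beam, seed = seed))
    fl_relation(recover_measurements(truth, "observed"),
                n_boot = 300, seed = seed)
  }
  fl0 <- run_fl(0, 21)
  expect_lt(abs(fl0$slope), 3 * fl0$slope_se)
  fl1 <- run_fl(1, 22)
  fl3 <- run_fl(3, 23)
  expect_rel(fl3$slope / fl1$slope, 3, 0.1)
  # zero-preload point pinned at 0% increase
  expect_equal(fl1$points$pct_increase[1], 0)
  expect_equal(fl1$points$rel_preload, seq(0, 1, length.out = 4),
               tolerance = 0.02)
  expect_error(fl_relation(list(make_meas(0, 1:3), make_meas(1e-3, 2:4))),
               "3 preload")
})

test_that("fl_relation tolerates duplicated preload levels", {
  set.seed(8)
  eps <- c(0, 5e-4, 5e-4, 1e-3)
  peaks <- lapply(c(1, 1.5, 1.5, 2) * 1e-5,
                  function(p) p * (1 + rnorm(6, 0, 0.01)))
  meas <- Map(make_meas, eps, peaks, seq_along(eps))
  fl <- fl_relation(meas, n_boot = 100, seed = 1)
  expect_equal(nrow(fl$points), 4L)
  expect_rel(fl$slope, 100, 0.1)   # 100% increase across the range
})

test_that("compare_conditions: identity, antisymmetry, discrimination", {
  set.seed(12)
  mk <- function(slope, sd = 0.02) {
    eps <- seq(0, 1e-3, length.out = 5)
    Map(function(e, j) make_meas(e, 1e-5 * (1 + slope * e / 1e-3) *
                                   (1 + rnorm(8, 0, sd)), j),
        eps, seq_along(eps))
  }
  fl_a <- fl_relation(mk(1), n_boot = 400, seed = 31, label = "untreated")
  fl_b <- fl_relation(mk(3), n_boot = 400, seed = 32, label = "inotrope")
  same <- compare_conditions(fl_a, fl_a, n_boot = 400, seed = 33)
  expect_equal(same$delta_slope, 0)
  expect_identical(same$verdict, "not distinguishable")
  ab <- compare_conditions(fl_a, fl_b, n_boot = 400, seed = 34)
  ba <- compare_conditions(fl_b, fl_a, n_boot = 400, seed = 34)
  expect_equal(ba$delta_slope, -ab$delta_slope)
  expect_identical(ab$verdict, "steeper")
  expect_lt(ab$p_value, 0.05)
  # mismatched grids: warn, then use common levels
  fl_c <- fl_relation(mk(3)[c(1, 3, 5)], n_boot = 100, seed = 35)
  expect_warning(cc <- compare_conditions(fl_a, fl_c, n_boot = 100,
                                          seed = 36), "common levels")
  expect_true(is.finite(cc$delta_slope))
})

test_that("run_dtl_experiment assembles truth, loops and FL consistently", {
  beam <- default_beam()
  pr <- small_protocol(beam, n_twitches = 2L)
  res <- run_dtl_experiment(pr, twitch_model(), beam, seed = 6,
                            n_boot = 100)
  expect_s3_class(res$fl, "fl_relation")
  expect_length(res$loops, 3)
  expect_equal(res$fl$points$eps_pre,
               vapply(res$measurements, `[[`, 0, "eps_pre"))
  out <- file.path(tempdir(), "analysis")
  write_analysis(res, out)
  expect_true(file.exists(file.path(out, "twitches.csv")))
  expect_true(file.exists(file.path(out, "loops.csv")))
  rep <- jsonlite::read_json(file.path(out, "fl_report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$slope, res$fl$slope, tolerance = 1e-9)
})
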