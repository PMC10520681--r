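rc_tc <- function(beam, noise_sd = 0, px_per_mm = 20) {
  rc <- render_config(beam, px_per_mm = px_per_mm, noise_sd = noise_sd)
  tc <- tracking_config(px_per_mm = rc$px_per_mm,
                        clamp_px = as.integer(floor(rc$clamp_px)),
                        L0 = beam$L0)
  list(rc = rc, tc = tc)
}

test_that("renderer geometry: tip row moves by W * px, frames deterministic", {
  beam <- default_beam()
  s <- rc_tc(beam)
  f0 <- render_frame(0, s$rc)
  expect_true(all(f0 >= 0 & f0 <= 1))
  # undeflected midline sits at y0 in the last beam column
  W <- 1.3e-3
  f1 <- render_frame(W, s$rc)
  col <- s$rc$clamp_px + floor(beam$L0 * s$rc$px) - 2
  mid0 <- sum(seq_len(s$rc$nrow) * f0[, col]) / sum(f0[, col])
  mid1 <- sum(seq_len(s$rc$nrow) * f1[, col]) / sum(f1[, col])
  x <- (col - 0.5 - s$rc$clamp_px) / s$rc$px
  expect_lt(abs((mid1 - mid0) - W * (x / beam$L0)^2 * s$rc$px), 0.5)
  # identical W -> identical frames; seeded noise is reproducible
  expect_identical(render_frame(0, s$rc), f0)
  s$rc$noise_sd <- 0.02
  v1 <- render_video(c(0, W), s$rc, seed = 5)
  v2 <- render_video(c(0, W), s$rc, seed = 5)
  expect_identical(v1, v2)
  expect_false(identical(v1[[1]], render_video(c(0, W), s$rc, seed = 6)[[1]]))
  # beam out of frame
  rc2 <- render_config(beam, w_range = c(-1e-3, 1e-3))
  expect_error(render_frame(2.5e-3, rc2), "out of frame")
})

test_that("PGM round trip preserves frames to 8-bit precision", {
  beam <- default_beam()
  s <- rc_tc(beam)
  f <- render_frame(8e-4, s$rc)
  p5 <- file.path(tempdir(), "f.pgm")
  write_pgm(f, p5)
  expect_lt(max(abs(read_pgm(p5) - f)), 1 / 255)
  write_pgm(f, p5, ascii = TRUE)
  expect_lt(max(abs(read_pgm(p5) - f)), 1 / 255)
  dirp <- file.path(tempdir(), "frames")
  write_frames(list(f, f * 0.5), dirp)
  fr <- read_frames(dirp)
  expect_length(fr, 2)
  expect_lt(max(abs(fr[[2]] - f * 0.5)), 1 / 255)
})

test_that("binarize keeps the beam component and flags empty frames", {
  beam <- default_beam()
  s <- rc_tc(beam)
  f <- render_frame(5e-4, s$rc)
  mask <- binarize(f, s$tc)
  # mask area matches the rendered (anti-aliased) beam area
  expect_rel(sum(mask), sum(f), 0.02)
  expect_error(binarize(matrix(0, 50, 50), s$tc), "tracking lost")
  # a bright speck away from the clamp is discarded
  f2 <- f; f2[2, ncol(f2) - 1] <- 1
  expect_equal(sum(binarize(f2, s$tc)), sum(mask))
  # automatic threshold is symmetric under intensity inversion
  thr <- otsu_threshold(f)
  thr_inv <- otsu_threshold(1 - f)
  expect_lt(abs(thr_inv - (1 - thr)), 2 / 255)
  agree <- mean((f > thr) == !((1 - f) > thr_inv))
  expect_gt(agree, 0.99)
})

test_that("midline extraction: rectangle, parabola, holes, extent guard", {
  beam <- default_beam()
  s <- rc_tc(beam)
  # horizontal rectangle -> horizontal midline at its centre
  mask <- matrix(FALSE, 40, 60)
  mask[18:21, ] <- TRUE
  attr(mask, "threshold") <- 0.5
  pts <- extract_midline(mask, tracking_config(px_per_mm = 20))
  expect_true(all(pts$y == 19.5 / 2e4))
  # hole in one column is skipped silently
  mask2 <- mask; mask2[19, 30] <- FALSE
  pts2 <- extract_midline(mask2, tracking_config(px_per_mm = 20))
  expect_equal(nrow(pts2), nrow(pts) - 1L)
  expect_false(30 %in% pts2$col)
  # too few columns
  mask3 <- matrix(FALSE, 40, 60); mask3[18:21, 1:5] <- TRUE
  attr(mask3, "threshold") <- 0.5
  expect_error(extract_midline(mask3, tracking_config(px_per_mm = 20)),
               "insufficient")
  # rendered parabola: subpixel midline within 0.5 px of the true profile
  W <- 1e-3
  f <- render_frame(W, s$rc)
  m <- binarize(f, s$tc)
  p <- extract_midline(m, s$tc, frame = f)
  y_true <- s$rc$y0 / s$rc$px + W * (pmin(p$x, beam$L0) / beam$L0)^2
  expect_lt(max(abs(p$y - y_true)) * s$rc$px, 0.5)
})

test_that("fit_parabola recovers exact and rendered curvatures", {
  beam <- default_beam()
  tc <- tracking_config(px_per_mm = 20, L0 = beam$L0)
  x <- seq(0, beam$L0, length.out = 60)
  pts <- data.frame(col = seq_along(x), x = x,
                    y = 1e-3 + 0.02 * x + 50 * x^2)
  fit <- fit_parabola(pts, tc)
  expect_equal(unname(fit$coef), c(1e-3, 0.02, 50), tolerance = 1e-9)
  expect_equal(fit$curvature, 100, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-12)
  # straight line -> zero curvature
  pts$y <- 5e-4 + 0.01 * x
  expect_lt(abs(fit_parabola(pts, tc)$curvature), 1e-9)
  # rendered parabola: curvature within 2% of 2 W / L0^2
  s <- rc_tc(beam)
  f <- render_frame(1e-3, s$rc)
  p <- extract_midline(binarize(f, s$tc), s$tc, frame = f)
  fit2 <- fit_parabola(p, s$tc)
  expect_rel(fit2$curvature, curvature_from_tip(1e-3, beam), 0.02)
  expect_true(fit2$ok)
  # degenerate designs
  expect_error(fit_parabola(pts[1:4, ], tc), "midline points")
  pts3 <- data.frame(col = 1:12, x = rep(5e-3, 12), y = rnorm(12))
  expect_error(fit_parabola(pts3, tracking_config(px_per_mm = 20)),
               "ill-conditioned|half the free length")
})

test_that("track: static video, reversal symmetry, noiseless accuracy", {
  beam <- default_beam()
  s <- rc_tc(beam)
  W <- c(rep(0, 6), seq(0, 8e-4, length.out = 12), rep(8e-4, 6))
  frames <- render_video(W, s$rc, seed = NULL)
  tr <- track(frames, s$tc, beam, fps = 240, reference = 1:5)
  px_tol <- 0.5 / s$rc$px
  expect_lt(max(abs(tr$W - W)), px_tol)
  # all-identical frames give a flat zero trace
  tr0 <- track(frames[c(1, 1, 1, 1)], s$tc, beam, fps = 240)
  expect_true(all(abs(tr0$W) < 1e-12))
  expect_true(all(abs(tr0$Wdot) < 1e-9))
  # reversed frames give the reversed deflection trace
  trR <- track(rev(frames), s$tc, beam, fps = 240,
               reference = length(frames))
  expect_equal(trR$W, rev(tr$W), tolerance = 1e-9)
  # angle diagnostic: alpha vs W essentially linear in the small-angle range
  expect_gt(attr(tr, "alpha_r2"), 0.999)
})
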