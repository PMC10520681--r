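test_that("beam_spec validates geometry and material", {
  expect_s3_class(default_beam(), "beam_spec")
  expect_error(beam_spec(0, 1e-2, 2e-4, 1e4), "L0")
  expect_error(beam_spec(1e-2, 1e-2, 2e-4, 1e4, nu = 1), "Poisson")
  expect_error(beam_spec(1e-2, 1e-2, 2e-4, 1e4, nu = -0.1), "Poisson")
  expect_error(beam_spec(1e-2, 1e-2, 6e-3, 1e4), "thin-beam")
  expect_warning(beam_spec(1e-2, 1e-2, 1.5e-3, 1e4), "approximate")
  k <- beam_constants(default_beam())
  expect_equal(k$Ebar, 12e3 / (1 - 0.25))
  expect_equal(k$I, 1e-2 * (2e-4)^3 / 12)
  expect_gt(k$Ebar, 0)
  expect_gt(k$I, 0)
})

test_that("curvature, profile and strain follow the constant-curvature map", {
  beam <- default_beam()
  expect_identical(curvature_from_tip(0, beam), 0)
  expect_equal(curvature_from_tip(1e-3, beam), 20)
  expect_equal(curvature_from_tip(-1e-3, beam), -20)
  # odd symmetry and consistency dL = L0 c h / 2
  W <- c(-8e-4, -1e-5, 3e-4, 1e-3)
  s <- cell_layer_strain(W, beam)
  expect_equal(s$dL, beam$L0 * curvature_from_tip(W, beam) * beam$h / 2)
  expect_equal(s$dL, W * beam$h / beam$L0)
  expect_equal(s$eps, s$dL / beam$L0)
  expect_equal(cell_layer_strain(1e-3, beam)$dL, 20e-6)
  expect_equal(cell_layer_strain(1e-3, beam)$eps, 2e-3)
  expect_equal(cell_layer_strain(-5e-4, beam)$dL, -10e-6)
  # profile
  expect_identical(deflection_profile(1e-3, beam, 0), 0)
  expect_equal(deflection_profile(1e-3, beam, beam$L0), 1e-3)
  expect_equal(deflection_profile(1e-3, beam, beam$L0 / 2), 0.25e-3)
  x <- seq(0, beam$L0, length.out = 50)
  expect_true(all(diff(deflection_profile(1e-3, beam, x)) > 0))
  expect_error(deflection_profile(1e-3, beam, -1e-4), "within")
  expect_error(deflection_profile(1e-3, beam, beam$L0 * 1.01), "within")
  # model validity limits
  expect_error(curvature_from_tip(0.31 * beam$L0, beam), "validity")
  expect_warning(curvature_from_tip(0.2 * beam$L0, beam), "approximate")
})

test_that("drag coefficient matches the uniform-drag formula", {
  beam <- default_beam()
  expect_equal(drag_coefficient(beam), 3e-3 * pi)
  expect_equal(drag_coefficient(default_beam(mu = 0)), 0)
  expect_equal(drag_coefficient(default_beam(mu = 2e-3)),
               2 * drag_coefficient(beam))
})

test_that("cell_force reproduces the frozen static example and trivials", {
  beam <- default_beam()
  expect_identical(cell_force(0, 0, 0, beam), 0)
  expect_equal(cell_force(-1e-3, 0, 0, beam), 2.133333e-5,
               tolerance = 1e-6)
  expect_error(cell_force(NaN, 0, 0, beam), "non-finite")
})

test_that("cell_force equals the quadrature oracle on random states", {
  set.seed(42)
  for (i in 1:100) {
    beam <- random_beam()
    W <- runif(1, -0.25, 0.25) * beam$L0
    Wdot <- runif(1, -0.05, 0.05)
    if (abs(Wdot) < 1e-4) Wdot <- 1e-3
    p_m <- runif(1, 0, 2e-4)
    expect_rel(cell_force(W, Wdot, p_m, beam, check = FALSE),
               oracle_cell_force(W, Wdot, p_m, beam), 1e-10)
  }
})

test_that("cell_force is linear in W, Wdot and p_m separately", {
  beam <- default_beam()
  set.seed(7)
  for (i in 1:20) {
    W <- runif(1, -2e-3, 2e-3); Wd <- runif(1, -0.02, 0.02)
    pm <- runif(1, 0, 1e-4); a <- runif(1, 0.2, 3)
    F0 <- cell_force(0, 0, 0, beam)
    fW <- function(w) cell_force(w, 0, 0, beam, check = FALSE)
    fV <- function(v) cell_force(0, v, 0, beam)
    fP <- function(p) cell_force(0, 0, p, beam)
    expect_equal(fW(a * W), a * fW(W) + (1 - a) * F0)
    expect_equal(fV(a * Wd), a * fV(Wd))
    expect_equal(fP(a * pm), a * fP(pm))
    expect_equal(cell_force(W, Wd, pm, beam, check = FALSE),
                 fW(W) + fV(Wd) + fP(pm))
  }
})

test_that("calibration modes reproduce the frozen values and the 2/3 ratio", {
  beam <- default_beam()
  expect_identical(magnetic_density_from_static_deflection(0, beam), 0)
  expect_equal(magnetic_density_from_static_deflection(1e-3, beam),
               1.28e-4, tolerance = 1e-9)
  expect_equal(
    magnetic_density_from_static_deflection(1e-3, beam, "uniform_load"),
    8.533333e-5, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:25) {
    b <- random_beam()
    Wm <- runif(1, 1e-5, 2e-3)
    r <- magnetic_density_from_static_deflection(Wm, b, "uniform_load") /
      magnetic_density_from_static_deflection(Wm, b)
    expect_equal(r, 2 / 3, tolerance = 1e-12)
  }
})

test_that("energy-consistent calibration inverts cell-free data to zero force", {
  beam <- default_beam()
  Wm <- c(1e-4, 5e-4, 1e-3, 2e-3)
  pm <- magnetic_density_from_static_deflection(Wm, beam)
  expect_true(all(abs(cell_force(Wm, 0, pm, beam, check = FALSE)) < 1e-15))
  # the classical uniform-load inversion leaves the documented bias
  pm_u <- magnetic_density_from_static_deflection(Wm, beam, "uniform_load")
  k <- beam_constants(beam)
  expect_equal(cell_force(Wm, 0, pm_u, beam, check = FALSE),
               -k$Ebar * beam$b * beam$h^2 * Wm / (9 * beam$L0^2))
})

test_that("relaxation time scales as the ODE coefficients dictate", {
  beam <- default_beam()
  expect_equal(relaxation_time(beam), 0.04417865, tolerance = 1e-6)
  expect_equal(relaxation_time(default_beam(mu = 0)), 0)
  expect_equal(relaxation_time(default_beam(E = 24e3)),
               relaxation_time(beam) / 2)
  expect_equal(relaxation_time(default_beam(mu = 2e-3)),
               2 * relaxation_time(beam))
})

test_that("unit conversion happens only at the boundary", {
  expect_equal(as_metres(10, "mm"), 1e-2)
  expect_equal(as_metres(200, "um"), 2e-4)
  expect_identical(as_metres(0.01), 0.01)
})
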