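test_that("brain phantom has the stated perfusion truth and valid structure", {
  ph <- fix_phantom()
  cbf <- as.array(phantom_cbf(ph, "rest"))
  gm <- phantom_mask(ph, "gm", tissue = TRUE)
  wm <- phantom_mask(ph, "white_matter")
  expect_true(all(cbf[gm] == 35.7))
  expect_true(all(cbf[wm] == 25.8))
  acz <- as.array(phantom_cbf(ph, "acz"))
  expect_true(all(acz[gm] == 51.7))
  expect_true(sum(gm) > 0)
  # compartment masks are pairwise disjoint by construction (single label map)
  comp <- ph$compartments$name[-1]
  tot <- Reduce(`+`, lapply(comp, function(nm) phantom_mask(ph, nm)))
  expect_true(all(tot <= 1))
  # attenuation non-negative, skull denser than brain
  mu <- ph$compartments
  expect_true(all(mu$mu_cm >= 0))
  expect_gt(mu$mu_cm[mu$name == "skull"], mu$mu_cm[mu$name == "cortex"])
})

test_that("brain phantom is deterministic given the seed and fails on tiny grids", {
  a <- make_brain_phantom(seed = 9L)
  b <- make_brain_phantom(seed = 9L)
  expect_identical(a$labels, b$labels)
  c <- make_brain_phantom(seed = 10L)
  expect_false(identical(a$labels, c$labels))
  expect_error(make_brain_phantom(grid = 32L, spacing_mm = 2), "too small")
})

test_that("cylinder phantom geometry and edge cases", {
  cyl <- make_cylinder_phantom(160, 50000, "disc")
  area <- sum(phantom_mask(cyl, "source")) * cyl$spacing_mm^2
  ring <- pi * 160 * cyl$spacing_mm          # one-voxel ring around the rim
  expect_lt(abs(area - pi * 80^2), ring)
  pt <- make_cylinder_phantom(shape = "point")
  expect_equal(sum(as.array(phantom_activity(pt)) > 0), 1L)
  z <- make_cylinder_phantom(160, 0, "disc")
  expect_equal(max(as.array(phantom_activity(z))), 0)
  expect_error(make_cylinder_phantom(160, -5, "disc"), "non-negative")
  expect_error(make_cylinder_phantom(300, 1, "disc", grid = 64L), "fit")
})

test_that("standard input function: linearity, causality, positive sample value", {
  a <- standard_input_function(122.1)
  b <- standard_input_function(244.2)
  expect_equal(b$value_bqml, 2 * a$value_bqml)
  expect_equal(input_value(a, -1), 0)
  expect_equal(input_value(a, 0), 0)
  expect_gt(input_value(a, 10), 0)
  shifted <- standard_input_function(122.1, t_inject_min = 30)
  expect_equal(input_value(shifted, 29.9), 0)
  expect_equal(input_value(shifted, 40), input_value(a, 10))
})

test_that("tissue curve matches the one-tissue closed forms", {
  # f = 0: identically zero
  z <- tissue_tac(0, 35, standard_input_function(100), c(1, 10, 28))
  expect_equal(max(abs(z)), 0)
  # constant input: Ct(t) = Vd c (1 - exp(-f t / Vd))
  cin <- const_input(100)
  got <- tissue_tac(0.35, 35, cin, 28)
  expect_rel(got, 35 * 100 * (1 - exp(-0.28)), 1e-3)
  # equilibrium: t -> inf gives Vd * c
  eq <- tissue_tac(0.9, 35, const_input(40, t_end = 3000), 2500)
  expect_rel(eq, 35 * 40, 5e-3)
  # single-exponential input: analytic convolution oracle
  tg <- seq(0, 60, 0.05); aa <- 0.15; cc <- 800
  einp <- cbfspect:::new_input_function(tg, cc * exp(-aa * tg), 1, 0)
  f <- 0.45; k <- f / 35
  oracle <- f * cc / (aa - k) * (exp(-k * 25) - exp(-aa * 25))
  expect_rel(tissue_tac(f, 35, einp, 25), oracle, 1e-3)
  expect_error(tissue_tac(-0.1, 35, cin, 10), "negative")
})

test_that("blood sample is the input value scaled by the CCF", {
  inp <- standard_input_function(122.1)
  expect_equal(simulate_blood_sample(inp, 10, 1), input_value(inp, 10))
  expect_equal(simulate_blood_sample(inp, 10, 0.799),
               0.799 * input_value(inp, 10))
  zero <- const_input(0)
  expect_equal(simulate_blood_sample(zero, 10, 0.9), 0)
})
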