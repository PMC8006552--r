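test_that("margo pore count matches hand evaluations", {
  # margo annulus of a 10 um-lumen pit (Dm = 7 um under the 22 um cap)
  expect_equal(margo_pore_count(6.062, 0.2121, 0.140), 490.8,
               tolerance = 0.5 / 490)
  # capped 25 um membrane
  expect_equal(margo_pore_count(21.65, 0.7575, 0.140), 1230.3,
               tolerance = 0.5 / 1230)
  # degenerate single pore filling the whole annulus
  expect_equal(margo_pore_count(6.3, 10, 0), 1.0)
  # counts are real-valued, never rounded
  expect_false(margo_pore_count(5, 0.2, 0.14) ==
                 round(margo_pore_count(5, 0.2, 0.14)))
})

test_that("pit resistance is the exact series sum of its components", {
  p <- model_params(maxDm = 22)
  g <- derive_pit_geometry(seq(4, 40, by = 2), 4, p)
  r <- pit_resistance(g, p)
  expect_equal(r$R_pit, r$R_margo + r$R_canals + r$R_apertures)
  expect_true(all(r$R_margo >= 0 & r$R_canals >= 0 & r$R_apertures >= 0))
})

test_that("pit resistance reproduces the worked single-pit values", {
  # latewood-sized tracheid (L = 10 um under the linear WT law):
  # canal-dominated pit of ~91 MPa s mm^-3
  p22 <- model_params(maxDm = 22)
  g <- derive_pit_geometry(10, 8.857, p22)
  r <- pit_resistance(g, p22)
  expect_equal(r$R_pit, 91.2, tolerance = 0.01)
  expect_equal(r$R_canals, 77.1, tolerance = 0.01)
  expect_gt(r$R_canals / r$R_pit, 0.5)

  # wide earlywood cell with a capped 25 um membrane: thin wall, canal
  # and aperture terms comparable, total ~0.43 MPa s mm^-3
  p25 <- model_params(maxDm = 25)
  g2 <- derive_pit_geometry(36.09, 3.58, p25)
  r2 <- pit_resistance(g2, p25)
  expect_equal(r2$R_pit, 0.4336, tolerance = 0.01)
  expect_equal(r2$R_canals, 0.1916, tolerance = 0.01)
  expect_equal(r2$R_apertures, 0.1970, tolerance = 0.01)
})

test_that("independent term-by-term oracle agrees to 1e-12 relative", {
  p <- model_params(maxDm = 25)
  set.seed(97)
  for (i in 1:25) {
    L <- runif(1, 3, 55)
    WT <- runif(1, 1, 9)
    g <- derive_pit_geometry(L, WT, p)
    expect_equal(g$Npo, o_pore_count(g$Dmc, g$Dpo, p$t_f),
                 tolerance = 1e-12)
    r <- pit_resistance(g, p)
    expect_equal(r$R_pit, o_pit_resistance(g$Npo, g$Dpe, g$Da, g$t_a),
                 tolerance = 1e-12)
  }
})

test_that("component dominance shifts from canals to apertures with size", {
  p <- hydraulic_profile("pinaceae")
  law <- attr(p, "wt_law")
  small <- pit_resistance(derive_pit_geometry(5, law(5), p), p)
  big <- pit_resistance(derive_pit_geometry(30, law(30), p), p)
  # narrow latewood pits are canal-dominated
  expect_gt(small$R_canals, small$R_apertures)
  expect_gt(small$R_canals / small$R_pit, 0.5)
  # the aperture share grows with tracheid size; the margo stays minor
  expect_gt(big$R_apertures / big$R_pit, small$R_apertures / small$R_pit)
  expect_lt(small$R_margo / small$R_pit, 0.15)
  expect_lt(big$R_margo / big$R_pit, 0.15)
})

test_that("pit resistance falls strictly with membrane size at fixed canal length", {
  p <- model_params(maxDm = 60)  # cap out of the way
  g <- derive_pit_geometry(seq(5, 50, by = 1), 4, p)
  r <- pit_resistance(g, p)
  expect_true(all(diff(r$R_pit) < 0))
})

test_that("every component is linear in viscosity", {
  p1 <- model_params()
  p2 <- model_params(mu = 2 * p1$mu)
  g <- derive_pit_geometry(18, 4, p1)
  r1 <- pit_resistance(g, p1)
  r2 <- pit_resistance(g, p2)
  for (col in c("R_margo", "R_canals", "R_apertures", "R_pit")) {
    expect_equal(r2[[col]], 2 * r1[[col]])
  }
})

test_that("margo interaction hook scales the margo term only", {
  # f(eps) must satisfy f(0) = 1; a stronger interaction raises R_margo
  p0 <- model_params(epsilon = 0)
  ph <- model_params(epsilon = 0.3,
                     margo_interaction = function(eps) 1 - eps)
  g <- derive_pit_geometry(12, 5, p0)
  r0 <- pit_resistance(g, p0)
  rh <- pit_resistance(g, ph)
  expect_equal(rh$R_margo, r0$R_margo / 0.7)
  expect_equal(rh$R_canals, r0$R_canals)
  expect_equal(rh$R_apertures, r0$R_apertures)
})

test_that("degenerate geometry is rejected", {
  p <- model_params()
  g <- derive_pit_geometry(12, 5, p)
  g$Da <- 0
  expect_error(pit_resistance(g, p), "degenerate")
})
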