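# FE solutions on small meshes; the fine-mesh oracle comparison at the
# published vessel constants lives in test-acceptance.R

test_that("zero load and unit axial stretch give the trivial solution", {
  sl <- generate_cylinder_fixture(1.5, 3, 120)
  mesh <- build_mesh(sl, n_theta = 24, n_radial = 3)
  sol <- solve_slice(mesh, default_materials(), pressure = 0,
                     axial_stretch = 1, n_increments = 1)
  expect_true(sol$converged)
  expect_lt(max(abs(sol$u)), 1e-10)
  expect_lt(max(abs(sol$stress)), 1e-6)
  expect_lt(max(abs(sol$strain)), 1e-10)
})

test_that("equilibrium solutions are path independent in the increments", {
  sl <- generate_cylinder_fixture(1.5, 3, 120)
  mesh <- build_mesh(sl, n_theta = 24, n_radial = 3)
  s1 <- solve_slice(mesh, default_materials(), 10, 1 / 0.95,
                    n_increments = 3)
  s2 <- solve_slice(mesh, default_materials(), 10, 1 / 0.95,
                    n_increments = 6)
  p1 <- max(capmech:::max_principal(s1$stress))
  p2 <- max(capmech:::max_principal(s2$stress))
  expect_lt(abs(p1 - p2) / p1, 1e-3)
  expect_lt(max(abs(s1$u - s2$u)), 1e-6)
})

test_that("rigid-body constraints leave no net reaction", {
  sl <- generate_cylinder_fixture(1.5, 3, 120)
  mesh <- build_mesh(sl, n_theta = 24, n_radial = 3)
  sol <- solve_slice(mesh, default_materials(), 10, 1 / 0.95,
                     n_increments = 3)
  u <- as.vector(t(sol$u))
  expect_lt(abs(sum(sol$u[, 1])), 1e-6 * nrow(sol$u))
  expect_lt(abs(sum(sol$u[, 2])), 1e-6 * nrow(sol$u))
  expect_lt(sol$residual_norm, 1e-8)
})

test_that("solution is objective: rotating the slice rotates the solution", {
  sl <- annular_lipid_slice(rl = 1.4, ro = 2.6, cap = 0.3)
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mv <- function(p) p %*% t(R)
  sl2 <- slice_contours("rot", "p", "baseline", mv(sl$lumen), mv(sl$outer),
                        lipids = lapply(sl$lipids, mv),
                        pressure_mmHg = sl$pressure_mmHg)
  m1 <- build_mesh(sl, n_theta = 32, n_radial = 3)
  m2 <- build_mesh(sl2, n_theta = 32, n_radial = 3)
  s1 <- solve_slice(m1, default_materials(), 10, 1 / 0.95, n_increments = 3)
  s2 <- solve_slice(m2, default_materials(), 10, 1 / 0.95, n_increments = 3)
  p1 <- sort(capmech:::max_principal(s1$stress))
  p2 <- sort(capmech:::max_principal(s2$stress))
  # same element set up to relabelling of the start angle; compare the
  # distribution of principal stresses
  expect_equal(stats::quantile(p1, c(.1, .5, .9)),
               stats::quantile(p2, c(.1, .5, .9)), tolerance = 0.02)
  expect_equal(s1$lumen_area_deformed, s2$lumen_area_deformed,
               tolerance = 1e-6)
})

test_that("tube oracle has the expected limits", {
  m <- material_params("lipid")
  # pressure 0 under pure axial stretch: r = R / sqrt(lz)
  lz <- 1 / 0.95
  o0 <- analytic_tube_inflation(m, 1.5, 3, 0, lz)
  expect_equal(o0$ri, 1.5 / sqrt(lz), tolerance = 1e-6)
  # monotone response in pressure
  ps <- c(0.5, 1, 2, 4)
  ris <- vapply(ps, function(p) {
    analytic_tube_inflation(m, 1.5, 3, p, 1)$ri
  }, 0)
  expect_true(all(diff(ris) > 0))
  # compliance limit: response linear in pressure within a few percent
  r1 <- analytic_tube_inflation(m, 1.5, 3, 0.02, 1)$ri - 1.5
  r2 <- analytic_tube_inflation(m, 1.5, 3, 0.04, 1)$ri - 1.5
  expect_equal(r2 / r1, 2, tolerance = 0.02)
})

test_that("uniform inflation of a symmetric slice gives uniform cap stress", {
  sl <- generate_cylinder_fixture(1.5, 3, 180)
  mesh <- build_mesh(sl, n_theta = 36, n_radial = 4)
  sol <- solve_slice(mesh, default_materials(), 10, 1 / 0.95,
                     n_increments = 3)
  w <- capmech:::lumen_wall_recovery(sol)
  expect_lt(max(w$stress_max) / mean(w$stress_max), 1.02)
})

test_that("mesh convergence terminates and tracks its history", {
  sl <- generate_cylinder_fixture(1.5, 3, 180)
  mc <- mesh_convergence(sl, default_materials(), pressure = 13.3,
                         axial_stretch = 1 / 0.95, start_size = 0.25,
                         n_increments = 3)
  expect_true(mc$solution$converged)
  expect_gte(nrow(mc$history), 2)
  expect_lt(mc$history$rel_change[nrow(mc$history)], 0.02)
  expect_true(all(diff(mc$history$element_size) < 0))
  # converged metric sits near the oracle peak hoop stress; the
  # 10%-refinement / 2%-delta stopping rule leaves a few percent of
  # residual discretisation error by construction
  oracle <- analytic_tube_inflation(default_materials()$vessel, 1.5, 3,
                                    13.3, 1 / 0.95)
  expect_lt(abs(mc$history$metric[nrow(mc$history)] - max(oracle$hoop)) /
              max(oracle$hoop), 0.05)
})

test_that("cap extraction refuses an unconverged solution", {
  sl <- generate_cylinder_fixture(1.5, 3, 120)
  mesh <- build_mesh(sl, n_theta = 24, n_radial = 3)
  sol <- solve_slice(mesh, default_materials(), 5, 1 / 0.95,
                     n_increments = 2)
  sol$converged <- FALSE
  expect_error(extract_cap_mechanics(sol, cap_samples(sl, 100)),
               "not converged")
})

test_that("a thinner cap concentrates more stress (paired geometries)", {
  feats <- lapply(c(0.45, 0.2), function(cap) {
    sl <- annular_lipid_slice(rl = 1.5, ro = 2.8, cap = cap)
    mesh <- build_mesh(sl, n_theta = 48, n_radial = 5)
    sol <- solve_slice(mesh, default_materials(), 13.3, 1 / 0.95,
                       n_increments = 4)
    cs <- cap_thickness_profile(sl, cap_samples(sl, 100))
    cs <- extract_cap_mechanics(sol, cs)
    cap_aggregates(cs)
  })
  expect_gt(feats[[2]]$MaxCapS, feats[[1]]$MaxCapS)
})
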