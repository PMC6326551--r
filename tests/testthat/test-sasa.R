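test_that("an isolated sphere reproduces its closed-form area", {
  f <- toy_frame("LIGAND_C_MUS", x = 5, y = 5, z = 5, radius = 0.2)
  got <- shrake_rupley(f, 1L, sasa_params())
  expect_lt(abs(got$total_area - 4 * pi * 0.34^2) / (4 * pi * 0.34^2), 0.01)
  expect_equal(got$total_area, sum(got$per_atom$area))
  # probe 0 on a 4 nm sphere: the bare-surface reference area
  bare <- toy_frame("GOLD", x = 5, y = 5, z = 5, radius = 2)
  a <- shrake_rupley(bare, 1L, sasa_params(probe_radius = 0))$total_area
  expect_lt(abs(a - 4 * pi * 2^2) / (4 * pi * 2^2), 0.005)
})

test_that("overlapping spheres match the analytic two-sphere cap formula", {
  r <- 0.2
  p <- 0.14
  for (d in seq(0.1, 2 * (r + p) - 0.02, by = 0.08)) {
    f <- toy_frame(rep("LIGAND_C_MUS", 2), x = c(5, 5 + d), y = 5, z = 5,
                   radius = r)
    got <- shrake_rupley(f, 1:2, sasa_params())$total_area
    expect_lt(abs(got - two_sphere_area(r, p, d)) / two_sphere_area(r, p, d),
              0.01)
  }
})

test_that("the nonpolar subset is exactly the backbone carbons", {
  np <- build_np(2.0, 58, 0.5, seed = 1)
  sub <- nonpolar_subset(np)
  expect_length(sub, 29 * 11 + 29 * 8)
  roles <- np$atoms$role[match(sub, np$atoms$index)]
  expect_true(all(roles %in% c("LIGAND_C_MUS", "LIGAND_C_OT")))
  expect_length(nonpolar_subset(build_np(2.0, 0, 0, 1)), 0)
  expect_length(nonpolar_subset(build_np(2.0, 58, 0, 1)), 58 * 8)
})

test_that("quadrature converges and the result is rigid-motion invariant", {
  np <- build_np(2.0, 58, 0.5, seed = 1)
  f <- np_atoms_frame(np, center = c(6, 6, 6))
  sub <- nonpolar_subset(np)
  a1 <- shrake_rupley(f, sub, sasa_params(n_sphere_points = 960))$total_area
  a4 <- shrake_rupley(f, sub, sasa_params(n_sphere_points = 3840))$total_area
  expect_lt(abs(a4 - a1) / a1, 0.005)
  # translation leaves the quadrature unchanged; rotation only to the
  # (converged) quadrature resolution
  tr <- f
  tr$x <- tr$x + 1.3
  tr$z <- tr$z - 0.7
  at <- shrake_rupley(tr, sub, sasa_params(n_sphere_points = 3840))$total_area
  expect_lt(abs(at - a4) / a4, 1e-12)
  th <- 0.7
  rot <- f
  rot$x <- 6 + cos(th) * (f$x - 6) - sin(th) * (f$y - 6)
  rot$y <- 6 + sin(th) * (f$x - 6) + cos(th) * (f$y - 6)
  ar <- shrake_rupley(rot, sub, sasa_params(n_sphere_points = 3840))$total_area
  expect_lt(abs(ar - a4) / a4, 0.001)
})

test_that("solvent does not occlude but other frame atoms do", {
  base <- tibble::tibble(index = 1:2,
                         role = c("LIGAND_C_MUS", "WATER_O"),
                         x = c(5, 5.1), y = 5, z = 5,
                         radius = c(0.2, 0.152))
  f <- np_frame(base, box = c(10, 10, 10))
  a_water <- shrake_rupley(f, 1L, sasa_params())$total_area
  expect_lt(abs(a_water - 4 * pi * 0.34^2) / (4 * pi * 0.34^2), 0.01)
  base$role[2] <- "LIPID_TAIL"
  f2 <- np_frame(base, box = c(10, 10, 10))
  expect_lt(shrake_rupley(f2, 1L, sasa_params())$total_area, a_water)
})

test_that("burying backbone atoms reduces the subset SASA by their area", {
  np <- build_np(2.0, 6, 0.5, seed = 2)
  reference <- np_atoms_frame(np, center = c(6, 6, 6))
  sub <- nonpolar_subset(np)
  ref_res <- shrake_rupley(reference, sub, sasa_params())

  # engulf the three terminal backbone atoms of one MUS ligand in a fat
  # occluder so they become fully buried
  mus <- np$ligands[np$ligands$kind == "MUS", ]
  target <- tail(mus$backbone_atoms[[1]], 3)
  rows <- match(target, reference$index)
  extra <- tibble::tibble(
    index = max(reference$index) + seq_along(rows),
    role = "GOLD",
    x = reference$x[rows], y = reference$y[rows], z = reference$z[rows],
    radius = 0.8, ligand = NA_integer_, leaflet = NA_character_)
  buried <- np_frame(dplyr::bind_rows(tibble::as_tibble(reference), extra),
                     box = frame_box(reference))
  got <- delta_sasa(buried, reference, np, sasa_params())
  res_b <- shrake_rupley(buried, sub, sasa_params())
  expect_equal(res_b$per_atom$area[match(target, res_b$per_atom$index)],
               rep(0, 3))
  # per-atom bookkeeping: the total change is the sum of per-atom changes,
  # and at least the engulfed atoms' reference area must be lost
  expect_equal(got, sum(res_b$per_atom$area - ref_res$per_atom$area))
  lost <- sum(ref_res$per_atom$area[match(target, ref_res$per_atom$index)])
  expect_lte(got, -lost + 1e-9)
  # occlusion monotonicity: adding occluders never increases subset SASA
  expect_lte(got, 0)
  # identical frames: no change
  expect_equal(delta_sasa(reference, reference, np, sasa_params()), 0)
})

test_that("frames that do not share the particle topology are rejected", {
  np <- build_np(2.0, 6, 0.5, seed = 2)
  f <- np_atoms_frame(np, center = c(6, 6, 6))
  other <- f
  other$role[2] <- "LIPID_TAIL"
  expect_error(delta_sasa(other, f, np), "topology")
})

test_that("hydrophobic scoring is linear with exact additivity", {
  expect_equal(hydrophobic_dg(-11.1, 4.7)$dg, -52.17)
  expect_equal(hydrophobic_dg(-28.3, 4.7)$dg, -133.01)
  expect_equal(hydrophobic_dg(0, 4.7)$dg, 0)
  a <- hydrophobic_dg(-3.2, 4.7)$dg
  b <- hydrophobic_dg(-7.9, 4.7)$dg
  expect_equal(hydrophobic_dg(-3.2 + -7.9, 4.7)$dg, a + b)
  expect_error(hydrophobic_dg(1, Inf), "finite")
})

test_that("missing radii surface as a configuration error", {
  f <- toy_frame("ION_NA", x = 5, y = 5, z = 5)
  f$radius <- NA_real_
  params <- sasa_params(radii_table = c(GOLD = 0.166))
  expect_error(shrake_rupley(f, 1L, params), "radius")
})
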