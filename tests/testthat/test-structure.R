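test_that("the RDF of a uniform gas is flat at unity", {
  withr::with_seed(7, {
    frames <- lapply(1:20, function(i) gas_frame(400, 6))
    prof <- rdf(frames, "WATER_O", "WATER_O", dr = 0.1, r_max = 2.9)
    expect_true(all(abs(prof$g[prof$r > 0.5] - 1) < 0.05))
  })
})

test_that("pairs at a fixed separation populate exactly one bin", {
  # five S-N pairs at 0.52 nm (inside one bin), pairs far apart
  s <- tibble::tibble(index = 1:5, role = "SULFONATE_S",
                      x = seq(1, 9, by = 2), y = 2, z = 5)
  n <- tibble::tibble(index = 6:10, role = "CHOLINE_N",
                      x = seq(1, 9, by = 2), y = 2.52, z = 5)
  f <- np_frame(dplyr::bind_rows(s, n), box = c(10.5, 10.5, 10.5))
  prof <- rdf(f, "SULFONATE_S", "CHOLINE_N", dr = 0.05, r_max = 1.5)
  expect_equal(sum(prof$count), 5)
  occupied <- prof[prof$count > 0, ]
  expect_equal(nrow(occupied), 1)
  expect_lt(abs(occupied$r - 0.52), 0.05)
  expect_equal(occupied$count, 5)
  expect_error(rdf(f, "SULFONATE_S", "ION_CL", dr = 0.05, r_max = 1.5),
               "roles_b")
  expect_error(rdf(f, "SULFONATE_S", "CHOLINE_N", dr = 0.05, r_max = 9),
               "r_max")
})

test_that("RDF pair counts agree exactly with the brute-force oracle", {
  withr::with_seed(13, {
    f <- np_frame(tibble::tibble(
      index = 1:60,
      role = rep(c("SULFONATE_S", "CHOLINE_N", "WATER_O"), each = 20),
      x = runif(60, 0, 4), y = runif(60, 0, 4), z = runif(60, 0, 4)),
      box = c(4, 4, 4))
    prof <- rdf(f, "SULFONATE_S", "CHOLINE_N", dr = 0.1, r_max = 1.9)
    expect_equal(sum(prof$count),
                 brute_force_count(f, "SULFONATE_S", "CHOLINE_N", 1.9))
  })
})

test_that("first_min finds the trough between constructed shells", {
  r <- seq(0.025, 1.5, by = 0.05)
  # two Gaussian shells with the analytic trough at 0.70 nm by symmetry
  g <- exp(-(r - 0.45)^2 / 0.02) + exp(-(r - 0.95)^2 / 0.02)
  prof <- structure(tibble::tibble(r = r, g = g, count = 0), dr = 0.05,
                    class = c("rdf_profile", class(tibble::tibble())))
  expect_lt(abs(first_min(prof) - 0.70), 0.05 + 1e-9)
  # smoothing must not move the minimum of a clean profile
  expect_equal(first_min(prof, smooth_window = 1),
               first_min(prof, smooth_window = 3))
  mono <- structure(tibble::tibble(r = r, g = exp(-r), count = 0), dr = 0.05,
                    class = c("rdf_profile", class(tibble::tibble())))
  expect_error(first_min(mono), "maximum|minimum")
})

test_that("contact counts match brute force and behave physically", {
  withr::with_seed(21, {
    # constructed frame: exactly 3 close S-N pairs, all others far
    s <- tibble::tibble(index = 1:4, role = "SULFONATE_S",
                        x = c(1, 3, 5, 7), y = 1, z = 1)
    n <- tibble::tibble(index = 5:8, role = "CHOLINE_N",
                        x = c(1.5, 3.5, 5.5, 7 + 1.2), y = 1, z = 1)
    f <- np_frame(dplyr::bind_rows(s, n), box = c(9.5, 9.5, 9.5))
    cs <- count_contacts(f, 0.7)
    expect_equal(cs$n_contacts, 3)
    expect_equal(cs$n_contacts, brute_force_count(f, "SULFONATE_S",
                                                  "CHOLINE_N", 0.7))
    # monotone in the threshold
    expect_lte(count_contacts(f, 0.4)$n_contacts,
               count_contacts(f, 0.7)$n_contacts)
    expect_lte(count_contacts(f, 0.7)$n_contacts,
               count_contacts(f, 1.4)$n_contacts)
    # no choline: zero contacts
    f2 <- np_frame(s, box = c(9.5, 9.5, 9.5))
    expect_equal(count_contacts(f2, 0.7)$n_contacts, 0)
  })
})

test_that("contacts are invariant under rigid shifts and re-wrapping", {
  withr::with_seed(31, {
    f <- np_frame(tibble::tibble(
      index = 1:40, role = rep(c("SULFONATE_S", "CHOLINE_N"), each = 20),
      x = runif(40, 0, 5), y = runif(40, 0, 5), z = runif(40, 0, 5)),
      box = c(5, 5, 5))
    base <- count_contacts(f, 0.7)$n_contacts
    shifted <- f
    shifted$x <- shifted$x + 1.7
    shifted$y <- shifted$y - 0.9
    expect_equal(count_contacts(shifted, 0.7)$n_contacts, base)
    expect_equal(count_contacts(wrap_frame(shifted), 0.7)$n_contacts, base)
  })
})

test_that("coordination counts constructed shells exactly", {
  # a sulfonate sulfur with 7 waters inside the threshold and 4 outside
  ang <- seq(0, 2 * pi, length.out = 8)[1:7]
  atoms <- dplyr::bind_rows(
    tibble::tibble(index = 1L, role = "SULFONATE_S", x = 5, y = 5, z = 5,
                   ligand = 1L),
    tibble::tibble(index = 1L + seq_len(7), role = "WATER_O",
                   x = 5 + 0.5 * cos(ang), y = 5 + 0.5 * sin(ang), z = 5,
                   ligand = NA_integer_),
    tibble::tibble(index = 8L + seq_len(4), role = "WATER_O",
                   x = 5 + c(1.2, -1.2, 0, 0), y = 5 + c(0, 0, 1.2, -1.2),
                   z = 5, ligand = NA_integer_))
  f <- np_frame(atoms, box = c(10, 10, 10))
  rec <- npflip:::coordination_core(f, 1L, c(WATER_O = 0.7))
  expect_equal(rec, 7)
  # isolated end group: nothing in range
  f0 <- np_frame(atoms[1, ], box = c(10, 10, 10))
  expect_equal(npflip:::coordination_core(f0, 1L, c(WATER_O = 0.7)), 0)
})

test_that("coordination grows with distance from the midplane", {
  p <- study_params(15, 14, n_frames = 12, seed = 17)
  frames <- gen_trajectory(p)
  dzb <- attr(frames[[1]], "synth")$dz_base
  near <- as.integer(names(dzb)[which.min(abs(dzb))])
  far <- as.integer(names(dzb)[which.max(abs(dzb))])
  rec_near <- coordination(frames, near)
  rec_far <- coordination(frames, far)
  expect_gt(rec_far$coordination_mean, rec_near$coordination_mean)
})

test_that("the density map conserves counts and localises constructions", {
  # bilayer for the midplane, a core for the axis, probes on the axis at z=0
  bl <- tibble::as_tibble(build_bilayer(16, 0.65, box_z = 8))
  core <- tibble::tibble(index = max(bl$index) + 1L, role = "GOLD",
                         x = 1.2, y = 1.2, z = 0.5, radius = 1)
  probes <- tibble::tibble(index = max(bl$index) + 1L + 1:5, role = "ION_NA",
                           x = 1.2, y = 1.2, z = 0.01 * (1:5))
  f <- np_frame(dplyr::bind_rows(bl, core, probes),
                box = c(2.6, 2.6, 8))
  dm <- density_map(f, "ION_NA", dr = 0.2, dz = 0.5)
  occupied <- dm[dm$density > 0, ]
  expect_equal(nrow(occupied), 1)
  expect_lt(occupied$r, 0.2)
  expect_lt(abs(occupied$z), 0.5)
  # volume integral equals the mean mapped atom count
  r_edges <- attr(dm, "r_edges")
  dr_w <- diff(r_edges)[1]
  vols <- 2 * pi * dm$r * dr_w * 0.5
  expect_lt(abs(sum(dm$density * vols) - 5) / 5, 0.001)
  expect_error(density_map(f, "ION_NA", dr = 0, dz = 0.5), "bins")
})

test_that("a uniform gas maps to a flat density", {
  withr::with_seed(41, {
    bl <- tibble::as_tibble(build_bilayer(16, 0.65, box_z = 6))
    core <- tibble::tibble(index = max(bl$index) + 1L, role = "GOLD",
                           x = 1.3, y = 1.3, z = 0, radius = 1)
    box <- c(2.6, 2.6, 6)
    frames <- lapply(1:40, function(i) {
      gas <- tibble::tibble(index = max(bl$index) + 1L + seq_len(2000),
                            role = "WATER_O",
                            x = runif(2000, 0, box[1]),
                            y = runif(2000, 0, box[2]),
                            z = runif(2000, -3, 3))
      np_frame(dplyr::bind_rows(bl, core, gas), box = box)
    })
    dm <- density_map(frames, "WATER_O", dr = 0.65, dz = 3)
    rho <- 2000 / prod(box)
    inner <- dm[dm$r < 1.3, ]   # bins fully inside the box footprint
    expect_true(all(abs(inner$density - rho) / rho < 0.1))
  })
})

test_that("the depth trend fit is exact on a line and robust to ties", {
  exact <- tibble::tibble(n_flipped = 0:14, z = 1 - 0:14 / 14)
  fit <- core_depth_trend(exact)
  expect_equal(fit$slope, -1 / 14)
  expect_equal(fit$intercept, 1)
  expect_true(all(abs(fit$residuals) < 1e-12))
  dup <- tibble::tibble(n_flipped = c(1, 1, 2), z = c(0.9, 1.1, 0.5))
  dup_fit <- core_depth_trend(dup)
  expect_error(core_depth_trend(exact[1, ]), "at least 2")
  # broom-style accessors
  expect_equal(nrow(tidy(dup_fit)), 2)
  expect_true("r.squared" %in% names(glance(dup_fit)))
})

test_that("block averaging matches sigma/sqrt(N) for white noise", {
  withr::with_seed(51, {
    x <- rnorm(4096, 0, 2)
    est <- block_error(x)
    expect_lt(abs(est - 2 / sqrt(4096)) / (2 / sqrt(4096)), 0.2)
  })
  expect_equal(block_error(rep(3.2, 64)), 0)
  expect_error(block_error(c(1, 2)), "too short")
})

test_that("block averaging inflates the error of correlated series", {
  withr::with_seed(61, {
    x <- as.numeric(stats::arima.sim(list(ar = 0.9), 4096))
    expect_gt(block_error(x), 2 * stats::sd(x) / sqrt(4096))
  })
})
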