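# Latitude/longitude orientation analysis and state extraction.
# (make_rot_traj and fake_membrane come from helper-fixtures.R)

test_that("orientation angles match a rotation-matrix oracle over random rotations", {
  set.seed(71)
  rots <- c(list(diag(3)), replicate(100, rand_rotation(), simplify = FALSE))
  sys <- make_rot_traj(rots)
  body <- body_frame(sys$ref)
  os <- orientation_series(sys$traj, sys$rigid_sel, body, fake_membrane())
  for (f in seq_along(rots)) {
    exp_ll <- latlon_oracle(rots[[f]], body$axes)
    expect_lt(abs(os$lat[f] - exp_ll["lat"]), 1e-6)
    expect_lt(abs(lon_diff(os$lon[f], exp_ll["lon"])), 1e-6)
  }
  # identity rotation: reference angles, and repeated calls identical
  os2 <- orientation_series(sys$traj, sys$rigid_sel, body, fake_membrane())
  expect_identical(os$lat, os2$lat)
  expect_identical(os$lon, os2$lon)
})

test_that("rotation about the body z-axis shifts longitude only; rotation about the membrane normal shifts nothing", {
  body0 <- body_frame(memtraj:::rigid_reference_coords(10))
  zb <- body0$axes[3, ]
  rots <- list(diag(3), memtraj:::rot_axis_angle(zb, 30),
               memtraj:::rot_z(30))
  sys <- make_rot_traj(rots)
  body <- body_frame(sys$ref)
  os <- orientation_series(sys$traj, sys$rigid_sel, body, fake_membrane())
  # body z-axis rotation: latitude unchanged, longitude shifted by 30 deg
  expect_equal(os$lat[2], os$lat[1], tolerance = 1e-6)
  expect_equal(abs(lon_diff(os$lon[2], os$lon[1])), 30, tolerance = 1e-6)
  # membrane-normal rotation: both angles unchanged (the normal is the
  # rotation axis, so its body-frame direction cannot move)
  expect_equal(os$lat[3], os$lat[1], tolerance = 1e-6)
  expect_equal(lon_diff(os$lon[3], os$lon[1]), 0, tolerance = 1e-6)
})

test_that("orientation is invariant to rigid translation of the whole system", {
  set.seed(5)
  rots <- replicate(10, rand_rotation(), simplify = FALSE)
  sys <- make_rot_traj(rots)
  body <- body_frame(sys$ref)
  os <- orientation_series(sys$traj, sys$rigid_sel, body, fake_membrane())
  moved <- sys$traj
  for (f in 1:10)
    moved$coords[, , f] <- sweep(sys$traj$coords[, , f], 2,
                                 runif(3, -15, 15), "+")
  os2 <- orientation_series(moved, sys$rigid_sel, body, fake_membrane())
  expect_equal(os2$lat, os$lat, tolerance = 1e-9)
  expect_equal(os2$lon, os$lon, tolerance = 1e-9)
})

test_that("degenerate or mismatched rigid selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(body_frame(line), "degenerate|collinear")
  sys <- make_rot_traj(list(diag(3)))
  body <- body_frame(sys$ref)
  expect_error(orientation_series(sys$traj, 0:8, body, fake_membrane()),
               "mismatch")
})

test_that("orientation histograms count bound frames and respect periodicity", {
  s <- data.frame(time = 0:9, lat = rep(10.2, 10),
                  lon = c(rep(40.1, 6), rep(-120.3, 4)),
                  bound = rep(TRUE, 10))
  h <- orientation_histogram(s, bin_deg = 5)
  expect_equal(sum(h$mass), 1)
  expect_equal(sort(h$mass[h$mass > 0]), c(0.4, 0.6))
  one <- orientation_histogram(s[1:6, ], bin_deg = 5)
  expect_equal(sum(one$mass > 0), 1)
  expect_equal(max(one$mass), 1)
  # smoothing is continuous across the longitude seam
  seam <- data.frame(time = 0:199, lat = 0,
                     lon = rep(c(179, -179), 100), bound = TRUE)
  hs <- orientation_histogram(seam, bin_deg = 5)
  sm <- memtraj:::smooth_orientation_histogram(hs$mass, 5, 10)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # mass at +179 and -179 must blur into one symmetric blob across the seam
  lat_band <- which(abs(hs$lat_centers) < 2.6)
  profile <- sm[, lat_band]
  i_plus <- which(hs$lon_centers == 177.5)
  i_minus <- which(hs$lon_centers == -177.5)
  expect_equal(profile[i_plus], profile[i_minus], tolerance = 1e-9)
  expect_error(orientation_histogram(s[s$lon > 500, ]), "no bound")
})

test_that("a single planted cluster yields one state with population 1", {
  set.seed(2)
  s <- data.frame(time = 1:400, lat = 30 + rnorm(400, sd = 3),
                  lon = -60 + rnorm(400, sd = 3), bound = TRUE)
  sm <- extract_states(orientation_histogram(s))
  expect_equal(nrow(sm$states), 1)
  expect_equal(sm$states$population, 1)
  expect_equal(sm$unassigned_mass, 0)
  expect_lt(memtraj:::great_circle_deg(sm$states$lat, sm$states$lon, 30, -60), 5)
})

test_that("peaks closer than the assignment radius merge deterministically", {
  # two equal-mass spikes 15 deg apart (< 30 deg radius): one state
  s <- data.frame(time = 1:200, lat = 0,
                  lon = rep(c(12.5, 27.5), each = 100), bound = TRUE)
  sm <- extract_states(orientation_histogram(s), smooth_sigma_deg = 2)
  expect_equal(nrow(sm$states), 1)
  expect_equal(sm$states$population, 1)
  # tie-break keeps the lower linear bin index as the centre
  expect_equal(sm$states$lon, 12.5)
})

test_that("scheduled multi-state trajectories recover planted centres and populations", {
  states <- data.frame(lat = c(0, 60, 0, -60),
                       lon = c(-90, 0, 90, 0),
                       population = c(0.4, 0.3, 0.2, 0.1))
  sys <- small_bound_system(n_frames = 2000, seed = 301, states = states)
  bs <- detect_bound_frames(sys$traj)
  memb <- assign_leaflets(get_frame(sys$traj, 1), sys$traj$topology)
  os <- orientation_series(sys$traj, sys$gt$rigid_sel, sys$gt$body, memb, bs)
  sm <- extract_states(orientation_histogram(os))
  expect_equal(nrow(sm$states), 4)
  for (k in seq_len(4)) {
    d <- memtraj:::great_circle_deg(sm$states$lat, sm$states$lon,
                                    states$lat[k], states$lon[k])
    j <- which.min(d)
    expect_lt(d[j], 6)
    expect_equal(sm$states$population[j], states$population[k],
                 tolerance = 0.025)
  }
  # populations + unassigned mass account for every bound frame
  expect_equal(sum(sm$states$population) + sm$unassigned_mass, 1,
               tolerance = 1e-12)
})

test_that("representative frames are the angular medoids with smallest-index ties", {
  series <- data.frame(time = 1:10, lat = 0, lon = 0, bound = TRUE)
  series$lat[2] <- 1; series$lat[4] <- 3; series$lat[9] <- -1
  sm <- structure(list(members = list(c(4L, 9L, 2L)),
                       states = data.frame(state = 1, lat = 0, lon = 0,
                                           population = 1)),
                  class = "orientation_state_map")
  # members at 3, 1 and 1 degrees from the centre: the 1-degree frames tie
  # and the smaller frame index (2) wins over 9
  expect_equal(representative_frame(sm, 1, series), 2L)
  # members at 1 and 3 degrees: the closer frame wins outright
  sm$members <- list(c(2L, 4L))
  expect_equal(representative_frame(sm, 1, series), 2L)
  # one-member state returns that frame
  sm$members <- list(4L)
  expect_equal(representative_frame(sm, 1, series), 4L)
  sm$members <- list(integer(0))
  expect_error(representative_frame(sm, 1, series), "empty")
})

test_that("state-restricted contact profiles isolate planted signatures", {
  # state A plants contacts on residue 1 only, state B on residue 5 only
  tg <- rbind(c(1, 0, 0, 0, 0, 1, 1, 1),
              c(0, 0, 0, 0, 1, 1, 1, 1))
  states <- data.frame(lat = c(0, 0), lon = c(-90, 90),
                       population = c(0.5, 0.5))
  sys <- small_bound_system(n_frames = 600, seed = 88, states = states,
                            contact_targets = tg)
  bs <- detect_bound_frames(sys$traj, min_residues = 4)
  memb <- assign_leaflets(get_frame(sys$traj, 1), sys$traj$topology)
  os <- orientation_series(sys$traj, sys$gt$rigid_sel, sys$gt$body, memb, bs)
  sm <- extract_states(orientation_histogram(os))
  expect_equal(nrow(sm$states), 2)
  whichA <- which.min(abs(lon_diff(sm$states$lon, -90)))
  profA <- state_contact_profile(sm, whichA, sys$traj, part = "head",
                                 collapse_species = TRUE)
  profB <- state_contact_profile(sm, 3 - whichA, sys$traj, part = "head",
                                 collapse_species = TRUE)
  expect_gte(profA$fraction[1, 1], 0.9)
  expect_lte(profB$fraction[1, 1], 0.1)
  expect_gte(profB$fraction[5, 1], 0.9)
  expect_lte(profA$fraction[5, 1], 0.1)
  # membership = all frames reproduces the global profile
  all_frames <- residue_lipid_contact_fractions(sys$traj, part = "head",
                                                collapse_species = TRUE)
  manual <- residue_lipid_contact_fractions(sys$traj, part = "head",
                                            frames = seq_len(n_frames(sys$traj)),
                                            collapse_species = TRUE)
  expect_equal(manual$fraction, all_frames$fraction)
  # single-frame state equals the direct per-frame oracle
  f1 <- sm$members[[1]][1]
  prof1 <- residue_lipid_contact_fractions(sys$traj, part = "head",
                                           frames = f1)
  expect_equal(prof1$fraction, contact_oracle(sys$traj, "head", 7, frames = f1),
               tolerance = 1e-12)
})
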