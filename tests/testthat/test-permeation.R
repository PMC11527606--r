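test_that("compartment boundaries match the planted layout", {
  gen <- generate_trajectory(tiny_spec(seed = 2L), 5L)
  model <- make_model(gen$trajectory)
  expect_true(all(abs(model$z_ext_gate - 25) < 1e-6))
  expect_true(all(abs(model$z_sf_bottom - 15) < 1e-6))
  expect_true(all(abs(model$z_hbc - 0) < 1e-6))
  expect_true(all(abs(model$z_gloop - (-15)) < 1e-6))
})

test_that("swapped boundary selections raise the ordering error", {
  gen <- generate_trajectory(tiny_spec(seed = 2L), 3L)
  b <- boundary_sels(gen$trajectory$topology)
  expect_error(build_compartments(gen$trajectory, b$gloop, b$hbc, b$sf),
               "ordering violated at frame 0")
})

test_that("boundaries are recovered after re-aligning a tilted copy", {
  gen <- generate_trajectory(tiny_spec(seed = 4L), 3L)
  model0 <- make_model(gen$trajectory)
  th <- 0.4
  R <- rbind(c(1, 0, 0),
             c(0, cos(th), -sin(th)),
             c(0, sin(th), cos(th)))
  coords <- gen$trajectory$coords
  for (f in 1:3) coords[, , f] <- sweep(coords[, , f] %*% t(R), 2L,
                                        c(5, -3, 8), "+")
  tilted <- poregate:::new_trajectory(gen$trajectory$topology, coords)
  # realign each frame back onto the original with the package's own
  # superposition, then rebuild
  for (f in 0:2) {
    sup <- superpose(poregate:::frame_coords(tilted, f),
                     poregate:::frame_coords(gen$trajectory, f))
    coords[, , f + 1L] <- poregate:::apply_superposition(
      poregate:::frame_coords(tilted, f), sup)
  }
  aligned <- poregate:::new_trajectory(gen$trajectory$topology, coords)
  model1 <- make_model(aligned)
  expect_equal(model1$z_ext_gate, model0$z_ext_gate, tolerance = 1e-3)
  expect_equal(model1$z_gloop, model0$z_gloop, tolerance = 1e-3)
})

test_that("scripted crossings are counted exactly and directionally", {
  spec <- tiny_spec(n_ions = 5L, seed = 6L)
  gen <- generate_trajectory(spec, 60L,
    ions = make_ion_scripts(spec, 60L, n_complete = 3L, n_abort = 2L))
  traj <- gen$trajectory
  model <- make_model(traj)
  ions <- select_atoms(traj$topology, "resname K")
  ev <- detect_permeation_events(traj, ions, model)
  expect_equal(nrow(ev), 3L)
  expect_equal(nrow(ev), gen$manifest$planted_events$ext_to_int)
  expect_true(all(ev$frame_enter_sf <= ev$frame_cross_hbc))
  expect_true(all(ev$frame_cross_hbc <= ev$frame_exit_gloop))
  # frame-reversed trajectory, same direction: nothing crosses ext->int
  rev <- reverse_frames(traj)
  expect_equal(nrow(detect_permeation_events(rev, ions, make_model(rev))), 0L)
  # zero ions selected -> empty
  none <- suppressWarnings(select_atoms(traj$topology, "resname XX"))
  expect_equal(nrow(detect_permeation_events(traj, none, model)), 0L)
})

test_that("one ion can record several events", {
  spec <- tiny_spec(n_ions = 1L, seed = 7L)
  z_top <- spec$z_ext + 8; z_bot <- spec$z_int - 8
  wp <- data.frame(frame = c(0, 20, 40, 60, 80),
                   z = c(z_top, z_bot, z_top, z_bot, z_bot))
  gen <- generate_trajectory(spec, 90L,
                             ions = list(ion_script(1L, wp, 0.3, "complete")))
  traj <- gen$trajectory
  ev <- detect_permeation_events(traj, select_atoms(traj$topology, "resname K"),
                                 make_model(traj))
  expect_equal(nrow(ev), 2L)
})

test_that("event count is stride-invariant for slow crossings", {
  spec <- tiny_spec(n_ions = 2L, seed = 8L)
  z_top <- spec$z_ext + 8; z_bot <- spec$z_int - 8
  scripts <- list(
    ion_script(1L, data.frame(frame = c(0, 40), z = c(z_top, z_bot)), 0.3,
               "complete"),
    ion_script(2L, data.frame(frame = c(10, 55), z = c(z_top, z_bot)), 0.3,
               "complete"))
  gen <- generate_trajectory(spec, 60L, ions = scripts)
  traj <- gen$trajectory
  model <- make_model(traj)
  ions <- select_atoms(traj$topology, "resname K")
  n1 <- nrow(detect_permeation_events(traj, ions, model,
                                      window = frame_window(0, 60, 1L)))
  n2 <- nrow(detect_permeation_events(traj, ions, model,
                                      window = frame_window(0, 60, 2L)))
  expect_equal(n1, 2L)
  expect_equal(n2, 2L)
})

test_that("reversal duality: ext_to_int on reversed == int_to_ext", {
  spec <- tiny_spec(n_ions = 6L, seed = 9L)
  gen <- generate_trajectory(spec, 80L,
    ions = make_ion_scripts(spec, 80L, n_complete = 2L, n_abort = 1L,
                            n_retrograde = 3L))
  traj <- gen$trajectory
  model <- make_model(traj)
  ions <- select_atoms(traj$topology, "resname K")
  fwd_int <- detect_permeation_events(traj, ions, model, "int_to_ext")
  rev <- reverse_frames(traj)
  rev_ext <- detect_permeation_events(rev, ions, make_model(rev), "ext_to_int")
  expect_equal(nrow(fwd_int), 3L)
  expect_equal(nrow(rev_ext), nrow(fwd_int))
})

test_that("state machine agrees with the brute-force oracle", {
  for (seed in 1:3) {
    spec <- tiny_spec(n_ions = 8L, seed = seed)
    gen <- generate_trajectory(
      spec, 70L,
      ions = make_ion_scripts(spec, 70L, n_complete = 3L, n_abort = 3L,
                              n_retrograde = 2L, lateral_noise_sd = 1.0))
    traj <- gen$trajectory
    model <- make_model(traj)
    ions <- select_atoms(traj$topology, "resname K")
    for (dir in c("ext_to_int", "int_to_ext")) {
      ev <- detect_permeation_events(traj, ions, model, dir)
      expect_equal(nrow(ev),
                   brute_force_events(traj, poregate:::sel_rows(ions),
                                      model, dir),
                   info = paste("seed", seed, dir))
    }
  }
})

test_that("occupancy distributions are exact and sum to 100", {
  spec <- tiny_spec(n_ions = 4L, seed = 11L)
  park <- function(ion, z) ion_script(ion, data.frame(frame = c(0, 99),
                                                      z = c(z, z)), 0.2, "park")
  gen <- generate_trajectory(spec, 100L,
                             ions = list(park(1L, 20), park(2L, 18),
                                         park(3L, 7)))
  traj <- gen$trajectory
  model <- make_model(traj)
  ions <- select_atoms(traj$topology, "resname K")
  occ <- occupancy_distribution(traj, ions, model, "sf")
  expect_equal(occ$percent[occ$k == 2L], 100)
  expect_equal(sum(occ$percent), 100, tolerance = 1e-6)
  occ_c <- occupancy_distribution(traj, ions, model, "cavity")
  expect_equal(occ_c$percent[occ_c$k == 1L], 100)

  # radial gating: move the parked SF ions off-axis beyond the cutoff
  coords <- traj$coords
  rows <- poregate:::sel_rows(ions)[1:2]
  coords[rows, 1L, ] <- 30
  off <- poregate:::new_trajectory(traj$topology, coords)
  occ_r <- occupancy_distribution(off, ions, make_model(off), "sf")
  expect_equal(occ_r$percent[occ_r$k == 0L], 100)
})

test_that("alternating cavity occupancy splits 50/50", {
  spec <- tiny_spec(n_ions = 4L, seed = 12L)
  # ions 1-3 parked in the cavity; ion 4 alternates in/out every frame
  sc <- list(
    ion_script(1L, data.frame(frame = c(0, 99), z = c(10, 10)), 0.2, "park"),
    ion_script(2L, data.frame(frame = c(0, 99), z = c(6, 6)), 0.2, "park"),
    ion_script(3L, data.frame(frame = c(0, 99), z = c(3, 3)), 0.2, "park"),
    ion_script(4L, data.frame(frame = 0:99,
                              z = rep(c(8, 40), 50L)), 0.2, "park"))
  gen <- generate_trajectory(spec, 100L, ions = sc)
  traj <- gen$trajectory
  occ <- occupancy_distribution(traj, select_atoms(traj$topology, "resname K"),
                                make_model(traj), "cavity")
  expect_equal(occ$percent[occ$k == 3L], 50)
  expect_equal(occ$percent[occ$k == 4L], 50)
})

test_that("dwell profile recovers scripted 60/30/10 region split", {
  spec <- tiny_spec(n_ions = 1L, seed = 13L)
  wp <- data.frame(frame = c(0, 59, 60, 89, 90, 99),
                   z = c(20, 20, 7, 7, -5, -5))
  gen <- generate_trajectory(spec, 100L,
                             ions = list(ion_script(1L, wp, 0.2, "park")))
  traj <- gen$trajectory
  dw <- dwell_profile(traj, select_atoms(traj$topology, "resname K"),
                      make_model(traj),
                      select_atoms(traj$topology, "protein", "residue"))
  expect_equal(unname(dw$region_percent[c("sf", "cavity", "gloop")]),
               c(60, 30, 10))
  expect_equal(sum(dw$region_percent), 100, tolerance = 1e-6)
})

test_that("residue assignment ties break to the lower (chain, resid)", {
  spec <- tiny_spec(n_ions = 1L, seed = 14L)
  # noiseless ion on the pore axis at the HBC gate: equidistant from all
  # four gate CZ beads -> chain A wins
  gen <- generate_trajectory(
    spec, 10L,
    schedules = list(gate_schedule("HBC", "constant", value = 8)),
    ions = list(ion_script(1L, data.frame(frame = c(0, 9), z = c(0, 0)),
                           lateral_noise_sd = 0, outcome = "park")))
  traj <- gen$trajectory
  dw <- dwell_profile(traj, select_atoms(traj$topology, "resname K"),
                      make_model(traj),
                      select_atoms(traj$topology, "protein", "residue"))
  hit <- dw$residue_percent[dw$residue_percent$percent > 0, ]
  expect_equal(hit$residue, "PHE7(A)")
  expect_equal(hit$percent, 100)
})

test_that("permeating_ions_only restricts dwell to event intervals", {
  spec <- tiny_spec(n_ions = 2L, seed = 15L)
  z_top <- spec$z_ext + 8; z_bot <- spec$z_int - 8
  sc <- list(
    ion_script(1L, data.frame(frame = c(10, 50), z = c(z_top, z_bot)), 0.3,
               "complete"),
    ion_script(2L, data.frame(frame = c(0, 99), z = c(10, 10)), 0.3, "park"))
  gen <- generate_trajectory(spec, 100L, ions = sc)
  traj <- gen$trajectory
  model <- make_model(traj)
  ions <- select_atoms(traj$topology, "resname K")
  res <- select_atoms(traj$topology, "protein", "residue")
  all_ions <- dwell_profile(traj, ions, model, res)
  perm <- dwell_profile(traj, ions, model, res, scope = "permeating_ions_only")
  expect_lt(perm$n_ion_frames, all_ions$n_ion_frames)
  # the permeating ion traverses every region
  expect_true(all(perm$region_percent[c("sf", "cavity", "gloop")] > 0))
  expect_error(dwell_profile(traj, ions, model, res, assign_cutoff = 0),
               "positive")
})
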