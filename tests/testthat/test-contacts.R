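test_that("salt bridge forms below and not above the cutoff", {
  atoms <- data.frame(name = c("CA", "NZ", "CA", "OE1"),
                      resid = c(5L, 5L, 40L, 40L),
                      resname = c("LYS", "LYS", "GLU", "GLU"),
                      chain = c("A", "A", "B", "B"))
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0), c(4.4, 0, 0))
  traj <- hand_system(atoms, near)
  crit <- contact_criteria("salt_bridge")  # 4.0 A
  hits <- detect_contacts_frame(poregate:::frame_coords(traj, 0L),
                                traj$topology, crit)
  expect_equal(nrow(hits), 1L)   # NZ-OE1 at 3.4 A
  far <- near; far[4L, 1L] <- 5.5
  traj2 <- hand_system(atoms, far)
  expect_equal(nrow(detect_contacts_frame(poregate:::frame_coords(traj2, 0L),
                                          traj2$topology, crit)), 0L)
})

test_that("hydrogen bonds require both distance and angle", {
  atoms <- data.frame(name = c("OG", "HG", "OE1"),
                      resid = c(5L, 5L, 40L),
                      resname = c("SER", "SER", "GLN"),
                      chain = c("A", "A", "B"))
  crit <- contact_criteria("hbond")  # 3.5 A, 135 deg
  linear <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.4, 0, 0))
  traj <- hand_system(atoms, linear)
  expect_equal(nrow(detect_contacts_frame(poregate:::frame_coords(traj, 0L),
                                          traj$topology, crit)), 1L)
  # same donor-acceptor distance but D-H...A angle of 90 degrees
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 3.3, 0))
  stopifnot(sqrt(sum((bent[3, ] - bent[1, ])^2)) <= 3.5)
  traj2 <- hand_system(atoms, bent)
  expect_equal(nrow(detect_contacts_frame(poregate:::frame_coords(traj2, 0L),
                                          traj2$topology, crit)), 0L)
})

test_that("backbone-adjacent and intra-residue pairs are excluded", {
  atoms <- data.frame(name = c("CD1", "CD1", "CD1"),
                      resid = c(5L, 6L, 9L),
                      resname = "LEU", chain = "A")
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  traj <- hand_system(atoms, xyz)
  hits <- detect_contacts_frame(poregate:::frame_coords(traj, 0L),
                                traj$topology, contact_criteria("hydrophobic"))
  # 5-6 adjacent (excluded); 6-9 at 2 A allowed; 5-9 at 4 A allowed
  expect_equal(nrow(hits), 2L)
  expect_true(all(abs(hits$resid_a - hits$resid_b) > 1L))
})

test_that("frame detection equals the brute-force all-pairs oracle", {
  spec <- tiny_spec(seed = 31L)
  gen <- generate_trajectory(
    spec, 3L,
    schedules = list(gate_schedule("HBC", "constant", value = 4.2)),
    contacts = list(
      contact_plan(res_ref("A", 12), res_ref("B", 12), "salt_bridge", 1.0),
      contact_plan(res_ref("A", 14), res_ref("C", 14), "hbond", 1.0),
      contact_plan(res_ref("B", 13), res_ref("D", 13), "hydrophobic", 1.0)))
  traj <- gen$trajectory
  for (ct in c("salt_bridge", "hbond", "hydrophobic")) {
    crit <- contact_criteria(ct)
    mine <- detect_contacts_frame(poregate:::frame_coords(traj, 1L),
                                  traj$topology, crit)
    ref <- brute_force_contacts(poregate:::frame_coords(traj, 1L),
                                traj$topology, crit)
    expect_identical(sort(poregate:::pair_id(mine)), ref, info = ct)
  }
})

test_that("planted fractions are recovered exactly for all types", {
  spec <- tiny_spec(seed = 32L)
  plans <- list(
    contact_plan(res_ref("A", 12), res_ref("B", 12), "salt_bridge", 0.10),
    contact_plan(res_ref("C", 12), res_ref("D", 12), "hbond", 0.50),
    contact_plan(res_ref("A", 14), res_ref("C", 14), "hydrophobic", 0.75))
  gen <- generate_trajectory(spec, 200L, contacts = plans)
  for (p in plans) {
    tab <- pair_fractions(gen$trajectory, contact_criteria(p$contact_type))
    expect_equal(lookup_fraction(tab, p$res_a$chain, p$res_a$resid,
                                 p$res_b$chain, p$res_b$resid),
                 p$planted_fraction, info = p$contact_type)
  }
})

test_that("static repeated frame gives fraction 1; absent pair reads 0", {
  spec <- tiny_spec(seed = 33L)
  gen <- generate_trajectory(spec, 50L,
    contacts = list(contact_plan(res_ref("A", 12), res_ref("B", 12),
                                 "salt_bridge", 1.0)))
  tab <- pair_fractions(gen$trajectory, contact_criteria("salt_bridge"))
  expect_equal(tab$entries$fraction, 1.0)
  expect_equal(lookup_fraction(tab, "A", 3L, "B", 3L), 0)
})

test_that("difference tables subtract holo - apo with missing-as-zero", {
  spec <- tiny_spec(seed = 34L)
  mk <- function(f) {
    gen <- generate_trajectory(spec, 100L,
      contacts = list(contact_plan(res_ref("A", 12), res_ref("B", 12),
                                   "salt_bridge", f)))
    pair_fractions(gen$trajectory, contact_criteria("salt_bridge"),
                   system_label = paste0("f", f))
  }
  apo <- mk(0.9); holo <- mk(0.2)
  d <- difference_table(apo, holo)
  expect_equal(d$entries$delta, -0.7)
  # identical tables -> all zero
  expect_equal(difference_table(apo, apo)$entries$delta, 0)
  # pair present only in holo
  none <- mk(0.0)
  d2 <- difference_table(none, mk(0.6))
  expect_equal(d2$entries$delta, 0.6)
  expect_equal(d2$entries$fraction_apo, 0)
  # antisymmetry
  d3 <- difference_table(holo, apo)
  expect_equal(d3$entries$delta, -d$entries$delta)
  # type mismatch
  gen2 <- generate_trajectory(spec, 10L)
  hb <- pair_fractions(gen2$trajectory, contact_criteria("hbond"))
  expect_error(difference_table(apo, hb), "mismatch")
})

test_that("top_differences ranks |delta| with deterministic ties", {
  base <- generate_trajectory(tiny_spec(seed = 35L), 10L)
  tab0 <- pair_fractions(base$trajectory, contact_criteria("salt_bridge"))
  fake <- function(entries) {
    t <- tab0; t$entries <- entries; t
  }
  e <- data.frame(chain_a = c("A", "A", "B"), resid_a = c(1L, 2L, 3L),
                  resname_a = "LYS", chain_b = c("B", "B", "C"),
                  resid_b = c(1L, 2L, 3L), resname_b = "GLU",
                  type = "salt_bridge", fraction = c(0.9, 0.5, 0.5),
                  stringsAsFactors = FALSE)
  apo <- fake(e)
  holo <- fake(transform(e, fraction = 0))
  d <- difference_table(apo, holo)   # deltas -0.9, -0.5, -0.5
  top2 <- top_differences(d, k = 2L)
  expect_equal(abs(top2$delta), c(0.9, 0.5))
  expect_equal(top2$chain_a[2L], "A")   # tie broken by canonical key
  expect_equal(nrow(top_differences(d, threshold = 0.95)), 0L)
  expect_equal(nrow(top_differences(d, threshold = 0.9)), 1L)
  expect_error(top_differences(d, k = 0L), "positive")
})

test_that("fractions are invariant under rigid-body motion", {
  spec <- tiny_spec(seed = 36L)
  gen <- generate_trajectory(spec, 40L,
    contacts = list(contact_plan(res_ref("A", 12), res_ref("B", 12),
                                 "salt_bridge", 0.5)))
  coords <- gen$trajectory$coords
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  for (f in seq_len(dim(coords)[3L]))
    coords[, , f] <- sweep(coords[, , f] %*% t(R), 2L, c(7, -2, 3), "+")
  moved <- poregate:::new_trajectory(gen$trajectory$topology, coords)
  t0 <- pair_fractions(gen$trajectory, contact_criteria("salt_bridge"))
  t1 <- pair_fractions(moved, contact_criteria("salt_bridge"))
  expect_equal(t1$entries$fraction, t0$entries$fraction)
})

test_that("ligand contact percentages are planted and bounded", {
  spec <- tiny_spec(n_ligands = 1L, seed = 37L)
  gen <- generate_trajectory(spec, 100L,
    ligand_contacts = list(ligand_plan(1L, res_ref("A", 12), 0.4)))
  traj <- gen$trajectory
  lig <- select_atoms(traj$topology, "ligand")
  res <- select_atoms(traj$topology, "protein", "residue")
  prof <- ligand_contact_profile(traj, lig, res)
  expect_equal(prof$percent[prof$residue == "ALA12(A)"], 40)
  expect_true(all(prof$percent >= 0 & prof$percent <= 100))
  expect_equal(sum(prof$percent > 0), 1L)
  none <- suppressWarnings(select_atoms(traj$topology, "resname ZZZ"))
  expect_error(ligand_contact_profile(traj, none, res), "empty ligand")
})
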