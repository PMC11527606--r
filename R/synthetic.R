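#' @section Synthetic channels:
#' The generator builds a toy C4-symmetric tetrameric channel (chains
#' A-D) around the z pore axis, with the extracellular side at larger z.
#' Geometry is kinematic, not physical: beads are placed to realise
#' planted ground truth exactly — gate aperture schedules, scripted ion
#' crossings, contact formed-fractions, residue-pair displacement
#' correlations, and backbone phi/psi torsions — and every planted
#' quantity is echoed in a machine-readable manifest so analysis output
#' can be verified without running MD.
#' @name poregate-synthetic
NULL

#' Toy channel specification
#'
#' Defaults emulate the architecture of an inwardly rectifying potassium
#' channel pore: a selectivity filter (SF) near the extracellular mouth,
#' the helix-bundle-crossing (HBC) gate mid-membrane, and the G-loop gate
#' in the cytosolic domain, ordered z_SF > z_HBC > z_Gloop.
#'
#' @param residues_per_subunit residues per chain (>= 12 with the default
#'   layout).
#' @param pore_radius pore radius in Angstrom; the protein backbone ring
#'   sits 4 A outside it.
#' @param z_extents `c(z_int, z_ext)` in Angstrom; residues are laid out
#'   linearly from z_ext (residue 1) down to z_int.
#' @param gate_layout named list of `list(resid=, z=)` for gates `HBC`
#'   and `Gloop`.
#' @param sf_layout `list(resids=, z=c(lo, hi))` for the SF residues.
#' @param n_ions number of potassium ions appended.
#' @param n_ligands number of ligand beads (resname CHS) appended.
#' @param seed integer master seed; all generator randomness derives
#'   from it.
#' @return a `pg_channel_spec`.
#' @export
channel_spec <- function(residues_per_subunit = 16L,
                         pore_radius = 10,
                         z_extents = c(-45, 30),
                         gate_layout = list(HBC = list(resid = 7L, z = 0),
                                            Gloop = list(resid = 10L, z = -15)),
                         sf_layout = list(resids = 2:4, z = c(15, 25)),
                         n_ions = 0L,
                         n_ligands = 0L,
                         seed = 1L) {
  nres <- as.integer(residues_per_subunit)
  z_int <- min(z_extents); z_ext <- max(z_extents)
  special <- c(unlist(lapply(gate_layout, `[[`, "resid")), sf_layout$resids)
  if (nres < max(special))
    stop("residues_per_subunit smaller than the laid-out special residues")
  # per-residue z: linear ladder with gate/SF overrides
  res_z <- seq(z_ext, z_int, length.out = nres)
  sfr <- sort(as.integer(sf_layout$resids))
  res_z[sfr] <- seq(max(sf_layout$z), min(sf_layout$z), length.out = length(sfr))
  for (g in names(gate_layout)) res_z[gate_layout[[g]]$resid] <- gate_layout[[g]]$z
  z_sf <- mean(sf_layout$z)
  if (!(z_sf > gate_layout$HBC$z && gate_layout$HBC$z > gate_layout$Gloop$z))
    stop("gates must be ordered z_SF > z_HBC > z_Gloop")
  structure(list(n_subunits = 4L, residues_per_subunit = nres,
                 pore_radius = pore_radius,
                 z_int = z_int, z_ext = z_ext,
                 gate_layout = gate_layout, sf_layout = sf_layout,
                 res_z = res_z, backbone_radius = pore_radius + 4,
                 n_ions = as.integer(n_ions), n_ligands = as.integer(n_ligands),
                 seed = as.integer(seed)),
            class = "pg_channel_spec")
}

#' Reference a residue of the toy channel
#' @param chain chain id `"A"`..`"D"`.
#' @param resid residue number within the subunit.
#' @export
res_ref <- function(chain, resid) {
  list(chain = as.character(chain), resid = as.integer(resid))
}

ref_label <- function(r) paste0(r$chain, ":", r$resid)

#' Gate aperture schedule
#'
#' @param gate gate name from the spec's `gate_layout`.
#' @param kind `"constant"`, `"square"`, `"sine"` or `"explicit"`.
#' @param value constant aperture (A).
#' @param lo,hi square-wave apertures (A).
#' @param frac_hi fraction of frames at `hi` (square).
#' @param period square/sine period in frames.
#' @param mean_d,amplitude sine parameters (A).
#' @param values explicit per-frame aperture vector (A).
#' @export
gate_schedule <- function(gate, kind = c("constant", "square", "sine", "explicit"),
                          value = 8, lo = 4, hi = 9, frac_hi = 0.5,
                          period = 10L, mean_d = 6, amplitude = 2,
                          values = NULL) {
  kind <- match.arg(kind)
  structure(list(gate = gate, kind = kind, value = value, lo = lo, hi = hi,
                 frac_hi = frac_hi, period = as.integer(period),
                 mean_d = mean_d, amplitude = amplitude, values = values),
            class = "pg_gate_schedule")
}

schedule_values <- function(sched, n_frames) {
  t <- seq_len(n_frames) - 1L
  v <- switch(sched$kind,
    constant = rep(sched$value, n_frames),
    square = ifelse((t %% sched$period) < sched$frac_hi * sched$period,
                    sched$hi, sched$lo),
    sine = sched$mean_d + sched$amplitude * sin(2 * pi * t / sched$period),
    explicit = {
      if (length(sched$values) != n_frames)
        stop("explicit schedule length must equal n_frames")
      sched$values
    })
  if (any(v <= 0)) stop("gate schedule must be positive at every frame")
  v
}

#' Scripted ion
#'
#' An ion's z trajectory is the piecewise-linear interpolation of
#' `waypoints` (held constant before the first and after the last), with
#' seeded Gaussian lateral noise clipped to 80% of the pore radius. The
#' z component carries no noise, so the permeation detector's hysteresis
#' margin guarantees exact event recovery.
#'
#' @param ion 1-based index among the spec's ions.
#' @param waypoints data frame with columns `frame` (0-based) and `z` (A),
#'   monotone in `frame`.
#' @param lateral_noise_sd lateral noise SD (A).
#' @param outcome `"complete"` (extracellular to intracellular),
#'   `"abort"`, `"retrograde"` or `"park"`; bookkeeping for the manifest.
#' @export
ion_script <- function(ion, waypoints, lateral_noise_sd = 0.5,
                       outcome = c("complete", "abort", "retrograde", "park")) {
  outcome <- match.arg(outcome)
  waypoints <- as.data.frame(waypoints)
  stopifnot(all(c("frame", "z") %in% names(waypoints)))
  if (is.unsorted(waypoints$frame, strictly = FALSE))
    stop("ion waypoints must be monotone in frame")
  structure(list(ion = as.integer(ion), waypoints = waypoints,
                 lateral_noise_sd = lateral_noise_sd, outcome = outcome),
            class = "pg_ion_script")
}

#' Build a batch of crossing/abort/retrograde ion scripts
#'
#' Convenience wrapper that spreads the scripted passes over the frame
#' range of a trajectory. Complete scripts traverse from above the SF to
#' below the G loop; aborts descend to the central cavity and return;
#' retrograde scripts run intracellular to extracellular.
#'
#' @param spec a `pg_channel_spec` (its z extents set the endpoints).
#' @param n_frames trajectory length the scripts must fit in.
#' @param n_complete,n_abort,n_retrograde script counts.
#' @param lateral_noise_sd lateral noise SD (A).
#' @return list of `pg_ion_script`, one per ion `1..n_total`.
#' @export
make_ion_scripts <- function(spec, n_frames, n_complete = 0L, n_abort = 0L,
                             n_retrograde = 0L, lateral_noise_sd = 0.5) {
  z_top <- spec$z_ext + 8
  z_bot <- spec$z_int - 8
  z_cav <- (spec$gate_layout$HBC$z + mean(spec$sf_layout$z)) / 2
  total <- n_complete + n_abort + n_retrograde
  if (total == 0L) return(list())
  span <- max(8L, n_frames - 2L)
  scripts <- vector("list", total)
  k <- 0L
  stagger <- function(i, n) {
    # spread departures; every script still spans >= 8 frames
    f0 <- ((i - 1L) %% max(1L, n_frames - 9L))
    c(f0, min(n_frames - 1L, f0 + 8L))
  }
  for (i in seq_len(n_complete)) {
    k <- k + 1L
    f <- stagger(k, total)
    scripts[[k]] <- ion_script(k, data.frame(frame = f, z = c(z_top, z_bot)),
                               lateral_noise_sd, outcome = "complete")
  }
  for (i in seq_len(n_abort)) {
    k <- k + 1L
    f <- stagger(k, total)
    mid <- floor(mean(f))
    scripts[[k]] <- ion_script(k, data.frame(frame = c(f[1L], mid, f[2L]),
                                             z = c(z_top, z_cav, z_top)),
                               lateral_noise_sd, outcome = "abort")
  }
  for (i in seq_len(n_retrograde)) {
    k <- k + 1L
    f <- stagger(k, total)
    scripts[[k]] <- ion_script(k, data.frame(frame = f, z = c(z_bot, z_top)),
                               lateral_noise_sd, outcome = "retrograde")
  }
  scripts
}

#' Planted contact between two residues
#'
#' The generator assigns residue types by role: salt bridges pair a
#' lysine (NZ) with a glutamate (OE1); hydrogen bonds a serine donor
#' (OG/HG) with a glutamine acceptor (OE1); hydrophobic contacts two
#' leucines (CD1). In formed frames the partner bead sits at
#' `formed_distance`, otherwise at `broken_distance`; both must clear
#' the detection cutoff by at least 0.5 A so classification is
#' unambiguous and fraction recovery exact.
#'
#' @param res_a,res_b [res_ref()] residues (a residue may appear in at
#'   most one contact plan).
#' @param contact_type `"salt_bridge"`, `"hbond"` or `"hydrophobic"`.
#' @param planted_fraction fraction of frames formed, in `[0, 1]`.
#' @param formed_distance,broken_distance bead distances (A); defaults
#'   straddle the default criteria cutoffs.
#' @export
contact_plan <- function(res_a, res_b,
                         contact_type = c("salt_bridge", "hbond", "hydrophobic"),
                         planted_fraction,
                         formed_distance = NULL, broken_distance = NULL) {
  contact_type <- match.arg(contact_type)
  cutoff <- default_contact_cutoff(contact_type)
  if (is.null(formed_distance)) formed_distance <- cutoff - 1.0
  if (is.null(broken_distance)) broken_distance <- cutoff + 2.5
  if (!(formed_distance < cutoff - 0.5 && broken_distance > cutoff + 0.5))
    stop("formed/broken distances must clear the cutoff by 0.5 A")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must be in [0, 1]")
  structure(list(res_a = res_a, res_b = res_b, contact_type = contact_type,
                 planted_fraction = planted_fraction,
                 formed_distance = formed_distance,
                 broken_distance = broken_distance),
            class = "pg_contact_plan")
}

#' Planted displacement correlation between two residues
#'
#' Both residues are displaced along the unit vector joining them in
#' the xy-plane by `d_i(t) = a s(t) + e_i(t)` (the second with
#' `sign(rho) * a`), with `a^2 = |rho|` and noise variance `1 - |rho|`,
#' so the analytic Pearson correlation of the two displacement series —
#' and hence the displacement-vector cross-correlation — equals `rho`.
#'
#' @param res_a,res_b [res_ref()] residues.
#' @param target_rho value in (-1, 1).
#' @param amplitude displacement scale (A).
#' @export
correlation_plan <- function(res_a, res_b, target_rho, amplitude = 1.5) {
  if (abs(target_rho) >= 1) stop("target_rho must be in (-1, 1)")
  structure(list(res_a = res_a, res_b = res_b, target_rho = target_rho,
                 amplitude = amplitude),
            class = "pg_correlation_plan")
}

#' Planted backbone torsions for one residue
#'
#' The residue's carbonyl carbon and the next residue's amide nitrogen
#' are re-placed by internal-coordinate (NeRF) construction so the
#' computed phi/psi equal the planted values exactly at zero jitter;
#' per-frame jitter is added on the dihedral itself. The residue must be
#' interior (not first/last of its chain) and not adjacent to another
#' torsion-planned residue.
#'
#' @param res a [res_ref()].
#' @param phi,psi planted dihedrals in degrees, in (-180, 180].
#' @param jitter_sd circular jitter SD in degrees.
#' @export
torsion_plan <- function(res, phi, psi, jitter_sd = 0) {
  structure(list(res = res, phi = phi, psi = psi, jitter_sd = jitter_sd),
            class = "pg_torsion_plan")
}

#' Planted collective breathing mode
#'
#' Displaces one residue ring (the given residue in all four chains)
#' radially by `amplitude * s(t)` with `s ~ N(0,1)`. A C4-symmetric
#' radial mode carries no net translation or torque, so it survives
#' rigid-body superposition exactly — the planted single-mode fixture
#' for PCA checks.
#'
#' @param resid residue number displaced in all four subunits.
#' @param amplitude mode amplitude (A).
#' @export
breathing_plan <- function(resid, amplitude = 2) {
  structure(list(resid = as.integer(resid), amplitude = amplitude),
            class = "pg_breathing_plan")
}

#' Planted ligand-residue contact schedule
#'
#' @param ligand 1-based ligand index.
#' @param res target [res_ref()].
#' @param fraction fraction of frames in contact.
#' @param near,far bead distances (A) from the residue's outer side-chain
#'   bead in contact / no-contact frames.
#' @export
ligand_plan <- function(ligand, res, fraction, near = 3.0, far = 40) {
  structure(list(ligand = as.integer(ligand), res = res, fraction = fraction,
                 near = near, far = far),
            class = "pg_ligand_plan")
}

## ---- topology construction ----

BEAD_SETS <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  PHE = c("N", "CA", "C", "O", "CB", "CZ"),
  LYS = c("N", "CA", "C", "O", "NZ"),
  GLU = c("N", "CA", "C", "O", "OE1"),
  SER = c("N", "CA", "C", "O", "OG", "HG"),
  GLN = c("N", "CA", "C", "O", "OE1"),
  LEU = c("N", "CA", "C", "O", "CD1")
)

bead_element <- function(name) {
  first <- substr(gsub("^[0-9]+", "", name), 1, 1)
  toupper(first)
}

# Decide each residue's type from the spec and plans.
assign_residue_types <- function(spec, contacts, chains = c("A", "B", "C", "D")) {
  nres <- spec$residues_per_subunit
  types <- matrix("ALA", nrow = 4L, ncol = nres, dimnames = list(chains, NULL))
  for (g in names(spec$gate_layout))
    types[, spec$gate_layout[[g]]$resid] <- "PHE"
  role_types <- list(salt_bridge = c("LYS", "GLU"),
                     hbond = c("SER", "GLN"),
                     hydrophobic = c("LEU", "LEU"))
  seen <- character()
  for (cp in contacts) {
    for (side in 1:2) {
      r <- if (side == 1L) cp$res_a else cp$res_b
      lab <- ref_label(r)
      if (lab %in% seen)
        stop("residue ", lab, " appears in more than one contact plan")
      seen <- c(seen, lab)
      if (r$resid > nres) stop("contact plan references residue beyond subunit")
      if (types[r$chain, r$resid] != "ALA")
        stop("contact plan residue ", lab, " collides with a special residue")
      types[r$chain, r$resid] <- role_types[[cp$contact_type]][side]
    }
  }
  types
}

subunit_angle <- function(chain) {
  deg2rad(45 + 90 * (match(chain, c("A", "B", "C", "D")) - 1L))
}

# Base (frame-independent) bead positions for one residue.
residue_base_coords <- function(beads, theta, radius, z, pore_radius) {
  er <- c(cos(theta), sin(theta), 0)
  et <- c(-sin(theta), cos(theta), 0)
  ca <- radius * er + c(0, 0, z)
  pos <- list(
    N = ca - 1.2 * et - 0.5 * er,
    CA = ca,
    C = ca + 1.2 * et - 0.5 * er,
    O = ca + 1.2 * et + 0.1 * er,
    CB = ca + 1.5 * er,
    CZ = (pore_radius / 2) * er + c(0, 0, z),  # gate bead; re-placed per frame
    NZ = ca + 2.5 * er,
    OE1 = ca + 2.5 * er,
    OG = ca + 2.0 * er,
    HG = ca + 3.0 * er,
    CD1 = ca + 2.0 * er
  )
  do.call(rbind, pos[beads])
}

#' Generate a toy channel topology
#'
#' Four chains A-D with C4 symmetry about z; each residue carries
#' backbone beads N/CA/C/O plus type-specific side-chain beads, with
#' residue types driven by the gate layout and any contact plans. Ions
#' (resname K, chain I) and ligand beads (resname CHS, chain X) are
#' appended. Deterministic: the construction draws no random numbers.
#'
#' @param spec a `pg_channel_spec`.
#' @param contacts optional list of [contact_plan()]s (they determine
#'   residue types, so the topology must know them).
#' @return a `pg_topology`.
#' @export
generate_topology <- function(spec, contacts = list()) {
  base <- build_base_system(spec, contacts)
  base$topology
}

# Build atom table + base coordinate matrix + lookup index.
build_base_system <- function(spec, contacts = list()) {
  chains <- c("A", "B", "C", "D")
  types <- assign_residue_types(spec, contacts, chains)
  rows <- list()
  coords <- list()
  for (ch in chains) {
    theta <- subunit_angle(ch)
    for (i in seq_len(spec$residues_per_subunit)) {
      ty <- types[ch, i]
      beads <- BEAD_SETS[[ty]]
      xyz <- residue_base_coords(beads, theta, spec$backbone_radius,
                                 spec$res_z[i], spec$pore_radius)
      rows[[length(rows) + 1L]] <- data.frame(
        name = beads, element = vapply(beads, bead_element, ""),
        resid = i, resname = ty, chain = ch, insert = "",
        is_ion = FALSE, is_ligand = FALSE, stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- xyz
    }
  }
  if (spec$n_ions > 0L) {
    i <- seq_len(spec$n_ions)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "K", element = "K", resid = i, resname = "K", chain = "I",
      insert = "", is_ion = TRUE, is_ligand = FALSE, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- cbind(2 * cos(i), 2 * sin(i),
                                           spec$z_ext + 12 + 3 * i)
  }
  if (spec$n_ligands > 0L) {
    i <- seq_len(spec$n_ligands)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "C1", element = "C", resid = i, resname = "CHS", chain = "X",
      insert = "", is_ion = FALSE, is_ligand = TRUE, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- cbind(spec$backbone_radius + 40 + 5 * i,
                                           0 * i, 0 * i)
  }
  atoms <- do.call(rbind, rows)
  atoms$index <- seq_len(nrow(atoms)) - 1L
  atoms <- atoms[, c("index", "name", "element", "resid", "resname",
                     "chain", "insert", "is_ion", "is_ligand")]
  list(topology = new_topology(atoms),
       base = do.call(rbind, coords))
}

# Row (1-based) of a named bead of residue (chain, resid); 0 rows if absent.
bead_row <- function(topology, chain, resid, name) {
  a <- topology$atoms
  which(a$chain == chain & a$resid == resid & a$name == name & !a$is_ion &
          !a$is_ligand)
}

residue_rows <- function(topology, chain, resid) {
  a <- topology$atoms
  which(a$chain == chain & a$resid == resid & !a$is_ion & !a$is_ligand)
}

## ---- trajectory generation ----

#' Generate a toy channel trajectory with planted ground truth
#'
#' Realises every plan exactly (see the individual plan constructors)
#' and returns the trajectory together with a manifest sufficient to
#' verify every analysis output. Identical inputs and seed give
#' byte-identical results.
#'
#' @param spec a `pg_channel_spec`.
#' @param n_frames number of frames (>= 1).
#' @param schedules list of [gate_schedule()]s.
#' @param ions list of [ion_script()]s.
#' @param contacts list of [contact_plan()]s.
#' @param correlations list of [correlation_plan()]s.
#' @param torsions list of [torsion_plan()]s.
#' @param modes list of [breathing_plan()]s.
#' @param ligand_contacts list of [ligand_plan()]s.
#' @param seed master seed (default `spec$seed`).
#' @return `list(trajectory = pg_trajectory, manifest = list)`.
#' @export
generate_trajectory <- function(spec, n_frames,
                                schedules = list(), ions = list(),
                                contacts = list(), correlations = list(),
                                torsions = list(), modes = list(),
                                ligand_contacts = list(),
                                seed = spec$seed) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  sys <- build_base_system(spec, contacts)
  topo <- sys$topology
  n_atoms <- topo$n_atoms
  coords <- array(sys$base, dim = c(n_atoms, 3L, n_frames))
  manifest <- list(
    spec = list(residues_per_subunit = spec$residues_per_subunit,
                pore_radius = spec$pore_radius,
                z_int = spec$z_int, z_ext = spec$z_ext,
                n_ions = spec$n_ions, n_ligands = spec$n_ligands,
                seed = as.integer(seed)),
    n_frames = n_frames,
    planted_events = list(ext_to_int = 0L, int_to_ext = 0L),
    gate_distances = list(), contacts = list(), correlations = list(),
    torsions = list(), modes = list(), ligand_contacts = list()
  )

  ## gate schedules: place the 4 CZ beads at radius d/2, pointing inward
  for (sched in schedules) {
    gl <- spec$gate_layout[[sched$gate]]
    if (is.null(gl)) stop("schedule names unknown gate: ", sched$gate)
    d <- schedule_values(sched, n_frames)
    for (ch in c("A", "B", "C", "D")) {
      row <- bead_row(topo, ch, gl$resid, "CZ")
      if (!length(row)) stop("gate residue lacks its CZ bead for chain ", ch)
      theta <- subunit_angle(ch)
      coords[row, 1L, ] <- (d / 2) * cos(theta)
      coords[row, 2L, ] <- (d / 2) * sin(theta)
      coords[row, 3L, ] <- gl$z
    }
    manifest$gate_distances[[sched$gate]] <- d
  }

  ## scripted ions
  ion_atoms <- which(topo$atoms$is_ion)
  for (sc in ions) {
    if (sc$ion > length(ion_atoms))
      stop("ion script references ion ", sc$ion, " but spec has ",
           length(ion_atoms))
    row <- ion_atoms[sc$ion]
    t <- seq_len(n_frames) - 1L
    z <- stats::approx(sc$waypoints$frame, sc$waypoints$z, xout = t,
                       rule = 2L, ties = "ordered")$y
    set.seed(derive_seed(seed, paste0("ion", sc$ion)))
    xy <- matrix(stats::rnorm(2L * n_frames, sd = sc$lateral_noise_sd),
                 ncol = 2L)
    r <- sqrt(rowSums(xy^2))
    lim <- 0.8 * spec$pore_radius
    scl <- ifelse(r > lim, lim / r, 1)
    coords[row, 1L, ] <- xy[, 1L] * scl
    coords[row, 2L, ] <- xy[, 2L] * scl
    coords[row, 3L, ] <- z
    if (sc$outcome == "complete")
      manifest$planted_events$ext_to_int <- manifest$planted_events$ext_to_int + 1L
    if (sc$outcome == "retrograde")
      manifest$planted_events$int_to_ext <- manifest$planted_events$int_to_ext + 1L
  }

  ## contact plans: move partner bead between formed/broken distance
  plan_beads <- list(salt_bridge = c("NZ", "OE1"), hbond = c("OG", "OE1"),
                     hydrophobic = c("CD1", "CD1"))
  for (k in seq_along(contacts)) {
    cp <- contacts[[k]]
    beads <- plan_beads[[cp$contact_type]]
    row_a <- bead_row(topo, cp$res_a$chain, cp$res_a$resid, beads[1L])
    row_b <- bead_row(topo, cp$res_b$chain, cp$res_b$resid, beads[2L])
    if (!length(row_a) || !length(row_b))
      stop("contact plan beads missing; check plan residues")
    n_formed <- round(cp$planted_fraction * n_frames)
    set.seed(derive_seed(seed, paste0("contact", k)))
    formed <- sort(sample.int(n_frames, n_formed))
    dist <- rep(cp$broken_distance, n_frames)
    dist[formed] <- cp$formed_distance
    theta <- subunit_angle(cp$res_a$chain)
    u <- c(cos(theta), sin(theta), 0)
    a_pos <- sys$base[row_a, ]
    for (ax in 1:3) coords[row_b, ax, ] <- a_pos[ax] + u[ax] * dist
    if (cp$contact_type == "hbond") {
      row_h <- bead_row(topo, cp$res_a$chain, cp$res_a$resid, "HG")
      for (ax in 1:3) coords[row_h, ax, ] <- a_pos[ax] + u[ax] * 1.0
    }
    manifest$contacts[[k]] <- list(
      res_a = ref_label(cp$res_a), res_b = ref_label(cp$res_b),
      contact_type = cp$contact_type,
      planted_fraction = cp$planted_fraction,
      n_formed = n_formed, formed_frames = formed - 1L)
  }

  ## correlation plans: shared-signal displacement along the pair's
  ## in-plane separation axis (a stretching mode, which minimises
  ## coupling into the rigid-body fit of downstream analyses)
  for (k in seq_along(correlations)) {
    pl <- correlations[[k]]
    rows_a <- residue_rows(topo, pl$res_a$chain, pl$res_a$resid)
    rows_b <- residue_rows(topo, pl$res_b$chain, pl$res_b$resid)
    if (!length(rows_a) || !length(rows_b))
      stop("correlation plan references unknown residue")
    ca_a <- sys$base[bead_row(topo, pl$res_a$chain, pl$res_a$resid, "CA"), ]
    ca_b <- sys$base[bead_row(topo, pl$res_b$chain, pl$res_b$resid, "CA"), ]
    u <- ca_a - ca_b
    u[3L] <- 0
    u <- if (sqrt(sum(u^2)) < 1e-6) c(1, 0, 0) else unit(u)
    a <- sqrt(abs(pl$target_rho))
    sd_e <- sqrt(1 - abs(pl$target_rho))
    set.seed(derive_seed(seed, paste0("corr", k)))
    s <- stats::rnorm(n_frames)
    e1 <- stats::rnorm(n_frames, sd = sd_e)
    e2 <- stats::rnorm(n_frames, sd = sd_e)
    d_a <- pl$amplitude * (a * s + e1)
    d_b <- pl$amplitude * (sign(pl$target_rho) * a * s + e2)
    if (pl$target_rho == 0) d_b <- pl$amplitude * e2
    for (ax in which(abs(u) > 0)) {
      for (r in rows_a) coords[r, ax, ] <- coords[r, ax, ] + u[ax] * d_a
      for (r in rows_b) coords[r, ax, ] <- coords[r, ax, ] + u[ax] * d_b
    }
    manifest$correlations[[k]] <- list(
      res_a = ref_label(pl$res_a), res_b = ref_label(pl$res_b),
      target_rho = pl$target_rho,
      sample_rho = stats::cor(d_a, d_b))
  }

  ## torsion plans: NeRF re-placement of C(i) and N(i+1)
  for (k in seq_along(torsions)) {
    tp <- torsions[[k]]
    ch <- tp$res$chain; i <- tp$res$resid
    if (i <= 1L || i >= spec$residues_per_subunit)
      stop("torsion plan residue must be interior to its chain")
    other <- vapply(torsions[-k], function(x)
      x$res$chain == ch && abs(x$res$resid - i) <= 1L, TRUE)
    if (length(other) && any(other))
      stop("torsion-planned residues must not be adjacent")
    c_prev <- sys$base[bead_row(topo, ch, i - 1L, "C"), ]
    n_i <- sys$base[bead_row(topo, ch, i, "N"), ]
    ca_i <- sys$base[bead_row(topo, ch, i, "CA"), ]
    row_c <- bead_row(topo, ch, i, "C")
    row_n1 <- bead_row(topo, ch, i + 1L, "N")
    set.seed(derive_seed(seed, paste0("torsion", k)))
    phi_t <- tp$phi + (if (tp$jitter_sd > 0)
      stats::rnorm(n_frames, sd = tp$jitter_sd) else 0)
    psi_t <- tp$psi + (if (tp$jitter_sd > 0)
      stats::rnorm(n_frames, sd = tp$jitter_sd) else 0)
    phi_t <- rep_len(phi_t, n_frames)
    psi_t <- rep_len(psi_t, n_frames)
    c_pos <- nerf_place(c_prev, n_i, ca_i, 1.525, 111.2, phi_t)
    coords[row_c, , ] <- t(c_pos)
    for (f in seq_len(n_frames)) {
      coords[row_n1, , f] <- nerf_place(n_i, ca_i, c_pos[f, ],
                                        1.329, 116.2, psi_t[f])[1L, ]
    }
    manifest$torsions[[k]] <- list(res = ref_label(tp$res),
                                   phi = tp$phi, psi = tp$psi,
                                   jitter_sd = tp$jitter_sd)
  }

  ## breathing modes: C4-symmetric radial displacement of one ring
  for (k in seq_along(modes)) {
    md <- modes[[k]]
    set.seed(derive_seed(seed, paste0("mode", k)))
    s <- stats::rnorm(n_frames)
    dir_ca <- list()
    for (ch in c("A", "B", "C", "D")) {
      theta <- subunit_angle(ch)
      er <- c(cos(theta), sin(theta), 0)
      rows <- residue_rows(topo, ch, md$resid)
      if (!length(rows)) stop("breathing plan references unknown residue")
      for (r in rows) for (ax in 1:2)
        coords[r, ax, ] <- coords[r, ax, ] + er[ax] * md$amplitude * s
      dir_ca[[ch]] <- er
    }
    manifest$modes[[k]] <- list(resid = md$resid, amplitude = md$amplitude,
                                ca_directions = dir_ca)
  }

  ## ligand contact plans
  lig_atoms <- which(topo$atoms$is_ligand)
  for (k in seq_along(ligand_contacts)) {
    lp <- ligand_contacts[[k]]
    if (lp$ligand > length(lig_atoms))
      stop("ligand plan references ligand ", lp$ligand, " but spec has ",
           length(lig_atoms))
    row_l <- lig_atoms[lp$ligand]
    anchor_row <- bead_row(topo, lp$res$chain, lp$res$resid, "CB")
    if (!length(anchor_row))
      anchor_row <- residue_rows(topo, lp$res$chain, lp$res$resid)[1L]
    anchor <- sys$base[anchor_row, ]
    n_near <- round(lp$fraction * n_frames)
    set.seed(derive_seed(seed, paste0("ligand", k)))
    near <- sort(sample.int(n_frames, n_near))
    dist <- rep(lp$far, n_frames)
    dist[near] <- lp$near
    theta <- subunit_angle(lp$res$chain)
    u <- c(cos(theta), sin(theta), 0)
    for (ax in 1:3) coords[row_l, ax, ] <- anchor[ax] + u[ax] * dist
    manifest$ligand_contacts[[k]] <- list(
      ligand = lp$ligand, res = ref_label(lp$res),
      fraction = lp$fraction, n_near = n_near)
  }

  list(trajectory = new_trajectory(topo, coords),
       manifest = manifest)
}

default_contact_cutoff <- function(type) {
  switch(type, salt_bridge = 4.0, hbond = 3.5, hydrophobic = 4.5)
}
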