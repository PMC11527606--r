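# Shared fixtures and independent oracles. Everything is generated in
# code; no binary fixtures.

tiny_spec <- function(n_ions = 0L, n_ligands = 0L, seed = 1L, nres = 16L) {
  channel_spec(residues_per_subunit = nres, n_ions = n_ions,
               n_ligands = n_ligands, seed = seed)
}

boundary_sels <- function(topology) {
  list(sf = select_atoms(topology, "protein and resid 2:4", "residue"),
       hbc = select_atoms(topology, "protein and resid 7", "residue"),
       gloop = select_atoms(topology, "protein and resid 10", "residue"))
}

make_model <- function(traj, ...) {
  b <- boundary_sels(traj$topology)
  build_compartments(traj, b$sf, b$hbc, b$gloop, ...)
}

reverse_frames <- function(traj) {
  poregate:::new_trajectory(traj$topology,
                            traj$coords[, , traj$n_frames:1, drop = FALSE],
                            rev(traj$frame_times))
}

# Independent dihedral oracle: project the outer bonds onto the plane
# perpendicular to the central bond and measure the signed angle there.
ref_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  w <- (p4 - p3) - sum((p4 - p3) * b) * b
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  s <- -sign(sum(cr * b))
  if (s == 0) s <- 1
  out <- s * ang
  if (out <= -180) out <- out + 360
  out
}

# Independent brute-force oracle for directional permeation counting:
# split each ion's time line into segments separated by re-arming above
# the entry boundary, then require ordered first crossings of all four
# boundaries (with hysteresis and the radial gate) within a segment.
brute_force_events <- function(traj, ion_rows, model,
                               direction = "ext_to_int") {
  zr <- poregate:::ion_zr(traj, ion_rows, model)
  if (direction == "ext_to_int") {
    b <- rbind(model$z_ext_gate, model$z_sf_bottom, model$z_hbc, model$z_gloop)
    z <- zr$z
  } else {
    b <- rbind(-model$z_gloop, -model$z_hbc, -model$z_sf_bottom,
               -model$z_ext_gate)
    z <- -zr$z
  }
  h <- model$hysteresis
  rc <- model$radial_cutoff
  total <- 0L
  for (k in seq_along(ion_rows)) {
    zi <- z[k, ]; ri <- zr$r[k, ]
    armed_at <- if (zi[1] > b[1, 1] + h) 1L else NA_integer_
    # initial state inside the pore gives no credit
    t <- 1L
    nf <- length(zi)
    while (t <= nf) {
      if (zi[t] > b[1, t] + h) armed_at <- t
      if (!is.na(armed_at) && armed_at < t) {
        # check whether segment [armed_at, t] completes a pass at t
        seg <- armed_at:t
        cross <- rep(NA_integer_, 4L)
        stage <- 1L
        for (s in seg) {
          if (s > armed_at && zi[s] > b[1, s] + h) { stage <- 1L; cross[] <- NA }
          while (stage <= 4L && zi[s] < b[stage, s] - h && ri[s] <= rc) {
            cross[stage] <- s
            stage <- stage + 1L
          }
        }
        if (stage == 5L) {
          total <- total + 1L
          armed_at <- NA_integer_   # must re-arm before another event
        }
      }
      t <- t + 1L
    }
  }
  total
}

# Independent naive contact oracle: evaluate the published predicates
# over every residue pair with double loops over atoms.
brute_force_contacts <- function(xyz, topology, criteria) {
  a <- topology$atoms
  prot <- which(!a$is_ion & !a$is_ligand)
  keys <- unique(poregate:::residue_key(a[prot, ]))
  res_list <- lapply(keys, function(k)
    prot[poregate:::residue_key(a[prot, ]) == k])
  found <- character()
  n <- length(res_list)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ri <- res_list[[i]]; rj <- res_list[[j]]
    ai <- a[ri[1L], ]; aj <- a[rj[1L], ]
    if (ai$chain == aj$chain && abs(ai$resid - aj$resid) <= 1L) next
    formed <- FALSE
    for (dir in 1:2) {
      r1 <- if (dir == 1L) ri else rj
      r2 <- if (dir == 1L) rj else ri
      if (criteria$contact_type == "salt_bridge") {
        bas <- poregate:::BASIC_N_ATOMS[[toupper(a$resname[r1[1L]])]]
        aci <- poregate:::ACIDIC_O_ATOMS[[toupper(a$resname[r2[1L]])]]
        if (is.null(bas) || is.null(aci)) next
        for (p in r1[a$name[r1] %in% bas]) for (q in r2[a$name[r2] %in% aci])
          if (sqrt(sum((xyz[p, ] - xyz[q, ])^2)) <= criteria$distance_cutoff)
            formed <- TRUE
      } else if (criteria$contact_type == "hydrophobic") {
        hp <- poregate:::HYDROPHOBIC_RESIDUES
        pick <- function(rr) rr[toupper(a$resname[rr[1L]]) %in% hp &
                                  toupper(a$element[rr]) == "C" &
                                  !(a$name[rr] %in% c("N", "CA", "C", "O", "OXT", "CA"))]
        for (p in pick(r1)) for (q in pick(r2))
          if (sqrt(sum((xyz[p, ] - xyz[q, ])^2)) <= criteria$distance_cutoff)
            formed <- TRUE
      } else {
        dt <- poregate:::DONOR_ATOMS[[toupper(a$resname[r1[1L]])]]
        if (is.null(dt)) next
        for (heavy in names(dt)) {
          p <- r1[a$name[r1] == heavy]
          hs <- r1[startsWith(a$name[r1], dt[[heavy]]) &
                     toupper(a$element[r1]) == "H"]
          if (!length(p) || !length(hs)) next
          accs <- r2[a$name[r2] %in% poregate:::ACCEPTOR_ATOMS]
          for (q in accs) {
            if (sqrt(sum((xyz[p, ] - xyz[q, ])^2)) > criteria$distance_cutoff) next
            for (hh in hs) {
              v1 <- xyz[p, ] - xyz[hh, ]
              v2 <- xyz[q, ] - xyz[hh, ]
              ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                        sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
              if (ang >= criteria$angle_cutoff) formed <- TRUE
            }
          }
        }
      }
    }
    if (formed) {
      p <- poregate:::canonical_pair(a, ri[1L], rj[1L])
      found <- c(found, poregate:::pair_id(p))
    }
  }
  sort(unique(found))
}

# Minimal hand-built topology + single-frame trajectory for geometric
# edge cases.
hand_system <- function(atoms, xyz, n_frames = 1L) {
  atoms$index <- seq_len(nrow(atoms)) - 1L
  defaults <- list(element = NA, insert = "", is_ion = FALSE,
                   is_ligand = FALSE)
  for (f in names(defaults))
    if (is.null(atoms[[f]])) atoms[[f]] <- defaults[[f]]
  if (all(is.na(atoms$element)))
    atoms$element <- toupper(substr(atoms$name, 1, 1))
  topo <- poregate:::new_topology(
    atoms[, c("index", "name", "element", "resid", "resname", "chain",
              "insert", "is_ion", "is_ligand")])
  coords <- array(rep(as.matrix(xyz), n_frames),
                  dim = c(nrow(xyz), 3L, n_frames))
  poregate:::new_trajectory(topo, coords)
}
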