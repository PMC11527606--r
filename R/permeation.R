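#' @section Permeation:
#' A completed permeation event is one ion's passage through the
#' selectivity filter, the HBC gate and the G-loop gate, judged by
#' z-boundary crossings (not instantaneous gate aperture) while the ion
#' stays within a radial cutoff of the pore axis. Crossings must clear
#' each boundary by a hysteresis margin so thermal jitter at a boundary
#' cannot double-count; returning above the extracellular entrance
#' resets the per-ion state machine.
#' @name poregate-permeation
NULL

#' Build the pore compartment model
#'
#' Per-frame region boundaries are centroid z values of the anchor
#' selections: the SF selection's top and bottom residues give the
#' extracellular entrance and the SF/cavity boundary (a single-residue
#' SF is padded by +/- 2 A), and the HBC and G-loop selections give the
#' lower boundaries. The pore axis is the per-frame centroid of the
#' channel's CA atoms.
#'
#' @param traj a `pg_trajectory`.
#' @param sf_sel,hbc_sel,gloop_sel `pg_selection`s anchoring the
#'   boundaries (protein atoms).
#' @param radial_cutoff max distance from the pore axis for an ion to
#'   count as in-pore (A).
#' @param hysteresis boundary crossing margin (A).
#' @param channel_sel optional selection defining the pore axis
#'   (default: all protein CA atoms).
#' @return a `pg_compartments`.
#' @export
build_compartments <- function(traj, sf_sel, hbc_sel, gloop_sel,
                               radial_cutoff = 10, hysteresis = 2,
                               channel_sel = NULL) {
  if (radial_cutoff <= 0) stop("radial_cutoff must be positive")
  topo <- traj$topology
  for (s in list(sf_sel, hbc_sel, gloop_sel))
    if (!length(as_sel_rows(s))) stop("empty boundary selection")
  axis_rows <- if (is.null(channel_sel)) {
    which(topo$atoms$name == "CA" & !topo$atoms$is_ion & !topo$atoms$is_ligand)
  } else as_sel_rows(channel_sel)
  if (!length(axis_rows)) stop("empty channel axis selection")

  sf_rows <- as_sel_rows(sf_sel)
  sf_keys <- residue_key(topo$atoms[sf_rows, ])
  uk <- unique(sf_keys)
  nf <- traj$n_frames
  mean_axis <- function(rows, ax) {
    m <- traj$coords[rows, ax, , drop = FALSE]
    dim(m) <- c(length(rows), nf)
    colMeans(m)
  }
  mean_z <- function(rows) mean_axis(rows, 3L)
  if (length(uk) >= 2L) {
    z0 <- vapply(uk, function(k) mean(traj$coords[sf_rows[sf_keys == k], 3L, 1L]), 0)
    top_rows <- sf_rows[sf_keys == uk[which.max(z0)]]
    bot_rows <- sf_rows[sf_keys == uk[which.min(z0)]]
    z_ext_gate <- mean_z(top_rows)
    z_sf_bottom <- mean_z(bot_rows)
  } else {
    zc <- mean_z(sf_rows)
    z_ext_gate <- zc + 2
    z_sf_bottom <- zc - 2
  }
  z_hbc <- mean_z(as_sel_rows(hbc_sel))
  z_gloop <- mean_z(as_sel_rows(gloop_sel))
  bad <- which(!(z_ext_gate > z_sf_bottom & z_sf_bottom > z_hbc &
                   z_hbc > z_gloop))
  if (length(bad))
    stop(sprintf(paste0("boundary z-ordering violated at frame %d ",
                        "(check selections / alignment)"), bad[1L] - 1L))
  axis_xy <- cbind(mean_axis(axis_rows, 1L), mean_axis(axis_rows, 2L))
  structure(list(z_ext_gate = z_ext_gate, z_sf_bottom = z_sf_bottom,
                 z_hbc = z_hbc, z_gloop = z_gloop, axis_xy = axis_xy,
                 radial_cutoff = radial_cutoff, hysteresis = hysteresis,
                 n_frames = nf),
            class = "pg_compartments")
}

# Ion z and radial-distance series: list(z = n_ions x nf, r = n_ions x nf).
ion_zr <- function(traj, ion_rows, model) {
  z <- traj$coords[ion_rows, 3L, , drop = FALSE]
  dim(z) <- c(length(ion_rows), traj$n_frames)
  x <- traj$coords[ion_rows, 1L, , drop = FALSE]
  dim(x) <- c(length(ion_rows), traj$n_frames)
  y <- traj$coords[ion_rows, 2L, , drop = FALSE]
  dim(y) <- c(length(ion_rows), traj$n_frames)
  r <- sqrt(sweep(x, 2L, model$axis_xy[, 1L])^2 +
              sweep(y, 2L, model$axis_xy[, 2L])^2)
  list(z = z, r = r)
}

#' Detect completed directional permeation events
#'
#' Per-ion finite-state machine over
#' OUTSIDE -> IN_SF -> IN_CAVITY -> PAST_GLOOP; a transition fires when
#' the ion's z clears the next boundary by more than the hysteresis
#' while its radial distance from the pore axis is within the radial
#' cutoff. Within one frame the machine may cascade through several
#' boundaries (fast crossings). Returning above the entrance boundary
#' plus hysteresis resets the machine; an ion can record several events.
#' Ions starting inside the pore take the state matching their position
#' but earn no event credit until an entrance crossing is observed.
#'
#' @param traj a `pg_trajectory`.
#' @param ions a `pg_selection` of ion atoms.
#' @param model a [build_compartments()] result.
#' @param direction `"ext_to_int"` (with the applied-field direction) or
#'   `"int_to_ext"`.
#' @param window optional [frame_window()].
#' @return data frame with one row per event: `ion` (0-based atom
#'   index), `frame_enter_sf`, `frame_cross_hbc`, `frame_exit_gloop`,
#'   `direction`.
#' @export
detect_permeation_events <- function(traj, ions, model,
                                     direction = c("ext_to_int", "int_to_ext"),
                                     window = NULL) {
  direction <- match.arg(direction)
  ion_rows <- as_sel_rows(ions)
  empty <- data.frame(ion = integer(), frame_enter_sf = integer(),
                      frame_cross_hbc = integer(),
                      frame_exit_gloop = integer(),
                      direction = character(), stringsAsFactors = FALSE)
  if (!length(ion_rows)) return(empty)
  frames <- window_frames(traj, window)
  zr <- ion_zr(traj, ion_rows, model)
  # boundary matrix in travel order: entry, sf/cavity, hbc, exit
  if (direction == "ext_to_int") {
    b <- rbind(model$z_ext_gate, model$z_sf_bottom, model$z_hbc, model$z_gloop)
    z <- zr$z
  } else {
    b <- rbind(-model$z_gloop, -model$z_hbc, -model$z_sf_bottom, -model$z_ext_gate)
    z <- -zr$z
  }
  h <- model$hysteresis
  rc <- model$radial_cutoff
  events <- list()
  for (k in seq_along(ion_rows)) {
    zi <- z[k, ]; ri <- zr$r[k, ]
    f0 <- frames[1L] + 1L
    stage <- sum(zi[f0] < b[, f0])  # 0..4: position-derived initial state
    if (stage > 3L) stage <- 5L     # already below the exit: inert until reset
    t_enter <- NA_integer_; t_hbc <- NA_integer_
    for (t in frames) {
      j <- t + 1L
      if (zi[j] > b[1L, j] + h) {
        stage <- 0L
        t_enter <- NA_integer_; t_hbc <- NA_integer_
        next
      }
      repeat {
        if (stage == 0L && zi[j] < b[1L, j] - h && ri[j] <= rc) {
          stage <- 1L; t_enter <- t
        } else if (stage == 1L && zi[j] < b[2L, j] - h && ri[j] <= rc) {
          stage <- 2L
        } else if (stage == 2L && zi[j] < b[3L, j] - h && ri[j] <= rc) {
          stage <- 3L; t_hbc <- t
        } else if (stage == 3L && zi[j] < b[4L, j] - h && ri[j] <= rc) {
          stage <- 5L
          if (!is.na(t_enter)) {
            events[[length(events) + 1L]] <- data.frame(
              ion = ion_rows[k] - 1L, frame_enter_sf = t_enter,
              frame_cross_hbc = t_hbc, frame_exit_gloop = t,
              direction = direction, stringsAsFactors = FALSE)
          }
          t_enter <- NA_integer_; t_hbc <- NA_integer_
        } else break
      }
    }
  }
  if (!length(events)) return(empty)
  do.call(rbind, events)
}

region_bounds <- function(model, region) {
  switch(region,
    sf = list(lo = model$z_sf_bottom, hi = model$z_ext_gate, hi_incl = TRUE),
    cavity = list(lo = model$z_hbc, hi = model$z_sf_bottom, hi_incl = FALSE),
    gloop = list(lo = model$z_gloop, hi = model$z_hbc, hi_incl = FALSE),
    stop("unknown region: ", region))
}

#' Ion-count occupancy distribution of a pore region
#'
#' Per frame, ions whose z lies inside the region slab and whose radial
#' distance is within the cutoff are counted; the result maps each
#' observed count k to its percentage of window frames (summing to 100).
#'
#' @param traj a `pg_trajectory`.
#' @param ions ion selection.
#' @param model a `pg_compartments`.
#' @param region `"sf"`, `"cavity"` or `"gloop"`.
#' @param window optional [frame_window()].
#' @return a `pg_occupancy`: data frame `k`, `percent` plus attributes.
#' @export
occupancy_distribution <- function(traj, ions, model,
                                   region = c("sf", "cavity", "gloop"),
                                   window = NULL) {
  region <- match.arg(region)
  frames <- window_frames(traj, window)
  if (!length(frames)) stop("empty window")
  ion_rows <- as_sel_rows(ions)
  zr <- ion_zr(traj, ion_rows, model)
  rb <- region_bounds(model, region)
  j <- frames + 1L
  lo <- matrix(rb$lo[j], nrow = length(ion_rows), ncol = length(j), byrow = TRUE)
  hi <- matrix(rb$hi[j], nrow = length(ion_rows), ncol = length(j), byrow = TRUE)
  zin <- if (rb$hi_incl) zr$z[, j, drop = FALSE] >= lo & zr$z[, j, drop = FALSE] <= hi
         else zr$z[, j, drop = FALSE] >= lo & zr$z[, j, drop = FALSE] < hi
  inside <- zin & zr$r[, j, drop = FALSE] <= model$radial_cutoff
  counts <- colSums(inside)
  tab <- table(factor(counts, levels = 0:max(counts)))
  out <- data.frame(k = as.integer(names(tab)),
                    percent = 100 * as.numeric(tab) / length(frames))
  structure(out, region = region, n_frames = length(frames),
            class = c("pg_occupancy", "data.frame"))
}

#' Ion dwell-time profile per region and per residue
#'
#' Every in-channel ion-frame (z between the G-loop and the entrance,
#' radius within cutoff) is attributed to the pore region containing it
#' and to the residue whose nearest heavy atom is closest, provided that
#' distance is within `assign_cutoff` (ties break to the lower
#' (chain, resid); beyond the cutoff the frame is "unassigned").
#' Percentages are over all in-channel ion-frames.
#'
#' @param traj a `pg_trajectory`.
#' @param ions ion selection.
#' @param model a `pg_compartments`.
#' @param residues residue-granular selection of candidate residues.
#' @param scope `"all_channel_ions"` or `"permeating_ions_only"` (ions
#'   with at least one detected event, between entry and exit frames).
#' @param assign_cutoff max ion-to-residue heavy-atom distance (A).
#' @param window optional [frame_window()].
#' @param direction event direction used for `"permeating_ions_only"`.
#' @return a `pg_dwell` list: `region_percent`, `residue_percent` (data
#'   frame), `n_ion_frames`.
#' @export
dwell_profile <- function(traj, ions, model, residues,
                          scope = c("all_channel_ions", "permeating_ions_only"),
                          assign_cutoff = 6.0, window = NULL,
                          direction = "ext_to_int") {
  scope <- match.arg(scope)
  if (assign_cutoff <= 0) stop("assign_cutoff must be positive")
  frames <- window_frames(traj, window)
  ion_rows <- as_sel_rows(ions)
  res_rows <- as_sel_rows(residues)
  if (!length(res_rows)) stop("empty residue selection")
  topo <- traj$topology
  ra <- topo$atoms[res_rows, ]
  heavy <- toupper(ra$element) != "H"
  res_rows <- res_rows[heavy]; ra <- ra[heavy, ]
  keys <- residue_key(ra)
  ord <- order(ra$chain, ra$resid)   # tie-break order
  key_levels <- unique(keys[ord])
  labels <- vapply(key_levels, function(k) {
    i <- which(keys == k)[1L]
    residue_label(ra$chain[i], ra$resid[i], ra$resname[i])
  }, "")

  zr <- ion_zr(traj, ion_rows, model)
  allowed <- matrix(TRUE, nrow = length(ion_rows), ncol = traj$n_frames)
  if (scope == "permeating_ions_only") {
    ev <- detect_permeation_events(traj, ions, model, direction, window)
    allowed[] <- FALSE
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        k <- match(ev$ion[i] + 1L, ion_rows)
        allowed[k, (ev$frame_enter_sf[i]:ev$frame_exit_gloop[i]) + 1L] <- TRUE
      }
    }
  }

  region_ct <- c(sf = 0, cavity = 0, gloop = 0)
  res_ct <- stats::setNames(numeric(length(key_levels)), key_levels)
  unassigned <- 0
  total <- 0
  for (t in frames) {
    j <- t + 1L
    zin <- zr$z[, j] >= model$z_gloop[j] & zr$z[, j] <= model$z_ext_gate[j]
    ok <- zin & zr$r[, j] <= model$radial_cutoff & allowed[, j]
    if (!any(ok)) next
    xyz <- frame_coords(traj, t)
    res_xyz <- xyz[res_rows, , drop = FALSE]
    for (k in which(ok)) {
      total <- total + 1
      zi <- zr$z[k, j]
      reg <- if (zi >= model$z_sf_bottom[j]) "sf"
             else if (zi >= model$z_hbc[j]) "cavity" else "gloop"
      region_ct[reg] <- region_ct[reg] + 1
      p <- xyz[ion_rows[k], ]
      d2 <- (res_xyz[, 1L] - p[1L])^2 + (res_xyz[, 2L] - p[2L])^2 +
        (res_xyz[, 3L] - p[3L])^2
      dmin <- tapply(d2, factor(keys, levels = key_levels), min)
      best <- which.min(dmin)   # first minimum in (chain, resid) order
      if (sqrt(dmin[best]) <= assign_cutoff) {
        res_ct[key_levels[best]] <- res_ct[key_levels[best]] + 1
      } else unassigned <- unassigned + 1
    }
  }
  denom <- max(total, 1)
  structure(list(
    scope = scope,
    n_ion_frames = total,
    region_percent = c(100 * region_ct / denom,
                       unassigned = 0),
    residue_percent = data.frame(residue = labels,
                                 percent = 100 * as.numeric(res_ct) / denom,
                                 stringsAsFactors = FALSE),
    unassigned_percent = 100 * unassigned / denom
  ), class = "pg_dwell")
}

#' Write permeation events as TSV
#' @param events event data frame from [detect_permeation_events()].
#' @param path output path.
#' @export
write_events <- function(events, path) write_tsv(events, path)

#' Write an occupancy distribution as TSV
#' @param occ a `pg_occupancy`.
#' @param path output path.
#' @export
write_occupancy <- function(occ, path) {
  write_tsv(data.frame(region = attr(occ, "region"), k = occ$k,
                       percent = occ$percent), path)
}

#' Write a dwell profile as TSV
#' @param dwell a `pg_dwell`.
#' @param path output path.
#' @export
write_dwell <- function(dwell, path) {
  reg <- data.frame(residue = paste0("region:", names(dwell$region_percent)),
                    percent = as.numeric(dwell$region_percent),
                    stringsAsFactors = FALSE)
  write_tsv(rbind(reg, dwell$residue_percent), path)
}
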