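#' @section Gate geometry:
#' A gate's aperture at a frame is summarised from the inter-subunit
#' distances of one residue per subunit (e.g. the phenylalanine of the
#' helix-bundle-crossing gate). The default statistic is the mean over
#' the two trans-pore diagonal subunit pairs (A-C and B-D) of the
#' minimum inter-atomic distance between the gate residues' atoms; the
#' pairing rule is configurable because published "average minimum
#' distance" traces rarely state it.
#' @name poregate-gating
NULL

#' Define a gate
#'
#' @param name gate label (e.g. `"HBC"`, `"Gloop"`).
#' @param resid gate residue number, present in all four subunits.
#' @param chains the four subunit chain ids, in diagonal-pair order:
#'   chains 1/3 and 2/4 form the two diagonals.
#' @param atom_scope atoms entering the distance: `"sidechain_heavy"`
#'   (default; backbone N/CA/C/O and hydrogens excluded, falling back to
#'   CA when a residue has no side-chain heavy atoms), `"all_heavy"`, or
#'   `"CA"`.
#' @param pairing `"diagonal"` (mean of the two diagonal minima),
#'   `"adjacent"` (mean of the four adjacent-pair minima) or
#'   `"global_min"` (minimum over all inter-subunit pairs).
#' @return a `pg_gate_definition`.
#' @export
gate_definition <- function(name, resid, chains = c("A", "B", "C", "D"),
                            atom_scope = c("sidechain_heavy", "all_heavy", "CA"),
                            pairing = c("diagonal", "adjacent", "global_min")) {
  atom_scope <- match.arg(atom_scope)
  pairing <- match.arg(pairing)
  if (length(chains) != 4L) stop("a gate needs exactly 4 subunits")
  structure(list(name = name, resid = as.integer(resid), chains = chains,
                 atom_scope = atom_scope, pairing = pairing),
            class = "pg_gate_definition")
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

gate_scope_rows <- function(topology, chain, resid, atom_scope) {
  a <- topology$atoms
  rows <- which(a$chain == chain & a$resid == resid & !a$is_ion & !a$is_ligand)
  if (!length(rows)) return(rows)
  if (atom_scope == "CA") {
    rows <- rows[a$name[rows] == "CA"]
  } else {
    rows <- rows[toupper(a$element[rows]) != "H"]
    if (atom_scope == "sidechain_heavy") {
      sc <- rows[!(a$name[rows] %in% BACKBONE_NAMES)]
      rows <- if (length(sc)) sc else rows[a$name[rows] == "CA"]
    }
  }
  rows
}

min_set_distance <- function(xyz, rows_a, rows_b) {
  dx <- outer(xyz[rows_a, 1L], xyz[rows_b, 1L], "-")
  dy <- outer(xyz[rows_a, 2L], xyz[rows_b, 2L], "-")
  dz <- outer(xyz[rows_a, 3L], xyz[rows_b, 3L], "-")
  sqrt(min(dx^2 + dy^2 + dz^2))
}

#' Per-frame gate aperture trace
#'
#' @param traj a `pg_trajectory`.
#' @param gate a [gate_definition()].
#' @param window a [frame_window()] (default: all frames).
#' @return a `pg_gate_trace` with fields `gate`, `frames` (0-based),
#'   `times_ns` and `distance` (Angstrom).
#' @export
gate_distance_trace <- function(traj, gate, window = NULL) {
  frames <- window_frames(traj, window)
  topo <- traj$topology
  rows <- lapply(gate$chains, function(ch) {
    r <- gate_scope_rows(topo, ch, gate$resid, gate$atom_scope)
    if (!length(r))
      stop(sprintf("gate '%s': no atoms for residue %d in subunit %s",
                   gate$name, gate$resid, ch))
    r
  })
  pair_idx <- switch(gate$pairing,
    diagonal = list(c(1L, 3L), c(2L, 4L)),
    adjacent = list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
    global_min = utils::combn(4L, 2L, simplify = FALSE))
  dist <- vapply(frames, function(f) {
    xyz <- frame_coords(traj, f)
    mins <- vapply(pair_idx, function(p)
      min_set_distance(xyz, rows[[p[1L]]], rows[[p[2L]]]), 0)
    if (gate$pairing == "global_min") min(mins) else mean(mins)
  }, 0)
  structure(list(gate = gate, frames = frames,
                 times_ns = traj$frame_times[frames + 1L],
                 distance = dist),
            class = "pg_gate_trace")
}

#' Open fraction and distance distribution of a gate trace
#'
#' A frame is open iff its gate distance strictly exceeds the cutoff
#' (ties count as closed). The default 5.69 Angstrom cutoff is the
#' conventional open/closed aperture threshold for inwardly rectifying
#' potassium channel gates.
#'
#' @param trace a `pg_gate_trace`.
#' @param cutoff open/closed aperture cutoff in Angstrom.
#' @param bin_width histogram bin width in Angstrom.
#' @return a `pg_gate_stats` with `open_fraction`, `cutoff`, `histogram`
#'   (`breaks`, `counts`), and `mean`/`min`/`max` distance.
#' @export
open_fraction <- function(trace, cutoff = 5.69, bin_width = 0.25) {
  d <- trace$distance
  if (!length(d)) stop("empty gate trace")
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.integer(table(cut(d, breaks, include.lowest = TRUE)))
  structure(list(gate_name = trace$gate$name,
                 open_fraction = mean(d > cutoff),
                 cutoff = cutoff,
                 histogram = list(breaks = breaks, counts = counts),
                 mean = mean(d), min = min(d), max = max(d),
                 n_frames = length(d)),
            class = "pg_gate_stats")
}

#' Write a gate trace as TSV
#'
#' Columns: frame, time_ns, gate_name, distance_A, is_open.
#'
#' @param trace a `pg_gate_trace`.
#' @param path output path.
#' @param cutoff aperture cutoff defining `is_open`.
#' @export
write_gate_trace <- function(trace, path, cutoff = 5.69) {
  write_tsv(data.frame(frame = trace$frames,
                       time_ns = trace$times_ns,
                       gate_name = trace$gate$name,
                       distance_A = trace$distance,
                       is_open = trace$distance > cutoff), path)
}

#' Write gate statistics as a JSON summary
#' @param stats a `pg_gate_stats`.
#' @param path output path.
#' @export
write_gate_stats <- function(stats, path) {
  write_json_summary(list(gate = stats$gate_name,
                          open_fraction = stats$open_fraction,
                          cutoff = stats$cutoff,
                          mean_distance = stats$mean,
                          min_distance = stats$min,
                          max_distance = stats$max,
                          histogram = stats$histogram), path)
}
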