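#' @section Backbone torsions:
#' phi(i) is the C(i-1)-N(i)-CA(i)-C(i) dihedral and psi(i) the
#' N(i)-CA(i)-C(i)-N(i+1) dihedral, both signed and in (-180, 180].
#' Chain termini lack one of the two and are omitted for that angle;
#' residues missing a backbone atom are skipped with a warning.
#' Averages are circular means and spreads circular SDs.
#' @name poregate-torsions
NULL

backbone_atom_rows <- function(topology) {
  a <- topology$atoms
  prot <- !a$is_ion & !a$is_ligand
  key <- residue_key(a)
  res <- unique(key[prot])
  find <- function(k, nm) {
    r <- which(prot & key == k & a$name == nm)
    if (length(r)) r[1L] else NA_integer_
  }
  info <- data.frame(key = res, stringsAsFactors = FALSE)
  info$chain <- a$chain[match(res, key)]
  info$resid <- a$resid[match(res, key)]
  info$resname <- a$resname[match(res, key)]
  info$N <- vapply(res, find, 0L, nm = "N")
  info$CA <- vapply(res, find, 0L, nm = "CA")
  info$C <- vapply(res, find, 0L, nm = "C")
  info[order(info$chain, info$resid), ]
}

#' Circular phi/psi summary over a window
#'
#' @param traj a `pg_trajectory`.
#' @param window optional [frame_window()].
#' @param residues optional residue-granular `pg_selection` restricting
#'   the summary.
#' @param keep_series keep the per-frame angle series (for dial plots,
#'   whose centre is the first frame of the window).
#' @return a `pg_torsion_summary`: data frame `chain`, `resid`,
#'   `resname`, `phi_mean`, `psi_mean`, `phi_sd`, `psi_sd` (circular,
#'   degrees; NA where undefined), plus a `series` list when requested.
#' @export
torsion_summary <- function(traj, window = NULL, residues = NULL,
                            keep_series = FALSE) {
  frames <- window_frames(traj, window)
  topo <- traj$topology
  info <- backbone_atom_rows(topo)
  if (!is.null(residues)) {
    keys <- unique(residue_key(topo$atoms[as_sel_rows(residues), ]))
    info <- info[info$key %in% keys, , drop = FALSE]
  }
  all_info <- backbone_atom_rows(topo)
  jf <- frames + 1L
  at <- function(row) {
    m <- traj$coords[row, , jf, drop = FALSE]
    dim(m) <- c(3L, length(jf))
    t(m)
  }
  rows_out <- list()
  series <- list()
  skipped <- 0L
  for (i in seq_len(nrow(info))) {
    ri <- info[i, ]
    if (is.na(ri$N) || is.na(ri$CA) || is.na(ri$C)) {
      skipped <- skipped + 1L
      next
    }
    prev <- all_info[all_info$chain == ri$chain &
                       all_info$resid == ri$resid - 1L, ]
    nxt <- all_info[all_info$chain == ri$chain &
                      all_info$resid == ri$resid + 1L, ]
    phi <- NULL; psi <- NULL
    if (nrow(prev) == 1L && !is.na(prev$C))
      phi <- dihedral_series(at(prev$C), at(ri$N), at(ri$CA), at(ri$C))
    if (nrow(nxt) == 1L && !is.na(nxt$N))
      psi <- dihedral_series(at(ri$N), at(ri$CA), at(ri$C), at(nxt$N))
    if (is.null(phi) && is.null(psi)) next
    rows_out[[length(rows_out) + 1L]] <- data.frame(
      chain = ri$chain, resid = ri$resid, resname = ri$resname,
      phi_mean = if (is.null(phi)) NA_real_ else circular_mean(phi),
      psi_mean = if (is.null(psi)) NA_real_ else circular_mean(psi),
      phi_sd = if (is.null(phi)) NA_real_ else circular_sd(phi),
      psi_sd = if (is.null(psi)) NA_real_ else circular_sd(psi),
      stringsAsFactors = FALSE)
    if (keep_series)
      series[[paste0(ri$chain, ":", ri$resid)]] <-
        list(phi = phi, psi = psi, frames = frames)
  }
  if (skipped > 0L)
    warning(skipped, " residue(s) missing backbone atoms were skipped")
  tab <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(chain = character(), resid = integer(), resname = character(),
               phi_mean = numeric(), psi_mean = numeric(),
               phi_sd = numeric(), psi_sd = numeric())
  structure(list(table = tab, series = if (keep_series) series else NULL,
                 n_frames = length(frames)),
            class = "pg_torsion_summary")
}

#' Write a torsion summary as TSV
#' @param summary a `pg_torsion_summary`.
#' @param path output path.
#' @export
write_torsions <- function(summary, path) write_tsv(summary$table, path)
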