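#' @section Interaction networks:
#' Contacts are detected per frame from geometric criteria and
#' aggregated into per-residue-pair formed fractions over an analysis
#' window; two systems' tables are then differenced (holo minus apo) to
#' rank the interactions gained or lost on ligand binding. Pair keys
#' carry chain ids, so inter-subunit pairs are first-class. Criteria
#' values are conventional defaults (salt bridge N-O <= 4.0 A; hydrogen
#' bond heavy-atom distance <= 3.5 A with donor-H...acceptor angle >=
#' 135 degrees; hydrophobic side-chain C-C <= 4.5 A), all configurable.
#' @name poregate-contacts
NULL

BASIC_N_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                      HIP = c("ND1", "NE2"), HSP = c("ND1", "NE2"))
ACIDIC_O_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
# donor heavy atom -> its hydrogen name prefixes (any H whose name starts
# with the prefix counts)
DONOR_ATOMS <- list(
  SER = list(OG = "HG"), THR = list(OG1 = "HG1"), TYR = list(OH = "HH"),
  ASN = list(ND2 = "HD2"), GLN = list(NE2 = "HE2"), TRP = list(NE1 = "HE1"),
  LYS = list(NZ = "HZ"), ARG = list(NE = "HE", NH1 = "HH1", NH2 = "HH2"),
  HIS = list(ND1 = "HD1", NE2 = "HE2"), HIP = list(ND1 = "HD1", NE2 = "HE2"),
  CYS = list(SG = "HG")
)
ACCEPTOR_ATOMS <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                    "ND1", "NE2", "SD", "OXT")
# residues whose side-chain carbons count as hydrophobic
HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "TRP",
                          "PRO", "CYS", "TYR")

#' Contact detection criteria
#'
#' @param contact_type `"salt_bridge"`, `"hbond"` or `"hydrophobic"`.
#' @param distance_cutoff formed-distance cutoff (A); defaults 4.0 /
#'   3.5 / 4.5 by type.
#' @param angle_cutoff donor-H...acceptor angle cutoff in degrees
#'   (hbond only).
#' @return a `pg_contact_criteria`.
#' @export
contact_criteria <- function(contact_type = c("salt_bridge", "hbond", "hydrophobic"),
                             distance_cutoff = NULL, angle_cutoff = 135) {
  contact_type <- match.arg(contact_type)
  if (is.null(distance_cutoff))
    distance_cutoff <- default_contact_cutoff(contact_type)
  if (distance_cutoff <= 0) stop("distance_cutoff must be positive")
  if (contact_type == "hbond" && (angle_cutoff <= 0 || angle_cutoff > 180))
    stop("angle_cutoff must be in (0, 180]")
  structure(list(contact_type = contact_type,
                 distance_cutoff = distance_cutoff,
                 angle_cutoff = if (contact_type == "hbond") angle_cutoff else NULL),
            class = "pg_contact_criteria")
}

# Resolve per-topology atom roles once; reused across frames.
resolve_contact_roles <- function(topology, criteria) {
  a <- topology$atoms
  prot <- !a$is_ion & !a$is_ligand
  rn <- toupper(a$resname)
  nm <- toupper(a$name)
  key <- residue_key(a)
  pick_by_table <- function(tab) {
    rows <- integer()
    for (res in names(tab))
      rows <- c(rows, which(prot & rn == res & nm %in% toupper(tab[[res]])))
    sort(rows)
  }
  if (criteria$contact_type == "salt_bridge") {
    list(a_rows = pick_by_table(BASIC_N_ATOMS),
         b_rows = pick_by_table(ACIDIC_O_ATOMS), key = key)
  } else if (criteria$contact_type == "hydrophobic") {
    side_c <- prot & rn %in% HYDROPHOBIC_RESIDUES &
      toupper(a$element) == "C" & !(nm %in% BACKBONE_NAMES) & nm != "CA"
    rows <- which(side_c)
    list(a_rows = rows, b_rows = rows, key = key)
  } else {
    donors <- list()
    for (res in names(DONOR_ATOMS)) {
      for (heavy in names(DONOR_ATOMS[[res]])) {
        hpre <- DONOR_ATOMS[[res]][[heavy]]
        drows <- which(prot & rn == res & nm == heavy)
        for (dr in drows) {
          hs <- which(prot & key == key[dr] & startsWith(nm, toupper(hpre)) &
                        toupper(a$element) == "H")
          if (length(hs))
            donors[[length(donors) + 1L]] <- list(d = dr, h = hs)
        }
      }
    }
    list(donors = donors,
         b_rows = which(prot & nm %in% ACCEPTOR_ATOMS), key = key)
  }
}

pair_allowed <- function(atoms, i, j) {
  same_res <- atoms$chain[i] == atoms$chain[j] & atoms$resid[i] == atoms$resid[j]
  adjacent <- atoms$chain[i] == atoms$chain[j] &
    abs(atoms$resid[i] - atoms$resid[j]) <= 1L
  !(same_res | adjacent)
}

canonical_pair <- function(atoms, i, j) {
  swap <- (atoms$chain[j] < atoms$chain[i]) |
    (atoms$chain[j] == atoms$chain[i] & atoms$resid[j] < atoms$resid[i])
  ii <- ifelse(swap, j, i)
  jj <- ifelse(swap, i, j)
  data.frame(chain_a = atoms$chain[ii], resid_a = atoms$resid[ii],
             resname_a = atoms$resname[ii],
             chain_b = atoms$chain[jj], resid_b = atoms$resid[jj],
             resname_b = atoms$resname[jj], stringsAsFactors = FALSE)
}

pair_id <- function(p) {
  paste(p$chain_a, p$resid_a, p$chain_b, p$resid_b, sep = "|")
}

#' Detect contacts in one frame
#'
#' Salt bridge: minimum basic-N to acidic-O distance within cutoff.
#' Hydrogen bond: donor-heavy to acceptor distance within cutoff and
#' donor-H...acceptor angle at the hydrogen at or above the angle
#' cutoff (any hydrogen of the donor may satisfy it). Hydrophobic:
#' minimum side-chain carbon-carbon distance within cutoff.
#' Intra-residue and backbone-adjacent pairs are excluded.
#'
#' @param xyz n_atoms x 3 coordinate matrix of one frame.
#' @param topology the matching `pg_topology`.
#' @param criteria a [contact_criteria()].
#' @param roles optional pre-resolved roles (internal speed-up).
#' @return data frame of canonical residue pairs formed in the frame.
#' @export
detect_contacts_frame <- function(xyz, topology, criteria, roles = NULL) {
  if (is.null(roles)) roles <- resolve_contact_roles(topology, criteria)
  atoms <- topology$atoms
  cut2 <- criteria$distance_cutoff^2
  empty <- canonical_pair(atoms, integer(), integer())

  collect <- function(ai, bi) {
    if (!length(ai)) return(empty)
    keep <- pair_allowed(atoms, ai, bi)
    ai <- ai[keep]; bi <- bi[keep]
    if (!length(ai)) return(empty)
    p <- canonical_pair(atoms, ai, bi)
    p[!duplicated(pair_id(p)), , drop = FALSE]
  }

  if (criteria$contact_type %in% c("salt_bridge", "hydrophobic")) {
    ar <- roles$a_rows; br <- roles$b_rows
    if (!length(ar) || !length(br)) return(empty)
    d2 <- outer(xyz[ar, 1L], xyz[br, 1L], "-")^2 +
      outer(xyz[ar, 2L], xyz[br, 2L], "-")^2 +
      outer(xyz[ar, 3L], xyz[br, 3L], "-")^2
    hit <- which(d2 <= cut2, arr.ind = TRUE)
    collect(ar[hit[, 1L]], br[hit[, 2L]])
  } else {
    br <- roles$b_rows
    if (!length(roles$donors) || !length(br)) return(empty)
    ai <- integer(); bi <- integer()
    amin <- cos(deg2rad(criteria$angle_cutoff))
    for (dn in roles$donors) {
      d <- xyz[dn$d, ]
      d2 <- (xyz[br, 1L] - d[1L])^2 + (xyz[br, 2L] - d[2L])^2 +
        (xyz[br, 3L] - d[3L])^2
      cand <- br[d2 <= cut2 & br != dn$d]
      for (acc in cand) {
        ok <- FALSE
        for (hrow in dn$h) {
          hv <- xyz[hrow, ]
          v1 <- d - hv              # H -> donor
          v2 <- xyz[acc, ] - hv     # H -> acceptor
          ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          # angle >= cutoff  <=>  cos(angle) <= cos(cutoff)
          if (ca <= amin) { ok <- TRUE; break }
        }
        if (ok) { ai <- c(ai, dn$d); bi <- c(bi, acc) }
      }
    }
    collect(ai, bi)
  }
}

#' Per-pair contact formed fractions over a window
#'
#' @param traj a `pg_trajectory`.
#' @param criteria a [contact_criteria()].
#' @param window optional [frame_window()].
#' @param system_label label recorded in the table.
#' @return a `pg_pair_fractions`: data frame with the canonical pair
#'   columns, `type` and `fraction`; pairs never formed are omitted
#'   (lookup treats them as 0).
#' @export
pair_fractions <- function(traj, criteria, window = NULL,
                           system_label = "system") {
  frames <- window_frames(traj, window)
  if (!length(frames)) stop("empty window")
  roles <- resolve_contact_roles(traj$topology, criteria)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (t in frames) {
    p <- detect_contacts_frame(frame_coords(traj, t), traj$topology,
                               criteria, roles)
    if (!nrow(p)) next
    ids <- pair_id(p)
    for (i in seq_along(ids)) {
      id <- ids[i]
      counts[[id]] <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
      if (is.null(meta[[id]])) meta[[id]] <- p[i, ]
    }
  }
  ids <- sort(ls(counts))
  tab <- if (length(ids)) {
    cbind(do.call(rbind, lapply(ids, function(id) meta[[id]])),
          type = criteria$contact_type,
          fraction = vapply(ids, function(id) counts[[id]], 0L) / length(frames))
  } else {
    cbind(canonical_pair(traj$topology$atoms, integer(), integer()),
          type = character(), fraction = numeric())
  }
  rownames(tab) <- NULL
  structure(list(entries = tab, system_label = system_label,
                 contact_type = criteria$contact_type,
                 n_frames = length(frames)),
            class = "pg_pair_fractions")
}

#' Look up a pair's formed fraction (0 if absent)
#'
#' @param table a `pg_pair_fractions`.
#' @param chain_a,resid_a,chain_b,resid_b pair identity (order-free).
#' @export
lookup_fraction <- function(table, chain_a, resid_a, chain_b, resid_b) {
  e <- table$entries
  hit <- (e$chain_a == chain_a & e$resid_a == resid_a &
            e$chain_b == chain_b & e$resid_b == resid_b) |
    (e$chain_a == chain_b & e$resid_a == resid_b &
       e$chain_b == chain_a & e$resid_b == resid_a)
  if (any(hit)) e$fraction[which(hit)[1L]] else 0
}

#' Difference two systems' pair-fraction tables
#'
#' Delta = holo fraction - apo fraction over the union of pair
#' universes (missing entries read as 0). Negative deltas are contacts
#' formed in the apo system and lost in the holo system.
#'
#' @param apo,holo `pg_pair_fractions` of the same contact type.
#' @return a `pg_difference_table`: pair columns, `fraction_apo`,
#'   `fraction_holo`, `delta`.
#' @export
difference_table <- function(apo, holo) {
  if (!identical(apo$contact_type, holo$contact_type))
    stop(sprintf("contact type mismatch: %s vs %s",
                 apo$contact_type, holo$contact_type))
  ea <- apo$entries; eh <- holo$entries
  ids_a <- pair_id(ea); ids_h <- pair_id(eh)
  ids <- sort(union(ids_a, ids_h))
  rows <- lapply(ids, function(id) {
    src <- if (id %in% ids_a) ea[match(id, ids_a), 1:6] else eh[match(id, ids_h), 1:6]
    fa <- if (id %in% ids_a) ea$fraction[match(id, ids_a)] else 0
    fh <- if (id %in% ids_h) eh$fraction[match(id, ids_h)] else 0
    cbind(src, fraction_apo = fa, fraction_holo = fh, delta = fh - fa)
  })
  entries <- if (length(rows)) do.call(rbind, rows) else
    cbind(ea[0L, 1:6, drop = FALSE], fraction_apo = numeric(0),
          fraction_holo = numeric(0), delta = numeric(0))
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 contact_type = apo$contact_type,
                 labels = c(apo = apo$system_label, holo = holo$system_label)),
            class = "pg_difference_table")
}

#' Rank the largest fraction differences
#'
#' Pairs sorted by |delta| descending, ties broken by the canonical
#' pair key; select the top `k` or all pairs with `|delta| >= threshold`.
#'
#' @param diff a `pg_difference_table`.
#' @param k number of pairs to keep.
#' @param threshold absolute-delta threshold (alternative to `k`).
#' @return data frame of ranked entries.
#' @export
top_differences <- function(diff, k = NULL, threshold = NULL) {
  e <- diff$entries
  if (!nrow(e)) stop("empty difference table")
  ord <- order(-abs(e$delta), pair_id(e))
  e <- e[ord, , drop = FALSE]
  if (!is.null(threshold)) {
    e <- e[abs(e$delta) >= threshold, , drop = FALSE]
  } else {
    if (is.null(k) || k <= 0) stop("k must be a positive count")
    e <- utils::head(e, k)
  }
  rownames(e) <- NULL
  e
}

#' Ligand contact percentage per residue
#'
#' For each candidate residue, the percentage of window frames in which
#' any ligand heavy atom lies within `cutoff` of any residue heavy
#' atom.
#'
#' @param traj a `pg_trajectory`.
#' @param ligand ligand atom selection (nonempty).
#' @param residues protein residue selection.
#' @param cutoff heavy-atom distance cutoff (A).
#' @param window optional [frame_window()].
#' @return data frame `residue`, `percent`.
#' @export
ligand_contact_profile <- function(traj, ligand, residues, cutoff = 4.0,
                                   window = NULL) {
  lig_rows <- as_sel_rows(ligand)
  if (!length(lig_rows)) stop("empty ligand selection")
  res_rows <- as_sel_rows(residues)
  topo <- traj$topology
  heavy_l <- lig_rows[toupper(topo$atoms$element[lig_rows]) != "H"]
  ra <- topo$atoms[res_rows, ]
  keep <- toupper(ra$element) != "H"
  res_rows <- res_rows[keep]; ra <- ra[keep, ]
  keys <- residue_key(ra)
  ord <- order(ra$chain, ra$resid)
  key_levels <- unique(keys[ord])
  labels <- vapply(key_levels, function(k) {
    i <- which(keys == k)[1L]
    residue_label(ra$chain[i], ra$resid[i], ra$resname[i])
  }, "")
  frames <- window_frames(traj, window)
  hits <- stats::setNames(numeric(length(key_levels)), key_levels)
  cut2 <- cutoff^2
  fac <- factor(keys, levels = key_levels)
  for (t in frames) {
    xyz <- frame_coords(traj, t)
    d2 <- outer(xyz[res_rows, 1L], xyz[heavy_l, 1L], "-")^2 +
      outer(xyz[res_rows, 2L], xyz[heavy_l, 2L], "-")^2 +
      outer(xyz[res_rows, 3L], xyz[heavy_l, 3L], "-")^2
    near <- tapply(apply(d2, 1L, min), fac, min) <= cut2
    hits[near] <- hits[near] + 1
  }
  data.frame(residue = labels, percent = 100 * as.numeric(hits) / length(frames),
             stringsAsFactors = FALSE)
}

#' Write a pair-fraction table as TSV
#' @param table a `pg_pair_fractions`.
#' @param path output path.
#' @export
write_pair_fractions <- function(table, path) {
  e <- table$entries
  e$system <- rep(table$system_label, nrow(e))
  write_tsv(e, path)
}

#' Write a difference table as TSV (and optional dense-matrix heatmap)
#'
#' The heatmap matrix uses the sign convention of published comparison
#' plots: negative delta (apo-only contacts) plots "red", positive
#' (holo-gained) "blue"; the TSV stores the signed delta and leaves
#' colouring to the consumer.
#'
#' @param diff a `pg_difference_table`.
#' @param path output path for the tidy table.
#' @param matrix_path optional path for a dense residue-by-residue
#'   delta matrix TSV.
#' @export
write_difference_table <- function(diff, path, matrix_path = NULL) {
  write_tsv(diff$entries, path)
  if (!is.null(matrix_path)) {
    e <- diff$entries
    la <- paste0(e$chain_a, ":", e$resid_a)
    lb <- paste0(e$chain_b, ":", e$resid_b)
    labs <- sort(unique(c(la, lb)))
    m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (i in seq_len(nrow(e))) {
      m[la[i], lb[i]] <- e$delta[i]
      m[lb[i], la[i]] <- e$delta[i]
    }
    utils::write.table(m, matrix_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}
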