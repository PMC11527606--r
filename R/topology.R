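#' @section Topology:
#' A `pg_topology` holds the static atom metadata of a system: one row per
#' atom with 0-based `index`, atom `name`, `element`, author `resid`
#' (1-based, preserved from the source file), `resname`, `chain`,
#' insertion code `insert`, and the `is_ion` / `is_ligand` flags used by
#' the permeation and ligand-contact analyses.
#' @name poregate-topology
NULL

DEFAULT_ION_NAMES <- c("K", "K+", "POT", "NA", "NA+", "SOD", "CL", "CLA")
DEFAULT_LIGAND_NAMES <- c("PIP", "PIP2", "PI2", "CHS", "CHL", "Y01")

new_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("index", "name", "element", "resid", "resname", "chain",
            "insert", "is_ion", "is_ligand")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("topology atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$index) || !identical(as.integer(atoms$index),
                                               seq_len(nrow(atoms)) - 1L))
    stop("atom indices must be unique and contiguous from 0")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms = nrow(atoms)),
            class = "pg_topology")
}

#' @export
print.pg_topology <- function(x, ...) {
  cat(sprintf("<pg_topology> %d atoms, %d chains, %d ions, %d ligand atoms\n",
              x$n_atoms, length(unique(x$atoms$chain)),
              sum(x$atoms$is_ion), sum(x$atoms$is_ligand)))
  invisible(x)
}

# Residue key used for grouping and cross-system matching.
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resid, trimws(atoms$insert), sep = "|")
}

residue_label <- function(chain, resid, resname) {
  sprintf("%s%d(%s)", resname, resid, chain)
}

#' Read a PDB topology
#'
#' Parses ATOM/HETATM records of a PDB file into a topology. Only the
#' first MODEL of a multi-model file is used. Ions and ligands are
#' flagged by residue name against configurable lists.
#'
#' @param path PDB file path.
#' @param format only `"pdb"` is supported.
#' @param ion_names residue names flagged as ions.
#' @param ligand_names residue names flagged as ligands.
#' @return a `pg_topology`.
#' @export
read_topology <- function(path, format = "pdb",
                          ion_names = DEFAULT_ION_NAMES,
                          ligand_names = DEFAULT_LIGAND_NAMES) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- parse_pdb_atom_lines(lines, first_model_only = TRUE)
  atoms <- parsed$atoms
  if (nrow(atoms) == 0L) stop("no atoms: file contains no ATOM/HETATM records")
  dup <- duplicated(atoms$serial)
  if (any(dup)) {
    stop(sprintf("duplicate atom serial %s at line %d",
                 atoms$serial[which(dup)[1L]], parsed$line_no[which(dup)[1L]]))
  }
  atoms$index <- seq_len(nrow(atoms)) - 1L
  atoms$is_ion <- toupper(atoms$resname) %in% toupper(ion_names)
  atoms$is_ligand <- !atoms$is_ion &
    toupper(atoms$resname) %in% toupper(ligand_names)
  new_topology(atoms[, c("index", "name", "element", "resid", "resname",
                         "chain", "insert", "is_ion", "is_ligand")])
}

# Shared fixed-column PDB ATOM/HETATM parser. Returns the atom table with
# coordinates plus source line numbers; honours MODEL/ENDMDL blocks.
parse_pdb_atom_lines <- function(lines, first_model_only = TRUE) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (first_model_only) {
    endm <- which(startsWith(lines, "ENDMDL"))
    if (length(endm)) is_atom[seq_along(lines) > endm[1L]] <- FALSE
  }
  idx <- which(is_atom)
  ln <- lines[idx]
  sub_f <- function(a, b) substr(ln, a, b)
  num <- function(s) suppressWarnings(as.numeric(s))
  name <- trimws(sub_f(13, 16))
  element <- trimws(sub_f(77, 78))
  fallback <- toupper(substr(gsub("^[0-9]+", "", name), 1, 1))
  element <- ifelse(element == "", fallback, element)
  atoms <- data.frame(
    serial = trimws(sub_f(7, 11)),
    name = name,
    resname = trimws(sub_f(18, 21)),
    chain = trimws(sub_f(22, 22)),
    resid = as.integer(num(sub_f(23, 26))),
    insert = trimws(sub_f(27, 27)),
    x = num(sub_f(31, 38)),
    y = num(sub_f(39, 46)),
    z = num(sub_f(47, 54)),
    element = element,
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))
  if (length(bad)) stop(sprintf("unparsable coordinates at line %d", idx[bad[1L]]))
  atoms$chain[atoms$chain == ""] <- "_"
  list(atoms = atoms, line_no = idx)
}

format_pdb_atom_line <- function(serial, name, resname, chain, resid,
                                 x, y, z, element) {
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, substr(resname, 1, 3), chain, resid,
          x, y, z, 1, 0, element)
}

# Write one frame of coordinates (n x 3) for a topology as PDB ATOM lines.
pdb_frame_lines <- function(topology, xyz) {
  a <- topology$atoms
  format_pdb_atom_line(a$index + 1L, a$name, a$resname, a$chain, a$resid,
                       xyz[, 1L], xyz[, 2L], xyz[, 3L], a$element)
}
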