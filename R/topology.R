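# Bead topologies: residue mapping, chemical roles, species; GRO/PDB readers.
#
# A bead topology is a data.frame with one row per bead:
#   bead_index (0-based), bead_name, residue_seq (author numbering, preserved
#   from input), residue_name, molecule_id, role, species.
# Roles follow the coarse-grained convention: protein backbone/sidechain,
# lipid head/linker/acyl, solvent, ion. Species is the lipid residue name
# (POPC, POPS, PIP2, ...) or "PROT" for protein beads.

BEAD_ROLES <- c("protein_backbone", "protein_sidechain", "lipid_head",
                "lipid_acyl", "lipid_linker", "solvent", "ion")

#' Construct and validate a bead topology
#'
#' @param bead_name,residue_seq,residue_name,molecule_id,role,species
#'   Parallel per-bead vectors; see Details.
#' @return A `bead_topology` data.frame with 0-based `bead_index`.
#' @details Invariants enforced: every bead has exactly one known role;
#'   every lipid molecule has at least one head bead; residue numbering is
#'   constant within a residue.
#' @export
bead_topology <- function(bead_name, residue_seq, residue_name, molecule_id,
                          role, species) {
  n <- length(bead_name)
  stopifnot(length(residue_seq) == n, length(residue_name) == n,
            length(molecule_id) == n, length(role) == n, length(species) == n)
  bad <- setdiff(unique(role), BEAD_ROLES)
  if (length(bad))
    stop("unknown bead role(s): ", paste(bad, collapse = ", "))
  top <- data.frame(bead_index = seq_len(n) - 1L,
                    bead_name = as.character(bead_name),
                    residue_seq = as.integer(residue_seq),
                    residue_name = as.character(residue_name),
                    molecule_id = as.integer(molecule_id),
                    role = as.character(role),
                    species = as.character(species),
                    stringsAsFactors = FALSE)
  lip <- top[startsWith(top$role, "lipid"), ]
  if (nrow(lip)) {
    heads <- tapply(lip$role == "lipid_head", lip$molecule_id, any)
    if (!all(heads))
      stop("lipid molecule(s) without a head bead: ",
           paste(names(heads)[!heads], collapse = ", "))
  }
  class(top) <- c("bead_topology", "data.frame")
  top
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf("bead_topology: %d beads, %d molecules; roles: %s\n",
              nrow(x), length(unique(x$molecule_id)),
              paste(names(table(x$role)), collapse = ", ")))
  invisible(x)
}

is_protein_role <- function(role) role %in% c("protein_backbone", "protein_sidechain")
is_lipid_role <- function(role) startsWith(role, "lipid")

# Default Martini-style bead-name -> role resolution. A user table (named
# character vector bead_name -> role, or a list species -> such vector)
# takes precedence. Plain C1/C2/C3 beads are inositol-ring (head) beads for
# phosphoinositide residues and unknown otherwise.
PIP_RESNAMES <- c("PIP2", "POP2", "PIP", "PIP3", "PI45")

resolve_bead_role <- function(bead_name, residue_name, role_table = NULL) {
  if (!is.null(role_table)) {
    tab <- if (is.list(role_table)) role_table[[residue_name]] else role_table
    if (!is.null(tab) && bead_name %in% names(tab)) return(unname(tab[[bead_name]]))
  }
  if (bead_name == "BB") return("protein_backbone")
  if (grepl("^SC[0-9]?$", bead_name)) return("protein_sidechain")
  if (bead_name %in% c("NC3", "NH3", "CNO", "PO4", "CP", "PO1", "PO2",
                       "P1", "P2", "P3")) return("lipid_head")
  if (residue_name %in% PIP_RESNAMES && bead_name %in% c("C1", "C2", "C3"))
    return("lipid_head")
  if (grepl("^(GL[0-9]|AM[0-9])$", bead_name)) return("lipid_linker")
  if (grepl("^[CD][1-9][AB]$", bead_name)) return("lipid_acyl")
  if (bead_name %in% c("W", "WF", "WN", "PW")) return("solvent")
  if (bead_name %in% c("NA", "CL", "ION", "NA+", "CL-", "CA", "NC"))
    return("ion")
  stop(sprintf("cannot resolve role for bead '%s' in residue '%s'; supply a role_table entry",
               bead_name, residue_name))
}

# Amino-acid 3-letter codes (for species = "PROT" classification from PDB-ish
# residue names; coarse-grained files often keep them).
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

build_topology_from_atoms <- function(bead_name, residue_seq, residue_name,
                                      role_table = NULL) {
  n <- length(bead_name)
  role <- character(n)
  for (i in seq_len(n))
    role[i] <- resolve_bead_role(bead_name[i], residue_name[i], role_table)
  species <- ifelse(is_protein_role(role), "PROT", residue_name)
  # molecule ids: contiguous protein residues share a molecule; each
  # non-protein residue (lipid, solvent, ion) is its own molecule.
  molecule_id <- integer(n)
  mid <- 0L
  prev_res <- NA_integer_; prev_prot <- NA
  new_res <- c(TRUE, residue_seq[-1] != residue_seq[-n] |
                     residue_name[-1] != residue_name[-n])
  for (i in seq_len(n)) {
    prot <- is_protein_role(role[i])
    if (new_res[i]) {
      if (!prot || is.na(prev_prot) || !prev_prot) mid <- mid + 1L
    }
    molecule_id[i] <- mid
    prev_prot <- prot
  }
  bead_topology(bead_name, residue_seq, residue_name, molecule_id, role, species)
}

# ---- GRO I/O (fixed-width; coordinates nm in file, A in memory) ----------

parse_gro_block <- function(lines) {
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || length(lines) < natoms + 3)
    stop("malformed GRO file: bad atom count or truncated block")
  at <- lines[3:(2 + natoms)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  atname <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("malformed GRO file: unparseable atom line")
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3]), "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop("malformed GRO file: bad box line")
  if (length(boxv) > 3 && any(abs(boxv[4:length(boxv)]) > 1e-9))
    stop("triclinic box not supported: off-diagonal GRO box components present")
  tm <- 0
  m <- regmatches(lines[1], regexpr("t=\\s*[-0-9.eE+]+", lines[1]))
  if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m))
  list(resid = resid, resname = resname, atname = atname,
       coords = cbind(x, y, z) * 10, box = boxv[1:3] * 10, time = tm,
       nlines = natoms + 3L)
}

#' Read a bead structure file (GRO or PDB)
#'
#' Parses a coarse-grained structure into a [bead_topology()] plus a single
#' coordinate frame. GRO coordinates (nm) are converted to Angstrom; PDB
#' files (read via \pkg{bio3d}) are already in Angstrom.
#'
#' @param path Path to a `.gro` or `.pdb` file.
#' @param role_table Optional override: named character vector
#'   (bead name -> role) or list of such vectors keyed by residue name.
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`.
#' @return List with elements `topology` and `frame` (a [traj_frame()]).
#' @export
read_structure <- function(path, role_table = NULL,
                           format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (format == "gro") {
    lines <- readLines(path)
    b <- parse_gro_block(lines)
    top <- build_topology_from_atoms(b$atname, b$resid, b$resname, role_table)
    frame <- traj_frame(b$coords, b$box, b$time)
  } else {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    top <- build_topology_from_atoms(trimws(at$elety), at$resno,
                                     trimws(at$resid), role_table)
    box <- c(200, 200, 200)
    if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
        all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0))
      box <- pdb$cryst1$abc
    frame <- traj_frame(cbind(at$x, at$y, at$z), box, 0)
  }
  list(topology = top, frame = frame)
}

format_gro_frame <- function(topology, coords, box, time, title = "memtraj") {
  n <- nrow(topology)
  hdr <- sprintf("%s t= %.3f", title, time)
  at <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                topology$residue_seq %% 100000, topology$residue_name,
                topology$bead_name, (topology$bead_index + 1L) %% 100000,
                coords[, 1] / 10, coords[, 2] / 10, coords[, 3] / 10)
  c(hdr, sprintf("%5d", n), at, sprintf("%10.5f%10.5f%10.5f",
                                        box[1] / 10, box[2] / 10, box[3] / 10))
}

#' Write a structure (or trajectory) in GRO format
#'
#' @param topology A [bead_topology()].
#' @param frame A [traj_frame()], or a [trajectory()] to write all frames as
#'   a concatenated multi-frame GRO file.
#' @param path Output path.
#' @export
write_gro <- function(topology, frame, path) {
  if (inherits(frame, "trajectory")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n_frames(frame)))
      writeLines(format_gro_frame(topology, frame$coords[, , i],
                                  frame$box[i, ], frame$times[i]), con)
  } else {
    writeLines(format_gro_frame(topology, frame$coords, frame$box, frame$time),
               path)
  }
  invisible(path)
}
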