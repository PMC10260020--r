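# Membrane bookkeeping: leaflet assignment, elastic networks for rigid
# domains, and generation of initial membrane-facing orientations.

#' Assign lipids to bilayer leaflets
#'
#' The midplane is the mean z of all lipid head beads; each lipid goes to
#' the upper or lower leaflet by the sign of (mean head z - midplane), with
#' ties assigned to the lower leaflet. The membrane normal convention is
#' +z pointing toward the upper-leaflet solvent.
#'
#' @param frame A [traj_frame()].
#' @param topology A [bead_topology()].
#' @return A `membrane_model`: list with `midplane_z`, `leaflet` (named by
#'   lipid `molecule_id`), and `normal`.
#' @export
assign_leaflets <- function(frame, topology) {
  heads <- topology$role == "lipid_head"
  if (!any(heads)) stop("no lipid head beads in topology")
  hz <- frame$coords[heads, 3]
  mol <- topology$molecule_id[heads]
  mol_z <- tapply(hz, mol, mean)
  if (length(mol_z) < 2) stop("need >= 2 lipids with head beads")
  midplane <- mean(hz)
  leaflet <- ifelse(mol_z > midplane, "upper", "lower")
  if (!all(c("upper", "lower") %in% leaflet))
    stop("no bilayer detected: all lipid heads on one side of the midplane")
  # a genuine bilayer separates its head planes by at least a head-group
  # diameter; a jittered single layer straddling its own mean does not
  sep <- mean(mol_z[leaflet == "upper"]) - mean(mol_z[leaflet == "lower"])
  if (sep < 5)
    stop(sprintf("no bilayer detected: leaflet separation %.2f A < 5 A", sep))
  structure(list(midplane_z = midplane,
                 leaflet = stats::setNames(as.vector(leaflet), names(mol_z)),
                 normal = c(0, 0, 1)),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("membrane_model: midplane z = %.2f A; %d upper / %d lower lipids\n",
              x$midplane_z, sum(x$leaflet == "upper"), sum(x$leaflet == "lower")))
  invisible(x)
}

# Molecule ids (as integers) of lipids in one leaflet.
leaflet_molecules <- function(membrane, leaflet) {
  as.integer(names(membrane$leaflet)[membrane$leaflet == leaflet])
}

#' Build an elastic network over protein backbone beads
#'
#' One harmonic bond per backbone-bead pair (i, j) with |i - j| >= 2 (in
#' backbone order) whose reference distance lies inside `[lower, upper]`
#' (inclusive); the equilibrium length is the reference distance. Distances
#' are plain Euclidean at the reference frame, so the bond set is invariant
#' to rigid motion of the reference.
#'
#' @param frame Reference [traj_frame()].
#' @param topology A [bead_topology()] with protein backbone beads.
#' @param lower,upper Distance cutoffs (A); defaults 5 and 9.
#' @param k Force constant (kJ mol-1 nm-2); default 400.
#' @return An `elastic_bond_set` data.frame (0-based bead indices `i`, `j`,
#'   `r0` in A, `k`), with the cutoffs as attributes.
#' @export
build_elastic_bonds <- function(frame, topology, lower = 5, upper = 9, k = 400) {
  bb <- which(topology$role == "protein_backbone")
  if (length(bb) < 3) stop("need >= 3 protein backbone beads")
  X <- frame$coords[bb, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  n <- length(bb)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  keep <- idx[, 2] - idx[, 1] >= 2 & D[idx] >= lower & D[idx] <= upper
  idx <- idx[keep, , drop = FALSE]
  bonds <- data.frame(i = topology$bead_index[bb[idx[, 1]]],
                      j = topology$bead_index[bb[idx[, 2]]],
                      r0 = D[idx],
                      k = rep(k, nrow(idx)))
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  attr(bonds, "lower") <- lower
  attr(bonds, "upper") <- upper
  class(bonds) <- c("elastic_bond_set", "data.frame")
  bonds
}

#' Write an elastic bond set as a topology-style text table
#'
#' Columns: 1-based bead numbers `i`, `j`, equilibrium length `r0_nm`, and
#' force constant `k` (kJ mol-1 nm-2), with a commented provenance header.
#'
#' @param bonds An `elastic_bond_set` from [build_elastic_bonds()].
#' @param path Output path.
#' @export
write_elastic_bonds <- function(bonds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("; elastic bonds: lower=%g A upper=%g A", attr(bonds, "lower"),
                       attr(bonds, "upper")),
               "; i j r0_nm k"), con)
  writeLines(sprintf("%d %d %.6f %g", bonds$i + 1L, bonds$j + 1L,
                     bonds$r0 / 10, bonds$k), con)
  invisible(path)
}

#' Generate initial membrane-facing orientations of a complex
#'
#' Rotates the complex about its centre of geometry in equal angular steps
#' of 360/n degrees, alternating between the x and y axes (step `k` uses
#' angle `k * 360/n` about x for even `k` and y for odd `k`), then
#' translates each pose along z so that the minimum z-gap between the
#' complex and the lower-leaflet head beads equals `offset`, with the
#' complex below the lower leaflet (intracellular geometry).
#'
#' @param frame Complex [traj_frame()] (rigid coordinates).
#' @param topology Complex [bead_topology()].
#' @param bilayer A list with `frame`, `topology` and optionally `membrane`
#'   describing the bilayer (e.g. from [make_bilayer()]).
#' @param n Number of orientations (default 16).
#' @param offset Target z-gap in A (default 7).
#' @return List of `n` [traj_frame()]s in the bilayer box.
#' @export
generate_start_orientations <- function(frame, topology, bilayer, n = 16,
                                        offset = 7) {
  if (n < 1) stop("n must be >= 1")
  stop_if_not_scalar_pos(offset, "offset")
  membrane <- bilayer$membrane %||% assign_leaflets(bilayer$frame, bilayer$topology)
  lower_mol <- leaflet_molecules(membrane, "lower")
  hsel <- bilayer$topology$role == "lipid_head" &
          bilayer$topology$molecule_id %in% lower_mol
  min_head_z <- min(bilayer$frame$coords[hsel, 3])
  ctr <- colMeans(frame$coords)
  box <- bilayer$frame$box
  out <- vector("list", n)
  for (kk in seq_len(n) - 1L) {
    ang <- kk * 360 / n
    R <- if (kk %% 2 == 0) rot_x(ang) else rot_y(ang)
    X <- sweep(sweep(frame$coords, 2, ctr) %*% t(R), 2, ctr, "+")
    dz <- (min_head_z - offset) - max(X[, 3])
    X[, 3] <- X[, 3] + dz
    # centre the complex in xy within the bilayer box
    X[, 1] <- X[, 1] - mean(X[, 1]) + box[1] / 2
    X[, 2] <- X[, 2] - mean(X[, 2]) + box[2] / 2
    out[[kk + 1L]] <- traj_frame(X, box, 0)
  }
  out
}
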