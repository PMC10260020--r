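# 2D lipid density and enrichment/depletion maps (xy-plane) and backbone
# RMSF. Density maps count reference beads (default PO4) per square bin and
# average over frames; enrichment is the percent deviation of each bin from
# the mean over the full leaflet footprint.

#' 2D lipid density map in the membrane plane
#'
#' Accumulates the xy positions of the reference beads of one lipid species
#' (one leaflet or both) into a square grid covering the box footprint and
#' divides by the number of frames. With `center_on`, every frame is first
#' translated (with periodic wrapping) so that the xy centre of geometry of
#' the given bead selection sits at the box centre, which keeps a laterally
#' diffusing protein at the map centre.
#'
#' @param traj A [trajectory()].
#' @param species Lipid species (e.g. `"PIP2"`).
#' @param bead_name Reference bead name (default `"PO4"`).
#' @param bin Bin size in A (default 1).
#' @param leaflet `"lower"`, `"upper"` or `"both"`.
#' @param center_on Optional 0-based bead indices used for per-frame
#'   centering, or `NULL` for none.
#' @param membrane Optional `membrane_model`; computed from frame 1 if absent.
#' @return A `density_map`: list with `counts` (nx x ny mean counts), `bin`,
#'   `box_xy`, `species`, `bead_name`, `leaflet`, `centering`, `n_frames`.
#' @export
lipid_density_map <- function(traj, species, bead_name = "PO4", bin = 1,
                              leaflet = c("lower", "upper", "both"),
                              center_on = NULL, membrane = NULL) {
  leaflet <- match.arg(leaflet)
  stop_if_not_scalar_pos(bin, "bin")
  top <- traj$topology
  sel <- which(top$species %in% species & top$bead_name %in% bead_name)
  if (leaflet != "both") {
    membrane <- membrane %||% assign_leaflets(get_frame(traj, 1), top)
    sel <- sel[top$molecule_id[sel] %in% leaflet_molecules(membrane, leaflet)]
  }
  if (!length(sel)) stop(sprintf("no '%s' beads of species %s in leaflet '%s'",
                                 bead_name, paste(species, collapse = "/"), leaflet))
  cidx <- NULL
  if (!is.null(center_on)) {
    cidx <- match(center_on, top$bead_index)
    if (anyNA(cidx)) stop("center_on contains unknown bead indices")
  }
  box <- traj$box[1, ]
  nx <- max(1L, ceiling(box[1] / bin - 1e-9))
  ny <- max(1L, ceiling(box[2] / bin - 1e-9))
  counts <- matrix(0, nx, ny)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xy <- slice_coords(traj$coords, sel, f)[, 1:2, drop = FALSE]
    if (!is.null(cidx)) {
      cog <- colMeans(slice_coords(traj$coords, cidx, f))[1:2]
      xy <- sweep(xy, 2, cog - box[1:2] / 2, "-")
    }
    xy[, 1] <- xy[, 1] - floor(xy[, 1] / box[1]) * box[1]
    xy[, 2] <- xy[, 2] - floor(xy[, 2] / box[2]) * box[2]
    ix <- pmin(nx, floor(xy[, 1] / bin) + 1L)
    iy <- pmin(ny, floor(xy[, 2] / bin) + 1L)
    for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  structure(list(counts = counts / nf, bin = bin, box_xy = box[1:2],
                 species = species, bead_name = bead_name, leaflet = leaflet,
                 centering = if (is.null(center_on)) "none" else "selection",
                 n_frames = nf),
            class = "density_map")
}

#' Combine density maps computed on identical grids
#'
#' Frame-weighted average of compatible maps (same grid, species, leaflet),
#' used to pool replicate trajectories or bilayer realizations.
#'
#' @param maps List of `density_map` objects.
#' @export
average_density_maps <- function(maps) {
  m0 <- maps[[1]]
  tot <- 0
  acc <- matrix(0, nrow(m0$counts), ncol(m0$counts))
  for (m in maps) {
    if (!identical(dim(m$counts), dim(m0$counts)) || m$bin != m0$bin)
      stop("density maps have incompatible grids")
    acc <- acc + m$counts * m$n_frames
    tot <- tot + m$n_frames
  }
  m0$counts <- acc / tot
  m0$n_frames <- tot
  m0
}

#' Percent enrichment/depletion map
#'
#' `E(bin) = 100 * (rho(bin) - rho_bar) / rho_bar`, with `rho_bar` the mean
#' over the full leaflet footprint (all bins) by default, so that the map
#' mean is zero by construction. `nonzero_only = TRUE` restricts `rho_bar`
#' to bins with at least one observation.
#'
#' @param density A `density_map`.
#' @param nonzero_only Restrict the reference mean to occupied bins.
#' @return An `enrichment_map` with `percent` matrix and grid metadata.
#' @export
enrichment_map <- function(density, nonzero_only = FALSE) {
  rho <- density$counts
  ref <- if (nonzero_only) mean(rho[rho > 0]) else mean(rho)
  if (!is.finite(ref) || ref <= 0) stop("all-zero density map: no reference density")
  structure(list(percent = 100 * (rho - ref) / ref, bin = density$bin,
                 box_xy = density$box_xy, species = density$species,
                 leaflet = density$leaflet, centering = density$centering,
                 reference_density = ref, nonzero_only = nonzero_only),
            class = "enrichment_map")
}

#' Mean enrichment inside a disc of the map
#'
#' Average percent enrichment over bins whose centres lie within `radius`
#' of `center` (xy, A); used to read out planted or observed microdomains.
#'
#' @param emap An `enrichment_map`.
#' @param center xy coordinates (A) of the disc centre.
#' @param radius Disc radius (A).
#' @export
disc_mean_enrichment <- function(emap, center, radius) {
  nx <- nrow(emap$percent); ny <- ncol(emap$percent)
  xc <- (seq_len(nx) - 0.5) * emap$bin
  yc <- (seq_len(ny) - 0.5) * emap$bin
  dx <- outer(xc - center[1], rep(1, ny))
  dy <- outer(rep(1, nx), yc - center[2])
  inside <- (dx^2 + dy^2) <= radius^2
  mean(emap$percent[inside])
}

#' Write a density or enrichment map as a text matrix plus JSON sidecar
#' @param map A `density_map` or `enrichment_map`.
#' @param path Output path for the matrix; metadata goes to `<path>.json`.
#' @export
write_map <- function(map, path) {
  M <- if (inherits(map, "density_map")) map$counts else map$percent
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- map[setdiff(names(map), c("counts", "percent"))]
  meta$kind <- class(map)[1]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Backbone root-mean-square fluctuation per residue
#'
#' Frames are least-squares superposed (rotation + translation) onto the
#' mean structure using the `align_on` beads; the fit is refined once by
#' re-averaging after an initial alignment to the first frame. RMSF of a
#' residue is the root time-mean squared displacement of its backbone bead
#' from its time-mean position.
#'
#' @param traj A [trajectory()].
#' @param align_on 0-based bead indices used for the superposition; default
#'   all protein backbone beads.
#' @param report_on 0-based bead indices to report (default: all protein
#'   backbone beads).
#' @return A data.frame `(residue_seq, rmsf)` of class `residue_series`
#'   with attribute `kind = "RMSF"`.
#' @export
backbone_rmsf <- function(traj, align_on = NULL, report_on = NULL) {
  top <- traj$topology
  bb <- top$bead_index[top$role == "protein_backbone"]
  align_on <- align_on %||% bb
  report_on <- report_on %||% bb
  if (!length(align_on) || !length(report_on)) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("need >= 2 frames for RMSF")
  ai <- match(align_on, top$bead_index)
  ri <- match(report_on, top$bead_index)
  if (anyNA(ai) || anyNA(ri)) stop("selection contains unknown bead indices")
  N <- dim(traj$coords)[1]
  aligned <- array(0, c(N, 3, nf))
  ref <- slice_coords(traj$coords, seq_len(N), 1)
  for (f in seq_len(nf))
    aligned[, , f] <- superpose_onto(slice_coords(traj$coords, seq_len(N), f),
                                     ref, ai)
  mean1 <- apply(aligned, c(1, 2), mean)
  for (f in seq_len(nf))
    aligned[, , f] <- superpose_onto(aligned[, , f], mean1, ai)
  mu <- apply(aligned[ri, , , drop = FALSE], c(1, 2), mean)
  sq <- 0
  for (f in seq_len(nf)) {
    d <- aligned[ri, , f, drop = FALSE]
    dim(d) <- dim(d)[1:2]
    sq <- sq + rowSums((d - mu)^2)
  }
  out <- data.frame(residue_seq = top$residue_seq[ri],
                    value = sqrt(sq / nf))
  residue_series(out$residue_seq, out$value, kind = "RMSF")
}
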