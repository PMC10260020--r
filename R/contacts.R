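# Protein-lipid contact fractions, residue-residue distance maps, and
# membrane-bound-state detection/statistics.
#
# A contact is counted when a protein bead lies within `cutoff` (inclusive,
# minimum image) of a lipid bead of the requested part; the contact fraction
# of residue r and species s is the fraction of analysed frames in which any
# such bead pair exists.

lipid_part_roles <- function(part) {
  switch(part,
         head = "lipid_head",
         acyl = "lipid_acyl",
         any  = c("lipid_head", "lipid_acyl", "lipid_linker"),
         stop("part must be 'head', 'acyl' or 'any'"))
}

protein_residue_info <- function(topology, protein_beads = "backbone") {
  sel_role <- if (protein_beads == "backbone") "protein_backbone"
              else c("protein_backbone", "protein_sidechain")
  pidx <- which(topology$role %in% sel_role)
  if (!length(pidx)) stop("no protein beads of the requested kind in topology")
  res <- topology$residue_seq[pidx]
  list(idx = pidx, res = res, residues = unique(res))
}

#' Per-residue protein-lipid contact fractions
#'
#' For each protein residue and lipid species, the fraction of frames in
#' which any lipid bead of the requested part (head-group, acyl-chain, or
#' any lipid bead) of that species lies within `cutoff` A (inclusive,
#' minimum-image) of a bead of the residue.
#'
#' @param traj A [trajectory()].
#' @param part `"head"`, `"acyl"` or `"any"`.
#' @param cutoff Contact cutoff in A (default 7).
#' @param species Optional character vector restricting lipid species.
#' @param protein_beads `"backbone"` (default) or `"all"`.
#' @param frames Optional frame indices to analyse (e.g. a state's members).
#' @param equil_offset Number of initial frames discarded as equilibration
#'   (default 0); ignored when `frames` is given.
#' @param collapse_species If `TRUE`, report a single `"ALL"` column with
#'   the union contact over all selected species.
#' @return A `contact_profile`: list with `residue_seq`, `species`, `part`,
#'   `fraction` (residue x species matrix), `n_frames`, and the parameters.
#' @export
residue_lipid_contact_fractions <- function(traj, part = c("head", "acyl", "any"),
                                            cutoff = 7, species = NULL,
                                            protein_beads = c("backbone", "all"),
                                            frames = NULL, equil_offset = 0,
                                            collapse_species = FALSE) {
  part <- match.arg(part)
  protein_beads <- match.arg(protein_beads)
  top <- traj$topology
  pinfo <- protein_residue_info(top, protein_beads)
  roles <- lipid_part_roles(part)
  lsel <- which(top$role %in% roles)
  if (!is.null(species)) lsel <- lsel[top$species[lsel] %in% species]
  if (!length(lsel)) stop("empty lipid species selection")
  sp <- if (collapse_species) rep("ALL", length(lsel)) else top$species[lsel]
  sp_levels <- sort(unique(sp))
  sp_f <- factor(sp, levels = sp_levels)
  res_f <- factor(pinfo$res, levels = pinfo$residues)
  if (is.null(frames)) {
    if (equil_offset < 0 || equil_offset >= n_frames(traj))
      stop("equil_offset must be in [0, n_frames)")
    frames <- seq_len(n_frames(traj))
    if (equil_offset > 0) frames <- frames[-seq_len(equil_offset)]
  }
  if (!length(frames)) stop("zero frames selected")
  counts <- matrix(0, length(pinfo$residues), length(sp_levels),
                   dimnames = list(pinfo$residues, sp_levels))
  for (f in frames) {
    D <- pdist_mi(slice_coords(traj$coords, pinfo$idx, f),
                  slice_coords(traj$coords, lsel, f), traj$box[f, ])
    M <- (D <= cutoff) + 0
    byres <- rowsum(M, res_f, reorder = FALSE)
    byres <- byres[match(as.character(pinfo$residues), rownames(byres)), ,
                   drop = FALSE]
    bysp <- rowsum(t(byres), sp_f, reorder = FALSE)
    bysp <- t(bysp[match(sp_levels, rownames(bysp)), , drop = FALSE])
    counts <- counts + (bysp > 0)
  }
  structure(list(residue_seq = pinfo$residues, species = sp_levels, part = part,
                 fraction = counts / length(frames), n_frames = length(frames),
                 cutoff = cutoff, protein_beads = protein_beads),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile (%s beads, cutoff %g A, %d frames): %d residues x %s\n",
              x$part, x$cutoff, x$n_frames, length(x$residue_seq),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Write a contact profile as a delimited table with provenance header
#' @param profile A `contact_profile`.
#' @param path Output path.
#' @export
write_contact_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact_profile part=%s cutoff=%g protein_beads=%s n_frames=%d",
                     profile$part, profile$cutoff, profile$protein_beads,
                     profile$n_frames), con)
  df <- data.frame(residue_seq = profile$residue_seq, profile$fraction,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Time-averaged residue-residue minimum-distance map
#'
#' Cell (a, b) holds the time average over frames of the minimum bead-bead
#' distance (minimum image) between residues a of selection A and b of
#' selection B. Masks flag close contacts (average <= `close_cutoff`) and
#' no-contact pairs (average >= `far_cutoff`), both inclusive.
#'
#' @param traj A [trajectory()].
#' @param sel_a,sel_b Bead index vectors (0-based, as in the topology);
#'   must be non-empty and disjoint.
#' @param close_cutoff,far_cutoff Mask cutoffs in A (defaults 4 and 6).
#' @return A `residue_distance_map`: list with residue vectors, `avg`
#'   matrix (A), and logical `close` / `no_contact` masks.
#' @export
residue_residue_distance_map <- function(traj, sel_a, sel_b,
                                         close_cutoff = 4, far_cutoff = 6) {
  if (!length(sel_a) || !length(sel_b)) stop("selections must be non-empty")
  if (length(intersect(sel_a, sel_b))) stop("selections overlap")
  top <- traj$topology
  ia <- match(sel_a, top$bead_index); ib <- match(sel_b, top$bead_index)
  if (anyNA(ia) || anyNA(ib)) stop("selection contains unknown bead indices")
  res_a <- unique(top$residue_seq[ia]); res_b <- unique(top$residue_seq[ib])
  fa <- factor(top$residue_seq[ia], levels = res_a)
  fb <- factor(top$residue_seq[ib], levels = res_b)
  acc <- matrix(0, length(res_a), length(res_b),
                dimnames = list(res_a, res_b))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    D <- pdist_mi(slice_coords(traj$coords, ia, f),
                  slice_coords(traj$coords, ib, f), traj$box[f, ])
    # per-residue-pair minimum: aggregate rows then columns with min
    m1 <- apply(D, 2, function(col) tapply(col, fa, min))
    if (is.null(dim(m1))) m1 <- matrix(m1, length(res_a), length(ib))
    m2 <- t(apply(m1, 1, function(row) tapply(row, fb, min)))
    if (is.null(dim(m2)) || nrow(m2) != length(res_a))
      m2 <- matrix(m2, length(res_a), length(res_b))
    acc <- acc + m2
  }
  avg <- acc / nf
  structure(list(residues_a = res_a, residues_b = res_b, avg = avg,
                 close = avg <= close_cutoff, no_contact = avg >= far_cutoff,
                 close_cutoff = close_cutoff, far_cutoff = far_cutoff),
            class = "residue_distance_map")
}

#' Detect membrane-bound frames
#'
#' A frame is raw-bound when at least `min_residues` protein residues have
#' any lipid head-group bead within `cutoff` A. The raw flag is debounced by
#' a hysteresis rule: the bound state is entered only by a run of at least
#' `dwell_frames` consecutive raw-bound frames (the whole run counts as
#' bound) and left only by a run of at least `dwell_frames` raw-unbound
#' frames; shorter excursions in either direction are absorbed.
#'
#' @param traj A [trajectory()].
#' @param cutoff Contact cutoff in A (default 7).
#' @param min_residues Minimum contacting residues (default 5).
#' @param dwell_frames Debounce length in frames (default 5).
#' @return A `bound_series`: list with logical `bound`, `raw`, `times`, and
#'   the parameters used.
#' @export
detect_bound_frames <- function(traj, cutoff = 7, min_residues = 5,
                                dwell_frames = 5) {
  if (dwell_frames < 1) stop("dwell_frames must be >= 1")
  top <- traj$topology
  pinfo <- protein_residue_info(top, "backbone")
  hsel <- which(top$role == "lipid_head")
  if (!length(hsel)) stop("no lipid head beads: bilayer missing")
  nf <- n_frames(traj)
  res_f <- factor(pinfo$res, levels = pinfo$residues)
  raw <- logical(nf)
  for (f in seq_len(nf)) {
    D <- pdist_mi(slice_coords(traj$coords, pinfo$idx, f),
                  slice_coords(traj$coords, hsel, f), traj$box[f, ])
    mind <- tapply(apply(D, 1, min), res_f, min)
    raw[f] <- sum(mind <= cutoff) >= min_residues
  }
  bound <- debounce_series(raw, dwell_frames)
  structure(list(bound = bound, raw = raw, times = traj$times,
                 cutoff = cutoff, min_residues = min_residues,
                 dwell_frames = dwell_frames),
            class = "bound_series")
}

# Hysteresis smoothing of a logical series on run-length encoding.
debounce_series <- function(raw, dwell) {
  r <- rle(raw)
  state <- FALSE
  out <- logical(0)
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]; val <- r$values[k]
    if (val != state && len >= dwell) state <- val
    out <- c(out, rep(state, len))
  }
  out
}

#' Summary statistics of a bound series
#'
#' @param series A `bound_series` (or logical vector).
#' @param times Optional frame times; defaults to the series' own.
#' @return List with `bound_fraction`, `first_binding_time` (`NA` if never
#'   bound), and `n_binding_events` (unbound-to-bound transitions; a series
#'   that starts bound counts its initial run as an event).
#' @export
bound_statistics <- function(series, times = NULL) {
  bound <- if (is.list(series)) series$bound else as.logical(series)
  if (!length(bound)) stop("empty bound series")
  times <- times %||% (if (is.list(series)) series$times else seq_along(bound) - 1)
  r <- rle(bound)
  events <- sum(r$values)
  first <- if (any(bound)) times[which(bound)[1]] else NA_real_
  list(bound_fraction = mean(bound), first_binding_time = first,
       n_binding_events = events)
}

#' Write a bound series as a two-column (time, bound) table
#' @param series A `bound_series`.
#' @param path Output path.
#' @export
write_bound_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bound_series cutoff=%g min_residues=%d dwell_frames=%d",
                     series$cutoff, series$min_residues, series$dwell_frames), con)
  utils::write.table(data.frame(time = series$times, bound = as.integer(series$bound)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
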