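# Synthetic fixtures with planted ground truth: bead bilayers (lipid
# compositions, optional radial enrichment of one species), protein
# trajectories following a scheduled orientation-state and bound/unbound
# sequence with planted per-residue contact fractions, correlated NMR
# titration profiles, and exponential relaxation decays.
#
# Reproducibility contract: every generator is deterministic given
# (spec, seed). Independent aspects (lipid positions, species assignment,
# protein schedule, noise) draw from separate sub-streams derived from the
# seed, so e.g. changing the lipid composition never perturbs the protein
# poses -- which is what makes concentration-coupling tests well defined.

# Largest-remainder apportionment of n items to fractions.
largest_remainder <- function(fracs, n) {
  exact <- fracs * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(exact - base), seq_along(fracs))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Specification of a synthetic two-leaflet bead bilayer
#'
#' Lipids are 3-bead caricatures (1 PO4 head + 2 acyl beads pointing toward
#' the midplane) on a jittered square lattice at the stated area per lipid.
#' Species are assigned per leaflet by composition with largest-remainder
#' rounding; an optional enrichment disc concentrates one species around a
#' centre at a planted fold relative to the leaflet mean density. Species
#' blocks are taken in the order of the composition vector from a
#' composition-independent site permutation, so increasing the fraction of
#' the last-listed species yields a nested site set (used for
#' concentration-coupling tests).
#'
#' @param box_xy Box xy dimensions (A).
#' @param apl Area per lipid (A^2).
#' @param lower,upper Named species-fraction vectors per leaflet (sum 1).
#' @param leaflet_z Named z positions (A) of the lower/upper head planes.
#' @param jitter_xy,jitter_z Positional jitter SD (A).
#' @param enrichment Optional list `(species, center, radius, fold)`;
#'   `fold = 1` means no enrichment bias.
#' @export
bilayer_spec <- function(box_xy = c(160, 160), apl = 64,
                         lower = c(POPC = 0.8, POPS = 0.1, PIP2 = 0.1),
                         upper = c(POPC = 1),
                         leaflet_z = c(lower = 20, upper = 58),
                         jitter_xy = 0.8, jitter_z = 0.3,
                         enrichment = NULL) {
  for (comp in list(lower, upper))
    if (abs(sum(comp) - 1) > 1e-9) stop("leaflet fractions must sum to 1")
  if (!is.null(enrichment)) {
    enrichment$center <- enrichment$center %||% (box_xy / 2)
    enrichment$fold <- enrichment$fold %||% 1
    if (enrichment$fold < 0) stop("enrichment fold must be >= 0")
  }
  structure(list(box_xy = box_xy, apl = apl, lower = lower, upper = upper,
                 leaflet_z = leaflet_z, jitter_xy = jitter_xy,
                 jitter_z = jitter_z, enrichment = enrichment),
            class = "bilayer_spec")
}

# Lattice geometry shared by the bilayer builders.
bilayer_lattice <- function(spec) {
  s <- sqrt(spec$apl)
  nx <- max(1L, round(spec$box_xy[1] / s))
  ny <- max(1L, round(spec$box_xy[2] / s))
  sx <- spec$box_xy[1] / nx; sy <- spec$box_xy[2] / ny
  sites <- cbind(rep((seq_len(nx) - 0.5) * sx, ny),
                 rep((seq_len(ny) - 0.5) * sy, each = nx))
  list(nx = nx, ny = ny, sx = sx, sy = sy, sites = sites,
       n_sites = nx * ny)
}

# Species assignment for one leaflet; returns a character vector per site.
assign_species <- function(spec, lat, composition, enrichment_here) {
  n <- lat$n_sites
  counts <- largest_remainder(composition, n)
  names(counts) <- names(composition)
  species <- character(n)
  if (!is.null(enrichment_here) && enrichment_here$fold != 1) {
    en <- enrichment_here
    dx <- lat$sites[, 1] - en$center[1]
    dx <- dx - spec$box_xy[1] * round(dx / spec$box_xy[1])
    dy <- lat$sites[, 2] - en$center[2]
    dy <- dy - spec$box_xy[2] * round(dy / spec$box_xy[2])
    disc <- which(dx^2 + dy^2 <= en$radius^2)
    k_s <- counts[[en$species]]
    # area-based target: the disc's time-averaged bead density reads out at
    # `fold` times the leaflet mean on a continuous grid
    area_frac <- min(1, pi * en$radius^2 / prod(spec$box_xy))
    target <- en$fold * k_s * area_frac
    s_in <- floor(target) + (stats::runif(1) < (target - floor(target)))
    s_in <- max(0L, min(length(disc), k_s, as.integer(s_in)))
    in_sites <- disc[sample.int(length(disc), s_in)]
    outside <- setdiff(seq_len(n), disc)
    out_sites <- outside[sample.int(length(outside), k_s - s_in)]
    species[c(in_sites, out_sites)] <- en$species
    rest <- which(species == "")
    perm <- rest[sample.int(length(rest))]
    pos <- 1L
    for (sp in names(counts)) {
      if (sp == en$species) next
      k <- counts[[sp]]
      species[perm[pos:(pos + k - 1L)]] <- sp
      pos <- pos + k
    }
  } else {
    perm <- sample.int(n)
    pos <- 1L
    for (sp in names(counts)) {
      k <- counts[[sp]]
      if (k > 0) species[perm[pos:(pos + k - 1L)]] <- sp
      pos <- pos + k
    }
  }
  species
}

bilayer_bead_template <- c("PO4", "C1A", "C2A")

# z offsets of the three beads relative to the head plane, pointing toward
# the midplane (sign +1 for the lower leaflet, -1 for the upper).
bead_z_offsets <- function(toward_mid) c(0, 5, 10) * toward_mid

#' Build a synthetic bilayer
#'
#' @param spec A [bilayer_spec()].
#' @param seed Integer seed; the build is deterministic given (spec, seed).
#' @return A `bilayer_system`: list with `topology`, `frame`, `membrane`,
#'   plus lattice/species metadata used by the trajectory generators.
#' @export
make_bilayer <- function(spec, seed = 1) {
  lat <- bilayer_lattice(spec)
  if (lat$n_sites < 4) stop("box too small: need >= 4 lipids per leaflet")
  species <- with_seed(substream_seed(seed, "species"), {
    lapply(c(lower = "lower", upper = "upper"), function(lf) {
      en <- spec$enrichment
      if (!is.null(en) && !(en$species %in% names(spec[[lf]]))) en <- NULL
      assign_species(spec, lat, spec[[lf]], en)
    })
  })
  jit <- with_seed(substream_seed(seed, "positions"), {
    list(lower = matrix(stats::rnorm(lat$n_sites * 3 * 3,
                                     sd = rep(c(spec$jitter_xy, spec$jitter_xy,
                                                spec$jitter_z), each = 1)),
                        ncol = 3, byrow = TRUE),
         upper = matrix(stats::rnorm(lat$n_sites * 3 * 3,
                                     sd = rep(c(spec$jitter_xy, spec$jitter_xy,
                                                spec$jitter_z), each = 1)),
                        ncol = 3, byrow = TRUE))
  })
  # generous z so that a protein placed (or scheduled unbound) well below the
  # lower leaflet never approaches the far leaflet through the periodic z
  # boundary
  box <- c(spec$box_xy, spec$leaflet_z[["upper"]] + 100)
  build <- function(lf, toward_mid) {
    sp <- species[[lf]]
    z0 <- spec$leaflet_z[[lf]]
    offs <- bead_z_offsets(toward_mid)
    n <- lat$n_sites
    coords <- matrix(0, n * 3, 3)
    for (b in 1:3) {
      rows <- seq(b, n * 3, by = 3)
      coords[rows, 1] <- lat$sites[, 1]
      coords[rows, 2] <- lat$sites[, 2]
      coords[rows, 3] <- z0 + offs[b]
    }
    coords <- coords + jit[[lf]][seq_len(n * 3), , drop = FALSE]
    list(coords = coords, species = sp)
  }
  lo <- build("lower", +1)
  up <- build("upper", -1)
  n_lip <- 2L * lat$n_sites
  resseq <- rep(seq_len(n_lip), each = 3)
  resname <- rep(c(lo$species, up$species), each = 3)
  top <- bead_topology(bead_name = rep(bilayer_bead_template, n_lip),
                       residue_seq = resseq, residue_name = resname,
                       molecule_id = resseq,
                       role = rep(c("lipid_head", "lipid_acyl", "lipid_acyl"),
                                  n_lip),
                       species = resname)
  frame <- traj_frame(rbind(lo$coords, up$coords), box, 0)
  membrane <- assign_leaflets(frame, top)
  structure(list(topology = top, frame = frame, membrane = membrane,
                 lattice = lat, spec = spec, seed = seed,
                 species_lower = lo$species, species_upper = up$species),
            class = "bilayer_system")
}

# Regenerate the jittered bead coordinates of a bilayer for frame f using
# stream `stream`; species and lattice stay fixed.
jitter_bilayer_frame <- function(bilayer) {
  spec <- bilayer$spec; lat <- bilayer$lattice
  n <- lat$n_sites
  mk <- function(lf, toward_mid) {
    z0 <- spec$leaflet_z[[lf]]
    offs <- bead_z_offsets(toward_mid)
    coords <- matrix(0, n * 3, 3)
    for (b in 1:3) {
      rows <- seq(b, n * 3, by = 3)
      coords[rows, 1] <- lat$sites[, 1]
      coords[rows, 2] <- lat$sites[, 2]
      coords[rows, 3] <- z0 + offs[b]
    }
    coords + cbind(stats::rnorm(n * 3, sd = spec$jitter_xy),
                   stats::rnorm(n * 3, sd = spec$jitter_xy),
                   stats::rnorm(n * 3, sd = spec$jitter_z))
  }
  rbind(mk("lower", +1), mk("upper", -1))
}

#' Multi-frame bilayer trajectory (fixed species, re-jittered positions)
#'
#' @param spec A [bilayer_spec()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param dt Frame spacing (ps).
#' @export
make_bilayer_trajectory <- function(spec, n_frames, seed = 1, dt = 200) {
  bil <- make_bilayer(spec, seed)
  nb <- nrow(bil$topology)
  coords <- array(0, c(nb, 3, n_frames))
  with_seed(substream_seed(seed, "lipid_frames"), {
    for (f in seq_len(n_frames)) coords[, , f] <- jitter_bilayer_frame(bil)
  })
  trajectory(bil$topology, coords, bil$frame$box,
             times = (seq_len(n_frames) - 1) * dt)
}

#' Specification of a scheduled synthetic protein trajectory
#'
#' The protein is one molecule: `n_residues` flexible contact residues
#' (one backbone bead each) followed by a rigid helical domain of
#' `rigid_beads` residues used for orientation analysis. Bound segments
#' pose the rigid domain at scheduled (lat, lon) orientation states with
#' angular jitter and plant per-residue head-group contacts at the target
#' fractions; unbound segments drop the whole protein far below the
#' leaflet.
#'
#' @param n_residues Flexible contact residues (default 8).
#' @param contact_targets Per-residue contact probabilities during bound
#'   frames: a vector (recycled over states) or an n_states x n_residues
#'   matrix. Default: first 6 residues at 1, rest 0.
#' @param states data.frame with columns `lat`, `lon`, `population`
#'   (populations sum to 1). Default: a single state at (45, 60).
#' @param state_dwell Frames per orientation-state block (default 40).
#' @param bound_fraction Planted fraction of bound frames (default 1).
#' @param unbound_dwell Nominal unbound run length in frames (default 25).
#' @param jitter_deg Angular jitter SD about state centres (default 3).
#' @param rigid_beads Rigid-domain residues (default 12).
#' @param rigid_depth Depth of the rigid-domain centre below the lower
#'   head plane (A, default 25).
#' @param diffusion_step Protein xy random-walk step SD (A/frame, default 0).
#' @param contact_z_offset Depth below the contacted head bead (A, default 3).
#' @param start_residue First residue number (author numbering, default 1).
#' @export
protein_schedule_spec <- function(n_residues = 8,
                                  contact_targets = NULL,
                                  states = data.frame(lat = 45, lon = 60,
                                                      population = 1),
                                  state_dwell = 40,
                                  bound_fraction = 1,
                                  unbound_dwell = 25,
                                  jitter_deg = 3,
                                  rigid_beads = 12,
                                  rigid_depth = 25,
                                  diffusion_step = 0,
                                  contact_z_offset = 3,
                                  start_residue = 1L) {
  if (is.null(contact_targets))
    contact_targets <- c(rep(1, min(6, n_residues)),
                         rep(0, max(0, n_residues - 6)))
  if (is.null(dim(contact_targets)))
    contact_targets <- matrix(rep(contact_targets, each = nrow(states)),
                              nrow(states), n_residues)
  if (ncol(contact_targets) != n_residues || nrow(contact_targets) != nrow(states))
    stop("contact_targets must be n_states x n_residues")
  if (any(contact_targets < 0 | contact_targets > 1))
    stop("infeasible planted contact fractions (must be in [0, 1])")
  if (abs(sum(states$population) - 1) > 1e-9)
    stop("state populations must sum to 1")
  if (state_dwell < 1 || unbound_dwell < 1) stop("dwells must be >= 1")
  structure(list(n_residues = n_residues, contact_targets = contact_targets,
                 states = states, state_dwell = state_dwell,
                 bound_fraction = bound_fraction,
                 unbound_dwell = unbound_dwell, jitter_deg = jitter_deg,
                 rigid_beads = rigid_beads, rigid_depth = rigid_depth,
                 diffusion_step = diffusion_step,
                 contact_z_offset = contact_z_offset,
                 start_residue = as.integer(start_residue)),
            class = "protein_schedule_spec")
}

# Rigid reference domain: a coarse helix (radius 6 A, rise 16 A), chosen
# non-planar so principal axes and superposition are well conditioned.
rigid_reference_coords <- function(n_beads) {
  t <- seq_len(n_beads)
  cbind(6 * cos(deg2rad(100 * t)), 6 * sin(deg2rad(100 * t)),
        seq(-8, 8, length.out = n_beads))
}

# Alternating bound/unbound run-length schedule hitting round(f * n) bound
# frames with unbound runs near `unbound_dwell` frames.
bound_schedule <- function(n_frames, f, unbound_dwell) {
  n_b <- round(f * n_frames)
  if (n_b >= n_frames) return(rep(TRUE, n_frames))
  if (n_b <= 0) return(rep(FALSE, n_frames))
  n_u <- n_frames - n_b
  k <- max(1L, round(n_u / unbound_dwell))
  u_lens <- largest_remainder(rep(1 / k, k), n_u)
  b_lens <- largest_remainder(rep(1 / (k + 1), k + 1), n_b)
  out <- logical(0)
  for (i in seq_len(k))
    out <- c(out, rep(TRUE, b_lens[i]), rep(FALSE, u_lens[i]))
  c(out, rep(TRUE, b_lens[k + 1]))
}

#' Generate a scheduled synthetic protein + bilayer trajectory
#'
#' @param bilayer A `bilayer_system` from [make_bilayer()].
#' @param spec A [protein_schedule_spec()].
#' @param n_frames Number of frames.
#' @param seed Integer seed; deterministic given (bilayer, spec, seed).
#' @param dt Frame spacing (ps).
#' @return A [trajectory()] (protein beads first, then lipids) with a
#'   `ground_truth` attribute: planted per-frame `bound`, `state_id`,
#'   `lat`, `lon`, realised contact indicators, the rigid selection and
#'   its [body_frame()].
#' @export
make_protein_trajectory <- function(bilayer, spec, n_frames, seed = 1,
                                    dt = 200) {
  if (nrow(spec$states) < 1) stop("need >= 1 orientation state")
  lat <- bilayer$lattice
  bspec <- bilayer$spec
  n_res <- spec$n_residues
  n_rig <- spec$rigid_beads
  lower_z <- bspec$leaflet_z[["lower"]]
  box <- bilayer$frame$box
  # --- protein topology (one molecule), then lipids --------------------
  prot_res <- seq(spec$start_residue, length.out = n_res + n_rig)
  lip_top <- bilayer$topology
  n_prot <- n_res + n_rig
  top <- bead_topology(
    bead_name = c(rep("BB", n_prot), lip_top$bead_name),
    residue_seq = c(prot_res, lip_top$residue_seq + max(prot_res)),
    residue_name = c(rep("ALA", n_prot), lip_top$residue_name),
    molecule_id = c(rep(1L, n_prot), lip_top$molecule_id + 1L),
    role = c(rep("protein_backbone", n_prot), lip_top$role),
    species = c(rep("PROT", n_prot), lip_top$species))
  rigid_rows <- n_res + seq_len(n_rig)
  rigid_ref <- rigid_reference_coords(n_rig)
  body <- body_frame(rigid_ref)
  A <- body$axes
  nhat <- c(0, 0, -1)          # inward normal: lower leaflet -> protein side
  # --- schedules (protein stream) ---------------------------------------
  bound <- bound_schedule(n_frames, spec$bound_fraction, spec$unbound_dwell)
  nb <- sum(bound)
  ps <- substream_seed(seed, "protein")
  sched <- with_seed(ps, {
    n_blocks <- ceiling(nb / spec$state_dwell)
    blk <- largest_remainder(spec$states$population, n_blocks)
    blk_all <- rep.int(seq_len(nrow(spec$states)), blk)
    blk_states <- blk_all[sample.int(length(blk_all))]
    state_id <- integer(n_frames)
    state_id[bound] <- rep(blk_states, each = spec$state_dwell)[seq_len(nb)]
    jit_ax <- matrix(stats::rnorm(n_frames * 3), n_frames, 3)
    jit_ang <- stats::rnorm(n_frames, sd = spec$jitter_deg)
    walk <- if (spec$diffusion_step > 0)
      apply(matrix(stats::rnorm(n_frames * 2, sd = spec$diffusion_step),
                   n_frames, 2), 2, cumsum)
    else matrix(0, n_frames, 2)
    contacts <- matrix(stats::runif(n_frames * n_res), n_frames, n_res)
    list(state_id = state_id, jit_ax = jit_ax, jit_ang = jit_ang,
         walk = walk, u_contact = contacts)
  })
  state_id <- sched$state_id
  # planted contact indicator: bound frame & u < target[state, residue]
  contact <- matrix(FALSE, n_frames, n_res)
  for (f in which(bound)) {
    tg <- spec$contact_targets[state_id[f], ]
    contact[f, ] <- sched$u_contact[f, ] < tg
  }
  # --- per-frame true orientations --------------------------------------
  true_lat <- true_lon <- rep(NA_real_, n_frames)
  Rlist <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    st <- if (state_id[f] > 0) state_id[f] else 1L
    v0 <- drop(latlon_to_vec(spec$states$lat[st], spec$states$lon[st]))
    Rj <- rot_axis_angle(sched$jit_ax[f, ], sched$jit_ang[f])
    v <- drop(Rj %*% v0)
    ll <- vec_to_latlon(v)
    true_lat[f] <- ll["lat"]; true_lon[f] <- ll["lon"]
    u <- drop(t(A) %*% v)               # lab direction with body components v
    Rlist[[f]] <- rot_between(u, nhat)
  }
  # --- coordinates -------------------------------------------------------
  n_beads <- n_prot + nrow(lip_top)
  coords <- array(0, c(n_beads, 3, n_frames))
  ctr_xy <- box[1:2] / 2
  res_home_x <- ctr_xy[1] + (seq_len(n_res) - (n_res + 1) / 2) * 4
  head_rows_lower <- n_prot + seq(1, 3 * lat$n_sites, by = 3)
  lipid_coords <- with_seed(substream_seed(seed, "lipid_frames"), {
    lapply(seq_len(n_frames), function(f) jitter_bilayer_frame(bilayer))
  })
  site_of_xy <- function(x, y) {
    ix <- (round(x / lat$sx - 0.5) %% lat$nx)
    iy <- (round(y / lat$sy - 0.5) %% lat$ny)
    as.integer(ix + iy * lat$nx + 1L)
  }
  for (f in seq_len(n_frames)) {
    L <- lipid_coords[[f]]
    coords[(n_prot + 1):n_beads, , f] <- L
    dz_unbound <- if (bound[f]) 0 else -40
    offx <- sched$walk[f, 1]; offy <- sched$walk[f, 2]
    # flexible contact residues
    hx <- res_home_x + offx
    hy <- rep(ctr_xy[2] + offy, n_res)
    for (r in seq_len(n_res)) {
      if (bound[f] && contact[f, r]) {
        s <- site_of_xy(hx[r], hy[r])
        head <- L[(s - 1L) * 3L + 1L, ]
        coords[r, , f] <- head + c(0, 0, -spec$contact_z_offset)
      } else {
        coords[r, , f] <- c(hx[r], hy[r], lower_z - 15 + dz_unbound)
      }
    }
    # rigid domain
    ctr <- c(ctr_xy[1] + offx, ctr_xy[2] + offy,
             lower_z - spec$rigid_depth + dz_unbound)
    coords[rigid_rows, , f] <- sweep(rigid_ref %*% t(Rlist[[f]]), 2, ctr, "+")
  }
  traj <- trajectory(top, coords, box, times = (seq_len(n_frames) - 1) * dt)
  attr(traj, "ground_truth") <- list(
    bound = bound, state_id = state_id, lat = true_lat, lon = true_lon,
    contact = contact, contact_targets = spec$contact_targets,
    states = spec$states,
    rigid_sel = top$bead_index[rigid_rows], body = body,
    flexible_residues = prot_res[seq_len(n_res)])
  traj
}

#' Specification of a synthetic NMR titration
#'
#' Intensity ratios follow `I/I0(r) = 1 - slope_j * fraction(r) + eps` with
#' Gaussian `eps`; at the final titration point the noise SD is solved so
#' that the expected sample Pearson correlation between `I/I0` and the
#' contact fraction equals `target_r` (negative for positive slope).
#' Intermediate points scale the slope by their ligand ratio. Residues
#' whose ratio falls below `vanish_threshold` are marked unobserved.
#'
#' @param target_r Target Pearson correlation (|r| <= 1); `NULL` to use
#'   `noise_sd` directly.
#' @param slope Signal-loss slope at the final point (default 0.5).
#' @param noise_sd Noise SD; solved from `target_r` when `NULL`.
#' @param vanish_threshold Ratio below which a peak disappears (default 0.05).
#' @param ratios Ligand molar-excess schedule (default 0, 5, 10, 25).
#' @param seed Integer seed.
#' @export
nmr_spec <- function(target_r = -0.55, slope = 0.5, noise_sd = NULL,
                     vanish_threshold = 0.05, ratios = c(0, 5, 10, 25),
                     seed = 1) {
  if (!is.null(target_r) && abs(target_r) > 1) stop("|target_r| must be <= 1")
  if (!is.null(target_r) && slope == 0 && abs(target_r) > 0)
    stop("target correlation unreachable with slope 0")
  structure(list(target_r = target_r, slope = slope, noise_sd = noise_sd,
                 vanish_threshold = vanish_threshold, ratios = ratios,
                 seed = seed),
            class = "nmr_spec")
}

#' Generate a synthetic NMR titration correlated with a contact profile
#'
#' @param contacts A `contact_profile` (first species column is used) or a
#'   numeric per-residue contact-fraction vector.
#' @param spec An [nmr_spec()].
#' @return A [titration_series()]; ground truth (fractions, noise SD,
#'   slope) in the `ground_truth` attribute.
#' @export
make_nmr_titration <- function(contacts, spec) {
  if (inherits(contacts, "contact_profile")) {
    f <- contacts$fraction[, 1]
    res <- contacts$residue_seq
  } else {
    f <- as.numeric(contacts)
    res <- seq_along(f)
  }
  n <- length(f)
  sdf <- stats::sd(f)
  slope <- spec$slope
  if (!is.null(spec$target_r)) {
    if (sdf == 0) stop("contact profile has zero variance; correlation undefined")
    if (spec$target_r > 0) slope <- -abs(slope)
    r <- abs(spec$target_r)
    noise_sd <- if (r >= 1) 0 else abs(slope) * sdf * sqrt(1 / r^2 - 1)
  } else noise_sd <- spec$noise_sd %||% 0
  I0 <- 100
  H0 <- 8 + 0.3 * sin(0.31 * res)
  N0 <- 118 + 4 * sin(0.17 * res)
  tabs <- list(peak_table(res, H0, N0, rep(I0, n)))
  eps <- with_seed(substream_seed(spec$seed, "nmr_noise"), {
    matrix(stats::rnorm(n * (length(spec$ratios) - 1), sd = noise_sd),
           n, length(spec$ratios) - 1)
  })
  rmax <- max(spec$ratios)
  for (k in seq_along(spec$ratios)[-1]) {
    sj <- slope * spec$ratios[k] / rmax
    ratio <- 1 - sj * f + eps[, k - 1]
    obs <- ratio >= spec$vanish_threshold
    tabs[[k]] <- peak_table(res,
                            ifelse(obs, H0 + 0.02 * sj * f, NA),
                            ifelse(obs, N0 + 0.10 * sj * f, NA),
                            ifelse(obs, pmax(ratio, 0) * I0, NA),
                            observed = obs)
  }
  out <- titration_series(spec$ratios, tabs)
  attr(out, "ground_truth") <- list(fraction = f, slope = slope,
                                    noise_sd = noise_sd,
                                    target_r = spec$target_r)
  out
}

#' Generate a synthetic exponential relaxation decay
#'
#' `I(t) = I0 * exp(-R2 * t) * (1 + eps)` per replicate with Gaussian
#' multiplicative noise.
#'
#' @param R2_true True rate (s-1), >= 0.
#' @param delays Delay schedule (s); default [default_r2_delays()].
#' @param noise_sd Multiplicative noise SD (e.g. 0.02 for 2%).
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed.
#' @param I0 Intensity at zero delay.
#' @return A [decay_curve()].
#' @export
make_decay <- function(R2_true, delays = default_r2_delays(), noise_sd = 0,
                       replicates = 3, seed = 1, I0 = 100) {
  if (R2_true < 0) stop("R2_true must be >= 0")
  if (noise_sd < 0) stop("negative noise")
  base <- I0 * exp(-R2_true * delays)
  I <- with_seed(substream_seed(seed, "decay_noise"), {
    matrix(base, length(delays), replicates) *
      (1 + matrix(stats::rnorm(length(delays) * replicates, sd = noise_sd),
                  length(delays), replicates))
  })
  decay_curve(delays, I)
}
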