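# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately use scalar loops and their own arithmetic so they
# stay independent of the vectorised implementation paths.

# 27-image periodic distance oracle (points assumed inside the box).
dist_oracle_27 <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# Random test system: n_res single-bead protein residues plus n_lip 3-bead
# lipids (head + 2 acyl) at uniform random positions in the box.
rand_system <- function(n_res, n_lip, n_frames, box = c(30, 30, 30),
                        seed = 1, species = c("POPC", "PIP2")) {
  set.seed(seed)
  sp <- rep(species, length.out = n_lip)
  top <- bead_topology(
    bead_name = c(rep("BB", n_res), rep(c("PO4", "C1A", "C2A"), n_lip)),
    residue_seq = c(seq_len(n_res), rep(n_res + seq_len(n_lip), each = 3)),
    residue_name = c(rep("ALA", n_res), rep(sp, each = 3)),
    molecule_id = c(rep(1L, n_res), rep(1L + seq_len(n_lip), each = 3)),
    role = c(rep("protein_backbone", n_res),
             rep(c("lipid_head", "lipid_acyl", "lipid_acyl"), n_lip)),
    species = c(rep("PROT", n_res), rep(sp, each = 3)))
  nb <- nrow(top)
  coords <- array(runif(nb * 3 * n_frames, 0, min(box)), c(nb, 3, n_frames))
  trajectory(top, coords, box, times = seq_len(n_frames) - 1)
}

# Brute-force contact-fraction oracle: all frames x residues x lipid beads
# with scalar minimum-image distances.
contact_oracle <- function(traj, part, cutoff, species = NULL,
                           frames = NULL) {
  top <- traj$topology
  roles <- switch(part, head = "lipid_head", acyl = "lipid_acyl",
                  any = c("lipid_head", "lipid_acyl", "lipid_linker"))
  lsel <- which(top$role %in% roles)
  if (!is.null(species)) lsel <- lsel[top$species[lsel] %in% species]
  pres <- unique(top$residue_seq[top$role == "protein_backbone"])
  sps <- sort(unique(top$species[lsel]))
  frames <- frames %||% seq_len(n_frames(traj))
  frac <- matrix(0, length(pres), length(sps), dimnames = list(pres, sps))
  for (f in frames) {
    box <- traj$box[f, ]
    for (ri in seq_along(pres)) {
      pidx <- which(top$role == "protein_backbone" &
                    top$residue_seq == pres[ri])
      for (si in seq_along(sps)) {
        hit <- FALSE
        for (p in pidx) for (l in lsel[top$species[lsel] == sps[si]]) {
          if (min_image_distance(traj$coords[p, , f], traj$coords[l, , f],
                                 box) <= cutoff) { hit <- TRUE; break }
        }
        if (hit) frac[ri, si] <- frac[ri, si] + 1
      }
    }
  }
  frac / length(frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random rotation matrix from a random unit quaternion.
rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Expected (lat, lon) for a frame built as ref %*% t(R), computed from the
# known rotation matrix (never via the superposition code under test).
latlon_oracle <- function(R, axes, nhat = c(0, 0, -1)) {
  v <- drop(t(R) %*% nhat)
  comp <- unname(drop(axes %*% v))
  lat <- 90 - acos(max(-1, min(1, comp[3]))) * 180 / pi
  lon <- atan2(comp[2], comp[1]) * 180 / pi
  if (lon <= -180) lon <- lon + 360
  c(lat = lat, lon = lon)
}

# Wrap a longitude difference into (-180, 180].
lon_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}

# Rigid reference cloud plus a trajectory whose frames are known rotations
# of it, for orientation-angle oracle tests.
make_rot_traj <- function(rotations, box = c(100, 100, 100)) {
  ref <- memtraj:::rigid_reference_coords(10)
  n <- length(rotations)
  top <- bead_topology(rep("BB", 12), c(1:10, 11L, 11L),
                       rep("ALA", 12), rep(1L, 12),
                       rep("protein_backbone", 12), rep("PROT", 12))
  full_ref <- rbind(ref, c(0, 0, 12), c(0, 0, 14))
  co <- array(0, c(12, 3, n))
  ctr <- c(50, 50, 20)
  for (f in seq_len(n))
    co[, , f] <- sweep(full_ref %*% t(rotations[[f]]), 2, ctr, "+")
  list(traj = trajectory(top, co, box), ref = ref, rigid_sel = 0:9)
}

fake_membrane <- function(midplane = 60)
  structure(list(midplane_z = midplane,
                 leaflet = c(`1` = "lower", `2` = "upper"),
                 normal = c(0, 0, 1)), class = "membrane_model")

# Small bound protein system used by several modules.
small_bound_system <- function(n_frames = 200, seed = 7, bound_fraction = 1,
                               states = data.frame(lat = 45, lon = 60,
                                                   population = 1),
                               box_xy = c(64, 64), ...) {
  bil <- make_bilayer(bilayer_spec(box_xy = box_xy), seed = seed)
  spec <- protein_schedule_spec(bound_fraction = bound_fraction,
                                states = states, ...)
  traj <- make_protein_trajectory(bil, spec, n_frames, seed = seed + 1)
  list(bilayer = bil, traj = traj, gt = attr(traj, "ground_truth"))
}
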