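# Contact fractions, residue-residue distance maps, bound-state detection.

# one protein residue and one lipid at a controlled distance
fixed_pair_traj <- function(d, n_frames = 5, box = c(50, 50, 50)) {
  top <- bead_topology(c("BB", "PO4", "C1A", "C2A"), c(1L, 2L, 2L, 2L),
                       c("ALA", "POPC", "POPC", "POPC"), c(1L, 2L, 2L, 2L),
                       c("protein_backbone", "lipid_head", "lipid_acyl",
                         "lipid_acyl"), c("PROT", "POPC", "POPC", "POPC"))
  co <- rbind(c(10, 10, 10), c(10 + d, 10, 10), c(10 + d, 10, 15),
              c(10 + d, 10, 20))
  trajectory(top, array(rep(co, n_frames), c(4, 3, n_frames)), box)
}

test_that("contact cutoff is inclusive at exactly 7 A", {
  at7 <- residue_lipid_contact_fractions(fixed_pair_traj(7.0), part = "head")
  expect_equal(unname(at7$fraction[1, "POPC"]), 1.0)
  at75 <- residue_lipid_contact_fractions(fixed_pair_traj(7.5), part = "head")
  expect_equal(unname(at75$fraction[1, "POPC"]), 0.0)
})

test_that("contact fractions match the brute-force all-pairs oracle", {
  traj <- rand_system(5, 6, 50, box = c(18, 18, 18), seed = 21)
  for (part in c("head", "acyl", "any")) {
    got <- residue_lipid_contact_fractions(traj, part = part, cutoff = 7)
    expect_equal(got$fraction, contact_oracle(traj, part, 7),
                 tolerance = 1e-12)
  }
})

test_that("contact fractions are invariant to rigid motion and frame order", {
  traj <- rand_system(4, 5, 20, box = c(16, 16, 16), seed = 8)
  base <- residue_lipid_contact_fractions(traj, part = "head")
  # rotate protein + membrane together about the box centre each frame; the
  # same rotation applied to everything preserves all pairwise distances
  # only if the box is symmetric under it: use a 90-degree z rotation
  Rz <- memtraj:::rot_z(90)
  rot <- traj
  for (f in seq_len(n_frames(traj))) {
    X <- sweep(traj$coords[, , f], 2, c(8, 8, 8))
    rot$coords[, , f] <- sweep(X %*% t(Rz), 2, c(8, 8, 8), "+")
  }
  expect_equal(residue_lipid_contact_fractions(rot, part = "head")$fraction,
               base$fraction, tolerance = 1e-12)
  shuf <- traj
  perm <- sample(n_frames(traj))
  shuf$coords <- traj$coords[, , perm, drop = FALSE]
  expect_equal(residue_lipid_contact_fractions(shuf, part = "head")$fraction,
               base$fraction, tolerance = 1e-12)
})

test_that("'any' fractions equal the per-frame union of head and acyl events", {
  traj <- rand_system(4, 6, 40, box = c(15, 15, 15), seed = 31)
  any_got <- residue_lipid_contact_fractions(traj, part = "any")$fraction
  # union oracle on the same trajectory
  top <- traj$topology
  pres <- unique(top$residue_seq[top$role == "protein_backbone"])
  sps <- sort(unique(top$species[startsWith(top$role, "lipid")]))
  union_frac <- matrix(0, length(pres), length(sps),
                       dimnames = list(pres, sps))
  for (f in seq_len(n_frames(traj))) {
    h <- contact_oracle(traj, "head", 7, frames = f)
    a <- contact_oracle(traj, "acyl", 7, frames = f)
    union_frac <- union_frac + ((h > 0) | (a > 0))
  }
  expect_equal(any_got, union_frac / n_frames(traj), tolerance = 1e-12)
  head_got <- residue_lipid_contact_fractions(traj, part = "head")$fraction
  acyl_got <- residue_lipid_contact_fractions(traj, part = "acyl")$fraction
  expect_true(all(any_got >= pmax(head_got, acyl_got) - 1e-12))
})

test_that("residue-residue distance maps average per-frame minima (inclusive masks)", {
  top <- bead_topology(rep("BB", 2), 1:2, rep("ALA", 2), rep(1L, 2),
                       rep("protein_backbone", 2), rep("PROT", 2))
  mk <- function(dists) {
    co <- array(0, c(2, 3, length(dists)))
    for (f in seq_along(dists)) co[, , f] <- rbind(c(5, 5, 5),
                                                   c(5 + dists[f], 5, 5))
    trajectory(top, co, c(40, 40, 40))
  }
  m1 <- residue_residue_distance_map(mk(rep(3, 4)), 0, 1)
  expect_equal(unname(m1$avg[1, 1]), 3.0)
  expect_true(m1$close[1, 1]); expect_false(m1$no_contact[1, 1])
  m2 <- residue_residue_distance_map(mk(rep(c(2, 10), 5)), 0, 1)
  expect_equal(unname(m2$avg[1, 1]), 6.0)
  expect_true(m2$no_contact[1, 1]); expect_false(m2$close[1, 1])
  expect_error(residue_residue_distance_map(mk(3), 0:1, 1), "overlap")
})

test_that("distance maps match a brute-force oracle on a random toy", {
  traj <- rand_system(8, 0, 6, box = c(20, 20, 20), seed = 13)
  top <- traj$topology
  sel_a <- top$bead_index[top$residue_seq %in% 1:4]
  sel_b <- top$bead_index[top$residue_seq %in% 5:8]
  got <- residue_residue_distance_map(traj, sel_a, sel_b)
  for (a in 1:4) for (b in 5:8) {
    vals <- numeric(0)
    for (f in seq_len(n_frames(traj))) {
      ia <- which(top$residue_seq == a); ib <- which(top$residue_seq == b)
      dmin <- Inf
      for (i in ia) for (j in ib)
        dmin <- min(dmin, dist_oracle_27(traj$coords[i, , f],
                                         traj$coords[j, , f], traj$box[f, ]))
      vals <- c(vals, dmin)
    }
    expect_lt(abs(got$avg[as.character(a), as.character(b)] - mean(vals)), 1e-9)
  }
})

test_that("bound-state detection debounces short excursions", {
  sys <- small_bound_system(n_frames = 60, seed = 17)
  bs <- detect_bound_frames(sys$traj)
  expect_true(all(bs$bound))
  # a single-frame raw spike never enters the bound state at dwell 5
  expect_equal(memtraj:::debounce_series(c(rep(FALSE, 10), TRUE,
                                           rep(FALSE, 10)), 5),
               rep(FALSE, 21))
  # short unbound gaps inside a long bound stretch are absorbed
  raw <- c(rep(TRUE, 10), FALSE, FALSE, rep(TRUE, 10))
  expect_equal(memtraj:::debounce_series(raw, 5), rep(TRUE, 22))
  expect_error(detect_bound_frames(sys$traj, dwell_frames = 0), "dwell")
})

test_that("planted 97% bound schedules are recovered within 0.01", {
  sys <- small_bound_system(n_frames = 1500, seed = 23, bound_fraction = 0.97)
  bs <- detect_bound_frames(sys$traj)
  st <- bound_statistics(bs)
  expect_equal(st$bound_fraction, 0.97, tolerance = 0.01)
  expect_equal(bs$bound, sys$gt$bound)
})

test_that("bound statistics count events and first binding time", {
  expect_equal(bound_statistics(rep(FALSE, 10)),
               list(bound_fraction = 0, first_binding_time = NA_real_,
                    n_binding_events = 0L))
  pat <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  st <- bound_statistics(pat, times = 0:9)
  expect_equal(st$bound_fraction, 0.6)
  expect_equal(st$n_binding_events, 2L)
  expect_equal(st$first_binding_time, 2)
})

test_that("an ensemble with three planted binders yields exactly three bound replicas", {
  planted <- c(1, 0, 0, 1, 0, 1, 0, 0)  # 3 binders of 8 replicas
  got <- vapply(seq_along(planted), function(i) {
    sys <- small_bound_system(n_frames = 80, seed = 100 + i,
                              bound_fraction = planted[i] * 0.9)
    bound_statistics(detect_bound_frames(sys$traj))$bound_fraction
  }, 1)
  expect_equal(sum(got > 0), 3)
  expect_true(all(got[planted == 0] == 0))
})
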