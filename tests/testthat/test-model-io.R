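# Structure/trajectory I/O, periodic geometry, leaflet assignment, elastic
# networks, and start-orientation generation.

toy_gro_lines <- function() {
  # 3 lipids x 5 beads (NC3, PO4, GL1, C1A, C2A), nm coordinates
  atoms <- character(0)
  n <- 0L
  for (l in 1:3) for (b in c("NC3", "PO4", "GL1", "C1A", "C2A")) {
    n <- n + 1L
    atoms <- c(atoms, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              l, "POPC", b, n, l * 1.0, 1.0, 2.0 - n * 0.05))
  }
  c("toy bilayer t= 0.000", sprintf("%5d", n), atoms,
    "  10.00000  10.00000  10.00000")
}

test_that("GRO reading resolves bead roles (role table wins) and is deterministic", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(toy_gro_lines(), path)
  tab <- c(NC3 = "lipid_linker", PO4 = "lipid_head", GL1 = "lipid_linker",
           C1A = "lipid_acyl", C2A = "lipid_acyl")
  st <- read_structure(path, role_table = tab)
  per_lipid <- table(st$topology$molecule_id, st$topology$role)
  expect_true(all(per_lipid[, "lipid_head"] == 1))
  expect_true(all(per_lipid[, "lipid_acyl"] >= 1))
  st2 <- read_structure(path, role_table = tab)
  expect_identical(st$topology, st2$topology)
  expect_identical(st$frame$coords, st2$frame$coords)
  # unresolvable bead names are reported by name
  bad <- sub("C2A", "XXX", readLines(path))
  path2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(bad, path2)
  expect_error(read_structure(path2), "XXX")
})

test_that("author residue numbering is preserved (disordered-tail chain 235-300)", {
  path <- withr::local_tempfile(fileext = ".gro")
  res <- 235:300
  atoms <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", res, "ALA", "BB",
                   seq_along(res), seq_along(res) * 0.4, 1, 1)
  writeLines(c("chain", sprintf("%5d", length(res)), atoms,
               "  30.00000  30.00000  30.00000"), path)
  st <- read_structure(path)
  expect_equal(sum(st$topology$role == "protein_backbone"), 66)
  expect_equal(st$topology$residue_seq, res)
  expect_equal(length(unique(st$topology$molecule_id)), 1)
})

test_that("coarse-grained PDB files read through the bio3d-backed path", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       1:5, c("BB", "BB", "PO4", "C1A", "C2A"),
                       c("ALA", "GLY", "POP", "POP", "POP"), "A",
                       c(235L, 236L, 300L, 300L, 300L),
                       c(1, 4, 10, 10, 10), c(0, 0, 5, 5, 5),
                       c(0, 0, 20, 25, 30)), "END"), path)
  st <- read_structure(path)
  expect_equal(st$topology$residue_seq, c(235L, 236L, 300L, 300L, 300L))
  expect_equal(st$topology$role,
               c("protein_backbone", "protein_backbone", "lipid_head",
                 "lipid_acyl", "lipid_acyl"))
  expect_equal(st$topology$species, c("PROT", "PROT", "POP", "POP", "POP"))
  expect_equal(st$frame$coords[3, ], c(10, 5, 20))
})

test_that("trajectory writers and readers round-trip within format precision", {
  sys <- small_bound_system(n_frames = 10, seed = 3)
  traj <- sys$traj
  for (fmt in c("gro", "dcd")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trajectory(traj, path)
    back <- read_trajectory(path, traj$topology)
    tol <- if (fmt == "gro") 0.0051 else 1e-4  # 0.001 nm / float32
    expect_equal(n_frames(back), 10)
    expect_lt(max(abs(back$coords - traj$coords)), tol)
    expect_lt(max(abs(back$box - traj$box)), tol)
    strided <- read_trajectory(path, traj$topology, stride = 2)
    expect_equal(n_frames(strided), 5)
    expect_equal(strided$coords[, , 2], back$coords[, , 3], tolerance = 1e-12)
  }
  # streaming callback yields frames in order without materialising
  seen <- numeric(0)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(traj, path)
  read_trajectory(path, traj$topology,
                  callback = function(fr) seen <<- c(seen, fr$coords[1, 1]))
  expect_equal(seen, traj$coords[1, 1, ], tolerance = 1e-4)
  # bead-count mismatch names expected and found counts
  small_top <- traj$topology[1:10, ]
  class(small_top) <- c("bead_topology", "data.frame")
  expect_error(read_trajectory(path, small_top), "expected 10")
})

test_that("DCD output agrees with the independent bio3d reader", {
  sys <- small_bound_system(n_frames = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(sys$traj, path)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  for (f in 1:4)
    expect_lt(max(abs(matrix(xyz[f, ], ncol = 3, byrow = TRUE) -
                      sys$traj$coords[, , f])), 1e-4)
})

test_that("minimum-image distance matches the 27-image oracle and is metric", {
  expect_equal(min_image_distance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10)), 1.0)
  expect_equal(min_image_distance(c(2, 3, 4), c(2, 3, 4), c(10, 10, 10)), 0)
  set.seed(11)
  for (i in 1:1000) {
    box <- runif(3, 5, 40)
    a <- runif(3) * box; b <- runif(3) * box
    d <- min_image_distance(a, b, box)
    expect_lt(abs(d - dist_oracle_27(a, b, box)), 1e-9)
    expect_equal(d, min_image_distance(b, a, box))
  }
  expect_error(min_image_distance(c(0, 0, 0), c(1, 1, 1), c(10, -1, 10)),
               "positive")
})

test_that("leaflet assignment recovers a planted bilayer and its composition", {
  bil <- make_bilayer(bilayer_spec(box_xy = c(80, 80),
                                   lower = c(POPC = 0.8, POPS = 0.1, PIP2 = 0.1)),
                      seed = 2)
  m <- assign_leaflets(bil$frame, bil$topology)
  expect_equal(unname(m$leaflet[as.character(1:100)]), rep("lower", 100))
  expect_equal(unname(m$leaflet[as.character(101:200)]), rep("upper", 100))
  expect_gt(m$midplane_z, 20); expect_lt(m$midplane_z, 58)
  # 80:10:10 composition is exact (largest-remainder rounding)
  lower_species <- bil$topology$species[bil$topology$role == "lipid_head" &
                                        bil$topology$molecule_id <= 100]
  expect_equal(as.vector(table(lower_species)[c("POPC", "POPS", "PIP2")]),
               c(80, 10, 10))
  # one-leaflet input is rejected
  lower_only <- bil$topology[bil$topology$molecule_id <= 100, ]
  class(lower_only) <- c("bead_topology", "data.frame")
  fr <- traj_frame(bil$frame$coords[seq_len(nrow(lower_only)), ],
                   bil$frame$box)
  expect_error(assign_leaflets(fr, lower_only), "no bilayer")
})

test_that("elastic network matches an O(N^2) oracle and is rigid-motion invariant", {
  # collinear 3 beads spaced 4 A: only pair (0, 2) at 8 A
  top <- bead_topology(rep("BB", 3), 1:3, rep("ALA", 3), rep(1L, 3),
                       rep("protein_backbone", 3), rep("PROT", 3))
  fr <- traj_frame(cbind(c(0, 4, 8), 0, 0), c(50, 50, 50))
  eb <- build_elastic_bonds(fr, top)
  expect_equal(nrow(eb), 1)
  expect_equal(c(eb$i, eb$j, eb$r0), c(0, 2, 8))
  # all pairs beyond the upper cutoff: empty set
  fr2 <- traj_frame(cbind(c(0, 20, 40), 0, 0), c(200, 200, 200))
  expect_equal(nrow(build_elastic_bonds(fr2, top)), 0)
  # 20-bead random coil vs brute-force scan
  set.seed(5)
  n <- 20
  X <- apply(matrix(rnorm(n * 3, sd = 2), n, 3), 2, cumsum)
  top20 <- bead_topology(rep("BB", n), 1:n, rep("ALA", n), rep(1L, n),
                         rep("protein_backbone", n), rep("PROT", n))
  fr20 <- traj_frame(X, c(500, 500, 500))
  eb20 <- build_elastic_bonds(fr20, top20)
  expected <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i < 2) next
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (d >= 5 && d <= 9)
      expected <- rbind(expected, c(i - 1, j - 1, d))
  }
  expect_equal(as.matrix(eb20[, c("i", "j", "r0")]),
               expected, ignore_attr = TRUE, tolerance = 1e-12)
  # invariance to rigid rotation + translation of the reference
  R <- rand_rotation()
  frR <- traj_frame(sweep(X %*% t(R), 2, c(30, -12, 7), "+"), c(500, 500, 500))
  ebR <- build_elastic_bonds(frR, top20)
  expect_equal(ebR$i, eb20$i); expect_equal(ebR$j, eb20$j)
  expect_equal(ebR$r0, eb20$r0, tolerance = 1e-9)
  # text export carries 1-based indices and nm lengths
  path <- withr::local_tempfile(fileext = ".txt")
  write_elastic_bonds(eb20, path)
  tab <- read.table(path, comment.char = ";")
  expect_equal(tab$V1, eb20$i + 1)
  expect_equal(tab$V3, eb20$r0 / 10, tolerance = 1e-5)
})

test_that("start orientations step alternately about x and y and sit at the offset", {
  sys <- small_bound_system(n_frames = 2, seed = 4)
  bil <- sys$bilayer
  top <- sys$traj$topology[sys$traj$topology$role == "protein_backbone", ]
  class(top) <- c("bead_topology", "data.frame")
  fr <- traj_frame(sys$traj$coords[top$bead_index + 1, , 1], sys$traj$box[1, ])
  lower_heads <- bil$frame$coords[bil$topology$role == "lipid_head" &
                                  bil$frame$coords[, 3] < 40, 3]
  check_gap <- function(frames, offset) {
    vapply(frames, function(f) min(lower_heads) - max(f$coords[, 3]), 1)
  }
  o4 <- generate_start_orientations(fr, top, bil, n = 4, offset = 7)
  expect_equal(check_gap(o4), rep(7, 4), tolerance = 1e-6)
  # n = 4: angles 0, 90, 180, 270 about x, y, x, y respectively
  ctr <- colMeans(fr$coords)
  Xc <- sweep(fr$coords, 2, ctr)
  expect_rot <- function(frame, R) {
    Y <- frame$coords
    Yc <- sweep(Y, 2, colMeans(Y))
    expect_equal(Yc, Xc %*% t(R), tolerance = 1e-9, ignore_attr = TRUE)
  }
  rot_x <- memtraj:::rot_x; rot_y <- memtraj:::rot_y
  expect_rot(o4[[1]], diag(3))
  expect_rot(o4[[2]], rot_y(90))
  expect_rot(o4[[3]], rot_x(180))
  expect_rot(o4[[4]], rot_y(270))
  # n = 16: sixteen pairwise distinct rotations
  o16 <- generate_start_orientations(fr, top, bil, n = 16, offset = 7)
  sigs <- vapply(o16, function(f) {
    Yc <- sweep(f$coords, 2, colMeans(f$coords))
    paste(round(Yc[1:2, ], 6), collapse = ",")
  }, "")
  expect_equal(length(unique(sigs)), 16)
  expect_equal(check_gap(o16), rep(7, 16), tolerance = 1e-6)
  expect_error(generate_start_orientations(fr, top, bil, n = 0), "n must")
  expect_error(generate_start_orientations(fr, top, bil, offset = -1),
               "offset")
})
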