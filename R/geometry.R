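# Periodic geometry: minimum-image distances, rotations, least-squares
# superposition. All lengths in Angstrom; boxes orthorhombic.

check_box <- function(box) {
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths (A); triclinic boxes are not supported")
  invisible(as.numeric(box))
}

#' Minimum-image distance between two points
#'
#' Euclidean distance between `a` and `b` under the minimum-image convention
#' in an orthorhombic box, applied per axis independently.
#'
#' @param a,b Numeric length-3 coordinates (A).
#' @param box Numeric length-3 orthorhombic box edges (A), all positive.
#' @return Scalar distance in A.
#' @export
min_image_distance <- function(a, b, box) {
  if (length(a) != 3 || length(b) != 3) stop("points must be length-3 coordinates")
  box <- check_box(box)
  d <- as.numeric(a) - as.numeric(b)
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# All-pairs minimum-image distance matrix between rows of A (n x 3) and
# rows of B (m x 3). Vectorised; the workhorse behind every cutoff rule.
pdist_mi <- function(A, B, box) {
  box <- check_box(box)
  dx <- outer(A[, 1], B[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(A[, 2], B[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(A[, 3], B[, 3], "-"); dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Extract the coordinates of beads `idx` at frame `f` as a matrix even for
# a single bead (3D-array slicing would otherwise drop dimensions).
slice_coords <- function(coords, idx, f) {
  m <- coords[idx, , f, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

# Wrap coordinates into [0, box) per axis.
wrap_coords <- function(X, box) {
  for (k in 1:3) X[, k] <- X[, k] - floor(X[, k] / box[k]) * box[k]
  X
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
rot_y <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
rot_z <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation by `deg` about unit axis `u`.
rot_axis_angle <- function(u, deg) {
  u <- u / sqrt(sum(u^2))
  t <- deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# Minimal rotation mapping unit vector a onto unit vector b.
rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate 180 deg about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3], a[1] * p[2] - a[2] * p[1])
    return(rot_axis_angle(ax, 180))
  }
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + (K %*% K) / (1 + c_)
}

# Least-squares (Kabsch) rotation R such that, after centering both sets,
# Q ~= P %*% t(R); i.e. R maps reference P onto frame Q as column vectors.
# Errors on degenerate (collinear) point sets where R is underdetermined.
kabsch_rotation <- function(P, Q, check_degenerate = TRUE) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- t(Pc) %*% Qc
  s <- svd(H)
  if (check_degenerate && s$d[2] < 1e-8 * max(s$d[1], 1e-300))
    stop("degenerate selection: points are (near-)collinear, rotation underdetermined")
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# Superpose frame coords X onto reference `ref` using the subset `idx` for
# the fit; the returned coordinates have the fit applied to all rows.
superpose_onto <- function(X, ref, idx) {
  R <- kabsch_rotation(X[idx, , drop = FALSE], ref[idx, , drop = FALSE])
  cx <- colMeans(X[idx, , drop = FALSE])
  cr <- colMeans(ref[idx, , drop = FALSE])
  sweep(sweep(X, 2, cx) %*% t(R), 2, cr, "+")
}

# Great-circle angle (deg) between two (lat, lon) directions in degrees.
great_circle_deg <- function(lat1, lon1, lat2, lon2) {
  v1 <- latlon_to_vec(lat1, lon1)
  v2 <- latlon_to_vec(lat2, lon2)
  rad2deg(acos(pmin(1, pmax(-1, v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2] + v1[, 3] * v2[, 3]))))
}

latlon_to_vec <- function(lat, lon) {
  la <- deg2rad(lat); lo <- deg2rad(lon)
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

vec_to_latlon <- function(v) {
  lat <- rad2deg(asin(pmin(1, pmax(-1, v[3]))))
  lon <- rad2deg(atan2(v[2], v[1]))
  if (lon <= -180) lon <- lon + 360
  c(lat = lat, lon = lon)
}
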