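# Geographic (latitude/longitude) orientation analysis of a rigid domain
# relative to the membrane: per-frame angles, population histograms over
# the orientation sphere, state extraction, and representative frames.
#
# The membrane normal pointing from the lower leaflet toward the protein
# (intracellular) side is expressed in a body-fixed frame of the rigid
# domain: with R the least-squares rotation taking the reference rigid
# coordinates onto the frame, v = t(R) %*% n_hat, and
#   latitude  = 90 - acos(v . z_body)   in [-90, 90]
#   longitude = atan2(v . y_body, v . x_body) in (-180, 180].

#' Body-fixed axes of a rigid selection
#'
#' Default axes are the principal axes of the reference coordinates
#' (descending variance), made deterministic by fixing the sign of the
#' first two axes toward the hemisphere of the highest-index bead and
#' completing a right-handed triad with the cross product.
#'
#' @param ref_coords n x 3 reference coordinates (A) of the rigid selection.
#' @param axes Optional user-supplied 3 x 3 matrix of row-wise axes
#'   (overrides the principal-axes default; must be orthonormal).
#' @return A `body_frame`: list with centred `ref` coordinates and `axes`
#'   (rows x_body, y_body, z_body).
#' @export
body_frame <- function(ref_coords, axes = NULL) {
  ref_coords <- as.matrix(ref_coords)
  if (nrow(ref_coords) < 3) stop("rigid selection needs >= 3 beads")
  ctr <- colMeans(ref_coords)
  Xc <- sweep(ref_coords, 2, ctr)
  user_axes <- !is.null(axes)
  if (is.null(axes)) {
    ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
    if (ev$values[2] < 1e-8 * max(ev$values[1], 1e-300))
      stop("degenerate rigid selection: (near-)collinear reference coordinates")
    v_hi <- Xc[nrow(Xc), ]
    fix_sign <- function(a) {
      d <- sum(a * v_hi)
      if (abs(d) > 1e-8) a * sign(d)
      else { j <- which.max(abs(a)); a * sign(a[j]) }
    }
    a1 <- fix_sign(ev$vectors[, 1])
    a2 <- fix_sign(ev$vectors[, 2])
    a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
            a1[3] * a2[1] - a1[1] * a2[3],
            a1[1] * a2[2] - a1[2] * a2[1])
    axes <- rbind(a1, a2, a3)
  } else {
    axes <- as.matrix(axes)
    if (max(abs(axes %*% t(axes) - diag(3))) > 1e-6)
      stop("user-supplied axes must be orthonormal")
  }
  dimnames(axes) <- list(c("x_body", "y_body", "z_body"), NULL)
  structure(list(ref = Xc, center = ctr, axes = axes,
                 mode = if (user_axes) "user-supplied" else "principal-axes"),
            class = "body_frame")
}

#' Per-frame orientation (latitude, longitude) of a rigid domain
#'
#' @param traj A [trajectory()].
#' @param rigid_sel 0-based bead indices of the rigid selection; must match
#'   the body frame's reference bead-for-bead.
#' @param body A [body_frame()] built on the same selection.
#' @param membrane A `membrane_model` (for the normal convention).
#' @param bound Optional `bound_series` (or logical vector); defaults to
#'   all frames bound.
#' @return An `orientation_series` data.frame `(time, lat, lon, bound)`.
#' @export
orientation_series <- function(traj, rigid_sel, body, membrane, bound = NULL) {
  top <- traj$topology
  idx <- match(rigid_sel, top$bead_index)
  if (anyNA(idx)) stop("rigid_sel contains unknown bead indices")
  if (length(idx) != nrow(body$ref))
    stop(sprintf("selection mismatch: body frame has %d beads, selection %d",
                 nrow(body$ref), length(idx)))
  nf <- n_frames(traj)
  bflag <- if (is.null(bound)) rep(TRUE, nf)
           else if (is.list(bound)) bound$bound else as.logical(bound)
  if (length(bflag) != nf) stop("bound series length must equal frame count")
  # inward normal: from the lower leaflet toward the protein side
  prot <- top$bead_index[is_protein_role(top$role)]
  pz <- mean(slice_coords(traj$coords, match(prot, top$bead_index), 1)[, 3])
  nhat <- c(0, 0, if (pz >= membrane$midplane_z) 1 else -1)
  A <- body$axes
  lat <- lon <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- slice_coords(traj$coords, idx, f)
    R <- kabsch_rotation(body$ref, sweep(X, 2, colMeans(X)))
    v <- drop(t(R) %*% nhat)
    comp <- drop(A %*% v)
    lat[f] <- 90 - rad2deg(acos(pmin(1, pmax(-1, comp[3]))))
    lo <- rad2deg(atan2(comp[2], comp[1]))
    lon[f] <- if (lo <= -180) lo + 360 else lo
  }
  out <- data.frame(time = traj$times, lat = lat, lon = lon, bound = bflag)
  class(out) <- c("orientation_series", "data.frame")
  out
}

lon_breaks <- function(bin_deg) seq(-180, 180, by = bin_deg)
lat_breaks <- function(bin_deg) seq(-90, 90, by = bin_deg)

#' Population histogram over (longitude, latitude)
#'
#' Normalised 2D histogram of the orientation sphere with longitude
#' periodic; mass over the analysed (bound) frames sums to 1.
#'
#' @param series An [orientation_series()].
#' @param bin_deg Bin width in degrees (must divide 360; default 5).
#' @param bound_only Use bound frames only (default `TRUE`).
#' @return An `orientation_histogram`: list with `mass` (lon x lat matrix),
#'   bin centres, `bin_deg`, and the frames used (with their angles).
#' @export
orientation_histogram <- function(series, bin_deg = 5, bound_only = TRUE) {
  if (360 %% bin_deg != 0) stop("bin_deg must divide 360")
  keep <- if (bound_only) which(series$bound) else seq_len(nrow(series))
  if (!length(keep)) stop("no bound frames")
  lon <- series$lon[keep]; lat <- series$lat[keep]
  lb <- lon_breaks(bin_deg); tb <- lat_breaks(bin_deg)
  ix <- pmin(length(lb) - 1L, pmax(1L, ceiling((lon + 180) / bin_deg)))
  iy <- pmin(length(tb) - 1L, pmax(1L, floor((lat + 90) / bin_deg) + 1L))
  mass <- matrix(0, length(lb) - 1L, length(tb) - 1L)
  for (k in seq_along(ix)) mass[ix[k], iy[k]] <- mass[ix[k], iy[k]] + 1
  mass <- mass / length(keep)
  structure(list(mass = mass, bin_deg = bin_deg,
                 lon_centers = lb[-length(lb)] + bin_deg / 2,
                 lat_centers = tb[-length(tb)] + bin_deg / 2,
                 frames = keep, lon = lon, lat = lat,
                 n_bound = length(keep)),
            class = "orientation_histogram")
}

# Gaussian smoothing of the (lon x lat) mass matrix: circular in longitude,
# reflected at the latitude edges. Kernel normalised, so mass is conserved.
smooth_orientation_histogram <- function(mass, bin_deg, sigma_deg) {
  if (sigma_deg <= 0) return(mass)
  s <- sigma_deg / bin_deg
  half <- max(1L, ceiling(3 * s))
  kern <- stats::dnorm(seq(-half, half), sd = s)
  kern <- kern / sum(kern)
  nl <- nrow(mass); nt <- ncol(mass)
  # longitude: circular convolution of each column
  sm <- mass
  for (j in seq_len(nt)) {
    col <- mass[, j]
    out <- numeric(nl)
    for (o in seq_along(kern)) {
      shift <- o - half - 1L
      out <- out + kern[o] * col[((seq_len(nl) - 1L + shift) %% nl) + 1L]
    }
    sm[, j] <- out
  }
  # latitude: reflected convolution of each row
  out2 <- sm
  for (i in seq_len(nl)) {
    row <- sm[i, ]
    acc <- numeric(nt)
    for (o in seq_along(kern)) {
      shift <- o - half - 1L
      jj <- seq_len(nt) + shift
      jj[jj < 1L] <- 1L - jj[jj < 1L]          # reflect below
      jj[jj > nt] <- 2L * nt + 1L - jj[jj > nt] # reflect above
      jj <- pmin(nt, pmax(1L, jj))
      acc <- acc + kern[o] * row[jj]
    }
    out2[i, ] <- acc
  }
  out2
}

#' Extract orientation states from a population histogram
#'
#' The histogram is Gaussian-smoothed (periodic in longitude, reflected in
#' latitude); local maxima of the smoothed map are candidate state centres.
#' Candidates closer than `assign_radius_deg` (great-circle) to a stronger
#' candidate are merged into it (ties keep the lower linear bin index).
#' Every bound frame is assigned to the nearest surviving centre within
#' `assign_radius_deg`, otherwise left unassigned. States whose population
#' (member frames / bound frames) falls below `min_peak_mass` are dropped
#' (members become unassigned). States are numbered by descending
#' population.
#'
#' @param map An [orientation_histogram()].
#' @param smooth_sigma_deg Gaussian smoothing width (deg; default 10).
#' @param min_peak_mass Minimum state population (default 0.02).
#' @param assign_radius_deg Assignment radius (deg; default 30).
#' @return An `orientation_state_map`: list with `states` data.frame
#'   (`state`, `lat`, `lon`, `population`, `n_members`,
#'   `representative_frame`), `members` (list of frame-index vectors into
#'   the bound-frame set used by the histogram), `unassigned_mass`,
#'   `smoothed` map, and parameters.
#' @export
extract_states <- function(map, smooth_sigma_deg = 10, min_peak_mass = 0.02,
                           assign_radius_deg = 30) {
  sm <- smooth_orientation_histogram(map$mass, map$bin_deg, smooth_sigma_deg)
  nl <- nrow(sm); nt <- ncol(sm)
  # 8-neighbourhood local maxima, longitude wrapped, latitude truncated
  is_max <- matrix(FALSE, nl, nt)
  for (i in seq_len(nl)) for (j in seq_len(nt)) {
    v <- sm[i, j]
    if (v <= 0) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- ((i - 1L + di) %% nl) + 1L
      jj <- j + dj
      if (jj < 1L || jj > nt) next
      nbr <- sm[ii, jj]
      if (nbr > v || (nbr == v && (ii + (jj - 1L) * nl) < (i + (j - 1L) * nl)))
        ok <- FALSE
    }
    if (ok) is_max[i, j] <- TRUE
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand)) {
    lin <- cand[, 1] + (cand[, 2] - 1L) * nl
    val <- sm[cand]
    ord <- order(-val, lin)
    cand <- cand[ord, , drop = FALSE]
    keep <- integer(0)
    clat <- map$lat_centers[cand[, 2]]; clon <- map$lon_centers[cand[, 1]]
    for (k in seq_len(nrow(cand))) {
      if (!length(keep) ||
          all(great_circle_deg(clat[k], clon[k], clat[keep], clon[keep]) >=
              assign_radius_deg))
        keep <- c(keep, k)
    }
    centers <- data.frame(lat = clat[keep], lon = clon[keep])
  } else centers <- data.frame(lat = numeric(0), lon = numeric(0))

  nb <- map$n_bound
  members <- rep(list(integer(0)), nrow(centers))
  if (nrow(centers) && nb > 0) {
    fv <- latlon_to_vec(map$lat, map$lon)
    cv <- latlon_to_vec(centers$lat, centers$lon)
    ang <- rad2deg(acos(pmax(pmin(fv %*% t(cv), 1), -1)))
    nearest <- apply(ang, 1, which.min)
    mind <- ang[cbind(seq_len(nrow(ang)), nearest)]
    assigned <- mind <= assign_radius_deg
    for (s in seq_len(nrow(centers)))
      members[[s]] <- which(assigned & nearest == s)
  }
  pop <- vapply(members, length, 1L) / max(nb, 1L)
  ok <- pop >= min_peak_mass
  centers <- centers[ok, , drop = FALSE]
  members <- members[ok]
  pop <- pop[ok]
  ord <- order(-pop)
  centers <- centers[ord, , drop = FALSE]; members <- members[ord]; pop <- pop[ord]
  reps <- integer(length(members))
  for (s in seq_along(members)) {
    m <- members[[s]]
    d <- great_circle_deg(map$lat[m], map$lon[m], centers$lat[s], centers$lon[s])
    reps[s] <- map$frames[m[which.min(d)]]
  }
  states <- if (nrow(centers))
    data.frame(state = seq_len(nrow(centers)), lat = centers$lat,
               lon = centers$lon, population = pop,
               n_members = vapply(members, length, 1L),
               representative_frame = reps)
  else data.frame(state = integer(0), lat = numeric(0), lon = numeric(0),
                  population = numeric(0), n_members = integer(0),
                  representative_frame = integer(0))
  member_frames <- lapply(members, function(m) map$frames[m])
  structure(list(states = states, members = member_frames,
                 unassigned_mass = 1 - sum(pop), smoothed = sm,
                 histogram = map, smooth_sigma_deg = smooth_sigma_deg,
                 min_peak_mass = min_peak_mass,
                 assign_radius_deg = assign_radius_deg),
            class = "orientation_state_map")
}

#' @export
print.orientation_state_map <- function(x, ...) {
  cat(sprintf("orientation_state_map: %d states, unassigned mass %.3f\n",
              nrow(x$states), x$unassigned_mass))
  if (nrow(x$states)) print(x$states, row.names = FALSE)
  invisible(x)
}

#' Representative frame of an orientation state
#'
#' The member frame whose (lat, lon) lies angularly closest to the state
#' centre; ties resolved to the smallest frame index.
#'
#' @param state_map An `orientation_state_map`.
#' @param state State number (row of `state_map$states`).
#' @param series The [orientation_series()] the states were built from.
#' @return Frame index (into the trajectory).
#' @export
representative_frame <- function(state_map, state, series) {
  m <- state_map$members[[state]]
  if (!length(m)) stop("empty state")
  st <- state_map$states[state, ]
  d <- great_circle_deg(series$lat[m], series$lon[m], st$lat, st$lon)
  min(m[d <= min(d) + 1e-9])   # ties resolve to the smallest frame index
}

#' Contact profile restricted to one orientation state
#'
#' [residue_lipid_contact_fractions()] evaluated on the state's member
#' frames only, normalised by the member-frame count.
#'
#' @param state_map An `orientation_state_map`.
#' @param state State number.
#' @param traj The underlying [trajectory()].
#' @param part,cutoff,... Passed to [residue_lipid_contact_fractions()].
#' @export
state_contact_profile <- function(state_map, state, traj, part = "head",
                                  cutoff = 7, ...) {
  m <- state_map$members[[state]]
  if (!length(m)) stop("empty state membership")
  residue_lipid_contact_fractions(traj, part = part, cutoff = cutoff,
                                  frames = m, ...)
}

#' Write an orientation series as a delimited table
#' @param series An [orientation_series()].
#' @param path Output path.
#' @export
write_orientation_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an orientation state summary as JSON
#' @param state_map An `orientation_state_map`.
#' @param path Output path.
#' @export
write_state_summary <- function(state_map, path) {
  jsonlite::write_json(list(states = state_map$states,
                            unassigned_mass = state_map$unassigned_mass,
                            smooth_sigma_deg = state_map$smooth_sigma_deg,
                            min_peak_mass = state_map$min_peak_mass,
                            assign_radius_deg = state_map$assign_radius_deg),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
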