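# Solution-experiment analyses: chemical shift perturbations, titration
# intensity ratios, secondary chemical shifts, R2 relaxation fitting,
# CD processing, and the confocal line-scan membrane-localization ratio,
# plus the correlation of NMR signal changes with simulation contacts.

#' Per-residue scalar track
#'
#' Generic container for per-residue values (CSP, intensity ratio, SCS,
#' RMSF, delta-I): a data.frame `(residue_seq, value)` tagged with a kind.
#'
#' @param residue_seq Residue numbers (author numbering).
#' @param value One value per residue.
#' @param kind Tag, e.g. `"CSP"`, `"intensity-ratio"`, `"SCS"`, `"RMSF"`.
#' @export
residue_series <- function(residue_seq, value, kind = "value") {
  if (length(residue_seq) != length(value)) stop("lengths differ")
  if (anyDuplicated(residue_seq)) stop("duplicate residues in series")
  out <- data.frame(residue_seq = as.integer(residue_seq),
                    value = as.numeric(value))
  attr(out, "kind") <- kind
  class(out) <- c("residue_series", "data.frame")
  out
}

#' Amide peak table
#'
#' @param residue_seq Residue numbers (unique).
#' @param H_ppm,N_ppm Amide 1H and 15N shifts (ppm).
#' @param intensity Peak intensities (arbitrary units).
#' @param observed Logical; unobserved residues must carry `NA` shifts and
#'   intensity.
#' @export
peak_table <- function(residue_seq, H_ppm, N_ppm, intensity,
                       observed = NULL) {
  observed <- observed %||% !is.na(intensity)
  out <- data.frame(residue_seq = as.integer(residue_seq),
                    H_ppm = as.numeric(H_ppm), N_ppm = as.numeric(N_ppm),
                    intensity = as.numeric(intensity),
                    observed = as.logical(observed))
  if (anyDuplicated(out$residue_seq)) stop("duplicate residues in peak table")
  out$H_ppm[!out$observed] <- NA_real_
  out$N_ppm[!out$observed] <- NA_real_
  out$intensity[!out$observed] <- NA_real_
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Read a peak table from a delimited text file
#'
#' Expects columns `residue_seq`, `H_ppm`, `N_ppm`, `intensity`; lines
#' starting with `#` are ignored.
#' @param path Input path.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  peak_table(df$residue_seq, df$H_ppm, df$N_ppm, df$intensity)
}

#' Titration series of peak tables
#'
#' @param ratios Ordered ligand molar-excess ratios; the first entry is the
#'   reference point (typically 0).
#' @param tables One [peak_table()] per ratio.
#' @export
titration_series <- function(ratios, tables) {
  if (length(ratios) != length(tables)) stop("one peak table per ratio required")
  if (length(ratios) < 2) stop("need a reference plus >= 1 titration point")
  structure(list(ratios = as.numeric(ratios), tables = tables),
            class = "titration_series")
}

#' Amide chemical shift perturbations
#'
#' `CSP(r) = sqrt(dH^2 + (alpha * dN)^2)` over residues observed in both
#' tables; the conventional 15N scaling is `alpha = 0.154`. Residues
#' unobserved in either table are omitted and listed in the `omitted`
#' attribute.
#'
#' @param reference,titrated [peak_table()]s.
#' @param alpha 15N scaling factor (default 0.154).
#' @return A [residue_series()] of kind `"CSP"` (ppm).
#' @export
csp <- function(reference, titrated, alpha = 0.154) {
  shared <- merge(reference[reference$observed, c("residue_seq", "H_ppm", "N_ppm")],
                  titrated[titrated$observed, c("residue_seq", "H_ppm", "N_ppm")],
                  by = "residue_seq", suffixes = c("_ref", "_tit"))
  if (!nrow(shared)) stop("no residues observed in both tables")
  val <- sqrt((shared$H_ppm_tit - shared$H_ppm_ref)^2 +
              (alpha * (shared$N_ppm_tit - shared$N_ppm_ref))^2)
  out <- residue_series(shared$residue_seq, val, kind = "CSP")
  attr(out, "alpha") <- alpha
  attr(out, "omitted") <- sort(setdiff(union(reference$residue_seq,
                                             titrated$residue_seq),
                                       shared$residue_seq))
  out
}

#' Intensity ratios across a titration
#'
#' For each titration point, `I/I0` per residue relative to the reference
#' point. Residues observed at the reference whose peak disappears at a
#' titration point are reported with ratio 0 and `vanished = TRUE`.
#'
#' @param titration A [titration_series()].
#' @return List (one element per non-reference point) of data.frames
#'   `(residue_seq, ratio, vanished)`, named by ratio; each also carries a
#'   `"kind"` attribute `"intensity-ratio"`.
#' @export
intensity_profile <- function(titration) {
  ref <- titration$tables[[1]]
  if (any(ref$observed & !(ref$intensity > 0)))
    stop("reference intensities must be positive for observed residues")
  out <- list()
  for (k in seq_along(titration$ratios)[-1]) {
    tab <- titration$tables[[k]]
    m <- merge(ref[ref$observed, c("residue_seq", "intensity")],
               tab[, c("residue_seq", "intensity", "observed")],
               by = "residue_seq", suffixes = c("_ref", ""))
    ratio <- ifelse(m$observed, m$intensity / m$intensity_ref, 0)
    df <- data.frame(residue_seq = m$residue_seq, ratio = ratio,
                     vanished = !m$observed)
    attr(df, "kind") <- "intensity-ratio"
    attr(df, "ligand_ratio") <- titration$ratios[k]
    out[[as.character(titration$ratios[k])]] <- df
  }
  out
}

#' Secondary chemical shifts
#'
#' `SCS(r) = delta_obs(r) - delta_rc(r)` against a supplied random-coil
#' table (pre-corrected for pH/temperature); residues missing from the
#' assignment are omitted, residues missing from the random-coil table are
#' an error.
#'
#' @param assigned data.frame `(residue_seq, shift_ppm)` of observed shifts
#'   (e.g. C-alpha).
#' @param random_coil data.frame `(residue_seq, shift_ppm)` of random-coil
#'   reference shifts.
#' @return A [residue_series()] of kind `"SCS"` (ppm).
#' @export
secondary_chemical_shifts <- function(assigned, random_coil) {
  missing_rc <- setdiff(assigned$residue_seq, random_coil$residue_seq)
  if (length(missing_rc))
    stop("residue(s) absent from random-coil table: ",
         paste(missing_rc, collapse = ", "))
  rc <- random_coil$shift_ppm[match(assigned$residue_seq, random_coil$residue_seq)]
  residue_series(assigned$residue_seq, assigned$shift_ppm - rc, kind = "SCS")
}

#' Relaxation decay curve
#'
#' @param delays Relaxation delays (s), non-negative and strictly
#'   increasing, at least 3 points. The default is the eight-point schedule
#'   0, 33.92, 67.84, 135.68, 169.6, 203.52, 271.36 and 339.2 ms used by
#'   the package's fixtures.
#' @param intensities Matrix (delays x replicates) or vector of peak
#'   intensities.
#' @export
decay_curve <- function(delays = default_r2_delays(), intensities) {
  delays <- as.numeric(delays)
  if (length(delays) < 3) stop("need >= 3 delay points")
  if (any(delays < 0) || any(diff(delays) <= 0))
    stop("delays must be non-negative and strictly increasing")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(delays))
    stop("intensities must have one row per delay")
  structure(list(delays = delays, intensities = intensities),
            class = "decay_curve")
}

#' Default transverse-relaxation delay schedule (s)
#' @export
default_r2_delays <- function()
  c(0, 33.92, 67.84, 135.68, 169.6, 203.52, 271.36, 339.2) / 1000

#' Fit a single-exponential transverse relaxation decay
#'
#' Joint least-squares fit of `I(t) = I0 * exp(-R2 * t)` over all replicate
#' points: log-linear initialisation followed by nonlinear refinement
#' (Levenberg-Marquardt, relative tolerance 1e-10). Standard errors come
#' from the fit's curvature.
#'
#' @param curve A [decay_curve()].
#' @return List with `R2` (s-1), `I0`, `R2_se`, `I0_se`, `converged`, and
#'   `negative_rate` flag.
#' @export
fit_r2_decay <- function(curve) {
  t_all <- rep(curve$delays, ncol(curve$intensities))
  y_all <- as.numeric(curve$intensities)
  keep <- is.finite(y_all)
  t_all <- t_all[keep]; y_all <- y_all[keep]
  if (!any(curve$delays == 0) || !all(curve$intensities[curve$delays == 0, ] > 0))
    stop("intensities at delay 0 must be present and positive")
  pos <- y_all > 0
  fit0 <- stats::lm(log(y_all[pos]) ~ t_all[pos])
  start <- list(I0 = exp(unname(stats::coef(fit0)[1])),
                R2 = -unname(stats::coef(fit0)[2]))
  df <- data.frame(t = t_all, y = y_all)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-R2 * t), data = df, start = start,
                      control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                           ptol = 1e-10,
                                                           maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # degenerate cases (e.g. an exactly flat or exactly exponential curve)
    # are already solved by the log-linear initialisation
    sm0 <- suppressWarnings(summary(fit0))$coefficients
    return(list(R2 = start$R2, I0 = start$I0,
                R2_se = unname(sm0[2, "Std. Error"]),
                I0_se = unname(start$I0 * sm0[1, "Std. Error"]),
                converged = TRUE, negative_rate = start$R2 < 0,
                diagnostics = paste("log-linear solution;",
                                    conditionMessage(fit))))
  }
  co <- summary(fit)$coefficients
  list(R2 = unname(co["R2", "Estimate"]), I0 = unname(co["I0", "Estimate"]),
       R2_se = unname(co["R2", "Std. Error"]),
       I0_se = unname(co["I0", "Std. Error"]),
       converged = TRUE, negative_rate = unname(co["R2", "Estimate"]) < 0)
}

#' Correlation between NMR signal change and contact frequency
#'
#' Pearson correlation between a per-residue NMR series (intensity ratio or
#' delta-I) and the contact fraction of one species/part, over the residues
#' present in both; two-sided p from the t transform with n - 2 degrees of
#' freedom; `R2 = r^2`.
#'
#' @param nmr A [residue_series()] (or data.frame with `residue_seq` and
#'   `value`/`ratio` column).
#' @param contacts A `contact_profile`.
#' @param species Species column of the profile to use (default: sum over
#'   all columns is not taken; the single column must be named).
#' @return List `(r, p, R2, n)`.
#' @export
nmr_contact_correlation <- function(nmr, contacts, species = NULL) {
  species <- species %||% contacts$species[1]
  if (!species %in% contacts$species) stop("species not present in contact profile")
  frac <- contacts$fraction[, species]
  val <- if ("value" %in% names(nmr)) nmr$value else nmr$ratio
  shared <- intersect(nmr$residue_seq, contacts$residue_seq)
  if (length(shared) < 3) stop("need >= 3 paired residues")
  x <- val[match(shared, nmr$residue_seq)]
  y <- frac[match(shared, contacts$residue_seq)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the paired series")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, R2 = r^2, n = length(shared))
}

# ---- circular dichroism ---------------------------------------------------

#' CD spectrum container
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @param value Ellipticity; unit per `unit`.
#' @param unit `"mdeg"` (raw) or `"MRE"` (deg cm2 dmol-1 res-1).
#' @param meta Optional metadata list (concentration, path length, ...).
#' @export
cd_spectrum <- function(wavelength_nm, value, unit = c("mdeg", "MRE"),
                        meta = list()) {
  unit <- match.arg(unit)
  if (length(wavelength_nm) != length(value)) stop("lengths differ")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 value = as.numeric(value), unit = unit, meta = meta),
            class = "cd_spectrum")
}

#' Convert raw ellipticity to mean residue ellipticity
#'
#' `MRE(lambda) = theta_mdeg(lambda) * MRW / (10 * path_cm * conc_mg_ml)`
#' with `MRW = molar_mass / (n_residues - 1)` unless `mean_residue_weight`
#' is given directly.
#'
#' @param raw A [cd_spectrum()] in mdeg.
#' @param concentration Protein concentration (mg/mL).
#' @param path_length Cuvette path length (cm).
#' @param n_residues Number of residues.
#' @param mean_residue_weight Mean residue weight (g/mol), or `NULL` to
#'   derive it from `molar_mass`.
#' @param molar_mass Molar mass (g/mol); required if
#'   `mean_residue_weight` is `NULL`.
#' @return A [cd_spectrum()] in MRE units.
#' @export
cd_mre <- function(raw, concentration, path_length, n_residues,
                   mean_residue_weight = NULL, molar_mass = NULL) {
  if (raw$unit != "mdeg") stop("input spectrum must be in mdeg")
  for (v in list(concentration = concentration, path_length = path_length,
                 n_residues = n_residues)) if (!is.numeric(v) || v <= 0)
    stop("CD metadata (concentration, path length, residue count) must be positive")
  mrw <- mean_residue_weight %||% {
    if (is.null(molar_mass)) stop("supply mean_residue_weight or molar_mass")
    molar_mass / (n_residues - 1)
  }
  cd_spectrum(raw$wavelength_nm,
              raw$value * mrw / (10 * path_length * concentration),
              unit = "MRE",
              meta = c(raw$meta, list(concentration = concentration,
                                      path_length = path_length,
                                      n_residues = n_residues,
                                      mean_residue_weight = mrw)))
}

#' Difference CD spectrum (bound minus free)
#'
#' Pointwise subtraction on identical wavelength grids and units. The
#' wavelength of the most negative difference ellipticity is reported
#' (`NA` when the difference is numerically zero everywhere); a minimum
#' near 218 nm is the classic signature of beta-strand formation.
#'
#' @param bound,free [cd_spectrum()]s on the same grid and unit.
#' @return A [cd_spectrum()] of the difference with attribute
#'   `minimum_wavelength_nm`.
#' @export
cd_difference <- function(bound, free) {
  if (bound$unit != free$unit) stop("unit mismatch between spectra")
  if (length(bound$wavelength_nm) != length(free$wavelength_nm) ||
      any(abs(bound$wavelength_nm - free$wavelength_nm) > 1e-9))
    stop("wavelength grid mismatch")
  d <- bound$value - free$value
  out <- cd_spectrum(bound$wavelength_nm, d, unit = bound$unit)
  attr(out, "minimum_wavelength_nm") <-
    if (all(abs(d) < 1e-12)) NA_real_ else bound$wavelength_nm[which.min(d)]
  out
}

#' Membrane-localization ratio of a confocal line scan
#'
#' Mean intensity over the membrane section divided by the mean over the
#' remaining (intracellular) section of a 1D fluorescence profile.
#'
#' @param profile Numeric intensity track.
#' @param membrane_idx Indices of the membrane section (the rest is the
#'   intracellular section); both sections must be non-empty.
#' @export
line_scan_membrane_ratio <- function(profile, membrane_idx) {
  n <- length(profile)
  membrane_idx <- as.integer(membrane_idx)
  if (!length(membrane_idx) || any(membrane_idx < 1 | membrane_idx > n))
    stop("membrane section indices out of range")
  intra <- setdiff(seq_len(n), membrane_idx)
  if (!length(intra)) stop("intracellular section is empty")
  mi <- mean(profile[intra])
  if (mi == 0) stop("zero intracellular mean")
  mean(profile[membrane_idx]) / mi
}
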