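# SEC-MALLS: forward simulation of multi-detector chromatograms and
# inversion to molar-mass-versus-elution profiles via the zero-angle
# Debye-Zimm relation R(0) = K* c M (dilute limit, second virial term
# dropped).

#' MALLS calibration constants
#'
#' The optical constant is recomputed on every access from its inputs:
#' \eqn{K^* = 4\pi^2 n_0^2 (dn/dc)^2 / (\lambda^4 N_A)} with the wavelength
#' in cm, giving Rayleigh ratios in 1/cm for concentrations in g/mL and
#' molar masses in g/mol.
#'
#' @param dn_dc Refractive-index increment, mL/g (default 0.185, the
#'   protein convention).
#' @param wavelength_nm Laser wavelength in nm (default 658).
#' @param solvent_ri Solvent refractive index (default 1.331, aqueous
#'   buffer).
#' @param uv_extinction UV extinction coefficient, mL/(mg cm) (default 1.0).
#' @param delays_s Named numeric: interdetector delays in seconds relative
#'   to the light-scattering detector, e.g. `c(uv = 0, ri = 0)`.
#' @return Object of class `"malls_calibration"`.
#' @export
malls_calibration <- function(dn_dc = 0.185, wavelength_nm = 658,
                              solvent_ri = 1.331, uv_extinction = 1.0,
                              delays_s = c(uv = 0, ri = 0)) {
  if (dn_dc <= 0) stop("dn_dc must be positive")
  if (wavelength_nm <= 0) stop("wavelength_nm must be positive")
  structure(list(dn_dc = dn_dc, wavelength_nm = wavelength_nm,
                 solvent_ri = solvent_ri, uv_extinction = uv_extinction,
                 delays_s = delays_s),
            class = "malls_calibration")
}

#' Debye-Zimm optical constant of a calibration, mol cm^2 / g^2
#' @param calibration A [malls_calibration()].
#' @return K* (numeric scalar).
#' @export
optical_constant <- function(calibration) {
  stopifnot(inherits(calibration, "malls_calibration"))
  lambda_cm <- calibration$wavelength_nm * 1e-7
  4 * pi^2 * calibration$solvent_ri^2 * calibration$dn_dc^2 /
    (lambda_cm^4 * 6.02214076e23)
}

new_chromatogram <- function(time, uv, ri, ls, flow_rate_ml_min, injected) {
  n <- length(time)
  if (length(uv) != n || length(ri) != n || length(ls) != n)
    stop("detector traces must share the time grid")
  if (n >= 2 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = time, uv = uv, ri = ri, ls = ls,
                 flow_rate_ml_min = flow_rate_ml_min, injected = injected),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("SEC chromatogram: %d points, %.0f-%.0f s, flow %.2f mL/min\n",
              length(x$time), min(x$time), max(x$time), x$flow_rate_ml_min))
  if (!is.null(x$injected) && nrow(x$injected))
    print(x$injected, row.names = FALSE)
  invisible(x)
}

#' Simulate a multi-detector SEC-MALLS chromatogram
#'
#' Each injected species elutes as a Gaussian concentration band whose
#' integral over elution volume equals the injected amount. Detector
#' responses follow the ideal dilute-limit forward model: `ri = c dn/dc`,
#' `uv = 1000 c epsilon` (1 cm path, c in g/mL), `ls = K* c M`. Optional
#' interdetector delays shift the UV/RI traces; Gaussian noise is added per
#' detector under the given seed.
#'
#' @param species data.frame with columns `mass_kda`, `amount_ug`,
#'   `retention_s`, `width_s`.
#' @param time Time grid in seconds (uniform).
#' @param calibration A [malls_calibration()].
#' @param flow_rate_ml_min Flow rate (default 0.5 mL/min).
#' @param noise_sd Named numeric noise standard deviations on the detector
#'   scale, `c(uv = , ri = , ls = )`; default zero.
#' @param seed Integer RNG seed for the noise (default `NULL`: no seeding).
#' @return A `"chromatogram"` object; `injected` records the ground truth.
#' @export
simulate_chromatogram <- function(species, time = seq(0, 1800, by = 2),
                                  calibration = malls_calibration(),
                                  flow_rate_ml_min = 0.5,
                                  noise_sd = c(uv = 0, ri = 0, ls = 0),
                                  seed = NULL) {
  stopifnot(is.data.frame(species),
            all(c("mass_kda", "amount_ug", "retention_s", "width_s")
                %in% names(species)))
  if (any(species$width_s <= 0)) stop("peak widths must be positive")
  if (any(species$amount_ug < 0)) stop("amounts must be >= 0")
  flow_ml_s <- flow_rate_ml_min / 60
  conc <- numeric(length(time))           # total, g/mL at the detector
  ls <- numeric(length(time))
  Kstar <- optical_constant(calibration)
  for (i in seq_len(nrow(species))) {
    # integral of c dV over the band = injected grams
    ci <- species$amount_ug[i] * 1e-6 / flow_ml_s *
      stats::dnorm(time, species$retention_s[i], species$width_s[i])
    conc <- conc + ci
    ls <- ls + Kstar * ci * species$mass_kda[i] * 1000
  }
  ri <- conc * calibration$dn_dc
  uv <- conc * 1000 * calibration$uv_extinction   # c in mg/mL, 1 cm path
  delays <- calibration$delays_s
  shift <- function(y, d) {
    if (is.null(d) || d == 0) return(y)
    stats::approx(time + d, y, xout = time, rule = 2)$y
  }
  uv <- shift(uv, delays["uv"])
  ri <- shift(ri, delays["ri"])
  nsd <- function(k) if (k %in% names(noise_sd)) noise_sd[[k]] else 0
  if (any(c(nsd("uv"), nsd("ri"), nsd("ls")) > 0)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    uv <- uv + stats::rnorm(length(time), 0, nsd("uv"))
    ri <- ri + stats::rnorm(length(time), 0, nsd("ri"))
    ls <- ls + stats::rnorm(length(time), 0, nsd("ls"))
  }
  new_chromatogram(time, uv, ri, ls, flow_rate_ml_min,
                   injected = species)
}

#' Estimate and remove interdetector delays
#'
#' Cross-correlates the UV and RI traces against the light-scattering trace
#' on the shared grid and shifts each by the lag that maximizes the
#' correlation. A flat correlation (no usable signal) leaves the trace
#' untouched with a warning.
#'
#' @param chromatogram A `"chromatogram"`.
#' @param max_lag_s Search window in seconds (default 30).
#' @param min_cor Minimum peak correlation to act on (default 0.5).
#' @return The aligned chromatogram with attribute `delays_s`, the
#'   estimated (and removed) delays for `uv` and `ri`.
#' @export
align_detectors <- function(chromatogram, max_lag_s = 30, min_cor = 0.5) {
  stopifnot(inherits(chromatogram, "chromatogram"))
  time <- chromatogram$time
  dt <- stats::median(diff(time))
  max_lag <- max(1L, round(max_lag_s / dt))
  ref <- chromatogram$ls
  est <- function(y) {
    if (stats::sd(y) == 0 || stats::sd(ref) == 0) return(NA_real_)
    cc <- stats::ccf(y, ref, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)
    if (max(cc$acf) < min_cor) return(NA_real_)
    cc$lag[which.max(cc$acf)] * dt
  }
  out <- chromatogram
  delays <- c(uv = est(chromatogram$uv), ri = est(chromatogram$ri))
  unshift <- function(y, d) stats::approx(time - d, y, xout = time, rule = 2)$y
  if (is.na(delays["uv"]) || is.na(delays["ri"])) {
    warning("interdetector correlation too flat; traces left unaligned")
    delays[is.na(delays)] <- 0
  }
  out$uv <- unshift(out$uv, delays["uv"])
  out$ri <- unshift(out$ri, delays["ri"])
  attr(out, "delays_s") <- delays
  out
}

#' Molar-mass-versus-elution profile (zero-angle Debye-Zimm inversion)
#'
#' Recovers concentration from the RI trace, `c(t) = ri(t) / (dn/dc)`, and
#' molar mass from `M(t) = ls(t) / (K* c(t))` wherever the concentration
#' exceeds a floor; elsewhere the profile is masked (division by detector
#' noise is meaningless below the floor).
#'
#' @param chromatogram An aligned `"chromatogram"`.
#' @param calibration A [malls_calibration()].
#' @param conc_floor Concentration floor in g/mL; default 2% of the maximum
#'   recovered concentration.
#' @return Object of class `"mass_profile"`: `time`, `molar_mass` (g/mol,
#'   `NA` where masked), `valid` (logical), `conc` (g/mL).
#' @export
mass_profile <- function(chromatogram, calibration = malls_calibration(),
                         conc_floor = NULL) {
  stopifnot(inherits(chromatogram, "chromatogram"),
            inherits(calibration, "malls_calibration"))
  conc <- chromatogram$ri / calibration$dn_dc
  if (is.null(conc_floor)) conc_floor <- 0.02 * max(conc, 0)
  valid <- conc >= conc_floor & conc > 0
  M <- rep(NA_real_, length(conc))
  M[valid] <- chromatogram$ls[valid] /
    (optical_constant(calibration) * conc[valid])
  structure(list(time = chromatogram$time, molar_mass = M, valid = valid,
                 conc = conc, conc_floor = conc_floor),
            class = "mass_profile")
}

#' @export
print.mass_profile <- function(x, ...) {
  if (any(x$valid)) {
    cat(sprintf("Mass profile: %d/%d valid points, %.1f-%.1f kDa\n",
                sum(x$valid), length(x$valid),
                min(x$molar_mass[x$valid]) / 1000,
                max(x$molar_mass[x$valid]) / 1000))
  } else cat("Mass profile: fully masked (concentration below floor)\n")
  invisible(x)
}

#' @export
plot.mass_profile <- function(x, ...) {
  graphics::plot(x$time, x$conc / max(x$conc, 1e-30), type = "l",
                 xlab = "time (s)", ylab = "relative concentration", ...)
  ok <- x$valid
  graphics::par(new = TRUE)
  graphics::plot(x$time[ok], x$molar_mass[ok] / 1000, axes = FALSE,
                 xlab = "", ylab = "", col = "red", pch = 20,
                 xlim = range(x$time))
  graphics::axis(4)
  graphics::mtext("molar mass (kDa)", side = 4, line = 2)
  invisible(x)
}

# ---- peak detection & assignment -------------------------------------------

# contiguous regions where conc exceeds frac*max of its own peak; simple
# local-maximum detection adequate for baseline-separated SEC peaks
find_peaks <- function(time, conc, prominence_frac = 0.05,
                       boundary_frac = 0.1) {
  floor_val <- prominence_frac * max(conc, 0)
  if (max(conc, 0) <= 0) return(list())
  above <- conc > floor_val
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  peaks <- list()
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- conc[i0:i1]
    apex <- i0 + which.max(seg) - 1
    core <- which(conc[i0:i1] >= boundary_frac * conc[apex]) + i0 - 1
    peaks[[length(peaks) + 1]] <- list(
      from = min(core), to = max(core), apex = apex)
  }
  peaks
}

#' Per-peak amount-weighted molar masses
#'
#' Finds peaks on the concentration trace (RI-derived, the concentration
#' proxy) and reports each peak's amount-weighted mean molar mass. The
#' weighted mean over the peak's valid points,
#' \eqn{\sum c M / \sum c = \sum R_\theta / (K^* \sum c)}, is a ratio of
#' summed detector signals, so detector noise averages out over the band
#' instead of being amplified by pointwise division at low concentration.
#'
#' @param profile A `"mass_profile"`.
#' @param prominence_frac Peak threshold as a fraction of the maximum
#'   concentration (default 0.05).
#' @return data.frame with one row per peak: `t_from`, `t_to`, `t_apex`,
#'   `mass_kda`.
#' @export
peak_mass_table <- function(profile, prominence_frac = 0.05) {
  stopifnot(inherits(profile, "mass_profile"))
  peaks <- find_peaks(profile$time, profile$conc, prominence_frac)
  rows <- lapply(peaks, function(p) {
    idx <- p$from:p$to
    idx <- idx[profile$valid[idx]]
    if (!length(idx)) return(NULL)
    w <- profile$conc[idx]
    data.frame(t_from = profile$time[p$from], t_to = profile$time[p$to],
               t_apex = profile$time[p$apex],
               mass_kda = sum(w * profile$molar_mass[idx]) / sum(w) / 1000)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(t_from = numeric(0), t_to = numeric(0),
                      t_apex = numeric(0), mass_kda = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect peaks and assign complex species
#'
#' Computes per-peak masses with [peak_mass_table()] and matches each
#' against a species catalog with [match_species()].
#'
#' @param profile A `"mass_profile"`.
#' @param catalog A `"species_catalog"`.
#' @param rel_tol Mass-matching tolerance (default 0.15).
#' @param prominence_frac Peak threshold as a fraction of the maximum
#'   concentration (default 0.05).
#' @return data.frame with one row per detected peak: `t_from`, `t_to`,
#'   `t_apex`, `mass_kda`, `label` (best match or `NA`), `rel_error`.
#' @export
detect_and_assign <- function(profile, catalog, rel_tol = 0.15,
                              prominence_frac = 0.05) {
  stopifnot(inherits(catalog, "species_catalog"))
  if (!length(catalog$species)) stop("empty species catalog")
  out <- peak_mass_table(profile, prominence_frac)
  out$label <- rep(NA_character_, nrow(out))
  out$rel_error <- rep(NA_real_, nrow(out))
  for (i in seq_len(nrow(out))) {
    m <- match_species(catalog, out$mass_kda[i], rel_tol = rel_tol)
    if (nrow(m)) {
      out$label[i] <- m$label[1]
      out$rel_error[i] <- m$rel_error[1]
    }
  }
  out
}

# ---- delimited-text I/O -----------------------------------------------------

#' Write a chromatogram as delimited text
#'
#' Four tab-separated columns (`time`, `uv`, `ri`, `ls`) preceded by a
#' commented key-value header carrying the flow rate, so a run can be
#' archived and re-read losslessly.
#'
#' @param chromatogram A `"chromatogram"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chromatogram, path) {
  stopifnot(inherits(chromatogram, "chromatogram"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# flow_rate_ml_min: %.6g", chromatogram$flow_rate_ml_min),
    "# columns: time\tuv\tri\tls"), con)
  utils::write.table(
    data.frame(time = chromatogram$time, uv = chromatogram$uv,
               ri = chromatogram$ri, ls = chromatogram$ls),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromatogram written by [write_chromatogram()]
#' @param path Input path.
#' @return A `"chromatogram"` object.
#' @export
read_chromatogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  flow <- 0.5
  fr <- grep("flow_rate_ml_min", header, value = TRUE)
  if (length(fr)) flow <- as.numeric(sub(".*:\\s*", "", fr[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = body, sep = "\t",
                          col.names = c("time", "uv", "ri", "ls"))
  new_chromatogram(df$time, df$uv, df$ri, df$ls, flow, injected = NULL)
}
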