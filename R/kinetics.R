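# 1:1 Langmuir SPR kinetics: rate-constant arithmetic, sensorgram
# simulation, and global nonlinear least-squares fitting.

#' Equilibrium dissociation constant from rate constants
#'
#' \eqn{K_D = k_d / k_a}, reported in picomolar to 3 significant figures,
#' the convention of SPR kinetics tables.
#'
#' @param ka Association rate constant, 1/(M s).
#' @param kd Dissociation rate constant, 1/s.
#' @param signif_digits Significant figures for the pM value (default 3;
#'   `NULL` for full precision).
#' @return KD in pM.
#' @export
kd_from_rates <- function(ka, kd, signif_digits = 3) {
  if (any(!is.finite(ka)) || any(ka <= 0)) stop("ka must be positive")
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive")
  kd_pm <- kd / ka * 1e12
  if (is.null(signif_digits)) kd_pm else signif(kd_pm, signif_digits)
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association phase
#' \eqn{R(t) = R_{max} \frac{C}{C+K_D} (1 - e^{-(k_a C + k_d) t})},
#' dissociation decaying as \eqn{e^{-k_d (t - t_{assoc})}} from the
#' association endpoint. Gaussian noise is added under the given seed.
#'
#' @param ka,kd Rate constants (1/(M s), 1/s).
#' @param rmax Saturation response, RU.
#' @param conc Analyte concentration, M.
#' @param t_assoc,t_diss Phase durations, s.
#' @param dt Time step, s (default 1).
#' @param noise_sd Noise standard deviation, RU (default 0).
#' @param seed Integer seed (default `NULL`).
#' @return Object of class `"sensorgram"`: `time`, `response`, `conc`,
#'   `t_assoc`.
#' @export
simulate_sensorgram <- function(ka, kd, rmax, conc, t_assoc = 300,
                                t_diss = 600, dt = 1, noise_sd = 0,
                                seed = NULL) {
  if (ka <= 0 || kd <= 0 || rmax <= 0) stop("ka, kd, rmax must be positive")
  if (conc < 0) stop("conc must be >= 0")
  if (t_assoc <= 0 || t_diss < 0) stop("phase durations must be positive")
  time <- seq(0, t_assoc + t_diss, by = dt)
  response <- langmuir_response(time, ka, kd, rmax, conc, t_assoc)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    response <- response + stats::rnorm(length(time), 0, noise_sd)
  }
  structure(list(time = time, response = response, conc = conc,
                 t_assoc = t_assoc),
            class = "sensorgram")
}

# noiseless 1:1 model response at arbitrary times
langmuir_response <- function(time, ka, kd, rmax, conc, t_assoc) {
  KD <- kd / ka
  req <- if (conc > 0) rmax * conc / (conc + KD) else 0
  kobs <- ka * conc + kd
  r <- ifelse(time <= t_assoc,
              req * (1 - exp(-kobs * time)),
              NA_real_)
  r_end <- req * (1 - exp(-kobs * t_assoc))
  idx <- time > t_assoc
  r[idx] <- r_end * exp(-kd * (time[idx] - t_assoc))
  r
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram: C = %.3g M, %d points, association 0-%g s\n",
              x$conc, length(x$time), x$t_assoc))
  invisible(x)
}

#' @export
plot.sensorgram <- function(x, ...) {
  graphics::plot(x$time, x$response, type = "l", xlab = "time (s)",
                 ylab = "response (RU)", ...)
  graphics::abline(v = x$t_assoc, lty = 3)
  invisible(x)
}

#' Global 1:1 Langmuir fit of a concentration series
#'
#' Fits a single (ka, kd, Rmax) triple to all sensorgrams simultaneously by
#' Levenberg-Marquardt least squares on log10 parameters, with a small
#' multi-start grid around a heuristic initial guess for robustness. A
#' series that cannot constrain the parameters (fewer than 3 concentrations,
#' or a single saturating curve) triggers an ill-conditioning warning.
#'
#' @param sensorgrams List of `"sensorgram"` objects at different analyte
#'   concentrations.
#' @param drop_top Drop the highest concentration before fitting (the
#'   common practice when the top curve shows nonspecific binding)?
#'   Default `FALSE`.
#' @param start Optional named list `list(ka=, kd=, rmax=)` overriding the
#'   heuristic start.
#' @return Object of class `"spr_fit"`: elements `ka`, `kd`, `rmax`,
#'   `kd_molar`, `kd_pm`, `se` (approximate standard errors on the log10
#'   scale), `residual_norm`, `converged`, `n_curves`, `data`.
#' @export
fit_one_to_one <- function(sensorgrams, drop_top = FALSE, start = NULL) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(all(vapply(sensorgrams, inherits, TRUE, "sensorgram")))
  concs <- vapply(sensorgrams, function(s) s$conc, 0)
  if (drop_top && length(sensorgrams) > 1)
    sensorgrams <- sensorgrams[concs < max(concs)]
  concs <- vapply(sensorgrams, function(s) s$conc, 0)
  if (length(unique(concs[concs > 0])) < 3)
    warning("fewer than 3 distinct non-zero concentrations: ",
            "1:1 fit is ill-conditioned")
  resid_fun <- function(p) {
    ka <- 10^p[1]; kd <- 10^p[2]; rmax <- 10^p[3]
    unlist(lapply(sensorgrams, function(s)
      s$response - langmuir_response(s$time, ka, kd, rmax, s$conc, s$t_assoc)))
  }
  rmax0 <- max(vapply(sensorgrams, function(s) max(s$response), 0))
  c_mid <- stats::median(concs[concs > 0])
  p0 <- if (!is.null(start)) log10(c(start$ka, start$kd, start$rmax))
  else c(log10(1e6), log10(1e-3), log10(max(rmax0, 1e-6)))
  starts <- rbind(p0,
                  p0 + c(1, -1, 0.3), p0 + c(-1, 1, -0.3),
                  p0 + c(2, 0, 0), p0 + c(0, -2, 0),
                  c(log10(1 / c_mid), log10(1e-4), p0[3]))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("1:1 fit did not converge from any start")
  p <- best$par
  se <- tryCatch({
    hinv <- solve(best$hessian)
    dof <- max(1, length(resid_fun(p)) - 3)
    sqrt(pmax(diag(hinv), 0) * best$deviance / dof)
  }, error = function(e) rep(NA_real_, 3))
  if (all(is.na(se)))
    warning("parameter covariance singular: fit is ill-conditioned ",
            "(final residual norm ", signif(sqrt(best$deviance), 4), ")")
  ka <- 10^p[1]; kd <- 10^p[2]
  structure(list(ka = ka, kd = kd, rmax = 10^p[3],
                 kd_molar = kd / ka,
                 kd_pm = kd_from_rates(ka, kd, signif_digits = NULL),
                 se = stats::setNames(se, c("log10_ka", "log10_kd", "log10_rmax")),
                 residual_norm = sqrt(best$deviance),
                 converged = best$info %in% 1:4,
                 n_curves = length(sensorgrams),
                 data = sensorgrams),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat("Global 1:1 Langmuir fit\n")
  cat(sprintf("  ka   = %.4g 1/(M s)\n  kd   = %.4g 1/s\n", x$ka, x$kd))
  cat(sprintf("  Rmax = %.4g RU\n  KD   = %.3g pM\n", x$rmax, x$kd_pm))
  cat(sprintf("  %d curves, residual norm %.4g, %s\n", x$n_curves,
              x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) {
  c(ka = object$ka, kd = object$kd, rmax = object$rmax,
    KD = object$kd_molar)
}

#' @export
summary.spr_fit <- function(object, ...) {
  out <- data.frame(estimate = c(object$ka, object$kd, object$rmax),
                    se_log10 = object$se,
                    row.names = c("ka", "kd", "rmax"))
  cat(sprintf("KD = %.3g pM (= kd/ka)\n", object$kd_pm))
  print(out)
  invisible(out)
}

# ---- four-parameter logistic ------------------------------------------------

#' Four-parameter logistic (variable-slope) dose-response fit
#'
#' Fits \eqn{y = bottom + (top - bottom)/(1 + (EC_{50}/x)^{h})} by
#' Levenberg-Marquardt least squares with log10(EC50) as the free dose
#' parameter — the "sigmoidal dose response (variable slope)" model.
#' Decreasing curves (inhibition) are fitted with a negative slope and
#' flagged `inverted`; the reported `ec50` is the inflection dose (an IC50
#' for inverted curves).
#'
#' @param dose Dose series (M), positive, >= 5 points.
#' @param response Measured responses.
#' @return Object of class `"fourpl_fit"`: `bottom`, `top`, `ec50`, `hill`,
#'   `inverted`, `residual_norm`, `data`.
#' @export
fourpl_fit <- function(dose, response) {
  if (length(dose) != length(response)) stop("dose/response length mismatch")
  if (any(dose <= 0)) stop("doses must be positive")
  if (length(dose) < 5) stop("need at least 5 doses")
  if (stats::sd(response) == 0)
    stop("degenerate fit: response is flat across all doses")
  ord <- order(dose)
  x <- dose[ord]; y <- response[ord]
  increasing <- stats::cor(log10(x), y) >= 0
  p0 <- c(bottom = min(y), span = max(diff(range(y)), 1e-12),
          log_ec50 = stats::median(log10(x)),
          hill = if (increasing) 1 else -1)
  model <- function(p, xx)
    p[1] + p[2] / (1 + 10^((p[3] - log10(xx)) * p[4]))
  resid_fun <- function(p) y - model(p, x)
  starts <- rbind(p0,
                  p0 + c(0, 0, 1, 0), p0 + c(0, 0, -1, 0),
                  replace(p0, 4, p0[4] * 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("4PL fit did not converge")
  p <- unname(best$par)
  # normalize: express with positive span between asymptotes
  bottom <- p[1]; top <- p[1] + p[2]; hill <- p[4]
  inverted <- (top < bottom) || (hill < 0)
  lo <- min(bottom, top); hi <- max(bottom, top)
  structure(list(bottom = lo, top = hi, ec50 = 10^p[3], hill = abs(hill),
                 inverted = inverted,
                 residual_norm = sqrt(best$deviance),
                 par = p,
                 data = data.frame(dose = x, response = y)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: %s = %.4g M (hill %.3g)\n",
              if (x$inverted) "IC50" else "EC50", x$ec50, x$hill))
  cat(sprintf("  asymptotes %.4g .. %.4g, residual norm %.4g\n",
              x$bottom, x$top, x$residual_norm))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) {
  c(bottom = object$bottom, top = object$top, ec50 = object$ec50,
    hill = object$hill)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$data$dose
  else if (is.data.frame(newdata)) newdata$dose else newdata
  p <- object$par
  p[1] + p[2] / (1 + 10^((p[3] - log10(xx)) * p[4]))
}

#' @export
plot.fourpl_fit <- function(x, ...) {
  graphics::plot(x$data$dose, x$data$response, log = "x",
                 xlab = "dose (M)", ylab = "response", ...)
  xx <- 10^seq(log10(min(x$data$dose)), log10(max(x$data$dose)),
               length.out = 200)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(v = x$ec50, lty = 3)
  invisible(x)
}
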