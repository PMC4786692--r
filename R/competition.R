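# Equilibrium competition model for receptor-binding inhibition, and the
# sequestration-capacity curve distinguishing 1-dimer and 2-dimer traps.

#' Competition assay setup
#'
#' Mass-action model of a receptor-binding inhibition assay: free antigen
#' (VEGF dimer) partitions between a fixed pool of inhibitor binding sites
#' (independent and equivalent, `dimers_trapped` per inhibitor molecule,
#' per-site dissociation constant `kd_inhibitor_site`) and a receptor probe
#' whose occupancy generates the signal. The receptor surface is treated as
#' non-depleting, so the read-out is
#' \eqn{signal \propto V_{free}/(K_{D,R} + V_{free})}.
#'
#' @param vegf_total Total antigen concentration, M (e.g. 10 ng/mL at a
#'   user-supplied dimer mass; see [ngml_to_molar()]).
#' @param inhibitor_conc Inhibitor concentration series, M.
#' @param kd_receptor_vegf Receptor-antigen KD, M.
#' @param kd_inhibitor_site Per-site inhibitor-antigen KD, M.
#' @param dimers_trapped Antigen units sequestered per inhibitor molecule at
#'   saturation (1 for a trap, 2 for the dual-domain antibody).
#' @return Object of class `"competition_setup"`.
#' @export
competition_setup <- function(vegf_total, inhibitor_conc,
                              kd_receptor_vegf = 1e-9,
                              kd_inhibitor_site = 1e-11,
                              dimers_trapped = 1L) {
  if (vegf_total < 0 || any(inhibitor_conc < 0))
    stop("concentrations must be >= 0")
  if (kd_receptor_vegf <= 0 || kd_inhibitor_site < 0)
    stop("dissociation constants must be positive")
  dimers_trapped <- as.integer(dimers_trapped)
  if (dimers_trapped < 1L) stop("dimers_trapped must be >= 1")
  structure(list(vegf_total = vegf_total,
                 inhibitor_conc = sort(unique(inhibitor_conc)),
                 kd_receptor_vegf = kd_receptor_vegf,
                 kd_inhibitor_site = kd_inhibitor_site,
                 dimers_trapped = dimers_trapped),
            class = "competition_setup")
}

#' Convert a mass concentration to molar
#' @param ngml Concentration in ng/mL.
#' @param molar_mass_kda Molar mass in kDa (must be supplied explicitly).
#' @return Concentration in M.
#' @export
ngml_to_molar <- function(ngml, molar_mass_kda) {
  if (molar_mass_kda <= 0) stop("molar_mass_kda must be positive")
  ngml * 1e-6 / (molar_mass_kda * 1000)
}

# free antigen at equilibrium: V_tot = V + S*V/(k_site + V), solved by
# bisection (uniroot) on the conservation equation
free_antigen <- function(v_total, site_total, kd_site) {
  if (v_total == 0) return(0)
  if (site_total == 0) return(v_total)
  f <- function(v) v + site_total * v / (kd_site + v) - v_total
  stats::uniroot(f, lower = 0, upper = v_total,
                 tol = max(v_total * 1e-14, 1e-300),
                 extendInt = "no")$root
}

#' Solve the equilibrium competition curve
#'
#' For every inhibitor concentration, solves the free-antigen conservation
#' equation by root finding, evaluates the receptor-bound signal, and
#' extracts the IC50 with a four-parameter logistic fit of signal versus
#' inhibitor concentration.
#'
#' @param setup A [competition_setup()].
#' @return Object of class `"competition_result"`: `table` (data.frame with
#'   `inhibitor_conc`, `free_vegf`, `free_vegf_fraction`, `signal`,
#'   `signal_rel` relative to the no-inhibitor control), `ic50` (M, `NA` if
#'   the series does not bracket it), and the `fourpl_fit` object.
#' @export
equilibrium_competition <- function(setup) {
  stopifnot(inherits(setup, "competition_setup"))
  v_tot <- setup$vegf_total
  kd_site <- setup$kd_inhibitor_site
  rows <- lapply(setup$inhibitor_conc, function(I) {
    S <- setup$dimers_trapped * I
    vf <- free_antigen(v_tot, S, kd_site)
    data.frame(inhibitor_conc = I, free_vegf = vf,
               free_vegf_fraction = if (v_tot > 0) vf / v_tot else 0,
               signal = vf / (setup$kd_receptor_vegf + vf))
  })
  tab <- do.call(rbind, rows)
  control <- free_antigen(v_tot, 0, kd_site)
  control_sig <- control / (setup$kd_receptor_vegf + control)
  tab$signal_rel <- if (control_sig > 0) tab$signal / control_sig else 0
  pos <- tab$inhibitor_conc > 0
  fit <- NULL; ic50 <- NA_real_
  if (sum(pos) >= 5 && stats::sd(tab$signal_rel[pos]) > 0) {
    fit <- tryCatch(fourpl_fit(tab$inhibitor_conc[pos], tab$signal_rel[pos]),
                    error = function(e) NULL)
    if (!is.null(fit)) ic50 <- fit$ec50
  }
  structure(list(table = tab, ic50 = ic50, fit = fit, setup = setup),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("Equilibrium competition: %d inhibitor points, %d site(s)/molecule\n",
              nrow(x$table), x$setup$dimers_trapped))
  cat(sprintf("  IC50 = %s\n",
              if (is.na(x$ic50)) "not bracketed" else sprintf("%.4g M", x$ic50)))
  invisible(x)
}

#' Antigen-sequestration capacity versus inhibitor:antigen ratio
#'
#' For each architecture, reports the number of antigen units bound per
#' inhibitor molecule across a range of inhibitor:antigen molar ratios at
#' equilibrium. In antigen excess with tight per-site binding the curve
#' saturates at the architecture's `dimers_trapped` capacity — 2 for the
#' dual-domain antibody, 1 for a receptor trap — which is the potency
#' advantage of trapping two antigen dimers per molecule at low inhibitor
#' concentrations.
#'
#' @param capacities Named integer vector of per-molecule capacities, e.g.
#'   `c("dual-dAb" = 2, trap = 1)`.
#' @param vegf_total Antigen concentration, M.
#' @param ratios Inhibitor:antigen molar ratios (default `10^seq(-2,1,.25)`).
#' @param kd_site Per-site KD, M (default 1e-12: effectively stoichiometric).
#' @return data.frame with `architecture`, `ratio`, `inhibitor_conc`,
#'   `dimers_per_molecule`.
#' @export
capacity_curve <- function(capacities, vegf_total,
                           ratios = 10^seq(-2, 1, 0.25),
                           kd_site = 1e-12) {
  stopifnot(length(capacities) >= 1, !is.null(names(capacities)))
  rows <- list()
  for (arch in names(capacities)) {
    m <- as.integer(capacities[[arch]])
    for (r in ratios) {
      I <- r * vegf_total
      if (I == 0 || vegf_total == 0) {
        bound_per <- 0
      } else {
        vf <- free_antigen(vegf_total, m * I, kd_site)
        bound_per <- (vegf_total - vf) / I
      }
      rows[[length(rows) + 1]] <- data.frame(
        architecture = arch, ratio = r, inhibitor_conc = I,
        dimers_per_molecule = bound_per)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
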