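# Linker-reach feasibility: can the peptide linkers of a multivalent binder
# span the measured separations between its domain attachment points?

#' Peptide linker specification
#'
#' @param n_residues Number of linker residues (>= 0).
#' @param contour_per_residue Contour length per residue in Angstrom for a
#'   fully extended chain; default 3.5, must lie in \[3.0, 3.8\].
#' @param anchor_allowance Angstrom of slack contributed by the separation of
#'   the linker attachment points on the scaffold (e.g. the two Fc chain
#'   termini); default 10.
#' @return Object of class `"linker_spec"`.
#' @export
linker_spec <- function(n_residues, contour_per_residue = 3.5,
                        anchor_allowance = 10) {
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 0) stop("n_residues must be >= 0")
  if (contour_per_residue < 3.0 || contour_per_residue > 3.8)
    stop("contour_per_residue must lie in [3.0, 3.8] Angstrom")
  if (anchor_allowance < 0) stop("anchor_allowance must be >= 0")
  structure(list(n_residues = n_residues,
                 contour_per_residue = contour_per_residue,
                 anchor_allowance = anchor_allowance),
            class = "linker_spec")
}

#' Maximum span of a fully extended linker
#'
#' Contour length `n_residues * contour_per_residue`; the anchor allowance is
#' accounted separately at the pair level (see [coengagement_feasibility()]).
#'
#' @param linker A [linker_spec()].
#' @return Span in Angstrom.
#' @export
max_linker_span <- function(linker) {
  stopifnot(inherits(linker, "linker_spec"))
  linker$n_residues * linker$contour_per_residue
}

#' Can a pair of linkers co-engage two sites a given distance apart?
#'
#' The available span is the sum of the two linkers' contour lengths plus
#' the shared anchor span (separation of their attachment points on the
#' scaffold). The verdict is graded by the required fraction of full
#' extension: a real peptide linker rarely approaches its contour length,
#' so demanding more than ~75% extension is scored `marginal` ("extremely
#' extended") and more than ~95% `infeasible`.
#'
#' @param required_span Distance to be bridged, Angstrom (>= 0).
#' @param linkers List of [linker_spec()] objects (usually two).
#' @param shared_anchor_span Angstrom between the linker anchor points
#'   (default 0).
#' @param feasible_max,marginal_max Extension-fraction thresholds
#'   (defaults 0.75 and 0.95).
#' @return Object of class `"coengagement_verdict"`: `required_span`,
#'   `available_span`, `extension_fraction`, `verdict` in
#'   `{"feasible","marginal","infeasible"}`.
#' @export
coengagement_feasibility <- function(required_span, linkers,
                                     shared_anchor_span = 0,
                                     feasible_max = 0.75,
                                     marginal_max = 0.95) {
  if (!is.finite(required_span) || required_span < 0)
    stop("required_span must be >= 0")
  if (shared_anchor_span < 0) stop("shared_anchor_span must be >= 0")
  if (inherits(linkers, "linker_spec")) linkers <- list(linkers)
  avail <- sum(vapply(linkers, max_linker_span, 0)) + shared_anchor_span
  frac <- if (avail > 0) required_span / avail else if (required_span == 0) 0 else Inf
  verdict <- if (frac <= feasible_max) "feasible"
  else if (frac <= marginal_max) "marginal"
  else "infeasible"
  structure(list(required_span = required_span, available_span = avail,
                 extension_fraction = frac, verdict = verdict),
            class = "coengagement_verdict")
}

#' @export
print.coengagement_verdict <- function(x, ...) {
  cat(sprintf("required %.1f A / available %.1f A (extension %.0f%%): %s\n",
              x$required_span, x$available_span,
              100 * x$extension_fraction, x$verdict))
  invisible(x)
}

# ---- binder / antigen descriptions -----------------------------------------

#' Multivalent binder architecture
#'
#' Describes a binder molecule as a scaffold carrying binding sites through
#' peptide linkers. `sites` lists the sites of one scaffold monomer; the
#' molecule carries `copies_per_molecule` copies (2 for an Fc homodimer).
#'
#' @param name Label.
#' @param sites List of sites, each a list with `domain` (e.g. `"vh"`,
#'   `"vk"`, `"fab"`, `"trap"`), `terminus` (`"n_term"`/`"c_term"`, where the
#'   linker attaches on the scaffold) and `linker` (a [linker_spec()]).
#' @param copies_per_molecule Scaffold copies per molecule (default 2).
#' @param molecule_mass_kda Molar mass of the whole molecule, kDa.
#' @return Object of class `"binder_architecture"`.
#' @export
binder_architecture <- function(name, sites, copies_per_molecule = 2L,
                                molecule_mass_kda) {
  if (!length(sites)) stop("sites must be non-empty")
  if (molecule_mass_kda <= 0) stop("molecule_mass_kda must be positive")
  for (s in sites) {
    if (!all(c("domain", "terminus", "linker") %in% names(s)))
      stop("each site needs fields domain, terminus, linker")
    stopifnot(inherits(s$linker, "linker_spec"))
  }
  structure(list(name = name, sites = sites,
                 copies_per_molecule = as.integer(copies_per_molecule),
                 molecule_mass_kda = molecule_mass_kda),
            class = "binder_architecture")
}

# site-type vector over the whole molecule, e.g. c("vh","vk","vh","vk")
site_types <- function(arch) {
  rep(vapply(arch$sites, function(s) s$domain, ""), arch$copies_per_molecule)
}

site_linker <- function(arch, domain) {
  for (s in arch$sites) if (s$domain == domain) return(s$linker)
  stop("architecture has no site of domain type ", domain)
}

#' Default dual-domain-antibody architecture
#'
#' Fc homodimer with a VH domain fused through a linker at each Fc
#' N-terminus and a VK domain at each Fc C-terminus: four sites per
#' molecule, ~109 kDa. Linker lengths of the real molecule are not public;
#' the defaults (15 residues, 3.5 A/residue contour) are stated package
#' parameters, configurable per call.
#'
#' @param vh_linker,vk_linker [linker_spec()] objects.
#' @param molecule_mass_kda Molar mass, default 109 kDa.
#' @return A [binder_architecture()].
#' @export
dual_dab_architecture <- function(vh_linker = linker_spec(15, anchor_allowance = 0),
                                  vk_linker = linker_spec(15, anchor_allowance = 10),
                                  molecule_mass_kda = 109) {
  binder_architecture(
    "dual-dAb",
    sites = list(
      list(domain = "vh", terminus = "n_term", linker = vh_linker),
      list(domain = "vk", terminus = "c_term", linker = vk_linker)),
    copies_per_molecule = 2L,
    molecule_mass_kda = molecule_mass_kda)
}

#' Conventional IgG architecture (two equivalent Fab sites)
#' @param molecule_mass_kda Molar mass, default 148 kDa.
#' @return A [binder_architecture()].
#' @export
igg_architecture <- function(molecule_mass_kda = 148) {
  binder_architecture(
    "IgG",
    sites = list(list(domain = "fab", terminus = "n_term",
                      linker = linker_spec(0, anchor_allowance = 0))),
    copies_per_molecule = 2L,
    molecule_mass_kda = molecule_mass_kda)
}

#' Receptor-trap architecture (one composite site, 1:1 binder)
#' @param molecule_mass_kda Molar mass, default 115 kDa.
#' @return A [binder_architecture()].
#' @export
trap_architecture <- function(molecule_mass_kda = 115) {
  binder_architecture(
    "trap",
    sites = list(list(domain = "trap", terminus = "n_term",
                      linker = linker_spec(0, anchor_allowance = 0))),
    copies_per_molecule = 1L,
    molecule_mass_kda = molecule_mass_kda)
}

#' Homodimeric antigen model
#'
#' @param name Label (default `"VEGF dimer"`).
#' @param epitopes_per_unit Equivalent epitopes per antigen unit (2 for a
#'   two-fold symmetric homodimer).
#' @param unit_mass_kda Molar mass of one antigen unit, default 48 kDa.
#' @return Object of class `"antigen_model"`.
#' @export
antigen_model <- function(name = "VEGF dimer", epitopes_per_unit = 2L,
                          unit_mass_kda = 48) {
  epitopes_per_unit <- as.integer(epitopes_per_unit)
  if (epitopes_per_unit < 1L) stop("epitopes_per_unit must be >= 1")
  if (unit_mass_kda <= 0) stop("unit_mass_kda must be positive")
  structure(list(name = name, epitopes_per_unit = epitopes_per_unit,
                 unit_mass_kda = unit_mass_kda),
            class = "antigen_model")
}

# ---- engagement-mode classification ----------------------------------------

#' Classify the engagement mode of a dual-domain binder
#'
#' Given the three measured inter-terminal distances and the binder's linker
#' parameterization, scores each candidate clamp pair with
#' [coengagement_feasibility()]:
#' \itemize{
#'   \item `vh_vh` — both VH linkers, no shared anchor (the two Fc
#'     N-termini sit together at the hinge);
#'   \item `vk_vk` — both VK linkers plus the VK anchor allowance (the two
#'     Fc C-termini are a few Angstrom apart);
#'   \item `cross` — one VH and one VK linker plus anchor allowance.
#' }
#' The headline mode is `"end-on"` when both like-domain pairs are feasible
#' (the molecule can clamp one antigen at either end), `"side-on"` when the
#' cross pair is feasible while the VH pair is not (each half of the
#' molecule clamps its own antigen laterally), else `"none"`.
#'
#' @param report A `"terminal_distances"` object (or list with `d_vh_vh`,
#'   `d_vk_vk`, `d_cross`).
#' @param architecture A [binder_architecture()] with `vh` and `vk` sites.
#' @param feasible_max,marginal_max Thresholds passed through to
#'   [coengagement_feasibility()].
#' @return Object of class `"engagement_mode"`: per-pair verdicts
#'   (`vh_vh`, `vk_vk`, `cross`) and the headline `mode`.
#' @export
classify_engagement_mode <- function(report, architecture,
                                     feasible_max = 0.75,
                                     marginal_max = 0.95) {
  vh <- site_linker(architecture, "vh")
  vk <- site_linker(architecture, "vk")
  score <- function(d, linkers, anchor) {
    if (is.null(d) || is.na(d)) return(NULL)
    coengagement_feasibility(d, linkers, anchor,
                             feasible_max = feasible_max,
                             marginal_max = marginal_max)
  }
  verdicts <- list(
    vh_vh = score(report$d_vh_vh, list(vh, vh), vh$anchor_allowance),
    vk_vk = score(report$d_vk_vk, list(vk, vk), vk$anchor_allowance),
    cross = score(report$d_cross, list(vh, vk),
                  max(vh$anchor_allowance, vk$anchor_allowance)))
  ok <- function(v) !is.null(v) && v$verdict == "feasible"
  mode <- if (ok(verdicts$vh_vh) && ok(verdicts$vk_vk)) "end-on"
  else if (ok(verdicts$cross) && !is.null(verdicts$vh_vh) &&
           verdicts$vh_vh$verdict != "feasible") "side-on"
  else "none"
  complete <- !vapply(verdicts, is.null, TRUE)
  structure(list(verdicts = verdicts, mode = mode,
                 complete = all(complete)),
            class = "engagement_mode")
}

#' @export
print.engagement_mode <- function(x, ...) {
  lab <- c(vh_vh = "VH..VH (end-on top)", vk_vk = "VK..VK (end-on bottom)",
           cross = "VH..VK (side-on)")
  for (k in names(x$verdicts)) {
    v <- x$verdicts[[k]]
    if (is.null(v)) {
      cat(sprintf("  %-24s not measured\n", lab[k]))
    } else {
      cat(sprintf("  %-24s", lab[k])); print(v)
    }
  }
  cat("Headline engagement mode:", x$mode,
      if (!x$complete) "(partial: some distances missing)", "\n")
  invisible(x)
}
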