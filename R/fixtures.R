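# Deterministic synthetic inputs: toy antigen/binder co-crystal structures
# with configurable terminal separations, SEC-MALLS mixing series with known
# composition, and SPR sensorgram datasets with ground-truth manifests.

#' Build a toy pair of antigen/binder-domain complexes
#'
#' Constructs two idealized poly-alanine (C-alpha trace) structures sharing
#' an identical two-fold-symmetric homodimeric antigen, emulating a pair of
#' co-crystal structures: one with a VH-style domain bound at each of the
#' two equivalent epitopes, one with a VK-style domain at each epitope. The
#' binder-domain termini are placed so the three inter-terminal distances
#' are *exactly* the configured values: the two VH C-termini `d_vh_vh`
#' apart, the two VK N-termini `d_vk_vk` apart, and each VH C-terminus
#' `d_cross` from the VK N-terminus at the opposite epitope. The defaults
#' reproduce the 81/70/77 Angstrom layout of the VEGF system.
#'
#' Geometry: termini are placed on a C2 axis (z). With radii
#' `r_p = d_vh_vh/2`, `r_q = d_vk_vk/2`, the VK termini are lifted by
#' `h = sqrt(d_cross^2 - (r_p+r_q)^2)` when the cross distance exceeds the
#' in-plane span, or rotated in-plane otherwise; a cross distance below
#' `|r_p - r_q|` is geometrically impossible and raises an error.
#'
#' @param d_vh_vh,d_vk_vk,d_cross Target separations in Angstrom
#'   (defaults 81, 70, 77).
#' @param antigen_residues,binder_residues Residues per chain (C-alpha
#'   only).
#' @param displace_second Apply a rigid motion to the VK complex so that
#'   antigen superposition is non-trivial? Default `TRUE`.
#' @param seed Integer seed controlling the rigid displacement; the
#'   construction is a pure function of its arguments.
#' @return List with `vh_complex` and `vk_complex` (`structure3d`; antigen
#'   chains `A`,`B`, binder chains `C`,`D`) and `truth` (the configured
#'   separations).
#' @export
make_toy_complex <- function(d_vh_vh = 81, d_vk_vk = 70, d_cross = 77,
                             antigen_residues = 24, binder_residues = 12,
                             displace_second = TRUE, seed = 1) {
  if (any(c(d_vh_vh, d_vk_vk, d_cross) < 0))
    stop("separations must be >= 0")
  r_p <- d_vh_vh / 2
  r_q <- d_vk_vk / 2
  # VH C-termini at +-(r_p, 0, 0); VK N-termini C2-related about z
  p1 <- c(r_p, 0, 0)
  lift2 <- d_cross^2 - (r_p + r_q)^2
  if (lift2 >= 0) {
    q1 <- c(-r_q, 0, sqrt(lift2))
  } else {
    if (d_cross < abs(r_p - r_q) - 1e-9)
      stop(sprintf(
        "impossible geometry: d_cross %.1f below minimum %.1f for the given vh/vk separations",
        d_cross, abs(r_p - r_q)))
    cos_a <- (r_p^2 + r_q^2 - d_cross^2) / (2 * r_p * r_q)
    cos_a <- min(max(cos_a, -1), 1)
    q1 <- c(r_q * cos_a, r_q * sqrt(1 - cos_a^2), 0)
  }
  c2 <- function(v) c(-v[1], -v[2], v[3])
  p2 <- c2(p1); q2 <- c2(q1)

  spacing <- 3.8
  strand <- function(end_point, direction, n, from_end) {
    # CA positions; from_end=TRUE anchors the LAST residue at end_point
    direction <- direction / sqrt(sum(direction^2))
    offs <- if (from_end) rev(seq_len(n) - 1) else seq_len(n) - 1
    t(vapply(offs, function(k) end_point + k * spacing * direction,
             numeric(3)))
  }
  ca_chain <- function(chain_id, coords, resno_start = 1L) {
    n <- nrow(coords)
    data.frame(chain = chain_id,
               resno = seq.int(resno_start, length.out = n),
               insert = "", resid = "ALA", elety = "CA", elesy = "C",
               x = coords[, 1], y = coords[, 2], z = coords[, 3], o = 1,
               stringsAsFactors = FALSE)
  }
  # two-fold symmetric antigen dimer straddling the origin
  half <- antigen_residues
  ag_a <- strand(c(-2, 3, -8), c(-1, 0.2, 0), half, from_end = FALSE)
  ag_b <- t(apply(ag_a, 1, c2))
  antigen <- rbind(ca_chain("A", ag_a), ca_chain("B", ag_b))

  up <- c(0, 0, 1)
  vh_c <- strand(p1, up, binder_residues, from_end = TRUE)   # C-term at p1
  vh_d <- t(apply(vh_c, 1, c2))                              # C-term at p2
  vk_c <- strand(q1, up, binder_residues, from_end = FALSE)  # N-term at q1
  vk_d <- t(apply(vk_c, 1, c2))                              # N-term at q2
  vh_complex <- new_structure3d(
    rbind(antigen, ca_chain("C", vh_c), ca_chain("D", vh_d)),
    source_id = "toy_vh_complex")
  vk_atoms <- rbind(antigen, ca_chain("C", vk_c), ca_chain("D", vk_d))
  if (displace_second) {
    R <- rotation_from_seed(seed)
    shift <- c(25, -40, 15)
    xyz <- as.matrix(vk_atoms[, c("x", "y", "z")])
    vk_atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, shift, "+")
  }
  vk_complex <- new_structure3d(vk_atoms, source_id = "toy_vk_complex")
  list(vh_complex = vh_complex, vk_complex = vk_complex,
       truth = list(d_vh_vh = d_vh_vh, d_vk_vk = d_vk_vk,
                    d_cross = d_cross,
                    vh_terminal = rbind(p1, p2), vk_terminal = rbind(q1, q2)))
}

# deterministic proper rotation derived from an integer seed
rotation_from_seed <- function(seed) {
  g <- function(k) sin(seed * 97.13 + k * 12.9898) * 43758.5453 %% 1
  axis <- c(g(1), g(2), g(3)) - 0.5
  axis <- axis / sqrt(sum(axis^2))
  angle <- (g(4) %% 1) * pi
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# ---- SEC-MALLS mixing series -----------------------------------------------

#' Scenario configuration for synthetic mixing series
#'
#' @param name One of `"dualdab_side_on"`, `"igg_network"`, `"trap_1to1"`.
#' @param binder_mass_kda,antigen_mass_kda Component masses (defaults by
#'   scenario: 109/148/115 binder, 48 antigen).
#' @param ratios List of binder:antigen molar ratios, e.g.
#'   `list(c(1,1), c(1,2), c(2,1), c(4,1))`.
#' @param base_nmol Amount scale: one ratio "part" corresponds to this many
#'   nmol injected (default 0.5).
#' @param noise_sd Detector noise passed to [simulate_chromatogram()].
#' @param seed Integer seed.
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(name = c("dualdab_side_on", "igg_network",
                                     "trap_1to1"),
                            binder_mass_kda = NULL, antigen_mass_kda = 48,
                            ratios = list(c(1, 1), c(1, 2), c(2, 1), c(4, 1)),
                            base_nmol = 0.5,
                            noise_sd = c(uv = 0, ri = 0, ls = 0),
                            seed = 1) {
  name <- match.arg(name)
  if (is.null(binder_mass_kda))
    binder_mass_kda <- switch(name, dualdab_side_on = 109,
                              igg_network = 148, trap_1to1 = 115)
  if (any(vapply(ratios, function(r)
    length(r) != 2 || any(r < 0) || r[1] <= 0, TRUE)))
    stop("each ratio needs a positive binder part and a non-negative antigen part")
  structure(list(name = name, binder_mass_kda = binder_mass_kda,
                 antigen_mass_kda = antigen_mass_kda, ratios = ratios,
                 base_nmol = base_nmol, noise_sd = noise_sd, seed = seed),
            class = "scenario_config")
}

# simplified equilibrium occupancy: how many nmol of each species form from
# B nmol binder and G nmol antigen under each scenario's engagement rules
scenario_composition <- function(name, B, G) {
  sp <- function(label, nb, na, nmol)
    data.frame(label = label, n_binders = nb, n_antigens = na, nmol = nmol)
  out <- switch(
    name,
    dualdab_side_on = {
      # each molecule traps up to two antigen dimers; closed 1:1 / 1:2 only
      x <- max(min(B, G - B), 0)              # 1:2 complexes
      if (G >= 2 * B) x <- B
      y <- min(B - x, G - 2 * x)              # 1:1 complexes
      rbind(sp("1:2", 1, 2, x), sp("1:1", 1, 1, y),
            sp("1:0", 1, 0, B - x - y), sp("0:1", 0, 1, G - 2 * x - y))
    },
    igg_network = {
      # bivalent binder + bivalent antigen: ladder of n:n complexes
      n <- min(B, G)
      w <- c(`2` = 0.6, `3` = 0.3, `4` = 0.1)
      rows <- lapply(names(w), function(k) {
        kk <- as.integer(k)
        sp(paste0(k, ":", k), kk, kk, w[[k]] * n / kk)
      })
      rbind(do.call(rbind, rows), sp("1:0", 1, 0, B - n), sp("0:1", 0, 1, G - n))
    },
    trap_1to1 = {
      y <- min(B, G)
      rbind(sp("1:1", 1, 1, y), sp("1:0", 1, 0, B - y),
            sp("0:1", 0, 1, G - y))
    },
    stop("unknown scenario: ", name))
  out[out$nmol > 1e-12, , drop = FALSE]
}

# retention model: larger complexes elute earlier (log-linear column)
retention_of_mass <- function(mass_kda, t0 = 1500, slope = 400) {
  t0 - slope * log10(mass_kda)
}

#' Simulate a SEC-MALLS mixing series for a scenario
#'
#' For each binder:antigen molar ratio, allocates the injected material to
#' complex species according to the scenario's engagement rules
#' (dual-domain antibody: closed 1:1/1:2 only; bivalent IgG: a ladder of
#' n:n network complexes; trap: strict 1:1), assigns each species a
#' retention time from a log-linear column model, and forward-simulates the
#' three-detector chromatogram.
#'
#' @param scenario A [scenario_config()].
#' @param calibration A [malls_calibration()].
#' @param time Time grid, s.
#' @return List with one element per ratio, each containing `ratio`,
#'   `composition` (ground-truth species table) and `chromatogram`.
#' @export
make_mixing_series <- function(scenario, calibration = malls_calibration(),
                               time = seq(0, 1800, by = 2)) {
  stopifnot(inherits(scenario, "scenario_config"))
  lapply(seq_along(scenario$ratios), function(i) {
    r <- scenario$ratios[[i]]
    B <- r[1] * scenario$base_nmol
    G <- r[2] * scenario$base_nmol
    comp <- scenario_composition(scenario$name, B, G)
    comp$mass_kda <- comp$n_binders * scenario$binder_mass_kda +
      comp$n_antigens * scenario$antigen_mass_kda
    comp$amount_ug <- comp$nmol * comp$mass_kda   # nmol x kDa = ug
    comp$retention_s <- retention_of_mass(comp$mass_kda)
    comp$width_s <- 25
    chrom <- simulate_chromatogram(
      comp[, c("mass_kda", "amount_ug", "retention_s", "width_s")],
      time = time, calibration = calibration,
      noise_sd = scenario$noise_sd,
      seed = scenario$seed + i)
    chrom$injected <- comp
    list(ratio = r, composition = comp, chromatogram = chrom)
  })
}

# ---- SPR datasets -----------------------------------------------------------

#' Simulate an SPR kinetics dataset with a ground-truth manifest
#'
#' Forward-simulates a concentration series of 1:1 Langmuir sensorgrams
#' (default concentrations 32, 8, 2, 0.5, 0.125 and 0.03 nM) and returns
#' them together with a manifest holding the generating parameters, so
#' recovery tests read the truth from the manifest rather than from the
#' signal path. Optionally writes each sensorgram as delimited text plus a
#' `manifest.tsv` into a directory.
#'
#' @param ka,kd,rmax Generating parameters.
#' @param conc Analyte concentrations, M.
#' @param t_assoc,t_diss Phase durations, s.
#' @param noise_sd Noise, RU.
#' @param seed Integer seed; curve i uses `seed + i`.
#' @param dir Optional output directory.
#' @return List with `sensorgrams` and `manifest`
#'   (`ka`, `kd`, `rmax`, `kd_pm`).
#' @export
make_kinetics_dataset <- function(ka, kd, rmax = 20,
                                  conc = c(32, 8, 2, 0.5, 0.125, 0.03) * 1e-9,
                                  t_assoc = 300, t_diss = 600,
                                  noise_sd = 0, seed = 1, dir = NULL) {
  if (!length(conc)) stop("empty concentration list")
  sgs <- lapply(seq_along(conc), function(i)
    simulate_sensorgram(ka, kd, rmax, conc[i], t_assoc, t_diss,
                        noise_sd = noise_sd, seed = seed + i))
  manifest <- list(ka = ka, kd = kd, rmax = rmax,
                   kd_pm = kd_from_rates(ka, kd, signif_digits = NULL))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(sgs))
      write_sensorgram(sgs[[i]],
                       file.path(dir, sprintf("sensorgram_%02d.tsv", i)))
    utils::write.table(
      data.frame(key = names(manifest), value = unlist(manifest)),
      file.path(dir, "manifest.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(sensorgrams = sgs, manifest = manifest)
}

#' Write a sensorgram as delimited text
#' @param sensorgram A `"sensorgram"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensorgram <- function(sensorgram, path) {
  stopifnot(inherits(sensorgram, "sensorgram"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# conc_molar: %.10g", sensorgram$conc),
               sprintf("# t_assoc_s: %.10g", sensorgram$t_assoc),
               "# columns: time\tresponse"), con)
  utils::write.table(
    data.frame(time = sensorgram$time, response = sensorgram$response),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sensorgram written by [write_sensorgram()]
#' @param path Input path.
#' @return A `"sensorgram"` object.
#' @export
read_sensorgram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  get_num <- function(key, default) {
    ln <- grep(key, header, value = TRUE)
    if (length(ln)) as.numeric(sub(".*:\\s*", "", ln[1])) else default
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = body, sep = "\t",
                          col.names = c("time", "response"))
  structure(list(time = df$time, response = df$response,
                 conc = get_num("conc_molar", NA_real_),
                 t_assoc = get_num("t_assoc_s", max(df$time))),
            class = "sensorgram")
}
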