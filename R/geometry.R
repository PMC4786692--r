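# Rigid-body superposition, terminal distances, interface contacts and
# crystal solvent content.

#' Kabsch least-squares superposition
#'
#' Closed-form optimal rigid superposition of two paired point sets. The
#' cross-covariance matrix is decomposed by SVD and the reflection case is
#' resolved by the usual determinant correction, so the returned rotation is
#' always proper (det = +1). The transform maps `moving` onto `fixed`:
#' `x_new = x %*% t(R) + t` for row coordinates.
#'
#' @param moving,fixed n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return An object of class `"superposition"`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom, after transformation) and
#'   `n_atoms`.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)))
    stop("point sets differ in size")
  if (ncol(moving) != 3) stop("coordinates must be n x 3")
  n <- nrow(moving)
  if (n < 3) stop("need at least 3 paired points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  # collinearity => rank of the centered cloud < 2
  if (min(svd(P)$d[2], svd(Q)$d[2]) < 1e-8 * max(1, max(abs(P)), max(abs(Q))))
    stop("degenerate (collinear) point set: superposition ill-conditioned")
  H <- crossprod(P, Q)                       # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # proper rotation, q ~ R p
  t_vec <- as.numeric(cf - R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition over %d atoms: rmsd %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 coordinate matrix.
#' @param sup A `"superposition"` object from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

# matched C-alpha coordinates for one mapped chain pair, matched by resno
matched_ca <- function(sa, chain_a, sb, chain_b) {
  a <- chain_atoms(sa, chain_a); b <- chain_atoms(sb, chain_b)
  a <- a[a$elety == "CA", ]; b <- b[b$elety == "CA", ]
  key_a <- paste(a$resno, a$insert); key_b <- paste(b$resno, b$insert)
  common <- intersect(key_a, key_b)
  list(a = as.matrix(a[match(common, key_a), c("x", "y", "z")]),
       b = as.matrix(b[match(common, key_b), c("x", "y", "z")]))
}

#' Superpose one complex onto another via shared antigen chains
#'
#' Least-squares fits the antigen chains of `complex_b` onto the mapped
#' antigen chains of `complex_a` (C-alpha atoms matched by residue number)
#' and applies the resulting rigid transform to *all* atoms of `complex_b`.
#' This is the step that places two independently solved antigen/binder
#' complexes in one frame so cross-complex distances can be measured.
#'
#' @param complex_a,complex_b `structure3d` objects sharing an antigen.
#' @param antigen_map Named character vector or list mapping chains of
#'   `complex_a` to chains of `complex_b`, e.g. `c(A = "A", B = "B")`.
#' @param max_rmsd Sanity cap in Angstrom (default 5); a larger antigen rmsd
#'   sets a warning flag but does not fail.
#' @return `complex_b` transformed into `complex_a`'s frame, with attributes
#'   `antigen_rmsd`, `n_matched` and `rmsd_flag`.
#' @export
superpose_on_antigen <- function(complex_a, complex_b, antigen_map,
                                 max_rmsd = 5) {
  map <- unlist(antigen_map)
  if (is.null(names(map)) || any(names(map) == ""))
    stop("antigen_map must name chains of complex_a")
  A <- NULL; B <- NULL
  for (i in seq_along(map)) {
    m <- matched_ca(complex_a, names(map)[i], complex_b, map[[i]])
    A <- rbind(A, m$a); B <- rbind(B, m$b)
  }
  if (is.null(A) || nrow(A) < 3)
    stop("fewer than 3 matched antigen C-alpha positions")
  sup <- kabsch_superpose(B, A)
  out <- complex_b
  out$atoms[, c("x", "y", "z")] <-
    apply_superposition(as.matrix(complex_b$atoms[, c("x", "y", "z")]), sup)
  flag <- sup$rmsd > max_rmsd
  if (flag)
    warning(sprintf("antigen rmsd %.2f A exceeds sanity cap %.2f A",
                    sup$rmsd, max_rmsd))
  attr(out, "antigen_rmsd") <- sup$rmsd
  attr(out, "n_matched") <- sup$n_atoms
  attr(out, "rmsd_flag") <- flag
  out
}

#' Inter-terminal C-alpha distances of a two-fold engaged antigen
#'
#' Measures the three separations that decide whether linkers of a
#' dual-domain-antibody can reach both bound domains: the distance between
#' the two VH-domain attachment termini (C-terminal C-alpha by default),
#' between the two VK-domain attachment termini (N-terminal C-alpha), and
#' the "cross" distance from each VH terminus to the VK terminus at the
#' *opposite* epitope (taken as the farther of the two VK termini, averaged
#' over the two VH chains).
#'
#' @param structure A `structure3d`, typically a merged frame from
#'   [superpose_on_antigen()].
#' @param vh_chains,vk_chains Character vectors (length 2 for the
#'   corresponding distance; either may be `NULL`, leaving that field `NA`).
#' @param vh_end,vk_end Which terminus anchors each domain type; defaults
#'   `"c_term"` for VH (its C-terminus joins the Fc N-terminal linker) and
#'   `"n_term"` for VK (its N-terminus joins the Fc C-terminal linker).
#' @return Object of class `"terminal_distances"`: list with `d_vh_vh`,
#'   `d_vk_vk`, `d_cross` (Angstrom, `NA` where chains were not supplied)
#'   and `provenance`.
#' @export
terminal_distances <- function(structure, vh_chains = NULL, vk_chains = NULL,
                               vh_end = "c_term", vk_end = "n_term") {
  for (ch in c(vh_chains, vk_chains))
    if (!ch %in% chain_ids(structure)) stop("chain not in structure: ", ch)
  term <- function(chains, end)
    lapply(chains, function(ch) chain_terminal_ca(structure, ch, end))
  d <- function(p, q) sqrt(sum((p - q)^2))
  vh <- if (length(vh_chains)) term(vh_chains, vh_end)
  vk <- if (length(vk_chains)) term(vk_chains, vk_end)
  d_vh_vh <- if (length(vh) == 2) d(vh[[1]], vh[[2]]) else NA_real_
  d_vk_vk <- if (length(vk) == 2) d(vk[[1]], vk[[2]]) else NA_real_
  d_cross <- NA_real_
  if (length(vh) >= 1 && length(vk) >= 1) {
    # opposite-epitope partner = the farther VK terminus from each VH terminus
    cross <- vapply(vh, function(p)
      max(vapply(vk, function(q) d(p, q), 0)), 0)
    d_cross <- mean(cross)
  }
  structure(list(d_vh_vh = d_vh_vh, d_vk_vk = d_vk_vk, d_cross = d_cross,
                 provenance = structure$source_id),
            class = "terminal_distances")
}

#' @export
print.terminal_distances <- function(x, ...) {
  cat("Inter-terminal C-alpha distances",
      if (nzchar(x$provenance)) sprintf(" (%s)", x$provenance), ":\n", sep = "")
  cat(sprintf("  VH..VH   : %s\n  VK..VK   : %s\n  VH..VK x : %s\n",
              fmt_A(x$d_vh_vh), fmt_A(x$d_vk_vk), fmt_A(x$d_cross)))
  invisible(x)
}

fmt_A <- function(d) if (is.na(d)) "not measured" else sprintf("%.1f A", d)

#' Interface residues between two chain groups
#'
#' Reports every residue pair with any heavy-atom (non-hydrogen) distance at
#' or below `cutoff`, split into the epitope side (`group_a`) and paratope
#' side (`group_b`). Both lists are deduplicated and sorted.
#'
#' @param structure A `structure3d`.
#' @param group_a,group_b Disjoint character vectors of chain ids.
#' @param cutoff Heavy-atom contact cutoff in Angstrom (default 4.5).
#' @return List with `epitope` and `paratope` data.frames (`chain`, `resno`),
#'   `pairs` (contact pairs) and `cutoff`.
#' @export
interface_residues <- function(structure, group_a, group_b, cutoff = 4.5) {
  if (!length(group_a) || !length(group_b)) stop("empty chain group")
  if (length(intersect(group_a, group_b)))
    stop("chain groups must be disjoint")
  heavy <- function(groups) {
    at <- structure$atoms[structure$atoms$chain %in% groups &
                            structure$atoms$elesy != "H", , drop = FALSE]
    if (!nrow(at)) stop("no heavy atoms in group: ",
                        paste(groups, collapse = ","))
    at
  }
  a <- heavy(group_a); b <- heavy(group_b)
  if (cutoff <= 0 || !nrow(a) || !nrow(b)) {
    empty <- data.frame(chain = character(0), resno = integer(0))
    return(list(epitope = empty, paratope = empty,
                pairs = data.frame(), cutoff = cutoff))
  }
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  hits <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  uniq_res <- function(at, idx) {
    df <- unique(data.frame(chain = at$chain[idx], resno = at$resno[idx]))
    df[order(df$chain, df$resno), , drop = FALSE]
  }
  pairs <- unique(data.frame(
    chain_a = a$chain[hits[, 1]], resno_a = a$resno[hits[, 1]],
    chain_b = b$chain[hits[, 2]], resno_b = b$resno[hits[, 2]]))
  rownames(pairs) <- NULL
  list(epitope = uniq_res(a, hits[, 1]),
       paratope = uniq_res(b, hits[, 2]),
       pairs = pairs, cutoff = cutoff)
}

#' Matthews solvent content of a crystal
#'
#' Computes the Matthews volume \eqn{V_M = V_{cell}/(Z \cdot M)} (cubic
#' Angstrom per Dalton) and the solvent fraction
#' \eqn{1 - v_p/V_M} with the conventional protein packing constant
#' \eqn{v_p = 1.23}, clamped to `[0, 1)`.
#'
#' @param cell A [crystal_cell()]; `cell$z` asymmetric units per cell.
#' @param asu_protein_mass_da Protein mass per asymmetric unit, Dalton.
#' @param packing_constant Matthews packing constant (default 1.23).
#' @return List with `vm` (A^3/Da) and `solvent_fraction`.
#' @export
solvent_content <- function(cell, asu_protein_mass_da,
                            packing_constant = 1.23) {
  stopifnot(inherits(cell, "crystal_cell"))
  if (!is.finite(asu_protein_mass_da) || asu_protein_mass_da <= 0)
    stop("asu_protein_mass_da must be positive")
  vm <- cell_volume(cell) / (cell$z * asu_protein_mass_da)
  frac <- 1 - packing_constant / vm
  frac <- min(max(frac, 0), 1 - 1e-12)
  list(vm = vm, solvent_fraction = frac)
}
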