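# Independent oracles and shared fixtures for the test suite.

# ---- rigid-motion helpers ---------------------------------------------------

rotation_xyz <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3,
               byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, 3,
               byrow = TRUE)
  rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

# Brute-force superposition oracle: numerically minimize rmsd over Euler
# angles (translation handled by centering), independent of the closed-form
# route under test.
oracle_min_rmsd <- function(moving, fixed) {
  P <- sweep(as.matrix(moving), 2, colMeans(moving))
  Q <- sweep(as.matrix(fixed), 2, colMeans(fixed))
  obj <- function(ang) {
    R <- rotation_xyz(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  starts <- as.matrix(expand.grid(a = c(0, pi / 2, pi, -pi / 2),
                                  b = c(0, pi / 2), c = c(0, pi)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# ---- merged toy structure ---------------------------------------------------

# one frame holding the VH complex plus the superposed VK binder domains
merged_toy_structure <- function(toy) {
  m <- superpose_on_antigen(toy$vh_complex, toy$vk_complex,
                            c(A = "A", B = "B"))
  vk <- m$atoms[m$atoms$chain %in% c("C", "D"), ]
  vk$chain <- ifelse(vk$chain == "C", "K", "L")
  merged <- toy$vh_complex
  merged$atoms <- rbind(merged$atoms, vk)
  merged
}

# ---- species-enumeration oracle --------------------------------------------

# Exhaustive brute-force enumeration, generated in the opposite direction to
# the implementation (per-epitope choice of binding site rather than
# per-site choice of epitope), with constraints applied wholesale to
# complete assignments and isomorphism classes counted via igraph VF2 on a
# colored expansion graph.
oracle_enumerate <- function(arch, antigen, nb, na, rules) {
  types <- vapply(arch$sites, function(s) s$domain, "")
  S <- length(types) * arch$copies_per_molecule
  slot_binder <- rep(seq_len(nb), each = S)
  slot_copy <- rep(rep(seq_len(arch$copies_per_molecule),
                       each = length(types)), nb)
  slot_type <- rep(rep(types, arch$copies_per_molecule), nb)
  E <- antigen$epitopes_per_unit
  n_eslots <- na * E
  eslot_antigen <- rep(seq_len(na), each = E)
  # every injective assignment of eslots to {unbound} + slots, generated
  # in the opposite direction to the implementation (per epitope, not per
  # site) with no domain-specific pruning
  rows <- vector("list", 1024); n_rows <- 0L
  gen <- function(i, acc) {
    if (i > n_eslots) {
      if (any(acc > 0)) {
        n_rows <<- n_rows + 1L
        if (n_rows > length(rows)) length(rows) <<- 2L * n_rows
        rows[[n_rows]] <<- acc
      }
      return()
    }
    gen(i + 1L, c(acc, 0L))
    free <- setdiff(seq_len(nb * S), acc)
    for (s in free) gen(i + 1L, c(acc, s))
  }
  gen(1L, integer(0))
  M <- do.call(rbind, rows[seq_len(n_rows)])
  classes <- list()
  class_count <- integer(0)
  for (r in seq_len(nrow(M))) {
    row <- M[r, ]
    bound <- which(row > 0)
    slots <- row[bound]
    eb <- slot_binder[slots]
    ea <- eslot_antigen[bound]
    if (length(unique(eb)) < nb || length(unique(ea)) < na) next
    ok <- TRUE
    for (a in unique(ea)) {
      idx <- which(ea == a)
      if (length(idx) < 2) next
      for (i in idx) for (j in idx) {
        if (i >= j) next
        if (eb[i] == eb[j]) {
          pr <- sort(c(slot_type[slots[i]], slot_type[slots[j]]))
          hit <- any(vapply(rules$clamp_pairs, identical, TRUE, pr))
          if (!hit) { ok <- FALSE }
        } else if (!rules$intermolecular) ok <- FALSE
      }
    }
    if (!ok) next
    if (rules$require_clamp && length(bound) < na * E) next
    g <- igraph::graph_from_edgelist(
      cbind(eb, nb + ea), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nb + na - igraph::vcount(g)))
    if (igraph::components(g)$no != 1) next
    cg <- oracle_colored_graph(nb, na, eb, slot_copy[slots],
                               slot_type[slots], ea, types,
                               arch$copies_per_molecule)
    found <- FALSE
    for (k in seq_along(classes)) {
      if (igraph::vcount(classes[[k]]$g) != igraph::vcount(cg$g)) next
      if (!identical(classes[[k]]$sig, cg$sig)) next
      if (igraph::isomorphic(classes[[k]]$g, cg$g, method = "vf2",
                             vertex.color1 = classes[[k]]$col,
                             vertex.color2 = cg$col)) {
        class_count[k] <- class_count[k] + 1L
        found <- TRUE
        break
      }
    }
    if (!found) {
      cg$closed <- length(bound) == na * E
      cg$n_bonds <- length(bound)
      classes[[length(classes) + 1]] <- cg
      class_count <- c(class_count, 1L)
    }
  }
  if (!length(classes))
    return(data.frame(n_binders = integer(0), n_antigens = integer(0),
                      n_bonds = integer(0), closed = logical(0)))
  data.frame(
    n_binders = nb, n_antigens = na,
    n_bonds = vapply(classes, function(x) x$n_bonds, 1L),
    closed = vapply(classes, function(x) x$closed, TRUE))
}

# expansion graph: binder nodes, per-binder copy hubs, antigen nodes, and
# one node per bond colored by site type; copy hubs encode which scaffold
# copy a bond uses while staying interchangeable within a molecule
oracle_colored_graph <- function(nb, na, eb, ecopy, etype, ea,
                                 types, n_copies) {
  n_bond <- length(eb)
  # vertex ids: binders 1..nb, copies nb + (b-1)*n_copies + c,
  # antigens nb + nb*n_copies + a, bonds after that
  copy_id <- function(b, cc) nb + (b - 1) * n_copies + cc
  ant_id <- function(a) nb + nb * n_copies + a
  bond_id <- function(k) nb + nb * n_copies + na + k
  edges <- c()
  for (b in seq_len(nb)) for (cc in seq_len(n_copies))
    edges <- c(edges, b, copy_id(b, cc))
  for (k in seq_len(n_bond)) {
    edges <- c(edges, bond_id(k), copy_id(eb[k], ecopy[k]),
               bond_id(k), ant_id(ea[k]))
  }
  nv <- nb + nb * n_copies + na + n_bond
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  col <- c(rep(1L, nb), rep(2L, nb * n_copies), rep(3L, na),
           3L + match(etype, sort(unique(types))))
  sig <- paste(sort(table(col)), collapse = ",")
  list(g = g, col = col, sig = sig)
}

# implementation species graph -> the same colored expansion, for duplicate
# checks against the oracle's representatives
species_colored_graph <- function(sp, arch) {
  types <- vapply(arch$sites, function(s) s$domain, "")
  site_tab <- dualreach:::molecule_sites(arch)
  e <- sp$edges
  oracle_colored_graph(sp$n_binders, sp$n_antigens, e$binder,
                       site_tab$copy[e$site], site_tab$type[e$site],
                       e$antigen, types, arch$copies_per_molecule)
}

# monovalent single-site binder used in hand-checkable enumerations
monovalent_architecture <- function(mass = 50) {
  binder_architecture(
    "monovalent", sites = list(list(domain = "fab", terminus = "n_term",
                                    linker = linker_spec(0, anchor_allowance = 0))),
    copies_per_molecule = 1L, molecule_mass_kda = mass)
}
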