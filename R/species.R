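# Enumeration of binder:antigen complex species under reach-feasibility
# rules, with predicted masses and matching to observed SEC-MALLS masses.

#' Feasibility rules for complex-species enumeration
#'
#' Encodes which binding topologies the linker-reach analysis allows:
#' \itemize{
#'   \item `clamp_pairs` — unordered pairs of site *types* of one molecule
#'     that may occupy the two epitopes of the same antigen unit
#'     (intramolecular clamp). A pair absent from the list is forbidden.
#'   \item `intermolecular` — may two different binder molecules engage the
#'     same antigen unit (one epitope each)? This is what permits chain and
#'     ring growth.
#'   \item `require_clamp` — must every bound antigen be fully clamped at
#'     all of its epitopes (avid engagement), as opposed to dangling
#'     single-epitope attachment?
#' }
#'
#' @param clamp_pairs List of length-2 character vectors of site types.
#' @param intermolecular Logical.
#' @param require_clamp Logical.
#' @return Object of class `"feasibility_rules"`.
#' @export
feasibility_rules <- function(clamp_pairs = list(), intermolecular = TRUE,
                              require_clamp = FALSE) {
  clamp_pairs <- lapply(clamp_pairs, function(p) sort(as.character(p)))
  structure(list(clamp_pairs = clamp_pairs,
                 intermolecular = isTRUE(intermolecular),
                 require_clamp = isTRUE(require_clamp)),
            class = "feasibility_rules")
}

#' Default dual-domain-antibody rules
#'
#' Side-on (VH+VK) and bottom end-on (VK+VK) clamps are reach-feasible;
#' the VH+VK pair per molecule half can clamp an antigen laterally and the
#' two VK domains can clamp one antigen at the bottom, while the VH+VH
#' top clamp is forbidden (linkers cannot span it). Engagement is avid
#' (every bound antigen clamped) and sharing of one antigen between two
#' binder molecules is off by default: the corresponding ~370 kDa
#' twinned species is not observed experimentally.
#'
#' @param share_antigen Allow two molecules to share one antigen unit?
#' @return A [feasibility_rules()] object.
#' @export
dual_dab_rules <- function(share_antigen = FALSE) {
  feasibility_rules(
    clamp_pairs = list(c("vh", "vk"), c("vk", "vk")),
    intermolecular = share_antigen,
    require_clamp = TRUE)
}

#' Conventional-IgG rules: no intramolecular clamp, intermolecular bridging
#' allowed, single-epitope attachment allowed (chains and rings can grow).
#' @return A [feasibility_rules()] object.
#' @export
igg_rules <- function() {
  feasibility_rules(clamp_pairs = list(), intermolecular = TRUE,
                    require_clamp = FALSE)
}

# ---- enumeration ------------------------------------------------------------

# site table of one molecule: copy index, within-copy position, type
molecule_sites <- function(arch) {
  types <- vapply(arch$sites, function(s) s$domain, "")
  if (anyDuplicated(types))
    stop("site types must be unique within a scaffold copy")
  data.frame(copy = rep(seq_len(arch$copies_per_molecule), each = length(types)),
             pos = rep(seq_along(types), arch$copies_per_molecule),
             type = rep(types, arch$copies_per_molecule),
             stringsAsFactors = FALSE)
}

#' Predicted mass of a complex species
#'
#' Plain arithmetic sum: `n_binders * binder mass + n_antigens * antigen
#' unit mass`, matching how SEC-MALLS masses are compared with candidate
#' stoichiometries.
#'
#' @param n_binders,n_antigens Non-negative counts.
#' @param architecture A [binder_architecture()].
#' @param antigen An [antigen_model()].
#' @return Mass in kDa.
#' @export
species_mass <- function(n_binders, n_antigens, architecture, antigen) {
  if (n_binders < 0 || n_antigens < 0) stop("counts must be >= 0")
  n_binders * architecture$molecule_mass_kda +
    n_antigens * antigen$unit_mass_kda
}

#' Enumerate feasible binder:antigen complex species
#'
#' Generates every connected, non-isomorphic complex of up to `max_binders`
#' binder molecules and `max_antigens` antigen units in which each binding
#' site and each epitope carries at most one bond and every bond pattern
#' obeys the [feasibility_rules()]. Isomorphic duplicates are removed by
#' canonical labelling over the full symmetry group (permutations of binder
#' molecules, of antigen units, of equivalent scaffold copies within a
#' molecule, and of equivalent epitopes within an antigen).
#'
#' @param architecture A [binder_architecture()].
#' @param antigen An [antigen_model()].
#' @param max_binders,max_antigens Enumeration limits (>= 1).
#' @param rules A [feasibility_rules()] object.
#' @param max_explore Cap on explored partial assignments; exceeding it
#'   raises an overflow error rather than running unbounded.
#' @return Object of class `"species_catalog"`.
#' @export
enumerate_species <- function(architecture, antigen, max_binders,
                              max_antigens, rules = igg_rules(),
                              max_explore = 2e5) {
  stopifnot(inherits(architecture, "binder_architecture"),
            inherits(antigen, "antigen_model"),
            inherits(rules, "feasibility_rules"))
  if (max_binders < 1 || max_antigens < 1) stop("limits must be >= 1")
  sites <- molecule_sites(architecture)
  E <- antigen$epitopes_per_unit
  seen <- new.env(parent = emptyenv())
  out <- list()
  counter <- new.env(parent = emptyenv()); counter$n <- 0
  add_species <- function(nb, na, edges) {
    key <- canonical_species_key(nb, na, edges, sites, E)
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    closed <- na >= 1 && nrow(edges) == na * E
    out[[length(out) + 1]] <<- structure(
      list(n_binders = nb, n_antigens = na,
           edges = edges,
           mass_kda = species_mass(nb, na, architecture, antigen),
           label = paste0(nb, ":", na), closed = closed),
      class = "species_graph")
  }
  # free components
  add_species(1L, 0L, empty_edges())
  add_species(0L, 1L, empty_edges())
  for (nb in seq_len(max_binders)) {
    for (na in seq_len(max_antigens)) {
      # no intermolecular sharing => a connected species has one binder
      if (!rules$intermolecular && nb > 1) next
      enumerate_assignments(nb, na, sites, E, rules, counter, max_explore,
                            add_species)
    }
  }
  structure(list(species = out, architecture = architecture,
                 antigen = antigen,
                 limits = c(binders = max_binders, antigens = max_antigens),
                 rules = rules),
            class = "species_catalog")
}

empty_edges <- function() {
  data.frame(binder = integer(0), site = integer(0),
             antigen = integer(0), epitope = integer(0))
}

# Depth-first assignment of site slots to epitope slots with constraint
# pruning; calls `emit` for every valid fully-connected assignment.
enumerate_assignments <- function(nb, na, sites, E, rules, counter,
                                  max_explore, emit) {
  S <- nrow(sites)
  n_slots <- nb * S
  n_eslots <- na * E
  slot_binder <- rep(seq_len(nb), each = S)
  slot_site <- rep(seq_len(S), nb)
  eslot_antigen <- rep(seq_len(na), each = E)
  allowed_pair <- function(t1, t2) {
    p <- sort(c(t1, t2))
    for (cp in rules$clamp_pairs)
      if (identical(cp, p)) return(TRUE)
    FALSE
  }
  assign_vec <- integer(n_slots)        # 0 = unbound, else epitope slot
  recurse <- function(i) {
    counter$n <- counter$n + 1
    if (counter$n > max_explore)
      stop("species enumeration overflow: more than ", max_explore,
           " partial assignments explored; lower the limits")
    if (i > n_slots) { finalize(); return() }
    assign_vec[i] <<- 0L
    recurse(i + 1)
    b <- slot_binder[i]; t_i <- sites$type[slot_site[i]]
    for (es in seq_len(n_eslots)) {
      if (es %in% assign_vec[seq_len(i - 1)]) next
      a <- eslot_antigen[es]
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (assign_vec[j] == 0L) next
        if (eslot_antigen[assign_vec[j]] != a) next
        if (slot_binder[j] == b) {
          # same molecule on the same antigen: must be an allowed clamp
          if (!allowed_pair(sites$type[slot_site[j]], t_i)) { ok <- FALSE; break }
        } else if (!rules$intermolecular) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[i] <<- es
      recurse(i + 1)
      assign_vec[i] <<- 0L
    }
  }
  finalize <- function() {
    bound <- which(assign_vec > 0L)
    if (length(bound) == 0L) return()
    eb <- slot_binder[bound]; ea <- eslot_antigen[assign_vec[bound]]
    if (length(unique(eb)) < nb || length(unique(ea)) < na) return()
    if (rules$require_clamp && length(bound) < na * E) return()
    if (!connected_units(nb, na, eb, ea)) return()
    emit(nb, na, data.frame(
      binder = eb, site = slot_site[bound],
      antigen = ea,
      epitope = ((assign_vec[bound] - 1L) %% E) + 1L))
  }
  recurse(1L)
}

# union-find connectivity over nb binder + na antigen nodes
connected_units <- function(nb, na, edge_binder, edge_antigen) {
  n <- nb + na
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(edge_binder)) {
    r1 <- find(edge_binder[k]); r2 <- find(nb + edge_antigen[k])
    if (r1 != r2) parent[r1] <- r2
  }
  length(unique(vapply(seq_len(n), find, 1L))) == 1L
}

# Canonical key: lexicographic minimum of the serialized edge list over all
# symmetry operations (binder perms x per-binder copy perms x antigen perms
# x per-antigen epitope perms). Site identity is reduced to (type, copy) so
# equivalent scaffold copies are interchangeable. The whole group is applied
# as vectorized matrix indexing: one row per group element, one column per
# bond, each entry a packed integer code.
canonical_species_key <- function(nb, na, edges, sites, E) {
  if (!nrow(edges)) return(paste0("free:", nb, ":", na))
  n_copies <- max(sites$copy)
  bp <- perm_matrix(nb)                       # binder permutations
  ap <- perm_matrix(na)                       # antigen permutations
  cc <- per_unit_perms(n_copies, nb)          # per-binder copy perms
  copy_of <- sites$copy[edges$site]
  type_of <- match(sites$type[edges$site], sort(unique(sites$type)))
  pos_of <- sites$pos[edges$site]
  nk <- nrow(edges)
  # Epitope indices are NOT part of the identity: epitopes of one antigen
  # are equivalent and each carries at most one bond, so relabelling them
  # is always a symmetry. Component contribution matrices below have one
  # row per group-component element and one column per bond.
  Bm <- bp[, edges$binder, drop = FALSE] * 1e5
  Am <- ap[, edges$antigen, drop = FALSE]
  Cm <- matrix(0L, nrow(cc$index), nk)
  for (g in seq_len(nrow(cc$index)))
    Cm[g, ] <- vapply(seq_len(nk), function(k)
      cc$perms[[cc$index[g, edges$binder[k]]]][copy_of[k]], 1L)
  Cm <- Cm * 1e4
  const <- pos_of * 1e3 + type_of * 1e2
  # full group = outer product of the three components
  gidx <- expand.grid(b = seq_len(nrow(Bm)), c = seq_len(nrow(Cm)),
                      a = seq_len(nrow(Am)))
  X <- Bm[gidx$b, , drop = FALSE] + Cm[gidx$c, , drop = FALSE] +
    Am[gidx$a, , drop = FALSE] + rep(const, each = nrow(gidx))
  X <- sort_rows(X)                           # bond order is immaterial
  # lexicographic minimum row
  rows <- seq_len(nrow(X))
  for (j in seq_len(ncol(X))) {
    rows <- rows[X[rows, j] == min(X[rows, j])]
    if (length(rows) == 1L) break
  }
  paste0(nb, ":", na, "#", paste(X[rows[1], ], collapse = ","))
}

# sort each row ascending via a vectorized bubble comparator network
# (few columns, many rows)
sort_rows <- function(X) {
  n <- ncol(X)
  if (n < 2) return(X)
  for (p in seq_len(n - 1)) {
    for (i in seq_len(n - p)) {
      lo <- pmin(X[, i], X[, i + 1]); hi <- pmax(X[, i], X[, i + 1])
      X[, i] <- lo; X[, i + 1] <- hi
    }
  }
  X
}

# all permutations of 1..n as a matrix (one per row)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# independent choice of one permutation of 1..n for each of n_units units:
# returns the base perms plus an index grid (choice rows x units)
per_unit_perms <- function(n, n_units) {
  pm <- perm_matrix(n)
  perms <- lapply(seq_len(nrow(pm)), function(i) pm[i, ])
  index <- as.matrix(expand.grid(rep(list(seq_along(perms)), n_units)))
  storage.mode(index) <- "integer"
  list(perms = perms, index = index)
}

#' @export
print.species_catalog <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Species catalog: %s binder + %s antigen, limits (%d, %d), %d species\n",
              x$architecture$name, x$antigen$name,
              x$limits["binders"], x$limits["antigens"], nrow(df)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.species_catalog <- function(x, ...) {
  do.call(rbind, lapply(x$species, function(s)
    data.frame(label = s$label, n_binders = s$n_binders,
               n_antigens = s$n_antigens, n_bonds = nrow(s$edges),
               mass_kda = s$mass_kda, closed = s$closed)))
}

# ---- mass matching ----------------------------------------------------------

#' Match an observed molar mass to enumerated species
#'
#' Ranks the unique compositions of a catalog by relative mass error
#' against an observed mass (or an observed mass interval), keeping those
#' within `rel_tol` (the ~10-15% accuracy band conventional for SEC-MALLS
#' conjugate masses). For an interval, any overlap between the interval and
#' the species' tolerance band counts as a match and the error is zero
#' inside the interval, else the relative distance to its nearest endpoint.
#'
#' @param catalog A `"species_catalog"` from [enumerate_species()].
#' @param observed_mass Scalar mass in kDa, or a length-2 interval
#'   `c(lo, hi)`.
#' @param rel_tol Relative tolerance (default 0.15).
#' @param closed_only Restrict to closed (fully clamped/ring) species?
#'   Default `FALSE`.
#' @return data.frame with `label`, `n_binders`, `n_antigens`, `mass_kda`,
#'   `rel_error`, sorted by increasing error (may be empty).
#' @export
match_species <- function(catalog, observed_mass, rel_tol = 0.15,
                          closed_only = FALSE) {
  stopifnot(inherits(catalog, "species_catalog"))
  if (rel_tol <= 0) stop("rel_tol must be positive")
  obs <- sort(as.numeric(observed_mass))
  if (any(obs <= 0) || !length(obs) %in% c(1L, 2L))
    stop("observed_mass must be a positive scalar or length-2 interval")
  df <- as.data.frame(catalog)
  if (closed_only) df <- df[df$closed, , drop = FALSE]
  df <- unique(df[, c("label", "n_binders", "n_antigens", "mass_kda")])
  if (!nrow(df)) stop("empty species catalog")
  if (length(obs) == 1L) {
    err <- abs(df$mass_kda - obs) / obs
    keep <- err <= rel_tol
  } else {
    below <- df$mass_kda < obs[1]; above <- df$mass_kda > obs[2]
    err <- numeric(nrow(df))
    err[below] <- (obs[1] - df$mass_kda[below]) / obs[1]
    err[above] <- (df$mass_kda[above] - obs[2]) / obs[2]
    # any overlap of the species' tolerance band with the interval
    keep <- df$mass_kda * (1 + rel_tol) >= obs[1] &
      df$mass_kda * (1 - rel_tol) <= obs[2]
  }
  res <- df[keep, , drop = FALSE]
  res$rel_error <- err[keep]
  res <- res[order(res$rel_error, res$mass_kda), , drop = FALSE]
  rownames(res) <- NULL
  res
}
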