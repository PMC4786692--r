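# Complex-species enumeration and mass matching.

antigen <- antigen_model()

test_that("species mass is a plain arithmetic sum", {
  dd <- dual_dab_architecture()
  igg <- igg_architecture()
  expect_equal(species_mass(1, 2, dd, antigen), 205)
  expect_equal(species_mass(2, 2, igg, antigen), 392)
  expect_equal(species_mass(0, 1, dd, antigen), 48)
  # additive and permutation-invariant in the counts
  expect_equal(species_mass(3, 1, dd, antigen) + species_mass(0, 2, dd, antigen),
               species_mass(3, 3, dd, antigen))
  expect_error(species_mass(-1, 0, dd, antigen), ">= 0")
})

test_that("monovalent binder on a two-epitope dimer yields 1:1 and 2:1", {
  mono <- monovalent_architecture()
  cat_m <- enumerate_species(mono, antigen, 2, 2, igg_rules())
  df <- as.data.frame(cat_m)
  bound <- df[df$n_bonds > 0, ]
  expect_setequal(bound$label, c("1:1", "2:1"))
  # agrees with the igraph brute-force oracle cell by cell
  for (nb in 1:2) for (na in 1:2) {
    got <- df[df$n_binders == nb & df$n_antigens == na & df$n_bonds > 0, ]
    oracle <- oracle_enumerate(mono, antigen, nb, na, igg_rules())
    expect_equal(nrow(got), nrow(oracle),
                 info = sprintf("monovalent cell (%d,%d)", nb, na))
  }
})

test_that("dual-dAb rules admit only clamped 1:1 and 1:2 closed species", {
  dd <- dual_dab_architecture()
  cat_dd <- enumerate_species(dd, antigen, 3, 3, dual_dab_rules())
  df <- as.data.frame(cat_dd)
  closed <- df[df$closed, ]
  expect_setequal(unique(closed$label), c("1:1", "1:2"))
  # avid engagement: no dangling antigen, so every bound species is closed
  expect_true(all(df$n_bonds[!df$closed] == 0))
  # every species holds at most two antigen dimers per binder molecule
  expect_true(all(df$n_antigens[df$n_binders == 1] <= 2))
  # no multi-binder chains without antigen sharing
  expect_true(all(df$n_binders <= 1 | df$n_bonds == 0))
})

test_that("dual-dAb enumeration matches the brute-force oracle", {
  dd <- dual_dab_architecture()
  rules <- dual_dab_rules()
  cat_dd <- enumerate_species(dd, antigen, 2, 2, rules)
  df <- as.data.frame(cat_dd)
  for (nb in 1:2) for (na in 1:2) {
    got <- df[df$n_binders == nb & df$n_antigens == na & df$n_bonds > 0, ]
    oracle <- oracle_enumerate(dd, antigen, nb, na, rules)
    expect_equal(nrow(got), nrow(oracle),
                 info = sprintf("dual-dAb cell (%d,%d)", nb, na))
    if (nrow(oracle))
      expect_equal(sort(got$n_bonds), sort(oracle$n_bonds),
                   info = sprintf("dual-dAb bonds (%d,%d)", nb, na))
  }
})

test_that("no two emitted species are isomorphic (canonical dedup works)", {
  dd <- dual_dab_architecture()
  cat_dd <- enumerate_species(dd, antigen, 2, 2, dual_dab_rules())
  sp <- Filter(function(s) nrow(s$edges) > 0, cat_dd$species)
  graphs <- lapply(sp, species_colored_graph, arch = dd)
  for (i in seq_along(graphs)) for (j in seq_along(graphs)) {
    if (i >= j) next
    if (sp[[i]]$n_binders != sp[[j]]$n_binders ||
        sp[[i]]$n_antigens != sp[[j]]$n_antigens ||
        nrow(sp[[i]]$edges) != nrow(sp[[j]]$edges)) next
    expect_false(
      igraph::isomorphic(graphs[[i]]$g, graphs[[j]]$g, method = "vf2",
                         vertex.color1 = graphs[[i]]$col,
                         vertex.color2 = graphs[[j]]$col),
      info = sprintf("species %d and %d are duplicates", i, j))
  }
})

test_that("IgG rules grow bridged networks up to the caps", {
  igg <- igg_architecture()
  cat_igg <- enumerate_species(igg, antigen, 3, 3, igg_rules(),
                               max_explore = 5e5)
  df <- as.data.frame(cat_igg)
  expect_true(all(c("2:2", "3:3") %in% df$label))
  # the ring series is closed, the chain series is not
  expect_true(any(df$label == "2:2" & df$closed))
  expect_true(any(df$label == "3:3" & !df$closed))
  # size grows to the caps (unbounded chain growth, unlike the dual-dAb)
  expect_equal(max(df$n_binders + df$n_antigens), 6)
})

test_that("enumeration overflow cap raises an explicit error", {
  igg <- igg_architecture()
  expect_error(enumerate_species(igg, antigen, 3, 3, igg_rules(),
                                 max_explore = 100), "overflow")
})

test_that("antigen sharing between molecules is representable when enabled", {
  dd <- dual_dab_architecture()
  shared <- enumerate_species(dd, antigen, 2, 2,
                              dual_dab_rules(share_antigen = TRUE),
                              max_explore = 5e5)
  df <- as.data.frame(shared)
  expect_true(any(df$n_binders == 2 & df$n_bonds > 0))
  # default rules forbid exactly this
  df0 <- as.data.frame(enumerate_species(dd, antigen, 2, 2,
                                         dual_dab_rules()))
  expect_false(any(df0$n_binders == 2 & df0$n_bonds > 0))
})

test_that("mass matching picks the right stoichiometry inside the band", {
  dd <- dual_dab_architecture()
  igg <- igg_architecture()
  cat_dd <- enumerate_species(dd, antigen, 3, 3, dual_dab_rules())
  cat_igg <- enumerate_species(igg, antigen, 3, 3, igg_rules(),
                               max_explore = 5e5)
  # the observed 183-201 kDa band is the 1:2 complex (predicted 205)
  m1 <- match_species(cat_dd, c(183, 201))
  expect_equal(m1$label[1], "1:2")
  # 397 kDa against the IgG catalog is the 2:2 ring (predicted 392)
  m2 <- match_species(cat_igg, 397)
  expect_equal(m2$label[1], "2:2")
  expect_lt(m2$rel_error[1], 0.15)
  # an exact catalog mass ranks first with zero error
  m3 <- match_species(cat_dd, 205)
  expect_equal(m3$label[1], "1:2")
  expect_equal(m3$rel_error[1], 0)
  # nothing within tolerance gives an empty result, not an error
  expect_equal(nrow(match_species(cat_dd, 1e4)), 0)
  expect_error(match_species(cat_dd, 205, rel_tol = 0), "positive")
  expect_error(match_species(cat_dd, -5), "positive")
})

test_that("candidate compositions for the unobserved twinned species are
           reported without guessing", {
  dd <- dual_dab_architecture()
  # a shared-engagement complex of two molecules would weigh ~370 kDa;
  # both plausible compositions bracket it and neither is privileged
  expect_equal(species_mass(2, 3, dd, antigen), 362)
  expect_equal(species_mass(2, 4, dd, antigen), 410)
  shared <- enumerate_species(dd, antigen, 2, 3,
                              dual_dab_rules(share_antigen = TRUE),
                              max_explore = 5e5)
  m <- match_species(shared, 370)
  expect_true("2:3" %in% m$label)
  # both compositions sit inside the matching band around 370 kDa
  expect_lt(abs(362 - 370) / 370, 0.15)
  expect_lt(abs(410 - 370) / 370, 0.15)
})
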