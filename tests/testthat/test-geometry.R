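# Superposition, terminal distances, interfaces, solvent content.

test_that("superposing identical point sets gives identity and zero rmsd", {
  set.seed(11)
  P <- matrix(rnorm(30, sd = 10), 10, 3)
  sup <- kabsch_superpose(P, P)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(sup$rmsd, 1e-10)
})

test_that("a known rigid motion is recovered exactly", {
  set.seed(12)
  P <- matrix(rnorm(30, sd = 10), 10, 3)
  R90 <- rotation_xyz(0, 0, pi / 2)
  Q <- sweep(P %*% t(R90), 2, c(5, -3, 2), "+")
  sup <- kabsch_superpose(P, Q)
  expect_equal(sup$rotation, R90, tolerance = 1e-9)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-12)
  expect_equal(apply_superposition(P, sup), Q, tolerance = 1e-9)
})

test_that("closed-form rmsd matches the brute-force rotational oracle", {
  for (seed in c(21, 22, 23)) {
    set.seed(seed)
    P <- matrix(rnorm(30, sd = 8), 10, 3)
    Q <- matrix(rnorm(30, sd = 8), 10, 3)
    sup <- kabsch_superpose(P, Q)
    expect_equal(sup$rmsd, oracle_min_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("superposition rmsd is invariant under rigid pre-transformation", {
  set.seed(31)
  P <- matrix(rnorm(24, sd = 6), 8, 3)
  Q <- matrix(rnorm(24, sd = 6), 8, 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (k in 1:5) {
    R <- rotation_xyz(runif(1, -pi, pi), runif(1, -pi, pi),
                      runif(1, -pi, pi))
    t1 <- rnorm(3, sd = 30)
    expect_equal(kabsch_superpose(sweep(P %*% t(R), 2, t1, "+"), Q)$rmsd,
                 base, tolerance = 1e-9)
    expect_equal(kabsch_superpose(P, sweep(Q %*% t(R), 2, t1, "+"))$rmsd,
                 base, tolerance = 1e-9)
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear|degenerate")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "size")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "3")
})

test_that("antigen superposition maps a rigidly moved copy back, and flags
           a poor fit", {
  toy <- make_toy_complex(displace_second = TRUE, seed = 5)
  m <- superpose_on_antigen(toy$vh_complex, toy$vk_complex,
                            c(A = "A", B = "B"))
  expect_lt(attr(m, "antigen_rmsd"), 1e-9)
  expect_false(attr(m, "rmsd_flag"))
  # the antigen atoms must land exactly on complex_a's antigen
  a1 <- toy$vh_complex$atoms
  a2 <- m$atoms
  for (ch in c("A", "B")) {
    expect_equal(as.matrix(a2[a2$chain == ch, c("x", "y", "z")]),
                 as.matrix(a1[a1$chain == ch, c("x", "y", "z")]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # identity case: rmsd 0 and coordinates unchanged
  m0 <- superpose_on_antigen(toy$vh_complex, toy$vh_complex,
                             c(A = "A", B = "B"))
  expect_equal(m0$atoms, toy$vh_complex$atoms, tolerance = 1e-10)
  # distorted copy exceeds the sanity cap -> warning flag, not failure
  bad <- toy$vk_complex
  idx <- bad$atoms$chain == "A"
  bad$atoms$x[idx] <- bad$atoms$x[idx] + rep_len(c(0, 14), sum(idx))
  expect_warning(mb <- superpose_on_antigen(toy$vh_complex, bad,
                                            c(A = "A", B = "B")),
                 "sanity cap")
  expect_true(attr(mb, "rmsd_flag"))
})

test_that("terminal distances reproduce the constructed 81/70/77 layout", {
  toy <- make_toy_complex()
  merged <- merged_toy_structure(toy)
  td <- terminal_distances(merged, vh_chains = c("C", "D"),
                           vk_chains = c("K", "L"))
  expect_equal(td$d_vh_vh, 81, tolerance = 1e-8)
  expect_equal(td$d_vk_vk, 70, tolerance = 1e-8)
  expect_equal(td$d_cross, 77, tolerance = 1e-8)
  # symmetric in chain order
  td2 <- terminal_distances(merged, vh_chains = c("D", "C"),
                            vk_chains = c("L", "K"))
  expect_equal(td2$d_vh_vh, td$d_vh_vh)
  expect_equal(td2$d_cross, td$d_cross)
  # invariant under a global rigid motion
  rigid <- merged
  R <- rotation_xyz(0.4, -1.1, 2.2)
  xyz <- as.matrix(rigid$atoms[, c("x", "y", "z")])
  rigid$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, c(7, 8, 9), "+")
  td3 <- terminal_distances(rigid, vh_chains = c("C", "D"),
                            vk_chains = c("K", "L"))
  expect_equal(td3$d_vh_vh, td$d_vh_vh, tolerance = 1e-8)
  expect_equal(td3$d_vk_vk, td$d_vk_vk, tolerance = 1e-8)
  expect_equal(td3$d_cross, td$d_cross, tolerance = 1e-8)
  # missing roles give NA fields; unknown chains error
  td4 <- terminal_distances(merged, vh_chains = c("C", "D"))
  expect_true(is.na(td4$d_vk_vk) && is.na(td4$d_cross))
  expect_error(terminal_distances(merged, vh_chains = c("C", "Z")),
               "chain")
})

test_that("coincident termini give zero distances", {
  toy <- make_toy_complex(d_vh_vh = 0, d_vk_vk = 0, d_cross = 0)
  merged <- merged_toy_structure(toy)
  td <- terminal_distances(merged, vh_chains = c("C", "D"),
                           vk_chains = c("K", "L"))
  expect_equal(td$d_vh_vh, 0, tolerance = 1e-8)
  expect_equal(td$d_vk_vk, 0, tolerance = 1e-8)
})

test_that("interface residues find an engineered contact pair only", {
  mk <- function(chain, resno, x, elety = "CB")
    data.frame(chain = chain, resno = resno, insert = "", resid = "ALA",
               elety = elety, elesy = substr(elety, 1, 1), x = x, y = 0,
               z = 0, o = 1, stringsAsFactors = FALSE)
  atoms <- rbind(mk("A", 1, 0), mk("A", 2, 50), mk("B", 7, 3),
                 mk("B", 8, 80))
  s <- dualreach:::new_structure3d(atoms, source_id = "contact_fixture")
  iface <- interface_residues(s, "A", "B", cutoff = 4.5)
  expect_equal(iface$epitope, data.frame(chain = "A", resno = 1L),
               ignore_attr = TRUE)
  expect_equal(iface$paratope, data.frame(chain = "B", resno = 7L),
               ignore_attr = TRUE)
  # all atoms beyond the cutoff -> empty; cutoff 0 -> empty
  far <- interface_residues(s, "A", "B", cutoff = 1)
  expect_equal(nrow(far$epitope), 0)
  expect_equal(nrow(interface_residues(s, "A", "B", cutoff = 0)$epitope), 0)
  # hydrogens are never counted
  ath <- rbind(mk("A", 1, 0), mk("B", 7, 1, elety = "H"),
               mk("B", 8, 60))
  sh <- dualreach:::new_structure3d(ath, source_id = "h_fixture")
  expect_equal(nrow(interface_residues(sh, "A", "B")$epitope), 0)
  expect_error(interface_residues(s, character(0), "B"), "empty")
  expect_error(interface_residues(s, "A", "A"), "disjoint")
})

test_that("solvent content follows the Matthews relation", {
  # V_M = 2.46 A^3/Da forces a solvent fraction of exactly 0.50
  cell <- crystal_cell(100, 100, 100, z = 1)
  mass <- 1e6 / 2.46
  expect_equal(solvent_content(cell, mass)$solvent_fraction, 0.5,
               tolerance = 1e-12)
  # strictly decreasing in the ASU mass
  masses <- seq(2e5, 8e5, length.out = 20)
  fr <- vapply(masses, function(m)
    solvent_content(cell, m)$solvent_fraction, 0)
  expect_true(all(diff(fr) < 0))
  # doubling Z at fixed mass halves V_M and lowers the solvent fraction
  cell2 <- crystal_cell(100, 100, 100, z = 2)
  s1 <- solvent_content(cell, 4e5); s2 <- solvent_content(cell2, 4e5)
  expect_equal(s2$vm, s1$vm / 2)
  expect_lt(s2$solvent_fraction, s1$solvent_fraction)
  expect_error(solvent_content(cell, -5), "positive")
})

test_that("the published I222 cell with the crystallized composition gives
           ~68% solvent", {
  cell <- crystal_cell(61.221, 147.128, 175.171,
                       space_group = "I 2 2 2", z = 8)
  # ASU: one receptor-binding-domain antigen homodimer (~25.9 kDa) plus two
  # ~12.6 kDa binder domains
  asu_mass <- 2 * 12950 + 2 * 12600
  sc <- solvent_content(cell, asu_mass)
  expect_equal(100 * sc$solvent_fraction, 67.6, tolerance = 0.03)
})

test_that("triclinic cell volume reduces correctly for orthogonal axes", {
  cell <- crystal_cell(10, 20, 30)
  expect_equal(cell_volume(cell), 6000)
  mono <- crystal_cell(10, 20, 30, beta = 106.53)
  expect_equal(cell_volume(mono), 6000 * sin(106.53 * pi / 180))
})
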