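test_that("effective distance uses r^-6 summation over resolved pairs", {
  m <- toy_model(name = c("HA", "HN", "HB1", "HB2"),
                 element = rep("H", 4), resname = "ALA",
                 resno = c(1L, 2L, 2L, 2L),
                 xyz = rbind(c(0, 0, 0), c(4, 0, 0), c(3, 0, 0),
                             c(0, 8, 0)))
  expect_equal(effective_distance(m, simple_noe(1, "HA", 2, "HN", 4)), 4.0)
  # two pairs at 3 and 8 A
  amb <- noe_restraint(data.frame(resid = 1, name = "HA"),
                       data.frame(resid = 2, name = c("HB1", "HB2")),
                       4, 2, 1)
  expect_equal(effective_distance(m, amb), (3^-6 + 8^-6)^(-1 / 6),
               tolerance = 1e-12)
  # two pairs both at distance d -> d * 2^(-1/6)
  m2 <- toy_model(name = c("HA", "HB1", "HB2"), element = rep("H", 3),
                  resname = "ALA", resno = c(1L, 2L, 2L),
                  xyz = rbind(c(0, 0, 0), c(5, 0, 0), c(-5, 0, 0)))
  amb2 <- noe_restraint(data.frame(resid = 1, name = "HA"),
                        data.frame(resid = 2, name = c("HB1", "HB2")),
                        4, 2, 1)
  expect_equal(effective_distance(m2, amb2), 5 * 2^(-1 / 6),
               tolerance = 1e-12)
})

test_that("restraint energies match independent piecewise oracles", {
  expect_equal(noe_energy(3.4, 1.8, 5.0), 0)          # flat bottom
  expect_equal(noe_energy(5.5, 1.8, 5.0), 0.25)       # harmonic branch
  expect_equal(dihedral_energy(-55, -60, 20), 0)
  expect_equal(dihedral_energy(-90, -60, 20, k = 1), 100)
  expect_equal(dihedral_energy(175, -175, 5, k = 1), 25)

  set.seed(11)
  for (i in 1:1000) {
    lower <- runif(1, 0, 4)
    upper <- lower + runif(1, 0, 4)
    k <- runif(1, 0.1, 3)
    rs <- runif(1, 0.2, 2)
    fmax <- runif(1, 0.5, 1) * 2 * k * rs
    r <- runif(1, 0, upper + 4 * rs)
    p <- noe_params(k, rs, fmax)
    expect_equal(noe_energy(r, lower, upper, p),
                 ref_noe_energy(r, lower, upper, k, rs, fmax),
                 tolerance = 1e-9)
    th <- runif(1, -360, 360)
    th0 <- runif(1, -180, 180)
    dl <- runif(1, 0, 90)
    expect_equal(dihedral_energy(th, th0, dl, k),
                 ref_dihedral_energy(th, th0, dl, k), tolerance = 1e-9)
  }
})

test_that("the soft-asymptote potential is C1 at both branch points", {
  p <- noe_params(k_noe = 1.3, r_switch = 0.8)
  lower <- 1.8; upper <- 5.0
  h <- 1e-7
  slope <- function(r) (noe_energy(r + h, lower, upper, p) -
                          noe_energy(r - h, lower, upper, p)) / (2 * h)
  one_sided <- function(r, dir) (noe_energy(r + dir * h, lower, upper, p) -
                                   noe_energy(r, lower, upper, p)) / (dir * h)
  # value continuity and slope agreement at `upper`
  expect_lt(abs(one_sided(upper, 1) - one_sided(upper, -1)), 1e-5)
  sw <- upper + p$r_switch
  expect_lt(abs(one_sided(sw, 1) - one_sided(sw, -1)), 1e-5)
  # linear asymptote: equal slopes far out
  expect_equal(slope(upper + 2 * p$r_switch), slope(upper + 3 * p$r_switch),
               tolerance = 1e-6)
})

test_that("STAP tables are built, interpolated and serialised correctly", {
  fix <- fixture_bundle()
  # zero observations -> uniform zero grid
  empty <- rebuild_from_torsions(NULL, "GG")  # glycines: no chi1
  t0 <- build_stap_table(list(), "chi1_chi2", pseudocount = 1)
  expect_true(all(t0$grid == 0))
  # all observations in one bin, no smoothing
  h <- rebuild_from_torsions(nmrefine:::motif_torsions("AAAAAA", "helix"),
                             "AAAAAA")
  t1 <- build_stap_table(list(h), "phi_psi", smoothing_sigma = 0,
                         pseudocount = 0.5)
  loaded <- t1$grid == 0
  expect_equal(sum(loaded), 1)
  off <- t1$grid[!loaded]
  expect_true(all(abs(off - off[1]) < 1e-12) && off[1] > 0)
  # smoothing kernel is normalised: convolution preserves the total count
  kern <- nmrefine:::circular_gaussian(36, 10, 15)
  expect_equal(rowSums(kern), rep(1, 36), tolerance = 1e-12)
  hgrid <- matrix(runif(36 * 36), 36)
  expect_equal(sum(kern %*% hgrid %*% t(kern)), sum(hgrid),
               tolerance = 1e-9)

  # interpolation: bin centre exact; uniform zero; midpoint mean
  tab <- fix$tables$phi_psi
  bw <- tab$bin_width
  c1 <- -180 + (3 - 0.5) * bw
  c2 <- -180 + (7 - 0.5) * bw
  expect_equal(stap_energy(c(c1, c2), tab), tab$grid[3, 7])
  expect_equal(stap_energy(c(c1 + bw / 2, c2), tab),
               mean(c(tab$grid[3, 7], tab$grid[4, 7])))
  expect_equal(stap_energy(c(12.3, -77.2), t0), 0)
  # grid sampling: nonnegative with min ~0
  th <- seq(-180, 175, by = 5)
  vals <- outer(th, th, function(a, b)
    stap_energy(cbind(a, b), tab))
  expect_gte(min(vals), 0)
  expect_lt(min(vals), 0.3)

  # serialisation round trip
  path <- tempfile(fileext = ".stap")
  write_stap_table(tab, path)
  back <- read_stap_table(path)
  expect_equal(back$grid, tab$grid, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$pair_type, tab$pair_type)
  expect_equal(back$bin_width, tab$bin_width)
})

test_that("soft-core stereochemical term penalises only true overlaps", {
  sq <- "GGGGGG"
  tors <- nmrefine:::motif_torsions(sq, "helix")
  tors$angle[tors$name %in% c("phi", "psi")] <- 180
  ext <- rebuild_from_torsions(tors, sq)
  expect_equal(stereo_energy(ext), 0)
  # two nonbonded carbons: zero at r_min, 0.25 at r_min/2
  rmin <- 2 * default_topology()$radii[["C"]]
  mk <- function(r) toy_model(name = c("CA", "CA"), element = c("C", "C"),
                              resname = "ALA", resno = c(1L, 5L),
                              xyz = rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_equal(stereo_energy(mk(rmin)), 0)
  expect_equal(stereo_energy(mk(rmin / 2)), 0.25)
  expect_equal(stereo_energy(mk(rmin / 2), eps = 2), 0.5)
})

test_that("burial solvation surrogate counts neighbours deterministically", {
  iso <- toy_model(name = "CA", element = "C", resname = "ALA", resno = 1L,
                   xyz = matrix(c(0, 0, 0), 1))
  expect_equal(solv_energy(iso), 0)
  # two hydrophobic atoms 5 A apart with preference -0.1 -> -0.2
  topo <- default_topology()
  topo$solvation["C"] <- -0.1
  two <- toy_model(name = c("CA", "CA"), element = c("C", "C"),
                   resname = "ALA", resno = c(1L, 5L),
                   xyz = rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(solv_energy(two, topo), -0.2)
  # pulling coordinates apart never increases burial
  fix <- fixture_bundle()
  m <- fix$truth
  far <- m
  far$atoms[, c("x", "y", "z")] <- 2 * far$atoms[, c("x", "y", "z")]
  ctx <- nmrefine:::solv_context(m$atoms, nmrefine:::model_bonds(m),
                                 default_topology())
  b1 <- nmrefine:::cpp_burial(model_xyz(m), ctx$pi, ctx$pj, 6.5)
  b2 <- nmrefine:::cpp_burial(model_xyz(far), ctx$pi, ctx$pj, 6.5)
  expect_true(all(b2 <= b1))
})

test_that("total energy is an exact weighted sum and rigid-body invariant", {
  fix <- fixture_bundle()
  m <- fix$start
  rs <- fix$restraints
  tabs <- fix$tables
  eb <- total_energy(m, rs, tabs)
  expect_equal(eb$E_tot, eb$E_stereo + eb$E_solv + eb$E_exp_noe +
                 eb$E_exp_dihe + eb$E_stap)
  # zero weights isolate terms
  eb2 <- total_energy(m, rs, tabs,
                      weights = energy_weights(1, 0, 0, 0, 0))
  expect_equal(eb2$E_tot, eb2$E_stereo)
  expect_equal(eb2$E_solv + eb2$E_exp_noe + eb2$E_exp_dihe + eb2$E_stap, 0)
  # model satisfying all restraints -> zero experimental terms
  ebT <- total_energy(fix$truth, rs, list())
  expect_equal(ebT$E_exp_noe, 0)
  expect_lte(ebT$E_exp_dihe, 1e-9)
  # rigid-body invariance of every term
  for (seed in 1:3) {
    mt <- rigid_transform(m, seed)
    ebt <- total_energy(mt, rs, tabs)
    for (term in c("E_stereo", "E_solv", "E_exp_noe", "E_exp_dihe",
                   "E_stap", "E_tot"))
      expect_equal(ebt[[term]], eb[[term]], tolerance = 1e-8)
  }
  # hand-summed toy: three restraints on a fixed geometry
  m3 <- toy_model(name = c("HA", "HN", "HB1"), element = rep("H", 3),
                  resname = "ALA", resno = c(1L, 3L, 9L),
                  xyz = rbind(c(0, 0, 0), c(6, 0, 0), c(0, 3, 0)))
  rs3 <- restraint_set(list(
    simple_noe(1, "HA", 3, "HN", 5.0, 1.0, 0.5),   # r=6, upper 5.5 -> 0.25
    simple_noe(1, "HA", 9, "HB1", 3.0, 0.5, 0.5),  # r=3, satisfied -> 0
    simple_noe(3, "HN", 9, "HB1", 9.0, 1.0, 1.0))) # r=6.7..; below lower
  r3 <- sqrt(45)
  hand <- 0.25 + 0 + (8 - r3)^2
  eb3 <- total_energy(m3, rs3)
  expect_equal(eb3$E_exp_noe, hand, tolerance = 1e-9)
  expect_equal(eb3$E_tot, eb3$E_exp_noe + eb3$E_solv + eb3$E_stereo)
})
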