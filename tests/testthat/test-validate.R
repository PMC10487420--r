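# a model and restraints engineered to violate by exactly {0, 0.3, 0.6, 1.2}
viol_scenario <- function() {
  # atoms on a 4 x 4 square: every edge distance is exactly 4
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 4, 0), c(0, 4, 0))
  m <- toy_model(name = c("HA", "HN", "HA", "HN"), element = rep("H", 4),
                 resname = "ALA", resno = 1:4, xyz = xyz)
  rs <- list(
    simple_noe(1, "HA", 2, "HN", 3.5, 0.5, 0.5),   # upper 4.0 -> 0
    simple_noe(3, "HA", 4, "HN", 3.2, 0.5, 0.5),   # upper 3.7 -> 0.3
    simple_noe(1, "HA", 4, "HN", 3.0, 0.5, 0.4),   # upper 3.4 -> 0.6
    simple_noe(2, "HN", 3, "HA", 2.5, 0.5, 0.3))   # upper 2.8 -> 1.2
  list(model = m, restraints = rs)
}

test_that("NOE violation is the excess over the upper bound only", {
  sc <- viol_scenario()
  v <- vapply(sc$restraints, function(r) noe_violation(sc$model, r), 0)
  expect_equal(v, c(0, 0.3, 0.6, 1.2), tolerance = 1e-9)
  # short-side excursions are excluded
  short <- simple_noe(1, "HA", 2, "HN", 6.0, 1.0, 1.0)  # lower 5, r 4
  expect_equal(noe_violation(sc$model, short), 0)
})

test_that("violation statistics reproduce the binned counts and RMS", {
  sc <- viol_scenario()
  vs <- violation_stats(sc$model, sc$restraints)
  expect_equal(vs["all", "max_violation"], 1.2, tolerance = 1e-9)
  expect_equal(vs["all", "rms_violation"],
               sqrt((0 + 0.09 + 0.36 + 1.44) / 4), tolerance = 1e-9)
  expect_equal(unlist(vs["all", c("n_gt_0", "n_gt_0.5", "n_gt_1", "n_gt_2")]),
               c(3, 2, 1, 0), ignore_attr = TRUE)
  expect_equal(vs["sequential", "n_restraints"], 3)
  expect_equal(vs["medium", "n_restraints"], 1)
  # all satisfied -> zeros
  sat <- violation_stats(sc$model, list(simple_noe(1, "HA", 2, "HN", 4, 1, 1)))
  expect_equal(sat["all", "max_violation"], 0)
  expect_equal(sat["all", "rms_violation"], 0)
  expect_equal(sat["all", "n_gt_0"], 0)
  # violated-only RMS variant
  vo <- violation_stats(sc$model, sc$restraints, violated_only = TRUE)
  expect_equal(vo["all", "rms_violation"],
               sqrt((0.09 + 0.36 + 1.44) / 3), tolerance = 1e-9)
})

test_that("violation statistics match brute force on random synthetic sets", {
  fix <- fixture_bundle()
  at <- fix$truth$atoms
  h_idx <- which(at$element == "H")
  cutoffs <- c(0, 0.5, 1, 2)
  for (trial in 1:25) {
    set.seed(300 + trial)
    n <- sample(5:25, 1)
    idx <- matrix(sample(h_idx, 2 * n, replace = TRUE), ncol = 2)
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    rs <- lapply(seq_len(nrow(idx)), function(i)
      simple_noe(at$resno[idx[i, 1]], at$name[idx[i, 1]],
                 at$resno[idx[i, 2]], at$name[idx[i, 2]],
                 d = runif(1, 1, 6), dminus = runif(1, 0, 1),
                 dplus = runif(1, 0, 1)))
    # brute force: direct coordinate arithmetic per restraint
    v <- vapply(seq_len(nrow(idx)), function(i) {
      r <- sqrt(sum((model_xyz(fix$truth)[idx[i, 1], ] -
                       model_xyz(fix$truth)[idx[i, 2], ])^2))
      max(0, r - rs[[i]]$upper)
    }, 0)
    vs <- violation_stats(fix$truth, rs)
    expect_equal(vs["all", "max_violation"], max(v), tolerance = 1e-9)
    expect_equal(vs["all", "rms_violation"], sqrt(mean(v^2)),
                 tolerance = 1e-9)
    counts <- unlist(vs["all", c("n_gt_0", "n_gt_0.5", "n_gt_1", "n_gt_2")])
    expect_equal(counts, vapply(cutoffs, function(cc) sum(v > cc), 0),
                 ignore_attr = TRUE)
    # bin counts monotone nonincreasing in the cutoff, in every category
    for (rowname in rownames(vs)) {
      cc <- unlist(vs[rowname, c("n_gt_0", "n_gt_0.5", "n_gt_1", "n_gt_2")])
      expect_true(all(diff(cc) <= 0))
    }
  }
})

test_that("ensemble violations aggregate per-restraint means over models", {
  sc <- viol_scenario()
  m2 <- sc$model
  m2$atoms$x <- m2$atoms$x * 1.1  # second member violates more
  ens <- ensemble(list(sc$model, m2))
  vper <- function(m) vapply(sc$restraints,
                             function(r) noe_violation(m, r), 0)
  vmean <- (vper(sc$model) + vper(m2)) / 2
  vs <- violation_stats(ens, sc$restraints)
  expect_equal(vs["all", "max_violation"], max(vmean), tolerance = 1e-9)
  expect_equal(vs["all", "rms_violation"], sqrt(mean(vmean^2)),
               tolerance = 1e-9)
})

test_that("dihedral violations wrap angle differences", {
  fix <- fixture_bundle()
  tors <- torsions_of(fix$truth)
  phi5 <- tors$angle[tors$resi == 5 & tors$name == "phi"]
  mk <- function(theta0, delta) dihedral_restraint(
    nmrefine:::dihedral_quad_selection("phi", 6), theta0 = theta0,
    delta = delta)
  inside <- mk(phi5 + 3, 10)
  out12 <- mk(wrap180(phi5 + 22), 10)
  st <- dihedral_violation_stats(fix$truth, list(inside, out12))
  expect_equal(st$max_violation, 12, tolerance = 1e-6)
  expect_equal(st$rms_violation, sqrt((0 + 144) / 2), tolerance = 1e-6)
  expect_equal(st$n_restraints, 2L)
  # wrap case: theta 178 vs theta0 -178, delta 2 -> violation 2
  expect_equal(max(0, abs(wrap180(178 - (-178))) - 2), 2)
})

test_that("clash score counts nonbonded overlaps per 1000 atoms", {
  fix <- fixture_bundle()
  m <- fix$truth
  base <- clash_score(m)
  # brute-force recount
  at <- m$atoms
  np <- nmrefine:::nonbonded_pairs(nrow(at), nmrefine:::model_bonds(m),
                                   at$element, default_topology()$radii)
  xyz <- model_xyz(m)
  d <- sqrt(rowSums((xyz[np$i, ] - xyz[np$j, ])^2))
  expect_equal(base, 1000 * sum(d < np$rmin - 0.4) / nrow(at),
               tolerance = 1e-9)
  # invariant under rigid transforms and atom order
  expect_equal(clash_score(rigid_transform(m, 4)), base, tolerance = 1e-6)
  perm <- sample(nrow(at))
  mp <- structure_model(at[perm, ], m$disulfides)
  expect_equal(clash_score(mp), base, tolerance = 1e-9)
  # separated atoms never clash; bonded short contacts are excluded
  far <- toy_model(name = c("CA", "CA"), element = c("C", "C"),
                   resname = "ALA", resno = c(1L, 2L),
                   xyz = rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_equal(clash_score(far), 0)
  bonded <- toy_model(name = c("N", "CA"), element = c("N", "C"),
                      resname = "ALA", resno = c(1L, 1L),
                      xyz = rbind(c(0, 0, 0), c(1.0, 0, 0)))
  expect_equal(clash_score(bonded), 0)
})

test_that("Ramachandran percentage counts allowed non-terminal residues", {
  fix <- fixture_bundle()
  helix <- rebuild_from_torsions(
    nmrefine:::motif_torsions("AAAAAAAAAAAA", "helix"), "AAAAAAAAAAAA")
  # map with everything allowed -> 100 regardless of structure
  all_ok <- list(bin_width = 10, allowed = matrix(TRUE, 36, 36))
  expect_equal(ramachandran_pct(helix, all_ok), 100)
  expect_equal(ramachandran_pct(fix$start, all_ok), 100)
  # helix residues at (-57, -47) in an allowed bin -> 100
  rmap <- rama_region_map(fix$tables$phi_psi, threshold = 4)
  expect_equal(ramachandran_pct(helix, rmap), 100)
  # exactly 1 of 10 assigned residues in a disallowed bin -> 90
  none <- list(bin_width = 10, allowed = matrix(TRUE, 36, 36))
  none$allowed[nmrefine:::angle_bin(-125, 10, 36),
               nmrefine:::angle_bin(135, 10, 36)] <- FALSE
  sq12 <- "AAAAAAAAAAAA"   # 12 residues -> 10 non-terminal (phi+psi)
  tors <- nmrefine:::motif_torsions(sq12, "helix")
  tors$angle[tors$resi == 5 & tors$name == "phi"] <- -125
  tors$angle[tors$resi == 5 & tors$name == "psi"] <- 135
  m10 <- rebuild_from_torsions(tors, sq12)
  expect_equal(ramachandran_pct(m10, none), 90)
  short <- rebuild_from_torsions(NULL, "GA")
  expect_error(ramachandran_pct(short, all_ok), "few")
})

test_that("secondary-structure ratio follows the torsion-window rules", {
  sq <- "AAAAAAAAAAAA"
  helix <- rebuild_from_torsions(nmrefine:::motif_torsions(sq, "helix"), sq)
  ss <- secondary_structure_ratio(helix)
  expect_equal(unname(ss["helix"]), 100)
  strand <- rebuild_from_torsions(nmrefine:::motif_torsions(sq, "strand"), sq)
  ss2 <- secondary_structure_ratio(strand)
  expect_equal(unname(ss2["sheet"]), 100)
  # alternating torsions break all runs -> 100% coil
  tors <- nmrefine:::motif_torsions(sq, "helix")
  alt <- tors$resi %% 2 == 0
  tors$angle[tors$name == "phi" & alt] <- 60
  tors$angle[tors$name == "psi" & alt] <- 60
  coil <- rebuild_from_torsions(tors, sq)
  ss3 <- secondary_structure_ratio(coil)
  expect_equal(unname(ss3["coil"]), 100)
  expect_equal(sum(ss), 100, tolerance = 0.01)
})

test_that("binding residues use strict heavy-atom contact cutoffs", {
  fix <- fixture_bundle()
  m <- fix$truth
  far <- matrix(apply(model_xyz(m), 2, max) + 25, 1)
  expect_equal(length(binding_residues(m, far)), 0)
  expect_error(binding_residues(m, matrix(numeric(0), 0, 3)), "ligand")
  # an atom exactly at the cutoff is excluded (strict <)
  at <- m$atoms
  cb <- which(at$name == "CB" & at$resno == 5)
  pos <- model_xyz(m)[cb, ] + c(4.5, 0, 0)
  # ensure no other atom is closer than 4.5 to pos before asserting
  dmin <- min(sqrt(rowSums(sweep(model_xyz(m)[at$element != "H", ], 2, pos)^2)))
  if (dmin >= 4.5) expect_equal(length(binding_residues(m, rbind(pos))), 0)
  inside <- model_xyz(m)[cb, ] + c(4.0, 0, 0)
  expect_true(5 %in% binding_residues(m, rbind(inside)))
})

test_that("MCC matches the closed form with the zero-denominator convention", {
  expect_equal(mcc(list(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_equal(mcc(list(TP = 0, TN = 0, FP = 3, FN = 3)), -1)
  expect_equal(mcc(list(TP = 3, TN = 5, FP = 1, FN = 1)), 14 / 24,
               tolerance = 1e-12)
  expect_equal(mcc(list(TP = 0, TN = 0, FP = 0, FN = 0)), 0)
  # complementary sets: full disagreement scores -1
  expect_equal(mcc(list(TP = 0, TN = 0, FP = 4, FN = 6)), -1)
  expect_equal(mcc(list(TP = 2, TN = 0, FP = 3, FN = 0)), 0)
  expect_equal(mcc(confusion_counts(1:3, 4:6, 1:6)), -1)
  # symmetry under simultaneous TP<->TN, FP<->FN swap
  set.seed(5)
  for (i in 1:200) {
    c4 <- as.list(setNames(sample(0:20, 4, replace = TRUE),
                           c("TP", "TN", "FP", "FN")))
    swapped <- list(TP = c4$TN, TN = c4$TP, FP = c4$FN, FN = c4$FP)
    expect_equal(mcc(c4), mcc(swapped), tolerance = 1e-12)
    expect_gte(mcc(c4), -1)
    expect_lte(mcc(c4), 1)
  }
  # confusion counts partition the universe
  cc <- confusion_counts(c(2, 3, 9), c(3, 9, 11), 1:12)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 12)
  expect_equal(cc$TP, 2)
  expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 1)
  expect_error(confusion_counts(13, 1:2, 1:12), "subset")
})
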