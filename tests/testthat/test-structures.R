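test_that("multi-model PDB reading yields consistent ensembles", {
  path <- write_tmp(toy_pdb_text(3))
  ens <- read_pdb_ensemble(path)
  expect_s3_class(ens, "nmr_ensemble")
  expect_length(ens$models, 3)
  expect_identical(ens$models[[1]]$atoms$name, ens$models[[3]]$atoms$name)

  # no MODEL records -> single-model ensemble
  single <- grep("^(MODEL|ENDMDL)", toy_pdb_text(1), value = TRUE,
                 invert = TRUE)
  ens1 <- read_pdb_ensemble(write_tmp(single))
  expect_length(ens1$models, 1)

  # a model missing one atom is a topology error
  expect_error(read_pdb_ensemble(write_tmp(toy_pdb_text(3, drop_atom_in_model = 2))),
               "topology error")

  # malformed coordinates name the line
  bad <- toy_pdb_text(1)
  bad[3] <- sub("^(.{30}).{8}", "\\1   xxxxx", bad[3])
  expect_error(read_pdb_ensemble(write_tmp(bad)), "line 3")
})

test_that("PDB writing round-trips and agrees with an independent reader", {
  fix <- fixture_bundle()
  path <- write_tmp(character(0))
  write_pdb(fix$truth, path)
  back <- read_pdb_ensemble(path)$models[[1]]
  expect_equal(back$atoms$name, fix$truth$atoms$name)
  expect_equal(model_xyz(back), model_xyz(fix$truth), tolerance = 1e-3,
               ignore_attr = TRUE)
  skip_if_not_installed("bio3d")
  pdb <- bio3d::read.pdb(path)
  expect_equal(nrow(pdb$atom), nrow(fix$truth$atoms))
  expect_equal(cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z),
               round(model_xyz(fix$truth), 3), ignore_attr = TRUE)
})

test_that("entry filter applies strict 'more than' thresholds", {
  mk <- function(nmodels, nres) {
    seqv <- rep("ALA", nres)
    m <- rebuild_from_torsions(NULL, seqv)
    ensemble(rep(list(m), nmodels))
  }
  expect_true(passes_entry_filter(mk(11, 25)))
  expect_false(passes_entry_filter(mk(10, 25)))
  expect_false(passes_entry_filter(mk(11, 20)))
  expect_true(passes_entry_filter(mk(10, 20), strict = FALSE))
})

test_that("disulfide detection pairs nearest SG atoms greedily", {
  expect_equal(detect_disulfides(two_cys_model(2.05)),
               matrix(c(1L, 2L), 1), ignore_attr = TRUE)
  expect_equal(nrow(detect_disulfides(two_cys_model(5.0))), 0)

  # three mutually close CYS: one pair (the nearest), third unpaired
  xyz <- rbind(c(0, 0, 0), c(2.0, 0, 0), c(4.2, 0, 0))
  m3 <- toy_model(name = rep("SG", 3), element = rep("S", 3),
                  resname = "CYS", resno = 1:3, xyz = xyz)
  got <- detect_disulfides(m3)
  expect_equal(nrow(got), 1)
  expect_equal(got[1, ], c(1L, 2L), ignore_attr = TRUE)

  # detected bridges round-trip through SSBOND records
  m <- two_cys_model(2.05)
  m$disulfides <- detect_disulfides(m)
  path <- write_tmp(character(0))
  write_pdb(m, path)
  expect_true(any(startsWith(readLines(path), "SSBOND")))
  back <- read_pdb_ensemble(path)$models[[1]]
  expect_equal(back$disulfides, m$disulfides, ignore_attr = TRUE)
})

test_that("strip_nonstandard removes foreign residues and atoms, idempotently", {
  fix <- fixture_bundle()
  at <- fix$truth$atoms
  mse <- at[at$resi == 0, ]
  mse$resname <- "MSE"
  mse$resno <- 99L
  mse$resi <- 99L
  spur <- at[1, ]
  spur$name <- "XX1"
  m <- structure_model(rbind(at, mse, spur))
  stripped <- strip_nonstandard(m)
  expect_false(any(stripped$atoms$resname == "MSE"))
  expect_false(any(stripped$atoms$name == "XX1"))
  expect_equal(nrow(stripped$atoms), nrow(at))
  # idempotent; identity on an all-standard model
  expect_identical(strip_nonstandard(stripped)$atoms, stripped$atoms)
  expect_identical(strip_nonstandard(fix$truth)$atoms, fix$truth$atoms)
  # hetero ligands kept on request
  lig <- at[1:3, ]
  lig$resname <- "LIG"
  lig$het <- TRUE
  lig$resno <- 200L
  withlig <- structure_model(rbind(at, lig))
  expect_true(any(strip_nonstandard(withlig, keep_ligands = TRUE)$atoms$het))
  expect_false(any(strip_nonstandard(withlig)$atoms$het))
})

test_that("atom-name dialect mapping is a bijection on its table", {
  fix <- fixture_bundle()
  ch <- map_atom_names(fix$truth, "charmm")
  at <- fix$truth$atoms
  expect_true(all(ch$atoms$name[at$name == "H"] == "HN"))
  expect_true(all(ch$atoms$name[at$name == "OXT"] == "OT2"))
  expect_true(all(ch$atoms$name[at$resname == "ILE" & at$name == "CD1"] == "CD"))
  back <- map_atom_names(ch, "pdb3")
  expect_identical(back$atoms$name, at$name)

  # round trip over the full packaged table, residue by residue
  tab <- default_topology()$dialect
  for (res in unique(tab$resname[tab$resname != "*"])) {
    rows <- tab[tab$resname == res, ]
    m <- toy_model(name = rows$pdb3, element = substr(rows$pdb3, 1, 1),
                   resname = res, resno = rep(1L, nrow(rows)),
                   xyz = matrix(seq_len(3 * nrow(rows)), ncol = 3))
    m2 <- map_atom_names(map_atom_names(m, "charmm"), "pdb3")
    expect_identical(m2$atoms$name, rows$pdb3)
  }

  # unmappable names warn and pass through
  odd <- toy_model(name = c("N", "QQ7"), element = c("N", "C"),
                   resname = "ALA", resno = c(1L, 1L),
                   xyz = rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_warning(out <- map_atom_names(odd, "charmm"), "QQ7")
  expect_identical(out$atoms$name[2], "QQ7")
})

test_that("dihedral angles follow the standard sign convention", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(0, 2, 0)), 0)   # cis, planar
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(1, 1, 1)), 90)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(1, 1, -1)), -90)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(2, 1, 0)), -180)  # trans wraps to -180
})

test_that("torsion measurement and rebuild are mutually inverse", {
  seqs <- list("GASGLV", "MKELAQAFRELGNGSKTVTVEWKY")
  for (sq in seqs) {
    cp <- nmrefine:::compile_placement(sq)
    for (trial in 1:3) {
      set.seed(100 + trial)
      tors <- cp$torsions
      tors$angle <- runif(nrow(tors), -180, 180)
      m <- rebuild_from_torsions(tors, sq)
      t2 <- torsions_of(m)
      mm <- merge(tors, t2, by = c("resi", "name"))
      expect_equal(nrow(mm), nrow(tors))
      expect_lt(max(abs(nmrefine:::wrap_signed(mm$angle.x - mm$angle.y))),
                1e-6)
    }
  }
})

test_that("rebuilt canonical conformations have textbook geometry", {
  sq <- "AAAAAAAAAAAA"
  h <- rebuild_from_torsions(nmrefine:::motif_torsions(sq, "helix"), sq)
  at <- h$atoms
  for (i in 1:8) {
    o <- which(at$resi == i - 1 & at$name == "O")
    n <- which(at$resi == i + 3 & at$name == "N")
    d <- sqrt(sum((at[o, c("x", "y", "z")] - at[n, c("x", "y", "z")])^2))
    expect_lt(d, 3.5)  # i -> i+4 helical H-bond geometry
  }
  tors <- nmrefine:::motif_torsions(sq, "helix")
  tors$angle[tors$name %in% c("phi", "psi")] <- 180
  e <- rebuild_from_torsions(tors, sq)
  ca <- model_xyz(e)[e$atoms$name == "CA", ]
  dd <- sqrt(rowSums(diff(ca)^2))
  expect_equal(dd, rep(3.804, length(dd)), tolerance = 0.02)
})

test_that("ensembles enforce topology identity across members", {
  m <- rebuild_from_torsions(NULL, "GAV")
  m2 <- m
  m2$atoms <- m2$atoms[-5, ]
  expect_error(ensemble(list(m, m2)), "topology error")
  expect_silent(ensemble(list(m, m)))
})
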