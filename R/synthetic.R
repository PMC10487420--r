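#' Specification for a synthetic refinement fixture
#'
#' Describes a ground-truth peptide, the restraints derived from it and
#' the perturbed starting structure, so that the full parse/refine/
#' validate pipeline can be exercised without any deposited data.
#'
#' @param sequence residue codes (one-letter string or 3-letter vector).
#' @param motif named backbone motif: \code{"helix"}, \code{"strand"} or
#'   \code{"mixed"} (helix-turn-strand hairpin).
#' @param n_noe named integer vector of NOE counts per category
#'   (\code{intraresidual}, \code{sequential}, \code{medium},
#'   \code{long}).
#' @param noe_noise_sigma Gaussian noise on target distances, Angstrom.
#' @param bound_padding half width of the restraint interval, Angstrom
#'   (\code{dminus = dplus = bound_padding}).
#' @param dihedral_restraint_fraction fraction of residues receiving
#'   phi/psi restraints.
#' @param dihedral_noise_sigma Gaussian noise on dihedral targets, deg.
#' @param dihedral_delta flat-bottom half width of dihedral restraints,
#'   deg.
#' @param dihedral_k dihedral force constant, energy deg^-2.
#' @param perturb_sigma torsion perturbation of the starting structure,
#'   deg.
#' @param seed RNG seed controlling all sampling.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(sequence = "MKELAQAFRELGNGSKTVTVEWKY",
                         motif = "mixed",
                         n_noe = c(intraresidual = 60, sequential = 60,
                                   medium = 40, long = 40),
                         noe_noise_sigma = 0.1, bound_padding = 0.5,
                         dihedral_restraint_fraction = 0.5,
                         dihedral_noise_sigma = 5, dihedral_delta = 20,
                         dihedral_k = 0.02, perturb_sigma = 25,
                         seed = 1337) {
  stopifnot(noe_noise_sigma >= 0, bound_padding >= 0, perturb_sigma >= 0,
            all(n_noe >= 0))
  structure(list(sequence = sequence, motif = motif, n_noe = n_noe,
                 noe_noise_sigma = noe_noise_sigma,
                 bound_padding = bound_padding,
                 dihedral_restraint_fraction = dihedral_restraint_fraction,
                 dihedral_noise_sigma = dihedral_noise_sigma,
                 dihedral_delta = dihedral_delta, dihedral_k = dihedral_k,
                 perturb_sigma = perturb_sigma, seed = seed),
            class = "fixture_spec")
}

# Frozen turn torsions of the mixed (helix-turn-strand) motif, chosen so
# the strand folds back against the helix (tight hairpin, no steric
# collapse).
..mixed_turn <- list(phi = c(-64, -90, 85, -90),
                     psi = c(-40, 5, 5, 125))

# Canonical backbone torsions for a named motif. The mixed motif is a
# helix (residues 1..11), a frozen four-residue turn, and a strand that
# packs back against the helix, giving genuine long-range contacts.
motif_torsions <- function(sequence, motif, topology = default_topology()) {
  seq3 <- as_sequence3(sequence)
  n <- length(seq3)
  if (motif == "helix") {
    phi <- rep(-57, n); psi <- rep(-47, n)
  } else if (motif == "strand") {
    phi <- rep(-120, n); psi <- rep(130, n)
  } else if (motif == "mixed") {
    if (n < 18) stop("mixed motif needs at least 18 residues")
    nh <- 11
    turn <- ..mixed_turn
    phi <- c(rep(-57, nh), turn$phi, rep(-120, n - nh - length(turn$phi)))
    psi <- c(rep(-47, nh), turn$psi, rep(130, n - nh - length(turn$psi)))
  } else stop("unknown motif: ", motif)
  cp <- compile_placement(seq3, topology)
  tors <- cp$torsions
  ang <- default_theta(cp)
  ang[tors$name == "phi"] <- phi[tors$resi[tors$name == "phi"] + 1]
  ang[tors$name == "psi"] <- psi[tors$resi[tors$name == "psi"] + 1]
  ang[tors$name == "omega"] <- 180
  ang[tors$name == "chi1"] <- -60
  ang[grepl("^chi[234]$", tors$name)] <- 180
  structure(data.frame(resi = tors$resi, resno = tors$resi + 1L,
                       name = tors$name, angle = ang,
                       stringsAsFactors = FALSE),
            class = c("torsion_set", "data.frame"))
}

#' Build the ground-truth model of a fixture
#'
#' Ideal-geometry model at the motif torsions; deterministic.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param topology an \code{nmr_topology}.
#' @return an \code{nmr_model}.
#' @export
make_truth <- function(spec, topology = default_topology()) {
  tors <- motif_torsions(spec$sequence, spec$motif, topology)
  rebuild_from_torsions(tors, spec$sequence, topology)
}

#' Derive restraints from a ground-truth model
#'
#' Samples proton-proton pairs with true distance < 5.5 A (the physical
#' NOE observability range) and bond-graph separation > 3, stratified to
#' the per-category counts; the target distance is the true distance plus
#' Gaussian noise, with the bound interval \code{[d - padding, d +
#' padding]}. Dihedral phi/psi restraints are drawn at the truth torsions
#' plus noise. Errors when a category cannot supply the requested count,
#' or when the truth violates more than 5\% of the emitted restraints.
#'
#' @param truth an \code{nmr_model} (from \code{\link{make_truth}}).
#' @param spec a \code{\link{fixture_spec}}.
#' @param topology an \code{nmr_topology}.
#' @return a \code{restraint_set}.
#' @export
derive_restraints <- function(truth, spec, topology = default_topology()) {
  set.seed(spec$seed)
  at <- truth$atoms
  xyz <- coords(truth)
  np <- nonbonded_pairs(nrow(at), model_bonds(truth, topology),
                        at$element, topology$radii)
  is_h <- at$element == "H"
  keep <- is_h[np$i] & is_h[np$j]
  pi <- np$i[keep]; pj <- np$j[keep]
  d <- sqrt(rowSums((xyz[pi, , drop = FALSE] - xyz[pj, , drop = FALSE])^2))
  obs <- d < 5.5
  pi <- pi[obs]; pj <- pj[obs]; d <- d[obs]
  sep <- abs(at$resno[pi] - at$resno[pj])
  category <- ifelse(sep == 0, "intraresidual",
                     ifelse(sep == 1, "sequential",
                            ifelse(sep <= 4, "medium", "long")))
  noes <- list()
  for (cl in names(spec$n_noe)) {
    want <- spec$n_noe[[cl]]
    if (want == 0) next
    cand <- which(category == cl)
    if (length(cand) < want)
      stop("category '", cl, "' unsatisfiable: ", length(cand),
           " candidate pair(s) < requested ", want)
    take <- sample(cand, want)
    for (k in take) {
      dd <- max(0.5, d[k] + rnorm(1, 0, spec$noe_noise_sigma))
      noes[[length(noes) + 1]] <- noe_restraint(
        data.frame(resid = at$resno[pi[k]], name = at$name[pi[k]]),
        data.frame(resid = at$resno[pj[k]], name = at$name[pj[k]]),
        d = dd, dminus = spec$bound_padding, dplus = spec$bound_padding,
        source_line = length(noes) + 1L)
    }
  }
  # flat-bottom phi/psi restraints on a residue subset
  tors <- torsions_of(truth, topology)
  n <- n_residues(truth)
  resnos <- sort(unique(at$resno[!at$het]))
  eligible <- resnos[resnos > min(resnos) & resnos < max(resnos)]
  picked <- sort(sample(eligible,
                        round(spec$dihedral_restraint_fraction *
                                length(eligible))))
  dihedrals <- list()
  for (rn in picked) {
    ri <- at$resi[match(rn, at$resno)]
    for (nm in c("phi", "psi")) {
      truth_ang <- tors$angle[tors$resi == ri & tors$name == nm]
      if (!length(truth_ang)) next
      sel <- dihedral_quad_selection(nm, rn)
      dihedrals[[length(dihedrals) + 1]] <- dihedral_restraint(
        sel, theta0 = wrap180(truth_ang +
                                rnorm(1, 0, spec$dihedral_noise_sigma)),
        delta = spec$dihedral_delta, k = spec$dihedral_k,
        source_line = length(dihedrals) + 1L)
    }
  }
  rs <- restraint_set(noes, dihedrals,
                      provenance = sprintf("synthetic (seed %d)", spec$seed))
  viol <- vapply(rs$noes, function(r) noe_violation(truth, r), 0)
  if (mean(viol == 0) < 0.95)
    stop("construction check failed: truth violates ",
         sum(viol > 0), "/", length(viol), " restraints")
  rs
}

dihedral_quad_selection <- function(name, resno) {
  if (name == "phi")
    data.frame(resid = c(resno - 1, resno, resno, resno),
               name = c("C", "N", "CA", "C"), stringsAsFactors = FALSE)
  else
    data.frame(resid = c(resno, resno, resno, resno + 1),
               name = c("N", "CA", "C", "N"), stringsAsFactors = FALSE)
}

#' Perturb a model's torsions
#'
#' Adds wrapped Gaussian noise to all rotatable torsions except omega and
#' rebuilds with ideal geometry; \code{sigma = 0} returns the idealised
#' rebuild unchanged.
#'
#' @param truth an \code{nmr_model} (ideal geometry).
#' @param sigma torsion noise in degrees (>= 0).
#' @param seed RNG seed.
#' @param topology an \code{nmr_topology}.
#' @return perturbed \code{nmr_model}.
#' @export
perturb_model <- function(truth, sigma, seed = 1,
                          topology = default_topology()) {
  set.seed(seed)
  tors <- torsions_of(truth, topology)
  jitter <- rnorm(nrow(tors), 0, sigma)
  jitter[tors$name == "omega"] <- 0
  tors$angle <- wrap180(tors$angle + jitter)
  rebuild_from_torsions(tors, model_sequence(truth), topology)
}

#' Place a pseudo-ligand next to a residue pocket
#'
#' Scatters \code{n_atoms} ligand pseudo-atoms 3.0-3.8 A from randomly
#' chosen side-chain heavy atoms of the pocket residues (rejecting
#' placements that clash with the protein), then records the reference
#' binding set as \code{binding_residues(truth, ligand, 4.5)}.
#'
#' @param truth an \code{nmr_model}.
#' @param pocket_residues residue numbers (resno) forming the pocket.
#' @param seed RNG seed.
#' @param n_atoms number of ligand atoms (default 8, range 5-10).
#' @return list with \code{ligand} (n x 3 matrix) and \code{reference}
#'   (residue-number vector).
#' @export
make_ligand_scene <- function(truth, pocket_residues, seed = 1,
                              n_atoms = 8) {
  stopifnot(length(pocket_residues) > 0, n_atoms >= 5, n_atoms <= 10)
  set.seed(seed)
  at <- truth$atoms
  xyz <- coords(truth)
  side <- which(at$resno %in% pocket_residues & at$element != "H" &
                  !at$name %in% c("N", "CA", "C", "O", "OXT"))
  if (!length(side)) stop("pocket residues have no side-chain heavy atoms")
  heavy <- xyz[at$element != "H", , drop = FALSE]
  lig <- matrix(NA_real_, n_atoms, 3)
  for (k in seq_len(n_atoms)) {
    for (try in 1:100) {
      anchor <- xyz[sample(side, 1), ]
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- anchor + runif(1, 3.0, 3.8) * u
      dmin <- min(sqrt(rowSums(sweep(heavy, 2, pos)^2)))
      if (dmin > 2.8) break
    }
    lig[k, ] <- pos
  }
  list(ligand = lig,
       reference = binding_residues(truth, lig, 4.5))
}

# cache for the packaged fixture (deterministic, so safe to reuse)
.fixture_cache <- new.env(parent = emptyenv())

#' The packaged 24-residue demonstration fixture
#'
#' A helix-turn-strand peptide (seed 1337) with 200 ground-truth-derived
#' NOE restraints (60 intraresidual / 60 sequential / 40 medium / 40
#' long), flat-bottom phi/psi restraints on half the interior residues,
#' and a starting structure perturbed by 25 degrees of torsion noise.
#' Used by the tests, the documentation and the demo command.
#'
#' @param topology an \code{nmr_topology}.
#' @return list with \code{spec}, \code{truth}, \code{restraints},
#'   \code{start}.
#' @export
packaged_fixture <- function(topology = default_topology()) {
  if (!is.null(.fixture_cache$fix)) return(.fixture_cache$fix)
  spec <- fixture_spec()
  truth <- make_truth(spec, topology)
  restraints <- derive_restraints(truth, spec, topology)
  start <- perturb_model(truth, spec$perturb_sigma, seed = spec$seed + 1,
                         topology = topology)
  fix <- list(spec = spec, truth = truth, restraints = restraints,
              start = start)
  .fixture_cache$fix <- fix
  fix
}

#' Write fixture files to disk
#'
#' Emits the truth and start models as PDB and the restraints as
#' XPLOR-dialect text, so downstream runs exercise the real parsers.
#'
#' @param fixture a fixture list (see \code{\link{packaged_fixture}}).
#' @param dir output directory (created if missing).
#' @return named vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(truth = file.path(dir, "truth.pdb"),
             start = file.path(dir, "start.pdb"),
             noe = file.path(dir, "noe.tbl"),
             dihedral = file.path(dir, "dihedral.tbl"))
  write_pdb(fixture$truth, paths["truth"])
  write_pdb(fixture$start, paths["start"])
  writeLines(write_xplor_noe(fixture$restraints$noes), paths["noe"])
  writeLines(write_xplor_dihedral(fixture$restraints$dihedrals),
             paths["dihedral"])
  invisible(paths)
}
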