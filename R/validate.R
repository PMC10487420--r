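#' NOE upper-bound violation of a restraint
#'
#' The distance by which the model's effective distance exceeds the upper
#' bound: \code{max(0, effective_distance - upper)}. Lower-bound
#' excursions are excluded from this statistic by definition.
#'
#' @param model an \code{nmr_model}.
#' @param restraint an \code{noe_restraint}.
#' @return violation in Angstrom (>= 0).
#' @export
noe_violation <- function(model, restraint) {
  max(0, effective_distance(model, restraint) - restraint$upper)
}

#' NOE violation statistics per sequence-separation category
#'
#' Per-restraint violations are computed on each model; for an ensemble
#' the per-restraint violation is the mean over models
#' (\code{aggregate = "mean"}, the default) before statistics are taken,
#' or the per-model violations are pooled (\code{aggregate =
#' "per_model"}). The RMS is taken over all restraints in the category
#' with satisfied restraints contributing zero (set
#' \code{violated_only = TRUE} for the violated-only variant);
#' \code{n_gt_<c>} counts restraints with violation strictly greater than
#' cutoff c for the bins 0.0, 0.5, 1.0 and 2.0 A.
#'
#' @param x an \code{nmr_model}, \code{nmr_ensemble} or list of models.
#' @param restraints a \code{restraint_set} or list of
#'   \code{noe_restraint}.
#' @param cutoffs violation bin cutoffs in Angstrom.
#' @param aggregate ensemble aggregation rule.
#' @param violated_only RMS over violated restraints only (default FALSE).
#' @return data frame (class \code{violation_stats}) with one row per
#'   category (\code{all}, \code{intraresidual}, \code{sequential},
#'   \code{medium}, \code{long}) and columns \code{n_restraints},
#'   \code{max_violation}, \code{rms_violation} and one count column per
#'   cutoff.
#' @export
violation_stats <- function(x, restraints, cutoffs = c(0, 0.5, 1, 2),
                            aggregate = c("mean", "per_model"),
                            violated_only = FALSE) {
  aggregate <- match.arg(aggregate)
  noes <- if (inherits(restraints, "restraint_set")) restraints$noes
          else restraints
  models <- if (inherits(x, "nmr_ensemble")) x$models
            else if (inherits(x, "nmr_model")) list(x) else x
  viol_m <- vapply(models, function(m)
    vapply(noes, function(r) noe_violation(m, r), 0),
    numeric(length(noes)))
  viol_m <- matrix(viol_m, nrow = length(noes))
  cat_r <- vapply(noes, classify_noe, "")
  if (aggregate == "mean") {
    v <- rowMeans(viol_m)
    cats <- cat_r
  } else {
    v <- as.vector(viol_m)
    cats <- rep(cat_r, ncol(viol_m))
  }
  levels <- c("all", "intraresidual", "sequential", "medium", "long")
  stat_row <- function(vv) {
    if (!length(vv)) {
      counts <- rep(0L, length(cutoffs))
      row <- c(0L, 0, 0, counts)
    } else {
      rms_set <- if (violated_only) vv[vv > 0] else vv
      rms <- if (length(rms_set)) sqrt(mean(rms_set^2)) else 0
      row <- c(length(vv), max(vv), rms,
               vapply(cutoffs, function(cc) sum(vv > cc), 0))
    }
    row
  }
  rows <- rbind(stat_row(v),
                t(vapply(levels[-1], function(cl) stat_row(v[cats == cl]),
                         numeric(3 + length(cutoffs)))))
  out <- as.data.frame(rows)
  names(out) <- c("n_restraints", "max_violation", "rms_violation",
                  paste0("n_gt_", sub("\\.?0+$", "", format(cutoffs))))
  rownames(out) <- levels
  structure(out, class = c("violation_stats", "data.frame"))
}

#' Dihedral restraint violation statistics
#'
#' Per-restraint violation is \code{max(0, |wrap(theta - theta0)| -
#' delta)} in degrees; max and RMS are taken over all restraints with
#' satisfied restraints contributing zero.
#'
#' @param model an \code{nmr_model}.
#' @param dihedrals a \code{restraint_set} or list of
#'   \code{dihedral_restraint}.
#' @return list with \code{max_violation}, \code{rms_violation},
#'   \code{n_restraints}.
#' @export
dihedral_violation_stats <- function(model, dihedrals) {
  dih <- if (inherits(dihedrals, "restraint_set")) dihedrals$dihedrals
         else dihedrals
  if (!length(dih))
    return(list(max_violation = 0, rms_violation = 0, n_restraints = 0L))
  at <- model$atoms
  xyz <- coords(model)
  quads <- t(vapply(dih, function(r) resolve_dihedral_atoms(at, r),
                    integer(4)))
  th <- cpp_dihedrals(xyz, quads[, 1], quads[, 2], quads[, 3],
                      quads[, 4]) * 180 / pi
  v <- pmax(0, abs(wrap_signed(th - vapply(dih, `[[`, 0, "theta0"))) -
              vapply(dih, `[[`, 0, "delta"))
  list(max_violation = max(v), rms_violation = sqrt(mean(v^2)),
       n_restraints = length(v))
}

#' All-atom steric clash score
#'
#' Number of nonbonded atom pairs (bond-graph separation > 3) whose
#' distance falls below the summed contact radii minus
#' \code{overlap_threshold}, normalised per 1000 atoms.
#'
#' @param model an \code{nmr_model}.
#' @param overlap_threshold allowed overlap in Angstrom (default 0.4).
#' @param topology an \code{nmr_topology}.
#' @return clashing pairs per 1000 atoms.
#' @export
clash_score <- function(model, overlap_threshold = 0.4,
                        topology = default_topology()) {
  at <- model$atoms
  np <- nonbonded_pairs(nrow(at), model_bonds(model, topology),
                        at$element, topology$radii)
  cnt <- cpp_clash_count(coords(model), np$i, np$j, np$rmin,
                         overlap_threshold)
  1000 * cnt / nrow(at)
}

#' Allowed-region map for Ramachandran scoring
#'
#' Thresholds a phi-psi STAP table: a bin is allowed when its potential
#' value is below \code{threshold} (low potential = frequently observed).
#'
#' @param table a phi-psi \code{stap_table}.
#' @param threshold allowed-region potential cutoff (default 4).
#' @return list with \code{bin_width} and logical \code{allowed} grid.
#' @export
rama_region_map <- function(table, threshold = 4) {
  stopifnot(inherits(table, "stap_table"), table$pair_type == "phi_psi")
  list(bin_width = table$bin_width, allowed = table$grid < threshold)
}

#' Percentage of residues in allowed Ramachandran regions
#'
#' Fraction of non-terminal residues whose (phi, psi) pair falls in an
#' allowed bin of the region map.
#'
#' @param model an \code{nmr_model}.
#' @param region_map a map from \code{\link{rama_region_map}}.
#' @param topology an \code{nmr_topology}.
#' @return percentage in [0, 100].
#' @export
ramachandran_pct <- function(model, region_map,
                             topology = default_topology()) {
  pp <- phi_psi_table(model, topology)
  if (nrow(pp) < 1 || n_residues(model) < 3)
    stop("too few residues for Ramachandran analysis")
  nb <- nrow(region_map$allowed)
  i <- angle_bin(pp$phi, region_map$bin_width, nb)
  j <- angle_bin(pp$psi, region_map$bin_width, nb)
  100 * mean(region_map$allowed[cbind(i, j)])
}

phi_psi_table <- function(model, topology = default_topology()) {
  tors <- torsions_of(model, topology)
  phi <- tors[tors$name == "phi", c("resi", "angle")]
  psi <- tors[tors$name == "psi", c("resi", "angle")]
  mm <- merge(phi, psi, by = "resi")
  names(mm) <- c("resi", "phi", "psi")
  # non-terminal residues only: phi needs a preceding residue, and the
  # final residue's psi is dropped here
  mm[mm$resi < max(model$atoms$resi[!model$atoms$het]), , drop = FALSE]
}

#' Secondary-structure ratio by torsion windows
#'
#' A torsion-window heuristic (not DSSP): a residue is helix when
#' (phi, psi) lies in [-100, -30] x [-80, -5] for at least 3 consecutive
#' residues, sheet when (phi, psi) lies in [-180, -90] x ([90, 180] or
#' [-180, -170]) for at least 2 consecutive residues, coil otherwise.
#' Percentages are over assignable (non-terminal) residues.
#'
#' @param model an \code{nmr_model}.
#' @param topology an \code{nmr_topology}.
#' @return named numeric vector \code{c(helix, sheet, coil)} in percent,
#'   summing to 100.
#' @export
secondary_structure_ratio <- function(model,
                                      topology = default_topology()) {
  pp <- phi_psi_table(model, topology)
  helix_ok <- pp$phi >= -100 & pp$phi <= -30 & pp$psi >= -80 & pp$psi <= -5
  sheet_ok <- pp$phi >= -180 & pp$phi <= -90 &
    (pp$psi >= 90 | pp$psi <= -170)
  run_assign <- function(ok, min_run) {
    out <- logical(length(ok))
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values))
      if (r$values[k] && r$lengths[k] >= min_run)
        out[starts[k]:ends[k]] <- TRUE
    out
  }
  helix <- run_assign(helix_ok, 3)
  sheet <- run_assign(sheet_ok, 2) & !helix
  n <- nrow(pp)
  c(helix = 100 * sum(helix) / n, sheet = 100 * sum(sheet) / n,
    coil = 100 * sum(!helix & !sheet) / n)
}

#' Ligand-binding residues by heavy-atom contact
#'
#' Residues with at least one heavy atom strictly within \code{cutoff} of
#' at least one ligand heavy atom.
#'
#' @param model an \code{nmr_model}.
#' @param ligand_atoms n x 3 matrix of ligand heavy-atom coordinates.
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @return sorted integer vector of residue numbers (\code{resno}).
#' @export
binding_residues <- function(model, ligand_atoms, cutoff = 4.5) {
  if (is.null(dim(ligand_atoms)) || nrow(ligand_atoms) == 0)
    stop("empty ligand")
  stopifnot(cutoff > 0)
  at <- model$atoms
  heavy <- which(at$element != "H" & !at$het)
  xyz <- coords(model)[heavy, , drop = FALSE]
  hit <- rep(FALSE, length(heavy))
  for (k in seq_len(nrow(ligand_atoms))) {
    d2 <- (xyz[, 1] - ligand_atoms[k, 1])^2 +
      (xyz[, 2] - ligand_atoms[k, 2])^2 +
      (xyz[, 3] - ligand_atoms[k, 3])^2
    hit <- hit | d2 < cutoff^2
  }
  sort(unique(at$resno[heavy[hit]]))
}

#' Confusion counts for two residue sets over a universe
#'
#' @param predicted,reference vectors of residue identifiers (subsets of
#'   \code{universe}).
#' @param universe vector of all residue identifiers considered.
#' @return list with integer \code{TP}, \code{TN}, \code{FP}, \code{FN}
#'   (class \code{confusion_counts}); they sum to
#'   \code{length(universe)}.
#' @export
confusion_counts <- function(predicted, reference, universe) {
  if (length(setdiff(predicted, universe)) ||
      length(setdiff(reference, universe)))
    stop("predicted/reference sets must be subsets of the universe")
  p <- universe %in% predicted
  r <- universe %in% reference
  structure(list(TP = sum(p & r), TN = sum(!p & !r), FP = sum(p & !r),
                 FN = sum(!p & r)), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \code{MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}; when
#' any factor of the denominator is zero the value is 0 by convention.
#'
#' @param counts a \code{confusion_counts} (or list with TP/TN/FP/FN).
#' @return value in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}
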