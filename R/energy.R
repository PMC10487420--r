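#' NOE soft-asymptote potential parameters
#'
#' The soft-asymptote restraint energy is flat between the bounds,
#' harmonic (force constant \code{k_noe}) immediately outside, and beyond
#' \code{upper + r_switch} switches to a linear asymptote of slope
#' \code{min(f_max, 2 k_noe r_switch)} so that badly violated restraints
#' exert a bounded force. The default \code{f_max = 2 k_noe r_switch}
#' makes the potential C1-continuous at the switch.
#'
#' @param k_noe harmonic force constant, energy A^-2 (> 0).
#' @param r_switch width of the harmonic region beyond the upper bound, A.
#' @param f_max maximum asymptotic slope, energy A^-1.
#' @return object of class \code{noe_params}.
#' @export
noe_params <- function(k_noe = 1, r_switch = 1, f_max = 2 * k_noe * r_switch) {
  stopifnot(k_noe > 0, r_switch > 0, f_max > 0)
  structure(list(k_noe = k_noe, r_switch = r_switch, f_max = f_max),
            class = "noe_params")
}

#' Energy term weights
#'
#' Nonnegative multipliers applied to each term before summation into the
#' total energy. All default to 1; the composite energy is reported in
#' reduced (dimensionless) units.
#'
#' @param w_stereo,w_solv,w_noe,w_dihe,w_stap nonnegative weights.
#' @return object of class \code{energy_weights}.
#' @export
energy_weights <- function(w_stereo = 1, w_solv = 1, w_noe = 1, w_dihe = 1,
                           w_stap = 1) {
  w <- c(w_stereo = w_stereo, w_solv = w_solv, w_noe = w_noe,
         w_dihe = w_dihe, w_stap = w_stap)
  stopifnot(all(w >= 0))
  structure(as.list(w), class = "energy_weights")
}

#' Soft-asymptote NOE restraint energy
#'
#' Piecewise potential in the model distance \code{r}: harmonic
#' \code{k (lower - r)^2} below the lower bound, zero inside
#' \code{[lower, upper]}, harmonic \code{k (r - upper)^2} up to
#' \code{upper + r_switch}, then linear with slope
#' \code{min(f_max, 2 k r_switch)}.
#'
#' @param r_eff effective distance(s), Angstrom (vectorised).
#' @param lower,upper restraint bounds, Angstrom.
#' @param params an \code{\link{noe_params}}.
#' @return energy value(s), reduced units.
#' @export
noe_energy <- function(r_eff, lower, upper, params = noe_params()) {
  k <- params$k_noe
  rs <- params$r_switch
  slope <- min(params$f_max, 2 * k * rs)
  n <- length(r_eff)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  e <- numeric(n)
  lo <- r_eff < lower
  e[lo] <- k * (lower[lo] - r_eff[lo])^2
  hi <- r_eff > upper & r_eff <= upper + rs
  e[hi] <- k * (r_eff[hi] - upper[hi])^2
  far <- r_eff > upper + rs
  e[far] <- k * rs^2 + slope * (r_eff[far] - upper[far] - rs)
  e
}

#' Flat-bottom harmonic dihedral restraint energy
#'
#' Zero within \code{delta} degrees of \code{theta0} (angular difference
#' wrapped to \code{(-180, 180]}), harmonic beyond:
#' \code{k (|wrap(theta - theta0)| - delta)^2}.
#'
#' @param theta model dihedral(s), degrees (vectorised).
#' @param theta0 target angle(s), degrees.
#' @param delta flat-bottom half width(s), degrees.
#' @param k force constant(s), energy deg^-2.
#' @return energy value(s), reduced units.
#' @export
dihedral_energy <- function(theta, theta0, delta, k = 1) {
  dev <- abs(wrap_signed(theta - theta0))
  exc <- pmax(0, dev - delta)
  k * exc^2
}

# --- selection resolution ---------------------------------------------------

# Expand one atom selection (resid/name pattern/segid) against an atom
# table. Wildcard (#, *, %) is terminal and matches any suffix.
match_selection <- function(atoms, resid, pattern, segid = NA) {
  sel <- atoms$resno == resid
  if (!is.na(segid)) sel <- sel & atoms$chain == segid
  if (grepl("[#*%]$", pattern)) {
    prefix <- substr(pattern, 1, nchar(pattern) - 1)
    sel <- sel & startsWith(toupper(atoms$name), toupper(prefix))
  } else {
    sel <- sel & toupper(atoms$name) == toupper(pattern)
  }
  which(sel)
}

resolve_group <- function(atoms, g, what = "selection") {
  idx <- unique(unlist(lapply(seq_len(nrow(g)), function(i)
    match_selection(atoms, g$resid[i], g$name[i], g$segid[i]))))
  if (!length(idx))
    stop("unresolvable ", what, ": ",
         paste(paste0("resid ", g$resid, " name ", g$name), collapse = " / "))
  sort(idx)
}

# Atom index pair matrix for an NOE restraint (all cross pairs a x b).
resolve_noe_pairs <- function(atoms, restraint) {
  ia <- resolve_group(atoms, restraint$group_a,
                      paste0("selection (restraint line ",
                             restraint$source_line, ")"))
  ib <- resolve_group(atoms, restraint$group_b,
                      paste0("selection (restraint line ",
                             restraint$source_line, ")"))
  pairs <- expand.grid(a = ia, b = ib)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  if (!nrow(pairs))
    stop("restraint resolves to no atom pair (line ",
         restraint$source_line, ")")
  as.matrix(pairs)
}

resolve_dihedral_atoms <- function(atoms, restraint) {
  vapply(seq_len(4), function(i) {
    w <- match_selection(atoms, restraint$atoms$resid[i],
                         restraint$atoms$name[i], restraint$atoms$segid[i])
    if (length(w) != 1)
      stop("dihedral selection does not resolve to one atom (line ",
           restraint$source_line, ")")
    w
  }, 0L)
}

#' Effective distance of an (ambiguous) NOE restraint
#'
#' r^-6 summed effective distance over all resolved selection pairs:
#' \code{r_eff = (sum r_ij^-6)^(-1/6)}; a single pair reduces to the plain
#' Euclidean distance.
#'
#' @param model an \code{nmr_model}.
#' @param restraint an \code{noe_restraint}.
#' @return effective distance in Angstrom.
#' @export
effective_distance <- function(model, restraint) {
  pairs <- resolve_noe_pairs(model$atoms, restraint)
  xyz <- coords(model)
  cpp_reff(xyz, pairs[, 1], pairs[, 2], c(1L, nrow(pairs) + 1L))
}

# --- stereochemical and solvation terms --------------------------------------

#' Soft-core nonbonded repulsion energy
#'
#' Sum over nonbonded atom pairs (bond-graph separation > 3) of
#' \code{eps ((rmin - r) / rmin)^2} for \code{r < rmin}, where \code{rmin}
#' is the sum of per-element contact radii, with two standard
#' attenuations: hydrogen-bond-capable pairs get a reduced limit, and 1-4
#' pair limits are scaled (see \code{nonbonded_pairs}). With bonds and
#' angles held ideal by the torsion-space representation, nonbonded
#' overlap is the only stereochemical degree of freedom requiring a
#' penalty.
#'
#' @param model an \code{nmr_model}.
#' @param topology an \code{nmr_topology}.
#' @param eps repulsion strength (default 1).
#' @return energy, reduced units.
#' @export
stereo_energy <- function(model, topology = default_topology(), eps = 1) {
  at <- model$atoms
  np <- nonbonded_pairs(nrow(at), model_bonds(model, topology),
                        at$element, topology$radii)
  cpp_softcore(coords(model), np$i, np$j, np$rmin, eps)
}

#' Contact-burial solvation surrogate energy
#'
#' A deterministic stand-in for implicit solvation: each heavy atom
#' contributes \code{s(class) * burial}, where burial is the number of
#' heavy atoms within \code{cutoff} (excluding itself and directly bonded
#' atoms) and \code{s} is a per-element preference (negative for
#' hydrophobic C/S, positive for polar N/O), so the term rewards
#' hydrophobic burial and penalises buried polar atoms. It is not a
#' generalized-Born model.
#'
#' @param model an \code{nmr_model}.
#' @param topology an \code{nmr_topology}.
#' @param cutoff burial counting radius, Angstrom (default 6.5).
#' @return energy, reduced units.
#' @export
solv_energy <- function(model, topology = default_topology(), cutoff = 6.5) {
  ctx <- solv_context(model$atoms, model_bonds(model, topology), topology)
  solv_eval(coords(model), ctx, cutoff)
}

solv_context <- function(atoms, bonds, topology) {
  heavy <- which(atoms$element != "H")
  if (length(heavy) < 2)
    return(list(pi = integer(0), pj = integer(0),
                s = rep(0, nrow(atoms))))
  pairs <- t(utils::combn(heavy, 2))
  bkey <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  keep <- !(paste(pairs[, 1], pairs[, 2]) %in% bkey)
  s <- topology$solvation[atoms$element]
  s[is.na(s)] <- 0
  list(pi = pairs[keep, 1], pj = pairs[keep, 2], s = s)
}

solv_eval <- function(xyz, ctx, cutoff = 6.5) {
  counts <- cpp_burial(xyz, ctx$pi, ctx$pj, cutoff)
  sum(ctx$s * counts)
}

# --- total energy ------------------------------------------------------------

#' Composite refinement energy of a model
#'
#' Evaluates the composite target energy
#' \code{E_tot = E_stereo + E_solv + (E_exp_noe + E_exp_dihe) + E_stap}
#' on the model's coordinates, with each term multiplied by its weight.
#' The full breakdown is returned, never just the scalar.
#'
#' @param model an \code{nmr_model}.
#' @param restraints a \code{restraint_set}.
#' @param tables list of \code{stap_table} (may be empty).
#' @param weights an \code{\link{energy_weights}}.
#' @param params an \code{\link{noe_params}}.
#' @param topology an \code{nmr_topology}.
#' @return object of class \code{energy_breakdown}: named list with
#'   \code{E_stereo}, \code{E_solv}, \code{E_exp_noe}, \code{E_exp_dihe},
#'   \code{E_stap}, \code{E_tot}.
#' @export
total_energy <- function(model, restraints = restraint_set(),
                         tables = list(), weights = energy_weights(),
                         params = noe_params(),
                         topology = default_topology()) {
  at <- model$atoms
  xyz <- coords(model)
  bonds <- model_bonds(model, topology)
  np <- nonbonded_pairs(nrow(at), bonds, at$element, topology$radii)
  e_stereo <- weights$w_stereo * cpp_softcore(xyz, np$i, np$j, np$rmin, 1)
  e_solv <- weights$w_solv * solv_eval(xyz, solv_context(at, bonds, topology))

  e_noe <- 0
  if (length(restraints$noes)) {
    reff <- vapply(restraints$noes, function(r) effective_distance(model, r),
                   0)
    lo <- vapply(restraints$noes, `[[`, 0, "lower")
    up <- vapply(restraints$noes, `[[`, 0, "upper")
    e_noe <- weights$w_noe * sum(noe_energy(reff, lo, up, params))
  }
  e_dihe <- 0
  if (length(restraints$dihedrals)) {
    quads <- t(vapply(restraints$dihedrals,
                      function(r) resolve_dihedral_atoms(at, r),
                      integer(4)))
    th <- cpp_dihedrals(xyz, quads[, 1], quads[, 2], quads[, 3],
                        quads[, 4]) * 180 / pi
    e_dihe <- weights$w_dihe * sum(dihedral_energy(
      th, vapply(restraints$dihedrals, `[[`, 0, "theta0"),
      vapply(restraints$dihedrals, `[[`, 0, "delta"),
      vapply(restraints$dihedrals, `[[`, 0, "k")))
  }
  e_stap <- 0
  if (length(tables)) {
    tors <- torsions_of(model, topology)
    e_stap <- weights$w_stap * stap_model_energy(tors, at, tables)
  }
  energy_breakdown(e_stereo, e_solv, e_noe, e_dihe, e_stap)
}

energy_breakdown <- function(e_stereo, e_solv, e_noe, e_dihe, e_stap) {
  out <- list(E_stereo = e_stereo, E_solv = e_solv, E_exp_noe = e_noe,
              E_exp_dihe = e_dihe, E_stap = e_stap,
              E_tot = e_stereo + e_solv + e_noe + e_dihe + e_stap)
  stopifnot(all(vapply(out, is.finite, TRUE)))
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("E_tot = %.4f  (stereo %.4f, solv %.4f, ",
                     "noe %.4f, dihe %.4f, stap %.4f)\n"),
              x$E_tot, x$E_stereo, x$E_solv, x$E_exp_noe, x$E_exp_dihe,
              x$E_stap))
  invisible(x)
}
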