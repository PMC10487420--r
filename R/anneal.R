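#' Simulated-annealing temperature schedule
#'
#' Heat/hold/cool schedule: linear heating from \code{t_start} to
#' \code{t_high} over \code{heat_steps}, a constant hold at \code{t_high}
#' for \code{hold_steps}, then linear cooling to \code{t_end} over
#' \code{cool_steps}. Defaults follow the protocol's printed schedule:
#' 100 -> 1000 K in 3200 steps, 4000 steps at 1000 K, then 8000 steps of
#' relaxation from 1000 K to 25 K. Temperatures are kelvin-labelled
#' reduced temperatures: only the ratio T / t_high enters the acceptance
#' rule.
#'
#' @param t_start,t_high,t_end phase temperatures (> 0).
#' @param heat_steps,hold_steps,cool_steps phase lengths (> 0).
#' @param cycles number of heat/hold/cool cycles (default 1).
#' @return object of class \code{sa_schedule}.
#' @export
sa_schedule <- function(t_start = 100, t_high = 1000, t_end = 25,
                        heat_steps = 3200, hold_steps = 4000,
                        cool_steps = 8000, cycles = 1) {
  stopifnot(t_start > 0, t_high > 0, t_end > 0,
            heat_steps > 0, hold_steps > 0, cool_steps > 0, cycles >= 1)
  structure(list(t_start = t_start, t_high = t_high, t_end = t_end,
                 heat_steps = heat_steps, hold_steps = hold_steps,
                 cool_steps = cool_steps, cycles = cycles),
            class = "sa_schedule")
}

total_steps <- function(schedule) {
  with(schedule, cycles * (heat_steps + hold_steps + cool_steps))
}

#' Temperature at a schedule step
#'
#' Step numbering is 0-based. Returns \code{t_start} at step 0, exactly
#' \code{t_high} throughout the hold phase, and \code{t_end} at the final
#' step.
#'
#' @param step 0-based step index, \code{0 <= step < total}.
#' @param schedule an \code{\link{sa_schedule}}.
#' @return temperature (reduced, kelvin-labelled).
#' @export
temperature_at <- function(step, schedule = sa_schedule()) {
  per <- with(schedule, heat_steps + hold_steps + cool_steps)
  if (any(step < 0 | step >= per * schedule$cycles))
    stop("step out of schedule range [0, ", per * schedule$cycles - 1, "]")
  s <- step %% per
  with(schedule, ifelse(
    s < heat_steps,
    t_start + (t_high - t_start) * s / heat_steps,
    ifelse(s < heat_steps + hold_steps,
           t_high,
           t_high + (t_end - t_high) *
             (s - heat_steps - hold_steps + 1) / cool_steps)))
}

#' Monte Carlo move set
#'
#' Proposals use a mixture kernel: with probability \code{p_uniform} the
#' picked torsion is redrawn uniformly on the circle (barrier crossing),
#' otherwise it is perturbed by a wrapped Gaussian of width \code{sigma}.
#' Both kernels are symmetric, so the Metropolis rule is unchanged.
#'
#' @param sigma Gaussian torsion perturbation width, degrees (> 0).
#' @param p_uniform probability of a uniform redraw proposal (default
#'   0.2; 0 disables the mixture).
#' @param moves_per_step proposed torsion changes per MC step.
#' @param backbone,sidechain enable moves on backbone (phi/psi) and
#'   side-chain (chi) torsions.
#' @param freeze_omega keep peptide omega torsions fixed (default TRUE).
#' @return object of class \code{move_set}.
#' @export
move_set <- function(sigma = 10, p_uniform = 0.2, moves_per_step = 1,
                     backbone = TRUE, sidechain = TRUE,
                     freeze_omega = TRUE) {
  stopifnot(sigma > 0, moves_per_step >= 1, p_uniform >= 0, p_uniform <= 1)
  structure(list(sigma = sigma, p_uniform = p_uniform,
                 moves_per_step = moves_per_step,
                 backbone = backbone, sidechain = sidechain,
                 freeze_omega = freeze_omega), class = "move_set")
}

# symmetric mixture proposal for the chosen torsion indices
propose_angles <- function(current, moveset) {
  u <- runif(length(current)) < moveset$p_uniform
  out <- wrap180(current + rnorm(length(current), 0, moveset$sigma))
  if (any(u)) out[u] <- runif(sum(u), -180, 180)
  out
}

#' One Metropolis Monte Carlo step in torsion space
#'
#' Proposes Gaussian perturbations of randomly chosen torsions and accepts
#' with probability \code{min(1, exp(-dE * t_ref / T))}; downhill moves
#' are always accepted. Angles are wrapped to \code{[-180, 180)}. Uses
#' R's RNG stream, so results are fully determined by the seed in effect.
#'
#' @param torsions named numeric vector of torsion angles (degrees).
#' @param energy_fn function mapping such a vector to a scalar energy (or
#'   to anything with an \code{E_tot} element).
#' @param temperature current temperature.
#' @param moveset a \code{\link{move_set}}.
#' @param t_ref reference temperature multiplying the reduced energy
#'   (default 1000, the schedule's hold temperature).
#' @param movable integer indices of torsions eligible for moves (default
#'   all).
#' @param energy optional current energy (avoids re-evaluation).
#' @return list with \code{torsions}, \code{accepted}, \code{energy}.
#' @export
mc_step <- function(torsions, energy_fn, temperature, moveset = move_set(),
                    t_ref = 1000, movable = seq_along(torsions),
                    energy = NULL) {
  e0 <- energy %||% scalar_energy(energy_fn(torsions))
  prop <- torsions
  pick <- if (length(movable) == 1) rep(movable, moveset$moves_per_step)
          else sample(movable, moveset$moves_per_step, replace = TRUE)
  prop[pick] <- propose_angles(prop[pick], moveset)
  e1 <- scalar_energy(energy_fn(prop))
  de <- e1 - e0
  accepted <- de <= 0 || runif(1) < exp(-de * t_ref / temperature)
  if (accepted) list(torsions = prop, accepted = TRUE, energy = e1)
  else list(torsions = torsions, accepted = FALSE, energy = e0)
}

scalar_energy <- function(e) {
  if (is.list(e)) e$E_tot else as.numeric(e)
}

# --- full-model refinement ---------------------------------------------------

# Precompiled evaluation context for torsion-space annealing: placement,
# resolved restraint indices, nonbonded pair lists and STAP lookups.
build_anneal_context <- function(model, restraints, tables, weights, params,
                                 topology) {
  cp <- compile_placement(model_sequence(model), topology)
  at <- cp$atoms
  np <- nonbonded_pairs(nrow(at), cp$bonds, at$element, topology$radii)
  sctx <- solv_context(at, cp$bonds, topology)

  noe <- NULL
  if (length(restraints$noes)) {
    plist <- lapply(restraints$noes, function(r) resolve_noe_pairs(at, r))
    starts <- cumsum(c(1L, vapply(plist, nrow, 0L)))
    pm <- do.call(rbind, plist)
    noe <- list(ai = pm[, 1], bi = pm[, 2], starts = starts,
                lower = vapply(restraints$noes, `[[`, 0, "lower"),
                upper = vapply(restraints$noes, `[[`, 0, "upper"),
                category = vapply(restraints$noes, classify_noe, ""))
  }
  dihe <- NULL
  if (length(restraints$dihedrals)) {
    quads <- t(vapply(restraints$dihedrals,
                      function(r) resolve_dihedral_atoms(at, r), integer(4)))
    dihe <- list(quads = quads,
                 theta0 = vapply(restraints$dihedrals, `[[`, 0, "theta0"),
                 delta = vapply(restraints$dihedrals, `[[`, 0, "delta"),
                 k = vapply(restraints$dihedrals, `[[`, 0, "k"))
  }
  stap <- NULL
  if (length(tables)) {
    types <- vapply(tables, `[[`, "", "pair_type")
    classes <- vapply(tables, `[[`, "", "residue_class")
    tkey <- paste(cp$torsions$resi, cp$torsions$name)
    items <- list()
    resis <- unique(cp$torsions$resi)
    rn <- at$resname[match(resis, at$resi)]
    for (pt in unique(types)) {
      parts <- strsplit(pt, "_")[[1]]
      for (ri in seq_along(resis)) {
        i1 <- match(paste(resis[ri], parts[1]), tkey)
        i2 <- match(paste(resis[ri], parts[2]), tkey)
        if (is.na(i1) || is.na(i2)) next
        cand <- which(types == pt & classes == rn[ri])
        if (!length(cand)) cand <- which(types == pt & classes == "ALL")
        if (!length(cand)) next
        items[[length(items) + 1]] <- c(i1, i2, cand[1])
      }
    }
    if (length(items)) {
      im <- do.call(rbind, items)
      stap <- list(t1 = im[, 1], t2 = im[, 2], tab = im[, 3],
                   tables = tables)
    }
  }
  list(cp = cp, np = np, sctx = sctx, noe = noe, dihe = dihe, stap = stap,
       weights = weights, params = params)
}

# Energy breakdown at a torsion vector, using the precompiled context.
eval_context_energy <- function(ctx, theta) {
  xyz <- rebuild_coords(ctx$cp, theta)
  w <- ctx$weights
  e_stereo <- w$w_stereo * cpp_softcore(xyz, ctx$np$i, ctx$np$j,
                                        ctx$np$rmin, 1)
  e_solv <- w$w_solv * solv_eval(xyz, ctx$sctx)
  e_noe <- 0
  if (!is.null(ctx$noe)) {
    reff <- cpp_reff(xyz, ctx$noe$ai, ctx$noe$bi, ctx$noe$starts)
    e_noe <- w$w_noe * sum(noe_energy(reff, ctx$noe$lower, ctx$noe$upper,
                                      ctx$params))
  }
  e_dihe <- 0
  if (!is.null(ctx$dihe)) {
    th <- cpp_dihedrals(xyz, ctx$dihe$quads[, 1], ctx$dihe$quads[, 2],
                        ctx$dihe$quads[, 3], ctx$dihe$quads[, 4]) * 180 / pi
    e_dihe <- w$w_dihe * sum(dihedral_energy(th, ctx$dihe$theta0,
                                             ctx$dihe$delta, ctx$dihe$k))
  }
  e_stap <- 0
  if (!is.null(ctx$stap)) {
    s <- ctx$stap
    vals <- vapply(unique(s$tab), function(tb) {
      sel <- s$tab == tb
      sum(stap_energy(cbind(theta[s$t1[sel]], theta[s$t2[sel]]),
                      s$tables[[tb]]))
    }, 0)
    e_stap <- w$w_stap * sum(vals)
  }
  energy_breakdown(e_stereo, e_solv, e_noe, e_dihe, e_stap)
}

# Map a model's measured torsions into the context's theta vector.
theta_from_model <- function(ctx, model, topology) {
  theta <- default_theta(ctx$cp)
  tors <- torsions_of(model, topology)
  m <- match(paste(ctx$cp$torsions$resi, ctx$cp$torsions$name),
             paste(tors$resi, tors$name))
  theta[!is.na(m)] <- tors$angle[m[!is.na(m)]]
  theta
}

#' Refine one model by simulated annealing
#'
#' Metropolis Monte Carlo in torsion space (single-torsion Gaussian moves
#' by default) under the heat/hold/cool schedule, minimising the composite
#' energy. Bond lengths and angles are held at topology-ideal values: the
#' model is converted to torsions and rebuilt, so the starting coordinates
#' are the idealised representation of the input. Fully deterministic
#' given \code{seed}.
#'
#' @param model an \code{nmr_model}.
#' @param restraints a \code{restraint_set}.
#' @param tables list of \code{stap_table} (empty to disable the STAP
#'   term).
#' @param weights an \code{\link{energy_weights}}.
#' @param params an \code{\link{noe_params}}.
#' @param schedule an \code{\link{sa_schedule}}.
#' @param moveset a \code{\link{move_set}}.
#' @param seed integer RNG seed.
#' @param topology an \code{nmr_topology}.
#' @return object of class \code{refinement_result}: \code{final_model},
#'   \code{best_model} (lowest \code{E_tot} seen), \code{energy_trace}
#'   (one row per step), \code{acceptance_rate}, \code{seed}.
#' @export
refine_model <- function(model, restraints, tables = list(),
                         weights = energy_weights(), params = noe_params(),
                         schedule = sa_schedule(), moveset = move_set(),
                         seed = 1, topology = default_topology()) {
  ctx <- build_anneal_context(model, restraints, tables, weights, params,
                              topology)
  theta <- theta_from_model(ctx, model, topology)
  cls <- ctx$cp$torsions$class
  movable <- which((moveset$backbone & cls == "backbone") |
                     (moveset$sidechain & cls == "sidechain") |
                     (!moveset$freeze_omega & cls == "omega"))
  if (!length(movable)) stop("move set leaves no movable torsion")
  nsteps <- total_steps(schedule)
  set.seed(seed)
  eb <- eval_context_energy(ctx, theta)
  best_theta <- theta
  best_e <- eb$E_tot
  trace <- matrix(NA_real_, nsteps, 8,
                  dimnames = list(NULL, c("step", "temperature", "E_stereo",
                                          "E_solv", "E_exp_noe",
                                          "E_exp_dihe", "E_stap", "E_tot")))
  accepted <- 0L
  for (s in seq_len(nsteps) - 1L) {
    temp <- temperature_at(s, schedule)
    pick <- if (length(movable) == 1) rep(movable, moveset$moves_per_step)
            else sample(movable, moveset$moves_per_step, replace = TRUE)
    prop <- theta
    prop[pick] <- propose_angles(prop[pick], moveset)
    eb1 <- eval_context_energy(ctx, prop)
    de <- eb1$E_tot - eb$E_tot
    if (de <= 0 || runif(1) < exp(-de * schedule$t_high / temp)) {
      theta <- prop
      eb <- eb1
      accepted <- accepted + 1L
      if (eb$E_tot < best_e) {
        best_e <- eb$E_tot
        best_theta <- theta
      }
    }
    trace[s + 1L, ] <- c(s, temp, eb$E_stereo, eb$E_solv, eb$E_exp_noe,
                         eb$E_exp_dihe, eb$E_stap, eb$E_tot)
  }
  structure(list(final_model = model_from_theta(ctx$cp, theta),
                 best_model = model_from_theta(ctx$cp, best_theta),
                 final_energy = eb,
                 best_energy = best_e,
                 energy_trace = as.data.frame(trace),
                 acceptance_rate = accepted / nsteps,
                 seed = seed),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf(paste0("<refinement_result> seed %d: best E_tot %.3f, ",
                     "final E_tot %.3f, acceptance %.1f%% over %d steps\n"),
              x$seed, x$best_energy, x$final_energy$E_tot,
              100 * x$acceptance_rate, nrow(x$energy_trace)))
  invisible(x)
}

#' Refine every member of an ensemble
#'
#' Each model is refined with seed \code{base_seed + index - 1}, so runs
#' are reproducible and independent of execution order. The representative
#' conformer is the lexicographic minimum over (number of NOE restraints
#' violated at the 0.0 A cutoff, E_tot) of the best models: fewest
#' violations first, lowest energy as tie-break.
#'
#' @param ens an \code{nmr_ensemble}.
#' @param restraints,tables,weights,params,schedule,moveset,topology as in
#'   \code{\link{refine_model}}.
#' @param base_seed integer; model k uses seed \code{base_seed + k - 1}.
#' @return list with \code{results} (list of \code{refinement_result}) and
#'   \code{representative} (index).
#' @export
refine_ensemble <- function(ens, restraints, tables = list(),
                            weights = energy_weights(),
                            params = noe_params(), schedule = sa_schedule(),
                            moveset = move_set(), base_seed = 1,
                            topology = default_topology()) {
  results <- lapply(seq_along(ens$models), function(k)
    refine_model(ens$models[[k]], restraints, tables, weights, params,
                 schedule, moveset, seed = base_seed + k - 1, topology))
  viol <- vapply(results, function(r) {
    vs <- violation_stats(r$best_model, restraints)
    vs["all", "n_gt_0"]
  }, 0)
  etot <- vapply(results, function(r)
    total_energy(r$best_model, restraints, tables, weights, params,
                 topology)$E_tot, 0)
  rep_idx <- order(viol, etot)[1]
  list(results = results, representative = rep_idx)
}
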