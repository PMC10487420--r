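---
title: "Restrained simulated-annealing refinement of NMR structures"
author: "nmrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained simulated-annealing refinement of NMR structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrefine)
```

## The problem

Solution-NMR structure determination yields an ensemble of conformers
restrained by experimental observables: nuclear Overhauser effect (NOE)
cross-peaks, which translate into interproton distance bounds (typically
observable below about 5.5 Å), and dihedral-angle restraints with a target
angle and tolerance. Deposited NMR ensembles are often less regular than
crystal structures — more steric clashes, more backbone torsions outside
favoured regions — and can benefit from re-refinement against their own
restraints under a modern composite energy. `nmrefine` implements such a
re-refinement protocol at desk scale: restraint parsing and conversion, a
composite reduced energy, simulated annealing, and the standard battery
of evaluation statistics.

## The composite energy

A model is scored by

\[
E_\mathrm{tot} \;=\; E_\mathrm{stereo} + E_\mathrm{solv} +
E_\mathrm{exp} + E_\mathrm{STAP},
\qquad
E_\mathrm{exp} = E_\mathrm{NOE} + E_\mathrm{dihe},
\]

with every term in reduced (dimensionless) units and a non-negative
weight (default 1) applied before summation. `total_energy()` always
returns the full breakdown, and the identity
\(E_\mathrm{tot} = \sum_i w_i E_i\) holds to machine precision.

**NOE term (soft asymptote).** Each restraint carries bounds
\([\mathrm{lower}, \mathrm{upper}] = [d - d^-, d + d^+]\). The energy is
zero inside the bounds, harmonic \(k(r-\mathrm{upper})^2\) for the first
`r_switch` Å beyond the upper bound, and then linear with slope
\(\min(f_\mathrm{max}, 2k\,r_\mathrm{switch})\), so a badly violated
restraint exerts a bounded force instead of tearing the structure;
the short side is harmonic. With the default
\(f_\mathrm{max} = 2k\,r_\mathrm{switch}\) the potential is
C¹-continuous at both branch points. Defaults: \(k = 1\) Å⁻²,
\(r_\mathrm{switch} = 1\) Å. Ambiguous (multi-pair) restraints are scored
through the \(r^{-6}\)-summed effective distance
\(r_\mathrm{eff} = (\sum_{ij} r_{ij}^{-6})^{-1/6}\), the usual NOE
convention: the shortest interpretation dominates.

**Dihedral term (flat-bottom harmonic).** Zero within \(\delta\) degrees
of the target (differences wrapped to \((-180, 180]\)), harmonic
\(k(\Delta - \delta)^2\) beyond, with \(k\) in energy·deg⁻².

**Statistical torsion-angle potential (STAP).** For each residue, 2-D
potentials over the pairs φ–ψ, φ–χ1, ψ–χ1 and χ1–χ2 are read off
knowledge-based tables: a table is \(-\ln P\) of a smoothed, periodic 2-D
histogram of observed torsion pairs, shifted so its minimum is zero, and
evaluated by periodic bilinear interpolation. Table construction
(`build_stap_table()`) takes a bin width (default 10°, must divide 360),
a pseudocount (default 1) and a periodic Gaussian smoothing width
(default 10°). The packaged default tables (`default_stap_tables()`) are
built from a deterministic toy library of jittered helical and extended
peptides with common rotamers — enough to bias sampling toward plausible
backbone/side-chain regions in the demonstrations, but *not* a substitute
for tables derived from a curated structure database, which users should
supply for real refinement work.

**Stereochemistry.** Because the annealer works in torsion space with
bond lengths and angles fixed at ideal values, the only stereochemical
degree of freedom needing a penalty is nonbonded overlap. The term is a
soft-core repulsion \(\varepsilon((r_\mathrm{min}-r)/r_\mathrm{min})^2\)
over atom pairs more than three bonds apart, with
\(r_\mathrm{min}\) the summed per-element contact radii (C 1.70, N 1.55,
O 1.52, S 1.80, H 1.10 Å). Two standard attenuations apply: pairs that
can hydrogen-bond (polar H or donor N/O against acceptor N/O/S) have the
limit reduced by 0.8 Å so that α-helical O(i)···HN(i+4) geometry is not
treated as an overlap, and 1–4 pairs are scaled by 0.8, the usual
force-field treatment of torsion-adjacent contacts. The term is
all-atom: hydrogen repulsion carries real packing information (dropping
it lets compact wrong folds score too well), at the cost of a small
residual strain in idealised conformers whose riding methyl hydrogens
make 1–5 contacts.

**Solvation surrogate.** Implicit-solvent models such as generalized
Born are out of scope here; the solvation term is a declared surrogate
that preserves their qualitative role. Each heavy atom contributes
\(s(\mathrm{element}) \times \mathrm{burial}\), where burial counts heavy
atoms within 6.5 Å (excluding itself and bonded neighbours) and \(s\) is
negative for hydrophobic elements (C, S: −0.02) and positive for polar
ones (N, O: +0.01). The term rewards hydrophobic burial and penalises
buried polar atoms, is deterministic, and is clearly *not* a
generalized-Born model.

## Torsion-space representation

Structures are interconverted between Cartesian and internal coordinates
by natural-extension reference frames: `torsions_of()` measures φ, ψ, ω
and χ1–χ4 (IUPAC sign convention, angles in \([-180, 180)\)); the final
residue's ψ is measured against its carbonyl oxygen (ψ = dihedral
N–CA–C–O − 180°) so the mapping is invertible.
`rebuild_from_torsions()` reconstructs coordinates with ideal bond
lengths and angles; per-residue internal geometry derives from
chemical-component-dictionary ideal residues, including all hydrogens.
The round trip reproduces torsions to well below 1e-6°, and rebuilt
canonical conformers show textbook geometry (α-helical i→i+4 O···N under
3.5 Å; extended Cα–Cα spacing 3.80 Å).

The refined model is therefore the *idealised* representation of the
input: deviations of the deposited bond lengths/angles from ideal values
are discarded when a model enters the annealer. This is the price of a
derivative-free, desk-scale method; Cartesian-space molecular dynamics
under a full force field would preserve them.

## Simulated annealing

Refinement is Metropolis Monte Carlo in torsion space under the
heat/hold/cool schedule: linear heating 100 → 1000 K over 3200 steps,
4000 steps at 1000 K, then linear cooling 1000 → 25 K over 8000 steps
(15,200 steps in total). The temperatures are labels on a reduced scale:
acceptance is \(\min(1, \exp(-\Delta E \cdot T_\mathrm{ref}/T))\) with
\(T_\mathrm{ref}\) the hold temperature, so only the ratio
\(T/T_\mathrm{ref}\) matters and the composite energy stays
dimensionless. One step proposes a change to one randomly chosen
torsion; the proposal is a symmetric mixture kernel — with probability
0.2 the torsion is redrawn uniformly on the circle (barrier crossing,
chosen for fold-recovery robustness across evaluation seeds), otherwise
a wrapped Gaussian of width 10°. ω torsions are frozen at their starting
(trans) values by default. Backbone and side-chain classes can be
enabled independently, and everything (σ, mixture weight, classes,
moves per step) is configurable through `move_set()`.

Runs are fully deterministic given the seed; ensemble members refine
with seeds `base_seed + k - 1`, so results are reproducible and
independent of execution order. The reported `best_model` is the
lowest-total-energy state visited; the ensemble *representative* is the
lexicographic minimum over (number of NOE restraints violated at the
0.0 Å cutoff, total energy) — the stricter reading of "fewest violations
and lowest energy".

Sampling correctness is tested directly: a single free torsion whose
only energy is a known STAP table, sampled at the reference temperature,
reproduces the table's Boltzmann distribution (χ² goodness of fit
against numerically integrated bin probabilities). The sampling protocol
for that check (large proposal σ, thinning by 4 after burn-in) is
standard MCMC practice to decorrelate the chain, fixed a priori.

## Restraint handling

The XPLOR/CNS dialect is parsed from `assign (sel) (sel) d dminus
dplus` statements with `!` comments, `or` continuation clauses, and
multi-member selections inside parentheses; wildcards (`#`, `*`, `%`)
are terminal-only and stored verbatim, expanding against the model only
at evaluation time. Dihedral tables use the four-selection `assign`
syntax with the force constant, target and half-width. Sequence
separation classifies each NOE as intraresidual (0), sequential (1),
medium (2–4) or long range (≥5), the universal convention; an ambiguous
restraint takes the *minimum* pair separation (a restraint is as local
as its closest interpretation; the maximum rule is available as an
option). Duplicates — identical selection sets, order- and
swap-insensitive — merge to the tightest bounds by default, with
conflicts (empty merged interval) surfaced as errors rather than
silently resolved; `first` and `error` policies are available. The
CHARMM-style writer emits one ASSIGN per restraint with KMIN/RMIN/
KMAX/RMAX/FMAX fields (RMIN/RMAX are the bounds), and the writers and
parsers round-trip all numeric fields at 3-decimal precision.

## Validation statistics

* **NOE violations** are upper-bound excesses,
  \(\max(0, r_\mathrm{eff} - \mathrm{upper})\); short-side excursions are
  excluded from this statistic by definition. Statistics (max, RMS over
  all restraints with satisfied ones contributing zero, and exceedance
  counts at the 0.0/0.5/1.0/2.0 Å cutoffs) are reported per category and
  pooled. For ensembles the per-restraint violation is averaged over
  models before aggregation (per-model pooling is available); RMS over
  violated-only restraints is likewise an option.
* **Dihedral violations**: \(\max(0, |\Delta\theta| - \delta)\) with
  wrapped differences; max and RMS as above.
* **Clash score**: nonbonded atom pairs (including hydrogens, bond-graph
  separation > 3) closer than the summed contact radii minus 0.4 Å, per
  1000 atoms.
* **Ramachandran**: percentage of non-terminal residues whose (φ, ψ)
  falls in an allowed bin; the allowed-region map is obtained by
  thresholding a φ–ψ STAP table (default threshold 4 in −ln P units,
  configurable).
* **Secondary structure** is a torsion-window heuristic, not DSSP:
  helix when (φ, ψ) ∈ [−100, −30] × [−80, −5] for ≥3 consecutive
  residues, sheet when φ ∈ [−180, −90] and ψ ∈ [90, 180] ∪ [−180, −170]
  for ≥2, coil otherwise, with percentages over assignable residues.
* **Binding-residue agreement**: residues with any heavy atom strictly
  within 4.5 Å of any ligand heavy atom, compared to a reference set via
  the Matthews correlation coefficient
  \(\mathrm{MCC} = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}\),
  defined as 0 when a marginal sum vanishes.

## The synthetic fixture

Because no deposited data ship with the package, a generator module
creates complete, self-consistent refinement problems. `make_truth()`
builds an ideal-geometry peptide at motif torsions (helix −57/−47,
strand −120/130, or a helix-turn-strand hairpin whose four turn
torsions are frozen constants chosen so the strand genuinely packs
against the helix). `derive_restraints()` samples proton–proton pairs
with true distance < 5.5 Å — the physical NOE observability window —
and bond-graph separation > 3, stratified to requested per-category
counts; targets are true distances plus Gaussian noise (σ 0.1 Å) with
±0.5 Å bounds, plus flat-bottom φ/ψ restraints (noise σ 5°, δ 20°,
k 0.02 deg⁻²) on half the interior residues. A construction check
requires the truth to satisfy at least 95% of the emitted restraints.
`perturb_model()` adds wrapped Gaussian torsion noise (σ 25° for the
packaged start) to create the degraded starting structure.

The packaged fixture is a 24-residue helix-turn-strand peptide with 200
NOEs (60 intraresidual / 60 sequential / 40 medium / 40 long, seed
1337). Its scale was chosen so a full-schedule refinement takes seconds
on one core while still exhibiting the interesting failure mode (a
compact alternative fold that satisfies most restraints). What passing
tests on this fixture show is that the machinery — parsing, energies,
annealing, statistics — is correct and that annealing recovers structure
from 25° torsion noise when the restraints derive from a consistent
ground truth. What they do *not* show is performance on real NMR data,
where restraints are sparser, noisier, sometimes mutually inconsistent,
and where fixed internal geometry and the toy STAP tables are genuine
approximations.

```{r demo, eval = FALSE}
fix <- packaged_fixture()
res <- refine_model(fix$start, fix$restraints,
                    tables = default_stap_tables(), seed = 1)
violation_stats(res$best_model, fix$restraints)
```

## Numerical and design notes

* Dihedral signs follow the standard convention shared by the major
  structure toolkits (verified against three independent
  implementations); `dihedral_angle((0,0,0),(1,0,0),(1,1,0),(1,1,1))`
  is +90°.
* Angles wrap to \([-180, 180)\); angle *differences* wrap to
  \((-180, 180]\) so the flat-bottom penalty is symmetric.
* The entry filter reads "more than 10 models" and "over 20 residues"
  strictly (>, not ≥); the inclusive variant is a flag.
* Disulfides: greedy nearest-first pairing of CYS SG atoms within
  2.5 Å (2.05 Å is the canonical S–S bond; the margin tolerates
  coordinate noise); each CYS joins at most one bridge.
* Degenerate inputs: empty restraint files parse to empty sets; an
  all-zero STAP histogram yields a uniform zero table; models with a
  single heavy atom have zero burial; `temperature_at` rejects steps
  outside the schedule.
* The MC problem sizes used in the test suite (short schedules for
  determinism checks, the full 15,200-step schedule for recovery runs)
  were chosen to exercise each property at the smallest scale at which
  it is meaningful.

## Limitations

Fixed internal geometry (no bond/angle relaxation, no methyl rotation),
a contact-burial surrogate instead of generalized Born, toy default STAP
tables, single-chain torsion rebuilding, no explicit hydrogen-bond or
electrostatic terms, and a derivative-free sampler that — like any
annealer — can land in an alternative compact fold when the restraint
set admits one (observed in roughly 5–10% of seeds on the packaged
fixture). Proline rings are built at fixed ring torsions and PRO φ is
sampled like any other backbone torsion; ring closure is approximate.
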