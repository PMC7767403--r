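---
title: "Methods: rigidity, hydrogen bonds and the LIE thermodynamic cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigidity, hydrogen bonds and the LIE thermodynamic cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindshift)
```

bindshift quantifies the effect of a single regulatory base-pair
substitution (A:T → G:C) on transcription-factor–DNA binding from the
post-processing side of an MD study: it does not run dynamics, it analyses
structures, trajectories and interaction-energy series. This vignette
documents the models, the parameters that matter, the numerical choices,
and what the synthetic generator does and does not emulate. Units are
Angstrom, kcal/mol, picoseconds and degrees throughout; frame indices are
0-based internally and 1-based in reports.

## The LIE estimator and the four-system cycle

The core quantity is the relative binding free energy between the
substituted (GC) and wild-type (AT) systems. Per variant, the linear
interaction energy ansatz estimates

$$\Delta G_{bind} = \alpha\,(\langle E_{vdW}\rangle_{bound} -
\langle E_{vdW}\rangle_{unbound}) + \beta\,(\langle E_{el}\rangle_{bound}
- \langle E_{el}\rangle_{unbound}),$$

where the averages are ligand–surrounding interaction energies sampled in
the protein-bound complex and in the free DNA. The empirical weights
default to $\alpha = 0.18$, $\beta = 0.43$, the preoptimized values for
this class of systems; entropy is implicit in that parametrisation, so no
explicit entropy term appears. Absolute LIE values are known to be
unreliable; the package therefore treats the *relative* quantity as the
result:

$$\Delta\Delta G_{bind} = \Delta G_{bind}^{GC} - \Delta G_{bind}^{AT},$$

the closed four-system thermodynamic cycle {AT, GC} × {Complex, DNA}.
`cycle_closure()` verifies the defining identity (binding legs minus
alchemical legs vanish) to round-off; the suite asserts it below 1e-10
kcal/mol on random cycles, along with exact antisymmetry under a variant
swap and linearity in $\alpha, \beta$.

The "ligand" whose interaction energies enter the cycle is the
substitution-site base pair. The free-energy expression is equally valid
for a whole-DNA ligand selection; the `ligand_label` metadata of each
energy table records which selection produced the series, and the
estimator is agnostic to it — the base-pair reading is the default
convention because the relative cycle is anchored on the substituted pair.

### Uncertainties

MD interaction-energy samples are strongly autocorrelated, so naive
standard errors of the mean are optimistic. `mean_interaction_energies()`
uses block averaging: the series is cut into `block_count` contiguous
blocks (default 10; trailing remainder dropped), and the sd of the block
means over $\sqrt{block\_count}$ estimates the SE. The tests compare this
against an independent moving-block bootstrap oracle on AR(1) series and
require agreement within a factor of two. Per-run cycle SEs propagate as
the root sum of squares of the four $\alpha$/$\beta$-scaled cell SEs.

Replicates are pooled by `pool_runs()` as the unweighted mean of per-run
$\Delta\Delta G$ values — the runs are equal-length replicates, so no
weighting basis exists — with the pooled SE taken as the sample standard
deviation (n−1 denominator) of the per-run values over $\sqrt{n_{runs}}$.
With equal-length runs, the mean of per-run estimates coincides with the
estimate from pooled means, so the distinction is moot here.
`confint.lie_result()` uses a t quantile on $n_{runs}-1$ degrees of
freedom.

## RMSD and rigidity

`superpose()` implements the SVD-based Kabsch solution of the optimal
rigid superposition, with the determinant correction that excludes
reflections; the suite checks it against a brute-force rotation-grid
search (coarse global axis–angle grid refined below a 0.1° step) on
random point sets, to 1e-3 Å. `rmsd_series()` measures per-frame RMSD
over a selection, superposing first when `fit = TRUE`.

Two conventions are deliberate choices, surfaced as arguments because any
particular MD study may have used others:

* **Selection**: heavy atoms of the whole system, unweighted. Hydrogens
  ride their parents and carry no independent information.
* **Reference**: the first frame of each run (`reference = NULL`), making
  each run's series self-contained; a crystal/ideal structure can be
  passed explicitly.

`rmsd_histogram()` pools all frames of all runs into fixed-width bins
starting at 0 (default 0.1 Å, right-open), so histograms of different
systems share a layout. `rigidity_summary()` compares pooled mean and sd:
the mutant group is "more rigid" only when *both* are lower; if the sds
tie to within 1e-12 the verdict falls back to the means alone (this makes
the verdict total — without the tie rule, exactly symmetric inputs would
be undecidable); anything else is "inconclusive". No significance test is
attached: the comparison mirrors a visual histogram reading, and
inventing one would overstate what the measure supports.

## Hydrogen bonds and water bridges

Detection is strictly geometric: a bond exists when the donor–acceptor
heavy-atom distance is **below** `d_max` (3.0 Å) and the angle at the
donor between D→H and D→A is **below** `theta_max` (20°). Both
inequalities are strict — boundary values excluded — and both cutoffs are
configuration (`hbond_criteria()`). The angle convention measures
deviation from a linear D–H⋯A arrangement at the donor, the only reading
under which "smaller than 20°" selects near-linear bonds.

Chemistry the geometry cannot supply comes from a fixed, versioned
dictionary (`assign_donors_acceptors()`): Watson–Crick faces and ring
edges of DA/DT/DG/DC, nucleotide backbone oxygens, protein backbone
N–H/C=O, the H-bonding side chains of the 20 amino acids, and water.
Hydrogens attach to their nearest heavy atom, which must lie within
1.2 Å (a violation is a topology error); donors additionally must not be
covalently bonded to the acceptor (heavy–heavy distance > 1.8 Å).

Bond *keys* are (donor heavy atom, acceptor), ignoring which hydrogen
satisfied the criteria, so a rotating water or amino group does not
fragment one physical bond into several. `hbond_statistics()` reports per
key the occupancy (fraction of frames present), the number of events
(maximal runs of consecutive presence) and the mean event duration (run
length × frame spacing), plus the per-frame count trace used to compare
systems.

A water bridge (`detect_water_bridges()`) is a water whose oxygen lies
within 10 Å of the substitution-site centroid — recomputed per frame,
since "around the site" is positional, not lab-frame — and that
simultaneously H-bonds, in either direction, to at least one protein and
one DNA atom. One bridge per water per frame.

## The synthetic generator

The generator produces *controlled* inputs whose correct analysis results
are known by construction. It emulates:

* **Idealized B-DNA** (`build_duplex()`): rise 3.38 Å, twist 36°/step,
  planar base pairs. Single-base heavy-atom templates are expressed in
  the standard base-pair reference frame; at assembly the complementary
  base is flipped 180° about the pair axis and rigidly snapped so every
  Watson–Crick donor–acceptor distance is 2.90 Å, and polar hydrogens are
  placed on the donor→acceptor line. The snap-plus-placement step is why
  the G:C = 3 / A:T = 2 bond counts hold *exactly* under the strict
  criteria, rather than depending on a fixed coordinate set happening to
  clear a hard 3.0 Å cutoff; template coordinates only need to be
  approximately right. Residues carry base atoms, the C1′ anchor and
  polar hydrogens — no backbone phosphates, which the analysis does not
  require.
* **Substitution** (`mutate_pair()`): the pair template of the new pair
  placed in the same local helical frame; all other atoms bit-identical.
* **Toy complexes** (`build_toy_complex()`, `place_bridging_water()`): a
  two-residue SER–ASN peptide whose serine hydroxyl donates to the site
  purine's N7 (guaranteeing a direct protein–DNA bond for either
  variant), and one water solved geometrically to bridge the purine N7
  and the serine carbonyl within the default criteria.
* **Trajectories** (`simulate_trajectory()`): frames are base coordinates
  plus i.i.d. isotropic Gaussian displacements per heavy atom per frame;
  hydrogens ride their heavy atom. This reproduces the *amplitude*
  statistics rigidity comparisons need (E[RMSD²] = 3σ² against the base,
  which the tests verify in closed form) while having none of the
  kinetics, anisotropy or collective modes of real MD.
* **Energy series** (`simulate_energy_series()`): independent stationary
  AR(1) processes per channel, $x_t = \mu + \phi(x_{t-1} - \mu) +
  \varepsilon_t$ with marginal sd $\sigma$, matching the autocorrelation
  structure that motivates block averaging.

### Presets — the study conditions

`synthetic_preset("paper_default", seed)` fixes the canonical conditions:
sequence GCATG with the A:T pair at position 3 substituted to G:C; 16
replicate runs per system; 100 frames per trajectory at 50 ps spacing
(5 ns per run); energy series of 10,000 samples at 0.02 ps (every 10
steps of a 2 fs integrator). Cell means sit at −100/−200 (Complex) and
−90/−180 (DNA) kcal/mol for vdW/el — arbitrary absolute levels, stated
here for transparency, since only the cycle's differences are
meaningful — with the GC-Complex cell shifted by exactly −0.10/0.18 kcal/mol
(vdW) and −0.70/0.43 kcal/mol (el), so the generating
$\Delta\Delta G_{bind}$ is −0.800 kcal/mol with components −0.700
(electrostatic) and −0.100 (van der Waals): the electrostatically
dominated, mutant-favouring regime the analysis is built to resolve.
Fluctuation sd is 1.5 (vdW) and 3.0 (el) kcal/mol with $\phi = 0.9$ —
realistic interaction-energy noise at strong autocorrelation — giving a
pooled SE near 0.03 kcal/mol, so the −0.8 signal stands at roughly 25
standard errors while per-run estimates still scatter visibly.
Trajectory noise is σ = 0.5 Å (wild-type) vs 0.35 Å (mutant, 0.7×),
encoding the "substituted systems are more rigid" ordering.

The series length is 10,000 samples rather than the 250,000 a full
5 ns/10-step production run would yield: estimator correctness does not
depend on the factor of 25, and the smaller size keeps every stage a
desk-scale computation.

`synthetic_preset("null", seed)` is the exactly symmetric control: all
four energy cells share means *and* derived seeds across variants, and
the "substitution" is the identity swap A:T → A:T, so both variants are
structurally identical. Every comparison is then null *by construction* —
pooled $\Delta\Delta G$ identically 0, hydrogen-bond difference 0,
rigidity verdict "inconclusive" — not merely null in expectation. (A null
with independent noise would still produce coin-flip verdicts; an exact
control is the stronger calibration.) All replicate streams derive from
the master seed through a deterministic mixing function, so a preset is
reproducible from one integer and runs never share a stream.

### What passing on synthetic data does not show

The generator has no force field, solvent, electrostatics or kinetics:
trajectory noise is uncorrelated in time and across atoms, energies are
Gaussian AR(1), and the toy peptide is two residues. Green tests
demonstrate that the *analysis machinery* — geometry, statistics,
thermodynamic bookkeeping — is correct on inputs with known answers. They
say nothing about whether a particular real system's ΔΔG is −0.8
kcal/mol; that number is a property of the simulations being analysed.

## Degenerate inputs and error surfaces

Readers fail loudly with located errors: unparseable PDB fields name the
line, trajectory models with the wrong atom count name the model, energy
tables lacking variant/environment metadata or containing non-numeric
cells name the defect. `superpose()` rejects fewer than 3 points;
selections resolving below 3 atoms are selection errors; an incomplete
cycle names the missing (variant, environment) cell; pooling a single run
is an error (the single-run result is already the answer). Structures
without water yield an empty bridge set with a warning, and structures
without hydrogens yield zero donors with a warning — neither aborts a
multi-run analysis.

## Problem sizes

The default conditions were chosen so the full suite (unit, property and
end-to-end checks) runs in well under a minute of compute: 64 trajectories
of 100 frames over ~130-atom systems, 128 energy series of 10,000
samples, 100 superposition-oracle instances. These sizes are the
package's canonical desk-scale profile, not a ceiling; all of them scale
through the preset definition.
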