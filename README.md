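# bindshift

Post-simulation analysis of how a single regulatory base-pair substitution
(a wild-type A:T pair replaced by a G:C pair in a transcription-factor
binding site) changes the factor's binding to DNA. The package takes the
outputs an explicit-solvent MD study of such a system produces — structures,
replicate trajectories, and per-sample ligand–surrounding interaction
energies — and answers three questions:

1. **Rigidity** — does the substituted system fluctuate less? Per-frame
   RMSD after optimal (Kabsch) superposition, pooled histograms over
   replicate runs, and a mean/sd-based rigidity verdict.
2. **Contacts** — does the substituted complex form more hydrogen bonds?
   Strictly geometric detection (donor–acceptor distance < 3.0 Å,
   hydrogen–donor–acceptor angle < 20°), water-mediated protein–DNA
   bridges within 10 Å of the substitution site, and occupancy / lifetime
   statistics per bond.
3. **Thermodynamics** — by how much does the binding free energy shift?
   Linear interaction energy (LIE) estimates per system,

   ΔG_bind = α (⟨E_vdW⟩_bound − ⟨E_vdW⟩_unbound) + β (⟨E_el⟩_bound − ⟨E_el⟩_unbound),

   with α = 0.18 and β = 0.43, combined through the four-system
   thermodynamic cycle {AT, GC} × {Complex, DNA} into

   ΔΔG_bind = ΔG_bind^GC − ΔG_bind^AT,

   decomposed into its electrostatic and van der Waals components, with
   block-averaged standard errors per run and replicate pooling over the
   16 production runs of the canonical design. A negative ΔΔG_bind means
   the factor binds the substituted DNA more strongly.

Because real MD inputs are large and system-specific, the package ships a
first-class synthetic-data generator: an idealized B-DNA duplex builder
with explicit polar hydrogens (every G:C pair satisfies 3 and every A:T
pair 2 hydrogen bonds by construction), base-pair substitution, toy
protein–DNA complexes with a bridging water, noise trajectories with
controllable rigidity, and AR(1) interaction-energy series whose
generating ΔΔG_bind is known exactly. Every stage of the pipeline runs at
desk scale with no downloads.

## Worked example

```r
library(bindshift)

# idealized duplex: 5 bp, wild-type A:T pair at position 3
duplex <- build_duplex("GCATG")
nrow(detect_hbonds(duplex))
#> [1] 13                      # 3+3+2+2+3 Watson-Crick bonds

mutant <- mutate_pair(duplex, position = 3, new_pair = "GC")
nrow(detect_hbonds(mutant))
#> [1] 14                      # the substituted pair gains one bond

# canonical synthetic study: 16 runs x 10,000 AR(1) samples per system
data <- synthetic_preset("paper_default", seed = 42)
fit <- lie_ddg(data$energies)
fit
#> Relative LIE binding free energy (GC - AT)
#>   ddG_bind = -0.802 +/- 0.027 kcal/mol (16 pooled runs)
#>   components: electrostatic -0.703, van der Waals -0.099
#>   dG_bind: AT -10.405, GC -11.206 (alpha=0.18, beta=0.43)
confint(fit)
#>          2.5 %     97.5 %
#> ddg -0.8598924 -0.7431117

wt  <- lapply(data$trajectories$complex_AT, rmsd_series)
mut <- lapply(data$trajectories$complex_GC, rmsd_series)
rigidity_summary(wt, mut)
#> <rigidity_summary>
#>   wild-type: mean 1.2002 A, sd 0.1276 A (1600 frames)
#>   mutant:    mean 0.8369 A, sd 0.0893 A (1600 frames)
#>   mean difference (mut - wt): -0.3634 A -> mut_more_rigid
```

The pooled ΔΔG_bind of about −0.8 kcal/mol recovers the preset's
generating value (−0.800 exactly on noiseless means), its sign and
electrostatic dominance carrying the scientific reading: the substituted
pair binds the factor more strongly, mostly through electrostatics, and
its systems are more rigid.

`run_pipeline(snp_config("paper_default", seed = 42))` executes all three
stages and returns a combined report; `write_report()` emits the
per-stage CSV tables and a machine-readable JSON summary.
`write_dataset()` / `read_dataset()` move the whole four-system dataset
through plain-text formats (multi-model PDB trajectories, CSV energy
tables with `# key=value` headers).

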