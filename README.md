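# dnapucker

Computational machinery for refining the deoxyribose sugar-pucker torsion
potential in AMBER-style DNA force fields, and for the conformational
analysis used to validate such refinements.

The balance between B-DNA (south sugar pucker, C2'-endo, high-*anti*
glycosidic angle) and A-DNA (north pucker, C3'-endo, *anti* glycosidic
angle, inclined base pairs displaced from the helical axis) matters
wherever DNA bends toward the A-form: protein–DNA complexes, DNA/RNA
hybrids, and duplexes in dehydrating solvents. Refitting the sugar
torsion terms against solvation-corrected quantum-chemical conformer
scans is how force fields are corrected for understabilized north
pucker; this package provides everything around the QM and MD engines,
for force-field developers and simulators who analyze the results:

- **Pseudorotation algebra** (Altona–Sundaralingam): phase/amplitude
  from ring torsions and back, N/S classification, constrained-scan
  construction over the pucker cycle
  (`pseudorotation`, `ring_torsions_from_phase`, `scan_constraints`).
- **Torsion model and refit**: AMBER Fourier dihedral energies, frcmod
  parameter I/O with multi-term (negative-periodicity) dihedrals,
  composite CBS/CCSD(T) reference-energy assembly, and the
  solvation-aware weighted linear least-squares amplitude refit with
  diagnostics (`dihedral_energy`, `read_frcmod`, `write_frcmod`,
  `composite_reference_energy`, `fit_target`, `fit_fourier`,
  `empirical_adjustment`).
- **Conformer statistics**: per-residue and aggregate %N, pseudorotation
  PMFs, `PMF = -RT ln(n_bin/n_max)`, on 3° bins with block-averaged
  ±1.96×SEM confidence intervals, BI/BII and α/γ backbone substate
  populations (`percent_N`, `pmf`, `classify_bi_bii`,
  `substate_populations`).
- **Helical geometry**: standard-frame base fitting, CEHS mid-frame
  intra-pair/step parameters, local helical parameters (x-displacement,
  inclination, tip, hrise, htwist — the standard A/B monitors), and
  El Hassan–Calladine groove widths (`base_frame`, `step_parameters`,
  `helical_parameters`, `groove_widths`, `duplex_report`).
- **Restraint bookkeeping**: flat-well distance and glycosidic-angle
  penalties with C¹ walls (`flat_well_energy`, `chi_well_energy`).
- **Synthetic fixtures with planted truth**: two-state N/S pucker time
  series, Fourier-planted torsion scans, and idealized A-/B-form fiber
  duplexes whose re-analysis round-trips the planted parameters
  (`simulate_pucker_series`, `synth_scan`, `build_fiber_duplex`).

PDB reading/writing goes through `bio3d`; a thin command-line front end
(`inst/cli/dnapucker`) exposes the main workflows as subcommands
(`pucker`, `fit`, `energy`, `pmf`, `classify`, `populations`, `helix`,
`restraint-energy`, `simulate`, `build`).

## Worked example

Build an idealized A-form duplex, re-derive its helical description, and
check a planted torsion refit:

```r
library(dnapucker)

## pseudorotation round trip at the north minimum
nu <- ring_torsions_from_phase(18, 38)
round(nu, 3)
#> [1]   0.000 -22.336  36.140 -36.140  22.336
pseudorotation(nu)
#> pucker: P = 18.000 deg, tau_m = 38.000 deg, class = N

## A-form fixture analyzed with the CEHS algebra
rep_a <- duplex_report(build_fiber_duplex(fiber_spec("A")))
subset(rep_a$summary, parameter %in%
       c("inclination", "x_displacement", "htwist", "hrise", "P", "chi"))
#>       parameter  value
#>             chi 202.00
#>               P  18.00
#>  x_displacement  -5.30
#>           hrise   2.81
#>     inclination  20.70
#>          htwist  32.70

## noiseless planted-amplitude refit recovers the plant exactly
types <- list(tau1 = torsion_type(c("CT","CT","CT","OS"),
              list(fourier_term(1, 1.2, 0), fourier_term(2, -0.4, 180),
                   fourier_term(3, 0.8, 0))))
skel <- lapply(types, function(tt) {
  tt$terms <- lapply(tt$terms, function(tm)
    fourier_term(tm$periodicity, 0, tm$phase)); tt })
fit_fourier(synth_scan(types, offset = 2.2),
            fit_spec(skel, instances = list(tau1 = "tau1")))
#> Fourier torsion fit: 1 type(s), RMSE 0.0000 kcal/mol, cond 1.53e+05
#>   tau1:n1_g0 tau1:n2_g180   tau1:n3_g0       offset
#>          1.2         -0.4          0.8          2.2

## %N recovery from the two-state generator
s <- simulate_pucker_series(two_state_spec(p_N = 0.15, switch_time = 1/0.85,
                                           n_frames = 2e5, seed = 1))
percent_N(s)$aggregate
#> [1] 14.92
```

The A-form summary shows the package's two standard A/B monitors at
their reference values — inclination 20.7° and x-displacement −5.3 Å
(B-form: 1.5° and 0.0 Å) — recovered from built coordinates, which
cross-validates the fiber builder and the parameter algebra. The fit
output prints the recovered half barriers (V<sub>n</sub>/2, kcal/mol)
and the fitted constant offset; the large condition number is intrinsic
to fitting low periodicities on a ring torsion that spans only
±τ<sub>m</sub> (see the methods vignette).

## Vignette

`vignettes/methods.Rmd` documents the models and conventions: the
pseudorotation formulas, the dual-solvation fitting target and CBS
assembly, the CEHS construction and its inverse, window conventions,
confidence-interval methodology, what the synthetic generators do and
do not emulate, and known limitations.
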