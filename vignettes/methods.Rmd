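---
title: "Sugar pucker refitting and DNA conformational analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sugar pucker refitting and DNA conformational analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnapucker)
```

## The scientific problem

The equilibrium between B-DNA (south sugar pucker, high-*anti*
glycosidic angle, narrow minor groove) and A-DNA (north pucker, *anti*
glycosidic angle, inclined base pairs displaced from the helical axis)
governs protein--DNA recognition, DNA/RNA hybrid geometry and the
behaviour of DNA in dehydrating solvents. Classical AMBER-type force
fields systematically understabilize the north (N) deoxyribose pucker,
and refinements of the sugar torsion potential address this by refitting
the dihedral Fourier terms against solvation-corrected quantum-chemical
conformer scans and then validating the result against conformational
statistics of simulated duplexes.

`dnapucker` implements the computational machinery of that workflow --
not the MD or electronic-structure engines, but everything around them:

1. pseudorotation algebra and constrained pucker-scan construction;
2. AMBER frcmod dihedral I/O, composite reference-energy assembly, and
   the solvation-aware linear least-squares Fourier refit;
3. trajectory conformer statistics (%N, pseudorotation PMFs with
   confidence intervals, BI/BII and alpha/gamma substate populations);
4. base-pair, step and helical parameter algebra (CEHS mid-frame
   construction) with El Hassan--Calladine groove widths;
5. flat-well restraint bookkeeping;
6. synthetic fixtures with planted ground truth: two-state pucker time
   series, Fourier-planted scans, and idealized A-/B-form fiber duplexes.

## Pseudorotation

The five endocyclic furanose torsions are parameterized as
$\nu_j = \tau_m \cos(P + (j-2)\,144^\circ)$, so $\nu_2 = \tau_m\cos P$.
The inverse uses
$\tan P = [(\nu_4+\nu_1)-(\nu_3+\nu_0)] / [2\nu_2(\sin 36^\circ + \sin 72^\circ)]$
evaluated with `atan2`, and the amplitude as the pole-free modulus
$\tau_m = \sqrt{\nu_2^2 + s^2}$ with $s$ the sine-projection; on any
torsion set generated by the forward map this equals $\nu_2/\cos P$ but
it stays finite at $P = 90^\circ, 270^\circ$. A sugar is classified N
when the wrapped phase lies in the open interval $(-90^\circ, 90^\circ)$,
S otherwise; the boundary itself is S by the strict inequality.

Constrained scans place 36 targets on a 10-degree grid over the full
cycle. Two dihedrals are constrained per point: the ring scan torsion
(by default $\nu_1$, directly from the inverse map -- the identity of
this dihedral is configuration, since different parametrizations pick
different ring torsions) and the backbone angle $\delta$, which is not a
ring torsion but tracks $\nu_3$ up to an approximately constant
exocyclic offset. The default offset, 123.2 degrees, was calibrated once
as the measured $\delta - \nu_3$ of the package's own B-form fiber
fixture and is exposed as a parameter.

## Reference energies and the torsion refit

The fitting target for each scan conformer is the solvation-aware residual
$r_i = (E^{QM,gas}_i + G^{QM}_{solv,i}) - (E^{MM,nontors}_i + G^{MM}_{solv,i})$:
solvation enters both sides, so subtracting the full MM non-torsion
energy avoids double counting. The QM side can be assembled with
`composite_reference_energy()`: HF and correlation energies are
extrapolated separately from (T, Q) basis levels with the two-point
inverse-power formula (the correlation exponent is the standard
$X^{-3}$; the HF exponent defaults to the same power law for
consistency, is configurable, and the chosen scheme is recorded in the
result attributes), a CCSD(T)$-$MP2 double-zeta correction is added, and
the conformer solvation energy last. Energies are kcal/mol throughout;
a hartree converter (627.509474 kcal/mol) is provided.

With phases restricted to 0/180 degrees the AMBER dihedral energy is
linear in the half barriers $V_n/2$, so `fit_fourier()` is a weighted
linear least squares with an always-fitted constant offset;
contributions are summed over all instances of a fitted type per
conformer, the design rank is checked before solving (collinear columns
are named in the error), and per-coefficient standard errors and the
design condition number are returned. Periodicities default to
$n \in \{1,2,3\}$ per torsion and are configurable; per-conformer
weights are equal by default with optional Boltzmann down-weighting of
high-energy points.

One numerical caveat is intrinsic to the problem: a ring torsion only
spans $\pm\tau_m \approx \pm 35^\circ$ along the pucker cycle, so
low-periodicity cosines are nearly collinear over that range and
individual amplitudes are poorly determined from a noisy 36-point scan
(the reported standard errors and condition number make this visible).
The fitted energy *profile* is well determined; tests therefore assert
exact recovery for noiseless scans, unbiasedness across seeds for noisy
ones, and honesty of the reported standard errors, rather than small
per-seed amplitude errors.

`empirical_adjustment()` reproduces the post-hoc step in which the north
minimum is stabilized to match solution populations: it finds the
minimum-norm amplitude change that shifts the energy at the centre of a
target phase window by a requested amount while pinning the current
south minimum, and fails loudly (rather than silently distorting the
potential) when the available periodicities cannot represent the
request. The magnitude of the shift is a user decision, not a default.

## Conformer statistics

`percent_N()` reports per-residue and aggregate percentages of N-classified
frames, with a configurable number of terminal residues excluded per
chain end (terminal pairs fray and are conventionally dropped).
`pmf()` implements the histogram estimator
$\mathrm{PMF} = -RT\,\ln(n_{bin}/n_{max})$ on 3-degree bins at 298.15 K
($R = 1.987204\times10^{-3}$ kcal/(mol K)); empty bins are reported as
missing, never clamped. Count confidence intervals are
$\pm 1.96\times$SEM with the SEM estimated by block averaging (10 equal
time blocks by default) because simulation frames are autocorrelated;
whether a published SEM is over blocks, replicas or residues is rarely
stated, and block averaging is the choice that degrades gracefully with
correlation. The interval is propagated through the logarithm, giving
asymmetric PMF bounds.

Backbone substates use the tripartite rotamer windows
g+ = [0, 120), t = [120, 240), g- = [240, 360): BI is
$\epsilon/\zeta$ = t/g-, BII is g-/t, the canonical
$\alpha/\gamma$ combination is g-/g+ and the noncanonical flip g+/t.
The windows are a package convention -- the substates are named in the
literature without printed windows -- and are the same windows the
synthetic generator emits into, so classification recovery is exact by
construction.

## Helical parameter algebra

Base reference frames are obtained by least-squares (Kabsch)
superposition of embedded standard-geometry bases (Olson-convention
reference frames) onto the observed ring atoms. Intra-pair and step
parameters follow the CEHS mid-frame construction used by 3DNA-family
tools: merge the two z-axes by rotating each half of the bending angle
about the mutual hinge, read twist about the merged axis, decompose the
bend into tilt/roll by the hinge phase, and express the origin
displacement in the mid-frame; the strand-2 frame is flipped (y and z
negated) before pairing. `build_step()` is the exact inverse, which
gives the rebuild oracle used throughout the tests.

Local helical parameters derive from the same step transform: the
helical axis is the rotation axis carrying frame 1 into frame 2, htwist
the rotation about it, hrise the origin displacement along it, and
inclination/tip/x-displacement locate each pair relative to the axis in
the pair's own helically aligned frame, averaged over the two pairs of
the step. The per-pair form is used deliberately: on an ideal regular
helix it returns the generating parameters exactly, whereas reading the
axis offset in the mid-step frame biases the x-displacement by
$\cos(\Omega_h/2)$ (about 4% at A-form twist).

Groove widths follow the El Hassan--Calladine phosphate-distance
prescription: at each level (indexed 5' to 3' on strand 1) the
minor-groove width is the shortest cross-strand P--P distance over
reversed-strand offsets $-2..-4$, the major-groove width over offsets
$0..3$, each minus 5.8 angstrom for the phosphate radii. Levels whose
offset window runs off a strand end are dropped by default
(`interior_only`), since an ambiguity in how groove averages treat
near-terminal levels is best resolved by a flag.

## Restraints

`flat_well_energy()` implements the flat-bottomed wells used to suppress
terminal-pair fraying (flat between 2.5 and 3.2 angstrom, 20 and 30
kcal/(mol A^2) walls) and `chi_well_energy()` the angular well keeping
nucleoside glycosidic angles in the *anti* region (zero on
[160, 310] degrees, 10 kcal/rad^2 outside). Both are continuous and
once-differentiable at the walls. The angular well wraps at 360 degrees
and penalizes through the shorter path to the nearest wall -- the
published form does not address wrapping, and the shorter-path rule is
the only choice that keeps the penalty continuous on the excluded arc.

## Synthetic fixtures and what passing tests mean

The generator module produces every input the test suite needs, always
with a planted-ground-truth sidecar:

* **Two-state pucker series** -- hidden N/S Markov chains with stationary
  $p_N$, mean N dwell `switch_time`, Gaussian phase emission
  (defaults $p_N = 0.15$, means 18/150 degrees, $\sigma_P = 12$), plus
  categorical BI/BII and alpha/gamma emissions. Setting
  `switch_time = 1/(1-p_N)` makes the chain memoryless, which is the
  regime where binomial standard errors are the exact yardstick for %N
  recovery; dwell kinetics are validated separately at
  `switch_time = 50` against the planted mean.
* **Fourier-planted scans** -- conformer records whose fit target equals
  the planted torsion profile exactly at zero noise.
* **Fiber duplexes** -- base-pair frames propagated along a straight
  axis from planted helical parameters (B: htwist 36, hrise 3.38,
  inclination 1.5, x-displacement 0; A: 32.7, 2.81, 20.7, $-5.3$), with
  standard Watson--Crick bases and a deoxyribose/phosphate backbone grown
  from the planted pucker ($P$ = 150/18, $\tau_m$ = 36/38), glycosidic
  angle (250/202 degrees) and $\gamma$/$\beta$ torsions. The ring is
  solved by Newton refinement of pentagon out-of-plane displacements so
  the measured $(P, \tau_m)$ match the plant to $10^{-8}$; exocyclic
  branches are fixed to the unique choice giving 5'-3' backbone
  connectivity and natural sugar chirality. Re-analysis of the built
  coordinates recovers the planted helical description to $10^{-6}$,
  validating builder and algebra against each other.

The fixtures emulate geometry and stationary statistics, not physics:
there is no explicit solvent, no sequence-dependent fine structure, no
correlated backbone/pucker coupling, and dwell kinetics are memoryless.
Passing tests therefore demonstrate that the estimators and the
parameter algebra are correct on data whose truth is known -- they say
nothing about force-field quality on real trajectories, which requires
the MD sampling that is explicitly out of scope here.

## Numerical choices

* Angles: internal canonical ranges are $[0, 360)$ for backbone
  dihedrals and $[-180, 180)$ for raw torsions, with explicit wrap
  utilities and no implicit re-wrapping; exact trans is reported as
  $-180$.
* Degenerate geometry (collinear atom triples, planar rings, fewer than
  three ring atoms) raises errors rather than returning NaN.
* Twist-free steps have no defined axis point; x-displacement is
  reported as `NA` there.
* Circular means are used for all angular averages in reports.
* Problem sizes in the shipped tests (for example $5\times10^5$ frames
  for %N recovery, 200 seeds for noisy-fit unbiasedness, $10^5$-sample
  PMFs over 10 or 100 seeds) were chosen so that each statistical
  assertion has a false-failure probability well under 1% at the
  planted effect sizes while the whole suite completes in well under a
  minute; coverage-style properties use 100 seeds with an 85% bound
  because 10-seed coverage checks of a 95% interval are underpowered.

## Known limitations

* The frcmod reader interprets only the DIHE block; other blocks are
  verbatim pass-through (sufficient for dihedral refitting, not a
  general parameter editor).
* Base-pairing for PDB input must be supplied explicitly; no
  hydrogen-bond inference is attempted.
* The fiber builder produces idealized geometry: backbone linkage
  distances across residues are approximate (the O3'--P virtual bond is
  near, not exactly at, bond length), so cross-residue angles
  ($\alpha, \epsilon, \zeta$) of fixtures are emergent rather than
  planted.
* Trajectory ingestion is limited to PDB snapshots and delimited angle
  tables; binary trajectory formats are out of scope by design.
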