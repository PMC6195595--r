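---
title: "Models and methods for docking-domain interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for docking-domain interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpsdock)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where several were
defensible, and what its synthetic-data tests do and do not demonstrate
about real data. The running example throughout is the Kj12ABC
rhabdopeptide NRPS of *Xenorhabdus stockiae*, whose docking-domain (DD)
fixtures are bundled.

## The binding model underneath everything

Both detection channels — NMR chemical shifts and calorimetric heats — sit
on the same exact 1:1 equilibrium. For total macromolecule $P$, total
ligand $L$ and dissociation constant $K_d$, the fraction of macromolecule
bound is the physical root of the depletion quadratic,

$$ f \;=\; \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2P}, $$

evaluated in the subtraction-free form $f = 2L\big/\big(b + \sqrt{b^2 -
4PL}\big)$ with $b = P+L+K_d$, which is stable when $K_d \ll P$. No
approximation (e.g. free ligand $\approx$ total ligand) is used anywhere:
at the 50–100 µM working concentrations of these domains, depletion is
severe.

## CSP titrations

In the fast-exchange regime each amide resonance sits at the
population-weighted average of its free and bound positions, so a titration
traces a straight line in the ($^1$H, $^{15}$N) plane. The combined shift
perturbation is

$$ \Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / 6.5)^2 } $$

with the conventional nitrogen scaling of 6.5 (the $^{15}$N shift range is
roughly 6–7 times wider than $^1$H; 6.5 is the value used for these
domains and is a fixed constant here, not a tunable).

**Binding-site mapping.** The classical recipe — iteratively trim shifts
above `mean + k·SD`, recompute, threshold — is unstable for small `k`: on
continuous noise every pass removes the top tail of what remains and the
cutoff walks down toward the minimum (with `k = 1` it ends up calling
essentially every residue). We therefore use the robust closed form of the
same idea: the background location and scale are the median and the scaled
MAD of the profile, which the shifted contact class (a minority of
residues) cannot drag, and residues are called above `median + 4·mad`.
The factor 4 puts the operating point on the high-specificity side for a
~70-residue domain; it is an argument (`n_mad`), not a constant.
Residues whose peaks vanish during the titration are always reported, as
`"broadened"` — intermediate-exchange intensity loss is evidence of
contact, not missing data, which mirrors how the loop-2 amides of these
NDDs behave on complex formation.

**Kd from trajectories.** `fit_kd_from_csp()` shares one $K_d$ across all
shifting residues; the per-residue saturation amplitudes enter linearly in
$f$ and are profiled out in closed form, leaving a 1-D minimisation over
$\log K_d$ (golden-section, interval $10^{-9}$–$10^{-2}$ M). Residues are
weighted by their endpoint CSP so that flat trajectories do not dilute the
objective. Two diagnostics are emitted as warnings: predicted saturation
below 80% at the largest ratio (the isotherm then barely bends and $K_d$
is poorly constrained), and $K_d < 0.02\,P$ (stoichiometric regime — only
an upper bound on $K_d$ is identifiable). The confidence interval comes
from the curvature of the profiled sum of squares at the optimum; it is
honest at moderate noise but, like all curvature intervals, optimistic
when the fit is nearly degenerate.

## ITC: forward model, fitting, and the c-value gate

The forward model mimics a perfusion (overflow) cell of constant active
volume $V_0$: each injection of volume $v$ displaces an equal volume of
current cell contents, so totals dilute by $1 - v/V_0$ per injection while
the syringe adds $L_{syr}\,v/V_0$. After re-solving the equilibrium (site
concentration $n\,M$), the measured heat of injection $i$ uses the
mean-concentration correction for material displaced mid-injection:

$$ q_i = \Delta H \, V_0 \Big[ (C_i - C_{i-1}) +
   \tfrac{v_i}{V_0}\,\tfrac{C_i + C_{i-1}}{2} \Big] + q_{base}. $$

The sum of heats therefore equals $\Delta H$ times the *cumulative* moles
of complex formed, including complex that left the cell — the quantity the
forward model also reports — rather than the final in-cell amount, which
is smaller by the displaced fraction (roughly 15% over a full 38 µl
titration into 200 µl). Unit discipline: molar concentrations internally,
enthalpies in cal·mol⁻¹, heats in µcal; conversions happen only at I/O.

Baseline handling has the two modes used in practice: subtracting the mean
of the final `m = 3` injections when the titration saturates to a plateau,
and injection-wise subtraction of a matched titrant-into-buffer run when it
does not (the plateau mode warns, via a last-`m` slope test at 1% of the
amplitude per injection, when it is being applied to an unsaturated
curve — the situation of the weaker Kj12B-NDD titrations).

The fitter is trust-region Levenberg–Marquardt (minpack.lm) over
($n$, $\log_{10} K_d$, $\Delta H$, baseline), restarted from $K_d$ =
100, 10 and 1 µM to escape local minima; $n$ floats within (0.5, 2) by
default — instrument-software convention — or can be fixed at 1. The
priming injection (0.2 µl) is excluded from the objective, as its heat is
corrupted by diffusion across the syringe tip during equilibration.
Standard errors come from the Gauss–Newton $J^\top J$ at the optimum, with
the $K_d$ error delta-mapped from the log scale.

The verdict is gated **only** by the Wiseman parameter $c = n[M]_T/K_d$:
`reliable` for $c > 1$, else `weak_qualitative`. Below $c = 1$ the
isotherm is a featureless slope and the likelihood in $K_d$ is flat, so a
small residual proves nothing; the package enforces this by construction
(the gate never sees the residuals) and the test suite checks it with a
zero-noise weak titration. A thermogram whose heats carry no signal at all
(zero enthalpy) is flagged unidentifiable rather than fitted.

## hetNOE rigidity

The steady-state $\{^1H\}$-$^{15}$N NOE ratio $I = I_{sat}/I_{ref}$
classifies backbone rigidity: residues above 0.5 are treated as ordered
(the threshold used when selecting residues for torsion-angle restraints),
with 0.6 as the stricter validation-grade cut. Both thresholds are plain
arguments. The linked-construct template in the tests — rigid NDD core,
flexible GS linker and CDD helix, rigid five-residue CDD tail — encodes
the observed dynamics of the fused NDD–CDD complex, where only the β3
residues of the CDD share the core's high NOE values.

## The recognition rules

The structural picture is economical: only the last five residues of the
CDD (the β3 register, positions −5…−1 with −1 the C-terminus) contact the
NDD, adding an antiparallel strand to β2 and leaning into helix α2. Five
contacts carry the code:

| contact | NDD side | register | default weights |
|---|---|---|---|
| electrostatic | position 24 | −2 | salt bridge +2, clash −2, H-bond +1, neutral 0 |
| electrostatic | position 28 | −4 | same |
| steric | position 27 (Tyr) | −3 | Gly +1, Ala −1, larger −2 |
| hydrophobic pocket (α2) | — | −1 | Ile/Leu/Val/Met/Phe +1, else −1 |
| hydrophobic pocket (β2/loop2) | — | −5 | same |

Charges are assigned at the experimental pH 6.5: Asp/Glu negative,
Lys/Arg positive, His neutral-but-H-bond-capable by default with a
`his_charged` switch — the weak Kj12A-CDD interactions hinge on a His at
register −2, and whether it is counted as charged changes that contact
from H-bond (+1) to clash (−2). Polarity-reversed bridges score as full
salt bridges, as observed in other megasynthase families where the
acid/base sides are swapped. Position 26 is mutated in published
reprogramming designs but has no assigned contact in the structure, so it
carries weight 0 by default and participates only through user-edited
rules. The weights are uncalibrated priors chosen to reproduce the
qualitative affinity ordering of the Kj12 system; they live in an editable
table (`default_rules()`), and the class cutpoints are *fitted* to a Kd
ladder (`calibrate_classes()`) rather than hard-coded.

**What the additive rules cannot do.** Because the score is a sum of
per-contact terms and the electrostatic term sees only formal charge, any
two basic residues (Lys vs Arg) are interchangeable. A consequence worth
stating openly: with the bundled fixtures, the censored
Kj12B-NDD/Kj12A-CDD pair scores a K28–E(−4) salt bridge and lands *above*
the measured weak pair Kj12C-NDD/Kj12A-CDD, which no assignment of the −4
chemistry can avoid while simultaneously keeping the (measured) ordering
Kj12B/Kj12B over Kj12C/Kj12A — the two requirements pull the −4 residue in
opposite directions. The rank correlation over the nine-row ladder is 0.83
(Spearman, censored rows tied at the bottom) with that single systematic
inversion; the inversion report of `rank_consistency()` names it. Fixing
it would require a non-additive term (e.g. context-dependent His/Glu
geometry), which we deliberately do not invent.

**Kj12A numbering.** The published record for the Kj12A-CDD is internally
inconsistent: the synthesised 25-mer peptide ends …LLFGHI (Phe at register
−4), while the described interface chemistry and the named mutation sites
(E1169, H1171) imply a glutamate at −4. The package bundles both — the
peptide as printed, and a separate β3-register fixture `LEGHI` numbered
1168–1172 so the documented mutations resolve — and applies ladder
mutations in lenient mode (reference mismatches warn instead of failing).
Tests assert the chemistry of the register fixture, never the −4 letter of
the peptide. Similarly, NDD key positions that are only visible in
structure-figure alignments (Kj12A 24/26/27, Kj12B 27) are conservative
stand-ins flagged as such in the fixture notes.

**Design and scanning.** `suggest_reprogramming()` exploits additivity:
per-position contribution lookups replace exhaustive re-scoring, and sets
of up to three substitutions are enumerated with the constraints that every
member individually moves the score in the requested direction and that
smaller sets win ties. The validated designs fall out: E1169R + H1171E
tops the Kj12A-CDD strengthening list (tied with the chemically equivalent
Asp/Lys variants), K28E leads the Kj12B-NDD rescue, and the Q26K + E28A
pair scores as weakening. `scan_for_cdd_termini()` treats every C-terminal
5-mer of a sequence set as a candidate register — a rule-based surrogate
for homology surveys that found this interaction mode across bacterial
megasynthases.

## Structure verification

Superposition is the standard Kabsch solution (SVD of the centred
covariance, determinant-corrected to a proper rotation); the test suite
cross-checks it against both a brute-force rotation-grid oracle and an
independent library implementation. Ensemble precision is the mean pairwise
backbone RMSD over a stated ordered-residue set, the convention for NMR
bundles (the deposited NDD ensembles report 0.1–0.2 Å for ordered
residues; the corresponding check runs only when the user supplies the
coordinate files, as they are not bundled). Salt bridges are side-chain
N–O pairs across chains within 4.0 Å — a common convention; the His
protonation switch is shared with the rules module. β-register inference
collects inter-chain backbone N···O contacts within 3.5 Å, requires the
N–O=C angle to exceed 90° when the carbonyl carbon is present, and flags
the ladder as antiparallel when the paired residue numbers run in opposite
directions (Spearman trend < 0). For NMR ensembles, contacts are reported
per model with a ≥50% consensus rule, since individual conformers vary.

## The synthetic-data generators

Every generator is a pure function of `(seed, parameters)`: the RNG state
is saved, seeded, and restored, so outputs are bit-reproducible and the
caller's random stream is untouched; the full ground truth travels with
the data (and can be written as a `key=value` sidecar). Defaults encode
the study conditions: 100 µM protein titrated at ratios 0.25/1/2.5/5 for
CSP; the 50 µM/1 mM, 0.2 µl + 19 × 2 µl protocol for ITC; Kd = 8 µM for
the reference tight pair. Noise defaults — σ_H = 0.005 ppm, σ_N =
0.03 ppm, σ_heat = 0.2 µcal — are plausible instrument scales chosen by
the package (the source study does not state them). The default CSP
contact patch (residues 22–28 and 39–43 of a 70-residue domain) stands in
for strand β2 plus the α2 face, with bound-state shifts of 0.08–0.25 ppm
(¹H) — the 10–30× signal-to-noise regime that real histograms of these
titrations show.

What passing the round-trip tests shows: the analysis inverts its own
forward models correctly (exactly at zero noise, within stated tolerances
under noise), and the detection rules hit their designed operating points.
What it does not show: robustness to baseline drift, peak-picking errors,
assignment mistakes, non-1:1 stoichiometry, or slow-exchange lineshapes —
none of which the generators emulate, all of which occur in real spectra
and thermograms. One statistical fact the tests surface deliberately: at a
contact signal only 5× the background CSP level, *perfect* set recovery is
intrinsically a chance event — the maximum of ~58 background values
overlaps the weakest contact at any threshold — so the exactness
demonstration is run at a fixed seed while across-seed robustness is
asserted in the realistic amplitude regime.

## Problem sizes and runtime

The test suite simulates 30-replicate ITC recovery studies, 12-replicate
CSP fits and single-profile analyses on 70-residue domains — sizes chosen
so the full suite runs in about a minute on one core while still giving
median-error statistics stable enough to test against 15% bounds.
`scripts/acceptance.R` re-runs the same analyses from scratch at the
caller's seed and writes the headline numbers as JSON.

## Known limitations

* The rules engine is additive and charge-symmetric; see the inversion
  discussed above. Calibrated cutpoints cannot separate pairs with equal
  scores (the weak Kj12C/Kj12A pair ties a censored pair at score 2).
* Kd from CSP assumes one global site and fast exchange throughout; the
  fast-to-intermediate behaviour of the real complexes biases endpoint
  shifts of broadened residues, which the fitter excludes rather than
  models.
* The ITC model is single-site and equilibrium; no competitive,
  multi-site, or kinetic variants.
* `percent_identity()` uses a fixed simple scoring (match +1, mismatch 0,
  gap −1, configurable); it is meant for the >70% identity regime of the
  NDD family, not for remote homology.
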