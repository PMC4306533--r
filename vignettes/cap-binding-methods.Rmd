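---
title: "Methods: cap-analogue binding affinity, thermodynamics and family-discriminating residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cap-analogue binding affinity, thermodynamics and family-discriminating residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capaffinity)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what its validation does and
does not demonstrate.

## The binding model

One titration follows a protein P (eIF4E-family cap-binding protein, at
nominal total concentration 0.1–0.2 µM) through increasing total ligand
L₀ (a cap analogue). Binding is modelled as a single site at
equilibrium,

$$K_\mathrm{as} = \frac{[PL]}{[P][L]}, \qquad
[P] = P_0^\mathrm{act} - [PL], \quad [L] = L_0 - [PL],$$

whose solution is the ligand-depletion (quadratic) isotherm

$$[PL] = \tfrac{1}{2}\left(b - \sqrt{b^2 - 4P_0^\mathrm{act}L_0}\right),
\qquad b = P_0^\mathrm{act} + L_0 + 1/K_\mathrm{as}.$$

Depletion matters here: the dissociation constants of the tight cap
analogues (m⁷GTP, m⁷Gp₄, m⁷Gp₅) are in the low-nanomolar range, far
below the protein concentration, so the free-ligand approximation
`[L] ≈ L₀` would be badly wrong. `complex_concentration()` evaluates the
root in the algebraically equivalent form
$2P_0L_0/(b+\sqrt{b^2-4P_0L_0})$, which avoids the catastrophic
cancellation of the textbook form when $K_\mathrm{as}$ is large; the
test suite checks it against a bisection oracle over a $10^4$-point grid
to $10^{-10}\cdot P_0$.

The observable is intrinsic tryptophan fluorescence:

$$F(L_0) = f_0 \;-\; \Delta f\,[PL] \;+\; f_L\,(L_0 - [PL]).$$

* `f0` — baseline emission at zero ligand (arbitrary units). It absorbs
  the emission of *both* active and inactive apo-protein: the inactive
  fraction contributes a constant that no titration can separate from
  the active apo signal, so it is deliberately a single fitted baseline.
* `delta_f` — quench amplitude per µM of complex
  ($f_{P^\mathrm{act}} - f_{PL}$), non-negative for a quenching system.
* `f_lig` — emission efficiency of free cap analogue per µM. At
  millimolar ligand this term dominates and the curve *rises* linearly;
  modelling it is what lets the fit use the high-concentration arm
  instead of discarding it.

Raw intensities are corrected before fitting
(`correct_intensities()`): dilution by the cumulative-volume ratio
`volume/reference_volume`, and the inner filter effect by the standard
half-path absorbance factor $10^{(A_\mathrm{ex}+A_\mathrm{em})/2}$. The
source experiments state both corrections were applied without printing
the formulas; these are the field-standard forms. Dilution is handled by
rescaling fluorescence while keeping the nominal protein concentration
fixed, rather than re-computing concentrations per point; the simulator
can carry per-point volumes so this choice is testable.

## Fitting and pooling

`fit_titration()` estimates
$\{K_\mathrm{as}, P_0^\mathrm{act}, f_0, \Delta f, f_L\}$ by bounded
Levenberg–Marquardt least squares (via `minpack.lm::nls.lm`). Choices
that were open:

* **Bounds encode physics**: $K_\mathrm{as} > 0$,
  $0 < P_0^\mathrm{act} \le 2\times$ nominal protein, $\Delta f \ge 0$,
  $f_L \ge 0$.
* **$P_0^\mathrm{act}$ is fitted, not fixed.** The active fraction of a
  refolded protein preparation is unknown, and for tight binders the
  curvature near the equivalence point determines it. For very weak
  binders only the product $\Delta f \cdot P_0^\mathrm{act}$ is
  identifiable; the optimizer then wanders a flat ridge, which surfaces
  honestly as `converged = FALSE` plus an enormous `p0_act` standard
  error rather than being hidden by fixing the parameter.
* **Multi-start in $K_\mathrm{as}$** over {0.1, 1, 10, 100} µM⁻¹ (other
  starts are data-driven: `f0` from the first point, `f_lig` from the
  terminal slope, `delta_f` from the observed quench amplitude). Tight
  binders put the optimum in a shallow valley; starting from several
  decades and keeping the best residual sum of squares avoids the local
  traps. A stalled best run is polished by one restart from its own
  optimum.
* **Standard errors** come from the residual-variance-scaled inverse
  curvature $\,(J^\top J)^{-1}\hat\sigma^2$ at the optimum, read as the
  per-fit "numerical standard deviation". When $J^\top J$ is singular
  (the weak-binder ridge) the Moore–Penrose pseudoinverse is used, which
  reports curvature within the identifiable subspace.
* **Degenerate input** (a perfectly flat curve) raises an error naming
  `delta_f` as unidentifiable instead of returning an arbitrary fit;
  fewer than six points is an error because five parameters are fitted.

Replicates are pooled by inverse-variance weighting
(`weighted_average()`): $\hat K = \sum(K_i/\sigma_i^2)/\sum(1/\sigma_i^2)$
with pooled SE $(\sum 1/\sigma_i^2)^{-1/2}$. Exact ties in the weights
need no tie-breaking; a zero standard error is rejected explicitly. One
property of this estimator worth knowing: because the weights are
estimated from the same fits as the values, and an underestimated
$K_\mathrm{as}$ tends to come with an underestimated SE, the pooled
constant is biased a few percent low at 1% noise. The pipeline-closure
test sizes its Monte-Carlo bundle (100 replicates per cell) so that
sampling noise sits below this systematic component, and the
affinity-*ratio* between two proteins cancels most of it.

## Thermodynamic layer

`delta_g()` converts a pooled constant to
$\Delta G^\circ = -RT\ln K_\mathrm{as}$ with $K_\mathrm{as}$ rescaled
from µM⁻¹ to M⁻¹ (1 M standard state), $R = 1.9872041\times10^{-3}$
kcal mol⁻¹ K⁻¹ and $T = 293.15$ K by default (the 20 °C assay
temperature); both are arguments. Ligand transitions use
$\Delta\Delta G^\circ = -RT\ln(K_B/K_A)$ — the µM⁻¹ scale cancels — with
first-order propagation of independent relative errors. Transition
energies are antisymmetric, path-additive and invariant to common
rescaling of all constants (property-tested), and a *negative* value is
an energy gain, i.e. the target ligand binds tighter.

`build_ddg_table()` emits one row per protein × buffer × transition and
keeps unmeasurable cells as explicit `NA` gaps, because a dropped row
and a gap mean different things in a published table. Energies and
ratios are only formed within a buffer: the bundled table keeps the
10%-glycerol measurements (used to stabilize the truncated *Xenopus*
eIF4E1b) under a separate `buffer_tag`, since glycerol itself lowers cap
affinities up to ~2-fold.

Reproduction from the bundled association-constant table is limited by
the table's own rounding: recomputed transition energies agree with the
published ones to within 0.015 kcal/mol in 57 of 58 cells; the one
exception (*Xenopus* eIF4E1a, GTP→et⁷GTP, deviation 0.017 kcal/mol)
divides by a constant printed as 0.031 ± 0.006, where the last rounded
digit alone moves the energy by more than the band. The propagated ±
column similarly matches only approximately (e.g. 0.046 computed vs
0.045 printed for the human m⁷GTP→et⁷GTP cell); exactness from rounded
inputs is impossible, so the uncertainty check is documentation-level.

## Cap-analogue chemistry

`parse_analogue_name()` accepts the label grammar covering the ligand
panel: N7 prefix (`m7`/`et7`/`bn7`, `m227` for the trimethylated
snRNA-type cap), phosphate codes `MP`/`DP`/`TP`/`p4`/`p5`, dinucleotide
tails `ppp`+`G`/`A`, and 2′-O-methyl tokens (`m7G2OpppG`,
`m7Gpppm2OG`). Validation enforces chemistry: N2 dimethylation only with
N7-methyl, ribose methylation only on dinucleotides.

`net_charge()` uses Henderson–Hasselbalch fractional deprotonation per
ionizable group, independently (no site–site coupling):
$q(\mathrm{pH}) = q_\mathrm{base} + \sum_g \delta_g/(1+10^{pK_{a,g}-\mathrm{pH}})$.
The shipped catalogue lists, per analogue, the reference charge with all
modelled groups protonated plus two groups — the N1 proton of the
(7-alkyl)guanine ring and the secondary dissociation of the terminal
phosphate. Their pK_a values are *illustrative* literature-range
numbers, shipped as editable YAML configuration: the measured constants
behind published charge estimates live in primary references, so net
charges computed from the defaults are qualitative (ordering and trend),
not reproductions of any published coordinate.

## The synthetic-data generator

`simulate_titration()` is the stand-in for unpublished raw fluorescence
data. It emulates:

* the assay layout — a zero-ligand baseline plus 24 log-spaced
  additions, nominal protein 0.1 µM (0.2 µM variant available);
* homoscedastic Gaussian noise scaled to `f0` (default 1%), since
  photon-count detail of the instrument is unavailable;
* linear-in-index apo-signal drift (`drift_total_frac`, 0.10/0.25
  emulating unstable preparations losing 10–25% of signal over a run).
  Real drift is a time process; point timing is unpublished, so linear
  in point index is a documented simplification.

One design value needed interpretation. The assay description quotes cap
concentrations "from 2 µM to 5 mM", which can only be the titrant stock
series: with 0.1 µM protein and dissociation constants down to ~2 nM,
every in-cuvette point at ≥2 µM is past saturation and the association
constant would be structurally unidentifiable from such a schedule
(the information sits in the sub-µM transition and the near-equivalence
curvature). Small additions of the 2 µM stock deliver tens of nM in the
cuvette, so the generator's default in-cuvette schedule is 0 plus 24
log-spaced points over 0.02–5000 µM.

What the generator does **not** emulate: instrument-level effects (lamp
flicker, bandwidth, Raman scatter), heteroscedastic photon noise,
pipetting error in the ligand schedule, slow binding kinetics, or
protein aggregation beyond the smooth drift term. Passing the
simulation-based tests therefore shows the *estimator and pipeline* are
correct and well-calibrated under the stated noise model — not that any
particular real dataset meets that model.

The drift term supports a directional regression test: fitting the
drift-free model to 25%-drift curves biases the recovered association
constant downward, dose-dependently — the quantitative reason unstable
apo-protein preparations must be stabilized (N-terminal truncation, 10%
glycerol) before titration, and why an unstabilized fragile paralog can
masquerade as a far weaker cap binder.

## Comparative-sequence stage

`find_discriminating_positions()` operationalizes "conserved within each
family, different between families": a column qualifies when each
family's modal residue reaches the conservation threshold and the two
modal residues differ. Open choices, and how they were fixed:

* **Threshold default 1.0** (strict within-family identity), with 0.875
  (7 of 8 sequences) as the documented alternative for
  eight-pairs-style panels; the published criterion is unstated, so the
  strictest reading is the default. Raising the threshold can only
  remove positions (tested monotonicity).
* **Gap policy**: under the default `"strict"` policy any in-family gap
  disqualifies a column; `"exclude"` drops gapped rows first. Strict is
  the default because a gap is evidence against "conserved residue".
* **Numbering** is reported 1-based in the ungapped coordinates of a
  declared reference sequence (`ref_position`), the convention used for
  residue labels like Trp56 or Glu103; columns where the reference is
  gapped report `NA`. `map_numbering()` plus the bundled offset table
  convert between conventions (e.g. the *Xenopus* eIF4E1a frame runs 4
  behind the human one).
* The scan is verified against an independently written brute-force
  column enumeration on randomized alignments with planted signals.

`nterm_charge()` counts K/R as +1 and D/E as −1 over a leading window
(default 27 residues, the unstructured N-terminal region); histidine is
0 by default and +1 optionally, since its protonation at cytoplasmic pH
is marginal.

## Problem sizes used in validation

The test suite and the acceptance script run, by the package's choice:
the isotherm-vs-bisection grid at $10^4$ points; noiseless recovery at
three association constants (0.3, 7.8, 68.4 µM⁻¹) to $10^{-6}$ relative;
Monte-Carlo calibration with 200 simulated curves per constant at 1%
noise (median bias and 2-SE coverage); pipeline closure with 100
replicates per cell on the 68.4/22.0 µM⁻¹ contrast; and the
discrimination scan versus brute force on random 12–16-sequence,
150–220-column alignments with 10–15 planted columns.

## Known limitations

* Single-site binding only: no cooperativity, no multi-site or competing
  equilibria, no kinetics, no anisotropy observable.
* The inactive-protein fraction is absorbed into `f0`; only
  $P_0^\mathrm{act}$ is estimated, and for weak binders only up to the
  $\Delta f \cdot P_0^\mathrm{act}$ product.
* Inverse-variance pooling with estimated weights is a few percent
  biased at realistic noise (see above); with 2–6 replicates, as in a
  real panel, replicate sampling noise dominates cell-level estimates.
* The Henderson–Hasselbalch charge model ignores site coupling and
  tautomers, and the default pK_a catalogue is illustrative.
* The discrimination scan treats columns independently; it does not
  model phylogenetic structure, so a family-correlated substitution in a
  small panel can mimic a diagnostic position.
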