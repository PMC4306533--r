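# capaffinity

Quantitative analysis of mRNA 5′ cap analogue binding to eIF4E-family
translation initiation factors, from raw fluorescence titrations to
thermodynamic tables and comparative-sequence summaries.

## The problem

Canonical eIF4E1a and its oocyte-enriched paralog eIF4E1b both carry the
class-I cap-binding fold, yet differ markedly in how well — and how —
they bind the m⁷G(5′)ppp(5′)N cap and its synthetic analogues (m⁷GTP,
et⁷GTP, bn⁷GDP, m⁷Gp₄, m⁷GpppG, …). The standard way to quantify this is
intrinsic-fluorescence quenching titration: protein at ~0.1 μM is
titrated with cap analogue, tryptophan fluorescence is quenched as the
complex forms, and at high ligand the emission of free cap dominates the
signal. Because the dissociation constants (down to a few nM) are far
below the protein concentration, the hyperbolic binding curve is wrong;
the ligand-depletion (quadratic) isotherm is required.

`capaffinity` implements that full analysis path:

* **Forward model.** The complex concentration solves mass action
  K<sub>as</sub> = [PL]/([P][L]) with depletion,

      [PL] = (b − √(b² − 4·P₀·L₀)) / 2,   b = P₀ + L₀ + 1/Kas,

  (computed in a cancellation-free form), and the observable is
  F(L₀) = f₀ − Δf·[PL] + f_L·(L₀ − [PL]), with raw intensities first
  corrected for dilution and the inner filter effect
  (`10^((A_ex+A_em)/2)`).
* **Estimation.** `fit_titration()` estimates
  {K<sub>as</sub>, [P₀ᵃᶜᵗ], f₀, Δf, f_L} by bounded Levenberg–Marquardt
  least squares with multi-start initialization;
  `weighted_average()` / `aggregate_affinity()` pool replicates with
  inverse-variance weights.
* **Thermodynamics.** ΔG° = −RT ln K<sub>as</sub> (1 M standard state),
  ligand-transition tables ΔΔG° = −RT ln(K_B/K_A) with first-order error
  propagation (`build_ddg_table()`), paralog affinity ratios
  (`affinity_ratio()`), all at T = 293.15 K by default.
* **Cap chemistry.** Analogue-name parsing (`parse_analogue_name()`) and
  Henderson–Hasselbalch net charge at a given pH (`net_charge()`), with
  an editable pK_a catalogue.
* **Sequence comparison.** `find_discriminating_positions()` scans a
  family-labelled alignment for residues conserved within each paralog
  family but differing between them; `nterm_charge()` summarizes the
  basic/acidic N-terminal contrast; `map_numbering()` converts residue
  numbering conventions.
* **Synthetic data.** `simulate_titration()` /
  `simulate_replicate_study()` generate titrations with known ground
  truth, including the 10–25% apo-signal drift of unstable protein
  preparations, so every stage is testable without instrument data.

## Worked example

```r
library(capaffinity)

# simulate one m7GTP-like titration and refit it
truth <- binding_parameters(kas = 22, p0_act = 0.1, f0 = 1000,
                            delta_f = 5000, f_lig = 1.5)
curve <- simulate_titration(truth, simulation_design(noise_sd_frac = 0.01,
                                                     seed = 1))
fit_titration(curve)
#> <fit_result> kas = 23.09 +/- 3.6 uM^-1 (p0_act 0.11 uM, 25 points, rss 2.06e+03)

# thermodynamics over the bundled association-constant table
kas <- published_kas_table()
h1a <- function(l) kas[kas$protein_id == "heIF4E1a" & kas$ligand == l &
                       kas$buffer_tag == "standard", ]
delta_delta_g(h1a("m7GTP"), h1a("et7GTP"))
#> <transition_energy> heIF4E1a: m7GTP -> et7GTP  ddG = 0.965 +/- 0.046 kcal/mol

h1b <- function(l) kas[kas$protein_id == "heIF4E1b" & kas$ligand == l &
                       kas$buffer_tag == "standard", ]
format_ratio(affinity_ratio(h1a("m7GTP"), h1b("m7GTP")))
#> [1] 3.11
```

The fitted association constant recovers the generating value within its
standard error; the ΔΔG° of the N7 methyl→ethyl swap (~1 kcal/mol
penalty for eIF4E1a) and the ~3-fold eIF4E1a/eIF4E1b affinity contrast
for m⁷GTP come straight from the bundled table.

The numbered scripts under `analysis/` run the full workflow
(simulate → fit/pool → thermodynamic tables → sequence scan) and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate_titrations.R
Rscript analysis/02_fit_affinities.R
Rscript analysis/03_thermodynamics.R
Rscript analysis/04_sequence_analysis.R
```

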