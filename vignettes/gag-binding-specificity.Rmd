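---
title: "Locating GAG-binding sites and classifying their specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating GAG-binding sites and classifying their specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbscan)
```

## The problem

Glycosaminoglycans (GAGs) — heparin, heparan sulfate and their relatives —
are highly sulfated, polyanionic polysaccharides that regulate hundreds of
proteins. Because the interaction is dominated by long-range Coulomb
attraction between sulfate/carboxylate groups and surface Arg/Lys residues,
GAG–protein binding is often dismissed as nonspecific. Yet some systems are
exquisitely specific: antithrombin recognises one unique heparin
pentasaccharide in one unique geometry, while thrombin's exosite II or serum
albumin will take almost any sulfated chain in almost any orientation.

gbscan implements a structure-only analysis of this distinction. The
operating hypothesis is that specificity is *not* encoded in the basic
residues themselves but in the placement of **neutral hydrogen-bond donors**
(Asn ND2, Gln NE2, and related hydroxyl/indole/imidazole donors) inside a
field of basic residues. A neutral donor ringed by Arg/Lys experiences an
unusually strong electropositive potential; it can hydrogen-bond to a
specific sulfate while paying a much smaller desolvation penalty than an
ion pair would. A protein whose neutral-donor potential distribution has one
(or a few) extreme outliers therefore presents a *specific* GAG-binding
site; a protein with a diffuse, roughly Gaussian distribution binds GAGs
nonspecifically.

## The potential at a locus

For a locus atom $\ell$ (a donor atom on the surface) the multi-body
electrostatic potential energy manifested by the rest of the structure is
the exact Coulomb sum

$$
G_{ES}(\ell) \;=\; p \sum_{j \notin \mathrm{res}(\ell)}
\frac{332.0636 \; q_j}{\varepsilon(r_{j\ell})\, r_{j\ell}}
\quad \text{kcal/mol},
$$

with $q_j$ the partial charge (e) of atom $j$, $r_{j\ell}$ the distance in
Å, and 332.0636 kcal·Å/(mol·e²) the Coulomb constant. The probe sign
$p = -1$ by default, so an electropositive (GAG-attractive) environment
yields a *negative* $G_{ES}$ — the most negative loci are the most
conducive to binding a polyanion. All atoms of the locus's own residue are
excluded (a `"self-atom-only"` exclusion mode exists for sensitivity
checks), and no cutoff radius is applied: the structures involved are small
enough that the exact $O(NL)$ sum costs nothing.

Evaluated over the neutral-donor catalog this quantity is the structure's
**G~GAG-binding~** profile, the package's central object.

### Choices that matter

* **Charge models.** Crystal structures lack hydrogens, so all models are
  heavy-atom residue templates with hydrogen charges folded into their
  bonded heavy atoms; each template sums to the residue's formal charge
  within 0.01 e. Three models ship: `formal` (unit charges on Arg/Lys
  terminal N and Asp/Glu carboxylate O only — transparent and exactly
  integer-valued), `charmm-like` (condensed from the CHARMM all-atom
  protein set) and `mmff94-like` (a more polar template set in the spirit
  of MMFF94 bond increments). Histidine is neutral by default — its pK~a~
  near 6.9 makes the protonation state ambiguous — with a `his_plus` flag
  for the imidazolium form.
* **Dielectric.** Uniform $\varepsilon = 4$ by default, the middle of the
  customary protein-interior sweep; $\varepsilon \in \{2, 3, 4, 10\}$ and a
  distance-dependent $\varepsilon(r) = \varepsilon r$ form are selectable.
  For any uniform dielectric, $G_{ES}(\varepsilon) = G_{ES}(1)/\varepsilon$
  exactly, so the *rank order* of loci — all that the downstream statistic
  consumes — is invariant across the sweep.
* **Donor catalogs.** The strict catalog is Asn ND2 / Gln NE2. The extended
  (default) catalog adds Ser OG, Thr OG1, Tyr OH, Trp NE1 and neutral His
  ND1/NE2 — a deliberate extension covering "other neutral hydrogen-bond
  donors"; both are available because the minimal reading is defensible.
  A donor only counts as neutral while its sidechain is actually uncharged
  under the assigned model (|charge| < 0.25 e), which also removes donors
  whose charge was swapped in silico.

## 2DSE plots

A 2D-Surface-Energy plot maps each locus from 3D onto the plane by
plotting $\rho = \sqrt{x^2 + y^2}$ against $z$, and scales each marker's
*area* by the Boltzmann-type affinity factor

$$
A(\ell) = \min\!\left( e^{(G_\mathrm{ref} - G_{ES}(\ell))/RT},\; \mathrm{cap} \right),
$$

so that for two uncapped loci $A_i / A_j = e^{(G_j - G_i)/RT}$ — the ratio
of dissociation constants their energy difference would imply. Defaults:
$RT = 0.593$ kcal/mol (298 K), reference = mean $G_{ES}$ over the plotted
loci (making area 1 the "average" locus; `least_negative` and explicit
values are alternatives), cap $e^5$ (purely presentational, so one hot
spot cannot dominate the canvas). The projection is taken in the deposited
coordinate frame by default (`origin = "raw"`); because deposited frames
are arbitrary, a `centroid` origin is offered. The plot is exactly
invariant under rotation about *z*, and a translation along *z* shifts the
ordinate only.

## Hot spots and the specificity call

Over the neutral-donor potential table the package computes $n$, mean, sd,
minimum, sample skewness and a Shapiro–Wilk normality p-value. A **hot
spot** is a locus with

$$
z(\ell) = \frac{G_{ES}(\ell) - \bar{G}}{s} \;\le\; -z_\mathrm{thr},
\qquad z_\mathrm{thr} = 2 \text{ by default},
$$

annotated with its basic constellation: every Arg/Lys whose terminal
sidechain nitrogen (NE/NH1/NH2, NZ) lies within 12 Å (minimum distance per
residue). The verdict is **specific** iff at least one hot spot exists.
The visual criterion this formalises — "a long negative tail" — has no
canonical numeric threshold; $z \le -2$ is a declared package decision,
configurable, with the normality p-value reported as supporting evidence
rather than used as a gate. Degenerate inputs are refused explicitly:
fewer than 3 loci is an insufficient-data error, zero variance a
no-variance error.

Note a small-sample fact that shaped the validation design: the sample
z-score of a single outlier among $n$ values is bounded by
$(n-1)/\sqrt{n}$ (≈ 3.18 for $n = 12$). Separations of a planted site are
therefore quoted against the *background* loci (excluding the plant),
while the hot-spot rule itself uses the full-sample z-score.

## Mutant energetics

Binding data enter through dissociation constants:
$\Delta\Delta G_\mathrm{OBS} = RT \ln (K_d^\mathrm{variant} /
K_d^\mathrm{reference})$ with $R = 1.9872 \times 10^{-3}$ kcal/(mol·K),
$T = 298$ K by default. The packaged antithrombin–pentasaccharide (9
records) and thrombin–heparin (7 records) tables carry literature $K_d$
values together with continuum-solver electrostatic and desolvation
components, which the package treats as *data*: `mutant_table_analysis()`
recomputes $\Delta\Delta G_\mathrm{OBS}$ from the $K_d$ column (honouring
each record's comparator; the double mutants' ES/DS components are
referenced to their single-mutant background, recorded in a separate
`es_ds_comparator` column) and fits three regressions on the printed
columns. Two results are robust: observed binding varies moderately
linearly with electrostatics (r² ≈ 0.68 for antithrombin), and
electrostatics is almost perfectly opposed by desolvation (r² > 0.999,
negative slope) — the quantitative reason a pure charge–charge picture of
GAG binding fails. One antithrombin record (N135A/K114A) carries a $K_d$
derived from an external calorimetric reference; it is flagged
`kd_external` and its printed value is not expected to reproduce from the
RT·ln ratio.

Regressions pass through a normality gate: OLS with a two-tailed F-test
when both series pass Shapiro–Wilk at $\alpha = 0.05$ (for a single
predictor the F-test equals the two-tailed slope test), Spearman rank
correlation otherwise (method flagged, $\rho^2$ reported; the OLS r² is
always included alongside).

### The desolvation surrogate

The published component energies came from a proprietary
Poisson–Boltzmann solver and are not reproduction targets. For *de novo*
decompositions the package provides `decompose_interaction()`:
$\Delta G_{ES}$ is the Coulomb cross-term at the inner dielectric
(default uniform 2), and $\Delta G_{DS}$ comes from a pluggable solver.
The shipped `born_surrogate` is a contract-level continuum model: each
atom's effective Born radius grows linearly with burial
($R = 1.5 + 0.08 b$ Å, $b$ = non-self heavy atoms within 6 Å, partner
included in the complex), and

$$
\Delta G_{DS} = \sum_i -166\, q_i^2
\left( \tfrac{1}{\varepsilon_\mathrm{out}} - \tfrac{1}{\varepsilon_\mathrm{in}} \right)
\left( \tfrac{1}{R_i^\mathrm{alone}} - \tfrac{1}{R_i^\mathrm{complex}} \right),
\qquad \varepsilon_\mathrm{in} = 2,\ \varepsilon_\mathrm{out} = 80 .
$$

The coefficients (1.5 Å base radius, 0.08 Å per neighbour, 6 Å counting
radius) are declared package-level constants. The surrogate guarantees the
properties the decomposition contract needs — zero in the separated limit,
non-negative when burial only increases, exact $q^2$ scaling, and
sign-opposition of $\Delta\Delta G_{ES}$ / $\Delta\Delta G_{DS}$ under
interface charge perturbations — and nothing more; its absolute magnitudes
are not comparable to grid Poisson–Boltzmann output.

## What the synthetic generator emulates

`make_structure(site_spec(...))` builds point-charge toy proteins with
real residue and atom names (ASN ND2, LYS NZ, ASP OD1/OD2) so the entire
pipeline — PDB round trip, charge templates, catalogs, potentials,
statistics — runs on them unmocked. The *specific* kind plants one Asn
donor whose ND2 is ringed by `n_basic` (default 4) Lys NZ charges at
`ring_radius` (default 5 Å, hydrogen-bond-to-salt-bridge range), with 11
further Asn donors and 20 scattered ±1 residues on a ~25 Å shell — the
ringed-donor geometry that creates real hot spots. A candidate is accepted
only when the *brute-force oracle* confirms the planted donor is the
minimum, at least 4 background sd below the rest. The *nonspecific* kind
spends the same atom budget with all charges scattered, rejection-sampled
(up to 1000 attempts) until no donor deviates more than 1.5 sd from the
mean. Positional noise (`noise_sd`, default 0.3 Å) is applied as a rigid
per-residue displacement: independent per-atom jitter at that amplitude
routinely collapses 1.2 Å bonded distances below the 0.8 Å overlap guard,
whereas rigid displacement mimics thermal disorder while preserving
internal geometry. Coordinates are rounded to PDB precision (3 decimals)
before acceptance, so generation is byte-identical per seed and survives
the file round trip exactly.

What passing on these fixtures does **not** show: real proteins have
folded backbones, partial burial, correlated charge placement, crystal
contacts and ambiguous protonation. The synthetic battery validates the
*machinery* (potentials, statistics, classification logic) and the
qualitative laws (rank stability across dielectrics, hot-spot destruction
on mutation), not predictive accuracy on the PDB.

## Numerical choices and degenerate inputs

* Coulomb constant 332.0636 kcal·Å/(mol·e²); R = 1.9872×10⁻³ kcal/(mol·K).
* Atom pairs closer than 10⁻⁶ Å raise a coincident-atom error rather than
  returning an overflowing term.
* Alternate-location tie-break: first-listed conformer, deterministically.
* Waters are always removed; HETATM and hydrogens removed unless kept.
* `charge_swap` places +1 e on the outermost retained sidechain atom
  (largest PDB remoteness letter, first listed on ties) — the hot-spot
  consequence depends on where the charge sits, not on rotamer geometry,
  so no rotamer is built.
* Shapiro–Wilk is reported as `NA` for zero-variance input and capped at
  n ≤ 5000 (the test's domain).
* Problem sizes in the shipped validation: 100 random 50-atom oracle
  fixtures, 100 seeded synthetic structures (50/50 specific/nonspecific),
  a 10-structure dielectric sweep and a 10-structure mutation battery —
  sizes chosen so the whole battery runs in about a minute on a laptop
  while leaving the statistical margins wide.

## Known limitations

* No Poisson–Boltzmann grid solving, ionic-strength screening, or
  polarizable charges; the uniform-dielectric Coulomb sum is the model.
* No protonation engine, pKa prediction or rotamer building; His handling
  is a flag, mutations are charge-level operations.
* Potentials are evaluated and reported per donor atom (an optional
  per-residue minimum aggregation exists downstream of the table); whether
  per-atom or per-residue aggregation better matches experimental
  footprints is an open question.
* The specificity verdict is a two-class call with a single threshold; no
  p-value is attached to the verdict itself.
* 2DSE projections are frame-dependent by construction; compare plots only
  within one frame convention.
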