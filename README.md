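# gbscan

Locating glycosaminoglycan (GAG)-binding sites on protein structures, and
telling the *specific* ones from the *nonspecific* ones, from structure
alone.

## The science

Heparin, heparan sulfate and other GAGs are polyanions that bind hundreds
of proteins through long-range Coulomb attraction to surface Arg/Lys
residues. That picture explains affinity but not specificity: why does
antithrombin recognise one unique pentasaccharide while thrombin's exosite
II binds almost any sulfated chain? gbscan implements the view that the
discriminating signal sits at **neutral hydrogen-bond donors** (Asn ND2,
Gln NE2, and related donors). For a donor locus ℓ the package evaluates
the exact multi-body Coulomb potential manifested by the rest of the
structure,

    G_ES(ℓ) = p · Σ_j 332.0636 · q_j / (ε(r_jℓ) · r_jℓ)   [kcal/mol]

(heavy-atom template charges q in e, distances r in Å, probe sign p = −1
so electropositive environments give negative, "GAG-attractive" values;
the locus's own residue is excluded). Over the neutral-donor catalog this
is the structure's G_GAG-binding profile. The workflow then

1. projects each locus onto a **2DSE plot** — √(x²+y²) against z, marker
   area scaled by exp((G_ref − G_ES)/RT), so uncapped marker areas relate
   like the Kd ratios the energy differences imply;
2. mines the distribution for **hot spots**, loci with
   z = (G_ES − mean)/sd ≤ −2, each annotated with the Arg/Lys
   constellation within 12 Å — at least one hot spot ⇒ verdict
   *specific*, none ⇒ *nonspecific*;
3. analyses mutant binding tables: ΔΔG_OBS = RT·ln(Kd ratio), plus
   normality-gated regressions showing observed binding varies moderately
   with electrostatics (r² ≈ 0.68) while electrostatics is almost exactly
   opposed by desolvation (r² > 0.99) — packaged antithrombin and
   thrombin mutant tables included;
4. generates deterministic synthetic structures with planted
   specific/nonspecific sites and a brute-force potential oracle, so every
   claim above is testable end to end.

See the vignette (`vignettes/gag-binding-specificity.Rmd`) for the model,
parameter choices and limitations.

## Worked example

```r
library(gbscan)

# a synthetic structure with one Asn donor ringed by four Lys (+1) at 5 A
s <- make_structure(site_spec("specific", seed = 1))
t <- all_locus_potentials(s, "neutral_donor", dielectric_model("uniform", 4))
classify_specificity(t, s, threshold_z = 2)
#> GAG-binding specificity call for 'synthetic_specific_seed1': SPECIFIC
#>   12 neutral-donor loci, mean -15.74, sd 17.48 kcal/mol, z threshold 2.0
#>   hot spot A:ASN 1:ND2: G_ES -63.33 kcal/mol (z = -2.72), 4 basic residues nearby
```

The planted donor is the one locus far down the negative tail (−63.3
kcal/mol against a −15.7 ± 17.5 background), and its reported
constellation is exactly the four ringing lysines — the geometry that
creates specific GAG sites.

```r
mutant_table_analysis(packaged_tables()$antithrombin)
#> mutant table analysis (9 records, T = 298 K)
#>   max |recomputed - printed ddG_OBS| = 0.13 kcal/mol
#>   ddG_ES vs ddG_OBS: pearson_ols: r^2 = 0.6828 (OLS r^2 = 0.6828), p = 0.00604, slope = 0.0554, intercept = -0.3388
#>   ddG_DS vs ddG_OBS: pearson_ols: r^2 = 0.6882 (OLS r^2 = 0.6882), p = 0.00567, slope = -0.0609, intercept = -0.3659
#>   ddG_ES vs ddG_DS:  pearson_ols: r^2 = 0.9997 (OLS r^2 = 0.9997), p = 7.37e-14, slope = -0.9130, intercept = -0.3040
```

The Kd-derived ΔΔG_OBS values reproduce the published table to 0.1
kcal/mol (the one 0.13 outlier is the flagged external-reference Kd), the
electrostatics–binding correlation is moderate, and the near-perfect
negative ES/DS slope quantifies how desolvation opposes every
electrostatic gain.

For real structures, run the same pipeline from the shell:

```sh
exec/gbscan scan --pdb my_protein.pdb --charge-model charmm-like \
    --epsilon 4 --catalog extended --out results/
exec/gbscan mutants --out results/
exec/gbscan simulate --kind specific --seed 7 --out fixtures/
```

`scan` writes `potentials.tsv`, `dse.tsv`, `dse.png`, `hotspots.tsv` and
`report.txt`; every parameter used is logged.

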