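# bifhyd

Sequence analysis of the flavin-binding **beta subunits**
(HydB/NuoF/Nqo1 homologs) shared by multimeric [FeFe]-hydrogenases,
formate dehydrogenases and respiratory Complex I, for researchers working
on anaerobic metabolism and syntrophy. The package decides whether a
beta-subunit homolog belongs to the **electron-bifurcating (BF)** group —
enzymes that co-oxidize NADH and reduced ferredoxin — or to the
**non-bifurcating (non-BF) NADH-dependent** group, whose hydrogen
production from NADH alone is feasible only at the very low hydrogen
partial pressures maintained by a hydrogen-consuming partner organism.

## What it computes

**Residue fingerprints in a reference frame.** Four diagnostic criteria in
*T. maritima* HydB numbering: position 232 (BF: A/E, non-BF: T/S),
position 234 (BF: M, non-BF: K/S/A) near the NADH site, position 367
(BF: F, non-BF: Y) near the FMN site, and the SLBB-domain motif at
427–431 (BF: exact `GGPSG`). Each query is globally aligned to a reference
scaffold (Needleman–Wunsch, affine gaps, BLOSUM62 −11/−1 default), a
monotone-injective position map transfers the coordinates, and a
unanimity-with-quorum rule yields BF / nonBF / ambiguous with per-criterion
evidence.

**Iron-sulfur cluster scanning.** Cysteine-spacing motifs for [4Fe-4S],
[2Fe-2S] and H-cluster regions with predicted iron stoichiometry
(4 + 2 + 6 Fe respectively; five [4Fe-4S] + two [2Fe-2S] + one H-cluster =
30 Fe per αβ heterodimer). The extra-cluster count relative to the
reference is attached as advisory evidence only.

**Phylogeny.** Star alignment through the reference, occupancy-based
column trimming, p or Poisson (−ln(1−p)) distances, neighbor joining
(exact on additive matrices) and an edge-bipartition monophyly test for
the non-BF clade.

**Thermodynamics.** Nernst machinery for NADH + H⁺ ⇌ NAD⁺ + H₂: with the
Nernst slope s = ln(10)·RT/F,

    E_NAD = E0'_NAD − (s/2)(pH−7) + (s/2)·log10([NAD+]/[NADH])
    E_H2  = E0'_H2  −  s  (pH−7) − (s/2)·log10(p/p°)

and the closed-form equilibrium hydrogen pressure at which the two are
equal — exactly proportional to the NADH/NAD⁺ ratio.

**Biochemistry worked examples.** Protein mass from average residue
masses, theoretical pI by bisection, Beer–Lambert specific activities,
purification fold/yield tables, per-subcomplex conversions.

**Synthetic data.** A seeded generator of beta-subunit-like sequences with
planted fingerprints, cluster motifs and truth labels, so the whole
pipeline is testable offline.

## Worked example

```r
library(bifhyd)

ds  <- generateDataset(nBf = 5, nNonbf = 5,
                       identityRange = c(0.7, 0.9), seed = 7)
set <- classifyBatch(ds$records, ds$scaffold)
classSummary(set)
#>        BF     nonBF ambiguous
#>         5         5         0

set@results[[1]]
#> ClassificationResult BF_001: BF (identity 0.858, Fe-S support +4)
#>            rule observed verdict
#> 1 nadh_site_232        E      BF
#> 2 nadh_site_234        M      BF
#> 3  fmn_site_367        F      BF
#> 4  slbb_427_431    GGPSG      BF

equilibriumH2Pressure(c(5, 1, 0.2))
#>   ratio_nadh_nad    p_h2_Pa E_couple_mV
#> 1            5.0 106.372369   -355.4651
#> 2            1.0  21.274474   -334.7898
#> 3            0.2   4.254895   -314.1145
```

All ten planted sequences classify to their truth labels with no ambiguous
calls, and each result carries the observed residue at every criterion.
The equilibrium pressures say that at an intracellular NADH/NAD⁺ ratio of
5 a non-BF enzyme can sustain at most ~106 Pa of hydrogen (pH 7.5, 25 °C),
falling proportionally to ~4 Pa at a ratio of 0.2 — the quantitative basis
for why such organisms need a hydrogen-scavenging partner.

A command-line front-end is installed at
`system.file("exec", "bifhyd", package = "bifhyd")` with subcommands
`classify`, `phylo`, `thermo`, `biochem` and `simulate`.

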