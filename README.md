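# osteokit

Quantitative zooarchaeology in R: from specimen-level bone records to the
summary statistics that subsistence studies report — skeletal-part
quantification, diet breadth, prey selection, mortality profiles,
taphonomy, Bayesian transport/attrition inference, travel-time site
catchments and productivity–diversity correlation.

## Who this is for

Zooarchaeologists and palaeoecologists analysing Palaeolithic faunal
assemblages. The package takes delimited-text inputs (specimen records,
skeleton templates, DEMs, NPP series) and produces the per-unit tables a
site report prints, with every quantity computed by tested, reusable
functions rather than spreadsheet arithmetic. A synthetic assemblage
generator with known ground truth lets each stage be validated end to end.

## What it computes

**Quantification.** NISP per taxon; MNE as the minimum number of whole
elements consistent with the observed anatomical portion codes (each
element divided into 20 coded portions), sides and age classes; MNI from
element/side/age pairing; MAU = MNE / elements-per-skeleton and %MAU.

**Diet and prey selection.** Inverse Simpson diversity `1/D` with
`D = Σ pᵢ²`; juvenile-to-adult ratio `(F+J+SAd)/(Ad+S)` over the five age
classes F (foetal/neonatal), J (juvenile), SAd (sub-adult), Ad (adult),
S (senile); mountain/plain and high/low-rank prey ratios; usable-meat
biomass; ternary (juvenile, prime, old) mortality coordinates.

**Taphonomy.** Butchery-mark tables (percussion, cut, both; %BM),
burning-stage histograms over colour codes 0–5 (multi-colour records
counted once at their highest code), and biostratinomic/diagenetic
modification tables.

**Skeletal-part formation model.** Observed element counts are modelled
as multinomial with cell probabilities

```
p_i ∝ k_i · w(region_i, α) · d_i^β ,   w = 1−α (axial), 1+α (appendicular)
```

where `k_i` is the element count per skeleton and `d_i` its maximum bone
density. `α ∈ [−1, 1]` is carcass-transport preference (0 = complete
transport) and `β ≥ 0` density-mediated attrition. The posterior under
uniform priors is sampled by random-walk Metropolis; the preservation
fraction `Σ k_i d_i^β / Σ k_i` is derived from the draws.

**Catchments.** Horn-kernel percent slope; anisotropic walking times from
Tobler's hiking function `v = 6 e^{−3.5 |dh/dx + 0.05|}` km/h over a
16-direction lattice (Dijkstra); isochrone areas split at a 30% slope
threshold into plain and mountain terrain.

**NPP statistics.** Per-unit means/SDs of an externally produced NPP
series, Mann–Whitney comparisons (exact for small samples), and Spearman
productivity–diversity correlations (exact permutation p for small n).

## Worked example

```r
library(osteokit)

fumane <- counts_summary(fumane_counts())   # bundled published count tables
subset(as.data.frame(fumane$by_unit),
       select = c(unit, inv_simpson_mni, juvenile_adult_ratio,
                  hunting_pref_nisp, mountain_nisp_pct))
#>    unit inv_simpson_mni juvenile_adult_ratio hunting_pref_nisp mountain_nisp_pct
#> 1 A2-A1        4.298507            0.8461538          2.602740          72.24335
#> 2    D3        4.245283            0.8750000          2.590909          72.15190
```

Diet breadth is effectively identical in the two occupations (≈ 4.3 vs
4.25 equally-abundant-species equivalents), juveniles were taken slightly
less often than adults (ratios 0.85 and 0.88), and mountain-adapted prey
(ibex, chamois) dominate the identified specimens (72% in both units,
NISP ratio ≈ 2.6) — a stable, locally focused hunting pattern.

A fully synthetic round trip with known truth:

```r
tmpl <- caprine_template()
sc <- assemblage_scenario(tibble::tibble(taxon = "Capra ibex", n = 8),
                          tmpl, alpha = 0.1, beta = 1, fragmentation = 2,
                          seed = 42)
g <- generate_assemblage(sc)
quantify_unit(g$specimens, "SYN", tmpl)
#> Quantification of unit SYN: NR 675, NISP 675, MNE 322, MNI 8
```

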