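# phyloturn

Tools for asking why related lineages live where they do: does climate sort
them (phylogenetic niche conservatism) or do oceans and distance keep them
apart (dispersal limitation)? The package implements, as one tested pipeline,
the spatial-phylogenetics workflow used to answer that question for
pantropical plant radiations:

1. **Tree assembly** — grafting dated subtrees onto a dated backbone
   ("metachronograms"), genus-level polytomy expansion, and time slicing for
   ancient turnover.
2. **Gridding** — occurrence records onto a 0.5° lattice with richness and
   latitude filters, per-cell climate summaries, dry season length (DSL: the
   longest circular run of months < 100 mm), and categorical biome
   distances.
3. **Beta diversity** — pairwise taxonomic and phylogenetic Simpson
   turnover, `beta-sim = min(b, c) / (a + min(b, c))`, Sørensen, the reverse
   PBD deviation `-(TBD − PBD)/TBD`, and ancient turnover after collapsing
   branches younger than a cutoff.
4. **Generalized dissimilarity modelling** — from-scratch monotone I-spline
   GDM, `d = 1 − exp(−η)` with non-negative coefficients fitted by
   iteratively reweighted non-negative least squares, percent deviance
   explained, variation partitioning between predictor sets, and geographic
   residuals.
5. **Phyloregionalization** — Ward/UPGMA agglomeration of cell
   dissimilarities, cophenetic-correlation algorithm selection, and
   Wilcoxon / Kruskal–Wallis / Dunn tests of climatic distinctness.
6. **Niche evolution** — ML Brownian ancestral states, Pagel's λ,
   precipitation-regime shift detection (dry < 1200 mm, wet > 1800 mm,
   ≥ 250-mm change, midpoint dating) and per-5-Ma shift fractions.
7. **Biogeography** — all-rates-different Mk fitting with stochastic
   mapping and majority-rule transition branches; DEC and DEC+J likelihoods
   (implemented from scratch), ML fitting, AIC-weighted model averaging, the
   greedy > 50 % ancestral-range rule, and transoceanic dispersal counts
   under a seven-region and a stricter three-region definition.

A synthetic-data module (`sim_config()`, `simulate_dataset()`) generates
birth–death trees, λ-transformed Brownian niches, Mk and DEC range
histories, gradient climate landscapes and occurrence clouds with known
ground truth, so every stage is benchmarked without any download.

## Worked example

The `analysis/` scripts run the whole pipeline on one seeded synthetic
dataset (80 species, 1600 occurrences, a 200-cell landscape):

```sh
Rscript analysis/01_simulate.R   # simulated 80 species, 1600 occurrences over 200 cells
Rscript analysis/02_grid.R       # retained 74 cells; median richness 11.5
Rscript analysis/03_turnover.R   # 2701 cell pairs; mean phylogenetic Simpson 0.542
Rscript analysis/04_gdm.R        # joint deviance explained 75.8%;
                                 #   unique climate 57.2%, unique geography 0.1%
Rscript analysis/05_regions.R    # cophenetic r: ward 0.827 upgma 0.837;
                                 #   k=2 MAP distinctness: wilcoxon p = 4.9e-13
Rscript analysis/06_niche.R      # Pagel's lambda: MAP 1.000, DSL 1.000; 0 niche shifts
Rscript analysis/07_biogeography.R
                                 # DEC d=0.0227 e=0.0116 | DEC+J j=0.020
                                 # seven grouping: 16 dispersal events; three: 6
```

Reading these numbers: the synthetic landscape assigns species ranges purely
by their precipitation niche, so climatic distance absorbs nearly all
explainable turnover (unique climate 57 %, unique geography 0.1 %) — the
pattern expected when niche conservatism, not dispersal limitation, structures
the assemblages. λ = 1.0 recovers the Brownian signal the generator used, the
k = 2 phyloregions split the landscape at the precipitation boundary, and the
DEC fit recovers the generating rates (d = 0.02, e = 0.005) to the right
order. Stage outputs land in `results/` as CSV/Newick/ASCII-grid files.

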