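# erosionet

Soil erosion strips organic matter, nutrients and moisture from sloped
agricultural land, and with them the microbial communities that drive soil
functioning. `erosionet` is an R package for the downstream analysis that
links the three observables of such studies — a soil **multifunctionality
index**, microbial **diversity**, and **co-occurrence network complexity**
— along a gradient of erosion intensity (E0 non-eroded, EL light, EM
moderate, EH heavy), analyzed per site. It is aimed at soil microbial
ecologists working with amplicon OTU tables plus plot-level soil
chemistry.

The core quantities:

* **Multifunctionality (MF)** — each of 12 soil variables (moisture, OC,
  TN, TP, NH₄⁺, NO₃⁻, AP, AK, MBC, MBN, Cm, Nm; pH excluded) is
  normality-transformed (Shapiro–Wilk-guided log/√), scaled to [0, 1],
  and averaged per plot: `MF_j = (1/12) Σ_v s_v(x_vj)`.
* **Diversity** — Shannon `H = −Σ p_i ln p_i`, observed species, ACE
  richness `S_ace = S_abund + S_rare/C_ace + (F1/C_ace)γ²`; Bray–Curtis
  dissimilarity with ANOSIM (`R = (r̄_B − r̄_W)/(n(n−1)/4)`, permutation
  or exact p) and constrained PCoA.
* **Networks** — per-site Spearman correlation matrices over OTUs with
  mean relative abundance > 0.01%; the edge threshold `s_t` is selected by
  random-matrix theory (the point where eigenvalue nearest-neighbour
  spacings transition from Wigner/GOE to Poisson `e^(−d)` statistics);
  edges require `|ρ| ≥ s_t` **and** Benjamini–Hochberg `q < 0.05`.
  Topology (nodes, edges, betweenness, assortativity, transitivity,
  modularity) is reported globally and per sample via induced subgraphs,
  and keystone OTUs satisfy degree > 6, weighted degree > 6, closeness
  > 0.14, betweenness < 0.05, transitivity > 0.09.
* **Associations** — OLS regressions of MF on diversity and network
  metrics, Pearson tables, Kruskal–Wallis with compact-letter post hoc,
  blocked two-way ANOVA (site × erosion, transect as block), and RDA.

A synthetic-data generator reproduces the full study design (2 sites × 4
erosion levels × 2 transects × 3 plots, lognormal abundances with
calibrated erosion-driven diversity decline, correlated OTU guilds with
hub taxa, field-calibrated soil declines), so the entire pipeline is
testable without sequencing data. See the methods vignette
(`vignettes/erosion-microbiome-networks.Rmd`) for the model details and
conventions.

## Worked example

```r
library(erosionet)

bundle <- generate_dataset(simulation_config(seed = 1))
ids    <- bundle$metadata$sample_id[bundle$metadata$site == "blacksoil"]
counts <- filter_otus(bundle$otu_table[ids, ])

diversity <- alpha_diversity(counts)
head(diversity, 3)
#>            sample_id  shannon observed_species      ace ace_undefined
#> 1 blacksoil_E0_T1_P1 3.766519              229 231.7776         FALSE
#> 2 blacksoil_E0_T1_P2 3.935858              227 230.0248         FALSE
#> 3 blacksoil_E0_T1_P3 4.218028              229 229.1666         FALSE

corr <- spearman_matrix(counts)
scan <- rmt_select_threshold(corr)
scan$selected
#> [1] 0.76
net <- build_network(corr, scan$selected)
net
#> co-occurrence network: 117 nodes, 145 edges (|rho| >= 0.76, q < 0.05)
global_topology(net)
#>   node_number edge_number betweenness assortativity transitivity degree modularity
#> 1         117         145      0.0187         0.139        0.145   2.48      0.709

mf <- multifunctionality(bundle$soil_table[bundle$soil_table$site == "blacksoil", ])
linear_regression(diversity$shannon, mf$mf, "shannon", "mf")
#>   predictor response slope intercept r_squared  p_value  n
#> 1   shannon       mf 0.344    -0.727     0.559 2.64e-05 24
```

The RMT scan settles on a correlation threshold of 0.76 for this site and
seed; at that threshold 117 OTUs remain connected by 145 significant
correlations. The regression shows the coupling the analysis is designed
to detect: plots with higher Shannon diversity have higher soil
multifunctionality (slope 0.34 per nat, p ≈ 3 × 10⁻⁵, n = 24).

`run_pipeline()` executes everything above per site and writes TSV/JSON
results plus a log of the threshold scan and all seeds. A thin CLI lives
in `inst/scripts/erosionet` (`erosionet simulate`, `erosionet run`).

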