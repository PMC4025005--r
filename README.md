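# riskSOM

Social-ecological pattern discovery for soil heavy-metal risk.

Regional soil surveys measure metal concentrations at point locations,
but land-use decisions are made for administrative units ("towns") whose
contamination is shaped as much by social drivers — population density,
industry, roads, agriculture — as by geochemistry. `riskSOM` implements
the full screening workflow that joins the two views:

1. **Risk indexing.** For each sample and metal *i*, the contamination
   factor is C_r^i = concentration / reference, the ecological risk
   factor is E_r^i = T_r^i x C_r^i with the Hakanson toxic-response
   factors (Hg 40, Cd 30, As 10, Cu = Pb = Ni 5, Cr 2, Zn 1), and the
   potential ecological risk index aggregates RI = Σ_i E_r^i. Per-metal
   grades step at E_r = 40 / 80 / 160 / 320 (low, moderate,
   considerable, high, very high).
2. **Spatial aggregation.** Point indices are interpolated to a regular
   grid by ordinary kriging (spherical or exponential variogram fitted
   by pair-count-weighted least squares) and averaged within unit
   polygons by the cell-center rule.
3. **Pattern discovery.** A batch self-organizing map (SOM) is trained
   on the towns x (19 covariates + RI) matrix; map size is scanned by
   quantization error (QE) and topographic error (TE); the codebook is
   clustered by k-means with the number of clusters selected by the
   minimum Davies-Bouldin index (DBI); towns inherit the cluster of
   their best matching unit.
4. **Characterization.** Per-cluster mean (SD) tables with one-way
   ANOVA compact-letter groupings (Tukey HSD or Duncan's multiple range
   test) and per-cluster Spearman correlations of each covariate with
   RI, with "not computable" markers where a variable is constant.

Because survey datasets of this kind are rarely redistributable, the
package ships a synthetic-scene generator (`simulateScene()`) that
plants nine covariate archetypes — spanning mountainous, agricultural
and urbanized town profiles — with lognormal metal concentrations and a
calibrated synthetic reference panel, so the entire pipeline can be
exercised and validated against known ground truth.

## Worked example

```r
library(riskSOM)

scene <- simulateScene(nTowns = 120, nSamples = 400, seed = 42)
risk  <- scoreSamples(scene@samples, scene@panel)
head(risk[, c("subject_id", "cf_Hg", "er_Hg", "ri", "grade_Hg")], 3)
#>   subject_id    cf_Hg    er_Hg       ri     grade_Hg
#> 1      S0001 3.363975 134.5590 273.1057 considerable
#> 2      S0002 3.052410 122.0964 453.5145 considerable
#> 3      S0003 2.609956 104.3982 310.0921 considerable

table(gradeRisk(risk$er_Hg))
#>          low     moderate considerable         high    very_high
#>          124          174           82           17            3

vgm  <- fitVariogram(empiricalVariogram(scene@samples$lon,
                                        scene@samples$lat, risk$ri))
vgm
#> VariogramModel (spherical): nugget 8788, partial sill 1509, range 0.1522
grid   <- krigeGrid(scene@samples$lon, scene@samples$lat, risk$ri,
                    vgm, cellSize = 0.02)
townRI <- zonalMean(grid, scene@towns)
feats  <- assembleFeatureMatrix(scene@covariates, townRI)

som <- trainSOM(feats[, -1], nRows = 8, nCols = 5)
round(quantizationError(som, feats[, -1]), 3)   #> 2.299
round(topographicError(som, feats[, -1]), 4)    #> 0.0583

sel <- selectK(codebook(som), 2:10, seed = 42)
sel$k                                           #> 10
round(sel$dbi, 3)                               #> 0.877
towns <- projectLabels(som, sel$labels, feats[, -1])
```

The per-sample table reads: sample S0001 holds about 3.4 times the
mercury reference (`cf_Hg`), which the toxic-response factor 40 turns
into a considerable per-metal risk (`er_Hg` = 134.6), and the eight
metals together give RI = 273. The fitted variogram says neighbouring
samples share structure out to about 0.15 degrees. QE is the mean
distance from a town's (z-scored) profile to its best matching unit; TE
is the share of towns whose two best units are not lattice neighbours.
`selectK` picks the partition with the lowest Davies-Bouldin index —
on a small 120-town scene the planted archetypes overlap substantially,
so the selected k need not equal the planted nine (see the methods
vignette for what recovery the default scene does and does not
support).

`runPipeline()` executes the same chain end to end, writing per-stage
CSV artifacts and a JSON manifest with checksums; a thin command-line
front end is installed at `inst/scripts/risksom`
(`risksom run-all --seed 1 --out out/`).

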