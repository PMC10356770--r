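# metabomark

Predictive metabolomics for chemotype and maternal-genotype markers from
untargeted feature tables.

## The problem

Plants of one species often split into **chemotypes** — classes defined by
their dominant specialised metabolites (e.g. the leaf terpenoids of tansy).
An untargeted LC–MS/GC–MS **metabolic fingerprint** quantifies thousands of
aligned features per sample. `metabomark` answers two questions about such
tables:

1. Can the fingerprint *predict* a sample's chemotype or maternal genotype,
   and which features (markers) carry the prediction?
2. How much chemical variance is *uniquely attributable* to chemotype
   versus maternal genotype?

## The methods at its core

- **Preprocessing**: blank-ratio filter (mean sample ≥ 50 × mean blank),
  presence filter (detected in ≥ 2 samples), internal-standard and
  dry-weight normalisation, median normalisation, cube-root transformation
  and Pareto scaling (x ↦ (x − x̄)/√s).
- **Ensemble prediction**: N resampled models, each a stratified 60/20/20
  train/validation/test split with a multinomial elastic-net fit
  (objective −(1/n)·ℓ(β) + λ Σⱼ[(1−α)/2‖βⱼ‖² + α‖βⱼ‖₁]) tuned over an
  (α, λ) grid on the validation set and scored on the test set. Markers
  are selected by **occurrence** — in how many of the N models a feature
  kept a nonzero coefficient; the top-5% rule applied to 3,688 candidate
  features yields exactly 184 markers.
- **Validation**: permutation-null ensembles (labels reshuffled per
  permuted dataset), Welch t-test between real and null score vectors,
  and cross-batch **transfer** of the marker model to an independently
  normalised later batch.
- **Variation partitioning**: partial redundancy analysis with Ezekiel
  adjustment, decomposing adjusted R² into fractions unique to each factor
  (a, c), shared (b) and residual (d); unique fractions tested by
  residual-permutation ANOVA.
- **Synthetic data**: a generator with a planted ground-truth ledger
  (marker identities, effect sizes, structural zeros, blank behaviour,
  batch shifts) so every stage is testable without instrument data.

## Worked example

Simulate a 5-chemotype study (150 samples, 500 features, 20 planted
markers with 2σ effects plus 50 genotype markers), preprocess, run a
20-model ensemble, select 39 markers and validate against a permutation
null:

```r
library(metabomark)

cfg <- simulationConfig(nChemotypes = 5, nGenotypes = 10,
                        nSamplesPerGenotype = 15, nFeatures = 500,
                        fracChemotypeMarkers = 0.04, fracGenotypeMarkers = 0.1,
                        effectSizeChemo = 2, effectSizeGeno = 2,
                        fracClassExclusive = 0, noiseSigma = 0.4, seed = 1)
sim <- generateDataset(cfg)
pp  <- preprocess(sim$table, blanks = generateBlanks(cfg, 4))
metadata(pp)$preprocessLog
#>                   step features_in features_out
#> 1         blank_filter         501          476
#> 2      presence_filter         476          476
#> 3         is_normalize         476          475
#> 4 dry_weight_normalize         475          475
#> 5     median_normalize         475          475
#> 6            cube_root         475          475
#> 7         pareto_scale         475          475

ctrl <- ensembleControl(nModels = 20, alphaGrid = c(0.1, 0.5, 0.9),
                        nLambda = 15, baseSeed = 1)
ens <- runEnsemble(pp, "chemotype", ctrl)
ens
#> EnsembleResult: 20 models, 475 features, 5 classes
#>   mean test accuracy 0.970 (sd 0.032)

markers <- selectMarkers(ens, k = 39)
markers
#> MarkerSet: 39 markers (rule: top_k = 39 )
#>   top: F0481(20) F0418(20) F0213(20) F0129(20) F0277(20)
sum(chemoMarkerIds(sim$truth) %in% featureIds(markers))
#> [1] 19   # of the 20 planted chemotype markers

nullScores <- permutationNull(pp, "chemotype", 10, ctrl)
cmp <- compareScores(testScores(ens), nullScores)
#> real 0.970 vs null 0.187 accuracy, Welch t = 31.3, p = 7.56e-12
```

The 25 features removed by the blank filter are exactly the generator's
planted weak-blank features; the ensemble's 97% test accuracy against a
~19% permutation null, and the 19/20 recovered planted markers, are what
a strong, mostly quantitative chemotype signal looks like after the full
chain. `variationPartition(t(intensities(pp)), chemotype, genotype)`
then attributes unique and shared fractions of the scaled feature
variance to the two factors (with genotypes fully nested in chemotypes,
the chemotype-attributable variance appears in the shared fraction).

`runPipeline(runConfig(...), outDir)` chains every stage (preprocess →
univariate ANOVA/Tukey/FDR → ensemble + permutation null → markers →
variation partitioning) and writes all intermediate tables plus a
machine-readable `summary.json`.

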