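# tmsn — temporal multilayer symptom networks and graph-diffusion prediction

`tmsn` is an R package for two-wave clinical symptom panels (one row per
subject, item scores at a baseline and a follow-up assessment, plus age and
sex). It answers two questions that cross-sectional symptom networks
cannot:

1. **Which symptoms drive the flow of psychopathology over time?**
   Both waves are modelled as one symmetric `2p x 2p` adjacency — the
   temporal multilayer symptom network (TMSN) — whose diagonal blocks hold
   cross-sectional correlations and whose off-diagonal block holds
   baseline-to-follow-up correlations, after age/sex residualization and
   Benjamini–Yekutieli FDR thresholding of the whole family of pairs at
   `alpha = 0.05`. Shortest paths (Floyd–Warshall on lengths `1/w`) from
   every baseline item to every follow-up item give each node a
   *longitudinal betweenness* — the number of such paths on which it is
   strictly interior. Against a null of 10,000 edge-reshuffled networks,
   significant baseline-layer nodes are **gateways** (they broadly mediate
   effects onto later symptoms) and significant follow-up-layer nodes are
   **funnels** (broadly influenced by earlier symptoms). A spectral
   embedding of the adjacency (eigendecomposition, components retained
   against a reshuffled-spectrum null) lays the network out so that the
   first dimension captures the cross-sectional symptom structure and the
   second captures time.

2. **Can an individual's follow-up profile be predicted from their
   baseline?** For each held-out subject the TMSN is re-fit on the other
   `n - 1` subjects; the subject's baseline severities (z units) are
   clamped on the baseline layer, follow-up nodes start at 0, and the
   signal diffuses by `dx/dt = -gamma * L * x` (combinatorial Laplacian,
   clamp re-imposed every step) until the change over free nodes is below
   `1e-9`. The steady state — the harmonic extension of the clamped
   values, which the default solver computes exactly — is the predicted
   follow-up profile. Accuracy is compared against the *clinical
   stability* baseline (predict no change; its MSE is exactly the mean
   squared symptom change) with a paired test on per-observation squared
   errors.

Because real high-risk cohorts are not publicly deposited, the package
ships a synthetic-cohort generator (`generative_spec()`,
`sample_cohort()`, `plant_pathway_structure()`, `null_cohort()`) — a
stationary linear-Gaussian cross-lagged panel with block-structured
modules, known planted gateways/funnels, and age/sex effects — so every
stage of the pipeline can be tested against ground truth.

## Worked example

Simulate a cohort of 150 subjects and 12 items per wave with one planted
gateway (`item01` sends a standardized cross-lag of 0.3 to half of the
follow-up items), fit the network, test longitudinal centrality, and run
the leave-one-out diffusion prediction:

```r
library(tmsn)

spec <- plant_pathway_structure(
  generative_spec(n_subjects = 150, p_items = 12, seed = 42),
  gateway_count = 1, funnel_count = 0, effect = 0.3)
sim <- sample_cohort(spec)

net <- tmsn(sim$cohort, sign_mode = "positive_only")
summary(net)
#> TMSN summary: 24 nodes, pearson edges at BY alpha = 0.05 (n = 150)
#>              tested surviving positive
#> baseline         66        29       29
#> followup         66        17       17
#> longitudinal    144        21       21
#> negative surviving correlations: 0
#> mean node strength: 1.954

cr <- centrality_null_test(net, n_null = 1000, seed = 7)
cr
#> Longitudinal betweenness permutation test (1000 reshuffled networks, BY alpha = 0.05)
#>   1 gateway(s), 0 funnel(s):
#>       node    layer betweenness            p           q   class
#>  item01@bl baseline          43 8.332639e-05 0.007551287 gateway

ev <- evaluate_predictions(loocv_predict(sim$cohort))
ev
#> Prediction evaluation (z units, pooled over 1800 observations)
#>   MSE of clinical stability=1.26±1.8, MSE of graph diffusion=1.02±1.5, p<0.00001
#>   real vs predicted severity:  R=0.361, p<0.00001
#>   real vs predicted change:    R=0.458, p<0.00001
#>   per-subject mean severity:   R=0.567, p<0.00001
#>   per-subject mean change:     R=0.206, p=0.01159
```

The planted gateway is recovered (43 baseline-to-follow-up shortest paths
run through `item01@bl`, far above the reshuffled null), and the diffusion
prediction beats clinical stability (MSE 1.02 vs 1.26, paired t on 1800
held-out observations) while the pooled real-vs-predicted severity
correlation is R = 0.36. `plot(net)` draws the spectral embedding with
layers colour-coded; `embed_nodes()`, `distance_correlation_check()` and
`dim2_longitudinal_association()` expose the embedding validation
statistics; `nodewise_predictability()` gives per-symptom R² from network
neighbours.

A thin command-line wrapper is installed under `inst/scripts/symptomflow`:

```sh
Rscript inst/scripts/symptomflow simulate --n 200 --p 20 --gateways 1 --seed 17 --out cohort.csv
Rscript inst/scripts/symptomflow build    --cohort cohort.csv --alpha 0.05 --out-prefix net
Rscript inst/scripts/symptomflow pathways --cohort cohort.csv --n-null 10000 --seed 17 --out nodes.csv
Rscript inst/scripts/symptomflow predict  --cohort cohort.csv --target-instrument AFF --augment NEG --out pred.csv
```

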