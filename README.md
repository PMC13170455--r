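# TcellFlux

Constraint-based metabolic modelling of T cell subsets in R.

Proliferating T cells run strongly glycolytic programmes while resting
cells burn fatty acids; TcellFlux turns cell-type transcriptomes into
**context-specific genome-scale metabolic models** and asks what those
programmes imply for metabolic fluxes. It implements the full
comparative workflow:

* **Model I/O** — SBML Level 3 (fbc) and COBRA-style JSON readers/writers,
  uptake media as TSV.
* **Consistency & extraction** — blocked-reaction detection, the largest
  flux-consistent sub-model, and a fastcore-style extraction (LP-7/LP-10)
  that returns a compact consistent sub-network containing a core set.
* **Expression integration** — replicate averaging, GPR scoring
  (AND = min, OR = max), quantile-based core selection, and eFlux bound
  scaling.
* **Flux analyses** — FBA, FVA, and production-capacity probes for ATP,
  NADPH (redox demand) and metabolite secretion, all on the steady-state
  polytope `S v = 0, lb ≤ v ≤ ub` (fluxes in mmol/gDW/h).
* **Perturbations** — an in silico inhibitor panel (reaction blocks mapped
  from genes through GPR membership), anoxia, and relative biomass/ATP
  reporting with failure flags.
* **Superoxide challenge** — stoichiometric rewriting that diverts a
  fraction (default 2%) of electron-chain oxygen consumption to
  mitochondrial superoxide, plus per-sample fate accounting
  (SOD / ascorbate / glutathione / leakage, summing exactly to
  production).
* **Flux sampling** — a seeded artificial-centering hit-and-run chain with
  null-space projection, plus distribution summaries and kernel densities.
* **Synthetic test bed** — a hand-authored 86-reaction, three-compartment
  toy network of central T cell metabolism and three expression archetypes
  (an activated glycolytic/glutaminolytic subset, a metabolically flexible
  effector subset, and a resting oxidative subset), so the entire pipeline
  runs and is testable without any download.

The LP engine is a built-in bounded-variable two-phase simplex with
Bland's rule — deterministic and dependency-free.

## Worked example

```r
library(TcellFlux)

cfg <- runConfig(seed = 1, samplingN = 2000, samplingWarmup = 500,
                 samplingThinning = 5)
res <- runPipeline(cfg)
compareModels(res)$capacities
#>           cell_type   biomass      atp     nadph   lactate anoxia_atp_relative
#> alps_like alps_like 1.2500000 53.37500  4.297487 20.000000           0.3747073
#> ebv_like   ebv_like 1.0000000 51.49436 30.108894  4.815757           0.0935201
#> hd_like     hd_like 0.2766598 98.18182 46.526299  0.000000           0.0000000
```

Reading the table: the activated archetypes build biomass 3–4x faster
than the resting one; lactate secretion tracks the glycolytic programme
(20 -> 4.8 -> 0 mmol/gDW/h); NADPH production capacity — the currency of
ascorbate-dependent superoxide detoxification — runs the other way
(4.3 < 30.1 < 46.5); and blocking oxygen uptake collapses ATP production
only in the oxidative resting model (relative capacity 0 vs 0.09-0.37).
`res$<cell_type>$panelBiomass` holds the inhibitor panel — biomass fails
(zero flux) under glutamine-uptake blockade only in the
glutamine-dependent activated archetype and under CPT1 blockade only in
the FAO-dependent resting one — and `res$<cell_type>$fate` the
superoxide-fate decomposition, with leakage highest where the
detoxification arms are transcriptionally silent.

Single pieces compose just as well:

```r
toy <- applyMedium(buildToyNetwork(), defaultMedium())
fba(toy)                        # FluxSolution: optimal, objective = 2.25
atpCapacity(toy)                # 121.5
nadphCapacity(toy)              # 130
ch <- addSuperoxideCoupling(toy, fraction = 0.02)
s  <- sampleFluxes(ch$model, n = 2000, seed = 1, warmup = 500, thinning = 5)
superoxideFate(ch$model, ch$challenge, s)$summary
```

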