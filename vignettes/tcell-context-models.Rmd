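---
title: "Transcriptome-constrained metabolic models of T cell subsets"
author: "TcellFlux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-constrained metabolic models of T cell subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TcellFlux)
```

## The modelling problem

Activated T cells rewire their metabolism: strongly proliferating subsets
run high aerobic glycolysis, while resting cells lean on fatty-acid
oxidation (FAO) and oxidative phosphorylation (OXPHOS). TcellFlux asks what
those transcriptional programmes imply at the level of metabolic *fluxes*.
It builds, for each cell type, a context-specific genome-scale metabolic
model constrained by that cell type's transcriptome, and then interrogates
the models with the standard constraint-based toolbox.

All analyses live on the steady-state flux polytope

$$\{\,v \;:\; S\,v = 0,\;\; lb \le v \le ub\,\}$$

where $S$ is the stoichiometric matrix (metabolites by reactions) and the
bounds are in mmol/gDW/h. The pipeline per cell type is:

1. **Replicate averaging** — per-gene arithmetic mean over the union of
   gene ids, genes absent from a replicate counting as zero (not detected).
2. **GPR scoring** — each reaction's gene–protein–reaction rule is
   evaluated with AND = min (an enzyme complex is limited by its scarcest
   subunit) and OR = max (isozymes are alternative routes). Reactions
   without a rule score *missing*.
3. **Core selection** — a reaction enters the expression core when its
   score reaches the 0.75 quantile of all non-missing scores; a small
   mandatory core (biomass, ATP demand, the respiratory chain, superoxide
   membrane passage, biomass export) is always included.
4. **Consistency and extraction** — a flux-consistency pass removes
   blocked reactions, then a fastcore-style extraction (LP-7 activation and
   LP-10 L1-penalised support search) returns a compact flux-consistent
   sub-network containing the core.
5. **Medium and eFlux** — exchange uptakes are capped by a simulated T cell
   medium; enzymatic reaction bounds are scaled to
   $v_{max}\, s / s_{max}$ by their expression score (eFlux). Exchanges and
   rule-less reactions keep their bounds: the medium, not expression,
   governs uptake.
6. **Interrogation** — biomass FBA, flux variability analysis at optimal
   biomass, ATP/NADPH/lactate capacities, an in silico inhibitor panel,
   artificial-centering hit-and-run flux sampling, and a mitochondrial
   superoxide challenge with fate accounting.

The only difference between the cell-type models is the expression input;
medium, core-selection rule, tolerances and seeds are shared.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 1e-4 mmol/gDW/h | minimum activation flux defining consistency; the value of the original fastcore family of algorithms |
| `thresholdQuantile` | 0.75 | expression quantile for core membership |
| `vMax` | 1000 mmol/gDW/h | eFlux scale; the customary "effectively unbounded" flux |
| superoxide `fraction` | 0.02 | mmol superoxide per mmol O2 consumed by the mitochondrial electron chain |
| sampling `n`/`warmup`/`thinning` | 10000 / 1000 / 100 | hit-and-run chain settings; 10,000 samples characterise each flux distribution |

Every run records these in its JSON manifest alongside model hashes and
seeds, so any table can be traced to the exact model and chain that
produced it.

## Design choices where the design was open

* **GPR convention.** AND = min / OR = max is the conservative standard for
  complexes and isozymes; nothing in the integrated data justifies a more
  elaborate (e.g. sum-over-isozymes) rule.
* **Medium composition.** The simulated T cell medium is an explicit,
  configurable stand-in: glucose 10, glutamine 5, amino-acid pool 4, fatty
  acid 2, O2 20, ribose 1, heme 0.2, ascorbate 0.5, phosphate and water
  effectively free (all mmol/gDW/h). Magnitudes follow the usual
  glucose-dominated in silico media for mammalian cells.
* **eFlux scope.** Only reactions with a GPR are scaled; lower bounds of
  reversible reactions are scaled symmetrically, irreversible ones stay at
  zero. Applying expression constraints to exchanges would conflate
  environment with enzyme capacity.
* **NADPH capacity probe.** NADP(H) is a conserved moiety, so a bare
  `nadph ->` removal sink can never carry steady-state flux. The capacity
  probe is therefore the redox demand `nadph -> nadp`, the maximal
  sustainable oxidation of newly produced NADPH, summed over a configurable
  compartment list (default: cytosol, where the ascorbate-recovering
  glutaredoxin operates). For a single sink reaction the FBA maximum and
  the FVA upper bound coincide.
* **Superoxide challenge.** The 2% coupling is implemented by rewriting
  the stoichiometry of the electron-chain reactions — per unit flux,
  `fraction x |O2 coefficient|` of superoxide appears among the products
  and twice that much product water disappears, conserving oxygen atoms.
  Keeping the model a plain $Sv=0$ system means every downstream solver
  and the sampler work unchanged. "Leakage" is operationalised as flux
  through an added irreversible superoxide sink; all fate components are
  reported in superoxide equivalents so that production equals
  SOD + ascorbate + glutathione + leakage exactly in every sample.
* **Extraction determinism.** Candidate reactions are processed in
  lexicographic id order and the LP solver uses Bland's rule, so the
  extracted sub-network is identical across runs and platforms. The LP-10
  step activates core reactions at `1e4 x epsilon` (capped by the bounds),
  which keeps support reactions with small stoichiometric coefficients
  (e.g. biomass precursors) above the support-detection threshold.
* **Futile cycles.** Consistency is defined purely by $Sv = 0$ and bounds;
  thermodynamically infeasible loops are not pruned, but stoichiometric
  2-cycles are reported (`findTwoCycles`) for manual curation.
* **Empty models.** A consistency pass may legitimately remove everything;
  a reaction-free model is a valid (if degenerate) result rather than an
  error.

## The synthetic test bed

`buildToyNetwork()` returns a fixed, hand-authored model (73 metabolites,
86 reactions, 3 compartments) covering glycolysis with two hexokinase
isozymes, lactate fermentation, the oxidative PPP plus a ribose salvage
route, pyruvate oxidation with a lumped TCA cycle and electron chain
(P/O 2.5), glutaminolysis, CPT1-gated FAO, glutathione synthesis/recycling
and efflux, ascorbate/glutaredoxin superoxide detoxification, superoxide
dismutases, an NADPH oxidase, heme oxygenase releasing CO, biliverdin and
Fe2+, a multi-precursor biomass reaction and an ATP demand. Every internal
reaction balances C, O, N and P exactly (the biomass pseudo-species carries
a fractional pool formula). The network is authored, not generated: the
comparative contrasts below must be achievable by expression input alone,
which constrains the topology (redundant ATP routes for the flexible
archetype, obligate glutamine anaplerosis when amino-acid import is
silent, NADPH-gated ascorbate recovery).

`simulateExpression()` produces replicate transcriptomes for three
archetypes as baseline x per-gene multiplier x lognormal noise (unit mean,
coefficient of variation 0.1 by default — right-skewed, strictly positive,
like depth-normalised RNA-seq abundances):

* **alps_like** — activated and glycolytic: glycolysis, glutaminolysis,
  amino-acid synthesis from glutamate, translation machinery and heme
  oxygenase high; PPP, FAO, amino-acid import, NADPH oxidase and the
  ascorbate/SOD/glutathione detoxification arms not expressed.
* **ebv_like** — activated and flexible: glycolysis with both hexokinase
  isozymes, the NADH shuttle, ribose salvage and the glutathione system
  high; everything else intermediate.
* **hd_like** — resting oxidative: FAO, PPP, SODs and ascorbate recycling
  high; lower glycolysis, glutaminolysis, pyruvate oxidation and the
  translation machinery low or off.

A multiplier of **zero means the gene is not detected** and is omitted from
the simulated profiles; its reactions then score 0 and their eFlux bounds
close. This is deliberately stronger than a small positive multiplier:
proportional bound scaling alone can never produce an exactly failed
(zero-flux) phenotype, while "transcript absent" is a routine observation
in real RNA-seq. The multiplier table ships as data
(`archetypeMultipliers()`), not code.

What the generator does *not* emulate: transcript-length and library-size
effects, within-population heterogeneity, post-transcriptional regulation,
and the sheer scale of a genome-wide reconstruction. Passing tests
demonstrate that the algorithms and their couplings behave correctly and
that the comparative logic (topology via core selection, capacity via
eFlux) works; they do not validate biological conclusions on real data.

## Numerical choices

The LP engine is a dense two-phase bounded-variable primal simplex with
Bland's anti-cycling rule (pivot tolerance 1e-9, infinities clamped to
1e7). For models of the size treated here (tens to a few hundred
reactions) this is fast, dependency-free and bit-reproducible — degenerate
optima are ubiquitous in FBA, so the *objective value*, not the flux
vector, is the contract. The sampler draws warmup points from an
objective-free FVA, projects them orthogonally onto the null space of $S$,
and walks with directions towards randomly chosen warmup points from a
running centre; the chain state is re-projected every 200 steps because the
centring updates slowly amplify rounding drift out of the null space.
Reactions whose FVA range is below 1e-9 are held at their forced value and
excluded from the walk.

The test-suite and acceptance runs use scaled-down chains (1,500–10,000
samples with thinning 4–10) — sizes chosen so that the Monte-Carlo
tolerances in the assertions hold with wide margins while the whole
comparative panel remains a minutes-scale computation on one CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- runConfig(seed = 1, samplingN = 2000, samplingWarmup = 500,
                 samplingThinning = 5)
res <- runPipeline(cfg)
compareModels(res)$capacities
```

The capacity table reproduces the comparative pattern the package is
designed around: biomass and lactate-secretion capacity highest in the
activated glycolytic archetype and lowest in the resting one, NADPH
production capacity in the reverse order, ATP capacity collapsing under
anoxia only for the oxidative archetype, biomass failing under glutamine
blockade only for the glutamine-dependent archetype and under CPT1 blockade
only for the FAO-dependent one, and superoxide leakage highest where the
detoxification arms are silent.

## Known limitations

* The fastcore-style extraction guarantees an approximately minimal
  non-core complement; exactness is verified by exhaustive enumeration only
  on small fixtures.
* No thermodynamic (loopless) constraints; sampled distributions can
  include internal cycles if a network contains them (the toy network does
  not).
* The sampler is a single seeded chain; convergence is checked by a
  stability property (doubling the sample count), not by formal
  diagnostics.
* SBML support covers Level 3 core + fbc (bounds, objectives, gene
  associations, formulas/charges, subsystem notes); groups, annotations and
  units are not preserved.
* Inhibitor specs map enzymes to reactions via GPR gene membership; models
  with unusual gene naming need the explicit reaction-id override.
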