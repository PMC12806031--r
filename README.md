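# glucoflux

Where does the glucose that a tumor imports actually go?

`glucoflux` answers that question from bulk transcriptomes. It implements
a two-step flux balance analysis over a glucose-centric stoichiometric
network — one source (imported glucose), ten internal transit metabolites,
and eight terminal sink pathways (nucleotide synthesis, lactate,
glycosylation, sialic acid, lipids, serine, gangliosides, TCA entry) —
and the downstream accounting that partition implies:

1. **Catalytic efficiencies** (kcat/Km per reaction) by prior-regularized
   nonnegative least squares under the pseudo-steady-state constraint
   `S v = 0`, with fluxes modeled as `v = eff ∘ Ē`, where the enzyme
   activity proxy `E_ij = Σ_{g∈Rj} w_g · TPM_ig` weights each GPR gene by
   `w_g = 2^(γ·log2FC) · (1 − p_adj)^η` (γ = 0.75, η = 0.7). Efficiencies
   are validated across EC classes by a Kruskal–Wallis test.
2. **Per-sample flux allocation** by a balanced quadratic program:
   maximize `Σ_s (w_s v_s − λ v_s²)` subject to internal mass balance,
   `Σ_s v_s = v_glc_in`, and ssGSEA-derived capacity bounds
   `0 ≤ v_s ≤ B_s = G_s × kcat/Km`, with `w_s = √B_s / Σ √B_s'`.
3. **Lactate fate**: a closed-form quadratic program splits the lactate
   flux between export and lactylation using softmax-blended ssGSEA
   weights.
4. **Proton accounting**: per-pathway proton fluxes `J = v · h` with `h`
   the mean net proton coefficient of the pathway's reactions, and
   production percentages with proton-consuming pathways floored at zero.
5. **Causal inference**: the backdoor-adjusted average treatment effect of
   nucleotide-synthesis activity on MKI67-measured cell-cycle activity
   (`Y = β0 + β_ATE·T + β_W·W`), with a permutation test (N = 500) and a
   latent-confounder refutation curve.
6. **Signature regressions**: one-component PLS scores feeding OLS fits
   for proliferation, migration, and the fraction of Fenton-reaction
   variability explained by the eight glucose pathways.

A synthetic-data module (`simulate_network()`, `simulate_cohort()`,
`simulate_causal_data()`) plants networks, cohorts and causal triples with
known ground truth, so every stage is exercised and validated at desk
scale. A curated eight-sink network reproducing the canonical topology
ships as `inst/extdata/glucose_network.json`.

The package is tidyverse-native: tabular results are tibbles, fitted
objects have `tidy()` / `glance()` methods, and result types have
`autoplot()` methods.

## Worked example

```r
library(glucoflux)

sim    <- simulate_network(n_internal_mets = 10, n_sinks = 8, seed = 1)
cohort <- simulate_cohort(sim$network, sim_config(seed = 2))
priors <- tibble::tibble(reaction_id = cohort$truth$true_eff$reaction,
                         eff0 = cohort$truth$true_eff$eff, source = "curated")

run <- run_pipeline(cohort$expression, cohort$metadata, sim$network,
                    priors, cohort$gene_sets, flux_config(seed = 3))

allocation_fractions(run$allocation)
#> # A tibble: 8 × 4
#>   pathway               mean_fraction n_samples mean_percent
#>   <chr>                         <dbl>     <int>        <dbl>
#> 1 ganglioside_synthesis        0.0698        60         6.98
#> 2 glycosylation                0.137         60        13.7
#> 3 lactate                      0.172         60        17.2
#> 4 lipid_synthesis              0.0882        60         8.82
#> 5 nucleotide_synthesis         0.293         60        29.3
#> 6 serine_synthesis             0.0794        60         7.94
#> 7 sialic_acid                  0.105         60        10.5
#> 8 tca_cycle                    0.0551        60         5.51

run$causal$estimate
#> <glc_ate> ATE = 0.4689 (unadjusted 0.5605), beta_W = 0.4624, n = 60
#> permutation p = 0.001996
```

The allocation table reads: averaged over the 60 tumor samples, 29.3% of
the imported glucose is routed to nucleotide synthesis, 17.2% to lactate,
and so on (the generator planted 28% / 18% / … — the pipeline recovers
the partition within ~1 percentage point and ranks nucleotide synthesis
first). The causal block shows that adjusting for the general
proliferation confounder W shrinks the nucleotide-synthesis effect on
MKI67 from 0.56 to 0.47 standard deviations, with the smallest attainable
permutation p-value at 500 permutations. `run$signatures$fenton$r2`
(0.871 here) is the fraction of Fenton-reaction score variance jointly
explained by the eight pathway signatures, and `run$lactate` splits each
sample's lactate flux into export (48.4% overall in this cohort) versus
lactylation.

Each stage is also callable on its own (`differential_expression()`,
`gene_weights()`, `activity_matrix()`, `estimate_efficiencies()`,
`ssgsea_score()`, `solve_flux_qp()`, `partition_lactate()`,
`proton_ledger()`, `estimate_ate()`, `fit_pls()`, …); see the methods
vignette (`vignettes/glucoflux-methods.Rmd`) for the model, assumptions,
parameter provenance and numerical choices. A thin command-line wrapper
lives at `inst/scripts/glucoflux.R` (`simulate` and `pipeline`
subcommands).

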