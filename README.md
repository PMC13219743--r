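# nitrisip

Soil nitrification is carried out by three guilds of ammonia oxidizers —
ammonia-oxidizing archaea (AOA), ammonia-oxidizing bacteria (AOB) and
complete ammonia oxidizers (comammox *Nitrospira*) — whose relative
contributions and carbon metabolism are hard to disentangle because all
three act on the same substrate. `nitrisip` implements the full inference
chain used to separate them with two complementary experimental designs:

1. **DNA stable-isotope probing (DNA-SIP).** Organisms assimilating a
   ¹³C-labeled substrate build denser DNA, which migrates toward the heavy
   end of a CsCl buoyant-density gradient. Comparing the relative qPCR
   abundance of a marker gene (*amoA*) between matched ¹³C- and
   ¹²C-substrate gradients in an operationally defined heavy window gives
   the labeled proportion of each guild,

   p̂ = (S₁₃ − S₁₂) / (1 − S₁₂),

   where S₁₃ and S₁₂ are the replicate-mean summed relative abundances in
   the heavy window. Multiplying p̂ by the total *amoA* copy number yields
   the ¹³C-labeled absolute abundance.

2. **Multi-inhibitor slurry partitioning.** Shaken soil slurries amended
   with selective inhibitors (NaClO₃ blocks nitrite oxidation by NOB;
   simvastatin blocks AOA; DMPP blocks AOB; acetylene blocks all
   autotrophic ammonia oxidation) isolate each guild's linear NO₂⁻ or
   NO₃⁻ production rate R. The nitrification potential is

   Np = R · (0.1 + V) / m · 24  [mg N kg⁻¹ dry soil d⁻¹],

   with 0.1 L the buffer volume, V the soil water volume (L) and m the
   soil dry mass (kg). The five assay arms are mapped to named potentials
   and percentage contributions under two schemes — scheme U
   ([AOA+AOB] vs [comammox], ammonia oxidizers uninhibited) and scheme I
   (AOA, AOB, comammox alone, fully resolved) — plus interaction indices
   `delta_AB = Np[AOA+AOB] − (Np_AOA + Np_AOB)` (antagonism when
   negative) and `delta_C = Np[comammox] − Np_comammox_alone` (synergy
   when positive).

On top of this, per-ASV differential ¹³C-enrichment tests across two
inhibitor contexts (no inhibitor vs acetylene) classify each ASV's
metabolic capability (`both`, `inorganic_only`, `organic_only`,
`unlabeled`), and a first-principles statistical toolkit provides one-way
ANOVA, Duncan's multiple range test with compact letter displays,
studentized-range quantiles and two-sample t-tests.

Because raw gradient and slurry measurements of this kind are rarely
published, the package includes a seeded synthetic-data generator
(two-Gaussian density mixtures with GC- and ¹³C-dependent peaks, lognormal
qPCR noise, inhibitor-modulated linear kinetics, negative-binomial ASV
counts) whose machine-readable ground truth supports end-to-end
parameter-recovery validation.

## Worked example

```r
library(nitrisip)

sc  <- make_scenario("WI2", seed = 42)      # high-organic-input soil preset
est <- quantify_labeling(sc$gradients, sc$totals, seed = 42)
est[, c("gene", "p_hat", "ci_low", "ci_high", "p_value", "labeled_abundance")]
#>       gene p_hat ci_low ci_high  p_value labeled_abundance
#> 1      AOA 0.845  0.840   0.853 4.15e-09          16896398
#> 2      AOB 0.594  0.591   0.596 4.73e-10          47548378
#> 3 comammox 0.592  0.584   0.598 1.66e-08           5919765

res <- estimate_potentials(sc$slurry, V = 0.005, m = 0.0095,
                           ace_baseline = TRUE)
interaction_report(list(res$partition))
#>   soil substrate delta_AB delta_C ab_interaction comammox_interaction
#> 1  WI2  13C-Urea    -6.82       4     antagonism              synergy
#>   comammox_share_U comammox_share_I
#> 1             39.4             21.9

round(res$partition$pct_scheme_I, 1)
#>            AOA            AOB comammox_alone
#>            6.1           72.0           21.9

classify_table(sc$asv_counts)$class_counts
#>           both inorganic_only   organic_only      unlabeled
#>             11             18             16            105
```

Reading: in this scenario 84.5% of the AOA population assimilated the
¹³C substrate; AOB dominate the fully resolved partition (72.0%), and the
comammox share rises from 21.9% (scheme I, AOA/AOB inhibited) to 39.4%
(scheme U, AOA/AOB active) — a positive `delta_C`, i.e. coexisting
ammonia oxidizers boost comammox nitrification. The negative `delta_AB`
shows AOA and AOB together fall short of the sum of their individual
potentials. The classifier recovers the planted metabolic classes of the
150 simulated ASVs.

A thin command-line front end over the same functions ships in
`inst/scripts/nitrisip`:

```sh
inst/scripts/nitrisip all --preset WI2 --seed 42 --out out_dir
```

## Package layout

- `R/` — simulators (`simulate_gradient`, `simulate_slurry*`,
  `simulate_asv_counts`, `make_scenario`), SIP quantification
  (`quantify_labeling` and friends), potential partitioning
  (`fit_rate`, `nitrification_potential`, `partition_contributions`,
  `interaction_report`), enrichment classification
  (`differential_enrichment`, `classify_metabolism`, `classify_table`),
  statistics (`one_way_anova`, `duncan_mrt`,
  `studentized_range_quantile`, `two_sample_t`) and the pipeline driver
  (`pipeline_config`, `run_pipeline`, `validate_inputs`).
- `vignettes/nitrification-partitioning.Rmd` — the methods vignette:
  models, assumptions, parameter choices and limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
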