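# restocc

Hierarchical Bayesian occupancy and group-size models for evaluating
habitat restoration from retrospective, stratified bird surveys.

## Who this is for

Ecologists and biostatisticians who need to quantify the demographic
effect of restoration works on a territorial, group-living species when
the "design" is opportunistic: an extensive historical survey, a
stratified resurvey years later, one count per site per era, and a
small repeated-count panel to calibrate detectability. The package was
built around monitoring of a cooperatively breeding woodland bird whose
family-group size is the performance metric (group size drives breeding
success), but the model is generic for count data of social groups.

## The model

For site *i* in year *k*:

```
Z_ik ~ Bernoulli(psi_ik)                    occupancy
N_ik ~ ZTPois(lambda_ik)   given Z_ik = 1   group size (>= 1)
A_ik ~ Bernoulli(p * Z_ik)                  group availability
Y_ik ~ Binomial(N_ik, d * A_ik)             counted birds
```

Occupancy is logit-linear in scaled distance-to-nearest-group, scaled
large-tree density and a restoration flag; group size is log-linear
with a site random effect, a 1995–2008 time effect (`beta3`) and its
restoration interaction (`beta4`) — the quantity of interest. Strata
encode detection history (detected in the first survey / detected later
/ surveyed only in the final two years) and enter the likelihood as
known-occupancy constraints. `p` and `d` are identified by a 29-site,
4-visit within-season panel. Inference is by an adaptive
Metropolis-within-Gibbs sampler (Rcpp) over the exactly marginalized
likelihood; convergence by split-chain Gelman–Rubin PSRF; model
comparison by posterior mean conditional deviance.

See the methods vignette
(`vignettes/restoration-occupancy-model.Rmd`) for assumptions,
identifiability caveats and design decisions.

## Worked example

```r
library(restocc)

params <- true_parameters()          # the study-like generating values
sim <- simulate_dataset(params, paper_like_config(seed = 1))
det <- simulate_detection_study(params, generator_config(seed = 2))
dataset <- sim$dataset
dataset$detection <- det$detection

fits <- fit(dataset, "M2",
            mcmc_config(n_chains = 2, n_burnin = 1000, n_samples = 5000,
                        seed = 3))
scenario_predictions(fits)
```

Output (posterior medians and 95% credible intervals):

```
            scenario median lower95 upper95
1              Y1995  4.465  3.8444   5.125
2   Y2008_unrestored  4.257  3.7175   4.870
3     Y2008_restored  5.069  4.2953   5.943
4  change_unrestored -0.212 -0.9484   0.566
5 restoration_effect  0.808 -0.0824   1.786
```

Read: at an average site, groups held about 4.5 birds in 1995; by 2008
unrestored sites drifted slightly down while restored sites averaged
5.1 birds, so restoration accounts for about +0.8 birds per group
(interval just crossing zero at this chain length). The generating
truth here was `alpha = 1.5` (4.48 birds), `beta3 = -0.15`,
`beta4 = 0.20`; `summarize(fits)` shows each recovered within its
interval, e.g. `alpha 1.496 (1.347, 1.634)`, `p 0.727 (0.651, 0.796)`
against a true availability of 0.8.

`groupsize_effect_table(fits)` re-expresses coefficients as percent
changes (here `beta4` ~ +19% larger groups with restoration);
`occupancy_effect_table(fits)` gives odds ratios;
`covariate_balance(dataset)` runs the restored-vs-unrestored tree
density check; `compare_models(dataset, c("M1", "M2"), ...)` ranks
variants by posterior deviance.

## Command line

```sh
Rscript -e 'restocc::restocc_cli()' simulate --seed 7 --out sim_out
Rscript -e 'restocc::restocc_cli()' fit --study sim_out/study.csv \
    --detection sim_out/detection.csv --chains 3 --samples 10000 --out fit_out
Rscript -e 'restocc::restocc_cli()' report --draws fit_out/draws.csv --out rep_out
Rscript -e 'restocc::restocc_cli()' recover --replicates 20 --seed 1 --out rec_out
```

Every artifact directory carries a JSON manifest (command, seed,
package version, dataset fingerprint) from which the run can be
reproduced.

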