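# isofactor

Bayesian supervised factor analysis for protein isoform quantification
from bottom-up mass-spectrometry data.

## The problem

A single gene can encode several protein isoforms through alternative
splicing. Shotgun proteomics measures peptides, not proteins, and many
peptides are *shared*: their sequence maps onto two or more isoforms, so
their measured abundance cannot be attributed to any single isoform.
Standard practice collapses isoforms into protein groups or rolls peptides
up with an average, sum or maximum, losing isoform resolution. When
transcript expression has been measured on the same tissue, it carries
complementary information: transcript levels are roughly proportional to
the abundances of the isoforms they encode.

`isofactor` treats isoform abundances as latent factors in a two-layer
model and estimates them jointly from both data types:

```
I = I0 + T W + A D' + E_I        (latent layer, E_I ~ N(0, 1))
P = I Z + E_P                    (peptide layer, E_P,k ~ N(0, sigma2_k))
```

where `T` (n × q) is transcript expression, `P` (n × r) peptide
abundances, `A` a binary condition (e.g. diagnosis), `W` a diagonal matrix
of transcript-to-isoform conversion weights with prior `N(1, tau_w)`, `D`
the condition effects with prior `N(0, tau_d)` (optionally
spike-and-slab), and `Z` a q × r detectability matrix, zero wherever the
input compatibility mask says a peptide cannot derive from an isoform, and
truncated-normal on the support with data-driven bounds that tie the
latent scale to the observed peptide level. All full conditionals are
conjugate, so the posterior is sampled by Gibbs sampling (default: 10
chains × 3000 iterations, 2000 burn-in). Differential abundance of
isoform *j* is summarized by the local false sign rate

```
LFSR_j = min{ P(D_j >= 0 | data), P(D_j <= 0 | data) }
```

with detection at `LFSR <= 0.05`. Transcripts and condition are optional:
the model runs from peptides and a mask alone.

The package also provides the surrounding workflow: peptide/transcript
normalization (total-intensity scaling, log2, OLS batch removal; log2
CPM), rolling up isoforms with identical peptide support into groups,
decomposing the compatibility mask into independent blocks (sampled
independently and reproducibly), simulation generators with t-test
baselines for benchmarking, and post-hoc transcript–isoform correlation
analysis with exact null tail probabilities.

## Worked example

```r
library(isofactor)

# a benchmark dataset: one isoform, two peptides, condition effect D = 1
sim <- simulate_easy(n = 500, effect = 1, seed = 7)
fit <- isofactor(sim$data, chains = 1, iter = 3000, burnin = 2000, seed = 7)
fit
#> Bayesian isoform factor model fit
#>   500 samples, 1 isoforms, 2 peptides, 1 blocks
#>   1 chain(s) x 3000 iterations (2000 burn-in), normal prior
#>   1 isoform(s) detected at LFSR <= 0.05 (>= 1 of 1 chains)

fit$differential
#>   isoform_id post_mean_D post_sd_D lfsr pip detected detection_count
#> 1       iso1    1.163334 0.1098327    0  NA     TRUE               1

evaluate_recovery(sim, fit)$abs_corr_I
#> [1] 0.938781
```

The condition effect is recovered near its true value 1 (its scale is
identified only up to the dataset's mean detectability, which averages 1
over replicates), its sign is certain (LFSR 0), and the posterior-mean
latent abundances correlate strongly with the simulated truth. For
comparison, `ttest_baseline(sim$data$P, sim$data$A, sim$data$mask,
"average")` gives the conventional rollup p-value.

A thin command-line wrapper over the same functions is installed at
`inst/cli/isofactor-cli.R` (subcommands `simulate`, `run`, `benchmark`,
`config-init`).

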