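# blockrar

Familywise error rate control for block response-adaptive randomized
trials with a fixed control allocation.

## The problem

Response-adaptive randomization (RAR) lets a multi-arm trial shift new
patients toward treatments that are performing well. The cost is
inferential: the usual z-test treats the realized sample sizes
$\tilde n_k$ as fixed, and allocation rules that depend on observed
responses can freeze favourable noise into an arm's estimate, inflating
the type I error rate — unacceptably so for confirmatory trials.

`blockrar` implements a variance-matched reweighting of the z-statistic
for trials where experimental patients are allocated in blocks by RAR
while the control schedule stays fixed. The realized trial is compared
with a pre-specified *auxiliary design* (a uniform randomization list
under which the z-test would be valid). With auxiliary counts $n_{j,k}$,
tail sums $m_{j,k} = n_{j,k} + \dots + n_{B,k}$, realized counts
$\tilde n_{j,k}$, and weights defined by $w_0 = n_k$,

$$
w_j = w_{j-1}\sqrt{\frac{\tilde n_{j,k}+m_{j+1,k}}{n_{j,k}+m_{j+1,k}}}
\quad (j < B), \qquad
w_B = w_{B-1}\sqrt{\tilde n_{B,k}/n_{B,k}},
$$

each block enters through $v_j = \tilde n_{j,k}/w_j$ and the adjusted
statistic is

$$
\tilde T_k = \frac{\sum_{j} v_j \bar X_k(\tilde n_{j,k})
  - (\sum_j v_j)\,\bar X_0(n_0)}
  {\sigma \sqrt{1/n_k + (\sum_j v_j)^2/n_0}} .
$$

The weights are strictly positive by construction, $\tilde T_k$ is
standard normal under $H_k:\mu_k=\mu_0$ (known $\sigma^2$), and it
reduces *exactly* to the standard z-statistic when nothing was adapted.
Familywise control over the $K$ arms comes from closed testing — a
pooled "closed z-test" or Bonferroni–Holm on the per-arm statistics —
and a Bonferroni $\alpha$-spending monitor supports pre-specified
interim looks. The package also ships the allocation schemes used to
study these methods (Bayesian adaptive randomization, an adversarial
error-inflator rule, fixed randomization), a per-patient trial
simulator, and a vectorized Monte-Carlo engine for operating
characteristics. See `vignettes/blockrar-methods.Rmd` for the full
methodology.

## Worked example

Simulate one trial of the default design (two experimental arms, burn-in
of 5 per arm, three adaptive blocks of 40 experimental + 20 control
patients) under Bayesian adaptive randomization, with a real effect on
arm 2 only, and analyze it against its auxiliary design:

```r
library(blockrar)

design <- trial_design(K = 2)
trial  <- simulate_trial(design, mu = c(0, 0.5), scheme = "bar", seed = 42)
analyze_trial(trial$data, design, trial$aux)
#> Block-RAR trial analysis (one-sided alpha = 0.05 )
#>
#> # A tibble: 4 × 7
#>   method     arm statistic p.value  v_sum n_realized n_aux
#>   <chr>    <int>     <dbl>   <dbl>  <dbl>      <int> <int>
#> 1 adjusted     1     0.383 0.351    1.07          65    57
#> 2 adjusted     2     2.87  0.00205  0.943         65    73
#> 3 naive        1     0.360 0.359   NA             65    NA
#> 4 naive        2     2.86  0.00214 NA             65    NA
#>
#> Closed-test decisions:
#> # A tibble: 4 × 3
#>   method         H1    H2
#>   <chr>          <lgl> <lgl>
#> 1 new_closed_z   FALSE TRUE
#> 2 naive_closed_z FALSE TRUE
#> 3 new_holm       FALSE TRUE
#> 4 naive_holm     FALSE TRUE
```

BAR gave arm 2 more patients than its auxiliary plan (73 planned vs the
realized split shown per block in `tidy(fit)`); the adjusted statistic
reweights each block so its null distribution stays N(0,1), here
rejecting H2 and retaining H1 under every procedure. Operating
characteristics over many simulated trials:

```r
operating_characteristics(design, mu = c(0, 0.5), scheme = "bar",
                          n_reps = 20000, seed = 1)
#> Operating characteristics (bar scheme, mu = 0, 0.5, alpha = 0.05)
#> # A tibble: 4 × 6
#>   method         error error_se power power_se n_reps
#>   <chr>          <dbl>    <dbl> <dbl>    <dbl>  <dbl>
#> 1 new_closed_z    5.06    0.155  62.4    0.343  20000
#> 2 naive_closed_z  4.96    0.153  62.4    0.343  20000
#> 3 new_holm        4.99    0.154  84.0    0.259  20000
#> 4 naive_holm      4.89    0.152  83.8    0.260  20000
```

`error` is the familywise error rate (% of replicates rejecting the true
null H1) and `power` the disjunctive power (% rejecting the false null
H2), each with its Monte-Carlo standard error. Under BAR the adjusted
and naive methods agree — the guarantee costs nothing here; under
`scheme = "inflator"` the naive tests inflate the FWER while the
adjusted ones hold their level. `autoplot()` methods visualise weight
traces and operating characteristics, and a thin command-line interface
(`inst/cli/blockrar.R`, subcommands `simulate` / `analyze` /
`case-study`) drives the same functions from a shell with YAML design
configs (`inst/extdata/example_design.yaml`).

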