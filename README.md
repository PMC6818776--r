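# dyadseq

Lag-sequential analysis of micro-coded dyadic interaction.

Observational researchers who code an interaction in short fixed
intervals — e.g. a mother–child reunion after a stress task, scored
every 2 seconds for seven binary behaviour categories (`M+`, `M-`,
`C+`, `C-`, `MAlone`, `CAlone`, `Together`) — need two kinds of per-dyad
measures: how *often* each behaviour occurs, and how *likely* one
behaviour is to follow another from one interval to the next. `dyadseq`
implements the second with a chance-corrected statistic and wraps both
in a full sample-level pipeline: aggregation and testing across dyads,
correlation with dyad-level covariates (trust, avoidance, anxiety),
inter-rater reliability, outlier screening, network visualisation, and
a seeded synthetic-dyad generator for validation.

## The statistic

For an ordered behaviour pair, count over the T−1 lag-1 interval pairs
(t, t+1): n11 (first at t, second at t+1), n10 (first without second),
n01 (second without first), n00 (neither). Then

    Jac_obs  = n11 / (n11 + n10 + n01)
    Jac_exp  = p1 p2 / (1 − (1 − p1)(1 − p2))
    Jac_norm = (Jac_obs − Jac_exp) / (1 − Jac_exp)

with p1, p2 the two behaviours' rates over the lag-aligned windows.
Like kappa, `Jac_norm` is 0 when the sequence occurs no more often than
chance and 1 when the second behaviour always and only follows the
first; it is undefined (NA) when either behaviour never occurs in its
window. Auto-loops (first = second) measure behavioural persistence.

## Worked example

```r
library(dyadseq)

cfg <- generator_config(n_dyads = 54, T = 90, seed = 2026)
fit <- dyadseq(generate_sample(cfg))
fit
#> Lag-sequential dyad analysis
#>   dyads analysed: 53 (1 screened out)
#>   frequency convention for chance correction: lagged
#>   sequences above chance at alpha = 0.05 : 11 of 49
#>   covariate correlations computed for: trust, avoidance, anxiety
```

One simulated dyad happened to have an extreme trust score and was set
aside by the leave-one-out outlier screen (|z| ≥ 3), exactly as a real
low-trust dyad would be. The strongest sequences, by upper-tailed
one-sample t-test of the mean likelihood against 0:

```r
su <- fit$summary$sequences
head(su[order(su$p_value),
        c("first", "second", "dyads", "n_defined", "prop_gt0",
          "mean", "sd", "p_value")], 6)
#>  first second dyads n_defined prop_gt0 mean    sd p_value
#> CAlone CAlone    53        53     1.00 0.42 0.131 9.7e-30
#> MAlone MAlone    50        53     0.94 0.29 0.154 2.3e-19
#>     C+     C+    53        53     0.89 0.15 0.111 3.5e-14
#>     M+     M+    53        53     0.91 0.12 0.104 5.0e-12
#>     M+     C+    53        53     0.91 0.10 0.095 2.1e-10
#>     C+     M+    53        53     0.89 0.11 0.109 2.1e-10
```

Read: the task-occupation auto-loops persist strongly (a dyad working
solo tends to stay solo from one 2-s interval to the next), and the
positive mother–child loop (`M+ -> C+`, `C+ -> M+`) runs above chance
in ~90% of dyads with mean likelihoods around 0.10 — `dyads` counts
dyads in which the sequence is observed at all, `n_defined` those with
a defined statistic, and `prop_gt0`, `mean`, `sd` are computed over
defined values only.

```r
coef(fit)["C+", "M+"]        # mean sequencing likelihood C+ -> M+
#> [1] 0.114
plot(fit)                                       # sample network
plot(fit, "correlation", covariate = "avoidance")  # covariate network
```

`run_analysis()` writes the whole bundle (per-dyad profiles, summary
tables, the covariate correlation grid, DOT/GraphML networks, run log)
to a directory; a thin command-line wrapper ships at
`inst/cli/dyadseq.R` with `analyze`, `simulate`, `compare-dyad` and
`network` subcommands.

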