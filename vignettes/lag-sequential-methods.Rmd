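---
title: "Chance-corrected lag-sequential analysis of micro-coded dyadic interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance-corrected lag-sequential analysis of micro-coded dyadic interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadseq)
```

## The measurement problem

Micro-coding an interaction means registering, for every short fixed
interval (here 2 s), whether each of a set of behaviour categories is
present. For a mother–child dyad coded with the MCAM scheme this yields
seven parallel binary time series per dyad — positive and negative
mother and child behaviour (`M+`, `M-`, `C+`, `C-`) and three
task-occupation codes (`MAlone`, `CAlone`, `Together`) — typically about
90 intervals for a three-minute reunion episode. Several categories may
co-occur in one interval.

Two families of per-dyad measures summarise such data:

* **relative frequency** of a category: the proportion of intervals in
  which it is present;
* **sequencing likelihood** of an ordered pair: the chance-corrected
  tendency of the first behaviour at interval $t$ to be followed by the
  second at $t+1$ (auto-loops, first = second, measure behavioural
  persistence).

## The normalized Jaccard sequencing index

For an ordered pair, count over the $T-1$ lag-1 interval pairs
$(t, t+1)$:

* $n_{11}$ — first present at $t$, second present at $t+1$;
* $n_{10}$ — first present at $t$, second absent at $t+1$;
* $n_{01}$ — second present at $t+1$, first absent at $t$;
* $n_{00}$ — neither.

The observed Jaccard index is
$\mathrm{Jac}_{obs} = n_{11} / (n_{11} + n_{10} + n_{01})$. Its expected
value if the two streams were sequenced purely by chance at rates $p_1$
(first behaviour) and $p_2$ (second behaviour) is
$$\mathrm{Jac}_{exp} = \frac{p_1 p_2}{1 - (1 - p_1)(1 - p_2)},$$
and the chance-corrected index is
$$\mathrm{Jac}_{norm} = \frac{\mathrm{Jac}_{obs} - \mathrm{Jac}_{exp}}
{1 - \mathrm{Jac}_{exp}}.$$

Like Cohen's kappa, $\mathrm{Jac}_{norm} = 0$ means the sequence occurs
no more often than expected by chance and $1$ means the second
behaviour always and only follows the first. The index is bounded above
by 1; its lower bound, $-\mathrm{Jac}_{exp}/(1-\mathrm{Jac}_{exp})$, is
attained when $n_{11} = 0$.

```{r}
s <- behavior_series("demo", cbind(a = c(1, 0, 1, 0, 1),
                                   b = c(0, 1, 0, 1, 0)))
jaccard_normalized(s, "a", "b")
```

### The frequency-window convention

The definition of $p_1$ and $p_2$ leaves a genuine choice: frequencies
over the full series, or over the windows that actually generate the
lag-1 pairs ($1..T-1$ for the first behaviour, $2..T$ for the second)?
We adopt the lag-aligned windows as the default (`p_window = "lagged"`)
because then observed and expected counts range over an identical set
of $T-1$ pairs; in particular a first behaviour that is always present
gives $\mathrm{Jac}_{norm} = 0$ exactly against any second stream,
which is the behaviour the null anchor demands. Full-series frequencies
remain available (`p_window = "full"`) for sensitivity analysis; the
two conventions differ by at most the weight of one interval and
converge as $T$ grows. Relative frequencies reported in the summary
tables always use all $T$ intervals: frequency is a property of the
whole interaction, not of a lag window.

### Undefined values

The statistic is reported as missing — never as 0, and never as an
error — whenever it is not estimable: when either behaviour never
occurs in its window (a sequencing tendency of an absent behaviour is
unobservable) or when both behaviours are always present
($\mathrm{Jac}_{exp} = 1$). Undefined values are excluded from all
across-dyad aggregation, and every summary reports how many dyads had a
defined value. This matters for rare behaviours: with a base rate of
0.02 over 90 intervals, many dyads never show the behaviour at all.

## Sample-level inference

Per ordered pair, the across-dyad summary reports: the number of dyads
in which the sequence is observed at all ($n_{11} > 0$), the number
with a defined index, the proportion of those exceeding chance
(strictly positive index), mean, SD and range over defined values, and
an upper-tailed one-sample t-test of the mean index against 0. The
upper tail is used because the confirmatory question is whether a
sequence occurs *more* often than chance. Using defined-value
denominators is not optional: with all-dyad denominators the
"proportion above chance" of a rare sequence could exceed the number of
dyads able to show it.

Dyad-level covariates (trust on a 1–4 scale, avoidance and anxiety on
1–7) are related to the measures by Spearman rank correlation, which is
robust to the skewed, bounded distributions such scores have. Because
avoidance and anxiety typically correlate substantially, first-order
partial correlations (avoidance controlling anxiety, and vice versa)
are computed by rank-transforming all three variables with average
ranks and applying the partial-correlation identity
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$
on the ranks; p-values use the t approximation with $n-3$ degrees of
freedom. No multiplicity correction is applied by default — the
correlation grid is descriptive — but Benjamini–Hochberg adjustment is
available (`adjust = "BH"`).

Before sample-level stages, `flag_outliers()` screens the covariate
distribution with leave-one-out z-scores (default threshold $|z| \ge
3$): a single extreme dyad would otherwise dominate the rank
correlations. Screened-out dyads are not discarded — `compare_dyad()`
z-scores their full profile against the retained sample, which is the
appropriate lens for a clinically interesting outlier.

### Reliability

Inter-rater agreement on the raw codes is pooled Cohen's kappa: all
interval × category binary decisions of the two raters form one 2×2
agreement table, and kappa corrects observed agreement for the
agreement implied by the marginal presence rates. The 95% CI uses the
large-sample standard error
$\sqrt{p_o(1-p_o)/(N(1-p_e)^2)}$; a bootstrap CI is available since the
pooled decisions are not strictly independent. Agreement on the derived
measures (frequencies, sequencing likelihoods per dyad) is a
correlation across paired defined values, Pearson by default
(the measures are on a common scale, so linear agreement is the natural
criterion), Spearman switchable.

## The synthetic-dyad generator

Real coded interactions cannot be bundled, so validation rests on a
generator whose mechanism is the minimal one able to produce nonzero
$\mathrm{Jac}_{norm}$: first-order cross-lag coupling. A coupling
$(f, s, q_1, q_0)$ makes stream $s$ at $t+1$ Bernoulli($q_1$) when $f$
was present at $t$ and Bernoulli($q_0$) otherwise; uncoupled categories
are independent Bernoulli draws at their base rate, interval 1 is drawn
from the base rates, and multiple couplings onto one target combine by
noisy-OR (which keeps probabilities valid without renormalisation).

The defaults describe the study conditions the package is meant for:
54 dyads × 90 intervals; base rates matching the typical relative
frequencies of the seven MCAM categories (0.45, 0.02, 0.39, 0.05,
0.13, 0.47, 0.04 for `M+`, `M-`, `C+`, `C-`, `MAlone`, `CAlone`,
`Together`); persistence auto-loops on all frequent categories plus the
positive mother–child loop (`M+` ↔ `C+`) and a weak negative loop
(`M-` → `C-`). For auto-loops the default $q_0$ is set to
$p(1-q_1)/(1-p)$ so the stationary rate of the coupled stream stays at
its base rate $p$; $q_1$ values were chosen once to give
chance-corrected sequencing strengths of roughly the magnitude seen in
real middle-childhood interaction data (≈0.1–0.5, strongest for the
task-occupation auto-loops).

Dyads differ genuinely in sequencing strength: each dyad's $q_1$ values
are jittered by Gaussian deviations (sd `coupling_sd`, default 0.08,
clipped to $[0,1]$). Covariates are built from these realized
deviations: the weighted sum named in `covariate_link` is standardized
by its theoretical sd and mixed with independent Gaussian noise so that
it carries a `link_strength` share (default 0.6) of the covariate's
variance, then scaled to the instrument moments (trust 3.51 ± 0.32,
avoidance 2.44 ± 0.84, anxiety 2.11 ± 0.79 — typical questionnaire
spreads for this population, emulation targets rather than claims) and
truncated to the instrument range. The default links make trust
negatively, and avoidance/anxiety positively, related to the
negative-loop strength.

All randomness derives from one integer seed; each dyad uses a
deterministic substream keyed by (seed, dyad index), so a single dyad
can be regenerated without the rest and identical configurations yield
bit-identical samples.

**What the generator does not emulate.** Real coded interactions have
structural zeros (e.g. `MAlone` and `Together` rarely co-occur),
non-stationarity across the reunion episode, coder autocorrelation
beyond lag 1, and subcategory-level dynamics. Passing tests on
synthetic samples therefore demonstrate the *statistical machinery* —
estimator calibration, parameter recovery, table semantics — not the
substantive validity of any coding scheme.

## Numerical and design choices

* **Problem sizes.** Validation uses 1,000 independent dyads at
  $T = 90$ for null calibration, 200 dyads per coupling-gap level for
  parameter recovery, and 500 dyads for covariate-link sign checks —
  sizes at which Monte-Carlo error is small relative to the effects
  being verified while a full run stays comfortably interactive.
* **Outlier screening** uses leave-one-out moments: with a genuinely
  extreme value in the sample, full-sample moments understate its
  z-score. On reference moments mean 3.51, sd 0.32, a trust score of
  1.5 sits at $z \approx -6.3$ either way.
* **Network edge selection.** The per-pair summary p-value is
  upper-tailed, but below-chance sequencing (e.g. rare switches between
  the two partners' solo task work) is exactly what dashed edges are
  for; the sample network therefore folds the upper-tail p into a
  two-sided p ($2\min(p, 1-p)$) by default, with `tail = "upper"`
  available. Node sizes are linear in the mean frequency with a
  configurable floor (default 0.05) so that zero-frequency categories
  remain legible; auto-loop widths are downscaled by a factor (default
  0.5) so cross-node edges stay readable. Any monotone linear mapping
  satisfies the depiction rules; the constants are configurable.
* **Ties** in rank correlations use average ranks throughout.
* **Missing intervals are an error**, not imputed: interval indices
  must run $1..T$ per dyad. Silent imputation would bias the lag
  counts. All-zero intervals, by contrast, are legal and must be
  explicit rows (or cells) in the input.
* **No smoothing or continuity correction** is applied to the
  contingency counts; the index is defined on raw counts.

## Worked pipeline

```{r}
cfg <- generator_config(n_dyads = 20, T = 90, seed = 42)
fit <- dyadseq(generate_sample(cfg))
fit
round(coef(fit)[c("M+", "C+"), c("M+", "C+")], 2)
```

`summary(fit)` prints the full frequency and sequence tables;
`plot(fit)` draws the sample network and
`plot(fit, "correlation", covariate = "avoidance")` a covariate
network; `run_analysis()` writes the complete bundle (profiles,
summary tables, correlation grid, DOT/GraphML networks, and a run log
recording every convention in force) to a directory.

## Limitations

* The index is symmetric in information but not in interpretation:
  $\mathrm{Jac}_{norm}(a \to b)$ conflates "b follows a" with "b is
  common right after the window in which a is common"; it is a
  descriptive association measure, not a causal transition model.
* Inference treats dyads as independent replicates; dyadic
  interdependence models (actor–partner) and permutation nulls are out
  of scope.
* With rare behaviours and short series, many dyads have undefined
  indices; the defined-only denominators make this visible but cannot
  recover the lost information.
* Lag is fixed at one interval by default. The lag length is a
  parameter of `lag_contingency()`'s callers in the sense that any lag
  can be emulated by thinning the series, but multi-step sequence
  mining is not attempted.
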