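---
title: "Detecting host-factor disparities in spontaneous adverse-event reports"
author: "aedisparity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting host-factor disparities in spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedisparity)
```

## The question and the model

Spontaneous reporting systems such as FAERS collect adverse-event (AE)
reports, each tagged with the suspect drug, a MedDRA Preferred Term, and
patient attributes. Classical signal detection asks whether a drug–AE pair
is reported disproportionally often. This package asks a different question:
for a given AE, does a drug show an unusual *disparity* between two levels
of a host factor (male/female, under-65/at-least-65) relative to the other
drugs reported with that AE? A positive answer points at a drug–host
interaction worth mechanistic follow-up, not merely at a safety signal.

The data for one context are $J$ 2×2 tables. In the drug-stratified
orientation the context is an AE $i$; table $j$ counts reports of $i$ with
drug $j$ ($n^{(1)}_{ij}, n^{(2)}_{ij}$ by group, exposed cells `a1`, `a2`)
against reports of $i$ with any other drug (`b1`, `b2`). The group margins
$M_1 = n^{(1)}_{i\cdot}$, $M_2 = n^{(2)}_{i\cdot}$ are shared by the whole
family. In the AE-stratified orientation the roles of drug and AE swap.
Modelling the cell counts as Poisson and conditioning on margins gives the
working null for every table:

$$ n^{(1)}_{ij} \mid n_{ij}, M_1, M_2 \;\sim\;
   \mathrm{Binomial}\!\left(n_{ij},\, p\right), \qquad p = M_1/(M_1+M_2). $$

Because the reporting base (prescription counts per group) is unobserved,
$p$ plays the role of the background disparity shared by all drugs of the
family; the tests ask whether a drug departs from that background, not from
a 50/50 split. Consequently the drug-stratified tests inherit any
prescription-pattern imbalance of the whole family — the package tests
relative disparity within a family, which is why applications should group
drugs with comparable prescription patterns (e.g. one therapeutic class).

## The four tests

* **Likelihood ratio** (`lr_statistic`):
  $LR_{ij} = -n\log(n/N) + a_1\log(a_1/M_1) + a_2\log(a_2/M_2)$ with
  $N = M_1+M_2$, natural logs, and $0\log 0 \equiv 0$. Its null
  distribution is discrete and is approximated by Monte Carlo
  (`sample_null`).
* **Normal approximation** (`z_statistic`):
  $z = \sqrt{n}\,(a_1/n - p)/\sqrt{p(1-p)}$, the binomial z score. Signed,
  so the direction of the disparity is preserved; two-sided p-values use
  $|z|$.
* **PRR / ROR** (`prr_statistic`, `ror_statistic`): the proportional
  reporting ratio and reporting odds ratio recast as between-group
  disparity measures, with delta-method normal approximations for their
  logs. The z score is $\sqrt{n}(\log\mathrm{ratio} - c)/\sigma$ with
  centering $c$ and variance $\sigma^2$ that depend only on the margins.

### The PRR/ROR formula variants

Two algebraic presentations of the delta-method centering and variance
circulate. For the PRR centering the denominator can be written as
$N - M_1$ or as $N - n$; only the latter equals the value obtained by
plugging the null expectation $a_1 \approx np$ into the PRR, and the former
adds a constant bias $\log\{(N-n)/(N-M_1)\}$ to every log-PRR — on the
acetaminophen analgesic table that bias alone is worth $|z| \approx 13$
versus $|z| \approx 11.5$ for the plain binomial z, and under the null it
drives the rejection rate toward 1. Likewise the ROR variance's second term
can be written with the observed $a_1/n$ or with the margin analogue
$M_2/n - (1-p)$; the observed form has a near-zero denominator whenever the
groups are close to balanced, which collapses the z score toward 0.
Neither pathology is compatible with the moderate (2–7×) family-wise error
inflation that PRR/ROR-type disparity tests actually exhibit, so this
package defaults to the *consistent* forms and keeps the other variant
available as `variant = "printed"` for sensitivity analysis. The consistent
ROR form is also what makes the z score exactly antisymmetric under
swapping the two group labels.

## Monte-Carlo conventions

* Null draws are `Binomial(n_j, p)` per table, independent across tables
  and replicates; the per-replicate maximum over the family gives the null
  of the maximal statistic (MLR). The sum constraint on $M_1$ is ignored,
  matching the per-table conditional model.
* Each table uses a private random substream seeded from the master seed
  and a hash of the unit id, so null samples do not depend on the order in
  which tables appear.
* `mc_p_value` is the *inclusive* upper tail, $\#\{LR^\ast \ge lr\}/m$.
  The simulated LR distribution is discrete; counting ties out of the tail
  visibly inflates the FDR of downstream Benjamini–Hochberg adjustment.
  An observed statistic above every draw gets p = 0 (stored as 0, printed
  as `< 1/m`); no +1 continuity correction is applied.
* `mlr_quantile` returns the $\lceil (1-\alpha) m\rceil$-th order statistic
  of the MLR draws. This convention makes the step-down rule
  “reject where $LR_j >$ quantile” *exactly* equivalent to “Monte-Carlo
  adjusted p $\le \alpha$”, which the test suite asserts.
* The default $m = 10^5$ puts the relative Monte-Carlo error of a p-value
  near 0.005 at about 4%; the simulation harness uses smaller per-family
  nulls (default $m = 5000$) because only the $1-\alpha$ quantile and
  moderate tail probabilities are consumed there.

## Multiplicity

Family-wise control uses the max-statistic step-down rule. For the LRT the
critical value is the empirical $(1-\alpha)$ MLR quantile; for the z-based
tests it is $\Phi^{-1}\{(1-\alpha/2)^{1/J}\}$, the standard approximation
to the $(1-\alpha)$ quantile of the maximum of $J$ independent $|N(0,1)|$
variables (the exact quantile is available via `exact = TRUE`; the two
agree to about three decimals even at $J$ of several hundred). Adjusted
p-values for the z-based tests use the independence transform
$1-(1-p)^J$, computed through `expm1`/`log1p` so that tiny p-values do not
underflow to an adjusted 0. FDR control uses Benjamini–Hochberg via
`stats::p.adjust`; for the LRT its raw p-values come from the per-table
Monte-Carlo nulls.

## Preprocessing rules

`preprocess_reports` counts only primary-suspect drug records and removes
records with a missing host-factor value, logging how many records each
rule removed. Upstream, `read_ae_reports` case-folds and
whitespace-normalizes drug names and event terms, maps any value outside
the two declared group labels to missing, and removes exact duplicate
(report, drug, term) triples — a deliberately transparent simplification of
full case de-duplication, which in production FAERS work involves
demographic matching across versions of the same case and is out of scope
here. Composite events (e.g. a liver-toxicity event defined as a
user-supplied list of Preferred Terms) are applied before tabulation, and a
report contributing several member terms for the same drug counts once.
When the host factor is age, the numeric age is cut at a configurable
threshold (default 65) with the boundary age assigned to the older group.

Table-level filters: tables with any cell below 5 are dropped (the
asymptotic approximations and the subgroup ratios are unreliable below
that); families with 5 or fewer remaining tables are dropped ("more than 5
associated drugs" read strictly); and, when preparing simulation bases
only, families containing a table whose exposed total exceeds a group
margin are excluded, because binomial resampling could then overrun the
margin. Filtering happens after the primary-suspect restriction; the
removal log records both steps.

## The simulation harness

`run_simulation` estimates empirical FWER, FDR and sensitivity for every
method × adjustment. Families are grouped into small/moderate/large strata
by their AE totals; cutpoints default to the base's own 25%/50% quantiles,
with the reference values 674/1337 available as a fixed override. Under the
alternative, $\mathrm{round}(J/5)$ tables per family (halves away from
zero, so $J=12 \to 2$, $J=13 \to 3$) are redrawn with the shifted
proportion $p' = p + \Delta$ if $p \le 0.5$, $p - \Delta$ otherwise; a
shifted value outside $(0,1)$ is clipped to $[0.001, 0.999]$ with a
warning (the clip never triggers for realistic $p$). The alternative
subset is selected once per family per call, mirroring a design in which a
block of iterations is allocated to each AE; re-selecting each iteration
would leave all three estimators unchanged in distribution. The estimators
are: FWER = share of all-null runs with any rejection; FDR = mean of
false/total rejections with $0/0 \equiv 0$; sensitivity = mean share of
true alternatives rejected. A reference design allocates 250 AEs per
stratum × 2000 iterations (500,000 runs per stratum); whether such a
budget is read per stratum or overall is a parameterization choice here
(`aes_per_stratum`, `iterations_per_ae`), not a fixed constant.

### The synthetic base generator

`generate_synthetic_base` stands in for marginals extracted from a real
database. Per synthetic AE it draws a total count from a log-normal whose
25%/50% quantiles sit at 674/1337 (meanlog $= \log 1337$, sdlog chosen so
the lower quartile lands at 674), a group-1 share from Beta(15, 17)
(mean 0.469, close to the male share among sex-known FAERS reports, sd
≈ 0.09), a drug count $6 + \mathrm{Poisson}(6)$, and per-drug exposed
totals proportional to normalized exponential weights of half the AE total,
floored at 15 so that the min-cell filter retains most tables. Groups are
split binomially at the drawn share, and only families passing all filters
are emitted. The generator reproduces the features the tests rely on —
shared margins, realistic total/drug-count spread, stratum structure,
binomial group splits — and deliberately not others: no duplicated or
incomplete reports, no drug-name noise, no correlation between AEs of one
report, no prescription-pattern confounding between drugs. Passing
simulations therefore validate the inferential machinery under the stated
conditional model, not robustness to the full messiness of raw FAERS
extracts.

### Problem sizes

The package's own checks run the harness at desk scale — tens of families
per stratum and 100–200 iterations each with per-family nulls of a few
thousand draws — which is ample to verify calibration (Monte-Carlo
standard errors on a FWER near 0.05 are then about 0.003) and the
qualitative ordering between methods: LRT and normal-approximation FWER at
or below the nominal 0.05 under the global null, PRR/ROR clearly inflated,
and sensitivity increasing in $\Delta$ for every method. Production
analyses with the 250 × 2000 reference design run in minutes, not hours,
because all per-family work is vectorized over iterations.

## Degenerate inputs and numerical choices

Zero exposed cells give a finite LR ($0\log 0 \equiv 0$) but are refused by
the subgroup ratios, which need all four cells positive; tables reaching
the tests normally have cells ≥ 5 anyway. Zero margins are an error. In
the simulation harness a degenerately extreme simulated z (non-finite from
a zero cell) counts as a rejection — the convention that penalizes, rather
than hides, an unstable statistic. BH ties are resolved by `p.adjust`'s
step-up transform, whose rejection set is tie-order-invariant; Max-Stat
rejection sets are order-invariant by construction. All output files are
plain TSV; full precision is written by default with an optional
presentation mode rounding statistics and p-values to 4 decimals.

## Known limitations

Only two-level host factors are supported (a multi-level LRT extension is
natural but not implemented). The drug-stratified orientation is
confounded by prescription patterns when applied across unrelated drugs;
the AE-stratified orientation can miss a disparity shared across all AEs of
a drug and can flag AEs that are intrinsically group-specific. Empirical p
values of exactly 0 are reported as such rather than bounded away from
zero. Report-level ingestion assumes one row per (report, drug, event);
reconstructing that layout from raw quarterly FAERS tables (joins across
demographics, drug and reaction files, case versioning) is left to the
caller, with only a delimiter switch provided for the `$`-separated ASCII
format.
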