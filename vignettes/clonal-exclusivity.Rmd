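---
title: "Testing clonal exclusivity and co-occurrence on tumour phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing clonal exclusivity and co-occurrence on tumour phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonex)
```

## The problem

Single-cell and multi-region sequencing resolve a tumour into clones related
by a phylogeny. Two mutated genes in the same tumour can sit in a common
clonal lineage (*clonal co-occurrence*: same branch, or ancestor and
descendant) or in incomparable branches so that no clone carries both
(*clonal exclusivity*). Pairs that are exclusive more often than chance
predicts across a patient cohort are candidates for clone–clone cooperation
or synthetic lethality; pairs that co-occur too often suggest within-lineage
synergy. The statistical difficulty is that clone genotypes within one
tumour are not independent observations — they inherit mutations along the
tree — so any test that pools clones as if they were independent (the
"naive" baselines in this package) is confounded by the phylogeny itself.
`clonex` implements a family of likelihood-ratio tests that condition on the
observed trees.

## Data model

A cohort is a tibble with one row per patient, built by `read_cohort()` from
a TSV edge list or by `as_cohort()` from `clonal_tree` objects. For each
patient we derive:

* the background clonal exclusivity rate $r_i$ — the fraction of that
  patient's unordered gene pairs that are clonally exclusive, averaged over
  the patient's (posterior sample of) trees. Linear chain topologies give
  $r_i = 0$, star topologies $r_i = 1$; both are *uninformative* for
  placement testing because a logit shift fixes those endpoints;
* the pair-count weight $w_i = \binom{\#\text{genes}_i}{2}$, used by the
  occurrence test.

For a gene pair $(j, k)$, `collect_pair()` records the carrier set $S$, the
per-patient exclusivity outcome $O_i \in [0, 1]$ (the fraction of the
patient's trees containing both genes in which the pair is exclusive), and
the count columns $n_t = n + n_l + n_s$ (carriers = informative + linear +
star) plus $n_{cx}$ (informative exclusives) and $m = n_{cx} + n_s$.

Clones below a frequency threshold (default 1%) are merged into their parent
at read time; the branch mutations are re-attached to the parent so gene
content is never lost. When a patient contributes several posterior trees we
take the gene set as the union across trees, and $O_i$ counts only trees
containing both genes in its denominator — trees lacking one of the genes
say nothing about the pair's placement. Genes appearing on several branches
of one tree (parallel evolution) are handled by the genotype-based
definition: a pair is exclusive iff no clone's genotype carries both.

## The placement test

Conditioning on the carriers' trees, the null places the pair's exclusivity
outcome as Bernoulli($r_i$) per informative patient. The alternative shifts
every rate by a single score $\Delta$ on the logit scale,
$\operatorname{logit}(r_i') = \operatorname{logit}(r_i) - \Delta$, so that
negative $\Delta$ means exclusivity enrichment. The statistic is
$\mathrm{LLR} = 2(\ell_1 - \ell_0)$ with $\ell_1$ maximised over
$\Delta \in [-10, 10]$; beyond $\pm 10$ the saturating logit no longer moves
the likelihood appreciably, and optima within $10^{-6}$ of a bound are
reported as $\pm\infty$.

Three p-values are available:

* **chi-squared** (`p_placement_chisq()`): the asymptotic
  $\chi^2_1$ upper tail, adequate once the pair is carried by more than
  about a dozen informative patients but anti-conservative below that;
* **exact** (`p_placement_exact()`): enumerates the $2^n$ binary outcome
  patterns with their null probabilities and applies the half-tie (mid-p)
  rule — patterns whose LLR ties the observed one count half. The mid-p rule
  is what makes the exact p-value's null expectation equal to one half
  despite heavy discreteness;
* **Monte-Carlo smoothed** (`p_placement_mc()`): samples outcome vectors
  from the null after perturbing each rate by a
  $\mathrm{Beta}(\nu r, \nu(1-r))$ draw. The noise ($\nu = 10$ by default)
  breaks ties, so the smoothed p-values are continuous; as
  $\nu \to \infty$, $M \to \infty$ the procedure recovers the exact test.

A computational note: because the shifted Bernoulli log-likelihood is linear
in the outcome vector given $\Delta$, the LLR depends on a binary pattern
only through its exclusive count $k = \sum_i b_i$ — the shift is the natural
parameter of a one-parameter exponential family with sufficient statistic
$k$. The exact enumeration therefore collapses onto $k = 0, \dots, n$ with
Poisson-binomial probabilities: $n + 1$ bounded concave maximisations
instead of $2^n$. The test suite verifies, by brute-force enumeration with
an independent optimiser, that this collapse reproduces the pattern-level
p-values exactly, ties included. The optimiser itself is a vectorised
golden-section search; the objective is concave in $\Delta$ (a sum of
log-sigmoids), so the search converges to the global maximum, including
boundary optima, without derivatives or seeds.

The default exact/asymptotic switch is $n \le 12$, kept although the
collapsed enumeration would be cheap at much larger $n$, because the
chi-squared approximation is already accurate there and the discrete exact
null increasingly pointless.

**Alpha budgeting.** A pair carried by few informative patients may be
unable to reach $p \le \alpha$ for *any* outcome. `min_possible_p()`
computes the smallest achievable exact p-value from the carriers' rates;
`run_cohort()` removes such pairs before testing so they do not dilute the
Benjamini–Hochberg correction.

## The occurrence test

The placement test conditions on *which* patients carry the pair, but that
set is itself informative: exclusivity-prone pairs should favour branched
(high-$r$) trees. Under the null the pair lands in a patient set $S$ with
probability proportional to $\prod_{i \in S} w_i$, conditioned on $|S|$ —
the Fisher non-central hypergeometric law. Its normaliser is the elementary
symmetric polynomial $e_{|S|}(w)$, computed by the standard
$O(N\,|S|)$ dynamic programme (`esp()`) on weights rescaled by their maximum
to stay inside double range; the assembly is done in log space. The
alternative tilts each weight by the patient's rate,
$w_i' = 2 w_i[\rho(1-r_i) + (1-\rho) r_i]$ with
$\operatorname{logit}(\rho) = \Delta_o$, and the LLR is maximised over
$\Delta_o$. Enumerating all $\binom{N}{|S|}$ sets for an exact p-value is
prohibitive, so this test uses the $\chi^2_1$ approximation only and is
flagged as such; on weighted-sampling nulls it is conservative at the
significance levels that matter (checked in the test suite).

The null-eligible cohort is all patients with $w \ge 1$ — a patient with
fewer than two genes can never exhibit a pair and has zero selection
probability. `eligible_only = FALSE` conditions on the full cohort instead;
the extra zero-weight patients change nothing, but the switch makes the
conditioning explicit.

## The combined test

Equating the two shifts, $\Delta = \Delta_p = \Delta_o$, the joint
likelihood of "which patients" and "how placed" simplifies: the tilt factor
of each selected patient's weight cancels against the denominator of its
placement term, leaving a function of the data only through $m$, the number
of carriers whose trees show the pair as exclusive *including* star trees
(linear trees count as co-occurring). The reduced objective maximised by
`combined_llr()` is

$$ g(\Delta) = n_t \log 2 + m \log(1-\rho) + (n_t - m)\log\rho
   + \log e_{n_t}(w) - \log e_{n_t}(w'(\rho)), \qquad
   \rho = \operatorname{logistic}(\Delta), $$

with $g(0) = 0$, so $\mathrm{LLR} = 2\max_\Delta g$. The package verifies
this reduction against direct numerical maximisation of the full joint
log-likelihood (independent implementation, agreement to $10^{-8}$).

Because $m$ ranges over $0, \dots, n_t$, an exact p-value is cheap: the null
distribution of $m$ — weighted set sampling, then independent
Bernoulli($r_i$) placements within the set — is computed by a bivariate
dynamic programme over patients tracking (selected, exclusive) counts
(`combined_null_m()`, validated against brute-force set-by-outcome
enumeration), and the same mid-p rule is applied over the $n_t + 1$
outcomes. Fisher's-method combination of the two marginal p-values is
reported alongside (`p_fisher`) for comparison; the shared-$\Delta$ test is
the headline statistic because it rewards *consistent* direction in the two
signals.

## Naive baselines

`clone_table()` pools every carrier's clones into one 2×2 table of genotype
presence and `fisher_p()`, `g_test_p()`, `log_or_z()` run the standard
independence tests (two-sided; log-OR with the Haldane–Anscombe +0.5
correction applied to all cells whenever any cell is zero, chosen as the
textbook default since the correction is not otherwise pinned down; the
G-test uses the plain likelihood-ratio statistic with 1 df, no Williams
correction). Tables with a zero margin return $p = 1$. These tests exist to
quantify the confounding: on tree-generated null data they reject at 5%
roughly half the time (see below).

## What the generator emulates

`synth_cohort()` is the package's fixture factory and defines its study
conditions:

* 40 patients mixing topologies — 55% linear, 5% star, the rest branched
  binary trees of 6 clones — mirroring real single-cell leukaemia cohorts in
  which most trees are linear and star trees are rare;
* 6 background genes per patient drawn from a pool of 24, placed uniformly
  on branches;
* optionally a planted pair with effect $\Delta$ in a chosen number of
  informative host patients: each host's outcome is Bernoulli at its
  background rate shifted by $\Delta$, and the two genes are then placed on
  incomparable branches or a common lineage accordingly. Planting adds the
  two genes *after* the host's rate is drawn, so the realised background
  rate seen by the tests differs slightly — as it would in real data, where
  the tested pair contributes to the background;
* clone frequencies from a flat Dirichlet, floored at the sixth decimal so
  the written TSV frequencies never sum above one.

`random_binary_tree()` draws tree shapes uniformly (Catalan-weighted
recursive splitting) and scatters a fixed number of mutations uniformly with
replacement over branches. Uniformity of the *shape* distribution is not
essential for the downstream null — only the exchangeability of mutations
under uniform placement is — but a uniform scheme is adopted and tested so
the null is unambiguous.

What the generator does **not** emulate: mutation-rate heterogeneity across
genes, recurrent (hot-spot) mutations shared across many patients, copy
number events, tree-inference uncertainty correlated with clone frequency,
and cohort-level gene frequency spectra. Passing calibration and recovery
tests on these cohorts therefore demonstrates correctness of the statistics
under the stated null, not robustness to every feature of real data.

## Calibration and power studies

`run_calibration()` simulates gene pairs under the null with rates from
$\mathrm{Beta}(2, 3)$ (mean 0.4, matching the background-rate spectrum of
real cohorts) and outcomes Bernoulli at those rates. The exact test is
conservative at the 5% level with pronounced discreteness; the chi-squared
variant is anti-conservative for small $n$; the $\nu = 10$ smoothed variant
is close to uniform. `run_power()` shifts the rates before drawing outcomes:
at the 5% level the exact test detects $\Delta = -3$ in 10 carriers with
power above 96%, and $\Delta = -4$ in 4 carriers with power near 75%. (The
5% level is used throughout; on the natural scale, a $\Delta$ of $-4$ moves
a 40% background rate to 97%, and $-3$ to 93%.)

`run_naive_comparison()` generates 400 cohorts of 10 random binary trees
(10 branches, 20 mutations each) and tests a designated pair — a null case
by exchangeability. The clone-pooling baselines reject at the 5% level
roughly half the time; the smoothed placement test stays at the nominal
level, and the chi-squared variant shows the expected slight excess.

Problem sizes used by the automated checks: $10^4$ replicates for
type-I-error and mid-p calibration at $n \in \{4, 8\}$ (and $n = 6$),
$10^3$ replicates per power cell, 400 naive-comparison cohorts, and 200
synthetic cohorts for parameter recovery — sizes at which the binomial
3-standard-error bands in the assertions are a few tenths of a percent wide.

## Numerical choices

* Optimisation bound $\pm 10$ on all shift parameters; boundary optima
  reported as $\pm\infty$ at tolerance $10^{-6}$.
* Golden-section iterations fixed at 62 (bracket below $10^{-11}$), no
  seeds, deterministic; `stats::optimize` (tolerance $10^{-8}$) for the
  occurrence and combined objectives where one optimisation per pair
  suffices.
* LLR ties detected at relative tolerance $10^{-9}$ — enumerated ties are
  exact in real arithmetic, so the tolerance only absorbs float noise.
* LLRs are clamped at zero (the null is nested in the alternative, so
  negative values can only be optimisation noise).
* Fractional posterior outcomes enter the chi-squared variant as-is (the
  log-likelihood is linear in $O_i$); the exact and combined tests binarise
  at $O_i \ge 0.5$, since their nulls are defined on binary patterns.
* Beta draws in the smoother are clamped to $[10^{-12}, 1 - 10^{-12}]$
  before the logit.
* ESP dynamic programmes run on weights divided by their maximum; all
  probability assembly is in log space.

## Known limitations

* The occurrence test has no exact variant; its chi-squared p-values are
  approximate (conservative on the nulls examined) and flagged as such.
* Pairs whose carriers are all uninformative cannot be placement-tested at
  all; they surface only through the occurrence and combined tests.
* Self-pairs and pairs always sharing a branch receive no special casing.
* The package tests pairs only; higher-order gene sets, tree inference
  itself, and copy-number or expression markers are out of scope.
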