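---
title: "Disproportionality and case-series methods for LMWH-associated HIT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality and case-series methods for LMWH-associated HIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitsignal)
```

## The problem

Heparin-induced thrombocytopenia (HIT) is an immune-mediated adverse
reaction in which IgG antibodies against the platelet-factor-4/heparin
complex activate platelets, producing a falling platelet count together
with a paradoxically *increased* risk of arterial and venous thrombosis.
Under low-molecular-weight heparins (LMWHs) the incidence is roughly an
order of magnitude lower than under unfractionated heparin (about 0.2% of
exposed patients), which is precisely why it is easily missed: a rare,
severe event under a drug regarded as the safer alternative.

`hitsignal` implements the two complementary ways this question is studied
quantitatively:

1. **Spontaneous-report disproportionality.** Given a FAERS-style corpus of
   adverse-event reports, does HIT appear disproportionately often among
   reports for a given LMWH?
2. **Structured case-series analysis.** What do the published individual
   case reports of LMWH-induced HIT look like clinically: onset, platelet
   nadir, 4Ts pretest score, management, outcome?

## Disproportionality model

For one drug and one event, deduplicated reports are cross-classified as

|             | event | other events |
|-------------|-------|--------------|
| drug        | a     | b            |
| other drugs | c     | d            |

and summarised by the proportional reporting ratio and reporting odds ratio

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}, \qquad
  \mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc},$$

with the Pearson chi-square (optionally Yates-corrected) and log-scale Wald
intervals, $\exp(\log\hat\theta \pm 1.96\,SE)$, where
$SE(\log\mathrm{ROR}) = \sqrt{1/a + 1/b + 1/c + 1/d}$ and
$SE(\log\mathrm{PRR}) = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$.
A pair is screened as a signal under either of the standard dual rules,
both with strict inequalities and $N = a$:

* PRR rule: $\mathrm{PRR} > 2$, $\chi^2 > 4$, $N > 2$;
* ROR rule: lower 95% bound of the ROR $> 1$, $N > 2$.

Design choices where the field leaves latitude:

* **Unit of counting** is the deduplicated report, not the drug–event
  mention; the same rule (one report per case id, highest version, ties by
  latest receipt date) is applied before any counting.
* **Exposure** counts a report toward a drug when the drug appears with a
  suspect role code (PS/SS); concomitant roles are included only on request,
  as is standard in signal detection.
* **Zero cells** receive the Haldane–Anscombe +0.5 on all four cells, only
  when some cell is zero, and the row is flagged `corrected`.
* **Chi-square** defaults to the uncorrected Pearson statistic with Yates
  behind a flag. At signal-scale magnitudes the choice is immaterial to
  screening; the reconstruction oracle (below) treats the correction as an
  unknown and identifies it from the data.
* **Event matching** is exact string equality of MedDRA preferred terms
  after case-folding and whitespace collapse against the three HIT PTs
  ("heparin-induced thrombocytopenia", "... test", "... test positive") —
  a closed keyword list, deliberately not substring matching.

## Inverting published summary statistics

Published signal tables typically print `a`, a reporting ratio with its CI,
and a chi-square — but not `b`, `c`, `d`. Because these statistics are
smooth functions of the cells, the printed (rounded) values confine the
integer cells to a small feasible set. `reconstruct_table()` enumerates
that set exactly: it anchors on the manifold where the point estimate and
the CI-implied SE hold exactly, locates the chi-square crossings, and then
scans integer `(b, c)` with a per-cell interval intersection for `d`. The
member closest to the feasible-set centroid is returned, with the set's
spread as diagnostics.

Three honest limitations are built into the interface rather than hidden:

* For ROR-kind inputs, every supplied statistic is invariant under
  transposing the table (`b <-> c`), so the feasible set contains a mirror
  branch and the held-out PRR is two-valued; the diagnostics expose both.
* For weakly associated tables the chi-square is nearly a deterministic
  function of the ratio and its SE, so the printed values leave the cells
  underdetermined along a long sliver; enumeration is then truncated at a
  cap and flagged `truncated`.
* The held-out statistic is determined only up to the feasible-set spread;
  with three rounded inputs per drug this spread can exceed the printed
  precision of the held-out value.

`reconstruct_table_set()` removes all three limitations when several drugs'
tables come from one database snapshot, which is exactly the situation in a
published multi-drug signal table: all drugs then share the grand total
$N = a+b+c+d$ and the event total $a+c$ (assuming no report names two of
the studied drugs — safe for rarely co-prescribed anticoagulants). These
two shared unknowns couple the per-drug feasible sets so strongly that in
the LMWH/HIT case the joint feasible set collapses to a single
configuration, pinning every held-out statistic to well within half a unit
in its last printed decimal. The package treats the joint reconstruction
as the reference validation route; per-drug reconstruction remains for
single-table use.

When reconstructing the three LMWH tables, the joint solve also identifies
*which* chi-square the original analysis used: only the Yates-corrected
statistic admits any feasible integer table, so the oracle selects it
automatically under `chi2_correction = "auto"`.

## The 43-case series

The case-series arm ships a structured reconstruction of a published
43-patient literature series of type II HIT under LMWHs. The published
tables report banded values only (onset in days, platelet nadir, fall
percentage, 4Ts band, recovery time) with drug-stratified counts; raw
per-patient values are not public. Accordingly:

* the fixture stores **bands, not raw values**, and `summarize_series()`
  reports the modal onset band with an explicit `binned_only` marker rather
  than fabricating a median;
* joint attributes are filled by a small seeded constraint-satisfaction
  pass (`build_case_fixture()`): drug-stratified bands are permuted within
  each drug, set-valued items (history, symptoms, treatments, alternative
  anticoagulants) are dealt to the least-loaded eligible cases, and purely
  marginal variables are seeded permutations of their published multisets.
  Every published drug-stratified marginal is reproduced exactly and
  verified by `check_case_series()`; cross-variable correlations that the
  published tables do not constrain are **arbitrary** and must not be
  interpreted;
* two quirks of the published tables are modeled rather than corrected:
  the primary-disease counts sum to 44 over 43 patients (one patient
  carries two indications, so indication is set-valued), and the
  combined-medication percentages use a denominator of 42 (one case's
  combined-medication status is treated as missing, after which the uniform
  non-missing-denominator rule reproduces every printed percentage);
* percentages are rounded half away from zero to 2 decimals
  (`round_half_up()`), matching the published tables.

The Warkentin 4Ts pretest score is implemented as the standard rubric —
four criteria (thrombocytopenia magnitude, timing, thrombosis, other
causes) each scored 0/1/2, bands low 0–3, intermediate 4–5, high 6–8 —
because the published band structure matches it. A day-1 fall scores the
full 2 timing points only with heparin exposure in the previous 30 days;
a missing criterion yields an explicitly missing score, never an imputed
one.

## What the synthetic generator emulates

`generate_reports()` draws FAERS-like corpora with known ground truth: one
drug per report from a mixed prescription pool, a background HIT reporting
probability $p_0$, and a designated drug whose event probability is
$\operatorname{logit}^{-1}(\operatorname{logit}(p_0) + \log \mathrm{OR})$,
so the injected OR is the exact conditional odds ratio. A configurable
fraction of cases is re-emitted as version 2 with a later receipt date, and
demographics carry configurable missingness.

Defaults describe the study conditions used throughout the tests: 20,000
unique cases, target-drug exposure 10%, $p_0 = 1\%$, 5% duplicates, modest
missingness (10% age, 5% sex and country). At these sizes the target cell
is $a \approx 180$ under $\mathrm{OR} = 10$, comfortably inside the
asymptotic regime of the Wald interval. Features of real spontaneous-report
data that the generator deliberately does **not** emulate: free-text drug
name noise beyond the shipped synonym list, multi-drug reports (behind a
flag, off by default so the ground-truth table stays unambiguous),
reporting-rate drift over time, and correlated demographics. Passing
calibration tests on this generator therefore validates the *statistical
machinery*, not the vagaries of real FAERS extraction.

Simulation-based checks run at 500 corpora per condition: under the null
the ROR rule's false-flag rate stays below 7% (nominally ~2.5% plus the
$N > 2$ gate), and under $\mathrm{OR} = 10$ the 95% ROR interval covers
truth at its nominal rate (93–97%) while both screening rules essentially
always fire. Corpus size and run counts were chosen so the whole suite
stays desk-scale.

## Numerical choices and degenerate inputs

* All randomness flows through one seeded Mersenne-Twister stream per
  operation (`with_seed`), restoring the caller's RNG state.
* `z = 1.96` exactly (not `qnorm(0.975)`) for 95% intervals, matching
  universal pharmacovigilance practice and the printed-value arithmetic.
* Undefined statistics (zero margins without correction) return an `NA`
  carrying its reason (`value_reason()`), never a silent zero.
* Empty inputs yield empty, zero-denominator tables, not errors; a drug
  with no reports yields a row with `n_reports = 0` and no flags.
* Reconstruction tolerances default to half a unit in the last printed
  decimal (0.005 for two-decimal statistics) and are per-statistic
  overridable, e.g. `tol = c(chi2 = 5e-4)` for a three-decimal chi-square.

## Known limitations

* Report-level counting and suspect-only exposure are documented defaults;
  the original analyses behind published tables may have counted
  differently, which is invisible at the printed precision.
* The case fixture's unconstrained cross-variable correlations mean it
  supports marginal (table-level) analyses only.
* No multiplicity adjustment across drug–event pairs is applied (none is
  standard in this screening setting), and Bayesian disproportionality
  (IC, EBGM) is out of scope.
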