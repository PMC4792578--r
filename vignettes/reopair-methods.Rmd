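---
title: "Rank-based gene-pair signatures: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopair)
```

## The method in one page

Microarray (and other) expression measurements are hard to compare
across batches and platforms, but the *ordering* of two genes within one
sample — does gene A exceed gene B? — survives any monotone
normalisation of that sample. `reopair` builds survival signatures
entirely from such within-sample relative expression orderings (REOs):

1. **Stable pairs.** In a reference collection of normal-tissue samples,
   a directed pair (A,B) is *stable* when A > B strictly in more than a
   threshold fraction (default 99%) of samples. Lists from two platforms
   can be intersected; the chance level for direction agreement is 0.5
   per pair, so the observed agreement is judged with an exact
   upper-tail binomial test.
2. **Reversals and disruption.** A tumour sample *reverses* a stable
   pair when it shows the strict opposite ordering. For each pathway
   (gene set), the fraction of its intra-pathway stable pairs reversed
   in a sample is that sample's *disruption index* for the pathway.
3. **Screening.** Pathways whose disruption index associates with
   recurrence-free survival (univariate Cox, BH-FDR < 5%) are reduced to
   a *core* set: the largest connected component of the network that
   links pathway pairs with Spearman rho > 0.6 (BH-FDR < 5% over all
   pathway pairs). Within the core pathways, individual stable pairs
   whose reversal predicts poor survival (Cox HR > 1, BH-FDR < 10%)
   become candidates.
4. **Signature selection.** A minimal subset of candidates is chosen by
   forward-stepwise maximisation of Harrell's C-index under the
   *zero-reversal rule*: a patient is favorable iff none of the
   signature's pairs is reversed. The seed is the best single pair; the
   search stops when no addition improves C.
5. **Coupling.** Two signatures are applied sequentially: a drug-free
   prognostic signature discovered on surgery-only patients assigns
   low-risk patients; a treatment-benefit signature, discovered on the
   treated patients the first signature calls high-risk, splits the rest
   into benefit and non-benefit groups.

Because every statistic consumes only within-sample orderings, every
output — stable pairs, reversal statuses, disruption indexes,
classifications, three-group labels — is invariant under per-sample
strictly increasing transforms, and cohorts measured on different
platforms can be pooled at the reversal-matrix level without joint
normalisation. The test suite asserts these invariances directly.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.99 | stability fraction in normals; *strict* (`count > threshold * n`), so 99/100 fails at 0.99 |
| `fdr_pathway` | 0.05 | BH-FDR for the pathway survival screen |
| `rho_min` | 0.6 | Spearman threshold for network edges; strict (`rho > rho_min`) |
| `fdr_spearman` | 0.05 | BH-FDR over all pathway pairs for edge significance |
| `fdr_pair` | 0.10 | BH-FDR for the candidate-pair reversal screen |
| `min_pathway_pairs` | 5 | pathways with fewer intra-pathway stable pairs are not scored: a fraction of very few pairs is noise-dominated |
| `eps` | 1e-10 | minimal C-index gain counted as improvement in the greedy search ("did not improve" read as no gain beyond floating-point noise) |
| `min_stage2` | 40 | smallest acceptable stage-2 discovery cohort |

Times are months throughout; hazard ratios are per unit of the covariate
(the disruption index enters Cox as a raw fraction, so its HR is "per
whole unit of disruption" and is large when effects are real — this is a
reporting scale, not a significance issue).

## Conventions the data forced us to fix

**Ties.** Expression ties are vanishingly rare on a continuous log2
scale but must have a defined meaning: a tie counts *against* stability
in normals and as *non-reversal* (status 0) in tumours. Both choices are
conservative — a tie never creates evidence of disruption.

**Strict thresholds.** "More than 99%" and "larger than 0.6" are
implemented as strict inequalities; the stability denominator is always
the full normal sample count.

**Largest component.** The "core" of the pathway network is the largest
connected component (ties between equal-sized components broken by the
lexicographically smallest member name); isolated nodes are not a
component of interest, so an edgeless network has an empty core.

**Direction filter after BH.** The candidate screen computes BH across
all tested pairs first and applies the HR > 1 direction filter second,
so the multiple-testing family is not shrunk by the filter.

**Greedy tie-breaks.** Equal C-index candidates are ordered by larger
univariate HR, then lexicographically by gene ids — discovery is fully
deterministic given its inputs.

**Published signature fixtures.** The packaged 9-pair prognostic and
10-pair benefit signatures carry gene identities only: the printed
tables do not state which gene of a pair is higher in normal tissue, so
the fixtures load with `direction_known = FALSE` and refuse to classify
until `bind_signature_direction()` orients them against a user-supplied
normal-tissue stable-pair set. Guessing a direction would silently
invert risk groups; refusing is safer.

## Numerical choices

**Binomial tail in log space.** The consistency test must evaluate
upper tails like "at least 98% of 17.5 million pairs agree". The
implementation sums the smaller binomial tail via `lchoose` +
log-sum-exp in bounded-memory chunks; `log_p` stays exact even when `p`
underflows the smallest positive double (the two headline bounds are
`log p` of about −1.04e7 and −3682, hence `p = 0` at double precision —
many orders below the printed `1e−16` bounds).

**Cox fitting.** `survival::coxph` with Efron tie handling,
Newton–Raphson tolerance 1e-9, at most 100 iterations. Warnings
(including monotone-likelihood "coefficient may be infinite") mark a fit
non-converged; screens exclude such fits rather than crash.

**Wald versus likelihood ratio.** Reported CIs and p-values are Wald
(`exp(coef ± 1.96 SE)`), matching standard HR reporting. The *screening*
families, however, test on the partial-likelihood-ratio p. Rationale: a
disruption index that varies in only a handful of samples gives a
near-degenerate covariate for which the Wald z is anti-conservative in
the far tail; on signal-free simulations the Wald-based pathway screen
fired in ~30% of runs, violating nominal FDR calibration, while the LRT
screen stays at ~5%. This is a deliberate deviation from Wald-only
testing, made to honour the calibration requirement.

**Spearman p-values.** Exact permutation null (all n! permutations) for
n ≤ 10, t approximation on n − 2 df above; midranks for ties.

**Censoring calibration.** Uniform censoring on [0, M] with M solved by
`uniroot` so the expected censored fraction, averaged over the cohort's
per-sample hazards, equals the target rate.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the world every pipeline stage assumes:

- **Normal tissue**: a consensus mean per gene (Uniform(4, 11) log2
  units for ordinary genes) plus Normal(0, 0.5) noise, so pairs
  separated by more than ~3 noise SDs are >99%-stable by construction.
- **Planted pairs**: each planted (prognostic or benefit) pair occupies
  a reserved expression band above the ordinary range with a 6-noise-SD
  intra-pair gap. A *reversal* is simulated by swapping the two genes'
  values, which flips exactly that one stable comparison and leaves
  marginal distributions unchanged — the cleanest possible isolation of
  the rank signal the method consumes. Defaults: three prognostic pairs,
  reversal probability 0.35 each, hazard ratio 4 per reversed pair.
- **Survival**: exponential times with hazard
  `0.005/month × 4^(#reversed prognostic pairs)`, uniform censoring
  calibrated to 30%; a treated flag (default half the cohort) multiplies
  the hazard by 0.4 for treated samples whose benefit pair is *not*
  reversed (the benefit stratum; benefit-pair reversal probability 0.5).
- **Pathways**: random gene sets (default 50 of size 10–40) plus *two*
  overlapping "signal" pathways that both contain all planted genes with
  disjoint small filler sets. Two are generated, not one, because the
  core-extraction step keeps the largest connected *component*: a single
  signal pathway can never acquire an edge, so the planted signal would
  be structurally invisible to the network stage regardless of its
  strength. Their shared planted pairs make the two indexes strongly
  rank-correlated, which is exactly the situation the network step is
  designed to detect.
- **Streams**: every artifact draws from its own RNG stream at a fixed
  offset from the master seed; independent cohorts (e.g. a surgery-only
  and an all-treated cohort) come from distinct streams over the same
  consensus.

For the *coupled* discovery tests the world plants **two** prognostic
pairs rather than three. With three pairs at reversal probability 0.35,
the zero-reversal binary classification's C-index peaks at two pairs
(adding the third shrinks the favorable group faster than it sharpens
discrimination), so stage 1 structurally leaves one prognostic pair
unrecovered and stage 2 then rediscovers that confounder instead of the
benefit signal. That is a property of the greedy objective, not a bug;
since the coupled tests are about the *sequential benefit logic*, their
world is chosen so the prognostic structure is fully identifiable in
stage 1.

A green simulation test therefore establishes that the pipeline recovers
planted rank structure under its own model assumptions. It does **not**
establish performance on real tumours: the generator has no probe-level
artifacts, no correlated co-expression modules beyond the planted
pathways, no batch effects beyond monotone transforms (which the method
ignores by design), proportional hazards hold exactly, and censoring is
independent and uniform.

## Known limitations

- Expression values are assumed complete; the loader rejects missing
  values by default (orderings are undefined on them) and offers only
  per-gene median imputation.
- The greedy C-index search returns a local optimum by construction; the
  exhaustive-search tests bound it from above on small fixtures but no
  optimality guarantee exists at scale.
- The marginal hazard ratio of one planted pair underestimates its
  conditional effect when other prognostic pairs are omitted
  (non-collapsibility); tests of the estimation band therefore use a
  single-pair world.
- Stage-2 discovery pools treated high-risk samples without re-weighting
  by dataset of origin; REO semantics make pooling legitimate at the
  reversal level, but dataset-specific case mix is not modelled.
- No proportional-hazards diagnostics, time-dependent covariates or
  competing risks.
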