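---
title: "Falsifying the biological meaning of prognostic signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Falsifying the biological meaning of prognostic signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigfalsify)
```

## The question the tool asks

A prognostic signature is a gene set whose expression stratifies patients
by outcome. Predictive performance alone, however, says nothing about
whether the member genes are involved in the disease: in transcriptome
data with pervasive co-expression, many gene sets stratify patients
equally well. `sigfalsify` operationalizes one specific falsification
test: *can gene sets that provably share no GO biological-process
annotation with the signature match its prognostic performance?* A "yes"
refutes the claim that the signature's biology drives its performance.

The disjointness is constructed, not hoped for. The meaning of a gene set
is the union of its members' GO-BP terms, `M(S)`; the strong removal
regime deletes from the sampling pool every gene annotated to any term of
`M(BM)` (plus the signature itself and an optional proliferation list), so
every surrogate set drawn from the remaining pool `G'` satisfies
`M(RGS) ∩ M(BM) = ∅`. This identity is asserted at run time for every
emitted surrogate, and the package's tests verify it against a brute-force
enumeration of all gene–term memberships.

## The prognostic task

Each gene set is evaluated exactly as the signature would be in a
discovery study:

1. **PC1 stratification.** The expression submatrix of the set is
   restricted to the cohort, each gene is z-scored across samples
   (zero-variance genes dropped), and the first principal component of the
   samples in this gene space is computed by SVD — deterministic, no
   iterative estimation. The sign of PC1 is fixed so that scores correlate
   non-negatively with per-sample mean z-expression, making LOW/HIGH
   groups interpretable. The default split is at the median score (ties to
   LOW), which guarantees balanced, non-degenerate groups; a sign split
   (at zero) is available since the threshold used by earlier PC1-based
   studies is not standardized.
2. **Kaplan–Meier / log-rank.** The two strata are compared with the
   Mantel–Haenszel log-rank test using the tie-corrected hypergeometric
   variance per distinct event time, with the statistic referred to a
   two-sided chi-squared(1) distribution. Subjects censored exactly at an
   event time remain in the risk set at that time. Both the product-limit
   estimator and the test are implemented in the package and are checked
   in the test suite against the independent `survival` package to 1e-6
   relative accuracy, plus an exact hand-computed two-event case.

Gene-wise z-scoring before PCA is a deliberate design choice: it prevents
high-variance genes from dominating PC1 and makes the stratification
invariant to per-gene scale. It is a divergence point from any particular
prior implementation, which may run PCA on unstandardized expression.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `B` | 1000 | surrogate sets drawn; also the Bonferroni multiplier |
| `alpha` | 0.05 | significance level after correction |
| `mode` | `"strong"` | removal regime; `weak_i`/`weak_ii` for comparison |
| `split` | `"median"` | PC1 threshold rule |
| `propagate` | off | close annotations over `is_a`/`part_of` ancestors |
| `pg` | empty | proliferation gene list (user-supplied, loud warning if absent) |

Ancestor propagation is off by default: mapping genes to their directly
recorded GO terms is the literal reading of the annotation, while
propagation strictly enlarges each meaning and hence the removal set,
making the strong regime more conservative. Both behaviors are exposed
because published annotation pipelines differ; propagation excludes the
BP root term (`GO:0008150`), which annotates everything and would empty
the pool. Similarly, all GAF evidence codes are kept by default (IEA can
be excluded), the inclusive default again being the conservative one for
the removal step.

Unannotated genes keep an *empty* meaning rather than raising an error:
they satisfy the disjointness requirement vacuously and stay eligible.
Their count is reported in the removal provenance so users can judge how
annotation-dark their pool is. Signature genes are excluded from the
eligible pool under the strong regime even when unannotated.

Because the appropriate summary of "surrogate performance" is not
standardized, the report emits all raw material: the B raw and adjusted
p-values, the count/fraction significant at `alpha`, the count of
surrogates with raw p at or below the signature's, and the signature's
p-value both raw and Bonferroni-corrected against B (the latter a
reporting convenience, labelled as such).

## Numerical and degenerate-input choices

* Bonferroni is `min(1, B·p)` with `B` an explicit argument, since the
  multiplier is the family size, not necessarily the length of the vector
  being corrected.
* A surrogate draw whose stratification is degenerate (fewer than two
  usable genes after dropping zero-variance rows, or an empty stratum) is
  recorded as a skip and redrawn from the same RNG stream, so the report
  always contains exactly `B` valid tasks; a retry cap of `10·B` draws
  turns pathological inputs into an informative error instead of a loop.
* A cohort with zero events makes the log-rank test undefined and errors.
* All randomness flows through a single integer seed; a fixed seed plus
  fixed inputs reproduces the report byte-for-byte (verified in the
  tests), and seeding is isolated via `withr` so library callers' RNG
  state is untouched.

## What the synthetic generator emulates

`synth_spec()`/`make_synthetic_study()` produce the full input bundle with
known ground truth. Expression is standard-normal log-scale noise;
survival is exponential with a proportional-hazards log-linear effect
(`hazard = baseline · exp(effect · driver)`), and censoring is independent
exponential whose rate is solved numerically against the realized
per-sample hazards so the expected censored fraction equals
`censor_rate`. Defaults describe a plausible oncology cohort: 1000 genes,
200 patients, baseline hazard 0.05 per month (median survival around one
year), 30% censoring, a 20-gene signature, effect 1.0 per driver SD.

Three regimes define the ground truth:

* `none` — survival independent of expression; used for calibration
  (log-rank p-values are uniform; the Bonferroni family-wise error stays
  at or below `alpha`).
* `signature_only` — the signature genes share one latent factor (unit
  loading on unit noise) and the hazard is driven by the standardized mean
  z-expression of the signature. The shared factor is what makes PC1 of
  the signature recover the hazard direction; with independent noise genes
  the mean-expression driver would live in a direction PC1 has no reason
  to find, and the regime would not represent a *detectable*
  signature-borne signal. The signature's GO terms are reserved for it
  alone, so the strong removal deletes exactly the signature and the
  surrogate pool is pure noise — the discriminating fixture separating a
  causal-like signature from a merely predictive one.
* `latent_global` — one latent factor with per-gene loadings
  (uniform 0.5–1.5) on a `frac_affected` = 0.5 fraction of the genes,
  including the signature, drives the hazard. Random surrogate sets then
  contain affected genes, PC1 recovers the factor, and surrogates remain
  prognostic: the mechanism by which co-expressed proliferation-like
  programs make arbitrary gene sets "work".

The generator deliberately omits microarray/RNA-seq noise models, batch
effects, competing risks and realistic GO topology (term counts per gene
are truncated-Poisson draws from a flat term pool). Passing tests
therefore demonstrate the *logic* of the procedure — disjoint
construction, calibration, discrimination between the two signal
architectures — not robustness to platform artifacts of real cohorts.

## Problem sizes used by the checks

The test suite and the acceptance script run, as the package's own
choices: 100 random annotation instances (up to 500 genes x 50 terms) for
the disjointness and nesting properties; 100 random cohorts against the
`survival` oracle; 2000 null replicates at n = 100 for type-I-error
calibration (empirical rate expected in [0.04, 0.06]); 100 null
falsification runs at B = 100 for the family-wise error bound; and the
two-regime discrimination experiment at effect 1.0, n = 200, B = 200.

## Known limitations

* GO-BP disjointness is only as meaningful as the annotation supplied;
  sparse or biased annotation weakens the removal (the provenance counts
  make this visible, but cannot repair it).
* Only two-group stratification and the two-group log-rank test are
  provided; no Cox modelling, hazard-ratio estimates, or multi-group
  extensions.
* Gene identifiers are matched literally; no alias resolution.
* The proliferation list is user-supplied; the package ships none.
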