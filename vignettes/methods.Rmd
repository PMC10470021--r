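---
title: "Methods: repertoire tracking, ELISPOT positivity, and the effector-target balance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire tracking, ELISPOT positivity, and the effector-target balance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrbalance)
```

# The scientific problem

Therapeutic cancer vaccines against a shared neoantigen (here the mutant
calreticulin frameshift of *CALR*-mutant myeloproliferative neoplasms) can
raise circulating specific T cells, yet the malignant compartment may not
shrink. This package implements the three quantitative analyses used to
investigate why: do the vaccine-induced clonotypes enrich in bone marrow,
do the specific cells actually recognize autologous mutant cells, and —
even granting recognition — can the effector pool plausibly keep up with
the mutant burden at all?

# The effector-target balance model

## Model and assumptions

The model is deliberately algebraic, not dynamic. The transformed
compartment is the mutant fraction of the peripheral neutrophil plus
monocyte pools. Because the driver mutation is heterozygous, a variant
allele fraction $v$ corresponds to a mutant-cell fraction $2v$, so the
burden is

$$B = 2\,(N + M)\,v .$$

The effector pool is a fraction $b$ of the total T-cell pool $T$. Each
effector kills serially, one target at a time, at a constant per-kill time
$\tau$; targets do not regrow during the killing campaign except through
the self-renewal criterion below. Hence

$$\text{kills per effector} = \frac{2 (N+M) v}{b\,T}, \qquad
  \tau_{\text{total}} = \tau \cdot \frac{2 (N+M) v}{b\,T}.$$

Neutrophils and monocytes turn over with characteristic lifetimes, so
eradication is only possible if the effectors clear the burden faster
than it self-renews. The neutrophil lifetime dominates, giving the
criterion $\tau_{\text{total}} \le L_N$ and, solved for the allele
fraction, the maximal controllable VAF

$$v_{\max} = \frac{L_N\, b\, T}{2\,\tau\,(N+M)} .$$

Note the consistency identity used in the test suite: evaluating
$\tau_{\text{total}}$ at $v = v_{\max}$ returns exactly $L_N$, for any
valid parameter set. The monocyte lifetime is stored for completeness but
does not enter the criterion, since the neutrophil lifetime is the
dominant self-renewal time.

## Parameters, units and defaults

| symbol | meaning | default | unit |
|---|---|---|---|
| $N$ | total neutrophil count | $6\times10^{11}$ | cells |
| $M$ | total monocyte count | $1\times10^{10}$ | cells |
| $T$ | total T-cell count | $7\times10^{11}$ | cells |
| $L_N$ | neutrophil lifetime | 6.6 | days |
| $L_M$ | monocyte lifetime (unused in the criterion) | 3.5 | days |
| $v$ | variant allele fraction | 0.41 | — |
| $b$ | specific fraction of the T-cell pool | $10^{-4}$ | — |
| $\tau$ | per-kill time | 90 | minutes |

The cell counts and lifetimes are total-body literature estimates of human
cell numbers and turnover. The default VAF of 0.41 is a typical trial
median; $b = 10^{-4}$ is the order of magnitude measured by ex vivo
ELISPOT (`estimate_b_from_elispot(45, 6e5)` gives a raw $7.5\times10^{-5}$,
magnitude $10^{-4}$); per-kill times of 90 minutes to 12 hours span
published in vivo kill-rate estimates. Because the inputs mix minutes,
hours and days, `balance_params()` takes `tau` with an explicit unit tag
and converts once, through `to_days()`, so 90 minutes, 1.5 hours and
0.0625 days are bit-identical internally.

Numerical choices: `vaf` outside $[0, 0.5]$ is rejected at construction
(the heterozygous bound); `max_controllable_vaf()` is *not* clamped — a
value above 0.5 means any biologically possible VAF is controllable, and
`clamp_vaf()` exists separately for display so the pure formula stays
testable. `kills_per_effector()` returns the raw float; rounding (e.g. to
"about 7000") is the caller's concern.

`balance_sweep()` evaluates one output over an axis × series grid where
every cell is an independent scalar call — the grid is plumbing for
plotting/CSV export, and the test suite asserts cell-by-cell equality with
the scalar operations.

# Repertoire filtering and tracking

Clonotype tables arrive per (patient, sample, chain) as AIRR Rearrangement
TSV or a minimal TSV dialect; α and β chains are always separate samples
(bulk data are unpaired). Identity is a configurable key: chain + CDR3
amino-acid sequence + V gene by default (`"aa_v"`), with `"aa"` and
`"nt_vj"` variants; the recipe is recorded in every tracking result, and a
coarser recipe can only merge clonotypes, never split them. Rows sharing a
key merge by summing reads at ingest.

Two filters mirror standard practice:

- **Read filter.** Clonotypes with fewer than 2 reads are excluded
  (sequencing noise). The boundary is inclusive: 2 reads survive. Whether
  frequencies should then be renormalized over the survivors is a genuine
  choice; the default renormalizes (keeping the frequencies-sum-to-1
  invariant that every downstream step relies on), and
  `renormalize = FALSE` preserves pre-filter denominators so both
  conventions can be reported.
- **Culture specificity filter.** In an antigen-enriched culture,
  clonotypes below 1% within-culture frequency are attributed to
  background (feeder-cell) T cells; those at or above 1% are called
  specific. The boundary is again inclusive at exactly 1%. The returned
  key set carries a rank/frequency table so callers can flag doubtful
  matches (a bulk hit whose culture clonotype ranked low in the culture
  is weak evidence of specificity); no additional rank filter is applied
  by default.

`track_clonotypes()` builds a keys × samples frequency matrix with exact
zeros for absence (no pseudocounts), and `specific_fraction_report()` sums
the specific keys' frequencies in baseline, end-of-trial and culture
samples — the per-patient, per-chain summary table. Machine outputs format
percentages with three decimals and a dot separator.

# ELISPOT statistics

The normalized count is the mean stimulated-well count minus the mean
unstimulated-well count, additionally minus the mean target-alone count
when target cells (which secrete cytokine themselves) are the stimulus.
Negative values are floored to zero in reports with the raw value kept as
an attribute for audit.

Positivity is a one-sided permutation test on replicate wells
(distribution-free resampling). Under the null that stimulated wells do
not exceed `multiplier` × control, control counts are scaled by the
multiplier, the scaled pool is re-split into stimulated-sized and
control-sized arms in every possible way, and the p-value is the fraction
of splits whose stimulated-minus-control mean difference reaches the
observed one (observed split included, so $p \in (0, 1]$; ties compared
with a $10^{-9}$ relative tolerance). `multiplier = 2` is the conservative
DFR2x variant. For triplicates the permutation space has
$\binom{6}{3} = 20$ splits, so the smallest attainable p-value is 0.05 —
exactly reachable by a clean response. Enumeration is used automatically
up to $10^6$ splits (deterministic); beyond that, Monte-Carlo resampling
with a recorded seed and the add-one estimate $(h+1)/(R+1)$. The test
suite checks the Monte-Carlo path against an independently coded
enumeration oracle, verifies DFR2x rejections are a subset of DFR1x
rejections, and measures the empirical type-I error on 2000 simulated
null assays.

The test can be run on raw or normalized inputs: `dfr_test()` accepts the
assay (raw arms, with `control_arm` selecting unstimulated or target-alone
wells) or explicit replicate vectors, and the returned call records which
was used.

# The synthetic-data generator

Patient-level TCR sequencing data of this kind are generally not
shareable, so the package generates its own inputs with known ground
truth:

- **Bulk repertoires**: `n` background clonotypes with heavy-tailed
  Zipf rank weights (`power_law(e)` means weight $\propto r^{-e}$, so the
  rank-frequency log-log slope is $-e$ by construction; a geometric law is
  available), sampled multinomially at a configurable read depth. Default
  depth $10^6$ so that a $2.2\times10^{-4}$-scale spike yields ~220
  expected reads. CDR3s are uniform-random 8–20-mers over the 20-letter
  amino-acid alphabet with V/J labels from a small fixed catalogue — only
  identity-key behaviour matters, not biological realism.
- **Spike-ins** are injected at exact target frequencies (background
  weights are rescaled to the remaining mass), so recovery can be judged
  against binomial sampling error at the generated depth.
- **Paired timepoints**: the end-of-trial sample reuses a retention
  fraction of baseline clonotypes (default 0.9 — bulk marrow repertoires
  are expected to remain largely stable over a trial) with novel clones
  replacing the rest; spikes go into the end-of-trial sample only,
  emulating vaccine-induced clones absent at baseline.
- **Cultures**: a few dominant clonotypes share a configured fraction of
  reads (default 0.9, matching near-monoclonal antigen-enriched cultures)
  over a background of ~120 sub-1% clones.
- **ELISPOT**: Poisson counts per well, stimulated rate = background +
  effect; effect 0 gives null assays for type-I-error studies.

Every generator is deterministic given its seed (seeds are set locally and
the caller's RNG stream restored) and attaches its ground truth to the
output.

What the generator does **not** emulate: V(D)J recombination statistics,
sequencing error and UMI collapse, clonal expansion dynamics between
timepoints, cross-sample contamination, or non-Poisson ELISPOT
overdispersion. Passing recovery tests therefore demonstrates that the
pipeline's accounting is correct at realistic scales — not that the
filters are optimal for real noise processes.

# Pipeline and reproducibility

`run_pipeline()` orchestrates simulate → filter → specific-set → track →
report → model sweeps → ELISPOT calls, writing tidy TSV/CSV outputs plus a
JSON manifest (package version, seed, thresholds, key recipe) into an
immutable run directory named by a hash of the configuration. The
directory name deliberately excludes a timestamp: identical configurations
must map to byte-identical outputs, which the test suite asserts, and an
existing run directory is never overwritten. Every reported number is
recomputable from the module functions with the logged inputs; the suite
spot-checks that the per-patient fractions equal the column sums of the
corresponding tracking matrices.

Problem sizes in the shipped tests are chosen to keep the full suite
fast while leaving sampling error well inside the asserted tolerances:
bulk samples of 500–4000 clonotypes at depths $5\times10^4$–$10^6$,
2000 simulated null ELISPOT assays, 1000 random parameter sets for the
algebraic-identity property.

# Known limitations

- The balance model is a static worst-case comparison: no
  tumor–immune dynamics, no hematopoietic stem-cell compartment, no
  effector exhaustion or proliferation. It answers "could the effector
  pool even in principle keep up?", not "what trajectory would the burden
  follow?".
- Specificity calling rests entirely on the 1% culture threshold;
  low-avidity clones below 1% are invisible, and culture expansion bias
  is not modelled.
- The DFR implementation is a permutation construction validated against
  exhaustive enumeration; it does not reproduce any particular software
  package's tie-handling to the last ulp.
- Frequencies are maximum-likelihood read fractions; no abundance
  uncertainty is propagated into the tracking matrices.
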