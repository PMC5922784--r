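---
title: "Correcting cross-annotation in functional profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting cross-annotation in functional profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsacor)
```

## Why best-hit profiles need correction

A metagenomic functional profile built by the read-count approach assigns
each ~100-base read to the protein family of its best homology hit and
tabulates relative abundances. Since a short translated read covers only a
fragment of a protein (prokaryotic coding sequences average roughly 900
base pairs), best hits are noisy between related families: a family's
observed count mixes reads it truly emitted with reads that belong to
other families, while some of its own reads are credited elsewhere. These
two coupled errors are what we call cross-annotation. Empirical score
cutoffs reduce spurious alignments but cannot undo the mixing — the
observed profile is the true profile pushed through a confusion process.

## The mixture model

Let `a_1..a_N` be the aligned families (all families that received at
least one best-hit read) and `c_1..c_M` the estimated existing families.
The existing list is constructed from the aligned list by removing
*artificial* families — families with zero read support in the RPS-BLAST
output after its own score filtration — and appending one reserved family,
`EXTRA`, which models reads originating from coding sequences outside the
family catalogue and from non-coding sequence. Thus `M = N − |artificial| + 1`.

The model has two parameter blocks:

* the confusion matrix `α` (N × M), `α_ij = P(aligned = a_i | origin = c_j)`,
  each column a probability vector; and
* the origin proportions `β` (length M), `β_j = P(origin = c_j)`.

A read falls in cell `(i, j)` with probability `α_ij β_j`; only the
aligned margin `y_i` is observed. The observed-data log-likelihood is
`ℓ(α, β) = Σ_i y_i log(Σ_j α_ij β_j)`. The origin of each read is a latent
class, so we maximize `ℓ` by EM:

* **E step.** The posterior that a read aligned to `a_i` originates from
  `c_j` is `α_ij β_j / Σ_s α_is β_s`; multiplying by `y_i` gives the
  expected allocation `Φ_ij` and its column sums `Ψ_j`. Reads are never
  enumerated — `Φ` carries the whole conditional law.
* **M step.** Lagrangian maximization under the simplex constraints gives
  the closed forms `α_ij ← Φ_ij / Ψ_j` and `β_j ← Ψ_j / Σ_i y_i`.

Each sweep cannot decrease `ℓ`; the test suite asserts this on every fit
it runs. The corrected profile reported to the user is `β̂` together with
corrected counts `ŷ_j = [ (Σ_i y_i) β̂_j ]`, rounded half away from zero.
The rounded counts are allowed to miss the observed total by up to half a
read per family; the decomposition of an integer vector through a
continuous model is approximate by nature, and we do not force the sum.

## Starting values and why they matter

With `α` free the model has far more parameters than the `N` observed
counts, so the likelihood surface carries many maxima and EM converges to
a point determined largely by its start. The remedy implemented here is
statistical learning from a *learning sample*: a sample in which each
read's true origin family is known (in practice, simulated reads traced
back to their source genome positions), summarized as a joint
(origin × aligned) count matrix.

From that matrix we estimate two empirical conditionals: `α^L`, the
fraction of reads from origin `j` aligned to `i`, and `γ^L`, the fraction
of reads aligned to `i` that originate from `j`. For a new sample:

* `α⁰` columns for origins seen in the learning sample copy `α^L` on the
  aligned families the two samples share; aligned families private to the
  new sample split the leftover mass `1 − Σ_shared α^L` equally. Origins
  unseen in the learning sample (often `EXTRA`) start uniform at `1/N`.
* `β⁰_j` for shared origins is the learned origin share of the new
  sample's reads, `Σ_shared γ^L_ji y_i / Σ y`; unseen origins split the
  leftover equally.

Two transferability assumptions justify this: reads from a common origin
family distribute over aligned families with similar frequencies across
samples, and conversely for the origin composition of reads aligned to a
common family. Violating them degrades only the starting point, not the
model. When the learning sample covered aligned families the new sample
lacks, a copied column can sum below one with no private families left to
take the remainder; we renormalize the column — the natural completion of
the remaining-mass rule for a combination the rule does not address.

Every initial column and the initial `β⁰` are floored at `ε = 1e-12` and
renormalized. EM's updates are multiplicative, so an exact zero could
never become positive again; the floor removes these absorbing states
while staying far below any meaningful probability.

Without a learning sample, `run_correction()` falls back (with a warning)
to uniform confusion columns and `β⁰` proportional to each real family's
observed count, `EXTRA` starting at the read share of the artificial
families. This is a labeled convenience, not a recommendation: with an
uninformative `α⁰` the fit typically stays near the raw profile.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `score_cutoff` | 66 (bits) | BLAST alignments kept when bit score is strictly greater; tuned for ~100-base reads against COG |
| `rps_cutoff` | 61 (bits) | same rule on the RPS-BLAST output used for artificial-family flagging |
| `evalue_cutoff` | 1e-3 | alternative filter mode (`e ≤ cutoff`), for comparison with conventional e-value pipelines |
| `tol` | 1e-6 | EM stops when every parameter's absolute change falls below this |
| `max_iter` | 1000 | iteration cap; `converged = FALSE` past it |
| `eps` | 1e-12 | probability floor in initialization |

Both cutoffs are applied strictly (`>`): the filtering rule is phrased as
"greater than" for the BLAST score, and we apply the same strictness to
the RPS cutoff for consistency. Best-hit ties are broken deterministically
by highest bit score, then lowest e-value, then lexicographically smallest
subject id, so a fit is a pure function of its inputs.

The convergence criterion is the maximum absolute change over *all*
parameters — every entry of `α` and of `β` must move less than `tol`. An
`M = 1` or identity-confusion instance converges in two sweeps with `β̂`
equal to the empirical proportions exactly, which the tests use as a
closed-form anchor. The `fix_alpha` option of `fit_plsa()` freezes the
confusion matrix and updates only `β`; since `ℓ` is concave in `β` for
fixed `α`, that fit reaches the unique conditional maximizer, and the test
suite verifies it against a `1e-3` grid search over the `β` simplex.

## What the synthetic generator emulates

`sample_truth()` draws ground-truth models: each real family has a "self"
aligned family whose Dirichlet-mean mass is exactly `1 − cross_rate`, the
remainder spreading over the other aligned families; `EXTRA`'s column and
`β` are symmetric Dirichlet draws (mean uniform). `simulate_counts()`
draws all reads in one multinomial over the `(aligned, origin)` cells, so
a labeled draw's aligned margin coincides with the unlabeled draw under
the same seed. Defaults (`concentration = 50`, `cross_rate = 0.2`) give
confusion columns dominated by their own family with 10–30% leakage,
matching the regime where a raw best-hit profile is visibly but not
hopelessly distorted.

The generator emulates the *generative structure the model assumes* —
multinomial sampling from a fixed confusion law. Real data differ in ways
the generator does not attempt: alignment scores correlate with read
position and sequencing error, confusion is driven by sequence similarity
and hence is far from exchangeable across families, family abundances are
heavy-tailed over thousands of families, and read counts are biased by
CDS length and conservation (a correction outside this package's scope).
Passing the recovery tests therefore demonstrates correctness of the
estimator under its own assumptions, not performance on any particular
real sample; for real data the learning sample's transferability is the
operative leap.

`label_read_truth()` implements the truth-labeling rule used when
constructing learning samples from reads with known genomic placements:
identity strictly greater than 95% and overlap of at least 60 bases with
a family's coding region, both as printed; with competing families the
larger overlap wins, and an exact tie is refused rather than silently
broken, since the rule's source is silent on ties.

## Evaluation metrics

`profile_accuracy()` computes RRMSE, AVGRE, MAXRE and DTV over the real
families `j = 1..M−1`, excluding `EXTRA` — the only index convention under
which the `M − 1` denominators make sense, given that `EXTRA` is appended
last by construction. RRMSE takes the square root (it is a *root* relative
mean square error), MAXRE's maximum runs over the same `M − 1` range as
the other measures, and the fitted `β̂` entries are used as-is, without
renormalizing after dropping `EXTRA`. True proportions must be positive on
the real families, since relative errors are undefined at zero.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on simulated instances of
up to 10 existing / 15 aligned families and 10^5 reads — large enough that
multinomial noise is well below the effects being tested, small enough to
fit comfortably in a desktop R session; the whole suite completes in a few
seconds. The EM works on `Φ` in dense `N × M` arithmetic, the
log-likelihood in log space throughout. Degenerate situations are handled
explicitly rather than by convention: an aligned family with positive
count but zero marginal probability is an error (the initialization made
it unreachable); an M-step column with `Ψ_j = 0` keeps its previous `α`
column and receives a vanishing `β_j` before renormalization; an all-zero
count vector is rejected.

## Known limitations

* The method corrects mixing among the families present in the filtered
  alignment output; families whose reads were entirely lost below the
  score cutoff are invisible to it.
* The quality of the corrected profile hinges on the learning sample's
  transferability; a learning sample from a very different community
  composition degrades the start and may select a poorer local maximum.
* Read-count bias from CDS length and conservation is not modeled.
* `α̂` is exposed in the fit result but is estimated from a single
  sample's margin; treat it as a by-product, not as a calibrated confusion
  estimate.
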