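---
title: "Residue-type recognition from chemical shifts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-type recognition from chemical shifts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftlda)
```

## The statistical model

A spin system is the vector of chemical shifts (in ppm) of one
residue's nuclei: amide proton HN, amide nitrogen N, carbonyl CO, alpha
and beta carbons CA/CB, and alpha and beta protons HA/HB. In disordered
proteins the secondary-structure contribution to these shifts is mostly
averaged out, so shifts of a given residue type scatter approximately
normally around type-specific means. `shiftlda` exploits this: each
residue type $k$ is modeled as a multivariate Gaussian with mean
$\mu_k$ and covariance $\Sigma_k$, estimated with the **population**
normalization

$$\mu_k = \frac{1}{n_k}\sum_{i=1}^{n_k} x_i,\qquad
  \Sigma_k = \frac{1}{n_k}\sum_{i=1}^{n_k}(x_i-\mu_k)(x_i-\mu_k)^\top .$$

The linear classifier assumes a covariance shared by all classes, the
count-weighted **pooled covariance**

$$\Sigma_{\mathrm{pooled}} = \frac{1}{N}\sum_k n_k\,\Sigma_k ,$$

and scores a query $x$ per class with

$$f_k(x) = \mu_k^\top \Sigma_{\mathrm{pooled}}^{-1} x
  - \tfrac12 \mu_k^\top \Sigma_{\mathrm{pooled}}^{-1}\mu_k
  + \ln \pi_k,\qquad \pi_k = n_k/N .$$

The $1/n_k$ (rather than $1/(n_k-1)$) convention is used deliberately
throughout so that $\Sigma_{\mathrm{pooled}}$ is exactly the weighted
average of the per-class matrices; the difference is a scalar factor
that Pareto scaling largely absorbs anyway. The quadratic variant
(`qda_score()`) drops the shared-covariance assumption and scores with
the per-class Gaussian log-density plus log prior; with all
$\Sigma_k = \Sigma_{\mathrm{pooled}}$ it reproduces the linear ranking
exactly, which the test suite verifies.

**Posterior probabilities.** The reference analysis reports per-type
probabilities but no formula. Under the shared-covariance Gaussian
model the posterior is exactly the softmax of the $f_k$, so
`posterior_probabilities()` computes
$p_k = e^{f_k - \max_j f_j} / \sum_l e^{f_l - \max_j f_j}$
(the max subtraction is for numerical stability only). This is a
standard derivation, not a guess about different mathematics: any
formula consistent with the stated model is monotone-equivalent to it.

**Tie-breaking.** Exact score ties are resolved alphabetically by
one-letter code. Classes are stored sorted, so `which.max`-style
selection implements this deterministically.

## Pareto scaling

Chemical-shift referencing can differ by small constant offsets between
laboratories. Training and query shifts are therefore normalized
*jointly*: for each shift column, the center is the mean of the
concatenated training + query values and the divisor is
$\sqrt{\sigma}$, the square root of that concatenation's population
standard deviation (Pareto scaling — softer than unit-variance
autoscaling, so large-dispersion nuclei such as N keep more weight).
Mean-centering is adopted as the standard definition of Pareto scaling;
a centering-free variant would differ only by a constant shift per
column, which cancels in score differences between classes but not in
the stored state, so the conventional form is used and documented. The
scaling is recomputed for every restricted model (below), because its
columns and row set differ.

## Incomplete spin systems: restricted models

Spin systems often lack shifts — systematically (glycine has no CB/HB,
proline no HN; the residue preceding a chain typically shows only the
(i−1)-type shifts) or accidentally. A query with present-shift set $P$
is classified by a fresh model trained on only the columns in $P$,
using the training spin systems that have all of them, Pareto-scaled
jointly with the query. Consequences worth stating:

* A model over all seven shifts cannot contain glycine or proline
  (no training row of those types is complete), and a query exhibiting
  CB/HB (or HN) cannot be glycine (or proline) anyway. Restricted
  models therefore *silently drop* structurally impossible classes and
  assign them zero posterior, rather than failing. A class that is
  empty for any other reason (data sparsity) is still an error, because
  silently dropping it would bias predictions toward the remaining
  types.
* Classes must have $n_k \ge 2$ complete rows; a covariance needs two
  points.
* Within one `classify_spins()` call, queries are grouped by
  missingness pattern and one restricted model is fitted per pattern
  (the pattern cache), which keeps per-residue cost negligible.

**Class universe.** Callers pass `allowed_types` — the residue types in
the protein under study; types absent from it are removed from
training, since leaving them in can only steal posterior mass.

**Degenerate covariances.** If a (pooled or per-class) covariance is
not positive definite, $\lambda\,\overline{\mathrm{diag}}\,I$ is added
with $\lambda = 10^{-6}$, escalating by decades to $10^{-3}$ before
failing. Real training tables (seven features, $\ge$ hundreds of rows)
never need this; degenerate synthetic fixtures do.

## Evaluation protocols

**Protein-level leave-one-out.** Hold out one protein, train on the
rest (types limited to the held-out protein), classify its spin
systems, report per-protein accuracy and the residue-weighted mean
$\sum_p a_p n_p / \sum_p n_p$. Two eligibility modes exist because the
published figures differ on the treatment of incomplete spin systems:
`"complete"` scores only spin systems complete for the subset (with
glycine and proline exempted from their structurally absent shifts),
while `"restricted"` scores everything with at least one usable shift
through restricted models. The two modes bracket the published 89.51 %
vs 89.43 % pair for the full shift set; both are exposed rather than
guessing which inclusion rule produced which number.

**Confusion charts** are row-normalized: row $k$ shows how true type
$k$ was distributed over predicted types, so the diagonal is per-type
sensitivity and every occupied row sums to 1.

**Permutation importance.** Train once on the intact table; for each
shift column and repeat, shuffle that column alone in a copy and
measure the error rate (1 − accuracy) of the intact model on it.
Shuffling destroys the column's association with residue type while
preserving its marginal distribution. 1,000 repeats per column give
publication-grade error bars; tests use 30–200 repeats, which changes
only the Monte-Carlo noise, not the ranking. One seeded generator per
run makes results bit-reproducible.

## Chain mapping

For a chain (optionally preceded by a partially observed "pre"
residue), each position retains the types with posterior at or above
`inclusion_threshold` (default 0.01), capped at the `top_k = 5` most
probable. The reference narrative says types "predicted as probable"
without an operational definition; these two knobs are the package's
operationalization and both are exposed. Candidate sequences are the
Cartesian product over positions, each scored by the product of its
per-position posteriors; with threshold 0 and no caps the joint
probabilities sum to 1 exactly, a property the tests assert. Candidates
absent from the protein sequence are *discarded but kept in the report*
with their probabilities untouched, because the discarded combinations
are themselves diagnostic (a high-probability discarded candidate
signals a borderline classification). All overlapping occurrences are
reported with 1-based positions; a chain is "unambiguously mapped" when
exactly one surviving candidate has exactly one position. An empty
survivor set is a reported outcome, not an error — it is the failure
mode where the classifier excluded the true type at some position and
manual intervention is needed.

`manual_baseline()` reproduces the traditional manual typing used as
comparison: G from the structural absence of beta shifts, A/S/T from CB
windows (15–23, 60–66.5, 66.5–73 ppm), X otherwise. The windows are
deliberately wide, non-overlapping brackets of the disordered-state CB
ranges. `structural_exclusions()` encodes the covalent-structure rules
(beta shifts exclude G; two distinct HB protons exclude A/I/T/V) as an
optional posterior mask.

## Assignment transfer

References peaks (labeled `X##-Y##`, first residue = preceding) are
matched to experimental peaks within a per-axis window (default 0.1 ppm
H, 0.5 ppm N — chosen to cover typical condition-induced peak movement;
no radius is stated in the reference narrative). Candidates rank
lexicographically by (class consistency of the preceding type,
posterior of that type, −distance), with distance Euclidean after
dividing H by 1 ppm and N by 5 ppm to balance dispersion. Assignment is
greedy one-to-one in order of decreasing margin between the two best
class-consistent candidates, and a match is flagged ambiguous whenever
two or more class-consistent candidates exist — the tool always emits
the full ranked candidate table, since the reference workflow resolves
such cases manually. With flat posteriors the procedure degrades to
nearest-neighbor matching, which is precisely the failure mode the
classifier exists to prevent; the tests include a case where
nearest-neighbor is wrong and class consistency corrects it.

## The synthetic generator, and what a green test proves

`default_class_model()` ships 20 residue-type mean vectors with
plausible random-coil-like values (e.g. Gly CA ≈ 45 ppm, Ala CB ≈ 19
ppm) and diagonal covariances (defaults: HN 0.25, N 2.5, CO 0.7, CA
0.7, CB 0.8, HA 0.15, HB 0.20 ppm — the order of magnitude seen in
disordered-protein shift scatter). These numbers are **synthetic
fixture data**, stored in `extdata/synthetic_class_model.tsv` and
clearly labeled as such; they are not database statistics and must not
be used as reference shifts. Class frequencies follow typical proteome
abundances. Generators are pure functions of (parameters, seed):
`sample_protein()` applies the structural missingness rules plus an
optional completely-at-random dropout; `sample_chains()` samples
contiguous runs that never include a proline member (amide-detected
chains break at prolines); `jitter_peaks()` emulates condition-shifted
peak lists.

What the generator does *not* emulate: sequence-neighbor effects on
shifts, heteroscedastic or correlated within-class scatter, systematic
referencing errors beyond what joint scaling removes, and the long tail
of real missingness mechanisms. A green synthetic test therefore
establishes the correctness of the *machinery* (estimators, scoring,
bookkeeping, invariants) and its behavior as separation and noise vary
— not the published accuracy figures, which depend on the real BMRB
training distribution. The published-scale check is implemented and runs
when the 17 training entries are available locally
(`tests/testthat/bmrb/`); in an offline environment it reports its
unavailability as a test failure rather than silently passing.

## Numerical and interface choices

* Missing shifts are `NA`, never sentinels; stereo pairs HB2/HB3 (and
  glycine HA2/HA3) collapse to one value by arithmetic mean, the least
  surprising reduction given that the classifier treats HB as a single
  feature (a lone stereo partner is used as-is; the raw values are kept
  in extra columns for the structural-exclusion rules). The atom-name
  normalization table is shipped as versioned data, not code branches.
* Models serialize to versioned JSON (`save_model()` / `load_model()`);
  scaling state is stored with names so round-trips are exact.
* The CLI resolves configuration as flags > config file > defaults,
  writes every report as TSV, and drops a `manifest.json` (command,
  versions, seed, input MD5 digests) into each output directory; equal
  config + seed + inputs give byte-identical outputs.
* Exit codes: 0 success, 1 validation error, 2 runtime error.

## Known limitations

* No automatic chain formation from sequential connectivities and no
  global combinatorial assignment — chains are inputs, as in the
  workflow this package supports.
* The transfer procedure automates a narrative that is semi-manual in
  the reference workflow; its greedy one-to-one policy is a documented
  design choice, and the ranked candidate table is the authoritative
  output for careful users.
* Restricted models are refitted per missingness pattern; with
  pathological per-residue missingness (every spin system a unique
  pattern) classification cost grows linearly in the number of
  patterns.
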