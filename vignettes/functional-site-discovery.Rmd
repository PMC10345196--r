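---
title: "Discovering functional sites from stability and conservation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering functional sites from stability and conservation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conserved residues are important, but conservation alone cannot say *why* a
residue is important. Most proteins must fold to function, so a position can
be conserved because substitutions destabilize the fold (and the protein is
degraded), or because the residue does something directly -- catalysis,
binding, allostery, recognition. Experimentally the two are separable with
paired multiplexed assays of variant effects (MAVEs): one assay reading out
cellular abundance, one reading out function. A variant with wild-type-like
abundance but lost activity -- *stable but inactive* (SBI) -- points at a
residue whose conservation is functional rather than structural.

`funsites` reimplements this logic computationally. Substitution-level
predictions of stability change and evolutionary tolerance, combined with
simple structural and physicochemical descriptors, are enough to learn the
four phenotype classes that the paired assays define, and aggregating
variant predictions yields residue-level functional-site calls.

## The model

### Training labels from paired assay scores

Each assay's score distribution is fitted with a three-component Gaussian
mixture (`fit_three_gaussians()`): a low mode, a high mode, and a middle
component that only absorbs intermediate-effect variants. The decision
threshold is the score where the weighted densities of the two *outer*
components are equal (`intersection_threshold()`); the equality is a
quadratic in the score and the root lying strictly between the outer means
is taken (with equal outer standard deviations the equation degenerates to
a linear one with the single root
$\frac{\mu_1+\mu_3}{2} + \frac{\sigma^2 \ln(w_1/w_3)}{\mu_3-\mu_1}$).
Binarizing both assays and crossing the calls gives the four classes:

| abundance | activity | class |
|---|---|---|
| high | high | `WT_LIKE` |
| low  | low  | `TOTAL_LOSS` |
| high | low  | `SBI` |
| low  | high | `LOW_ABUNDANCE_HIGH_ACTIVITY` |

Assay orientation (whether a large score means functional) is a required
input, never inferred from the data; a tie exactly at the threshold counts
as `high`, a fixed documented convention for a measure-zero event.

### The eight variant features

For a substitution at position $i$ to amino acid $a$:

1. **ddG** -- predicted stability change, consumed from an upstream
   predictor. Values arriving in Rosetta energy units are divided by 2.9 to
   land on a kcal/mol scale and all values are clamped into [0, 5] kcal/mol
   (`normalize_ddg()`; the clamp is idempotent and order-preserving).
2. **ddE** -- evolutionary tolerance of the substitution from an MSA-based
   model, 0 (conservative) down to about $-7$ (incompatible). Used as read;
   excursions outside $[-7, 0]$ are warned about, not altered.
3. + 4. **Residue averages** of ddG and ddE: the mean over all scored
   substitutions at position $i$ (wild-type self-substitutions never count).
5. + 6. **Neighbour averages**: all scored substitutions at positions
   $i-1$ and $i+1$ pooled, then averaged. At a terminus the single
   existing neighbour is used.
7. **Hydrophobicity of the target amino acid** (Kyte-Doolittle by default;
   any 20-entry scale can be supplied as a TSV -- the scale is data, not
   code).
8. **Weighted contact number**,
   $\mathrm{WCN}_i = \sum_{j \neq i} s(r_{ij})$ with
   $s(r) = \frac{1-(r/r_0)^6}{1-(r/r_0)^{12}}$ over C$\alpha$--C$\alpha$
   distances and $r_0 = 7\,$Å. As printed the switching function is $0/0$
   at $r = r_0$; the implementation uses the algebraically identical
   factorization $s(r) = 1/(1+(r/r_0)^6)$, which removes the singularity
   and takes the limit value $1/2$ there. All chains present in the model
   contribute, so oligomer input yields oligomer-context contact numbers.

Rows missing any feature are flagged incomplete and excluded from training
and prediction, with coverage reported (positions covered / length).

### Classifier

Gradient-boosted trees with a multinomial cross-entropy objective and L2
leaf regularization (xgboost backend, single-threaded so that retraining
with the same seed is bit-identical). The iteration count is fixed first by
early stopping on a stratified hold-out (patience 50, cap 2000); depth,
learning rate and L2 strength are then scanned over a grid (default
4/6/8 x 0.03/0.1/0.3 x 1/3/10) by mean stratified 5-fold CV accuracy.
Reported metrics are accuracy, per-class precision/recall, and the
generalized (Gorodkin) multiclass Matthews correlation coefficient; a
zero-variance denominator (e.g. a constant predictor) yields MCC 0 by
convention. Two baselines ship with the model: a most-frequent-class null
model (ties broken lexicographically) and a random-forest comparator run
on the *same* folds with an identical metrics schema.

### From variants to residues

A residue is assigned a class when at least half of its classified
variants share that class; positions where no class reaches 50% stay
unclassified, as does an exact two-way 50/50 tie (a tie has no
majority-like winner, and the assignment rule's own wording -- remaining
positions are not classified -- favours abstention). Fractions use the
variants actually classified at the position as denominator, so partial
coverage is handled naturally. Residues assigned `SBI` are the predicted
functional sites. For single-assay validation the four classes project
onto two: function mode (`WT_LIKE`/`LOW_ABUNDANCE_HIGH_ACTIVITY` =
functional) and abundance mode (`WT_LIKE`/`SBI` = high).

Comparing two runs of the same protein -- typically monomer-context versus
oligomer-context stability input -- tabulates per-position class
transitions (`compare_runs()`). Positions that are functional sites with
monomer input but total-loss with oligomer input are highlighted as
interface candidates: substitutions there destabilize the complex but not
the isolated chain.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `rosetta_divisor` | 2.9 | -- | Rosetta energy units to kcal/mol |
| `clamp_low`, `clamp_high` | 0, 5 | kcal/mol | informative ddG range |
| `r0` | 7.0 | Å | contact switching midpoint |
| `exposure_threshold` | 0.20 | fraction | buried/exposed split (analysis only) |
| `folds` | 5 | -- | stratified CV (20% validation sets) |
| `assign_fraction` | 0.5 | fraction | residue class assignment rule |
| `distance_cutoff` | 10 | Å | proximity to reference sites |

All of them are config keys of `run_pipeline()` and are recorded in the
output manifest.

## Design choices where the design was open

- **Neighbour score**: pooled variant values from $i\pm1$ rather than the
  mean of the two residue means. With full 19-substitution coverage the two
  readings coincide; under missing data pooling degrades gracefully instead
  of giving equal weight to a thinly covered neighbour.
- **Termini** use whichever neighbour exists rather than being dropped:
  discarding terminal positions would silently lose real sites.
- **Residue numbering**: author numbering from the PDB is kept by default
  (it is reference-aligned for the intended inputs); `renumber = TRUE`
  remaps to 1..n per chain and reports the mapping. Blind remapping of
  structures with unresolved gaps would misalign every downstream join.
- **Mixture fitting**: own EM with seeded k-means initialization and 10
  restarts (best log-likelihood kept), components returned sorted by mean.
  All three components have free weight, mean and variance. A standard-
  deviation floor of $10^{-4}$ sd(data) guards against component collapse.
- **Intersection root**: of the up-to-two real roots, the one strictly
  between the outer means -- the decision-boundary reading of "cutoff".
- **WCN** uses the full pairwise sum, no neighbour-list cutoff: the
  intended proteins are at most a few thousand residues, where the exact
  $O(n^2)$ sum is cheap and unambiguous.
- **Solvent exposure** is computed with a Shrake-Rupley sampler over heavy
  atoms (Fibonacci sphere, 120 points/atom, probe 1.4 Å) normalized by the
  Tien et al. (2013) theoretical maxima and capped at 1. It is an
  analysis-level quantity, not a model feature, so approximate agreement
  with other SASA implementations suffices.
- **Class imbalance** is left unweighted by default; inverse-frequency
  weighting is deliberately out of the default path because the residue
  assignment rule already operates on class fractions.

## What the synthetic generator emulates -- and what it does not

`fixture_spec()` plants one true class per position and draws all 19
substitution scores from class-conditional distributions: stable classes
(`WT_LIKE`, `SBI`) centre ddG at 0.5 kcal/mol, destabilized classes at 4;
conserved classes (`SBI`, `TOTAL_LOSS`) centre ddE at $-5$, tolerant ones
at $-1$ (sd 0.6 each, clipped to the valid ranges). The four classes
occupy the corners of a 2x2 layout, so *no single feature separates any
class* -- the method's motivating observation -- while the combination
separates them cleanly. Assay scores are trimodal (components at 0, 0.5,
1, sd 0.08), the true class dictating the outer component per assay, with
4% of variants reading out as intermediate-effect from the middle
component; intermediate draws land on either side of the threshold, which
bounds label recovery at about 96% by construction. Structures are
idealized C$\alpha$ helix bundles (consecutive spacing ~3.8 Å) with a
central helix providing genuinely buried, high-WCN positions.

The generator does **not** emulate: real energetics or geometry, correlated
errors between ddG and ddE predictors, position-to-position autocorrelation
of classes, assay-specific noise floors, or incomplete mutational coverage.
Passing the recovery tests therefore demonstrates that the pipeline's
machinery is correct and self-consistent -- not that its accuracy on real
proteins matches these numbers. Real-data accuracy depends on upstream
predictor quality and is outside what a self-contained fixture can show.

One consequence of planting classes per position is worth stating plainly:
with variant-level (stratified) cross-validation, variants of one position
occur in both training and validation folds, and position-constant features
(the residue averages) let boosted trees memorize positions. Synthetic CV
accuracy is therefore near the ceiling and should be read as a recovery
check, not a generalization estimate; the feature-relevance test in the
suite scores on a *freshly generated* fixture for exactly this reason.

## Numerical notes

- The EM threshold estimator inherits the sampling noise of the maximum
  likelihood fit: with outer components $\Delta$ apart and $n_k$ points per
  component, the recovered intersection scatters with standard error on the
  order of $\Delta/(4\sqrt{2 n_k})$ around the planted value. At $n = 5000$
  and 5-sd separation that is roughly 0.004-0.005 score units.
- Training determinism requires `nthread = 1`; this is hard-coded. Fold
  assignment, model fitting and every generator draw from one master seed
  with fixed offsets.
- Degenerate inputs error early with actionable messages: all-equal assay
  scores, classes rarer than the fold count, empty hyperparameter grids,
  single-residue structures, missing chains (listing those available).

## Problem sizes

The shipped tests run the classifier recovery at ~4000 variants
(211 positions x 19 substitutions), the end-to-end pipeline at 160
positions, mixture recovery at n = 5000 per simulation, and the oracle
equivalence checks at 100-200 residues x 50 random fixtures. These sizes
were chosen as the smallest at which the planted effects are comfortably
resolved.

## Known limitations

- Residues important for *both* function and stability are, by the
  method's own premise, assigned to the total-loss class and missed as
  functional sites.
- The residue assignment rule needs several classified variants per
  position to be meaningful; with one variant it degenerates to the
  variant call (a `min_variants` filter is available).
- mmCIF input, non-C$\alpha$ contact definitions and secondary-structure
  features are out of scope.
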