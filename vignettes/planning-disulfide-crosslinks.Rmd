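---
title: "Planning disulfide cross-links for protein fold determination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning disulfide cross-links for protein fold determination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofold)
```

## The problem

Fold recognition produces pools of candidate 3-D models for a target sequence,
and the correct fold is often among the highly ranked models without being the
top-ranked one. Disulfide trapping offers a fast experimental arbiter: engineer
a cysteine pair, oxidize, and observe whether an S–S bond forms — a binary
proximity test for a chosen residue pair. Because each experiment costs real
effort, the question is *which* residue pairs to test so that a small panel of
cross-links discriminates the candidate folds as reliably as possible.

`topofold` implements a two-stage plan. Models are first reduced to their
fold-level topology: a binary contact pattern over pairs of secondary-structure
elements (SSEs) shared by the ensemble. Stage 1 selects a small *topological
fingerprint* of SSE pairs that separates the candidate folds; stage 2 selects,
for each fingerprint pair, a panel of residue pairs whose cross-link outcomes
robustly decide whether that SSE pair is in contact. Both stages are
minimum-redundancy maximum-relevance (mRMR) feature selections over discrete
probability models, and both are assessed *before* any experiment by exact
Bayes-error enumeration.

## The probability model over SSE contacts

Each SSE pair $c$ is a binary variable (in contact or not). From the models'
contact graphs we estimate

$$\Pr(c = x) = \frac{1}{|M|}\sum_{i}\sum_{y\in\{0,1\}} Q(x,y)\,
\mathbf{1}[\text{state of } c \text{ in model } i = y],
\qquad Q(x,y) = \begin{cases} q & x = y\\ 1-q & x \ne y\end{cases}$$

with joint tables over two pairs built the same way from co-occurrence counts.
The agreement weight $q$ encodes how much we trust the eventual experimental
evaluation of a contact; $q = 0.8$ by default, the middle of the sensible
range, and the planner's orderings are insensitive to it within 0.7–0.9.

Contact states come from a geometric criterion: an SSE pair is in contact when
at least 5 residue pairs lie closer than 9 Å (Cβ–Cβ) *and* at least 20% of each
SSE's residues have a partner within 9 Å in the other SSE. We require the
fraction on both SSEs (the conservative reading of "each"). Glycine, having no
Cβ, gets a virtual Cβ placed at ideal tetrahedral geometry (1.53 Å bond,
109.47° to both backbone neighbours, L-chirality) so the distance definition is
uniform across residue types.

Relevance of a pair is its entropy $H(c)$ in bits; redundancy between pairs is
their mutual information $I(c, c')$. The fingerprint grows greedily, adding at
each step the pair maximizing

$$H(c) - \frac{1}{|F|}\sum_{c' \in F} I(c, c'),$$

with the first pick maximizing $H(c)$ alone and argmax ties broken
lexicographically for determinism. The search stops when the best incremental
score drops below 0.01 bits (we interpret the threshold on the raw incremental
difference, in bits; the base of the logarithm is not essential, only orderings
and the threshold scale are affected).

One structural consequence worth knowing: with $q < 1$ every marginal is
confined to $[1-q, q]$, so $H(c) \ge H(q) \approx 0.72$ bits at $q = 0.8$ and
the 0.01-bit threshold only ever fires at $q \approx 1$. In practice the
fingerprint is therefore an *ordering* of the universe and `maxPairs` (or the
enumeration cap) is the effective size control. We keep the threshold because
it is part of the method's definition and it does bind for near-deterministic
$q$.

## Plan assessment: Bayes error, ties, none-of-the-above

Given a fingerprint $F$ and data vector $X$ (one bit per pair), the likelihood
of a model is the naive product $\Pr(X\mid m) = q^{\#\text{agree}}
(1-q)^{\#\text{disagree}}$ over its signature restricted to $F$. Before any
experiment we enumerate all $2^{|F|}$ datasets (refusing beyond $|F| = 20$) and
compute:

* **Bayes error** $\epsilon$: the mass of (model, dataset) cases in which a
  fold with a *different* restricted signature strictly beats the correct
  model. Being matched by a same-signature model is a tie, not an error, and
  ties contribute zero.
* **Expected tie ratio** $\tau$: the mass of cases in which the correct model
  is tied for the maximum with a model of a *different fold*. Fold identity is
  the full-universe contact signature: folds the fingerprint has not yet
  separated have identical restricted signatures and tie permanently, so
  $\tau$ starts high and falls as discriminating pairs are added, flat-lining
  once the remaining co-winners genuinely share a fold. This formulation keeps
  error and tie events disjoint ($\epsilon + \tau \le 1$); the exact indicator
  is the one design point where the written formula is ambiguous, and we chose
  the reading that yields the expected trend curves and the permanent-tie
  limit.
* **None-of-the-above ratio** $\nu$: the fraction of the $2^{|F|}$ datasets for
  which some *uncovered* fold vector (not matching any model's signature)
  strictly outscores the best covered fold. No prior is placed on datasets and
  uncovered folds are uniform, making $\nu$ a direct count of outcomes that
  would force a "no model is right" call. Early in the trajectory the few
  distinct signatures still span all fingerprint values and $\nu = 0$; it grows
  as the value space outpaces the fold set. For any $q > 0.5$ a dataset
  contributes exactly when it is itself uncovered, a useful cross-check on the
  enumeration.

Interpretation of real data mirrors the assessment: the tied-for-optimal model
set is returned, and none-of-the-above is declared when an uncovered fold beats
every model, in which case the nearest uncovered vector is reported.

## Stage 2: cross-link selection under noise

For a fingerprint SSE pair we pool the residues lying inside the pair's matched
annotation interval in at least half of the models possessing the SSE, and take
as candidates the union over models of residue pairs with Cβ–Cβ distance at
most 19 Å (the cross-linkable window for engineered disulfides; the prior for
a link is tiered 0.95 / 0.5 / 0.05 for distances ≤ 9 Å, 9–19 Å, > 19 Å,
reflecting measured disulfide formation rates). Two noise sources are marginalized:

* **Threading misalignment**: each SSE may be registered off by $\delta$
  residues. $\Pr(\delta)$ puts 0.5 at zero and decays exponentially to
  $\pm\delta_{\max}$ (default 2, decay 1/residue); offsets are independent per
  SSE and shift the whole SSE rigidly. Offsets walking outside the model fall
  into the far tier.
* **Backbone flexibility**: alternative backbones are sampled along the lowest
  non-trivial mode of an anisotropic elastic network on the Cα trace (unit
  springs, 10 Å cutoff), 5 samples evenly spaced in ±3 Å maximum Cα
  displacement, weighted by the Hookean energy of the mode with $kT$ chosen so
  the extreme sample has 5% of the central weight. The mode shape and
  eigenvalue agree with an independent normal-mode implementation to numerical
  precision (see the test suite). A network without exactly six near-zero
  modes falls back to the unperturbed structure with a warning.

Cross-links are conditionally independent given (model, offsets, backbone), so
joints marginalize products of per-link tier probabilities over the shared
latent variables. Relevance of a candidate link is $I(\ell, c)$ with the
stage-1 $\Pr(c)$ as class weight (a configuration switch restores a uniform
prior), the in-contact class using noise-marginalized link probabilities and
the no-contact class the background rate 0.05. Redundancy is $I(\ell, \ell')$
with the same marginalization. Selection is greedy mRMR to a fixed plan size
(default 10 experiments).

Data interpretation is deliberately simple: with $k$ of the planned links
detected, $\Pr(Y \mid c{=}1)$ is a logistic in $k$ centered at $k_0 = 3$ (the
minimum count to start believing contact). The printed anchors 0.05 / 0.5 /
0.95 at $k = 0, 3, 6$ fix the slope to $\ln(19)/k_0$, which reproduces them
exactly; the no-contact likelihood is the mirrored logistic, so the decision
reduces to $k > k_0$, with the $k = k_0$ tie resolved conservatively to "not in
contact" and flagged. Plans smaller than $k_0 + 1$ links scale $k_0$ down to
keep the decision well-defined. The plan's Bayes error (Eq.-level definition:
uniform prior on $c$, exact enumeration of all outcome vectors) uses a
generative law the text leaves open; we generate $Y$ under $c = 1$ from the
in-contact models' noise-marginalized per-link conditionals and under $c = 0$
as independent background firing at 0.05, consistent with the tiers and their
false-positive floor.

## The synthetic ensemble generator

CASP-style decoy sets are emulated at desk scale: $n$ idealized SSEs (helix:
1.5 Å rise, 100°/residue, 2.3 Å radius; strand: 3.3 Å rise) placed on a line
lattice with 10 Å spacing, chain directions alternating so laterally adjacent
SSEs pack against each other. A *topology variant* is a slot permutation with a
distinct adjacency structure, so variants differ in which SSE pairs are in
contact; models are assigned to variants round-robin. Per model, each SSE's
residue numbering may shift by up to ±`boundaryJitter` residues (threading
register error) and all atoms of a residue share a Gaussian displacement of sd
`coordinateNoise` (a smooth perturbation; deliberately *not* independent
per-atom noise, which would break the Cβ–Cα bond geometry). Defaults — five
12-residue SSEs, 30 models, 3 variants, ±1 residue jitter, 0.5 Å noise — were
chosen once as a plausible desk-scale analogue of real fold-recognition
ensembles (tens to ~200 models, 5–7 SSEs, register errors of 1–2 residues). The ground
truth is the noise-free structure of a designated variant and can be excluded
from the model pool to exercise the none-of-the-above path. Every generated
model is written to PDB and read back through the package's own input path.

What the generator does *not* emulate: real decoys differ in loop geometry,
SSE lengths and partial folds; contacts here are cleanly block-structured, and
flexibility in real proteins is not confined to one normal mode. Passing the
end-to-end suite therefore demonstrates the correctness and internal
consistency of the planning machinery under controlled conditions, not
performance on CASP archives.

## Simulation study and problem sizes

The end-to-end harness (`runEndToEnd`) simulates outcomes from the ground truth
(a link forms iff its Cβ–Cβ distance is < 9 Å — stricter than the 19 Å planning
window), interprets them into contact states and a fold decision, labels each
model correct/incorrect by comparing full-universe signatures to the truth at
contact fractions $r \in \{0.05, 0.1, 0.15, 0.2\}$, and runs a ROC analysis
with the fold-level likelihood as the ranking score (the only model-level score
the method produces; positives are the correct-fold models). AUC uses the
standard trapezoid / midrank convention via pROC, cross-checked against a
pairwise Mann–Whitney oracle.

The shipped study sizes are 20-model, 4-SSE, 2-variant noiseless fixtures swept
over 200 seeds for the recovery and none-of-the-above checks, and 6–8-link
plans for the Monte-Carlo versus enumeration comparisons; these sizes make each
claim exactly enumerable or statistically decidable (3σ) while keeping a full
run of the suite in the minutes range on one core. With zero jitter and noise
the per-seed pipeline is deterministic, so the 200-seed sweep functions as a
determinism-and-robustness sweep across fixture instantiations.

## Numerical choices and degenerate inputs

* Probabilities are compared exactly; equal Hamming distances give exactly
  equal likelihoods, so ties are decided without tolerances.
* $q = 1$ degenerates cleanly ($0^0 = 1$), turning likelihoods into indicator
  functions; $q \le 0.5$ is rejected (relevance/redundancy become degenerate).
* Mutual information of an edge with itself is its entropy (same random
  variable); for two *distinct* edges with identical states the q-smoothing
  keeps $I < H$ except at $q = 1$ — full redundancy is a $q \to 1$ limit.
* Greedy argmax ties break lexicographically in both stages; the incremental
  mRMR scores are *typically* but not provably monotone decreasing (a later
  pick can be less redundant against the grown set than an earlier pick was
  against a smaller one), so the class validity does not enforce it.
* Enumeration refuses beyond $2^{20}$ outcomes in both assessment paths.
* Models with fewer than two SSEs, SSE pairs with no cross-linkable candidate,
  and label sets without both classes produce explicit warnings/errors or an
  "AUC undefined" marker rather than silent values.

## Limitations

The planner treats SSE pair contacts as conditionally independent given the
model (both in the fold likelihood and in the per-pair planning); correlated
misalignment across SSEs and local unfolding are not modelled. Cross-link
formability is a three-tier distance prior rather than a geometric disulfide
energy. The none-of-the-above machinery reasons over fingerprint value space,
not over all physically realizable folds. These follow the method's stated
scope; extensions would slot in at `linkProbTiers`, the noise model, and the
fold prior respectively.
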