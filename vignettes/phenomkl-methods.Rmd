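---
title: "Methods: phenotypic multi-task multi-kernel learning"
author: "phenomkl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic multi-task multi-kernel learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Missense variants in ion-channel genes are labelled by their net biophysical
effect: gain-of-function (GOF) or loss-of-function (LOF). The two classes
correlate with distinct clinical pictures — for several sodium channels the
GOF and LOF phenotypes are essentially different diseases — so clinical
phenotype terms carry genuine label information, alongside sequence/structure
descriptors of the substituted residue and the identity of the channel
itself. `phenomkl` casts all three sources as kernels over variants and
classifies with a C-SVM on the combined Gram matrix.

## Phenotype kernels from an ontology

Variants are annotated with terms from a phenotype ontology, a rooted DAG in
which a term may have several parents. Annotation sets are first
*propagated*: every ancestor of every annotated term is added, up to the
root (`propagate()`). Propagation makes set overlap meaningful — two sets
that share no leaf term can still share informative internal terms.

Three similarity measures are supported (`set_similarity()`,
`similarity_matrix()`):

* **Jaccard**: `|A ∩ B| / |A ∪ B|` on the propagated sets. This is a
  set-intersection kernel and is always positive semi-definite.
* **Resnik**: a term pair scores the information content of its most
  informative common ancestor (MICA), `IC(t) = -log2(f_t)` with `f_t` the
  term's frequency across all propagated sets of the cohort.
* **Lin**: rescales Resnik by the individual ICs,
  `2·IC(MICA)/(IC(t1) + IC(t2))`, defined as 0 when both ICs are 0 (a
  zero-information pair carries no similarity signal).

Resnik and Lin are defined for term *pairs*; variants carry *sets*. The
package aggregates by the symmetric best-match average,
`sim(A, B) = ½(mean_a max_b s(a,b) + mean_b max_a s(a,b))`, with `max` and
`mean` available as options. Aggregation runs over the **raw** annotation
sets (ancestry still enters through the MICA): best-matching over propagated
sets would be dominated by the many shallow ancestors shared by almost all
variants, compressing the dynamic range of the similarity — raw-set
aggregation is the convention of the ontology-similarity toolchain this
mirrors. Jaccard, by contrast, operates on propagated sets (set `sets =
"raw"` to override either choice).

The IC corpus is the set of propagated term sets of the loaded cohort, so
every term that can appear as a MICA has a defined IC; looking up a term
outside the corpus is a hard error rather than a silent 0. MICA ties are
broken toward the lexicographically smallest term id, which makes results
order-independent; since a term's ancestors never have higher IC than the
term itself, ties only arise between equally frequent terms and never change
the similarity value.

## Indefinite similarities and spectral correction

On multi-parent ontologies the Resnik/Lin similarity matrices are often
indefinite, which breaks the SVM's convexity assumptions. `check_psd()`
tests the spectrum against a *relative* tolerance,
`λ_min ≥ -1e-8 · max(1, λ_max)` — Jaccard matrices routinely have
eigenvalues within float noise of zero, and an absolute threshold would
misclassify them. `nearest_psd()` offers three spectral surgeries:

* `clip` — negative eigenvalues to zero; this is the Frobenius-nearest PSD
  matrix (verified in the tests against a direct factor-parameterized
  minimization);
* `flip` — negative eigenvalues change sign (eigenvalues become singular
  values);
* `shift` — adds `|λ_min|` to the diagonal, leaving off-diagonal
  similarities untouched; a no-op on matrices that already pass the check.

Out-of-sample columns can be embedded into a corrected kernel with
`embed_similarities()` (the clip/flip eigenbasis transform; shift leaves
cross-similarities unchanged). Inside cross-validation the package instead
computes similarity matrices, IC and corrections **once on the full loaded
cohort** and lets folds index submatrices. All of these quantities are
label-free, so no label leakage is possible; this matches the practice of
precomputing a single n-by-n Gram matrix for a fixed study cohort and keeps
clip/flip — which are global spectral operations — well-defined across
folds. Users who need strictly inductive kernels for truly external samples
should correct on the training cohort and embed with
`embed_similarities()`.

## Task kernels and the hierarchical decomposition

The channel taxonomy is a rooted tree whose leaves are tasks. Task
similarity uses a shared-ancestor count: with `c(s, t)` the number of nodes
common to the root paths of leaves `s` and `t` (counting the leaf itself)
and `c_max` the deepest leaf's self-count,

```
K_task(s, t) = (a + c(s, t)) / (a + c_max),    a > 0.
```

The exact alignment-based formula of the earlier multi-task work is not
restated in the literature this follows; this surrogate was chosen because
it is monotone in tree proximity, equals 1 on the diagonal for equal-depth
leaves, and degenerates to the pooled (Union) model as `a → ∞` — exactly the
role the baseline parameter plays in the tuning grid `a ∈ {1, 3, 5, 10,
100}`. Edges are treated as unit length. The multi-task kernel is the Schur
product `K_task(task_i, task_j) · K_base(i, j)`, PSD as a product of PSD
factors.

For localized learning, every node `n` of the taxonomy defines the subset
kernel `K_leaves(n)` — the modality combination restricted to samples whose
task lies under `n`, zero elsewhere — and the model kernel is
`K̂ = Σ_n β_n K_leaves(n)` with `β` on the simplex. Putting all weight on
the root recovers Union; uniform weight on the leaves recovers the
block-diagonal Dirac kernel. The latent task similarity
`γ_{k,l} = Σ_{subsets containing both} β_i` reports what the learned weights
imply about task relatedness.

## Weight learning

Where weights are learned they are learned by a *wrapper*: the objective is
the inner-cross-validated AU-ROC of the SVM on the combined kernel. For up
to three modalities the simplex is scanned exhaustively at resolution 0.1;
for more kernels (the per-node weights of the hierarchical decomposition) a
deterministic coordinate-ascent from uniform weights at resolution 0.2 with
at most two passes is used. Candidate weightings are ordered by distance
from the uniform point, so exact objective ties resolve toward the least
extreme combination — a meaningful choice because a kernel-sum SVM is only
mildly degraded by one uninformative kernel, and plateaus in the objective
are therefore common.

In the hierarchical mode, nodes whose sample block has fewer than 10
samples or a single class fall back to uniform modality weights — small
channel-specific blocks cannot support weight estimation, and the fallback
mirrors how sparsely represented channels must be handled in real cohorts.

For `mkl_global` and `mkl_hierarchical`, hyperparameters (C, σ, a, measure,
correction) are first selected by inner CV with uniform weights, and the
kernel weights are then learned on the outer-training block at the selected
grid point. Folding the wrapper inside the full grid would multiply the
search cost by the number of grid points for little benefit: weight learning
is a refinement step on top of the uniform-weight model.

## Evaluation protocol

`nested_cv()` runs stratified nested k-fold cross-validation (default
k = 5 outer and inner). Inner folds of each outer-training set select the
grid point with the best mean inner AU-ROC; ties break toward smaller `C`,
then larger `σ` (smoother models). The fold model is refit on the full
outer-training set and scored on the held-out fold; aggregates are mean ±
SD over outer folds. Stratification is by label only — per-task counts in
realistic cohorts are too small to stratify by task as well. GOF is the
positive class throughout (sensitivity, AU-PRC); this is a documented
convention, not learned. Curve metrics are computed from raw decision
values (rank-statistic AU-ROC with midrank ties; step-integrated AU-PRC
over score-tie blocks), with no probability calibration. Degenerate 0/0
metric ratios are reported as 0. The `dirac` baseline trains one SVM per
task; a per-task training block with a single class yields a constant-class
vote with decision value ±1.

## Perturbation experiments

`perturb_termsets()` simulates imperfect phenotyping on the raw annotation
sets before similarity computation, parameterized by a term ratio `r`:
`r < 1` keeps `round(r·|set|)` terms (half-up rounding, floor of one term —
a set is never emptied); `r > 1` adds `(r-1)·|set|` terms sampled without
replacement from the ontology's terms outside the set, per variant. A ratio
of 0.25 on a 4-term set removes 3 terms; a ratio of 4 adds 3 terms per
original term. Propagation is re-applied afterwards, since the similarity
measures operate downstream of propagation. `robustness_sweep()` wraps this
in the full nested-CV loop per (ratio, measure, seed).

## Confidence analysis

`projection_histogram()` projects training samples onto the SVM's normal
vector; the projection is the margin-scaled decision value `f(x)` — support
vectors fall in `[-1, 1]` — rather than the geometric (`‖w‖`-normalized)
distance, because the margin band is stated on that scale.
`confidence_split()` labels samples with `|f| ≤ 0.5` low-confidence
(boundary inclusive), and `feature_association()` compares each feature
between the groups with a two-sided unpaired Wilcoxon rank-sum test
(exact for small tie-free groups) and Benjamini-Hochberg adjustment across
features at α = 0.05. Features constant across both groups get p = 1 and a
flag rather than an error.

## The synthetic cohort generator

`generate_cohort()` builds complete cohorts so every stage is testable
without external data. Defaults mirror the cohort statistics of the
curated sodium-channel variant set this framework targets: 375 variants,
164/375 GOF, 9 tasks in a two-level family taxonomy, 62 features, a
446-term multi-parent ontology, and raw set sizes with mean 9 clipped to
3–42 terms (Poisson sizes; the real cohort's median of 9 is matched by
construction).

* **Ontology**: terms are created in order and each non-root term receives
  1..`max_parents` parents among earlier terms — acyclic by construction,
  single root, and multi-parent (so IC-based similarity matrices exhibit
  the indefiniteness pathology that motivates spectral correction).
* **Phenotype signal**: disjoint class-preferred and task-preferred term
  pools; each drawn term comes from the class pool with probability
  `phenotype_effect`, else from the task pool with probability
  `task_effect`, else uniformly. One knob per signal source, directly
  interpretable as a mixture weight.
* **Features**: Gaussian with a task-level random intercept (SD 0.5) and a
  per-class mean shift of `feature_effect` SD units. Defaults
  `phenotype_effect = 0.5`, `task_effect = 0.3`, `feature_effect = 0.15`
  give moderate, non-saturating signal in both learnable channels — weak
  enough that the classes overlap, as they do in real cohorts.

What the generator does *not* emulate: real HPO semantics (term pools are
random, so there is no clinically meaningful hierarchy of signs), feature
correlation structure (real sequence/structure descriptors are strongly
collinear), per-channel class imbalance patterns, and annotation biases
(e.g. deeply phenotyped syndromic cases). Passing recovery tests therefore
demonstrates that the pipeline extracts planted class-dependent phenotype
structure — not that real cohort performance is reproduced.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on cohorts
of n = 300 variants over 9 tasks with 10 seeds and a single-point
hyperparameter grid (C = 1, σ = 1, a = 5, Jaccard/clip); these sizes give
stable averages for the qualitative recoveries (chance-level AU-ROC on null
cohorts, MKL > MTL under planted phenotype-only signal, MKL → MTL
convergence under keep-one-term sparsity, higher accuracy in the
high-confidence projection group) while keeping a complete run in the order
of a minute. The sparsity-convergence check uses the generator defaults —
both modalities carrying signal — because that is the regime in which the
multi-task model retains its own accuracy while the phenotype channel is
drained; under a phenotype-only cohort a single kept class-pool term still
identifies the class often enough to leave a residual gap.

Kernel matrices are plain base-R matrices with sample-id dimnames and a
`psd_status` attribute; symmetry is enforced to a relative 1e-8 before any
eigendecomposition, and corrected matrices are re-symmetrized to kill
floating-point drift. The SVM backend is `kernlab::ksvm` on precomputed
Gram matrices; `train_svm()` re-orients the decision function so positive
values always predict GOF and exposes the full-length dual coefficient
vector, which the tests use to verify the KKT conditions (α ∈ [0, C],
Σα_i y_i ≈ 0, margin-band membership of support vectors) independently of
the solver.

## Known limitations

* Hierarchical weight learning is the computational bottleneck: its cost is
  roughly (number of nodes) × (simplex grid) × (inner folds) SVM fits per
  outer fold. The coarser ascent resolution bounds this but limits weight
  granularity to 0.2 for the node-level β when the taxonomy has more than
  three nodes.
* The transductive kernel convention means `nested_cv()` estimates
  generalization to variants whose phenotype terms were visible (unlabelled)
  when the kernel was built; truly external prediction should use
  `embed_similarities()`.
* The wrapper objective plateaus when kernels are redundant, so learned
  weights are identified only up to regions of equal inner AU-ROC; uniform
  tie-breaking makes the output deterministic but weights should be read as
  sufficient, not uniquely optimal.
* `read_obo()` implements the id/name/is_a/is_obsolete subset of OBO only;
  relationship types other than `is_a` are ignored.
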