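# phenomkl

Phenotypic multi-task multi-kernel learning for predicting the net
functional effect — gain-of-function (GOF) versus loss-of-function (LOF) —
of ion-channel missense variants.

Missense variants in voltage-gated ion channels cause a wide spectrum of
neurological and cardiac disease, and whether a variant increases or
decreases channel activity directly shapes diagnosis, prognosis and drug
choice. Electrophysiological characterization is slow and expensive;
`phenomkl` predicts the GOF/LOF label from three complementary data
modalities, each expressed as a kernel over variants:

* **phenotype kernel** — semantic similarity between the patients' clinical
  phenotype term sets in an ontology (Jaccard, Resnik or Lin similarity,
  after propagating every annotation to its ancestor closure);
* **task kernel** — similarity between the channels (tasks) that carry the
  variants, derived from the channel family taxonomy, which enables
  multi-task transfer between related channels;
* **structure kernel** — an RBF kernel over per-variant sequence/structure
  descriptor vectors (consumed as a numeric table, never computed here).

## Model

Each modality kernel is normalized in feature space,
`k̂(x, z) = k(x, z) / sqrt(k(x, x) k(z, z))`, and the modalities are
combined by multiple kernel learning (MKL), `K = Σ_m β_m K_m` with
`β ≥ 0`, using uniform weights, wrapper-learned global weights, or a
localized hierarchical decomposition over the task taxonomy `G`:

```
K̂ = Σ_{n ∈ G} β_n K_leaves(n)
```

where `leaves(n)` is the task subset under node `n`, each node kernel gets
its own modality weights, and the latent task similarity
`γ_{k,l} = Σ_{S_i ∋ k,l} β_i` summarizes what the weights imply about task
relatedness. A C-SVM is trained on the combined Gram matrix.

IC-based phenotype similarities (Resnik, Lin) are generally *indefinite* on
multi-parent ontologies; `nearest_psd()` restores positive
semi-definiteness by spectrum **clip** (negative eigenvalues to zero — the
Frobenius-nearest PSD matrix), **flip** (absolute values — eigenvalues
become singular values) or **shift** (add `|λ_min|` to the diagonal).

Model assessment uses stratified nested k-fold cross-validation (k = 5)
with grid search over cost `C`, RBF bandwidth `σ`, taxonomy baseline `a`,
similarity measure and PSD correction, reporting accuracy, sensitivity,
specificity, F1, Cohen's κ, MCC, AU-PRC and AU-ROC per outer fold
(mean ± SD). Model configurations: `dirac` (one SVM per channel), `union`
(one pooled SVM), `mtl` (task-similarity × structure kernel),
`mkl_uniform`, `mkl_global`, `mkl_hierarchical`.

## Worked example

Every pipeline stage runs on synthetic cohorts generated by the package
itself (no downloads). The generator plants a controllable class-dependent
phenotype signal, so the phenotype kernel is predictive while (here) the
structure features are nearly uninformative:

```r
library(phenomkl)

cohort <- generate_cohort(synthetic_config(n_variants = 150, seed = 42))
cohort
#> mkl_dataset: 150 variants, 9 tasks, 62 features, 446 ontology terms
#>   labels: LOF=88, GOF=62

grid <- hyper_grid(C = c(1, 100), sigma = c(0.1, 1), a = 5,
                   measure = "jaccard", correction = "clip")
nested_cv(cohort, mode = "mkl_uniform", grid = grid, k = 5, seed = 1)
#> Nested 5-fold CV, mode = mkl_uniform, seed = 1
#>   acc          0.779 ± 0.078
#>   sensitivity  0.645 ± 0.148
#>   specificity  0.873 ± 0.098
#>   f1           0.703 ± 0.109
#>   kappa        0.531 ± 0.166
#>   mcc          0.546 ± 0.168
#>   au_prc       0.834 ± 0.094
#>   au_roc       0.854 ± 0.103
```

The phenotype kernel drives this performance: the structure-only
multi-task model on the same cohort stays at chance
(`nested_cv(cohort, "mtl", ...)` gives mean AU-ROC 0.5), so including
phenotypic similarity lifts AU-ROC by ~0.35 here.

Real data enter through five plain-text files (see `load_dataset()`):
an OBO ontology, a TSV of `variant_id` → pipe-separated term ids, a CSV
feature table, a Newick task taxonomy, and a CSV of
`variant_id, task, label`. `write_cohort()` emits the same formats.

A command-line wrapper covers the common workflows:

```sh
inst/scripts/phenomkl simulate --seed 1 --out data/
inst/scripts/phenomkl cv --data data/ --out results/ --mode mkl_uniform \
    --C 1 --sigma 1 --a 5 --measure jaccard --correction clip
inst/scripts/phenomkl kernels --data data/ --measure lin --correction clip --out pheno.csv
```

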