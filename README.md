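# protfid

Distributional evaluation of protein structure ensembles in R.

Generative models of protein backbones are usually scored structure by
structure (designability, novelty). Those metrics say nothing about whether
the *collection* of generated structures covers the distribution the model
was trained to imitate: a model can emit one perfect fold forever and score
perfectly. `protfid` evaluates the ensemble instead, for people building or
benchmarking structure generators.

## The metric

Given a reference sample X = {x₁,…,x_N} and an evaluation sample
Y = {y₁,…,y_M}, each structure is embedded as a fixed-length vector E(x) ∈ ℝᵖ.
Both embedded samples are approximated by Gaussians, with moments estimated as

μ_X = (1/N) Σᵢ E(xᵢ),  Σ_X = (1/N) Σᵢ (E(xᵢ) − μ_X)(E(xᵢ) − μ_X)ᵀ

(note the 1/N normalization), and the score is the closed-form
2-Wasserstein distance between the two Gaussians:

W₂² = ‖μ_X − μ_Y‖² + Tr(Σ_X + Σ_Y − 2 (Σ_Y Σ_X)^{1/2})

Embedding covariances are typically near-degenerate, so both samples are
first projected onto the top d principal components (default d = 32) of a
PCA fit *jointly* on reference and evaluation embeddings; the trace term is
evaluated through the symmetric form Tr((Σ_X^{1/2} Σ_Y Σ_X^{1/2})^{1/2})
with eigenvalue clamping. Lower is better; 0 means the Gaussian summaries
coincide.

Around the metric the package implements the companion machinery used to
validate that such a score behaves like a diversity-and-plausibility
measure:

* **OT-TMScore** — exact optimal transport between two structure sets with
  cost C_ij = 1 − (TM(aᵢ,bⱼ) + TM(bⱼ,aᵢ))/2 and uniform marginals
  (`ot_tmscore()`, `solve_ot()`), with a built-in equal-length TM-score
  kernel and a loader for externally aligned score tables.
* **Diversity races** — drop structures cluster-by-cluster versus at
  random and watch the distance to a reference degrade (`run_race()`,
  `hierarchy_race()`); a faster-degrading clustered racer means the metric
  senses fold diversity, level by level of a cluster hierarchy.
* **Influence gradients** — derivative of a softmax-weighted FID with
  respect to per-sample logits at uniform weights (`fid_influence()`);
  positive gradients mark samples that worsen the score.
* **Perturbation curves** — Gaussian coordinate jitter of increasing
  severity (`jitter()`, `perturbation_curve()`); the score must rise
  monotonically.
* **Structure statistics** — secondary-structure-aware contact order
  (`set_contact_stats()`) and greedy motif-cover counts
  (`cover_analysis()`), which explain score gaps in interpretable
  geometric terms.

The default embedder is a deterministic, rigid-motion-invariant geometric
featurizer (64 dimensions: CA-distance histogram, coarse Ramachandran
occupancy, secondary-structure fractions, radius of gyration, contact
density, log length), so the whole pipeline runs offline. Vectors from
pretrained models (e.g. structure-level GearNet or ESM3 embeddings
computed elsewhere) drop in through `load_embeddings()` or any function
mapping a backbone to a fixed-length vector.

## Worked example

```r
library(protfid)

# a reference ensemble and a "generated" ensemble of mixed-topology chains
ref <- structure_set(lapply(1:30, function(i)
  make_multisegment(list(c("helix", 14), c("coil", 5), c("strand", 8)),
                    seed = i, id = sprintf("ref%02d", i))))
gen <- structure_set(lapply(31:50, function(i)
  make_multisegment(list(c("helix", 14), c("coil", 5), c("strand", 8)),
                    seed = i, id = sprintf("gen%02d", i))))
noisy <- jitter_set(gen, sigma = 1.5, seed = 7)   # implausible copies

E_ref <- embed_set(ref)
compute_fid(E_ref, embed_set(gen),   d = 8)
#> <fid_result> value = 0.0644338 (d = 8, n_ref = 30, n_eval = 20) [near-degenerate covariance]
compute_fid(E_ref, embed_set(noisy), d = 8)
#> <fid_result> value = 1.31973 (d = 8, n_ref = 30, n_eval = 20) [near-degenerate covariance]
```

The clean ensemble, drawn from the same generator as the reference, scores
near 0; 1.5 Å of coordinate noise inflates the distance twenty-fold. The
degeneracy flag reports that the raw 64-dimensional feature covariance is
ill-conditioned — the reason the PCA projection step exists.

```r
st <- set_contact_stats(gen)
st$mean_order; st$median_order
#> [1] 0
#> [1] 0
```

These single-domain fixtures have only low-order contacts (every contact
lives inside one secondary-structure element); native-like folds with
packed sheets score much higher, which is what makes contact order a
useful complexity statistic for generated ensembles.

A shell interface covering the same operations is installed at
`inst/cli/protfid` (subcommands `fid`, `ot`, `race`, `influence`,
`perturb`, `perturb-curve`, `contacts`, `cover`, `simulate`, `embed`).

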