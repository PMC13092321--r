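---
title: "Methods: a Frechet distance for protein structure ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Frechet distance for protein structure ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protfid)
```

## The model

`protfid` scores how well one sample of protein backbones reproduces the
*distribution* of another. Directly estimating a divergence between
distributions over 3D structures is hopeless, so the metric works in an
embedding space: each structure becomes a fixed-length vector, each
embedded sample is summarized by a Gaussian, and the score is the
closed-form 2-Wasserstein distance between the two Gaussians,

$$W_2^2 = \lVert\mu_X-\mu_Y\rVert^2 +
  \mathrm{Tr}\!\left(\Sigma_X+\Sigma_Y-2(\Sigma_Y\Sigma_X)^{1/2}\right),$$

with moments estimated with the biased $1/N$ normalization
(`fit_gaussian()`; a flag exposes $1/(N-1)$). The Gaussian approximation
is the modelling assumption: the score only sees the first two moments of
the embedded samples. It is exactly the construction used to evaluate
image generators, transplanted to protein backbones.

Two numerical choices matter:

* **Joint PCA before the distance.** Embedding covariances are routinely
  near-degenerate — a handful of directions carry almost all variance —
  which destabilizes the matrix square root. Both samples are therefore
  projected onto the top $d$ principal components (default $d = 32$) of a
  PCA fit on the *concatenation* of reference and evaluation embeddings,
  centered at the pooled mean, with no whitening. Fitting jointly keeps
  directions that separate the two sets; the basis is refit for every
  pair and never cached, because reusing a basis would silently change
  the metric. Pooled-mean centering (rather than per-set) is a design
  choice: it keeps the projection symmetric in its two arguments, and the
  pipeline symmetry is asserted in the tests. `compute_fid()` flags pairs
  whose pre-projection pooled covariance has condition number above
  1e12.
* **Symmetric square-root evaluation.** The trace term is computed as
  $\mathrm{Tr}((\Sigma_X^{1/2}\Sigma_Y\Sigma_X^{1/2})^{1/2})$ via
  symmetric eigendecompositions, clamping negative eigenvalues at zero,
  with a 1e-10 diagonal jitter retry if a decomposition fails. The final
  value is clamped to $[0,\infty)$ and the raw value kept as an
  attribute. Tests verify this route against an independent
  eigendecomposition of the nonsymmetric product $\Sigma_Y\Sigma_X$ to
  1e-6.

## Embeddings

The metric is embedder-agnostic: `embed_set()` accepts any function from
a backbone to a fixed-length numeric vector, and `load_embeddings()`
ingests vectors computed elsewhere (pretrained structure encoders such as
GearNet or ESM3 are the intended external source; which network layer to
use is the user's choice and no weights ship with the package). The
built-in default is a deterministic geometric featurizer (64 dimensions):
a log-spaced CA–CA distance histogram (22 bins, 3–60 Å), a coarse
6×6 Ramachandran occupancy grid, H/E/C secondary-structure fractions,
radius of gyration scaled by $L^{0.4}$, contact density at 8 Å, and log
length. All components are rotation- and translation-invariant, so the
metric cannot be gamed by rigid motion; the Ramachandran grid is offset
by 5° so canonical dihedrals never sit on a bin edge (bin membership
would otherwise flip under the 1e-13-scale noise a rotation introduces).
The featurizer is honest plumbing, not a learned embedder: it separates
topology classes and degrades smoothly under noise, which is what the
validation procedures need, but it is far coarser than a pretrained
network. A structure that fails to embed aborts the run with a report —
silently dropping structures would change sample sizes and bias the
score. The default dimension 64 is deliberately above the projection
target 32 so the PCA step stays meaningful.

## OT-TMScore

TM-score is a trusted structure-to-structure similarity; the transport
construction lifts it to sets. From the directed matrix
$D_{ij} = \mathrm{TM}(a_i, b_j)$ (normalized by the first argument's
length) the symmetrized cost is $C_{ij} = 1 - (D_{ij}+D_{ji})/2$, and the
OT-TMScore is the optimal value of the balanced transport problem with
uniform marginals $1/N$ and $1/M$. The printed row/column-sum-to-one
constraints of the usual formulation are infeasible when $N \neq M$ and
unnormalized otherwise; uniform marginals make the objective a mean,
size-free and always feasible, which is the evident intent ("how well
can the sets be soft-matched").

No exact linear-programming solver was available as a dependency, so
`solve_ot()` implements successive-shortest-path min-cost flow with node
potentials (Dijkstra inside), which is exact for this LP. Tests check it
against brute-force enumeration of all permutation matchings on seeded
4×4–6×6 problems, where the optimum of a uniform-marginal problem is
attained at a permutation.

The built-in TM kernel handles the equal-length, identity-alignment case
(the situation for fixed-length generated ensembles): fragment-seeded
Kabsch superposition (windows of length min(L, 20), stride 5), iterating
the included-residue set with an inclusion cutoff shrinking from
$2d_0$ to $d_0$, best score over seeds, with
$d_0(L) = \max(0.5,\ 1.24(L-15)^{1/3} - 1.8)$. Sequence-independent
structural alignment is out of scope; pairwise scores from external
aligners enter through `load_tm_matrix()`, which demands a dense table
and errors on missing or conflicting pairs. Which normalization an
external aligner used for its reported scores is the user's concern; the
symmetrization makes the cost insensitive to the direction convention
but not to the normalizing length.

## Diversity races

All racers start from the same full set; each round every racer drops the
same fixed number of structures (the explicit fairness rule — set sizes
stay equal across racers at every round) and the distance of the
remainder to a fixed reference is recorded. The clustered racer orders
members so that whole clusters are dropped before the next begins;
cluster traversal order and within-cluster order are re-randomized each
replicate. When a cluster boundary falls mid-round the racer simply
continues into the next cluster: the fixed drop count wins. The race is
formulated as *dropping* (equivalently one can narrate it as adding from
empty sets; that is just the reversed axis).

Inside a race the joint PCA is fit once, on (reference, full starting
set), and reused for every round; refitting per round would make rounds
mutually incomparable (toggle `refit_pca = TRUE` to study that variant).
Replicate seeds derive deterministically from one base seed, so
trajectories are bit-reproducible. `hierarchy_race()` builds one
clustered racer per label level plus the random baseline; on a clean
two-level synthetic hierarchy the final-round ordering
level-1 ≥ level-2 ≥ random is asserted at 50 replicates.

## Influence gradients

To ask which samples hurt the score, the evaluation moments are written
with softmax weights $w_i = e^{u_i}/\sum_j e^{u_j}$:
$\mu_X(w) = \sum_i w_i E(x_i)$,
$\Sigma_X(w) = \sum_i w_i (E(x_i)-\mu_X(w))(E(x_i)-\mu_X(w))^T$, and the
distance is differentiated with respect to the logits at the uniform
point $u = 0$ (the only point at which weighted moments reduce to the
plain $1/N$ moments; the weighted mean must appear inside the outer
products for $\Sigma_X(w)$ to be a covariance). Because
$\sum_k w_k (x_k-\mu) = 0$ at that point, the free-weight derivative
collapses to the closed form

$$h_i = 2(\mu-\mu_{\mathrm{ref}})\cdot x_i + (x_i-\mu)^T G (x_i-\mu),
\qquad G = I - \Sigma_{\mathrm{ref}}^{1/2} M^{-1/2}
\Sigma_{\mathrm{ref}}^{1/2},\quad
M = \Sigma_{\mathrm{ref}}^{1/2}\,\Sigma\,\Sigma_{\mathrm{ref}}^{1/2},$$

and the logit gradient is $g_i = w_i(h_i - \textstyle\sum_j w_j h_j)$,
which sums to zero by softmax shift invariance. The PCA basis is held
fixed during differentiation — the question asked is "which samples hurt
the score in the current embedding geometry", not "…after the geometry
re-adapts"; differentiating through the basis would answer the latter.
Positive gradient ⇒ upweighting the sample worsens the distance ⇒ the
sample has negative influence. Gradients with magnitude below 1e-9 are
classed neutral rather than forced into a sign. The analytic gradient is
validated against central finite differences (relative L2 below 1e-4
over 50 seeded instances); the closed form requires non-degenerate
evaluation moments ($n > d+1$ after projection), which is a documented
precondition.

## Perturbations

`jitter()` adds i.i.d. Gaussian noise per axis (σ in Å is per-axis; the
mean displacement norm is $\sigma\sqrt{8/\pi}$, which the tests verify to
3% at 10,000+ atoms). `perturbation_curve()` jitters the evaluation set
at each severity with fresh seeds and reports mean/sd of the distance;
monotone growth of that curve is the module's defining property and is
asserted with Spearman correlation exactly 1 on the default fixture
suite. Physically informed perturbations (torsion-space noise,
refolding by an external model) are out of scope, but the curve API
accepts arbitrary pre-perturbed sets in their place.

## Contact order and motif cover

The order of a contact $(i,j)$ is the number of whole non-coil
secondary-structure segments lying strictly inside the open interval
$(i,j)$; a contact within one segment has order 0, and with this reading
the same-segment rule is a special case rather than an exception. Coil
segments are not counted (the canonical examples of "structures between"
are helices and strands). Set-level statistics pool contacts across all
structures (a per-structure-average variant would weight small
structures up; pooling is the default and the per-structure table is
returned for anyone who wants the other convention). A set with zero
contacts is reported undefined, never 0.

Two declared substitutes stand in for external machinery here, and their
absolute numbers are accordingly *not* comparable to published
rotamer-based tables — the between-set orderings are the supported
claims:

* contacts are CA–CA distance contacts (8 Å cutoff, minimum sequence
  separation 3, both configurable) rather than rotamer-library potential
  contacts;
* secondary structure comes from a dihedral-basin classifier (H:
  φ∈[−100,−30], ψ∈[−80,−5]; E: φ∈[−170,−70], ψ∈[90,180]∪[−180,−170];
  minimum runs 4/3 smoothed to coil), adequate for ideal and near-ideal
  geometry.

`cover_analysis()` asks how many library motifs explain a set: the
universe is every residue plus every contact; a motif covers what its
RMSD-matched windows touch (sliding-window CA-RMSD under optimal
superposition; multi-segment motifs try ordered placements within a
budget); `greedy_cover()` repeatedly takes the candidate covering the
most uncovered elements, ties broken by smallest motif id for
determinism. Greedy set cover is within a $\ln|U|+1$ factor of optimal,
asserted against brute force on small random instances. The cover
accepts any motif library; none is bundled.

## Synthetic data

The generators exist so every procedure is testable offline, and their
defaults are the study conditions of the test suite:

* **Backbones** are grown by natural-extension (NeRF) chain building
  with ideal bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
  trans ω) from canonical dihedrals: helix (−60, −45), strand
  (−120, 120), coil by a self-avoiding random dihedral walk (CA clash
  threshold 2.5 Å, 100 retries). Consecutive CA–CA distances come out at
  3.80 Å.
* **Embedding clouds** are seeded Gaussian samples via the eigenvalue
  square root (PSD covariances allowed). `make_clustered_cloud()` places
  k unit-covariance components with pairwise mean separation at least
  the requested value; `make_hierarchical_cloud()` nests sub-clusters
  (default geometry in the tests: 4 super-clusters at separation 12,
  3 sub-clusters each at separation 4, well inside the regime where the
  hierarchy is real but sub-clusters overlap their siblings). Separation
  8–10 against unit covariance makes clusters crisply distinct, the
  regime the recapitulation and race properties describe.

What passing on these fixtures shows — and does not. The fixtures have
exactly Gaussian embedding clusters, equal-length chains and ideal
geometry; real ensembles have none of those properties. Green tests
therefore certify the *machinery* (estimators, solver, gradients,
orderings) under conditions where ground truth is analytic, not that any
particular generative model is good, and not that the built-in
featurizer matches a pretrained embedder's judgement on real proteins.

Problem sizes used by the test suite and the acceptance script (chosen
as comfortable desk-scale conditions): Gaussian-oracle and null checks
at n = 5000, p = 64 → d = 8; races on 5×100 clustered clouds at 50
replicates; perturbation curves on 20 chains of 27 residues at 10 seeds
per severity; transport oracles at 4×4–6×6.

## Degenerate inputs and edge policies

* Residues missing any of N/CA/C are dropped with a warning on read
  (strict mode rejects the file); real crystal structures have gaps,
  generated backbones should not.
* Multi-model files use the first model; alternate locations keep the
  highest-occupancy conformer; multi-chain files require an explicit
  chain selector rather than guessing.
* Sample sizes below d+1 trigger a rank-deficiency warning, not an
  error: the distance is still defined, its covariance term is just
  estimated at reduced rank.
* Resolution/experiment-method filtering of reference sets is a
  documented curation step, not enforced in code — the necessary
  metadata is too dialect-dependent across PDB/mmCIF files.

## Known limitations

* The built-in TM kernel requires equal lengths under the identity
  correspondence; unequal-length comparisons need an external aligner's
  score table.
* The Gaussian summary ignores higher moments; two samples with equal
  mean and covariance in embedding space are indistinguishable to the
  score regardless of shape.
* The influence analysis inspects the derivative at uniform weights
  only; it is a first-order diagnosis, not a reweighting optimizer.
* Absolute contact-order and cover numbers depend on the declared
  contact and secondary-structure substitutes (above) and should only be
  compared within runs of this package.
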