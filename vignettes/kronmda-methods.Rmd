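---
title: "Methods: similarity integration, symmetric NMF, and Kronecker RLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity integration, symmetric NMF, and Kronecker RLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kronmda)
```

## The model

`kronmda` scores every disease–miRNA pair by kernel ridge regression on
the observed binary association matrix $A \in \{0,1\}^{n_d \times n_m}$,
with a pairwise kernel that factorizes as the Kronecker product of a
disease kernel and a miRNA kernel:

$$\operatorname{vec}(S) = K (K + \lambda I)^{-1} \operatorname{vec}(A),
\qquad K = SD^{*} \otimes SM^{*}.$$

The two side kernels are *interpolated* integrated similarities: each is
the symmetric-NMF approximation $P P^{\top}$ ($P \ge 0$ entrywise) of an
average of a knowledge-based similarity and a data-driven
interaction-profile kernel.  The method's underlying assumption is
guilt-by-association: a pair scores high when similar diseases are
already known to associate with similar miRNAs.  The closed-form solve
uses only the two side eigendecompositions, so the
$n_d n_m \times n_d n_m$ kernel is never materialized.

### Disease similarity

Each disease's DAG is its ancestor closure in a child→parent hierarchy.
Two complementary semantic similarities are computed from DAG overlap and
averaged:

* **Model 1 (positional decay).**  A disease contributes 1 to its own
  semantic value and each ancestor contributes $\Delta^k$ where $k$ is
  its DAG distance (taken as a maximum over paths).  $\Delta$ defaults to
  0.5, the conventional value for this family of DAG similarities: it
  halves an ancestor's weight per generation, keeping the near ancestry
  dominant without discarding deep structure.
* **Model 2 (information content).**  A node shared by many disease DAGs
  is unspecific, so it contributes
  $-\log(\text{DAG count}/n_d)$ regardless of position.  The similarity
  is invariant to the base of the logarithm (numerator and denominator
  scale identically); the natural log is used.

The profile kernel
$KD(i,j) = \exp(-\gamma_d \lVert A_{i\cdot} - A_{j\cdot}\rVert^2)$ uses a
bandwidth normalized by the mean squared profile norm, with the raw
parameter $\gamma'_d = 1$; the normalization makes the kernel scale
independent of association density.  The integrated disease similarity
is the plain average $SD = (SS + KD)/2$.

### miRNA similarity

Functional similarity follows the group-max rule: each disease
associated with one miRNA is matched to its most similar disease
associated with the other, both directions are summed, and the total is
divided by the two group sizes.  A precomputed functional-similarity
matrix (e.g. downloaded MISIM scores) can be supplied and then takes
precedence over the internal computation.  The miRNA profile kernel and
integration mirror the disease side.

## Degenerate inputs and edge rules

* **Model-2 zero denominator.**  When both diseases' DAG nodes occur in
  every modeled disease's DAG, both semantic values are zero and the
  similarity ratio is 0/0.  It is totalized as 0 off the diagonal and 1
  on it, preserving the unit-diagonal convention of the averaged
  similarity; each occurrence is reported with a `message()`.
* **Diseases without a DAG.**  A disease absent from the hierarchy has
  zero semantic similarity to everything (1 to itself); integration
  still averages that zero with the kernel.  This is precisely the case
  the kernel term exists for.  Setting
  `mda_config(kernel_fallback = TRUE)` instead substitutes the kernel
  value alone for such pairs, which avoids halving their similarity;
  the default keeps the uniform average so that all entries are on the
  same scale.
* **Empty association profiles.**  A miRNA (or disease) with no
  associations has functional similarity 0 to every other miRNA and a
  kernel row determined by its zero profile.  Only a fully zero
  adjacency is an error ("bandwidth undefined"), since the mean profile
  norm would vanish.

## Symmetric NMF: update, fallback, termination

The factor update is multiplicative with damping $\alpha = 0.999$:
$R = (SD\,P) \oslash (P P^{\top} P)$, candidate
$P \odot (1 - \alpha + \alpha R)$.  The candidate is accepted only if it
lowers the squared Frobenius residual $\lVert SD - P P^{\top}\rVert_F^2$;
otherwise the conservative cube-root step $P \odot R^{1/3}$ is taken.
Design choices that were genuinely open:

* **Termination.**  The accept-or-fallback decision is applied per
  iteration inside a conventional outer loop that stops when the
  relative residual change drops below `tol` (default $10^{-6}$) or
  after `max_iter` (default 500) iterations.  Stopping at the *first*
  residual decrease would almost always terminate after one step of a
  damped multiplicative scheme and leave the factorization far from
  convergence, so the iterate-to-convergence reading is used.
* **Residual bookkeeping.**  Both branches are scored by the full
  residual against the target matrix; comparing factor norms alone would
  make the acceptance test meaningless.  The residual is computed as
  $\lVert SD\rVert_F^2 - 2\langle SD\,P, P\rangle +
  \lVert P^{\top}P\rVert_F^2$, avoiding the $n \times n$ intermediate;
  the products involved are reused across iterations.
* **Rank.**  The factor defaults to full rank ($P$ square, matching the
  input size); low-rank runs are available for synthetic experiments.
* **Initialization.**  $P^0$ is uniform on $(0, \sqrt{\bar{SD}/r}\,]$ so
  the initial residual is scale-matched to the input.  Each row's draw
  is keyed by (seed, row label): runs are bitwise reproducible per seed,
  and permuting or relabelling the input permutes the whole
  factorization identically, which makes the pipeline
  permutation-equivariant end to end.
* **Guards.**  Denominators are floored at $10^{-12}$ before entrywise
  division.  The output $P P^{\top}$ is *not* renormalized to unit
  diagonal; the solver consumes it as produced, and its positive
  semidefiniteness (by construction) is what keeps the Kronecker kernel
  well-behaved.

The 1×1 fixed point contracts at rate $\approx |1 - 2\alpha|$ per
candidate step, so convergence tests on scalar problems use a tighter
tolerance and a larger iteration cap than the defaults.

## KronRLS in the eigenbasis

With $SD^* = V_d \Lambda_d V_d^{\top}$ and
$SM^* = V_m \Lambda_m V_m^{\top}$, each Kronecker eigenvalue
$\lambda_{d,i}\lambda_{m,j}$ is shrunk to
$\lambda_{d,i}\lambda_{m,j}/(\lambda_{d,i}\lambda_{m,j} + \lambda)$ and
applied to the coefficient matrix $V_m^{\top} A^{\top} V_d$; the shrink
factors are held as an $n_m \times n_d$ table, never as a diagonal of
the full kernel.  Interpolated kernels are PSD up to rounding, so their
eigenvalues are clipped at zero before forming the products.  If the
interpolation stage is bypassed (`interpolate = FALSE`) the raw
integrated similarities may be indefinite; negative eigenvalues are then
used as-is and a warning is emitted.  $\lambda$ defaults to 1 and is the
only solver parameter; larger values shrink all scores toward zero
monotonically in every spectral coefficient.

## Cross-validation protocol

Each held-out association's score is converted to its mid-rank
percentile within its own fold's candidate pool — all unverified pairs
for the global protocol, only the test disease's unverified pairs for
the local one.  The AUC is the mean percentile (the probability that a
held-out true pair outranks a random unverified pair), and pooled ROC
curves sweep a shared threshold grid on the percentile scale.  Ties use
the midrank convention throughout.

Whether the adjacency-dependent similarities should be recomputed with
the test associations removed is genuinely underdetermined in this
literature.  Both protocols are first-class here:
`refresh_kernels = TRUE` (default) recomputes the kernels, the internal
functional similarity, and the symmetric-NMF interpolation per fold, so
no information about test pairs leaks into the model;
`refresh_kernels = FALSE` computes everything once from the full data,
which is far cheaper and matches common practice but leaks each test
association into the similarity matrices (and accordingly tends to give
slightly higher AUCs).  Per-repeat fold assignments in k-fold CV derive
their seeds as `seed + repeat_index - 1` for auditability.

## The synthetic benchmark

The generator plants the exact structure the model assumes: diseases and
miRNAs are partitioned into latent communities; true associations occur
with probability 0.35 inside matching communities and 0.02 elsewhere;
the hierarchy gives each disease community its own subtree (depth 3,
branching 3) under a common root, so DAG similarity is informative about
communities; and 20% of true associations are masked to form held-out
truth.  The default operating point — 30 diseases × 40 miRNAs, 3
communities, reported over generator seeds 1–5, with 10 repeats for
5-fold CV — keeps a full leakage-free leave-one-out sweep (one pipeline
rerun per known association) in the tens-of-seconds range per seed,
which is the problem size the package's own evaluation uses.

What the generator does *not* emulate: MeSH's real topology (depth
heterogeneity, multiple parentage), the heavy-tailed degree
distributions of curated association databases, correlated ascertainment
(well-studied diseases accumulate associations), or any sequence-level
signal behind functional similarity.  Passing the synthetic benchmark
therefore shows that the pipeline recovers planted community structure
through the full similarity → factorization → solver chain; it does not
certify performance on curated human data.

A ceiling argument calibrates expectations on this benchmark: within a
matching community, true-but-masked pairs and never-true pairs are
exchangeable once the held-out association itself is removed, so even an
oracle that knew the community assignments could not separate them.
With the default probabilities that caps the achievable global
leave-one-out AUC in the high 0.7s; the test suite checks a mean of at
least 0.70 over the five benchmark seeds for the leakage-free default
protocol, a shuffled-label null inside [0.4, 0.6], k-fold stability
below 0.05 standard deviation, and held-out recovery (AUC > 0.5) for a
masked disease on at least four of five seeds.

## Known limitations

* Dense eigendecompositions and full-rank factorization bound practical
  problem sizes to a few thousand diseases/miRNAs; no iterative solver
  is provided.
* The leave-one-out machinery reruns the entire pipeline per fold under
  the default refresh protocol; for database-scale inputs (thousands of
  associations) use `refresh_kernels = FALSE` or k-fold CV.
* Semantic similarity treats the hierarchy as authoritative; diseases
  missing from it fall back to profile kernels alone, which are
  uninformative for diseases with no known associations (the new-disease
  case then relies entirely on the miRNA side).
* Scores are not calibrated probabilities; only their ranking is
  meaningful.
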