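---
title: "F-statistics as geometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{F-statistics as geometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstatpca)
```

## The model

fstatpca works in *allele frequency space*: each population is the vector
$X_i = (x_{i1}, \dots, x_{iS})$ of its allele frequencies at $S$ biallelic
SNPs, a point in $[0,1]^S \subset \mathbb{R}^S$. The three Patterson
F-statistics are plug-in averages over loci,

$$
F_2(a,b) = \tfrac{1}{S}\lVert X_a - X_b\rVert^2,\qquad
F_3(t;a,b) = \tfrac{1}{S}\langle X_t - X_a,\, X_t - X_b\rangle,\qquad
F_4(a,b;c,d) = \tfrac{1}{S}\langle X_a - X_b,\, X_c - X_d\rangle,
$$

i.e. a squared Euclidean distance and two dot products of difference
vectors. Everything else in the package follows from two elementary facts:

1. dot products are invariant under rotation, so any orthonormal change of
   basis — in particular the principal-component basis — re-expresses every
   F-statistic as a sum of per-coordinate terms; and
2. $F_2$ distances are squared Euclidean, so the pairwise $F_2$ matrix
   determines the PC configuration up to rotation (classical
   multidimensional scaling).

Expanding the dot products also gives the exact linear identities used by
`f3_from_f2()` and `f4_from_f2()`:

$$
2F_3(t;a,b) = F_2(t,a) + F_2(t,b) - F_2(a,b), \qquad
2F_4(a,b;c,d) = F_2(a,d) + F_2(b,c) - F_2(a,c) - F_2(b,d).
$$

The F4 pairing is easy to get wrong: the form above is the one consistent
with the definition (setting $c=a$, $d=b$ recovers $F_4(a,b;a,b) =
F_2(a,b)$), and it is what the identity tests assert against the direct
computation.

### The two PCA routes

`pca_from_data()` centres the frequency matrix column-wise (unweighted mean
over populations), scales it by $1/\sqrt{S}$ and takes the SVD; coordinates
are $U\Sigma$, eigenvalues the squared singular values. `pca_from_f2()`
double-centres the pairwise $F_2$ matrix,
$B = -\tfrac12 C F_2 C$ with $C = I - \tfrac1n\mathbf{1}$, and
eigendecomposes $B$. For plug-in $F_2$ the two routes are algebraically the
same decomposition; the suite checks that eigenvalues agree to $10^{-8}$
and coordinate Gram matrices match, with coordinates identical up to column
sign (and up to rotation inside blocks of tied eigenvalues, which is why
the comparison is made on Gram matrices rather than raw coordinates).

**Metric scaling.** Folding $1/S$ into the decomposition (the
$1/\sqrt{S}$ factor) puts PC coordinates in F2 units: for every pair,
$F_2(i,j) = \sum_k (p_{ik}-p_{jk})^2$ holds over the full spectrum with no
extra constants, and both routes are directly comparable. This is the one
normalization decision everything downstream relies on.

**No SNP scaling.** The decomposition operates on unscaled population
frequencies. Dividing each SNP by its standard deviation (as
individual-genotype PCA usually does) breaks the exact F2 correspondence;
a `scale_snps` hook exists for exploration but is off by default and
outside every guarantee.

## Tunable parameters and numerical choices

* **Clamp threshold.** Estimated (external) $F_2$ matrices need not be
  Euclidean, so $B$ can have negative eigenvalues. Eigenvalues within
  $\tau = 10^{-9}\lambda_{\max}$ of zero are snapped to exactly zero and
  treated as round-off; eigenvalues below $-\tau$ are genuine
  non-Euclidean structure — clamped to zero and counted in `n_clamped`.
  The two cases are deliberately distinguished so that plug-in matrices
  always report `n_clamped = 0`.
* **Sign convention.** Each PC is flipped so its largest-magnitude
  coordinate is positive, ties resolved by lowest population index.
  Without this, LAPACK backends may return either sign and outputs would
  not be reproducible across platforms.
* **Symmetrization.** F2 matrices are symmetrized as $(M + M^\top)/2$ on
  construction after a tolerance check ($10^{-12}$ relative for in-memory
  construction, $10^{-8}$ on TSV read), guarding against asymmetric
  round-trips.
* **Identity tolerances.** All exact algebraic identities (F2
  combinations, rotation invariance, spectrum sums, the three-part
  projection decomposition) are asserted at $10^{-10}$–$10^{-12}$; these
  are double-precision dot products at desk scale, so anything looser
  would hide real bugs.
* **Degeneracy thresholds.** The F4-ratio errors out rather than report a
  huge ratio when the denominator is below $10^{-12}$ times the F2 scale
  of the populations involved; the outgroup-F3 projection and the residual
  rotation error out on a zero-length axis.
* **F3 classification.** `on_sphere` uses an absolute $10^{-12}$ band on
  F3; inside/outside are strict signs. Circle membership in a subspace is
  a strict inequality, so boundary points count as *not* outside — the
  conservative direction for the positivity guarantee below.

## The projected-circle guarantee

$F_3(t;a,b) < 0$ exactly when $t$ lies inside the $n$-ball with diameter
$\overline{ab}$ (Pythagoras). On a 2-PC plot two circles can be drawn:
the circle through the projected sources (radius = half their distance
*in the plotted subspace*) and the projection of the full ball (radius =
half the *full-space* $\sqrt{F_2(a,b)}$). Only the latter supports a
guarantee: a projection can only shrink the distance to the projected
centre, so a target outside the projected full ball in *any* subspace has
$F_3 > 0$ regardless of its higher-PC coordinates. `admixture_circle()`
therefore reports both radii, and `classify_f3()`'s
`outside_projected_circle` tests against the full-ball radius. The
subspace circle is still reported because it is what a plot naturally
suggests — but nothing is claimed for it.

## F4-ratio semantics

`f4_ratio()` computes
$\alpha = F_4(R_1,R_2;X_X,X_1)\,/\,F_4(R_1,R_2;X_2,X_1)$ literally. For a
drift-free mixture $X_X = (1-w)X_1 + wX_2$, linearity of the dot product
gives $\alpha = w$ exactly — so $\alpha$ is the ancestry fraction
attributed to the **X2 side** ($\alpha = 0$ at $X_X = X_1$). Because
"admixture proportion of $X_1$" is genuinely ambiguous between the two
conventions, the print method always shows both $\alpha$ and $1-\alpha$
with their endpoint labels. Post-admixture drift on $X_X$ adds a term
$\langle R_1 - R_2, \delta\rangle$ to the numerator with expectation zero
whenever $\delta$ is independent of the reference axis, so the estimate
stays unbiased (but noisier) — the property the recovery checks exercise.

## Projection of new samples

`project_sample()` centres a new frequency vector with the reference SNP
means and post-multiplies by $L^\top$. The residual outside the loading
span is reported as `projection_error_f2`; being orthogonal to the span,
it adds exactly, giving the three-part split of `f2_with_projected()`:
truncated part + truncation remainder + projection error = the directly
computed F2 against the raw sample.

With missing loci, the coordinates are the ordinary least-squares fit of
the observed centred values on the observed loading columns. When the
observed loading sub-matrix is close to orthonormal this reduces to the
plain masked projection with a scaling correction, and it recovers the
exact coordinates of any in-span sample from a consistent overdetermined
system (a build population with 20% of loci masked still returns its own
coordinates). The reported error is then computed on observed loci only,
still on the $1/S$ scale of the full decomposition; comparisons of errors
across masks with very different sizes should keep that in mind.

## What the simulator emulates — and what it does not

`sim_freqs()` evolves allele frequencies down a tree or admixture graph.
Root frequencies are i.i.d. from uniform$(lo,hi)$ or beta$(a,b)$; each
edge applies one drift step; an admixture child is the exact elementwise
mixture $w\,\mathrm{parent}_a + (1-w)\,\mathrm{parent}_b$, formed before
any of its own subsequent drift (mixture first, drift after — the admixed
point starts on the segment between its sources and drift then moves it
off). Two drift models are provided because the mapping from "branch
length in drift units" to a concrete transition is a modelling choice:

* `gaussian_truncated` (default): per locus add
  $N(0, \tau p(1-p))$ and clip to $[0,1]$. Supports the closed-form path
  expectation in `expected_f2()`: for an admixture-free graph,
  $E[F_2(i,j)] \approx E[p(1-p)] \sum_{e \in \mathrm{path}} \tau_e$, with
  $E[p(1-p)]$ integrated analytically under the root distribution
  (uniform$(0.4,0.6)$ gives $37/150 \approx 0.2467$). The approximation
  treats the heterozygosity factor as constant along the path; it is
  first-order in $\tau$ and the calibration checks hold it to 5% at
  $\tau \le 0.02$.
* `binomial_wright_fisher`: one collapsed binomial resampling step with
  $N = \mathrm{round}(1/\tau)$, a discrete sanity check with the same
  leading-order variance.

Defaults — root uniform$(0.1, 0.9)$, $\tau \le 0.05$ in all shipped
fixtures — keep frequencies away from the boundaries so that clipping
bias is negligible. Reproducibility: each node's draws come from an RNG
stream seeded by hashing (seed, node label), so identical configurations
are bit-identical and editing one branch never reshuffles draws
elsewhere; the global RNG state is saved and restored around simulation.

What the generator does **not** emulate: linkage (loci are independent),
mutation, selection, coalescent noise within populations (frequencies are
population parameters, not sample estimates), and ascertainment of SNP
panels. Tests passing on these fixtures therefore demonstrate the
*geometry* — identities, classifications, estimator recovery under drift
— not robustness to the sampling noise and ascertainment of real
genotype compendia, where externally bias-corrected F2 matrices should be
supplied via `read_f2_matrix()`.

## Validation scales

The checks are sized to run in seconds-to-minutes on one CPU: identity
suites use 100–500 random draws with $n \le 8$ populations and
$S \le 200$ SNPs; ball/circle classifications use 10,000 random triples
and completions; estimator-recovery studies use $S = 10{,}000$ with 200
replicates (F4-ratio, post-admixture drift $\tau = 0.01$, mixture weights
0.1/0.3/0.5) and $S = 100{,}000$ with 50 replicates (four-taxon treeness,
two-leaf calibration). These sizes make Monte-Carlo error small relative
to the tolerances asserted (e.g. the F4-ratio mean is required within
$\pm 0.02$ of the true weight; observed deviations are an order of
magnitude smaller).

## Known limitations

* Plug-in statistics only: no sample-size bias correction, no
  block-jackknife standard errors, no Z-scores. Significance assessment
  belongs to estimation tools; this package supplies the geometry.
* `pca_from_f2()` cannot return loadings (not recoverable from distances
  alone), so F2-only workflows cannot project new samples.
* The least-squares missing-data projection is exact for in-span samples
  but, like any projection without shrinkage, places far-out-of-span
  samples closer to the origin than resampling-based correctors would.
* `expected_f2()` covers trees only; expectations on admixture graphs
  would require tracking covariances across reticulations and are out of
  scope.
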