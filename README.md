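# fstatpca

Patterson F-statistics and principal component analysis are the two
workhorses of population-structure analysis, and they are usually treated
as separate tools: F-statistics (f2, f3, f4) for testing treeness and
admixture between small sets of populations, PCA for visualizing structure
across many. fstatpca implements the geometric bridge between them, for
population geneticists who want their PCA plots and their F-statistics to
speak the same language.

The key observation is that with populations represented by allele-frequency
vectors $X_i \in [0,1]^S$ over $S$ SNPs,

$$
F_2(a,b) = \tfrac{1}{S}\lVert X_a - X_b \rVert^2, \qquad
F_3(t;a,b) = \tfrac{1}{S}\langle X_t - X_a, X_t - X_b \rangle, \qquad
F_4(a,b;c,d) = \tfrac{1}{S}\langle X_a - X_b, X_c - X_d \rangle,
$$

and dot products are rotation-invariant. PCA is a rotation (plus
truncation), so every F-statistic splits exactly into per-PC
contributions, and the pairwise-F2 matrix alone reconstructs the PC
configuration by classical MDS (double-centring,
$PP^\top = -\tfrac12 C F_2 C$). From this one picture the package derives:

* **fstats**: `f2()`, `f3()`, `f4()`, `pairwise_f2()`, and the exact
  F2-combination identities `f3_from_f2()` / `f4_from_f2()`;
* **PCA link**: `pca_from_data()` (SVD of the centred, $1/\sqrt S$-scaled
  frequency matrix) and `pca_from_f2()` (double-centred F2, negative
  eigenvalues clamped and counted), with `fstat_spectrum()`,
  `fstat_truncated()` and `f2_frobenius_error()` for per-PC decomposition
  and truncation error;
* **geometry**: the admixture-F3 circle (`admixture_circle()`,
  `classify_f3()`: a target inside the ball with diameter
  $\overline{ab}$ has $F_3 < 0$; outside the *projected full ball* in any
  subspace, $F_3$ is guaranteed positive), outgroup-F3 ranking as an axis
  projection (`outgroup_f3_rank()`), F4 as an angle
  (`f4_angle()`, $\cos\varphi = F_4/\sqrt{F_2 F_2}$), F4-ratio admixture
  proportions (`f4_ratio()`) and the reference-axis residual rotation
  (`residual_rotation()`);
* **projection**: `project_sample()` / `f2_with_projected()` project new
  samples onto a reference PCA and split their F2 exactly into truncated
  part + truncation remainder + projection error;
* **simulator**: `admixture_graph()` / `sim_freqs()` evolve frequencies
  down trees and admixture graphs with controllable drift, with analytic
  path expectations (`expected_f2()`) for calibration;
* **I/O and CLI**: TSV frequency tables and F2 matrices, EIGENSTRAT
  aggregation (`freqs_from_eigenstrat()`), GraphSpec JSON, and a
  subcommand CLI at `inst/cli/fstatpca`.

Statistics are plug-in (no bias correction, no standard errors);
bias-corrected F2 matrices estimated elsewhere can be supplied as input.

## Worked example

Simulate a five-population admixture graph — references R1, R2 and sources
X1, X2 on a balanced tree, XX an admixed child (30% from the X2 side)
with post-admixture drift — then ask the geometric questions:

```r
library(fstatpca)
g <- admixture_graph(
  edges = data.frame(
    parent = c("root", "root", "U", "U", "V", "V", "XY"),
    child  = c("U", "V", "X1", "R1", "X2", "R2", "XX"),
    drift  = c(0.05, 0.05, 0.01, 0.01, 0.01, 0.01, 0.01)),
  admixtures = data.frame(child = "XY", parent_a = "X2", parent_b = "X1",
                          weight = 0.3),
  leaves = c("R1", "R2", "X1", "X2", "XX"))
fr <- sim_freqs(g, sim_config(S = 50000, seed = 7))$freqs

d <- pca_from_data(fr)
round(d$eigenvalues, 4)
#> [1] 0.0221 0.0028 0.0019 0.0010

classify_f3(fr, d, "XX", "X1", "X2", c(1, 2))
#> <f3_class> F3(XX; X1, X2) = -0.00299357: inside_ball
#>   outside projected circle in PCs (1,2): FALSE

f4_ratio(fr, "R1", "R2", "XX", "X1", "X2")
#> <f4_ratio> target XX on axis R1-R2
#>   alpha = 0.3006 (fraction from X2 side); 1 - alpha = 0.6994 (from X1 side)

fstat_truncated(d, "f2", c("X1", "X2"), 2)
#> <truncated_fstat> f2(X1, X2): K = 2
#>   approx 0.0215136 + error 0.00177612 = 0.0232898
```

Reading the output: the negative F3 puts XX inside the admixture ball
with diameter X1–X2, the geometric signature of admixture between those
sources; the F4-ratio recovers the simulated mixture weight (0.3006
versus the true 0.30), despite the drift XX accrued after admixing; and
the first two PCs carry 0.0215 of the total X1–X2 F2 of 0.0233, so a
2-PC plot underestimates that distance by the remaining 0.0018 —
truncation error is always non-negative for F2.

The same operations are available from a shell:

```sh
Rscript inst/cli/fstatpca simulate --graph graph.json --snps 50000 --seed 7 --out freqs.tsv
Rscript inst/cli/fstatpca ratio --freqs freqs.tsv --refs R1,R2 --endpoints X1,X2 --target XX
```

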