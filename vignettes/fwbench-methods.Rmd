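---
title: "Methods: Free-Wilson diagnosis of scoring-function errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Free-Wilson diagnosis of scoring-function errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwbench)
```

## 1. The model

A Free-Wilson model expresses an activity as a sum of additive fragment
contributions. Here the "activity" is either the experimental binding
affinity `pK_ref` (pK = -log10 of Kd or Ki, higher = stronger binding) or a
scoring function's prediction `pK_SF`, and the fragments are interaction
motifs a medicinal chemist tracks: hydrogen-bond donors and acceptors,
hydrophobic carbon at three saturation levels, six-membered aromatic rings,
nitrogen cations, anionic oxygens, heavy halogens, and fluorine.

Let `x_ij` be the number of occurrences of fragment `j` in ligand `i` and
`z_ij` its column-standardized version. Three L1-regularized regressions
are fit along a penalty grid:

* **reference scheme** - `pK_ref ~ Lasso(Z, lambda)`: which fragments carry
  measured affinity;
* **SF scheme** - `pK_SF ~ Lasso(Z, lambda)`: which fragments the scoring
  function actually rewards;
* **combined scheme** - `pK_ref ~ Lasso([Z, pK_SF], lambda)`: standardized
  fragments plus the **raw** (unstandardized) score column.

Keeping the score column raw is deliberate: its coefficient `beta_SF` then
has an absolute interpretation. If the SF were perfectly calibrated,
`pK_SF = pK_ref`, the unique least-squares solution is `beta_SF = 1` with
all fragment coefficients zero. Any fragment coefficient that survives the
penalty is a correction the SF needs, in pK units per standardized count -
a direct, interpretable localization of the residual error. Because of
this asymmetry, `beta_SF` and the fragment coefficients are **not**
comparable by magnitude; only the fragment coefficients are mutually
comparable.

The Lasso objective is

```
min over (beta0, beta):  (1/N) * ||y - beta0*1 - X beta||^2  +  lambda * ||beta||_1
```

with the explicit `1/N` factor on the squared loss. Solvers using the
`1/(2N)` convention (glmnet) match at `lambda_glmnet = lambda_here / 2`;
the tests verify this conversion numerically. The intercept is never
penalized, and `beta_SF` can optionally be excluded from the penalty
(`penalize_sf = FALSE`); the default penalizes it, i.e. a plain Lasso over
the augmented design, because reported SF coefficients in this kind of
analysis are visibly shrunken and the choice between the two conventions is
otherwise open. Both are available so the sensitivity can be checked.

## 2. Feature definitions

The fragment patterns are data, not code: `inst/extdata/feature_definitions.tsv`,
loaded by `default_features()`. The shipped set is this package's own
generalization of the eleven motif classes:

| name | SMARTS | rationale |
|------|--------|-----------|
| HBD1 | `[#7!H0,#8!H0]` | N/O bearing at least one hydrogen |
| HBD2 | `[#7!H0,#8!H0,#16!H0]` | as HBD1 plus thiols - a deliberate near-duplicate |
| HBA | `[#7,#8;!+]` | non-cationic N/O |
| HP1 | `[CX4]` | sp3 carbon (aliphatic hydrophobic) |
| HP2 | `[CX3]=[CX3]` | C=C double bonds |
| HP3 | `[CX2]#[CX2]` | C#C triple bonds |
| PIPI | `a1aaaaa1` | six-membered aromatic rings (pi-stacking donors) |
| PICat | `[#7+]` | nitrogen cations (cation-pi, ionic) |
| SaltBridge | `[#8-]` | anionic oxygens (carboxylate/phosphate/sulfate) |
| Hal | `[Cl,Br,I]` | heavy halogens (halogen-bond capable) |
| F | `F` | fluorine, isolated because it does not form halogen bonds |

HBD1/HBD2 exist in near-duplicate **by design**: duplicated descriptor
definitions are a routine hazard of assembling motif sets, and the pair
exercises the correlation filter's tie-break (see below) exactly as a real
duplicated donor definition would. Occurrence counting returns the number
of **distinct atom sets** matched - automorphic duplicates of the same
fragment instance collapse to one, so benzene scores 1 whole-ring match,
not 12 atom mappings. Every count in the fixture table
(`gen_toy_ligands()`) was verified against an independent cheminformatics
toolkit at development time and frozen.

The SMARTS engine supports the subset needed for such motif tables
(element/aromaticity/atomic-number primitives, H/X/D counts, charges,
`!`/`&`/`,`/`;` logic, ring closures, bond orders); recursive SMARTS and
ring-count primitives are rejected with a clear error. SMILES input is
taken at face value: aromatic systems must be written in aromatic
(lowercase) form, as no kekulization or aromaticity perception is
attempted. An unmarked bond between two aromatic atoms is aromatic only if
it lies in a ring (so the biphenyl bridge stays single).

Sanitization (`sanitize_ligand()`) repairs the two classic mol2-reading
artifacts - uncharged terminal oxygens on phosphate/sulfate groups and
amidinium groups read with all-single C-N bonds - idempotently and without
ever touching the heavy-atom graph. The oxyanion rules change the total
formal charge by construction: that *is* the correction.

## 3. Correlation filter and standardization

Feature redundancy is measured by the **uncentered cosine**
`r = a.b/(|a||b|)`, not Pearson. On non-negative count vectors the two
differ; the cosine is used literally because the exclusion rule is defined
on it, and a Pearson variant sits behind `method = "pearson"` for
sensitivity analysis. All-zero columns are removed first (they standardize
to 0/0). Then, greedily, the currently worst pair with `r > 0.9` loses the
member present in **fewer** ligands (ties keep the earlier column), and
correlations are recomputed after each removal. The default threshold 0.9
is the conventional QSAR redundancy cut. The exclusion report lists every
(kept, dropped, r) triple.

Standardization divides by the **population** sd (divisor N), the standard
machine-learning scaler convention; means and sds are retained for the
inverse transform and for converting combined-model coefficients back to
raw-count units.

## 4. Numerical choices

* Solver: cyclic coordinate descent with residual updates; closed-form
  soft-threshold coordinate update `b_j = S(x_j'r_j, N*lambda/2)/(x_j'x_j)`.
* Convergence: max coefficient change `< 1e-8`; iteration cap `1e5`;
  `converged` is reported rather than silently trusted.
* KKT subgradient residuals are computed at the solution and exposed
  (`kkt_max`); the tests require `<= 1e-6`.
* `lambda = 0` is solved directly by QR (it is ordinary least squares);
  coordinate descent would converge slowly on correlated designs.
* Coefficients with `|b| < 1e-12` after convergence are snapped to exact
  zero: at the boundary `lambda = lambda_max` the soft threshold leaves
  float dust of order 1e-16 that would otherwise break the exact-zero
  contract. `lambda_max = (2/N) max_j |x_j'(y - ybar)|`.
* Paths are warm-started in increasing lambda; the L1 norm of penalized
  coefficients is non-increasing along the path (tested).
* `r2` is the squared Pearson correlation of fitted vs observed (equal to
  1 - SSE/SST for OLS, not for penalized fits, where both are reported:
  `r2` and `r2_sse`). Residual `sd` uses denominator N - 2, the
  two-parameter regression convention.
* Default lambda grid: 16 points log-spaced on `[1e-3, lambda_max]`.

## 5. The synthetic world

`gen_feature_matrix()` draws counts from a zero-inflated shifted Poisson:
feature `j` occurs in a ligand with probability `occurrence_prob_j`
(occurrence indicators share a Gaussian latent factor with correlation
`rho = 0.2`, giving the mild inter-feature correlation real motif sets
show, while keeping marginals exact), and a containing ligand carries
`1 + Poisson(count_mean_j - 1)` copies. Defaults: 273 ligands x 10
features, the post-exclusion shape of a typical curated benchmark;
occurrence frequencies anchored to the two observable anchors (donors in
~94% of ligands, heavy halogens in ~15%) and otherwise set once to
med-chem-plausible values. They are illustrative, not calibrated - no
occurrence distribution beyond those anchors is published for the real
set.

`gen_affinities()` applies a sparse linear model on **standardized**
features (defaults: hydrophobic and aromatic terms dominant and positive,
ionic terms negative, fluorine positive, donors/acceptors near zero,
intercept 6.2 pK, noise sd 0.5 pK). `gen_sf_scores()` distorts the truth
on **raw** counts: `pK_SF = offset + slope*pK_ref + sum_j bias_j x_ij + noise`.
The asymmetry is intentional and documented: a raw-count bias `delta_j`
appears in the combined model as a standardized coefficient of
`-delta_j * sd_j`, so recovery tests are exact in expectation and the
stored sds convert back to per-count units.

One integer seed drives everything through named substreams (one per
generator call), so changing one generator's parameters never perturbs
another's draws.

What a green synthetic test does **not** establish: that real SF errors
are linear in fragment counts, that real count distributions match the
zero-inflated Poisson, or that 3D structure effects (poses, receptor
identity, water) are captured - the generator has no geometry at all
beyond the toy surface-area fixtures. Green tests establish that *if* the
data follow the stated model, the pipeline recovers the truth at the
stated tolerances.

## 6. Surface areas

`sasa()` implements Shrake-Rupley: each atom's sphere is inflated by the
probe radius (default 1.0 A, the benchmark convention for this score) and
sampled with a deterministic golden-spiral (Fibonacci) point set; a point
is accessible if outside every other inflated sphere. The upstream
"dot density = 3" quadrature setting has no published point-count mapping,
so this package maps it to **960 points per atom** (configurable);
absolute areas may therefore differ from other tools by a small quadrature
factor, while `deltaSAS` differences are much less sensitive (doubling the
point count moves the fixture values by < 0.5%). Radii are Bondi values
shipped as data; the radius set behind other implementations is not
specified, which is a second small source of absolute disagreement.
Hydrogens are included when present (prepared structures come
protonated); `strip_hydrogens` exists for heavy-atom-only inputs.

`delta_sas()` is exactly `(SASA_lig + SASA_prot - SASA_complex)/2` from
three calls with identical parameters - symmetric in the two partners,
zero for non-touching pairs, and verified against analytic sphere and
two-sphere-overlap formulas in the tests.

## 7. Known limitations

* No aromatic perception: Kekule-form SMILES or SDF files without aromatic
  bond flags undercount `PIPI` (write aromatic systems in aromatic form).
* MOL2 files carry no formal charges; charge-dependent features (PICat,
  SaltBridge) rely on the sanitization rules for the common oxyanion
  cases, and unusual cations will be missed.
* The SMARTS subset excludes recursive environments, so context-dependent
  definitions (e.g. "donor not adjacent to carbonyl") cannot be expressed
  in a feature file.
* Cosine-based filtering on high-occupancy count columns is generous:
  two dense but chemically distinct features can exceed 0.9. The Pearson
  flag exists precisely to check this sensitivity.
* `r2` of penalized fits is squared Pearson by convention here; comparing
  against a `1 - SSE/SST` figure from elsewhere requires `r2_sse`.
* ΔSAS treats the given coordinates as the pose; no minimization, no
  water, no polar/apolar surface split.
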