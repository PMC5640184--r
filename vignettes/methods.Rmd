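---
title: "Methods: moderated differential expression, independent expression modes and stage-aware enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated differential expression, independent expression modes and stage-aware enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icadex)
```

`icadex` analyses paired pre/post expression studies in which each subject
carries a continuous exposure covariate — the motivating design is a cohort
of endurance runners sampled before and after a mountain ultra-marathon,
where the exposure is the completed distance in km. The pipeline has two
arms: a *global* arm (which genes respond to the exposure, and which
pathways and transcriptional regulators they over-represent) and an
*independent* arm (which statistically independent expression modes make up
that response, and what each mode is enriched for).

## The per-gene linear model

For gene (or transcript cluster) $k$ the expression value is modelled as

$$ g_k = \beta_{0k} + \beta_{1k}\,g + \beta_{2k}\,d + \epsilon_k $$

with $g \in \{0, 1\}$ coding gender (0 = female, 1 = male) and $d$ the
completed distance in km. Pre-race samples sit at $d = 0$: the covariate
measures accumulated exposure, and zero is the only physically meaningful
pre-race baseline. $\beta_{2k}$ is therefore a log2 change *per km*.
`build_design()` constructs this design, `fit_linear_models()` solves the
per-gene least-squares problems through one shared QR factorisation, and
residual variances use $df = m - 3$.

Age is deliberately not a covariate; a subject-level random effect is also
omitted (the paired structure enters through shared subject baselines in
the simulator, and the fixed-effect model matches the analysis the pipeline
reproduces).

## Empirical-Bayes moderation

With tens of samples and thousands of genes, per-gene variance estimates
are noisy. `ebayes_moderate()` shrinks them towards a prior estimated from
all genes: residual variances are modelled as draws from a scaled inverse
chi-square distribution with $d_0$ degrees of freedom and scale $s_0^2$.
The prior is estimated in closed form by moment-matching on
$e_k = \log s_k^2 - \psi(df/2) + \log(df/2)$: the excess of
$\operatorname{Var}(e)$ over $\psi'(df/2)$ equals $\psi'(d_0/2)$, inverted
by a Newton iteration on the trigamma function (relative tolerance 1e-8,
at most 50 steps). When the observed spread is no larger than the sampling
noise the prior degrees of freedom are infinite and all variances collapse
to $s_0^2$; `d0 = 0` can be forced to recover ordinary t-statistics. The
posterior variance
$\tilde s_k^2 = (d_0 s_0^2 + df\, s_k^2) / (d_0 + df)$ yields moderated
t-statistics on $d_0 + df$ degrees of freedom; the installed `limma`
implementation of the same scheme is used in the test suite as an
independent cross-check, never as the implementation. One $(d_0, s_0^2)$
pair is shared by both tested coefficients, since moderation acts on the
residual variance rather than per coefficient.

Benjamini–Hochberg adjustment (via `stats::p.adjust`, verified against a
direct step-up implementation in the tests) is applied per coefficient, and
`select_differential()` keeps genes with adjusted p below `alpha`
(default 0.05). Multi-annotated features are excluded from the gene-level
list: their gene assignment is ambiguous, and keeping them would double
count genes in every enrichment universe. They are counted and reported
separately.

For display, `select_strong_effects()` retains differential features with
$|\beta_2| > \mu_{\beta_2} + 2\sigma_{\beta_2}$. Whether the moments are
taken over signed or absolute effects is genuinely ambiguous in this kind
of rule; the default reads it literally (moments of the signed
$\beta_2$ compared against $|\beta_2|$) and `convention = "absolute"`
provides the alternative. With a 63:37 down:up split the two differ only
slightly. Heatmap ordering uses complete-linkage clustering on
row-standardized values (standardization is the default and is
configurable, since clustering raw log2 rows lets baseline expression
dominate the dendrogram).

## Quality screening and the expression filter

`compute_rle()` summarises relative log expression (deviation of each
value from its gene's median across samples) per sample as a median and
IQR. `pca_outlier_screen()` scores samples on the first two principal
components and flags robust z-scores ($|x - \mathrm{med}|/(1.4826\,
\mathrm{MAD})$) above `z_cut = 3`. Two numerical choices matter:

* A principal component whose singular value is below $10^{-8}$ of the
  leading one carries no real variance and cannot flag anyone (otherwise
  floating-point noise on a degenerate PC would be standardized into
  spurious outliers).
* When the MAD itself is degenerate (most samples identical), any sample
  with a real deviation is flagged.

The screen is a numeric stand-in for what is usually a visual call on QC
plots. Applied pooled, it has a failure mode this package documents
explicitly: when the intervention effect is strong, PC1 separates pre from
post samples and the minority timepoint is flagged wholesale. The pipeline
therefore screens *within timepoint groups* (`groups =` argument); the
pooled rule remains the function default for generic use.

`filter_low_expressed()` implements the non-supervised filter: a feature is
kept iff it exceeds the grand mean of all log2 values on strictly more
than `min_samples` samples (both inequalities strict). The reference
configuration is 12 arrays out of 28; the pipeline scales that fraction to
the post-QC sample count. The grand mean is recomputed from the filter's
input, so the operation is intentionally not idempotent — the pipeline
applies it exactly once, after sample exclusion.

## PCA, component count and deflation

`fit_pca()` is SVD-based PCA of the gene-centred matrix; scores live on
samples, loadings on genes (orthonormal), and eigenvalues are score-column
variances. `estimate_ncp()` selects the number of informative components.
The default criterion is generalized cross-validation,

$$ \mathrm{GCV}(k) = \frac{nm\,\mathrm{RSS}_k}{(nm - df_k)^2},\qquad
   df_k = m + nk + mk - k^2 - k, $$

the parameter count of a rank-$k$ bilinear fit with centring. Two
numerical guards: the criterion is evaluated from $k = 0$ upward, and the
search is capped by default at half the matrix rank, because at full rank
the residual vanishes identically and the criterion degenerates to zero.
The `"smooth"` alternative is an eigen-gap heuristic (3-point moving
average of eigenvalue drops, largest ratio of successive smoothed drops);
it is provided for comparison, logged by the pipeline, but only GCV
carries a tested recovery guarantee (planted rank 3 in a 200×30 matrix at
10% noise is recovered in ≥90% of 50 seeds).

`deflate_first_component()` removes the first expression mode as a rank-1
reconstruction, $Y^T = z_1 \otimes \phi_1$ and $\hat X^T = X^T - Y^T$.
The deflated matrix is exactly orthogonal to $\phi_1$ and total variance
drops by exactly the first eigenvalue (both asserted to 1e-8 in the
tests). The point of deflation is that a dominant response — in the
motivating study, the immune-system response that PC1 captures — masks
weaker independent modes; removing it first lets ICA resolve them. After
deflation the pipeline extracts $k - 1$ components instead of $k$.

## FastICA and contributor selection

`run_fastica()` factorises $X^T = S A$: the columns of $S$ (samples ×
$k$) are independent source activations, the rows of $A$ ($k$ × genes)
are gene weights. The algorithm is the symmetric (parallel) fixed-point
iteration with the log-cosh contrast, $g(u) = \tanh(\alpha_1 u)$ with
$\alpha_1 = 1$: gene-wise centring, PCA whitening to exactly $k$
dimensions, simultaneous extraction of all components, convergence when
the largest absolute change in the unmixing directions falls below 1e-4
(at most 1000 iterations). Unit-variance whitening is used without gene
standardization; a config switch is unnecessary because the pipeline's
input (a differential-gene log2 matrix) is already on one scale.

Three conventions fix reproducibility where ICA is underdetermined:

* the random orthogonal start is seeded (`seed` is part of the model
  object);
* each component is sign-flipped so its largest-|weight| gene is
  positive (ICA signs are unidentifiable);
* non-convergence — typical when some whitened directions are essentially
  Gaussian, which admit no stable fixed point — returns the current
  estimate with `converged = FALSE` and a warning rather than an error.

Estimation accuracy is bounded by the number of samples, since the
fixed-point expectations average over samples; with a few dozen arrays
the recovered activations of well-separated super-Gaussian modes
correlate with truth at roughly $|r| \approx 0.9$, and approach 1 as the
sample count grows. The planted-source tests therefore use a few hundred
samples when asserting $|r| \ge 0.95$.

`select_contributors()` applies the ninth-decile rule: per component, the
top $\lceil n/10 \rceil$ genes by absolute weight. Selection is rank-based
— exactly $\lceil n/10 \rceil$ genes, ties at the boundary broken by gene
id — so the set size is identical across components and reproducible
(5,084 genes give exactly 509 contributors per component).
`contributor_overlap()` reports the pairwise intersection matrix and
per-component unique counts.

## Hypergeometric enrichment with stage-dependent backgrounds

One engine serves pathway gene-set enrichment and transcriptional
regulator enrichment: a regulator-target database is viewed as a gene-set
database whose terms are regulators and whose universe is the union of
target sets. For a term with $K$ background genes, a list of $n$
background genes and overlap $k$ against a background of size $N$,
`hypergeometric_upper_tail()` returns the inclusive tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated through the
log-space survival function so extreme geometries (p below 1e-300) stay
finite.

The background is stage-dependent (`stagewise_background()`):

* **global stage** — background = the database universe; list = the
  differential genes present in it;
* **component stage** — background = the differential genes present in
  the universe; list = the component's contributors within that
  background.

The component stage thus asks which terms concentrate in a mode *given*
the differential response, not merely which terms the response hits.
Query genes outside the background are dropped (and counted); terms with
no background gene are excluded before BH adjustment, which runs within
each database and stage, never pooled across databases. Significance
stars encode the adjusted p-value (`***` < 0.001, `**` < 0.01, `*` <
0.05). When a regulation map is supplied, each term reports the
percentage of its overlap genes that are up-regulated; genes missing
from the map leave the denominator.

`build_network()` exports the significant-term/gene bipartite graph
(GraphML plus an edge-list TSV) with regulation directions on gene nodes.
No figures are rendered by the core pipeline; `autoplot()` /
`plot_enrichment()` cover interactive use so the pipeline itself stays
headless.

## What the synthetic data emulates

`simulate_dataset()` generates the study conditions end to end: 16
subjects each with a pre-race sample, 12 of them with a post-race sample
(28 arrays), completed distances drawn from an observed 14–82 km race
record, a 12:5 male:female ratio, 10% of genes carrying a true distance
effect with $|\beta_2| \sim \Gamma(\text{shape}=10,\ \text{mean}=0.05)$
log2 per km and a 63:37 down:up split, 1% gender-responsive genes,
gene-wise noise variances from the scaled inverse chi-square prior
($d_0 = 4$, $s_0^2 = 0.05$), shared subject baselines linking paired
samples, and three latent modes with Laplace (super-Gaussian) activations
— mode 1 scaled up (default ×8) to act as the masking signal, 10% of
genes loaded per mode. The effect-size scale is chosen so typical planted
effects exceed three noise standard deviations across the observed
distance range, the regime in which the differential arm is expected to
reach ≥90% recall at ≤10% empirical FDR. A Gaussian activation option
exists purely as a negative control (Gaussian modes are not identifiable
by ICA).

One deliberate deviation from full realism: mode activations are
residualized against the design (intercept, gender, distance) before use.
Planted modes therefore contribute *no* distance signal, which keeps the
differential ground truth exact — a mode gene is a true null unless it
also carries a planted $\beta_2$. Real latent biology is of course not
orthogonal to the exposure; the simulator trades that realism for an
unambiguous FDR/recall bookkeeping. Other features of real arrays the
generator does not attempt: probe-level effects, batch artifacts,
intensity-dependent variance, annotation errors. Passing tests therefore
validate the statistical machinery under the stated model, not robustness
to those artifacts.

`simulate_databases()` builds pathway and regulator databases over the
simulated universe, with designated terms oversampling a target gene
group at configurable odds, so enrichment has known positives (and, at
odds 1, known nulls).

## Problem sizes and determinism

The shipped tests run the full pipeline on 800–2,000 simulated genes and
28 samples, recover the variance prior at 5,000 genes, check the
hypergeometric tail against exhaustive enumeration for every geometry
with $N \le 12$, compare BH against an independent step-up oracle on
1,000 random vectors, and repeat stochastic checks over 5–100 seeds
depending on the cost of one replicate — sizes chosen so the whole suite
runs in well under a minute on one core while keeping Monte-Carlo error
far from the asserted margins. All randomness flows from explicit seeds;
`run_pipeline()` with a fixed configuration and seed reproduces its run
manifest, tables and contributor sets byte for byte.

## Known limitations

* The PCA outlier rule is an operationalization of a visual judgement;
  its within-group variant presumes the timepoint labels are trustworthy.
* The GCV parameter-count formula is an approximation; outside the
  capped search range (half the matrix rank) the criterion is
  uninformative by construction.
* With a few dozen samples, ICA activations are estimates with
  appreciable sampling noise; contributor sets of weak modes should be
  read as rankings, not fixed gene lists.
* Gene sets are treated as flat; no ontology-graph propagation or
  topology-aware scoring.
* The enrichment engine conditions on the realized gene list; it does not
  model selection uncertainty from the differential step.
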