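---
title: "Models and methods: mutational effects on gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mutational effects on gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maexpr)
```

# The scientific setting

Mutation accumulation (MA) experiments propagate replicate lines through
repeated single-cell bottlenecks so that spontaneous mutations fix with
minimal interference from selection. Sequencing the transcriptomes of MA
lines next to their unmutated ancestor turns the accumulated mutations
into a direct readout of how de novo mutation perturbs gene regulation.
`maexpr` implements the statistical machinery for such an analysis in a
haploid unicellular design — two ancestral strains, on the order of a
dozen MA lines each, three biological replicates per line, and roughly a
thousand generations of propagation — together with a generative
simulator so every stage can be exercised and validated against known
truth without access to any external data set.

This vignette explains the models, their assumptions, the tunable
parameters and defaults, and the numerical choices. It states no
empirical result that the package's test suite and acceptance script do
not themselves compute.

# Differential expression against the ancestor

DEG calling follows the standard count-based contract: median-of-ratios
size factors, a low-count filter that retains a configurable fraction of
genes (default 95%), a per-gene negative-binomial Wald test of each MA
line against the ancestor of its strain, and Benjamini–Hochberg
correction at FDR 0.05.

The caller in `call_degs()` is deliberately simplified relative to a
production differential-expression package: dispersions are estimated by
the method of moments on normalized counts, shrunk toward a fitted
`a0 + a1/mu` mean–dispersion trend with a prior weight of five residual
degrees of freedom, and the two-group NB GLM is solved exactly per gene
(a one-dimensional Newton step per group with size-factor offsets),
giving a Wald z statistic for the line-vs-ancestor log fold change.
There is no outlier (Cook's) filtering and no fold-change shrinkage. The
contract — Wald test, BH, FDR threshold — is what downstream analyses
consume, and externally produced DEG tables in the same schema
(`gene_id`, `log2fc`, `p`, `p_adj`, `significant`, `direction`) can be
substituted anywhere. When a group mean is zero the reported log2 fold
change uses a pseudocount (default 0.5) on normalized means, and the
Fisher information is floored so standard errors stay finite.

Replicate quality control (`replicate_qc()`) computes each replicate's
mean Pearson correlation with its siblings on FPKM values; replicates
below the threshold (default 0.96) are flagged for exclusion from
mean-based summaries but deliberately retained for DEG calling, where
the model accounts for replicate variance.

Per-line DEG fits are contrasted pairwise against the ancestor rather
than through one joint multi-line model; with per-line random divergence
this keeps each contrast self-contained and is the assumption recorded
here.

# Mutational variance: a Poisson mixed model per gene

For one gene, read counts \(Y_{ijk}\) (line \(i\), replicate \(k\)) are
modelled as Poisson with log link:

\[
\log \lambda_{ijk} = \beta_0 + \beta_1 x_i + u_{1i} x_i + b_{ik} +
\ln(1/\mathrm{sf}_{ik}),
\qquad u_{1i} \sim N(0, \sigma^2_u),\quad b_{ik} \sim N(0, \sigma^2_b).
\]

The covariate \(x_i\) is the number of generations since the ancestor
(or the line's mutation count, selected by `covariate_kind`, which
rescales the divergence to "per mutation"). The per-line random slope
\(u_{1i}\) captures heritable between-line divergence accumulating with
\(x\); the observation-level random effect \(b_{ik}\) absorbs
extra-Poisson dispersion and plays the role of the environmental
residual. The mutational variance is \(V_m = 2\,\widehat{\sigma}^2_u\),
the environmental variance \(V_e = \widehat{\sigma}^2_b\), and the
mutational heritability \(h^2_m = V_m / V_e\).

Choices worth making explicit:

* **Intercept.** The divergence model can be written without a fixed
  intercept, but a Poisson model of expression level needs a baseline;
  `fit_gene_glmm()` always includes \(\beta_0\).
* **Offset sign.** The size-factor offset is \(\ln(1/\mathrm{sf})\) by
  default (`offset_sign = "printed"`); the conventional
  \(+\ln \mathrm{sf}\) is available via `offset_sign = "standard"`.
  The offset enters the linear predictor additively, so a global
  rescaling of all size factors is absorbed by the intercept and leaves
  \(V_m\) and \(V_e\) unchanged; the suite checks this at \(10^{-4}\)
  relative tolerance.
* **What \(V_e\) is.** In a Poisson GLMM the observation-level random
  effect *is* the extra-Poisson residual, so \(V_e :=
  \widehat{\sigma}^2_b\). Whether Poisson sampling variance should also
  be counted as "environmental" is a modelling convention; it is not
  included here.
* **Numerics.** Fitting uses `lme4::glmer` with the Laplace
  approximation. The covariate is rescaled to unit range internally and
  the estimates mapped back exactly (\(\hat\beta_1 \mapsto
  \hat\beta_1/c\), \(\widehat{\sigma}^2_u \mapsto
  \widehat{\sigma}^2_u/c^2\)), which makes covariate-rescaling
  equivariance exact by construction and keeps the optimizer
  well-conditioned when \(x \sim 10^3\).
* **Degenerate fits.** When \(\widehat{V}_e\) collapses to the boundary,
  \(h^2_m\) is returned as `NA` with `h2_defined = FALSE` — never
  infinity. Non-convergence is flagged (`converged = FALSE`) with the
  best-found estimates, never silently dropped.

`variance_table()` maps the fit across genes within a strain, reports
per-gene components with convergence flags, strain-level medians over
converged fits, and accepts an exclusion list so hypermutator lines can
be removed; exclusion refits from scratch.

# The distribution of expression effects (DEE)

The central inferential object is the distribution of the number of
genes \(X\) whose expression a single de novo mutation perturbs,
inferred only from per-line pairs \((m_i, d_i)\) of mutation count and
DEG count. Three nested models are supported (`dee_loglik()`):

* **gamma** — \(X \sim \Gamma(\text{shape}, \text{scale})\);
* **zero_gamma** — a point mass \(\pi_0\) at zero, else
  \(X = 1 + \Gamma(\text{shape}, \text{scale})\) (the shifted gamma);
* **zero_one_gamma** — additionally a point mass \(\pi_1\) at exactly
  one perturbed gene.

A line's DEG total is the sum of \(m_i\) independent draws. Because
sums of i.i.d. gamma variables stay gamma, the total given \(j\)
non-null mutations is \(j + \Gamma(j \cdot \text{shape}, \text{scale})\)
and the marginal likelihood is a binomial mixture over \(j\) (and, for
the three-component model, a further binomial convolution over the
exact-one spikes). The observed integer count \(d\) is matched to the
continuous total through the interval probability over \([d, d+1)\):
the interval convention is numerically stable at \(d = 0\) and for
shapes below one, where a density evaluation would be degenerate. All
mixture sums are accumulated in log space; interval probabilities use
the CDF in the left tail and the survival function in the right tail
(the naive CDF difference cancels catastrophically far into the upper
tail), and mixture terms whose binomial weight is below \(10^{-12}\)
are truncated with a guaranteed minimum window of eleven terms.

Fitting (`fit_dee()`) mirrors the original protocol: the zero-spike
weight is constrained to each of the five 0.2-wide intervals of
\([0,1]\] in turn and the best interval wins; within an interval the
search is seeded simulated annealing (`optim(method = "SANN")`) on
box-transformed parameters (logistic maps into shape
\(\in (10^{-4}, 10^2)\) and scale \(\in (10^{-2}, 10^5)\)), polished by
a quasi-Newton local optimizer. The desk-scale default budget (2,000
annealing steps per start, two random restarts per interval, plus the
deterministic polish) replaces the original's much larger fixed
iteration count; because the polished objective is smooth in the
transformed coordinates, the annealing stage only has to land in the
right basin. Everything is reproducible from one integer seed, and
permuting the line order does not change the result.

Model choice (`select_model()`) minimizes AIC, breaking ties toward
fewer parameters and flagging any AIC/BIC disagreement. Summaries come
in closed form: the mean number of perturbed genes per mutation is
\((1-\pi_0)(1 + \text{shape}\cdot\text{scale})\) for the two-component
model, and the per-mutation category probabilities \(P(0), P(1),
P(2{+})\) follow from the gamma CDF at 1 under the same interval
convention. `simulate_deg_counts()` draws whole simulated experiments
from a fitted DEE to ask whether the observed mutation-count/DEG-count
correlation is as strong as the additive model predicts.

# Colocalization tests

Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
is converted at the boundary by the readers/writers.

* **Cis proximity** (`cis_enrichment_test()`): the statistic is the
  number of DEGs with a mutation within 100 bp of the gene flanks,
  intragenic mutations included (they are assigned distance 1 by
  `nearest_mutation_distance()`). The null keeps mutation positions
  fixed and redraws DEG labels uniformly over the gene universe — so
  enrichment of DEGs near mutations is distinguished from mutations
  simply sitting near genes. Both the DEG-side and the mutation-side
  counts are reported, since "mutations near DEGs" and "DEGs near
  mutations" differ when several mutations flank one gene.
* **UTR enrichment** (`utr_enrichment()`): among intragenic mutations,
  the UTR fraction divided by the UTR share of sequence space. The
  default denominator is total gene-model bp (UTR placement *given*
  that a mutation is intragenic); the whole genome is available via a
  flag.
* **SV overlap** (`sv_deg_overlap_test()`): a gene is SV-overlapped if
  its model interval intersects any SV interval by at least 1 bp
  (translocations enter as their recorded interval); the statistic is
  the proportion of SV-overlapped genes that are DEGs, against random
  DEG sets of the same size. Duplicate SV records collapse under set
  semantics.

All permutation p-values use the add-one convention
\(p = (b+1)/(n_{\text{perm}}+1)\), so \(p \in [1/(n_{\text{perm}}+1),
1]\) and exact zeros are impossible. Significance is reported at
\(\alpha = 0.05\) with the marginal band \((0.05, 0.1)\) flagged
separately.

# Co-expression network and DEG clustering

`build_network()` computes the unsigned soft-threshold adjacency
\(a_{ij} = |\mathrm{cor}(i,j)|^\beta\) (default \(\beta = 2\); the sign
choice is a design decision — unsigned keeps strong repressive
correlations adjacent), the topological overlap matrix, average-linkage
hierarchical clustering on \(1 - \mathrm{TOM}\), a dendrogram cut into a
configurable number of modules (the cut rule itself is not specified by
the protocol being mirrored, so the module count is the exposed knob,
defaulting to roughly one module per 25 genes, capped at 33), iterative
merging of module pairs whose eigengenes — first principal components of
the module expression — correlate at \(\ge 0.75\), and intramodular/total
connectivity with hub genes as the top 5% of intramodular connectivity
per module.

For path queries the dense correlation graph is sparsified: edges with
\(|\mathrm{cor}|\) below a floor (default 0.1, recorded in the network
object) are dropped and remaining edges get length
\(1/|\mathrm{cor}|\), so short total path length means strong chained
correlation. "Path length" is the sum of edge lengths along the
weighted shortest path (Dijkstra, via igraph); unconnected pairs are
excluded rather than given infinite length.

`deg_clustering_test()` asks whether a line's DEGs sit closer together
in this network than expected. Because highly expressed genes are both
more likely to be called DEGs and differently placed in the network,
the null is expression-matched: genes are stratified into five quantile
bins of ancestral expression with the top bin split (expression is
right-skewed, so the top bin would otherwise be too heterogeneous), and
each permutation draws the observed number of DEGs per stratum. The
statistic is the median pairwise shortest-path length; the p-value is
the add-one fraction of permutations with a median at least as short.
A stratum smaller than its required draw falls back to sampling with
replacement and the result is flagged. With fewer than two connected
DEGs the test is undefined and says so (`p = NA`) rather than
fabricating a value.

# Expression correlates and fitness

`percentile_bins()` assigns equal-size rank bins (ties broken by stable
input order, making labels invariant under monotone transforms);
`median_change_by_bin()` summarizes each gene's median log2 fold change
across lines per bin. Two-group comparisons use the Brunner–Munzel
studentized rank statistic (`brunner_munzel()`), with Satterthwaite
degrees of freedom and a two-sided t-approximation — chosen over
rank-sum tests because it is valid under unequal variances; the
stochastic-superiority estimate \(P(X<Y) + \frac12 P(X=Y)\) is
returned. Complete separation returns superiority 1 and p = 0; samples
with degenerate rank variance raise an error naming the sample.

`fitness_regression()` is ordinary least squares of relative fitness on
a divergence summary (DEG count or summed |log2fc|), pooled across
strains, with a systematic leave-one-out influence report in place of
any ad hoc single-point exclusion: the slope, \(R^2\) and p-value are
recomputed without each line, so an influential line is visible rather
than silently removed.

# The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_experiment()`
produces annotation, truth and counts. Defaults are anchored to the MA
design described above wherever that design states a number: 2 strains
with 15 and 13 lines, 3 replicates, 800–1,100 generations, strain means
of 76.2 and 112.1 mutations per line, and the two-component DEE with
\(\pi_0 = 0.42\), shape 0.0118, scale 2,005 (mean 14.3 perturbed genes
per mutation). Where the design states no number, one realistic value
was chosen once and is documented here:

* `n_genes = 1000` on two 2-Mb chromosomes — a desk-scale genome; a
  real transcriptome is an order of magnitude larger, and tests use
  smaller values still.
* `cis_fraction = 0.2` of single-target mutations placed within 100 bp
  of their target, consistent with roughly one in ten of all mutations
  being proximal once the ~53% single-target share is accounted for.
* `effect_sd_log2 = 1.5`: perturbed genes receive signed normal log2
  shifts, putting typical true DEG effects in the 2–4 fold range.
* `baseline_log_mean = 4`, `baseline_log_sd = 1.2`: log-normal
  ancestral levels spanning a realistic dynamic range around ~55
  counts.
* `olre_sd = 0.2`: observation-level log-normal noise, equivalent to a
  negative-binomial dispersion of about 0.04.
* `sv_per_line = 30` with type frequencies and length scales matching
  the published SV catalogue of this system; each SV-overlapped gene
  gains an expression effect with probability `sv_effect_prob = 0.5`,
  so overlap tests have signal to find.
* `fitness_slope = -1e-3` per distinct affected gene with measurement
  noise `fitness_noise_sd = 0.1` — a linear stand-in for the fitness
  decline, chosen to make decline detectable at desk scale without
  asserting any mechanism.

Mechanically: mutation counts are Poisson per line; each mutation draws
its effect count \(X\) from the configured DEE, rounded to the nearest
integer with minimum 1 for non-spike draws (the continuous DEE has to
be discretized somewhere; rounding is the convention used throughout);
single-target mutations are cis candidates and are physically relocated
next to their target when selected; multi-target mutations draw all
targets from one synthetic co-expression module, which is the stand-in
generative rule that makes trans pleiotropy visible to the network
clustering test — the real regulatory architecture is unknown, and this
choice is flagged as such. Counts are Poisson draws of
\(\mathrm{sf}_s \exp(\mu_j + \delta_{j,\text{line}} + b_s)\). One
master seed drives everything through deterministically derived child
seeds, so any artifact is byte-reproducible.

What the simulator does **not** emulate: read-level artifacts (GC,
mappability, gene-length bias beyond the annotation), correlated
baseline expression between genes (except in
`simulate_module_expression()`, which exists precisely to give the
network stages structure), epistasis or compensatory interactions among
mutations, and selection during propagation. Passing tests on this
generator therefore validate the statistical machinery under the
stated model, not the biology of any particular data set.

# Problem sizes and reproducibility

The test suite and the acceptance script choose problem sizes that keep
each stage honest but desk-sized: DEE recovery uses 20 replicate
28-line experiments at the published parameters; mixed-model recovery
uses 100 genes at 15 lines × 3 replicates; permutation calibration uses
500 null lines per test at 199 permutations (the add-one p-value grid
then puts exactly 5% of the null mass at or below 0.05); power checks
use 50 seeded experiments with planted cis or module signal. All
randomness flows from explicit integer seeds.

# Known limitations

* The DEE likelihood treats mutations as exchangeable and additive;
  interactions, compensation and mutator heterogeneity are outside the
  model (a deliberately scoped choice — the 28-line design cannot
  support more).
* The NB caller's moment/trend dispersion is serviceable at 3 + 3
  replicates but less efficient than full shrinkage estimators; its FDR
  control is validated on the generator, not proven distribution-free.
* The three-component DEE model ("zero_one_gamma") is one reading of a
  spike-at-0-and-1 structure; its extra spike is only weakly
  identified at realistic line counts.
* `V_e` excludes Poisson sampling variance by construction; comparisons
  with estimates defined otherwise need care.
* Module detection cuts the dendrogram at a configurable count rather
  than an adaptive rule; hub labels and connectivity depend on that
  choice.
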