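---
title: "Methods: from GWAS summary statistics to drug-repurposing evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GWAS summary statistics to drug-repurposing evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`gwas2drug` chains five statistical components: gene-level association
scoring from SNP summary statistics, competitive gene-set regression,
an enrichment-curve AUC statistic for groups of gene-sets (drug classes),
kernel generative topographic maps of gene-set collections, and
protein–protein-interaction network metrics.  This vignette documents the
models, their assumptions, the tunable parameters, and the numerical and
design choices — including where the underlying methodology left genuine
freedom and what this package chose.

# Input preparation

Coordinates are 1-based inclusive (Ensembl convention) everywhere.  SNPs
are filtered on minor allele frequency with an *inclusive* threshold
(default 0.01: MAF = 1% is kept).  Inflation correction converts each
p-value to a 1-df chi-square, divides by the LD-score-regression
intercept, and converts back; intercepts below 1 are clamped to 1 with a
warning, since deflating test statistics is never intended.  When several
studies of growing sample size are compared, each is first restricted to
the SNP ids shared by all.

SNP-to-gene assignment uses a 35 kb upstream / 10 kb downstream window
around the gene body, intended to capture regulatory regions.  We treat
the window as **strand-aware**: "upstream" always means 5′ of the
transcription start, so on the minus strand the 35 kb pad sits on the
high-coordinate side.  The window convention for minus-strand genes is a
genuine choice — the regulatory-region rationale only makes sense in
transcript orientation, so that is what we implement.  The extended MHC
region (chr6:25,652,464–33,771,788) can be excluded; we apply the same
strand-aware 35/10 kb padding before testing the overlap, so genes that
would be scored from MHC SNPs are removed too, another point on which we
had to fix a convention.

# Gene scoring

Gene p-values combine a *top* and a *mean* SNP model, both aware of the
gene's SNP correlation (LD) matrix $R$:

* **Top model**: $p_{top} = 1 - (1 - \min_i p_i)^{M_{eff}(R)}$, a Šidák
  correction with the effective number of tests $M_{eff}$, defined as the
  smallest number of leading eigenvalues of $R$ reaching 99.5% of its
  trace.  Independent SNPs give the full correction; perfect LD gives
  none.
* **Mean model**: $T = \sum_i z_i^2$ has null distribution
  $\sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the eigenvalues of $R$; its
  tail is evaluated by Satterthwaite moment matching with a scaled
  chi-square (scale $\sum\lambda^2/\sum\lambda$, df
  $(\sum\lambda)^2/\sum\lambda^2$), exact whenever the eigenvalues are
  equal.
* **Combination**: the two probit scores are Stouffer-combined with a
  correlation-aware denominator, $z = (z_t + z_m)/\sqrt{2 + 2\rho}$.
  The null correlation $\rho$ of the two models is estimated by seeded
  Monte-Carlo (default 1000 draws of $Z \sim MVN(0, R)$ pushed through
  both models) and cached per distinct LD matrix.  Probits saturate at
  $|z| \le 37$ to avoid infinities at machine-precision p-values.

This gene model is an **approximation authored by this package**, designed
to be self-contained and oracle-checkable: it reproduces the qualitative
behaviour of combined top+mean gene scoring (Šidák/Satterthwaite limits,
perfect-LD collapse, monotonicity in signal strength) without claiming
numerical compatibility with any external gene-analysis tool.

# Competitive gene-set regression

The gene Z-scores are regressed on set membership plus covariates:
$Z = \beta_0 + \beta_s\,\mathbb{1}[g \in S] + \Gamma\,C$, with a one-sided
test of $\beta_s > 0$ ("genes in the set are more associated than genes
outside it").  The covariates correct the known confounders of gene-level
scores: gene size, SNP density, a minor-allele-count proxy (sum of
assigned SNP MAFs), and — because it is unstated whether raw or log scale
is the right one — both the raw and log forms are included, with automatic
pruning of covariates that turn out collinear.  The error covariance
defaults to the identity (OLS); a gene–gene correlation matrix can be
supplied and is handled by Cholesky whitening.  A zero-variance response
returns p = 1 with a warning rather than failing; a singular design is an
error naming the collinear columns.

Multiple-testing machinery: Benjamini–Hochberg, Benjamini–Yekutieli
(with $c(m)=\sum 1/i$), Bonferroni, and Bonferroni with an effective test
count from the same 99.5%-eigenvalue rule.  Druggable-gene selection uses
two Bonferroni cut-offs — $0.05/4298 = 1.163\times10^{-5}$ for the
druggable genome and $0.05/19870 = 2.516\times10^{-6}$ for the whole
protein-coding genome — and partitions significant genes by which they
pass, and by druggability tier.

# Drug libraries

Drug gene-sets merge two kinds of interaction records: curated drug–gene
pairs and binding-affinity measurements.  Affinity records pass at
$K_i \le 10\,\mu M$ by default; the exact activity cut-off used upstream
of such analyses is typically not published, so we expose it as
configuration (`ki_max_nM`) and default to the standard 10 µM screening
threshold.  Symbols without an identifier mapping are dropped and counted
in a report rather than failing the build.  ATC classes are formed at a
configurable code level (default 3 characters, e.g. N05) and scanned only
when they hold at least 10 drugs.  No minimum drug-set size is imposed by
default; it is configurable.

# Enrichment AUC and its significance

Drugs are ranked by $-\log_{10}(p_{competitive})$.  For a class, the
enrichment curve tracks the fraction of class members recovered (y)
against the fraction of non-members passed (x).  We deliberately put the
*non-hits* on the x-axis (the ROC convention) rather than the full ranked
list: with that choice the trapezoidal area equals
$100\,U/(n_1 n_2)$ exactly, where $U$ is the Wilcoxon–Mann–Whitney
statistic with ties credited $1/2$ — the identity that motivates using
WMW p-values for the AUC in the first place.  The area is accumulated in
integer units of hit × non-hit pairs, so boundary cases (perfect
separation = exactly 100%) carry no floating-point slack.  Tied scores
contribute a single diagonal segment.

Significance is a one-sided WMW test (class scores higher): exact
enumeration when the pooled size is ≤ 20 without ties, otherwise the
normal approximation with tie and continuity corrections; a completely
tied pooled sample returns 1.  The class scan applies Bonferroni over the
number of classes actually scanned — not a fixed constant — so 49 scanned
classes give a threshold of $0.05/49 \approx 1\times10^{-3}$.

# Pathway maps

Gene-sets are encoded as binary gene-content vectors and compared by
Tanimoto similarity $K_{ij} = |A_i \cap A_j| / |A_i \cup A_j|$.  The
kernel GTM is realized as standard GTM on a kernel-PCA embedding whose
dimension D captures 99.5% of the centered-kernel variance — exactly how
the feature-space dimension is prescribed for this family of methods; we
make no claim of equivalence with other kernel-GTM formulations.
Parameter rules: latent grid $k = \mathrm{round}(\sqrt N)$ per side, RBF
grid $m = \mathrm{round}(\sqrt k)$ per side — the square-root rules leave
rounding unspecified, so we round to nearest and floor both at 2 — RBF
width $w$ × the RBF grid spacing with $w = 1$, regularization $l = 1$.

Numerical choices in the EM fit:

* Initialization is deterministic: the latent grid is mapped through the
  first two principal axes of the embedding, scaled by their standard
  deviations; the noise precision $\beta$ starts at the reciprocal of the
  mean squared distance between the initially projected nodes and the
  data.
* With $l > 0$ the quantity EM provably never decreases is the *penalized*
  objective (data log-likelihood minus $\tfrac{l}{2}\lVert W\rVert^2$);
  that is what the `loglik` trace records and what the internal
  monotonicity sentinel checks (tolerance $10^{-9}$, violation = internal
  error).  The unpenalized log-likelihood is stored alongside as
  `loglik_data`.
* Convergence: relative objective change below $10^{-6}$ or 500
  iterations.

Projections are posterior means over the latent grid (convex combinations
of the nodes, hence inside $[-1, 1]^2$); duplicated gene-sets project
identically.  The map has no intrinsic orientation, so all validation uses
distances, never absolute coordinates.  Maps are colored by
$-\log_{10}(p)$ via ordinary kriging: an exponential variogram
$\gamma(h) = c_0 + c_1(1 - e^{-h/a})$ fitted to the binned empirical
semivariogram by weighted least squares (Cressie-style weights
$N_k/h_k^2$), with $\gamma(0)=0$ enforced so the surface honors the data
at observation points; when the variogram fit fails or collapses the
surface falls back to inverse-distance weighting, recorded in the output
metadata.  "Top 50" map selection breaks p-value ties by lexicographic
set id, so reruns are stable.

# Networks

PPI edge tables (combined scores in [0, 1000]) become undirected simple
graphs; the score only gates edge inclusion — centralities are computed on
the unweighted topology, since there is no principled way to interpret
the combined score as a path length.  Degree is normalized by $n-1$
possible neighbours and betweenness by $(n-1)(n-2)/2$ pairs, both as
percentages; the normalization denominators are stated because percentage
thresholds (hubs at 5% degree, 2.5% betweenness by default) only make
sense relative to them.  Subnetwork display rules: proteins targeted by at
least 2 distinct drugs of a class; genes present in at least 10 pathways
of a collection.  Significant genes are classified against GWAS loci as
`overlap` (strand-aware 35/10 kb pad intersects a locus), else
`ld_window` (symmetric 500 kb pad intersects), else `independent` — the
near rule is strand-aware because it is the regulatory-window rule, the
LD rule symmetric because LD decay has no strand.

# The synthetic generator: what it does and does not emulate

`gen_gwas()` draws per-gene SNP Z-scores from a multivariate normal with
*exchangeable* within-gene correlation (`ld_rho`, default 0.2) and
independence between genes — the simplest structure that exercises the
effective-test and GLS logic.  Causal genes (5% by default) shift every
SNP Z-score by `effect_delta` (default 2).  MAFs are uniform on
[0.005, 0.5] so the 1% filter always removes something.  Gene bodies are
5–50 kb on a 200 kb grid across ≥ 2 chromosomes, so scoring windows never
bridge neighbours.  The drug library assigns 300 drugs round-robin to 10
ATC classes; planted-class drugs draw Binomial(size, 0.9) of their genes
from the causal set.  Pathway collections perturb cluster templates by
swapping 10% of genes.  PPI graphs are Erdős–Rényi (optionally fully
connected or hub-biased) with scores uniform in the STRING range.

What passing tests on these data do **not** show: behaviour under
realistic human LD (long-range, block-structured, between-gene), real MAF
spectra, real drug-target promiscuity distributions, or correlated gene
scores induced by physical proximity.  The generator validates the
statistical machinery, not population-genetic realism.

# Validation problem sizes

The test suite works at sizes chosen to make the statistical checks sharp
yet quick to rerun: AUC calibration uses 500 replicates of 1000 scored
sets with 100 random hits (mean within 50 ± 1%); null calibration of the
competitive test and the WMW test uses 1000 replicates each
(Kolmogorov–Smirnov at α = 0.01, type-I error within the binomial 99% CI);
β recovery uses 100 replicates of a 2000-gene universe with a 50-gene set
shifted by +1 (median within 1.0 ± 0.15); EM monotonicity is checked over
200 seeded fits; and the end-to-end planted-class recovery runs 20
replicates at the generator defaults (2000 genes, 300 drugs,
planted_bias 0.9, effect_delta 2), requiring the planted class to attain
the maximum AUC and pass the realized Bonferroni threshold in the median
replicate.

# Known limitations

* The gene model approximates combined top+mean scoring; it is not a
  drop-in replacement for any external gene-analysis software, and
  gene-gene correlation estimation from an LD reference panel is out of
  scope (the competitive test accepts a correlation matrix if you have
  one).
* The WMW normal approximation is used for all but very small classes;
  for classes of ~10 drugs in thousands, its p-values are accurate but
  not exact.
* Kernel-GTM maps are identifiable only up to symmetries of the latent
  grid; compare distances and neighbourhoods, not coordinates, across
  runs.
* The synthetic generator's exchangeable LD understates the difficulty of
  real fine-mapping; power estimates derived from it are optimistic.
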