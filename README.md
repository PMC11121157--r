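# sCClust

Multi-omics cancer subtyping by sparse canonical correlation analysis
(sCCA) and latent-space clustering, with survival-based evaluation of
the identified subtypes.

## The problem

Matched tumor profiles — e.g. gene expression and DNA methylation on the
same patients — each carry partial, noisy views of the same underlying
disease biology. With far more features than patients (p, q ≫ n),
classical canonical correlation analysis is degenerate: infinitely many
weight vectors correlate the two views perfectly. `sCClust` integrates
the two views with *sparse* CCA, clusters patients in the shared
low-dimensional space, and judges the resulting subtypes by how well
they separate survival outcomes. It is aimed at computational biologists
who have paired omics matrices plus clinical follow-up and want
reproducible, survival-validated molecular subtypes.

## The method

**Sparse CCA.** For data matrices X (n × p) and Y (n × q), find weight
vectors w₁, w₂ maximising

    Cov(X w₁, Y w₂) − τ₁‖w₁‖₁ − τ₂‖w₂‖₁   s.t.  Var(X w₁) = Var(Y w₂) = 1,

with a *separate* sparsity penalty per view — expression and methylation
rarely need the same number of active features. Under the unit-variance
constraints this maximises the correlation of the canonical scores
u = X w₁, v = Y w₂, and is solved by alternating elastic-net
regressions (cyclical coordinate descent with soft-thresholding,
compiled in C++), each followed by rescaling to unit score variance.
Further components are extracted after deflating both views on their
own score vectors. With τ = 0 and p, q < n the procedure reproduces
classical CCA to machine precision (this is a unit test).

**Clustering.** The per-component scores (u_k, v_k) are z-scored,
concatenated, and clustered with k-means (k-means++ seeding, multiple
restarts). Elbow (WSS), silhouette and BSS/WSS diagnostics support the
choice of k.

**Survival evaluation.** For C subtypes with sizes nᵢ, a grouped Cox
proportional-hazards fit yields per-subtype log-hazard coefficients
β̂ᵢ, size-weighted centered so Σ nᵢ β̂ᵢ = 0. Reported statistics:

- **HRmin** = min over pairs of max(exp(β̂ᵢ−β̂ⱼ), exp(β̂ⱼ−β̂ᵢ)) — the
  worst-separated pair of subtypes; always ≥ 1;
- **SEP** — exp(Σ (nᵢ/n)|β̂ᵢ|) (reciprocal convention, ≥ 1, the default)
  or its inverse exp(−Σ (nᵢ/n)|β̂ᵢ|) (printed convention, ≤ 1); every
  output labels the convention used;
- the K-sample **log-rank** test and **Kaplan–Meier** curves;
- the **global Schoenfeld test** (GST) of proportional hazards on ranked
  event times — p > 0.05 supports the hazard-ratio analysis.

**Model selection.** `gridSearch()` scans (τ₁, τ₂, K) at fixed k and
selects the point maximising HRmin among those where the GST retains
proportional hazards.

**Interpretation.** Per subtype, moderated-t differential expression
(subtype vs rest) feeds hypergeometric over-representation analysis of
GMT gene-set collections; genes are also ranked by average absolute
canonical weight.

A seeded synthetic-data module (`simulateStudy()`, `genPairedOmics()`,
`genSubtypeSurvival()`, `genGeneSets()`) generates paired views with
planted sparse loadings, clusters, hazards and enriched gene sets, so
every stage is testable with known ground truth.

## Worked example

```r
library(sCClust)

## a synthetic study: 200 patients, 300 + 400 features, 3 subtypes with
## true hazard ratios 1 : 2 : 4 and a planted enriched gene set
sim <- simulateStudy("recovery", seed = 7)
x <- standardizeColumns(sim$x)
y <- standardizeColumns(sim$y)

fit <- fitSCCA(x, y, SCCAConfig(tau1 = 0.1, tau2 = 0.1,
                                ridge1 = 1e-3, ridge2 = 1e-3,
                                nComponents = 3))
canonicalCorrelations(fit)
#> [1] 0.9849401 0.9708272 0.9289057

scores <- aggregateScores(fit)               # n x 6, z-scored
cl <- kmeansCluster(scores, k = 3, seed = 7)
cx <- coxFitSubtypes(survivalTime(sim$surv), survivalEvent(sim$surv),
                     clusterLabels(cl))
cx
#> CoxGroupFit (efron ties): 3 groups (sizes 68/67/65)
#>   centered beta: 0.6973, -0.7253, 0.0181
#>   HRmin=1.9723, SEP(reciprocal)=1.6257, SEP(printed)=0.6151
#>   log-rank: chi2=44.638, p=2.03e-10; GST: chi2=0.361, p=0.835
```

The three subtypes recover the planted clusters (adjusted Rand index
0.955 vs `sim$truth@trueLabels`), the worst-separated pair of subtypes
still differs by a hazard ratio of 1.97, and the GST p-value of 0.835
retains proportional hazards, so the hazard-ratio summary is valid. The
planted gene set ranks first in the over-representation analysis of the
up-regulated genes:

```r
de <- subtypeDE(x, clusterLabels(cl), subtype = 2)
head(oraTest(de$gene_id[de$direction == "up"], sim$db), 1)
#>   set_name overlap set_size list_size universe_size gene_ratio      p_value
#> 1  planted      10       30        11           300  0.9090909 2.215333e-10
#>        q_value
#> 1 1.12982e-08
```

`runPipeline(pipelineConfig(preset = "recovery", seed = 7))` runs the
whole chain and writes weights, scores, labels, KM tables, evaluation
and enrichment tables plus `summary.json` into a run directory; a thin
command-line front end lives at `inst/cli/scclust.R` (subcommands
`simulate`, `run`, `fit`, `cluster`, `survival`, `tune`, `ora`).

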