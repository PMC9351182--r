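---
title: "Decoding methylome repatterning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding methylome repatterning: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylodecode)
library(dplyr)
```

# The problem

Heritable, non-genetic phenotype states in plants — stress-like versus
vigor-like conditions arising without DNA sequence change — leave their
signature in the cytosine methylome. Reading that signature from
whole-genome bisulfite sequencing (WGBS) is hard for three reasons: the
interesting changes are often *single cytosines* rather than broad regions;
wild-type plants fluctuate substantially among themselves, so treatment
effects must be measured *relative to the within-control noise*; and each
cytosine's methylation status in a pooled-cell sample is a proportion, not
a binary state. `methylodecode` implements an analysis chain built around
these three observations, from per-cytosine counts to differentially
methylated positions (DMPs), differentially methylated genes (DMGs),
state discrimination, network hubs, and 14-bp methylation sequence motifs
with a Monte-Carlo randomness test — all exercised end-to-end on synthetic
studies with planted ground truth.

# Divergence and DMP calling

## The statistic

Each cytosine in a sample is a pair of counts $(m, u)$ — methylated and
unmethylated reads — giving a level $p = m/(m+u)$. The reference is the
**pooled control centroid**: per-site counts summed over wild-type
replicates (`pool_reference()`). Treatment-vs-reference dissimilarity is
the Hellinger divergence. Two forms are exposed
(`hellinger_divergence()`):

* the coverage-weighted form (default)
  $$HD = 2\,\frac{n_1 n_2}{n_1+n_2}\left[(\sqrt{p_1}-\sqrt{p_2})^2 +
  (\sqrt{1-p_1}-\sqrt{1-p_2})^2\right],$$
  which grows with the evidence: the same level difference at deeper
  coverage scores higher. A useful property: under the null
  ($p_1 = p_2 = p$), the expectation of the bracket is approximately
  $\tfrac14(1/n_1 + 1/n_2)$, which the coverage factor cancels — the null
  expectation is roughly coverage-invariant, so a single cutoff is
  meaningful across sites of different depth;
* the plain Hellinger distance, bounded by 1, for users who want a
  coverage-free dissimilarity.

A site is a DMP iff its absolute level difference exceeds the 20% gate
(`tv_min = 0.20`) **and** its divergence reaches an estimated cutoff.

## The cutoff: a signal-detection estimate, not a fixed quantile

The within-control fluctuation is measured by scoring each control
replicate against the centroid of the *other* controls (a leave-one-out
jackknife). Scoring a control against a pool containing its own counts
deflates the null — the replicate is partially compared with itself — and
we found empirically that this bias is large enough to misplace any
data-driven cutoff.

Three cutoff estimators are implemented (`fit_null_cutoff()`):

* **quantile** — a Weibull fitted by maximum likelihood to the positive
  null divergences; cutoff at the $1-\alpha$ quantile. This is the
  classical calibrated-type-I choice and the function default.
* **youden** — the ROC-optimal cutpoint maximizing sensitivity +
  specificity − 1, treating control-derived divergences as negatives.
* **fdr** — the empirical-FDR cutpoint: the smallest threshold at which
  the expected number of null exceedances (the control null tail, rescaled
  to the number of treatment comparisons) is at most $\alpha$ times the
  observed treatment exceedances.

`run_pipeline()` defaults to **fdr**, and the reason is worth recording.
In a realistic study the treatment divergence distribution is a mixture:
overwhelmingly null-like sites plus a sub-percent contamination of true
signal. The control and treatment empirical distributions then differ only
in a thin upper tail. Youden's criterion, which balances the two error
rates symmetrically, becomes unstable in this regime — during development
a ~12% rescaling of the null moved the Youden cutpoint by a factor of
four, swinging the selected-set purity from near-zero to perfect. The
empirical-FDR cutpoint conditions on exactly the quantity a rare-signal
analysis cares about (the purity of what is selected) and varies by only a
few percent across replicate simulations. The cutoff is estimated on the
*candidate* sites — those already passing the 20% level gate — matching
the two-step selection the calling rule applies.

## Replicated DMP sites

Per-sample DMP calls are the unit the gene-level statistics consume. For
site-level reporting the pipeline additionally collapses calls to
**replicated DMP sites** (`replicated_dmp_sites()`): a site is
treatment-associated when called in a strict majority of a state's
replicates. Single-replicate false calls — which survive any per-sample
cutoff at some rate — almost never replicate, while planted effects are
carried by every replicate with adequate coverage; on the reference
synthetic study this collapses the site-level false-discovery proportion
to zero at a modest recall cost for shallow-coverage sites.

# Gene-level statistics (DMGs)

DMPs are counted per annotated gene (interval membership, 1-based
inclusive; overlapping genes each count). Genes pass to testing only if
the treatment replicates carry at least 7 DMPs in total and at least 3
DMPs per 10 kbp of annotated length. Each surviving gene is tested by a
GLM likelihood-ratio test of `count ~ group` against `count ~ 1` —
negative binomial with genewise dispersion by default, with an automatic
Poisson fallback when the NB fit fails (counts this small are frequently
not overdispersed enough to identify a dispersion) — then
Benjamini–Hochberg adjustment across tested genes. A gene is a DMG iff
additionally $\log_2\!\big(\tfrac{\bar c_{trt}+0.5}{\bar c_{ctl}+0.5}\big) > 1$
and $p_{adj} < 0.05$. The 0.5 pseudo-count guards the fold change against
empty control counts. Density uses the annotated gene length (not the
flanked interval) as denominator, and "at least 7" is read as the total
over treatment replicates; both readings are exposed as parameters.

TE and sRNA-cluster association is a proximity fraction: the share of
genes whose interval, extended 2 kb both ways, touches at least one
feature. Set-overlap structure across states (Venn cells, Jaccard, Fisher
exact tests against a stated universe) supports the shared-core analyses.

# Discrimination and networks

Individuals are represented as vectors over genes: entry $(g, s)$ sums a
per-DMP statistic (Hellinger divergence by default, Bayesian level
difference as an alternative) over sample $s$'s DMPs inside gene $g$.
On this matrix:

* **Ward clustering** (`ward_cluster()`) of the raw, uncentered sample
  vectors with Euclidean distance (`hclust` method `ward.D2`, which
  implements the Ward criterion on unsquared distances; the test suite
  checks its merge sequence against a Lance–Williams implementation).
* **PCA–LDA** (`pca_lda()`): genes centered (scaling optional and off by
  default, since divergence sums share a scale), components retained when
  each carries at least 1% of the sample variance and together at least
  95% (all components if unattainable), then linear discriminant analysis
  on the retained scores. One numerical guard: the LDA itself uses at most
  $n - g - 1$ leading components ($n$ samples, $g$ classes), because the
  within-class scatter is singular beyond that rank; the reported
  retention $K$ — and the PC scores — follow the variance rule alone.
* **PC scores** (`pc_scores()`): the per-gene Euclidean norm of loadings
  over the retained components. Loadings are orthonormal per component, so
  $\sum_g \text{score}_g^2 = K$ exactly; a gene's squared score is the
  fraction of retained variance it explains.
* **Correlation networks** (`correlation_network()`): pairwise Spearman
  (default) or Pearson correlations between gene rows; an edge is kept
  when $|\rho| \ge \tau$ (default 0.5; the sign is not used unless
  `signed = TRUE`, since a strong anticorrelation is equally informative
  about coordination). Constant rows are excluded with a warning.

# Network hubs

Given any undirected gene network, `node_attributes()` computes six node
attributes — betweenness, closeness, average shortest-path length, local
clustering coefficient, degree, eccentricity — within connected components
(path-based attributes are meaningless across components; singleton
components get zeros). `select_hubs()` z-score standardizes the
attributes, negates the two distance-like ones so that larger always means
more central, and runs k-means (k = 3, 300 iterations, Euclidean
distance) with a deterministic k-means++ seeding under a fixed seed. Hubs
are the members of the cluster with the highest mean standardized,
orientation-corrected centrality. Standardization before k-means is a
deliberate choice: on raw mixed-scale attributes the clustering would be
dominated by degree alone. If all nodes have identical attributes the
clustering is degenerate; this is reported with a warning and every node
is returned as a hub rather than an arbitrary subset.

# Motif discovery and scoring

Windows of 14 bp are extracted around every cytosine carrying a DMP at
the identical coordinate in at least 3 samples, with the cytosine at
window position 7: on the plus strand `genome[pos-6 .. pos+7]`, on the
minus strand the reverse complement of `genome[pos-7 .. pos+6]`. Windows
are clustered by UPGMA on pairwise distances (`ape::dist.dna`; raw
p-distance by default, Kimura two-parameter optionally), the tree is cut
into k flat clusters, and clusters under 10 members are discarded. Two
numerical choices:

* the tree is cut at the k-cluster merge *height* rather than by cluster
  count, so tied merges — identical sequences at height zero — stay
  together instead of being split arbitrarily;
* the default alignment mode is *anchored*: windows are fixed-width and
  coordinate-anchored at the DMP, so they already form a gap-free MSA, and
  the motif statistic below presumes equal-length rows. An external
  aligner can be configured for gapped alignment when windows come from
  other sources.

The motif score of an MSA with $M$ rows of width $N$ is built from
pairwise log match counts:
$$s_{jk} = \log_2 \sum_{i=1}^N \mathbf{1}[b_j^i = b_k^i], \qquad
S = \frac{1}{m}\sum_{j<k} s_{jk}, \quad m = \frac{M(M-1)}{2},$$
bounded by $\log_2 N$, and the information (uncertainty deficit) is
$I = \log_2 N - S \ge 0$, zero exactly for a perfectly conserved
alignment. A pair with zero matching positions has $s_{jk} = -\infty$,
which propagates faithfully through the mean; an optional `min_matches`
floor is provided for robustness, off by default.

# The Monte-Carlo randomness test

The null model for "this alignment is unremarkable" is a
Dirichlet-multinomial over base compositions: the $N \times 4$ count
matrix of the *entire* candidate-window set (not the tested cluster — the
null must describe candidates at large) is fitted with a single shared
$\alpha = (\alpha_A, \alpha_C, \alpha_G, \alpha_T)$, either by Mosimann
moment matching (default) or by the standard digamma fixed-point
maximum-likelihood iteration (tolerance $10^{-8}$, 1000 iterations).
Posterior column compositions follow
$\hat p_i = (n_i + \alpha_i)/(|n| + |\alpha|)$.

Random MSAs are generated column-wise: each column independently draws
$p \sim \text{Dirichlet}(\alpha)$ and then $M$ bases i.i.d. from $p$.
The column-wise reading (rather than one draw per alignment) is the more
conservative null — composition varies by position, but no cross-row
conservation is imposed, which is precisely the hypothesis being tested.
The Monte-Carlo p-value counts simulated scores at or above the observed
one, *including the observed alignment itself as the $i = 0$ term*:
$$p = \frac{1}{N_s+1}\sum_{i=0}^{N_s} \mathbf{1}[S_i \ge S_0],$$
so $p \ge 1/(N_s+1)$ always; the default is $N_s = 1000$ (999 in the
pipeline so that the attainable floor is the round 1/1000). A simulated
$-\infty$ score satisfies the inequality only when $S_0 = -\infty$.

# The synthetic study generator

`sim_config()` / `generate_study()` produce a fully ground-truthed study,
deterministic given the seed. The defaults define the reference
conditions used by the tests and the acceptance script:

* a single 300 kb chromosome, i.i.d. sequence at GC 0.36 — contexts (CG,
  CHG, CHH) then *arise from the sequence* rather than being painted on,
  which keeps the context/trinucleotide invariants honest;
* 120 genes (1.2–2.1 kb, non-overlapping), 60 TEs and 60 sRNA clusters,
  half placed within 2 kb of genes;
* wild type plus one treatment state, 3 replicates each (a four-state
  preset with a shared planted core, `preset_four_states()`, mirrors
  multi-state designs for overlap analyses);
* negative-binomial coverage per site and sample (mean 30, dispersion 5 —
  realistic WGBS overdispersion) and Beta-distributed replicate-level
  biological noise (precision 100) around each site's true level;
* context-specific background levels: CG drawn from a bimodal high/low
  mixture, CHG intermediate, CHH low, as in plant methylomes;
* 20 planted DMGs with 10 DMPs each; planted baselines are held in
  \[0.05, 0.15\] and shifted by +0.6 in the treatment state, so the level
  difference clears the 20% gate by construction;
* every planted DMP is the anchor cytosine (position 7) of a planted
  motif copy, mutated per base at rate 0.1 (the anchor is never mutated).
  The default plants **four distinct consensi**, assigned to genes
  round-robin. This matters for the Monte-Carlo null: the Dirichlet model
  is estimated from the whole candidate set, and a candidate set dominated
  by a single consensus is itself maximally "conserved", which makes the
  null degenerate (near-monomorphic simulated columns) and the test
  powerless by construction. Real candidate sets mix many families; four
  consensi with distinct bases per position emulate that.

What the generator does **not** emulate: read-level artifacts (bisulfite
conversion error, mapping bias, strand-coverage asymmetry), linkage
between neighbouring cytosines, genome-scale context autocorrelation, and
TE-family structure. Passing recovery tests on this generator therefore
demonstrates the statistical machinery — calibration of the null, power
at the planted effect size, correctness of every transformation — not
robustness to alignment artifacts, which are upstream of this package's
inputs.

# The pipeline and its problem sizes

`run_pipeline()` executes: centroid → divergences → cutoff → per-sample
DMPs → replicated sites → gene counts → DMG tests → gene matrix → Ward →
PCA-LDA → PC scores → correlation network (over called DMGs) → hub
selection → motif windows → UPGMA clusters → motif scores → Monte-Carlo
tests, and records a manifest (parameters, seeds, an input hash, record
counts per stage). Stage seeds derive from the master seed by a fixed
offset rule so stages can be rerun in isolation.

One default deviates from the thresholds above: the motif cluster count.
The 100-cluster default presumes thousands of candidate windows; on a
synthetic study the candidate set is a few hundred, so `motif_k = NULL`
scales the cut as `max(2, ceiling(n_windows / 25))` (about 8 clusters for
200 windows — an expected cluster size in the tens, the same design point
the 100-cluster choice represents at full scale). Passing `motif_k = 100`
restores the fixed behaviour.

The test-suite problem sizes are chosen to exercise every claim at
desk scale: the reference recovery study uses the default 300 kb / 6
sample configuration (~10^5 cytosines per strand pair, ~650k covered
records); the Monte-Carlo calibration uses 500 replicates of a 10 × 14
alignment at 99 simulations each; Dirichlet recovery uses 500 rows at
depth 100. Because single-study site recall depends on which planted
sites happen to draw adequate coverage, the recovery suite averages
recall over three replicate studies while asserting the false-discovery
bound in each.

# Known limitations

* The Hellinger-divergence coverage weighting means shallow-coverage true
  effects rank below any safe cutoff; the replicated-site collapse
  recovers purity but not those sites. Deeper coverage, not a looser
  cutoff, is the remedy.
* Genewise NB dispersion is noisy at 3 + 3 replicates; the LRT is
  anti-conservative in the extreme tail there, which the BH step and the
  fold-change gate absorb in practice.
* The Dirichlet null uses a single component; a mixture over position
  classes would sharpen the test for long, heterogeneous alignments.
* `proximity_fraction()` scans features per gene; it is quadratic in the
  worst case and intended for annotation-scale inputs, not base-pair
  tiling.

# A worked mini-study

```{r mini, eval = FALSE}
study <- generate_study(sim_config(seed = 42))
run <- run_pipeline(study, seed = 7)

truth_metrics(dplyr::distinct(run$dmp_sites, chrom, pos, strand),
              study$truth, "dmp")
truth_metrics(run$dmg$gene_id[run$dmg$is_dmg], study$truth, "dmg")
truth_metrics(run$motif$clusters, study$truth, "motif")
run$motif$summary
autoplot(run$pca_lda)
plot_frequency_matrix(frequency_matrix(run$motif$clusters$msas[[1]]))
```
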