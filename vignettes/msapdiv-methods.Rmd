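---
title: "Methods: MSAP epigenetic diversity analysis with msapdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSAP epigenetic diversity analysis with msapdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapdiv)
```

## The measurement and its model

Methylation-sensitive amplified polymorphism (MSAP) fingerprints a genome
twice with the isoschizomers *Hpa*II and *Msp*I, which share the CCGG
target but are blocked by different cytosine-methylation configurations.
After scoring, each enzyme combination yields a binary sample × locus band
matrix, and the joint (*Hpa*II, *Msp*I) pattern at a cell encodes the
methylation state of the underlying site:

| HpaII | MspI | state (code) |
|---|---|---|
| 1 | 1 | hemi-methylation of the inner cytosine (`I`) |
| 1 | 0 | hemi-methylation of the outer cytosine (`O`) |
| 0 | 1 | double-strand methylation of the inner cytosine (`D`) |
| 0 | 0 | double-strand methylation of both cytosines, or target absent (`U`) |

This is the reading used throughout the package. Much of the MSAP
literature instead calls the 1/1 pattern "unmethylated"; the
`nomenclature = "msap"` flag of `state_legend()` relabels outputs without
changing any computation, because the downstream statistics depend only on
the four-way partition, not on its naming. The `U` pattern is inherently
ambiguous (full methylation and a missing target are indistinguishable),
which is why `methylation_level_report()` offers an
`include_uninformative = FALSE` denominator.

`classify_pattern()` is a total bijection between $\{0,1\}^2$ and the four
states, and `decode_state()` inverts it exactly — the pair of band matrices
and the state matrix are equivalent representations, which the tests
enforce by round-tripping random datasets.

Loci are partitioned into methylation-susceptible loci (MSL) and
non-methylated loci (NML) by evidence: a locus is MSL when at least a
fraction `msl_threshold` of samples show an `O` or `D` pattern — the two
patterns that can only arise from differential enzyme blocking. The default
threshold is one sample's worth (`1/n`), the most inclusive rule; stricter
fractions are a parameter. A locus is *polymorphic* when its most frequent
joint pattern has frequency ≤ 1 − 0.05. The 5% boundary is inclusive
(a minor pattern at exactly 5% counts): the source convention prints
"frequency > 5%" without stating strictness, so the package fixes
inclusiveness here and documents the contrasting *strict* inequality used
for band-frequency statistics (below), where "> 5%" is printed explicitly.

## Diversity statistics for dominant markers

MSAP bands are dominant markers: heterozygotes are indistinguishable from
band-carrying homozygotes, so allele frequencies must be inferred from band
frequencies. `expected_heterozygosity()` defaults to the Hardy–Weinberg
square-root estimator, $q = \sqrt{1 - f}$, $He = 2q(1-q)$ with $f$ the
band frequency — the convention of the AFLP software family this analysis
descends from. The phenotypic estimator $He = 2f(1-f)$ is exposed because
published tables do not always name their formula. Both estimators vanish
exactly at $f \in \{0, 1\}$, which is why clonal within-population tables
are dominated by 0/0 rows. The SEM is the standard error of per-locus He
over loci.

Per-population band statistics follow the GenAlEx definitions: bands
present, bands at within-population frequency strictly above 5%, private
bands (present in no other population), and locally common bands — present
in the population, with overall frequency strictly above 5%, and occurring
in ≤ 25% (resp. ≤ 50%) of populations. The "or fewer" reading is used
because the worked 4-population example (a band in exactly 2 of 4
populations counting as "< 50%") is only consistent with the inclusive
boundary, which is also what GenAlEx computes.

Shannon diversity is the per-locus entropy of band presence,
$S = -(f \ln f + (1-f)\ln(1-f))$ with $0 \ln 0 = 0$, averaged over all
loci of a profile (natural log). Restricting to MSL or polymorphic loci is
a parameter, not the default, since the reference analysis reports one
index per enzyme.

Rank tests wrap the standard implementations: the Wilcoxon rank-sum test
uses exact enumeration when the pooled sample is ≤ 12 without ties and the
continuity-corrected normal approximation otherwise; the Kruskal–Wallis H
test is tie-corrected with a $\chi^2_{G-1}$ reference.

## AMOVA

`msap_amova()` implements the one-level Excoffier partition from pairwise
squared distances: with $N$ samples in $G$ populations,

$$SS_{total} = \tfrac{1}{N}\textstyle\sum_{i<j} d^2_{ij}, \qquad
  SS_{within} = \sum_g \tfrac{1}{n_g} \sum_{i<j \in g} d^2_{ij},$$

$\sigma^2_w = SS_{within}/(N-G)$,
$\sigma^2_a = (SS_{among}/(G-1) - \sigma^2_w)/n_0$ with
$n_0 = (N - \sum_g n_g^2/N)/(G-1)$, and
$\Phi_{st} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. A negative among
component is reported raw and truncated at zero only for the percentage
split. The default distance is the mismatch count between binary profiles
(the squared Euclidean distance of 0/1 vectors), the standard AMOVA input
for dominant data; Jaccard distances are reserved for clustering and the
matrix subtraction, but AMOVA-on-Jaccard is available (the distances are
then squared). Significance is by full label permutation with
$p = (\#\{\Phi^\ast \ge \Phi_{obs}\} + 1)/(B + 1)$; one seed governs a
whole run. The implementation is checked against an independent
double-loop oracle on all small instances and against `vegan::adonis2`
for the sums of squares.

## Clustering and ordination

UPGMA dendrograms are average-linkage `hclust` trees converted to rooted
ultrametric `phylo` objects (leaf depth = joining distance / 2), written as
Newick. Cophenetic round-trips are exact on ultrametric inputs. Tie
handling is `hclust`'s deterministic internal order.

The *Msp*I − *Hpa*II matrix subtraction is the elementwise signed
difference of two Jaccard distance matrices over the same samples.
Negative entries mean epigenetic (*Hpa*II) distance exceeds the *Msp*I
distance for that pair; the summary reports the mean difference and the
fraction of negative pairs. Jaccard is used because it is the coefficient
the clustering stage uses; the metric is a parameter.

PCoA is classical metric scaling (`cmdscale`): Gower double-centring of
$-d^2/2$, eigendecomposition, coordinates scaled by the square roots of
positive eigenvalues. Negative eigenvalues — possible under Jaccard — are
dropped with a reported count rather than corrected, and explained-variance
percentages (C1, C2, …) are taken over the positive part. Mismatch
distances are square-rooted before embedding since they are already
squared. Group dispersion ellipses are 1-standard-deviation ellipses from
the eigen-structure of each group's 2 × 2 coordinate covariance
(population convention, divide by $n$), so the major axis points along the
direction of maximum dispersion. Group separation is tested by the AMOVA
permutation machinery on the distance matrix.

## Latent-class clustering and Evanno ΔK

The cluster-number analysis replaces the Structure admixture model with a
finite mixture of per-locus Bernoulli components — appropriate because
dominant MSAP bands are binary phenotypes without genotype dosage. Each
sample belongs to one of $K$ classes; class $k$ carries per-locus presence
probabilities with Beta($a$, $b$) priors (default uniform) and the class
weights a symmetric Dirichlet prior. Inference is collapsed Gibbs sampling
over sample assignments.

Two algorithmic choices matter and were fixed after observing the sampler's
behaviour on well-separated data:

* **The scanned likelihood is computed under sampled parameters.** At each
  recorded sweep the component frequencies are drawn from their Beta full
  conditionals and the data log-likelihood is evaluated under the draw.
  Evaluating at the posterior mean instead makes runs of a converged
  chain numerically identical, so the run-to-run standard deviation in
  Evanno's ΔK denominator collapses to zero and the statistic is
  undefined. Sampling the parameters restores the dispersion that the
  ΔK method assumes of Structure runs. A side effect is a small downward
  (Jensen) bias of $L(K)$ relative to the plug-in value; it is immaterial
  because ΔK uses differences.
* **Annealed burn-in with restart selection.** Single-site Gibbs updates
  cannot split two truly distinct clusters once they merge, because the
  intermediate single-sample moves are strongly unfavourable. Each fit
  therefore runs `n_restarts` independent burn-ins with the assignment
  conditional tempered from `anneal_start` (default 0.4) up to 1, and
  continues the restart with the highest posterior-mean log-likelihood.
  On the study-scale preset this raised the fraction of runs reaching the
  dominant mode at the planted K from 8/20 to 20/20.

Labels are identifiable only up to permutation; the recorded membership
matrix Q matches component frequency vectors greedily across sweeps, and
all tests compare partitions, not labels. `run_k_scan()` seeds each run
from a master seed, and `evanno_delta_k()` computes
$\Delta K = \mathrm{mean}_r |L_r(K{+}1) - 2L_r(K) + L_r(K{-}1)| \,/\,
\mathrm{sd}_r L(K)$ over interior K, erroring when a K has fewer than two
runs and flagging zero-sd cases.

ΔK is a ratio statistic with known pathologies: it cannot evaluate the
endpoints of a scan, and it prefers the *first* large split when cluster
separations are strongly hierarchical (the K = 1→2 likelihood gain then
dwarfs the K = 2→3 gain, and |L″(2)| exceeds |L″(3)|). This is a property
of the method, not of this implementation; it shaped the synthetic preset
below.

## The synthetic generator

`generate_dataset()` draws each sample × locus joint pattern from a
4-simplex over (`I`, `O`, `D`, `U`) that belongs to the sample's genet
(clonal lineage), then tilts the `O` share by the population's
environmental covariate on the log-odds scale, and finally flips each
emitted bit independently with probability `scoring_noise` (peak-scoring
error). The tilt redistributes mass only within the {`O`, `U`} pair. Both
patterns have *Msp*I = 0, so the *Msp*I marginal is exactly invariant to
the environment: the environment converts fully methylated (or absent)
targets into hemi-methylated outer cytosines and back. This implements the
biological reading the analysis is designed to detect — stable *Msp*I
profiles, environment-driven outer-cytosine hemi-methylation in *Hpa*II —
and makes "the environmental effect acts only on the hemi-outer component"
literally true in distribution.

`preset_sardinia_like()` fixes the study conditions: 26 populations
totalling 83 samples (sizes 2–6), 130 loci, scoring noise 1% (a typical
AFLP/MSAP reproducibility error), and a binary environmental covariate
(−1/+1) alternating across populations so every lineage spans both
regimes. Loci: 95 near-monomorphic backbone loci (pattern mass 0.97 on
`I`), 12 lineage-diagnostic loci (four per lineage; `D` at 0.92 for the
owner, `U` at 0.93 otherwise — *Hpa*II-silent, so lineage structure lives
in the *Msp*I profile only), and 23 environment-sensitive MSL loci
(`I` 0.05, `D` 0.02, and an {`O`, `U`} pool of 0.93 split by the covariate
with log-odds effect 4, i.e. *Hpa*II band frequencies near 0.07 vs 0.96
between regimes).

The preset uses three clonal lineages of comparable extent (29/27/27
ramets across 7/9/10 populations), mirroring the three prevalent
haplotype lineages reported for the real system. Comparable extent is a
deliberate choice driven by the ΔK pathology above: with one strongly
dominant lineage the K = 1→2 gain exceeds twice the K = 2→3 gain and ΔK
mathematically settles on K = 2 regardless of implementation quality.
With comparable lineages the two gains nearly cancel at K = 2 and ΔK
selects K = 3 on the *Msp*I profile while the two environmental regimes
give K = 2 on *Hpa*II — the qualitative cluster-number contrast the
preset exists to emulate, alongside a higher *Hpa*II than *Msp*I
among-population variance share and a predominantly negative
*Msp*I − *Hpa*II distance subtraction.

What the generator does *not* emulate: linkage between loci, spatial
autocorrelation beyond the per-population covariate, fragment-size
homoplasy, admixed individuals, and any within-population environmental
heterogeneity. Tests passing on this generator therefore show that the
pipeline recovers planted structure of this specific kind; they do not
certify performance on electropherogram-level artefacts or on admixture.

## Numerical choices and problem sizes

* Canonical ordering: datasets are sorted lexicographically by sample and
  locus id at pairing time, so all downstream outputs are invariant to
  input row/column shuffles.
* Degenerate inputs: zero total variance flags AMOVA percentages as
  undefined rather than forcing 0/100; all-absent profile pairs get
  Jaccard distance 0 with the pair recorded; singleton groups yield
  zero-axis ellipses with a flag; empty populations yield `NA`
  frequencies with a warning.
* Permutation p-values use the add-one estimator, so the smallest
  achievable p is $1/(B+1)$.
* Desk-scale defaults used by the tests and the acceptance script: K scans
  over K = 1…6 with 4 runs per K, 120 burn-in sweeps per restart (6
  restarts) and 380 recorded sweeps; AMOVA with 999 permutations;
  permutation-calibration checks over 200 null datasets of 12 samples.
  These sizes keep a full run in minutes on one core; the chain lengths
  are far beyond what this mixture needs to converge on 83 × 130 data,
  and all of them are parameters.

## Limitations

* The latent-class model is a simplification of Structure's admixture
  model: no admixture proportions, no correlated allele frequencies, no
  dominant-genotype likelihood. Published ΔK magnitudes from Structure
  runs are therefore not comparable; only the selected K and the
  qualitative scan shape are.
* Locus identity across enzyme matrices is by label only; fragment-size
  binning and electropherogram processing are out of scope.
* The `U` state conflates full methylation with target absence; every
  statistic that treats `U` as methylation evidence inherits that
  ambiguity (the report's exclude mode quantifies its impact).
* One-level AMOVA only; regional hierarchies are not modelled.
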