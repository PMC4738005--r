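---
title: "CoFracNet methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoFracNet methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoFracNet)
```

# The inference problem

Co-fractionation mass spectrometry (CF-MS) infers protein complexes
without tagging or antibodies: a native extract is spread over many
chromatographic fractions, each fraction is measured by shotgun MS, and
each protein's quantitation across the ordered fractions forms an
elution profile. The central assumption is that stable complex subunits
migrate together, so their profiles share peak position and shape up to
sampling noise. CoFracNet's task is to turn a collection of such
profile matrices — several experiments, possibly several species — into
(i) a confidence-scored co-complex interaction network, (ii) putative
complexes, and (iii) orthology-projected networks for related species.

Inputs are gene-level profile matrices (one quantitation value per
protein per fraction): MS2 spectral counts (non-negative integers) and
MS1 precursor intensities (non-negative reals). Everything upstream —
spectral searching, FDR control, MS1 feature extraction — is assumed
done; CoFracNet starts at the quantitation tables. Undetected cells are
explicit zeros; a missing cell in a file is treated as a truncation
error rather than silently imputed, and zero-count fractions between
detections are taken at face value (no interpolation), since spectral
counting genuinely yields zeros for low-abundance fractions.

# Co-elution scores

Four features are computed per protein pair per experiment
(`scoreExperiment()`), each capturing a different facet of co-elution.

**Poisson-noised Pearson correlation** (`pearsonPoissonNoise()`). MS2
counts are Poisson-sampled by nature, and sparse count vectors produce
spuriously perfect correlations (two proteins seen once in the same
fraction correlate at 1.0). Both problems are addressed by averaging
the Pearson correlation over `noiseReps` = R resampled replicates with
x⁽ʳ⁾ᵢ ~ Poisson(xᵢ + p): resampling propagates count-level uncertainty,
and the pseudocount p > 0 injects independent noise that breaks
zero-sharing artifacts. Defaults R = 100 (score standard error well
below the biological signal at desk-scale cost) and p = 1 (one
pseudo-count, the conventional scale for count data). R = 0 switches
the noise off and returns the plain correlation. Each pair draws from
an RNG substream keyed by (seed, canonical pair id), with the
lexicographically smaller profile consuming the first block of draws;
this makes scores bit-reproducible, independent of matrix row order,
and exactly symmetric in the two proteins.

**Weighted cross-correlation** (`weightedCrossCorrelation()`).
Fraction collection discretizes a continuous separation, so genuine
co-elution can appear shifted by a fraction. WCC averages the Pearson
correlation of lag-aligned overlaps over k = −K..K with weights
wₖ = 1/(1+|k|): lag 0 dominates, neighbouring lags contribute half.
K defaults to 2 fractions; K = 0 reduces exactly to plain Pearson. The
1/(1+|k|) decay is a package choice — any monotone decay would do; this
one is parameter-free and keeps more than half the weight on |k| ≤ 1.

**Co-apex score** (`coApex()`). 1/(1 + |Δapex|) with the apex defined
as the *first* fraction attaining the profile maximum (a deterministic
tie-break). A graded score was preferred over a same-apex boolean
because ordering information survives; a boolean is recovered by
thresholding at 1.0. All-zero profiles have no apex and yield a missing
value rather than an error.

**MS1 Euclidean similarity** (`euclideanSimilarity()`). MS1
intensities span orders of magnitude between proteins, so profiles are
first normalized to unit sum — making the score scale-invariant and
comparable across abundances — and the Euclidean distance d (at most √2
for non-negative unit-sum vectors) is mapped to 1 − d/√2 ∈ [0, 1].
Because MS1 quantitation is unreliable for proteins never confirmed by
spectral identification, MS1 matrices are first restricted to proteins
with at least one nonzero MS2 count in the same sample
(`filterMS1ByMS2()`); mere presence of an all-zero MS2 row does not
count as identification.

Numerical conventions: Pearson on a zero-variance vector is defined as
0 (flat profiles carry no co-elution evidence, and the learner needs
total values, not NaNs); pairs sharing fewer than `minOverlap` (default
1) mutually nonzero fractions are omitted entirely, since their
correlation would be an artifact of joint absence.

# Orthology harmonization and projection

Multi-species evidence is merged in a reference (human) namespace.
`mapScoresToReference()` expands each scored pair over all combinations
of reference orthologs (maps may be many-to-many), drops pairs with an
unmapped side — the harmonized table must be purely orthologous — and
drops expansions collapsing onto one reference gene. When co-orthologs
collide on the same reference pair, each feature keeps its maximum over
non-missing values: the strongest co-elution evidence among in-paralogs
is the most defensible summary, because a duplicated gene may have
retained the complex role in only one copy (mean and abundance-weighted
summaries are reasonable alternatives; the max is the package default).
`projectNetwork()` applies the inverse expansion, carrying reference
edges onto ortholog pairs of a target species, again keeping the
maximum score on collisions. Projection through a bijective map and
back is the identity, a property the test suite asserts.

# Supervised co-complex classification

Reference complexes induce labels: pairs co-occurring in a complex are
positive, pairs whose proteins both appear in the reference but never
together are negative, everything else is unlabeled. The feature table
is kept wide — one column per (experiment, score) — rather than
averaged across experiments, so the learner can weight species and
fractionation techniques differently. Missing scores are encoded as a
zero-filled value plus a 0/1 observed-mask channel per column: "not
co-detected" is informative (complexes absent from a tissue) and must
stay distinguishable from "observed but uncorrelated".

The classifier is a probability random forest (`ranger`, 500 trees,
single-threaded for determinism, seeded). Tree ensembles were chosen
because the features are bounded, correlated, of mixed reliability and
partially missing; the module contract is model-agnostic and the family
and hyperparameters are recorded in the network's provenance.

Evaluation uses *complex-held-out* cross-validation
(`splitByComplex()`, `assignPairFolds()`): complexes, not pairs, are
dealt into k = 5 folds, a labeled pair is assigned to a fold only when
every complex containing either of its proteins lies in that fold, and
straddling pairs are excluded. Pair-level CV would leak — two pairs of
the same complex share subunits and elution peaks — and inflate
performance. "High confidence" is operationalized as the lowest score
whose cumulative held-out precision reaches a target (default 0.90,
`thresholdAtPrecision()`); an unattainable target is reported
explicitly rather than clamped.

# Clustering into complexes

`clusterNetwork()` grows possibly overlapping complexes from the
thresholded network by greedy cohesiveness optimization, in the spirit
of ClusterONE: cohesiveness C(S) = W_in/(W_in + W_bound + penalty·|S|),
seeds taken from edges in decreasing weight order, single-node
additions and removals applied while C strictly increases, acceptance
at C ≥ 0.3 and |S| ≥ 3, and accepted sets merged at Jaccard ≥ 0.8. The
penalty (default 2.0, in edge-weight units per node) plays the role of
expected unobserved boundary weight and stops weakly attached accretion.
All tie-breaks are explicit — higher cohesiveness gain first, additions
before removals, then lexicographic node id — so clustering is exactly
reproducible. One property worth knowing: because the penalty is linear
in |S|, the *unconstrained* cohesiveness optimum can pool dense but
disconnected components; the grower never does this (it only reaches
connected sets through adjacency), which is the behaviour one wants for
physical complexes, and the test suite's exhaustive oracle is therefore
restricted to connected subsets.

# The simulator and what it does (not) show

`generateWorld()` emulates the study design the pipeline targets:
several species sharing a reference proteome through (possibly
many-to-many) ortholog maps, several fractionation experiments per
species, Gaussian elution peaks, and realistic noise. Default
conditions: 2 species, 20 complexes of 3–6 members plus 40 monomers,
2 experiments per species, 60 fractions, peak widths σ ∈ [1, 3]
fractions, log-normal abundances (meanlog 3, sdlog 1 — median ≈ 20
total spectral counts per protein per experiment, spanning a realistic
dynamic range), MS2 counts Poisson(depth × expected signal), MS1 =
expected × LogNormal(0, 0.2), 10% per-protein-per-experiment dropout,
90% ortholog conservation. Complex members share apex and width within
an experiment (perfect co-elution before noise); apexes resample per
experiment, as different separation techniques would. Everything is
deterministic given the seed, and `writeWorld()`/`readSimManifest()`
make a world regenerable from its manifest.

The simulator deliberately omits several features of real CF-MS data:
substoichiometric or partial complex membership, shared subunits and
moonlighting, correlated (non-Poisson) technical noise, chimeric
peptide assignment between homologs, abundance-dependent dropout, and
realistic proteome sizes. Passing the end-to-end tests therefore shows
the pipeline's machinery is correct and well-calibrated under its own
generative assumptions — not that real interactomes will be recovered
at the same accuracy. Reference complexes in the synthetic world are
the complete truth, which inflates clustering evaluation relative to
real, incomplete gold standards.

# Problem sizes, determinism and limitations

The shipped tests and the acceptance script run the default study
(4 experiments of ~110–130 proteins × 60 fractions, ≈1,300–1,700
scored pairs each, ≈3,700 reference pairs in the feature table) —
sizes chosen so the full suite runs in well under a minute while every
stage still operates in its intended regime; all knobs scale up through
`SimParams` and the pipeline configuration. Every stochastic step
(simulation, noise replicates, fold shuffles, forest growth) draws from
an explicit seed, and stage reruns are byte-identical, which the tests
assert on file hashes. Known limitations: scoring is O(pairs × R ×
fractions) in pure R, comfortable to a few thousand proteins per
experiment but not proteome-wide without parallelization; the
precision threshold is estimated on held-out folds and applied to a
model trained on all labels, so its realized precision on truly novel
pairs is approximate; and ortholog maps are taken as given — no
inference of orthology is attempted.
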