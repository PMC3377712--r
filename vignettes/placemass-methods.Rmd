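---
title: "Methods: placement-based analysis of vaginal microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placement-based analysis of vaginal microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placemass)
```

# Scope and model of the data

`placemass` analyses 16S rRNA amplicon surveys of the vaginal microbiota
through the lens of *phylogenetic placement*: every read is represented
not as an OTU membership but as a probability distribution over
attachment points on a fixed, curated reference tree. All downstream
community mathematics — taxonomic classification, between-sample
distances, ordination, clustering — is carried out on those
distributions. The package covers the full chain:

1. quality control of raw barcoded pyrosequencing reads;
2. curation of a niche-specific reference package (alignment, taxonomy
   with provisional taxa such as BVAB1/2/3, tree);
3. placement-based taxonomic classification with compound naming;
4. tree-mass community comparison: the Kantorovich–Rubinstein (KR,
   "earth-mover") distance, squash clustering with bootstrap support,
   edge principal components analysis, and phylogenetic island
   clustering;
5. ecological statistics (Shannon diversity, Chao1 richness, abundance
   trimming, taxon co-occurrence);
6. two association models: per-taxon zero-inflated negative binomial
   (ZINB) likelihood-ratio tests for race-by-BV interactions, and
   cross-validated elastic-net models linking taxa to the four Amsel
   clinical signs.

A first-class synthetic-data generator produces reference worlds,
cohorts, placements and raw FASTQ runs with the statistical structure
these analyses assume, so the whole pipeline is testable end to end
without external downloads.

# Read quality control

Reads are retained when they (1) start with a known barcode, (2) carry
the exact primer sequence immediately after it, (3) keep at least 200
nucleotides after trimming barcode and primer, and (4) have mean
per-base Phred quality of at least 35. Discards are tallied under the
*first* failing criterion. Retained reads are then clipped to the
longest contiguous span in which every 30-base window has at least 90%
of bases above Phred 15, and criterion (3) is re-checked on the clipped
length.

Numerical choices worth stating:

* The quality-average criterion is interpreted as the mean Phred score,
  the only per-base quality a FASTQ file carries, and it is computed
  after trimming barcode and primer (the trimmed bases are synthetic
  constructs, not sequencing output).
* Spans shorter than the window are evaluated as a single window;
  otherwise a short span would contain no complete window and would be
  vacuously clean, which would make a fully bad read "clip" to 29 bases
  rather than to nothing.
* Ties between equally long clean spans go to the leftmost span, making
  clipping deterministic and idempotent.

# Reference package curation

Public 16S records are frequently mislabeled, so curation starts from
pairwise distances — the fraction of non-identical nucleotides over
columns where both sequences carry an unambiguous base (gap and
ambiguity columns are excluded pairwise, not masked globally). Per
taxon:

* the **primary reference "S"** is the sequence with the smallest median
  distance to its taxon siblings;
* sequences farther than 0.015 from S (below 98.5% identity, a standard
  species-level threshold) are discarded as mislabeled;
* **representatives** are selected by always keeping S and any type
  strains, then greedily adding the sequence that maximises the summed
  pairwise distance of the selected set, by default up to N = 5. Exact
  maximisation of the summed distance is NP-hard; on instances small
  enough for exhaustive search the greedy set reaches at least 90% of
  the optimum, which is what the selection needs (spread, not
  optimality).

When no tree is supplied, the package builds a neighbor-joining tree
from the same distance matrix, midpoint-roots it and clamps negative NJ
branch lengths to zero. This is a deliberate desk-scale stand-in for a
maximum-likelihood tree: topology (clade membership) is what the
placement mathematics consumes, and NJ recovers the engineered clades
exactly on synthetic data. The interface accepts an externally inferred
tree wherever one is available. All ties (primary selection, greedy
selection, merge order) are broken by lexicographic sequence id so
builds are reproducible.

Edges are numbered 0, 1, 2, … by preorder (cladewise) traversal; that
numbering is the coordinate system for every placement, mass map and
loading in the package, and is embedded as `{n}` annotations in jplace
output.

# Classification

**Edge labels.** Ranks are scanned from species upward over the leaves
on the edge's *distal* side; the edge takes the first rank at which that
side carries exactly one taxid. The distal side takes precedence across
the whole scan — this yields species labels on terminal and
within-clade edges and genus labels on clade stems. Only when no rank
purifies distally is the proximal side scanned, and the root taxid is
the final fallback. The stricter both-sides reading of the rule is
available behind a strategy switch; on trees whose taxa form pure
clades the two readings give compatible (nested) labels, which is
tested explicitly.

**Read classification.** A read's cumulative posterior for a taxon is
the summed posterior mass on edges labeled with that taxon or any of
its descendants. The read is assigned the most specific taxon whose
cumulative posterior reaches the 0.9 cutoff. Cumulative posteriors are
monotone along the lineage, so classification always succeeds at some
rank (the root in the worst case). Genus-or-higher assignments receive
a compound name listing up to three more-specific taxa with individual
posterior above 0.05 (e.g. `Lactobacillus crispatus/iners`).
Posteriors are renormalised to sum to one on load, since
like-weight-ratio fields in interchange files often truncate mass.

**Stand-in placer.** `naive_place()` is a distance-based placer used to
exercise the machinery on synthetic reads: leaves are scored by best
ungapped-offset identity, the top three are softmaxed into posteriors
(temperature 4e-4, sharp enough to resolve single-site differences),
and attachments sit at the midpoints of the chosen terminal edges. It
is not a likelihood placer and makes no claim to be one; jplace I/O
accepts placements from external engines.

# Tree-mass community comparison

Each sample is one unit of mass distributed over the tree. The KR
distance between two samples is
$Z(P,Q) = \sum_{\text{edges}} \int |F(y)|\, dy$, where $F(y)$ is the
net signed mass of $P - Q$ in the subtree below point $y$. Because $F$
is piecewise constant with breakpoints exactly at the point masses, the
package computes the integral in closed form in a single post-order
traversal; tests verify it against a discretised-integral oracle and,
for leaf-only mass, against an independent weighted-UniFrac-style
subtree tally (the KR metric generalises weighted UniFrac to internal
and split mass). The exponent generalisation of the metric is out of
scope; the implemented case is the UniFrac-comparable one.

**Squash clustering** is agglomerative clustering in which the distance
between clusters is the KR distance between the *averages* of their
member mass distributions ("squashing" the stacked distributions back
to unit mass), the reverse of average-linkage's average-of-distances.
Each child's branch length is the KR distance between the child's
average and the merged average, so trees carry meaningful internal
branch lengths and are generally not ultrametric. Merge ties are broken
on the sorted pair of cluster ids; permuting sample order cannot change
the result. Bootstrap support resamples each sample's placements (reads)
with replacement, re-clusters, and reports the fraction of replicates
reproducing each internal node's exact leaf bipartition.

**Edge PCA** transforms each sample into a vector indexed by edges:
the entry for edge $e$ is the sample's mass on the distal side minus
the proximal side ($2\,\text{distal} - 1$ for unit mass; point masses
on $e$ itself count as distal). Classical covariance PCA is applied to
those vectors — covariance, not correlation, because the transform
already puts every edge on one scale in $[-1, 1]$; zero-variance edges
are retained (they take zero loadings and are harmless under covariance
PCA). The signed-difference transform is affinely equivalent to raw
distal mass (identical eigenvectors, eigenvalues scaled by four), which
is asserted in tests. Signs follow the convention that each component's
largest-magnitude loading is positive; eigenvectors can be projected
back onto the tree, where positive and negative loadings draw as the
two directions of the component.

**Phylogenetic islands** single-linkage-cluster best attachment points
under tree path distance with a 0.02 cutoff; islands carried by fewer
than two subjects are dropped, the remainder take the majority
classification of their reads, and the representative is the read
nearest the island's medoid. Best placements (not the full posterior
spread) define membership, matching per-read cluster semantics; a
spread mode is provided behind a switch since the choice is not forced
by anything upstream. Path distance includes the partial edge segments
on both ends of the path.

# Ecological statistics

Shannon diversity uses the natural log (configurable base), Chao1 uses
the bias-corrected form by default with the classic form selectable.
Abundance trimming ranks taxa by total reads and keeps the top 30%; the
trim report states the retained read fraction, which exceeds 98.5% under
realistically skewed abundances. Co-occurrence analysis computes Pearson
correlations between `log(count + 0.5)` transformed per-taxon counts —
the continuity constant 0.5 only makes sense applied to counts, which is
how the package reads the transform — and clusters the correlation rows
with Euclidean distance and complete linkage via `dist`/`hclust`.
Zero-variance taxa have undefined correlations and are dropped with a
warning. Community summaries report per-taxon prevalence and read share
by BV group (Nugent or Amsel definition), per-sample dominant taxa
(plurality by default, majority selectable; ties broken lexicographically
and flagged), and the minimal top-taxon set covering a target read
share.

# Association models

**ZINB race-by-BV interaction.** Counts for one taxon follow a mixture:
with probability $\pi$ an observation is an excess zero; otherwise it is
negative binomial with mean $\mu_i = \exp(x_i^\top \beta)$ and
dispersion $\theta$. The zero component is intercept-only — every zero
has the same probability of belonging to it — which keeps the model
identifiable at microbiome sample sizes. Fitting maximises the exact
mixture log-likelihood by BFGS over $(\beta, \operatorname{logit}\pi,
\log\theta)$ from multiple starts ($\pi \in \{0.1, 0.5\}$, $\beta$ from
a Poisson GLM, $\theta$ by moments on the positive counts). The
likelihood-ratio test compares the full count model
(race + BV + race:BV) to the reduced model without the interaction,
referring $D = 2(\ell_{\text{full}} - \ell_{\text{reduced}})$ to
$\chi^2$ with one degree of freedom per interaction column; the full fit
is warm-started from the reduced solution so the nested ordering
$\ell_{\text{full}} \ge \ell_{\text{reduced}}$ holds by construction.
P-values are Benjamini–Hochberg adjusted across taxa (via
`p.adjust`). Taxa with too few nonzero counts, an all-zero design cell,
or non-converged fits are skipped with an explicit reason rather than
contributing unstable statistics.

**Elastic-net sign models.** Each clinical sign — pH (raw, not
thresholded at 4.5), whiff test, clue cells (any vs none), abnormal
discharge, and the composite Amsel diagnosis — is modeled as a linear
function of `log(count + 0.5)` taxon features, minimising
$\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 + \lambda\,(\alpha
\lVert\beta\rVert_1 + \frac{1-\alpha}{2}\lVert\beta\rVert_2^2)$ by
cyclic coordinate descent over a 50-point log-spaced $\lambda$ path with
warm starts. Binary signs keep the squared-error objective (a linear
probability model); a logistic variant is deliberately not the default.
Predictors are standardised internally with the population standard
deviation and coefficients reported on the original scale. The descent
asserts a non-increasing penalised objective after every sweep. $\lambda$
is chosen by seeded k-fold cross-validation (10 folds by default,
stratified on binary responses), with both the CV-minimum rule (default)
and the one-standard-error rule available. Defaults $\alpha = 0.5$ and
CV-min are conventions, not fitted constants; for sparse-support
questions ("which few taxa drive this sign?") the lasso end
($\alpha = 1$) with the 1-SE rule is the configuration that keeps false
positives near zero, and that is the configuration the package's own
recovery checks run. A caveat for anyone cross-checking against
`glmnet`: for $\alpha < 1$, `glmnet` standardises the response
internally, which rescales its quadratic penalty relative to the
objective written above; the two agree exactly at $\alpha = 1$, and at
$\alpha < 1$ this package's solution attains the lower value of the
objective it documents.

# The synthetic-data generator

The generator defines the study conditions the tests and acceptance
checks run under; its defaults are fixed once and describe a realistic
cohort, not a tuning surface.

**Reference world.** Sequence divergence is engineered with disjoint
blocks of alignment columns: each genus mutates a genus block and each
species additionally a species block, giving ~7% between-genus, ~4%
within-genus and <1% within-species distances — inside the curation
thresholds by construction, not merely in expectation. Within-species
variation is i.i.d. substitution outside all blocks. No indel process is
simulated (only distances matter downstream), so the "alignment" is
gap-free. The taxonomy names the taxa that structure real vaginal
communities — two Lactobacillus species (crispatus-like and iners-like),
Gardnerella, Atopobium, Prevotella, Megasphaera, Sneathia, Leptotrichia,
Eggerthella — plus provisional BVAB taxa flagged as uncultivated.

**Cohorts.** Default design mirrors a 220-woman STD-clinic cohort:
44.5% BV, race mix Black/White/Other = 0.34/0.44/0.22, sequencing depth
log-normal around 1620 reads per participant. Per-sample depth
variability is not dictated by anything upstream; the default
coefficient of variation is 0.5, chosen as typical for multiplexed
pyrosequencing runs and configurable. Non-BV communities draw a dominant
Lactobacillus (crispatus-like with probability 0.6) whose share is
$0.5 + 0.5\,\mathrm{Beta}$-distributed — always above half, ~90% on
average. BV communities draw log-normal abundances with shared latent
factors inducing configured co-occurrence sub-groups. Counts follow a
ZINB observation model ($\pi = 0.15$, $\theta = 1.5$) on composition
times depth; in Lactobacillus-dominated samples the dominant organism is
neither a dropout nor outnumbered, so its count is set from the realised
non-dominant total to preserve its compositional share. A multinomial
observation mode is provided when exact row sums are needed. The Nugent
score decreases logistically in the log Lactobacillus fraction —
reproducing, qualitatively, the continuum of scores along the iners
axis versus the discontinuity along crispatus — and the four Amsel
signs follow linear models on log counts with BV-associated taxa
loading positive and crispatus negative; `bv_amsel` then applies the
clinical 3-of-4 rule to the generated signs. Race-by-BV interactions
multiply configured taxa's count means on the log scale for the
baseline race level.

**Placements and FASTQ.** Simulated reads concentrate $1 -
\text{spread}$ of their posterior on a terminal edge of their taxon's
clade and scatter the remainder; read counts per sample equal the count
table exactly. The FASTQ writer emits barcode + primer + mutated
reference subsequence with Gaussian-profile qualities and injects a
logged fraction of deliberate failures (foreign barcode, short body,
low quality) for QC testing. Chimeras and homopolymer-specific error
modes are not emulated.

**What passing tests do and do not show.** The generator produces pure
clades, gap-free alignments, ideal barcodes and exactly-specified noise.
Passing tests therefore demonstrate that the algorithms implement their
definitions and behave correctly under the stated statistical structure;
they do not certify performance on real reads with alignment error,
chimeras, primer bias, or reference gaps.

# Problem sizes and determinism

The test-suite and acceptance runs use scaled-down designs chosen as the
smallest sizes at which each statistical claim is informative: reference
worlds of 5–12 taxa with 3–5 sequences each, cohorts of 10–220 samples,
500 null taxa at n = 200 for the type-I-error calibration, parameter
recovery at n = 2000, and 100 bootstrap replicates for squash support.
Every stochastic step draws from an explicit seed argument and restores
the caller's RNG state; rerunning any stage with the same configuration
reproduces byte-identical outputs.

# Known limitations

* The NJ stand-in tree is adequate for clade recovery, not for branch
  length accuracy; use an external ML tree for real data.
* The naive placer ignores alignment uncertainty and indels.
* The zero component of the ZINB is intercept-only by design; data in
  which zero-inflation itself depends on covariates would need a richer
  model.
* Linear probability models for binary signs can predict outside
  `[0, 1]`; coefficients remain interpretable as associations, which is
  the use made of them here.
* Island clustering builds a dense read-by-read distance matrix; the
  pipeline restricts it to the provisional-taxon subset (capped at 1500
  reads) for tractability.
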