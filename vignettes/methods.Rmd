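---
title: "Intra-hemispheric MEG network analysis: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra-hemispheric MEG network analysis: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Focal epilepsy originates within networks largely confined to one cerebral
hemisphere. `hemilat` implements a resting-state MEG analysis chain built
around that observation: instead of summarizing the whole-brain functional
connectome, it extracts the two *intra-hemispheric quadrants* of a
246-node adjacency matrix and asks whether their graph-level organization
differs between patient groups lateralized to the left (LP) or right (RP)
hemisphere, and healthy controls (HC). The stages are

1. LCMV beamformer virtual electrodes (VEs) at atlas ROI centroids,
2. debiased weighted phase-lag-index (dwPLI) connectomes in six bands
   (delta 0.5–3, theta 4–7, alpha 8–13, low beta 13–20, high beta 20–30,
   low gamma 30–50 Hz),
3. proportional thresholding and weighted graph measures per hemisphere
   (global efficiency GE, characteristic path length CPL, transitivity T;
   nodal CC, NE, BC, EVC),
4. Wilcoxon rank-sum group contrasts with Benjamini–Hochberg correction,
   the network-based statistic (NBS) for subnetwork differences, and a
   Gaussian Naive-Bayes classifier under repeated stratified
   cross-validation.

Because clinical MEG recordings cannot be redistributed, the package ships
a synthetic-data module whose cohorts have *known* coupling structure, so
every downstream stage is testable end to end.

## Source reconstruction

The beamformer follows the standard linearly-constrained minimum-variance
construction. The broadband (0.1–150 Hz) data covariance is computed from
the demeaned concatenation of all surviving trials — one long window
rather than per-trial covariances, which stabilizes the estimate at
usual resting-state data lengths. Demeaning is global per sensor; per-trial
demeaning would discard slow per-trial offsets that the 0.1 Hz high-pass
already controls. Tikhonov regularization adds `0.05 * mean(eigenvalues)`
to the diagonal; the mean eigenvalue equals `trace/M`, so no explicit
eigendecomposition is needed. The source orientation at each ROI is the
eigenvector of the source covariance `P(r) = (L' C^-1 L)^-1` with the
*largest* eigenvalue, which maximizes unit-gain output power
`1/(l' C^-1 l)`; the package verifies this against a dense grid search
over orientations in its tests. Because the literature convention on
which eigenvector to take is not always explicit, the minimum-power
alternative is available behind the `criterion` argument. The eigenvector
sign is fixed (largest-magnitude component positive) so VE signs are
reproducible; dwPLI magnitudes are unaffected by a global sign flip.

Lead fields in the synthetic path are a geometric toy: an inverse-cube
kernel of sensor–source displacement on a jittered spherical sensor
shell. They preserve what the beamformer actually relies on — full column
rank 3 per source, smooth decay with distance, distinct spatial patterns
per source — without modeling a volume conductor. Consequences: absolute
VE amplitudes are arbitrary, and no claim is made about spatial leakage
patterns matching real MEG geometry.

## Connectivity estimation

Cross-spectra are computed per trial with a Hann taper and no zero
padding, so the bin grid is `k / trial_length` Hz. Three-second trials
serve all bands above 3 Hz; the delta band uses 12-s trials formed from
exactly four *consecutive* surviving 3-s trials (tracked by original
trial indices; segments interrupted by a rejected trial are never glued).
Band averaging is closed on both band edges; per-bin dwPLI is averaged
over bins (not cross-spectra over trials first) — with the estimator
applied per bin, averaging afterwards is the natural reading of
band-averaged dwPLI.

The dwPLI is the debiased estimator of the squared weighted phase-lag
index: with per-trial imaginary cross-spectra `Im s_k`,

    dwPLI = sum_{k != j} Im s_k Im s_j / sum_{k != j} |Im s_k Im s_j|.

It discards zero-lag (volume-conduction-like) dependencies by
construction and removes the small-sample bias of wPLI²; the tests verify
both properties (null mean within ±0.01 at K = 40 while wPLI² stays
biased upward, and dwPLI ≈ 0 for a zero-lag mixture of a common source).
The estimator can be negative in small samples; raw per-bin values are
preserved, but adjacency construction clips negatives to zero *after*
band averaging because the downstream graph machinery requires
nonnegative weights. 0/0 situations (identical signals, `Im s = 0`)
return 0: identical signals carry no lagged coupling.

## Graph analysis

Node order is canonical block order — left hemisphere nodes 1–123, right
124–246 — so the right intra-hemispheric network is the right–right
principal submatrix and the left the left–left one. This removes the
ambiguity of visual "matrix quadrant" conventions; the atlas bundled with
the package fixes the ordering.

The "10% threshold" is implemented as proportional density by default:
the `round(0.1 * N(N-1)/2)` strongest edges are retained with their
weights (ties broken lexicographically for determinism). An absolute
cutoff mode (`> 0.1`) is provided as well, since published connectivity
figures sometimes describe exactly that; proportional thresholding is the
default because it equalizes edge counts across subjects, which the
group-level graph comparisons assume.

Path lengths are inverse weights; distances come from Dijkstra's
algorithm (via igraph). GE counts disconnected pairs as zero efficiency;
CPL averages only over connected pairs, which is the conventional way of
excluding infinite distances. Transitivity and the clustering coefficient
use Onnela's geometric-mean triangle intensity on weights normalized by
the graph maximum; T is collectively normalized
(`sum 2 t_i / sum k_i (k_i - 1)`) and is deliberately *not* the mean CC —
a property test on ring lattices vs heterogeneous graphs guards against
that common implementation error. Betweenness is reported as the fraction
of shortest paths through a node with the unordered pair count divided by
`(N-1)(N-2)` (raw counts behind a flag), and EVC is the unit-norm
nonnegative principal eigenvector of the thresholded weighted matrix,
computed by power iteration (tolerance 1e-12) with a small diagonal
shift; the shift leaves the eigenvector unchanged but prevents the
oscillation that bipartite spectra (eigenvalues ±λ) otherwise cause.
All seven measures are validated against brute-force enumerations
(Floyd–Warshall, triple-loop triangles, DP path counting) on random
graphs to 1e-9.

## Group statistics, NBS, and classification

Feature selection mirrors the analysis the pipeline automates: Wilcoxon
rank-sum tests on each (band × quadrant × measure) feature, BH-adjusted
across all 36 features. The Wilcoxon wrapper uses exact enumeration when
both groups have ≤ 10 observations without ties and the tie- and
continuity-corrected normal approximation otherwise.

The NBS operates on full 246-node, un-thresholded adjacencies: pooled-
variance edgewise t-tests, a primary threshold (default 3.45), connected
components of supra-threshold edges, and a permutation null of the
maximum component extent (edge count) with the `(1+k)/(P+1)` p-value
convention, which cannot produce zero p-values. Sidedness is not uniquely
determined by common usage, so the default runs both one-sided analyses
on a shared permutation stream and reports each direction. Subjects are
canonically reordered within groups before the permutation stream is
drawn, making results independent of input order. The permutation loop
(t statistics plus union-find component extents) is implemented in
C++ (Rcpp/Armadillo); at 30,135 edges and 500 permutations one NBS run
takes well under a second, which is what makes calibration studies
(hundreds of null cohorts) affordable in the test suite.

The classifier is Gaussian Naive-Bayes with per-class feature means and
variances (variance floored at `1e-9 * max feature variance` to survive
degenerate features at small n) under `n_repeats` random `n_folds`-fold
partitions. Folds are stratified by default: with 16 subjects in the
smallest group, unstratified 10-fold partitions frequently leave a
training fold without a class. Per repeat every subject is tested exactly
once; accuracy, one-vs-rest sensitivity/specificity/precision, and
rank-based AUC from class posteriors are computed over all subjects and
summarized as mean ± SD across repeats; multi-class AUC is
prevalence-weighted one-vs-rest.

Two notes on permutation-null classification accuracy, which the
package's validation uses as a negative control. First, a *single* label
permutation retains chance feature–label alignment whose dataset-level
variance is large; the null is therefore estimated by averaging over
independently re-drawn permutations. Second, for unbalanced groups the
chance level of a prevalence-matched classifier is `sum_k p_k^2` (about
0.524 for 25 vs 16), not 0.5.

The cohort-matching battery reproduces the standard demographic table
tests from printed group summaries: pooled-variance t from (n, mean, SD),
Fisher's exact test for 2×2 tables, and the Freeman–Halton extension for
r×c tables. Freeman–Halton is computed by exhaustive enumeration of all
tables with the observed margins — exact and affordable at these table
sizes (a 2×4 table at n = 41 enumerates a few thousand tables) — and is
cross-checked against the network-algorithm implementation in the tests.

## The synthetic cohort generator

The generator is the package's replacement for patient recordings, and
its defaults define the validation conditions; they were chosen once, on
the following grounds.

**Coupling model.** Each coupling makes the target node's band-limited
component `sqrt(c) ×` (the source node's carrier, phase-rotated by a
constant lag) `+ sqrt(1-c) ×` an independent carrier. The rotation is
applied in the frequency domain (all-pass), so the lag is constant across
the band and the population value of every phase-lag estimator is
analytically accessible. For this model the dwPLI converges to
`(E Im s / E |Im s|)^2` with
`Im s = sqrt(c) u sin(phi) + sqrt(1-c) W`, `u ~ Exp(1)`,
`W | u ~ N(0, u/2)`; `expected_dwpli()` evaluates this by numerical
integration, and simulation agrees with it to sampling error. The
expectation is monotone in the coupling and vanishes at zero lag, so the
implanted effects have known, deterministic adjacency-level targets.

**Adjacency-mode cohorts.** Subject matrices are the population dwPLI of
the subject's coupling configuration plus i.i.d. symmetric Gaussian
perturbation (SD 0.05), clipped to [0, 1]. Every subject shares a
heterogeneous background connectome: per-edge couplings drawn once per
cohort from Uniform(0, 0.2) at a π/2 lag, giving population dwPLI values
spread over roughly 0–0.55. The background matters: real dwPLI
connectomes have a broad weight distribution, and max-normalized triangle
measures respond to *relative*, not absolute, weight structure. Against a
zero background, any implanted strong subnetwork raises the graph maximum
and mechanically *lowers* transitivity — the opposite of the phenomenon
being emulated.

**Implanted effects.** Cohort sizes default to HC 22 / LP 25 / RP 16,
matching the unbalanced design typical of clinical cohorts. The default
RP effect raises theta-band coupling by +0.1 on the full clique over 15
right-hemisphere nodes (drawn from temporal, parietal, insular and
subcortical areas). A clique concentrates triangles, and the +0.1 delta
lifts the implanted edges to the top of — not beyond — the background
weight range, so the right theta quadrant of RP-like subjects shows
higher GE and T and lower CPL, the direction pattern reported for
right-lateralized patients, while the left quadrant stays null. The NBS
recovery validation instead uses the sparser, stronger configuration of
a 20-edge subnetwork over 7 nodes at delta +0.3, whose population effect
(≈ 0.7 vs ≈ 0.3 background) is detected with essentially unit power at
n = 15/15; effect sizes in this package are free design parameters, since
no quantitative coupling difference is available to match.

**Sensor mode** runs the full forward chain (carriers → toy lead fields →
sensors with additive noise at a requested SNR) and is used to validate
the beamformer path; it supports explicit coupling lists but not the
dense background (each node can be the target of one coupling per band).

**What passing tests do not show.** The generator draws subject
perturbations independently across edges, implants effects with a known
deterministic target, uses schematic geometry, and contains no
physiological artifacts, epileptiform activity, age/medication
confounds, or spatial leakage. Green tests demonstrate that the
estimators, graph measures, statistics and permutation machinery are
implemented correctly and calibrated — not that the pipeline would
reproduce any particular clinical effect size on real recordings.

## Problem sizes used in validation

The shipped validation suite uses: 100 random graphs (N ≤ 12) for the
brute-force oracle comparison; 5 simultaneous sources, 50 sensors, 60 s
at 20 dB SNR for beamformer recovery; 200 null cohorts × 500 permutations
for NBS family-wise-error calibration plus 50 seeds for effect recovery;
and the full 63-subject default cohort for the end-to-end lateralization
check with 100 cross-validation repeats. These sizes give stable
pass/fail behaviour at interactive runtimes; all of them are plain
function arguments, so larger replications are one-line changes.

## Known limitations

* Toy lead fields and schematic atlas coordinates: no anatomical claims.
* The adjacency-mode noise model is i.i.d. across edges; real connectome
  noise is spatially structured.
* The dwPLI population target assumes the generator's Gaussian carrier
  model; it is not a general closed form for arbitrary signals.
* NBS reports component extent (edge count) only; mass-based statistics
  and exchangeability blocks are out of scope.
* The classifier panel is deliberately minimal (Gaussian NB); no
  hyperparameter search or alternative classifiers.
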