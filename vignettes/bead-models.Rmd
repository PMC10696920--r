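---
title: "Bead models of 3D genome architecture from Hi-C counts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bead models of 3D genome architecture from Hi-C counts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicbeads)
```

# The model

A genome is discretised into beads: bead $k$ of a chromosome represents the
left-open genomic interval $](k-1)\,\mathrm{res},\ k\,\mathrm{res}]$ at a
chosen resolution (bead 1 covers $]0, \mathrm{res}]$; the trailing partial
interval is kept as an undersized bead rather than silently dropped).
Binned Hi-C contact counts $x_{ij}$ between beads $i$ and $j$ are modelled
as negative binomial draws whose mean decays as a power of the spatial
distance between the beads:

$$
x_{ij} \sim \mathrm{NB}(\mu_{ij}, r), \qquad
\mu_{ij} = \beta\, \lVert p_i - p_j \rVert^{\alpha},
$$

with the dispersion convention $\mathrm{Var} = \mu + \mu^2/r$ standard in
sequencing statistics ($r \to \infty$ recovers Poisson). The negative
binomial accommodates the over-dispersion of population-averaged Hi-C
counts and behaves well at low coverage. Coordinates $p_i \in
\mathbb{R}^3$ maximise the log-likelihood summed over the *observed*
(non-zero, off-diagonal) unordered pairs; pairs with zero counts are
treated as unobserved by default, which keeps the cost proportional to the
number of non-zero entries (a `zeros_informative` switch includes them as
genuine NB zeros).

Key model assumptions: one consensus structure for a cell population
(haploid, single string of beads per chromosome); a single global decay
exponent; counts conditionally independent across pairs given the
coordinates. The output is defined only up to a similarity transform —
translation, rotation, reflection and a global scale that trades off
against $\beta$ — so every comparison in the package superposes first.

# Fitting

1. **Wish distances.** Observed counts are inverted through the power law,
   $d_{ij} = c_{ij}^{1/\alpha}$, and rescaled so the median adjacent-bead
   wish distance is 1, fixing the arbitrary model unit.
2. **Initialisation.** Per connected component of the contact graph:
   shortest-path completion of the wish-distance graph, classical scaling
   (`cmdscale`), then L-BFGS refinement of the stress over observed pairs
   only. Components are placed apart along one axis with a warning;
   exactly coincident points are broken by a seeded jitter, so the
   initialisation is deterministic given the seed (default 42).
3. **Alternating ascent.** L-BFGS blocks on the flattened coordinate
   vector (analytic gradient; 50 iterations per block, 500 coordinate
   iterations in total by default, relative tolerance $10^{-6}$) alternate
   with parameter refreshes: $\beta = \sum c_{ij} / \sum d_{ij}^\alpha$
   (the Poisson maximum-likelihood closed form given coordinates) and $r$
   by method of moments on Pearson residuals, clamped to
   $[10^{-2}, 10^{12}]$. Because the closed-form $\beta$ is the *Poisson*
   MLE, it can occasionally decrease the NB likelihood; a refresh is
   therefore accepted only when the likelihood does not decrease, which
   guarantees a monotone likelihood trace.
4. **Numerical guards.** Distances are floored at $10^{-6}$ times the
   median wish distance so the likelihood stays finite for coincident
   beads; for $r \ge 10^{10}$ the Poisson limit expression is used
   directly, because the exact NB expression loses precision in
   $\log\Gamma(c + r) - \log\Gamma(r)$ at that magnitude.

$\alpha$ is fixed at $-3$ by default, the standard contact–distance decay
in Hi-C modelling; joint estimation of $\alpha$ is out of scope. Beads
whose bin has zero marginal count (typically centromeric/telomeric bins)
are excluded from the likelihood rather than pinned anywhere.

# Refinement

Fitting leaves holes where bins had no usable counts. Refinement runs, in
order: outlier filtering, interpolation, annotation
(`refine_model()`). A bead is an outlier when its distance to *every*
coordinate-bearing sequence neighbour exceeds the threshold (default 10
times the chromosome's median adjacent distance) — a bead far from one
neighbour but close to the other is conservatively kept. Interior runs of
missing beads are then filled, per axis, by monotone piecewise-cubic
Hermite interpolation (PCHIP) over bead index, which is exact on affine
stretches and never overshoots its knots; runs touching a chromosome end
are never extrapolated and are discarded instead. Filtering precedes
interpolation so aberrant beads end up replaced by interpolated positions
and the refined chain has no interior coordinate holes. The interpolation
abscissa is the bead index rather than the genomic midpoint because the
trailing partial bead makes midpoints non-uniform.

Annotation assigns chromosome $1, 2, 3, \ldots$ to chain letters
$A, B, C, \ldots$ (then $a$–$z$; 62 chromosomes at most) and residue names
`C01`, `C02`, …, so any molecular viewer colours chromosomes immediately;
`write_pdb()` also writes the chromosome number into the residue sequence
field and the per-bead signal into the B-factor column. The PDB writer is
canonical: coordinates are scaled by one uniform factor so the largest
absolute coordinate is 100.0, making write → read → write byte-identical.

# Omics painting

A bedGraph at exactly the model resolution maps bin
$[k \cdot \mathrm{res}, (k+1) \cdot \mathrm{res})$ to bead $k+1$; a width
mismatch is an error, not a resampling request. Two visualisation
thresholds are provided: `binarize` (value $\ge$ cutoff $\to$ 1, e.g. 80
normalised counts for high-residency cohesin anchors — the cutoff is
inclusive, a choice this package fixes) and `floor` (values below the
cutoff, e.g. 20 counts, become 0 while the rest stay continuous). Painting
only ever touches B-values, never geometry: "discarding" a low value is a
display decision, not a model edit.

# Inversion detection

On a correct assembly the Euclidean distance between beads with successive
sequence numbers is smooth; an inverted assembly segment shows up as two
isolated spikes, at its junctions, because the spatial chaining disagrees
with the sequence numbering there. The detector flags adjacent pairs
exceeding $\tau$ times the chromosome's *median* adjacent distance
(median, not mean, for robustness; default $\tau = 5$, far below junction
spikes yet tolerant of ordinary spacing noise), pairs flagged junctions
greedily left to right, and accepts a candidate segment $[i+1, j]$ only if
reversing it brings both junction distances back under the threshold.
Corrections reverse-complement the spanned genomic interval and permute
the bead labelling back; applying a correction twice is the identity.
Unpairable flagged junctions are reported but never "corrected" — only
inversions are modelled; a translocation-like anomaly stays flagged.
Multiple inversions are handled by iterating detect → correct (up to 5
rounds, `correct_assembly()`).

A geometric caveat, visible in the folded (Rabl-like) test structures: an
inversion whose junction beads are spatially close for *biological*
reasons — e.g. a short segment spanning the centromere of a
folded-in-half chromosome, where the two arms lie against each other —
produces junction distances that never exceed $\tau$ times the median and
is undetectable by this geometry-only method. Detectability requires the
junction beads to be far apart in space, which holds for segments lying
within one arm with a sequence span of more than a handful of beads.

# Shot-noise stability

Robustness to count noise is quantified by perturbing the raw counts,
$y_{ij} = x_{ij} + e_{ij}$ with $e_{ij} \sim \mathrm{Poisson}(\lambda)$
drawn once per unordered pair and mirrored ($e_{ij} = e_{ji}$), refitting,
and measuring RMSD to the reference structure after optimal superposition.
Choices fixed here: noise applies to raw (pre-normalisation) counts — a
warning is issued when counts look normalised; the diagonal receives noise
like any pair (switchable); the default grid is $\{0.1\} \cup \{5, 10,
\ldots, 110\}$ (23 levels) with 50 replicates, i.e. 1150 cells. Noise
seeds are derived per cell from the base seed, the grid position and the
replicate, so results are independent of scheduling order, while the
inference seed is shared across cells so RMSD differences reflect noise,
not initialisation.

Superposition centres both point sets, finds the least-squares rotation,
and by default also searches the reflection branch and fits a uniform
scale, because inferred structures carry arbitrary orientation, chirality
and scale. With scaling on, RMSD is asymmetric (the second model is scaled
onto the reference); with scaling off it is symmetric. Global RMSD uses
all common beads; per-chromosome RMSD superposes each chromosome
independently. Per-chromosome values are compared with global ones as
pooled distributions per $\lambda$ (the per-chromosome median at a noise
level versus the global median), since independent superposition of one
particular chromosome need not beat the global RMSD pointwise.

# The synthetic generator

`make_rabl_structure()` emulates what the fitted models of real fungal
genomes look like: centromeres clustered near one pole, both arms of each
chromosome running as interleaved helices toward the opposite telomere
side, chromosomes offset angularly into territories, plus a small seeded
Gaussian jitter. Defaults: 3 chromosomes of 1.0/0.8/0.6 Mb at 10 kb
(60–100 beads each), centromeres at 40% of the length, coil radius 0.8
and 10 beads per turn with an axial rise of 0.35 per bead. The rise is
deliberately small enough that *adjacent helix turns sit within contact
range* of the count model at realistic depth: with $\beta$ of a few
hundred (an adjacent-bin count typical of a shallow fungal Hi-C library)
and $\alpha = -3$, rounded counts vanish beyond a few model units, and a
coil whose pitch exceeds that range yields data that constrain only a
sliding window of the chain — the global shape is then genuinely
underdetermined under the observed-pairs-only likelihood. This is a
property of the data, not of the optimiser, and the generator's defaults
are chosen so the study conditions actually determine the structure.

`counts_from_structure()` inverts the model ($\mu = \beta d^\alpha$;
deterministic rounding, Poisson or NB realisations);
`plant_inversion()` builds the mislabelled-segment configuration;
`make_track()` writes two-level bedGraph tracks with truncated-Gaussian
noise (the consumed quantity is normalised coverage, not raw counts).

What the generator does *not* emulate: topological polymer constraints,
excluded volume, a nucleolus (rDNA holes are only representable as
missing bins), normalisation biases, restriction-fragment structure, or
distance-dependent noise. Passing tests on these fixtures therefore shows
the algorithms implement their contracts — power-law inversion,
monotone-ascent fitting, exact label bookkeeping — not that real Hi-C
libraries meet the model's assumptions.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, sizes
chosen so the full suite completes in well under a minute: a 100-bead
helix for recovery, an 80-bead three-chromosome genome for the reduced
noise scan ($\lambda \in \{0.1, 10, 30, 50\}$, 5 replicates), and a
400-bead chromosome for the inversion worked example. Every stochastic
step (generator jitter, noise injection, initial embedding) is seeded;
the end-to-end build is byte-deterministic given its config.

# Known limitations

- Consensus-model assumption: no ensemble or haplotype-resolved variants.
- $\alpha$ is not estimated; a wrong decay exponent distorts scale
  non-uniformly.
- The observed-pairs-only likelihood ignores the information in zeros
  unless `zeros_informative` is set, and very sparse matrices can leave
  the global arrangement of weakly linked components poorly determined.
- Inversion detection is geometry-only (see the caveat above) and models
  inversions exclusively.
- `read_pdb()` cannot re-anchor leading discarded beads to bins, because
  the PDB dialect carries bead identity only through record order.
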