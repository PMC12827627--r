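---
title: "Avidity geometry and free-energy post-processing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avidity geometry and free-energy post-processing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avidpmf)
```

## What this package computes

Pentameric IgM carries ten Fab arms on a rigid, roughly planar Fc core.
Whether that valency translates into avidity depends on geometry: an
antigen the size of a receptor ectodomain must physically reach a Fab's
complementarity-determining region (CDR) without colliding with the rest
of the antibody.  `avidpmf` implements the quantitative toolkit for that
question on coarse-grained (bead-resolution) conformational ensembles:

1. **Large-probe accessible surface area (ASA)** of the CDR, where the
   probe radius is derived from the antigen, not from a water molecule.
2. **Nearest-obstruction distances and the simultaneous-binding
   probability**: the fraction of (frame, Fab) configurations in which an
   antigen-sized sphere fits at the CDR.
3. **Ensemble dynamics metrics**: RMSD in two fit modes, per-bead RMSF,
   coordinate-covariance PCA, cutoff contacts, and centre-of-mass
   distance series.
4. **Potential of mean force (PMF)** estimation from umbrella-sampling
   windows by WHAM, with overlap diagnostics, integrated autocorrelation
   times, Bayesian bootstrap errors and a plateau-based binding energy.

A synthetic-data module generates both toy antibody ensembles and exact
Boltzmann umbrella samples from known potentials, so every stage has a
ground truth to be tested against without running molecular dynamics.

## The accessibility model

### Probe and threshold radii

Both radii are taken from the geometry of the bound receptor domain.
`domain_widths()` reports the maximum pairwise extent of a selection and
its minimal principal-axis extent, with half-values.  Applied to the
receptor's antibody-binding domain, half the maximum width (3.5 nm for
the EGFR case that motivates the defaults) is the ASA probe radius — the
effective radius of the sphere the antigen sweeps — and half the minimal
width (1.8 nm) is the smallest clearance at which binding is considered
geometrically possible.  "Minimal width" is deliberately a *global*
extent (the smallest side of the principal-axis bounding box), not a
minimum pairwise distance, which would approach the bead diameter and
carry no shape information.

### ASA with a large probe

`compute_asa()` is a Shrake–Rupley-style point-sampling estimator: each
selected bead's sphere of radius \(r_i + R\) is covered with a
deterministic golden-spiral lattice (default 960 points; no random
numbers, so results are exactly reproducible), and a point counts as
exposed when it lies outside every other bead's inflated sphere.  All
beads of the structure occlude, whether or not they are in the
selection.  The estimator converges as \(n^{-1/2}\) in the point count;
doubling from 960 to 1,920 points moves totals by under 0.5 % on test
structures.  Rigid-motion invariance holds to the same discretisation
error, because the lattice is fixed in space rather than co-rotating.

### Simultaneous-binding probability

For every (ensemble, frame, Fab) configuration,
`nearest_obstruction_distance()` measures the Euclidean distance from
the CDR's centre of mass (unweighted bead mean; a mass-weighted option
exists for inputs that carry masses) to the nearest bead centre of any
domain other than the host Fab.  Glycan and accessory domains count as
obstructions by default — they are part of the antibody — and can be
excluded with a flag.  A configuration is *accessible* when the
distance is at least the threshold; the comparison is closed, so exact
ties are accessible.  `binding_accessibility()` pools configurations
over ensembles, so three runs of 5,000 frames with ten Fabs yield
150,000 configurations, and reports per-Fab and pooled probabilities
with the full distance table for plotting.

## Ensemble metrics

`superpose()` solves the optimal rigid-body fit (Kabsch, with the
determinant-sign correction that forbids reflections) and errors on
degenerate — collinear or coincident — fit selections.  `rmsd_series()`
exposes the two fit conventions that matter for multidomain assemblies:
fitting on the whole assembly measures a domain's excursion within the
complex (hinge motion included), while fitting on the domain itself
measures internal deformation only.  On a toy pentamer with mobile arms
the whole-fit Fab RMSD strictly exceeds the self-fit RMSD, which is the
signature the two modes are designed to separate.

`rmsf()` and `pca()` align frames to the time-average structure with a
two-pass fit (fit to the first frame, average, refit to the average).
Full iterative convergence changes results by less than the test
tolerances and would cost determinism in the iteration count, so the
two-pass scheme is fixed.  PCA eigendecomposes the covariance of the
3N-vector (column-major: all x, then y, then z) via SVD of the centred
frame matrix; with fewer frames than coordinates the spectrum is rank
deficient, which is expected and only warned about.  The dense
eigenproblem is practical to a few thousand selected beads.

`contact_count()` uses a cell list with cells of the cutoff size, so
only 27 neighbouring cells are searched per bead; it is validated
against an \(O(N^2)\) double loop.  The default cutoff of 0.6 nm is the
conventional coarse-grained contact distance.  Contacts are
bead-centre distances, not surface distances.

## Umbrella sampling and WHAM

### The estimator

`wham_solve()` iterates the standard self-consistency equations

\[
P(x_b) = \frac{\sum_i h_i(x_b)}{\sum_j N_j\,
  e^{[f_j - w_j(x_b)]/k_BT}},
\qquad
f_i = -k_BT \ln \sum_b P(x_b)\, e^{-w_i(x_b)/k_BT},
\]

with harmonic biases \(w_i(x) = \tfrac{k_i}{2}(x - x_i^0)^2\), stopping
when the largest change in any \(f_i\) falls below the tolerance
(default \(10^{-6}\) kJ/mol, cap \(10^5\) iterations; non-convergence is
flagged on the profile rather than fatal).  Constants:
\(k_B = 0.0083144621\) kJ mol\(^{-1}\) K\(^{-1}\) and a default
temperature of 310 K, so \(k_BT = 2.5775\) kJ/mol.  The default bin
width of 0.02 nm puts five bins between windows spaced 0.1 nm apart —
enough to resolve the profile without starving bins of counts.

Two conventions to be aware of.  The PMF zero is the global minimum of
the profile, and \(f_1\) is pinned to zero.  Because the minimum is
taken over noisy bins, profiles from thin sampling carry a small
positive offset (the minimum of noise is biased low), and single-count
bins in the far tails of a window can receive enormous reweighting
factors; both effects are properties of the estimator, shrink as
\(n^{-1/2}\), and matter mainly when interpreting absolute levels
rather than shapes or barriers.  Bins inside the sampled range that
receive no samples get `NA` free energy and are reported.

### Diagnostics and errors

`histogram_overlap()` turns the usual visual check into a number: the
summed bin-wise minimum of adjacent windows' normalised histograms (1
for identical, 0 for disjoint), flagging pairs under 0.05.
`autocorrelation_time()` computes the integrated autocorrelation time
\(\tau = 1 + 2\sum_t \rho(t)\), truncated at the first negative
empirical autocorrelation (initial-positive-sequence rule); a constant
series returns \(\tau = 1\) by convention.  \(N/\tau\) is the effective
sample size; windows may be thinned by \(\lceil\tau\rceil\) before
WHAM, but the default is to leave samples in place.

`bootstrap_error()` implements the Bayesian bootstrap over complete
windows: each replicate rescales the window histograms by i.i.d.
unit-mean exponential weights and re-solves WHAM, and the per-bin error
is the standard deviation of the min-shifted replicate profiles.
Unconverged replicates are discarded and counted.  Weighting whole
windows (rather than resampling frames within windows) respects the
fact that the window, not the frame, is the independent unit when
samples are autocorrelated.

`binding_energy()` reads the profile depth as the mean PMF over a
dissociated plateau (default: the last 1.0 nm) relative to the zeroed
minimum.

## The synthetic-data generators

### Toy pentamer

`generate_toy_igm()` abstracts the pentameric architecture into a
parametric geometry: a planar ring of five rigid core segments (six
beads each, fixed across frames, with a small central J-chain-like
cluster), and ten arms attached at hinges on the ring.  Each arm is a
rigid zigzag rod of ten beads whose axis is redrawn *independently per
frame*, uniformly within a cone about the outward radial direction; the
last two beads form the CDR.  Defaults — 6 nm core radius, 7 nm arms, a
40° cone half-angle — were chosen once to match the scale of an IgM
pentamer (~30 nm span, Fab arms of 7–8 nm) and a hinge that is mobile
but not floppy.  Frames are i.i.d. because every downstream
accessibility statistic is frame-marginal; temporal correlation is
deliberately absent, and the AR(1) generator exists separately as the
fixture for autocorrelation estimation.  The generators are pure
functions of (parameters, seed).

What the toy model does *not* emulate: excluded volume between arms,
glycan geometry, elastic-network correlations within domains, and
kinetics.  Tests passing on the toy model therefore certify the
*statistics* (counting, distances, probabilities, spectra), not any
biological conclusion about real antibodies — real ensembles enter
through the PDB/XYZ readers.

### Exact umbrella windows

`generate_umbrella_series()` draws *exact* equilibrium samples from
\(\propto e^{-[U(x) + \frac{k}{2}(x - x_0)^2]/k_BT}\).  For flat and
harmonic reference potentials the total is Gaussian and the draw is
closed-form (harmonic: mean \((\kappa c + k x_0)/(\kappa + k)\),
variance \(k_BT/(\kappa + k)\)).  The double well
\(U(x) = B\,[(x-c)^2 - w^2]^2/w^4\) is parameterised so the barrier at
the midpoint equals \(B\) exactly, making the WHAM recovery target
analytic; sampling is by rejection against a Gaussian envelope centred
on the numerically located mode of the total potential, with the
envelope widened 1.5-fold and the acceptance bound computed on a grid.
An acceptance rate under 1 % raises an error as a symptom of ill-chosen
parameters rather than silently looping.

### Gaussian-mode ensembles

`generate_gaussian_ensemble()` plants known orthonormal displacement
modes with chosen variances on a mean structure, giving PCA a
closed-form target: with variances (4, 1) nm² the first mode carries
80 % of the variance.

## Problem sizes and verification

The test-suite and acceptance computations run at desk scale, chosen so
each statistical check has a closed-form target and a tolerance derived
from sampling theory: WHAM recovery uses 17 windows × 5,000 exact
samples (harmonic surface recovered to < 0.3 kJ/mol RMS on
\([-1.5, 1.5]\) nm; double-well barrier to ±0.5 kJ/mol); the binding
probability is recounted by brute force over 50,000 configurations and
pooled over 150,000; PCA uses 10,000 frames (PC1 fraction 0.80 ± 0.02);
RMSF uses 5,000 frames of isotropic jitter
(\(\sigma\sqrt{3} = 0.173\) nm ± 5 %); the AR(1) autocorrelation time
uses \(10^5\) samples (\(\tau = 9 \pm 1\)).  Validation against the
headline numbers of microsecond coarse-grained simulations of real
IgM–receptor systems (binding probabilities near 90–93 %, PMF depths of
tens of kJ/mol) requires the deposited trajectories of such a study and
is outside the test suite; the pipeline to perform it is
`read_ensemble()` + `load_domain_map()` + `binding_accessibility()` at
a 1.8 nm threshold, and `read_umbrella_manifest()` + `wham_solve()`.

## Known limitations

* The probe is a sphere; anisotropic receptor shapes and inter-domain
  flexibility of a real antigen are not captured.
* Whether the original distance statistic measured bead centres or
  residue centres of mass is ambiguous in the source material; the
  package defaults to bead centres and exposes a mass-weighted COM
  option.
* No periodic-boundary handling: inputs are assumed whole and
  unwrapped.
* The reaction coordinate is a 1D scalar; 2D umbrella integration and
  MBAR-style estimators are out of scope.
* PMF absolute levels inherit the min-shift noise discussed above;
  barriers and relative depths are the robust quantities.
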