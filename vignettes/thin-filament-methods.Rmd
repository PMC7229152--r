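---
title: "Methods: models, conventions, and design choices in thinfil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions, and design choices in thinfil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thinfil` implements the computational layer of a thin-filament regulation
study as a set of testable operations: trajectory descriptors and PCA,
energetic reweighting of boosted ensembles, dynamical network analysis,
rigid-body electrostatic landscape scanning, and muscle assay statistics.
This vignette records the science behind each stage, the conventions the
package fixes, and the reasoning behind choices that were genuinely open.
Everything quantitative stated here is computed by the test suite or the
acceptance script; nothing is quoted from elsewhere.

## Coordinate and unit conventions

All geometry is right-handed Cartesian in Angstrom.  The filament axis is
+z; azimuth is measured counter-clockwise looking down +z; positive
longitudinal offsets run toward the pointed end.  Energies are kcal/mol,
charges elementary charges, temperatures kelvin, with
k_B = 0.0019872041 kcal/(mol K) and the analysis temperature defaulting to
310 K (the simulation thermostat temperature), so beta = 1/(k_B T) ~ 1.62
mol/kcal.

## Trajectory descriptors and PCA

Frames are superposed by least-squares rigid fitting (Kabsch, via SVD of the
cross-covariance; proper rotations only, so mirror images keep a residual).
The `reference = "mean"` mode iterates fitting against the running mean
structure to self-consistency, the standard prelude to PCA.  PCA
diagonalizes the covariance of the selected sites' Cartesian fluctuations;
eigenvalues are reported in A^2 with variance fractions, and projections are
the centered frames dotted onto eigenvectors.  Descriptors follow common
practice for actin:

* Subdomain RMSDs exclude the DNase-binding loop (residues 39-50) and the
  hydrophobic plug (263-271) by default, because both elements stay highly
  mobile regardless of conformational state and would otherwise dominate the
  subdomain signal.  Subdomain ranges follow the standard actin convention
  (SD1 1-32/70-144/338-375, SD2 33-69, SD3 145-180/270-337, SD4 181-269).
  Note the plug straddles the SD3/SD4 junction under these ranges -- which
  is exactly why it is excluded from SD4 RMSDs as well as SD3.
* Cleft reporters are the C-alpha distances G15-D157 (inner, near the
  nucleotide) and E59-R206 (outer, near the surface).
* The radius of gyration is mass-unweighted: bead models carry no masses,
  and relative compactness comparisons are unaffected.
* Free-energy surfaces are `-(1/beta) ln(p/p_max)` over binned projections,
  shifted so the minimum is zero; unobserved bins are reported as missing
  (`NA`), never as zero, since an unvisited cell is evidence of *high* free
  energy, not zero.

Conformer clustering uses average-linkage agglomerative clustering on the
pairwise RMSD matrix after mutual superposition, cut to the requested number
of clusters, returning medoids ordered by cluster size.  Average linkage and
the medoid representative were chosen because they are the least
shape-assuming of the standard options; neither is forced by the science.

## Boosted ensembles and Maclaurin reweighting

Accelerated sampling adds a boost `dV(x) = (E - V(x))^2 / (alpha + E - V(x))`
wherever `V < E`, flattening barriers below the threshold energy E while
leaving the landscape above E untouched.  The closed forms
`E = <V_dihedral> + 3.5 N_residues` and `alpha = (3.5/5) N_residues`
parameterize the boost from a conventional run; `amd_parameters` evaluates
them exactly.

The synthetic generator applies the boost to the *total* potential of an
analytic 1D/2D system: an analytic potential has no dihedral term to single
out, and what the reweighting must invert is the boost-rule mathematics, not
the force-field bookkeeping.  Sampling is by inverse-CDF on a dense grid
(10^4 points, with uniform jitter inside each grid cell), so the target
density is exact and no integrator is involved.

Reweighting bins the samples (bin size 5 PC units, bins anchored at zero)
and multiplies each bin's biased probability by the truncated Maclaurin
series for `<exp(beta dV)>` (default order K = 10; the truncation order is
not dictated by the method, so it is configurable and recorded in the
output).  The series is monotone non-decreasing in K for `dV >= 0`, which
the tests verify along with convergence to the exponential average.

One recovery-testing subtlety: with 5-unit bins the planted potential rises
by more than 1 kcal/mol *within* a single bin on the steep well walls, so
comparing the recovered PMF to the potential evaluated at bin centers would
mostly measure discretization.  The reference used in the tests is therefore
the planted potential *represented at bin resolution* -- exact Boltzmann bin
probabilities computed on a dense grid -- which isolates what reweighting is
responsible for.  The planted double well used throughout has wells at
+-25 PC units and a 2 kcal/mol barrier, the energy scale typical of
conformational substates in a folded protein; recovery is required to
0.5 kcal/mol RMS on bins holding at least 200 samples.

## Dynamical networks

Cross-correlation is `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`
over frames.  Network edges join residue pairs whose minimum inter-site
distance is within 4.5 A in strictly more than 75% of frames ("more than"
taken literally: exactly 75% does not qualify).  Nearest sequence neighbors
(|i - j| <= 1) are excluded -- their contacts are trivially persistent and
carry no allosteric information.  Edge weight is the communication distance
`w = -ln |C_ij|` with |C| floored at 1e-6 before the log; the raw |C| is
kept as the edge *affinity*.

Two deliberate semantic choices:

* **Single-path betweenness.** Each unordered node pair contributes exactly
  one weighted shortest path, found by Dijkstra with equal-cost relaxations
  resolved toward the smaller-indexed predecessor.  This makes betweenness
  counts integers and the whole Girvan-Newman removal sequence
  deterministic, at the cost of ignoring path multiplicity (which the tests
  sidestep by using generic weights where relevant).
* **Distances for paths, affinities for modularity.** Shortest paths
  minimize summed `-ln |C|`; modularity is evaluated with |C| as the edge
  weight.  Using the distance as a modularity weight would reward weak
  edges, inverting the meaning of community structure.

Girvan-Newman removes the highest-betweenness edge (ties broken by
lexicographic edge order), recomputes betweenness after every removal, and
returns the connected-component partition of maximal weighted modularity
over the sequence, including the unsplit graph -- so a structureless graph
yields one community rather than a forced split.  Suboptimal communication
paths use Yen's algorithm; partition similarity is the adjusted Rand index
(bounded, chance-corrected, closed-form on small examples).

## Electrostatic landscapes

Filaments are built by the helical symmetry operation: protomer k is rotated
by k x twist about +z and translated by k x rise.  The defaults, rise 27.5 A
and twist -166.7 deg, are the canonical F-actin one-start helix values and
are configurable.  The tropomyosin pseudo-chain is placed rigidly: radial
docking translates the whole chain along its centroid's outward direction,
then it is rotated about the filament axis and translated along it.  For a
chain subtending a small azimuthal arc this is an excellent approximation to
per-bead radial motion, and it keeps the operation exactly rigid.

Energies are unscreened Coulomb sums over cross pairs,
`332.0636 q_i q_j / (eps r)`, with the distance-dependent dielectric
`eps = 4r` by default as a crude solvent screen.  Absolute energies from a
bead model with formal charges are not comparable to all-atom force-field
energies; only landscape *topology* -- basin count, location, relative depth
-- is interpreted.  The contour metadata (-1500..0 in steps of 300 kcal/mol)
is carried on every grid for display parity with the all-atom convention.

The scan covers azimuth -25..+25 deg x longitude -17.5..+17.5 A in
2.5 deg x 2.5 A steps (315 cells; the extents are package defaults chosen to
give a grid of that order, not values inherited from any particular study)
with radial docking 43 -> 39 A in 0.5 A steps.  Each cell's energy is the
minimum over the radial sweep -- the rigid surrogate for per-grid-point
docking plus minimization, which would require an all-atom force field that
is out of scope.  A radius producing any pair distance below 0.5 A is a
steric clash and infeasible; a cell infeasible at every radius is flagged
rather than scored.  Basins are strict local minima on the 8-neighborhood,
with membership by steepest descent and width counted as cells within one
contour interval (+300 kcal/mol) of the basin minimum.

The planted fixtures put one charge track per protomer at the scan origin
(wildtype-style: one deep basin at (0,0)) or split the same charge into two
tracks +-12 deg apart (two nearly degenerate flanking basins).  The charge
track sits at radius 33 A so the track-to-chain separation (6-10 A over the
docking sweep) makes the basins sharp enough to resolve on the 2.5 deg grid;
with the track at smaller radii the 1/r^2-screened interaction is too soft
and flanking tracks blur into a single central well.

## Muscle assay statistics

Motility: per-filament velocity is mean frame-to-frame centroid displacement
over the frame interval (path speed).  Each condition contributes its
(SD, V_avg) point; a pooled through-origin regression gives the slope m, and
`SD_pred = V_avg / m`, `V_cut = V_avg - 0.5 SD_pred`.  A filament is a mover
iff its velocity strictly exceeds V_cut.  The per-condition SD is the SD of
per-filament mean velocities (the per-filament mean is the tracked
observable; frame-wise SDs would mix measurement cadence into the
biological spread).

Sinusoidal mechanics: the complex modulus at the perturbation frequency is
extracted by single-frequency projection (the record must hold an integer
number of cycles, otherwise leakage biases the projection and the function
refuses).  Power is `pi f E_v (dL/L)^2` with the default strain amplitude
0.00125 (0.125% of muscle length).

The calcium-activation curve is implemented as
`y = A (1 + 10^(h (pCa - pCa50)))^-1`, under which activation rises with
Ca2+ concentration and y(pCa50) = A/2.  The mirrored exponent
`(pCa50 - pCa) h` is sometimes printed for the same relation; with h > 0 it
produces a curve that *decreases* with Ca2+, so it cannot be what positive
reported Hill coefficients describe.  Both conventions are exposed
(`convention = "rising"`/`"printed"`) and round-trip tests are
convention-independent; raw evaluations of the printed form are never
silently corrected.

The frequency response is fit with the three-term model
`Y(w) = A (iw/w0)^k - B iw/(iw + 2 pi b) + C iw/(iw + 2 pi c)`, the standard
decomposition into a viscoelastic power law, an exponential work-producing
process (rate constant 2 pi b), and a work-absorbing process (2 pi c).
Elastic and viscous moduli are fit jointly (residuals on Re Y and Im Y
concatenated) by Levenberg-Marquardt with the rate constants parameterized
on the log scale and a deterministic multi-start grid; rate constants
converging within 1% of each other are flagged as a degenerate
(non-separable) fit.  Hill fits use the deterministic multi-start
`A0 = max(y)`, `pCa50_0` at the half-maximal response, `h0 in {1, 2, 4}`;
flat, transitionless data return a non-converged result instead of raising.

`f_max` maximizes the power curve under the work-producing sign convention:
if the dominant lobe of `pi f E_v` is negative (the usual sign of the
viscous modulus in the work-generating band) it is flipped positive before
the search.  The grid maximum is refined by a quadratic in log10 f through
its two neighbors; note that a single-process response makes `f E_v`
monotone in f, so its "maximum" sits on the sweep boundary and is flagged
as such rather than refined.

## What the generators emulate -- and what they do not

The synthetic trajectory generator plants Gaussian amplitudes on orthonormal
displacement patterns plus isotropic noise, so the population covariance is
known exactly and PCA recovery is closed-loop.  It emulates the low-rank
covariance structure of hinge/twist protein motions, not their kinetics:
frames are independent draws, there is no time correlation, no anharmonicity
beyond what the planted potential forms provide, and no solvent.  Likewise
the filament fixture reproduces the charge-track geometry that shapes the
tropomyosin energy basin, not protein sterics; the motility generator draws
frame speeds i.i.d. around the planted means; and the mechanics generator
evaluates the fit models themselves plus noise.  Passing tests therefore
demonstrate that the *analysis machinery* is correct and invertible on data
with known truth -- they do not certify behavior on real MD or assay data,
where model misspecification (not estimator error) dominates.

Problem sizes used by the test suite were chosen to make sampling error
comfortably smaller than each tolerance: 2000-3000 frames for PCA recovery
on 40-site models, 50000-60000 samples for reweighting recovery, 400
filaments per motility condition, 30-frequency sweeps, and 16-protomer
filaments with half a dozen beads per protomer for landscape work.

## Known limitations

* The landscape scanner treats both partners as rigid; tropomyosin
  flexibility and pseudo-rotation, and any myosin interaction, are out of
  scope.
* Bead-model Coulomb energies are on an arbitrary absolute scale; only
  basin topology is meaningful.
* Single-path betweenness undercounts communication through degenerate path
  families (deliberately, for determinism).
* The Maclaurin estimator of `<exp(beta dV)>` is biased low at finite K for
  large boosts; with the default boost scales here (beta dV up to ~3) the
  K = 10 truncation error is far below the 0.5 kcal/mol recovery tolerance,
  but users planting much deeper boosts should raise K.
* `hill_fit` and `nyquist_fit` report covariance/diagnostics from the local
  quadratic approximation at the optimum; they are not profile intervals.
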