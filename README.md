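# thinfil

Analytics for thin-filament contractile regulation: how flexible actin has to
be, and how its surface charges position tropomyosin, studied through coarse
molecular-dynamics-style trajectory analysis, rigid-body electrostatic
landscape scanning, and the statistics of muscle functional assays.

`thinfil` is aimed at people working on actin/tropomyosin regulation and
striated-muscle mechanics who want the computational layer of such a study as
tested, reusable functions: MD-style trajectory descriptors and PCA,
accelerated-sampling reweighting, dynamical network analysis, filament
electrostatics, in vitro motility statistics, and sinusoidal fiber-mechanics
fitting.  Every stage runs end-to-end on synthetic inputs with planted ground
truth generated by the package itself, so the whole pipeline is verifiable
without any external data.

## What is computed

**Trajectory descriptors and free-energy surfaces** (`superpose`,
`rmsd_by_subdomain`, `cleft_distances`, `radius_of_gyration`,
`pca_trajectory`, `rmsf_along_pc`, `fes_histogram`, `cluster_conformers`).
Positional-fluctuation PCA over C-alpha (or bead) sites; subdomain RMSDs with
the customary exclusion of the DNase-binding loop (residues 39–50) and the
hydrophobic plug (263–271); nucleotide-cleft reporter distances (G15–D157,
E59–R206); potential-of-mean-force surfaces
`G(x) = -kT ln p(x)` over PC projections, shifted so min G = 0.

**Accelerated-sampling boost and reweighting** (`amd_parameters`,
`make_boosted_ensemble`, `reweight_pmf`).  Boost rule
`dV(x) = (E - V)^2 / (a + E - V)` for `V < E`, with threshold and
acceleration factor set from a conventional run:
`E = <V_dih> + 3.5 N_res`, `a = (3.5/5) N_res`.  Reweighting multiplies each
bin's biased probability by the Maclaurin-series estimate of
`<exp(b dV)>` (default order K = 10, bin size 5 PC units) and converts back
to a PMF.

**Dynamical networks** (`cross_correlation`, `contact_occupancy`,
`build_network`, `edge_betweenness_paths`, `girvan_newman`,
`optimal_paths`, `compare_partitions`).  Edges join residues in contact
(minimum site distance within 4.5 Å) for more than 75% of frames, weighted by
the communication distance `w = -ln |C_ij|` from the displacement
cross-correlation `C_ij`; Girvan–Newman community detection removes the
highest-betweenness edge iteratively and keeps the partition of maximal
weighted modularity.

**Actin–tropomyosin electrostatic landscapes** (`build_filament`,
`place_tpm`, `electrostatic_energy`, `scan_landscape`,
`average_landscapes`, `basin_analysis`).  A protomer is replicated onto the
F-actin helix (rise 27.5 Å, twist −166.7° per protomer, 16 protomers); a
tropomyosin pseudo-chain is rigidly scanned over azimuth × longitude
(2.5° × 2.5 Å grid) with radial docking from 43 Å to 39 Å in 0.5 Å steps,
scoring the Coulomb energy `E = 332.0636 q_i q_j / (eps(r) r)` (default
distance-dependent dielectric `eps = 4r`); each cell keeps its radial
minimum, and basins are strict local minima with steepest-descent membership.

**Muscle assays** (`track_velocities`, `fit_velocity_sd`, `mover_cutoff`,
`percent_movers`, `complex_modulus`, `power_from_modulus`, `hill_fit`,
`nyquist_fit`, `f_max`).  Motility mover classification via the pooled
through-origin velocity-vs-SD slope m, `SD_pred = V_avg / m`,
`V_cut = V_avg - 0.5 SD_pred`; sinusoidal analysis with
`power = pi f E_v (dL/L)^2` (strain 0.125%), Hill fits
`y = A (1 + 10^(h (pCa - pCa50)))^-1`, and three-term Nyquist fits yielding
the apparent rate constants 2πb and 2πc over the 0.5–600 Hz sweep.

## Worked example

Fit a noisy synthetic power–pCa sweep and its complex-modulus sweep, then map
the electrostatic basin structure of two filament fixtures:

```r
library(thinfil)

sw <- make_mechanics_sweeps(
  mechanics_spec(hill = list(A = 77.7, pCa50 = 6.11, h = 3.52, noise_sd = 1.5)),
  seed = 11)
fit <- hill_fit(sw$power_pca$pCa, sw$power_pca$power)
nf  <- nyquist_fit(sw$modulus_sweep$f, sw$modulus_sweep$E_e, sw$modulus_sweep$E_v)

fx  <- make_filament_fixture(filament_spec(style = "wt"))
L   <- scan_landscape(fx$actin, fx$tpm)
fx2 <- make_filament_fixture(filament_spec(style = "split"))
L2  <- scan_landscape(fx2$actin, fx2$tpm)
```

This prints (via the corresponding `sprintf` calls):

```
Hill fit: A = 77.7 W m^-3, pCa50 = 6.110, h = 3.30
Nyquist fit: 2pib = 1702 s^-1, 2pic = 2697 s^-1
WT-style landscape: 1 basin at (0.0 deg, 0.0 A), -6.4 kcal/mol
split-style landscape: 2 basins at azimuth -10.0 / +10.0 deg
```

The Hill fit recovers the planted half-activation point pCa50 = 6.11 from
noisy data (the slope coefficient is the least certain parameter at this
noise level); the noiseless modulus sweep returns the planted rate constants
exactly.  The wildtype-style charged filament produces a single electrostatic
basin at the inhibitory origin, while splitting the same protomer charge into
two flanking tracks produces two nearly degenerate basins displaced
azimuthally — the qualitative one-basin/two-basin contrast between an intact
and a perturbed inhibitory energy well, reproduced on synthetic ground truth.

A thin command-line front end over the same functions is installed at
`inst/cli/thinfil.R` (`Rscript .../thinfil.R simulate-tracks --seed 3 --out
dir`, then `motility`, `mechanics`, `network`, `landscape`, ...).

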