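---
title: "allokit: models, numerical methods and scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{allokit: models, numerical methods and scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# Methods vignette: code chunks are displayed, not executed. Every numerical
# claim made here is asserted by the test suite or computed by
# scripts/acceptance.R; nothing below reports results that are not.
knitr::opts_chunk$set(eval = FALSE)
```

`allokit` implements the analysis machinery used in studies of allosteric
regulation of protein kinases by buried lipid ligands — the style of study
in which a myristoylated N-terminus both anchors a kinase to a membrane and,
when bound in a C-lobe pocket, stabilizes the autoinhibited assembly. The
production inputs of such studies (microsecond all-atom trajectories,
hundreds of nanoseconds of umbrella windows) are not reproducible at desk
scale, so the package pairs every analysis algorithm with a *toy-physics
generator* whose ground truth is known analytically. This vignette documents
the models, the parameter choices, the numerical decisions, and the limits
of what the toys can and cannot validate.

## Units and constants

Energies are in kJ/mol, lengths in nm, times in ps, temperatures in K and
forces in pN throughout. The single Boltzmann constant lives in
`ak_constants$kB` = 0.0083145 kJ/mol/K (numerically the molar gas constant),
and forces convert at 1 kJ/mol/nm = 1.66054 pN. All stochastic stages draw
their seeds from one master seed via `derive_seed(master, counter)`
(= `(master + 7919 * counter) mod (2^31 - 1)`), so a whole multi-stage run
is reproducible from a single integer.

## The synthetic-data generator

### Overdamped Langevin dynamics

`simulate_langevin()` integrates the Euler–Maruyama discretisation of
overdamped (Brownian) dynamics,

$$ x_{t+\Delta t} = x_t + \frac{F(x_t)}{\gamma}\,\Delta t
   + \sqrt{\tfrac{2 k_B T \Delta t}{\gamma}}\,\xi, \qquad \xi \sim N(0,1), $$

whose stationary distribution is the Boltzmann distribution of the system's
potential. There is no inertia and no thermostat to tune: the integrator is
the simplest dynamics with the correct equilibrium, which is all the
downstream analyses require. Stability demands
$\Delta t < \gamma / k_\text{max}$ for the stiffest effective spring
constant $k_\text{max}$; the integrator warns when the bound is violated and
aborts, naming the step, if coordinates become non-finite. Note that at
practical time steps the discretisation inflates variances by
$O(k\,\Delta t/\gamma)$; the test suite therefore validates sampling at
small $k\,\Delta t/\gamma$ against quadrature oracles (including the $r^2$
Jacobian of radial marginals in 3-D).

Pair potentials are harmonic springs, radial double wells, or `"none"`
(a tracked non-interacting pair); an arbitrary external potential closes the
1-D toys. Alongside coordinates the integrator records, per stored frame,
the *signed scalar force* on every pair: the pair force projected on the
inter-particle axis, positive = repulsive. This convention is what
force-difference networks consume.

### The planted-pathway system

`make_condition_pair()` builds the synthetic analogue of a ligand-bound vs
ligand-free comparison: condition B equals condition A plus extra harmonic
couplings of stiffness `delta_k` along consecutive residues of a planted
path, resting at `rest_scale` (< 1) times the initial separation so they are
pre-tensioned. The base system matters. On a straight bead chain the planted
tension relaxes by bending and the planted pairs end up carrying almost no
mean force. `make_helix_chain()` therefore places beads on an ideal helix
(radius 0.23 nm, rise 0.15 nm, twist 100° per residue — the CA geometry
scale of an α-helix) and connects every pair within a 0.65 nm cutoff by a
spring resting at its initial distance: an elastic-network model with zero
initial strain. The stiff, multi-directional network resists the contraction
the planted springs ask for, so at equilibrium the planted pairs carry a
large mean tension while network pairs only reshuffle moderately — exactly
the signal a force-difference analysis is supposed to find. The pipeline
defaults (16 beads, `bond_k` 2000, `network_k` 1000, path 4–9–14,
`delta_k` 150, `rest_scale` 0.5) were chosen so the planted force difference
clears the documented 60 pN report threshold while the background stays
below it; the acceptance test asserts precision and recall ≥ 0.9 there.

The generator's scope: it produces ensembles with a known planted
force-transmission pathway, known Boltzmann statistics and known contact
occupancies. It does *not* model solvent, membranes, side chains, torsional
chemistry or any actual kinase conformational transition; conclusions about
real systems come from applying the same analyses to real trajectories, not
from these toys.

## Trajectory metrics

Superposition is least-squares rigid-body fitting by the Kabsch algorithm
(SVD with determinant correction), with separate *fit* and *analysis*
selections so one can fit on a stable core and measure RMSD of a moving
part. Near-collinear fit selections are rejected by name, since the rotation
is then ill-conditioned. RMSF is the root time-mean squared 3-D deviation
from the time-mean position; for isotropic Gaussian jitter of per-axis
standard deviation σ it converges to σ√3, which the tests assert. PCA
eigendecomposes the covariance of mean-centred coordinates; each eigenvector
is oriented so its largest-magnitude component is positive (making
projections platform-reproducible), rank deficiency (< 3 frames per
coordinate) and near-degenerate leading eigenvalues (gap < 5%) are flagged
with warnings because PC1 is then unstable.

Block averaging uses greedy tiling: a `block_length` section, a
`gap_length` skip, repeated from frame 1, trailing partial block discarded —
so a 2000-frame series with 400-frame blocks and 100-frame gaps gives 4
blocks, and a 1000-frame series gives 2. Independence of block means is
checked by the lag-1 autocorrelation against the $2/\sqrt{n}$ null bound.
Condition comparisons default to the two-sided Mann–Whitney U test on block
means — robust, and consistent with treating blocks as exchangeable units —
with a permutation test on the difference of means as an option. Boxplot
summaries follow the convention: centerline = mean, box = quartiles,
whiskers = 1.5× the interquartile range clamped to the data.

## Force-difference networks

`average_pair_forces()` reduces a pair-force series to the arithmetic time
mean of each residue pair's signed scalar force over all concatenated
replicate frames (particle pairs mapping to one residue pair are summed
first). `difference_network()` takes two such matrices over the same residue
universe, treats pairs missing from one condition as zero mean force, and
keeps pairs with |Δmean| at or above the threshold as edges weighted by
|Δ|. The default compares *signed* means — a pair whose force flips sign
between conditions is maximally interesting — and a `"magnitude"` mode
comparing |mean| values is available. Typical threshold sweeps run
20–100 pN. Connected components come from igraph and are reported in a
deterministic order (size descending, then smallest residue id);
`filter_components()` keeps components with at least 3 connected residues by
default (an `"edges"` unit is available), and `largest_component()` breaks
size ties by total edge weight then smallest id. The test suite checks all
component operations against an independent union-find oracle.

## Contacts and conservation

A residue pair is in contact in a frame when the minimum inter-particle
distance is ≤ 0.45 nm; pairs within 2 in sequence are excluded (the standard
native-contact convention). Occupancy is the fraction of frames in contact;
*native* pairs are those with occupancy ≥ 0.10 in the reference condition,
and a native pair is *conserved* when its occupancy stays ≥ 0.10 in the test
condition. The per-frame native fraction reports its dispersion as the mean
absolute deviation from the comparison condition's mean when one is given
(so the number answers "how far does this ensemble sit from the other
condition"), otherwise from its own mean.

## Enhanced sampling

### Well-tempered metadynamics

Every `pace` steps a Gaussian of width σ and height
$w_0 \exp(-V(s)/k_B \Delta T)$, $\Delta T = (\gamma_f - 1) T$, is deposited
at the current collective-variable value (bias factor $\gamma_f$ = 20,
$w_0$ = 1.2 kJ/mol, σ = 0.02, pace = 500 by default — production-style
settings for barriers of a few $k_BT$). The bias and its derivative are
maintained on a dense CV grid, updated per deposit and looked up by linear
interpolation per step, so the cost per step does not grow with the number
of Gaussians. The free-energy estimate is the standard well-tempered
estimator $F(s) = -\frac{\gamma_f}{\gamma_f - 1} V(s)$, shifted to zero
minimum. The acceptance test runs the 1-D double well and asserts the
recovered profile matches the analytic one within 1 $k_BT$ RMS (profiles
compared mean-aligned, since free energies are defined up to a constant).

### The helicity collective variable

`helicity_cv()` is a configurable analogue of helix-content CVs: for each
window of consecutive residues, the RMS deviation $d$ of intra-window
distances (default the (m, m+3) pairs) from supplied reference distances is
passed through the rational switch
$f(d) = \frac{1 - (d/r_0)^6}{1 - (d/r_0)^{12}} = \frac{1}{1 + (d/r_0)^6}$,
implemented in the right-hand form, which also supplies the analytic value
½ at the $d = r_0$ singularity of the quotient form. The CV is the sum over
windows and carries an analytic gradient (validated against finite
differences). Toy beads are not peptides, so reference distances are
parameters rather than hard-coded peptide geometry.

## Umbrella sampling and WHAM

`sample_umbrella_windows()` draws *independent* samples from each window's
biased Boltzmann density by inverse-transform sampling: the density is
tabulated on a fine grid (4001 points), accumulated with the trapezoid rule,
and inverted by linear interpolation. The trapezoid cumulative matters: a
plain `cumsum` of grid densities places each cell's mass at its right edge
and biases every sampled location by half a grid cell, which at stiff spring
constants is large enough to tilt the recovered profile systematically.
Independence is by construction — what is validated downstream is WHAM
correctness, not kinetics.

`build_histograms()` discards the leading 40% of each window (matching the
discard-the-first-80-of-200-ns convention of production umbrella runs) and
bins all windows on one shared half-open grid. `solve_wham()` iterates the
standard self-consistent equations in *linear* space with the bias
Boltzmann factors precomputed as a windows × bins matrix: factors for bins
far from a window underflow to zero and drop harmlessly out of the sums,
which is numerically benign here (unlike log-space arithmetic, which is
robust but orders of magnitude slower in R). Convergence is declared when
the largest change in any window free energy falls below $10^{-6} k_BT$;
non-convergence returns the best estimate with a warning and a flag.

`bootstrap_pmf()` implements a complete-histogram bootstrap over windows:
each iteration draws Dirichlet(1, …, 1) weights across windows — the
continuous analogue of resampling whole windows with replacement, which
avoids degenerate resamples that drop a window entirely — re-solves WHAM,
mean-aligns each bootstrap profile to the reference over shared occupied
bins, and reports the per-bin standard deviation. The acceptance test
asserts that 25 windows (k = 500 kJ/mol/nm², 10⁴ samples each) recover an
analytic double well within 0.5 kJ/mol RMS and that the ±2 sd band covers
the analytic curve at ≥ 90% of occupied bins. `extract_deltaG()` reads a
binding free energy as (mean plateau F) − (bound-region minimum), checks
plateau flatness, and combines the two regions' bootstrap errors in
quadrature.

## Binding thermodynamics

Free energies convert to dissociation constants by
$K_D = c^\circ e^{-\Delta G / RT}$ with $T$ = 300 K and the standard state
$c^\circ$ = 1 M — the conventions under which the package reproduces
reported kinase/membrane unbinding tables. Errors propagate to first order,
$\sigma_K = K_D \,\sigma_{\Delta G}/RT$; exact lognormal algebra gives a
relative bias of roughly $0.75\,(\sigma_{\Delta G}/RT)^2$, i.e. the linear
formula is good to 2% only for $\sigma_{\Delta G} \lesssim 0.16\,RT$, which
the tests document against a Monte-Carlo oracle. `competition_table()`
collates entries into a report with the antisymmetric pairwise
$\Delta\Delta G$ matrix and differences against a reference (default
`"Membrane"`).

Two caveats are carried explicitly rather than silently corrected. First,
published tables of this kind are rounded to one decimal, so round-trip
checks against printed $K_D$ values are asserted to the printed precision
(within 2% or half a unit of the last printed digit, whichever is larger).
Second, one reported row (ΔG = 47.3 kJ/mol alongside K_D ≈ 6 µM) is
inconsistent with its own conversion, which yields ~6 *nM*; the package
computes the conversion and leaves the discrepancy visible in the
competition table rather than overwriting either number.

## The pipeline and reproducibility

`run_pipeline()` executes synth → metrics → force network → contacts →
metadynamics → WHAM → competition report into one output directory, echoes
the fully resolved configuration (every applied default spelled out, unknown
keys rejected), and writes a `manifest.tsv` of md5 checksums. All
randomness derives from the master seed, so rerunning the same configuration
reproduces the manifest bit for bit; the acceptance test asserts this and
that the demo configuration completes well inside 10 minutes on one CPU.

## Example

```{r example}
library(allokit)

sys <- make_helix_chain(16, bond_k = 2000, network_k = 1000)
pair <- make_condition_pair(sys, planted_path = c(4, 9, 14), delta_k = 150,
                            n_steps = 15000, dt = 2e-4, n_replicates = 3,
                            seed = 1, stride = 10, rest_scale = 0.5)
g <- filter_components(
  difference_network(average_pair_forces(pair$forces_a),
                     average_pair_forces(pair$forces_b), threshold = 60),
  min_size = 3)
planted_edge_recovery(g, pair$planted_pairs)
```

## Limitations

* The generator validates *algorithms*, not biology: no solvent, membrane,
  side-chain or electrostatic physics, and chain lengths/step counts are
  desk-scale choices, not production values.
* Umbrella samples are independent draws; autocorrelation handling in WHAM
  (statistical inefficiencies per window) is not exercised and the
  bootstrap quantifies only window-to-window variation.
* The Euler–Maruyama integrator is first order; quantitative equilibrium
  checks require $k\,\Delta t/\gamma \ll 1$.
* Metadynamics error is assessed against 1-D analytic potentials only; CV
  quality on multidimensional systems is the user's responsibility.
* First-order $K_D$ error propagation degrades predictably for
  $\sigma_{\Delta G}$ above ~0.16 RT (see above).
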