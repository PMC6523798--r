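---
title: "Methods: threading statistics and shape of lasso-shaped polymers"
author: "lassopoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threading statistics and shape of lasso-shaped polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

A *lasso* is a closed polymer loop with one or two open tails attached at
a single vertex (the bridge).  When a tail passes through a surface
spanned on the loop the lasso is *non-trivial* (threaded); the biological
realisation is a protein backbone loop closed by a disulfide bridge and
pierced by a terminus.  The package studies two polymer models of this
geometry and connects them to protein structures.

## Phantom lassos

Phantom chains carry no interactions at all: the loop is a uniform random
*equilateral polygon* with `N` unit edges and the tail an equilateral
random walk of `t` unit steps started at the loop's first vertex.  The
polygon sampler works in fan-diagonal (action-angle) coordinates: the
`k-3` differences between neighbouring fan diagonals are uniform on
[-1, 1], sequences violating the triangle inequalities of the fan
triangles are rejected and redrawn, and valid sequences are completed
with uniform dihedral angles about each diagonal.  Rejection preserves
the uniform measure on the diagonal polytope, and the dihedral angles are
uniform on the fibres, so the polygons are uniform on equilateral polygon
space.  The tests cross-check the sampler against a brute-force
acceptance oracle and against an independent polygonal-fold Markov chain
sampler.

Everything about the phantom ensemble is scale-free, so unit edges are
used throughout; physical units enter only in the simulation module.

## Threading classification (minimal-surface method)

Threading is decided by spanning a near-minimal triangulated surface on
the loop and counting transversal crossings of the tail through the open
surface interior, each crossing signed by its orientation relative to the
consistent surface normal.

The surface construction is deliberately explicit and deterministic: a
triangle fan from the loop centroid, conforming edge-midpoint subdivision
until interior edges are at most one loop-edge length (with a few cheap
smoothing sweeps per subdivision level, so the refinement tracks the
contracting surface), then relaxation sweeps at full resolution.  A sweep
combines deterministic area-decreasing edge flips (which repair the badly
folded triangulations the centroid fan leaves on crumpled loops) with
over-relaxed Gauss-Seidel passes of cotangent-Laplacian vertex updates;
whenever a pass fails to lower the total area it falls back to plain
averaging and then to a backtracking step of exact area-gradient descent,
so the recorded area trace is monotonically non-increasing.  Relaxation
stops when the relative area change per sweep falls below `tol` (default
`1e-4`, with a cap of 200 sweeps).  The edge flips matter quantitatively:
without them the spanned surfaces on long crumpled loops stay ~2x above
minimal area and the piercing spectra are inflated enough to shift the
domination number; with them the trivial-versus-threaded split is stable
under further relaxation-depth changes.

Numerical choices: crossings are detected with the Möller–Trumbore
segment–triangle test; hits whose barycentric coordinates sit within
`1e-11` of a triangle edge or vertex, or within the same window of a tail
vertex, are resolved by re-running the count with the whole tail shifted
by a fixed tiny vector (`1e-10` of the mean edge length per retry) — a
deterministic symbolic perturbation.  Hits within `1e-9` mean-edge
lengths of the boundary curve or of the anchor vertex are excluded: the
tail leaves the surface exactly at its anchor and no rigid shift can make
that departure transversal.  Segments lying (near-)parallel in the
surface plane are not transversal and count zero; their entries and exits
are picked up by the neighbouring segments.  Raw transversal crossings
are reported without cancelling adjacent opposite-sign pairs, and
piercing directions are merged in the class label (`L0`, `L1`, `L2`, ...;
`LL_i,j` when both tails pierce).

## Threading statistics

Per `(N, t)` cell the package tabulates class counts with binomial
standard errors.  The trivial-lasso probability is fitted with a
double-exponential-plus-constant law in one length (the other held
fixed, or along the equal-length diagonal), and with a shared-asymptote
two-variable surface over the grid.  The two fitted rates typically
differ by an order of magnitude — a short-chain regime (sharp turns of a
phantom tail can pierce close to the boundary) on top of the long-chain
decay.  Fits are weighted (inverse variance, with zero SEs floored at
`1/(2n)`) and use multi-start initialisation over rate combinations
`alpha` in {0.3, 0.1, 0.03} x `beta` in {0.05, 0.005}; when the
nonlinear-least-squares wrapper refuses a rank-deficient Jacobian (a
fast rate that has died out on every point) the damped
Levenberg–Marquardt optimiser is driven directly.

The *domination number* `d(N, t)` is the largest piercing count `p` such
that non-trivial lassos with at least `p` piercings form a strict
majority of non-trivial lassos; ties (exactly 1/2) do not count.  The
asymptotic piercing spectrum is compared with a geometric law
`P(n) = p (1-p)^n` whose success parameter is the asymptotic
trivial-lasso probability; the geometric model is an idealisation and
empirically overestimates the plateau values, so it serves as a
stochastic upper envelope.

## Excluded-volume loop on a thread

The simulated loop is a coarse-grained C-alpha-like bead chain: harmonic
bonds `k = 20,000` kJ/(mol nm^2) about `r0 = 0.38` nm, repulsive
`A/r^12` excluded volume with `A = 0.16777216e-4` kJ nm^12/mol cut at
2 nm, no angular or attractive terms.  The thread is a straight immobile
line of beads at spacing `r0` along the x axis, made effectively
infinite by periodic images with period `0.38 * N_B` nm, where
`N_B = max(ceiling(N/2) + 5, 12)`.  Thread beads are `w` in {0, ..., 4}
times thicker than loop beads; the loop–thread repulsion coefficient is
scaled by `((1+w)/2)^12`, i.e. the contact radius is the additive mean
of the two bead radii.  `w = 0` means no thread at all.  The smallest
loop that fits around the thread is 3, 4, 6, 7, 7 beads for
`w = 0, ..., 4`.

Sampling is Metropolis Monte Carlo rather than molecular dynamics: all
observables are equilibrium ensemble averages, and a Metropolis chain
with the same potential samples the same Boltzmann ensemble without an
external MD engine.  The move set mixes single-bead displacements with
crankshaft rotations of a random sub-arc about the chord through its two
pivots; amplitudes are tuned to 30–50% acceptance during a pre-production
phase and then frozen.  Temperatures are the reduced (Gromacs) values
`T` in {10, 50, 100} — Kelvin with energies in kJ/mol — so the
acceptance weight is `exp(-dE / (kB T))` with
`kB = 0.0083144621` kJ/(mol K).  At `T = 100` the excluded-volume
contact diameter (where the pair energy reaches `kB T`) is about
0.4 nm, slightly above the bond length, which is what keeps strands from
passing through each other; treating `T` as a bare energy scale instead
would make the excluded volume invisible at these chain lengths, and the
measured shape asymptotes then drift to ideal-ring values.

For `w > 0` every proposal that would change the winding number of the
loop's (y, z) projection about the thread axis is rejected (the winding
sum is maintained incrementally per edge), so threading is conserved
exactly; every recorded frame is re-verified.  Pair energies are capped
at `1e6` so overlapping beads keep the Metropolis rule well defined.

Equilibration is set by the chord correlation function: the
autocorrelation of unit bond vectors over recorded frames, `C(0) = 1`;
the burn-in is three times the first lag at which `C` reaches 0.1.
Tightly threaded small loops rotate slowly about the thread, so their
`C` can take very long to reach 0.1; for those the sweep driver accepts
an explicit generous burn-in instead.  Shape averages use frames thinned
by the measured decorrelation lag, with standard errors from the
decorrelated sample.

## Shape descriptors and scaling laws

Per conformation: the radius of gyration `Rg` (centroid-centred
root-mean-square distance — written without centring in some compressed
notations, but only the centred reading makes the regular-polygon
distension equal one); the distension `D = (2 Rg / r0) sin(pi/N)`, 1 for
the maximally stretched symmetric loop; the gyration-tensor semi-axes
`a >= b >= c` (square roots of the eigenvalues — the principal radii of
gyration, so `Rg^2 = a^2 + b^2 + c^2`); the asphericity
`A = ((a-b)^2 + (b-c)^2 + (c-a)^2) / (2 (a+b+c)^2)` (0 sphere, 0.25
disk, 1 stick); and the prolateness
`P = (2a-b-c)(2b-c-a)(2c-a-b) / (2 (a^2+b^2+c^2-ab-bc-ca)^{3/2})`
(+1 degenerate prolate, -1 degenerate oblate, undefined for a sphere).
The semi-axis (rather than raw eigenvalue) convention is the one under
which the unthreaded asymptote lands at `A ~ 0.07`; the eigenvalue
convention is a documented non-goal.

Scaling laws, fitted over loops of at least 30 beads (below that
excluded-volume rigidity dominates): `<Rg> = c_r + a_r N^nu` with free
`nu` or `nu` frozen at 0.59 (frozen, the fit is linear and the `a_r`
ratios between thread thicknesses compare asymptotic sizes);
`<A> = A_inf + a_A N^mu`; `<P> = P_inf + a_P N^{-0.47}` with the
exponent frozen (concave traces; a free exponent does not converge on
feasible data, so the almost-inverse-square-root law is used as given).
In the asphericity fit the exponent is bounded to `mu <= -0.15`: over
any feasible length range a correction decaying more slowly is
numerically collinear with the constant `A_inf`, and the unbounded fit
can drift along that degenerate ridge.

## Protein bridge

Protein chains are reduced to their alpha-carbon trace (nm).  Disulfide
bridges come from SSBOND records, plus geometric detection of CYS SG–SG
pairs within 2.5 Å when sulfurs are present; other covalent bridge types
can be supplied explicitly.  For a bridge `(i, j)` the loop is the trace
between the bridged residues inclusive (`N = j - i + 1` residues, closed
by the bridge edge) and the tails are the terminal segments
(`t1 = i - 1`, `t2 = n - j`), so `N + t1 + t2` equals the chain length;
residue-per-bead is the mapping to the polymer models.  Classification
reuses the minimal-surface machinery with both tails tested.

The model threading probability of a tail is `1 - P(N, t)` from the
fitted phantom surface, clamped to [0, 1]; tails, and loops within a
chain, combine by inclusion–exclusion under independence.  The
probability of at least `n` piercings multiplies by `(1 - P_inf)^(n-1)`
per the geometric model.  Observed non-trivial loops whose model
probability falls below 0.2 are flagged as candidates: their threading
must be stabilised by something beyond chain entropy.

# What the synthetic data does and does not emulate

The generator reproduces the study conditions: uniform phantom loops and
tails on the `(N, t)` grid, and equilibrium excluded-volume loops on a
thread.  The packaged protein structures are *synthetic geometric
constructions* (planar circular loops with hand-routed tails at
Cα-like spacing) with known ground-truth classes; they exercise the
extraction/classification/scoring path, not protein realism — no
secondary structure, no folding bias in loop shapes, no redundancy
structure.  Passing the protein-bridge tests therefore demonstrates
correct geometry and bookkeeping, not biological conclusions; the
study's corpus-level protein statistics need an external structure set.

# Problem sizes and reproduction

The package's reproduction runs at desk scale, chosen so the complete
recomputation stays within tens of minutes on one core:

* the equal-length diagonal `N = t` in {10, 20, 30, 50, 70, 100, 150,
  200, 250, 300, 400, 500} with samples tapering from 1000 (short
  loops, where the fast decay rate is identified) to 300 (the largest
  loops, which dominate the runtime; the decay fit is inverse-variance
  weighted, so the extra error there is priced in), plus 1000 samples
  at `N = t = 250` for the domination number — the five-parameter decay
  law is statistically unidentified on a handful of long-loop cells
  alone, which is why the short cells are part of the fit;
* unthreaded sweep `N` in {30, 50, 70, 100, 150} at `T = 100` with
  9,000 production sweeps recorded every 2 sweeps, several thousand
  decorrelated frames per length;
* threaded comparison `w = 1`, `N` in {30, 50, 70, 100}, 5,000 sweeps.

At this scale the stochastic anchors carry visible sampling error; the
two fragile quantities are the asphericity asymptote (a three-parameter
fit on a shallow trend; see the exponent bound above) and the
prolateness asymptote, whose own reference values differ between text
(0.331) and table (0.300) sources — the desk-scale fit lands in that
band but with an uncertainty of a few hundredths.

The full-fidelity prefactor-ratio comparison (`a_r(w=1)/a_r(w=0)`, two
tight sweeps) is an hour-scale computation; the test suite runs a
reduced-statistics version with a correspondingly wider band.

# Known limitations

* The spanned surface is near-minimal, not a soap film: piercing counts
  on wildly crumpled loops can exceed those through the true minimal
  surface, though the trivial/non-trivial split is robust (see above).
* Piercing counts are raw transversal crossings; no smoothing of
  boundary-adjacent "shallow" piercings is attempted.
* The Monte Carlo uses local and crankshaft moves only; relaxation times
  grow quickly beyond a few hundred beads.
* Chains with several loops combine by independence; overlapping loops
  sharing residues violate that assumption.
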