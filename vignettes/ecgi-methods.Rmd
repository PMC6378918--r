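---
title: "Methods: simulating and inverting body-surface potentials for ischemia detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inverting body-surface potentials for ischemia detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design
decisions behind `ecgi`, in the spirit of a methods section: what is
computed, under which assumptions, and what the package's tests do and
do not establish about real data.

## The problem

Electrocardiographic imaging (ECGI) reconstructs the electric potential
on the outer heart surface from potentials measured on the torso. For a
homogeneous, source-free volume conductor between the two surfaces the
relation is linear at every time instant,

$$ \mathbf{k}_t = A\, \mathbf{r}_t, $$

where $\mathbf{r}_t$ holds the epicardial node potentials,
$\mathbf{k}_t$ the torso node potentials, and $A$ depends only on the
geometry of the two surfaces. The map is severely ill-posed: small
measurement errors are amplified without bound in a naive least-squares
inversion, so the package solves the Tikhonov-regularised problem

$$ \hat{R} = \arg\min_R \|A R - K\|_F^2 + \lambda^2 \|L R\|_F^2, $$

with $L$ the identity (order 0), a first-difference gradient operator
(order 1), or the surface Laplacian (order 2). The package's concern is
*quantitative*: how does lesion detectability degrade as the number of
recording electrodes, the noise level, and the lesion size and position
change, and which regularisation order holds up best.

Because no anatomical mesh pair ships with the package, all experiments
run on a synthetic heart–torso phantom with a prescribed ischemic
lesion, so that ground truth is known exactly and every score is
computable.

## Phantom geometry

`torso_ventricle_phantom()` builds two closed, outward-oriented
triangulated ellipsoids: a torso with semi-axes 170/120/300 mm and a
"ventricle" with semi-axes 45/40/70 mm, offset to the left-anterior
chest (convention: +x left, −y anterior, +z superior). These dimensions
were chosen once to mimic adult anatomy scale. Meshes are class-I
geodesic subdivisions of an icosahedron; the frequency parameter sets
the resolution, with the defaults (10 for the heart, 16 for the torso)
giving 1,002 heart nodes and 2,562 torso nodes — a deliberate
reduced-resolution working point at which the full factorial study runs
in minutes on one core while preserving the resolution ratio of
typical anatomical ECGI meshes (a few thousand nodes per surface).

Electrode layouts are regular grids in (azimuth, height) over the torso
surface, restricted to the central 80% of the torso's vertical extent
(the polar caps of an ellipsoid have degenerate azimuthal spacing) and
snapped to the nearest mesh nodes, with conflicts resolved
deterministically to the nearest unused node. This realises a "grid
like" electrode arrangement without claiming optimised placement.

## Synthetic electrophysiology

The epicardial source is phenomenological, not biophysical. Each node
carries an action-potential waveform parameterised by resting
potential, peak potential, APD at 90% repolarisation, and upstroke
duration:

* healthy: −85 mV resting, +20 mV peak, APD 274 ms, upstroke 2 ms;
* central ischemic: resting depolarised by +18 mV, APD shortened to
  150 ms, upstroke slowed three-fold, and the plateau amplitude
  depressed by 25 mV.

The waveform is a smooth piecewise construction — a squared-sine
upstroke, a plateau with 10% linear decay, and a logistic
repolarisation whose midpoint is placed so the 90% repolarisation
crossing falls *exactly* at the nominal APD (the tests recover APD to
within one timestep). The APD values and resting-potential shifts are
standard reported magnitudes for acute ischemia; the 25 mV plateau
depression is this package's own choice, needed so the lesion is
*depressed* relative to healthy tissue during the plateau (with resting
depolarisation alone the lesion would sit *above* its surroundings at
rest and indistinguishably during the plateau). The three-fold upstroke
slowing quantifies an otherwise qualitative "dramatic reduction".

The lesion is a transmural ball: Euclidean distance from a centre point
on the surface, with full remodelling inside 80% of the radius and a
linear taper to zero across the outer 20%. Geodesic distance was
considered and rejected: a ball intersecting the surface is the natural
model of a transmural lesion and behaves correctly on thick, curved
phantoms. At the half-weight point of the taper the interpolated
parameters are −76 mV resting / 212 ms APD, close to the usual border
zone values (−75 mV / 228 ms); exact linearity in all four parameters
was preferred over matching the border APD exactly.

Activation is a surface geodesic wavefront: times are shortest-path
distances along mesh edges from three fixed pacing sites (apex and two
opposed mid-wall points) divided by an effective conduction velocity of
0.8 mm/ms, completing activation of the default phantom in about
100 ms. This emulates a Purkinje-coordinated breakthrough pattern
without any reaction–diffusion computation. The default timeline is
400 ms at 1 ms resolution, covering one full beat.

Measurement noise is i.i.d. zero-mean Gaussian added to the
body-surface potentials before electrode sampling, calibrated to a
target SNR computed *globally* (signal power averaged over all nodes
and timesteps). A per-lead SNR convention was rejected as
under-specified; the global convention is the simplest reproducible
reading and calibrates to ±0.2 dB at study sizes.

What the generator does **not** emulate: endo/epi/mid cell-type
heterogeneity, a separate endocardial surface (the phantom is one
closed surface, so "inner wall" phenomena are out of reach), torso
inhomogeneities, correlated or electrode-specific noise, and 12-lead
ECG morphology. Tests passing on this phantom therefore demonstrate
the *pipeline's* correctness and the direction of its sensitivities,
not clinical performance.

## Forward model: boundary elements

`assemble_transfer()` discretises Green's representation theorem on the
two surfaces with vertex collocation: potentials are the nodal values
the rest of the pipeline works in. Double-layer (solid angle) integrals
use the exact van Oosterom–Strackee triangle solid angle, attributed
equally to the triangle's three vertices (a one-point rule for the
linearly varying density). Self-block diagonals are closed by
constant-potential consistency — each row of an on-surface solid-angle
block must total $2\pi$ — which simultaneously fixes the principal
value and makes constants map to constants *exactly*; the transfer
matrix's rows sum to 1 to machine precision, and no deflation of the
torso block is required in this formulation because the heart-surface
Dirichlet data anchor the potential level.

Single-layer integrals of $1/R$ need more care. A centroid rule split
equally per vertex has an *exact null space* whenever the triangulation
is 3-colorable — which class-I geodesic meshes are exactly when the
frequency is divisible by 3 (any colour weighting summing to zero on
every triangle is annihilated). The package therefore uses a 3-point
interior quadrature with points shifted towards each vertex and linear
shape-function weights (4/6, 1/6, 1/6), which is exact for linear
integrands and gives each vertex column a distinct weight; the
resulting heart single-layer block has a reciprocal condition number
around $10^{-2}$ at study resolutions, independent of frequency parity.
For the singular own-vertex triangles the integral of $1/R$ from a
vertex has the closed form $d\,[\operatorname{asinh}(s/d)]$ along the
opposite edge, of which the observation vertex's shape function takes
exactly one half (by the polar-coordinates identity
$\int N_P/R\,dS = \tfrac12\int 1/R\,dS$).

Verification is oracle-based: for a central dipole inside a bounded
insulated sphere the potential is
$V(r,\theta) \propto \cos\theta\,(1/r^2 + 2r/R^3)$, and the assembled
transfer applied to the analytic heart-surface values reproduces the
analytic torso values to well under 1% relative RMS at 1,280 faces per
surface, improving monotonically under refinement.

## Interpolation of the body-surface map

From a limited electrode set the full torso map is reconstructed as the
discrete harmonic extension: electrode nodes are fixed at their
measured values and all free nodes minimise the cotangent-Laplacian
Dirichlet energy, one sparse solve per timestep sharing a single
factorisation. This is the surface-mesh realisation of classical
laplacian ECG interpolation; it reproduces constants and planar linear
fields exactly and is exact at the electrodes by construction. Whether
to interpolate over the surface graph or in ambient 3-D space was an
open choice; the surface formulation was adopted because it respects
torso topology (no shortcuts through the body). Cotangent weights can
be negative on obtuse triangles, so the discrete maximum principle is
only guaranteed approximately; the test suite checks containment of
interpolated values within the electrode range inflated by 5%.

## Inverse solver numerics

`tikhonov_solve()` computes the minimiser through the augmented
least-squares system $[A; \lambda L]$ by QR — no normal equations, no
explicit inverse. For the study, however, the corner search evaluates
dozens of $\lambda$ values against the same $(A, L)$, so
`tikhonov_operator()` pre-diagonalises the symmetric pencil
$A^\top A\,v = \mu\,(A^\top A + L^\top L)\,v$ once (a GSVD-equivalent
filter-factor basis, computed via a Cholesky-whitened symmetric
eigenproblem). In that basis the solution, residual norm and seminorm
for *any* $\lambda$ and any right-hand side are diagonal re-weightings
costing $O(n)$ per column. The two routes are cross-checked against
each other and against SVD/GSVD filter-factor oracles in the tests
(agreement ~$10^{-13}$); the pencil route does square the conditioning,
which is immaterial at $\lambda > 0$ working precision but is why the
augmented route remains the reference implementation.

The regularisation parameter is chosen at the corner of the L-curve
$(\log\|AR-K\|, \log\|LR\|)$, located by a golden-section iteration on
$\log\lambda$ driven by 4-point Menger curvature, then refined as the
maximum-curvature point over the whole evaluated trace (near-duplicate
$\lambda$s merged; ties resolved to the smallest $\lambda$, preferring
fidelity over smoothing). The search bracket spans the generalised
singular spectrum $\gamma_i = \sqrt{\mu_i/(1-\mu_i)}$, clipped below at
$10^{-12}\gamma_{\max}$ — with the crucial exclusion of directions in
$\operatorname{null}(L)$ ($\mu \approx 1$): for orders 1 and 2 the
constant vector would otherwise inject an effectively infinite
$\gamma$ and stretch the bracket into a spurious far corner. Degenerate
requests fail loudly: $\lambda = 0$ on a rank-deficient system raises
an error advising $\lambda > 0$.

In global mode all timesteps are stacked and a single $\lambda$ is
selected from Frobenius norms; in per-timestep mode the corner search
runs per column. On the default phantom the two differ in mean spatial
RDMS by about 0.01 — consistent with the expectation that per-timestep
optimisation buys little — and global mode is the default.

## Scoring

Reconstruction error is the relative difference measure star: the
Euclidean distance between unit-normalised pattern vectors, computed
spatially (one value per timestep, summarised as mean ± sd) or
temporally. The conventional definition includes the square root and is
bounded by 2; `take_root = FALSE` exposes the squared variant for
comparison with sources that omit the root.

Detection thresholds follow
$w_{\text{thr}} = \bar{w} - Q(\bar{w} - w_{\min})$ at a single
detection timestep; a mesh element is ischemic iff the mean of its
three vertex potentials lies *strictly* below the threshold (ties are
healthy — an arbitrary but fixed rule). The element rule and the
node-to-element averaging are this package's choices; node potentials
are the stored quantity. Scores are areas: CI and IH partition the real
lesion area exactly (CI + IH = 100), and II — detected area outside
the lesion — is normalised by the real lesion area by default and may
exceed 100% under gross over-detection. A `reference_area` argument
supports normalising different lesion sizes against a common reference
area when comparing across radii.

The default detection timestep maximises the epicardial contrast
$\bar{w} - w_{\min}$ *within the plateau window* — after the last node
has activated and before 260 ms. The restriction matters: during the
activation wavefront the contrast between depolarised and resting
tissue (~100 mV) dwarfs the ischemic plateau depression (~20 mV), so an
unrestricted argmax would land mid-QRS and detect the wavefront, not
the lesion. Within the plateau the ischemic region is the dominant
minimum, matching the usual practice of detecting at the timestep of
peak lesion contrast. The timestep is user-overridable.

## The study harness

`run_study()` executes a full factorial over its configuration lists —
order × leads × location × radius × SNR — with every Q factor scored on
every reconstruction (thresholding is post-hoc, so Q costs nothing) and
one noise realisation per seed (noiseless cells are deterministic and
run once). Each cell runs the entire pipeline from the action-potential
source to the detection report; per-cell failures are recorded in an
`error` column without aborting the sweep, and the pair (configuration,
seeds) fully determines every number.

`run_default_study()` mirrors a one-factor-at-a-time design around the
primary condition (27 mm lesion on the right-ventricle lateral wall):
a main sweep of all three orders across 32–1,024 leads, a noise sweep
(order 2, 512 leads, anterior lesion, 10–40 dB plus noiseless), a
lesion-size sweep (20/14/8 mm) and a location sweep over the remaining
sites. The factor sweeps run at 30 dB SNR — the midpoint of the studied
10–40 dB range — with five fixed seeds, so that every trend summary is
a median over seeds; a fully noiseless main sweep would make the seeds
inert and the medians degenerate. The five default seeds are recorded
in the configuration defaults.

`trend_checks()` evaluates the qualitative findings the harness is
expected to reproduce — error falling with lead count per order,
order 2 at or below order 0 everywhere, over-detection (II) shrinking
with ≥128 leads (as a pooled lead-count effect across orders, with
per-order detail), noise degrading CI, II inflating as the lesion
shrinks, and detected area shrinking with Q — each as pass/fail/skip
with the levels it used. One caveat surfaced during development and is
deliberately left visible rather than patched: under *noiseless*
conditions the order-0 L-curve corner at 128 leads under-smooths enough
to break RDMS monotonicity at a single step (the corner matches a
dense-grid curvature oracle there, so it is a property of the selection
rule, not a solver defect); at 20–30 dB the medians are monotone for
all orders.

## Known limitations

* One closed epicardial surface: endocardial ("inner wall") lesion
  effects and septal lesions proper cannot be represented; the septal
  proxy is a medial posterior site and claims about septal detection
  are not asserted.
* The phantom's absolute CI/IH/II percentages are geometry-specific;
  only orderings and monotone trends are asserted, never absolute
  scores from other geometries.
* The L-curve corner is a heuristic; on noiseless, very smooth data its
  under-smoothing bias is visible (above). Discrepancy-principle or
  GCV selection are natural extensions.
* Homogeneous unit conductivity; absolute conductivity cancels in the
  potential-to-potential transfer, but inhomogeneity effects are out of
  scope.
* The AP template is phenomenological; no ionic mechanism, no
  rate-dependence, no transmural repolarisation gradient.
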