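---
title: "Self-organization of 3D grid cells: model, analysis and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organization of 3D grid cells: model, analysis and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridcell3d)
```

Grid cells in the medial entorhinal cortex (mEC) fire on a periodic lattice
of locations. In two dimensions the lattice is hexagonal; for an animal that
navigates a volume — a bat, say — the natural question is which
three-dimensional arrangement of firing fields emerges, how fast, and
whether it settles on one of the two regular optimal sphere packings:
face-centered cubic (FCC, ABC layer stacking) or hexagonal close packed
(HCP, ABA stacking). `gridcell3d` implements a self-organizing network
model of this process, the companion variational (cost-function) model of
its asymptotic states, and the measurement machinery needed to score 3D
periodic order.

# The network model

A virtual animal explores a cube of side $L$ at constant speed, its heading
re-drawn each time step by a Gaussian turn of width $\sigma_h = 0.15$ rad.
With the physical interpretation $\Delta t = 10$ ms, $v = 1$ m/s,
$L = 2.5$ m, one step covers $v\Delta t/L = 0.004$ box units; this single
combination is what the dynamics sees, and it sets the spatial scale of the
emerging grids.

An input layer of place-like units fires as Gaussian bumps
$r_j = \exp(-\|x - x_j^0\|^2 / 2\sigma_p^2)$ ($\sigma_p = 0.05\,L$) on a
cell-centered cubic lattice of centers. Each of the $N_\mathrm{mEC}$ output
units receives

$$h_i = f_{\theta_i}(\omega)\Big(\sum_j W_{ij} r_j +
  \rho \sum_k W^\mathrm{coll}_{ik} \Psi_k^{t-\tau}\Big),$$

a feed-forward drive plus a delayed collateral drive ($\rho = 0.1$,
$\tau = 25$ steps), multiplicatively gated by head-direction tuning
$f_\theta(\omega) = c + (1-c)\exp[\nu(\cos\gamma - 1)]$ with $c = 0.2$,
$\nu = 0.8$. The printed tuning law uses a one-dimensional angle
difference; since preferred directions cover the full solid angle, the only
rotation-invariant reading is $\cos\gamma = \theta\cdot\omega$ for unit
3-vectors, which is what we implement.

Firing rates pass through adaptation,
$\alpha' = \alpha + b_1(h - \beta - \alpha)$,
$\beta' = \beta + b_2(h - \beta)$ with $b_1 = 0.1$, $b_2 = b_1/3$, and a
threshold nonlinearity $\Psi = \tfrac{2}{\pi}\arctan[g(\alpha-\mu)]$ for
$\alpha > \mu$. Gain and threshold are iterated within each time step
($\mu' = \mu + b_3(a - a_0)$, $g' = g + b_4 g (s - s_0)$) until mean
activity and sparsity sit within 10% of $a_0 = 0.1$ and $s_0 = 0.3$; we cap
the iteration at 100 steps (the model statement gives no cap) and, on the
rare failures, keep the iterate with the smallest relative band violation
and count it. A cold start needs a few hundred iterations to find the
band (and heavy-tailed inputs can stall the fixed-rate iteration
altogether), but within a run the control is warm-started from the
previous step and the cap is essentially never binding — non-convergence
counts are a few tens per two million steps. Adaptation makes sustained firing expensive: fields form
where a unit both receives strong input and has recovered from its own
recent activity, and the Hebbian rule
$\tilde W_{ij} = W_{ij} + \epsilon(\Psi_i r_j - \bar\Psi_i \bar r_j)$
($\epsilon = 0.002$, running means with $\eta = 0.05$) followed by row-wise
L2 normalization slowly fixes these coincidences into the weights. Learning
applies from the first step; weights start as uniform random values,
row-normalized, and may go negative under the mean-subtracted update
(nothing in the model clips them).

Collateral weights are built once from auxiliary fields and shared
preferred directions and are not learned. Two printed details required a
decision: the offset in the pairwise distance is applied as $l\,\hat\omega_{ik}$
(displacement along the connecting direction; the printed component-wise
$l\cos(\omega_{ik})$ is not dimensionally meaningful for a 3D direction),
and the $[\cdot]^+$ rectification is the positive part rather than a 0/1
step, which would discard the Gaussian magnitude the formula constructs.
The diagonal is forced to zero.

## Simulation sizes

The package's default experiment is a reduced-scale run — 27 output units,
$8^3$ place inputs, a few million steps — which self-organizes the same way
as the full-scale network (125 units, $12^3$ inputs, tens of millions of
steps) at roughly 1/40 the cost. All headline numbers in the README were
produced at this reduced scale: 4 million steps take about 1.5 minutes. Test
runs use 20 thousand steps for mechanics and one shared 4-million-step run
for the self-organization properties. With $8^3$ inputs the
input-homogeneity margin $\sigma_p \cdot 8 = 0.4\,L$ is slightly below the
comfortable $0.5\,L$, visible as mild extra roughness in early maps but not
in the converged spacing.

Rate maps are occupancy-normalized sums of $\Psi$ on a $25^3$ voxel grid
(a choice; the analysis is insensitive between $20^3$ and $32^3$ at this
scale), accumulated within each window between checkpoints so a checkpoint
reflects the current, not cumulative, state of the map.

# The variational model

Asymptotic states are characterized by minimizing
$H = H_K + \gamma H_A$: a kinetic (smoothness) term
$\langle|\nabla\psi|^2\rangle$ plus an adaptation penalty
$\langle\psi (K * \psi)\rangle$ with a difference-of-Gaussians kernel
$K$ whose transform is
$\tilde K(k) = e^{-(k v\tau_L)^2/2} - \rho\, e^{-(k v\tau_S)^2/2}$
($v\tau_L = 1$, $v\tau_S = 1/3$, $\rho = 0.03$ by default; lengths in units
of the slow adaptation length). Candidate states are plane-wave
constructions: for FCC, $1 + \tfrac14\sum_{i=1}^4 \cos(k_i \cdot r)$ with
four tetrahedral wave vectors of squared magnitude
$\tfrac32(2\pi/a)^2$; for HCP, a pair of phase-shifted hexagonal patterns
modulated in counter-phase along the stacking axis, with free ratio
$k_z/k_{xy}$ (perfect ABA packing at $3/\sqrt{32} \approx 0.53$). Both are
raised to a power $n$ (sharper fields) and normalized to unit mean. The HCP
phase shifts are chosen geometrically so the peaks sit exactly on an ABA
close-packed lattice: in-plane shift $(a/\sqrt3, 0)$ and a half-period
shift along $z$; the printed shift values do not carry recoverable units
and a literal reading does not place the B layer on lattice sites.

Because every $\psi_n$ is a finite cosine sum on a periodic cell, an FFT of
the sampled field recovers its Fourier amplitudes to machine precision, and

$$H_K = \sum_q |c_q|^2 |q|^2, \qquad
  H_A = \sum_{q \neq 0} |c_q|^2 \tilde K(|q|).$$

The constant mode contributes $\gamma(1-\rho)$ to $H_A$ regardless of
spacing or stacking ratio; we report it separately and exclude it from
$H$, so the uniform state has $H = 0$ and "the trivial solution is
favored" is simply $H^* > 0$. The normalization constants $p_n$ are
computed numerically as unit-cell means, never symbolically. An independent
real-space oracle (fourth-order finite differences for $H_K$; circular
convolution with the kernel periodized by summed images for $H_A$) agrees
with the mode expansion to better than $10^{-3}$ relative and is part of
the test suite.

## The $n = 2$ FCC closed form: 73, not 71

Expanding the normalized $\psi_2^\mathrm{FCC}$ exposes an algebra subtlety:
the four tetrahedral wave vectors sum to zero, so the six pairwise-sum
cosines $\cos((k_i + k_j)\cdot r)$ coincide in three $\pm$ pairs and merge
*coherently* into three modes of doubled amplitude. Carrying this through,
the kinetic term is $\tfrac{73}{162} k^2$ — not the published
$\tfrac{71}{162} k^2$, which corresponds to treating the six sum modes as
independent (the companion adaptation expression shows the same miscount:
its $6\tilde K(2k/\sqrt3)$ should be $12\tilde K(2k/\sqrt3)$). Both of our
independent computational routes give 73/162 to nine digits, and the
discrepancy in the adaptation term equals exactly
$(12-6)/648 \cdot \tilde K(2k/\sqrt3)$. The package reports the computed
value; the corresponding acceptance expectation against the printed 71 is
knowingly left failing rather than adjusted.

## Optimization and the cost landscape

`optimize_lattice()` minimizes $H$ over the spacing (FCC) or jointly over
spacing and $k_z/k_{xy}$ (HCP) by a deterministic log-grid scan plus local
refinement; the mode table depends only on (kind, $n$), so each evaluation
is a few hundred kernel evaluations. Two structural facts worth noting,
because naive intuition gets them backwards: since $\psi$ scales with $a$
at fixed unit mean, the fields never "escape" the kernel — as
$a \to \infty$ the kernel acts as a delta and $H_A$ *increases* toward its
$\langle\psi^2\rangle$ limit while $H_K \propto a^{-2}$ falls, and the
finite optimal spacing comes from that balance. And the FCC/HCP
"close equivalence" of optimal costs is a statement about the envelopes
over powers $n$: it holds (we measure 1–5%) on the $\gamma$ window
bracketing the trivial-solution transition where the optimal power is
interior to the modeled set ($n \le 8$); at larger $\gamma$ ever-sharper
fields are favored and any finite power set truncates the envelope, where
the comparison is no longer meaningful.

The stacking-ratio asymptotics reproduce cleanly: $n = 1$ prefers
$k_z/k_{xy} = 0$ (columnar activity) for every $\gamma$, while higher
powers approach $3/\sqrt{32}$ from around (0.49 at $n=3$ to 0.55 at
$n=6$, $\gamma = 10^4$).

## Relaxation fits

`fit_cost_timecourse()` jointly fits the two empirical cost series with
double exponentials sharing the short time constant
($H_K = A e^{-t/\tau_S} + B e^{-t/\tau_L} + K$,
$H_A = C e^{-t/\tau_S} - D e^{-t/\tau_M} + E$), by bounded
Levenberg–Marquardt with per-series variance weighting; on synthetic curves
with 1% noise all nine parameters recover within 10%. The ansatz weight
$\gamma^\ast$ is the largest $\gamma$ keeping $H_K + \gamma H_A$
non-increasing, computed analytically from the fitted derivatives
($+\infty$ when the adaptation curve never rises, e.g. constant series).

# Measuring 3D order

**Autocorrelograms.** Masked Pearson correlation at every voxel
displacement, with all pairwise sums obtained by FFT cross-correlation;
displacements with less than 5% voxel overlap are masked. Grid spacing $d$
is the first secondary maximum of the spherically averaged profile,
parabolic-refined.

**Best plane and slice scores.** Central slices are scanned over a 5°
hemisphere grid (1° refinement) with trilinear interpolation; each slice is
sampled on a polar patch spanning the first shell (radii $0.7d$–$1.3d$) and
scored by its Pearson correlation with itself rotated by 60° — the
hexagonal template with $\pi/3$ periodicity. Two earlier designs were
rejected on fixtures: a pure sixth-angular-harmonic score rates a plane
containing a single $\pm$ peak pair ~0.5, and a plain patch correlation is
dominated by the rotation-invariant radial profile, so even isotropic
blobs scored ~0.6. For plane *detection* (the best plane and the plane
count) each ring is therefore centered before correlating, leaving only
angular structure; for the $\zeta$ cone-triplet scores below the full
planar values are kept, since their ratio removes the baseline shared by
the two triplets and centered scoring would leave most imperfect simulated
maps without any scoreable triplet. The best plane's normal is the
layer-stacking axis; its folded ring-profile peak gives the in-plane
hexagon axis. Structureless maps are already rejected one step earlier: a
radial profile whose secondary peak has essentially no prominence yields
no spacing, and all plane scores collapse to 0.

**FCC/HCP scores.** $\zeta_{2-4}$ sums the slice scores of the best triplet
of planes tilted ~72° from the best plane at ~120° azimuthal spacing
(present in both packings, mutual plane angles ≈ 69–71°, inside our ±8°
tolerance — note the geometric FCC inter-plane angle is
$\arccos(1/3) = 70.5°$, absorbed by the same tolerance); $\zeta_{5-7}$
scores the azimuth-interleaved triplet (≈ 56° from the first members) that
only HCP populates, and $\chi_\mathrm{FCC} = (\zeta_{2-4} -
\zeta_{5-7})/\zeta_{2-4}$, reported as missing when
$\zeta_{2-4} < 0.75$ — below one quarter of its range the unit expresses
no credible hexagonal triplet and the ratio's denominator makes it
unbounded. Layer periodicity is probed directly:
$\lambda_z = \sqrt{2/3}\,d$ is the interlayer distance of a close packing
with spacing $d$, and $\chi_\mathrm{HCP}$ is the strongest correlation
within ±15% of the two-layer displacement $2\lambda_z$ along the stacking
axis (ABA repeats there; ABC does not until three layers). Defining
$\lambda_z$ instead as the first correlation peak along the normal would
make the probe tautologically high for both packings, since that first
peak already sits at each packing's own repeat distance.

**Local (triplet) gridness.** Spikes are drawn from the rate map in
proportion to voxel rate and jittered within voxels. The pairwise-distance
histogram's second peak defines the grid distance; spike pairs inside the
surrounding-trough (fallback $[0.5d, 1.4d]$) window are neighbors, and all
mutual-neighbor triplets pool their internal angles. Dense patterns
generate combinatorially many triangles, so neighbor edges are capped at
4000 and each edge contributes at most 8 completing vertices — an unbiased
subsample of the triangle population. The angle distribution is divided by
that of structure-free control spikes; the characteristic angle is the
median of the above-chance region and the significance its maximal ratio.

**Calibration on ideal fixtures.** `make_fixture()` voxelizes the analytic
states. At the default sharpening $n = 12$ and $48^3$ resolution the
fixtures reproduce every fingerprint of the ideal packings: FCC shows 12
first-shell peaks in 6 symmetric pairs and exactly 4 hexagonal central
planes; HCP shows 18 peaks in 9 pairs (6 full, 12 half) and 7 planes; the
$\chi$ scores reach 1.09/0.11 (FCC fixture/HCP fixture) and $-0.05$/0.99.
Lower powers are unsuitable as fixtures: at $n \le 3$ the plane-wave
interference suppresses half of the HCP half-peak family below detection
threshold, and the weaker pyramidal plane triplet only separates from
background slices (scores 0.81–0.83 vs 0.66) from about $n = 10$. The
plane-count threshold (0.75) and merge radius (25°) were calibrated on
these fixtures and then frozen. What fixture tests do *not* establish is
behavior on noisy, partially sampled experimental maps; the simulated maps
(finite occupancy, control jitter in $a$ and $s$) are the closest proxy the
package exercises.

**Empirical cost.** On voxel maps, $H_K$ uses fourth-order central
differences (second-order within two voxels of the faces) and $H_A$
circular convolution with the kernel periodized on the box; unvisited
voxels are imputed from their smoothed neighborhood. Here the constant
background is kept (a constant map $c$ gives $H_A = c^2(1-\rho)$), unlike
the analytic-route convention, which drops the phase-independent DC term —
subtract $\bar\psi^2(1-\rho)$ when comparing the two. The network-implied
kernel lengths are $v\tau_L = v_\mathrm{step}/b_2 = 0.12\,L$ and
$v\tau_S = v_\mathrm{step}/b_1 = 0.04\,L$ (`kernel_from_config()`); the
model itself never fixes $\gamma$, only the monotonicity ansatz above.

# What the reduced-scale experiments show

At 27 units / $8^3$ inputs / 4 million steps (seeds as in
`scripts/acceptance.R`): activity and sparsity hold their bands at every
checkpoint; every unit's map is multi-peaked and smoothens monotonically
(mean neighbor-voxel correlation ≈ 0.46 → 0.82); pooled triplet angles
center on 60° from the earliest checkpoint; the population spacing rises
and tightens (≈ 0.47 ± 0.09 at 0.4 M steps to ≈ 0.51 ± 0.06 at 4 M)
toward the full-scale value 0.55 L, and heterogeneous per-unit adaptation
rates ($b_1 \sim U(0.85, 1.2) \times 0.1$) end near 0.52 as well; the
best-plane hexagonality climbs (≈ 0.38 → 0.47 on the conservative
centered score) without approaching the full-scale asymptote; and the
$\chi_\mathrm{FCC}$ population spreads across the FCC–HCP continuum
(mean ≈ 0.4–0.5, spread ≈ 0.3) — the signature result that individual
units commit to different, intermediate stacking arrangements rather than
converging on either pure packing. Two honest caveats at this scale.
First, removing the collateral connections — which at full scale is
reported to leave the spacing timecourse untouched — shifts the reduced
population's mean spacing by ~15% (0.51 → 0.43): with 27 units the
recurrent drive is a proportionally larger part of each unit's input, so
the desk-scale check of that claim is directional (the variant stays
within the standard population's spread), not an equality. Second,
population alignment ($\beta$, $\omega$ angles) stays at chance,
consistent with alignment being the slowest process in the hierarchy;
demonstrating it requires full-scale, multi-10M-step runs outside the
test budget.

# Known limitations

- The trajectory model is a constant-speed correlated walk with specular
  wall reflection; real bat flight has speed modulation, rests and wall
  avoidance, none of which the model needs but all of which shape real
  occupancy.
- Collateral weights are constructed, not learned; their self-organization
  is explicitly out of scope.
- Plane scoring assumes isotropic voxels; stretched-box runs support
  spacing and cost analyses but not best-plane scores.
- $\chi_\mathrm{HCP}$ on imperfect maps is conservative: it requires
  coherent two-layer stacking along the measured normal, and simulated
  units at reduced scale rarely reach it even when locally hexagonal.
- The half-peak asymmetry of the plane-wave HCP autocorrelogram (two
  families of half peaks with unequal heights) is a property of the finite
  cosine construction, not of an ideal HCP point lattice; it fades as the
  sharpening power grows but is still visible at $n = 12$.
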