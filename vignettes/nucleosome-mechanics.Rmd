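---
title: "Measuring nucleosome mechanics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nucleosome mechanics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoflex)
library(ggplot2)
```

nucleoflex estimates how stiff a nucleosome-scale particle is, from two very
different kinds of raw data: equilibrium molecular-dynamics (MD) trajectories
and AFM nanoindentation force curves. Both routes end in the same quantity —
an absolute Young's modulus on the MPa scale typical of nucleoprotein
assemblies — which is what makes a simulation-to-experiment comparison
possible. This vignette explains the models behind each estimator, the
parameters that matter, and exactly what the synthetic-data generators do and
do not validate.

## 1. The minimal-cylinder / equipartition estimator

### Model

A nucleosome at thermal equilibrium vibrates. If we model it as a homogeneous
elastic cylinder (height $h$, radius $r$) vibrating in a thermal bath, each
shear-free deformation mode — axial compression/extension and radial
dilation — is a quadratic degree of freedom and, by equipartition, stores
$\tfrac{1}{2}k_BT$ of energy on average. The strain energy of a homogeneous
deformation at strain $\varepsilon$ is $\tfrac{1}{2}E\varepsilon^2 V$ with
$V = \pi r^2 h$, so each mode gives an independent modulus estimate

$$E_m = \frac{k_B T}{V\,\varepsilon_m^2},\qquad
  \varepsilon_h = \frac{\Delta h}{h_\mathrm{avg}},\quad
  \varepsilon_r = \frac{\Delta r}{r_\mathrm{avg}},$$

and the headline $E$ is the arithmetic mean of the modes with non-zero
strain. With $k_BT$ in pN nm and lengths in nm, $E$ lands directly in
pN/nm² = MPa. The exact bookkeeping — two modes, $\tfrac{1}{2}k_BT$ per mode,
strain energy $\tfrac12 E\varepsilon^2V$, arithmetic mean — is the simplest
shear-free homogeneous-cylinder model; alternatives (e.g. coupling the modes
through a Poisson ratio) would change the headline value by factors of order
one, which is why the per-mode values are always reported alongside.

### From trajectory to $h$, $r$, $\Delta h$, $\Delta r$

1. **Orientation.** Every frame is centred on its mass-weighted centre of
   mass and rotated onto the principal axes of its inertia tensor, with the
   axis of the largest principal moment mapped to $z$. For a flat disc-like
   particle this puts the broadest plane on $x$–$y$, so height is a
   $z$-extent. Eigenvector signs follow the largest-magnitude-component
   convention so axes cannot flip between frames that differ only by thermal
   noise; the rotation is always proper.
2. **Windowed RMSF.** The trajectory is split into `n_windows` contiguous
   near-equal blocks (default 800, matching microsecond-scale sampling).
   RMSF is a time average, so each window needs at least 2 frames. Within a
   window each atom's mean position and RMSF are computed from the oriented
   frames.
3. **Minimal cylinder with stiff-face stopping.** A nucleosome's disordered
   tails should not set its mechanical envelope. Scanning inward from each
   extreme $z$, the face plane stops at the $z$-coordinate of the
   `n_exclude`-th atom (default 10) whose RMSF is below the stiffness
   threshold; floppy atoms never stop the plane, and a side with fewer than
   `n_exclude` stiff atoms keeps its extreme $z$. The radius is the largest
   in-plane distance among atoms between the faces. The default threshold is
   the median RMSF of the window — parameter-free, but exposed as an
   absolute value in nm because results can depend on it.
4. **Statistics and modulus.** One $(h, r)$ pair per window;
   $h_\mathrm{avg}, r_\mathrm{avg}$ are means and $\Delta h, \Delta r$
   population SDs across windows. The SD of $E$ comes from re-running the
   whole pipeline on 3 contiguous equal subsections of the analysed frames.

Window-mean coordinates (not per-frame extremes) define each window's
cylinder: RMSF is only meaningful per window, so the window is the natural
granularity of the fluctuation analysis. The consequence — deformations
faster than a window are averaged away — is deliberate and is mirrored by
the synthetic generator below.

Equilibration trimming is a user decision (`frames =` argument), not
automatic: how much of a production run to discard is a judgement about the
simulation, not about this estimator.

### What the synthetic trajectories emulate

`gen_cylinder_trajectory()` inverts the estimator's own model: it builds a
cylinder whose height and radius breathe with Gaussian strain
$\sigma = \sqrt{k_BT/(E_\mathrm{true}\,\pi r_0^2 h_0)}$, decorated with
surface particles that ride the breathing rigidly plus small isotropic
jitter (so they are stiff in the RMSF sense), floppy tail particles beyond
the faces with 5-fold jitter (exercising the 10-exclusion rule), and two
heavy equatorial anchors that break the transverse inertia degeneracy of an
ideal cylinder so the per-frame principal axes are numerically stable. All
decorations are placed as antipodal pairs, keeping the rest layout's centre
of mass on the cylinder axis and its inertia cross-moments zero.

The breathing strain is redrawn every `frames_per_deformation` frames
(default 10) and held constant in between, while jitter is redrawn every
frame. This encodes the timescale separation the windowed-RMSF method
presumes: collective breathing is slow compared with atomic jitter, and a
window samples a single deformation state. At the default settings (8000
frames, 800 windows) windows and deformation blocks coincide. Defaults
$h_0 = r_0 = 5.5$ nm and $E \in 1{-}50$ MPa keep the numerics at the scale
of real nucleosome systems.

Recovery of $E_\mathrm{true}$ on these fixtures validates the estimator's
internal consistency — orientation, window statistics, face stopping,
equipartition conversion — under its own model assumptions. It does *not*
validate the elastic-cylinder idealisation against a real nucleosome:
anisotropy, inhomogeneity, DNA unwrapping events and mode coupling are all
outside the generator, so agreement with experiment must be judged
separately.

```{r recovery}
traj <- gen_cylinder_trajectory(E_true = 10, n_frames = 1200, seed = 7)
fit <- estimate_elasticity(traj, n_windows = 120, n_subsections = 3)
glance(fit)
```

The analysis sizes used throughout the package's own validation (1200–8000
frames, 120–800 windows) were chosen so each window holds 10 frames, the
granularity at which the window/deformation alignment above is exact.

## 2. DNA gyre gaping and sliding

Three phosphate backbone atoms — by convention positions −33, −43 and +38
numbered 5′→3′ relative to the pseudodyad, as marked in FRET experiments —
triangulate the two DNA gyres. Every frame is least-squares superposed onto
the oriented reference frame using histone-core C-alpha atoms only, so
neither whole-particle rigid motion nor the measured DNA motion itself can
contaminate the reference. Displacement of the +38 vertex from its reference
position decomposes into **gaping** ($\Delta y$: the component along the
superhelical $z$ axis — gyres separating) and **sliding** ($\Delta x$: the
in-plane component along the local DNA tangent, estimated from the reference
−33→−43 direction). The triad labels map "−33 and −34" style statements onto
the only three defined atoms; the third vertex is always the moving one.

"Skew" has no standard numerical definition for this triangle; the package
records the mean absolute deviation of the three vertex angles from the
reference triangle (degrees) and exposes the extreme-skew frames, which is
one documented interpretation, not the only possible one. Box-plot summaries
use mean, median, linear-interpolation quartiles (`quantile type 7`) and
whiskers at the extrema, so they are reproducible bit for bit.

## 3. PCA free-energy landscapes and RMSF profiles

Frames are superposed onto their mean structure (two iterations, Kabsch),
and the covariance of the concatenated 3N representative coordinates
(protein C-alpha + nucleic P by default) is diagonalised. Histogramming the
first two principal components and Boltzmann-inverting the occupancy gives a
free-energy surface $F_i = -\ln(N_i/N_\mathrm{max})$ in $k_BT$, zero at the
most occupied bin. Defaults: 50 bins per axis; unoccupied bins are reported
as missing, not zero or infinite — absence of sampling is not evidence of
high energy. Bin counts are a resolution choice, not an inference: finer
bins resolve more structure but amplify counting noise roughly as
$1/\sqrt{N_i}$.

## 4. Hertz nanoindentation fitting

For a rigid spherical tip of radius $R$ indenting an elastic half-space by
$\delta$:

$$F = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}.$$

Defaults $\nu = 1/3$ and $R = 10$ nm are the conventional values for
nucleoprotein samples and sharp silicon-nitride probes; both are always
recorded in the output since $E \propto 1/\sqrt{R}$ makes the tip radius a
direct scale factor on the answer. The fit window is restricted to
$\delta \le 1.5$ nm and $F \le 200$ pN — beyond that a nucleosome-sized
particle violates the half-space assumption — and the fit itself is ordinary
least squares through the origin after the substitution $u = \delta^{3/2}$,
which is exact for noiseless data and unweighted by choice (weighting is a
reproducibility hazard unless the noise model is known).

The contact point is found by a deterministic piecewise grid search: flat
baseline before the candidate, $a\,\delta^{3/2}$ after, minimise total
squared residual. A candidate wins only if it improves on a single flat line
by at least 5% of its residual sum of squares — below that the curve is
indistinguishable from baseline noise and the detector refuses rather than
guessing. When curves are z-piezo travel rather than true indentation, an
optional cantilever spring constant applies the deflection correction
$\delta = z - F/k$.

Per-particle elastic uniformity (`modulus_map()`) uses the max/min modulus
ratio with a default acceptance bound of one order of magnitude, the
appropriate band when working near an instrument's noise floor.

```{r hertz}
curve <- gen_force_curve(E = 5.8, contact_at = 20, noise_sd = 2, seed = 42)
fit <- fit_hertz(curve)
glance(fit)
```

## 5. AFM particle morphometry

Particles are pixels above `background + threshold` (background = modal
height of the image, 0.05-nm histogram bins — robust when particles are
sparse on a flat support), grouped by 8-connectivity. Reported per particle:
maximum height above background, footprint area, equivalent-circle diameter,
volume as the background-subtracted height integral, and **roundness**
$4A/(\pi L^2)$ with $L$ the major-axis length of the second-moment
equivalent ellipse (each pixel counted as a unit square, adding 1/12 per
moment, which keeps small footprints from overshooting 1). A disc scores 1,
a 2:1 ellipse 0.5 — the anchors that fix this definition among the many
"roundness" variants imaging software uses. Plane/line flattening of raw
AFM images is assumed done upstream.

Cluster counting groups particle centroids by single-linkage agglomeration
with a hard 0.25 µm cutoff — equivalently, connected components of the
distance graph. The alternative reading of "counting within a radius around
grouped particles" (a fixed disc around each group centroid) is available as
`method = "fixed_disc"`; the two agree for compact, well-separated groups
and differ for chains longer than the radius.

```{r afm}
img <- gen_afm_image(
  tibble::tibble(x_nm = c(300, 400, 500, 1800), y_nm = c(300, 380, 300, 1800),
                 height_nm = 3.5, sigma_nm = 10),
  extent_nm = c(2000, 2000), pixel_size = 8, seed = 1
)
parts <- detect_particles(img, height_threshold = 1)
glance(count_clusters(parts, radius_um = 0.25))
```

## 6. Numerical choices and degenerate inputs

- Collinear or coincident atom sets have no broadest plane; orientation
  refuses them (`degenerate geometry`) rather than returning an arbitrary
  frame.
- A stiffness threshold permissive enough to cross the two face planes
  raises `cylinder collapsed` instead of reporting a negative height.
- Zero strain in one cylinder mode drops that mode; zero in both is an
  error (`no observable fluctuation`), since equipartition then says
  nothing.
- Ties in $z$ during face stopping are broken by input order (stable sort),
  making fits deterministic for identical inputs.
- Unit conversions are exact powers of ten (PDB Å ÷ 10; m→nm 1e9, N→pN
  1e12; MPa = pN/nm²), and $k_B$ is fixed at its exact SI value.

## 7. Known limitations

- The elastic-cylinder model is isotropic and homogeneous; the per-mode
  split (axial vs radial) is the only anisotropy it can express.
- The RMSF stiffness threshold default (window median) is pragmatic; for
  systems where more than half the representatives are disordered it will
  misclassify, and an absolute threshold should be supplied.
- Hertz fitting ignores adhesion (JKR/DMT), tip-shape deviations and
  substrate stiffening; with a tip radius comparable to the particle the
  result is an *effective* modulus, comparable between conditions measured
  identically rather than absolute.
- Cluster counting is purely geometric; it cannot distinguish genuine
  association from coincidental deposition density.
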