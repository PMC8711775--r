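---
title: "Modelling a compound-eye brain SPECT system: methods and design choices"
author: "scespect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a compound-eye brain SPECT system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system being modelled

`scespect` simulates a stationary brain SPECT scanner assembled from 502
micro-camera elements (MCEs) packed on a spherical support around the
head.  Each MCE is a 20 mm x 20 mm x 5 mm pixelated CZT detector
(80 x 80 pixels of 250 um pitch, read out as five 1-mm
depth-of-interaction layers) looking at the field of view through a single
narrow tungsten aperture.  The aperture plane sits 183.23 mm from the FOV
centre and the detector entrance 183.23/12 mm behind it, a 1:12
minification: each camera sees the whole 20-cm spherical FOV as a tiny
inverted image, and several hundred such views are combined in
reconstruction, in the manner of a superposition compound eye.

The default layout arranges the modules in 18 rings plus a polar cover:
345 modules over the hemisphere and 157 over seven partial neck rings that
span only the rear 180 degrees, leaving the face free.  Per-ring counts
are apportioned proportionally to ring circumference and clipped to a
collision-free capacity; because adjacent square modules on a ring are
mutually rotated by the angular pitch $\delta$, the required
centre-to-centre spacing is $10(1+\cos\delta+\sin\delta)/\cos(\delta/2)$
mm rather than the 20-mm module width.  The layout is deterministic, and
`ring_counts` is user-overridable so an externally specified layout can be
dropped in.

## Aperture solids

Three aperture families share a common construction: a 20-mm tungsten slab
split into an upper thickness $t_u$ (detector side) and lower thickness
$t_l$ (object side), minus an open channel.  The channel is the union of a
lower frustum flaring toward the object with acceptance half-angle(s)
$\alpha$, the opening in the aperture plane, and an upper frustum flaring
toward the detector with exit half-angle(s) $\beta$.  All half-angles are
measured from the aperture axis; with the default focal geometry,
$\alpha = 27.3^\circ$ covers the 20-cm FOV and $\beta = 29.4^\circ$
confines a module's projection within its own detector, which is how the
design avoids any projection multiplexing.

* **Lofthole** — circular knife-edge opening of diameter $d$ with square
  channel cross-sections away from the plane, so projections tile the
  square detector efficiently.  The solid is modelled as the square
  frustum intersected with a disc whose radius grows at
  $\sqrt2\,\tan(\cdot)$: exactly circular at the aperture plane, square
  dominated away from it.  The upper/lower split (11 mm / 9 mm) is a
  package default mirrored from the micro-slit split, as no published
  value exists.
* **Micro-slit** — rectangular opening $w \times l$ with $l/w \ge 10$ and
  independent angles along the short and long directions.  The opening and
  the lower profile are rotated by an angle $\theta$ about the axis; the
  upper channel stays aligned with (and is clipped to) the square module
  footprint, which is how the published design avoids upper-profile
  collisions.  Across the helmet the rotations are a seeded random
  permutation of the exact grid $k \cdot 360^\circ/502$
  ($\Delta\theta \approx 0.717^\circ$), so the multiset of angles is
  reproducible while their assignment varies with the seed.
* **Micro-ring** — annular opening between an outer cone ($r_o$) and a
  central plug ($r_i$), both flaring with the same $\alpha$ below and
  $\beta$ above the plane.  The defaults $r_o = 3.75$ mm, $r_i = 3.5$ mm
  follow the area-consistent reading of the published description
  (open area $\pi(r_o^2 - r_i^2) = 5.69$ mm$^2$, ring diameter within the
  stated 2.5-7.5 mm design range).

Tungsten attenuation at the working energy is interpolated log-log from an
embedded NIST-derived table (3.64 mm$^{-1}$ at 140 keV) and can be
overridden per aperture.

### Ray transmission: analytic chords with a marching oracle

Every constraint defining a channel cross-section is linear or quadratic
in the position along a straight ray, so the intersection of a ray with
the open channel is an exact interval list and the tungsten chord has a
closed form.  `path_length_in_tungsten()` therefore computes transmission
analytically; a fixed-step midpoint marcher over the same solid is kept as
an independent, step-controlled oracle (`method = "march"`), and the test
suite verifies agreement within twice a 5-um step for every aperture
family.  The analytic path is what makes the full-helmet protocols
tractable: a single-voxel response traces $502 \times 80 \times 80
\approx 3.2\times10^6$ rays in about a second on one core.

Edge penetration matters enormously for narrow openings: for a knife edge
the transmission-weighted effective widening per edge is
$1/[\mu_W(\cot\alpha+\cot\beta)]$, about 0.07-0.09 mm per edge here, which
roughly doubles the effective open width of a 250-um annulus.  Penetration
is therefore always on by default; `response_options(penetration = FALSE)`
gives the purely geometric system for closed-form checks.

## System response matrix

The voxel-driven builder traces a ray from each voxel centre to the centre
of each detector pixel of each MCE and stores

$$a_{m n} = \frac{A_{pix}\cos\gamma}{4\pi\,d^2}\;
  e^{-\mu_W x}\; e^{-\mu_{CZT} (k\,c)}\,(1 - e^{-\mu_{CZT} c}),$$

the product of the pixel solid-angle fraction, the tungsten transmission
along the exact chord $x$, and the Beer-Lambert absorption of DOI layer
$k$ along the oblique chord $c = t_{layer}/\cos\gamma$ (never the nominal
1 mm).  Optional uniform-water object attenuation applies one chord per
voxel-MCE pair along the voxel-to-aperture direction.  Entries below a
floor (default $10^{-12}$, i.e. transmissions below $\sim10^{-5}$ of a
central entry) are dropped; the floor is raised to $10^{-10}$ in the
scaled reconstruction studies where the penetration tail is irrelevant but
memory is not.  Columns are emitted in compressed sparse column order
(bins ordered MCE-major, pixel u-major, DOI layer fastest), and the
per-voxel column sum is the sensitivity map.  A pilot extrapolation
refuses builds whose entry count would exceed a configurable cap instead
of exhausting memory.

Because the full 96^3-grid, all-MCE matrix is far beyond a single
workstation, three access modes cover the use cases: single-voxel columns
(`voxel_response`, `point_sensitivity`) for sensitivity protocols; masked
sub-grid matrices (`build_srm`) for phantom studies; and streaming
accumulation (`project_points`) for mean projections of smooth objects
without storing anything.

The Monte-Carlo cross-check integrates the same per-ray integrand by
uniform area sampling of the detector face, which validates the
pixel-centre quadrature independently; agreement is asserted within three
standard errors plus a one-pixel boundary-discretisation allowance
(the quadrature counts pixel centres inside a sharp-edged footprint, so a
single-module response carries an $O(\text{pixel}/\text{footprint})$
discretisation error that averages out over 502 views).

## Aperture signal-to-noise ratio

Under a uniform source over the FOV sphere, rays from (strided) voxel
centres to every pixel centre of one module are classified: zero tungsten
chord is *signal* (count 1), a penetrating chord is *noise* (weight
$e^{-\mu_W x}$), and the ratio of the sums quantifies edge penetration.
Rays enter the sums unweighted by solid angle, following the plain reading
of the defining ratio; a rigid rotation of the system leaves the value
unchanged up to voxel-lattice orientation effects.  Note that under this
literal ray-count definition the ratio compares the effective areas of the
opening and of the transmission-weighted penetration rim, so its magnitude
is set by $\mu_W$ and the wall angles alone; see the limitations section.

## Digital phantoms

All phantoms are deterministic given their parameters and live on the
standard 96^3 x 2 mm grid (or any smaller grid for desk-scale work):

* **Defrise**: a 16-cm sphere cut into 6-mm disks and gaps along the
  craniocaudal axis, slab boundaries at $z = 0$ (14 nonempty disks on the
  standard grid); probes axial sampling completeness.
* **Hot-rod**: four quadrant groups of rods (4/6/8/10 mm, centre spacing
  twice the diameter, one-diameter clear margins) in a 16-cm x 8-cm
  cylinder.  The rod-to-background concentration ratio (20:1 or 5:1) is
  authoritative; the total activity is then scaled globally, since ratio
  and per-compartment totals cannot both hold exactly on a rasterised
  grid.  ROIs: the rod of each group nearest the axis, and the central
  8 x 8-voxel background column.
* **Ictal brain stand-in**: a parametric two-hemisphere head ellipsoid
  with 16 mirrored ellipsoidal functional regions (32 VOIs), white matter
  at 0.056 uCi/mL, an ictal left temporo-polar focus at 0.07 uCi/mL,
  an 8-mm reference sphere in the right cerebellum, and optional
  5/6/7/8-mm lesions at contrasts 3 : 2.5 : 2 : 1.5 against white matter.
  The region table is config-driven so a labelled atlas can replace the
  stand-in; the default geometry is synthetic and is not an anatomical
  atlas.
* **Point sources** and a **uniform FOV sphere** for footprint and
  information studies.

Activity converts to emitted photons either through a stated total photon
budget (2e9 for the brain studies) or through concentration x voxel volume
x 3.7e4 Bq/uCi x time x yield, with 0.885 photons/decay as the default
140.5-keV yield.

## Reconstruction

`osem()` implements the standard multiplicative ordered-subset EM update
$x \leftarrow x/(A_s^T 1) \odot A_s^T(y_s/(A_s x))$ with 0/0 bins treated
as 0, subsets visited in fixed ascending order (determinism over
randomised orders), MCEs dealt round-robin in ring-major azimuth order so
each subset sees a near-uniform angular distribution, uniform-1
initialisation, and zero-sensitivity voxels frozen at zero.  The per-
iteration NRMSE trace supports the two stopping rules: the NRMSE minimum
for noisy data, and for noiseless data the first iteration with
$|\Delta\mathrm{NRMSE}| < 10^{-4}$ (0.1 per mille, configurable).  The
6-mm-FWHM Gaussian post-filter is separable with a kernel truncated at
$4\sigma$ and normalised to unit sum.

## Fisher-information images

For the Poisson model the information matrix is
$J = A^T \mathrm{diag}(1/\bar y) A$ with $\bar y$ the mean projection of
the uniform FOV object.  A column of $J$ rearranged on the grid is a
resolution probe: its lateral/axial FWHM measures the correlation spread
around the target voxel and its peak the information collected about it.
Columns are computed as $A^T(a_l/\bar y)$ without materialising $J$; for
desk-scale comparisons $\bar y$ is accumulated from a stride-3 source
lattice (the uniform object is smooth, and a common scaling of $\bar y$
cancels from FWHMs and peak ratios), while the profile voxels use exact
columns.

## Problem sizes used by the shipped studies

The full-geometry protocols (sensitivity, aperture SNR, point
projections) run on the complete 502-MCE helmet.  The reconstruction and
information studies are run at desk scale, chosen once as the largest
sizes that keep the whole suite in tens of minutes on one core:

* Defrise: 24-module helmet, 36-mm sphere with the standard 6-mm disks on
  a 36 x 36 x 26 x 2 mm grid, 5e8 noiseless photons, 60 OSEM iterations
  (8 subsets), DOI collapsed.
* Hot-rod 5:1: same helmet, 60-mm x 12-mm cylinder with 4- and 6-mm rod
  groups at the full-scale protocol concentrations (total activity scaled
  by the volume ratio), 30-min acquisition, Poisson noise, 40 iterations with the
  minimum-NRMSE stop; resolvability is declared when the mean mid-rod
  valley falls below 70 % of the mean rod peak (a Rayleigh-like
  criterion fixed before running the studies).
* FIM: 96-module helmet with DOI layers kept, 40 x 40 x 26 grid,
  lateral profile through the centre.

A thinned helmet keeps each ring's share of modules, so angular sampling
degrades gracefully; the studies state their scales in the test sources
and the same generator parameters are the defaults of `run_experiment()`.

## What the scaled studies do and do not show

The synthetic studies exercise the full chain (phantom, ray-traced system
matrix, Poisson counts, OSEM, metrics) under ideal-detector assumptions:
no scatter, no charge sharing or trapping, ideal photopeak selection, and
a stand-in brain geometry.  Passing them shows the machinery is
self-consistent and reproduces the qualitative aperture ranking
(annulus > slits > single lofthole > mixed loftholes for resolution at
matched sensitivity).  They do not certify absolute clinical performance:
a 24-module helmet has ~20x fewer views than the full design, so absolute
noise and convergence behaviour differ, and several fine-grained
comparisons that hold at 502 modules (e.g. the micro-ring's information
FWHM matching the 150-um slit) visibly degrade at desk scale because the
annulus response relies on angular averaging.

## Known limitations

* The micro-ring's absolute sensitivity depends on how the central plug's
  flares are parameterised; only one $(\alpha, \beta)$ pair is published
  for the whole assembly, and applying it to both the outer cone and the
  plug (the package's reading) yields a central sensitivity around 1 %,
  i.e. a more conservative penetration contribution than the published
  1.38 % figure implies.  Lofthole and micro-slit sensitivities reproduce
  their published values within a few percent under the same conventions,
  which localises the ambiguity to the plug geometry.
* The aperture-SNR ray protocol, read literally as a ratio of ray counts,
  produces values of order unity-to-ten (the open-to-penetration
  effective-area ratio); published values in the hundreds imply an
  additional normalisation that the defining ratio does not state.  The
  package reports the literal quantity and preserves its within-family
  behaviour (SNR grows with lofthole diameter).
* Scatter, detector blurring, randoms and dead time are out of scope; the
  system matrix is exact for the ideal-absorption model it states.
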