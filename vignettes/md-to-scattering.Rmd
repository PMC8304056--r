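---
title: "From membrane MD trajectories to reflectivity and SANS curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From membrane MD trajectories to reflectivity and SANS curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scattermd)
```

## The model

Specular neutron or X-ray reflectivity and small-angle scattering are both
determined by the scattering-length-density (SLD) profile of the sample,

$$\rho(z) = \sum_j n_j(z)\, b_j,$$

the number density of each isotope weighted by its coherent scattering
length.  An MD trajectory of a membrane predicts $n_j(z)$ directly:
`bin_number_density()` slices frames into thin bins along the membrane
normal (0.13 Å by default), histograms every (group, isotope) species,
divides by the instantaneous slice volume and averages over frames;
`density_to_sld()` multiplies by the tabulated $b_j$.  Because densities
and scattering lengths only meet at this last step, isotopic substitution
is free: `apply_isotope_substitution()` relabels a species (e.g. tail
hydrogens to deuterium) without touching the histogram, and the
`fraction_d2o` argument mixes the water hydrogens linearly between
$b_\mathrm{H} = -3.74$ fm and $b_\mathrm{D} = 6.67$ fm, implementing
solvent contrast variation.  The isotope table is shipped as data
(`inst/extdata/isotope_table.tsv`, Sears 1992 values); the X-ray branch
uses $f_1 = Z$, $f_2 = 0$ with the Thomson scattering length, i.e. no
anomalous dispersion.

For an interface between media of SLD $\rho_0$ and $\rho_1 > \rho_0$ total
external reflection occurs below the critical edge

$$Q_c = \sqrt{16\pi(\rho_1 - \rho_0)}.$$

(The compact form $Q_c = 4\pi(\rho_1-\rho_0)$ sometimes quoted is
dimensionally inconsistent; the package implements the standard
expression above.)  For Si against D$_2$O this gives
$Q_c \approx 0.0147\,$Å$^{-1}$, which the exact kernels reproduce as the
largest $Q$ with $R = 1$.

## Exact reflectivity kernels

`parratt_reflectivity()` implements the recursive amplitude solution for a
stratified medium and `abeles_reflectivity()` the equivalent
transfer-matrix formulation.  Both are exact for a stack of constant-SLD
slabs and agree to $10^{-10}$ relative everywhere, including below the
critical edge and with roughness, so each serves as an oracle for the
other (this is property-tested on random 1–20-slab stacks).  Gaussian
interfacial roughness enters as the Nevot–Croce factor
$\exp(-2 k_{z,j} k_{z,j+1}\sigma_j^2)$ per interface; it is exact in the
limit $\sigma \to 0$ and trustworthy only for $\sigma$ well below the
adjacent layer thickness, so `slab_stack()` warns when
$\sigma > t/3$.  Arbitrary diffuse profiles are instead handled by
discretization: `profile_to_slabs()` turns every bin into a zero-roughness
micro-slab (optionally merging bins within a coarsening tolerance, which
collapses piecewise-constant regions and keeps stacks small).  A finely
binned erf-shaped interface agrees with the Nevot–Croce closed form to
better than 1% up to $Q = 0.3\,$Å$^{-1}$ — the two descriptions are never
mixed on one interface, since that would double-count the damping.

`born_reflectivity()` evaluates the weak-scattering master equation
$R = R_F\,|\int (d\rho/dz)\,e^{iQz}dz|^2/\Delta\rho^2$ as a cross-check.
It is exact for a sharp step, invalid at and below the critical edge
(flagged in the output), and approaches the exact result at large $Q$;
comparisons are made after light resolution smearing because the
relative deviation is undefined at the measure-zero fringe nulls.

## Assembling the measurable system

Simulations float the bilayer in water; measurements support it on a
substrate.  `splice_substrate()` builds
fronting | oxide | water gap | membrane | bulk solvent, with the two oxide
interfaces realized as erf-smoothed micro-slabs.  Every junction must be
continuous within a tolerance: a surface roughness too large to decay
inside the water gap, or a solvent mismatch between profile and reservoir,
raises an error instead of silently producing curve artefacts.  The
substrate–headgroup water gap is a free parameter of the real sample
(`adjust_water_gap()`), and a 10 Å versus 5 Å gap changes the reflectivity
of the supported-bilayer fixture far beyond the noise level of a typical
measurement — the package's tests pin this at $\chi^2 \ge 10\times$ the
noise floor.

Lamellar multilayers are built by `tile_unit_cell()`.  The unit cell must
start and end in half water gaps that merge into the same interlamellar
spacing found elsewhere in the stack; unequal gaps would double the
lattice constant and create a superlattice peak at half the first Bragg
$Q$, so they are rejected unless explicitly overridden (the override
exists precisely so the artefact can be demonstrated).  Interlamellar
disorder is modelled by `jitter_ensemble()`: independent realizations with
randomly perturbed water gaps, averaged *in intensity* by
`incoherent_mean()` — never on the profiles — which damps higher Bragg
orders like a Debye–Waller factor.  The jitter distribution family is not
settled by any reference we know of, so both `uniform` and `normal` are
provided with neither claimed canonical; the default ensemble is 64
realizations under a documented seed.  `scale_region_sld()` implements the
two solvent-contamination scenarios (bulk-only versus all solvent) whose
different fingerprints — critical-edge shift versus Bragg-intensity change
— the tests verify.

## SANS of vesicles

For spherically symmetric objects the scattering amplitude is the radial
Fourier integral; for a piecewise-constant concentric-shell profile it has
the closed form summed by `shell_amplitude()`, verified against brute-force
radial quadrature to $10^{-6}$.  `profile_to_shells()` wraps a
solvent-trimmed planar membrane profile onto a vesicle of given core
radius, one shell per bin.  Core-size polydispersity uses the Schulz–Zimm
distribution parameterised by the mean radius and the relative width
$p = \sigma_R/\langle R\rangle$ (shape $z = 1/p^2 - 1$), averaged with a
101-point Gauss–Legendre rule over mean $\pm 5\sigma$ truncated at
$R > 0$; shell thicknesses stay fixed, since it is the solvent core that
is polydisperse.  $p < 10^{-8}$ short-circuits to the monodisperse form
factor.  `fit_vesicle()` wraps weighted Levenberg–Marquardt least squares
with any subset of core radius, polydispersity, scale, background and a
common thickness factor free; uncertainties come from the
$\chi^2$-scaled covariance.  The high-$Q$ oscillation near
$0.25\,$Å$^{-1}$ is sharply sensitive to the membrane thickness — shifting
all shells by $\pm 2$ Å moves it visibly, and freezing the thickness 2 Å
off truth inflates the reduced $\chi^2$ of a 1%-noise synthetic data set
by more than a factor of five.

## Instrument non-idealities

Resolution smearing (`smear_resolution()`) convolves pointwise with a
Gaussian of width $dQ = (dQ/Q)\,Q$.  The width is interpreted as the
kernel FWHM, the common reflectometry convention; since conventions vary
between facilities this is configurable (`convention = "sigma"`).
Typical values are 3.5% for an angular-resolution-limited time-of-flight
reflectometer and 10% for a velocity-selector SANS instrument.  The
convolution preserves integrated peak areas to better than 1%.
`apply_scale_background()` adds the remaining $Q$-independent background
and an intensity scale; a scale error is detectable against the $R = 1$
total-reflection plateau.  Footprint and gravity corrections and
off-specular scattering are real effects of real instruments but are out
of scope here; off-specular intensity is treated as background.

## The synthetic-data generator

`bilayer_fixture_spec()` / `make_bilayer_frames()` generate a statistical
stand-in for a bilayer trajectory: Gaussian head layers at $\pm z_h$,
a Gaussian tail core, and uniform water outside the membrane.  The default
conditions are 128 lipids in a 62 Å × 62 Å box (64 per leaflet at
~60 Å$^2$ per lipid) with ~3000 waters, 0.13 Å bins and a ~66 Å lamellar
unit cell for multilayer work.  The water slab density implied by these
choices reproduces bulk water within a few percent, so converted profiles
hit the familiar bulk SLDs.  What the fixtures do *not* emulate: excluded
volume (head Gaussians overlap the water edge), atomic packing
correlations, capillary waves, or any force-field physics — so passing
tests demonstrate the correctness of the binning, assembly and scattering
machinery, not the realism of any particular membrane model.
`make_slab_profile()` provides analytic piecewise-constant profiles
(midpoint assignment on the bin grid), and `make_noisy_curve()` adds
seeded multiplicative Gaussian noise (clipped at zero) with matching
stated uncertainties; the mean reduced $\chi^2$ of truth against such
data is 1 within statistical scatter.

## Numerical choices

* Units: lengths in Å, $Q$ in Å$^{-1}$, $b$ stored in fm
  ($1\,\mathrm{fm} = 10^{-5}$ Å), SLD in Å$^{-2}$ (displayed
  $\times 10^{-6}$).
* The histogram bin width snaps to the nearest value that tiles the first
  frame's box exactly, so no partial-volume edge bin corrupts the bulk
  density.
* Frames are centred by shifting the mass-weighted circular mean of the
  non-water atoms to the grid centre before binning (suppresses drift
  broadening; circular so a boundary-straddling membrane is handled).
  Slice volumes use each frame's instantaneous box area.
* Evanescent square roots take the $+i\kappa$ branch; $Q$ grids are never
  auto-generated below $10^{-4}$ Å$^{-1}$.
* Bragg peaks are located on $\log_{10} R$ after smearing, with a 0.3
  decade prominence threshold and parabolic refinement.
* Solvent regions are auto-detected as bins within 1% of the backing SLD;
  explicit masks override.
* Test problem sizes (chosen to keep the full suite around ten seconds):
  12–36 bilayer repeats, ensembles of 16–32 realizations, 10-seed
  recovery experiments, $Q$ grids of a few hundred to a few thousand
  points.

## Limitations

United-atom trajectories must declare implicit hydrogens explicitly
(`implicit_h`); nothing is guessed.  Binary trajectory formats (XTC/TRR)
are not read — PDB and GRO only.  Lateral inhomogeneity, patchy coverage,
multilamellar vesicle admixtures, inter-vesicle structure factors,
multiple scattering and polarized beams are all outside the model.  The
bulk SLD values computed from the internal constants can differ from
commonly quoted figures by a few tenths of a percent (e.g. D$_2$O at
1.1044 g/cm$^3$ computes to $6.36\times10^{-6}$ Å$^{-2}$ against the
often-printed 6.35); the package reports computed values and does not
force agreement.
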