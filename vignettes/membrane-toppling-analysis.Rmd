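---
title: "Methods: tilt statistics, bilayer maps, lipid fingerprints and umbrella-sampling free energies"
author: "memtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tilt statistics, bilayer maps, lipid fingerprints and umbrella-sampling free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtraj)
```

# Scope

`memtraj` implements the trajectory-analysis computations used to
characterise membrane-mediated toppling of the S-component of ECF-type
transporters: (i) helix-tilt classification and replica-stability
statistics, (ii) per-leaflet polynomial surface fits yielding membrane
thickness and mean-curvature maps, (iii) contact-based lipid
depletion–enrichment fingerprints, and (iv) umbrella-sampling free-energy
profiles via WHAM with bootstrap errors. It does not run molecular
dynamics: inputs are coordinate files, plain-text trajectories and
umbrella-window sample files. A synthetic-data module generates all of
these with known ground truth, which is how the package validates itself.

All lengths are nm (PDB Ångström are converted on read/write), times ps,
energies kJ/mol, temperatures K. Boxes are orthorhombic; triclinic input
is rejected rather than silently mishandled, because every analysis here
is defined on a rectangular membrane patch.

# Orientation statistics

The S-component's orientation is summarised by the angle between its
helix 5 axis and the bilayer normal (laboratory +z by default; the
instantaneous normal of a fitted mid-surface is a reasonable extension
for strongly curved patches but the flat-normal convention matches how
tilt angles along a dissociation pathway are usually reported).

The helix axis is the principal axis (largest-variance eigenvector) of
the selected backbone beads, sign-oriented from the N-terminal half
centroid toward the C-terminal half centroid, so angles beyond 90° are
meaningful: an inverted helix reads 180°, not 0°. An `endpoints` method
(vector between the two half centroids) is available for comparison; for
an ideal helix long relative to its radius the two agree to well under a
degree. Tilt angles live on [0, 180] and are never folded onto [0, 90] —
folding would erase exactly the distinction between canonical (~30°) and
inverted orientations that the toppling analysis is about.

The *toppled* state is the band 75°–125°, bounds inclusive; inclusivity
is a determinism choice at the measure-zero boundary. A replica is a
*stable toppled* replica when strictly more than 50% of its frames are in
the band; strictness again only matters on the exact-half boundary, where
counting "half the time toppled" as stable would overstate stability.
Across replicas, the stable fraction p carries a binomial standard
deviation sqrt(p(1−p)/n) reported on the fraction scale (a `count` scale
multiplies by n). With all replicas stable the SD is exactly zero — the
error model is binomial sampling of replicas, not within-replica noise.

# Membrane surface maps

For each frame, lipids are assigned to leaflets by their phosphate-bead
z (bead-averaged per lipid, so two-phosphate cardiolipin is assigned
once). The midplane is the overall phosphate mean refined once to the
midpoint of the two sides; a plain bead-level median was rejected because
with unequal per-leaflet bead counts (one extra cardiolipin suffices) the
median of a strongly bimodal sample sits *inside* a leaflet and every
lipid of that leaflet lands in the dead zone. Lipids within 0.5 nm of the
midplane are excluded as unassignable; that dead-zone half-width and the
0.3 nm protein-footprint pad are toolkit defaults, exposed as arguments.

Each leaflet's phosphate positions are fit by least squares with a full
bivariate polynomial of total degree 4 (15 monomials; a radially
symmetric variant with terms 1, r², r⁴ is available). Thickness is the
upper-minus-lower surface difference at grid-cell centres; mean curvature
is the analytic Monge-patch expression

H = [(1 + z_y²) z_xx − 2 z_x z_y z_xy + (1 + z_x²) z_yy] / [2 (1 + z_x² + z_y²)^{3/2}]

evaluated from the fitted coefficients (verified against finite
differences to 1e-4 nm⁻¹ in the tests). Maps are computed per frame on
protein-centred, minimum-image-shifted coordinates and averaged cell-wise
over frames; per-frame fitting commutes with averaging of the thickness
field and keeps each fit consistent with a single configuration.

**Analysis patch.** The fit is restricted to a patch around the protein
(default half-width 4 nm, grid 0.2 nm). A single degree-4 polynomial
cannot follow a localised deformation across a 25 nm box — the
least-squares fit is dominated by the flat bulk and flattens the
deformation (numerically: a σ = 2 nm Gaussian dimple is recovered with
~0.016 nm centre bias per leaflet on an 8×8 nm patch, but ~0.15 nm bias
on the full box). A patch comparable to the deformation scale is
therefore part of the method, not an optimisation; bulk thickness is read
from a second patch away from the protein. Cells whose centre is within
the footprint pad of a protein bead are masked (carried as NA, never 0)
and phosphates in masked cells are excluded from the fit input.

# Lipid fingerprint

A protein residue and a lipid are *in contact* when any particle of the
residue is within 0.7 nm (minimum image) of any headgroup bead
(phosphatidyl/glycerol-type beads) of that lipid; each (residue, lipid)
pair counts at most once per frame, and a lipid is *in the annular shell*
when it has at least one such contact. Shell membership is molecule-level:
cardiolipin contacting through both headgroups is one molecule. Distances
are evaluated as vectorised all-pairs minimum-image distances, which is
exactly the brute-force definition (and is tested against an independent
O(N²) loop).

The depletion–enrichment index of lipid type L is

D–E(L) = ratio(L)_shell / ratio(L)_bulk,

where ratio(L)_shell is the fraction of shell lipids of type L and
ratio(L)_bulk the same fraction over the whole system. The default
estimator averages per-frame shell ratios over frames (frames with empty
shells are skipped and counted); a pooled estimator sums shell counts
first and satisfies the identity Σ_L bulk_ratio(L)·D–E(L) = 1 exactly.
The per-frame mean is the default because it weights every sampled
configuration equally rather than weighting frames by shell occupancy.
Whole-system bulk ratios are used (not leaflet-resolved), matching the
census most people mean by "bulk composition".

Per-residue contact occupancies (fraction of frames with ≥1 contact per
lipid type) support binding-site grouping: residues are joined by single
linkage when some single lipid molecule touches both in at least 20% of
frames — a toolkit convention for turning co-contact structure into
discrete sites that are otherwise identified visually.

# Umbrella sampling and WHAM

The reaction coordinate is the distance between the centres of mass of
two selections (for ECF transporters: the EcfT subunit and the
S-component bottom, residues 69–75 and 127–133). Masses default to
uniform — appropriate for standard coarse-grained beads of equal mass and
the reason a geometric centre is an acceptable default; a per-name mass
table switches to true mass weighting.

Windows carry a centre, a harmonic force constant and samples. Defaults
mirror the common design for this system: K = 2500 kJ mol⁻¹ nm⁻²,
0.1 nm spacing, T = 303 K. Validation reports per-window counts,
mean-vs-centre deviations and adjacent histogram overlaps, and refuses
disconnected sets (zero shared occupied bins), which WHAM cannot join.

WHAM solves the standard self-consistency between unbiased bin
probabilities p(x) and window offsets f_i under the harmonic biases.
Numerically the package minimises the equivalent convex log-likelihood in
the offsets with BFGS, then polishes with the textbook fixed-point
iteration until max|Δf_i| < tol (default 1e-7 kJ/mol; bin width
0.02 nm). The two routes share the same fixed point — tested — so the
acceleration changes runtime, not results. kB = 0.0083144621
kJ mol⁻¹ K⁻¹. The free energy −kT ln p(x) is anchored to zero at the
profile minimum (the bound state for a dissociation profile); either end
can be chosen instead. Bins inside the sampled range with no samples are
carried as NA. No Jacobian correction for the radial distance coordinate
is applied by default; `radial_correction = TRUE` adds 2kT ln x for users
who want the point-particle convention.

Errors come from a moving-block bootstrap: each window's series is
resampled in contiguous blocks, with block length from the integrated
autocorrelation time (minimum 1, which is what independent samples give),
WHAM is re-solved per replicate warm-started from the full-set offsets,
and the per-bin SD of anchored profiles is reported. Replicates that fail
to converge are dropped and counted; more than 10% dropped is an error.
Fixed seeds give bit-identical error bars.

# Synthetic data: what it emulates and what it does not

Every generator is a pure function of its spec and seed.

* **Bilayers** place phosphates on a per-frame jittered lattice at
  mid_surface(x, y) ± thickness(x, y)/2 plus Gaussian noise (default
  0.1 nm, a typical phosphate roughness scale), with a minimal
  headgroup + two-tail bead set per lipid and multinomial lipid types
  (default POPE:POPG:CL 70:25:5, the bacterial model membrane; area per
  lipid 0.64 nm²). This exercises leaflet logic, surface fitting and
  contact logic. It does *not* emulate lipid packing correlations,
  undulation spectra, tail order or protein-induced deformation
  dynamics — so passing tests demonstrate correct recovery of prescribed
  fields, not realism of any membrane model.
* **Tilt dynamics** are either Gaussian noise about one mean or a
  two-state continuous-time Markov chain between toppled and canonical
  mean angles with exponential dwells; the stationary toppled fraction is
  topple/(topple + untopple). Real toppling kinetics are not two-state
  Markov; the generator exists to give the stability statistic a known
  occupancy to recover.
* **Enriched shells** fix the whole-system composition exactly (largest
  remainder rounding) and draw shell members per frame with type weights
  shell/bulk, so the shell composition targets its prescription while the
  system composition stays the bulk one; shell and bulk populations are
  geometrically separated by more than the cutoff so D–E ground truth is
  unambiguous.
* **Umbrella windows** are drawn by inverse-CDF sampling on a ≤1e-3 nm
  grid from the exact biased Boltzmann density, giving exactly independent
  samples (block length 1) so that bootstrap calibration can be checked
  against the clean iid theory.

# Validation problem sizes

The self-validation suite recovers: a Gaussian-dimpled bilayer
(4.0 nm bulk thinning to 3.6 nm, σ = 2 nm) from 50 frames × 1000 lipids
per leaflet at 0.1 nm phosphate noise, to 0.05 nm at the minimum and in
bulk; sphere-cap mean curvature (R = 10 nm) to 5%; a harmonic potential
(½·100·x² kJ/mol) from 51 windows × 10⁴ samples to 0.3 kJ/mol RMS over
the central 2 nm, and a 10 kJ/mol double-well barrier to 0.5 kJ/mol;
bootstrap SDs against 50 independent regenerations within a factor 1.5;
prescribed cardiolipin shell enrichment (D–E = 2) and a neutral control
within three standard errors over 200 frames; and the two-state
stationary occupancy 0.3 within three standard errors over eight
replicas of 6000 frames. These sizes were chosen so each check is
decisively more precise than its tolerance while remaining quick to run.

# Known limitations

* Orthorhombic boxes only; no triclinic support.
* The curvature map is the mean curvature of the same degree-4 fit used
  for thickness, per leaflet; no Gaussian curvature, no Helfrich energy,
  no undulation spectra.
* The polynomial surface is global over the patch: deformations much
  narrower than the patch are attenuated (choose the patch accordingly).
* No lipid residence-time kinetics, no binding free energies, no MBAR
  (WHAM only, 1-D only), no toppling rate estimation.
* The whitespace trajectory dialect is deliberately simple; binary
  trajectory formats are out of scope for the core reader.
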