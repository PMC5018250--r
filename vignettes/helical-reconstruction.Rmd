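---
title: "Helical reconstruction and filament architecture analysis with helifil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical reconstruction and filament architecture analysis with helifil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helifil)
```

## The problem

Conjugative (F-family) pili are extracellular filaments through which
plasmid single-stranded DNA passes between bacteria. They are helical
polymers of a single small α-helical pilin (TraA) bound stoichiometrically
to a phosphatidylglycerol molecule. The filament lattice is described by a
helical symmetry: a twist near 28° and a rise of 12–13 Å between
successive subunits, combined with a C5 point group — equivalently, five
helical strands of ~12.8 subunits per turn, or stacked pentamer layers.

`helifil` implements, at desk scale, the computational chain used to solve
such structures and to quantify their architecture:

1. a synthetic-data generator (pseudo-atomic subunits, helically symmetric
   density, CTF-modulated noisy projection segments, two-population
   mixtures);
2. iterative helical real-space reconstruction (IHRSR): projection
   matching, filtered back-projection, helical symmetry search and
   imposition, plus two-class sorting of coexisting lattices by rise and
   alignment transfer between dose levels;
3. Fourier shell correlation (FSC) resolution assessment;
4. construction of complete filament atomic models from a single
   subunit(+lipid) unit via screw transforms;
5. interface analysis: solvent-accessible surface areas, buried-surface
   fractions, contact networks, radial geometry, and a screened-Coulomb
   model of the lumen electrostatics.

## Conventions and the helical lattice

The helix axis is +z; angles are in degrees; rotations are right-handed
about +z; a positive twist denotes a right-handed helix. The absolute
handedness of the pilus is not part of the model — the generator default is
right-handed and the sign of `twist_deg` switches it. Subunit (layer *i*,
strand *k*) of a Cn lattice sits at rotation `i·twist + k·360/n` and
translation `i·rise`:

```{r}
sym <- helical_symmetry(28.2, 12.1, 5)
subunits_per_turn(sym)          # 12.77 subunits per strand turn
layer_transforms(sym, 13)       # 65 transforms: 13 layers x C5
strand_lattice_equivalence(sym, 13)$equivalent   # 5-start == layer stack
```

Any rigid transform can be decomposed into screw parameters
(`screw_decompose`); degenerate cases (identity, pure translation) are
flagged explicitly rather than silently defaulted, because a failed
superposition would otherwise masquerade as a zero-twist lattice.

## The synthetic-data generator

`make_test_subunit()` builds the density-level stand-in for one
pilin(+lipid) unit: ~18 Gaussian scatterers in three rod-like clusters
(an α-helix proxy) within a ~25 × 15 × 15 Å envelope, offset so a rendered
filament spans radii ~14–47 Å. The template is deliberately asymmetric
(best nontrivial self-superposition RMSD > 2 Å) so that azimuth assignment
is well posed. `render_volume()` sums Gaussian copies over the lattice;
with `clip_z = TRUE` the filament continues through the whole box, the
correct forward model for segments cut from long filaments (free filament
ends never appear inside a segment).

`simulate_segment_stack()` draws, per segment: a uniform azimuth, an
out-of-plane tilt jittered ≤ 5° about 90° (filaments lie in the ice plane;
a full out-of-plane search is out of scope), a small in-plane rotation,
sub-pixel x/y shifts, an axial offset uniform over one rise, and a defocus
uniform over 0.5–3.5 μm underfocus (the display convention "−0.5 to −3.5
μm" maps to positive underfocus internally). The projection is multiplied
in Fourier space by a 300 kV CTF,
`CTF(s) = −(√(1−A²)·sin γ + A·cos γ)` with
`γ = πλΔf s² − (π/2)Cs λ³ s⁴`, and white Gaussian noise is added. The
noise model is deliberately minimal — no structural noise, no ice
gradient, no astigmatism, no beam-induced motion — which is what makes
clean parameter-recovery tests possible; it also means that passing tests
demonstrate correctness of the algorithms, not their robustness to every
pathology of real micrographs. Dose fractionation is emulated as two noise
levels per segment set (a high-dose and a half-dose partner with doubled
noise power) to exercise alignment-parameter transfer.

All simulation is bit-reproducible given (seed, configuration).

### Problem sizes

The package default geometry is 96-px boxes at 2.0 Å/px (a 192 Å box,
~1.25 helical turns, Nyquist 4 Å), 250 segments at SNR 0.1 for the
reconstruction demo and 200 segments for the sorting demo; the FSC
consistency demo uses 64-px boxes at 2.5 Å/px and 120 segments. These
sizes were chosen as the smallest at which every stage of the method is
exercised meaningfully: the box holds more than one full helical turn, the
Nyquist frequency sits beyond the first several layer lines, and the
per-dataset subunit count (250 segments × C5 × ~16 layers ≈ 20,000
asymmetric units) is enough for the symmetry signal to dominate the noise.
The full-size geometry of real data collections (384-px boxes at 1.1 Å/px,
tens of thousands of segments) is supported but not the default.

## The reconstruction engine

One IHRSR iteration is: project references from the current symmetrized
volume over one asymmetric unit of azimuth (`make_references`, default 4°
step), exhaustively match every segment over reference × in-plane rotation
× shift (`align_segments`; FFT cross-correlation, axial window covering
one rise), filtered back-projection (`backproject`), helical symmetry
search on the new volume, and symmetry imposition (`symmetrize`).
`ihrsr()` is the package's model-fitting entry point and returns a classed
fit with `print`, `summary`, `coef`, `plot`, `residuals` and `simulate`
methods.

Numerical choices worth knowing:

* **Interpolation** is trilinear (volumes) / bilinear (images)
  throughout — the accuracy/speed balance appropriate at 2–3 Å/px.
  Resampling attenuates content near Nyquist, so invariance checks on
  noisy maps are made on band-limited content
  (`screw_self_correlation(..., lowpass_sigma_vox = 1)`).
* **Back-projection** exploits the helical geometry (tilt ≈ 90°): each
  z-slice of the volume is a 2D parallel-beam problem, solved by
  Hann-windowed ramp-filtered back-projection; CTF amplitude weighting is
  removed by dividing the volume's Fourier shells by the segment-averaged
  squared CTF plus a Wiener constant (default 0.1 × its spectral mean —
  unstated in the original workflow, chosen as a conventional
  regularization).
* **Phase flipping** (`phase_flip`) multiplies each image by its own CTF
  and records that amplitudes now carry CTF²; `backproject` applies the
  corresponding amplitude correction only then.
* **Symmetry search** minimizes the mean squared difference between the
  volume and its screw-transformed copy, normalized by the signal power of
  the compared region, inside a cylindrical mask (default radii 5–45 Å) —
  the normalization makes different rises (different overlap regions)
  comparable. A coarse grid is refined by Nelder–Mead, clamped to the
  search window.
* **Convergence** is declared when consecutive (twist, rise) estimates
  change by less than (0.05°, 0.02 Å) — tolerances chosen for this scale,
  the original criterion being qualitative ("no changes with further
  iterations").

### Starting from nothing: the symmetry scan

A subtlety that shapes the design: when segments have been aligned against
references carrying an *imposed* symmetry, the reconstruction inherits
that lattice, and the volume-based symmetry search will simply return it —
the search is self-confirming. From a featureless-cylinder start at SNR
0.1 the plain loop therefore locks onto whatever the first (noise-driven)
search returns. The reliable data-driven discriminator is reconstruction
quality itself: the correct candidate symmetry yields a self-consistent
reconstruction whose references match the data best. `symmetry_scan()`
operationalizes this — each candidate (twist, rise) over the search window
gets a short fixed-symmetry reconstruction on 2×-binned segments and is
scored by its mean projection-matching correlation; coordinate passes
(rise, then twist, then a finer pass of each) with parabolic peak
interpolation give the starting estimate. This is the same logic by which
the point group itself is chosen (several candidate symmetries
investigated; only the right one "works"; see also
`compare_cyclic_orders`, which ranks Cn candidates by symmetrization
residual). `ihrsr()` runs the scan automatically on cold starts; the
volume-based search then refines within a narrowed window, starting only
once the map has developed structure, and estimates pinned to the window
boundary are rejected as noise artifacts.

### Two-class sorting and alignment transfer

`sort_segments()` separates coexisting lattices (rise 12.5 vs 13.2 Å by
default): a single unsorted reconstruction is symmetrized once with each
candidate symmetry to create two references; each cycle reassigns every
segment to the better-matching reference (ties deterministically to class
a) and rebuilds both class reconstructions; five cycles by default ("several"
in the original account is unquantified). `transfer_alignment()` applies
alignment parameters found on one dose level to the paired images of
another without re-alignment.

### What the FSC does and does not measure here

Aligning both half-sets against common references imprints correlated
reference noise into the two half-maps and inflates their FSC — at SNR 0.1
the shared-alignment half-map FSC can stay above threshold to Nyquist.
`run_demo_reconstruction()` therefore refines each half independently for
its final two iterations; the acceptance-level consistency check between
the half-map (0.143) and model:map (0.4) resolutions instead uses a small
reconstruction back-projected from ground-truth alignments, where the two
halves carry strictly independent noise. Full gold-standard half-set
refinement with masking and FSC weighting is intentionally out of scope.
FSC shells are one Fourier voxel wide, without masking or
phase-randomization corrections; model density for model:map FSC is a
single Gaussian per atom with amplitude ∝ atomic number and width from an
overall B-factor (σ² = B/8π²) — adequate for consistency checks at ~4–8 Å,
not a scattering-factor model.

## Building filament models

`kabsch_superpose()` gives the least-squares rigid superposition (proper
rotations only); `screw_from_chain_pair()` superposes two chains over
matched (residue, atom-name) pairs — mismatches are reported, never
silently dropped — and decomposes the motion into twist/rise.
`propagate_strand()` places successive screw powers of a unit (16 per
strand by default) and `build_full_pilus()` replicates the strand by the
exact Cn rotation, reporting the minimum inter-strand distance as a clash
diagnostic. The round trip build → extract reproduces the construction
parameters to 1e−6. Models read/write PDB (via bio3d; chain names mapped
deterministically into the 62-id PDB space, erroring beyond that) and a
minimal mmCIF `atom_site` dialect that carries full chain names.

`make_test_pilin()` is the atomic-level synthetic stand-in: a 63-residue
(numbered 2–64) Cα-trace pilin as a three-helix bundle oriented along the
filament axis and spanning the wall, a lumen-facing loop between the inner
helices, lysines on lumen-proximal residues, aspartate/glutamate at the
periphery, charged termini, and a phosphatidylglycerol proxy whose
phosphate sits at the lumen surface with the acyl tail buried outward
between strands. It is constructed from the published architectural
*description*, not from deposited coordinates, and is labelled synthetic
throughout. Its filament reproduces the qualitative architecture — outer
diameter ~90 Å, lumen ~25 Å, interior subunits contacting six neighbours,
each lipid touching three subunits, and the lumen potential flipping sign
when lipids are included — but its exact interface statistics are those of
a Cα-level toy, not of the real atomic model, and are reported as such.

## Interface analysis

SASA is Shrake–Rupley with standard van der Waals radii (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80, H 1.20 Å), probe 1.4 Å, 960 quadrature points per
atom (doubling the points changes totals by < 0.5%). Buried area of a
component is SASA(isolated) − SASA(in context); "contact" defaults to
buried area > 1 Å², with a 4.0 Å heavy-atom distance criterion available
as a cross-check. Radial geometry reports per-slice extrema of atom-center
radii, with vdW-padded variants alongside, because the measurement
convention behind published diameters (atom centers vs surface) is
ambiguous: the lumen diameter is twice the largest empty coaxial cylinder
radius over the central half of the filament, the outer diameter twice the
99th percentile of per-slice maxima.

Lumen electrostatics is a deliberately qualitative screened-Coulomb
(Debye–Hückel) model: +1 on Lys/Arg side chains, −1 on Asp/Glu, ±1 on
chain termini, −1 per lipid phosphate; uniform dielectric 80, 150 mM ionic
strength at 298 K (Debye length 7.85 Å), potentials in kT/e with the
self-region capped at 1 Å. The quantity of scientific interest is the
*sign* of the mean potential over the lumen-facing shell with and without
the lipid head groups — a Poisson–Boltzmann solver is out of scope.

## Known limitations

* The simulator omits structural noise, astigmatism, motion and dose
  damage; recovery results bound algorithmic, not experimental, accuracy.
* Orientation search covers azimuth, small in-plane rotations and shifts
  at tilt ≈ 90°; there is no full five-parameter search and no polarity
  (up/down) classification — simulated filaments share one polarity.
* Shift estimation is integer-pixel; at 2 Å/px this limits the useful
  resolution of reconstructions to roughly 6–8 Å, which is also where the
  desk-scale FSC curves cross their thresholds.
* The symmetry scan assumes the search window brackets the true lattice,
  as the IHRSR contract requires.
* Interface statistics on the synthetic Cα-level pilin are internally
  consistent (helically equivalent across interior subunits) but not
  comparable in absolute value to all-atom buried areas.

## Reproducing the demo numbers

```{r}
cfg <- run_config()                 # all defaults, seed 1
rec <- run_demo_reconstruction(cfg) # simulate + IHRSR + half-map FSC
summary(rec$fit)
srt <- run_demo_sorting(cfg)        # two-rise mixture + sorting
srt$confusion
ana <- run_structure_analysis(cfg)  # build + interfaces + lumen potential
ana$geometry
```

`scripts/acceptance.R` chains all of the above from a single seed and
writes the headline numbers as JSON.
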