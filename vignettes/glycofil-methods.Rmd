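---
title: "Modelling glycosylated helical filaments and their steric accommodation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glycosylated helical filaments and their steric accommodation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofil)
```

## The problem

Bacterial type IV pili (T4P) are helical filaments of thousands of pilin
subunits, extruded through an outer-membrane secretin channel.  In
*Thermus thermophilus* two filament forms coexist — a wide form (PilA4
pilin, three O-glycosylation sites S59/S66/S71) and a narrow form (PilA5,
one site S73) — and their surface glycans must pass through the secretin
(PilQ) lumen during extrusion.  Two questions are geometric at heart:

1. What does the filament lattice look like, given the helical symmetry
   parameters (twist per subunit in degrees, rise per subunit in
   Angstrom) refined from cryoEM?
2. How much conformational freedom do the surface glycans retain while
   the filament sits inside the channel — i.e. what fraction of a glycan
   conformer ensemble is sterically rejected, and where along the
   filament axis?

glycofil implements this as a desk-scale pipeline: screw-symmetry
filament assembly, Cn ring assembly, site-specific glycan decoration,
rigid conformer grafting with threshold-distance rejection, and axially
binned accommodation/aperture profiles.  All inputs can be produced by
the built-in seeded generators; externally deposited coordinates are an
optional alternative, never a requirement.

## Coordinate conventions

Every assembly lives in a single frame: the filament/channel axis is +z
through the origin, and positive twist is a right-handed rotation about
+z.  `align_to_axis()` brings arbitrarily oriented inputs into this
convention.  Twist is reported in (−180°, 180°]; the handedness of a
deposited model can be compared by negating.  Residue numbering is
1-based and preserves author numbering, so S59/S66/S71/S73 refer
directly to `res_seq` values.

## Helical and Cn symmetry

Subunit *k* of a filament is placed at `Rz(k·twist)·x + (0,0,k·rise)`.
The inverse operation, `fit_screw_transform()`, is a Kabsch
least-squares superposition (determinant-corrected SVD with
deterministic column-sign fixing, proper rotations enforced) decomposed
into rotation angle, screw axis, and translation along the axis; the
axis point solves the rank-2 system `(I − R)p = t⊥` by least squares.
`fit_helical_parameters()` fits all consecutive pairs, canonicalizes
each to the +z convention, and averages — circular mean for angles to
avoid wrap-around bias, arithmetic mean for the rise.  Pairs deviating
more than 0.5°/0.5 Å from the mean raise an error naming them; a pair of
identical subunits is flagged degenerate rather than fitted.  The
180°-rotation decomposition is ambiguous in axis sign; a deterministic
first-nonzero-positive convention is applied there.

Cn rings (`build_cn_ring()`) only rotate a pre-placed subunit about +z
in steps of 360/n: the C13 secretin step displays as 27.7°, the C6
motor-ATPase platform as 60.0°.  `step_deg` is stored as the exact
quotient; only display rounds to one decimal.

## Glycan model

The glycosylation maps are fixed by the observed chemistry: the wide
filament carries a trisaccharide H-N-N at S59, a single GalNAc (N) at
S66 and the tetrasaccharide W-H-N-N at S71 (8 monomers per subunit); the
narrow filament carries W-H-N-N at S73 (4 per subunit).  Codes: N =
α-GalNAc, H = hexose (modelled as Man), W = the pseudaminic-acid
derivative 5Am7Ac kept as its own code (it needs no force-field
substitute here, since grafting is purely geometric), X = an unassigned
346 Da monosaccharide sharing the same template.  Topologies are written
from the non-reducing end (W-H-N-N-Ser); the chain builder grows from
the serine end.

Monomer geometry is deliberately idealized: a planar hexagon of radius
1.4 Å — five carbons plus exactly one ring oxygen, named `O5` — with a
glycosidic link pseudo-atom 1.43 Å from the centre and consecutive
monomer centres 5 Å apart.  The steric statistic below depends only on
ring-oxygen positions, so higher chemical detail would not change any
result computed here; linkage labels (α(1-3), α(1-4)) are carried as
annotations only.

Grafting is rigid placement into a local backbone frame
(`attachment_frame()`): origin at the serine Cα, `e1` along Cα→N, `e2`
the Gram-Schmidt completion of Cα→C, `e3 = e1×e2`.  Conformers and
idealized chains anchor at a fixed O-γ offset (2.4 Å from Cα, the
canonical serine Cα–Oγ distance) expressed in that frame.  No torsional
relaxation is applied to clashing conformers: a conformer is accepted or
rejected as a rigid body, which keeps the rejection statistic
well-defined.

## The steric accommodation statistic

A grafted conformer is rejected when any selected glycan atom comes
closer than a threshold distance to any selected environment atom.  The
default pairing is protein α-carbons against glycan ring oxygens with
thresholds 3.25 Å or 3.75 Å — the pair of settings standardly used to
mimic lower and higher filament stiffness — and distance exactly at the
threshold counts as accepted (the convention is stated nowhere
authoritative, so one choice is documented here).  An all-heavy-atom
option exists for sensitivity analysis.  The attachment residue's own
atoms are excluded from the environment of its site: they are always
within bonded distance of the first monomer and would otherwise reject
everything.

`steric_accept()` prunes the environment with an axis-aligned bounding
box expanded by the threshold; any pair closer than the threshold
survives pruning, so decisions are exactly those of the all-pairs
evaluation (the test suite asserts this equivalence against an explicit
brute-force oracle).  `site_acceptance()` evaluates a seeded,
without-replacement subsample (default `min(M, 1000)`) of a conformer
library at one site; `accommodation_profile()` pools accepted/total
counts over all (subunit, site) instances into axial bins of 5 Å by
default (the appropriate bin width depends on the rise; profiles at one
site per bin are obtained by setting the bin width to the rise).  Each
site instance derives its own sub-seed deterministically from the
profile seed, so profiles are byte-reproducible.  Empty bins are
reported as NA, never interpolated.  Per-site rows are returned
alongside the pooled bins because pooling convention varies between
studies; both views are serialized to TSV with the threshold and seed in
a header comment.

`aperture_profile()` reports, per axial bin, the minimum radial distance
of channel atoms from the axis — the local clearance of the lumen.

## Synthetic generators

The generators emulate the geometric structure the analysis assumes,
not the proteins themselves; they are first-class, tested code.

* **Subunit** (`make_synthetic_subunit()`): backbone-only (N, Cα, C per
  residue, Oγ at site serines), an idealized α-helical N-terminal
  segment plus a globular head traced on concentric shells, offset from
  the filament axis, rescaled so the bounding-sphere diameter equals the
  configured width — default 30 Å, the approximate pilin subunit width.
  Residue counts default to 125 (wide-like) and 111 (narrow-like),
  matching the per-subunit residue counts of the two refined filament
  models, so that 45 and 31 copies give 5625 and 3441 residues.  A 0.3 Å
  seeded jitter makes different seeds distinct rigid bodies.  Side
  chains beyond the site Oγ are omitted: the default steric criterion
  only sees Cα and ring oxygens.
* **Conformer library** (`sample_conformer_library()`): self-avoiding
  random chains of monomer templates — uniform random step directions at
  fixed 5 Å step length, 4 Å minimum distance between non-adjacent
  centres, bounded retries then restart.  This stands in for an
  MD-derived ensemble with a documented, reproducible distribution; it
  does not reproduce MD torsion statistics, so accommodation fractions
  are properties of this ensemble, not predictions for a specific
  chemistry.  Default library size M = 500.
* **Channel** (`make_channel()`): a pseudo-atom cylinder with one
  Gaussian constriction, `R(z) = R₀ − δ·exp(−(z−z₀)²/2σ²)`, rings every
  2 Å and wall atoms 2 Å apart along each ring, flagged as Cα so the
  default criterion sees them.  Defaults R₀ = 40 Å (secretin-lumen
  scale), δ = 15 Å, σ = 10 Å, length 100 Å.  The single-Gaussian family
  is the minimal shape with a known ground-truth aperture minimum.

All generators are pure functions of their configuration; the subunit
and library consume a fixed RNG stream under `with_seed()`, the channel
draws no random numbers.

## Numerical choices and degenerate inputs

* Kabsch superposition needs ≥3 non-collinear atoms; reflection-optimal
  cases are forced to proper rotations with a warning.
* Rotation-angle recovery uses the trace formula with clamping; angles
  below 1e-9 rad are treated as pure translations.
* PDB output uses strict fixed columns (occupancy 1.00, B-factor 0.00,
  element column populated) and is byte-deterministic; coordinates
  outside the %8.3f range are refused rather than silently mangled.
  Conformer libraries serialize as MODEL/ENDMDL blocks.  Ring oxygens
  are recognised on re-reading by the `O5` name within glycan residues;
  a per-monomer name table can be supplied when loading externally
  deposited glycans with other conventions.
* Empty glycan selections accept with infinite clearance; an empty
  channel is an error for aperture profiling.

## What the tests show — and what they do not

The test suite verifies the machinery under the synthetic study
conditions: stoichiometry (5625/360 wide, 3441/124 narrow), exact
round-trip recovery of twist/rise (both filament forms and a random
parameter sweep), Cn ring invariance, exact agreement of the pruned
steric evaluation with brute force, a closed-form limit (single-atom
conformers uniform on a sphere of radius 10 Å inside a dense 12 Å
cylinder accept with probability `1 − sqrt(1 − ((R−t)/r)²) ≈ 0.516` at
t = 3.25 Å, matched within 3 standard errors at M = 10,000), and
monotonicity of acceptance in threshold, environment size and channel
radius, with the rejection peak co-located with the generated
constriction.  Problem sizes in the routine suite are kept small (3–10
subunit filaments, libraries of 20–200 conformers, 10,000 draws for the
Monte-Carlo limit) — sufficient for the properties tested, and chosen so
the whole suite runs in well under a minute of compute per module.

Passing these tests does **not** show that accommodation fractions for
real deposited filaments are reproduced: that computation requires the
deposited coordinates and MD conformer arrays (supported as external
inputs via `read_pdb()`), and ensemble-dependent numbers such as the
published ~50% narrow-filament accommodation are outside what the
synthetic ensemble can pin down.

## Known limitations

No force-field or free-energy scoring, no solvent, no electrostatics,
no intra-conformer flexibility; mmCIF, altlocs and insertion codes are
out of scope; the biological interpretation of constrained glycans
(e.g. extension after extrusion) is deliberately not computed.
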