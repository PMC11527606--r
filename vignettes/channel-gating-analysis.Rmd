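---
title: "Methods: quantifying channel gating and permeation from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying channel gating and permeation from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
```

This vignette documents the models, parameter choices and numerical
conventions behind `poregate`, in the spirit of a methods section: what
each statistic assumes, which knobs matter, what the synthetic
generator does and does not emulate, and where the design was genuinely
open.

## Coordinate model and conventions

All coordinates are Ångström. The pore axis is z, with the
extracellular side at larger z — the same orientation as an applied
transmembrane field driving cations inward. Inputs are assumed
whole-molecule imaged; nothing here unwraps periodic images, because
every statistic is distance-based and a channel that needs unwrapping
would already have produced nonsense gate distances. Alignment is
always explicit: `superpose()` is exported, and the analyses that need
a common frame (RMSF, PCA, DCCM) superpose internally onto the window
mean, iterated twice so the mean and the fit are self-consistent (the
mean shift after the second pass is far below 1e-4 Å for any realistic
ensemble).

Frames and atom indices are 0-based in every public interface; residue
numbers are preserved from the source file (author numbering), because
published residue labels (e.g. an HBC phenylalanine) are what users
must be able to type. Residue identity is (chain, resid, insertion
code); cross-system matching uses (chain, resid, resname).

## Gate aperture

A gate is one residue per subunit. Published "average minimum gate
distance" traces rarely state the pairing rule, so it is explicit and
configurable here:

* `diagonal` (default): mean over the two trans-pore diagonal pairs
  (chains 1–3 and 2–4) of the minimum inter-atomic distance. Diagonal
  pairs are the default because the physical constriction of a
  C4-symmetric pore is trans-pore, not between neighbours.
* `adjacent`: mean over the four neighbouring pairs.
* `global_min`: minimum over all six inter-subunit pairs.

`atom_scope` defaults to side-chain heavy atoms — for an HBC gate the
phenyl ring defines the constriction, not the backbone — and falls back
to Cα when a residue has no side-chain heavy atoms (coarse models).

`open_fraction()` uses a strict inequality at the cutoff and counts
ties as closed; a conservative convention that matters only for
degenerate synthetic traces sitting exactly at the cutoff. The default
cutoff of 5.69 Å is the published open/closed aperture threshold for
inwardly rectifying K⁺ channel gates and applies to both the HBC and
G-loop gates; it is a parameter everywhere.

## Permeation counting

A completed event is positional: the ion passes the SF entrance, the
SF/cavity boundary, the HBC and the G loop in order, judged purely from
z-boundary crossings — not from instantaneous gate aperture, which is
reported separately. Each boundary is the per-frame centroid z of an
anchor residue selection, so breathing of the protein moves the
boundaries with it. The pore axis is the per-frame centroid of the
channel Cα atoms.

Two guards make counting robust to thermal jitter:

* **hysteresis** (default 2.0 Å): a crossing only fires once the ion
  clears a boundary by this margin, and the machine re-arms only after
  the ion returns above the entrance by the same margin;
* **radial cutoff** (default 10.0 Å): transitions count only while the
  ion is within this distance of the pore axis, so ions diffusing past
  the channel in bulk never register.

Neither value is published for the reference analyses; both were chosen
so that boundary-level noise far below the hysteresis cannot
double-count, and both are configurable. Ions that start inside the
pore adopt the state matching their position but earn no event credit
until an entrance crossing is observed in-window — no credit for
partial paths. Within a single frame the machine may cascade through
several boundaries, so fast scripted crossings and strided reads give
identical counts. The int→ext direction runs the mirrored machine;
frame-reversing a trajectory exactly swaps the two directions' counts,
which the tests assert.

Dwell attribution uses the nearest heavy atom of any candidate residue
(not Cα), because ions coordinate side chains; the assignment cutoff
defaults to 6 Å and ties break deterministically to the lower
(chain, resid).

## Interaction networks

The reference analyses name the tool they used but not its geometric
criteria, so the defaults here are the field's conventional values,
documented as such and all configurable: salt bridge basic-N to
acidic-O ≤ 4.0 Å; hydrogen bond donor-heavy to acceptor ≤ 3.5 Å with a
donor–H⋯acceptor angle ≥ 135° (any hydrogen of the donor may satisfy
it); hydrophobic side-chain carbon–carbon ≤ 4.5 Å. "Formed" is
any-atom-of-group, not a specific atom pair. Histidine counts as basic
only in its protonated forms (HIP/HSP atom names), since protonation is
assigned upstream of any trajectory analysis. Intra-residue and
backbone-adjacent (|Δresid| ≤ 1, same chain) pairs are excluded. Pair
keys carry chain ids, making inter-subunit pairs (the interesting ones
in a tetramer) first-class.

Fractions are per analysis window. Differences are Δ = holo − apo over
the union of pair universes with missing entries read as zero, so a
contact present only in the apo system appears with a negative Δ — the
sign convention of published comparison heatmaps.

## Collective dynamics

RMSD/RMSF are standard Kabsch-superposed quantities. The DCCM uses Cα
displacement dot products — the standard estimator — normalised per
pair; zero-variance residues yield 0 with a warning rather than NaN.

One property deserves emphasis because it bounds what "recovering a
planted correlation" can mean: **rigid-body superposition removes the
common-mode component of any correlated motion.** Two residues that
genuinely move together carry net translation/rotation, and the
least-squares fit absorbs a fraction of order m/N of it (m moving among
N fitted atoms). This is intrinsic to every DCCM, not an artefact of
this implementation. The synthetic generator therefore (a) displaces
correlation-planted residues along the pair's in-plane separation axis,
which minimises coupling into the rotational modes, and (b) the
recovery fixtures use a 24-residue-per-subunit channel (96 fitted Cα),
keeping the systematic shrinkage at ≤ ~0.03 — within the ±0.05 recovery
tolerance the tests enforce. A larger real channel (hundreds of
residues per subunit) makes the effect proportionally smaller.

Combined PCA concatenates the two windows, superposes everything onto
the iterated joint mean, and eigendecomposes the 3N covariance.
Eigenvalues are clipped at zero (symmetric eigensolver round-off);
their sum equals the ensemble variance to < 1e-6 relative, asserted
against an independent two-pass variance computation. Morph export
interpolates mean ± 2 SD of the projection in six steps, the
conventional red-to-blue rendering.

Torsion summaries are circular throughout: mean = atan2 of mean sines
and cosines, SD from the resultant length. The package-level test that
{+179°, −179°} averages to 180° (never 0°) is the reason this is not
negotiable — several published "average ψ" values sit near ±180°, where
an arithmetic mean is meaningless. Chain termini omit their undefined
angle; residues missing backbone atoms are skipped with a warning.

## The synthetic generator: a stated world

`generate_trajectory()` builds a toy C4-symmetric tetramer — beads, not
atoms; kinematics, not physics. Its purpose is to make every analysis
falsifiable, so each planted quantity is realised *exactly*:

* gate side-chain beads sit at radius d(t)/2, so the diagonal minimum
  distance equals the schedule to machine precision;
* scripted ions interpolate z waypoints exactly (noise is lateral only
  and clipped inside the pore), so hysteresis margins guarantee exact
  event recovery;
* contact frames are sampled without replacement to hit
  `round(f · n_frames)` formed frames exactly, with formed/broken
  distances clearing the criteria cutoffs by ≥ 0.5 Å;
* correlation pairs use the shared-signal construction
  d_i = a·s(t) + e_i with a² = |ρ|, σ² = 1 − |ρ|, whose analytic
  Pearson correlation is ρ;
* torsion-planted backbones are built by internal-coordinate (NeRF)
  construction, exact at zero jitter;
* the `breathing_plan` radial mode is C4-symmetric and therefore
  orthogonal to all rigid-body modes — the planted single-mode PCA
  fixture survives superposition exactly.

All randomness flows from one integer seed through a documented
splitting scheme (a string-tagged hash per consumer), so identical
inputs give byte-identical output.

What the toy world does **not** emulate — and hence what a green test
does not establish: force fields, water and membrane, realistic
side-chain packing (one bead per functional group), SF site-by-site ion
coordination, and z-direction thermal noise on ions. Recovery being
exact here says the *bookkeeping* is correct; tolerances on real
trajectories are dominated by physics, not by these algorithms.

Default geometry, chosen once: 16 residues per subunit; backbone ring
at pore radius + 4 Å; residue ladder from z = +30 Å (extracellular) to
−45 Å with the SF at 15–25 Å, the HBC at 0 and the G loop at −15 Å —
proportions that mirror a real inward-rectifier pore (SF near the
extracellular mouth, HBC mid-membrane, G loop in the cytosolic domain);
5 Å vertical residue spacing keeps filler beads from forming accidental
contacts at the default cutoffs.

## Pipeline and determinism

`run_analysis()` takes one JSON config (YAML is deliberately not
supported: no YAML parser is available in the supported dependency set,
and JSON loses nothing here). Each analysis runs isolated under
`tryCatch`; one corrupt trajectory yields an error entry and a bundle
for the remaining systems. The run log records per-analysis status, row
counts and wall time; the summary carries the seed and a config
fingerprint. Re-running an identical config produces byte-identical
tables, which the tests hash-compare.

## Known limitations

* XTC reading shells out to the system `python`/MDAnalysis (the
  compressed-coordinate codec has no R implementation); PDB and DCD are
  native. No AMBER NetCDF.
* No pore-radius profiles (HOLE-style), no SF S0–S4 site decomposition,
  no hinge/domain segmentation, no free-energy or electrostatic maps —
  all out of scope by design.
* Published headline counts from microsecond all-atom runs (tens of
  permeation events, occupancy percentages) are not reproducible at
  desk scale and are not claimed; the acceptance battery checks the
  self-contained worked examples and exact recovery on the synthetic
  stated world instead.
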