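---
title: "The four-distance knowledge-based potential: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-distance knowledge-based potential: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`rotapack` scores protein structures with a statistical potential whose
central object is a *four-distance* description of a residue–residue
interaction. For every residue type pair, two heavy atoms are fixed per
residue, and an interaction is the quadruple `{d11, d12, d21, d22}` of
distances between atom *i* of the first residue and atom *j* of the
second. Compared with a single distance between reference points, the
quadruple captures mutual orientation: a hydrogen-bonded amide pair and
a stacked one have similar centroid distances but very different
quadruples. Two residues count as contacting when at least one of the
four distances is below 5 Å (strict). The contact atoms themselves are
chosen empirically ("Atom Set 1", `select_atom_pairs()`): for each type
pair, the combination with the maximal contact count over a corpus, with
lexicographic atom-name order as the deterministic tie-break.

Quadruples harvested from a corpus are binned into a 4-D histogram
(`build_histogram()`), normalized to probabilities, and compared with the
same quantity from a *randomized reference state*: each corpus structure
with every side chain rebuilt from a rotamer drawn uniformly from its
backbone-dependent library group, ignoring probabilities and clashes
(`randomize_side_chains()`). Clashes in the reference are harmless by
construction — an overpopulated clashing bin in the reference only makes
clashing geometry score worse in the ratio. The side-chain–side-chain
term is the inverse-Boltzmann log-ratio summed over unique contacting
pairs; the side-chain–main-chain term repeats the construction against
the backbone (O, N) pair of partner residues. Both contact terms assume
the corpus is representative and treat contacts as independent — the
usual pair-potential approximations.

Two physical terms complete the potential: a rotamer probability term
`−Σ ln(N_i p_i)` (zero for a uniform group; negative for
better-than-uniform choices), and a 12-6 Lennard-Jones term over 20
heavy-atom classes with geometric-mean well depths and additive radii,
whose repulsive branch is replaced by its tangent line below
0.89·r_min so that hard clashes during optimization are penalized
linearly rather than astronomically. The weighted total (defaults 0.13,
0.13, 0.33, 0.41) is the packing objective: lower is better, and a
native structure should score below its decoys.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| contact cutoff | 5 | Å | longest distance at which real and reference contact statistics still differ appreciably |
| histogram bin | 0.5 | Å | finer bins are noise-limited at desk-scale corpus sizes; coarser bins blur the geometry |
| histogram range | 0–10 | Å | covers every distance a 5 Å-triggered contact can produce; larger values clamp into the last bin rather than dropping the contact |
| smoothing | 3⁴ box mean | – | isotropic in all four distances; boundary-truncated and renormalized |
| probability floor | 1/(10·N_pair) | – | keeps empty-bin penalties finite and scaled to how much data the pair has |
| LJ linearization | 0.89 | ·r_min | tangent-line continuation; value and slope continuous |
| LJ evaluation cutoff | 10 | Å | beyond this the 12-6 terms are negligible for these radii |
| MCSA schedule | 100 × 10 000 | steps × moves | starting T doubled until 95 % acceptance, linear cooling to zero, then greedy quench |
| rotamer extension | ±1σ, 3ⁿ | – | discrete normal weights exp(0):exp(−½):exp(−½) at {−σ, 0, +σ} |
| library reduction tail | 0.03 | cum. prob. | drops the largest low-probability suffix, keeps ≥1 rotamer |
| burial threshold | 0.2 | rel. accessibility | side-chain SASA (1.4 Å probe) relative to an extended Gly-X-Gly maximum |

All of these are function arguments; the LJ class table and per-class
parameters are editable TSV configs shipped under `inst/extdata/`.

## Design choices where the design was open

* **Smoothing neighbourhood.** "Adjacent bins" is implemented as the
  full Chebyshev-1 neighbourhood (3⁴ cells) with boundary truncation and
  renormalization — isotropic in the four distances, unlike an
  axis-cross kernel.
* **Ala in ScSc pairs.** A two-atom side-chain pair is impossible for
  Ala (one heavy atom); its pair is (CA, CB), which preserves the full
  set of 190 ScSc types with only Gly excluded. Ala stays out of the
  ScMc family (18 types).
* **ScMc backbone pair.** The backbone side of an ScMc interaction is
  (O, N) of the partner residue: the two hydrogen-bonding backbone atoms,
  and the pair that best distinguishes approach direction.
* **Sequence neighbours.** Contacts between residues i and i±1 of the
  same chain are excluded from statistics and scoring: their geometry is
  dictated by covalent structure, not interaction preference.
* **Homo-pair symmetry.** Homo-type histograms accumulate both residue
  orderings of each contact, so stored tables — and therefore scores —
  are invariant to residue enumeration order.
* **Rotamer term form.** `−ln(N p)` rather than `−ln p`: the uniform
  reference zeroes the term for uninformative groups, and since `N` is
  fixed per position the two differ by a constant that cannot affect
  optimization.
* **LJ exclusions.** Same-residue pairs, backbone–backbone pairs
  (constant under side-chain packing), and the two 1-4 paths across the
  peptide bond (CBᵢ–Nᵢ₊₁ and Cᵢ–CBᵢ₊₁) are excluded.
* **Off-rotamer sampling.** The ±5° single-χ perturbation is provided as
  an exported building block (`off_rotamer_step()`) with exact inverse
  semantics, but the default MCSA loop stays rotamer-discrete: the
  energy decomposition that makes moves O(n) is a table over library
  rotamers, and continuous excursions would forfeit it for marginal
  accuracy gains.
* **Statistics container.** Tables serialize to a single versioned RDS
  file with real/random/meta groups and a bit-exact round trip
  (`save_tables()` / `load_tables()`).
* **Burial.** There is no single standard burial criterion; the package computes
  Shrake–Rupley SASA with a deterministic golden-spiral sphere and
  classifies side chains at ≤20 % of their extended Gly-X-Gly maximum,
  computed at run time with the same machinery (self-consistent radii).

## Numerical choices

Dihedrals follow the IUPAC sign convention and are built/measured by an
internal-coordinate (NeRF) constructor; a build–measure round trip is
exact to well below 0.01°. Side-chain topologies use ideal bond lengths
and angles; six-membered rings are exact hexagons so that a 180° χ₂ flip
maps Phe/Tyr rings onto themselves and symmetry-aware RMSD is exactly
zero for name-swapped rings. Histogram smoothing is computed separably
(per-axis truncated box sums for numerator and neighbour counts), which
is exact for the hypercube kernel. Temperature zero in the final MCSA
steps degenerates to accept-improvements-only, and quenching terminates
on a full pass with no single-rotamer improvement. Ties everywhere break
deterministically (lexicographic atom names; lower library index). Every
stochastic path takes a seed and restores the caller's RNG state.

## What the synthetic generators emulate — and what they do not

The fixtures build ideal-geometry backbones (helix −57/−47, extended
−135/135), library-built side chains, planted-geometry corpora in which
a chosen atom-pair quadruple is realized exactly (signal) or drawn
uniformly from the geometrically compatible region (noise), and decoy
sets (side-chain scrambles, optionally backbone-perturbed). They are
deterministic per seed and return their ground truth.

The planted-corpus defaults were chosen once, on geometric grounds. The
target quadruple (2.25, 3.25, 2.25, 3.25) Å sits at bin centres and well
inside the feasibility region, and the signal jitter is σ = 0.15 Å.
With 0.5 Å bins, a much smaller jitter concentrates essentially all
signal strictly inside one cell; the box-mean smoother then assigns the
planted cell and each of its 80 neighbours nearly identical values (each
neighbourhood contains the same mass), and the argmax of the smoothed
histogram is decided by noise-level ties. At σ = 0.15 the signal leaks
a few percent past each bin edge in both directions, which every
shifted neighbourhood loses on its far side — the planted cell's value
then strictly dominates and the smoothed argmax is a stable property
rather than a coin flip.

What passing these tests shows is that the machinery — selection,
extraction, binning, smoothing, reference randomization, scoring,
annealing, metrics — is correct and self-consistent. What it does not
show is accuracy on real proteins: ideal geometry has no crystallographic
noise, no truncated side chains, no alternate conformations, and the toy
rotamer library is far smaller than a real backbone-dependent library.
Corpus-scale statistics (thousands of structures, millions of contacts)
are the regime the method is designed for and are beyond a test suite;
the test corpora use 4–1000 small structures, packing problems of ≤6⁴
assignments are verified against exhaustive enumeration, and the
annealer's test configuration scales the schedule down (15–25 steps of
60–150 moves) to match those problem sizes.

## Known limitations

* Proline is packed from its library χ values; ring closure is
  approximate (no flap refinement).
* The randomized reference uses one randomized copy per corpus structure
  by default (`n_random` is configurable); very small corpora therefore
  have noisy reference distributions.
* The LJ class table is a chemically motivated default; the class
  definitions the potential was originally parameterized with are not
  recoverable, so `calibrate`-family functions exist to refit radii and
  weights against a user's own corpus.
* `read_structure()` reads PDB only (no mmCIF), drops hydrogens and
  HETATM records, and resolves altlocs to the highest-occupancy
  conformer.
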