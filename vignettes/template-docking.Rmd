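---
title: "Template docking by binding-site motif congruence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template docking by binding-site motif congruence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifdock)
```

## The model

motifdock implements *soft* docking: the binding geometry of a ligand is
not searched, it is copied from a known protein–ligand complex (the
holoenzyme) into a target protein whose site is spatially and
electrostatically congruent with the template's. The working hypothesis is
the one underlying active-site comparison generally — that a few side-chain
atoms in a particular spatial and electrostatic arrangement are what binds
the ligand, and that the same arrangement elsewhere will bind it too. The
method stands or falls with that hypothesis: it cannot dock into a site
that has no congruent template, and it never adjusts ligand or receptor
conformation.

The pipeline has four stages.

**Contact motif extraction.** The extractor collects the `n` protein atoms
closest to any ligand atom, growing a search radius from 2.5 Å in 0.1 Å
steps. A contact is accepted only if the protein/ligand element pair is
non-hydrophobic — the accepted list is O–N, N–O, O–H, H–O, O–O, N–N, N–H,
H–N, S–H, H–S on element classes — and only the closest atom of each
residue is kept. Hydrogens are normally stripped on parsing, so in
practice O/N/S pairings carry the motif. Processing within a radius shell
is by ascending exact distance with ties broken by (chain, residue number,
atom name), which makes the whole schedule equivalent to sorting all
accepted pairs by distance, deduplicating by residue and taking the first
`n` — the brute-force oracle the test suite checks against. The schedule
stops at 8 Å: anything farther is not a binding contact, and an incomplete
motif is reported as an error rather than padded.

**Motif features.** Each contacting residue is then represented by a
*designated functional atom* (Ser OG, Thr OG1, Asp OD1, Glu OE1, Tyr CZ,
Trp CZ2, Lys NZ, Arg NH1, His NE2, Asn OD1, Gln OE1, Cys SG, Phe CZ).
This matters: a tyrosine hydrogen-bonds through OH, but OH's position
depends on the hydroxyl rotamer, while CZ is a stable proxy for the ring's
position — and, crucially, the precompiled database on the target side can
only designate one atom per residue, so query and candidate must use the
same designation to be comparable. A motif of `k` atoms is characterised
by its pairwise distance matrix (Å) and pairwise potential-difference
matrix PD (kT/e), `PD[i,j] = phi(i) - phi(j)`, which is antisymmetric by
construction. From the `n = 5` contacts, all `choose(5, 4) = 5` sub-motifs
of size `k = 4` are enumerated and each is searched independently; a
partial motif can match where the full one does not, e.g. when one contact
residue has no counterpart in the target.

Where do the potentials come from? Absolute Poisson–Boltzmann potentials
depend on grid, dielectric and ionic-strength settings that differ between
runs, so the package treats potentials as pluggable: an OpenDX scalar grid
(the APBS output dialect) interpolated trilinearly at atom positions, a
per-atom table, or a built-in screened-Coulomb surrogate

$$\phi(i) = \sum_{j \neq i} \frac{q_j\, e^{-\kappa r_{ij}}}{\epsilon_r\, r_{ij}}$$

over a minimal formal-charge table (Asp/Glu −1 split over the carboxylate
oxygens, Lys +1 on NZ, Arg +1 split over NH1/NH2, His neutral). The
surrogate is not a Poisson–Boltzmann solution and is not meant to
reproduce one; it provides fields with correct sign structure, ordering
and rigid-motion invariance so the electrostatic scoring path is fully
exercisable without an external solver. Defaults: κ = 0.1 Å⁻¹, ε_r = 10,
self-exclusion 0.1 Å; all configurable.

**Congruence search.** On the target, one designated atom per residue of
the allowed types is collected and every `k`-subset with all pairwise
distances ≤ 15 Å is precompiled (the enumeration is exhaustive; the test
suite checks the count against brute force). Each candidate is tested
position-by-position against the query's *stereochemical groups* — the
default scheme pools {Asp, Glu}, {Asn, Gln}, {Ser, Thr}, {Lys, Arg},
{Tyr, Trp, Phe}, {Gly, Ala}, leaving His and Cys strict — and every
group-compatible ordered arrangement is scored:

$$\mathrm{CScore} = \sum_{i<j} \frac{|D_q(i,j) - D_c(i,j)|}{D_q(i,j)}
  \;+\; \lambda \sum_{i<j} g\!\left(\Delta PD_{ij}\right),
\qquad \Delta PD = \bigl||PD_q| - |PD_c|\bigr|$$

with `g(x) = 0` for `x < 100` kT/e and `(x − 100)/max(|PD_q|, 100)` above.
The distance term is normalised by the query distance, so the same absolute
deviation costs more on a short reference distance; the potential term
ignores deviations below a 100 kT/e dead-zone and constrains large
reference PDs more loosely than small ones, reflecting how noisy computed
potentials are at high magnitude. The score is zero for a self-match and
matches scoring above `s_thresh` (default 5) are discarded, survivors
ranked ascending. Two spatial metrics qualify each match: the
least-squares superposition RMSD of the two atom sets (Kabsch, proper
rotations only) and the maximum pairwise distance deviation. The second is
the sharper discriminator — averaging can hide a single badly displaced
atom that the maximum exposes.

**Rigid transplantation.** Three matched anchor atoms define the canonical
frame: anchor 1 at the origin, anchor 2 on the +Y axis, anchor 3 in the
Z = 0 plane with positive X. Holoenzyme and target are transformed into
this frame each by its *own* anchors, which unifies the two coordinate
systems; the ligand follows the holoenzyme's transform, and by default the
pose is mapped back through the inverse of the target's transform so it
lands in the target's original coordinates. The positive-X convention for
the third anchor forbids reflections — a mirror image would superpose
anchors equally well but invert the ligand's chirality, which is never
acceptable for a molecule. A `k`-point least-squares (Kabsch) anchoring is
available as an alternative when more than three positions matched well.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `n_contacts` | 5 | atoms | contact motif size extracted from the holo site |
| `k` | 4 | atoms | sub-motif size searched in the target |
| radius schedule | 2.5 + 0.1·t, cap 8 | Å | contact search shells |
| `cutoff` | 15 | Å | max pairwise distance inside a database motif |
| `s_thresh` | 5 | – | CScore acceptance threshold |
| `lambda` | 1 | – | weight of the electrostatic term |
| `deadzone` | 100 | kT/e | PD deviation ignored below this |
| `kappa`, `eps_r` | 0.1, 10 | Å⁻¹, – | surrogate screening and dielectric |
| clash cutoff | 2.0 | Å | heavy-atom distance counted as a clash |

The 15 Å cutoff comfortably exceeds the diameter of hydrogen-bonding
binding-site motifs (typically under 13 Å); raising it grows the database
combinatorially while admitting only biologically implausible motifs. The
threshold `s_thresh = 5` is permissive — with four atoms and six pairs, it
tolerates an average relative distance deviation above 80 % — so in
practice ranking, not thresholding, does the discrimination.

## Apo versus holo templates

Ligand binding perturbs the site, spatially and electrostatically — the
same four atoms can move by >1.5 Å between the unbound and bound forms of
the same enzyme. The pipeline therefore takes the *query features*
(distances, PDs) from the apo structure when one is supplied, because the
target being queried is itself unbound; the *superposition anchors* always
use holo coordinates, because that is the frame the ligand actually sits
in. Both structures must share residue numbering. When no apo form exists
the holo structure serves both roles, with the understanding that the
query is then biased toward the bound-state geometry.

## Strict versus reporting contacts

The extraction whitelist excludes carbon on either side. Published contact
tables, however, routinely list protein carbon partners (CZ, CD2, CE1) for
polar ligand atoms. The package keeps both rules explicit:
`mode = "strict"` is the extraction rule; `mode = "reporting"` accepts any
contact whose *ligand* atom is N, O or S, and is what pose reports use.
Strict output is a subset of reporting output at the residue level.

## What the fixtures emulate — and what they do not

`make_binding_fixture()` builds a pseudo-protein of single-side-chain
residues: each residue is a CA plus its designated functional atom (plus
the polar contact atom where the two differ, as in Tyr OH/CZ). Binding
residues are placed with contact atoms at 2.6–3.4 Å from ligand polar
atoms — the hydrogen-bond ladder — in rejection-sampled outward directions
that keep residues from overlapping each other or the ligand; background
residues sit on a 16–22 Å shell, outside any contact radius. The target is
a rigidly moved copy, optionally with group-compatible substitutions
(Glu→Asp), so the true transform, true motif and true docked coordinates
are known *by construction*, not estimated.

This buys exact ground truth at the price of realism: there is no
backbone, no rotamer variability, no induced fit, no crystallographic
noise, no solvent. A passing suite therefore demonstrates that the
algorithms are implemented correctly — extraction matches its oracle,
enumeration is complete, scoring is exact on its formula, transplantation
is rigid to 10⁻⁶ Å — not that the method will find the right site in a
real proteome. That judgement rests on the regression tests against
published archive structures, which require network access to the PDB and
reproduce published contact distances, the apo/holo site perturbation, a
cross-family motif match and a transplanted pose sharing the native
ligand's contact residues.

## Numerical choices

* **Alt-locs** collapse to the highest-occupancy conformer, ties broken by
  alt-loc letter; downstream geometry needs a single conformer. Waters and
  hydrogens are dropped on parse (flags retain them). Model 1 of
  multi-model files is used.
* **Ties in contact order** break by (chain, residue number, atom name),
  making extraction deterministic.
* **Degenerate geometry** errors rather than warns: zero query distances in
  CScore, coincident or collinear anchors in the frame construction.
* **Rotations** are proper by construction (det = +1 within 10⁻⁹);
  reflections are rejected in the Kabsch branch by sign correction.
* The **canonical frame of canonical points is the identity** to 10⁻⁹, and
  every transform preserves pairwise distances to well under 10⁻⁶ Å; both
  are asserted as properties.
* `bio3d::rmsd()` rounds to three decimals, so superposition RMSD is
  computed from the package's own Kabsch transform at full precision
  (bio3d still handles all PDB reading and writing).
* PDB output carries three decimals; round-tripped coordinates are equal
  to 5 × 10⁻⁴ Å, and tests that pass through files use tolerances above
  that floor.

## Open design points, as decided here

* **Threshold direction.** The acceptance rule is keep-if-`CScore ≤
  s_thresh` on a smaller-is-better score; survivors are ranked ascending.
* **Anchor RMSD.** The three-point frame alignment is not a least-squares
  fit, so its anchor residual can exceed the optimal RMSD. Poses report
  both: `anchor_rmsd` (least-squares, comparable with the search metrics)
  and `frame_rmsd` (residual of the alignment actually applied).
* **Order-preserving matching only.** Candidate position *p* answers query
  position *p*; permutations of the candidate atoms are generated, but a
  candidate is never matched against a reordered query. This keeps the
  group test per-position and the scoring unambiguous.
* **One atom per residue** in the contact motif: a residue contacting
  through two atoms contributes only its closest, since the motif is meant
  to enumerate residues, not interactions.
* **Multi-copy ligands** (two copies of the same het code in one file)
  must be disambiguated explicitly by chain or residue number; the
  selector lists candidates instead of guessing.
* **Close contacts in poses.** Transplanted poses can place ligand atoms
  closer to the target than physical hydrogen bonds allow (the price of
  rigid transfer between non-identical sites). The clash report flags
  such poses — count of heavy-atom pairs under 2 Å and the closest
  approach — but does not reject them; that decision belongs to the user.

## Problem sizes

The test suite and the acceptance script run on fixtures of 10–20 residues
(oracle-equivalence over 100 random fixtures, database completeness on 12
residue structures, 10 random docking recoveries), sizes at which the
brute-force oracles — all-pairs sorting, `combn` enumeration, exhaustive
ordered-arrangement scoring — are exact and fast. The algorithms have no
size-dependent branches, so correctness at these sizes carries to larger
structures; the database builder's clique enumeration is the only
combinatorial step and is bounded by the distance cutoff in practice.

## Known limitations

The method requires a solved complex of the ligand (or a close analogue)
and inherits its conformation wholesale: flexible ligands that adapt to
each site — long polysulfonated molecules being an extreme case, with
maximum intra-ligand spans differing by several Å between complexes — are
transplanted in the template's conformation, which may not fit the target.
`max_intraligand_distance()` quantifies that span so the user can judge.
There is no energy model: ranking is congruence-only, and a pose docked
onto a surface patch that happens to be congruent will not be penalised.
Electrostatic scoring with the surrogate is qualitative; for quantitative
PD comparisons supply solver-computed grids on both sides with matched
settings.
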