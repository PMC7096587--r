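---
title: "Nominating substrate-specificity residues: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating substrate-specificity residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpfinder)
```

## The problem

Enzyme families such as the gibberellin oxidases (GAOX) split into
functional classes (GA20OX, GA3OX, C19-/C20-GA2OX) and, within a class,
into clades (e.g. monocot vs. Brassicales GA3OX). All members share the
2-oxoglutarate-dependent dioxygenase (2ODD) core — a jelly-roll β-fold
whose cavity docks an Fe(II) ion, the 2-oxoglutarate (2OG) co-substrate
and the substrate — yet they discriminate between closely related
substrate variants. The residues that encode that discrimination are
*specificity-determining positions*: alignment columns conserved within
each group but different between groups, located where they can contact
the substrate. `sdpfinder` nominates such positions by intersecting
sequence-side evidence (phylogeny, motifs, column conservation) with
structure-side evidence (pocket geometry).

## Models and assumptions

### Distances and trees

Distances are Poisson-corrected: with `p` the proportion of differing
residues over columns where both sequences are ungapped,
`d = -ln(1 - p)` substitutions/site. This corrects for multiple hits
under a rate-homogeneous, exchange-symmetric model; it underestimates
divergence under strongly non-uniform exchangeabilities, which is
acceptable at the within-family divergences the pipeline targets
(`p` ≲ 0.5). Saturation (`p = 1`) is an error by default; an explicit
`cap` option bounds it at `-ln(1/ncols)` for exploratory use.

Trees are built with neighbor joining (the Saitou–Nei `Q` criterion),
which is consistent on additive distances — the property the test suite
verifies directly on random additive matrices. Determinism is pinned
down in two places the literature leaves open: `Q` ties break to the
lowest index pair in current label order, and negative branch lengths
are clamped to zero with the deficit moved to the sibling branch.
Bootstrap supports resample alignment columns with replacement,
rebuild the tree per replicate, and report the frequency of each
internal-edge bipartition of the point tree; replicates that saturate
are skipped with the denominator adjusted, and more than 20% skipped
aborts.

Column filtering before distances follows the usual deletion policies.
"Partial deletion" needs a coverage cutoff that the originating
workflow (MEGA-style) does not pin to the analysis; we default to 0.95,
the common site-coverage default, and keep it configurable. Residual
in-pair gaps are always pairwise-deleted.

### Motifs

Motifs are position weight matrices in the MEME-minimal interchange
format, scanned as log-odds in bits against a background distribution,
with a 0.01-per-letter pseudocount applied once at model construction.
The scan threshold default is motif-specific — the consensus score
minus 25% — because the usual E-value thresholds require a null model
that is out of scope; the default is deliberately permissive for sharp
motifs and strict for diffuse ones, and is configurable per motif.
Architectures select non-overlapping hits greedily by descending score
(ties: smaller start, then smaller motif id). A motif is *exclusive* to
a class set when present in ≥ 80% of its members and absent elsewhere,
*predominant* when present at ≥ 80% inside and < 20% outside, and
*ubiquitous* at ≥ 80% everywhere; 0.8 mirrors the conservation-shading
bin boundary used on the conservation side.

The ZOOPS (zero-or-one occurrence per sequence) EM discoverer exists to
exercise the scanning stages against planted ground truth; multi-motif
discovery belongs to external MEME. It uses a data-estimated background,
Dirichlet-style pseudocounts in the M-step (so the objective is a
posterior and is monotone — asserted every iteration in the tests), and
MEME-style ±1 column phase-shift moves after convergence, which
reliably fixes the classic off-by-one local optimum.

### Column conservation and property tables

A group's consensus at a column is the residue reaching a gap-excluded
frequency ≥ 0.8 (configurable in (0.5, 1]); a column more than half
gapped in a group yields no consensus, because logo-style analyses are
built from largely gapless blocks. A column is *core-conserved* when
all classes share one consensus; *class-characteristic* when one class
has a consensus differing from the shared consensus of all the others
(a looser majority-of-others mode exists but is off by default — the
strict rule is the one that reads directly as "characteristic");
*clade-polymorphic* when both designated clades have consensus residues
that differ; otherwise unconserved. Shading bins (100, 80–100, 60–80,
< 60) summarize the pooled majority frequency. Positions are reported
both as alignment columns and in the ungapped numbering of a named
reference sequence.

Substitutions are annotated with five fixed property dimensions
(charge, hydrophobicity, size, polarity, sidechain flexibility). The
tables are reproduced exactly as published, including two deliberate
gaps: cysteine carries no polarity label and glycine no flexibility
label. We preserve those gaps — fidelity to the published tables is the
contract — and surface them through an explicit `unclassified` channel;
`property_tables(repair = TRUE)` optionally adds C → non-polar and
G → high flexibility for users who prefer closure. The loader validates
coverage and disjointness on every construction, so any edit to the
tables breaks the build. One related convention: when a percent
"homology" between paralogs is quoted without saying identity or
similarity, we read it as *similarity* under the BLOSUM62 ≥ 1
criterion, since that is the similarity definition used everywhere
else in the pipeline; this is interpretive and only affects how users
compare their own numbers.

### Pairwise alignment and similarity

Global pairwise alignment is Needleman–Wunsch/Gotoh with affine gaps.
Gap penalties are not specified by the originating analysis, so we
adopt the EMBOSS-needle convention (open 10, extend 0.5), with a gap of
length L costing `open + (L-1)·extend`; traceback ties break
diagonal > up > left, making output deterministic. A residue pair is
"similar" when its BLOSUM62 score is ≥ 1 (every identical standard pair
qualifies, since the BLOSUM62 diagonal is ≥ 1 throughout; `X` never
does). Percent identity/similarity support three denominators —
ungapped columns (default), full alignment length, shorter sequence —
because published percentages rarely state which was used; the default
is the most common convention for "columns compared".

### Pocket triage

The structural criteria are distance and orientation: a residue is
flagged when any heavy atom lies within 5 Å (inclusive — "within 5 Å"
is read as ≤) of the docked substrate *and* its sidechain points inward
toward the reactive center. "Inward" is operationalized as the
sidechain heavy-atom centroid being strictly closer to the reactive
center than CA is — the simplest test consistent with the wording; an
angular variant (CA→centroid within 90° of CA→center) is available
behind a flag. Glycine has no sidechain heavy atoms and never passes,
but is flagged distinctly. The reactive center defaults to the Fe
coordinate (no explicit coordinate is ever published for "the reactive
center"; the Fe is where chemistry happens), with the substrate
centroid as an alternative. Cofactor partitioning uses sidechain
distance cutoffs of 2.6 Å to Fe (typical Fe–ligand coordination) and
3.5 Å to 2OG (H-bond/salt-bridge range); both are configurable and
echoed into the run manifest. Alternate locations keep the highest
occupancy (ties → 'A'), only the first MODEL of multi-model files is
read, hydrogens are ignored, and author residue numbering is preserved
alongside 1-based reference-sequence numbering.

## What the generators emulate — and what they do not

`simulate_family()` evolves gapless alignments leaf-ward along a known
tree under a 20-state uniform-replacement Poisson process (events at
the branch-length rate, uniform choice among the other 19 residues).
Under this process the expected difference proportion between two
leaves at path length *t* is `(19/20)(1 - exp(-t·20/19))`, which the
suite checks at 10,000 columns — and it is the process under which the
Poisson-correction distance is a consistent estimator, matching what
the phylogeny stage assumes. Planted clade-polymorphic columns are
overwritten per clade and then flipped with a per-site noise
probability; planted motif consensi are written into class subsets.
Because drift along the clade stems occasionally fixes different
residues at unplanted columns, the generator homogenizes any such
incidental clade-fixed background column (at the same 0.8 threshold the
detector uses), so "the planted columns are the only clade-conserved
polymorphisms" holds by construction and precision/recall against
ground truth are exact.

Defaults are the study-scale conditions used throughout the tests and
the acceptance script: 2 clades × 10 sequences, 300 columns, 5 planted
polymorphic columns, zero noise, root-to-tip depth 0.3
substitutions/site (edge lengths bounded away from zero so every
internal edge carries resolvable signal at a few hundred columns; the
clade stem is one sixth of the depth). What the generator does *not*
emulate: indels (alignments are gapless; gap handling is tested with
hand-built fixtures), realistic exchangeability matrices (WAG/LG), rate
heterogeneity, and compositional bias. Passing tests therefore
demonstrate algorithmic correctness under the stated model, not
robustness to every feature of real alignments.

`simulate_structure()` plants residues as CA plus a two-atom
pseudo-sidechain around a three-atom substrate surrogate at the origin,
an Fe site 4 Å below it and a two-atom 2OG beside the Fe: contact
residues at 3.5–4.9 Å with the sidechain nearer the ligand than CA,
lining residues at the same distances pointing away, cofactor residues
with a sidechain atom 2.2 Å from the Fe, and background beyond 6 Å.
Geometry is re-verified after placement and regenerated on failure (at
most 100 attempts). Real rotamer geometry, backbone continuity and
steric plausibility are out of scope — two pseudo-atoms are exactly
enough to make the centroid-orientation test meaningful.

## Numerical choices

* Consensus/conservation threshold 0.8 throughout, anchored to the
  80–100% shading bin; every output records the threshold used.
* Newick branch lengths and supports are written with 6 significant
  digits; round-trips preserve topology exactly and lengths to 1e-9 at
  that precision.
* The ZOOPS EM stops when the objective improves by < 1e-6 or at 200
  iterations, uses 5 restarts by default, and is deterministic given
  its seed.
* Problem sizes in the tests and acceptance script — 100 additive
  8-taxon matrices, 1,000 toy structures, 20 seeded family replicates,
  alignment-enumeration oracles at lengths ≤ 6 — were chosen as the
  smallest sizes at which the checked properties are sharp (topology
  recovery, role agreement, optimality) while keeping the whole suite
  in the low minutes on a single core.

## Known limitations

* Poisson correction and the uniform-replacement simulator ignore
  amino-acid exchangeability structure; distances between highly
  diverged classes are compressed relative to WAG/LG-based estimates.
* The motif scan has no E-value calibration; thresholds are relative to
  the consensus score and should be tuned when motifs differ greatly in
  information content.
* The 23 → 6 → 17-style pocket triage depends on the input structure
  and ligand placement; with homology models and manually docked
  surrogates the counts are qualitative, and the pipeline's value is
  the *report shape* (flagged / cofactor / contact, intersected with
  clade polymorphisms and class motifs), not any specific count.
* `class_characteristic` in strict mode requires all other classes to
  agree; with many classes and patchy conservation this is
  conservative, and the majority mode trades precision for recall.
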