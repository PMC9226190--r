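---
title: "Identifying proteinaceous binders in paint micro-samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying proteinaceous binders in paint micro-samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binderID)
```

## The problem

Proteomic analysis of artwork micro-samples asks three questions of a
set of peptide-spectrum matches (PSMs): which proteins are *really*
there, which species did they come from, and how damaged are they? All
three are easy to get wrong. Search engines report every match above an
FDR threshold, including one-hit wonders and laboratory contaminants;
peptide sequences that look species-specific may be indistinguishable by
mass from another species' sequence; and deamidation percentages based
on a handful of peptides carry large, easily under-reported
uncertainty. `binderID` encodes the defensible decision rules for each
step as explicit, testable operations, downstream of the spectral search
engine (which is treated as upstream metadata, never re-implemented —
FDR control, mass tolerances and modification limits belong to the
search configuration and are only echoed into the run manifest).

## Evidence model

The unit of input is the PSM row: plain peptide sequence, annotated
("modified") sequence, candidate protein accessions, search-engine
score, intensity, MS/MS count, charge, and decoy/contaminant markers.
Annotated sequences use underscore delimiters with parenthesised tags
after the modified residue (`_AGN(de)LK_`; position 0 denotes the
protein N-terminus), and the tag vocabulary is configurable and
case-insensitive because different search-engine versions write `(de)`,
`(Deamidation (NQ))` and other spellings. A missing intensity is
*missing*, never zero: weighting falls back to the MS/MS count, then to
equal weights. Extra columns pass through untouched, and reading never
silently drops rows — a malformed cell is a named, line-numbered error.

## Confident identification

Filtering removes, in a fixed precedence that makes the removal log
deterministic: decoy (reversed) matches; rows explained only by
contaminant accessions or flagged as contaminants; scores below 40;
peptides shorter than 7 residues. The score and length defaults are the
values commonly used for degraded-sample searches and are configurable.

A protein is confidently identified when at least two of its unique
peptides are non-overlapping. Two intervals conflict only under full
containment (`start_A >= start_B` and `end_A <= end_B`); partial overlap
is acceptable because the two peptides still cover distinct sequence
regions. Equal intervals are mutual containment, hence insufficient.
The implementation is checked against an exhaustive pairwise-enumeration
oracle on a thousand random interval sets.

"Unique to that protein" is ill-posed in redundant databases, so
uniqueness is computed after collapsing entries with identical
sequences; an optional protein-group mode evaluates uniqueness at the
level of user-defined groups (ortholog families). The group mode exists
because a well-built binder database *deliberately* carries orthologous
sequences from all candidate species (sheep, goat and cattle collagens,
chicken and duck vitellogenins); nearly every tryptic peptide of such a
family occurs in two or more entries, and entry-level uniqueness then
fails for reasons that have nothing to do with evidence quality.
Species resolution is the taxonomy step's job, not the confidence
rule's. The package default remains entry-level (with sequence
collapsing), and the analysis configuration switches the mode on
explicitly per analysis.

## Species-diagnostic peptides

A peptide supports a species only if its sequence occurs in a protein of
that species *and* the occurrence is consistent with the digestion
chemistry (preceded by K/R or the protein start, ending in K/R or at the
protein end, for tryptic searches; the proline-blocked variant and a
fully unspecific mode are available because hydrolysis-damaged material
yields non-tryptic peptides). Matching is equivalence-aware, because
three substitutions are routinely invisible to tandem MS:

* **I/L** — identical mass, never distinguishable.
* **N/D and Q/E** — deamidation converts N to D (Q to E) with the same
  +0.984 Da shift as the substitution, so a site distinguishes the two
  residues only if at least one supporting spectrum shows the
  non-deamidated form. The per-site evidence is aggregated from the
  observed spectra: a site counts as "deamidated-only" until a single
  unmodified observation removes it.
* **S/A** — serine differs from alanine by a hydroxyl that oxidation can
  also add to nearby residues (proline, methionine); within a
  configurable window (default 1 residue, "close to" being otherwise
  unquantified) of an observed oxidised site, S/A are equivalent unless
  a fragment ion covers the site and localises the hydroxyl.

Each rule can only *add* candidate species (relaxation monotonicity,
property-tested), so exact matching is the conservative lower bound.
Fragment coverage of distinguishing sites is required by the guideline
but optional in data: the default mode assumes coverage and attaches a
prominent warning note to every diagnostic call, while the strict mode
(`require_fragment_coverage = TRUE`) finds the distinguishing sites (by
near-miss scanning against non-target species, Hamming distance at most
2) and withholds the diagnostic flag unless all of them are covered.

Matches are then intersected with a plausibility filter — the
historical/geographical shortlist of species a conservator would accept
for the object, with the rationale recorded in every affected call. A
peptide is diagnostic when the filtered set is non-empty and lies within
the target taxon, which may be a named group of genuinely
indistinguishable species such as sheep/goat. Peptides that are not
diagnostic but whose plausible matches intersect exactly one confirmed
taxon are assigned to it by parsimony (`parsimony` note, or
`parsimony-group` when the match resolves to a confirmed group).

## Source attribution and the binder call

Confident proteins map to source classes by ordered name rules
(database metadata wins when present): vitellogenins and apolipoprotein
B indicate egg yolk; lysozyme, ovalbumin, ovotransferrin and
ovoinhibitor egg white; serum albumin is ambiguous between blood, yolk
and white; collagen I indicates animal glue and collagen III hide glue
specifically; non-contaminant keratins indicate wool. A peptide shared
between two classes is counted once, under the class of the protein
with more unique peptides (ties broken by rule order), so per-class
counts are disjoint and shares sum to one. The binder call reports the
dominant class by peptide share; below a configurable dominance
threshold (default 0.6 — an explicit artifact choice, since qualitative
practice argues from percentages) the call carries a mixed-layers
caveat, and egg-white presence alongside yolk always carries the caveat
that it does not prove intentional use of whole egg, because manual
separation of yolk from white is rarely complete.

## Deamidation

For one peptide, the deamidated fraction is
`sum(w_r * d_r) / sum(w_r * t_r)` over its supporting rows, where `d_r`
and `t_r` count deamidated and total residues of the requested type
(N or Q) and `w_r` is the row intensity (fallback MS/MS count, then 1).
Site assignment is taken from the annotation as written; no
re-localisation is attempted. Peptides lacking the residue are excluded
and do not count toward `n_peptides`. The sample estimate is the
unweighted mean of peptide fractions, times 100; peptides are the
resampling unit of a seeded bootstrap (B = 1000 by default) whose
standard deviation is reported, because the peptide count is the natural
"n" of these estimates. Across-peptide intensity weighting is available
as a switch but off by default. Estimates from 20 or fewer peptides are
flagged `low_n`, the count below which such calculations are usually
considered unreliable. Two estimates are compared on the difference
scale with combined uncertainty `sqrt(sd_A^2 + sd_B^2)`; the verdict is
"comparable" within twice that, otherwise "higher"/"lower".

## The synthetic generator

`make_proteomes()` builds random tryptic proteins — every fully cleaved
peptide is 7–16 residues, ends in K/R, and contains at least one N and
one Q, mirroring the N/Q-rich composition of collagens and egg proteins
and making every peptide informative for damage estimation. Ortholog
variants copy a base sequence and substitute residues at
peptide-interior sites (at least two residues from any cleavage site,
pairwise at least three apart) according to four divergence classes:
`IL` (I in the base, L in the variant), `ND` (N/D), `SA_near_P` (S/A
with a proline placed after the site in both), and `hard` (G/V, cleanly
distinguishable by mass). `make_evidence()` samples tryptic peptides
(up to two missed cleavages) from configured source compositions,
deamidates each N/Q independently with per-source probabilities,
annotates `(de)`, draws log-normal intensities, gives genuine rows
scores above 40 and spiked decoy rows scores below it, and appends
contaminant and reverse rows at binomial fractions. Random streams are
per-component (sequence construction, sampling, deamidation,
intensities, spiking), derived from one master seed, so changing one
knob does not reshuffle unrelated draws; everything is reproduced
byte-identically from the seed.

The `painting_scenario()` preset emulates an egg-tempera paint layer
over a glue-bound ground: three chicken yolk proteins, a chicken/duck
serum-albumin pair (identical sequences, so albumin peptides require
parsimony), a duck vitellogenin ortholog with six hard sites (so some
yolk peptides are chicken-diagnostic), sheep collagens whose goat
orthologs differ only at I/L sites (collagen resolves to the sheep/goat
group at best) and whose cattle orthologs carry hard sites (the group is
separable from cattle). The paint sample draws 160 observations at
roughly 88% egg / 12% collagen, the ground sample 140 at 93% collagen /
7% egg, mirroring the peptide-share magnitudes such layered samples
show; cross-layer carry-over is intentional, since scalpel sampling of
micrometre-thin layers inevitably mixes them. Deamidation probabilities
are 0.25/0.30 (N/Q) for egg-derived proteins and 0.45/0.70 for
collagen, encoding the higher damage of boiled glue; contaminant and
decoy rows are spiked at 5% each.

What the generator does *not* emulate: spectrum-level detail (fragment
ions, so fragment coverage must be supplied externally or assumed),
retention times, intensity-dependent identification bias, shared-peptide
razor assignment, and realistic sequence homology (divergence sites are
sparse and independent, unlike real ortholog divergence). Passing tests
on these fixtures therefore demonstrates the correctness of the decision
rules, not the field performance of the workflow on real paint samples.

## Numerical and design choices

* Trypsin default cleaves after K/R regardless of a following proline,
  matching common search-engine configuration; `trypsin_no_P` is
  available. Semi-tryptic termini are not matched by default; the
  unspecific mode covers hydrolysis-damaged material.
* Removal-reason precedence (reverse > contaminant > score > length) is
  fixed for log reproducibility.
* Peptide counts in reports are distinct sequences, not distinct
  (sequence, charge, modification) combinations.
* Bootstrap seeds are mandatory wherever a bootstrap is configured;
  reruns with the same configuration and seeds are byte-identical
  (timestamps excluded), and the run manifest echoes the full
  configuration.
* Degenerate inputs: an empty evidence file is a clean error naming the
  file; a sample with no confident proteins yields an empty summary; a
  subgroup without the requested residue is an error rather than a
  silent zero; all-unmodified input returns exactly 0 ± 0.
* Test problem sizes: oracle comparisons use 1,000 random interval sets
  and 100 random digestion sequences; equivalence-flip checks use 50
  generated fixtures; deamidation recovery uses 20 simulated samples of
  200 peptides (8 observations per peptide) at (pN, pQ) = (0.30, 0.70)
  with B = 1000.

## Known limitations

Uniqueness and protein grouping are deliberately simple (no razor
peptides, no probabilistic inference); the plausibility filter is a
hard intersection, not a prior; deamidation is a damage *proxy* whose
interpretation requires knowledge of preparation history (boiled glue,
alkali-extracted madder lake) and ideally comparison against modern
mock-ups of similar composition; and fragment-coverage verification is
only as good as the coverage annotations supplied. Live sequence-database
searches (e.g. BLAST against public repositories) are out of scope:
specificity is assessed against the user-supplied FASTA databases, so
the choice of database remains the user's paramount responsibility, and
an iterative strategy (ordered databases with fallback matching, tagged
`fallback-db`) is provided in place of repeated engine runs.
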