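---
title: "Rule-based lipid MS/MS prediction and metadata-weighted identification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based lipid MS/MS prediction and metadata-weighted identification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidrules)
```

## The problem

Untargeted lipidomics identifies compounds by matching acquired ESI-MS/MS
spectra against reference libraries, but experimental reference spectra
exist for only a small slice of lipid space. Lipids are modular molecules —
a class-specific polar backbone carrying one to four fatty chains — and
their collision-induced fragmentation is dominated by a handful of
stereotyped events: loss of the polar head group, loss of a chain as free
acid or ketene, and a few small constant head-group ions. That regularity
makes hand-curated, class- and adduct-specific fragmentation rules both
faster and more accurate than combinatorial bond-breaking for this chemical
space. `lipidrules` implements such a rule engine, the surrounding spectrum
arithmetic, and a library-search layer that blends spectral similarity with
two kinds of metadata: literature-citation counts and chemical-ontology
class frequencies.

## The fragmentation model

A lipid is parsed from shorthand (`PC(16:0/16:0)`,
`PS(16:0/18:1(9Z))`, `PC(O-16:0/16:0)`, `SM(d18:1/16:0)`, ...) into a class
label plus chain descriptors (carbons, double bonds, linkage: acyl ester,
alkyl ether, alkenyl vinyl-ether, or sphingoid base). The neutral formula
is assembled from a per-class fully hydroxylated backbone plus chain units,
condensing one H~2~O per bond; double-bond position/geometry annotations
such as `(9Z)` are retained but are mass-neutral — the rules cannot
distinguish stereoisomers or regiomers, a structural limitation of every
rule-based fragmenter.

Ion m/z uses the electron-corrected convention
$m/z = (kM + \Delta m - z\,m_e)/|z|$, so a proton contributes 1.007276 Da.
That convention reproduces the canonical phosphocholine head-group ion at
184.0733 (neutral C~5~H~14~NO~4~P, 183.0660 Da, under a proton carrier).

The rule registry has two layers:

* a **manifest** transcribing the curated coverage — 21 lipid classes,
  344 rules, 50 class/adduct combinations over the adduct set
  \{[M+H]^+^, [M+Na]^+^, [M+Li]^+^, [M+NH4]^+^, [M−H]^−^, [M+Cl]^−^,
  [M−2H]^2−^\} — verified at load time;
* a **concrete rule subset** (87 rules) fully encoding the
  phosphatidylcholine, phosphatidylserine, phosphatidic-acid,
  lysophosphatidylcholine, diacylglycerol, triacylglycerol and cardiolipin
  classes for every adduct the manifest lists for them. The full curated
  rule content is not public; this subset is reconstructed from the
  documented anchors (the PC/[M+H]^+^ pattern with exactly ten
  fragment-producing rules at 40 eV, the head-group ions at 184.0733,
  166.0628, 104.1070, 86.0964 and 124.9998, and the standard acid/ketene
  chain losses), so no rule-for-rule fidelity with the original curation is
  claimed. Remaining classes are manifest-only: they route correctly but
  predict no concrete fragments.

Rules come in three kinds. *Constant fragments* ionize a fixed composition
under their own charge carrier; *neutral losses* subtract a composition
from the ionized precursor; *chain losses* subtract the sn-indexed chain's
leaving group (free acid C~n~H~2n−2d~O~2~, ketene C~n~H~2n−2−2d~O, or
alkene), optionally combined with an extra neutral loss (e.g. ammonia for
[M+NH4]^+^ adducts). Rules are executed as modular-structure templates
rather than through a generic reaction language; the registry format
reserves a pattern-string column should a SMIRKS-style encoding be added.
For the doubly charged cardiolipin precursor, products default to singly
charged deprotonated ions (product charge states are otherwise
under-determined), carried by an explicit `[M-H]-` field in the rule.

Intensities are categorical, not numeric: each rule carries one of
\{absent, low, medium, high, maximum\} per collision energy (10, 20,
40 eV). Numeric rendering pins `maximum` to 100 (base peak) and maps the
other bins to their midpoints: high 75 (60–90% bin), medium 37.5 (15–60%),
low 8 (1–15%). Only the bins are curated; midpoints are this package's
rendering choice. The intact precursor is always emitted, at `maximum` for
10 and 20 eV and `medium` at 40 eV — low-energy spectra are dominated by
the unfragmented ion, while at high energy the head-group fragment
typically takes over as base peak. Collision energies other than 10/20/40
are rejected outright rather than nearest-mapped; a user-supplied
instrument energy-mapping table can be applied before dispatch.

Routing follows the decision logic of the original workflow: a covered
lipid with a covered adduct is fragmented by rules; a
glycero-/phospho-/sphingolipid without an applicable pattern stops with an
error (these classes must never fall through to combinatorial
fragmentation); anything else returns a `fallback_external` flag — this
package deliberately does not implement the general-purpose probabilistic
fragmenter.

## Spectral similarity

Spectra are compared with the standard dot-product (cosine) score over
tolerance-aligned peaks. Both spectra are base-peak normalized; candidate
peak pairs within the tolerance are accepted greedily by ascending |Δm/z|
(ties toward the lower m/z), one-to-one; unmatched peaks pair with zero.
Defaults are 0.01 Da when both sides are predicted and 0.25 Da when either
side is experimental — the tolerance is not part of the published method
description, so the historical default of the reference dot-product
implementation is used. When query and library both carry spectra at
several collision energies, the compound-level score is the arithmetic mean
of per-energy cosines over shared energies, and the maximum over the
library record's provenance sets (predicted vs experimental); the
aggregation rule is this package's choice.

## The combined candidate score

For a candidate list retrieved within a precursor m/z window, each
candidate receives three raw terms: the compound-level cosine similarity;
the chemical-class score; and the citation count capped at 156 (heavier
cited compounds otherwise drown out spectrally better matches; the cap
constant is taken as published even though it is hard to reconcile with the
published average citation count). Each column is normalized by its maximum
over the list (an all-zero column stays zero — a 0/0 guard the source
material does not address), and combined as

$$S_{TOTAL} = a_{CFM\_ORIG}\,S_{CFM\_ORIG} + a_{CLASS}\,S_{CLASS} +
a_{REF}\,S_{REF}, \qquad a_i \ge 0,\ \textstyle\sum a_i = 1$$

with default weights 0.6 / 0.1 / 0.3. A candidate whose **raw** similarity
reaches 0.95 bypasses the metadata terms entirely
($S_{TOTAL} = S_{CFM\_ORIG}$): a near-perfect spectral match must not be
penalized by citations or class frequencies. The threshold is applied to
the raw cosine because 0.95 is meaningful on the absolute similarity scale,
not on the list-normalized one. Score columns are computed once over the
full candidate list; bypassed candidates are not removed and the columns
are not recomputed.

The class score is deliberately simple: with the pool of all category
assignments (direct parent plus alternative parents) across the candidate
list, a candidate's raw score is the summed pool frequency of its own
categories divided by the pool total. Shared categories reward clusters of
structurally similar candidates, which is the term's published purpose; the
exact formula is under-specified in the source material and this
frequency-mass reading is a design decision of the package.

Ranking uses competition (min) ranks on $S_{TOTAL}$; the row order breaks
ties by raw similarity then compound id purely for determinism. Evaluation
reports top-1/3/10 counts, mean and median rank, and the medal score
$5\cdot\#\{rank\,1\} + 3\cdot\#\{rank\,2\} + 1\cdot\#\{rank\,3\}$.
Chemical-class prediction returns the direct parent of the unique top
candidate, or, under a tie, the most frequent direct-or-alternative parent
among all tied candidates (residual ties lexicographic).

Weight optimization enumerates all weight triples on a simplex grid and,
per cross-validation fold (default 5), keeps the triple maximizing the
top-1 count on the training split — the published optimization names no
objective, and top-1 count is the natural reading of "identification
potential". Ties prefer a larger similarity weight, then a larger citation
weight. The consensus snaps the per-coefficient median to the grid and
absorbs any rounding residue into the similarity weight so the constraint
$\sum a_i = 1$ survives.

## The synthetic-data generator

No public fixture can reproduce the original 397k-spectrum production
library or its contest-derived evaluation inputs, so every pipeline stage
is
exercised on synthetic data generated in-repo. `generate_library()` draws
structures uniformly from the seven concretely encoded classes (even-carbon
chains of 12–22 carbons, 0–4 double bonds — the common biological range),
predicts their three-energy spectra under each class's characteristic
adduct, assigns citation counts from a log-normal (meanlog 3, sdlog 1,
rounded, floored at 1 — matching the long-tailed citation distributions
seen in compound databases, with the floor mirroring the default-1 rule for
uncited compounds), and derives classifications from the class lineage.
Randomness uses a single root seed split arithmetically per compound, so
enlarging a library never reshuffles earlier records.

`perturb_spectrum()` emulates predicted-vs-experimental discrepancies with
Gaussian m/z jitter (default sd 0.002 Da, a typical high-resolution mass
error), truncated multiplicative intensity noise (sd 0.1) and independent
peak dropout (default 0.1). `generate_challenges()` perturbs each selected
truth's spectra into a query set; an energy whose perturbed spectrum loses
every peak is dropped from the query (an acquisition with no surviving
peaks would be discarded in practice), and the truths' experimental-
provenance spectra can be withheld from the searchable library.

What passing synthetic tests shows — and what it does not: the generator
produces spectra from the same rule engine the search uses, so
self-identification checks validate the plumbing (retrieval windows,
scoring, normalization, tie handling), not real-world accuracy. Real
experimental spectra differ in intensity far more than the categorical
model can express, contain chimeric and instrument-specific peaks, and the
production-scale identification rates depend on library size and
composition; none of that is claimed by these tests.

## Numerical choices and degenerate inputs

* Masses are IUPAC monoisotopic values from a versioned plain-text table;
  electron mass 0.000548580 Da; full double precision internally,
  round-half-even to 4 decimals (m/z) and 2 (intensity) at every I/O
  surface.
* Product peaks that coincide at the 4-dp surface (symmetric lipids: two
  identical chains losing the same acid) are merged keeping the highest
  category, so a spectrum never carries duplicate m/z.
* Empty spectra cannot be normalized, compared or perturbed; impossible
  neutral losses (negative element counts) are errors, not clamps.
* An alignment tolerance of zero degenerates to exact matching; negative
  tolerances are rejected.
* Retrieval, scoring and ranking are deterministic end to end; repeated
  seeded runs of the simulator and the search produce byte-identical
  files.

## Problem sizes used in the checks

The packaged checks run a 100-compound synthetic library for the
exact-recovery property, 1000 randomized candidate lists for the scoring
invariants, ~300 fuzzed spectrum pairs (≤ 6 peaks) against an exhaustive
alignment oracle, 220 fuzzed structures against an atom-by-atom formula
oracle, and a 40-compound library over 5 seeds for the dropout-degradation
trend. These sizes give stable statistics while keeping the default suite
fast on a single CPU.

## Known limitations

* Manifest-only classes (e.g. phosphatidylinositols, ceramides) route but
  produce precursor-only spectra; extending them means adding concrete
  rules to the registry resource, not code.
* Categorical intensities cannot express within-class intensity variation
  between homologues, instruments or solvents.
* The Jaccard similarity variant of the original scoring is not
  implemented (unspecified); the similarity layer is cosine-only.
* No isotope envelopes, chimeric spectra, retention time or collision
  cross-section metadata.

## A worked example

```{r example}
registry <- load_registry()
pc <- parse_lipid_name("PC(16:0/16:0)")
predict_spectrum(pc, "[M+H]+", 40, registry)$peaks
```
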