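---
title: "Methods: SRS mapping, mutation design and screen quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SRS mapping, mutation design and screen quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsmut)
```

## Scope and model

Cytochrome P450 monooxygenases share six substrate recognition sites
(SRS1–SRS6): sequence regions that line the catalytic pocket and govern
substrate binding and regio-specificity. `srsmut` implements a
semi-rational engineering workflow around them, in four connected parts:

1. **SRS mapping.** SRS intervals are established on a handful of
   reference P450s (classically rat CYP2A1 and two plant CYPs). A query
   is globally aligned to each annotated reference and the reference
   intervals are carried through the alignment columns onto query
   coordinates. Per-SRS, pooled-SRS and full-length percent identity are
   then read off a shared pairwise alignment.
2. **Mutation design.** Candidate residues are proposed by three rules:
   fixed offsets from the K-helix ExxR motif (the classic SRS5 hotspot
   positions), reciprocal differences between two homologues inside the
   SRS regions, and transfer of a position of interest from another P450
   through the alignment ("structurally equivalent position"). Variants
   are written in a compact grammar (`A99I`, `473DDP::EL`) that the
   package parses, renders canonically and applies to sequences.
3. **Screen quantification.** In vivo variant screens read out by GC–MS
   are reduced to internal-standard normalised responses, fold changes,
   absolute titers via linear standard curves, and two specificity
   metrics: the oxygenated share of total diterpenoids and the share
   that is the target product.
4. **Simulation.** Ground-truthed generators for homologous families and
   replicate peak tables make every step testable without external data.

## Alignment and projection choices

The aligner is Needleman–Wunsch with affine gaps (end gaps penalised),
delegated to `Biostrings::pairwiseAlignment`. The scoring scheme is
open: published SRS work rarely states matrices or penalties, so the
defaults are the field's workhorse values — BLOSUM62, gap open 10, gap
extend 0.5 — and all three are arguments of `align_params()`. Identity
percentages at this level of sequence similarity move by at most about a
point under reasonable parameter changes, which is why reported
identities are treated with a ±1-point slack downstream. Tie-breaking
between equal-scoring alignments follows the library's deterministic
internal order; the score, the quantity with a contract (it must equal
exhaustive enumeration over all global alignments, which the test suite
checks on short sequences), is unaffected by tie order.

Projection is conservative by construction: a reference interval
boundary that lands on a query gap moves **inward** to the nearest
aligned query residue, so a projected SRS never claims residues outside
the aligned region; an interval entirely gapped in the query becomes
empty with residue count 0. With several annotated references the
consensus interval is the intersection of the per-reference projections
— again the conservative choice; per-reference intervals are returned
alongside for inspection.

Identity denominators include gap-containing columns as mismatches
rather than dropping them. This is what makes full-length identity lower
than SRS identity for near-identical proteins of slightly different
length, the pattern seen in natural subfamily comparisons.

The ExxR scan returns the **first** E-x-x-R match in its window, which
by default starts right after SRS4: in the canonical P450 fold the
K-helix (and its ExxR) follows the I-helix, so scanning downstream of
SRS4 skips spurious upstream matches. Hotspot offsets are counted
downstream from the E: although the hotspot positions are conventionally
described as "upstream of ExxR", the published example coordinates
(E at 357, hotspots at 362 and 366) are only coherent with downstream
counting, so that is the default; the sign is configurable.

## Variant grammar and candidate rules

Substitutions are `<ref><pos><new>`; segment swaps are
`<pos><ref-seg>::<new-seg>` and may change length (a net deletion like
`473DDP::EL` shortens the protein by one residue). Edits in one variant
must have strictly increasing positions, all in the coordinates of the
unedited sequence; duplicate positions are rejected rather than
composed, because composition order would be ambiguous. Application
validates every reference residue first and edits right-to-left so
earlier coordinates stay valid.

Reciprocal candidates walk the alignment columns intersecting the
target's SRS intervals. Mismatch columns yield one substitution each.
Gap columns are merged into maximal runs and reported as one segment
swap per run, left-anchored on the preceding aligned column (as VCF
represents indels) so that both segments are non-empty and the candidate
is directly expressible and applicable in the grammar. Hotspot
candidates leave the replacement residue open (placeholder `X`) unless a
replacement panel is given — the choice of replacement chemistry is the
scientist's, not the enumerator's.

## Quantification arithmetic

Relative yield is the replicate mean of analyte area divided by the
internal-standard area of the same injection; it is invariant to any
per-injection rescaling of all areas, which is the point of the internal
standard. Standard curves are ordinary least squares of normalised
response on concentration (mg/L); titers invert the mapped curve and are
floored at zero. Compounds without their own authentic standard ride a
structurally similar compound's curve under an identical-response-factor
assumption; the default map sends the hydroxy and oxo-hydroxy
derivatives (compounds 3 and 7) to the 11-oxo compound-2 curve, and the
map is an explicit argument.

Per-strain metrics over a quantified compound set (default
{1, 2, 3, 7}): total is the plain sum;
oxygenated % = 100·(total − substrate)/total; content of target % =
100·target/total; zero-total strains report 0 rather than NaN. The
quantified set is configurable; the default includes the unquantified
derivative 7 because published totals exceed the sum of compounds 1–3 by
exactly that remainder. Reports round percentages to integers and titers
and fold changes to one decimal, matching the conventions of published
screening tables; unrounded values are always retained in the objects.

Group comparisons use the two-sided Welch t-test. Degenerate input with
zero variance in both groups returns p = 1 (equal means) or p = 0 by
convention instead of erroring, so screening loops never crash on
saturated values. A time-course is flagged as stagnated when the
final-interval increase is below 10% of the final value (threshold
configurable).

## What the simulators emulate — and what they do not

`simulate_family()` draws a uniform-random 500-residue ancestor, plants
an ExxR motif between SRS4 and SRS5 (E fixed at 357, R at 360, both
invariant in descendants) and six SRS intervals totalling 78 residues,
and mutates each descendant residue-wise: 18% per residue inside SRS,
12% outside by default. These defaults mirror the divergence structure
of a natural CYP76AH-like subfamily, where SRS regions of functionally
divergent members differ more than the background while close paralogues
are nearly identical. An optional single- or multi-residue deletion
inside SRS6 reproduces the 78-vs-77 SRS residue-count contrast observed
between natural paralogues. The generator is a star topology with
independent sites — no rate matrices, no indels outside SRS6, no
compositional bias — so passing tests demonstrate the correctness of the
projection/identity arithmetic, not robustness to deep evolutionary
divergence or alignment ambiguity on real proteins.

`simulate_screen()` produces peak areas as
titer × response factor × IS area × exp(ε), ε ~ N(0, log(1 + CV)),
with independent noise on the internal-standard row of each replicate.
Defaults are the shake-flask study conditions: a wild-type-like strain
(titers 15.9/23.4/0.2/4.3 mg/L for compounds 1/2/3/7), a
high-specificity variant (0.9/86.4/0.4/0), three biological replicates,
10% CV, calibration at 1–100 mg/L for the two compounds with authentic
standards. Multiplicative log-normal noise is the natural choice for
strictly positive chromatographic areas; the simulator does not model
peak overlap, drift, carry-over or limit-of-detection censoring, so
recovery tests certify the normalisation/calibration arithmetic, not
chromatographic robustness.

## Problem sizes and numerical choices

The test suite exercises alignments up to 500 residues, families of up
to four descendants, 20-seed recovery checks for candidate enumeration
and 100-seed recovery checks for fold-change estimation; the exhaustive
alignment oracle enumerates all global alignments for sequences up to
length 8, which is ample to pin down the affine gap accounting. These
sizes keep the full suite under a minute while leaving every code path
covered. R² of a perfect calibration is defined as 1 directly (avoiding
0/0), fold changes against a zero reference return `Inf` with a warning,
and self-fold-changes short-circuit to exactly 1.

## Known limitations

* SRS intervals for queries exist only by projection; no structural
  validation is attempted (homology modelling is out of scope).
* The reciprocal rule proposes every SRS difference; it does not rank
  candidates by predicted effect.
* Published microtiter fold changes are kept as fixture constants
  because the underlying raw areas were never published; only
  shake-flask arithmetic is recomputable end to end.
* Reproducing the published identity table requires the actual subfamily
  sequences, which this package does not redistribute; the optional
  stage-6 analysis script runs the comparison when they are supplied.
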