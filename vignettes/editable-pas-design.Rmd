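---
title: "Designing adenine-base-editor guides against polyadenylation signals"
author: "pasedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing adenine-base-editor guides against polyadenylation signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasedit)
```

## The model

A polyadenylation signal (PAS) is a hexamer - canonically `AATAAA` or
`ATTAAA` - that directs cleavage and polyadenylation of pre-mRNA some
10-30 nt downstream. Deviations from the canonical hexamers reduce cleavage
and polyadenylation efficiency, so a base edit inside the hexamer can silence
the transcript it stabilises without a double-strand break.

An adenine base editor (ABE) is a Cas9-nickase-deaminase fusion that converts
A:T base pairs to G:C, but only when the adenine lies inside a narrow
*activity window* of the protospacer, counted from its 5' (PAM-distal) end,
and only when a PAM (`NGG` for SpCas9) sits immediately 3' of the protospacer
on the protospacer strand. `pasedit` models *eligibility* under these
geometric rules; it does not model editing *efficiency*, which depends on
chromatin, delivery and sequence context that no placement rule captures.

A hexamer is considered disruptable at two kinds of position:

* **coding mode** - an adenine of the hexamer itself is edited (A to G on the
  strand the hexamer is read from). For the canonical motifs the rule covers
  the adenines at the last three hexamer positions (4-6).
* **template mode** - the adenine pairing with the hexamer's middle thymine
  (position 3) is edited on the opposite strand, so the coding strand reads
  T to C: `ATTAAA` becomes `ATCAAA`. That mutant hexamer is exactly the
  naturally non-functional variant observed on chromosome 10 in the DUX4
  context, which is what motivates treating this single T as disruptable.

Both restrictions are deliberate. `AATAAA` also carries adenines at
positions 1-2 and `ATTAAA` a thymine at position 2, but edits there are not
part of the default rule set (plausibly because position 1-2 variants retain
more residual activity); both position sets are fully configurable per motif
via `pasMotifSpec()`.

## Placement geometry and gap ranges

Let the protospacer have length $P$ (20), the PAM length $M$ (3), and the
activity window span positions $[w_{lo}, w_{hi}]$ (default 4-8). For a
disruptable hexamer position $p$ edited at window position $w$:

* coding mode places the PAM start at a gap
  $\gamma = (P - 6) - (w - p)$ nt downstream of the hexamer's 3' end;
* template mode places the (reverse-strand) PAM end at a gap
  $\delta = (P + 1) - p - w$ nt upstream of the hexamer's 5' start.

Over the default positions and window this yields $\gamma \in [10, 16]$ and
$\delta \in [10, 14]$:

```{r gaps}
ed <- editorPreset("spcas9-abemax")
att <- pasMotifSpec("ATTAAA")
gapRange(ed, att, "coding")
gapRange(ed, att, "template")
```

The activity window default of 4-8 is a documented assumption: the editor
this preset describes (ABEmax fused to the SpCas9 nickase) is reported to
edit efficiently at protospacer positions around 4-8, and the observed edits
at positions 4-6 with position 7 still described as in-window are consistent
with those bounds. The window is a constructor argument, so any other bound
can be supplied without touching the scan code.

## Two scan engines

`scanEditablePAS()` decides, for every motif occurrence on both strands,
whether at least one valid guide exists.

The **direct engine** enumerates placements: for every disruptable position
and window position it derives the protospacer interval, checks bounds,
checks that the edited base carries the source base, rejects any protospacer
or PAM containing non-ACGT characters, and matches the PAM against its IUPAC
pattern. Placements sharing a protospacer interval are merged into one guide
candidate listing every captured position (a single guide that covers hexamer
positions 4-6 is one candidate, not three).

The **regex engine** compiles the same geometry into patterns. Each feasible
$(p, w)$ pair becomes a fixed-length run of explicit character classes -
`[ACGT]` for protospacer positions, literals for the hexamer, IUPAC classes
for the PAM, intersected where components overlap - and the alternation over
pairs is matched through zero-width lookaheads so that overlapping
occurrences are never missed. Compared with the naive
`ATTAAA[ACGT]{10,16}[ACGT]GG` formulation this bounded-context construction
has two advantages: it never claims editability near a sequence end where the
protospacer would run out of bounds, and it stays correct when a non-default
position set makes the achievable gap set non-contiguous. Match existence at
a hexamer is, by construction, equivalent to "at least one valid guide exists
in that strand mode"; the regex engine therefore reports editability without
enumerating guides (`guideCount` is `NA`).

Both engines treat an `N` in the reference as unscannable: it never matches
the source base and never satisfies any PAM symbol, so no emitted protospacer
or PAM ever contains `N`. Soft-masked (lowercase) sequence is uppercased and
scanned by default; `maskSoftmasked = TRUE` converts it to `N` first for
users who want to exclude repeats.

## Annotations and the editable share

`readPolyAGFF3()` reads the GENCODE polyA dialect (feature type
`polyA_signal`), skipping and counting malformed lines. Intersection with
scan output (`editabilitySummary()`) joins on the exact
(chrom, interval, strand) tuple - GENCODE polyA_signal features are exact
hexamer spans, so proximity joins would only blur the statistic. Identical
tuples shared by transcript isoforms are deduplicated before counting, and
the denominator of the editable share is restricted to annotations whose
extracted hexamer is one of the two canonical motifs. At genome scale this
code path computes the two headline statistics of PAS editability (the
canonical-motif share of all annotated PAS, and the editable share among
those); the package's tests exercise the identical path on constructed toys
where the expected values are forced by construction (4/5 and 1/4).

## Off-target candidate filtering

`enumerateNearMatches()` is a brute-force contract: every placement on both
strands is tested, a locus is a site when its PAM matches and its protospacer
is within `maxMismatch` (default 4) of the query. The three filter criteria
of `applyOffTargetFilters()`:

1. mismatch placement: all mismatches outside the PAM and outside the
   PAM-proximal seed region, and at most 4 in total (strict reading, the
   default). The looser reading - cap only the mismatches outside the seed -
   is available with `strict = FALSE`, since the wording "up to 4 mismatches
   outside of the PAM region and the seed region" admits both. PAM
   mismatches are never counted: a locus whose PAM does not match is not a
   site at all.
2. at least one source base (adenine) inside the activity window, without
   which the editor has nothing to convert;
3. a single-copy locus, operationalised as: the exact protospacer+PAM
   sequence occurs exactly once genome-wide across both strands. This is a
   deliberate, checkable substitute for alignment-based uniqueness notions.

The seed length defaults to the PAM-proximal 12 protospacer positions. This
is a field convention, not a measured constant - published definitions range
from 8 to 12 nt - so it is an explicit argument surfaced in both the query
object and the filter.

## The synthetic fixture generator

`generateFixture()` emulates the situations the scanner must discriminate:
editable PAS sites in both strand modes, motifs with no reachable PAM,
motifs whose only PAM sits outside the valid gap range, motifs with a PAM on
the unusable strand, `ATCAAA` pseudo-motifs with perfect PAM geometry, and
near-match off-target loci with chosen mismatch positions (including
duplicated loci that must fail the single-copy criterion).

Plants are built as self-contained strings padded to the editor's full
geometric reach ($P + M + \gamma_{max}$ on each side), so nothing outside a
plant can alter its guide set, and placed in disjoint slots. The random
background is then reconciled with the truth manifest by targeted patching:
the brute-force oracle rescans the genome and any accidental editable site
(or accidental near-match of the query) is destroyed by mutating one base
outside all planted spans, iterating to a fixed point under a bounded budget.
Whole-genome rejection sampling is not viable here - at 50 kb an accidental
motif+PAM configuration arises with near certainty per draw - while targeted
patching terminates in a handful of passes and keeps the output a pure
function of the seed. A fixture that cannot be reconciled (the budget is
exhausted, or a collision with a planted span cannot be avoided) is refused
with an error rather than emitted.

What the fixture does *not* emulate: real base composition and repeat
structure, soft-masking, assembly gaps (`N` runs), chromatin accessibility,
and any notion of editing efficiency. Passing the recovery tests therefore
demonstrates correctness of the geometry and bookkeeping on clean ground
truth, not performance on real genomes.

The default fixture query protospacer is motif-free but carries adenines in
the activity window, mirroring a realistic ABE guide; a query containing a
PAS motif (as the DUX4 guide does) is legitimate, and in that case sites
inside off-target plants are excluded from the PAS truth universe rather
than patched away.

## Oracles and validation sizes

Two independent oracles ship as first-class code: `oracleScan()` (exhaustive
hexamer x disruptable-position x window x strand enumeration with its own
complement tables and IUPAC logic) and `oracleNearMatches()` (sliding-window
Hamming comparison at every position). They share no code with the engines
they check. The test suite asserts exact three-way agreement
(direct = regex = oracle, including guide counts) on 100 random 10-kb
genomes, off-target agreement on 50 genomes, window-monotonicity and
reverse-complement-invariance properties on 200 randomized cases each, and
exact recovery of a 50-kb fixture's truth manifest. These sizes keep the
whole suite under a couple of minutes on one CPU while the counting
arguments (about 10 motif sites per 10-kb genome, about 50 across
categories per fixture) give each repetition real discriminating power.

## Numerical and convention choices

* Coordinates are 0-based half-open in all flat-file output (BED) and in the
  placement tables; `GRanges` objects follow the Bioconductor 1-based closed
  convention; GFF3 input is converted on read. Window positions are 1-based
  from the protospacer 5' end.
* Deterministic output ordering everywhere: sites and BED rows sort by
  (chrom, start, strand); ties cannot occur beyond that key because a site
  is identified by it.
* Two disruptable positions captured by one placement produce one guide
  candidate with both positions listed.
* When both strand modes hit the same hexamer there is one site record with
  the modes' guides merged (`editableCoding` / `editableTemplate` record the
  breakdown).
* All fixture randomness flows through one seeded stream that is restored
  afterwards, so library calls never perturb a caller's RNG state.

## Known limitations

* Editing efficiency, chromatin context and expression consequences are out
  of scope by design; the output is a candidate list, not a ranking.
* The genome-scale shares (80% / 25%) require the human reference genome and
  the GENCODE v35 polyA annotation, which are not shipped; the package
  reproduces the code path on toys and leaves the genome-scale run to users
  with the data.
* The single-copy criterion counts exact sequence copies; loci unique in
  sequence but ambiguous to an aligner are not flagged.
* Only eligibility under one editor geometry is evaluated per scan; comparing
  editors means running the scan once per `EditorSpec`.
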