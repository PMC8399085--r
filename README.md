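# pasedit

Genome-wide discovery of polyadenylation signals (PAS) that an adenine base
editor can disrupt, with off-target candidate filtering and synthetic
ground-truth fixtures.

## The problem

Disease genes can be silenced by destroying the PAS that stabilises their
transcript: with a functional hexamer (canonically `AATAAA` or `ATTAAA`)
weakened, the pre-mRNA is no longer efficiently cleaved and polyadenylated.
An adenine base editor (ABE: a Cas9-nickase-deaminase fusion converting A:T
to G:C without double-strand breaks) can do this when a disruptable base of
the hexamer falls inside the editor's activity window of a protospacer whose
PAM (`NGG` for SpCas9) sits immediately 3' of it. `pasedit` answers, for
every PAS hexamer in a genome on either strand, whether such a guide exists
and what it looks like. It is aimed at researchers designing PAS-disruption
experiments (the motivating case is the *DUX4* somatic PAS in
facioscapulohumeral muscular dystrophy) and at anyone who wants the
genome-wide statistics of PAS editability.

A hexamer is disruptable in two ways:

* **coding mode** — edit one of the adenines at hexamer positions 4-6
  (e.g. `ATTAAA` → `ATTGAA`/`ATTAGA`/`ATTAAG`);
* **template mode** — edit the adenine pairing with the middle thymine
  (position 3) on the opposite strand, so the coding strand reads
  `ATTAAA` → `ATCAAA`, the naturally non-functional chromosome-10 variant.

For protospacer length $P$, window $[w_{lo}, w_{hi}]$ and hexamer position
$p$ edited at window position $w$, a coding-mode PAM starts
$\gamma = (P-6)-(w-p)$ nt after the hexamer and a template-mode PAM ends
$\delta = (P+1)-p-w$ nt before it; with the defaults ($P=20$, window 4-8)
the admissible gaps are $\gamma \in [10,16]$ and $\delta \in [10,14]$. Two
interchangeable engines implement the scan — a direct placement enumeration
and a compiled regular-expression construction — and agree exactly; a
brute-force oracle validates both.

## Worked example

The motivating guide geometry: `ATTAAA` followed by a 14-nt spacer and a
`TGG` PAM places the hexamer's last three adenines at activity-window
positions 4-6.

```r
library(pasedit)
ed  <- editorPreset("spcas9-abemax")
att <- pasMotifSpec("ATTAAA")
seq <- paste0("ATTAAA", "TCATCTCATCTCAT", "TGG")
enumerateGuidesForSite(seq, 0, "+", ed, att)
#>   guideStrand strandMode protoStart protoEnd pamStart pamEnd
#> 1           +     coding          0       20       20     23
#>            protospacer pam capturedPositions windowPositions
#> 1 ATTAAATCATCTCATCTCAT TGG             4,5,6           4,5,6
#>      predictedHexamers nCaptured
#> 1 ATTGAA,ATTAGA,ATTAAG         3
```

One guide candidate: its protospacer spans the hexamer, the PAM is `TGG`,
and it captures the three disruptable adenines at window positions 4-6 with
predicted mutant hexamers `ATTGAA`, `ATTAGA`, `ATTAAG`. The template-strand
route predicts the chromosome-10 pseudo-motif directly:

```r
predictedEditedHexamer(att, 3, "template")
#> [1] "ATCAAA"
gapRange(ed, att, "coding")    # hexamer 3' end to PAM start
#> [1] 10 16
gapRange(ed, att, "template")  # PAM end to hexamer 5' start
#> [1] 10 14
```

Genome-wide scanning, annotation intersection and off-target filtering:

```r
scan <- scanEditablePAS("genome.fa", ed, engine = "direct")
writeScanBed(scan, "sites.bed")          # BED6, score = guide count
writeGuidesTsv(scan, "guides.tsv")

ann <- readPolyAGFF3("gencode.polyAs.gff3")
editabilitySummary(ann, scan, genome = "genome.fa")

q  <- offTargetQuery("GTCGAAGCGATCGTCGACGT", pam = "NGG",
                     maxMismatch = 4, seedLength = 12)
ot <- applyOffTargetFilters(enumerateNearMatches("genome.fa", q, ed), ed)
ot[ot$pass]                              # all three criteria satisfied
```

A thin CLI wraps the same functions
(`system.file("cli", "pasedit", package = "pasedit")`) with subcommands
`scan`, `summarize`, `offtarget` and `simulate`.

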