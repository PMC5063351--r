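---
title: "Methods: how sinescout detects, annotates and maps SINEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how sinescout detects, annotates and maps SINEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinescout)
```

## The problem

Short interspersed nuclear elements (SINEs) are non-autonomous
retrotransposons of roughly 100-600 bp, derived from RNA polymerase III
transcripts — most often tRNAs (class SINE2) or 5S rRNA (class SINE3). A
SINE insertion leaves a characteristic anatomy behind:

* a **target site duplication (TSD)**: a short direct repeat (typically
  4-14 bp) created on both flanks by the staggered endonuclease cut;
* an **internal pol III promoter**: A and B boxes (tRNA-type, "type 2"),
  sometimes with an extra B' box downstream, or A/IE/C boxes (5S-type,
  "type 1");
* a gene-derived 5' **head**, an unrelated central **body**, and a 3'
  **tail** — an oligo-T tract or a simple tandem repeat, often A/T-rich,
  sometimes preceded by a TC motif;
* occasionally a retained pol III **termination signal** (in the 5S
  context, `GCTTTTCG`).

`sinescout` turns the classic desk workflow for characterising such a
family — inspect candidates for these hallmarks, separate them from true
tRNA/5S genes, classify them by head homology, and map their copies across
a genome — into tested, scriptable functions. The packaged catalogue
(`load_fixture_catalogue()`) contains the thirteen AfuSINE elements
described from *Aspergillus fumigatus* Af293: eight tRNA-derived AfuSINE2
and five 5S rRNA-derived AfuSINE3 elements, stored verbatim as published
(including their flanking TSD copies, which the published lengths count).

## Local alignment

All homology quantities rest on one primitive: Smith-Waterman local
alignment with affine gaps (Gotoh recurrence), implemented in C++
(`local_align()`). Design points that matter for reproducibility:

* **Scoring.** Defaults: match +2, mismatch -1, gap open -5, gap extend
  -1. A gap of length $L$ costs $g_{open} + L\,g_{ext}$ (the opening
  column pays both). No score was published for any of the similarity
  figures, so these standard nucleotide values are explicit package
  defaults, adjustable via `scoring_scheme()`.
* **Identity.** `identity_pct` = 100 x matches / aligned columns,
  *including gap columns*. The denominator must be pinned down for the
  60%-rule (below) to be reproducible; columns-including-gaps is the
  conservative choice.
* **Overlap.** `overlap_nt` counts subject positions covered — the
  "60-nucleotide overlap" side of the rule.
* **N.** `N` matches nothing, including another `N`. Unknown bases can
  never support a homology call.
* **Determinism.** Traceback ties prefer the diagonal, then the vertical
  (gap-in-subject) move, starting from the first maximal cell in
  row-major order, so equal-scoring alignments resolve identically on
  every platform.

The test suite validates the aligner against two independent oracles: an
exhaustive enumeration of all local alignments (every choice of aligned
position subsets with affinely-costed gap runs) on all two-letter strings
up to length 4, and an independently written plain-R recurrence on
hundreds of sampled pairs up to length 8. The exhaustive oracle is
exponential, so its exhaustive range is kept small and the longer pairs
are sampled; the two oracles are also cross-checked against each other.

## Motif scanning

`scan_motif()` matches IUPAC consensus strings with a per-model mismatch
allowance. Degeneracy is deliberately **one-way**: a consensus code
matches any compatible subject base (consensus `N` matches everything),
but a subject `N` matches only a consensus `N`. An unknown base is never
evidence for a motif — this is what makes an all-`N` contig scan return
nothing.

Two model sets ship with the package:

* `default_motif_models()` — degenerate type-2 boxes
  (`TRGCNNARYNNG` / `GKTTCGANNC`, 2 mismatches each) for *annotating*
  elements already supported by other evidence. The published consensus
  logos are graphical and not machine-readable, so these generalised
  consensus strings are explicit stand-ins; the per-element exact box
  strings from the published table are shipped in
  `table1_box_strings()` as an alternative. The type-1 (5S-type)
  consensus strings (`AYTYAARCCA`, `NTRGT`, `TAKAWRSNCC`) were derived
  from the annotated boxes of the five packaged 5S-derived elements, with
  search windows `[45,75)`, `[65,90)`, `[75,110)` following canonical 5S
  internal-control-region geometry.
* `strict_motif_models()` — the same type-2 strings with **zero**
  mismatches. With two mismatches allowed, chance A+B pairs appear every
  few hundred bp of random sequence, so wherever a promoter pair is the
  *sole* evidence — the classification fallback and de-novo discovery —
  exact matching is the default. This split (permissive for annotation,
  strict for evidence) is a deliberate design decision.

Promoter annotation picks the best-quality hits deterministically (fewest
mismatches, then leftmost), requires the A box before the B box with a
spacer of 10-150 nt (spacers count nucleotides *strictly between* hits,
which is what makes the published "20 bp" B-to-B' distance reproducible),
and calls type 1 when at least two of the three boxes are found in order.
The 10-150 nt spacer default covers all the packaged elements; nothing
tighter was published.

## TSD detection

Terminal mode (`find_tsd_terminal()`) treats a printed element as
carrying both TSD copies: the longest $k \in [4, 20]$ with
prefix$(k)$ = suffix$(k)$ (offsets up to `max_end_offset` allowed; ties
prefer the smallest offsets). Matching is exact — the source analysis
reads degraded TSDs as evidence of element age, i.e. as non-matches — and
reported lengths are not clipped to the published 4-14 bp range (the
upper bound 20 leaves headroom).

Flanking mode (`find_tsd_flanking()`) searches 30-nt genomic windows on
both sides of a locus. A plain "longest common substring of the two
windows" rule is noisy: two random 30-mers share a 5-mer about half the
time, so short genuine TSDs would regularly be out-reported by spurious
distant repeats. Because a real TSD abuts the insertion junction,
candidates are instead scored `length - left_gap - right_gap` (gaps =
distance from the upstream copy's end to the element start, and from the
element end to the downstream copy's start), and only positive scores are
reported. A repeat farther from the junction than its own length is
indistinguishable from background. Under this rule the planted-truth
simulations recover essentially all TSDs exactly at zero divergence; a
single substitution in one copy leaves only sub-minimum fragments and
returns nothing.

## Tails and terminal motifs

`annotate_tail()` inspects the final 50 nt (the window covers every
packaged tail; nothing longer was needed). If the element carries a
terminal TSD copy, that copy is trimmed first — the biological tail
precedes the 3' TSD, as in the packaged element whose tail is seven ACT
trinucleotides followed by its 14-bp TSD. The oligo-T tract is the
longest run of at least 4 T whose span intersects the window, reported at
its full length even when it starts upstream of the window boundary (one
packaged element carries an 18-T tract that straddles it); ties prefer
the 3'-most run, since the tail is by definition terminal. The terminal
tandem repeat is the maximal repeat of a primitive unit (1-6 nt, at least
3 copies) anchored at the trimmed 3' end — `ACTACT x 3` is always
reported as `ACT x 6`. A `TC` dinucleotide immediately upstream of the
A/T-rich stretch is flagged, and the A/T fraction of the window reported.
The oligo-T scan is sense-strand only; an antisense tail would belong to
an element annotated on the other strand. `check_terminal_motifs()` flags
`CCA` (5' 120 nt) and `ACATT` purely descriptively.

## Classification

`classify_element()` applies a fixed precedence:

1. **5S test**: best local alignment of the candidate's 5' head (default
   100 nt — the conserved 5S-derived head spans about 64 nt, and 100
   covers it plus divergence while bounding compute) against each 5S
   reference. Identity >= 60% over >= 60 subject nt calls SINE3. These
   are the published thresholds.
2. **tRNA test**: the same rule against tRNA references calls SINE2, with
   the isotype of the single best reference (exact ties across isotypes
   give `"ambiguous"`). No threshold was published for the tRNA side;
   reusing 60/60 symmetrically is an assumption, stated here.
3. **Promoter fallback**: an exact-consensus A+B pair alone calls SINE2
   with no isotype.

Running the 5S test first avoids spurious isotype calls on 5S heads. LINE
3'-UTR similarity (`line_3prime_similarity()`) is reported as evidence of
a retrotransposition partner but never changes the family call.

The true-gene filter discards a candidate only when a reference gene
aligns at >= 90% identity covering >= 90% of **both** the reference and
the candidate. The candidate-coverage condition is essential: a derived
element *contains* a complete gene-derived head, so reference coverage
alone would discard exactly the elements the pipeline exists to find.
Coordinate-based exclusion (`exclusion_filter()`, >= 50% overlap) handles
known gene annotations.

## Genome scanning

`map_copies()` is seed-and-extend: exact 12-mer seeds on both strands
(elements of 140-500 bp retain an intact 12-mer at 10% divergence with
high probability), clustered at element-length gaps, each cluster
extended by local alignment of the element against a window around it.
Loci pass at >= 80% identity and >= 80% query coverage; same-strand loci
within 50 nt merge into one locus (union interval, best identity), so
copy counts refer to whole insertions, not fragments. With thresholds at
100%/1.0 the scan reduces exactly to exact-substring search, which the
tests verify against a naive oracle. Loci on opposite strands are never
merged; a perfect palindrome could therefore yield two loci, which is the
honest description of such a locus.

`extend_boundaries()` widens a locus 1,000 nt upstream and 2,000 nt
downstream in the element's own orientation (mirrored on the minus
strand), clipped to the contig — the published curation practice for
re-inspecting a masked repeat.

`discover_candidates()` nominates de-novo candidates from strict A+B
pairs, ends them at the most prominent tail signal (longest oligo-T run
of >= 4 T, or a tandem simple repeat of >= 9 nt; ties earliest) within
600 nt of the A box — 600 nt exceeds the longest described element — and
drops pairs with no tail signal. Taking the *first* >= 4-T run instead of
the most prominent one was considered and rejected: a chance `TTTT`
occurs every ~256 bp, so the first-run rule would truncate roughly a
third of genuine candidates mid-body, while run length separates real
tails (>= 6-10 T) from background cleanly. Candidates always carry at
least two hallmarks (promoter pair + tail), usually three (+ TSD).

`distribution_report()` counts loci per contig and per user-supplied
region label (pericentromeric / subtelomeric / other), with a one-sided
binomial test of enrichment against the label's length share. Labels are
user input: the package does not infer centromere or telomere positions.

## The simulator

`simulate_genome()` is the package's benchmark instrument, not a fixture:
it plants elements with a complete, recorded ground truth so that every
stage closes the loop against known coordinates.

* **Background**: i.i.d. nucleotides at the configured GC content (0.5 by
  default). This is the simplest null for false-positive budgeting; a
  Markov background is future work.
* **Elements**: `[pad 6][A box][spacer 30][B box][body 120][tail T x 10]`
  by default, using the intact box strings of the youngest fully-featured
  packaged element. The A box sits 6 nt from the element start so that a
  promoter-anchored discovery call starts within a few nt of the true
  boundary.
* **Insertion**: each copy duplicates its target site — the TSD is drawn
  from the background at the insertion point and appears on both flanks,
  exactly as a staggered cut leaves it. TSD lengths are uniform on the
  published 4-14 bp range. Minus-strand insertions plant the reverse
  complement; the TSD remains a direct repeat.
* **Divergence**: per-site substitutions only (the analysis this emulates
  discusses divergence in substitution terms); indels are not simulated,
  and that is a stated limitation — real ancient insertions also decay by
  indels, which this benchmark does not probe.
* **Determinism**: everything runs under one seed; identical
  configurations byte-reproduce the genome, the truth table and the
  serialised FASTA/GFF3.

What passing the simulated benchmarks does **not** show: performance on
real repeat-rich backgrounds (segmental duplications, satellite arrays,
nested elements), robustness to indel decay, or anything about
transcription. Copy-number estimates from hybridisation experiments,
transcription assays and the chromosome-level distribution of the real
isolate's loci are outside what a desk re-analysis can reproduce; the
simulation loop is the package's evidence that the *machinery* measures
such quantities correctly when the truth is known.

## Problem sizes and runtime

The shipped tests run simulated genomes of 20-100 kb with 5-24 planted
copies, chosen so the whole suite completes in well under a minute on one
CPU while leaving the statistical margins comfortable (e.g. 24 planted
copies bound recall from below at 1/24 resolution). The same closed-loop
checks scale linearly to megabase contigs.

## Worked example

```{r example, eval = FALSE}
cat13 <- load_fixture_catalogue()
s3 <- cat13[grepl("SINE3", cat13$id), ]
refs_5s <- sine_catalogue(paste0(s3$id, "_head"), substr(s3$seq, 1, 64))
res <- run_pipeline(cat13, refs = list(r5s = refs_5s))
res$table[, c("id", "family", "promoter_type", "tsd_len", "tail_unit")]
```

This reproduces the published anatomy: thirteen records, the five
5S-derived elements isolated by the 60/60 rule, the 14-bp TSD and ACT
tail of the tRNA-Arg-derived element, and the terminator in exactly one
5S-derived element.
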