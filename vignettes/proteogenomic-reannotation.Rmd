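---
title: "Proteogenomic genome reannotation from peptide evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic genome reannotation from peptide evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protannotate)
```

## The problem

Automated annotations of bacterial genomes miss genes — especially short
ORFs and species-specific ones — and frequently mis-place translation start
sites. Shotgun proteomics offers direct evidence: a peptide observed by mass
spectrometry proves that its genomic locus is translated. `protannotate`
implements the proteogenomic workflow built on that idea for compact
(bacterial) genomes such as the multi-replicon genomes of filamentous
cyanobacteria: a chromosome plus plasmids, a few thousand genes, and a large
fraction of "hypothetical" annotations.

The workflow:

1. **Six-frame search space.** The genome is translated in all six reading
   frames (bacterial code, table 11) and split at stop codons. Every maximal
   stop-free segment strictly longer than 20 amino acids becomes one ORF.
   These are *stop-to-stop* segments, not start-initiated gene models: start
   selection is deferred to event calling, where peptide evidence constrains
   it.
2. **Target-decoy FDR.** Peptide-spectrum matches (PSMs) from external
   search engines are filtered at a 1% false-discovery rate. The score
   cutoff is the lowest score $s$ with
   $\#\{\text{decoys} \ge s\} / \#\{\text{targets} \ge s\} \le 0.01$,
   which maximizes the accepted target set under the constraint.
3. **Peptide classes.** Accepted peptides are located by exact substring
   search with fixed precedence: contaminants, then the annotated reference
   proteome (*known*, or *shared* when several proteins match), then the
   six-frame database. Peptides matching **only** the six-frame database are
   genome search-specific peptides (GSSPs) — the evidentiary unit for
   everything novel. GSSP uniqueness is defined at the genomic-locus level:
   one peptide, one interval.
4. **Protein inference.** A protein is *identified* with ≥2 unique peptides;
   a single unique peptide flags it for manual review; shared-only proteins
   are excluded from the identified set; microproteins are those ≤100 aa.
   Redundant proteins (identical sequences under different accessions) are
   grouped.
5. **Novelty calling.** Unique GSSPs sharing a stop-to-stop ORF form a
   support group; groups with ≥2 distinct peptides become candidate events.
   The bounding ORF's overlap with the annotation decides the category:
   no overlap → *intergenic*; same-strand overlap in a different frame →
   *alt_frame*; overlap only with opposite-strand genes → *antisense*;
   same strand, same frame, with peptides upstream of the annotated start →
   *n_term_extension* (the revised model shares the annotated stop).
6. **Model proposal.** The model ends at the ORF's bounding stop codon. The
   start codon is chosen from an allowed set — ATG, GTG, TTG, CTG plus the
   noncanonical ATA and ATT — inside the window between the upstream
   in-frame stop and the most upstream supporting peptide.
7. **Side analyses.** Signal-peptide predictions from two external tools are
   intersected and *refuted* when an identified peptide overlaps the
   predicted signal region (a cleaved signal peptide should not appear in
   the mature proteome); PTM site tables are filtered at score > 40 and
   localization probability > 0.75 (both strict) over a 27-type vocabulary;
   TMT reporter intensities are normalized by per-sample totals and tested
   per protein with an equal-variance two-sample *t* test, calling DEPs at
   fold change ≥ 1.2 or ≤ 0.83 and *P* < 0.05.

## Coordinate and numerical conventions

* Internal coordinates are 0-based half-open on the forward strand; GFF3 in
  and out is 1-based inclusive. Minus-strand intervals keep genomic
  orientation; biology is applied at translation.
* Frames 1–3 are forward offsets 0/1/2; frames 4–6 are offsets 0/1/2 on the
  reverse complement.
* The ">20 aa" ORF filter is strict (shortest retained segment: 21 aa), as
  are the PTM thresholds (41 passes, 40 does not; 0.76 passes, 0.75 does
  not) and the DEP *p*-value gate.
* Replicon-edge segments lacking a bounding stop are retained by default and
  flagged; a toggle (`include_unbounded`) switches the convention, because
  published six-frame database counts do not always state it. Circular
  replicons are processed as linear (no wrap-around ORFs); topology is
  recorded but unused.
* Codons containing `N` translate to `X`, which never matches a peptide
  residue.
* Trypsin/P digestion cleaves after every K/R **including** before proline,
  with ≤2 missed cleavages and a 6–50 aa peptide window (configurable).
* I/L collapse in peptide matching is off by default (exact matching treats
  them as distinct) and available as a flag.

## Design choices where the method description is open

* **Start selection** defaults to *minimal extension*: the allowed start
  closest to (at or upstream of) the most upstream supporting peptide. It is
  the conservative choice — it asserts no coding sequence beyond what
  peptides support — and `maximal_extension` is available for sensitivity
  analysis. When no allowed codon exists in the window the event is emitted
  with `start_codon = NA` and flagged rather than dropped.
* **FDR level**: PSM-level filtering is the default; best-score-per-peptide
  roll-up is available (`peptide_level = TRUE`).
* **Decoys**: when a PSM table lacks decoys, full-sequence reversal of the
  reference and six-frame databases is the generator's decoy model.
* **Refutation overlap**: "the signal region contains an identified
  peptide" is interpreted as *any* overlap of at least `min_overlap = 1`
  residue, since full containment versus partial overlap is ambiguous in
  the method descriptions we follow; initiator-Met-excision peptides
  (starting at residue 2) refute by default, with an exemption flag.
* **Multi-gene overlaps** in event classification use largest base-pair
  overlap, ties to the leftmost gene, and flag the event ambiguous.
* Same-frame GSSP groups that do not extend upstream of the overlapped gene
  are unreachable for consistent inputs (their peptides would match the
  reference) and are dropped with a warning if they ever appear.

## The synthetic world

Real inputs at full scale (raw MS data, a 7.2-Mb genome) are not usable for
desk-scale testing, so the package ships a generator whose defaults *are*
the stated test world: two replicons (50 kb + 10 kb), 40 genes of 120–300
aa, 3 intergenic + 2 alt-frame + 2 antisense planted novel ORFs (30 aa), 3
genes truncated by 30 nt at their start, trypsin/P peptides, decoy PSMs
from reversed proteins at 30% of true PSMs, true scores N(60, 5) versus
decoy/noise scores N(25, 5) (well separated, so a 1% FDR cutoff is
meaningful), an optional noise fraction of random peptides verified absent
from both databases (true negatives by construction), ~20% of plain genes
designed with signal peptides (alanine at the −1/−3 cleavage positions),
150 PTM sites at 70% confidence, and a 2-condition × 3-replicate quant
design (a nitrogen-deprivation-style contrast) with 15% true DEPs at fold
changes 1.5–1.8 or 0.5–0.6 and 5% replicate CV.

Construction details that make the truth exact: each planted ORF is written
between explicit in-frame stop codons, so its stop-to-stop segment equals
the planted coordinates; embedded alt-frame and antisense ORFs are designed
by rejection sampling so the host gene's own reading frame stays stop-free;
truncated genes carry two planted tryptic peptides overlapping the removed
N-terminal region, and an in-frame stop immediately upstream of the true
ATG pins the restored start exactly. Planted GSSPs are verified unique in
the genome and absent from the reference proteome at generation time.

What the generator does **not** emulate: fragment spectra, retention times,
intensity-dependent detectability, shared peptides between paralogs beyond
chance, sequencing errors, or wrap-around ORFs on circular replicons. A
green recovery test therefore establishes the correctness of the pipeline's
logic (coordinates, categories, thresholds, determinism), not
instrument-level performance.

## What the tests establish

Unit suites check each operation against independent brute-force oracles
(codon-walk translation, exhaustive stop-free-window scanning, cleavage
subset enumeration, try-every-cutoff FDR, direct interval overlap,
closed-form pooled *t*), plus the spec-level invariants: strand symmetry of
ORF extraction, partition of peptide categories, monotonicity of
`min_support` and of refutation, normalization invariance of DEP calls, and
byte-identical regeneration under a fixed seed. The end-to-end check
recovers 100% of planted events with exact coordinates and start codons
(including a planted noncanonical ATA initiator) on noise-free bundles, and
sustains ≥95% event precision with 5% noise PSMs at the 1% FDR across 20
seeded replicates.

Two published genome-scale counts (the 205,978-sequence six-frame database
and the ~7.21-Mb assembly size) can be reproduced only after downloading
the public assembly; the acceptance tests fetch it when a network is
available and report both edge-segment conventions alongside the count.

## Limitations

* C-terminal revisions and merges across adjacent ORFs are out of scope.
* Single-peptide identifications are flagged, never auto-promoted — the
  manual-validation step they would require is not codifiable.
* Exact-substring matching cannot place peptides across sequencing errors
  or true frameshifts.
* No multiple-testing correction is applied to DEP calls by default
  (matching the stated thresholds); Benjamini–Hochberg is available.
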