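# protannotate

Proteogenomic reannotation of bacterial genomes from shotgun-proteomics
peptide evidence, in R.

Automated bacterial genome annotations miss genes (especially short and
species-specific ORFs) and frequently mis-place start codons. A peptide
observed by mass spectrometry is direct evidence that its locus is
translated. `protannotate` turns filtered peptide-spectrum matches (PSMs)
into annotation decisions:

* **Six-frame search space** — translate every replicon in all six frames
  (NCBI table 11) and keep every stop-to-stop segment > 20 aa as an ORF.
* **Target-decoy FDR** — accept PSMs above the lowest score cutoff *s* with
  #(decoys ≥ s)/#(targets ≥ s) ≤ 1%.
* **Peptide classes** — contaminant ≻ reference proteome ≻ six-frame
  database; peptides matching *only* the six-frame database are **genome
  search-specific peptides (GSSPs)**.
* **Protein inference** — identified = ≥2 unique peptides; single-peptide
  and shared-only proteins are flagged, not identified; redundancy groups;
  microproteins (≤100 aa).
* **Novelty calling** — ≥2 unique GSSPs per stop-to-stop ORF call an event:
  `intergenic`, `alt_frame`, `antisense`, or `n_term_extension` (revised
  start, shared stop), with the start codon chosen from
  {ATG, GTG, TTG, CTG, ATA, ATT} to cover the peptide evidence.
* **Side analyses** — signal-peptide refutation by MS coverage of the
  predicted signal region; PTM-site filtering (score > 40, localization
  probability > 0.75, 27-type vocabulary); TMT-style total-intensity
  normalization and Student's *t*-test DEP calling (fold change ≥ 1.2 or
  ≤ 0.83, *P* < 0.05).
* **Synthetic world** — a seed-deterministic generator plants novel ORFs,
  truncated starts, decoys and noise with a ground-truth manifest, so the
  whole pipeline is testable offline.

## Worked example

```r
library(protannotate)

bundle <- generate_synthetic(synthetic_config(seed = 1))
run <- run_pipeline(bundle$genome, bundle$annotation, bundle$psms,
                    sigpep_a = bundle$sigpep$predisi,
                    sigpep_b = bundle$sigpep$signalp,
                    ptm_sites = bundle$ptm, quant = bundle$quant)
print(run)
#> Proteogenomic reannotation run
#>   PSMs: 222 in, 171 accepted (score cutoff 41.9)
#>   six-frame ORFs: 1898
#>   peptides: known=143, shared_known=0, gssp=28, unmatched=0, contaminant=0
#>   proteins: identified=36, single_peptide=0, shared_only=0, undetected=4
#>   events: intergenic=3, alt_frame=2, antisense=2, n_term_extension=3
```

Reading the report: 222 simulated PSMs (including decoys) pass through the
1% FDR filter, leaving 171 accepted target PSMs. 143 distinct peptides match
the annotated proteome ("known"), 28 match only the six-frame translation
(GSSPs). 36 of the 40 annotated proteins are identified with ≥2 unique
peptides. The GSSPs call 10 events — the 3 intergenic, 2 alternate-frame
and 2 antisense ORFs planted by the generator (exact coordinates and start
codons, including one noncanonical ATA initiator), plus 3 N-terminal
extensions that restore the deliberately truncated gene starts to the
nucleotide:

```r
run$events[, c("event_id", "category", "start", "end", "strand",
               "start_codon", "revised_gene_id")]
bundle$truth$novel_orfs      # the planted manifest it should match
```

File-based use (FASTA + GFF3 + TSV in, TSV/GFF3/JSON out):

```r
write_bundle(bundle, "demo")
# then: Rscript inst/scripts/protannotate.R run --config demo/config.json --out demo/out
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic world at the given seed, runs the complete
pipeline end to end (FDR filtering, classification, protein inference,
novelty calling, signal-peptide refutation, PTM filtering, differential
expression), prints the run report, and writes the JSON result object.

Genome-scale checks against the published *Nostoc* sp. PCC 7120 assembly
(six-frame database size, total genome length, reference-database record
count) live in `tests/testthat/test-acceptance.R`; they download
GCA_000009705.1 at run time and report both edge-segment conventions for
the six-frame count, so they require network access.
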