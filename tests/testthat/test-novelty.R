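# GSSP clustering, event classification and start-codon model proposal.

# A hand-built replicon: an annotated plus-strand gene, and downstream an
# unannotated ORF with three in-frame candidate start codons (ATG, GTG, ATG)
# ahead of the peptide evidence.
toy_world <- function() {
  set.seed(70)
  gene_prot <- paste0("M", random_protein_str(58))
  gene_nt <- paste0("ATG", paste(vapply(strsplit(gene_prot, "")[[1]][-1],
    function(a) {
      opts <- names(Biostrings::getGeneticCode("11"))[
        Biostrings::getGeneticCode("11") == a]
      opts[1]
    }, character(1)), collapse = ""), "TAA")
  # novel ORF: TAA | ATG GCT GTG GCT ATG GCT | 24 safe codons | peptide
  # region | TAA   (candidate starts at segment codons 1, 3, 5)
  body <- strrep("GCA", 18)
  pep_region <- "GATGAGCATTGGGATAAAGAGCATTTTCATAAG"  # DEHWDKEHFHK (no ATG/GTG)
  pep_region <- paste(vapply(
    strsplit(c("D", "E", "H", "W", "D", "K", "E", "H", "F", "H", "K"), ""),
    function(a) c(D = "GAT", E = "GAA", H = "CAT", W = "TGG", K = "AAA",
                  F = "TTT")[[a]], character(1)), collapse = "")
  novel_nt <- paste0("TAA", "ATGGCTGTGGCTATGGCT", body, pep_region, "TAA")
  seq <- paste0(random_dna_str(90), gene_nt, random_dna_str(60), novel_nt,
                random_dna_str(90))
  # force frame-clean placement bookkeeping
  gene_start <- 90L
  gene_end <- gene_start + nchar(gene_nt)
  novel_at <- gene_end + 60L
  genome <- make_genome(c(chr = seq))
  ann <- data.frame(gene_id = "g1", seqid = "chr", start = gene_start,
                    end = gene_end, strand = "+", product = NA_character_,
                    is_putative = FALSE, coding_ok = TRUE,
                    start_codon = "ATG", stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  seg_start <- novel_at + 3L
  seg_len <- (nchar(novel_nt) - 6L) %/% 3L
  list(genome = genome, ann = ann, seg_start = seg_start,
       seg_end = seg_start + 3L * seg_len,
       pep_offset_aa = 6L + 18L,   # candidate region + body codons
       novel_prot = translate_frame(substr(seq, seg_start + 1,
                                           seg_start + 3 * seg_len), "+", 0))
}

test_that("GSSP groups form per bounding ORF and respect min_support", {
  w <- toy_world()
  orfs <- extract_orfs(w$genome)
  idx <- build_peptide_index(c(g1 = "MWHMWHMWHMWH"), orfs)  # no ref matches
  pep1 <- substr(w$novel_prot, w$pep_offset_aa + 1, w$pep_offset_aa + 6)
  pep2 <- substr(w$novel_prot, w$pep_offset_aa + 4, w$pep_offset_aa + 11)
  a <- classify_peptides(c(pep1, pep2), idx)
  expect_true(all(a$category == "gssp" & a$is_unique))
  groups <- cluster_gssps(a, min_support = 2L)
  expect_length(groups, 1L)
  expect_setequal(groups[[1]]$peptides, c(pep1, pep2))
  # a single supporting peptide is not enough
  expect_length(cluster_gssps(a[1, ], min_support = 2L), 0L)
})

test_that("start-codon selection matches exhaustive enumeration under both policies", {
  w <- toy_world()
  orfs <- extract_orfs(w$genome)
  idx <- build_peptide_index(c(dummy = "MWHMWHMWHMWH"), orfs)
  pep1 <- substr(w$novel_prot, w$pep_offset_aa + 1, w$pep_offset_aa + 6)
  pep2 <- substr(w$novel_prot, w$pep_offset_aa + 4, w$pep_offset_aa + 11)
  a <- classify_peptides(c(pep1, pep2), idx)
  group <- cluster_gssps(a, 2L)[[1]]

  # oracle: scan every in-frame position from the segment start to the most
  # upstream peptide for allowed codons
  seq <- w$genome$seq[["chr"]]
  lead <- min(group$hits$start)
  cand <- seq(w$seg_start, lead, by = 3)
  codons <- substring(seq, cand + 1, cand + 3)
  allowed <- c("ATG", "GTG", "TTG", "CTG", "ATA", "ATT")
  hits <- cand[codons %in% allowed]
  expect_gte(length(hits), 3L)   # the three planted candidates

  m_min <- propose_model(group, w$genome, orfs,
                         start_codon_policy(selection = "minimal_extension"))
  m_max <- propose_model(group, w$genome, orfs,
                         start_codon_policy(selection = "maximal_extension"))
  expect_equal(m_min$start, max(hits))
  expect_equal(m_max$start, min(hits))
  expect_equal(m_max$start, w$seg_start)       # first candidate is the ATG
  expect_identical(m_max$start_codon, "ATG")
  # model ends at the bounding stop and translates cleanly
  expect_equal(m_min$end, w$seg_end + 3L)
  expect_false(grepl("*", m_min$protein, fixed = TRUE))
  # restricted start-codon set without any candidate flags the event
  m_none <- propose_model(group, w$genome, orfs,
                          start_codon_policy(allowed = "CCC"))
  expect_true(m_none$flagged)
  expect_true(is.na(m_none$start_codon))
})

test_that("event categories follow the overlap/frame/upstream rules", {
  b <- small_bundle()
  run <- small_run()
  ev <- run$events
  ann <- b$annotation[b$annotation$coding_ok, ]
  for (i in seq_len(nrow(ev))) {
    ov <- ann[ann$seqid == ev$seqid[i] & ann$start < ev$end[i] &
                ann$end > ev$start[i], ]
    if (ev$category[i] == "intergenic") {
      expect_equal(nrow(ov), 0L)
    } else if (ev$category[i] == "antisense") {
      expect_true(nrow(ov) > 0 && all(ov$strand != ev$strand[i]))
    } else if (ev$category[i] == "n_term_extension") {
      g <- ann[ann$gene_id == ev$revised_gene_id[i], ]
      expect_identical(g$strand, ev$strand[i])
      if (g$strand == "+") {
        expect_equal(g$end, ev$end[i])          # shared stop
        expect_lt(ev$start[i], g$start)         # strictly upstream start
        expect_equal((g$start - ev$start[i]) %% 3L, 0L)
      } else {
        expect_equal(g$start, ev$start[i])
        expect_gt(ev$end[i], g$end)
        expect_equal((ev$end[i] - g$end) %% 3L, 0L)
      }
    } else if (ev$category[i] == "alt_frame") {
      same <- ov[ov$strand == ev$strand[i], ]
      expect_gt(nrow(same), 0)
    }
  }
})

test_that("supporting peptides are in-frame substrings of the proposed model", {
  run <- small_run()
  ev <- run$events
  for (i in seq_len(nrow(ev))) {
    for (p in ev$peptides[[i]]) {
      pos <- regexpr(p, ev$protein[i], fixed = TRUE)
      expect_gt(pos, 0)
    }
    expect_gte(ev$n_support[i], 2L)
  }
})

test_that("raising min_support never adds events, and zero GSSPs give zero events", {
  b <- small_bundle()
  run <- small_run()
  orfs <- run$orfs
  ev2 <- run$events
  ev3 <- call_events(run$assignments, b$annotation, b$genome, orfs,
                     min_support = 3L)
  key <- function(e) paste(e$seqid, e$start, e$end, e$strand)
  expect_true(all(key(ev3) %in% key(ev2)))
  # classify only reference peptides: no GSSPs, no events
  idx <- build_peptide_index(b$proteome, orfs)
  a <- classify_peptides(digest(b$proteome[[1]])$sequence[1:4], idx)
  expect_equal(nrow(call_events(a, b$annotation, b$genome, orfs)), 0L)
})
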