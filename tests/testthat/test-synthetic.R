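# The synthetic-data generator: determinism, manifest bookkeeping, and
# consistency of the planted world with the pipeline's definitions.

test_that("identical seeds give byte-identical bundles", {
  b1 <- generate_synthetic(small_config())
  b2 <- generate_synthetic(small_config())
  expect_identical(b1$genome$seq, b2$genome$seq)
  expect_identical(b1$psms, b2$psms)
  expect_identical(b1$quant$matrix, b2$quant$matrix)
  expect_identical(b1$truth$novel_orfs, b2$truth$novel_orfs)
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seeds differ
  b3 <- generate_synthetic(small_config(seed = 12L))
  expect_false(identical(b1$genome$seq, b3$genome$seq))
})

test_that("the manifest reflects the configured planting", {
  b <- small_bundle()
  cfg <- b$config
  expect_equal(nrow(b$truth$novel_orfs), sum(cfg$planted))
  expect_equal(as.integer(table(b$truth$novel_orfs$category)[
    c("alt_frame", "antisense", "intergenic")]),
    as.integer(cfg$planted[c("alt_frame", "antisense", "intergenic")]))
  expect_equal(nrow(b$truth$truncations), cfg$n_truncated)
  expect_equal(nrow(b$annotation), cfg$n_genes)
  expect_equal(unname(nchar(b$genome$seq)), cfg$replicon_lengths)
})

test_that("annotated genes are valid ORFs and truncations remain in-frame", {
  b <- small_bundle()
  expect_true(all(b$annotation$coding_ok))
  expect_false(any(grepl("*", b$proteome, fixed = TRUE)))
  tt <- b$truth$truncations
  ann <- b$annotation
  for (i in seq_len(nrow(tt))) {
    a <- ann[ann$gene_id == tt$gene_id[i], ]
    if (tt$strand[i] == "+") {
      expect_equal(a$start - tt$true_start[i], b$config$truncation_nt)
      expect_equal(a$end, tt$true_end[i])
    } else {
      expect_equal(tt$true_end[i] - a$end, b$config$truncation_nt)
      expect_equal(a$start, tt$true_start[i])
    }
    # the true (restored) model still translates without internal stops
    p <- protannotate:::translate_interval(
      b$genome, tt$seqid[i],
      if (tt$strand[i] == "+") tt$true_start[i] else tt$true_start[i],
      tt$true_end[i], tt$strand[i])
    expect_false(grepl("*", substr(p, 1, nchar(p) - 1), fixed = TRUE))
    expect_identical(substr(p, nchar(p), nchar(p)), "*")
  }
})

test_that("planted novel ORFs exist as six-frame segments at their stated coordinates", {
  b <- small_bundle()
  orfs <- extract_orfs(b$genome)
  tn <- b$truth$novel_orfs
  for (i in seq_len(nrow(tn))) {
    hit <- orfs[orfs$seqid == tn$seqid[i] & orfs$start == tn$orf_start[i] &
                  orfs$end == tn$orf_end[i] & orfs$strand == tn$strand[i], ]
    expect_equal(nrow(hit), 1L, label = tn$label[i])
    expect_identical(hit$protein, tn$protein[i])
    expect_true(hit$up_stop && hit$down_stop)
  }
})

test_that("every true PSM is a tryptic fragment of its stated source", {
  b <- small_bundle()
  true_psms <- b$psms[!b$psms$is_decoy & b$psms$source != "noise", ]
  src_prot <- c(b$proteome,
                setNames(b$truth$novel_orfs$protein, b$truth$novel_orfs$label))
  # truncated genes: peptides come from the full-length (true) protein
  tt <- b$truth$truncations
  for (i in seq_len(nrow(tt))) {
    p <- protannotate:::translate_interval(b$genome, tt$seqid[i],
                                           tt$true_start[i], tt$true_end[i],
                                           tt$strand[i])
    src_prot[tt$gene_id[i]] <- substr(p, 1, nchar(p) - 1)
  }
  set.seed(100)
  check <- true_psms[sample.int(nrow(true_psms), 50), ]
  for (i in seq_len(nrow(check))) {
    src <- sub(":upstream$", "", check$source[i])
    parent <- src_prot[[src]]
    expect_true(check$peptide[i] %in%
                  oracle_digest(parent, max_missed = 2, min_len = 6,
                                max_len = 50),
                label = paste(check$peptide[i], "from", src))
  }
})

test_that("noise peptides are true negatives and decoys come from reversed proteins", {
  cfg <- small_config(seed = 21L, noise_fraction = 0.1)
  b <- generate_synthetic(cfg)
  noise <- b$truth$noise_peptides
  expect_gt(length(noise), 0L)
  orfs <- extract_orfs(b$genome)
  idx <- build_peptide_index(b$proteome, orfs)
  a <- classify_peptides(noise, idx)
  expect_true(all(a$category == "unmatched"))
  rev_prot <- make_decoy_proteins(b$proteome)
  decoys <- unique(b$psms$peptide[b$psms$is_decoy])
  some <- decoys[seq_len(min(10, length(decoys)))]
  for (p in some)
    expect_true(any(vapply(rev_prot, function(s)
      grepl(p, s, fixed = TRUE), logical(1))))
})

test_that("infeasible packings are rejected", {
  cfg <- small_config(seed = 3L)
  cfg$replicon_lengths <- c(3000L, 1000L)
  expect_error(generate_synthetic(cfg), "infeasible packing")
})
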