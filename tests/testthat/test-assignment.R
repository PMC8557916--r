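# Target-decoy FDR filtering, peptide classification and protein inference.

psm_df <- function(scores, decoy) {
  data.frame(spectrum_id = sprintf("s%d", seq_along(scores)),
             peptide = strrep("A", 7 + seq_along(scores) %% 3),
             score = scores, is_decoy = decoy, engine = "sim",
             stringsAsFactors = FALSE)
}

test_that("FDR cutoff maximizes accepted targets under the decoy constraint", {
  psms <- psm_df(c(9, 8, 7, 6, 5, 5.5), c(rep(FALSE, 5), TRUE))
  acc <- fdr_filter(psms, threshold = 0.01)
  # oracle: brute force over all candidate cutoffs
  exp_cut <- oracle_fdr_cutoff(c(9, 8, 7, 6, 5), 5.5, 0.01)
  expect_equal(attr(acc, "score_cutoff"), exp_cut)
  expect_setequal(acc$score, c(9, 8, 7, 6))

  # no decoys: estimated FDR 0, everything accepted
  all_t <- psm_df(c(3, 2, 1), rep(FALSE, 3))
  expect_equal(nrow(fdr_filter(all_t, 0.01)), 3L)

  # decoys dominating: nothing survives
  dom <- psm_df(c(1, 2, 9, 10, 11), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_warning(out <- fdr_filter(dom, 0.01), "no score cutoff")
  expect_equal(nrow(out), 0L)

  expect_warning(fdr_filter(psm_df(5, TRUE), 0.01), "no target")
})

test_that("FDR cutoff equals the brute-force oracle on random score mixtures", {
  set.seed(60)
  for (rep in 1:50) {
    nt <- sample(20:100, 1); nd <- sample(5:50, 1)
    t_sc <- round(rnorm(nt, 30, 8), 3)
    d_sc <- round(rnorm(nd, sample(c(10, 20, 28), 1), 6), 3)
    psms <- psm_df(c(t_sc, d_sc), c(rep(FALSE, nt), rep(TRUE, nd)))
    thr <- sample(c(0.01, 0.05, 0.1), 1)
    exp_cut <- oracle_fdr_cutoff(t_sc, d_sc, thr)
    got <- suppressWarnings(fdr_filter(psms, thr))
    if (is.na(exp_cut)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(attr(got, "score_cutoff"), exp_cut)
      expect_equal(nrow(got), sum(t_sc >= exp_cut))
      # empirical decoy fraction at the cutoff respects the threshold
      expect_lte(sum(d_sc >= exp_cut) / sum(t_sc >= exp_cut), thr)
    }
  }
})

test_that("classification follows contaminant > reference > six-frame precedence", {
  b <- small_bundle()
  orfs <- extract_orfs(b$genome)
  # a reference protein's tryptic peptide is also in the six-frame DB by
  # construction: reference must win
  ref_pep <- digest(b$proteome[[1]])$sequence[1]
  contam <- c(keratin = paste0("MSTT", ref_pep, "GGWWA"))
  idx <- build_peptide_index(b$proteome, orfs, contaminants = contam)
  a <- classify_peptides(ref_pep, idx)
  expect_identical(a$category, "contaminant")
  idx2 <- build_peptide_index(b$proteome, orfs)
  a2 <- classify_peptides(ref_pep, idx2)
  expect_identical(a2$category, "known")
  expect_gte(nrow(a2$orf_hits[[1]]), 0L)  # orf hits not consulted for knowns
  # a planted GSSP matches only the genome
  gssp <- b$truth$planted_gssps[[b$truth$novel_orfs$label[1]]][1]
  a3 <- classify_peptides(gssp, idx2)
  expect_identical(a3$category, "gssp")
  expect_true(a3$is_unique)
  expect_identical(a3$n_protein_hits, 0L)
  # nonsense peptide is unmatched
  expect_identical(classify_peptides("WWWWHHHHWWWW", idx2)$category,
                   "unmatched")
})

test_that("I/L collapse is off by default and merges hits when enabled", {
  ref <- c(p1 = "MAAALDEKAAGW")
  orfs <- extract_orfs(make_genome(c(r = random_dna_str(300))))
  idx_off <- build_peptide_index(ref, orfs)
  idx_on <- build_peptide_index(ref, orfs, collapse_IL = TRUE)
  expect_identical(classify_peptides("AIDEK", idx_off)$category, "unmatched")
  expect_identical(classify_peptides("AIDEK", idx_on)$category, "known")
})

test_that("every tryptic peptide of the reference is found at its generating offset", {
  b <- small_bundle()
  idx <- build_peptide_index(b$proteome, extract_orfs(b$genome))
  peps <- digest_set(b$proteome)
  set.seed(61)
  peps <- peps[sample.int(nrow(peps), 40), ]
  a <- classify_peptides(peps$sequence, idx)
  for (i in seq_len(nrow(peps))) {
    row <- a[a$peptide == peps$sequence[i], ]
    expect_true(row$category %in% c("known", "shared_known"))
    h <- row$protein_hits[[1]]
    expect_true(any(h$protein_id == peps$parent_id[i] &
                      h$offset == peps$start[i]))
  }
})

test_that("protein inference applies the two-unique-peptide rule", {
  set.seed(64)
  ref <- c(pA = random_protein_str(120),
           pB = random_protein_str(110))
  ref["pC"] <- ref[["pB"]]                      # pB/pC share everything
  ref["pD"] <- random_protein_str(90)
  orfs <- extract_orfs(make_genome(c(r = random_dna_str(300))))
  idx <- build_peptide_index(ref, orfs)
  pepsA <- digest(ref[["pA"]])$sequence[1:2]    # two unique peptides
  pepsB <- digest(ref[["pB"]])$sequence[1:2]    # shared between pB and pC
  pepsD <- digest(ref[["pD"]])$sequence[1]      # one unique peptide
  a <- classify_peptides(c(pepsA, pepsB, pepsD), idx)
  ev <- infer_proteins(a, ref)
  st <- setNames(ev$status, ev$protein_id)
  expect_identical(unname(st[c("pA", "pB", "pC", "pD")]),
                   c("identified", "shared_only", "shared_only",
                     "single_peptide"))
  # undetected protein has zero coverage
  ref2 <- c(ref, pE = random_protein_str(70))
  ev2 <- infer_proteins(a, ref2)
  expect_identical(ev2$status[ev2$protein_id == "pE"], "undetected")
  expect_equal(ev2$coverage[ev2$protein_id == "pE"], 0)
})

test_that("coverage is the reduced residue footprint over protein length", {
  ref <- c(p1 = paste0(strrep("A", 44), "K", strrep("G", 55)))  # 100 aa
  orfs <- extract_orfs(make_genome(c(r = random_dna_str(300))))
  idx <- build_peptide_index(ref, orfs)
  a <- classify_peptides(substr(ref[["p1"]], 1, 50), idx)  # 50-aa peptide
  ev <- infer_proteins(a, ref)
  expect_equal(ev$coverage, 0.5)
  stats <- coverage_stats(ev)
  expect_equal(stats$n_single_peptide, 1L)
  expect_true(ev$is_microprotein)  # 100 aa is within the microprotein bound
})

test_that("redundancy groups recover planted duplicate sequences", {
  set.seed(62)
  prot <- setNames(vapply(1:8, function(i) random_protein_str(60),
                          character(1)), paste0("p", 1:8))
  prot["p2"] <- prot[["p1"]]
  prot["p7"] <- prot[["p5"]]
  prot["p8"] <- prot[["p5"]]
  g <- group_redundant(prot)
  expect_equal(nrow(g), 2L)
  expect_setequal(g$members[[which(g$n_members == 2)]], c("p1", "p2"))
  expect_setequal(g$members[[which(g$n_members == 3)]], c("p5", "p7", "p8"))
  expect_equal(nrow(group_redundant(prot[c("p1", "p3", "p4")])), 0L)
})

test_that("reference-only PSM sets yield zero GSSPs and a clean partition", {
  b <- small_bundle()
  idx <- build_peptide_index(b$proteome, extract_orfs(b$genome))
  set.seed(63)
  peps <- digest_set(b$proteome)
  peps <- unique(peps$sequence[sample.int(nrow(peps), 60)])
  a <- classify_peptides(peps, idx)
  expect_equal(sum(a$category == "gssp"), 0L)
  expect_equal(sum(a$category == "unmatched"), 0L)
  # category partition: one category per peptide, no overlap by construction
  expect_equal(nrow(a), length(peps))
})
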