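# Signal-peptide prediction intersection, MS-based refutation, and the
# cleavage-site motif matrix.

write_pred <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("prediction tables validate cleavage positions and deduplicate", {
  prot <- c(pA = random_protein_str(50), pB = random_protein_str(40),
            pC = random_protein_str(30))
  f <- write_pred(data.frame(protein_id = c("pA", "pB", "pC"),
                             cleavage_pos = c(20, 25, 22), score = 0.9))
  p <- read_predictions(f, "predisi", prot)
  expect_equal(nrow(p), 3L)
  expect_identical(unique(p$predictor), "predisi")
  # c == protein length is invalid (no mature protein would remain)
  f2 <- write_pred(data.frame(protein_id = "pC", cleavage_pos = 30,
                              score = 0.9))
  expect_warning(p2 <- read_predictions(f2, "x", prot), "out of range")
  expect_equal(nrow(p2), 0L)
  f3 <- write_pred(data.frame(protein_id = c("pA", "pA"),
                              cleavage_pos = c(20, 21), score = c(0.8, 0.9)))
  expect_warning(p3 <- read_predictions(f3, "x", prot), "duplicate")
  expect_equal(p3$cleavage_pos, 21L)
  f4 <- write_pred(data.frame(protein_id = "pA", score = 0.9))
  expect_error(read_predictions(f4, "x", prot), "cleavage_pos")
})

test_that("intersection requires both predictors to agree within tolerance", {
  a <- data.frame(protein_id = c("p1", "p2", "p3"),
                  cleavage_pos = c(20L, 22L, 25L), predictor = "a",
                  score = 0.9, stringsAsFactors = FALSE)
  b <- data.frame(protein_id = c("p1", "p3", "p4"),
                  cleavage_pos = c(20L, 26L, 19L), predictor = "b",
                  score = 0.8, stringsAsFactors = FALSE)
  cons0 <- intersect_predictions(a, b, tolerance = 0L)
  expect_identical(cons0$protein_id, "p1")
  cons1 <- intersect_predictions(a, b, tolerance = 1L)
  expect_setequal(cons1$protein_id, c("p1", "p3"))
  expect_equal(cons1$cleavage_pos[cons1$protein_id == "p3"], 25L)  # a's value
})

test_that("peptides overlapping the signal region refute the prediction", {
  pred <- data.frame(protein_id = "p1", cleavage_pos = 25L, predictor = "a",
                     score = 0.9, stringsAsFactors = FALSE)
  ev_in <- data.frame(protein_id = "p1", start = 10L, end = 18L)
  ev_out <- data.frame(protein_id = "p1", start = 30L, end = 40L)
  expect_identical(refute(pred, ev_in)$status, "refuted")
  expect_identical(refute(pred, ev_out)$status, "retained")
  # initiator-Met excision exemption
  ev_met <- data.frame(protein_id = "p1", start = 2L, end = 9L)
  expect_identical(refute(pred, ev_met)$status, "refuted")
  expect_identical(refute(pred, ev_met, exempt_met_excision = TRUE)$status,
                   "retained")
})

test_that("refutation equals a brute-force interval-overlap oracle", {
  set.seed(80)
  for (rep in 1:30) {
    n_pred <- sample(3:8, 1)
    preds <- data.frame(protein_id = paste0("p", seq_len(n_pred)),
                        cleavage_pos = sample(10:40, n_pred, replace = TRUE),
                        predictor = "a", score = 0.9,
                        stringsAsFactors = FALSE)
    ev <- data.frame(
      protein_id = sample(preds$protein_id, 15, replace = TRUE),
      start = sample(1:60, 15, replace = TRUE))
    ev$end <- ev$start + sample(6:20, 15, replace = TRUE)
    min_ov <- sample(1:3, 1)
    r <- refute(preds, ev, min_overlap = min_ov)
    for (i in seq_len(n_pred)) {
      pe <- ev[ev$protein_id == preds$protein_id[i], ]
      exp_ref <- nrow(pe) > 0 &&
        oracle_refuted(preds$cleavage_pos[i], pe$start, pe$end, min_ov)
      expect_identical(r$status[i] == "refuted", exp_ref)
    }
    # retained + refuted partitions the prediction set
    expect_equal(sum(r$status == "refuted") + sum(r$status == "retained"),
                 n_pred)
  }
})

test_that("refutation is monotone in evidence", {
  set.seed(81)
  preds <- data.frame(protein_id = paste0("p", 1:5),
                      cleavage_pos = sample(15:30, 5), predictor = "a",
                      score = 0.9, stringsAsFactors = FALSE)
  ev1 <- data.frame(protein_id = sample(preds$protein_id, 5, replace = TRUE),
                    start = sample(1:40, 5, replace = TRUE))
  ev1$end <- ev1$start + 8L
  ev2 <- rbind(ev1, data.frame(protein_id = "p1", start = 1L, end = 10L))
  r1 <- refute(preds, ev1); r2 <- refute(preds, ev2)
  expect_true(all(!(r1$status == "refuted" & r2$status == "retained")))
})

test_that("cleavage motif columns are frequencies and recover the planted A at -1/-3", {
  # one-hot single prediction
  prot <- c(p1 = "MKKLLLLAVAGGGGGGGGGG")
  pred <- data.frame(protein_id = "p1", cleavage_pos = 10L, predictor = "a",
                     score = 1, stringsAsFactors = FALSE)
  pfm <- cleavage_motif(pred, prot)
  expect_equal(pfm["A", "-1"], 1)    # residue 10
  expect_equal(pfm["V", "-2"], 1)    # residue 9
  expect_equal(pfm["A", "-3"], 1)    # residue 8
  expect_equal(unname(colSums(pfm)[c("-1", "+1")]), c(1, 1))

  # generator truth: designed signal proteins carry A at -1 and -3
  b <- small_bundle()
  truth <- b$truth$signal
  preds <- data.frame(protein_id = truth$protein_id,
                      cleavage_pos = truth$cleavage_pos, predictor = "t",
                      score = 1, stringsAsFactors = FALSE)
  pfm2 <- cleavage_motif(preds, b$proteome)
  expect_identical(rownames(pfm2)[which.max(pfm2[, "-1"])], "A")
  expect_identical(rownames(pfm2)[which.max(pfm2[, "-3"])], "A")
  expect_true(all(abs(colSums(pfm2) - 1) < 1e-9))
})
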