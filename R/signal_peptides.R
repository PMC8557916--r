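# Signal-peptide prediction handling: intersect two predictors, refute
# predictions contradicted by MS peptide coverage of the predicted signal
# region (a cleaved signal peptide should never be observed in the mature
# proteome), and summarize the cleavage-site sequence motif.

#' Read a signal-peptide prediction table
#'
#' @param path TSV with columns `protein_id`, `cleavage_pos` (the signal
#'   peptide is residues `1..cleavage_pos`, 1-based) and `score`.
#' @param predictor Predictor name recorded with each row.
#' @param proteome Optional named character vector; rows with
#'   `cleavage_pos >= protein length` are rejected with a warning.
#' @return `data.frame` with `protein_id`, `cleavage_pos`, `predictor`,
#'   `score`. Duplicate `(protein_id)` rows keep the last one, with a
#'   warning.
#' @export
read_predictions <- function(path, predictor, proteome = NULL) {
  df <- read_tsv(path, required = c("protein_id", "cleavage_pos", "score"))
  df$cleavage_pos <- as.integer(df$cleavage_pos)
  df$predictor <- predictor
  bad <- df$cleavage_pos < 1L
  if (!is.null(proteome)) {
    len <- nchar(proteome)[df$protein_id]
    bad <- bad | (!is.na(len) & df$cleavage_pos >= len)
  }
  if (any(bad)) {
    warning(sum(bad), " prediction(s) with cleavage position out of range ",
            "rejected", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df$protein_id, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate prediction(s) for ",
            paste(unique(df$protein_id[dup]), collapse = ", "),
            "; keeping the last", call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("protein_id", "cleavage_pos", "predictor", "score")]
}

#' Intersect two predictors' signal-peptide calls
#'
#' Keeps proteins predicted by both, with cleavage positions agreeing within
#' `tolerance` residues; the consensus keeps the first set's position.
#'
#' @param preds_a,preds_b Prediction data.frames ([read_predictions()]).
#' @param tolerance Maximum allowed cleavage-position difference (default 0).
#' @return Consensus prediction data.frame (positions from `preds_a`).
#' @export
intersect_predictions <- function(preds_a, preds_b, tolerance = 0L) {
  m <- merge(preds_a, preds_b, by = "protein_id", suffixes = c("", ".b"))
  keep <- abs(m$cleavage_pos - m$cleavage_pos.b) <= tolerance
  out <- m[keep, c("protein_id", "cleavage_pos", "predictor", "score"),
           drop = FALSE]
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refute signal-peptide predictions by MS peptide coverage
#'
#' A prediction is refuted when any identified peptide overlaps the
#' predicted signal region (residues `1..cleavage_pos`) by at least
#' `min_overlap` residues; otherwise it is retained.
#'
#' @param predictions Prediction data.frame.
#' @param peptide_evidence `data.frame` with `protein_id`, `start`, `end`
#'   (1-based inclusive residue intervals of identified peptides).
#' @param min_overlap Minimum overlapping residues to refute (default 1).
#' @param exempt_met_excision If `TRUE`, peptides beginning at residue 2 do
#'   not refute (initiator-Met excision can expose residue 2 without signal
#'   cleavage); default `FALSE`.
#' @return `data.frame`: predictions plus `status`
#'   (`retained`/`refuted`) and `n_refuting` peptide count, with list-column
#'   `refuting_peptides` of row indices into `peptide_evidence`.
#' @export
refute <- function(predictions, peptide_evidence, min_overlap = 1L,
                   exempt_met_excision = FALSE) {
  .check_flag(exempt_met_excision, "exempt_met_excision")
  ev <- peptide_evidence
  if (exempt_met_excision) ev <- ev[ev$start != 2L, , drop = FALSE]
  status <- character(nrow(predictions))
  n_ref <- integer(nrow(predictions))
  refuting <- vector("list", nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    c_pos <- predictions$cleavage_pos[i]
    pe <- ev[ev$protein_id == predictions$protein_id[i], , drop = FALSE]
    ovl <- pmin(pe$end, c_pos) - pmax(pe$start, 1L) + 1L
    hit <- which(ovl >= min_overlap)
    n_ref[i] <- length(hit)
    refuting[[i]] <- pe[hit, , drop = FALSE]
    status[i] <- if (length(hit)) "refuted" else "retained"
  }
  out <- predictions
  out$status <- status
  out$n_refuting <- n_ref
  out$refuting_peptides <- refuting
  out
}

#' Position frequency matrix around predicted cleavage sites
#'
#' Residue frequencies per position relative to the cleavage site over the
#' retained predictions. Position -1 is the last signal residue
#' (`cleavage_pos`), position +1 the first mature residue; there is no
#' position 0. Positions clipped at protein boundaries are excluded from
#' that column's denominator.
#'
#' @param predictions Prediction data.frame (retained predictions only).
#' @param proteome Named character vector.
#' @param window Integer pair `(from, to)` of relative positions, default
#'   `c(-10, 2)`.
#' @return Numeric matrix, 20 amino-acid rows by window-position columns;
#'   every column sums to 1 (or is all-zero when no residue is in range).
#' @export
cleavage_motif <- function(predictions, proteome, window = c(-10L, 2L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rel <- setdiff(seq(window[1], window[2]), 0L)
  pfm <- matrix(0, nrow = length(aa), ncol = length(rel),
                dimnames = list(aa, ifelse(rel > 0, paste0("+", rel), rel)))
  for (i in seq_len(nrow(predictions))) {
    prot <- proteome[[predictions$protein_id[i]]]
    if (is.null(prot)) next
    c_pos <- predictions$cleavage_pos[i]
    for (j in seq_along(rel)) {
      pos <- c_pos + if (rel[j] < 0) rel[j] + 1L else rel[j]
      if (pos < 1L || pos > nchar(prot)) next
      r <- substr(prot, pos, pos)
      if (r %in% aa) pfm[r, j] <- pfm[r, j] + 1
    }
  }
  sums <- colSums(pfm)
  nz <- sums > 0
  pfm[, nz] <- sweep(pfm[, nz, drop = FALSE], 2, sums[nz], "/")
  pfm
}
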