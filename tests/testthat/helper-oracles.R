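# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: translation is a codon-by-codon table walk, ORF
# scanning enumerates stop-free windows directly, digestion enumerates
# cleavage-site subsets, the FDR cutoff is found by trying every candidate,
# and the t statistic uses the closed-form pooled expression.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_translate <- function(seq, strand = "+", offset = 0) {
  code <- Biostrings::getGeneticCode("11")
  if (strand == "-") seq <- oracle_revcomp(seq)
  seq <- substr(seq, offset + 1, nchar(seq))
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(seq, 3 * i - 2, 3 * i)
    out[i] <- if (grepl("N", codon)) "X" else unname(code[codon])
  }
  paste(out, collapse = "")
}

# stop-free windows longer than min_len in all six frames, with genomic
# coordinates, by direct scanning
oracle_orfs <- function(seqs, min_len = 20, bounded_only = FALSE) {
  rows <- list()
  for (sid in names(seqs)) {
    L <- nchar(seqs[[sid]])
    for (frame in 1:6) {
      strand <- if (frame >= 4) "-" else "+"
      o <- (frame - 1) %% 3
      tr <- oracle_translate(seqs[[sid]], strand, o)
      aa <- strsplit(tr, "")[[1]]
      i <- 1
      while (i <= length(aa)) {
        if (aa[i] == "*") { i <- i + 1; next }
        j <- i
        while (j < length(aa) && aa[j + 1] != "*") j <- j + 1
        len <- j - i + 1
        up <- i > 1
        down <- j < length(aa)
        if (len > min_len && (!bounded_only || (up && down))) {
          i0 <- i - 1
          if (strand == "+") { gs <- o + 3 * i0; ge <- o + 3 * (i0 + len) }
          else { gs <- L - o - 3 * (i0 + len); ge <- L - o - 3 * i0 }
          rows[[length(rows) + 1]] <- data.frame(
            seqid = sid, start = gs, end = ge, strand = strand,
            frame = frame, protein = paste(aa[i:j], collapse = ""),
            up_stop = up, down_stop = down, stringsAsFactors = FALSE)
        }
        i <- j + 2
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(out$seqid, out$frame, out$start), , drop = FALSE]
}

# every fragment over every choice of adjacent cleavage-boundary pairs
oracle_digest <- function(protein, max_missed = 2, min_len = 6,
                          max_len = 50) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  bounds <- c(0, which(res %in% c("K", "R") & seq_len(n) < n), n)
  out <- character()
  for (a in seq_len(length(bounds) - 1)) {
    for (b in (a + 1):length(bounds)) {
      missed <- b - a - 1
      if (missed > max_missed) next
      frag <- substr(protein, bounds[a] + 1, bounds[b])
      if (nchar(frag) >= min_len && nchar(frag) <= max_len)
        out <- c(out, frag)
    }
  }
  out
}

# lowest cutoff (over all observed scores) passing the FDR constraint
oracle_fdr_cutoff <- function(target_scores, decoy_scores, threshold) {
  cand <- sort(unique(c(target_scores, decoy_scores)))
  best <- NA_real_
  for (s in rev(cand)) {
    nt <- sum(target_scores >= s)
    nd <- sum(decoy_scores >= s)
    if (nt > 0 && nd / nt <= threshold) best <- s
  }
  if (is.na(best)) return(NA_real_)
  # accepted set is defined by the target scores >= best
  min(target_scores[target_scores >= best])
}

oracle_refuted <- function(c_pos, pep_starts, pep_ends, min_overlap = 1) {
  any(mapply(function(s, e) {
    ov <- min(e, c_pos) - max(s, 1) + 1
    ov >= min_overlap
  }, pep_starts, pep_ends))
}

oracle_t_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
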