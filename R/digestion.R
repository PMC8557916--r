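# In-silico trypsin/P digestion: cleavage after every K or R, including when
# the next residue is proline. Used by the synthetic PSM generator and by
# peptide-uniqueness computations.

#' Digest a protein with trypsin/P
#'
#' Cleaves after every K/R (trypsin/P: also before P) and returns all
#' fragments carrying up to `max_missed` internal cleavage sites, filtered to
#' the `[min_len, max_len]` length window. With `min_len = 1` and
#' `max_len = Inf` the 0-missed fragments concatenate to the input.
#'
#' @param protein Amino-acid string.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_len,max_len Peptide length window; defaults 6 and 50 (common
#'   search-engine convention: peptides shorter than six residues excluded).
#' @return `data.frame` with `sequence`, `start` (0-based residue offset in
#'   the parent) and `missed_cleavages`.
#' @export
digest <- function(protein, max_missed = 2L, min_len = 6L, max_len = 50L) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L)
  n <- nchar(protein)
  res <- strsplit(protein, "")[[1]]
  sites <- which(res == "K" | res == "R")     # cleave after these positions
  bounds <- c(0L, sites[sites < n], n)        # fragment boundaries
  nb <- length(bounds)
  out <- vector("list", max_missed + 1L)
  for (k in 0:max_missed) {
    i <- seq_len(nb - 1L - k)
    if (!length(i)) break
    s <- bounds[i]
    e <- bounds[i + 1L + k]
    out[[k + 1L]] <- data.frame(
      sequence = substring(protein, s + 1L, e),
      start = s,
      missed_cleavages = k,
      stringsAsFactors = FALSE
    )
  }
  pep <- do.call(rbind, out)
  pep <- pep[nchar(pep$sequence) >= min_len & nchar(pep$sequence) <= max_len, ,
             drop = FALSE]
  rownames(pep) <- NULL
  pep
}

#' Digest a set of proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @inheritParams digest
#' @return `data.frame` with `parent_id`, `sequence`, `start`,
#'   `missed_cleavages`.
#' @export
digest_set <- function(proteins, max_missed = 2L, min_len = 6L, max_len = 50L) {
  stopifnot(!is.null(names(proteins)))
  out <- lapply(names(proteins), function(id) {
    d <- digest(proteins[[id]], max_missed, min_len, max_len)
    if (nrow(d)) cbind(parent_id = id, d, stringsAsFactors = FALSE) else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(parent_id = character(), sequence = character(),
                      start = integer(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
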