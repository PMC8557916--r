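# Shared low-level helpers: bacterial translation (table 11), reverse
# complement, and small input checks used across modules.

#' @importFrom Biostrings DNAString DNAStringSet AAStringSet reverseComplement
#'   getGeneticCode translate readDNAStringSet readAAStringSet writeXStringSet
#'   vmatchPattern width subseq
#' @importFrom IRanges IRanges reduce start end
#' @importFrom S4Vectors mcols metadata
NULL

# Bacterial/plastid genetic code (NCBI table 11). The codon table is identical
# to the standard code; only initiation codons differ, which is handled by the
# start-codon policy, not by translation.
.genetic_code_11 <- function() Biostrings::getGeneticCode("11")

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over the DNA alphabet (IUPAC codes allowed).
#' @return The reverse-complemented string.
#' @export
dna_revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a DNA string with table 11. Stop codons render as '*'; codons
# containing N render as 'X'; a trailing partial codon is dropped.
translate_dna <- function(x) {
  n <- nchar(x)
  n3 <- n - n %% 3L
  if (n3 == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n3)),
    genetic.code = .genetic_code_11(),
    if.fuzzy.codon = "X",
    no.init.codon = TRUE
  ))
}

# Extract the genomic subsequence [start, end) (0-based half-open) of a
# replicon, reverse-complemented for the minus strand.
fetch_interval <- function(genome, seqid, start, end, strand = "+") {
  seq <- genome_sequence(genome, seqid)
  s <- substr(seq, start + 1L, end)
  if (strand == "-") s <- dna_revcomp(s) else s
}

# Translate a genomic interval in its biological orientation.
translate_interval <- function(genome, seqid, start, end, strand = "+") {
  translate_dna(fetch_interval(genome, seqid, start, end, strand))
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

.valid_peptide <- function(x) grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)

# Deterministic TSV writers/readers shared by the table-based modules.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}
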