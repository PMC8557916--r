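# Genome and annotation I/O. This module owns the coordinate conventions used
# everywhere else: internal coordinates are 0-based half-open on the forward
# strand; external GFF3 files are standard 1-based inclusive. Minus-strand
# features keep their genomic orientation in the stored interval; the
# biological orientation is applied only at translation time.

#' Read a multi-replicon genome from FASTA
#'
#' Reads one or more replicons (chromosome and plasmids) into a `GenomeSet`.
#' Sequences are normalized to uppercase and must be over the alphabet
#' `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file of DNA sequences.
#' @param topology Either a single value recycled over all replicons or a
#'   vector (one per record); `"linear"` (default) or `"circular"`. Topology
#'   is recorded but replicons are processed as linear for ORF extraction
#'   (no wrap-around ORFs).
#' @return A `GenomeSet`: list with `seq` (named character vector of
#'   sequences, record order preserved) and `topology`.
#' @export
read_genome <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("genome file not found: ", path, call. = FALSE)
  # read without an alphabet so invalid characters are caught (not silently
  # dropped) by make_genome's validation
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty genome file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  make_genome(seqs, topology)
}

#' Construct a GenomeSet from in-memory sequences
#'
#' @param seqs Named character vector of DNA sequences.
#' @param topology `"linear"` or `"circular"`, recycled as needed.
#' @return A `GenomeSet`.
#' @export
make_genome <- function(seqs, topology = "linear") {
  if (length(seqs) == 0L) stop("a GenomeSet must be non-empty", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("replicon ids must be present and unique", call. = FALSE)
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters (other than N) in record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  topology <- rep_len(match.arg(topology, c("linear", "circular"),
                                several.ok = TRUE), length(seqs))
  structure(list(seq = seqs, topology = stats::setNames(topology, names(seqs))),
            class = "GenomeSet")
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat(sprintf("GenomeSet with %d replicon(s), %s bp total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  for (id in names(x$seq))
    cat(sprintf("  %s: %s bp (%s)\n", id,
                format(nchar(x$seq[[id]]), big.mark = ","), x$topology[[id]]))
  invisible(x)
}

genome_ids <- function(genome) names(genome$seq)

genome_sequence <- function(genome, seqid) {
  if (!seqid %in% names(genome$seq))
    stop("unknown replicon: ", seqid, call. = FALSE)
  genome$seq[[seqid]]
}

genome_length <- function(genome, seqid) nchar(genome_sequence(genome, seqid))

#' Total genome size in base pairs
#'
#' @param genome A `GenomeSet`.
#' @return Total length over all replicons, in bases.
#' @export
genome_size <- function(genome) sum(nchar(genome$seq))

#' Read a gene annotation from GFF3
#'
#' Imports CDS (or, if absent, gene) features and converts the 1-based
#' inclusive GFF3 coordinates to the internal 0-based half-open convention.
#' Features whose length is not divisible by 3 are flagged (`coding_ok =
#' FALSE`) with a warning and are excluded from reading-frame computations
#' downstream.
#'
#' @param path Path to a GFF3 file.
#' @param genome The `GenomeSet` the features refer to; unknown seqids are an
#'   error.
#' @return A `data.frame` (class `gene_annotation`) with columns `gene_id`,
#'   `seqid`, `start`, `end` (0-based half-open), `strand`, `product`,
#'   `is_putative`, `start_codon`, `coding_ok`.
#' @export
read_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[keep]
  if (length(gr) == 0L) return(empty_annotation())
  seqid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(seqid), genome_ids(genome))
  if (length(unknown))
    stop("annotation refers to unknown replicon(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$locus_tag
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  ids <- as.character(ids)
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  product <- gr$product
  if (is.null(product)) product <- rep(NA_character_, length(gr))
  ann <- data.frame(
    gene_id = ids,
    seqid = seqid,
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(product),
    stringsAsFactors = FALSE
  )
  if (any(!ann$strand %in% c("+", "-")))
    stop("annotation features must be stranded (+/-)", call. = FALSE)
  too_long <- ann$end > nchar(genome$seq[ann$seqid]) | ann$start < 0L
  if (any(too_long))
    stop("feature(s) out of replicon bounds: ",
         paste(ann$gene_id[too_long], collapse = ", "), call. = FALSE)
  ann$is_putative <- grepl("hypothetical|unknown|putative", ann$product,
                           ignore.case = TRUE) & !is.na(ann$product)
  ann$coding_ok <- (ann$end - ann$start) %% 3L == 0L
  if (any(!ann$coding_ok))
    warning("gene(s) with length not divisible by 3 flagged non-coding-length: ",
            paste(ann$gene_id[!ann$coding_ok], collapse = ", "), call. = FALSE)
  ann$start_codon <- annotation_start_codons(ann, genome)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

empty_annotation <- function() {
  ann <- data.frame(gene_id = character(), seqid = character(),
                    start = integer(), end = integer(), strand = character(),
                    product = character(), is_putative = logical(),
                    coding_ok = logical(), start_codon = character(),
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# First codon of each gene in biological orientation (revcomp of the last
# three genomic bases for minus-strand genes).
annotation_start_codons <- function(ann, genome) {
  vapply(seq_len(nrow(ann)), function(i) {
    s <- genome_sequence(genome, ann$seqid[i])
    if (ann$strand[i] == "+") substr(s, ann$start[i] + 1L, ann$start[i] + 3L)
    else dna_revcomp(substr(s, ann$end[i] - 2L, ann$end[i]))
  }, character(1))
}

#' Translate annotated genes into the reference proteome
#'
#' Translates every coding-length gene (table 11) and strips the trailing
#' stop. Gene models flagged `coding_ok = FALSE` are skipped.
#'
#' @param genome A `GenomeSet`.
#' @param annotation A `gene_annotation`.
#' @return Named character vector of protein sequences (names = gene ids).
#' @export
annotation_proteome <- function(genome, annotation) {
  ann <- annotation[annotation$coding_ok, , drop = FALSE]
  prots <- vapply(seq_len(nrow(ann)), function(i) {
    p <- translate_interval(genome, ann$seqid[i], ann$start[i], ann$end[i],
                            ann$strand[i])
    sub("\\*$", "", p)
  }, character(1))
  stats::setNames(prots, ann$gene_id)
}

#' Write an annotation (and optional novel events) to GFF3
#'
#' Output is deterministic: features sorted by (seqid, start, end, ID),
#' 1-based inclusive coordinates. Novel/revised models carry `category=`,
#' `supporting_peptides=` and `start_codon=` attributes.
#'
#' @param annotation A `gene_annotation` (may be empty).
#' @param path Output path.
#' @param events Optional `novel_events` data.frame from [call_events()].
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, events = NULL) {
  rows <- character()
  ids <- character()
  if (nrow(annotation)) {
    attr_str <- paste0("ID=", annotation$gene_id,
                       ifelse(is.na(annotation$product), "",
                              paste0(";product=", annotation$product)),
                       ";start_codon=", annotation$start_codon)
    rows <- sprintf("%s\tprotannotate\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                    annotation$seqid, annotation$start + 1L, annotation$end,
                    annotation$strand, attr_str)
    ids <- annotation$gene_id
    ord <- order(annotation$seqid, annotation$start, annotation$end, ids)
    rows <- rows[ord]
    key <- data.frame(seqid = annotation$seqid, start = annotation$start)[ord, ]
  } else {
    key <- data.frame(seqid = character(), start = integer())
  }
  if (!is.null(events) && nrow(events)) {
    ev_attr <- paste0(
      "ID=", events$event_id,
      ";category=", events$category,
      ";supporting_peptides=", vapply(events$peptides, paste,
                                      character(1), collapse = ","),
      ";start_codon=", ifelse(is.na(events$start_codon), "none",
                              events$start_codon),
      ifelse(is.na(events$revised_gene_id), "",
             paste0(";revises=", events$revised_gene_id)))
    erow <- sprintf("%s\tprotannotate\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                    events$seqid, events$start + 1L, events$end,
                    events$strand, ev_attr)
    eord <- order(events$seqid, events$start, events$end, events$event_id)
    rows <- c(rows, erow[eord])
    ids <- c(ids, events$event_id)
    key <- rbind(key, data.frame(seqid = events$seqid,
                                 start = events$start)[eord, ])
    ord2 <- order(key$seqid, key$start)
    rows <- rows[ord2]
  }
  if (anyDuplicated(ids))
    stop("duplicate feature IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  con <- file(path, "wb")  # binary mode keeps output bit-stable across OSes
  on.exit(close(con))
  writeLines(c("##gff-version 3", rows), con, sep = "\n")
  invisible(path)
}

#' Write a GenomeSet to FASTA
#'
#' @param genome A `GenomeSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a named protein set to FASTA
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector (names truncated at first whitespace).
#' @export
read_proteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
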