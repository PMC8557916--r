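# Six-frame translation and stop-to-stop ORF extraction: the proteogenomic
# search space. Frames 1-3 are the forward strand at offsets 0/1/2 from the
# replicon 5' end; frames 4-6 are the reverse complement at offsets 0/1/2
# from its 5' end. ORFs are maximal stop-free translated segments, not
# start-codon-initiated models; start selection happens later, at event
# calling.

#' Translate one reading frame of a sequence
#'
#' For the minus strand the sequence is reverse-complemented before the
#' offset is applied. Stop codons render as `*`; codons containing `N` render
#' as `X`; a trailing partial codon is dropped.
#'
#' @param sequence DNA string.
#' @param strand `"+"` or `"-"`.
#' @param offset Frame offset, 0, 1 or 2.
#' @return The amino-acid string for that frame.
#' @export
translate_frame <- function(sequence, strand = "+", offset = 0L) {
  stopifnot(offset %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") sequence <- dna_revcomp(sequence)
  translate_dna(substr(sequence, offset + 1L, nchar(sequence)))
}

frame_strand <- function(frame) ifelse(frame >= 4L, "-", "+")
frame_offset <- function(frame) (frame - 1L) %% 3L

#' Extract stop-to-stop ORFs from all six frames
#'
#' Each frame's translation is split at stop codons; every maximal stop-free
#' segment strictly longer than `min_len` amino acids becomes one ORF with
#' exact genomic coordinates. Segments at replicon edges that lack a bounding
#' stop are retained (with the corresponding `up_stop`/`down_stop` flag
#' `FALSE`) unless `include_unbounded = FALSE`.
#'
#' @param genome A `GenomeSet`.
#' @param min_len Minimum retained protein length is `min_len + 1` (the
#'   length filter is strictly greater than `min_len`); default 20.
#' @param include_unbounded Keep replicon-edge segments lacking a bounding
#'   stop (default `TRUE`).
#' @return A `data.frame` (class `sixframe_orfs`): `orf_id`, `seqid`,
#'   `start`, `end` (0-based half-open, genomic), `strand`, `frame` (1-6),
#'   `protein`, `up_stop`, `down_stop`.
#' @export
extract_orfs <- function(genome, min_len = 20L, include_unbounded = TRUE) {
  out <- vector("list", length(genome$seq) * 6L)
  k <- 0L
  for (seqid in genome_ids(genome)) {
    seq <- genome_sequence(genome, seqid)
    L <- nchar(seq)
    for (frame in 1:6) {
      strand <- frame_strand(frame)
      o <- frame_offset(frame)
      tr <- translate_frame(seq, strand, o)
      n_aa <- nchar(tr)
      if (n_aa == 0L) next
      m <- gregexpr("[^*]+", tr)[[1]]
      if (m[1] == -1L) next
      i0 <- as.integer(m) - 1L                 # 0-based aa offset in frame
      len <- attr(m, "match.length")
      up <- i0 > 0L
      down <- (i0 + len) < n_aa
      keep <- len > min_len
      if (!include_unbounded) keep <- keep & up & down
      if (!any(keep)) next
      i0 <- i0[keep]; len <- len[keep]; up <- up[keep]; down <- down[keep]
      if (strand == "+") {
        gs <- o + 3L * i0
        ge <- o + 3L * (i0 + len)
      } else {
        gs <- L - o - 3L * (i0 + len)
        ge <- L - o - 3L * i0
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        orf_id = sprintf("%s|%d|%d|%d", seqid, frame, gs + 1L, ge),
        seqid = seqid, start = gs, end = ge, strand = strand, frame = frame,
        protein = substring(tr, i0 + 1L, i0 + len),
        up_stop = up, down_stop = down,
        stringsAsFactors = FALSE
      )
    }
  }
  orfs <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(orf_id = character(), seqid = character(), start = integer(),
               end = integer(), strand = character(), frame = integer(),
               protein = character(), up_stop = logical(),
               down_stop = logical(), stringsAsFactors = FALSE)
  orfs <- orfs[order(orfs$seqid, orfs$frame, orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  class(orfs) <- c("sixframe_orfs", "data.frame")
  orfs
}

#' Write the six-frame ORF database to FASTA
#'
#' Headers encode `seqid|frame|start|end` (1-based inclusive genomic
#' coordinates) plus the bounding-stop flags, so the genomic interval of
#' every record round-trips exactly. Output is byte-identical across runs on
#' the same genome.
#'
#' @param orfs A `sixframe_orfs` data.frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
build_sixframe_db <- function(orfs, path) {
  ss <- Biostrings::AAStringSet(orfs$protein)
  names(ss) <- sprintf("%s u=%d d=%d", orfs$orf_id,
                       as.integer(orfs$up_stop), as.integer(orfs$down_stop))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a six-frame ORF database written by [build_sixframe_db()]
#'
#' @param path FASTA path.
#' @return A `sixframe_orfs` data.frame equivalent to the one written.
#' @export
read_sixframe_db <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  parts <- strsplit(id, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed six-frame header(s): ", paste(full[bad][1], collapse = ""),
         call. = FALSE)
  fields <- do.call(rbind, parts)
  frame <- as.integer(fields[, 2])
  orfs <- data.frame(
    orf_id = id,
    seqid = fields[, 1],
    start = as.integer(fields[, 3]) - 1L,
    end = as.integer(fields[, 4]),
    strand = frame_strand(frame),
    frame = frame,
    protein = as.character(ss),
    up_stop = grepl("u=1", full),
    down_stop = grepl("d=1", full),
    stringsAsFactors = FALSE
  )
  class(orfs) <- c("sixframe_orfs", "data.frame")
  orfs
}
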