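# Novel-gene and gene-model-revision calling. Unique GSSPs are grouped by
# their bounding stop-to-stop ORF, each group is classified against the
# annotation (intergenic / alt_frame / antisense / n_term_extension), and a
# coding model is proposed by selecting a start codon from an allowed set
# that covers the peptide evidence.

#' Start-codon selection policy
#'
#' @param allowed Ordered set of allowed start codons. The default includes
#'   the canonical bacterial initiators ATG/GTG/TTG/CTG plus the
#'   noncanonical ATA and ATT observed in proteogenomic revisions.
#' @param selection `"minimal_extension"` (closest allowed start at or
#'   upstream of the most upstream supporting peptide; conservative default)
#'   or `"maximal_extension"` (closest to the upstream in-frame stop).
#' @return A `start_codon_policy` list.
#' @export
start_codon_policy <- function(allowed = c("ATG", "GTG", "TTG", "CTG",
                                           "ATA", "ATT"),
                               selection = c("minimal_extension",
                                             "maximal_extension")) {
  if (!length(allowed) || any(!grepl("^[ACGT]{3}$", allowed)))
    stop("allowed start codons must be DNA 3-mers", call. = FALSE)
  structure(list(allowed = toupper(allowed),
                 selection = match.arg(selection)),
            class = "start_codon_policy")
}

#' Group unique GSSPs by their bounding six-frame ORF
#'
#' Only GSSPs mapping to exactly one genomic locus are admitted. GSSPs
#' sharing the same stop-to-stop ORF form one support group; groups with
#' fewer than `min_support` distinct peptides are discarded.
#'
#' @param assignments A `peptide_assignments` data.frame.
#' @param min_support Minimum distinct supporting peptides (default 2).
#' @return A list of groups; each has `orf_id`, `peptides`, and a `hits`
#'   data.frame (peptide, offset, seqid, start, end, strand).
#' @export
cluster_gssps <- function(assignments, min_support = 2L) {
  g <- assignments[assignments$category == "gssp" & assignments$is_unique, ,
                   drop = FALSE]
  if (!nrow(g)) return(list())
  hits <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    h <- g$orf_hits[[i]][1, , drop = FALSE]  # unique locus: one interval
    cbind(peptide = g$peptide[i], h, stringsAsFactors = FALSE)
  }))
  groups <- split(hits, hits$orf_id)
  groups <- groups[vapply(groups, function(h)
    length(unique(h$peptide)) >= min_support, logical(1))]
  groups <- lapply(groups, function(h) {
    h <- h[order(h$start, h$peptide), , drop = FALSE]
    rownames(h) <- NULL
    list(orf_id = h$orf_id[1], peptides = unique(h$peptide), hits = h)
  })
  groups[order(vapply(groups, function(x) x$hits$seqid[1], character(1)),
               vapply(groups, function(x) min(x$hits$start), integer(1)))]
}

# Frame agreement between a gene interval and an ORF on the same strand:
# aligned from the left end for +, from the right end for -.
.in_frame <- function(gene_start, gene_end, orf_start, orf_end, strand) {
  if (strand == "+") (gene_start - orf_start) %% 3L == 0L
  else (gene_end - orf_end) %% 3L == 0L
}

#' Classify a GSSP support group against the annotation
#'
#' The group's bounding ORF interval decides the category: no overlap with
#' any annotated gene gives `intergenic`; overlap with a same-strand gene
#' gives `n_term_extension` when the frames agree and the peptides extend
#' upstream of the gene start, or `alt_frame` when the frames differ;
#' overlap with opposite-strand genes only gives `antisense`. When several
#' genes overlap, the gene with the largest base-pair overlap is used (ties
#' broken by leftmost gene) and the event is flagged ambiguous.
#'
#' @param group One group from [cluster_gssps()].
#' @param annotation A `gene_annotation`.
#' @param orfs The `sixframe_orfs` the GSSPs were matched against.
#' @return List with `category`, `gene_id` (overlapped gene or `NA`), and
#'   `ambiguous` flag.
#' @export
classify_event <- function(group, annotation, orfs) {
  orf <- orfs[orfs$orf_id == group$orf_id, , drop = FALSE]
  if (nrow(orf) != 1L) stop("unknown ORF id: ", group$orf_id, call. = FALSE)
  ann <- annotation[annotation$coding_ok, , drop = FALSE]
  ov <- ann[ann$seqid == orf$seqid & ann$start < orf$end &
              ann$end > orf$start, , drop = FALSE]
  if (!nrow(ov))
    return(list(category = "intergenic", gene_id = NA_character_,
                ambiguous = FALSE))
  ambiguous <- nrow(ov) > 1L
  pick <- function(cand) {
    bp <- pmin(cand$end, orf$end) - pmax(cand$start, orf$start)
    cand[order(-bp, cand$start), , drop = FALSE][1, , drop = FALSE]
  }
  same <- ov[ov$strand == orf$strand, , drop = FALSE]
  if (nrow(same)) {
    gene <- pick(same)
    if (.in_frame(gene$start, gene$end, orf$start, orf$end, orf$strand)) {
      upstream <- if (orf$strand == "+") min(group$hits$start) < gene$start
                  else max(group$hits$end) > gene$end
      if (upstream)
        return(list(category = "n_term_extension", gene_id = gene$gene_id,
                    ambiguous = ambiguous))
      # In-frame peptides not extending upstream would match the reference
      # proteome and so cannot be GSSPs; treat as unclassifiable.
      return(list(category = NA_character_, gene_id = gene$gene_id,
                  ambiguous = TRUE))
    }
    return(list(category = "alt_frame", gene_id = gene$gene_id,
                ambiguous = ambiguous))
  }
  gene <- pick(ov)
  list(category = "antisense", gene_id = gene$gene_id, ambiguous = ambiguous)
}

#' Propose a coding model for a GSSP support group
#'
#' The downstream boundary is the ORF's bounding stop codon (included in the
#' model interval). The upstream boundary is an allowed start codon chosen
#' inside the window between the upstream in-frame stop and the most
#' upstream supporting peptide: under `minimal_extension` the candidate
#' closest to the peptide evidence, under `maximal_extension` the candidate
#' closest to the upstream stop. When no allowed start exists in the window
#' the full ORF is emitted with `start_codon = NA` and `flagged = TRUE`.
#'
#' @param group One group from [cluster_gssps()].
#' @param genome A `GenomeSet`.
#' @param orfs The `sixframe_orfs` table.
#' @param policy A [start_codon_policy()].
#' @return List with `seqid`, `start`, `end` (model interval, 0-based
#'   half-open, including the stop codon when bounded), `strand`,
#'   `start_codon`, `protein`, `flagged`.
#' @export
propose_model <- function(group, genome, orfs,
                          policy = start_codon_policy()) {
  orf <- orfs[orfs$orf_id == group$orf_id, , drop = FALSE]
  if (nrow(orf) != 1L) stop("unknown ORF id: ", group$orf_id, call. = FALSE)
  seq <- genome_sequence(genome, orf$seqid)
  minimal <- policy$selection == "minimal_extension"
  if (orf$strand == "+") {
    lead <- min(group$hits$start)             # most upstream peptide (genomic)
    cand <- seq(orf$start, lead, by = 3L)
    codons <- substring(seq, cand + 1L, cand + 3L)
    hit <- which(codons %in% policy$allowed)
    model_end <- if (orf$down_stop) orf$end + 3L else orf$end
    if (length(hit)) {
      j <- if (minimal) max(hit) else min(hit)
      model_start <- cand[j]
      codon <- codons[j]
      flagged <- FALSE
    } else {
      model_start <- orf$start
      codon <- NA_character_
      flagged <- TRUE
    }
    prot <- sub("\\*$", "", translate_interval(genome, orf$seqid, model_start,
                                               model_end, "+"))
    list(seqid = orf$seqid, start = model_start, end = model_end,
         strand = "+", start_codon = codon, protein = prot, flagged = flagged)
  } else {
    lead <- max(group$hits$end)               # most upstream on minus strand
    cand <- seq(orf$end, lead, by = -3L)      # candidate start codon 3' ends
    codons <- vapply(cand, function(e)
      dna_revcomp(substr(seq, e - 2L, e)), character(1))
    hit <- which(codons %in% policy$allowed)
    model_start <- if (orf$down_stop) orf$start - 3L else orf$start
    if (length(hit)) {
      j <- if (minimal) max(hit) else min(hit)
      model_end <- cand[j]
      codon <- codons[j]
      flagged <- FALSE
    } else {
      model_end <- orf$end
      codon <- NA_character_
      flagged <- TRUE
    }
    prot <- sub("\\*$", "", translate_interval(genome, orf$seqid, model_start,
                                               model_end, "-"))
    list(seqid = orf$seqid, start = model_start, end = model_end,
         strand = "-", start_codon = codon, protein = prot, flagged = flagged)
  }
}

#' Call novel genes and gene-model revisions from GSSPs
#'
#' Composition of [cluster_gssps()], [classify_event()] and
#' [propose_model()]. Events are never merged across replicons or across
#' stop-to-stop ORFs, and output order is deterministic by (seqid, start).
#'
#' @param assignments A `peptide_assignments` data.frame.
#' @param annotation A `gene_annotation`.
#' @param genome A `GenomeSet`.
#' @param orfs The `sixframe_orfs` table used for classification.
#' @param min_support Minimum distinct unique GSSPs per event (default 2).
#' @param policy A [start_codon_policy()].
#' @return A `data.frame` (class `novel_events`): `event_id`, `category`,
#'   `seqid`, `start`, `end`, `strand`, `start_codon`, `protein`,
#'   `revised_gene_id`, `n_support`, `ambiguous`, `flagged`, and list-column
#'   `peptides`.
#' @export
call_events <- function(assignments, annotation, genome, orfs,
                        min_support = 2L, policy = start_codon_policy()) {
  groups <- cluster_gssps(assignments, min_support = min_support)
  rows <- list()
  for (group in groups) {
    cls <- classify_event(group, annotation, orfs)
    if (is.na(cls$category)) {
      warning("dropping unclassifiable GSSP group in ORF ", group$orf_id,
              call. = FALSE)
      next
    }
    model <- propose_model(group, genome, orfs, policy)
    rows[[length(rows) + 1L]] <- data.frame(
      category = cls$category, seqid = model$seqid, start = model$start,
      end = model$end, strand = model$strand,
      start_codon = model$start_codon, protein = model$protein,
      revised_gene_id = if (cls$category == "n_term_extension") cls$gene_id
                        else NA_character_,
      n_support = length(group$peptides),
      ambiguous = cls$ambiguous, flagged = model$flagged,
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$peptides <- list(group$peptides)
  }
  if (!length(rows)) {
    ev <- data.frame(event_id = character(), category = character(),
                     seqid = character(), start = integer(), end = integer(),
                     strand = character(), start_codon = character(),
                     protein = character(), revised_gene_id = character(),
                     n_support = integer(), ambiguous = logical(),
                     flagged = logical(), stringsAsFactors = FALSE)
    ev$peptides <- list()
    class(ev) <- c("novel_events", "data.frame")
    return(ev)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$seqid, ev$start, ev$end), , drop = FALSE]
  ev <- cbind(event_id = sprintf("NE-%03d", seq_len(nrow(ev))), ev,
              stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  class(ev) <- c("novel_events", "data.frame")
  ev
}

#' Write called events as a TSV table
#'
#' @param events A `novel_events` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  flat <- events
  flat$peptides <- vapply(events$peptides, paste, character(1), collapse = ",")
  write_tsv(flat, path)
}
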