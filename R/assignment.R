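# PSM filtering and peptide classification. Accepted peptides are classified
# against three databases with fixed precedence: contaminants, then the
# annotated reference proteome, then the six-frame ORF database. Peptides
# matching only the six-frame database are genome search-specific peptides
# (GSSPs), the evidentiary unit for novel genes and gene-model revisions.

#' Read a PSM table
#'
#' @param path TSV with columns `spectrum_id`, `peptide`, `score`,
#'   `is_decoy` and optionally `engine`.
#' @return `data.frame` of PSMs with `is_decoy` coerced to logical.
#' @export
read_psms <- function(path) {
  psms <- read_tsv(path, required = c("spectrum_id", "peptide", "score",
                                      "is_decoy"))
  psms$is_decoy <- as.logical(psms$is_decoy)
  if (is.null(psms$engine)) psms$engine <- NA_character_
  bad <- !.valid_peptide(psms$peptide)
  if (any(bad))
    stop("invalid peptide sequence(s): ",
         paste(utils::head(psms$peptide[bad], 3), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(psms$score)))
    stop("non-finite PSM score(s)", call. = FALSE)
  psms
}

#' Filter PSMs at a target-decoy FDR threshold
#'
#' The score cutoff is the lowest score `s` such that
#' `#(decoys with score >= s) / #(targets with score >= s) <= threshold`,
#' which maximizes the number of accepted targets. Decoys are removed from
#' the output.
#'
#' @param psms PSM `data.frame` with `score` and `is_decoy` columns.
#' @param threshold FDR threshold (default 0.01).
#' @param peptide_level If `TRUE`, roll PSMs up to the best-scoring PSM per
#'   peptide before estimating the FDR (default `FALSE`: PSM-level).
#' @return Accepted target PSMs; the chosen cutoff is in
#'   `attr(, "score_cutoff")` and the estimated FDR in `attr(, "fdr")`.
#' @export
fdr_filter <- function(psms, threshold = 0.01, peptide_level = FALSE) {
  stopifnot(is.data.frame(psms), threshold > 0)
  if (peptide_level && nrow(psms)) {
    ord <- order(psms$peptide, psms$is_decoy, -psms$score)
    psms <- psms[ord, , drop = FALSE]
    psms <- psms[!duplicated(paste(psms$peptide, psms$is_decoy)), ,
                 drop = FALSE]
  }
  targets <- psms[!psms$is_decoy, , drop = FALSE]
  decoys <- psms[psms$is_decoy, , drop = FALSE]
  empty <- targets[0, , drop = FALSE]
  if (nrow(targets) == 0L) {
    warning("no target PSMs", call. = FALSE)
    attr(empty, "score_cutoff") <- NA_real_
    return(empty)
  }
  cand <- sort(unique(targets$score))   # optimal cutoff sits on a target score
  ts <- sort(targets$score)
  ds <- sort(decoys$score)
  n_t <- length(ts) - findInterval(cand, ts, left.open = TRUE)  # targets >= s
  n_d <- length(ds) - findInterval(cand, ds, left.open = TRUE)  # decoys >= s
  ok <- n_d / n_t <= threshold
  if (!any(ok)) {
    warning("no score cutoff satisfies the FDR threshold", call. = FALSE)
    attr(empty, "score_cutoff") <- NA_real_
    return(empty)
  }
  cutoff <- cand[which(ok)[1]]
  out <- targets[targets$score >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "score_cutoff") <- cutoff
  attr(out, "fdr") <- n_d[which(ok)[1]] / n_t[which(ok)[1]]
  out
}

#' Reversed-sequence decoy proteins
#'
#' Full-sequence reversal of each input protein, for decoy PSM generation
#' when a search-engine table lacks decoy entries.
#'
#' @param proteins Named character vector.
#' @return Named character vector of reversed sequences (`rev_` prefix).
#' @export
make_decoy_proteins <- function(proteins) {
  rev1 <- vapply(strsplit(proteins, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  stats::setNames(rev1, paste0("rev_", names(proteins)))
}

.collapse_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Build an exact-substring peptide lookup index
#'
#' @param reference Named character vector: the annotated reference proteome.
#' @param sixframe A `sixframe_orfs` data.frame ([extract_orfs()]).
#' @param contaminants Optional named character vector of contaminant
#'   proteins; contaminant matches take precedence over everything else.
#' @param collapse_IL Treat I and L as identical when matching (default
#'   `FALSE`).
#' @return A `peptide_index` object.
#' @export
build_peptide_index <- function(reference, sixframe, contaminants = NULL,
                                collapse_IL = FALSE) {
  .check_flag(collapse_IL, "collapse_IL")
  reference <- unlist(as.list(reference))
  if (is.null(names(reference)) || anyDuplicated(names(reference)))
    stop("reference protein ids must be present and unique", call. = FALSE)
  if (anyDuplicated(sixframe$orf_id))
    stop("duplicate ORF ids in six-frame database", call. = FALSE)
  prep <- function(x) if (collapse_IL) .collapse_il(x) else x
  structure(list(
    reference = reference,
    ref_set = Biostrings::AAStringSet(prep(reference)),
    orfs = sixframe,
    orf_set = Biostrings::AAStringSet(prep(sixframe$protein)),
    contaminants = contaminants,
    contam_set = if (length(contaminants))
      Biostrings::AAStringSet(prep(contaminants)) else NULL,
    collapse_IL = collapse_IL
  ), class = "peptide_index")
}

# All exact-substring hits of `pep` in an AAStringSet; returns subject index
# and 0-based residue offsets.
.substring_hits <- function(pep, set) {
  if (is.null(set) || length(set) == 0L)
    return(data.frame(subject = integer(), offset = integer()))
  m <- Biostrings::vmatchPattern(pep, set, fixed = TRUE)
  counts <- S4Vectors::elementNROWS(m)
  hit <- which(counts > 0L)
  if (!length(hit)) return(data.frame(subject = integer(), offset = integer()))
  data.frame(
    subject = rep(hit, counts[hit]),
    offset = unlist(lapply(m[hit], IRanges::start), use.names = FALSE) - 1L
  )
}

# Genomic interval of a peptide hit inside an ORF (0-based half-open).
.orf_hit_interval <- function(orf, offset, pep_len) {
  if (orf$strand == "+") {
    s <- orf$start + 3L * offset
    c(start = s, end = s + 3L * pep_len)
  } else {
    e <- orf$end - 3L * offset
    c(start = e - 3L * pep_len, end = e)
  }
}

#' Classify accepted peptides against the databases
#'
#' Precedence: contaminant, then reference (known; `shared_known` when more
#' than one reference protein matches), then six-frame (GSSP), else
#' unmatched. GSSP uniqueness is defined at the genomic-locus level: the same
#' locus reached through overlapping ORFs counts once.
#'
#' @param peptides Character vector of peptide sequences (duplicates are
#'   collapsed).
#' @param index A `peptide_index`.
#' @return A `data.frame` (class `peptide_assignments`): `peptide`,
#'   `category` (`known`, `shared_known`, `gssp`, `unmatched`,
#'   `contaminant`), `n_protein_hits`, `n_loci`, `is_unique`, and
#'   list-columns `protein_hits` (protein_id, offset) and `orf_hits`
#'   (orf_id, offset, seqid, start, end, strand).
#' @export
classify_peptides <- function(peptides, index) {
  stopifnot(inherits(index, "peptide_index"))
  peptides <- unique(peptides)
  bad <- !.valid_peptide(peptides)
  if (any(bad)) stop("invalid peptide sequence(s)", call. = FALSE)
  n <- length(peptides)
  category <- character(n)
  n_protein_hits <- integer(n)
  n_loci <- integer(n)
  is_unique <- logical(n)
  protein_hits <- vector("list", n)
  orf_hits <- vector("list", n)
  empty_ph <- data.frame(protein_id = character(), offset = integer())
  empty_oh <- data.frame(orf_id = character(), offset = integer(),
                         seqid = character(), start = integer(),
                         end = integer(), strand = character())
  for (i in seq_len(n)) {
    pep <- if (index$collapse_IL) .collapse_il(peptides[i]) else peptides[i]
    protein_hits[[i]] <- empty_ph
    orf_hits[[i]] <- empty_oh
    ch <- .substring_hits(pep, index$contam_set)
    if (nrow(ch)) { category[i] <- "contaminant"; next }
    rh <- .substring_hits(pep, index$ref_set)
    if (nrow(rh)) {
      protein_hits[[i]] <- data.frame(
        protein_id = names(index$reference)[rh$subject],
        offset = rh$offset, stringsAsFactors = FALSE)
      n_protein_hits[i] <- length(unique(protein_hits[[i]]$protein_id))
      category[i] <- if (n_protein_hits[i] == 1L) "known" else "shared_known"
      is_unique[i] <- n_protein_hits[i] == 1L
      next
    }
    oh <- .substring_hits(pep, index$orf_set)
    if (nrow(oh)) {
      plen <- nchar(peptides[i])
      ivs <- t(vapply(seq_len(nrow(oh)), function(j)
        .orf_hit_interval(index$orfs[oh$subject[j], ], oh$offset[j], plen),
        c(start = 0, end = 0)))
      hits <- data.frame(
        orf_id = index$orfs$orf_id[oh$subject],
        offset = oh$offset,
        seqid = index$orfs$seqid[oh$subject],
        start = as.integer(ivs[, "start"]),
        end = as.integer(ivs[, "end"]),
        strand = index$orfs$strand[oh$subject],
        stringsAsFactors = FALSE)
      orf_hits[[i]] <- hits
      n_loci[i] <- nrow(unique(hits[, c("seqid", "start", "end", "strand")]))
      category[i] <- "gssp"
      is_unique[i] <- n_loci[i] == 1L
      next
    }
    category[i] <- "unmatched"
  }
  out <- data.frame(peptide = peptides, category = category,
                    n_protein_hits = n_protein_hits, n_loci = n_loci,
                    is_unique = is_unique, stringsAsFactors = FALSE)
  out$protein_hits <- protein_hits
  out$orf_hits <- orf_hits
  class(out) <- c("peptide_assignments", "data.frame")
  out
}

#' Infer identified proteins from classified peptides
#'
#' A protein is `identified` with at least two unique peptides; one unique
#' peptide gives `single_peptide` (flagged for manual review, not
#' auto-identified); only shared peptides give `shared_only` (excluded from
#' the identified set); no peptides at all gives `undetected`.
#'
#' @param assignments A `peptide_assignments` data.frame.
#' @param proteome Named character vector: the reference proteome.
#' @return A `data.frame` (class `protein_evidence`): `protein_id`, `length`,
#'   `unique_peptides`, `shared_peptides`, `coverage`, `status`,
#'   `is_microprotein` (length <= 100 aa).
#' @export
infer_proteins <- function(assignments, proteome) {
  known <- assignments[assignments$category %in% c("known", "shared_known"), ,
                       drop = FALSE]
  ids <- names(proteome)
  lens <- nchar(proteome)
  uniq_n <- stats::setNames(integer(length(ids)), ids)
  shared_n <- stats::setNames(integer(length(ids)), ids)
  cov_ranges <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(known))) {
    hits <- known$protein_hits[[i]]
    plen <- nchar(known$peptide[i])
    shared <- known$category[i] == "shared_known"
    for (pid in unique(hits$protein_id)) {
      if (shared) shared_n[pid] <- shared_n[pid] + 1L
      else uniq_n[pid] <- uniq_n[pid] + 1L
      off <- hits$offset[hits$protein_id == pid]
      cov_ranges[[pid]] <- c(cov_ranges[[pid]],
                             list(IRanges::IRanges(off + 1L, off + plen)))
    }
  }
  coverage <- vapply(ids, function(pid) {
    r <- cov_ranges[[pid]]
    if (is.null(r)) return(0)
    covered <- sum(IRanges::width(IRanges::reduce(do.call(c, r))))
    covered / lens[[pid]]
  }, numeric(1))
  status <- ifelse(uniq_n >= 2L, "identified",
            ifelse(uniq_n == 1L, "single_peptide",
            ifelse(shared_n >= 1L, "shared_only", "undetected")))
  out <- data.frame(protein_id = ids, length = unname(lens),
                    unique_peptides = unname(uniq_n),
                    shared_peptides = unname(shared_n),
                    coverage = unname(coverage), status = unname(status),
                    is_microprotein = unname(lens) <= 100L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("protein_evidence", "data.frame")
  out
}

#' Group redundant proteins by identical sequence
#'
#' @param proteome Named character vector.
#' @return `data.frame` with one row per multi-member group: `group_id`,
#'   `sequence`, `n_members`, and list-column `members` (protein ids).
#' @export
group_redundant <- function(proteome) {
  grp <- split(names(proteome), unname(proteome))
  grp <- grp[lengths(grp) >= 2L]
  grp <- lapply(grp, sort)
  ord <- order(vapply(grp, `[`, character(1), 1L))
  grp <- grp[ord]
  out <- data.frame(
    group_id = if (length(grp)) paste0("rg", seq_along(grp)) else character(),
    sequence = names(grp),
    n_members = lengths(grp),
    stringsAsFactors = FALSE
  )
  out$members <- unname(grp)
  rownames(out) <- NULL
  out
}

#' Aggregate coverage and identification statistics
#'
#' @param evidence A `protein_evidence` data.frame.
#' @return A list with the per-protein `table`, counts per status,
#'   `mean_coverage_identified`, and microprotein fractions among
#'   undetected/detected proteins.
#' @export
coverage_stats <- function(evidence) {
  idf <- evidence[evidence$status == "identified", , drop = FALSE]
  und <- evidence[evidence$status == "undetected" |
                    evidence$status == "shared_only", , drop = FALSE]
  list(
    table = evidence,
    n_total = nrow(evidence),
    n_identified = nrow(idf),
    n_single_peptide = sum(evidence$status == "single_peptide"),
    n_shared_only = sum(evidence$status == "shared_only"),
    n_undetected = sum(evidence$status == "undetected"),
    mean_coverage_identified = if (nrow(idf)) mean(idf$coverage) else NA_real_,
    mean_unique_peptides_identified =
      if (nrow(idf)) mean(idf$unique_peptides) else NA_real_,
    frac_micro_unidentified =
      if (nrow(und)) mean(und$is_microprotein) else NA_real_
  )
}
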