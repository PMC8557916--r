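# Synthetic-data generator: a toy multi-replicon genome with annotated genes,
# deliberately truncated gene starts, planted novel ORFs (intergenic /
# alt-frame / antisense), simulated tryptic PSMs with decoys and noise,
# signal-peptide prediction tables, PTM site tables, and a TMT-style quant
# matrix -- all tied to a ground-truth manifest so each pipeline stage can be
# scored without downloads. Identical seeds give byte-identical bundles.

#' Synthetic dataset configuration
#'
#' Defaults describe the toy world used throughout the test suite: two
#' replicons (50 kb + 10 kb, a chromosome-plus-plasmid layout), 40 genes,
#' 3/2/2 planted novel ORFs (intergenic / alt-frame / antisense), 3 genes
#' with starts truncated by 30 nt, noise-free PSMs (noise is opt-in), decoy
#' PSMs from reversed proteins, and well-separated true/noise score
#' distributions so a 1% FDR cutoff is meaningful. The quant design mirrors
#' a nitrogen-deprivation contrast with three biological replicates.
#'
#' @param seed Integer RNG seed.
#' @param replicon_lengths Replicon sizes in bp.
#' @param n_genes Total annotated genes (includes truncated genes and the
#'   host genes of alt-frame/antisense cassettes).
#' @param gene_len_aa Range of annotated protein lengths (amino acids).
#' @param planted Named counts of planted novel ORFs per category.
#' @param novel_len_aa Length of planted novel proteins (amino acids,
#'   including the initiator).
#' @param n_truncated Number of genes annotated with a truncated start.
#' @param truncation_nt Truncation length in nt (multiple of 3).
#' @param noncanonical_start Give the first intergenic novel ORF an ATA
#'   start codon (as seen for noncanonical bacterial initiators).
#' @param expressed_fraction Fraction of annotated genes with simulated PSMs.
#' @param peptides_per_protein Sampled tryptic peptides per expressed
#'   protein.
#' @param gssps_per_orf Simulated unique GSSPs per planted ORF (>= 2).
#' @param noise_fraction Noise (false-target) PSMs as a fraction of true
#'   PSMs; default 0 (the default bundle is noise-free).
#' @param decoy_fraction Decoy PSMs as a fraction of true PSMs.
#' @param true_score,noise_score `c(mean, sd)` of the true and noise/decoy
#'   score distributions.
#' @param signal_fraction Fraction of eligible plain genes designed with a
#'   signal peptide (alanine at the -1 and -3 cleavage positions).
#' @param n_ptm_sites Simulated PTM sites.
#' @param ptm_confident_fraction Fraction of PTM sites passing the
#'   confidence thresholds.
#' @param quant_reps Replicates per quant condition.
#' @param dep_fraction Fraction of quantified proteins that are true DEPs.
#' @param dep_fc Fold changes sampled for true DEPs.
#' @param quant_cv Replicate coefficient of variation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             replicon_lengths = c(50000L, 10000L),
                             n_genes = 40L,
                             gene_len_aa = c(120L, 300L),
                             planted = c(intergenic = 3L, alt_frame = 2L,
                                         antisense = 2L),
                             novel_len_aa = 30L,
                             n_truncated = 3L,
                             truncation_nt = 30L,
                             noncanonical_start = TRUE,
                             expressed_fraction = 0.9,
                             peptides_per_protein = 4L,
                             gssps_per_orf = 3L,
                             noise_fraction = 0,
                             decoy_fraction = 0.3,
                             true_score = c(60, 5),
                             noise_score = c(25, 5),
                             signal_fraction = 0.2,
                             n_ptm_sites = 150L,
                             ptm_confident_fraction = 0.7,
                             quant_reps = 3L,
                             dep_fraction = 0.15,
                             dep_fc = c(1.5, 1.8, 0.6, 0.5),
                             quant_cv = 0.05) {
  if (truncation_nt %% 3L != 0L || truncation_nt < 6L)
    stop("truncation_nt must be a multiple of 3 and >= 6", call. = FALSE)
  if (gssps_per_orf < 2L)
    stop("gssps_per_orf must be >= 2 (the minimum event support)",
         call. = FALSE)
  if (any(planted < 0L) ||
      !setequal(names(planted), c("intergenic", "alt_frame", "antisense")))
    stop("'planted' needs nonnegative intergenic/alt_frame/antisense counts",
         call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# ---- sequence design helpers -----------------------------------------------

.aa_pool <- function() {
  # all 20 residues; K/R weighted to give tryptic peptides of ~9 aa
  aa <- strsplit("ACDEFGHILMNPQSTVWYKR", "")[[1]]
  w <- c(rep(1, 18), 1.3, 1.3)
  list(aa = aa, w = w / sum(w))
}

.random_protein <- function(n_aa, first = "M") {
  pool <- .aa_pool()
  paste0(first, paste(sample(pool$aa, n_aa - 1L, replace = TRUE,
                             prob = pool$w), collapse = ""))
}

# random synonymous codon per residue (table 11)
.codons_for <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc11 <- .genetic_code_11()
      cache <<- split(names(gc11), unname(gc11))
    }
    cache
  }
})

.protein_to_nt <- function(protein, start_codon = "ATG",
                           stop_codon = NULL) {
  tab <- .codons_for()
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res[-1], function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  if (is.null(stop_codon))
    stop_codon <- c("TAA", "TAG", "TGA")[sample.int(3L, 1L)]
  paste0(start_codon, paste(codons, collapse = ""), stop_codon)
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# Flip a sense-space interval [a, b) into revcomp space for a block of
# length L.
.flip_iv <- function(a, b, L) c(L - b, L - a)

# ---- block builders ---------------------------------------------------------
# Each returns list(nt, ann = data.frame rows (block-relative, final
# orientation), truth = list). Annotation coords are 0-based half-open.

.plain_gene_block <- function(gene_id, len_aa, strand, signal_cleavage = NA) {
  prot <- .random_protein(len_aa)
  if (!is.na(signal_cleavage)) {
    # design an N-terminal signal: no tryptic site inside the signal region,
    # hydrophobic core, and A at the -1 and -3 positions
    c_pos <- signal_cleavage
    sig <- c("M", sample(c("A", "L", "V", "F", "S", "G"), c_pos - 1L,
                         replace = TRUE))
    sig[c_pos] <- "A"
    sig[c_pos - 2L] <- "A"
    prot <- paste0(paste(sig, collapse = ""),
                   substr(prot, c_pos + 1L, nchar(prot)))
  }
  nt <- .protein_to_nt(prot)
  L <- nchar(nt)
  iv <- if (strand == "+") c(0L, L) else .flip_iv(0L, L, L)
  list(
    nt = if (strand == "+") nt else dna_revcomp(nt),
    ann = data.frame(gene_id = gene_id, start = iv[1], end = iv[2],
                     strand = strand, product = "synthetic protein",
                     stringsAsFactors = FALSE),
    truth = list(gene_id = gene_id, protein = prot,
                 signal_cleavage = signal_cleavage)
  )
}

.truncated_gene_block <- function(gene_id, len_aa, strand, trunc_nt) {
  t_aa <- trunc_nt %/% 3L
  k1 <- 5L
  k2 <- t_aa + 4L
  pool <- setdiff(.aa_pool()$aa, c("K", "R"))
  head_res <- c("M", sample(pool, k2 - 1L, replace = TRUE))
  head_res[c(k1, k2)] <- "K"
  prot <- paste0(paste(head_res, collapse = ""),
                 .random_protein(len_aa - k2, first = sample(pool, 1L)))
  gene_nt <- .protein_to_nt(prot)
  nt <- paste0("TAA", gene_nt)            # upstream in-frame stop pins the ORF
  L <- nchar(nt)
  true_iv <- c(3L, L)
  ann_iv <- c(3L + trunc_nt, L)
  if (strand == "-") {
    true_iv <- .flip_iv(true_iv[1], true_iv[2], L)
    ann_iv <- .flip_iv(ann_iv[1], ann_iv[2], L)
    nt <- dna_revcomp(nt)
  }
  # the >= 2 upstream-overlapping tryptic peptides planted by construction
  gssps <- c(substr(prot, 1L, k2), substr(prot, k1 + 1L, k2))
  list(
    nt = nt,
    ann = data.frame(gene_id = gene_id, start = ann_iv[1], end = ann_iv[2],
                     strand = strand, product = "synthetic protein",
                     stringsAsFactors = FALSE),
    truth = list(gene_id = gene_id, protein = prot,
                 true_start = true_iv[1], true_end = true_iv[2],
                 ann_start = ann_iv[1], ann_end = ann_iv[2],
                 strand = strand, gssps = gssps)
  )
}

.novel_protein <- function(len_aa, start_codon = "ATG") {
  first <- as.character(.genetic_code_11()[[start_codon]])
  pool <- setdiff(.aa_pool()$aa, c("K", "R"))
  res <- c(first, sample(pool, len_aa - 1L, replace = TRUE))
  res[7L] <- "K"                                 # N-terminal tryptic peptide
  tail_sites <- seq(13L, len_aa - 6L, by = 7L)
  res[tail_sites] <- "K"
  paste(res, collapse = "")
}

.intergenic_block <- function(label, len_aa, strand, start_codon = "ATG") {
  prot <- .novel_protein(len_aa, start_codon)
  nt <- paste0("TAA", .protein_to_nt(prot, start_codon = start_codon,
                                     stop_codon = "TAA"))
  L <- nchar(nt)
  orf_iv <- c(3L, 3L + 3L * len_aa)       # stop-free segment
  model_iv <- c(3L, 3L + 3L * len_aa + 3L)
  if (strand == "-") {
    orf_iv <- .flip_iv(orf_iv[1], orf_iv[2], L)
    model_iv <- .flip_iv(model_iv[1], model_iv[2], L)
    nt <- dna_revcomp(nt)
  }
  list(nt = nt, ann = NULL,
       truth = list(label = label, category = "intergenic", protein = prot,
                    strand = strand, start_codon = start_codon,
                    orf_start = orf_iv[1], orf_end = orf_iv[2],
                    model_start = model_iv[1], model_end = model_iv[2],
                    host_gene = NA_character_))
}

# Overwrite host_nt[at+1 .. at+n] with insert (1-based), keeping length.
.splice <- function(host_nt, insert, at) {
  paste0(substr(host_nt, 1L, at),
         insert,
         substr(host_nt, at + nchar(insert) + 1L, nchar(host_nt)))
}

# Host gene (plus strand) carrying an embedded novel ORF either in a shifted
# frame (category "alt_frame") or on the opposite strand ("antisense").
# Rejection sampling: resample until the host-frame reading of the embedded
# window is stop-free, so the host stays a valid gene.
.cassette_block <- function(label, category, gene_id, host_len_aa,
                            novel_len_aa, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    host_prot <- .random_protein(host_len_aa)
    host_nt <- .protein_to_nt(host_prot)
    novel_prot <- .novel_protein(novel_len_aa)
    ins_sense <- paste0("TAA", .protein_to_nt(novel_prot, stop_codon = "TAA"))
    n_ins <- nchar(ins_sense)
    max_at <- 3L * host_len_aa - n_ins      # keep clear of the host stop
    if (max_at < 6L)
      stop("host gene too short for embedded ORF", call. = FALSE)
    if (category == "alt_frame") {
      shift <- sample(1:2, 1L)
      at <- 3L * sample.int((max_at - shift) %/% 3L, 1L) + shift
      insert <- ins_sense
    } else {
      at <- sample(6:max_at, 1L)
      insert <- dna_revcomp(ins_sense)
    }
    cand <- .splice(host_nt, insert, at)
    tr <- translate_dna(cand)
    body <- substr(tr, 1L, nchar(tr) - 1L)
    if (!grepl("*", body, fixed = TRUE) &&
        substr(tr, nchar(tr), nchar(tr)) == "*") {
      L <- nchar(cand)
      if (category == "alt_frame") {
        orf_iv <- c(at + 3L, at + 3L + 3L * novel_len_aa)
        model_iv <- c(orf_iv[1], orf_iv[2] + 3L)
        strand <- "+"
      } else {
        # insert = revcomp(TAA + coding + TAA): minus-strand coding sits at
        # [at + 3, at + 3 + 3*len) from the *right* edge of the insert
        orf_iv <- c(at + n_ins - 3L - 3L * novel_len_aa, at + n_ins - 3L)
        model_iv <- c(orf_iv[1] - 3L, orf_iv[2])
        strand <- "-"
      }
      return(list(
        nt = cand,
        ann = data.frame(gene_id = gene_id, start = 0L, end = L,
                         strand = "+", product = "synthetic host protein",
                         stringsAsFactors = FALSE),
        truth = list(label = label, category = category,
                     protein = novel_prot, strand = strand,
                     start_codon = "ATG",
                     orf_start = orf_iv[1], orf_end = orf_iv[2],
                     model_start = model_iv[1], model_end = model_iv[2],
                     host_gene = gene_id)
      ))
    }
  }
  stop("failed to design ", category, " cassette after ", max_tries,
       " attempts", call. = FALSE)
}

# ---- genome assembly --------------------------------------------------------

.assemble_genome <- function(cfg) {
  n_plain <- cfg$n_genes - cfg$n_truncated - cfg$planted[["alt_frame"]] -
    cfg$planted[["antisense"]]
  if (n_plain < 1L)
    stop("n_genes too small for the requested truncations and cassettes",
         call. = FALSE)
  gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
  gid <- 0L
  next_gene <- function() { gid <<- gid + 1L; gene_ids[gid] }

  # decide signal-positive plain genes up front
  n_signal <- round(cfg$signal_fraction * n_plain)
  signal_idx <- if (n_signal) sort(sample.int(n_plain, n_signal)) else integer()

  blocks <- list()
  for (i in seq_len(n_plain)) {
    cpos <- if (i %in% signal_idx) sample(18:30, 1L) else NA
    blocks[[length(blocks) + 1L]] <- .plain_gene_block(
      next_gene(), sample(cfg$gene_len_aa[1]:cfg$gene_len_aa[2], 1L),
      sample(c("+", "-"), 1L), signal_cleavage = cpos)
  }
  for (i in seq_len(cfg$n_truncated)) {
    blocks[[length(blocks) + 1L]] <- .truncated_gene_block(
      next_gene(), sample(cfg$gene_len_aa[1]:cfg$gene_len_aa[2], 1L),
      if (i %% 2L) "+" else "-", cfg$truncation_nt)
  }
  k <- 0L
  for (i in seq_len(cfg$planted[["intergenic"]])) {
    k <- k + 1L
    sc <- if (i == 1L && cfg$noncanonical_start) "ATA" else "ATG"
    blocks[[length(blocks) + 1L]] <- .intergenic_block(
      sprintf("NOV-%02d", k), cfg$novel_len_aa,
      if (i %% 2L) "+" else "-", start_codon = sc)
  }
  for (i in seq_len(cfg$planted[["alt_frame"]])) {
    k <- k + 1L
    blocks[[length(blocks) + 1L]] <- .cassette_block(
      sprintf("NOV-%02d", k), "alt_frame", next_gene(),
      sample(cfg$gene_len_aa[1]:cfg$gene_len_aa[2], 1L), cfg$novel_len_aa)
  }
  for (i in seq_len(cfg$planted[["antisense"]])) {
    k <- k + 1L
    blocks[[length(blocks) + 1L]] <- .cassette_block(
      sprintf("NOV-%02d", k), "antisense", next_gene(),
      sample(cfg$gene_len_aa[1]:cfg$gene_len_aa[2], 1L), cfg$novel_len_aa)
  }
  blocks <- blocks[sample.int(length(blocks))]

  # deal blocks to replicons proportionally to their lengths
  shares <- cfg$replicon_lengths / sum(cfg$replicon_lengths)
  counts <- diff(c(0, round(cumsum(shares) * length(blocks))))
  rep_of_block <- rep(seq_along(counts), counts)

  rep_ids <- sprintf("replicon%d", seq_along(cfg$replicon_lengths))
  seqs <- stats::setNames(character(length(rep_ids)), rep_ids)
  ann_rows <- list()
  gene_truth <- list()
  novel_truth <- list()
  trunc_truth <- list()
  bi <- 1L
  for (r in seq_along(rep_ids)) {
    target <- cfg$replicon_lengths[r]
    parts <- character()
    pos <- 0L
    while (bi <= length(blocks) && rep_of_block[bi] == r) {
      blk <- blocks[[bi]]
      spacer <- sample(60:200, 1L)
      need <- spacer + nchar(blk$nt)
      if (pos + need > target - 60L) break
      parts <- c(parts, .random_dna(spacer), blk$nt)
      at <- pos + spacer
      if (!is.null(blk$ann)) {
        a <- blk$ann
        a$seqid <- rep_ids[r]
        a$start <- a$start + at
        a$end <- a$end + at
        ann_rows[[length(ann_rows) + 1L]] <- a
      }
      tr <- blk$truth
      if (!is.null(tr$category)) {
        tr$seqid <- rep_ids[r]
        for (f in c("orf_start", "orf_end", "model_start", "model_end"))
          tr[[f]] <- tr[[f]] + at
        novel_truth[[length(novel_truth) + 1L]] <- tr
      } else if (!is.null(tr$true_start)) {
        tr$seqid <- rep_ids[r]
        for (f in c("true_start", "true_end", "ann_start", "ann_end"))
          tr[[f]] <- tr[[f]] + at
        trunc_truth[[length(trunc_truth) + 1L]] <- tr
      } else {
        tr$seqid <- rep_ids[r]
        gene_truth[[length(gene_truth) + 1L]] <- tr
      }
      pos <- pos + need
      bi <- bi + 1L
    }
    pad <- target - pos
    if (pad > 0L) parts <- c(parts, .random_dna(pad))
    seqs[r] <- paste(parts, collapse = "")
  }
  if (bi <= length(blocks))
    stop("infeasible packing: genes and planted ORFs exceed genome capacity",
         call. = FALSE)

  ann <- do.call(rbind, ann_rows)
  ann <- ann[, c("gene_id", "seqid", "start", "end", "strand", "product")]
  ann <- ann[order(ann$seqid, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  genome <- make_genome(seqs)
  ann$is_putative <- FALSE
  ann$coding_ok <- (ann$end - ann$start) %% 3L == 0L
  ann$start_codon <- annotation_start_codons(ann, genome)
  class(ann) <- c("gene_annotation", "data.frame")
  list(genome = genome, annotation = ann, gene_truth = gene_truth,
       novel_truth = novel_truth, trunc_truth = trunc_truth)
}

# ---- PSM simulation ---------------------------------------------------------

# all six frame translations, for uniqueness / absence checks
.frame_translations <- function(genome) {
  unlist(lapply(genome_ids(genome), function(sid) {
    seq <- genome_sequence(genome, sid)
    vapply(1:6, function(f)
      translate_frame(seq, frame_strand(f), frame_offset(f)), character(1))
  }))
}

.occurs <- function(pep, strings) {
  sum(vapply(strings, function(s)
    length(gregexpr(pep, s, fixed = TRUE)[[1]]) *
      (regexpr(pep, s, fixed = TRUE) > 0), numeric(1)))
}

#' Simulate search-engine PSMs for a synthetic world
#'
#' True PSMs are sampled from tryptic peptides (trypsin/P, up to 2 missed
#' cleavages, 6-50 aa) of the expressed annotated proteins (for truncated
#' genes, of the *true* full-length protein) and of the planted novel ORF
#' translations. Decoy PSMs draw peptides from reversed reference proteins;
#' noise PSMs use random sequences verified absent from both databases, so
#' they are true negatives by construction. Scores come from the configured
#' true and noise distributions.
#'
#' @param world Output of the internal genome assembly (genome, annotation,
#'   truths).
#' @param cfg A [synthetic_config()].
#' @return List with `psms` (a PSM `data.frame`), `expressed` gene ids, and
#'   per-event planted GSSP sets.
#' @keywords internal
.simulate_psms <- function(world, cfg) {
  genome <- world$genome
  ann <- world$annotation
  proteome <- annotation_proteome(genome, ann)
  frames <- .frame_translations(genome)

  trunc_ids <- vapply(world$trunc_truth, `[[`, character(1), "gene_id")
  host_ids <- unlist(lapply(world$novel_truth, `[[`, "host_gene"))
  host_ids <- host_ids[!is.na(host_ids)]
  n_expr <- round(cfg$expressed_fraction * nrow(ann))
  forced <- unique(c(trunc_ids, host_ids))
  rest <- setdiff(ann$gene_id, forced)
  expressed <- sort(c(forced, sample(rest, max(0L, n_expr - length(forced)))))

  signal_cpos <- stats::setNames(
    vapply(world$gene_truth, function(g)
      as.integer(g$signal_cleavage), integer(1)),
    vapply(world$gene_truth, `[[`, character(1), "gene_id"))

  true_prot <- stats::setNames(
    lapply(world$trunc_truth, `[[`, "protein"), trunc_ids)

  rows <- list()
  add <- function(pep, score, decoy, note = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide = pep, score = score, is_decoy = decoy, source = note,
      stringsAsFactors = FALSE)
  }
  rsc <- function(n, par) stats::rnorm(n, par[1], par[2])

  planted_gssps <- list()
  for (gid in expressed) {
    src <- if (gid %in% trunc_ids) true_prot[[gid]] else proteome[[gid]]
    peps <- digest(src)
    # mature-region peptides only for designed signal proteins
    cpos <- signal_cpos[gid]
    if (!is.na(cpos) && length(cpos))
      peps <- peps[peps$start >= cpos, , drop = FALSE]
    if (!nrow(peps)) next
    pick <- sample.int(nrow(peps), min(cfg$peptides_per_protein, nrow(peps)))
    for (p in peps$sequence[pick])
      add(p, rsc(1, cfg$true_score), FALSE, gid)
    if (gid %in% trunc_ids) {
      tt <- world$trunc_truth[[match(gid, trunc_ids)]]
      for (p in tt$gssps) {
        if (.occurs(p, proteome) > 0L || .occurs(p, frames) != 1L)
          stop("planted truncation peptide collides with the reference ",
               "proteome or maps to multiple loci; choose another seed",
               call. = FALSE)
        add(p, rsc(1, cfg$true_score), FALSE, paste0(gid, ":upstream"))
      }
      planted_gssps[[gid]] <- tt$gssps
    }
  }
  for (tr in world$novel_truth) {
    peps <- digest(tr$protein)
    nterm <- which(peps$start == 0L & peps$missed_cleavages == 0L)
    others <- setdiff(order(peps$start), nterm)
    pick <- c(nterm[1], others)
    pick <- pick[!duplicated(peps$sequence[pick])][seq_len(
      min(cfg$gssps_per_orf, nrow(peps)))]
    sel <- peps$sequence[pick]
    for (p in sel) {
      if (.occurs(p, proteome) > 0L || .occurs(p, frames) != 1L)
        stop("planted GSSP for ", tr$label,
             " is not unique in this world; choose another seed",
             call. = FALSE)
      add(p, rsc(1, cfg$true_score), FALSE, tr$label)
    }
    planted_gssps[[tr$label]] <- sel
  }

  n_true <- length(rows)
  n_decoy <- round(cfg$decoy_fraction * n_true)
  decoy_prots <- make_decoy_proteins(proteome)
  decoy_peps <- digest_set(decoy_prots)
  if (n_decoy > 0L && nrow(decoy_peps)) {
    pick <- sample.int(nrow(decoy_peps), min(n_decoy, nrow(decoy_peps)))
    for (p in decoy_peps$sequence[pick])
      add(p, rsc(1, cfg$noise_score), TRUE, "decoy")
  }
  n_noise <- round(cfg$noise_fraction * n_true)
  pool <- .aa_pool()
  made <- 0L
  while (made < n_noise) {
    p <- paste(sample(pool$aa, sample(8:15, 1L), replace = TRUE,
                      prob = pool$w), collapse = "")
    if (.occurs(p, proteome) == 0L && .occurs(p, frames) == 0L) {
      add(p, rsc(1, cfg$noise_score), FALSE, "noise")
      made <- made + 1L
    }
  }

  psms <- do.call(rbind, rows)
  psms <- cbind(
    spectrum_id = sprintf("S%06d", seq_len(nrow(psms))),
    psms,
    engine = sample(c("comet", "msgf", "xtandem", "pfind", "mascot"),
                    nrow(psms), replace = TRUE),
    stringsAsFactors = FALSE)
  rownames(psms) <- NULL
  list(psms = psms, expressed = expressed, planted_gssps = planted_gssps,
       proteome = proteome)
}

# ---- auxiliary tables -------------------------------------------------------

.simulate_sigpep <- function(world, expressed, proteome, cfg) {
  sig <- Filter(function(g) !is.na(g$signal_cleavage), world$gene_truth)
  sig_ids <- vapply(sig, `[[`, character(1), "gene_id")
  cpos <- vapply(sig, function(g) as.integer(g$signal_cleavage), integer(1))
  nonsig <- setdiff(expressed, sig_ids)
  n_fp <- max(2L, round(0.3 * length(sig_ids)))
  fp_a <- sample(nonsig, min(n_fp, length(nonsig)))
  fp_b <- sample(nonsig, min(n_fp, length(nonsig)))
  predisi <- data.frame(
    protein_id = c(sig_ids, fp_a),
    cleavage_pos = c(cpos, sample(15:30, length(fp_a), replace = TRUE)),
    score = round(stats::runif(length(sig_ids) + length(fp_a), 0.7, 1), 3),
    stringsAsFactors = FALSE)
  keep_b <- stats::runif(length(sig_ids)) < 0.8
  signalp <- data.frame(
    protein_id = c(sig_ids[keep_b], fp_b),
    cleavage_pos = c(cpos[keep_b], sample(15:30, length(fp_b),
                                          replace = TRUE)),
    score = round(stats::runif(sum(keep_b) + length(fp_b), 0.7, 1), 3),
    stringsAsFactors = FALSE)
  predisi$predictor <- "predisi"
  signalp$predictor <- "signalp"
  list(predisi = predisi[order(predisi$protein_id), ],
       signalp = signalp[order(signalp$protein_id), ],
       truth = data.frame(protein_id = sig_ids, cleavage_pos = cpos,
                          stringsAsFactors = FALSE))
}

.simulate_ptm <- function(expressed, proteome, cfg) {
  vocab <- ptm_vocabulary()
  res_of <- function(type) strsplit(sub(".*_", "", type), "")[[1]]
  rows <- list()
  guard <- 0L
  while (length(rows) < cfg$n_ptm_sites && guard < 50L * cfg$n_ptm_sites) {
    guard <- guard + 1L
    pid <- sample(expressed, 1L)
    type <- sample(vocab, 1L, prob = c(3, rep(1, 2), 3, 2, 1.5,
                                       rep(1, 18), 3, 1, 1))
    prot <- proteome[[pid]]
    targets <- which(strsplit(prot, "")[[1]] %in% res_of(type))
    if (!length(targets)) next
    pos <- targets[sample.int(length(targets), 1L)]
    confident <- stats::runif(1) < cfg$ptm_confident_fraction
    score <- if (confident) stats::runif(1, 45, 150) else stats::runif(1, 5, 40)
    prob <- if (confident) stats::runif(1, 0.76, 1) else stats::runif(1, 0.1, 0.75)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, position = pos,
      residue = substr(prot, pos, pos), ptm_type = type,
      score = round(score, 2), localization_prob = round(prob, 4),
      confident = confident, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  sites <- sites[!duplicated(sites[, c("protein_id", "position",
                                       "ptm_type")]), , drop = FALSE]
  rownames(sites) <- NULL
  truth <- sites$confident
  sites$confident <- NULL
  list(sites = sites, confident = truth)
}

.simulate_quant <- function(expressed, cfg) {
  n <- length(expressed)
  n_dep <- round(cfg$dep_fraction * n)
  dep_idx <- if (n_dep) sort(sample.int(n, n_dep)) else integer()
  fc <- rep(1, n)
  fc[dep_idx] <- sample(cfg$dep_fc, n_dep, replace = TRUE)
  base <- stats::rlnorm(n, meanlog = 10, sdlog = 1)
  groups <- rep(c("control", "nitrogen_minus"), each = cfg$quant_reps)
  mat <- matrix(0, n, length(groups),
                dimnames = list(expressed, sprintf("%s_r%d", groups,
                  rep(seq_len(cfg$quant_reps), 2))))
  for (j in seq_along(groups)) {
    mu <- if (groups[j] == "control") base else base * fc
    mat[, j] <- mu * (1 + stats::rnorm(n, 0, cfg$quant_cv))
  }
  mat <- abs(mat)
  load_f <- stats::runif(length(groups), 0.8, 1.2)  # per-sample loading
  mat <- sweep(mat, 2, load_f, "*")
  list(matrix = mat, groups = groups,
       truth = data.frame(protein_id = expressed, fold_change = fc,
                          is_dep = fc != 1, stringsAsFactors = FALSE))
}

# ---- top level --------------------------------------------------------------

#' Generate a synthetic proteogenomic dataset bundle
#'
#' Builds the toy genome, annotation (with deliberately truncated starts),
#' reference proteome, simulated PSMs, signal-peptide prediction tables, PTM
#' site table, quant matrix, and the ground-truth manifest. Identical seeds
#' give byte-identical bundles.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; when given, all bundle components
#'   are written as FASTA/GFF3/TSV (plus `truth.json`).
#' @return A list: `genome`, `annotation`, `proteome`, `psms`, `sigpep`
#'   (predisi/signalp tables), `ptm` (site table), `quant` (matrix +
#'   groups), and `truth` (manifest).
#' @export
generate_synthetic <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  world <- .assemble_genome(config)
  sim <- .simulate_psms(world, config)
  sig <- .simulate_sigpep(world, sim$expressed, sim$proteome, config)
  ptm <- .simulate_ptm(sim$expressed, sim$proteome, config)
  quant <- .simulate_quant(sim$expressed, config)

  novel <- if (length(world$novel_truth)) do.call(rbind, lapply(
    world$novel_truth, function(tr) data.frame(
      label = tr$label, category = tr$category, seqid = tr$seqid,
      strand = tr$strand, start_codon = tr$start_codon,
      orf_start = tr$orf_start, orf_end = tr$orf_end,
      model_start = tr$model_start, model_end = tr$model_end,
      host_gene = tr$host_gene, protein = tr$protein,
      stringsAsFactors = FALSE))) else NULL
  trunc <- if (length(world$trunc_truth)) do.call(rbind, lapply(
    world$trunc_truth, function(tr) data.frame(
      gene_id = tr$gene_id, seqid = tr$seqid, strand = tr$strand,
      true_start = tr$true_start, true_end = tr$true_end,
      ann_start = tr$ann_start, ann_end = tr$ann_end,
      stringsAsFactors = FALSE))) else NULL

  truth <- list(
    novel_orfs = novel,
    truncations = trunc,
    expressed = sim$expressed,
    planted_gssps = sim$planted_gssps,
    noise_peptides = unique(sim$psms$peptide[!sim$psms$is_decoy &
                                               sim$psms$source == "noise"]),
    signal = sig$truth,
    ptm_confident = ptm$confident,
    deps = quant$truth
  )
  bundle <- list(genome = world$genome, annotation = world$annotation,
                 proteome = sim$proteome,
                 psms = sim$psms[, c("spectrum_id", "peptide", "score",
                                     "is_decoy", "engine", "source")],
                 sigpep = list(predisi = sig$predisi, signalp = sig$signalp),
                 ptm = ptm$sites, quant = quant[c("matrix", "groups")],
                 truth = truth, config = config)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to standard files
#'
#' @param bundle Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_genome(bundle$genome, fp("genome.fasta"))
  write_annotation(bundle$annotation, fp("annotation.gff3"))
  write_proteins(bundle$proteome, fp("proteome.fasta"))
  write_tsv(bundle$psms[, c("spectrum_id", "peptide", "score", "is_decoy",
                            "engine")], fp("psms.tsv"))
  write_tsv(bundle$sigpep$predisi, fp("sigpep_predisi.tsv"))
  write_tsv(bundle$sigpep$signalp, fp("sigpep_signalp.tsv"))
  write_tsv(bundle$ptm, fp("ptm_sites.tsv"))
  qm <- data.frame(protein_id = rownames(bundle$quant$matrix),
                   bundle$quant$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(qm, fp("quant.tsv"))
  write_tsv(data.frame(sample = colnames(bundle$quant$matrix),
                       group = bundle$quant$groups), fp("quant_design.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
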