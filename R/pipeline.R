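# Pipeline orchestration: ingest -> six-frame -> FDR -> classify -> infer ->
# call events, with optional signal-peptide, PTM and quant stages, and a
# deterministic summary report whose every count is recomputable from the
# stage outputs.

#' Pipeline parameters
#'
#' Houses every numeric threshold of the workflow in one place.
#'
#' @param min_orf_len Six-frame ORF length filter (strictly greater than;
#'   default 20 aa).
#' @param fdr FDR threshold for PSM filtering (default 0.01).
#' @param min_support Minimum unique GSSPs per called event (default 2).
#' @param policy A [start_codon_policy()].
#' @param collapse_IL Identify I/L during peptide matching (default `FALSE`).
#' @param min_overlap Residue overlap needed to refute a signal-peptide
#'   prediction (default 1).
#' @param ptm_min_score,ptm_min_prob PTM confidence thresholds (40, 0.75;
#'   strict).
#' @param fc_up,fc_down,alpha DEP thresholds (1.2, 0.83, 0.05).
#' @param include_unbounded Keep replicon-edge six-frame segments lacking a
#'   bounding stop (default `TRUE`).
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(min_orf_len = 20L, fdr = 0.01, min_support = 2L,
                            policy = start_codon_policy(),
                            collapse_IL = FALSE, min_overlap = 1L,
                            ptm_min_score = 40, ptm_min_prob = 0.75,
                            fc_up = 1.2, fc_down = 0.83, alpha = 0.05,
                            include_unbounded = TRUE) {
  stopifnot(fdr > 0, fdr < 1, min_support >= 1L, min_orf_len >= 0L)
  structure(as.list(environment()), class = "pipeline_params")
}

#' Residue intervals of identified peptides per reference protein
#'
#' Converts known/shared peptide hits into 1-based inclusive residue
#' intervals, the evidence format consumed by [refute()].
#'
#' @param assignments A `peptide_assignments` data.frame.
#' @return `data.frame` with `protein_id`, `start`, `end`, `peptide`.
#' @export
peptide_evidence_from_assignments <- function(assignments) {
  known <- assignments[assignments$category %in% c("known", "shared_known"), ,
                       drop = FALSE]
  rows <- lapply(seq_len(nrow(known)), function(i) {
    h <- known$protein_hits[[i]]
    data.frame(protein_id = h$protein_id, start = h$offset + 1L,
               end = h$offset + nchar(known$peptide[i]),
               peptide = known$peptide[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), peptide = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Run the full proteogenomic reannotation pipeline
#'
#' Fixed stage order: six-frame ORF extraction, target-decoy FDR filtering,
#' peptide classification, protein inference, novelty calling; then the
#' optional signal-peptide, PTM and quant stages when their inputs are
#' supplied. The returned report is deterministic given the inputs.
#'
#' @param genome A `GenomeSet`.
#' @param annotation A `gene_annotation`.
#' @param psms PSM `data.frame` ([read_psms()] format).
#' @param contaminants Optional named character vector of contaminant
#'   proteins.
#' @param sigpep_a,sigpep_b Optional prediction data.frames (two
#'   predictors); refutation uses the identified-peptide evidence computed
#'   by the pipeline itself.
#' @param ptm_sites Optional PTM site `data.frame`.
#' @param quant Optional list `(matrix, groups)` of raw reporter
#'   intensities.
#' @param params A [pipeline_params()].
#' @return A `protannotate_run` list: `report` plus all stage outputs
#'   (`orfs`, `accepted`, `assignments`, `evidence`, `events`,
#'   `refutations`, `ptm_summary`, `deps`, ...).
#' @export
run_pipeline <- function(genome, annotation, psms, contaminants = NULL,
                         sigpep_a = NULL, sigpep_b = NULL, ptm_sites = NULL,
                         quant = NULL, params = pipeline_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  orfs <- stage("sixframe", extract_orfs(genome, params$min_orf_len,
                                         params$include_unbounded))
  proteome <- stage("reference", annotation_proteome(genome, annotation))
  accepted <- stage("fdr", fdr_filter(psms, params$fdr))
  index <- stage("index", build_peptide_index(proteome, orfs, contaminants,
                                              params$collapse_IL))
  assignments <- stage("classify",
                       classify_peptides(unique(accepted$peptide), index))
  evidence <- stage("infer", infer_proteins(assignments, proteome))
  events <- stage("call", call_events(assignments, annotation, genome, orfs,
                                      params$min_support, params$policy))
  refut <- NULL
  if (!is.null(sigpep_a)) {
    ev <- peptide_evidence_from_assignments(assignments)
    preds <- if (!is.null(sigpep_b))
      intersect_predictions(sigpep_a, sigpep_b) else sigpep_a
    refut <- stage("sigpep", refute(preds, ev, params$min_overlap))
  }
  ptm_sum <- NULL
  ptm_confident <- NULL
  if (!is.null(ptm_sites)) {
    ptm_confident <- stage("ptm", filter_sites(ptm_sites,
                                               params$ptm_min_score,
                                               params$ptm_min_prob))
    ptm_sum <- summarize_ptms(ptm_confident)
  }
  deps <- NULL
  if (!is.null(quant)) {
    norm <- stage("quant", normalize_intensities(quant$matrix))
    deps <- stage("quant", call_deps(norm, quant$groups,
                                     fc_up = params$fc_up,
                                     fc_down = params$fc_down,
                                     alpha = params$alpha))
  }
  cat_counts <- table(factor(assignments$category,
                             levels = c("known", "shared_known", "gssp",
                                        "unmatched", "contaminant")))
  status_counts <- table(factor(evidence$status,
                                levels = c("identified", "single_peptide",
                                           "shared_only", "undetected")))
  event_counts <- table(factor(events$category,
                               levels = c("intergenic", "alt_frame",
                                          "antisense", "n_term_extension")))
  report <- list(
    n_psms = nrow(psms),
    n_accepted_psms = nrow(accepted),
    score_cutoff = attr(accepted, "score_cutoff"),
    n_orfs = nrow(orfs),
    n_peptides = nrow(assignments),
    peptides_by_category = as.list(cat_counts),
    proteins_by_status = as.list(status_counts),
    proteome_size = length(proteome),
    events_by_category = as.list(event_counts),
    n_events = nrow(events),
    n_refuted = if (!is.null(refut)) sum(refut$status == "refuted") else NULL,
    n_retained = if (!is.null(refut)) sum(refut$status == "retained") else NULL,
    n_ptm_sites_confident = if (!is.null(ptm_confident))
      nrow(ptm_confident) else NULL,
    n_deps = if (!is.null(deps)) sum(deps$is_dep) else NULL
  )
  structure(list(report = report, orfs = orfs, proteome = proteome,
                 accepted = accepted, assignments = assignments,
                 evidence = evidence, events = events, refutations = refut,
                 ptm_summary = ptm_sum, ptm_confident = ptm_confident,
                 deps = deps, params = params),
            class = "protannotate_run")
}

#' @export
print.protannotate_run <- function(x, ...) {
  r <- x$report
  cat("Proteogenomic reannotation run\n")
  cat(sprintf("  PSMs: %d in, %d accepted (score cutoff %.3g)\n",
              r$n_psms, r$n_accepted_psms, r$score_cutoff))
  cat(sprintf("  six-frame ORFs: %d\n", r$n_orfs))
  cat("  peptides:",
      paste(names(r$peptides_by_category), unlist(r$peptides_by_category),
            sep = "=", collapse = ", "), "\n")
  cat("  proteins:",
      paste(names(r$proteins_by_status), unlist(r$proteins_by_status),
            sep = "=", collapse = ", "), "\n")
  cat("  events:",
      paste(names(r$events_by_category), unlist(r$events_by_category),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Run the pipeline from files (JSON config)
#'
#' The config maps input paths and optional parameter overrides:
#' `genome`, `gff`, `psms` (required), `sigpep_a`, `sigpep_b`, `ptm`,
#' `quant`, `quant_design`, `contaminants` (optional paths), and `params`
#' (list of [pipeline_params()] overrides). Stage outputs are written to
#' `out_dir` (assignments, evidence, events TSVs, updated GFF3, JSON
#' report).
#'
#' @param config_path Path to the JSON config.
#' @param out_dir Output directory.
#' @return The `protannotate_run`, invisibly.
#' @export
run_pipeline_files <- function(config_path, out_dir) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (f in c("genome", "gff", "psms"))
    if (is.null(cfg[[f]])) stop("config is missing '", f, "'", call. = FALSE)
  genome <- read_genome(cfg$genome)
  annotation <- read_annotation(cfg$gff, genome)
  psms <- read_psms(cfg$psms)
  params <- do.call(pipeline_params, as.list(cfg$params))
  proteome <- annotation_proteome(genome, annotation)
  sig_a <- if (!is.null(cfg$sigpep_a))
    read_predictions(cfg$sigpep_a, "predictor_a", proteome) else NULL
  sig_b <- if (!is.null(cfg$sigpep_b))
    read_predictions(cfg$sigpep_b, "predictor_b", proteome) else NULL
  ptm <- if (!is.null(cfg$ptm)) read_ptm_sites(cfg$ptm, proteome) else NULL
  quant <- NULL
  if (!is.null(cfg$quant)) {
    qdf <- read_tsv(cfg$quant, required = "protein_id")
    m <- as.matrix(qdf[, -1, drop = FALSE])
    rownames(m) <- qdf$protein_id
    design <- read_tsv(cfg$quant_design, required = c("sample", "group"))
    quant <- list(matrix = m,
                  groups = design$group[match(colnames(m), design$sample)])
  }
  contam <- if (!is.null(cfg$contaminants)) read_proteins(cfg$contaminants)
            else NULL
  run <- run_pipeline(genome, annotation, psms, contam, sig_a, sig_b, ptm,
                      quant, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  flat <- run$assignments[, c("peptide", "category", "n_protein_hits",
                              "n_loci", "is_unique")]
  write_tsv(flat, fp("assignments.tsv"))
  write_tsv(run$evidence, fp("protein_evidence.tsv"))
  write_events(run$events, fp("events.tsv"))
  write_annotation(annotation, fp("updated_annotation.gff3"),
                   events = run$events)
  if (!is.null(run$refutations))
    write_tsv(run$refutations[, c("protein_id", "cleavage_pos", "predictor",
                                  "score", "status", "n_refuting")],
              fp("sigpep_refutation.tsv"))
  if (!is.null(run$ptm_summary)) write_tsv(run$ptm_summary, fp("ptm_summary.tsv"))
  if (!is.null(run$deps)) write_tsv(run$deps, fp("deps.tsv"))
  jsonlite::write_json(run$report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(run)
}
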