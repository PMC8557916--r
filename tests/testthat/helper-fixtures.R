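# Shared fixtures. The small bundle keeps unit tests fast; the default-scale
# bundle is reserved for the end-to-end acceptance checks. Bundles are
# cached per session.

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 11L, ...) {
  synthetic_config(
    seed = seed,
    replicon_lengths = c(16000L, 5000L),
    n_genes = 14L,
    gene_len_aa = c(100L, 200L),
    planted = c(intergenic = 1L, alt_frame = 1L, antisense = 1L),
    n_truncated = 2L,
    signal_fraction = 0.3,
    n_ptm_sites = 60L,
    ...
  )
}

small_bundle <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_synthetic(small_config())
  }
  .fixture_cache$small
}

small_run <- function() {
  if (is.null(.fixture_cache$small_run)) {
    b <- small_bundle()
    .fixture_cache$small_run <- run_pipeline(
      b$genome, b$annotation, b$psms,
      sigpep_a = b$sigpep$predisi, sigpep_b = b$sigpep$signalp,
      ptm_sites = b$ptm, quant = b$quant)
  }
  .fixture_cache$small_run
}

# score a called event set against the planted manifest (exact model
# coordinates, strand and category)
score_events <- function(events, truth) {
  tn <- truth$novel_orfs
  matched_novel <- sum(apply(tn, 1, function(r) {
    any(events$seqid == r[["seqid"]] &
          events$start == as.integer(r[["model_start"]]) &
          events$end == as.integer(r[["model_end"]]) &
          events$strand == r[["strand"]] &
          events$category == r[["category"]])
  }))
  tt <- truth$truncations
  matched_trunc <- sum(apply(tt, 1, function(r) {
    any(events$seqid == r[["seqid"]] &
          events$start == as.integer(r[["true_start"]]) &
          events$end == as.integer(r[["true_end"]]) &
          events$strand == r[["strand"]] &
          events$category == "n_term_extension" &
          events$revised_gene_id == r[["gene_id"]])
  }))
  list(n_events = nrow(events),
       n_truth = nrow(tn) + nrow(tt),
       matched = matched_novel + matched_trunc,
       recall = (matched_novel + matched_trunc) / (nrow(tn) + nrow(tt)),
       precision = if (nrow(events)) (matched_novel + matched_trunc) /
         nrow(events) else NA_real_)
}
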