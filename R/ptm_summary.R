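# PTM-site confidence filtering and per-type aggregation. Site tables come
# from external localization engines; this module applies the confidence
# thresholds (identification score and localization probability, both
# strict) and counts sites and proteins per modification type.

#' Default PTM vocabulary (27 modification types)
#'
#' Lysine acylations (acetyl, succinyl, butyryl, crotonyl, malonyl,
#' propionyl, glutaryl, benzoyl, lactyl, biotinyl, 2-hydroxy...), the
#' methylation series on K/R/E/Q/C, phosphorylation, and the remaining
#' residue-specific chemistries tracked by restricted searches.
#'
#' @return Character vector of 27 PTM type labels.
#' @export
ptm_vocabulary <- function() {
  c("phosphorylation_STY",
    "monomethylation_C", "monomethylation_EQ", "monomethylation_KR",
    "dimethylation_KR", "trimethylation_K",
    "acetylation_K", "succinylation_K",
    "butyrylation_K", "crotonylation_K", "malonylation_K", "propionylation_K",
    "biotinylation_K",
    "persulfide_CD", "nitration_WY", "s_nitrosylation_C",
    "diphthamide_H", "farnesylation_C", "myristoylation_CK",
    "palmitoylation_STCK", "adp_ribosylation_CDEKNRS",
    "beta_methylthiolation_D", "hydroxymethylation_N",
    "hydroxytrimethylation_K",
    "glutarylation_K", "benzoylation_K", "lactylation_K")
}

#' Read a PTM site table
#'
#' @param path TSV with columns `protein_id`, `position` (1-based residue),
#'   `residue`, `ptm_type`, `score`, `localization_prob`.
#' @param proteome Optional named character vector; sites whose stated
#'   residue disagrees with the proteome draw a warning (not an error:
#'   revised gene models may shift coordinates).
#' @param vocabulary Allowed PTM types (default [ptm_vocabulary()]);
#'   out-of-vocabulary types are an error.
#' @return `data.frame` of sites.
#' @export
read_ptm_sites <- function(path, proteome = NULL,
                           vocabulary = ptm_vocabulary()) {
  df <- read_tsv(path, required = c("protein_id", "position", "residue",
                                    "ptm_type", "score", "localization_prob"))
  df$position <- as.integer(df$position)
  bad <- !df$ptm_type %in% vocabulary
  if (any(bad))
    stop("PTM type(s) outside the vocabulary: ",
         paste(unique(df$ptm_type[bad]), collapse = ", "), call. = FALSE)
  if (any(df$localization_prob < 0 | df$localization_prob > 1))
    stop("localization probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(proteome)) {
    obs <- substr(proteome[df$protein_id], df$position, df$position)
    mism <- !is.na(obs) & obs != df$residue
    if (any(mism))
      warning(sum(mism), " site(s) disagree with the proteome residue",
              call. = FALSE)
  }
  df
}

#' Filter PTM sites at the confidence thresholds
#'
#' Keeps sites with `score > min_score` AND
#' `localization_prob > min_prob`; both inequalities are strict.
#'
#' @param sites PTM site `data.frame`.
#' @param min_score Identification score threshold (default 40).
#' @param min_prob Localization probability threshold (default 0.75).
#' @return The confident subset of `sites`.
#' @export
filter_sites <- function(sites, min_score = 40, min_prob = 0.75) {
  out <- sites[sites$score > min_score & sites$localization_prob > min_prob, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize sites and proteins per modification type
#'
#' @param sites Filtered PTM site `data.frame`.
#' @return `data.frame` with `ptm_type`, `n_sites`, `n_proteins`, ordered by
#'   decreasing `n_sites`; a protein is counted once per type. The `n_sites`
#'   column sums to `nrow(sites)`.
#' @export
summarize_ptms <- function(sites) {
  if (!nrow(sites))
    return(data.frame(ptm_type = character(), n_sites = integer(),
                      n_proteins = integer(), stringsAsFactors = FALSE))
  sp <- split(sites, sites$ptm_type)
  out <- data.frame(
    ptm_type = names(sp),
    n_sites = vapply(sp, nrow, integer(1)),
    n_proteins = vapply(sp, function(x) length(unique(x$protein_id)),
                        integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_sites, out$ptm_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
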