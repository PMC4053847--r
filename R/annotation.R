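META_LABELS <- c("No Information", "Partial", "Quasi Full Length",
                 "Full Length")

#' Meta-annotate transcript completeness
#'
#' Compares the transcript's ORF length (in nucleotides) to the CDS
#' lengths of its assigned gene family. Families that are absent or
#' smaller than `min_family_size_meta` give `"No Information"`.
#' Otherwise the family CDS lengths are sorted, the longest and shortest
#' `trim_fraction` (floor of the count on each side) are removed to damp
#' outliers, and the mean and sample standard deviation of the remainder
#' are computed. An ORF shorter than mean minus `sd_multiplier` standard
#' deviations is `"Partial"`; otherwise it is `"Quasi Full Length"`,
#' upgraded to `"Full Length"` when the ORF has both a start and a stop
#' codon.
#'
#' @param orf_len_nt ORF length in nucleotides.
#' @param family_cds_lengths numeric vector of family CDS lengths (nt),
#'   or `NULL` when no family was assigned.
#' @param has_start,has_stop start/stop codon flags of the ORF call.
#' @param config a [pipeline_config()].
#' @return list with `label`, `trimmed_mean`, `trimmed_sd`, `threshold`.
#' @export
meta_annotate <- function(orf_len_nt, family_cds_lengths,
                          has_start = FALSE, has_stop = FALSE,
                          config = pipeline_config()) {
  stopifnot(orf_len_nt >= 0)
  n <- length(family_cds_lengths)
  if (n < config$min_family_size_meta) {
    return(list(label = "No Information", trimmed_mean = NA_real_,
                trimmed_sd = NA_real_, threshold = NA_real_))
  }
  lens <- sort(as.numeric(family_cds_lengths))
  drop <- floor(config$trim_fraction * n)
  kept <- lens[seq.int(drop + 1L, n - drop)]
  if (length(kept) < 2L) {
    warning("trimming left fewer than 2 CDS lengths; ",
            "falling back to untrimmed statistics")
    kept <- lens
  }
  m <- mean(kept)
  s <- stats::sd(kept)
  thr <- m - config$sd_multiplier * s
  label <- if (orf_len_nt < thr) {
    "Partial"
  } else if (has_start && has_stop) {
    "Full Length"
  } else {
    "Quasi Full Length"
  }
  list(label = label, trimmed_mean = m, trimmed_sd = s, threshold = thr)
}

#' Transfer functional annotation to a transcript
#'
#' Terms are transferred from the assigned gene family by consensus
#' (a term qualifies when the number of family members carrying it is at
#' least `consensus_fraction` of the family size, counting all members
#' in the denominator), copied verbatim from the best similarity-search
#' hit, or both (union). Transcripts with neither family nor hit receive
#' an empty term set.
#'
#' @param family_terms data.frame with columns `gene_id`, `term_id`,
#'   `term_type` restricted to the members of the assigned family, or
#'   `NULL` when no family was assigned.
#' @param family_size number of members of the assigned family
#'   (denominator of the consensus fraction).
#' @param best_hit_terms data.frame with columns `term_id`, `term_type`
#'   holding the best hit gene's terms, or `NULL`.
#' @param source `"family_consensus"`, `"best_hit"` or `"both"`.
#' @param config a [pipeline_config()].
#' @return data.frame with columns `term_id`, `term_type`, `source`.
#' @export
transfer_annotation <- function(family_terms = NULL, family_size = 0L,
                                best_hit_terms = NULL,
                                source = c("family_consensus", "best_hit",
                                           "both"),
                                config = pipeline_config()) {
  source <- match.arg(source)
  empty <- data.frame(term_id = character(), term_type = character(),
                      source = character(), stringsAsFactors = FALSE)
  consensus <- empty
  if (source %in% c("family_consensus", "both") &&
      !is.null(family_terms) && family_size >= 1L &&
      nrow(family_terms)) {
    ft <- unique(family_terms[, c("gene_id", "term_id", "term_type")])
    counts <- stats::aggregate(gene_id ~ term_id + term_type, data = ft,
                               FUN = length)
    keep <- counts$gene_id / family_size >= config$consensus_fraction
    consensus <- data.frame(term_id = counts$term_id[keep],
                            term_type = counts$term_type[keep],
                            source = rep("family_consensus", sum(keep)),
                            stringsAsFactors = FALSE)
  }
  besthit <- empty
  if (source %in% c("best_hit", "both") && !is.null(best_hit_terms) &&
      nrow(best_hit_terms)) {
    bh <- unique(best_hit_terms[, c("term_id", "term_type")])
    besthit <- data.frame(term_id = bh$term_id, term_type = bh$term_type,
                          source = rep("best_hit", nrow(bh)),
                          stringsAsFactors = FALSE)
  }
  out <- rbind(consensus, besthit)
  if (!nrow(out)) return(empty)
  key <- paste(out$term_id, out$term_type)
  dupd <- key %in% key[duplicated(key)]
  out$source[dupd] <- "both"
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$term_type, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
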