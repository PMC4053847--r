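#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for the number of annotated transcripts drawn in a subset:
#' `k` successes in a subset of size `n` drawn from a background of `N`
#' transcripts of which `K` carry the term.
#'
#' @param k observed count in the subset.
#' @param n subset size.
#' @param K background count carrying the term.
#' @param N background size.
#' @return the exact upper-tail probability.
#' @export
hypergeom_upper <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1,
            length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || k > K ||
      K > N) {
    stop("hypergeom_upper: bounds violated (need k <= n <= N, ",
         "k <= K <= N)")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Functional enrichment of labelled transcript subsets
#'
#' For every subset label, every term observed at least once in the
#' subset is tested for enrichment against the whole experiment (all
#' transcripts form the background) with an upper-tail hypergeometric
#' test. Raw p-values are Bonferroni-corrected by the number of terms
#' tested for that label. Transcript-level counting is used: a
#' transcript counts once per term.
#'
#' @param labels data.frame with columns `transcript_id`, `label`.
#' @param annotations data.frame with columns `transcript_id`,
#'   `term_id`, `term_type` (transferred annotations).
#' @param background_ids character vector of all transcript ids in the
#'   experiment.
#' @param config a [pipeline_config()] (supplies `alpha`).
#' @return data.frame with columns `label`, `term_id`, `term_type`,
#'   `k`, `n`, `K`, `N`, `p_raw`, `p_adj`, `significant`, sorted within
#'   label by `p_adj` then `term_id`.
#' @export
enrich_subsets <- function(labels, annotations, background_ids,
                           config = pipeline_config()) {
  stopifnot(nrow(labels) >= 1)
  N <- length(unique(background_ids))
  ann <- unique(annotations[, c("transcript_id", "term_id", "term_type")])
  ann <- ann[ann$transcript_id %in% background_ids, , drop = FALSE]
  term_key <- paste(ann$term_id, ann$term_type, sep = "\r")
  Kmap <- table(term_key)
  out <- list()
  for (lab in sort(unique(labels$label))) {
    subset_ids <- unique(labels$transcript_id[labels$label == lab])
    subset_ids <- intersect(subset_ids, background_ids)
    n <- length(subset_ids)
    if (n == 0) next
    sub_ann <- ann[ann$transcript_id %in% subset_ids, , drop = FALSE]
    if (!nrow(sub_ann)) next
    skey <- paste(sub_ann$term_id, sub_ann$term_type, sep = "\r")
    kmap <- table(skey)
    m <- length(kmap)
    terms <- names(kmap)
    p_raw <- vapply(terms, function(tk) {
      hypergeom_upper(as.integer(kmap[[tk]]), n,
                      as.integer(Kmap[[tk]]), N)
    }, numeric(1))
    parts <- strsplit(terms, "\r", fixed = TRUE)
    res <- data.frame(
      label = lab,
      term_id = vapply(parts, `[`, character(1), 1L),
      term_type = vapply(parts, `[`, character(1), 2L),
      k = as.integer(kmap), n = n,
      K = as.integer(Kmap[terms]), N = N,
      p_raw = unname(p_raw),
      p_adj = pmin(1, m * unname(p_raw)),
      stringsAsFactors = FALSE)
    res$significant <- res$p_adj < config$alpha
    res <- res[order(res$p_adj, res$term_id), , drop = FALSE]
    out[[lab]] <- res
  }
  if (!length(out)) {
    return(data.frame(label = character(), term_id = character(),
                      term_type = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Transcripts in a subset carrying a given term
#'
#' @param subset_ids character vector of transcript ids in the subset.
#' @param annotations transferred-annotation data.frame with columns
#'   `transcript_id`, `term_id`.
#' @param term_id exact term identifier to look up.
#' @return character vector of transcript ids (possibly empty; unknown
#'   terms give an empty result with a warning).
#' @export
query_terms <- function(subset_ids, annotations, term_id) {
  if (!term_id %in% annotations$term_id) {
    warning("term id not found in annotations: ", term_id)
    return(character(0))
  }
  carriers <- unique(
    annotations$transcript_id[annotations$term_id == term_id])
  intersect(subset_ids, carriers)
}
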