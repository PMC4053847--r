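#' Pipeline configuration
#'
#' Collects every tunable constant of the annotation pipeline in one
#' validated list. Defaults mirror the standard protocol: hits above the
#' e-value cutoff are discarded, family assignment uses the best hit (or
#' majority voting over the top five hits against representative
#' databases), functional terms are transferred when carried by at least
#' half of the family, completeness is judged against 10%-trimmed family
#' CDS-length statistics with a mean minus two standard deviations
#' threshold, and alignment editing removes gap columns above 10%
#' (stringent, plus one flanking column each side) or 25% (relaxed).
#'
#' @param evalue_cutoff maximum e-value for a hit to be retained.
#' @param topk_majority number of top hits considered by majority voting.
#' @param consensus_fraction minimum fraction of family members carrying a
#'   term for it to be transferred (inclusive).
#' @param trim_fraction fraction of family CDS lengths trimmed from each
#'   end before computing meta-annotation statistics.
#' @param sd_multiplier number of standard deviations subtracted from the
#'   trimmed mean to obtain the Partial threshold.
#' @param min_family_size_meta smallest family size for which length
#'   statistics are considered informative.
#' @param stringent_gap_threshold gap fraction above which (strictly) a
#'   column is removed under stringent editing.
#' @param relaxed_gap_threshold gap fraction at or above which a column is
#'   removed under relaxed editing.
#' @param flank_width columns removed on each side of a stringently
#'   removed gap column.
#' @param alpha significance level applied to Bonferroni-adjusted
#'   enrichment p-values.
#' @param assignment_method `"best_hit"` or `"majority"`; the default per
#'   database kind is best hit for species/clade proteomes and majority
#'   voting for family-representative databases.
#' @param annotation_source `"family_consensus"`, `"best_hit"` or `"both"`.
#' @param rng_seed integer seed used wherever the pipeline needs
#'   randomness (it is deterministic apart from the generator).
#'
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(evalue_cutoff = 1e-5,
                            topk_majority = 5L,
                            consensus_fraction = 0.5,
                            trim_fraction = 0.1,
                            sd_multiplier = 2.0,
                            min_family_size_meta = 5L,
                            stringent_gap_threshold = 0.10,
                            relaxed_gap_threshold = 0.25,
                            flank_width = 1L,
                            alpha = 0.05,
                            assignment_method = c("best_hit", "majority"),
                            annotation_source = c("family_consensus",
                                                  "best_hit", "both"),
                            rng_seed = 1L) {
  assignment_method <- match.arg(assignment_method)
  annotation_source <- match.arg(annotation_source)
  cfg <- list(
    evalue_cutoff = as.numeric(evalue_cutoff),
    topk_majority = as.integer(topk_majority),
    consensus_fraction = as.numeric(consensus_fraction),
    trim_fraction = as.numeric(trim_fraction),
    sd_multiplier = as.numeric(sd_multiplier),
    min_family_size_meta = as.integer(min_family_size_meta),
    stringent_gap_threshold = as.numeric(stringent_gap_threshold),
    relaxed_gap_threshold = as.numeric(relaxed_gap_threshold),
    flank_width = as.integer(flank_width),
    alpha = as.numeric(alpha),
    assignment_method = assignment_method,
    annotation_source = annotation_source,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$evalue_cutoff >= 0,
    cfg$topk_majority >= 1L,
    cfg$consensus_fraction > 0, cfg$consensus_fraction <= 1,
    cfg$trim_fraction >= 0, cfg$trim_fraction < 0.5,
    cfg$sd_multiplier >= 0,
    cfg$min_family_size_meta >= 1L,
    cfg$stringent_gap_threshold > 0, cfg$stringent_gap_threshold < 1,
    cfg$relaxed_gap_threshold > 0, cfg$relaxed_gap_threshold < 1,
    cfg$flank_width >= 0L,
    cfg$alpha > 0, cfg$alpha < 1
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in setdiff(names(x), NULL)) {
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

# Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}
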