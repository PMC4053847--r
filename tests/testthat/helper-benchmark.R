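# The frameshift benchmark run (default simulation conditions, built-in
# search) is the most expensive fixture in the suite; several test files
# share one memoised run.
benchmark_env <- new.env(parent = emptyenv())

benchmark_run <- function() {
  if (!is.null(benchmark_env$run)) {
    return(benchmark_env$run)
  }
  cfg <- sim_config(rng_seed = 42L)
  ref <- generate_reference(cfg)
  tx <- generate_transcripts(ref, cfg)
  hits <- translated_search(tx$transcripts, ref$proteins,
                            evalue_cutoff = 1e-5)
  orf_calls <- lapply(names(tx$transcripts), function(tid) {
    call_orf(tid, as.character(tx$transcripts[[tid]]),
             transannot:::best_hit_hsps(hits, tid))
  })
  names(orf_calls) <- names(tx$transcripts)
  orf_table <- orf_calls_table(orf_calls)
  assignments <- assign_families(hits, ref$families,
                                 transcript_ids = names(tx$transcripts))
  benchmark_env$run <- list(cfg = cfg, ref = ref, tx = tx, hits = hits,
                            orf_calls = orf_calls,
                            orf_table = orf_table,
                            assignments = assignments)
  benchmark_env$run
}

# A small simulated experiment for fast pipeline-level tests.
small_sim <- function(seed = 11L) {
  cfg <- sim_config(rng_seed = seed, n_families = 5L,
                    family_size_range = c(4L, 7L),
                    root_protein_length_range = c(70L, 120L),
                    n_clean_transcripts = 12L,
                    n_indel_transcripts = 6L,
                    n_truncated_transcripts = 4L)
  ref <- generate_reference(cfg)
  tx <- generate_transcripts(ref, cfg)
  list(cfg = cfg, ref = ref, tx = tx)
}
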