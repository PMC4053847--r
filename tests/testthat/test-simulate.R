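test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(rng_seed = 42L, n_families = 6L,
                    n_clean_transcripts = 10L,
                    n_indel_transcripts = 5L,
                    n_truncated_transcripts = 3L)
  r1 <- generate_reference(cfg); r2 <- generate_reference(cfg)
  expect_identical(as.character(r1$proteins), as.character(r2$proteins))
  expect_identical(r1$families, r2$families)
  expect_identical(r1$annotations, r2$annotations)
  t1 <- generate_transcripts(r1, cfg)
  t2 <- generate_transcripts(r2, cfg)
  expect_identical(as.character(t1$transcripts),
                   as.character(t2$transcripts))
  expect_identical(t1$truth, t2$truth)

  # a different seed changes the data
  r3 <- generate_reference(sim_config(rng_seed = 43L, n_families = 6L))
  expect_false(identical(as.character(r1$proteins),
                         as.character(r3$proteins)))
})

test_that("reference structure matches the configuration", {
  cfg <- sim_config(rng_seed = 7L, n_families = 20L)
  ref <- generate_reference(cfg)
  sizes <- table(ref$families$family_id)
  expect_identical(length(sizes), 20L)
  expect_true(all(sizes >= 4 & sizes <= 12))
  # roughly n_families * mean size rows
  expect_gt(nrow(ref$families), 20 * 4)
  expect_lt(nrow(ref$families), 20 * 13)
  # CDS length bookkeeping includes the stop codon
  expect_identical(unname(nchar(as.character(ref$cds))),
                   ref$families$cds_length_nt)
  expect_identical(
    unname(nchar(as.character(ref$proteins))) * 3L + 3L,
    ref$families$cds_length_nt)
  expect_true(all(ref$annotations$term_type %in% c("GO", "domain")))

  # every family carries at least one consensus term (>= half members)
  fmap <- setNames(ref$families$family_id, ref$families$gene_id)
  ann_fam <- data.frame(family_id = fmap[ref$annotations$gene_id],
                        term_id = ref$annotations$term_id)
  counts <- table(ann_fam$family_id, ann_fam$term_id)
  for (fam in names(sizes)) {
    expect_true(max(counts[fam, ]) >= ceiling(sizes[[fam]] / 2),
                label = paste("consensus term present in", fam))
  }
})

test_that("transcript classes have the constructed properties", {
  cfg <- sim_config(rng_seed = 9L, n_families = 8L,
                    n_clean_transcripts = 15L,
                    n_indel_transcripts = 10L,
                    n_truncated_transcripts = 5L)
  ref <- generate_reference(cfg)
  tx <- generate_transcripts(ref, cfg)
  expect_identical(nrow(tx$truth), 30L)
  expect_identical(names(tx$transcripts), tx$truth$transcript_id)

  cds <- as.character(ref$cds)
  for (i in seq_len(nrow(tx$truth))) {
    tr <- tx$truth[i, ]
    seq <- as.character(tx$transcripts[[tr$transcript_id]])
    fwd <- if (tr$strand == "-") revcomp(seq) else seq
    src <- cds[[tr$gene_id]]
    if (tr$class == "clean") {
      # the forward strand contains the source CDS verbatim
      expect_true(grepl(fwd, pattern = src, fixed = TRUE))
    } else if (tr$class == "indel") {
      # exactly one base inserted or deleted relative to the CDS
      utr_total <- nchar(fwd) - nchar(src) +
        ifelse(tr$indel_type == "del", 1L, -1L)
      expect_gte(utr_total, 0L)
      expect_false(grepl(fwd, pattern = src, fixed = TRUE))
    } else {
      # truncated: a contiguous window of the CDS, no UTRs
      expect_true(grepl(src, pattern = fwd, fixed = TRUE))
      expect_lt(nchar(fwd), nchar(src))
    }
  }
})

test_that("benchmark scoring handles edge cases", {
  truth <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = "g1", family_id = "F1", strand = "+",
    class = c("clean", "clean", "clean"),
    indel_pos = NA_integer_, indel_type = NA_character_,
    rel_pos = NA_real_, stringsAsFactors = FALSE)
  calls <- data.frame(transcript_id = c("t1", "t2", "t3"),
                      frameshift_flagged = FALSE,
                      stringsAsFactors = FALSE)
  m <- score_benchmark(calls, truth)
  expect_true(is.na(m$sensitivity))
  expect_identical(m$fpr, 0)

  truth$class <- c("indel", "indel", "clean")
  truth$rel_pos <- c(0.5, 0.1, NA)
  calls$frameshift_flagged <- c(TRUE, TRUE, FALSE)
  m2 <- score_benchmark(calls, truth)
  expect_identical(m2$sensitivity, 1)
  expect_identical(m2$fpr, 0)

  expect_error(score_benchmark(calls[1:2, ], truth), "missing")
})
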