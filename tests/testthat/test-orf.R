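test_that("frame statistics detect frame disagreement on the best hit", {
  same <- make_hsps("t1", sid = c("g1", "g1"), qframe = c(2, 2))
  fs <- frame_statistics(same)
  expect_true(fs$consistent)
  expect_identical(fs$evidence_frames, 2L)

  diff <- make_hsps("t1", sid = c("g1", "g1"), qframe = c(1, 3))
  fs2 <- frame_statistics(diff)
  expect_false(fs2$consistent)
  expect_identical(fs2$evidence_frames, c(1L, 3L))

  single <- make_hsps("t1", sid = "g1", qframe = -3)
  expect_true(frame_statistics(single)$consistent)

  expect_error(frame_statistics(make_hsps("t1", character(0),
                                          integer(0))),
               "at least one")
})

test_that("longest ORF extraction picks the longest stop-free codon run", {
  o <- longest_orf_in_frame("ATGAAATAA", 1)
  expect_identical(c(o$orf_start, o$orf_end), c(0L, 6L))
  expect_identical(o$protein, "MK")
  expect_true(o$has_start); expect_true(o$has_stop)

  o2 <- longest_orf_in_frame("TTTTAAATGCCC", 1)
  expect_identical(c(o2$orf_start, o2$orf_end), c(6L, 12L))
  expect_identical(o2$protein, "MP")
  expect_true(o2$has_start); expect_false(o2$has_stop)

  o3 <- longest_orf_in_frame("TTACAT", -1)
  expect_identical(o3$protein, "M")
  expect_true(o3$has_start); expect_true(o3$has_stop)
  # coordinates are on the input strand: ATG sits at the 3' end
  expect_identical(c(o3$orf_start, o3$orf_end), c(3L, 6L))

  # 5'-most run wins a length tie
  o4 <- longest_orf_in_frame("AAATAACCCTAAGGG", 1)
  expect_identical(c(o4$orf_start, o4$orf_end), c(0L, 3L))
})

test_that("call_orf composes frame statistics with ORF extraction", {
  cons <- make_hsps("t1", sid = "g1", qframe = 1)
  oc <- call_orf("t1", "ATGAAATAA", cons)
  expect_identical(oc$protein, "MK")
  expect_false(oc$frameshift_flagged)

  # disagreeing frames: flagged, longest ORF over all six frames
  seq <- "ATGAAACCCGGGTTTTAA"
  inc <- make_hsps("t1", sid = c("g1", "g1"), qframe = c(1, 2))
  oc2 <- call_orf("t1", seq, inc)
  expect_true(oc2$frameshift_flagged)
  expect_identical(oc2$evidence_frames, c(1L, 2L))
  all6 <- vapply(c(1, 2, 3, -1, -2, -3), function(f) {
    nchar(longest_orf_in_frame(seq, f)$protein)
  }, numeric(1))
  expect_identical(nchar(oc2$protein), as.integer(max(all6)))

  # hitless transcript: frame NA, still gets the all-frame longest ORF
  # (here the reverse strand holds the longest stop-free run, LFH)
  oc3 <- call_orf("t1", "ATGAAATAA", NULL)
  expect_true(is.na(oc3$frame))
  expect_identical(oc3$protein, "LFH")
  expect_false(oc3$frameshift_flagged)
  all6 <- vapply(c(1, 2, 3, -1, -2, -3), function(f) {
    nchar(longest_orf_in_frame("ATGAAATAA", f)$protein)
  }, numeric(1))
  expect_identical(nchar(oc3$protein), as.integer(max(all6)))
})

test_that("every ORF call's region re-translates to its protein", {
  withr::with_seed(101, {
    for (i in 1:60) {
      seq <- random_dna_seq(sample(30:400, 1))
      frame <- sample(c(1:3, -1:-3), 1)
      hs <- make_hsps("t", sid = "g", qframe = frame)
      oc <- call_orf("t", seq, hs)
      len <- oc$orf_end - oc$orf_start
      expect_identical(len %% 3L, 0L)
      expect_false(grepl("*", oc$protein, fixed = TRUE))
      if (len > 0) {
        region <- substr(seq, oc$orf_start + 1, oc$orf_end)
        if (frame < 0) region <- revcomp(region)
        expect_identical(
          transannot:::translate_frame(region, 1L), oc$protein)
      }
    }
  })
})

test_that("ORF calling is plus/minus symmetric under mirrored hits", {
  withr::with_seed(103, {
    for (i in 1:40) {
      L <- sample(30:300, 1)
      seq <- random_dna_seq(L)
      frame <- sample(c(1:3, -1:-3), 1)
      hs <- make_hsps("t", sid = "g", qframe = frame,
                      qstart = 5, qend = 20)
      oc <- call_orf("t", seq, hs)
      mirrored <- hs
      mirrored$qframe <- -hs$qframe
      mirrored$qstart <- L + 1 - hs$qstart
      mirrored$qend <- L + 1 - hs$qend
      oc_rc <- call_orf("t", revcomp(seq), mirrored)
      expect_identical(oc_rc$protein, oc$protein)
      expect_identical(oc_rc$orf_start, L - oc$orf_end)
      expect_identical(oc_rc$orf_end, L - oc$orf_start)
    }
  })
})

test_that("the naive corrector reconciles a single deletion", {
  withr::with_seed(107, prot <- paste0("M", random_protein(79)))
  cds <- paste0(backtranslate_first_codon(prot), "TAA")
  # delete one base inside codon 31 (nt 91..93)
  broken <- paste0(substr(cds, 1, 90), substr(cds, 92, nchar(cds)))
  # 5' block still frame +1; after the deletion the 3' part reads +3
  hs <- make_hsps("t", sid = c("g", "g"), qframe = c(1, 3),
                  qstart = c(1, 100), qend = c(84, 200),
                  bitscore = c(150, 120))
  fixed <- correct_frameshift_naive(broken, hs)
  expect_false(is.null(fixed))
  expect_identical(nchar(fixed), nchar(broken) + 1L)
  o <- longest_orf_in_frame(fixed, 1)
  # translation matches the source protein outside the edited codon
  expect_identical(substr(o$protein, 1, 28), substr(prot, 1, 28))
  expect_identical(substr(o$protein, 33, 80), substr(prot, 33, 80))

  # the same works on the minus strand
  hs_m <- hs
  Lb <- nchar(broken)
  hs_m$qframe <- -hs$qframe
  hs_m$qstart <- Lb + 1 - hs$qstart
  hs_m$qend <- Lb + 1 - hs$qend
  fixed_m <- correct_frameshift_naive(revcomp(broken), hs_m)
  expect_identical(fixed_m, revcomp(fixed))
})

test_that("the corrector refuses out-of-scope inputs", {
  three <- make_hsps("t", sid = rep("g", 3), qframe = c(1, 2, 3),
                     qstart = c(1, 40, 80), qend = c(30, 70, 110))
  expect_null(correct_frameshift_naive(random_dna_seq(120), three))

  overlap <- make_hsps("t", sid = c("g", "g"), qframe = c(1, 2),
                       qstart = c(1, 50), qend = c(80, 120))
  expect_null(correct_frameshift_naive(random_dna_seq(130), overlap))

  mixed <- make_hsps("t", sid = c("g", "g"), qframe = c(1, -2),
                     qstart = c(1, 120), qend = c(40, 80))
  expect_null(correct_frameshift_naive(random_dna_seq(130), mixed))

  unflagged <- make_hsps("t", sid = "g", qframe = 1)
  expect_error(correct_frameshift_naive(random_dna_seq(60), unflagged),
               "flagged")
})
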