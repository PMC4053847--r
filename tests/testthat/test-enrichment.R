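test_that("upper-tail hypergeometric matches hand-computed values", {
  # all 5 draws annotated out of 5/20: exactly 1 / C(20,5)
  expect_equal(hypergeom_upper(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_identical(hypergeom_upper(0, 5, 5, 20), 1)
  expect_identical(hypergeom_upper(6, 6, 6, 6), 1)
  expect_error(hypergeom_upper(3, 2, 5, 20), "bounds")
  expect_error(hypergeom_upper(1, 2, 5, 4), "bounds")
})

test_that("hypergeometric equals brute-force enumeration at small N", {
  for (N in c(6, 8, 9)) {
    for (n in 0:N) {
      for (K in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper(k, n, K, N),
                       hypergeom_brute(k, n, K, N),
                       tolerance = 1e-12,
                       label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
        }
      }
    }
  }
})

enrich_fixture <- function() {
  background <- sprintf("t%02d", 1:20)
  labels <- data.frame(transcript_id = sprintf("t%02d", 1:5),
                       label = "clusterA", stringsAsFactors = FALSE)
  ann <- data.frame(transcript_id = sprintf("t%02d", 1:5),
                    term_id = "GO:0003700", term_type = "GO",
                    stringsAsFactors = FALSE)
  list(background = background, labels = labels, ann = ann)
}

test_that("subset enrichment reproduces the worked example", {
  fx <- enrich_fixture()
  res <- enrich_subsets(fx$labels, fx$ann, fx$background)
  expect_identical(nrow(res), 1L)
  expect_equal(res$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_adj, res$p_raw)  # m = 1
  expect_true(res$significant)
  expect_identical(c(res$k, res$n, res$K, res$N), c(5L, 5L, 5L, 20L))

  # ten tested terms multiply the adjusted p-value tenfold
  ann10 <- do.call(rbind, lapply(1:10, function(i) {
    transform(fx$ann, term_id = sprintf("GO:%07d", i))
  }))
  res10 <- enrich_subsets(fx$labels, ann10, fx$background)
  expect_identical(nrow(res10), 10L)
  expect_equal(res10$p_adj, pmin(1, 10 * res10$p_raw))

  # terms absent from the subset are not tested
  ann_bg <- rbind(fx$ann,
                  data.frame(transcript_id = "t10", term_id = "GO:xx",
                             term_type = "GO", stringsAsFactors = FALSE))
  res_bg <- enrich_subsets(fx$labels, ann_bg, fx$background)
  expect_false("GO:xx" %in% res_bg$term_id)
})

test_that("adjusted p-values are monotone in the number of tests", {
  fx <- enrich_fixture()
  p <- numeric(0)
  for (m in c(1, 3, 7)) {
    annm <- do.call(rbind, lapply(seq_len(m), function(i) {
      transform(fx$ann, term_id = sprintf("GO:%07d", i))
    }))
    res <- enrich_subsets(fx$labels, annm, fx$background)
    p <- c(p, res$p_adj[res$term_id == "GO:0000001"])
  }
  expect_true(all(diff(p) >= 0))
})

test_that("term queries return subset carriers only", {
  ann <- data.frame(transcript_id = c("t1", "t2", "t5"),
                    term_id = "GO:0003700", term_type = "GO",
                    stringsAsFactors = FALSE)
  expect_setequal(query_terms(c("t1", "t2", "t3"), ann, "GO:0003700"),
                  c("t1", "t2"))
  expect_identical(query_terms(character(0), ann, "GO:0003700"),
                   character(0))
  expect_warning(res <- query_terms(c("t1"), ann, "GO:9999999"),
                 "not found")
  expect_identical(res, character(0))
})

test_that("permuted annotations give a calibrated type-I error", {
  # reduced version of the calibration in the acceptance suite
  withr::with_seed(71, {
    N <- 500L; n <- 125L
    hits <- 0L; total <- 0L
    for (perm in 1:150) {
      K <- sample(100:200, 5, replace = TRUE)
      for (K1 in K) {
        k <- sum(sample.int(N, K1) <= n)  # subset = first n transcripts
        p <- hypergeom_upper(k, n, K1, N)
        hits <- hits + (p < 0.05)
        total <- total + 1L
      }
    }
  })
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.08)
})
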