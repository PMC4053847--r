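fam_map <- c(g1 = "F1", g2 = "F2", g3 = "F1", g4 = "F3", g5 = "F2")

test_that("best-hit assignment takes the top mappable hit's family", {
  hits <- make_hsps("t1", sid = c("g1", "g2"), qframe = 1,
                    bitscore = c(100, 90))
  a <- assign_best_hit(hits, fam_map)
  expect_identical(a$family_id, "F1")
  expect_identical(a$best_hit_id, "g1")

  # no hits at all: no family, and downstream no annotation
  none <- assign_best_hit(make_hsps("t1", character(0), integer(0)),
                          fam_map)
  expect_true(is.na(none$family_id))

  # unmapped top subject is skipped with a warning
  hits2 <- make_hsps("t1", sid = c("gX", "g2"), qframe = 1,
                     bitscore = c(100, 90))
  expect_warning(a2 <- assign_best_hit(hits2, fam_map), "gX")
  expect_identical(a2$family_id, "F2")
})

test_that("majority voting counts one vote per subject and breaks ties
           toward the best-ranked hit", {
  hits <- make_hsps("t1", sid = c("g1", "g3", "g2", "gA", "gB"),
                    qframe = 1, bitscore = c(100, 95, 90, 85, 80))
  map <- c(g1 = "F1", g3 = "F1", g2 = "F2", gA = "F1", gB = "F3")
  a <- assign_majority(hits, map, k = 5)
  expect_identical(a$family_id, "F1")
  expect_identical(unname(a$votes[["F1"]]), 3L)

  # 2-2 tie between F1 and F2: the family of the best hit wins
  map2 <- c(g1 = "F1", g3 = "F2", g2 = "F1", gA = "F2", gB = "F3")
  a2 <- assign_majority(hits, map2, k = 5)
  expect_identical(a2$family_id, "F1")

  # fewer than k mappable hits: vote over what exists
  a3 <- assign_majority(hits[1:2, ], map, k = 5)
  expect_identical(a3$family_id, "F1")
})

test_that("majority voting with k = 1 reduces to best-hit assignment", {
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(1:7, 1)
      sids <- sample(c(names(fam_map), "gU1", "gU2"), n)
      hits <- make_hsps("t1", sid = sids, qframe = 1,
                        bitscore = sort(runif(n, 50, 200),
                                        decreasing = TRUE))
      a1 <- suppressWarnings(assign_best_hit(hits, fam_map))
      a2 <- suppressWarnings(assign_majority(hits, fam_map, k = 1))
      expect_identical(a1$family_id, a2$family_id)
      expect_identical(a1$best_hit_id, a2$best_hit_id)
    }
  })
})

test_that("assignment is invariant to hit row order", {
  hits <- make_hsps("t1", sid = c("g1", "g2", "g4"), qframe = 1,
                    bitscore = c(80, 95, 95))
  shuffled <- hits[c(3, 1, 2), ]
  expect_identical(assign_best_hit(hits, fam_map)$family_id,
                   assign_best_hit(shuffled, fam_map)$family_id)
  # equal bitscores: subject id breaks the tie deterministically (g2)
  expect_identical(assign_best_hit(hits, fam_map)$family_id, "F2")
})

test_that("representative selection maximises weighted degree", {
  members <- data.frame(gene_id = c("a", "b", "c"),
                        species = "X", stringsAsFactors = FALSE)
  edges <- data.frame(gene_a = c("a", "a", "b"),
                      gene_b = c("b", "c", "c"),
                      weight = c(100, 90, 10), stringsAsFactors = FALSE)
  rep <- select_representatives(members, edges)
  expect_identical(rep$gene_id, "a")
  expect_equal(rep$centrality, 190)

  # single-member species is its own representative
  solo <- select_representatives(
    data.frame(gene_id = "z", species = "Y"), edges[0, ])
  expect_identical(solo$gene_id, "z")
  expect_equal(solo$centrality, 0)

  # two members, no edges: lexicographically smaller id
  iso <- select_representatives(
    data.frame(gene_id = c("n2", "n1"), species = "Y"), edges[0, ])
  expect_identical(iso$gene_id, "n1")

  # edge order invariance
  rep2 <- select_representatives(members, edges[c(3, 1, 2), ])
  expect_equal(rep, rep2)

  expect_error(select_representatives(
    members, data.frame(gene_a = "a", gene_b = "a", weight = 5)),
    "self-edges")
})

test_that("representative selection matches a brute-force oracle on
           random family graphs", {
  withr::with_seed(41, {
    for (i in 1:20) {
      ngenes <- sample(3:10, 1)
      members <- data.frame(
        gene_id = sprintf("m%02d", sample(ngenes)),
        species = sample(c("s1", "s2", "s3"), ngenes, replace = TRUE),
        stringsAsFactors = FALSE)
      pairs <- t(utils::combn(members$gene_id, 2))
      keep <- runif(nrow(pairs)) < 0.6
      edges <- data.frame(gene_a = pairs[keep, 1],
                          gene_b = pairs[keep, 2],
                          weight = round(runif(sum(keep), 30, 300)),
                          stringsAsFactors = FALSE)
      expect_equal(select_representatives(members, edges),
                   representatives_brute(members, edges))
    }
  })
})
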