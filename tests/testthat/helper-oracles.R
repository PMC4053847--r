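# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (enumeration / textbook dynamic programming) and
# share no code with the package implementation they check.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic back-translation: always the first codon of each amino
# acid in the standard code (test fixture helper, not the simulator's
# uniform-synonymous scheme)
backtranslate_first_codon <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  first <- vapply(split(names(gc), unname(gc)), `[`, character(1), 1L)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(first[aa], collapse = "")
}

blosum_for_tests <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Textbook O(nm) Gotoh local alignment; a gap of length L costs
# open + L * ext, matching the package scoring scheme.
sw_score_naive <- function(a, b, open = 11, ext = 1,
                           mat = blosum_for_tests()) {
  A <- match(strsplit(a, "", fixed = TRUE)[[1]], rownames(mat))
  B <- match(strsplit(b, "", fixed = TRUE)[[1]], colnames(mat))
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exact upper-tail hypergeometric probability by enumerating every draw
# of n from N (successes are elements 1..K). Only feasible for N <= 12.
hypergeom_brute <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Brute-force per-species representative: maximal sum of incident edge
# weights, ties to the lexicographically smallest gene id.
representatives_brute <- function(members, edges) {
  cent <- sapply(members$gene_id, function(g) {
    sum(edges$weight[edges$gene_a == g | edges$gene_b == g])
  })
  out <- lapply(sort(unique(members$species)), function(sp) {
    genes <- members$gene_id[members$species == sp]
    cg <- cent[genes]
    best <- sort(genes[cg == max(cg)])[1]
    data.frame(species = sp, gene_id = best,
               centrality = unname(cg[best]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Minimal HSP row builder for hand-made fixtures.
make_hsps <- function(qid, sid, qframe, bitscore = 100,
                      qstart = 1, qend = 30, sstart = 1, send = 10,
                      evalue = 1e-20) {
  n <- length(sid)
  if (n == 0L) {
    return(transannot:::empty_hsp_frame())
  }
  data.frame(qid = rep_len(qid, n), sid = rep_len(sid, n),
             pident = 100, length = 10, mismatch = 0, gapopen = 0,
             qstart = rep_len(qstart, n), qend = rep_len(qend, n),
             sstart = rep_len(sstart, n), send = rep_len(send, n),
             evalue = rep_len(evalue, n),
             bitscore = rep_len(bitscore, n),
             qframe = rep_len(as.integer(qframe), n),
             stringsAsFactors = FALSE)
}
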