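#' Scoring scheme for the built-in translated search
#'
#' The built-in search aligns every frame translation of a transcript
#' against candidate reference proteins with a local Smith-Waterman
#' alignment under BLOSUM62 and affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`). Raw scores are converted to bit
#' scores and e-values with the standard Karlin-Altschul form using the
#' gapped BLOSUM62 constants lambda = 0.267 and K = 0.041.
#'
#' A k-mer prescreen keeps the search tractable: only proteins sharing at
#' least `min_kmer_hits` exact `kmer_length`-mers with the frame
#' translation are aligned. Set `min_kmer_hits = 0` to align against the
#' whole database.
#'
#' @param gap_open,gap_extend affine gap penalties (positive integers).
#' @param min_raw_score reporting floor on the raw alignment score.
#' @param lambda,K Karlin-Altschul constants for bitscore/e-value.
#' @param max_subjects report at most this many subjects per query.
#' @param max_hsps_per_pair report at most this many HSPs per
#'   (query, subject) pair.
#' @param kmer_length,min_kmer_hits prescreen parameters.
#' @return list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(gap_open = 11L, gap_extend = 1L,
                           min_raw_score = 40L,
                           lambda = 0.267, K = 0.041,
                           max_subjects = 50L, max_hsps_per_pair = 10L,
                           kmer_length = 5L, min_kmer_hits = 3L) {
  stopifnot(gap_open > 0, gap_extend > 0, min_raw_score >= 0,
            lambda > 0, K > 0, max_subjects >= 1, max_hsps_per_pair >= 1,
            kmer_length >= 1, min_kmer_hits >= 0)
  structure(list(matrix = "BLOSUM62",
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_raw_score = as.integer(min_raw_score),
                 lambda = lambda, K = K,
                 max_subjects = as.integer(max_subjects),
                 max_hsps_per_pair = as.integer(max_hsps_per_pair),
                 kmer_length = as.integer(kmer_length),
                 min_kmer_hits = as.integer(min_kmer_hits)),
            class = "scoring_scheme")
}

.transannot_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.transannot_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .transannot_env$BLOSUM62 <- e$BLOSUM62
  }
  .transannot_env$BLOSUM62
}

#' Local Smith-Waterman score between two amino-acid strings
#'
#' @param a,b amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @return the raw local alignment score (0 when nothing aligns).
#' @export
sw_score <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  max(0, s)
}

raw_to_bits <- function(S, scheme) {
  (scheme$lambda * S - log(scheme$K)) / log(2)
}

raw_to_evalue <- function(S, m, n_db, scheme) {
  scheme$K * m * n_db * exp(-scheme$lambda * S)
}

# k-mer index: environment mapping kmer -> integer vector of protein idx
build_kmer_index <- function(proteins, k) {
  seqs <- as.character(proteins)
  kmers <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
  idx <- rep(seq_along(seqs), lengths(kmers))
  tab <- split(idx, unlist(kmers))
  list2env(tab, envir = new.env(hash = TRUE, parent = emptyenv(),
                                size = max(1L, length(tab))))
}

kmer_candidates <- function(translation, index, k, min_hits, n_proteins) {
  n <- nchar(translation) - k + 1L
  if (n < 1L) return(integer(0))
  km <- unique(substring(translation, seq_len(n), seq_len(n) + k - 1L))
  hit <- unlist(mget(km, envir = index, ifnotfound = list(integer(0))),
                use.names = FALSE)
  if (!length(hit)) return(integer(0))
  counts <- tabulate(hit, nbins = n_proteins)
  which(counts >= min_hits)
}

#' Six-frame translated similarity search
#'
#' Translates every transcript in all six reading frames and aligns each
#' translation locally against the reference proteins, reporting HSPs in
#' the same 13-column dialect that [read_hits_table()] consumes, so the
#' built-in search and external tabular searches are interchangeable.
#' Transcript coordinates (`qstart`, `qend`) are 1-based inclusive
#' nucleotide positions of the aligned codons on the input strand, with
#' `qstart > qend` on the minus strand.
#'
#' @param transcripts named [Biostrings::DNAStringSet] (or named
#'   character vector) of query transcripts.
#' @param proteins named [Biostrings::AAStringSet] (or named character
#'   vector) of reference proteins.
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff if non-`NULL`, drop HSPs with larger e-value.
#' @return HSP data.frame (see [read_hits_table()]), sorted by `qid`,
#'   bitscore descending, e-value ascending, `sid`.
#' @export
translated_search <- function(transcripts, proteins,
                              scheme = scoring_scheme(),
                              evalue_cutoff = NULL) {
  if (is.character(transcripts)) {
    transcripts <- Biostrings::DNAStringSet(transcripts)
  }
  if (is.character(proteins)) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  stopifnot(length(proteins) > 0,
            !is.null(names(transcripts)), !is.null(names(proteins)))
  n_db <- sum(Biostrings::width(proteins))
  k <- scheme$kmer_length
  index <- if (scheme$min_kmer_hits > 0) build_kmer_index(proteins, k)
           else NULL
  qnames <- names(transcripts)
  qlen <- Biostrings::width(transcripts)
  trans <- frame_translations(transcripts)

  # enumerate candidate (query, frame, protein) triples
  p_qi <- list(); p_fr <- list(); p_pi <- list()
  for (fi in seq_along(FRAME_ORDER)) {
    tr <- trans[[fi]]
    for (qi in seq_along(qnames)) {
      if (nchar(tr[qi]) < 1L) next
      cand <- if (is.null(index)) seq_along(proteins)
              else kmer_candidates(tr[qi], index, k,
                                   scheme$min_kmer_hits,
                                   length(proteins))
      if (!length(cand)) next
      j <- length(p_qi) + 1L
      p_qi[[j]] <- rep.int(qi, length(cand))
      p_fr[[j]] <- rep.int(fi, length(cand))
      p_pi[[j]] <- cand
    }
  }
  if (!length(p_qi)) {
    hits <- empty_hsp_frame()
    return(hits)
  }
  p_qi <- unlist(p_qi); p_fr <- unlist(p_fr); p_pi <- unlist(p_pi)

  chunks <- split(seq_along(p_qi),
                  ceiling(seq_along(p_qi) / 4000L))
  rows <- lapply(chunks, function(idx) {
    align_pairs(p_qi[idx], p_fr[idx], p_pi[idx], trans, proteins,
                qnames, qlen, n_db, scheme)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  hits <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_hsp_frame()
  }
  hits <- sort_hits(hits)
  if (nrow(hits)) {
    capped <- lapply(split(hits, hits$qid), cap_hits, scheme = scheme)
    hits <- do.call(rbind, c(capped, list(make.row.names = FALSE)))
  }
  if (!is.null(evalue_cutoff)) {
    hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  }
  sort_hits(hits)
}

# All six frame translations for a set of transcripts, as a list (one
# element per frame in FRAME_ORDER) of character vectors.
frame_translations <- function(dna) {
  w <- Biostrings::width(dna)
  n <- length(dna)
  rc <- Biostrings::reverseComplement(dna)
  out <- vector("list", length(FRAME_ORDER))
  names(out) <- frame_label(FRAME_ORDER)
  for (fi in seq_along(FRAME_ORDER)) {
    f <- FRAME_ORDER[fi]
    src <- if (f > 0) dna else rc
    off <- abs(f)
    ncod <- pmax(0L, (w - off + 1L) %/% 3L)
    res <- character(n)
    ok <- which(ncod >= 1L)
    if (length(ok)) {
      xs <- Biostrings::subseq(src[ok], start = off,
                               width = 3L * ncod[ok])
      res[ok] <- as.character(
        Biostrings::translate(xs, if.fuzzy.codon = "X",
                              no.init.codon = TRUE))
    }
    names(res) <- names(dna)
    out[[fi]] <- res
  }
  out
}

# Align a batch of (query, frame, protein) candidate pairs elementwise
# and return the HSP rows passing the raw-score floor.
align_pairs <- function(qi, fi, pi, trans, proteins, qnames, qlen, n_db,
                        scheme) {
  subj <- character(length(qi))
  for (f in unique(fi)) {
    sel <- fi == f
    subj[sel] <- trans[[f]][qi[sel]]
  }
  aln <- Biostrings::pairwiseAlignment(
    proteins[pi], Biostrings::AAStringSet(subj), type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  S <- Biostrings::score(aln)
  keep <- which(S >= scheme$min_raw_score)
  if (!length(keep)) return(NULL)
  alnp <- Biostrings::pattern(aln)
  alns <- Biostrings::subject(aln)
  pat <- as.character(alnp)[keep]
  sub <- as.character(alns)[keep]
  sstart <- BiocGenerics::start(alnp)[keep]
  send <- BiocGenerics::end(alnp)[keep]
  qaa_start <- BiocGenerics::start(alns)[keep]
  qaa_end <- BiocGenerics::end(alns)[keep]
  S <- S[keep]
  frame <- FRAME_ORDER[fi[keep]]
  L <- qlen[qi[keep]]
  stats <- alignment_stats(pat, sub)
  qc <- aa_to_nt_range(qaa_start, qaa_end, frame, L)
  data.frame(
    qid = qnames[qi[keep]],
    sid = names(proteins)[pi[keep]],
    pident = stats$pident,
    length = stats$len,
    mismatch = stats$mismatch,
    gapopen = stats$gapopen,
    qstart = qc$start, qend = qc$end,
    sstart = sstart, send = send,
    evalue = raw_to_evalue(S, nchar(subj[keep]), n_db, scheme),
    bitscore = raw_to_bits(S, scheme),
    qframe = frame,
    stringsAsFactors = FALSE
  )
}

# pident / mismatch / gap-open counts from the aligned (gapped) strings.
alignment_stats <- function(pat, sub) {
  n <- length(pat)
  len <- nchar(pat)
  pident <- numeric(n); mismatch <- integer(n); gapopen <- integer(n)
  for (i in seq_len(n)) {
    pc <- strsplit(pat[i], "", fixed = TRUE)[[1]]
    sc <- strsplit(sub[i], "", fixed = TRUE)[[1]]
    gapp <- pc == "-"; gaps <- sc == "-"
    matches <- sum(!gapp & !gaps & pc == sc)
    mismatch[i] <- sum(!gapp & !gaps & pc != sc)
    gapopen[i] <- sum(rle(gapp)$values) + sum(rle(gaps)$values)
    pident[i] <- 100 * matches / len[i]
  }
  list(pident = round(pident, 3), len = len, mismatch = mismatch,
       gapopen = gapopen)
}

# Map aa ranges [p, q] (1-based on the frame translation) back to
# nucleotide coordinates on the input strand (1-based inclusive; start >
# end on the minus strand). Vectorized over p, q, frame, L.
aa_to_nt_range <- function(p, q, frame, L) {
  off <- abs(frame)
  rs <- off + 3L * (p - 1L)
  re <- off + 3L * q - 1L
  plus <- frame > 0
  list(start = ifelse(plus, rs, L - rs + 1L),
       end = ifelse(plus, re, L - re + 1L))
}

# Enforce max_subjects (by best bitscore) and max_hsps_per_pair on the
# canonically sorted hits of a single query.
cap_hits <- function(qhits, scheme) {
  first_rank <- !duplicated(qhits$sid)
  keep_sids <- qhits$sid[first_rank][seq_len(min(scheme$max_subjects,
                                                 sum(first_rank)))]
  qhits <- qhits[qhits$sid %in% keep_sids, , drop = FALSE]
  within_pair <- stats::ave(seq_len(nrow(qhits)), qhits$sid,
                            FUN = seq_along)
  qhits[within_pair <= scheme$max_hsps_per_pair, , drop = FALSE]
}
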