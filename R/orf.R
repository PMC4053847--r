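#' Frame statistics of the best hit's alignments
#'
#' Collects the reading frames reported by all HSPs between a transcript
#' and its single best hit (the highest-bitscore subject). When the
#' transcript contains no frameshift all alignments are expected to
#' report the same frame; disagreement is the frameshift signal.
#'
#' @param hsps HSP data.frame; all rows must share `qid` and `sid`.
#' @return list with `evidence_frames` (sorted integer vector of distinct
#'   frames) and `consistent` (logical: exactly one frame observed).
#' @export
frame_statistics <- function(hsps) {
  if (!nrow(hsps)) {
    stop("frame_statistics requires at least one HSP")
  }
  stopifnot(length(unique(hsps$qid)) == 1L,
            length(unique(hsps$sid)) == 1L)
  frames <- sort(unique(as.integer(hsps$qframe)))
  list(evidence_frames = frames, consistent = length(frames) == 1L)
}

#' Longest open reading frame in one reading frame
#'
#' Translates the requested frame, splits the translation at stop codons
#' and returns the longest stop-free codon run (ties go to the run
#' closest to the 5' end in reading direction). The run does not need to
#' start with ATG: start-codon presence is recorded separately, as is
#' whether the run is terminated by an in-frame stop codon inside the
#' transcript. Coordinates are 0-based half-open on the input strand; for
#' minus frames the translation is read from the reverse complement but
#' the coordinates still refer to the input sequence.
#'
#' @param seq transcript sequence (character or DNAString).
#' @param frame integer in `{+1,+2,+3,-1,-2,-3}`.
#' @return list with `frame`, `orf_start`, `orf_end`, `protein`,
#'   `has_start`, `has_stop`.
#' @export
longest_orf_in_frame <- function(seq, frame) {
  seq <- as.character(seq)
  stopifnot(frame %in% FRAME_ORDER)
  L <- nchar(seq)
  rs <- if (frame > 0) seq else revcomp(seq)
  off <- abs(frame)
  aa <- translate_frame(seq, frame)
  ncod <- nchar(aa)
  if (ncod == 0L) {
    return(list(frame = frame, orf_start = 0L, orf_end = 0L,
                protein = "", has_start = FALSE, has_stop = FALSE))
  }
  codons <- strsplit(aa, "", fixed = TRUE)[[1]]
  stops <- which(codons == "*")
  bounds <- c(0L, stops, ncod + 1L)
  run_start <- bounds[-length(bounds)] + 1L
  run_end <- bounds[-1] - 1L
  run_len <- run_end - run_start + 1L
  best <- which.max(run_len)  # first maximum = 5'-most run
  if (run_len[best] <= 0L) {
    # translation is all stops; report an empty ORF at the frame offset
    pos <- off - 1L
    ost <- if (frame > 0) pos else L - pos
    return(list(frame = frame, orf_start = ost, orf_end = ost,
                protein = "", has_start = FALSE, has_stop = FALSE))
  }
  i1 <- run_start[best]; i2 <- run_end[best]
  rstart <- off - 1L + 3L * (i1 - 1L)        # 0-based on reading strand
  rend <- off - 1L + 3L * i2
  has_stop <- i2 < ncod && codons[i2 + 1L] == "*"
  has_start <- substr(rs, rstart + 1L, rstart + 3L) == "ATG"
  if (frame > 0) {
    orf_start <- rstart; orf_end <- rend
  } else {
    orf_start <- L - rend; orf_end <- L - rstart
  }
  protein <- paste(codons[i1:i2], collapse = "")
  list(frame = frame, orf_start = as.integer(orf_start),
       orf_end = as.integer(orf_end), protein = protein,
       has_start = has_start, has_stop = has_stop)
}

#' Call the ORF of a transcript from best-hit frame statistics
#'
#' When all HSPs against the best hit agree on one reading frame, the
#' longest ORF in that frame is returned. When they disagree the
#' transcript is flagged as a putative frameshift and the longest ORF
#' over all six frames is returned instead (ties resolved in frame order
#' +1, +2, +3, -1, -2, -3). Hitless transcripts also receive the longest
#' ORF over all six frames, with `frame = NA` and no flag, so every
#' transcript is exportable.
#'
#' The returned region is verified on every call: re-translating
#' `seq[orf_start:orf_end]` (reverse-complemented first for minus
#' frames) must reproduce `protein` without internal stops.
#'
#' @param transcript_id transcript identifier.
#' @param seq transcript sequence.
#' @param hsps HSP data.frame restricted to the transcript's best hit,
#'   or `NULL`/empty for hitless transcripts.
#' @return list of class `"orf_call"` with fields `transcript_id`,
#'   `frame` (`NA` for hitless), `orf_start`, `orf_end`, `protein`,
#'   `has_start`, `has_stop`, `frameshift_flagged`, `evidence_frames`.
#' @export
call_orf <- function(transcript_id, seq, hsps = NULL) {
  seq <- as.character(seq)
  if (is.null(hsps) || !nrow(hsps)) {
    orf <- best_orf_all_frames(seq)
    out <- c(list(transcript_id = transcript_id), orf,
             list(frameshift_flagged = FALSE,
                  evidence_frames = integer(0)))
    out$strand <- sign(orf$frame)
    out$frame <- NA_integer_
    return(validate_orf_call(out, seq))
  }
  fs <- frame_statistics(hsps)
  if (fs$consistent) {
    orf <- longest_orf_in_frame(seq, fs$evidence_frames[1])
    flagged <- FALSE
  } else {
    orf <- best_orf_all_frames(seq)
    flagged <- TRUE
  }
  out <- c(list(transcript_id = transcript_id), orf,
           list(frameshift_flagged = flagged,
                evidence_frames = fs$evidence_frames))
  out$strand <- sign(orf$frame)
  validate_orf_call(out, seq)
}

best_orf_all_frames <- function(seq) {
  best <- NULL
  for (f in FRAME_ORDER) {
    o <- longest_orf_in_frame(seq, f)
    if (is.null(best) || nchar(o$protein) > nchar(best$protein)) {
      best <- o
    }
  }
  best
}

validate_orf_call <- function(call, seq) {
  len <- call$orf_end - call$orf_start
  stopifnot(len %% 3L == 0L, !grepl("*", call$protein, fixed = TRUE))
  if (len > 0L) {
    region <- substr(seq, call$orf_start + 1L, call$orf_end)
    if (call$strand < 0) {
      region <- revcomp(region)
    }
    check <- translate_frame(region, 1L)
    if (!identical(check, call$protein)) {
      stop("internal error: ORF region does not translate to protein for ",
           call$transcript_id)
    }
  }
  class(call) <- "orf_call"
  call
}

#' Naive single-indel frameshift correction
#'
#' A desk-scale corrector for transcripts whose best hit aligns in
#' exactly two frames on the same strand, separable into a 5' and a 3'
#' HSP block along the reading direction. It inserts `k` (1 or 2) `N`
#' bases at the midpoint between the two blocks, choosing `k` so the 3'
#' block's frame becomes congruent with the 5' block's. Returns `NULL`
#' when more than two frames are observed, the frames sit on different
#' strands, the blocks overlap, or no `k` in {1, 2} reconciles the
#' frames. On success, re-calling [call_orf()] on the corrected sequence
#' with re-searched hits yields a consistent, unflagged ORF.
#'
#' @param seq transcript sequence.
#' @param hsps HSP data.frame restricted to the best hit, with at least
#'   two distinct frames (i.e. the transcript is frameshift-flagged).
#' @return corrected sequence (character) or `NULL`.
#' @export
correct_frameshift_naive <- function(seq, hsps) {
  seq <- as.character(seq)
  fs <- frame_statistics(hsps)
  if (fs$consistent) {
    stop("correct_frameshift_naive requires a frameshift-flagged ",
         "transcript (>= 2 evidence frames)")
  }
  frames <- fs$evidence_frames
  if (length(frames) != 2L) return(NULL)
  if (sign(frames[1]) != sign(frames[2])) return(NULL)
  minus <- frames[1] < 0
  L <- nchar(seq)
  # normalise to reading-strand coordinates (1-based inclusive)
  if (minus) {
    rstart <- L - pmax(hsps$qstart, hsps$qend) + 1L
    rend <- L - pmin(hsps$qstart, hsps$qend) + 1L
    rframe <- -hsps$qframe
    work <- revcomp(seq)
  } else {
    rstart <- pmin(hsps$qstart, hsps$qend)
    rend <- pmax(hsps$qstart, hsps$qend)
    rframe <- hsps$qframe
    work <- seq
  }
  f <- sort(unique(rframe))
  b1 <- range(c(rstart[rframe == f[1]], rend[rframe == f[1]]))
  b2 <- range(c(rstart[rframe == f[2]], rend[rframe == f[2]]))
  if (b1[1] <= b2[1]) { b5 <- b1; b3 <- b2; f5 <- f[1]; f3 <- f[2] }
  else { b5 <- b2; b3 <- b1; f5 <- f[2]; f3 <- f[1] }
  if (b3[1] <= b5[2]) return(NULL)  # blocks overlap
  kk <- ((f5 - f3) %% 3L)
  if (!kk %in% c(1L, 2L)) return(NULL)
  mid <- (b5[2] + b3[1]) %/% 2L   # insert after this reading-strand pos
  corrected <- paste0(substr(work, 1L, mid),
                      strrep("N", kk),
                      substr(work, mid + 1L, nchar(work)))
  if (minus) revcomp(corrected) else corrected
}

#' Tabulate ORF calls for export
#'
#' @param calls list of `orf_call` objects.
#' @return data.frame with columns `transcript_id`, `frame`, `orf_start`,
#'   `orf_end`, `orf_length_nt`, `has_start`, `has_stop`,
#'   `frameshift_flagged`, `evidence_frames` (comma-separated).
#' @export
orf_calls_table <- function(calls) {
  rows <- lapply(calls, function(cl) {
    data.frame(transcript_id = cl$transcript_id,
               frame = if (is.na(cl$frame)) NA_integer_
                       else as.integer(cl$frame),
               orf_start = cl$orf_start, orf_end = cl$orf_end,
               orf_length_nt = cl$orf_end - cl$orf_start,
               has_start = cl$has_start, has_stop = cl$has_stop,
               frameshift_flagged = cl$frameshift_flagged,
               evidence_frames = paste(cl$evidence_frames,
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
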