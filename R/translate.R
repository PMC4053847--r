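FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1..+3` translate the sequence starting at offsets 0..2; frames
#' `-1..-3` translate the reverse complement the same way. The standard
#' genetic code is used, stop codons are rendered `*`, and any codon
#' containing an ambiguous base becomes `X`. Trailing bases that do not
#' fill a codon are ignored; sequences shorter than three bases give empty
#' translations.
#'
#' @param seq a DNA sequence (character or [Biostrings::DNAString]).
#' @return named character vector of six amino-acid strings, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @export
six_frame_translate <- function(seq) {
  seq <- as.character(seq)
  out <- vapply(FRAME_ORDER, function(f) translate_frame(seq, f),
                character(1))
  names(out) <- frame_label(FRAME_ORDER)
  out
}

frame_label <- function(frame) {
  ifelse(frame > 0, paste0("+", frame), as.character(frame))
}

# codon -> amino acid map (standard code, stops as '*'); codons with
# ambiguous bases are absent and translate to X
codon_map <- function() {
  if (is.null(.transannot_env$CODON_MAP)) {
    gc <- Biostrings::GENETIC_CODE
    .transannot_env$CODON_MAP <- stats::setNames(unname(gc), names(gc))
  }
  .transannot_env$CODON_MAP
}

# Translation of one reading frame; returns "" when no complete codon
# fits. Plain codon-table lookup: translating single sequences through
# heavier machinery dominates ORF-calling time at scale.
translate_frame <- function(seq, frame) {
  stopifnot(frame %in% FRAME_ORDER)
  s <- if (frame > 0) seq else revcomp(seq)
  off <- abs(frame)
  n <- nchar(s)
  ncod <- (n - off + 1L) %/% 3L
  if (is.na(ncod) || ncod < 1L) {
    return("")
  }
  starts <- seq.int(off, by = 3L, length.out = ncod)
  aa <- codon_map()[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#' @param seq character DNA sequence (`ACGTN`).
#' @return character reverse complement.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}
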