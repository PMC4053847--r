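#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased, `U` is mapped to `T`, and IUPAC ambiguity
#' codes other than `ACGT` are collapsed to `N` so that every transcript
#' lives in a single canonical alphabet. Record order is preserved;
#' duplicate or empty records are hard errors.
#'
#' @param path path to a DNA FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_transcript_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  ids <- fasta_ids(names(raw))
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs <- gsub("[^ACGT]", "N", seqs)
  check_fasta_records(ids, seqs, path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read reference protein sequences from FASTA
#'
#' @param path path to an amino-acid FASTA file.
#' @return a named [Biostrings::AAStringSet]; sequences are uppercased and
#'   letters outside the 20 standard amino acids plus `X*` become `X`.
#' @export
read_protein_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  ids <- fasta_ids(names(raw))
  seqs <- toupper(as.character(raw))
  seqs <- gsub("[^ACDEFGHIKLMNPQRSTVWY*]", "X", seqs)
  check_fasta_records(ids, seqs, path)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

fasta_ids <- function(headers) {
  sub("\\s.*$", "", headers)
}

check_fasta_records <- function(ids, seqs, path) {
  if (any(!nzchar(ids))) {
    stop("empty record id in ", path)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence record(s) in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param seqs a named `XStringSet` (or named character vector).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

hsp_columns <- c("qid", "sid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                 "qframe")

#' Read a tabular translated-search hit file
#'
#' Accepts the 12-column tab-separated format used by BLAST-style tools
#' (`qid sid pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`) with an optional 13th `qframe` column. When `qframe` is
#' absent it is derived from the transcript coordinates: plus strand when
#' `qstart < qend` with frame `((qstart-1) mod 3) + 1`; minus strand when
#' `qstart > qend` with frame `-(((L - qstart) mod 3) + 1)` where `L` is
#' the transcript length and `qstart` the larger coordinate. An explicit
#' `qframe` column always wins over the derivation.
#'
#' Hits with an e-value above `evalue_cutoff` are dropped at read time.
#'
#' @param path path to the tab-separated hit file (no header).
#' @param transcript_lengths named integer vector of transcript lengths;
#'   required when the `qframe` column must be derived.
#' @param evalue_cutoff drop hits with larger e-value; `NULL` keeps all.
#' @return a data.frame of HSPs with columns
#'   `r paste(hsp_columns, collapse = ", ")`, sorted canonically
#'   (`qid`, then bitscore descending, e-value ascending, `sid`).
#' @export
read_hits_table <- function(path, transcript_lengths = NULL,
                            evalue_cutoff = NULL) {
  stopifnot(file.exists(path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0) {
    hits <- empty_hsp_frame()
    return(hits)
  }
  if (length(unique(nf)) != 1 || !(nf[1] %in% c(12L, 13L))) {
    stop("hit table must have 12 or 13 tab-separated columns throughout: ",
         path)
  }
  x <- tryCatch(
    utils::read.table(path, sep = "\t", quote = "",
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character",
                                     rep("numeric", nf[1] - 2L))),
    error = function(e) {
      stop("non-numeric value in a numeric column of ", path, ": ",
           conditionMessage(e))
    })
  names(x) <- hsp_columns[seq_len(nf[1])]
  num_cols <- setdiff(names(x), c("qid", "sid"))
  if (any(vapply(x[num_cols], function(v) any(is.na(v)), logical(1)))) {
    stop("non-numeric value in a numeric column of ", path)
  }
  if (nf[1] == 12L) {
    x$qframe <- derive_qframe(x$qid, x$qstart, x$qend, transcript_lengths)
  } else {
    x$qframe <- as.integer(x$qframe)
  }
  if (!all(x$qframe %in% c(-3:-1, 1:3))) {
    stop("qframe values must lie in {-3..-1, 1..3}")
  }
  if (!is.null(evalue_cutoff)) {
    x <- x[x$evalue <= evalue_cutoff, , drop = FALSE]
  }
  sort_hits(x)
}

# Frame of the transcript coordinates of an HSP when no explicit frame
# column is available. qstart/qend are 1-based inclusive as reported by
# tabular search output; qstart > qend signals the minus strand.
derive_qframe <- function(qid, qstart, qend, transcript_lengths) {
  plus <- qstart <= qend
  frame <- integer(length(qid))
  frame[plus] <- ((qstart[plus] - 1L) %% 3L) + 1L
  if (any(!plus)) {
    if (is.null(transcript_lengths)) {
      stop("transcript_lengths required to derive minus-strand frames")
    }
    L <- transcript_lengths[qid[!plus]]
    if (any(is.na(L))) {
      stop("unknown transcript id(s) in hit table: ",
           paste(unique(qid[!plus][is.na(L)]), collapse = ", "))
    }
    frame[!plus] <- -((((L - qstart[!plus]) %% 3L)) + 1L)
  }
  as.integer(frame)
}

sort_hits <- function(hits) {
  ord <- order(hits$qid, -hits$bitscore, hits$evalue, hits$sid,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hsp_frame <- function() {
  out <- data.frame(qid = character(), sid = character(),
                    pident = numeric(), length = numeric(),
                    mismatch = numeric(), gapopen = numeric(),
                    qstart = numeric(), qend = numeric(),
                    sstart = numeric(), send = numeric(),
                    evalue = numeric(), bitscore = numeric(),
                    qframe = integer(), stringsAsFactors = FALSE)
  out
}

#' Write hits in the 13-column tabular dialect
#'
#' @param hits HSP data.frame as returned by [read_hits_table()] or
#'   [translated_search()].
#' @param path output path.
#' @export
write_hits_table <- function(hits, path) {
  utils::write.table(hits[, hsp_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_strict <- function(path, required_cols) {
  stopifnot(file.exists(path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    stop("ragged rows in ", path)
  }
  x <- utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(required_cols, names(x))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  x
}

#' Read a gene-family membership table
#'
#' @param path TSV with header columns `gene_id`, `species`, `family_id`,
#'   `cds_length_nt`.
#' @return data.frame with those columns (`cds_length_nt` integer).
#' @export
read_family_table <- function(path) {
  x <- read_tsv_strict(path, c("gene_id", "species", "family_id",
                               "cds_length_nt"))
  x$cds_length_nt <- as.integer(x$cds_length_nt)
  if (any(is.na(x$cds_length_nt)) || any(x$cds_length_nt < 3L)) {
    stop("cds_length_nt must be integer >= 3 in ", path)
  }
  x[, c("gene_id", "species", "family_id", "cds_length_nt")]
}

#' Write a gene-family membership table
#' @param families data.frame as from [read_family_table()].
#' @param path output path.
#' @export
write_family_table <- function(families, path) {
  utils::write.table(
    families[, c("gene_id", "species", "family_id", "cds_length_nt")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a functional-annotation table
#'
#' @param path TSV with header columns `gene_id`, `term_id`, `term_type`
#'   where `term_type` is `GO` or `domain`.
#' @return data.frame with those columns.
#' @export
read_annotation_table <- function(path) {
  x <- read_tsv_strict(path, c("gene_id", "term_id", "term_type"))
  if (!all(x$term_type %in% c("GO", "domain"))) {
    stop("term_type must be 'GO' or 'domain' in ", path)
  }
  x[, c("gene_id", "term_id", "term_type")]
}

#' Write a functional-annotation table
#' @param annotations data.frame as from [read_annotation_table()].
#' @param path output path.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations[, c("gene_id", "term_id", "term_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript subset labels
#'
#' @param path TSV with header columns `transcript_id`, `label`.
#' @return data.frame with those columns; a transcript may carry several
#'   labels (one row each).
#' @export
read_labels <- function(path) {
  x <- read_tsv_strict(path, c("transcript_id", "label"))
  if (any(grepl("\t", x$label, fixed = TRUE))) {
    stop("labels must not contain tab characters")
  }
  x[, c("transcript_id", "label")]
}

#' Write transcript subset labels
#' @param labels data.frame as from [read_labels()].
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("transcript_id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# family table -> named vector gene_id -> family_id
family_lookup <- function(families) {
  stats::setNames(families$family_id, families$gene_id)
}
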