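#' Read an aligned amino-acid FASTA file
#'
#' Rows must all have the same width; `.` gap characters are normalised
#' to `-` and sequences are uppercased.
#'
#' @param path aligned FASTA path.
#' @return named [Biostrings::AAStringSet] of equal-width rows.
#' @export
read_msa <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  ids <- fasta_ids(names(raw))
  seqs <- toupper(as.character(raw))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (any(duplicated(ids))) {
    stop("duplicate alignment row id(s) in ", path)
  }
  as_msa(stats::setNames(seqs, ids))
}

#' Write an aligned amino-acid FASTA file
#' @param msa named AAStringSet or named character vector.
#' @param path output path.
#' @export
write_msa <- function(msa, path) {
  write_fasta(msa, path)
}

as_msa <- function(x) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  w <- Biostrings::width(x)
  if (length(x) && length(unique(w)) != 1L) {
    stop("alignment rows must all have the same width")
  }
  if (is.null(names(x)) || any(duplicated(names(x)))) {
    stop("alignment rows must carry unique ids")
  }
  x
}

msa_matrix <- function(msa) {
  if (!length(msa)) return(matrix(character(0), nrow = 0, ncol = 0))
  do.call(rbind, strsplit(as.character(msa), "", fixed = TRUE))
}

#' Remove gap-rich alignment columns
#'
#' Stringent editing removes every column whose gap fraction strictly
#' exceeds `stringent_gap_threshold` (default 10%), together with
#' `flank_width` columns on each side of every such column. Relaxed
#' editing removes columns whose gap fraction is at least
#' `relaxed_gap_threshold` (default 25%), with no flanking removal.
#' Row order is preserved and retained residues are never altered.
#'
#' @param msa named AAStringSet (or named character vector) of
#'   equal-width aligned rows.
#' @param mode `"stringent"` or `"relaxed"`.
#' @param config a [pipeline_config()].
#' @return list with `msa` (edited alignment) and `removed_columns`
#'   (0-based ascending integer indices of removed columns, matching the
#'   sidecar TSV convention).
#' @export
edit_alignment <- function(msa, mode = c("stringent", "relaxed"),
                           config = pipeline_config()) {
  mode <- match.arg(mode)
  msa <- as_msa(msa)
  stopifnot(length(msa) > 0)
  mat <- msa_matrix(msa)
  ncol_aln <- ncol(mat)
  gap_frac <- colMeans(mat == "-")
  if (mode == "stringent") {
    marked <- which(gap_frac > config$stringent_gap_threshold)
    if (length(marked) && config$flank_width > 0L) {
      flanks <- unlist(lapply(marked, function(j) {
        seq.int(j - config$flank_width, j + config$flank_width)
      }))
      marked <- sort(unique(pmax(1L, pmin(ncol_aln, flanks))))
    }
  } else {
    marked <- which(gap_frac >= config$relaxed_gap_threshold)
  }
  keep <- setdiff(seq_len(ncol_aln), marked)
  if (!length(keep)) {
    warning("alignment editing removed every column")
    edited <- Biostrings::AAStringSet(
      stats::setNames(rep("", length(msa)), names(msa)))
  } else {
    rows <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
    edited <- Biostrings::AAStringSet(stats::setNames(rows, names(msa)))
  }
  list(msa = edited,
       removed_columns = as.integer(sort(marked)) - 1L)
}

#' Drop alignment rows labelled Partial
#'
#' Rows whose id carries the meta-annotation label `"Partial"` are
#' removed before tree building; rows without a meta-annotation entry
#' (reference proteins) are always kept. Columns are untouched.
#'
#' @param msa named AAStringSet or named character vector.
#' @param meta data.frame with columns `transcript_id`, `label`.
#' @return the filtered alignment.
#' @export
drop_partial_rows <- function(msa, meta) {
  msa <- as_msa(msa)
  partial <- meta$transcript_id[meta$label == "Partial"]
  msa[!(names(msa) %in% partial)]
}

#' Drop alignment rows belonging to excluded species
#'
#' @param msa named AAStringSet or named character vector.
#' @param species_excluded character vector of species to drop.
#' @param gene_species named character vector `gene_id -> species`; rows
#'   whose id is absent from the map are kept.
#' @return the filtered alignment (with a warning when empty).
#' @export
drop_species_rows <- function(msa, species_excluded, gene_species) {
  msa <- as_msa(msa)
  sp <- gene_species[names(msa)]
  drop <- !is.na(sp) & sp %in% species_excluded
  out <- msa[!drop]
  if (!length(out)) {
    warning("species exclusion removed every alignment row")
  }
  out
}
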