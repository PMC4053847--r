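#' Simulation configuration
#'
#' Parameters of the synthetic reference + transcript generator. Gene
#' families are grown from a random ancestral protein by per-member
#' BLOSUM62-weighted substitution; coding sequences are back-translated
#' with uniform synonymous codon choice; transcripts are family-member
#' CDSs wrapped in random UTRs on a random strand, optionally carrying
#' exactly one 1-nt insertion or deletion at a uniform position in the
#' CDS (the frameshift benchmark design) or truncated to a contiguous
#' fraction (for Partial-label tests). Everything is deterministic given
#' `rng_seed`.
#'
#' @param rng_seed integer seed.
#' @param n_families number of gene families.
#' @param species character vector of species names.
#' @param family_size_range integer range of members per family.
#' @param root_protein_length_range amino-acid length range of the
#'   ancestral protein.
#' @param substitution_rate per-site substitution probability between
#'   the ancestor and each member.
#' @param n_clean_transcripts,n_indel_transcripts,n_truncated_transcripts
#'   transcript counts per class.
#' @param truncation_fraction contiguous fraction of the CDS kept in
#'   truncated transcripts.
#' @param utr_length_range range of random UTR lengths added on each
#'   side (nt).
#' @param term_pool_size total number of distinct functional terms
#'   (half GO, half protein domains).
#' @param terms_per_family integer range of consensus terms per family.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(rng_seed = 42L,
                       n_families = 50L,
                       species = paste0("sp", 1:4),
                       family_size_range = c(4L, 12L),
                       root_protein_length_range = c(120L, 500L),
                       substitution_rate = 0.15,
                       n_clean_transcripts = 200L,
                       n_indel_transcripts = 200L,
                       n_truncated_transcripts = 50L,
                       truncation_fraction = 0.4,
                       utr_length_range = c(0L, 60L),
                       term_pool_size = 100L,
                       terms_per_family = c(1L, 4L)) {
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_families = as.integer(n_families),
              species = as.character(species),
              family_size_range = as.integer(family_size_range),
              root_protein_length_range =
                as.integer(root_protein_length_range),
              substitution_rate = as.numeric(substitution_rate),
              n_clean_transcripts = as.integer(n_clean_transcripts),
              n_indel_transcripts = as.integer(n_indel_transcripts),
              n_truncated_transcripts =
                as.integer(n_truncated_transcripts),
              truncation_fraction = as.numeric(truncation_fraction),
              utr_length_range = as.integer(utr_length_range),
              term_pool_size = as.integer(term_pool_size),
              terms_per_family = as.integer(terms_per_family))
  stopifnot(cfg$n_families >= 1, length(cfg$species) >= 1,
            all(cfg$family_size_range >= 1),
            all(cfg$root_protein_length_range >= 30),
            cfg$substitution_rate >= 0, cfg$substitution_rate < 1,
            cfg$n_clean_transcripts >= 0, cfg$n_indel_transcripts >= 0,
            cfg$n_truncated_transcripts >= 0,
            cfg$truncation_fraction > 0, cfg$truncation_fraction < 1,
            all(cfg$utr_length_range >= 0),
            cfg$term_pool_size >= 2,
            all(cfg$terms_per_family >= 1))
  class(cfg) <- "sim_config"
  cfg
}

# uniform draw from an integer range that is safe when lo == hi
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# substitution proposal matrix: P(replacement | original), BLOSUM62-
# weighted over the 19 alternatives so simulated families stay alignable
substitution_probs <- function() {
  if (is.null(.transannot_env$SUBPROB)) {
    B <- blosum62()[AA20, AA20]
    W <- exp(B / 2)
    diag(W) <- 0
    .transannot_env$SUBPROB <- sweep(W, 1, rowSums(W), "/")
  }
  .transannot_env$SUBPROB
}

# aa -> codons (stops excluded)
codon_table <- function() {
  if (is.null(.transannot_env$CODONS)) {
    gc <- Biostrings::GENETIC_CODE
    .transannot_env$CODONS <- split(names(gc), unname(gc))
  }
  .transannot_env$CODONS
}

mutate_protein <- function(aa_chars, rate) {
  n <- length(aa_chars)
  hit <- which(stats::runif(n) < rate)
  if (length(hit)) {
    probs <- substitution_probs()
    for (i in hit) {
      aa_chars[i] <- sample(AA20, 1L, prob = probs[aa_chars[i], ])
    }
  }
  # C-terminal jitter so family CDS lengths are not all identical
  delta <- sample(-2:2, 1L)
  if (delta < 0 && n + delta > 30L) {
    aa_chars <- aa_chars[seq_len(n + delta)]
  } else if (delta > 0) {
    aa_chars <- c(aa_chars, sample(AA20, delta, replace = TRUE))
  }
  aa_chars
}

back_translate <- function(aa_chars) {
  ct <- codon_table()
  codons <- vapply(aa_chars, function(a) {
    cs <- ct[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Generate a synthetic reference proteome with families and annotations
#'
#' Each family descends from a random ancestral protein (first residue
#' M); members receive BLOSUM62-weighted substitutions at
#' `substitution_rate` per site plus a little C-terminal length jitter,
#' and are back-translated into a CDS (stop codon included in
#' `cds_length_nt`). Family consensus terms are assigned to a random
#' subset of at least half of the members; families with three or more
#' members additionally get one term carried by a single member, so
#' consensus transfer is exercised in both directions.
#'
#' @param cfg a [sim_config()].
#' @return list with `proteins` (AAStringSet), `cds` (DNAStringSet),
#'   `families` (data.frame `gene_id`, `species`, `family_id`,
#'   `cds_length_nt`) and `annotations` (data.frame `gene_id`,
#'   `term_id`, `term_type`).
#' @export
generate_reference <- function(cfg = sim_config()) {
  with_seed(cfg$rng_seed, generate_reference_impl(cfg))
}

generate_reference_impl <- function(cfg) {
  n_go <- cfg$term_pool_size %/% 2L
  pool <- data.frame(
    term_id = c(sprintf("GO:%07d", seq_len(n_go)),
                sprintf("IPR%06d", seq_len(cfg$term_pool_size - n_go))),
    term_type = rep(c("GO", "domain"),
                    c(n_go, cfg$term_pool_size - n_go)),
    stringsAsFactors = FALSE)
  proteins <- character(0); cds <- character(0)
  fam_rows <- list(); ann_rows <- list()
  gene_counter <- 0L
  for (fi in seq_len(cfg$n_families)) {
    fam_id <- sprintf("F%04d", fi)
    size <- sample_range(cfg$family_size_range[1],
                         cfg$family_size_range[2])
    root_len <- sample_range(cfg$root_protein_length_range[1],
                             cfg$root_protein_length_range[2])
    root <- c("M", sample(AA20, root_len - 1L, replace = TRUE))
    sp <- sample(cfg$species, size, replace = TRUE)
    gene_ids <- sprintf("g%05d", gene_counter + seq_len(size))
    gene_counter <- gene_counter + size
    for (mi in seq_len(size)) {
      member <- mutate_protein(root, cfg$substitution_rate)
      member[1] <- "M"
      prot <- paste(member, collapse = "")
      this_cds <- back_translate(member)
      proteins[gene_ids[mi]] <- prot
      cds[gene_ids[mi]] <- this_cds
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        gene_id = gene_ids[mi], species = sp[mi], family_id = fam_id,
        cds_length_nt = nchar(this_cds), stringsAsFactors = FALSE)
    }
    n_terms <- sample_range(cfg$terms_per_family[1],
                            cfg$terms_per_family[2])
    term_idx <- sample.int(nrow(pool), n_terms)
    for (ti in term_idx) {
      n_carriers <- sample_range(as.integer(ceiling(size / 2)), size)
      carriers <- sample(gene_ids, n_carriers)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = carriers, term_id = pool$term_id[ti],
        term_type = pool$term_type[ti], stringsAsFactors = FALSE)
    }
    if (size >= 3L) {
      rare <- sample.int(nrow(pool), 1L)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = sample(gene_ids, 1L), term_id = pool$term_id[rare],
        term_type = pool$term_type[rare], stringsAsFactors = FALSE)
    }
  }
  families <- do.call(rbind, c(fam_rows, list(make.row.names = FALSE)))
  annotations <- unique(
    do.call(rbind, c(ann_rows, list(make.row.names = FALSE))))
  rownames(annotations) <- NULL
  list(proteins = Biostrings::AAStringSet(proteins),
       cds = Biostrings::DNAStringSet(cds),
       families = families,
       annotations = annotations)
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic transcripts with ground truth
#'
#' Clean transcripts are the CDS of a sampled family member flanked by
#' random UTRs on a random strand. Indel transcripts additionally carry
#' exactly one 1-nt insertion or deletion at a uniform position within
#' the CDS. Truncated transcripts keep a contiguous
#' `truncation_fraction` of the CDS.
#'
#' @param reference output of [generate_reference()].
#' @param cfg the same [sim_config()].
#' @return list with `transcripts` (named DNAStringSet) and `truth`
#'   (data.frame `transcript_id`, `gene_id`, `family_id`, `strand`,
#'   `class`, `indel_pos`, `indel_type`, `rel_pos`).
#' @export
generate_transcripts <- function(reference, cfg = sim_config()) {
  with_seed(cfg$rng_seed + 1L, generate_transcripts_impl(reference, cfg))
}

generate_transcripts_impl <- function(reference, cfg) {
  cds <- as.character(reference$cds)
  fam_of <- family_lookup(reference$families)
  classes <- rep(c("clean", "indel", "truncated"),
                 c(cfg$n_clean_transcripts, cfg$n_indel_transcripts,
                   cfg$n_truncated_transcripts))
  n <- length(classes)
  seqs <- character(n)
  truth <- data.frame(transcript_id = sprintf("t%05d", seq_len(n)),
                      gene_id = NA_character_, family_id = NA_character_,
                      strand = NA_character_, class = classes,
                      indel_pos = NA_integer_, indel_type = NA_character_,
                      rel_pos = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    gene <- sample(names(cds), 1L)
    body <- cds[[gene]]
    cls <- classes[i]
    if (cls == "indel") {
      len <- nchar(body)
      pos <- sample.int(len, 1L)
      type <- sample(c("ins", "del"), 1L)
      if (type == "del") {
        body <- paste0(substr(body, 1L, pos - 1L),
                       substr(body, pos + 1L, len))
      } else {
        body <- paste0(substr(body, 1L, pos),
                       random_dna(1L),
                       substr(body, pos + 1L, len))
      }
      truth$indel_pos[i] <- pos
      truth$indel_type[i] <- type
      truth$rel_pos[i] <- pos / len
    } else if (cls == "truncated") {
      len <- nchar(body)
      keep <- max(30L, floor(cfg$truncation_fraction * len))
      start <- sample.int(len - keep + 1L, 1L)
      body <- substr(body, start, start + keep - 1L)
    }
    if (cls == "truncated") {
      # assembly fragments: no UTRs, just a window of the CDS
      tx <- body
    } else {
      utr5 <- random_dna(sample_range(cfg$utr_length_range[1],
                                      cfg$utr_length_range[2]))
      utr3 <- random_dna(sample_range(cfg$utr_length_range[1],
                                      cfg$utr_length_range[2]))
      tx <- paste0(utr5, body, utr3)
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") tx <- revcomp(tx)
    seqs[i] <- tx
    truth$gene_id[i] <- gene
    truth$family_id[i] <- unname(fam_of[gene])
    truth$strand[i] <- strand
  }
  transcripts <- Biostrings::DNAStringSet(
    stats::setNames(seqs, truth$transcript_id))
  list(transcripts = transcripts, truth = truth)
}

#' Write a simulated data set to disk
#'
#' Emits exactly the formats the readers consume: reference protein
#' FASTA, family and annotation TSVs, transcript FASTA and the truth
#' table.
#'
#' @param reference output of [generate_reference()].
#' @param transcripts output of [generate_transcripts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(reference, transcripts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(reference$proteins, file.path(dir, "reference_proteins.fasta"))
  write_family_table(reference$families, file.path(dir, "families.tsv"))
  write_annotation_table(reference$annotations,
                         file.path(dir, "gene_annotations.tsv"))
  write_fasta(transcripts$transcripts, file.path(dir, "transcripts.fasta"))
  utils::write.table(transcripts$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score a frameshift benchmark run against the ground truth
#'
#' @param orf_calls data.frame from [orf_calls_table()].
#' @param truth truth table from [generate_transcripts()].
#' @param assignments optional data.frame from [assign_families()];
#'   adds family-assignment accuracy.
#' @param corrections optional data.frame with columns `transcript_id`,
#'   `corrected` (logical) for flagged indel transcripts; adds the naive
#'   correction success rate.
#' @return list with `sensitivity` (flagged fraction of indel
#'   transcripts; `NA` when there are none), `fpr` (flagged fraction of
#'   clean transcripts), `miss_by_bin` (indel miss rate in three bins of
#'   distance to the nearest CDS end: edge, mid, center),
#'   `assignment_accuracy` and `correction_success` when inputs allow.
#' @export
score_benchmark <- function(orf_calls, truth, assignments = NULL,
                            corrections = NULL) {
  if (!all(truth$transcript_id %in% orf_calls$transcript_id)) {
    stop("ORF calls missing for some transcripts in the truth table")
  }
  m <- merge(truth, orf_calls, by = "transcript_id", sort = TRUE)
  indel <- m[m$class == "indel", , drop = FALSE]
  clean <- m[m$class == "clean", , drop = FALSE]
  sensitivity <- if (nrow(indel)) mean(indel$frameshift_flagged)
                 else NA_real_
  fpr <- if (nrow(clean)) mean(clean$frameshift_flagged) else NA_real_
  miss_by_bin <- rep(NA_real_, 3)
  names(miss_by_bin) <- c("edge", "mid", "center")
  if (nrow(indel)) {
    d <- pmin(indel$rel_pos, 1 - indel$rel_pos)
    bin <- cut(d, breaks = c(-Inf, 1 / 6, 1 / 3, 0.5),
               labels = c("edge", "mid", "center"))
    miss <- tapply(!indel$frameshift_flagged, bin, mean)
    miss_by_bin[names(miss)] <- miss
  }
  out <- list(sensitivity = sensitivity, fpr = fpr,
              miss_by_bin = miss_by_bin)
  if (!is.null(assignments)) {
    a <- merge(truth, assignments, by = "transcript_id",
               suffixes = c(".true", ".called"))
    ok <- !is.na(a$family_id.called) &
      a$family_id.called == a$family_id.true
    out$assignment_accuracy <- mean(ok)
  }
  if (!is.null(corrections) && nrow(corrections)) {
    out$correction_success <- mean(corrections$corrected)
  }
  out
}
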