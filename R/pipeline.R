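#' Run the full annotation pipeline
#'
#' Executes the non-interactive processing chain on a set of assembled
#' transcripts: translated similarity search (built-in, or skipped when
#' precomputed hits are supplied), gene-family assignment, frame-
#' statistics ORF calling with frameshift flagging, completeness
#' meta-annotation, consensus/best-hit functional transfer and, when
#' subset labels are given, hypergeometric enrichment. All tabular and
#' FASTA outputs plus a JSON run manifest are written to `out_dir`;
#' given identical inputs, seed and configuration the outputs are
#' byte-identical across runs.
#'
#' @param transcripts named DNAStringSet, named character vector, or
#'   path to a transcript FASTA file.
#' @param proteins named AAStringSet, named character vector, or path
#'   to a reference protein FASTA file.
#' @param families family table data.frame or TSV path
#'   (see [read_family_table()]).
#' @param gene_annotations annotation table data.frame or TSV path
#'   (see [read_annotation_table()]); `NULL` skips functional transfer.
#' @param labels label data.frame or TSV path; `NULL` skips enrichment.
#' @param hits precomputed HSP data.frame or tabular hit file path; when
#'   `NULL` the built-in [translated_search()] is run.
#' @param config a [pipeline_config()].
#' @param scheme a [scoring_scheme()] for the built-in search.
#' @param out_dir output directory, created if needed.
#' @return (invisibly) a list with all intermediate tables: `hits`,
#'   `assignments`, `orf_calls` (list of `orf_call`), `orf_table`,
#'   `meta`, `transferred`, `enrichment` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(transcripts, proteins, families,
                         gene_annotations = NULL, labels = NULL,
                         hits = NULL,
                         config = pipeline_config(),
                         scheme = scoring_scheme(),
                         out_dir) {
  input_files <- character(0)
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    input_files["transcripts"] <- transcripts
    transcripts <- read_transcript_fasta(transcripts)
  } else if (is.character(transcripts)) {
    transcripts <- Biostrings::DNAStringSet(transcripts)
  }
  if (is.character(proteins) && length(proteins) == 1 &&
      file.exists(proteins)) {
    input_files["proteins"] <- proteins
    proteins <- read_protein_fasta(proteins)
  } else if (is.character(proteins)) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  if (is.character(families)) {
    input_files["families"] <- families
    families <- read_family_table(families)
  }
  if (is.null(families)) {
    stop("validation error: a family table is required (gene-family ",
         "assignment and consensus transfer depend on it)")
  }
  if (is.character(gene_annotations)) {
    input_files["gene_annotations"] <- gene_annotations
    gene_annotations <- read_annotation_table(gene_annotations)
  }
  if (is.character(labels)) {
    input_files["labels"] <- labels
    labels <- read_labels(labels)
  }
  if (is.character(hits)) {
    input_files["hits"] <- hits
    hits <- read_hits_table(hits,
                            transcript_lengths = stats::setNames(
                              Biostrings::width(transcripts),
                              names(transcripts)),
                            evalue_cutoff = config$evalue_cutoff)
  }
  if (is.null(hits)) {
    hits <- translated_search(transcripts, proteins, scheme,
                              evalue_cutoff = config$evalue_cutoff)
  }

  assignments <- assign_families(
    hits, families, method = config$assignment_method,
    k = config$topk_majority, transcript_ids = names(transcripts))

  orf_calls <- lapply(names(transcripts), function(tid) {
    call_orf(tid, as.character(transcripts[[tid]]),
             best_hit_hsps(hits, tid))
  })
  names(orf_calls) <- names(transcripts)
  orf_table <- orf_calls_table(orf_calls)

  fam_sizes <- table(families$family_id)
  meta_rows <- lapply(names(transcripts), function(tid) {
    fam <- assignments$family_id[assignments$transcript_id == tid]
    lens <- if (length(fam) && !is.na(fam)) {
      families$cds_length_nt[families$family_id == fam]
    } else NULL
    oc <- orf_calls[[tid]]
    ma <- meta_annotate(oc$orf_end - oc$orf_start, lens,
                        oc$has_start, oc$has_stop, config)
    data.frame(transcript_id = tid, label = ma$label,
               trimmed_mean = ma$trimmed_mean,
               trimmed_sd = ma$trimmed_sd, threshold = ma$threshold,
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, c(meta_rows, list(make.row.names = FALSE)))

  transferred <- NULL
  if (!is.null(gene_annotations)) {
    tr_rows <- lapply(names(transcripts), function(tid) {
      arow <- assignments[assignments$transcript_id == tid, ]
      fam <- arow$family_id[1]
      fam_terms <- NULL; fam_size <- 0L
      if (!is.na(fam)) {
        members <- families$gene_id[families$family_id == fam]
        fam_size <- length(members)
        fam_terms <- merge(
          gene_annotations[gene_annotations$gene_id %in% members, ],
          data.frame(gene_id = members), by = "gene_id")
      }
      bh <- arow$best_hit_id[1]
      bh_terms <- if (!is.na(bh)) {
        gene_annotations[gene_annotations$gene_id == bh,
                         c("term_id", "term_type")]
      } else NULL
      tt <- transfer_annotation(fam_terms, fam_size, bh_terms,
                                source = config$annotation_source,
                                config = config)
      if (!nrow(tt)) return(NULL)
      data.frame(transcript_id = tid, tt, stringsAsFactors = FALSE)
    })
    tr_rows <- tr_rows[!vapply(tr_rows, is.null, logical(1))]
    transferred <- if (length(tr_rows)) {
      do.call(rbind, c(tr_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(transcript_id = character(), term_id = character(),
                 term_type = character(), source = character(),
                 stringsAsFactors = FALSE)
    }
  }

  enrichment <- NULL
  if (!is.null(labels) && !is.null(transferred)) {
    enrichment <- enrich_subsets(labels, transferred,
                                 names(transcripts), config)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_hits_table(hits, file.path(out_dir, "hits.tsv"))
  write_table_out(assignments, file.path(out_dir, "assignments.tsv"))
  write_table_out(orf_table, file.path(out_dir, "orf_calls.tsv"))
  write_table_out(meta, file.path(out_dir, "meta_annotation.tsv"))
  write_orf_fastas(orf_calls, transcripts, out_dir)
  if (!is.null(transferred)) {
    write_table_out(transferred,
                    file.path(out_dir, "annotations_transferred.tsv"))
  }
  if (!is.null(enrichment)) {
    write_table_out(enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  counts <- list(transcripts = length(transcripts),
                 proteins = length(proteins),
                 hsps = nrow(hits),
                 assigned = sum(!is.na(assignments$family_id)),
                 frameshift_flagged = sum(orf_table$frameshift_flagged),
                 transferred_terms = if (is.null(transferred)) 0L
                                     else nrow(transferred),
                 enrichment_tests = if (is.null(enrichment)) 0L
                                    else nrow(enrichment))
  manifest <- write_manifest(out_dir, config, input_files, counts)
  invisible(list(hits = hits, assignments = assignments,
                 orf_calls = orf_calls, orf_table = orf_table,
                 meta = meta, transferred = transferred,
                 enrichment = enrichment, manifest = manifest))
}

# HSPs of the transcript's best hit (highest-bitscore subject, canonical
# tie-break); NULL when the transcript has no hits.
best_hit_hsps <- function(hits, transcript_id) {
  h <- hits[hits$qid == transcript_id, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h <- sort_hits(h)
  h[h$sid == h$sid[1], , drop = FALSE]
}

write_table_out <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_orf_fastas <- function(orf_calls, transcripts, out_dir) {
  nt <- character(0); aa <- character(0)
  for (oc in orf_calls) {
    if (oc$orf_end <= oc$orf_start) next
    region <- substr(as.character(transcripts[[oc$transcript_id]]),
                     oc$orf_start + 1L, oc$orf_end)
    if (oc$strand < 0) region <- revcomp(region)
    nt[oc$transcript_id] <- region
    if (nzchar(oc$protein)) aa[oc$transcript_id] <- oc$protein
  }
  write_fasta(Biostrings::DNAStringSet(nt),
              file.path(out_dir, "orf_nt.fasta"))
  write_fasta(Biostrings::AAStringSet(aa),
              file.path(out_dir, "orf_protein.fasta"))
  invisible(out_dir)
}

# JSON manifest: configuration snapshot, input checksums, version and
# per-stage record counts. Written atomically; deliberately contains no
# timestamps so reruns are byte-identical.
write_manifest <- function(out_dir, config, input_files, counts) {
  checksums <- if (length(input_files)) {
    as.list(tools::md5sum(unname(input_files)))
  } else list()
  names(checksums) <- names(input_files)
  manifest <- list(
    tool = "transannot",
    version = as.character(utils::packageVersion("transannot")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    input_checksums = checksums,
    record_counts = counts)
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  manifest
}
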