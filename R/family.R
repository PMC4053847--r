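#' Assign a transcript to a gene family from its best hit
#'
#' Takes the hits of a single transcript, ranks them canonically
#' (bitscore descending, e-value ascending, subject id) and assigns the
#' family of the first hit whose subject is present in the family map.
#' Subjects missing from the map are skipped with a warning. With no
#' usable hit the transcript gets no family (and, downstream, no
#' functional annotation).
#'
#' @param hits HSP data.frame for one transcript.
#' @param family_map named character vector `gene_id -> family_id` (see
#'   [family_lookup()]) or a family table data.frame.
#' @return list with `transcript_id`, `family_id` (`NA` if none),
#'   `method`, `votes` (named integer vector) and `best_hit_id`.
#' @export
assign_best_hit <- function(hits, family_map) {
  if (is.data.frame(family_map)) family_map <- family_lookup(family_map)
  tid <- if (nrow(hits)) hits$qid[1] else NA_character_
  if (nrow(hits)) {
    stopifnot(all(hits$qid == tid))
    hits <- sort_hits(hits)
  }
  sub_hits <- hits[!duplicated(hits$sid), , drop = FALSE]
  for (i in seq_len(nrow(sub_hits))) {
    fam <- unname(family_map[sub_hits$sid[i]])
    if (is.na(fam)) {
      warning("subject(s) absent from family map skipped for ",
              tid, ": ", sub_hits$sid[i])
      next
    }
    return(list(transcript_id = tid, family_id = fam,
                method = "best_hit",
                votes = stats::setNames(1L, fam),
                best_hit_id = sub_hits$sid[i]))
  }
  list(transcript_id = tid, family_id = NA_character_,
       method = "best_hit", votes = integer(0),
       best_hit_id = if (nrow(sub_hits)) sub_hits$sid[1]
                     else NA_character_)
}

#' Assign a transcript to a gene family by top-k majority voting
#'
#' Among the first `k` hits whose subjects are present in the family map
#' (after canonical ranking), each hit votes for its subject's family;
#' the family with most votes wins. Ties go to the tied family containing
#' the best-ranked hit. With `k = 1` this reduces exactly to
#' [assign_best_hit()].
#'
#' @inheritParams assign_best_hit
#' @param k number of top mappable hits to consider.
#' @param method_label method recorded in the result.
#' @return see [assign_best_hit()].
#' @export
assign_majority <- function(hits, family_map, k = 5L,
                            method_label = if (k == 1L) "best_hit"
                                           else "majority_topk") {
  stopifnot(k >= 1L)
  if (is.data.frame(family_map)) family_map <- family_lookup(family_map)
  tid <- if (nrow(hits)) hits$qid[1] else NA_character_
  if (nrow(hits)) {
    stopifnot(all(hits$qid == tid))
    hits <- sort_hits(hits)
  }
  # one vote per subject gene: rank subjects by their best HSP
  sub_hits <- hits[!duplicated(hits$sid), , drop = FALSE]
  fams <- unname(family_map[sub_hits$sid])
  unmapped <- sub_hits$sid[is.na(fams)]
  if (length(unmapped)) {
    warning("subject(s) absent from family map skipped for ",
            tid, ": ", paste(unique(unmapped), collapse = ", "))
  }
  mappable <- which(!is.na(fams))
  considered <- mappable[seq_len(min(k, length(mappable)))]
  if (!length(considered)) {
    return(list(transcript_id = tid, family_id = NA_character_,
                method = method_label, votes = integer(0),
                best_hit_id = if (nrow(sub_hits)) sub_hits$sid[1]
                              else NA_character_))
  }
  vote_fams <- fams[considered]
  votes <- table(vote_fams)
  votes <- stats::setNames(as.integer(votes), names(votes))
  top <- names(votes)[votes == max(votes)]
  # tie-break: the tied family whose first (best-ranked) hit comes first
  winner <- vote_fams[match(TRUE, vote_fams %in% top)]
  list(transcript_id = tid, family_id = winner, method = method_label,
       votes = votes, best_hit_id = sub_hits$sid[considered[1]])
}

#' Assign all transcripts in a hit table to families
#'
#' @param hits HSP data.frame covering any number of transcripts.
#' @param families family table data.frame or named lookup vector.
#' @param method `"best_hit"` or `"majority"`.
#' @param k top hits considered when `method = "majority"`.
#' @param transcript_ids optional character vector of all transcript ids;
#'   hitless transcripts then appear with `family_id = NA`.
#' @return data.frame with columns `transcript_id`, `family_id`,
#'   `method`, `vote_summary` (e.g. `"F1:3,F2:2"`), `best_hit_id`.
#' @export
assign_families <- function(hits, families,
                            method = c("best_hit", "majority"), k = 5L,
                            transcript_ids = NULL) {
  method <- match.arg(method)
  fmap <- if (is.data.frame(families)) family_lookup(families)
          else families
  kk <- if (method == "best_hit") 1L else as.integer(k)
  ids <- unique(hits$qid)
  if (!is.null(transcript_ids)) {
    ids <- transcript_ids
  }
  res <- lapply(ids, function(id) {
    h <- hits[hits$qid == id, , drop = FALSE]
    a <- assign_majority(h, fmap, k = kk,
                         method_label = if (kk == 1L) "best_hit"
                                        else "majority_topk")
    data.frame(transcript_id = id,
               family_id = if (is.na(a$family_id)) NA_character_
                           else a$family_id,
               method = a$method,
               vote_summary = vote_summary(a$votes),
               best_hit_id = a$best_hit_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(),
                      family_id = character(), method = character(),
                      vote_summary = character(),
                      best_hit_id = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

vote_summary <- function(votes) {
  if (!length(votes)) return("")
  votes <- votes[order(-votes, names(votes))]
  paste(sprintf("%s:%d", names(votes), votes), collapse = ",")
}

#' Select per-species family representatives
#'
#' Given a similarity graph over the members of one gene family (nodes =
#' genes, undirected edges weighted by alignment bitscore), the
#' representative of each species is the member with the largest weighted
#' degree, i.e. the sum of bitscores of its edges to other family
#' members. Ties go to the lexicographically smallest gene id; isolated
#' genes have centrality 0. Species without members are absent from the
#' output.
#'
#' @param members data.frame with columns `gene_id`, `species` (one row
#'   per family member).
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`
#'   (undirected; self-edges are rejected). Edges touching genes outside
#'   `members` are ignored.
#' @return data.frame with columns `species`, `gene_id`, `centrality`,
#'   one row per species, ordered by species.
#' @export
select_representatives <- function(members, edges) {
  stopifnot(all(c("gene_id", "species") %in% names(members)),
            all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$weight > 0))
    if (any(edges$gene_a == edges$gene_b)) {
      stop("self-edges are not allowed in the similarity graph")
    }
  }
  inset <- edges$gene_a %in% members$gene_id &
           edges$gene_b %in% members$gene_id
  edges <- edges[inset, , drop = FALSE]
  cent <- stats::setNames(numeric(nrow(members)), members$gene_id)
  if (nrow(edges)) {
    w <- c(edges$weight, edges$weight)
    g <- c(edges$gene_a, edges$gene_b)
    sums <- tapply(w, g, sum)
    cent[names(sums)] <- sums
  }
  species <- sort(unique(members$species))
  rows <- lapply(species, function(sp) {
    genes <- sort(members$gene_id[members$species == sp])
    cg <- cent[genes]
    best <- genes[which.max(cg)]  # which.max takes the first = smallest id
    data.frame(species = sp, gene_id = best,
               centrality = unname(cg[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
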