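# Graph-based orthology inference: forward and reciprocal similarity
# searches, reciprocal-best-hit pairing, Markov clustering of the
# relationship graph, within-cluster filtering, intersection of full-length
# and pore-domain evidence, relation typing, and metadata validation.

#' Orthology-inference parameters
#'
#' @param forward_evalue_max E-value cutoff of the forward search
#'   (default 1e-5, the conventional high-confidence cutoff).
#' @param reciprocal_evalue_max E-value cutoff of the reciprocal search
#'   (default 1e-200, a deliberately stringent top-hit filter; relax it for
#'   short or weakly diverged sequences, whose optimal scores cannot reach
#'   such e-values).
#' @param inflation Markov-clustering inflation exponent (default 1.5).
#' @param forward_mode `"top"` (default): only the top forward hit per
#'   organism enters the reciprocal stage. `"all"`: every forward hit below
#'   the cutoff is carried forward, so duplicate (co-ortholog) targets in
#'   one organism can all be retained.
#' @param weight Edge weight for clustering: `"bit_score"` (default) or
#'   `"neglog_evalue"`.
#' @return list of class `"orthology_params"`.
#' @export
orthology_params <- function(forward_evalue_max = 1e-5,
                             reciprocal_evalue_max = 1e-200,
                             inflation = 1.5,
                             forward_mode = c("top", "all"),
                             weight = c("bit_score", "neglog_evalue")) {
  stopifnot(forward_evalue_max > 0, reciprocal_evalue_max > 0, inflation > 1)
  structure(list(forward_evalue_max = forward_evalue_max,
                 reciprocal_evalue_max = reciprocal_evalue_max,
                 inflation = inflation,
                 forward_mode = match.arg(forward_mode),
                 weight = match.arg(weight)),
            class = "orthology_params")
}

#' Organism of a target gene identifier
#'
#' Target genes are named `"<organism>|<gene>"`; the organism is everything
#' before the first pipe.
#'
#' @param id Character vector of gene identifiers.
#' @return Character vector of organism identifiers.
#' @export
organism_of <- function(id) sub("\\|.*$", "", id)

.top_per_group <- function(hits, group) {
  ord <- order(group, -hits$bit_score, hits$evalue, hits$target)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(group[ord]), , drop = FALSE]
}

#' Reciprocal-best-hit pairing
#'
#' A query--target pair is retained when the target is the query's best
#' forward hit within the target's organism and the query is the target's
#' best reciprocal hit across the query proteome (ties broken by bit score,
#' then e-value, then identifier, so the "top hit" is deterministic). With
#' `forward_mode = "all"` every forward hit below the cutoff is eligible on
#' the forward side and only the reciprocal-best condition is enforced.
#'
#' @param forward_hits Hits of queries vs target proteomes
#'   ([search_all()] layout); target ids must carry the organism prefix.
#' @param reciprocal_hits Hits of candidate targets (as `query`) vs the
#'   query proteome (as `target`).
#' @param params An [orthology_params()].
#' @return data.frame: `query`, `target`, `organism`, `bit_score`
#'   (forward), `evalue_forward`, `evalue_reciprocal`.
#' @export
reciprocal_best_pairs <- function(forward_hits, reciprocal_hits,
                                  params = orthology_params()) {
  empty <- data.frame(query = character(), target = character(),
                      organism = character(), bit_score = numeric(),
                      evalue_forward = numeric(),
                      evalue_reciprocal = numeric(), stringsAsFactors = FALSE)
  fwd <- forward_hits[forward_hits$evalue <= params$forward_evalue_max, ,
                      drop = FALSE]
  rec <- reciprocal_hits[
    reciprocal_hits$evalue <= params$reciprocal_evalue_max, , drop = FALSE]
  if (!nrow(fwd) || !nrow(rec)) return(empty)
  fwd$organism <- organism_of(fwd$target)
  if (params$forward_mode == "top")
    fwd <- .top_per_group(fwd, paste(fwd$query, fwd$organism, sep = "\r"))
  rec_top <- .top_per_group(rec, rec$query)
  best_back <- stats::setNames(rec_top$target, rec_top$query)
  keep <- !is.na(best_back[fwd$target]) & best_back[fwd$target] == fwd$query
  rec_ev <- stats::setNames(rec_top$evalue, rec_top$query)
  out <- data.frame(query = fwd$query[keep], target = fwd$target[keep],
                    organism = fwd$organism[keep],
                    bit_score = fwd$bit_score[keep],
                    evalue_forward = fwd$evalue[keep],
                    evalue_reciprocal = unname(rec_ev[fwd$target[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$query, out$organism, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only pairs whose endpoints share a Markov cluster
#'
#' @param pairs Pair data.frame with `query` and `target` columns.
#' @param clusters Named vector node -> cluster id ([markov_cluster()]).
#' @return `pairs` with a `cluster_id` column, restricted to within-cluster
#'   pairs. Endpoints without an assignment raise an error naming them.
#' @export
filter_within_cluster <- function(pairs, clusters) {
  if (!nrow(pairs)) {
    pairs$cluster_id <- character(0)
    return(pairs)
  }
  ends <- unique(c(pairs$query, pairs$target))
  missing <- setdiff(ends, names(clusters))
  if (length(missing))
    stopf("no cluster assignment for: %s", paste(missing, collapse = ", "))
  same <- clusters[pairs$query] == clusters[pairs$target]
  out <- pairs[same, , drop = FALSE]
  out$cluster_id <- unname(clusters[out$query])
  rownames(out) <- NULL
  out
}

#' Intersect full-length and domain-based ortholog evidence
#'
#' Only pairs recovered by both the full-length and the pore-domain
#' pipeline are retained as high-confidence orthologs; retained pairs carry
#' both evidence flags.
#'
#' @param full_length_pairs,domain_pairs Pair data.frames (`query`,
#'   `target`, ...).
#' @return The full-length rows present in both inputs, with an `evidence`
#'   column set to `"full_length,domain"`.
#' @export
intersect_evidence <- function(full_length_pairs, domain_pairs) {
  key <- function(p) paste(p$query, p$target, sep = "\r")
  keep <- key(full_length_pairs) %in% key(domain_pairs)
  out <- full_length_pairs[keep, , drop = FALSE]
  out$evidence <- if (nrow(out)) "full_length,domain" else character(0)
  rownames(out) <- NULL
  out
}

#' Type retained pairs as one-to-one orthologs or co-orthologs
#'
#' For a query q and organism o, the relation is one-to-one exactly when q
#' has a single retained target in o and that target has a single retained
#' query; otherwise every retained pair between q and o is a co-ortholog
#' relationship (lineage-specific duplication has left multiple
#' counterparts).
#'
#' @param pairs Retained pair data.frame (`query`, `target`, `organism`).
#' @param clusters Optional cluster assignment (carried through untouched;
#'   typing itself is determined by retained-pair multiplicity).
#' @return `pairs` with a `relation` column.
#' @export
classify_relation <- function(pairs, clusters = NULL) {
  if (!nrow(pairs)) {
    pairs$relation <- character(0)
    return(pairs)
  }
  qo <- paste(pairs$query, pairs$organism, sep = "\r")
  n_targets <- table(qo)
  n_queries <- table(pairs$target)
  one <- as.vector(n_targets[qo] == 1L) & as.vector(n_queries[pairs$target] == 1L)
  pairs$relation <- ifelse(one, "one_to_one", "co_ortholog")
  # co-orthology is a property of the (query, organism) cell: if any pair
  # in the cell is multiple, all its pairs are co-ortholog
  bad_cells <- unique(qo[pairs$relation == "co_ortholog"])
  pairs$relation[qo %in% bad_cells] <- "co_ortholog"
  pairs
}

.domain_subsequences <- function(queries, query_domains) {
  missing <- setdiff(names(queries), query_domains$accession)
  if (length(missing))
    stopf("no domain coordinates for: %s", paste(missing, collapse = ", "))
  idx <- match(names(queries), query_domains$accession)
  Biostrings::subseq(queries, start = query_domains$start[idx],
                     end = pmin(query_domains$end[idx],
                                Biostrings::width(queries)))
}

.rbh_stage <- function(queries, proteomes, scheme, params) {
  forward <- list()
  for (org in names(proteomes)) {
    if (!length(proteomes[[org]])) next
    forward[[org]] <- search_all(queries, proteomes[[org]], scheme,
                                 params$forward_evalue_max)
  }
  forward <- if (length(forward)) do.call(rbind, forward) else .empty_hits()
  rownames(forward) <- NULL
  cand_fwd <- forward
  cand_fwd$organism <- organism_of(cand_fwd$target)
  if (params$forward_mode == "top")
    cand_fwd <- .top_per_group(cand_fwd,
                               paste(cand_fwd$query, cand_fwd$organism,
                                     sep = "\r"))
  candidates <- unique(cand_fwd$target)
  if (!length(candidates))
    return(reciprocal_best_pairs(forward, .empty_hits(), params))
  all_targets <- do.call(c, unname(proteomes))
  reciprocal <- search_all(all_targets[candidates], queries, scheme,
                           params$reciprocal_evalue_max)
  pairs <- reciprocal_best_pairs(forward, reciprocal, params)
  if (!nrow(pairs)) return(pairs)
  w <- if (params$weight == "bit_score") pairs$bit_score
       else -log10(pmax(pairs$evalue_forward, 1e-300))
  clusters <- markov_cluster(
    data.frame(from = pairs$query, to = pairs$target, weight = w,
               stringsAsFactors = FALSE),
    inflation = params$inflation)
  filter_within_cluster(pairs, clusters)
}

#' End-to-end orthology inference with dual evidence and validation
#'
#' Runs the full-length and pore-domain reciprocal-best-hit pipelines
#' (forward search, reciprocal search, RBH pairing, Markov clustering,
#' within-cluster filtering), intersects their pair sets, types the
#' retained relationships, and applies the metadata validation cascade to
#' the target side. A ledger of dropped pairs with reasons is kept.
#'
#' @param queries Named `AAStringSet` of query (human-side) sequences; only
#'   pore-containing entries, since the domain pipeline needs coordinates.
#' @param query_domains data.frame `accession`, `start`, `end`: pore-domain
#'   coordinates of every query (1-based inclusive).
#' @param proteomes Named list organism -> `AAStringSet`; gene identifiers
#'   must be `"<organism>|<gene>"`.
#' @param params An [orthology_params()].
#' @param metadata Optional metadata data.frame covering all target genes
#'   (see [validate_record()]); when supplied, pairs whose target fails the
#'   cascade are dropped with reason `"validation: <failed checks>"`.
#' @param vparams A [validation_params()].
#' @param scheme A [scoring_scheme()].
#' @return list: `pairs` (retained `OrthologPair` rows: query, target,
#'   organism, bit_score, evalues, cluster_id, evidence, relation),
#'   `dropped` (ledger: query, target, stage, reason), `full_length` and
#'   `domain` (the per-evidence pair sets before intersection).
#' @export
run_orthology <- function(queries, query_domains, proteomes,
                          params = orthology_params(), metadata = NULL,
                          vparams = validation_params(),
                          scheme = scoring_scheme()) {
  queries <- Biostrings::AAStringSet(queries)
  dropped <- list()
  note_drop <- function(q, t, stage, reason) {
    if (!length(q)) return(invisible())
    dropped[[length(dropped) + 1L]] <<- data.frame(
      query = q, target = t, stage = stage, reason = reason,
      stringsAsFactors = FALSE)
  }

  full <- .rbh_stage(queries, proteomes, scheme, params)
  dom_queries <- .domain_subsequences(queries, query_domains)
  dom <- .rbh_stage(dom_queries, proteomes, scheme, params)

  pairs <- intersect_evidence(full, dom)
  key <- paste(full$query, full$target)
  lost <- !(key %in% paste(pairs$query, pairs$target))
  note_drop(full$query[lost], full$target[lost], "intersection",
            "evidence: missing domain support")
  dkey <- paste(dom$query, dom$target)
  dlost <- !(dkey %in% paste(pairs$query, pairs$target))
  note_drop(dom$query[dlost], dom$target[dlost], "intersection",
            "evidence: missing full-length support")

  pairs <- classify_relation(pairs)

  if (!is.null(metadata) && nrow(pairs)) {
    targets <- unique(pairs$target)
    missing <- setdiff(targets, metadata$accession)
    if (length(missing))
      stopf("metadata missing for target(s): %s",
            paste(missing, collapse = ", "))
    md <- metadata[metadata$accession %in% targets, , drop = FALSE]
    verdicts <- validate_records(md, vparams)
    bad <- verdicts[!verdicts$passed, , drop = FALSE]
    if (nrow(bad)) {
      drop_idx <- pairs$target %in% bad$accession
      reason <- paste0("validation: ",
                       bad$failed_checks[match(pairs$target[drop_idx],
                                               bad$accession)])
      note_drop(pairs$query[drop_idx], pairs$target[drop_idx],
                "validation", reason)
      pairs <- pairs[!drop_idx, , drop = FALSE]
    }
  }
  rownames(pairs) <- NULL
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(query = character(), target = character(),
               stage = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(pairs = pairs, dropped = dropped, full_length = full, domain = dom)
}

#' Write / read an ortholog pair table
#'
#' @param pairs Pair data.frame from [run_orthology()].
#' @param path TSV path.
#' @return `write_ortholog_pairs()`: `path`, invisibly;
#'   `read_ortholog_pairs()`: the pair data.frame.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_pairs
#' @export
read_ortholog_pairs <- function(path) {
  if (!file.exists(path)) stopf("ortholog pair file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
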