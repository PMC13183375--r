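# Phylogenetic profiling of validated orthologs: the query x organism
# state matrix, family x lineage percentage summaries, Ward clustering of
# presence/absence profiles, and hypergeometric term enrichment per
# cluster.

#' Build the phylogenetic profile matrix
#'
#' One row per query, one column per organism; each cell is
#' `"one_to_one"`, `"co_ortholog"`, or `"absent"`. A query--organism cell
#' with at least one co-ortholog pair is a co-ortholog cell.
#'
#' @param pairs Retained ortholog pairs with `query`, `organism` and
#'   `relation` columns ([run_orthology()]).
#' @param queries Character vector of all query identifiers (rows; also
#'   queries with no retained ortholog anywhere).
#' @param organisms Character vector of organism identifiers (columns), or
#'   a `"taxonomy"` whose tips define the columns and carry lineage paths.
#' @return Character matrix of class `"profile_matrix"` with a `lineage`
#'   attribute (named list organism -> lineage path) when a taxonomy was
#'   given.
#' @export
build_profile_matrix <- function(pairs, queries, organisms) {
  lineage <- NULL
  if (inherits(organisms, "taxonomy")) {
    lineage <- organisms$lineage
    organisms <- names(organisms$lineage)
  }
  mat <- matrix("absent", nrow = length(queries), ncol = length(organisms),
                dimnames = list(queries, organisms))
  if (nrow(pairs)) {
    unknown <- setdiff(unique(pairs$organism), organisms)
    if (length(unknown))
      stopf("pair references unknown organism(s): %s",
            paste(unknown, collapse = ", "))
    unknown_q <- setdiff(unique(pairs$query), queries)
    if (length(unknown_q))
      stopf("pair references unknown query(s): %s",
            paste(unknown_q, collapse = ", "))
    for (i in seq_len(nrow(pairs))) {
      cur <- mat[pairs$query[i], pairs$organism[i]]
      rel <- pairs$relation[i]
      mat[pairs$query[i], pairs$organism[i]] <-
        if (cur == "co_ortholog" || rel == "co_ortholog") "co_ortholog"
        else "one_to_one"
    }
  }
  structure(mat, class = c("profile_matrix", class(mat)), lineage = lineage)
}

#' Family x lineage ortholog percentage
#'
#' For a family F and a taxonomic lineage L the summary is
#' `100 * found / (n_organisms * family_size)`, where `found` counts the
#' non-absent cells over F's rows and L's organisms; a co-ortholog cell
#' counts once per (query, organism).
#'
#' @param matrix A `"profile_matrix"` built against a taxonomy (so columns
#'   carry lineage paths), or any profile matrix plus an explicit
#'   `organisms` selection.
#' @param family_map Named vector query -> family designation covering all
#'   rows.
#' @param lineage Lineage (clade) label to select columns; alternatively
#'   pass `organisms` directly.
#' @param organisms Optional explicit organism selection overriding
#'   `lineage`.
#' @return data.frame `family`, `lineage`, `percentage` (one row per
#'   family).
#' @export
lineage_family_percentage <- function(matrix, family_map, lineage = NULL,
                                      organisms = NULL) {
  if (is.null(organisms)) {
    lin <- attr(matrix, "lineage")
    if (is.null(lin))
      stopf("matrix carries no lineage metadata; pass `organisms`")
    if (is.null(lineage)) stopf("supply `lineage` or `organisms`")
    hit <- vapply(lin, function(p) lineage %in% p, logical(1))
    organisms <- names(lin)[hit]
  }
  if (!length(organisms)) stopf("lineage selects no organism")
  rows <- rownames(matrix)
  missing <- setdiff(rows, names(family_map))
  if (length(missing))
    stopf("family_map does not cover: %s", paste(missing, collapse = ", "))
  fams <- sort(unique(family_map[rows]))
  out <- lapply(fams, function(f) {
    members <- rows[family_map[rows] == f]
    sub <- matrix[members, organisms, drop = FALSE]
    found <- sum(sub != "absent")
    data.frame(family = f, lineage = lineage %||% NA_character_,
               percentage = 100 * found /
                 (length(organisms) * length(members)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster phylogenetic profiles
#'
#' Encodes the profile matrix as presence (1 = one-to-one or co-ortholog)
#' versus absence (0), computes Euclidean distances between rows, applies
#' Ward agglomeration, and cuts the dendrogram into exactly `k` clusters.
#' Rows are ordered lexicographically before clustering and clusters are
#' renumbered by their first member, so the result is invariant to row
#' order.
#'
#' @param matrix A `"profile_matrix"`.
#' @param k Number of clusters (1 <= k <= number of rows).
#' @param organisms Optional column selection (e.g. only eukaryote
#'   organisms, the usual choice when prokaryotic profiles are sparse).
#' @return list: `assignments` (named vector row -> cluster label `"1"`..),
#'   `hclust` (the dendrogram object).
#' @export
cluster_profiles <- function(matrix, k, organisms = NULL) {
  if (!is.null(organisms)) matrix <- matrix[, organisms, drop = FALSE]
  n <- nrow(matrix)
  if (k > n) stopf("k (%d) exceeds the number of profiles (%d)", k, n)
  num <- (matrix != "absent") * 1
  num <- num[order(rownames(num)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(num, method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # renumber by first (lexicographic) member for determinism
  first <- vapply(split(names(raw), raw), min, character(1))
  relabel <- stats::setNames(seq_along(first), names(first)[order(first)])
  assignments <- stats::setNames(as.character(relabel[as.character(raw)]),
                                 names(raw))
  list(assignments = assignments, hclust = hc)
}

#' Hypergeometric term over-representation per cluster
#'
#' For every cluster and term, tests whether the term's genes are
#' over-represented in the cluster with the one-sided hypergeometric tail
#' `P(X >= k)`, `X ~ Hypergeom(N, K, n)` (universe size N, term size K,
#' cluster size n, overlap k). Benjamini-Hochberg correction is applied
#' across all cluster x term tests jointly (set `per_cluster = TRUE` to
#' correct within clusters instead).
#'
#' @param clusters Named list cluster label -> gene identifiers, or a named
#'   vector gene -> cluster label.
#' @param term_map data.frame with `term` and `gene` columns (or a named
#'   list term -> genes).
#' @param universe Character vector of all genes under consideration; must
#'   contain every clustered gene.
#' @param fdr_max Retention threshold on the corrected FDR (default 0.01).
#' @param per_cluster Correct within each cluster separately.
#' @return data.frame `cluster`, `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `fdr`, `retained`, sorted by fdr then p.
#' @export
enrich_terms <- function(clusters, term_map, universe, fdr_max = 0.01,
                         per_cluster = FALSE) {
  if (!is.list(clusters))
    clusters <- split(names(clusters), unname(clusters))
  out_genes <- setdiff(unlist(clusters, use.names = FALSE), universe)
  if (length(out_genes))
    stopf("gene(s) outside the universe: %s",
          paste(utils::head(out_genes, 5), collapse = ", "))
  if (is.data.frame(term_map))
    term_map <- split(term_map$gene, term_map$term)
  term_map <- lapply(term_map, function(g) unique(intersect(g, universe)))
  N <- length(unique(universe))
  rows <- list()
  for (cl in names(clusters)) {
    genes <- unique(clusters[[cl]])
    n <- length(genes)
    for (term in names(term_map)) {
      K <- length(term_map[[term]])
      k <- length(intersect(genes, term_map[[term]]))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, term = term, k = k, K = K, n = n, N = N, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (per_cluster) {
    res$fdr <- stats::ave(res$p_value, res$cluster,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  } else {
    res$fdr <- stats::p.adjust(res$p_value, "BH")
  }
  res$retained <- res$fdr < fdr_max
  res <- res[order(res$fdr, res$p_value, res$cluster, res$term), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a profile matrix as TSV
#'
#' States are encoded `2` (one-to-one), `1` (co-ortholog), `0` (absent);
#' the legend is written as a `#` comment line above the header.
#'
#' @param matrix A `"profile_matrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  num <- matrix(0L, nrow(matrix), ncol(matrix), dimnames = dimnames(matrix))
  num[matrix == "one_to_one"] <- 2L
  num[matrix == "co_ortholog"] <- 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# states: 2=one_to_one, 1=co_ortholog, 0=absent", con)
  utils::write.table(data.frame(query = rownames(num), num,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
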