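# Scored local-alignment search: Smith-Waterman with affine gaps (BLOSUM62
# by default) and Karlin-Altschul e-value scaling, plus ingestion of
# externally computed 12-column tabular hits so that a real BLAST run can
# drive the orthology pipeline unchanged.

.extended_matrix <- function(name = "BLOSUM62") {
  mat <- get(utils::data(list = name, package = "Biostrings",
                         envir = environment()))
  # Selenocysteine (U), pyrrolysine (O) and ambiguous J are absent from the
  # shipped matrices; score them like X (-1 vs everything).
  extra <- setdiff(c("U", "O", "J"), colnames(mat))
  if (length(extra)) {
    for (e in extra) {
      mat <- rbind(mat, -1L)
      rownames(mat)[nrow(mat)] <- e
      mat <- cbind(mat, -1L)
      colnames(mat)[ncol(mat)] <- e
    }
  }
  mat
}

#' Scoring scheme for local alignment and e-value scaling
#'
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings;
#'   default `"BLOSUM62"`). Residues U, O and J are scored like X.
#' @param gap_open,gap_extend Affine gap penalties (positive; a gap of
#'   length w costs `gap_open + w * gap_extend`). Defaults 11/1.
#' @param lambda,K Karlin-Altschul parameters for converting raw scores to
#'   bit scores and e-values; defaults are the standard gapped BLOSUM62
#'   constants (0.267, 0.041). E-values here need only be monotone and
#'   threshold-comparable, not publication-grade.
#' @return A list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix_name = matrix, matrix = .extended_matrix(matrix),
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

.check_sequence <- function(x, scheme, what) {
  if (!nzchar(x)) stopf("%s sequence is empty", what)
  ok <- strsplit(x, "")[[1]] %in% rownames(scheme$matrix)
  if (!all(ok))
    stopf("%s sequence contains illegal character(s): %s", what,
          paste(unique(strsplit(x, "")[[1]][!ok]), collapse = ", "))
}

.bit_score <- function(raw, scheme)
  (scheme$lambda * raw - log(scheme$K)) / log(2)

.evalue <- function(raw, scheme, m, n)
  scheme$K * m * n * exp(-scheme$lambda * raw)

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps. The e-value is computed from the raw
#' score as `K * m * n * exp(-lambda * raw)` where `n` is the query length
#' and `m` the database letter count (defaults to the subject length for a
#' single pairwise comparison); the bit score is
#' `(lambda * raw - ln K) / ln 2`.
#'
#' @param a,b Query and target sequences (character or `AAString`).
#' @param scheme A [scoring_scheme()].
#' @param m Database letter count for the e-value; default `nchar(b)`.
#' @return One-row data.frame: `query`, `target` (names if available, else
#'   `"a"`/`"b"`), `raw_score`, `bit_score`, `evalue`, `qstart`, `qend`,
#'   `tstart`, `tend`, `pident`, `align_length`, `mismatches`, `gapopens`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(), m = NULL) {
  qa <- as.character(a); qb <- as.character(b)
  .check_sequence(qa, scheme, "query")
  .check_sequence(qb, scheme, "target")
  if (is.null(m)) m <- nchar(qb)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa), Biostrings::AAString(qb), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  raw <- Biostrings::score(aln)
  ind <- Biostrings::nindel(aln)
  gapopens <- ind@insertion[, "Length"] + ind@deletion[, "Length"]
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  nmat <- Biostrings::nmatch(aln)
  data.frame(query = names(a) %||% "a", target = names(b) %||% "b",
             raw_score = raw,
             bit_score = .bit_score(raw, scheme),
             evalue = .evalue(raw, scheme, m, nchar(qa)),
             qstart = Biostrings::start(Biostrings::pattern(aln)),
             qend = Biostrings::end(Biostrings::pattern(aln)),
             tstart = Biostrings::start(Biostrings::subject(aln)),
             tend = Biostrings::end(Biostrings::subject(aln)),
             pident = 100 * nmat / alen,
             align_length = alen,
             mismatches = Biostrings::nmismatch(aln),
             gapopens = gapopens,
             stringsAsFactors = FALSE)
}

#' All-vs-all local-alignment search
#'
#' Aligns every query against every database sequence, scales e-values by
#' the total database letter count, and keeps hits with
#' `evalue <= evalue_max`. Hits are sorted per query by bit score
#' (descending), then e-value (ascending), then target identifier, so the
#' "top hit" is deterministic.
#'
#' @param queries,database Named `AAStringSet`s (or named character
#'   vectors); identifiers must be unique within each set.
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Retention threshold (default 1e-5).
#' @return Hit data.frame in the [local_align()] layout.
#' @export
search_all <- function(queries, database, scheme = scoring_scheme(),
                       evalue_max = 1e-5) {
  queries <- Biostrings::AAStringSet(queries)
  database <- Biostrings::AAStringSet(database)
  if (anyDuplicated(names(queries)) || is.null(names(queries)))
    stopf("query identifiers must be present and unique")
  if (anyDuplicated(names(database)) || is.null(names(database)))
    stopf("database identifiers must be present and unique")
  m <- sum(Biostrings::width(database))
  hits <- list()
  for (j in seq_along(database)) {
    aln <- Biostrings::pairwiseAlignment(
      queries, database[[j]], type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    raw <- Biostrings::score(aln)
    ev <- .evalue(raw, scheme, m, Biostrings::width(queries))
    keep <- which(ev <= evalue_max)
    if (!length(keep)) next
    ind <- Biostrings::nindel(aln)
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))[keep]
    nmat <- Biostrings::nmatch(aln)[keep]
    hits[[length(hits) + 1L]] <- data.frame(
      query = names(queries)[keep], target = names(database)[j],
      raw_score = raw[keep],
      bit_score = .bit_score(raw[keep], scheme),
      evalue = ev[keep],
      qstart = Biostrings::start(Biostrings::pattern(aln))[keep],
      qend = Biostrings::end(Biostrings::pattern(aln))[keep],
      tstart = Biostrings::start(Biostrings::subject(aln))[keep],
      tend = Biostrings::end(Biostrings::subject(aln))[keep],
      pident = 100 * nmat / alen,
      align_length = alen,
      mismatches = Biostrings::nmismatch(aln)[keep],
      gapopens = (ind@insertion[, "Length"] + ind@deletion[, "Length"])[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  sort_hits(out)
}

.empty_hits <- function() {
  data.frame(query = character(), target = character(), raw_score = numeric(),
             bit_score = numeric(), evalue = numeric(), qstart = integer(),
             qend = integer(), tstart = integer(), tend = integer(),
             pident = numeric(), align_length = integer(),
             mismatches = integer(), gapopens = integer(),
             stringsAsFactors = FALSE)
}

#' Deterministic hit ordering
#'
#' Per query: bit score descending, e-value ascending, target id ascending.
#'
#' @param hits Hit data.frame.
#' @return Reordered data.frame.
#' @export
sort_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query, -hits$bit_score, hits$evalue, hits$target)
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write 12-column tabular hits
#'
#' The columns are query, target, percent identity, alignment length,
#' mismatches, gap opens, qstart, qend, tstart, tend, e-value, bit score
#' (the common tab-separated search output dialect). Spans are 1-based
#' inclusive; input ordering is preserved.
#'
#' @param path Tabular file path.
#' @return `ingest_tabular_hits()`: hit data.frame (with `raw_score = NA`;
#'   raw scores are not representable in this dialect);
#'   `write_tabular_hits()`: `path`, invisibly.
#' @export
ingest_tabular_hits <- function(path) {
  if (!file.exists(path)) stopf("hit file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stopf("line %d of '%s' has %d columns (expected 12)",
          bad[1], path, lengths(parts)[bad[1]])
  m <- do.call(rbind, parts)
  data.frame(query = m[, 1], target = m[, 2], raw_score = NA_real_,
             bit_score = as.numeric(m[, 12]), evalue = as.numeric(m[, 11]),
             qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
             tstart = as.integer(m[, 9]), tend = as.integer(m[, 10]),
             pident = as.numeric(m[, 3]), align_length = as.integer(m[, 4]),
             mismatches = as.integer(m[, 5]), gapopens = as.integer(m[, 6]),
             stringsAsFactors = FALSE)
}

#' @rdname ingest_tabular_hits
#' @param hits Hit data.frame ([local_align()] layout).
#' @export
write_tabular_hits <- function(hits, path) {
  out <- data.frame(hits$query, hits$target,
                    format(hits$pident, digits = 17, trim = TRUE),
                    hits$align_length, hits$mismatches, hits$gapopens,
                    hits$qstart, hits$qend, hits$tstart, hits$tend,
                    format(hits$evalue, digits = 17, scientific = TRUE,
                           trim = TRUE),
                    format(hits$bit_score, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
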