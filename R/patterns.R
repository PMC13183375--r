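# Foreground/background conserved-pattern detection in a multiple sequence
# alignment: per-column binomial log-likelihood-ratio contrast with greedy
# residue-set growth, label-permutation significance, BH-FDR selection, and
# mapping of alignment columns to reference-sequence numbering. This is a
# contrast-statistic analogue of Bayesian pattern partitioning (BPPS-style),
# not a re-implementation of the hierarchical Gibbs sampler.

#' Aligned sequence family with foreground/background labels
#'
#' @param alignment Equal-length gapped sequences (`AAStringSet` or named
#'   character vector). Sequence ids prefixed `"FG|"` / `"BG|"` are
#'   auto-labelled when `labels` is omitted.
#' @param labels Per-sequence `"foreground"`/`"background"` labels (>= 2 of
#'   each).
#' @param reference_id Identifier of the numbering reference (must be in
#'   the alignment); defaults to the first foreground sequence.
#' @return list of class `"aligned_family"`: `alignment` (character
#'   matrix, rows = sequences), `labels`, `reference_id`.
#' @export
aligned_family <- function(alignment, labels = NULL, reference_id = NULL) {
  seqs <- as.character(Biostrings::AAStringSet(alignment))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("alignment sequences must have unique identifiers")
  if (length(unique(nchar(seqs))) != 1L)
    stopf("alignment rows must all have the same length")
  if (is.null(labels)) {
    labels <- ifelse(startsWith(names(seqs), "FG|"), "foreground",
                     ifelse(startsWith(names(seqs), "BG|"), "background",
                            NA_character_))
    if (anyNA(labels))
      stopf("cannot infer labels; ids lack FG|/BG| prefixes and no labels given")
  }
  stopifnot(length(labels) == length(seqs),
            all(labels %in% c("foreground", "background")))
  if (sum(labels == "foreground") < 2L || sum(labels == "background") < 2L)
    stopf("need at least 2 foreground and 2 background sequences")
  if (is.null(reference_id))
    reference_id <- names(seqs)[labels == "foreground"][1]
  if (!reference_id %in% names(seqs))
    stopf("reference '%s' is not in the alignment", reference_id)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  structure(list(alignment = mat, labels = labels,
                 reference_id = reference_id),
            class = "aligned_family")
}

.is_gap <- function(x) x == "-" | x == "."

.contrast <- function(k_F, n_F, k_B, n_B, a) {
  p <- (k_F + a) / (n_F + 2 * a)
  q <- (k_B + a) / (n_B + 2 * a)
  pmax(0, k_F * log(p / q) + (n_F - k_F) * log((1 - p) / (1 - q)))
}

#' Column contrast score for a fixed residue set
#'
#' One-sided foreground-enrichment log-likelihood ratio for an alignment
#' column: with k_F of n_F ungapped foreground residues matching the set R
#' (and k_B of n_B in the background), smoothed proportions
#' `p = (k_F + a)/(n_F + 2a)` and `q = (k_B + a)/(n_B + 2a)` give
#' `score = max(0, k_F log(p/q) + (n_F - k_F) log((1-p)/(1-q)))`.
#'
#' @param residues Character vector, the column (gaps allowed, excluded
#'   from counts).
#' @param labels Matching `"foreground"`/`"background"` labels.
#' @param residue_set Non-empty character vector R of amino acids.
#' @param pseudocount Smoothing constant a > 0 (default 1).
#' @return Non-negative score; `NA` with a warning when either class is
#'   empty after gap removal (the column is skipped).
#' @export
column_contrast_score <- function(residues, labels, residue_set,
                                  pseudocount = 1) {
  stopifnot(pseudocount > 0, length(residue_set) >= 1)
  keep <- !.is_gap(residues)
  res <- residues[keep]
  lab <- labels[keep]
  n_F <- sum(lab == "foreground")
  n_B <- sum(lab == "background")
  if (n_F < 1L || n_B < 1L) {
    warning("column skipped: empty foreground or background after gap removal")
    return(NA_real_)
  }
  inR <- res %in% residue_set
  .contrast(sum(inR & lab == "foreground"), n_F,
            sum(inR & lab == "background"), n_B, pseudocount)
}

# Greedy maximal contrast for a column given per-residue foreground and
# total counts (classes in a fixed sorted order): grow the set from the
# most frequent foreground residue while the score increases. Prefix
# scores are computed vectorized; the greedy stop is the first
# non-increase. Returns list(score, size, order).
.greedy_max <- function(cf, call, n_F, n_B, a) {
  ord <- order(-cf, seq_along(cf))
  kf <- cumsum(cf[ord])
  kb <- cumsum(call[ord] - cf[ord])
  s <- .contrast(kf, n_F, kb, n_B, a)
  if (length(s) > 1L) {
    drop <- which(diff(s) <= 0)
    stop_at <- if (length(drop)) drop[1] else length(s)
  } else stop_at <- 1L
  list(score = s[stop_at], size = stop_at, order = ord)
}

# B draws of per-class foreground counts under label permutation:
# multivariate hypergeometric via sequential rhyper, vectorized over draws.
.draw_fg_counts <- function(call, n_F, B) {
  L <- length(call)
  out <- matrix(0L, B, L)
  left <- sum(call)
  pick <- rep.int(n_F, B)
  for (l in seq_len(L)) {
    left <- left - call[l]
    x <- stats::rhyper(B, call[l], left, pick)
    out[, l] <- x
    pick <- pick - x
  }
  out
}

#' Detect significantly foreground-conserved pattern positions
#'
#' Per column, the diagnostic residue set is grown greedily from the most
#' frequent foreground residue while the contrast score increases. The
#' significance of the column's maximal score is assessed against a
#' label-permutation null (`n_perm` shuffles, shared seed); p-values are
#' rank-based with seeded random tie-breaking by default, which keeps them
#' exactly uniform under the exchangeable null (`tie = "conservative"`
#' gives the classical `(1 + #{null >= obs})/(P + 1)` instead, and
#' `exact = TRUE` enumerates all label assignments, feasible for small
#' families). Columns are selected at BH-FDR < `fdr` and reported with
#' reference numbering.
#'
#' @param family An [aligned_family()].
#' @param fdr FDR cutoff (default 0.01).
#' @param n_perm Number of permutations (default 2999; the attainable p-value floor is 1/(n_perm + 1), so BH selection at stringent FDR needs enough permutations).
#' @param pseudocount Contrast smoothing constant (default 1).
#' @param seed Seed for the permutation stream.
#' @param tie `"randomized"` (default) or `"conservative"`.
#' @param exact Enumerate all foreground assignments instead of sampling
#'   (conservative p; only for small columns).
#' @return data.frame `column`, `residue_set` (comma-joined), `score`,
#'   `p_value`, `fdr`, `ref_letter`, `ref_number`, sorted by column, with
#'   attribute `"all_columns"` carrying the unfiltered per-column table.
#' @export
select_pattern_positions <- function(family, fdr = 0.01, n_perm = 2999L,
                                     pseudocount = 1, seed = 1L,
                                     tie = c("randomized", "conservative"),
                                     exact = FALSE) {
  stopifnot(inherits(family, "aligned_family"))
  tie <- match.arg(tie)
  mat <- family$alignment
  n_col <- ncol(mat)
  if (n_col == 0L)
    return(.empty_patterns())
  fg <- family$labels == "foreground"
  with_seed(seed, {
    rows <- vector("list", n_col)
    for (j in seq_len(n_col)) {
      col <- mat[, j]
      keep <- !.is_gap(col)
      res <- col[keep]
      isfg <- fg[keep]
      n_F <- sum(isfg)
      n_B <- sum(!isfg)
      if (n_F < 1L || n_B < 1L) next
      lev <- sort(unique(res))
      code <- match(res, lev)
      call <- tabulate(code, length(lev))
      cf <- tabulate(code[isfg], length(lev))
      obs <- .greedy_max(cf, call, n_F, n_B, pseudocount)
      set <- lev[obs$order[seq_len(obs$size)]]
      n <- length(code)
      if (exact) {
        combos <- utils::combn(n, n_F, simplify = FALSE)
        null <- vapply(combos, function(fg_idx)
          .greedy_max(tabulate(code[fg_idx], length(lev)), call,
                      n_F, n_B, pseudocount)$score, numeric(1))
        p <- mean(null >= obs$score - 1e-12)
      } else {
        cfmat <- .draw_fg_counts(call, n_F, n_perm)
        null <- vapply(seq_len(n_perm), function(b)
          .greedy_max(cfmat[b, ], call, n_F, n_B, pseudocount)$score,
          numeric(1))
        g <- sum(null > obs$score + 1e-12)
        e <- sum(abs(null - obs$score) <= 1e-12)
        p <- if (tie == "conservative") (1 + g + e) / (n_perm + 1)
             else (1 + g + sample.int(e + 1L, 1L) - 1L) / (n_perm + 1)
      }
      rows[[j]] <- data.frame(column = j,
                              residue_set = paste(set, collapse = ","),
                              score = obs$score, p_value = p,
                              stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(.empty_patterns())
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p_value, "BH")
    ref <- lapply(tab$column, function(j) map_to_reference(family, j))
    tab$ref_letter <- vapply(ref, `[[`, character(1), "letter")
    tab$ref_number <- vapply(ref, `[[`, integer(1), "number")
    out <- tab[tab$fdr < fdr, , drop = FALSE]
    out <- out[order(out$column), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "all_columns") <- tab
    out
  })
}

.empty_patterns <- function() {
  structure(data.frame(column = integer(), residue_set = character(),
                       score = numeric(), p_value = numeric(),
                       fdr = numeric(), ref_letter = character(),
                       ref_number = integer(), stringsAsFactors = FALSE),
            all_columns = NULL)
}

#' Map an alignment column to reference-sequence numbering
#'
#' The residue number is the count of non-gap reference positions from
#' column 1 through the given column. Columns where the reference itself is
#' gapped are flagged (`letter = "-"`, `gapped = TRUE`) and report the
#' preceding residue number.
#'
#' @param family An [aligned_family()].
#' @param column Alignment column (1-based).
#' @return list `letter`, `number`, `gapped`.
#' @export
map_to_reference <- function(family, column) {
  mat <- family$alignment
  if (column < 1L || column > ncol(mat))
    stopf("column %d out of range (alignment has %d columns)",
          column, ncol(mat))
  ref <- mat[family$reference_id, ]
  nongap <- !.is_gap(ref)
  number <- sum(nongap[seq_len(column)])
  if (nongap[column])
    list(letter = unname(ref[column]), number = as.integer(number),
         gapped = FALSE)
  else
    list(letter = "-", number = as.integer(number), gapped = TRUE)
}

#' Two-level pattern analysis: family-wide vs clade-specific positions
#'
#' Runs pattern detection twice: the whole labelled family against its
#' outgroup background (family-wide patterns), and a focal sub-clade of the
#' foreground against the remaining foreground members (clade-specific
#' patterns). When the focal clade is the entire foreground the second pass
#' degenerates to the first. Columns appearing in both tiers are flagged.
#'
#' @param family An [aligned_family()].
#' @param partition list of two disjoint character vectors of foreground
#'   sequence ids covering the foreground exactly; the first element is the
#'   focal sub-clade.
#' @param ... Passed to [select_pattern_positions()].
#' @return list `family_wide`, `clade_specific` (pattern tables),
#'   `overlap` (columns reported in both).
#' @export
two_level_analysis <- function(family, partition, ...) {
  stopifnot(inherits(family, "aligned_family"))
  fg_ids <- rownames(family$alignment)[family$labels == "foreground"]
  if (!is.list(partition) || length(partition) != 2L)
    stopf("partition must be a list of two id vectors")
  focal <- partition[[1]]
  rest <- partition[[2]]
  if (length(intersect(focal, rest)) ||
      !setequal(c(focal, rest), fg_ids))
    stopf("partition is not a partition of the foreground sequences")
  family_wide <- select_pattern_positions(family, ...)
  if (!length(rest)) {
    clade <- family_wide
  } else {
    sub <- family$alignment[fg_ids, , drop = FALSE]
    labels <- ifelse(fg_ids %in% focal, "foreground", "background")
    ref <- if (family$reference_id %in% focal) family$reference_id
           else focal[1]
    subfam <- aligned_family(
      Biostrings::AAStringSet(apply(sub, 1, paste, collapse = "")),
      labels = labels, reference_id = ref)
    clade <- select_pattern_positions(subfam, ...)
  }
  list(family_wide = family_wide, clade_specific = clade,
       overlap = intersect(family_wide$column, clade$column))
}
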