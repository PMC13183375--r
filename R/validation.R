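# Three-step ortholog validation cascade over UniProt-style metadata.
# Step 1 passes manually reviewed entries outright; step 2 passes
# unreviewed entries with dependable protein-existence evidence (levels
# 1-3); everything else must clear five integrity checks (sequence
# version, compositional bias, non-standard residues, length, presence of
# cross-references) to be retained.

#' Validation thresholds
#'
#' The cascade names its checks but leaves the numeric cutoffs to the
#' operator; these defaults are deliberately permissive and all
#' configurable. `bias_window`/`bias_entropy_min` parameterize the
#' SEG-like low-complexity screen of [low_complexity_fraction()].
#'
#' @param max_version Highest acceptable sequence version (unstable entries
#'   accumulate many updates). Default 100.
#' @param bias_max Maximum tolerated fraction of residues inside
#'   low-entropy windows. Default 0.5.
#' @param bias_window Sliding window length (residues). Default 12.
#' @param bias_entropy_min Entropy cutoff in bits below which a window
#'   counts as low-complexity. Default 2.2.
#' @param ns_max Maximum tolerated fraction of non-standard residues
#'   (anything outside the 20 canonical letters, so B, J, O, U, X and Z all
#'   count). Default 0.05.
#' @param min_length,max_length Length bounds in residues (fragments /
#'   fusion errors). Defaults 30 and 5000.
#' @param checks Character vector selecting which step-3 checks run;
#'   subset of `c("version", "compositional_bias", "nonstandard_aa",
#'   "length", "crossrefs")`.
#' @return list of class `"validation_params"`.
#' @export
validation_params <- function(max_version = 100L, bias_max = 0.5,
                              bias_window = 12L, bias_entropy_min = 2.2,
                              ns_max = 0.05, min_length = 30L,
                              max_length = 5000L,
                              checks = c("version", "compositional_bias",
                                         "nonstandard_aa", "length",
                                         "crossrefs")) {
  all_checks <- c("version", "compositional_bias", "nonstandard_aa",
                  "length", "crossrefs")
  stopifnot(all(checks %in% all_checks), bias_window >= 2)
  structure(list(max_version = max_version, bias_max = bias_max,
                 bias_window = as.integer(bias_window),
                 bias_entropy_min = bias_entropy_min, ns_max = ns_max,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length), checks = checks),
            class = "validation_params")
}

#' Fraction of a sequence covered by low-entropy windows
#'
#' Slides a window of `window` residues along the sequence, computes the
#' Shannon entropy (base 2) of the empirical residue distribution inside
#' each window, and returns the fraction of residues covered by at least
#' one window whose entropy falls below `entropy_min`. Sequences shorter
#' than the window are assessed as a single whole-sequence window.
#'
#' @param sequence Residue string.
#' @param window Window length (>= 2).
#' @param entropy_min Entropy cutoff in bits.
#' @return Fraction in `[0, 1]`.
#' @examples
#' low_complexity_fraction(strrep("A", 12))         # 1: zero entropy
#' low_complexity_fraction("ARNDCQEGHILKMFPSTWYV")  # 0: maximally diverse
#' @export
low_complexity_fraction <- function(sequence, window = 12L,
                                    entropy_min = 2.2) {
  stopifnot(window >= 2)
  chars <- strsplit(as.character(sequence), "")[[1]]
  n <- length(chars)
  if (n == 0L) return(0)
  w <- min(window, n)
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  covered <- logical(n)
  for (s in seq_len(n - w + 1L)) {
    if (ent(chars[s:(s + w - 1L)]) < entropy_min)
      covered[s:(s + w - 1L)] <- TRUE
  }
  mean(covered)
}

.nonstandard_fraction <- function(sequence) {
  chars <- strsplit(as.character(sequence), "")[[1]]
  if (!length(chars)) return(0)
  mean(!chars %in% AA_STANDARD)
}

#' Validate one metadata record through the three-step cascade
#'
#' @param record A one-row data.frame (or list) with fields `accession`,
#'   `entry_type` (`"Reviewed"`/`"Unreviewed"`), `protein_existence`
#'   (integer 1-5), `sequence_version`, `sequence`, `domain_count`,
#'   `xref_count`.
#' @param params A [validation_params()].
#' @return list of class `"validation_verdict"`: `accession`, `passed`,
#'   `deciding_step` (1, 2 or 3), `failed_checks` (character, empty unless
#'   the record failed at step 3).
#' @export
validate_record <- function(record, params = validation_params()) {
  pe <- as.integer(record$protein_existence)
  if (is.na(pe) || pe < 1L || pe > 5L)
    stopf("protein_existence must be in 1..5 (got %s for %s)",
          record$protein_existence, record$accession)
  verdict <- function(passed, step, failed = character(0))
    structure(list(accession = record$accession, passed = passed,
                   deciding_step = step, failed_checks = failed),
              class = "validation_verdict")
  if (identical(record$entry_type, "Reviewed"))
    return(verdict(TRUE, 1L))
  if (pe %in% 1:3)
    return(verdict(TRUE, 2L))
  failed <- character(0)
  seq <- as.character(record$sequence)
  len <- nchar(seq)
  if ("version" %in% params$checks &&
      record$sequence_version > params$max_version)
    failed <- c(failed, "version")
  if ("compositional_bias" %in% params$checks &&
      low_complexity_fraction(seq, params$bias_window,
                              params$bias_entropy_min) > params$bias_max)
    failed <- c(failed, "compositional_bias")
  if ("nonstandard_aa" %in% params$checks &&
      .nonstandard_fraction(seq) > params$ns_max)
    failed <- c(failed, "nonstandard_aa")
  if ("length" %in% params$checks &&
      (len < params$min_length || len > params$max_length))
    failed <- c(failed, "length")
  if ("crossrefs" %in% params$checks &&
      record$domain_count == 0L && record$xref_count == 0L)
    failed <- c(failed, "crossrefs")
  verdict(length(failed) == 0L, 3L, failed)
}

#' Validate a batch of metadata records
#'
#' @param records data.frame of records (see [validate_record()]).
#' @param params A [validation_params()].
#' @return data.frame with `accession`, `passed`, `deciding_step`,
#'   `failed_checks` (comma-joined, `""` when none).
#' @export
validate_records <- function(records, params = validation_params()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    v <- validate_record(records[i, , drop = FALSE], params)
    data.frame(accession = v$accession, passed = v$passed,
               deciding_step = v$deciding_step,
               failed_checks = paste(v$failed_checks, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write metadata records
#'
#' TSV (one record per row, columns as in [make_metadata()]) or JSON (an
#' array of record objects).
#'
#' @param path File path; format chosen by extension (`.json` vs TSV).
#' @return `read_metadata()`: records data.frame; `write_metadata()`:
#'   `path`, invisibly.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}

#' @rdname read_metadata
#' @param records Records data.frame.
#' @export
write_metadata <- function(records, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
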