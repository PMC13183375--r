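# Curated ion-channel annotation table: TSV serialization of the Table-1
# style schema, invariant checks, and summary tallies.

.ann_header_map <- c(
  "UniProt"                  = "accession",
  "Name"                     = "name",
  "Symbol"                   = "symbol",
  "Target Development Level" = "tdl",
  "Length"                   = "length",
  "Family designation"       = "family",
  "Group"                    = "group",
  "Unit"                     = "unit",
  "Ion"                      = "ion",
  "Gate mechanism"           = "gating",
  "TMsList"                  = "tms_list",
  "Pore domain start"        = "pore_start",
  "Pore domain end"          = "pore_end",
  "Complex evidence"         = "complex_evidence",
  "Two pore"                 = "two_pore",
  "Verified"                 = "verified"
)

.unit_in <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(x)))
  map <- c(pore_containing = "pore_containing", two_pore = "two_pore",
           auxiliary = "auxiliary", excluded = "excluded")
  out <- map[key]
  if (anyNA(out))
    stopf("unknown unit value(s): %s",
          paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

.unit_out <- function(x) {
  map <- c(pore_containing = "Pore-containing", two_pore = "Two-pore",
           auxiliary = "Auxiliary", excluded = "Excluded")
  unname(map[x])
}

#' Read a curated ion-channel annotation table
#'
#' Reads a UTF-8 TSV whose header uses the curated-table column labels
#' (at minimum `UniProt` and `Unit`; typically also `Name`, `Symbol`,
#' `Target Development Level`, `Length`, `Family designation`, `Group`,
#' `Ion`, `Gate mechanism`, `TMsList`, `Pore domain start`,
#' `Pore domain end`). Known columns are mapped to canonical names; unknown
#' columns are preserved untouched so that round-tripping through
#' [write_annotation_table()] is the identity.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of class `"channel_annotation_table"` with canonical
#'   columns (`accession`, `unit`, `tdl`, `family`, `tms_list`, `pore_start`,
#'   `pore_end`, ...) plus any extra columns. Unit values are normalized to
#'   `pore_containing` / `two_pore` / `auxiliary` / `excluded`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stopf("annotation table not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = "", colClasses = "character",
                           fileEncoding = "UTF-8")
  missing <- setdiff(c("UniProt", "Unit"), names(raw))
  if (length(missing))
    stopf("annotation table is missing mandatory column(s): %s",
          paste(missing, collapse = ", "))
  known <- names(raw) %in% names(.ann_header_map)
  names(raw)[known] <- .ann_header_map[names(raw)[known]]
  raw$unit <- .unit_in(raw$unit)
  for (col in c("length", "pore_start", "pore_end"))
    if (col %in% names(raw)) raw[[col]] <- as.integer(raw[[col]])
  for (col in c("complex_evidence", "two_pore", "verified"))
    if (col %in% names(raw)) raw[[col]] <- toupper(raw[[col]]) %in% c("TRUE", "YES", "1")
  class(raw) <- c("channel_annotation_table", "data.frame")
  raw
}

#' Write a curated ion-channel annotation table
#'
#' @param tab Table as returned by [read_annotation_table()] (or built in
#'   code with the same canonical column names).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(tab, path) {
  out <- as.data.frame(tab, check.names = FALSE)
  if (!"accession" %in% names(out) || !"unit" %in% names(out))
    stopf("annotation table must carry 'accession' and 'unit' columns")
  out$unit <- .unit_out(out$unit)
  rev_map <- stats::setNames(names(.ann_header_map), .ann_header_map)
  known <- names(out) %in% names(rev_map)
  names(out)[known] <- rev_map[names(out)[known]]
  for (col in names(out))
    if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Check annotation-table invariants
#'
#' Verifies, per row, that the structural-unit call is consistent with the
#' rest of the record: an auxiliary subunit must have no pore domain and must
#' carry complex evidence; a (two-)pore-containing entry must have a pore
#' domain that spans every TM segment in its segment list; the target
#' development level must be one of the four knowledge tiers.
#'
#' @param tab A `"channel_annotation_table"`.
#' @return data.frame with columns `accession` and `problem`; zero rows when
#'   the table is internally consistent.
#' @export
check_annotation_table <- function(tab) {
  probs <- list()
  note <- function(acc, msg)
    probs[[length(probs) + 1L]] <<- data.frame(accession = acc, problem = msg,
                                               stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    acc <- tab$accession[i]
    has_pore <- !is.null(tab$pore_start) && !is.na(tab$pore_start[i]) &&
      !is.na(tab$pore_end[i])
    unit <- tab$unit[i]
    if (unit == "auxiliary" && has_pore)
      note(acc, "unit is auxiliary but a pore domain is present")
    if (unit == "auxiliary" && isFALSE(tab$complex_evidence[i]))
      note(acc, "unit is auxiliary but complex evidence is absent")
    if (unit %in% c("pore_containing", "two_pore") && !has_pore)
      note(acc, "unit is pore-containing but no pore domain is recorded")
    if (has_pore && !is.null(tab$tms_list) && !is.na(tab$tms_list[i])) {
      segs <- tryCatch(parse_segment_list(tab$tms_list[i]), error = function(e) NULL)
      if (is.null(segs)) {
        note(acc, "TMsList does not parse")
      } else {
        tm <- segs[segs$kind == "TM", , drop = FALSE]
        if (nrow(tm) > 0L &&
            (tab$pore_start[i] > min(tm$start) || tab$pore_end[i] < max(tm$end)))
          note(acc, "pore domain does not span all TM segments")
      }
    }
    if (!is.null(tab$tdl) && !is.na(tab$tdl[i]) &&
        !tab$tdl[i] %in% c("Tclin", "Tchem", "Tbio", "Tdark"))
      note(acc, sprintf("unknown target development level '%s'", tab$tdl[i]))
  }
  if (!length(probs))
    return(data.frame(accession = character(), problem = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, probs)
}

#' Tally a curated annotation table
#'
#' @param tab A `"channel_annotation_table"`.
#' @return A list with `n_total`, `by_unit` (named counts), `n_families`
#'   (distinct family designations), and `by_tdl` (named counts over the four
#'   target development levels).
#' @export
summarize_annotation_table <- function(tab) {
  by_unit <- table(factor(tab$unit, levels = c("pore_containing", "two_pore",
                                               "auxiliary", "excluded")))
  by_tdl <- if (!is.null(tab$tdl))
    table(factor(tab$tdl, levels = c("Tclin", "Tchem", "Tbio", "Tdark")))
  else table(factor(character(), levels = c("Tclin", "Tchem", "Tbio", "Tdark")))
  list(n_total = nrow(tab),
       by_unit = c(by_unit),
       n_families = if (!is.null(tab$family))
         length(unique(tab$family[!is.na(tab$family)])) else 0L,
       by_tdl = c(by_tdl))
}
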