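#' Parse a membrane-segment list
#'
#' Curated ion-channel tables encode the membrane topology of a protein as a
#' comma-separated list of `K:start-end` tokens, where `K` is `T` for a
#' transmembrane (TM) segment that fully crosses the bilayer and `I` for an
#' intramembrane (IM) segment that only partially embeds. Coordinates are
#' 1-based inclusive residue indices (UniProt convention). Both the en-dash
#' and the plain hyphen are accepted as the coordinate separator.
#'
#' @param text Segment-list string, e.g. `"T:8-36,T:49-66,I:71-76"`. An
#'   empty string yields an empty segment table.
#' @return A data.frame with columns `kind` (`"TM"` or `"IM"`), `start`,
#'   `end` (integers), one row per segment, in input order.
#' @seealso [format_segment_list()], [derive_pore_domain()]
#' @examples
#' parse_segment_list("T:8-36,T:49-66,I:71-76")
#' @export
parse_segment_list <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(kind = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  text <- trimws(text)
  if (is.na(text) || !nzchar(text)) return(empty)
  tokens <- strsplit(text, ",", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  out <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Za-z]):([0-9]+)[–-]([0-9]+)$", tok))[[1]]
    if (length(m) != 4L)
      stopf("malformed segment token: '%s'", tok)
    code <- toupper(m[2])
    if (!code %in% c("T", "I"))
      stopf("unknown segment kind code in token '%s' (expected T or I)", tok)
    start <- as.integer(m[3]); end <- as.integer(m[4])
    if (start < 1L)
      stopf("segment start must be >= 1 in token '%s'", tok)
    if (end < start)
      stopf("segment end < start in token '%s'", tok)
    data.frame(kind = if (code == "T") "TM" else "IM",
               start = start, end = end, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Format a membrane-segment table back to its string form
#'
#' Inverse of [parse_segment_list()]; always emits the plain hyphen.
#'
#' @param segments data.frame as returned by [parse_segment_list()].
#' @return A single string; empty segments give `""`.
#' @export
format_segment_list <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) return("")
  stopifnot(all(segments$kind %in% c("TM", "IM")))
  code <- ifelse(segments$kind == "TM", "T", "I")
  paste0(code, ":", segments$start, "-", segments$end, collapse = ",")
}

#' Derive the pore-containing functional domain from membrane segments
#'
#' The pore-containing functional domain of an ion channel is defined as the
#' sequence span that covers the pore region and every transmembrane segment:
#' it runs from the first residue of the first TM segment to the last residue
#' of the last TM segment. Intramembrane segments do not extend the span
#' (they always fall between TMs in curated topologies). The curated tables
#' print the domain length as `end - start`; the inclusive residue count is
#' exposed separately as `span`.
#'
#' @param segments data.frame of membrane segments ([parse_segment_list()]).
#' @return A list with `start`, `end`, `reported_length` (= end - start) and
#'   `span` (= end - start + 1), class `"pore_domain"`.
#' @examples
#' segs <- parse_segment_list("T:8-36,T:49-66,T:208-228")
#' derive_pore_domain(segs)
#' @export
derive_pore_domain <- function(segments) {
  tm <- segments[segments$kind == "TM", , drop = FALSE]
  if (nrow(tm) == 0L)
    stopf("no pore-containing domain derivable: no TM segment present")
  start <- min(tm$start)
  end <- max(tm$end)
  structure(list(start = start, end = end,
                 reported_length = end - start,
                 span = end - start + 1L),
            class = "pore_domain")
}

#' @export
print.pore_domain <- function(x, ...) {
  cat(sprintf("pore domain %d-%d (reported length %d, span %d)\n",
              x$start, x$end, x$reported_length, x$span))
  invisible(x)
}

#' Classify the structural unit of an ion-channel entry
#'
#' An entry with a derivable pore domain is a pore-containing channel (or a
#' two-pore channel when curation says it carries two tandem pore-conducting
#' regions). An entry without a pore domain is an auxiliary subunit if there
#' is experimental evidence of membership in an ion-channel complex, and is
#' excluded from the curated channel list otherwise.
#'
#' @param pore_domain A `"pore_domain"` object or `NULL` when no domain is
#'   derivable.
#' @param complex_evidence Logical; experimental evidence that the protein is
#'   part of an IC complex.
#' @param curated_two_pore Logical; curated flag for tandem two-pore
#'   architecture (not computed from sequence).
#' @return One of `"two_pore"`, `"pore_containing"`, `"auxiliary"`,
#'   `"excluded"`.
#' @export
classify_unit <- function(pore_domain, complex_evidence,
                          curated_two_pore = FALSE) {
  stopifnot(is.logical(complex_evidence), length(complex_evidence) == 1L,
            is.logical(curated_two_pore), length(curated_two_pore) == 1L)
  if (!is.null(pore_domain)) {
    if (curated_two_pore) "two_pore" else "pore_containing"
  } else if (complex_evidence) "auxiliary" else "excluded"
}
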