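# IUPAC nucleotide code tables and degenerate-motif primitives.

#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

#' Stop with a classed validation error
#' @noRd
validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("allelepam_validation_error", "error")))
}

#' Stop with a classed contract-violation error
#' @noRd
contract_error <- function(msg) {
  stop(errorCondition(msg, class = c("allelepam_contract_error", "error")))
}

#' Validate and normalize a plain DNA string
#'
#' Uppercases the input and checks that every character is one of A, C, G, T.
#' Flanks and alleles must be unambiguous: IUPAC ambiguity codes (including N
#' from a reference genome) are rejected because an ambiguous base makes the
#' allele-specificity decision undecidable.  The empty string is allowed (it is
#' the representation of the absent allele of an insertion or deletion).
#'
#' @param s character scalar.
#' @param what label used in error messages (e.g. "upstream flank").
#' @return The normalized (uppercase) string.
#' @export
#' @examples
#' validate_sequence("acgt")
validate_sequence <- function(s, what = "sequence") {
  if (length(s) != 1L || is.na(s) || !is.character(s))
    validation_error(sprintf("%s must be a single character string", what))
  s <- toupper(s)
  if (nzchar(s)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    if (length(bad))
      validation_error(sprintf(
        "invalid character '%s' in %s at position %d (0-based; only A/C/G/T allowed)",
        chars[bad[1L]], what, bad[1L] - 1L))
  }
  s
}

#' Validate an IUPAC motif pattern
#' @noRd
validate_iupac <- function(pattern, what = "PAM pattern") {
  if (length(pattern) != 1L || is.na(pattern) || !is.character(pattern) ||
      !nzchar(pattern))
    validation_error(sprintf("%s must be a non-empty character string", what))
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% IUPAC_CODES)
  if (length(bad))
    validation_error(sprintf(
      "invalid IUPAC character '%s' in %s at position %d (0-based)",
      chars[bad[1L]], what, bad[1L] - 1L))
  pattern
}

# fixed IUPAC complement translation table
COMP_FROM <- "ACGTRYWSKMBDHVN"
COMP_TO   <- "TGCAYRWSMKVHDBN"

#' Reverse complement of a DNA or IUPAC string
#'
#' Full IUPAC complementing (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H;
#' W, S and N are self-complementary).
#'
#' @param s character scalar over IUPAC codes; may be empty.
#' @return The reverse complement as a character scalar.
#' @export
#' @examples
#' revcomp("TTCN")  # "NGAA"
revcomp <- function(s) {
  if (length(s) != 1L || is.na(s) || !is.character(s))
    validation_error("revcomp() expects a single character string")
  s <- toupper(s)
  if (!nzchar(s)) return(s)
  if (grepl(sprintf("[^%s]", COMP_FROM), s))
    validation_error(sprintf("invalid nucleotide code in '%s'", s))
  intToUtf8(rev(utf8ToInt(chartr(COMP_FROM, COMP_TO, s))))
}

# cache of compiled anchored regexes, keyed by pattern
.regex_cache <- new.env(parent = emptyenv())

#' Convert a degenerate motif to an anchored regular expression
#' @noRd
motif_regex <- function(pattern) {
  cached <- .regex_cache[[pattern]]
  if (!is.null(cached)) return(cached)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  rx <- paste0("^", paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1L)), collapse = ""), "$")
  .regex_cache[[pattern]] <- rx
  rx
}

#' Match a concrete DNA window against a degenerate PAM motif
#'
#' @param motif IUPAC pattern string (e.g. "NNGRRT").
#' @param window concrete A/C/G/T string of the same length.
#' @return TRUE iff every window base lies in the IUPAC set of the
#'   corresponding motif position.
#' @export
#' @examples
#' iupac_match("NNGRRT", "AAGAGT")
iupac_match <- function(motif, window) {
  motif <- validate_iupac(motif)
  window <- validate_sequence(window, "window")
  if (nchar(window) != nchar(motif))
    contract_error(sprintf(
      "window length %d does not match motif length %d",
      nchar(window), nchar(motif)))
  grepl(motif_regex(motif), window, perl = TRUE)
}

#' Vectorized internal matcher (windows pre-validated)
#' @noRd
iupac_match_many <- function(pattern, windows) {
  if (!length(windows)) return(logical(0))
  grepl(motif_regex(pattern), windows, perl = TRUE)
}

# cache of concrete expansions, keyed by pattern
.motif_cache <- new.env(parent = emptyenv())

#' Enumerate all concrete sequences matching a degenerate motif
#'
#' The result size is the product of per-position code cardinalities
#' (e.g. "NNGRRT" expands to 4*4*1*2*2*1 = 64 sequences).
#'
#' @param motif IUPAC pattern string.
#' @return character vector of concrete A/C/G/T strings.
#' @export
#' @examples
#' length(expand_motif("NGG"))  # 4
expand_motif <- function(motif) {
  motif <- validate_iupac(motif)
  cached <- .motif_cache[[motif]]
  if (!is.null(cached)) return(cached)
  sets <- unname(IUPAC_SETS[strsplit(motif, "", fixed = TRUE)[[1L]]])
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  out <- do.call(paste0, rev(grid))
  .motif_cache[[motif]] <- out
  out
}
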