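# Variant records and materialization of reference/variant allele sequences.
#
# Coordinate convention: 0-based, half-open intervals on the plus strand of
# the sequence being indexed.  The variant-allele sequence (var_seq) is the
# canonical reporting frame.

#' Construct a variant record
#'
#' One single-nucleotide variant (substitution, single-base insertion or
#' single-base deletion) with its flanking sequences.  Alleles are 0- or
#' 1-base strings; the empty string is the absent side of an indel.
#' Multi-allelic sites list several alternate alleles; each is analysed
#' individually.
#'
#' @param id record identifier.
#' @param upstream plus-strand flank immediately 5' of the variant.
#' @param ref_allele reference allele, "" or one base.
#' @param alt_alleles character vector of alternate alleles ("" or one base),
#'   each different from \code{ref_allele}.
#' @param downstream plus-strand flank immediately 3' of the variant.
#' @return object of class "variant_record".
#' @export
#' @examples
#' variant_record("rs1", "TT", "C", "T", "TA")
variant_record <- function(id, upstream, ref_allele, alt_alleles, downstream) {
  upstream <- validate_sequence(upstream, "upstream flank")
  downstream <- validate_sequence(downstream, "downstream flank")
  ref_allele <- validate_sequence(ref_allele, "reference allele")
  if (nchar(ref_allele) > 1L)
    validation_error("reference allele must be empty or a single base")
  if (!length(alt_alleles))
    validation_error("at least one alternate allele is required")
  alt_alleles <- vapply(alt_alleles, validate_sequence, character(1L),
                        what = "alternate allele", USE.NAMES = FALSE)
  for (alt in alt_alleles) {
    if (nchar(alt) > 1L)
      validation_error("alternate alleles must be empty or a single base")
    if (identical(alt, ref_allele))
      validation_error("alternate allele equals the reference allele")
    if (!nzchar(alt) && !nzchar(ref_allele))
      validation_error("reference and alternate alleles cannot both be empty")
  }
  if (anyDuplicated(alt_alleles))
    validation_error("duplicate alternate alleles")
  structure(list(
    id = as.character(id),
    upstream = upstream,
    ref_allele = ref_allele,
    alt_alleles = alt_alleles,
    downstream = downstream
  ), class = "variant_record")
}

#' Variant type of one alternate allele
#' @param record a "variant_record".
#' @param alt one of \code{record$alt_alleles}.
#' @return "substitution", "insertion" or "deletion".
#' @export
variant_type <- function(record, alt = record$alt_alleles[[1L]]) {
  r <- nchar(record$ref_allele); a <- nchar(alt)
  if (r == 1L && a == 1L) "substitution"
  else if (r == 0L && a == 1L) "insertion"
  else if (r == 1L && a == 0L) "deletion"
  else validation_error("unsupported allele length combination")
}

#' Materialize reference and variant allele sequences for one alt allele
#'
#' Builds ref_seq = upstream + ref + downstream and
#' var_seq = upstream + alt + downstream, plus the variant-affected intervals
#' in both frames (0-based, half-open):
#' \itemize{
#'   \item substitution: the alt base in var_seq, the ref base in ref_seq;
#'   \item insertion: the inserted base in var_seq; in ref_seq the zero-length
#'     junction widened to one base each side (clipped to bounds), since an
#'     insertion-derived PAM arises by juxtaposition at the junction;
#'   \item deletion: the two bases flanking the deletion junction in var_seq
#'     (clipped); the deleted base in ref_seq.
#' }
#' A candidate PAM window must overlap the affected interval; the homologous
#' reference-frame interval anchors the reference-rejection check.
#'
#' @param record a "variant_record".
#' @param alt one of the record's alternate alleles.
#' @return object of class "allele_context" with fields ref_seq, var_seq,
#'   affected (in var_seq), ref_affected (in ref_seq), alt_used, upstream_len.
#' @export
#' @examples
#' build_alleles(variant_record("r", "ACG", "T", "G", "TTA"), "G")
build_alleles <- function(record, alt = record$alt_alleles[[1L]]) {
  stopifnot(inherits(record, "variant_record"))
  alt <- toupper(alt)
  if (!alt %in% record$alt_alleles)
    contract_error(sprintf("allele '%s' is not an alternate allele of record '%s'",
                           alt, record$id))
  u <- nchar(record$upstream)
  type <- variant_type(record, alt)
  var_seq <- paste0(record$upstream, alt, record$downstream)
  ref_seq <- paste0(record$upstream, record$ref_allele, record$downstream)
  clip <- function(iv, len) c(max(0L, iv[1L]), min(len, iv[2L]))
  affected <- switch(type,
    substitution = c(u, u + 1L),
    insertion    = c(u, u + 1L),
    deletion     = clip(c(u - 1L, u + 1L), nchar(var_seq)))
  ref_affected <- switch(type,
    substitution = c(u, u + 1L),
    insertion    = clip(c(u - 1L, u + 1L), nchar(ref_seq)),
    deletion     = c(u, u + 1L))
  structure(list(
    ref_seq = ref_seq,
    var_seq = var_seq,
    affected = as.integer(affected),
    ref_affected = as.integer(ref_affected),
    alt_used = alt,
    upstream_len = u,
    variant_type = type,
    record_id = record$id
  ), class = "allele_context")
}

#' Map a var_seq interval to its homologous ref_seq interval
#'
#' Positions 5' of the variant are unchanged; positions 3' of it shift by
#' len(ref) - len(alt).  The resulting interval may differ in length from the
#' input for indels (it absorbs or drops the varying base).
#' @noRd
map_to_ref <- function(ctx, iv) {
  u <- ctx$upstream_len
  delta <- nchar(ctx$ref_seq) - nchar(ctx$var_seq)
  alt_len <- nchar(ctx$alt_used)
  map_pos <- function(p) if (p <= u) p else max(u, p + delta)
  # for the deletion junction, a window starting exactly at the junction must
  # still cover the deleted base on the reference side
  s <- map_pos(iv[1L]); e <- map_pos(iv[2L])
  if (delta > 0L && iv[1L] >= u && iv[2L] > u) e <- max(e, iv[2L] + delta)
  c(as.integer(s), as.integer(max(s, e)))
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant %s> %s[%s/%s]%s\n", x$id, x$upstream,
              if (nzchar(x$ref_allele)) x$ref_allele else "-",
              paste(ifelse(nzchar(x$alt_alleles), x$alt_alleles, "-"),
                    collapse = ","),
              x$downstream))
  invisible(x)
}
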