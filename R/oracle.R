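# Independent re-derivation of the scan by literal substring search over the
# full concrete expansion of every motif.  Used as a verification oracle in
# tests and inside the fixture generator; deliberately shares no window
# enumeration or degenerate-matching code with scan_variant.

# all 0-based starts where any member of `expansions` occurs in s as a literal
# substring, for a fixed word length
literal_hits <- function(s, expansions, word_len) {
  n <- nchar(s)
  if (n < word_len) return(integer(0))
  starts <- 0:(n - word_len)
  words <- substring(s, starts + 1L, starts + word_len)
  starts[words %in% expansions]
}

overlaps <- function(starts, word_len, iv) {
  starts + word_len > iv[1L] & starts < iv[2L]
}

#' Brute-force reference scan oracle
#'
#' Recomputes \code{\link{scan_variant}} from first principles: every motif is
#' expanded to its full set of concrete sequences
#' (\code{\link{expand_motif}}), matches are found by literal substring
#' equality on both explicitly constructed strands, and the same
#' allele-specificity acceptance rule is applied (reject an enzyme on a
#' strand if any of its motifs -- primary or off-target -- literally occurs
#' on the reference sequence overlapping the locus).  Quadratic and
#' allocation-heavy by design; intended for verification on short contexts.
#'
#' @param record a \code{\link{variant_record}}.
#' @param registry a "cas_registry" (all motifs must be of modest length so
#'   the expansions stay enumerable).
#' @return data.frame with columns record_id, alt, cas, motif, strand,
#'   pam_start, pam_end (plus-strand var_seq coordinates), comparable
#'   order-insensitively with the corresponding scan_variant columns.
#' @export
brute_force_oracle <- function(record, registry = pam_registry()) {
  stopifnot(inherits(record, "variant_record"),
            inherits(registry, "cas_registry"))
  out <- list(); n_out <- 0L
  for (alt in record$alt_alleles) {
    ctx <- build_alleles(record, alt)
    L <- nchar(ctx$var_seq)
    frames <- list(
      list(strand = "+", v = ctx$var_seq, r = ctx$ref_seq,
           av = ctx$affected, ar = ctx$ref_affected),
      list(strand = "-", v = revcomp(ctx$var_seq), r = revcomp(ctx$ref_seq),
           av = c(L - ctx$affected[2L], L - ctx$affected[1L]),
           ar = c(nchar(ctx$ref_seq) - ctx$ref_affected[2L],
                  nchar(ctx$ref_seq) - ctx$ref_affected[1L])))
    for (enz in registry) {
      for (fr in frames) {
        blocked <- FALSE
        for (m in c(enz$primary_motifs, enz$off_target_motifs)) {
          wl <- nchar(m)
          hs <- literal_hits(fr$r, expand_motif(m), wl)
          if (any(overlaps(hs, wl, fr$ar))) { blocked <- TRUE; break }
        }
        if (blocked) next
        for (m in enz$primary_motifs) {
          wl <- nchar(m)
          hs <- literal_hits(fr$v, expand_motif(m), wl)
          hs <- hs[overlaps(hs, wl, fr$av)]
          for (s in hs) {
            win_plus <- if (fr$strand == "+") c(s, s + wl)
                        else c(L - (s + wl), L - s)
            n_out <- n_out + 1L
            out[[n_out]] <- data.frame(
              record_id = record$id, alt = alt, cas = enz$name, motif = m,
              strand = fr$strand,
              pam_start = as.integer(win_plus[1L]),
              pam_end = as.integer(win_plus[2L]),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!n_out)
    return(data.frame(record_id = character(0), alt = character(0),
                      cas = character(0), motif = character(0),
                      strand = character(0), pam_start = integer(0),
                      pam_end = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
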