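# Core algorithm: enumerate candidate PAM windows overlapping the variant on
# both strands, keep a (Cas, motif, window) only when the variant allele
# matches and the reference allele carries no PAM of that Cas (primary or
# off-target) overlapping the locus on the same strand, and suggest spacers.

#' Scan options
#'
#' @param registry the Cas/PAM registry to scan against.
#' @param scan_minus_strand also scan the complementary strand (default TRUE).
#' @param include_incomplete_grna keep matches whose flank is too short for a
#'   full-length spacer (reported with grna_complete = FALSE); if FALSE such
#'   matches are dropped.
#' @return list of class "scan_options".
#' @export
scan_options <- function(registry = pam_registry(),
                         scan_minus_strand = TRUE,
                         include_incomplete_grna = TRUE) {
  stopifnot(inherits(registry, "cas_registry"))
  structure(list(registry = registry,
                 scan_minus_strand = isTRUE(scan_minus_strand),
                 include_incomplete_grna = isTRUE(include_incomplete_grna)),
            class = "scan_options")
}

#' Candidate PAM windows overlapping the variant
#'
#' All half-open windows of length \code{motif_len} that fit inside the
#' sequence and overlap the affected interval, ascending by start.
#'
#' @param seq_len sequence length.
#' @param affected integer 0-based half-open interval c(start, end).
#' @param motif_len window length (>= 1).
#' @return integer matrix with columns start, end (possibly 0 rows).
#' @export
#' @examples
#' candidate_windows(5, c(2, 3), 4)  # starts 0 and 1
candidate_windows <- function(seq_len, affected, motif_len) {
  seq_len <- as.integer(seq_len); motif_len <- as.integer(motif_len)
  affected <- as.integer(affected)
  if (motif_len < 1L) contract_error("motif_len must be >= 1")
  if (affected[1L] < 0L || affected[2L] > seq_len || affected[1L] > affected[2L])
    contract_error("affected interval out of sequence bounds")
  lo <- max(0L, affected[1L] - motif_len + 1L)
  hi <- min(seq_len - motif_len, affected[2L] - 1L)
  if (hi < lo)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  starts <- lo:hi
  cbind(start = starts, end = starts + motif_len)
}

# substrings of s at 0-based half-open windows (matrix rows)
window_seqs <- function(s, wins) {
  if (!nrow(wins)) return(character(0))
  substring(s, wins[, 1L] + 1L, wins[, 2L])
}

#' Is the reference allele targetable by any PAM of an enzyme at the locus?
#'
#' TRUE iff any motif of the enzyme -- primary or off-target -- matches the
#' reference sequence at some window overlapping the reference-side affected
#' interval on the strand under scan.  A TRUE result vetoes every candidate
#' of this enzyme on that strand: a reference-side PAM means the enzyme could
#' also engage the reference allele, defeating allele specificity.
#'
#' @param cas a "cas_enzyme".
#' @param ref_seq reference sequence in the frame being scanned.
#' @param ref_affected 0-based half-open interval within ref_seq.
#' @return logical scalar.
#' @export
#' @examples
#' reg <- pam_registry()
#' reference_blocked(reg[["SpCas9"]], "TAG", c(1, 2))  # TRUE: NAG off-target
reference_blocked <- function(cas, ref_seq, ref_affected) {
  stopifnot(inherits(cas, "cas_enzyme"))
  n <- nchar(ref_seq)
  for (m in c(cas$primary_motifs, cas$off_target_motifs)) {
    wins <- candidate_windows(n, ref_affected, nchar(m))
    if (nrow(wins) && any(iupac_match_many(m, window_seqs(ref_seq, wins))))
      return(TRUE)
  }
  FALSE
}

# one scanning frame: plus uses the sequences as given; minus uses their
# reverse complements with mirrored affected intervals
make_frames <- function(ctx, minus = TRUE) {
  Lv <- nchar(ctx$var_seq); Lr <- nchar(ctx$ref_seq)
  frames <- list(plus = list(
    strand = "+", var_seq = ctx$var_seq, ref_seq = ctx$ref_seq,
    affected = ctx$affected, ref_affected = ctx$ref_affected, L = Lv))
  if (minus) {
    mirror <- function(iv, L) c(L - iv[2L], L - iv[1L])
    frames$minus <- list(
      strand = "-", var_seq = revcomp(ctx$var_seq), ref_seq = revcomp(ctx$ref_seq),
      affected = mirror(ctx$affected, Lv),
      ref_affected = mirror(ctx$ref_affected, Lr), L = Lv)
  }
  frames
}

# spacer immediately 5' (class II) or 3' (class V) of the PAM window, in the
# scanned frame; truncated when the flank is shorter than spacer_length
spacer_in_frame <- function(frame_seq, win, cas) {
  L <- nchar(frame_seq); k <- cas$spacer_length
  if (cas$cas_class == "II") {
    s <- max(0L, win[1L] - k)
    g <- substring(frame_seq, s + 1L, win[1L])
  } else {
    e <- min(L, win[2L] + k)
    g <- substring(frame_seq, win[2L] + 1L, e)
  }
  list(grna = g, complete = nchar(g) == k)
}

# homologous reference window sequence, read in motif orientation
ref_window_in_frame <- function(ctx, win_plus, strand) {
  riv <- map_to_ref(ctx, win_plus)
  s <- substring(ctx$ref_seq, riv[1L] + 1L, riv[2L])
  if (strand == "-") revcomp(s) else s
}

empty_matches <- function() {
  data.frame(record_id = character(0), alt = character(0), cas = character(0),
             motif = character(0), strand = character(0),
             pam_start = integer(0), pam_end = integer(0),
             pam_seq_variant = character(0), pam_seq_reference = character(0),
             grna = character(0), grna_complete = logical(0),
             cas_class = character(0), cas_origin = character(0),
             approx_size_bp = integer(0), stringsAsFactors = FALSE)
}

#' Scan a variant for allele-specific, variant-derived PAMs
#'
#' For each alternate allele, each strand and each registry enzyme, every
#' candidate window overlapping the variant is tested against the enzyme's
#' primary PAM motifs on the variant allele.  A hit is reported only if the
#' reference allele is not targetable by any PAM of that enzyme (primary or
#' off-target) at the homologous locus on the same strand
#' (\code{\link{reference_blocked}}), so every reported match is guaranteed
#' allele specific.  All matches of a multi-PAM-generating variant are
#' reported.
#'
#' Minus-strand windows are mapped back to plus-strand var_seq coordinates
#' (0-based, half-open); pam_seq_variant/pam_seq_reference are read in motif
#' orientation (reverse-complemented for minus-strand hits).  Output order is
#' deterministic: alt allele, registry order, plus before minus, window start
#' ascending, then motif.
#'
#' @param record a \code{\link{variant_record}}.
#' @param options a \code{\link{scan_options}} object.
#' @return data.frame of matches, one row per (alt, Cas, motif, strand,
#'   window), with suggested spacer (grna) per match.
#' @export
#' @examples
#' rec <- variant_record("ex", "AA", "T", "G", "GA")
#' scan_variant(rec)
scan_variant <- function(record, options = scan_options()) {
  stopifnot(inherits(record, "variant_record"))
  if (!inherits(options, "scan_options"))
    options <- scan_options(options)  # allow passing a registry directly
  registry <- options$registry
  if (!length(registry))
    stop(errorCondition("registry is empty",
                        class = c("allelepam_config_error", "error")))
  rows <- vector("list", 64L); nrows <- 0L
  push <- function(row) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- row
  }
  for (alt_i in seq_along(record$alt_alleles)) {
    alt <- record$alt_alleles[[alt_i]]
    ctx <- build_alleles(record, alt)
    frames <- make_frames(ctx, minus = options$scan_minus_strand)
    for (enz_i in seq_along(registry)) {
      enz <- registry[[enz_i]]
      for (f_i in seq_along(frames)) {
        fr <- frames[[f_i]]
        if (reference_blocked(enz, fr$ref_seq, fr$ref_affected)) next
        for (m_i in seq_along(enz$primary_motifs)) {
          m <- enz$primary_motifs[[m_i]]
          wins <- candidate_windows(fr$L, fr$affected, nchar(m))
          if (!nrow(wins)) next
          hits <- which(iupac_match_many(m, window_seqs(fr$var_seq, wins)))
          for (k in hits) {
            win <- wins[k, ]
            win_plus <- if (fr$strand == "+") win
                        else c(fr$L - win[2L], fr$L - win[1L])
            sp <- spacer_in_frame(fr$var_seq, win, enz)
            push(list(alt_i = alt_i, enz_i = enz_i, f_i = f_i, m_i = m_i,
              record_id = record$id, alt = alt, cas = enz$name, motif = m,
              strand = fr$strand,
              pam_start = as.integer(win_plus[1L]),
              pam_end = as.integer(win_plus[2L]),
              pam_seq_variant = substring(fr$var_seq, win[1L] + 1L, win[2L]),
              pam_seq_reference = ref_window_in_frame(ctx, win_plus, fr$strand),
              grna = sp$grna, grna_complete = sp$complete,
              cas_class = enz$cas_class, cas_origin = enz$origin,
              approx_size_bp = enz$approx_size_bp))
          }
        }
      }
    }
  }
  if (!nrows) return(empty_matches())
  rows <- rows[seq_len(nrows)]
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[-(1:4)], stringsAsFactors = FALSE)))
  ord <- order(vapply(rows, `[[`, integer(1L), "alt_i"),
               vapply(rows, `[[`, integer(1L), "enz_i"),
               vapply(rows, `[[`, integer(1L), "f_i"),
               vapply(rows, `[[`, integer(1L), "pam_start"),
               vapply(rows, `[[`, integer(1L), "m_i"))
  df <- df[ord, , drop = FALSE]
  if (!options$include_incomplete_grna)
    df <- df[df$grna_complete, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Suggest the spacer (gRNA) for a PAM match
#'
#' Class II enzymes (PAM 3' of the protospacer) take the spacer_length bases
#' immediately 5' of the PAM window on the PAM-containing strand; class V
#' enzymes (PAM 5') take the bases immediately 3'.  Returned 5'->3' on the
#' PAM-containing strand; truncated with complete = FALSE when the flank is
#' too short.
#'
#' @param match one row of a \code{\link{scan_variant}} result (or any list
#'   with strand, pam_start, pam_end).
#' @param context the \code{\link{build_alleles}} context the match came from.
#' @param cas the matched "cas_enzyme".
#' @return list(grna = character, complete = logical).
#' @export
suggest_grna <- function(match, context, cas) {
  stopifnot(inherits(context, "allele_context"), inherits(cas, "cas_enzyme"))
  L <- nchar(context$var_seq)
  if (match$strand == "-") {
    frame_seq <- revcomp(context$var_seq)
    win <- c(L - match$pam_end, L - match$pam_start)
  } else {
    frame_seq <- context$var_seq
    win <- c(match$pam_start, match$pam_end)
  }
  spacer_in_frame(frame_seq, as.integer(win), cas)
}
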