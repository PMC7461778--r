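# shared test utilities: random record generators and independent checkers

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(len) paste(sample(BASES4, len, replace = TRUE), collapse = "")

# random substitution (or, with p_indel, single-base indel) record;
# relies on the caller having fixed the RNG seed
rand_record <- function(id, flank_min = 10, flank_max = 10, p_indel = 0) {
  up <- rand_seq(sample(flank_min:flank_max, 1L))
  down <- rand_seq(sample(flank_min:flank_max, 1L))
  roll <- runif(1)
  if (roll < p_indel / 2) {              # insertion
    variant_record(id, up, "", sample(BASES4, 1L), down)
  } else if (roll < p_indel) {           # deletion
    variant_record(id, up, sample(BASES4, 1L), "", down)
  } else {
    ref <- sample(BASES4, 1L)
    variant_record(id, up, ref, sample(setdiff(BASES4, ref), 1L), down)
  }
}

# order-insensitive canonical key of a match table
match_key <- function(df) {
  sort(paste(df$alt, df$cas, df$motif, df$strand, df$pam_start, df$pam_end,
             sep = "|"))
}

# the reverse-complemented view of a record: flanks swapped and
# reverse-complemented, alleles complemented
flip_record <- function(rec) {
  variant_record(rec$id, revcomp(rec$downstream), revcomp(rec$ref_allele),
                 vapply(rec$alt_alleles, revcomp, character(1L),
                        USE.NAMES = FALSE),
                 revcomp(rec$upstream))
}

# independent allele-specificity recheck for one emitted match: TRUE iff no
# motif (primary or off-target) of the matched enzyme literally occurs on the
# reference allele at a window overlapping the locus on the matched strand.
# Uses expand_motif() membership only; shares no code with reference_blocked.
specificity_holds <- function(match_row, record, registry) {
  enz <- registry[[match_row$cas]]
  ctx <- build_alleles(record, match_row$alt)
  ref <- ctx$ref_seq; iv <- ctx$ref_affected
  if (match_row$strand == "-") {
    L <- nchar(ref)
    ref <- revcomp(ref)
    iv <- c(L - iv[2L], L - iv[1L])
  }
  n <- nchar(ref)
  for (m in c(enz$primary_motifs, enz$off_target_motifs)) {
    wl <- nchar(m)
    if (n < wl) next
    words <- expand_motif(m)
    for (s in 0:(n - wl)) {
      if (s + wl > iv[1L] && s < iv[2L] &&
          substring(ref, s + 1L, s + wl) %in% words)
        return(FALSE)
    }
  }
  TRUE
}
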