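# Seeded generator of variant records with known ground truth: planted
# PAM-generating substitutions for a chosen Cas/motif, guaranteed negatives,
# and whole cohorts.  Every emitted record is self-verified against the
# brute-force oracle before it leaves the generator, so planted truth is
# never asserted on construction alone.

BASES <- c("A", "C", "G", "T")

random_flank <- function(len, gc = 0.5) {
  if (len <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

generation_failure <- function(msg) {
  stop(errorCondition(msg, class = c("allelepam_generation_failure", "error")))
}

single_enzyme_registry <- function(cas) new_registry(list(cas))

#' Plant a guaranteed PAM-generating substitution for one enzyme
#'
#' Samples a concrete realization of the motif, places it over a designated
#' variant base embedded in random flanks, sets the alternate allele to the
#' motif base at that offset, and searches for a reference base such that the
#' enzyme has no PAM (primary or off-target) on the reference allele
#' overlapping the locus.  The candidate is verified with
#' \code{\link{brute_force_oracle}} before being returned; flanks and offsets
#' are resampled (bounded) when no valid reference base exists, e.g. when the
#' sampled motif offset is an N position that any base would satisfy.
#'
#' Deterministic given (cas, motif, flank_len, seed).
#'
#' @param cas a "cas_enzyme".
#' @param motif one of the enzyme's primary motifs (default: the first).
#' @param flank_len flank length on each side; must accommodate motif plus a
#'   full spacer so planted records carry complete gRNAs.
#' @param seed integer seed (the global RNG state is left untouched).
#' @param id record identifier.
#' @param gc flank GC fraction (default 0.5, uniform base composition).
#' @param max_tries resampling budget before giving up.
#' @return list(record = variant_record, truth = one-row data.frame with
#'   record_id, expected_matched, planted_cas, planted_motif,
#'   planted_window_offset).
#' @export
#' @examples
#' pp <- plant_positive(pam_registry()[["SaCas9"]], seed = 1)
plant_positive <- function(cas, motif = cas$primary_motifs[[1L]],
                           flank_len = 30L, seed = 1L, id = "planted+",
                           gc = 0.5, max_tries = 100L) {
  stopifnot(inherits(cas, "cas_enzyme"))
  if (!motif %in% cas$primary_motifs)
    contract_error(sprintf("'%s' is not a primary motif of %s", motif, cas$name))
  wl <- nchar(motif)
  if (flank_len < wl + cas$spacer_length)
    contract_error("flank_len must be >= motif length + spacer length")
  reg1 <- single_enzyme_registry(cas)
  words <- expand_motif(motif)
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      w <- sample(words, 1L)
      # prefer constrained motif positions: an N position accepts every base,
      # so the reference allele would carry the same PAM and be blocked
      sets <- IUPAC_SETS[strsplit(motif, "", fixed = TRUE)[[1L]]]
      card <- lengths(sets)
      j <- if (any(card < 4L)) sample(rep(which(card < 4L), 2L), 1L)
           else sample(seq_len(wl), 1L)
      chars <- strsplit(w, "", fixed = TRUE)[[1L]]
      alt <- chars[j]
      up <- paste0(random_flank(flank_len - (j - 1L), gc),
                   paste(chars[seq_len(j - 1L)], collapse = ""))
      down <- paste0(paste(chars[seq_len(wl - j) + j], collapse = ""),
                     random_flank(flank_len - (wl - j), gc))
      for (ref in sample(setdiff(BASES, alt))) {
        rec <- variant_record(id, up, ref, alt, down)
        hits <- brute_force_oracle(rec, reg1)
        if (any(hits$cas == cas$name)) {
          truth <- data.frame(record_id = id, expected_matched = TRUE,
                              planted_cas = cas$name, planted_motif = motif,
                              planted_window_offset = j - 1L,
                              stringsAsFactors = FALSE)
          return(list(record = rec, truth = truth))
        }
      }
    }
  })
  generation_failure(sprintf(
    "could not plant a %s (%s) positive in %d tries", cas$name, motif, max_tries))
}

#' Generate a record guaranteed to have no variant-derived PAM
#'
#' Rejection-samples random substitution records until the brute-force oracle
#' reports zero matches over the whole registry (a cheap scan pre-filter runs
#' first).  Deterministic given seed; fails after a bounded attempt budget.
#'
#' @param flank_len flank length on each side (>= 8).
#' @param registry registry the record must be negative against.
#' @param seed integer seed.
#' @param id record identifier.
#' @param gc flank GC fraction.
#' @param max_tries attempt budget (default 10000).
#' @return list(record, truth) as in \code{\link{plant_positive}} with
#'   expected_matched = FALSE and no planted enzyme.
#' @export
plant_negative <- function(flank_len = 10L, registry = pam_registry(),
                           seed = 1L, id = "planted-", gc = 0.5,
                           max_tries = 10000L) {
  if (flank_len < 8L) contract_error("flank_len must be >= 8")
  opts <- scan_options(registry)
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      ref <- sample(BASES, 1L)
      alt <- sample(setdiff(BASES, ref), 1L)
      rec <- variant_record(id, random_flank(flank_len, gc), ref, alt,
                            random_flank(flank_len, gc))
      if (nrow(scan_variant(rec, opts)) == 0L &&
          nrow(brute_force_oracle(rec, registry)) == 0L) {
        truth <- data.frame(record_id = id, expected_matched = FALSE,
                            planted_cas = NA_character_,
                            planted_motif = NA_character_,
                            planted_window_offset = NA_integer_,
                            stringsAsFactors = FALSE)
        return(list(record = rec, truth = truth))
      }
    }
  })
  generation_failure(sprintf(
    "no PAM-free substitution record found in %d tries", max_tries))
}

#' Build a shuffled cohort with planted ground truth
#'
#' Plants \code{n_positive_per_cas} positive records per registry enzyme
#' (cycling through the enzyme's primary motifs) and \code{n_negative}
#' guaranteed negatives, then shuffles deterministically.  The truth table
#' additionally records, per record, the full set of matching enzymes as
#' established by the brute-force oracle over the whole registry, so cohort
#' summaries can be checked field by field against an independently derived
#' truth.
#'
#' @param n_positive_per_cas positives per enzyme (>= 0).
#' @param n_negative negatives (>= 0); sizes must not both be zero.
#' @param seed integer seed.
#' @param registry a "cas_registry".
#' @param flank_len flank length for all records.
#' @param gc flank GC fraction.
#' @return list(records = list of variant_record, truths = data.frame with
#'   one row per record incl. matched_cas).
#' @export
make_cohort <- function(n_positive_per_cas, n_negative, seed = 1L,
                        registry = pam_registry(), flank_len = 30L,
                        gc = 0.5) {
  if (n_positive_per_cas < 0L || n_negative < 0L ||
      (n_positive_per_cas == 0L && n_negative == 0L))
    contract_error("cohort sizes must be >= 0 and not both zero")
  n_pos <- n_positive_per_cas * length(registry)
  n <- n_pos + n_negative
  out_rec <- vector("list", n)
  out_truth <- vector("list", n)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n + 1L))
  i <- 0L
  for (enz in registry) {
    for (k in seq_len(n_positive_per_cas)) {
      i <- i + 1L
      motif <- enz$primary_motifs[[(k - 1L) %% length(enz$primary_motifs) + 1L]]
      pp <- plant_positive(enz, motif, flank_len = flank_len,
                           seed = seeds[i], id = sprintf("pos_%03d", i),
                           gc = gc)
      out_rec[[i]] <- pp$record; out_truth[[i]] <- pp$truth
    }
  }
  for (k in seq_len(n_negative)) {
    i <- i + 1L
    pn <- plant_negative(flank_len = max(8L, flank_len), registry = registry,
                         seed = seeds[i], id = sprintf("neg_%03d", i), gc = gc)
    out_rec[[i]] <- pn$record; out_truth[[i]] <- pn$truth
  }
  truths <- do.call(rbind, out_truth)
  truths$matched_cas <- vapply(out_rec, function(rec)
    paste(unique(brute_force_oracle(rec, registry)$cas), collapse = ","),
    character(1L))
  perm <- withr::with_seed(seeds[n + 1L], sample.int(n))
  list(records = out_rec[perm],
       truths = { t <- truths[perm, , drop = FALSE]; rownames(t) <- NULL; t })
}
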