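# Cohort-level targetability statistics: fraction of variants with at least
# one variant-derived PAM, per-Cas coverage, exclusive and
# exclusively-synthetic matches, and the substitution-type profile of
# untargetable records.

SUBSTITUTION_TYPES <- c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              function(r, a) paste0(r, ">", a)))
SUBSTITUTION_TYPES <- SUBSTITUTION_TYPES[
  substr(SUBSTITUTION_TYPES, 1, 1) != substr(SUBSTITUTION_TYPES, 3, 3)]

#' Directed substitution type of a variant allele
#'
#' @param record a \code{\link{variant_record}}.
#' @param alt one of the record's alternate alleles.
#' @return "R>A" style directed type (no strand collapsing: C>T and G>A stay
#'   distinct), or NA for insertions/deletions, which have no substitution
#'   type.
#' @export
#' @examples
#' classify_substitution(variant_record("r", "A", "C", "T", "G"), "T")
classify_substitution <- function(record, alt = record$alt_alleles[[1L]]) {
  if (variant_type(record, alt) != "substitution") return(NA_character_)
  paste0(record$ref_allele, ">", alt)
}

#' Summarize allele-specific targetability over a cohort of variants
#'
#' Runs \code{\link{scan_variant}} on every record.  A record counts as
#' matched when any of its alternate alleles yields at least one PAM match.
#' Per-enzyme coverage counts records with >= 1 match for that enzyme;
#' exclusive counts identify records matched by exactly one enzyme, and
#' records whose matching enzymes are all engineered (synthetic) variants --
#' the latter quantifies how much of the targetable space exists only thanks
#' to PAM-relaxed engineered Cas proteins.  Unmatched substitution records
#' are profiled by directed substitution type (first alt allele when it is a
#' substitution; indels excluded).
#'
#' @param records list of \code{\link{variant_record}} objects (non-empty).
#' @param options a \code{\link{scan_options}} object (or a registry).
#' @return object of class "cohort_summary": n_total, n_matched,
#'   fraction_matched, per_cas_coverage (named integer over all registry
#'   enzymes), n_exclusive_synthetic, n_exclusive_by_cas,
#'   unmatched_substitution_profile (named integer over the 12 directed
#'   types), and record_matches (per-record data.frame with the matching
#'   enzyme set).
#' @export
summarize_cohort <- function(records, options = scan_options()) {
  if (!inherits(options, "scan_options")) options <- scan_options(options)
  if (!length(records))
    stop(errorCondition("cohort is empty",
                        class = c("allelepam_input_error", "error")))
  registry <- options$registry
  cas_names <- names(registry)
  synthetic <- vapply(registry, function(e) e$origin == "synthetic", logical(1L))

  per_record <- lapply(records, function(rec) {
    m <- scan_variant(rec, options)
    unique(m$cas)
  })
  matched <- vapply(per_record, function(cs) length(cs) > 0L, logical(1L))

  per_cas <- vapply(cas_names, function(cn)
    sum(vapply(per_record, function(cs) cn %in% cs, logical(1L))),
    integer(1L))
  excl_by_cas <- vapply(cas_names, function(cn)
    sum(vapply(per_record, function(cs) identical(cs, cn), logical(1L))),
    integer(1L))
  excl_synth <- sum(vapply(per_record, function(cs)
    length(cs) > 0L && all(synthetic[cs]), logical(1L)))

  profile <- setNames(integer(length(SUBSTITUTION_TYPES)), SUBSTITUTION_TYPES)
  for (i in which(!matched)) {
    ty <- classify_substitution(records[[i]])
    if (!is.na(ty)) profile[ty] <- profile[ty] + 1L
  }

  structure(list(
    n_total = length(records),
    n_matched = sum(matched),
    fraction_matched = sum(matched) / length(records),
    per_cas_coverage = per_cas,
    n_exclusive_synthetic = as.integer(excl_synth),
    n_exclusive_by_cas = excl_by_cas,
    unmatched_substitution_profile = profile,
    record_matches = data.frame(
      record_id = vapply(records, `[[`, character(1L), "id"),
      matched = matched,
      matched_cas = vapply(per_record, paste, character(1L), collapse = ","),
      stringsAsFactors = FALSE)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d variants: %d (%.1f%%) with >= 1 variant-derived PAM\n",
              x$n_total, x$n_matched, 100 * x$fraction_matched))
  cat(sprintf("  exclusively targetable by synthetic Cas variants: %d (%.2f%%)\n",
              x$n_exclusive_synthetic,
              100 * x$n_exclusive_synthetic / x$n_total))
  top <- sort(x$per_cas_coverage, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("  per-Cas coverage (records with a match):\n")
    for (i in seq_along(top))
      cat(sprintf("    %-20s %d\n", names(top)[i], top[i]))
  }
  unm <- x$unmatched_substitution_profile
  if (sum(unm) > 0) {
    cat("  unmatched substitutions by type:",
        paste(sprintf("%s:%d", names(unm)[unm > 0], unm[unm > 0]),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Flatten a cohort summary to a two-column statistic table
#' @param summary a "cohort_summary".
#' @return data.frame with columns statistic, value.
#' @export
summary_table <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  rows <- c(
    n_total = summary$n_total,
    n_matched = summary$n_matched,
    fraction_matched = summary$fraction_matched,
    n_exclusive_synthetic = summary$n_exclusive_synthetic,
    setNames(summary$per_cas_coverage,
             paste0("coverage.", names(summary$per_cas_coverage))),
    setNames(summary$n_exclusive_by_cas,
             paste0("exclusive.", names(summary$n_exclusive_by_cas))),
    setNames(summary$unmatched_substitution_profile,
             paste0("unmatched.", names(summary$unmatched_substitution_profile)))
  )
  data.frame(statistic = names(rows), value = unname(rows),
             stringsAsFactors = FALSE)
}
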