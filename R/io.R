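# Readers and writers: 5-column TSV batch dialect, VCF + reference FASTA
# ingestion, and TSV/JSON result serialization.

BATCH_COLUMNS <- c("id", "upstream", "ref", "alt", "downstream")

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("allelepam_format_error", "error")))
}

#' Parse a batch TSV of variant records
#'
#' Tab-delimited, header required, columns id / upstream / ref / alt /
#' downstream.  Multi-allelic sites list comma-separated alternate alleles in
#' the alt column; an empty ref or alt cell is the absent side of an indel.
#'
#' @param path path to the TSV file.
#' @return list of \code{\link{variant_record}} objects.
#' @export
parse_batch <- function(path) {
  if (!file.exists(path)) format_error(sprintf("batch file '%s' not found", path))
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  missing_cols <- setdiff(BATCH_COLUMNS, names(df))
  if (length(missing_cols))
    format_error(sprintf("batch file is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i) {
    alts <- if (nzchar(df$alt[i]))
      strsplit(df$alt[i], ",", fixed = TRUE)[[1L]] else ""
    withCallingHandlers(
      variant_record(df$id[i], df$upstream[i], df$ref[i], alts,
                     df$downstream[i]),
      error = function(e) {
        if (inherits(e, "allelepam_validation_error"))
          validation_error(sprintf("batch row %d (id '%s'): %s",
                                   i, df$id[i], conditionMessage(e)))
      })
  })
}

#' Serialize variant records back to the batch TSV dialect
#' @param records list of \code{\link{variant_record}} objects.
#' @param path output path.
#' @export
write_batch <- function(records, path) {
  df <- data.frame(
    id = vapply(records, `[[`, character(1L), "id"),
    upstream = vapply(records, `[[`, character(1L), "upstream"),
    ref = vapply(records, `[[`, character(1L), "ref_allele"),
    alt = vapply(records, function(r) paste(r$alt_alleles, collapse = ","),
                 character(1L)),
    downstream = vapply(records, `[[`, character(1L), "downstream"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build variant records from a VCF and a reference FASTA
#'
#' Supports SNVs and single-base indels in the VCF anchor-base convention
#' (e.g. REF "CT" / ALT "C" is a single-base deletion): the shared leading
#' base is stripped to the internal empty/one-base allele representation, and
#' flanks of the requested length are cut from the reference around the
#' normalized variant position (1-based VCF POS mapped to the package's
#' 0-based frame).  Records that cannot be represented -- multi-base
#' substitutions, multi-base indels, flanks containing non-A/C/G/T reference
#' bases, or REF disagreeing with the FASTA -- are skipped with a warning.
#' Alternate alleles at the same site that normalize to different reference
#' intervals (e.g. an SNV and a deletion) become separate records.
#'
#' @param vcf_path VCF file (plain or bgzipped).
#' @param fasta_path reference FASTA containing the VCF contigs.
#' @param flank flank length to extract on each side (default 30).
#' @return list of \code{\link{variant_record}} objects.
#' @export
parse_vcf <- function(vcf_path, fasta_path, flank = 30L) {
  flank <- as.integer(flank)
  if (flank < 1L) contract_error("flank must be >= 1")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  records <- list(); n_rec <- 0L
  for (i in seq_len(nrow(fx))) {
    chrom <- unname(fx[i, "CHROM"]); pos <- as.integer(fx[i, "POS"])
    id <- unname(fx[i, "ID"])
    if (is.na(id) || id == ".") id <- sprintf("%s:%d", chrom, pos)
    ref <- toupper(unname(fx[i, "REF"]))
    alts <- toupper(strsplit(unname(fx[i, "ALT"]), ",", fixed = TRUE)[[1L]])
    if (!chrom %in% names(genome))
      stop(errorCondition(sprintf("contig '%s' not found in FASTA", chrom),
                          class = c("allelepam_lookup_error", "error")))
    contig <- genome[[chrom]]
    clen <- length(contig)

    # normalize each ALT to (0-based variant position, internal ref, internal alt)
    norm <- list()
    for (alt in alts) {
      nr <- nchar(ref); na <- nchar(alt)
      if (nr == 1L && na == 1L) {
        norm[[length(norm) + 1L]] <- list(pos0 = pos - 1L, r = ref, a = alt)
      } else if (nr == 2L && na == 1L && substr(ref, 1L, 1L) == alt) {
        norm[[length(norm) + 1L]] <- list(pos0 = pos, r = substr(ref, 2L, 2L), a = "")
      } else if (nr == 1L && na == 2L && substr(alt, 1L, 1L) == ref) {
        norm[[length(norm) + 1L]] <- list(pos0 = pos, r = "", a = substr(alt, 2L, 2L))
      } else {
        warning(sprintf("skipping %s at %s:%d: unsupported REF/ALT '%s'/'%s'",
                        id, chrom, pos, ref, alt))
      }
    }
    if (!length(norm)) next

    # check anchor/ref agreement with the genome
    obs_ref <- toupper(as.character(contig[pos:min(clen, pos + nchar(ref) - 1L)]))
    if (!identical(obs_ref, ref)) {
      warning(sprintf("skipping %s: VCF REF '%s' disagrees with FASTA '%s'",
                      id, ref, obs_ref))
      next
    }

    keys <- vapply(norm, function(x) sprintf("%d|%s", x$pos0, x$r), character(1L))
    for (key in unique(keys)) {
      grp <- norm[keys == key]
      pos0 <- grp[[1L]]$pos0; r <- grp[[1L]]$r
      rlen <- nchar(r)
      up_start <- max(0L, pos0 - flank)
      up <- if (pos0 > up_start)
        as.character(contig[(up_start + 1L):pos0]) else ""
      dn_end <- min(clen, pos0 + rlen + flank)
      dn <- if (dn_end > pos0 + rlen)
        as.character(contig[(pos0 + rlen + 1L):dn_end]) else ""
      rec <- tryCatch(
        variant_record(if (length(unique(keys)) > 1L)
                         sprintf("%s[%s]", id, if (rlen) "del" else "ins") else id,
                       up, r, vapply(grp, `[[`, character(1L), "a"), dn),
        allelepam_validation_error = function(e) {
          warning(sprintf("skipping %s: %s", id, conditionMessage(e)))
          NULL
        })
      if (!is.null(rec)) { n_rec <- n_rec + 1L; records[[n_rec]] <- rec }
    }
  }
  records
}

#' Write scan results to TSV or JSON
#'
#' TSV: one row per match, stable 14-column order (record_id, alt, cas,
#' motif, strand, pam_start, pam_end, pam_seq_variant, pam_seq_reference,
#' grna, grna_complete, cas_class, cas_origin, approx_size_bp); an empty
#' result yields a header-only file.  JSON mirrors the same fields as an
#' array of row objects.
#'
#' @param matches data.frame from \code{\link{scan_variant}}.
#' @param format "tsv" or "json".
#' @param destination output path.
#' @export
write_results <- function(matches, format = c("tsv", "json"), destination) {
  format <- match.arg(format)
  cols <- names(empty_matches())
  matches <- matches[, cols, drop = FALSE]
  if (format == "tsv") {
    utils::write.table(matches, destination, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(matches, destination, dataframe = "rows",
                         auto_unbox = FALSE, na = "null", pretty = TRUE)
  }
  invisible(destination)
}

#' Read scan results written by \code{\link{write_results}}
#' @param path input path.
#' @param format "tsv" or "json".
#' @return data.frame with the standard match columns.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (format == "tsv") {
    utils::read.delim(path, colClasses = c(
      record_id = "character", alt = "character", cas = "character",
      motif = "character", strand = "character", pam_start = "integer",
      pam_end = "integer", pam_seq_variant = "character",
      pam_seq_reference = "character", grna = "character",
      grna_complete = "logical", cas_class = "character",
      cas_origin = "character", approx_size_bp = "integer"),
      na.strings = "NA", quote = "")
  } else {
    out <- jsonlite::fromJSON(path)
    if (!length(out)) empty_matches() else {
      out$pam_start <- as.integer(out$pam_start)
      out$pam_end <- as.integer(out$pam_end)
      out$approx_size_bp <- as.integer(out$approx_size_bp)
      out
    }
  }
  df[, names(empty_matches()), drop = FALSE]
}
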