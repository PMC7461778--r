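# Cas enzyme / PAM registry: construction, the built-in table, user-defined
# entries, and plain-text (DCF) serialization.

#' Construct a single Cas enzyme entry
#'
#' @param name unique identifier.
#' @param cas_class "II" (PAM downstream of the protospacer, Cas9-type) or
#'   "V" (PAM upstream, Cas12a-type).  The PAM orientation is implied by the
#'   class.
#' @param primary_motifs character vector of IUPAC PAM patterns that generate
#'   candidates.
#' @param off_target_motifs suboptimal PAMs the enzyme still binds (e.g. NAG
#'   for SpCas9); used only to reject candidates whose reference allele
#'   carries one, never to generate candidates.
#' @param spacer_length spacer (gRNA) length in nt; defaults to the canonical
#'   20 nt for class II and 23 nt for class V.
#' @param origin "natural" ortholog or engineered "synthetic" variant.
#' @param approx_size_bp approximate coding size in bp; pure metadata used for
#'   delivery-vector capacity decisions, never in scanning logic.
#' @return object of class "cas_enzyme".
#' @export
cas_enzyme <- function(name, cas_class = c("II", "V"), primary_motifs,
                       off_target_motifs = character(0),
                       spacer_length = NULL,
                       origin = c("natural", "synthetic"),
                       approx_size_bp = NA_integer_) {
  cas_class <- match.arg(cas_class)
  origin <- match.arg(origin)
  if (length(name) != 1L || !nzchar(name))
    validation_error("enzyme name must be a non-empty string")
  if (!length(primary_motifs))
    validation_error(sprintf("enzyme '%s' needs at least one primary motif", name))
  primary_motifs <- vapply(primary_motifs, validate_iupac, character(1L),
                           USE.NAMES = FALSE)
  off_target_motifs <- vapply(off_target_motifs, validate_iupac, character(1L),
                              USE.NAMES = FALSE)
  if (anyDuplicated(primary_motifs) || anyDuplicated(off_target_motifs))
    validation_error(sprintf("duplicate motif pattern within enzyme '%s'", name))
  if (is.null(spacer_length))
    spacer_length <- if (cas_class == "II") 20L else 23L
  spacer_length <- as.integer(spacer_length)
  if (is.na(spacer_length) || spacer_length < 1L)
    validation_error("spacer_length must be a positive integer")
  structure(list(
    name = name,
    cas_class = cas_class,
    pam_orientation = if (cas_class == "II") "downstream_of_protospacer"
                      else "upstream_of_protospacer",
    primary_motifs = primary_motifs,
    off_target_motifs = off_target_motifs,
    spacer_length = spacer_length,
    origin = origin,
    approx_size_bp = as.integer(approx_size_bp)
  ), class = "cas_enzyme")
}

new_registry <- function(enzymes) {
  names(enzymes) <- vapply(enzymes, `[[`, character(1L), "name")
  if (anyDuplicated(names(enzymes)))
    validation_error("registry enzyme names must be unique")
  structure(enzymes, class = "cas_registry")
}

#' The built-in Cas/PAM registry
#'
#' 23 Cas enzymes (AsCas12a and LbCas12a share one entry because they share
#' the TTTN PAM) covering 26 distinct primary PAM patterns.  SpCas9
#' additionally carries NAG as an off-target-only PAM: NAG never generates a
#' candidate but its presence on the reference allele at the locus vetoes an
#' NGG candidate, since SpCas9 binding to the reference NAG would defeat
#' allele specificity.
#'
#' @return object of class "cas_registry": an ordered, name-unique list of
#'   \code{\link{cas_enzyme}} entries.
#' @export
#' @examples
#' reg <- pam_registry()
#' length(reg)                       # 23 enzymes
#' reg[["SpCas9"]]$off_target_motifs # "NAG"
pam_registry <- function() {
  e <- cas_enzyme
  new_registry(list(
    e("SpCas9",            "II", "NGG", "NAG", origin = "natural",  approx_size_bp = 4100),
    e("VRER SpCas9",       "II", "NGCG",       origin = "synthetic"),
    e("EQR SpCas9",        "II", "NGAG",       origin = "synthetic"),
    e("VQR SpCas9",        "II", "NGAN",       origin = "synthetic"),
    e("SpCas9-NG",         "II", c("NG", "NANG"), origin = "synthetic"),
    e("xCas9",             "II", "NG",         origin = "synthetic"),
    e("SpCas9-NRRH",       "II", c("NRRH", "NGGN"), origin = "synthetic"),
    e("SpCas9-NRTH",       "II", c("NRTH", "NGGN"), origin = "synthetic"),
    e("SpCas9-NRCH",       "II", c("NRCH", "NGGN"), origin = "synthetic"),
    e("SaCas9",            "II", "NNGRRT",     origin = "natural",  approx_size_bp = 3150),
    e("KKH SaCas9",        "II", "NNNRRT",     origin = "synthetic"),
    e("NmCas9",            "II", "NNNNGATT",   origin = "natural",  approx_size_bp = 3240),
    e("St1Cas9",           "II", "NNRGAAW",    origin = "natural",  approx_size_bp = 4180),
    e("St3Cas9",           "II", "NGGNG",      origin = "natural"),
    e("TdCas9",            "II", "NAAAAC",     origin = "natural",  approx_size_bp = 4200),
    e("CjCas9",            "II", "NNNVRYM",    origin = "natural",  approx_size_bp = 2950),
    e("SpCas9-Spa",        "II", "NNGTGA",     origin = "natural",  approx_size_bp = 3400),
    e("AsCas12a/LbCas12a", "V",  "TTTN",       origin = "natural",  approx_size_bp = 3685),
    e("AsCas12a-RVR",      "V",  "TATV",       origin = "synthetic"),
    e("AsCas12a-RR",       "V",  "TYCV",       origin = "synthetic"),
    e("enAsCas12a",        "V",  c("TGTV", "VTTV", "TTTT", "TTCN"), origin = "synthetic"),
    e("FnCas12a",          "V",  "TTV",        origin = "natural",  approx_size_bp = 3900),
    e("Cas12e",            "V",  "TTCN",       origin = "natural",  approx_size_bp = 2940)
  ))
}

#' Append a user-defined Cas enzyme to a registry
#'
#' Value semantics: the input registry is not modified; a new registry with
#' the entry appended (origin "synthetic") is returned.
#'
#' @param registry a "cas_registry".
#' @param name new unique enzyme name.
#' @param motifs character vector of IUPAC PAM patterns.
#' @param orientation "downstream" (class II style) or "upstream" (class V
#'   style) of the protospacer.
#' @param spacer_length spacer length in nt (default by orientation: 20
#'   downstream, 23 upstream).
#' @param off_target_motifs optional reference-rejection-only motifs.
#' @return a new "cas_registry".
#' @export
#' @examples
#' reg <- register_custom(pam_registry(), "MyCas", "NGGNG", "downstream", 20)
register_custom <- function(registry, name, motifs,
                            orientation = c("downstream", "upstream"),
                            spacer_length = NULL,
                            off_target_motifs = character(0)) {
  stopifnot(inherits(registry, "cas_registry"))
  orientation <- match.arg(orientation)
  if (name %in% names(registry))
    stop(errorCondition(
      sprintf("an enzyme named '%s' is already registered", name),
      class = c("allelepam_name_collision", "error")))
  enz <- cas_enzyme(name,
                    cas_class = if (orientation == "downstream") "II" else "V",
                    primary_motifs = motifs,
                    off_target_motifs = off_target_motifs,
                    spacer_length = spacer_length,
                    origin = "synthetic")
  new_registry(c(unclass(registry), list(enz)))
}

#' All distinct primary PAM patterns in a registry
#' @param registry a "cas_registry".
#' @return character vector of unique primary motif patterns.
#' @export
primary_patterns <- function(registry) {
  unique(unlist(lapply(registry, `[[`, "primary_motifs"), use.names = FALSE))
}

#' @export
format.cas_enzyme <- function(x, ...) {
  sprintf("<%s> class %s (%s PAM, %s), PAM %s%s, spacer %d nt%s",
          x$name, x$cas_class,
          if (x$cas_class == "II") "3'" else "5'", x$origin,
          paste(x$primary_motifs, collapse = ", "),
          if (length(x$off_target_motifs))
            paste0(" (off-target: ",
                   paste(x$off_target_motifs, collapse = ", "), ")") else "",
          x$spacer_length,
          if (!is.na(x$approx_size_bp))
            sprintf(", ~%d bp", x$approx_size_bp) else "")
}

#' @export
print.cas_enzyme <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.cas_registry <- function(x, ...) {
  cat(sprintf("Cas/PAM registry: %d enzymes, %d distinct primary PAM patterns\n",
              length(x), length(primary_patterns(x))))
  for (enz in x) cat(" ", format(enz), "\n")
  invisible(x)
}

#' Flatten a registry to a data frame (one row per enzyme)
#' @param x a "cas_registry".
#' @param row.names,optional,... ignored (data.frame method signature).
#' @export
as.data.frame.cas_registry <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    name = vapply(x, `[[`, character(1L), "name"),
    cas_class = vapply(x, `[[`, character(1L), "cas_class"),
    pam_orientation = vapply(x, `[[`, character(1L), "pam_orientation"),
    primary_motifs = vapply(x, function(e) paste(e$primary_motifs, collapse = ","), character(1L)),
    off_target_motifs = vapply(x, function(e) paste(e$off_target_motifs, collapse = ","), character(1L)),
    spacer_length = vapply(x, `[[`, integer(1L), "spacer_length"),
    origin = vapply(x, `[[`, character(1L), "origin"),
    approx_size_bp = vapply(x, `[[`, integer(1L), "approx_size_bp"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a registry to a plain-text config file
#'
#' One DCF stanza per enzyme (blank-line separated), fields matching the
#' \code{\link{cas_enzyme}} constructor.  \code{\link{read_registry}} inverts
#' it exactly.
#'
#' @param registry a "cas_registry".
#' @param path output file path.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "cas_registry"))
  df <- as.data.frame(registry)
  df$approx_size_bp[is.na(df$approx_size_bp)] <- ""
  write.dcf(df, file = path)
  invisible(path)
}

#' Read a registry from a plain-text config file
#' @param path file written by \code{\link{write_registry}} (or hand-edited in
#'   the same stanza format).
#' @return a "cas_registry".
#' @export
read_registry <- function(path) {
  m <- read.dcf(path)
  need <- c("name", "cas_class", "primary_motifs", "spacer_length", "origin")
  missing_cols <- setdiff(need, colnames(m))
  if (length(missing_cols))
    validation_error(sprintf("registry config is missing field(s): %s",
                             paste(missing_cols, collapse = ", ")))
  get_col <- function(col, default = "") {
    if (col %in% colnames(m)) ifelse(is.na(m[, col]), default, m[, col])
    else rep(default, nrow(m))
  }
  split_motifs <- function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1L]] else character(0)
  enzymes <- lapply(seq_len(nrow(m)), function(i) {
    size <- get_col("approx_size_bp")[i]
    cas_enzyme(
      name = unname(m[i, "name"]),
      cas_class = unname(m[i, "cas_class"]),
      primary_motifs = split_motifs(m[i, "primary_motifs"]),
      off_target_motifs = split_motifs(get_col("off_target_motifs")[i]),
      spacer_length = as.integer(m[i, "spacer_length"]),
      origin = unname(m[i, "origin"]),
      approx_size_bp = if (nzchar(size)) as.integer(size) else NA_integer_
    )
  })
  new_registry(enzymes)
}
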