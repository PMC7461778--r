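test_that("validate_sequence normalizes case and pinpoints bad characters", {
  expect_identical(validate_sequence("acgt"), "ACGT")
  expect_identical(validate_sequence(""), "")  # empty allele of an indel
  err <- tryCatch(validate_sequence("ACGU"), error = identity)
  expect_s3_class(err, "allelepam_validation_error")
  expect_match(conditionMessage(err), "'U'")
  expect_match(conditionMessage(err), "position 3")  # 0-based
  expect_error(validate_sequence("ACNT"), class = "allelepam_validation_error")
})

test_that("revcomp applies the full IUPAC complement table", {
  expect_identical(revcomp("ACGT"), "ACGT")  # palindrome
  expect_identical(revcomp("AAG"), "CTT")
  expect_identical(revcomp("TTCN"), "NGAA")
  expect_identical(revcomp(""), "")
  expect_error(revcomp("ACX"), class = "allelepam_validation_error")
})

test_that("revcomp is an involution and agrees with Biostrings", {
  codes <- strsplit("ACGTRYWSKMBDHVN", "")[[1]]
  withr::with_seed(101, {
    for (i in 1:200) {
      s <- paste(sample(codes, sample(1:40, 1), replace = TRUE), collapse = "")
      expect_identical(revcomp(revcomp(s)), s)
      expect_identical(
        revcomp(s),
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
    }
  })
})

test_that("iupac_match follows the degenerate code sets", {
  expect_true(iupac_match("NGG", "AGG"))
  expect_true(iupac_match("NNGRRT", "AAGAGT"))
  expect_false(iupac_match("TTTN", "TTCA"))
  expect_true(iupac_match("NNRGAAW", "CCGGAAT"))
  expect_error(iupac_match("NGG", "AG"), class = "allelepam_contract_error")
})

test_that("expand_motif cardinality is the product of per-position set sizes", {
  expect_length(expand_motif("NGG"), 4L)
  expect_length(expand_motif("NNGRRT"), 64L)
  expect_identical(expand_motif("TTTT"), "TTTT")
  expect_length(expand_motif("NNNVRYM"), 4 * 4 * 4 * 3 * 2 * 2 * 2)
})

test_that("iupac_match and expand_motif agree exhaustively on every registry motif", {
  reg <- pam_registry()
  motifs <- unique(unlist(lapply(reg, function(e)
    c(e$primary_motifs, e$off_target_motifs))))
  for (m in motifs) {
    all_windows <- expand_motif(strrep("N", nchar(m)))
    via_match <- vapply(all_windows, function(w) iupac_match(m, w), logical(1L),
                        USE.NAMES = FALSE)
    via_expand <- all_windows %in% expand_motif(m)
    expect_identical(via_match, via_expand, label = m)
  }
})

test_that("build_alleles materializes ref/var sequences and affected intervals", {
  sub <- build_alleles(variant_record("s", "ACG", "T", "G", "TTA"), "G")
  expect_identical(sub$ref_seq, "ACGTTTA")
  expect_identical(sub$var_seq, "ACGGTTA")
  expect_identical(sub$affected, c(3L, 4L))
  expect_identical(sub$ref_affected, c(3L, 4L))

  ins <- build_alleles(variant_record("i", "ACG", "", "T", "TTA"), "T")
  expect_identical(ins$var_seq, "ACGTTTA")
  expect_identical(ins$affected, c(3L, 4L))
  expect_identical(ins$ref_affected, c(2L, 4L))  # junction widened each side

  del <- build_alleles(variant_record("d", "ACG", "T", "", "TTA"), "")
  expect_identical(del$var_seq, "ACGTTA")
  expect_identical(del$affected, c(2L, 4L))      # one base each side of junction
  expect_identical(del$ref_affected, c(3L, 4L))  # the deleted base
})

test_that("substitution contexts differ at exactly the affected position", {
  withr::with_seed(7, {
    for (i in 1:100) {
      rec <- rand_record("p", flank_min = 3, flank_max = 15)
      ctx <- build_alleles(rec)
      expect_identical(nchar(ctx$ref_seq), nchar(ctx$var_seq))
      r <- strsplit(ctx$ref_seq, "")[[1]]
      v <- strsplit(ctx$var_seq, "")[[1]]
      expect_identical(which(r != v) - 1L, ctx$affected[1L])
    }
  })
})

test_that("record validation rejects malformed alleles", {
  expect_error(variant_record("x", "AA", "T", "T", "GG"),
               class = "allelepam_validation_error")  # alt == ref
  expect_error(variant_record("x", "AA", "", "", "GG"),
               class = "allelepam_validation_error")  # both empty
  expect_error(variant_record("x", "AA", "AC", "T", "GG"),
               class = "allelepam_validation_error")  # multi-base allele
  expect_error(variant_record("x", "ANA", "C", "T", "GG"),
               class = "allelepam_validation_error")  # ambiguous flank
  expect_error(build_alleles(variant_record("x", "AA", "C", "T", "GG"), "G"),
               class = "allelepam_contract_error")    # alt not in record
})
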