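test_that("candidate_windows enumerates exactly the variant-overlapping windows", {
  expect_identical(candidate_windows(5, c(2, 3), 4),
                   cbind(start = 0:1, end = 4:5))
  expect_identical(candidate_windows(3, c(1, 2), 3),
                   cbind(start = 0L, end = 3L))
  expect_identical(nrow(candidate_windows(2, c(0, 1), 8)), 0L)  # cannot fit
  # deletion-style two-base affected interval
  expect_identical(candidate_windows(6, c(2, 4), 2),
                   cbind(start = 1:3, end = 3:5))
})

test_that("reference_blocked vetoes an enzyme when any of its PAMs sits on the reference", {
  reg <- pam_registry()
  # the reference allele of the C-to-T example carries the alternative TTCN PAM
  expect_true(reference_blocked(reg[["enAsCas12a"]], "TTCTA", c(2, 3)))
  # NAG is an off-target PAM of SpCas9: present on the reference, it blocks
  expect_true(reference_blocked(reg[["SpCas9"]], "TAG", c(1, 2)))
  # no NNGRRT window in a homopolymer
  expect_false(reference_blocked(reg[["SaCas9"]], "AAAAAA", c(2, 3)))
})

test_that("multi-PAM enzymes are rejected when the reference carries an alternative PAM", {
  # hypothetical point mutation TT<C>TA -> TT<T>TA: the variant creates TTTT
  # (enAsCas12a) but the reference still carries its TTCN PAM, so only the
  # single-PAM TTTN enzyme is an allele-specific candidate
  rec <- variant_record("hyp", "TT", "C", "T", "TA")
  m <- scan_variant(rec)
  expect_false("enAsCas12a" %in% m$cas)
  aslb <- m[m$cas == "AsCas12a/LbCas12a" & m$strand == "+", ]
  expect_true(nrow(aslb) >= 1)
  expect_true(any(aslb$motif == "TTTN" & aslb$pam_start == 0 & aslb$pam_end == 4 &
                  aslb$pam_seq_variant == "TTTT"))
})

test_that("an NAG on the reference disqualifies an NGG candidate for SpCas9", {
  m <- scan_variant(variant_record("nag", "T", "A", "G", "G"))
  expect_false("SpCas9" %in% m$cas)
})

test_that("a clean NGG creation is reported for SpCas9 with window evidence", {
  m <- scan_variant(variant_record("agg", "AA", "T", "G", "GA"))
  sp <- m[m$cas == "SpCas9", ]
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$motif, "NGG")
  expect_identical(sp$strand, "+")
  expect_identical(c(sp$pam_start, sp$pam_end), c(1L, 4L))
  expect_identical(sp$pam_seq_variant, "AGG")
  expect_identical(sp$pam_seq_reference, "ATG")
})

test_that("spacer suggestion takes 5' (class II) or 3' (class V) of the PAM", {
  up <- "ACGTACGTACGTACG"; down <- "TGCATGCATGCATG"  # 15 + 1 + 14 = 30 nt
  rec <- variant_record("g", up, "A", "C", down)
  ctx <- build_alleles(rec, "C")
  reg <- pam_registry()

  m2 <- list(strand = "+", pam_start = 24L, pam_end = 27L)
  g2 <- suggest_grna(m2, ctx, reg[["SpCas9"]])
  expect_true(g2$complete)
  expect_identical(g2$grna, substring(ctx$var_seq, 5, 24))  # 20 nt, 5' of PAM

  m5 <- list(strand = "+", pam_start = 0L, pam_end = 4L)
  g5 <- suggest_grna(m5, ctx, reg[["AsCas12a/LbCas12a"]])
  expect_true(g5$complete)
  expect_identical(g5$grna, substring(ctx$var_seq, 5, 27))  # 23 nt, 3' of PAM

  mshort <- list(strand = "+", pam_start = 2L, pam_end = 5L)
  gs <- suggest_grna(mshort, ctx, reg[["SpCas9"]])
  expect_false(gs$complete)
  expect_identical(gs$grna, substring(ctx$var_seq, 1, 2))   # truncated to 2 nt
})

test_that("reported spacers are reproducible from the match coordinates", {
  reg <- pam_registry()
  withr::with_seed(33, {
    for (i in 1:20) {
      rec <- rand_record(paste0("g", i), flank_min = 25, flank_max = 30,
                         p_indel = 0.3)
      m <- scan_variant(rec)
      for (j in seq_len(nrow(m))) {
        ctx <- build_alleles(rec, m$alt[j])
        sg <- suggest_grna(m[j, ], ctx, reg[[m$cas[j]]])
        expect_identical(sg$grna, m$grna[j])
        expect_identical(sg$complete, m$grna_complete[j])
        if (sg$complete)
          expect_identical(nchar(sg$grna), reg[[m$cas[j]]]$spacer_length)
      }
    }
  })
})

test_that("scanning is deterministic and ordered (alt, enzyme, strand, window)", {
  rec <- variant_record("ord", "AATTTAAGG", "T", c("G", "C"), "GATTTAGCA")
  m1 <- scan_variant(rec)
  m2 <- scan_variant(rec)
  expect_true(nrow(m1) > 0)
  expect_identical(m1, m2)
  reg_order <- names(pam_registry())
  key <- order(match(m1$alt, rec$alt_alleles),
               match(m1$cas, reg_order),
               match(m1$strand, c("+", "-")))
  expect_identical(key, sort(key))  # grouped in specification order
  # window starts ascend within each (alt, cas, strand) group
  grp <- paste(m1$alt, m1$cas, m1$strand)
  for (g in unique(grp)) {
    expect_false(is.unsorted(m1$pam_start[grp == g]))
  }
})

test_that("strand and multi-allele options prune the match table coherently", {
  rec <- variant_record("opt", "AATTTAAGG", "T", c("G", "C"), "GATTTAGCA")
  plus_only <- scan_variant(rec, scan_options(scan_minus_strand = FALSE))
  expect_true(all(plus_only$strand == "+"))
  full <- scan_variant(rec)
  expect_identical(match_key(full[full$strand == "+", ]), match_key(plus_only))

  # multi-allelic scan decomposes into per-alt scans
  per_alt <- lapply(rec$alt_alleles, function(a)
    scan_variant(variant_record(rec$id, rec$upstream, rec$ref_allele, a,
                                rec$downstream)))
  expect_identical(match_key(full), sort(unlist(lapply(per_alt, match_key))))
})

test_that("a truncated-spacer match is dropped when incomplete gRNAs are excluded", {
  rec <- variant_record("edge", "A", "T", "G", "GA")  # too short for any spacer
  with_inc <- scan_variant(rec)
  without <- scan_variant(rec, scan_options(include_incomplete_grna = FALSE))
  expect_true(nrow(with_inc) > 0)
  expect_identical(nrow(without), 0L)
  expect_true(all(!with_inc$grna_complete))
})

test_that("removing an enzyme never changes the matches of the others", {
  reg <- pam_registry()
  withr::with_seed(55, {
    for (i in 1:15) {
      rec <- rand_record(paste0("m", i), p_indel = 0.2)
      full <- scan_variant(rec)
      drop <- sample(names(reg), 1L)
      sub <- reg[names(reg) != drop]
      class(sub) <- "cas_registry"
      pruned <- scan_variant(rec, scan_options(sub))
      expect_identical(match_key(pruned),
                       match_key(full[full$cas != drop, ]))
    }
  })
})

test_that("scanning an empty registry is a configuration error", {
  empty <- structure(list(), class = "cas_registry")
  expect_error(scan_variant(variant_record("x", "AA", "C", "T", "GG"),
                            scan_options(empty)),
               class = "allelepam_config_error")
})

test_that("scan_variant agrees with the brute-force oracle on random records", {
  reg <- pam_registry()
  opts <- scan_options(reg)
  withr::with_seed(77, {
    for (i in 1:60) {
      rec <- rand_record(paste0("o", i), flank_min = 8, flank_max = 14,
                         p_indel = 0.3)
      expect_identical(match_key(scan_variant(rec, opts)),
                       match_key(brute_force_oracle(rec, reg)),
                       label = rec$id)
    }
  })
})

test_that("reverse-complementing the input flips strands but preserves matches", {
  withr::with_seed(88, {
    for (i in 1:40) {
      rec <- rand_record(paste0("s", i), flank_min = 8, flank_max = 12,
                         p_indel = 0.3)
      fwd <- scan_variant(rec)
      rev <- scan_variant(flip_record(rec))
      k <- function(df) sort(paste(df$cas, df$motif,
                                   ifelse(df$strand == "+", "-", "+")))
      expect_identical(sort(paste(fwd$cas, fwd$motif, fwd$strand)), k(rev))
    }
  })
})
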