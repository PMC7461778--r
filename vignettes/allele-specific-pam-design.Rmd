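---
title: "Methods: detecting variant-derived PAMs for allele-specific CRISPR targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting variant-derived PAMs for allele-specific CRISPR targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `allelepam`, the conventions and
parameters it commits to, how the synthetic validation data are built, and
the design decisions that a user extending the package should know about.

## 1. Model

A heterozygous single-nucleotide variant changes the local DNA sequence in
one of three ways handled here: a base substitution, a single-base
insertion, or a single-base deletion. CRISPR-Cas enzymes require a
protospacer-adjacent motif (PAM) directly next to the protospacer; unlike
gRNA:DNA pairing, PAM recognition is effectively all-or-nothing. A variant
that *creates* a PAM absent from the reference allele therefore offers a
structurally guaranteed handle for allele-specific cleavage: the enzyme
physically cannot engage the wild-type allele at that site, regardless of
spacer design.

For each variant the package builds the reference-allele sequence
(`ref_seq`) and the variant-allele sequence (`var_seq`) from the supplied
flanks, then asks, for every enzyme in the registry, every motif of that
enzyme, and both strands:

* **Creation.** Does a primary motif of the enzyme match `var_seq` in a
  window that overlaps the variant base? Windows not overlapping the
  variant are irrelevant: a PAM already present in shared flanking sequence
  exists on both alleles.
* **Reference rejection.** Does *any* motif of the same enzyme — primary or
  off-target — match `ref_seq` in any window overlapping the locus on the
  same strand? If so, the enzyme is vetoed on that strand for this variant.

Both conditions are evaluated per enzyme, not per motif. The rejection set
includes motifs one would never design against but that the enzyme still
cleaves at reduced efficiency (the canonical example is SpCas9's `NAG`): if
the reference allele carries such a motif at the locus, residual wild-type
cleavage would defeat allele specificity, so the candidate is discarded.
This is the single most consequential design decision in the package and it
is deliberately conservative — it trades sensitivity (some workable sites
are dropped) for a guarantee that every reported match is exclusive to the
variant allele at the level of PAM recognition.

Motifs are written in IUPAC one-letter codes (`R`, `Y`, `W`, `S`, `K`,
`M`, `B`, `D`, `H`, `V`, `N`); matching is implemented both as anchored
character-class regular expressions (production path) and as literal
expansion of the degenerate motif into its concrete words (oracle path,
section 4).

## 2. Registry

`pam_registry()` ships 23 enzymes covering 26 primary PAM patterns: natural
class II (Cas9-type) and class V (Cas12a-type) nucleases plus engineered
PAM-relaxed variants (e.g. SpCas9-NG, xCas9, the NRRH/NRTH/NRCH set,
AsCas12a-RVR/-RR, enAsCas12a). Each entry records the motif list, known
off-target motifs, the enzyme class, its origin (natural or engineered),
approximate gene size, and the default spacer length. AsCas12a and LbCas12a
share the `TTTN` motif and identical behaviour under this model, so they
occupy a single registry entry; this is why the enzyme count is 23 rather
than the number of names in common catalogues. Users can add enzymes with
`register_custom()` (value semantics; name collisions are errors) and
persist registries with `write_registry()`/`read_registry()`.

The class determines geometry. Class II enzymes read the PAM downstream of
the protospacer, so the suggested spacer is the 20 nt immediately 5' of the
PAM window on the PAM-bearing strand. Class V enzymes read it upstream, so
the spacer is the 23 nt immediately 3'. When the flank is too short the
spacer is truncated and flagged `grna_complete = FALSE`; such matches are
kept by default (the user may have more flank available than they supplied)
and can be excluded via `scan_options(include_incomplete_grna = FALSE)`.
The 20/23 defaults are the conventional lengths for the two classes and are
per-enzyme fields, not global constants.

## 3. Coordinates and indel conventions

All coordinates are 0-based, half-open, in the variant-allele (`var_seq`)
plus-strand frame. The "affected interval" — the positions a window must
overlap — is:

* substitution: `[u, u+1)` on both alleles, where `u` is the length of the
  upstream flank;
* insertion: `[u, u+1)` on the variant allele; on the reference allele the
  inserted base is absent, so the affected region is the junction
  `[u-1, u+1)` (clipped at sequence ends) — a reference PAM straddling the
  junction must still veto;
* deletion: symmetric — junction `[u-1, u+1)` on the variant allele,
  `[u, u+1)` (the deleted base) on the reference allele.

Minus-strand scanning reverse-complements both sequences, mirrors the
affected intervals, runs the identical plus-strand algorithm, and maps
window coordinates back. A property test (section 5) checks that
reverse-complementing the *input* record exactly flips strand labels
without changing the match set.

## 4. Verification strategy: an independent oracle

The production scanner (`scan_variant()`) enumerates candidate windows and
tests them with cached regular expressions. To guard against shared bugs,
the package also ships `brute_force_oracle()`, which takes a deliberately
different route: every degenerate motif is expanded into its complete set
of literal words (`expand_motif()`), and acceptance is decided by literal
substring search over explicitly constructed plus- and minus-strand frames.
The two implementations share only the registry and the acceptance rule's
*definition*, not its code.

The test suite asserts exact agreement between scanner and oracle on
hundreds of random records spanning all three variant types, and
additionally cross-checks the package's hand-rolled reverse complement
against `Biostrings::reverseComplement` on random sequences.

## 5. Synthetic cohorts and what they can show

`make_cohort()` builds seeded cohorts from two generators, each of which
*verifies its own output through the oracle* before returning:

* `plant_positive()` embeds a concrete word of a chosen enzyme's motif at a
  position overlapping a substitution, choosing the reference base so that
  the enzyme is not reference-blocked; it retries (bounded) until the
  oracle confirms the plant.
* `plant_negative()` rejection-samples short-flank records until the full
  registry yields zero matches.

Flanks are i.i.d. uniform over A/C/G/T (optionally GC-biased). This is a
deliberate simplification: real genomes have dinucleotide structure,
repeats, and mutation-type biases (human SNVs are dominated by
transitions, especially CpG-driven C>T). The synthetic cohorts therefore
support *correctness* claims — planted truth is recovered exactly; negative
records stay negative — but not quantitative claims about clinical variant
databases. Cohort summaries (`summarize_cohort()`) report the matched
fraction, per-enzyme coverage, records rescued only by engineered enzymes,
and the substitution-type profile of untargetable records.

One mechanistic observation the uniform model *does* support: among
substitutions in uniform random context, untargetable records concentrate
in the C>T and G>A types. This is registry structure, not biology — the
registry is rich in G-gaining PAM opportunities (`NGG` and relatives) and
T-rich class V motifs, and a C>T change on the plus strand is a G>A change
on the minus strand, the one direction that destroys rather than creates
both kinds of signal. The test suite asserts this concentration on a
12,000-record uniform cohort (1,000 per directed substitution type), and
`scripts/acceptance.R` recomputes it for any seed.

Problem sizes used by the shipped tests are the package's own choices,
sized to finish in minutes while leaving no variant type or enzyme
unexercised: 600 random records for scanner/oracle equivalence, 200 for
strand symmetry, 12,000 for the substitution-type profile, plus
per-example unit tests for every registry entry and every documented
convention.

## 6. Numerical and engineering choices

* Regular expressions and motif expansions are memoised in package-local
  environments; a full 23-enzyme, both-strand scan of one variant runs in
  roughly 10–15 ms, so cohort-scale runs are linear and fast.
* All randomness is namespaced through `withr::with_seed()`; generators
  never touch the caller's RNG state, and derived seeds are drawn below
  2^31.
* Sequence validation is strict (A/C/G/T only, errors report 0-based
  offending positions); VCF ingestion normalises anchor-base indels,
  verifies REF against the FASTA, and skips unsupported records with
  warnings rather than failing a whole file.

## 7. Open decisions and limitations

* **Exclusivity semantics.** Rejection is per enzyme and per strand. An
  enzyme blocked on the plus strand may still be reported on the minus
  strand; whether a strand-level veto should escalate to the whole enzyme
  is a judgement call — the current choice reports the strand-resolved
  truth and leaves policy to the user.
* **PAM-level specificity only.** The package guarantees the PAM is absent
  from the reference allele at the locus. It does not score genome-wide
  off-targets, spacer efficiency, chromatin accessibility, or delivery —
  reported gRNAs are candidates for downstream tools, not final designs.
* **Binary PAM model.** PAM recognition is treated as all-or-nothing per
  motif; quantitative cleavage preferences within a degenerate motif are
  out of scope.
* **Variant scope.** Substitutions and single-base indels only; multi-base
  events are skipped at ingestion with a warning.
* **Registry counting.** Enzymes that are behaviourally identical under
  this model share one entry (AsCas12a/LbCas12a); users who need them
  listed separately can register duplicates under distinct names.
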