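---
title: "Methods: substitution-space analytics and evidence-driven labelling of coding variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substitution-space analytics and evidence-driven labelling of coding variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unsense)
```

## The problem

Annotation pipelines classify coding SNVs from the codon table alone:
missense, nonsense, or "synonymous". The third label is an overstatement —
it asserts a negative (no functional consequence) that the codon table
cannot establish. A substitution that preserves the amino acid can still
abolish the protein by impairing splicing or expression regulation. This
package provides (i) exact combinatorics of the genetic code's
substitution space, (ii) a deterministic, evidence-driven rule engine
assigning labels that say only what is known, and (iii) an auditor for
existing annotations.

## The substitution space

Counting is **directed**: each ordered ref→alt change at one codon
position is one record, giving exactly 9 per codon and 64 × 9 = 576 for a
64-codon table. This convention makes the arithmetic exact and makes the
symmetric categories (synonymous, stop-to-stop) necessarily even in
count.

```{r}
s <- summarize_space(enumerate_substitution_space(codon_table()))
s$counts
```

Two figures sometimes quoted for this space — 141 synonymous (24.5%) and
137 between coding codons (23.8%) — cannot both be right under any
symmetric counting: their difference is the 4 stop-to-stop changes, and
137 is odd while the synonymous relation is symmetric. We therefore treat
an **independent oracle** as the authority: list, per amino acid, the
unordered codon pairs at Hamming distance 1 and double for direction.
Enumeration and oracle agree on 134 coding-synonymous records
(+4 stop-to-stop = 138 folded, 24.0%). Similarly, brute force finds 8 of
the 16 first-two-base codon groups fully third-position interchangeable
(TC, CT, CC, CG, AC, GT, GC, GG), not the sometimes-quoted 7. Both
discrepancies are stated in the summary's `notes` field rather than
hidden; the verifiable printed counts (576 total, 4 stop-to-stop, 8
synonymous records off the third position, all at position 1, 1.4% of the
space) reproduce exactly.

Chemistry is a pure partition: at each of the 192 (codon, position)
slots, exactly 1 of the 3 alternatives is a transition, so
transitions:transversions = 192:384 at every position.

## The classification rule engine

Labels are assigned in two stages.

**Stage 1 — codon level.** `MISSENSE`, `NONSENSE` and `STOP_LOSS` changes
are decided by the codon table regardless of evidence; evidence is kept as
co-annotation. `STOP_LOSS` maps to the final label `MISSENSE`: it changes
the protein product (read-through) without introducing a stop at the
site, and the final-label vocabulary reserves `NONSENSE` for introduced
stops.

**Stage 2 — evidence level**, for codon-`SYNONYMOUS` changes
(`STOP_TO_STOP` routes through the same rules, since no amino acid
changes; the codon category is preserved in the output):

| evidence | final label |
|---|---|
| none | `UNVERIFIED_SYNONYMOUS_PREDICTED` |
| any mechanism in {`SPLICE_SITE`, `ESE`, `ESS`, `MIRNA_BINDING`} | `UNSENSE` |
| effect evidence only via `TF_BINDING` (DNA), `MRNA_STRUCTURE_STABILITY` (RNA), or protein-level mechanisms | `SYNONYMOUS_WITH_EFFECT` |
| all evidence shows no effect | `VERIFIED_SYNONYMOUS` |

Mixed evidence: an unsense mechanism dominates, but all mechanisms,
effects and levels are reported. Conflicting no-effect plus effect
records set a `conflict` flag and the label follows the effect evidence
(a positive finding outweighs a negative one from another assay).

Design choices that were genuinely open:

* **Unsense scope.** `MRNA_STRUCTURE_STABILITY` affects expression, and
  DNA-level TF-binding disruption can too; one could argue both belong
  under unsense ("impairs gene expression"). We keep unsense for the
  three RNA regulatory mechanisms (splicing, splicing regulation, miRNA
  regulation) and report the others as `SYNONYMOUS_WITH_EFFECT` with
  their levels — the narrower reading keeps the term crisp and the
  information is not lost.
* **Evidence, never prediction.** The package contains no splice-site,
  ESE/ESS or miRNA-site predictor. Sequence-based predictors of
  "synonymous variant effects" are a separate, error-prone activity;
  here mechanism assignment requires an evidence record (assay,
  mechanism, effect, level), and their absence yields an explicitly
  *unverified* label.
* **A bare `synonymous` claim** is confirmed in audit only by
  `VERIFIED_SYNONYMOUS`; against any other computed synonymous-family
  label it is `OVERCLAIMED_SYNONYMOUS` — that asymmetry is the point of
  the audit.

## Frame and NMD rules

For an exon-skip or exonic indel, the reading frame is retained iff the
affected **coding** length is divisible by 3 (the skipped exon's overlap
with the CDS, not its full length). A frameshift is assumed to create a
premature termination codon (PTC); when no measured PTC position is
supplied and no sequence is at hand, it is modelled at the event start,
a deliberately conservative (most-5') choice. Decay is predicted unless
the PTC escapes: escape iff the PTC lies in the last exon or within
`penultimate_window_nt` (default 50 nt, the conventional boundary
relative to the last exon–exon junction; configurable, ≥ 0) of the 3'
end of the penultimate exon. Formally, with penultimate exon ending at
transcript position $e$, a PTC at $p$ escapes iff $p > e - w$ — a single
threshold, so escape is monotone in $p$: anything downstream of an
escaping PTC also escapes. Predicted decay adds the `MISSING_RNA` effect
(a variant in a degraded transcript is not "silent"; there is no RNA and
no protein). Single-exon transcripts always escape (no junction
downstream); skipping the only exon is a model error, and events in
fully non-coding exons are no-ops with empty tags.

## Coordinates and formats

CDS positions are 1-based; `codon_index = ceiling(pos/3)`,
`codon_pos = ((pos-1) mod 3) + 1`. Exon boundaries are 1-based inclusive
in transcript space, both in the JSON schema and in the GFF3 subset
(per the GFF3 standard). DNA is the internal alphabet; U is normalised
to T on input. Only the HGVS `c.` substitution subset plus
length-bearing `del`/`ins` (parsed solely for the frame rule) is
accepted; intronic offsets, duplications, inversions and protein-level
descriptions raise explicit out-of-scope errors, never silent skips.
The VCF annotator streams text and edits only the INFO column, so
CHROM..FILTER are byte-identical on output — a deliberate substitution
of a hand-streamed writer for a parse/reserialize round trip, which
would not give that guarantee. Percentages print rounded half-up to one
decimal.

## What the fixture generator emulates — and what it does not

`generate_fixture()` states a world: transcripts of 3–6 exons of 60–180
nt, CDS sequences drawn uniformly over the 61 sense codons with a
terminal stop; SNVs at distinct CDS positions; evidence planted on
codon-synonymous variants at a splicing fraction of 0.23 (the reported
rate at which saturation minigene assays of one well-studied exon found
synonymous variants decreasing exon inclusion, 32/138), and 0.05 each
for miRNA-binding and protein-level mechanisms (single-digit-percent
mechanisms; no published per-mechanism rate exists, so a small value was
fixed once). Half of the evidence-free codon-synonymous variants are
claimed "synonymous" — the misuse under audit; published accounts are
qualitative ("widely misused"), so 0.5 was fixed once as a neutral
default. Planting is by exact round-half-up counts so tests are
deterministic; a Bernoulli mode exists behind a flag. All randomness is
integer-based (`sample.int`) for cross-platform reproducibility.

The generator does **not** emulate: realistic splice-motif content
(evidence is planted, not derivable from sequence), codon-usage bias,
linkage between variants, indels, or genomic (as opposed to transcript)
coordinates. A green planted-truth test therefore establishes that the
classifier and auditor propagate evidence correctly and
deterministically — not that any sequence-based effect could be
detected, which is explicitly out of scope.

## Numerical and degenerate-input choices

* Errors are typed conditions (`uns_input_error`, `uns_parse_error`,
  `uns_out_of_scope_error`, `uns_model_error`, `uns_consistency_error`,
  `uns_linkage_error`, ...) so callers can discriminate; distance-0 and
  distance-≥2 codon changes are distinct errors.
* `summarize_space()` refuses incomplete enumerations (total ≠ 9 × number
  of codons).
* Audit records without a claimed label are skipped and counted, keeping
  verdict counts a partition of the input.
* The term registry validates id uniqueness and parent-link acyclicity on
  load; the original figure's ontology accession codes were not available
  in machine-readable form, so `vario_code` is `null` (untranscribed) and
  ids are package-local.

## Known limitations

Transcript-coordinate VCFs only (no genome liftover); no pathogenicity or
population-frequency scoring; no effect prediction from sequence; the
HGVS grammar beyond the substitution/del/ins subset is rejected rather
than parsed; alternative codon tables are supported by the combinatorics
but the shipped defaults and all quoted counts assume the standard code.
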