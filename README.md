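# unsense

Looking only at the genetic code, a coding single-nucleotide variant is
missense, nonsense or "synonymous". But a codon-synonymous substitution can
still destroy a transcript or its protein — by altering an exonic splice
site or splicing regulator (ESE/ESS), an exonic miRNA binding site, mRNA
structure/stability, a transcription-factor binding site overlapping the
codon, codon-usage-dependent translation, co-translational folding, or a
post-translational modification. Variant files that call every such change
"synonymous" without evidence routinely bury disease-causing variants.

`unsense` is an R toolkit for clinical-genetics and annotation pipelines
that takes this seriously:

* **Substitution-space analytics.** Exhaustive, directed enumeration of
  the 64 × 9 = 576 single-base codon substitutions of a codon table, with
  category counts (synonymous / missense / nonsense / stop-loss /
  stop-to-stop), transition:transversion partition, per-position
  breakdowns, wobble-group analysis, and an independent per-amino-acid
  pair-listing oracle that serves as the authority for the counts.
* **Evidence-driven classification.** A codon-synonymous change is never
  labelled "synonymous" from the codon table alone. With experimental
  evidence of a splicing, splicing-regulation or miRNA-binding mechanism
  it is an **unsense** variant (expression/protein production affected
  without a stop codon at the site); with effects only at DNA or protein
  level, **synonymous-with-effect**; with evidence of no effect,
  **verified synonymous**; with no evidence,
  **unverified synonymous (predicted)**. Frame-retention
  (length divisible by 3) and nonsense-mediated-decay escape rules
  (last exon, or within a configurable 50-nt window of the penultimate
  exon's 3' end) interpret splicing consequences.
* **Audit mode.** Recomputes labels for a variant file and flags every
  evidence-free or evidence-contradicted "synonymous" claim as
  `OVERCLAIMED_SYNONYMOUS`.
* **I/O.** Minimal HGVS `c.` substitution parsing, transcript models as
  JSON or a GFF3 subset, evidence TSVs, codon-table TSVs, and a streaming
  VCF annotator that adds `UNS_CAT`/`UNS_LABEL`/`UNS_MECH`/`UNS_EVID`
  INFO keys while passing CHROM..FILTER through byte-identical.
* **Seeded fixtures.** A deterministic generator of toy transcripts,
  coding sequences, variants, claimed labels and planted evidence, so the
  whole pipeline is testable offline.

## Worked example

```r
library(unsense)

summarize_space(enumerate_substitution_space(codon_table()))
#> substitution space of codon table 'standard'
#>   total records: 576
#>   synonymous     134 (23.3%)
#>   missense       392 (68.1%)
#>   nonsense        23 (4.0%)
#>   stop_loss       23 (4.0%)
#>   stop_to_stop     4 (0.7%)
#>   synonymous off third position: 8 (pos1=8, pos2=0)
#>   transitions:transversions = 192:384
#>   fully wobble-interchangeable groups: 8 of 16
```

576 directed records; 134 are coding-synonymous (138 when stop-to-stop
changes are folded in), only 8 of them (1.4% of the space) off the wobble
position — all 8 at the first codon position. Sometimes-quoted totals of
141/137 cannot arise under directed counting (137 is odd; the relation is
symmetric) and are documented in the summary's `notes` field.

```r
obs <- variant_observation("SMN2", 840, "C", "T")
ev  <- evidence_record(variant_key(obs), "minigene", "ESS",
                       "MISSING_RNA", "RNA")
classify_variant(obs, "GGC", "GGT", ev)
#> SMN2:c.840C>T: UNSENSE (codon level synonymous)
#>   mechanisms: ESS
#>   effects:    MISSING_RNA
#>   evidence: effect_shown (1 record(s))

classify_variant(obs, "GGC", "GGT")   # same change, no evidence
#> SMN2:c.840C>T: UNVERIFIED_SYNONYMOUS_PREDICTED (codon level synonymous)
#>   evidence: none (0 record(s))
```

The same codon change is an unsense variant with minigene evidence of an
exonic-splicing-silencer mechanism, and only an unverified prediction
without it.

```r
b <- generate_fixture(fixture_spec(seed = 7, n_variants = 100))
audit_annotations(b$variants, b$evidence)
#> audit of 100 record(s): 86 confirmed, 14 overclaimed synonymous,
#> 0 mislabeled, 0 skipped
```

The 14 overclaims are exactly the variants whose claimed "synonymous"
label the planted evidence (or its absence) does not support.

## Command line

```sh
SCRIPT=$(Rscript -e 'cat(system.file("cli", "unsense.R", package = "unsense"))')
Rscript $SCRIPT space    --out space.json
Rscript $SCRIPT fixtures --seed 1 --out fx/
Rscript $SCRIPT audit    --variants fx/variants.tsv --evidence fx/evidence.tsv --out audit
Rscript $SCRIPT classify --vcf fx/variants.vcf --transcripts fx/transcripts.json \
                         --evidence fx/evidence.tsv --out annotated.vcf
```

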