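# Seeded generator of toy transcripts, coding sequences, variants, claimed
# labels and planted evidence. Everything downstream of the seed uses
# sample.int()-style integer draws only, so identical spec + seed gives
# identical bundles across platforms.

#' Fixture generation specification
#'
#' Defaults state the emulated world: a splicing-evidence fraction of 0.23
#' among codon-synonymous variants (matching the reported 23% = 32/138
#' exon-inclusion-decreasing rate in a saturation minigene screen of one
#' exon), miRNA-binding and protein-level evidence fractions of 0.05 each
#' (small, single-digit-percent mechanisms), and half of the evidence-free
#' codon-synonymous variants claimed "synonymous" (emulating annotation
#' pipelines that label from the codon table alone).
#'
#' @param seed integer RNG seed.
#' @param n_transcripts number of transcripts.
#' @param exons_per_transcript length-2 range of exon counts.
#' @param exon_length_range length-2 range of exon lengths (nt).
#' @param n_variants number of SNVs to place (all within CDS).
#' @param fraction_splicing_evidence fraction of codon-synonymous variants
#'   given `SPLICE_SITE`/`ESE`/`ESS` evidence.
#' @param fraction_mirna_evidence fraction given `MIRNA_BINDING` evidence.
#' @param fraction_protein_evidence fraction given protein-level evidence.
#' @param fraction_claimed_synonymous_without_evidence fraction of the
#'   evidence-free codon-synonymous variants claimed `"synonymous"`.
#' @param bernoulli draw planting per-variant (stochastic counts) instead
#'   of planting exact round-half-up counts.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_transcripts = 5L,
                         exons_per_transcript = c(3L, 6L),
                         exon_length_range = c(60L, 180L),
                         n_variants = 200L,
                         fraction_splicing_evidence = 0.23,
                         fraction_mirna_evidence = 0.05,
                         fraction_protein_evidence = 0.05,
                         fraction_claimed_synonymous_without_evidence = 0.5,
                         bernoulli = FALSE) {
  fr <- c(fraction_splicing_evidence, fraction_mirna_evidence,
          fraction_protein_evidence)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    uns_stop("evidence fractions must be in [0,1] and jointly <= 1",
             "uns_input_error")
  f4 <- fraction_claimed_synonymous_without_evidence
  if (f4 < 0 || f4 > 1)
    uns_stop("fraction_claimed_synonymous_without_evidence must be in [0,1]",
             "uns_input_error")
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 exons_per_transcript = exons_per_transcript,
                 exon_length_range = exon_length_range,
                 n_variants = n_variants,
                 fraction_splicing_evidence = fraction_splicing_evidence,
                 fraction_mirna_evidence = fraction_mirna_evidence,
                 fraction_protein_evidence = fraction_protein_evidence,
                 fraction_claimed_synonymous_without_evidence = f4,
                 bernoulli = isTRUE(bernoulli)),
            class = "fixture_spec")
}

# evidence templates per planted mechanism class
plant_evidence_row <- function(key, mechanism) {
  switch(mechanism,
    SPLICE_SITE = evidence_record(key, "minigene", "SPLICE_SITE",
                                  "ABERRANT_SPLICING", "RNA"),
    ESE = evidence_record(key, "minigene", "ESE", "EXON_SKIPPING", "RNA"),
    ESS = evidence_record(key, "minigene", "ESS", "MISSING_RNA", "RNA"),
    MIRNA_BINDING = evidence_record(key, "reporter", "MIRNA_BINDING",
                                    "EXPRESSION_CHANGE", "RNA"),
    CODON_USAGE_TRANSLATION = evidence_record(key, "pulse-chase",
                                              "CODON_USAGE_TRANSLATION",
                                              "PROTEIN_ABUNDANCE_CHANGE",
                                              "PROTEIN"),
    COTRANSLATIONAL_FOLDING = evidence_record(key, "folding assay",
                                              "COTRANSLATIONAL_FOLDING",
                                              "CONFORMATION_CHANGE",
                                              "PROTEIN"),
    PTM = evidence_record(key, "phosphoproteomics", "PTM", "PTM_LOSS",
                          "PROTEIN"),
    uns_stop(sprintf("no evidence template for '%s'", mechanism),
             "uns_input_error"))
}

#' Generate a seeded fixture bundle
#'
#' Builds transcripts with CDS sequences (codons sampled uniformly over
#' the 61 sense codons, a terminal stop appended), places `n_variants`
#' distinct SNVs within the CDSs, plants evidence on codon-synonymous
#' variants at the spec's exact round-half-up counts (or Bernoulli draws
#' when `spec$bernoulli`), assigns claimed labels, and records the planted
#' truth for every variant in a manifest.
#'
#' Claimed labels: missense/nonsense codon changes are claimed correctly;
#' every evidence-bearing codon-synonymous variant is claimed
#' `"synonymous"` (the misuse under audit); of the evidence-free
#' codon-synonymous variants, the configured fraction is claimed
#' `"synonymous"` (overclaim) and the rest
#' `"unverified_synonymous_predicted"`.
#'
#' @param spec a [fixture_spec()].
#' @return a `fixture_bundle`: `transcripts` (models with sequences),
#'   `variants` (data.frame incl. codons and `claimed_label`), `evidence`,
#'   `manifest` (planted mechanism, expected label and expected audit
#'   verdict per variant), and the `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  table <- codon_table()
  sense <- sort(names(table)[table != "*"])

  rint <- function(lo, hi, n = 1L) lo + sample.int(hi - lo + 1L, n,
                                                   replace = TRUE) - 1L
  transcripts <- list()
  for (i in seq_len(spec$n_transcripts)) {
    id <- sprintf("TX%03d", i)
    n_ex <- rint(spec$exons_per_transcript[1], spec$exons_per_transcript[2])
    ex <- rint(spec$exon_length_range[1], spec$exon_length_range[2], n_ex)
    total <- sum(ex)
    cds_start <- rint(1L, max(1L, min(30L, ex[1] - 1L)))
    utr3 <- rint(0L, max(0L, min(30L, ex[n_ex] - 1L)))
    cds_len <- ((total - utr3 - cds_start + 1L) %/% 3L) * 3L
    cds_end <- cds_start + cds_len - 1L
    n_codons <- cds_len %/% 3L
    seq <- paste0(c(sense[sample.int(length(sense), n_codons - 1L,
                                     replace = TRUE)], "TAA"),
                  collapse = "")
    transcripts[[id]] <- transcript_model(id, ex, cds_start, cds_end,
                                          "+", seq)
  }

  # all (transcript, cds position) slots; sample distinct ones
  slots <- do.call(rbind, lapply(transcripts, function(tx)
    data.frame(transcript_id = tx$transcript_id,
               cds_pos = seq_len(nchar(tx$cds_seq)))))
  if (spec$n_variants > nrow(slots))
    uns_stop(sprintf("n_variants = %d exceeds the %d available CDS positions",
                     spec$n_variants, nrow(slots)), "uns_spec_error")
  pick <- sort(sample.int(nrow(slots), spec$n_variants))
  variants <- slots[pick, , drop = FALSE]
  rownames(variants) <- NULL
  variants$ref_base <- vapply(seq_len(nrow(variants)), function(i)
    substr(transcripts[[variants$transcript_id[i]]]$cds_seq,
           variants$cds_pos[i], variants$cds_pos[i]), character(1))
  variants$alt_base <- vapply(variants$ref_base, function(r) {
    alts <- setdiff(UNS_BASES, r)
    alts[sample.int(3L, 1L)]
  }, character(1), USE.NAMES = FALSE)
  variants <- derive_codons(variants, transcripts)
  variants$category <- vapply(seq_len(nrow(variants)), function(i)
    classify_codon_substitution(variants$ref_codon[i], variants$alt_codon[i],
                                table), character(1))
  variants$variant_id <- vapply(seq_len(nrow(variants)), function(i)
    variant_key(variants[i, ]), character(1))

  # plant evidence on codon-synonymous (incl. stop-to-stop) variants
  eligible <- which(variants$category %in% c("SYNONYMOUS", "STOP_TO_STOP"))
  n_el <- length(eligible)
  if (spec$bernoulli) {
    u <- sample.int(10000L, n_el, replace = TRUE) / 10000
    cut1 <- spec$fraction_splicing_evidence
    cut2 <- cut1 + spec$fraction_mirna_evidence
    cut3 <- cut2 + spec$fraction_protein_evidence
    splice_i <- eligible[u <= cut1]
    mirna_i <- eligible[u > cut1 & u <= cut2]
    protein_i <- eligible[u > cut2 & u <= cut3]
  } else {
    n_splice <- round_half_up(spec$fraction_splicing_evidence * n_el)
    n_mirna <- round_half_up(spec$fraction_mirna_evidence * n_el)
    n_protein <- round_half_up(spec$fraction_protein_evidence * n_el)
    shuffled <- eligible[sample.int(n_el)]
    splice_i <- head(shuffled, n_splice)
    mirna_i <- head(shuffled[-seq_len(n_splice)], n_mirna)
    protein_i <- head(shuffled[-seq_len(n_splice + n_mirna)], n_protein)
  }
  splice_mechs <- c("SPLICE_SITE", "ESE", "ESS")
  protein_mechs <- c("CODON_USAGE_TRANSLATION", "COTRANSLATIONAL_FOLDING",
                     "PTM")
  planted <- rep(NA_character_, nrow(variants))
  planted[splice_i] <- splice_mechs[sample.int(3L, length(splice_i),
                                               replace = TRUE)]
  planted[mirna_i] <- "MIRNA_BINDING"
  planted[protein_i] <- protein_mechs[sample.int(3L, length(protein_i),
                                                 replace = TRUE)]
  ev_rows <- lapply(which(!is.na(planted)), function(i)
    plant_evidence_row(variants$variant_id[i], planted[i]))
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows)
    else read_evidence_empty()

  # expected final labels (planted truth)
  expected <- ifelse(variants$category %in% c("MISSENSE", "STOP_LOSS"),
                     "MISSENSE",
              ifelse(variants$category == "NONSENSE", "NONSENSE",
              ifelse(!is.na(planted) & planted %in% UNSENSE_MECHANISMS,
                     "UNSENSE",
              ifelse(!is.na(planted), "SYNONYMOUS_WITH_EFFECT",
                     "UNVERIFIED_SYNONYMOUS_PREDICTED"))))

  # claimed labels
  claimed <- tolower(expected)
  claimed[!is.na(planted)] <- "synonymous"           # misuse under audit
  free_syn <- which(is.na(planted) &
                    variants$category %in% c("SYNONYMOUS", "STOP_TO_STOP"))
  n_over <- round_half_up(
    spec$fraction_claimed_synonymous_without_evidence * length(free_syn))
  over_i <- head(free_syn[sample.int(max(length(free_syn), 1L))[
    seq_len(length(free_syn))]], n_over)
  claimed[over_i] <- "synonymous"
  variants$claimed_label <- claimed

  verdict <- ifelse(claimed == "synonymous" &
                    expected %in% c("UNVERIFIED_SYNONYMOUS_PREDICTED",
                                    "UNSENSE", "SYNONYMOUS_WITH_EFFECT"),
                    "OVERCLAIMED_SYNONYMOUS",
             ifelse(toupper(claimed) == expected, "CONFIRMED", "MISLABELED"))

  manifest <- data.frame(variant_id = variants$variant_id,
                         codon_category = variants$category,
                         planted_mechanism = planted,
                         expected_label = expected,
                         claimed_label = claimed,
                         expected_verdict = verdict,
                         stringsAsFactors = FALSE)
  structure(list(spec = spec, transcripts = transcripts,
                 variants = variants, evidence = evidence,
                 manifest = manifest),
            class = "fixture_bundle")
}

read_evidence_empty <- function() {
  evidence_record("x", "x", "NONE_OBSERVED", "NO_EFFECT", "RNA")[0, ]
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("fixture bundle (seed %d): %d transcript(s), %d variant(s), %d evidence record(s)\n",
              x$spec$seed, length(x$transcripts), nrow(x$variants),
              nrow(x$evidence)))
  cat("  codon categories:",
      paste(sprintf("%s=%d", names(table(x$variants$category)),
                    table(x$variants$category)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a fixture bundle to a directory
#'
#' Emits the same dialects the readers consume: `transcripts.json` (with
#' sequences), `transcripts.gff3`, `variants.tsv` (with codons and claimed
#' labels), `variants.vcf`, `evidence.tsv` and `manifest.json`.
#'
#' @param bundle a [generate_fixture()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transcript_models_json(bundle$transcripts,
                               file.path(dir, "transcripts.json"))
  write_transcript_models_gff3(bundle$transcripts,
                               file.path(dir, "transcripts.gff3"))
  v <- bundle$variants
  write.table(v[, c("variant_id", "transcript_id", "cds_pos", "ref_base",
                    "alt_base", "ref_codon", "alt_codon", "claimed_label")],
              file.path(dir, "variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", names(bundle$transcripts)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$transcript_id, v$cds_pos,
                   v$variant_id, v$ref_base, v$alt_base))
  writeLines(vcf, file.path(dir, "variants.vcf"))
  write_evidence(bundle$evidence, file.path(dir, "evidence.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
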