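# Evidence-driven classification. The design principle throughout: the
# codon table alone can never justify the label "synonymous"; only
# experimental evidence can. No mechanism is ever predicted from sequence.

#' Final variant labels
#'
#' `MISSENSE` and `NONSENSE` are decided at codon level. A codon-level
#' synonymous (or stop-to-stop) change becomes `UNSENSE` when evidence
#' shows a splicing / splicing-regulation / miRNA-regulation mechanism,
#' `SYNONYMOUS_WITH_EFFECT` when evidence shows an effect only at DNA or
#' protein level or via mRNA structure/stability, `VERIFIED_SYNONYMOUS`
#' when evidence shows no effect, and
#' `UNVERIFIED_SYNONYMOUS_PREDICTED` when there is no evidence at all.
#'
#' @export
UNS_FINAL_LABELS <- c("MISSENSE", "NONSENSE", "UNSENSE",
                      "SYNONYMOUS_WITH_EFFECT", "VERIFIED_SYNONYMOUS",
                      "UNVERIFIED_SYNONYMOUS_PREDICTED")

# ---- TranscriptModel -------------------------------------------------------

#' Transcript model
#'
#' Exon lengths in transcript order (5' to 3'), with the CDS span given as
#' 1-based inclusive transcript coordinates. CDS length must be divisible
#' by 3 (the terminal stop codon is part of the CDS).
#'
#' @param transcript_id identifier.
#' @param exon_lengths positive integer vector, at least one exon.
#' @param cds_start,cds_end 1-based inclusive transcript coordinates.
#' @param strand optional `"+"`/`"-"` marker for genomic mapping.
#' @param cds_seq optional CDS nucleotide sequence of length
#'   `cds_end - cds_start + 1` (used to derive codons for variants).
#' @return a `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exon_lengths, cds_start, cds_end,
                             strand = NA_character_, cds_seq = NULL) {
  exon_lengths <- as.integer(exon_lengths)
  if (length(exon_lengths) < 1L || any(exon_lengths <= 0L))
    uns_stop(sprintf("transcript '%s': need at least one positive exon length",
                     transcript_id), "uns_model_error")
  total <- sum(exon_lengths)
  if (cds_start < 1L || cds_end > total || cds_end < cds_start)
    uns_stop(sprintf("transcript '%s': CDS span [%d, %d] outside transcript of length %d",
                     transcript_id, cds_start, cds_end, total),
             "uns_model_error")
  cds_len <- cds_end - cds_start + 1L
  if (cds_len %% 3L != 0L)
    uns_stop(sprintf("transcript '%s': CDS length %d not divisible by 3",
                     transcript_id, cds_len), "uns_model_error")
  if (!is.null(cds_seq)) {
    cds_seq <- normalize_codon_chars(cds_seq)
    if (nchar(cds_seq) != cds_len)
      uns_stop(sprintf("transcript '%s': cds_seq length %d != CDS length %d",
                       transcript_id, nchar(cds_seq), cds_len),
               "uns_model_error")
  }
  structure(list(transcript_id = transcript_id, exon_lengths = exon_lengths,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 strand = strand, cds_seq = cds_seq),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript %s: %d exon(s), length %d nt, CDS %d..%d (%d nt)%s\n",
              x$transcript_id, length(x$exon_lengths), sum(x$exon_lengths),
              x$cds_start, x$cds_end, x$cds_end - x$cds_start + 1L,
              if (is.null(x$cds_seq)) "" else ", with sequence"))
  invisible(x)
}

# 1-based inclusive transcript-space exon boundaries
exon_bounds <- function(model) {
  ends <- cumsum(model$exon_lengths)
  data.frame(exon = seq_along(ends),
             start = c(1L, head(ends, -1L) + 1L), end = ends)
}

exon_of_position <- function(model, tx_pos) {
  b <- exon_bounds(model)
  idx <- findInterval(tx_pos, b$start)
  idx[tx_pos < 1L | tx_pos > sum(model$exon_lengths)] <- NA_integer_
  idx
}

# coding overlap of exon k with the CDS, in nt
exon_coding_length <- function(model, k) {
  b <- exon_bounds(model)
  max(0L, min(b$end[k], model$cds_end) - max(b$start[k], model$cds_start) + 1L)
}

# ---- coordinate mapping ----------------------------------------------------

#' Map a CDS position to its codon
#'
#' `codon_index = ceiling(cds_pos / 3)`;
#' `codon_pos = ((cds_pos - 1) %% 3) + 1`. The round trip
#' `3 * (codon_index - 1) + codon_pos == cds_pos` always holds.
#'
#' @param cds_pos 1-based position(s) within the CDS.
#' @param transcript optional [transcript_model()]; when supplied,
#'   positions beyond the CDS length raise a range error.
#' @return data.frame with columns `cds_pos`, `codon_index`, `codon_pos`.
#' @examples
#' map_cds_position(840)  # codon 280, position 3
#' @export
map_cds_position <- function(cds_pos, transcript = NULL) {
  cds_pos <- as.integer(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L))
    uns_stop("cds_pos must be a positive integer", "uns_input_error")
  if (!is.null(transcript)) {
    cds_len <- transcript$cds_end - transcript$cds_start + 1L
    if (any(cds_pos > cds_len))
      uns_stop(sprintf("cds_pos %d exceeds CDS length %d of transcript %s",
                       max(cds_pos), cds_len, transcript$transcript_id),
               "uns_range_error")
  }
  data.frame(cds_pos = cds_pos,
             codon_index = (cds_pos - 1L) %/% 3L + 1L,
             codon_pos = (cds_pos - 1L) %% 3L + 1L)
}

#' Extract a codon from a CDS sequence
#' @param cds_seq CDS nucleotide string.
#' @param codon_index 1-based codon index.
#' @return the codon.
#' @export
codon_at <- function(cds_seq, codon_index) {
  s <- 3L * (codon_index - 1L) + 1L
  if (s + 2L > nchar(cds_seq))
    uns_stop(sprintf("codon index %d beyond CDS of %d nt", codon_index,
                     nchar(cds_seq)), "uns_range_error")
  substr(cds_seq, s, s + 2L)
}

# ---- NMD configuration -----------------------------------------------------

#' NMD escape configuration
#'
#' A premature termination codon escapes nonsense-mediated decay when it
#' lies in the last exon or within `penultimate_window_nt` of the 3' end
#' of the penultimate exon (the conventional 50-nt boundary upstream of
#' the last exon-exon junction).
#'
#' @param penultimate_window_nt non-negative window, default 50.
#' @return an `nmd_config`.
#' @export
nmd_config <- function(penultimate_window_nt = 50L) {
  if (!is_count(penultimate_window_nt) || penultimate_window_nt < 0)
    uns_stop("penultimate_window_nt must be a non-negative integer",
             "uns_input_error")
  structure(list(penultimate_window_nt = as.integer(penultimate_window_nt)),
            class = "nmd_config")
}

# TRUE iff a PTC at transcript position ptc_pos escapes NMD; monotone in
# ptc_pos (single transcript-space threshold)
nmd_escapes <- function(model, ptc_pos, nmd = nmd_config()) {
  b <- exon_bounds(model)
  n <- nrow(b)
  if (n == 1L) return(rep(TRUE, length(ptc_pos)))
  threshold <- b$end[n - 1L] - nmd$penultimate_window_nt
  ptc_pos > threshold
}

# ---- splice consequence ----------------------------------------------------

#' Consequence of a splicing-level event on a transcript
#'
#' Applies the frame rule and the NMD escape rule to an exon-skipping or
#' exonic insertion/deletion event. The reading frame is retained iff the
#' affected coding length is divisible by 3. A frameshift is assumed to
#' create a premature termination codon (PTC) downstream; decay is
#' predicted unless the PTC escapes per [nmd_config()], and predicted
#' decay adds the `MISSING_RNA` effect.
#'
#' @param transcript a [transcript_model()].
#' @param event a list: `list(type = "exon_skip", exon = k)` or
#'   `list(type = "deletion"|"insertion", length = L)`, optionally with
#'   `ptc_pos` (a measured PTC transcript position) and, for indels,
#'   `at` (transcript position of the event, used to locate the assumed
#'   PTC).
#' @param nmd an [nmd_config()].
#' @return list with `frame_status` (`"IN_FRAME"`/`"FRAMESHIFT"`, `NA`
#'   for a non-coding no-op), `affected_length`, `ptc` (transcript
#'   position or `NA`), `nmd_predicted`, `effects`.
#' @export
splice_consequence <- function(transcript, event, nmd = nmd_config()) {
  b <- exon_bounds(transcript)
  effects <- character()
  if (identical(event$type, "exon_skip")) {
    k <- event$exon
    if (is.null(k) || k < 1L || k > nrow(b))
      uns_stop(sprintf("no exon %s in transcript %s", format(event$exon),
                       transcript$transcript_id), "uns_model_error")
    if (nrow(b) == 1L)
      uns_stop(sprintf("transcript %s has a single exon; skipping it removes the transcript",
                       transcript$transcript_id), "uns_model_error")
    affected <- exon_coding_length(transcript, k)
    if (affected == 0L)  # non-coding exon: splicing no-op for the CDS
      return(list(frame_status = NA_character_, affected_length = 0L,
                  ptc = NA_integer_, nmd_predicted = FALSE,
                  effects = character()))
    effects <- c(effects, "EXON_SKIPPING")
    event_pos <- b$start[k]
  } else if (event$type %in% c("deletion", "insertion")) {
    affected <- as.integer(event$length)
    if (is.na(affected) || affected < 1L)
      uns_stop("indel event needs a positive length", "uns_input_error")
    effects <- c(effects, "ABERRANT_SPLICING")
    event_pos <- as.integer(event$at %||% transcript$cds_start)
  } else {
    uns_stop(sprintf("unknown event type '%s'", format(event$type)),
             "uns_input_error")
  }

  if (affected %% 3L == 0L) {
    frame <- "IN_FRAME"
    ptc <- if (!is.null(event$ptc_pos)) as.integer(event$ptc_pos)
           else NA_integer_
  } else {
    frame <- "FRAMESHIFT"
    effects <- c(effects, "FRAMESHIFT", "PREMATURE_STOP")
    # without a measured PTC, model it immediately downstream of the event
    ptc <- as.integer(event$ptc_pos %||% event_pos)
  }
  nmd_predicted <- if (is.na(ptc)) FALSE else !nmd_escapes(transcript, ptc, nmd)
  if (nmd_predicted) effects <- c(effects, "MISSING_RNA")
  list(frame_status = frame, affected_length = affected, ptc = ptc,
       nmd_predicted = nmd_predicted, effects = unique(effects))
}

# ---- variant observation & evidence ----------------------------------------

#' Variant observation in CDS coordinates
#'
#' @param transcript_id transcript the position refers to.
#' @param cds_pos 1-based position within the CDS.
#' @param ref_base,alt_base single bases.
#' @param claimed_label optional externally supplied label (for audit).
#' @return a `variant_observation` with derived `codon_index`/`codon_pos`.
#' @export
variant_observation <- function(transcript_id, cds_pos, ref_base, alt_base,
                                claimed_label = NA_character_) {
  m <- map_cds_position(cds_pos)
  ref_base <- normalize_codon_chars(ref_base)
  alt_base <- normalize_codon_chars(alt_base)
  if (!ref_base %in% UNS_BASES || !alt_base %in% UNS_BASES)
    uns_stop("ref_base/alt_base must be single bases in A,C,G,T",
             "uns_input_error")
  structure(list(transcript_id = transcript_id, cds_pos = as.integer(cds_pos),
                 ref_base = ref_base, alt_base = alt_base,
                 codon_index = m$codon_index, codon_pos = m$codon_pos,
                 claimed_label = claimed_label),
            class = "variant_observation")
}

#' Canonical variant key
#'
#' `"<transcript_id>:c.<pos><ref>><alt>"`; the join key between variants
#' and evidence records.
#'
#' @param obs a [variant_observation()] (or anything with the four fields).
#' @return string key.
#' @export
variant_key <- function(obs) {
  sprintf("%s:c.%d%s>%s", obs$transcript_id, obs$cds_pos, obs$ref_base,
          obs$alt_base)
}

#' Evidence record
#'
#' One experimental observation attached to a variant: the assay, the
#' mechanism seen (or `NONE_OBSERVED`), the effect tag and the molecular
#' level. A real mechanism's level must equal the record's level.
#'
#' @param variant_id the [variant_key()] of the variant.
#' @param assay free text (e.g. `"minigene"`, `"RNA-seq"`, `"reporter"`).
#' @param mechanism a name of [UNS_MECHANISMS], or `"NONE_OBSERVED"`.
#' @param effect one of [UNS_EFFECTS].
#' @param level `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @return one-row data.frame.
#' @export
evidence_record <- function(variant_id, assay, mechanism, effect, level) {
  if (!effect %in% UNS_EFFECTS)
    uns_stop(sprintf("unknown effect tag '%s'", effect), "uns_input_error")
  level <- match.arg(toupper(level), UNS_LEVELS)
  if (!identical(mechanism, "NONE_OBSERVED")) {
    if (!mechanism %in% names(UNS_MECHANISMS))
      uns_stop(sprintf("unknown mechanism tag '%s'", mechanism),
               "uns_input_error")
    if (UNS_MECHANISMS[[mechanism]] != level)
      uns_stop(sprintf("mechanism %s acts at level %s, not %s", mechanism,
                       UNS_MECHANISMS[[mechanism]], level),
               "uns_input_error")
  }
  data.frame(variant_id = variant_id, assay = assay, mechanism = mechanism,
             effect = effect, level = level, stringsAsFactors = FALSE)
}

# ---- classification --------------------------------------------------------

validate_classification_result <- function(x) {
  stopifnot(x$final_label %in% UNS_FINAL_LABELS,
            x$codon_category %in% UNS_CATEGORIES,
            x$evidence_status %in% c("NONE", "EFFECT_SHOWN",
                                     "NO_EFFECT_SHOWN"))
  if (x$final_label == "UNSENSE" &&
      !any(x$mechanisms %in% UNSENSE_MECHANISMS))
    uns_stop("UNSENSE label requires a splicing/regulation/miRNA mechanism",
             "uns_invariant_error")
  if (x$final_label %in% c("VERIFIED_SYNONYMOUS",
                           "UNVERIFIED_SYNONYMOUS_PREDICTED",
                           "SYNONYMOUS_WITH_EFFECT", "UNSENSE") &&
      !x$codon_category %in% c("SYNONYMOUS", "STOP_TO_STOP"))
    uns_stop("synonymous-family label on a non-synonymous codon change",
             "uns_invariant_error")
  if (x$evidence_status == "NONE" &&
      !x$final_label %in% c("MISSENSE", "NONSENSE",
                            "UNVERIFIED_SYNONYMOUS_PREDICTED"))
    uns_stop("evidence-free result must be missense, nonsense or unverified",
             "uns_invariant_error")
  if ("NO_EFFECT" %in% x$effects && length(x$effects) > 1L)
    uns_stop("NO_EFFECT is mutually exclusive with other effect tags",
             "uns_invariant_error")
  invisible(x)
}

#' Classify one variant from its codon change and evidence
#'
#' Rule order: (1) a codon-level `MISSENSE`/`NONSENSE`/`STOP_LOSS` change
#' is labelled at codon level regardless of evidence (`STOP_LOSS` maps to
#' `MISSENSE`; evidence is carried as co-annotation). (2) A codon-level
#' `SYNONYMOUS` (or `STOP_TO_STOP`) change is labelled from evidence: no
#' evidence gives `UNVERIFIED_SYNONYMOUS_PREDICTED`; any evidence with a
#' mechanism among `SPLICE_SITE`, `ESE`, `ESS`, `MIRNA_BINDING` gives
#' `UNSENSE` (which dominates mixed evidence; all mechanisms are still
#' reported); effect evidence only at DNA level, protein level or via
#' `MRNA_STRUCTURE_STABILITY` gives `SYNONYMOUS_WITH_EFFECT` with those
#' levels; evidence showing no effect gives `VERIFIED_SYNONYMOUS`.
#' Conflicting no-effect plus effect evidence sets `conflict = TRUE` and
#' the label follows the effect evidence.
#'
#' @param obs a [variant_observation()].
#' @param ref_codon,alt_codon the codons containing the change; the base
#'   at `obs$codon_pos` must change `ref_base` to `alt_base`.
#' @param evidence data.frame of [evidence_record()] rows for this
#'   variant (rows keyed to a different variant raise a linkage error).
#' @param table a [codon_table()].
#' @param nmd an [nmd_config()] (carried for downstream splice
#'   consequence interpretation).
#' @return a `classification_result`.
#' @export
classify_variant <- function(obs, ref_codon, alt_codon, evidence = NULL,
                             table = codon_table(), nmd = nmd_config()) {
  ref_codon <- check_codon(ref_codon)
  alt_codon <- check_codon(alt_codon)
  if (substr(ref_codon, obs$codon_pos, obs$codon_pos) != obs$ref_base ||
      substr(alt_codon, obs$codon_pos, obs$codon_pos) != obs$alt_base)
    uns_stop(sprintf(
      "codon change %s>%s inconsistent with observation %s at codon position %d",
      ref_codon, alt_codon, variant_key(obs), obs$codon_pos),
      "uns_input_error")
  category <- classify_codon_substitution(ref_codon, alt_codon, table)
  key <- variant_key(obs)

  if (!is.null(evidence) && nrow(evidence)) {
    other <- setdiff(unique(evidence$variant_id), key)
    if (length(other))
      uns_stop(sprintf("evidence for %s supplied to variant %s",
                       paste(other, collapse = ", "), key),
               "uns_linkage_error")
  }
  n_ev <- if (is.null(evidence)) 0L else nrow(evidence)
  no_eff <- effective <- evidence_record("x", "x", "NONE_OBSERVED",
                                         "NO_EFFECT", "RNA")[0, ]
  if (n_ev) {
    null_row <- evidence$effect == "NO_EFFECT" |
      evidence$mechanism == "NONE_OBSERVED"
    no_eff <- evidence[null_row, , drop = FALSE]
    effective <- evidence[!null_row, , drop = FALSE]
  }
  conflict <- nrow(no_eff) > 0L && nrow(effective) > 0L
  evidence_status <- if (n_ev == 0L) "NONE"
    else if (nrow(effective)) "EFFECT_SHOWN" else "NO_EFFECT_SHOWN"

  mechanisms <- unique(effective$mechanism)
  effects <- unique(effective$effect)
  levels <- unique(effective$level)

  if (category %in% c("MISSENSE", "STOP_LOSS")) {
    final <- "MISSENSE"
  } else if (category == "NONSENSE") {
    final <- "NONSENSE"
  } else {  # SYNONYMOUS or STOP_TO_STOP: evidence decides
    if (n_ev == 0L) {
      final <- "UNVERIFIED_SYNONYMOUS_PREDICTED"
    } else if (any(mechanisms %in% UNSENSE_MECHANISMS)) {
      final <- "UNSENSE"
    } else if (nrow(effective)) {
      final <- "SYNONYMOUS_WITH_EFFECT"
    } else {
      final <- "VERIFIED_SYNONYMOUS"
      effects <- "NO_EFFECT"
    }
  }
  res <- structure(list(
    variant_id = key, codon_category = category, final_label = final,
    mechanisms = mechanisms, effects = effects, levels = levels,
    evidence_status = evidence_status, conflict = conflict,
    n_evidence = n_ev), class = "classification_result")
  validate_classification_result(res)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s: %s (codon level %s)\n", x$variant_id, x$final_label,
              tolower(x$codon_category)))
  if (length(x$mechanisms))
    cat("  mechanisms:", paste(x$mechanisms, collapse = ", "), "\n")
  if (length(x$effects))
    cat("  effects:   ", paste(x$effects, collapse = ", "), "\n")
  cat(sprintf("  evidence: %s (%d record(s))%s\n", tolower(x$evidence_status),
              x$n_evidence, if (x$conflict) " [conflicting]" else ""))
  invisible(x)
}

# ---- audit -----------------------------------------------------------------

# claimed labels accepted in variant files, normalised to final labels;
# a bare "synonymous" claim is the one under audit
normalize_claimed <- function(x) {
  y <- toupper(trimws(x))
  y[y %in% c("SILENT", "SSNV")] <- "SYNONYMOUS"
  y
}

#' Audit claimed variant labels against evidence-aware classification
#'
#' Recomputes the final label of every record and compares it with the
#' claimed one. Verdicts: `CONFIRMED` (claim matches; a claim of
#' `synonymous` is confirmed only by `VERIFIED_SYNONYMOUS`),
#' `OVERCLAIMED_SYNONYMOUS` (claimed synonymous, computed unverified /
#' unsense / synonymous-with-effect), `MISLABELED` (any other mismatch).
#' Records without a claimed label are skipped with a warning count.
#'
#' @param variants data.frame with columns `transcript_id`, `cds_pos`,
#'   `ref_base`, `alt_base`, `ref_codon`, `alt_codon`, `claimed_label`
#'   (a `variant_id` column is added if absent). Codons can be derived
#'   from transcript models with [derive_codons()].
#' @param evidence data.frame of evidence records (possibly empty/NULL).
#' @param table a [codon_table()].
#' @param nmd an [nmd_config()].
#' @return an `audit_report`: `records` (per-record verdicts and computed
#'   labels) and `summary` (verdict counts plus `n_skipped`; counts
#'   partition the input).
#' @export
audit_annotations <- function(variants, evidence = NULL,
                              table = codon_table(), nmd = nmd_config()) {
  need <- c("transcript_id", "cds_pos", "ref_base", "alt_base",
            "ref_codon", "alt_codon", "claimed_label")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    uns_stop(sprintf("variants table lacks column(s): %s",
                     paste(miss, collapse = ", ")), "uns_input_error")
  n <- nrow(variants)
  verdict <- character(n)
  computed <- character(n)
  category <- character(n)
  keys <- character(n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    v <- variants[i, ]
    obs <- variant_observation(v$transcript_id, v$cds_pos, v$ref_base,
                               v$alt_base, v$claimed_label)
    keys[i] <- variant_key(obs)
    if (is.na(v$claimed_label) || !nzchar(v$claimed_label)) {
      warning(sprintf("record %s has no claimed label; skipped", keys[i]),
              call. = FALSE)
      verdict[i] <- "SKIPPED"
      computed[i] <- category[i] <- NA_character_
      n_skipped <- n_skipped + 1L
      next
    }
    ev <- if (is.null(evidence) || !nrow(evidence)) NULL
          else evidence[evidence$variant_id == keys[i], , drop = FALSE]
    res <- classify_variant(obs, v$ref_codon, v$alt_codon, ev, table, nmd)
    computed[i] <- res$final_label
    category[i] <- res$codon_category
    claim <- normalize_claimed(v$claimed_label)
    verdict[i] <- if (claim == "SYNONYMOUS") {
      if (res$final_label == "VERIFIED_SYNONYMOUS") "CONFIRMED"
      else if (res$final_label %in% c("UNVERIFIED_SYNONYMOUS_PREDICTED",
                                      "UNSENSE", "SYNONYMOUS_WITH_EFFECT"))
        "OVERCLAIMED_SYNONYMOUS"
      else "MISLABELED"
    } else if (claim == res$final_label) "CONFIRMED" else "MISLABELED"
  }
  records <- data.frame(variant_id = keys,
                        claimed_label = variants$claimed_label,
                        codon_category = category,
                        computed_label = computed, verdict = verdict,
                        stringsAsFactors = FALSE)
  summary <- c(n_records = n,
               CONFIRMED = sum(verdict == "CONFIRMED"),
               OVERCLAIMED_SYNONYMOUS = sum(verdict ==
                                            "OVERCLAIMED_SYNONYMOUS"),
               MISLABELED = sum(verdict == "MISLABELED"),
               n_skipped = n_skipped)
  structure(list(records = records, summary = as.list(summary)),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("audit of %d record(s): %d confirmed, %d overclaimed synonymous, %d mislabeled, %d skipped\n",
              s$n_records, s$CONFIRMED, s$OVERCLAIMED_SYNONYMOUS,
              s$MISLABELED, s$n_skipped))
  invisible(x)
}

#' Derive ref/alt codons for a variants table from transcript models
#'
#' Fills `ref_codon`/`alt_codon` from each transcript's CDS sequence,
#' checking that the stated reference base matches the sequence.
#'
#' @param variants data.frame with `transcript_id`, `cds_pos`, `ref_base`,
#'   `alt_base`.
#' @param transcripts named list of [transcript_model()]s carrying
#'   `cds_seq`.
#' @return `variants` with `ref_codon`/`alt_codon` columns filled.
#' @export
derive_codons <- function(variants, transcripts) {
  n <- nrow(variants)
  rc <- ac <- character(n)
  for (i in seq_len(n)) {
    tx <- transcripts[[variants$transcript_id[i]]]
    if (is.null(tx) || is.null(tx$cds_seq))
      uns_stop(sprintf("no CDS sequence for transcript '%s'",
                       variants$transcript_id[i]), "uns_input_error")
    m <- map_cds_position(variants$cds_pos[i], tx)
    cod <- codon_at(tx$cds_seq, m$codon_index)
    if (substr(cod, m$codon_pos, m$codon_pos) != variants$ref_base[i])
      uns_stop(sprintf("reference base mismatch at %s:c.%d (sequence %s, stated %s)",
                       variants$transcript_id[i], variants$cds_pos[i],
                       substr(cod, m$codon_pos, m$codon_pos),
                       variants$ref_base[i]), "uns_input_error")
    alt <- cod
    substr(alt, m$codon_pos, m$codon_pos) <- variants$alt_base[i]
    rc[i] <- cod; ac[i] <- alt
  }
  variants$ref_codon <- rc
  variants$alt_codon <- ac
  variants
}
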