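# Readers/writers for the formats the toolkit touches. Only the HGVS
# substitution subset (plus length-bearing del/ins, parsed for the frame
# rule) is supported; everything else is an explicit out-of-scope error,
# never a silent skip.

# ---- HGVS c. subset --------------------------------------------------------

#' Parse an HGVS coding-substitution description
#'
#' Supported subset: `[<accession>:]c.<pos><ref>><alt>` substitutions, and
#' length-bearing deletions/insertions (`c.<start>_<end>del[seq]`,
#' `c.<pos>del[base]`, `c.<start>_<end>ins<seq|length>`) which are parsed
#' only so the frame rule can be applied. Intronic offsets (`+5`, `-2`)
#' and protein-level (`p.`) descriptions raise a distinct
#' "non-exonic, out of scope" error; anything else malformed raises a
#' parse error naming the failure position (1-based, within the part
#' after the accession).
#'
#' @param text one HGVS string.
#' @return an `hgvs_c` list: `type` (`"sub"`, `"del"`, `"ins"`),
#'   `accession` (or `NA`), `cds_pos`, and for substitutions
#'   `ref_base`/`alt_base`, for indels `end`/`length`/`seq`.
#' @examples
#' parse_hgvs_c("NM_000000.0:c.6C>T")
#' parse_hgvs_c("c.840C>T")
#' @export
parse_hgvs_c <- function(text) {
  if (!is_string(text))
    uns_stop("HGVS input must be a single string", "uns_parse_error")
  accession <- NA_character_
  body <- text
  if (grepl(":", text, fixed = TRUE)) {
    accession <- sub(":.*$", "", text)
    body <- sub("^[^:]*:", "", text)
  }
  fail <- function(at) uns_stop(
    sprintf("malformed HGVS '%s': cannot parse at position %d of '%s'",
            text, at, body), "uns_parse_error")
  oos <- function(what) uns_stop(
    sprintf("'%s': %s is non-exonic or not a coding substitution, out of scope",
            text, what), "uns_out_of_scope_error")

  if (grepl("^p\\.", body)) oos("protein-level description")
  if (!grepl("^c\\.", body)) fail(1L)
  rest <- substr(body, 3L, nchar(body))
  off <- 3L  # 1-based offset of `rest` within `body`

  mpos <- regmatches(rest, regexpr("^[0-9]+", rest))
  if (!length(mpos)) fail(off)
  cds_pos <- as.integer(mpos)
  rest <- substr(rest, nchar(mpos) + 1L, nchar(rest))
  off <- off + nchar(mpos)
  if (grepl("^[+-][0-9]", rest)) oos("intronic offset")

  # substitution: REF>ALT
  if (grepl("^[ACGTUacgtu]>[ACGTUacgtu]$", rest)) {
    return(structure(list(type = "sub", accession = accession,
                          cds_pos = cds_pos,
                          ref_base = normalize_codon_chars(substr(rest, 1, 1)),
                          alt_base = normalize_codon_chars(substr(rest, 3, 3))),
                     class = "hgvs_c"))
  }

  end <- cds_pos
  if (grepl("^_", rest)) {
    mend <- regmatches(rest, regexpr("^_[0-9]+", rest))
    if (!length(mend)) fail(off + 1L)
    end <- as.integer(substr(mend, 2L, nchar(mend)))
    rest <- substr(rest, nchar(mend) + 1L, nchar(rest))
    off <- off + nchar(mend)
    if (grepl("^[+-][0-9]", rest)) oos("intronic offset")
  }
  if (grepl("^del([ACGTUNacgtun]*)$", rest)) {
    seq <- sub("^del", "", rest)
    len <- end - cds_pos + 1L
    if (nzchar(seq) && nchar(seq) != len)
      fail(off + 3L)
    return(structure(list(type = "del", accession = accession,
                          cds_pos = cds_pos, end = end, length = len,
                          seq = if (nzchar(seq)) normalize_codon_chars(seq)
                                else NA_character_),
                     class = "hgvs_c"))
  }
  if (grepl("^ins([ACGTUNacgtun]+|[0-9]+)$", rest)) {
    if (end != cds_pos + 1L)
      fail(off)
    ins <- sub("^ins", "", rest)
    if (grepl("^[0-9]+$", ins)) {
      len <- as.integer(ins); seq <- NA_character_
    } else {
      seq <- normalize_codon_chars(ins); len <- nchar(ins)
    }
    return(structure(list(type = "ins", accession = accession,
                          cds_pos = cds_pos, end = end, length = len,
                          seq = seq), class = "hgvs_c"))
  }
  if (grepl("^(dup|inv|delins|=)", rest)) oos(sprintf("'%s' description", rest))
  fail(off)
}

#' Format an HGVS coding description
#'
#' Canonical rendering; `parse_hgvs_c(format_hgvs_c(x))` is the identity
#' on the supported subset.
#'
#' @param x an `hgvs_c`.
#' @return string.
#' @export
format_hgvs_c <- function(x) {
  acc <- if (is.na(x$accession)) "" else paste0(x$accession, ":")
  body <- switch(x$type,
    sub = sprintf("c.%d%s>%s", x$cds_pos, x$ref_base, x$alt_base),
    del = if (x$end > x$cds_pos)
            sprintf("c.%d_%ddel%s", x$cds_pos, x$end,
                    if (is.na(x$seq)) "" else x$seq)
          else sprintf("c.%ddel%s", x$cds_pos,
                       if (is.na(x$seq)) "" else x$seq),
    ins = sprintf("c.%d_%dins%s", x$cds_pos, x$end,
                  if (is.na(x$seq)) as.character(x$length) else x$seq),
    uns_stop(sprintf("unknown hgvs_c type '%s'", x$type), "uns_input_error"))
  paste0(acc, body)
}

# ---- transcript models -----------------------------------------------------

#' Read transcript models (JSON or GFF3 subset)
#'
#' JSON schema: an array of objects with `transcript_id`, `exon_lengths`,
#' `cds_start`, `cds_end`, optional `strand` and `cds_seq` — mirroring
#' [transcript_model()] exactly, with coordinates in transcript space.
#' The GFF3 subset carries one transcript per ID as `exon` and `CDS`
#' features in transcript-space coordinates (seqid = transcript id,
#' 1-based inclusive per the GFF3 standard); it is read with
#' \pkg{rtracklayer}.
#'
#' @param path `.json`, or `.gff3`/`.gff` file.
#' @return named list of [transcript_model()]s.
#' @export
read_transcript_models <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    models <- lapply(lst, function(m)
      transcript_model(m$transcript_id, unlist(m$exon_lengths), m$cds_start,
                       m$cds_end, m$strand %||% NA_character_,
                       m$cds_seq %||% NULL))
  } else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    typ <- as.character(gr$type)
    tx_of <- function(i) {
      p <- gr$Parent[[i]]
      if (length(p)) as.character(p)[1L] else as.character(gr$ID[i])
    }
    tx_ids <- vapply(seq_along(gr), tx_of, character(1))
    models <- lapply(unique(tx_ids[typ %in% c("exon", "CDS")]), function(id) {
      sel <- tx_ids == id
      ex <- gr[sel & typ == "exon"]
      cds <- gr[sel & typ == "CDS"]
      if (!length(ex) || !length(cds))
        uns_stop(sprintf("transcript '%s': need both exon and CDS features",
                         id), "uns_model_error")
      ex <- ex[order(BiocGenerics::start(ex))]
      strand <- as.character(BiocGenerics::strand(ex))[1L]
      transcript_model(id, BiocGenerics::width(ex),
                       min(BiocGenerics::start(cds)),
                       max(BiocGenerics::end(cds)),
                       if (strand %in% c("+", "-")) strand else NA_character_)
    })
  } else {
    uns_stop(sprintf("unrecognised transcript-model format: '%s'", path),
             "uns_input_error")
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  models
}

#' Write transcript models as JSON
#' @param models list of [transcript_model()]s.
#' @param path output path.
#' @param with_seq include `cds_seq` fields.
#' @export
write_transcript_models_json <- function(models, path, with_seq = TRUE) {
  lst <- lapply(models, function(m) {
    o <- list(transcript_id = m$transcript_id,
              exon_lengths = m$exon_lengths,
              cds_start = m$cds_start, cds_end = m$cds_end)
    if (!is.na(m$strand)) o$strand <- m$strand
    if (with_seq && !is.null(m$cds_seq)) o$cds_seq <- m$cds_seq
    o
  })
  jsonlite::write_json(unname(lst), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write transcript models as a GFF3 subset
#'
#' Transcript-space coordinates (seqid = transcript id); `gene`-free
#' minimal layout with one `mRNA`, its `exon`s and a single spliced `CDS`
#' feature per exon overlap.
#'
#' @param models list of [transcript_model()]s.
#' @param path output path.
#' @export
write_transcript_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    b <- exon_bounds(m)
    strand <- if (is.na(m$strand)) "." else m$strand
    total <- sum(m$exon_lengths)
    lines <- c(lines, sprintf("%s\tunsense\tmRNA\t1\t%d\t.\t%s\t.\tID=%s",
                              m$transcript_id, total, strand,
                              m$transcript_id))
    for (k in seq_len(nrow(b))) {
      lines <- c(lines, sprintf(
        "%s\tunsense\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        m$transcript_id, b$start[k], b$end[k], strand, m$transcript_id, k,
        m$transcript_id))
      cs <- max(b$start[k], m$cds_start); ce <- min(b$end[k], m$cds_end)
      if (cs <= ce)
        lines <- c(lines, sprintf(
          "%s\tunsense\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
          m$transcript_id, cs, ce, strand, m$transcript_id, m$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- evidence tables -------------------------------------------------------

#' Read an evidence table
#'
#' TSV with header columns `variant_id`, `assay`, `mechanism`, `effect`,
#' `level` (or a JSON array of such objects). Every row is validated
#' through [evidence_record()].
#'
#' @param path file path.
#' @return evidence data.frame (possibly zero rows).
#' @export
read_evidence <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df))
    return(evidence_record("x", "x", "NONE_OBSERVED", "NO_EFFECT", "RNA")[0, ])
  need <- c("variant_id", "assay", "mechanism", "effect", "level")
  miss <- setdiff(need, names(df))
  if (length(miss))
    uns_stop(sprintf("evidence table lacks column(s): %s",
                     paste(miss, collapse = ", ")), "uns_input_error")
  do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    evidence_record(df$variant_id[i], df$assay[i], df$mechanism[i],
                    df$effect[i], df$level[i])))
}

#' Write an evidence table as TSV
#' @param evidence evidence data.frame.
#' @param path output path.
#' @export
write_evidence <- function(evidence, path) {
  write.table(evidence, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- audit report ----------------------------------------------------------

#' Write an audit report (per-record TSV + JSON summary)
#' @param report an `audit_report`.
#' @param tsv_path per-record output path.
#' @param json_path summary output path.
#' @export
write_audit_report <- function(report, tsv_path, json_path) {
  write.table(report$records, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(tsv_path)
}

# ---- VCF annotation --------------------------------------------------------

UNS_VCF_HEADERS <- c(
  '##INFO=<ID=UNS_CAT,Number=.,Type=String,Description="Codon-level substitution category">',
  '##INFO=<ID=UNS_LABEL,Number=.,Type=String,Description="Final evidence-aware variant label">',
  '##INFO=<ID=UNS_MECH,Number=.,Type=String,Description="Comma-joined evidence mechanisms">',
  '##INFO=<ID=UNS_EVID,Number=.,Type=String,Description="Evidence status: none, effect_shown, no_effect_shown">')

#' Annotate a VCF in transcript coordinates
#'
#' Streams the file line by line: the CHROM..FILTER columns of every
#' record pass through byte-identical; only INFO gains the `UNS_*` keys
#' (declared in the header). The transcript/CDS mapping is taken from the
#' INFO keys `UNS_TX`/`UNS_CDS` when present, else CHROM is read as a
#' transcript id and POS as the CDS position. Records without a usable
#' mapping (unknown transcript, no CDS sequence, reference mismatch, or
#' position outside the CDS) pass through with `UNS_LABEL=.` and a
#' per-record warning.
#'
#' @param in_vcf input VCF path (uncompressed).
#' @param transcripts named list of [transcript_model()]s with `cds_seq`.
#' @param evidence evidence data.frame (or NULL).
#' @param out_vcf output path.
#' @param table a [codon_table()].
#' @param nmd an [nmd_config()].
#' @return `out_vcf`, invisibly.
#' @export
annotate_vcf <- function(in_vcf, transcripts, evidence = NULL, out_vcf,
                         table = codon_table(), nmd = nmd_config()) {
  lines <- readLines(in_vcf)
  is_meta <- startsWith(lines, "##")
  header_i <- which(startsWith(lines, "#CHROM"))
  if (!length(header_i))
    uns_stop(sprintf("'%s': no #CHROM header line", in_vcf),
             "uns_input_error")
  header_i <- header_i[1L]
  out <- c(lines[seq_len(header_i - 1L)][is_meta[seq_len(header_i - 1L)]],
           UNS_VCF_HEADERS, lines[header_i])

  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (!length(m)) NA_character_ else sub(paste0("^;?", key, "="), "", m)
  }
  passthrough <- function(fields, msg) {
    warning(msg, call. = FALSE)
    fields[8L] <- add_info(fields[8L], "UNS_LABEL=.")
    paste(fields, collapse = "\t")
  }
  add_info <- function(info, kv) {
    if (is.na(info) || info == "." || !nzchar(info)) kv
    else paste(info, kv, sep = ";")
  }

  for (ln in lines[seq.int(header_i + 1L, length.out = length(lines) -
                                                       header_i)]) {
    if (!nzchar(ln)) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 8L) fields <- c(fields, rep(".", 8L -
                                                     length(fields)))
    tx_id <- info_get(fields[8L], "UNS_TX")
    cds_pos <- suppressWarnings(as.integer(info_get(fields[8L], "UNS_CDS")))
    if (is.na(tx_id)) tx_id <- fields[1L]
    if (is.na(cds_pos)) cds_pos <- suppressWarnings(as.integer(fields[2L]))
    tx <- transcripts[[tx_id]]
    if (is.null(tx)) {
      out <- c(out, passthrough(fields,
        sprintf("record %s:%s: unknown transcript id; passed through",
                fields[1L], fields[2L])))
      next
    }
    if (is.null(tx$cds_seq) || is.na(cds_pos) ||
        cds_pos > nchar(tx$cds_seq)) {
      out <- c(out, passthrough(fields,
        sprintf("record %s:%s: no CDS mapping; passed through",
                fields[1L], fields[2L])))
      next
    }
    ref <- fields[4L]; alt <- fields[5L]
    if (nchar(ref) != 1L || nchar(alt) != 1L ||
        substr(tx$cds_seq, cds_pos, cds_pos) != ref) {
      out <- c(out, passthrough(fields,
        sprintf("record %s:%s: not an SNV or reference mismatch; passed through",
                fields[1L], fields[2L])))
      next
    }
    obs <- variant_observation(tx_id, cds_pos, ref, alt)
    m <- map_cds_position(cds_pos, tx)
    ref_codon <- codon_at(tx$cds_seq, m$codon_index)
    alt_codon <- ref_codon
    substr(alt_codon, m$codon_pos, m$codon_pos) <- alt
    ev <- if (is.null(evidence) || !nrow(evidence)) NULL
          else evidence[evidence$variant_id == variant_key(obs), ,
                        drop = FALSE]
    res <- classify_variant(obs, ref_codon, alt_codon, ev, table, nmd)
    kv <- sprintf("UNS_CAT=%s;UNS_LABEL=%s;UNS_MECH=%s;UNS_EVID=%s",
                  tolower(res$codon_category), tolower(res$final_label),
                  if (length(res$mechanisms))
                    paste(res$mechanisms, collapse = ",") else ".",
                  tolower(res$evidence_status))
    fields[8L] <- add_info(fields[8L], kv)
    out <- c(out, paste(fields, collapse = "\t"))
  }
  writeLines(out, out_vcf)
  invisible(out_vcf)
}
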