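#' @importFrom utils combn read.delim write.table head
#' @importFrom stats setNames
NULL

UNS_BASES <- c("A", "C", "G", "T")
UNS_PURINES <- c("A", "G")

#' Substitution categories of a single-base codon change
#'
#' The five codon-level outcomes of a directed single-nucleotide codon
#' substitution: both codons code the same amino acid (`SYNONYMOUS`), a
#' different amino acid (`MISSENSE`), coding to stop (`NONSENSE`), stop to
#' coding (`STOP_LOSS`), or stop to stop (`STOP_TO_STOP`).
#'
#' @export
UNS_CATEGORIES <- c("SYNONYMOUS", "MISSENSE", "NONSENSE",
                    "STOP_LOSS", "STOP_TO_STOP")

# three-letter <-> one-letter amino-acid codes; "Stop"/"*" for termination
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Stop"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

# ---- CodonTable ------------------------------------------------------------

new_codon_table <- function(map, table_id) {
  structure(map, table_id = table_id, class = "codon_table")
}

validate_codon_table <- function(map, table_id = "custom") {
  if (length(map) != 64L)
    uns_stop(sprintf("codon table '%s' must have exactly 64 codons, got %d",
                     table_id, length(map)), "uns_input_error")
  keys <- names(map)
  bad <- keys[nchar(keys) != 3L | grepl("[^ACGT]", keys)]
  if (length(bad))
    uns_stop(sprintf("invalid codon key(s): %s", paste(bad, collapse = ", ")),
             "uns_input_error")
  if (anyDuplicated(keys))
    uns_stop("duplicated codon keys in table", "uns_input_error")
  vals <- unname(map)
  badv <- vals[!vals %in% names(AA_THREE)]
  if (length(badv))
    uns_stop(sprintf("unknown amino-acid code(s): %s",
                     paste(unique(badv), collapse = ", ")), "uns_input_error")
  invisible(map)
}

#' Codon table
#'
#' Build the standard genetic code (sourced from
#' [Biostrings::GENETIC_CODE]) or wrap a user-supplied 64-entry
#' codon-to-amino-acid map. Stop codons are encoded as `"*"`.
#'
#' @param table_id identifier; only `"standard"` is built in.
#' @param map optional named character vector of 64 codons (DNA alphabet)
#'   to one-letter amino-acid codes, `"*"` for stop. When supplied,
#'   `table_id` labels it.
#' @return a `codon_table`: named character vector with a `table_id`
#'   attribute.
#' @examples
#' tab <- codon_table()
#' tab[["ATG"]]
#' @export
codon_table <- function(table_id = "standard", map = NULL) {
  if (is.null(map)) {
    if (!identical(table_id, "standard"))
      uns_stop(sprintf("unknown built-in codon table '%s'", table_id),
               "uns_input_error")
    map <- as.character(Biostrings::GENETIC_CODE)
    names(map) <- names(Biostrings::GENETIC_CODE)
  } else {
    map <- toupper(map)
    names(map) <- normalize_codon_chars(names(map))
  }
  validate_codon_table(map, table_id)
  new_codon_table(map[order(names(map))], table_id)
}

#' Read a codon table from a two-column TSV file
#'
#' Expected columns: `codon`, `amino_acid` (one-letter code, three-letter
#' code, or `"Stop"`); exactly 64 rows.
#'
#' @param path file path.
#' @param table_id identifier attached to the result.
#' @return a `codon_table`.
#' @export
read_codon_table <- function(path, table_id = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "amino_acid")
  if (!all(need %in% names(df)))
    uns_stop(sprintf("codon table file must have columns %s",
                     paste(need, collapse = ", ")), "uns_input_error")
  aa <- df$amino_acid
  three <- match(aa, AA_THREE)
  aa1 <- ifelse(!is.na(three), names(AA_THREE)[three],
                ifelse(aa %in% c("Stop", "stop", "STOP", "*"), "*", aa))
  codon_table(table_id %||% basename(path), setNames(aa1, df$codon))
}

#' Write a codon table as TSV
#' @param table a `codon_table`.
#' @param path output path.
#' @export
write_codon_table <- function(table, path) {
  df <- data.frame(codon = names(table),
                   amino_acid = ifelse(unname(table) == "*", "Stop",
                                       unname(table)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("codon table '%s': %d codons, %d stop codon(s)\n",
              attr(x, "table_id"), length(x), sum(x == "*")))
  invisible(x)
}

# validate/normalise one or more codon strings: uppercase, U -> T
normalize_codon_chars <- function(codon) {
  codon <- chartr("u", "U", toupper(codon))
  chartr("U", "T", codon)
}

check_codon <- function(codon) {
  if (!is.character(codon) || anyNA(codon))
    uns_stop("codon must be a character string", "uns_input_error")
  codon <- normalize_codon_chars(codon)
  bad <- codon[nchar(codon) != 3L | grepl("[^ACGT]", codon)]
  if (length(bad))
    uns_stop(sprintf("invalid codon '%s': need length-3 string over A,C,G,T/U",
                     bad[[1L]]), "uns_input_error")
  codon
}

# ---- basic operations ------------------------------------------------------

#' Translate a codon
#'
#' @param codon length-3 string over A,C,G,T (U accepted and mapped to T).
#' @param table a [codon_table()].
#' @param one_letter return one-letter codes (`"*"` for stop) instead of
#'   three-letter codes (`"Stop"` for stop).
#' @return amino-acid code, e.g. `"Met"`, or `"Stop"`.
#' @examples
#' translate_codon("ATG")  # "Met"
#' translate_codon("UAA")  # "Stop"
#' @export
translate_codon <- function(codon, table = codon_table(), one_letter = FALSE) {
  codon <- check_codon(codon)
  aa <- unname(table[codon])
  if (one_letter) aa else unname(AA_THREE[aa])
}

#' Transition or transversion?
#'
#' A substitution is a transition when both bases are purines or both are
#' pyrimidines, a transversion otherwise.
#'
#' @param ref_base,alt_base distinct single bases in A,C,G,T (U accepted).
#' @return `"TRANSITION"` or `"TRANSVERSION"` (vectorised).
#' @export
substitution_chemistry <- function(ref_base, alt_base) {
  ref_base <- normalize_codon_chars(ref_base)
  alt_base <- normalize_codon_chars(alt_base)
  bad <- !(ref_base %in% UNS_BASES) | !(alt_base %in% UNS_BASES)
  if (any(bad))
    uns_stop("bases must be single characters in A,C,G,T", "uns_input_error")
  if (any(ref_base == alt_base))
    uns_stop("identical bases: not a substitution", "uns_input_error")
  ifelse((ref_base %in% UNS_PURINES) == (alt_base %in% UNS_PURINES),
         "TRANSITION", "TRANSVERSION")
}

#' Classify a single-base codon substitution
#'
#' Categories at codon level: `SYNONYMOUS` (both coding, same amino acid),
#' `NONSENSE` (coding to stop), `STOP_LOSS` (stop to coding),
#' `STOP_TO_STOP`, otherwise `MISSENSE`. The relation is directed;
#' `SYNONYMOUS` and `STOP_TO_STOP` are symmetric under reversal.
#'
#' @param ref_codon,alt_codon codons differing at exactly one position.
#' @param table a [codon_table()].
#' @return one of [UNS_CATEGORIES].
#' @examples
#' classify_codon_substitution("TTA", "CTA")  # SYNONYMOUS
#' classify_codon_substitution("CAG", "TAG")  # NONSENSE
#' @export
classify_codon_substitution <- function(ref_codon, alt_codon,
                                        table = codon_table()) {
  ref_codon <- check_codon(ref_codon)
  alt_codon <- check_codon(alt_codon)
  d <- sum(strsplit(ref_codon, "")[[1L]] != strsplit(alt_codon, "")[[1L]])
  if (d == 0L)
    uns_stop(sprintf("'%s' -> '%s': not a substitution", ref_codon, alt_codon),
             "uns_not_a_substitution")
  if (d > 1L)
    uns_stop(sprintf("'%s' -> '%s': multi-nucleotide change out of scope",
                     ref_codon, alt_codon), "uns_multi_nucleotide")
  categorize_aa_pair(table[[ref_codon]], table[[alt_codon]])
}

# vectorised category from one-letter amino acids ("*" = stop)
categorize_aa_pair <- function(ref_aa, alt_aa) {
  ifelse(ref_aa == "*" & alt_aa == "*", "STOP_TO_STOP",
  ifelse(ref_aa == "*", "STOP_LOSS",
  ifelse(alt_aa == "*", "NONSENSE",
  ifelse(ref_aa == alt_aa, "SYNONYMOUS", "MISSENSE"))))
}

#' Degeneracy of an amino acid
#'
#' Number of codons translating to the given amino acid under the table.
#' Under the standard code this ranges from 1 (Met, Trp) to 6 (Leu, Ser,
#' Arg).
#'
#' @param amino_acid one-letter or three-letter code, or `"Stop"`/`"*"`.
#' @param table a [codon_table()].
#' @return integer codon count.
#' @export
degeneracy <- function(amino_acid, table = codon_table()) {
  aa <- amino_acid
  if (aa %in% AA_THREE) aa <- AA_ONE[[aa]]
  if (!aa %in% names(AA_THREE) || !aa %in% table)
    uns_stop(sprintf("unknown amino acid '%s'", amino_acid), "uns_input_error")
  sum(table == aa)
}

# ---- substitution space ----------------------------------------------------

#' Enumerate the directed single-base substitution space of a codon table
#'
#' One record per ordered (codon, position, alternative base) triple:
#' 9 per codon, 576 for a 64-codon table. Deterministic order: reference
#' codon lexicographic, then position 1..3, then alternative base
#' lexicographic.
#'
#' @param table a [codon_table()].
#' @return a `substitution_space` data.frame with columns `ref_codon`,
#'   `alt_codon`, `position`, `ref_base`, `alt_base`, `category`,
#'   `chemistry`.
#' @export
enumerate_substitution_space <- function(table = codon_table()) {
  codons <- sort(names(table))
  n <- length(codons)
  ref_codon <- rep(codons, each = 12L)
  position <- rep(rep(1:3, each = 4L), times = n)
  alt_base <- rep(UNS_BASES, times = 3L * n)
  ref_base <- substr(ref_codon, position, position)
  keep <- ref_base != alt_base
  df <- data.frame(ref_codon = ref_codon[keep], alt_codon = ref_codon[keep],
                   position = position[keep], ref_base = ref_base[keep],
                   alt_base = alt_base[keep], stringsAsFactors = FALSE)
  substr(df$alt_codon, df$position, df$position) <- df$alt_base
  df$category <- categorize_aa_pair(unname(table[df$ref_codon]),
                                    unname(table[df$alt_codon]))
  df$chemistry <- substitution_chemistry(df$ref_base, df$alt_base)
  structure(df, class = c("substitution_space", "data.frame"),
            table_id = attr(table, "table_id"))
}

#' Wobble-group analysis
#'
#' For each of the 16 codon groups sharing their first two bases, test
#' whether all 6 unordered third-position codon pairs are synonymous
#' coding changes (i.e. the four codons code one amino acid, none a stop).
#'
#' @param table a [codon_table()].
#' @return data.frame with columns `group`, `fully_synonymous`; attribute
#'   `n_full` counts the fully interchangeable groups.
#' @export
wobble_group_analysis <- function(table = codon_table()) {
  groups <- sort(unique(substr(names(table), 1L, 2L)))
  full <- vapply(groups, function(g) {
    aas <- unname(table[paste0(g, UNS_BASES)])
    length(unique(aas)) == 1L && all(aas != "*")
  }, logical(1))
  structure(data.frame(group = groups, fully_synonymous = unname(full)),
            n_full = sum(full))
}

#' Summarise a substitution space
#'
#' Counts and percentages per category, per-position-per-category counts,
#' the synonymous records off the wobble (third) position with their
#' per-position breakdown, transition/transversion counts and the
#' wobble-group flags. Percentages are `100 * count / total` rounded
#' half-up to one decimal.
#'
#' @param records a complete enumeration from
#'   [enumerate_substitution_space()].
#' @param fold_stop_to_stop also report a folded synonymous count that
#'   includes stop-to-stop changes (the convention that first counts them
#'   inside synonymous, then excludes them).
#' @return a `space_summary` list.
#' @export
summarize_space <- function(records, fold_stop_to_stop = FALSE) {
  n_codons <- length(unique(records$ref_codon))
  per_codon <- table(records$ref_codon)
  if (nrow(records) != 9L * n_codons || any(per_codon != 9L))
    uns_stop(sprintf(
      "incomplete enumeration: %d records for %d codons (expected %d)",
      nrow(records), n_codons, 9L * n_codons), "uns_consistency_error")
  total <- nrow(records)
  counts <- vapply(UNS_CATEGORIES,
                   function(k) sum(records$category == k), integer(1))
  pct <- round_half_up(100 * counts / total, 1)
  by_pos <- table(factor(records$position, levels = 1:3),
                  factor(records$category, levels = UNS_CATEGORIES))
  syn <- records[records$category == "SYNONYMOUS", ]
  off <- syn[syn$position != 3L, ]
  syn_off_pos <- vapply(1:3, function(p) sum(off$position == p), integer(1))
  chem <- c(TRANSITION = sum(records$chemistry == "TRANSITION"),
            TRANSVERSION = sum(records$chemistry == "TRANSVERSION"))
  # wobble flags are derivable from the records alone: a group is fully
  # interchangeable iff all 12 directed third-position changes within it
  # are SYNONYMOUS
  third <- records[records$position == 3L, ]
  grp <- substr(third$ref_codon, 1L, 2L)
  wg <- vapply(split(third$category, grp),
               function(k) all(k == "SYNONYMOUS"), logical(1))
  notes <- paste(
    "Directed counting (each ordered ref->alt change is one record) makes",
    "the synonymous and stop-to-stop counts even by symmetry; quoted totals",
    "of 141 synonymous / 137 coding-synonymous cannot arise this way and do",
    "not reproduce. Enumeration and the independent pair-listing oracle",
    sprintf("agree on %d coding-synonymous (+%d stop-to-stop = %d folded).",
            counts[["SYNONYMOUS"]], counts[["STOP_TO_STOP"]],
            counts[["SYNONYMOUS"]] + counts[["STOP_TO_STOP"]]),
    "A quoted figure of 7 fully wobble-interchangeable codon groups also",
    sprintf("does not reproduce: brute force gives %d of %d.",
            sum(wg), length(wg)))
  out <- list(
    table_id = attr(records, "table_id") %||% "unknown",
    total = total,
    counts = counts,
    percentages = pct,
    by_position = by_pos,
    syn_off_wobble = nrow(off),
    syn_off_wobble_by_position = setNames(syn_off_pos, paste0("pos", 1:3)),
    transitions = unname(chem[["TRANSITION"]]),
    transversions = unname(chem[["TRANSVERSION"]]),
    wobble_groups = wg,
    wobble_groups_full = sum(wg),
    notes = notes)
  if (isTRUE(fold_stop_to_stop)) {
    out$synonymous_folded <- counts[["SYNONYMOUS"]] + counts[["STOP_TO_STOP"]]
    out$synonymous_folded_pct <- round_half_up(100 * out$synonymous_folded /
                                               total, 1)
  }
  structure(out, class = "space_summary")
}

#' @export
print.space_summary <- function(x, ...) {
  cat(sprintf("substitution space of codon table '%s'\n", x$table_id))
  cat(sprintf("  total records: %d\n", x$total))
  for (k in names(x$counts))
    cat(sprintf("  %-13s %4d (%.1f%%)\n", tolower(k), x$counts[[k]],
                x$percentages[[k]]))
  cat(sprintf("  synonymous off third position: %d (pos1=%d, pos2=%d)\n",
              x$syn_off_wobble, x$syn_off_wobble_by_position[["pos1"]],
              x$syn_off_wobble_by_position[["pos2"]]))
  cat(sprintf("  transitions:transversions = %d:%d\n",
              x$transitions, x$transversions))
  cat(sprintf("  fully wobble-interchangeable groups: %d of %d\n",
              x$wobble_groups_full, length(x$wobble_groups)))
  cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Export a space summary
#'
#' Writes fixed keys `total`, `synonymous`, `missense`, `nonsense`,
#' `stop_loss`, `stop_to_stop`, `syn_off_wobble`, `transitions`,
#' `transversions`, `wobble_groups_full` (plus percentages and a `notes`
#' string documenting count discrepancies) as TSV key/value pairs or JSON.
#'
#' @param summary a `space_summary`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @export
write_space_summary <- function(summary, path,
                                format = if (grepl("\\.json$", path))
                                  "json" else "tsv") {
  vals <- list(
    total = summary$total,
    synonymous = unname(summary$counts[["SYNONYMOUS"]]),
    missense = unname(summary$counts[["MISSENSE"]]),
    nonsense = unname(summary$counts[["NONSENSE"]]),
    stop_loss = unname(summary$counts[["STOP_LOSS"]]),
    stop_to_stop = unname(summary$counts[["STOP_TO_STOP"]]),
    syn_off_wobble = summary$syn_off_wobble,
    transitions = summary$transitions,
    transversions = summary$transversions,
    wobble_groups_full = summary$wobble_groups_full)
  format <- match.arg(format, c("tsv", "json"))
  if (format == "json") {
    vals$percentages <- as.list(setNames(unname(summary$percentages),
                                         tolower(names(summary$percentages))))
    vals$notes <- summary$notes
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- data.frame(key = names(vals),
                     value = vapply(vals, as.character, character(1)))
    df <- rbind(df, data.frame(key = "notes", value = summary$notes))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- independent oracle ----------------------------------------------------

#' Pair-listing oracle for substitution-space category counts
#'
#' Independent of [enumerate_substitution_space()]: lists all unordered
#' codon pairs at Hamming distance 1 (grouping synonymous pairs per amino
#' acid), classifies each pair, and doubles for direction. Used as the
#' authority for category counts.
#'
#' @param table a [codon_table()].
#' @return named integer vector of directed counts per category plus
#'   `total`.
#' @export
substitution_space_oracle <- function(table = codon_table()) {
  codons <- sort(names(table))
  pairs <- combn(codons, 2L)
  counts <- setNames(integer(length(UNS_CATEGORIES)), UNS_CATEGORIES)
  n_pairs <- 0L
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    if (sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]) != 1L) next
    n_pairs <- n_pairs + 1L
    ca <- categorize_aa_pair(table[[a]], table[[b]])
    cb <- categorize_aa_pair(table[[b]], table[[a]])
    counts[[ca]] <- counts[[ca]] + 1L
    counts[[cb]] <- counts[[cb]] + 1L
  }
  c(counts, total = 2L * n_pairs)
}

#' Synonymous codon pairs per amino acid
#'
#' The per-amino-acid listing behind the oracle: for each coding amino
#' acid, the unordered pairs of its codons at Hamming distance 1.
#'
#' @param table a [codon_table()].
#' @return data.frame with columns `amino_acid`, `codon_a`, `codon_b`,
#'   `position` (the differing position).
#' @export
synonymous_codon_pairs <- function(table = codon_table()) {
  out <- list()
  for (aa in sort(unique(unname(table[table != "*"])))) {
    cods <- sort(names(table)[table == aa])
    if (length(cods) < 2L) next
    prs <- combn(cods, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- strsplit(prs[1L, j], "")[[1L]]
      b <- strsplit(prs[2L, j], "")[[1L]]
      diffpos <- which(a != b)
      if (length(diffpos) != 1L) next
      out[[length(out) + 1L]] <- data.frame(
        amino_acid = unname(AA_THREE[[aa]]),
        codon_a = prs[1L, j], codon_b = prs[2L, j],
        position = diffpos)
    }
  }
  do.call(rbind, out)
}
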