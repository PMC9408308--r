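# Controlled vocabulary: substitution-type terms, mechanism tags and effect
# tags at DNA/RNA/protein level. The registry ships as JSON under
# inst/extdata/ so users can extend it without code changes. The original
# ontology codes for the substitution types come from a figure that is not
# machine-readable; `vario_code` is therefore null (untranscribed) and the
# term_ids are artifact-local.

UNS_LEVELS <- c("DNA", "RNA", "PROTEIN")

#' Mechanism tags and their molecular levels
#'
#' The nine mechanisms through which a codon-synonymous substitution can
#' act, each at exactly one molecular level: `TF_BINDING` (DNA);
#' `SPLICE_SITE`, `ESE`, `ESS`, `MRNA_STRUCTURE_STABILITY`,
#' `MIRNA_BINDING` (RNA); `CODON_USAGE_TRANSLATION`,
#' `COTRANSLATIONAL_FOLDING`, `PTM` (protein).
#'
#' @export
UNS_MECHANISMS <- c(
  TF_BINDING = "DNA",
  SPLICE_SITE = "RNA", ESE = "RNA", ESS = "RNA",
  MRNA_STRUCTURE_STABILITY = "RNA", MIRNA_BINDING = "RNA",
  CODON_USAGE_TRANSLATION = "PROTEIN", COTRANSLATIONAL_FOLDING = "PROTEIN",
  PTM = "PROTEIN")

# RNA mechanisms that make a codon-synonymous change an unsense variant:
# splicing, splicing regulation, or miRNA regulation of expression.
# MRNA_STRUCTURE_STABILITY is deliberately excluded (expression effect via
# stability is reported as synonymous-with-effect at RNA level).
UNSENSE_MECHANISMS <- c("SPLICE_SITE", "ESE", "ESS", "MIRNA_BINDING")

#' Effect tags
#'
#' Observable consequences attachable to a classification:
#' `MISSING_RNA`, `EXON_SKIPPING`, `EXON_INCLUSION`, `ABERRANT_SPLICING`,
#' `PREMATURE_STOP`, `FRAMESHIFT`, `EXPRESSION_CHANGE`,
#' `PROTEIN_ABUNDANCE_CHANGE`, `CONFORMATION_CHANGE`, `ACTIVITY_CHANGE`,
#' `PTM_LOSS`, `NO_EFFECT`. `NO_EFFECT` is mutually exclusive with every
#' other tag on one result.
#'
#' @export
UNS_EFFECTS <- c("MISSING_RNA", "EXON_SKIPPING", "EXON_INCLUSION",
                 "ABERRANT_SPLICING", "PREMATURE_STOP", "FRAMESHIFT",
                 "EXPRESSION_CHANGE", "PROTEIN_ABUNDANCE_CHANGE",
                 "CONFORMATION_CHANGE", "ACTIVITY_CHANGE", "PTM_LOSS",
                 "NO_EFFECT")

#' Load the term registry
#'
#' Reads the packaged JSON registry (or a user-supplied file with the same
#' schema: a list of objects with `term_id`, `name`, `definition`, `level`,
#' `parent`, `vario_code`). Validates uniqueness of ids and acyclicity of
#' parent links.
#'
#' @param path optional path to a registry JSON; default is the packaged
#'   registry.
#' @return a `term_registry` data.frame.
#' @export
load_term_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "term_registry.json",
                                package = "unsense", mustWork = TRUE)
  df <- jsonlite::fromJSON(path)
  need <- c("term_id", "name", "definition", "level", "parent")
  if (!all(need %in% names(df)))
    uns_stop(sprintf("registry must have fields %s",
                     paste(need, collapse = ", ")), "uns_input_error")
  if (anyDuplicated(df$term_id))
    uns_stop("duplicated term_id in registry", "uns_input_error")
  if (any(!df$level %in% UNS_LEVELS))
    uns_stop("term level must be one of DNA, RNA, PROTEIN", "uns_input_error")
  # parent links must resolve and be acyclic
  for (i in seq_len(nrow(df))) {
    seen <- character()
    p <- df$parent[[i]]
    while (!is.null(p) && !is.na(p)) {
      if (p %in% seen)
        uns_stop(sprintf("cycle in parent links at '%s'", p),
                 "uns_input_error")
      if (!p %in% df$term_id)
        uns_stop(sprintf("unresolved parent '%s'", p), "uns_input_error")
      seen <- c(seen, p)
      p <- df$parent[[match(p, df$term_id)]]
    }
  }
  structure(df, class = c("term_registry", "data.frame"))
}

#' Write a term registry
#' @param registry a `term_registry`.
#' @param path output JSON path.
#' @export
write_term_registry <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, auto_unbox = FALSE,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' Look up a term
#'
#' Exact match on `term_id`, or case-insensitive exact match on `name`.
#' On failure the error lists the nearest names (approximate match).
#'
#' @param query term id or name.
#' @param registry a [load_term_registry()] result.
#' @return one-row `Term` as a list.
#' @examples
#' lookup_term("unsense")$level  # "RNA"
#' @export
lookup_term <- function(query, registry = load_term_registry()) {
  i <- match(query, registry$term_id)
  if (is.na(i)) i <- match(tolower(query), tolower(registry$name))
  if (is.na(i)) {
    near <- unique(c(
      registry$name[agrepl(query, registry$name, ignore.case = TRUE,
                           max.distance = 0.3)],
      registry$term_id[agrepl(query, registry$term_id, ignore.case = TRUE,
                              max.distance = 0.3)]))
    hint <- if (length(near))
      paste0("; nearest: ", paste(head(near, 5L), collapse = ", ")) else ""
    uns_stop(sprintf("unknown term '%s'%s", query, hint), "uns_lookup_error")
  }
  as.list(registry[i, , drop = FALSE])
}

#' Mechanisms acting at a molecular level
#'
#' @param level `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @return character vector of mechanism tags.
#' @examples
#' mechanisms_for_level("DNA")  # TF_BINDING
#' @export
mechanisms_for_level <- function(level) {
  level <- match.arg(toupper(level), UNS_LEVELS)
  names(UNS_MECHANISMS)[UNS_MECHANISMS == level]
}
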