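tab <- codon_table()
space <- enumerate_substitution_space(tab)

test_that("standard codon table satisfies its invariants", {
  expect_length(tab, 64L)
  expect_true(all(nchar(names(tab)) == 3L))
  expect_setequal(names(tab)[tab == "*"], c("TAA", "TAG", "TGA"))
  expect_equal(sum(tab != "*"), 61L)
  deg <- table(tab[tab != "*"])
  expect_setequal(names(deg)[deg == 1L],
                  c("M", "W"))  # Met and Trp only single-codon amino acids
  expect_equal(range(deg), c(1L, 6L))
})

test_that("translate_codon handles normalisation and bad input", {
  expect_equal(translate_codon("ATG", tab), "Met")
  expect_equal(translate_codon("TAA", tab), "Stop")
  expect_equal(translate_codon("UUA", tab), "Leu")
  expect_equal(translate_codon("atg", tab, one_letter = TRUE), "M")
  expect_error(translate_codon("AT", tab), class = "uns_input_error")
  expect_error(translate_codon("AXG", tab), class = "uns_input_error")
})

test_that("classify_codon_substitution matches the category definitions", {
  cases <- list(
    list("TTA", "CTA", "SYNONYMOUS"),   # first-position Leu <-> Leu
    list("CAG", "TAG", "NONSENSE"),
    list("TAG", "CAG", "STOP_LOSS"),
    list("TAA", "TAG", "STOP_TO_STOP"),
    list("TTT", "TTA", "MISSENSE"))
  for (cs in cases)
    expect_equal(classify_codon_substitution(cs[[1]], cs[[2]], tab), cs[[3]])
  # symmetric categories hold for the reversed pair
  expect_equal(classify_codon_substitution("CTA", "TTA", tab), "SYNONYMOUS")
  expect_equal(classify_codon_substitution("TAG", "TAA", tab), "STOP_TO_STOP")
  expect_error(classify_codon_substitution("ATG", "ATG", tab),
               class = "uns_not_a_substitution")
  expect_error(classify_codon_substitution("ATG", "TAC", tab),
               class = "uns_multi_nucleotide")
})

test_that("chemistry partitions purine/pyrimidine changes", {
  expect_equal(substitution_chemistry("A", "G"), "TRANSITION")
  expect_equal(substitution_chemistry("T", "C"), "TRANSITION")
  expect_equal(substitution_chemistry("C", "A"), "TRANSVERSION")
  expect_error(substitution_chemistry("A", "A"), class = "uns_input_error")
  expect_error(substitution_chemistry("A", "X"), class = "uns_input_error")
})

test_that("enumeration is complete, ordered and per-codon uniform", {
  expect_equal(nrow(space), 576L)
  expect_true(all(table(space$ref_codon) == 9L))
  expect_equal(sum(space$ref_codon == "ATG"), 9L)
  # each record differs from its reference at exactly the stated position
  pos_base <- substr(space$ref_codon, space$position, space$position)
  expect_true(all(pos_base == space$ref_base))
  same <- mapply(function(r, a, p) {
    rr <- strsplit(r, "")[[1]]; aa <- strsplit(a, "")[[1]]
    all(rr[-p] == aa[-p]) && rr[p] != aa[p]
  }, space$ref_codon, space$alt_codon, space$position)
  expect_true(all(same))
  # deterministic order: codon lexicographic, then position, then alt base
  o <- order(space$ref_codon, space$position, space$alt_base)
  expect_equal(o, seq_len(nrow(space)))
})

test_that("summary reproduces the frozen brute-force counts", {
  s <- summarize_space(space, fold_stop_to_stop = TRUE)
  expect_equal(s$total, 576L)
  expect_equal(unname(s$counts["SYNONYMOUS"]), 134L)
  expect_equal(unname(s$counts["MISSENSE"]), 392L)
  expect_equal(unname(s$counts["NONSENSE"]), 23L)
  expect_equal(unname(s$counts["STOP_LOSS"]), 23L)
  expect_equal(unname(s$counts["STOP_TO_STOP"]), 4L)
  expect_equal(sum(s$counts), s$total)      # categories partition the space
  expect_equal(s$synonymous_folded, 138L)
  expect_equal(s$syn_off_wobble, 8L)
  expect_equal(unname(s$syn_off_wobble_by_position),
               c(8L, 0L, 0L))
  expect_equal(round(100 * s$syn_off_wobble / s$total, 1), 1.4)
  expect_equal(s$transitions, 192L)
  expect_equal(s$transversions, 384L)
  # the documented discrepancy note is part of the report output
  expect_match(s$notes, "137")
  expect_error(summarize_space(space[-1, ]), class = "uns_consistency_error")
})

test_that("percentages are 100*count/total rounded half-up to one decimal", {
  s <- summarize_space(space)
  expect_equal(unname(s$percentages),
               unname(floor(1000 * s$counts / s$total + 0.5) / 10))
})

test_that("chemistry and position partitions are exact at every position", {
  for (p in 1:3) {
    at_p <- space[space$position == p, ]
    expect_equal(nrow(at_p), 192L)
    expect_equal(sum(at_p$chemistry == "TRANSITION"), 64L)
    expect_equal(sum(at_p$chemistry == "TRANSVERSION"), 128L)
  }
})

test_that("synonymous relation is symmetric, hence counts even", {
  syn <- space[space$category %in% c("SYNONYMOUS", "STOP_TO_STOP"), ]
  key <- paste(syn$ref_codon, syn$alt_codon)
  rev <- paste(syn$alt_codon, syn$ref_codon)
  expect_setequal(key, rev)
  s <- summarize_space(space)
  expect_equal(unname(s$counts["SYNONYMOUS"]) %% 2L, 0L)
  expect_equal(unname(s$counts["STOP_TO_STOP"]) %% 2L, 0L)
})

test_that("pair-listing oracle agrees with enumeration for every category", {
  oracle <- substitution_space_oracle(tab)
  s <- summarize_space(space)
  for (k in UNS_CATEGORIES)
    expect_equal(unname(oracle[k]), unname(s$counts[k]), label = k)
  expect_equal(unname(oracle["total"]), s$total)
  # the per-amino-acid pair listing underlying it: directed synonymous
  pairs <- synonymous_codon_pairs(tab)
  expect_equal(2L * nrow(pairs), unname(s$counts[["SYNONYMOUS"]]))
  expect_equal(2L * sum(pairs$position != 3L), s$syn_off_wobble)
})

test_that("degeneracy matches the code and rejects unknowns", {
  expect_equal(degeneracy("Met", tab), 1L)
  expect_equal(degeneracy("Trp", tab), 1L)
  expect_equal(degeneracy("Leu", tab), 6L)
  expect_equal(degeneracy("L", tab), 6L)
  expect_equal(degeneracy("Stop", tab), 3L)
  expect_error(degeneracy("Xyz", tab), class = "uns_input_error")
})

test_that("wobble-group analysis flags fully interchangeable groups", {
  wg <- wobble_group_analysis(tab)
  expect_equal(nrow(wg), 16L)
  expect_true(wg$fully_synonymous[wg$group == "CT"])   # four Leu codons
  expect_false(wg$fully_synonymous[wg$group == "AT"])  # ATG is Met
  expect_false(wg$fully_synonymous[wg$group == "TA"])  # contains stops
  # brute force is authoritative: 8 groups, matching summarize_space
  expect_equal(attr(wg, "n_full"), 8L)
  s <- summarize_space(space)
  expect_equal(s$wobble_groups_full, attr(wg, "n_full"))
  expect_equal(unname(s$wobble_groups[wg$group]),
               wg$fully_synonymous)
})

test_that("codon table TSV round-trips and alternative tables work", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_codon_table(tab, path)
  tab2 <- read_codon_table(path, table_id = "standard")
  expect_equal(as.character(tab2[names(tab)]), as.character(tab))
  # a variant code: TGA reassigned to Trp loses a stop and gains records
  map <- as.character(tab); names(map) <- names(tab)
  map["TGA"] <- "W"
  alt <- codon_table("tga_trp", map)
  s <- summarize_space(enumerate_substitution_space(alt))
  expect_equal(s$total, 576L)
  expect_equal(unname(s$counts["STOP_TO_STOP"]), 2L)  # only TAA<->TAG left
  expect_equal(degeneracy("Trp", alt), 2L)
  oracle <- substitution_space_oracle(alt)
  expect_equal(unname(oracle["SYNONYMOUS"]), unname(s$counts["SYNONYMOUS"]))
})

test_that("space summary exports fixed keys to TSV and JSON", {
  s <- summarize_space(space)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_space_summary(s, jp)
  write_space_summary(s, tp)
  j <- jsonlite::fromJSON(jp)
  keys <- c("total", "synonymous", "missense", "nonsense", "stop_loss",
            "stop_to_stop", "syn_off_wobble", "transitions", "transversions",
            "wobble_groups_full")
  expect_true(all(keys %in% names(j)))
  expect_equal(j$synonymous, 134L)
  expect_match(j$notes, "137")
  tsv <- read.delim(tp)
  expect_setequal(setdiff(tsv$key, "notes"), keys)
  expect_equal(as.integer(tsv$value[tsv$key == "total"]), 576L)
})
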