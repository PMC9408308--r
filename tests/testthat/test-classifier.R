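test_that("map_cds_position does the codon arithmetic and round-trips", {
  expect_equal(map_cds_position(840)[, c("codon_index", "codon_pos")],
               data.frame(codon_index = 280L, codon_pos = 3L))
  expect_equal(map_cds_position(1)$codon_index, 1L)
  expect_equal(map_cds_position(5)$codon_pos, 2L)
  pos <- 1:300
  m <- map_cds_position(pos)
  expect_equal(3L * (m$codon_index - 1L) + m$codon_pos, pos)
  expect_error(map_cds_position(0), class = "uns_input_error")
  tx <- toy_transcript()
  expect_error(map_cds_position(151, tx), class = "uns_range_error")
  expect_equal(map_cds_position(150, tx)$codon_index, 50L)
})

test_that("transcript_model enforces its invariants", {
  expect_error(transcript_model("t", integer(0), 1, 3),
               class = "uns_model_error")
  expect_error(transcript_model("t", c(10, 20), 1, 31),
               class = "uns_model_error")  # CDS beyond transcript
  expect_error(transcript_model("t", c(50, 50), 1, 100),
               class = "uns_model_error")  # 100 not divisible by 3
  expect_error(transcript_model("t", 90, 1, 90, cds_seq = "ATG"),
               class = "uns_model_error")  # sequence length mismatch
  m <- transcript_model("t", c(30, 30, 30), 4, 87)
  expect_equal(sum(m$exon_lengths), 90L)
})

test_that("splice_consequence applies the frame rule", {
  tx <- toy_transcript()  # exons 60/60/60, CDS 10..159
  r <- splice_consequence(tx, list(type = "exon_skip", exon = 2))
  expect_equal(r$frame_status, "IN_FRAME")  # coding overlap 60 nt
  expect_equal(r$affected_length, 60L)
  expect_false(r$nmd_predicted)
  r <- splice_consequence(tx, list(type = "deletion", length = 54))
  expect_equal(r$frame_status, "IN_FRAME")
  r <- splice_consequence(tx, list(type = "deletion", length = 100, at = 20,
                                   ptc_pos = 30))
  expect_equal(r$frame_status, "FRAMESHIFT")
  expect_true(all(c("FRAMESHIFT", "PREMATURE_STOP") %in% r$effects))
})

test_that("NMD escape follows the last-exon / penultimate-window rule", {
  tx <- toy_transcript()  # penultimate exon ends at 120, last exon 121..180
  fs <- function(ptc, window = 50)
    splice_consequence(tx, list(type = "deletion", length = 100, ptc_pos = ptc),
                       nmd = nmd_config(window))
  r <- fs(30)  # internal exon -> decay predicted
  expect_true(r$nmd_predicted)
  expect_true("MISSING_RNA" %in% r$effects)
  r <- fs(130)  # last exon -> escapes
  expect_false(r$nmd_predicted)
  expect_false("MISSING_RNA" %in% r$effects)
  # window boundary: escapes iff ptc > 120 - window
  expect_true(fs(70)$nmd_predicted)
  expect_false(fs(71)$nmd_predicted)
  expect_true(fs(100, window = 10)$nmd_predicted)
  expect_false(fs(111, window = 10)$nmd_predicted)
})

test_that("NMD escape is monotone in PTC position", {
  set.seed(42)
  for (i in 1:20) {
    n_ex <- sample(2:6, 1)
    ex <- sample(30:200, n_ex, replace = TRUE)
    total <- sum(ex)
    cds_len <- (total %/% 3L) * 3L
    tx <- transcript_model(sprintf("p%d", i), ex, 1L, cds_len)
    esc <- vapply(seq_len(total), function(p)
      !splice_consequence(tx, list(type = "deletion", length = 1,
                                   ptc_pos = p))$nmd_predicted, logical(1))
    # once escape starts it never reverts downstream
    expect_true(all(diff(esc) >= 0), label = sprintf("transcript %d", i))
    # and the last position always escapes
    expect_true(esc[total])
  }
})

test_that("splice_consequence edge cases error or no-op as specified", {
  tx <- toy_transcript()
  expect_error(splice_consequence(tx, list(type = "exon_skip", exon = 9)),
               class = "uns_model_error")
  one <- transcript_model("one", 90, 1, 90)
  expect_error(splice_consequence(one, list(type = "exon_skip", exon = 1)),
               class = "uns_model_error")
  # fully non-coding exon: no-op with empty tags
  utr <- transcript_model("utr", c(30, 60, 30), 31L, 90L)
  r <- splice_consequence(utr, list(type = "exon_skip", exon = 1))
  expect_equal(r$effects, character(0))
  expect_true(is.na(r$frame_status))
})

test_that("classify_variant follows the evidence rule table", {
  cs <- syn_case()
  # no evidence -> unverified prediction
  r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon)
  expect_equal(r$final_label, "UNVERIFIED_SYNONYMOUS_PREDICTED")
  expect_equal(r$evidence_status, "NONE")

  # ESS creation impairing splicing -> unsense with missing RNA
  r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon,
                        ev_for(cs$obs, "ESS", "MISSING_RNA", "RNA",
                               "minigene"))
  expect_equal(r$final_label, "UNSENSE")
  expect_equal(r$mechanisms, "ESS")
  expect_true("MISSING_RNA" %in% r$effects)

  # loss of an exonic miRNA site -> unsense
  r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon,
                        ev_for(cs$obs, "MIRNA_BINDING", "EXPRESSION_CHANGE",
                               "RNA", "reporter"))
  expect_equal(r$final_label, "UNSENSE")
  expect_equal(r$mechanisms, "MIRNA_BINDING")

  # phosphorylation loss -> synonymous with effect at protein level
  r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon,
                        ev_for(cs$obs, "PTM", "PTM_LOSS", "PROTEIN"))
  expect_equal(r$final_label, "SYNONYMOUS_WITH_EFFECT")
  expect_equal(r$levels, "PROTEIN")
  expect_equal(r$effects, "PTM_LOSS")

  # mRNA structure/stability and DNA-level TF binding stay with-effect
  for (m in list(c("MRNA_STRUCTURE_STABILITY", "RNA"),
                 c("TF_BINDING", "DNA"))) {
    r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon,
                          ev_for(cs$obs, m[1], "EXPRESSION_CHANGE", m[2]))
    expect_equal(r$final_label, "SYNONYMOUS_WITH_EFFECT", label = m[1])
    expect_equal(r$levels, m[2])
  }

  # all-no-effect evidence -> verified synonymous
  r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon,
                        ev_for(cs$obs, "NONE_OBSERVED", "NO_EFFECT", "RNA"))
  expect_equal(r$final_label, "VERIFIED_SYNONYMOUS")
  expect_equal(r$effects, "NO_EFFECT")
  expect_equal(r$evidence_status, "NO_EFFECT_SHOWN")

  # mixed levels: unsense dominates, all mechanisms reported
  mixed <- rbind(ev_for(cs$obs, "PTM", "PTM_LOSS", "PROTEIN"),
                 ev_for(cs$obs, "ESE", "EXON_SKIPPING", "RNA"))
  r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon, mixed)
  expect_equal(r$final_label, "UNSENSE")
  expect_setequal(r$mechanisms, c("PTM", "ESE"))
  expect_setequal(r$levels, c("PROTEIN", "RNA"))

  # conflict: NO_EFFECT plus effect evidence -> flag, label from effect
  confl <- rbind(ev_for(cs$obs, "NONE_OBSERVED", "NO_EFFECT", "RNA"),
                 ev_for(cs$obs, "ESS", "MISSING_RNA", "RNA"))
  r <- classify_variant(cs$obs, cs$ref_codon, cs$alt_codon, confl)
  expect_true(r$conflict)
  expect_equal(r$final_label, "UNSENSE")
})

test_that("codon level decides missense/nonsense/stop-loss regardless of evidence", {
  obs <- variant_observation("TXM", 4, "T", "A")
  ev <- ev_for(obs, "ESS", "MISSING_RNA", "RNA")
  r <- classify_variant(obs, "TTT", "ATT", ev)  # Phe -> Ile
  expect_equal(r$final_label, "MISSENSE")
  expect_equal(r$mechanisms, "ESS")  # evidence kept as co-annotation
  obs2 <- variant_observation("TXM", 4, "C", "T")
  r2 <- classify_variant(obs2, "CAG", "TAG", ev_for(obs2, "PTM", "PTM_LOSS",
                                                    "PROTEIN"))
  expect_equal(r2$final_label, "NONSENSE")
  obs3 <- variant_observation("TXM", 6, "A", "C")
  r3 <- classify_variant(obs3, "TGA", "TGC")  # stop loss -> missense label
  expect_equal(r3$codon_category, "STOP_LOSS")
  expect_equal(r3$final_label, "MISSENSE")
})

test_that("stop-to-stop changes route through the evidence rules", {
  obs <- variant_observation("TXM", 3, "A", "G")
  r <- classify_variant(obs, "TAA", "TAG")
  expect_equal(r$codon_category, "STOP_TO_STOP")
  expect_equal(r$final_label, "UNVERIFIED_SYNONYMOUS_PREDICTED")
  r <- classify_variant(obs, "TAA", "TAG",
                        ev_for(obs, "ESS", "MISSING_RNA", "RNA"))
  expect_equal(r$final_label, "UNSENSE")
})

test_that("classify_variant rejects inconsistent input and foreign evidence", {
  cs <- syn_case()
  expect_error(classify_variant(cs$obs, "GCA", "GTA"),
               class = "uns_input_error")  # codon base != obs ref base
  foreign <- evidence_record("OTHER:c.1A>G", "assay", "ESS", "MISSING_RNA",
                             "RNA")
  expect_error(classify_variant(cs$obs, cs$ref_codon, cs$alt_codon, foreign),
               class = "uns_linkage_error")
  expect_error(evidence_record("k", "a", "ESS", "MISSING_RNA", "PROTEIN"),
               class = "uns_input_error")  # mechanism level mismatch
  expect_error(evidence_record("k", "a", "ESS", "NOT_A_TAG", "RNA"),
               class = "uns_input_error")
})

test_that("classification is deterministic and always satisfies invariants", {
  set.seed(11)
  tab <- codon_table()
  mechs <- c(names(UNS_MECHANISMS), "NONE_OBSERVED")
  for (i in 1:60) {
    cod <- sample(names(tab), 1)
    p <- sample(1:3, 1)
    alts <- setdiff(c("A", "C", "G", "T"), substr(cod, p, p))
    alt <- cod
    substr(alt, p, p) <- sample(alts, 1)
    obs <- variant_observation("T", 3 * sample(1:50, 1) - 3 + p,
                               substr(cod, p, p), substr(alt, p, p))
    m <- sample(mechs, 1)
    ev <- if (m == "NONE_OBSERVED")
      ev_for(obs, m, "NO_EFFECT", "RNA")
    else ev_for(obs, m, setdiff(UNS_EFFECTS, "NO_EFFECT")[1],
                unname(UNS_MECHANISMS[m]))
    r1 <- classify_variant(obs, cod, alt, ev)
    r2 <- classify_variant(obs, cod, alt, ev)
    expect_identical(r1, r2)  # determinism; invariants checked internally
  }
})

test_that("audit verdicts and counts partition the records", {
  tx <- "TXA"
  mk <- function(pos, ref, alt, rc, ac, claim)
    data.frame(transcript_id = tx, cds_pos = pos, ref_base = ref,
               alt_base = alt, ref_codon = rc, alt_codon = ac,
               claimed_label = claim, stringsAsFactors = FALSE)
  # 10 records: 4 evidence-free claimed synonymous, 1 synonymous with ESS
  # evidence claimed synonymous, 1 verified-synonymous claim, 2 correct
  # missense, 1 wrong claim, 1 missing claim
  v <- rbind(
    mk(3, "C", "T", "GGC", "GGT", "synonymous"),
    mk(6, "C", "T", "GGC", "GGT", "synonymous"),
    mk(9, "A", "G", "CCA", "CCG", "synonymous"),
    mk(12, "T", "C", "CGT", "CGC", "synonymous"),
    mk(15, "C", "T", "AGC", "AGT", "synonymous"),
    mk(18, "G", "A", "CTG", "CTA", "synonymous"),
    mk(20, "T", "A", "TTT", "TAT", "missense"),
    mk(23, "T", "A", "GTC", "GAC", "missense"),
    mk(26, "A", "T", "CAG", "CTG", "nonsense"),
    mk(29, "C", "G", "TCA", "TGA", NA))
  obs5 <- variant_observation(tx, 15, "C", "T")
  obs6 <- variant_observation(tx, 18, "G", "A")
  ev <- rbind(ev_for(obs5, "ESS", "MISSING_RNA", "RNA"),
              ev_for(obs6, "NONE_OBSERVED", "NO_EFFECT", "RNA"))
  rep <- suppressWarnings(audit_annotations(v, ev))
  s <- rep$summary
  expect_equal(s$n_records, 10L)
  expect_equal(s$OVERCLAIMED_SYNONYMOUS, 5L)  # 4 evidence-free + 1 unsense
  expect_equal(s$CONFIRMED, 3L)  # verified-syn claim + 2 missense
  expect_equal(s$MISLABELED, 1L)  # "nonsense" claim on a missense change
  expect_equal(s$n_skipped, 1L)
  expect_equal(s$CONFIRMED + s$OVERCLAIMED_SYNONYMOUS + s$MISLABELED +
               s$n_skipped, s$n_records)
  expect_warning(audit_annotations(v[10, , drop = FALSE], NULL),
                 "no claimed label")
  recs <- rep$records
  expect_equal(recs$verdict[5], "OVERCLAIMED_SYNONYMOUS")
  expect_equal(recs$computed_label[5], "UNSENSE")
  expect_equal(recs$verdict[6], "CONFIRMED")  # verified synonymous
})
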