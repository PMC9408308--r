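# shared in-code fixtures for the test suite

# a 3-exon transcript whose CDS covers positions 10..159 (150 nt, 50 codons)
toy_transcript <- function(id = "TX1", cds_seq = NULL) {
  if (is.null(cds_seq))
    cds_seq <- paste0(paste(rep("ATG", 49), collapse = ""), "TAA")
  transcript_model(id, exon_lengths = c(60L, 60L, 60L),
                   cds_start = 10L, cds_end = 159L, strand = "+",
                   cds_seq = cds_seq)
}

# an observation plus consistent codons for a synonymous change
# (GGC -> GGT, Gly -> Gly, third position)
syn_case <- function(tx = "TXS", cds_pos = 6L) {
  list(obs = variant_observation(tx, cds_pos, "C", "T"),
       ref_codon = "GGC", alt_codon = "GGT")
}

ev_for <- function(obs, mechanism, effect, level, assay = "assay") {
  evidence_record(variant_key(obs), assay, mechanism, effect, level)
}
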