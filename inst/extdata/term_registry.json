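[
  {
    "term_id": "rna_substitution",
    "name": "RNA substitution",
    "definition": "Replacement of one nucleotide by another in an RNA molecule; root of the six substitution categories (transition, transversion, missense, nonsense, synonymous, unsense).",
    "level": "RNA",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "transition",
    "name": "transition",
    "definition": "Substitution in which a purine is replaced by the other purine, or a pyrimidine by the other pyrimidine; describes the chemical change of the base group.",
    "level": "RNA",
    "parent": "rna_substitution",
    "vario_code": null
  },
  {
    "term_id": "transversion",
    "name": "transversion",
    "definition": "Substitution in which a purine is replaced by a pyrimidine or vice versa; describes the chemical change of the base group.",
    "level": "RNA",
    "parent": "rna_substitution",
    "vario_code": null
  },
  {
    "term_id": "missense",
    "name": "missense",
    "definition": "Coding-region substitution that replaces the encoded amino acid by a different amino acid.",
    "level": "RNA",
    "parent": "rna_substitution",
    "vario_code": null
  },
  {
    "term_id": "nonsense",
    "name": "nonsense",
    "definition": "Coding-region substitution that introduces a translation stop codon at the variation site.",
    "level": "RNA",
    "parent": "rna_substitution",
    "vario_code": null
  },
  {
    "term_id": "synonymous",
    "name": "synonymous",
    "definition": "Coding-region substitution that replaces a codon by another codon for the same amino acid and has no verified effect on expression or protein production.",
    "level": "RNA",
    "parent": "rna_substitution",
    "vario_code": null
  },
  {
    "term_id": "unsense",
    "name": "unsense",
    "definition": "Substitution in the mRNA coding region that affects gene expression and protein production without introducing a stop codon at the variation site; mechanisms are impaired splicing, impaired splicing regulation (ESE/ESS) or impaired miRNA-mediated regulation of expression.",
    "level": "RNA",
    "parent": "rna_substitution",
    "vario_code": null
  },
  {
    "term_id": "mech_tf_binding",
    "name": "TF_BINDING",
    "definition": "Alteration of a transcription-factor binding site overlapping the coding sequence (dual-use codon), affecting transcription.",
    "level": "DNA",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_splice_site",
    "name": "SPLICE_SITE",
    "definition": "Alteration or generation of an exonic splice site.",
    "level": "RNA",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_ese",
    "name": "ESE",
    "definition": "Alteration of an exonic splicing enhancer motif regulating splice-site use.",
    "level": "RNA",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_ess",
    "name": "ESS",
    "definition": "Alteration or creation of an exonic splicing silencer motif regulating splice-site use.",
    "level": "RNA",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_mrna_structure_stability",
    "name": "MRNA_STRUCTURE_STABILITY",
    "definition": "Change to mRNA secondary structure or intracellular stability, affecting expression and protein abundance.",
    "level": "RNA",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_mirna_binding",
    "name": "MIRNA_BINDING",
    "definition": "Alteration of an exonic microRNA binding site, impairing miRNA regulation of gene expression.",
    "level": "RNA",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_codon_usage_translation",
    "name": "CODON_USAGE_TRANSLATION",
    "definition": "Replacement by a codon of different usage frequency, affecting translation speed via codon usage bias and aminoacyl-tRNA availability.",
    "level": "PROTEIN",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_cotranslational_folding",
    "name": "COTRANSLATIONAL_FOLDING",
    "definition": "Change in translation kinetics altering co-translational protein folding, with possible conformational or activity change.",
    "level": "PROTEIN",
    "parent": null,
    "vario_code": null
  },
  {
    "term_id": "mech_ptm",
    "name": "PTM",
    "definition": "Change affecting a post-translational modification of the coded protein, with effects on regulation, stability or activity.",
    "level": "PROTEIN",
    "parent": null,
    "vario_code": null
  }
]
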